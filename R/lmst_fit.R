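#' Fit the Lorenz-Mie hologram model to an image
#'
#' Nonlinear least squares of the forward model ([render_hologram()],
#' unquantized) against an observed hologram, via Levenberg-Marquardt.
#' By default the bead radius and medium index are held fixed and the six
#' pattern parameters `x`, `y`, `z`, `n_p`, plus the scaling coefficients
#' `alpha`, `beta`, `gamma_px`, are free.
#'
#' @param image Observed hologram matrix (8-bit counts or float).
#' @param model Initial [optical_model()].
#' @param pose Initial `c(x, y, z)` pose (nm).
#' @param fixed Character vector of parameters to hold fixed, among
#'   `x_nm`, `y_nm`, `z_nm`, `a_um`, `n_p`, `n_m`, `alpha`, `beta`,
#'   `gamma_px`.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return Object of class `lmst_fit`: fitted `model` and `pose`,
#'   coefficient table with asymptotic standard errors, `residual` image
#'   (data - model), `converged` flag and optimizer `info`. Non-convergence
#'   is flagged, not thrown.
#' @examples
#' \donttest{
#' m <- optical_model()
#' img <- render_hologram(m, c(0, 0, 8000), roi = 64, quantize = FALSE)
#' fit <- fit_lmst(img, m, c(10, -10, 8100))
#' coef(fit)
#' }
#' @export
fit_lmst <- function(image, model, pose, fixed = c("a_um", "n_m"),
                     max_iter = 60L) {
  stopifnot(is.matrix(image), inherits(model, "optical_model"),
            length(pose) == 3)
  s <- nrow(image)
  all_par <- c(x_nm = pose[1], y_nm = pose[2], z_nm = pose[3],
               a_um = model$a_um, n_p = model$n_p, n_m = model$n_m,
               alpha = model$alpha, beta = model$beta,
               gamma_px = model$gamma_px)
  bad <- setdiff(fixed, names(all_par))
  if (length(bad)) stop("unknown fixed parameter(s): ",
                        paste(bad, collapse = ", "))
  free <- setdiff(names(all_par), fixed)
  # parameters are rescaled to comparable magnitudes for the optimizer
  scales <- c(x_nm = 100, y_nm = 100, z_nm = 1000, a_um = 0.1, n_p = 0.1,
              n_m = 0.1, alpha = 0.1, beta = 10, gamma_px = 10)
  build <- function(th_scaled) {
    p <- all_par
    p[free] <- th_scaled * scales[free]
    m <- optical_model(a_um = p["a_um"], n_p = p["n_p"], n_m = p["n_m"],
                       lambda_nm = model$lambda_nm, alpha = p["alpha"],
                       beta = p["beta"], gamma_px = p["gamma_px"],
                       pixel_nm = model$pixel_nm)
    list(model = m, pose = unname(p[c("x_nm", "y_nm", "z_nm")]))
  }
  resid_fun <- function(th_scaled) {
    b <- tryCatch(build(th_scaled), error = function(e) NULL)
    if (is.null(b)) return(rep(1e6, length(image)))
    pred <- suppressWarnings(
      render_hologram(b$model, b$pose, roi = s, quantize = FALSE))
    as.numeric(image - pred)
  }
  th0 <- all_par[free] / scales[free]
  nls_out <- minpack.lm::nls.lm(
    par = th0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))
  th <- nls_out$par
  b <- build(th)
  res <- matrix(resid_fun(th), s, s)
  dof <- length(image) - length(free)
  sigma2 <- sum(res^2) / dof
  se <- rep(NA_real_, length(free))
  cov_ok <- tryCatch({
    cv <- solve(nls_out$hessian) * 2 * sigma2
    se <- sqrt(pmax(diag(cv), 0)) * scales[free]
    TRUE
  }, error = function(e) FALSE)
  converged <- nls_out$info %in% 1:4
  coefs <- data.frame(estimate = unname(th * scales[free]),
                      std_error = unname(se),
                      row.names = free)
  structure(
    list(model = b$model, pose = b$pose, coefficients = coefs,
         residual = res, converged = converged, info = nls_out$info,
         message = nls_out$message, sigma = sqrt(sigma2),
         fixed = all_par[fixed], cov_ok = cov_ok),
    class = "lmst_fit")
}

#' @export
print.lmst_fit <- function(x, ...) {
  cat("Lorenz-Mie hologram fit",
      if (!x$converged) "(DID NOT CONVERGE)" else "", "\n")
  printCoefmat(as.matrix(x$coefficients), digits = 4)
  cat(sprintf("fixed: %s\n",
              paste(names(x$fixed), signif(x$fixed, 4), sep = " = ",
                    collapse = ", ")))
  cat(sprintf("residual SD %.3f gray (optimizer info %d)\n", x$sigma,
              x$info))
  invisible(x)
}

#' @export
coef.lmst_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))
}

#' @export
residuals.lmst_fit <- function(object, ...) object$residual
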