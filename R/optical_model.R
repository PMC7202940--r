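#' Optical model of a bead hologram
#'
#' Bundles the bead, medium and illumination parameters that define the
#' Lorenz-Mie forward model of an in-line hologram. The defaults are the
#' parameters that reproduce realistic diffraction patterns of 1.0 um
#' diameter paramagnetic beads on a 645 nm LED magnetic-tweezers setup
#' (112 nm pixels).
#'
#' @param a_um Bead radius (um).
#' @param n_p Bead refractive index (must exceed `n_m`).
#' @param n_m Medium refractive index (>= 1).
#' @param lambda_nm Vacuum wavelength of the illumination (nm).
#' @param alpha Illumination scale of the scattered field (dimensionless,
#'   about 1).
#' @param beta Intensity scale: the background grayscale level of the
#'   normalized image.
#' @param gamma_px Width (pixels) of the raised-cosine coherence envelope
#'   that truncates the ring pattern (finite spatial coherence of the LED).
#' @param pixel_nm Camera pixel size in the object plane (nm/pixel).
#' @return An object of class `optical_model`.
#' @examples
#' m <- optical_model()
#' size_parameter(m)
#' @export
optical_model <- function(a_um = 0.5, n_p = 1.9, n_m = 1.33,
                          lambda_nm = 645, alpha = 1.0, beta = 54,
                          gamma_px = 45, pixel_nm = 112) {
  stopifnot(a_um > 0, n_p > n_m, n_m >= 1, lambda_nm > 0,
            alpha >= 0, beta > 0, gamma_px > 0, pixel_nm > 0)
  structure(
    list(a_um = a_um, n_p = n_p, n_m = n_m, lambda_nm = lambda_nm,
         alpha = alpha, beta = beta, gamma_px = gamma_px,
         pixel_nm = pixel_nm),
    class = "optical_model")
}

#' Mie size parameter of an optical model
#'
#' @param model An [optical_model()].
#' @return `2 pi n_m a / lambda` (dimensionless).
#' @export
size_parameter <- function(model) {
  stopifnot(inherits(model, "optical_model"))
  2 * pi * model$n_m * model$a_um * 1000 / model$lambda_nm
}

#' @export
print.optical_model <- function(x, ...) {
  cat("Optical model (Lorenz-Mie hologram forward model)\n")
  cat(sprintf("  bead radius a      : %.3f um (index n_p = %.3f)\n",
              x$a_um, x$n_p))
  cat(sprintf("  medium index n_m   : %.3f, wavelength %.0f nm\n",
              x$n_m, x$lambda_nm))
  cat(sprintf("  alpha = %.2f, beta = %.1f gray, gamma = %.0f px, pixel = %.0f nm\n",
              x$alpha, x$beta, x$gamma_px, x$pixel_nm))
  cat(sprintf("  size parameter x = %.3f, relative index m = %.4f\n",
              size_parameter(x), x$n_p / x$n_m))
  invisible(x)
}

#' Write / read an optical model as JSON
#'
#' @param model An [optical_model()].
#' @param path File path.
#' @return `read_optical_model` returns an [optical_model()];
#'   `write_optical_model` returns `path` invisibly.
#' @export
write_optical_model <- function(model, path) {
  stopifnot(inherits(model, "optical_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_optical_model
#' @export
read_optical_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(optical_model, x[names(x) %in% names(formals(optical_model))])
}
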