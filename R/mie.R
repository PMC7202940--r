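#' Series truncation order for the Mie partial-wave expansion
#'
#' Wiscombe-style cutoff `N = x + 4 x^(1/3) + 2`, rounded up. Beyond this
#' order the Riccati-Bessel coefficients decay super-exponentially for real
#' size parameters, so the truncated sum is converged to well below 1e-10
#' relative for the bead sizes used here.
#'
#' @param x Size parameter `2 pi n_m a / lambda` (dimensionless).
#' @return Integer truncation order.
#' @export
mie_nmax <- function(x) {
  as.integer(ceiling(x + 4 * x^(1 / 3) + 2))
}

#' Mie partial-wave coefficients a_n, b_n
#'
#' Computes the electric and magnetic partial-wave coefficients of a
#' homogeneous sphere by the logarithmic-derivative downward recursion
#' (Bohren-Huffman scheme): `D_n(mx)` by downward recurrence started well
#' above the truncation order, Riccati-Bessel `psi_n`, `chi_n` by upward
#' recurrence.
#'
#' @param x Size parameter `2 pi n_m a / lambda`; must be positive.
#' @param m Relative refractive index `n_p / n_m` (real; the beads modelled
#'   here are non-absorbing).
#' @param nmax Truncation order; defaults to [mie_nmax()].
#' @return List with complex vectors `a` and `b` of length `nmax`, plus the
#'   inputs `x`, `m`, `nmax`.
#' @examples
#' cf <- mie_coefficients(6.477, 1.9 / 1.33)
#' Mod(cf$a[1])
#' @export
mie_coefficients <- function(x, m, nmax = mie_nmax(x)) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 0,
            is.numeric(m), length(m) == 1L, m > 0)
  nmax <- as.integer(nmax)
  if (nmax < 1L) stop("'nmax' must be at least 1")
  mx <- m * x
  # downward recurrence for the logarithmic derivative D_n(mx)
  nmx <- max(nmax, ceiling(abs(mx))) + 16L
  D <- numeric(nmx)
  for (n in nmx:2L) {
    D[n - 1L] <- n / mx - 1 / (D[n] + n / mx)
  }
  a <- b <- complex(nmax)
  # Riccati-Bessel psi_n = x j_n(x), chi_n = -x y_n(x), xi_n = psi_n - i chi_n
  psi0 <- cos(x)   # psi_{n-1} seed
  psi1 <- sin(x)   # psi_n seed
  chi0 <- -sin(x)
  chi1 <- cos(x)
  xi1 <- complex(real = psi1, imaginary = -chi1)
  for (n in seq_len(nmax)) {
    psi <- (2 * n - 1) / x * psi1 - psi0
    chi <- (2 * n - 1) / x * chi1 - chi0
    xi <- complex(real = psi, imaginary = -chi)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    a[n] <- (da * psi - psi1) / (da * xi - xi1)
    b[n] <- (db * psi - psi1) / (db * xi - xi1)
    psi0 <- psi1; psi1 <- psi
    chi0 <- chi1; chi1 <- chi
    xi1 <- xi
  }
  if (!all(is.finite(Mod(a))) || !all(is.finite(Mod(b)))) {
    stop("Mie series did not evaluate to finite coefficients; ",
         "check x = ", x, ", m = ", m, ", nmax = ", nmax)
  }
  # convergence diagnostic: the last retained term must be negligible
  tail_mag <- max(Mod(a[nmax]), Mod(b[nmax]))
  if (tail_mag > 1e-6) {
    stop("Mie series not converged at nmax = ", nmax,
         " (last coefficient magnitude ", signif(tail_mag, 3),
         "); increase 'nmax'")
  }
  list(a = a, b = b, x = x, m = m, nmax = nmax)
}

#' Far-field scattering amplitudes S1, S2
#'
#' Sums the partial-wave series with the angular functions `pi_n`, `tau_n`
#' (upward recurrence in the scattering angle cosine). `S1` is perpendicular,
#' `S2` parallel polarization; the scalar model used by the simulator takes
#' their mean.
#'
#' @param coefs Output of [mie_coefficients()].
#' @param cos_theta Numeric vector of scattering-angle cosines.
#' @return List of complex vectors `S1`, `S2` matching `cos_theta`.
#' @export
mie_s_amplitudes <- function(coefs, cos_theta) {
  mu <- as.numeric(cos_theta)
  nmax <- coefs$nmax
  S1 <- S2 <- complex(length(mu))
  p_prev <- numeric(length(mu))      # pi_0 = 0
  p_cur <- rep(1, length(mu))        # pi_1 = 1
  for (n in seq_len(nmax)) {
    if (n > 1L) {
      p_new <- (2 * n - 1) / (n - 1) * mu * p_cur - n / (n - 1) * p_prev
      p_prev <- p_cur
      p_cur <- p_new
    }
    tau <- n * mu * p_cur - (n + 1) * p_prev
    fac <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fac * (coefs$a[n] * p_cur + coefs$b[n] * tau)
    S2 <- S2 + fac * (coefs$a[n] * tau + coefs$b[n] * p_cur)
  }
  list(S1 = S1, S2 = S2)
}

#' Scalar Lorenz-Mie scattered field amplitude
#'
#' Evaluates the scattered field at a displacement from the bead center in
#' the scalar, far-field approximation: the partial-wave sum
#' `(S1 + S2) / 2` at the scattering angle, times the outgoing spherical
#' wave `exp(i k R) / (-i k R)` with `R` the 3D bead-to-point distance and
#' `k = 2 pi n_m / lambda` the wavenumber in the medium. Polarization is
#' dropped: the tracker exploits only the circular symmetry of the pattern.
#'
#' @param model An [optical_model()].
#' @param displacement Numeric length-3 vector or n x 3 matrix of
#'   displacements (nm) from the bead center; column 3 is the axial distance
#'   along the propagation direction.
#' @return Complex vector of field amplitudes.
#' @export
scattering_amplitude <- function(model, displacement) {
  stopifnot(inherits(model, "optical_model"))
  d <- if (is.matrix(displacement)) displacement else matrix(displacement, ncol = 3)
  R <- sqrt(rowSums(d^2))
  a_nm <- model$a_um * 1000
  if (any(R <= a_nm)) {
    stop("displacement inside the bead (|d| <= a); the scattered field is ",
         "only evaluated outside the sphere")
  }
  k <- 2 * pi * model$n_m / model$lambda_nm
  cf <- mie_coefficients(size_parameter(model), model$n_p / model$n_m)
  S <- mie_s_amplitudes(cf, abs(d[, 3]) / R)
  0.5 * (S$S1 + S$S2) * exp(1i * k * R) / (-1i * k * R)
}
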