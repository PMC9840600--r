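# Orthonormal Hermite functions adapted to the OU stationary Gaussian.
#
# phi_p are the L^2(d eta)-orthonormal eigenfunctions of the OU Fokker-Planck
# operator written in symmetrized form: phi_0(eta)^2 is the Gaussian density
# with variance sigma^2 and the ladder relation
#   eta * phi_p = sigma * (sqrt(p+1) phi_{p+1} + sqrt(p) phi_{p-1})
# holds. Densities are expanded as phi_0(eta) * sum_p c_p phi_p(eta), so the
# OU operator acts diagonally with eigenvalues -p/tau on the expansion.

#' Evaluate the orthonormal Hermite functions of the OU operator
#'
#' @param eta numeric vector of noise values.
#' @param p_max highest index.
#' @param sigma noise standard deviation (sets the Gaussian width).
#' @return A \code{length(eta) x (p_max + 1)} matrix whose column \code{p + 1}
#'   holds \code{phi_p(eta)}.
#' @keywords internal
hermite_functions <- function(eta, p_max, sigma) {
  stopifnot(sigma > 0, p_max >= 0)
  Phi <- matrix(0, length(eta), p_max + 1L)
  # phi_0 = (2 pi sigma^2)^(-1/4) exp(-eta^2/(4 sigma^2)); phi_0^2 = N(0, sigma^2)
  Phi[, 1L] <- (2 * pi * sigma^2)^(-1 / 4) * exp(-eta^2 / (4 * sigma^2))
  if (p_max >= 1L)
    Phi[, 2L] <- (eta / sigma) * Phi[, 1L]
  if (p_max >= 2L) {
    for (p in 1L:(p_max - 1L)) {
      # upward ladder: phi_{p+1} = (eta phi_p / sigma - sqrt(p) phi_{p-1}) / sqrt(p+1)
      Phi[, p + 2L] <- ((eta / sigma) * Phi[, p + 1L] -
                          sqrt(p) * Phi[, p]) / sqrt(p + 1)
    }
  }
  Phi
}
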