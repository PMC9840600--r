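# Stationary solution of the theta-neuron/OU Fokker-Planck equation by the
# matrix-continued-fraction (MCF) method.
#
# The stationary density is expanded in Fourier modes exp(i n theta) over the
# phase and Hermite functions phi_p over the noise,
#   P0(theta, eta) = phi_0(eta)/(2 pi) * sum_{n,p} c_{n,p} e^{i n theta} phi_p(eta),
# with c_{0,0} = 1 fixed by normalization and c_{-n,p} = Conj(c_{n,p}).
# Substituting into the stationary equation yields the tridiagonal matrix
# recurrence K_n c_n = c_{n-1} + c_{n+1}, solved by the continued fraction
# S_{n-1} = (K_n - S_n)^{-1} with S_{n_max} = 0 and c_{n+1} = S_n c_n.

#' Diagonal relaxation matrix of the OU expansion
#'
#' Entries \code{i * q / tau} on the diagonal, \code{q = 0..p_max}: the
#' eigenvalues of the OU generator on the Hermite ladder, made imaginary by
#' the division by \code{-i n} that brings the mode-n equation to recurrence
#' form.
#'
#' @param p_max highest Hermite index.
#' @param tau noise correlation time (in membrane time units).
#' @return Complex \code{(p_max+1) x (p_max+1)} diagonal matrix.
#' @export
build_A <- function(p_max, tau) {
  stopifnot(tau > 0)
  diag(1i * (0:p_max) / tau, nrow = p_max + 1L)
}

#' Symmetric tridiagonal drift matrix of the Fourier-Hermite recurrence
#'
#' Diagonal \code{(1 - mu)/2}; entries \code{-(sigma/2) sqrt(p + 1)} between
#' neighbouring Hermite indices p and p + 1 (the ladder coupling of the
#' multiplicative noise term \code{(1 + cos theta) eta}).
#'
#' @param p_max highest Hermite index (\code{p_max >= 1}).
#' @param mu mean input.
#' @param sigma noise standard deviation.
#' @return Real symmetric \code{(p_max+1) x (p_max+1)} matrix.
#' @export
build_B <- function(p_max, mu, sigma) {
  stopifnot(p_max >= 1)
  m <- p_max + 1L
  B <- diag((1 - mu) / 2, m)
  idx <- seq_len(p_max)
  off <- -(sigma / 2) * sqrt(idx)
  B[cbind(idx, idx + 1L)] <- off
  B[cbind(idx + 1L, idx)] <- off
  B
}

# Inverse of B with a conditioning guard. B is exactly singular e.g. at
# mu = 1 with odd dimension (zero-diagonal symmetric tridiagonal matrices of
# odd size are singular); the advice to the user is to change p_max parity.
invert_B <- function(B, cond_limit = 1e12) {
  rc <- rcond(B)
  if (!is.finite(rc) || rc < 1 / cond_limit)
    stop("matrix B is singular or badly conditioned (rcond = ",
         format(rc, digits = 3),
         "); change p_max (e.g. its parity: at mu = 1, B is singular ",
         "whenever p_max + 1 is odd)")
  solve(B)
}

#' Recurrence matrix K_n of the matrix continued fraction
#'
#' \code{K_n = 2 (B^{-1} - I) - B^{-1} A / n}.
#'
#' @param n Fourier index (\code{n >= 1}).
#' @param A output of \code{\link{build_A}}.
#' @param B output of \code{\link{build_B}}.
#' @return Complex matrix.
#' @export
build_K <- function(n, A, B) {
  stopifnot(n >= 1)
  Binv <- invert_B(B)
  2 * (Binv - diag(nrow(B))) - (Binv %*% A) / n
}

#' Backward continued-fraction recursion for the transition matrices
#'
#' Starting from \code{S_{n_max} = 0}, iterates
#' \code{S_{n-1} = (K_n - S_n)^{-1}} down to \code{S_0}. The transition
#' matrices propagate the coefficient vectors upward in the Fourier index:
#' \code{c_{n+1} = S_n c_n}.
#'
#' @param params a \code{theta_params} object.
#' @param trunc a \code{trunc_spec}.
#' @return List of complex matrices \code{S[[n + 1]] = S_n},
#'   \code{n = 0..n_max - 1}.
#' @export
continued_fraction_S <- function(params, trunc) {
  n_max <- trunc$n_max
  p_max <- trunc$p_max
  A <- build_A(p_max, params$tau)
  B <- build_B(p_max, params$mu, params$sigma)
  Binv <- invert_B(B)
  if (max(abs(A)) == 0 && max(abs(Binv - diag(p_max + 1L))) < 1e-14)
    stop("degenerate configuration (A = 0, B = identity): ",
         "K_n vanishes and the continued fraction diverges")
  K0 <- 2 * (Binv - diag(p_max + 1L))
  BinvA <- Binv %*% A
  S <- vector("list", n_max)
  Sn <- matrix(0 + 0i, p_max + 1L, p_max + 1L)  # S_{n_max} = 0 truncation
  for (n in n_max:1) {
    M <- (K0 - BinvA / n) - Sn
    Sn <- tryCatch(solve(M),
                   error = function(e)
                     stop("singular K_n - S_n at n = ", n, ": ",
                          conditionMessage(e)))
    S[[n]] <- Sn
  }
  S
}

#' Stationary expansion coefficients
#'
#' Forward application of the transition matrices to
#' \code{c_0 = (1, 0, 0, ...)^T}; negative Fourier indices are filled by
#' conjugation (the density is real).
#'
#' @inheritParams continued_fraction_S
#' @return An object of class \code{"mcf_coeffs"}: a complex
#'   \code{(2 n_max + 1) x (p_max + 1)} matrix, rows indexed by
#'   \code{n = -n_max..n_max} (dimnames give the indices), with attributes
#'   \code{n_max}, \code{p_max}.
#' @export
stationary_coefficients <- function(params, trunc) {
  S <- continued_fraction_S(params, trunc)
  n_max <- trunc$n_max
  p_max <- trunc$p_max
  C <- matrix(0 + 0i, 2L * n_max + 1L, p_max + 1L,
              dimnames = list(n = as.character(-n_max:n_max),
                              p = as.character(0:p_max)))
  i0 <- n_max + 1L  # row of n = 0
  cn <- c(1 + 0i, rep(0 + 0i, p_max))
  C[i0, ] <- cn
  for (n in 0:(n_max - 1L)) {
    cn <- drop(S[[n + 1L]] %*% cn)
    C[i0 + n + 1L, ] <- cn
    C[i0 - n - 1L, ] <- Conj(cn)
  }
  structure(C, n_max = n_max, p_max = p_max, class = "mcf_coeffs")
}

# Residual of the three-term recurrence K_n c_n = c_{n-1} + c_{n+1},
# maximized over 1 <= n < n_max. Direct-substitution diagnostic.
recurrence_residual <- function(C, params, trunc) {
  n_max <- trunc$n_max
  p_max <- trunc$p_max
  A <- build_A(p_max, params$tau)
  B <- build_B(p_max, params$mu, params$sigma)
  Binv <- invert_B(B)
  K0 <- 2 * (Binv - diag(p_max + 1L))
  BinvA <- Binv %*% A
  i0 <- n_max + 1L
  res <- 0
  for (n in 1:(n_max - 1L)) {
    Kn <- K0 - BinvA / n
    r <- Kn %*% C[i0 + n, ] - C[i0 + n - 1L, ] - C[i0 + n + 1L, ]
    res <- max(res, max(Mod(r)))
  }
  res
}

#' Stationary firing rate by the matrix-continued-fraction method
#'
#' Computes the stationary rate from the coefficient formula
#' \code{r0 = ((1 + mu) - (1 - mu) Re c_{1,0} + sigma Re c_{1,1}) / (2 pi)}
#' and cross-checks it against the independent threshold-current expression
#' \code{r0 = (1/pi) sum_n (-1)^n c_{n,0}} (the eta-integrated probability
#' current through theta = pi, where the phase velocity equals 2). Relative
#' disagreement beyond \code{check_tol} signals insufficient truncation.
#'
#' @inheritParams continued_fraction_S
#' @param check_tol relative tolerance for the agreement of the two rate
#'   formulas (default 1e-6).
#' @param coeffs optionally, a precomputed \code{\link{stationary_coefficients}}
#'   result for these \code{params} and \code{trunc}.
#' @return List with \code{rate} (coefficient formula), \code{rate_check}
#'   (threshold formula), \code{coeffs}, \code{params}, \code{trunc}.
#' @export
stationary_rate <- function(params, trunc = trunc_spec(),
                            check_tol = 1e-6, coeffs = NULL) {
  C <- if (is.null(coeffs)) stationary_coefficients(params, trunc) else coeffs
  i0 <- trunc$n_max + 1L
  mu <- params$mu
  r26 <- ((1 + mu) - (1 - mu) * Re(C[i0 + 1L, 1L]) +
            params$sigma * Re(C[i0 + 1L, 2L])) / (2 * pi)
  r21 <- rate_from_threshold(C)
  denom <- max(abs(r26), abs(r21), .Machine$double.eps)
  # absolute floor: agreement of two essentially-zero rates is agreement
  if (abs(r26 - r21) > check_tol * denom + 1e-12)
    stop(sprintf(
      "stationary rate formulas disagree (coefficient %.10g vs threshold %.10g, rel %.3g): increase n_max/p_max",
      r26, r21, abs(r26 - r21) / denom))
  list(rate = r26, rate_check = r21, coeffs = C,
       params = params, trunc = trunc)
}

# Rate from the probability density at the threshold phase (valid for any
# coefficient set a_{n,p}; uses only p = 0 because int phi_0 phi_p = delta_p0):
# r = (1/pi) sum_n (-1)^n a_{n,0}.
rate_from_threshold <- function(C) {
  n_max <- attr(C, "n_max")
  n_idx <- -n_max:n_max
  Re(sum((-1)^n_idx * C[, 1L]))/pi
}

#' Marginal phase density from the stationary coefficients
#'
#' \code{P0(theta) = (1/2 pi) sum_n c_{n,0} e^{i n theta}}.
#'
#' @param params a \code{theta_params} object.
#' @param trunc a \code{trunc_spec}.
#' @param theta_grid phases in \code{(-pi, pi]}.
#' @param coeffs optional precomputed coefficients.
#' @param neg_tol tolerance for truncation-induced negativity (warns beyond).
#' @return Numeric vector of density values on \code{theta_grid}.
#' @export
marginal_phase_density <- function(params, trunc = trunc_spec(), theta_grid,
                                   coeffs = NULL, neg_tol = 1e-6) {
  C <- if (is.null(coeffs)) stationary_coefficients(params, trunc) else coeffs
  n_max <- attr(C, "n_max")
  E <- exp(1i * outer(theta_grid, -n_max:n_max))
  dens <- Re(E %*% C[, 1L]) / (2 * pi)
  if (min(dens) < -neg_tol)
    warning("marginal phase density negative beyond tolerance (",
            format(min(dens), digits = 3), "): truncation too low")
  drop(dens)
}

#' Joint stationary density of phase and noise
#'
#' Reconstructs \code{P0(theta, eta)} including the Gaussian prefactor
#' \code{phi_0(eta)} of the Hermite expansion.
#'
#' @inheritParams marginal_phase_density
#' @param eta_grid noise values.
#' @return Matrix of density values, \code{length(theta_grid) x length(eta_grid)}.
#' @export
joint_density <- function(params, trunc = trunc_spec(), theta_grid, eta_grid,
                          coeffs = NULL) {
  C <- if (is.null(coeffs)) stationary_coefficients(params, trunc) else coeffs
  n_max <- attr(C, "n_max")
  p_max <- attr(C, "p_max")
  E <- exp(1i * outer(theta_grid, -n_max:n_max))
  Phi <- hermite_functions(eta_grid, p_max, params$sigma)
  core <- Re(E %*% C %*% t(Phi)) / (2 * pi)
  sweep(core, 2L, Phi[, 1L], `*`)
}
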