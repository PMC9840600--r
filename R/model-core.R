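#' Model parameters for the theta neuron with Ornstein-Uhlenbeck input
#'
#' Bundles the three parameters of the spontaneous (signal-free) model: the
#' mean input \code{mu} (bifurcation parameter of the SNIC normal form), the
#' standard deviation \code{sigma} of the Ornstein-Uhlenbeck (OU) noise, and
#' its correlation time \code{tau}. All times are measured in units of the
#' membrane time constant, so rates come out in units of the inverse membrane
#' time; divide by the membrane time (in seconds) to convert to Hz.
#'
#' @param mu dimensionless mean input; \code{mu < 0} is the excitable regime,
#'   \code{mu > 0} the mean-driven (tonically firing) regime.
#' @param sigma noise standard deviation (dimensionless), \code{sigma >= 0}.
#' @param tau noise correlation time in units of the membrane time constant,
#'   \code{tau > 0}.
#' @param scaling one of \code{"raw"}, \code{"constant_variance"} (sigma is
#'   held fixed as tau varies; the conventional choice is sigma^2 = 1) or
#'   \code{"constant_intensity"} (the intensity D = sigma^2 tau is held
#'   fixed; conventional choice D = 1).
#' @return An object of class \code{"theta_params"}: a list with fields
#'   \code{mu}, \code{sigma}, \code{tau}, \code{scaling} and the derived
#'   noise intensity \code{D = sigma^2 * tau}.
#' @examples
#' p <- theta_params(mu = 0.5, sigma = 1, tau = 1)
#' p$D
#' @export
theta_params <- function(mu, sigma, tau,
                         scaling = c("raw", "constant_variance",
                                     "constant_intensity")) {
  scaling <- match.arg(scaling)
  stopifnot(is.finite(mu), length(mu) == 1L,
            is.finite(sigma), sigma >= 0,
            is.finite(tau), tau > 0)
  structure(list(mu = mu, sigma = sigma, tau = tau,
                 D = sigma^2 * tau, scaling = scaling),
            class = "theta_params")
}

#' @export
print.theta_params <- function(x, ...) {
  cat(sprintf(
    "theta neuron parameters: mu = %g, sigma = %g, tau = %g (D = %g, %s)\n",
    x$mu, x$sigma, x$tau, x$D, x$scaling))
  invisible(x)
}

#' Specification of one cosine stimulus
#'
#' @param epsilon signal amplitude in the dimensionless input units of
#'   \code{mu} (\code{epsilon >= 0}).
#' @param omega angular frequency in units of the inverse membrane time
#'   constant (\code{omega > 0}).
#' @return An object of class \code{"signal_spec"}, describing the stimulus
#'   \code{s(t) = epsilon * cos(omega * t)}.
#' @export
signal_spec <- function(epsilon, omega) {
  stopifnot(is.finite(epsilon), epsilon >= 0, is.finite(omega), omega > 0)
  structure(list(epsilon = epsilon, omega = omega), class = "signal_spec")
}

#' Truncation orders of the Fourier-Hermite expansion
#'
#' @param n_max highest retained Fourier index in the phase theta.
#' @param p_max highest retained Hermite index in the noise eta. Note that at
#'   \code{mu = 1} the tridiagonal matrix entering the continued fraction is
#'   exactly singular when \code{p_max} is even (its dimension
#'   \code{p_max + 1} is odd); choose an odd \code{p_max} there.
#' @return An object of class \code{"trunc_spec"}.
#' @export
trunc_spec <- function(n_max = 150L, p_max = 150L) {
  stopifnot(n_max >= 1, p_max >= 1)
  structure(list(n_max = as.integer(n_max), p_max = as.integer(p_max)),
            class = "trunc_spec")
}

#' Phase velocity of the theta neuron
#'
#' The deterministic drift of the phase,
#' \code{f(theta, eta, s) = (1 - cos(theta)) + (1 + cos(theta)) (mu + eta + s)}.
#' At the threshold phase \code{theta = pi} the velocity is input-independent
#' and equals 2, which is what ties the firing rate to the probability density
#' at threshold.
#'
#' @param theta phase (radians); vectorized.
#' @param eta instantaneous OU noise value.
#' @param s instantaneous signal value.
#' @param mu mean input.
#' @return Phase velocity in radians per membrane time constant.
#' @export
phase_velocity <- function(theta, eta = 0, s = 0, mu = 0) {
  (1 - cos(theta)) + (1 + cos(theta)) * (mu + eta + s)
}

#' Deterministic firing rate of the theta neuron
#'
#' Closed form for the noise-free model: \code{sqrt(mu)/pi} for \code{mu > 0}
#' and 0 otherwise (the model is excitable, not firing, below the SNIC
#' bifurcation at \code{mu = 0}).
#'
#' @param mu mean input; vectorized.
#' @return Nonnegative rate in units of the inverse membrane time constant.
#' @export
deterministic_rate <- function(mu) {
  ifelse(mu > 0, sqrt(pmax(mu, 0)) / pi, 0)
}

#' Quasi-static (long correlation time) firing rate
#'
#' In the limit of very slow noise the rate is the deterministic rate averaged
#' over the stationary Gaussian distribution of the OU noise:
#' \code{r_inf(mu) = E[ r_det(mu + eta) ]} with \code{eta ~ N(0, sigma^2)}.
#' Evaluated by adaptive Gauss-Kronrod quadrature over the half line where
#' the deterministic rate is nonzero.
#'
#' @param mu mean input.
#' @param sigma noise standard deviation (\code{sigma > 0}).
#' @param rel_tol relative quadrature tolerance.
#' @return Nonnegative rate.
#' @export
quasi_static_rate <- function(mu, sigma, rel_tol = 1e-10) {
  stopifnot(sigma > 0)
  f <- function(I) deterministic_rate(I) * stats::dnorm(I, mean = mu, sd = sigma)
  q <- stats::integrate(f, lower = 0, upper = Inf, rel.tol = rel_tol,
                        abs.tol = 0, stop.on.error = FALSE)
  if (!q$message %in% c("OK", "the integral is probably divergent") &&
      q$message != "OK")
    stop("quasi_static_rate: quadrature did not converge: ", q$message)
  q$value
}

#' Weak-noise firing-rate correction (phase-response-curve approximation)
#'
#' For weak noise in the mean-driven regime (\code{sigma << mu}) the colored
#' noise reduces the rate below the deterministic value:
#' \code{r0 ~ r_det - (sigma^2 / 2 pi) * (tau^2 / sqrt(mu)) / (4 mu tau^2 + 1)}.
#'
#' @param mu mean input, strictly positive.
#' @param sigma noise standard deviation.
#' @param tau noise correlation time.
#' @return Approximate rate.
#' @export
galan_rate <- function(mu, sigma, tau) {
  if (any(mu <= 0)) stop("galan_rate: requires mu > 0 (mean-driven regime)")
  deterministic_rate(mu) -
    (sigma^2 / (2 * pi)) * (tau^2 / sqrt(mu)) / (4 * mu * tau^2 + 1)
}

#' Map parameters to the constant-variance normal form (sigma = 1)
#'
#' The three-parameter space (mu, sigma, tau) collapses onto two parameters
#' via \code{mu_hat = mu/sigma}, \code{tau_hat = sqrt(sigma) tau}; time runs
#' as \code{t_hat = sqrt(sigma) t} so physical rates are recovered as
#' \code{r = sqrt(sigma) * r_hat}. Signals map as \code{eps_hat = eps/sigma},
#' \code{omega_hat = omega/sqrt(sigma)}.
#'
#' @param p a \code{theta_params} object with \code{sigma > 0}.
#' @param signals optional list of \code{signal_spec} objects.
#' @return List with \code{params} (rescaled, sigma = 1), \code{signals}
#'   (rescaled), and \code{rate_factor} such that
#'   physical rate = rate_factor * rescaled rate.
#' @export
rescale_constant_variance <- function(p, signals = list()) {
  if (p$sigma <= 0) stop("rescale_constant_variance: requires sigma > 0")
  s <- p$sigma
  list(
    params = theta_params(mu = p$mu / s, sigma = 1, tau = sqrt(s) * p$tau,
                          scaling = "constant_variance"),
    signals = lapply(signals, function(sg)
      signal_spec(epsilon = sg$epsilon / s, omega = sg$omega / sqrt(s))),
    rate_factor = sqrt(s))
}

#' Map parameters to the constant-intensity normal form (D = 1)
#'
#' Holds the noise intensity \code{D = sigma^2 tau} fixed at 1:
#' \code{mu_tilde = mu/D^(2/3)}, \code{tau_tilde = D^(1/3) tau}; time runs as
#' \code{t_tilde = D^(1/3) t}, so physical rate = \code{D^(1/3)} * rescaled
#' rate. Signals map as \code{eps/D^(2/3)}, \code{omega/D^(1/3)}.
#'
#' @inheritParams rescale_constant_variance
#' @return List with \code{params}, \code{signals}, \code{rate_factor}.
#' @export
rescale_constant_intensity <- function(p, signals = list()) {
  D <- p$D
  if (D <= 0) stop("rescale_constant_intensity: requires D = sigma^2 * tau > 0")
  tau_t <- D^(1 / 3) * p$tau
  # sigma_tilde follows from D_tilde = 1 at the new correlation time
  list(
    params = theta_params(mu = p$mu / D^(2 / 3), sigma = sqrt(1 / tau_t),
                          tau = tau_t, scaling = "constant_intensity"),
    signals = lapply(signals, function(sg)
      signal_spec(epsilon = sg$epsilon / D^(2 / 3), omega = sg$omega / D^(1 / 3))),
    rate_factor = D^(1 / 3))
}

#' High-frequency limit of the firing-rate susceptibility
#'
#' The theta neuron is a second-order low-pass filter at high stimulus
#' frequencies: \code{|chi| -> 2 r0 / omega^2} with phase lag \code{pi}.
#'
#' @param r0 stationary firing rate.
#' @param omega angular stimulus frequency (\code{omega > 0}).
#' @return List with \code{amplitude} and \code{phase}.
#' @export
high_freq_susceptibility <- function(r0, omega) {
  stopifnot(all(omega > 0))
  list(amplitude = 2 * r0 / omega^2, phase = pi)
}

#' Zero-frequency limit of the susceptibility via finite differences
#'
#' In the quasi-static limit the amplitude gain equals the slope of the
#' stationary rate with respect to the mean input, \code{d r0 / d mu},
#' evaluated here by a central difference of the matrix-continued-fraction
#' stationary rate.
#'
#' @param p a \code{theta_params} object.
#' @param trunc a \code{trunc_spec}.
#' @param dmu finite-difference step (default 1e-3).
#' @return Amplitude (equals \code{|chi(omega -> 0)|}; the phase limit is 0).
#' @export
low_freq_susceptibility <- function(p, trunc = trunc_spec(), dmu = 1e-3) {
  stopifnot(dmu > 0)
  rp <- stationary_rate(theta_params(p$mu + dmu, p$sigma, p$tau), trunc)$rate
  rm <- stationary_rate(theta_params(p$mu - dmu, p$sigma, p$tau), trunc)$rate
  (rp - rm) / (2 * dmu)
}
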