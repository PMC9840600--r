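# Euler-Maruyama simulation of the theta neuron driven by OU noise and
# optional cosine signals. All trials advance in lockstep as vectors; spikes
# are detected as upward crossings of theta = pi (the phase velocity there is
# always 2, so every crossing is upward) with linear interpolation of the
# crossing time, after which theta is wrapped by -2*pi.

#' Simulation settings
#'
#' @param dt integration step (dimensionless time; default 5e-3).
#' @param T trial duration.
#' @param n_trials ensemble size.
#' @param seed integer RNG seed (one seeded stream drives all trials in
#'   lockstep; identical settings and seed give bit-identical ensembles).
#' @param t_transient initial interval discarded by the estimators.
#' @param eta_update \code{"exact"} uses the exact OU transition density per
#'   step (no time-discretization bias in the noise channel);
#'   \code{"euler"} is the plain Euler-Maruyama update.
#' @param init \code{"stationary"} draws \code{eta ~ N(0, sigma^2)} and runs a
#'   burn-in of the phase before recording; \code{"reset"} starts every trial
#'   at \code{eta = 0, theta = -pi} (transient-response studies).
#' @param t_burnin burn-in length used by \code{init = "stationary"}.
#' @return Object of class \code{"sim_settings"}.
#' @export
sim_settings <- function(dt = 5e-3, T = 100, n_trials = 100L, seed = 1L,
                         t_transient = 0, eta_update = c("exact", "euler"),
                         init = c("stationary", "reset"), t_burnin = 20) {
  eta_update <- match.arg(eta_update)
  init <- match.arg(init)
  stopifnot(dt > 0, T > t_transient, t_transient >= 0, n_trials >= 1)
  structure(list(dt = dt, T = T, n_trials = as.integer(n_trials),
                 seed = as.integer(seed), t_transient = t_transient,
                 eta_update = eta_update, init = init, t_burnin = t_burnin),
            class = "sim_settings")
}

#' Simulate an ensemble of theta-neuron spike trains
#'
#' Integrates the Langevin pair
#' \code{dtheta/dt = f(theta, eta, s(t))},
#' \code{tau deta/dt = -eta + sqrt(2 tau sigma^2) xi(t)}
#' and records the spike times of every trial.
#'
#' @param params a \code{theta_params} object.
#' @param signals list of \code{signal_spec} objects (may be empty).
#' @param settings a \code{sim_settings} object.
#' @param record_state_at optional times at which to snapshot the state of
#'   every trial (for comparing empirical phase/noise distributions against
#'   the Fokker-Planck densities).
#' @return Object of class \code{"spike_ensemble"}: list with
#'   \code{spike_times} (per-trial sorted vectors), \code{eta_samples}
#'   (final-time noise values, a convenience diagnostic),
#'   \code{theta_snapshots}/\code{eta_snapshots} (matrices, one row per
#'   recorded time), \code{settings}, \code{params}, \code{signals}.
#' @export
simulate_theta <- function(params, signals = list(), settings = sim_settings(),
                           record_state_at = numeric(0)) {
  set.seed(settings$seed)
  nt <- settings$n_trials
  dt <- settings$dt
  mu <- params$mu; sig <- params$sigma; tau <- params$tau
  eta_exact <- settings$eta_update == "exact"
  if (eta_exact) {
    a <- exp(-dt / tau)
    b <- sig * sqrt(1 - a^2)
  }
  sgn <- function(t) {
    s <- 0
    for (sg in signals) s <- s + sg$epsilon * cos(sg$omega * t)
    s
  }
  if (settings$init == "reset") {
    eta <- rep(0, nt)
    theta <- rep(-pi, nt)
  } else {
    eta <- stats::rnorm(nt, 0, sig)
    theta <- stats::runif(nt, -pi, pi)
    if (settings$t_burnin > 0) {
      nb <- ceiling(settings$t_burnin / dt)
      for (i in seq_len(nb)) {
        v <- phase_velocity(theta, eta, 0, mu)
        theta <- theta + dt * v
        theta <- theta - 2 * pi * (theta > pi)
        eta <- if (eta_exact) a * eta + b * stats::rnorm(nt)
               else if (sig > 0) eta + dt * (-eta / tau) +
                 sqrt(2 * sig^2 * dt / tau) * stats::rnorm(nt)
               else eta
      }
    }
  }
  nsteps <- ceiling(settings$T / dt)
  rec_steps <- if (length(record_state_at))
    pmin(pmax(round(record_state_at / dt), 1L), nsteps) else integer(0)
  th_snap <- matrix(NA_real_, length(rec_steps), nt)
  et_snap <- matrix(NA_real_, length(rec_steps), nt)
  sp_trial <- vector("list", 0L)
  sp_time <- vector("list", 0L)
  t <- 0
  for (i in seq_len(nsteps)) {
    s_now <- sgn(t)
    v <- phase_velocity(theta, eta, s_now, mu)
    theta_new <- theta + dt * v
    crossed <- theta_new > pi
    if (any(crossed)) {
      idx <- which(crossed)
      ts <- t + dt * (pi - theta[idx]) / (theta_new[idx] - theta[idx])
      sp_trial[[length(sp_trial) + 1L]] <- idx
      sp_time[[length(sp_time) + 1L]] <- ts
      theta_new[idx] <- theta_new[idx] - 2 * pi
    }
    theta <- theta_new
    eta <- if (eta_exact) a * eta + b * stats::rnorm(nt)
           else if (sig > 0) eta + dt * (-eta / tau) +
             sqrt(2 * sig^2 * dt / tau) * stats::rnorm(nt)
           else eta
    t <- t + dt
    if (length(rec_steps)) {
      hit <- which(rec_steps == i)
      if (length(hit)) {
        th_snap[hit, ] <- rep(theta, each = length(hit))
        et_snap[hit, ] <- rep(eta, each = length(hit))
      }
    }
  }
  trial <- unlist(sp_trial)
  time <- unlist(sp_time)
  spike_times <- vector("list", nt)
  if (length(trial)) {
    o <- order(trial, time)
    spike_times <- unname(split(time[o], factor(trial[o], levels = seq_len(nt))))
  } else {
    spike_times <- rep(list(numeric(0)), nt)
  }
  structure(list(spike_times = spike_times, eta_samples = eta,
                 theta_snapshots = th_snap, eta_snapshots = et_snap,
                 settings = settings, params = params, signals = signals),
            class = "spike_ensemble")
}

#' Count-based estimate of the stationary firing rate
#'
#' Total spikes after the transient divided by total observed time, with the
#' standard error from the across-trial variance of per-trial rates.
#'
#' @param e a \code{spike_ensemble}.
#' @return List with \code{rate}, \code{se}, \code{n_spikes},
#'   \code{observed_time}.
#' @export
estimate_stationary_rate <- function(e) {
  tt <- e$settings$t_transient
  T_obs <- e$settings$T - tt
  if (T_obs <= 0) stop("no observation time after transient")
  counts <- vapply(e$spike_times, function(s) sum(s >= tt), numeric(1))
  rates <- counts / T_obs
  n <- length(rates)
  se <- if (n > 1) stats::sd(rates) / sqrt(n) else 0
  list(rate = mean(rates), se = se, n_spikes = sum(counts),
       observed_time = n * T_obs)
}

#' Peri-stimulus time histogram (trial-averaged instantaneous rate)
#'
#' Bins all spikes after the transient across trials and divides by
#' \code{n_trials * bin_width}; per-bin standard errors come from the
#' across-trial variance of binned counts.
#'
#' @param e a \code{spike_ensemble}.
#' @param bin_width bin width (\code{>= dt}).
#' @param t_start,t_end observation window (defaults: transient to T).
#' @return Object of class \code{"rate_estimate"}: data frame with columns
#'   \code{t} (bin centers), \code{rate}, \code{se}; attribute
#'   \code{bin_width}.
#' @export
estimate_rate_psth <- function(e, bin_width, t_start = NULL, t_end = NULL) {
  stopifnot(bin_width >= e$settings$dt)
  if (is.null(t_start)) t_start <- e$settings$t_transient
  if (is.null(t_end)) t_end <- e$settings$T
  breaks <- seq(t_start, t_end, by = bin_width)
  if (breaks[length(breaks)] < t_end - 1e-12)
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  nb <- length(breaks) - 1L
  nt <- length(e$spike_times)
  counts <- matrix(0L, nt, nb)
  for (i in seq_len(nt)) {
    s <- e$spike_times[[i]]
    s <- s[s >= t_start & s < breaks[nb + 1L]]
    if (length(s))
      counts[i, ] <- tabulate(findInterval(s, breaks), nbins = nb)
  }
  rate <- colMeans(counts) / bin_width
  se <- apply(counts, 2L, stats::sd) / sqrt(nt) / bin_width
  out <- data.frame(t = (breaks[-1L] + breaks[-(nb + 1L)]) / 2,
                    rate = rate, se = se)
  structure(out, bin_width = bin_width, n_trials = nt,
            class = c("rate_estimate", "data.frame"))
}

#' Fourier harmonics of a cyclo-stationary rate estimate
#'
#' Projects the PSTH onto \code{exp(i k omega t)} over an integer number of
#' stimulus periods: the returned complex amplitude \code{A_k} estimates the
#' term \code{|A_k| cos(k omega t - Arg(A_k))} of the rate, so dividing the
#' k = 1 amplitude by the signal amplitude epsilon estimates the
#' susceptibility. A sinc correction removes the first-order binning bias.
#'
#' @param r a \code{rate_estimate}.
#' @param omega angular stimulus frequency.
#' @param k_list integer harmonics to extract (\code{k >= 1}; the \code{k = 0}
#'   term is the time-averaged rate).
#' @return Data frame with columns \code{k}, \code{re}, \code{im},
#'   \code{amplitude}, \code{phase}, \code{se} (isotropic standard error of
#'   the complex estimate).
#' @export
estimate_harmonics <- function(r, omega, k_list = 1L) {
  bw <- attr(r, "bin_width")
  period <- 2 * pi / omega
  span <- nrow(r) * bw
  n_per <- floor(span / period + 1e-9)
  if (n_per < 1) stop("observation window shorter than one stimulus period")
  keep <- r$t < r$t[1L] - bw / 2 + n_per * period + 1e-12
  if (abs(sum(keep) * bw - n_per * period) > bw / 2)
    stop("observation window does not cover an integer number of periods")
  t <- r$t[keep]; rate <- r$rate[keep]; se <- r$se[keep]
  T_obs <- sum(keep) * bw
  out <- lapply(k_list, function(k) {
    w <- exp(1i * k * omega * t)
    A <- 2 * sum(rate * w) * bw / T_obs
    A <- A / sinc_half(k * omega * bw / 2)   # bin-averaging correction
    seA <- sqrt(sum((2 * se * bw / T_obs)^2) / 2)
    data.frame(k = k, re = Re(A), im = Im(A),
               amplitude = Mod(A), phase = Arg(A), se = seA)
  })
  do.call(rbind, out)
}

sinc_half <- function(x) ifelse(x == 0, 1, sin(x) / x)
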