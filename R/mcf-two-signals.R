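# Mixed response to two periodic signals s(t) = eps1*cos(w1 t) + eps2*cos(w2 t),
# generally with incommensurable frequencies. The density is expanded in both
# amplitudes and both harmonic ladders,
#   P = sum epsilon_1^l1 epsilon_2^l2 e^{-i(k1 w1 + k2 w2) t} P^{l1,l2}_{k1,k2},
# and the hierarchy is solved up to second order (l1 + l2 <= 2): the two
# linear members, the three single-signal second-order members, and the two
# genuinely mixed members at the sum and difference frequencies. Reality of P
# implies P^{l1,l2}_{-k1,-k2} = Conj(P^{l1,l2}_{k1,k2}).

#' Solve the two-signal response hierarchy to second order
#'
#' Solves the seven non-vanishing first- and second-order members plus the
#' stationary zeroth order. A member whose operator frequency
#' \code{k1 w1 + k2 w2} is (numerically) zero for \code{(k1,k2) != (0,0)}
#' makes the operator singular (commensurable degeneracy); the solver errors
#' with advice to perturb a frequency.
#'
#' @param params a \code{theta_params} object.
#' @param s1,s2 \code{signal_spec} objects (amplitudes enter only at
#'   reconstruction).
#' @param trunc a \code{trunc_spec}.
#' @param stationary optional precomputed \code{\link{stationary_rate}} result.
#' @param degeneracy_tol threshold on \code{|k1 w1 + k2 w2|} below which a
#'   non-(0,0) member is considered degenerate.
#' @return Object of class \code{"mcf_two_signal"}: list with
#'   \code{components} named \code{"l1,l2,k1,k2"}, the frequencies, params,
#'   trunc, and the largest linear-system residual.
#' @export
solve_two_signal_hierarchy <- function(params, s1, s2, trunc = trunc_spec(),
                                       stationary = NULL,
                                       degeneracy_tol = 1e-6) {
  w1 <- s1$omega; w2 <- s2$omega
  st <- if (is.null(stationary)) stationary_rate(params, trunc) else stationary
  P0 <- st$coeffs
  Lp <- function(C) 0.5 * apply_Lper(C)
  freq_of <- function(k1, k2) k1 * w1 + k2 * w2
  resid <- 0
  comps <- list()
  solve_member <- function(l1, l2, k1, k2, rhs) {
    fr <- freq_of(k1, k2)
    if ((k1 != 0L || k2 != 0L) && abs(fr) < degeneracy_tol)
      stop(sprintf(
        "degenerate member (l1,l2,k1,k2)=(%d,%d,%d,%d): |k1*w1 + k2*w2| = %.3g ~ 0; perturb one frequency",
        l1, l2, k1, k2, abs(fr)))
    x <- solve_Lk(params, trunc, freq = fr, rhs = rhs, norm_value = 0 + 0i)
    resid <<- max(resid, attr(x, "resid"))
    comps[[paste(l1, l2, k1, k2, sep = ",")]] <<- x
    x
  }
  comps[["0,0,0,0"]] <- P0
  # first order: one member per signal channel
  P10 <- solve_member(1L, 0L, 1L, 0L, Lp(P0))
  P01 <- solve_member(0L, 1L, 0L, 1L, Lp(P0))
  # second order, single channels: second harmonics and mean-rate corrections
  solve_member(2L, 0L, 2L, 0L, Lp(P10))
  solve_member(0L, 2L, 0L, 2L, Lp(P01))
  solve_member(2L, 0L, 0L, 0L, Lp(P10 + conj_coeffs(P10)))
  solve_member(0L, 2L, 0L, 0L, Lp(P01 + conj_coeffs(P01)))
  # mixed members at the sum and difference frequencies
  solve_member(1L, 1L, 1L, 1L, Lp(P10 + P01))
  solve_member(1L, 1L, 1L, -1L, Lp(P10 + conj_coeffs(P01)))
  structure(list(components = comps, omega1 = w1, omega2 = w2,
                 params = params, trunc = trunc, stationary = st,
                 resid = resid),
            class = "mcf_two_signal")
}

#' Rate components of a two-signal hierarchy
#'
#' \code{r^{l1,l2}_{k1,k2} = 2 (2 - delta_{k1,0} delta_{k2,0})
#' int d eta P^{l1,l2}_{k1,k2}(pi, eta)}.
#'
#' @param h an \code{"mcf_two_signal"} object.
#' @return Data frame with columns \code{l1}, \code{l2}, \code{k1}, \code{k2},
#'   \code{amplitude}, \code{phase}, \code{re}, \code{im}.
#' @export
two_signal_components <- function(h) {
  keys <- names(h$components)
  idx <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  r <- vapply(seq_along(keys), function(i)
    rate_component(h$components[[i]],
                   k_zero = idx[i, 3L] == 0L && idx[i, 4L] == 0L),
    complex(1))
  data.frame(l1 = idx[, 1L], l2 = idx[, 2L], k1 = idx[, 3L], k2 = idx[, 4L],
             amplitude = Mod(r), phase = Arg(r), re = Re(r), im = Im(r))
}

#' Reconstruct the rate under two periodic signals (second order)
#'
#' \code{r(t) = sum eps1^l1 eps2^l2 |r| cos((k1 w1 + k2 w2) t - phi)} over the
#' solved members, including the mixed terms at \code{w1 + w2} and
#' \code{w1 - w2}.
#'
#' @param h an \code{"mcf_two_signal"} object.
#' @param eps1,eps2 signal amplitudes.
#' @param time_grid evaluation times.
#' @return Numeric rate values; warns on negative values.
#' @export
two_signal_rate <- function(h, eps1, eps2, time_grid) {
  comp <- two_signal_components(h)
  r <- numeric(length(time_grid))
  for (i in seq_len(nrow(comp))) {
    freq <- comp$k1[i] * h$omega1 + comp$k2[i] * h$omega2
    r <- r + eps1^comp$l1[i] * eps2^comp$l2[i] * comp$amplitude[i] *
      cos(freq * time_grid - comp$phase[i])
  }
  if (any(r < 0))
    warning("reconstructed two-signal rate negative at some times: ",
            "amplitudes outside perturbative validity")
  r
}

#' Scan the mixed response over a frequency grid
#'
#' Solves the two-signal hierarchy at every \code{(omega1, omega2)} pair and
#' tabulates all seven response amplitudes and phases. Per-point failures
#' (e.g. commensurable degeneracies) are recorded and the scan continues.
#'
#' @param params a \code{theta_params} object.
#' @param omega1_grid,omega2_grid frequency grids.
#' @param trunc a \code{trunc_spec}.
#' @return Data frame with columns \code{mu}, \code{sigma}, \code{tau},
#'   \code{omega1}, \code{omega2}, \code{l1}, \code{l2}, \code{k1}, \code{k2},
#'   \code{amplitude}, \code{phase}, \code{error} (NA_character_ on success).
#' @export
mixed_response_scan <- function(params, omega1_grid, omega2_grid,
                                trunc = trunc_spec()) {
  st <- stationary_rate(params, trunc)
  rows <- list()
  for (w1 in omega1_grid) for (w2 in omega2_grid) {
    res <- tryCatch({
      h <- solve_two_signal_hierarchy(params, signal_spec(1, w1),
                                      signal_spec(1, w2), trunc,
                                      stationary = st)
      comp <- two_signal_components(h)
      cbind(data.frame(mu = params$mu, sigma = params$sigma, tau = params$tau,
                       omega1 = w1, omega2 = w2),
            comp[, c("l1", "l2", "k1", "k2", "amplitude", "phase")],
            error = NA_character_)
    }, error = function(e)
      data.frame(mu = params$mu, sigma = params$sigma, tau = params$tau,
                 omega1 = w1, omega2 = w2, l1 = NA_integer_, l2 = NA_integer_,
                 k1 = NA_integer_, k2 = NA_integer_, amplitude = NA_real_,
                 phase = NA_real_, error = conditionMessage(e)))
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
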