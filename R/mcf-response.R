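# Cyclo-stationary response to one periodic signal s(t) = epsilon*cos(omega t).
#
# The periodically driven density is expanded in powers of the amplitude and
# in harmonics of the drive,
#   P(theta, eta, t) = sum_{l>=0} sum_k epsilon^l e^{-i k omega t} P_{l,k},
# which turns the Fokker-Planck equation into the iterative hierarchy
#   (L0 + i k omega) P_{l,k} = (1/2) L_per (P_{l-1,k-1} + P_{l-1,k+1}),
# seeded by the stationary density P_{0,0}. Members with k > l or k + l odd
# vanish identically; only k >= 0 is solved, negatives follow from
# P_{l,-k} = Conj(P_{l,k}). Each member is one block-tridiagonal linear
# system over the Fourier-Hermite coefficients; the amplitude epsilon enters
# only at rate reconstruction.

#' Solve the single-signal response hierarchy
#'
#' @param params a \code{theta_params} object.
#' @param signal a \code{signal_spec}; only its frequency \code{omega} enters
#'   the hierarchy (the amplitude is applied at reconstruction).
#' @param L_max highest retained power of the signal amplitude
#'   (\code{L_max >= 1}).
#' @param trunc a \code{trunc_spec}.
#' @param stationary optional precomputed \code{\link{stationary_rate}} result
#'   for \code{params}/\code{trunc} (seeds the hierarchy).
#' @return An object of class \code{"mcf_hierarchy"}: list with
#'   \code{components} (named \code{"l,k"}, coefficient matrices for
#'   \code{k >= 0}, \code{k <= l}, \code{k + l} even), \code{omega},
#'   \code{L_max}, \code{params}, \code{trunc}, \code{resid} (largest
#'   linear-system residual).
#' @export
solve_hierarchy <- function(params, signal, L_max = 2L, trunc = trunc_spec(),
                            stationary = NULL) {
  stopifnot(L_max >= 1)
  omega <- if (inherits(signal, "signal_spec")) signal$omega else signal
  st <- if (is.null(stationary)) stationary_rate(params, trunc) else stationary
  comps <- list("0,0" = st$coeffs)
  resid <- 0
  for (l in seq_len(L_max)) {
    for (k in seq(l %% 2L, l, by = 2L)) {
      rhs <- 0.5 * apply_Lper(hier_member(comps, l - 1L, k - 1L, trunc) +
                                hier_member(comps, l - 1L, k + 1L, trunc))
      x <- solve_Lk(params, trunc, freq = k * omega, rhs = rhs,
                    norm_value = 0 + 0i)
      resid <- max(resid, attr(x, "resid"))
      comps[[paste(l, k, sep = ",")]] <- x
    }
  }
  structure(list(components = comps, omega = omega, L_max = as.integer(L_max),
                 params = params, trunc = trunc, stationary = st,
                 resid = resid),
            class = "mcf_hierarchy")
}

# Fetch member P_{l,k} from the solved set, applying the conjugation rule for
# k < 0 and the vanishing pattern (k > l or k + l odd) otherwise.
hier_member <- function(comps, l, k, trunc) {
  zero <- matrix(0 + 0i, 2L * trunc$n_max + 1L, trunc$p_max + 1L)
  if (l < 0L || abs(k) > l || (k + l) %% 2L != 0L) return(zero)
  if (k >= 0L) comps[[paste(l, k, sep = ",")]]
  else conj_coeffs(comps[[paste(l, -k, sep = ",")]])
}

# Complex rate component from a coefficient matrix:
# r = (2 - delta_{k,0})/pi * sum_n (-1)^n a_{n,0}
# (the eta-integrated density at the threshold phase pi, times the velocity 2,
# times 2 for the k>0 cosine pairing).
rate_component <- function(C, k_zero) {
  n_max <- attr(C, "n_max")
  n_idx <- -n_max:n_max
  (if (k_zero) 1 else 2) * sum((-1)^n_idx * C[, 1L]) / pi
}

#' Rate response components of a solved hierarchy
#'
#' Evaluates \code{r_{l,k} = 2 (2 - delta_{k,0}) int d eta P_{l,k}(pi, eta)}
#' for every solved member; \code{r_{0,0}} is the stationary rate and
#' \code{r_{2,0}} the leading correction of the time-averaged rate.
#'
#' @param h an \code{"mcf_hierarchy"} from \code{\link{solve_hierarchy}}.
#' @return Data frame with columns \code{ell}, \code{k}, \code{amplitude},
#'   \code{phase} (in \code{(-pi, pi]}, convention
#'   \code{cos(k omega t - phase)}), \code{re}, \code{im}.
#' @export
response_components <- function(h) {
  keys <- names(h$components)
  lk <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  r <- vapply(seq_along(keys), function(i)
    rate_component(h$components[[i]], k_zero = lk[i, 2L] == 0L),
    complex(1))
  data.frame(ell = lk[, 1L], k = lk[, 2L],
             amplitude = Mod(r), phase = Arg(r), re = Re(r), im = Im(r))
}

#' Firing-rate susceptibility
#'
#' The complex linear response coefficient \code{chi(omega) = r_{1,1}(omega)}:
#' its modulus is the amplitude gain of the firing rate for a weak cosine
#' stimulus, its argument the phase lag.
#'
#' @param params a \code{theta_params} object.
#' @param omega angular stimulus frequency (\code{omega > 0}), vectorized.
#' @param trunc a \code{trunc_spec}.
#' @param stationary optional precomputed stationary solution.
#' @return Complex vector of the same length as \code{omega}.
#' @export
susceptibility <- function(params, omega, trunc = trunc_spec(),
                           stationary = NULL) {
  stopifnot(all(omega > 0))
  st <- if (is.null(stationary)) stationary_rate(params, trunc) else stationary
  vapply(omega, function(w) {
    h <- solve_hierarchy(params, signal_spec(1, w), L_max = 1L, trunc = trunc,
                         stationary = st)
    rate_component(h$components[["1,1"]], k_zero = FALSE)
  }, complex(1))
}

#' Reconstruct the cyclo-stationary firing rate
#'
#' \code{r(t) = sum_{l,k} epsilon^l |r_{l,k}| cos(k omega t - phi_{l,k})},
#' truncated at the hierarchy's order.
#'
#' @param components data frame from \code{\link{response_components}} (or a
#'   subset of its rows, e.g. to compare truncation orders).
#' @param epsilon signal amplitude.
#' @param time_grid times at which to evaluate the rate.
#' @param omega angular frequency of the signal.
#' @return Numeric vector of rate values; warns if any value is negative
#'   (amplitude outside the validity of the truncated series).
#' @export
cyclostationary_rate <- function(components, epsilon, time_grid, omega) {
  r <- numeric(length(time_grid))
  for (i in seq_len(nrow(components))) {
    r <- r + epsilon^components$ell[i] * components$amplitude[i] *
      cos(components$k[i] * omega * time_grid - components$phase[i])
  }
  if (any(r < 0))
    warning("reconstructed rate is negative at some times: ",
            "signal amplitude outside perturbative validity or series over-truncated")
  r
}
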