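# Independent oracles and small utilities shared by the tests.

# White-noise QIF firing rate by brute-force quadrature: the mean first
# passage time of dx/dt = x^2 + mu + sqrt(2 D) xi from -Inf to Inf reduces
# (after one Gaussian integration) to
#   T = sqrt(pi / D) * int_0^inf w^{-1/2} exp(-(w^3/12 + mu w)/D) dw.
white_noise_qif_rate <- function(mu, D = 1) {
  f <- function(w) w^(-1 / 2) * exp(-(w^3 / 12 + mu * w) / D)
  1 / (sqrt(pi / D) * stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
}

# Distance between two angles on the circle.
circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Indices of strict interior local maxima of a vector.
local_maxima <- function(x) which(diff(sign(diff(x))) == -2) + 1L

# RMS of a vector.
rms <- function(x) sqrt(mean(x^2))

# Trapezoid rule on a uniform grid.
trapz <- function(x, y) {
  h <- diff(x)
  sum((y[-1] + y[-length(y)]) / 2 * h)
}
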