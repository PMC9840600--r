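test_that("recurrence matrices have their printed entries", {
  expect_equal(build_A(1L, 1), diag(c(0, 1i), 2))
  expect_equal(build_A(2L, 2), diag(c(0, 0.5i, 1i), 3))
  A <- build_A(5L, 0.7)
  expect_true(all(A[row(A) != col(A)] == 0))

  expect_equal(build_B(1L, -1, 1), matrix(c(1, -0.5, -0.5, 1), 2))
  expect_equal(build_B(3L, 0.2, 0), diag((1 - 0.2) / 2, 4))
  B <- build_B(7L, 0.3, 1.7)
  expect_equal(B, t(B))
})

test_that("K_n matches a hand-inverted 2x2 oracle and its limits", {
  # A = 0, B = I: K_n = 2(I - I) - 0 = 0
  expect_lt(max(Mod(build_K(1L, matrix(0, 2, 2), diag(2)))), 1e-15)
  # p_max = 1, mu = -1, sigma = 1, tau = 1: B = [[1,-1/2],[-1/2,1]],
  # B^{-1} = (4/3)[[1,1/2],[1/2,1]]; frozen from the hand inversion
  K1 <- build_K(1L, build_A(1L, 1), build_B(1L, -1, 1))
  K1_hand <- matrix(c(2 / 3, 4 / 3, 4 / 3 - (2 / 3) * 1i,
                      2 / 3 - (4 / 3) * 1i), 2, 2)
  expect_lt(max(Mod(K1 - K1_hand)), 1e-14)
  # 1/n factor: K_n -> 2(B^{-1} - I) entrywise as n grows
  Binf <- build_B(1L, -1, 1)
  expect_lt(max(Mod(build_K(1e9, build_A(1L, 1), Binf) -
                      2 * (solve(Binf) - diag(2)))), 1e-8)
})

test_that("singular B is rejected with advice about p_max", {
  # mu = 1: B is a zero-diagonal symmetric tridiagonal matrix, exactly
  # singular when its dimension p_max + 1 is odd
  expect_error(build_K(1L, build_A(2L, 1), build_B(2L, 1, 1)), "p_max")
  expect_error(stationary_rate(theta_params(1, 1, 1), trunc_spec(20L, 20L)),
               "p_max")
  # even dimension at mu = 1 is fine
  expect_no_error(stationary_rate(theta_params(1, 1, 1), trunc_spec(60L, 61L)))
})

test_that("continued fraction satisfies its defining relation", {
  params <- theta_params(0.5, 1, 1)
  tr <- trunc_spec(40L, 20L)
  S <- continued_fraction_S(params, tr)
  A <- build_A(tr$p_max, params$tau)
  B <- build_B(tr$p_max, params$mu, params$sigma)
  # S_0 = (K_1 - S_1)^{-1} to machine precision
  K1 <- build_K(1L, A, B)
  expect_lt(max(Mod((K1 - S[[2]]) %*% S[[1]] - diag(tr$p_max + 1L))), 1e-10)
  # self-convergence: doubling a production-scale n_max barely moves S_0
  Sa <- continued_fraction_S(params, trunc_spec(150L, 20L))
  Sb <- continued_fraction_S(params, trunc_spec(300L, 20L))
  expect_lt(max(Mod(Sa[[1]] - Sb[[1]])), 1e-8)
})

test_that("degenerate noise-free excitable configuration is rejected", {
  # sigma = 0, mu = -1 gives B = I and a K_n whose q = 0 entry vanishes:
  # the very first continued-fraction inversion is singular
  expect_error(continued_fraction_S(theta_params(-1, 0, 1),
                                    trunc_spec(10L, 5L)),
               "singular")
})

test_that("stationary coefficients obey the recurrence and conjugation", {
  params <- theta_params(0.5, 1, 1)
  tr <- trunc_spec(60L, 60L)
  C <- stationary_coefficients(params, tr)
  i0 <- tr$n_max + 1L
  expect_equal(unname(C[i0, 1L]), 1 + 0i)
  expect_lt(max(Mod(C[i0, -1L])), 1e-15)
  # c_{-n,p} = Conj(c_{n,p})
  expect_equal(C[i0 - 5L, ], Conj(C[i0 + 5L, ]))
  # first transition: c_{1,0} = (S_0)_{0,0}, c_{1,1} = (S_0)_{1,0}
  S <- continued_fraction_S(params, tr)
  expect_equal(C[i0 + 1L, 1L], S[[1]][1L, 1L])
  expect_equal(C[i0 + 1L, 2L], S[[1]][2L, 1L])
  expect_lte(Mod(C[i0 + 1L, 1L]), 1)
  # direct substitution into the three-term recurrence
  expect_lt(thetamcf:::recurrence_residual(C, params, tr), 1e-8)
  # the stationary operator annihilates the full coefficient set
  expect_lt(max(Mod(thetamcf:::apply_L0(C, params))), 1e-8)
})

test_that("stationary rate reaches its deterministic limits as tau -> 0", {
  st <- stationary_rate(theta_params(1, 1, 1e-3), trunc_spec(60L, 21L))
  expect_equal(st$rate, 1 / pi, tolerance = 2e-3)
  # excitable regime: exponentially small rate (needs many Fourier modes)
  st2 <- stationary_rate(theta_params(-1, 1, 1e-3), trunc_spec(400L, 21L))
  expect_lt(abs(st2$rate), 1e-6)
})

test_that("coefficient and threshold rate formulas agree", {
  st <- stationary_rate(theta_params(0.5, 1, 1), trunc_spec(80L, 80L))
  expect_equal(st$rate, st$rate_check, tolerance = 1e-6)
  expect_gt(st$rate, 0)
})

test_that("constant-variance scaling invariance holds for the MCF rate", {
  r_phys <- stationary_rate(theta_params(1, 4, 0.25),
                            trunc_spec(120L, 121L))$rate
  sc <- rescale_constant_variance(theta_params(1, 4, 0.25))
  r_hat <- stationary_rate(sc$params, trunc_spec(120L, 121L))$rate
  expect_equal(r_phys, sc$rate_factor * r_hat, tolerance = 1e-6)
})

test_that("marginal phase density is a normalized density peaked at the fixed point", {
  theta <- seq(-pi, pi, length.out = 2001)
  params <- theta_params(-1, 1, 0.5)
  tr <- trunc_spec(80L, 80L)
  dens <- marginal_phase_density(params, tr, theta)
  expect_gte(min(dens), -1e-6)
  expect_equal(trapz(theta, dens), 1, tolerance = 1e-8)
  # excitable regime: density maximal near the stable fixed point
  # theta* = 2 atan(-sqrt(|mu|)) = -pi/2
  expect_lt(abs(theta[which.max(dens)] - (-pi / 2)), 0.3)
  # uniform coefficient set reconstructs the flat density 1/(2 pi)
  C <- stationary_coefficients(params, tr)
  C[] <- 0; C[tr$n_max + 1L, 1L] <- 1
  expect_equal(marginal_phase_density(params, tr, theta, coeffs = C),
               rep(1 / (2 * pi), length(theta)), tolerance = 1e-14)
})

test_that("joint density marginalizes consistently in both directions", {
  params <- theta_params(0.5, 1, 1)
  tr <- trunc_spec(60L, 60L)
  theta <- seq(-pi, pi, length.out = 401)
  eta <- seq(-6, 6, length.out = 801)
  J <- joint_density(params, tr, theta, eta)
  expect_gte(min(J), -1e-6)
  # double integral = 1
  row_int <- apply(J, 1L, function(y) trapz(eta, y))
  expect_equal(trapz(theta, row_int), 1, tolerance = 1e-6)
  # eta-marginal reproduces the phase density
  expect_equal(row_int, marginal_phase_density(params, tr, theta),
               tolerance = 1e-6)
  # theta-marginal is the stationary OU Gaussian
  col_int <- apply(J, 2L, function(y) trapz(theta, y))
  expect_equal(col_int, dnorm(eta, 0, params$sigma), tolerance = 1e-6)
})

test_that("constant-intensity rates stay below the white-noise limit", {
  rw <- white_noise_qif_rate(0.5, D = 1)
  for (tau in c(0.05, 0.2, 1)) {
    r <- stationary_rate(theta_params(0.5, sqrt(1 / tau), tau),
                         trunc_spec(150L, 150L), check_tol = 1e-5)$rate
    expect_lt(r, rw)
  }
  # and the tau -> 0 end approaches it
  r_small <- stationary_rate(theta_params(0.5, sqrt(1 / 0.02), 0.02),
                             trunc_spec(150L, 150L), check_tol = 1e-5)$rate
  expect_equal(r_small, rw, tolerance = 2e-2)
})

test_that("colored noise increases the rate below and decreases it above the separation line", {
  r_lo <- stationary_rate(theta_params(0.25, 1, 1), trunc_spec(100L, 100L))$rate
  r_hi <- stationary_rate(theta_params(2, 1, 1), trunc_spec(100L, 100L))$rate
  expect_gt(r_lo, deterministic_rate(0.25))
  expect_lt(r_hi, deterministic_rate(2))
  # excitable regime: any rate beats the vanishing deterministic one
  r_exc <- stationary_rate(theta_params(-1, 1, 1), trunc_spec(100L, 100L))$rate
  expect_gt(r_exc, 0)
})

test_that("truncation error decreases monotonically", {
  params <- theta_params(0.5, 1, 1)
  r <- vapply(c(20L, 40L, 80L, 160L), function(n)
    stationary_rate(params, trunc_spec(n, n), check_tol = Inf)$rate, numeric(1))
  d <- abs(diff(r))
  expect_true(all(diff(d) < 0))
})
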