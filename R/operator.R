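# Coefficient-space form of the Fokker-Planck operators.
#
# A density component Q(theta, eta) = phi_0(eta)/(2 pi) sum_{n,p} a_{n,p}
# e^{i n theta} phi_p(eta) is represented by its complex coefficient matrix
# a with rows n = -n_max..n_max and columns p = 0..p_max. In this basis the
# stationary operator acts block-tridiagonally over the Fourier index:
#
#   (L0 a)_n = -i n [ (2 I - 2 B) a_n - B (a_{n-1} + a_{n+1}) ] + i A a_n,
#
# with A, B the matrices of the stationary recurrence (dividing the n-th row
# by -i n B recovers the three-term recurrence K_n c_n = c_{n-1} + c_{n+1}).
# The periodic-drive operator L_per = d/dtheta (1 + cos theta) acts as
#
#   (L_per a)_n = i n [ a_n + (a_{n-1} + a_{n+1}) / 2 ],
#
# diagonal in the Hermite index.

# Shift the Fourier index: row n of the result holds a_{n+shift} (zero-padded).
shift_n <- function(C, shift) {
  out <- matrix(0 + 0i, nrow(C), ncol(C))
  if (shift == 0L) return(C)
  if (shift > 0L) out[seq_len(nrow(C) - shift), ] <- C[(shift + 1L):nrow(C), ]
  else out[(1L - shift):nrow(C), ] <- C[seq_len(nrow(C) + shift), ]
  out
}

# Apply the stationary operator L0 (plus an optional uniform shift i*freq)
# to a coefficient matrix. Used for residual diagnostics.
apply_L0 <- function(C, params, freq_shift = 0) {
  n_max <- (nrow(C) - 1L) %/% 2L
  p_max <- ncol(C) - 1L
  B <- build_B(p_max, params$mu, params$sigma)
  n_vec <- -n_max:n_max
  nb <- shift_n(C, 1L) + shift_n(C, -1L)          # a_{n+1} + a_{n-1} per row
  drift <- (2 * C - (2 * C + nb) %*% B) * (-1i * n_vec)
  ou <- sweep(C, 2L, (0:p_max) / params$tau, `*`)  # +iA a = -(q/tau) a
  drift - ou + (1i * freq_shift) * C
}

# Apply L_per = d/dtheta (1 + cos theta).
apply_Lper <- function(C) {
  n_max <- (nrow(C) - 1L) %/% 2L
  n_vec <- -n_max:n_max
  (C + (shift_n(C, 1L) + shift_n(C, -1L)) / 2) * (1i * n_vec)
}

# Take the complex conjugate of the represented density: coefficients map as
# a_{n,p} -> Conj(a_{-n,p}).
conj_coeffs <- function(C) {
  out <- Conj(C[rev(seq_len(nrow(C))), , drop = FALSE])
  dimnames(out) <- dimnames(C)
  attributes(out)[c("n_max", "p_max", "class")] <-
    attributes(C)[c("n_max", "p_max", "class")]
  out
}

# Solve (L0 + i * freq) x = rhs for a coefficient matrix x, with the
# normalization row (n = 0, p = 0) replaced by the constraint
# x_{0,0} = norm_value (the double integral of the represented component).
#
# The system is block tridiagonal over the Fourier index with blocks
#   D_n = -i n (2 I - 2 B) + i A + i freq I,   C_n = i n B
# (row n couples to both neighbours through the same matrix C_n); it is
# eliminated by a block-Thomas sweep with dense complex LAPACK solves.
solve_Lk <- function(params, trunc, freq, rhs, norm_value = 0 + 0i,
                     resid_tol = 1e-9) {
  n_max <- trunc$n_max
  p_max <- trunc$p_max
  m <- p_max + 1L
  stopifnot(nrow(rhs) == 2L * n_max + 1L, ncol(rhs) == m)
  B <- build_B(p_max, params$mu, params$sigma)
  I2B <- 2 * diag(m) - 2 * B
  iAdiag <- -(0:p_max) / params$tau          # iA = diag(-q/tau)
  i0 <- n_max + 1L
  M <- 2L * n_max + 1L

  b <- rhs
  b[i0, 1L] <- norm_value                     # normalization constraint row

  # forward elimination: x_j = E_j x_{j+1} + f_j
  E <- vector("list", M)
  f <- matrix(0 + 0i, M, m)
  Eprev <- NULL
  for (j in seq_len(M)) {
    n <- j - i0
    Dj <- (-1i * n) * I2B
    diag(Dj) <- diag(Dj) + iAdiag + 1i * freq   # iA contributes -q/tau (real)
    Cj <- (1i * n) * B
    bj <- b[j, ]
    if (n == 0L) {
      # Cj = 0; replace the (0,0) row by the normalization constraint
      Dj[1L, ] <- 0
      Dj[1L, 1L] <- 1
      bj[1L] <- b[i0, 1L]
    }
    if (is.null(Eprev)) {
      Mj <- Dj
    } else {
      CE <- Cj %*% Eprev
      Mj <- Dj + CE
      bj <- bj - drop(Cj %*% f[j - 1L, ])
    }
    sol <- tryCatch(solve(Mj, cbind(-Cj, bj)),
                    error = function(e)
                      stop("singular block at Fourier index n = ", n,
                           " (freq = ", format(freq, digits = 6), "): ",
                           conditionMessage(e)))
    E[[j]] <- sol[, seq_len(m), drop = FALSE]
    f[j, ] <- sol[, m + 1L]
    Eprev <- E[[j]]
  }
  x <- matrix(0 + 0i, M, m,
              dimnames = list(n = as.character(-n_max:n_max),
                              p = as.character(0:p_max)))
  x[M, ] <- f[M, ]
  for (j in (M - 1L):1L) x[j, ] <- drop(E[[j]] %*% x[j + 1L, ]) + f[j, ]

  # residual of the solved linear system (excluding the replaced row)
  res <- apply_L0(x, params, freq_shift = freq) - rhs
  res[i0, 1L] <- x[i0, 1L] - norm_value
  scale <- max(1, max(Mod(rhs)))
  resid <- max(Mod(res)) / scale
  if (resid > resid_tol)
    warning(sprintf("linear-system residual %.3g exceeds %.1g (freq = %g)",
                    resid, resid_tol, freq))
  structure(x, n_max = n_max, p_max = p_max, resid = resid,
            class = "mcf_coeffs")
}
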