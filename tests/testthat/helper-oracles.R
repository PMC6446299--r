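# Independent brute-force oracles: direct double-loop / enumeration
# implementations used to validate the FFT- and matrix-based fast paths.

# Direct evaluation of the locally normalized correlation and the local
# standard deviation at every valid footprint position.
flc_bruteforce <- function(T, so) {
  b <- nrow(so$S)
  P <- so$P
  nx <- nrow(T) - b + 1
  ny <- ncol(T) - b + 1
  C <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      w <- T[i:(i + b - 1), j:(j + b - 1)]
      num <- sum(so$S * so$M * w)
      s1 <- sum(so$M * w) / P
      s2 <- sum(so$M * w^2) / P
      sg <- sqrt(max(s2 - s1 * s1, 0))
      C[i, j] <- if (sg > 0) num / (P * sg) else 0
    }
  }
  C
}

# Enumerated E-step: normalized Gaussian posterior weights over every
# (class, grid point) pair for every particle, plus the log evidence.
estep_bruteforce <- function(stack, theta, grid) {
  n <- dim(stack)[3]
  J <- prod(dim(stack)[1:2])
  K <- length(theta$A)
  G <- nrow(grid)
  lp_t <- -(grid$tx^2 + grid$ty^2) / (2 * theta$xi^2)
  lp_t <- lp_t - log(sum(exp(lp_t)))
  lw <- matrix(0, n, K * G)
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      for (g in seq_len(G)) {
        ref <- bofem::transform_image(theta$A[[k]], grid$alpha[g],
                                      grid$tx[g], grid$ty[g])
        d2 <- sum((stack[, , i] - ref)^2)
        lw[i, (k - 1) * G + g] <- -d2 / (2 * theta$sigma^2) + lp_t[g] +
          log(theta$weights[k]) - J / 2 * log(2 * pi * theta$sigma^2)
      }
    }
  }
  logz <- apply(lw, 1, function(r) {
    m <- max(r)
    m + log(sum(exp(r - m)))
  })
  list(resp = exp(lw - logz), log_evidence = logz)
}

# Enumerated M-step from brute-force responsibilities.
mstep_bruteforce <- function(stack, resp, theta, grid) {
  n <- dim(stack)[3]
  box <- dim(stack)[1]
  J <- box^2
  K <- length(theta$A)
  G <- nrow(grid)
  A <- vector("list", K)
  wk <- numeric(K)
  ss <- 0
  for (k in seq_len(K)) {
    acc <- matrix(0, box, box)
    Wk <- 0
    for (i in seq_len(n)) {
      for (g in seq_len(G)) {
        p <- resp[i, (k - 1) * G + g]
        Wk <- Wk + p
        if (p > 0) {
          acc <- acc + p * bofem::transform_image_inv(
            stack[, , i], grid$alpha[g], grid$tx[g], grid$ty[g])
          ref <- bofem::transform_image(theta$A[[k]], grid$alpha[g],
                                        grid$tx[g], grid$ty[g])
          ss <- ss + p * sum((stack[, , i] - ref)^2)
        }
      }
    }
    A[[k]] <- acc / Wk
    wk[k] <- Wk / n
  }
  list(A = A, weights = wk, sigma = sqrt(ss / (n * J)))
}

# Direct per-pixel ring accumulation of the Fourier ring correlation.
frc_bruteforce <- function(a, b) {
  n <- nrow(a)
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  fx <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[1:n]
  out <- numeric(floor(n / 2))
  for (r in seq_len(floor(n / 2))) {
    num <- 0; pa <- 0; pb <- 0
    for (i in 1:n) {
      for (j in 1:n) {
        rr <- round(sqrt(fx[i]^2 + fx[j]^2))
        if (rr == r) {
          num <- num + Re(fa[i, j] * Conj(fb[i, j]))
          pa <- pa + abs(fa[i, j])^2
          pb <- pb + abs(fb[i, j])^2
        }
      }
    }
    out[r] <- num / sqrt(pa * pb)
  }
  out
}

# Voxel line sums along the rotated z axis, summed over the whole volume:
# total projected mass must match the volume integral for any rotation.
projection_mass_oracle <- function(vol) sum(vol)
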