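# Multi-reference maximum-likelihood 2D alignment by expectation-
# maximization. The generative model for particle i is
#
#   X_i = R(phi_i) A_k + sigma G_i
#
# with latent in-plane transform phi = (alpha, tx, ty) and latent class k.
# The E-step evaluates responsibilities P(k, phi | X_i, Theta) on a discrete
# transform grid (Gaussian data term, uniform rotation prior, isotropic
# Gaussian translation prior of std xi normalized over the grid, mixing
# weights w_k), using log-sum-exp. The M-step updates the class averages as
# probability-weighted averages of the back-transformed images,
#
#   A_k <- sum_i sum_phi P(k, phi | X_i) R^-1(phi) X_i / sum P ,
#
# the mixing weights as mean responsibilities, sigma^2 as the probability-
# weighted mean of ||X_i - R(phi) A_k||^2 / J, and xi as the responsibility-
# weighted RMS shift. With delta (hard) responsibilities the update reduces
# to the plain average of aligned images, which is the classical iterative
# cross-correlation alignment provided here as cc_align().

#' Transform sampling grid for the latent in-plane transforms
#'
#' @param n_rot number of rotation samples (uniform over `[0, 360)`).
#' @param t_max maximum translation magnitude, pixels.
#' @param t_step translation step, pixels (integer steps by default).
#' @return data.frame (`alpha`, `tx`, `ty`) of class `transform_grid`.
#' @export
transform_grid <- function(n_rot = 72, t_max = 3, t_step = 1) {
  alphas <- seq(0, 360 - 360 / n_rot, by = 360 / n_rot)
  ts <- seq(-t_max, t_max, by = t_step)
  g <- expand.grid(tx = ts, ty = ts, alpha = alphas,
                   KEEP.OUT.ATTRS = FALSE)[, c("alpha", "tx", "ty")]
  structure(g, class = c("transform_grid", "data.frame"))
}

#' Normalize particles against their background annulus
#'
#' Shifts and scales each image so the background annulus (pixels with
#' radius in `annulus` from the box center) has mean 0 and standard
#' deviation 1.
#'
#' @param stack particle stack `c(box, box, n)`.
#' @param annulus radii `c(r_in, r_out)` in pixels (default: from
#'   `0.4 * box` to the box corners).
#' @return normalized stack, attributes preserved.
#' @export
normalize_particles <- function(stack, annulus = NULL) {
  d <- dim(stack)
  box <- d[1]
  annulus <- annulus %||% c(0.4 * box, Inf)
  c0 <- (box - 1) / 2
  r <- sqrt(outer((0:(box - 1) - c0)^2, (0:(box - 1) - c0)^2, "+"))
  bg <- r >= annulus[1] & r <= annulus[2]
  if (!any(bg)) stop("empty background annulus")
  out <- stack
  for (i in seq_len(d[3])) {
    v <- stack[, , i][bg]
    s <- stats::sd(v)
    if (s == 0) stop("image ", i, " has zero background standard deviation")
    out[, , i] <- (stack[, , i] - mean(v)) / s
  }
  attributes(out) <- attributes(stack)
  out
}

#' Bin a particle stack by Fourier cropping
#'
#' Keeps the central `box/factor` square of Fourier coefficients, preserving
#' the per-pixel mean (DC) exactly; the pixel size is multiplied by the
#' factor.
#'
#' @param stack particle stack `c(box, box, n)`.
#' @param factor integer scaling factor dividing the box size.
#' @return binned stack with updated `pixel_size` attribute.
#' @export
bin_particles <- function(stack, factor) {
  factor <- as.integer(factor)
  d <- dim(stack)
  if (factor == 1L) return(stack)
  if (d[1] %% factor != 0) stop("box size not divisible by the factor")
  b <- d[1]; m <- b %/% factor
  out <- array(0, c(m, m, d[3]))
  ctr <- floor(b / 2) + 1
  rows <- (ctr - floor(m / 2)):(ctr + ceiling(m / 2) - 1)
  for (i in seq_len(d[3])) {
    Fs <- fftshift2(stats::fft(stack[, , i]))[rows, rows]
    out[, , i] <- Re(stats::fft(ifftshift2(Fs), inverse = TRUE)) / b^2
  }
  attr(out, "pixel_size") <- (attr(stack, "pixel_size") %||% 1) * factor
  attr(out, "coords") <- attr(stack, "coords")
  out
}

#' Starting references for EM alignment
#'
#' The three initialization schemes: `random_noise_image` draws K distinct
#' particles from the stack; `gaussian_circle` uses K copies of a Gaussian
#' circle, each with a small seeded perturbation (1% of the reference std)
#' to break the symmetry between classes; `unaligned_average` averages K
#' random disjoint subsets of the (unaligned) stack — for K = 1 this is the
#' plain stack mean.
#'
#' @param stack particle stack `c(box, box, n)`.
#' @param mode one of `"random_noise_image"`, `"gaussian_circle"`,
#'   `"unaligned_average"`.
#' @param K number of classes (`1 <= K <= n`).
#' @param rng_seed integer seed.
#' @param sigma_circle Gaussian-circle radial std, pixels.
#' @param t_max translation range used to initialize the shift prior.
#' @return object of class `model_state`: list with `A` (list of K class
#'   averages), `weights`, `sigma`, `xi`, `pixel_size`.
#' @export
make_start_references <- function(stack, mode = c("random_noise_image",
                                                  "gaussian_circle",
                                                  "unaligned_average"),
                                  K = 5, rng_seed = 1, sigma_circle = NULL,
                                  t_max = 3) {
  mode <- match.arg(mode)
  d <- dim(stack)
  n <- d[3]; box <- d[1]
  if (K > n) stop("K exceeds the number of particles")
  sigma_circle <- sigma_circle %||% (box / 6)
  A <- with_seed(rng_seed, switch(mode,
    random_noise_image = {
      lapply(sample(n, K), function(i) stack[, , i])
    },
    gaussian_circle = {
      g <- make_gaussian_circle(box, sigma_circle)
      lapply(seq_len(K), function(k) {
        g + matrix(stats::rnorm(box^2, 0, 0.01 * stats::sd(g)), box, box)
      })
    },
    unaligned_average = {
      grp <- sample(rep_len(seq_len(K), n))
      lapply(seq_len(K), function(k) {
        idx <- which(grp == k)
        apply(stack[, , idx, drop = FALSE], c(1, 2), mean)
      })
    }))
  structure(list(A = A, weights = rep(1 / K, K),
                 sigma = stats::sd(as.vector(stack)),
                 xi = max(t_max / 2, 0.5),
                 pixel_size = attr(stack, "pixel_size") %||% 1),
            class = "model_state")
}

# Flatten a stack to an n x J matrix (images as rows).
stack_matrix <- function(stack) {
  d <- dim(stack)
  t(matrix(stack, d[1] * d[2], d[3]))
}

# Reference matrix over (class, grid) rows: row index runs g fastest within
# class k, i.e. row (k - 1) * G + g is R(phi_g) A_k.
reference_matrix <- function(theta, grid) {
  K <- length(theta$A)
  G <- nrow(grid)
  J <- length(theta$A[[1]])
  box <- nrow(theta$A[[1]])
  refm <- matrix(0, K * G, J)
  alphas <- unique(grid$alpha)
  for (k in seq_len(K)) {
    for (a in alphas) {
      rot <- transform_image(theta$A[[k]], a)
      rows <- which(grid$alpha == a)
      for (g in rows) {
        refm[(k - 1) * G + g, ] <-
          shift_integer(rot, grid$tx[g], grid$ty[g])
      }
    }
  }
  refm
}

# Log prior over grid points (rotation uniform, translation Gaussian with
# std xi, normalized over the discrete grid).
grid_log_prior <- function(grid, xi) {
  lp <- -(grid$tx^2 + grid$ty^2) / (2 * xi^2)
  lp - log(sum(exp(lp - max(lp)))) - max(lp)
}

#' Expectation step
#'
#' Computes the posterior responsibilities P(k, phi | X_i, Theta) of every
#' particle over classes and the discrete transform grid, together with the
#' per-particle log evidence; their sum is the (grid-discretized)
#' log-likelihood L(Theta).
#'
#' @param stack normalized particle stack.
#' @param theta a `model_state`.
#' @param grid a [transform_grid()].
#' @param truncate responsibilities below this value are dropped and the
#'   rest renormalized (sparse storage).
#' @return object of class `posterior_table`: list with `resp` (sparse
#'   n x (K*G) responsibilities, grid index fastest within class),
#'   `log_evidence` (length n), `loglik`, and the sufficient statistics
#'   `ss_d2` (responsibility-weighted sum of squared residuals) and
#'   `shift_m2` (responsibility-weighted sum of squared shift magnitudes).
#' @export
e_step <- function(stack, theta, grid, truncate = 1e-12) {
  if (theta$sigma <= 0) stop("sigma must be > 0")
  X <- stack_matrix(stack)
  n <- nrow(X); J <- ncol(X)
  K <- length(theta$A); G <- nrow(grid)
  refm <- reference_matrix(theta, grid)
  r2 <- rowSums(refm * refm)
  x2 <- rowSums(X * X)
  CP <- X %*% t(refm)                              # n x (K*G)
  lp_grid <- grid_log_prior(grid, theta$xi)
  lp <- rep(lp_grid, K) + rep(log(theta$weights), each = G)
  s2 <- theta$sigma^2
  const <- -J / 2 * log(2 * pi * s2)
  d2 <- outer(x2, r2, "+") - 2 * CP
  lw <- sweep(-d2 / (2 * s2), 2, lp, "+") + const
  logz <- log_sum_exp_rows(lw)
  resp <- exp(lw - logz)
  # sufficient statistics on the untruncated responsibilities
  ss_d2 <- sum(resp * d2)
  shift_m2 <- sum(resp %*% rep(grid$tx^2 + grid$ty^2, K))
  col_tot <- colSums(resp)
  resp[resp < truncate] <- 0
  rs <- rowSums(resp)
  resp <- resp / rs
  structure(list(resp = Matrix::Matrix(resp, sparse = TRUE),
                 log_evidence = logz, loglik = sum(logz),
                 ss_d2 = ss_d2, shift_m2 = shift_m2, col_tot = col_tot,
                 K = K, G = G),
            class = "posterior_table")
}

#' Maximization step
#'
#' Probability-weighted updates of the class averages, mixing weights, noise
#' sigma and shift-prior std from the E-step responsibilities.
#'
#' @param stack normalized particle stack.
#' @param posteriors an [e_step()] result.
#' @param grid the same [transform_grid()].
#' @param theta_prev previous model (used to carry the pixel size, to guard
#'   the xi update, and to re-seed empty classes).
#' @return updated `model_state`.
#' @export
m_step <- function(stack, posteriors, grid, theta_prev = NULL) {
  d <- dim(stack)
  box <- d[1]; n <- d[3]; J <- box * box
  K <- posteriors$K; G <- posteriors$G
  X <- stack_matrix(stack)
  Y <- as.matrix(Matrix::crossprod(posteriors$resp, X))   # (K*G) x J
  W <- posteriors$col_tot
  alphas <- unique(grid$alpha)
  A <- vector("list", K)
  wk <- numeric(K)
  for (k in seq_len(K)) {
    rows_k <- (k - 1) * G + seq_len(G)
    Wk <- sum(W[rows_k])
    wk[k] <- Wk / n
    acc <- matrix(0, box, box)
    for (a in alphas) {
      ga <- which(grid$alpha == a)
      za <- matrix(0, box, box)
      any_mass <- FALSE
      for (g in ga) {
        row <- (k - 1) * G + g
        if (W[row] <= 0 && sum(abs(Y[row, ])) == 0) next
        any_mass <- TRUE
        za <- za + shift_integer(matrix(Y[row, ], box, box),
                                 -grid$tx[g], -grid$ty[g])
      }
      if (any_mass) acc <- acc + transform_image(za, -a)
    }
    A[[k]] <- if (Wk > 0) acc / Wk else acc
  }
  # empty-class policy: re-seed from the particle with the worst evidence
  empty <- which(vapply(seq_len(K), function(k) {
    sum(W[(k - 1) * G + seq_len(G)]) < 1e-6 * n
  }, logical(1)))
  if (length(empty)) {
    worst <- order(posteriors$log_evidence)[seq_along(empty)]
    for (j in seq_along(empty)) {
      A[[empty[j]]] <- stack[, , worst[j]]
      wk[empty[j]] <- 1 / n
      bof_log("m_step: re-seeded empty class ", empty[j],
              " from particle ", worst[j])
    }
    wk <- wk / sum(wk)
  }
  sigma <- sqrt(max(posteriors$ss_d2 / (n * J), 1e-12))
  # xi: responsibility-weighted RMS shift (per dimension), guarded so the
  # discrete-grid prior likelihood never decreases relative to the old xi
  xi_new <- max(sqrt(posteriors$shift_m2 / (2 * n)), 0.25)
  if (!is.null(theta_prev)) {
    q_shift <- function(xi) {
      lp <- grid_log_prior(grid, xi)
      sum(W * rep(lp, K))
    }
    if (q_shift(theta_prev$xi) > q_shift(xi_new)) xi_new <- theta_prev$xi
  }
  structure(list(A = A, weights = wk, sigma = sigma, xi = xi_new,
                 pixel_size = theta_prev$pixel_size %||%
                   (attr(stack, "pixel_size") %||% 1)),
            class = "model_state")
}

#' Maximum-likelihood multi-reference alignment by EM
#'
#' Alternates [e_step()] and [m_step()] until the relative log-likelihood
#' change falls below `tol` or `max_iter` is reached. The log-likelihood is
#' non-decreasing up to grid-discretization/interpolation tolerance.
#'
#' @param stack normalized particle stack.
#' @param start starting `model_state` (see [make_start_references()]).
#' @param grid a [transform_grid()].
#' @param max_iter iteration cap.
#' @param tol relative log-likelihood convergence tolerance.
#' @param milestones iterations at which class-average snapshots are kept.
#' @return list with `model` (final `model_state`), `trace` (data.frame of
#'   per-iteration log-likelihood, sigma, xi, weights; class `em_trace`,
#'   with milestone snapshots in `attr(trace, "snapshots")`), and
#'   `posteriors` (final [e_step()] table).
#' @export
em_align <- function(stack, start, grid, max_iter = 100, tol = 1e-7,
                     milestones = c(1, 10, 50, 100)) {
  theta <- start
  trace <- data.frame(iter = integer(0), loglik = numeric(0),
                      sigma = numeric(0), xi = numeric(0))
  wtrace <- NULL
  snapshots <- list()
  post <- NULL
  prev_ll <- -Inf
  for (it in seq_len(max_iter)) {
    post <- e_step(stack, theta, grid)
    theta_new <- m_step(stack, post, grid, theta_prev = theta)
    if (!is.finite(theta_new$sigma) || theta_new$sigma <= 0) {
      stop("divergent sigma at iteration ", it, "; trace:\n",
           paste(utils::capture.output(print(trace)), collapse = "\n"))
    }
    theta <- theta_new
    trace[it, ] <- list(it, post$loglik, theta$sigma, theta$xi)
    wtrace <- rbind(wtrace, theta$weights)
    if (it %in% milestones) snapshots[[as.character(it)]] <- theta$A
    bof_log("em_align: iter ", it, " loglik ", post$loglik,
            " sigma ", theta$sigma)
    if (is.finite(prev_ll) &&
        abs(post$loglik - prev_ll) < tol * abs(prev_ll)) break
    prev_ll <- post$loglik
  }
  snapshots[["final"]] <- theta$A
  colnames(wtrace) <- paste0("w", seq_along(theta$weights))
  trace <- cbind(trace, as.data.frame(wtrace))
  attr(trace, "snapshots") <- snapshots
  class(trace) <- c("em_trace", "data.frame")
  list(model = theta, trace = trace, posteriors = post)
}

#' Iterative cross-correlation alignment (hard assignment)
#'
#' The classical single-reference alignment: each iteration assigns every
#' image the transform maximizing its inner product with the current
#' average, then recomputes the plain average of the back-transformed
#' images. This is the sigma -> 0 (delta-responsibility) limit of
#' [em_align()].
#'
#' @param stack particle stack.
#' @param start_reference starting average (matrix).
#' @param max_iter iteration cap (stops early when assignments stabilize).
#' @param grid a [transform_grid()].
#' @return list with `average`, `transforms` (data.frame `alpha`, `tx`,
#'   `ty` per image), `n_iter`.
#' @export
cc_align <- function(stack, start_reference, max_iter = 20,
                     grid = transform_grid()) {
  X <- stack_matrix(stack)
  n <- nrow(X)
  box <- nrow(start_reference)
  A <- start_reference
  theta1 <- structure(list(A = list(A), weights = 1, sigma = 1, xi = 1e6,
                           pixel_size = attr(stack, "pixel_size") %||% 1),
                      class = "model_state")
  assign_prev <- rep(-1L, n)
  it <- 0
  for (it in seq_len(max_iter)) {
    theta1$A[[1]] <- A
    refm <- reference_matrix(theta1, grid)
    scores <- X %*% t(refm)
    best <- max.col(scores, ties.method = "first")
    acc <- matrix(0, box, box)
    for (i in seq_len(n)) {
      g <- best[i]
      acc <- acc + transform_image_inv(stack[, , i], grid$alpha[g],
                                       grid$tx[g], grid$ty[g])
    }
    A <- acc / n
    if (all(best == assign_prev)) break
    assign_prev <- best
  }
  list(average = A,
       transforms = data.frame(alpha = grid$alpha[assign_prev],
                               tx = grid$tx[assign_prev],
                               ty = grid$ty[assign_prev]),
       n_iter = it)
}
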