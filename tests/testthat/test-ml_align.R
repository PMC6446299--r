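test_that("background normalization is idempotent and hits mean 0 / sd 1", {
  set.seed(41)
  st <- array(rnorm(32 * 32 * 5, mean = 3, sd = 2), c(32, 32, 5))
  nm <- normalize_particles(st)
  box <- 32
  c0 <- (box - 1) / 2
  r <- sqrt(outer((0:(box - 1) - c0)^2, (0:(box - 1) - c0)^2, "+"))
  bg <- r >= 0.4 * box
  for (i in 1:5) {
    expect_lt(abs(mean(nm[, , i][bg])), 1e-6)
    expect_lt(abs(sd(nm[, , i][bg]) - 1), 1e-6)
  }
  expect_equal(normalize_particles(nm), nm, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(normalize_particles(array(1, c(16, 16, 1))), "zero background")
})

test_that("Fourier-crop binning divides the box and preserves the mean", {
  set.seed(42)
  st <- array(rnorm(180 * 180 * 2), c(180, 180, 2))
  attr(st, "pixel_size") <- 1
  expect_identical(bin_particles(st, 1), st)
  b3 <- bin_particles(st, 3)
  expect_equal(dim(b3), c(60, 60, 2))
  expect_equal(attr(b3, "pixel_size"), 3)
  for (i in 1:2) expect_equal(mean(b3[, , i]), mean(st[, , i]),
                              tolerance = 1e-6)
  expect_error(bin_particles(st, 7), "divisible")
})

test_that("starting references follow the three initialization schemes", {
  set.seed(43)
  st <- array(rnorm(20 * 20 * 12), c(20, 20, 12))
  # K = 1 unaligned average is the plain mean of the stack
  m1 <- make_start_references(st, "unaligned_average", K = 1, rng_seed = 1)
  expect_equal(m1$A[[1]], apply(st, c(1, 2), mean), tolerance = 1e-12)
  expect_equal(sum(m1$weights), 1)
  # gaussian-circle starts are rotationally symmetric up to the perturbation
  m2 <- make_start_references(st, "gaussian_circle", K = 3, rng_seed = 2)
  g <- m2$A[[1]]
  expect_lt(max(abs(g - t(g)[, ncol(g):1])),
            0.1 * max(abs(g)))
  expect_false(identical(m2$A[[1]], m2$A[[2]]))  # symmetry broken
  # random-noise-image starts are actual stack members
  m3 <- make_start_references(st, "random_noise_image", K = 2, rng_seed = 3)
  found <- vapply(1:2, function(k) {
    any(vapply(1:12, function(i) {
      isTRUE(all.equal(m3$A[[k]], st[, , i]))
    }, logical(1)))
  }, logical(1))
  expect_true(all(found))
  expect_error(make_start_references(st, "gaussian_circle", K = 20), "K")
})

test_that("E-step responsibilities match the enumeration oracle below 1e-10", {
  toy <- toy_em_problem()
  post <- e_step(toy$stack, toy$theta, toy$grid)
  oracle <- estep_bruteforce(toy$stack, toy$theta, toy$grid)
  expect_lt(max(abs(as.matrix(post$resp) - oracle$resp)), 1e-10)
  expect_equal(post$log_evidence, oracle$log_evidence, tolerance = 1e-10)
  expect_equal(Matrix::rowSums(post$resp), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("M-step updates match the enumeration oracle below 1e-10", {
  toy <- toy_em_problem()
  post <- e_step(toy$stack, toy$theta, toy$grid)
  oracle_post <- estep_bruteforce(toy$stack, toy$theta, toy$grid)
  oracle <- mstep_bruteforce(toy$stack, oracle_post$resp, toy$theta, toy$grid)
  upd <- m_step(toy$stack, post, toy$grid, theta_prev = toy$theta)
  for (k in 1:2) {
    expect_lt(max(abs(upd$A[[k]] - oracle$A[[k]])), 1e-10)
  }
  expect_equal(upd$weights, oracle$weights, tolerance = 1e-10)
  expect_equal(sum(upd$weights), 1, tolerance = 1e-12)
  expect_equal(upd$sigma, oracle$sigma, tolerance = 1e-10)
})

test_that("a noiseless particle at a grid transform gets a delta posterior", {
  # asymmetric reference so no two grid transforms coincide
  A <- make_gaussian_circle(16, 3)
  A[4:6, 8:10] <- A[4:6, 8:10] + 1.5
  grid <- transform_grid(n_rot = 4, t_max = 1)
  st <- array(0, c(16, 16, 1))
  g0 <- which(grid$alpha == 90 & grid$tx == 1 & grid$ty == 0)
  st[, , 1] <- transform_image(A, 90, 1, 0)
  theta <- structure(list(A = list(A), weights = 1, sigma = 0.02, xi = 1,
                          pixel_size = 1), class = "model_state")
  post <- e_step(st, theta, grid)
  expect_gt(as.matrix(post$resp)[1, g0], 0.999)
})

test_that("identical classes share responsibilities equally at every transform", {
  set.seed(44)
  A <- matrix(rnorm(64), 8, 8)
  st <- array(rnorm(64 * 2, sd = 0.5), c(8, 8, 2))
  grid <- transform_grid(n_rot = 2, t_max = 1)
  theta <- structure(list(A = list(A, A), weights = c(0.5, 0.5), sigma = 1,
                          xi = 1, pixel_size = 1), class = "model_state")
  post <- e_step(st, theta, grid)
  r <- as.matrix(post$resp)
  G <- nrow(grid)
  expect_equal(r[, 1:G], r[, G + 1:G], tolerance = 1e-12)
})

test_that("delta posteriors at the identity reduce the M-step to the plain mean", {
  set.seed(45)
  st <- array(rnorm(10 * 10 * 6), c(10, 10, 6))
  grid <- transform_grid(n_rot = 2, t_max = 1)
  theta <- structure(list(A = list(apply(st, c(1, 2), mean)), weights = 1,
                          sigma = 1, xi = 1, pixel_size = 1),
                     class = "model_state")
  # construct a posterior table with all mass on the identity transform
  G <- nrow(grid)
  id <- which(grid$alpha == 0 & grid$tx == 0 & grid$ty == 0)
  resp <- matrix(0, 6, G)
  resp[, id] <- 1
  post <- structure(list(resp = Matrix::Matrix(resp, sparse = TRUE),
                         log_evidence = rep(0, 6), loglik = 0,
                         ss_d2 = sum((st - c(theta$A[[1]]))^2),
                         shift_m2 = 0, col_tot = colSums(resp),
                         K = 1, G = G),
                    class = "posterior_table")
  upd <- m_step(st, post, grid, theta_prev = theta)
  expect_equal(upd$A[[1]], apply(st, c(1, 2), mean), tolerance = 1e-12)
})

test_that("EM separates a noiseless two-view stack started from the views", {
  set.seed(46)
  bank <- desk_bank()
  v1 <- bin_particles(array(bank[[1]], c(180, 180, 1)), 6)[, , 1]
  v2 <- bin_particles(array(bank[[2]], c(180, 180, 1)), 6)[, , 1]
  v1 <- v1 / sd(v1); v2 <- v2 / sd(v2)
  st <- array(0, c(30, 30, 8))
  for (i in 1:8) st[, , i] <- if (i %% 2) v1 else v2
  st <- st + array(rnorm(30 * 30 * 8, sd = 1e-3), c(30, 30, 8))
  grid <- transform_grid(n_rot = 8, t_max = 1)
  theta0 <- structure(list(A = list(v1, v2), weights = c(0.5, 0.5),
                           sigma = 0.05, xi = 1, pixel_size = 6),
                      class = "model_state")
  fit <- em_align(st, theta0, grid, max_iter = 2, milestones = 1)
  r <- as.matrix(fit$posteriors$resp)
  G <- nrow(grid)
  class_of <- ifelse(rowSums(r[, 1:G]) > 0.5, 1, 2)
  expect_equal(class_of, rep(c(1, 2), 4))
  expect_equal(sum(fit$model$weights), 1, tolerance = 1e-12)
})

test_that("EM log-likelihood is non-decreasing and responsibilities stay
           normalized on a noisy stack", {
  set.seed(47)
  A <- make_gaussian_circle(16, 3)
  st <- array(0, c(16, 16, 40))
  for (i in 1:40) {
    st[, , i] <- transform_image(A, runif(1, 0, 360)) +
      matrix(rnorm(256, sd = 1), 16, 16)
  }
  st <- normalize_particles(st, annulus = c(6, Inf))
  grid <- transform_grid(n_rot = 12, t_max = 1)
  start <- make_start_references(st, "gaussian_circle", K = 2, rng_seed = 5,
                                 t_max = 1)
  fit <- em_align(st, start, grid, max_iter = 12)
  ll <- fit$trace$loglik
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-length(ll)])))
  expect_equal(Matrix::rowSums(fit$posteriors$resp), rep(1, 40),
               tolerance = 1e-9, ignore_attr = TRUE)
  wcols <- grep("^w", names(fit$trace))
  expect_equal(rowSums(fit$trace[, wcols, drop = FALSE]), rep(1, nrow(fit$trace)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("cc_align recovers known shifts and sharpens the average", {
  set.seed(48)
  A <- make_gaussian_circle(24, 4)
  shifts <- cbind(sample(-2:2, 30, TRUE), sample(-2:2, 30, TRUE))
  st <- array(0, c(24, 24, 30))
  for (i in 1:30) {
    st[, , i] <- transform_image(A, 0, shifts[i, 1], shifts[i, 2]) +
      matrix(rnorm(576, sd = 0.05), 24, 24)
  }
  grid <- transform_grid(n_rot = 1, t_max = 3)
  out <- cc_align(st, apply(st, c(1, 2), mean), max_iter = 10, grid = grid)
  expect_equal(out$transforms$tx, shifts[, 1])
  expect_equal(out$transforms$ty, shifts[, 2])
  unaligned <- apply(st, c(1, 2), mean)
  expect_gt(max(out$average), max(unaligned))

  # single image: the average is the best-aligned copy of itself
  one <- array(st[, , 1], c(24, 24, 1))
  o1 <- cc_align(one, st[, , 1], max_iter = 3, grid = grid)
  expect_equal(o1$average, st[, , 1], tolerance = 1e-9)
})

test_that("EM with tiny sigma and a flat shift prior matches cc_align
           assignments (hard-assignment limit)", {
  set.seed(49)
  A <- make_gaussian_circle(16, 3)
  st <- array(0, c(16, 16, 10))
  sh <- cbind(sample(-1:1, 10, TRUE), sample(-1:1, 10, TRUE))
  for (i in 1:10) {
    st[, , i] <- transform_image(A, 0, sh[i, 1], sh[i, 2]) +
      matrix(rnorm(256, sd = 0.02), 16, 16)
  }
  grid <- transform_grid(n_rot = 1, t_max = 1)
  cc <- cc_align(st, A, max_iter = 1, grid = grid)
  theta <- structure(list(A = list(A), weights = 1, sigma = 0.02, xi = 1e6,
                          pixel_size = 1), class = "model_state")
  post <- e_step(st, theta, grid)
  em_best <- apply(as.matrix(post$resp), 1, which.max)
  cc_best <- match(paste(cc$transforms$tx, cc$transforms$ty),
                   paste(grid$tx, grid$ty))
  expect_equal(em_best, cc_best, ignore_attr = TRUE)
})
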