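test_that("projection of a point volume is a centered point in every view", {
  n <- 33
  vol <- array(0, c(n, n, n))
  vol[17, 17, 17] <- 1   # voxel at the rotation center (n-1)/2 = 16 (0-based)
  bank <- render_projection_set(vol, n_views = 4, rng_seed = 3, box = n)
  for (p in bank) {
    # trilinear interpolation spreads the point over the neighboring pixels
    peak <- which(p == max(p), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - 17)), 1)
    expect_gt(sum(p[16:18, 16:18]), 0.95 * sum(p))
  }
})

test_that("projections of a spherically symmetric blob are view-independent", {
  n <- 33
  c0 <- (n - 1) / 2
  g <- exp(-outer(
    outer((0:(n - 1) - c0)^2, (0:(n - 1) - c0)^2, "+"),
    (0:(n - 1) - c0)^2, "+") / (2 * 4^2))
  bank <- render_projection_set(g, n_views = 5, rng_seed = 4, box = n)
  for (i in 2:5) {
    # agreement up to trilinear-interpolation anisotropy
    expect_lt(max(abs(bank[[i]] - bank[[1]])), 0.01 * max(bank[[1]]))
  }
})

test_that("projection conserves the volume integral (line-sum oracle)", {
  vol <- phantom_trimer(n = 48, pixel_size = 3)
  total <- projection_mass_oracle(vol)
  bank <- render_projection_set(vol, n_views = 8, rng_seed = 5, box = 64)
  for (p in bank) expect_equal(sum(p), total, tolerance = 1e-3)
  expect_error(render_projection_set(array(0, c(8, 8, 8)), 2), "empty")
})

test_that("micrograph synthesis places particles with separation and conserves mass", {
  vol <- phantom_trimer(n = 48, pixel_size = 3)
  bank <- render_projection_set(vol, n_views = 2, rng_seed = 6, box = 60)
  one <- synthesize_micrograph(bank, 1, c(256, 256), rng_seed = 11)
  expect_equal(nrow(one$truth), 1)
  # nonzero support is one box around the recorded center
  nz <- which(abs(one$micrograph) > 1e-9, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - 1 - one$truth$x) <= 30))
  expect_true(all(abs(nz[, 2] - 1 - one$truth$y) <= 30))

  many <- synthesize_micrograph(bank, 20, c(512, 512), rng_seed = 12)
  expect_equal(nrow(many$truth), 20)
  d <- as.matrix(dist(many$truth[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 0.8 * 60)
  # additive placement conserves total intensity within interpolation tolerance
  placed <- sum(vapply(seq_len(20), function(i) {
    sum(transform_image(bank[[many$truth$view[i]]], many$truth$angle[i]))
  }, numeric(1)))
  expect_equal(sum(many$micrograph), placed, tolerance = 1e-6)

  expect_error(
    synthesize_micrograph(bank, 50, c(128, 128), rng_seed = 1),
    "density|too small")
})

test_that("CTF closed forms: pure amplitude contrast, DC value, first zero", {
  ctf1 <- ctf_params(voltage = 200, defocus = 0, cs = 0,
                     amplitude_contrast = 1, envelope_halfwidth = Inf)
  set.seed(8)
  img <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(apply_ctf(img, ctf1), -img, tolerance = 1e-10,
               ignore_attr = TRUE)

  ctf <- ctf_params()  # 200 kV, -1 um, Cs 2.0 mm, A = 0.10, b = 0.333 1/A
  expect_equal(ctf_eval(0, ctf), -0.10)
  # DC component scaled by -A exactly
  out <- apply_ctf(img, ctf)
  expect_equal(mean(out), -0.10 * mean(img), tolerance = 1e-10)

  # independent oracle: root-find the analytic expression written out here
  lambda <- 12.2643 / sqrt(200e3 * (1 + 0.97845e-6 * 200e3))
  gam <- function(k) pi * lambda * k^2 * 1e4 - (pi / 2) * 2e7 * lambda^3 * k^4
  f <- function(k) -(sqrt(1 - 0.01) * sin(gam(k)) + 0.10 * cos(gam(k)))
  root <- uniroot(f, c(0.01, 0.07), tol = 1e-12)$root
  expect_equal(first_ctf_zero(ctf), root, tolerance = 1e-4)
})

test_that("CTF application is linear", {
  set.seed(9)
  ctf <- ctf_params(pixel_size = 2)
  i1 <- matrix(rnorm(48 * 48), 48, 48)
  i2 <- matrix(rnorm(48 * 48), 48, 48)
  lhs <- apply_ctf(2.5 * i1 - 1.3 * i2, ctf)
  rhs <- 2.5 * apply_ctf(i1, ctf) - 1.3 * apply_ctf(i2, ctf)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("noise scaling hits the target SNR and leaves the signal intact", {
  vol <- phantom_trimer(n = 48, pixel_size = 3)
  bank <- render_projection_set(vol, n_views = 2, rng_seed = 7, box = 60)
  sim <- synthesize_micrograph(bank, 60, c(1024, 1024), rng_seed = 13)
  nl <- sim$micrograph
  noisy <- add_noise_to_snr(nl, 0.02, rng_seed = 21)
  noise <- noisy - nl
  expect_equal(compute_snr(nl, noise), 0.02, tolerance = 0.01)
  # independence of noise and signal
  expect_lt(abs(cor(as.vector(noise), as.vector(nl))), 0.01)
  # infinite target returns the input unchanged
  expect_identical(add_noise_to_snr(nl, Inf), nl)
  expect_error(add_noise_to_snr(matrix(1, 8, 8), 0.1), "zero-variance")

  snrs <- c(0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001, 0.0005)
  realized <- vapply(seq_along(snrs), function(i) {
    ns <- add_noise_to_snr(nl, snrs[i], rng_seed = 30 + i)
    compute_snr(nl, ns - nl)
  }, numeric(1))
  expect_true(all(diff(realized) < 0))
})

test_that("compute_snr follows the variance-ratio definition", {
  set.seed(10)
  a <- rnorm(5000)
  expect_equal(compute_snr(a, a), 1.0)
  expect_equal(compute_snr(rnorm(2e4, sd = 1), rnorm(2e4, sd = 2)), 0.25,
               tolerance = 0.05)
  expect_error(compute_snr(a, rep(1, 10)), "zero noise variance")
})

test_that("Gaussian circle template has the closed-form profile and symmetry", {
  g <- make_gaussian_circle(33, sigma = 6, amplitude = 2)
  expect_equal(g[17, 17], 2)                       # center pixel
  expect_equal(g[17 + 6, 17], 2 * exp(-0.5))       # value at radius sigma
  # invariant under 90-degree rotation
  expect_equal(g, t(g)[, ncol(g):1], tolerance = 1e-12)
  # radial average matches the 1D profile
  c0 <- 16
  r <- sqrt(outer((0:32 - c0)^2, (0:32 - c0)^2, "+"))
  for (rr in c(3, 8)) {
    ring <- abs(r - rr) < 0.5
    expect_equal(mean(g[ring]), 2 * exp(-rr^2 / (2 * 36)), tolerance = 0.02)
  }
  expect_warning(make_gaussian_circle(16, sigma = 20), "flat")
})

test_that("low-pass filter preserves DC, is identity at infinite cutoff,
           and empties the stopband", {
  set.seed(11)
  img <- matrix(rnorm(128 * 128), 128, 128)
  attr(img, "pixel_size") <- 1
  expect_identical(lowpass_filter(img, Inf), img)
  lp <- lowpass_filter(img, 8, pixel_size = 1)
  expect_equal(mean(lp), mean(img), tolerance = 1e-10)
  pin <- rotational_power_spectrum(img, 1)
  pout <- rotational_power_spectrum(lp, 1)
  beyond <- pin$freq > 1 / 8
  expect_gt(sum(pin$power[beyond]), 100 * sum(pout$power[beyond]))
})
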