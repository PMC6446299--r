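# Shared fixtures, built once per test session and cached. The heavier
# simulation fixtures (used by the acceptance suite) live here so several
# test blocks can share one simulated dataset.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small projection bank of the trimer phantom at the working box size.
desk_bank <- function() {
  fixture("desk_bank", {
    render_projection_set(phantom_trimer(), n_views = 3, rng_seed = 101,
                          box = 180, pixel_size = 1)
  })
}

decoy_template <- function() {
  fixture("decoy_template", {
    p <- render_projection_set(phantom_decoy(), n_views = 1, rng_seed = 102,
                               box = 180, pixel_size = 1)[[1]]
    out <- lowpass_filter(p, 30, pixel_size = 1)
    attr(out, "pixel_size") <- 1
    out
  })
}

# Desk-scale noiseless micrographs (field of view reduced, particle and
# density at the reference values) with the CTF applied; shared across the
# picking-statistics tests.
desk_sims <- function(n = 3) {
  fixture("desk_sims", {
    bank <- desk_bank()
    ctf <- ctf_params(pixel_size = 1)
    lapply(seq_len(n), function(i) {
      sim <- synthesize_micrograph(bank, 80, c(2048, 2048),
                                   rng_seed = 500 + i)
      list(noiseless = apply_ctf(sim$micrograph, ctf), truth = sim$truth)
    })
  })
}

desk_ctf <- function() ctf_params(pixel_size = 1)

desk_gaussian_template <- function() {
  fixture("desk_gauss_tmpl", {
    out <- -make_gaussian_circle(180, 12)
    attr(out, "pixel_size") <- 1
    out
  })
}

# Tiny toy stack for the EM enumeration-oracle tests: 3 particles, 8x8.
toy_em_problem <- function() {
  fixture("toy_em", {
    set.seed(33)
    A1 <- make_gaussian_circle(8, 1.5)
    A2 <- matrix(0, 8, 8); A2[3:6, 3:6] <- 1
    stack <- array(0, c(8, 8, 3))
    stack[, , 1] <- A1 + matrix(rnorm(64, 0, 0.3), 8, 8)
    stack[, , 2] <- transform_image(A2, 0, 1, 0) + matrix(rnorm(64, 0, 0.3), 8, 8)
    stack[, , 3] <- matrix(rnorm(64, 0, 0.5), 8, 8)
    grid <- structure(
      data.frame(alpha = c(0, 0, 0, 0, 90, 90, 180, 270),
                 tx = c(0, 1, -1, 0, 0, 1, 0, 0),
                 ty = c(0, 0, 0, 1, 0, 0, 0, 0)),
      class = c("transform_grid", "data.frame"))
    theta <- structure(list(A = list(A1, A2), weights = c(0.6, 0.4),
                            sigma = 0.4, xi = 1.3, pixel_size = 1),
                       class = "model_state")
    list(stack = stack, grid = grid, theta = theta)
  })
}
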