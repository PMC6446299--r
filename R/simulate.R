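# Ground-truthed micrograph simulator. Particles are 2D projections of a 3D
# pseudo-atom phantom, placed additively at random non-overlapping positions
# with random in-plane rotations, passed through a parametric CTF, and
# degraded with Gaussian noise scaled to a prescribed micrograph-level SNR
# (variance ratio of the noiseless micrograph to the added noise).
#
# The phantom volumes are SYNTHETIC stand-ins built from pseudo-atoms: a
# three-fold-symmetric trimer-like particle (the pick target) and a
# dissimilar bent-rod decoy (used to probe reference bias). They are fully
# deterministic constructions, not derived from any deposited structure.

# Gaussian pseudo-atom cloud -> 3D density cube of side n voxels.
volume_from_atoms <- function(atoms, n, pixel_size = 1) {
  vol <- array(0, c(n, n, n))
  c0 <- (n - 1) / 2
  ax <- atoms$x / pixel_size + c0
  ay <- atoms$y / pixel_size + c0
  az <- atoms$z / pixel_size + c0
  for (i in seq_len(nrow(atoms))) {
    s <- atoms$sigma[i] / pixel_size
    w <- ceiling(4 * s)
    xs <- max(1, floor(ax[i]) - w):min(n, ceiling(ax[i]) + w)
    ys <- max(1, floor(ay[i]) - w):min(n, ceiling(ay[i]) + w)
    zs <- max(1, floor(az[i]) - w):min(n, ceiling(az[i]) + w)
    if (!length(xs) || !length(ys) || !length(zs)) next
    gx <- exp(-((xs - 1 - ax[i])^2) / (2 * s^2))
    gy <- exp(-((ys - 1 - ay[i])^2) / (2 * s^2))
    gz <- exp(-((zs - 1 - az[i])^2) / (2 * s^2))
    vol[xs, ys, zs] <- vol[xs, ys, zs] +
      atoms$amp[i] * (gx %o% gy %o% gz)
  }
  attr(vol, "pixel_size") <- pixel_size
  vol
}

#' Synthetic trimer-like phantom volume
#'
#' A deterministic, three-fold-symmetric pseudo-atom particle, moderately
#' globular (~130 A wide, ~95 A tall): three subunits around the z axis, each decorated with
#' finer sub-blobs so the projection spectrum carries power into the
#' mid-frequency range (as a protein does). Synthetic construction; not
#' derived from a deposited structure.
#'
#' @param n cube side in voxels.
#' @param pixel_size Angstrom per voxel.
#' @return 3D array `c(n, n, n)` with a `pixel_size` attribute.
#' @export
phantom_trimer <- function(n = 160, pixel_size = 1) {
  atoms <- NULL
  heights <- seq(-40, 40, length.out = 10)
  for (sub in 0:2) {
    phi0 <- sub * 2 * pi / 3
    # subunit backbone: a gently twisting column off-axis
    for (j in seq_along(heights)) {
      z <- heights[j]
      r <- 28 - 10 * (abs(z) / 40)^2          # bulge at the equator
      phi <- phi0 + 0.012 * z                  # slight twist
      atoms <- rbind(atoms, data.frame(
        x = r * cos(phi), y = r * sin(phi), z = z, sigma = 7, amp = 1))
      # fine interior features: deterministic quasi-random satellites
      for (m in 1:3) {
        u <- sin(17.3 * j + 5.1 * m + sub) * 6
        v <- cos(11.7 * j + 3.7 * m + sub) * 6
        w <- sin(7.9 * j + 2.3 * m) * 4
        atoms <- rbind(atoms, data.frame(
          x = r * cos(phi) + u, y = r * sin(phi) + v, z = z + w,
          sigma = 2.2, amp = 0.55))
      }
    }
  }
  volume_from_atoms(atoms, n, pixel_size)
}

#' Synthetic decoy phantom volume
#'
#' A deterministic compact pseudo-atom particle of roughly the same overall
#' size as [phantom_trimer()] but with a clearly different architecture: a
#' four-fold ring of squat subunits around a central channel, flatter along
#' z. Plays the role of an "unrelated structure" picking template when
#' probing reference bias. Synthetic construction; not derived from any
#' deposited structure.
#'
#' @inheritParams phantom_trimer
#' @return 3D array with a `pixel_size` attribute.
#' @export
phantom_decoy <- function(n = 160, pixel_size = 1) {
  atoms <- NULL
  heights <- seq(-22, 22, length.out = 6)
  for (sub in 0:3) {
    phi0 <- sub * pi / 2 + pi / 4
    for (j in seq_along(heights)) {
      z <- heights[j]
      r <- 38 - 6 * (abs(z) / 22)              # squat ring, central channel
      phi <- phi0 - 0.02 * z
      atoms <- rbind(atoms, data.frame(
        x = r * cos(phi), y = r * sin(phi), z = z, sigma = 8, amp = 1))
      for (m in 1:3) {
        u <- sin(13.1 * j + 4.3 * m + sub) * 7
        v <- cos(9.7 * j + 2.9 * m + sub) * 7
        w <- sin(6.1 * j + 1.7 * m) * 4
        atoms <- rbind(atoms, data.frame(
          x = r * cos(phi) + u, y = r * sin(phi) + v, z = z + w,
          sigma = 2.2, amp = 0.55))
      }
    }
  }
  volume_from_atoms(atoms, n, pixel_size)
}

# Uniform random rotation matrix (Shoemake quaternion method).
random_rotation_matrix <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Line-integral projection of a cubic volume along z after rotating the
# volume by Rm, sampled on a box x box grid by trilinear interpolation.
project_volume <- function(vol, Rm, box) {
  nv <- dim(vol)[1]
  cv <- (nv - 1) / 2
  cb <- (box - 1) / 2
  px <- rep(0:(box - 1), times = box) - cb
  py <- rep(0:(box - 1), each = box) - cb
  acc <- numeric(box * box)
  for (iz in 0:(nv - 1)) {
    t <- iz - cv
    # source coordinate in the unrotated volume: R^T (px, py, t)
    sx <- Rm[1, 1] * px + Rm[2, 1] * py + Rm[3, 1] * t + cv
    sy <- Rm[1, 2] * px + Rm[2, 2] * py + Rm[3, 2] * t + cv
    sz <- Rm[1, 3] * px + Rm[2, 3] * py + Rm[3, 3] * t + cv
    acc <- acc + trilinear_sample(vol, sx, sy, sz)
  }
  matrix(acc, box, box)
}

trilinear_sample <- function(vol, sx, sy, sz) {
  nv <- dim(vol)
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  wx <- sx - x0; wy <- sy - y0; wz <- sz - z0
  out <- numeric(length(sx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    cx <- x0 + dx; cy <- y0 + dy; cz <- z0 + dz
    w <- (if (dx == 0) 1 - wx else wx) * (if (dy == 0) 1 - wy else wy) *
         (if (dz == 0) 1 - wz else wz)
    ok <- cx >= 0 & cx < nv[1] & cy >= 0 & cy < nv[2] & cz >= 0 & cz < nv[3] & w > 0
    if (any(ok)) {
      out[ok] <- out[ok] + w[ok] *
        vol[cbind(cx[ok] + 1L, cy[ok] + 1L, cz[ok] + 1L)]
    }
  }
  out
}

#' Render a bank of 2D projections from a phantom
#'
#' Projects a 3D density cube along `n_views` uniformly random directions
#' (line integrals, trilinear interpolation), or passes through a
#' user-supplied bank of 2D images. Each projection is zero-padded/cropped
#' to `box` pixels and has background mean zero.
#'
#' @param phantom 3D array (density cube) or a list of 2D matrices
#'   (pre-rendered bank).
#' @param n_views number of projection directions (ignored for a bank).
#' @param rng_seed integer seed for the view directions.
#' @param box output box size in pixels.
#' @param pixel_size Angstrom per pixel (default: phantom attribute).
#' @return list of `box` x `box` matrices with a `pixel_size` attribute.
#' @export
render_projection_set <- function(phantom, n_views = 8, rng_seed = 1,
                                  box = NULL, pixel_size = NULL) {
  if (is.list(phantom)) {
    bank <- lapply(phantom, function(p) {
      pad_to_box(p, box %||% max(dim(p)))
    })
    attr(bank, "pixel_size") <- pixel_size %||% attr(phantom, "pixel_size") %||% 1
    return(bank)
  }
  stopifnot(length(dim(phantom)) == 3, n_views >= 1)
  if (all(phantom == 0)) stop("empty phantom: all-zero volume")
  pixel_size <- pixel_size %||% attr(phantom, "pixel_size") %||% 1
  box <- box %||% dim(phantom)[1]
  bof_log("render_projection_set: n_views=", n_views, " box=", box,
          " seed=", rng_seed)
  bank <- with_seed(rng_seed, {
    lapply(seq_len(n_views), function(v) {
      p <- project_volume(phantom, random_rotation_matrix(), box)
      # enforce zero background via the median of the border frame
      border <- c(p[1, ], p[nrow(p), ], p[, 1], p[, ncol(p)])
      p - stats::median(border)
    })
  })
  attr(bank, "pixel_size") <- pixel_size
  bank
}

#' Center an image on its center of mass
#'
#' Shifts the image (bilinear resampling) so the center of mass of its
#' positive part sits on the box center `(n-1)/2`. Picking templates are
#' centered this way so that correlation peaks land on particle centers.
#'
#' @param img numeric matrix.
#' @return shifted matrix.
#' @export
center_by_mass <- function(img) {
  w <- pmax(img, 0)
  s <- sum(w)
  if (s <= 0) return(img)
  cx <- sum((row(img) - 1) * w) / s
  cy <- sum((col(img) - 1) * w) / s
  out <- shift_image(img, (nrow(img) - 1) / 2 - cx, (ncol(img) - 1) / 2 - cy)
  attributes(out) <- attributes(img)
  out
}

pad_to_box <- function(img, box) {
  n <- nrow(img)
  if (n == box) return(img)
  if (n > box) {
    i0 <- (n - box) %/% 2
    return(img[(i0 + 1):(i0 + box), (i0 + 1):(i0 + box)])
  }
  out <- matrix(0, box, box)
  i0 <- (box - n) %/% 2
  out[(i0 + 1):(i0 + n), (i0 + 1):(i0 + n)] <- img
  out
}

#' Synthesize a noiseless micrograph with ground truth
#'
#' Places `n_particles` randomly chosen, randomly in-plane-rotated bank
#' projections additively at uniform-random positions, rejecting positions
#' closer than `min_separation` to an accepted particle or too close to the
#' edge for a full box.
#'
#' @param projection_bank list of square projection images (see
#'   [render_projection_set()]).
#' @param n_particles number of particles to place.
#' @param dims micrograph dimensions `c(nx, ny)` in pixels.
#' @param min_separation minimum center-to-center distance in pixels
#'   (default `0.8 * box`).
#' @param rng_seed integer seed.
#' @param max_attempts rejection-sampling budget per particle.
#' @return list with `micrograph` (matrix, `pixel_size` attribute) and
#'   `truth` (data.frame: `x`, `y` 0-based center pixels, `angle` degrees,
#'   `view` bank index).
#' @export
synthesize_micrograph <- function(projection_bank, n_particles, dims,
                                  min_separation = NULL, rng_seed = 1,
                                  max_attempts = 1e4) {
  box <- nrow(projection_bank[[1]])
  min_separation <- min_separation %||% (0.8 * box)
  nx <- dims[1]; ny <- dims[2]
  b2 <- box %/% 2
  lo <- b2; hix <- nx - box + b2; hiy <- ny - box + b2
  if (hix < lo || hiy < lo) stop("dims too small for the box size")
  bof_log("synthesize_micrograph: n=", n_particles, " dims=", nx, "x", ny,
          " box=", box, " min_sep=", min_separation, " seed=", rng_seed)
  mic <- matrix(0, nx, ny)
  truth <- data.frame(x = integer(0), y = integer(0), angle = numeric(0),
                      view = integer(0))
  with_seed(rng_seed, {
    cx <- integer(0); cy <- integer(0)
    for (i in seq_len(n_particles)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        px <- sample(lo:hix, 1)
        py <- sample(lo:hiy, 1)
        if (length(cx) == 0 ||
            min((cx - px)^2 + (cy - py)^2) >= min_separation^2) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("particle placement failed after ", max_attempts,
             " attempts; lower the particle density or min_separation")
      }
      v <- sample(length(projection_bank), 1)
      ang <- stats::runif(1, 0, 360)
      proj <- transform_image(projection_bank[[v]], ang)
      x0 <- px - b2; y0 <- py - b2
      mic[(x0 + 1):(x0 + box), (y0 + 1):(y0 + box)] <-
        mic[(x0 + 1):(x0 + box), (y0 + 1):(y0 + box)] + proj
      cx <- c(cx, px); cy <- c(cy, py)
      truth[i, ] <- list(px, py, ang, v)
    }
  })
  attr(mic, "pixel_size") <- attr(projection_bank, "pixel_size") %||% 1
  list(micrograph = mic, truth = truth)
}

#' Add Gaussian noise scaled to a target micrograph SNR
#'
#' SNR is the variance ratio of signal to noise: i.i.d. Gaussian noise of
#' mean zero and variance `var(noiseless) / target_snr` is added, so the
#' realized variance-ratio SNR of the output matches the target within
#' sampling error.
#'
#' @param noiseless noiseless micrograph (matrix).
#' @param target_snr target variance-ratio SNR (> 0; `Inf` returns the
#'   input unchanged).
#' @param rng_seed integer seed.
#' @return noisy micrograph with attributes `pixel_size` and `noise_sd`.
#' @export
add_noise_to_snr <- function(noiseless, target_snr, rng_seed = 1) {
  stopifnot(target_snr > 0)
  if (is.infinite(target_snr)) return(noiseless)
  v <- stats::var(as.vector(noiseless))
  if (v == 0) stop("zero-variance noiseless input")
  sd_n <- sqrt(v / target_snr)
  bof_log("add_noise_to_snr: target=", target_snr, " noise_sd=", sd_n,
          " seed=", rng_seed)
  out <- noiseless +
    with_seed(rng_seed, matrix(stats::rnorm(length(noiseless), 0, sd_n),
                               nrow(noiseless), ncol(noiseless)))
  attr(out, "pixel_size") <- attr(noiseless, "pixel_size")
  attr(out, "noise_sd") <- sd_n
  out
}

#' Variance-ratio signal-to-noise ratio
#'
#' `var(signal_region) / var(noise_region)`. For a micrograph-level SNR pass
#' the noiseless micrograph and the pure-noise image; for a single-particle
#' SNR pass the boxed noise-free particle and a boxed background area.
#'
#' @param signal_region,noise_region numeric arrays.
#' @return dimensionless ratio.
#' @export
compute_snr <- function(signal_region, noise_region) {
  stopifnot(length(signal_region) > 1, length(noise_region) > 1)
  vn <- stats::var(as.vector(noise_region))
  if (vn == 0) stop("zero noise variance")
  stats::var(as.vector(signal_region)) / vn
}

#' Gaussian-circle template
#'
#' A rotationally symmetric 2D Gaussian centered in the box: an unbiased
#' picking template / alignment start that carries no structural prior.
#'
#' @param box box size in pixels.
#' @param sigma radial standard deviation in pixels.
#' @param amplitude peak value at the center.
#' @return `box` x `box` matrix.
#' @export
make_gaussian_circle <- function(box, sigma = box / 6, amplitude = 1) {
  stopifnot(sigma > 0)
  if (sigma >= box) warning("sigma >= box: template is nearly flat")
  c0 <- (box - 1) / 2
  r2 <- outer((0:(box - 1) - c0)^2, (0:(box - 1) - c0)^2, "+")
  amplitude * exp(-r2 / (2 * sigma^2))
}

#' Low-pass filter with a raised-cosine edge
#'
#' Fourier amplitudes beyond `1/cutoff` are removed; the transition is a
#' raised cosine of width `edge_width` Fourier pixels ending at the cutoff,
#' so the stopband is exactly zero. `cutoff = Inf` is the identity; DC is
#' always preserved.
#'
#' @param img numeric matrix.
#' @param cutoff resolution cutoff in Angstrom.
#' @param pixel_size Angstrom per pixel (default: attribute of `img`).
#' @param edge_width transition width in Fourier pixels.
#' @return filtered image.
#' @export
lowpass_filter <- function(img, cutoff, pixel_size = NULL, edge_width = 5) {
  if (is.infinite(cutoff)) return(img)
  pixel_size <- pixel_size %||% attr(img, "pixel_size") %||% 1
  nx <- nrow(img); ny <- ncol(img)
  r <- sqrt(freq2_grid(nx, ny, pixel_size)) * nx * pixel_size  # Fourier px
  rc <- nx * pixel_size / cutoff
  h <- matrix(0, nx, ny)
  h[r <= rc - edge_width] <- 1
  band <- r > rc - edge_width & r < rc
  h[band] <- 0.5 * (1 + cos(pi * (r[band] - (rc - edge_width)) / edge_width))
  h[1, 1] <- 1  # DC always preserved, even for cutoffs inside the edge
  out <- Re(ifft2(stats::fft(img) * h))
  attr(out, "pixel_size") <- pixel_size
  out
}
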