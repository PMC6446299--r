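#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit a progress/log line
#'
#' All pipeline stages log their RNG seeds, input shapes and parameter sets
#' through this function. Silenced unless `options(bofem.verbose = TRUE)`.
#' @param ... values pasted into the message.
#' @return invisibly, the message string.
#' @export
bof_log <- function(...) {
  msg <- paste0(...)
  if (isTRUE(getOption("bofem.verbose", FALSE))) {
    message("[bofem ", format(Sys.time(), "%H:%M:%S"), "] ", msg)
  }
  invisible(msg)
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a per-item RNG seed from a master seed
#'
#' Deterministic mixing of `(master_seed, index)` into a 31-bit seed so that
#' every micrograph / stage draws from its own reproducible stream.
#' @param master_seed,index non-negative integers.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master_seed, index) {
  s <- (as.double(master_seed) * 2654435761 + as.double(index) * 40503) %% 2147483647
  as.integer(s)
}

# DFT sample frequencies (cycles per unit), numpy-style layout.
fft_freq <- function(n, d = 1) {
  i <- 0:(n - 1)
  i[i >= ceiling(n / 2)] <- i[i >= ceiling(n / 2)] - n
  i / (n * d)
}

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Shift zero frequency to the center of the array (and back).
fftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq(floor(d[1] / 2) + 1, d[1]), seq_len(floor(d[1] / 2))),
    c(seq(floor(d[2] / 2) + 1, d[2]), seq_len(floor(d[2] / 2)))]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq(ceiling(d[1] / 2) + 1, d[1]), seq_len(ceiling(d[1] / 2))),
    c(seq(ceiling(d[2] / 2) + 1, d[2]), seq_len(ceiling(d[2] / 2)))]
}

# Radial Fourier ring index (in Fourier pixels) for an nx-by-ny spectrum in
# native (unshifted) fft layout. Ring r collects pixels with round(|k|) == r.
ring_index <- function(nx, ny) {
  fx <- fft_freq(nx) * nx
  fy <- fft_freq(ny) * ny
  r <- sqrt(outer(fx^2, fy^2, "+"))
  round(r)
}

# Squared spatial frequency grid |k|^2 in 1/Angstrom^2, unshifted layout.
freq2_grid <- function(nx, ny, pixel_size) {
  kx <- fft_freq(nx, pixel_size)
  ky <- fft_freq(ny, pixel_size)
  outer(kx^2, ky^2, "+")
}

# Bilinear sampling of img (matrix indexed [x+1, y+1], 0-based coords) at
# fractional source coordinates (sx, sy); out-of-support samples are zero.
bilinear_sample <- function(img, sx, sy) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(sx); y0 <- floor(sy)
  wx <- sx - x0; wy <- sy - y0
  out <- numeric(length(sx))
  # contributions from the four surrounding pixels, each guarded for bounds
  for (corner in 1:4) {
    cx <- x0 + (corner == 2 | corner == 4)
    cy <- y0 + (corner == 3 | corner == 4)
    w <- (if (corner %% 2 == 1) 1 - wx else wx) *
         (if (corner <= 2) 1 - wy else wy)
    ok <- cx >= 0 & cx < nx & cy >= 0 & cy < ny & w > 0
    if (any(ok)) {
      out[ok] <- out[ok] + w[ok] * img[cbind(cx[ok] + 1L, cy[ok] + 1L)]
    }
  }
  out
}

# Rigid warp: out[p] = img[ Rot(theta) (p - c) + c + offset ], c = (n-1)/2.
warp_rigid <- function(img, theta_deg, offset = c(0, 0)) {
  nx <- nrow(img); ny <- ncol(img)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  px <- rep(0:(nx - 1), times = ny) - cx
  py <- rep(0:(ny - 1), each = nx) - cy
  sx <- ct * px - st * py + cx + offset[1]
  sy <- st * px + ct * py + cy + offset[2]
  matrix(bilinear_sample(img, sx, sy), nx, ny)
}

#' Apply an in-plane rigid transform R(phi) to an image
#'
#' The forward transform rotates by `alpha` degrees (counter-clockwise in
#' (x, y)) about the box center `(n-1)/2`, then shifts by `(tx, ty)` pixels.
#' Resampling is bilinear; samples falling outside the support are zero.
#' `transform_image_inv()` applies the exact inverse (shift by `-t`, then
#' rotate by `-alpha`), so that `transform_image_inv(transform_image(A, ...))`
#' recovers `A` up to interpolation error.
#'
#' @param img numeric matrix.
#' @param alpha rotation in degrees.
#' @param tx,ty translation in pixels.
#' @return transformed matrix of the same dimension.
#' @export
transform_image <- function(img, alpha, tx = 0, ty = 0) {
  if (alpha == 0 && tx == round(tx) && ty == round(ty)) {
    return(shift_integer(img, as.integer(tx), as.integer(ty)))
  }
  th <- -alpha * pi / 180
  off <- c(cos(th) * (-tx) - sin(th) * (-ty),
           sin(th) * (-tx) + cos(th) * (-ty))
  warp_rigid(img, -alpha, off)
}

#' @rdname transform_image
#' @export
transform_image_inv <- function(img, alpha, tx = 0, ty = 0) {
  if (alpha == 0 && tx == round(tx) && ty == round(ty)) {
    return(shift_integer(img, -as.integer(tx), -as.integer(ty)))
  }
  # rot_{-alpha} o shift_{-t} collapses to a single resampling:
  # out[p] = img[ R(alpha)(p - c) + c + t ]
  warp_rigid(img, alpha, c(tx, ty))
}

# Integer-pixel shift with zero fill: out[p] = img[p - t].
shift_integer <- function(img, tx, ty) {
  if (tx == 0 && ty == 0) return(img)
  nx <- nrow(img); ny <- ncol(img)
  out <- matrix(0, nx, ny)
  xs <- intersect(seq_len(nx), seq_len(nx) + tx)
  ys <- intersect(seq_len(ny), seq_len(ny) + ty)
  if (length(xs) && length(ys)) out[xs, ys] <- img[xs - tx, ys - ty]
  out
}

shift_image <- function(img, tx, ty) {
  if (tx == round(tx) && ty == round(ty)) {
    return(shift_integer(img, as.integer(tx), as.integer(ty)))
  }
  warp_rigid(img, 0, c(-tx, -ty))
}

# Soft circular mask: 1 inside radius - width, cosine rolloff to 0 at radius.
soft_disk <- function(n, radius = 0.45 * n, width = 0.1 * n) {
  cx <- (n - 1) / 2
  r <- sqrt(outer((0:(n - 1) - cx)^2, (0:(n - 1) - cx)^2, "+"))
  m <- matrix(0, n, n)
  m[r <= radius - width] <- 1
  band <- r > radius - width & r < radius
  m[band] <- 0.5 * (1 + cos(pi * (r[band] - (radius - width)) / width))
  m
}

# Block-average binning of a 2D image (requires divisibility). Used for the
# optional coarse picking pass; particle stacks are binned by Fourier cropping.
bin_image <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  nx <- nrow(img); ny <- ncol(img)
  if (nx %% factor != 0 || ny %% factor != 0) {
    stop("image dimensions must be divisible by the binning factor")
  }
  mx <- nx %/% factor; my <- ny %/% factor
  dim(img) <- c(factor, mx * factor * my)
  s <- colSums(img)                      # (mx, factor, my)
  dim(s) <- c(mx, factor, my)
  s <- aperm(s, c(2, 1, 3))
  dim(s) <- c(factor, mx * my)
  matrix(colSums(s), mx, my) / factor^2
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}
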