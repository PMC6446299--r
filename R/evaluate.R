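# Quantitative readouts: pick-vs-truth matching, ranked-peak drop-off
# detection, Fourier ring correlation (with the FRC-0.5 crossing frequency),
# rotationally averaged power spectra, spectral SNR, and the conversion
# between micrograph-level and single-particle SNR.

#' Match picks against ground-truth particle centers
#'
#' Greedy one-to-one matching in descending pick-rank order: a pick is a
#' true positive if an unmatched true center lies within `d_max` pixels,
#' otherwise a false positive. `fp_fraction` is in percent.
#'
#' @param picks pick set data.frame (`x`, `y`, `rank`).
#' @param truth data.frame of true centers (`x`, `y`).
#' @param d_max match radius in pixels (a common choice is `box / 4`).
#' @return list of class `match_result`: counts `n_true`, `n_picked`,
#'   `true_positives`, `false_positives`, `false_negatives`, percentage
#'   `fp_fraction`, and `centering_errors` (pixel distances of matched
#'   pairs, in pick-rank order).
#' @export
match_picks <- function(picks, truth, d_max) {
  stopifnot(d_max > 0)
  picks <- picks[order(picks$rank), , drop = FALSE]
  n_true <- nrow(truth)
  n_picked <- nrow(picks)
  matched <- rep(FALSE, n_true)
  tp <- 0L
  errs <- numeric(0)
  for (i in seq_len(n_picked)) {
    if (n_true == 0) break
    d2 <- (truth$x - picks$x[i])^2 + (truth$y - picks$y[i])^2
    d2[matched] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= d_max^2) {
      matched[j] <- TRUE
      tp <- tp + 1L
      errs <- c(errs, sqrt(d2[j]))
    }
  }
  fp <- n_picked - tp
  structure(list(n_true = n_true, n_picked = n_picked, true_positives = tp,
                 false_positives = fp, false_negatives = n_true - tp,
                 fp_fraction = if (n_picked > 0) 100 * fp / n_picked else 0,
                 centering_errors = errs),
            class = "match_result")
}

#' Rank of the steepest drop in a ranked peak curve
#'
#' Applies a moving-median smoothing (window `smooth_window`) and returns
#' the rank `r` maximizing the single-step drop `p_r - p_{r+1}`; in a
#' sorted picking curve this demarcates true particles from noise picks.
#' When no drop stands out (e.g. a strictly linear sequence) the first
#' maximal step is returned and the result is flagged low-confidence
#' (attribute `confident`).
#'
#' @param ranked_peaks non-increasing numeric vector of peak values.
#' @param smooth_window moving-median window (odd integer; 1 disables).
#' @return integer rank (position of the step), with attribute `confident`.
#' @export
dropoff_rank <- function(ranked_peaks, smooth_window = 5) {
  n <- length(ranked_peaks)
  if (n < 2) stop("need at least two ranked peaks")
  x <- if (smooth_window > 1 && n > smooth_window) {
    as.numeric(stats::runmed(ranked_peaks, smooth_window))
  } else {
    ranked_peaks
  }
  drops <- x[-n] - x[-1]
  r <- which.max(drops)
  confident <- max(drops) > 3 * stats::median(drops) + 1e-15
  structure(as.integer(r), confident = confident)
}

#' Fourier ring correlation between two images
#'
#' Per-ring normalized cross-correlation of the Fourier coefficients
#' (rings of width one Fourier pixel up to Nyquist). By default both images
#' are multiplied by a soft circular mask (cosine edge, radius
#' `0.45 * box`) to suppress box-edge cross terms.
#'
#' @param img_a,img_b images of identical shape.
#' @param pixel_size Angstrom per pixel (default: attribute of `img_a`).
#' @param mask apply the soft circular mask (default TRUE).
#' @return data.frame of class `frc_curve`: `ring` (Fourier pixels), `freq`
#'   (ring center, 1/Angstrom), `frc`, `n_pixels`.
#' @export
frc <- function(img_a, img_b, pixel_size = NULL, mask = TRUE) {
  if (!all(dim(img_a) == dim(img_b))) stop("mismatched image shapes")
  pixel_size <- pixel_size %||% attr(img_a, "pixel_size") %||% 1
  n <- nrow(img_a)
  if (mask) {
    w <- soft_disk(n)
    img_a <- img_a * w
    img_b <- img_b * w
  }
  fa <- stats::fft(img_a)
  fb <- stats::fft(img_b)
  ring <- ring_index(n, ncol(img_a))
  rmax <- floor(n / 2)
  keep <- ring >= 1 & ring <= rmax
  rr <- factor(ring[keep], levels = seq_len(rmax))
  num <- tapply(Re(fa[keep] * Conj(fb[keep])), rr, sum)
  pa <- tapply(abs(fa[keep])^2, rr, sum)
  pb <- tapply(abs(fb[keep])^2, rr, sum)
  cnt <- tapply(rep(1, sum(keep)), rr, sum)
  v <- as.numeric(num) / sqrt(as.numeric(pa) * as.numeric(pb))
  v[!is.finite(v)] <- 0
  structure(data.frame(ring = seq_len(rmax),
                       freq = seq_len(rmax) / (n * pixel_size),
                       frc = v, n_pixels = as.numeric(cnt)),
            class = c("frc_curve", "data.frame"))
}

#' FRC-0.5 crossing frequency
#'
#' Lowest frequency at which the curve first falls below 0.5, linearly
#' interpolated between rings. Returns 0 if the curve never reaches 0.5;
#' returns Nyquist (flagged via attribute `at_nyquist`) if it never falls
#' below.
#'
#' @param curve an [frc()] result.
#' @return crossing frequency in 1/Angstrom.
#' @export
frc_half_crossing <- function(curve) {
  stopifnot(nrow(curve) > 0)
  v <- curve$frc
  f <- curve$freq
  if (v[1] < 0.5) return(0)
  below <- which(v < 0.5)
  if (!length(below)) {
    return(structure(f[length(f)], at_nyquist = TRUE))
  }
  i <- below[1]
  f0 <- f[i - 1]; f1 <- f[i]
  v0 <- v[i - 1]; v1 <- v[i]
  f0 + (0.5 - v0) / (v1 - v0) * (f1 - f0)
}

#' Rotationally averaged power spectrum
#'
#' Ring-averaged `|FFT|^2`; the DC term is excluded from the profile. Rings
#' extend to the spectrum corners so that `sum(power * n_pixels)` plus the
#' DC power equals the total Fourier power (Parseval).
#'
#' @param image numeric matrix.
#' @param pixel_size Angstrom per pixel (default: attribute of `image`).
#' @return data.frame: `ring`, `freq` (1/Angstrom), `power` (mean per ring),
#'   `n_pixels`; attribute `dc_power`.
#' @export
rotational_power_spectrum <- function(image, pixel_size = NULL) {
  pixel_size <- pixel_size %||% attr(image, "pixel_size") %||% 1
  n <- nrow(image)
  f <- stats::fft(image)
  p <- abs(f)^2
  ring <- ring_index(n, ncol(image))
  rmax <- max(ring)
  keep <- ring >= 1
  rr <- factor(ring[keep], levels = seq_len(rmax))
  s <- tapply(p[keep], rr, sum)
  cnt <- tapply(rep(1, sum(keep)), rr, sum)
  s[is.na(s)] <- 0
  cnt[is.na(cnt)] <- 0
  out <- data.frame(ring = seq_len(rmax),
                    freq = seq_len(rmax) / (n * pixel_size),
                    power = ifelse(cnt > 0, as.numeric(s) / pmax(cnt, 1), 0),
                    n_pixels = as.numeric(cnt))
  attr(out, "dc_power") <- p[1, 1]
  out
}

#' Spectral signal-to-noise ratio from a simulation pair
#'
#' Per-ring power of the noiseless micrograph divided by the per-ring power
#' of the realized noise (`noisy - noiseless`). Rings where the noise power
#' is zero are flagged infinite.
#'
#' @param noisy,noiseless micrographs of identical shape.
#' @param pixel_size Angstrom per pixel.
#' @return data.frame: `ring`, `freq`, `ssnr`.
#' @export
ssnr <- function(noisy, noiseless, pixel_size = NULL) {
  if (!all(dim(noisy) == dim(noiseless))) stop("mismatched image shapes")
  pixel_size <- pixel_size %||% attr(noiseless, "pixel_size") %||% 1
  ps_sig <- rotational_power_spectrum(noiseless, pixel_size)
  ps_noise <- rotational_power_spectrum(noisy - noiseless, pixel_size)
  data.frame(ring = ps_sig$ring, freq = ps_sig$freq,
             ssnr = ifelse(ps_noise$power > 0, ps_sig$power / ps_noise$power,
                           Inf))
}

#' Convert micrograph-level SNR to single-particle SNR
#'
#' A micrograph is mostly empty background, so its variance-ratio SNR
#' underestimates the SNR of an appropriately boxed particle by the area
#' fraction: the conversion multiplies by
#' `(micrograph area) / (n_particles * box^2)`.
#'
#' @param micrograph_snr variance-ratio SNR of the whole micrograph.
#' @param n_particles particles per micrograph.
#' @param box particle box size, pixels.
#' @param dims micrograph dimensions: either `c(nx, ny)` or the total pixel
#'   count.
#' @return single-particle SNR (dimensionless).
#' @export
single_particle_snr <- function(micrograph_snr, n_particles, box, dims) {
  area <- if (length(dims) == 2) prod(dims) else dims
  stopifnot(n_particles * box^2 <= area)
  micrograph_snr * area / (n_particles * box^2)
}

#' FRC after exhaustive rigid alignment
#'
#' Aligns `img_b` onto `img_a` by exhaustive search over in-plane rotations
#' and integer shifts (maximizing the masked inner product), then computes
#' the FRC. Used to compare class averages, whose in-plane orientation is
#' arbitrary, against reference projections.
#'
#' @param img_a reference image.
#' @param img_b image to align.
#' @param rot_step rotation search step, degrees.
#' @param t_max shift search range, pixels.
#' @param pixel_size Angstrom per pixel.
#' @return an [frc()] curve (attribute `alignment` holds the best
#'   transform).
#' @export
aligned_frc <- function(img_a, img_b, rot_step = 3, t_max = 2,
                        pixel_size = NULL) {
  alphas <- seq(0, 360 - rot_step, by = rot_step)
  shifts <- expand.grid(tx = -t_max:t_max, ty = -t_max:t_max)
  w <- soft_disk(nrow(img_a))
  av <- as.vector(img_a * w)
  best <- c(0, 0, 0); best_s <- -Inf
  for (a in alphas) {
    rot <- transform_image(img_b, a)
    for (s in seq_len(nrow(shifts))) {
      tb <- shift_integer(rot, shifts$tx[s], shifts$ty[s])
      sc <- sum(av * as.vector(tb * w))
      if (sc > best_s) {
        best_s <- sc
        best <- c(a, shifts$tx[s], shifts$ty[s])
      }
    }
  }
  out <- frc(img_a, transform_image(img_b, best[1], best[2], best[3]),
             pixel_size = pixel_size)
  attr(out, "alignment") <- data.frame(alpha = best[1], tx = best[2],
                                       ty = best[3])
  out
}
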