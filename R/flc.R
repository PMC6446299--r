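# Template-matching particle picking by the fast local correlation (FLC)
# function. With the search object S normalized to mean 0 / standard
# deviation 1 under the binary mask M (P nonzero points), the locally
# normalized correlation at footprint position x is
#
#   C_L(x) = (1 / (P sigma_MT(x))) * sum_k S_k M_k T_{k+x}
#   sigma_MT^2(x) = (1/P) sum_k M_k T_{k+x}^2 - [ (1/P) sum_k M_k T_{k+x} ]^2
#
# All three sliding sums are cross-correlations computed with FFTs; only
# footprint positions where the mask fits entirely inside T are kept
# ("valid" mode). |C_L| <= 1 wherever sigma_MT > 0 (Cauchy-Schwarz).

#' Build a normalized search object for FLC
#'
#' Normalizes the template to mean 0 and (population) standard deviation 1
#' under the mask footprint.
#'
#' @param template 2D template image.
#' @param mask binary mask of the same shape (default: filled disk of
#'   diameter `0.9 * box`).
#' @return object of class `search_object`: list with `S` (normalized
#'   template), `M`, `P` (number of nonzero mask points).
#' @export
search_object <- function(template, mask = NULL) {
  mask <- mask %||% disk_mask(nrow(template))
  stopifnot(all(dim(template) == dim(mask)))
  m <- mask != 0
  P <- sum(m)
  if (P < 2) stop("mask is empty or nearly empty (P < 2)")
  mu <- mean(template[m])
  sdev <- sqrt(mean((template[m] - mu)^2))
  if (sdev == 0) stop("template is constant under the mask")
  S <- (template - mu) / sdev
  S[!m] <- 0
  structure(list(S = S, M = m + 0, P = P), class = "search_object")
}

#' Filled-disk binary mask
#'
#' @param box box size in pixels.
#' @param diameter disk diameter in pixels (default `0.9 * box`).
#' @return `box` x `box` 0/1 matrix.
#' @export
disk_mask <- function(box, diameter = 0.9 * box) {
  c0 <- (box - 1) / 2
  r2 <- outer((0:(box - 1) - c0)^2, (0:(box - 1) - c0)^2, "+")
  (r2 <= (diameter / 2)^2) + 0
}

#' Fast local correlation map
#'
#' @param T micrograph (matrix, at least as large as the template).
#' @param S a [search_object()]; an unnormalized template triggers an error.
#' @param sigma_floor positions whose local standard deviation falls below
#'   this floor are set to 0 and flagged (default
#'   `max(1e-6 * sd(T), 1e-12)`).
#' @return object of class `correlation_map`: list with `C` (matrix over
#'   valid footprint positions; element `[i, j]` is the footprint with
#'   0-based top-left `(i-1, j-1)`), `box`, `center_offset` (added to the
#'   top-left to get the box-center pixel), and `flagged` (logical matrix of
#'   floored positions).
#' @export
local_correlation_map <- function(T, S, sigma_floor = NULL) {
  if (!inherits(S, "search_object")) {
    stop("S must be a search_object (template normalized to mean 0, sd 1 ",
         "under the mask); see search_object()")
  }
  m <- S$M != 0
  mu <- mean(S$S[m]); sdev <- sqrt(mean((S$S[m] - mu)^2))
  if (abs(mu) > 1e-6 || abs(sdev - 1) > 1e-6) {
    stop("search object not normalized (mean 0, sd 1 under mask); ",
         "rebuild it with search_object()")
  }
  nx <- nrow(T); ny <- ncol(T)
  b <- nrow(S$S)
  if (nx < b || ny < b) stop("micrograph smaller than the template")
  P <- S$P
  sigma_floor <- sigma_floor %||% max(1e-6 * stats::sd(as.vector(T)), 1e-12)

  pad <- function(x) {
    out <- matrix(0, nx, ny)
    out[1:b, 1:b] <- x
    out
  }
  FT <- stats::fft(T)
  FT2 <- stats::fft(T * T)
  FM <- Conj(stats::fft(pad(S$M)))
  FSM <- Conj(stats::fft(pad(S$S * S$M)))
  vx <- 1:(nx - b + 1); vy <- 1:(ny - b + 1)
  num <- Re(ifft2(FT * FSM))[vx, vy, drop = FALSE]
  s1 <- Re(ifft2(FT * FM))[vx, vy, drop = FALSE] / P
  s2 <- Re(ifft2(FT2 * FM))[vx, vy, drop = FALSE] / P
  var_loc <- pmax(s2 - s1 * s1, 0)   # clamp float cancellation
  sigma <- sqrt(var_loc)
  flagged <- sigma < sigma_floor
  C <- num / (P * pmax(sigma, sigma_floor))
  C[flagged] <- 0
  structure(list(C = C, box = b, center_offset = b %/% 2, flagged = flagged),
            class = "correlation_map")
}

#' Extract ranked correlation peaks
#'
#' Greedy selection of local maxima of the correlation map in descending
#' peak order, suppressing any candidate within `exclusion_radius` of an
#' already accepted peak. Ties are broken by row-major scan order (y, then
#' x) and logged. Ranks are 1..n by descending peak value.
#'
#' @param cmap a [local_correlation_map()] result.
#' @param exclusion_radius suppression radius in pixels (>= 1).
#' @param n_max maximum number of peaks to return.
#' @param micrograph_id identifier copied into the output records.
#' @return data.frame (`micrograph_id`, `x`, `y`, `peak`, `rank`) with `x`,
#'   `y` the 0-based box-CENTER pixel coordinates in the micrograph.
#' @export
find_peaks <- function(cmap, exclusion_radius, n_max = Inf,
                       micrograph_id = "mic") {
  stopifnot(inherits(cmap, "correlation_map"), exclusion_radius >= 1)
  C <- cmap$C
  nx <- nrow(C); ny <- ncol(C)
  empty <- data.frame(micrograph_id = character(0), x = numeric(0),
                      y = numeric(0), peak = numeric(0), rank = integer(0))
  if (nx == 0 || ny == 0) return(empty)
  # local maximum: >= all 8 neighbours (edges padded with -Inf)
  pad <- matrix(-Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- C
  is_max <- !cmap$flagged
  above_one <- matrix(FALSE, nx, ny)  # reject interior plateau pixels
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
    is_max <- is_max & (C >= nb)
    above_one <- above_one | (is.finite(nb) & C > nb)
  }
  idx <- which(is_max & above_one)
  if (!length(idx)) return(empty)
  ix <- (idx - 1) %% nx          # 0-based footprint x
  iy <- (idx - 1) %/% nx         # 0-based footprint y
  val <- C[idx]
  # descending value; ties by row-major scan order (y, then x)
  ord <- order(-val, iy, ix)
  ix <- ix[ord]; iy <- iy[ord]; val <- val[ord]
  if (anyDuplicated(val)) bof_log("find_peaks: ties broken by scan order")

  keep_x <- numeric(0); keep_y <- numeric(0); keep_v <- numeric(0)
  r2 <- exclusion_radius^2
  for (i in seq_along(val)) {
    if (length(keep_x) &&
        min((keep_x - ix[i])^2 + (keep_y - iy[i])^2) < r2) next
    keep_x <- c(keep_x, ix[i]); keep_y <- c(keep_y, iy[i])
    keep_v <- c(keep_v, val[i])
    if (length(keep_x) >= n_max) break
  }
  data.frame(micrograph_id = micrograph_id,
             x = keep_x + cmap$center_offset,
             y = keep_y + cmap$center_offset,
             peak = keep_v, rank = seq_along(keep_v))
}

#' Threshold a ranked pick set
#'
#' @param picks data.frame from [find_peaks()].
#' @param n_keep keep the top `n_keep` picks, or
#' @param peak_floor keep picks with `peak >= peak_floor`.
#' @return the filtered pick set, ranks preserved.
#' @export
threshold_picks <- function(picks, n_keep = NULL, peak_floor = NULL) {
  if (!is.null(n_keep)) {
    return(picks[picks$rank <= n_keep, , drop = FALSE])
  }
  if (!is.null(peak_floor)) {
    return(picks[picks$peak >= peak_floor, , drop = FALSE])
  }
  picks
}

#' Extract boxed particle images at pick positions
#'
#' @param T micrograph.
#' @param picks pick set (box centers, 0-based).
#' @param box box size in pixels.
#' @return array `c(box, box, n)` in rank order, with attributes
#'   `pixel_size` and `coords` (the pick records).
#' @export
extract_particles <- function(T, picks, box) {
  picks <- picks[order(picks$rank), , drop = FALSE]
  n <- nrow(picks)
  stack <- array(0, c(box, box, n))
  b2 <- box %/% 2
  for (i in seq_len(n)) {
    x0 <- picks$x[i] - b2; y0 <- picks$y[i] - b2
    if (x0 < 0 || y0 < 0 || x0 + box > nrow(T) || y0 + box > ncol(T)) {
      stop("pick out of bounds: rank ", picks$rank[i], " at (",
           picks$x[i], ", ", picks$y[i], ")")
    }
    stack[, , i] <- T[(x0 + 1):(x0 + box), (y0 + 1):(y0 + box)]
  }
  attr(stack, "pixel_size") <- attr(T, "pixel_size") %||% 1
  attr(stack, "coords") <- picks
  stack
}

#' Phase-flip a particle stack
#'
#' Multiplies each image's Fourier transform by the sign of the CTF
#' (coefficients at exact CTF zeros are left unchanged), partially
#' correcting the contrast inversions. An involution: applying twice
#' restores the input.
#'
#' @param stack particle stack `c(box, box, n)`.
#' @param ctf a [ctf_params()] object (its `pixel_size` must match the
#'   stack).
#' @return phase-flipped stack with attributes preserved.
#' @export
phase_flip <- function(stack, ctf) {
  stopifnot(inherits(ctf, "ctf_params"))
  d <- dim(stack)
  g <- ctf_grid(d[1], d[2], ctf)
  s <- sign(g)
  s[s == 0] <- 1
  out <- stack
  for (i in seq_len(d[3])) {
    out[, , i] <- Re(ifft2(stats::fft(stack[, , i]) * s))
  }
  attributes(out) <- attributes(stack)
  out
}

#' Pick particles from a micrograph (convenience wrapper)
#'
#' Runs FLC with optional coarse binning for speed: micrograph and template
#' are block-binned, the correlation map is computed at the binned scale,
#' and pick coordinates are rescaled to the unbinned frame.
#'
#' @param T micrograph.
#' @param template picking template (unbinned scale).
#' @param mask optional mask (unbinned scale).
#' @param exclusion_radius suppression radius in unbinned pixels (default
#'   `0.5 * box`).
#' @param n_max maximum number of picks.
#' @param bin integer binning factor (1 = off).
#' @param micrograph_id identifier for the records.
#' @return pick set data.frame in unbinned coordinates.
#' @export
pick_particles <- function(T, template, mask = NULL, exclusion_radius = NULL,
                           n_max = Inf, bin = 1, micrograph_id = "mic") {
  box <- nrow(template)
  nx0 <- nrow(T); ny0 <- ncol(T)
  exclusion_radius <- exclusion_radius %||% (0.5 * box)
  if (bin > 1) {
    T <- bin_image(T, bin)
    template <- bin_image(template, bin)
    if (!is.null(mask)) mask <- (bin_image(mask, bin) > 0.5) + 0
  }
  so <- search_object(template, mask)
  cmap <- local_correlation_map(T, so)
  picks <- find_peaks(cmap, exclusion_radius / bin, n_max, micrograph_id)
  if (bin > 1) {
    # rescale to the unbinned frame and clamp into the extractable range
    # (the rescaling can overshoot the valid region by up to bin pixels)
    b2 <- box %/% 2
    picks$x <- pmin(pmax(picks$x * bin + (bin %/% 2), b2), nx0 - box + b2)
    picks$y <- pmin(pmax(picks$y * bin + (bin %/% 2), b2), ny0 - box + b2)
  }
  picks
}
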