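# Weak-phase contrast transfer function of the objective lens:
#   CTF(k) = -[ sqrt(1 - A^2) sin(gamma(k)) + A cos(gamma(k)) ] * E(k)
#   gamma(k) = pi * lambda * k^2 * dz - (pi/2) * Cs * lambda^3 * k^4
# with lambda the relativistic electron wavelength, A the amplitude-contrast
# fraction and E(k) = exp(-k^2 / (2 b^2)) a Gaussian envelope of half width b.
#
# Sign convention: defocus is quoted with NEGATIVE values meaning underfocus
# (the common microscopy sign in data-collection reports). Internally gamma
# uses dz = -defocus * 1e4 Angstrom, so that an underfocused lens transfers
# the whole low-frequency band with a single (negative) sign -- protein
# appears dark, the usual cryo-EM contrast. Set
# `defocus_enters_directly = TRUE` to flip the convention and feed the quoted
# value into gamma unchanged.

#' Relativistic electron wavelength
#'
#' @param voltage acceleration voltage in kV.
#' @return wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage) {
  v <- voltage * 1e3
  12.2643 / sqrt(v * (1 + 0.97845e-6 * v))
}

#' Contrast transfer function parameter set
#'
#' @param voltage acceleration voltage, kV.
#' @param defocus defocus in micrometer; negative = underfocus.
#' @param cs spherical aberration, mm.
#' @param amplitude_contrast amplitude-contrast fraction in `[0, 1]`.
#' @param envelope_halfwidth Gaussian envelope half width, 1/Angstrom;
#'   `Inf` disables the envelope.
#' @param pixel_size Angstrom per pixel of the images the CTF acts on.
#' @param defocus_enters_directly flip the defocus sign convention (see
#'   source comments).
#' @return an object of class `ctf_params`.
#' @export
ctf_params <- function(voltage = 200, defocus = -1, cs = 2.0,
                       amplitude_contrast = 0.10,
                       envelope_halfwidth = 0.333, pixel_size = 1,
                       defocus_enters_directly = FALSE) {
  stopifnot(voltage > 0, cs >= 0, amplitude_contrast >= 0,
            amplitude_contrast <= 1, envelope_halfwidth > 0, pixel_size > 0)
  structure(list(voltage = voltage, defocus = defocus, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 envelope_halfwidth = envelope_halfwidth,
                 pixel_size = pixel_size,
                 defocus_enters_directly = defocus_enters_directly),
            class = "ctf_params")
}

#' Evaluate the CTF at spatial frequencies
#'
#' @param k spatial frequency (1/Angstrom), scalar or vector.
#' @param ctf a [ctf_params()] object.
#' @param envelope include the Gaussian envelope (default TRUE).
#' @return CTF values; `ctf_eval(0, ctf)` equals `-amplitude_contrast`.
#' @export
ctf_eval <- function(k, ctf, envelope = TRUE) {
  lambda <- electron_wavelength(ctf$voltage)
  dz <- if (isTRUE(ctf$defocus_enters_directly)) ctf$defocus * 1e4 else -ctf$defocus * 1e4
  cs_A <- ctf$cs * 1e7
  a <- ctf$amplitude_contrast
  gamma <- pi * lambda * k^2 * dz - (pi / 2) * cs_A * lambda^3 * k^4
  v <- -(sqrt(1 - a^2) * sin(gamma) + a * cos(gamma))
  if (envelope && is.finite(ctf$envelope_halfwidth)) {
    v <- v * exp(-k^2 / (2 * ctf$envelope_halfwidth^2))
  }
  v
}

#' First zero crossing of the CTF
#'
#' Scans outward from DC and refines the first sign change by root finding.
#'
#' @param ctf a [ctf_params()] object.
#' @param k_max upper search bound, 1/Angstrom (default: Nyquist).
#' @return frequency of the first zero in 1/Angstrom, or `NA` if none below
#'   `k_max`.
#' @export
first_ctf_zero <- function(ctf, k_max = 1 / (2 * ctf$pixel_size)) {
  ks <- seq(1e-5, k_max, length.out = 4096)
  v <- ctf_eval(ks, ctf, envelope = FALSE)
  flip <- which(v[-1] * v[-length(v)] < 0)
  if (!length(flip)) return(NA_real_)
  i <- flip[1]
  stats::uniroot(function(k) ctf_eval(k, ctf, envelope = FALSE),
                 c(ks[i], ks[i + 1]), tol = 1e-10)$root
}

# 2D CTF values on the fft frequency grid (unshifted layout).
ctf_grid <- function(nx, ny, ctf) {
  k <- sqrt(freq2_grid(nx, ny, ctf$pixel_size))
  matrix(ctf_eval(as.vector(k), ctf), nx, ny)
}

#' Apply the CTF to an image in Fourier space
#'
#' Multiplies the Fourier transform of the image by `CTF(|k|)` and returns
#' the real part of the inverse transform. Linear in the image. If the first
#' CTF zero lies beyond Nyquist this is logged, not an error.
#'
#' @param img numeric matrix; `pixel_size` is taken from `ctf`.
#' @param ctf a [ctf_params()] object.
#' @return filtered image (same dimensions), with a `pixel_size` attribute.
#' @export
apply_ctf <- function(img, ctf) {
  stopifnot(inherits(ctf, "ctf_params"))
  z0 <- first_ctf_zero(ctf)
  if (is.na(z0)) {
    bof_log("apply_ctf: first CTF zero beyond Nyquist (",
            1 / (2 * ctf$pixel_size), " 1/A)")
  }
  out <- Re(ifft2(stats::fft(img) * ctf_grid(nrow(img), ncol(img), ctf)))
  attr(out, "pixel_size") <- ctf$pixel_size
  out
}
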