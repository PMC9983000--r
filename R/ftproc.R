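#' Magnitude Fourier spectrum of a channel transient
#'
#' Subtracts the transient mean (the cos^2 fringe law carries a 1/2 DC
#' offset that would otherwise dominate bin zero), optionally applies a
#' Hann window, zero-fills, and returns the one-sided magnitude spectrum on
#' a cycles-per-scan axis spanning \[0, 0.5\].
#'
#' @param transient A `channel_transient` (from
#'   [extract_channel_transient()]) or a plain numeric vector of length
#'   >= 2.
#' @param window `"none"` (default; matches the FWHM = 1.2067/T
#'   rectangular-window calibration used for resolving powers) or
#'   `"hann"`.
#' @param zero_fill Zero-fill factor (default 2): the transform length is
#'   `zero_fill * length(transient)`.
#' @param scan_step Scan-axis step in s, used to convert cycles/scan to Hz;
#'   taken from the transient's scan axis when available.
#' @return Object of class `frequency_spectrum` with fields `frequency`
#'   (cycles/scan), `magnitude`, `frequency_hz` (when `scan_step` is
#'   known), `n_input`, `window`, `zero_fill` and `mode = "magnitude"`.
#' @export
#' @examples
#' x <- cos(2 * pi * 50 * (0:1023) / 1024)
#' sp <- fft_magnitude(x)
#' sp$frequency[which.max(sp$magnitude)]  # ~50/1024
fft_magnitude <- function(transient, window = c("none", "hann"),
                          zero_fill = 2L, scan_step = NULL) {
  window <- match.arg(window)
  if (inherits(transient, "channel_transient")) {
    if (is.null(scan_step) && length(transient$scan_axis) >= 2)
      scan_step <- diff(transient$scan_axis[1:2])
    transient <- transient$intensity
  }
  x <- as.numeric(transient)
  n <- length(x)
  if (n < 2) stop("transient must have at least 2 samples")
  stopifnot(zero_fill >= 1)
  x <- x - mean(x)
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
  m <- as.integer(round(zero_fill * n))
  X <- stats::fft(c(x, numeric(m - n)))
  half <- floor(m / 2) + 1L
  structure(list(frequency = (0:(half - 1L)) / m,
                 magnitude = Mod(X[1:half]),
                 frequency_hz = if (!is.null(scan_step))
                   (0:(half - 1L)) / m / scan_step else NULL,
                 scan_step = scan_step,
                 n_input = n, window = window,
                 zero_fill = zero_fill, mode = "magnitude"),
            class = "frequency_spectrum")
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat("<frequency_spectrum>", length(x$frequency), "points |",
      x$n_input, "input samples | window", x$window,
      "| zero-fill x", x$zero_fill, "\n")
  invisible(x)
}

# Parabolic vertex through three equally spaced points; returns the
# fractional offset from the middle point and the interpolated height.
.parabolic_vertex <- function(y1, y2, y3) {
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(list(delta = 0, height = y2))
  delta <- 0.5 * (y1 - y3) / denom
  list(delta = delta, height = y2 - 0.25 * (y1 - y3) * delta)
}

#' Pick peaks from a magnitude spectrum
#'
#' Local maxima above a relative height threshold. Each peak's centroid and
#' height come from three-point parabolic interpolation of the magnitude;
#' the FWHM comes from linear interpolation of the half-height crossings on
#' either flank. Resolving powers are attached per [resolving_power()].
#'
#' @param spectrum A `frequency_spectrum`.
#' @param min_relative_height Threshold as a fraction of the tallest
#'   magnitude (default 0.1).
#' @return Data frame of class `peak_list` with columns `centroid`
#'   (cycles/scan), `centroid_hz` (when the scan step is known), `height`,
#'   `fwhm` (cycles/scan), `rp_f`, `rp_mz`, sorted by height, possibly
#'   empty.
#' @export
pick_peaks <- function(spectrum, min_relative_height = 0.1) {
  stopifnot(inherits(spectrum, "frequency_spectrum"))
  y <- spectrum$magnitude
  f <- spectrum$frequency
  n <- length(y)
  empty <- data.frame(centroid = numeric(), centroid_hz = numeric(),
                      height = numeric(), fwhm = numeric(),
                      rp_f = numeric(), rp_mz = numeric())
  class(empty) <- c("peak_list", "data.frame")
  if (n < 3 || max(y) <= 0) return(empty)
  thresh <- min_relative_height * max(y)
  i <- 2:(n - 1)
  is_peak <- y[i] >= thresh & y[i] > y[i - 1] & y[i] >= y[i + 1]
  idx <- i[is_peak]
  if (length(idx) == 0) return(empty)
  df <- f[2] - f[1]
  rows <- lapply(idx, function(i0) {
    v <- .parabolic_vertex(y[i0 - 1], y[i0], y[i0 + 1])
    cent <- f[i0] + v$delta * df
    half <- v$height / 2
    iL <- i0
    while (iL > 1 && y[iL] > half) iL <- iL - 1L
    fL <- if (y[iL] > half) f[iL]
          else f[iL] + (half - y[iL]) / (y[iL + 1] - y[iL]) * df
    iR <- i0
    while (iR < n && y[iR] > half) iR <- iR + 1L
    fR <- if (y[iR] > half) f[iR]
          else f[iR - 1] + (half - y[iR - 1]) / (y[iR] - y[iR - 1]) * df
    data.frame(centroid = cent, height = v$height, fwhm = fR - fL)
  })
  out <- do.call(rbind, rows)
  out <- out[out$fwhm > 0, , drop = FALSE]
  out$centroid_hz <- if (!is.null(spectrum$scan_step))
    out$centroid / spectrum$scan_step else NA_real_
  out$rp_f <- out$centroid / out$fwhm
  out$rp_mz <- out$rp_f / 2
  out <- out[order(-out$height),
             c("centroid", "centroid_hz", "height", "fwhm", "rp_f",
               "rp_mz")]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' FWHM resolving power of a picked peak
#'
#' `RP_f = centroid / FWHM` in the frequency domain. Because
#' m/z = (D/f)^2, a fractional frequency width maps to twice the fractional
#' m/z width, so the m/z-domain resolving power is exactly half the
#' frequency-domain one.
#'
#' @param peak One row of a [pick_peaks()] result (or any list with
#'   `centroid` and `fwhm`).
#' @return Named numeric `c(rp_f, rp_mz)`.
#' @export
#' @examples
#' resolving_power(list(centroid = 0.25, fwhm = 0.001))
resolving_power <- function(peak) {
  cent <- peak$centroid[1]
  fwhm <- peak$fwhm[1]
  if (is.null(fwhm) || fwhm <= 0) stop("degenerate peak: FWHM must be > 0")
  rp <- cent / fwhm
  c(rp_f = rp, rp_mz = rp / 2)
}

#' Check a modulation frequency against the Nyquist criterion
#'
#' A species modulated faster than half the scan-axis sampling rate cannot
#' be assigned unambiguously: its peak folds back into \[0, 0.5\]
#' cycles/scan. This reports the aliased apparent frequency and warns.
#'
#' @param frequency Expected modulation frequency in cycles per scan.
#' @return List with `status` (`"pass"` or `"alias"`), the input
#'   `frequency`, and `apparent_frequency` (folded into \[0, 0.5\]).
#' @export
#' @examples
#' check_nyquist(0.25)$status   # "pass"
#' check_nyquist(0.6)$apparent_frequency  # 0.4
check_nyquist <- function(frequency) {
  stopifnot(frequency >= 0)
  if (frequency <= 0.5)
    return(list(status = "pass", frequency = frequency,
                apparent_frequency = frequency))
  fold <- frequency %% 1
  apparent <- if (fold > 0.5) 1 - fold else fold
  warning(sprintf(
    "modulation at %.4g cycles/scan exceeds Nyquist (0.5); aliases to %.4g",
    frequency, apparent))
  list(status = "alias", frequency = frequency,
       apparent_frequency = apparent)
}
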