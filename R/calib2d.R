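#' Fit the inverse-square-root frequency calibration
#'
#' Modulation frequency and precursor m/z obey f = D / sqrt(m/z): the
#' calibration constant D is shared by all masses at fixed charge, in both
#' the TOF (D = lateral speed per sqrt(Th) over the fringe spacing) and the
#' sector variant. The fit is one-parameter least squares of f against
#' (m/z)^(-1/2) through the origin, which is exact for noiseless
#' law-consistent points. The phase constant C (offset between the ions'
#' start point and the first fringe maximum) is stored for completeness but
#' plays no role in magnitude-mode processing.
#'
#' @param frequency Measured peak frequencies (any single consistent unit:
#'   cycles/scan or Hz); positive.
#' @param mz Known precursor m/z values, Th; positive, same length.
#' @param variant `"tof"` or `"sector"`, recorded on the model.
#' @param frequency_unit Unit label recorded on the model
#'   (default `"cycles/scan"`).
#' @param C Phase constant, recorded but unused in magnitude mode.
#' @return Object of class `calibration_model` with fields `D`, `C`,
#'   `variant`, `frequency_unit`, `residual_rms`, `n_points`.
#' @export
#' @examples
#' m <- fit_inverse_sqrt_calibration(c(0.2, 0.1), c(100, 400))
#' m$D  # 2
fit_inverse_sqrt_calibration <- function(frequency, mz,
                                         variant = c("tof", "sector"),
                                         frequency_unit = "cycles/scan",
                                         C = 0) {
  variant <- match.arg(variant)
  if (length(frequency) != length(mz) || length(frequency) < 1)
    stop("need >= 1 matched (frequency, mz) point")
  if (any(frequency <= 0) || any(mz <= 0))
    stop("frequencies and m/z values must be positive")
  x <- 1 / sqrt(mz)
  D <- sum(frequency * x) / sum(x^2)
  res <- frequency - D * x
  structure(list(D = D, C = C, variant = variant,
                 frequency_unit = frequency_unit,
                 residual_rms = sqrt(mean(res^2)),
                 n_points = length(frequency)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>", x$variant, "| D =", signif(x$D, 8),
      x$frequency_unit, "* Th^1/2 | residual RMS",
      signif(x$residual_rms, 3), "| n =", x$n_points, "\n")
  invisible(x)
}

#' Map a modulation frequency to precursor m/z
#'
#' Inverts the calibration law: m/z = (D / f)^2, strictly decreasing in f.
#'
#' @param f Frequency, same unit as the model (positive; vectorized).
#' @param model A [fit_inverse_sqrt_calibration()] model.
#' @return Precursor m/z in Th.
#' @export
frequency_to_precursor_mz <- function(f, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(f <= 0)) stop("frequency must be positive")
  (model$D / f)^2
}

#' Predicted modulation frequency of a precursor under a calibration
#'
#' @param mz Precursor m/z, Th (positive; vectorized).
#' @param model A [fit_inverse_sqrt_calibration()] model.
#' @return Frequency in the model's unit.
#' @export
precursor_mz_to_frequency <- function(mz, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(mz <= 0)) stop("mz must be positive")
  model$D / sqrt(mz)
}

#' Assemble the 2D precursor-by-fragment map
#'
#' For every fragment channel of the cube: Fourier-transform its transient,
#' pick peaks, map each peak frequency to precursor m/z through the
#' calibration, and emit (precursor_mz, fragment_mz, intensity) triplets.
#' Triplets whose inferred precursor m/z does not exceed the fragment m/z
#' (impossible under the singly-charged convention) are dropped and
#' counted, as are peaks below `min_frequency`: ions that enter or leave
#' the zone mid-schedule gate their transient with a baseline step whose
#' spectral content sits in the first few bins and does not encode a
#' precursor mass.
#'
#' @param cube A `transient_cube`.
#' @param model A [fit_inverse_sqrt_calibration()] model whose `variant`
#'   matches the cube's.
#' @param min_relative_height Peak threshold passed to [pick_peaks()];
#'   the default 0.3 sits above the 21.7% first sidelobe of the
#'   unapodized line shape.
#' @param min_frequency Smallest peak frequency (cycles/scan) mapped to a
#'   precursor; defaults to 10 transform bins of the unpadded transient.
#' @param window,zero_fill Passed to [fft_magnitude()].
#' @return Object of class `spectrum2d`: a data frame of triplets
#'   `precursor_mz, fragment_mz, intensity` with attributes `variant` and
#'   `n_dropped`.
#' @export
assemble_2d <- function(cube, model, min_relative_height = 0.3,
                        min_frequency = NULL, window = "none",
                        zero_fill = 2L) {
  stopifnot(inherits(cube, "transient_cube"),
            inherits(model, "calibration_model"))
  if (cube$variant != model$variant)
    stop(sprintf("variant mismatch: cube is '%s', model is '%s'",
                 cube$variant, model$variant))
  frag_idx <- which(cube$channels$kind == "fragment")
  if (is.null(min_frequency))
    min_frequency <- 10 / nrow(cube$intensity)
  rows <- list()
  dropped <- 0L
  for (j in frag_idx) {
    fmz <- cube$channels$channel_mz[j]
    sp <- fft_magnitude(cube$intensity[, j], window = window,
                        zero_fill = zero_fill)
    pk <- pick_peaks(sp, min_relative_height)
    pk <- pk[pk$centroid >= min_frequency, , drop = FALSE]
    if (nrow(pk) == 0) next
    pmz <- frequency_to_precursor_mz(pk$centroid, model)
    ok <- pmz > fmz
    dropped <- dropped + sum(!ok)
    if (any(ok))
      rows[[length(rows) + 1L]] <-
        data.frame(precursor_mz = pmz[ok], fragment_mz = fmz,
                   intensity = pk$height[ok])
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(precursor_mz = numeric(),
                         fragment_mz = numeric(), intensity = numeric())
  out <- out[order(out$precursor_mz, out$fragment_mz), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "variant") <- cube$variant
  attr(out, "n_dropped") <- dropped
  class(out) <- c("spectrum2d", "data.frame")
  out
}

#' Fragment spectrum of one precursor (horizontal slice of the 2D map)
#'
#' @param map A [assemble_2d()] result.
#' @param precursor_mz Requested precursor m/z, Th.
#' @param tolerance Matching half-width on the precursor axis, Th.
#' @return Data frame `fragment_mz, intensity` (possibly empty), summed
#'   over matching precursor entries per fragment.
#' @export
precursor_slice <- function(map, precursor_mz, tolerance = 0) {
  stopifnot(inherits(map, "spectrum2d"))
  sel <- abs(map$precursor_mz - precursor_mz) <= tolerance
  hit <- map[sel, , drop = FALSE]
  if (nrow(hit) == 0)
    return(data.frame(fragment_mz = numeric(), intensity = numeric()))
  agg <- stats::aggregate(intensity ~ fragment_mz, data = hit, FUN = sum)
  agg[order(agg$fragment_mz), , drop = FALSE]
}

#' Theoretical TOF calibration implied by a configuration
#'
#' Computes D directly from the configured kick potential, fringe spacing
#' and delay increment (cycles/scan unit):
#' `D = sqrt(2 e v_kick / u) * delay_increment / fringe_spacing`.
#' Useful as the ground truth against fitted calibrations.
#'
#' @param config A [tof_config()].
#' @param pattern A [fragmentation_pattern()].
#' @param schedule A [scan_schedule()].
#' @param charge Charge state (default 1).
#' @return A `calibration_model`.
#' @export
tof_calibration_from_config <- function(config, pattern, schedule,
                                        charge = 1L) {
  D <- speed_from_potential(1, charge, config$v_kick) *
    schedule$delay_increment / pattern$fringe_spacing
  structure(list(D = D, C = 0, variant = "tof",
                 frequency_unit = "cycles/scan",
                 residual_rms = 0, n_points = 0L),
            class = "calibration_model")
}
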