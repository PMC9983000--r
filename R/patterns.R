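#' Spatially periodic fragmentation pattern
#'
#' Describes the relative light intensity I(d) across the fragmentation
#' zone. Ions capture a photon (and fragment) with probability proportional
#' to I at their position, so a periodic pattern modulates fragmentation as
#' ions drift across it.
#'
#' Kinds:
#' * `dual_slit` — ideal two-beam interference fringes,
#'   I(d) = cos^2(pi (d - phase_offset) / fringe_spacing).
#' * `grating` — N-slit (Dirichlet) fringes with the same maxima spacing but
#'   sharper peaks; `n_slits` controls the sharpness.
#' * `custom_tabulated` — linear interpolation of a user-supplied
#'   (position_m, relative_intensity) table.
#'
#' Intensity is zero outside `[0, zone_length]`. An optional sinc^2
#' visibility envelope (centred on the zone) models finite slit width; it is
#' off by default because ideal fringes have maximal modulation depth and
#' are exactly analyzable.
#'
#' @param kind One of `"dual_slit"`, `"grating"`, `"custom_tabulated"`.
#' @param fringe_spacing Distance between adjacent intensity maxima, m.
#' @param zone_length Extent of the fragmentation zone, m.
#' @param phase_offset Position of the first maximum relative to the zone
#'   start, m, in `[0, fringe_spacing)`.
#' @param envelope `"none"` (default) or `"sinc2"`.
#' @param envelope_width Characteristic half-width of the sinc^2 envelope, m
#'   (defaults to the zone length).
#' @param n_slits Number of slits for `kind = "grating"`.
#' @param table Two-column data frame `(position_m, relative_intensity)` for
#'   `kind = "custom_tabulated"`; intensities must lie in \[0, 1\].
#' @return Object of class `fragmentation_pattern`.
#' @export
#' @examples
#' pat <- fragmentation_pattern("dual_slit", fringe_spacing = 0.2e-3,
#'                              zone_length = 36.2e-3)
#' pattern_intensity(pat, c(0, 0.1e-3, 0.2e-3))
fragmentation_pattern <- function(kind = c("dual_slit", "grating",
                                           "custom_tabulated"),
                                  fringe_spacing = 0.2e-3,
                                  zone_length = 36.2e-3,
                                  phase_offset = 0,
                                  envelope = c("none", "sinc2"),
                                  envelope_width = zone_length,
                                  n_slits = 5L,
                                  table = NULL) {
  kind <- match.arg(kind)
  envelope <- match.arg(envelope)
  stopifnot(fringe_spacing > 0, zone_length > 0,
            phase_offset >= 0, phase_offset < fringe_spacing)
  if (kind == "custom_tabulated") {
    if (is.null(table) || ncol(table) < 2)
      stop("custom_tabulated patterns need a (position_m, relative_intensity) table")
    table <- data.frame(position_m = as.numeric(table[[1]]),
                        relative_intensity = as.numeric(table[[2]]))
    if (any(!is.finite(table$position_m)) ||
        any(table$relative_intensity < 0) ||
        any(table$relative_intensity > 1))
      stop("tabulated intensities must be finite and within [0, 1]")
    table <- table[order(table$position_m), ]
  }
  structure(list(kind = kind, fringe_spacing = fringe_spacing,
                 zone_length = zone_length, phase_offset = phase_offset,
                 envelope = envelope, envelope_width = envelope_width,
                 n_slits = as.integer(n_slits), table = table),
            class = "fragmentation_pattern")
}

#' @export
print.fragmentation_pattern <- function(x, ...) {
  cat("<fragmentation_pattern>", x$kind,
      "| fringe", signif(x$fringe_spacing * 1e3, 4), "mm",
      "| zone", signif(x$zone_length * 1e3, 4), "mm",
      "| maxima", maxima_count(x), "\n")
  invisible(x)
}

#' Read a tabulated pattern from CSV
#'
#' @param path CSV file with columns `position_m, relative_intensity`.
#' @param zone_length Zone extent, m; defaults to the largest tabulated
#'   position.
#' @param fringe_spacing Nominal fringe spacing, m, used only for metadata
#'   on tabulated patterns; defaults to the zone length.
#' @return A `custom_tabulated` [fragmentation_pattern()].
#' @export
read_pattern_csv <- function(path, zone_length = NULL, fringe_spacing = NULL) {
  tab <- utils::read.csv(path)
  if (!all(c("position_m", "relative_intensity") %in% names(tab)))
    stop("pattern CSV must have columns position_m, relative_intensity")
  if (is.null(zone_length)) zone_length <- max(tab$position_m)
  if (is.null(fringe_spacing)) fringe_spacing <- zone_length
  fragmentation_pattern("custom_tabulated", fringe_spacing = fringe_spacing,
                        zone_length = zone_length, table = tab)
}

#' Evaluate the pattern intensity at ion positions
#'
#' @param pattern A [fragmentation_pattern()].
#' @param d Positions along the fragmentation axis, m, measured from the
#'   zone entrance; values outside the zone return 0.
#' @return Relative intensities in \[0, 1\], same length as `d`.
#' @export
pattern_intensity <- function(pattern, d) {
  stopifnot(inherits(pattern, "fragmentation_pattern"))
  inside <- d >= 0 & d <= pattern$zone_length
  out <- numeric(length(d))
  if (!any(inside)) return(out)
  x <- d[inside]
  base <- switch(pattern$kind,
    dual_slit = cos(pi * (x - pattern$phase_offset) / pattern$fringe_spacing)^2,
    grating = {
      # squared Dirichlet kernel, normalized so maxima reach 1
      n <- pattern$n_slits
      ph <- pi * (x - pattern$phase_offset) / pattern$fringe_spacing
      num <- sin(n * ph)
      den <- n * sin(ph)
      v <- ifelse(abs(den) < 1e-12, 1, (num / den)^2)
      pmin(v, 1)
    },
    custom_tabulated = stats::approx(pattern$table$position_m,
                                     pattern$table$relative_intensity,
                                     xout = x, rule = 2)$y
  )
  if (pattern$envelope == "sinc2") {
    arg <- (x - pattern$zone_length / 2) / pattern$envelope_width
    env <- ifelse(abs(arg) < 1e-12, 1, (sin(pi * arg) / (pi * arg))^2)
    base <- base * env
  }
  out[inside] <- base
  out
}

#' Number of intensity maxima in the fragmentation zone
#'
#' For analytic fringe patterns, maxima sit at `phase_offset + k * Lambda`,
#' so n = 1 + floor((zone_length - phase_offset) / Lambda). For tabulated
#' patterns the count comes from a scan for local maxima.
#'
#' @param pattern A [fragmentation_pattern()].
#' @param zone_length Zone extent, m; defaults to the pattern's own.
#' @return Integer count of intensity maxima within `[0, zone_length]`.
#' @export
#' @examples
#' maxima_count(fragmentation_pattern(fringe_spacing = 0.2e-3,
#'                                    zone_length = 36.2e-3))  # 182
maxima_count <- function(pattern, zone_length = pattern$zone_length) {
  stopifnot(inherits(pattern, "fragmentation_pattern"), zone_length > 0)
  if (pattern$kind %in% c("dual_slit", "grating")) {
    as.integer(1 + floor((zone_length - pattern$phase_offset) /
                           pattern$fringe_spacing + 1e-9))
  } else {
    y <- pattern$table$relative_intensity
    sum(diff(sign(diff(c(-Inf, y, -Inf)))) == -2)
  }
}

#' Fragmentation-modulation frequency of a precursor (TOF variant)
#'
#' An ion drifting laterally at v crosses one fringe per Lambda / v seconds,
#' so its fragmentation intensity oscillates at f = v / Lambda with respect
#' to the delay time. Since v scales as 1/sqrt(m/z), f = D / sqrt(m/z) with
#' D = sqrt(2 e v_kick z / u) / Lambda: the calibration constant is the same
#' for all masses at fixed charge.
#'
#' @param pattern A [fragmentation_pattern()].
#' @param mz Precursor m/z, Th (vectorized).
#' @param charge Charge state (default 1).
#' @param v_kick Side-kick potential, V.
#' @return Modulation frequency in Hz (with respect to delay time).
#' @export
#' @examples
#' modulation_frequency_tof(fragmentation_pattern(), 1000, v_kick = 7)
modulation_frequency_tof <- function(pattern, mz, charge = 1L, v_kick) {
  stopifnot(inherits(pattern, "fragmentation_pattern"))
  speed_from_potential(mz, charge, v_kick) / pattern$fringe_spacing
}
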