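#' Scan schedule for the incremental-delay TOF acquisition
#'
#' The acquisition runs `n_scans` scan lines; scan k (k = 0, 1, ...) waits
#' `initial_delay + k * delay_increment` seconds between the side kick and
#' the fragmentation pulse. By default the increment is chosen at
#' initialization to split the fragmentation zone evenly across the
#' schedule: a reference ion (`mz_ref`, default 1000 Th) traverses the zone
#' exactly once over the full acquisition, and the initial delay is its
#' zone-entry time.
#'
#' @param n_scans Number of scan lines (default 2^15 = 32768).
#' @param delay_increment Delay step, s; default
#'   `zone_length / (v_ref * n_scans)`.
#' @param initial_delay First-scan delay, s; default `zone_start / v_ref`.
#' @param config A [tof_config()] (used only for the defaults).
#' @param mz_ref Reference m/z for the default rule, Th.
#' @return Object of class `scan_schedule`.
#' @export
#' @examples
#' scan_schedule(config = tof_config())
scan_schedule <- function(n_scans = 2L^15L, delay_increment = NULL,
                          initial_delay = NULL, config = NULL,
                          mz_ref = 1000) {
  stopifnot(n_scans >= 2)
  if (is.null(delay_increment) || is.null(initial_delay)) {
    if (is.null(config))
      stop("config is required to derive default delays")
    v_ref <- speed_from_potential(mz_ref, 1L, config$v_kick)
    if (is.null(delay_increment))
      delay_increment <- config$zone_length / (v_ref * n_scans)
    if (is.null(initial_delay))
      initial_delay <- config$zone_start / v_ref
  }
  stopifnot(delay_increment > 0, initial_delay >= 0)
  structure(list(n_scans = as.integer(n_scans),
                 delay_increment = delay_increment,
                 initial_delay = initial_delay,
                 mz_ref = mz_ref),
            class = "scan_schedule")
}

#' Delay value of every scan line
#'
#' @param schedule A [scan_schedule()].
#' @return Numeric vector of length `n_scans`, strictly increasing.
#' @export
scan_delays <- function(schedule) {
  stopifnot(inherits(schedule, "scan_schedule"))
  schedule$initial_delay +
    (0:(schedule$n_scans - 1L)) * schedule$delay_increment
}

# Build the channel table for a mixture: one channel per distinct fragment
# m/z (shared channels are summed and flagged) plus one depleted-precursor
# channel per precursor.
.build_channels <- function(mixture) {
  frag_mz <- unlist(lapply(mixture, function(p) p$fragments$fragment_mz))
  overlap <- any(duplicated(frag_mz))
  frag_mz <- sort(unique(frag_mz))
  channels <- data.frame(
    channel_mz = c(frag_mz, vapply(mixture, `[[`, numeric(1), "mz")),
    kind = c(rep("fragment", length(frag_mz)),
             rep("precursor", length(mixture))))
  list(channels = channels, overlapping = overlap)
}

# Shared scan engine for both variants. positions is an n_scans x n_prec
# matrix of fragmentation-axis coordinates (m, zone-entrance origin).
.run_scan_engine <- function(mixture, positions, scan_axis, pattern,
                             mode, seed, n_ions, event_log, variant,
                             extra_meta = list()) {
  if (inherits(mixture, "precursor_species")) mixture <- list(mixture)
  stopifnot(all(vapply(mixture, inherits, logical(1), "precursor_species")))
  n_scans <- length(scan_axis)
  ch <- .build_channels(mixture)
  channels <- ch$channels
  intensity <- matrix(0, nrow = n_scans, ncol = nrow(channels))
  log_rows <- if (event_log) vector("list", length(mixture)) else NULL

  if (mode == "stochastic") {
    if (is.null(seed)) stop("stochastic mode requires a seed")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(seed)
  }

  overshoot <- 0L
  for (i in seq_along(mixture)) {
    p <- mixture[[i]]
    d <- positions[, i]
    I <- pattern_intensity(pattern, d)
    overshoot <- overshoot + sum(d > pattern$zone_length)
    prec_col <- which(channels$kind == "precursor")[i]
    if (mode == "deterministic") {
      frac <- I
      if (nrow(p$fragments) > 0) {
        for (j in seq_len(nrow(p$fragments))) {
          col <- which(channels$kind == "fragment" &
                         channels$channel_mz == p$fragments$fragment_mz[j])
          intensity[, col] <- intensity[, col] +
            p$abundance * p$fragments$branching_ratio[j] * I
        }
      }
      intensity[, prec_col] <- intensity[, prec_col] + p$abundance * (1 - I)
    } else {
      n_frag <- stats::rbinom(n_scans, n_ions, I)
      frac <- n_frag / n_ions
      remaining <- n_frag
      rem_p <- 1
      if (nrow(p$fragments) > 0) {
        for (j in seq_len(nrow(p$fragments))) {
          br <- p$fragments$branching_ratio[j]
          x <- stats::rbinom(n_scans, remaining, min(1, br / rem_p))
          remaining <- remaining - x
          rem_p <- rem_p - br
          col <- which(channels$kind == "fragment" &
                         channels$channel_mz == p$fragments$fragment_mz[j])
          intensity[, col] <- intensity[, col] + p$abundance * x / n_ions
        }
      }
      intensity[, prec_col] <- intensity[, prec_col] +
        p$abundance * (1 - frac)
    }
    if (event_log)
      log_rows[[i]] <- data.frame(scan_index = 0:(n_scans - 1L),
                                  ion_id = i,
                                  precursor_mz = p$mz,
                                  lateral_position_m = d,
                                  fragmentation_intensity = frac)
  }

  log_df <- if (event_log) {
    df <- do.call(rbind, log_rows)
    df[order(df$scan_index, df$ion_id), , drop = FALSE]
  } else NULL

  structure(list(
    intensity = intensity,
    scan_axis = scan_axis,
    channels = channels,
    variant = variant,
    event_log = log_df,
    metadata = c(list(mode = mode, seed = seed,
                      n_ions = if (mode == "stochastic") n_ions else NA,
                      overlapping_channels = ch$overlapping,
                      loss_tally = overshoot,
                      pattern = pattern),
                 extra_meta)),
    class = "transient_cube")
}

#' Run the side kick-delay-fragment-detect TOF scan sequence
#'
#' For each scan line, every precursor drifts laterally for that scan's
#' delay; its fragmentation intensity is the pattern intensity at its
#' position at the start of the fragmentation period. In deterministic mode
#' each fragment channel receives `abundance * branching_ratio * I(d)` and a
#' depleted precursor channel receives `abundance * (1 - I(d))`; in
#' stochastic mode each of `n_ions` ion copies fragments as an independent
#' Bernoulli(I(d)) draw and fragments are distributed multinomially over the
#' branching ratios.
#'
#' @param mixture A list of [precursor_species()] (or a single one).
#' @param config A [tof_config()].
#' @param pattern A [fragmentation_pattern()].
#' @param schedule A [scan_schedule()]; defaults to the zone-splitting rule
#'   for `config`.
#' @param mode `"deterministic"` (default) or `"stochastic"`.
#' @param seed Integer seed, required in stochastic mode.
#' @param n_ions Ion copies per precursor per scan in stochastic mode.
#' @param event_log If `TRUE` (default) the per-scan event log
#'   (scan_index, ion_id, precursor_mz, lateral_position_m,
#'   fragmentation_intensity) is kept on the cube; disable for speed.
#' @return A `transient_cube`: scans x channels intensity matrix, the scan
#'   (delay) axis in s, the channel table, the event log, and provenance
#'   metadata (including a Nyquist check per precursor).
#' @export
#' @examples
#' cfg <- tof_config()
#' sp <- precursor_species(1000, fragments = data.frame(
#'   fragment_mz = 650, branching_ratio = 0.5))
#' cube <- run_tof_scan_sequence(sp, cfg, fragmentation_pattern(),
#'                               scan_schedule(1024, config = cfg))
#' dim(cube$intensity)
run_tof_scan_sequence <- function(mixture, config, pattern,
                                  schedule = scan_schedule(config = config),
                                  mode = c("deterministic", "stochastic"),
                                  seed = NULL, n_ions = 1000L,
                                  event_log = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "tof_config"),
            inherits(pattern, "fragmentation_pattern"),
            inherits(schedule, "scan_schedule"))
  if (inherits(mixture, "precursor_species")) mixture <- list(mixture)
  delays <- scan_delays(schedule)
  nyq <- vapply(mixture, function(p) {
    v <- speed_from_potential(p$mz, p$charge, config$v_kick)
    if (v <= 0) stop("precursor with zero lateral speed: check v_kick")
    v / pattern$fringe_spacing * schedule$delay_increment  # cycles/scan
  }, numeric(1))
  for (f in nyq) check_nyquist(f)
  positions <- vapply(mixture, function(p) {
    st <- ion_state(p, config)
    state_d <- st$lateral_speed * delays - config$zone_start
    state_d
  }, numeric(length(delays)))
  positions <- matrix(positions, nrow = length(delays))
  .run_scan_engine(mixture, positions, delays, pattern, mode, seed,
                   n_ions, event_log, variant = "tof",
                   extra_meta = list(config = config, schedule = schedule,
                                     cycles_per_scan = nyq))
}

#' Map one scan's fragment intensities onto the TOF detector axis
#'
#' Each channel's intensity is placed at its flight time and accumulated
#' into a binned detector time axis; total intensity is conserved except for
#' ions whose flight time falls outside the detector window, which are
#' dropped and tallied.
#'
#' @param intensities Named numeric vector of per-channel intensities; names
#'   are channel m/z values in Th.
#' @param config A [tof_config()].
#' @param window Detector time window `c(t_min, t_max)` in s; defaults to
#'   `c(0, 1.05 * max flight time)` of the supplied channels.
#' @param n_bins Number of detector time bins.
#' @return List with `spectrum` (data frame `time_s`, `intensity` for
#'   nonzero bins, in flight-time order) and `loss` (dropped intensity).
#' @export
detect_fragments <- function(intensities, config, window = NULL,
                             n_bins = 1024L) {
  stopifnot(inherits(config, "tof_config"))
  if (length(intensities) == 0)
    return(list(spectrum = data.frame(time_s = numeric(),
                                      intensity = numeric()),
                loss = 0))
  mz <- as.numeric(names(intensities))
  if (any(is.na(mz)) || any(mz <= 0))
    stop("intensities must be named by positive m/z values")
  t <- flight_time_from_mz(mz, config)
  if (is.null(window)) window <- c(0, 1.05 * max(t))
  keep <- t >= window[1] & t <= window[2]
  loss <- sum(intensities[!keep])
  edges <- seq(window[1], window[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(t[keep], edges, rightmost.closed = TRUE),
                   1L), n_bins)
  acc <- tapply(intensities[keep], bin, sum)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  idx <- as.integer(names(acc))
  spec <- data.frame(time_s = centers[idx], intensity = as.numeric(acc))
  spec <- spec[order(spec$time_s), , drop = FALSE]
  rownames(spec) <- NULL
  list(spectrum = spec, loss = loss)
}

#' Extract one fragment channel's transient from a cube
#'
#' @param cube A `transient_cube`.
#' @param fragment_mz Channel m/z to look up, Th.
#' @param tolerance Matching half-width, Th; channels within the tolerance
#'   are summed elementwise.
#' @param kind Restrict the lookup to `"fragment"` or `"precursor"`
#'   channels, or `"any"` (default).
#' @return Object of class `channel_transient`: `intensity` (length
#'   n_scans), `scan_axis` (s), matched `channel_mz`, and the cube variant.
#' @export
extract_channel_transient <- function(cube, fragment_mz, tolerance = 0,
                                      kind = c("any", "fragment",
                                               "precursor")) {
  stopifnot(inherits(cube, "transient_cube"))
  kind <- match.arg(kind)
  sel <- abs(cube$channels$channel_mz - fragment_mz) <= tolerance
  if (kind != "any") sel <- sel & cube$channels$kind == kind
  if (!any(sel)) {
    pool <- if (kind == "any") cube$channels$channel_mz
            else cube$channels$channel_mz[cube$channels$kind == kind]
    nearest <- pool[which.min(abs(pool - fragment_mz))]
    stop(sprintf("no channel within %g Th of %g Th (nearest: %g Th)",
                 tolerance, fragment_mz, nearest))
  }
  y <- if (sum(sel) == 1L) cube$intensity[, sel]
       else rowSums(cube$intensity[, sel, drop = FALSE])
  structure(list(intensity = as.numeric(y),
                 scan_axis = cube$scan_axis,
                 channel_mz = cube$channels$channel_mz[sel],
                 variant = cube$variant),
            class = "channel_transient")
}

#' @export
print.transient_cube <- function(x, ...) {
  cat("<transient_cube>", x$variant, "|", nrow(x$intensity), "scans x",
      ncol(x$intensity), "channels | mode", x$metadata$mode, "\n")
  invisible(x)
}
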