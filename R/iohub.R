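#' Generate a reproducible synthetic precursor mixture
#'
#' Draws a seeded mixture of precursors whose modulation frequencies,
#' under the active configuration, are pairwise separated by at least
#' `min_frequency_separation` peak widths (FWHM = 1.2067 / n_scans
#' cycles/scan for the unapodized magnitude spectrum) and sit below the
#' Nyquist limit. Fragments are drawn uniformly in (50 Th, precursor m/z);
#' branching ratios are uniform draws normalized to sum to 0.8 (leaving
#' 20% of fragmentation events in unmonitored channels); abundances are
#' uniform in \[0.5, 1\].
#'
#' @param seed Integer seed; the same seed reproduces the same mixture.
#' @param n_precursors Number of precursors (0 gives an empty list).
#' @param mz_range Precursor m/z range, Th.
#' @param fragments_per_precursor Integer range `c(min, max)` of fragment
#'   channels per precursor.
#' @param min_frequency_separation Minimum pairwise separation of the
#'   precursors' modulation frequencies, in FWHM units.
#' @param config A [tof_config()] or [sector_config()] defining the active
#'   variant.
#' @param pattern The active [fragmentation_pattern()].
#' @param schedule A [scan_schedule()] (TOF variant only; the sector
#'   schedule lives on its config).
#' @param max_attempts Rejection-sampling budget before giving up.
#' @return List of [precursor_species()].
#' @export
#' @examples
#' cfg <- tof_config()
#' mix <- generate_mixture(1, 5, config = cfg,
#'                         pattern = fragmentation_pattern(),
#'                         schedule = scan_schedule(config = cfg))
#' length(mix)
generate_mixture <- function(seed, n_precursors, mz_range = c(500, 2500),
                             fragments_per_precursor = c(3L, 6L),
                             min_frequency_separation = 3,
                             config, pattern, schedule = NULL,
                             max_attempts = 1e5) {
  stopifnot(mz_range[1] > 0, mz_range[2] > mz_range[1])
  if (n_precursors == 0) return(list())
  freq_of <- function(mz) {
    if (inherits(config, "tof_config")) {
      if (is.null(schedule)) stop("TOF mixtures need a schedule")
      modulation_frequency_tof(pattern, mz, 1L, config$v_kick) *
        schedule$delay_increment
    } else {
      deflection_state(mz, 1L, config, config$pulse_step)$d /
        pattern$fringe_spacing
    }
  }
  n_scans <- if (inherits(config, "tof_config")) schedule$n_scans
             else config$n_runs
  fwhm <- 1.2067 / n_scans
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  set.seed(seed)
  mzs <- numeric(0)
  freqs <- numeric(0)
  attempts <- 0
  while (length(mzs) < n_precursors) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("could not satisfy the frequency-separation constraint; ",
           "widen the mass range or lower the separation")
    mz <- stats::runif(1, mz_range[1], mz_range[2])
    f <- freq_of(mz)
    if (f > 0.5) next
    if (length(freqs) > 0 &&
        min(abs(freqs - f)) < min_frequency_separation * fwhm) next
    mzs <- c(mzs, mz)
    freqs <- c(freqs, f)
  }
  lapply(mzs, function(mz) {
    nf <- sample(fragments_per_precursor[1]:fragments_per_precursor[2], 1)
    fmz <- sort(stats::runif(nf, 50, mz * 0.999))
    br <- stats::runif(nf)
    br <- br / sum(br) * 0.8
    precursor_species(mz, abundance = stats::runif(1, 0.5, 1),
                      fragments = data.frame(fragment_mz = fmz,
                                             branching_ratio = br))
  })
}

# full-precision numeric formatting for lossless CSV round trips
.fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a transient cube as wide CSV
#'
#' The CSV holds the scan axis in the first column (`scan_axis_s`) and one
#' column per channel, named `<kind>_<m/z>`. Channel table, variant and
#' scalar metadata (mode, seed, loss tally, config hash) travel in a JSON
#' sidecar at `<path>.json`. Intensities survive the round trip to better
#' than 1e-12 relative.
#'
#' @param cube A `transient_cube`.
#' @param path Output CSV path.
#' @return `write_cube_csv` returns `path` invisibly; `read_cube_csv`
#'   returns a `transient_cube` (without the event log or full config
#'   objects, which are run-time artifacts).
#' @export
write_cube_csv <- function(cube, path) {
  stopifnot(inherits(cube, "transient_cube"))
  m <- cube$intensity
  colnames(m) <- paste0(substr(cube$channels$kind, 1, 4), "_",
                        .fmt_num(cube$channels$channel_mz))
  df <- data.frame(scan_axis_s = .fmt_num(cube$scan_axis),
                   apply(m, 2, .fmt_num), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(variant = cube$variant,
               channel_mz = cube$channels$channel_mz,
               channel_kind = cube$channels$kind,
               mode = cube$metadata$mode,
               seed = cube$metadata$seed,
               loss_tally = cube$metadata$loss_tally,
               overlapping_channels = cube$metadata$overlapping_channels,
               config_hash = config_hash(cube$metadata$config))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cube_csv
#' @export
read_cube_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0 || names(df)[1] != "scan_axis_s")
    stop(sprintf("parse error in '%s': expected a scan_axis_s first column",
                 path))
  if (any(!vapply(df, is.numeric, logical(1))))
    stop(sprintf("parse error in '%s': non-numeric cube values", path))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else NULL
  channels <- if (!is.null(meta))
    data.frame(channel_mz = as.numeric(meta$channel_mz),
               kind = as.character(meta$channel_kind))
  else {
    nm <- names(df)[-1]
    data.frame(channel_mz = as.numeric(sub("^[a-z]+_", "", nm)),
               kind = ifelse(grepl("^prec", nm), "precursor", "fragment"))
  }
  if (nrow(channels) != ncol(df) - 1L)
    stop(sprintf("parse error in '%s': %d channels in metadata, %d columns",
                 path, nrow(channels), ncol(df) - 1L))
  structure(list(intensity = as.matrix(df[, -1, drop = FALSE]),
                 scan_axis = df$scan_axis_s,
                 channels = channels,
                 variant = if (!is.null(meta)) meta$variant else NA,
                 event_log = NULL,
                 metadata = list(mode = meta$mode, seed = meta$seed,
                                 loss_tally = meta$loss_tally,
                                 overlapping_channels =
                                   meta$overlapping_channels,
                                 config_hash = meta$config_hash)),
            class = "transient_cube")
}

#' Write the per-scan event log to CSV
#'
#' Columns: `scan_index, ion_id, precursor_mz, lateral_position_m,
#' fragmentation_intensity` -- one row per precursor per scan line.
#'
#' @param cube A `transient_cube` carrying an event log.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(cube, path) {
  stopifnot(inherits(cube, "transient_cube"))
  if (is.null(cube$event_log))
    stop("cube was run with event_log = FALSE")
  utils::write.csv(cube$event_log, path, row.names = FALSE)
  invisible(path)
}

#' Write a peak list to CSV
#'
#' @param peaks A [pick_peaks()] result.
#' @param path Output CSV path.
#' @param channel_mz Optional channel m/z recorded alongside each peak.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path, channel_mz = NA_real_) {
  df <- cbind(channel_mz = channel_mz, as.data.frame(peaks))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a 2D map as sparse triplet CSV
#'
#' @param map A [assemble_2d()] result.
#' @param path CSV path with columns
#'   `precursor_mz, fragment_mz, intensity`.
#' @return `write_spectrum2d` returns `path` invisibly; `read_spectrum2d`
#'   returns a `spectrum2d` data frame.
#' @export
write_spectrum2d <- function(map, path) {
  stopifnot(inherits(map, "spectrum2d"))
  df <- data.frame(precursor_mz = .fmt_num(map$precursor_mz),
                   fragment_mz = .fmt_num(map$fragment_mz),
                   intensity = .fmt_num(map$intensity))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum2d
#' @export
read_spectrum2d <- function(path) {
  df <- utils::read.csv(path)
  need <- c("precursor_mz", "fragment_mz", "intensity")
  if (!all(need %in% names(df)))
    stop(sprintf("parse error in '%s': expected columns %s", path,
                 paste(need, collapse = ", ")))
  class(df) <- c("spectrum2d", "data.frame")
  df
}

#' Parse a quantity string with an explicit unit
#'
#' Configuration files state every physical quantity with its unit
#' ("7 V", "1 us", "0.2 mm"); only a strict whitelist of units is
#' accepted, and the value is converted to SI (V, s, m) or left as-is for
#' Th and dimensionless values.
#'
#' @param x A string like `"7 V"`, or a bare number (returned unchanged).
#' @return Numeric value in SI units.
#' @export
#' @examples
#' parse_quantity("0.2 mm")  # 2e-4
#' parse_quantity("1 us")    # 1e-6
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  stopifnot(is.character(x), length(x) == 1)
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([A-Za-z]*)\\s*$", x))[[1]]
  if (length(m) == 0 || m[2] == "")
    stop(sprintf("cannot parse quantity '%s'", x))
  val <- as.numeric(m[2])
  if (is.na(val)) stop(sprintf("cannot parse quantity '%s'", x))
  unit <- m[3]
  scale <- c(V = 1, mV = 1e-3, kV = 1e3,
             s = 1, ms = 1e-3, us = 1e-6, ns = 1e-9,
             m = 1, mm = 1e-3, um = 1e-6, nm = 1e-9,
             Th = 1)
  if (unit == "") return(val)
  if (!unit %in% names(scale))
    stop(sprintf("unknown unit '%s' in '%s' (allowed: %s)", unit, x,
                 paste(names(scale), collapse = ", ")))
  val * unname(scale[unit])
}

#' Hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; recorded in every output so a
#' result can be traced to the exact configuration that produced it.
#'
#' @param config Any serializable configuration object (or `NULL`).
#' @return Character hash, or `NA` for `NULL` input.
#' @export
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(rapply(config, unclass, how = "replace")),
                              auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Read a YAML run configuration
#'
#' The YAML file describes one simulation run: `variant` (tof | sector),
#' an `instrument` block, a `pattern` block, a `schedule` block (TOF), a
#' `mixture` block (inline table or generator parameters), `mode` and
#' `seed`. Every physical quantity is a string with an explicit unit (see
#' [parse_quantity()]).
#'
#' @param path YAML file path.
#' @return A `run_config` list with constructed configuration objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$variant) || !y$variant %in% c("tof", "sector"))
    stop("config must set variant: tof or sector")
  q <- function(block, name, default = NULL) {
    v <- block[[name]]
    if (is.null(v)) default else parse_quantity(v)
  }
  inst <- y$instrument
  config <- if (y$variant == "tof") {
    tof_config(v_kick = q(inst, "v_kick", 7),
               v_repeller = q(inst, "v_repeller", 1000),
               v_extractor = q(inst, "v_extractor", 905),
               v_lens = q(inst, "v_lens", 914),
               flight_length = q(inst, "flight_length", 1),
               zone_start = q(inst, "zone_start", 5e-3),
               zone_length = q(inst, "zone_length", 36.2e-3))
  } else {
    sector_config(deflection_potential = q(inst, "deflection_potential", 3),
                  gap = q(inst, "gap", 0.01),
                  pulse_step = q(inst, "pulse_step", 1e-6),
                  n_runs = q(inst, "n_runs", 2L^13L),
                  entry_potential = q(inst, "entry_potential", 1000),
                  entry_angle = q(inst, "entry_angle", 0),
                  drift_after = q(inst, "drift_after", 0.025))
  }
  pattern <- if (is.null(y$pattern) && y$variant == "sector") {
    sector_default_pattern(config)
  } else {
    pb <- y$pattern
    fragmentation_pattern(
      kind = if (is.null(pb$kind)) "dual_slit" else pb$kind,
      fringe_spacing = q(pb, "fringe_spacing",
                         if (y$variant == "sector")
                           sector_default_fringe_spacing(config) else 0.2e-3),
      zone_length = q(pb, "zone_length",
                      if (y$variant == "tof") config$zone_length
                      else sector_default_fringe_spacing(config) * 2175),
      phase_offset = q(pb, "phase_offset", 0))
  }
  schedule <- if (y$variant == "tof") {
    sb <- y$schedule
    scan_schedule(n_scans = if (is.null(sb$n_scans)) 2L^15L
                            else as.integer(sb$n_scans),
                  delay_increment = q(sb, "delay_increment"),
                  initial_delay = q(sb, "initial_delay"),
                  config = config)
  } else NULL
  mode <- if (is.null(y$mode)) "deterministic" else y$mode
  if (mode == "stochastic" && is.null(y$seed))
    stop("stochastic mode requires a seed in the config")
  mixture <- if (!is.null(y$mixture$table)) {
    lapply(y$mixture$table, function(row) {
      fr <- if (is.null(row$fragments))
        data.frame(fragment_mz = numeric(), branching_ratio = numeric())
      else do.call(rbind, lapply(row$fragments, function(f)
        data.frame(fragment_mz = parse_quantity(f$fragment_mz),
                   branching_ratio = f$branching_ratio)))
      precursor_species(parse_quantity(row$mz),
                        charge = if (is.null(row$charge)) 1L else row$charge,
                        abundance = if (is.null(row$abundance)) 1
                                    else row$abundance,
                        fragments = fr)
    })
  } else if (!is.null(y$mixture$generator)) {
    g <- y$mixture$generator
    generate_mixture(seed = g$seed, n_precursors = g$n_precursors,
                     mz_range = c(parse_quantity(g$mz_min),
                                  parse_quantity(g$mz_max)),
                     fragments_per_precursor =
                       c(g$fragments_min, g$fragments_max),
                     min_frequency_separation =
                       if (is.null(g$min_frequency_separation)) 3
                       else g$min_frequency_separation,
                     config = config, pattern = pattern,
                     schedule = schedule)
  } else stop("config must provide mixture: table or mixture: generator")
  structure(list(variant = y$variant, config = config, pattern = pattern,
                 schedule = schedule, mixture = mixture, mode = mode,
                 seed = y$seed, n_ions = if (is.null(y$n_ions)) 1000L
                                         else as.integer(y$n_ions)),
            class = "run_config")
}

#' Execute a run configuration
#'
#' @param rc A [read_run_config()] result (or a path to a YAML file).
#' @return A `transient_cube`.
#' @export
run_from_config <- function(rc) {
  if (is.character(rc)) rc <- read_run_config(rc)
  stopifnot(inherits(rc, "run_config"))
  if (rc$variant == "tof")
    run_tof_scan_sequence(rc$mixture, rc$config, rc$pattern, rc$schedule,
                          mode = rc$mode, seed = rc$seed,
                          n_ions = rc$n_ions)
  else
    run_sector_scan_sequence(rc$mixture, rc$config, rc$pattern,
                             mode = rc$mode, seed = rc$seed,
                             n_ions = rc$n_ions)
}
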