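#' Reproduction experiments: precursor-dimension resolving power
#'
#' `reproduce_rp_tof_1000()` runs the pinned TOF experiment end-to-end: a
#' single precursor (default 1000 Th) with the 7 V side kick, 1000 V
#' repeller, dual-slit cos^2 pattern (0.2 mm fringes over the 36.2 mm
#' zone) and 2^15 scan lines whose delay increment splits the zone evenly,
#' then Fourier-transforms the precursor's channel (magnitude mode, no
#' window, zero-fill x2), picks the dominant peak, and measures the FWHM
#' resolving power in the m/z domain (half the frequency-domain value).
#'
#' `reproduce_rp_sector()` does the same for the stepped-pulse
#' electric-sector variant: 3 V across a 10 mm gap, 1 us pulse steps,
#' 2^13 runs, the ions entering at the 1000 V acceleration speed, with the
#' fringe spacing pinned so the 1000 Th reference ion sweeps 2172 fringe
#' periods over the schedule.
#'
#' @param mz Precursor m/z to measure, Th.
#' @param n_scans,n_runs Acquisition length.
#' @param config,pattern,schedule Optional overrides of the pinned
#'   defaults.
#' @return List with `rp_mz`, `rp_f`, `centroid` (cycles/scan), `fwhm`
#'   (cycles/scan), `expected_frequency` (cycles/scan), `n_scans`, and
#'   `variant`.
#' @export
#' @examples
#' \donttest{
#' res <- reproduce_rp_tof_1000(n_scans = 2^12)
#' res$rp_mz
#' }
reproduce_rp_tof_1000 <- function(mz = 1000, n_scans = 2L^15L,
                                  config = tof_config(),
                                  pattern = fragmentation_pattern(
                                    zone_length = config$zone_length),
                                  schedule = scan_schedule(
                                    n_scans, config = config)) {
  sp <- precursor_species(mz, fragments = data.frame(
    fragment_mz = round(mz * 0.65), branching_ratio = 0.8))
  cube <- run_tof_scan_sequence(sp, config, pattern, schedule,
                                mode = "deterministic", event_log = FALSE)
  .measure_rp(cube, mz, schedule$n_scans,
              expected = modulation_frequency_tof(pattern, mz, 1L,
                                                  config$v_kick) *
                schedule$delay_increment)
}

#' @rdname reproduce_rp_tof_1000
#' @export
reproduce_rp_sector <- function(mz = 1000, n_runs = 2L^13L,
                                config = sector_config(n_runs = n_runs),
                                pattern = sector_default_pattern(config)) {
  sp <- precursor_species(mz, fragments = data.frame(
    fragment_mz = round(mz * 0.65), branching_ratio = 0.8))
  cube <- run_sector_scan_sequence(sp, config, pattern,
                                   mode = "deterministic",
                                   event_log = FALSE)
  .measure_rp(cube, mz, config$n_runs,
              expected = deflection_state(mz, 1L, config,
                                          config$pulse_step)$d /
                pattern$fringe_spacing)
}

.measure_rp <- function(cube, mz, n_scans, expected) {
  tr <- extract_channel_transient(cube, mz, tolerance = 1e-9,
                                  kind = "precursor")
  sp <- fft_magnitude(tr, window = "none", zero_fill = 2L)
  pk <- pick_peaks(sp, min_relative_height = 0.2)
  if (nrow(pk) == 0) stop("no peak found in the precursor channel")
  rp <- resolving_power(pk[1, ])
  list(rp_mz = unname(rp["rp_mz"]), rp_f = unname(rp["rp_f"]),
       centroid = pk$centroid[1], fwhm = pk$fwhm[1],
       expected_frequency = expected, n_scans = n_scans,
       variant = cube$variant)
}

#' Named reproduction experiments for the command line
#'
#' Runs one of the packaged end-to-end experiments and returns its
#' measured quantities: `"rp-tof-1000"` (TOF variant, 1000 Th, 2^15
#' scans), `"rp-sector-1000"` and `"rp-sector-2000"` (sector variant,
#' 2^13 runs).
#'
#' @param name Experiment name.
#' @return The corresponding `reproduce_rp_*()` result.
#' @export
reproduce_experiment <- function(name = c("rp-tof-1000", "rp-sector-1000",
                                          "rp-sector-2000")) {
  name <- match.arg(name)
  switch(name,
         "rp-tof-1000" = reproduce_rp_tof_1000(),
         "rp-sector-1000" = reproduce_rp_sector(1000),
         "rp-sector-2000" = reproduce_rp_sector(2000))
}
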