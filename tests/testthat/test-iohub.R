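cfg <- tof_config()
pat <- fragmentation_pattern(zone_length = cfg$zone_length)
sched <- scan_schedule(4096, config = cfg)

test_that("mixture generation is seeded and honours its constraints", {
  m1 <- generate_mixture(5, 8, config = cfg, pattern = pat,
                         schedule = sched)
  m2 <- generate_mixture(5, 8, config = cfg, pattern = pat,
                         schedule = sched)
  expect_identical(m1, m2)
  expect_identical(generate_mixture(5, 0, config = cfg, pattern = pat,
                                    schedule = sched), list())
  # repeated draws: frequencies always below Nyquist and pairwise
  # separated by >= 3 FWHM; fragments inside (50, precursor)
  fwhm <- 1.2067 / sched$n_scans
  for (seed in 1:200) {
    mix <- generate_mixture(seed, 5, config = cfg, pattern = pat,
                            schedule = sched)
    f <- vapply(mix, function(p)
      modulation_frequency_tof(pat, p$mz, 1, cfg$v_kick) *
        sched$delay_increment, numeric(1))
    expect_true(all(f <= 0.5))
    expect_gte(min(dist(f)), 3 * fwhm)
    for (p in mix) {
      expect_true(all(p$fragments$fragment_mz > 50 &
                        p$fragments$fragment_mz < p$mz))
      expect_lte(sum(p$fragments$branching_ratio), 1)
    }
  }
  expect_error(generate_mixture(1, 50, mz_range = c(1000, 1001),
                                config = cfg, pattern = pat,
                                schedule = sched, max_attempts = 200),
               "separation")
})

test_that("transient cubes round-trip through wide CSV to 1e-12 relative", {
  mix <- list(make_species(800), make_species(1500))
  cube <- run_tof_scan_sequence(mix, cfg, pat,
                                scan_schedule(512, config = cfg))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cube_csv(cube, path)
  back <- read_cube_csv(path)
  expect_equal(unname(back$intensity), unname(cube$intensity),
               tolerance = 1e-12)
  expect_equal(back$scan_axis, cube$scan_axis, tolerance = 1e-12)
  expect_identical(back$variant, "tof")
  expect_equal(back$channels$channel_mz, cube$channels$channel_mz)
  expect_identical(back$channels$kind, cube$channels$kind)
  # truncated file -> parse error, not silent corruption
  lines <- readLines(path)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1], "1e-6,0.5,oops"), bad)
  expect_error(read_cube_csv(bad), "parse error")
})

test_that("event logs, peak lists and 2D maps write and read back", {
  cube <- run_tof_scan_sequence(make_species(1000), cfg, pat,
                                scan_schedule(512, config = cfg))
  lp <- withr::local_tempfile(fileext = ".csv")
  write_event_log(cube, lp)
  log <- read.csv(lp)
  expect_identical(names(log),
                   c("scan_index", "ion_id", "precursor_mz",
                     "lateral_position_m", "fragmentation_intensity"))
  expect_identical(nrow(log), 512L)

  sched4 <- scan_schedule(4096, config = cfg)
  truth <- tof_calibration_from_config(cfg, pat, sched4)
  cube4 <- run_tof_scan_sequence(make_species(1000), cfg, pat, sched4,
                                 event_log = FALSE)
  map <- assemble_2d(cube4, truth)
  mp <- withr::local_tempfile(fileext = ".csv")
  write_spectrum2d(map, mp)
  back <- read_spectrum2d(mp)
  expect_equal(back$precursor_mz, map$precursor_mz, tolerance = 1e-12)
  expect_equal(back$intensity, map$intensity, tolerance = 1e-12)

  pk <- pick_peaks(fft_magnitude(
    extract_channel_transient(cube4, 650)), 0.2)
  pp <- withr::local_tempfile(fileext = ".csv")
  write_peak_list(pk, pp, channel_mz = 650)
  expect_equal(read.csv(pp)$channel_mz[1], 650)
})

test_that("quantity strings parse on a strict unit whitelist", {
  expect_identical(parse_quantity("7 V"), 7)
  expect_identical(parse_quantity("1 us"), 1e-6)
  expect_identical(parse_quantity("0.2 mm"), 2e-4)
  expect_identical(parse_quantity("3 kV"), 3000)
  expect_identical(parse_quantity(42), 42)
  expect_identical(parse_quantity("1000 Th"), 1000)
  expect_error(parse_quantity("9 mT"), "unknown unit")
  expect_error(parse_quantity("fast"), "cannot parse")
})

test_that("YAML run configs execute end-to-end and hash deterministically", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "variant: tof",
    "instrument:",
    "  v_kick: 7 V",
    "  zone_start: 5 mm",
    "  zone_length: 36.2 mm",
    "pattern:",
    "  fringe_spacing: 0.2 mm",
    "  zone_length: 36.2 mm",
    "schedule:",
    "  n_scans: 512",
    "mixture:",
    "  table:",
    "    - mz: 1000 Th",
    "      fragments:",
    "        - {fragment_mz: 650 Th, branching_ratio: 0.5}"), yml)
  rc <- read_run_config(yml)
  expect_identical(rc$variant, "tof")
  expect_equal(rc$pattern$fringe_spacing, 2e-4)
  cube <- run_from_config(rc)
  expect_identical(nrow(cube$intensity), 512L)
  expect_identical(config_hash(rc$config), config_hash(rc$config))
  expect_error(read_run_config(withr::local_tempfile()), "not found")
})

test_that("the CLI runs simulate/process/map2d and rejects bad usage", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "run.yaml")
  writeLines(c(
    "variant: tof",
    "schedule: {n_scans: 4096}",
    "mixture:",
    "  generator: {seed: 3, n_precursors: 3, mz_min: 500 Th,",
    "              mz_max: 2500 Th, fragments_min: 2, fragments_max: 3}"),
    yml)
  cube_csv <- file.path(dir, "cube.csv")
  expect_identical(cli_main(c("simulate-tof", "--config", yml,
                              "--out", cube_csv)), 0L)
  expect_true(file.exists(cube_csv))
  peaks_csv <- file.path(dir, "peaks.csv")
  expect_identical(cli_main(c("process", "--cube", cube_csv,
                              "--out", peaks_csv)), 0L)
  pk <- read.csv(peaks_csv)
  expect_gt(nrow(pk), 0)
  # calibrate from the precursor-channel peaks, then map
  prec <- pk[pk$channel_kind == "precursor", ]
  prec_best <- do.call(rbind, lapply(split(prec, prec$channel_mz),
                                     function(d) d[which.max(d$height), ]))
  cal_csv <- file.path(dir, "cal.csv")
  write.csv(data.frame(centroid = prec_best$centroid,
                       known_mz = prec_best$channel_mz), cal_csv,
            row.names = FALSE)
  model_json <- file.path(dir, "model.json")
  expect_identical(cli_main(c("calibrate", "--peaks", cal_csv,
                              "--out", model_json)), 0L)
  map_csv <- file.path(dir, "map.csv")
  expect_identical(cli_main(c("map2d", "--cube", cube_csv,
                              "--model", model_json,
                              "--out", map_csv)), 0L)
  expect_gt(nrow(read_spectrum2d(map_csv)), 0)
  # usage errors exit 2
  expect_identical(suppressMessages(cli_main(character())), 2L)
  expect_identical(suppressMessages(
    cli_main(c("simulate-tof", "--out", "x.csv"))), 2L)
  expect_identical(suppressMessages(
    cli_main(c("simulate-tof", "--config", "missing.yaml",
               "--out", "x.csv"))), 2L)
  expect_identical(suppressMessages(cli_main("frobnicate")), 2L)
})
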