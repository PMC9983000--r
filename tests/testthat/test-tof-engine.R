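cfg <- tof_config()
pat <- fragmentation_pattern(zone_length = cfg$zone_length)
sched_small <- scan_schedule(2048, config = cfg)

test_that("a uniform light field gives flat transients", {
  flat <- fragmentation_pattern("custom_tabulated",
                                zone_length = cfg$zone_length,
                                table = data.frame(
                                  position_m = c(0, cfg$zone_length),
                                  relative_intensity = c(1, 1)))
  cube <- run_tof_scan_sequence(make_species(1000), cfg, flat, sched_small)
  for (j in seq_len(ncol(cube$intensity)))
    expect_lt(diff(range(cube$intensity[, j])), 1e-12)
})

test_that("identical precursors give proportional transients at the abundance ratio", {
  frags <- data.frame(fragment_mz = c(400, 650),
                      branching_ratio = c(0.3, 0.5))
  a <- precursor_species(1000, abundance = 1, fragments = frags)
  cube_a <- run_tof_scan_sequence(a, cfg, pat, sched_small)
  cube_ab <- run_tof_scan_sequence(list(a,
      precursor_species(1000, abundance = 0.25, fragments = frags)),
      cfg, pat, sched_small)
  ta <- extract_channel_transient(cube_a, 650)$intensity
  tab <- extract_channel_transient(cube_ab, 650)$intensity
  expect_equal(tab, ta * 1.25, tolerance = 1e-12)
})

test_that("a single precursor's transient is the fringe law sampled per scan", {
  sp <- make_species(1000)
  cube <- run_tof_scan_sequence(sp, cfg, pat, sched_small)
  # brute-force per-scan re-evaluation with the oracle constants
  vlat <- sqrt(2 * ORA_E * cfg$v_kick / (1000 * ORA_U))
  delays <- sched_small$initial_delay +
    (0:2047) * sched_small$delay_increment
  d <- vlat * delays - cfg$zone_start
  expected <- ifelse(d >= 0 & d <= cfg$zone_length,
                     cos(pi * d / pat$fringe_spacing)^2, 0)
  tr <- extract_channel_transient(cube, 650)$intensity
  expect_equal(tr, 0.5 * expected, tolerance = 1e-9)
  # depleted precursor channel carries the complement
  prec <- extract_channel_transient(cube, 1000, kind = "precursor")
  expect_equal(prec$intensity, 1 - expected, tolerance = 1e-9)
})

test_that("the scan axis is uniform and deterministic runs are bit-reproducible", {
  sp <- make_species(1000)
  c1 <- run_tof_scan_sequence(sp, cfg, pat, sched_small)
  c2 <- run_tof_scan_sequence(sp, cfg, pat, sched_small)
  expect_identical(c1$intensity, c2$intensity)
  steps <- diff(c1$scan_axis)
  expect_true(all(steps > 0))
  expect_lt(diff(range(steps)) / mean(steps), 1e-12)
})

test_that("stochastic mode is seed-reproducible and converges to the deterministic intensity", {
  sp <- precursor_species(1000, fragments = data.frame(
    fragment_mz = 650, branching_ratio = 1))
  sch <- scan_schedule(2048, config = cfg)
  det <- run_tof_scan_sequence(sp, cfg, pat, sch)
  s1 <- run_tof_scan_sequence(sp, cfg, pat, sch, mode = "stochastic",
                              seed = 42, n_ions = 1e4, event_log = FALSE)
  s2 <- run_tof_scan_sequence(sp, cfg, pat, sch, mode = "stochastic",
                              seed = 42, n_ions = 1e4, event_log = FALSE)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- run_tof_scan_sequence(sp, cfg, pat, sch, mode = "stochastic",
                              seed = 43, n_ions = 1e4, event_log = FALSE)
  expect_false(identical(s1$intensity, s3$intensity))
  # binomial convergence: every scan within 4.5 sigma, small mean deviation
  p_det <- extract_channel_transient(det, 650)$intensity
  p_sto <- extract_channel_transient(s1, 650)$intensity
  sigma <- sqrt(pmax(p_det * (1 - p_det), 1e-12) / 1e4)
  dev <- abs(p_sto - p_det)
  expect_true(all(dev <= 4.5 * sigma + 1e-12))
  keep <- p_det >= 0.1
  expect_lt(mean(dev[keep] / p_det[keep]), 0.02)
  expect_error(run_tof_scan_sequence(sp, cfg, pat, sch,
                                     mode = "stochastic"), "seed")
})

test_that("the dominant FFT frequency matches the configured modulation frequency", {
  for (mz in c(700, 1000, 1800)) {
    cube <- run_tof_scan_sequence(make_species(mz), cfg, pat,
                                  scan_schedule(4096, config = cfg),
                                  event_log = FALSE)
    tr <- extract_channel_transient(cube, mz, kind = "precursor")
    pk <- measure_dominant_peak(tr)
    f_expect <- sqrt(2 * ORA_E * cfg$v_kick / (mz * ORA_U)) /
      pat$fringe_spacing * diff(tr$scan_axis[1:2])
    expect_lt(abs(pk$centroid - f_expect), 1 / 4096)
  }
})

test_that("detector binning conserves intensity and orders fragments by flight time", {
  res0 <- detect_fragments(numeric(0), cfg)
  expect_identical(nrow(res0$spectrum), 0L)
  expect_identical(res0$loss, 0)
  two <- c("400" = 0.4, "900" = 0.6)
  res <- detect_fragments(two, cfg)
  expect_identical(nrow(res$spectrum), 2L)
  expect_true(all(diff(res$spectrum$time_s) > 0))
  expect_equal(sum(res$spectrum$intensity), 1, tolerance = 1e-9)
  # random 50-fragment scan: conservation within the window
  set.seed(7)
  mzv <- runif(50, 100, 3000)
  iv <- runif(50)
  res50 <- detect_fragments(setNames(iv, mzv), cfg)
  expect_equal(sum(res50$spectrum$intensity) + res50$loss, sum(iv),
               tolerance = 1e-9)
  # narrow window drops slow ions into the loss tally
  resw <- detect_fragments(two, cfg,
                           window = c(0, flight_time_from_mz(500, cfg)))
  expect_equal(resw$loss, 0.6, tolerance = 1e-12)
})

test_that("channel extraction matches columns, sums within tolerance, errors otherwise", {
  sp <- precursor_species(1000, fragments = data.frame(
    fragment_mz = c(400, 402), branching_ratio = c(0.3, 0.4)))
  cube <- run_tof_scan_sequence(sp, cfg, pat, sched_small)
  j400 <- which(cube$channels$channel_mz == 400 &
                  cube$channels$kind == "fragment")
  expect_identical(extract_channel_transient(cube, 400)$intensity,
                   as.numeric(cube$intensity[, j400]))
  both <- extract_channel_transient(cube, 401, tolerance = 1.5)
  expect_equal(both$intensity,
               cube$intensity[, j400] + cube$intensity[, j400 + 1L],
               tolerance = 1e-12)
  expect_error(extract_channel_transient(cube, 500, tolerance = 0),
               "nearest")
})

test_that("the event log records every precursor at every scan", {
  mix <- list(make_species(800), make_species(1500))
  cube <- run_tof_scan_sequence(mix, cfg, pat,
                                scan_schedule(512, config = cfg))
  log <- cube$event_log
  expect_identical(nrow(log), 1024L)
  expect_setequal(unique(log$precursor_mz), c(800, 1500))
  # intensities in the log are the pattern intensities at the positions
  expect_equal(log$fragmentation_intensity,
               pattern_intensity(pat, log$lateral_position_m),
               tolerance = 1e-12)
})

test_that("overlapping fragment channels are summed and flagged", {
  a <- precursor_species(1000, fragments = data.frame(
    fragment_mz = 500, branching_ratio = 0.5))
  b <- precursor_species(2000, fragments = data.frame(
    fragment_mz = 500, branching_ratio = 0.5))
  cube <- run_tof_scan_sequence(list(a, b), cfg, pat, sched_small)
  expect_true(cube$metadata$overlapping_channels)
  expect_identical(sum(cube$channels$channel_mz == 500), 1L)
})
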