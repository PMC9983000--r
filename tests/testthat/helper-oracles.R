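# Independent oracles for the kinematics and signal-processing chain.
# Constants pinned here on purpose (not taken from the package) so the
# oracles stay an independent route.
ORA_E <- 1.602176634e-19   # C
ORA_U <- 1.66053906660e-27 # kg

# Small-step leapfrog (kick-drift-kick) integration of an ion accelerated
# from rest through a uniform-field gap at `potential` volts; returns the
# exit speed.
oracle_gap_speed <- function(mz, charge, potential, gap = 0.01,
                             n_steps = 2e4) {
  m <- mz * charge * ORA_U
  a <- charge * ORA_E * potential / gap / m
  if (a == 0) return(0)
  # total time from x = a t^2 / 2 = gap
  t_total <- sqrt(2 * gap / a)
  dt <- t_total / n_steps
  v <- 0; x <- 0
  while (x < gap) {
    v_half <- v + 0.5 * a * dt
    x <- x + v_half * dt
    v <- v_half + 0.5 * a * dt
  }
  # roll back the overshoot past the gap exit with the exact local solution
  v_exit <- sqrt(max(v^2 - 2 * a * (x - gap), 0))
  v_exit
}

# Small-step integration of the orthogonal velocity through a finite
# deflection region with the field gated on for `pulse` seconds, then a
# drift; returns exit angle and displacement relative to the undeflected
# chord after drifting `X`.
oracle_deflection <- function(mz, charge, field, pulse, v_entry,
                              theta_i = 0, X = 0.025, n_steps = 2e4) {
  m <- mz * charge * ORA_U
  a <- charge * ORA_E * field / m
  v_fwd <- v_entry * cos(theta_i)
  v_orth <- v_entry * sin(theta_i)
  dt <- pulse / n_steps
  tt <- 0
  for (i in seq_len(n_steps)) {
    v_orth <- v_orth + a * dt
    tt <- tt + dt
  }
  theta_f <- atan(v_orth / v_fwd)
  list(theta_f = theta_f,
       d = X * (tan(theta_f) - tan(theta_i)))
}

# O(N^2) direct DFT magnitude (one-sided), mean already subtracted by the
# caller if desired.
oracle_dft_magnitude <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  Mod(as.vector(W %*% x))
}

# Brute-force count of local intensity maxima of a pattern over
# [0, zone], sampling `per_fringe` points per fringe period; boundary
# maxima count.
oracle_count_maxima <- function(pattern, zone, per_fringe = 1e4) {
  n_pts <- max(1000, ceiling(zone / pattern$fringe_spacing * per_fringe))
  d <- seq(0, zone, length.out = n_pts)
  y <- pattern_intensity(pattern, d)
  padded <- c(-1, y, -1)
  sum(diff(sign(diff(padded))) == -2)
}

# FWHM of the unapodized magnitude peak of a T-second rectangular cosine,
# from dense numerical evaluation of the |sinc| line shape.
oracle_asinc_fwhm <- function(T) {
  g <- function(x) abs(sin(pi * x) / (pi * x)) - 0.5
  2 * stats::uniroot(g, c(0.4, 0.9), tol = 1e-12)$root / T
}

# Tiny helpers for building fixtures
make_species <- function(mz, frags = NULL, abundance = 1) {
  if (is.null(frags))
    frags <- data.frame(fragment_mz = round(mz * c(0.4, 0.65)),
                        branching_ratio = c(0.3, 0.5))
  precursor_species(mz, abundance = abundance, fragments = frags)
}

measure_dominant_peak <- function(transient, ...) {
  sp <- fft_magnitude(transient, ...)
  pk <- pick_peaks(sp, 0.2)
  pk[1, ]
}
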