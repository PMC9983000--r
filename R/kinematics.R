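#' TOF instrument configuration
#'
#' Geometry and voltages of the idealized side-kick TOF instrument. The ion
#' source accelerates ions axially through `v_repeller` volts; a split lens
#' applies a low-voltage lateral kick (`v_kick`) that disperses ions by m/z
#' across the fragmentation zone. Extractor and lens voltages are recorded
#' for provenance but do not enter the idealized uniform-field kinematics,
#' where acceleration regions are collapsed to their net potential.
#'
#' @param v_kick Side-kick potential, V. Must be small relative to
#'   `v_repeller` so the kicked trajectory stays nearly parallel to the
#'   detector.
#' @param v_repeller Repeller (axial acceleration) potential, V.
#' @param v_extractor,v_lens Extractor and lens potentials, V (provenance
#'   only).
#' @param flight_length Field-free flight-tube length, m.
#' @param zone_start Distance from the kick exit to the first point of the
#'   fragmentation zone, m.
#' @param zone_length Extent of the fragmentation zone along the kick axis, m.
#' @return Object of class `tof_config`.
#' @export
#' @examples
#' cfg <- tof_config()
#' cfg$v_kick
tof_config <- function(v_kick = 7, v_repeller = 1000, v_extractor = 905,
                       v_lens = 914, flight_length = 1,
                       zone_start = 5e-3, zone_length = 36.2e-3) {
  stopifnot(v_kick > 0, v_repeller > 0, flight_length > 0,
            zone_start > 0, zone_length > 0)
  if (v_kick >= 0.1 * v_repeller)
    warning("v_kick is not small relative to v_repeller; ",
            "lateral/axial independence is a poor approximation")
  structure(list(v_kick = v_kick, v_repeller = v_repeller,
                 v_extractor = v_extractor, v_lens = v_lens,
                 flight_length = flight_length,
                 zone_start = zone_start, zone_length = zone_length),
            class = "tof_config")
}

#' @export
print.tof_config <- function(x, ...) {
  cat("<tof_config> kick", x$v_kick, "V | repeller", x$v_repeller,
      "V | L", x$flight_length, "m | zone", x$zone_start * 1e3, "+",
      x$zone_length * 1e3, "mm\n")
  invisible(x)
}

#' Speed acquired by an ion falling through a potential
#'
#' An ion of charge z falling through V volts gains kinetic energy
#' K = z e V, so its speed is sqrt(2 z e V / m) with m = (m/z) z u. Every ion
#' of the same charge acquires the same kinetic energy, which is what makes
#' the spatial dispersion purely an m/z effect.
#'
#' @param mz Mass-to-charge ratio, Th. Must be positive.
#' @param charge Charge state, positive integer (default 1).
#' @param potential Accelerating potential, V. Must be non-negative.
#' @return Speed in m/s. Vectorized over `mz` and `potential`.
#' @export
#' @examples
#' speed_from_potential(1000, 1, 1000)  # ~1.389e4 m/s
speed_from_potential <- function(mz, charge = 1L, potential) {
  if (any(mz <= 0)) stop("mz must be positive")
  if (any(potential < 0)) stop("potential must be non-negative")
  if (any(charge < 1)) stop("charge must be a positive integer")
  sqrt(2 * charge * .e_charge * potential / (mz * charge * .u_mass))
}

#' Ion state after the side kick
#'
#' Builds the kinematic state of a precursor at the kick exit: lateral speed
#' from the impulsive kick potential, axial speed from the repeller
#' potential, and total kinetic energy. Lateral and axial motions are treated
#' as independent.
#'
#' @param species A [precursor_species()].
#' @param config A [tof_config()].
#' @return Object of class `ion_state` with fields `species`,
#'   `lateral_speed`, `axial_speed`, `lateral_position` (0 at the kick exit,
#'   i.e. `zone_start` metres before the zone), `kinetic_energy` (J) and
#'   `zone_start`.
#' @export
ion_state <- function(species, config) {
  stopifnot(inherits(species, "precursor_species"),
            inherits(config, "tof_config"))
  vl <- speed_from_potential(species$mz, species$charge, config$v_kick)
  va <- speed_from_potential(species$mz, species$charge, config$v_repeller)
  m  <- species$mz * species$charge * .u_mass
  structure(list(species = species,
                 lateral_speed = vl,
                 axial_speed = va,
                 lateral_position = 0,
                 kinetic_energy = 0.5 * m * (vl^2 + va^2),
                 zone_start = config$zone_start),
            class = "ion_state")
}

#' Lateral position across the fragmentation zone after a delay
#'
#' After the impulsive kick the lateral motion is field-free drift at
#' constant speed, so position is linear in the delay. The coordinate is
#' measured from the start of the fragmentation zone: negative values mean
#' the ion has not yet reached the zone.
#'
#' @param state An [ion_state()].
#' @param delay Post-kick delay, s (non-negative; vectorized).
#' @return Position d in m relative to the zone entrance, with attribute
#'   `in_zone` (logical) when the state carries a zone extent.
#' @export
#' @examples
#' sp <- precursor_species(1000)
#' st <- ion_state(sp, tof_config())
#' lateral_position_at_delay(st, 10e-6)  # ~6.62 mm into the zone
lateral_position_at_delay <- function(state, delay) {
  stopifnot(inherits(state, "ion_state"))
  if (any(delay < 0)) stop("delay must be non-negative")
  d <- state$lateral_speed * delay - state$zone_start
  attr(d, "in_zone") <- d >= 0
  d
}

#' Flight time of an ion down the TOF tube
#'
#' Field-free flight after axial acceleration: t = L / v with
#' v = sqrt(2 z e V / m), so t grows with sqrt(m/z) and heavier ions arrive
#' later.
#'
#' @param mz Mass-to-charge ratio, Th (positive; vectorized).
#' @param config A [tof_config()].
#' @param charge Charge state (default 1).
#' @return Flight time in s.
#' @export
flight_time_from_mz <- function(mz, config, charge = 1L) {
  stopifnot(inherits(config, "tof_config"))
  if (any(mz <= 0)) stop("mz must be positive")
  config$flight_length / speed_from_potential(mz, charge, config$v_repeller)
}

#' m/z from a measured TOF arrival time
#'
#' Inverse of [flight_time_from_mz()]: m/z = 2 e V t^2 / (u L^2) per charge.
#'
#' @param t Flight time, s (positive; vectorized).
#' @param config A [tof_config()].
#' @param charge Charge state (default 1).
#' @return m/z in Th.
#' @export
#' @examples
#' cfg <- tof_config()
#' mz_from_flight_time(flight_time_from_mz(1000, cfg), cfg)  # 1000
mz_from_flight_time <- function(t, config, charge = 1L) {
  stopifnot(inherits(config, "tof_config"))
  if (any(t <= 0)) stop("flight time must be positive")
  2 * .e_charge * config$v_repeller * t^2 /
    (config$flight_length^2 * .u_mass)
}
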