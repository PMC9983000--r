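---
title: "Trap-free 2DMS: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trap-free 2DMS: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatial2dms)
```

## The method

Two-dimensional mass spectrometry (2DMS) records, without any precursor
preselection, which fragment belongs to which precursor. Existing
implementations need an ion trap: the precursor dimension is encoded by
resonantly modulating trapped ions. This package simulates a trap-free
alternative in which the precursor dimension is encoded *spatially*: ions
are dispersed across a fragmentation zone by their m/z-dependent speed and
photofragmented by a spatially periodic light pattern, so each precursor's
fragment intensity oscillates, over a series of scans, at a frequency set
by its m/z. A Fourier transform of each fragment channel's scan series
then correlates fragments to precursors.

Two dispersion geometries are implemented.

**TOF side-kick variant.** In the pusher region of a TOF instrument a
split lens applies a weak lateral kick (`v_kick`, default 7 V). An ion of
mass-to-charge m/z and charge z leaves with lateral speed
$v = \sqrt{2 z e V_\mathrm{kick} / (m/z \cdot z \cdot u)}$ — every ion of
the same charge gets the same kinetic energy, so the speed, and hence the
position after a delay, depends only on m/z. After a programmed delay the
ions are irradiated by a dual-slit fringe pattern,
$I(d) = \cos^2(\pi d / \Lambda)$, and fragment with probability
proportional to the local intensity. Incrementing the delay by
$\Delta t$ per scan line makes each precursor's fragmentation intensity a
sampled cosine at

$$ f \;=\; \frac{v}{\Lambda}\,\Delta t \;=\; \frac{D}{\sqrt{m/z}}
\quad\text{cycles/scan}, \qquad
D = \frac{\sqrt{2 e V_\mathrm{kick} z / u}}{\Lambda}\,\Delta t . $$

The calibration constant $D$ is shared by all masses; a phase constant
$C$ (the offset between the ions' start point and the first fringe
maximum) exists but is irrelevant in magnitude-mode processing, which is
all this package does.

**Electric-sector variant.** Ions enter at the speed set by a 1000 V
acceleration and receive an orthogonal impulse from a fixed field
($E = V/\mathrm{gap}$, default 3 V across 10 mm) gated on for a pulse
length stepped by 1 µs per run. The velocity kick
$\Delta v = eEt/(m/z \cdot u)$ is linear in the pulse length; with
tangential entry ($\theta_i = 0$) the displacement after a drift $X$ is
$d = X \tan\theta_F = X\,\Delta v / v_\mathrm{fwd}$ — *exactly* linear in
$t$, with a slope proportional to $1/\sqrt{m/z}$ because
$\Delta v \propto 1/(m/z)$ and $v_\mathrm{fwd} \propto 1/\sqrt{m/z}$. The
same $f = D/\sqrt{m/z}$ law therefore holds with the pulse length as the
scan axis. The engine monitors $\max |\tan\theta_F - \theta_F|/\theta_F$
and records it in the cube metadata, since at long pulses the exit angles
leave the small-angle regime even though the frequency law is unaffected.

Processing is identical for both variants: subtract the transient mean
(the $\cos^2$ law carries a 1/2 DC offset), optionally window, zero-fill
(default ×2), take the one-sided magnitude FFT, pick local maxima with
three-point parabolic centroids and linear half-height crossings, and
report $\mathrm{RP}_f = f_0/\mathrm{FWHM}$. Because $m \propto f^{-2}$,
the m/z-domain resolving power is exactly half the frequency-domain one.

## Pinned defaults and why

* **Kinematics** is idealized: uniform-field acceleration regions
  collapsed to their net potential, impulsive kick, field-free drift,
  lateral and axial motion independent. Constants are pinned at
  $e = 1.602176634\times10^{-19}$ C,
  $u = 1.66053906660\times10^{-27}$ kg; SI internally, Th at interfaces.
  Fringe fields, lens-stack tuning, space charge and detector response
  are out of scope; a small-step trajectory integrator exists in the test
  suite purely as an independent oracle for the closed forms.
* **TOF geometry**: 7 V kick; 1000 V repeller (extractor 905 V and lens
  914 V are recorded for provenance only); 1 m flight tube; fragmentation
  zone starting 5 mm from the kick exit. Zone length 36.2 mm and fringe
  spacing 0.2 mm give 181 fringe periods across the zone (182 maxima
  counting both ends). The fringe spacing is the one genuinely free
  optical parameter; it was fixed once so that the standard acquisition
  reproduces the intended resolving-power regime (below).
* **Schedule**: $2^{15} = 32768$ scan lines. The delay increment is set
  at initialization to split the zone evenly across the schedule:
  $\Delta t = L_\mathrm{zone}/(v_\mathrm{ref} N)$ with the 1000 Th ion as
  reference, and the initial delay is that ion's zone-entry time. The
  1000 Th ion then sweeps exactly 181 fringes, its peak sits at
  $181/32768 \approx 0.0055$ cycles/scan, and the unapodized magnitude
  FWHM of $1.2067/N$ bins yields
  $\mathrm{RP}_{m/z} = 181/(2\times1.2067) \approx 75$.
* **Sector defaults**: 3 V / 10 mm gap, 1 µs steps, $2^{13} = 8192$
  runs, 25 mm post-deflection drift, tangential entry. The fringe
  spacing is derived at initialization so the 1000 Th reference ion
  sweeps 2172 fringe periods over the full schedule
  (`sector_default_fringe_spacing()`), i.e. 0.265 cycles/run — safely
  below Nyquist — giving $\mathrm{RP}_{m/z} \approx 900$ at 1000 Th and
  $\approx 900/\sqrt{2} \approx 636$ at 2000 Th. We deliberately measure
  these on the full 8192-run acquisition: pinning the same 2172 periods
  onto a 4096-run acquisition would put the reference peak at 0.53
  cycles/run, past the Nyquist limit, where the peak aliases and the
  magnitude-mode FWHM caps $\mathrm{RP}_{m/z}$ at
  $0.5 N/(2\times1.2067) \approx 849 < 900$. The 8192-run reading is
  also the one consistent with the companion comparison the package
  reproduces: roughly an order of magnitude more resolving power than
  the TOF variant with four times fewer scans ($32768/8192 = 4$,
  $900/75 = 12$).
* **Nyquist.** A species' expected frequency is checked on every run;
  above 0.5 cycles/scan the engine warns and reports the folded apparent
  frequency (`check_nyquist()`), since an aliased peak calibrates to the
  wrong precursor mass.

## Open choices we had to make

* **Displacement convention (sector).** Whether the displacement is
  measured from the deflection center or from the undeflected path is
  ambiguous; we measure from the undeflected chord,
  $d = X(\tan\theta_F - \tan\theta_i)$, which reproduces the
  inverse-square-root scaling and makes $d = 0$ at zero pulse length.
* **Unfragmented precursors.** Whether surviving precursors reach the
  detector is not specified; the cube records, per precursor, a depleted
  precursor channel carrying $\mathrm{abundance}\times(1 - I(d))$
  alongside the fragment channels, so both conventions are available.
* **Two quoted sector figures vs. the law.** The targeted sector
  resolving powers (~900 at 1000 Th, ~600 at 2000 Th) are mutually
  inconsistent with the $1/\sqrt{m/z}$ law at the 2% level
  ($900/\sqrt 2 = 636$). The engine follows its own law; the acceptance
  test asserts law-consistency tightly and the rounded 600 only loosely.
* **Resolving power at high m/z.** At 2300 Th the same derivation
  predicts $\mathrm{RP} \approx 75\sqrt{1000/2300} \approx 49$, reduced
  a further ~7% because the slower ion enters the zone partway into the
  schedule (measured: ~46). A much lower figure sometimes quoted for
  this regime is inconsistent with the law itself and is *not*
  reproduced; the suite instead verifies the engine tracks its own
  prediction.
* **Near-DC gating peaks.** Ions that enter or leave the zone
  mid-schedule gate their transient with a baseline step whose spectrum
  sits in the first few bins; `assemble_2d()` excludes peaks below 10
  (unpadded) bins by default because they encode zone geometry, not
  precursor mass. Its default height threshold (0.3 of the tallest peak)
  sits above the 21.7% first sidelobe of the unapodized line shape.

## Numerical behaviour

FWHM values are read off a half-bin grid (zero-fill ×2) by linear
interpolation; on a coherently sampled tone this overestimates the
1.2067-bin FWHM by ~0.7%, and on arbitrary tone phases the error stays
within ~1.5%. This is the dominant uncertainty in every reported
resolving power and is why end-to-end RP assertions use 2–3%
tolerances while centroid-based quantities (calibration, assignment)
are tested much tighter: noiseless centroids are good to < 0.05 bin.

The stochastic mode draws, per scan, the number of fragmented ions as
Binomial($n_\mathrm{ions}$, $I(d)$) and splits them multinomially over
the branching ratios. Its per-scan deviation from the deterministic
intensity is binomial: at $I = 0.1$ and $n_\mathrm{ions} = 10^4$ the
relative standard error is already 3%, so convergence is asserted as
"every scan within 4.5σ plus a small mean deviation", not as a uniform
per-scan percentage.

## What the synthetic mixtures do and do not emulate

`generate_mixture()` draws seeded mixtures whose modulation frequencies,
under the active configuration, are below Nyquist and pairwise separated
by a requested number of peak FWHMs — the regime in which fragment→parent
assignment should be exact, which the test suite verifies at 5, 10 and 20
precursors. Real spectra add detector noise, isotope envelopes, charge
states above 1 sharing channels, kinetic-energy release broadening the
fragment dimension, and precursors closer than a FWHM; none of these are
modeled, so a passing suite demonstrates correctness of the encoding and
decoding chain, not robustness to real-instrument artifacts.

## Problem sizes

The standard experiments run at their full published sizes ($2^{15}$
TOF scans, $2^{13}$ sector runs) — the engines are vectorized and a full
acquisition takes well under a second. Property-style tests use 2048–4096
scans, where a frequency bin is still fine enough to separate every
generated precursor.

## A worked run

```{r example}
cfg <- tof_config()
pat <- fragmentation_pattern(zone_length = cfg$zone_length)
sched <- scan_schedule(4096, config = cfg)
mix <- generate_mixture(seed = 11, n_precursors = 4,
                        config = cfg, pattern = pat, schedule = sched)
cube <- run_tof_scan_sequence(mix, cfg, pat, sched, event_log = FALSE)
model <- tof_calibration_from_config(cfg, pat, sched)
map <- assemble_2d(cube, model)
head(as.data.frame(map))
reproduce_rp_tof_1000()$rp_mz
```

## Known limitations

Idealized fields only (no electrode-level field solving); singly-charged
fragment convention; magnitude-mode processing only (absorption mode,
which would need the phase constant $C$, is not implemented); no
detector or electronics model; the magnetic-sector geometry is not
implemented. Cubes persist as wide CSV with a JSON metadata sidecar;
there is no binary container format.
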