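---
title: "hcasim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hcasim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`hcasim` is a desk-scale digital twin of an RFID home-cage monitoring
system for group-housed rats: a baseplate of 12 transceiver coils beneath a
38 x 50 cm cage reads subcutaneous glass transponders (ID plus temperature)
while an infrared side-view camera records the whole cage.  The package
simulates the animals and the instrument, runs the same analytics a real
installation would run (tracking, transition counting, vertical-activity
detection), and quantifies agreement between measurement routes.  This
vignette documents the models, the tunable parameters, and the design
choices made where the design was genuinely open.

## The cohort simulator

Each rat follows a bounded correlated random walk on the cage floor.  Per
0.1 s timestep a Poisson number of steps is drawn with rate

```
base_step_rate x circadian(t) x active(t) x perturbation(t)   [steps/s]
```

and the animal advances `step_length` (3 cm) per step along a heading that
diffuses with turning SD `turn_sd` (0.6 rad) on stepped timesteps.
Positions are reflected at the walls.  The circadian multiplier is
piecewise constant: 1 in the light phase, `dark_light_activity_ratio`
(default 1.4, the dark:light activity contrast typical of group-housed
rats) in the dark phase, with the session clock starting at lights-on and a
12:12 photoperiod.  Rest/active bouts form a two-state semi-Markov process
with exponential bout lengths (means 270 s rest / 90 s active, giving a 25%
active duty cycle and light-phase transition counts of a few tens per
15-minute bin, the scale seen in vivo).  The rest-bout means are
deliberately phase-independent by default so that the configured dark:light
ratio is carried entirely by the step rate and is therefore recoverable
from generated step counts; per-phase bout means remain configurable.

Rearing and climbing are Poisson events (12/20 per hour light/dark for
rearing, 2 s bouts; climbing rarer and longer).  The movement model is the
simplest generator with controllable activity level and path tortuosity; it
makes no attempt at social behaviour (huddling, play fighting), thigmotaxis
or food/water visits, so passing tests demonstrate instrument-model
correctness, not behavioural realism.

Subcutaneous temperature is a two-level circadian mean — `temp_baseline`
(37.5 °C) in the light phase plus `temp_dark_elevation` in the dark — with
AR(1) noise (stationary SD 0.1 °C, coefficient 0.999 at 0.1 s, i.e. a
fluctuation timescale of minutes).  Two elevation presets are provided:
`0.5` °C (the default, matching the plainly visible circadian swing) and
`0.25` °C (`temp_presets$regression`, the smaller contrast a binned
regression attributes to photoperiod once day and week effects are
modelled).  Both are legitimate readings of the published record; the
larger one is the default and nothing in the package asserts which is
canonical.

Perturbations (`perturbation_event`) modulate generation: a cage change
multiplies the step rate (default x3 for 45 min), oral gavage gives a brief
x2.5 spike (10 min), and single housing subtracts 0.5 °C for 16 h.
`apply_perturbation()` also works post hoc on a realized series, but only
where that is well-defined: it offsets `true_temp` directly and scales the
per-sample step counts, leaving positions untouched.  Re-deriving a
perturbed *path* from an already-generated series is not possible without
regenerating it, so the pipeline always passes events to
`simulate_cohort()`.

Tag pose follows the implant site: the transponder sits `height` cm above
the plate (posture-dependent: resting x0.85, rearing +8 cm, climbing
+12 cm), with its long axis along the body midline ("body" sites) or
dorsoventral (`flank_vertical`), and flank sites offset 2 cm from the
midline.  Upright postures pitch the body, so body-axis tags become
vertical and dorsoventral tags horizontal.

## The baseplate reader

The 12 coils (3 x 4 grid) are polled sequentially in a row-major serpentine
order.  Each slot is 90 ms with the coil energised for 75 ms followed by a
15 ms settle gap; the full cycle is 1080 ms, bounding the per-tag read rate
at 0.926 Hz.  The printed timing constants (75 ms activation, 1080 ms
cycle) only reconcile if the slot exceeds the activation, hence the 15 ms
gap; both constants are configurable.

Each coil is approximated by a vertical magnetic dipole at its centroid.
The tag signal is `field_scale x gain x |B(r) . axis|`, which reproduces
the qualitative coupling pattern of such arrays: vertical tags couple best
directly above a coil, horizontal tags best between coils, and tags are
also picked up by adjacent antennae without any explicit rule.  A tag is
read during an activation only if its coupling stays at or above
`read_threshold` continuously for `min_dwell` = 60 ms (the transponder
charge-and-read time); among simultaneously readable tags only the one
with the highest time-averaged coupling is reported, and within a full scan
cycle a tag is counted once, on the antenna where its mean coupling was
highest.  Dwell is evaluated per activation; charge does not carry over
between antennae.

Couplings are evaluated at the start, middle and end of each 75 ms window;
only windows in which the tag crosses the threshold are re-evaluated on a
5 ms grid, with threshold-crossing times refined by linear interpolation
and a 0.5 ms numerical tolerance on the dwell comparison.  This adaptive
scheme assumes coupling does not dip below threshold *between* the three
probes during an essentially stationary 75 ms window — movement within a
window is under a centimetre at realistic speeds.

Stray-RF interference is modelled as multiplicative log-normal noise on the
coupling (sigma 0.6), evolving as an AR(1) process per tag-antenna pair
across scan cycles with a 300 s correlation time.  The noise gates whether
a tag charges; the reported strength ranking uses the noise-free coupling,
since ranking reflects time-averaged signal.  Slow, charge-gating noise
matters: per-cycle independent noise that also re-ranked antennae generated
large activity-independent flicker in the tracks, inflating transition
counts at rest and inverting the truncation property.

Temperature reads add uniform error (+/-0.5 °C), clamp to the
transponder's 33.0-43.0 °C recording range and quantise to 0.1 °C.
Clamping (rather than dropping) keeps read drop-out statistics independent
of temperature; clamped readings are flagged and excluded from bin means.

### Calibration

`field_scale`, `read_threshold`, `shielding_gain`, the coupling-noise sigma
and the per-site heights are calibration constants, fitted once by grid
search so that simulated 24 h read rates of 3-rat cages reproduce the
measured per-site values (0.74 Hz ventral midline pre-upgrade, and offsets
of roughly -0.1, -0.3 and -0.44 Hz for flank-vertical, flank-horizontal
and interscapular), and stored in the versioned
`inst/extdata/calibration.yaml`.  The fitted heights (2.5, 3.4, 8.75,
10.15 cm) are *effective coupling distances*: the pure dipole model has no
tissue attenuation or orientation scatter, so the flank-horizontal and
interscapular constants absorb those losses into distance.  The shielding
upgrade is a single multiplicative field gain (fitted value 4.0), raising
the ventral-midline rate to about 0.87-0.88 Hz, close to the 0.93 Hz
ceiling.

## Tracking

Reads are snapped to antenna centroids.  The flicker filter is a
2-consecutive confirmation rule: a change of antenna is accepted only when
the immediately following read repeats the new antenna, and unconfirmed
single-read excursions are replaced by the held antenna.  The rule is
idempotent, removes pure two-antenna flicker, and passes genuine moves with
one-cycle latency; a majority-of-3 median variant is available behind
`filter_variant = "majority3"`.  A probabilistic (hidden-state) smoother
over the 12-cell grid would be the natural next step and is deliberately
out of scope.

Missed cycles are filled by linear interpolation when the gap is at most
`max_gap` = 5 s (about 4 cycles); longer gaps are flagged `missing` with no
invented positions.  Every sample carries a provenance flag (`read`,
`filtered`, `interpolated`, `missing`), so the raw stream is recoverable
from a track.  Transitions are counted on *filtered* labels between
consecutive labelled samples (counting raw labels would overcount
stationary animals sitting on a cell boundary), and distance sums
centroid-to-centroid segments.  Activity and temperature are summarised in
15-minute bins; a bin's temperature mean requires at least 3 reads.

Because positions are quantised to 12 centroids, baseplate-derived distance
systematically *truncates* the true path, and the shortfall grows with
speed: fast crossings touch cells for single cycles, which the confirmation
rule discards.  On 7-day default runs this also attenuates the end-to-end
dark:light transitions ratio to about 1.2 at a configured step-rate ratio
of 1.4 — the dark phase is faster, so it loses proportionally more.  The
configured ratio itself is recovered from the generator's binned step
counts (`true_path_bins()` + `light_dark_summary()`); the binned read-stream
temperature recovers the configured phase contrast essentially unbiased
(about -0.504 °C at -0.5 configured, well within 3 standard errors).

## Synthetic video

The renderer draws an orthographic side view (320 x 180 px, 25 fps,
1/6 cm per pixel at the far wall, floor at row 170): each rat is a filled
ellipse whose height doubles and whose centre rises when rearing, over a
static background with a tunnel-shaped enrichment fixture.  Upright
postures bob with a 1 cm, 0.2 s sawtooth so the blob moves by more than a
pixel every frame — a motionless rearing blob would otherwise be invisible
to frame differencing, which detects movement, not posture.  Resolution is
a scaled-down stand-in for the real 720p camera; the analytics are
resolution-independent given the calibration record.  Perspective effects
(foreground tails triggering the line, obscured far-wall rears) are
explicitly not modelled.

Whole-cage motion is the count of pixels whose absolute frame-to-frame
difference exceeds `diff_threshold` (10 intensity units).  Vertical
activity marks frames with any supra-threshold differenced pixel above the
8 cm line (row 122 at the default calibration); runs merge across quiet
gaps shorter than `min_frames` (3 frames, 120 ms) and shorter runs are
discarded as single-frame noise.  Episodes are assigned to the animal whose
track x-position is nearest the episode's motion centroid at its midpoint;
ties or missing positions stay unassigned.  Pixel noise defaults to SD 1,
far enough below the differencing threshold (about 7.8 sigma on a
difference) that false vertical frames are negligible; neither the
difference threshold nor the minimum episode length is printed anywhere
authoritative, so both are declared defaults.

## Agreement statistics

* `icc_1k()` computes the one-way random-effects, average-of-k-measures
  ICC(1,k) = (BMS - WMS)/BMS from the ANOVA decomposition.  The published
  label "ICC1k average absolute agreement" mixes two naming systems, so the
  two-way absolute-agreement average-measures ICC(A,k) is provided as an
  option.
* `bland_altman()` reports bias and 95% limits of agreement (bias +/- 1.96
  sample SD of the differences).
* `fit_ols()` / `fit_random_intercept()` / `fit_negbin()` wrap the
  classical least-squares, REML random-intercept (`lme4`) and negative
  binomial (`MASS`) fits behind a uniform coefficient-table interface.  All
  published model structures have exactly one grouping factor, so a single
  random intercept suffices; REML is used (the published account does not
  say), and a model printed with a bare "+1" alongside "rat was treated as
  a random factor" is read as `+ (1 | rat)`.  Categorical terms use
  treatment coding with the alphabetically first level as reference.  When
  the negative binomial dispersion is unidentifiable (constant or
  under-dispersed counts) the fit degenerates to its Poisson limit with
  theta reported as infinite.
* `paired_t()` follows the error contract: zero-variance differences are an
  undefined-statistic error rather than t = 0.
* `rubric_scores()` maps read frequency, tracking ICC, side-view R² and
  implantation issues onto the 1-5 site-selection bands.  The published
  bands use strict inequalities on both sides, leaving boundary values
  undefined; they are implemented as half-open `[lower, upper)` intervals,
  so 0.75 Hz scores 5 and 0.74 Hz scores 4.
* No multiplicity correction is applied; per-term two-sided Wald tests at
  p < 0.05 mirror the published analysis style.

## Pipeline and formats

`run_pipeline()` chains `simulate` → `reads` → `track` → `video` →
`analyze` → `validate` → `report` over a session bundle of CSV/PNG/JSON
artifacts; every artifact records the producing configuration checksum and
seed in a manifest, and `report` refuses mixed-checksum bundles.  All
randomness flows from the single configuration seed.  A thin command-line
wrapper is installed at `inst/cli/hcasim.R`.  Antennas are numbered 1-12
(row-major) in all file formats.

## Problem sizes and numerical choices in the test suite

The validation suite exercises the system at the sizes the analyses need,
chosen for statistical resolution: 24 h cage-sessions for read-rate
calibration (Monte-Carlo SE well under the +/-0.05 Hz band), one 7-day
3-rat session for circadian parameter recovery (21 animal-days for the
activity ratio; ~2000 15-min bins for the temperature regression), 100
15-min bins for the truncation sign test, and 40 s noise-free fixtures with
scripted rearing schedules for the video suite.  Statistical oracles
(explicit sums of squares, normal equations, closed-form t) are kept
independent of the implementation paths they check.

## Known limitations

* One cage per session: no multi-cage orchestration, no between-cage
  variance components (the `cage`, `week` and `baseplate` terms of the
  published models are constant in a single simulated bundle and are
  dropped from the fitted structure).
* The dipole field has no mutual inductance, cross-talk or RF protocol;
  site constants are effective, not anatomical.
* The renderer is orthographic and noise-stationary; real-video artifacts
  (compression, illumination drift, perspective) are out of scope.
* Behavioural realism is limited to circadian structure, rest bouts and
  posture events; detection of eating, drinking or grooming is not
  attempted.
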