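# hcasim

A desk-scale digital twin of an RFID baseplate home-cage monitoring system
for group-housed rats.

Continuous welfare and pharmacology studies increasingly monitor rats in
their own home cage: a baseplate of 12 transceiver coils (3 × 4 grid under
a 38 × 50 cm cage) polls subcutaneous glass RFID transponders for identity,
position and temperature, while an infrared side-view camera records the
whole cage.  `hcasim` simulates both the animals and the instrument, runs
the analytics such a system runs on its raw data, and quantifies agreement
between the measurement routes.  It is aimed at people developing or
validating home-cage analytics who need ground truth that real animals
cannot provide: every simulated read stream comes with the exact trajectory,
posture schedule and temperature series that produced it.

The package covers, end to end:

* **Cohort simulation** — bounded correlated random walk with circadian
  step-rate modulation (dark:light ratio 1.4 by default), rest bouts,
  rearing/climbing events, implant-site-dependent tag pose, AR(1)
  subcutaneous temperature with a dark-phase elevation, and husbandry
  perturbations (cage change, single housing, oral gavage).
* **Baseplate physics** — sequential antenna polling (75 ms activation,
  1080 ms scan cycle, max 0.93 Hz per tag), magnetic-dipole tag coupling,
  the 60 ms charge-dwell rule, collision resolution ("strongest tag wins"),
  slow stray-RF noise, and ±0.5 °C clamped, quantised temperature reads.
* **Tracking** — flicker filtering (2-consecutive confirmation),
  centroid snapping, gap interpolation with provenance flags, antenna
  transition counts and temperature means in 15-minute circadian bins.
* **Video motion** — synthetic side-view rendering, frame-differencing
  whole-cage motion, vertical-activity episodes above the 8 cm line, and
  per-individual episode assignment from the RFID track.
* **Agreement statistics** — ICC(1,k) from the one-way ANOVA
  decomposition, Bland–Altman limits of agreement, OLS / random-intercept
  REML / negative-binomial regressions, paired *t*, the 1–5 implant-site
  scoring rubric, and light/dark summaries.

## Worked example

Six simulated hours of a 3-rat cage, ventral-midline implants,
pre-shielding-upgrade baseplate:

```r
library(hcasim)
cfg   <- sim_config(duration = 6 * 3600, seed = 7)
gt    <- simulate_cohort(cfg)
arr   <- antenna_array()
reads <- simulate_readstream(gt, arr, calibrated_model(), seed = 7)
read_rate(reads, cfg$duration, unique(gt$animal_id))
#>    tag_id n_reads read_rate_hz
#> 1:  rat01   15336    0.7100000
#> 2:  rat02   15601    0.7222685
#> 3:  rat03   16110    0.7458333

track <- build_tracks(reads, arr, duration = cfg$duration)
act   <- count_transitions(track, 900, duration = cfg$duration)
truth <- true_path_bins(gt, 900, duration = cfg$duration)
m     <- merge(act[, c("window_start", "animal_id", "distance_cm")], truth,
               by = c("window_start", "animal_id"))
icc_1k(cbind(m$distance_cm, m$true_distance_cm))$icc
#> [1] 0.8508332
rubric_scores(read_freq_hz = 0.726, icc_tracking = 0.851)
#>         criterion metric score
#> 1: read_frequency  0.726     4
#> 2:   tracking_icc  0.851     4
```

Read rates sit at the calibrated ~0.74 Hz for this site, the
baseplate-derived distance agrees with the true path at ICC ≈ 0.85 while
remaining truncated (positions are snapped to 12 antenna centroids, so
distance is systematically underestimated, increasingly so at higher
speeds), and both metrics land in band 4 of the site-selection rubric.

The same chain is scriptable from a shell via the bundled CLI:

```sh
Rscript inst/cli/hcasim.R simulate --out session1 --duration 3600 --seed 7
Rscript inst/cli/hcasim.R reads    --out session1
Rscript inst/cli/hcasim.R track    --out session1
Rscript inst/cli/hcasim.R analyze  --out session1
Rscript inst/cli/hcasim.R report   --out session1
```

See `vignettes/hcasim-methods.Rmd` for the full model description,
calibration procedure and known limitations.

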