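# phosread

Reading through artificial vision, in simulation. `phosread` models a
visual prosthesis that renders the world as 2000 retinotopically locked
Gaussian phosphenes and asks the question that matters for head-steered
devices: what happens to reading when the scene camera follows the full
gaze (head + eye, spatially congruent stimulation) versus the head alone
(incongruent whenever the eyes move)? It is written for visual-prosthetics
and low-vision researchers who want a reproducible, desk-scale testbed for
gaze-contingency questions without hardware.

The package implements the whole experiment in code:

* **Geometry** — tangent-plane pixel/degree mapping for a 59.9 x 33.6 cm,
  1600 x 900 px screen at 70 cm; pose algebra `gaze = head + eye_in_head`;
  camera steering `camera = gaze` (full gaze) or `camera = head`
  (head only); incongruence `gaze - camera`.
* **Phosphene field** — spacing grows linearly with eccentricity,
  `s(e) = s0 (1 + e/e2)`; `calibrate_profile()` solves `(s0, e2)` so the
  90-degree field holds 2000 phosphenes with one quarter inside the central
  10 degrees; `generate_field()` places them by seeded dart-throwing with a
  `0.7 s(e)` exclusion radius, `sigma = 0.3 s(e)`.
* **Stimuli** — three-line, exactly-60-character sentences from a packaged
  elementary vocabulary (the licensed reading-acuity corpus is not
  shipped), rasterized white-on-black in a Times-metric serif with the
  x-height calibrated by measurement to `5 x 10^logMAR` arcmin.
* **Renderer** — each phosphene samples the reference image through a
  Gaussian aperture along the *camera* axis and is drawn at its
  retinotopic position along the *gaze* axis, with per-frame viewing
  distance compensation of the drawn size; blobs composite by max.
* **Session simulation** — a synthetic observer runs the full protocol
  (mini-blocks A1 B1 C1 B2 C2 A2; Start/Pre-Stimulus/Reading/End phases;
  350 ms dot dwell; 2000 ms intertrial interval), recognizing each word
  with probability `1/(1 + exp(-k (coverage - c50)))`, further penalized
  by `exp(-||incongruence||/1 deg)` under head-only steering.
* **Psychometrics** — accuracy (% words correct) and speed (WPM), medians
  with 16/84 percentile offsets, a constrained logistic
  `A(x) = 100/(1 + exp(-k(x - m)))` whose 50% point `m` is the equivalent
  acuity, and Wilcoxon rank-sum / signed-rank tests with exact small-sample
  enumeration, Spearman correlation, and a KS normality screen.

## A worked example

```r
library(phosread)

geom  <- viewing_geometry()                       # the default apparatus
field <- generate_field(calibrate_profile(), 2000, seed = 11)

count_in_rect(field, screen_rect_deg(geom))       # phosphenes on the monitor
#> [1] 1120
theoretical_acuity(field, r_outer_deg = 2)        # foveal sampling acuity
#> [1] 1.054829

log    <- simulate_cohort(n_subjects = 23, seed = 42, field = field, geom = geom)
curves <- psychometric_curves(log)
dplyr::filter(curves, metric == "accuracy_pct", logmar == 1.4)
#> # A tibble: 3 x 9
#>   condition logmar metric       median lower upper   p16   p84     n
#>   <chr>      <dbl> <chr>         <dbl> <dbl> <dbl> <dbl> <dbl> <int>
#> 1 full_gaze    1.4 accuracy_pct   95.8  2     4.17  93.8 100      23
#> 2 head_only    1.4 accuracy_pct   19.2  3.85  7.69  15.4  26.9    23
#> 3 normal       1.4 accuracy_pct  100    0     0    100   100      23
```

At the largest print size the simulated cohort reads nearly perfectly under
full-gaze steering but only ~19% of words under head-only steering; the
rank-sum comparison of the two conditions gives z = 5.9, p = 4 x 10^-9,
r = 1.2. Fitting the constrained logistic to the full-gaze accuracy medians,

```r
acc <- dplyr::filter(curves, metric == "accuracy_pct", condition == "full_gaze")
fit_equivalent_acuity(acc$logmar, acc$median)
#> <acuity_fit> equivalent acuity 1.053 logMAR (95% CI 1.031-1.074), slope 8.5
```

an equivalent acuity of about 1.05 logMAR — the print size at which the
observer's word recognition crosses 50%. `autoplot(curves)`,
`autoplot(field)` and `plot_traces()` draw the standard figures, and
`run_end_to_end(default_config(), "out/")` writes the full artifact set
(pattern JSON, session CSV, curve tables, plots, summary JSON) from one
seeded config. A thin CLI over the same functions ships in
`inst/cli/phosread.R`.

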