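---
title: "Simulating gaze-contingent phosphene vision for reading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating gaze-contingent phosphene vision for reading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Head-steered visual prostheses image the world with a camera fixed to the
head and convert it into patterns of phosphenes -- focal percepts evoked by
electrical stimulation of the visual pathway. Phosphenes are retinotopically
locked: they appear at fixed positions relative to the current gaze
direction. When the wearer moves their eyes, the brain applies its knowledge
of eye position to the retinal input (spatial updating), but a head-steered
camera does not move with the eyes, so the percept and the sampled scene
disagree by exactly the eye-in-head rotation. `phosread` simulates this
situation in a reading task: a synthetic observer reads three-line,
60-character sentences through a 2000-phosphene prosthesis whose camera is
steered either by full gaze (head + eye, spatially congruent) or by the head
alone (incongruent whenever the eyes deviate), and the resulting session
logs are analyzed with the standard reading-acuity toolkit.

## Geometry

All angles are visual angles relative to the screen-center axis, with a
tangent-plane (gnomonic) mapping between pixels and degrees:
`azimuth = atan((x_cm - width/2) / distance)`, elevation analogous with the
sign flipped so positive is upward. The default apparatus is a 59.9 x 33.6
cm monitor at 1600 x 900 pixels viewed from 70 cm. Under the tangent rule
this subtends 46.3 x 27.0 degrees. (Descriptions of comparable apparatus
sometimes quote ~41 x 24 degrees for this screen and distance, which no
standard mapping reproduces; the package uses the tangent formula
throughout, and no reported quantity here depends on the difference.)

Angular composition is additive in degrees -- a small-angle approximation
that is accurate to well under a pixel for the < 25 degree rotations that
occur in the task. Torsion and eye translation are ignored; poses are
2-DOF directions for the head and for the eye-in-head.

## The phosphene field

The simulated device places electrodes at constant density in a
retinotopically magnified structure, so phosphene spacing in the visual
field grows with eccentricity. The package adopts the simplest law with
that character, linear growth

$$ s(e) = s_0 \left(1 + e / e_2\right), $$

with foveal spacing $s_0$ and doubling eccentricity $e_2$. The areal
density $1/s(e)^2$ integrates in closed form over a central disc, which
makes calibration direct: the packaged field solves for $(s_0, e_2)$ such
that the whole 90-degree field holds 2000 phosphenes in expectation and the
central 10 degrees (5-degree radius) holds one quarter of them. The central
fraction depends only on $e_2$, so a bisection on $e_2$ followed by a
closed-form $s_0$ meets both constraints to better than $10^{-6}$ relative
residual (`calibrate_profile()`); for the defaults this gives
$s_0 \approx 0.123$ deg and $e_2 \approx 1.20$ deg.

Placement is dart-throwing with an eccentricity-dependent exclusion radius:
candidates are drawn from the density, and a candidate at eccentricity $e$
is kept only if no accepted phosphene lies within $0.7\,s(e)$. This yields
a blue-noise-like arrangement whose local mean nearest-neighbour spacing
tracks $s(e)$; generation is bit-reproducible per seed. Each phosphene is
displayed as a Gaussian with $\sigma = 0.3\,s(e)$ -- neighbouring
phosphenes remain distinct but tile without large gaps -- and unit gain
(per-phosphene brightness variation is not modeled).

Two characterizations follow from the calibrated field rather than being
imposed: the number of phosphenes landing on the monitor rectangle at
straight-ahead gaze (the tests and the acceptance script compute it across
seeds), and the "theoretical acuity" of a region, defined here as
`log10(mean nearest-neighbour spacing in arcmin)` so that a 1-arcmin grid
reads 0.0 logMAR. Acuity declines monotonically from fixation to the screen
edge by construction. Published characterizations of comparable
thalamic-prosthesis patterns quote a steeper fovea-to-edge acuity ratio
than any linear-spacing profile can produce while also honoring the
2000-total / one-quarter-central count constraints; the count constraints
take precedence here, and the acuity figures are treated as qualitative.
This same difference in mid-eccentricity density is the likely reason the
activated-phosphene count for a 1.0 logMAR sentence (~290 under this
profile, computed by `scripts/acceptance.R`) exceeds the ~175 quoted for
the unpublished density law those characterizations describe.

## Text stimuli

Sentence fixtures emulate the printed constraints of standardized
continuous-text acuity sentences: exactly 60 characters including spaces
and no terminal period, no punctuation, no proper nouns, three lines (here
18-20 characters each, matching the ~19-character average of the printed
cards and keeping the widest line on screen at the largest size). The
licensed corpus itself is not shipped; `make_fixtures()` assembles
sentences from a packaged elementary vocabulary by seeded template filling
(determiner-adjective-noun-verb clauses joined by simple conjunctions).
The fixtures reproduce the *format* of the standard sentences, not their
validated equal readability -- a caveat that does not matter for the
synthetic observer, which has no lexicon.

Print size follows the acuity-letter convention: x-height
$= 5 \times 10^{\mathrm{logMAR}}$ arcmin. Rendering is white-on-black
(the display polarity of the simulation, opposite to the printed cards) in
R's built-in Hershey stroked serif, with two numerical choices worth
stating:

* **Metric condensation.** The Hershey serif's character advances are about
  25% wider than Times-style metrics. Rendered lines are horizontally
  resampled by a factor 0.8 (`condense`), bringing a 20-character line to
  about 18 x-heights -- Times-like proportions -- so that the largest print
  size (1.4 logMAR, x-height 2.09 deg) fits the screen as it does on real
  apparatus. Stroke width scales with print size (`stroke_frac`, default
  0.16 of x-height).
* **Measured calibration.** Rather than trusting font metrics, the
  rasterized x-height of a lowercase "x" is measured (with subpixel
  0.5-crossing interpolation) and the text scale is corrected iteratively
  until the measurement is within 2% of the target; the achieved value is
  stored on the `rendered_text` object.

Line spacing is 1.5 x-heights baseline-to-baseline and the block is
centered on screen; both are exposed as arguments since printed layouts
vary. Per-word tight bounding boxes from the raster drive the observer's
coverage computation.

## Rendering

A frame of phosphene vision separates *sampling* from *display*:

* sampling follows the **camera** axis: each phosphene's brightness is the
  Gaussian-weighted mean of reference luminance in a window of radius
  $3\sigma$ around `camera + retinotopic position`, weights
  $\exp(-d^2/2\sigma^2)$ in degree space. Window regions beyond the screen
  contribute zero luminance at full weight (off-screen is black); the
  alternative -- renormalizing over the visible part -- is a one-line
  change but would brighten phosphenes straddling the bezel.
* display follows **gaze**: the blob is drawn at
  `gaze + retinotopic position` with a pixel sigma recomputed from the
  per-frame viewing distance (`compensated_sigma_px()`), so percept sizes
  on the retina stay constant if the head approaches the screen.

Under full-gaze steering camera = gaze and stimulation is congruent; under
head-only steering camera = head, and the percept disagrees with the
sampled content by the eye-in-head rotation -- the modes are bit-identical
exactly when the eyes are straight in the head. Overlapping blobs combine
by maximum, which keeps luminance bounded in [0, 1] without a later
normalization pass (summation would need one). One Gaussian serves as both
sampling aperture and display point-spread. A phosphene is counted as
*activated* by a stimulus when its sampled brightness exceeds 0.01 of full
scale. Display latency is not modeled; the simulation is turn-based per
fixation rather than clocked at the refresh rate.

## The synthetic observer and the trial protocol

The observer is a modeling stand-in for human subjects, not a claim about
them. It fixates words in reading order and recognizes each word with
probability

$$ L(c) = \frac{1}{1 + e^{-k (c - c_{50})}}, $$

where the coverage $c$ is the number of activated phosphenes inside the
word's glyph box divided by the word's width in x-height units. Under
head-only steering each attempt also pays a congruence penalty
$\exp(-\lVert \text{incongruence} \rVert / 1^\circ)$, with the eye-in-head
drawn per attempt from a centered Gaussian (sd `incongruence_sd_deg`).

Defaults (set once against the packaged field, documented units):

| parameter | default | why |
|---|---|---|
| `legibility_midpoint_ppx` | 27 phosphenes/x-height | mean fixated-word coverage crosses 27 near 1.05 logMAR, placing the 50% point inside the tested range |
| `legibility_slope` | 0.3 per coverage unit | spreads the sigmoid over 0.9-1.4 logMAR rather than a step |
| `fixation_ms`, `saccade_ms` | 280, 50 ms | normal reading lands in the low hundreds of WPM |
| `phosphene_effort` | 3 | phosphene-view reading is slower than natural even at ceiling accuracy |
| `headscan_speed_dps` | 1.5 deg/s | deliberate head scanning is an order of magnitude slower than saccades |
| `incongruence_sd_deg` | 3 deg | produces severe but nonzero head-only performance |
| `give_up_ms` | 180000 ms | stands in for "as long as they wanted"; unbounded trials are not simulated |
| `prestim_ms` | 500 ms | the pre-stimulus fixation hold (brief pause before text onset) |

Trials run the four phases Start (fixation-dot foveation), Pre-Stimulus,
Reading, End; the trial ends when gaze dwells 350 ms on the Next Sentence
dot, followed by a 2000 ms intertrial interval, all bookkept exactly in the
record's timestamps. Reading duration is measured from text onset to the
dot foveation. Fixation-dot cue colors (white/red/orange by condition) are
protocol metadata; the observer is cue-blind. Sessions are six mini-blocks
of six trials, ordered A1 B1 C1 B2 C2 A2 (Normal, Full Gaze, Head Only,
each twice), each size 0.9-1.4 logMAR once per mini-block in a seeded
order conserved across subjects, every trial a distinct sentence. Cohorts
jitter the continuous observer parameters log-normally (sdlog 0.05) per
subject.

What the simulation reproduces of real reading data is structural: perfect
performance under normal viewing, a sigmoidal accuracy curve under
full-gaze phosphene vision whose 50% crossing is recoverable from the logs
(the parameter-recovery test demands agreement within 0.05 logMAR with the
acuity implied by the legibility midpoint), stochastic dominance of full
gaze over head-only at every size, and center-out-and-back gaze loops with
raster-like head traces under head steering. What it does not emulate:
oculomotor dynamics, learning across mini-blocks, inter-subject strategy
differences, lexical guessing, fatigue or nausea. Absolute accuracies,
speeds and durations under phosphene viewing are therefore
stand-in-calibrated magnitudes, not predictions; tests assert orderings,
shapes and recoverability, not those absolute values.

## Analysis

Per-trial accuracy is `100 * words correct / words total`; speed is
correct words per minute over the reading duration. Each condition x size
pair appears twice per session and enters as the mean of its two
presentations. Population summaries are medians with distances to the 16th
and 84th percentiles (linear interpolation, inclusive method), the natural
summary for bounded, floor-heavy metrics.

Equivalent acuity is the 50% point of
$A(x) = 100 / (1 + e^{-k(x - m)})$ least-squares fitted to accuracy versus
print size with floor and ceiling fixed at 0 and 100 -- the control data
sit at 100% and the hardest condition near 0%, so only $m$ and $k$ are
free. The optimizer is Nelder-Mead from multiple starts (interpolated 50%
crossing, three slope scales); the 95% CI is a seeded nonparametric
bootstrap over points. Fits whose midpoint falls more than 0.5 logMAR
outside the tested range are flagged `converged = FALSE`: data that never
bracket 50% (head-only-like curves) yield extrapolated midpoints whose
instability the wide bootstrap intervals make explicit, and such midpoints
are reported only with that flag.

The nonparametric tests are authored in-package because the analysis needs
the z statistic and effect sizes that `stats::wilcox.test` does not expose:
rank-sum and signed-rank with midrank tie correction and continuity
correction, exact enumeration of the null (all group assignments, or all
sign assignments) whenever at most 12 observations are involved, and effect
size $r = |z| / \sqrt{n_{\text{per group}}}$ (reported alongside
$|z|/\sqrt{N}$; published reading-performance comparisons at $n = 23$ per
group quote $r$ values above 1, which only the per-group convention can
produce). Spearman correlation uses midranks with the t approximation, and
the normality screen is the KS statistic against a normal with the sample's
own mean and sd -- parameter estimation makes the textbook p conservative
(the Lilliefors caveat), which is acceptable for its only role here,
justifying the nonparametric choices.

## Reproducibility and problem sizes

All randomness flows from explicit seeds (config, generator, scheduler,
per-trial); reruns of `run_end_to_end()` are byte-identical. The packaged
analyses run at desk scale: 20 generation seeds for field statistics, 10
sentences x 10 seeds for activation counts, and a 23-subject cohort
(36 trials each) for the recovery and ordering checks, which completes in
a few minutes on one core.

```{r example}
library(phosread)
geom <- viewing_geometry()
field <- generate_field(calibrate_profile(), 2000, seed = 11)
log <- simulate_cohort(n_subjects = 23, seed = 42, field = field,
                       geom = geom)
curves <- psychometric_curves(log)
autoplot(curves)
```
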