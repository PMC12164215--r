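---
title: "Movement synchrony, gaze and impressions of observed dyads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement synchrony, gaze and impressions of observed dyads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dyadsync implements, end to end, the computational chain of a study design
in which observers watch short silent video segments of dyadic interactions
and rate how pleasant they find them, while an eye tracker records their
gaze. The scientific question is how two properties of the *stimulus* —
the interpersonal synchrony of the interactants' movements (IPS), and
whether the dyad includes an autistic interactant — and one property of the
*observer* (autistic vs. non-autistic) shape the ratings and the gaze
behaviour. Everything here runs on synthetic data with known generative
truth; no participant data is used or required.

## The measurement chain

### Motion energy

Movement of each interactant is quantified by motion energy analysis: for a
region of interest (ROI) in a grayscale video, the per-frame count of
pixels whose intensity changes by more than a threshold between consecutive
frames. `compute_mea()` implements exactly this definition (strict
inequality, first frame set to 0 so series length equals frame count) and
`rescale_mea()` divides by the ROI pixel count so values are proportions of
the ROI in motion, comparable across ROI sizes. The threshold defaults to
10 on the 0–255 intensity scale, a conventional setting; results at desk
scale are insensitive to it because the synthetic frames are built to flip
pixels by exactly threshold + 1.

The frame generator `gen_motion_frames()` inverts this computation: given a
target series it toggles exactly the required number of ROI pixels between
intensity 0 and threshold + 1 per frame, so
`compute_mea(gen_motion_frames(s)) == s` holds *exactly*. This round-trip
identity is the backbone of the motion-energy tests: the extraction code is
checked against a brute-force per-pixel oracle, and the generator against
the extraction.

### Coupled dyad motion

`gen_coupled_motion()` generates the two interactants' series with a
controllable lagged correlation. Partner A's latent motion is a stationary
AR(1) with autocorrelation 0.95 (motion energy of conversational movement
is strongly autocorrelated at 25 fps); partner B is
`coupling * A[t - lag] + sqrt(1 - coupling^2) * E[t]` with `E` an
independent copy of the same process, so the latent lagged Pearson
correlation equals `coupling` by construction. Both series are shifted by
+4 SD and rectified at zero: motion energy is non-negative, and the large
shift makes rectification rare enough that the Pearson structure survives
(at coupling 0.7 the realized lagged correlation is within ±0.05 of 0.7 on
15000 frames). `coupling` may be a per-frame vector, which is how test
fixtures create within-video epochs of high and low synchrony.

A Monte-Carlo calibration run before the test suite was frozen (200
simulations) put the 99% envelope of the maximum absolute lagged
correlation between *uncoupled* dyads at 0.132 across lags ±3 s on 12000
frames; the suite asserts a 0.15 bound. This is the honest null envelope
for autocorrelated series — it is an order of magnitude wider than the
i.i.d. intuition `1/sqrt(n)` suggests, which is exactly why the synchrony
literature evaluates significance against surrogate (shuffled-pair) data
rather than against nominal correlation quantiles.

### Windowed-lagged cross-correlation and segment selection

IPS of a window is the peak over lags of the Pearson correlation between
partner A's windowed series and partner B's shifted series (`wlcc()`,
window 10 s, lags ±3 s). The peak is the maximum *absolute* correlation —
the standard convention in motion-energy synchrony work, since
anti-phase coordination is still coordination; the signed value at the
peak is stored alongside. Windows with zero variance are undefined (`NA`),
never zero: a motionless window carries no synchrony information.

`select_segments()` reproduces the stimulus-construction logic: enumerate
candidate 10-s segments at 1-s steps; per dyad, keep candidates whose
overall motion (mean framewise sum of the two rescaled series) lies in the
closed interquartile interval [Q1, Q3] of that dyad's candidates (R's
default linear-interpolation quantiles); then greedily take the 4
highest-IPS candidates (ties to the earlier start) subject to
non-overlap, and likewise the 4 lowest. Eight dyads × 8 segments gives the
64-trial, 2 (dyad type) × 2 (IPS) within-design with 16 segments per cell.
Selecting *within* dyads is what de-confounds synchrony from dyad identity;
the package checks balance the way the stimulus set demands it — a JZS
Bayes-factor t-test comparing the dyad types' selected IPS values should
favour the null.

### Gaze events

`detect_events()` implements an adaptive velocity-threshold event detector
for 500 Hz monocular gaze data. Positions are smoothed with a
Savitzky–Golay filter (20 ms window, order 2) whose analytic derivative
gives angular velocity, using the per-axis pixel pitch of the monitor
(1920 × 1080 px, 533 × 300 mm, 570 mm viewing distance; `px_to_deg()` uses
the exact subtense formula, which reproduces the published AOI visual
angles of 5.85° for 210 px heads and 3.91° for 140 px hands).
Velocity/acceleration caps (1000 °/s, 100 000 °/s²) mark artifacts. The
saccadic peak threshold is data driven: `PT <- mean + 6 SD` of sub-PT
samples iterated to a fixed point from 200 °/s (`adaptive_threshold()`),
with a 30 °/s physiological floor so that near-noise-free recordings do
not collapse the threshold onto numerical dust. Saccade onsets walk back
to the last sample below `mean + 3 SD` of the fixation noise; offsets use
the locally adapted threshold `0.7 * onset + 0.3 * local noise`; a
supra-threshold run must last at least 3 samples (6 ms) to count as a
peak. Post-saccadic wobbles within 40 ms become glissades; remaining
stretches of at least 40 ms become fixations (start point = first sample,
centroid = mean smoothed position). Peak velocities are reported from
central-difference speed rather than the segmentation filter's output, so
they are not attenuated by smoothing. Invalid gaps under 75 ms are
linearly interpolated (blink handling); longer gaps split the recording.

The companion generator `gen_gaze_scanpath()` produces ground truth for
all of this: fixations are targets plus isotropic Gaussian noise, and
saccades follow a logistic position sigmoid with duration
`21 ms + 2.2 ms/°` and shape constant `alpha = 8`, giving the closed-form
peak velocity `amplitude * alpha / (4 * duration)` — about 465 °/s at 10°,
saturating near 900 °/s, inside the physiological envelope and under the
artifact caps. On 20-fixation scanpaths with 0.1° noise the detector
recovers ≥ 95% of fixation onsets within 10 ms; on noise-free scanpaths
the saccade count is exact. Test scanpaths keep planned targets at least
3° apart: closer re-fixations produce sub-degree saccades that belong to
the microsaccade regime, which neither the generator's truth model nor
the detector's threshold logic is meant to capture.

### AOIs and dwell

Heads and hands are circular AOIs (diameters 210 and 140 px) whose centres
move frame by frame; bodies are static per-dyad ellipses that contain the
moving circles. A fixation is classified by its *start point* against the
AOI geometry of the frame containing its onset
(`floor((onset - segment_start) * fps)`, clamped); circle membership is
inclusive, and any head or hand hit also counts as body (the nested-AOI
rule — so head ≤ body and hand ≤ body holds for every dwell cell by
construction). Dwell time per AOI is the summed duration of its fixations,
expressed as a proportion of all fixation time regardless of location;
per-segment proportions are aggregated as medians per participant × dyad ×
condition × AOI (six values per participant-dyad), while saccade counts
stay at segment grain for the Poisson model. Segments without fixation
time are undefined cells: dropped and logged, not imputed as zero.

`gen_aoi_tracks()` makes the synthetic tracks: Ornstein–Uhlenbeck wanders
around per-part anchors, projected back inside the body ellipse (with a
margin) whenever they stray, so confinement is guaranteed rather than
probable.

## The inference layer

### Models

All four study models are hierarchical regressions sampled with JAGS:

* **Ratings** (Gaussian): aggregated mean rating per participant × dyad ×
  condition on observer group × dyad type × IPS with participant and dyad
  random intercepts.
* **Dwell** (Gaussian, percent scale): adds the AOI factor (sum-coded into
  two columns) and its full factorial, with independent random slopes for
  the within factors and their interactions by participant and by dyad.
* **Saccades** (Poisson, log link): segment-level counts on the same
  factorial with random intercepts.
* **Gaze → rating** (Gaussian): mean rating per participant × dyad on the
  four z-scored gaze predictors (head/hand/body dwell, saccade count) with
  random intercepts.

Factors enter as sum-to-zero ±1 codes (ASD, mixed, high = +1), so a
two-level coefficient is half the marginal condition difference: a
dyad-type coefficient of −3.87 means mixed dyads are rated 7.74 points
lower. `marginal_difference()` computes the same quantity by averaging the
linear predictor over the design grid, which is also how the Poisson
model's group rates are read out on the response scale.

### Parametrization and priors

Random-effect terms are independent (one variance per term, no
correlations). The correlated alternative adds little at these
dimensionalities and costs a great deal of sampler efficiency; the
independent structure is the `||` convention of the mixed-model
literature.

Two parametrization details matter for honest Gibbs sampling. First,
a random-effect term's level effects are confounded with every
fixed-effect column expressible through that term — the intercept with any
intercept term, the observer-group code with participant intercepts, the
dyad-type code with dyad intercepts. The model projects each term's
effects onto the orthogonal complement of those columns inside the
sampler, so the betas stay identified and the projected-out directions
mix trivially under the prior. The sampled coefficient of a confounded
column is then the identified *total* of the fixed effect and the
cluster-mean component; because the likelihood depends only on that
total, the split between the two is exactly the Gaussian-prior
conditional, which is re-drawn per iteration in post-processing — so the
reported coefficient posteriors carry the full between-cluster
uncertainty of the unconstrained model (the test suite checks that
nominal 95% intervals cover null effects at better than 90% across
replicated studies). Second, variance parameters use a
Gamma(0.5, (0.1·SD(y))²) prior on the *precision*: fully conjugate, so
the SD updates are direct Gibbs draws, and nearly flat on log(SD)
between a soft floor at a few percent of the outcome SD and the outcome
scale. The known cost is that SDs cannot reach exactly zero — variance
estimates for truly-null terms settle at the floor rather than at zero —
which is conservative for the variance components and immaterial for the
location effects the hypotheses are about. Coefficients get normal(0, 2.5·SD(y)) priors (centred at
mean(y) for the intercept), the residual SD an exponential(1/SD(y));
Poisson models use scale 2.5 on the log link. All priors are recorded in
each fit's `config` and overridable per model.

Sampling uses JAGS's `glm` module (joint block updates of the linear
structure) for models up to ~120 coefficient nodes; beyond that the block
factorization costs more per effective draw than the base samplers with
the projection, so large models (the dwell model) run base samplers on
long thinned chains instead. Convergence is judged by rank-normalized
split-R-hat (robust to the skewed posteriors of variance parameters);
a fit fails loudly if any monitored parameter exceeds 1.01, carrying its
R-hat table in the error so the failure is diagnosable.

### Hypotheses

`test_hypothesis()` mirrors the study's decision rules: a *directed*
hypothesis is supported when the posterior probability of the hypothesised
sign reaches 1 − α with α = 0.05 (reported with the equal-tailed 90%
interval); an *undirected* hypothesis uses α = 0.025, i.e. a 95%
equal-tailed interval excluding zero. The full preregistered list —
dyad type, IPS, observer group, IPS × dyad type and group × dyad type on
ratings; group × AOI, IPS × AOI and dyad type × AOI on dwell; the group
effect on saccades — is assembled by `hypothesis_table()`. For the dwell
interactions the decision is carried by the head-axis sum-code column
(`aoi1`), the axis along which the generative group difference lives; both
AOI columns are available in the posterior for finer contrasts.

### Bayes-factor t-test

`bayes_t_test()` is the default-prior (JZS) two-sample Bayes factor:
Cauchy(√2/2) prior on the standardized effect, computed by numerical
integration over the inverse-gamma mixture representation, returned as
log BF10. It is used for the stimulus balance checks and sample
comparisons, with an automatic joint rank transform when a Shapiro–Wilk
check flags non-normality. The implementation is validated against an
independent dense-grid quadrature in the tests.

### Predictive checks

`predictive_check()` simulates replicated outcomes from prior or posterior
draws (random effects included) and locates each design cell's observed
statistic within the replicated distribution. On data generated from the
fitted model itself these quantiles are approximately uniform; the
self-consistency test asserts they stay inside (0.01, 0.99). Full
simulation-based calibration over the prior is out of scope; this lighter
check guards against gross misimplementation of the likelihood or the
random-effect plumbing, not against subtle prior miscalibration.

## The synthetic study and what it shows

`run_study()` wires everything together: coupled motion (optionally
rendered to frames and re-extracted), segment selection, synthetic
observers whose scanpaths are planned on the AOI tracks, event detection,
dwell aggregation, trial filtering (missed 4-s responses dropped,
participants under two-thirds completion excluded), model fitting and the
hypothesis table, all derived from one master seed and emitted as CSVs
plus a JSON manifest.

The generative defaults encode the study conditions: 8 dyads of 5 minutes
at 25 fps with coupling 0.5 at a 0.48 s lag; 64 trials per observer with a
6% miss rate (reproducing the observed ~60 of 64 completed trials);
rating effects at the published point estimates (dyad type −3.87,
IPS 0.83, group 1.07, interactions −0.06 and 0.24) around a grand mean of
55 with participant/dyad/residual SDs of 8/4/10, which reproduce the
published interval widths to the right order; group gaze profiles with
17.7 (ASD) vs 20.2 (COMP) saccades per segment and head-target
probabilities chosen so the head-dwell group difference is about 10
percentage points. The analysis drivers run 6 observers per group through
the full gaze pipeline, and parameter recovery at 30 + 30 observers (the
order of the study's 27 + 36 sample) through the table generators — sizes
chosen so each driver completes in minutes on a single core.

What passing tests show: the measurement chain is internally exact (oracle
equivalence and round trips), the detector recovers known events at
realistic noise, selection reproduces the combinatorial structure of the
stimulus set, and the models recover the generative coefficients they are
pointed at. What they do not show: anything about real videos (frames are
abstract pixel flips, not silhouettes; real MEA series have burst
structure, camera noise and cross-interactant occlusion), real gaze
(no drift, no pursuit, no pupil artifacts, stationary noise), or the
original participant estimates — the published values function as
generative truth for recovery, not as quantities this package claims to
re-estimate from data.

## Numerical conventions and edge cases

* Quantiles everywhere are R type 7 (linear interpolation); the
  middle-50% motion filter uses the *closed* interval [Q1, Q3].
* Selection ties break to the earlier start frame; picked segments never
  overlap within a dyad.
* `peak_ips()` on an all-undefined lag row raises an error rather than
  returning 0 — a constant-motion dyad has no defined synchrony.
* `rescale_mea()` refuses to rescale twice; series carry a `rescaled`
  flag.
* Event duration conventions are sample-inclusive: an event covering k
  samples at 500 Hz lasts k/500 s; minimum durations are enforced on that
  scale.
* Zero-variance samples, empty ROIs, off-screen targets, rank-deficient
  designs and all-invalid gaze raise typed, message-bearing errors at the
  stage that detects them, with the dyad or participant named where
  relevant.
* The frame/second boundary lives in one place: every generator and
  consumer takes `fps` (default 25; the source videos' rate is not
  published) and all conversions flow through it.
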