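---
title: "Measuring courtship display consistency with recurrence quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring courtship display consistency with recurrence quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartwheel)
```

## The system and the measurement

In the cooperative cartwheel display of swallow-tailed manakins, two to
six males queue on a perch and take turns performing a vertical hover
flight in front of a female, each returning to the back of the row after
his turn. The measurable trace of the collective performance is
one-dimensional: the vertical position of whichever male currently
occupies the edge of the dance (the spot next to the female), sampled at
a fixed frame rate. All of this package's machinery exists to produce
that trace (from rendered frames or directly from a generative model),
to quantify its temporal consistency, and to relate consistency to group
size and to female visitation and copulation rates.

Positions are stored in raw raster pixel coordinates throughout: the
image y-axis points downward, so a higher flight is a *smaller* y.
Plotting code may invert the axis; the analysis never does.

## The synthetic-data generator

`simulate_display_series()` models a display as a queue of flight events
with nominal inter-flight interval $1/f$ (default flight rate
$f = 1.89$ Hz, the tempo of field displays). Each flight is a
raised-cosine excursion from the perch height (`baseline_y`, default
120 px) to `baseline_y - hop_amplitude` (default amplitude 50 px) and
back over one nominal interval; a smooth waveform gives realistic peak
detection and non-trivial recurrence structure, which a square pulse
would not. Three noise sources, all reproducible from `seed`:

* `timing_noise_sd` (s) jitters each inter-flight interval. The
  effective SD is inflated by `group_jitter_per_male` (default 0.25) per
  additional male, modelling imprecision accumulating at queue handoffs
  in larger courts; setting it to 0 generates the null in which group
  size has no timing effect. How per-male jitter maps to group-level
  entropy is not empirically constrained; this linear inflation is a
  modelling choice, flagged as such.
* `height_noise_sd` (px) jitters the amplitude of whole flights.
* `motion_noise_sd` (px) jitters every sample — fine-motor wobble of the
  head along the flight path. Default 0 (a perfectly smooth path).

The trace is identity-free by construction: it depends on the flight
event sequence only, never on which male flies, matching how the field
series is defined. Noise draws are taken from fixed-size streams, so
with `group_jitter_per_male = 0` the trace is bit-identical across group
sizes under one seed.

Why a dedicated wobble parameter? Microstate entropy is advertised as
the metric sensitive to subtle dynamical change, and one might expect
any added noise to raise it. Empirically that is false for per-flight
amplitude noise: unequal flight heights *sparsify* the recurrence
matrix, sampled 2×2 blocks concentrate on the all-zero microstate, and
entropy at the entropy-maximising radius stays flat or drops slightly.
Per-sample wobble instead fragments recurrence structures at the block
scale and raises entropy monotonically (the property suite verifies this
with a paired design across wobble levels). Fine-scale imprecision —
not flight-to-flight amplitude variation — is what this metric detects,
which is also the biologically interesting axis: a male in a large queue
may keep his amplitude while losing micro-precision.

`simulate_display_video()` rasterises a display into RGB frames: a
neutral background, one blob per male (dark body, square head patch
coloured inside the tracked red range), males in a row with the edge
male executing the flight, and an optional red-free female one slot
beyond the edge. The geometry simplifies the real dance — queued males
do not swap places — which is immaterial to the tracker because the
series is read only at the edge of the dance. The default 240×160 frame
holds a six-male court plus female without overlapping detections. The
head patch (16 px) is twice the default tracker quadrant (8 px), so
whatever the head's alignment some quadrant is fully covered — a single
head can always saturate a quadrant, which is what makes a 40%-coverage
rule meaningful. `truth_trace` records the rendered head-centre y per
frame, the ground truth all tracker fidelity statements refer to.

## The tracker

Per frame: (i) `color_mask()` marks pixels whose RGB channels all lie in
`[color_lo, color_hi]` (defaults `[150,0,0]`–`[255,100,100]`, inclusive);
(ii) `quadrant_coverage()` reports the masked fraction of each grid
cell, using the actual area of smaller edge cells; (iii)
`detect_males()` thresholds coverage at `coverage_threshold` (default
0.40) and merges 8-connected registered cells into one detection at
their coverage-weighted centroid — sub-pixel, stable, and robust to a
head straddling a grid line. Raising the threshold can only remove
detections; widening the colour range can only add mask pixels (both are
tested properties).

`edge_male_series()` then keeps, per frame, the detection at the extreme
horizontal position toward the female (`female_column`) or toward the
configured dance side; with `dance_direction = "auto"` the side is
inferred from the sign of the median frame-to-frame displacement of mean
detection x (ties default to the right side). A tracked male is retained
until another detection passes him horizontally by more than
`handoff_eps` (default 0: strict passing, the simplest reading of the
handoff moment in the cartwheel queue; a hysteresis band is available
for noisy footage). Detection dropouts up to `max_gap` frames (default
3) are bridged by carrying the last position; longer dropouts split the
series and the longest segment is returned with a warning — the field
procedure is silent on gaps, so the policy is deliberately conservative
and loud. Finally `downsample_series()` reduces 30 fps to the analysis
rate of 15 fps by keeping every second sample (the factor must be an
integer; no resampling filter is applied, and a band-limited signal
below the target Nyquist keeps its oscillation count).

The grid geometry is a free parameter of the method: the default cell
(8 px) is about half the rendered head diameter so a head saturates a
cell regardless of alignment. `calibrate_threshold()` reproduces the
operating-characteristic-style sweep used to fix the 40% default: over
labelled scenes it counts, per frame and candidate threshold, missed
males plus spurious detections, and returns the error-minimising
threshold, breaking ties toward the smaller (more sensitive) value.
Centroid output is the default; a coarser quadrant-index mode would add
nothing the tests could distinguish at the default geometry.

## Recurrence quantification

The recurrence matrix of a series $y$ is
$R_{ij} = \mathbf{1}\{|y_i - y_j| \le r\}$ — symmetric, unit main
diagonal. Two conventions deliberately fixed here:

* **No phase-space embedding.** Recurrence is read directly on the
  scalar height series (embedding dimension 1); the question is about
  coincident vertical positions, not attractor reconstruction. An
  optional `(m, τ)` embedding hook exists (`embed_dim`, `embed_lag`) but
  is off by default.
* **Inclusive comparison**, so radius 0 reproduces exact-match
  recurrence.

RR is the percentage of recurrent cells, main diagonal included (the
literal "percentage of cells that are recurrent"). DET and LAM, by
contrast, are computed on line histograms that exclude the line of
identity (a Theiler window of 1): without the exclusion every series,
however erratic, would carry one perfect diagonal of length $N$ and DET
would be inflated by trivially-true self-recurrence. Whether the
original field analysis excluded it is not documented; both behaviours
are exposed (`exclude_diag`), exclusion is the default, and the tests
pin the convention exactly against a naive enumeration oracle. Minimum
line lengths are $l_{\min} = v_{\min} = 2$, the standard floor below
which a "line" is a point. Degenerate conventions worth knowing: an
identity matrix has empty histograms, and DET/LAM return 0 on an empty
denominator; an all-ones matrix (constant series) has
$\mathrm{DET} = 100(T-2)/T$ with $T = N^2 - N$, because the two corner
diagonals have length 1 — not the 100 a rounded intuition suggests.

Microstate entropy samples `n_samples` (default 10 000) 2×2 blocks
uniformly with replacement from all $(N-1)^2$ positions (blocks may
straddle the main diagonal), maps each to one of 16 microstates, and
returns the Shannon entropy of the empirical distribution in nats
(maximum $\ln 16 \approx 2.77$). An exhaustive mode enumerates every
position and equals the exact plug-in entropy — the tests use it as the
sampling oracle. With 10 000 draws the plug-in bias is
$(K-1)/2n \approx 0.00075$ nats, negligible against the ±0.02 tolerance
used for the Bernoulli limit check.

The radius is selected by the maximum-entropy principle: entropy is
evaluated on a grid of 50 candidates spanning 1–100% of the series range
and the *smallest* candidate attaining the maximum is returned
(`select_radius()`). The same sampling seed is reused at every
candidate so the entropy curve is smooth in $r$ rather than jittered by
resampling; a constant series has no scale and returns radius 0. Grid
density and tie-break are conventions of this implementation; a
seed-stability test checks the selected radius moves by at most one grid
step when the sampling seed changes. `rqa_summary()` selects the radius
once, builds the matrix once, and reports RR/DET/LAM/MCEntr/r together
with the sampling parameters, so a stored result is fully reproducible.

## Display metrics

Each vertical oscillation is one cartwheel flight, so
`cartwheel_frequency()` counts upward peaks (toward smaller raster y)
with topographic prominence of at least 25% of the series range and
divides by the duration. A prominence floor, rather than zero-crossing
counting, is robust to the baseline drift that imperfect tracking
introduces; the floor is the oscillation-counting rule of this package,
stated rather than inherited. Full peaks are counted (not half-cycles).
The estimate is exact on pure tones (a 2 Hz sinusoid over 10 s yields
exactly 2.0 Hz) and recovers the generator's 1.89 Hz within 5% under
field-like noise. `female_rates()` is plain arithmetic: event counts
over recording hours.

## Inference

`fit_gamma_glmm()` fits `response ~ predictors + (1 | court)` with a
Gamma distribution and log link via glmmTMB, which in our experience
converges far more reliably than alternatives for Gamma random-intercept
models of this size; a cross-check test confirms agreement with an
independent lme4 fit on the same data. Wald statistics are
$\chi^2 = (\hat\beta/\mathrm{se})^2$ on 1 d.f. (a likelihood-ratio
alternative would require refitting per term; Wald matches the
single-fit reporting layout used for these analyses). Standardizing
predictors (default for the female-choice models) is a pure
reparameterisation — the tests assert identical log-likelihoods — and
makes coefficients per-SD effects; the group-size models are fit
unstandardized so slopes read per additional male. Zero rates (common
for copulations) are shifted to half the smallest positive observed
rate before a Gamma fit, and the shift is recorded in the result; an
all-zero response is an error, not a silent fit. Non-convergence or a
single-level grouping factor triggers a fixed-effects Gamma GLM fallback
with a warning and an engine flag, never a silent substitution.

`vif_screen()` iteratively computes $\mathrm{VIF}_k = 1/(1-R^2_k)$ from
regressing each predictor on the rest, dropping the worst offender while
any VIF exceeds 3.5 (perfect collinearity ⇒ infinite VIF, dropped
first). On datasets from `simulate_court_dataset()` the screen
reproduces the field outcome: determinism, generated as a near-linear
blend of laminarity and entropy, shows VIF ≈ 9 and is excluded, after
which all remaining VIFs fall below threshold.

## The court-level generator and what passing tests show

`simulate_court_dataset()` draws, per court, independent normal random
intercepts (SD `court_sd`, default 0.3) for each metric and for the rate
scale; per display, a male count uniform on 2–6, Gamma-distributed
metrics with log-means linear in male count (slope
`beta_entropy_vs_males`, default 0.04, on entropy; 0 elsewhere), and
Poisson visit/copulation counts with exposure `recording_hours` (default
5 h) and log-rates linear in the standardized predictors (defaults
+0.18 for RR, −0.16 for entropy, −0.04 for male count, echoing the
field-scale effect structure; copulations share the betas with a much
lower intercept, −2.98). Frequency noise uses Gamma shape 14, i.e. a
CV of about 27%. Counts are drawn per display so the display-level GLMM
is correctly specified; court-level rates (counts pooled over a court's
recording time) are what `female_rates()` computes in the pipeline, and
duplicating a court rate across its displays — the random intercept
absorbing the induced dependence — is the supported join for field-style
data.

Recovery experiments define what the inference stage is trusted to do:
over 100 replicates of 30 courts × 10 displays, the entropy–group-size
slope 0.04 is recovered with mean bias below 0.01 and 95% CI coverage
above 90%; on null data the Wald test's type-I error at α = 0.05 lies
within [0.02, 0.09] over 200 replicates. These are properties of the
*model on generator data*. The generator emulates the study conditions
— group sizes, tempo, court structure, rate scales — but not occlusion,
lighting, plumage variation, camera shake, or display start/end
ambiguity; tracker fidelity of ≥99% on noise-free rendered scenes
bounds implementation error, not field performance.

## Numerical and reproducibility choices

* All stochastic steps take explicit seeds and restore the global RNG
  state (`withr::with_seed`); `rqa_summary()` output is bit-identical
  across reruns for a fixed seed.
* `run_pipeline()` fans one global seed out to deterministic per-stage,
  per-display child seeds (kept below 2³¹), so stages can be rerun
  independently; the manifest lists every artifact with an MD5 checksum
  and the acceptance script verifies two full runs agree checksum for
  checksum.
* Problem sizes in the shipped tests — e.g. 10-second scenes at 30 fps,
  30 × 10 court experiments, 200-replicate null studies — are chosen so
  the whole suite runs in minutes on a single core while leaving every
  statistical check adequately powered; all scale linearly if larger
  experiments are wanted.

## Known limitations

* MP4/AVI decoding is not provided; frames are consumed as PNG
  directories or in-memory arrays. Decoded video from any external tool
  can be dropped into a frame directory.
* The tracker assumes the tracked colour is unique to male heads in the
  scene, as in the field protocol; no appearance model or identity
  tracking is attempted (identities are deliberately not part of the
  series).
* The entropy-maximising radius makes MCEntr comparable across displays
  recorded under one protocol, but radii (and hence metrics) from
  different geometries or zoom levels are not directly comparable.
* Gamma models of shifted zero-heavy copulation rates are a pragmatic
  convention; with many structural zeros a hurdle model would be the
  honest alternative, and the zero-shift count in the result flags when
  that territory is near.
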