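# cartwheel

Quantifying the consistency of cooperative courtship displays with
recurrence quantification analysis (RQA).

## The problem

Male swallow-tailed manakins (*Chiroxiphia caudata*) display in courts of
two to six birds: the males queue on a perch and take turns performing
vertical hover ("cartwheel") flights in front of a visiting female, each
male cycling to the back of the row after his flight. Female choice in
such cooperative systems may track the *consistency* of the group
performance — how repeatable and temporally precise the collective
movement is — rather than its raw tempo or the number of performers.

`cartwheel` packages the full analysis chain for this question, testable
end to end on synthetic data with known ground truth:

1. **Scene synthesis** — `simulate_display_series()`,
   `simulate_display_video()`, `simulate_court_dataset()` generate
   displays, rendered RGB frames and multi-court datasets with
   controllable timing, height and fine-motor noise.
2. **Tracking** — `track_scene()` extracts the displaying male's
   vertical-position time series from frames by colour-range quadrant
   scanning: a pixel is "red" if every RGB channel lies in
   [150, 0, 0]–[255, 100, 100]; a quadrant registers a male when ≥ 40% of
   it is covered (threshold calibratable with `calibrate_threshold()`);
   detections merge across touching quadrants; per frame the series
   records the male at the edge of the dance (closest to the female),
   with handoff when another male passes him. Series are downsampled to
   15 fps.
3. **Recurrence quantification** — `rqa_summary()` computes, from the
   binary recurrence matrix `R[i,j] = 1 ⇔ |yᵢ − yⱼ| ≤ r`:
   - **RR** (recurrence rate): % of recurrent cells — inverse variability
     of flight heights;
   - **DET** (determinism): % of recurrent mass on diagonal lines of
     length ≥ 2 — predictability of future from past motion;
   - **LAM** (laminarity): the vertical-line analogue — share of
     stationary episodes;
   - **MCEntr** (microstate entropy): Shannon entropy (nats) of randomly
     sampled 2×2 sub-blocks of the matrix, sensitive to subtle dynamical
     changes (maximum ln 16 ≈ 2.77);
   - **r**: the recurrence radius, chosen by maximising the microstate
     entropy over a candidate grid (maximum-entropy principle).

   Consistency reads as high RR and DET with low MCEntr.
4. **Display metrics** — `cartwheel_frequency()` (prominence-based peak
   count per second; each vertical oscillation is one flight) and
   `female_rates()` (visits and copulations per recording hour).
5. **Inference** — `run_group_size_analysis()` and
   `run_female_choice_analysis()` fit Gamma log-link mixed models
   (`glmmTMB`) with a court random intercept, after Spearman screening
   (`spearman_matrix()`) and iterative VIF collinearity exclusion
   (`vif_screen()`, threshold 3.5). Wald χ² = (β̂/se)².
6. **Pipeline** — `run_pipeline()` chains simulate → track → rqa →
   metrics → analyze with a single seed fanned out per stage, writing
   CSV/JSON artifacts and an MD5 manifest so reruns are verifiably
   bit-identical. A thin CLI lives at `inst/cli/cartwheel.R`.

## Worked example

```r
library(cartwheel)

params <- display_params(n_males = 4, duration = 20, seed = 42)
series <- downsample_series(simulate_display_series(params)$series, 15)
series
#> <display_series> 300 samples @ 15 fps (20.00 s)
#>   y range: [64.0, 120.0] px
rqa_summary(series, seed = 1)
#> <rqa_metrics> n=300  r=14.1
#>   RR   40.73 %
#>   DET  69.84 %
#>   LAM  92.32 %
#>   MCEntr 2.4191 nats (q=2, 10000 samples)
cartwheel_frequency(series)
#> [1] 1.85
```

The trace oscillates between the perch (y = 120 px; the raster y-axis
points down) and the flight apex (~64 px) about 1.85 times per second.
At the entropy-maximising radius (14.1 px) 40.7% of time pairs recur;
most recurrent mass sits on long diagonal/vertical lines (DET 69.8%,
LAM 92.3%), i.e. a predictable, strongly periodic display.

Group-level inference on a simulated 10-court experiment:

```r
courts <- simulate_court_dataset(court_sim_params(
  n_courts = 10, displays_per_court = 8, seed = 42))
run_group_size_analysis(courts)
#> <group_size_analysis> effect of n_males per response:
#>    response estimate      se  chisq        p  engine
#> 1 frequency  0.00572 0.01607  0.127 0.721854 glmmTMB
#> 2        rr -0.00801 0.01313  0.372 0.541863 glmmTMB
#> 3       det -0.01613 0.00617  6.842 0.008904 glmmTMB
#> 4       lam -0.00804 0.01104  0.531 0.466124 glmmTMB
#> 5    mcentr  0.04773 0.01304 13.393 0.000253 glmmTMB
#> 6     r_sel  0.02340 0.01360  2.960 0.085335 glmmTMB
```

The generator's only built-in group-size effect is on microstate entropy
(+0.04 per male on the log scale); the fit recovers it (0.048 ± 0.013,
χ² = 13.4). The smaller determinism effect is inherited: DET is generated
as a near-linear blend of LAM and MCEntr, the same redundancy that makes
the VIF screen exclude it in the female-choice models:

```r
fc <- run_female_choice_analysis(courts)
fc$vif$dropped
#> [1] "det"
fc$visitation$coefficients[, c("term", "estimate", "se", "chisq", "p")]
#>          term estimate    se chisq      p
#> 1 (Intercept)   -0.061 0.113 0.291     NA
#> 2     n_males   -0.011 0.060 0.034 0.8539
#> 3   frequency   -0.119 0.060 3.978 0.0461
#> 4          rr    0.185 0.108 2.928 0.0870
#> 5         lam    0.090 0.093 0.932 0.3343
#> 6      mcentr   -0.279 0.089 9.864 0.0017
```

Predictors are standardized, so estimates are per-SD effects on the log
visitation rate: visitation rises with recurrence rate and falls with
microstate entropy — females favour consistent displays.

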