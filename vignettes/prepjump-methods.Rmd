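---
title: "Models and methods: preparatory and movement subspaces in target-jump reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: preparatory and movement subspaces in target-jump reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

During delayed reaching, motor-cortical population activity separates into
a small number of functional classes of dimensions: *preparatory*
dimensions that become active during the instructed delay and differ
across reach directions, *movement* dimensions that are active during
execution, and a largely direction-independent *trigger* component whose
change precedes movement onset. A last-moment target jump — the reach
target moving after the go cue but before the hand starts — forces a
mid-course correction and asks a sharp question: is the correction
*re-prepared* through the same preparatory dimensions used during the
delay (preparation and execution running simultaneously), or does activity
move directly between movement-dimension patterns without re-engaging
preparation?

`prepjump` implements the full analysis chain needed to answer this on a
single session of simultaneously recorded units, and a synthetic-session
generator with exported ground truth so that every stage can be tested as
a recovery problem.

## Analysis pipeline

1. **Rates.** Each unit's spike train is convolved with a 30 ms Gaussian
   kernel, evaluated in continuous time on a 10 ms grid aligned to task
   events. The kernel is truncated at 5 s.d. and renormalized to the
   observed trial window, so rates do not droop at trial edges; grid
   points outside the recorded window are `NA`. Each unit is then
   *soft-normalized*: rates concatenated over all trials are divided by
   `max(sd, 1)` — the floor prevents near-silent units from being
   inflated into population analyses.
2. **Behaviour.** Movement onset is the first time, tracing backward from
   peak hand speed, that speed falls below 5% of the peak (speed from
   central differences with a light 3-sample smoothing). The *initial
   reach angle* is the hand heading at 1 cm from the start position,
   normalized per jump condition so that −1 is the first target's
   direction and +1 the final target's, linearly along the shorter arc
   (overshoots exceed ±1). A 4-parameter logistic of normalized angle
   against jump→onset latency summarizes each jump condition; its 50%
   crossing is the behavioural transition time. Conditions whose
   bootstrap 95% CI half-width on the 50% crossing is not below 50 ms
   are excluded from crossing-time statistics; one-way ANOVAs compare
   crossing times and slopes across jump angles.
3. **Trigger dimension.** A linear soft-margin SVM (cost 1) is trained on
   single-timepoint population vectors from all non-jump trials to
   separate a pre-movement epoch (−360 to −180 ms before onset) from a
   peri-movement epoch (−120 to +60 ms); 10% of non-jump trials are held
   out for accuracy. The unit-normalized hyperplane normal is the trigger
   dimension; the signed decision value's first upward zero crossing after
   the go cue (linearly interpolated on the 10 ms grid) is the per-trial
   neural trigger event. Concentration of decoder weights on a few units
   is tested by comparing the kurtosis (fourth standardized moment) of
   the weight profile against 10,000 random unit vectors on the sphere.
4. **Single-trial prediction.** Per jump condition, the behaviour sigmoid
   is fitted to (trigger − jump) offsets; leave-one-out predictions give
   `R² = 1 − SS_res/SS_tot`, which may be negative out of sample, and a
   side-of-zero classification accuracy.
5. **Subspaces.** Non-jump condition averages are restricted to the delay
   epoch (0–300 ms after target onset, using only trials whose delay
   covers the epoch) and the movement epoch (0–300 ms after movement
   onset), centered across conditions at each timepoint, projected into
   the orthogonal complement of the trigger dimension, and row-centered.
   Subspace sizes are the smallest PCA dimensionalities explaining
   strictly over 70% of each epoch's variance. The preparatory and
   movement bases jointly maximize the symmetric trace-ratio objective
   (each trace normalized by the sum of its covariance's top singular
   values, so the objective is at most 1) under mutual orthogonality —
   projected gradient ascent on the Stiefel manifold with QR retraction,
   backtracking line search (monotone by construction), tolerance 1e-9,
   and 10 deterministic starts (one spectral, nine seeded random).
6. **Jump responses.** Condition averages of jump trials, split by the
   behavioural initial-direction label, are compared with non-jump
   trajectories by Euclidean distance within each subspace, per alignment
   (target on, go cue, movement onset). The headline statistic averages
   the preparatory-space distance 0–200 ms after movement onset and
   compares, across jump conditions, jump-initiated-first distances with
   the non-jump first-vs-final baseline by a two-sided Wilcoxon rank-sum
   test (exact when both sides have ≤ 25 conditions and no ties).

### Numerical and design choices

* **Movement-epoch window.** The epoch end is set to 300 ms after onset,
  mirroring the 300 ms delay epoch; it is exposed as a parameter.
* **Centering.** Epoch matrices are centered across conditions at each
  timepoint before the covariances are formed. This removes
  condition-invariant, time-varying components — in particular any
  residual initiation signal that survives the (estimated, hence
  imperfect) trigger null-space projection — which would otherwise claim
  subspace dimensions despite carrying no direction information. The
  pooled-mean alternative is available (`center = "pooled"`).
* **Trial-count matching in distance panels.** A Euclidean distance
  between noisy trial-averages is biased upward by sampling noise, and
  the bias grows as trial counts shrink. Jump trials initiated toward the
  first target are typically few, so comparing their distances against
  baselines averaged over many non-jump trials would inflate the jump
  side systematically and miscalibrate the rank-sum test. The panel
  therefore subsamples the non-jump baseline trials (seeded) to match the
  jump group's count; the common final-target reference stays at full
  count. Setting `match_trials = FALSE` reproduces the unmatched
  behaviour.
* **Sigmoid fitting.** The 4-parameter logistic is fitted by profiling
  the asymptotes out with closed-form bounded least squares (asymptotes
  in [−1.5, 0] and [0, 1.5], tolerating overshoot angles) inside a
  deterministic 5-start Nelder–Mead over (t50, log scale); sparse
  transitions make the problem multimodal, hence the multi-start. The CI
  on t50 is a seeded 1,000-resample trial bootstrap (percentile).
  Resamples without both behavioural regimes are dropped; if fewer than
  half survive the CI is reported as infinite (the condition then fails
  the CI filter).
* **Zero crossings.** Decision values are not smoothed beyond the 30 ms
  rate kernel; crossings are linearly interpolated between grid samples
  and constrained to the go-cue-to-trial-end window.
* **Decoder regularization and training size.** The soft-margin cost
  defaults to 0.001: at single-session trial counts a cost-1 max-margin
  solution is carried by a few boundary points and estimates the
  initiation dimension noisily, whereas a strongly regularized margin
  shrinks toward the epoch-difference direction and improves held-out
  accuracy, dimension recovery and crossing timing together. Training is
  capped at a seeded subsample of 300 trials (weights saturate well
  below that; quadratic-programming time does not), with held-out
  evaluation always on the full held-out set.
* **Kurtosis convention.** Pearson (non-excess) kurtosis with population
  moments; the spherical null makes the convention immaterial to
  p-values.
* **Exclusions are outcomes.** Sessions with fewer than 10 units, jump
  trials whose detected onset precedes the jump, conditions failing the
  CI filter, and groups without trials are recorded with reasons in the
  run report rather than raised as errors.

## The synthetic-session generator

The generator produces sessions with the latent structure the analysis
assumes, plus the ground truth needed for recovery testing. Defaults
describe a realistic recording day and are the package's reference study
conditions:

* 60 units, 400 trials, 8 reach targets on a 10 cm ring, 20% jump
  trials over eight ordered target pairs (45–180°), delay uniform 0–900 ms,
  non-jump reaction times Normal(300, 50) ms (truncated at 180 ms).
* Latent bases: an exactly orthonormal set of `d_prep = 3` preparatory,
  `d_move = 3` movement dimensions and one trigger vector. The trigger
  loadings are same-signed across units — the initiation component raises
  firing broadly — which also keeps units away from the rate floor during
  movement. Per-target patterns are low-order Fourier features of target
  angle (equal variance across the ring, so the 70% rule should find the
  generative dimensionality).
* Time courses: preparatory latents ramp up ~60 ms after target onset
  (80 ms rise) and collapse at the trigger event (preparation hands off
  to execution by movement onset); movement latents are active from just
  before onset to ~350 ms after; the trigger latent ramps through its
  threshold `trigger_lead = 150` ms before onset with 20 ms jitter. Its
  amplitude (default 1.25 in tuned-pattern units) makes the
  condition-invariant initiation component a large, broadly shared rate
  increase while keeping per-unit initiation drives within the
  quasi-linear range of the softplus link, so the generative trigger
  direction remains well-defined in rate space.
* Behavioural rule: a jump reach is initiated toward the first target
  exactly when the true trigger crossing precedes the jump. With
  trigger jitter σ, the probability of initiating toward the final
  target at jump→onset latency ℓ is `pnorm((ℓ − trigger_lead)/σ)` — the
  closed-form 50% point used by the recovery tests is `trigger_lead`.
* Emission: per-unit rate `softplus(baseline + gain·B·z + noise)` with
  baselines 10–30 spikes/s and direction-tuning depths of roughly 20–40
  spikes/s — an active, strongly tuned arm-area population with peak
  movement-epoch rates below ~80 spikes/s. Because spiking is Poisson,
  the signal-to-noise ratio of trial-averaged rates grows with the firing
  rate when tuning scales with baseline; this regime is what makes the
  recovery targets attainable at a few hundred trials per session. Slow
  per-unit Gaussian noise has s.d. equal to the tuned-drive s.d. divided
  by `snr` (default 2; the trigger component is excluded from the
  reference so `snr` measures condition-separating signal). Spikes are
  drawn by inhomogeneous-Poisson thinning at 1 kHz.
* Kinematics: minimum-jerk reaches toward the initially selected target;
  corrected reaches superimpose a second minimum-jerk submovement toward
  the final target starting `correction_latency + motor_delay` after the
  jump (never before the hand clears the 1 cm measurement radius, so the
  initial angle reflects the initial plan); heading noise of 6° decays
  over the reach so endpoints land on the target; 0.5 mm tracking
  jitter.
* `mode = "always_prepare"` (default) re-engages the preparatory latents
  after every jump — the structure whose detection the pipeline exists
  for; `mode = "direct_response"` corrects late jumps in movement latents
  only, giving a null model the pipeline should *not* flag.
  `jump_max_lead` narrows the jump window toward movement onset,
  emulating sessions whose jump timing was placed late to obtain
  first-target initiations.

**What the generator does not emulate.** Non-Poisson spiking history
(refractoriness, bursting), unit-to-unit noise correlations beyond the
shared latents, slow drifts across the session, eye movements, EMG, the
occasional anti-directional transient in preparatory dimensions after a
jump (an optional phenomenon in real data that is not reproduced), and
any nonlinearity beyond the softplus link. Passing recovery tests
therefore shows the pipeline is correct and well-calibrated under the
assumed model class, not that real cortex satisfies those assumptions.

## Problem sizes used by the test suite

Recovery tests use 20 default-condition sessions (60 units, 400
trials). Hypothesis-discrimination tests run the full pipeline on 50
sessions per mode at a reduced size chosen to keep the suite fast while
preserving the effect: 16 units, 220 trials, eight jump pairs, 40% jumps
with a late (≤180 ms before onset) jump window, 50-resample sigmoid CIs
and 3 optimizer starts. The behavioural CI-filter monotonicity check uses
150-resample bootstraps; kurtosis calibration uses 2,000-draw nulls per
test (the package default is 10,000). The Eq.-style trace-ratio optimizer
is validated against an exhaustive 5-angle grid search (18° coarse grid,
refined by thirds to below 0.1°) in ambient dimension 4.

## A worked run

```{r}
library(prepjump)

gs <- generate_session(generator_config(seed = 1))
run <- run_pipeline(gs$session, pipeline_config(seed = 1))
run
glance(run)

# behavioural psychometrics per jump condition
run$behavior$fits

# variance shares (delay vs movement epochs)
plot_variance_trace(run$variance$delay, normalized = TRUE)

# jump-distance traces and the movement-epoch test
plot_distance_panel(run$distance$panel)
run$distance$test
```

## Known limitations

* The optimizer identifies subspaces, not bases; compare recovered and
  generative spaces by principal angles only.
* The 5%-of-peak onset rule lags smooth speed profiles by roughly one
  kinematic sample plus the rise to threshold (~10–15 ms here); all
  latency-based quantities inherit this detector property.
* The estimated trigger dimension is used as the null-space constraint;
  its estimation error (cosine ≈ 0.95 at default conditions) propagates
  a small rotation into the recovered subspaces.
* Exact rank-sum p-values switch to a tie-corrected normal approximation
  when ties occur or either side exceeds 25 conditions.
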