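---
title: "Quantifying memory-state gating of stimulation-evoked cortical input"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying memory-state gating of stimulation-evoked cortical input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmgating)
```

## The problem

During a memory-guided saccade (MGS) task, a monkey fixates, sees a brief
peripheral cue either inside (`In`) or outside (`Out`) a recorded neuron's
response field, holds the location in working memory through a delay, and
then makes a saccade to it. If single electrical pulses are delivered to an
upstream visual area (V4) on half of the trials, the spikes evoked in
downstream prefrontal (FEF) neurons probe the *efficacy* of the
corticocortical connection trial by trial — and whether that efficacy
depends on what is currently held in memory.

`wmgating` implements the full analysis chain for such experiments:
identifying which units receive input (and which are activated
antidromically), measuring evoked efficacy, latency and pairwise synchrony
per memory condition, and characterising the visual/memory/motor profile of
each unit. A seeded synthetic-session generator with the same statistical
structure makes every stage testable without animal data.

## Time conventions

All times are milliseconds from trial start, real-valued. Analysis bins are
half-open 1 ms intervals `[t, t + 1)`, and every window is half-open at its
right edge; a spike exactly at the edge belongs to the next bin. Stimulation
occurs 500 ms after fixation onset, cue onset or cue offset, or 150 ms after
the go cue, depending on the stimulated epoch. Non-stimulated trials are
assigned a *virtual* stimulation time from the same schedule, so "the same
time window on non-stimulated trials" is always well defined; when several
stimulation epochs are pooled, each non-stimulated trial contributes one
matched window per epoch.

The first `artifact_end` ms after the pulse (default 3 ms) are treated as
blanked by the stimulation artifact. The default is configurable; 3 ms keeps
the 5–9 ms evoked-response window untouched while covering the artifact
transient.

## Detecting activation and estimating latency

For each unit, the probability of firing in each 1 ms bin is computed over
stimulated trials and over time-matched non-stimulated windows
(`peristim_probability()`). The *evoked latency* is the left edge of the
earliest searchable bin whose stimulated-trial firing probability
significantly exceeds the matched non-stimulated probability
(`detect_latency()`). Design choices here, made where the procedure was
genuinely open:

* **Per-bin test.** A one-sided Fisher exact two-proportion test (computed
  via the hypergeometric tail) at `alpha = 0.05`, with no multiplicity
  correction across bins. The search is limited to bins with left edges in
  `(artifact_end, 20)` ms — 16 bins with the defaults — which bounds the
  family-wise false-activation probability at roughly
  `1 - (1 - alpha_eff)^16`; because the exact test is conservative at
  millisecond bin occupancies, the realised family-wise rate is well below
  the nominal 0.15 bound (see the acceptance tests, which require >= 85%
  silence on null units).
* **First significant bin, not peak bin.** This matches the operational
  definition of latency, but it has a measurable cost: for units with long
  latencies, false positives accumulate over the preceding searchable bins,
  so a small fraction of detections land early. At 10 Hz background, 200
  trials per arm and evoked probability 0.5, about 2% of detections across
  configured latencies of 5–12 ms are off by more than 1 ms.

Latencies below 10 ms classify a unit as *visual-recipient* (fast,
consistent with monosynaptic transmission); 10 ms or more as *slow input*;
no significant bin as *non-activated*.

### Bimodality of the latency distribution

Across units, activation latencies form two groups (near 6.5 ms and near
12.7 ms). `dip_bimodality()` tests unimodality with Hartigan's dip
statistic. No dip implementation exists among this package's dependencies,
so the statistic is computed from first principles (`src/dip.cpp`): the dip
is the smallest half-width `d` such that a unimodal CDF — convex up to a
mode, concave after, possibly with an atom at the mode — fits inside the
band of half-width `d` around the sample ECDF. Feasibility at a given `d`
reduces to finding a split index where a convex in-band prefix and a
concave in-band suffix share a feasible value; convex (concave) in-band
feasibility is a chord condition on the band bounds. Bisection on `d` gives
the dip to ~1e-12. The implementation is validated against hand-derivable
exact values (dip of two distinct points = 1/4, of any three distinct
points = 1/6, of n equally spaced points = 1/(2n), of two balanced point
masses = 1/4) and against an independent triple-loop reference
implementation in the test suite.

The p-value is a parametric bootstrap against the uniform null — the
least-favourable unimodal distribution — so the test is conservative for
peaked unimodal alternatives. The null depends only on the sample size and
can be precomputed (`dip_null()`) and shared across many tests.

## The collision test

Stimulation can also activate FEF neurons *antidromically* through their own
axons projecting to V4. The collision test separates the two: if a
spontaneous spike occurs within a few milliseconds before the pulse, an
antidromic spike is annihilated by collision in the axon, while a
synaptically mediated (orthodromic) response survives. `collision_test()`
partitions stimulated trials by the presence of a spontaneous spike in the
`collision_window_ms` (default 4 ms) before the pulse and compares
evoked-spike probabilities in a ±1 ms window around the detected latency.
The defaults — elimination ratio 0.25, at least 10 trials per class — are
conventions, configurable, chosen so that a genuine antidromic unit with a
reliable response is essentially never confused with an orthodromic one at
~30 Hz background and a few hundred trials (the acceptance ensemble requires
sensitivity and specificity >= 0.95). Antidromic verdicts override the
latency class and remove the unit from all downstream analyses.

A caveat that matters for simulation design: the ±1 ms presence window is
anchored at the *first significant bin*. It works because within-unit
trial-to-trial latency jitter of evoked spikes is small (tenths of a
millisecond; antidromic latencies are nearly fixed). The population latency
SDs (0.67 and 1.40 ms) describe spread *across* units; feeding them in as
within-unit jitter makes the presence window miss most of the response and
is not a realistic regime.

## Evoked efficacy by memory condition

All efficacy measures use the 5–9 ms post-stimulation window and
delay-period stimulation, and all are adjusted by subtracting the same
measure on non-stimulated trials:

* `evoked_spike_count()` — mean evoked-window spike count (or, optionally,
  the per-trial probability of at least one spike), stimulated minus
  non-stimulated. Under the no-effect null its expectation is 0; it
  increases monotonically in the generative evoked probability.
* `response_magnitude()` — `log10(after/before)` of summed spike counts,
  stimulated minus non-stimulated. The "before" window mirrors the evoked
  window at −9 to −5 ms (the source procedure does not state it). A
  pseudocount of 0.5 is applied only when some count is zero, keeping the
  statistic finite without biasing the common case. Note that the log-ratio
  shrinks as background rate grows: a unit with strongly elevated
  In-condition delay activity can show a *smaller* In magnitude even when
  it emits more evoked spikes, so the sign of the population In−Out
  contrast depends on the joint configuration of evoked probabilities and
  delay-period gains, not on the evoked counts alone.
* `evoked_latency_by_condition()` — mean time of the first evoked-window
  spike over stimulated trials; trials without such a spike are excluded
  rather than imputed.
* `normalized_evoked_timecourse()` — per-bin stimulated-minus-matched
  deviation scaled by each unit's peak absolute deviation (the source says
  only "normalized"; peak scaling makes units with different response sizes
  commensurable), averaged across units.

## Joint spiking of simultaneously recorded pairs

Synchrony is the fraction of trials in which both units of a pair occupy
the same 1 ms bin, averaged over the five bins with left edges 5–9 ms
post-stimulation. Two corrections remove rate confounds:

1. **Shuffle correction** — subtract the mean joint proportion after
   randomly permuting the second unit's trial assignment within the same
   condition and stimulation status (1,000 shuffles by default, seeded;
   permuting one side suffices under the exchangeable null).
2. **Non-stimulation subtraction** — subtract the same shuffle-corrected
   quantity computed on non-stimulated trials at virtual stimulation times.

The result, `adjusted_joint`, is 0 in expectation for independent units at
any firing rate and invariant to common rate changes; only excess
coincident firing attributable to stimulation survives. Same-bin
co-occupancy was chosen as the operational meaning of "within 1 ms"
(the across-bin-edge alternative can be obtained by widening `bin_ms`).
Because the statistic averages over five bins, a perfectly coincident
evoked spike pair occurring with probability kappa contributes kappa/5.

## Selectivity and functional classification

On non-stimulated trials only — stimulated trials are excluded from
characterisation so that evoked spikes never contaminate epoch rates —
each unit's visual (cue onset +100 to +1000 ms), memory (cue offset +300 to
+1000 ms) and motor (saccade −125 to 0 ms) rates are compared against the
fixation baseline (cue onset −300 to 0 ms) or, for the motor epoch, a
saccade-aligned baseline (−450 to −250 ms), with the paired Wilcoxon
sign-rank test; only response *enhancement* counts as activity. In/Out
selectivity is the area under the ROC curve built by the criterion-sweep
construction (ties at half weight, so the AUC equals the tie-corrected
Mann–Whitney `U/(n1*n2)` — an identity the tests verify exactly), with a
two-sided permutation p-value on `|AUC − 0.5|` (2,000 label permutations,
seeded; the source states significance without naming a test). Units
significant in the visual epoch only are *visual*, motor only *motor*, both
*visuomotor*, neither *unclassified*; unclassified units stay in the
activity-proportion comparisons but are excluded from the functional-class
contingency comparison.

Population comparisons use Pearson chi-square without continuity correction
(`proportion_test()`), parallel-slopes ANCOVA via the extra-sum-of-squares
F test (`ancova_group_effect()`), and Pearson correlation
(`efficacy_delay_correlation()`); these standard fits are delegated to
`chisq.test`, `lm`/`anova` and `cor.test`.

## The synthetic-session generator

`simulate_session()` emulates the statistical structure the analysis
assumes:

* **Task schedule** — 1 s fixation, 1 s cue, 1 s delay; saccade latency
  N(200, 20) ms after the go cue; 50% of trials stimulated, single pulse at
  the epoch's nominal offset.
* **Background spiking** — per-1-ms-bin Bernoulli process with
  piecewise-constant rate (baseline × epoch × condition gain), sampled
  exactly but efficiently as Binomial occupied-bin counts per constant-rate
  segment with uniform sub-millisecond placement, then thinned to enforce
  the refractory period (>= 1 ms).
* **Evoked spikes** — on stimulated trials, with the unit's per-condition
  probability, one spike at `stim_time` + a Normal latency truncated to
  `[artifact_end, 20]` ms; evoked spikes win refractory conflicts with
  background spikes, preserving the configured evoked probability.
* **Pair coupling** — with probability `kappa` a pulse evokes a coincident
  spike in both members of a pair (one shared latency draw); otherwise each
  member fires independently with the residual probability
  `(p − kappa)/(1 − kappa)`, preserving marginals. `kappa` is a modelling
  convenience, not an estimate of any true generative coupling.
* **Antidromic units** — the evoked spike is suppressed whenever a
  background spike occurred within the collision window before the pulse.
* **Reproducibility** — every unit, the trial schedule and every coupling
  consume their own substream derived from the master seed, so adding a
  unit never perturbs the others and identical configurations give
  byte-identical sessions.

Defaults mirror the study conditions the analysis was built for: evoked
probability In 0.22 / Out 0.18, fast latencies near 6.5 ms (across-unit SD
0.67) and slow ones near 12.7 ms (SD 1.40), an In−Out latency shift of
−0.16 ms, and coupling kappa In 0.103 / Out 0.065 (a ~60% In/Out contrast).

What the generator does *not* emulate — and hence what passing tests do not
show about real recordings: spike-sorting errors and waveform overlap
during near-coincident firing, bursting and other non-Poisson interval
structure, slow drifts in excitability, eye-position-dependent rate
changes, true polysynaptic dynamics behind slow-input latencies, and
stimulation artifacts beyond a clean blank.

## Problem sizes and numerical choices

The shipped demonstration session uses 30 units and 120 trials per
condition; the statistical acceptance checks use the sizes their properties
need (e.g. 500 null units for the family-wise false-activation bound, 100
seeds for latency recovery, 100 pairs for the synchrony contrast, n = 115
for the dip-test power study with a shared 499-sample null table). Exact
oracle identities (ROC vs Mann–Whitney, chi-square vs expected-count
formula, ANCOVA vs extra sum of squares) are checked to 1e-10 or better.
Degenerate inputs have defined behaviour: constant samples have dip 0 and
p 1; all-zero paired differences give sign-rank p 1 and no activity flag;
zero-variance inputs to the correlation and a constant ANCOVA covariate are
errors; units with zero peak deviation are skipped (with a warning) in the
normalized time course.

## Known limitations

* The latency estimator inherits the first-significant-bin convention's
  small early-detection rate for long-latency units.
* The response magnitude is background-dependent by construction (see
  above); comparisons across conditions with very different delay-period
  rates conflate evoked drive and background.
* The dip test against the uniform null is conservative for peaked
  unimodal alternatives, and at n ≈ 115 it has essentially no power against
  strongly *unbalanced* mixtures (e.g. 96:19): the package's power study
  uses the balanced mixture.
* `kappa`-style coupling can only express coincidence at the shared evoked
  latency, not lagged or jittered correlation.
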