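# wmgating

Working-memory gating of stimulation-evoked cortical input: analysis of
trial-based primate electrophysiology in which single electrical pulses to a
visual cortical area (V4) probe the efficacy of its input to prefrontal
(FEF) neurons while a monkey performs a memory-guided saccade (MGS) task.
The cue is held either inside (`In`) or outside (`Out`) a neuron's response
field, so every evoked measure can be compared across memory states.

The package is for systems neuroscientists who have (or simulate)
trial-aligned spike tables from such experiments and want a tested,
reproducible implementation of the full analysis chain:

* **Activation detection and latency.** Per-1-ms-bin firing probabilities on
  stimulated versus time-matched non-stimulated trials; the evoked latency
  is the first bin whose probability significantly exceeds the matched null
  (one-sided Fisher exact test per bin). Latencies < 10 ms mark
  *visual-recipient* units, >= 10 ms *slow input*. Hartigan's dip test
  (implemented from scratch, with a bootstrap uniform null) checks the
  bimodality of the latency distribution.
* **Collision test.** Antidromically activated units (axons projecting to
  the stimulated site) are identified by the annihilation of evoked spikes
  on trials where a spontaneous spike immediately precedes the pulse, and
  removed from the visual-recipient pool.
* **Evoked efficacy by memory condition.** Adjusted spike count (stimulated
  minus matched non-stimulated mean in the 5–9 ms window), the log-ratio
  response magnitude `log10(after/before)_stim − log10(after/before)_nonstim`,
  and the mean first-evoked-spike latency.
* **Joint spiking of simultaneous pairs.** Fraction of trials with same-bin
  (1 ms) coincidences averaged over the 5–9 ms bins, corrected by trial
  shuffling and by the same measure on non-stimulated trials, so only
  stimulation-locked excess synchrony survives.
* **Visual/memory/motor characterisation.** Epoch rates against baselines
  (paired sign-rank, enhancement only), In/Out selectivity as ROC area
  (criterion sweep; equals tie-corrected Mann–Whitney U/(n1·n2)) with
  permutation significance, functional classes
  (visual/visuomotor/motor), and population comparisons (Pearson
  chi-square, parallel-slopes ANCOVA, Pearson correlation).
* **Synthetic sessions.** A seeded generator (`simulate_session()`)
  producing Poisson-background spike trains with epoch/condition gains,
  truncated-Normal evoked latencies, pair coupling, collision behaviour and
  exact reproducibility, used by the tests and usable as a power-analysis
  tool.

## Worked example

```r
library(wmgating)

# a 30-unit demonstration session: 120 trials per condition, half stimulated
cfg <- run_config(simulation = demo_simulation_config(seed = 1, n_trials = 60),
                  out_dir = "demo_out", seed = 1)
res <- run_full_analysis(cfg)

attr(res$identification, "counts")
#>       antidromic visual_recipient       slow_input    non_activated
#>                2               18                5                5

eff <- res$efficacy
tapply(eff$adjusted_spike_count, eff$condition, mean)
#>        In       Out
#> 0.2091880 0.1490741
tapply(eff$evoked_latency_ms, eff$condition, mean, na.rm = TRUE)
#>       In      Out
#> 6.577308 6.677495
```

The generator was configured with evoked probabilities In 0.22 / Out 0.18
and an In−Out latency advance of 0.16 ms; the recovered adjusted spike
counts (0.209 vs 0.149) and evoked latencies (6.58 vs 6.68 ms) show the
pipeline reading those conditions back out of raw spike tables. Six result
tables (`activation`, `identification`, `efficacy`, `selectivity`,
`synchrony`, `population_stats`) plus a seed- and config-hash-recording
`manifest.json` are written to `demo_out/`.

A thin command-line front end is installed under `inst/scripts/wmgating`:

```sh
Rscript inst/scripts/wmgating simulate --seed 1 --out session_dir
Rscript inst/scripts/wmgating analyze --trials session_dir/trials.csv \
    --spikes session_dir/spikes.csv --pairs session_dir/pairs.csv --out out_dir
Rscript inst/scripts/wmgating report --in out_dir
```

Input formats are plain CSV: `trials.csv` (one row per trial with task event
times, condition, stimulation flag/epoch/time), `spikes.csv`
(`unit_id, trial_id, time_ms`), `pairs.csv` (`unit_a, unit_b`). See
`?read_session`.

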