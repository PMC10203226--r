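# wmcircuit

Analysis pipeline for simultaneous two-region intracranial LFP
recordings — an amygdala (`AMY`) and a hippocampus (`HIP`) analogue —
during a Sternberg working-memory task (memorize 4, 6 or 8 letters for
2 s, hold them over a 3 s delay, answer a probe). It is written for
electrophysiologists who want the full chain from continuous signal to
group statistics as tested, file-separable R functions, plus a
synthetic session generator with known ground truth to validate every
stage.

## What it computes

With z-scored Morlet power *z*(channel, frequency, time) as the
feature substrate (1–40 Hz, baseline-bootstrap z-scoring), patterns are
averaged in 100 ms windows (10 ms steps) and vectorized over
channels × frequencies:

* **Encoding–encoding dissimilarity (EED)** between trials *i ≠ j* and
  windows *(w₁, w₂)*:
  `d = 1 − atanh(ρ_spearman(v_i(w₁), v_j(w₂)))`, averaged over trial
  pairs → a 201 × 201 map. High values = distinct item
  representations.
* **Encoding–maintenance similarity (EMS)** within a trial:
  `atanh(ρ_spearman(v(w_enc), v(w_maint)))`, averaged over trials → a
  201 × 301 map. High values = representations stable across the
  delay.
* **Phase slope index (PSI)** between hippocampus and amygdala
  channels: `Ψ(c) = Im Σ_f conj(C(f)) C(f+1Hz)` over bins in
  `c ± 2 Hz`, where `C(f)` is the trial-averaged Hann-tapered
  coherency. Positive = hippocampus leads. Significance from a
  200-fold trial-shuffle null, pooled over channel pairs and expressed
  as a z-score per frequency (|z| > 1.96).
* **Load decoding**: flattened EED/EMS/PSI feature maps → train-only
  standardization and PCA (99% variance) → linear SVM (cost 1),
  repeated stratified 70/30 splits; permutation tests for
  region/direction accuracy differences and against chance.
* **Cluster-based permutation tests** on time–time maps across
  participants (paired t, 4-connected clusters, sign-flip max-null).

## Worked example

Simulate three ~50-trial sessions at the generator's default channel
counts (4 amygdala, 6 hippocampus channels; 200 Hz here to keep the
example fast), run the chain on each, and average the map means over
sessions, as a multi-session recording study would:

```r
library(wmcircuit)

analyze_session <- function(seed) {
  sess   <- synthesize_session(sim_config(rate_hz = 200, seed = seed))
  epochs <- epoch_recording(sess$recording, sess$trials)
  epochs <- lapply(epochs, select_trials, tt = sess$trials,
                   correct_only = TRUE)
  null  <- bootstrap_baseline_null(morlet_power(epochs$baseline, 1:40),
                                   n_boot = 200, seed = seed)
  z_enc <- zscore_power(morlet_power(epochs$encoding, 1:40), null)
  z_mnt <- zscore_power(morlet_power(epochs$maintenance, 1:40), null)
  ge <- make_window_grid(0, 2, step_s = 0.1)   # coarse grid for speed
  gm <- make_window_grid(0, 3, step_s = 0.1)
  out <- c()
  for (rg in c("AMY", "HIP")) {
    out[paste0("eed_", rg)] <-
      mean(eed_map(power_region(z_enc, rg), ge)$values)
    out[paste0("ems_", rg)] <-
      mean(ems_map(power_region(z_enc, rg), power_region(z_mnt, rg),
                   ge, gm)$values)
  }
  list(means = out, maintenance = epochs$maintenance)
}

runs <- lapply(1:3, analyze_session)
round(rowMeans(sapply(runs, `[[`, "means")), 3)
#> eed_AMY ems_AMY eed_HIP ems_HIP
#>   0.754   0.262   0.719   0.286

psi_session(runs[[1]]$maintenance, n_shuffles = 200, seed = 1)
#> <wm_psi> 24 channel pairs, 40 frequencies
#>   significant: 3 Hz (HIP_leads), 4 Hz (HIP_leads), 5 Hz (HIP_leads),
#>   6 Hz (HIP_leads), 7 Hz (HIP_leads), 8 Hz (HIP_leads),
#>   16 Hz (AMY_leads), 19 Hz (AMY_leads), 20 Hz (AMY_leads),
#>   21 Hz (AMY_leads), 22 Hz (AMY_leads), 23 Hz (AMY_leads),
#>   24 Hz (AMY_leads), 25 Hz (AMY_leads), 26 Hz (AMY_leads),
#>   27 Hz (AMY_leads)
```

Reading the output: the amygdala's mean EED (0.754) exceeds the
hippocampus's (0.719) — its trial patterns are more distinct — while
the hippocampus's mean EMS (0.286) exceeds the amygdala's (0.262) —
its encoding patterns persist into the delay. Both match the
generator's configuration (`delta = c(AMY = .9, HIP = .2)`,
`rho = c(AMY = .1, HIP = .8)`). The PSI z-spectrum flags
hippocampus-leads flow covering the configured 4–8 Hz theta coupling
and amygdala-leads flow in the 20–28 Hz beta band (plus a few
adjacent bins, a consequence of the ±2 Hz phase-slope integration
window).

`run_pipeline(pipeline_config(seed = 1), "run1/")` chains
simulate → preprocess → time–frequency → maps → PSI into a run
directory with a manifest; rerunning the same configuration reproduces
every output hash.

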