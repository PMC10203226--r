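# Shared fixtures: small synthetic sessions and their z-scored power.
# Sizes are reduced relative to the generator defaults (200 Hz, 2 channels
# per region) so the full suite stays fast; the statistical structure is
# unchanged.

small_config <- function(seed = 1, n_trials_per_load = 4,
                         n_channels = c(AMY = 2, HIP = 2), ...) {
  sim_config(n_trials_per_load = n_trials_per_load,
             n_channels = n_channels, rate_hz = 200,
             seed = seed, ...)
}

# Epoch a session, keep correct trials present in all analysis periods.
session_epochs <- function(sess) {
  ep <- epoch_recording(sess$recording, sess$trials)
  ep <- lapply(ep, select_trials, tt = sess$trials, correct_only = TRUE)
  ids <- Reduce(intersect, lapply(ep[c("baseline", "encoding",
                                       "maintenance")], `[[`, "trial_ids"))
  lapply(ep, function(e) {
    k <- e$trial_ids %in% ids
    e$data <- e$data[k, , , drop = FALSE]
    e$trial_ids <- e$trial_ids[k]
    e$kept_mask <- rep(TRUE, sum(k))
    e
  })
}

# Z-scored encoding and maintenance power for a session.
session_zpower <- function(sess, seed = 1, freqs_hz = 1:40, n_boot = 200) {
  ep <- session_epochs(sess)
  null <- bootstrap_baseline_null(morlet_power(ep$baseline, freqs_hz),
                                  n_boot = n_boot, seed = seed)
  list(encoding = zscore_power(morlet_power(ep$encoding, freqs_hz), null),
       maintenance = zscore_power(morlet_power(ep$maintenance, freqs_hz),
                                  null),
       epochs = ep, null = null)
}

# Mean EED/EMS per region on a coarse grid, the quantity the recovery
# checks compare between regions.
region_map_means <- function(seed, n_trials_per_load = 12, step_s = 0.1,
                             ...) {
  sess <- synthesize_session(small_config(
    seed = seed, n_trials_per_load = n_trials_per_load, ...))
  zp <- session_zpower(sess, seed = seed)
  ge <- make_window_grid(0, 2, step_s = step_s)
  gm <- make_window_grid(0, 3, step_s = step_s)
  out <- c()
  for (rg in c("AMY", "HIP")) {
    pe <- power_region(zp$encoding, rg)
    pm <- power_region(zp$maintenance, rg)
    out[paste0("eed_", rg)] <- mean(eed_map(pe, ge)$values)
    out[paste0("ems_", rg)] <- mean(ems_map(pe, pm, ge, gm)$values)
  }
  out
}

# Per-load EMS trial-feature matrices for one session (HIP channels),
# the feature set used by the decoding calibration checks. Sessions use
# the generator's channel counts and ~50 trials: the load effect on
# rank-correlation features is weak by construction, and thin sessions
# cannot resolve it.
ems_load_features <- function(seed, gain_on = TRUE, n_trials_per_load = 17) {
  lg <- if (gain_on) c(`4` = 1.0, `6` = 1.15, `8` = 1.3) else
    c(`4` = 1, `6` = 1, `8` = 1)
  # no inter-regional coupling: the decoding calibration isolates the
  # load construct from the connectivity one
  sess <- synthesize_session(sim_config(
    seed = seed, n_trials_per_load = n_trials_per_load,
    n_channels = c(AMY = 4, HIP = 6), rate_hz = 200,
    load_gain = lg, error_rate = 0, coupling = list()))
  zp <- session_zpower(sess, seed = seed)
  ge <- make_window_grid(0, 2, step_s = 0.1)
  gm <- make_window_grid(0, 3, step_s = 0.1)
  pe <- power_region(zp$encoding, "HIP")
  pm <- power_region(zp$maintenance, "HIP")
  m <- ems_map(pe, pm, ge, gm, per_trial = TRUE)
  loads <- sess$trials$load[match(pe$trial_ids, sess$trials$trial_id)]
  lapply(split(seq_along(loads), loads),
         function(i) m$trial_values[i, , drop = FALSE])
}
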