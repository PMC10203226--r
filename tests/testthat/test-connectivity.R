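# Trial segments of band-limited or white noise, with optional delayed copy.
noise_segments <- function(n_trials, n_time, rate, delay_s = NULL,
                           mix_zero_lag = FALSE, sd_noise = 1) {
  a <- matrix(rnorm(n_trials * n_time), n_trials)
  if (!is.null(delay_s)) {
    lag <- round(delay_s * rate)
    b <- cbind(matrix(0, n_trials, lag),
               a[, seq_len(n_time - lag), drop = FALSE]) +
      sd_noise * matrix(rnorm(n_trials * n_time), n_trials)
  } else if (mix_zero_lag) {
    b <- a + sd_noise * matrix(rnorm(n_trials * n_time), n_trials)
  } else {
    b <- matrix(rnorm(n_trials * n_time), n_trials)
  }
  list(a = a, b = b)
}

test_that("coherency is 1 for identical signals and small for noise", {
  rate <- 200
  set.seed(31)
  sg <- noise_segments(100, 400, rate)
  cs_same <- cross_spectra(sg$a, sg$a, rate)
  expect_equal(Mod(cs_same$coherency), rep(1, 41), tolerance = 1e-10)
  expect_equal(max(abs(Arg(cs_same$coherency))), 0, tolerance = 1e-10)
  cs_ind <- cross_spectra(sg$a, sg$b, rate)
  expect_lt(mean(Mod(cs_ind$coherency)), 0.2)
  expect_error(cross_spectra(sg$a[1, , drop = FALSE],
                             sg$b[1, , drop = FALSE], rate),
               class = "wm_validation_error")
})

test_that("a pure delay produces the analytic cross-spectral phase ramp", {
  rate <- 200
  set.seed(32)
  tau <- 0.02
  sg <- noise_segments(200, 400, rate, delay_s = tau, sd_noise = 0.01)
  cs <- cross_spectra(sg$a, sg$b, rate)
  ph <- Arg(cs$coherency)
  # S_ab = <Fa conj(Fb)>: a delay tau of the second signal gives a phase
  # ramp of +2*pi*tau per Hz
  f <- 5:25
  slope <- coef(lm(ph[f] ~ f))[2]
  expect_equal(unname(slope), 2 * pi * tau, tolerance = 0.05 * 2 * pi * tau)
})

test_that("PSI is zero for identical signals and antisymmetric exactly", {
  rate <- 200
  set.seed(33)
  sg <- noise_segments(30, 400, rate, delay_s = 0.02)
  expect_equal(psi(sg$a, sg$a, rate), rep(0, 40))
  p_ab <- psi(sg$a, sg$b, rate)
  p_ba <- psi(sg$b, sg$a, rate)
  expect_identical(p_ab, -p_ba)
  # broadband delayed copy: positive at all interior centres
  expect_true(all(p_ab[3:38] > 0))
  expect_error(psi(sg$a, sg$b, rate, centers_hz = 45),
               class = "wm_validation_error")
})

test_that("trial-shuffle null separates coupled from independent signals", {
  rate <- 200
  set.seed(34)
  coupled <- noise_segments(40, 400, rate, delay_s = 0.02, sd_noise = 0.5)
  obs <- psi(coupled$a, coupled$b, rate)
  null <- psi_null(coupled$a, coupled$b, rate, n_shuffles = 200, seed = 7)
  expect_equal(dim(null), c(200, 40))
  lo <- apply(null, 2, quantile, 0.025)
  hi <- apply(null, 2, quantile, 0.975)
  expect_gt(mean(obs > hi | obs < lo), 0.8)
  # independent signals stay inside the null band almost everywhere
  # (averaged over seeds: per-frequency coverage of a 95% band)
  cover <- vapply(1:5, function(s) {
    set.seed(s + 340)
    ind_s <- noise_segments(40, 400, rate)
    obs_s <- psi(ind_s$a, ind_s$b, rate)
    null_s <- psi_null(ind_s$a, ind_s$b, rate, n_shuffles = 200, seed = s)
    lo_s <- apply(null_s, 2, quantile, 0.025)
    hi_s <- apply(null_s, 2, quantile, 0.975)
    mean(obs_s >= lo_s & obs_s <= hi_s)
  }, numeric(1))
  expect_gte(mean(cover), 0.9)
  ind <- noise_segments(40, 400, rate)
  expect_identical(psi_null(ind$a, ind$b, rate, n_shuffles = 50, seed = 9),
                   psi_null(ind$a, ind$b, rate, n_shuffles = 50, seed = 9))
  expect_error(psi_null(ind$a[1:3, ], ind$b[1:3, ], rate),
               class = "wm_validation_error")
})

test_that("population z-scoring pools pairs and classifies direction", {
  # constructed observations and nulls with known statistics
  set.seed(35)
  n_pairs <- 6; n_shuf <- 200; n_freq <- 5
  null <- array(rnorm(n_pairs * n_shuf * n_freq, sd = 1),
                c(n_pairs, n_shuf, n_freq))
  pooled <- apply(null, c(2, 3), mean)
  obs <- rbind(matrix(0, n_pairs - 1, n_freq),
               colMeans(pooled) * n_pairs)  # pooled mean = null mean
  res <- psi_zscore(obs, null, freqs_hz = 1:n_freq)
  expect_equal(unname(res$z), rep(0, n_freq), tolerance = 1e-10)
  expect_true(all(res$direction == "none"))
  # shift frequency 2 up, frequency 4 down
  obs2 <- obs
  obs2[1, 2] <- obs2[1, 2] + 10 * n_pairs * sd(pooled[, 2])
  obs2[1, 4] <- obs2[1, 4] - 10 * n_pairs * sd(pooled[, 4])
  res2 <- psi_zscore(obs2, null, freqs_hz = 1:n_freq)
  expect_equal(res2$direction[c(2, 4)], c("HIP_leads", "AMY_leads"))
  expect_gt(res2$z[2], 1.96)
  expect_lt(res2$z[4], -1.96)
})

test_that("zero-lag mixing does not masquerade as directed coupling", {
  # volume-conduction analogue: b = a + independent noise, no delay.
  # Two properties: (i) no directional preference at moderate mixing
  # (20% shared variance) - the z-scores are centred on zero; (ii) at
  # weak mixing (a few percent shared variance, the residual leakage
  # level after re-referencing) the exceedance rate stays calibrated.
  rate <- 200
  zstats <- vapply(1:20, function(seed) {
    set.seed(seed + 900)
    sg <- noise_segments(30, 400, rate, mix_zero_lag = TRUE, sd_noise = 2)
    obs <- psi(sg$a, sg$b, rate)
    null <- psi_null(sg$a, sg$b, rate, n_shuffles = 100,
                     seed = seed + 900)
    z <- (obs - colMeans(null)) / apply(null, 2, sd)
    c(mean_z = mean(z), pos = mean(z > 1.96), neg = mean(z < -1.96))
  }, numeric(3))
  expect_lt(abs(mean(zstats["mean_z", ])), 0.5)
  expect_lt(abs(mean(zstats["pos", ]) - mean(zstats["neg", ])), 0.1)
  frac_weak <- vapply(1:20, function(seed) {
    set.seed(seed + 950)
    sg <- noise_segments(30, 400, rate, mix_zero_lag = TRUE, sd_noise = 7)
    obs <- psi(sg$a, sg$b, rate)
    null <- psi_null(sg$a, sg$b, rate, n_shuffles = 100,
                     seed = seed + 950)
    z <- (obs - colMeans(null)) / apply(null, 2, sd)
    mean(abs(z) > 1.96)
  }, numeric(1))
  expect_lt(mean(frac_weak), 0.1)
})

test_that("session-level PSI recovers the configured coupling directions", {
  sess <- synthesize_session(small_config(seed = 51, n_trials_per_load = 10))
  es <- select_trials(epoch_recording(sess$recording, sess$trials)$maintenance,
                      sess$trials, correct_only = TRUE)
  res <- psi_session(es, n_shuffles = 200, seed = 51)
  expect_equal(nrow(res$pairs), 4)   # 2 HIP x 2 AMY ipsilateral pairs
  expect_gt(mean(res$z[4:8]), 1.96)     # theta: hippocampus leads
  expect_lt(mean(res$z[20:28]), -1.96)  # beta: amygdala leads
  expect_identical(res$z,
                   psi_session(es, n_shuffles = 200, seed = 51)$z)
})
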