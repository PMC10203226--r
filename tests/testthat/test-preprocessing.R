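# Helper: Hann-tapered periodogram power around a frequency band.
band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- Mod(stats::fft(x * w))^2
  f <- (seq_len(n) - 1) * rate / n
  mean(X[f >= lo & f <= hi])
}

two_chan <- function(x1, x2, rate) {
  recording(rbind(x1, x2), rate, c("a1", "h1"), c("AMY", "HIP"))
}

test_that("band-pass keeps in-band sines, kills drift, and is zero-phase", {
  rate <- 1000
  t <- (0:9999) / rate
  rec <- two_chan(sin(2 * pi * 50 * t), sin(2 * pi * 0.1 * t), rate)
  out <- bandpass_fir(rec, 1, 200)
  mid <- 2000:8000
  expect_lt(abs(max(abs(out$samples[1, mid])) - 1), 0.02)   # 50 Hz kept
  expect_lt(max(abs(out$samples[2, mid])), 10^(-20 / 20))   # > 20 dB down
  # impulse response symmetric about the impulse: zero phase delay
  imp <- matrix(0, 1, 4001); imp[1, 2001] <- 1
  h <- bandpass_fir(recording(imp, rate, "a1", "AMY"), 1, 200)$samples[1, ]
  expect_equal(h, rev(h), tolerance = 1e-12)
  expect_equal(which.max(abs(h)), 2001)
  expect_error(bandpass_fir(rec, 1, 600), class = "wm_validation_error")
})

test_that("DFT line-noise removal nulls target bins and spares neighbours", {
  rate <- 1000
  t <- (0:19999) / rate
  set.seed(1)
  noise <- rnorm(length(t))
  line <- 5 * sin(2 * pi * 50 * t) + 2 * sin(2 * pi * 100 * t) +
    sin(2 * pi * 150 * t)
  rec <- two_chan(noise + line, noise, rate)
  out <- remove_line_noise(rec, c(50, 100, 150))
  for (f0 in c(50, 100, 150)) {
    drop_db <- 10 * log10(band_power(rec$samples[1, ], rate, f0, f0) /
                          band_power(out$samples[1, ], rate, f0, f0))
    expect_gt(drop_db, 20)
  }
  # neighbouring content barely changes
  p49_before <- band_power(rec$samples[1, ], rate, 48.5, 49.5)
  p49_after <- band_power(out$samples[1, ], rate, 48.5, 49.5)
  expect_lt(abs(p49_after - p49_before) / p49_before, 0.05)
  # a channel with no line component passes through almost unchanged:
  # least squares can only strip the sinusoid basis' share of the noise,
  # ~sqrt(2/n) of the RMS per removed frequency
  set.seed(2)
  long <- two_chan(rnorm(60000), rnorm(60000), rate)
  out2 <- remove_line_noise(long, 50)
  rms_change <- sqrt(mean((out2$samples[1, ] - long$samples[1, ])^2)) /
    sqrt(mean(long$samples[1, ]^2))
  expect_lt(rms_change, 0.01)
})

test_that("downsampling preserves the passband and suppresses aliases", {
  rate <- 4000
  t <- (0:39999) / rate
  set.seed(2)
  rec <- two_chan(sin(2 * pi * 10 * t), rnorm(length(t)), rate)
  out <- downsample_recording(rec, 1000)
  expect_equal(out$rate_hz, 1000)
  expect_equal(ncol(out$samples), 10000)
  expect_lt(abs(max(abs(out$samples[1, 1000:9000])) - 1), 0.02)
  # white-noise channel: upper band of the output (aliased content from
  # above the new Nyquist) is > 40 dB below the passband
  rel_db <- 10 * log10(
    band_power(out$samples[2, ], 1000, 450, 499) /
    band_power(out$samples[2, ], 1000, 10, 390))
  expect_lt(rel_db, -40)
  expect_error(downsample_recording(out, 4000),
               class = "wm_validation_error")
})

test_that("common-average re-reference zeroes the clean-channel mean", {
  set.seed(3)
  x <- matrix(rnorm(4000), 4)
  rec <- recording(x, 1000, c("a1", "a2", "h1", "h2"),
                   c("AMY", "AMY", "HIP", "HIP"),
                   channel_clean = c(TRUE, TRUE, TRUE, FALSE))
  out <- rereference_car(rec)
  expect_equal(max(abs(colMeans(out$samples[1:3, ]))), 0, tolerance = 1e-12)
  # the unclean channel is re-referenced with the same clean average
  expect_equal(out$samples[4, ], x[4, ] - colMeans(x[1:3, ]))
  # two identical clean channels cancel exactly
  rec2 <- two_chan(x[1, ], x[1, ], 1000)
  expect_equal(max(abs(rereference_car(rec2)$samples)), 0)
  rec$channel_clean <- c(TRUE, FALSE, FALSE, FALSE)
  expect_error(rereference_car(rec), class = "wm_validation_error")
})

test_that("epoching yields period-exact sample counts and flags edge trials", {
  sess <- synthesize_session(small_config(seed = 5, n_trials_per_load = 2))
  ep <- epoch_recording(sess$recording, sess$trials)
  rate <- sess$recording$rate_hz
  expect_equal(dim(ep$encoding$data)[3], 2 * rate)
  expect_equal(dim(ep$maintenance$data)[3], 3 * rate)
  expect_equal(dim(ep$fixation$data)[3], 1 * rate)
  expect_equal(dim(ep$retrieval$data)[3], 2 * rate)
  expect_equal(dim(ep$baseline$data)[3], 0.5 * rate)
  expect_true(all(ep$encoding$kept_mask))
  # a trial whose retrieval window runs past the end of the recording
  tt <- sess$trials
  short <- sess$recording
  last_needed <- round((tt$t_probe[nrow(tt)] + 2) * rate)
  short$samples <- short$samples[, seq_len(last_needed - 10)]
  ep2 <- epoch_recording(short, tt)
  expect_false(ep2$retrieval$kept_mask[nrow(tt)])
  expect_true(all(ep2$encoding$kept_mask))
})

test_that("epoch content matches the raw recording at the right offsets", {
  sess <- synthesize_session(small_config(seed = 6, n_trials_per_load = 1))
  ep <- epoch_recording(sess$recording, sess$trials)
  rate <- sess$recording$rate_hz
  i0 <- round(sess$trials$t_encoding[1] * rate) + 1
  expect_equal(ep$encoding$data[1, , ],
               sess$recording$samples[, i0:(i0 + 2 * rate - 1)])
})

test_that("MAD rule flags amplitude-outlier trials", {
  sess <- synthesize_session(small_config(seed = 7, n_trials_per_load = 3))
  ep <- epoch_recording(sess$recording, sess$trials)
  es <- ep$encoding
  es$data[4, 1, 50:60] <- 50 * max(abs(es$data))   # inject a gross artifact
  out <- reject_artifact_trials(es, k = 8)
  expect_false(out$kept_mask[4])
  expect_true(all(out$kept_mask[-4]))
  # an external mask overrides the amplitude rule
  out2 <- reject_artifact_trials(es, mask = c(TRUE, FALSE, rep(TRUE, 7)))
  expect_false(out2$kept_mask[2])
})

test_that("trial selection filters by correctness and load", {
  sess <- synthesize_session(small_config(seed = 8, n_trials_per_load = 10,
                                          error_rate = 0))
  tt <- sess$trials
  tt$correct[c(1, 5, 9)] <- FALSE
  ep <- epoch_recording(sess$recording, tt)
  sel <- select_trials(ep$encoding, tt, correct_only = TRUE)
  expect_equal(dim(sel$data)[1], 27)
  expect_equal(sort(attr(sel, "dropped_trials")), c(1L, 5L, 9L))
  sel68 <- select_trials(ep$encoding, tt, correct_only = FALSE,
                         loads = c(6, 8))
  expect_equal(dim(sel68$data)[1], 20)
  expect_error(select_trials(ep$encoding, tt, loads = integer(0)),
               class = "wm_validation_error")
  expect_error(select_trials(ep$encoding, tt[tt$load == 4, ],
                             loads = c(6, 8)),
               class = "wm_validation_error")
})
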