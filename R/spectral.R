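# Morlet time-frequency decomposition and bootstrap baseline z-scoring.
# Power is computed at every sample, so the time resolution equals the
# sampling grid (1 ms at 1 kHz). The z-scored 1-40 Hz power is the feature
# band for all downstream representational analyses.

#' Construct a power tensor
#'
#' @param values Numeric array trials x channels x frequencies x time.
#' @param freqs_hz Frequency axis (Hz), strictly increasing.
#' @param time_s Time axis (s, relative to period onset).
#' @param rate_hz Sampling rate.
#' @param window_label Task period the tensor was computed from.
#' @param channel_names,channel_region Channel metadata.
#' @param trial_ids Trial identifiers.
#' @param zscored Whether values are baseline z-scores.
#' @param baseline_window Baseline interval `(start_s, end_s)` used for
#'   z-scoring, or `NULL`.
#' @param edge_mask Logical frequencies x time matrix flagging samples
#'   within half a wavelet width of the epoch edges.
#' @return An object of class `wm_power`.
#' @export
power_tensor <- function(values, freqs_hz, time_s, rate_hz, window_label,
                         channel_names, channel_region, trial_ids,
                         zscored = FALSE, baseline_window = NULL,
                         edge_mask = NULL) {
  stopifnot(length(dim(values)) == 4L)
  if (is.unsorted(freqs_hz, strictly = TRUE)) {
    stop_validation("freqs_hz must be strictly increasing")
  }
  structure(list(values = values, freqs_hz = freqs_hz, time_s = time_s,
                 rate_hz = rate_hz, window_label = window_label,
                 channel_names = channel_names,
                 channel_region = channel_region,
                 trial_ids = as.integer(trial_ids), zscored = zscored,
                 baseline_window = baseline_window, edge_mask = edge_mask),
            class = "wm_power")
}

#' @export
print.wm_power <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<wm_power:%s%s> %d trials x %d channels x %d freqs (%g-%g Hz) x %d samples\n",
    x$window_label, if (x$zscored) " z" else "", d[1], d[2], d[3],
    min(x$freqs_hz), max(x$freqs_hz), d[4]))
  invisible(x)
}

# Unit-energy complex Morlet wavelet at frequency f, truncated at +/- 3.5
# standard deviations of its Gaussian envelope.
morlet_wavelet <- function(f, rate_hz, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3.5 * sigma_t * rate_hz)
  t <- (-half:half) / rate_hz
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet wavelet power
#'
#' Convolves every trial and channel with complex Morlet wavelets
#' (default 6 cycles) at each frequency and returns squared magnitudes,
#' at full sample resolution. Samples within half a wavelet length of
#' the epoch edges are flagged in `edge_mask`.
#'
#' @param es An [epoch_set()] (kept trials only are transformed; the
#'   tensor rows follow `es$trial_ids` of kept trials).
#' @param freqs_hz Frequencies in Hz (default 1-100 in 1 Hz steps).
#' @param n_cycles Wavelet cycles (default 6).
#' @return A [power_tensor()] with `zscored = FALSE`.
#' @export
morlet_power <- function(es, freqs_hz = 1:100, n_cycles = 6) {
  stopifnot(inherits(es, "wm_epochs"))
  if (any(freqs_hz >= es$rate_hz / 2)) {
    stop_validation("frequencies must be below Nyquist")
  }
  keep <- which(es$kept_mask)
  d <- dim(es$data)
  n <- d[3]
  nf <- length(freqs_hz)
  wavelets <- lapply(freqs_hz, morlet_wavelet, rate_hz = es$rate_hz,
                     n_cycles = n_cycles)
  halves <- vapply(wavelets, function(w) (length(w) - 1L) %/% 2L, integer(1))
  nfft <- stats::nextn(n + max(lengths(wavelets)) - 1L, 2)
  W <- vapply(seq_len(nf), function(i) {
    stats::fft(c(wavelets[[i]], complex(real = numeric(nfft - length(wavelets[[i]])))))
  }, complex(nfft))
  out <- array(NA_real_, c(length(keep), d[2], nf, n))
  edge <- matrix(FALSE, nf, n)
  for (i in seq_len(nf)) {
    h <- min(halves[i], n)
    if (h >= 1) {
      edge[i, seq_len(h)] <- TRUE
      edge[i, (n - h + 1L):n] <- TRUE
    }
  }
  for (ti in seq_along(keep)) {
    for (ch in seq_len(d[2])) {
      X <- stats::fft(c(es$data[keep[ti], ch, ], numeric(nfft - n)))
      for (i in seq_len(nf)) {
        conv <- stats::fft(X * W[, i], inverse = TRUE) / nfft
        # 'same' alignment: wavelet centre over each sample
        out[ti, ch, i, ] <- Mod(conv[(halves[i] + 1L):(halves[i] + n)])^2
      }
    }
  }
  power_tensor(out, freqs_hz, epoch_times(es)[seq_len(n)], es$rate_hz,
               es$window_label, es$channel_names, es$channel_region,
               es$trial_ids[keep], edge_mask = edge)
}

#' Bootstrap null distribution of baseline power
#'
#' For every channel x frequency, baseline power samples are pooled over
#' the kept trials' baseline time points; `n_boot` bootstrap replicates
#' are drawn, each the mean of `m` points sampled with replacement, and
#' the mean and standard deviation of those replicate means are stored
#' as the null against which task power is z-scored.
#'
#' @param power Baseline [power_tensor()] (raw power, pretrial window).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param m Points averaged per replicate; default the number of baseline
#'   time points in one trial (500 at 1 kHz).
#' @param seed RNG seed.
#' @param per_trial If `TRUE`, draw each replicate's points within a
#'   single randomly chosen trial instead of pooling across trials.
#' @return A `wm_baseline_null` with `mean` and `sd` matrices
#'   (channels x frequencies).
#' @export
bootstrap_baseline_null <- function(power, n_boot = 1000, m = NULL,
                                    seed = 1L, per_trial = FALSE) {
  stopifnot(inherits(power, "wm_power"))
  if (power$zscored) stop_validation("baseline power must be raw")
  d <- dim(power$values)
  if (d[1] < 1 || d[4] < 2) stop_validation("no baseline samples")
  m <- m %||% d[4]
  mu <- matrix(NA_real_, d[2], d[3])
  sdv <- matrix(NA_real_, d[2], d[3])
  with_seed(seed, {
    for (ch in seq_len(d[2])) {
      for (fi in seq_len(d[3])) {
        pool <- as.vector(power$values[, ch, fi, ])
        if (stats::sd(pool) == 0) {
          stop_degenerate("zero-variance baseline at channel ",
                          power$channel_names[ch], ", ",
                          power$freqs_hz[fi], " Hz")
        }
        reps <- if (per_trial) {
          trs <- sample.int(d[1], n_boot, replace = TRUE)
          vapply(trs, function(tr) {
            mean(sample(power$values[tr, ch, fi, ], m, replace = TRUE))
          }, numeric(1))
        } else {
          idx <- sample.int(length(pool), n_boot * m, replace = TRUE)
          rowMeans(matrix(pool[idx], n_boot, m))
        }
        mu[ch, fi] <- mean(reps)
        sdv[ch, fi] <- stats::sd(reps)
      }
    }
  })
  if (any(sdv == 0)) stop_degenerate("degenerate baseline null (sd = 0)")
  structure(list(mean = mu, sd = sdv, freqs_hz = power$freqs_hz,
                 channel_names = power$channel_names, n_boot = n_boot,
                 m = m, baseline_window = c(power$time_s[1],
                                            power$time_s[d[4]])),
            class = "wm_baseline_null")
}

#' Z-score task power against the baseline bootstrap null
#'
#' Every task time point is z-scored per channel x frequency as
#' `(x - null mean) / null sd`. Because both null statistics scale
#' linearly with raw power, the z-score is invariant to rescaling the
#' input signal.
#'
#' @param power Task [power_tensor()] (raw).
#' @param null A `wm_baseline_null` from [bootstrap_baseline_null()].
#' @return The z-scored [power_tensor()].
#' @export
zscore_power <- function(power, null) {
  stopifnot(inherits(power, "wm_power"), inherits(null, "wm_baseline_null"))
  d <- dim(power$values)
  if (d[2] != nrow(null$mean) || d[3] != ncol(null$mean) ||
      !isTRUE(all.equal(power$freqs_hz, null$freqs_hz))) {
    stop_validation("power and baseline null axes do not match")
  }
  mu <- aperm(array(null$mean, c(d[2], d[3], d[1], d[4])), c(3, 1, 2, 4))
  sdv <- aperm(array(null$sd, c(d[2], d[3], d[1], d[4])), c(3, 1, 2, 4))
  power$values <- (power$values - mu) / sdv
  power$zscored <- TRUE
  power$baseline_window <- null$baseline_window
  power
}
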