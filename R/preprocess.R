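# Signal-conditioning chain: zero-phase Hamming-window FIR band-pass,
# DFT-based line-noise removal, anti-aliased downsampling, common-average
# re-referencing over clean channels, epoching into task periods, and
# trial selection/rejection.

# Hamming-window FIR design via signal::fir1; order set from the transition
# bandwidth (25% of each cutoff), using the Hamming transition width of
# ~3.3 normalized-frequency units. Returns symmetric (linear-phase) taps.
design_bandpass <- function(low_hz, high_hz, rate_hz, max_order = 8192) {
  tb <- 0.25 * min(low_hz, rate_hz / 2 - high_hz, high_hz)
  ord <- ceiling(3.3 / (tb / rate_hz))
  ord <- min(ord + ord %% 2, max_order)  # even order -> odd symmetric length
  signal::fir1(ord, c(low_hz, high_hz) / (rate_hz / 2), type = "pass",
               window = signal::hamming(ord + 1))
}

# Linear convolution of each row with taps via FFT, compensating the
# group delay (length-1)/2 so a symmetric filter is exactly zero-phase.
# Edges are reflection-padded.
filter_zero_phase <- function(x, taps) {
  L <- length(taps)
  half <- (L - 1L) %/% 2L
  n <- ncol(x)
  pad <- min(half, n - 1L)
  nfft <- stats::nextn(n + 2L * pad + L - 1L, 2)
  H <- stats::fft(c(taps, numeric(nfft - L)))
  out <- x
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    xp <- c(rev(xi[2:(pad + 1L)]), xi, rev(xi[(n - pad):(n - 1L)]))
    y <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - length(xp)))) * H,
                       inverse = TRUE)) / nfft
    out[i, ] <- y[(pad + half + 1L):(pad + half + n)]
  }
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR with the order chosen automatically from a
#' transition bandwidth of 25% of each cutoff; the symmetric (linear
#' phase) filter is applied with group-delay compensation, so the net
#' filter has zero phase delay. Passband ripple of the Hamming design is
#' well under 1 dB.
#'
#' @param rec A [recording()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < rate_hz / 2`.
#' @return The filtered `wm_recording`.
#' @export
bandpass_fir <- function(rec, low_hz, high_hz) {
  stopifnot(inherits(rec, "wm_recording"))
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop_validation("need 0 < low_hz < high_hz")
  }
  if (high_hz >= rec$rate_hz / 2) {
    stop_validation("high_hz must be below the Nyquist frequency")
  }
  taps <- design_bandpass(low_hz, high_hz, rec$rate_hz)
  rec$samples <- filter_zero_phase(rec$samples, taps)
  rec
}

#' Remove line-noise harmonics by DFT subtraction
#'
#' For each target frequency the sine/cosine component over the whole
#' recording is estimated by least squares and subtracted, per channel.
#' This nulls the target bin while leaving neighboring frequencies
#' essentially untouched.
#'
#' @param rec A [recording()].
#' @param freqs_hz Frequencies to remove (e.g. `c(50, 100, 150)`).
#' @return The cleaned `wm_recording`.
#' @export
remove_line_noise <- function(rec, freqs_hz) {
  stopifnot(inherits(rec, "wm_recording"))
  if (any(freqs_hz >= rec$rate_hz / 2)) {
    stop_validation("line frequencies must be below Nyquist")
  }
  n <- ncol(rec$samples)
  t <- (seq_len(n) - 1L) / rec$rate_hz
  for (f0 in freqs_hz) {
    B <- cbind(cos(2 * pi * f0 * t), sin(2 * pi * f0 * t))
    # least-squares fit of the two-column sinusoid basis, per channel
    coefs <- solve(crossprod(B), crossprod(B, t(rec$samples)))
    rec$samples <- rec$samples - t(B %*% coefs)
  }
  rec
}

#' Downsample a recording with anti-alias filtering
#'
#' For integer rate ratios, a zero-phase Hamming FIR low-pass (cutoff at
#' 80% of the new Nyquist frequency) is applied before decimation; for
#' non-integer ratios the band-limited signal is resampled in the
#' Fourier domain after the same anti-alias filter. Content below the
#' new Nyquist frequency is preserved, higher content suppressed by the
#' stopband of the Hamming design (> 50 dB).
#'
#' @param rec A [recording()].
#' @param target_hz New sampling rate; must not exceed the current rate.
#' @return The resampled `wm_recording`.
#' @export
downsample_recording <- function(rec, target_hz) {
  stopifnot(inherits(rec, "wm_recording"))
  if (target_hz > rec$rate_hz) {
    stop_validation("target rate exceeds current rate")
  }
  if (target_hz == rec$rate_hz) return(rec)
  cutoff <- 0.8 * target_hz / 2
  tb <- 0.1 * cutoff
  ord <- ceiling(5.5 / (tb / rec$rate_hz))
  ord <- min(ord + ord %% 2, 8192)
  # Blackman design: ~74 dB stopband keeps the summed alias images of a
  # large decimation factor below -40 dB
  taps <- signal::fir1(ord, cutoff / (rec$rate_hz / 2), type = "low",
                       window = signal::blackman(ord + 1))
  filt <- filter_zero_phase(rec$samples, taps)
  ratio <- rec$rate_hz / target_hz
  n_out <- floor(ncol(filt) * target_hz / rec$rate_hz)
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, by = round(ratio), length.out = n_out)
    rec$samples <- filt[, idx, drop = FALSE]
  } else {
    rec$samples <- t(apply(filt, 1, fourier_resample, n_out = n_out))
  }
  rec$rate_hz <- target_hz
  rec
}

# Fourier-domain resampling of a band-limited signal to n_out samples.
fourier_resample <- function(x, n_out) {
  n <- length(x)
  X <- stats::fft(x)
  half <- min(n, n_out) %/% 2
  Y <- complex(real = numeric(n_out))
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 1) Y[(n_out - half + 2):n_out] <- X[(n - half + 2):n]
  # unnormalized inverse FFT: divide by n_out, then rescale amplitudes by
  # n_out / n to preserve the time-domain amplitude
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Re-reference to the common average of clean channels
#'
#' Subtracts, at every sample, the mean over channels flagged clean from
#' every channel (clean or not). After re-referencing, the mean over the
#' clean channels is identically zero.
#'
#' @param rec A [recording()].
#' @return The re-referenced `wm_recording`.
#' @export
rereference_car <- function(rec) {
  stopifnot(inherits(rec, "wm_recording"))
  if (sum(rec$channel_clean) < 2) {
    stop_validation("common-average reference needs >= 2 clean channels")
  }
  avg <- colMeans(rec$samples[rec$channel_clean, , drop = FALSE])
  rec$samples <- sweep(rec$samples, 2, avg, "-")
  rec
}

# Task period definitions: onset column in the trial table, duration (s),
# and offset of the epoch start relative to that onset.
period_defs <- function() {
  list(
    baseline    = list(col = "t_fixation",    dur = 0.5, t0 = -0.5),
    fixation    = list(col = "t_fixation",    dur = 1,   t0 = 0),
    encoding    = list(col = "t_encoding",    dur = 2,   t0 = 0),
    maintenance = list(col = "t_maintenance", dur = 3,   t0 = 0),
    retrieval   = list(col = "t_probe",       dur = 2,   t0 = 0)
  )
}

#' Segment a recording into event-related epochs
#'
#' Cuts the four task periods (1 s fixation, 2 s encoding, 3 s
#' maintenance, 2 s retrieval) plus a 500 ms pretrial baseline window
#' ending at fixation onset, used for bootstrap z-scoring. Sample grids
#' are half-open `[onset, onset + duration)`, so an encoding epoch at
#' 1 kHz has exactly 2000 samples. A trial whose window falls outside
#' the recording is flagged in `kept_mask` rather than silently dropped
#' (its data are zero-filled).
#'
#' @param rec A [recording()].
#' @param tt A [trial_table()].
#' @return Named list of [epoch_set()]s: `baseline`, `fixation`,
#'   `encoding`, `maintenance`, `retrieval`.
#' @export
epoch_recording <- function(rec, tt) {
  stopifnot(inherits(rec, "wm_recording"), inherits(tt, "wm_trials"))
  n <- ncol(rec$samples)
  out <- list()
  for (nm in names(period_defs())) {
    pd <- period_defs()[[nm]]
    m <- round(pd$dur * rec$rate_hz)
    dat <- array(0, c(nrow(tt), nrow(rec$samples), m))
    kept <- rep(TRUE, nrow(tt))
    for (tr in seq_len(nrow(tt))) {
      i0 <- round((tt[[pd$col]][tr] + pd$t0) * rec$rate_hz) + 1L
      if (i0 < 1L || i0 + m - 1L > n) {
        kept[tr] <- FALSE
        next
      }
      dat[tr, , ] <- rec$samples[, i0:(i0 + m - 1L)]
    }
    out[[nm]] <- epoch_set(dat, nm, pd$t0, rec$rate_hz, tt$trial_id,
                           rec$channel_names, rec$channel_region, kept)
  }
  out
}

#' Flag artifact trials by a robust amplitude rule
#'
#' A reproducible surrogate for manual artifact screening: a trial is
#' rejected when the peak absolute amplitude on any channel exceeds
#' `k` times that channel's median absolute deviation (computed over all
#' trials and time points). Alternatively an external rejection mask may
#' be supplied.
#'
#' @param es A [epoch_set()].
#' @param k MAD multiplier (default 8).
#' @param mask Optional logical per-trial mask of trials to KEEP;
#'   overrides the amplitude rule.
#' @return The epoch set with `kept_mask` updated (AND-ed with the rule).
#' @export
reject_artifact_trials <- function(es, k = 8, mask = NULL) {
  stopifnot(inherits(es, "wm_epochs"))
  if (!is.null(mask)) {
    stopifnot(length(mask) == dim(es$data)[1])
    es$kept_mask <- es$kept_mask & mask
    return(es)
  }
  d <- dim(es$data)
  keep <- rep(TRUE, d[1])
  for (ch in seq_len(d[2])) {
    x <- es$data[, ch, , drop = FALSE]
    thr <- k * stats::mad(as.vector(x))
    peak <- apply(abs(x), 1, max)
    keep <- keep & (peak <= thr)
  }
  es$kept_mask <- es$kept_mask & keep
  es
}

#' Select trials by correctness and load
#'
#' Subsets an epoch set to kept trials matching the requested correctness
#' and load levels; the analyses operate on correct trials.
#'
#' @param es A [epoch_set()].
#' @param tt The matching [trial_table()].
#' @param correct_only Keep only correct trials (default `TRUE`).
#' @param loads Load levels to keep (subset of `c(4, 6, 8)`).
#' @return A filtered `wm_epochs`; the identities of dropped trials are
#'   attached as attribute `"dropped_trials"`.
#' @export
select_trials <- function(es, tt, correct_only = TRUE, loads = c(4, 6, 8)) {
  stopifnot(inherits(es, "wm_epochs"), inherits(tt, "wm_trials"))
  if (length(loads) == 0) stop_validation("loads must be non-empty")
  if (!all(es$trial_ids %in% tt$trial_id)) {
    stop_validation("epoch trial ids not found in trial table")
  }
  info <- tt[match(es$trial_ids, tt$trial_id), ]
  keep <- es$kept_mask & info$load %in% loads
  if (correct_only) keep <- keep & info$correct
  if (!any(keep)) stop_validation("trial selection left an empty set")
  dropped <- es$trial_ids[!keep]
  es$data <- es$data[keep, , , drop = FALSE]
  es$trial_ids <- es$trial_ids[keep]
  es$kept_mask <- rep(TRUE, sum(keep))
  attr(es, "dropped_trials") <- dropped
  es
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: band-pass, line-noise removal, downsampling,
#' common-average re-reference, epoching and amplitude-based trial
#' rejection, in the standard order.
#'
#' @param rec A [recording()].
#' @param tt A [trial_table()].
#' @param band Band-pass edges in Hz, or `NULL` to skip.
#' @param line_hz Line frequencies to remove, or `NULL` to skip.
#' @param resample_hz Target rate, or `NULL` to skip.
#' @param reject_mad MAD multiplier for trial rejection, or `NULL` to skip.
#' @return Named list of epoch sets (see [epoch_recording()]).
#' @export
preprocess <- function(rec, tt, band = c(1, 200), line_hz = c(50, 100, 150),
                       resample_hz = 1000, reject_mad = 8) {
  if (!is.null(band)) {
    band[2] <- min(band[2], rec$rate_hz / 2 - 1)
    rec <- bandpass_fir(rec, band[1], band[2])
  }
  if (!is.null(line_hz)) {
    rec <- remove_line_noise(rec, line_hz[line_hz < rec$rate_hz / 2])
  }
  if (!is.null(resample_hz) && resample_hz < rec$rate_hz) {
    rec <- downsample_recording(rec, resample_hz)
  }
  rec <- rereference_car(rec)
  epochs <- epoch_recording(rec, tt)
  if (!is.null(reject_mad)) {
    epochs <- lapply(epochs, reject_artifact_trials, k = reject_mad)
  }
  epochs
}
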