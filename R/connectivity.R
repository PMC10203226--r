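# Phase slope index (PSI) directional connectivity between the
# hippocampus and the amygdala. Per-trial task segments are Hann-tapered,
# zero-padded and Fourier transformed; cross- and auto-spectra are
# averaged over trials into the complex coherency C(f), and
#
#   psi(c) = Im( sum_{f in band} Conj(C(f)) C(f + 1 Hz) )
#
# over adjacent 1 Hz bins around the centre frequency. With the
# hippocampus channel as the first signal, positive psi means the
# hippocampus leads. Significance comes from a trial-shuffle null:
# permuting the trial pairing between the two channels destroys
# trial-locked coupling while preserving each channel's spectrum.

# Tapered, zero-padded per-trial spectra at integer frequencies.
# seg: trials x time matrix. Returns complex matrix freqs x trials at
# 1..fmax Hz. nfft is a multiple of the sampling rate at least twice the
# segment length, so integer frequencies fall exactly on DFT bins.
segment_spectra <- function(seg, rate_hz, fmax = 41) {
  n <- ncol(seg)
  taper <- signal::hanning(n)
  nfft <- rate_hz * max(1, ceiling(2 * n / rate_hz))
  f_idx <- seq_len(min(fmax, floor(rate_hz / 2) - 1)) * (nfft / rate_hz) + 1
  out <- matrix(NA_complex_, length(f_idx), nrow(seg))
  for (tr in seq_len(nrow(seg))) {
    X <- stats::fft(c(seg[tr, ] * taper, numeric(nfft - n)))
    out[, tr] <- X[f_idx]
  }
  out
}

#' Trial-averaged complex coherency between two channels
#'
#' Each trial's segment is multiplied with a Hann taper and zero padded
#' to an integer-frequency DFT grid; cross- and auto-spectra are averaged
#' over trials and the coherency `C(f) = S_ab / sqrt(S_aa S_bb)` returned
#' at 1 Hz steps.
#'
#' @param seg_a,seg_b Trials x time matrices (equal dimensions); by the
#'   package's sign convention `seg_a` is the hippocampus channel. The
#'   cross-spectrum is `S_ab = <Fa conj(Fb)>`, so delaying the second
#'   signal produces a positive phase ramp `+2 pi f tau` and a positive
#'   phase slope index.
#' @param rate_hz Sampling rate.
#' @param fmax Highest frequency (Hz) returned (default 41, one bin above
#'   the 1-40 Hz analysis range so the phase slope at 40 Hz is defined).
#' @return A list with `coherency` (complex, per frequency), `freqs_hz`,
#'   and the per-trial spectra `spec_a`, `spec_b` (freqs x trials).
#' @export
cross_spectra <- function(seg_a, seg_b, rate_hz, fmax = 41) {
  if (!all(dim(seg_a) == dim(seg_b))) {
    stop_validation("segments must have equal trial counts and lengths")
  }
  if (nrow(seg_a) < 2) stop_validation("coherency needs >= 2 trials")
  Fa <- segment_spectra(seg_a, rate_hz, fmax)
  Fb <- segment_spectra(seg_b, rate_hz, fmax)
  list(coherency = coherency_from_spectra(Fa, Fb),
       freqs_hz = seq_len(nrow(Fa)), spec_a = Fa, spec_b = Fb)
}

coherency_from_spectra <- function(Fa, Fb, perm = NULL) {
  if (!is.null(perm)) Fb <- Fb[, perm, drop = FALSE]
  Sab <- rowMeans(Fa * Conj(Fb))
  Saa <- rowMeans(Mod(Fa)^2)
  Sbb <- rowMeans(Mod(Fb)^2)
  Sab / sqrt(Saa * Sbb)
}

# PSI at every centre frequency from a coherency vector on a 1 Hz grid.
# Bands truncated at the range edges are computed on the available bins.
psi_from_coherency <- function(C, centers, halfwidth) {
  fmax <- length(C)
  vapply(centers, function(cf) {
    f <- seq(max(1, cf - halfwidth), min(fmax - 1, cf + halfwidth - 1))
    sum(Im(Conj(C[f]) * C[f + 1]))
  }, numeric(1))
}

#' Phase slope index between two channels
#'
#' @param seg_a,seg_b Trials x time matrices; `seg_a` leading gives
#'   positive values.
#' @param rate_hz Sampling rate.
#' @param centers_hz Centre frequencies (default 1-40 Hz).
#' @param halfwidth_hz Half-width of the adjacent-bin band summed per
#'   centre (default 2, i.e. up to 5 bins); bands are truncated at the
#'   edges of the 1-40 Hz range.
#' @return Numeric vector of PSI values, one per centre frequency.
#' @export
psi <- function(seg_a, seg_b, rate_hz, centers_hz = 1:40, halfwidth_hz = 2) {
  if (any(centers_hz < 1 | centers_hz > 40)) {
    stop_validation("centre frequencies must lie within 1-40 Hz")
  }
  cs <- cross_spectra(seg_a, seg_b, rate_hz)
  psi_from_coherency(cs$coherency, centers_hz, halfwidth_hz)
}

#' Trial-shuffle null distribution of the PSI
#'
#' Randomly permutes the trial order of the second channel's segments and
#' recomputes the PSI, `n_shuffles` times. The per-trial spectra are
#' computed once and re-paired per shuffle.
#'
#' @inheritParams psi
#' @param n_shuffles Number of shuffles (default 200).
#' @param seed RNG seed.
#' @return Matrix n_shuffles x frequencies of null PSI values.
#' @export
psi_null <- function(seg_a, seg_b, rate_hz, centers_hz = 1:40,
                     halfwidth_hz = 2, n_shuffles = 200, seed = 1L) {
  if (nrow(seg_a) < 5) stop_validation("trial shuffling needs >= 5 trials")
  cs <- cross_spectra(seg_a, seg_b, rate_hz)
  nt <- ncol(cs$spec_a)
  with_seed(seed, {
    t(vapply(seq_len(n_shuffles), function(s) {
      C <- coherency_from_spectra(cs$spec_a, cs$spec_b,
                                  perm = sample.int(nt))
      psi_from_coherency(C, centers_hz, halfwidth_hz)
    }, numeric(length(centers_hz))))
  })
}

#' Population-level z-scored PSI with direction classification
#'
#' Raw PSI values are averaged over the pooled channel pairs (and
#' sessions/participants, when several results are pooled); the null
#' replicates are averaged the same way, and `z(f) = (obs - mean null) /
#' sd null`. Direction per frequency: hippocampus leads when `z > 1.96`,
#' amygdala leads when `z < -1.96`, none otherwise.
#'
#' @param psi_raw Matrix channel pairs x frequencies of observed PSI
#'   (first signal = hippocampus channel), or a list of such matrices to
#'   pool across sessions.
#' @param null Array pairs x shuffles x frequencies (or a list to pool;
#'   each element shuffles x frequencies per pair stacked along dim 1).
#' @param freqs_hz Frequency axis.
#' @param z_crit Direction threshold (default 1.96).
#' @return A `wm_psi` with `psi_raw`, `z`, `null_mean`, `null_sd`,
#'   `direction`.
#' @export
psi_zscore <- function(psi_raw, null, freqs_hz = 1:40, z_crit = 1.96) {
  if (is.list(psi_raw)) psi_raw <- do.call(rbind, psi_raw)
  if (is.list(null)) null <- abind3(null)
  if (is.matrix(psi_raw) && nrow(psi_raw) != dim(null)[1]) {
    stop_validation("psi_raw and null pair counts differ")
  }
  obs <- colMeans(psi_raw)                       # pooled over pairs
  pooled_null <- apply(null, c(2, 3), mean)      # shuffles x freqs
  nm <- colMeans(pooled_null)
  ns <- apply(pooled_null, 2, stats::sd)
  if (any(ns == 0)) stop_degenerate("degenerate PSI null (sd = 0)")
  z <- (obs - nm) / ns
  dir <- ifelse(z > z_crit, "HIP_leads",
                ifelse(z < -z_crit, "AMY_leads", "none"))
  structure(list(psi_raw = psi_raw, z = z, null_mean = nm, null_sd = ns,
                 freqs_hz = freqs_hz, direction = dir, z_crit = z_crit),
            class = "wm_psi")
}

# Bind a list of shuffles x freqs matrices into pairs x shuffles x freqs.
abind3 <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(NA_real_, c(length(lst), d[1], d[2]))
  for (i in seq_along(lst)) out[i, , ] <- lst[[i]]
  out
}

#' @export
print.wm_psi <- function(x, ...) {
  cat(sprintf("<wm_psi> %d channel pairs, %d frequencies\n",
              nrow(x$psi_raw), length(x$freqs_hz)))
  sig <- x$direction != "none"
  if (any(sig)) {
    cat("  significant:",
        paste(sprintf("%g Hz (%s)", x$freqs_hz[sig], x$direction[sig]),
              collapse = ", "), "\n")
  } else cat("  no frequency exceeds |z| >", x$z_crit, "\n")
  invisible(x)
}

#' PSI analysis of one epoch set across all inter-regional channel pairs
#'
#' Forms every hippocampus x amygdala channel pair (the hippocampus
#' channel first, so positive PSI means the hippocampus leads), computes
#' raw PSI and its trial-shuffle null per pair, and pools them into a
#' population z-score.
#'
#' @param es An [epoch_set()] containing channels of both regions
#'   (kept trials are used).
#' @param centers_hz,halfwidth_hz PSI frequency parameters.
#' @param n_shuffles Trial shuffles per pair (default 200).
#' @param seed RNG seed.
#' @return A `wm_psi` (see [psi_zscore()]); the pair table is attached as
#'   element `pairs`.
#' @export
psi_session <- function(es, centers_hz = 1:40, halfwidth_hz = 2,
                        n_shuffles = 200, seed = 1L) {
  stopifnot(inherits(es, "wm_epochs"))
  hip <- which(es$channel_region == "HIP")
  amy <- which(es$channel_region == "AMY")
  if (!length(hip) || !length(amy)) {
    stop_validation("need channels in both regions")
  }
  keep <- which(es$kept_mask)
  pairs <- expand.grid(hip = hip, amy = amy)
  raw <- matrix(NA_real_, nrow(pairs), length(centers_hz))
  null <- array(NA_real_, c(nrow(pairs), n_shuffles, length(centers_hz)))
  for (p in seq_len(nrow(pairs))) {
    a <- es$data[keep, pairs$hip[p], , drop = TRUE]
    b <- es$data[keep, pairs$amy[p], , drop = TRUE]
    raw[p, ] <- psi(a, b, es$rate_hz, centers_hz, halfwidth_hz)
    null[p, , ] <- psi_null(a, b, es$rate_hz, centers_hz, halfwidth_hz,
                            n_shuffles, seed = derive_seed(seed, paste0("pair", p)))
  }
  res <- psi_zscore(raw, null, freqs_hz = centers_hz)
  res$pairs <- data.frame(hip = es$channel_names[pairs$hip],
                          amy = es$channel_names[pairs$amy])
  res
}
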