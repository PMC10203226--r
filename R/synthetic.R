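# Synthetic two-region LFP sessions with known ground truth. The generator
# emulates the statistical structure the analysis assumes: item-specific
# oscillatory patterns during encoding whose cross-trial distinctiveness
# differs between regions, partial persistence of the encoding pattern into
# maintenance, frequency-specific lagged coupling between regions, and
# multiplicative load modulation of pattern amplitude.

#' Configuration for the synthetic session generator
#'
#' Defaults emulate one recording session of a Sternberg working-memory
#' study: ~50 trials (17 per load in {4, 6, 8}), 4 amygdala and 6
#' hippocampus channels at 1 kHz, pink background noise, distinct
#' amygdala encoding patterns (`delta["AMY"] = 0.9`) versus overlapping
#' hippocampal ones (`delta["HIP"] = 0.2`), stable hippocampal
#' maintenance (`rho["HIP"] = 0.8`) versus labile amygdala maintenance
#' (`rho["AMY"] = 0.1`), theta-band hippocampus-to-amygdala coupling
#' (4-8 Hz) and beta-band amygdala-to-hippocampus coupling (20-28 Hz),
#' and load gains 1 / 1.15 / 1.3 for loads 4 / 6 / 8.
#'
#' @param n_trials_per_load Trials per load level.
#' @param n_channels Named integer vector `c(AMY = , HIP = )`.
#' @param rate_hz Sampling rate.
#' @param noise_exponent Spectral exponent alpha of the 1/f^alpha noise.
#' @param noise_sd Standard deviation of the background noise (microvolts).
#' @param line_noise_hz,line_noise_amp Mains frequency and amplitude
#'   (microvolts); amplitude 0 disables it.
#' @param delta Named per-region pattern distinctiveness in \[0, 1\]: 1 means
#'   fully independent item patterns across trials, 0 one shared template.
#' @param rho Named per-region persistence in \[0, 1\] carrying the encoding
#'   pattern into maintenance.
#' @param pattern_freqs_hz Integer frequencies (within 1-40 Hz) carrying the
#'   item patterns.
#' @param osc_amplitude Base oscillation amplitude (microvolts).
#' @param coupling List of couplings, each
#'   `list(src =, dst =, band_hz = c(lo, hi), lag_ms =, gain =)`: the
#'   target region receives the source's band-limited component delayed by
#'   `lag_ms` and scaled by `gain`.
#' @param coupling_amp Amplitude (sd, microvolts) of each band-limited
#'   coupled component at the source.
#' @param load_gain Named multiplicative pattern-amplitude gain per load.
#' @param error_rate Probability that a trial is answered incorrectly.
#' @param iti_s Inter-trial gap after the retrieval period (s).
#' @param lead_in_s Recording time before the first trial (s).
#' @param seed Master seed; all randomness flows from it.
#' @return A `wm_simconfig` list.
#' @export
sim_config <- function(n_trials_per_load = 17,
                       n_channels = c(AMY = 4, HIP = 6),
                       rate_hz = 1000,
                       noise_exponent = 1,
                       noise_sd = 10,
                       line_noise_hz = 50,
                       line_noise_amp = 0,
                       delta = c(AMY = 0.9, HIP = 0.2),
                       rho = c(AMY = 0.1, HIP = 0.8),
                       pattern_freqs_hz = 4:32,
                       osc_amplitude = 4.5,
                       coupling = list(
                         list(src = "HIP", dst = "AMY",
                              band_hz = c(4, 8), lag_ms = 25, gain = 1),
                         list(src = "AMY", dst = "HIP",
                              band_hz = c(20, 28), lag_ms = 25, gain = 1)),
                       coupling_amp = 20,
                       load_gain = c(`4` = 1.0, `6` = 1.15, `8` = 1.3),
                       error_rate = 0.08,
                       iti_s = 2,
                       lead_in_s = 2,
                       seed = 1L) {
  # tolerate list-valued fields from YAML/JSON configurations
  n_channels <- unlist(n_channels)
  delta <- unlist(delta)
  rho <- unlist(rho)
  load_gain <- unlist(load_gain)
  pattern_freqs_hz <- unlist(pattern_freqs_hz)
  coupling <- lapply(coupling, function(cp) {
    cp$band_hz <- unlist(cp$band_hz)
    cp
  })
  cfg <- list(n_trials_per_load = n_trials_per_load,
              n_channels = n_channels, rate_hz = rate_hz,
              noise_exponent = noise_exponent, noise_sd = noise_sd,
              line_noise_hz = line_noise_hz, line_noise_amp = line_noise_amp,
              delta = delta, rho = rho,
              pattern_freqs_hz = pattern_freqs_hz,
              osc_amplitude = osc_amplitude,
              coupling = coupling, coupling_amp = coupling_amp,
              load_gain = load_gain, error_rate = error_rate,
              iti_s = iti_s, lead_in_s = lead_in_s, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "wm_simconfig")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_trials_per_load < 1) stop_validation("need >= 1 trial per load")
  if (!all(wm_regions() %in% names(cfg$n_channels))) {
    stop_validation("n_channels must name both AMY and HIP")
  }
  if (any(cfg$delta < 0 | cfg$delta > 1) || any(cfg$rho < 0 | cfg$rho > 1)) {
    stop_validation("delta and rho must lie in [0, 1]")
  }
  if (any(cfg$pattern_freqs_hz < 1 | cfg$pattern_freqs_hz > 40)) {
    stop_validation("pattern frequencies must lie within 1-40 Hz")
  }
  for (cp in cfg$coupling) {
    if (cp$gain < 0) stop_validation("coupling gain must be >= 0")
    if (cp$lag_ms <= 0) stop_validation("coupling lag must be > 0")
    if (cp$band_hz[1] < 1 || cp$band_hz[2] > 40) {
      stop_validation("coupling band must lie within 1-40 Hz")
    }
    if (cp$band_hz[2] >= cfg$rate_hz / 2) {
      stop_validation("coupling band exceeds Nyquist")
    }
  }
  if (any(cfg$load_gain < 0)) stop_validation("load gains must be >= 0")
  invisible(cfg)
}

# Fixed trial timeline (s): 1 s fixation, 2 s encoding, 3 s maintenance,
# 2 s retrieval.
TRIAL_LEN_S <- 8

#' Generate the trial table for a synthetic session
#'
#' Loads 4/6/8 are interleaved in a seeded random order; onsets follow the
#' 1 s fixation / 2 s encoding / 3 s maintenance structure with a fixed
#' 2 s retrieval period and `iti_s` gap between trials. Trials are marked
#' incorrect independently with probability `error_rate`.
#'
#' @param cfg A [sim_config()].
#' @return A `wm_trials` table.
#' @export
generate_trial_table <- function(cfg) {
  stopifnot(inherits(cfg, "wm_simconfig"))
  with_seed(derive_seed(cfg$seed, "trials"), {
    loads <- sample(rep(c(4L, 6L, 8L), each = cfg$n_trials_per_load))
    n <- length(loads)
    t_fix <- cfg$lead_in_s + (seq_len(n) - 1L) * (TRIAL_LEN_S + cfg$iti_s)
    correct <- stats::runif(n) >= cfg$error_rate
    rt <- round(stats::rlnorm(n, log(1.4), 0.25), 3)
    trial_table(data.frame(
      trial_id = seq_len(n), load = loads,
      t_fixation = t_fix, t_encoding = t_fix + 1,
      t_maintenance = t_fix + 3, t_probe = t_fix + 6,
      correct = correct, rt_s = rt))
  })
}

# 1/f^alpha Gaussian noise via spectral shaping, unit variance.
pink_noise <- function(n, alpha) {
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- f ^ (-alpha / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

# Band-limited Gaussian noise via an FFT brick-wall mask, unit variance.
narrowband_noise <- function(n, band_hz, rate_hz) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * rate_hz / n
  f <- pmin(f, rate_hz - f)  # two-sided frequency axis
  X[f < band_hz[1] | f > band_hz[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Unit root-mean-square normalization: the typical per-entry amplitude is
# independent of the pattern dimensionality, so regions with different
# channel counts get the same per-feature oscillation strength.
normalize_rms <- function(p) p / sqrt(mean(p^2))

# Draw a unit-RMS nonnegative pattern over (channel x pattern frequency):
# a delta-weighted mix of the region template and an independent vector.
mix_pattern <- function(template, delta) {
  indep <- normalize_rms(abs(stats::rnorm(length(template))))
  normalize_rms((1 - delta) * template + delta * indep)
}

#' Synthesize a two-region LFP session
#'
#' Builds the continuous recording as the sum of 1/f background noise,
#' optional mains line noise, item-pattern oscillations during encoding
#' (the sinusoid amplitude at each channel x frequency given by the
#' trial's pattern vector, scaled by the trial's load gain), a
#' `rho`-blended pattern during maintenance, and band-limited coupled
#' components in which the target region receives the source's component
#' delayed by `lag_ms` and scaled by `gain` — so the cross-spectral phase
#' slope between the regions is known by construction.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `recording` ([recording()]), `trials`
#'   ([trial_table()]) and `truth` — a `wm_groundtruth` list holding the
#'   per-trial encoding/maintenance pattern vectors per region, their mean
#'   pairwise Pearson correlation per region, the coupling table and the
#'   load labels.
#' @export
synthesize_session <- function(cfg) {
  stopifnot(inherits(cfg, "wm_simconfig"))
  validate_sim_config(cfg)
  tt <- generate_trial_table(cfg)
  rate <- cfg$rate_hz
  n_trials <- nrow(tt)
  dur_s <- cfg$lead_in_s + n_trials * (TRIAL_LEN_S + cfg$iti_s)
  n <- round(dur_s * rate)
  regions <- wm_regions()
  nch <- cfg$n_channels[regions]
  ch_region <- rep(regions, nch)
  ch_names <- unlist(lapply(regions, function(r) {
    paste0(tolower(r), seq_len(nch[[r]]))
  }))
  nfq <- length(cfg$pattern_freqs_hz)

  with_seed(derive_seed(cfg$seed, "signal"), {
    X <- matrix(0, length(ch_region), n)
    # background noise + optional line noise
    tgrid <- (seq_len(n) - 1L) / rate
    for (c_i in seq_len(nrow(X))) {
      X[c_i, ] <- cfg$noise_sd * pink_noise(n, cfg$noise_exponent)
    }
    if (cfg$line_noise_amp > 0) {
      ln <- cfg$line_noise_amp * sin(2 * pi * cfg$line_noise_hz * tgrid)
      X <- sweep(X, 2, ln, "+")
    }
    # coupled band-limited components: one independent component per source
    # channel, its delayed scaled copy assigned cyclically to target
    # channels. Independent components survive common-average
    # re-referencing, which would cancel a component shared by a whole
    # region.
    coupling_tab <- do.call(rbind, lapply(cfg$coupling, function(cp) {
      data.frame(src = cp$src, dst = cp$dst, band_lo_hz = cp$band_hz[1],
                 band_hi_hz = cp$band_hz[2], lag_ms = cp$lag_ms,
                 gain = cp$gain)
    }))
    for (cp in cfg$coupling) {
      lag <- round(cp$lag_ms / 1000 * rate)
      src_idx <- which(ch_region == cp$src)
      dst_idx <- which(ch_region == cp$dst)
      comps <- lapply(src_idx, function(i) {
        cfg$coupling_amp * narrowband_noise(n, cp$band_hz, rate)
      })
      for (k in seq_along(src_idx)) {
        X[src_idx[k], ] <- X[src_idx[k], ] + comps[[k]]
      }
      for (j in seq_along(dst_idx)) {
        k <- (j - 1L) %% length(src_idx) + 1L
        delayed <- c(numeric(lag), comps[[k]][seq_len(n - lag)])
        X[dst_idx[j], ] <- X[dst_idx[j], ] + cp$gain * delayed
      }
    }
    # item-pattern oscillations
    templates <- lapply(stats::setNames(regions, regions), function(r) {
      normalize_rms(abs(stats::rnorm(nch[[r]] * nfq)))
    })
    pat_enc <- lapply(stats::setNames(regions, regions), function(r) {
      matrix(NA_real_, n_trials, nch[[r]] * nfq)
    })
    pat_mnt <- pat_enc
    for (tr in seq_len(n_trials)) {
      gain <- cfg$load_gain[[as.character(tt$load[tr])]]
      for (r in regions) {
        pe <- mix_pattern(templates[[r]], cfg$delta[[r]])
        pnew <- mix_pattern(templates[[r]], cfg$delta[[r]])
        # blend in power space: the analysis correlates squared-amplitude
        # (power) patterns, and pm^2 proportional to
        # rho * pe^2 + sqrt(1 - rho^2) * q^2 makes corr(pe^2, pm^2) = rho,
        # so the persistence knob is the target power-pattern correlation
        rho_r <- cfg$rho[[r]]
        pm <- normalize_rms(sqrt(rho_r * pe^2 +
                                   sqrt(1 - rho_r^2) * pnew^2))
        pat_enc[[r]][tr, ] <- pe
        pat_mnt[[r]][tr, ] <- pm
        idx_r <- which(ch_region == r)
        for (win in list(list(p = pe, on = tt$t_encoding[tr], len = 2),
                         list(p = pm, on = tt$t_maintenance[tr], len = 3))) {
          i0 <- round(win$on * rate) + 1L
          m <- round(win$len * rate)
          ts <- (seq_len(m) - 1L) / rate
          # pattern vector is channel-major over (channel, frequency);
          # phases are independent per channel x frequency so that the
          # oscillations carry no common component across channels
          amp <- cfg$osc_amplitude * gain *
            matrix(win$p, nch[[r]], nfq, byrow = FALSE)
          for (ci in seq_along(idx_r)) {
            phases <- stats::runif(nfq, 0, 2 * pi)
            sin_mat <- sin(outer(2 * pi * cfg$pattern_freqs_hz, ts) + phases)
            X[idx_r[ci], i0:(i0 + m - 1L)] <-
              X[idx_r[ci], i0:(i0 + m - 1L)] + amp[ci, ] %*% sin_mat
          }
        }
      }
    }
    rec <- recording(X, rate, ch_names, ch_region)
    pattern_cor <- vapply(regions, function(r) {
      cm <- stats::cor(t(pat_enc[[r]]))
      mean(cm[upper.tri(cm)])
    }, numeric(1))
    truth <- structure(list(
      patterns_encoding = pat_enc, patterns_maintenance = pat_mnt,
      mean_pattern_cor = pattern_cor, coupling = coupling_tab,
      loads = tt$load, pattern_freqs_hz = cfg$pattern_freqs_hz,
      seed = cfg$seed), class = "wm_groundtruth")
    list(recording = rec, trials = tt, truth = truth)
  })
}
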