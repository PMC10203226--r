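# Sliding-window representational analysis. Within each 100 ms window
# (10 ms steps) the z-scored 1-40 Hz power is averaged over time and
# vectorized over channels x frequencies; patterns are compared across
# trials (encoding-encoding dissimilarity, EED) or across periods within
# trials (encoding-maintenance similarity, EMS) by Fisher-z-transformed
# Spearman correlation.
#
# All window-pair correlations are obtained in one crossprod of
# standardized rank matrices, which is algebraically identical to
# computing Spearman's rho per pair.

#' Sliding window grid over a task period
#'
#' Window centers run from the period start to its end inclusive in
#' `step` increments, so a 2 s encoding period with 10 ms steps yields
#' 201 windows and a 3 s maintenance period 301. Edge windows are
#' truncated to the available samples.
#'
#' @param start_s,end_s Period limits in seconds (relative to onset).
#' @param width_s Window width (default 0.1 s).
#' @param step_s Step between centers (default 0.01 s).
#' @param period Optional label.
#' @return A `wm_window_grid` with `centers_s`, `width_s`, `step_s`.
#' @examples
#' length(make_window_grid(0, 2)$centers_s)  # 201
#' @export
make_window_grid <- function(start_s, end_s, width_s = 0.1, step_s = 0.01,
                             period = NULL) {
  if (end_s <= start_s) stop_validation("end must exceed start")
  if (step_s <= 0) stop_validation("step must be positive")
  k <- round((end_s - start_s) / step_s)
  structure(list(centers_s = start_s + step_s * (0:k), width_s = width_s,
                 step_s = step_s, period = period),
            class = "wm_window_grid")
}

#' Windowed feature vectors for one sliding window
#'
#' Averages z-scored power over the time points falling in
#' `[center - width/2, center + width/2]` (truncated to the epoch), then
#' vectorizes over channels and the 1-40 Hz feature frequencies in
#' channel-major order (all channels at the lowest frequency first).
#'
#' @param power A z-scored [power_tensor()].
#' @param center_s Window centre (s, relative to period onset).
#' @param width_s Window width (default 0.1 s).
#' @param freqs_hz Feature frequencies (default 1-40 Hz).
#' @return Numeric matrix trials x (channels * frequencies).
#' @export
window_features <- function(power, center_s, width_s = 0.1,
                            freqs_hz = 1:40) {
  stopifnot(inherits(power, "wm_power"))
  fi <- match(freqs_hz, power$freqs_hz)
  if (anyNA(fi)) stop_validation("requested frequencies not in tensor")
  half <- width_s / 2
  sel <- which(power$time_s >= center_s - half - 1e-9 &
               power$time_s <= center_s + half + 1e-9)
  if (!length(sel)) stop_validation("window lies outside the epoch")
  d <- dim(power$values)
  blk <- power$values[, , fi, sel, drop = FALSE]
  avg <- apply(blk, c(1, 2, 3), mean)              # trials x ch x freq
  matrix(avg, d[1], d[2] * length(fi))             # channel-major
}

# Stack of standardized rank feature vectors for every window in a grid:
# returns features x (windows * trials), columns centred, unit-norm ranks,
# so crossprod(Z1, Z2) gives the Spearman correlation of every
# (window, trial) pair. Column order: trial fastest within window.
rank_feature_stack <- function(power, grid, width_s = 0.1, freqs_hz = 1:40) {
  nw <- length(grid$centers_s)
  d <- dim(power$values)
  p <- d[2] * length(freqs_hz)
  if (p < 3) stop_validation("need >= 3 features for rank correlation")
  Z <- matrix(NA_real_, p, nw * d[1])
  for (w in seq_len(nw)) {
    fv <- t(window_features(power, grid$centers_s[w],
                            width_s = grid$width_s %||% width_s,
                            freqs_hz = freqs_hz))   # features x trials
    R <- apply(fv, 2, rank)                         # average ranks for ties
    R <- sweep(R, 2, colMeans(R))
    nrm <- sqrt(colSums(R^2))
    if (any(nrm == 0)) {
      stop_degenerate("zero-variance feature vector (undefined correlation)")
    }
    Z[, (w - 1L) * d[1] + seq_len(d[1])] <- sweep(R, 2, nrm, "/")
  }
  Z
}

#' Fisher-z Spearman dissimilarity between two feature vectors
#'
#' Computes Spearman's rank correlation, clips it to
#' `+/-(1 - 1e-10)`, Fisher z-transforms it and subtracts from 1:
#' `d = 1 - atanh(rho)`. Uncorrelated patterns give d = 1; identical
#' patterns give a strongly negative value.
#'
#' @param v1,v2 Numeric vectors of equal length >= 3.
#' @return The dissimilarity (scalar).
#' @examples
#' pair_dissimilarity(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
pair_dissimilarity <- function(v1, v2) {
  if (length(v1) != length(v2) || length(v1) < 3) {
    stop_validation("vectors must have equal length >= 3")
  }
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop_degenerate("zero-variance vector: correlation undefined")
  }
  rho <- stats::cor(v1, v2, method = "spearman")
  1 - atanh(clip_rho(rho))
}

clip_rho <- function(rho, bound = 1 - 1e-10) pmin(pmax(rho, -bound), bound)

#' Sample unordered trial pairs
#'
#' Draws `k` distinct unordered pairs uniformly from the `C(n, 2)`
#' possible pairs of the supplied trials; when fewer than `k` exist,
#' sampling falls back to with-replacement and the result is flagged
#' via attribute `"with_replacement"`.
#'
#' @param trial_ids Trial identifiers (length >= 2).
#' @param k Number of pairs (default 100).
#' @param seed RNG seed.
#' @return Integer matrix k x 2 of trial ids.
#' @export
sample_trial_pairs <- function(trial_ids, k = 100, seed = 1L) {
  n <- length(trial_ids)
  if (n < 2) stop_validation("need >= 2 trials to form pairs")
  all_pairs <- t(utils::combn(n, 2))
  with_seed(seed, {
    replace <- nrow(all_pairs) < k
    idx <- sample.int(nrow(all_pairs), k, replace = replace)
    out <- cbind(trial_ids[all_pairs[idx, 1]], trial_ids[all_pairs[idx, 2]])
    attr(out, "with_replacement") <- replace
    out
  })
}

#' Encoding-encoding dissimilarity (EED) map
#'
#' For every pair of encoding windows `(w1, w2)` the Fisher-z Spearman
#' dissimilarity between the window-`w1` pattern of trial i and the
#' window-`w2` pattern of trial j is averaged over trial pairs,
#' symmetrized over the two orderings, yielding a windows x windows map.
#' Higher values mean more distinct item representations.
#'
#' @param power Z-scored encoding [power_tensor()].
#' @param grid Encoding [make_window_grid()].
#' @param pairs Optional k x 2 matrix of trial ids (from
#'   [sample_trial_pairs()]); default all unordered pairs.
#' @param freqs_hz Feature frequencies (default 1-40 Hz).
#' @return A `wm_repmap` with `values` (windows x windows), `kind = "EED"`.
#' @export
eed_map <- function(power, grid, pairs = NULL, freqs_hz = 1:40) {
  stopifnot(inherits(power, "wm_power"), inherits(grid, "wm_window_grid"))
  if (!power$zscored) stop_validation("EED requires z-scored power")
  nt <- dim(power$values)[1]
  if (is.null(pairs)) {
    if (nt < 2) stop_validation("need >= 2 trials")
    cmb <- t(utils::combn(nt, 2))
  } else {
    cmb <- cbind(match(pairs[, 1], power$trial_ids),
                 match(pairs[, 2], power$trial_ids))
    if (anyNA(cmb)) stop_validation("pair trial ids not in tensor")
  }
  if (nrow(cmb) < 1) stop_validation("no trial pairs")
  maps <- eed_pair_values(power, grid, cmb, freqs_hz)
  nw <- length(grid$centers_s)
  vals <- matrix(colMeans(maps), nw, nw)
  structure(list(values = vals, kind = "EED", grid1 = grid, grid2 = grid,
                 region = region_of(power), n_units = nrow(cmb)),
            class = "wm_repmap")
}

# Per-trial-pair EED values: rows = pairs, columns = vectorized
# (w1, w2) map (w2 fastest is FALSE: values fill column-major over w1).
eed_pair_values <- function(power, grid, cmb, freqs_hz = 1:40) {
  nt <- dim(power$values)[1]
  nw <- length(grid$centers_s)
  Z <- rank_feature_stack(power, grid, freqs_hz = freqs_hz)
  C <- crossprod(Z)                                # (w*t) x (w*t) Spearman
  D <- 1 - atanh(clip_rho(C))
  out <- matrix(NA_real_, nrow(cmb), nw * nw)
  i_of <- function(w, t) (w - 1L) * nt + t
  for (p in seq_len(nrow(cmb))) {
    i <- cmb[p, 1]; j <- cmb[p, 2]
    di <- D[i_of(seq_len(nw), rep(i, nw)), i_of(seq_len(nw), rep(j, nw))]
    out[p, ] <- as.vector((di + t(di)) / 2)        # symmetrize orderings
  }
  out
}

#' Encoding-maintenance similarity (EMS) map
#'
#' For every pair of one encoding window and one maintenance window, the
#' Fisher-z Spearman correlation between the two patterns of the *same*
#' trial is computed and averaged over trials, yielding an
#' encoding-windows x maintenance-windows map. Higher values mean the
#' encoding pattern persists into maintenance.
#'
#' @param power_enc,power_maint Z-scored encoding / maintenance
#'   [power_tensor()]s over the same trials.
#' @param grid_enc,grid_maint Window grids for the two periods.
#' @param freqs_hz Feature frequencies (default 1-40 Hz).
#' @param per_trial If `TRUE`, also return the trials x (we * wm) matrix
#'   of per-trial similarity values (used as decoding features).
#' @param as_dissimilarity If `TRUE`, report `1 - atanh(rho)` instead of
#'   `atanh(rho)`.
#' @return A `wm_repmap` with `kind = "EMS"`; when `per_trial`, the
#'   per-trial matrix is attached as element `trial_values`.
#' @export
ems_map <- function(power_enc, power_maint, grid_enc, grid_maint,
                    freqs_hz = 1:40, per_trial = FALSE,
                    as_dissimilarity = FALSE) {
  stopifnot(inherits(power_enc, "wm_power"),
            inherits(power_maint, "wm_power"))
  if (!identical(power_enc$trial_ids, power_maint$trial_ids)) {
    stop_validation("encoding and maintenance tensors hold different trials")
  }
  if (!power_enc$zscored || !power_maint$zscored) {
    stop_validation("EMS requires z-scored power")
  }
  nt <- dim(power_enc$values)[1]
  nwe <- length(grid_enc$centers_s)
  nwm <- length(grid_maint$centers_s)
  Ze <- rank_feature_stack(power_enc, grid_enc, freqs_hz = freqs_hz)
  Zm <- rank_feature_stack(power_maint, grid_maint, freqs_hz = freqs_hz)
  C <- crossprod(Ze, Zm)                    # (we*t) x (wm*t)
  S <- atanh(clip_rho(C))
  if (as_dissimilarity) S <- 1 - S
  tv <- matrix(NA_real_, nt, nwe * nwm)
  for (tr in seq_len(nt)) {
    block <- S[(seq_len(nwe) - 1L) * nt + tr,
               (seq_len(nwm) - 1L) * nt + tr, drop = FALSE]
    tv[tr, ] <- as.vector(block)
  }
  res <- structure(list(values = matrix(colMeans(tv), nwe, nwm),
                        kind = "EMS", grid1 = grid_enc, grid2 = grid_maint,
                        region = region_of(power_enc), n_units = nt),
                   class = "wm_repmap")
  if (per_trial) res$trial_values <- tv
  res
}

region_of <- function(power) {
  r <- unique(power$channel_region)
  if (length(r) == 1) r else NA_character_
}

#' @export
print.wm_repmap <- function(x, ...) {
  cat(sprintf("<wm_repmap:%s> %d x %d windows, region %s, mean %.4f (n=%d)\n",
              x$kind, nrow(x$values), ncol(x$values),
              x$region %||% "?", mean(x$values), x$n_units))
  invisible(x)
}

# Subset a power tensor to the channels of one region.
#' Restrict a power tensor to one region's channels
#' @param power A [power_tensor()].
#' @param region `"AMY"` or `"HIP"`.
#' @return The subset `wm_power`.
#' @export
power_region <- function(power, region) {
  stopifnot(inherits(power, "wm_power"))
  idx <- which(power$channel_region == region)
  if (!length(idx)) stop_validation("no channels in region ", region)
  power$values <- power$values[, idx, , , drop = FALSE]
  power$channel_names <- power$channel_names[idx]
  power$channel_region <- power$channel_region[idx]
  power
}
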