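# Shared data containers and their on-disk formats. Every downstream stage
# consumes these types only; vendor acquisition formats are out of scope.

#' Construct a continuous multichannel recording
#'
#' A `wm_recording` bundles a channels-by-time sample matrix (microvolts)
#' with its sampling rate and per-channel metadata: a unique name, a region
#' label (`"AMY"` amygdala or `"HIP"` hippocampus) and a clean flag used by
#' common-average re-referencing.
#'
#' @param samples Numeric matrix, channels x time points, in microvolts.
#' @param rate_hz Sampling rate in Hz (positive).
#' @param channel_names Character vector of unique channel names.
#' @param channel_region Character vector of region labels, one per channel,
#'   each `"AMY"` or `"HIP"`.
#' @param channel_clean Logical vector, one per channel; `TRUE` marks
#'   artifact-free channels. Defaults to all clean.
#' @return An object of class `wm_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), 2), 1000,
#'                  c("a1", "h1"), c("AMY", "HIP"))
#' rec
#' @export
recording <- function(samples, rate_hz, channel_names, channel_region,
                      channel_clean = rep(TRUE, nrow(samples))) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop_validation("samples must be a numeric channels x time matrix")
  }
  nch <- nrow(samples)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop_validation("rate_hz must be a positive scalar")
  }
  if (length(channel_names) != nch || anyDuplicated(channel_names)) {
    stop_validation("channel_names must be unique, one per channel")
  }
  if (length(channel_region) != nch) {
    stop_validation("channel_region must have one label per channel")
  }
  bad <- setdiff(unique(channel_region), wm_regions())
  if (length(bad)) {
    stop_validation("unknown region label(s): ", paste(bad, collapse = ", "))
  }
  if (length(channel_clean) != nch || !is.logical(channel_clean)) {
    stop_validation("channel_clean must be logical, one per channel")
  }
  for (rg in intersect(wm_regions(), channel_region)) {
    if (!any(channel_clean[channel_region == rg])) {
      stop_validation("region ", rg, " has no clean channel")
    }
  }
  structure(list(
    samples = samples,
    rate_hz = as.numeric(rate_hz),
    channel_names = as.character(channel_names),
    channel_region = as.character(channel_region),
    channel_clean = channel_clean
  ), class = "wm_recording")
}

#' @export
print.wm_recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$rate_hz
  cat(sprintf("<wm_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$samples), ncol(x$samples), dur, x$rate_hz))
  tab <- table(x$channel_region)
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf(" | clean: %d/%d\n", sum(x$channel_clean), nrow(x$samples)))
  invisible(x)
}

#' Write / read a recording as flat binary plus JSON sidecar
#'
#' The sample matrix is stored channel-major (all samples of channel 1,
#' then channel 2, ...) as little-endian IEEE floats in `<prefix>.dat`;
#' metadata (rate, channel names, regions, clean flags, storage size)
#' goes to `<prefix>.json`. The round trip is lossless for metadata and
#' for samples within float precision (exact with the default
#' `size = 8`).
#'
#' @param rec A [recording()].
#' @param prefix Path prefix (without extension).
#' @param size Bytes per sample on disk: 8 (double, default) or 4 (float32).
#' @return `write_recording` returns `prefix` invisibly; `read_recording`
#'   returns a `wm_recording`.
#' @export
write_recording <- function(rec, prefix, size = 8) {
  stopifnot(inherits(rec, "wm_recording"), size %in% c(4, 8))
  meta <- list(
    rate_hz = rec$rate_hz,
    channel_names = rec$channel_names,
    channel_region = as.list(stats::setNames(rec$channel_region,
                                             rec$channel_names)),
    channel_clean = rec$channel_clean,
    n_samples = ncol(rec$samples),
    sample_size_bytes = size
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  # channel-major: write row by row
  writeBin(as.vector(t(rec$samples)), con, size = size, endian = "little")
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  jpath <- paste0(prefix, ".json")
  dpath <- paste0(prefix, ".dat")
  if (!file.exists(jpath)) stop_format("missing sidecar metadata: ", jpath)
  if (!file.exists(dpath)) stop_format("missing sample file: ", dpath)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  req <- c("rate_hz", "channel_names", "channel_region", "n_samples")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop_format("sidecar missing field(s): ",
                                paste(miss, collapse = ", "))
  size <- meta$sample_size_bytes %||% 8
  nch <- length(meta$channel_names)
  n <- meta$n_samples
  con <- file(dpath, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = nch * n, size = size, endian = "little")
  samples <- matrix(x, nrow = nch, ncol = n, byrow = TRUE)
  region <- unlist(meta$channel_region)[meta$channel_names]
  recording(samples, meta$rate_hz, meta$channel_names, unname(region),
            as.logical(meta$channel_clean %||% rep(TRUE, nch)))
}

#' Construct and validate a trial table
#'
#' Per-trial task annotations for the Sternberg working-memory task:
#' memory load (4, 6 or 8 letters), the onsets of the fixation (1 s),
#' encoding (2 s), maintenance (3 s) and probe periods in seconds from
#' recording start, response correctness and response time.
#'
#' @param df Data frame with columns `trial_id`, `load`, `t_fixation`,
#'   `t_encoding`, `t_maintenance`, `t_probe`, `correct`, `rt_s`.
#' @param tol_s Tolerance, in seconds, for the fixed period durations
#'   (1 s fixation, 2 s encoding, 3 s maintenance); default one
#'   millisecond, i.e. one sample at 1 kHz.
#' @return A `wm_trials` data frame.
#' @export
trial_table <- function(df, tol_s = 1e-3) {
  req <- c("trial_id", "load", "t_fixation", "t_encoding", "t_maintenance",
           "t_probe", "correct", "rt_s")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_format("trial table missing column(s): ",
                                paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  bad_load <- which(!df$load %in% c(4L, 6L, 8L))
  if (length(bad_load)) {
    stop_validation("invalid load (must be 4, 6 or 8) in row(s): ",
                    paste(bad_load, collapse = ", "))
  }
  ord <- df$t_fixation < df$t_encoding & df$t_encoding < df$t_maintenance &
    df$t_maintenance < df$t_probe
  if (any(!ord)) {
    stop_validation("onsets not strictly increasing in row(s): ",
                    paste(which(!ord), collapse = ", "))
  }
  durs <- cbind(df$t_encoding - df$t_fixation - 1,
                df$t_maintenance - df$t_encoding - 2,
                df$t_probe - df$t_maintenance - 3)
  bad <- which(apply(abs(durs) > tol_s, 1, any))
  if (length(bad)) {
    stop_validation("period durations violate the 1/2/3 s task structure ",
                    "in row(s): ", paste(bad, collapse = ", "))
  }
  df$trial_id <- as.integer(df$trial_id)
  df$load <- as.integer(df$load)
  df$correct <- as.logical(df$correct)
  df$rt_s <- as.numeric(df$rt_s)
  if (any(df$rt_s < 0 & !is.na(df$rt_s))) {
    stop_validation("negative response time")
  }
  class(df) <- c("wm_trials", "data.frame")
  df
}

# Sentinel for missing response time in the TSV representation.
RT_SENTINEL <- -1

#' Read / write a trial table as TSV
#'
#' Columns are exactly `trial_id load t_fixation t_encoding t_maintenance
#' t_probe correct rt_s`; a missing response time is stored as the
#' sentinel value `-1`, never as an empty field.
#'
#' @param path TSV file path.
#' @param tt A `wm_trials` table.
#' @return `read_trial_table` returns a validated `wm_trials`;
#'   `write_trial_table` returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if ("rt_s" %in% names(df)) {
    df$rt_s[!is.na(df$rt_s) & df$rt_s == RT_SENTINEL] <- NA_real_
  }
  trial_table(df)
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(tt, path) {
  stopifnot(inherits(tt, "wm_trials"))
  out <- as.data.frame(tt)
  out$rt_s[is.na(out$rt_s)] <- RT_SENTINEL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an epoch set
#'
#' A `wm_epochs` holds trial x channel x time data cut around one task
#' period, with the time of the first sample relative to the period onset,
#' channel metadata inherited from the recording, and a per-trial
#' `kept_mask` recording which trials survived extraction and artifact
#' rejection.
#'
#' @param data Numeric array, trials x channels x time.
#' @param window_label One of `"baseline"`, `"fixation"`, `"encoding"`,
#'   `"maintenance"`, `"retrieval"`.
#' @param t0_s Time of the first sample relative to the period onset (s).
#' @param rate_hz Sampling rate (Hz).
#' @param trial_ids Integer trial identifiers, one per trial.
#' @param channel_names,channel_region Channel metadata.
#' @param kept_mask Logical per trial; `FALSE` marks dropped trials.
#' @return An object of class `wm_epochs`.
#' @export
epoch_set <- function(data, window_label, t0_s, rate_hz, trial_ids,
                      channel_names, channel_region,
                      kept_mask = rep(TRUE, dim(data)[1])) {
  stopifnot(length(dim(data)) == 3L)
  if (!window_label %in% c("baseline", "fixation", "encoding",
                           "maintenance", "retrieval")) {
    stop_validation("unknown window label: ", window_label)
  }
  if (length(trial_ids) != dim(data)[1] ||
      length(kept_mask) != dim(data)[1]) {
    stop_validation("trial_ids/kept_mask length must match trial count")
  }
  if (length(channel_names) != dim(data)[2]) {
    stop_validation("channel metadata must match channel count")
  }
  structure(list(
    data = data, window_label = window_label, t0_s = t0_s,
    rate_hz = rate_hz, trial_ids = as.integer(trial_ids),
    channel_names = channel_names, channel_region = channel_region,
    kept_mask = kept_mask
  ), class = "wm_epochs")
}

#' @export
print.wm_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<wm_epochs:%s> %d trials (%d kept) x %d channels x %d samples @ %g Hz\n",
    x$window_label, d[1], sum(x$kept_mask), d[2], d[3], x$rate_hz))
  invisible(x)
}

# Time grid (s, relative to period onset) for an epoch set.
epoch_times <- function(es) {
  es$t0_s + (seq_len(dim(es$data)[3]) - 1L) / es$rate_hz
}
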