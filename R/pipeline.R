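# End-to-end orchestration: simulate -> preprocess -> time-frequency ->
# representational maps -> PSI -> load decoding, written to a run
# directory with a manifest so every stage is file-separable and the run
# reproduces exactly from its configuration.

#' Default pipeline configuration
#'
#' Returns the full stage-parameter list consumed by [run_pipeline()],
#' with every stochastic stage's seed derived deterministically from the
#' master seed. Any element may be overridden via `...` (or by passing a
#' YAML file path to [run_pipeline()]).
#'
#' @param seed Master seed.
#' @param ... Named overrides merged over the defaults (one level deep).
#' @return A named list of stage parameter blocks.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    simulate = list(),                    # sim_config() overrides
    preprocess = list(band = c(1, 45), line_hz = NULL, resample_hz = NULL,
                      reject_mad = 8),
    tfr = list(freqs_hz = 1:40, n_cycles = 6, n_boot = 200),
    rsa = list(step_s = 0.05, n_pairs = 50),
    psi = list(n_shuffles = 200, halfwidth_hz = 2),
    decode = list(n_repeats = 25, enabled = FALSE)
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full analysis pipeline into a directory
#'
#' Synthesizes a session (or loads one from `rec_prefix`/`trials_path`),
#' preprocesses and epochs it, computes z-scored Morlet power, region
#' EED/EMS maps, the population PSI spectrum, optionally load decoding
#' from EMS features, and writes each stage's outputs plus a manifest
#' (`manifest.json`: configuration, seeds, output checksums) to
#' `out_dir`. Rerunning with the same configuration reproduces the
#' outputs exactly.
#'
#' @param config A [pipeline_config()] list, or the path of a YAML file
#'   holding one (requires the `yaml` package).
#' @param out_dir Output directory (created if needed).
#' @param rec_prefix,trials_path Optional on-disk inputs; when `NULL` a
#'   session is synthesized from `config$simulate`.
#' @return Invisibly, a list with the computed objects and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         rec_prefix = NULL, trials_path = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_format("reading YAML configs requires the yaml package")
    }
    config <- utils::modifyList(pipeline_config(), yaml::read_yaml(config))
  }
  if (is.null(config$seed)) stop_validation("config must carry a seed")
  for (nm in c("preprocess", "tfr", "rsa", "psi", "decode")) {
    config[[nm]] <- lapply(config[[nm]],
                           function(x) if (is.list(x)) unlist(x) else x)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    note("stage ", name, " start")
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    note("stage ", name, " done")
    res
  }

  sess <- stage("simulate", {
    if (!is.null(rec_prefix)) {
      list(recording = read_recording(rec_prefix),
           trials = read_trial_table(trials_path), truth = NULL)
    } else {
      scfg <- do.call(sim_config, utils::modifyList(
        list(seed = derive_seed(config$seed, "simulate")),
        config$simulate))
      out <- synthesize_session(scfg)
      write_recording(out$recording, file.path(out_dir, "recording"))
      write_trial_table(out$trials, file.path(out_dir, "trials.tsv"))
      out
    }
  })

  epochs <- stage("preprocess", {
    pp <- config$preprocess
    pp$band[2] <- min(pp$band[2], sess$recording$rate_hz / 2 - 1)
    preprocess(sess$recording, sess$trials, band = pp$band,
               line_hz = pp$line_hz, resample_hz = pp$resample_hz,
               reject_mad = pp$reject_mad)
  })
  epochs_sel <- lapply(epochs, select_trials, tt = sess$trials,
                       correct_only = TRUE)
  common <- Reduce(intersect, lapply(epochs_sel[c("baseline", "encoding",
                                                  "maintenance")],
                                     `[[`, "trial_ids"))
  restrict <- function(es) {
    keep <- es$trial_ids %in% common
    es$data <- es$data[keep, , , drop = FALSE]
    es$trial_ids <- es$trial_ids[keep]
    es$kept_mask <- rep(TRUE, sum(keep))
    es
  }
  epochs_sel <- lapply(epochs_sel, restrict)

  power <- stage("tfr", {
    tf <- config$tfr
    p_base <- morlet_power(epochs_sel$baseline, tf$freqs_hz, tf$n_cycles)
    null <- bootstrap_baseline_null(p_base, n_boot = tf$n_boot,
                                    seed = derive_seed(config$seed, "boot"))
    list(encoding = zscore_power(
           morlet_power(epochs_sel$encoding, tf$freqs_hz, tf$n_cycles), null),
         maintenance = zscore_power(
           morlet_power(epochs_sel$maintenance, tf$freqs_hz, tf$n_cycles),
           null))
  })

  maps <- stage("rsa", {
    rs <- config$rsa
    grid_e <- make_window_grid(0, 2, step_s = rs$step_s, period = "encoding")
    grid_m <- make_window_grid(0, 3, step_s = rs$step_s,
                               period = "maintenance")
    out <- list()
    for (rg in wm_regions()) {
      pe <- power_region(power$encoding, rg)
      pm <- power_region(power$maintenance, rg)
      pairs <- sample_trial_pairs(pe$trial_ids, k = rs$n_pairs,
                                  seed = derive_seed(config$seed,
                                                     paste0("pairs", rg)))
      out[[rg]] <- list(
        eed = eed_map(pe, grid_e, pairs = pairs,
                      freqs_hz = config$tfr$freqs_hz),
        ems = ems_map(pe, pm, grid_e, grid_m,
                      freqs_hz = config$tfr$freqs_hz, per_trial = TRUE))
    }
    out
  })

  psi_res <- stage("psi", {
    psi_session(epochs_sel$maintenance,
                halfwidth_hz = config$psi$halfwidth_hz,
                n_shuffles = config$psi$n_shuffles,
                seed = derive_seed(config$seed, "psi"))
  })

  decoding <- NULL
  if (isTRUE(config$decode$enabled)) {
    decoding <- stage("decode", {
      tt <- sess$trials
      by_load <- lapply(stats::setNames(c(4, 6, 8), c(4, 6, 8)),
        function(l) {
          rows <- maps$HIP$ems$trial_values[
            tt$load[match(power$encoding$trial_ids, tt$trial_id)] == l, ,
            drop = FALSE]
          rows
        })
      fs <- build_ems_features(by_load, provenance = "HIP EMS")
      decode_load(fs, n_repeats = config$decode$n_repeats,
                  seed = derive_seed(config$seed, "decode"))
    })
  }

  # persist stage summaries
  summary <- list(
    config = config,
    n_trials_analyzed = length(common),
    eed_mean = lapply(maps, function(m) mean(m$eed$values)),
    ems_mean = lapply(maps, function(m) mean(m$ems$values)),
    psi_z = as.numeric(psi_res$z),
    psi_direction = psi_res$direction,
    decoding_mean = if (!is.null(decoding)) decoding$mean else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, c("manifest.json", "run.log")))
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("wmcircuit")),
    outputs = as.list(tools::md5sum(sort(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(session = sess, epochs = epochs_sel, power = power,
                 maps = maps, psi = psi_res, decoding = decoding,
                 out_dir = out_dir))
}
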