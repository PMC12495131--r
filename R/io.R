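#' Write a trace to delimited text
#'
#' Tidy CSV with explicit unit-bearing column names (`time_s`, `abp_mmhg`,
#' `cvp_mmhg`, `co_l_min`, `label`, optionally `animal`), numeric values at
#' 6 significant digits, plus an optional JSON sidecar with the sampling
#' rate, scenario hash, seed and code version.
#'
#' @param trace Trace tibble.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` metadata.
#' @param seed Optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sidecar = TRUE, seed = NULL) {
  df <- as.data.frame(trace)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    sc <- attr(trace, "scenario")
    meta <- list(
      fs = trace_fs(trace),
      scenario_hash = if (!is.null(sc)) rlang::hash(sc) else NULL,
      seed = seed,
      code_version = as.character(utils::packageVersion("zeroflow"))
    )
    jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return Trace tibble; the sampling rate is restored from the sidecar
#'   when present, otherwise inferred from the time column.
#' @export
read_trace <- function(path) {
  tr <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(tr, "fs") <- jsonlite::read_json(sidecar)$fs
  }
  tr
}

#' Compare a simulated trace against a synthetic reference group
#'
#' Builds the noiseless reference mean curve of the group from the anchor
#' table (noiseless synthesis followed by the zero-phase filter), filters
#' the simulated trace the same way, and computes the range-normalized RMSE
#' per channel over the post-arrest comparison window.
#'
#' @param trace Simulated trace.
#' @param group Reference group (`"vf_eu"`, `"vf_hypo"`, `"pento_eu"`).
#' @param channels,window,normalize Passed to [normalized_rmse()].
#' @param anchors Anchor tibble.
#' @return Tibble of per-channel nRMSE with a `mean_nrmse_pct` attribute.
#' @export
compare_to_reference <- function(trace, group, channels = c("map", "cvp"),
                                 window = c(0, 600), normalize = "range",
                                 anchors = anchor_table()) {
  spec <- noiseless_cohort_spec(fs = trace_fs(trace))
  ref <- lowpass_mean(synthesize_animal(group, 1L, spec, anchors))
  sim <- lowpass_mean(trace)
  out <- normalized_rmse(sim, ref, channels = channels, window = window,
                         normalize = normalize)
  attr(out, "mean_nrmse_pct") <- mean(out$nrmse_pct)
  out
}

#' Run the complete desk-scale study
#'
#' One call reproduces the whole pipeline: synthesize the pig-like cohort,
#' run the four arrest scenarios on the chosen model calibration, extract
#' the time-point summary table (groups x channels x analysis times), run
#' the group statistics, compute the normalized-RMSE report of the
#' simulations against the synthetic references, and write all artifacts
#' plus a manifest. Deterministic for a given seed.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for the synthetic cohort.
#' @param calibration `"pig"` (default) or `"human"`, or a `zf_model`.
#' @param cohort A [cohort_spec()]; its seed is overridden by `seed`.
#' @param scenarios Scenario list, default [study_scenarios()].
#' @param verbose Log stage progress.
#' @return Invisibly, a list with `summary`, `stats`, `nrmse`, `manifest`.
#' @export
run_full_study <- function(out_dir, seed = 1L, calibration = "pig",
                           cohort = cohort_spec(), scenarios = study_scenarios(),
                           verbose = TRUE) {
  t_start <- Sys.time()
  log_stage <- function(stage) {
    if (verbose) message(sprintf("[zeroflow] stage=%s seed=%d elapsed=%.1fs",
                                 stage, seed, as.numeric(Sys.time() - t_start, units = "secs")))
  }
  run_stage <- function(stage, expr) {
    log_stage(stage)
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
            class = "zf_stage_error")
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort$seed <- as.integer(seed)

  model <- if (inherits(calibration, "zf_model")) calibration else
    build_default_model(read_model_config(calibration = calibration))

  syn <- run_stage("synthesize_cohort",
                   synthesize_cohort(cohort, dir = file.path(out_dir, "cohort")))
  sims <- run_stage("simulate_scenarios", run_study(model, scenarios))
  run_stage("write_traces", {
    for (lb in unique(sims$traces$label)) {
      write_trace(dplyr::filter(sims$traces, .data$label == lb),
                  file.path(out_dir, paste0("sim_", lb, ".csv")), seed = seed)
    }
  })
  summary_tbl <- run_stage("summary_table", {
    tp <- cohort_timepoints(syn$traces)
    tbl <- tp |>
      dplyr::group_by(.data$group, .data$channel, .data$time_s) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       n = dplyr::n(), .groups = "drop")
    write.csv(tbl, file.path(out_dir, "summary_table.csv"), row.names = FALSE)
    tbl
  })
  stats <- run_stage("group_statistics",
                     group_statistics(cohort_timepoints(syn$traces)))
  write.csv(tidy(stats), file.path(out_dir, "group_statistics.csv"),
            row.names = FALSE)
  nrmse <- run_stage("nrmse_report", {
    comparisons <- list(
      vf_eu = c(sim = "vf_eu", ref = "vf_eu"),
      vf_hypo = c(sim = "vf_hypo", ref = "vf_hypo"),
      pento_eu = c(sim = "pento_eu", ref = "pento_eu"),
      reflex_off_vs_vf_eu = c(sim = "pento_eu", ref = "vf_eu")
    )
    rep <- purrr::imap(comparisons, function(cmp, nm) {
      tr <- dplyr::filter(sims$traces, .data$label == cmp[["sim"]])
      attr(tr, "fs") <- model$global$fs
      res <- compare_to_reference(tr, cmp[["ref"]])
      list(channels = as.list(setNames(res$nrmse_pct, res$channel)),
           mean_nrmse_pct = attr(res, "mean_nrmse_pct"),
           window_clipped = isTRUE(attr(res, "clipped")))
    })
    jsonlite::write_json(rep, file.path(out_dir, "nrmse_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    rep
  })
  manifest <- run_stage("manifest", {
    mf <- list(
      config_hash = rlang::hash(list(model$compartments, model$connections,
                                     model$global, cohort[names(cohort) != "seed"])),
      seed = seed,
      code_version = as.character(utils::packageVersion("zeroflow")),
      scenarios = names(scenarios),
      outputs = list.files(out_dir, recursive = TRUE),
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    mf
  })
  log_stage("done")
  invisible(list(summary = summary_tbl, stats = stats, nrmse = nrmse,
                 manifest = manifest))
}
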