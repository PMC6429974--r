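#' Default pipeline configuration
#'
#' One auditable place for every fixed constant of the analysis: 33 samples
#' per beat, the physiologic beat validity band, the four-class scheme, the
#' presyncope stop thresholds (80 mmHg floor; 25/15 mmHg/min and 15 bpm/min
#' declines), 200 Hz sampling, the 30-min LBNP limit, and the evaluation
#' protocol (10 bootstraps of 10%, 20-beat smoothing, the C grid).
#'
#' @param seed Global seed; all subject, fold and draw streams derive from it.
#' @return Nested configuration list with blocks `synthetic`, `beats`,
#'   `criteria`, `eval`, plus `seed`.
#' @export
default_config <- function(seed = 1L) {
  list(synthetic = unclass(synth_config(seed = seed)),
       beats = list(n_samples = 33L, min_duration_s = 0.25,
                    max_duration_s = 2.5, min_pp_mmHg = 10,
                    deriv_cutoff_hz = 10, refractory_s = 0.25),
       criteria = unclass(presyncope_criteria()),
       eval = unclass(eval_config(seed = seed)),
       seed = as.integer(seed))
}

#' Validate a pipeline configuration
#'
#' @param config A configuration list (as from [default_config()]) or the
#'   path to a YAML file holding one.
#' @return Character vector of violations, empty when the configuration is
#'   valid. Each entry names the offending field.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)
  sy <- config$synthetic
  tryCatch(validate_synth_config(normalize_synth(sy)),
           error = function(e) note(paste0("synthetic: ", conditionMessage(e))))
  bt <- config$beats
  if (!identical(as.integer(bt$n_samples %||% 33L), 33L)) {
    note("beats$n_samples: fixed-length beats use 33 samples unless deliberately overridden")
  }
  if ((bt$min_duration_s %||% 0.25) <= 0) note("beats$min_duration_s: must be > 0")
  if ((bt$max_duration_s %||% 2.5) <= (bt$min_duration_s %||% 0.25)) {
    note("beats$max_duration_s: must exceed min_duration_s")
  }
  if ((bt$min_pp_mmHg %||% 10) <= 0) note("beats$min_pp_mmHg: must be > 0")
  cr <- config$criteria
  for (f in c("sap_floor_mmHg", "sap_drop_rate", "dap_drop_rate",
              "hr_drop_rate", "window_s")) {
    if (!is.null(cr[[f]]) && (!is.numeric(cr[[f]]) || cr[[f]] <= 0)) {
      note(sprintf("criteria$%s: must be > 0", f))
    }
  }
  ev <- config$eval
  if (!is.null(ev)) {
    if (!is.null(ev$subsample_fraction) &&
        (ev$subsample_fraction <= 0 || ev$subsample_fraction > 1)) {
      note("eval$subsample_fraction: must lie in (0, 1]")
    }
    if (!is.null(ev$smooth_window_beats) && ev$smooth_window_beats < 1) {
      note("eval$smooth_window_beats: must be >= 1")
    }
    if (!is.null(ev$n_bootstrap) && ev$n_bootstrap < 1) {
      note("eval$n_bootstrap: must be >= 1")
    }
    if (!is.null(ev$C_grid) && any(ev$C_grid <= 0)) {
      note("eval$C_grid: all values must be > 0")
    }
    if (!is.null(ev$k_components) && ev$k_components < 1) {
      note("eval$k_components: must be >= 1")
    }
  }
  bad
}

# Rebuild classed sub-configs from plain (e.g. YAML-parsed) lists.
normalize_synth <- function(sy) {
  sy <- sy %||% list()
  for (f in c("hr_baseline_bpm", "sap_baseline_mmHg", "dap_baseline_mmHg")) {
    if (!is.null(sy[[f]])) {
      v <- unlist(sy[[f]])
      if (is.null(names(v)) && length(v) == 2L) names(v) <- c("mean", "sd")
      sy[[f]] <- v
    }
  }
  do.call(synth_config, sy)
}

normalize_eval <- function(ev) {
  ev <- ev %||% list()
  ev$C_grid <- unlist(ev$C_grid %||% NULL)
  if (is.null(ev$C_grid)) ev$C_grid <- NULL
  do.call(eval_config, ev)
}

#' Run the full staging pipeline
#'
#' Wires the stages simulate -> extract -> evaluate: generates the synthetic
#' cohort, builds the labeled beat matrix, runs the leave-one-subject-out
#' bootstrap evaluation, and (when `out_dir` is given) writes the artifacts:
#' `metrics.json`, the median-[IQR] `cohort_table.csv`, the pooled
#' `confusion.csv`, per-subject trace CSVs, and a `run_info.json` stamped
#' with the configuration hash and seed. The log (via `message()`) records
#' any subject exclusions.
#'
#' @param config Configuration list or YAML path (see [default_config()]).
#' @param stages Subset of `c("simulate", "extract", "evaluate")` to run
#'   (prefix order is enforced).
#' @param out_dir Optional artifact directory.
#' @param seed Optional seed overriding the configured one.
#' @param write_signals Also write the per-subject signal/marks files under
#'   `out_dir/cohort/` (off by default; they are large).
#' @return Invisibly, a list with `cohort`, `beats`, `eval`, `config_hash`.
#' @export
run_pipeline <- function(config = default_config(), stages = c("simulate", "extract", "evaluate"),
                         out_dir = NULL, seed = NULL, write_signals = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- match.arg(stages, several.ok = TRUE)
  bad <- validate_config(config)
  if (length(bad) > 0L) {
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$synthetic$seed <- as.integer(seed)
    config$eval$seed <- as.integer(seed)
  }
  hash <- config_hash(config)
  out <- list(config_hash = hash)
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if ("simulate" %in% stages) {
    scfg <- normalize_synth(config$synthetic)
    out$cohort <- generate_cohort(scfg)
    message(sprintf("simulated %d subjects (%d presyncope)",
                    length(out$cohort),
                    sum(vapply(out$cohort, function(s)
                      s$recording$marks$end_reason == "presyncope", logical(1)))))
    if (!is.null(out_dir) && isTRUE(write_signals)) {
      write_cohort(out$cohort, file.path(out_dir, "cohort"))
    }
  }
  if ("extract" %in% stages) {
    if (is.null(out$cohort)) stop("extract requires the simulate stage", call. = FALSE)
    bt <- config$beats
    out$beats <- build_beat_matrix(out$cohort,
                                   n_samples = bt$n_samples %||% 33L,
                                   min_duration_s = bt$min_duration_s %||% 0.25,
                                   max_duration_s = bt$max_duration_s %||% 2.5,
                                   min_pp_mmHg = bt$min_pp_mmHg %||% 10,
                                   deriv_cutoff_hz = bt$deriv_cutoff_hz %||% 10,
                                   refractory_s = bt$refractory_s %||% 0.25)
    message(sprintf("extracted %d labeled beats from %d subjects",
                    nrow(out$beats$values), length(unique(out$beats$subject_id))))
  }
  if ("evaluate" %in% stages) {
    if (is.null(out$beats)) stop("evaluate requires the extract stage", call. = FALSE)
    er <- vapply(out$cohort, function(s) s$recording$marks$end_reason, character(1))
    names(er) <- vapply(out$cohort, function(s) s$recording$subject_id, character(1))
    ecfg <- normalize_eval(config$eval)
    out$eval <- loso_bootstrap_evaluate(out$beats, er, ecfg)
    message(sprintf("evaluation done: pooled kappa %.3f", out$eval$pooled_kappa))
    if (!is.null(out_dir)) write_eval_artifacts(out$eval, out_dir, hash, config$seed)
  }
  invisible(out)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf, precision = 15L)
  unname(tools::md5sum(tf))
}

write_eval_artifacts <- function(ev, out_dir, hash, seed) {
  data.table::fwrite(ev$table, file.path(out_dir, "cohort_table.csv"))
  utils::write.csv(ev$pooled_confusion, file.path(out_dir, "confusion.csv"))
  trace_dir <- file.path(out_dir, "traces")
  if (!dir.exists(trace_dir)) dir.create(trace_dir)
  for (r in ev$subjects) {
    tab <- data.table::data.table(time_s = r$onset_s, true_class = r$label)
    for (b in seq_len(ncol(r$raw))) tab[[sprintf("model%02d", b)]] <- r$raw[, b]
    tab$averaged <- r$averaged
    data.table::fwrite(tab, file.path(trace_dir, paste0(r$subject_id, ".csv")))
  }
  metrics <- list(pooled_kappa = ev$pooled_kappa, C = ev$C, k = ev$k,
                  trends = lapply(ev$subjects, function(r)
                    list(end_reason = r$end_reason, trend = r$trend)))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(config_hash = hash, seed = seed,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       file.path(out_dir, "run_info.json"), auto_unbox = TRUE)
  invisible(NULL)
}
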