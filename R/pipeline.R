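#' Default run configuration
#'
#' Nested parameter list driving [run_pipeline()]: simulation block
#' (cohort sizes; `NULL` to analyse existing recordings), signal
#' conditioning (band, order, smoothing window), segmentation
#' thresholds, analysis window, comparison settings (bootstrap B, alpha)
#' and prediction tasks. The resolved configuration is written beside
#' the outputs of every run.
#'
#' @param ... named overrides, e.g. `compare = list(B = 500)`; nested
#'   lists are merged element-wise.
#' @return configuration list of class `respvar_config`.
#' @export
respvar_config <- function(...) {
  base <- list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_patients = 44L, n_controls = 44L),
    signal = list(band = c(0.1, 0.7), order = 4L, ma_window = 0.5),
    breaths = list(min_breath_s = 1.5, min_prominence_frac = 0.3,
                   refine = "cosine", polarity = "auto"),
    window_s = 300,
    compare = list(B = 1000L, alpha = 0.05, boot_stage = "after_adjust"),
    predict = list(tasks = character(0), n_iter = 20L)
  )
  merge_cfg <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) {
        merge_cfg(a[[nm]], b[[nm]])
      } else b[[nm]]
    }
    a
  }
  cfg <- merge_cfg(base, list(...))
  # YAML round-trips empty vectors as empty lists; normalise
  cfg$predict$tasks <- as.character(unlist(cfg$predict$tasks))
  cfg$signal$band <- as.numeric(unlist(cfg$signal$band))
  class(cfg) <- c("respvar_config", "list")
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys override [respvar_config()] defaults.
#' @return `respvar_config` list.
#' @export
read_config <- function(path) {
  do.call(respvar_config, yaml::read_yaml(path))
}

write_table <- function(d, path) {
  utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Run the full respiratory-variability pipeline
#'
#' Orchestrates simulate (or load) -> signal conditioning + QC ->
#' breath segmentation -> RV metrics -> group comparison -> optional
#' prediction, writing per-stage artifacts and a reproducibility
#' manifest into `out_dir`. Subjects failing quality control are
#' excluded from downstream stages and listed in the exclusion log.
#' With a fixed seed the feature, comparison and report files are
#' byte-identical across reruns.
#'
#' @param config a [respvar_config()] (or list of overrides).
#' @param out_dir output directory (created if needed).
#' @param recordings optional named list of `raw_recording` objects to
#'   analyse instead of simulating (requires `subjects` too).
#' @param subjects subject covariate table when `recordings` is given.
#' @return invisibly, a list with `features`, `comparison`, `subjects`,
#'   `excluded`, `reports`, `manifest_path`.
#' @export
run_pipeline <- function(config = respvar_config(), out_dir = "respvar_run",
                         recordings = NULL, subjects = NULL) {
  if (!inherits(config, "respvar_config")) {
    config <- do.call(respvar_config, config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[respvar] ", msg)
  }

  if (is.null(recordings)) {
    if (!isTRUE(config$simulate$enabled)) {
      stop("stage `simulate` failed: no recordings given and simulation disabled",
           call. = FALSE)
    }
    say("simulate: %d patients + %d controls (seed %d)",
        config$simulate$n_patients, config$simulate$n_controls, seed)
    cohort <- simulate_cohort(
      cohort_spec(n_patients = config$simulate$n_patients,
                  n_controls = config$simulate$n_controls),
      seed = seed)
    recordings <- lapply(cohort$subjects, `[[`, "recording")
    names(recordings) <- vapply(cohort$subjects,
                                function(s) s$record$subject_id, "")
    subjects <- cohort_subjects(cohort)
  }
  if (is.null(subjects)) {
    stop("stage `extract` failed: subject table required", call. = FALSE)
  }
  write_table(subjects[, setdiff(names(subjects), "crsr_latent")],
              file.path(out_dir, "subjects.csv"))

  feats <- list(); excluded <- list()
  for (sid in names(recordings)) {
    bt <- tryCatch(
      extract_breaths(recordings[[sid]],
                      band = config$signal$band, order = config$signal$order,
                      ma_window = config$signal$ma_window,
                      min_breath_s = config$breaths$min_breath_s,
                      min_prominence_frac = config$breaths$min_prominence_frac,
                      refine = config$breaths$refine,
                      polarity = config$breaths$polarity),
      respvar_qc_error = function(e) e)
    if (inherits(bt, "respvar_qc_error")) {
      excluded[[sid]] <- paste(attr(bt, "qc")$flags %||% "qc", collapse = ",")
      say("exclude %s: %s", sid, conditionMessage(bt))
      next
    }
    wt <- tryCatch(window_select(bt, config$window_s), error = function(e) e)
    if (inherits(wt, "error")) {
      excluded[[sid]] <- "too_short_window"
      say("exclude %s: %s", sid, conditionMessage(wt))
      next
    }
    prof <- compute_rv_profile(wt)
    feats[[sid]] <- data.frame(subject_id = sid,
                               n_breaths = attr(prof, "n_breaths"),
                               as.list(unclass(prof)))
  }
  features <- do.call(rbind, c(feats, make.row.names = FALSE))
  say("features: %d/%d subjects analysed (%d excluded)",
      nrow(features), length(recordings), length(excluded))
  write_table(features, file.path(out_dir, "features.csv"))

  comparison <- compare_groups(features, subjects,
                               B = config$compare$B, seed = seed,
                               alpha = config$compare$alpha,
                               boot_stage = config$compare$boot_stage)
  write_table(as.data.frame(comparison), file.path(out_dir, "comparison.csv"))
  say("compare: %d/%d metrics significant at q < %g",
      sum(comparison$significant), nrow(comparison), config$compare$alpha)

  reports <- list()
  for (task in config$predict$tasks) {
    mat <- build_matrix(features, subjects, target = task)
    rep_i <- if (task == "crsr") {
      train_crsr_models(mat$X, mat$y,
                        config = list(n_iter = config$predict$n_iter),
                        seed = seed)
    } else {
      train_outcome_models(mat$X, mat$y,
                           config = list(n_iter = config$predict$n_iter),
                           seed = seed)
    }
    reports[[task]] <- rep_i
    jsonlite::write_json(
      lapply(rep_i$metrics, function(col) col),
      file.path(out_dir, sprintf("report_%s.json", task)),
      auto_unbox = TRUE, digits = NA)
    say("predict[%s]: done", task)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  artifacts <- c("subjects.csv", "features.csv", "comparison.csv",
                 vapply(names(reports),
                        function(tk) sprintf("report_%s.json", tk), ""))
  manifest <- list(
    package = "respvar",
    version = as.character(utils::packageVersion("respvar")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_attempted = length(recordings),
    n_analysed = nrow(features),
    excluded = if (length(excluded)) excluded else NULL,
    files = as.list(tools::md5sum(file.path(out_dir, artifacts))))
  names(manifest$files) <- artifacts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(features = features, comparison = comparison,
                 subjects = subjects, excluded = excluded, reports = reports,
                 manifest_path = file.path(out_dir, "manifest.json")))
}

#' Write a recording to the interchange CSV format
#'
#' @param rec a `raw_recording`.
#' @param path output CSV (`time,ax,ay,az` header).
#' @export
write_recording <- function(rec, path) {
  write_table(as.data.frame(rec)[, c("time", "ax", "ay", "az")], path)
}
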