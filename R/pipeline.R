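#' Pipeline configuration
#'
#' Aggregates the settings of every stage. Round-trips losslessly through
#' YAML via [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param filter A [filter_config()].
#' @param delineation A [delineation_config()].
#' @param iab_threshold_ms,iab_leads,iab_lead_rule,iab_use_corrected IAB
#'   settings, see [classify_iab()].
#' @param alpha Two-sided significance level of the statistics layer.
#' @param standardize_continuous Z-score continuous Cox covariates.
#' @param censor_months Censoring horizon for successes.
#' @param seed Integer seed for all randomised steps.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(filter = filter_config(),
                            delineation = delineation_config(),
                            iab_threshold_ms = 120,
                            iab_leads = c("II", "III", "aVF"),
                            iab_lead_rule = "any",
                            iab_use_corrected = FALSE,
                            alpha = 0.05,
                            standardize_continuous = TRUE,
                            censor_months = 12,
                            seed = 1L) {
  structure(list(
    filter = filter, delineation = delineation,
    iab_threshold_ms = iab_threshold_ms, iab_leads = iab_leads,
    iab_lead_rule = iab_lead_rule, iab_use_corrected = iab_use_corrected,
    alpha = alpha, standardize_continuous = standardize_continuous,
    censor_months = censor_months, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    filter = do.call(filter_config, raw$filter %||% list()),
    delineation = do.call(delineation_config, raw$delineation %||% list())
  )
  for (k in setdiff(names(raw), c("filter", "delineation"))) cfg[[k]] <- raw[[k]]
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$filter <- unclass(out$filter)
  out$delineation <- unclass(out$delineation)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract patient features from recordings
#'
#' End-to-end feature stage: for each input — a recording file path or a
#' [synthetic_spec()] — the recording is read or generated, preprocessed
#' (Bessel bandpass then notch), delineated, and reduced to one
#' [extract_features()] row. Manual overrides are picked up from a
#' `<stem>.overrides.csv` file next to each recording. Failures of single
#' recordings are logged and skipped; the run fails only if every input
#' fails. Deterministic given config and seeds.
#'
#' @param inputs List of file paths and/or `synthetic_spec` objects; names
#'   are used as patient ids (defaults to `p<k>` / the file stem).
#' @param config A [pipeline_config()].
#' @param out_csv Optional path for the feature table CSV.
#' @return The feature data frame, with attributes `log` (character vector
#'   of per-recording events) and `skipped` (ids that failed).
#' @export
run_features <- function(inputs, config = pipeline_config(), out_csv = NULL) {
  if (!is.list(inputs) || inherits(inputs, "synthetic_spec")) inputs <- list(inputs)
  ids <- names(inputs)
  if (is.null(ids)) ids <- rep("", length(inputs))
  log <- character(0)
  skipped <- character(0)
  rows <- list()
  for (k in seq_along(inputs)) {
    inp <- inputs[[k]]
    id <- ids[k]
    if (!nzchar(id)) {
      id <- if (is.character(inp)) {
        tools::file_path_sans_ext(basename(inp))
      } else {
        sprintf("p%d", k)
      }
    }
    res <- tryCatch({
      overrides <- NULL
      if (is.character(inp)) {
        rec <- read_recording(inp)
        ov_path <- paste0(tools::file_path_sans_ext(inp), ".overrides.csv")
        if (file.exists(ov_path)) {
          overrides <- read_annotations(ov_path)
          log <- c(log, sprintf("%s: %d override record(s) applied", id, nrow(overrides)))
        }
      } else if (inherits(inp, "synthetic_spec")) {
        rec <- generate_recording(inp)$recording
      } else {
        stop("input must be a file path or a synthetic_spec")
      }
      rec <- preprocess_recording(rec, config$filter)
      del <- withCallingHandlers(
        delineate_recording(rec, config$delineation, overrides),
        warning = function(w) {
          log <<- c(log, sprintf("%s: %s", id, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
      nflag <- sum(!is.na(del$beats$flag))
      if (nflag > 0) log <- c(log, sprintf("%s: %d beat(s) flagged", id, nflag))
      extract_features(del$beats, del$heart_rate_bpm, patient_id = id,
                       iab_threshold_ms = config$iab_threshold_ms,
                       iab_leads = config$iab_leads,
                       iab_lead_rule = config$iab_lead_rule,
                       iab_use_corrected = config$iab_use_corrected)$features
    }, error = function(e) {
      log <<- c(log, sprintf("%s: SKIPPED (%s)", id, conditionMessage(e)))
      skipped <<- c(skipped, id)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("all recordings failed:\n", paste(log, collapse = "\n"))
  # align columns across patients (leads may differ)
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(cols, names(r))) r[[m]] <- NA
    r[cols]
  })
  features <- do.call(rbind, rows)
  if (!is.null(out_csv)) write_feature_table(features, out_csv)
  attr(features, "log") <- log
  attr(features, "skipped") <- skipped
  features
}

#' Run the cohort statistics stage
#'
#' Joins a feature table to an outcome table on `patient_id` and produces
#' the per-variable comparison report ([cohort_report()]) plus run
#' metadata. Unmatched ids are listed; the run aborts when more than half
#' of the feature rows are unmatched.
#'
#' @param features Feature data frame or CSV path (from [run_features()]).
#' @param outcomes Outcome data frame or CSV path with `patient_id`,
#'   `outcome`, `followup_months`, `event_time_months`.
#' @param config A [pipeline_config()].
#' @param out_prefix Optional path prefix: writes `<prefix>_report.csv` and
#'   `<prefix>_meta.json`.
#' @return List with `report` (a `cohort_report`), `unmatched`, `meta`.
#' @export
run_cohort <- function(features, outcomes, config = pipeline_config(),
                       out_prefix = NULL) {
  if (is.character(features)) features <- read_feature_table(features)
  if (is.character(outcomes)) outcomes <- read_cohort_table(outcomes)
  stopifnot("patient_id" %in% names(features), "patient_id" %in% names(outcomes))
  unmatched <- setdiff(features$patient_id, outcomes$patient_id)
  if (length(unmatched) > 0.5 * nrow(features)) {
    stop("more than 50% of feature rows unmatched in the outcome table: ",
         paste(utils::head(unmatched, 5), collapse = ", "), " ...")
  }
  merged <- merge(outcomes, features, by = "patient_id")
  if (!any(merged$outcome == "failure")) stop("cohort has no failures after joining")
  rep <- cohort_report(merged, alpha = config$alpha,
                       standardize_continuous = config$standardize_continuous,
                       censor_months = config$censor_months)
  meta <- list(
    n_patients = nrow(merged),
    n_success = sum(merged$outcome == "success"),
    n_failure = sum(merged$outcome == "failure"),
    unmatched_ids = unmatched,
    alpha = config$alpha,
    standardize_continuous = config$standardize_continuous,
    censor_months = config$censor_months,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pwavetools"))
  )
  if (!is.null(out_prefix)) {
    utils::write.csv(as.data.frame(rep), paste0(out_prefix, "_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(meta, paste0(out_prefix, "_meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(report = rep, unmatched = unmatched, meta = meta)
}
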