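#' Mean and standard error of the mean
#'
#' @param values Numeric vector, length >= 2.
#' @return Named list `mean`, `sem` (sample sd over sqrt(n)).
#' @export
mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a standard error")
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n))
}

#' Compare a continuous variable between two groups
#'
#' Normality-gated two-sample test: Shapiro-Wilk is run on each group and,
#' when both pass at `normality_alpha`, a two-sided Welch t-test is used;
#' otherwise a Mann-Whitney U test with the tie-corrected normal
#' approximation. Group summaries are mean +/- SEM.
#'
#' @param x_success,x_failure Numeric vectors (each n >= 3).
#' @param normality_alpha Shapiro-Wilk gate level.
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row `comparison_result` data frame: group n/mean/sem,
#'   `test` (`"t"` or `"mann_whitney"`), `statistic`, `p`, `significant`.
#' @export
compare_continuous <- function(x_success, x_failure, normality_alpha = 0.05,
                               alpha = 0.05) {
  x_success <- x_success[!is.na(x_success)]
  x_failure <- x_failure[!is.na(x_failure)]
  if (length(x_success) < 3 || length(x_failure) < 3) {
    stop("both groups need at least 3 observations")
  }
  degenerate <- stats::sd(x_success) == 0 && stats::sd(x_failure) == 0
  if (degenerate && isTRUE(all.equal(mean(x_success), mean(x_failure)))) {
    warning("both groups constant and equal; p set to 1")
    test <- "t"; statistic <- 0; p <- 1
  } else {
    # shapiro.test caps n at 5000; subsample is not needed at cohort scale
    normal <- function(v) {
      if (stats::sd(v) == 0) return(FALSE)
      stats::shapiro.test(v)$p.value > normality_alpha
    }
    if (normal(x_success) && normal(x_failure)) {
      ht <- stats::t.test(x_success, x_failure, var.equal = FALSE)
      test <- "t"; statistic <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- suppressWarnings(
        stats::wilcox.test(x_success, x_failure, exact = FALSE, correct = TRUE)
      )
      test <- "mann_whitney"; statistic <- unname(ht$statistic); p <- ht$p.value
    }
  }
  ms <- mean_sem(x_success); mf <- mean_sem(x_failure)
  res <- data.frame(
    n_success = length(x_success), n_failure = length(x_failure),
    mean_success = ms$mean, sem_success = ms$sem,
    mean_failure = mf$mean, sem_failure = mf$sem,
    test = test, statistic = statistic, p = p,
    significant = p < alpha,
    stringsAsFactors = FALSE
  )
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Compare a categorical variable between two groups
#'
#' 2x2 association test: Fisher's exact test when any expected cell count is
#' below 5, otherwise Pearson's chi-squared without continuity correction.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = category levels).
#' @param alpha Significance level for the flag.
#' @return A one-row `comparison_result` data frame with `test`
#'   (`"chi2"` or `"fisher"`), `statistic` (chi-squared statistic or NA),
#'   `p`, `significant`, and the group counts.
#' @export
compare_categorical <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in 2x2 table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    test <- "fisher"; statistic <- NA_real_; p <- ht$p.value
  } else {
    ht <- stats::chisq.test(tab, correct = FALSE)
    test <- "chi2"; statistic <- unname(ht$statistic); p <- ht$p.value
  }
  res <- data.frame(
    n_success = sum(tab[1, ]), n_failure = sum(tab[2, ]),
    count_success = tab[1, 1], count_failure = tab[2, 1],
    test = test, statistic = statistic, p = p,
    significant = p < alpha,
    stringsAsFactors = FALSE
  )
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Intraobserver variability of paired measurements
#'
#' Element-wise absolute differences between two measurement passes of the
#' same recordings: returns their mean, standard error, and the mean
#' expressed as a percentage of the mean paired measurement level
#' `100 * mean(|d1 - d2|) / mean((d1 + d2) / 2)`.
#'
#' @param day1,day2 Paired numeric vectors of equal length.
#' @return List `mean_abs_diff`, `sem_abs_diff`, `percent`.
#' @export
intraobserver_variability <- function(day1, day2) {
  if (length(day1) != length(day2)) stop("day1 and day2 must have equal length")
  d <- abs(day1 - day2)
  ms <- if (length(d) >= 2) mean_sem(d) else list(mean = mean(d), sem = NA_real_)
  level <- mean((day1 + day2) / 2)
  pct <- if (level == 0) 0 else 100 * ms$mean / abs(level)
  list(mean_abs_diff = ms$mean, sem_abs_diff = ms$sem, percent = pct)
}

#' Paired P wave count of a variability protocol
#'
#' Number of paired P wave measurements analysed in one pass of an
#' intraobserver study: recordings x leads x beats averaged per lead.
#'
#' @param n_ecgs Number of re-analysed recordings.
#' @param n_leads Leads per recording.
#' @param n_beats Beats averaged per lead.
#' @return Integer count.
#' @export
variability_protocol_count <- function(n_ecgs = 22, n_leads = 12, n_beats = 20) {
  as.integer(n_ecgs) * as.integer(n_leads) * as.integer(n_beats)
}

#' Per-variable cohort comparison report
#'
#' For every requested feature column, compares the success and failure arms
#' (continuous variables via [compare_continuous()], logical/binary ones via
#' [compare_categorical()]) and fits a univariable Cox hazard ratio for
#' recurrence ([cox_univariable()]) with successes censored at
#' `censor_months`. Continuous covariates are z-standardised before the Cox
#' fit by default, so their hazard ratios are per standard deviation (noted
#' in the `hr_scale` column). P-values are reported unadjusted, with a
#' Benjamini-Hochberg column added for transparency.
#'
#' @param cohort Data frame with `outcome` (`"success"`/`"failure"`),
#'   `event_time_months` (for failures), feature columns.
#' @param variables Character vector of feature columns to compare; default
#'   all numeric/logical columns except identifiers and outcome fields.
#' @param alpha Significance level.
#' @param standardize_continuous Z-score continuous covariates in the Cox fit.
#' @param censor_months Administrative censoring time for successes.
#' @return A `cohort_report` data frame: one row per variable with group
#'   summaries, test, p, HR and 95% CI, `p_bh`, `significant`.
#' @export
cohort_report <- function(cohort, variables = NULL, alpha = 0.05,
                          standardize_continuous = TRUE, censor_months = 12) {
  stopifnot(is.data.frame(cohort), "outcome" %in% names(cohort))
  bad <- setdiff(unique(cohort$outcome), c("success", "failure"))
  if (length(bad)) stop("outcome must be success/failure")
  if (!any(cohort$outcome == "failure")) stop("cohort has no failures")
  if (!any(cohort$outcome == "success")) stop("cohort has no successes")

  reserved <- c("patient_id", "outcome", "followup_months", "event_time_months")
  if (is.null(variables)) {
    variables <- setdiff(names(cohort), reserved)
    ok <- vapply(cohort[variables], function(v) is.numeric(v) || is.logical(v),
                 logical(1))
    variables <- variables[ok]
  }
  missing <- setdiff(variables, names(cohort))
  if (length(missing)) {
    warning("missing feature column(s) skipped: ", paste(missing, collapse = ", "))
    variables <- intersect(variables, names(cohort))
  }

  event <- cohort$outcome == "failure"
  time <- ifelse(event,
                 cohort$event_time_months,
                 censor_months)
  if (any(event & is.na(cohort$event_time_months))) {
    stop("failures must carry event_time_months")
  }

  rows <- list()
  for (v in variables) {
    val <- cohort[[v]]
    is_binary <- is.logical(val) ||
      (is.numeric(val) && all(val %in% c(0, 1, NA)))
    row <- tryCatch({
      if (is_binary) {
        val_l <- as.logical(val)
        tab <- rbind(
          success = c(sum(val_l & !event, na.rm = TRUE), sum(!val_l & !event, na.rm = TRUE)),
          failure = c(sum(val_l & event, na.rm = TRUE), sum(!val_l & event, na.rm = TRUE))
        )
        cmp <- compare_categorical(tab, alpha = alpha)
        cx <- cox_univariable(as.numeric(val_l), time, event, standardize = FALSE)
        data.frame(
          variable = v, type = "binary",
          n_success = cmp$n_success, n_failure = cmp$n_failure,
          mean_success = cmp$count_success, sem_success = NA_real_,
          mean_failure = cmp$count_failure, sem_failure = NA_real_,
          test = cmp$test, statistic = cmp$statistic, p = cmp$p,
          hr = cx$hr, hr_ci_low = cx$ci_low, hr_ci_high = cx$ci_high,
          hr_p = cx$p, hr_scale = "per_unit",
          separation = cx$separation,
          stringsAsFactors = FALSE
        )
      } else {
        cmp <- compare_continuous(val[!event], val[event], alpha = alpha)
        cx <- cox_univariable(val, time, event,
                              standardize = standardize_continuous)
        data.frame(
          variable = v, type = "continuous",
          n_success = cmp$n_success, n_failure = cmp$n_failure,
          mean_success = cmp$mean_success, sem_success = cmp$sem_success,
          mean_failure = cmp$mean_failure, sem_failure = cmp$sem_failure,
          test = cmp$test, statistic = cmp$statistic, p = cmp$p,
          hr = cx$hr, hr_ci_low = cx$ci_low, hr_ci_high = cx$ci_high,
          hr_p = cx$p,
          hr_scale = if (standardize_continuous) "per_sd" else "per_unit",
          separation = cx$separation,
          stringsAsFactors = FALSE
        )
      }
    }, error = function(e) {
      warning(sprintf("variable '%s' skipped: %s", v, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no variable could be compared")
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("cohort_report", "data.frame")
  out
}
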