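#' Simulate a synthetic ablation cohort
#'
#' Generates an outcome table with exact arm sizes, per-group continuous
#' features, and a binary covariate whose true recurrence hazard ratio is
#' `hr_true`. The generative model is: covariate `X ~ Bernoulli(prevalence)`,
#' event time `T ~ Exponential(lambda0 * hr_true^X)`, failure iff
#' `T <= followup_months` with successes censored at `followup_months`.
#' The baseline rate `lambda0` is solved so the marginal failure probability
#' matches `n_failure / (n_success + n_failure)`, and sampling is performed
#' conditionally on the outcome (Bernoulli posterior for `X`, truncated
#' exponential for the event times), so the requested arm sizes are exact
#' while a Cox fit recovers `hr_true` in expectation.
#'
#' @param n_success,n_failure Arm sizes (> 0).
#' @param effects Optional data frame describing continuous features, with
#'   columns `variable`, `mean_success`, `sd_success`, `mean_failure`,
#'   `sd_failure` (sds > 0); each feature is drawn normally per arm.
#' @param hr_true True hazard ratio of the binary covariate (> 0).
#' @param followup_months Administrative censoring horizon.
#' @param prevalence Marginal prevalence of the binary covariate.
#' @param seed Integer seed.
#' @param path Optional CSV path; when given the table is also written.
#' @return Data frame with `patient_id`, `outcome`, `followup_months`,
#'   `event_time_months`, `risk_covariate` (0/1), and one column per
#'   requested feature.
#' @export
simulate_cohort <- function(n_success, n_failure, effects = NULL,
                            hr_true = 2, followup_months = 12,
                            prevalence = 0.3, seed = 1L, path = NULL) {
  if (n_success <= 0 || n_failure <= 0) stop("arm sizes must be > 0")
  if (hr_true <= 0) stop("hr_true must be > 0")
  if (!is.null(effects)) {
    need <- c("variable", "mean_success", "sd_success", "mean_failure", "sd_failure")
    if (!all(need %in% names(effects))) {
      stop("effects needs columns: ", paste(need, collapse = ", "))
    }
    if (any(effects$sd_success <= 0) || any(effects$sd_failure <= 0)) {
      stop("effect sds must be > 0")
    }
  }
  set.seed(as.integer(seed))
  n <- n_success + n_failure
  q <- n_failure / n
  fu <- followup_months

  # lambda0 such that the marginal event probability equals q
  pev <- function(l0) {
    prevalence * (1 - exp(-fu * l0 * hr_true)) +
      (1 - prevalence) * (1 - exp(-fu * l0))
  }
  lambda0 <- stats::uniroot(function(l) pev(l) - q,
                            interval = c(1e-10, 100), tol = 1e-12)$root

  # covariate prevalence conditional on outcome (Bayes)
  p_ev_x1 <- 1 - exp(-fu * lambda0 * hr_true)
  p_ev_x0 <- 1 - exp(-fu * lambda0)
  p1_fail <- prevalence * p_ev_x1 / q
  p1_succ <- prevalence * (1 - p_ev_x1) / (1 - q)

  x_fail <- stats::rbinom(n_failure, 1, p1_fail)
  x_succ <- stats::rbinom(n_success, 1, p1_succ)

  # truncated exponential on (0, fu] by inverse CDF
  rate_fail <- lambda0 * hr_true^x_fail
  u <- stats::runif(n_failure)
  t_fail <- -log(1 - u * (1 - exp(-rate_fail * fu))) / rate_fail

  df <- data.frame(
    patient_id = sprintf("p%04d", seq_len(n)),
    outcome = c(rep("failure", n_failure), rep("success", n_success)),
    followup_months = fu,
    event_time_months = c(t_fail, rep(NA_real_, n_success)),
    risk_covariate = c(x_fail, x_succ),
    stringsAsFactors = FALSE
  )
  if (!is.null(effects)) {
    for (i in seq_len(nrow(effects))) {
      v <- effects$variable[i]
      df[[v]] <- NA_real_
      df[[v]][df$outcome == "failure"] <-
        stats::rnorm(n_failure, effects$mean_failure[i], effects$sd_failure[i])
      df[[v]][df$outcome == "success"] <-
        stats::rnorm(n_success, effects$mean_success[i], effects$sd_success[i])
    }
  }
  # shuffle so row order carries no outcome information
  df <- df[sample.int(n), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}
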