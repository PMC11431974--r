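#' Univariable Cox proportional hazards fit
#'
#' Single-covariate Cox regression fitted by Newton-Raphson on the partial
#' likelihood with Breslow handling of tied event times. Reports the hazard
#' ratio `exp(beta)`, the Wald 95% confidence interval and two-sided p-value.
#' With `standardize = TRUE` a continuous covariate is z-scored first, so
#' the hazard ratio is per standard deviation of the covariate.
#'
#' Monotone likelihoods (complete separation of events in the risk sets,
#' e.g. every event carries one covariate value and no event the other) are
#' detected by divergence of the estimate and returned flagged, without a
#' confidence interval.
#'
#' @param x Numeric covariate vector.
#' @param time Follow-up or event time (months).
#' @param event Logical or 0/1 event indicator.
#' @param standardize Z-score the covariate before fitting.
#' @param max_iter,tol Newton-Raphson controls.
#' @return List with `hr`, `ci_low`, `ci_high`, `p`, `beta`, `se`,
#'   `n_events`, `separation` (logical flag), `standardized`.
#' @export
cox_univariable <- function(x, time, event, standardize = FALSE,
                            max_iter = 50L, tol = 1e-10) {
  event <- as.integer(as.logical(event))
  stopifnot(length(x) == length(time), length(x) == length(event))
  keep <- stats::complete.cases(x, time, event)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  if (sum(event) < 5) stop("need at least 5 events to fit a hazard ratio")
  if (stats::sd(x) == 0) stop("covariate is constant")
  if (standardize) x <- (x - mean(x)) / stats::sd(x)

  # sort by decreasing time so risk sets are cumulative prefixes
  ord <- order(time, decreasing = TRUE)
  x <- x[ord]; time <- time[ord]; event <- event[ord]

  neg_gradient_info <- function(beta) {
    w <- exp(beta * x)
    s0 <- cumsum(w)
    s1 <- cumsum(w * x)
    s2 <- cumsum(w * x^2)
    # Breslow: each event at time t uses the full risk set {time >= t};
    # within a tie block every event must see the whole block, i.e. the
    # prefix sums at the last index of the block
    bi <- seq_along(time)
    block_end <- bi
    # propagate the block-end index backwards over ties
    for (i in rev(seq_along(bi))) {
      if (i < length(bi) && time[i] == time[i + 1]) block_end[i] <- block_end[i + 1]
    }
    ev <- event == 1L
    mu <- s1[block_end[ev]] / s0[block_end[ev]]
    v <- s2[block_end[ev]] / s0[block_end[ev]] - mu^2
    list(
      grad = sum(x[ev] - mu),
      info = sum(v),
      loglik = sum(beta * x[ev] - log(s0[block_end[ev]]))
    )
  }

  beta <- 0
  separation <- FALSE
  for (it in seq_len(max_iter)) {
    gi <- neg_gradient_info(beta)
    if (gi$info <= 1e-12) { separation <- TRUE; break }
    step <- gi$grad / gi$info
    # dampen wild steps for stability
    if (abs(step) > 5) step <- sign(step) * 5
    beta <- beta + step
    if (abs(beta) > 20) { separation <- TRUE; break }
    if (abs(step) < tol) break
  }

  if (separation) {
    return(list(hr = exp(beta), ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, beta = beta, se = NA_real_,
                n_events = sum(event), separation = TRUE,
                standardized = standardize))
  }
  gi <- neg_gradient_info(beta)
  se <- 1 / sqrt(gi$info)
  z <- beta / se
  list(
    hr = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)),
    beta = beta, se = se,
    n_events = sum(event), separation = FALSE,
    standardized = standardize
  )
}
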