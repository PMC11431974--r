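test_that("mean and SEM follow the sample-sd definition", {
  ms <- mean_sem(c(1, 2, 3))
  expect_equal(ms$mean, 2)
  expect_equal(ms$sem, 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(mean_sem(rep(4.2, 5))$sem, 0)
  expect_error(mean_sem(7), "at least 2")
})

test_that("identical groups are not significant", {
  x <- c(1.2, 1.7, 2.4, 3.3, 2.2, 1.9, 2.8)
  res <- compare_continuous(x, x)
  expect_gt(res$p, 0.9)
  expect_false(res$significant)
})

test_that("a clear mean shift selects the t branch and rejects", {
  set.seed(42)
  xs <- rnorm(154, 0, 1)
  xf <- rnorm(57, 1, 1)
  res <- compare_continuous(xs, xf)
  expect_equal(res$test, "t")
  expect_lt(res$p, 0.001)
  # cross-check statistic against the Welch formula
  tW <- (mean(xs) - mean(xf)) /
    sqrt(var(xs) / length(xs) + var(xf) / length(xf))
  expect_equal(res$statistic, tW, tolerance = 1e-10)
  expect_equal(res$mean_success, mean(xs))
  expect_equal(res$sem_success, sd(xs) / sqrt(154), tolerance = 1e-10)
})

test_that("non-normal samples route to the Mann-Whitney branch", {
  set.seed(7)
  xs <- rexp(60)^3
  xf <- rexp(40)^3
  res <- compare_continuous(xs, xf)
  expect_equal(res$test, "mann_whitney")
  # the branch decision mirrors per-group Shapiro-Wilk at 0.05
  expect_true(shapiro.test(xs)$p.value <= 0.05 ||
                shapiro.test(xf)$p.value <= 0.05)
})

test_that("Mann-Whitney p-values are invariant under monotone transforms", {
  set.seed(8)
  xs <- rexp(50)^2
  xf <- rexp(50)^2 + 0.5
  p1 <- compare_continuous(xs, xf)$p
  p2 <- compare_continuous(log(xs + 1), log(xf + 1))$p
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("t-branch p-values are invariant under common affine transforms", {
  set.seed(9)
  xs <- rnorm(40, 5, 2)
  xf <- rnorm(30, 6, 2)
  p1 <- compare_continuous(xs, xf)$p
  p2 <- compare_continuous(3 * xs - 7, 3 * xf - 7)$p
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("degenerate equal-constant groups warn and return p = 1", {
  expect_warning(res <- compare_continuous(rep(1, 5), rep(1, 6)), "constant")
  expect_equal(res$p, 1)
})

test_that("the 2x2 test picks chi-squared vs Fisher by expected counts", {
  # long-term AAD use by outcome, counts as published
  aad <- rbind(success = c(39, 154 - 39), failure = c(33, 57 - 33))
  res <- compare_categorical(aad)
  expect_equal(res$test, "chi2")
  expect_lt(res$p, 0.001)
  # chi-squared equals the sum((O-E)^2/E) oracle
  E <- outer(rowSums(aad), colSums(aad)) / sum(aad)
  expect_equal(res$statistic, sum((aad - E)^2 / E), tolerance = 1e-9)
  expect_equal(res$p, pchisq(sum((aad - E)^2 / E), 1, lower.tail = FALSE),
               tolerance = 1e-9)

  res2 <- compare_categorical(matrix(1, 2, 2))
  expect_equal(res2$test, "fisher")
  expect_equal(res2$p, 1)

  res3 <- compare_categorical(rbind(c(10, 0), c(0, 10)))
  expect_lt(res3$p, 0.001)

  expect_error(compare_categorical(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(compare_categorical(rbind(c(1.5, 2), c(1, 2))), "integer")
})

test_that("intraobserver variability returns raw and percent agreement", {
  same <- intraobserver_variability(c(100, 120, 130), c(100, 120, 130))
  expect_equal(same$mean_abs_diff, 0)
  expect_equal(same$percent, 0)
  two <- intraobserver_variability(c(100, 100), c(104, 96))
  expect_equal(two$mean_abs_diff, 4)
  expect_equal(two$percent, 4)
  expect_error(intraobserver_variability(1:3, 1:4), "equal length")
})

test_that("the variability protocol size is recordings x leads x beats", {
  expect_equal(variability_protocol_count(22, 12, 20), 5280L)
  expect_equal(variability_protocol_count(1, 12, 20), 240L)
})

test_that("the Cox fit agrees with the survival package on fixed fixtures", {
  skip_if_not_installed("survival")
  set.seed(11)
  x <- rbinom(211, 1, 0.3)
  t0 <- rexp(211, 0.05 * 2^x)
  ev <- t0 <= 12
  tt <- round(pmin(t0, 12), 1)  # rounding induces ties -> Breslow path
  mine <- cox_univariable(x, tt, ev)
  ref <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = "breslow")
  expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-4)
  expect_equal(mine$se, sqrt(vcov(ref)[1, 1]), tolerance = 1e-4)

  z <- rnorm(211)
  t1 <- rexp(211, 0.05 * exp(0.4 * z))
  e1 <- t1 <= 12
  tt1 <- pmin(t1, 12)
  mine2 <- cox_univariable(z, tt1, e1)
  ref2 <- survival::coxph(survival::Surv(tt1, e1) ~ z, ties = "breslow")
  expect_equal(mine2$beta, unname(coef(ref2)), tolerance = 1e-4)
})

test_that("a covariate independent of outcome gives HR near 1 with covering CI", {
  set.seed(12)
  x <- rbinom(200, 1, 0.4)
  tt <- rexp(200, 0.08)
  ev <- tt <= 12
  tt <- pmin(tt, 12)
  f <- cox_univariable(x, tt, ev)
  expect_true(f$ci_low <= 1 && 1 <= f$ci_high)
  expect_equal(f$hr, 1, tolerance = 0.5)
  expect_gt(f$p, 0.05)
})

test_that("complete separation is flagged rather than reported with a CI", {
  x <- c(rep(1, 30), rep(0, 170))
  tt <- c(runif(30, 1, 11), rep(12, 170))
  ev <- c(rep(TRUE, 30), rep(FALSE, 170))
  f <- cox_univariable(x, tt, ev)
  expect_true(f$separation)
  expect_true(is.na(f$ci_low))
})

test_that("degenerate Cox inputs are rejected", {
  expect_error(cox_univariable(rep(1, 10), 1:10, rep(TRUE, 10)), "constant")
  expect_error(cox_univariable(rnorm(10), 1:10, c(TRUE, rep(FALSE, 9))),
               "5 events")
})

test_that("the cohort report flags a planted effect and only that row's family", {
  eff <- data.frame(
    variable = c("marker", "noise1", "noise2"),
    mean_success = c(0, 0, 0), sd_success = c(1, 1, 1),
    mean_failure = c(1.2, 0, 0), sd_failure = c(1, 1, 1)
  )
  hits_marker <- 0
  for (s in 1:20) {
    d <- simulate_cohort(154, 57, effects = eff, hr_true = 2, seed = 100 + s)
    rep <- cohort_report(d, variables = c("marker", "noise1", "noise2",
                                          "risk_covariate"))
    hits_marker <- hits_marker + rep$significant[rep$variable == "marker"]
  }
  expect_gte(hits_marker, 18)  # ~ the planted effect is found almost always
})

test_that("the report carries HR columns and a BH adjustment without altering p", {
  d <- simulate_cohort(80, 40, hr_true = 2, seed = 3)
  rep <- cohort_report(d)
  expect_true(all(c("hr", "hr_ci_low", "hr_ci_high", "p_bh") %in% names(rep)))
  expect_true(all(rep$p_bh >= rep$p - 1e-12))
  expect_true(all(rep$hr_ci_low <= rep$hr & rep$hr <= rep$hr_ci_high |
                    rep$separation))
})

test_that("a cohort without failures is a hard error", {
  d <- simulate_cohort(50, 25, hr_true = 1.5, seed = 5)
  d$outcome <- "success"
  expect_error(cohort_report(d), "failures")
})
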