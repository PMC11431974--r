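test_that("P wave duration is the fiducial gap in milliseconds", {
  expect_equal(compute_pwd(400, 520, 1000), 120)
  expect_equal(compute_pwd(100, 160, 500), 120)
  expect_error(compute_pwd(400, 400, 1000), "greater")
})

test_that("the Hodges correction is additive in heart rate", {
  expect_equal(correct_pwd_hodges(120, 60), 120)
  expect_equal(correct_pwd_hodges(120, 80), 155)
  expect_equal(correct_pwd_hodges(140, 40), 105)
  expect_error(correct_pwd_hodges(120, 0), "heart_rate")
  # identity at 60 bpm for arbitrary durations
  set.seed(1)
  pwd <- runif(50, 60, 200)
  expect_equal(correct_pwd_hodges(pwd, 60), pwd)
})

test_that("P wave voltage is the signed extremal deviation from the isoelectric line", {
  tri <- triangle_signal()$x[501:621]
  expect_equal(compute_pwv(tri, 0), 0.2)
  expect_equal(compute_pwv(tri + 0.05, 0.05), 0.2)
  biph <- c(0.1 * sin(pi * (0:60) / 60), -0.15 * sin(pi * (0:60) / 60))
  expect_equal(compute_pwv(biph, 0), -0.15)
  expect_error(compute_pwv(numeric(0)), "empty")
})

test_that("triangle and trapezoid areas agree on triangular P waves", {
  expect_equal(compute_pwa(pwd_ms = 140, pwv_mv = 0.2, method = "triangle"), 14)
  seg <- triangle_signal(duration = 120, amp = 0.2)$x[501:621]
  trap <- compute_pwa(seg, 0, fs = 1000, method = "trapezoid")
  expect_equal(trap, 12, tolerance = 0.2 / 12)
  expect_equal(compute_pwa(rep(0, 50), 0, fs = 1000), 0)
  # property: equality within one-sample discretisation across random triangles
  set.seed(2)
  for (i in 1:10) {
    d <- sample(60:180, 1)
    a <- runif(1, 0.05, 0.4)
    seg <- a * (1 - abs(2 * (0:d) / d - 1))
    expect_equal(compute_pwa(seg, 0, fs = 1000),
                 compute_pwa(pwd_ms = d, pwv_mv = a, method = "triangle"),
                 tolerance = a * 2 / (0.5 * d * a))
  }
})

test_that("trapezoid area is non-negative and scales with amplitude", {
  set.seed(3)
  seg <- rnorm(100, 0, 0.1)
  expect_gte(compute_pwa(seg, 0, fs = 1000), 0)
  c_ <- 3.7
  expect_equal(compute_pwa(c_ * seg, 0, fs = 1000),
               c_ * compute_pwa(seg, 0, fs = 1000))
  expect_equal(compute_pwv(c_ * seg, 0), c_ * compute_pwv(seg, 0))
})

test_that("dispersion is the range of its inputs, permutation-invariant", {
  expect_equal(compute_pwdisp(c(110, 120, 150)), 40)
  expect_equal(compute_pwdisp(rep(120, 5)), 0)
  expect_error(compute_pwdisp(120), "at least 2")
  set.seed(4)
  for (i in 1:10) {
    v <- 120 + rnorm(20, 0, 5)
    expect_equal(compute_pwdisp(v, "within_lead_beats"), max(v) - min(v))
    expect_equal(compute_pwdisp(sample(v), "within_lead_beats"),
                 compute_pwdisp(v, "within_lead_beats"))
    expect_gte(compute_pwdisp(v), 0)
  }
})

test_that("morphology labels follow qualifying phase runs", {
  hump <- 0.2 * sin(pi * (0:100) / 100)
  expect_equal(classify_morphology(hump, 0, 1000), "mono_pos")
  expect_equal(classify_morphology(-hump, 0, 1000), "mono_neg")
  bi <- c(0.1 * sin(pi * (0:60) / 60), -0.08 * sin(pi * (0:50) / 50))
  expect_equal(classify_morphology(bi, 0, 1000), "biphasic_pm")
  expect_equal(classify_morphology(-bi, 0, 1000), "biphasic_mp")
  # 5 ms sign flicker below the phase duration threshold is ignored
  flick <- hump
  flick[50:54] <- -0.05
  expect_equal(classify_morphology(flick, 0, 1000), "mono_pos")
  expect_equal(classify_morphology(rep(0.001, 100), 0, 1000), "flat")
})

test_that("PTFV1 is the signed terminal-phase force in mm.s", {
  v1 <- c(0.08 * sin(pi * (0:60) / 60), -0.05 * sin(pi * (0:59) / 59))
  expect_equal(compute_ptfv1(v1, 0, 1000), -0.03, tolerance = 0.02)
  v2 <- c(0.08 * sin(pi * (0:60) / 60), -0.1 * sin(pi * (0:79) / 79))
  expect_equal(compute_ptfv1(v2, 0, 1000), -0.08, tolerance = 0.02)
  mono <- 0.2 * sin(pi * (0:100) / 100)
  expect_equal(compute_ptfv1(mono, 0, 1000), 0)
})

test_that("IAB needs both the duration threshold and inferior biphasic morphology", {
  morph_bi_avf <- c(II = "mono_pos", III = "mono_pos", aVF = "biphasic_pm")
  morph_mono <- c(II = "mono_pos", III = "mono_pos", aVF = "mono_pos")
  expect_true(classify_iab(c(II = 125, III = 110, aVF = 115), morph_bi_avf))
  expect_false(classify_iab(c(II = 110, III = 108, aVF = 112),
                            c(II = "biphasic_pm", III = "biphasic_pm",
                              aVF = "biphasic_pm")))
  expect_false(classify_iab(c(II = 130, III = 125, aVF = 128), morph_mono))
  expect_error(classify_iab(c(II = 130), c(II = "biphasic_pm")), "not measured")
  # 'all' rule is stricter than 'any'
  morph_one <- c(II = "biphasic_pm", III = "mono_pos", aVF = "mono_pos")
  expect_true(classify_iab(c(II = 130, III = 120, aVF = 120), morph_one, lead_rule = "any"))
  expect_false(classify_iab(c(II = 130, III = 120, aVF = 120), morph_one, lead_rule = "all"))
})

test_that("IAB is monotone in P wave duration", {
  set.seed(5)
  morph <- c(II = "biphasic_pm", III = "mono_pos", aVF = "mono_pos")
  for (i in 1:20) {
    base <- runif(3, 90, 140)
    names(base) <- names(morph)
    lo <- classify_iab(base, morph)
    hi <- classify_iab(base + runif(1, 0, 40), morph)
    expect_false(lo && !hi)
  }
})

test_that("feature extraction averages beats and assembles the patient row", {
  beats <- data.frame(
    lead = rep(c("II", "III", "aVF", "V1"), each = 2),
    beat = rep(1:2, 4),
    pwd_ms = c(118, 122, 118, 122, 130, 130, 110, 110),
    pwv_mv = c(0.2, 0.2, 0.1, 0.1, 0.15, 0.15, 0.08, 0.08),
    pwa_msmv = c(12, 12, 6, 6, 9, 9, 4, 4),
    morphology = c(rep("mono_pos", 6), rep("biphasic_pm", 2)),
    ptfv1_mms = c(rep(NA, 6), -0.03, -0.03),
    used = TRUE, flag = NA_character_,
    stringsAsFactors = FALSE
  )
  f <- extract_features(beats, heart_rate_bpm = 60, patient_id = "x")
  expect_equal(f$leads$pwd_ms[f$leads$lead == "II"], 120)
  expect_equal(f$leads$pwdc_ms[f$leads$lead == "II"], 120)   # 60 bpm identity
  expect_equal(f$pwdisp_global_ms, 130 - 110)
  expect_equal(f$ptfv1_mms, -0.03)
  expect_false(f$iab)  # max PWD 130 >= 120 but biphasic only in V1
  expect_equal(f$features$II_pwd_ms, 120)
  # twenty identical beats per lead reduce to the single-beat values
  b20 <- beats[rep(c(1, 3, 5, 7), each = 20), ]
  b20$beat <- rep(1:20, 4)
  f20 <- extract_features(b20, 70)
  expect_equal(f20$leads$pwd_ms[f20$leads$lead == "II"], 118)
  expect_true(all(f20$leads$disp_ms == 0))
  expect_error(extract_features(beats[beats$used == FALSE, ], 60), "no measurable")
})
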