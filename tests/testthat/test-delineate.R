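test_that("R peaks are recovered in number and position on clean recordings", {
  g <- generate_recording(test_spec(seed = 5, duration_s = 30,
                                    heart_rate_bpm = 60))
  x <- lead_signal(g$recording, "II")
  peaks <- detect_r_peaks(x, 1000)
  expect_equal(length(peaks), length(g$truth$r_peaks))
  expect_lte(max(abs(peaks - g$truth$r_peaks)), 2)
  expect_true(all(diff(peaks) > 0))
})

test_that("a flat signal yields no R peaks, with a warning", {
  expect_warning(peaks <- detect_r_peaks(numeric(3000), 1000), "no R peaks")
  expect_length(peaks, 0)
})

test_that("heart rate is the median-RR rate", {
  expect_equal(estimate_heart_rate(c(0, 1000, 2000, 3000), 1000), 60)
  # one missed beat: median RR robust
  expect_equal(estimate_heart_rate(cumsum(c(0, 750, 750, 1500)), 1000), 80)
  expect_error(estimate_heart_rate(100L, 1000), "2 R peaks")
})

test_that("heart rate estimation survives RR jitter", {
  g <- generate_recording(test_spec(seed = 3, duration_s = 30,
                                    heart_rate_bpm = 75, rr_jitter_ms = 30))
  del <- suppressWarnings(delineate_recording(g$recording))
  expect_equal(del$heart_rate_bpm, 75, tolerance = 2 / 75)
})

test_that("the tangent method finds a triangular T wave's end", {
  fs <- 1000
  x <- numeric(2000)
  x[196:206] <- 1                           # crude QRS at ~200
  x[401:601] <- 0.3 * (1 - abs(seq(-1, 1, length.out = 201)))  # T: 400..600
  res <- detect_t_end(x, r_peak = 200L, next_r = 1100L, fs = fs)
  expect_true(is.na(res$flag))
  expect_lte(abs(res$t_end - 600), 5)
  expect_equal(res$t_peak, 500)
})

test_that("a flat post-QRS segment flags the beat", {
  x <- numeric(2000)
  x[196:206] <- 1
  res <- detect_t_end(x, 200L, 1100L, 1000)
  expect_false(is.na(res$flag))
})

test_that("P peak detection honours the minimum width rule", {
  tri <- triangle_signal()
  # unique extremum: apex found exactly
  res <- detect_p_peak(tri$x, c(300L, 700L), baseline = 0, fs = 1000)
  expect_equal(res$p_peak, tri$apex)

  # a taller but 5 ms noise spike must lose against the 120 ms P wave
  spiky <- tri$x
  spiky[351:355] <- 0.3
  res2 <- detect_p_peak(spiky, c(300L, 700L), 0, 1000)
  expect_equal(res2$p_peak, tri$apex)

  # brute-force oracle: enumerate local extrema, widths by half-prominence walk
  d <- spiky[301:701]
  cand <- which(diff(sign(diff(d))) < 0) + 1
  widths <- vapply(cand, function(i) {
    half <- d[i] / 2
    l <- i; while (l > 1 && d[l - 1] > half) l <- l - 1
    r <- i; while (r < length(d) && d[r + 1] > half) r <- r + 1
    r - l + 1
  }, numeric(1))
  ok <- cand[widths >= 15]
  expect_equal(300L + ok[which.max(d[ok])] - 1L, res2$p_peak)
})

test_that("the larger phase of a biphasic P wins peak detection", {
  x <- numeric(1000)
  x[401:461] <- 0.1 * sin(pi * (0:60) / 60)
  x[461:521] <- -0.15 * sin(pi * (0:60) / 60)
  res <- detect_p_peak(x, c(200L, 600L), 0, 1000)
  expect_equal(res$p_peak, 460L + 30L)  # negative apex
})

test_that("chord onset: degenerate straight line ties to the earliest interior sample", {
  x <- seq(0, 0.2, length.out = 101)  # the signal is the chord
  res <- detect_p_onset(x, 0L, 100L, 1000)
  expect_equal(res$p_onset, 1L)
})

test_that("chord onset finds a piecewise-linear corner exactly (brute-force oracle)", {
  # baseline 0 over [0,100] ms then linear rise to 0.2 mV at 160 ms
  x <- c(rep(0, 101), seq(0, 0.2, length.out = 60)[-1])
  res <- detect_p_onset(x, 0L, 159L, 1000)
  expect_equal(res$p_onset, 100L)
  # oracle: signed perpendicular distance on the mm grid over all samples
  i <- 0:159
  tx <- (i / 1000 * 1000) / 40
  ty <- x * 10
  dx <- tx[160] - tx[1]; dy <- ty[160] - ty[1]
  d <- (dx * (ty - ty[1]) - dy * (tx - tx[1])) / sqrt(dx^2 + dy^2)
  expect_equal(which.min(d[2:159]) + 1L - 1L, 100L)
})

test_that("chord onset is within 2 ms of truth for a clean Gaussian P at a long anchor", {
  fs <- 1000
  pw <- pwave_spec("gaussian", 115, 0.2)
  ps <- pwavetools:::p_wave_samples(pw, fs)
  x <- numeric(1300)
  x[501:(500 + length(ps$y))] <- ps$y
  apex <- 500L + ps$apex - 1L
  res <- detect_p_onset(x, 100L, apex, fs)
  expect_lte(abs(res$p_onset - 500L), 2)
})

test_that("chord offset is symmetric to onset for a symmetric triangular P", {
  tri <- triangle_signal()
  on <- detect_p_onset(tri$x, 200L, as.integer(tri$apex), 1000)
  off <- detect_p_offset(tri$x, as.integer(tri$apex), 900L, 1000)
  expect_lte(abs((tri$apex - on$p_onset) - (off$p_offset - tri$apex)), 1)
  expect_lte(abs(off$p_offset - tri$offset), 1)
})

test_that("threshold-return offset agrees with the mirrored chord on clean input", {
  tri <- triangle_signal()
  cfg_m <- delineation_config(offset_method = "mirrored_chord")
  cfg_t <- delineation_config(offset_method = "threshold_return")
  a <- detect_p_offset(tri$x, as.integer(tri$apex), 900L, 1000, cfg_m)
  b <- detect_p_offset(tri$x, as.integer(tri$apex), 900L, 1000, cfg_t, baseline = 0)
  expect_lte(abs(a$p_offset - b$p_offset), 4)
})

test_that("exactly 20 beats are averaged per lead on a one-minute recording", {
  g <- generate_recording(test_spec(seed = 1, duration_s = 60,
                                    heart_rate_bpm = 60))
  del <- delineate_recording(g$recording)
  used <- table(del$beats$lead[del$beats$used])
  expect_true(all(used == 20))
})

test_that("a shortfall of clean beats uses what is available and warns", {
  g <- generate_recording(test_spec(seed = 1, duration_s = 16,
                                    heart_rate_bpm = 60))
  w <- capture_warnings(del <- delineate_recording(g$recording))
  expect_true(all(grepl("clean beat", w)))
  expect_length(w, 12)  # one shortfall warning per lead
  used <- table(del$beats$lead[del$beats$used])
  expect_true(all(used < 20) && all(used > 5))
})

test_that("an onset override shifts that beat's PWD by exactly the index delta", {
  g <- generate_recording(test_spec(seed = 2, duration_s = 25))
  del0 <- suppressWarnings(delineate_recording(g$recording))
  b0 <- del0$beats[del0$beats$lead == "II" & del0$beats$used, ][3, ]
  ov <- annotation_set("II", b0$beat, "P_ONSET", b0$p_onset - 12L, "override")
  del1 <- suppressWarnings(delineate_recording(g$recording, overrides = ov))
  b1 <- del1$beats[del1$beats$lead == "II" & del1$beats$beat == b0$beat, ]
  expect_equal(b1$p_onset, b0$p_onset - 12L)
  expect_equal(b1$pwd_ms - b0$pwd_ms, 12)
})

test_that("override fiducials are returned verbatim in the annotation set", {
  g <- generate_recording(test_spec(seed = 2, duration_s = 25))
  del0 <- suppressWarnings(delineate_recording(g$recording))
  b0 <- del0$beats[del0$beats$lead == "V1" & del0$beats$used, ][2, ]
  ov <- annotation_set("V1", b0$beat, "T_END", b0$t_end + 7L, "override")
  del1 <- suppressWarnings(delineate_recording(g$recording, overrides = ov))
  ann <- as.data.frame(del1$annotations)
  got <- ann[ann$lead == "V1" & ann$beat == b0$beat & ann$kind == "T_END", ]
  expect_equal(got$sample, b0$t_end + 7L)
  expect_equal(got$provenance, "override")
})

test_that("fiducial ordering holds for every emitted beat", {
  g <- generate_recording(test_spec(seed = 4, duration_s = 25,
                                    noise = noise_spec(white_sd_mv = 0.01)))
  del <- suppressWarnings(delineate_recording(preprocess_recording(g$recording)))
  u <- del$beats[del$beats$used, ]
  expect_true(all(u$t_end < u$p_onset & u$p_onset < u$p_peak &
                    u$p_peak < u$p_offset & u$p_offset < u$r_peak))
})

test_that("delineation is translation-equivariant", {
  g <- generate_recording(test_spec(seed = 6, duration_s = 20))
  rec <- g$recording
  k <- 37L
  shifted <- rec
  shifted$samples <- cbind(matrix(0, nrow(rec$samples), k),
                           rec$samples[, 1:(ncol(rec$samples) - k)])
  d0 <- suppressWarnings(delineate_recording(rec))
  d1 <- suppressWarnings(delineate_recording(shifted))
  u0 <- d0$beats[d0$beats$used & d0$beats$lead == "II", ]
  u1 <- d1$beats[d1$beats$used & d1$beats$lead == "II", ]
  m <- merge(u0, u1, by = "beat", suffixes = c("", ".s"))
  expect_true(all(m$p_onset.s - m$p_onset == k))
  expect_true(all(m$p_offset.s - m$p_offset == k))
})

test_that("onset and offset recover ground truth on clean and noisy recordings", {
  errs_clean <- sapply(1:3, function(s) {
    g <- generate_recording(test_spec(seed = s))
    recovery_errors(g, suppressWarnings(delineate_recording(g$recording)))
  })
  expect_lte(mean(errs_clean["onset", ]), 2)
  expect_lte(mean(errs_clean["offset", ]), 2)

  errs_noisy <- sapply(1:2, function(s) {
    g <- generate_recording(test_spec(
      seed = s, noise = noise_spec(white_sd_mv = 0.02)
    ))
    del <- suppressWarnings(delineate_recording(preprocess_recording(g$recording)))
    recovery_errors(g, del)
  })
  expect_lte(mean(errs_noisy["onset", ]), 8)
  expect_lte(mean(errs_noisy["offset", ]), 8)
})
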