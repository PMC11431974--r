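#' Delineation configuration
#'
#' Parameters of the fiducial detector. The P peak must be at least
#' `p_peak_min_width_ms` wide at half prominence; `n_beats_average` beats per
#' lead are averaged into one number per parameter. Onset detection uses the
#' chord-distance rule: over the window from the anchor (T end by default) to
#' the P peak, the onset is the sample with the extreme signed perpendicular
#' distance to the chord joining the window endpoints, computed on the
#' standard clinical paper geometry (25 mm/s, 10 mm/mV). The offset applies
#' the mirrored rule from the P peak to the QRS onset anchor.
#'
#' @param p_peak_min_width_ms Minimum width at half prominence for a P peak
#'   candidate (ms).
#' @param n_beats_average Beats averaged per lead.
#' @param r_refractory_ms Minimum separation between detected R peaks (ms).
#' @param t_end_method `"tangent"` (steepest-descent tangent crossing the
#'   baseline) or `"window"` (fixed offset after the T peak).
#' @param t_end_window_ms Offset used by the `"window"` T-end method (ms).
#' @param onset_chord_anchor `"t_end"` or `"t_peak"`: start of the onset
#'   search window and chord.
#' @param extremum_rule `"signed_min"` (maximal excursion on the convex side
#'   of the chord, the default) or `"unsigned_max"` (maximal absolute
#'   distance).
#' @param offset_method `"mirrored_chord"` or `"threshold_return"` (first
#'   sample after the peak returning within `return_frac` of the peak
#'   deviation to baseline).
#' @param qrs_onset_ms QRS onset taken this many ms before the R peak.
#' @param mm_per_mv,ms_per_mm Grid scaling for chord geometry.
#' @param baseline_window_ms Window (ms) ending at the candidate onset whose
#'   median defines the isoelectric line; one refinement iteration is run.
#' @param edge_trim_s Seconds excluded at each end of the recording (filter
#'   settling).
#' @param min_t_amp_mv T waves with deviation below this are flagged flat.
#' @param return_frac Threshold fraction for `"threshold_return"`.
#' @return A `delineation_config` list.
#' @export
delineation_config <- function(p_peak_min_width_ms = 15, n_beats_average = 20,
                               r_refractory_ms = 250,
                               t_end_method = c("tangent", "window"),
                               t_end_window_ms = 120,
                               onset_chord_anchor = c("t_end", "t_peak"),
                               extremum_rule = c("signed_min", "unsigned_max"),
                               offset_method = c("mirrored_chord", "threshold_return"),
                               qrs_onset_ms = 60,
                               mm_per_mv = 10, ms_per_mm = 40,
                               baseline_window_ms = 20,
                               edge_trim_s = 0.5,
                               min_t_amp_mv = 0.05,
                               return_frac = 0.05) {
  if (p_peak_min_width_ms <= 0) stop("p_peak_min_width_ms must be > 0")
  if (n_beats_average < 1) stop("n_beats_average must be >= 1")
  structure(list(
    p_peak_min_width_ms = p_peak_min_width_ms,
    n_beats_average = n_beats_average,
    r_refractory_ms = r_refractory_ms,
    t_end_method = match.arg(t_end_method),
    t_end_window_ms = t_end_window_ms,
    onset_chord_anchor = match.arg(onset_chord_anchor),
    extremum_rule = match.arg(extremum_rule),
    offset_method = match.arg(offset_method),
    qrs_onset_ms = qrs_onset_ms,
    mm_per_mv = mm_per_mv, ms_per_mm = ms_per_mm,
    baseline_window_ms = baseline_window_ms,
    edge_trim_s = edge_trim_s,
    min_t_amp_mv = min_t_amp_mv,
    return_frac = return_frac
  ), class = "delineation_config")
}

# local maxima of x (strictly greater than one neighbour, >= the other)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

#' Detect R peaks in a single lead
#'
#' Threshold detector on the absolute amplitude: candidate local maxima of
#' |x| above 60% of the lead's 99.5th percentile, thinned so consecutive
#' peaks are at least `r_refractory_ms` apart (larger peak wins).
#'
#' @param x Numeric signal (mV), preprocessed.
#' @param fs Sampling rate (Hz).
#' @param cfg A [delineation_config()].
#' @return Integer vector of 0-based R peak sample indices (strictly
#'   increasing). Empty, with a warning, if nothing crosses the threshold.
#' @export
detect_r_peaks <- function(x, fs, cfg = delineation_config()) {
  if (length(x) < 2 * fs) stop("signal shorter than 2 s")
  ax <- abs(x)
  thr <- 0.6 * stats::quantile(ax, 0.995, names = FALSE)
  if (thr <= 0 || !any(ax > thr)) {
    warning("no R peaks found")
    return(integer(0))
  }
  cand <- local_maxima(ax)
  cand <- cand[ax[cand] > thr]
  if (!length(cand)) {
    warning("no R peaks found")
    return(integer(0))
  }
  refr <- round(cfg$r_refractory_ms / 1000 * fs)
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || i - keep[length(keep)] >= refr) {
      keep <- c(keep, i)
    } else if (ax[i] > ax[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  as.integer(keep - 1L)  # 0-based
}

#' Estimate heart rate from R peaks
#'
#' `60000 / median RR interval (ms)`; the median makes the estimate robust
#' to a missed or spurious beat.
#'
#' @param r_peaks 0-based R peak sample indices.
#' @param fs Sampling rate (Hz).
#' @return Heart rate in beats per minute.
#' @export
estimate_heart_rate <- function(r_peaks, fs) {
  if (length(r_peaks) < 2) stop("need at least 2 R peaks to estimate heart rate")
  rr_ms <- diff(r_peaks) / fs * 1000
  60000 / stats::median(rr_ms)
}

#' Detect the end of the T wave
#'
#' Finds the T peak after `r_peak` and locates its end either by the tangent
#' method (tangent at the steepest point of the descending limb, intersected
#' with the baseline) or a fixed window after the T peak.
#'
#' @param x Signal (mV).
#' @param r_peak 0-based R peak index of the current beat.
#' @param next_r 0-based R peak index of the next beat.
#' @param fs Sampling rate (Hz).
#' @param cfg A [delineation_config()].
#' @return List with `t_end`, `t_peak` (0-based indices) and `flag`
#'   (`NA_character_` when clean, otherwise a reason string).
#' @export
detect_t_end <- function(x, r_peak, next_r, fs, cfg = delineation_config()) {
  rr <- next_r - r_peak
  lo <- r_peak + round(0.100 * fs)
  hi <- r_peak + min(round(0.450 * fs), round(0.6 * rr))
  lo1 <- lo + 1L; hi1 <- min(hi + 1L, length(x))  # 1-based
  if (hi1 - lo1 < 3) return(list(t_end = NA, t_peak = NA, flag = "short_t_window"))
  seg <- x[lo1:hi1]
  base <- stats::median(x[(hi1):min(length(x), hi1 + round(0.1 * fs))])
  dev <- seg - base
  pk_rel <- which.max(abs(dev))
  if (abs(dev[pk_rel]) < cfg$min_t_amp_mv) {
    return(list(t_end = NA, t_peak = NA, flag = "flat_t"))
  }
  t_peak1 <- lo1 + pk_rel - 1L
  if (cfg$t_end_method == "window") {
    t_end1 <- t_peak1 + round(cfg$t_end_window_ms / 1000 * fs)
    return(list(t_end = t_end1 - 1L, t_peak = t_peak1 - 1L, flag = NA_character_))
  }
  # tangent method on the descending limb
  limb_hi <- min(length(x), t_peak1 + round(0.250 * fs))
  if (limb_hi - t_peak1 < 3) return(list(t_end = NA, t_peak = NA, flag = "short_t_limb"))
  limb <- x[t_peak1:limb_hi]
  sl <- diff(limb)
  sign_pk <- sign(x[t_peak1] - base)
  # steepest return towards baseline
  s_rel <- if (sign_pk >= 0) which.min(sl) else which.max(sl)
  slope <- sl[s_rel] * fs                      # mV per second
  y_s <- limb[s_rel]
  if (abs(slope) < 1e-9) return(list(t_end = NA, t_peak = NA, flag = "flat_t_limb"))
  t_s <- t_peak1 + s_rel - 1L
  cross <- t_s + (base - y_s) / slope * fs     # samples, 1-based fractional
  t_end1 <- round(cross)
  t_end1 <- max(t_end1, t_s)
  t_end1 <- min(t_end1, length(x))
  list(t_end = t_end1 - 1L, t_peak = t_peak1 - 1L, flag = NA_character_)
}

# width (ms) at half prominence around candidate i (1-based) of deviation d
half_prominence_width <- function(d, i, fs) {
  half <- abs(d[i]) / 2
  sgn <- sign(d[i])
  l <- i
  while (l > 1 && sgn * d[l - 1] > half) l <- l - 1
  r <- i
  while (r < length(d) && sgn * d[r + 1] > half) r <- r + 1
  (r - l + 1) / fs * 1000
}

#' Detect the P peak within a search window
#'
#' Returns the sample with the largest absolute deviation from the
#' isoelectric line among candidate extrema whose width at half prominence
#' is at least `p_peak_min_width_ms` — short noise spikes are rejected even
#' when taller than the P wave.
#'
#' @param x Signal (mV).
#' @param window 0-based index pair `c(from, to)` (inclusive), typically
#'   T end to QRS onset.
#' @param baseline Isoelectric line level (mV).
#' @param fs Sampling rate (Hz).
#' @param cfg A [delineation_config()].
#' @return List with `p_peak` (0-based index or `NA`) and `flag`.
#' @export
detect_p_peak <- function(x, window, baseline, fs, cfg = delineation_config()) {
  lo1 <- window[1] + 1L; hi1 <- window[2] + 1L
  if (hi1 - lo1 < 3) return(list(p_peak = NA, flag = "short_p_window"))
  d <- x[lo1:hi1] - baseline
  cand <- sort(unique(c(local_maxima(d), local_maxima(-d))))
  if (!length(cand)) return(list(p_peak = NA, flag = "no_p_candidates"))
  widths <- vapply(cand, function(i) half_prominence_width(d, i, fs), numeric(1))
  ok <- cand[widths >= cfg$p_peak_min_width_ms & abs(d[cand]) > 0]
  if (!length(ok)) return(list(p_peak = NA, flag = "no_p_width"))
  best <- ok[which.max(abs(d[ok]))]
  list(p_peak = lo1 + best - 1L - 1L, flag = NA_character_)  # 0-based
}

# Signed perpendicular distances from samples (a1..b1, 1-based) to the chord
# through (a1, x[a1]) and (b1, x[b1]), on the mm grid of the clinical paper.
chord_distances <- function(x, a1, b1, fs, cfg) {
  i <- a1:b1
  t_mm <- ((i - a1) / fs * 1000) / cfg$ms_per_mm
  y_mm <- x[i] * cfg$mm_per_mv
  dx <- t_mm[length(t_mm)] - t_mm[1]
  dy <- y_mm[length(y_mm)] - y_mm[1]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) len <- 1
  (dx * (y_mm - y_mm[1]) - dy * (t_mm - t_mm[1])) / len
}

#' Detect the P wave onset by the chord-distance rule
#'
#' Draws the chord from the anchor point (T end) to the P peak and returns
#' the interior sample with the extreme signed perpendicular distance to it,
#' i.e. the point of maximal excursion on the baseline side of the chord —
#' the corner where the signal first rises from the isoelectric line.
#' Distances are computed on the standard ECG paper grid (25 mm/s,
#' 10 mm/mV) so "perpendicular" is geometrically defined. Ties break to the
#' earliest sample. With `extremum_rule = "unsigned_max"` the maximal
#' absolute distance is used instead.
#'
#' @param x Signal (mV).
#' @param anchor_idx 0-based anchor index (T end).
#' @param p_peak_idx 0-based P peak index.
#' @param fs Sampling rate (Hz).
#' @param cfg A [delineation_config()].
#' @param restrict Optional 0-based index pair: consider only samples in
#'   this range (used by the cross-beat consensus step).
#' @return List with `p_onset` (0-based or `NA`) and `flag`.
#' @export
detect_p_onset <- function(x, anchor_idx, p_peak_idx, fs,
                           cfg = delineation_config(), restrict = NULL) {
  a1 <- anchor_idx + 1L; b1 <- p_peak_idx + 1L
  if (b1 - a1 < 3) return(list(p_onset = NA, flag = "short_onset_window"))
  d <- chord_distances(x, a1, b1, fs, cfg)
  inner <- 2:(length(d) - 1)
  if (!is.null(restrict)) {
    keep <- inner[(a1 + inner - 2L) >= restrict[1] &
                    (a1 + inner - 2L) <= restrict[2]]
    if (length(keep) >= 1) inner <- keep
  }
  di <- d[inner]
  rel <- pick_chord_extremum(di, x[b1] - x[a1], cfg$extremum_rule, tie = "first")
  list(p_onset = a1 + inner[rel] - 1L - 1L, flag = NA_character_)
}

#' Detect the P wave offset by the mirrored chord rule
#'
#' Applies the chord-distance rule to the chord from the P peak to the QRS
#' onset anchor; ties break to the latest sample. The `"threshold_return"`
#' variant instead returns the first sample after the peak whose deviation
#' from baseline falls below `return_frac` of the peak deviation.
#'
#' @param x Signal (mV).
#' @param p_peak_idx 0-based P peak index.
#' @param qrs_onset_idx 0-based QRS onset anchor index.
#' @param fs Sampling rate (Hz).
#' @param cfg A [delineation_config()].
#' @param baseline Isoelectric level, used by `"threshold_return"`.
#' @param restrict Optional 0-based index pair restricting the candidates
#'   (used by the cross-beat consensus step).
#' @return List with `p_offset` (0-based or `NA`) and `flag`.
#' @export
detect_p_offset <- function(x, p_peak_idx, qrs_onset_idx, fs,
                            cfg = delineation_config(), baseline = 0,
                            restrict = NULL) {
  a1 <- p_peak_idx + 1L; b1 <- qrs_onset_idx + 1L
  if (b1 - a1 < 3) return(list(p_offset = NA, flag = "short_offset_window"))
  if (cfg$offset_method == "threshold_return") {
    dev <- abs(x[a1:b1] - baseline)
    thr <- cfg$return_frac * dev[1]
    hit <- which(dev[-1] <= thr)
    if (!length(hit)) return(list(p_offset = NA, flag = "no_return"))
    return(list(p_offset = a1 + hit[1] - 1L, flag = NA_character_))
  }
  d <- chord_distances(x, a1, b1, fs, cfg)
  inner <- 2:(length(d) - 1)
  if (!is.null(restrict)) {
    keep <- inner[(a1 + inner - 2L) >= restrict[1] &
                    (a1 + inner - 2L) <= restrict[2]]
    if (length(keep) >= 1) inner <- keep
  }
  di <- d[inner]
  rel <- pick_chord_extremum(di, x[a1] - x[b1], cfg$extremum_rule, tie = "last")
  list(p_offset = a1 + inner[rel] - 1L - 1L, flag = NA_character_)
}

# Choose the extremal chord distance. For the default signed rule the convex
# side is set by the polarity of the wave relative to the chord: positive
# waves bow the signal above the chord, so the onset corner is the most
# negative signed distance, and vice versa. `rise` is (peak - anchor) for
# onsets and (peak - anchor) mirrored for offsets.
pick_chord_extremum <- function(di, rise, rule, tie = c("first", "last")) {
  tie <- match.arg(tie)
  score <- if (rule == "unsigned_max") abs(di) else if (rise >= 0) -di else di
  mx <- max(score)
  hits <- which(score >= mx - 1e-12)
  if (tie == "first") hits[1] else hits[length(hits)]
}

# Qualifying P apices in the search window: local extrema of the deviation
# from baseline with |dev| >= 25% of the dominant deviation (residual filter
# droop stays well under that fraction of a measurable P wave) and width at
# half prominence >= the P peak width rule. For a biphasic wave this returns
# one apex per phase in temporal order; the onset chord targets the first,
# the offset chord starts from the last, so neither chord sweeps across an
# opposite-signed phase.
p_apices <- function(x, window, baseline, fs, cfg, rel_frac = 0.25) {
  lo1 <- window[1] + 1L; hi1 <- window[2] + 1L
  if (hi1 - lo1 < 3) return(integer(0))
  d <- x[lo1:hi1] - baseline
  cand <- sort(unique(c(local_maxima(d), local_maxima(-d))))
  if (!length(cand)) return(integer(0))
  widths <- vapply(cand, function(i) half_prominence_width(d, i, fs), numeric(1))
  ok <- cand[widths >= cfg$p_peak_min_width_ms]
  if (!length(ok)) return(integer(0))
  thr <- rel_frac * max(abs(d[ok]))
  ok <- ok[abs(d[ok]) >= thr]
  # P wave phases are contiguous: only apices within one generous P-wave
  # span of the dominant apex can belong to the same wave; this drops
  # residual-droop humps elsewhere in the TP segment
  dom <- ok[which.max(abs(d[ok]))]
  ok <- ok[abs(ok - dom) <= round(0.150 * fs)]
  as.integer(lo1 + ok - 1L - 1L)  # 0-based
}

# Replace the samples of [t_end, qrs_onset] by their residual after a local
# cubic fit of the baseline trend around the provisional P support (the
# support padded by 10 ms is masked; fitting samples are taken from up to
# 150 ms on either side of it). A local polynomial tracks the exponential
# recovery of the 1 Hz high-pass to well under a microvolt, which matters
# because the onset chord slope is of the same order. Returns a copy of x;
# indices are 0-based.
detrend_window <- function(x, t_end, qrs_onset, p_onset, p_offset, fs) {
  lo1 <- max(t_end + 1L, p_onset + 1L - round(0.160 * fs))
  hi1 <- min(qrs_onset + 1L, p_offset + 1L + round(0.160 * fs))
  i <- lo1:hi1
  pad <- round(0.010 * fs)
  mask <- i < (p_onset + 1L - pad) | i > (p_offset + 1L + pad)
  if (sum(mask) < 10) return(x)
  u <- (i - lo1) / fs
  X <- cbind(1, u, u^2, u^3)
  fit <- stats::lm.fit(X[mask, , drop = FALSE], x[i[mask]])
  co <- fit$coefficients
  co[is.na(co)] <- 0
  trend <- X %*% co
  # extend the trend's edge values across the rest of the search window so
  # the chord anchor at T end sits on the same detrended scale
  full <- (t_end + 1L):(qrs_onset + 1L)
  x[full[full < lo1]] <- x[full[full < lo1]] - trend[1]
  x[full[full > hi1]] <- x[full[full > hi1]] - trend[length(trend)]
  x[i] <- x[i] - trend
  x
}

# Departure-from-baseline refinement of a chord-rule candidate, applying
# the complementary definition of the P boundary: the first sustained rise
# of |signal - isoelectric line| above a noise-adaptive threshold. The
# chord extremum localises the boundary; within +/- max_shift_ms of it the
# last sample (for onsets; first, mirrored, for offsets) whose deviation
# stays below the threshold over a 5 ms run is returned. On noise-free
# signals the threshold floors at two ADC quanta and the refinement
# reproduces the support corner exactly.
refine_departure <- function(xs, baseline, apex0, cand0, bound0, thr, fs,
                             side = c("onset", "offset"),
                             max_shift_ms = 20) {
  side <- match.arg(side)
  sgn <- sign(xs[apex0 + 1L] - baseline)
  if (sgn == 0) return(cand0)
  dev <- sgn * (xs - baseline)
  run <- max(1L, round(0.005 * fs))
  shift <- round(max_shift_ms / 1000 * fs)
  if (side == "onset") {
    lo1 <- max(bound0 + 2L, cand0 - shift) + 1L   # 1-based
    hi1 <- apex0 + 1L - 1L
  } else {
    lo1 <- apex0 + 1L + 1L
    hi1 <- min(bound0 - 1L, cand0 + shift) + 1L
  }
  if (hi1 - lo1 < run) return(cand0)
  below <- dev[lo1:hi1] < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  okruns <- which(r$values & r$lengths >= run)
  if (!length(okruns)) return(cand0)
  if (side == "onset") {
    j <- ends[okruns[length(okruns)]]     # last quiet sample before the rise
  } else {
    j <- starts[okruns[1]]                # first quiet sample after the fall
  }
  out0 <- lo1 + j - 1L - 1L               # back to 0-based
  # first-order compensation of the threshold-crossing delay: the ramp
  # reaches thr one thr/slope after leaving the baseline, so the boundary
  # sits thr/slope before (after, for offsets) the crossing, estimated with
  # the local limb slope
  span <- round(0.008 * fs)
  j1 <- lo1 + j - 1L
  if (side == "onset") {
    k1 <- min(apex0 + 1L, j1 + span)
    slope <- (dev[k1] - dev[j1]) / max(1L, k1 - j1)      # per sample
  } else {
    k1 <- max(apex0 + 1L, j1 - span)
    slope <- (dev[k1] - dev[j1]) / max(1L, j1 - k1)
  }
  if (is.finite(slope) && slope > 0) {
    corr <- min(thr / slope, 0.010 * fs)
    out0 <- if (side == "onset") {
      max(bound0 + 1L, as.integer(floor(out0 + 1 - corr)))
    } else {
      min(bound0 - 1L, as.integer(ceiling(out0 - 1 + corr)))
    }
  }
  out0
}

# median of the baseline window (win_ms ending at idx1, 1-based)
baseline_at <- function(x, idx1, fs, win_ms) {
  w <- max(1L, round(win_ms / 1000 * fs))
  lo <- max(1L, idx1 - w + 1L)
  stats::median(x[lo:idx1])
}

lookup_override <- function(overrides, lead, beat, kind) {
  if (is.null(overrides) || nrow(overrides) == 0) return(NA_integer_)
  hit <- overrides$lead == lead & overrides$beat == beat &
    overrides$kind == kind & overrides$provenance == "override"
  if (!any(hit)) return(NA_integer_)
  overrides$sample[which(hit)[1]]
}

#' Delineate a preprocessed recording
#'
#' Runs the full fiducial chain on every lead: R peaks (detected once on
#' lead II, or the first available lead), heart rate from the median RR,
#' then per beat the T end, isoelectric baseline, P peak (15 ms minimum
#' width), chord-rule onset and mirrored-chord offset. Manual override
#' annotations replace detected fiducials before any measurement. The first
#' `n_beats_average` clean beats per lead are retained; if fewer are
#' available all clean beats are used and a warning is recorded.
#'
#' @param rec A preprocessed [ecg_recording].
#' @param cfg A [delineation_config()].
#' @param overrides Optional [annotation_set] of `provenance = "override"`
#'   records.
#' @return List with `annotations` (resolved [annotation_set]), `beats`
#'   (per-beat measurement data frame: lead, beat, fiducials, `pwd_ms`,
#'   `pwv_mv`, `pwa_msmv`, `morphology`, `ptfv1_mms`, `flag`, `used`),
#'   `heart_rate_bpm`, `r_peaks`, and `warnings`.
#' @export
delineate_recording <- function(rec, cfg = delineation_config(),
                                overrides = NULL) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (!is.null(overrides)) validate_annotations(overrides, rec)
  fs <- rec$fs
  ref_lead <- if ("II" %in% rec$lead_names) "II" else rec$lead_names[1]
  r_peaks <- detect_r_peaks(lead_signal(rec, ref_lead), fs, cfg)
  if (length(r_peaks) < 3) stop("too few R peaks detected to delineate")
  hr <- estimate_heart_rate(r_peaks, fs)

  trim <- round(cfg$edge_trim_s * fs)
  n <- ncol(rec$samples)
  warnings <- character(0)
  beat_rows <- list()
  ann_rows <- list()

  for (lead in rec$lead_names) {
    x <- lead_signal(rec, lead)
    ctxs <- list()
    n_clean <- 0L
    for (b in 2:length(r_peaks)) {
      r_prev <- r_peaks[b - 1]
      r_cur <- r_peaks[b]
      if (r_prev < trim || r_cur > n - trim) next
      if (n_clean >= cfg$n_beats_average) break
      ctx <- delineate_beat(x, lead, b, r_prev, r_cur, fs, cfg, overrides)
      ctxs[[length(ctxs) + 1L]] <- ctx
      if (is.na(ctx$flag)) n_clean <- n_clean + 1L
    }

    ctxs <- consensus_refine(x, ctxs, lead, fs, cfg, overrides)

    for (ctx in ctxs) {
      clean <- is.na(ctx$flag)
      if (clean) {
        xw <- ctx$xd_win
        loc <- function(idx0) idx0 - ctx$t_end + 1L  # window-local 1-based
        baseline <- baseline_at(xw, loc(ctx$p_onset), fs, cfg$baseline_window_ms)
        seg <- xw[loc(ctx$p_onset):loc(ctx$p_offset)]
        pwd <- compute_pwd(ctx$p_onset, ctx$p_offset, fs)
        pwv <- compute_pwv(seg, baseline)
        pwa <- compute_pwa(seg, baseline, fs = fs, method = "trapezoid")
        morph <- classify_morphology(seg, baseline, fs = fs)
        ptf <- if (lead == "V1") compute_ptfv1(seg, baseline, fs) else NA_real_
      } else {
        baseline <- NA_real_
        pwd <- pwv <- pwa <- ptf <- NA_real_
        morph <- NA_character_
      }
      beat_rows[[length(beat_rows) + 1L]] <- data.frame(
        lead = lead, beat = ctx$beat,
        r_peak = ctx$r_cur,
        t_end = if (is.na(ctx$t_end)) NA_integer_ else ctx$t_end,
        p_onset = if (clean) ctx$p_onset else NA_integer_,
        p_peak = if (clean) ctx$p_peak else NA_integer_,
        p_offset = if (clean) ctx$p_offset else NA_integer_,
        baseline_mv = baseline,
        pwd_ms = pwd, pwv_mv = pwv, pwa_msmv = pwa,
        morphology = morph, ptfv1_mms = ptf,
        flag = ctx$flag, used = clean,
        stringsAsFactors = FALSE
      )
      if (clean) {
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          lead = lead, beat = ctx$beat,
          kind = c("R_PEAK", "T_END", "P_ONSET", "P_PEAK", "P_OFFSET"),
          sample = c(ctx$r_cur, ctx$t_end, ctx$p_onset, ctx$p_peak, ctx$p_offset)
        )
      }
    }
    n_used <- sum(vapply(ctxs, function(c) is.na(c$flag), logical(1)))
    if (n_used < cfg$n_beats_average) {
      warnings <- c(warnings, sprintf(
        "lead %s: only %d clean beat(s) available of %d requested",
        lead, n_used, cfg$n_beats_average
      ))
    }
  }

  beats <- do.call(rbind, beat_rows)
  anns <- if (length(ann_rows)) {
    aa <- do.call(rbind, ann_rows)
    annotation_set(aa$lead, aa$beat, aa$kind, aa$sample, "detected")
  } else {
    annotation_set()
  }
  if (!is.null(overrides) && nrow(overrides)) {
    anns <- resolve_annotations(rbind_annotations(anns, overrides))
  }
  for (w in warnings) warning(w, call. = FALSE)
  list(annotations = anns, beats = beats, heart_rate_bpm = hr,
       r_peaks = r_peaks, warnings = warnings)
}

# Delineate one beat of one lead: T end, isoelectric baseline, P apices,
# chord onset and offset, with one detrend-and-redetect refinement.
# Returns a context list; flag is NA when the beat is clean.
delineate_beat <- function(x, lead, beat, r_prev, r_cur, fs, cfg, overrides) {
  flag <- NA_character_
  te <- detect_t_end(x, r_prev, r_cur, fs, cfg)
  t_end <- lookup_override(overrides, lead, beat, "T_END")
  if (is.na(t_end)) t_end <- te$t_end
  if (is.na(t_end)) flag <- te$flag

  qrs_onset <- r_cur - round(cfg$qrs_onset_ms / 1000 * fs)
  if (is.na(flag) && t_end >= qrs_onset - 3) flag <- "short_p_window"
  anchor <- if (cfg$onset_chord_anchor == "t_peak" && !is.na(te$t_peak)) {
    te$t_peak
  } else {
    t_end
  }

  ctx <- list(beat = beat, r_cur = r_cur, t_end = t_end, anchor = anchor,
              qrs_onset = qrs_onset, p_peak = NA_integer_,
              apex_first = NA_integer_, apex_last = NA_integer_,
              p_onset = NA_integer_, p_offset = NA_integer_,
              xd_win = NULL, flag = flag)
  if (!is.na(flag)) return(ctx)

  ov_peak <- lookup_override(overrides, lead, beat, "P_PEAK")
  ov_on <- lookup_override(overrides, lead, beat, "P_ONSET")
  ov_off <- lookup_override(overrides, lead, beat, "P_OFFSET")

  pass <- function(xs) {
    base0 <- stats::median(xs[(t_end + 1L):(qrs_onset + 1L)])
    p_peak <- ov_peak
    if (is.na(p_peak)) {
      pp <- detect_p_peak(xs, c(t_end, qrs_onset), base0, fs, cfg)
      if (is.na(pp$p_peak)) return(list(flag = pp$flag))
      p_peak <- pp$p_peak
    }
    ap <- p_apices(xs, c(t_end, qrs_onset), base0, fs, cfg)
    apex_first <- if (length(ap)) ap[1] else p_peak
    apex_last <- if (length(ap)) ap[length(ap)] else p_peak
    p_onset <- ov_on
    if (is.na(p_onset)) {
      po <- detect_p_onset(xs, anchor, apex_first, fs, cfg)
      if (is.na(po$p_onset)) return(list(flag = po$flag))
      p_onset <- po$p_onset
    }
    p_offset <- ov_off
    if (is.na(p_offset)) {
      pf <- detect_p_offset(xs, apex_last, qrs_onset, fs, cfg, base0)
      if (is.na(pf$p_offset)) return(list(flag = pf$flag))
      p_offset <- pf$p_offset
    }
    list(flag = NA_character_, p_peak = p_peak, apex_first = apex_first,
         apex_last = apex_last, p_onset = p_onset, p_offset = p_offset)
  }

  r1 <- pass(x)
  if (!is.na(r1$flag)) { ctx$flag <- r1$flag; return(ctx) }

  # one refinement iteration: remove the local baseline trend that the 1 Hz
  # high-pass leaves under the P support (its linear part cannot bias the
  # chord rule, but its curvature can), then re-detect on the detrended
  # window; on an undistorted baseline the fitted trend is null
  xd <- detrend_window(x, t_end, qrs_onset, r1$p_onset, r1$p_offset, fs)
  r2 <- pass(xd)
  if (!is.na(r2$flag)) { ctx$flag <- r2$flag; return(ctx) }

  # departure refinement: the chord extremum localises each boundary; the
  # final index is the last (first, for the offset) sample whose deviation
  # from the isoelectric line stays below a noise-adaptive threshold,
  # implementing the complementary "first point of rise above the
  # isoelectric line" definition of the P boundary
  win1 <- (t_end + 1L):(qrs_onset + 1L)
  pad <- round(0.010 * fs)
  mask1 <- win1[win1 < (r2$p_onset + 1L - pad) | win1 > (r2$p_offset + 1L + pad)]
  if (length(mask1) >= 10) {
    sigma <- stats::mad(xd[mask1])
    xs <- xd
    if (sigma > 0.0015) {
      w <- round(0.009 * fs)
      if (w %% 2 == 0) w <- w + 1L
      sm <- stats::filter(xd[win1], rep(1 / w, w), sides = 2)
      keep <- !is.na(sm)
      xs[win1[keep]] <- sm[keep]
      sigma <- stats::mad(xs[mask1])
    }
    bmed <- stats::median(xs[mask1])
    thr <- max(3 * sigma, 0.0005)
    if (is.na(ov_on)) {
      r2$p_onset <- refine_departure(xs, bmed, r2$apex_first, r2$p_onset,
                                     anchor, thr, fs, "onset")
    }
    if (is.na(ov_off)) {
      r2$p_offset <- refine_departure(xs, bmed, r2$apex_last, r2$p_offset,
                                      qrs_onset, thr, fs, "offset")
    }
  }

  ord_ok <- t_end < r2$p_onset && r2$p_onset < r2$p_peak &&
    r2$p_peak < r2$p_offset && r2$p_offset < r_cur
  if (!ord_ok) { ctx$flag <- "fiducial_order"; return(ctx) }

  ctx[c("p_peak", "apex_first", "apex_last", "p_onset", "p_offset")] <-
    r2[c("p_peak", "apex_first", "apex_last", "p_onset", "p_offset")]
  ctx$xd_win <- xd[(t_end + 1L):(qrs_onset + 1L)]
  ctx
}

# Cross-beat consensus: the beat ensemble of a lead provides a robust prior
# for each beat's onset and offset. Beats whose apex-to-onset (or
# offset-to-apex) interval deviates from the lead median by more than
# consensus_tol_ms re-run the chord extremum restricted to the median
# interval +/- the tolerance, which suppresses occasional argmin outliers in
# the shallow part of the distance profile under noise.
consensus_refine <- function(x, ctxs, lead, fs, cfg, overrides,
                             consensus_tol_ms = 25) {
  clean <- vapply(ctxs, function(c) is.na(c$flag), logical(1))
  if (sum(clean) < 5) return(ctxs)
  tol <- round(consensus_tol_ms / 1000 * fs)
  oa <- vapply(ctxs[clean], function(c) c$apex_first - c$p_onset, numeric(1))
  ob <- vapply(ctxs[clean], function(c) c$p_offset - c$apex_last, numeric(1))
  med_oa <- stats::median(oa)
  med_ob <- stats::median(ob)
  for (k in which(clean)) {
    ctx <- ctxs[[k]]
    xp <- x
    xp[(ctx$t_end + 1L):(ctx$qrs_onset + 1L)] <- ctx$xd_win
    if (abs((ctx$apex_first - ctx$p_onset) - med_oa) > tol &&
        is.na(lookup_override(overrides, lead, ctx$beat, "P_ONSET"))) {
      lo <- ctx$apex_first - med_oa - tol
      hi <- ctx$apex_first - med_oa + tol
      po <- detect_p_onset(xp, ctx$anchor, ctx$apex_first, fs, cfg,
                           restrict = c(lo, hi))
      if (!is.na(po$p_onset) && po$p_onset > ctx$t_end) {
        ctx$p_onset <- po$p_onset
      }
    }
    if (abs((ctx$p_offset - ctx$apex_last) - med_ob) > tol &&
        is.na(lookup_override(overrides, lead, ctx$beat, "P_OFFSET"))) {
      lo <- ctx$apex_last + med_ob - tol
      hi <- ctx$apex_last + med_ob + tol
      pf <- detect_p_offset(xp, ctx$apex_last, ctx$qrs_onset, fs, cfg,
                            restrict = c(lo, hi))
      if (!is.na(pf$p_offset) && pf$p_offset < ctx$r_cur) {
        ctx$p_offset <- pf$p_offset
      }
    }
    if (!(ctx$p_onset < ctx$p_peak && ctx$p_peak < ctx$p_offset)) {
      ctx$flag <- "fiducial_order"
    }
    ctxs[[k]] <- ctx
  }
  ctxs
}

rbind_annotations <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  annotation_set(out$lead, out$beat, out$kind, out$sample, out$provenance)
}
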