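#' P wave duration
#'
#' Time from P onset to P offset in milliseconds.
#'
#' @param p_onset,p_offset 0-based sample indices with `p_onset < p_offset`.
#' @param fs Sampling rate (Hz).
#' @return Duration in ms.
#' @export
compute_pwd <- function(p_onset, p_offset, fs) {
  if (any(p_offset <= p_onset)) stop("p_offset must be greater than p_onset")
  (p_offset - p_onset) / fs * 1000
}

#' Hodges heart-rate correction of the P wave duration
#'
#' `PWDc = PWD + 1.75 * (HR - 60)`, the additive Hodges adjustment used for
#' QT intervals, applied to the P wave duration. At 60 bpm the correction is
#' the identity.
#'
#' @param pwd_ms P wave duration (ms).
#' @param heart_rate_bpm Heart rate (> 0).
#' @return Corrected duration in ms.
#' @export
correct_pwd_hodges <- function(pwd_ms, heart_rate_bpm) {
  if (any(heart_rate_bpm <= 0)) stop("heart_rate_bpm must be > 0")
  pwd_ms + 1.75 * (heart_rate_bpm - 60)
}

#' P wave voltage
#'
#' Maximal vertical distance of the P wave from the isoelectric line, signed
#' by the dominant phase: positive when the largest excursion is above the
#' line, negative when below.
#'
#' @param segment Samples (mV) between P onset and P offset, inclusive.
#' @param baseline Isoelectric line level (mV).
#' @return Signed peak amplitude in mV.
#' @export
compute_pwv <- function(segment, baseline = 0) {
  if (!length(segment)) stop("empty P wave segment")
  d <- segment - baseline
  d[which.max(abs(d))]
}

#' P wave area
#'
#' `"trapezoid"`: numeric integral of the absolute deviation from the
#' isoelectric line over the segment, in ms.mV. `"triangle"`: the
#' approximation `0.5 * PWD * |PWV|`.
#'
#' @param segment Samples (mV) over the P wave support (trapezoid method).
#' @param baseline Isoelectric level (mV).
#' @param fs Sampling rate (Hz), required for the trapezoid method.
#' @param pwd_ms,pwv_mv Duration and voltage, required for the triangle
#'   method.
#' @param method `"trapezoid"` or `"triangle"`.
#' @return Area in ms.mV (always >= 0).
#' @export
compute_pwa <- function(segment = NULL, baseline = 0, fs = NULL,
                        pwd_ms = NULL, pwv_mv = NULL,
                        method = c("trapezoid", "triangle")) {
  method <- match.arg(method)
  if (method == "triangle") {
    if (is.null(pwd_ms) || is.null(pwv_mv)) {
      stop("triangle method needs pwd_ms and pwv_mv")
    }
    return(0.5 * pwd_ms * abs(pwv_mv))
  }
  if (is.null(segment) || !length(segment)) stop("empty P wave segment")
  if (is.null(fs)) stop("trapezoid method needs fs")
  d <- abs(segment - baseline)
  dt_ms <- 1000 / fs
  sum((d[-1] + d[-length(d)]) / 2) * dt_ms
}

#' P wave dispersion
#'
#' Maximum minus minimum of a set of P wave durations, either across the
#' twelve lead means (`across_leads`) or across the beats of one lead
#' (`within_lead_beats`); the arithmetic is identical, the mode only
#' documents the provenance of the inputs.
#'
#' @param durations Numeric vector of P wave durations (ms), length >= 2.
#' @param mode `"across_leads"` or `"within_lead_beats"`.
#' @return Dispersion in ms (>= 0).
#' @export
compute_pwdisp <- function(durations, mode = c("across_leads", "within_lead_beats")) {
  match.arg(mode)
  durations <- durations[!is.na(durations)]
  if (length(durations) < 2) stop("need at least 2 durations")
  max(durations) - min(durations)
}

# maximal runs of samples above/below baseline qualifying as phases
p_wave_phases <- function(segment, baseline, fs, min_phase_ms, min_phase_mv) {
  d <- segment - baseline
  s <- sign(d)
  r <- rle(as.integer(s))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  phases <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i] == 0L) next
    dur_ms <- r$lengths[i] / fs * 1000
    ext <- d[starts[i]:ends[i]][which.max(abs(d[starts[i]:ends[i]]))]
    if (dur_ms >= min_phase_ms && abs(ext) >= min_phase_mv) {
      phases[[length(phases) + 1L]] <- list(
        sign = r$values[i], start = starts[i], end = ends[i],
        duration_ms = dur_ms, extremum_mv = ext
      )
    }
  }
  phases
}

#' Classify P wave morphology
#'
#' Segments the P wave into phases — maximal runs above or below the
#' isoelectric line lasting at least `min_phase_ms` with an extremum of at
#' least `min_phase_mv` — and labels the wave `mono_pos`, `mono_neg`,
#' `biphasic_pm` (+ then -), `biphasic_mp` (- then +) or `flat`. Brief
#' noise flickers below the phase thresholds do not change the label; more
#' than two qualifying phases are reduced to the dominant two by order.
#'
#' @param segment P wave samples (mV).
#' @param baseline Isoelectric level (mV).
#' @param fs Sampling rate (Hz).
#' @param min_phase_ms Minimum phase duration (ms).
#' @param min_phase_mv Minimum phase extremum (mV).
#' @return Label string.
#' @export
classify_morphology <- function(segment, baseline = 0, fs = 1000,
                                min_phase_ms = 20, min_phase_mv = 0.025) {
  ph <- p_wave_phases(segment, baseline, fs, min_phase_ms, min_phase_mv)
  if (!length(ph)) return("flat")
  signs <- vapply(ph, `[[`, 0L, "sign")
  if (length(ph) == 1) return(if (signs == 1L) "mono_pos" else "mono_neg")
  # keep the two largest-extremum phases in temporal order
  if (length(ph) > 2) {
    mags <- vapply(ph, function(p) abs(p$extremum_mv), numeric(1))
    keep <- sort(order(mags, decreasing = TRUE)[1:2])
    ph <- ph[keep]
    signs <- signs[keep]
  }
  if (signs[1] == signs[2]) {
    return(if (signs[1] == 1L) "mono_pos" else "mono_neg")
  }
  if (signs[1] == 1L) "biphasic_pm" else "biphasic_mp"
}

#' P wave terminal force in lead V1
#'
#' For a biphasic V1 P wave, the product of the terminal (second,
#' opposite-signed) phase's absolute peak amplitude — converted to mm at the
#' standard 10 mm/mV — and its duration in seconds. Stored signed: negative
#' when the terminal phase is negative (the common abnormal pattern). A
#' monophasic V1 P wave scores 0.
#'
#' @param segment V1 P wave samples (mV).
#' @param baseline Isoelectric level (mV).
#' @param fs Sampling rate (Hz).
#' @param min_phase_ms,min_phase_mv Phase qualification thresholds, as in
#'   [classify_morphology()].
#' @param mm_per_mv Amplitude grid scale.
#' @return Terminal force in mm.s (signed), or 0 for monophasic waves.
#' @export
compute_ptfv1 <- function(segment, baseline = 0, fs = 1000,
                          min_phase_ms = 20, min_phase_mv = 0.025,
                          mm_per_mv = 10) {
  ph <- p_wave_phases(segment, baseline, fs, min_phase_ms, min_phase_mv)
  if (length(ph) < 2) return(0)
  signs <- vapply(ph, `[[`, 0L, "sign")
  term <- ph[[length(ph)]]
  if (term$sign == signs[1]) return(0)  # not opposite-signed: not biphasic
  force <- abs(term$extremum_mv) * mm_per_mv * (term$duration_ms / 1000)
  if (term$sign < 0) -force else force
}

#' Inter-atrial block classification
#'
#' IAB is flagged when the maximum per-lead P wave duration (uncorrected by
#' default) reaches `pwd_threshold_ms` and a biphasic P wave morphology is
#' present in the configured inferior leads (`any` one of II, III, aVF by
#' default; `all` gives the stricter advanced-IAB convention).
#'
#' @param pwd_ms Named numeric vector of per-lead P wave durations (ms).
#' @param morphology Named character vector of per-lead morphology labels.
#' @param pwd_threshold_ms Duration threshold (ms).
#' @param leads Inferior leads inspected for biphasic morphology.
#' @param lead_rule `"any"` or `"all"`.
#' @return Logical.
#' @export
classify_iab <- function(pwd_ms, morphology, pwd_threshold_ms = 120,
                         leads = c("II", "III", "aVF"),
                         lead_rule = c("any", "all")) {
  lead_rule <- match.arg(lead_rule)
  leads <- canonical_lead(leads)
  missing <- leads[!(leads %in% names(morphology))]
  if (length(missing)) {
    stop("inferior lead(s) not measured: ", paste(missing, collapse = ", "))
  }
  biph <- grepl("^biphasic", morphology[leads])
  morph_ok <- if (lead_rule == "any") any(biph) else all(biph)
  max(pwd_ms, na.rm = TRUE) >= pwd_threshold_ms && morph_ok
}

#' Assemble patient-level features from per-beat measurements
#'
#' Averages the per-beat measurements of [delineate_recording()] into one
#' number per parameter per lead, then derives the recording-level features:
#' Hodges-corrected duration from the lead-mean PWD and the recording heart
#' rate, within-lead dispersion (max - min of beat durations), global P wave
#' dispersion across the lead means, terminal force from the V1 beat means,
#' and the inter-atrial block flag.
#'
#' @param beats Per-beat measurement data frame from
#'   [delineate_recording()] (rows with `used = TRUE` are averaged).
#' @param heart_rate_bpm Recording heart rate (bpm).
#' @param patient_id Identifier for the output row.
#' @param iab_threshold_ms,iab_leads,iab_lead_rule IAB settings, see
#'   [classify_iab()].
#' @param iab_use_corrected Use PWDc instead of PWD for the IAB threshold.
#' @return List with `leads` (per-lead data frame), `features` (one-row
#'   data frame in the feature-table schema), `iab`, `pwdisp_global_ms`,
#'   `ptfv1_mms`.
#' @export
extract_features <- function(beats, heart_rate_bpm, patient_id = "p1",
                             iab_threshold_ms = 120,
                             iab_leads = c("II", "III", "aVF"),
                             iab_lead_rule = "any",
                             iab_use_corrected = FALSE) {
  used <- beats[beats$used %in% TRUE, , drop = FALSE]
  if (!nrow(used)) stop("no measurable lead: all beats flagged")
  sp <- split(used, used$lead)
  lead_rows <- lapply(sp, function(g) {
    morphs <- g$morphology[!is.na(g$morphology)]
    morph <- if (length(morphs)) names(sort(table(morphs), decreasing = TRUE))[1] else "flat"
    data.frame(
      lead = g$lead[1],
      pwd_ms = mean(g$pwd_ms),
      pwdc_ms = correct_pwd_hodges(mean(g$pwd_ms), heart_rate_bpm),
      pwv_mv = mean(g$pwv_mv),
      pwa_msmv = mean(g$pwa_msmv),
      disp_ms = if (nrow(g) >= 2) compute_pwdisp(g$pwd_ms, "within_lead_beats") else 0,
      morphology = morph,
      n_beats_used = nrow(g),
      stringsAsFactors = FALSE
    )
  })
  leads_df <- do.call(rbind, lead_rows)
  rownames(leads_df) <- NULL

  pwdisp <- if (nrow(leads_df) >= 2) compute_pwdisp(leads_df$pwd_ms, "across_leads") else NA_real_
  ptfv1 <- if ("V1" %in% used$lead) {
    v1 <- used[used$lead == "V1", ]
    mean(v1$ptfv1_mms, na.rm = TRUE)
  } else {
    NA_real_
  }
  pwd_for_iab <- stats::setNames(
    if (iab_use_corrected) leads_df$pwdc_ms else leads_df$pwd_ms,
    leads_df$lead
  )
  iab <- classify_iab(pwd_for_iab,
                      stats::setNames(leads_df$morphology, leads_df$lead),
                      pwd_threshold_ms = iab_threshold_ms,
                      leads = iab_leads, lead_rule = iab_lead_rule)

  row <- data.frame(patient_id = patient_id, hr_bpm = heart_rate_bpm,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(leads_df))) {
    ld <- leads_df$lead[i]
    row[[paste0(ld, "_pwd_ms")]] <- leads_df$pwd_ms[i]
    row[[paste0(ld, "_pwdc_ms")]] <- leads_df$pwdc_ms[i]
    row[[paste0(ld, "_pwv_mv")]] <- leads_df$pwv_mv[i]
    row[[paste0(ld, "_pwa_msmv")]] <- leads_df$pwa_msmv[i]
    row[[paste0(ld, "_disp_ms")]] <- leads_df$disp_ms[i]
  }
  row$pwdisp_global_ms <- pwdisp
  row$ptfv1_mms <- ptfv1
  row$iab <- iab

  list(leads = leads_df, features = row, iab = iab,
       pwdisp_global_ms = pwdisp, ptfv1_mms = ptfv1)
}
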