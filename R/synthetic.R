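#' P wave component specification
#'
#' Describes one lead's P wave on the synthetic beat template. The declared
#' `duration_ms` is the literal support of the component: the true onset and
#' offset used as ground truth are its endpoints. Gaussian humps are
#' truncated at three standard deviations and renormalised so the endpoints
#' are exactly zero; biphasic waves are two opposite-signed half-sine phases.
#'
#' @param shape `"gaussian"`, `"triangular"`, or `"biphasic"`.
#' @param duration_ms Total support of the P wave in ms (> 0).
#' @param amplitude_mv Signed apex amplitude of the (first) phase in mV.
#' @param second_phase_amplitude_mv Signed apex of the second phase
#'   (biphasic only; must oppose the first phase's sign).
#' @param second_phase_fraction Fraction of `duration_ms` occupied by the
#'   second phase, in (0, 1).
#' @return A `pwave_spec` list.
#' @export
pwave_spec <- function(shape = c("gaussian", "triangular", "biphasic"),
                       duration_ms = 115, amplitude_mv = 0.2,
                       second_phase_amplitude_mv = -0.08,
                       second_phase_fraction = 0.4) {
  shape <- match.arg(shape)
  if (duration_ms <= 0) stop("duration_ms must be > 0")
  if (shape == "biphasic") {
    if (second_phase_fraction <= 0 || second_phase_fraction >= 1) {
      stop("second_phase_fraction must lie in (0, 1)")
    }
    if (amplitude_mv * second_phase_amplitude_mv >= 0 &&
        !(amplitude_mv == 0 && second_phase_amplitude_mv == 0)) {
      stop("biphasic phases must have opposite signs")
    }
  }
  structure(list(
    shape = shape, duration_ms = duration_ms, amplitude_mv = amplitude_mv,
    second_phase_amplitude_mv = second_phase_amplitude_mv,
    second_phase_fraction = second_phase_fraction
  ), class = "pwave_spec")
}

#' Default per-lead P wave morphology
#'
#' Amplitudes bracket typical sinus-rhythm values in each lead (negative P
#' in aVR, biphasic P in V1). The default shape is triangular: its support
#' endpoints are crisp corners, so ground-truth onset and offset are
#' operationally identifiable landmarks; Gaussian humps (whose tails leave
#' the baseline tangentially, below one ADC quantum for several
#' milliseconds) are available for studying the smooth-tail behaviour of
#' boundary detectors.
#'
#' @param duration_ms P wave support in ms for every lead.
#' @param shape Shape of the eleven monophasic leads (V1 is always
#'   biphasic).
#' @return Named list of [pwave_spec()] per standard lead.
#' @export
default_lead_pwaves <- function(duration_ms = 115,
                                shape = c("triangular", "gaussian")) {
  shape <- match.arg(shape)
  amps <- c(I = 0.24, II = 0.26, III = 0.18, aVR = -0.19, aVL = 0.19,
            aVF = 0.21, V2 = 0.16, V3 = 0.18, V4 = 0.20, V5 = 0.17, V6 = 0.15)
  out <- lapply(amps, function(a) {
    pwave_spec(shape, duration_ms = duration_ms, amplitude_mv = a)
  })
  out$V1 <- pwave_spec("biphasic", duration_ms = duration_ms,
                       amplitude_mv = 0.10,
                       second_phase_amplitude_mv = -0.06,
                       second_phase_fraction = 0.4)
  out[standard_leads()]
}

#' Noise specification for synthetic recordings
#'
#' @param white_sd_mv Standard deviation of i.i.d. Gaussian noise per sample.
#' @param mains_hz Mains interference frequency (Hz).
#' @param mains_amp_mv Mains sinusoid amplitude (mV); 0 disables it.
#' @param wander_amp_mv Baseline-wander sinusoid amplitude (mV).
#' @param wander_hz Baseline-wander frequency (Hz).
#' @return A named list.
#' @export
noise_spec <- function(white_sd_mv = 0, mains_hz = 50, mains_amp_mv = 0,
                       wander_amp_mv = 0, wander_hz = 0.3) {
  if (white_sd_mv < 0 || mains_amp_mv < 0 || wander_amp_mv < 0) {
    stop("noise amplitudes must be >= 0")
  }
  list(white_sd_mv = white_sd_mv, mains_hz = mains_hz,
       mains_amp_mv = mains_amp_mv, wander_amp_mv = wander_amp_mv,
       wander_hz = wander_hz)
}

#' Full synthetic 12-lead recording specification
#'
#' Defaults emulate the acquisition this package targets: one-minute 12-lead
#' recordings digitised at 16 bits over a 10 mV span, sinus rhythm around
#' 70 bpm, P wave morphology per lead from [pwave_spec()] defaults.
#'
#' @param p_waves Named list of [pwave_spec()] per lead, or a single spec
#'   applied to all leads in `leads`.
#' @param leads Lead labels to generate.
#' @param qrs_amplitude_mv,qrs_width_ms QRS triangular spike parameters.
#' @param t_amplitude_mv,t_duration_ms T wave half-sine parameters.
#' @param st_segment_ms Gap between QRS end and T onset (ms).
#' @param pr_segment_ms Gap between P offset and QRS onset (ms).
#' @param heart_rate_bpm Mean heart rate (> 0).
#' @param rr_jitter_ms Gaussian SD of beat-to-beat RR jitter (ms).
#' @param fs_hz Sampling rate (>= 250 Hz).
#' @param duration_s Recording length in seconds.
#' @param noise A [noise_spec()].
#' @param adc_bits,adc_range_mv Quantisation applied to the generated samples.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(p_waves = default_lead_pwaves(),
                           leads = standard_leads(),
                           qrs_amplitude_mv = 1.0, qrs_width_ms = 80,
                           t_amplitude_mv = 0.3, t_duration_ms = 200,
                           st_segment_ms = 80, pr_segment_ms = 60,
                           heart_rate_bpm = 70, rr_jitter_ms = 0,
                           fs_hz = 1000, duration_s = 60,
                           noise = noise_spec(),
                           adc_bits = 16L, adc_range_mv = 10,
                           seed = 1L) {
  if (heart_rate_bpm <= 0) stop("heart_rate_bpm must be > 0")
  if (fs_hz < 250) stop("fs_hz must be >= 250")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (inherits(p_waves, "pwave_spec")) {
    p_waves <- stats::setNames(rep(list(p_waves), length(leads)), leads)
  }
  leads <- canonical_lead(leads)
  names(p_waves) <- canonical_lead(names(p_waves))
  missing <- setdiff(leads, names(p_waves))
  if (length(missing)) stop("no pwave_spec for lead(s): ", paste(missing, collapse = ", "))
  structure(list(
    p_waves = p_waves[leads], leads = leads,
    qrs_amplitude_mv = qrs_amplitude_mv, qrs_width_ms = qrs_width_ms,
    t_amplitude_mv = t_amplitude_mv, t_duration_ms = t_duration_ms,
    st_segment_ms = st_segment_ms, pr_segment_ms = pr_segment_ms,
    heart_rate_bpm = heart_rate_bpm, rr_jitter_ms = rr_jitter_ms,
    fs_hz = fs_hz, duration_s = duration_s, noise = noise,
    adc_bits = as.integer(adc_bits), adc_range_mv = adc_range_mv,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Sample a P wave on its support; returns list(y, apex) with apex the 1-based
# offset of the extremum within the support.
p_wave_samples <- function(pw, fs) {
  d <- pw$duration_ms / 1000
  m <- round(d * fs)
  t <- (0:m) / fs
  y <- switch(pw$shape,
    triangular = pw$amplitude_mv * (1 - abs(2 * t / d - 1)),
    gaussian = {
      sigma <- d / 6
      raw <- exp(-0.5 * ((t - d / 2) / sigma)^2)
      pw$amplitude_mv * (raw - exp(-4.5)) / (1 - exp(-4.5))
    },
    biphasic = {
      d1 <- d * (1 - pw$second_phase_fraction)
      yy <- numeric(length(t))
      in1 <- t <= d1
      yy[in1] <- pw$amplitude_mv * sin(pi * t[in1] / d1)
      yy[!in1] <- pw$second_phase_amplitude_mv *
        sin(pi * (t[!in1] - d1) / (d - d1))
      yy
    }
  )
  list(y = y, apex = which.max(abs(y)))
}

#' Generate a synthetic 12-lead ECG with ground truth
#'
#' Places P-QRS-T components on an analytic beat template: the QRS is a
#' triangular spike centred on the R peak, the T wave a half-sine starting
#' `st_segment_ms` after the QRS, and the P wave support ends
#' `pr_segment_ms` before QRS onset. True fiducials are the analytic support
#' endpoints, so ground truth carries no delineation circularity. Noise from
#' the spec is added afterwards and the result quantised to the configured
#' ADC grid. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `recording` (an [ecg_recording]) and `truth`
#'   (list: `annotations`, an [annotation_set] of true fiducials; `leads`,
#'   per-lead true PWD/PWV/PWA; `heart_rate_bpm`; `r_peaks`, 0-based R
#'   sample indices).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fs <- spec$fs_hz
  n <- round(spec$duration_s * fs)
  rr_s <- 60 / spec$heart_rate_bpm

  set.seed(spec$seed)

  # shared QRS and T templates; the QRS is triphasic (Q-R-S) so its
  # low-frequency content resembles a real complex rather than a
  # monophasic spike
  qrs <- qrs_template(spec$qrs_amplitude_mv, spec$qrs_width_ms, fs)
  m_t <- round(spec$t_duration_ms / 1000 * fs)
  t_y <- spec$t_amplitude_mv * sin(pi * (0:m_t) / m_t)
  pre_qrs_s <- (qrs$apex - 1L) / fs              # QRS onset to R apex
  post_qrs_s <- (length(qrs$y) - qrs$apex) / fs  # R apex to QRS end

  # R peak times: first beat leaves room for its own P wave, last leaves room
  # for a full T wave before the end of the record
  max_p_dur <- max(vapply(spec$p_waves, `[[`, 0, "duration_ms")) / 1000
  t_first <- max(1.0, pre_qrs_s + spec$pr_segment_ms / 1000 + max_p_dur + 0.1)
  tail_s <- post_qrs_s + (spec$st_segment_ms + spec$t_duration_ms) / 1000 + 0.1
  r_times <- numeric(0)
  t_cur <- t_first
  while (t_cur < spec$duration_s - tail_s) {
    r_times <- c(r_times, t_cur)
    jit <- if (spec$rr_jitter_ms > 0) stats::rnorm(1, 0, spec$rr_jitter_ms / 1000) else 0
    t_cur <- t_cur + rr_s + jit
  }
  if (length(r_times) < 2) stop("duration_s too short for two beats at this heart rate")

  t_start_off <- post_qrs_s + spec$st_segment_ms / 1000
  t_end_off <- t_start_off + spec$t_duration_ms / 1000

  # overlap check: every P support must start after the previous beat's T end
  p_onset_off <- pre_qrs_s + spec$pr_segment_ms / 1000 + max_p_dur
  min_rr <- min(diff(r_times))
  if (min_rr - p_onset_off < t_end_off) {
    stop("P wave support overlaps the preceding T wave at this heart rate; ",
         "use shorter P/T durations or a lower rate")
  }

  n_beats <- length(r_times)
  r_idx <- round(r_times * fs)

  samples <- matrix(0, nrow = length(spec$leads), ncol = n,
                    dimnames = list(spec$leads, NULL))
  ann <- list()
  lead_truth <- list()
  for (j in seq_along(spec$leads)) {
    lead <- spec$leads[j]
    pw <- spec$p_waves[[lead]]
    ps <- p_wave_samples(pw, fs)
    sig <- numeric(n)
    rows <- vector("list", n_beats)
    for (k in seq_len(n_beats)) {
      rk <- r_idx[k]
      # QRS, aligned so its R apex falls on the R peak index
      i0 <- rk - (qrs$apex - 1L)
      sig <- add_component(sig, i0, qrs$y)
      # T wave
      ti <- rk + round(t_start_off * fs)
      sig <- add_component(sig, ti, t_y)
      t_end_idx <- ti + m_t
      # P wave: support ends pr_segment before QRS onset
      p_off_idx <- i0 - round(spec$pr_segment_ms / 1000 * fs)
      p_on_idx <- p_off_idx - (length(ps$y) - 1)
      sig <- add_component(sig, p_on_idx, ps$y)
      rows[[k]] <- data.frame(
        beat = k,
        kind = c("R_PEAK", "T_END", "P_ONSET", "P_PEAK", "P_OFFSET"),
        sample = c(rk, t_end_idx, p_on_idx, p_on_idx + ps$apex - 1, p_off_idx)
      )
    }
    samples[j, ] <- sig
    bt <- do.call(rbind, rows)
    bt$lead <- lead
    ann[[j]] <- bt
    # per-lead analytic truth; PWA by trapezoid on the clean P support
    dt_ms <- 1000 / fs
    pwa <- sum((abs(ps$y)[-1] + abs(ps$y)[-length(ps$y)]) / 2) * dt_ms
    lead_truth[[j]] <- data.frame(
      lead = lead, pwd_ms = pw$duration_ms,
      pwv_mv = ps$y[ps$apex],
      pwa_msmv = pwa
    )
  }

  allann <- do.call(rbind, ann)
  truth_ann <- annotation_set(allann$lead, allann$beat, allann$kind,
                              allann$sample, "detected")

  rec <- ecg_recording(samples, fs, lead_names = spec$leads,
                       adc_bits = spec$adc_bits,
                       adc_range_mv = spec$adc_range_mv,
                       source_id = sprintf("synthetic-seed-%d", spec$seed))
  rec <- add_noise(rec, spec$noise, spec$seed)
  # quantise to the ADC grid
  q <- rec$adc_range_mv / 2^rec$adc_bits
  rec$samples <- round(rec$samples / q) * q
  rec$samples <- pmin(pmax(rec$samples, -rec$adc_range_mv / 2),
                      rec$adc_range_mv / 2)

  list(
    recording = rec,
    truth = list(
      annotations = truth_ann,
      leads = do.call(rbind, lead_truth),
      heart_rate_bpm = spec$heart_rate_bpm,
      r_peaks = r_idx
    )
  )
}

# Triphasic Q-R-S template: contiguous triangular phases with fixed
# proportions (Q: 20% of the width at -12% of R, R: 50%, S: 30% at -25% of
# R). Returns the sample vector and the 1-based apex (R peak) offset.
qrs_template <- function(amplitude_mv, width_ms, fs) {
  m_q <- round(0.2 * width_ms / 1000 * fs)
  m_r <- round(0.5 * width_ms / 1000 * fs)
  m_s <- round(0.3 * width_ms / 1000 * fs)
  tri <- function(a, m) a * (1 - abs(2 * (0:m) / m - 1))
  q <- tri(-0.12 * amplitude_mv, m_q)
  r <- tri(amplitude_mv, m_r)
  s <- tri(-0.25 * amplitude_mv, m_s)
  # phases share their boundary samples (all zero there)
  y <- c(q[-length(q)], r[-length(r)], s)
  list(y = y, apex = m_q + round(m_r / 2) + 1L)
}

# add component y starting at 0-based index i0 into sig, clipping to bounds
add_component <- function(sig, i0, y) {
  n <- length(sig)
  idx <- i0 + seq_along(y) - 1   # 0-based
  keep <- idx >= 0 & idx < n
  sig[idx[keep] + 1] <- sig[idx[keep] + 1] + y[keep]
  sig
}

#' Add noise to a recording
#'
#' Adds, per lead: i.i.d. Gaussian noise, a pure mains sinusoid, and a
#' low-frequency baseline-wander sinusoid. Each lead draws from its own RNG
#' sub-stream keyed by `seed` and the lead position, so results do not depend
#' on lead evaluation order. All-zero amplitudes return the input unchanged.
#'
#' @param rec An [ecg_recording].
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return An [ecg_recording] with noise added (not re-quantised).
#' @export
add_noise <- function(rec, noise, seed = 1L) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (noise$white_sd_mv == 0 && noise$mains_amp_mv == 0 &&
      noise$wander_amp_mv == 0) {
    return(rec)
  }
  n <- ncol(rec$samples)
  t <- (seq_len(n) - 1) / rec$fs
  for (j in seq_len(nrow(rec$samples))) {
    set.seed((as.integer(seed) + 7919L * j) %% 2147483647L)
    add <- numeric(n)
    if (noise$mains_amp_mv > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      add <- add + noise$mains_amp_mv * sin(2 * pi * noise$mains_hz * t + phase)
    }
    if (noise$wander_amp_mv > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      add <- add + noise$wander_amp_mv * sin(2 * pi * noise$wander_hz * t + phase)
    }
    if (noise$white_sd_mv > 0) {
      add <- add + stats::rnorm(n, 0, noise$white_sd_mv)
    }
    rec$samples[j, ] <- rec$samples[j, ] + add
  }
  rec
}
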