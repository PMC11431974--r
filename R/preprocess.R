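#' Filtering configuration
#'
#' Settings of the preprocessing chain: a second-order Bessel bandpass
#' (1-50 Hz by default) plus a biquad mains notch. With `zero_phase` the
#' filter is applied forward and backward ([signal::filtfilt()]), which
#' squares the magnitude response but leaves fiducial timing unbiased;
#' this is the default because delineation downstream is timing-critical.
#'
#' @param low_hz Lower cut-off (Hz).
#' @param high_hz Upper cut-off (Hz).
#' @param order Analog prototype order of the Bessel design.
#' @param notch_hz Mains notch centre frequency (Hz); 50 by default,
#'   set 60 for 60 Hz mains.
#' @param notch_q Notch quality factor (centre / -3 dB bandwidth).
#' @param zero_phase Apply forward-backward for zero phase distortion.
#' @return A `filter_config` list.
#' @export
filter_config <- function(low_hz = 1, high_hz = 50, order = 2,
                          notch_hz = 50, notch_q = 30, zero_phase = TRUE) {
  if (low_hz <= 0 || high_hz <= low_hz) stop("need 0 < low_hz < high_hz")
  if (order < 1) stop("order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 notch_hz = notch_hz, notch_q = notch_q,
                 zero_phase = zero_phase),
            class = "filter_config")
}

# Analog Bessel lowpass prototype poles, normalised to a -3 dB frequency of 1.
# Poles are the roots of the reverse Bessel polynomial; the -3 dB scale
# factor is computed numerically from the prototype's magnitude response.
bessel_prototype <- function(order) {
  # reverse Bessel polynomial coefficients a_k = (2n-k)! / (2^(n-k) k! (n-k)!)
  n <- order
  k <- 0:n
  a <- factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
  # polyroot wants ascending powers: a[k+1] is coefficient of s^k
  p <- polyroot(a)
  g <- a[1]  # DC gain numerator (denominator at s=0)
  # -3 dB frequency of H(s) = g / prod(s - p): solve |H(jw)|^2 = 1/2
  mag2 <- function(w) {
    h <- g / prod(complex(real = 0, imaginary = w) - p)
    Mod(h)^2
  }
  w3 <- stats::uniroot(function(w) mag2(w) - 0.5, c(1e-6, 10 * n))$root
  list(poles = p / w3, gain = g / w3^n)
}

# Digital Bessel bandpass via lowpass-to-bandpass s-plane transform and the
# bilinear transform (matching signal::butter's prewarping convention).
design_bessel_bandpass <- function(low_hz, high_hz, order, fs) {
  if (high_hz >= fs / 2) stop("high_hz must be below the Nyquist frequency fs/2")
  proto <- bessel_prototype(order)
  W <- tan(pi * c(low_hz, high_hz) / fs)   # prewarped, T = 2 convention
  zpg <- signal::Zpg(zero = numeric(0), pole = proto$poles, gain = proto$gain)
  bp <- signal::sftrans(zpg, W = W, stop = FALSE)
  dig <- signal::bilinear(bp, T = 2)
  as_arma(dig)
}

as_arma <- function(zpg) {
  arma <- signal::as.Arma(zpg)
  list(b = Re(arma$b), a = Re(arma$a))
}

# Biquad notch with unit gain away from the centre and a zero at notch_hz.
design_notch <- function(notch_hz, q, fs) {
  if (notch_hz >= fs / 2) stop("notch_hz must be below the Nyquist frequency fs/2")
  w0 <- 2 * pi * notch_hz / fs
  beta <- tan(w0 / (2 * q))
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * gain * cos(w0), 2 * gain - 1)
  list(b = b, a = a)
}

#' Magnitude response of a digital filter
#'
#' Evaluates |H(e^{i omega})| for the rational filter (b, a) at the given
#' frequencies. Used as the analytic oracle for passband/stopband checks.
#'
#' @param ba List with numerator `b` and denominator `a`.
#' @param f_hz Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of magnitudes.
#' @export
filter_magnitude <- function(ba, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  vapply(w, function(wi) {
    z <- exp(complex(imaginary = -wi))
    Mod(sum(ba$b * z^(seq_along(ba$b) - 1)) /
          sum(ba$a * z^(seq_along(ba$a) - 1)))
  }, numeric(1))
}

apply_ba <- function(x, ba, zero_phase) {
  if (zero_phase) {
    as.numeric(signal::filtfilt(signal::Arma(b = ba$b, a = ba$a), x))
  } else {
    as.numeric(signal::filter(signal::Arma(b = ba$b, a = ba$a), x))
  }
}

#' Apply the Bessel bandpass to a recording
#'
#' Filters every lead with the configured Bessel bandpass. Length is
#' preserved and DC is removed; with `zero_phase` (default) symmetric
#' features keep their peak positions.
#'
#' @param rec An [ecg_recording].
#' @param cfg A [filter_config()].
#' @return The filtered [ecg_recording].
#' @export
apply_bandpass <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(rec, "ecg_recording"))
  ba <- design_bessel_bandpass(cfg$low_hz, cfg$high_hz, cfg$order, rec$fs)
  for (j in seq_len(nrow(rec$samples))) {
    rec$samples[j, ] <- apply_ba(rec$samples[j, ], ba, cfg$zero_phase)
  }
  rec
}

#' Apply the mains notch filter to a recording
#'
#' Biquad notch at `cfg$notch_hz` with quality `cfg$notch_q`: deep
#' attenuation at the mains frequency, under 3 dB within +/- 5 Hz for the
#' default quality factor.
#'
#' @inheritParams apply_bandpass
#' @return The filtered [ecg_recording].
#' @export
apply_notch <- function(rec, cfg = filter_config()) {
  stopifnot(inherits(rec, "ecg_recording"))
  ba <- design_notch(cfg$notch_hz, cfg$notch_q, rec$fs)
  for (j in seq_len(nrow(rec$samples))) {
    rec$samples[j, ] <- apply_ba(rec$samples[j, ], ba, cfg$zero_phase)
  }
  rec
}

#' Run the full preprocessing chain
#'
#' Bandpass then notch, the order used throughout the pipeline.
#'
#' @inheritParams apply_bandpass
#' @return The preprocessed [ecg_recording].
#' @export
preprocess_recording <- function(rec, cfg = filter_config()) {
  apply_notch(apply_bandpass(rec, cfg), cfg)
}
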