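#' Standard 12-lead labels in conventional order
#'
#' @return Character vector of the twelve standard lead names.
#' @export
standard_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", "V1", "V2", "V3", "V4", "V5", "V6")
}

# Map a label to its canonical-case standard form, or return it unchanged.
canonical_lead <- function(lead) {
  std <- standard_leads()
  idx <- match(toupper(lead), toupper(std))
  ifelse(is.na(idx), lead, std[idx])
}

#' Multi-lead ECG recording
#'
#' Container for a digitised multi-lead ECG: a lead-major sample matrix in
#' millivolts plus acquisition metadata. The twelve standard lead labels are
#' recognised case-insensitively and stored in canonical case; non-standard
#' labels are kept as given (with a warning at file ingest).
#'
#' @param samples Numeric matrix, one row per lead, one column per sample,
#'   amplitudes in mV.
#' @param fs Sampling rate in Hz (> 0).
#' @param lead_names Character vector of unique lead labels, one per row.
#' @param adc_bits Integer ADC resolution (bits); `NA` if unknown.
#' @param adc_range_mv Total ADC voltage span in mV (e.g. 10 for a
#'   -5 to +5 mV range); `NA` if unknown.
#' @param source_id Free-text identifier of the recording.
#'
#' @return An object of class `ecg_recording` with fields `samples`, `fs`,
#'   `lead_names`, `duration_s`, `adc_bits`, `adc_range_mv`, `source_id`.
#' @export
ecg_recording <- function(samples, fs, lead_names = rownames(samples),
                          adc_bits = NA_integer_, adc_range_mv = NA_real_,
                          source_id = "") {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (is.null(lead_names)) {
    lead_names <- paste0("L", seq_len(nrow(samples)))
  }
  lead_names <- canonical_lead(as.character(lead_names))
  if (length(lead_names) != nrow(samples)) {
    stop("`lead_names` must have one entry per row of `samples`")
  }
  if (anyDuplicated(lead_names)) stop("lead names must be unique")
  if (!is.na(adc_range_mv) && ncol(samples) > 0) {
    half <- adc_range_mv / 2
    tol <- adc_quantum(adc_bits, adc_range_mv)
    if (any(abs(samples) > half + tol, na.rm = TRUE)) {
      stop("amplitudes exceed +/- adc_range_mv/2")
    }
  }
  rownames(samples) <- lead_names
  structure(
    list(
      samples = samples,
      fs = as.numeric(fs),
      lead_names = lead_names,
      duration_s = ncol(samples) / fs,
      adc_bits = as.integer(adc_bits),
      adc_range_mv = as.numeric(adc_range_mv),
      source_id = as.character(source_id)
    ),
    class = "ecg_recording"
  )
}

# One ADC quantum in mV; Inf when the metadata is absent so range checks
# degrade gracefully.
adc_quantum <- function(adc_bits, adc_range_mv) {
  if (is.na(adc_bits) || is.na(adc_range_mv)) return(Inf)
  adc_range_mv / (2^adc_bits)
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf(
    "<ecg_recording> %d lead(s) x %d samples @ %g Hz (%.3f s)\n",
    nrow(x$samples), ncol(x$samples), x$fs, x$duration_s
  ))
  cat("  leads:", paste(x$lead_names, collapse = ", "), "\n")
  if (!is.na(x$adc_bits)) {
    cat(sprintf("  ADC: %d bits over %g mV\n", x$adc_bits, x$adc_range_mv))
  }
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' Extract a single lead's sample vector
#'
#' @param rec An [ecg_recording].
#' @param lead Lead label (case-insensitive for standard leads).
#' @return Numeric vector of amplitudes in mV.
#' @export
lead_signal <- function(rec, lead) {
  stopifnot(inherits(rec, "ecg_recording"))
  lead <- canonical_lead(lead)
  i <- match(lead, rec$lead_names)
  if (is.na(i)) stop(sprintf("lead '%s' not present in recording", lead))
  rec$samples[i, ]
}
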