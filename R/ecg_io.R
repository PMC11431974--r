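#' Fiducial vocabulary
#'
#' The closed set of fiducial kinds used in annotation files.
#' @return Character vector of valid kinds.
#' @export
fiducial_kinds <- function() {
  c("R_PEAK", "T_END", "P_PEAK", "P_ONSET", "P_OFFSET")
}

#' Fiducial annotation set
#'
#' A table of per-lead, per-beat fiducial sample indices. Sample indices are
#' 0-based, matching the on-disk convention; times derive as `sample / fs`.
#' `provenance` distinguishes automatically `detected` fiducials from manual
#' `override` records; overrides replace detected records with the same
#' (lead, beat, kind) key at resolution time.
#'
#' @param lead Character vector of lead labels.
#' @param beat Integer beat ordinals (1-based beat numbering).
#' @param kind Fiducial kind, one of [fiducial_kinds()].
#' @param sample 0-based sample index.
#' @param provenance `"detected"` or `"override"`.
#' @return A data frame of class `annotation_set`.
#' @export
annotation_set <- function(lead = character(), beat = integer(),
                           kind = character(), sample = integer(),
                           provenance = "detected") {
  kind <- as.character(kind)
  bad <- setdiff(unique(kind), fiducial_kinds())
  if (length(bad)) {
    stop("unknown fiducial kind(s): ", paste(bad, collapse = ", "))
  }
  provenance <- rep_len(as.character(provenance), length(lead))
  badp <- setdiff(unique(provenance), c("detected", "override"))
  if (length(lead) && length(badp)) {
    stop("provenance must be 'detected' or 'override'")
  }
  df <- data.frame(
    lead = canonical_lead(as.character(lead)),
    beat = as.integer(beat),
    kind = kind,
    sample = as.integer(sample),
    provenance = provenance,
    stringsAsFactors = FALSE
  )
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' Resolve manual overrides against detected fiducials
#'
#' Override records replace detected records sharing the same
#' (lead, beat, kind) key; the result carries at most one record per key.
#' Resolution is idempotent and order-independent within a provenance class
#' (duplicate keys within one class keep the last occurrence).
#'
#' @param set An [annotation_set].
#' @return An [annotation_set] with overrides applied.
#' @export
resolve_annotations <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  if (nrow(set) == 0) return(set)
  key <- paste(set$lead, set$beat, set$kind, sep = "\r")
  # stable: overrides win over detected; within a class, last record wins
  rank <- ifelse(set$provenance == "override", 2L, 1L)
  ord <- order(key, rank, seq_len(nrow(set)))
  set <- set[ord, , drop = FALSE]
  keep <- !duplicated(key[ord], fromLast = TRUE)
  out <- set[keep, , drop = FALSE]
  out <- out[order(out$lead, out$beat, match(out$kind, fiducial_kinds())), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_set", "data.frame")
  out
}

#' Validate an annotation set against a recording
#'
#' Checks that sample indices fall inside the recording and that, within each
#' (lead, beat), P onset < P peak < P offset whenever all three are present.
#'
#' @param set An [annotation_set] (resolved or not; resolution is applied).
#' @param rec An [ecg_recording].
#' @return The resolved set, invisibly. Errors on violation.
#' @export
validate_annotations <- function(set, rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  set <- resolve_annotations(set)
  n <- ncol(rec$samples)
  if (any(set$sample < 0 | set$sample >= n)) {
    stop("annotation sample index outside recording bounds [0, ", n - 1, "]")
  }
  if (nrow(set)) {
    sp <- split(set, paste(set$lead, set$beat))
    for (g in sp) {
      on <- g$sample[g$kind == "P_ONSET"]
      pk <- g$sample[g$kind == "P_PEAK"]
      off <- g$sample[g$kind == "P_OFFSET"]
      if (length(on) && length(pk) && length(off) &&
          !(on < pk && pk < off)) {
        stop(sprintf(
          "fiducial order violated for lead %s beat %d: onset %d, peak %d, offset %d",
          g$lead[1], g$beat[1], on, pk, off
        ))
      }
    }
  }
  invisible(set)
}

# ---------------------------------------------------------------------------
# Recording text format:
#   '#key=value' metadata lines (fs, units, adc_bits, adc_range_mv, source_id),
#   then a delimited header of lead names, then one sample row per time step.
# A same-stem '.meta' sidecar with key=value lines may supply metadata instead.
# ---------------------------------------------------------------------------

parse_kv <- function(lines) {
  lines <- sub("^#", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- sub("=.*$", "", lines)
  vals <- sub("^[^=]*=", "", lines)
  stats::setNames(trimws(vals), trimws(keys))
}

guess_delim <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

#' Read an ECG recording from a plain-text file
#'
#' Reads the package's self-describing text dialect: comment lines of the
#' form `#key=value` carrying metadata, a header line of lead names, then
#' tab- or comma-delimited numeric sample rows (one per time step). Metadata
#' may alternatively live in a same-stem `.meta` sidecar file. Supported
#' `units` are `mV` (default), `uV`, and `adc` (raw counts converted using
#' `adc_bits`/`adc_range_mv`).
#'
#' @param path Path to the recording file.
#' @param format Only `"txt_matrix"` is supported.
#' @return An [ecg_recording].
#' @export
read_recording <- function(path, format = "txt_matrix") {
  format <- match.arg(format, c("txt_matrix", "wfdb"))
  if (format == "wfdb") {
    stop("WFDB record reading is not supported; convert to txt_matrix first")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  meta <- parse_kv(meta_lines)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".meta")
  if (file.exists(sidecar)) {
    side <- parse_kv(readLines(sidecar, warn = FALSE))
    meta <- c(meta, side[setdiff(names(side), names(meta))])
  }
  if (!("fs" %in% names(meta))) {
    stop("no sampling rate: 'fs' missing from header and sidecar of ", path)
  }
  fs <- as.numeric(meta[["fs"]])
  if (is.na(fs) || fs <= 0) stop("invalid fs in metadata: ", meta[["fs"]])
  if (!length(body)) stop("no header line of lead names in ", path)
  delim <- guess_delim(body[1])
  leads <- trimws(strsplit(body[1], delim, fixed = TRUE)[[1]])
  std <- standard_leads()
  unknown <- leads[is.na(match(toupper(leads), toupper(std)))]
  if (length(unknown)) {
    warning("unknown lead label(s) retained: ", paste(unknown, collapse = ", "))
  }
  rows <- body[-1]
  n_lead <- length(leads)
  if (length(rows)) {
    parts <- strsplit(rows, delim, fixed = TRUE)
    lens <- lengths(parts)
    if (any(lens != n_lead)) {
      first_bad <- which(lens != n_lead)[1]
      # +1 for the lead header; comment lines precede it in our own files but
      # the reported number counts data rows, which is unambiguous
      stop(sprintf(
        "ragged row: data row %d has %d column(s), expected %d",
        first_bad, lens[first_bad], n_lead
      ))
    }
    vals <- suppressWarnings(as.numeric(unlist(parts)))
    if (anyNA(vals)) stop("non-numeric sample value in ", path)
    samples <- matrix(vals, nrow = n_lead, byrow = FALSE)
  } else {
    samples <- matrix(numeric(0), nrow = n_lead, ncol = 0)
  }
  adc_bits <- if ("adc_bits" %in% names(meta)) as.integer(meta[["adc_bits"]]) else NA_integer_
  adc_range <- if ("adc_range_mv" %in% names(meta)) as.numeric(meta[["adc_range_mv"]]) else NA_real_
  units <- if ("units" %in% names(meta)) tolower(meta[["units"]]) else "mv"
  samples <- switch(units,
    mv = samples,
    uv = samples / 1000,
    adc = {
      if (is.na(adc_bits) || is.na(adc_range)) {
        stop("units=adc requires adc_bits and adc_range_mv metadata")
      }
      samples * (adc_range / 2^adc_bits)
    },
    stop("unknown units: ", units)
  )
  ecg_recording(
    samples, fs,
    lead_names = leads,
    adc_bits = adc_bits, adc_range_mv = adc_range,
    source_id = if ("source_id" %in% names(meta)) meta[["source_id"]] else basename(path)
  )
}

#' Write an ECG recording to a plain-text file
#'
#' Writes the dialect read by [read_recording()]: `#key=value` metadata
#' lines, a header of lead names, then delimited sample rows in mV.
#' Round-trips are exact on metadata and within one ADC quantum on samples.
#'
#' @param rec An [ecg_recording].
#' @param path Output path.
#' @param format Only `"txt_matrix"`.
#' @param delim Column delimiter, tab by default.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, format = "txt_matrix", delim = "\t") {
  stopifnot(inherits(rec, "ecg_recording"))
  format <- match.arg(format, "txt_matrix")
  if (rec$fs <= 0) stop("refusing to write recording with fs <= 0")
  header <- c(
    sprintf("#fs=%.10g", rec$fs),
    "#units=mV"
  )
  if (!is.na(rec$adc_bits)) header <- c(header, sprintf("#adc_bits=%d", rec$adc_bits))
  if (!is.na(rec$adc_range_mv)) header <- c(header, sprintf("#adc_range_mv=%.10g", rec$adc_range_mv))
  if (nzchar(rec$source_id)) header <- c(header, paste0("#source_id=", rec$source_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(rec$lead_names, collapse = delim), con)
  if (ncol(rec$samples) > 0) {
    # 6 decimals in mV: well below the 16-bit quantum of 10/65536 mV
    txt <- formatC(t(rec$samples), format = "f", digits = 6)
    writeLines(apply(txt, 1, paste, collapse = delim), con)
  }
  invisible(path)
}

#' Read fiducial annotations from CSV
#'
#' Expects columns `lead,beat,kind,sample,provenance` with kinds from
#' [fiducial_kinds()]. An empty file (header only or zero bytes) yields an
#' empty set.
#'
#' @param path Path to the annotation CSV.
#' @return An [annotation_set].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(annotation_set())
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(annotation_set())
  need <- c("lead", "beat", "kind", "sample")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  prov <- if ("provenance" %in% names(df)) df$provenance else "detected"
  annotation_set(df$lead, df$beat, df$kind, df$sample, prov)
}

#' Write fiducial annotations to CSV
#'
#' @param set An [annotation_set].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  utils::write.csv(as.data.frame(set), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a patient feature table
#'
#' Plain CSV with one header row and one row per patient; `read_feature_table`
#' is a thin validated wrapper around [utils::read.csv()].
#'
#' @param path CSV path.
#' @return Data frame of features.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("patient_id" %in% names(df))) stop("feature table must have a patient_id column")
  df
}

#' @rdname read_feature_table
#' @param df Data frame with a `patient_id` column.
#' @export
write_feature_table <- function(df, path) {
  stopifnot(is.data.frame(df), "patient_id" %in% names(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort outcome table
#'
#' CSV with columns `patient_id`, `outcome` (success/failure),
#' `followup_months`, and `event_time_months` (required for failures, empty
#' for successes).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "outcome", "followup_months")
  if (!all(need %in% names(df))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$outcome), c("success", "failure"))
  if (length(bad)) stop("outcome must be 'success' or 'failure', got: ", paste(bad, collapse = ", "))
  if (any(df$followup_months <= 0)) stop("followup_months must be positive")
  df
}
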