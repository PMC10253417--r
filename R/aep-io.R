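#' Acquisition defaults for an AEP subtype
#'
#' Default sampling, analysis-window and stimulus parameters for the two
#' supported auditory evoked potential subtypes. ABR recordings use a click
#' stimulus at 22/s and 80 dB nHL, acquired at 30 kHz over a 15 ms window
#' (450 samples) with a 33--1500 Hz acquisition band. AMLR recordings use a
#' 2 kHz tone burst at 6.1/s and 70 dB nHL, acquired at 3 kHz over 150 ms
#' (450 samples) with a 10--1500 Hz band.
#'
#' @param subtype `"ABR"` or `"AMLR"`.
#' @return A named list with elements `fs_hz`, `n_samples`, `stimulus_type`,
#'   `rate_hz`, `intensity_db_nhl`, `highpass_hz`, `lowpass_hz`.
#' @examples
#' aep_defaults("ABR")$fs_hz
#' @export
aep_defaults <- function(subtype = c("ABR", "AMLR")) {
  subtype <- match.arg(subtype)
  if (subtype == "ABR") {
    list(fs_hz = 30000, n_samples = 450L, stimulus_type = "click",
         rate_hz = 22, intensity_db_nhl = 80, highpass_hz = 33,
         lowpass_hz = 1500)
  } else {
    list(fs_hz = 3000, n_samples = 450L, stimulus_type = "tone_burst",
         rate_hz = 6.1, intensity_db_nhl = 70, highpass_hz = 10,
         lowpass_hz = 1500)
  }
}

#' Construct a single AEP record
#'
#' Builds a one-row record tibble. Voltages are in microvolts throughout;
#' latency conventions downstream are milliseconds from stimulus onset at
#' sample index 0. Omitted acquisition or stimulus fields are filled from
#' [aep_defaults()] for the subtype.
#'
#' @param record_id,patient_id Opaque identifier strings.
#' @param ear `"left"` or `"right"`.
#' @param subtype `"ABR"` or `"AMLR"`.
#' @param samples Numeric vector of voltages in microvolts.
#' @param fs_hz Sampling rate in Hz; default from [aep_defaults()].
#' @param stimulus_type,rate_hz,intensity_db_nhl,highpass_hz,lowpass_hz
#'   Stimulus and acquisition metadata; defaults from [aep_defaults()].
#' @return A one-row tibble with a `samples` list-column.
#' @export
aep_record <- function(record_id, patient_id, ear, subtype, samples,
                       fs_hz = NULL, stimulus_type = NULL, rate_hz = NULL,
                       intensity_db_nhl = NULL, highpass_hz = NULL,
                       lowpass_hz = NULL) {
  subtype <- match.arg(subtype, c("ABR", "AMLR"))
  d <- aep_defaults(subtype)
  rec <- tibble(
    record_id = as.character(record_id),
    patient_id = as.character(patient_id),
    ear = match.arg(ear, c("left", "right")),
    subtype = subtype,
    fs_hz = if (is.null(fs_hz)) d$fs_hz else as.numeric(fs_hz),
    samples = list(as.numeric(samples)),
    stimulus_type = if (is.null(stimulus_type)) d$stimulus_type else stimulus_type,
    rate_hz = if (is.null(rate_hz)) d$rate_hz else as.numeric(rate_hz),
    intensity_db_nhl = if (is.null(intensity_db_nhl)) d$intensity_db_nhl else as.numeric(intensity_db_nhl),
    highpass_hz = if (is.null(highpass_hz)) d$highpass_hz else as.numeric(highpass_hz),
    lowpass_hz = if (is.null(lowpass_hz)) d$lowpass_hz else as.numeric(lowpass_hz)
  )
  validate_aep_records(rec, notify_deviations = FALSE)
  rec
}

aep_record_columns <- c("record_id", "patient_id", "ear", "subtype", "fs_hz",
                        "samples", "stimulus_type", "rate_hz",
                        "intensity_db_nhl", "highpass_hz", "lowpass_hz")

#' Validate a collection of AEP records
#'
#' Checks the record invariants: non-empty sample series, positive sampling
#' rate, valid ear/subtype codes and unique record ids. Deviations from the
#' subtype defaults (sampling rate or length) are legal but never silent:
#' they are reported via a message so that non-standard analysis windows are
#' always explicit.
#'
#' @param records A record tibble as produced by [aep_record()],
#'   [generate_cohort()] or [read_aep_records()].
#' @param notify_deviations Report records whose sampling rate or length
#'   differs from the subtype defaults (default `TRUE`).
#' @return `records`, invisibly. Errors describe the offending record and
#'   field.
#' @export
validate_aep_records <- function(records, notify_deviations = TRUE) {
  missing_cols <- setdiff(aep_record_columns, names(records))
  if (length(missing_cols)) {
    abort(paste0("records is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(records$record_id)) {
    abort(paste0("duplicate record_id: ",
                 paste(unique(records$record_id[duplicated(records$record_id)]),
                       collapse = ", ")))
  }
  for (i in seq_len(nrow(records))) {
    id <- records$record_id[i]
    if (!records$subtype[i] %in% c("ABR", "AMLR")) {
      abort(paste0("record ", id, ": invalid subtype '", records$subtype[i], "'"))
    }
    if (!records$ear[i] %in% c("left", "right")) {
      abort(paste0("record ", id, ": invalid ear '", records$ear[i], "'"))
    }
    fs <- records$fs_hz[i]
    if (!is.finite(fs) || fs <= 0) {
      abort(paste0("record ", id, ": fs_hz must be > 0 (got ", fs, ")"))
    }
    x <- records$samples[[i]]
    if (!length(x)) abort(paste0("record ", id, ": samples is empty"))
    if (anyNA(x) || !all(is.finite(x))) {
      abort(paste0("record ", id, ": samples contain non-finite values"))
    }
  }
  if (notify_deviations) {
    dev <- purrr::map_lgl(seq_len(nrow(records)), function(i) {
      d <- aep_defaults(records$subtype[i])
      records$fs_hz[i] != d$fs_hz ||
        length(records$samples[[i]]) != d$n_samples
    })
    if (any(dev)) {
      inform(paste0(sum(dev), " record(s) deviate from subtype defaults ",
                    "(fs_hz or length): ",
                    paste(head(records$record_id[dev], 5), collapse = ", "),
                    if (sum(dev) > 5) ", ..."))
    }
  }
  invisible(records)
}

#' Analysis duration of each record in milliseconds
#'
#' Duration is `length(samples) / fs_hz * 1000`; with the 0-based latency
#' convention, sample `k` sits at `k / fs_hz * 1000` ms.
#'
#' @inheritParams validate_aep_records
#' @return Numeric vector of durations in ms, one per record.
#' @export
record_duration_ms <- function(records) {
  purrr::map2_dbl(records$samples, records$fs_hz,
                  function(x, fs) length(x) / fs * 1000)
}

#' Truncate record waveforms to a fixed number of samples
#'
#' Optional preprocessing step that keeps the first `n_samples` voltages of
#' each record (for example shortening a 450-sample AMLR series to 420
#' before scattering). The truncation is reported, never silent, and the
#' returned tibble carries the applied length in the `truncated_to`
#' attribute so a run log can record which series length was analysed.
#'
#' @inheritParams validate_aep_records
#' @param n_samples Target length; must not exceed any record's length.
#' @return The records tibble with shortened `samples`.
#' @export
truncate_records <- function(records, n_samples) {
  n_samples <- as.integer(n_samples)
  short <- purrr::map_lgl(records$samples, ~ length(.x) < n_samples)
  if (any(short)) {
    abort(paste0("cannot truncate to ", n_samples, ": record(s) ",
                 paste(head(records$record_id[short], 5), collapse = ", "),
                 " are shorter"))
  }
  inform(paste0("truncating ", nrow(records), " record(s) to ", n_samples,
                " samples"))
  records$samples <- purrr::map(records$samples, ~ .x[seq_len(n_samples)])
  attr(records, "truncated_to") <- n_samples
  records
}

# full-precision decimal text so voltages round-trip bit-identically
format_uv <- function(x) sprintf("%.17g", x)

#' Read AEP records from XML or CSV
#'
#' The XML dialect (documented in `docs/formats.md` of the source
#' repository) stores one `<record>` element per waveform with metadata
#' attributes and a whitespace-separated `<samples_uv>` payload in
#' microvolts. The CSV dialect is long-format with columns `record_id`,
#' `patient_id`, `ear`, `subtype`, `fs_hz`, `sample_index` (0-based),
#' `value_uv`. Reading applies no resampling, filtering or scaling; stimulus
#' metadata omitted by the file is filled from [aep_defaults()] with a
#' logged notice.
#'
#' @param path Path to the file.
#' @param format `"xml"` or `"csv"`; default guessed from the extension.
#' @return A record tibble (see [aep_record()]), in file order.
#' @export
read_aep_records <- function(path, format = c("auto", "xml", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml" else "csv"
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  records <- if (format == "xml") read_aep_xml(path) else read_aep_csv(path)
  validate_aep_records(records)
}

read_aep_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed XML in ", path, ": ", conditionMessage(e)))
  })
  if (xml2::xml_name(doc) != "aep_records") {
    abort(paste0(path, ": root element must be <aep_records>, found <",
                 xml2::xml_name(doc), ">"))
  }
  nodes <- xml2::xml_find_all(doc, "./record")
  defaults_used <- character()
  rows <- purrr::map(nodes, function(node) {
    att <- function(name) {
      v <- xml2::xml_attr(node, name)
      if (is.na(v)) NULL else v
    }
    id <- att("id")
    subtype <- att("subtype")
    if (is.null(id) || is.null(subtype)) {
      abort(paste0(path, ": <record> element missing 'id' or 'subtype' ",
                   "attribute (line ",
                   xml2::xml_path(node), ")"))
    }
    d <- aep_defaults(match.arg(subtype, c("ABR", "AMLR")))
    sm <- xml2::xml_find_first(node, "./samples_uv")
    if (inherits(sm, "xml_missing")) {
      abort(paste0(path, ": record ", id, " has no <samples_uv> element"))
    }
    vals <- suppressWarnings(
      as.numeric(strsplit(trimws(xml2::xml_text(sm)), "\\s+")[[1]]))
    if (anyNA(vals)) {
      abort(paste0(path, ": record ", id,
                   " contains non-numeric sample text"))
    }
    opt <- function(name) {
      v <- att(name)
      if (is.null(v)) {
        defaults_used <<- c(defaults_used, paste0(id, ":", name))
        NULL
      } else as.numeric(v)
    }
    aep_record(
      record_id = id,
      patient_id = if (is.null(att("patient"))) id else att("patient"),
      ear = att("ear") %||% "left",
      subtype = subtype,
      samples = vals,
      fs_hz = opt("fs_hz"),
      stimulus_type = att("stimulus_type"),
      rate_hz = opt("rate_hz"),
      intensity_db_nhl = opt("intensity_db_nhl"),
      highpass_hz = opt("highpass_hz"),
      lowpass_hz = opt("lowpass_hz")
    )
  })
  if (length(defaults_used)) {
    inform(paste0("applied subtype defaults for omitted fields: ",
                  paste(head(defaults_used, 5), collapse = ", "),
                  if (length(defaults_used) > 5) ", ..."))
  }
  if (!length(rows)) return(empty_aep_records())
  bind_rows(rows)
}

read_aep_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = list(
      record_id = "character", patient_id = "character")),
    error = function(e) abort(paste0("malformed CSV in ", path, ": ",
                                     conditionMessage(e))))
  needed <- c("record_id", "patient_id", "ear", "subtype", "fs_hz",
              "sample_index", "value_uv")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(paste0(path, ": CSV is missing columns ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(df)) return(empty_aep_records())
  inform("CSV carries no stimulus metadata; applying subtype defaults")
  ids <- unique(df$record_id)  # preserve file order
  rows <- purrr::map(ids, function(id) {
    sub <- df[df$record_id == id, ]
    sub <- sub[order(sub$sample_index), ]
    if (!identical(as.integer(sub$sample_index),
                   seq_len(nrow(sub)) - 1L)) {
      abort(paste0(path, ": record ", id,
                   ": sample_index must be 0..n-1 without gaps"))
    }
    aep_record(record_id = id, patient_id = sub$patient_id[1],
               ear = sub$ear[1], subtype = sub$subtype[1],
               samples = sub$value_uv, fs_hz = sub$fs_hz[1])
  })
  bind_rows(rows)
}

empty_aep_records <- function() {
  tibble(record_id = character(), patient_id = character(),
         ear = character(), subtype = character(), fs_hz = numeric(),
         samples = list(), stimulus_type = character(), rate_hz = numeric(),
         intensity_db_nhl = numeric(), highpass_hz = numeric(),
         lowpass_hz = numeric())
}

#' Write AEP records to XML or CSV
#'
#' Voltages are written as decimal text with 17 significant digits, so
#' `read_aep_records(write_aep_records(x))` reproduces the sample series
#' bit-identically in both formats.
#'
#' @inheritParams validate_aep_records
#' @inheritParams read_aep_records
#' @return `path`, invisibly.
#' @export
write_aep_records <- function(records, path, format = c("auto", "xml", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml" else "csv"
  }
  validate_aep_records(records, notify_deviations = FALSE)
  if (format == "xml") write_aep_xml(records, path) else write_aep_csv(records, path)
  invisible(path)
}

write_aep_xml <- function(records, path) {
  doc <- xml2::xml_new_root("aep_records")
  for (i in seq_len(nrow(records))) {
    node <- xml2::xml_add_child(
      doc, "record",
      id = records$record_id[i], patient = records$patient_id[i],
      ear = records$ear[i], subtype = records$subtype[i],
      fs_hz = format_uv(records$fs_hz[i]),
      stimulus_type = records$stimulus_type[i],
      rate_hz = format_uv(records$rate_hz[i]),
      intensity_db_nhl = format_uv(records$intensity_db_nhl[i]),
      highpass_hz = format_uv(records$highpass_hz[i]),
      lowpass_hz = format_uv(records$lowpass_hz[i]))
    xml2::xml_add_child(node, "samples_uv",
                        paste(format_uv(records$samples[[i]]), collapse = " "))
  }
  xml2::write_xml(doc, path)
}

write_aep_csv <- function(records, path) {
  header <- "record_id,patient_id,ear,subtype,fs_hz,sample_index,value_uv"
  lines <- purrr::map(seq_len(nrow(records)), function(i) {
    x <- records$samples[[i]]
    paste(records$record_id[i], records$patient_id[i], records$ear[i],
          records$subtype[i], format_uv(records$fs_hz[i]),
          seq_along(x) - 1L, format_uv(x), sep = ",")
  })
  writeLines(c(header, unlist(lines)), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
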