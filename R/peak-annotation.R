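#' Default search windows for the waves of interest
#'
#' Windows follow the physiological ranges of the two responses: ABR waves
#' fall within the first 10 ms after a click, AMLR components between
#' roughly 12 and 60 ms. Peaks (I, III, V, Pa, Pb) are searched as local
#' maxima, troughs (Na, Nb) as local minima.
#'
#' @param subtype `"ABR"` or `"AMLR"`.
#' @return Tibble with columns `wave`, `start_ms`, `end_ms`, `polarity`
#'   (`1` peak, `-1` trough).
#' @export
wave_windows <- function(subtype = c("ABR", "AMLR")) {
  subtype <- match.arg(subtype)
  if (subtype == "ABR") {
    tibble(wave = c("I", "III", "V"),
           start_ms = c(1.0, 3.0, 4.8), end_ms = c(2.5, 4.8, 7.5),
           polarity = c(1, 1, 1))
  } else {
    tibble(wave = c("Na", "Pa", "Nb", "Pb"),
           start_ms = c(12, 25, 35, 45), end_ms = c(25, 40, 52, 80),
           polarity = c(-1, 1, -1, 1))
  }
}

# strict local extrema of the requested polarity inside [lo, hi] (1-based
# sample indices); plateau ties resolve to the earliest sample
find_extremum <- function(x, lo, hi, polarity) {
  n <- length(x)
  lo <- max(lo, 2L); hi <- min(hi, n - 1L)
  if (lo > hi) return(NA_integer_)
  idx <- lo:hi
  v <- polarity * x
  is_ext <- v[idx] > v[idx - 1L] & v[idx] >= v[idx + 1L]
  cand <- idx[is_ext]
  if (!length(cand)) return(NA_integer_)
  cand[which.max(v[cand])]
}

annotate_one <- function(x, fs_hz, windows) {
  nw <- nrow(windows)
  latency <- rep(NA_real_, nw)
  amplitude <- rep(NA_real_, nw)
  prev_idx <- 0L
  for (k in seq_len(nw)) {
    lo <- as.integer(ceiling(windows$start_ms[k] / 1000 * fs_hz)) + 1L
    hi <- as.integer(floor(windows$end_ms[k] / 1000 * fs_hz)) + 1L
    lo <- max(lo, prev_idx + 1L)  # enforce canonical ordering greedily
    i <- find_extremum(x, lo, hi, windows$polarity[k])
    if (!is.na(i)) {
      prev_idx <- i
      latency[k] <- (i - 1L) / fs_hz * 1000
      amplitude[k] <- x[i]
    }
  }
  list(wave = windows$wave, latency_ms = latency, amplitude_uv = amplitude,
       found = !is.na(latency))
}

#' Annotate the waves of interest in AEP records
#'
#' Locates, per record, the extremum of the correct polarity inside each
#' wave's latency window. Latency is the extremum's sample index over the
#' sampling rate (0-based, ms); amplitude is the signed signal value at the
#' extremum in microvolts. A wave whose window contains no strict local
#' extremum of the right polarity is reported `found = FALSE` with `NA`
#' metrics. Canonical ordering (I < III < V; Na < Pa < Nb < Pb) is enforced
#' by a greedy left-to-right search: each window is additionally truncated
#' to start after the previously found wave.
#'
#' @param records Record tibble (see [aep_record()]).
#' @param windows Optional window tibble as from [wave_windows()]; default
#'   chosen per record subtype. Windows must lie inside the analysis time.
#' @param smooth Apply zero-phase Gaussian low-pass smoothing before
#'   detection (off by default; metrics are still read from the smoothed
#'   series when enabled).
#' @param smooth_sd_ms Standard deviation of the smoothing kernel in ms.
#' @return Tibble with one row per record and wave: `record_id`,
#'   `patient_id`, `ear`, `subtype`, `wave`, `latency_ms`, `amplitude_uv`,
#'   `found`.
#' @export
annotate_records <- function(records, windows = NULL, smooth = FALSE,
                             smooth_sd_ms = 0.1) {
  validate_aep_records(records, notify_deviations = FALSE)
  default_w <- list(ABR = wave_windows("ABR"), AMLR = wave_windows("AMLR"))
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    sub <- records$subtype[i]
    w <- windows %||% default_w[[sub]]
    dur <- length(records$samples[[i]]) / records$fs_hz[i] * 1000
    if (any(w$end_ms > dur)) {
      abort(paste0("record ", records$record_id[i], ": search window ends at ",
                   max(w$end_ms), " ms but the analysis time is ",
                   round(dur, 2), " ms (unit mismatch?)"))
    }
    x <- records$samples[[i]]
    if (smooth) x <- gaussian_smooth(x, records$fs_hz[i], smooth_sd_ms)
    annotate_one(x, records$fs_hz[i], w)
  })
  nw <- lengths(purrr::map(out, "wave"))
  tibble(
    record_id = rep(records$record_id, nw),
    patient_id = rep(records$patient_id, nw),
    ear = rep(records$ear, nw),
    subtype = rep(records$subtype, nw),
    wave = unlist(purrr::map(out, "wave")),
    latency_ms = unlist(purrr::map(out, "latency_ms")),
    amplitude_uv = unlist(purrr::map(out, "amplitude_uv")),
    found = unlist(purrr::map(out, "found"))
  )
}

# zero-phase FIR smoothing with a truncated Gaussian kernel
gaussian_smooth <- function(x, fs_hz, sd_ms) {
  sd_samp <- sd_ms / 1000 * fs_hz
  if (sd_samp < 0.25) return(x)
  half <- max(1L, ceiling(3 * sd_samp))
  k <- exp(-((-half):half)^2 / (2 * sd_samp^2))
  k <- k / sum(k)
  n <- length(x)
  xp <- x[reflect_index(seq(1 - half, n + half), n)]
  as.numeric(stats::filter(xp, k, sides = 2))[half + seq_len(n)]
}

#' Long-format table of latency/amplitude metrics
#'
#' One row per record, wave and metric (`latency`, `amplitude`). Waves not
#' found carry an explicit `NA` value (never zero) with `found = FALSE`.
#'
#' @param annotations Output of [annotate_records()], from records of a
#'   single subtype per call.
#' @return Tibble with columns `record_id`, `patient_id`, `ear`, `subtype`,
#'   `wave`, `metric`, `value`, `found`.
#' @export
metrics_table <- function(annotations) {
  if (!nrow(annotations)) {
    return(tibble(record_id = character(), patient_id = character(),
                  ear = character(), subtype = character(),
                  wave = character(), metric = character(),
                  value = numeric(), found = logical()))
  }
  dup <- annotations %>%
    count(.data$record_id, .data$wave) %>%
    filter(n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate (record_id, wave) pairs in annotations: ",
                 paste(head(unique(dup$record_id), 5), collapse = ", ")))
  }
  annotations %>%
    tidyr::pivot_longer(cols = c("latency_ms", "amplitude_uv"),
                        names_to = "metric", values_to = "value") %>%
    mutate(metric = ifelse(.data$metric == "latency_ms",
                           "latency", "amplitude")) %>%
    select("record_id", "patient_id", "ear", "subtype", "wave",
           "metric", "value", "found")
}
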