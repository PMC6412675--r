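# SignalTrace container and delimited-text I/O for traces, events files and
# CRF parameter configs.

#' Uniformly sampled physiological time series
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling rate in Hz (> 0).
#' @param modality `"fIRI"` (thermal ROI average) or `"SCR"` (phasic skin
#'   conductance).
#' @param units Free-text units, e.g. `"degC"`, `"uS"`, `"z"`.
#' @param meta Named list of labels (subject, session, ...).
#'
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, rate, modality = c("fIRI", "SCR"),
                         units = "a.u.", meta = list()) {
  modality <- match.arg(modality)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite numeric", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate),
                 modality = modality, units = units, meta = meta),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat("<signal_trace> ", x$modality, ":", length(x$samples), "samples at",
      x$rate, "Hz (", format(length(x$samples) / x$rate), "s ),", x$units, "\n")
  invisible(x)
}

#' Read and write trace files
#'
#' Traces are stored as plain text: comment headers (`# key: value`)
#' carrying `rate`, `modality` and `units`, followed by one sample value
#' per line printed with 17 significant digits, so a write/read round trip
#' reproduces the samples exactly.
#'
#' @param path File path.
#' @param trace A [signal_trace()].
#' @return `read_trace` returns a [signal_trace()]; `write_trace` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- .parse_header(lines[is_hdr])
  if (is.null(hdr$rate))
    stop("trace file ", path, " has no `# rate:` header", call. = FALSE)
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1L]
    stop("non-numeric value at data line ", bad, " of ", path, call. = FALSE)
  }
  signal_trace(samples, rate = as.numeric(hdr$rate),
               modality = hdr$modality %||% "fIRI",
               units = hdr$units %||% "a.u.",
               meta = hdr[setdiff(names(hdr), c("rate", "modality", "units"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_header <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) out[[trimws(m[2L])]] <- trimws(m[3L])
  }
  out
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  hdr <- c(sprintf("# rate: %.17g", trace$rate),
           paste0("# modality: ", trace$modality),
           paste0("# units: ", trace$units))
  if (length(trace$meta))
    hdr <- c(hdr, sprintf("# %s: %s", names(trace$meta),
                          vapply(trace$meta, as.character, "")))
  writeLines(c(hdr, sprintf("%.17g", trace$samples)), path)
  invisible(path)
}

#' Read and write events files
#'
#' Tab-separated events files in a BIDS `events.tsv`-compatible dialect,
#' with header columns `onset`, `duration`, `trial_id`, `condition`,
#' `isi`, `position` (onset and duration in seconds; `n/a` for missing
#' values). Extra columns are tolerated on read with a warning. Onset
#' monotonicity is validated.
#'
#' @param path File path.
#' @param schedule An `event_schedule`.
#' @param rest_duration,lead_in Paradigm timing attributes to attach on
#'   read (seconds); stored as comment-free columns are not part of the
#'   dialect, so they must be re-supplied if non-default.
#' @return `read_events` returns an `event_schedule`; `write_events`
#'   returns `path` invisibly.
#' @export
read_events <- function(path, rest_duration = 120, lead_in = 10) {
  df <- utils::read.delim(path, na.strings = c("n/a", "NA"),
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_id", "condition", "isi", "position")
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
    df <- df[need[need %in% names(df)]]
  }
  .validate_schedule_events(df)
  df$isi <- as.numeric(df$isi)
  last <- df[!duplicated(df$trial_id, fromLast = TRUE), ]
  total <- max(last$onset + last$duration) + 40
  .new_event_schedule(df, rest_duration = rest_duration, lead_in = lead_in,
                      total_duration = total)
}

#' @rdname read_events
#' @export
write_events <- function(schedule, path) {
  df <- as.data.frame(schedule)
  .validate_schedule_events(df)
  out <- df
  out$onset <- sprintf("%.17g", df$onset)
  out$duration <- sprintf("%.17g", df$duration)
  out$isi <- ifelse(is.na(df$isi), "n/a", sprintf("%.17g", df$isi))
  out$position <- ifelse(is.na(df$position), "n/a", df$position)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write CRF parameter configs
#'
#' Flat YAML key-value blocks with fields `tau`, `sigma`, `lambda1`,
#' `lambda2`, `sign`.
#'
#' @param path File path.
#' @param params A [crf_params()].
#' @return `read_crf_config` returns a [crf_params()]; `write_crf_config`
#'   returns `path` invisibly.
#' @export
read_crf_config <- function(path) {
  v <- yaml::read_yaml(path)
  crf_params(tau = v$tau, sigma = v$sigma, lambda1 = v$lambda1,
             lambda2 = v$lambda2, sign = v$sign %||% -1)
}

#' @rdname read_crf_config
#' @export
write_crf_config <- function(params, path) {
  stopifnot(inherits(params, "crf_params"))
  yaml::write_yaml(unclass(params), path, precision = 17)
  invisible(path)
}
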