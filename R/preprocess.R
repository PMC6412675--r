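# Preprocessing: zero-phase Butterworth filtering, decimation,
# standardization, and tracking-artifact correction.
#
# Recommended order -- fIRI: lowpass -> correct_artifacts -> ztransform
# (filtering and sample substitution on the raw scale, standardization
# last); SCR (phasic input): bandpass -> downsample -> ztransform.

# Forward-backward filtering, zero-phase by construction. Edge transients
# are controlled by (a) removing the mean before filtering (the filter
# state starts at zero, so any DC offset would otherwise ring through the
# slowest pole) and (b) odd-reflection padding long enough for the
# slowest pole to settle -- the settling scale is rate / lowest critical
# frequency. `filt` is a filter object from signal::butter; the design
# order names the one-pass filter, and the forward-backward cascade
# doubles the magnitude rolloff.
.zero_phase <- function(filt, x, rate, f_low, add_mean = TRUE) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(4 * rate / f_low)))
  m <- mean(x)
  xd <- x - m
  front <- 2 * xd[1L] - xd[seq(pad + 1L, 2L)]
  back <- 2 * xd[n] - xd[seq(n - 1L, n - pad)]
  xx <- c(front, xd, back)
  y <- signal::filter(filt, xx)
  y <- rev(signal::filter(filt, rev(y)))
  out <- as.numeric(y[(pad + 1L):(pad + n)])
  if (add_mean) out + m else out
}

#' Zero-phase low-pass filter for thermal traces
#'
#' Third-order Butterworth low-pass (0.4 Hz cutoff by default), applied
#' forward and backward so the net phase response is zero: stimulus-locked
#' features are not delayed by filtering.
#'
#' @param trace A [signal_trace()] with modality `"fIRI"`.
#' @param cutoff Cutoff frequency in Hz.
#' @param order Butterworth design order of the single pass.
#'
#' @return The filtered [signal_trace()] (same length and rate).
#' @export
lowpass_firi <- function(trace, cutoff = 0.4, order = 3) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$modality != "fIRI")
    stop("lowpass_firi expects an fIRI trace", call. = FALSE)
  if (cutoff >= trace$rate / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         trace$rate / 2, " Hz)", call. = FALSE)
  bf <- signal::butter(order, cutoff / (trace$rate / 2), type = "low")
  trace$samples <- .zero_phase(bf, trace$samples, trace$rate, cutoff)
  trace
}

#' Zero-phase band-pass filter for skin conductance
#'
#' Third-order Butterworth band-pass (0.01-5 Hz by default) applied
#' forward-backward; removes the DC level and out-of-band drift while
#' preserving phasic response timing.
#'
#' @param trace A [signal_trace()] with modality `"SCR"`.
#' @param band Two-element vector of band edges in Hz.
#' @param order Butterworth design order of the single pass.
#'
#' @return The filtered [signal_trace()] (same length and rate).
#' @export
bandpass_scr <- function(trace, band = c(0.01, 5), order = 3) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$modality != "SCR")
    stop("bandpass_scr expects an SCR trace", call. = FALSE)
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L])
    stop("`band` must be increasing positive edges", call. = FALSE)
  if (band[2L] >= trace$rate / 2)
    stop("upper band edge (", band[2L], " Hz) must be below the Nyquist ",
         "frequency (", trace$rate / 2, " Hz)", call. = FALSE)
  bf <- signal::butter(order, band / (trace$rate / 2), type = "pass")
  trace$samples <- .zero_phase(bf, trace$samples, trace$rate, band[1L],
                               add_mean = FALSE)
  trace
}

#' Down-sample a trace by decimation
#'
#' Keeps every `rate/target`-th sample starting from the first. The caller
#' is responsible for prior anti-alias filtering (for SCR, the 5 Hz upper
#' band edge of [bandpass_scr()] is at or below the 10 Hz target Nyquist).
#'
#' @param trace A [signal_trace()].
#' @param target Target rate in Hz; `rate/target` must be an integer.
#'
#' @return The decimated [signal_trace()] with updated rate.
#' @export
downsample <- function(trace, target = 10) {
  stopifnot(inherits(trace, "signal_trace"))
  k <- trace$rate / target
  if (abs(k - round(k)) > 1e-9)
    stop("rate (", trace$rate, " Hz) is not an integer multiple of the ",
         "target (", target, " Hz)", call. = FALSE)
  k <- as.integer(round(k))
  trace$samples <- trace$samples[seq(1L, length(trace$samples), by = k)]
  trace$rate <- target
  trace
}

#' Z-transform a trace
#'
#' Subtracts the mean and divides by the standard deviation, so the output
#' has mean 0 and SD 1; used to remove between-subject amplitude scale.
#'
#' @param trace A [signal_trace()] with non-constant samples.
#' @return The standardized [signal_trace()], units `"z"`.
#' @export
ztransform <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  s <- stats::sd(trace$samples)
  if (!is.finite(s) || s == 0)
    stop("cannot z-transform a constant trace", call. = FALSE)
  trace$samples <- (trace$samples - mean(trace$samples)) / s
  trace$units <- "z"
  trace
}

#' Substitute artifact-contaminated samples
#'
#' Every sample inside each bad interval is replaced by the mean of the 6
#' clean samples immediately preceding and the 6 immediately following the
#' interval (12 samples in total). Samples inside any other bad interval do
#' not count as clean. When an interval abuts a trace boundary, the
#' available side alone is used.
#'
#' @param trace A [signal_trace()].
#' @param bad_intervals List of two-element integer vectors
#'   `c(first, last)` (1-based sample indices, inclusive), or a two-column
#'   matrix of the same.
#' @param n_context Clean samples used on each side (default 6).
#'
#' @return The corrected [signal_trace()].
#' @export
correct_artifacts <- function(trace, bad_intervals, n_context = 6) {
  stopifnot(inherits(trace, "signal_trace"))
  if (is.matrix(bad_intervals))
    bad_intervals <- lapply(seq_len(nrow(bad_intervals)),
                            function(i) bad_intervals[i, ])
  if (!length(bad_intervals)) return(trace)
  x <- trace$samples
  n <- length(x)
  is_bad <- rep(FALSE, n)
  for (sp in bad_intervals) {
    if (length(sp) != 2L || sp[1L] < 1L || sp[2L] > n || sp[1L] > sp[2L])
      stop("invalid bad interval: ", paste(sp, collapse = "-"), call. = FALSE)
    is_bad[sp[1L]:sp[2L]] <- TRUE
  }
  if (all(is_bad))
    stop("bad intervals cover the whole trace; nothing clean to use",
         call. = FALSE)
  clean_idx <- which(!is_bad)
  for (sp in bad_intervals) {
    before <- rev(clean_idx[clean_idx < sp[1L]])
    after <- clean_idx[clean_idx > sp[2L]]
    ctx <- c(utils::head(before, n_context), utils::head(after, n_context))
    if (!length(ctx))
      stop("no clean context samples around interval ",
           paste(sp, collapse = "-"), call. = FALSE)
    x[sp[1L]:sp[2L]] <- mean(trace$samples[ctx])
  }
  trace$samples <- x
  trace
}

#' Flag tracking-failure intervals by rolling variance
#'
#' ROI-tracking failures show up as bursts of large variance in the
#' extracted trace. This automated surrogate for visual inspection flags
#' windows whose rolling variance exceeds `z_threshold` robust standard
#' scores (median/MAD) above the trace's median rolling variance, and
#' merges overlapping flagged windows into intervals.
#'
#' @param trace A [signal_trace()].
#' @param window Rolling-window length in samples (>= 2).
#' @param z_threshold Robust z-score threshold.
#'
#' @return A list of `c(first, last)` sample intervals; empty for clean
#'   traces.
#' @export
flag_tracking_failures <- function(trace, window = 10, z_threshold = 5) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$samples
  n <- length(x)
  if (window < 2L) stop("`window` must be >= 2", call. = FALSE)
  if (window > n) stop("`window` exceeds the trace length", call. = FALSE)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  i <- seq_len(n - window + 1L)
  s1 <- cs[i + window] - cs[i]
  s2 <- cs2[i + window] - cs2[i]
  rv <- (s2 - s1^2 / window) / (window - 1L)
  med <- stats::median(rv)
  scale <- stats::mad(rv)
  if (scale == 0) scale <- stats::sd(rv)
  if (!is.finite(scale) || scale == 0) return(list())
  hot <- which((rv - med) / scale > z_threshold)
  if (!length(hot)) return(list())
  flagged <- rep(FALSE, n)
  for (j in hot) flagged[j:(j + window - 1L)] <- TRUE
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- Map(c, starts[r$values], ends[r$values])
  unname(spans)
}

#' Apply the analysis low-pass filter to a sampled kernel
#'
#' Passes a response kernel through the same zero-phase Butterworth
#' low-pass used on the recordings, so that model kernels live in the
#' same band as filtered data (e.g. when predicting carryover in
#' filtered traces). The kernel is zero-padded before filtering and
#' re-normalized to unit peak magnitude.
#'
#' @param kernel A [sampled_kernel()].
#' @param cutoff,order Filter settings as in [lowpass_firi()].
#' @return The filtered, normalized [sampled_kernel()].
#' @export
filter_kernel <- function(kernel, cutoff = 0.4, order = 3) {
  stopifnot(inherits(kernel, "sampled_kernel"))
  rate <- 1 / kernel$dt
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  pad <- as.integer(round(10 / kernel$dt))
  v <- .zero_phase(bf, c(numeric(pad), kernel$values, numeric(pad)),
                   rate, cutoff)
  normalize_kernel(sampled_kernel(v[(pad + 1L):(pad + length(kernel$values))],
                                  dt = kernel$dt, t0 = kernel$t0))
}

#' Standard preprocessing pipelines
#'
#' `preprocess_firi()` applies low-pass filtering, artifact correction
#' (intervals auto-detected via [flag_tracking_failures()] when not
#' supplied), and z-transformation, in that order. `preprocess_scr()`
#' applies band-pass filtering, decimation to the target rate, and
#' z-transformation.
#'
#' @param trace A [signal_trace()].
#' @param bad_intervals Optional list of artifact intervals; `NULL`
#'   auto-detects.
#' @param cutoff,band,order Filter settings (see [lowpass_firi()],
#'   [bandpass_scr()]).
#' @param target Target rate for SCR decimation (Hz).
#' @return A preprocessed [signal_trace()] in z-units.
#' @export
preprocess_firi <- function(trace, bad_intervals = NULL, cutoff = 0.4,
                            order = 3) {
  out <- lowpass_firi(trace, cutoff = cutoff, order = order)
  if (is.null(bad_intervals)) bad_intervals <- flag_tracking_failures(out)
  out <- correct_artifacts(out, bad_intervals)
  ztransform(out)
}

#' @rdname preprocess_firi
#' @export
preprocess_scr <- function(trace, band = c(0.01, 5), order = 3, target = 10) {
  out <- bandpass_scr(trace, band = band, order = order)
  if (out$rate != target) out <- downsample(out, target)
  ztransform(out)
}
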