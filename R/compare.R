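# Head-to-head agreement of GLM-fIRI and GLM-SCR on paired recordings.

#' Run paired GLM inference on fIRI and SCR channels
#'
#' For each trial, analyses the 30 s window starting at the trial's first
#' stimulus with modality-specific designs: the thermal CRF convolved with
#' the trial's stimulus sticks for the fIRI channel, and the
#' skin-conductance CRF for the SCR channel (double trials get two
#' predictors and are analysed jointly). Detections are reported per
#' event predictor by default; `aggregate = "trial"` instead calls a trial
#' detected when any of its event predictors is significant.
#'
#' @param firi,scr Preprocessed [signal_trace()] objects on the same
#'   clock and rate.
#' @param schedule An `event_schedule` covering both traces.
#' @param firi_crf,scr_crf [crf_params()] for each modality (defaults:
#'   [firi_crf_default()], [scr_crf_default()]).
#' @param alpha Significance level.
#' @param window Analysis-window length in seconds.
#' @param fwhm Smoothness width for [effective_df()]: numeric or
#'   `"estimate"` (per window and channel).
#' @param aggregate `"event"` (default) or `"trial"` accounting.
#' @param carryover `"canonical"` (default) adds a nuisance regressor per
#'   window modelling the response tails of preceding trials (predicted
#'   from each channel's CRF); `"none"` disables it.
#'
#' @return A data frame with one row per event (or trial): `trial_id`,
#'   `condition`, `isi`, `position`, weights, p-values and logical
#'   `firi_detected`, `scr_detected`.
#' @export
run_dual_glm <- function(firi, scr, schedule,
                         firi_crf = firi_crf_default(),
                         scr_crf = scr_crf_default(),
                         alpha = 0.05, window = 30, fwhm = "estimate",
                         aggregate = c("event", "trial"),
                         carryover = c("canonical", "none")) {
  aggregate <- match.arg(aggregate)
  carryover <- match.arg(carryover)
  stopifnot(inherits(firi, "signal_trace"), inherits(scr, "signal_trace"))
  if (abs(firi$rate - scr$rate) > 1e-9)
    stop("fIRI and SCR traces must share a sampling rate", call. = FALSE)
  if (length(firi$samples) != length(scr$samples))
    stop("fIRI and SCR traces are misaligned (different lengths)",
         call. = FALSE)
  rate <- firi$rate
  n_samp <- as.integer(round(window * rate))
  kf <- normalize_kernel(discretize_crf(firi_crf, rate = rate,
                                        support = max(window, 90)))
  ks <- normalize_kernel(discretize_crf(scr_crf, rate = rate,
                                        support = max(window, 90)))
  ev <- as.data.frame(schedule)
  rows <- list()
  for (tr in unique(ev$trial_id)) {
    tev <- ev[ev$trial_id == tr, ]
    t0 <- min(tev$onset)
    start <- round(t0 * rate) + 1L
    if (start + n_samp - 1L > length(firi$samples))
      stop("analysis window for trial ", tr, " overruns the traces",
           call. = FALSE)
    idx <- start:(start + n_samp - 1L)
    sticks <- stick_function(tev, rate, n_samp, t0 = t0, split_events = TRUE)
    Xf <- build_design(sticks, kf, rate = rate)$X
    Xs <- build_design(sticks, ks, rate = rate)$X
    ne <- nrow(tev)
    if (carryover == "canonical") {
      ccf <- .carry_curve(ev, t0, n_samp, kf, rate)
      ccs <- .carry_curve(ev, t0, n_samp, ks, rate)
      if (any(ccf != 0))
        Xf <- cbind(Xf[, seq_len(ne), drop = FALSE], carry = ccf,
                    intercept = 1)
      if (any(ccs != 0))
        Xs <- cbind(Xs[, seq_len(ne), drop = FALSE], carry = ccs,
                    intercept = 1)
    }
    inf_f <- .window_inference(firi$samples[idx], Xf,
                               alpha = alpha, fwhm = fwhm)
    inf_s <- .window_inference(scr$samples[idx], Xs,
                               alpha = alpha, fwhm = fwhm)
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = tr, condition = tev$condition,
      isi = tev$isi, position = tev$position,
      firi_beta = inf_f$beta[seq_len(ne)], scr_beta = inf_s$beta[seq_len(ne)],
      firi_p = inf_f$p_value[seq_len(ne)], scr_p = inf_s$p_value[seq_len(ne)],
      firi_detected = inf_f$detected[seq_len(ne)],
      scr_detected = inf_s$detected[seq_len(ne)])
  }
  det <- do.call(rbind, rows)
  rownames(det) <- NULL
  if (aggregate == "trial") {
    det <- do.call(rbind, lapply(split(det, det$trial_id), function(d) {
      data.frame(trial_id = d$trial_id[1L], condition = d$condition[1L],
                 isi = d$isi[1L], position = NA_character_,
                 firi_beta = NA_real_, scr_beta = NA_real_,
                 firi_p = min(d$firi_p), scr_p = min(d$scr_p),
                 firi_detected = any(d$firi_detected),
                 scr_detected = any(d$scr_detected))
    }))
    det <- det[order(det$trial_id), ]
    rownames(det) <- NULL
  }
  det
}

#' Cross-tabulate paired detections against the reference channel
#'
#' Builds the 2 x 2 confusion matrix of test-channel detections (GLM-fIRI)
#' against reference-channel detections (GLM-SCR, treated as the gold
#' standard).
#'
#' @param detections Data frame from [run_dual_glm()], or any data frame
#'   with logical columns named by `test` and `reference`.
#' @param test,reference Column names of the test and reference detection
#'   flags.
#'
#' @return An object of class `confusion_counts`: list with `tn`, `fp`,
#'   `fn`, `tp` and `row_totals` (reference-negative, reference-positive).
#' @export
confusion_matrix <- function(detections, test = "firi_detected",
                             reference = "scr_detected") {
  if (!nrow(detections)) stop("no detections to tabulate", call. = FALSE)
  tv <- as.logical(detections[[test]])
  rv <- as.logical(detections[[reference]])
  counts <- list(tn = sum(!rv & !tv), fp = sum(!rv & tv),
                 fn = sum(rv & !tv), tp = sum(rv & tv))
  counts$row_totals <- c(reference_negative = counts$tn + counts$fp,
                         reference_positive = counts$fn + counts$tp)
  structure(counts, class = "confusion_counts")
}

#' Construct confusion counts directly
#'
#' @param tn,fp,fn,tp Nonnegative integer cell counts (reference on rows:
#'   negatives split into `tn`/`fp`, positives into `fn`/`tp`).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tn, fp, fn, tp) {
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp,
                 row_totals = c(reference_negative = tn + fp,
                                reference_positive = fn + tp)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), nrow = 2, byrow = TRUE,
              dimnames = list(reference = c("0", "1"), test = c("0", "1")))
  cat("<confusion_counts> (rows: reference, cols: test)\n")
  print(m)
  invisible(x)
}

#' Sensitivity and specificity of the test channel
#'
#' `sensitivity = 100 * tp / (fn + tp)` and
#' `specificity = 100 * tn / (tn + fp)` as percentages, with their
#' complements (false-negative and false-positive percentages). Full
#' precision is retained; the print method rounds to one decimal for
#' display.
#'
#' @param counts A `confusion_counts` object.
#' @return An object of class `agreement_stats`: list with `sensitivity`,
#'   `specificity`, `false_negative_pct`, `false_positive_pct` (all in
#'   percent).
#' @export
#' @examples
#' sensitivity_specificity(confusion_counts(tn = 771, fp = 244,
#'                                          fn = 150, tp = 955))
sensitivity_specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$fn + counts$tp == 0)
    stop("reference-positive row is empty; sensitivity undefined",
         call. = FALSE)
  if (counts$tn + counts$fp == 0)
    stop("reference-negative row is empty; specificity undefined",
         call. = FALSE)
  sens <- 100 * counts$tp / (counts$fn + counts$tp)
  spec <- 100 * counts$tn / (counts$tn + counts$fp)
  structure(list(sensitivity = sens, specificity = spec,
                 false_negative_pct = 100 - sens,
                 false_positive_pct = 100 - spec),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  (FN %.1f%%, FP %.1f%%)\n",
              x$sensitivity, x$specificity,
              x$false_negative_pct, x$false_positive_pct))
  invisible(x)
}
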