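# Event-related stimulation paradigm: schedule generation, stick functions,
# design matrices, and post-stimulus epoch extraction.

#' Paradigm configuration
#'
#' Describes the event-related white-noise stimulation design: single-
#' stimulus trials and double-stimulus trials at three inter-stimulus
#' intervals (ISIs), separated by randomized inter-trial silences, after an
#' initial rest recording and a short lead-in silence.
#'
#' @param n_single Number of single-stimulus trials.
#' @param n_double_per_isi Number of double-stimulus trials per ISI.
#' @param isis Inter-stimulus intervals in seconds for double trials.
#' @param silences Candidate inter-trial silence durations in seconds
#'   (after the last stimulus of each trial).
#' @param lead_in Silence before the first trial, seconds.
#' @param rest Initial rest-period duration, seconds.
#' @param stim_duration Stimulus duration in seconds.
#' @param balanced_silences If `TRUE`, silence durations are balanced
#'   across trials (as equal as counts allow) before shuffling; the
#'   default draws them independently and uniformly.
#'
#' @return A list of class `paradigm_config`.
#' @export
paradigm_config <- function(n_single = 8, n_double_per_isi = 8,
                            isis = c(2, 5.5, 9), silences = c(30, 35, 40),
                            lead_in = 10, rest = 120, stim_duration = 1,
                            balanced_silences = FALSE) {
  if (length(isis) < 1L) stop("`isis` must be non-empty", call. = FALSE)
  if (n_single < 0 || n_double_per_isi <= 0)
    stop("trial counts must be positive", call. = FALSE)
  if (any(silences <= 0) || lead_in < 0 || rest < 0 || stim_duration <= 0)
    stop("durations must be positive", call. = FALSE)
  structure(list(n_single = n_single, n_double_per_isi = n_double_per_isi,
                 isis = isis, silences = silences, lead_in = lead_in,
                 rest = rest, stim_duration = stim_duration,
                 balanced_silences = balanced_silences),
            class = "paradigm_config")
}

# Run `code` under `seed` without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.new_event_schedule <- function(events, rest_duration, lead_in, total_duration) {
  structure(events,
            rest_duration = rest_duration, lead_in = lead_in,
            total_duration = total_duration,
            class = c("event_schedule", "data.frame"))
}

.validate_schedule_events <- function(events) {
  need <- c("onset", "duration", "trial_id", "condition", "isi", "position")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(events$onset, strictly = TRUE))
    stop("event onsets must be strictly increasing", call. = FALSE)
  invisible(events)
}

#' Generate an event-related stimulation schedule
#'
#' Builds a randomized trial sequence honouring the paradigm constraints:
#' the first stimulus occurs at `rest + lead_in` seconds; within a double
#' trial the second stimulus onset equals the first onset plus the trial's
#' ISI; and the last stimulus of every trial is followed by a randomized
#' silence (30/35/40 s by default) before the next trial. Trial order and
#' silence durations are drawn from the supplied seed, so the schedule is
#' a pure function of `(config, seed)`.
#'
#' @param config A [paradigm_config()].
#' @param seed Integer seed fixing trial order and silence randomization.
#'
#' @return An `event_schedule`: a data frame with columns `onset`,
#'   `duration`, `trial_id`, `condition` (`"single"`/`"double"`), `isi`
#'   (`NA` for single trials) and `position` (`"first"`/`"second"`, `NA`
#'   for single trials), plus attributes `rest_duration`, `lead_in` and
#'   `total_duration`.
#' @export
#' @examples
#' sch <- build_paradigm(paradigm_config(), seed = 1)
#' table(sch$condition) / c(1, 2)  # 8 single trials, 24 double trials
build_paradigm <- function(config = paradigm_config(), seed = 1) {
  stopifnot(inherits(config, "paradigm_config"))
  trials <- data.frame(
    condition = c(rep("single", config$n_single),
                  rep("double", config$n_double_per_isi * length(config$isis))),
    isi = c(rep(NA_real_, config$n_single),
            rep(config$isis, each = config$n_double_per_isi))
  )
  n_trials <- nrow(trials)
  .with_seed(seed, {
    trials <- trials[sample.int(n_trials), , drop = FALSE]
    if (config$balanced_silences) {
      sil <- rep_len(config$silences, n_trials)
      sil <- sample(sil)
    } else {
      sil <- sample(config$silences, n_trials, replace = TRUE)
    }
  })
  onset <- config$rest + config$lead_in
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    if (trials$condition[i] == "single") {
      rows[[i]] <- data.frame(onset = onset, duration = config$stim_duration,
                              trial_id = i, condition = "single",
                              isi = NA_real_, position = NA_character_)
      last_onset <- onset
    } else {
      rows[[i]] <- data.frame(onset = c(onset, onset + trials$isi[i]),
                              duration = config$stim_duration, trial_id = i,
                              condition = "double", isi = trials$isi[i],
                              position = c("first", "second"))
      last_onset <- onset + trials$isi[i]
    }
    onset <- last_onset + config$stim_duration + sil[i]
  }
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  .validate_schedule_events(events)
  .new_event_schedule(events,
                      rest_duration = config$rest, lead_in = config$lead_in,
                      total_duration = onset)
}

#' @export
print.event_schedule <- function(x, ...) {
  n_trials <- length(unique(x$trial_id))
  cat("<event_schedule> ", nrow(x), "events in", n_trials, "trials;",
      "rest", attr(x, "rest_duration"), "s; total",
      format(attr(x, "total_duration")), "s\n")
  invisible(x)
}

# Select rows of a schedule/events table by condition and/or position.
.select_events <- function(events, condition = NULL, position = NULL) {
  keep <- rep(TRUE, nrow(events))
  if (!is.null(condition)) keep <- keep & events$condition %in% condition
  if (!is.null(position)) keep <- keep & !is.na(events$position) &
      events$position %in% position
  events[keep, , drop = FALSE]
}

#' Impulse ("stick") trains from an event schedule
#'
#' For each selected event, places a unit impulse at the sample nearest the
#' event onset (relative to `t0`). The stimulus is treated as punctate: its
#' 1 s duration is far below the response time scale, so sticks are
#' single-sample impulses, not boxcars.
#'
#' @param schedule An `event_schedule` or compatible events data frame.
#' @param rate Sampling rate in Hz.
#' @param n Length of the output series in samples.
#' @param condition,position Optional filters on the events used.
#' @param t0 Time (seconds) of the first output sample on the schedule
#'   clock; onsets are mapped to samples relative to this origin.
#' @param split_events If `TRUE`, return a matrix with one impulse train
#'   per selected event (columns named `ev<k>`); otherwise a single train
#'   summing all selected impulses.
#'
#' @return A numeric vector of length `n`, or an `n` x k matrix.
#' @export
stick_function <- function(schedule, rate, n, condition = NULL,
                           position = NULL, t0 = 0, split_events = FALSE) {
  ev <- .select_events(as.data.frame(schedule), condition, position)
  idx <- round((ev$onset - t0) * rate) + 1L
  bad <- idx < 1L | idx > n
  if (any(bad))
    stop("event onset(s) at ", paste(ev$onset[bad], collapse = ", "),
         " s fall outside the ", n, "-sample series", call. = FALSE)
  if (split_events) {
    out <- matrix(0, nrow = n, ncol = length(idx))
    colnames(out) <- paste0("ev", seq_along(idx))
    for (k in seq_along(idx)) out[idx[k], k] <- 1
    out
  } else {
    out <- numeric(n)
    for (i in idx) out[i] <- out[i] + 1
    out
  }
}

#' Build a GLM design matrix by stick-kernel convolution
#'
#' Each predictor column is the discrete convolution of an impulse train
#' with the sampled response kernel, truncated to the series length; an
#' intercept column of ones is appended by default.
#'
#' @param sticks Impulse train vector or matrix (columns = predictors), as
#'   from [stick_function()].
#' @param kernel A [sampled_kernel()]; its `dt` must equal `1/rate`.
#' @param rate Sampling rate in Hz of the sticks.
#' @param intercept Append an intercept column? Default `TRUE`.
#'
#' @return An object of class `design_matrix`: a list with the numeric
#'   matrix `X` (`n` x p), `rate`, and `intercept` flag.
#' @export
build_design <- function(sticks, kernel, rate, intercept = TRUE) {
  stopifnot(inherits(kernel, "sampled_kernel"))
  if (abs(kernel$dt - 1 / rate) > 1e-9)
    stop("kernel dt (", kernel$dt, " s) does not match the stick sampling ",
         "rate (", rate, " Hz)", call. = FALSE)
  S <- as.matrix(sticks)
  n <- nrow(S)
  X <- apply(S, 2L, function(s) {
    full <- stats::convolve(s, rev(kernel$values), type = "open")
    full[seq_len(n)]
  })
  X <- matrix(X, nrow = n)
  colnames(X) <- colnames(S)
  if (is.null(colnames(X))) colnames(X) <- paste0("ev", seq_len(ncol(X)))
  if (intercept) X <- cbind(X, intercept = 1)
  if (any(!is.finite(X))) stop("non-finite values in design", call. = FALSE)
  structure(list(X = X, rate = rate, intercept = intercept),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), "samples x", ncol(x$X), "predictors (",
      paste(colnames(x$X), collapse = ", "), ") at", x$rate, "Hz\n")
  invisible(x)
}

#' Extract post-stimulus epochs from a trace
#'
#' Cuts the `window`-second segment starting at each selected event onset
#' (half-open `[onset, onset + window)`, onset sample included). For the
#' default 30 s window at 10 Hz each epoch has 300 samples. Epochs from
#' double trials contain the overlap of both events; no deconvolution is
#' attempted here (the GLM handles overlap).
#'
#' @param trace A [signal_trace()].
#' @param schedule An `event_schedule`.
#' @param window Epoch length in seconds (default 30).
#' @param condition,position Optional event filters (e.g. `condition =
#'   "single"` for single-stimulus thermal impulse responses).
#'
#' @return An object of class `epoch_set`: list with `epochs` (matrix,
#'   one row per event), `events` (the selected event metadata), `rate`.
#' @export
extract_epochs <- function(trace, schedule, window = 30,
                           condition = NULL, position = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  ev <- .select_events(as.data.frame(schedule), condition, position)
  if (nrow(ev) == 0L) stop("no events selected", call. = FALSE)
  w <- as.integer(round(window * trace$rate))
  start <- round(ev$onset * trace$rate) + 1L
  over <- start + w - 1L > length(trace$samples)
  if (any(over))
    stop("epoch window overruns the trace for event(s) at ",
         paste(ev$onset[over], collapse = ", "), " s", call. = FALSE)
  ep <- t(vapply(start, function(s) trace$samples[s:(s + w - 1L)],
                 numeric(w)))
  structure(list(epochs = ep, events = ev, rate = trace$rate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", nrow(x$epochs), "epochs x", ncol(x$epochs),
      "samples at", x$rate, "Hz\n")
  invisible(x)
}
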