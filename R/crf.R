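# Canonical response function (CRF): Gaussian-smoothed causal bi-exponential.
#
# The thermal impulse response to a brief sympathetic-activating stimulus is
# modelled as the convolution of a Gaussian N(t) (centre tau, spread sigma)
# with the sum of two causal exponentials exp(-lambda1 t) + exp(-lambda2 t)
# (zero for t < 0), times a polarity sign. The default polarity is -1: the
# nose-tip temperature *drops* on arousal.

#' Canonical response function parameters
#'
#' Container for the four shape parameters of the Gaussian-smoothed
#' bi-exponential canonical response function (CRF), plus a polarity sign.
#'
#' @param tau Gaussian centre in seconds; sets the event-to-peak time scale.
#' @param sigma Gaussian spread in seconds (> 0); sets the rise time.
#' @param lambda1,lambda2 Decay constants in 1/seconds (> 0) of the two
#'   causal exponentials.
#' @param sign Response polarity, `-1` (temperature decrease, the default)
#'   or `+1`.
#'
#' @return An object of class `crf_params`.
#' @seealso [evaluate_crf()], [discretize_crf()], [firi_crf_default()]
#' @export
#' @examples
#' crf_params(10.37, 6.76, 0.0765, 0.0994)
crf_params <- function(tau, sigma, lambda1, lambda2, sign = -1) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single strictly positive number", call. = FALSE)
  if (!is.numeric(lambda1) || length(lambda1) != 1L || !is.finite(lambda1) || lambda1 <= 0)
    stop("`lambda1` must be a single strictly positive number", call. = FALSE)
  if (!is.numeric(lambda2) || length(lambda2) != 1L || !is.finite(lambda2) || lambda2 <= 0)
    stop("`lambda2` must be a single strictly positive number", call. = FALSE)
  if (!sign %in% c(-1, 1))
    stop("`sign` must be -1 or +1", call. = FALSE)
  structure(
    list(tau = as.numeric(tau), sigma = as.numeric(sigma),
         lambda1 = as.numeric(lambda1), lambda2 = as.numeric(lambda2),
         sign = as.numeric(sign)),
    class = "crf_params"
  )
}

#' @export
print.crf_params <- function(x, ...) {
  cat("<crf_params>  tau =", format(x$tau), "s,  sigma =", format(x$sigma),
      "s,  lambda1 =", format(x$lambda1), "1/s,  lambda2 =",
      format(x$lambda2), "1/s,  sign =", x$sign, "\n")
  invisible(x)
}

#' Packaged default CRF parameter sets
#'
#' `firi_crf_default()` returns the fitted thermal (fIRI) CRF parameters
#' shipped with the package (tau = 10.3734 s, sigma = 6.7601 s,
#' lambda1 = 0.0765 1/s, lambda2 = 0.0994 1/s, negative polarity).
#' `scr_crf_default()` returns a *synthetic* stand-in for a skin-conductance
#' response function in the same Gaussian-smoothed bi-exponential family:
#' faster dynamics (peak within a few seconds) and positive polarity
#' (conductance rises on arousal). It is a configurable placeholder, not a
#' published electrodermal model; replace it with your own `crf_params`
#' when a validated SCR kernel is available.
#'
#' @return A [crf_params()] object.
#' @export
firi_crf_default <- function() {
  crf_params(tau = 10.3734, sigma = 6.7601,
             lambda1 = 0.0765, lambda2 = 0.0994, sign = -1)
}

#' @rdname firi_crf_default
#' @export
scr_crf_default <- function() {
  crf_params(tau = 2, sigma = 1.1, lambda1 = 0.25, lambda2 = 0.45, sign = 1)
}

# One Gaussian (x) causal-exponential term, closed form.
# g(t) = exp(l^2 s^2/2 - l mu) * erfc(b) / 2 with mu = t - tau,
# b = (l s^2 - mu) / (sqrt(2) s). Rewritten with the scaled complement
# erfcx(b) = exp(b^2) erfc(b), using a - b^2 = -mu^2/(2 s^2), which is
# numerically stable for all b except b << 0 where erfcx overflows; there
# erfc(b) -> 2 to within exp(-b^2) and g ~= exp(l^2 s^2/2 - l mu).
.exg_term <- function(t, tau, sigma, lambda) {
  mu <- t - tau
  b <- (lambda * sigma^2 - mu) / (sqrt(2) * sigma)
  out <- numeric(length(t))
  far <- b <= -25
  out[far] <- exp(lambda^2 * sigma^2 / 2 - lambda * mu[far])
  out[!far] <- 0.5 * pracma::erfcx(b[!far]) * exp(-mu[!far]^2 / (2 * sigma^2))
  out
}

#' Evaluate the canonical response function
#'
#' Closed-form evaluation of the Gaussian-smoothed causal bi-exponential:
#' `sign * [N (x) (E1 + E2)](t)`, where `N` is the Gaussian of centre
#' `tau` and spread `sigma`, and `E1`, `E2` are causal exponentials with
#' rates `lambda1`, `lambda2`. Each Gaussian-exponential convolution has an
#' analytic expression through the scaled complementary error function;
#' the implementation is overflow-safe over the whole parameter domain and
#' agrees with the quadrature oracle [crf_numeric_oracle()] to well below
#' 1e-6 relative error.
#'
#' @param params A [crf_params()] object.
#' @param times Numeric vector of evaluation times in seconds (relative to
#'   stimulus onset).
#'
#' @return Numeric vector of kernel amplitudes, one per time.
#' @export
#' @examples
#' h <- evaluate_crf(firi_crf_default(), seq(0, 60, by = 0.1))
evaluate_crf <- function(params, times) {
  stopifnot(inherits(params, "crf_params"))
  if (!is.numeric(times) || any(!is.finite(times)))
    stop("`times` must be finite numeric", call. = FALSE)
  params$sign * (.exg_term(times, params$tau, params$sigma, params$lambda1) +
                 .exg_term(times, params$tau, params$sigma, params$lambda2))
}

#' Quadrature reference for the canonical response function
#'
#' Brute-force trapezoid-rule evaluation of the defining convolution
#' integral, provided as an independent numerical reference for testing the
#' closed-form [evaluate_crf()]. The causal exponentials are tabulated on a
#' fine grid, end weights halved (trapezoid rule), and convolved with the
#' Gaussian via FFT; requested times are then linearly interpolated from
#' the fine output grid.
#'
#' @inheritParams evaluate_crf
#' @param integration_step Quadrature step in seconds; must be small
#'   relative to `sigma` (a warning is raised when `integration_step >
#'   sigma / 20`).
#' @param n_sigma Half-width of the tabulated Gaussian in units of `sigma`.
#'
#' @return Numeric vector of kernel amplitudes, one per time.
#' @export
crf_numeric_oracle <- function(params, times, integration_step = 1e-3,
                               n_sigma = 12) {
  stopifnot(inherits(params, "crf_params"))
  h <- integration_step
  if (h <= 0) stop("`integration_step` must be positive", call. = FALSE)
  if (h > params$sigma / 20)
    warning("integration step is coarse relative to sigma; ",
            "accuracy may be degraded")
  s_max <- max(max(times) - params$tau + n_sigma * params$sigma,
               n_sigma * params$sigma)
  sg <- seq(0, s_max, by = h)
  E <- exp(-params$lambda1 * sg) + exp(-params$lambda2 * sg)
  E[1L] <- E[1L] / 2
  E[length(E)] <- E[length(E)] / 2
  L <- ceiling(n_sigma * params$sigma / h) * h
  gg <- seq(-L, L, by = h)
  Ng <- stats::dnorm(gg, mean = 0, sd = params$sigma)
  nz <- length(E) + length(Ng) - 1L
  m <- stats::nextn(nz, c(2, 3, 5))
  z <- Re(stats::fft(stats::fft(c(E, rep(0, m - length(E)))) *
                     stats::fft(c(Ng, rep(0, m - length(Ng)))),
                     inverse = TRUE)) / m
  z <- z[seq_len(nz)]
  tk <- params$tau - L + (seq_len(nz) - 1L) * h
  vals <- stats::approx(tk, z * h, xout = times, rule = 2)$y
  params$sign * vals
}

#' Discretely sampled response kernel
#'
#' @param values Numeric vector of kernel amplitudes.
#' @param dt Seconds per sample.
#' @param t0 Time of the first sample relative to stimulus onset, seconds.
#'
#' @return An object of class `sampled_kernel`.
#' @export
sampled_kernel <- function(values, dt, t0 = 0) {
  stopifnot(is.numeric(values), length(values) >= 1L, all(is.finite(values)),
            is.numeric(dt), length(dt) == 1L, dt > 0)
  structure(list(values = as.numeric(values), dt = as.numeric(dt),
                 t0 = as.numeric(t0)),
            class = "sampled_kernel")
}

#' @export
print.sampled_kernel <- function(x, ...) {
  cat("<sampled_kernel> ", length(x$values), "samples, dt =", x$dt,
      "s, t0 =", x$t0, "s, peak |value| =", format(max(abs(x$values))), "\n")
  invisible(x)
}

#' Sample the CRF on a uniform grid
#'
#' Evaluates the CRF on `[0, support)` at `1/rate` spacing and truncates
#' trailing samples whose magnitude falls below `trunc_tol` times the peak
#' magnitude. The peak sample is always retained.
#'
#' @inheritParams evaluate_crf
#' @param rate Sampling rate in Hz.
#' @param support Kernel support in seconds; must exceed `tau` so the peak
#'   is representable. The default (90 s at 10 Hz) covers roughly three
#'   times the slowest default decay time constant past the Gaussian
#'   centre, i.e. >99.99% of the kernel energy.
#' @param trunc_tol Fraction of peak magnitude below which trailing samples
#'   are dropped; `0` keeps the full grid.
#'
#' @return A [sampled_kernel()] with `t0 = 0`.
#' @export
#' @examples
#' k <- discretize_crf(firi_crf_default(), rate = 10, support = 90)
discretize_crf <- function(params, rate = 10, support = 90, trunc_tol = 1e-6) {
  stopifnot(inherits(params, "crf_params"))
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive", call. = FALSE)
  if (support <= params$tau)
    stop("`support` (", support, " s) must exceed tau (", params$tau,
         " s): the kernel peak would be truncated", call. = FALSE)
  tgrid <- seq(0, support - 1 / rate, by = 1 / rate)
  v <- evaluate_crf(params, tgrid)
  if (trunc_tol > 0) {
    peak <- max(abs(v))
    keep_until <- max(which(abs(v) >= trunc_tol * peak))
    keep_until <- max(keep_until, which.max(abs(v)))
    v <- v[seq_len(keep_until)]
  }
  sampled_kernel(v, dt = 1 / rate, t0 = 0)
}

#' Normalize a sampled kernel to unit peak magnitude
#'
#' Divides the kernel by its maximum absolute value, so that
#' `max(abs(values)) == 1` while the polarity is preserved. Idempotent and
#' invariant to prior rescaling.
#'
#' @param kernel A [sampled_kernel()].
#' @return A [sampled_kernel()] with unit peak magnitude.
#' @export
normalize_kernel <- function(kernel) {
  stopifnot(inherits(kernel, "sampled_kernel"))
  peak <- max(abs(kernel$values))
  if (peak == 0) stop("cannot normalize an all-zero kernel", call. = FALSE)
  sampled_kernel(kernel$values / peak, dt = kernel$dt, t0 = kernel$t0)
}
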