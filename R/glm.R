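# Per-window general linear model: ordinary least squares, spectral
# smoothness (FWHM) estimation, effective degrees of freedom under
# autocorrelation, and t-inference on the predictor weights.

#' Ordinary least-squares fit of Y = X beta + e
#'
#' Fits the predictor weights by QR-based least squares and stores the
#' quantities inference needs (residual sum of squares, Gram-matrix
#' inverse). Errors on rank deficiency and length mismatch.
#'
#' @param y Numeric response series of length `n`.
#' @param design A [build_design()] object, or a plain numeric matrix with
#'   `n` rows.
#'
#' @return An object of class `glm_result` with elements `beta` (named),
#'   `residuals`, `rss`, `n`, `p`, `df_resid` (`n - p`),
#'   `residual_variance` (`rss / (n - p)`), and `xtx_inv`.
#' @export
#' @examples
#' k <- normalize_kernel(discretize_crf(firi_crf_default()))
#' s <- c(1, numeric(299))
#' d <- build_design(s, k, rate = 10)
#' fit <- fit_glm(2.5 * d$X[, 1] + 1, d)
#' fit$beta  # c(ev1 = 2.5, intercept = 1)
fit_glm <- function(y, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (length(y) != nrow(X))
    stop("length(y) (", length(y), ") does not match design rows (",
         nrow(X), ")", call. = FALSE)
  p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p)
    stop("design matrix is rank deficient (rank ", qrx$rank, " < ", p,
         " columns)", call. = FALSE)
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  xtx_inv <- chol2inv(qr.R(qrx))
  structure(list(beta = stats::setNames(as.numeric(beta), colnames(X)),
                 residuals = as.numeric(res), rss = rss,
                 n = length(y), p = p, df_resid = length(y) - p,
                 residual_variance = rss / (length(y) - p),
                 xtx_inv = xtx_inv),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat("<glm_result> ", x$p, "predictors, n =", x$n, ", residual variance =",
      format(x$residual_variance), "\n")
  print(data.frame(beta = x$beta,
                   t = if (is.null(x$t)) NA else x$t,
                   p = if (is.null(x$p_value)) NA else x$p_value,
                   detected = if (is.null(x$detected)) NA else x$detected))
  invisible(x)
}

#' Spectral full-width-half-maximum smoothness of a series
#'
#' Expresses a signal's autocorrelation as the full width at half maximum
#' (FWHM, in samples) of the equivalent Gaussian smoothing kernel. The
#' estimator matches a Gaussian main lobe to the power spectrum by
#' moments: with `sigma_nu` the power-weighted RMS frequency of the
#' tapered periodogram (cycles/sample), the equivalent smoothing FWHM is
#' `sqrt(log(2)) / (pi * sigma_nu)`, floored at 1 sample. White noise
#' yields ~1; a series smoothed by a Gaussian kernel of FWHM `w` yields
#' approximately `w`. A moment-matched width is used rather than a literal
#' half-power crossing because the latter is dominated by periodogram
#' noise and smoother bandwidth at these window lengths.
#'
#' @param x Numeric series, length >= 16, non-constant.
#' @param rate Sampling rate in Hz (informational; the width is in
#'   samples and does not depend on it).
#' @param taper Split-cosine taper proportion passed to
#'   [stats::spec.pgram()].
#'
#' @return Smoothness FWHM in samples (numeric, >= 1).
#' @export
spectral_fwhm <- function(x, rate = NULL, taper = 0.1) {
  if (length(x) < 16L) stop("series too short (need >= 16 samples)",
                            call. = FALSE)
  if (stats::sd(x) == 0) stop("constant series has no spectral width",
                              call. = FALSE)
  sp <- stats::spec.pgram(stats::ts(x), taper = taper, detrend = TRUE,
                          demean = TRUE, plot = FALSE, fast = TRUE)
  sigma_nu <- sqrt(sum(sp$freq^2 * sp$spec) / sum(sp$spec))
  max(1, sqrt(log(2)) / (pi * sigma_nu))
}

#' Effective degrees of freedom under autocorrelation
#'
#' Discounts the nominal sample count for the serial correlation of the
#' signal: a series of `n` samples whose smoothness FWHM is `fwhm` samples
#' carries about `n / fwhm` statistically independent samples, so the
#' degrees of freedom available to inference are
#' `floor(n / fwhm) - p`, with `p` the number of fitted parameters
#' (intercept included). For a 30 s epoch at 10 Hz with the study-average
#' FWHM of 12 samples and one parameter: `floor(300/12) - 1 = 24`.
#'
#' @param n Number of samples.
#' @param fwhm Smoothness FWHM in samples (see [spectral_fwhm()]).
#' @param p Number of fitted model parameters, intercept included.
#'
#' @return Integer degrees of freedom (>= 1).
#' @export
#' @examples
#' effective_df(300, 12, 1)  # 24
effective_df <- function(n, fwhm, p) {
  stopifnot(n > 0, fwhm > 0, p > 0)
  df <- floor(n / fwhm) - p
  if (df < 1)
    stop("insufficient effective samples: floor(", n, "/", fwhm, ") = ",
         floor(n / fwhm), " <= p = ", p, call. = FALSE)
  as.integer(df)
}

#' t-inference on fitted predictor weights
#'
#' Fills the inference fields of a [fit_glm()] result: standard errors
#' from the residual variance computed with the supplied (effective)
#' degrees of freedom and the design Gram matrix, two-sided p-values from
#' the t distribution, and per-predictor detection flags at level `alpha`.
#' A zero-residual fit is the noiseless limit: any nonzero weight is
#' reported with `t = Inf`, `p = 0`, detected; an exactly zero weight
#' with `t = 0`, `p = 1`.
#'
#' @param result A `glm_result` from [fit_glm()].
#' @param df Effective degrees of freedom (integer >= 1), typically from
#'   [effective_df()].
#' @param alpha Significance level (default 0.05).
#'
#' @return The `glm_result` with fields `se`, `t`, `df`, `p_value`,
#'   `detected`, `alpha` filled, and `residual_variance` recomputed as
#'   `rss / df`.
#' @export
infer_activation <- function(result, df, alpha = 0.05) {
  stopifnot(inherits(result, "glm_result"))
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  sigma2 <- result$rss / df
  se <- sqrt(sigma2 * diag(result$xtx_inv))
  tstat <- ifelse(se > 0, result$beta / se,
                  ifelse(result$beta == 0, 0, Inf * sign(result$beta)))
  pval <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df = df),
                 0)
  pval[tstat == 0 & se == 0] <- 1
  result$se <- se
  result$t <- as.numeric(tstat)
  result$df <- as.integer(df)
  result$p_value <- as.numeric(pval)
  result$alpha <- alpha
  result$detected <- result$p_value < alpha
  result$residual_variance <- sigma2
  result
}

# Fit + infer one analysis window. `fwhm` is either "estimate" (per-window
# spectral estimate from y) or a numeric study-average width in samples.
# Parameters counted for df include the intercept.
.window_inference <- function(y, design, alpha = 0.05, fwhm = "estimate") {
  fit <- fit_glm(y, design)
  w <- if (identical(fwhm, "estimate")) spectral_fwhm(y) else as.numeric(fwhm)
  df <- effective_df(fit$n, w, fit$p)
  infer_activation(fit, df, alpha = alpha)
}
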