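# Shared fixtures, all built in code at test time.

table1_params <- function() firi_crf_default()

# A compact paradigm for fast end-to-end runs.
tiny_paradigm <- function() {
  paradigm_config(n_single = 2, n_double_per_isi = 1, rest = 30, lead_in = 10)
}

# Cohort in the list-of-subjects shape consumed by linearity_test().
as_linearity_cohort <- function(cohort) {
  lapply(cohort$subjects, function(s) list(firi = s$firi,
                                           schedule = s$schedule))
}

# White noise smoothed by a Gaussian kernel of FWHM `w` samples; edge
# effects avoided by generating extra samples and trimming.
gaussian_smoothed_noise <- function(n, w) {
  s <- w / (2 * sqrt(2 * log(2)))
  half <- ceiling(6 * s)
  k <- stats::dnorm(seq(-half, half), 0, s)
  k <- k / sqrt(sum(k^2))
  x <- stats::rnorm(n + 2 * half + length(k))
  y <- stats::filter(x, k, sides = 2)
  y <- y[!is.na(y)]
  y[seq_len(n)]
}

random_crf_params <- function() {
  crf_params(tau = stats::runif(1, 2, 15), sigma = stats::runif(1, 2, 8),
             lambda1 = stats::runif(1, 0.02, 0.3),
             lambda2 = stats::runif(1, 0.02, 0.3),
             sign = sample(c(-1, 1), 1))
}
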