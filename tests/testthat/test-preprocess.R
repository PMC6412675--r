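# Zero-phase filtering, decimation, standardization, artifact handling.

test_that("fIRI low-pass passes DC, rejects high frequency, adds no lag", {
  tr <- signal_trace(rep(3.2, 500), 10, modality = "fIRI")
  out <- lowpass_firi(tr)
  expect_equal(out$samples, tr$samples, tolerance = 1e-9)
  # 2 Hz sinusoid at 10 Hz sampling is far above the 0.4 Hz cutoff
  t <- seq(0, 50, by = 0.1)
  sine <- signal_trace(sin(2 * pi * 2 * t), 10, modality = "fIRI")
  out2 <- lowpass_firi(sine)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out2$samples) / rms(sine$samples), 0.05)
  # symmetric pulse keeps its peak sample (zero-lag contract)
  pulse <- exp(-(seq_len(501) - 251)^2 / (2 * 30^2))
  outp <- lowpass_firi(signal_trace(pulse, 10, modality = "fIRI"))
  expect_equal(which.max(outp$samples), 251L)
  expect_error(lowpass_firi(signal_trace(rnorm(100), 10, "fIRI"),
                            cutoff = 6), "Nyquist")
  expect_error(lowpass_firi(signal_trace(rnorm(100), 10, "SCR")), "fIRI")
})

test_that("SCR band-pass rejects DC and preserves in-band amplitude", {
  tr <- signal_trace(rep(5, 3000), 100, modality = "SCR")
  out <- bandpass_scr(tr)
  expect_lt(max(abs(out$samples)), 0.05)
  t <- seq(0, 30, by = 0.01)
  sine <- signal_trace(sin(2 * pi * 1 * t), 100, modality = "SCR")
  outs <- bandpass_scr(sine)
  mid <- 1000:2000
  expect_equal(max(abs(outs$samples[mid])), 1, tolerance = 0.05)
  expect_error(bandpass_scr(signal_trace(rnorm(100), 10, "SCR"),
                            band = c(0.01, 5)), "Nyquist")
  expect_error(bandpass_scr(signal_trace(rnorm(100), 100, "SCR"),
                            band = c(5, 1)), "edges")
})

test_that("downsample decimates by integer factors", {
  t <- seq(0, 10 - 1e-4, by = 1e-3)
  tr <- signal_trace(sin(2 * pi * t), 1000, modality = "SCR")
  out <- downsample(tr, 10)
  expect_length(out$samples, 100)
  expect_equal(out$rate, 10)
  expect_equal(out$samples, sin(2 * pi * seq(0, 9.9, by = 0.1)),
               tolerance = 1e-2)
  tr10 <- signal_trace(rnorm(50), 10, modality = "fIRI")
  expect_identical(downsample(tr10, 10)$samples, tr10$samples)
  expect_error(downsample(signal_trace(rnorm(50), 25, "SCR"), 10),
               "integer multiple")
})

test_that("z-transform standardizes, is idempotent and affine invariant", {
  set.seed(5)
  tr <- signal_trace(rnorm(200, 31, 0.4), 10, modality = "fIRI",
                     units = "degC")
  z <- ztransform(tr)
  expect_equal(mean(z$samples), 0, tolerance = 1e-9)
  expect_equal(sd(z$samples), 1, tolerance = 1e-9)
  expect_equal(z$units, "z")
  expect_equal(ztransform(z)$samples, z$samples, tolerance = 1e-9)
  aff <- signal_trace(tr$samples * 5 + 3, 10, modality = "fIRI")
  expect_equal(ztransform(aff)$samples, z$samples, tolerance = 1e-9)
  expect_error(ztransform(signal_trace(rep(1, 50), 10, "fIRI")), "constant")
})

test_that("artifact substitution uses the six clean neighbours on each side", {
  x <- rep(5, 30)
  x[11:14] <- 99
  tr <- signal_trace(x, 10, modality = "fIRI")
  out <- correct_artifacts(tr, list(c(11, 14)))
  expect_equal(out$samples[11:14], rep(5, 4))
  # asymmetric neighbourhood: mean of 6 before (1.0) and 6 after (3.0)
  y <- c(rep(1, 10), rep(99, 5), rep(3, 10))
  out2 <- correct_artifacts(signal_trace(y, 10, "fIRI"), list(c(11, 15)))
  expect_equal(out2$samples[11:15], rep(2, 5))
  # untouched outside the span
  expect_equal(out2$samples[-(11:15)], y[-(11:15)])
  # boundary: span at the start uses only the following samples
  z <- c(rep(99, 3), rep(4, 10))
  out3 <- correct_artifacts(signal_trace(z, 10, "fIRI"), list(c(1, 3)))
  expect_equal(out3$samples[1:3], rep(4, 3))
  expect_error(correct_artifacts(signal_trace(rep(1, 5), 10, "fIRI"),
                                 list(c(1, 5))), "whole trace")
})

test_that("tracking failures are flagged by rolling-variance outliers", {
  set.seed(21)
  x <- rnorm(2000, sd = 0.1)
  clean <- signal_trace(x, 10, modality = "fIRI")
  expect_length(flag_tracking_failures(clean), 0)
  x2 <- x
  x2[800:840] <- x2[800:840] + rnorm(41, sd = 1)   # 10x noise burst
  spans <- flag_tracking_failures(signal_trace(x2, 10, "fIRI"))
  expect_gt(length(spans), 0)
  covered <- unlist(lapply(spans, function(sp) sp[1]:sp[2]))
  expect_gt(length(intersect(covered, 800:840)), 0)
  expect_error(flag_tracking_failures(signal_trace(rnorm(5), 10, "fIRI"),
                                      window = 10), "length")
})

test_that("filters are zero-phase on broadband input", {
  set.seed(9)
  x <- rnorm(3000)
  tr <- signal_trace(x, 10, modality = "fIRI")
  y <- lowpass_firi(tr)$samples
  cc <- ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter_kernel matches the analysis band and keeps unit peak", {
  k <- normalize_kernel(discretize_crf(table1_params(), rate = 10))
  kf <- filter_kernel(k)
  expect_equal(max(abs(kf$values)), 1)
  expect_length(kf$values, length(k$values))
  # the slow thermal kernel is barely touched by a 0.4 Hz low-pass
  expect_gt(cor(kf$values, k$values), 0.999)
})
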