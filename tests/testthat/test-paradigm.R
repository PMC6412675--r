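# Event schedules, stick functions, design matrices, epochs.

test_that("default paradigm realizes the configured trial counts and timing", {
  sch <- build_paradigm(paradigm_config(), seed = 1)
  expect_equal(length(unique(sch$trial_id)), 32)
  expect_equal(sum(sch$condition == "single"), 8)
  dbl <- sch[sch$condition == "double" & sch$position == "first", ]
  expect_equal(nrow(dbl), 24)
  expect_equal(as.numeric(table(dbl$isi)), c(8, 8, 8))
  # first stimulus after rest + lead-in
  expect_equal(min(sch$onset), 120 + 10)
  # double trials: second onset = first onset + isi
  for (tr in unique(sch$trial_id[sch$condition == "double"])) {
    tev <- sch[sch$trial_id == tr, ]
    expect_equal(tev$onset[2], tev$onset[1] + tev$isi[1])
  }
})

test_that("inter-trial silences come from the configured set", {
  cfg <- paradigm_config()
  sch <- build_paradigm(cfg, seed = 7)
  last <- sch[!duplicated(sch$trial_id, fromLast = TRUE), ]
  nxt <- sch[!duplicated(sch$trial_id), ]
  gaps <- nxt$onset[-1] - (last$onset[-nrow(last)] + last$duration[-nrow(last)])
  expect_true(all(gaps %in% cfg$silences))
  expect_true(all(gaps >= min(cfg$silences)))
})

test_that("schedule generation is a pure function of config and seed", {
  a <- build_paradigm(seed = 42)
  b <- build_paradigm(seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- build_paradigm(seed = 43)
  expect_false(identical(a$onset, c$onset))
  # balanced silences still draw from the set, 10-11 trials each
  sch <- build_paradigm(paradigm_config(balanced_silences = TRUE), seed = 1)
  expect_equal(length(unique(sch$trial_id)), 32)
})

test_that("stick functions place unit impulses at onset samples", {
  sch <- build_paradigm(seed = 1)
  n <- as.integer(ceiling(attr(sch, "total_duration") * 10))
  s_all <- stick_function(sch, rate = 10, n = n)
  expect_equal(sum(s_all), nrow(sch))
  expect_true(all(s_all %in% c(0, 1)))
  # single condition: one impulse per event at the rounded onset sample
  s_single <- stick_function(sch, 10, n, condition = "single")
  expect_equal(sum(s_single), 8)
  first_single <- sch$onset[sch$condition == "single"][1]
  expect_equal(s_single[round(first_single * 10) + 1], 1)
  # double trial at ISI 2: impulses 20 samples apart within the window
  tev <- sch[sch$condition == "double" & sch$isi == 2, ][1:2, ]
  sw <- stick_function(tev, 10, 300, t0 = tev$onset[1], split_events = TRUE)
  expect_equal(which(sw[, 1] == 1), 1L)
  expect_equal(which(sw[, 2] == 1), 21L)
  expect_error(stick_function(sch, 10, 100), "outside")
})

test_that("design matrices convolve, superpose, and shift correctly", {
  k <- normalize_kernel(discretize_crf(table1_params(), rate = 10))
  n <- 1000
  s0 <- numeric(n); s0[1] <- 1
  d0 <- build_design(s0, k, rate = 10, intercept = FALSE)
  padded <- c(k$values, numeric(n - length(k$values)))
  expect_equal(as.numeric(d0$X[, 1]), padded, tolerance = 1e-12)
  # linearity: two impulses equal the sum of single-impulse predictors
  s1 <- numeric(n); s1[60] <- 1
  d1 <- build_design(s1, k, rate = 10, intercept = FALSE)
  d01 <- build_design(s0 + s1, k, rate = 10, intercept = FALSE)
  expect_equal(d01$X, d0$X + d1$X, tolerance = 1e-10)
  # shift-equivariance: impulse at sample j delays the sample-1 predictor
  expect_equal(as.numeric(d1$X[60:n, 1]), as.numeric(d0$X[1:(n - 59), 1]),
               tolerance = 1e-10)
  expect_lt(max(abs(d1$X[1:59, 1])), 1e-10)  # FFT round-off only
  expect_error(build_design(s0, k, rate = 25), "rate")
})

test_that("design built from a double stick equals the sum of single designs", {
  k <- normalize_kernel(discretize_crf(table1_params(), rate = 10))
  sch <- build_paradigm(seed = 3)
  tev <- sch[sch$condition == "double" & sch$isi == 5.5, ][1:2, ]
  both <- stick_function(tev, 10, 300, t0 = tev$onset[1])
  d_both <- build_design(both, k, rate = 10, intercept = FALSE)
  sp <- stick_function(tev, 10, 300, t0 = tev$onset[1], split_events = TRUE)
  d_split <- build_design(sp, k, rate = 10, intercept = FALSE)
  expect_equal(as.numeric(d_both$X[, 1]),
               as.numeric(d_split$X[, 1] + d_split$X[, 2]))
})

test_that("epochs are window x rate samples and carry metadata", {
  sch <- build_paradigm(seed = 1)
  n <- as.integer(ceiling((attr(sch, "total_duration") + 5) * 10))
  tr <- signal_trace(rnorm(n), 10, modality = "fIRI")
  eps <- extract_epochs(tr, sch, window = 30, condition = "single")
  expect_equal(dim(eps$epochs), c(8L, 300L))
  # epoch content matches the trace slice, onset sample included
  i0 <- round(eps$events$onset[1] * 10) + 1
  expect_equal(as.numeric(eps$epochs[1, ]), tr$samples[i0:(i0 + 299)])
  # a window overrunning the end errors and names the event
  short <- signal_trace(tr$samples[1:(round(max(sch$onset) * 10) + 100)], 10,
                        modality = "fIRI")
  expect_error(extract_epochs(short, sch, window = 30), "overruns")
})

test_that("config validation rejects degenerate designs", {
  expect_error(paradigm_config(isis = numeric(0)), "isis")
  expect_error(paradigm_config(n_double_per_isi = 0), "positive")
})
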