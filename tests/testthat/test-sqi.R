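mk_match <- function(n, na, nb) {
  structure(list(n_matched = n, n_a = na, n_b = nb, tolerance_s = 0.15),
            class = "rpeak_match")
}

test_that("qSQI is the symmetrised detector agreement in percent", {
  expect_equal(compute_qsqi(mk_match(30L, 30L, 30L)), 100)
  expect_equal(compute_qsqi(mk_match(9L, 10L, 10L)), 90)
  expect_equal(compute_qsqi(mk_match(0L, 5L, 3L)), 0)
  expect_error(compute_qsqi(mk_match(0L, 0L, 0L)),
               class = "ecgsqi_error_undefined_index")
})

test_that("grade breakpoints fall exactly where the criteria place them", {
  expect_identical(grade_qsqi(95), "optimal")
  expect_identical(grade_qsqi(90), "suspicious")   # closed upper bound
  expect_identical(grade_qsqi(60), "suspicious")
  expect_identical(grade_qsqi(59.9), "unqualified")

  expect_identical(grade_psqi(0.6, 80), "optimal")
  expect_identical(grade_psqi(0.45, 80), "suspicious")
  expect_identical(grade_psqi(0.85, 80), "unqualified")
  expect_identical(grade_psqi(0.35, 80), "unqualified")
  # 130-160 bpm band uses shifted limits
  expect_identical(grade_psqi(0.45, 140), "optimal")
  expect_identical(grade_psqi(0.35, 140), "suspicious")
  expect_warning(grade_psqi(0.6, 50), class = "ecgsqi_warning_hr_band")

  expect_identical(grade_csqi(0.1), "optimal")
  expect_identical(grade_csqi(0.5), "suspicious")
  expect_identical(grade_csqi(0.45), "suspicious")
  expect_identical(grade_csqi(0.7), "unqualified")

  expect_identical(grade_ksqi(7.2), "optimal")
  expect_identical(grade_ksqi(5.0), "unqualified")
  expect_identical(grade_ksqi(2.9), "unqualified")

  expect_identical(grade_bassqi(0.966), "optimal")
  expect_identical(grade_bassqi(0.95), "optimal")
  expect_identical(grade_bassqi(0.92), "suspicious")
  expect_identical(grade_bassqi(0.5), "unqualified")
})

test_that("spectrum concentrates a pure tone at its frequency", {
  spec <- estimate_spectrum(tone_record(10))
  in_band <- band_power(spec, 9.5, 10.5)
  expect_gt(in_band / band_power(spec, 0, 40), 0.99)
  expect_lte(spec$freqs[2] - spec$freqs[1], 0.25)
  expect_error(estimate_spectrum(ecg_record(rnorm(500), 300)),
               class = "ecgsqi_error_input_too_short")
})

test_that("white noise gives an approximately flat density", {
  set.seed(8)
  spec <- estimate_spectrum(ecg_record(rnorm(120 * 300), fs = 300))
  lo <- band_power(spec, 5, 20) / 15
  hi <- band_power(spec, 20, 35) / 15
  expect_lt(abs(lo / hi - 1), 0.1)
})

test_that("a constant offset does not perturb the band-power indices", {
  rec <- tone_record(10)
  shifted <- ecg_record(rec$samples + 50, fs = 300)
  expect_equal(compute_bassqi(estimate_spectrum(shifted)),
               compute_bassqi(estimate_spectrum(rec)), tolerance = 1e-10)
})

test_that("cSQI is the sample coefficient of variation of the RR series", {
  mk_set <- function(times_s) {
    ecgsqi:::new_rpeak_set(as.integer(round(times_s * 300)) + 1L,
                           "hilbert_adaptive", 300)
  }
  expect_equal(compute_csqi(mk_set(cumsum(c(0, rep(1, 10))))), 0)
  # RR = 0.8, 1.0, 1.2 s: sample SD 0.2, mean 1.0
  expect_equal(compute_csqi(mk_set(cumsum(c(0, 0.8, 1.0, 1.2)))), 0.2,
               tolerance = 1e-2)
  expect_error(compute_csqi(mk_set(c(0, 1))),
               class = "ecgsqi_error_undefined_index")
})

test_that("standardized moments match their closed forms", {
  set.seed(123)
  mom <- compute_moments(ecg_record(rnorm(1e5), fs = 300))
  expect_equal(mom$ksqi, 3, tolerance = 0.1)
  expect_equal(mom$ssqi, 0, tolerance = 0.1)

  mom_sin <- compute_moments(tone_record(7, duration_s = 100))
  expect_equal(mom_sin$ksqi, 1.5, tolerance = 0.02)
  expect_equal(mom_sin$ssqi, 0, tolerance = 0.02)

  expect_error(compute_moments(ecg_record(rep(2, 100), fs = 300)),
               class = "ecgsqi_error_undefined_index")
})

test_that("kurtosis dominates squared skewness plus one wherever defined", {
  set.seed(9)
  for (i in 1:20) {
    x <- switch(1 + i %% 4,
                rnorm(2000), rexp(2000), runif(2000), cumsum(rnorm(2000)))
    mom <- compute_moments(ecg_record(x, fs = 300))
    expect_gte(mom$ksqi, mom$ssqi^2 + 1)
  }
})

test_that("every SQI is invariant to positive amplitude rescaling", {
  lab <- clean_record(seed = 31)
  a <- suppressWarnings(compute_sqis(lab$record))
  scaled <- lab$record
  scaled$samples <- 5.5 * scaled$samples
  b <- suppressWarnings(compute_sqis(scaled))
  for (col in c("qsqi", "psqi", "csqi", "ssqi", "ksqi", "bassqi")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-8, label = col)
  }
})

test_that("indices respond monotonically to their target noise class", {
  bass <- vapply(c(0.05, 0.15, 0.3, 0.45), function(a) {
    compute_bassqi(estimate_spectrum(
      noisy_record(c(baseline_wander = a), seed = 9)$record))
  }, numeric(1))
  expect_true(all(diff(bass) < 0))

  psqi <- vapply(c(0.1, 0.3, 0.6, 1.0), function(a) {
    compute_psqi(estimate_spectrum(noisy_record(c(emg = a), seed = 9)$record))
  }, numeric(1))
  expect_true(all(diff(psqi) < 0))
})

test_that("compute_sqis grades a clean segment optimal and degrades under noise", {
  clean <- suppressWarnings(compute_sqis(clean_record(seed = 3)$record))
  expect_identical(clean$grade_qsqi, "optimal")
  expect_identical(clean$grade_psqi, "optimal")
  expect_identical(clean$grade_csqi, "optimal")
  expect_identical(clean$grade_ksqi, "optimal")
  expect_identical(clean$grade_bassqi, "optimal")

  drifty <- suppressWarnings(compute_sqis(
    noisy_record(c(baseline_wander = 0.6), seed = 11)$record))
  expect_identical(drifty$grade_bassqi, "unqualified")

  flat <- suppressWarnings(compute_sqis(ecg_record(rep(0.5, 9000), fs = 300)))
  grades <- unlist(flat[grep("^grade_", names(flat))])
  expect_true(all(grades == "unqualified"))
  expect_true(is.na(flat$qsqi) && is.na(flat$ksqi))
})
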