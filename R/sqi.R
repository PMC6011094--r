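#' @title Signal quality indices and their grades
#' @description
#' The six indices and the three-level grading criteria used throughout the
#' package:
#'
#' * `qSQI = 100 * 2N / (Na + Nb)` — agreement of two independent R-peak
#'   detectors (percent).
#' * `pSQI` — fraction of 5-40 Hz spectral power lying in the QRS band
#'   5-15 Hz.
#' * `cSQI` — coefficient of variation (SD/mean) of the RR intervals.
#' * `sSQI`, `kSQI` — third and fourth standardized moments of the samples
#'   (skewness and non-excess kurtosis; a Gaussian has kurtosis 3).
#' * `basSQI` — one minus the fraction of 0-40 Hz power below 1 Hz; values
#'   near 1 mean a clean baseline.
#'
#' Grades take values `"optimal"`, `"suspicious"`, `"unqualified"`; kurtosis is
#' two-level (never `"suspicious"`). Boundary conventions follow the printed
#' criteria: e.g. qSQI of exactly 90 is suspicious, kurtosis of exactly 5 is
#' unqualified.
#' @name sqi_indices
NULL

undefined_index <- function(msg) {
  abort(msg, class = "ecgsqi_error_undefined_index")
}

#' @param match An `rpeak_match` from [match_rpeaks()].
#' @rdname sqi_indices
#' @export
compute_qsqi <- function(match) {
  stopifnot(inherits(match, "rpeak_match"))
  if (match$n_a + match$n_b == 0L) {
    undefined_index("qSQI undefined: neither detector found any R peaks.")
  }
  q <- 100 * 2 * match$n_matched / (match$n_a + match$n_b)
  min(100, max(0, q))
}

#' @param q qSQI value in percent.
#' @rdname sqi_indices
#' @export
grade_qsqi <- function(q) {
  stopifnot(q >= 0, q <= 100)
  if (q > 90) "optimal" else if (q >= 60) "suspicious" else "unqualified"
}

#' @param spectrum A `power_spectrum` from [estimate_spectrum()].
#' @rdname sqi_indices
#' @export
compute_psqi <- function(spectrum) {
  den <- band_power(spectrum, 5, 40)
  if (den <= 0) undefined_index("pSQI undefined: no 5-40 Hz power.")
  min(1, max(0, band_power(spectrum, 5, 15) / den))
}

#' @param p pSQI value in `[0, 1]`.
#' @param heart_rate_bpm Heart rate used to pick the pSQI limit band.
#' @param limits Heart-rate band table (see [sqi_config()]).
#' @rdname sqi_indices
#' @export
grade_psqi <- function(p, heart_rate_bpm,
                       limits = sqi_config()$psqi_limits_by_hr) {
  stopifnot(p >= 0, p <= 1)
  row <- which(heart_rate_bpm >= limits$hr_low & heart_rate_bpm <= limits$hr_high)
  if (length(row) == 0L) {
    mid <- (limits$hr_low + limits$hr_high) / 2
    row <- which.min(abs(mid - heart_rate_bpm))
    warn(sprintf("heart rate %.0f bpm outside defined bands; using nearest band.",
                 heart_rate_bpm), class = "ecgsqi_warning_hr_band")
  }
  row <- row[1L]
  l1 <- limits$l1[row]; l2 <- limits$l2[row]; l3 <- limits$l3[row]
  if (p >= l1 && p <= l2) "optimal"
  else if (p >= l3 && p < l1) "suspicious"
  else "unqualified"
}

#' @param rpeaks An `rpeak_set` with at least 3 peaks.
#' @rdname sqi_indices
#' @export
compute_csqi <- function(rpeaks) {
  stopifnot(inherits(rpeaks, "rpeak_set"))
  if (length(rpeaks$indices) < 3L) {
    undefined_index("cSQI undefined: need >= 3 peaks (>= 2 RR intervals).")
  }
  rr <- diff(rpeaks$indices) / rpeaks$fs
  sd(rr) / mean(rr)
}

#' @param cv cSQI value (RR coefficient of variation).
#' @param thresholds Two cut points, default `c(0.45, 0.64)`.
#' @rdname sqi_indices
#' @export
grade_csqi <- function(cv, thresholds = c(0.45, 0.64)) {
  stopifnot(cv >= 0)
  if (cv < thresholds[1]) "optimal"
  else if (cv <= thresholds[2]) "suspicious"
  else "unqualified"
}

#' @param record An [ecg_record()] (moments are computed on the raw samples).
#' @rdname sqi_indices
#' @export
compute_moments <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  if (length(x) < 2L) undefined_index("moments undefined: record too short.")
  mu <- mean(x)
  s2 <- mean((x - mu)^2)
  if (s2 <= 0) undefined_index("moments undefined: constant signal.")
  list(ssqi = mean((x - mu)^3) / s2^1.5,
       ksqi = mean((x - mu)^4) / s2^2)
}

#' @param k kSQI value (non-excess kurtosis).
#' @param threshold Cut point, default 5.
#' @rdname sqi_indices
#' @export
grade_ksqi <- function(k, threshold = 5) {
  if (k > threshold) "optimal" else "unqualified"
}

#' @rdname sqi_indices
#' @export
compute_bassqi <- function(spectrum) {
  den <- band_power(spectrum, 0, 40)
  if (den <= 0) undefined_index("basSQI undefined: zero total power.")
  min(1, max(0, 1 - band_power(spectrum, 0, 1) / den))
}

#' @param b basSQI value in `[0, 1]`.
#' @param bounds Two cut points, default `c(0.90, 0.95)`.
#' @rdname sqi_indices
#' @export
grade_bassqi <- function(b, bounds = c(0.90, 0.95)) {
  stopifnot(b >= 0, b <= 1)
  if (b >= bounds[2]) "optimal"
  else if (b >= bounds[1]) "suspicious"
  else "unqualified"
}

#' Compute all six SQIs and their grades for one segment
#'
#' Runs both R-peak detectors, matches them, estimates the spectrum, and
#' computes the full index vector. Any index that is undefined on the segment
#' (flatline, no peaks, zero power) is returned as `NA` and graded
#' `"unqualified"`. Skewness is computed and reported but not graded: it is
#' less robust to noise than kurtosis and does not enter any fusion rule.
#'
#' @param record An [ecg_record()].
#' @param config An [sqi_config()].
#' @return A one-row tibble: `source_id`, the six index values,
#'   `heart_rate_bpm`, and `grade_qsqi` .. `grade_bassqi`.
#' @examples
#' rec <- generate_clean(synth_spec(duration_s = 30))$record
#' compute_sqis(rec)
#' @export
compute_sqis <- function(record, config = sqi_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "sqi_config"))
  safe <- function(expr) tryCatch(expr, ecgsqi_error_undefined_index = function(e) NULL,
                                  ecgsqi_error_input_too_short = function(e) NULL)
  pk_h <- safe(detect_rpeaks_hilbert(record))
  pk_w <- safe(detect_rpeaks_dwt(record))
  rr_peaks <- if (identical(config$rr_detector, "dwt_modmax")) pk_w else pk_h

  qsqi <- NA_real_
  if (!is.null(pk_h) && !is.null(pk_w)) {
    m <- match_rpeaks(pk_h, pk_w, config$match_tolerance_s)
    qsqi <- if (m$n_a + m$n_b > 0L) compute_qsqi(m) else NA_real_
  }

  hr <- NA_real_
  csqi <- NA_real_
  if (!is.null(rr_peaks) && length(rr_peaks$indices) >= 3L) {
    rr <- diff(rr_peaks$indices) / rr_peaks$fs
    hr <- 60 / mean(rr)
    csqi <- safe(compute_csqi(rr_peaks))
    if (is.null(csqi)) csqi <- NA_real_
  }

  spec <- safe(estimate_spectrum(record))
  psqi <- if (is.null(spec)) NA_real_ else {
    v <- safe(compute_psqi(spec)); if (is.null(v)) NA_real_ else v
  }
  bassqi <- if (is.null(spec)) NA_real_ else {
    v <- safe(compute_bassqi(spec)); if (is.null(v)) NA_real_ else v
  }

  mom <- safe(compute_moments(record))
  ssqi <- if (is.null(mom)) NA_real_ else mom$ssqi
  ksqi <- if (is.null(mom)) NA_real_ else mom$ksqi

  g <- function(val, grader) if (is.na(val)) "unqualified" else grader(val)
  tibble(
    source_id = record$source_id,
    qsqi = qsqi, psqi = psqi, csqi = csqi, ssqi = ssqi, ksqi = ksqi,
    bassqi = bassqi, heart_rate_bpm = hr,
    grade_qsqi = g(qsqi, grade_qsqi),
    grade_psqi = if (is.na(psqi) || is.na(hr)) "unqualified" else
      grade_psqi(psqi, hr, config$psqi_limits_by_hr),
    grade_csqi = g(csqi, function(v) grade_csqi(v, config$csqi_thresholds)),
    grade_ksqi = g(ksqi, function(v) grade_ksqi(v, config$ksqi_threshold)),
    grade_bassqi = g(bassqi, function(v) grade_bassqi(v, config$bassqi_grade_bounds))
  )
}
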