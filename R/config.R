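#' Analysis configuration
#'
#' Collects every tunable threshold of the assessment pipeline in one place.
#' Defaults reproduce the published criteria; all breakpoints are exposed so
#' the boundary conventions can be audited or re-tuned.
#'
#' @param segment_length_samples Analysis window length (default 9000 samples).
#' @param match_tolerance_s R-peak matching window in seconds (PhysioNet
#'   beat-matching convention, 150 ms).
#' @param psqi_limits_by_hr Data frame of heart-rate bands and pSQI limits with
#'   columns `hr_low`, `hr_high`, `l1`, `l2`, `l3`. Outside all bands the
#'   nearest band applies (with a warning).
#' @param csqi_thresholds Two cut points for the RR coefficient of variation:
#'   optimal below the first, unqualified above the second.
#' @param ksqi_threshold Kurtosis cut: optimal strictly above it.
#' @param bassqi_grade_bounds Two cut points for baseline relative power:
#'   suspicious from the first, optimal from the second.
#' @param weights Fuzzy weights for (qSQI, pSQI, kSQI, basSQI); must sum to 1.
#' @param decision_thresholds Decision-score cuts `(v_th1, v_th2)`:
#'   Excellent at or below the first, Unacceptable at or above the second.
#' @param membership_mode `"continuity_corrected"` (default) uses trapezoid
#'   slopes that make the pSQI membership functions continuous;
#'   `"literal"` uses the printed 0.1 slopes (discontinuous; see vignette).
#' @param synthesis_operator Fuzzy synthesis operator; the weighted
#'   bounded-sum operator `"bounded"` (M(., +)) is the published choice. The
#'   alternatives `"max_min"`, `"max_prod"`, `"bounded_min"` are provided as
#'   options only.
#' @param acceptable_labels Labels mapped to the binary "acceptable" class when
#'   computing Se/Sp/Acc.
#' @param rr_detector Which detector's RR series feeds cSQI and heart rate.
#' @param rng_seed Integer seed from which all randomness in the package flows.
#'
#' @return A list of class `sqi_config`.
#' @export
sqi_config <- function(segment_length_samples = 9000L,
                       match_tolerance_s = 0.15,
                       psqi_limits_by_hr = data.frame(
                         hr_low = c(60, 130), hr_high = c(130, 160),
                         l1 = c(0.5, 0.4), l2 = c(0.8, 0.7), l3 = c(0.4, 0.3)
                       ),
                       csqi_thresholds = c(0.45, 0.64),
                       ksqi_threshold = 5,
                       bassqi_grade_bounds = c(0.90, 0.95),
                       weights = c(0.4, 0.4, 0.1, 0.1),
                       decision_thresholds = c(1.50, 2.40),
                       membership_mode = c("continuity_corrected", "literal"),
                       synthesis_operator = c("bounded", "max_min", "max_prod", "bounded_min"),
                       acceptable_labels = c("E", "B"),
                       rr_detector = c("hilbert_adaptive", "dwt_modmax"),
                       rng_seed = 1L) {
  membership_mode <- match.arg(membership_mode)
  synthesis_operator <- match.arg(synthesis_operator)
  rr_detector <- match.arg(rr_detector)
  stopifnot(
    is.data.frame(psqi_limits_by_hr),
    all(c("hr_low", "hr_high", "l1", "l2", "l3") %in% names(psqi_limits_by_hr)),
    length(csqi_thresholds) == 2L, csqi_thresholds[1] <= csqi_thresholds[2],
    length(bassqi_grade_bounds) == 2L,
    bassqi_grade_bounds[1] < bassqi_grade_bounds[2],
    length(decision_thresholds) == 2L,
    decision_thresholds[1] < decision_thresholds[2],
    length(weights) == 4L, all(weights >= 0)
  )
  if (!all(is.finite(unlist(psqi_limits_by_hr))) ||
      any(with(psqi_limits_by_hr, !(l3 < l1 & l1 < l2)))) {
    abort("pSQI limits must be finite with l3 < l1 < l2 in every band.",
          class = "ecgsqi_error_argument")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must sum to 1.", class = "ecgsqi_error_argument")
  }
  structure(
    list(
      segment_length_samples = as.integer(segment_length_samples),
      match_tolerance_s = match_tolerance_s,
      psqi_limits_by_hr = psqi_limits_by_hr,
      csqi_thresholds = csqi_thresholds,
      ksqi_threshold = ksqi_threshold,
      bassqi_grade_bounds = bassqi_grade_bounds,
      weights = weights,
      decision_thresholds = decision_thresholds,
      membership_mode = membership_mode,
      synthesis_operator = synthesis_operator,
      acceptable_labels = acceptable_labels,
      rr_detector = rr_detector,
      rng_seed = as.integer(rng_seed)
    ),
    class = "sqi_config"
  )
}
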