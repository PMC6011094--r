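#' @title Fuzzy membership functions for the four retained indices
#' @description
#' Each retained index (qSQI, pSQI, kSQI, basSQI) is mapped to a membership
#' triple `(r_E, r_B, r_U)` — its degree of belonging to the Excellent,
#' Barely-acceptable and Unacceptable grades:
#'
#' * qSQI (percent scale): Excellent is a rising half-Cauchy (zero up to 80,
#'   `1 / (1 + (0.3 (q - 80))^-2)` on 80-90, then `q/100` to 100 — the 0.3
#'   scale makes the two branches meet at 0.9); Barely acceptable is a full
#'   Cauchy centred at 75 with scale 7.5; Unacceptable is 1 up to 55 then a
#'   falling Cauchy with centre 55 and scale 5, so that it equals 0.5 at 60.
#' * pSQI (fraction): trapezoids. In the default `continuity_corrected` mode
#'   the Excellent side rises linearly 0 to 1 over `[0.25, 0.35]` and the
#'   Unacceptable side falls 1 to 0 over `[0.15, 0.25]`; `literal` mode keeps
#'   the printed 0.1 slopes, which leave both functions discontinuous (they
#'   jump from 0.01 to 1) — see the vignette. The middle grade rises over
#'   `[0.18, 0.22]`, plateaus to 0.28 and falls to zero at 0.32 in both modes.
#' * kSQI: rectangular — `(1,0,0)` above 5, `(0,0,1)` otherwise.
#' * basSQI (percent scale, `b = 100 * basSQI`): same Cauchy shapes as qSQI
#'   with centres 90/92/85 and scales 0.8718 / 2.5 / 5; the 0.8718 scale makes
#'   the Excellent branches meet at 0.95.
#'
#' @param q qSQI in `[0, 100]`.
#' @param p pSQI in `[0, 1]`.
#' @param k kSQI (kurtosis).
#' @param b basSQI on the percent scale, `[0, 100]`.
#' @param mode Trapezoid slope convention for pSQI, see above.
#' @return A named numeric triple `c(E = , B = , U = )` in `[0, 1]^3`.
#' @name membership
NULL

#' @rdname membership
#' @export
membership_qsqi <- function(q) {
  if (!is.finite(q) || q < 0 || q > 100) {
    abort("qSQI must lie in [0, 100].", class = "ecgsqi_error_argument")
  }
  rE <- if (q <= 80) 0
        else if (q < 90) 1 / (1 + (0.3 * (q - 80))^-2)
        else q / 100
  rB <- 1 / (1 + ((q - 75) / 7.5)^2)
  rU <- if (q <= 55) 1 else 1 / (1 + ((q - 55) / 5)^2)
  c(E = rE, B = rB, U = rU)
}

#' @rdname membership
#' @export
membership_psqi <- function(p, mode = c("continuity_corrected", "literal")) {
  mode <- match.arg(mode)
  if (!is.finite(p) || p < 0 || p > 1) {
    abort("pSQI must lie in [0, 1].", class = "ecgsqi_error_argument")
  }
  slope <- if (mode == "continuity_corrected") 10 else 0.1
  rE <- if (p <= 0.25) 0
        else if (p < 0.35) slope * (p - 0.25)
        else 1
  rB <- if (p < 0.18) 0
        else if (p < 0.22) 25 * (p - 0.18)
        else if (p < 0.28) 1
        else if (p < 0.32) 25 * (0.32 - p)
        else 0
  rU <- if (p < 0.15) 1
        else if (p <= 0.25) slope * (0.25 - p)
        else 0
  c(E = min(1, rE), B = rB, U = min(1, rU))
}

#' @rdname membership
#' @export
membership_ksqi <- function(k) {
  if (!is.finite(k)) abort("kSQI must be finite.", class = "ecgsqi_error_argument")
  if (k > 5) c(E = 1, B = 0, U = 0) else c(E = 0, B = 0, U = 1)
}

#' @rdname membership
#' @export
membership_bassqi <- function(b) {
  if (!is.finite(b) || b < 0 || b > 100) {
    abort("basSQI (percent scale) must lie in [0, 100].",
          class = "ecgsqi_error_argument")
  }
  rE <- if (b <= 90) 0
        else if (b < 95) 1 / (1 + (0.8718 * (b - 90))^-2)
        else b / 100
  rB <- 1 / (1 + ((b - 92) / 2.5)^2)
  rU <- if (b <= 85) 1 else 1 / (1 + ((b - 85) / 5)^2)
  c(E = rE, B = rB, U = rU)
}

#' Assemble the 4x3 fuzzy evaluation matrix
#'
#' Stacks the membership rows of the four retained indices in the fixed order
#' qSQI, pSQI, kSQI, basSQI. basSQI is converted to the percent scale before
#' its membership functions are applied.
#'
#' @param sqis A one-row tibble (or list) with `qsqi`, `psqi`, `ksqi`,
#'   `bassqi`, as produced by [compute_sqis()].
#' @param mode pSQI trapezoid mode, see [membership_psqi()].
#' @return A 4x3 numeric matrix with rownames `qsqi`, `psqi`, `ksqi`,
#'   `bassqi` and colnames `E`, `B`, `U`.
#' @export
build_fuzzy_matrix <- function(sqis, mode = c("continuity_corrected", "literal")) {
  mode <- match.arg(mode)
  need <- c("qsqi", "psqi", "ksqi", "bassqi")
  vals <- vapply(need, function(nm) as.numeric(sqis[[nm]][1L]), numeric(1))
  if (any(!is.finite(vals))) {
    undefined_index(sprintf("undefined SQI(s): %s",
                            paste(need[!is.finite(vals)], collapse = ", ")))
  }
  R <- rbind(
    qsqi = membership_qsqi(vals[["qsqi"]]),
    psqi = membership_psqi(vals[["psqi"]], mode),
    ksqi = membership_ksqi(vals[["ksqi"]]),
    bassqi = membership_bassqi(100 * vals[["bassqi"]])
  )
  colnames(R) <- c("E", "B", "U")
  R
}

#' Fuzzy synthesis S = W o R
#'
#' Combines the weight vector with the membership matrix. The default
#' `"bounded"` operator (weighted bounded sum, M(., +)) gives
#' `s_j = min(1, sum_i w_i r_ij)`; because the weights sum to 1 and every
#' membership is at most 1, the bound never truncates and the result equals
#' the plain weighted mean. The classical alternatives are provided as
#' options.
#'
#' @param weights Numeric weights for the four rows, summing to 1.
#' @param R A 4x3 membership matrix from [build_fuzzy_matrix()].
#' @param operator Synthesis operator.
#' @return Numeric triple `(s_E, s_B, s_U)` in `[0, 1]^3`.
#' @export
synthesize <- function(weights, R,
                       operator = c("bounded", "max_min", "max_prod", "bounded_min")) {
  operator <- match.arg(operator)
  stopifnot(is.matrix(R), nrow(R) == length(weights))
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    abort("weights must be non-negative and sum to 1.",
          class = "ecgsqi_error_argument")
  }
  s <- switch(operator,
    bounded = pmin(1, as.numeric(weights %*% R)),
    max_min = apply(pmin(R, weights), 2, max),
    max_prod = apply(R * weights, 2, max),
    bounded_min = pmin(1, colSums(pmin(R, weights)))
  )
  stats::setNames(as.numeric(s), colnames(R))
}

#' Weighted-membership decision
#'
#' Collapses the synthesis vector to a scalar decision score
#' `v = sum_j j * s_j^2 / sum_j s_j^2` with grade indices E=1, B=2, U=3, and
#' thresholds it: Excellent for `v <= v_th1`, Unacceptable for `v >= v_th2`,
#' Barely acceptable in between (defaults 1.50 and 2.40).
#'
#' @param s Synthesis triple from [synthesize()].
#' @param thresholds `(v_th1, v_th2)`.
#' @return A list of class `quality_decision` with `v`, `label`, `s`.
#' @export
decide_quality <- function(s, thresholds = c(1.50, 2.40)) {
  stopifnot(length(s) == 3L, all(is.finite(s)), all(s >= 0))
  if (sum(s) == 0) {
    warn("all-zero synthesis vector; reporting Unacceptable.",
         class = "ecgsqi_warning_degenerate")
    return(structure(list(v = NA_real_, label = "U", s = s),
                     class = "quality_decision"))
  }
  v <- sum(seq_len(3L) * s^2) / sum(s^2)
  label <- if (v <= thresholds[1]) "E" else if (v < thresholds[2]) "B" else "U"
  structure(list(v = v, label = label, s = s), class = "quality_decision")
}

#' @export
print.quality_decision <- function(x, ...) {
  cat(sprintf("<quality_decision> v=%.3f label=%s S=(%.3f, %.3f, %.3f)\n",
              x$v, x$label, x$s[1], x$s[2], x$s[3]))
  invisible(x)
}

#' Follow-up recommendation
#'
#' Post-assessment triage: Excellent segments are accepted as-is; an
#' Unacceptable verdict with unqualified kurtosis or baseline power points to
#' removable noise (denoise and reassess), whereas unqualified detector
#' agreement or QRS band power calls for re-collection; Barely acceptable
#' segments are flagged for a second-pass reassessment.
#'
#' @param label `"E"`, `"B"` or `"U"`.
#' @param grades Named grades as produced by [compute_sqis()]
#'   (`grade_qsqi`, `grade_psqi`, `grade_ksqi`, `grade_bassqi`).
#' @return One of `"accept"`, `"denoise_and_reassess"`, `"recollect"`,
#'   `"reassess"`.
#' @export
recommend_action <- function(label, grades) {
  unq <- function(nm) identical(grades[[nm]][1L], "unqualified")
  switch(label,
    E = "accept",
    B = "reassess",
    U = if (unq("grade_ksqi") || unq("grade_bassqi")) "denoise_and_reassess"
        else if (unq("grade_qsqi") || unq("grade_psqi")) "recollect"
        else "denoise_and_reassess",
    abort("unknown label.", class = "ecgsqi_error_argument")
  )
}

#' Evaluate one segment end to end
#'
#' Full chain: SQI extraction, fuzzy matrix, synthesis, decision,
#' recommendation. If any of the four retained indices is undefined on the
#' segment (flatline, no detectable beats, zero power), the segment is
#' reported Unacceptable with `v = NA`.
#'
#' @param record An [ecg_record()].
#' @param config An [sqi_config()].
#' @return A one-row tibble: source id, SQI values and grades, the synthesis
#'   triple `s1..s3`, decision score `v`, `label`, `recommendation`.
#' @examples
#' rec <- generate_clean(synth_spec(duration_s = 30))$record
#' evaluate_segment(rec)
#' @export
evaluate_segment <- function(record, config = sqi_config()) {
  sq <- compute_sqis(record, config)
  res <- tryCatch({
    R <- build_fuzzy_matrix(sq, config$membership_mode)
    s <- synthesize(config$weights, R, config$synthesis_operator)
    suppressWarnings(decide_quality(s, config$decision_thresholds))
  }, ecgsqi_error_undefined_index = function(e) {
    structure(list(v = NA_real_, label = "U", s = c(E = 0, B = 0, U = 1)),
              class = "quality_decision")
  })
  mutate(sq,
         s1 = res$s[[1L]], s2 = res$s[[2L]], s3 = res$s[[3L]],
         v = res$v, label = res$label,
         recommendation = recommend_action(res$label, sq))
}
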