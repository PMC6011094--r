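#' Repeated stratified 10-fold cross-validation of a quality classifier
#'
#' Evaluates either the fuzzy comprehensive evaluation or the heuristic
#' rule-table fusion against the construction-time labels of a synthetic
#' dataset. Folds are stratified by class so each preserves the label
#' distribution; the whole procedure is repeated with fresh random fold
#' assignments and the grand mean over repeats is reported, as is standard for
#' repeated k-fold validation. The classifiers have no trainable parameters,
#' so a "fold" is purely an evaluation subset; per-fold metrics are averaged
#' per repeat and then across repeats.
#'
#' Three-level labels are binarised before scoring: labels in
#' `config$acceptable_labels` (default E and B) count as acceptable.
#'
#' @param dataset A list of `labeled_ecg` objects (>= 20, >= 2 classes).
#' @param method `"fuzzy"` or `"heuristic"` (4-index rule table).
#' @param repeats Number of CV repeats (default 10).
#' @param folds Folds per repeat (default 10; reduced with a warning when the
#'   rarest class has fewer members).
#' @param seed Integer seed for the fold assignments.
#' @param config An [sqi_config()].
#' @param assessments Optional precomputed result of [assess_quality()] on
#'   `dataset`, to avoid recomputation across harness calls.
#' @return An object of class `cv_result`; see [tidy.cv_result()] and
#'   [glance.cv_result()].
#' @export
cross_validate <- function(dataset, method = c("fuzzy", "heuristic"),
                           repeats = 10L, folds = 10L, seed = 1L,
                           config = sqi_config(), assessments = NULL) {
  method <- match.arg(method)
  if (length(dataset) < 20L) {
    abort("cross-validation needs at least 20 records.",
          class = "ecgsqi_error_argument")
  }
  truth <- vapply(dataset, function(d) d$intended_label, character(1))
  if (length(unique(truth)) < 2L) {
    abort("dataset must contain at least two classes.",
          class = "ecgsqi_error_argument")
  }
  if (is.null(assessments)) assessments <- assess_quality(dataset, config)
  if (nrow(assessments) != length(dataset)) {
    abort("`assessments` must have exactly one row per dataset record.",
          class = "ecgsqi_error_argument")
  }
  pred <- predict_labels(assessments, method, config)
  # canonical ordering by record id so the folds (hence the result) do not
  # depend on how the dataset list happens to be ordered
  ids <- vapply(dataset, function(d) d$record$source_id, character(1))
  ord <- order(ids)
  truth <- truth[ord]
  pred <- pred[ord]
  min_class <- min(table(truth))
  if (min_class < folds) {
    warn(sprintf("rarest class has %d members; reducing folds to %d.",
                 min_class, min_class), class = "ecgsqi_warning_stratification")
    folds <- min_class
  }
  assignments <- vector("list", repeats)
  per_fold <- with_seed(seed, {
    purrr::map(seq_len(repeats), function(rep_i) {
      fold_idx <- caret::createFolds(factor(truth), k = folds)
      assignments[[rep_i]] <<- fold_idx
      purrr::imap(fold_idx, function(test_ids, fold_name) {
        m <- label_confusion(pred[test_ids], truth[test_ids],
                             config$acceptable_labels)
        mutate(m, repeat_i = rep_i, fold = fold_name,
               n_test = length(test_ids))
      }) |> bind_rows()
    }) |> bind_rows()
  })
  structure(list(per_fold = per_fold, fold_assignments = assignments,
                 method = method, repeats = repeats,
                 folds = folds, n = length(dataset), seed = seed),
            class = "cv_result")
}

predict_labels <- function(assessments, method, config) {
  if (method == "fuzzy") return(assessments$label)
  vapply(seq_len(nrow(assessments)), function(i) {
    fuse_heuristic(c(assessments$grade_qsqi[i], assessments$grade_psqi[i],
                     assessments$grade_ksqi[i], assessments$grade_bassqi[i]))
  }, character(1))
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cv_result> %s: %d x %d-fold CV on %d records\n",
              x$method, x$repeats, x$folds, x$n))
  cat(sprintf("  Acc %.2f%% (SD %.2f), Se %.2f%%, Sp %.2f%%\n",
              g$acc, g$acc_sd, g$se, g$sp))
  invisible(x)
}

#' Per-fold cross-validation metrics
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per repeat and fold: `se`, `sp`, `acc`,
#'   `repeat_i`, `fold`, `n_test`.
#' @export
tidy.cv_result <- function(x, ...) as_tibble(x$per_fold)

#' Grand-mean cross-validation summary
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble: grand means `acc`, `se`, `sp` (of per-repeat
#'   means), their SDs across repeats, and the design sizes.
#' @export
glance.cv_result <- function(x, ...) {
  per_rep <- x$per_fold |>
    group_by(.data$repeat_i) |>
    summarise(acc = mean(.data$acc, na.rm = TRUE),
              se = mean(.data$se, na.rm = TRUE),
              sp = mean(.data$sp, na.rm = TRUE), .groups = "drop")
  tibble(acc = mean(per_rep$acc), acc_sd = sd(per_rep$acc),
         se = mean(per_rep$se), se_sd = sd(per_rep$se),
         sp = mean(per_rep$sp), sp_sd = sd(per_rep$sp),
         repeats = x$repeats, folds = x$folds, n = x$n, method = x$method)
}

#' Sweep candidate fuzzy weight vectors
#'
#' Runs the cross-validation harness once per candidate weight vector and
#' tabulates the grand-mean accuracy, mirroring the empirical selection of
#' the default weights (0.4, 0.4, 0.1, 0.1).
#'
#' @param dataset A list of `labeled_ecg` objects.
#' @param candidate_weights List of length-4 numeric vectors, each summing
#'   to 1.
#' @param ... Passed to [cross_validate()].
#' @param config Base [sqi_config()]; its weights are replaced per candidate.
#' @return A tibble with one row per candidate: `w1..w4`, `acc`, `acc_sd`,
#'   `se`, `sp`, and `best` marking the argmax-accuracy row.
#' @export
weight_sweep <- function(dataset, candidate_weights, config = sqi_config(), ...) {
  stopifnot(is.list(candidate_weights), length(candidate_weights) >= 1L)
  for (w in candidate_weights) {
    if (length(w) != 4L || abs(sum(w) - 1) > 1e-9 || any(w < 0)) {
      abort("each candidate must be 4 non-negative weights summing to 1.",
            class = "ecgsqi_error_argument")
    }
  }
  # SQIs do not depend on the weights; compute them once
  sq <- assess_quality(dataset, config)
  rows <- purrr::map(candidate_weights, function(w) {
    cfg <- config
    cfg$weights <- w
    reassessed <- reweight_assessments(sq, cfg)
    cv <- cross_validate(dataset, "fuzzy", config = cfg,
                         assessments = reassessed, ...)
    g <- glance(cv)
    tibble(w1 = w[1], w2 = w[2], w3 = w[3], w4 = w[4],
           acc = g$acc, acc_sd = g$acc_sd, se = g$se, sp = g$sp)
  }) |> bind_rows()
  mutate(rows, best = dplyr::row_number() == which.max(rows$acc))
}

# recompute synthesis/decision columns from stored SQI values under a new
# weight vector without re-running detectors or spectra
reweight_assessments <- function(assessments, config) {
  purrr::map(seq_len(nrow(assessments)), function(i) {
    row <- assessments[i, ]
    res <- tryCatch({
      R <- build_fuzzy_matrix(row, config$membership_mode)
      s <- synthesize(config$weights, R, config$synthesis_operator)
      suppressWarnings(decide_quality(s, config$decision_thresholds))
    }, ecgsqi_error_undefined_index = function(e) {
      structure(list(v = NA_real_, label = "U", s = c(E = 0, B = 0, U = 1)),
                class = "quality_decision")
    })
    mutate(row, s1 = res$s[[1]], s2 = res$s[[2]], s3 = res$s[[3]],
           v = res$v, label = res$label,
           recommendation = recommend_action(res$label, row))
  }) |> bind_rows()
}

#' ROC over the decision-score threshold
#'
#' Varies the Excellent/Barely-acceptable acceptance threshold on the decision
#' score `v` over a grid in `[1, 3]`: at each threshold, windows with
#' `v <= threshold` are called acceptable and Se/Sp/Acc are computed against
#' the construction-time labels. Windows with undefined `v` (degenerate
#' segments) are always unacceptable.
#'
#' @param dataset A list of `labeled_ecg` objects.
#' @param grid Numeric thresholds within `[1, 3]`.
#' @param config An [sqi_config()].
#' @param assessments Optional precomputed [assess_quality()] output.
#' @return An object of class `roc_curve_v`: tibble of `threshold`, `se`,
#'   `sp`, `acc` with the argmax-accuracy threshold in attribute `"best"`.
#' @export
roc_over_v <- function(dataset, grid = seq(1, 3, by = 0.05),
                       config = sqi_config(), assessments = NULL) {
  if (length(grid) == 0L) {
    abort("threshold grid must be non-empty.", class = "ecgsqi_error_argument")
  }
  stopifnot(all(grid >= 1), all(grid <= 3))
  if (is.null(assessments)) assessments <- assess_quality(dataset, config)
  truth <- assessments$intended_label
  v <- assessments$v
  rows <- purrr::map(sort(grid), function(th) {
    pred <- ifelse(!is.na(v) & v <= th, "E", "U")
    mutate(label_confusion(pred, truth, config$acceptable_labels),
           threshold = th, .before = 1L)
  }) |> bind_rows()
  best <- rows$threshold[which.max(rows$acc)]
  structure(rows, best = best, class = c("roc_curve_v", class(rows)))
}

#' @export
print.roc_curve_v <- function(x, ...) {
  cat(sprintf("<roc_curve_v> %d thresholds; best accuracy %.2f%% at v <= %.2f\n",
              nrow(x), max(x$acc, na.rm = TRUE), attr(x, "best")))
  NextMethod()
}
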