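#' Heuristic rule-table fusion of SQI grades
#'
#' Fuses the three-level grades of 2-5 entered indices into an overall
#' Excellent / Barely acceptable / Unacceptable label using fixed rule tables
#' keyed on the counts of `"optimal"`, `"suspicious"` and `"unqualified"`
#' grades. The tables (one per number of entered indices) are applied exactly
#' as published; the Excellent clause is checked first, then Unacceptable,
#' with Barely acceptable as the residual class — except for the two-index
#' table, where Unacceptable is the residual.
#'
#' @param grades Character vector of 2-5 grades from
#'   `c("optimal", "suspicious", "unqualified")`.
#' @return A single label: `"E"`, `"B"` or `"U"`.
#' @examples
#' fuse_heuristic(c("optimal", "optimal", "optimal", "suspicious"))  # "E"
#' @export
fuse_heuristic <- function(grades) {
  k <- length(grades)
  if (k < 2L || k > 5L) {
    abort("heuristic fusion takes 2 to 5 grades.", class = "ecgsqi_error_argument")
  }
  if (!all(grades %in% c("optimal", "suspicious", "unqualified"))) {
    abort("grades must be optimal/suspicious/unqualified.",
          class = "ecgsqi_error_argument")
  }
  o <- sum(grades == "optimal")
  s <- sum(grades == "suspicious")
  u <- sum(grades == "unqualified")
  switch(as.character(k),
    "2" = if (o == 2L) "E"
          else if (s == 2L || (o == 1L && s == 1L)) "B"
          else "U",
    "3" = if (o >= 2L && u == 0L) "E"
          else if (u == 2L || (s == 2L && u == 1L)) "U"
          else "B",
    "4" = if (o >= 3L && u == 0L) "E"
          else if (u >= 3L || (u == 2L && s >= 1L) || (u == 1L && s == 3L)) "U"
          else "B",
    "5" = if (o >= 4L && u == 0L) "E"
          else if (u >= 4L || (u == 3L && s >= 1L) || (u == 2L && s >= 2L) ||
                   (u == 1L && s == 4L)) "U"
          else "B"
  )
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`, `Acc = (TP+TN)/(TP+TN+FP+FN)`, all as
#' percentages. "Positive" is the acceptable-quality class. A metric whose
#' denominator is zero is returned as `NA` rather than raising an error.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A one-row tibble with columns `se`, `sp`, `acc` (percent).
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tot <- tp + tn + fp + fn
  tibble(
    se = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    acc = if (tot > 0) 100 * (tp + tn) / tot else NA_real_
  )
}

# binary confusion between predicted and true E/B/U labels, given the label
# set treated as "acceptable"
label_confusion <- function(pred, truth, acceptable = c("E", "B")) {
  p <- pred %in% acceptable
  t <- truth %in% acceptable
  confusion_metrics(tp = sum(p & t), tn = sum(!p & !t),
                    fp = sum(p & !t), fn = sum(!p & t))
}
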