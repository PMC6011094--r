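#' Assess the quality of ECG records
#'
#' The main user-facing entry point. Takes any mix of `ecg_record`s,
#' `labeled_ecg`s and file paths (WFDB headers or one-column CSVs), cuts each
#' record into fixed-length analysis windows, and evaluates every window with
#' the fuzzy comprehensive evaluation chain. Records shorter than one window
#' are assessed whole.
#'
#' @param x A single record/path or a list of them.
#' @param config An [sqi_config()]; `segment_length_samples` controls the
#'   windowing.
#' @param fs Sampling rate, required for CSV paths only.
#' @param segment Whether to window long records (default TRUE).
#' @return A tibble with one row per analysed window: SQI values and grades,
#'   synthesis triple, decision score `v`, `label`, `recommendation`, plus an
#'   `intended_label` column when the input carries construction-time labels.
#' @examples
#' ds <- generate_dataset(2, seed = 42)
#' assess_quality(ds)[, c("source_id", "v", "label", "intended_label")]
#' @export
assess_quality <- function(x, config = sqi_config(), fs = NULL, segment = TRUE) {
  items <- if (inherits(x, c("ecg_record", "labeled_ecg")) || is.character(x) &&
               length(x) == 1L) list(x) else x
  rows <- purrr::map(items, function(item) {
    intended <- NA_character_
    if (inherits(item, "labeled_ecg")) {
      intended <- item$intended_label
      item <- item$record
    } else if (is.character(item)) {
      item <- if (grepl("\\.hea$", item) || file.exists(paste0(item, ".hea"))) {
        read_wfdb(item)
      } else {
        if (is.null(fs)) {
          abort("`fs` is required to read CSV records.",
                class = "ecgsqi_error_argument")
        }
        read_ecg_csv(item, fs = fs)
      }
    }
    stopifnot(inherits(item, "ecg_record"))
    wins <- if (segment && length(item$samples) > config$segment_length_samples) {
      segment_ecg(item, config$segment_length_samples)
    } else list(item)
    if (length(wins) == 0L) wins <- list(item)
    purrr::map(wins, evaluate_segment, config = config) |>
      bind_rows() |>
      mutate(intended_label = intended)
  })
  bind_rows(rows)
}
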