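separable_ds <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- generate_dataset(10, seed = 101)
    ds
  }
})
separable_sq <- local({
  sq <- NULL
  function() {
    if (is.null(sq)) sq <<- suppressWarnings(assess_quality(separable_ds()))
    sq
  }
})

test_that("a separable dataset cross-validates at 100% accuracy", {
  cv <- cross_validate(separable_ds(), "fuzzy", repeats = 3, seed = 2,
                       assessments = separable_sq())
  g <- glance(cv)
  expect_equal(g$acc, 100)
  expect_equal(g$se, 100)
  expect_equal(g$sp, 100)

  cvh <- cross_validate(separable_ds(), "heuristic", repeats = 3, seed = 2,
                        assessments = separable_sq())
  expect_equal(glance(cvh)$acc, 100)
})

test_that("shuffled labels collapse accuracy to chance level", {
  ds <- separable_ds()
  truth <- vapply(ds, function(d) d$intended_label, character(1))
  # average the CV grand mean over several independent label permutations:
  # one 20-record shuffle has ~11-point sampling spread, the average is tight
  accs <- vapply(1:6, function(i) {
    set.seed(990 + i)
    labs <- sample(truth)
    shuffled <- purrr::map2(ds, labs, function(d, l) {
      d$intended_label <- l
      d
    })
    sq <- separable_sq()
    sq$intended_label <- labs
    glance(cross_validate(shuffled, "fuzzy", repeats = 2, seed = 2,
                          assessments = sq))$acc
  }, numeric(1))
  expect_gte(mean(accs), 40)
  expect_lte(mean(accs), 60)
})

test_that("each repeat's folds partition the dataset exactly", {
  cv <- cross_validate(separable_ds(), "fuzzy", repeats = 3, seed = 7,
                       assessments = separable_sq())
  for (folds in cv$fold_assignments) {
    expect_length(folds, 10L)
    all_ids <- sort(unlist(folds, use.names = FALSE))
    expect_identical(all_ids, seq_along(separable_ds()))  # disjoint + exhaustive
  }
})

test_that("the grand mean does not depend on dataset ordering", {
  ds <- separable_ds()
  sq <- separable_sq()
  perm <- rev(seq_along(ds))
  cv1 <- cross_validate(ds, "fuzzy", repeats = 2, seed = 3, assessments = sq)
  cv2 <- cross_validate(ds[perm], "fuzzy", repeats = 2, seed = 3,
                        assessments = sq[perm, ])
  expect_equal(glance(cv1)$acc, glance(cv2)$acc)
})

test_that("cross-validation is reproducible and validates its inputs", {
  cv1 <- cross_validate(separable_ds(), "fuzzy", repeats = 2, seed = 5,
                        assessments = separable_sq())
  cv2 <- cross_validate(separable_ds(), "fuzzy", repeats = 2, seed = 5,
                        assessments = separable_sq())
  expect_identical(tidy(cv1), tidy(cv2))
  expect_error(cross_validate(separable_ds()[1:5], "fuzzy"),
               class = "ecgsqi_error_argument")
  one_class <- generate_dataset(10, seed = 1, classes = "E")
  expect_error(cross_validate(one_class, "fuzzy", repeats = 1),
               class = "ecgsqi_error_argument")
})

test_that("weight sweep tabulates candidates and matches single-candidate CV", {
  ds <- separable_ds()
  cands <- list(c(0.4, 0.4, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))
  tab <- suppressWarnings(weight_sweep(ds, cands, repeats = 2, seed = 4))
  expect_identical(nrow(tab), 2L)
  expect_identical(sum(tab$best), 1L)

  single <- suppressWarnings(weight_sweep(ds, cands[1], repeats = 2, seed = 4))
  cv <- cross_validate(ds, "fuzzy", repeats = 2, seed = 4,
                       assessments = separable_sq())
  expect_equal(single$acc, glance(cv)$acc)

  expect_error(weight_sweep(ds, list(c(0.5, 0.5, 0.5, 0.5))),
               class = "ecgsqi_error_argument")
})

test_that("the ROC over v has valid corners and recovers the fixed threshold", {
  ds <- separable_ds()
  sq <- separable_sq()
  roc <- roc_over_v(ds, grid = c(1, 1.5, 2.4, 3), assessments = sq)
  expect_equal(max(roc$acc), 100)

  corner_lo <- roc[roc$threshold == 1, ]   # almost nothing accepted
  expect_equal(corner_lo$sp, 100)
  corner_hi <- roc[roc$threshold == 3, ]   # everything with defined v accepted
  expect_equal(corner_hi$se, 100)

  single <- roc_over_v(ds, grid = 1.5, assessments = sq)
  pred <- ifelse(!is.na(sq$v) & sq$v <= 1.5, "E", "U")
  manual <- ecgsqi:::label_confusion(pred, sq$intended_label)
  expect_equal(single$acc, manual$acc)

  expect_error(roc_over_v(ds, grid = numeric(0)),
               class = "ecgsqi_error_argument")
})

test_that("assessment pipeline windows long records and reads files", {
  lab <- clean_record(seed = 44, duration_s = 65)
  res <- suppressWarnings(assess_quality(lab$record))
  expect_identical(nrow(res), 2L)  # two full 9000-sample windows
  expect_true(all(res$label %in% c("E", "B", "U")))

  dir <- withr::local_tempdir()
  csv <- file.path(dir, "rec.csv")
  write_ecg_csv(segment_ecg(lab$record, 9000)[[1]], csv)
  res_csv <- suppressWarnings(assess_quality(csv, fs = 300))
  expect_identical(nrow(res_csv), 1L)
  expect_identical(res_csv$label, "E")
  expect_error(suppressWarnings(assess_quality(csv)),
               class = "ecgsqi_error_argument")
})
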