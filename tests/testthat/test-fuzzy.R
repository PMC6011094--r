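test_that("qSQI membership hits its anchor values", {
  expect_equal(membership_qsqi(60)[["U"]], 0.5)
  expect_equal(membership_qsqi(100)[["E"]], 1)
  expect_equal(membership_qsqi(75)[["B"]], 1)
  expect_equal(membership_qsqi(90)[["E"]], 0.9)
  expect_equal(membership_qsqi(80)[["E"]], 0)
  expect_equal(membership_qsqi(50)[["U"]], 1)
  expect_error(membership_qsqi(120), class = "ecgsqi_error_argument")
})

test_that("pSQI trapezoids: plateaus, corrected midpoints, literal mode", {
  expect_equal(membership_psqi(0.40)[["E"]], 1)
  expect_equal(membership_psqi(0.25)[["B"]], 1)
  expect_equal(membership_psqi(0.10)[["U"]], 1)
  expect_equal(membership_psqi(0.30)[["E"]], 0.5)   # midpoint of the rise
  expect_equal(membership_psqi(0.20)[["U"]], 0.5)
  expect_equal(membership_psqi(0.20)[["B"]], 0.5)   # 25 * (0.20 - 0.18)
  # literal mode keeps the printed 0.1 slopes
  expect_equal(membership_psqi(0.30, mode = "literal")[["E"]], 0.005)
  expect_equal(membership_psqi(0.20, mode = "literal")[["U"]], 0.005)
  expect_equal(membership_psqi(0.40, mode = "literal")[["E"]], 1)
})

test_that("kSQI membership is rectangular at the kurtosis cut", {
  expect_equal(membership_ksqi(6.0), c(E = 1, B = 0, U = 0))
  expect_equal(membership_ksqi(5.0), c(E = 0, B = 0, U = 1))
  expect_equal(membership_ksqi(3.0), c(E = 0, B = 0, U = 1))
})

test_that("basSQI membership anchors, including the continuity-fixing scale", {
  expect_equal(membership_bassqi(92)[["B"]], 1)
  expect_equal(membership_bassqi(90)[["U"]], 0.5)
  expect_equal(membership_bassqi(95)[["E"]], 0.95, tolerance = 1e-3)
  # both branches of the Excellent function agree at 95
  rising <- 1 / (1 + (0.8718 * (95 - 90))^-2)
  expect_equal(rising, 95 / 100, tolerance = 1e-3)
  expect_equal(membership_bassqi(85)[["U"]], 1)
  expect_equal(membership_bassqi(100)[["E"]], 1)
})

test_that("memberships stay in [0,1] and are monotone where they should be", {
  qs <- seq(0, 100, length.out = 2001)
  mq <- t(vapply(qs, membership_qsqi, numeric(3)))
  expect_true(all(mq >= 0 & mq <= 1))
  expect_true(all(diff(mq[, "E"]) >= -1e-12))   # U_qH non-decreasing
  expect_true(all(diff(mq[, "U"]) <= 1e-12))    # U_qJ non-increasing

  bs <- seq(0, 100, length.out = 2001)
  mb <- t(vapply(bs, membership_bassqi, numeric(3)))
  expect_true(all(mb >= 0 & mb <= 1))
  expect_true(all(diff(mb[, "E"]) >= -1e-12))
  expect_true(all(diff(mb[, "U"]) <= 1e-12))

  ps <- seq(0, 1, length.out = 2001)
  mp <- t(vapply(ps, membership_psqi, numeric(3)))
  expect_true(all(mp >= 0 & mp <= 1))
})

test_that("fuzzy matrix stacks the four rows with basSQI on the percent scale", {
  perfect <- tibble::tibble(qsqi = 100, psqi = 0.40, ksqi = 7, bassqi = 1.0)
  R <- build_fuzzy_matrix(perfect)
  expect_identical(dim(R), c(4L, 3L))
  expect_equal(unname(R[, "E"]), rep(1, 4))
  expect_equal(unname(R["ksqi", ]), c(1, 0, 0))

  awful <- tibble::tibble(qsqi = 50, psqi = 0.05, ksqi = 3, bassqi = 0.5)
  expect_equal(unname(build_fuzzy_matrix(awful)[, "U"]), rep(1, 4))

  undef <- tibble::tibble(qsqi = NA_real_, psqi = 0.4, ksqi = 7, bassqi = 1)
  expect_error(build_fuzzy_matrix(undef), class = "ecgsqi_error_undefined_index")
})

test_that("bounded synthesis equals the weighted mean and honours hand cases", {
  w <- c(0.4, 0.4, 0.1, 0.1)
  allE <- matrix(rep(c(1, 0, 0), each = 4), 4, dimnames = list(NULL, c("E", "B", "U")))
  expect_equal(unname(synthesize(w, allE)), c(1, 0, 0))
  allU <- allE[, c(3, 2, 1)]
  colnames(allU) <- c("E", "B", "U")
  expect_equal(unname(synthesize(w, allU)), c(0, 0, 1))

  R <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  colnames(R) <- c("E", "B", "U")
  expect_equal(unname(synthesize(w, R)), c(0.5, 0.4, 0.1))

  set.seed(4)
  for (i in 1:20) {
    Rr <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("E", "B", "U")))
    wr <- runif(4); wr <- wr / sum(wr)
    expect_equal(unname(synthesize(wr, Rr)), as.numeric(wr %*% Rr))
    for (op in c("max_min", "max_prod", "bounded_min")) {
      s <- synthesize(wr, Rr, operator = op)
      expect_true(all(s >= 0 & s <= 1))
    }
  }
  expect_error(synthesize(c(0.5, 0.5, 0.5, 0.5), R), class = "ecgsqi_error_argument")
})

test_that("the decision score is a squared-weighted grade index in [1,3]", {
  expect_equal(decide_quality(c(1, 0, 0))$v, 1)
  expect_identical(decide_quality(c(1, 0, 0))$label, "E")
  expect_equal(decide_quality(c(0, 0, 1))$v, 3)
  expect_identical(decide_quality(c(0, 0, 1))$label, "U")

  d <- decide_quality(c(0.5, 0.4, 0.1))
  expect_equal(d$v, (0.25 + 2 * 0.16 + 3 * 0.01) / 0.42, tolerance = 1e-12)
  expect_equal(d$v, 1.4286, tolerance = 1e-4)
  expect_identical(d$label, "E")

  set.seed(6)
  for (i in 1:50) {
    s <- runif(3)
    expect_true(dplyr::between(decide_quality(s)$v, 1, 3))
  }
  expect_warning(dz <- decide_quality(c(0, 0, 0)),
                 class = "ecgsqi_warning_degenerate")
  expect_identical(dz$label, "U")
})

test_that("row/weight permutation leaves the decision unchanged", {
  set.seed(11)
  R <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("E", "B", "U")))
  w <- c(0.4, 0.3, 0.2, 0.1)
  perm <- c(3, 1, 4, 2)
  v1 <- decide_quality(synthesize(w, R))$v
  v2 <- decide_quality(synthesize(w[perm], R[perm, ]))$v
  expect_equal(v1, v2)
})

test_that("recommendations follow the post-assessment triage", {
  g <- function(k = "optimal", b = "optimal", q = "optimal", p = "optimal") {
    tibble::tibble(grade_qsqi = q, grade_psqi = p, grade_ksqi = k, grade_bassqi = b)
  }
  expect_identical(recommend_action("E", g()), "accept")
  expect_identical(recommend_action("B", g()), "reassess")
  expect_identical(recommend_action("U", g(k = "unqualified")), "denoise_and_reassess")
  expect_identical(recommend_action("U", g(q = "unqualified")), "recollect")
  expect_identical(recommend_action("U", g(k = "unqualified", q = "unqualified")),
                   "denoise_and_reassess")
})

test_that("end-to-end evaluation separates clean, EMG-heavy and mild-drift segments", {
  clean <- suppressWarnings(evaluate_segment(clean_record(seed = 3)$record))
  expect_identical(clean$label, "E")
  expect_identical(clean$recommendation, "accept")

  emg <- suppressWarnings(evaluate_segment(
    noisy_record(c(emg = 1.2), seed = 11)$record))
  expect_identical(emg$label, "U")

  mild <- suppressWarnings(evaluate_segment(
    noisy_record(c(baseline_wander = 0.1), seed = 9)$record))
  expect_true(mild$label %in% c("E", "B"))
})

test_that("evaluation is deterministic and degenerate input maps to U", {
  rec <- clean_record(seed = 17)$record
  expect_identical(suppressWarnings(evaluate_segment(rec)),
                   suppressWarnings(evaluate_segment(rec)))

  flat <- suppressWarnings(evaluate_segment(ecg_record(rep(1, 9000), fs = 300)))
  expect_identical(flat$label, "U")
  expect_true(is.na(flat$v))
})
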