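meta4 <- make_meta(4L)

test_that("presence/absence screen implements the min-detected rule", {
  vals <- matrix(1, nrow = 3, ncol = 8,
                 dimnames = list(c("pyr_like", "complete", "partial"), NULL))
  vals["pyr_like", 5:8] <- NA       # MUT all missing
  vals["partial", c(3, 4)] <- NA    # only 2 of 4 WT values
  m <- make_am(vals, meta4)
  scr <- presence_absence_screen(m, min_detected = 3L)
  expect_identical(scr$detection[scr$feature_id == "pyr_like"], "WT_only")
  expect_identical(scr$detection[scr$feature_id == "complete"], "both")
  expect_identical(scr$detection[scr$feature_id == "partial"], "MUT_only")
  expect_error(presence_absence_screen(m, min_detected = 5L),
               "exceeds group size")
})

test_that("log2 fold change is log2 of the MUT/WT mean ratio", {
  m <- make_am(matrix(c(2, 2, 4, 4,     # means WT 2, MUT 4
                        3, 3, 3, 3,     # equal means
                        2, 2, 3, 3),    # MUT 3 / WT 2
                      nrow = 3, byrow = TRUE), make_meta(2L))
  fc <- log2_fold_change(m)
  expect_equal(unname(fc), c(1, 0, log2(1.5)), tolerance = 1e-12)
})

test_that("Student t-test matches its closed-form cases", {
  # identical groups: t = 0, p = 1
  m_id <- am_from_log2(matrix(1:4, 1), matrix(1:4, 1), meta4)
  expect_equal(ttest_two_sample(m_id)$p_value, 1)
  # [1,2,3,4] vs [3,4,5,6]: t = -2.1909, df = 6 (oracle: Student CDF)
  m_ab <- am_from_log2(matrix(c(3, 4, 5, 6), 1), matrix(1:4, 1), meta4)
  res <- ttest_two_sample(m_ab)
  expect_equal(res$df, 6)
  expect_equal(res$t, -2.1909, tolerance = 1e-4)
  expect_equal(res$p_value, 2 * stats::pt(-2.1908902300206643, 6),
               tolerance = 1e-9)
  expect_equal(res$p_value, 0.071, tolerance = 1e-2)
  # two-sided symmetry under group swap
  m_ba <- am_from_log2(matrix(1:4, 1), matrix(c(3, 4, 5, 6), 1), meta4)
  expect_equal(ttest_two_sample(m_ba)$p_value, res$p_value)
})

test_that("t-test agrees with a brute-force textbook oracle on random fixtures", {
  set.seed(101)
  for (i in 1:100) {
    wt <- matrix(stats::rnorm(4, 8, 1), 1)
    mut <- matrix(stats::rnorm(4, 8.5, 1.3), 1)
    m <- am_from_log2(wt, mut, meta4)
    got <- ttest_two_sample(m)$p_value
    expect_equal(got, oracle_student_t(drop(mut), drop(wt)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate variance cases follow the stated conventions", {
  m_same <- am_from_log2(matrix(c(2, 2, 2, 2), 1), matrix(c(2, 2, 2, 2), 1),
                         meta4)
  expect_equal(ttest_two_sample(m_same)$p_value, 1)
  m_diff <- am_from_log2(matrix(c(2, 2, 2, 2), 1), matrix(c(3, 3, 3, 3), 1),
                         meta4)
  expect_warning(res <- ttest_two_sample(m_diff), "zero within-group")
  expect_identical(res$p_value, .Machine$double.xmin)
})

test_that("Storey q-values reproduce the hand-enumerated example and reduce to BH", {
  q <- storey_qvalues(c(0.01, 0.2, 0.6, 0.8), lambda = 0.5)
  expect_equal(as.numeric(q), c(0.04, 0.4, 0.8, 0.8), tolerance = 1e-12)
  expect_equal(attr(q, "pi0"), 1.0)
  # equal p -> equal q
  q_eq <- as.numeric(storey_qvalues(rep(0.3, 5)))
  expect_true(all(q_eq == q_eq[1L]))
  # pi0 = 1 gives exactly Benjamini-Hochberg
  set.seed(5)
  p <- stats::runif(40)
  q1 <- storey_qvalues(p, lambda = 0)      # pi0 = mean(p>0)/1 = 1
  expect_equal(as.numeric(q1), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q-values are permutation-invariant and monotone in p", {
  set.seed(8)
  for (i in 1:20) {
    p <- stats::runif(30)
    q <- as.numeric(storey_qvalues(p))
    perm <- sample(30)
    expect_equal(as.numeric(storey_qvalues(p[perm])), q[perm],
                 tolerance = 1e-12)
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
  }
})

test_that("the joint significance gate requires both thresholds", {
  cls <- classify_features(log2fc = c(0.60, 0.60, 0.50),
                           p_value = c(0.01, 0.06, 0.001))
  expect_identical(cls$significant, c(TRUE, FALSE, FALSE))
  expect_identical(cls$direction, c("up", "none", "none"))
  expect_error(classify_features(1, c(0.1, 0.2)), "mismatched")
})

test_that("type-I error of the p-gate is calibrated on null data and the joint gate is stricter", {
  set.seed(2024)
  n_feat <- 40; n_rep <- 50
  p_all <- joint_all <- numeric(0)
  for (r in seq_len(n_rep)) {
    vals <- 2^matrix(stats::rnorm(n_feat * 8, 10, 0.5), n_feat)
    m <- make_am(vals, meta4)
    res <- differential_abundance(m)
    p_all <- c(p_all, res$p_value)
    joint_all <- c(joint_all, res$significant)
  }
  rate_p <- mean(p_all < 0.05)
  expect_gt(rate_p, 0.03)
  expect_lt(rate_p, 0.07)
  expect_lte(mean(joint_all), rate_p)
})

test_that("differential_abundance separates tested and presence/absence features", {
  vals <- 2^matrix(stats::rnorm(3 * 8, 10, 0.1), 3,
                   dimnames = list(c("A", "B", "C"), NULL))
  vals["C", 5:8] <- NA
  m <- make_am(vals, meta4)
  res <- differential_abundance(m)
  expect_true(is.na(res$log2fc[res$feature_id == "C"]))
  expect_identical(res$detection[res$feature_id == "C"], "WT_only")
  expect_false(res$significant[res$feature_id == "C"])
  expect_false(anyNA(res$p_value[res$detection == "both"]))
})
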