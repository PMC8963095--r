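test_that("confusion counts match hand-placed voxel layouts", {
  p <- array(0L, dim = c(4, 4, 4))
  g <- array(0L, dim = c(4, 4, 4))
  g[1:7] <- 1L          # 7 truth voxels
  p[3:7] <- 1L          # 5 overlap with truth
  p[10:12] <- 1L        # 3 false positives
  cc <- confusion_counts(binary_mask(p), binary_mask(g))
  expect_identical(cc[c("TP", "TN", "FP", "FN")],
                   list(TP = 5L, TN = 54L, FP = 3L, FN = 2L))
  expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, 64L)
  same <- confusion_counts(binary_mask(g), binary_mask(g))
  expect_identical(same$FP + same$FN, 0L)
  comp <- confusion_counts(binary_mask(1L - g), binary_mask(g))
  expect_identical(comp$TP + comp$TN, 0L)
})

test_that("each measure reproduces its closed-form hand value", {
  p <- array(0L, dim = c(4, 4, 4))
  g <- array(0L, dim = c(4, 4, 4))
  g[1:7] <- 1L; p[3:7] <- 1L; p[10:12] <- 1L
  cc <- confusion_counts(binary_mask(p), binary_mask(g))
  expect_equal(specificity(cc), 54 / 57)
  expect_equal(sensitivity(cc), 5 / 7)
  expect_equal(auc_balanced(cc), 1 - 0.5 * (3 / 57 + 2 / 7))
  # dice: |p| = 2, |g| = 2, overlap 1 -> 0.5
  a <- array(0L, dim = c(2, 2, 2)); a[1:2] <- 1L
  b <- array(0L, dim = c(2, 2, 2)); b[2:3] <- 1L
  expect_equal(dice(binary_mask(a), binary_mask(b)), 0.5)
  # subset saturates the overlap coefficient: |p| = 3 inside |g| = 7
  ps <- array(0L, dim = c(4, 4, 4)); ps[2:4] <- 1L
  gs <- array(0L, dim = c(4, 4, 4)); gs[1:7] <- 1L
  expect_equal(overlap_coefficient(binary_mask(ps), binary_mask(gs)), 1)
})

test_that("degenerate inputs hit the documented edge contracts", {
  e <- binary_mask(array(0L, dim = c(3, 3, 3)))
  n <- binary_mask(array(1L, dim = c(3, 3, 3)))
  expect_warning(d <- dice(e, e), "empty")
  expect_equal(d, 1)
  expect_error(overlap_coefficient(e, n), "empty")
  expect_error(specificity(confusion_counts(n, n)), "negative")
  expect_error(sensitivity(confusion_counts(e, e)), "empty")
  expect_error(auc_balanced(confusion_counts(n, n)), "classes")
  # all-background prediction against a nonempty truth: AUC 0.5
  g <- array(0L, dim = c(3, 3, 3)); g[1:5] <- 1L
  expect_equal(auc_balanced(confusion_counts(e, binary_mask(g))), 0.5)
})

test_that("all five measures agree with the exhaustive voxel-loop oracle", {
  set.seed(12)
  for (i in 1:100) {
    p <- random_mask(c(16, 16, 16), p = runif(1, 0.1, 0.9))
    g <- random_mask(c(16, 16, 16), p = runif(1, 0.1, 0.9))
    if (sum(p) == 0 || sum(g) == 0 || sum(p) == length(p)) next
    rep <- evaluate_masks(binary_mask(p), binary_mask(g))
    orc <- oracle_metrics(as.numeric(p), as.numeric(g))
    for (nm in c("DSC", "OC", "SP", "SN", "AUC")) {
      expect_lt(abs(rep[[nm]] - orc[[nm]]), 1e-12)
    }
    expect_identical(unclass(rep$counts)[c("TP", "TN", "FP", "FN")],
                     orc$counts[c("TP", "TN", "FP", "FN")])
    # algebraic identity
    expect_equal(rep$AUC, (rep$SN + rep$SP) / 2, tolerance = 1e-12)
    # squared-sum and cardinality Dice agree on binary input
    cc <- rep$counts
    expect_equal(rep$DSC, 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN),
                 tolerance = 1e-12)
  }
})

test_that("the report row follows the results-table column layout", {
  g <- random_mask(c(8, 8, 8))
  rep <- evaluate_masks(binary_mask(g), binary_mask(g))
  row <- report_row(rep, id = "s1")
  expect_identical(names(row), c("id", "DSC", "OC", "SP", "SN", "AUC"))
  expect_equal(unlist(row[-1], use.names = FALSE), rep(1, 5))
})
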