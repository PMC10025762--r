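test_that("metrics reproduce the formula block and flag undefined cases", {
  m <- metrics(confusion_counts(tp = 8, fp = 2, tn = 90, fn = 0))
  expect_equal(unname(m), c(0.98, 1.0, 2 / 92, 0.2, 16 / 18))

  perfect <- metrics(confusion_counts(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unname(perfect), c(1, 1, 0, 0, 1))

  degenerate <- metrics(confusion_counts(tp = 0, fp = 3, tn = 0, fn = 2))
  expect_equal(degenerate[["recall"]], 0)
  expect_equal(degenerate[["fdr"]], 1)

  allzero <- metrics(confusion_counts())
  expect_true(all(is.na(allzero)))
  expect_error(confusion_counts(tp = -1), "non-negative")
})

test_that("metrics agree with independent hand computation over a full grid", {
  grid <- expand.grid(tp = 0:5, fp = 0:5, tn = 0:5, fn = 0:5)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    m <- metrics(confusion_counts(g$tp, g$fp, g$tn, g$fn))
    hand <- function(num, den) if (den == 0) NA_real_ else num / den
    expect_identical(m[["accuracy"]],
                     hand(g$tp + g$tn, g$tp + g$tn + g$fp + g$fn))
    expect_identical(m[["recall"]], hand(g$tp, g$tp + g$fn))
    expect_identical(m[["fpr"]], hand(g$fp, g$fp + g$tn))
    expect_identical(m[["fdr"]], hand(g$fp, g$fp + g$tp))
    expect_identical(m[["f1"]], hand(2 * g$tp, 2 * g$tp + g$fp + g$fn))
  }
})

test_that("F1 is the harmonic mean of precision and recall where defined", {
  set.seed(10)
  for (i in 1:50) {
    cnt <- confusion_counts(sample(0:20, 1), sample(0:20, 1),
                            sample(0:20, 1), sample(0:20, 1))
    m <- metrics(cnt)
    prec <- 1 - m[["fdr"]]
    if (!anyNA(c(m[["f1"]], prec, m[["recall"]])) &&
        prec + m[["recall"]] > 0) {
      expect_equal(m[["f1"]],
                   2 * prec * m[["recall"]] / (prec + m[["recall"]]))
    }
  }
})

simple_truth <- function(pos, strand = "+") {
  data.frame(contig = "c1", pos = pos, strand = strand,
             expression = 1, gene_id = paste0("t", seq_along(pos)),
             stringsAsFactors = FALSE)
}

test_that("scan_confusion applies the tolerance rule", {
  pred <- data.frame(contig = "c1", strand = "+", pos = 1050L, score = 0.9,
                     stringsAsFactors = FALSE)
  cc <- scan_confusion(pred, simple_truth(1000L))
  expect_equal(unname(cc[c("TP", "FP", "FN")]), c(1, 0, 0))
  expect_true(is.na(cc[["TN"]]))

  pred2 <- data.frame(contig = "c1", strand = "+", pos = 1200L, score = 0.9)
  cc2 <- scan_confusion(pred2, simple_truth(1000L))
  expect_equal(unname(cc2[c("TP", "FP", "FN")]), c(0, 1, 1))

  # truth with no prediction above threshold nearby -> FN
  cc3 <- scan_confusion(pred[0, ], simple_truth(1000L))
  expect_equal(unname(cc3[["FN"]]), 1)
})

test_that("scan_confusion matches one-to-one by decreasing score", {
  truth <- simple_truth(1000L)
  pred <- data.frame(contig = "c1", strand = "+", pos = c(1010L, 1090L),
                     score = c(0.6, 0.95), stringsAsFactors = FALSE)
  cc <- scan_confusion(pred, truth)
  # the stronger (farther) signal wins the single truth; the closer one is FP
  expect_equal(unname(cc[["TP"]]), 1)
  expect_equal(unname(cc[["FP"]]), 1)
  expect_equal(attr(cc, "matched")$pred_pos, 1090L)

  # each prediction labeled exactly once; strand must match
  pred_minus <- transform(pred, strand = "-")
  cc2 <- scan_confusion(pred_minus, truth)
  expect_equal(unname(cc2[["FP"]]), 2)
})

test_that("scan_confusion bookkeeping holds on random cases", {
  set.seed(11)
  for (rep in 1:20) {
    truth <- simple_truth(sort(sample(seq(1000, 50000, by = 400),
                                      sample(3:10, 1))))
    pred <- data.frame(contig = "c1", strand = "+",
                       pos = sample(1000:50000, sample(3:15, 1)))
    pred$score <- round(stats::runif(nrow(pred), 0.4, 1), 3)
    cc <- scan_confusion(pred, truth)
    expect_equal(unname(cc[["TP"]] + cc[["FP"]]), nrow(pred))
    expect_lte(cc[["TP"]], nrow(truth))
    expect_lte(cc[["TP"]] + cc[["FN"]], nrow(truth))
    expect_equal(anyDuplicated(attr(cc, "matched")$truth_pos), 0L)
  }
})

test_that("fps_per_kb is the stated normalization", {
  expect_equal(fps_per_kb(5, 10000), 0.5)
  expect_equal(fps_per_kb(0, 1234), 0)
  expect_equal(fps_per_kb(7, 20000), fps_per_kb(7, 10000) / 2)
  expect_true(is.na(fps_per_kb(3, 0)))
})

test_that("score/expression correlation behaves at the boundaries and null", {
  x <- matrix(stats::runif(30), 3, 10)
  expect_equal(score_expression_correlation(x, x), rep(1, 3))
  expect_equal(score_expression_correlation(x, 2 - 3 * x), rep(-1, 3))
  const <- x; const[1, ] <- 5
  expect_true(is.na(score_expression_correlation(const, x)[1]))
  expect_error(score_expression_correlation(x[, 1:2], x[, 1:2]), "3 cell")
  expect_error(score_expression_correlation(x, x[, 1:5]), "mismatch")

  set.seed(12)
  n <- 2000L
  r <- score_expression_correlation(matrix(stats::rnorm(n * 10), n, 10),
                                    matrix(stats::rnorm(n * 10), n, 10))
  # independent vectors: mean r ~ 0 within 3 standard errors
  se <- stats::sd(r) / sqrt(n)
  expect_lt(abs(mean(r)), 3 * se + 1e-3)
})
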