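make_flat_fixture <- function(L = 25000L, peaks_pos = c(8000L, 16000L),
                              strand = c("+", "-")) {
  set.seed(99)
  g <- tsscan:::new_genome(c(c1 = paste(
    sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")))
  cov <- structure(list(c1 = list(plus = rep(1, L), minus = rep(1, L))),
                   class = "coverage_track")
  peaks <- structure(data.frame(
    contig = "c1", pos = peaks_pos, strand = strand,
    expression = c(2, 5), gene_id = c("a", "b"), stringsAsFactors = FALSE),
    class = c("tss_peaks", "data.frame"))
  list(genome = g, coverage = cov, peaks = peaks)
}

test_that("select_active_peaks filters on the expression threshold", {
  p <- structure(data.frame(contig = "c", pos = 1:3, strand = "+",
                            expression = c(0, 0.5, 2.0), gene_id = letters[1:3]),
                 class = c("tss_peaks", "data.frame"))
  expect_equal(select_active_peaks(p, 1.0)$expression, 2.0)
  expect_equal(nrow(select_active_peaks(p, 0)), 3L)
  expect_equal(nrow(select_active_peaks(p[0, ], 1.0)), 0L)
})

test_that("extract_window takes the right slice and respects bounds", {
  fx <- make_flat_fixture()
  fx$coverage$c1$plus <- seq_len(25000)  # position-identifying depth
  w <- extract_window(fx$genome, fx$coverage, "c1", 600L, "+")
  expect_equal(unname(w$seq), unname(one_hot(substr(fx$genome$contigs[["c1"]],
                                                    101, 1101))))
  expect_equal(w$cov, 101:1101)
  expect_null(extract_window(fx$genome, fx$coverage, "c1", 400L, "+"))

  # minus-strand window = reverse complement of the plus extraction on the
  # minus track at the same coordinates
  fx$coverage$c1$minus <- seq_len(25000) + 0.5
  wm <- extract_window(fx$genome, fx$coverage, "c1", 600L, "-")
  ref <- reverse_complement_window(
    one_hot(substr(fx$genome$contigs[["c1"]], 101, 1101)),
    fx$coverage$c1$minus[101:1101])
  expect_equal(unname(wm$seq), unname(ref$seq))
  expect_equal(wm$cov, ref$cov)
})

test_that("positive shifts stay within 50 bp and are uniform over 101 values", {
  fx <- make_flat_fixture()
  set.seed(1)
  deltas <- integer(0)
  for (rep in 1:500) {
    w <- sample_positives(fx$peaks, fx$genome, fx$coverage)
    deltas <- c(deltas, w$origin$center - fx$peaks$pos)
  }
  expect_true(all(abs(deltas) <= 50))
  # chi-squared uniformity over the 101 possible offsets
  counts <- table(factor(deltas, levels = -50:50))
  pval <- stats::chisq.test(counts)$p.value
  expect_gt(pval, 0.01)
})

test_that("negative centers sit 500-1000 bp from the nearest same-strand peak", {
  fx <- make_flat_fixture()
  set.seed(2)
  neg <- sample_negatives(fx$peaks, 200L, fx$genome, fx$coverage)
  expect_equal(n_windows(neg), 200L)
  expect_true(all(neg$label == 0L))
  # brute-force nearest-peak re-check
  for (i in seq_len(n_windows(neg))) {
    same <- fx$peaks$pos[fx$peaks$strand == neg$origin$strand[i]]
    d <- min(abs(same - neg$origin$center[i]))
    expect_true(d >= 500 && d <= 1000)
  }
  expect_equal(n_windows(sample_negatives(fx$peaks, 0L, fx$genome,
                                          fx$coverage)), 0L)
})

test_that("single-peak negative geometry matches the enumerated valid set", {
  fx <- make_flat_fixture(peaks_pos = c(10000L, 18000L), strand = c("+", "+"))
  fx$peaks <- fx$peaks[1, , drop = FALSE]
  # brute-force enumeration of positions at distance in [500, 1000]
  valid <- which(vapply(0:24999, function(x) {
    d <- abs(x - 10000L)
    d >= 500 && d <= 1000
  }, logical(1))) - 1L
  expect_setequal(range(valid), c(9000L, 11000L))
  set.seed(8)
  neg <- sample_negatives(fx$peaks, 100L, fx$genome, fx$coverage)
  expect_true(all(neg$origin$center %in% valid))
  expect_true(any(neg$origin$center < 10000L) && any(neg$origin$center > 10000L))
})

test_that("split_dataset is stratified, disjoint, exhaustive and reproducible", {
  w <- random_windows(100L)
  w$label <- rep(c(0L, 1L), 50)
  set.seed(7)
  sp <- split_dataset(w, c(0.8, 0.1, 0.1))
  expect_equal(vapply(sp, n_windows, integer(1)),
               c(train = 80L, val = 10L, test = 10L))
  expect_equal(sum(sp$train$label), 40L)  # stratified
  all_centers <- sort(c(sp$train$origin$center, sp$val$origin$center,
                        sp$test$origin$center))
  expect_equal(all_centers, sort(w$origin$center))  # union = input
  set.seed(7)
  sp2 <- split_dataset(w, c(0.8, 0.1, 0.1))
  expect_identical(sp$train$origin, sp2$train$origin)
})

test_that("build_dataset yields a balanced set anchored on active peaks", {
  fx <- make_flat_fixture()
  set.seed(3)
  ds <- build_dataset(fx$genome, fx$coverage, fx$peaks,
                      dataset_spec(active_expression_threshold = 1))
  expect_equal(sum(ds$label == 1L), sum(ds$label == 0L))
  pos <- windows_subset(ds, ds$label == 1L)
  # every positive's unshifted anchor is an active peak position
  expect_true(all(vapply(seq_len(n_windows(pos)), function(i) {
    any(abs(fx$peaks$pos - pos$origin$center[i]) <= 50)
  }, logical(1))))
})
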