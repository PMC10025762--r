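test_that("filter_to_pwm yields stochastic columns with the right extremes", {
  z <- matrix(0, 4, 10)
  expect_equal(unname(unclass(filter_to_pwm(z))), matrix(0.25, 4, 10))

  set.seed(31)
  f <- matrix(stats::rnorm(40), 4, 10)
  p <- filter_to_pwm(f)
  expect_equal(colSums(p), rep(1, 10))
  expect_true(all(p > 0))

  # strong A weight everywhere -> near-consensus A
  fa <- matrix(0, 4, 10); fa[1, ] <- 10
  pa <- filter_to_pwm(fa)
  expect_true(all(pa["A", ] > 0.99))

  # vector input (column of the weight matrix) matches matrix input
  expect_equal(filter_to_pwm(as.vector(f)), p)
  expect_error(filter_to_pwm(matrix(NaN, 4, 10)), "non-finite")

  # alternative min-shift conversion also yields stochastic columns
  ps <- filter_to_pwm(f, method = "shift")
  expect_equal(colSums(ps), rep(1, 10))
})

test_that("compute_gmis pairs filters by index with the right count and signs", {
  set.seed(32)
  cfg <- train_config(n_filters = 8L, filter_width = 6L, hidden_units = 4L,
                      window_len = 41L, pool_size = 12L)
  meta <- init_params(cfg)
  ft <- list(alpha = init_params(cfg), beta = init_params(cfg))

  g <- compute_gmis(meta, ft)
  expect_length(g, 2L * 8L)
  expect_equal(unique(vapply(g, `[[`, character(1), "cell_type")),
               c("alpha", "beta"))

  # identity case: fine-tuned == meta -> all deltas exactly zero
  g0 <- compute_gmis(meta, list(same = meta))
  expect_true(all(vapply(g0, function(x) all(x$delta == 0), logical(1))))

  # antisymmetry under swapping meta and fine-tuned
  gab <- compute_gmis(meta, list(a = ft$alpha))
  gba <- compute_gmis(ft$alpha, list(a = meta))
  for (i in seq_along(gab)) {
    expect_equal(gab[[i]]$delta, -gba[[i]]$delta)
  }

  # architecture mismatch is fatal
  other <- init_params(train_config(n_filters = 8L, filter_width = 4L,
                                    hidden_units = 4L, window_len = 41L,
                                    pool_size = 12L))
  expect_error(compute_gmis(meta, list(x = other)), "mismatch")
})

test_that("a 64-filter model with k cell types yields k x 64 GMIs", {
  set.seed(33)
  cfg <- train_config(n_filters = 64L, hidden_units = 8L)
  meta <- init_params(cfg)
  ft <- replicate(2, init_params(cfg), simplify = FALSE)
  names(ft) <- c("ct1", "ct2")
  expect_length(compute_gmis(meta, ft), 128L)
})

test_that("MEME export passes a grammar check and round-trips", {
  set.seed(34)
  cfg <- train_config(n_filters = 6L, filter_width = 8L, hidden_units = 4L,
                      window_len = 41L, pool_size = 12L)
  g <- compute_gmis(init_params(cfg), list(ct = init_params(cfg)))
  f <- withr::local_tempfile()
  export_motifs(g, f)
  lines <- readLines(f)
  expect_equal(lines[1], "MEME version 4")
  expect_true(any(grepl("^ALPHABET= ACGT$", lines)))
  expect_equal(sum(grepl("^MOTIF ", lines)), length(g))
  expect_true(all(grepl("alength= 4 w= 8", lines[grepl("letter-probability",
                                                       lines)])))
  back <- read_meme(f)
  expect_length(back, length(g))
  expect_named(back, vapply(g, function(x) {
    paste0(x$cell_type, "_f", x$filter)
  }, character(1)))
  for (i in seq_along(g)) {
    prob <- tsscan:::gmi_to_prob(g[[i]]$delta)[tsscan:::PWM_EXPORT_ORDER, ]
    expect_equal(unname(back[[i]]), unname(t(prob)), tolerance = 1e-4)
    expect_equal(rowSums(back[[i]]), rep(1, 8L), tolerance = 1e-5)
  }

  # zero delta -> uniform motif rows
  gz <- compute_gmis(init_params(cfg), list(ct = init_params(cfg)))
  gz[[1]]$delta[] <- 0
  f2 <- withr::local_tempfile()
  export_motifs(gz[1], f2)
  expect_equal(unname(read_meme(f2)[[1]]), matrix(0.25, 8, 4))
  expect_error(export_motifs(structure(list(), class = "gmi_set"), f2),
               "empty")
})

test_that("match_motifs finds a planted motif and rejects noise", {
  set.seed(35)
  planted <- matrix(stats::runif(40, 0, 0.1), 10, 4)
  planted[cbind(1:10, c(1, 2, 4, 1, 1, 1, 1, 3, 2, 4))] <- 0.9
  planted <- planted / rowSums(planted)
  shifted <- rbind(matrix(0.25, 2, 4), planted[1:8, ])
  ref <- list(target = planted,
              noise = matrix(1 / 4, 12, 4) + stats::runif(48, 0, 1e-3))
  hits <- match_motifs(list(q = shifted), ref, n_perm = 60L, p_max = 0.05)
  expect_true("target" %in% hits$reference)
  expect_gt(hits$similarity[hits$reference == "target"], 0.8)
})

test_that("concordance_filter selects expression-matched profiles", {
  profile <- rbind(on = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
                   off = c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1),
                   const = rep(1, 10))
  expr <- rbind(on = c(9, 8, 0.1, 0.2, 0.1, 0, 0.1, 0.2, 0, 0.1),
                off = c(9, 8, 0.1, 0.2, 0.1, 0, 0.1, 0.2, 0, 0.1),
                const = stats::runif(10))
  expect_message(res <- concordance_filter(profile, expr, r_min = 0.2),
                 "constant")
  expect_true(res$retained[res$tf == "on"])
  expect_false(res$retained[res$tf == "off"])  # anti-correlated
  expect_true(is.na(res$r[res$tf == "const"]))
  expect_gt(res$r[res$tf == "on"], 0.9)

  # an impossible threshold retains nothing
  res2 <- suppressMessages(concordance_filter(profile, expr, r_min = 1.01))
  expect_false(any(res2$retained))
})
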