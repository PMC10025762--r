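# Reptile meta-learning and fine-tuning. (Circular-training properties are
# exercised end-to-end in test-acceptance.R; here the cheap invariants.)

test_that("reptile on the scalar quadratic matches the closed form", {
  # inner loss (theta - c)^2 / 2, one full-gradient step of rate alpha:
  # W = theta - alpha * (theta - c); meta update theta' = theta + eps*(W-theta)
  #                                                      = theta - eps*alpha*(theta - c)
  alpha <- 0.3
  cvals <- c(th = 1.7)
  inner <- function(params, task) {
    list(th = params$th - alpha * (params$th - task$c))
  }
  cfg <- meta_config(inner_steps = 1L, meta_step = 0.25, meta_iterations = 1L)
  got <- reptile_meta_train(list(list(c = 4)), cfg, inner_fit = inner,
                            init = list(th = 1.7))
  expect_equal(got$th, 1.7 - 0.25 * alpha * (1.7 - 4), tolerance = 1e-12)

  # iterating converges linearly to c
  cfg2 <- meta_config(inner_steps = 1L, meta_step = 0.25,
                      meta_iterations = 400L)
  got2 <- reptile_meta_train(list(list(c = 4)), cfg2, inner_fit = inner,
                             init = list(th = 1.7))
  expect_equal(got2$th, 4, tolerance = 1e-8)

  # eps = 0 would never move; the config forbids it, so check tiny eps
  cfg3 <- meta_config(inner_steps = 1L, meta_step = 1e-12,
                      meta_iterations = 3L)
  got3 <- reptile_meta_train(list(list(c = 4)), cfg3, inner_fit = inner,
                             init = list(th = 1.7))
  expect_equal(got3$th, 1.7, tolerance = 1e-9)
})

test_that("single-task reptile with eps = 1 equals plain inner training exactly", {
  set.seed(51)
  task <- toy_separable_windows(12L, 41L)
  cfg <- tiny_cfg(41L, keep_prob = 1, batch_size = 8L)
  mc <- meta_config(inner_steps = 5L, meta_step = 1, meta_iterations = 1L)

  set.seed(99)
  init <- init_params(cfg)
  set.seed(100)
  theta <- reptile_meta_train(list(task), mc, cfg, init = init)

  # plain inner training under the identical RNG stream
  set.seed(100)
  p <- init
  state <- NULL
  for (i in 1:5) {
    idx <- sample.int(n_windows(task), 8L)
    st <- train_step(p, windows_subset(task, idx), cfg, state)
    p <- st$params
    state <- st$state
  }
  for (nm in names(p)) expect_identical(theta[[nm]], p[[nm]])
})

test_that("empty tasks are skipped with a warning", {
  set.seed(52)
  cfg <- tiny_cfg(keep_prob = 1, batch_size = 4L)
  mc <- meta_config(inner_steps = 1L, meta_step = 0.5, meta_iterations = 1L)
  init <- init_params(cfg)
  expect_warning(
    theta <- reptile_meta_train(list(windows_subset(random_windows(4L), 0L)),
                                mc, cfg, init = init),
    "empty task")
  for (nm in names(init)) expect_identical(theta[[nm]], init[[nm]])
})

test_that("finetune starts from the meta model and leaves it untouched", {
  set.seed(53)
  cfg <- tiny_cfg(41L, keep_prob = 1, epochs = 0L, batch_size = 8L)
  meta <- init_params(cfg)
  meta_copy <- meta
  task <- toy_separable_windows(12L, 41L)

  # zero epochs: the fine-tuned model carries the meta parameters unchanged
  m0 <- finetune(meta, task, cfg)
  for (nm in names(meta)) expect_identical(m0$params[[nm]], meta[[nm]])

  cfg$epochs <- 10L
  m1 <- finetune(meta, task, cfg)
  expect_false(identical(m1$params$W1, meta$W1))
  # isolation: the stored meta checkpoint is unchanged
  for (nm in names(meta)) expect_identical(meta[[nm]], meta_copy[[nm]])
})

test_that("meta_task_split is stratified at the requested fraction", {
  set.seed(54)
  w <- random_windows(50L)
  w$label <- rep(c(0L, 1L), 25)
  sp <- meta_task_split(w, 0.2)
  expect_equal(n_windows(sp$meta), 10L)
  expect_equal(sum(sp$meta$label), 5L)
  expect_equal(n_windows(sp$meta) + n_windows(sp$rest), 50L)
})

test_that("fine-tuning improves a task with a task-specific motif over the meta model", {
  set.seed(55)
  # two tasks with different discriminative signals: task A sequence motif
  # only, task B coverage step only
  taskA <- toy_separable_windows(40L, 41L, seq_signal = TRUE,
                                 cov_signal = FALSE)
  taskB <- toy_separable_windows(40L, 41L, seq_signal = FALSE,
                                 cov_signal = TRUE)
  holdA <- toy_separable_windows(40L, 41L, seq_signal = TRUE,
                                 cov_signal = FALSE)
  cfg <- toy_cfg(epochs = 30L, batch_size = 40L)
  mc <- meta_config(inner_steps = 10L, meta_step = 0.3, meta_iterations = 30L)
  f1_of <- function(params) {
    ev <- evaluate_binary(params, holdA)
    f <- ev$metrics[["f1"]]
    if (is.na(f)) 0 else f
  }
  res <- sapply(1:3, function(s) {
    set.seed(60 + s)
    meta <- reptile_meta_train(list(taskA, taskB), mc, cfg)
    ft <- finetune(meta, taskA, cfg)
    c(meta = f1_of(meta), ft = f1_of(ft$params))
  })
  expect_gte(median(res["ft", ]), median(res["meta", ]))
})
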