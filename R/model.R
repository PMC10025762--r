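# Dual-branch convolutional binary classifier. Each branch applies a valid
# 1-D convolution (64 filters of width 10 by default) to its input -- the
# one-hot sequence matrix or the raw coverage vector -- followed by ReLU and
# strided max pooling (16 bins of 62 positions by default; global pooling
# when pool_size covers the conv output). The pooled feature vectors of the
# two branches are concatenated, passed through one ReLU hidden layer (with
# inverted dropout during training) and a 2-unit softmax. Forward and
# backward passes are written as im2col + BLAS matrix products; gradients
# are exact analytic derivatives, verified against finite differences in
# the test suite.

#' Training configuration
#'
#' The `"paper"` preset carries the published optimization settings
#' (10,000 epochs, batch 4000, learning rate 1e-4, momentum 0.98, weight
#' decay 4e-4, keep probability 0.5). The `"desk"` preset is a small-problem
#' profile used throughout the test suite: at most a few hundred epochs and
#' batches of at most 256, with a more aggressive learning rate suited to
#' the small synthetic fixtures.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param epochs,batch_size,learning_rate,momentum,weight_decay,keep_prob
#'   Optimization hyperparameters; defaults come from the preset.
#' @param n_filters,filter_width Convolution bank geometry (both branches).
#' @param pool_size Width (in convolution output positions) of each max
#'   pooling bin; pooling is global when `pool_size` reaches the
#'   convolution output length. The default 62 gives 16 bins over a
#'   1001-bp window, preserving the coarse positional information that
#'   stride-1 scanning needs for base-level TSS placement.
#' @param window_len Input window length in bp (both branches).
#' @param hidden_units Width of the fully connected hidden layer.
#' @param branches `"both"`, `"seq"` or `"cov"`: which input branches the
#'   model uses (single-branch models support ablation studies).
#' @param eval_every Validation cadence in epochs.
#' @param select_metric Validation metric used for checkpoint selection
#'   (`"f1"`, `"recall"`, `"fdr"` or `"accuracy"`; FDR is minimized).
#' @param init_sd Standard deviation of the Gaussian weight initialization
#'   for the convolution banks.
#' @return A list of class `train_config`.
#' @export
train_config <- function(preset = c("desk", "paper"),
                         epochs = NULL, batch_size = NULL,
                         learning_rate = NULL, momentum = NULL,
                         weight_decay = 4e-4, keep_prob = 0.5,
                         n_filters = 64L, filter_width = 10L,
                         pool_size = 62L, window_len = 1001L,
                         hidden_units = 128L,
                         branches = c("both", "seq", "cov"),
                         eval_every = 10L, select_metric = "f1",
                         init_sd = 0.05) {
  preset <- match.arg(preset)
  branches <- match.arg(branches)
  defaults <- switch(preset,
    paper = list(epochs = 10000L, batch_size = 4000L,
                 learning_rate = 1e-4, momentum = 0.98),
    desk = list(epochs = 150L, batch_size = 128L,
                learning_rate = 2e-3, momentum = 0.9))
  cfg <- list(
    preset = preset,
    epochs = as.integer(epochs %||% defaults$epochs),
    batch_size = as.integer(batch_size %||% defaults$batch_size),
    learning_rate = learning_rate %||% defaults$learning_rate,
    momentum = momentum %||% defaults$momentum,
    weight_decay = weight_decay,
    keep_prob = keep_prob,
    n_filters = as.integer(n_filters),
    filter_width = as.integer(filter_width),
    pool_size = as.integer(pool_size),
    window_len = as.integer(window_len),
    hidden_units = as.integer(hidden_units),
    branches = branches,
    eval_every = as.integer(eval_every),
    select_metric = select_metric,
    init_sd = init_sd
  )
  stopifnot(cfg$keep_prob > 0, cfg$keep_prob <= 1,
            cfg$learning_rate > 0, cfg$epochs >= 0, cfg$batch_size >= 1,
            cfg$pool_size >= 1, cfg$window_len > cfg$filter_width)
  structure(cfg, class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize model parameters
#'
#' Convolution and fully connected weights are drawn from centered
#' Gaussians (conv: `init_sd`; FC: He scaling), biases start at zero.
#' Sequence filters are stored as a `(4 * width) x n_filters` matrix whose
#' rows are ordered channel-fastest within each filter position, matching
#' the im2col layout of the forward pass.
#'
#' @param cfg A `train_config`.
#' @return A named list of parameter arrays of class `model_params`, with
#'   the architecture recorded in `attr(, "arch")`.
#' @export
init_params <- function(cfg = train_config()) {
  F <- cfg$n_filters
  W <- cfg$filter_width
  H <- cfg$hidden_units
  P <- cfg$window_len - W + 1L
  nbins <- max(1L, P %/% min(cfg$pool_size, P))
  per_branch <- F * nbins
  feat <- switch(cfg$branches, both = 2L * per_branch, seq = per_branch,
                 cov = per_branch)
  p <- list()
  if (cfg$branches %in% c("both", "seq")) {
    p$W_seq <- matrix(stats::rnorm(4L * W * F, sd = cfg$init_sd), 4L * W, F)
    p$b_seq <- numeric(F)
  }
  if (cfg$branches %in% c("both", "cov")) {
    p$W_cov <- matrix(stats::rnorm(W * F, sd = cfg$init_sd), W, F)
    p$b_cov <- numeric(F)
  }
  p$W1 <- matrix(stats::rnorm(feat * H, sd = sqrt(2 / feat)), feat, H)
  p$b1 <- numeric(H)
  p$W2 <- matrix(stats::rnorm(H * 2L, sd = sqrt(2 / H)), H, 2L)
  p$b2 <- numeric(2L)
  attr(p, "arch") <- list(n_filters = F, filter_width = W, hidden_units = H,
                          branches = cfg$branches, pool_size = cfg$pool_size,
                          n_bins = nbins, window_len = cfg$window_len)
  class(p) <- "model_params"
  p
}

# im2col for a batch of one-hot sequences: (n, L, 4) array -> (n*P) x (4*width)
# matrix, P = L - width + 1; row index runs batch-fastest then position.
im2col_seq <- function(S, width) {
  n <- dim(S)[1L]
  L <- dim(S)[2L]
  P <- L - width + 1L
  M <- matrix(0, n * P, 4L * width)
  for (w in seq_len(width)) {
    sl <- S[, w:(w + P - 1L), , drop = FALSE]
    dim(sl) <- c(n * P, 4L)
    M[, (w - 1L) * 4L + 1:4] <- sl
  }
  M
}

im2col_cov <- function(V, width) {
  n <- nrow(V)
  L <- ncol(V)
  P <- L - width + 1L
  M <- matrix(0, n * P, width)
  for (w in seq_len(width)) {
    M[, w] <- as.vector(V[, w:(w + P - 1L), drop = FALSE])
  }
  M
}

add_row_vec <- function(M, b) M + rep(b, each = nrow(M))

softmax_rows <- function(logits) {
  m <- pmax(logits[, 1L], logits[, 2L])
  e1 <- exp(logits[, 1L] - m)
  e2 <- exp(logits[, 2L] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}

# Full forward pass; returns class-1 probabilities and (optionally) the
# cache needed by the backward pass.
model_forward_impl <- function(params, seq, cov, train_mode = FALSE,
                               keep_prob = 1, want_cache = FALSE) {
  arch <- attr(params, "arch")
  width <- arch$filter_width
  F <- arch$n_filters
  n <- dim(seq)[1L]
  L <- dim(seq)[2L]
  P <- L - width + 1L
  if (!all(is.finite(seq)) || !all(is.finite(cov))) {
    stop("model_forward: non-finite input")
  }
  if (L != arch$window_len) {
    stop("model_forward: window length ", L, " does not match the model's ",
         arch$window_len)
  }
  cache <- list(n = n, P = P, F = F)
  pooled_parts <- list()
  # Bias and ReLU commute with the per-bin max, so each branch pools the
  # raw convolution and applies relu(. + bias) to the n x (F * nbins)
  # result (the per-filter bias is recycled across bins, bin-major layout).
  if (arch$branches %in% c("both", "seq")) {
    Ms <- im2col_seq(seq, width)
    ps <- pool_max_raw(Ms %*% params$W_seq, n, P, arch$pool_size)
    act <- add_row_vec(ps$pooled, rep(params$b_seq, ps$nbins))
    mask_s <- act > 0
    pooled_parts$seq <- act * mask_s
    if (want_cache) cache[c("Ms", "mask_s", "idx_s")] <- list(Ms, mask_s, ps$idx)
  }
  if (arch$branches %in% c("both", "cov")) {
    Mc <- im2col_cov(cov, width)
    pc <- pool_max_raw(Mc %*% params$W_cov, n, P, arch$pool_size)
    act <- add_row_vec(pc$pooled, rep(params$b_cov, pc$nbins))
    mask_c <- act > 0
    pooled_parts$cov <- act * mask_c
    if (want_cache) cache[c("Mc", "mask_c", "idx_c")] <- list(Mc, mask_c, pc$idx)
  }
  X <- do.call(cbind, unname(pooled_parts))
  H0 <- add_row_vec(X %*% params$W1, params$b1)
  Hr <- pmax(H0, 0)
  if (train_mode && keep_prob < 1) {
    drop_mask <- matrix((stats::runif(length(Hr)) < keep_prob) / keep_prob,
                        nrow(Hr), ncol(Hr))
    H <- Hr * drop_mask
  } else {
    drop_mask <- NULL
    H <- Hr
  }
  logits <- add_row_vec(H %*% params$W2, params$b2)
  prob <- softmax_rows(logits)
  if (want_cache) {
    cache[c("X", "H0", "H", "drop_mask", "prob")] <-
      list(X, H0, H, drop_mask, prob)
  }
  list(prob = prob, cache = cache)
}

#' Forward pass: score paired windows
#'
#' In evaluation mode (the default) the pass is fully deterministic; dropout
#' on the hidden layer is active only when `train_mode = TRUE`.
#'
#' @param params A `model_params` object.
#' @param windows A `tss_windows`.
#' @param train_mode Apply dropout?
#' @param keep_prob Dropout keep probability (train mode only).
#' @return Numeric vector of class-1 probabilities in `[0, 1]`.
#' @export
model_forward <- function(params, windows, train_mode = FALSE, keep_prob = 1) {
  if (n_windows(windows) == 0L) return(numeric(0))
  model_forward_impl(params, windows$seq, windows$cov, train_mode,
                     keep_prob)$prob[, 2L]
}

sum_sq_weights <- function(params) {
  nm <- grep("^W", names(params), value = TRUE)  # weights only, not biases
  sum(vapply(nm, function(k) sum(params[[k]]^2), numeric(1)))
}

#' Batch loss: mean cross-entropy plus L2 weight penalty
#'
#' `loss = mean(-log p_label) + weight_decay * sum(W^2)` over all weight
#' matrices (biases are not penalized).
#'
#' @param params A `model_params`.
#' @param batch A labeled `tss_windows`.
#' @param weight_decay L2 penalty coefficient.
#' @return The scalar loss.
#' @export
model_loss <- function(params, batch, weight_decay = 0) {
  n <- n_windows(batch)
  if (n == 0L) stop("model_loss: empty batch")
  prob <- model_forward_impl(params, batch$seq, batch$cov)$prob
  p_true <- prob[cbind(seq_len(n), batch$label + 1L)]
  mean(-log(pmax(p_true, 1e-12))) + weight_decay * sum_sq_weights(params)
}

#' Analytic gradients of the batch loss
#'
#' @inheritParams model_loss
#' @param train_mode Sample a dropout mask (as during a training step)?
#' @param keep_prob Dropout keep probability.
#' @return `list(loss = , grads = )` where `grads` mirrors the parameter
#'   list.
#' @export
model_grad <- function(params, batch, weight_decay = 0, train_mode = FALSE,
                       keep_prob = 1) {
  n <- n_windows(batch)
  if (n == 0L) stop("model_grad: empty batch")
  arch <- attr(params, "arch")
  fw <- model_forward_impl(params, batch$seq, batch$cov, train_mode,
                           keep_prob, want_cache = TRUE)
  cc <- fw$cache
  prob <- cc$prob
  p_true <- prob[cbind(seq_len(n), batch$label + 1L)]
  loss <- mean(-log(pmax(p_true, 1e-12))) +
    weight_decay * sum_sq_weights(params)
  Y <- matrix(0, n, 2L)
  Y[cbind(seq_len(n), batch$label + 1L)] <- 1
  dlogits <- (prob - Y) / n
  g <- list()
  g$W2 <- crossprod(cc$H, dlogits) + 2 * weight_decay * params$W2
  g$b2 <- colSums(dlogits)
  dH <- dlogits %*% t(params$W2)
  if (!is.null(cc$drop_mask)) dH <- dH * cc$drop_mask
  dH0 <- dH * (cc$H0 > 0)
  g$W1 <- crossprod(cc$X, dH0) + 2 * weight_decay * params$W1
  g$b1 <- colSums(dH0)
  dX <- dH0 %*% t(params$W1)
  F <- cc$F
  per_branch <- F * arch$n_bins
  col_at <- 0L
  if (arch$branches %in% c("both", "seq")) {
    dact <- dX[, col_at + seq_len(per_branch), drop = FALSE] * cc$mask_s
    col_at <- col_at + per_branch
    g$W_seq <- pool_conv_grad(cc$Ms, dact, cc$idx_s, cc$n, F) +
      2 * weight_decay * params$W_seq
    g$b_seq <- rowSums(matrix(colSums(dact), F, arch$n_bins))
  }
  if (arch$branches %in% c("both", "cov")) {
    dact <- dX[, col_at + seq_len(per_branch), drop = FALSE] * cc$mask_c
    g$W_cov <- pool_conv_grad(cc$Mc, dact, cc$idx_c, cc$n, F) +
      2 * weight_decay * params$W_cov
    g$b_cov <- rowSums(matrix(colSums(dact), F, arch$n_bins))
  }
  list(loss = loss, grads = g[names(params)])
}

#' One momentum-SGD update
#'
#' `v <- momentum * v - lr * grad; w <- w + v`. With `momentum = 0` this is
#' vanilla SGD; with `learning_rate = 0` parameters are unchanged.
#'
#' @param params A `model_params`.
#' @param batch A labeled `tss_windows`.
#' @param cfg A `train_config`.
#' @param state Optimizer state (velocities) from the previous step, or
#'   `NULL` to start at zero.
#' @return `list(params = , state = , loss = )`.
#' @export
train_step <- function(params, batch, cfg, state = NULL) {
  gl <- model_grad(params, batch, cfg$weight_decay,
                   train_mode = cfg$keep_prob < 1, keep_prob = cfg$keep_prob)
  if (!all(vapply(gl$grads, function(x) all(is.finite(x)), logical(1)))) {
    stop("train_step: non-finite gradient (batch of ", n_windows(batch), ")")
  }
  if (is.null(state)) {
    state <- lapply(params, function(x) x * 0)  # zero velocities, same shapes
  }
  for (nm in names(params)) {
    state[[nm]] <- cfg$momentum * state[[nm]] - cfg$learning_rate * gl$grads[[nm]]
    params[[nm]] <- params[[nm]] + state[[nm]]
  }
  list(params = params, state = state, loss = gl$loss)
}

validation_metric <- function(params, val, metric) {
  scores <- model_forward(params, val)
  pred <- as.integer(scores > 0.5)
  cnt <- confusion_counts(tp = sum(pred == 1L & val$label == 1L),
                          fp = sum(pred == 1L & val$label == 0L),
                          tn = sum(pred == 0L & val$label == 0L),
                          fn = sum(pred == 0L & val$label == 1L))
  m <- metrics(cnt)[[metric]]
  if (is.na(m)) m <- if (metric == "fdr") 1 else 0
  if (metric == "fdr") -m else m  # maximize throughout
}

#' Fit the dual-branch TSS classifier
#'
#' Runs epoch-based momentum-SGD training. `train` may be a fixed
#' `tss_windows` or a function of the epoch index (see [epoch_sampler()])
#' so that positive-shift augmentation is re-drawn every epoch. When a
#' validation set is given, the checkpoint maximizing the selection metric
#' (validation F1 by default) is retained.
#'
#' @param train A labeled `tss_windows`, or a function `(epoch) ->
#'   tss_windows`.
#' @param val Optional labeled `tss_windows` for checkpoint selection.
#' @param config A `train_config`.
#' @param init Optional starting `model_params` (e.g. a meta-model for
#'   fine-tuning); freshly initialized when `NULL`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used, so callers can manage reproducibility themselves.
#' @return An object of class `tss_model` with elements `params` (selected
#'   checkpoint), `final_params`, `config`, `history` (per-epoch losses and
#'   validation metric) and `best_epoch`.
#' @export
tss_fit <- function(train, val = NULL, config = train_config(), init = NULL,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- init %||% init_params(config)
  state <- NULL
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_metric = numeric(0))
  best <- list(params = params, metric = -Inf, epoch = 0L)
  if (!is.null(val) && n_windows(val) > 0L && config$epochs > 0L) {
    best$metric <- validation_metric(params, val, config$select_metric)
  }
  for (epoch in seq_len(config$epochs)) {
    data <- if (is.function(train)) train(epoch) else train
    n <- n_windows(data)
    perm <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      step <- train_step(params, windows_subset(data, idx), config, state)
      params <- step$params
      state <- step$state
      losses <- c(losses, step$loss)
    }
    vm <- NA_real_
    if (!is.null(val) && n_windows(val) > 0L &&
        (epoch %% config$eval_every == 0L || epoch == config$epochs)) {
      vm <- validation_metric(params, val, config$select_metric)
      # ties go to the later (more trained, sharper) checkpoint
      if (vm >= best$metric) {
        best <- list(params = params, metric = vm, epoch = epoch)
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses),
                                         val_metric = vm))
  }
  selected <- if (is.null(val) || n_windows(val) == 0L || best$epoch == 0L) {
    params
  } else {
    best$params
  }
  structure(list(params = selected, final_params = params, config = config,
                 history = history, best_epoch = best$epoch,
                 best_metric = best$metric),
            class = "tss_model")
}

#' @export
print.tss_model <- function(x, ...) {
  arch <- attr(x$params, "arch")
  cat("<tss_model> dual-branch convolutional TSS classifier\n",
      "  branches: ", arch$branches, "; ", arch$n_filters, " filters x width ",
      arch$filter_width, "; hidden ", arch$hidden_units, "\n",
      "  trained ", nrow(x$history), " epoch(s)", sep = "")
  if (x$best_epoch > 0L) {
    cat("; selected checkpoint from epoch ", x$best_epoch,
        " (validation ", x$config$select_metric, " = ",
        signif(abs(x$best_metric), 4), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.tss_model <- function(object, ...) {
  print(object)
  h <- object$history
  if (nrow(h) > 0L) {
    cat("  loss: first ", signif(h$loss[1L], 4), " -> last ",
        signif(h$loss[nrow(h)], 4), "\n", sep = "")
  }
  cat("  parameters: ", sum(vapply(object$params, length, integer(1))),
      " values in ", length(object$params), " arrays\n", sep = "")
  invisible(object)
}

#' @export
coef.tss_model <- function(object, ...) object$params

#' Score paired windows with a fitted model
#'
#' @param object A `tss_model`.
#' @param newdata A `tss_windows`.
#' @param type `"score"` for class-1 probabilities, `"class"` for 0/1 calls
#'   at threshold 0.5.
#' @param chunk Evaluation chunk size (memory control only).
#' @param ... Unused.
#' @return Numeric (or integer) vector, one value per window.
#' @export
predict.tss_model <- function(object, newdata, type = c("score", "class"),
                              chunk = 1024L, ...) {
  type <- match.arg(type)
  n <- n_windows(newdata)
  scores <- numeric(n)
  for (start in seq(1L, max(n, 1L), by = chunk)) {
    if (n == 0L) break
    idx <- start:min(start + chunk - 1L, n)
    scores[idx] <- model_forward(object$params, windows_subset(newdata, idx))
  }
  if (type == "class") as.integer(scores > 0.5) else scores
}

#' @export
plot.tss_model <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) {
    warning("no training history to plot")
    return(invisible(x))
  }
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss",
       main = "tss_model training", ...)
  if (any(!is.na(h$val_metric))) {
    ok <- !is.na(h$val_metric)
    graphics::points(h$epoch[ok], h$val_metric[ok] * max(h$loss),
                     pch = 20, col = "firebrick")
  }
  invisible(x)
}

#' Binary-classification evaluation of a model on labeled windows
#'
#' Predictions are thresholded at 0.5 and summarized by the standard
#' confusion counts and the five derived metrics.
#'
#' @param model A `tss_model` (or bare `model_params`).
#' @param windows A labeled `tss_windows`.
#' @return `list(counts = confusion_counts, metrics = named numeric)`.
#' @export
evaluate_binary <- function(model, windows) {
  params <- if (inherits(model, "tss_model")) model$params else model
  scores <- model_forward(params, windows)
  pred <- as.integer(scores > 0.5)
  cnt <- confusion_counts(tp = sum(pred == 1L & windows$label == 1L),
                          fp = sum(pred == 1L & windows$label == 0L),
                          tn = sum(pred == 0L & windows$label == 0L),
                          fn = sum(pred == 0L & windows$label == 1L))
  list(counts = cnt, metrics = metrics(cnt))
}
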