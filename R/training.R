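# Hard-negative ("circular") retraining and Reptile meta-learning with
# per-cell-type fine-tuning.

#' Circular-training configuration
#'
#' @param rounds Number of training rounds. Round 0 is plain training on
#'   the initial balanced dataset; each later round trains on negatives
#'   half-replaced by false positives harvested from a scan.
#' @param n_scan_tss True TSSs drawn (from the training positives) per
#'   round for the false-positive harvesting scan.
#' @param scan_halfwidth Half-width (bp) of the scan window around each
#'   drawn TSS.
#' @param positive_halfwidth Half-width (bp) of the positive region around
#'   each drawn TSS: sites scoring above 0.5 inside it count as TP, outside
#'   as FP.
#' @param replace_fraction Fraction of the negative set replaced per round.
#' @param harvest_margin Minimum distance (bp) between a harvested FP site
#'   and any active peak on the same strand before it may enter the
#'   negative set. The default equals the positive shift-augmentation range
#'   (50 bp): a harvested site closer than that to a true peak is
#'   indistinguishable from a training positive and would poison the
#'   labels, while sites beyond it are legitimate hard negatives (the FP
#'   counts themselves are never filtered).
#' @return A list of class `circular_config`.
#' @export
circular_config <- function(rounds = 3L, n_scan_tss = 100L,
                            scan_halfwidth = 5000L, positive_halfwidth = 500L,
                            replace_fraction = 0.5, harvest_margin = 50L) {
  stopifnot(rounds >= 1, replace_fraction > 0, replace_fraction < 1,
            positive_halfwidth < scan_halfwidth)
  structure(list(rounds = as.integer(rounds),
                 n_scan_tss = as.integer(n_scan_tss),
                 scan_halfwidth = as.integer(scan_halfwidth),
                 positive_halfwidth = as.integer(positive_halfwidth),
                 replace_fraction = replace_fraction,
                 harvest_margin = as.integer(harvest_margin)),
            class = "circular_config")
}

#' Split peaks into training and validation anchors
#'
#' @param peaks A `tss_peaks`.
#' @param val_fraction Fraction held out for validation.
#' @return `list(train = , val = )` of `tss_peaks`.
#' @export
split_peaks <- function(peaks, val_fraction = 0.2) {
  n <- nrow(peaks)
  n_val <- max(1L, round(val_fraction * n))
  idx_val <- sample.int(n, n_val)
  list(train = peaks[-idx_val, , drop = FALSE],
       val = peaks[idx_val, , drop = FALSE])
}

# Score every site of the +/- scan window around each drawn TSS; classify
# each above-threshold site TP (inside the positive region of its own
# window) or FP (outside). All windows are scored in one scan pass so each
# contig/strand convolution track is computed once.
scan_true_tss_windows <- function(params, genome, coverage, drawn, cfg,
                                  window_len = WINDOW_LEN) {
  half <- (window_len - 1L) %/% 2L
  ranges <- lapply(seq_len(nrow(drawn)), function(i) {
    L <- genome$lengths[[drawn$contig[i]]]
    lo <- max(half, drawn$pos[i] - cfg$scan_halfwidth)
    hi <- min(L - 1L - half, drawn$pos[i] + cfg$scan_halfwidth)
    if (hi < lo) return(NULL)
    data.frame(contig = drawn$contig[i], strand = drawn$strand[i],
               site = lo:hi, stringsAsFactors = FALSE)
  })
  sites <- unique(do.call(rbind, ranges))
  track <- scan_genome(params, genome, coverage, sites = sites,
                       window_len = window_len)
  hit <- track[track$score > 0.5, , drop = FALSE]
  fp_sites <- list()
  fp_per_window <- integer(nrow(drawn))
  tp_per_window <- integer(nrow(drawn))
  for (i in seq_len(nrow(drawn))) {
    h <- hit[hit$contig == drawn$contig[i] & hit$strand == drawn$strand[i] &
               abs(hit$site - drawn$pos[i]) <= cfg$scan_halfwidth, ,
             drop = FALSE]
    inside <- abs(h$site - drawn$pos[i]) <= cfg$positive_halfwidth
    tp_per_window[i] <- sum(inside)
    fp_per_window[i] <- sum(!inside)
    if (any(!inside)) {
      fp_sites[[length(fp_sites) + 1L]] <-
        data.frame(contig = drawn$contig[i], strand = drawn$strand[i],
                   site = h$site[!inside], stringsAsFactors = FALSE)
    }
  }
  fp <- if (length(fp_sites)) unique(do.call(rbind, fp_sites)) else NULL
  list(fp_sites = fp, fp_per_window = fp_per_window,
       tp_per_window = tp_per_window)
}

#' Circular training: iterative false-positive enhancement
#'
#' Round 0 trains on the initial balanced dataset (so it is identical to
#' plain training under the same RNG state and serves as the built-in
#' ablation baseline). After each round, the current model scans +/-
#' `scan_halfwidth` bp around up to `n_scan_tss` true TSSs drawn from the
#' training positives; above-0.5 sites outside the +/- 500 bp positive
#' region are false positives, a random half of the negative set is
#' replaced by windows drawn from them (without replacement; fewer are
#' replaced if fewer were harvested), and training repeats. The negative
#' set size is invariant across rounds.
#'
#' @param peaks A `tss_peaks` (actives are selected internally by
#'   `spec$active_expression_threshold`).
#' @param genome,coverage Inputs.
#' @param cfg A `circular_config`.
#' @param train_cfg A `train_config` used for every round.
#' @param spec A `dataset_spec`.
#' @param seed Optional seed set once at entry; all draws of all rounds
#'   then flow from the single global RNG stream.
#' @return An object of class `circular_fit`: list with `model` (final
#'   round), `round0_model` (ablation baseline), `models` (per round),
#'   `history` (per-round data frame: validation metric, TP/FP totals,
#'   median FPs per scanned window, negatives replaced).
#' @export
circular_train <- function(peaks, genome, coverage, cfg = circular_config(),
                           train_cfg = train_config(), spec = dataset_spec(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  active <- select_active_peaks(peaks, spec$active_expression_threshold)
  if (nrow(active) < 2L) stop("circular_train: need at least 2 active peaks")
  sp <- split_peaks(active)
  neg <- sample_negatives(sp$train, nrow(sp$train), genome, coverage, spec)
  sampler <- epoch_sampler(sp$train, neg, genome, coverage, spec)
  val <- windows_bind(
    sample_positives(sp$val, genome, coverage, spec),
    sample_negatives(sp$val, nrow(sp$val), genome, coverage, spec))
  by_key <- lapply(split(active$pos, paste0(active$contig, "/", active$strand)),
                   sort)
  models <- vector("list", cfg$rounds)
  history <- data.frame()
  for (r in seq_len(cfg$rounds) - 1L) {
    model <- tss_fit(sampler, val, train_cfg)
    models[[r + 1L]] <- model
    n_draw <- min(cfg$n_scan_tss, nrow(sp$train))
    drawn <- sp$train[sample.int(nrow(sp$train), n_draw), , drop = FALSE]
    sc <- scan_true_tss_windows(model$params, genome, coverage, drawn, cfg,
                                spec$window_len)
    negs <- attr(sampler, "get_negatives")()
    n_neg <- n_windows(negs)
    n_replaced <- 0L
    if (r < cfg$rounds - 1L) {
      pool <- sc$fp_sites
      if (!is.null(pool)) {
        # keep mislabeled windows out: drop FPs near any same-strand peak
        ok <- vapply(seq_len(nrow(pool)), function(i) {
          key <- paste0(pool$contig[i], "/", pool$strand[i])
          nearest_peak_dist(pool$site[i], by_key[[key]]) > cfg$harvest_margin
        }, logical(1))
        pool <- pool[ok, , drop = FALSE]
      }
      if (is.null(pool) || nrow(pool) == 0L) {
        message("circular_train: round ", r, " harvested no usable FPs; ",
                "negatives unchanged")
      } else {
        n_rep <- min(floor(cfg$replace_fraction * n_neg), nrow(pool))
        take <- pool[sample.int(nrow(pool), n_rep), , drop = FALSE]
        fresh <- windows_from_centers(
          genome, coverage,
          data.frame(contig = take$contig, center = take$site,
                     strand = take$strand, stringsAsFactors = FALSE),
          0L, spec$window_len)
        n_rep <- n_windows(fresh)  # out-of-bounds never occurs; keep honest
        slot <- sample.int(n_neg, n_rep)
        keep <- windows_subset(negs, setdiff(seq_len(n_neg), slot))
        attr(sampler, "set_negatives")(windows_bind(keep, fresh))
        n_replaced <- n_rep
      }
    }
    history <- rbind(history, data.frame(
      round = r,
      val_metric = abs(model$best_metric),
      tp_total = sum(sc$tp_per_window),
      fp_total = sum(sc$fp_per_window),
      fp_median_per_window = stats::median(sc$fp_per_window),
      n_negatives = n_neg,
      n_replaced = n_replaced))
  }
  structure(list(model = models[[cfg$rounds]], round0_model = models[[1L]],
                 models = models, history = history, config = cfg),
            class = "circular_fit")
}

#' @export
print.circular_fit <- function(x, ...) {
  cat("<circular_fit> ", nrow(x$history), " round(s)\n", sep = "")
  print(x$history, row.names = FALSE)
  invisible(x)
}

# ---- Reptile meta-learning ---------------------------------------------------

#' Meta-learning configuration
#'
#' @param inner_steps Inner SGD batches per meta-iteration (k).
#' @param meta_step Reptile step size epsilon in (0, 1].
#' @param meta_iterations Number of meta-iterations.
#' @param finetune_fraction Fraction of a cell type's data used for
#'   fine-tuning (and, symmetrically, for its meta-training share).
#' @return A list of class `meta_config`.
#' @export
meta_config <- function(inner_steps = 50L, meta_step = 0.1,
                        meta_iterations = 200L, finetune_fraction = 0.2) {
  stopifnot(inner_steps >= 1, meta_step > 0, meta_step <= 1,
            meta_iterations >= 0)
  structure(list(inner_steps = as.integer(inner_steps),
                 meta_step = meta_step,
                 meta_iterations = as.integer(meta_iterations),
                 finetune_fraction = finetune_fraction),
            class = "meta_config")
}

#' Stratified meta/fine-tune split of one task's windows
#'
#' @param windows A labeled `tss_windows`.
#' @param fraction Fraction assigned to the meta-training share.
#' @return `list(meta = , rest = )`.
#' @export
meta_task_split <- function(windows, fraction = 0.2) {
  n <- n_windows(windows)
  pick <- logical(n)
  for (lab in unique(windows$label)) {
    idx <- which(windows$label == lab)
    pick[sample(idx, max(1L, round(fraction * length(idx))))] <- TRUE
  }
  list(meta = windows_subset(windows, pick),
       rest = windows_subset(windows, !pick))
}

default_inner_fit <- function(train_cfg) {
  function(params, task) {
    n <- n_windows(task)
    state <- NULL
    k <- attr(params, ".inner_steps")
    for (i in seq_len(k)) {
      idx <- sample.int(n, min(train_cfg$batch_size, n))
      step <- train_step(params, windows_subset(task, idx), train_cfg, state)
      params <- step$params
      state <- step$state
    }
    params
  }
}

#' Reptile meta-training across cell-type tasks
#'
#' Serial Reptile: repeatedly sample a task, copy the meta-parameters,
#' train the copy for `inner_steps` batches on that task alone, then move
#' the meta-parameters a fraction `meta_step` of the way toward the trained
#' copy: `theta <- theta + eps * (W - theta)`. With a single task no task
#' sampling draw is consumed, and with `eps = 1` the update is exact
#' adoption of the inner-trained parameters.
#'
#' @param tasks List of labeled `tss_windows`, one per cell type (each
#'   should be that cell type's designated meta-training share, e.g. 20%).
#' @param cfg A `meta_config`.
#' @param train_cfg A `train_config` for the inner loop.
#' @param inner_fit Optional replacement inner loop, a function
#'   `(params, task) -> params`; the meta-update itself is agnostic to what
#'   the parameters are, so closed-form toy problems can be plugged in.
#' @param init Optional initial parameters (default [init_params()]).
#' @param seed Optional seed set once at entry.
#' @return Meta-trained `model_params`.
#' @export
reptile_meta_train <- function(tasks, cfg = meta_config(),
                               train_cfg = train_config(),
                               inner_fit = NULL, init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(tasks) >= 1L)
  theta <- init %||% init_params(train_cfg)
  if (is.null(inner_fit)) {
    attr(theta, ".inner_steps") <- cfg$inner_steps
    inner_fit <- default_inner_fit(train_cfg)
  }
  n_tasks <- length(tasks)
  for (it in seq_len(cfg$meta_iterations)) {
    t <- if (n_tasks > 1L) sample.int(n_tasks, 1L) else 1L
    task <- tasks[[t]]
    if (inherits(task, "tss_windows") && n_windows(task) == 0L) {
      warning("reptile_meta_train: empty task ", t, " skipped")
      next
    }
    W <- inner_fit(theta, task)
    if (cfg$meta_step == 1) {
      theta <- W
    } else {
      for (nm in names(theta)) {
        theta[[nm]] <- theta[[nm]] + cfg$meta_step * (W[[nm]] - theta[[nm]])
      }
    }
  }
  attr(theta, ".inner_steps") <- NULL
  theta
}

#' Fine-tune a meta-model on one cell type
#'
#' Standard training initialized from the meta-parameters on the task's
#' fine-tuning split; with a validation set the best checkpoint is
#' returned. The meta-parameters themselves are never modified. With
#' `config$epochs = 0` the returned model carries the meta-parameters
#' unchanged.
#'
#' @param meta_params Meta-trained `model_params`.
#' @param task A labeled `tss_windows` (the cell type's fine-tuning data).
#' @param config A `train_config`.
#' @param val Optional validation `tss_windows`.
#' @param seed Optional seed.
#' @return A `tss_model`.
#' @export
finetune <- function(meta_params, task, config = train_config(), val = NULL,
                     seed = NULL) {
  tss_fit(task, val = val, config = config, init = meta_params, seed = seed)
}
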