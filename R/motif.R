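# Gain-of-motif-information (GMI) extraction: each convolution filter of a
# meta-model is paired with the same-index filter of a fine-tuned model,
# both are converted to position weight matrices, and the difference
# (fine-tuned minus meta) is the GMI -- the sequence information a cell
# type gained during fine-tuning. GMIs are exported in MEME minimal format
# for external motif matching (e.g. Tomtom against JASPAR); a built-in
# best-offset correlation comparator covers dependency-free use.

PWM_EXPORT_ORDER <- c(1L, 3L, 4L, 2L)  # internal (A,T,C,G) -> export (A,C,G,T)

#' Convert a convolution filter to a position weight matrix
#'
#' Per-position softmax over the four channels (the `"softmax"` method,
#' default), or min-shift followed by renormalization (`"shift"`). Either
#' way every column is a probability distribution over bases.
#'
#' @param filter_weights One filter: a length `4 * width` vector in the
#'   internal channel-fastest layout (a column of the sequence weight
#'   matrix), or a `4 x width` matrix with rows in (A, T, C, G) order.
#' @param method `"softmax"` or `"shift"`.
#' @return A `4 x width` matrix of class `pwm`, rows named A, T, C, G,
#'   columns summing to 1.
#' @export
filter_to_pwm <- function(filter_weights, method = c("softmax", "shift")) {
  method <- match.arg(method)
  m <- if (is.matrix(filter_weights)) filter_weights else {
    matrix(filter_weights, nrow = 4L)
  }
  if (nrow(m) != 4L) stop("filter_to_pwm: expected 4 channels")
  if (!all(is.finite(m))) stop("filter_to_pwm: non-finite weights")
  p <- if (method == "softmax") {
    e <- exp(sweep(m, 2L, apply(m, 2L, max)))
    sweep(e, 2L, colSums(e), "/")
  } else {
    s <- sweep(m, 2L, apply(m, 2L, min))
    cs <- colSums(s)
    cs[cs == 0] <- 1
    s <- sweep(s, 2L, cs, "/")
    s[, colSums(s) == 0] <- 0.25
    s
  }
  dimnames(p) <- list(ONE_HOT_CHANNELS, NULL)
  class(p) <- c("pwm", class(p))
  p
}

# All sequence-branch filters of a parameter set as PWMs.
extract_pwms <- function(params, method = "softmax") {
  if (is.null(params$W_seq)) stop("model has no sequence branch")
  width <- attr(params, "arch")$filter_width
  lapply(seq_len(ncol(params$W_seq)), function(i) {
    filter_to_pwm(matrix(params$W_seq[, i], nrow = 4L, ncol = width), method)
  })
}

#' Compute gains of motif information between meta and fine-tuned models
#'
#' One GMI per (cell type, filter): the fine-tuned filter's PWM minus the
#' meta filter's PWM at the same index (fine-tuning preserves filter
#' indices). With k cell types and 64 filters this yields k x 64 GMIs.
#'
#' @param meta Meta-model parameters (`model_params` or `tss_model`).
#' @param finetuned Named list of fine-tuned parameter sets, one per cell
#'   type.
#' @param method PWM conversion method, see [filter_to_pwm()].
#' @return A list of class `gmi_set`; each element has `cell_type`,
#'   `filter` (1-based index) and `delta` (4 x width matrix).
#' @export
compute_gmis <- function(meta, finetuned, method = "softmax") {
  as_params <- function(x) if (inherits(x, "tss_model")) x$params else x
  meta <- as_params(meta)
  meta_arch <- attr(meta, "arch")
  meta_pwms <- extract_pwms(meta, method)
  if (is.null(names(finetuned))) {
    names(finetuned) <- paste0("celltype", seq_along(finetuned))
  }
  out <- list()
  for (ct in names(finetuned)) {
    p <- as_params(finetuned[[ct]])
    arch <- attr(p, "arch")
    if (!identical(dim(p$W_seq), dim(meta$W_seq)) ||
        arch$filter_width != meta_arch$filter_width) {
      stop("compute_gmis: architecture mismatch for ", ct)
    }
    pw <- extract_pwms(p, method)
    for (i in seq_along(pw)) {
      out[[length(out) + 1L]] <- list(cell_type = ct, filter = i,
                                      delta = unclass(pw[[i]]) -
                                        unclass(meta_pwms[[i]]))
    }
  }
  structure(out, class = "gmi_set")
}

#' @export
print.gmi_set <- function(x, ...) {
  cts <- unique(vapply(x, `[[`, character(1), "cell_type"))
  cat("<gmi_set> ", length(x), " GMIs across ", length(cts),
      " cell type(s)\n", sep = "")
  invisible(x)
}

gmi_to_prob <- function(delta) {
  pos <- pmax(delta, 0)
  cs <- colSums(pos)
  pos[, cs == 0] <- 0.25  # no gained information -> uniform column
  cs[cs == 0] <- 1
  sweep(pos, 2L, cs, "/")
}

#' Export GMIs as a MEME minimal motif file
#'
#' The positive (gained) part of each GMI is rectified and per-column
#' renormalized into a probability motif (uniform where nothing was
#' gained), named `<celltype>_f<index>`, and written in MEME minimal
#' format with rows in A, C, G, T order for matching against motif
#' databases with Tomtom or similar tools.
#'
#' @param gmis A `gmi_set`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
export_motifs <- function(gmis, path) {
  if (length(gmis) == 0L) stop("export_motifs: empty GMI set")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (g in gmis) {
    prob <- gmi_to_prob(g$delta)[PWM_EXPORT_ORDER, , drop = FALSE]
    w <- ncol(prob)
    writeLines(sprintf("MOTIF %s_f%d", g$cell_type, g$filter), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", w), con)
    for (j in seq_len(w)) {
      writeLines(paste(sprintf("%.6f", prob[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal motif file
#'
#' Parses the subset of the format written by [export_motifs()] (and by
#' common motif databases): `MOTIF` records with letter-probability
#' matrices.
#'
#' @param path A MEME-format file.
#' @return Named list of `w x 4` probability matrices with columns
#'   A, C, G, T.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) &&
             !startsWith(lines[j], "letter-probability matrix")) j <- j + 1L
      if (j > length(lines)) stop("read_meme: motif ", name, " has no matrix")
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[j + seq_len(w)]
      m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
      colnames(m) <- c("A", "C", "G", "T")
      out[[name]] <- m
      i <- j + w + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Best-offset Pearson correlation between two probability motifs (w x 4,
# same alphabet order), sliding the shorter over the longer with at least
# `min_overlap` overlapping positions.
motif_similarity <- function(a, b, min_overlap = 4L) {
  if (ncol(a) != 4L || ncol(b) != 4L) stop("motifs must be w x 4")
  if (nrow(a) > nrow(b)) return(motif_similarity(b, a, min_overlap))
  wa <- nrow(a); wb <- nrow(b)
  best <- -Inf
  for (off in seq(-(wa - min_overlap), wb - min_overlap)) {
    ia <- max(1L, 1L - off):min(wa, wb - off)
    if (length(ia) < min_overlap) next
    va <- as.vector(a[ia, , drop = FALSE])
    vb <- as.vector(b[ia + off, , drop = FALSE])
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    best <- max(best, stats::cor(va, vb))
  }
  best
}

#' Match GMI motifs against a reference motif set
#'
#' Dependency-free stand-in for an external motif comparison tool:
#' similarity is the best-offset Pearson correlation between probability
#' matrices, and significance is a permutation P value obtained by
#' shuffling the query's columns.
#'
#' @param query Named list of `w x 4` probability matrices (e.g. from
#'   [read_meme()]).
#' @param reference Named list of `w x 4` probability matrices.
#' @param n_perm Number of column permutations.
#' @param p_max Keep matches with permutation `P <= p_max`.
#' @return Data frame `query`, `reference`, `similarity`, `p_value`,
#'   one row per retained match.
#' @export
match_motifs <- function(query, reference, n_perm = 100L, p_max = 0.05) {
  rows <- list()
  for (qn in names(query)) {
    q <- query[[qn]]
    for (rn in names(reference)) {
      obs <- motif_similarity(q, reference[[rn]])
      if (!is.finite(obs)) next
      perm <- vapply(seq_len(n_perm), function(i) {
        motif_similarity(q[sample.int(nrow(q)), , drop = FALSE],
                         reference[[rn]])
      }, numeric(1))
      p <- (1 + sum(perm >= obs)) / (n_perm + 1)
      if (p <= p_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = qn, reference = rn, similarity = obs, p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query = character(0), reference = character(0),
                      similarity = numeric(0), p_value = numeric(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Select transcription factors with expression-concordant GMI profiles
#'
#' For each TF, the binary per-cell-type profile (1: the cell type's
#' fine-tuned model produced an associated GMI; 0: it did not) is
#' correlated with the TF's expression across the same cell types; TFs
#' with Pearson `r > r_min` are retained. A TF with a constant profile has
#' no defined correlation and is skipped with a note.
#'
#' @param match_profile Numeric 0/1 matrix, TFs x cell types, rownames =
#'   TF names.
#' @param expression Numeric matrix of matching shape.
#' @param r_min Correlation threshold (exclusive), default 0.2.
#' @return Data frame `tf`, `r`, `retained`, one row per TF (constant
#'   profiles get `r = NA`, `retained = FALSE`).
#' @export
concordance_filter <- function(match_profile, expression, r_min = 0.2) {
  if (!all(dim(match_profile) == dim(expression))) {
    stop("profile/expression dimension mismatch")
  }
  if (ncol(match_profile) < 3L) stop("need at least 3 cell types")
  tf <- rownames(match_profile) %||% paste0("TF", seq_len(nrow(match_profile)))
  r <- vapply(seq_len(nrow(match_profile)), function(i) {
    p <- match_profile[i, ]
    e <- expression[i, ]
    if (stats::sd(p) == 0 || stats::sd(e) == 0) return(NA_real_)
    stats::cor(p, e)
  }, numeric(1))
  if (anyNA(r)) {
    message(sum(is.na(r)), " TF(s) with constant profile skipped")
  }
  data.frame(tf = tf, r = r, retained = !is.na(r) & r > r_min,
             stringsAsFactors = FALSE)
}
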