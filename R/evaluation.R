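# Binary-classification metrics and genome-scanning evaluation with
# positional tolerance. Undefined metrics (zero denominators) are reported
# as NA, never silently as 0.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative counts. `tn` may be `NA` for scanning
#'   evaluation, where true negatives are not enumerable.
#' @return A named integer-ish vector of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  v <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (any(v < 0, na.rm = TRUE)) stop("confusion counts must be non-negative")
  structure(v, class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)`, FPR
#' `FP/(FP+TN)`, FDR `FP/(FP+TP)` and F1 `2TP/(2TP+FP+FN)`. Any metric with
#' a zero (or `NA`) denominator is returned as `NA`.
#'
#' @param counts A `confusion_counts`.
#' @return Named numeric: `accuracy`, `recall`, `fpr`, `fdr`, `f1`.
#' @export
metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]])
  fn <- as.numeric(counts[["FN"]])
  safe_div <- function(num, den) {
    if (is.na(den) || den == 0) NA_real_ else num / den
  }
  c(accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    recall = safe_div(tp, tp + fn),
    fpr = safe_div(fp, fp + tn),
    fdr = safe_div(fp, fp + tp),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn))
}

#' Scanning-evaluation configuration
#'
#' @param tolerance Maximum distance (bp) between a predicted signal and a
#'   true TSS for the prediction to count as a true positive.
#' @param signal_threshold Score above which a site counts as a signal.
#' @param fp_window Width (bp) of the false-positive rate unit used by
#'   [fps_per_kb()].
#' @return A list of class `scan_eval_config`.
#' @export
scan_eval_config <- function(tolerance = 100L, signal_threshold = 0.5,
                             fp_window = 1000L) {
  stopifnot(tolerance > 0)
  structure(list(tolerance = as.integer(tolerance),
                 signal_threshold = signal_threshold,
                 fp_window = as.integer(fp_window)),
            class = "scan_eval_config")
}

#' Tolerance-based confusion counts for genome-scanning predictions
#'
#' Greedy one-to-one matching in decreasing score order: each prediction
#' within `tolerance` of a still-unmatched same-strand truth becomes a TP
#' (consuming that truth), otherwise an FP. Score ties are broken by
#' distance to the nearest truth, then by position. A truth with no signal
#' scoring above `signal_threshold` within tolerance is an FN. TN is not
#' enumerable when scanning and is reported as `NA`.
#'
#' @param pred Data frame of predicted positions with columns `contig`,
#'   `strand`, `pos` and `score` (cluster representatives or raw sites).
#' @param truth A `tss_peaks`-like data frame of true TSSs.
#' @param cfg A `scan_eval_config`.
#' @return A `confusion_counts` with `TN = NA`, plus attributes
#'   `matched` (data frame of TP prediction/truth pairs with offsets).
#' @export
scan_confusion <- function(pred, truth, cfg = scan_eval_config()) {
  tp <- 0L; fp <- 0L; fn <- 0L
  matched <- data.frame(contig = character(0), strand = character(0),
                        pred_pos = integer(0), truth_pos = integer(0),
                        offset = integer(0), stringsAsFactors = FALSE)
  keys <- unique(rbind(pred[c("contig", "strand")],
                       truth[c("contig", "strand")]))
  for (i in seq_len(nrow(keys))) {
    ctg <- keys$contig[i]; std <- keys$strand[i]
    p <- pred[pred$contig == ctg & pred$strand == std, , drop = FALSE]
    t_pos <- truth$pos[truth$contig == ctg & truth$strand == std]
    if (nrow(p) > 0L) {
      t_sorted <- sort(t_pos)
      dist_any <- vapply(p$pos, nearest_peak_dist, numeric(1),
                         sorted_peaks = t_sorted)
      o <- order(-p$score, dist_any, p$pos)
      p <- p[o, , drop = FALSE]
      taken <- logical(length(t_pos))
      for (j in seq_len(nrow(p))) {
        d <- abs(t_pos - p$pos[j])
        d[taken] <- Inf
        if (length(d) > 0L && min(d) <= cfg$tolerance) {
          k <- which.min(d)
          taken[k] <- TRUE
          tp <- tp + 1L
          matched <- rbind(matched, data.frame(
            contig = ctg, strand = std, pred_pos = p$pos[j],
            truth_pos = t_pos[k], offset = p$pos[j] - t_pos[k],
            stringsAsFactors = FALSE))
        } else {
          fp <- fp + 1L
        }
      }
      # FN: truths with no above-threshold signal within tolerance
      strong <- p$pos[p$score > cfg$signal_threshold]
      for (k in which(!taken)) {
        if (length(strong) == 0L || min(abs(strong - t_pos[k])) > cfg$tolerance) {
          fn <- fn + 1L
        }
      }
    } else {
      fn <- fn + length(t_pos)
    }
  }
  out <- confusion_counts(tp = tp, fp = fp, tn = NA, fn = fn)
  attr(out, "matched") <- matched
  out
}

#' False positives per kilobase of scanned sequence
#'
#' The scanning-scale surrogate for FPR: with hundreds of millions of true
#' negatives, `FP/(FP+TN)` is uninformative, so the false-positive burden
#' is expressed per 1000 bp scanned.
#'
#' @param fp_count Number of false-positive calls.
#' @param scanned_bp Total scanned bases.
#' @return `fp_count * 1000 / scanned_bp`, or `NA` if `scanned_bp` is 0.
#' @export
fps_per_kb <- function(fp_count, scanned_bp) {
  if (scanned_bp == 0) return(NA_real_)
  fp_count * 1000 / scanned_bp
}

#' Per-TSS correlation between prediction score and expression
#'
#' For each TSS (row), the Pearson correlation between its prediction
#' scores and its expression levels across cell types (columns). Rows where
#' either vector is constant yield `NA`.
#'
#' @param pred_scores Numeric matrix, TSSs x cell types.
#' @param expression Numeric matrix of matching shape.
#' @return Numeric vector of per-TSS correlations.
#' @export
score_expression_correlation <- function(pred_scores, expression) {
  if (!all(dim(pred_scores) == dim(expression))) {
    stop("score/expression dimension mismatch")
  }
  if (ncol(pred_scores) < 3L) stop("need at least 3 cell types")
  vapply(seq_len(nrow(pred_scores)), function(i) {
    x <- pred_scores[i, ]
    y <- expression[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0 || anyNA(x) || anyNA(y)) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
}
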