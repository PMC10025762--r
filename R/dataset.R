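# Construction of balanced paired-window training sets: one 1001-bp one-hot
# sequence matrix plus the matched 1001-bp strand-specific coverage vector
# per example. Positives are shift-augmented active TSS peaks; negatives sit
# 500-1000 bp from the nearest same-strand peak.

WINDOW_LEN <- 1001L
WINDOW_HALF <- 500L

#' Dataset construction parameters
#'
#' @param window_len Window length in bp for both inputs (default 1001).
#' @param shift_max Maximum positive-window shift from the peak base, bp.
#' @param neg_min_dist,neg_max_dist Allowed distance range (bp) from a
#'   negative window's center to the nearest same-strand peak.
#' @param active_expression_threshold Minimum expression for a peak to count
#'   as active (positive class).
#' @param fractions Train/validation/test fractions, summing to 1.
#' @return A list of class `dataset_spec`.
#' @export
dataset_spec <- function(window_len = 1001L, shift_max = 50L,
                         neg_min_dist = 500L, neg_max_dist = 1000L,
                         active_expression_threshold = 1.0,
                         fractions = c(train = 0.8, val = 0.1, test = 0.1)) {
  stopifnot(neg_min_dist < neg_max_dist,
            abs(sum(fractions) - 1) < 1e-8,
            window_len %% 2L == 1L)
  structure(list(window_len = as.integer(window_len),
                 shift_max = as.integer(shift_max),
                 neg_min_dist = as.integer(neg_min_dist),
                 neg_max_dist = as.integer(neg_max_dist),
                 active_expression_threshold = active_expression_threshold,
                 fractions = fractions),
            class = "dataset_spec")
}

# ---- paired-window container -------------------------------------------------

new_windows <- function(seq, cov, label, origin) {
  structure(list(seq = seq, cov = cov, label = as.integer(label), origin = origin),
            class = "tss_windows")
}

empty_windows <- function(window_len = WINDOW_LEN) {
  new_windows(array(0, dim = c(0L, window_len, 4L)),
              matrix(0, nrow = 0L, ncol = window_len),
              integer(0),
              data.frame(contig = character(0), center = integer(0),
                         strand = character(0), stringsAsFactors = FALSE))
}

#' Number of paired windows in a window set
#' @param w A `tss_windows` object.
#' @return Integer count.
#' @export
n_windows <- function(w) dim(w$seq)[1L]

#' Subset a window set
#' @param w A `tss_windows` object.
#' @param idx Row indices (or logical mask).
#' @return A `tss_windows` with the selected examples.
#' @export
windows_subset <- function(w, idx) {
  new_windows(w$seq[idx, , , drop = FALSE], w$cov[idx, , drop = FALSE],
              w$label[idx], w$origin[idx, , drop = FALSE])
}

#' Concatenate window sets
#' @param ... `tss_windows` objects with matching window length.
#' @return A single combined `tss_windows`.
#' @export
windows_bind <- function(...) {
  parts <- Filter(function(p) n_windows(p) > 0L, list(...))
  if (length(parts) == 0L) return(empty_windows())
  L <- dim(parts[[1]]$seq)[2L]
  n <- sum(vapply(parts, n_windows, integer(1)))
  seq <- array(0, dim = c(n, L, 4L))
  cov <- matrix(0, nrow = n, ncol = L)
  at <- 0L
  for (p in parts) {
    k <- n_windows(p)
    seq[at + seq_len(k), , ] <- p$seq
    cov[at + seq_len(k), ] <- p$cov
    at <- at + k
  }
  new_windows(seq, cov,
              unlist(lapply(parts, `[[`, "label")),
              do.call(rbind, lapply(parts, `[[`, "origin")))
}

#' @export
print.tss_windows <- function(x, ...) {
  cat("<tss_windows> ", n_windows(x), " windows of length ", dim(x$seq)[2L],
      " (", sum(x$label == 1L), " positive / ", sum(x$label == 0L),
      " negative)\n", sep = "")
  invisible(x)
}

# ---- sampling ----------------------------------------------------------------

#' Filter peaks to the active (expressed) set
#'
#' @param peaks A `tss_peaks` data frame.
#' @param threshold Minimum expression; peaks with `expression >= threshold`
#'   are kept, order preserved.
#' @return The filtered `tss_peaks`.
#' @export
select_active_peaks <- function(peaks, threshold = 1.0) {
  stopifnot(threshold >= 0)
  peaks[peaks$expression >= threshold, , drop = FALSE]
}

#' Extract one paired sequence/coverage window
#'
#' The window spans `[center - 500, center + 500]` (for the default length).
#' Minus-strand windows are reverse-complemented and take coverage from the
#' minus track, so transcription always reads left-to-right; coverage is the
#' raw depth, used without preprocessing.
#'
#' @param genome A `tss_genome`.
#' @param coverage A `coverage_track`.
#' @param contig Contig name.
#' @param center 0-based center coordinate.
#' @param strand `"+"` or `"-"`.
#' @param window_len Window length (odd).
#' @return `list(seq = one-hot matrix, cov = numeric vector)`, or `NULL` if
#'   the window does not fit inside the contig.
#' @export
extract_window <- function(genome, coverage, contig, center, strand,
                           window_len = WINDOW_LEN) {
  half <- (window_len - 1L) %/% 2L
  L <- genome$lengths[[contig]]
  if (is.null(L)) stop("unknown contig: ", contig)
  if (center - half < 0L || center + half >= L) return(NULL)
  from <- center - half + 1L  # 1-based substring bounds
  to <- center + half + 1L
  seq <- substr(genome$contigs[[contig]], from, to)
  track <- if (strand == "+") coverage[[contig]]$plus else coverage[[contig]]$minus
  cov <- track[from:to]
  sm <- one_hot(seq)
  if (strand == "-") {
    rc <- reverse_complement_window(sm, cov)
    sm <- rc$seq
    cov <- rc$cov
  }
  list(seq = sm, cov = cov)
}

windows_from_centers <- function(genome, coverage, centers, label,
                                 window_len = WINDOW_LEN) {
  n <- nrow(centers)
  half <- (window_len - 1L) %/% 2L
  seq <- array(0, dim = c(n, window_len, 4L))
  cov <- matrix(0, nrow = n, ncol = window_len)
  keep <- logical(n)
  for (i in seq_len(n)) {
    w <- extract_window(genome, coverage, centers$contig[i], centers$center[i],
                        centers$strand[i], window_len)
    if (is.null(w)) next
    seq[i, , ] <- w$seq
    cov[i, ] <- w$cov
    keep[i] <- TRUE
  }
  if (!all(keep)) {
    warning(sum(!keep), " window(s) out of contig bounds skipped")
  }
  new_windows(seq[keep, , , drop = FALSE], cov[keep, , drop = FALSE],
              rep(as.integer(label), sum(keep)), centers[keep, , drop = FALSE])
}

#' Sample shift-augmented positive windows
#'
#' Draws one window per active peak, centered at `pos + delta` with `delta`
#' uniform on the integers `[-shift_max, shift_max]`; a draw that falls out
#' of bounds is redrawn up to 10 times, then the peak is skipped.
#'
#' @param active Active `tss_peaks`.
#' @param genome,coverage Inputs for window extraction.
#' @param spec A `dataset_spec`.
#' @return A `tss_windows` with `label = 1`.
#' @export
sample_positives <- function(active, genome, coverage, spec = dataset_spec()) {
  half <- (spec$window_len - 1L) %/% 2L
  n <- nrow(active)
  centers <- data.frame(contig = character(n), center = integer(n),
                        strand = character(n), stringsAsFactors = FALSE)
  keep <- logical(n)
  for (i in seq_len(n)) {
    L <- genome$lengths[[active$contig[i]]]
    for (try in seq_len(10L)) {
      delta <- sample.int(2L * spec$shift_max + 1L, 1L) - spec$shift_max - 1L
      ctr <- active$pos[i] + delta
      if (ctr - half >= 0L && ctr + half < L) {
        centers[i, ] <- list(active$contig[i], ctr, active$strand[i])
        keep[i] <- TRUE
        break
      }
    }
  }
  if (!all(keep)) warning(sum(!keep), " positive peak(s) skipped (no in-bounds shift)")
  windows_from_centers(genome, coverage, centers[keep, , drop = FALSE], 1L,
                       spec$window_len)
}

# Distance from position `pos` to the nearest peak of `peaks` on one contig
# (positions pre-extracted as a sorted vector).
nearest_peak_dist <- function(pos, sorted_peaks) {
  if (length(sorted_peaks) == 0L) return(Inf)
  i <- findInterval(pos, sorted_peaks)
  d <- Inf
  if (i >= 1L) d <- min(d, abs(pos - sorted_peaks[i]))
  if (i < length(sorted_peaks)) d <- min(d, abs(sorted_peaks[i + 1L] - pos))
  d
}

#' Sample distance-constrained negative windows
#'
#' Each negative window center lies 500-1000 bp (by default) from the
#' nearest peak on the same strand; the strand itself is drawn uniformly
#' among strands that carry at least one peak. Candidate centers are drawn
#' around a random peak and re-checked against the full peak set, so a
#' center landing closer than `neg_min_dist` to some other peak is rejected.
#'
#' @param active Peaks defining the distance constraint.
#' @param n Number of negatives to draw.
#' @param genome,coverage Inputs for window extraction.
#' @param spec A `dataset_spec`.
#' @return A `tss_windows` with `label = 0`.
#' @export
sample_negatives <- function(active, n, genome, coverage, spec = dataset_spec()) {
  stopifnot(n >= 0)
  if (n == 0L) return(empty_windows(spec$window_len))
  half <- (spec$window_len - 1L) %/% 2L
  strands <- unique(active$strand)
  if (length(strands) == 0L) stop("sample_negatives: no peaks to anchor negatives")
  by_key <- split(active$pos, paste0(active$contig, "/", active$strand))
  by_key <- lapply(by_key, sort)
  centers <- data.frame(contig = character(n), center = integer(n),
                        strand = character(n), stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    placed <- FALSE
    for (peak_try in seq_len(50L)) {
      strand <- strands[sample.int(length(strands), 1L)]
      anchor_set <- active[active$strand == strand, , drop = FALSE]
      a <- anchor_set[sample.int(nrow(anchor_set), 1L), , drop = FALSE]
      key <- paste0(a$contig, "/", strand)
      L <- genome$lengths[[a$contig]]
      for (try in seq_len(100L)) {
        d <- spec$neg_min_dist +
          sample.int(spec$neg_max_dist - spec$neg_min_dist + 1L, 1L) - 1L
        side <- if (stats::runif(1) < 0.5) -1L else 1L
        ctr <- a$pos + side * d
        if (ctr - half < 0L || ctr + half >= L) next
        dd <- nearest_peak_dist(ctr, by_key[[key]])
        if (dd >= spec$neg_min_dist && dd <= spec$neg_max_dist) {
          centers[j, ] <- list(a$contig, ctr, strand)
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) stop("sample_negatives: no valid negative position found")
  }
  windows_from_centers(genome, coverage, centers, 0L, spec$window_len)
}

#' Stratified train/validation/test split
#'
#' Partitions a window set into disjoint label-stratified subsets with the
#' given fractions; reproducible under a fixed RNG state.
#'
#' @param windows A `tss_windows`.
#' @param fractions Length-3 numeric summing to 1 (train, val, test).
#' @return `list(train = , val = , test = )` of `tss_windows`.
#' @export
split_dataset <- function(windows, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  n <- n_windows(windows)
  assign_grp <- integer(n)
  for (lab in unique(windows$label)) {
    idx <- which(windows$label == lab)
    idx <- idx[sample.int(length(idx))]
    k <- length(idx)
    n_train <- round(fractions[1] * k)
    n_val <- round(fractions[2] * k)
    grp <- rep(3L, k)
    grp[seq_len(n_train)] <- 1L
    if (n_val > 0L) grp[n_train + seq_len(min(n_val, k - n_train))] <- 2L
    assign_grp[idx] <- grp
  }
  list(train = windows_subset(windows, assign_grp == 1L),
       val = windows_subset(windows, assign_grp == 2L),
       test = windows_subset(windows, assign_grp == 3L))
}

#' Build a balanced labeled dataset from peaks, genome and coverage
#'
#' Selects active peaks, draws one shift-augmented positive window per peak
#' and the same number of distance-constrained negatives.
#'
#' @param genome,coverage,peaks Inputs.
#' @param spec A `dataset_spec`.
#' @return A balanced `tss_windows`.
#' @export
build_dataset <- function(genome, coverage, peaks, spec = dataset_spec()) {
  active <- select_active_peaks(peaks, spec$active_expression_threshold)
  if (nrow(active) == 0L) stop("no active peaks at threshold ",
                               spec$active_expression_threshold)
  pos <- sample_positives(active, genome, coverage, spec)
  neg <- sample_negatives(active, n_windows(pos), genome, coverage, spec)
  windows_bind(pos, neg)
}

# Fresh-epoch materializer: fixed negatives, fresh positive shifts each call.
# Returned closure is what `tss_fit()` consumes when shift augmentation is on.
#' Per-epoch training-set sampler with fresh shift augmentation
#'
#' Returns a function of the epoch index that re-draws the positive-window
#' shifts each epoch (the augmentation is applied when windows are
#' materialized, not frozen once) while keeping the negative set fixed.
#' The negative set can be swapped in place via the `set_negatives`
#' attribute, which is how circular training injects harvested false
#' positives.
#'
#' @param active Active peaks (positive anchors).
#' @param negatives A fixed `tss_windows` of negatives.
#' @param genome,coverage,spec Inputs for positive extraction.
#' @return A function `(epoch) -> tss_windows`, with attributes
#'   `get_negatives` / `set_negatives`.
#' @export
epoch_sampler <- function(active, negatives, genome, coverage,
                          spec = dataset_spec()) {
  env <- new.env(parent = emptyenv())
  env$neg <- negatives
  f <- function(epoch) {
    pos <- sample_positives(active, genome, coverage, spec)
    windows_bind(pos, env$neg)
  }
  attr(f, "get_negatives") <- function() env$neg
  attr(f, "set_negatives") <- function(neg) env$neg <- neg
  f
}
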