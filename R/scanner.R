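# Genome-wide stride-1 scoring over expressed regions, and clustering of
# the resulting score tracks into TSS calls.
#
# Scanning exploits translation invariance: each max-pool bin of a window
# is a maximum over a fixed-width run of convolution outputs, so scoring
# every window of a contig needs only one full-contig convolution per
# branch, one sliding maximum (width = pool bin), and a gather of the bin
# offsets per requested site before the fully connected head. This yields
# the same scores as window-by-window forward passes, at a small fraction
# of the arithmetic.

#' Enumerate expressed candidate sites
#'
#' Yields the sites whose strand-matched depth is at least `min_cov` and
#' whose scan window fits inside the contig. Restricting the scan to
#' expressed regions is what makes stride-1 genome scanning tractable.
#'
#' @param coverage A `coverage_track`.
#' @param min_cov Minimum per-base depth (default 1 read).
#' @param window_len Scan window length (for the fit constraint).
#' @return Data frame with columns `contig`, `strand`, `site` (0-based).
#' @export
expressed_sites <- function(coverage, min_cov = 1, window_len = WINDOW_LEN) {
  stopifnot(min_cov >= 0)
  half <- (window_len - 1L) %/% 2L
  out <- list()
  for (ctg in names(coverage)) {
    L <- length(coverage[[ctg]]$plus)
    lo <- half
    hi <- L - 1L - half
    if (hi < lo) next
    for (std in c("+", "-")) {
      track <- if (std == "+") coverage[[ctg]]$plus else coverage[[ctg]]$minus
      sites <- which(track >= min_cov) - 1L
      sites <- sites[sites >= lo & sites <= hi]
      if (length(sites) > 0L) {
        out[[paste0(ctg, std)]] <- data.frame(contig = ctg, strand = std,
                                              site = sites,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(0), strand = character(0),
                      site = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Sliding-max convolution tracks of one oriented contig, one per branch.
# seq_mat: L x 4 one-hot (already in transcription orientation); covvec:
# matching per-base depth. Row r of a track is the max of the raw
# convolution over output positions r-1 .. r-2+pool_w (0-based).
contig_branch_tracks <- function(params, seq_mat, covvec, window_len) {
  arch <- attr(params, "arch")
  width <- arch$filter_width
  P <- window_len - width + 1L
  pool_w <- min(arch$pool_size, P)
  tracks <- list(pool_w = pool_w)
  if (arch$branches %in% c("both", "seq")) {
    S <- seq_mat
    dim(S) <- c(1L, nrow(seq_mat), 4L)
    tracks$seq <- sliding_col_max(im2col_seq(S, width) %*% params$W_seq,
                                  pool_w)
  }
  if (arch$branches %in% c("both", "cov")) {
    tracks$cov <- sliding_col_max(
      im2col_cov(matrix(covvec, nrow = 1L), width) %*% params$W_cov, pool_w)
  }
  tracks
}

# Pooled features for window centers whose conv-output start (center -
# half, 0-based) is rows0: gather the per-bin offsets from the sliding-max
# tracks and apply relu(. + bias).
gather_pooled_features <- function(params, tracks, rows0) {
  arch <- attr(params, "arch")
  F <- arch$n_filters
  nbins <- arch$n_bins
  gather <- function(SM, bias) {
    X <- matrix(0, length(rows0), F * nbins)
    for (k in seq_len(nbins) - 1L) {
      X[, k * F + seq_len(F)] <-
        SM[rows0 + k * tracks$pool_w + 1L, , drop = FALSE]
    }
    pmax(add_row_vec(X, rep(bias, nbins)), 0)
  }
  parts <- list()
  if (arch$branches %in% c("both", "seq")) {
    parts$seq <- gather(tracks$seq, params$b_seq)
  }
  if (arch$branches %in% c("both", "cov")) {
    parts$cov <- gather(tracks$cov, params$b_cov)
  }
  do.call(cbind, unname(parts))
}

fc_head_scores <- function(params, X) {
  H <- pmax(add_row_vec(X %*% params$W1, params$b1), 0)
  softmax_rows(add_row_vec(H %*% params$W2, params$b2))[, 2L]
}

#' Scan genome positions with a trained model
#'
#' Scores each requested site with a deterministic evaluation-mode forward
#' pass on the 1001-bp window centered there (stride 1). When `sites` is
#' `NULL`, all expressed sites at depth `min_cov` are scanned. Minus-strand
#' sites are scored on the reverse-complemented sequence with the reversed
#' minus-strand coverage, exactly as training windows are built.
#'
#' @param model A `tss_model` or bare `model_params`.
#' @param genome A `tss_genome`.
#' @param coverage A `coverage_track`.
#' @param sites Optional data frame (`contig`, `strand`, `site`) of 0-based
#'   positions to score; out-of-range sites are dropped.
#' @param min_cov Expressed-site depth threshold used when `sites` is `NULL`.
#' @param window_len Window length (must match the trained model's input).
#' @return A `score_track` data frame: `contig`, `strand`, `site`, `score`,
#'   sorted by (contig, strand, site).
#' @export
scan_genome <- function(model, genome, coverage, sites = NULL, min_cov = 1,
                        window_len = WINDOW_LEN) {
  params <- if (inherits(model, "tss_model")) model$params else model
  if (is.null(sites)) sites <- expressed_sites(coverage, min_cov, window_len)
  half <- (window_len - 1L) %/% 2L
  res <- list()
  for (ctg in unique(sites$contig)) {
    L <- genome$lengths[[ctg]]
    if (is.null(L)) stop("scan_genome: unknown contig ", ctg)
    for (std in c("+", "-")) {
      ss <- sites$site[sites$contig == ctg & sites$strand == std]
      ss <- sort(unique(ss[ss >= half & ss <= L - 1L - half]))
      if (length(ss) == 0L) next
      if (std == "+") {
        seq_mat <- one_hot(genome$contigs[[ctg]])
        covvec <- coverage[[ctg]]$plus
        rows0 <- ss - half
      } else {
        seq_mat <- one_hot(revcomp_string(genome$contigs[[ctg]]))
        covvec <- rev(coverage[[ctg]]$minus)
        rows0 <- (L - 1L - ss) - half  # center in flipped coordinates
      }
      tracks <- contig_branch_tracks(params, seq_mat, covvec, window_len)
      scores <- numeric(length(ss))
      chunk <- 16384L  # bound the gathered feature matrix
      for (at in seq(1L, length(ss), by = chunk)) {
        span <- at:min(at + chunk - 1L, length(ss))
        X <- gather_pooled_features(params, tracks, rows0[span])
        scores[span] <- fc_head_scores(params, X)
      }
      res[[paste0(ctg, std)]] <- data.frame(contig = ctg, strand = std,
                                            site = ss, score = scores,
                                            stringsAsFactors = FALSE)
    }
  }
  track <- if (length(res) == 0L) {
    data.frame(contig = character(0), strand = character(0),
               site = integer(0), score = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(res, list(make.row.names = FALSE)))
  }
  track <- track[order(track$contig, track$strand, track$site), , drop = FALSE]
  rownames(track) <- NULL
  class(track) <- c("score_track", "data.frame")
  track
}

#' Cluster a score track into TSS calls
#'
#' Single left-to-right pass per contig/strand: sites scoring above
#' `score_min` that lie within `gap` bp of the previous qualifying site are
#' merged into one cluster. Sites at or below `score_min` are discarded.
#' The representative is the maximal-score member (leftmost on ties) and
#' the cluster score is `member count x mean member score` (equivalently
#' the summed member score), a density statistic favouring the dense
#' high-score runs that mark true TSSs over isolated high scores.
#'
#' @param track A `score_track`.
#' @param score_min Score threshold (exclusive), default 0.5.
#' @param gap Maximum distance (bp) between consecutive member sites.
#' @return A `tss_clusters` data frame: `contig`, `strand`, `start`, `end`
#'   (0-based half-open), `members`, `representative`, `score`.
#' @export
cluster_scores <- function(track, score_min = 0.5, gap = 10L) {
  cols <- c("contig", "strand", "start", "end", "members", "representative",
            "score")
  empty <- structure(
    data.frame(contig = character(0), strand = character(0),
               start = integer(0), end = integer(0), members = integer(0),
               representative = integer(0), score = numeric(0),
               stringsAsFactors = FALSE),
    class = c("tss_clusters", "data.frame"))
  keep <- track$score > score_min
  if (!any(keep)) return(empty)
  tr <- track[keep, , drop = FALSE]
  out <- list()
  for (key in unique(paste0(tr$contig, "\r", tr$strand))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- tr[tr$contig == parts[1] & tr$strand == parts[2], , drop = FALSE]
    g <- g[order(g$site), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(g$site) > gap))
    for (k in unique(grp)) {
      m <- g[grp == k, , drop = FALSE]
      rep_i <- which.max(m$score)  # leftmost maximal score
      out[[length(out) + 1L]] <- data.frame(
        contig = parts[1], strand = parts[2],
        start = min(m$site), end = max(m$site) + 1L,
        members = nrow(m), representative = m$site[rep_i],
        score = sum(m$score), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res <- res[order(res$contig, res$strand, res$start), cols, drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("tss_clusters", "data.frame")
  res
}

#' Filter clusters on score density
#'
#' Keeps clusters meeting both a minimum cluster score and a minimum member
#' count, in input order. The defaults (3 members, score 2.0) implement the
#' density criterion: a true TSS is marked by a dense run of high-scoring
#' sites, whereas isolated high scores are typically false positives.
#'
#' @param clusters A `tss_clusters`.
#' @param min_cluster_score Minimum cluster score.
#' @param min_members Minimum member count.
#' @return The filtered `tss_clusters`.
#' @export
filter_clusters <- function(clusters, min_cluster_score = 2.0, min_members = 3L) {
  stopifnot(min_cluster_score >= 0, min_members >= 0)
  clusters[clusters$score >= min_cluster_score &
             clusters$members >= min_members, , drop = FALSE]
}

#' Representative positions of clusters as a prediction table
#'
#' Convenience accessor for [scan_confusion()]: one row per cluster with
#' the representative site as the predicted TSS position.
#'
#' @param clusters A `tss_clusters`.
#' @return Data frame with `contig`, `strand`, `pos`, `score`.
#' @export
cluster_representatives <- function(clusters) {
  data.frame(contig = clusters$contig, strand = clusters$strand,
             pos = clusters$representative, score = clusters$score,
             stringsAsFactors = FALSE)
}
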