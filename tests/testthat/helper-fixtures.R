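# Shared helpers: tiny windows, tiny model configs, brute-force oracles,
# small fixtures.

# Small-architecture config for unit tests (window 21 bp, 4 filters of
# width 5, pooling in 3 bins of 5 conv positions).
tiny_cfg <- function(window_len = 21L, ...) {
  train_config(n_filters = 4L, filter_width = 5L, hidden_units = 6L,
               window_len = window_len, pool_size = 5L, ...)
}

# Mid-size config for the 41-bp separable toys.
toy_cfg <- function(...) {
  train_config(n_filters = 8L, filter_width = 6L, hidden_units = 16L,
               window_len = 41L, pool_size = 12L, keep_prob = 1,
               weight_decay = 0, learning_rate = 5e-3, momentum = 0.9, ...)
}

# Random labeled windows of arbitrary length (valid one-hot rows).
random_windows <- function(n, len = 21L) {
  seq <- array(0, dim = c(n, len, 4L))
  for (i in seq_len(n)) {
    idx <- sample.int(4L, len, replace = TRUE)
    seq[i, , ][cbind(seq_len(len), idx)] <- 1
  }
  tsscan:::new_windows(
    seq, matrix(stats::rexp(n * len), n, len),
    sample(0:1, n, replace = TRUE),
    data.frame(contig = "c", center = seq_len(n), strand = "+",
               stringsAsFactors = FALSE))
}

# Windows whose label is linearly recoverable: positives carry a fixed
# 6-mer at a fixed offset and/or a coverage step at the center.
toy_separable_windows <- function(n, len = 41L, seq_signal = TRUE,
                                  cov_signal = TRUE) {
  w <- random_windows(n, len)
  half <- (len - 1L) %/% 2L
  for (i in seq_len(n)) {
    if (w$label[i] == 1L) {
      if (seq_signal) {
        at <- (half - 8L):(half - 3L)
        w$seq[i, at, ] <- 0
        w$seq[i, at, ][cbind(seq_along(at), c(2L, 1L, 2L, 1L, 1L, 1L))] <- 1
      }
      if (cov_signal) {
        w$cov[i, (half + 1L):len] <- w$cov[i, (half + 1L):len] + 5
      }
    }
  }
  w
}

# Independent union-find interval-merge oracle for score clustering.
oracle_cluster <- function(track, score_min = 0.5, gap = 10L) {
  keep <- track[track$score > score_min, , drop = FALSE]
  out <- list()
  for (key in unique(paste(keep$contig, keep$strand))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    g <- keep[keep$contig == parts[1] & keep$strand == parts[2], , drop = FALSE]
    g <- g[order(g$site), , drop = FALSE]
    n <- nrow(g)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && abs(g$site[i] - g$site[j]) <= gap) {
        parent[find(j)] <- find(i)
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    for (r in unique(root)) {
      m <- g[root == r, , drop = FALSE]
      best <- which(m$score == max(m$score))[1L]
      out[[length(out) + 1L]] <- data.frame(
        contig = parts[1], strand = parts[2], start = min(m$site),
        end = max(m$site) + 1L, members = nrow(m),
        representative = m$site[best], score = sum(m$score),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$contig, res$strand, res$start), , drop = FALSE]
}

random_sparse_track <- function(n_sites = 30L, span = 500L) {
  sites <- sort(sample.int(span, n_sites))
  structure(data.frame(contig = "c1", strand = "+", site = sites,
                       score = stats::runif(n_sites),
                       stringsAsFactors = FALSE),
            class = c("score_track", "data.frame"))
}

small_fixture_cfg <- function(genome_length = 60000L, n_tss = 15L, ...) {
  synth_config(genome_length = genome_length, n_tss = n_tss, ...)
}
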