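# Deterministic synthetic-fixture generator. Emulates the statistical
# structure the scanner assumes: a random genome with a promoter-like
# motif planted at a fixed offset upstream of each TSS, a step-up of
# strand-specific coverage downstream of each TSS (transcription), Poisson
# background depth, and decoy motif sites that carry the sequence signal
# but no expression -- the hard negatives that make coverage informative.

#' Synthetic-fixture configuration
#'
#' Defaults describe the standard study fixture: a 200-kb contig carrying
#' 50 TSSs at least 2 kb apart, a TATA-like 8-mer planted 30 bp upstream
#' of each TSS with 10% per-base mismatch, log-normal expression
#' (meanlog 2, sdlog 0.6, so nearly all TSSs clear an activity threshold
#' of 1 while spanning an order of magnitude in depth), Poisson(0.5)
#' background depth, 1500-bp transcripts (long enough that a 1001-bp
#' window always sees the coverage step), and one decoy motif site for
#' every four real ones.
#'
#' @param genome_length Contig length in bp.
#' @param n_tss Number of planted TSSs (requires `n_tss * 2000 <
#'   genome_length`).
#' @param motif Consensus motif string planted upstream of each TSS.
#' @param mismatch_prob Per-base probability of mutating a planted motif
#'   base to a different random base.
#' @param motif_offset Gap (bp) between motif 3' end and the TSS.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters.
#' @param background_depth Poisson rate of background per-base depth.
#' @param transcript_length Length (bp) of the covered region downstream
#'   of each TSS.
#' @param decoy_fraction Fraction of all motif instances that are decoys
#'   (motif planted, no expression).
#' @param fraction_minus Probability a TSS lies on the minus strand.
#' @param plant_motif Plant the motif at real TSSs? (`FALSE` removes the
#'   sequence signal, for ablation fixtures.)
#' @param coverage_signal Add transcript coverage at real TSSs? (`FALSE`
#'   removes the coverage signal.)
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(genome_length = 200000L, n_tss = 50L,
                         motif = "TATAAAAG", mismatch_prob = 0.1,
                         motif_offset = 30L, expr_meanlog = 2,
                         expr_sdlog = 0.6, background_depth = 0.5,
                         transcript_length = 1500L, decoy_fraction = 0.2,
                         fraction_minus = 0.5, plant_motif = TRUE,
                         coverage_signal = TRUE) {
  stopifnot(n_tss * 2000 < genome_length, mismatch_prob >= 0,
            mismatch_prob <= 1, background_depth >= 0,
            decoy_fraction >= 0, decoy_fraction < 1)
  structure(as.list(environment()), class = "synth_config")
}

mutate_motif <- function(motif_chars, mismatch_prob) {
  hit <- stats::runif(length(motif_chars)) < mismatch_prob
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    motif_chars[hit] <- vapply(motif_chars[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1))
  }
  motif_chars
}

# Plant a (mutated) motif upstream of `pos` on `strand`; chars is the
# genome as a character vector, modified in place by the caller.
plant_motif_at <- function(chars, pos, strand, motif, mismatch_prob,
                           offset) {
  mchars <- mutate_motif(strsplit(motif, "")[[1]], mismatch_prob)
  len <- length(mchars)
  if (strand == "+") {
    idx <- (pos - offset - len):(pos - offset - 1L) + 1L  # 1-based
  } else {
    idx <- (pos + offset + 1L):(pos + offset + len) + 1L
    mchars <- rev(chartr("ACGT", "TGCA", mchars))
  }
  chars[idx] <- mchars
  chars
}

#' Generate a synthetic genome, coverage and truth set
#'
#' Fully reproducible under a fixed seed: the same seed yields identical
#' sequence, coverage and annotations.
#'
#' @param cfg A `synth_config`.
#' @param seed Optional integer seed set at entry.
#' @return A list of class `synth_fixture` with `genome` (`tss_genome`),
#'   `coverage` (`coverage_track`), `truth` (`tss_peaks` of planted TSSs),
#'   `decoys` (`tss_peaks` with expression 0) and `config`.
#' @export
generate_fixture <- function(cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(cfg$genome_length)
  n <- as.integer(cfg$n_tss)
  margin <- 2000L
  spacing <- 2000L
  avail <- L - 2L * margin - (n - 1L) * spacing
  if (avail < n) {
    stop("infeasible spacing: ", n, " TSSs at >=", spacing, " bp apart do ",
         "not fit in ", L, " bp with ", margin, " bp margins")
  }
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, L, replace = TRUE)
  pos <- margin + sort(sample.int(avail, n)) + (seq_len(n) - 1L) * spacing
  strand <- ifelse(stats::runif(n) < cfg$fraction_minus, "-", "+")
  expression <- stats::rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
  if (cfg$plant_motif) {
    for (i in seq_len(n)) {
      chars <- plant_motif_at(chars, pos[i], strand[i], cfg$motif,
                              cfg$mismatch_prob, cfg$motif_offset)
    }
  }
  # decoys: motif without expression, well away from any true TSS
  n_decoy <- round(n * cfg$decoy_fraction / (1 - cfg$decoy_fraction))
  dpos <- integer(0)
  dstrand <- character(0)
  tries <- 0L
  while (length(dpos) < n_decoy && tries < 1000L * n_decoy) {
    tries <- tries + 1L
    cand <- sample.int(L - 2L * margin, 1L) + margin
    if (min(abs(cand - pos)) < 1500L) next
    if (length(dpos) > 0L && min(abs(cand - dpos)) < 1000L) next
    std <- sample(c("+", "-"), 1L)
    chars <- plant_motif_at(chars, cand, std, cfg$motif, cfg$mismatch_prob,
                            cfg$motif_offset)
    dpos <- c(dpos, cand)
    dstrand <- c(dstrand, std)
  }
  if (length(dpos) < n_decoy) {
    stop("could not place ", n_decoy, " decoys with the required spacing")
  }
  genome <- new_genome(c(chrS = paste(chars, collapse = "")))
  plus <- stats::rpois(L, cfg$background_depth)
  minus <- stats::rpois(L, cfg$background_depth)
  if (cfg$coverage_signal) {
    tl <- as.integer(cfg$transcript_length)
    for (i in seq_len(n)) {
      if (strand[i] == "+") {
        idx <- pos[i]:min(L - 1L, pos[i] + tl - 1L) + 1L
        plus[idx] <- plus[idx] + stats::rpois(length(idx), expression[i])
      } else {
        idx <- max(0L, pos[i] - tl + 1L):pos[i] + 1L
        minus[idx] <- minus[idx] + stats::rpois(length(idx), expression[i])
      }
    }
  }
  coverage <- structure(list(chrS = list(plus = as.numeric(plus),
                                         minus = as.numeric(minus))),
                        class = "coverage_track")
  truth <- structure(
    data.frame(contig = "chrS", pos = pos, strand = strand,
               expression = expression,
               gene_id = paste0("tss_", seq_len(n)), stringsAsFactors = FALSE),
    class = c("tss_peaks", "data.frame"))
  ord <- order(dpos)
  decoys <- structure(
    data.frame(contig = rep("chrS", length(dpos)), pos = dpos[ord],
               strand = dstrand[ord], expression = numeric(length(dpos)),
               gene_id = sprintf("decoy_%d", seq_along(dpos)),
               stringsAsFactors = FALSE),
    class = c("tss_peaks", "data.frame"))
  structure(list(genome = genome, coverage = coverage, truth = truth,
                 decoys = decoys, config = cfg),
            class = "synth_fixture")
}

#' @export
print.synth_fixture <- function(x, ...) {
  cat("<synth_fixture> ", format(x$config$genome_length, big.mark = ","),
      " bp, ", nrow(x$truth), " TSSs (", sum(x$truth$strand == "+"), "+/",
      sum(x$truth$strand == "-"), "-), ", nrow(x$decoys), " decoys\n",
      sep = "")
  invisible(x)
}

rle_bedgraph <- function(track, contig, path) {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(contig, starts[keep], ends[keep], r$values[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write a synthetic fixture to disk
#'
#' Emits `genome.fa`, `cov_plus.bedGraph`, `cov_minus.bedGraph`,
#' `tss_truth.bed` and `decoys.bed` in the formats the package's readers
#' consume (BED6+ with expression in column 7; zero-depth runs omitted
#' from the bedGraphs).
#'
#' @param fixture A `synth_fixture`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir)
  }
  fa <- file.path(dir, "genome.fa")
  con <- file(fa, "w")
  for (ctg in names(fixture$genome$contigs)) {
    writeLines(paste0(">", ctg), con)
    s <- fixture$genome$contigs[[ctg]]
    writeLines(substring(s, seq(1, nchar(s), 70), pmin(seq(70, nchar(s) + 69, 70), nchar(s))), con)
  }
  close(con)
  ctg <- names(fixture$coverage)[1]
  rle_bedgraph(fixture$coverage[[ctg]]$plus, ctg,
               file.path(dir, "cov_plus.bedGraph"))
  rle_bedgraph(fixture$coverage[[ctg]]$minus, ctg,
               file.path(dir, "cov_minus.bedGraph"))
  write_peaks_bed <- function(peaks, path) {
    df <- data.frame(peaks$contig, peaks$pos, peaks$pos + 1L, peaks$gene_id,
                     0L, peaks$strand, peaks$expression)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_peaks_bed(fixture$truth, file.path(dir, "tss_truth.bed"))
  write_peaks_bed(fixture$decoys, file.path(dir, "decoys.bed"))
  invisible(dir)
}
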