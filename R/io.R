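# Readers/writers for genome sequence, TSS peak annotations, per-base
# coverage tracks and prediction output, plus one-hot sequence encoding.
# Coordinates are 0-based half-open internally, matching BED/bedGraph.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and any character outside `{A,C,G,T}` is mapped
#' to `N`, so downstream one-hot encoding only ever sees the five-letter
#' alphabet.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `tss_genome`: a list with `contigs` (named
#'   character vector of sequences) and `lengths` (named integer vector).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) {
    warning("empty FASTA: ", path)
    return(new_genome(character(0)))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))  # first token of header
  seqs <- gsub("[^ACGT]", "N", seqs)
  new_genome(seqs)
}

new_genome <- function(seqs) {
  structure(
    list(contigs = seqs, lengths = vapply(seqs, nchar, integer(1))),
    class = "tss_genome"
  )
}

#' @export
print.tss_genome <- function(x, ...) {
  cat("<tss_genome> ", length(x$contigs), " contig(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Read TSS peaks from a BED-like file
#'
#' Expects tab-separated BED6+ with strand in column 6 and a per-peak
#' expression value (e.g. CAGE TPM) in `expression_column`. For multi-bp
#' peak intervals the TSS base is the summit column when one is given,
#' otherwise the strand-aware 5' end (start for `+`, `end - 1` for `-`),
#' the conventional CAGE proxy.
#'
#' @param path BED-like file, 0-based half-open coordinates.
#' @param expression_column 1-based column index of the expression value.
#' @param summit_column Optional 1-based column index holding an absolute
#'   summit coordinate; used as the TSS base when given.
#' @return A `data.frame` of class `tss_peaks` with columns `contig`, `pos`
#'   (0-based TSS base), `strand`, `expression`, `gene_id`.
#' @export
read_peaks <- function(path, expression_column = 7L, summit_column = NULL) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- max(6L, expression_column, if (is.null(summit_column)) 0L else summit_column)
  ok_len <- lengths(fields) >= ncol_min
  if (any(!ok_len)) stop("peak line with fewer than ", ncol_min, " columns at line ",
                         which(!ok_len)[1L])
  get <- function(i) vapply(fields, `[[`, character(1), i)
  strand <- get(6L)
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sum(bad), " peak line(s) with strand outside {+,-} rejected")
    fields <- fields[!bad]
    strand <- strand[!bad]
    if (length(fields) == 0L) return(empty_peaks())
  }
  contig <- get(1L)
  start <- as.integer(get(2L))
  end <- as.integer(get(3L))
  expr <- suppressWarnings(as.numeric(get(expression_column)))
  if (anyNA(expr)) stop("non-numeric expression value at line ", which(is.na(expr))[1L])
  if (any(expr < 0)) stop("negative expression value at line ", which(expr < 0)[1L])
  if (!is.null(summit_column)) {
    pos <- as.integer(get(summit_column))
  } else {
    pos <- ifelse(strand == "+", start, end - 1L)
  }
  structure(
    data.frame(contig = contig, pos = as.integer(pos), strand = strand,
               expression = expr, gene_id = get(4L), stringsAsFactors = FALSE),
    class = c("tss_peaks", "data.frame")
  )
}

empty_peaks <- function() {
  structure(
    data.frame(contig = character(0), pos = integer(0), strand = character(0),
               expression = numeric(0), gene_id = character(0),
               stringsAsFactors = FALSE),
    class = c("tss_peaks", "data.frame")
  )
}

#' Read strand-specific per-base coverage from bedGraph tracks
#'
#' Expands bedGraph intervals into dense per-base arrays, one pair of arrays
#' (plus/minus) per contig. Overlapping intervals are summed, matching the
#' additive depth semantics of per-read counting. Intervals extending past a
#' contig end are clipped with a warning; intervals on unknown contigs are
#' dropped with a warning.
#'
#' @param plus_path bedGraph for the plus strand (`NULL` for all-zero).
#' @param minus_path bedGraph for the minus strand (`NULL` for all-zero).
#' @param genome A `tss_genome` supplying contig names and lengths.
#' @return An object of class `coverage_track`: a named list (per contig) of
#'   `list(plus = , minus = )` numeric vectors of per-base depth.
#' @export
read_coverage <- function(plus_path, minus_path, genome) {
  stopifnot(inherits(genome, "tss_genome"))
  tracks <- lapply(genome$lengths, function(L) {
    list(plus = numeric(L), minus = numeric(L))
  })
  names(tracks) <- names(genome$lengths)
  fill <- function(path, strand) {
    if (is.null(path)) {
      warning("no bedGraph for ", strand, " strand; depth set to 0")
      return()
    }
    if (!file.exists(path)) stop("bedGraph not found: ", path)
    bg <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("contig", "start", "end", "value"),
                            colClasses = c("character", "integer", "integer", "numeric"))
    if (nrow(bg) == 0L) return()
    if (any(bg$value < 0)) stop("negative coverage value in ", path)
    unknown <- !(bg$contig %in% names(tracks))
    if (any(unknown)) {
      warning(sum(unknown), " bedGraph interval(s) on unknown contig dropped")
      bg <- bg[!unknown, , drop = FALSE]
    }
    for (ctg in unique(bg$contig)) {
      sub <- bg[bg$contig == ctg, , drop = FALSE]
      L <- length(tracks[[ctg]][[strand]])
      over <- sub$end > L
      if (any(over)) {
        warning(sum(over), " interval(s) beyond end of ", ctg, " clipped")
        sub$end[over] <- L
      }
      sub <- sub[sub$start < sub$end, , drop = FALSE]
      arr <- tracks[[ctg]][[strand]]
      for (i in seq_len(nrow(sub))) {
        idx <- (sub$start[i] + 1L):sub$end[i]
        arr[idx] <- arr[idx] + sub$value[i]
      }
      tracks[[ctg]][[strand]] <<- arr
    }
  }
  fill(plus_path, "plus")
  fill(minus_path, "minus")
  structure(tracks, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x, function(t) sum(t$plus) + sum(t$minus), numeric(1)))
  cat("<coverage_track> ", length(x), " contig(s), total depth ",
      format(tot, big.mark = ","), "\n", sep = "")
  invisible(x)
}

ONE_HOT_CHANNELS <- c("A", "T", "C", "G")

#' One-hot encode a DNA sequence
#'
#' Channel order is (A, T, C, G): A -> (1,0,0,0), T -> (0,1,0,0),
#' C -> (0,0,1,0), G -> (0,0,0,1). `N` encodes as an all-zero row rather
#' than a uniform prior, so row sums stay in `{0,1}`.
#'
#' @param seq A string over `{A,C,G,T,N}`.
#' @return An `L x 4` numeric matrix with columns named A, T, C, G.
#' @export
one_hot <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, ONE_HOT_CHANNELS))
  if (length(chars) == 0L) return(m)
  idx <- match(chars, ONE_HOT_CHANNELS)
  bad <- is.na(idx) & chars != "N"
  if (any(bad)) stop("one_hot: invalid character '", chars[bad][1L], "'")
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Reverse-complement a paired sequence/coverage window
#'
#' Rows are reversed and the A/T and C/G channels swapped; the coverage
#' vector is reversed. Applying the operation twice returns the input.
#'
#' @param seq_mat An `L x 4` one-hot matrix in (A, T, C, G) channel order.
#' @param cov A length-`L` coverage vector.
#' @return `list(seq = , cov = )` with both components flipped.
#' @export
reverse_complement_window <- function(seq_mat, cov) {
  if (nrow(seq_mat) != length(cov)) {
    stop("sequence/coverage length mismatch: ", nrow(seq_mat), " vs ", length(cov))
  }
  rev_rows <- rev(seq_len(nrow(seq_mat)))
  out <- seq_mat[rev_rows, c(2L, 1L, 4L, 3L), drop = FALSE]  # A<->T, C<->G
  colnames(out) <- ONE_HOT_CHANNELS
  list(seq = out, cov = rev(cov))
}

revcomp_string <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Write TSS cluster calls to BED6+
#'
#' Output columns: contig, start, end (0-based half-open), name, cluster
#' score, strand, representative (maximal-score) position. Input is sorted
#' by (contig, start) if it is not already.
#'
#' @param clusters A `tss_clusters` data frame (see [cluster_scores()]).
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_predictions <- function(clusters, path) {
  df <- as.data.frame(clusters)
  if (nrow(df) > 0L) {
    o <- order(df$contig, df$start)
    if (!identical(o, seq_len(nrow(df)))) {
      message("write_predictions: clusters were unsorted; sorting by (contig, start)")
      df <- df[o, , drop = FALSE]
    }
    out <- data.frame(df$contig, df$start, df$end,
                      paste0("TSS_", seq_len(nrow(df))),
                      df$score, df$strand, df$representative)
  } else {
    out <- data.frame()
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read cluster calls written by [write_predictions()]
#'
#' @param path BED6+ file produced by [write_predictions()].
#' @return A `tss_clusters` data frame (without member counts).
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  if (file.size(path) == 0L || length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(contig = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      representative = integer(0), score = numeric(0)))
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "numeric", "character",
                                          "integer"))
  data.frame(contig = bed[[1]], strand = bed[[6]], start = bed[[2]],
             end = bed[[3]], representative = bed[[7]], score = bed[[5]],
             stringsAsFactors = FALSE)
}
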