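all_kmers <- function(k) {
  mkAllStrings <- Biostrings::mkAllStrings
  mkAllStrings(BASES, k)
}

is_homopolymer <- function(kmers) {
  k <- nchar(kmers)
  kmers == strrep(substr(kmers, 1, 1), k)
}

#' Count k-mers in a set of sequences
#'
#' Dense count table over all 4^k k-mers. In circular mode the first k-1
#' bases of each sequence are appended before scanning so that k-mers
#' bridging the end/start junction are counted too (bacterial chromosomes).
#' Linear sequences shorter than k contribute no k-mers. K-mers containing
#' N are skipped and tallied separately. With `both_strands`, the reverse
#' complement of every sequence is scanned as well, making counts
#' strand-symmetric.
#'
#' @param seqs character vector of sequences, a `read_set` data frame, or a
#'   single [reference_genome()] (whose `circular` flag is then used)
#' @param k k-mer size (default 6, matching the ~6 nt nanopore sensing
#'   window); dense tables are limited to k <= 12
#' @param circular treat each sequence as circular
#' @param both_strands also count the reverse-complement strand
#' @return an object of class `kmer_table`: list with `k`, `counts` (named
#'   integer vector over all 4^k k-mers), `total`, `n_skipped_N`, `source`
#' @export
count_kmers <- function(seqs, k = 6L, circular = FALSE, both_strands = TRUE) {
  k <- as.integer(k)
  if (k < 1L) stop_usage("k must be >= 1")
  if (k > 12L) stop_usage("dense k-mer tables are limited to k <= 12")
  source <- "sequences"
  if (inherits(seqs, "ref_genome")) {
    circular <- seqs$circular
    source <- if (circular) "reference_circular" else "reference_linear"
    seqs <- seqs$sequence
  } else if (is.data.frame(seqs)) {
    seqs <- seqs$sequence
    source <- "reads_linear"
  }
  seqs <- toupper(seqs)
  if (circular && any(nchar(seqs) > 0L))
    seqs <- paste0(seqs, substr(seqs, 1L, k - 1L))
  x <- Biostrings::DNAStringSet(seqs)
  cnt <- Biostrings::oligonucleotideFrequency(x, width = k,
                                              simplify.as = "collapsed")
  if (both_strands)
    cnt <- cnt + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(x), width = k,
      simplify.as = "collapsed")
  cnt <- setNames(as.integer(cnt), names(cnt))
  windows <- sum(pmax(0L, nchar(seqs) - k + 1L)) * (1L + both_strands)
  structure(list(k = k, counts = cnt, total = sum(cnt),
                 n_skipped_N = windows - sum(cnt), source = source),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("<kmer_table> k=%d, %s k-mers counted (%d containing N skipped), source: %s\n",
              x$k, format(x$total, big.mark = ","), x$n_skipped_N, x$source))
  invisible(x)
}

#' K-mer representation difference between reads and reference
#'
#' Per k-mer, the relative rate difference
#' `diff = (f_reads - f_ref) / f_ref` between read-set and reference
#' frequencies (`f = count / total`). `sigma` is the sample standard
#' deviation of `diff` over all k-mers present in the reference; k-mers
#' with `|diff| > 3 * sigma` are flagged as outliers (the 3-sigma band of
#' representation scatter plots). K-mers absent from the reference get
#' `diff = NA` and are never outliers.
#'
#' @param ref_table [count_kmers()] table of the reference
#' @param reads_table [count_kmers()] table of the read set (same k)
#' @return a `data.frame` of class `kmer_representation` with one row per
#'   k-mer: `kmer`, `count_ref`, `count_reads`, `f_ref`, `f_reads`, `diff`,
#'   `is_homopolymer`, `is_outlier`; attribute `sigma`
#' @export
representation_diff <- function(ref_table, reads_table) {
  if (ref_table$k != reads_table$k)
    stop_usage("k mismatch: reference k=%d vs reads k=%d",
               ref_table$k, reads_table$k)
  km <- names(ref_table$counts)
  f_ref <- ref_table$counts / ref_table$total
  f_reads <- reads_table$counts[km] / reads_table$total
  diff <- ifelse(f_ref > 0, (f_reads - f_ref) / f_ref, NA_real_)
  sigma <- sd(diff[f_ref > 0])
  out <- data.frame(
    kmer = km,
    count_ref = as.integer(ref_table$counts),
    count_reads = as.integer(reads_table$counts[km]),
    f_ref = as.numeric(f_ref), f_reads = as.numeric(f_reads),
    diff = as.numeric(diff),
    is_homopolymer = is_homopolymer(km),
    is_outlier = !is.na(diff) & abs(diff) > 3 * sigma,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sigma") <- sigma
  class(out) <- c("kmer_representation", "data.frame")
  out
}

#' Rank over- or under-represented k-mers
#'
#' Sorts representation rows by `diff` (descending for `over`, ascending
#' for `under`), breaking ties lexicographically; optionally removes
#' homopolymers before truncating to the top `n`.
#'
#' @param rows a [representation_diff()] table
#' @param n how many k-mers to return
#' @param direction `"over"` or `"under"`
#' @param exclude_homopolymers drop homopolymer k-mers first
#' @return the selected rows, in rank order
#' @export
rank_represented <- function(rows, n = 10L, direction = c("over", "under"),
                             exclude_homopolymers = FALSE) {
  direction <- match.arg(direction)
  rows <- rows[!is.na(rows$diff), , drop = FALSE]
  if (exclude_homopolymers)
    rows <- rows[!rows$is_homopolymer, , drop = FALSE]
  ord <- if (direction == "over") order(-rows$diff, rows$kmer)
         else order(rows$diff, rows$kmer)
  rows <- rows[ord, , drop = FALSE]
  if (n > nrow(rows)) {
    warning(sprintf("requested %d k-mers but only %d available", n, nrow(rows)),
            call. = FALSE)
    n <- nrow(rows)
  }
  out <- rows[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Position frequency matrix ("frequency plot" logo) of a k-mer list
#'
#' @param kmers non-empty character vector of equal-length k-mers
#' @return a 4 x k column-stochastic matrix of class `logo_matrix`
#'   (rows A, C, G, T; entry = fraction of k-mers with that base at that
#'   position)
#' @export
logo_matrix <- function(kmers) {
  if (length(kmers) == 0L) stop_usage("empty k-mer list")
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop_usage("k-mers have mixed lengths")
  mat <- matrix(0, 4L, k, dimnames = list(BASES, seq_len(k)))
  chars <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  for (j in seq_len(k)) {
    tab <- table(factor(chars[, j], levels = BASES))
    mat[, j] <- as.numeric(tab) / length(kmers)
  }
  class(mat) <- c("logo_matrix", class(mat))
  mat
}

#' Change in k-mer representation between two read sets
#'
#' Pairs two representation tables (e.g. raw vs corrected reads relative
#' to the same reference) and reports `delta = diff_corrected - diff_raw`
#' per k-mer. Use `top_n` to keep the k-mers with the largest |delta|
#' (ties broken lexicographically).
#'
#' @param raw_rows,corrected_rows [representation_diff()] tables over the
#'   same k-mer universe
#' @param top_n optional: keep only the `top_n` k-mers by `|delta|`
#' @return a `data.frame` with columns `kmer`, `diff_raw`,
#'   `diff_corrected`, `delta`
#' @export
frequency_change <- function(raw_rows, corrected_rows, top_n = NULL) {
  if (!identical(raw_rows$kmer, corrected_rows$kmer))
    stop_usage("representation tables cover different k-mer universes")
  out <- data.frame(kmer = raw_rows$kmer, diff_raw = raw_rows$diff,
                    diff_corrected = corrected_rows$diff,
                    delta = corrected_rows$diff - raw_rows$diff,
                    stringsAsFactors = FALSE)
  if (!is.null(top_n)) {
    out <- out[!is.na(out$delta), , drop = FALSE]
    out <- out[order(-abs(out$delta), out$kmer), , drop = FALSE]
    out <- head(out, top_n)
    rownames(out) <- NULL
  }
  out
}

#' Write a k-mer representation table as TSV
#'
#' @param rows a [representation_diff()] table
#' @param path output path
#' @export
write_kmer_tsv <- function(rows, path) {
  write.table(as.data.frame(rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
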