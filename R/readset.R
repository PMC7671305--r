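#' Read-set census statistics
#'
#' @param reads a `read_set` data frame
#' @param genome_length reference length (bp) for fold-coverage
#' @param bin_width histogram bin width (bp)
#' @return an object of class `readset_stats`: `n_reads`, `total_bases`,
#'   `mean_length` (nearest bp), `max_length`, `coverage`, `histogram`
#'   (data frame `bin_start`, `bin_end`, `count`)
#' @export
readset_stats <- function(reads, genome_length, bin_width = 1000L) {
  if (genome_length <= 0) stop_usage("genome_length must be > 0")
  lens <- nchar(reads$sequence)
  if (length(lens) == 0L) {
    warning("empty read set", call. = FALSE)
    return(structure(list(n_reads = 0L, total_bases = 0, mean_length = 0L,
                          max_length = 0L, coverage = 0,
                          histogram = data.frame(bin_start = integer(),
                                                 bin_end = integer(),
                                                 count = integer())),
                     class = "readset_stats"))
  }
  bins <- floor((lens - 1) / bin_width)
  tab <- table(bins)
  hb <- as.integer(names(tab))
  structure(list(
    n_reads = length(lens), total_bases = sum(as.numeric(lens)),
    mean_length = as.integer(round(mean(lens))), max_length = max(lens),
    coverage = sum(as.numeric(lens)) / genome_length,
    histogram = data.frame(bin_start = hb * bin_width + 1L,
                           bin_end = (hb + 1L) * bin_width,
                           count = as.integer(tab))),
    class = "readset_stats")
}

#' @export
print.readset_stats <- function(x, ...) {
  cat(sprintf("<readset_stats> %d reads, %s bp (%.1fx), mean %d bp, max %d bp\n",
              x$n_reads, format(x$total_bases, big.mark = ","), x$coverage,
              x$mean_length, x$max_length))
  invisible(x)
}

#' Keep reads strictly longer than a minimum length
#'
#' The cutoff is strict ("larger than"): a read of exactly `min_len` bp is
#' removed. Input order is preserved; the removed count is reported via
#' `message()`.
#'
#' @param reads a `read_set` data frame
#' @param min_len length cutoff (bp), default 200
#' @return the filtered `read_set`
#' @export
filter_min_length <- function(reads, min_len = 200L) {
  keep <- nchar(reads$sequence) > min_len
  if (!any(keep) && nrow(reads) > 0L)
    warning("all reads are at or below the length cutoff", call. = FALSE)
  message(sprintf("filter_min_length: removed %d of %d reads (<= %d bp)",
                  sum(!keep), length(keep), min_len))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Seeded downsampling of a read set to a target coverage
#'
#' Reads are permuted with a seeded RNG and taken in permuted order until
#' the cumulative base count reaches `target_cov * genome_length`; the
#' read that crosses the threshold is included. Deterministic for a fixed
#' (input, seed) pair. If the set holds less than the target coverage, all
#' reads are returned with a warning.
#'
#' @param reads a `read_set` data frame
#' @param genome_length reference length (bp)
#' @param target_cov target fold-coverage (> 0)
#' @param seed RNG seed (23 echoes the conventional seqtk seed)
#' @return the selected reads, in permuted order
#' @export
downsample_to_coverage <- function(reads, genome_length, target_cov,
                                   seed = 23L) {
  if (target_cov <= 0) stop_usage("target_cov must be > 0")
  lens <- nchar(reads$sequence)
  needed <- target_cov * genome_length
  if (sum(as.numeric(lens)) < needed) {
    warning(sprintf("read set holds %.2fx < target %.2fx: returning all reads",
                    sum(as.numeric(lens)) / genome_length, target_cov),
            call. = FALSE)
    return(reads)
  }
  perm <- local_seed(seed, sample.int(nrow(reads)))
  csum <- cumsum(as.numeric(lens[perm]))
  n_take <- which(csum >= needed)[1]
  out <- reads[perm[seq_len(n_take)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove reads by name (exclude list)
#'
#' Generic hook for removing reads known to be affected by structural
#' differences between sample and reference (e.g. a deletion region)
#' before downsampling.
#'
#' @param reads a `read_set` data frame
#' @param names character vector of read names to drop
#' @return the filtered `read_set`
#' @export
exclude_reads <- function(reads, names) {
  keep <- !(reads$name %in% names)
  message(sprintf("exclude_reads: removed %d of %d reads", sum(!keep),
                  length(keep)))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
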