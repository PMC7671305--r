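OP_LEVELS <- c("match", "sub", "ins", "del", "ambiguous")

#' Classify the columns of an edit script into error counts
#'
#' Each alignment column is counted exactly once: match, substitution,
#' inserted read base, deleted reference base, or ambiguous (N-touching).
#' Insertions are counted as inserted BASES, not insertion events.
#'
#' @param script an `edit_script`
#' @return an object of class `error_counts` (fields `n_match`, `n_sub`,
#'   `n_ins`, `n_del`, `n_ambiguous`, `n_columns`)
#' @export
count_errors <- function(script) {
  tab <- tabulate(match(script$columns$op, OP_LEVELS), nbins = 5L)
  structure(list(n_match = tab[1], n_sub = tab[2], n_ins = tab[3],
                 n_del = tab[4], n_ambiguous = tab[5],
                 n_columns = sum(tab)),
            class = "error_counts")
}

#' @export
print.error_counts <- function(x, ...) {
  cat(sprintf("<error_counts> match %d, sub %d, ins %d, del %d, ambiguous %d (%d columns)\n",
              x$n_match, x$n_sub, x$n_ins, x$n_del, x$n_ambiguous, x$n_columns))
  invisible(x)
}

#' Longest perfect match of an alignment
#'
#' Length (bp) of the longest contiguous run of match columns; runs are
#' broken by substitutions, insertions, deletions and ambiguous columns.
#'
#' @param script an `edit_script`
#' @return integer run length (0 for an all-error script)
#' @export
longest_perfect_run <- function(script) {
  r <- rle(script$columns$op == "match")
  hit <- r$lengths[r$values]
  if (length(hit)) max(hit) else 0L
}

#' Aggregate edit scripts into a read-set error profile
#'
#' Rates are POOLED over the read set: each percentage is
#' `100 * sum(type) / sum(columns)`, so substitution, insertion and
#' deletion shares add up to the total error rate by construction.
#' `longest_perfect_match` and `longest_alignment` (reference span) are
#' maxima over alignments; `max_stretch_pct` is how much the longest
#' alignment's reference span exceeds its aligned read span.
#'
#' @param scripts list of `edit_script` objects (primary alignments)
#' @param n_reads_total total reads in the set (aligned or not)
#' @param n_reads_aligned number of distinct aligned reads; defaults to the
#'   number of distinct read names among `scripts`
#' @param dataset label carried into reports
#' @return an object of class `error_profile`
#' @export
aggregate_profile <- function(scripts, n_reads_total,
                              n_reads_aligned = NULL, dataset = "dataset") {
  if (length(scripts) == 0L) {
    warning("no aligned reads: returning an empty profile", call. = FALSE)
    return(structure(list(
      dataset = dataset, n_reads_total = n_reads_total, n_reads_aligned = 0L,
      aligned_pct = 0, sub_pct = NA_real_, ins_pct = NA_real_,
      del_pct = NA_real_, total_pct = NA_real_,
      longest_perfect_match = NA_integer_, longest_alignment = NA_integer_,
      max_stretch_pct = NA_real_,
      counts = list(n_match = 0L, n_sub = 0L, n_ins = 0L, n_del = 0L,
                    n_ambiguous = 0L, n_columns = 0L)),
      class = "error_profile"))
  }
  per <- lapply(scripts, count_errors)
  tot <- function(f) sum(vapply(per, `[[`, 0, f))
  n_cols <- tot("n_columns")
  if (is.null(n_reads_aligned)) {
    nms <- vapply(scripts, `[[`, "", "read_name")
    n_reads_aligned <- length(unique(nms))
  }
  ref_spans <- vapply(scripts, `[[`, 0L, "ref_span")
  imax <- which.max(ref_spans)
  longest <- scripts[[imax]]
  structure(list(
    dataset = dataset,
    n_reads_total = n_reads_total,
    n_reads_aligned = n_reads_aligned,
    aligned_pct = 100 * n_reads_aligned / n_reads_total,
    sub_pct = 100 * tot("n_sub") / n_cols,
    ins_pct = 100 * tot("n_ins") / n_cols,
    del_pct = 100 * tot("n_del") / n_cols,
    total_pct = 100 * (tot("n_sub") + tot("n_ins") + tot("n_del")) / n_cols,
    longest_perfect_match = max(vapply(scripts, longest_perfect_run, 0L)),
    longest_alignment = max(ref_spans),
    max_stretch_pct =
      100 * (longest$ref_span - longest$read_span) / longest$read_span,
    counts = list(n_match = tot("n_match"), n_sub = tot("n_sub"),
                  n_ins = tot("n_ins"), n_del = tot("n_del"),
                  n_ambiguous = tot("n_ambiguous"), n_columns = n_cols)),
    class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("<error_profile> %s\n", x$dataset))
  cat(sprintf("  reads: %d total, %d aligned (%s%%)\n", x$n_reads_total,
              x$n_reads_aligned, fmt_num(x$aligned_pct)))
  cat(sprintf("  sub %s%%  ins %s%%  del %s%%  total %s%%\n",
              fmt_num(x$sub_pct), fmt_num(x$ins_pct), fmt_num(x$del_pct),
              fmt_num(x$total_pct)))
  cat(sprintf("  longest perfect match %s bp, longest alignment %s bp (stretch %s%%)\n",
              x$longest_perfect_match, x$longest_alignment,
              fmt_num(x$max_stretch_pct)))
  invisible(x)
}

profile_row <- function(p) {
  data.frame(dataset = p$dataset, n_reads = p$n_reads_total,
             aligned_pct = round(p$aligned_pct, 2),
             sub_pct = round(p$sub_pct, 2), ins_pct = round(p$ins_pct, 2),
             del_pct = round(p$del_pct, 2), total_pct = round(p$total_pct, 2),
             longest_perfect_match_bp = p$longest_perfect_match,
             longest_alignment_bp = p$longest_alignment,
             max_stretch_pct = round(p$max_stretch_pct, 2),
             stringsAsFactors = FALSE)
}

#' Serialize error profiles as TSV
#'
#' One row per read set; percentages rounded to 2 decimals (raw counts are
#' preserved in the JSON bundle, not here).
#'
#' @param profiles an `error_profile` or list of them
#' @param path output path
#' @export
write_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "error_profile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, profile_row))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Substitution matrix of a read set
#'
#' Accumulates a 4x4 (reference base x read base) count matrix over all
#' match and substitution columns. Reverse-strand alignments contribute in
#' reference-forward orientation, exactly as the stored SAM sequence reads.
#' `rates` are row-conditional: `rate(X->Y) = count(X->Y) / columns with
#' reference base X` (diagonal = match rate). The pooled transition rate
#' covers A<->G and C<->T; the transversion rate the remaining off-diagonal
#' mass; both are fractions of all match+sub columns.
#'
#' @param scripts list of `edit_script` objects
#' @return an object of class `subst_matrix` with `counts`, `rates`,
#'   `transition_rate`, `transversion_rate`, `transition_share`
#' @export
substitution_matrix <- function(scripts) {
  counts <- matrix(0L, 4, 4, dimnames = list(ref = BASES, read = BASES))
  for (s in scripts) {
    cl <- s$columns
    sel <- cl$op %in% c("match", "sub")
    if (!any(sel)) next
    ri <- match(cl$ref_base[sel], BASES)
    qi <- match(cl$read_base[sel], BASES)
    ok <- !is.na(ri) & !is.na(qi)
    counts <- counts + table(factor(ri[ok], levels = 1:4),
                             factor(qi[ok], levels = 1:4))
  }
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(ref = BASES, read = BASES))
  rs <- rowSums(counts)
  rates <- counts / ifelse(rs > 0, rs, 1)
  total <- sum(counts)
  trans <- counts["A", "G"] + counts["G", "A"] +
           counts["C", "T"] + counts["T", "C"]
  offdiag <- total - sum(diag(counts))
  structure(list(
    counts = counts, rates = rates,
    transition_rate = if (total > 0) trans / total else 0,
    transversion_rate = if (total > 0) (offdiag - trans) / total else 0,
    transition_share = if (offdiag > 0) trans / offdiag else NA_real_),
    class = "subst_matrix")
}

#' @export
print.subst_matrix <- function(x, ...) {
  cat("<subst_matrix> counts (ref rows, read columns):\n")
  print(x$counts)
  cat(sprintf("  transition rate %s, transversion rate %s (transition share of subs: %s)\n",
              fmt_num(100 * x$transition_rate, 3),
              fmt_num(100 * x$transversion_rate, 3),
              fmt_num(x$transition_share, 3)))
  invisible(x)
}

#' Write a substitution matrix as 4x4 TSV (header row and column A,C,G,T)
#'
#' @param m a `subst_matrix`
#' @param path output path
#' @param what `"counts"` or `"rates"`
#' @export
write_subst_matrix <- function(m, path, what = c("counts", "rates")) {
  what <- match.arg(what)
  tab <- as.data.frame(m[[what]])
  colnames(tab) <- BASES
  tab <- cbind(ref = BASES, tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
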