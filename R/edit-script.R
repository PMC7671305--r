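#' Expand an alignment into a per-column edit script
#'
#' Reconstructs the full per-column alignment (match / substitution /
#' insertion / deletion) of one SAM record from its CIGAR plus either the
#' MD tag or the reference sequence. M segments are split into match/sub
#' columns via MD (or by base comparison against the reference); `=`/`X`
#' operators are accepted as pre-split columns. Soft clips contribute no
#' columns but offset read positions; hard clips additionally offset read
#' positions through `read_length`. For reverse-strand alignments,
#' `read_pos` is reported in the ORIGINAL read orientation
#' (`read_length - stored_pos + 1`), which is what 5'-end analyses need.
#' Columns touching an N base (reference or read) are classified
#' `ambiguous` and are excluded from match/error tallies downstream.
#'
#' When both MD and a reference are supplied they must agree; a
#' disagreement raises a validation error. Circular references are indexed
#' modulo the genome length so wrap-around alignments expand correctly.
#'
#' @param aln one alignment record: a single-row `alignment_set` data frame
#'   or an equivalent named list (fields `cigar`, `seq`, `ref_start`,
#'   `strand`, `read_length`, optionally `md`, `read_name`, `ref_name`)
#' @param ref optional [reference_genome()] (required when MD is absent)
#' @return an object of class `edit_script`: a list with `columns`
#'   (data frame `op`, `read_pos`, `ref_pos`, `ref_base`, `read_base`),
#'   `read_span`, `ref_span`, `read_name`, `ref_name`, `strand`,
#'   `read_length`
#' @export
expand_edit_script <- function(aln, ref = NULL) {
  if (is.data.frame(aln)) {
    if (nrow(aln) != 1L) stop_usage("expand_edit_script() expects one record")
    aln <- as.list(aln)
  }
  cg <- parse_cigar(aln$cigar)
  op <- cg$op; len <- cg$len
  if (any(op %in% c("N", "P")))
    stop_format("unsupported CIGAR operator in '%s'", aln$cigar)
  n_ops <- length(op)
  left_hard  <- if (op[1] == "H") len[1] else 0L
  right_hard <- if (n_ops > 1L && op[n_ops] == "H") len[n_ops] else 0L
  core <- which(!op %in% c("H", "S"))
  if (!length(core)) stop_format("CIGAR '%s' has no aligned columns", aln$cigar)
  pre <- seq_len(core[1] - 1L)
  left_soft <- sum(len[pre][op[pre] == "S"])

  keep <- op %in% c("M", "=", "X", "I", "D")
  ops_col <- rep(op[keep], len[keep])
  nc <- length(ops_col)
  consumes_q <- ops_col %in% c("M", "=", "X", "I")
  consumes_r <- ops_col %in% c("M", "=", "X", "D")
  read_span <- sum(consumes_q)
  ref_span  <- sum(consumes_r)
  qcum <- cumsum(consumes_q)
  rcum <- cumsum(consumes_r)

  if (is.null(aln$seq) || is.na(aln$seq))
    stop_format("record '%s' has no stored sequence", aln$read_name %||% "?")
  seq_chars <- explode(aln$seq)
  read_base <- rep(NA_character_, nc)
  read_base[consumes_q] <- seq_chars[left_soft + qcum[consumes_q]]

  read_length <- aln$read_length %||% NA_integer_
  if (is.na(read_length))
    read_length <- cigar_query_length(op, len, with_hard = TRUE)

  md <- aln$md %||% NA_character_
  have_md <- !is.na(md) && nzchar(md)
  if (!have_md && is.null(ref))
    stop_format(paste0("record '%s': no MD tag and no reference supplied; ",
                       "provide a reference to expand this alignment"),
                aln$read_name %||% "?")

  ridx <- which(consumes_r)
  ref_base <- rep(NA_character_, nc)
  md_type <- NULL
  if (have_md) {
    toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
    if (sum(nchar(toks)) != nchar(md))
      stop_format("malformed MD tag '%s'", md)
    is_num <- grepl("^[0-9]", toks)
    is_del <- startsWith(toks, "^")
    tok_len <- ifelse(is_num, suppressWarnings(as.integer(toks)),
                      ifelse(is_del, nchar(toks) - 1L, 1L))
    tok_type <- ifelse(is_num, "m", ifelse(is_del, "d", "x"))
    md_type <- rep(tok_type, tok_len)
    basel <- vector("list", length(toks))
    basel[is_num] <- lapply(tok_len[is_num], function(l) rep(NA_character_, l))
    basel[!is_num & !is_del] <- as.list(toks[!is_num & !is_del])
    basel[is_del] <- strsplit(substring(toks[is_del], 2L), "", fixed = TRUE)
    md_base <- unlist(basel, use.names = FALSE)
    if (length(md_type) != ref_span)
      stop_format("record '%s': MD covers %d reference bases, CIGAR implies %d",
                  aln$read_name %||% "?", length(md_type), ref_span)
    if (!identical(unname(md_type == "d"), unname(ops_col[ridx] == "D")))
      stop_format("record '%s': MD deletion segments disagree with CIGAR",
                  aln$read_name %||% "?")
    ref_base[ridx] <- ifelse(md_type == "m", read_base[ridx], md_base)
  }

  ref_pos <- rep(NA_integer_, nc)
  if (!is.null(ref)) {
    L <- genome_length(ref)
    end0 <- aln$ref_start + ref_span            # 0-based exclusive end
    if (end0 > L && !ref$circular)
      stop_format("alignment runs past the end of linear reference '%s'",
                  ref$name)
    span_str <- if (end0 <= L) {
      substr(ref$sequence, aln$ref_start + 1L, end0)
    } else {
      paste0(substr(ref$sequence, aln$ref_start + 1L, L),
             substr(ref$sequence, 1L, end0 - L))
    }
    ref_chars <- explode(span_str)
    if (have_md) {
      bad <- which(ref_base[ridx] != ref_chars)
      if (length(bad))
        stop_validation(
          "record '%s': MD disagrees with the reference at %d column(s) (first at reference position %d)",
          aln$read_name %||% "?", length(bad),
          ((aln$ref_start + bad[1] - 1L) %% L) + 1L)
    } else {
      ref_base[ridx] <- ref_chars
    }
    ref_pos[ridx] <- ((aln$ref_start + rcum[ridx] - 1L) %% L) + 1L
  } else {
    ref_pos[ridx] <- aln$ref_start + rcum[ridx]
  }

  col_op <- character(nc)
  col_op[ops_col == "I"] <- "ins"
  col_op[ops_col == "D"] <- "del"
  aligned <- ops_col %in% c("M", "=", "X")
  is_sub <- logical(nc)
  is_sub[ops_col == "X"] <- TRUE
  if (have_md) {
    is_sub[ridx[md_type == "x"]] <- TRUE
  } else {
    cmp <- ridx[ops_col[ridx] != "D"]
    is_sub[cmp] <- ref_base[cmp] != read_base[cmp]
  }
  is_sub[ops_col == "="] <- FALSE
  col_op[aligned] <- ifelse(is_sub[aligned], "sub", "match")
  amb <- (!is.na(ref_base) & ref_base == "N") |
         (!is.na(read_base) & read_base == "N")
  col_op[amb] <- "ambiguous"

  read_pos <- rep(NA_integer_, nc)
  stored <- left_hard + left_soft + qcum
  if (identical(aln$strand, "reverse")) {
    read_pos[consumes_q] <- read_length - stored[consumes_q] + 1L
  } else {
    read_pos[consumes_q] <- stored[consumes_q]
  }

  structure(list(
    columns = fast_df(op = col_op, read_pos = read_pos, ref_pos = ref_pos,
                      ref_base = ref_base, read_base = read_base),
    read_span = read_span, ref_span = ref_span,
    read_name = aln$read_name %||% NA_character_,
    ref_name = aln$ref_name %||% NA_character_,
    strand = aln$strand %||% "forward",
    read_length = as.integer(read_length)),
    class = "edit_script")
}

#' @export
print.edit_script <- function(x, ...) {
  tab <- table(factor(x$columns$op,
                      levels = c("match", "sub", "ins", "del", "ambiguous")))
  cat(sprintf("<edit_script> %s (%s): %d columns [%s], read span %d, ref span %d\n",
              x$read_name, x$strand, nrow(x$columns),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
              x$read_span, x$ref_span))
  invisible(x)
}
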