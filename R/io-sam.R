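CIGAR_QUERY_OPS <- c("M", "I", "S", "=", "X")
CIGAR_REF_OPS   <- c("M", "D", "=", "X")

# Parse a CIGAR string into parallel op/length vectors.
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar))
    stop_format("missing CIGAR")
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop_format("malformed CIGAR string '%s'", cigar)
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

cigar_query_length <- function(op, len, with_hard = TRUE) {
  ops <- CIGAR_QUERY_OPS
  if (with_hard) ops <- c(ops, "H")
  sum(len[op %in% ops])
}

#' Parse a SAM file into alignment records
#'
#' Reads text SAM, keeping mapped records and counting unmapped, secondary
#' and supplementary records for aligned-fraction statistics. Hard-clipped
#' bases are included in `read_length` so that coordinate flipping of
#' reverse-strand alignments stays correct. Reference starts are stored
#' 0-based (SAM POS - 1); all reported coordinates elsewhere are 1-based.
#'
#' @param path path to a SAM file with a header
#' @param primary_only drop secondary (flag 0x100) and supplementary
#'   (flag 0x800) records
#' @return a `data.frame` of class `alignment_set` with one row per kept
#'   record (columns `read_name`, `flag`, `ref_name`, `ref_start`, `strand`,
#'   `cigar`, `md`, `seq`, `is_primary`, `read_length`) and a `census`
#'   attribute with record counters and the distinct aligned read names
#' @export
parse_alignments <- function(path, primary_only = TRUE) {
  if (!file.exists(path)) stop_format("SAM file not found: %s", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  census <- list(n_records = length(body), n_unmapped = 0L, n_secondary = 0L,
                 n_supplementary = 0L, n_no_cigar = 0L)
  if (length(body) == 0L) {
    warning("SAM file has an empty body", call. = FALSE)
    res <- data.frame(read_name = character(), flag = integer(),
                      ref_name = character(), ref_start = integer(),
                      strand = character(), cigar = character(),
                      md = character(), seq = character(),
                      is_primary = logical(), read_length = integer(),
                      stringsAsFactors = FALSE)
    census$aligned_read_names <- character()
    attr(res, "census") <- census
    class(res) <- c("alignment_set", "data.frame")
    return(res)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop_format("SAM record %d has %d fields (< 11)", which(nf < 11L)[1],
                min(nf))
  getf <- function(i) vapply(fields, `[[`, "", i)
  flag <- as.integer(getf(2L))
  unmapped <- bitwAnd(flag, 4L) != 0L
  census$n_unmapped <- sum(unmapped)
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  cigar <- getf(6L)
  keep <- !unmapped
  no_cigar <- keep & cigar == "*"
  if (any(no_cigar)) {
    warning(sprintf("%d mapped record(s) without CIGAR skipped", sum(no_cigar)),
            call. = FALSE)
    census$n_no_cigar <- sum(no_cigar)
    keep <- keep & !no_cigar
  }
  census$n_secondary <- sum(secondary & keep)
  census$n_supplementary <- sum(supplementary & keep)
  if (primary_only) keep <- keep & !secondary & !supplementary
  md <- vapply(fields, function(f) {
    hit <- grep("^MD:Z:", f[-(1:11)], value = TRUE)
    if (length(hit)) substring(hit[1], 6L) else NA_character_
  }, "")
  seqs <- getf(10L)
  seqs[seqs == "*"] <- NA_character_
  read_length <- integer(length(fields))
  for (i in which(keep)) {
    cg <- parse_cigar(cigar[i])
    read_length[i] <- cigar_query_length(cg$op, cg$len, with_hard = TRUE)
    if (!is.na(seqs[i])) {
      ql <- cigar_query_length(cg$op, cg$len, with_hard = FALSE)
      if (ql != nchar(seqs[i]))
        stop_format("record '%s': CIGAR query length %d != SEQ length %d",
                    getf(1L)[i], ql, nchar(seqs[i]))
    }
  }
  res <- data.frame(
    read_name = getf(1L)[keep], flag = flag[keep],
    ref_name = getf(3L)[keep],
    ref_start = as.integer(getf(4L))[keep] - 1L,
    strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "reverse", "forward"),
    cigar = cigar[keep], md = md[keep], seq = toupper(seqs[keep]),
    is_primary = !(secondary[keep] | supplementary[keep]),
    read_length = read_length[keep], stringsAsFactors = FALSE)
  census$aligned_read_names <-
    unique(res$read_name[res$is_primary])
  attr(res, "census") <- census
  class(res) <- c("alignment_set", "data.frame")
  res
}

#' Write alignment records to SAM
#'
#' @param aln an `alignment_set`-shaped data frame (1-based positions are
#'   reconstructed from the stored 0-based `ref_start`)
#' @param refs list of `ref_genome` objects for the `@SQ` header lines
#' @param path output path
#' @param comments character vector of `@CO` lines (e.g. seed provenance)
#' @export
write_sam <- function(aln, refs, path, comments = character()) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           vapply(refs, function(r)
             sprintf("@SQ\tSN:%s\tLN:%d", r$name, genome_length(r)), ""),
           sprintf("@PG\tID:lrprofile\tPN:lrprofile\tVN:%s",
                   as.character(utils::packageVersion("lrprofile"))),
           if (length(comments)) paste0("@CO\t", comments))
  md <- ifelse(is.na(aln$md), "", paste0("\tMD:Z:", aln$md))
  qual <- aln$qual %||% strrep("I", nchar(aln$seq))
  recs <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s%s",
                  aln$read_name, aln$flag, aln$ref_name, aln$ref_start + 1L,
                  aln$cigar, aln$seq, qual, md)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
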