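#' Reference genome record
#'
#' Lightweight container for a (possibly circular) reference sequence.
#' The alphabet is restricted to A, C, G, T, N; the circular flag only
#' controls k-mer bridging and wrap-around coordinate arithmetic.
#'
#' @param name sequence identifier
#' @param sequence DNA string over A/C/G/T/N (uppercased on input)
#' @param circular logical; is the molecule circular (e.g. a bacterial
#'   chromosome)?
#' @return an object of class `ref_genome`
#' @export
reference_genome <- function(name, sequence, circular = FALSE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop_format("reference '%s' has an empty sequence", name)
  if (grepl("[^ACGTN]", sequence))
    stop_format("reference '%s' contains characters outside {A,C,G,T,N}", name)
  structure(
    list(name = as.character(name), sequence = sequence,
         circular = isTRUE(circular)),
    class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %s: %s bp (%s)\n", x$name,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

genome_length <- function(ref) nchar(ref$sequence)

#' Read a FASTA file of reference sequences
#'
#' Sequences are uppercased; IUPAC ambiguity codes other than N are mapped
#' to N with a warning. Record names are taken up to the first whitespace.
#'
#' @param path path to a FASTA file
#' @param circular logical flag applied to every returned record
#' @return a list of [reference_genome()] objects, in file order
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop_format("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop_format("cannot parse %s as FASTA: %s", path,
                                conditionMessage(e)))
  if (length(set) == 0L) stop_format("FASTA file %s contains no records", path)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    bad <- names(set)[!nzchar(seqs)][1]
    stop_format("FASTA record '%s' in %s has no sequence", bad, path)
  }
  n_amb <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_amb > 0) {
    warning(sprintf("%d non-ACGTN base(s) in %s mapped to N", n_amb, path),
            call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  nm <- sub("\\s.*$", "", names(set))
  unname(Map(function(n, s) reference_genome(n, s, circular = circular), nm, seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences, or a list of
#'   `ref_genome` objects
#' @param path output path
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1]], "ref_genome"))
    seqs <- setNames(vapply(seqs, `[[`, "", "sequence"),
                     vapply(seqs, `[[`, "", "name"))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a 4-line-record FASTQ file
#'
#' Names are truncated at the first whitespace; quality strings are kept
#' verbatim. A sequence/quality length mismatch is a format error naming
#' the offending record.
#'
#' @param path path to an uncompressed FASTQ file
#' @return a `data.frame` of class `read_set` with columns `name`,
#'   `sequence`, `qualities`
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_format("FASTQ file not found: %s", path)
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop_format("FASTQ file %s: line count %d is not a multiple of 4",
                path, length(lines))
  n <- length(lines) %/% 4L
  heads <- lines[seq(1L, by = 4L, length.out = n)]
  seqs  <- lines[seq(2L, by = 4L, length.out = n)]
  plus  <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(substr(heads, 1, 1) != "@"))
    stop_format("FASTQ file %s: header line without '@' near record %d",
                path, which(substr(heads, 1, 1) != "@")[1])
  if (any(substr(plus, 1, 1) != "+"))
    stop_format("FASTQ file %s: separator line without '+' near record %d",
                path, which(substr(plus, 1, 1) != "+")[1])
  nm <- sub("\\s.*$", "", substring(heads, 2))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop_format("FASTQ record '%s': sequence length %d != quality length %d",
                nm[bad[1]], nchar(seqs[bad[1]]), nchar(quals[bad[1]]))
  structure(
    data.frame(name = nm, sequence = toupper(seqs), qualities = quals,
               stringsAsFactors = FALSE),
    class = c("read_set", "data.frame"))
}

#' Write reads to FASTQ
#'
#' @param reads a `read_set` data frame (columns name, sequence, qualities)
#' @param path output path
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qualities
  if (is.null(qual)) qual <- strrep("I", nchar(reads$sequence))
  out <- character(4L * nrow(reads))
  out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$name)
  out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$sequence
  out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(reads))] <- qual
  writeLines(out, path)
  invisible(path)
}
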