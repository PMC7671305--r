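# Shared in-code fixtures: no data files, everything is built at test time.

make_aln <- function(cigar, seq, md = NA_character_, strand = "forward",
                     ref_start = 0L, read_length = NULL, name = "r",
                     ref_name = "g") {
  list(read_name = name, ref_name = ref_name, cigar = cigar, md = md,
       seq = seq, strand = strand, ref_start = as.integer(ref_start),
       read_length = read_length)
}

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

sam_header <- function(ref_name = "g", ref_len = 100L) {
  c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
}

sam_rec <- function(qname, flag, rname, pos, cigar, seq, md = NULL) {
  qual <- if (identical(seq, "*")) "*" else strrep("I", nchar(seq))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                 qname, flag, rname, pos, cigar, seq, qual)
  if (!is.null(md)) rec <- paste0(rec, "\tMD:Z:", md)
  rec
}

# Error-model config with short reads, for fast simulator-driven tests.
short_cfg <- function(preset = "ont", seed = 1L, ...) {
  sim_preset(preset, seed = seed,
             read_length = list(meanlog = log(800), sdlog = 0.4,
                                min_len = 200L, max_len = 3000L), ...)
}

# Brute-force oracle: pool all columns of all scripts into one vector and
# count each op directly (independent of aggregate_profile's bookkeeping).
brute_pooled_counts <- function(scripts) {
  ops <- unlist(lapply(scripts, function(s) s$columns$op))
  c(n_match = sum(ops == "match"), n_sub = sum(ops == "sub"),
    n_ins = sum(ops == "ins"), n_del = sum(ops == "del"),
    n_ambiguous = sum(ops == "ambiguous"), n_columns = length(ops))
}

expand_all <- function(sam_df, ref = NULL) {
  rows <- lapply(seq_len(nrow(sam_df)), function(i) lapply(sam_df, `[[`, i))
  lapply(rows, expand_edit_script, ref = ref)
}
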