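#' Simulation configuration for the long-read error model
#'
#' The generative model is calibrated so that `p_sub`, `p_ins` and `p_del`
#' are the EXPECTED FRACTIONS OF ALIGNMENT COLUMNS of each error type
#' (the same denominator the profiling side uses), not raw per-position
#' draw probabilities: event probabilities are solved from them, so
#' recovered pooled rates converge to the configured values. Insertions
#' are drawn as events with geometric length extension; substitution
#' replacement bases follow the row-stochastic, zero-diagonal preference
#' matrix `sub_pref`. The optional homopolymer model perturbs reference
#' runs of at least `min_run` identical bases by +-1 base (expansion as an
#' extra inserted run base, contraction as a deletion within the run).
#' The 5'-noise model multiplies all error rates by `multiplier` for the
#' first `n5` emitted read bases (in original read orientation, so the
#' noisy end is the read's 5' end on either strand). Read lengths are
#' lognormal, truncated to `[min_len, max_len]`.
#'
#' @param p_sub,p_ins,p_del expected per-column error fractions; their sum
#'   (times the 5' multiplier) must stay below 1
#' @param sub_pref 4x4 row-stochastic matrix with zero diagonal (rows =
#'   reference base A,C,G,T; columns = replacement base); default uniform
#'   over the three alternatives
#' @param ins_ext geometric extension parameter of insertion events in
#'   [0, 1); event length is 1 + Geom(1 - ins_ext), mean 1/(1 - ins_ext)
#' @param ins_base_probs length-4 base distribution of inserted bases
#' @param homopolymer list(enabled, min_run, p_expand, p_contract)
#' @param five_prime list(n5, multiplier)
#' @param read_length list(meanlog, sdlog, min_len, max_len)
#' @param seed integer RNG seed used by [simulate_readset()]
#' @return an object of class `sim_config`
#' @export
simulation_config <- function(p_sub = 0.04, p_ins = 0.04, p_del = 0.04,
                              sub_pref = NULL, ins_ext = 0.25,
                              ins_base_probs = rep(0.25, 4),
                              homopolymer = list(enabled = FALSE,
                                                 min_run = 4L,
                                                 p_expand = 0.2,
                                                 p_contract = 0.05),
                              five_prime = list(n5 = 1000L, multiplier = 1),
                              read_length = list(meanlog = log(9000),
                                                 sdlog = 0.55,
                                                 min_len = 200L,
                                                 max_len = 60000L),
                              seed = 1L) {
  if (is.null(sub_pref)) {
    sub_pref <- matrix(1 / 3, 4, 4, dimnames = list(BASES, BASES))
    diag(sub_pref) <- 0
  }
  stopifnot(is.matrix(sub_pref), dim(sub_pref) == c(4, 4))
  dimnames(sub_pref) <- list(BASES, BASES)
  if (any(abs(rowSums(sub_pref) - 1) > 1e-8) || any(diag(sub_pref) != 0))
    stop_usage("sub_pref must be row-stochastic with a zero diagonal")
  if (p_sub < 0 || p_ins < 0 || p_del < 0)
    stop_usage("error probabilities must be non-negative")
  m5 <- five_prime$multiplier %||% 1
  if (m5 < 1) stop_usage("five_prime multiplier must be >= 1")
  if (m5 * (p_sub + p_ins + p_del) >= 1)
    stop_usage("multiplier * (p_sub + p_ins + p_del) must be < 1")
  if (ins_ext < 0 || ins_ext >= 1) stop_usage("ins_ext must be in [0, 1)")
  hp <- utils::modifyList(list(enabled = FALSE, min_run = 4L,
                               p_expand = 0.2, p_contract = 0.05),
                          homopolymer)
  if (hp$p_expand + hp$p_contract > 1)
    stop_usage("p_expand + p_contract must be <= 1")
  fp <- utils::modifyList(list(n5 = 1000L, multiplier = 1), five_prime)
  rl <- utils::modifyList(list(meanlog = log(9000), sdlog = 0.55,
                               min_len = 200L, max_len = 60000L),
                          read_length)
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 sub_pref = sub_pref, ins_ext = ins_ext,
                 ins_base_probs = ins_base_probs / sum(ins_base_probs),
                 homopolymer = hp, five_prime = fp, read_length = rl,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Error-model presets echoing measured ONT / PacBio profiles
#'
#' Per-type rates follow published cross-aligner averages for raw reads:
#' ONT-like sub/ins/del = 4.33/3.69/4.54%; PacBio-like = 1.68/8.04/3.16%.
#' The substitution preference concentrates 70% of each row's mass on the
#' transition partner for the ONT preset (A<->G, C<->T elevated) and 40%
#' on the favored transversion partner for the PacBio preset (A<->C,
#' G<->T slightly elevated); exact weights are free model parameters.
#' Read-length defaults put the mean near 10.5 kbp (ONT) and 8.9 kbp
#' (PacBio). The homopolymer model ships disabled; enable it explicitly.
#'
#' @param preset `"ont"` or `"pacbio"`
#' @param seed RNG seed
#' @param ... overrides passed to [simulation_config()]
#' @return a `sim_config`
#' @export
sim_preset <- function(preset = c("ont", "pacbio"), seed = 1L, ...) {
  preset <- match.arg(preset)
  transition_pref <- function(w) {
    m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    partners <- c(A = "G", C = "T", G = "A", T = "C")
    for (b in BASES) {
      m[b, partners[b]] <- w
      others <- setdiff(BASES, c(b, partners[b]))
      m[b, others] <- (1 - w) / 2
    }
    m
  }
  transversion_pref <- function(w) {
    m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    partners <- c(A = "C", C = "A", G = "T", T = "G")
    for (b in BASES) {
      m[b, partners[b]] <- w
      others <- setdiff(BASES, c(b, partners[b]))
      m[b, others] <- (1 - w) / 2
    }
    m
  }
  defaults <- switch(preset,
    ont = list(p_sub = 0.0433, p_ins = 0.0369, p_del = 0.0454,
               sub_pref = transition_pref(0.70),
               read_length = list(meanlog = log(9000), sdlog = 0.55,
                                  min_len = 200L, max_len = 140000L)),
    pacbio = list(p_sub = 0.0168, p_ins = 0.0804, p_del = 0.0316,
                  sub_pref = transversion_pref(0.40),
                  read_length = list(meanlog = log(8000), sdlog = 0.45,
                                     min_len = 200L, max_len = 45000L)))
  args <- utils::modifyList(c(defaults, list(seed = seed)), list(...))
  do.call(simulation_config, args)
}

#' Generate a random reference genome
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2`, `P(A) = P(T) = (1 - gc)/2`;
#' deterministic for a fixed seed.
#'
#' @param length genome length (bp)
#' @param gc GC fraction in [0, 1]
#' @param seed RNG seed
#' @param circular circularity flag of the product
#' @param name sequence name
#' @return a [reference_genome()]
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L, circular = TRUE,
                            name = "sim_genome") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- local_seed(seed, paste(sample(BASES, length, replace = TRUE,
                                       prob = probs), collapse = ""))
  reference_genome(name, seq, circular = circular)
}

# Event probabilities solved from per-column target rates at multiplier m:
# columns per reference position are 1 (emitted or deleted) + inserted
# bases; lam = expected inserted bases / position.
rates_for <- function(cfg, m) {
  ps <- cfg$p_sub * m; pi_ <- cfg$p_ins * m; pd <- cfg$p_del * m
  lam <- pi_ / (1 - pi_)
  d <- pd * (1 + lam)
  q <- if (d < 1) ps * (1 + lam) / (1 - d) else 1
  list(d = d, q = q, pe = lam * (1 - cfg$ins_ext))
}

draw_block <- function(chars, r, cfg) {
  n <- length(chars)
  del <- runif(n) < r$d
  sub <- !del & (runif(n) < r$q)
  ins_ev <- runif(n) < r$pe
  ins_len <- integer(n)
  if (any(ins_ev))
    ins_len[ins_ev] <- 1L + as.integer(rgeom(sum(ins_ev), 1 - cfg$ins_ext))
  read_emit <- chars
  for (b in seq_along(BASES)) {
    idx <- which(sub & chars == BASES[b])
    if (length(idx))
      read_emit[idx] <- sample(BASES, length(idx), replace = TRUE,
                               prob = cfg$sub_pref[b, ])
  }
  read_emit[del] <- NA_character_
  total_ins <- sum(ins_len)
  ins_bases <- if (total_ins)
    sample(BASES, total_ins, replace = TRUE, prob = cfg$ins_base_probs)
  else character()
  list(del = del, sub = sub, read_emit = read_emit, ins_len = ins_len,
       ins_bases = ins_bases)
}

truncate_block <- function(blk, cut) {
  keep_ins <- sum(blk$ins_len[seq_len(cut)])
  list(del = blk$del[seq_len(cut)], sub = blk$sub[seq_len(cut)],
       read_emit = blk$read_emit[seq_len(cut)],
       ins_len = blk$ins_len[seq_len(cut)],
       ins_bases = blk$ins_bases[seq_len(keep_ins)])
}

concat_blocks <- function(blocks) {
  list(del = unlist(lapply(blocks, `[[`, "del")),
       sub = unlist(lapply(blocks, `[[`, "sub")),
       read_emit = unlist(lapply(blocks, `[[`, "read_emit")),
       ins_len = unlist(lapply(blocks, `[[`, "ins_len")),
       ins_bases = unlist(lapply(blocks, `[[`, "ins_bases")))
}

# Draw all per-position events along the ORIGINAL read orientation,
# applying the 5' multiplier to the first n5 emitted read bases.
emit_orig <- function(chars, cfg) {
  n <- length(chars)
  m5 <- cfg$five_prime$multiplier
  n5 <- cfg$five_prime$n5
  if (m5 > 1 && n5 > 0) {
    acc <- list(); emitted <- 0L; i0 <- 0L
    r1 <- rates_for(cfg, m5)
    while (i0 < n && emitted < n5) {
      bs <- min(n - i0, max(256L, as.integer(n5 - emitted) + 64L))
      blk <- draw_block(chars[(i0 + 1L):(i0 + bs)], r1, cfg)
      em <- cumsum(blk$ins_len + !blk$del)
      if (emitted + em[bs] >= n5) {
        cut <- which(emitted + em >= n5)[1]
        acc <- c(acc, list(truncate_block(blk, cut)))
        emitted <- emitted + em[cut]; i0 <- i0 + cut
        break
      }
      acc <- c(acc, list(blk)); emitted <- emitted + em[bs]; i0 <- i0 + bs
    }
    if (i0 < n)
      acc <- c(acc, list(draw_block(chars[(i0 + 1L):n], rates_for(cfg, 1),
                                    cfg)))
    blk <- concat_blocks(acc)
  } else {
    blk <- draw_block(chars, rates_for(cfg, 1), cfg)
  }

  hp_pos <- integer(); hp_base <- character()
  if (isTRUE(cfg$homopolymer$enabled)) {
    hp <- cfg$homopolymer
    r <- rle(chars)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    qual <- which(r$lengths >= hp$min_run & r$values %in% BASES)
    for (j in qual) {
      u <- runif(1)
      if (u < hp$p_expand) {
        hp_pos <- c(hp_pos, ends[j] + 1L)   # insert adjacent to run end
        hp_base <- c(hp_base, r$values[j])
      } else if (u < hp$p_expand + hp$p_contract) {
        cand <- starts[j]:ends[j]
        cand <- cand[!blk$del[cand]]
        if (length(cand)) {
          i <- cand[length(cand)]
          blk$del[i] <- TRUE; blk$sub[i] <- FALSE
          blk$read_emit[i] <- NA_character_
        }
      }
    }
  }
  list(blk = blk, hp_pos = hp_pos, hp_base = hp_base)
}

#' Simulate one long read with exact truth alignment
#'
#' Walks a reference span, drawing deletions, substitutions (replacement
#' from the preference matrix) and insertions (geometric length), with the
#' 5' multiplier applied to the first `n5` emitted bases in original read
#' orientation, plus optional homopolymer run perturbation. Returns the
#' read, its truth alignment (CIGAR + MD, SAM conventions: reverse-strand
#' reads are stored reference-forward), the truth edit script (identical
#' to what [expand_edit_script()] reconstructs) and truth error counts.
#' Uses the CURRENT RNG state; seed via [simulate_readset()] or
#' `set.seed()`.
#'
#' @param genome a [reference_genome()]
#' @param start 1-based start of the reference span (wrap-around allowed on
#'   circular genomes)
#' @param span reference span length (bp)
#' @param strand `"forward"` or `"reverse"`
#' @param config a [simulation_config()]
#' @param name read name
#' @return a list with elements `read` (name/sequence/qualities), `sam`
#'   (one-row alignment record), `truth` (`edit_script`), `counts`
#'   (`error_counts`)
#' @export
simulate_read <- function(genome, start, span, strand = "forward",
                          config = simulation_config(), name = "read_1") {
  L <- genome_length(genome)
  stopifnot(span >= 1, start >= 1, start <= L)
  end0 <- start - 1L + span
  if (end0 > L && !genome$circular)
    stop_usage("span runs past the end of a linear genome")
  fwd <- if (end0 <= L) substr(genome$sequence, start, end0)
         else paste0(substr(genome$sequence, start, L),
                     substr(genome$sequence, 1L, end0 - L))
  fwd_chars <- explode(fwd)
  orig_chars <- if (strand == "reverse") rev(comp_bases(fwd_chars)) else fwd_chars

  em <- emit_orig(orig_chars, config)
  blk <- em$blk
  n <- span
  hp_cnt <- integer(n + 1L)
  if (length(em$hp_pos)) {
    t <- table(em$hp_pos)
    hp_cnt[as.integer(names(t))] <- as.integer(t)
  }

  # merged insertion bases ordered by slot; homopolymer bases first in slot
  ord_slot <- rep(seq_len(n), blk$ins_len)
  ins_df_slot <- c(em$hp_pos, ord_slot)
  ins_df_prio <- c(rep(0L, length(em$hp_pos)), rep(1L, length(ord_slot)))
  ins_df_base <- c(em$hp_base, blk$ins_bases)
  o <- order(ins_df_slot, ins_df_prio, seq_along(ins_df_slot))
  merged_ins <- ins_df_base[o]

  bs <- hp_cnt[seq_len(n)] + blk$ins_len + 1L
  pos_idx <- cumsum(bs)
  N <- sum(bs) + hp_cnt[n + 1L]
  kind <- rep(3L, N)
  kind[pos_idx] <- ifelse(blk$del, 4L, ifelse(blk$sub, 2L, 1L))
  orig_ref_idx <- rep(NA_integer_, N)
  orig_ref_idx[pos_idx] <- seq_len(n)
  col_ref_base <- rep(NA_character_, N)
  col_ref_base[pos_idx] <- orig_chars
  col_read_base <- rep(NA_character_, N)
  col_read_base[pos_idx] <- blk$read_emit
  col_read_base[kind == 3L] <- merged_ins

  q_col <- kind != 4L
  read_pos <- rep(NA_integer_, N)
  read_pos[q_col] <- cumsum(q_col)[q_col]
  read_len <- sum(q_col)

  if (strand == "reverse") {
    ord <- N:1L
    kind <- kind[ord]; read_pos <- read_pos[ord]
    col_ref_base <- comp_bases(col_ref_base[ord])
    col_read_base <- comp_bases(col_read_base[ord])
    fwd_ref_idx <- span + 1L - orig_ref_idx[ord]
  } else {
    fwd_ref_idx <- orig_ref_idx
  }
  ref_pos <- rep(NA_integer_, N)
  rr <- !is.na(fwd_ref_idx)
  ref_pos[rr] <- ((start - 1L + fwd_ref_idx[rr] - 1L) %% L) + 1L

  op_str <- c("match", "sub", "ins", "del")[kind]
  stored_seq <- paste(col_read_base[kind != 4L], collapse = "")

  cig_op <- c("M", "M", "I", "D")[kind]
  r <- rle(cig_op)
  cigar <- paste0(r$lengths, r$values, collapse = "")

  md_types <- c("m", "x", NA, "d")[kind[rr]]
  md <- md_build(md_types, col_ref_base[rr])

  truth <- structure(list(
    columns = fast_df(op = op_str, read_pos = read_pos, ref_pos = ref_pos,
                      ref_base = col_ref_base, read_base = col_read_base),
    read_span = read_len, ref_span = span, read_name = name,
    ref_name = genome$name, strand = strand,
    read_length = read_len), class = "edit_script")

  read_seq <- if (strand == "reverse") revcomp(stored_seq) else stored_seq
  sam <- data.frame(read_name = name,
                    flag = if (strand == "reverse") 16L else 0L,
                    ref_name = genome$name, ref_start = start - 1L,
                    strand = strand, cigar = cigar, md = md,
                    seq = stored_seq, is_primary = TRUE,
                    read_length = read_len, stringsAsFactors = FALSE)
  list(read = list(name = name, sequence = read_seq,
                   qualities = strrep("I", read_len)),
       sam = sam, truth = truth, counts = count_errors(truth))
}

# Build a canonical MD string from the ref-consuming column stream:
# numbers (0 allowed) interleave every mismatch letter and deletion run.
md_build <- function(types, bases) {
  r <- rle(types)
  n <- length(r$values)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  pieces <- character(n)
  m <- r$values == "m"
  pieces[m] <- as.character(r$lengths[m])
  x1 <- r$values == "x" & r$lengths == 1L       # the common singleton runs
  pieces[x1] <- bases[starts[x1]]
  d1 <- r$values == "d" & r$lengths == 1L
  pieces[d1] <- paste0("^", bases[starts[d1]])
  for (i in which(!(m | x1 | d1))) {
    seg <- bases[starts[i]:ends[i]]
    pieces[i] <- if (r$values[i] == "x") paste(seg, collapse = "0")
                 else paste0("^", paste(seg, collapse = ""))
  }
  sep <- c(r$values[-n] != "m" & r$values[-1] != "m", FALSE)
  out <- paste0(paste0(pieces, ifelse(sep, "0", "")), collapse = "")
  if (r$values[1] != "m") out <- paste0("0", out)
  if (r$values[n] != "m") out <- paste0(out, "0")
  out
}

#' Simulate a whole read set with truth alignments
#'
#' Read starts are uniform over the (circular) genome, strands are
#' Bernoulli(0.5), reference spans follow the configured truncated
#' lognormal. Reads are emitted until the cumulative emitted read bases
#' reach `coverage * genome_length`. Deterministic (byte-identical output
#' files) for a fixed config/seed.
#'
#' @param genome a [reference_genome()]
#' @param coverage target fold-coverage (> 0)
#' @param config a [simulation_config()] (its `seed` drives all draws)
#' @param out_dir optional directory: writes `<prefix>.fastq`,
#'   `<prefix>.sam` (with MD tags), `<prefix>_truth.tsv`,
#'   `<prefix>_config.json`
#' @param prefix file name prefix
#' @param keep_columns keep per-read truth edit scripts in memory (set
#'   FALSE for large runs; truth counts are always kept)
#' @return a list: `reads` (`read_set`), `sam` (`alignment_set`-shaped
#'   data frame), `truths` (list of `edit_script` or NULL), `counts` (list
#'   of `error_counts`), `genome`, `config`, `files`
#' @export
simulate_readset <- function(genome, coverage, config = simulation_config(),
                             out_dir = NULL, prefix = "sim",
                             keep_columns = TRUE) {
  stopifnot(coverage > 0)
  L <- genome_length(genome)
  target <- coverage * L
  rl <- config$read_length
  reads <- list(); sams <- list(); truths <- list(); counts <- list()
  local_seed(config$seed, {
    total <- 0; i <- 0L
    while (total < target) {
      i <- i + 1L
      repeat {
        x <- rlnorm(1, rl$meanlog, rl$sdlog)
        if (x >= rl$min_len && x <= rl$max_len) break
      }
      span <- min(as.integer(round(x)), L)
      start <- if (genome$circular) sample.int(L, 1L)
               else sample.int(L - span + 1L, 1L)
      strand <- if (runif(1) < 0.5) "forward" else "reverse"
      sr <- simulate_read(genome, start, span, strand, config,
                          name = sprintf("read_%06d", i))
      reads[[i]] <- sr$read
      sams[[i]] <- sr$sam
      counts[[i]] <- sr$counts
      if (keep_columns) truths[[i]] <- sr$truth
      total <- total + sr$truth$read_length
    }
  })
  read_df <- structure(
    data.frame(name = vapply(reads, `[[`, "", "name"),
               sequence = vapply(reads, `[[`, "", "sequence"),
               qualities = vapply(reads, `[[`, "", "qualities"),
               stringsAsFactors = FALSE),
    class = c("read_set", "data.frame"))
  sam_df <- do.call(rbind, sams)
  class(sam_df) <- c("alignment_set", "data.frame")
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(fastq = file.path(out_dir, paste0(prefix, ".fastq")),
                  sam = file.path(out_dir, paste0(prefix, ".sam")),
                  truth = file.path(out_dir, paste0(prefix, "_truth.tsv")),
                  config = file.path(out_dir, paste0(prefix, "_config.json")))
    write_fastq(read_df, files$fastq)
    write_sam(sam_df, list(genome), files$sam,
              comments = sprintf("lrprofile simulate seed=%d", config$seed))
    truth_df <- data.frame(
      read_name = sam_df$read_name, ref_start = sam_df$ref_start + 1L,
      strand = sam_df$strand, read_length = sam_df$read_length,
      n_match = vapply(counts, `[[`, 0L, "n_match"),
      n_sub = vapply(counts, `[[`, 0L, "n_sub"),
      n_ins = vapply(counts, `[[`, 0L, "n_ins"),
      n_del = vapply(counts, `[[`, 0L, "n_del"),
      n_ambiguous = vapply(counts, `[[`, 0L, "n_ambiguous"),
      n_columns = vapply(counts, `[[`, 0L, "n_columns"),
      stringsAsFactors = FALSE)
    write.table(truth_df, files$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cfg_out <- config
    cfg_out$sub_pref <- as.data.frame(cfg_out$sub_pref)
    jsonlite::write_json(unclass(cfg_out), files$config, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(reads = read_df, sam = sam_df,
       truths = if (keep_columns) truths else NULL,
       counts = counts, genome = genome, config = config, files = files)
}
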