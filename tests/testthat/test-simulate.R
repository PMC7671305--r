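test_that("generate_genome respects GC content and determinism", {
  at_only <- generate_genome(500, gc = 0, seed = 1)
  expect_true(grepl("^[AT]+$", at_only$sequence))

  g <- generate_genome(1e6, gc = 0.5, seed = 2)
  gc_obs <- sum(Biostrings::letterFrequency(
    Biostrings::DNAString(g$sequence), c("G", "C"))) / 1e6
  expect_lt(abs(gc_obs - 0.5), 0.002)

  expect_identical(generate_genome(1000, seed = 7)$sequence,
                   generate_genome(1000, seed = 7)$sequence)
  expect_false(identical(generate_genome(1000, seed = 7)$sequence,
                         generate_genome(1000, seed = 8)$sequence))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(p_sub = 0.5, p_ins = 0.3, p_del = 0.3),
               class = "lrp_usage_error")
  expect_error(simulation_config(p_del = 1), class = "lrp_usage_error")
  expect_error(simulation_config(p_sub = 0.3, p_ins = 0.3, p_del = 0.3,
                                 five_prime = list(multiplier = 2)),
               class = "lrp_usage_error")
  bad_pref <- matrix(0.25, 4, 4)
  expect_error(simulation_config(sub_pref = bad_pref),
               class = "lrp_usage_error")
})

test_that("an error-free config reproduces the reference span", {
  g <- generate_genome(5000, seed = 3, circular = TRUE)
  cfg <- simulation_config(0, 0, 0, seed = 1)
  set.seed(1)
  sr <- simulate_read(g, 11, 500, "forward", cfg)
  expect_equal(sr$sam$cigar, "500M")
  expect_equal(sr$sam$md, "500")
  expect_equal(sr$counts$n_match, 500L)
  expect_equal(sr$read$sequence, substr(g$sequence, 11, 510))
  set.seed(1)
  rv <- simulate_read(g, 11, 500, "reverse", cfg)
  expect_equal(rv$read$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(g$sequence, 11, 510)))))
  expect_equal(rv$sam$seq, substr(g$sequence, 11, 510))
})

test_that("simulate_readset stops at the coverage threshold", {
  g <- generate_genome(100000, seed = 4, circular = TRUE)
  rs <- simulate_readset(g, coverage = 3, short_cfg("ont", seed = 10),
                         keep_columns = FALSE)
  total <- sum(nchar(rs$reads$sequence))
  expect_gte(total, 3 * 100000)
  last <- nchar(rs$reads$sequence[nrow(rs$reads)])
  expect_lt(total - last, 3 * 100000)
})

test_that("strands are Bernoulli(0.5)", {
  g <- generate_genome(50000, seed = 6, circular = TRUE)
  cfg <- sim_preset("ont", seed = 12,
                    read_length = list(meanlog = log(250), sdlog = 0.2,
                                       min_len = 200L, max_len = 400L))
  rs <- simulate_readset(g, coverage = 50, cfg, keep_columns = FALSE)
  expect_gt(nrow(rs$sam), 5000)
  frac_fwd <- mean(rs$sam$strand == "forward")
  expect_lt(abs(frac_fwd - 0.5), 0.02)
})

test_that("pooled truth rates recover the configured column fractions", {
  g <- generate_genome(250000, seed = 14, circular = TRUE)
  for (preset in c("ont", "pacbio")) {
    cfg <- sim_preset(preset, seed = 31)
    rs <- simulate_readset(g, coverage = 8, cfg, keep_columns = FALSE)
    tot <- function(f) sum(vapply(rs$counts, `[[`, 0, f))
    nc <- tot("n_columns")
    for (type in c("sub", "ins", "del")) {
      p <- cfg[[paste0("p_", type)]]
      rate <- tot(paste0("n_", type)) / nc
      se <- sqrt(p * (1 - p) / nc)
      expect_lt(abs(rate - p), 3 * se,
                label = sprintf("%s %s rate |%.5f - %.5f|", preset, type,
                                rate, p))
    }
  }
})

test_that("homopolymer expansion bias raises insertion counts", {
  g <- generate_genome(40000, gc = 0.3, seed = 16, circular = TRUE)
  cfg_on <- short_cfg("ont", seed = 20,
                      homopolymer = list(enabled = TRUE, p_expand = 0.4,
                                         p_contract = 0))
  cfg_off <- short_cfg("ont", seed = 20)
  on <- simulate_readset(g, 3, cfg_on, keep_columns = FALSE)
  off <- simulate_readset(g, 3, cfg_off, keep_columns = FALSE)
  ins_rate <- function(rs) {
    sum(vapply(rs$counts, `[[`, 0, "n_ins")) /
      sum(vapply(rs$counts, `[[`, 0, "n_columns"))
  }
  expect_gt(ins_rate(on), ins_rate(off) * 1.1)
})

test_that("the 5' multiplier concentrates errors in original-read heads", {
  g <- generate_genome(60000, seed = 18, circular = TRUE)
  cfg <- sim_preset("ont", seed = 22,
                    five_prime = list(n5 = 500L, multiplier = 3),
                    read_length = list(meanlog = log(4000), sdlog = 0.1,
                                       min_len = 3000L, max_len = 6000L))
  rs <- simulate_readset(g, coverage = 4, cfg)
  ops <- unlist(lapply(rs$truths, function(s) s$columns$op))
  pos <- unlist(lapply(rs$truths, function(s)
    lrprofile:::assign_read_pos(s)))
  err <- ops %in% c("sub", "ins", "del")
  head_rate <- mean(err[pos <= 500])
  tail_rate <- mean(err[pos > 1000 & pos <= 3000])
  expect_gt(head_rate / tail_rate, 2.5)
  expect_lt(head_rate / tail_rate, 3.5)
})
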