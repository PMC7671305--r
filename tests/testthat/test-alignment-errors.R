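test_that("count_errors and longest_perfect_run match hand-expanded cases", {
  perfect <- expand_edit_script(make_aln("10M", "ACGTACGTAC", md = "10"))
  expect_equal(unclass(count_errors(perfect)),
               list(n_match = 10L, n_sub = 0L, n_ins = 0L, n_del = 0L,
                    n_ambiguous = 0L, n_columns = 10L))
  expect_equal(longest_perfect_run(perfect), 10L)

  indel <- expand_edit_script(make_aln("3M1I2M1D4M", "ACGTAGCTTA",
                                       md = "5^A4"))
  expect_equal(unclass(count_errors(indel)),
               list(n_match = 9L, n_sub = 0L, n_ins = 1L, n_del = 1L,
                    n_ambiguous = 0L, n_columns = 11L))

  mism <- expand_edit_script(make_aln("10M", "ACGTGGCTTA", md = "4A5"))
  expect_equal(unclass(count_errors(mism)),
               list(n_match = 9L, n_sub = 1L, n_ins = 0L, n_del = 0L,
                    n_ambiguous = 0L, n_columns = 10L))
  expect_equal(longest_perfect_run(mism), 5L)

  split <- expand_edit_script(make_aln("3M1I7M", "ACGTACGTACG", md = "10"))
  expect_equal(longest_perfect_run(split), 7L)
})

test_that("aggregate_profile pools counts across the read set", {
  s1 <- expand_edit_script(make_aln("10M", "ACGTACGTAC", md = "10",
                                    name = "a"))
  s2 <- expand_edit_script(make_aln("5M1I4M", "ACGTACGTAC", md = "2A6",
                                    name = "b"))
  expect_equal(unclass(count_errors(s2))[c("n_match", "n_sub", "n_ins")],
               list(n_match = 8L, n_sub = 1L, n_ins = 1L))
  prof <- aggregate_profile(list(s1, s2), n_reads_total = 2)
  expect_equal(prof$sub_pct, 5)
  expect_equal(prof$ins_pct, 5)
  expect_equal(prof$del_pct, 0)
  expect_equal(prof$total_pct, 10)
  expect_equal(prof$aligned_pct, 100)
  expect_equal(prof$longest_perfect_match, 10L)
  expect_equal(prof$longest_alignment, 10L)
  expect_equal(prof$max_stretch_pct, 0)
})

test_that("a single perfect alignment yields a zero-error profile", {
  seqs <- strrep("A", 100)
  s <- expand_edit_script(make_aln("100M", seqs, md = "100"))
  prof <- aggregate_profile(list(s), n_reads_total = 1)
  expect_equal(prof$total_pct, 0)
  expect_equal(prof$longest_perfect_match, 100L)
})

test_that("zero aligned reads gives an empty profile with a warning", {
  expect_warning(prof <- aggregate_profile(list(), n_reads_total = 5),
                 "no aligned reads")
  expect_true(is.na(prof$total_pct))
  expect_equal(prof$n_reads_aligned, 0L)
})

test_that("pooled rates equal a brute-force column-concatenation oracle", {
  g <- generate_genome(20000, seed = 13, circular = TRUE)
  rs <- simulate_readset(g, coverage = 1.5, short_cfg("ont", seed = 4))
  prof <- aggregate_profile(rs$truths, n_reads_total = nrow(rs$reads))
  brute <- brute_pooled_counts(rs$truths)
  expect_equal(prof$counts$n_sub, unname(brute["n_sub"]))
  expect_equal(prof$counts$n_columns, unname(brute["n_columns"]))
  expect_equal(prof$sub_pct, 100 * brute[["n_sub"]] / brute[["n_columns"]])
  expect_equal(prof$ins_pct, 100 * brute[["n_ins"]] / brute[["n_columns"]])
  expect_equal(prof$del_pct, 100 * brute[["n_del"]] / brute[["n_columns"]])
})

test_that("adding an error-free alignment never increases error rates", {
  g <- generate_genome(10000, seed = 3, circular = TRUE)
  rs <- simulate_readset(g, coverage = 0.5, short_cfg("ont", seed = 6))
  before <- aggregate_profile(rs$truths, n_reads_total = nrow(rs$reads))
  clean <- expand_edit_script(make_aln("1000M", strrep("A", 1000),
                                       md = "1000", name = "clean"))
  after <- aggregate_profile(c(rs$truths, list(clean)),
                             n_reads_total = nrow(rs$reads) + 1)
  expect_lte(after$sub_pct, before$sub_pct)
  expect_lte(after$ins_pct, before$ins_pct)
  expect_lte(after$del_pct, before$del_pct)
})

test_that("aggregate_profile counts equal the simulator truth exactly", {
  g <- generate_genome(15000, seed = 8, circular = TRUE)
  rs <- simulate_readset(g, coverage = 1, short_cfg("pacbio", seed = 5))
  prof <- aggregate_profile(rs$truths, n_reads_total = nrow(rs$reads))
  truth_tot <- function(f) sum(vapply(rs$counts, `[[`, 0L, f))
  expect_true(prof$counts$n_sub == truth_tot("n_sub"))
  expect_true(prof$counts$n_ins == truth_tot("n_ins"))
  expect_true(prof$counts$n_del == truth_tot("n_del"))
  expect_true(prof$counts$n_columns == truth_tot("n_columns"))
})

test_that("substitution_matrix counts and conditional rates", {
  # one A->G substitution among 10 aligned A columns
  s <- expand_edit_script(make_aln("10M", "AAAAGAAAAA", md = "4A5"))
  m <- substitution_matrix(list(s))
  expect_equal(m$counts["A", "G"], 1L)
  expect_equal(m$counts["A", "A"], 9L)
  expect_equal(m$rates["A", "G"], 0.1)
  expect_equal(sum(m$counts), 10L)

  perfect <- expand_edit_script(make_aln("10M", "ACGTACGTAC", md = "10"))
  m0 <- substitution_matrix(list(perfect))
  expect_true(all(m0$counts[row(m0$counts) != col(m0$counts)] == 0))
  expect_equal(m0$transition_rate, 0)
})

test_that("row sums of the substitution matrix equal per-base column counts", {
  g <- generate_genome(15000, seed = 7, circular = TRUE)
  rs <- simulate_readset(g, coverage = 1, short_cfg("ont", seed = 9))
  m <- substitution_matrix(rs$truths)
  ops <- unlist(lapply(rs$truths, function(s) s$columns$op))
  refb <- unlist(lapply(rs$truths, function(s) s$columns$ref_base))
  sel <- ops %in% c("match", "sub")
  expect_equal(unname(rowSums(m$counts)),
               as.vector(table(factor(refb[sel], levels = c("A", "C", "G", "T")))))
})

test_that("profile TSV serialization has the contracted columns", {
  s <- expand_edit_script(make_aln("10M", "ACGTACGTAC", md = "4A5"))
  prof <- aggregate_profile(list(s), n_reads_total = 1, dataset = "toy")
  p <- tempfile(fileext = ".tsv")
  write_profile_tsv(prof, p)
  tab <- read.delim(p)
  expect_equal(colnames(tab),
               c("dataset", "n_reads", "aligned_pct", "sub_pct", "ins_pct",
                 "del_pct", "total_pct", "longest_perfect_match_bp",
                 "longest_alignment_bp", "max_stretch_pct"))
  expect_equal(tab$sub_pct, 10)
})
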