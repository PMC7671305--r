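kt <- function(counts, k) {
  structure(list(k = k, counts = counts, total = sum(counts),
                 n_skipped_N = 0L, source = "manual"),
            class = "kmer_table")
}

test_that("circular both-strand counting includes bridging k-mers", {
  g <- reference_genome("g", "ACGT", circular = TRUE)
  tab <- count_kmers(g, k = 2)
  expect_equal(tab$total, 8L)                      # 2 x genome length
  nz <- tab$counts[tab$counts > 0]
  expect_equal(nz[order(names(nz))],
               c(AC = 2L, CG = 2L, GT = 2L, TA = 2L))

  g2 <- reference_genome("g", "AAAA", circular = TRUE)
  tab2 <- count_kmers(g2, k = 2)
  expect_equal(tab2$counts[["AA"]], 4L)
  expect_equal(tab2$counts[["TT"]], 4L)
  expect_equal(tab2$total, 8L)
})

test_that("linear sequences shorter than k contribute nothing", {
  tab <- count_kmers("AAAA", k = 6, circular = FALSE, both_strands = TRUE)
  expect_equal(tab$total, 0L)
})

test_that("k-mers containing N are skipped and tallied", {
  tab <- count_kmers("ACGNACGT", k = 2, circular = FALSE,
                     both_strands = FALSE)
  expect_equal(tab$total, 5L)
  expect_equal(tab$n_skipped_N, 2L)
})

test_that("count identities and strand symmetry hold on random genomes", {
  set.seed(42)
  for (i in 1:20) {
    len <- sample(500:3000, 1)
    k <- sample(2:6, 1)
    g <- generate_genome(len, gc = runif(1, 0.2, 0.8),
                         seed = sample.int(1e6, 1), circular = TRUE)
    tab <- count_kmers(g, k = k)
    expect_equal(tab$total, 2L * len)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(names(tab$counts))))
    expect_equal(unname(tab$counts), unname(tab$counts[rc]))
  }
})

test_that("representation_diff: identical tables give all-zero diffs", {
  g <- generate_genome(2000, seed = 1, circular = TRUE)
  tab <- count_kmers(g, k = 4)
  rows <- representation_diff(tab, tab)
  expect_true(all(rows$diff[rows$f_ref > 0] == 0))
  expect_equal(attr(rows, "sigma"), 0)
  expect_false(any(rows$is_outlier))
})

test_that("representation_diff computes the relative rate difference", {
  ref <- kt(c(A = 10L, C = 10L, G = 20L, T = 0L), k = 1)
  reads <- kt(c(A = 20L, C = 2L, G = 18L, T = 0L), k = 1)
  rows <- representation_diff(ref, reads)
  expect_equal(rows$diff[rows$kmer == "A"], 1.0)   # frequency doubled
  expect_true(is.na(rows$diff[rows$kmer == "T"]))  # absent from reference
  expect_true(rows$is_homopolymer[rows$kmer == "A"])
  expect_error(representation_diff(ref, kt(c(AA = 1L), k = 2)),
               class = "lrp_usage_error")
})

test_that("rank_represented filters homopolymers and breaks ties lexically", {
  rows <- data.frame(
    kmer = c("AAAAAA", "ACGTAC", "TTTTTT"),
    diff = c(0.5, 0.2, 0.4),
    is_homopolymer = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  expect_warning(
    top <- rank_represented(rows, n = 2, direction = "over",
                            exclude_homopolymers = TRUE),
    "only 1 available")
  expect_equal(top$kmer, "ACGTAC")

  under <- rank_represented(rows, n = 3, direction = "under")
  expect_equal(under$kmer, c("ACGTAC", "TTTTTT", "AAAAAA"))

  ties <- data.frame(kmer = c("TTAAAA", "AATTAA", "CCGGCC"),
                     diff = c(0.3, 0.3, 0.3),
                     is_homopolymer = FALSE, stringsAsFactors = FALSE)
  expect_equal(rank_represented(ties, 3, "over")$kmer,
               c("AATTAA", "CCGGCC", "TTAAAA"))
})

test_that("logo_matrix builds column-stochastic position frequencies", {
  m <- logo_matrix(c("AC", "AG"))
  expect_equal(m["A", 1], 1.0)
  expect_equal(m["C", 2], 0.5)
  expect_equal(m["G", 2], 0.5)
  expect_equal(unname(colSums(m)), c(1, 1))

  one <- logo_matrix("ACGT")
  expect_equal(unname(diag(one[, 1:4])), rep(1, 4))

  sym <- logo_matrix(c("AA", "CC", "GG", "TT"))
  expect_true(all(sym == 0.25))

  expect_error(logo_matrix(c("AC", "ACG")), class = "lrp_usage_error")
  expect_error(logo_matrix(character()), class = "lrp_usage_error")
})

test_that("frequency_change reports deltas and honors the tie rule", {
  raw <- data.frame(kmer = c("AA", "AC", "AG"), diff = c(0.2, 0.1, -0.1),
                    stringsAsFactors = FALSE)
  same <- frequency_change(raw, raw)
  expect_true(all(same$delta == 0))

  corr <- raw; corr$diff <- c(0, 0.1, -0.1)
  fc <- frequency_change(raw, corr)
  expect_equal(fc$delta[fc$kmer == "AA"], -0.2)

  corr2 <- raw; corr2$diff <- c(0.4, 0.3, -0.3)   # |delta| = .2, .2, .2
  top <- frequency_change(raw, corr2, top_n = 2)
  expect_equal(top$kmer, c("AA", "AC"))

  expect_error(frequency_change(raw, raw[c(2, 1, 3), ]),
               class = "lrp_usage_error")
})
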