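test_that("global alignment handles identity, gaps and derived oracle cases", {
  aln <- pairwise_global("ACGT", "ACGT")
  expect_equal(alignment_ncol(aln), 4L)
  expect_false(any(grepl("-", aln$aligned, fixed = TRUE)))

  # one gap column: 4 columns align 4 residues against 3
  aln2 <- pairwise_global("ACGT", "AGT")
  expect_equal(alignment_ncol(aln2), 4L)
  expect_equal(sum(strsplit(aln2$aligned[2], "")[[1]] == "-"), 1)
  expect_equal(attr(aln2, "score"),
               oracle_global_score("ACGT", "AGT", 1, 0, 10, 0.2))
  expect_error(pairwise_global("", "ACGT"), "empty")
})

test_that("degapping any alignment row returns the input sequence", {
  set.seed(31)
  for (k in 1:20) {
    a <- random_dna_str(sample(5:40, 1))
    b <- random_dna_str(sample(5:40, 1))
    aln <- pairwise_global(a, b)
    expect_equal(gsub("-", "", aln$aligned[1], fixed = TRUE), a)
    expect_equal(gsub("-", "", aln$aligned[2], fixed = TRUE), b)
  }
})

test_that("progressive MSA: identical, nested-prefix and diverged families", {
  same <- seq_tbl(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC"))
  aln <- progressive_msa(same)
  expect_equal(aln$id, same$id)  # row order preserved
  expect_false(any(grepl("-", aln$aligned, fixed = TRUE)))

  # non-periodic sequences so end-gap placement is strictly optimal
  full <- "ACGGTCATTGCA"
  pre <- seq_tbl(c(a = full, b = substr(full, 1, 8), c = substr(full, 1, 5)))
  aln2 <- progressive_msa(pre)
  # gaps only at the ends
  expect_true(all(grepl("^[ACGT]+-*$", aln2$aligned)))

  one <- progressive_msa(seq_tbl(c(x = "ACGT")))
  expect_equal(nrow(one), 1)

  # substitution-only family: true homologous columns stay aligned
  set.seed(41)
  root <- random_dna_str(300, gc = 0.45)
  fam <- seq_tbl(setNames(
    vapply(1:10, function(k) {
      evolve_seq(root, 0.10, phylo_model(), seed = 500 + k)
    }, character(1)),
    paste0("s", 1:10)))
  aln3 <- progressive_msa(fam)
  # no indels were simulated, so a perfect alignment is gap-free and
  # every homologous column pair is aligned
  expect_gte(mean(!grepl("-", strsplit(paste(aln3$aligned, collapse = ""),
                                       "")[[1]])), 0.95)
  expect_equal(alignment_ncol(aln3), 300L)
})

test_that("percent identity modes agree with hand counts", {
  aln <- helhunt:::new_alignment(c("r1", "r2"), c("ACGT", "ACGT"))
  expect_equal(percent_identity(aln, 1, 2), 100)
  aln2 <- helhunt:::new_alignment(c("r1", "r2"), c("ACGT", "ACGA"))
  expect_equal(percent_identity(aln2, 1, 2), 75)
  aln3 <- helhunt:::new_alignment(c("r1", "r2"), c("AC-GT", "ACAGT"))
  expect_equal(percent_identity(aln3, 1, 2, mode = "all_columns"), 80)
  expect_equal(percent_identity(aln3, 1, 2, mode = "ungapped_columns"), 100)
  # symmetry in both modes
  expect_equal(percent_identity(aln3, 2, 1, mode = "all_columns"),
               percent_identity(aln3, 1, 2, mode = "all_columns"))
  # zero denominator flags, does not crash
  aln4 <- helhunt:::new_alignment(c("r1", "r2"), c("A-", "-A"))
  expect_warning(v <- percent_identity(aln4, 1, 2,
                                       mode = "ungapped_columns"))
  expect_true(is.nan(v))
})

test_that("complete deletion removes gapped columns and is idempotent", {
  aln <- helhunt:::new_alignment(c("a", "b", "c"),
                                 c("ACGTACGTAC", "AC-TACGTAC",
                                   "ACGTACG-AC"))
  cd <- complete_deletion(aln)
  mat <- helhunt:::alignment_matrix(aln)
  expect_equal(alignment_ncol(cd), sum(colSums(mat == "-") == 0))
  expect_equal(alignment_ncol(cd), 8L)
  cd2 <- complete_deletion(cd)
  expect_equal(cd2$aligned, cd$aligned)
  gap_free <- helhunt:::new_alignment("x", "ACGT")
  expect_equal(complete_deletion(gap_free)$aligned, "ACGT")
  all_gap <- helhunt:::new_alignment(c("a", "b"), c("A-", "-A"))
  expect_warning(out <- complete_deletion(all_gap))
  expect_equal(alignment_ncol(out), 0L)
})

test_that("identity matrices are symmetric with a 100 diagonal", {
  seqs <- seq_tbl(c(a = "ACGTACGTACGTACGT", b = "ACGTACGAACGTACGT",
                    c = "ACGTACGTACGTACTT"))
  m <- identity_matrix(as_alignment(seqs))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(m >= 0 & m <= 100))
  # pairwise route agrees on ungapped equal-length sequences
  mp <- identity_matrix(seqs, method = "pairwise")
  expect_equal(unclass(m), unclass(mp))
  two <- identity_matrix(as_alignment(seqs[c(1, 1), ] |>
                                        dplyr::mutate(id = c("x", "y"))))
  expect_equal(unname(unclass(two)), matrix(100, 2, 2))
})

test_that("consensus sequence takes the column majority", {
  aln <- helhunt:::new_alignment(c("a", "b", "c"),
                                 c("ACGT-", "ACGTA", "ACTT-"))
  cons <- consensus_sequence(aln)
  expect_equal(cons$residues, "ACGT")
})
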