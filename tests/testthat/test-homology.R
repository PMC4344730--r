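test_that("exact and reverse-complement copies are found with 100% identity", {
  set.seed(1)
  host <- random_dna_str(400, gc = 0.4)
  q <- "ACGTTGCAACGGATCCTAGG"
  subj <- paste0(substr(host, 1, 150), q, substr(host, 151, 400))
  hits <- local_align(q, subj, score_floor = 20)
  expect_equal(hits$strand[1], "+")
  expect_equal(hits$identity_pct[1], 100)
  expect_equal(hits$score[1], 2 * nchar(q))
  expect_equal(hits$s_start[1], 151)
  expect_equal(hits$s_end[1], 150 + nchar(q))
  expect_equal(hits$coverage_class[1], "full_length")

  subj_rc <- paste0(substr(host, 1, 150), revcomp(q), substr(host, 151, 400))
  rhits <- local_align(q, subj_rc, score_floor = 20)
  expect_equal(rhits$strand[1], "-")
  expect_equal(rhits$identity_pct[1], 100)
  expect_equal(rhits$s_start[1], 151)
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("local and global scores match the enumeration oracles", {
  set.seed(101)
  sc <- scoring_scheme()
  for (case in 1:30) {
    a <- random_dna_str(sample(2:8, 1))
    b <- random_dna_str(sample(2:8, 1))
    # local (Smith-Waterman); the scanner searches both strands
    hits <- local_align(a, b, scoring = sc, score_floor = 0.5, max_hits = 1)
    got <- if (nrow(hits)) hits$score[1] else 0
    want <- max(oracle_local_score(a, b, sc$match, sc$mismatch,
                                   sc$gap_open, sc$gap_extend),
                oracle_local_score(a, revcomp(b), sc$match, sc$mismatch,
                                   sc$gap_open, sc$gap_extend))
    expect_equal(got, want, info = paste(a, b))
    # global, ClustalW-style parameters
    aln <- pairwise_global(a, b)
    expect_equal(attr(aln, "score"),
                 oracle_global_score(a, b, 1, 0, 10, 0.2),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("E-values follow the Karlin-Altschul closed form", {
  sc <- scoring_scheme(karlin_lambda = 1.37, karlin_K = 0.711)
  expect_equal(evalue(0, 10, 100, sc), 0.711 * 10 * 100)
  expect_equal(evalue(20, 10, 200, sc), 2 * evalue(20, 10, 100, sc))
  # independent numeric evaluation of the closed form
  expect_equal(evalue(40, 250, 1e6, sc),
               0.711 * 250 * 1e6 * exp(-1.37 * 40))
  # strictly decreasing in score
  s <- seq(0, 50, by = 5)
  expect_true(all(diff(evalue(s, 100, 1000, sc)) < 0))
})

test_that("retention filters apply identity, E-value and terminal rules", {
  base <- tibble::tibble(
    query_id = "q", subject_id = "s", strand = "+",
    q_start = 1L, q_end = 250L, s_start = 1L, s_end = 250L,
    score = 100, matches = 200L, columns = 250L,
    identity_pct = 80, evalue = 1e-8, query_length = 250L,
    coverage_class = "full_length")
  # identity 64.9%, excellent E-value, full length -> rejected
  h <- base; h$identity_pct <- 64.9
  expect_equal(nrow(filter_hits(h)), 0)
  # identity 80%, E-value 1e-3 -> rejected
  h <- base; h$evalue <- 1e-3
  expect_equal(nrow(filter_hits(h)), 0)
  # 52 bp at the query 5' end, identity 70%, E 1e-6 -> five_prime_partial
  h <- base
  h$q_start <- 1L; h$q_end <- 52L; h$identity_pct <- 70; h$evalue <- 1e-6
  out <- filter_hits(h)
  expect_equal(nrow(out), 1)
  expect_equal(out$coverage_class, "five_prime_partial")
  # same span but too short for the terminal rule
  h$q_end <- 40L
  expect_equal(nrow(filter_hits(h)), 0)
  expect_equal(nrow(filter_hits(h[0, ])), 0)
})

test_that("filter monotonicity: relaxing thresholds never drops a hit", {
  set.seed(3)
  tpl <- render_template(element_template(), seed = 21)
  host <- seq_tbl(c(g = random_dna_str(3000, gc = 0.4)))
  pl <- plant_elements(host, tpl$seq, 2, seed = 22)
  el_div <- evolve_seq(tpl$seq$residues[[1]], 0.15, phylo_model(), seed = 23)
  raw <- local_align(el_div, pl$genome$residues[[1]])
  strict <- filter_hits(raw, min_identity = 70, max_evalue = 1e-8)
  loose <- filter_hits(raw, min_identity = 60, max_evalue = 1e-4)
  key <- function(h) paste(h$s_start, h$s_end)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("scanning the reverse-complemented subject mirrors hits", {
  set.seed(9)
  tpl <- render_template(element_template(), seed = 31)
  host <- seq_tbl(c(g = random_dna_str(2000, gc = 0.4)))
  pl <- plant_elements(host, tpl$seq, 2, seed = 32)
  subj <- pl$genome$residues[[1]]
  n <- nchar(subj)
  fwd <- filter_hits(local_align(tpl$seq, subj))
  rev <- filter_hits(local_align(tpl$seq, revcomp(subj)))
  expect_equal(nrow(fwd), nrow(rev))
  fwd <- dplyr::arrange(fwd, s_start)
  rev <- dplyr::arrange(rev, dplyr::desc(s_end))
  expect_equal(fwd$s_start, n - rev$s_end + 1)
  expect_equal(fwd$s_end, n - rev$s_start + 1)
  expect_true(all(fwd$strand != rev$strand))
  expect_equal(fwd$score, rev$score)
})
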