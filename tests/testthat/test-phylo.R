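make_pair <- function(n_ts, n_tv, n_same) {
  # two rows with the requested transition / transversion counts
  a <- c(rep("A", n_ts), rep("A", n_tv), rep("C", n_same))
  b <- c(rep("G", n_ts), rep("T", n_tv), rep("C", n_same))
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

test_that("T3P distance: identity, K2P reduction, closed-form value", {
  m1 <- phylo_model(n_rate_categories = 1, gc_content = 0.5)
  expect_equal(t3p_distance("ACGTACGT", "ACGTACGT", m1), 0)

  # theta = 0.5 reduces T3P to K2P on the same P and Q
  pq <- make_pair(20, 10, 170)  # P = 0.1, Q = 0.05 over 200 sites
  P <- 0.1; Q <- 0.05
  k2p <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(t3p_distance(pq$a, pq$b, m1), k2p, tolerance = 1e-9)

  # closed-form T3P at theta = 0.4 (independent formula evaluation)
  m4 <- phylo_model(n_rate_categories = 1, gc_content = 0.4)
  h <- 2 * 0.4 * 0.6
  want <- -h * log(1 - P / h - Q) - (1 - h) / 2 * log(1 - 2 * Q)
  expect_equal(t3p_distance(pq$a, pq$b, m4), want, tolerance = 1e-9)

  # gamma-rates transform (shape 2.249)
  mg <- phylo_model(gamma_shape = 2.249, n_rate_categories = 4,
                    gc_content = 0.4)
  a <- 2.249
  want_g <- h * a * ((1 - P / h - Q)^(-1 / a) - 1) +
    (1 - h) / 2 * a * ((1 - 2 * Q)^(-1 / a) - 1)
  expect_equal(t3p_distance(pq$a, pq$b, mg), want_g, tolerance = 1e-9)

  # saturation flags as NA rather than crashing
  sat <- make_pair(100, 0, 0)
  expect_true(is.na(t3p_distance(sat$a, sat$b, m1)))
  expect_error(t3p_distance("", "", m1), "zero-length")
})

test_that("T3P matrix agrees with an independent T92 implementation", {
  set.seed(61)
  root <- random_dna_str(400, gc = 0.45)
  seqs <- seq_tbl(setNames(
    vapply(1:4, function(k) {
      evolve_seq(root, 0.25, phylo_model(n_rate_categories = 1),
                 seed = 600 + k)
    }, character(1)), paste0("t", 1:4)))
  aln <- as_alignment(seqs)
  d <- t3p_matrix(aln, phylo_model(n_rate_categories = 1))
  bin <- ape::as.DNAbin(helhunt:::alignment_matrix(aln) |>
                          tolower() |>
                          matrix(nrow = 4, dimnames = list(aln$id, NULL)))
  d_ref <- as.matrix(ape::dist.dna(bin, model = "T92"))
  expect_equal(unname(d), unname(d_ref[aln$id, aln$id]), tolerance = 1e-9)
})

test_that("NJ: 3-taxon closed form, additive recovery, NA handling, ties", {
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d3)
  tip_edge <- function(tr, tip) {
    tr$edge.length[tr$edge[, 2] == match(tip, tr$tip.label)]
  }
  expect_equal(tip_edge(tr, "a"), (2 + 3 - 4) / 2)
  expect_equal(tip_edge(tr, "b"), (2 + 4 - 3) / 2)
  expect_equal(tip_edge(tr, "c"), (3 + 4 - 2) / 2)

  set.seed(71)
  for (k in 1:20) {
    true <- ape::rtree(sample(5:12, 1))
    d <- stats::cophenetic(true)
    got <- nj_tree(d)
    expect_equal(robinson_foulds(true, got), 0)
    expect_equal(stats::cophenetic(got)[rownames(d), colnames(d)], d,
                 tolerance = 1e-6)
  }

  dna <- d3; dna["a", "b"] <- dna["b", "a"] <- NA
  expect_error(nj_tree(dna), "a~b")
  # all-equal distances resolve deterministically
  deq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(deq) <- 0
  t1 <- nj_tree(deq); t2 <- nj_tree(deq)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("pruning log-likelihood: degenerate case, oracle, re-rooting", {
  # two identical tips on zero-length branches: loglik = log(pi[state])
  tr2 <- ape::read.tree(text = "(t1:0,t2:0);")
  aln1 <- helhunt:::new_alignment(c("t1", "t2"), c("A", "A"))
  m <- phylo_model(gc_content = 0.4, n_rate_categories = 1)
  expect_equal(pruning_loglik(tr2, aln1, m), log(0.3), tolerance = 1e-9)

  # exhaustive ancestral-state enumeration oracle (full scale in the
  # acceptance suite)
  set.seed(81)
  for (k in 1:50) {
    ntaxa <- sample(4:5, 1)
    tr <- ape::unroot(ape::rtree(ntaxa))
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.6)
    aln <- helhunt:::new_alignment(
      tr$tip.label,
      vapply(seq_len(ntaxa), function(i) random_dna_str(6), character(1)))
    mm <- phylo_model(gamma_shape = sample(c(0.5, 2.249), 1),
                      n_rate_categories = sample(c(1L, 4L), 1),
                      gc_content = stats::runif(1, 0.3, 0.7),
                      kappa = stats::runif(1, 1, 4))
    expect_equal(pruning_loglik(tr, aln, mm), oracle_loglik(tr, aln, mm),
                 tolerance = 1e-6)
  }

  # invariance to the rooting of the unrooted tree (pulley principle)
  tr <- ape::unroot(ape::rtree(5))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.4)
  aln <- helhunt:::new_alignment(tr$tip.label,
                                 vapply(1:5, function(i) random_dna_str(20),
                                        character(1)))
  rerooted <- ape::unroot(ape::root(tr, outgroup = tr$tip.label[3],
                                    resolve.root = TRUE))
  expect_equal(pruning_loglik(tr, aln, m), pruning_loglik(rerooted, aln, m),
               tolerance = 1e-9)
})

test_that("NNI search equals exhaustive topology evaluation at 4 taxa", {
  set.seed(91)
  m <- phylo_model(gc_content = 0.5, n_rate_categories = 1)
  topos <- lapply(list(c("(a:.1,b:.1,(c:.1,d:.1):.1);"),
                       c("(a:.1,c:.1,(b:.1,d:.1):.1);"),
                       c("(a:.1,d:.1,(b:.1,c:.1):.1);")),
                  function(s) ape::read.tree(text = s))
  # signal favouring ((a,b),(c,d))
  aln <- helhunt:::new_alignment(
    c("a", "b", "c", "d"),
    c("AAAAAAGGGCCC", "AAAAAAGGGCCT", "TTTAAAGGGCCC", "TTTAAAGGGCCT"))
  lls <- vapply(topos, pruning_loglik, numeric(1), aln = aln, model = m)
  best <- which.max(lls)
  for (start in seq_along(topos)) {
    res <- nni_search(topos[[start]], aln, m)
    expect_equal(res$loglik, lls[best], tolerance = 1e-6)
  }
  # starting at the optimum: no improving move accepted
  res0 <- nni_search(topos[[best]], aln, m)
  expect_equal(res0$n_moves, 0)
})

test_that("bootstrap consensus: clade support, floor, determinism", {
  set.seed(95)
  base <- random_dna_str(60, gc = 0.5)
  ch <- strsplit(base, "")[[1]]
  alt <- ch
  flip <- c(A = "C", C = "A", G = "T", T = "G")  # transversions
  idx <- sample(60, 9)
  alt[idx] <- flip[alt[idx]]
  rows <- c(rep(paste(ch, collapse = ""), 3),
            rep(paste(alt, collapse = ""), 3))
  aln <- helhunt:::new_alignment(c("a1", "a2", "a3", "b1", "b2", "b3"), rows)
  m <- phylo_model(n_rate_categories = 1)
  cons <- bootstrap_consensus(aln, m, n_reps = 100, seed = 5)
  splits <- oracle_bipartitions(cons)
  expect_true(paste(sort(c("a1", "a2", "a3")), collapse = "|") %in% splits ||
                paste(sort(c("b1", "b2", "b3")), collapse = "|") %in% splits)
  sup <- suppressWarnings(as.numeric(cons$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup[sup > 0] >= 50))  # retained edges meet the floor
  expect_gte(max(sup), 99)
  cons2 <- bootstrap_consensus(aln, m, n_reps = 100, seed = 5)
  expect_equal(ape::write.tree(cons), ape::write.tree(cons2))
  expect_error(bootstrap_consensus(aln, m, n_reps = 5), "n_reps")
})

test_that("Robinson-Foulds matches the bipartition-set oracle", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  set.seed(97)
  for (k in 1:20) {
    n <- sample(5:10, 1)
    x <- ape::rtree(n); y <- ape::rtree(n)
    y$tip.label <- sample(x$tip.label)
    expect_equal(robinson_foulds(ape::unroot(x), ape::unroot(y)),
                 oracle_rf(ape::unroot(x), ape::unroot(y)))
  }
  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(robinson_foulds(t1, t3), "leaf")
})

test_that("NJ on simulated T3P data recovers the generating topology", {
  set.seed(123)
  m <- phylo_model(gamma_shape = 2.249, n_rate_categories = 4,
                   gc_content = 0.5)
  ok <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    true <- ape::unroot(ape::rtree(8))
    true$edge.length <- stats::runif(nrow(true$edge), 0.03, 0.12)
    root <- random_dna_str(500, gc = 0.5)
    tips <- helhunt:::evolve_along_tree(root, true, 1, m,
                                        seed = 7000 + r)$nodes
    aln <- helhunt:::new_alignment(true$tip.label,
                                   tips[seq_along(true$tip.label)])
    d <- t3p_matrix(aln, m)
    if (any(is.na(d))) next
    got <- nj_tree(d)
    if (robinson_foulds(true, got) == 0) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.9)
})
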