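test_that("template rendering is seed-deterministic with stated features", {
  tpl <- element_template(microsat_copies = 6)
  r1 <- render_template(tpl, seed = 4)
  r2 <- render_template(tpl, seed = 4)
  expect_identical(r1$seq$residues, r2$seq$residues)
  expect_equal(r1$seq$length, 300L)
  ms <- find_microsatellites(r1$seq)
  expect_true(any(ms$copies >= 6))
  expect_error(element_template(length = 60), "length")
})

test_that("planted copies sit between AT/TT dinucleotides without TSD", {
  set.seed(14)
  host <- seq_tbl(c(g = random_dna_str(4000, gc = 0.4)))
  el <- render_template(element_template(), seed = 15)$seq
  pl <- plant_elements(host, el, 10, seed = 16)
  expect_equal(nrow(pl$truth), 10)
  expect_true(all(pl$truth$site_dinucleotide %in% c("AT", "TT")))
  g <- pl$genome$residues[[1]]
  expect_equal(nchar(g), 4000 + 10 * el$length)
  for (k in seq_len(10)) {
    expect_equal(substr(g, pl$truth$start[k], pl$truth$end[k]),
                 el$residues[[1]])
    # the element splits the dinucleotide: A/T on the left, T on the right
    left <- substr(g, pl$truth$start[k] - 1, pl$truth$start[k] - 1)
    right <- substr(g, pl$truth$end[k] + 1, pl$truth$end[k] + 1)
    expect_equal(paste0(left, right), pl$truth$site_dinucleotide[k])
  }
  # removing every element by its coordinates reconstructs the host
  rem <- g
  ord <- order(pl$truth$start, decreasing = TRUE)
  for (k in ord) {
    rem <- paste0(substr(rem, 1, pl$truth$start[k] - 1),
                  substr(rem, pl$truth$end[k] + 1, nchar(rem)))
  }
  expect_identical(rem, host$residues[[1]])

  none <- plant_elements(host, el, 0)
  expect_identical(none$genome$residues, host$residues)
  tiny <- seq_tbl(c(t = "GGGGGG"))
  expect_error(plant_elements(tiny, el, 2), "eligible")
})

test_that("the substitution simulator matches T3P expectations", {
  m <- phylo_model(gamma_shape = 2.249, n_rate_categories = 4,
                   gc_content = 0.5, kappa = 2)
  base <- random_dna_str(5000, gc = 0.5)
  expect_identical(evolve_seq(base, 0, m, seed = 1), base)

  exp_div <- expected_divergence(m, 0.1)
  n_rep <- 40
  mism <- ts_frac <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(4000 + r)
    b <- random_dna_str(5000, gc = 0.5)
    e <- evolve_seq(b, 0.1, m, seed = 4100 + r)
    a <- strsplit(b, "")[[1]]; z <- strsplit(e, "")[[1]]
    ch <- a != z
    mism[r] <- mean(ch)
    pur <- c("A", "G")
    ts <- ch & ((a %in% pur) == (z %in% pur))
    ts_frac[r] <- sum(ts) / sum(ch)
  }
  se <- stats::sd(mism) / sqrt(n_rep)
  expect_lt(abs(mean(mism) - exp_div$mismatch), 3 * se)
  want_ts <- exp_div$transitions / exp_div$mismatch
  expect_lt(abs(mean(ts_frac) - want_ts), 0.03)
})

test_that("scenario simulation: determinism, null and HTT behaviour", {
  tree <- "((a:0.1,b:0.1):0.1,(c:0.1,(d:0.05,e:0.05):0.05):0.1,f:0.2);"
  sp <- scenario_spec(tree, seed = 50)
  scn <- simulate_scenario(sp)
  scn2 <- simulate_scenario(sp)
  expect_identical(scn$genomes$residues, scn2$genomes$residues)
  expect_identical(scn$te$residues, scn2$te$residues)
  expect_equal(nrow(scn$truth), 6 * sp$copies_per_genome)

  # vertical-only null with equal clocks: deltas are small
  small <- 0
  for (r in 1:20) {
    s <- simulate_scenario(scenario_spec(tree, seed = 6000 + r))
    im <- scenario_identity_matrices(s)
    cmp <- compare_matrices(im$te, im$host)
    small <- small + mean(abs(cmp$delta) < 6)
  }
  expect_gte(small / 20, 0.9)

  # a recent transfer between non-sister tips dominates the deltas
  top <- 0
  for (r in 1:25) {
    s <- simulate_scenario(scenario_spec(
      tree, htt_events = tibble::tibble(donor = "a", recipient = "d",
                                        time = 0.9),
      seed = 6500 + r))
    im <- scenario_identity_matrices(s)
    cmp <- compare_matrices(im$te, im$host)
    if (setequal(c(cmp$species_a[1], cmp$species_b[1]), c("a", "d"))) {
      top <- top + 1
    }
  }
  expect_gte(top / 25, 0.9)
  expect_error(scenario_spec(tree, htt_events = tibble::tibble(
    donor = "a", recipient = "nope", time = 0.5)), "nope")
})

test_that("scenario files round-trip through the serialisers", {
  dir <- withr::local_tempdir()
  scn <- simulate_scenario(scenario_spec(
    "((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);", seed = 3))
  paths <- write_scenario(scn, dir)
  expect_true(all(file.exists(paths)))
  g <- read_fasta(paths[["genomes"]])
  expect_equal(sort(g$id), sort(scn$species))
  expect_identical(g$residues[match(scn$genomes$id, g$id)],
                   scn$genomes$residues)
  truth <- read_annotations(paths[["truth"]], format = "bed")
  expect_equal(sort(truth$start), sort(scn$truth$start))
  expect_equal(sort(truth$end), sort(scn$truth$end))
  tr <- ape::read.tree(paths[["tree"]])
  expect_equal(sort(tr$tip.label), sort(scn$species))
})
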