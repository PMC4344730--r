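test_that("termini are called with motifs, flanks and the A/T site rule", {
  el <- paste0("TCCAG", strrep("G", 12), "ATTTACCGGATGCAAGG", "CTAG")
  t <- find_termini(el, context_left = "GGCA", context_right = "TTGG",
                    end_window = 10)
  expect_equal(sort(t$kind), c("five_prime", "three_prime"))
  expect_equal(t$motif[t$kind == "five_prime"], "TCC")
  expect_equal(t$position[t$kind == "five_prime"], 1L)
  expect_equal(t$motif[t$kind == "three_prime"], "CTAG")
  expect_true(all(t$matches_canonical))  # flanks ...A | el | T...

  # non-A/T flank breaks the canonical site rule but not the call
  t2 <- find_termini(el, context_left = "GGCC", context_right = "GGGG",
                     end_window = 10)
  expect_false(any(t2$matches_canonical))

  # no termini at all
  expect_equal(nrow(find_termini(strrep("G", 40), end_window = 10)), 0)

  # CTGG is a valid CTRR (R = purine)
  el3 <- paste0("TC", strrep("A", 20), "CTGG")
  t3 <- find_termini(el3, end_window = 8)
  expect_equal(t3$motif[t3$kind == "three_prime"], "CTGG")

  # missing context: flanking fields absent, not an error
  t4 <- find_termini(el, end_window = 10)
  expect_true(all(is.na(t4$flanking_dinucleotide)))
})

test_that("hairpin free energy equals hand-summed stacks plus loop penalty", {
  hp <- fold_hairpin("GGGGAAAACCCC", dg_ceiling = Inf)
  expect_equal(hp$arm_len, 4L)
  expect_equal(hp$loop_len, 4L)
  # three GG stacks plus the tetraloop penalty (3.5 + 0.35)
  expect_equal(hp$dg, 3 * (-1.84) + 3.5 + 0.35)
  # default reporting ceiling (-3) hides this weak structure
  expect_equal(nrow(fold_hairpin("GGGGAAAACCCC")), 0)
  # no complementary arms -> nothing
  expect_equal(nrow(fold_hairpin(strrep("A", 20), dg_ceiling = Inf)), 0)
})

test_that("hairpin folder matches the enumeration oracle on random windows", {
  set.seed(202)
  n_cases <- 120
  for (k in seq_len(n_cases)) {
    w <- random_dna_str(sample(12:30, 1), gc = runif(1, 0.3, 0.7))
    got <- fold_hairpin(w, dg_ceiling = Inf)
    want <- oracle_hairpin(w)
    if (is.na(want)) {
      expect_equal(nrow(got), 0, info = w)
    } else {
      expect_equal(got$dg, want, tolerance = 1e-9, info = w)
    }
  }
})

test_that("a mismatch in the stem raises the free energy", {
  stem <- "GCGGCC"
  perfect <- paste0(stem, "TTTT", revcomp(stem))
  broken <- paste0(stem, "TTTT", sub("^(..).", "\\1T", revcomp(stem)))
  dg_p <- fold_hairpin(perfect, dg_ceiling = Inf)$dg
  dg_b <- fold_hairpin(broken, dg_ceiling = Inf)$dg
  expect_lt(dg_p, dg_b)
  expect_equal(dg_p, oracle_hairpin(perfect))
  expect_equal(dg_b, oracle_hairpin(broken))
})

test_that("hairpin energies and IR runs mirror under reverse complement", {
  set.seed(11)
  for (k in 1:10) {
    w <- paste0(random_dna_str(10), "GCCGGC", "TTAT", revcomp("GCCGGC"),
                random_dna_str(10))
    a <- fold_hairpin(w, dg_ceiling = Inf)
    b <- fold_hairpin(revcomp(w), dg_ceiling = Inf)
    expect_equal(a$dg, b$dg)
    expect_equal(a$left_start, nchar(w) - b$right_end + 1)
  }
})

test_that("inverted repeats are found in their windows", {
  arm <- "ATTATAATTA"  # A/T-only arm on an all-C background never
  bg <- function(n) strrep("C", n)
  el <- paste0(bg(4), arm, bg(15), revcomp(arm), bg(21))
  ir <- find_inverted_repeats(el, min_arm = 10, max_mismatch = 0)
  expect_true("five_prime_IR" %in% ir$kind)
  row <- ir[ir$kind == "five_prime_IR", ][1, ]
  expect_equal(row$a_start, 5L)
  expect_equal(row$a_end, 14L)
  expect_equal(row$b_start, 30L)
  expect_equal(row$b_end, 39L)

  sirarm <- "TTAATTAATTAA"
  el2 <- paste0(bg(19), sirarm, bg(250 - 19 - 12 - 60), revcomp(sirarm),
                bg(48))
  ir2 <- find_inverted_repeats(el2, min_arm = 12, max_mismatch = 0)
  expect_true("SIR" %in% ir2$kind)
  srow <- ir2[ir2$kind == "SIR", ][1, ]
  expect_equal(srow$a_start, 20L)
  expect_equal(srow$b_end, 250L - 48L)

  # random 250-mer, exact 12 bp arms: expected count ~ 0.25^12 * pairs
  set.seed(77)
  rnd <- random_dna_str(250)
  expect_equal(nrow(find_inverted_repeats(rnd, min_arm = 12,
                                          max_mismatch = 0)), 0)
  expect_error(find_inverted_repeats(rnd, min_arm = 3), "min_arm")
})

test_that("microsatellite arrays: units, rotations, merging, thresholds", {
  m <- find_microsatellites("CTGTCTGTCTGTCTGT")
  expect_equal(m$unit, "CTGT")
  expect_equal(m$copies, 4)
  m2 <- find_microsatellites("GTTTGTTTGTTT")
  expect_equal(m2$unit, "GTTT")
  expect_equal(m2$copies, 3)
  expect_equal(nrow(find_microsatellites("CTGTCTGA")), 0)
  # rotation-equivalent phase and partial final unit
  m3 <- find_microsatellites(paste0("AA", "TGTC", "TGTC", "TGTC", "TG", "AA"),
                             units = "CTGT")
  expect_equal(nrow(m3), 1)
  expect_equal(m3$copies, 14 / 4)
  expect_equal(m3$end - m3$start + 1L, floor(m3$copies * 4))
  # merged arrays never overlap
  set.seed(5)
  s <- paste0(random_dna_str(30), strrep("CTGT", 5), random_dna_str(10),
              strrep("GTTT", 4), random_dna_str(30))
  arr <- find_microsatellites(s)
  if (nrow(arr) > 1) {
    arr <- dplyr::arrange(arr, start)
    expect_true(all(arr$start[-1] > arr$end[-nrow(arr)]))
  }
  expect_true(all(arr$copies * 4 <= (arr$end - arr$start + 1) + 3))
})

test_that("tier classification follows the feature logic", {
  t2 <- tibble::tibble(kind = c("five_prime", "three_prime"))
  t1 <- t2[2, ]
  t0 <- t2[0, ]
  hp <- tibble::tibble(dg = -8)
  no_hp <- hp[0, ]
  sir <- tibble::tibble(kind = "SIR")
  no_ir <- sir[0, ]
  expect_equal(classify_element(t2, hp, sir), "full")
  expect_equal(classify_element(t1, hp, no_ir), "partial")
  expect_equal(classify_element(t2, no_hp, no_ir), "partial")
  expect_equal(classify_element(t0, hp, no_ir), "structural_only")
  expect_equal(classify_element(t0, no_hp, sir), "structural_only")
  expect_equal(classify_element(t0, no_hp, no_ir), "rejected")
})

test_that("a rendered template annotates at tier full with all features", {
  for (seed in c(1, 17, 99)) {
    tpl <- render_template(element_template(microsat_copies = 6),
                           seed = seed)
    an <- annotate_element(tpl$seq, context_left = "CCA",
                           context_right = "TCC")
    expect_equal(an$tier, "full")
    expect_equal(nrow(an$termini), 2)
    expect_true(nrow(an$hairpin) == 1 && an$hairpin$dg < -3)
    expect_true("five_prime_IR" %in% an$irs$kind)
    expect_true("SIR" %in% an$irs$kind)
    expect_true(any(an$microsatellites$copies >= 6))
    feats <- annotation_features(an)
    expect_true(all(c("helitron", "terminus_5p", "terminus_3p", "hairpin",
                      "inverted_repeat", "microsatellite") %in% feats$type))
  }
})
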