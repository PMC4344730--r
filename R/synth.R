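# Synthetic genomes with planted elements and known ground truth:
# element templates rendered with all diagnostic features, insertion
# between AT/TT dinucleotides without target-site duplication, a T3P
# substitution simulator, and vertical/HTT inheritance scenarios along a
# species tree.

# deterministic child-seed derivation from one global seed
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483647)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Synthetic Helitron element template
#'
#' Describes a renderable non-autonomous element (~250-340 bp) with
#' 5'-TC(C) and 3'-CTRR termini, a 5'-IR, a SIR arm pair bridging the
#' subterminal windows, a (CTGT)n-style microsatellite and a GC-rich 3'
#' stem-loop.
#'
#' @param length total element length in bases.
#' @param terminus_5p `"TC"` or `"TCC"`.
#' @param terminus_3p a CTRR choice (CTAA/CTAG/CTGA/CTGG).
#' @param hairpin_arm,hairpin_loop stem pairs and loop length of the 3'
#'   hairpin.
#' @param ir_arm 5'-IR arm length.
#' @param sir_arm SIR arm length.
#' @param microsat_unit,microsat_copies tandem-repeat unit and copy
#'   number.
#' @param gc background GC proportion of filler sequence.
#' @return an `element_template` list.
#' @export
element_template <- function(length = 300, terminus_5p = "TCC",
                             terminus_3p = "CTAG", hairpin_arm = 10,
                             hairpin_loop = 4, ir_arm = 10, sir_arm = 12,
                             microsat_unit = "CTGT", microsat_copies = 5,
                             gc = 0.5) {
  stopifnot(terminus_5p %in% c("TC", "TCC"),
            grepl("^CT[AG][AG]$", terminus_3p),
            hairpin_arm >= 4, ir_arm >= 4, sir_arm >= 4,
            microsat_copies >= 1)
  t <- structure(list(length = length, terminus_5p = terminus_5p,
                      terminus_3p = terminus_3p, hairpin_arm = hairpin_arm,
                      hairpin_loop = hairpin_loop, ir_arm = ir_arm,
                      sir_arm = sir_arm, microsat_unit = microsat_unit,
                      microsat_copies = microsat_copies, gc = gc),
                 class = "element_template")
  used <- nchar(terminus_5p) + 2 * ir_arm + 4 + sir_arm +
    nchar(microsat_unit) * microsat_copies + sir_arm +
    2 * hairpin_arm + hairpin_loop + nchar(terminus_3p) + 20
  if (used > length) {
    abort(sprintf("features need ~%d bp but template length is %d",
                  used, length))
  }
  t
}

stamp <- function(chars, at, what) {
  w <- strsplit(what, "", fixed = TRUE)[[1]]
  chars[at:(at + length(w) - 1)] <- w
  chars
}

#' Render an element template to a concrete sequence
#'
#' The rendered sequence carries every specified feature at recorded
#' coordinates and, by construction, annotates at tier `full` at zero
#' divergence.
#'
#' @param template an [element_template()].
#' @param seed integer seed; the same seed yields an identical
#'   sequence.
#' @return list with `seq` (1-row sequence tibble) and `features`
#'   (tibble of `type`, `start`, `end`).
#' @export
render_template <- function(template, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- template$length
  # random filler, avoiding stray CTRR near the 3' end by construction:
  # the terminal CTRR is always the rightmost because it ends at L
  chars <- strsplit(random_dna(L, template$gc), "", fixed = TRUE)[[1]]
  feats <- list()
  pos <- 1L
  t5 <- template$terminus_5p
  chars <- stamp(chars, pos, t5)
  feats$t5 <- tibble(type = "terminus_5p", start = pos,
                     end = pos + nchar(t5) - 1L)
  pos <- pos + nchar(t5) + 1L
  # 5'-IR: arm A, 4 nt spacer, arm B (reverse complement)
  arm <- random_dna(template$ir_arm, 0.5)
  chars <- stamp(chars, pos, arm)
  a_start <- pos
  pos <- pos + template$ir_arm + 4L
  chars <- stamp(chars, pos, revcomp(arm))
  feats$ir <- tibble(type = "five_prime_IR", start = a_start,
                     end = pos + template$ir_arm - 1L)
  pos <- pos + template$ir_arm + 3L
  # SIR arm A (5' subterminal)
  sir <- random_dna(template$sir_arm, 0.5)
  chars <- stamp(chars, pos, sir)
  sir_a <- c(pos, pos + template$sir_arm - 1L)
  pos <- pos + template$sir_arm + 3L
  # microsatellite
  ms <- strrep(template$microsat_unit, template$microsat_copies)
  chars <- stamp(chars, pos, ms)
  feats$ms <- tibble(type = "microsatellite", start = pos,
                     end = pos + nchar(ms) - 1L)
  # 3' side, laid out backwards from the end
  t3 <- template$terminus_3p
  chars <- stamp(chars, L - 3L, t3)
  feats$t3 <- tibble(type = "terminus_3p", start = L - 3L, end = L)
  hp_len <- 2L * template$hairpin_arm + template$hairpin_loop
  hp_start <- L - 4L - hp_len + 1L
  hp_arm <- paste(sample(c("G", "C"), template$hairpin_arm, replace = TRUE),
                  collapse = "")
  loop <- random_dna(template$hairpin_loop, 0)  # A/T loop never pairs arms
  chars <- stamp(chars, hp_start, paste0(hp_arm, loop, revcomp(hp_arm)))
  feats$hp <- tibble(type = "hairpin", start = hp_start,
                     end = hp_start + hp_len - 1L)
  # SIR arm B (3' subterminal), upstream of the hairpin
  sirb_start <- hp_start - template$sir_arm - 2L
  chars <- stamp(chars, sirb_start, revcomp(sir))
  feats$sir <- tibble(type = "SIR", start = sir_a[1],
                      end = sirb_start + template$sir_arm - 1L)
  # scrub accidental TC upstream of position 1 cannot occur; scrub any
  # accidental CTRR whose final base falls after the hairpin but before
  # the terminus (there is no room: terminus is flush with the end)
  seqs <- seq_tbl(setNames(paste(chars, collapse = ""), "element"))
  list(seq = seqs, features = bind_rows(feats))
}

#' Plant element copies into a host sequence
#'
#' Insertion sites are uniformly chosen AT or TT dinucleotides; the
#' element is placed between the two bases of the dinucleotide, so the
#' immediate flanks read `...A | element | T...` or `...T | element |
#' T...`. No host bases are duplicated (no target-site duplication):
#' removing an element by its truth coordinates reconstructs the
#' original host exactly.
#'
#' @param host 1-row sequence tibble or DNA string.
#' @param element 1-row sequence tibble or DNA string.
#' @param n number of copies to insert.
#' @param seed integer seed.
#' @return list with `genome` (1-row sequence tibble) and `truth`
#'   (tibble of 1-based element coordinates in the new genome,
#'   `site_dinucleotide`, and the original host site position).
#' @export
plant_elements <- function(host, element, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hs <- seq_string(host)
  es <- seq_string(element)
  gid <- if (is.data.frame(host)) host$id[[1]] else "genome"
  truth0 <- tibble(genome_id = character(), start = integer(),
                   end = integer(), site_pos = integer(),
                   site_dinucleotide = character(), strand = character())
  if (n == 0) {
    return(list(genome = seq_tbl(setNames(hs, gid)), truth = truth0))
  }
  # eligible sites: positions p with host[p:p+1] in {AT, TT}
  ch <- strsplit(hs, "", fixed = TRUE)[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  sites <- which(di %in% c("AT", "TT"))
  if (length(sites) < n) {
    abort(sprintf("only %d eligible AT/TT sites for %d insertions",
                  length(sites), n))
  }
  pick <- sort(sample(sites, n))
  el <- nchar(es)
  pieces <- character(0)
  prev <- 1L
  for (p in pick) {
    pieces <- c(pieces, substr(hs, prev, p), es)
    prev <- p + 1L
  }
  pieces <- c(pieces, substr(hs, prev, nchar(hs)))
  genome <- paste(pieces, collapse = "")
  truth <- tibble(
    genome_id = gid,
    start = pick + (seq_len(n) - 1L) * el + 1L,
    end = pick + seq_len(n) * el,
    site_pos = pick,
    site_dinucleotide = di[pick],
    strand = "+"
  )
  list(genome = seq_tbl(setNames(genome, gid)), truth = truth)
}

#' Evolve a sequence under the T3P substitution process
#'
#' Applies per-site substitutions drawn from the T3P transition
#' probabilities at the given expected branch length (substitutions per
#' site), with optional discrete-gamma rate variation. Ambiguity codes
#' are left untouched.
#'
#' @param seq 1-row sequence tibble or DNA string.
#' @param divergence expected substitutions/site (>= 0).
#' @param model a [phylo_model()] (`gc_content = NULL` uses the
#'   sequence's own GC).
#' @param seed integer seed.
#' @param site_rates optional fixed per-site rate multipliers (recycled);
#'   when `NULL` and the model has > 1 rate category, each site draws a
#'   gamma category.
#' @return the evolved sequence in the same representation (tibble in,
#'   tibble out).
#' @export
evolve_seq <- function(seq, divergence, model = phylo_model(), seed = NULL,
                       site_rates = NULL) {
  stopifnot(divergence >= 0)
  if (!is.null(seed)) set.seed(seed)
  s <- seq_string(seq)
  if (divergence == 0) return(if (is.data.frame(seq)) seq else s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  idx <- match(ch, bases)
  known <- !is.na(idx)
  if (is.null(model$gc_content)) {
    model$gc_content <- max(min(mean(ch[known] %in% c("C", "G")), 0.95), 0.05)
  }
  n <- length(ch)
  rates <- if (!is.null(site_rates)) {
    rep_len(site_rates, n)
  } else if (model$n_rate_categories > 1) {
    cats <- gamma_category_rates(model$gamma_shape, model$n_rate_categories)
    sample(cats, n, replace = TRUE)
  } else {
    rep(1, n)
  }
  out <- ch
  for (r in unique(rates)) {
    P <- t3p_pmatrix(model, divergence * r)
    sel <- which(rates == r & known)
    if (!length(sel)) next
    u <- runif(length(sel))
    cum <- t(apply(P, 1, cumsum))
    pick <- max.col(cum[idx[sel], , drop = FALSE] >= u, ties.method = "first")
    out[sel] <- bases[pick]
  }
  res <- paste(out, collapse = "")
  if (is.data.frame(seq)) {
    seq$residues <- res
    seq
  } else {
    res
  }
}

#' Expected observed divergence under the T3P process
#'
#' Closed-form expected mismatch proportion (P + Q) after evolving for
#' branch length `t`, from the model's transition probability matrix;
#' used to check the simulator against theory.
#'
#' @param model a [phylo_model()] with `gc_content` set.
#' @param t branch length in substitutions/site.
#' @return list with `mismatch`, `transitions` (P) and `transversions`
#'   (Q) expected proportions, gamma-averaged over rate categories.
#' @export
expected_divergence <- function(model, t) {
  rates <- gamma_category_rates(model$gamma_shape, model$n_rate_categories)
  pi <- t3p_rate_matrix(model)$pi
  agg <- c(mismatch = 0, P = 0, Q = 0)
  purine <- c(TRUE, FALSE, TRUE, FALSE)  # A,C,G,T
  for (r in rates) {
    Pm <- t3p_pmatrix(model, t * r)
    mism <- 1 - sum(pi * diag(Pm))
    ts <- pi["A"] * Pm["A", "G"] + pi["G"] * Pm["G", "A"] +
      pi["C"] * Pm["C", "T"] + pi["T"] * Pm["T", "C"]
    agg <- agg + c(mism, ts, mism - ts) / length(rates)
  }
  list(mismatch = unname(agg[1]), transitions = unname(agg[2]),
       transversions = unname(agg[3]))
}

#' Scenario specification for inheritance simulations
#'
#' @param species_tree a `phylo` tree with branch lengths, or a newick
#'   string; tip labels are the species. A star-like tree models
#'   exchangeable lineages.
#' @param te_clock,host_clock substitutions/site per unit branch
#'   length for the element and the host marker.
#' @param htt_events tibble with `donor`, `recipient`, `time` (fraction
#'   of the root-to-tip height at which the transferred copy branches
#'   off the donor lineage; 1 = at the tips).
#' @param copies_per_genome planted element copies per species genome.
#' @param te_template an [element_template()].
#' @param marker_length host-marker gene length in bp.
#' @param genome_length background genome length in bp.
#' @param gc background genome GC proportion.
#' @param model a [phylo_model()] for the substitution process.
#' @param seed integer master seed; all child seeds derive from it.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(species_tree, te_clock = 1, host_clock = 1,
                          htt_events = NULL, copies_per_genome = 3,
                          te_template = element_template(),
                          marker_length = 500, genome_length = 5000,
                          gc = 0.4, model = phylo_model(), seed = 1) {
  if (is.character(species_tree)) {
    species_tree <- ape::read.tree(text = species_tree)
  }
  stopifnot(inherits(species_tree, "phylo"),
            !is.null(species_tree$edge.length),
            te_clock >= 0, host_clock >= 0)
  if (is.null(htt_events)) {
    htt_events <- tibble(donor = character(), recipient = character(),
                         time = numeric())
  }
  bad <- setdiff(c(htt_events$donor, htt_events$recipient),
                 species_tree$tip.label)
  if (length(bad)) {
    abort(sprintf("HTT lineages not in tree: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(list(species_tree = species_tree, te_clock = te_clock,
                 host_clock = host_clock, htt_events = htt_events,
                 copies_per_genome = copies_per_genome,
                 te_template = te_template, marker_length = marker_length,
                 genome_length = genome_length, gc = gc, model = model,
                 seed = seed),
            class = "scenario_spec")
}

# Evolve a root sequence down every branch of the tree; returns node
# sequences indexed by node number. `breaks` (optional) is a tibble with
# `edge` (edge index), `depth` (absolute depth of the breakpoint on that
# edge) and `id`: the edge is then simulated in segments so the returned
# `mids` sequences lie on the realised lineage at those depths.
evolve_along_tree <- function(root_seq, tree, clock, model, seed,
                              breaks = NULL) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  seqs <- character(max(edge))
  mids <- list()
  root <- ntip + 1L
  seqs[root] <- root_seq
  depth <- node_depths(tree)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(ord))) {
    parent <- ord[k, 1]; child <- ord[k, 2]
    e <- which(edge[, 1] == parent & edge[, 2] == child)
    br <- if (is.null(breaks)) NULL else breaks[breaks$edge == e, , drop = FALSE]
    if (is.null(br) || nrow(br) == 0) {
      seqs[child] <- evolve_seq(seqs[parent],
                                tree$edge.length[e] * clock, model,
                                seed = child_seed(seed, e))
    } else {
      br <- br[order(br$depth), , drop = FALSE]
      cur <- seqs[parent]
      at <- depth[parent]
      for (b in seq_len(nrow(br))) {
        cur <- evolve_seq(cur, (br$depth[b] - at) * clock, model,
                          seed = child_seed(seed, e * 101L + b))
        mids[[br$id[b]]] <- cur
        at <- br$depth[b]
      }
      seqs[child] <- evolve_seq(cur, (depth[child] - at) * clock, model,
                                seed = child_seed(seed, e))
    }
  }
  list(nodes = seqs, mids = mids)
}

node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  depth <- numeric(max(tree$edge))
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(ord))) {
    e <- which(tree$edge[, 1] == ord[k, 1] & tree$edge[, 2] == ord[k, 2])
    depth[ord[k, 2]] <- depth[ord[k, 1]] + tree$edge.length[e]
  }
  depth
}

#' Simulate a vertical / horizontal inheritance scenario
#'
#' The element template and a random host-marker gene are evolved along
#' the species tree at their clocks. Each HTT event takes the donor
#' lineage's realised sequence at the event time (the last ancestral
#' node before the event, evolved forward for the remaining partial
#' branch) and replaces the recipient's element lineage with it,
#' evolved to the present. Per-species genomes carry
#' `copies_per_genome` planted copies of the species' element at AT/TT
#' sites. Everything derives from the scenario seed.
#'
#' @param spec a [scenario_spec()].
#' @return an `htt_scenario` list: `species`, `tree`, `te` (per-species
#'   element tibble), `marker`, `genomes`, `truth` (planted-copy
#'   coordinates), `events`, `template` (the rendered root element and
#'   its features).
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  tree <- spec$species_tree
  ntip <- length(tree$tip.label)
  rendered <- render_template(spec$te_template, seed = child_seed(spec$seed, 1))
  root_te <- rendered$seq$residues[[1]]
  set.seed(child_seed(spec$seed, 2))
  root_marker <- random_dna(spec$marker_length, 0.5)
  depth <- node_depths(tree)
  height <- max(depth[seq_len(ntip)])
  ev <- spec$htt_events
  # breakpoints on the donor lineage: the transferred copy branches off
  # the donor's realised sequence at the event depth
  breaks <- NULL
  if (nrow(ev)) {
    breaks <- purrr::map_dfr(seq_len(nrow(ev)), function(k) {
      t_ev <- ev$time[k] * height
      donor_tip <- match(ev$donor[k], tree$tip.label)
      path <- ape::nodepath(tree, from = ntip + 1L, to = donor_tip)
      for (s in seq_len(length(path) - 1)) {
        e <- which(tree$edge[, 1] == path[s] & tree$edge[, 2] == path[s + 1])
        if (depth[path[s]] <= t_ev + 1e-12 &&
            t_ev <= depth[path[s + 1]] + 1e-12) {
          return(tibble(edge = e, depth = t_ev, id = paste0("ev", k)))
        }
      }
      abort(sprintf("event time %.3f not on the donor lineage", ev$time[k]))
    })
  }
  te_evo <- evolve_along_tree(root_te, tree, spec$te_clock, spec$model,
                              child_seed(spec$seed, 3), breaks = breaks)
  te_nodes <- te_evo$nodes
  marker_nodes <- evolve_along_tree(root_marker, tree, spec$host_clock,
                                    spec$model,
                                    child_seed(spec$seed, 4))$nodes
  te_tips <- setNames(te_nodes[seq_len(ntip)], tree$tip.label)
  htt_flag <- setNames(rep(FALSE, ntip), tree$tip.label)
  for (k in seq_len(nrow(ev))) {
    t_ev <- ev$time[k] * height
    transferred <- evolve_seq(te_evo$mids[[paste0("ev", k)]],
                              (height - t_ev) * spec$te_clock,
                              spec$model,
                              seed = child_seed(spec$seed, 200 + k))
    te_tips[ev$recipient[k]] <- transferred
    htt_flag[ev$recipient[k]] <- TRUE
  }
  genomes <- list()
  truth <- list()
  for (i in seq_len(ntip)) {
    sp <- tree$tip.label[i]
    set.seed(child_seed(spec$seed, 300 + i))
    bg <- seq_tbl(setNames(random_dna(spec$genome_length, spec$gc), sp))
    pl <- plant_elements(bg, te_tips[[sp]], spec$copies_per_genome,
                         seed = child_seed(spec$seed, 400 + i))
    genomes[[sp]] <- pl$genome
    if (nrow(pl$truth)) {
      pl$truth$source_lineage <- sp
      pl$truth$divergence_applied <- depth[i] * spec$te_clock
      pl$truth$htt_event <- htt_flag[[sp]]
      truth[[sp]] <- pl$truth
    }
  }
  structure(list(
    species = tree$tip.label,
    tree = tree,
    te = seq_tbl(te_tips),
    marker = seq_tbl(setNames(marker_nodes[seq_len(ntip)], tree$tip.label)),
    genomes = bind_rows(genomes),
    truth = if (length(truth)) bind_rows(truth) else
      tibble(genome_id = character(), start = integer(), end = integer()),
    events = ev,
    template = rendered,
    spec = spec
  ), class = "htt_scenario")
}

#' Identity matrices of a simulated scenario
#'
#' @param scn an `htt_scenario`.
#' @param mode identity mode, see [percent_identity()].
#' @return list with `te` and `host` `identity_matrix` objects.
#' @export
scenario_identity_matrices <- function(scn, mode = "all_columns") {
  list(te = identity_matrix(as_alignment(scn$te), mode = mode),
       host = identity_matrix(as_alignment(scn$marker), mode = mode))
}

#' Write a simulated scenario to files
#'
#' FASTA for genomes/elements/markers, BED truth, newick species tree
#' and a TSV event log.
#'
#' @param scn an `htt_scenario`.
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genomes = file.path(dir, "genomes.fasta"),
    te = file.path(dir, "te.fasta"),
    marker = file.path(dir, "marker.fasta"),
    truth = file.path(dir, "truth.bed"),
    tree = file.path(dir, "species_tree.nwk"),
    events = file.path(dir, "events.tsv")
  )
  write_fasta(scn$genomes, paths["genomes"])
  write_fasta(scn$te, paths["te"])
  write_fasta(scn$marker, paths["marker"])
  truth <- scn$truth
  if (nrow(truth)) {
    truth$seq_id <- truth$genome_id
    truth$name <- sprintf("planted_%d", seq_len(nrow(truth)))
  }
  write_annotations(if (nrow(truth)) truth else
    tibble(seq_id = character(), start = integer(), end = integer()),
    paths["truth"], format = "bed")
  ape::write.tree(scn$tree, paths["tree"])
  write.table(scn$events, paths["events"], sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(paths)
}
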