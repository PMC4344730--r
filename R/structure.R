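# Diagnostic Helitron structure: 5'-TC / 3'-CTRR termini with flanking A/T
# integration-site bases, a 3'-subterminal stem-loop scored by DNA
# nearest-neighbour free energies, 5'-IR and SIR inverted repeats, and
# internal tandem tetranucleotide microsatellites.

#' DNA nearest-neighbour folding parameters
#'
#' Unified duplex stack free energies (kcal/mol, 37 degrees C, 1 M NaCl)
#' with a simple linear hairpin-loop penalty and a flat per-mismatch
#' stem penalty. Stems are contiguous; bulges and internal loops are not
#' modelled.
#'
#' @param loop_init loop initiation penalty at the minimum loop length.
#' @param loop_per_nt additional penalty per loop base beyond the
#'   minimum.
#' @param mismatch_penalty penalty per mismatched stem position.
#' @return a parameter list with the 4x4 `stack` matrix (rows/cols in
#'   A,C,G,T order; entry \[x,y\] is the free energy of the x->y
#'   dinucleotide step on the top strand).
#' @export
dna_nn_params <- function(loop_init = 3.5, loop_per_nt = 0.35,
                          mismatch_penalty = 0.5) {
  stack <- matrix(c(
    -1.00, -1.44, -1.28, -0.88,   # AA AC AG AT
    -1.45, -1.84, -2.17, -1.28,   # CA CC CG CT
    -1.30, -2.24, -1.84, -1.44,   # GA GC GG GT
    -0.58, -1.30, -1.45, -1.00),  # TA TC TG TT
    nrow = 4, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  list(stack = stack, loop_init = loop_init, loop_per_nt = loop_per_nt,
       mismatch_penalty = mismatch_penalty)
}

#' Call 5'-TC and 3'-CTRR termini of a candidate element
#'
#' The 5' call is the leftmost `TC` starting within the first
#' `end_window` bases (reported as `TCC` when a third C is present); the
#' 3' call is the rightmost `CTRR` (R = A/G) whose final base lies in
#' the last `end_window` bases. Flanking dinucleotides are read from the
#' context immediately outside each terminus when supplied;
#' `matches_canonical` additionally requires the adjacent outside base
#' to be A or T (the AT/TT integration-site rule).
#'
#' @param element 1-row sequence tibble or DNA string.
#' @param context_left,context_right flanking host sequence outside the
#'   element ("" when unknown).
#' @param end_window search window at each end, in bases.
#' @return tibble of terminus calls (possibly 0 rows).
#' @export
find_termini <- function(element, context_left = "", context_right = "",
                         end_window = 30) {
  s <- seq_string(element)
  n <- nchar(s)
  if (end_window > n) abort("end_window exceeds element length")
  out <- list()
  m5 <- regexpr("TC", s, fixed = TRUE)
  if (m5 > 0 && m5 <= end_window) {
    motif <- if (substr(s, m5 + 2, m5 + 2) == "C") "TCC" else "TC"
    fl <- if (nzchar(context_left)) {
      substr(context_left, max(1, nchar(context_left) - 1),
             nchar(context_left))
    } else {
      NA_character_
    }
    adj <- if (is.na(fl)) NA_character_ else substr(fl, nchar(fl), nchar(fl))
    out$five <- tibble(kind = "five_prime", position = as.integer(m5),
                       motif = motif, flanking_dinucleotide = fl,
                       matches_canonical = if (is.na(adj)) NA else
                         adj %in% c("A", "T"))
  }
  m3 <- gregexpr("CT[AG][AG]", s)[[1]]
  if (m3[1] > 0) {
    ends <- as.integer(m3) + 3L
    keep <- ends >= n - end_window + 1L
    if (any(keep)) {
      pos <- max(as.integer(m3)[keep])
      motif <- substr(s, pos, pos + 3)
      fl <- if (nzchar(context_right)) substr(context_right, 1, 2) else
        NA_character_
      adj <- if (is.na(fl)) NA_character_ else substr(fl, 1, 1)
      out$three <- tibble(kind = "three_prime", position = as.integer(pos),
                          motif = motif, flanking_dinucleotide = fl,
                          matches_canonical = if (is.na(adj)) NA else
                            adj %in% c("A", "T"))
    }
  }
  if (!length(out)) {
    return(tibble(kind = character(), position = integer(),
                  motif = character(), flanking_dinucleotide = character(),
                  matches_canonical = logical()))
  }
  bind_rows(out)
}

#' Minimum-free-energy stem-loop in a 3'-terminal window
#'
#' Enumerates contiguous-stem hairpins (stem >= `min_stem` pairs, at
#' most `max_mismatch` internal mismatches, terminal stem pairs
#' Watson-Crick, loop length in `[min_loop, max_loop]`) and returns the
#' structure minimising the nearest-neighbour free energy: stack
#' energies between adjacent matched pairs, a flat penalty per stem
#' mismatch, and a linear loop penalty.
#'
#' @param window 1-row sequence tibble or DNA string (the 3' subterminal
#'   window, at most ~200 nt).
#' @param min_stem,max_stem stem length bounds in pairs.
#' @param max_mismatch mismatches tolerated inside the stem.
#' @param min_loop,max_loop loop length bounds in nt.
#' @param dg_ceiling report only structures with free energy at or
#'   below this value (kcal/mol); use `Inf` to always report the MFE
#'   structure.
#' @param params [dna_nn_params()].
#' @return a 1-row tibble (`left_start`, `left_end`, `right_start`,
#'   `right_end`, `arm_len`, `loop_len`, `mismatches`, `dg`) or a 0-row
#'   tibble when no structure qualifies.
#' @export
fold_hairpin <- function(window, min_stem = 4, max_stem = 25,
                         max_mismatch = 2, min_loop = 3, max_loop = 30,
                         dg_ceiling = -3, params = dna_nn_params()) {
  s <- seq_string(window)
  empty <- tibble(left_start = integer(), left_end = integer(),
                  right_start = integer(), right_end = integer(),
                  arm_len = integer(), loop_len = integer(),
                  mismatches = integer(), dg = numeric())
  if (nchar(s) < 2 * min_stem + min_loop) return(empty)
  res <- .hairpin_scan_cpp(encode_dna(s), params$stack, min_stem, max_stem,
                           max_mismatch, min_loop, max_loop,
                           params$loop_init, params$loop_per_nt,
                           params$mismatch_penalty)
  if (!res$found || res$dg > dg_ceiling) return(empty)
  tibble(left_start = res$left_start, left_end = res$left_end,
         right_start = res$right_start, right_end = res$right_end,
         arm_len = res$left_end - res$left_start + 1L,
         loop_len = res$loop_len, mismatches = res$mismatches, dg = res$dg)
}

#' Find 5'-IR and SIR inverted-repeat pairs
#'
#' Reports maximal mismatch-bounded inverted-repeat arm pairs. A
#' `five_prime_IR` has both arms inside the first `five_prime_window`
#' bases; a `SIR` pairs an arm in the first `subterminal_window` bases
#' with one in the last `subterminal_window` bases.
#'
#' @param element 1-row sequence tibble or DNA string.
#' @param min_arm minimum arm length (>= 4).
#' @param max_mismatch mismatches tolerated per arm pair.
#' @param five_prime_window,subterminal_window window sizes in bases.
#' @param min_sep minimum unpaired bases between arms.
#' @return tibble with `kind`, arm coordinates, `arm_len`, `mismatches`.
#' @export
find_inverted_repeats <- function(element, min_arm = 8, max_mismatch = 1,
                                  five_prime_window = 60,
                                  subterminal_window = 120, min_sep = 3) {
  if (min_arm < 4) abort("min_arm must be >= 4")
  s <- seq_string(element)
  n <- nchar(s)
  runs <- as_tibble(.ir_runs_cpp(encode_dna(s), min_arm, max_mismatch,
                                 min_sep))
  if (!nrow(runs)) {
    return(tibble(kind = character(), a_start = integer(), a_end = integer(),
                  b_start = integer(), b_end = integer(),
                  arm_len = integer(), mismatches = integer()))
  }
  five <- runs %>%
    filter(.data$a_start >= 1, .data$b_end <= five_prime_window) %>%
    mutate(kind = "five_prime_IR")
  sir <- runs %>%
    filter(.data$a_end <= subterminal_window,
           .data$b_start >= n - subterminal_window + 1) %>%
    mutate(kind = "SIR")
  out <- bind_rows(five, sir) %>%
    select("kind", "a_start", "a_end", "b_start", "b_end", "arm_len",
           "mismatches") %>%
    arrange(.data$kind, desc(.data$arm_len), .data$a_start)
  # keep the dominant (longest) pair per kind plus any non-overlapping ones
  out %>%
    group_by(.data$kind) %>%
    filter(!duplicated(paste(.data$a_start, .data$b_end))) %>%
    ungroup()
}

rotations <- function(unit) {
  k <- nchar(unit)
  unique(vapply(seq_len(k) - 1L, function(r) {
    paste0(substr(unit, r + 1, k), substr(unit, 1, r))
  }, character(1)))
}

#' Find tandem microsatellite arrays
#'
#' Maximal tandem arrays of any rotation of the given repeat units,
#' extended into a final (and leading) partial unit; overlapping arrays
#' are merged to the longest. Copy number may be fractional.
#'
#' @param seq 1-row sequence tibble or DNA string.
#' @param units repeat units to search (rotation-equivalent forms are
#'   detected automatically).
#' @param min_copies minimum copy number (on the possibly fractional
#'   count).
#' @return tibble with `unit` (canonical form), `copies`, `start`,
#'   `end`.
#' @export
find_microsatellites <- function(seq, units = c("CTGT", "GTTT"),
                                 min_copies = 3) {
  if (!length(units)) abort("no repeat units supplied")
  s <- seq_string(seq)
  n <- nchar(s)
  cand <- list()
  for (unit in toupper(units)) {
    k <- nchar(unit)
    for (rot in rotations(unit)) {
      m <- gregexpr(sprintf("(?:%s)+", rot), s)[[1]]
      if (m[1] < 0) next
      lens <- attr(m, "match.length")
      for (t in seq_along(m)) {
        start <- as.integer(m[t]); end <- start + lens[t] - 1L
        # extend the periodic run into partial units on both sides
        while (end < n && substr(s, end + 1, end + 1) ==
               substr(s, end + 1 - k, end + 1 - k)) end <- end + 1L
        while (start > 1 && substr(s, start - 1, start - 1) ==
               substr(s, start - 1 + k, start - 1 + k)) start <- start - 1L
        cand[[length(cand) + 1]] <- tibble(unit = unit, start = start,
                                           end = end,
                                           span = end - start + 1L,
                                           copies = (end - start + 1L) / k)
      }
    }
  }
  if (!length(cand)) {
    return(tibble(unit = character(), copies = numeric(),
                  start = integer(), end = integer()))
  }
  arrays <- bind_rows(cand) %>%
    filter(.data$copies >= min_copies) %>%
    arrange(desc(.data$span), .data$start) %>%
    distinct_overlaps()
  arrays %>% select("unit", "copies", "start", "end")
}

# keep the longest array among mutually overlapping candidates
distinct_overlaps <- function(arrays) {
  keep <- rep(TRUE, nrow(arrays))
  for (i in seq_len(nrow(arrays))) {
    if (!keep[i]) next
    if (i < nrow(arrays)) {
      for (j in seq(i + 1, nrow(arrays))) {
        if (keep[j] && arrays$start[j] <= arrays$end[i] &&
            arrays$end[j] >= arrays$start[i]) {
          keep[j] <- FALSE
        }
      }
    }
  }
  arrays[keep, , drop = FALSE]
}

#' Confidence tier from annotation parts
#'
#' `full`: both canonical termini and a qualifying hairpin;
#' `partial`: exactly one terminus with a hairpin, or both termini
#' without one; `structural_only`: a hairpin or SIR but no canonical
#' terminus; `rejected` otherwise.
#'
#' @param termini terminus tibble from [find_termini()].
#' @param hairpin hairpin tibble from [fold_hairpin()] (0 rows = none).
#' @param irs inverted-repeat tibble from [find_inverted_repeats()].
#' @return one of `"full"`, `"partial"`, `"structural_only"`,
#'   `"rejected"`.
#' @export
classify_element <- function(termini, hairpin, irs) {
  n_term <- nrow(termini)
  has_hp <- nrow(hairpin) > 0
  has_sir <- nrow(irs) > 0 && any(irs$kind == "SIR")
  if (n_term == 2 && has_hp) return("full")
  if ((n_term == 1 && has_hp) || (n_term == 2 && !has_hp)) return("partial")
  if (n_term == 0 && (has_hp || has_sir)) return("structural_only")
  "rejected"
}

#' Annotate one candidate element
#'
#' Runs the full structural workup: termini, 3'-window hairpin,
#' inverted repeats, microsatellites, and the confidence tier.
#'
#' @param element 1-row sequence tibble or DNA string.
#' @param context_left,context_right flanking host sequence ("" if
#'   unknown).
#' @param end_window terminus search window (bases).
#' @param hairpin_window bases upstream of the 3' terminus searched for
#'   the stem-loop (the element 3' end is used when no terminus is
#'   found).
#' @param dg_ceiling hairpin reporting ceiling, kcal/mol.
#' @param min_arm,max_ir_mismatch inverted-repeat parameters.
#' @param microsat_units,min_copies microsatellite parameters.
#' @param id element id (defaults to the tibble id).
#' @return a `hel_annotation` object.
#' @export
annotate_element <- function(element, context_left = "", context_right = "",
                             end_window = 30, hairpin_window = 100,
                             dg_ceiling = -3, min_arm = 8,
                             max_ir_mismatch = 1,
                             microsat_units = c("CTGT", "GTTT"),
                             min_copies = 3, id = NULL) {
  s <- seq_string(element)
  if (is.null(id)) {
    id <- if (is.data.frame(element)) element$id[[1]] else "element"
  }
  n <- nchar(s)
  termini <- find_termini(s, context_left, context_right,
                          end_window = min(end_window, n))
  pos3 <- if (any(termini$kind == "three_prime")) {
    termini$position[termini$kind == "three_prime"]
  } else {
    n + 1L
  }
  win_start <- max(1L, pos3 - hairpin_window)
  win_end <- max(win_start, pos3 - 1L)
  hairpin <- fold_hairpin(substr(s, win_start, win_end),
                          dg_ceiling = dg_ceiling)
  if (nrow(hairpin)) {
    hairpin <- hairpin %>%
      mutate(across(c("left_start", "left_end", "right_start", "right_end"),
                    ~ .x + win_start - 1L))
  }
  irs <- find_inverted_repeats(s, min_arm = min_arm,
                               max_mismatch = max_ir_mismatch)
  micro <- find_microsatellites(s, units = microsat_units,
                                min_copies = min_copies)
  structure(list(id = id, length = n, termini = termini, hairpin = hairpin,
                 irs = irs, microsatellites = micro,
                 tier = classify_element(termini, hairpin, irs)),
            class = "hel_annotation")
}

#' @export
print.hel_annotation <- function(x, ...) {
  cat(sprintf("<hel_annotation> %s (%d bp), tier = %s\n", x$id, x$length,
              x$tier))
  if (nrow(x$termini)) {
    cat(sprintf("  termini: %s\n",
                paste(sprintf("%s %s@%d", x$termini$kind, x$termini$motif,
                              x$termini$position), collapse = ", ")))
  }
  if (nrow(x$hairpin)) {
    cat(sprintf("  hairpin: %d bp stem / %d nt loop, dG = %.2f kcal/mol\n",
                x$hairpin$arm_len, x$hairpin$loop_len, x$hairpin$dg))
  }
  if (nrow(x$irs)) {
    cat(sprintf("  inverted repeats: %s\n",
                paste(unique(x$irs$kind), collapse = ", ")))
  }
  if (nrow(x$microsatellites)) {
    cat(sprintf("  microsatellites: %s\n",
                paste(sprintf("(%s)%.2g", x$microsatellites$unit,
                              x$microsatellites$copies), collapse = ", ")))
  }
  invisible(x)
}

#' Annotate a set of candidate elements
#'
#' @param seqs sequence tibble of candidate elements.
#' @param contexts optional tibble with `id`, `context_left`,
#'   `context_right`.
#' @inheritParams annotate_element
#' @param ... passed to [annotate_element()].
#' @return a tibble with one row per element (tier and feature summary)
#'   and the full `hel_annotation` in the `annotation` list-column.
#' @export
annotate_elements <- function(seqs, contexts = NULL, ...) {
  annos <- purrr::map(seq_len(nrow(seqs)), function(k) {
    cl <- cr <- ""
    if (!is.null(contexts)) {
      row <- contexts[contexts$id == seqs$id[k], , drop = FALSE]
      if (nrow(row)) {
        cl <- row$context_left[[1]]
        cr <- row$context_right[[1]]
      }
    }
    annotate_element(seqs[k, ], context_left = cl, context_right = cr, ...)
  })
  tibble(
    id = seqs$id,
    length = seqs$length,
    tier = vapply(annos, `[[`, character(1), "tier"),
    n_termini = vapply(annos, function(a) nrow(a$termini), integer(1)),
    has_hairpin = vapply(annos, function(a) nrow(a$hairpin) > 0, logical(1)),
    hairpin_dg = vapply(annos, function(a) {
      if (nrow(a$hairpin)) a$hairpin$dg else NA_real_
    }, numeric(1)),
    n_ir = vapply(annos, function(a) nrow(a$irs), integer(1)),
    n_microsat = vapply(annos, function(a) nrow(a$microsatellites),
                        integer(1)),
    annotation = annos
  )
}

#' Feature table of an annotation, for GFF3/BED export
#'
#' @param anno a `hel_annotation`.
#' @return tibble with `seq_id`, `type`, `start`, `end`, `strand`,
#'   `name`, `score`.
#' @export
annotation_features <- function(anno) {
  stopifnot(inherits(anno, "hel_annotation"))
  rows <- list(tibble(seq_id = anno$id, type = "helitron", start = 1L,
                      end = anno$length, strand = "+",
                      name = paste0(anno$id, "_element"), score = 0))
  if (nrow(anno$termini)) {
    t <- anno$termini
    rows$termini <- tibble(
      seq_id = anno$id,
      type = ifelse(t$kind == "five_prime", "terminus_5p", "terminus_3p"),
      start = t$position, end = t$position + nchar(t$motif) - 1L,
      strand = "+", name = paste0(anno$id, "_", t$kind), score = 0)
  }
  if (nrow(anno$hairpin)) {
    h <- anno$hairpin
    rows$hairpin <- tibble(seq_id = anno$id, type = "hairpin",
                           start = h$left_start, end = h$right_end,
                           strand = "+", name = paste0(anno$id, "_hairpin"),
                           score = h$dg)
  }
  if (nrow(anno$irs)) {
    r <- anno$irs
    rows$irs <- tibble(seq_id = anno$id, type = "inverted_repeat",
                       start = r$a_start, end = r$b_end, strand = "+",
                       name = paste0(anno$id, "_", r$kind,
                                     seq_len(nrow(r))), score = 0)
  }
  if (nrow(anno$microsatellites)) {
    m <- anno$microsatellites
    rows$micro <- tibble(seq_id = anno$id, type = "microsatellite",
                         start = m$start, end = m$end, strand = "+",
                         name = sprintf("%s_(%s)n", anno$id, m$unit),
                         score = 0)
  }
  bind_rows(rows)
}
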