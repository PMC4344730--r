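# Local homology scanning: affine-gap Smith-Waterman on both strands with
# greedy suboptimal-hit extraction, Karlin-Altschul E-values, and the
# identity / E-value / terminal-coverage retention filters.

encode_dna <- function(s) {
  # A=0 C=1 G=2 T=3, ambiguity=4, masked(x)=5
  map <- c(A = 0L, C = 1L, G = 2L, T = 3L, x = 5L)
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  ch[ch == "X"] <- "x"
  out <- map[ch]
  out[is.na(out)] <- 4L
  unname(out)
}

#' Scoring scheme for local homology search
#'
#' blastn-like defaults: match +2, mismatch -3, gap open 5, gap extend 2
#' (a gap of length L costs `gap_open + L * gap_extend`). The
#' Karlin-Altschul parameters are documented constants, not estimated:
#' `karlin_lambda` solves the ungapped stationarity equation for +2/-3 at
#' uniform base frequencies and `karlin_K` is a conventional value.
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @param gap_open,gap_extend positive gap penalties,
#'   `gap_open >= gap_extend > 0`.
#' @param karlin_lambda,karlin_K positive Karlin-Altschul statistics.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2, karlin_lambda = 0.634,
                           karlin_K = 0.41) {
  stopifnot(match > 0, mismatch < 0, gap_open >= gap_extend, gap_extend > 0,
            karlin_lambda > 0, karlin_K > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_K = karlin_K),
            class = "scoring_scheme")
}

#' Karlin-Altschul expected number of chance hits
#'
#' `E = K * m * n * exp(-lambda * score)`.
#'
#' @param score alignment raw score (>= 0).
#' @param m,n query and subject lengths in bases.
#' @param scoring a [scoring_scheme()].
#' @return expected number of chance hits at or above `score`.
#' @export
evalue <- function(score, m, n, scoring = scoring_scheme()) {
  stopifnot(all(score >= 0), m > 0, n > 0)
  scoring$karlin_K * m * n * exp(-scoring$karlin_lambda * score)
}

# score a 50 bp, 65%-identity gapless alignment would achieve: the floor
# for suboptimal-hit extraction (mirrors the terminal-partial filter)
default_score_floor <- function(scoring, min_terminal = 50,
                                min_identity = 65) {
  p <- min_identity / 100
  min_terminal * (p * scoring$match + (1 - p) * scoring$mismatch)
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         strand = character(), q_start = integer(), q_end = integer(),
         s_start = integer(), s_end = integer(), score = numeric(),
         matches = integer(), columns = integer(), identity_pct = numeric(),
         evalue = numeric(), query_length = integer(),
         coverage_class = character())
}

coverage_class_of <- function(q_start, q_end, qlen, end_slack,
                              min_terminal = 1) {
  span <- q_end - q_start + 1
  full <- q_start <= 1 + end_slack & q_end >= qlen - end_slack
  five <- q_start <= 1 + end_slack & span >= min_terminal
  three <- q_end >= qlen - end_slack & span >= min_terminal
  dplyr::case_when(full ~ "full_length",
                   five ~ "five_prime_partial",
                   three ~ "three_prime_partial",
                   TRUE ~ "internal")
}

#' Local alignment of a query element against a subject sequence
#'
#' Affine-gap Smith-Waterman on both strands. Non-overlapping suboptimal
#' hits are extracted by greedily masking the subject span of each
#' reported hit and re-aligning, down to `score_floor` (default: the
#' score of a 50 bp, 65%-identity gapless alignment). Subject
#' coordinates are always reported on the forward strand;
#' `identity_pct` counts gap columns in the denominator.
#'
#' @param query,subject sequence tibbles (1 row) or plain DNA strings.
#' @param scoring a [scoring_scheme()].
#' @param score_floor minimum reported raw score.
#' @param end_slack bases of terminal erosion tolerated when classing a
#'   hit as full-length.
#' @param max_hits cap on reported hits per subject.
#' @return a hit tibble sorted by descending score.
#' @export
local_align <- function(query, subject, scoring = scoring_scheme(),
                        score_floor = NULL, end_slack = 5, max_hits = 50) {
  qid <- if (is.data.frame(query)) query$id[[1]] else "query"
  sid <- if (is.data.frame(subject)) subject$id[[1]] else "subject"
  qs <- seq_string(query)
  ss <- seq_string(subject)
  if (!nchar(qs) || !nchar(ss)) abort("empty sequence in local_align()")
  if (is.null(score_floor)) score_floor <- default_score_floor(scoring)
  qv <- encode_dna(qs)
  fwd <- encode_dna(ss)
  rev <- encode_dna(revcomp(ss))
  n <- length(fwd)
  qlen <- length(qv)
  rows <- list()
  repeat {
    hf <- .sw_align_cpp(qv, fwd, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
    hr <- .sw_align_cpp(qv, rev, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
    use_fwd <- hf$score >= hr$score
    h <- if (use_fwd) hf else hr
    if (h$score < score_floor || h$score <= 0) break
    if (use_fwd) {
      s_start <- h$s_start; s_end <- h$s_end; strand <- "+"
    } else {
      s_start <- n - h$s_end + 1; s_end <- n - h$s_start + 1; strand <- "-"
    }
    rows[[length(rows) + 1]] <- tibble(
      query_id = qid, subject_id = sid, strand = strand,
      q_start = h$q_start, q_end = h$q_end,
      s_start = s_start, s_end = s_end,
      score = h$score, matches = h$matches, columns = h$columns,
      identity_pct = round(100 * h$matches / h$columns, 2),
      evalue = evalue(h$score, qlen, n, scoring),
      query_length = qlen)
    # mask the subject span in both orientations
    fwd[s_start:s_end] <- 5L
    rev[(n - s_end + 1):(n - s_start + 1)] <- 5L
    if (length(rows) >= max_hits) break
  }
  if (!length(rows)) return(empty_hits())
  hits <- bind_rows(rows) %>% arrange(desc(.data$score))
  hits$coverage_class <- coverage_class_of(hits$q_start, hits$q_end,
                                           qlen, end_slack)
  hits
}

#' Retention filters for homology hits
#'
#' A hit is retained when `identity_pct >= min_identity`,
#' `evalue <= max_evalue`, and it either spans the whole query (within
#' the end slack used by [local_align()]) or aligns at least
#' `min_terminal` bases anchored at the query 5' or 3' end.
#'
#' @param hits hit tibble from [local_align()].
#' @param min_identity percent identity threshold.
#' @param max_evalue E-value ceiling.
#' @param min_terminal minimum anchored terminal alignment length in bp.
#' @param end_slack anchor tolerance in bases at the query ends.
#' @return filtered hit tibble with `coverage_class` set.
#' @export
filter_hits <- function(hits, min_identity = 65, max_evalue = 1e-5,
                        min_terminal = 50, end_slack = 5) {
  if (!nrow(hits)) return(hits)
  hits$coverage_class <- coverage_class_of(hits$q_start, hits$q_end,
                                           hits$query_length, end_slack,
                                           min_terminal)
  hits %>%
    filter(.data$identity_pct >= min_identity,
           .data$evalue <= max_evalue,
           .data$coverage_class != "internal")
}

#' Scan a set of subject sequences for element copies
#'
#' Runs [local_align()] against every subject row and applies
#' [filter_hits()].
#'
#' @param subjects sequence tibble of target sequences (genomes/contigs).
#' @param query 1-row sequence tibble or DNA string of the query element.
#' @param scoring a [scoring_scheme()].
#' @param min_identity,max_evalue,min_terminal retention thresholds.
#' @param end_slack full-length end slack in bases.
#' @param max_hits per-subject hit cap.
#' @return retained hit tibble across all subjects.
#' @export
scan_sequences <- function(subjects, query, scoring = scoring_scheme(),
                           min_identity = 65, max_evalue = 1e-5,
                           min_terminal = 50, end_slack = 5, max_hits = 50) {
  if (!nrow(subjects)) abort("no subject sequences supplied")
  hits <- purrr::map(seq_len(nrow(subjects)), function(k) {
    local_align(query, subjects[k, ], scoring = scoring,
                end_slack = end_slack, max_hits = max_hits)
  }) %>% bind_rows()
  filter_hits(hits, min_identity = min_identity, max_evalue = max_evalue,
              min_terminal = min_terminal, end_slack = end_slack)
}

#' Extract hit regions as sequences
#'
#' @param hits retained hit tibble.
#' @param subjects sequence tibble the hits refer to.
#' @return sequence tibble of hit regions (minus-strand hits are
#'   reverse-complemented so elements read 5' to 3').
#' @export
hit_sequences <- function(hits, subjects) {
  if (!nrow(hits)) return(seq_tbl(character()))
  out <- purrr::map(seq_len(nrow(hits)), function(k) {
    h <- hits[k, ]
    r <- extract_region(subjects, h$subject_id, h$s_start, h$s_end,
                        strand = h$strand)
    r$id <- sprintf("%s_hit%d_%s_%d_%d", h$subject_id, k, h$strand,
                    h$s_start, h$s_end)
    r
  })
  bind_rows(out)
}
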