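# The horizontal-transfer screen: per species pair, compare TE identity
# with host-marker identity; pairs where the TE is more conserved than
# the genomic background (delta > 0) are flagged, with a label-permutation
# p-value reported alongside.

check_identity_matrix <- function(m, what = "identity matrix") {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("%s must have row and column labels", what))
  }
  if (!isTRUE(all.equal(unname(m), unname(t(m)), tolerance = 1e-8))) {
    abort(sprintf("%s is not symmetric", what))
  }
  m
}

#' Compare TE and host-marker identity matrices
#'
#' One record per unordered species pair with
#' `delta = te_identity - host_identity`; pairs with `delta > 0` (the
#' TE is more conserved than the genomic background) are flagged.
#' Output is sorted by descending delta and invariant to input label
#' ordering.
#'
#' @param te,host symmetric labelled percent-identity matrices over the
#'   same species set (e.g. from [identity_matrix()]).
#' @return tibble with `species_a`, `species_b`, `te_identity`,
#'   `host_identity`, `delta`, `flagged`.
#' @export
compare_matrices <- function(te, host) {
  te <- check_identity_matrix(te, "TE matrix")
  host <- check_identity_matrix(host, "host matrix")
  if (!setequal(rownames(te), rownames(host))) {
    only_te <- setdiff(rownames(te), rownames(host))
    only_host <- setdiff(rownames(host), rownames(te))
    abort(sprintf("label mismatch: only in TE [%s]; only in host [%s]",
                  paste(only_te, collapse = ", "),
                  paste(only_host, collapse = ", ")))
  }
  labs <- sort(rownames(te))
  te <- te[labs, labs]
  host <- host[labs, labs]
  pairs <- which(upper.tri(te), arr.ind = TRUE)
  tibble(
    species_a = labs[pairs[, 1]],
    species_b = labs[pairs[, 2]],
    te_identity = te[pairs],
    host_identity = host[pairs],
    delta = te[pairs] - host[pairs]
  ) %>%
    mutate(flagged = .data$delta > 0) %>%
    arrange(desc(.data$delta))
}

#' Permutation p-value for one species pair's delta
#'
#' The observed `delta = te - host` for the focal pair is compared with
#' the null deltas obtained at the focal pair's position after jointly
#' relabelling the taxa of the matrix pair; relabellings that leave the
#' focal pair in place reproduce the observed arrangement (already
#' represented by the +1 of the permutation formula) and are excluded
#' from the null draw. `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#' When the permutation group is small (`n! <= n_perm`, which includes
#' every case with fewer than 8 taxa at the default `n_perm`), the
#' p-value is computed by exact enumeration instead of sampling.
#'
#' @param te,host symmetric labelled identity matrices.
#' @param pair length-2 character vector naming the focal species pair.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed (used only when sampling).
#' @return the permutation p-value in (0, 1].
#' @export
permutation_test <- function(te, host, pair, n_perm = 999, seed = NULL) {
  if (n_perm < 99) abort("n_perm must be >= 99")
  cmp <- compare_matrices(te, host)
  labs <- sort(union(cmp$species_a, cmp$species_b))
  n <- length(labs)
  pair <- sort(as.character(pair))
  obs_row <- cmp$species_a == pair[1] & cmp$species_b == pair[2]
  if (!any(obs_row)) abort(sprintf("pair %s~%s not found", pair[1], pair[2]))
  obs <- cmp$delta[obs_row]
  deltas <- cmp$delta
  exhaustive <- factorial(n) <= n_perm || n < 4
  if (exhaustive) {
    # each non-focal pair receives equal weight 2(n-2)! among the
    # pair-moving permutations; count in permutation units
    per_pair <- 2 * factorial(n - 2)
    ge <- sum(deltas[!obs_row] >= obs) * per_pair
    total <- factorial(n) - per_pair  # pair-moving permutations
    (1 + ge) / (1 + total)
  } else {
    if (!is.null(seed)) set.seed(seed)
    others <- deltas[!obs_row]
    draw <- sample(others, n_perm, replace = TRUE)
    (1 + sum(draw >= obs)) / (1 + n_perm)
  }
}

#' Screen all species pairs for horizontal-transfer signal
#'
#' Runs [compare_matrices()] and attaches a [permutation_test()]
#' p-value to every pair. The primary flag stays the raw inequality
#' `delta > 0`; the p-value is reported alongside, never substituted.
#'
#' @param te,host symmetric labelled identity matrices.
#' @param n_perm permutations per pair.
#' @param seed integer seed.
#' @param identity_mode metadata string recording how the identities
#'   were computed (stored in the result attributes).
#' @return an `htt_screen` tibble (one row per pair, descending delta)
#'   with `p_value`.
#' @export
htt_screen <- function(te, host, n_perm = 999, seed = NULL,
                       identity_mode = "all_columns") {
  cmp <- compare_matrices(te, host)
  cmp$p_value <- vapply(seq_len(nrow(cmp)), function(k) {
    permutation_test(te, host, c(cmp$species_a[k], cmp$species_b[k]),
                     n_perm = n_perm, seed = seed)
  }, numeric(1))
  structure(cmp, class = c("htt_screen", class(cmp)),
            n_perm = n_perm, identity_mode = identity_mode)
}

#' @export
print.htt_screen <- function(x, ...) {
  cat(sprintf(
    "<htt_screen> %d species pairs, %d flagged (TE more conserved)\n",
    nrow(x), sum(x$flagged)))
  NextMethod()
}
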