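# Pairwise and progressive multiple alignment with ClustalW-style
# parameters (match +1, mismatch 0, gap penalty 10 / extension 0.2),
# percent identity in two modes, complete deletion of gapped sites, and
# identity matrices.

new_alignment <- function(ids, aligned, score = NA_real_) {
  stopifnot(length(ids) == length(aligned))
  if (length(aligned) && length(unique(nchar(aligned))) != 1) {
    abort("alignment rows differ in length")
  }
  structure(tibble(id = as.character(ids), aligned = toupper(aligned)),
            score = score, class = c("hel_alignment", "tbl_df", "tbl",
                                     "data.frame"))
}

#' Treat equal-length ungapped sequences as an alignment
#' @param seqs sequence tibble with equal-length rows.
#' @return a `hel_alignment`.
#' @export
as_alignment <- function(seqs) {
  if (inherits(seqs, "hel_alignment")) return(seqs)
  if (length(unique(seqs$length)) != 1) {
    abort("sequences must have equal length to form an alignment directly")
  }
  new_alignment(seqs$id, seqs$residues)
}

#' @export
print.hel_alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d rows x %d columns\n", nrow(x),
              alignment_ncol(x)))
  NextMethod()
}

#' Number of columns in an alignment
#' @param aln a `hel_alignment`.
#' @return integer column count.
#' @export
alignment_ncol <- function(aln) {
  if (!nrow(aln)) return(0L)
  nchar(aln$aligned[[1]])
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$aligned, "", fixed = TRUE))
}

profile_of <- function(gapped) {
  # 5 x L frequency profile over A,C,G,T,gap; ambiguity codes weightless
  mat <- do.call(rbind, strsplit(gapped, "", fixed = TRUE))
  L <- ncol(mat)
  prof <- matrix(0, nrow = 5, ncol = L)
  lev <- c("A", "C", "G", "T", "-")
  for (r in 1:5) prof[r, ] <- colSums(mat == lev[r]) / nrow(mat)
  prof
}

merge_profiles <- function(ga, gb, match, mismatch, gap_open, gap_extend) {
  res <- .nw_profile_cpp(profile_of(ga), profile_of(gb), match, mismatch,
                         gap_open, gap_extend)
  pa <- res$path_a; pb <- res$path_b
  expand <- function(g, path) {
    ch <- strsplit(g, "", fixed = TRUE)
    vapply(ch, function(v) {
      paste(ifelse(path > 0, v[pmax(path, 1)], "-"), collapse = "")
    }, character(1))
  }
  list(a = expand(ga, pa), b = expand(gb, pb), score = res$score)
}

#' Optimal global pairwise alignment
#'
#' Affine-gap Needleman-Wunsch under ClustalW-style nucleotide scoring
#' (match +1, mismatch 0) with gap penalty 10 and gap extension 0.2 by
#' default; a gap of length L costs `gap_open + L * gap_extend` and end
#' gaps are penalized. Traceback ties resolve diagonal > up > left, so
#' the result is deterministic.
#'
#' @param a,b 1-row sequence tibbles or DNA strings.
#' @param gap_open,gap_extend gap penalties.
#' @param match,mismatch column scores.
#' @return a `hel_alignment` with the optimal score in
#'   `attr(, "score")`.
#' @export
pairwise_global <- function(a, b, gap_open = 10, gap_extend = 0.2,
                            match = 1, mismatch = 0) {
  ida <- if (is.data.frame(a)) a$id[[1]] else "a"
  idb <- if (is.data.frame(b)) b$id[[1]] else "b"
  sa <- seq_string(a); sb <- seq_string(b)
  if (!nchar(sa) || !nchar(sb)) abort("empty sequence in pairwise_global()")
  m <- merge_profiles(sa, sb, match, mismatch, gap_open, gap_extend)
  new_alignment(c(ida, idb), c(m$a, m$b), score = m$score)
}

kmer_distance <- function(seqs, k = 3) {
  counts <- lapply(seqs$residues, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character()))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  kmers <- sort(unique(unlist(lapply(counts, names))))
  mat <- t(vapply(counts, function(ct) {
    v <- setNames(numeric(length(kmers)), kmers)
    v[names(ct)] <- as.numeric(ct)
    v / max(sum(v), 1)
  }, numeric(length(kmers))))
  d <- as.matrix(stats::dist(mat, method = "manhattan")) / 2
  dimnames(d) <- list(seqs$id, seqs$id)
  d
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from k-mer distances and neighbor joining; profiles are
#' merged in guide-tree postorder with the same affine scoring as
#' [pairwise_global()]. Input row order is preserved.
#'
#' @param seqs sequence tibble (>= 1 row).
#' @param gap_open,gap_extend gap penalties (ClustalW-style default
#'   10 / 0.2).
#' @param match,mismatch column scores.
#' @param k k-mer size for the guide distances.
#' @return a `hel_alignment`.
#' @export
progressive_msa <- function(seqs, gap_open = 10, gap_extend = 0.2,
                            match = 1, mismatch = 0, k = 3) {
  n <- nrow(seqs)
  if (n == 0) abort("no sequences to align")
  if (n == 1) return(new_alignment(seqs$id, seqs$residues))
  if (n == 2) {
    return(pairwise_global(seqs[1, ], seqs[2, ], gap_open, gap_extend,
                           match, mismatch))
  }
  d <- kmer_distance(seqs, k = k)
  guide <- ape::nj(stats::as.dist(d))
  guide <- ape::root(guide, outgroup = guide$tip.label[1], resolve.root = TRUE)
  # postorder merge over the rooted guide tree
  groups <- setNames(lapply(seqs$id, function(i) {
    setNames(seqs$residues[seqs$id == i], i)
  }), seqs$id)
  nodes <- ape::postorder(guide)
  edge <- guide$edge
  node_group <- vector("list", max(edge))
  ntip <- length(guide$tip.label)
  for (t in seq_len(ntip)) node_group[[t]] <- groups[[guide$tip.label[t]]]
  for (e in nodes) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    cg <- node_group[[child]]
    pg <- node_group[[parent]]
    if (is.null(pg)) {
      node_group[[parent]] <- cg
    } else {
      m <- merge_profiles(pg, cg, match, mismatch, gap_open, gap_extend)
      node_group[[parent]] <- c(setNames(m$a, names(pg)),
                                setNames(m$b, names(cg)))
    }
  }
  res <- node_group[[ntip + 1]]
  new_alignment(seqs$id, unname(res[seqs$id]))
}

#' Percent identity between two alignment rows
#'
#' `all_columns` counts every column in which at least one of the two
#' rows has a residue (a gap column is a non-match); `ungapped_columns`
#' restricts the denominator to columns where both rows have residues.
#'
#' @param aln a `hel_alignment`.
#' @param i,j row indices or ids.
#' @param mode `"all_columns"` or `"ungapped_columns"`.
#' @return percent identity, rounded to 2 decimals; `NaN` (with a
#'   warning) when the denominator is zero.
#' @export
percent_identity <- function(aln, i, j,
                             mode = c("all_columns", "ungapped_columns")) {
  mode <- match.arg(mode)
  if (is.character(i)) i <- match(i, aln$id)
  if (is.character(j)) j <- match(j, aln$id)
  a <- strsplit(aln$aligned[[i]], "", fixed = TRUE)[[1]]
  b <- strsplit(aln$aligned[[j]], "", fixed = TRUE)[[1]]
  both_res <- a != "-" & b != "-"
  any_res <- a != "-" | b != "-"
  matches <- sum(a == b & both_res)
  denom <- if (mode == "all_columns") sum(any_res) else sum(both_res)
  if (denom == 0) {
    warn("zero aligned columns; identity undefined")
    return(NaN)
  }
  round(100 * matches / denom, 2)
}

#' Remove every column containing a gap ("complete deletion")
#'
#' @param aln a `hel_alignment`.
#' @return the gap-free alignment; a 0-column alignment (with a
#'   warning) when every column is gapped.
#' @export
complete_deletion <- function(aln) {
  mat <- alignment_matrix(aln)
  keep <- colSums(mat == "-") == 0
  if (!any(keep)) warn("complete deletion removed every column")
  new_alignment(aln$id, apply(mat[, keep, drop = FALSE], 1, paste,
                              collapse = ""))
}

#' Pairwise percent-identity matrix
#'
#' @param x a `hel_alignment`, or a sequence tibble (aligned with
#'   [progressive_msa()] when `method = "msa"`, or per-pair with
#'   [pairwise_global()] when `method = "pairwise"`).
#' @param mode identity mode, see [percent_identity()].
#' @param method how to align a sequence tibble.
#' @param ... passed to the aligner.
#' @return a symmetric `identity_matrix` (percent, diagonal 100).
#' @export
identity_matrix <- function(x, mode = c("all_columns", "ungapped_columns"),
                            method = c("msa", "pairwise"), ...) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (!inherits(x, "hel_alignment") && method == "pairwise") {
    n <- nrow(x)
    m <- matrix(100, n, n, dimnames = list(x$id, x$id))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        aln <- pairwise_global(x[i, ], x[j, ], ...)
        m[i, j] <- m[j, i] <- percent_identity(aln, 1, 2, mode = mode)
      }
    }
    return(structure(m, class = c("identity_matrix", "matrix", "array")))
  }
  aln <- if (inherits(x, "hel_alignment")) x else progressive_msa(x, ...)
  n <- nrow(aln)
  if (n < 2) abort("need at least 2 rows for an identity matrix")
  m <- matrix(100, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- percent_identity(aln, i, j, mode = mode)
    }
  }
  structure(m, class = c("identity_matrix", "matrix", "array"))
}

#' Majority-rule consensus of an alignment
#'
#' Columns whose most frequent symbol is a gap are dropped, so the
#' result is the consensus span.
#'
#' @param aln a `hel_alignment`.
#' @return a 1-row sequence tibble.
#' @export
consensus_sequence <- function(aln) {
  mat <- alignment_matrix(aln)
  cons <- apply(mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  })
  seq_tbl(c(consensus = paste(cons[cons != "-"], collapse = "")))
}
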