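# Distance and likelihood phylogenetics for element copies: Tamura
# 3-parameter (+ discrete gamma) distances, neighbor joining, pruning
# log-likelihood under the T3P rate matrix, NNI hill-climbing, bootstrap
# majority-rule consensus, and Robinson-Foulds comparison.

#' Substitution model specification
#'
#' The Tamura 3-parameter (T3P) model distinguishes transitions,
#' transversions and GC content; `gamma_shape` controls among-site rate
#' variation (discretised into `n_rate_categories` equal-probability
#' categories at their distribution means; 1 category = uniform rates).
#'
#' @param model `"T3P"`, `"K2P"` or `"JC"` (K2P is T3P at GC 0.5; JC
#'   additionally sets kappa to 1).
#' @param gamma_shape gamma shape parameter (> 0); default 2.249.
#' @param n_rate_categories number of discrete gamma categories (>= 1).
#' @param gc_content equilibrium GC proportion (theta); `NULL` =
#'   estimate from the data.
#' @param kappa transition/transversion rate ratio for the likelihood
#'   rate matrix and the sequence simulator.
#' @return a `phylo_model` list.
#' @export
phylo_model <- function(model = c("T3P", "K2P", "JC"), gamma_shape = 2.249,
                        n_rate_categories = 4, gc_content = NULL,
                        kappa = 2) {
  model <- match.arg(model)
  stopifnot(gamma_shape > 0, n_rate_categories >= 1,
            is.null(gc_content) || (gc_content > 0 && gc_content < 1))
  if (model == "K2P") gc_content <- 0.5
  if (model == "JC") { gc_content <- 0.5; kappa <- 1 }
  structure(list(model = model, gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 gc_content = gc_content, kappa = kappa),
            class = "phylo_model")
}

#' Discrete gamma category rates (category means, mean 1)
#' @param shape gamma shape parameter.
#' @param k number of equal-probability categories.
#' @return numeric vector of k rates averaging 1.
#' @export
gamma_category_rates <- function(shape, k) {
  if (k == 1) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape,
                     rate = shape)
  # mean of Gamma(shape, shape) on each inter-quantile slice
  p_hi <- stats::pgamma(q[-1], shape = shape + 1, rate = shape)
  p_lo <- stats::pgamma(q[-(k + 1)], shape = shape + 1, rate = shape)
  r <- (p_hi - p_lo) * k
  r / mean(r)
}

row_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

ts_tv_counts <- function(a, b) {
  # transitions: A<->G, C<->T; transversions: the rest
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[valid]; b <- b[valid]
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  list(n = length(a), P = sum(ts) / max(length(a), 1),
       Q = sum(diff & !ts) / max(length(a), 1),
       gc = mean(c(a, b) %in% c("C", "G")))
}

#' Tamura 3-parameter distance between two aligned rows
#'
#' Closed-form T3P estimator from the transition proportion P,
#' transversion proportion Q and GC content theta:
#' `d = -h log(1 - P/h - Q) - (1 - h)/2 log(1 - 2Q)` with
#' `h = 2 theta (1 - theta)`. With more than one rate category the
#' standard gamma-rates transform `-log(x) -> a (x^(-1/a) - 1)` is
#' applied. Saturated pairs (a log argument <= 0) return `NA`.
#'
#' @param a,b gapped alignment rows (apply [complete_deletion()]
#'   first) or plain equal-length strings.
#' @param model a [phylo_model()]; `gc_content = NULL` uses the
#'   empirical GC of the two rows.
#' @return substitutions/site, or `NA` when saturated.
#' @export
t3p_distance <- function(a, b, model = phylo_model()) {
  ca <- row_chars(a); cb <- row_chars(b)
  if (!length(ca) || !length(cb)) abort("zero-length alignment rows")
  if (length(ca) != length(cb)) abort("rows differ in length")
  st <- ts_tv_counts(ca, cb)
  if (st$n == 0) abort("no comparable sites")
  theta <- if (is.null(model$gc_content)) st$gc else model$gc_content
  h <- 2 * theta * (1 - theta)
  c1 <- 1 - st$P / h - st$Q
  c2 <- 1 - 2 * st$Q
  if (c1 <= 0 || c2 <= 0) return(NA_real_)
  if (model$n_rate_categories > 1) {
    ga <- model$gamma_shape
    h * ga * (c1^(-1 / ga) - 1) + (1 - h) / 2 * ga * (c2^(-1 / ga) - 1)
  } else {
    -h * log(c1) - (1 - h) / 2 * log(c2)
  }
}

#' T3P distance matrix for an alignment
#'
#' Applies [complete_deletion()], then computes all pairwise T3P
#' distances with theta taken from the whole gap-filtered alignment
#' (unless fixed in the model).
#'
#' @param aln a `hel_alignment`.
#' @param model a [phylo_model()].
#' @return symmetric distance matrix (substitutions/site); saturated
#'   pairs are `NA`.
#' @export
t3p_matrix <- function(aln, model = phylo_model()) {
  aln <- complete_deletion(aln)
  mat <- alignment_matrix(aln)
  if (is.null(model$gc_content)) {
    model$gc_content <- mean(mat %in% c("C", "G"))
  }
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- t3p_distance(aln$aligned[[i]], aln$aligned[[j]],
                                         model)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (via \pkg{ape}); negative branch lengths are clamped to
#' zero with the deficit moved to the sibling edge, so total path
#' lengths are approximately preserved.
#'
#' @param d symmetric distance matrix (>= 3 taxa, no `NA`).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("neighbor joining needs at least 3 taxa")
  if (any(is.na(d))) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    abort(sprintf("undefined distances: %s",
                  paste(rownames(d)[bad[, 1]], colnames(d)[bad[, 2]],
                        sep = "~", collapse = ", ")))
  }
  tr <- ape::nj(stats::as.dist(d))
  # clamp negative edges, moving the deficit to the sibling edge
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

# --- T3P rate matrix and transition probabilities --------------------------

#' T3P instantaneous rate matrix (A,C,G,T order)
#'
#' Transition rates are `kappa * pi_j`, transversion rates `pi_j`, with
#' `pi = ((1-theta)/2, theta/2, theta/2, (1-theta)/2)`; scaled to one
#' expected substitution per site per unit branch length.
#'
#' @param model a [phylo_model()] with `gc_content` set.
#' @return list with `Q` (4x4) and `pi`.
#' @export
t3p_rate_matrix <- function(model) {
  theta <- model$gc_content
  if (is.null(theta)) abort("model gc_content must be set for the rate matrix")
  pi <- c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2,
          T = (1 - theta) / 2)
  k <- model$kappa
  is_transition <- matrix(FALSE, 4, 4,
                          dimnames = list(names(pi), names(pi)))
  is_transition["A", "G"] <- is_transition["G", "A"] <- TRUE
  is_transition["C", "T"] <- is_transition["T", "C"] <- TRUE
  Q <- matrix(rep(pi, each = 4), 4, 4,
              dimnames = list(names(pi), names(pi)))
  Q[is_transition] <- Q[is_transition] * k
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  list(Q = Q, pi = pi)
}

t3p_pmatrix <- function(model, t) {
  # transition probability matrix via symmetric eigen decomposition
  rm <- t3p_rate_matrix(model)
  s <- sqrt(rm$pi)
  B <- diag(s) %*% rm$Q %*% diag(1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / s) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(s)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(rm$Q)
  P
}

aln_codes <- function(aln) {
  mat <- alignment_matrix(aln)
  codes <- matrix(match(mat, c("A", "C", "G", "T")), nrow = nrow(mat))
  rownames(codes) <- aln$id
  codes
}

#' Pruning log-likelihood of an alignment on a tree
#'
#' Felsenstein's pruning algorithm under the T3P rate matrix with
#' discrete-gamma rate mixing; base frequencies come from the model GC
#' content (estimated from the alignment when unset). Ambiguous or
#' missing states get a flat partial. The likelihood is invariant to
#' the rooting of the unrooted tree.
#'
#' @param tree a `phylo` with branch lengths; leaf labels must match
#'   alignment row ids.
#' @param aln a gap-filtered `hel_alignment`.
#' @param model a [phylo_model()].
#' @return log-likelihood in nats.
#' @export
pruning_loglik <- function(tree, aln, model = phylo_model()) {
  if (!setequal(tree$tip.label, aln$id)) {
    abort("tree tip labels do not match alignment ids")
  }
  if (is.null(model$gc_content)) {
    model$gc_content <- mean(alignment_matrix(aln) %in% c("C", "G"))
  }
  codes <- aln_codes(aln)
  nsite <- ncol(codes)
  rates <- gamma_category_rates(model$gamma_shape, model$n_rate_categories)
  pi <- t3p_rate_matrix(model)$pi
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  sitelik <- matrix(0, nrow = length(rates), ncol = nsite)
  for (rc in seq_along(rates)) {
    Pmats <- lapply(seq_len(nrow(edge)), function(e) {
      t3p_pmatrix(model, tree$edge.length[e] * rates[rc])
    })
    # partials: nodes x 4 x sites
    partial <- array(NA_real_, dim = c(max(edge), 4, nsite))
    for (tip in seq_len(ntip)) {
      st <- codes[tree$tip.label[tip], ]
      m <- matrix(0, 4, nsite)
      known <- !is.na(st)
      m[cbind(st[known], which(known))] <- 1
      m[, !known] <- 1
      partial[tip, , ] <- m
    }
    done <- c(rep(TRUE, ntip), rep(FALSE, max(edge) - ntip))
    acc <- vector("list", max(edge))
    for (k in seq_len(nrow(po))) {
      e <- which(edge[, 1] == po[k, 1] & edge[, 2] == po[k, 2])
      parent <- po[k, 1]; child <- po[k, 2]
      contrib <- Pmats[[e]] %*% partial[child, , ]
      if (is.null(acc[[parent]])) {
        acc[[parent]] <- contrib
      } else {
        acc[[parent]] <- acc[[parent]] * contrib
      }
      partial[parent, , ] <- acc[[parent]]
    }
    root <- po[nrow(po), 1]
    sitelik[rc, ] <- as.numeric(pi %*% partial[root, , ])
  }
  sum(log(colMeans(sitelik)))
}

#' Hill-climbing tree search by nearest-neighbor interchange
#'
#' Evaluates every NNI neighbor of the current tree with
#' [pruning_loglik()] and moves to the best strictly improving
#' neighbor, repeating until a local optimum. Branch lengths of
#' rearranged trees are kept as produced by the NNI operation.
#'
#' @param start binary start tree (e.g. from [nj_tree()]).
#' @param aln a gap-filtered `hel_alignment`.
#' @param model a [phylo_model()].
#' @param max_iter iteration cap.
#' @return list with `tree`, `loglik`, `n_moves`.
#' @export
nni_search <- function(start, aln, model = phylo_model(), max_iter = 25) {
  cur <- start
  cur_ll <- pruning_loglik(cur, aln, model)
  moves <- 0
  for (it in seq_len(max_iter)) {
    nbrs <- phangorn::nni(cur)
    mean_edge <- mean(cur$edge.length)
    lls <- vapply(nbrs, function(tr) {
      if (is.null(tr$edge.length)) {
        tr$edge.length <- rep(mean_edge, nrow(tr$edge))
      }
      pruning_loglik(tr, aln, model)
    }, numeric(1))
    best <- which.max(lls)
    if (lls[best] <= cur_ll + 1e-9) break
    cur <- nbrs[[best]]
    if (is.null(cur$edge.length)) {
      cur$edge.length <- rep(mean_edge, nrow(cur$edge))
    }
    cur_ll <- lls[best]
    moves <- moves + 1
  }
  list(tree = cur, loglik = cur_ll, n_moves = moves)
}

#' Bootstrap majority-rule consensus tree
#'
#' Resamples alignment columns with replacement, builds a tree per
#' pseudoreplicate (NJ on T3P distances, optionally polished by NNI),
#' and reports the >= `support_floor`% majority-rule consensus with
#' percent supports on internal nodes.
#'
#' @param aln a `hel_alignment`.
#' @param model a [phylo_model()].
#' @param n_reps number of pseudoreplicates (>= 10).
#' @param support_floor percent support below which edges collapse.
#' @param seed integer seed for reproducibility.
#' @param search `"nj"` or `"nj+nni"`.
#' @return a `phylo` consensus tree with `node.label` percent supports.
#' @export
bootstrap_consensus <- function(aln, model = phylo_model(), n_reps = 1000,
                                support_floor = 50, seed = NULL,
                                search = c("nj", "nj+nni")) {
  search <- match.arg(search)
  if (n_reps < 10) abort("n_reps must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  base <- complete_deletion(aln)
  mat <- alignment_matrix(base)
  L <- ncol(mat)
  if (L == 0) abort("no gap-free columns to resample")
  trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- new_alignment(base$id,
                             apply(mat[, cols, drop = FALSE], 1, paste,
                                   collapse = ""))
    d <- t3p_matrix(rep_aln, model)
    # saturated pairs in a replicate: cap at the largest finite distance
    if (any(is.na(d))) {
      mx <- max(d, na.rm = TRUE)
      d[is.na(d)] <- mx * 1.5
    }
    tr <- nj_tree(d)
    if (search == "nj+nni") tr <- nni_search(tr, rep_aln, model)$tree
    trees[[r]] <- tr
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = max(support_floor, 50) / 100)
  counts <- ape::prop.clades(cons, part = ape::prop.part(trees),
                             rooted = FALSE)
  counts[is.na(counts)] <- 0
  cons$node.label <- as.character(round(100 * counts / n_reps, 1))
  cons
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees have different leaf sets")
  }
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}
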