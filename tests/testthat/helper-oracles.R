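# Independent reference implementations used as oracles. These are
# deliberately written in a different style from the package internals
# (memoized recursion / explicit enumeration in R vs iterative C++ DP).

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# --- alignment score oracles (gap of length L costs open + L*ext) ----------

oracle_global_score <- function(a, b, match, mismatch, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, st) {
    key <- paste(i, j, st)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    if (i > na && j > nb) {
      res <- 0
    } else {
      best <- -Inf
      if (i <= na && j <= nb) {
        s <- if (av[i] == bv[j]) match else mismatch
        best <- max(best, s + rec(i + 1, j + 1, 0L))
      }
      if (i <= na) {
        best <- max(best, -(ext + if (st == 1L) 0 else open) +
                      rec(i + 1, j, 1L))
      }
      if (j <= nb) {
        best <- max(best, -(ext + if (st == 2L) 0 else open) +
                      rec(i, j + 1, 2L))
      }
      res <- best
    }
    memo[[key]] <- res
    res
  }
  rec(1L, 1L, 0L)
}

oracle_local_score <- function(a, b, match, mismatch, open, ext) {
  # best over all start points, stopping allowed anywhere (suffix form)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, st) {
    key <- paste(i, j, st)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- 0
    if (i <= na && j <= nb) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0L))
    }
    if (i <= na) {
      best <- max(best, -(ext + if (st == 1L) 0 else open) +
                    rec(i + 1, j, 1L))
    }
    if (j <= nb) {
      best <- max(best, -(ext + if (st == 2L) 0 else open) +
                    rec(i, j + 1, 2L))
    }
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) best <- max(best, rec(i, j, 0L))
  }
  best
}

# --- hairpin free-energy oracle --------------------------------------------

# published unified duplex stack energies, independent named-vector form
oracle_stacks <- c(AA = -1.00, AT = -0.88, TA = -0.58, CA = -1.45,
                   GT = -1.44, CT = -1.28, GA = -1.30, CG = -2.17,
                   GC = -2.24, GG = -1.84, TT = -1.00, TG = -1.45,
                   AC = -1.44, AG = -1.28, TC = -1.30, CC = -1.84)

oracle_hairpin <- function(s, min_stem = 4, max_stem = 25,
                           max_mismatch = 2, min_loop = 3, max_loop = 30,
                           loop_init = 3.5, loop_per_nt = 0.35,
                           mm_pen = 0.5) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(toupper(s), "")[[1]]
  n <- length(ch)
  best <- Inf; found <- FALSE
  for (i in seq_len(n)) {
    for (L in min_stem:max_stem) {
      e <- i + L - 1
      if (e > n) break
      for (loop in min_loop:max_loop) {
        jend <- e + loop + L
        if (jend > n) break
        pair <- vapply(0:(L - 1), function(k) {
          a <- ch[i + k]; b <- ch[jend - k]
          a %in% names(comp) && b %in% names(comp) && comp[[b]] == a
        }, logical(1))
        mm <- sum(!pair)
        if (mm > max_mismatch || !pair[1] || !pair[L]) next
        dg <- loop_init + loop_per_nt * (loop - min_loop) + mm_pen * mm
        for (k in seq_len(L - 1)) {
          if (pair[k] && pair[k + 1]) {
            dg <- dg + oracle_stacks[[paste0(ch[i + k - 1], ch[i + k])]]
          }
        }
        if (dg < best) { best <- dg; found <- TRUE }
      }
    }
  }
  if (found) best else NA_real_
}

# --- pruning likelihood oracle ---------------------------------------------

oracle_expm <- function(Q, t) {
  # scaling-and-squaring Taylor series, independent of the eigen route
  k <- 12L
  A <- Q * t / 2^k
  P <- diag(4) + A + A %*% A / 2 + A %*% A %*% A / 6 +
    A %*% A %*% A %*% A / 24
  for (s in seq_len(k)) P <- P %*% P
  P
}

oracle_loglik <- function(tree, aln, model) {
  if (is.null(model$gc_content)) {
    model$gc_content <- mean(helhunt:::alignment_matrix(aln) %in% c("C", "G"))
  }
  rm <- t3p_rate_matrix(model)
  rates <- gamma_category_rates(model$gamma_shape, model$n_rate_categories)
  codes <- helhunt:::aln_codes(aln)
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  internals <- sort(unique(edge[edge[, 1] > ntip, 1]))
  root <- ntip + 1L
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  total <- 0
  for (site in seq_len(ncol(codes))) {
    sl <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(edge)), function(e) {
        oracle_expm(rm$Q, tree$edge.length[e] * r)
      })
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        state <- integer(max(edge))
        state[internals] <- grid[g, ]
        for (tp in seq_len(ntip)) {
          state[tp] <- codes[tree$tip.label[tp], site]
        }
        pr <- unname(rm$pi[state[root]])
        for (e in seq_len(nrow(edge))) {
          pr <- pr * Ps[[e]][state[edge[e, 1]], state[edge[e, 2]]]
        }
        lik <- lik + pr
      }
      sl <- sl + lik / length(rates)
    }
    total <- total + log(sl)
  }
  total
}

# --- Robinson-Foulds bipartition oracle ------------------------------------

oracle_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(edge[edge[, 1] == node, 2], tips_below))
  }
  out <- character(0)
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2]
    if (child <= ntip) next
    side <- sort(tips_below(child))
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    other <- sort(setdiff(tree$tip.label, side))
    canon <- if (min(side) < min(other)) side else other
    out <- c(out, paste(canon, collapse = "|"))
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}
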