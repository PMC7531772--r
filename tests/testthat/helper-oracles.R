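# Independent oracles and small fixture builders used across the suite.
# Every oracle here is written from the definition of the quantity it
# checks, sharing no code with the package internals.

# Minimum number of losses over ALL labelings of internal nodes with at
# most one gain (a 0->1 edge transition, or origination at the root when
# the root is labelled 1).  Pure enumeration over the 2^m internal
# labelings; tip states are fixed.
brute_force_dollo_losses <- function(tree, tip_states) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  edges <- tree$edge
  root <- n + 1L
  masks <- 0:(2^m - 1)
  internal <- vapply(masks, function(mk) as.integer(intToBits(mk))[seq_len(m)],
                     integer(m))
  internal <- matrix(internal, nrow = m)         # m x 2^m labelings
  ST <- rbind(matrix(tip_states, nrow = n, ncol = ncol(internal)), internal)
  P <- ST[edges[, 1L], , drop = FALSE]
  C <- ST[edges[, 2L], , drop = FALSE]
  gains <- colSums(P == 0L & C == 1L) + ST[root, ]
  losses <- colSums(P == 1L & C == 0L)
  ok <- gains <= 1L
  if (!any(ok)) return(NA_integer_)
  min(losses[ok])
}

# Random binary rooted tree with uniform branch lengths, labelled A, B, ...
random_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, tip.label = paste0("s", seq_len(n_tips)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 2)
  tr
}

# Root-to-MRCA depth of a pair of tips by explicit path traversal.
path_mrca_depth <- function(tree, tip_i, tip_j) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    parent[tree$edge[k, 2L]] <- tree$edge[k, 1L]
    elen[tree$edge[k, 2L]] <- tree$edge.length[k]
  }
  root <- n + 1L
  path_to_root <- function(v) {
    out <- v
    while (v != root) {
      v <- parent[v]
      out <- c(out, v)
    }
    out
  }
  i <- match(tip_i, tree$tip.label)
  j <- match(tip_j, tree$tip.label)
  anc <- intersect(path_to_root(i), path_to_root(j))
  mrca <- anc[1L]  # paths are listed tipward -> rootward
  depth <- 0
  v <- mrca
  while (v != root) {
    depth <- depth + elen[v]
    v <- parent[v]
  }
  depth
}

# Exhaustive Fisher-Pitman p-value straight from the definition: loop over
# every assignment of na pooled values to group A.
enumerate_fisher_pitman <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  t_obs <- mean(a) - mean(b)
  splits <- utils::combn(n, na)
  stats <- apply(splits, 2, function(ix) {
    mean(pooled[ix]) - mean(pooled[-ix])
  })
  mean(abs(stats) >= abs(t_obs) - 1e-12)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every split of
# the pooled ranks (tie-free inputs).  Two-sided convention: twice the
# smaller tail of the (symmetric) null rank-sum distribution, capped at 1.
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  rk <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(rk[seq_len(nx)])
  splits <- utils::combn(length(pooled), nx)
  w_null <- apply(splits, 2, function(ix) sum(rk[ix]))
  lower <- mean(w_null <= w_obs)
  upper <- mean(w_null >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Ultrametric star phylogeny with n tips of equal height.
star_tree <- function(n, height = 1) {
  tr <- ape::stree(n, type = "star", tip.label = paste0("s", seq_len(n)))
  tr$edge.length <- rep(height, nrow(tr$edge))
  tr
}

# Small tagged count matrix fixture.
toy_counts <- function() {
  m <- matrix(c(1L, 3L, 0L, 2L), nrow = 2,
              dimnames = list(c("tA", "tB"), c("OG1", "OG2")))
  count_matrix(m, tags = list(focal = c("OG1", "OG2")))
}
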