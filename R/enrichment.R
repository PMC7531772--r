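# Clade-wise enrichment/depletion testing of orthogroup counts.

#' Fisher-Pitman two-sample permutation test
#'
#' Tests whether two groups of values differ in mean by permuting group
#' labels.  The statistic is `mean(a) - mean(b)`.  When the number of
#' distinct group assignments `choose(n, |a|)` is at most `exact_limit`,
#' all assignments are enumerated and the p-value is the exact proportion
#' of assignments whose |statistic| reaches the observed one; otherwise a
#' seeded Monte-Carlo permutation p-value with the add-one correction
#' `(#{|T_perm| >= |T_obs|} + 1) / (B + 1)` is returned.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param n_perm Number of Monte-Carlo permutations (>= 99).
#' @param seed Seed for the Monte-Carlo branch.
#' @param exact_limit Enumerate exhaustively when `choose(n, |a|)` does not
#'   exceed this (default 20000).
#' @return List with `statistic`, `p_value`, `method` (`"exact"` or
#'   `"monte-carlo"`) and `n_perm` (number of assignments evaluated).
#' @export
fisher_pitman <- function(a, b, n_perm = 9999, seed = NULL,
                          exact_limit = 20000) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (n_perm < 99) stop("n_perm must be >= 99")
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  nb <- length(b)
  t_obs <- mean(a) - mean(b)
  eps <- 1e-12 * (1 + abs(t_obs))
  n_assign <- choose(n, na)
  if (n_assign <= exact_limit) {
    idx <- utils::combn(n, na)
    sums <- colSums(matrix(pooled[idx], nrow = na))
    tot <- sum(pooled)
    tstat <- sums / na - (tot - sums) / nb
    p <- mean(abs(tstat) >= abs(t_obs) - eps)
    list(statistic = t_obs, p_value = p, method = "exact", n_perm = n_assign)
  } else {
    tperm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        s <- sum(pooled[sample.int(n, na)])
        s / na - (sum(pooled) - s) / nb
      }, numeric(1))
    })
    p <- (sum(abs(tperm) >= abs(t_obs) - eps) + 1) / (n_perm + 1)
    list(statistic = t_obs, p_value = p, method = "monte-carlo", n_perm = n_perm)
  }
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1
#' and mapped back to the input order.  NA p-values propagate as NA.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Clade-wise per-orthogroup enrichment scan
#'
#' Runs one Fisher-Pitman test per orthogroup, comparing per-taxon gene
#' counts between two (possibly composite) clade groups, then adjusts
#' across orthogroups by Benjamini-Hochberg.  Exact enumeration is used
#' when feasible; otherwise all orthogroups share one seeded set of
#' Monte-Carlo label permutations (taxa are the permutation units).
#'
#' @param m A [count_matrix()].
#' @param partition A [clade_partition()].
#' @param clade_a,clade_b Clade name(s) from the partition; `clade_a` may
#'   be composite (e.g. the two non-molting bilaterian clades pooled
#'   against Ecdysozoa).
#' @param n_perm Monte-Carlo permutations (default 9999).
#' @param seed Seed for the Monte-Carlo branch.
#' @param alpha FDR level for the significance flag (default 0.1).
#' @param orthogroups Subset of orthogroup IDs to test (default all), or a
#'   tag name on `m`.
#' @param exact_limit As in [fisher_pitman()].
#' @return Data frame of class `enrichment_scan`: per orthogroup the group
#'   means, statistic (mean A - mean B), permutation p, BH q, direction
#'   (`"enriched_in_A"` / `"depleted_in_A"` / `"none"`), an `all_zero`
#'   flag, and `significant = q < alpha`.
#' @export
clade_enrichment_scan <- function(m, partition, clade_a, clade_b,
                                  n_perm = 9999, seed = NULL, alpha = 0.1,
                                  orthogroups = NULL, exact_limit = 20000) {
  bad <- setdiff(c(clade_a, clade_b), names(partition))
  if (length(bad)) stop("unknown clade(s): ", paste(bad, collapse = ", "))
  if (length(intersect(clade_a, clade_b))) stop("clades A and B overlap")
  taxa_a <- intersect(unlist(partition[clade_a], use.names = FALSE), rownames(m))
  taxa_b <- intersect(unlist(partition[clade_b], use.names = FALSE), rownames(m))
  if (length(taxa_a) < 2L || length(taxa_b) < 2L) {
    stop("each clade group needs >= 2 taxa present in the count matrix")
  }
  og <- if (is.null(orthogroups)) colnames(m) else {
    if (length(orthogroups) == 1L && orthogroups %in% names(count_tags(m))) {
      count_tags(m)[[orthogroups]]
    } else orthogroups
  }
  if (length(og) == 0L) stop("no orthogroups to test")
  X <- t(unclass(m)[c(taxa_a, taxa_b), og, drop = FALSE])  # og x taxa
  na <- length(taxa_a)
  nb <- length(taxa_b)
  n <- na + nb
  mean_a <- rowMeans(X[, seq_len(na), drop = FALSE])
  mean_b <- rowMeans(X[, na + seq_len(nb), drop = FALSE])
  t_obs <- mean_a - mean_b
  eps <- 1e-12 * (1 + abs(t_obs))

  n_assign <- choose(n, na)
  if (n_assign <= exact_limit) {
    idx <- utils::combn(n, na)
    W <- matrix(-1 / nb, n, ncol(idx))
    W[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = na))] <- 1 / na
    S <- X %*% W
    p <- rowMeans(abs(S) >= abs(t_obs) - eps)
    method <- "exact"
    B <- n_assign
  } else {
    idx <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample.int(n, na), integer(na))
    })
    W <- matrix(-1 / nb, n, n_perm)
    W[cbind(as.vector(idx), rep(seq_len(n_perm), each = na))] <- 1 / na
    S <- X %*% W
    p <- (rowSums(abs(S) >= abs(t_obs) - eps) + 1) / (n_perm + 1)
    method <- "monte-carlo"
    B <- n_perm
  }
  all_zero <- mean_a == 0 & mean_b == 0
  p[all_zero] <- 1
  q <- bh_fdr(p)
  out <- data.frame(
    orthogroup = og,
    mean_a = mean_a,
    mean_b = mean_b,
    statistic = t_obs,
    p = p,
    q = q,
    direction = ifelse(t_obs > 0, "enriched_in_A",
                       ifelse(t_obs < 0, "depleted_in_A", "none")),
    all_zero = all_zero,
    significant = q < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "clade_a") <- clade_a
  attr(out, "clade_b") <- clade_b
  attr(out, "method") <- method
  attr(out, "n_perm") <- B
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_scan", "data.frame")
  out
}

#' Clade depletion log-ratio contrast
#'
#' For each orthogroup, the depletion statistic is the natural log of the
#' ratio of total gene counts in clade group A to clade group B, with a
#' pseudocount added to both totals so that orthogroups fully lost in one
#' clade (the phenomenon of interest) remain finite.  The focal set's
#' log-ratios are then compared with the background's by a two-sided
#' Wilcoxon rank-sum test (exact when both groups have at most 12 tie-free
#' values, otherwise the normal approximation with mid-ranks and tie
#' correction).  The reported `W` is the rank-sum of the focal group.
#'
#' @inheritParams clade_enrichment_scan
#' @param focal Tag name on `m` or character vector of focal orthogroup IDs.
#' @param pseudocount Positive pseudocount added to both clade totals
#'   (default 1); may be 0 only with `drop_zeros = TRUE`.
#' @param drop_zeros Drop orthogroups with zero total count in both groups
#'   before forming ratios (allows `pseudocount = 0`).
#' @return Object of class `depletion_result`: `table` (per-orthogroup
#'   totals, `d`, focal flag), `W` (focal rank-sum), `U` (Mann-Whitney
#'   statistic of the focal group), `p`, group sizes, and the settings.
#' @export
depletion_contrast <- function(m, partition, clade_a, clade_b,
                               focal = "focal", pseudocount = 1,
                               drop_zeros = FALSE) {
  bad <- setdiff(c(clade_a, clade_b), names(partition))
  if (length(bad)) stop("unknown clade(s): ", paste(bad, collapse = ", "))
  taxa_a <- intersect(unlist(partition[clade_a], use.names = FALSE), rownames(m))
  taxa_b <- intersect(unlist(partition[clade_b], use.names = FALSE), rownames(m))
  if (length(taxa_a) == 0L || length(taxa_b) == 0L) {
    stop("a clade group is absent from the count matrix")
  }
  if (pseudocount < 0 || (pseudocount == 0 && !drop_zeros)) {
    stop("pseudocount must be > 0 (or 0 with drop_zeros = TRUE)")
  }
  if (length(focal) == 1L && focal %in% names(count_tags(m))) {
    focal_ids <- count_tags(m)[[focal]]
  } else {
    focal_ids <- intersect(focal, colnames(m))
  }
  if (length(focal_ids) == 0L) stop("focal set is empty")
  tot_a <- colSums(unclass(m)[taxa_a, , drop = FALSE])
  tot_b <- colSums(unclass(m)[taxa_b, , drop = FALSE])
  keep <- if (drop_zeros) tot_a + tot_b > 0 else rep(TRUE, ncol(m))
  tab <- data.frame(
    orthogroup = colnames(m)[keep],
    total_a = tot_a[keep],
    total_b = tot_b[keep],
    d = log((tot_a[keep] + pseudocount) / (tot_b[keep] + pseudocount)),
    focal = colnames(m)[keep] %in% focal_ids,
    stringsAsFactors = FALSE, row.names = NULL)
  d_f <- tab$d[tab$focal]
  d_bg <- tab$d[!tab$focal]
  if (length(d_f) == 0L || length(d_bg) == 0L) {
    stop("need both focal and background orthogroups after filtering")
  }
  exact <- length(d_f) <= 12L && length(d_bg) <= 12L &&
    !anyDuplicated(c(d_f, d_bg))
  wt <- suppressWarnings(stats::wilcox.test(d_f, d_bg, exact = exact))
  nf <- length(d_f)
  structure(list(
    table = tab,
    W = unname(wt$statistic) + nf * (nf + 1) / 2,  # rank-sum convention
    U = unname(wt$statistic),
    p = wt$p.value,
    n_focal = nf,
    n_background = length(d_bg),
    pseudocount = pseudocount,
    exact = exact,
    clade_a = clade_a,
    clade_b = clade_b
  ), class = "depletion_result")
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf("Depletion log-ratio contrast: %d focal vs %d background orthogroups\n",
              x$n_focal, x$n_background))
  cat(sprintf("  Wilcoxon rank-sum W = %.0f, p = %.4g (%s)\n",
              x$W, x$p, if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}
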