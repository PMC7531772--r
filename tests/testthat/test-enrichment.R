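# Permutation tests, FDR control and the depletion contrast.

test_that("fisher_pitman exact mode matches exhaustive enumeration", {
  # identical groups: statistic 0, p = 1
  res <- fisher_pitman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$method, "exact")

  # fully separated: only the observed split and its mirror are as extreme
  res2 <- fisher_pitman(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res2$p_value, 2 / choose(6, 3))

  # random inputs against the independent enumeration oracle
  for (seed in 1:6) {
    set.seed(seed + 900)
    a <- rpois(sample(3:6, 1), 4); b <- rpois(sample(3:6, 1), 4)
    expect_equal(fisher_pitman(a, b)$p_value, enumerate_fisher_pitman(a, b))
  }

  expect_error(fisher_pitman(1, c(1, 2)), ">= 2")
  expect_error(fisher_pitman(c(1, 2), c(1, 2), n_perm = 50), ">= 99")
})

test_that("fisher_pitman Monte-Carlo agrees with exact within 3 SE", {
  set.seed(11)
  a <- rpois(6, 5); b <- rpois(6, 3)
  p_exact <- fisher_pitman(a, b)$p_value
  B <- 10000
  p_mc <- fisher_pitman(a, b, n_perm = B, seed = 77, exact_limit = 1)$p_value
  se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1 / B)
  # determinism under the seed
  expect_equal(p_mc,
               fisher_pitman(a, b, n_perm = B, seed = 77, exact_limit = 1)$p_value)
})

test_that("bh_fdr matches the step-up formula and is order-equivariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(sort(bh_fdr(p)), sort(bh_fdr(p[perm])))
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(bh_fdr(runif(50)) <= 1))
  # direct formula oracle
  q_oracle <- function(p) {
    m <- length(p); o <- order(p)
    q <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
    q[order(o)]
  }
  expect_equal(bh_fdr(p), q_oracle(p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_scan_fixture <- function(seed, n_a = 4, n_b = 4, n_og = 10,
                              mean_a = 5, mean_b = 5, n_dep = 0) {
  set.seed(seed)
  taxa <- c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b)))
  og <- paste0("OG", seq_len(n_og))
  lam <- matrix(mean_a, n_a + n_b, n_og)
  lam[(n_a + 1):(n_a + n_b), ] <- mean_b
  if (n_dep > 0) lam[(n_a + 1):(n_a + n_b), seq_len(n_dep)] <-
      lam[(n_a + 1):(n_a + n_b), seq_len(n_dep)] * 0.1
  m <- count_matrix(matrix(rpois(length(lam), lam), nrow = n_a + n_b,
                           dimnames = list(taxa, og)),
                    tags = list(focal = og[seq_len(max(n_dep, 1))]))
  part <- clade_partition(list(A = taxa[seq_len(n_a)],
                               B = taxa[(n_a + 1):(n_a + n_b)]))
  list(m = m, part = part)
}

test_that("clade_enrichment_scan: exchangeable null, antisymmetry, power", {
  # identical rows: nothing can be significant
  taxa <- paste0("t", 1:8)
  m <- count_matrix(matrix(3L, 8, 6, dimnames = list(taxa, paste0("OG", 1:6))))
  part <- clade_partition(list(A = taxa[1:4], B = taxa[5:8]))
  s <- clade_enrichment_scan(m, part, "A", "B", seed = 1)
  expect_equal(sum(s$significant), 0)
  expect_true(all(s$p == 1))

  # swapping clade labels flips directions, p unchanged (exact mode)
  fx <- make_scan_fixture(31, n_dep = 3)
  s1 <- clade_enrichment_scan(fx$m, fx$part, "A", "B", seed = 5)
  s2 <- clade_enrichment_scan(fx$m, fx$part, "B", "A", seed = 5)
  expect_equal(attr(s1, "method"), "exact")
  expect_equal(s1$p, s2$p)
  expect_equal(s1$statistic, -s2$statistic)
  flip <- c(enriched_in_A = "depleted_in_A", depleted_in_A = "enriched_in_A",
            none = "none")
  expect_equal(unname(flip[s1$direction]), s2$direction)

  # strong depletion is recovered with the right direction
  fx2 <- make_scan_fixture(32, mean_a = 10, mean_b = 10, n_dep = 3)
  s3 <- clade_enrichment_scan(fx2$m, fx2$part, "A", "B", seed = 6, alpha = 0.1)
  hit <- s3$orthogroup[s3$significant & s3$direction == "enriched_in_A"]
  expect_setequal(hit, paste0("OG", 1:3))

  # all-zero orthogroups are flagged with p = 1
  mz <- unclass(fx$m); mz[, 1] <- 0L
  sz <- clade_enrichment_scan(count_matrix(mz), fx$part, "A", "B", seed = 2)
  expect_true(sz$all_zero[1])
  expect_equal(sz$p[1], 1)

  expect_error(clade_enrichment_scan(fx$m, fx$part, "A", "C", seed = 1),
               "unknown clade")
  expect_error(clade_enrichment_scan(fx$m, fx$part, "A", "A", seed = 1),
               "overlap")
})

test_that("depletion_contrast computes log-ratios and the rank-sum contrast", {
  taxa <- paste0("t", 1:4)
  counts <- matrix(c(5, 5, 3, 2,    # OG1: A total 10, B total 5
                     4, 4, 4, 4),   # OG2: equal totals
                   nrow = 4,
                   dimnames = list(taxa, c("OG1", "OG2")))
  m <- count_matrix(counts, tags = list(focal = "OG1"))
  part <- clade_partition(list(A = taxa[1:2], B = taxa[3:4]))
  res <- depletion_contrast(m, part, "A", "B", focal = "focal")
  expect_equal(res$table$d[res$table$orthogroup == "OG1"], log(11 / 6))
  expect_equal(res$table$d[res$table$orthogroup == "OG2"], 0)
  expect_equal(res$pseudocount, 1)

  expect_error(depletion_contrast(m, part, "A", "B", focal = "focal",
                                  pseudocount = 0), "pseudocount")
})

test_that("depletion Wilcoxon matches the exact enumeration oracle", {
  # engineered d values: focal ranks (1,2,3) vs background (4,5,6)
  taxa <- c("a1", "a2", "b1", "b2")
  og <- paste0("OG", 1:6)
  tot_a <- c(1, 2, 3, 9, 14, 19)   # d = log((tot_a+1)/1), increasing
  counts <- rbind(tot_a, rep(0, 6), rep(0, 6), rep(0, 6))
  dimnames(counts) <- list(taxa, og)
  m <- count_matrix(counts, tags = list(focal = og[1:3]))
  part <- clade_partition(list(A = taxa[1:2], B = taxa[3:4]))
  res <- depletion_contrast(m, part, "A", "B", focal = "focal")
  expect_true(res$exact)
  expect_equal(res$W, 6)          # rank-sum of the focal group
  expect_equal(res$p, 0.1)        # 2 / C(6,3)
  d_f <- res$table$d[res$table$focal]
  d_b <- res$table$d[!res$table$focal]
  expect_equal(res$p, enumerate_wilcoxon_p(d_f, d_b))
})

test_that("exact Wilcoxon agrees with enumeration across small group sizes", {
  for (seed in 1:10) {
    set.seed(seed + 700)
    nf <- sample(2:7, 1); nb <- sample(2:7, 1)
    vals <- sample(1:50, nf + nb)   # distinct -> tie-free
    og <- paste0("OG", seq_len(nf + nb))
    counts <- rbind(vals, rep(0, nf + nb), rep(0, nf + nb), rep(0, nf + nb))
    dimnames(counts) <- list(c("a1", "a2", "b1", "b2"), og)
    m <- count_matrix(counts, tags = list(focal = og[seq_len(nf)]))
    part <- clade_partition(list(A = c("a1", "a2"), B = c("b1", "b2")))
    res <- depletion_contrast(m, part, "A", "B", focal = "focal")
    d_f <- res$table$d[res$table$focal]
    d_b <- res$table$d[!res$table$focal]
    expect_equal(res$p, enumerate_wilcoxon_p(d_f, d_b), tolerance = 1e-12)
  }
})
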