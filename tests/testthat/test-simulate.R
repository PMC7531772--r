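# Generators: determinism, structural invariants, and calibration.

test_that("Yule trees are ultrametric, deterministic, and height-calibrated", {
  t2 <- simulate_yule_tree(2, 1, seed = 1)
  d <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(d[1], d[2], tolerance = 1e-9)

  ta <- simulate_yule_tree(16, 1, seed = 99)
  tb <- simulate_yule_tree(16, 1, seed = 99)
  expect_identical(ape::write.tree(ta), ape::write.tree(tb))
  expect_false(identical(ape::write.tree(ta),
                         ape::write.tree(simulate_yule_tree(16, 1, seed = 100))))
  depths <- ape::node.depth.edgelength(ta)[seq_len(16)]
  expect_lt(max(depths) - min(depths), 1e-9)

  # E[height] for a pure-birth tree run from 2 to n lineages plus the final
  # stretch: sum_{k=2}^{n} 1/(b k)
  b <- 2; n <- 12; reps <- 400
  hts <- vapply(seq_len(reps), function(i) {
    max(ape::node.depth.edgelength(simulate_yule_tree(n, b, seed = 1e4 + i)))
  }, numeric(1))
  expected <- sum(1 / (b * (2:n)))
  se <- sd(hts) / sqrt(reps)
  expect_lt(abs(mean(hts) - expected), 4 * se)

  expect_error(simulate_yule_tree(1, 1, seed = 1), ">= 2")
})

test_that("Brownian simulation reproduces the analytic covariance", {
  tr <- simulate_yule_tree(6, 1, seed = 3)
  C <- vcv_matrix(tr, order = tr$tip.label)
  reps <- 1500
  Ysim <- vapply(seq_len(reps), function(i) {
    simulate_bm(tr, sigma2 = 2, lambda = 1, seed = 2e4 + i)[tr$tip.label]
  }, numeric(6))
  S <- tcrossprod(Ysim - rowMeans(Ysim)) / (reps - 1)
  # entrywise within ~4 SE of 2*C (SE of a covariance ~ sqrt(2/reps)*scale)
  scale <- 2 * max(C)
  expect_lt(max(abs(S - 2 * C)), 4 * sqrt(2 / reps) * scale)

  # lambda = 0: non-sister tips uncorrelated
  Y0 <- vapply(seq_len(reps), function(i) {
    simulate_bm(tr, sigma2 = 1, lambda = 0, seed = 3e4 + i)[tr$tip.label]
  }, numeric(6))
  S0 <- stats::cor(t(Y0))
  expect_lt(max(abs(S0[upper.tri(S0)])), 0.12)

  expect_identical(simulate_bm(tr, 1, 1, seed = 5), simulate_bm(tr, 1, 1, seed = 5))
  expect_error(simulate_bm(tr, sigma2 = 0, seed = 1), "sigma2")
})

test_that("Dollo character simulation respects the single-gain process", {
  tr <- simulate_yule_tree(12, 1, seed = 8)
  all1 <- simulate_dollo_characters(tr, 5, loss_rate = 0, seed = 1)
  expect_true(all(all1$matrix == 1L))
  expect_true(all(all1$truth$true_losses == 0))

  sim <- simulate_dollo_characters(tr, 200, loss_rate = 0.3, seed = 2)
  rec <- dollo_reconstruct(tr, sim$matrix)
  # parsimony reconstruction can never need more losses than truly occurred
  expect_true(all(rec$loss_count <= sim$truth$true_losses))

  expect_identical(simulate_dollo_characters(tr, 5, 0.2, seed = 9)$matrix,
                   simulate_dollo_characters(tr, 5, 0.2, seed = 9)$matrix)
})

test_that("reconstructed loss counts track the truth at moderate loss rates", {
  tr <- simulate_yule_tree(24, 1, seed = 13)
  # loss rate giving roughly one expected loss per character
  total_bl <- sum(tr$edge.length)
  rate <- 1 / total_bl
  sim <- simulate_dollo_characters(tr, 800, loss_rate = rate, seed = 21)
  rec <- dollo_reconstruct(tr, sim$matrix)
  informative <- colSums(sim$matrix) > 0
  m_true <- mean(sim$truth$true_losses[informative])
  m_rec <- mean(rec$loss_count[informative])
  expect_lt(abs(m_rec - m_true) / m_true, 0.15)
})

test_that("simulated count matrices carry the configured depletion", {
  cfg <- sim_config(seed = 5, n_taxa = 24, loss_clade_size = 8, n_focal = 30,
                    n_background = 60, delta = 0.25, depleted_fraction = 1,
                    linkage_beta = 0, genome_effect = 0, genome_shift = 0,
                    mu_sdlog = 0, base_mean = 6)
  d <- simulate_dataset(cfg)
  loss <- d$partition$loss_clade
  ret <- d$partition$retained_clade
  dep <- d$truth$orthogroup[d$truth$depleted]
  m <- unclass(d$counts)
  ratio <- mean(m[loss, dep]) / mean(m[ret, dep])
  # Poisson mean ratio ~ delta
  se <- sqrt(1 / sum(m[loss, dep]) + 1 / sum(m[ret, dep])) * ratio
  expect_lt(abs(ratio - 0.25), 4 * se + 0.02)
  # delta = 0 would zero the loss clade entirely (structural zeros)
  cfg0 <- sim_config(seed = 6, n_taxa = 12, loss_clade_size = 4, n_focal = 10,
                     n_background = 10, delta = 1e-9, depleted_fraction = 1)
  d0 <- simulate_dataset(cfg0)
  dep0 <- d0$truth$orthogroup[d0$truth$depleted]
  expect_true(all(unclass(d0$counts)[d0$partition$loss_clade, dep0] == 0L))
})

test_that("generated objects satisfy their type invariants and are reproducible", {
  cfg <- sim_config(seed = 17)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(unclass(d1$counts), unclass(d2$counts))
  expect_identical(d1$genome_size, d2$genome_size)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))

  expect_s3_class(d1$counts, "count_matrix")
  expect_equal(sort(rownames(d1$counts)), sort(d1$tree$tip.label))
  expect_equal(length(count_tags(d1$counts)$focal), 59)
  expect_equal(ncol(d1$counts), 559)
  expect_true(all(d1$domains >= 0))
  expect_true(all(d1$domains[, "p53"] >= 1))
  # architectures tabulate back to the profile
  expect_equal(tabulate_domain_counts(d1$architectures), d1$domains[order(rownames(d1$domains)), ])
  # gene set: mapped genes resolve onto the focal set, surjectively
  mapped <- d1$gene_set$orthogroup[d1$gene_set$orthogroup != "UNMAPPED"]
  expect_setequal(unique(mapped), count_tags(d1$counts)$focal)
  expect_equal(sum(d1$gene_set$orthogroup == "UNMAPPED"), 56)
  expect_equal(nrow(d1$gene_set), 137)
})

test_that("write_dataset emits files the readers round-trip", {
  cfg <- sim_config(seed = 23, n_taxa = 10, loss_clade_size = 4, n_focal = 6,
                    n_background = 10, n_genes = 12, n_unmapped = 3)
  d <- simulate_dataset(cfg)
  dir <- file.path(tempdir(), "simds")
  paths <- write_dataset(d, dir)
  tr <- read_newick(paths[["tree"]])
  expect_equal(sort(tr$tip.label), sort(d$tree$tip.label))
  m <- read_count_matrix(paths[["counts"]], taxa = tr$tip.label)
  expect_equal(unclass(m)[rownames(d$counts), colnames(d$counts)],
               unclass(d$counts), ignore_attr = TRUE)
  cp <- read_clade_partition(paths[["clades"]], tree = tr,
                             monophyly = "ignore")
  expect_setequal(cp$loss_clade, d$partition$loss_clade)
  arch <- read_domain_architectures(paths[["domains"]])
  expect_equal(tabulate_domain_counts(arch),
               d$domains[order(rownames(d$domains)), ])
  gs <- read_gene_set_map(paths[["gene_set"]])
  expect_equal(nrow(gs), 12)
})
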