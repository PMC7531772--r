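# Seeded generators for trees, traits, binary characters, domain profiles
# and count matrices with the statistical structure the analysis assumes.
# Every generator draws from a sub-stream derived from the run seed, so
# adding a generator never perturbs the others' output.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic dataset.  The
#' defaults emulate the scale and structure of a 29-genome metazoan
#' dataset with a 9-taxon gene-loss clade: 59 focal (apoptosis-like)
#' orthogroups plus 500 background orthogroups, clade-biased depletion on
#' half of the focal set, loss of the accessory domain types (TAD, TET,
#' SAM) in the loss clade, a Brownian genome-size covariate with a
#' clade-level downward shift, and a mild positive linkage between total
#' domain count and orthogroup size.
#'
#' @param seed Mandatory integer seed.
#' @param n_taxa Number of tips (default 29).
#' @param birth_rate Yule birth rate (default 1, time in units of 1/rate).
#' @param loss_clade_size Target tip count of the designated loss clade
#'   (default 9); the internal node whose tip count is closest is chosen.
#' @param n_focal,n_background Focal and background orthogroup counts
#'   (defaults 59 and 500).
#' @param base_mean Baseline Poisson mean per orthogroup (default 2);
#'   per-orthogroup means are drawn log-normally around it
#'   (`mu_sdlog`, default 0.5) to mimic between-family size variation.
#' @param mu_sdlog Log-scale SD of the per-orthogroup baseline means.
#' @param delta Clade depletion multiplier in `(0, 1]` applied to depleted
#'   focal orthogroups in loss-clade taxa (default 0.2; 1 = no depletion).
#' @param depleted_fraction Fraction of the focal set that is depleted
#'   (default 0.5).
#' @param domain_loss_prob Probability that a loss-clade taxon has lost
#'   each accessory domain type (default 0.9; the DNA-binding domain is
#'   always retained).
#' @param sigma2 Brownian variance of the genome-size covariate (default 1).
#' @param lambda Pagel's lambda of the covariate simulation (default 1).
#' @param linkage_beta Coefficient tying log orthogroup mean to a taxon's
#'   total domain count (default 0.05; 0 = no linkage).
#' @param genome_effect Coefficient tying log orthogroup mean to the
#'   centred genome-size covariate (default 0.3; 0 = no effect).
#' @param genome_shift Downward shift of the loss clade's genome-size
#'   covariate (default 0.5), emulating clade-wide genome reduction.
#' @param n_genes,n_unmapped Size of the emitted curated gene set and the
#'   number of its members left unmapped (defaults 137 and 56, so the
#'   mapped remainder is homologised onto the focal orthogroups
#'   many-to-one).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_taxa = 29L,
                       birth_rate = 1,
                       loss_clade_size = 9L,
                       n_focal = 59L,
                       n_background = 500L,
                       base_mean = 2,
                       mu_sdlog = 0.5,
                       delta = 0.2,
                       depleted_fraction = 0.5,
                       domain_loss_prob = 0.9,
                       sigma2 = 1,
                       lambda = 1,
                       linkage_beta = 0.05,
                       genome_effect = 0.3,
                       genome_shift = 0.5,
                       n_genes = 137L,
                       n_unmapped = 56L) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  stopifnot(n_taxa >= 4, birth_rate > 0,
            loss_clade_size >= 2, loss_clade_size <= n_taxa - 2,
            n_focal >= 1, n_background >= 0,
            base_mean > 0, mu_sdlog >= 0,
            delta > 0, delta <= 1,
            sigma2 > 0, genome_shift >= 0,
            n_genes >= 1, n_unmapped >= 0, n_unmapped < n_genes)
  stop_if_not_scalar_prob(depleted_fraction, "depleted_fraction")
  stop_if_not_scalar_prob(domain_loss_prob, "domain_loss_prob")
  stop_if_not_scalar_prob(lambda, "lambda")
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 birth_rate = birth_rate,
                 loss_clade_size = as.integer(loss_clade_size),
                 n_focal = as.integer(n_focal),
                 n_background = as.integer(n_background),
                 base_mean = base_mean, mu_sdlog = mu_sdlog, delta = delta,
                 depleted_fraction = depleted_fraction,
                 domain_loss_prob = domain_loss_prob, sigma2 = sigma2,
                 lambda = lambda, linkage_beta = linkage_beta,
                 genome_effect = genome_effect, genome_shift = genome_shift,
                 n_genes = as.integer(n_genes),
                 n_unmapped = as.integer(n_unmapped)),
            class = "sim_config")
}

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Forward simulation: starting from two lineages at the root, waiting
#' times between speciations are exponential with rate (birth_rate x
#' current lineage count) and the splitting lineage is chosen uniformly;
#' after the n-th tip appears, one further waiting time at rate
#' `n * birth_rate` sets the present.  Deterministic under `seed`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with tips `t1 ... tn`.
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 2L) stop("n_taxa must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  with_seed(seed, {
    parent <- integer(0)
    btime <- c(0, 0)
    split_time <- rep(NA_real_, 2)
    children <- list(NULL, NULL)
    active <- c(1L, 2L)
    t_now <- 0
    nxt <- 3L
    while (length(active) < n_taxa) {
      k <- length(active)
      t_now <- t_now + stats::rexp(1, rate = birth_rate * k)
      i <- active[sample.int(k, 1L)]
      split_time[i] <- t_now
      kids <- c(nxt, nxt + 1L)
      children[[i]] <- kids
      for (kid in kids) {
        btime[kid] <- t_now
        split_time[kid] <- NA_real_
        children[kid] <- list(NULL)
      }
      active <- c(active[active != i], kids)
      nxt <- nxt + 2L
    }
    t_end <- t_now + stats::rexp(1, rate = birth_rate * n_taxa)
    tips <- sort(active)
    tip_name <- stats::setNames(paste0("t", seq_along(tips)), tips)
    nwk <- function(v) {
      len <- (if (is.null(children[[v]])) t_end else split_time[v]) - btime[v]
      if (is.null(children[[v]])) {
        sprintf("%s:%.12g", tip_name[[as.character(v)]], len)
      } else {
        sprintf("(%s,%s):%.12g", nwk(children[[v]][1L]), nwk(children[[v]][2L]), len)
      }
    }
    tree <- ape::read.tree(text = sprintf("(%s,%s);", nwk(1L), nwk(2L)))
    tree
  })
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Draws one realisation from `Normal(0, sigma2 * lambda-transform(C))`
#' where `C` is the tree's Brownian covariance.  `lambda = 0` yields
#' phylogenetically independent tips with the correct tip variances.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param sigma2 Brownian variance per unit branch length (> 0).
#' @param lambda Pagel's lambda of the generating model, in `[0, 1]`.
#' @param seed Integer seed.
#' @return Named numeric vector over the tips.
#' @export
simulate_bm <- function(tree, sigma2 = 1, lambda = 1, seed = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  stop_if_not_scalar_prob(lambda, "lambda")
  C <- ape::vcv(tree)
  V <- sigma2 * lambda_transform(C, lambda)
  R <- chol_or_stop(V, "lambda-transformed C")
  with_seed(seed, {
    z <- stats::rnorm(nrow(V))
    stats::setNames(drop(crossprod(R, z)), rownames(C))
  })
}

#' Simulate binary characters under a Dollo process
#'
#' Each character originates at the root (or at an internal node sampled
#' uniformly, with `gain = "random"`), then is lost independently along
#' each descendant branch with probability `1 - exp(-loss_rate * length)`;
#' descendants of a lost lineage stay absent.  The true histories are
#' recorded for recovery scoring.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param n_chars Number of characters.
#' @param loss_rate Loss rate per unit branch length (>= 0).
#' @param seed Integer seed.
#' @param gain `"root"` (default) or `"random"` internal gain node.
#' @return List with `matrix` (tips x characters 0/1) and `truth` (data
#'   frame: character, gain node number, true loss count).
#' @export
simulate_dollo_characters <- function(tree, n_chars, loss_rate, seed = NULL,
                                      gain = c("root", "random")) {
  gain <- match.arg(gain)
  if (loss_rate < 0) stop("loss_rate must be >= 0")
  tree <- validate_phylogeny(tree, force_rooted = TRUE)
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  root <- n + 1L
  pre <- stats::reorder(tree, "postorder")$edge
  pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]  # preorder edges
  elen <- stats::reorder(tree, "postorder")$edge.length[rev(seq_len(nrow(pre)))]
  desc <- tip_descendants(tree)
  with_seed(seed, {
    mat <- matrix(0L, n, n_chars, dimnames = list(tree$tip.label,
                                                  paste0("char", seq_len(n_chars))))
    truth <- data.frame(character = colnames(mat),
                        gain_node = integer(n_chars),
                        true_losses = integer(n_chars),
                        stringsAsFactors = FALSE)
    for (j in seq_len(n_chars)) {
      g <- if (gain == "root") root else n + sample.int(m, 1L)
      state <- integer(n + m)
      state[g] <- 1L
      losses <- 0L
      for (k in seq_len(nrow(pre))) {
        p <- pre[k, 1L]; ch <- pre[k, 2L]
        if (state[p] == 1L) {
          lost <- stats::runif(1) < 1 - exp(-loss_rate * elen[k])
          if (lost) losses <- losses + 1L else state[ch] <- 1L
        }
      }
      mat[, j] <- state[seq_len(n)]
      truth$gain_node[j] <- g
      truth$true_losses[j] <- losses
    }
    list(matrix = mat, truth = truth)
  })
}

# Pick the internal node whose tip count is closest to `target`, excluding
# the root (ties broken toward the smaller node number).
pick_loss_clade <- function(tree, target) {
  n <- ape::Ntip(tree)
  desc <- tip_descendants(tree)
  root <- n + 1L
  cand <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  sizes <- lengths(desc[cand])
  node <- cand[which.min(abs(sizes - target))]
  tree$tip.label[desc[[node]]]
}

#' Simulate a full synthetic dataset
#'
#' Generates every input the pipeline consumes, with known truth: an
#' ultrametric Yule tree; a two-clade partition (`loss_clade` vs
#' `retained_clade`); per-taxon domain architectures in which loss-clade
#' taxa have typically lost the accessory domains; a genome-size covariate
#' evolving by Brownian motion with a clade shift; and an orthogroup count
#' matrix `N_gt ~ Poisson(mu_g * exp(beta * D_t + gamma * g_t) * m_gt)`
#' where `m_gt = delta` for depleted focal orthogroups in loss-clade taxa
#' and 1 otherwise.  A curated gene set mapping many-to-one onto the focal
#' orthogroups is emitted for the bookkeeping stage.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset` with elements `tree`, `partition`,
#'   `counts` (tagged [count_matrix()]), `domains` (profile matrix),
#'   `architectures` (locus-level records), `genome_size`, `gene_set`,
#'   `truth` (per-orthogroup depletion truth table) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tree <- simulate_yule_tree(cfg$n_taxa, cfg$birth_rate,
                             seed = derive_seed(cfg$seed, "tree"))
  loss_tips <- pick_loss_clade(tree, cfg$loss_clade_size)
  partition <- clade_partition(list(loss_clade = loss_tips,
                                    retained_clade = setdiff(tree$tip.label,
                                                             loss_tips)),
                               tree = tree, monophyly = "ignore")

  # domain architectures: the DNA-binding domain is universal; accessory
  # domains are carried by retained taxa and mostly lost in the loss clade
  vocab <- c("TAD", "p53", "TET", "SAM")
  domains <- with_seed(derive_seed(cfg$seed, "domains"), {
    taxa <- tree$tip.label
    prof <- matrix(0L, length(taxa), 4L, dimnames = list(taxa, vocab))
    for (tx in taxa) {
      in_loss <- tx %in% loss_tips
      present <- c(TAD = TRUE, p53 = TRUE, TET = TRUE, SAM = TRUE)
      if (in_loss) {
        present[c("TAD", "TET", "SAM")] <-
          stats::runif(3) > cfg$domain_loss_prob
      }
      counts <- ifelse(present, 1L + stats::rpois(4, 1), 0L)
      counts[2L] <- max(counts[2L], 1L)  # p53 domain always present
      prof[tx, ] <- counts
    }
    prof
  })
  architectures <- profile_to_architectures(domains)

  genome_size <- simulate_bm(tree, sigma2 = cfg$sigma2, lambda = cfg$lambda,
                             seed = derive_seed(cfg$seed, "genome_size"))
  genome_size[loss_tips] <- genome_size[loss_tips] - cfg$genome_shift

  og_ids <- sprintf("OG%06d", seq_len(cfg$n_focal + cfg$n_background))
  focal_ids <- og_ids[seq_len(cfg$n_focal)]
  counts_and_truth <- with_seed(derive_seed(cfg$seed, "counts"), {
    n_dep <- round(cfg$depleted_fraction * cfg$n_focal)
    depleted <- sort(sample(focal_ids, n_dep))
    mu <- stats::rlnorm(length(og_ids), meanlog = log(cfg$base_mean),
                        sdlog = cfg$mu_sdlog)
    names(mu) <- og_ids
    D_t <- rowSums(domains)[tree$tip.label]
    g_t <- genome_size[tree$tip.label] - mean(genome_size)
    taxon_factor <- exp(cfg$linkage_beta * D_t + cfg$genome_effect * g_t)
    lam <- outer(taxon_factor, mu)  # taxa x orthogroups
    dep_mask <- outer(tree$tip.label %in% loss_tips, og_ids %in% depleted, `&`)
    lam[dep_mask] <- lam[dep_mask] * cfg$delta
    counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                     dimnames = list(tree$tip.label, og_ids))
    truth <- data.frame(orthogroup = og_ids,
                        focal = og_ids %in% focal_ids,
                        depleted = og_ids %in% depleted,
                        mu = unname(mu),
                        delta = ifelse(og_ids %in% depleted, cfg$delta, 1),
                        stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
  counts <- count_matrix(counts_and_truth$counts,
                         tags = list(focal = focal_ids))

  gene_set <- with_seed(derive_seed(cfg$seed, "gene_set"), {
    n_mapped <- cfg$n_genes - cfg$n_unmapped
    targets <- if (n_mapped >= cfg$n_focal) {
      # surjective many-to-one map onto the focal set
      c(focal_ids, sample(focal_ids, n_mapped - cfg$n_focal, replace = TRUE))
    } else {
      sample(focal_ids, n_mapped)
    }
    data.frame(gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
               orthogroup = c(targets, rep("UNMAPPED", cfg$n_unmapped)),
               stringsAsFactors = FALSE)
  })

  structure(list(tree = tree, partition = partition, counts = counts,
                 domains = domains, architectures = architectures,
                 genome_size = genome_size, gene_set = gene_set,
                 truth = counts_and_truth$truth, config = cfg),
            class = "sim_dataset")
}

# Pack a per-taxon domain-count profile into locus-level architecture
# records (first locus gets one copy of each present domain; extra copies
# become additional loci), so that tabulate_domain_counts() round-trips.
profile_to_architectures <- function(profile) {
  rows <- list()
  for (tx in rownames(profile)) {
    left <- profile[tx, ]
    locus <- 1L
    while (any(left > 0L)) {
      doms <- names(left)[left > 0L]
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, locus = sprintf("%s_locus%d", tx, locus),
        domains = paste(doms, collapse = ";"),
        evalue = NA_real_, stringsAsFactors = FALSE)
      left[doms] <- left[doms] - 1L
      locus <- locus + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to disk in the pipeline's file formats
#'
#' Emits the Newick tree, count-matrix TSV, domain-architecture TSV, clade
#' partition TSV, gene-set map TSV, a covariate TSV and the truth table.
#'
#' @param data A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tree = file.path(dir, "tree.nwk"),
    counts = file.path(dir, "counts.tsv"),
    domains = file.path(dir, "domains.tsv"),
    clades = file.path(dir, "clades.tsv"),
    gene_set = file.path(dir, "gene_set.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_newick(data$tree, paths[["tree"]])
  write_count_matrix(data$counts, paths[["counts"]])
  arch <- data$architectures
  utils::write.table(arch[order(arch$taxon, arch$locus),
                          c("taxon", "locus", "domains")],
                     paths[["domains"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_clade_partition(data$partition, paths[["clades"]])
  utils::write.table(data$gene_set, paths[["gene_set"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  cov <- data.frame(taxon = names(data$genome_size),
                    genome_size = unname(data$genome_size),
                    stringsAsFactors = FALSE)
  cov <- cov[order(cov$taxon), ]
  utils::write.table(cov, paths[["covariates"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
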