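# Orchestration: run every analysis stage over one dataset (simulated or
# read from files) and collect a machine-readable report.

default_pipeline_settings <- function() {
  list(clade_a = "retained_clade", clade_b = "loss_clade",
       focal_tag = "focal", fdr = 0.1, n_perm = 9999, cca_n_perm = 999,
       pseudocount = 1, transform = "log1p", adjust = "global-BH",
       binarize_threshold = 1)
}

# Read the five standard input files named in a config 'files' block.
load_pipeline_files <- function(files) {
  tree <- read_newick(files$tree)
  counts <- read_count_matrix(files$counts, taxa = tree$tip.label)
  partition <- read_clade_partition(files$clades, tree = tree,
                                    monophyly = "warn")
  arch <- read_domain_architectures(files$domains)
  domains <- tabulate_domain_counts(arch)
  gene_set <- if (!is.null(files$gene_set)) read_gene_set_map(files$gene_set)
  genome_size <- NULL
  if (!is.null(files$covariates)) {
    cov <- utils::read.delim(files$covariates, stringsAsFactors = FALSE)
    genome_size <- stats::setNames(cov[[2L]], cov[[1L]])
  }
  list(tree = tree, counts = counts, partition = partition,
       domains = domains, gene_set = gene_set, genome_size = genome_size)
}

#' Run the full comparative pipeline
#'
#' Executes, in order: curated-gene-set mapping, the clade enrichment scan,
#' the depletion log-ratio contrast, phylogenetic signal estimation
#' (Blomberg's K and Pagel's lambda) for repertoire size and genome size,
#' the uncorrected genome-size regression, Dollo reconstruction of domain
#' and orthogroup presence, the CCA permutation test, and the PGLS
#' domain-vs-orthogroup scan.  All randomness derives from `config$seed`
#' via per-stage sub-streams, so a rerun with the same config reproduces
#' the report exactly (timestamp aside).
#'
#' @param config Either a named list or the path to a YAML file.  Must
#'   contain `seed` and either a `simulate` block (arguments to
#'   [sim_config()] other than `seed`) or a `files` block naming `tree`,
#'   `counts`, `domains`, `clades` and optionally `gene_set` and
#'   `covariates`.  Optional settings: `clade_a`, `clade_b` (defaults
#'   `"retained_clade"` / `"loss_clade"`), `fdr` (0.1), `n_perm` (9999),
#'   `cca_n_perm` (999), `pseudocount` (1), `transform` (`"log1p"`),
#'   `adjust` (`"global-BH"`), `binarize_threshold` (1).
#' @param out_dir Optional directory for per-stage TSV/JSON outputs.
#' @param quiet Suppress per-stage progress messages.
#' @return A `pipeline_report` (nested list; see [render_report()] and
#'   [write_report()]).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must contain a 'seed'")
  cfg <- utils::modifyList(default_pipeline_settings(), config)
  seed <- as.integer(cfg$seed)
  say <- function(stage) if (!quiet) message("[", stage, "] ",
                                             format(Sys.time(), "%H:%M:%S"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(cfg$simulate)) {
    say("simulate")
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% seed
    data_cfg <- run_stage("simulate", do.call(sim_config, sim_args))
    dat <- run_stage("simulate", simulate_dataset(data_cfg))
    inputs <- list(mode = "simulated",
                   config_hash = sprintf("%08x", string_hash(
                     jsonlite::toJSON(unclass(data_cfg), auto_unbox = TRUE))))
    data <- list(tree = dat$tree, counts = dat$counts,
                 partition = dat$partition, domains = dat$domains,
                 gene_set = dat$gene_set, genome_size = dat$genome_size)
    truth <- dat$truth
  } else if (!is.null(cfg$files)) {
    say("load")
    data <- run_stage("load", load_pipeline_files(cfg$files))
    inputs <- list(mode = "files",
                   digests = lapply(cfg$files, hash_file))
    truth <- NULL
  } else {
    stop("config needs either a 'simulate' or a 'files' block")
  }

  report <- list(provenance = list(
    package = "phylorep",
    version = as.character(utils::packageVersion("phylorep")),
    seed = seed,
    config_hash = sprintf("%08x", string_hash(
      jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                       force = TRUE))),
    inputs = inputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))

  counts <- data$counts
  tag <- cfg$focal_tag

  # -- curated gene set mapping ------------------------------------------
  if (!is.null(data$gene_set)) {
    say("gene_set")
    mapped <- run_stage("gene_set", map_gene_set(data$gene_set, counts, tag = tag))
    counts <- mapped$matrix
    report$gene_set <- mapped$summary
  }
  if (!tag %in% names(count_tags(counts))) {
    stop("no focal orthogroup set: supply a gene_set or a tagged count matrix")
  }
  focal_ids <- count_tags(counts)[[tag]]

  # -- clade enrichment scan over the focal set --------------------------
  say("enrichment")
  enr <- run_stage("enrichment", clade_enrichment_scan(
    counts, data$partition, cfg$clade_a, cfg$clade_b,
    n_perm = cfg$n_perm, seed = derive_seed(seed, "enrichment"),
    alpha = cfg$fdr, orthogroups = tag))
  report$enrichment <- list(
    n_tested = nrow(enr),
    n_enriched_in_a = sum(enr$significant & enr$direction == "enriched_in_A"),
    n_enriched_in_b = sum(enr$significant & enr$direction == "depleted_in_A"),
    fdr = cfg$fdr,
    clade_a = paste(cfg$clade_a, collapse = "+"),
    clade_b = paste(cfg$clade_b, collapse = "+"),
    method = attr(enr, "method"))

  # -- depletion log-ratio contrast over all orthogroups -----------------
  say("depletion")
  dep <- run_stage("depletion", depletion_contrast(
    counts, data$partition, cfg$clade_a, cfg$clade_b, focal = tag,
    pseudocount = cfg$pseudocount))
  report$depletion <- list(W = dep$W, p = dep$p, n_focal = dep$n_focal,
                           n_background = dep$n_background,
                           pseudocount = dep$pseudocount, exact = dep$exact)

  # -- phylogenetic signal -----------------------------------------------
  say("signal")
  rep_size <- repertoire_size(counts, tag)
  sig_rep <- run_stage("signal", list(
    K = blomberg_k(rep_size, data$tree)$estimate,
    lambda = pagel_lambda(rep_size, data$tree)$estimate))
  report$signal <- list(repertoire = sig_rep)
  if (!is.null(data$genome_size)) {
    report$signal$genome_size <- run_stage("signal", list(
      K = blomberg_k(data$genome_size, data$tree)$estimate,
      lambda = pagel_lambda(data$genome_size, data$tree)$estimate))
  }

  # -- uncorrected genome-size regression --------------------------------
  if (!is.null(data$genome_size)) {
    say("ols")
    g <- data$genome_size[names(rep_size)]
    ols <- run_stage("ols", ols_r2(rep_size, g))
    report$ols <- list(slope = ols$slope, r2 = ols$r2, p = ols$p, n = ols$n)
  }

  # -- Dollo reconstructions ---------------------------------------------
  say("dollo")
  dom_bin <- (data$domains[data$tree$tip.label, , drop = FALSE] > 0) * 1L
  recon_dom <- run_stage("dollo", dollo_reconstruct(data$tree, dom_bin))
  og_bin <- binarize_counts(counts, cfg$binarize_threshold)[
    data$tree$tip.label, focal_ids, drop = FALSE]
  recon_og <- run_stage("dollo", dollo_reconstruct(data$tree, og_bin))
  root <- ape::Ntip(data$tree) + 1L
  loss_tips <- intersect(unlist(data$partition[cfg$clade_b], use.names = FALSE),
                         data$tree$tip.label)
  desc <- tip_descendants(data$tree)
  clade_b_nodes <- if (length(loss_tips) >= 1L) {
    mr <- mrca_node(data$tree, loss_tips)
    which(vapply(seq_along(desc), function(v) {
      all(data$tree$tip.label[desc[[v]]] %in% data$tree$tip.label[desc[[mr]]])
    }, logical(1)))
  } else integer(0)
  root_rep <- ancestral_repertoire(recon_og, root)
  weights <- apply(unclass(counts)[, focal_ids, drop = FALSE], 2, modal_count)
  root_total_weighted <- ancestral_repertoire(recon_og, root,
                                              weights = weights)$total
  og_losses <- unlist(recon_og$losses, use.names = FALSE)
  report$dollo <- list(
    domain_root_repertoire = ancestral_repertoire(recon_dom, root)$characters,
    domain_total_losses = sum(recon_dom$loss_count),
    orthogroup_root_repertoire_size = length(root_rep$characters),
    orthogroup_root_additive_total = root_total_weighted,
    orthogroup_total_losses = length(og_losses),
    orthogroup_losses_in_clade_b = sum(og_losses %in% clade_b_nodes))

  # -- CCA ----------------------------------------------------------------
  say("cca")
  Y <- unclass(counts)[data$tree$tip.label, focal_ids, drop = FALSE]
  X <- data$domains[data$tree$tip.label, , drop = FALSE]
  cca <- run_stage("cca", suppressWarnings(cca_permutation_test(
    Y, X, n_perm = cfg$cca_n_perm, seed = derive_seed(seed, "cca"))))
  report$cca <- list(F = cca$pseudo_F, p = cca$p,
                     df1 = cca$df[1], df2 = cca$df[2],
                     constrained_inertia = cca$fit$constrained_inertia,
                     total_inertia = cca$fit$total_inertia,
                     n_perm = cca$n_perm)

  # -- PGLS scan ----------------------------------------------------------
  say("pgls")
  scan <- run_stage("pgls", pgls_scan(
    counts, data$domains, genome_size = data$genome_size, tree = data$tree,
    focal = tag, transform = cfg$transform, adjust = cfg$adjust,
    alpha = cfg$fdr))
  report$pgls <- list(
    n_orthogroups = length(unique(scan$orthogroup)),
    n_significant = length(attr(scan, "significant_orthogroups")),
    alpha = cfg$fdr, transform = cfg$transform, adjust = cfg$adjust)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dep$table, file.path(out_dir, "depletion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(scan), file.path(out_dir, "pgls_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gain_loss_table(recon_og, file.path(out_dir, "dollo_orthogroups.tsv"))
    write_gain_loss_table(recon_dom, file.path(out_dir, "dollo_domains.tsv"))
    write_cca_scores(cca$fit, out_dir)
    if (!is.null(truth)) {
      utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_report(structure(report, class = "pipeline_report"),
                 file.path(out_dir, "report.json"))
  }
  structure(report, class = "pipeline_report")
}

# Most frequent non-zero count (smallest on ties); 1 when a column has no
# non-zero entries.  Used as the per-orthogroup weight for additive
# ancestral gene totals.
modal_count <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0L) return(1)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Serialise a pipeline report as JSON
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a pipeline report back from JSON
#'
#' @param path Path written by [write_report()].
#' @return A `pipeline_report`.
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "pipeline_report")
}

#' Render a pipeline report as human-readable text
#'
#' One headline line per stage with the run's numbers substituted; a stage
#' absent from the report is rendered as skipped, never an error.
#'
#' @param report A `pipeline_report`.
#' @return Character vector of lines.
#' @export
render_report <- function(report) {
  num <- function(x, d = 3) formatC(x, digits = d, format = "g")
  lines <- c(sprintf("phylorep pipeline report (version %s, seed %s)",
                     report$provenance$version %||% "?",
                     report$provenance$seed %||% "?"))
  lines <- c(lines, if (is.null(report$gene_set)) "gene set: stage skipped" else
    with(report$gene_set, sprintf(
      "gene set: %d curated genes; %d unmapped; %d mapped onto %d distinct orthogroups (%d sharing an orthogroup)",
      total, unmapped, mapped, distinct_orthogroups, genes_sharing_orthogroup)))
  lines <- c(lines, if (is.null(report$enrichment)) "enrichment: stage skipped" else
    with(report$enrichment, sprintf(
      "enrichment: %d of %d focal orthogroups enriched in %s and %d in %s (FDR < %g)",
      n_enriched_in_a, n_tested, clade_a, n_enriched_in_b, clade_b, fdr)))
  lines <- c(lines, if (is.null(report$depletion)) "depletion: stage skipped" else
    with(report$depletion, sprintf(
      "depletion: focal vs background log-ratio Wilcoxon W = %.0f, p = %s (%d focal, %d background)",
      W, num(p), n_focal, n_background)))
  lines <- c(lines, if (is.null(report$signal)) "signal: stage skipped" else {
    s <- sprintf("signal (repertoire size): K = %s, lambda = %s",
                 num(report$signal$repertoire$K),
                 num(report$signal$repertoire$lambda))
    if (!is.null(report$signal$genome_size)) {
      s <- c(s, sprintf("signal (genome size): K = %s, lambda = %s",
                        num(report$signal$genome_size$K),
                        num(report$signal$genome_size$lambda)))
    }
    s
  })
  lines <- c(lines, if (is.null(report$ols)) "ols: stage skipped" else
    with(report$ols, sprintf(
      "ols repertoire ~ genome size: r2 = %s, slope = %s, p = %s",
      num(r2), num(slope), num(p))))
  lines <- c(lines, if (is.null(report$dollo)) "dollo: stage skipped" else
    with(report$dollo, sprintf(
      "dollo: root repertoire %d orthogroups (additive total %.0f); %d losses, %d within the loss clade; domain losses %d",
      orthogroup_root_repertoire_size, orthogroup_root_additive_total,
      orthogroup_total_losses, orthogroup_losses_in_clade_b,
      domain_total_losses)))
  lines <- c(lines, if (is.null(report$cca)) "cca: stage skipped" else
    with(report$cca, sprintf("cca: F(%d, %d) = %s, p = %s",
                             df1, df2, num(F), num(p))))
  lines <- c(lines, if (is.null(report$pgls)) "pgls: stage skipped" else
    with(report$pgls, sprintf(
      "pgls: %d of %d focal orthogroups predicted by >= 1 domain (FDR < %g)",
      n_significant, n_orthogroups, alpha)))
  lines
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
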