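#' Read a rooted phylogeny from a Newick file
#'
#' Reads a single rooted Newick tree and validates it for downstream use:
#' unique non-empty tip labels, at least two tips, non-negative branch
#' lengths.  Square-bracket comments are stripped before parsing; quoted
#' labels are honoured; internal node labels are retained as annotations
#' (typically support values) and never interpreted as tips.
#'
#' @param path Path to a file containing one Newick string.
#' @param unit_branch_lengths If `TRUE`, a tree without branch lengths is
#'   accepted and every branch is assigned length 1.  Default `FALSE`
#'   (missing lengths are an error): the phylogenetic covariance structure
#'   is meaningless without real lengths.
#' @param force_rooted Accept a tree whose root is a polytomy as rooted.
#'   By default such trees are rejected because they are indistinguishable
#'   from unrooted trees, and both Dollo reconstruction and the Brownian
#'   covariance need a root.
#' @return An object of class `phylo` (see \pkg{ape}).
#' @export
read_newick <- function(path, unit_branch_lengths = FALSE, force_rooted = FALSE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read tree file: ", path)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\[[^]]*\\]", "", txt)
  if (!nzchar(gsub("\\s", "", txt))) stop("empty Newick file: ", path)
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string (", n_open, " '(' vs ",
         n_close, " ')')")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("failed to parse Newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("failed to parse Newick string in ", path)
  if (inherits(tree, "multiPhylo")) stop("file contains more than one tree: ", path)
  validate_phylogeny(tree, unit_branch_lengths = unit_branch_lengths,
                     force_rooted = force_rooted)
}

#' Write a phylogeny as Newick
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Validate the invariants required of every tree entering the pipeline.
validate_phylogeny <- function(tree, unit_branch_lengths = FALSE,
                               force_rooted = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  n <- ape::Ntip(tree)
  if (n < 2L) stop("tree has fewer than 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  if (is.null(tree$edge.length)) {
    if (!unit_branch_lengths) {
      stop("tree has no branch lengths; set unit_branch_lengths = TRUE to use 1.0")
    }
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!ape::is.rooted(tree) && !force_rooted) {
    stop("tree is unrooted (or has a basal polytomy); a rooted tree is required. ",
         "Use force_rooted = TRUE to accept a basal polytomy as a rooted polytomy.")
  }
  tree
}

#' Phylogenetic variance-covariance matrix
#'
#' The Brownian-motion covariance implied by a rooted tree: `C[i, j]` is the
#' shared root-to-MRCA path length of tips i and j, and `C[i, i]` the
#' root-to-tip distance of tip i.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param order Optional character vector giving the tip order of the rows
#'   and columns.  Defaults to sorted tip labels, so that matrices produced
#'   from different serialisations of the same tree are identical.
#' @return A symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
vcv_matrix <- function(tree, order = NULL) {
  tree <- validate_phylogeny(tree, force_rooted = TRUE)
  C <- ape::vcv(tree)
  ord <- order %||% sort(rownames(C))
  if (!setequal(ord, rownames(C)) || length(ord) != nrow(C)) {
    stop("'order' must be a permutation of the tip labels")
  }
  C[ord, ord, drop = FALSE]
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `phylo` object.
#' @param tips Non-empty character vector of tip labels.
#' @return The node number (tip number for a singleton) of the MRCA.
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tips) == 0L) stop("'tips' must be non-empty")
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip label(s): ", paste(tips[is.na(idx)], collapse = ", "))
  }
  if (length(unique(idx)) == 1L) return(idx[[1L]])
  ape::getMRCA(tree, unique(tips))
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lam`, leaving root-to-tip
#' variances untouched.  `lam = 1` returns `C`; `lam = 0` collapses the tree
#' to a star.
#'
#' @param C Covariance matrix from [vcv_matrix()].
#' @param lam Scalar in `[0, 1]`.
#' @return The transformed matrix (still positive semi-definite).
#' @export
lambda_transform <- function(C, lam) {
  stop_if_not_scalar_prob(lam, "lam")
  D <- C * lam
  diag(D) <- diag(C)
  D
}

# Per-node tip-descendant index sets; element i of the returned list holds
# the tip numbers below node i (a tip is its own descendant).
tip_descendants <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  po <- stats::reorder(tree, "postorder")$edge
  desc <- vector("list", n + m)
  for (i in seq_len(n)) desc[[i]] <- i
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1L]
    desc[[p]] <- c(desc[[p]], desc[[po[k, 2L]]])
  }
  desc
}

# Deterministic labels for every node: tips keep their labels; internal
# nodes keep non-empty Newick labels, otherwise get "N<k>" where k is the
# node's rank in the postorder traversal of internal nodes.
node_labels <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  po <- stats::reorder(tree, "postorder")$edge
  internal_order <- unique(po[, 1L])
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[[1L]]
  if (!root %in% internal_order) internal_order <- c(internal_order, root)
  lab <- character(n + m)
  lab[seq_len(n)] <- tree$tip.label
  auto <- paste0("N", seq_along(internal_order))
  lab[internal_order] <- auto
  if (!is.null(tree$node.label)) {
    keep <- nzchar(tree$node.label) & !is.na(tree$node.label)
    lab[n + which(keep)] <- tree$node.label[keep]
  }
  lab
}

#' Construct a clade partition
#'
#' A clade partition assigns tree tips to named, disjoint clades (e.g. the
#' major bilaterian lineages contrasted in gene-loss analyses).  When a tree
#' is supplied, every listed tip must exist on it and each clade is checked
#' for monophyly.
#'
#' @param x Named list mapping clade name to a character vector of tip labels.
#' @param tree Optional `phylo` used for validation.
#' @param monophyly What to do when a clade is not monophyletic on the
#'   tree: `"error"` (default), `"warn"`, or `"ignore"` (override for
#'   partitions that deliberately pool paraphyletic groups, e.g. the
#'   complement of a clade).
#' @return An object of class `clade_partition` (a named list of tip-label
#'   vectors, with a `monophyletic` attribute when a tree was supplied).
#' @export
clade_partition <- function(x, tree = NULL,
                            monophyly = c("error", "warn", "ignore")) {
  monophyly <- match.arg(monophyly)
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("'x' must be a named list of tip-label vectors")
  }
  x <- lapply(x, as.character)
  all_tips <- unlist(x, use.names = FALSE)
  if (anyDuplicated(all_tips)) {
    stop("clades are not disjoint; tip(s) listed twice: ",
         paste(unique(all_tips[duplicated(all_tips)]), collapse = ", "))
  }
  if (!is.null(tree)) {
    missing <- setdiff(all_tips, tree$tip.label)
    if (length(missing)) {
      stop("tip(s) not present in the tree: ", paste(missing, collapse = ", "))
    }
    desc <- tip_descendants(tree)
    mono <- vapply(x, function(tips) {
      node <- mrca_node(tree, tips)
      setequal(tree$tip.label[desc[[node]]], tips)
    }, logical(1))
    if (any(!mono) && monophyly != "ignore") {
      msg <- paste0("clade(s) not monophyletic on the tree: ",
                    paste(names(x)[!mono], collapse = ", "))
      if (monophyly == "error") stop(msg) else warning(msg, call. = FALSE)
    }
    attr(x, "monophyletic") <- mono
  }
  class(x) <- "clade_partition"
  x
}

#' Read a clade partition from a two-column TSV
#'
#' Format: `tip_label<TAB>clade_name`, no header, `#` comment lines allowed.
#'
#' @inheritParams clade_partition
#' @param path Path to the TSV file.
#' @return A [clade_partition()].
#' @export
read_clade_partition <- function(path, tree = NULL,
                                 monophyly = c("error", "warn", "ignore")) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("tip", "clade"))
  if (nrow(df) == 0L) stop("empty clade partition file: ", path)
  clade_partition(split(df$tip, df$clade), tree = tree, monophyly = monophyly)
}

#' Write a clade partition as TSV
#'
#' Rows are sorted by clade then tip, so identical partitions serialise
#' byte-identically.
#'
#' @param partition A [clade_partition()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clade_partition <- function(partition, path) {
  df <- data.frame(tip = unlist(partition, use.names = FALSE),
                   clade = rep(names(partition), lengths(partition)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$clade, df$tip), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.clade_partition <- function(x, ...) {
  cat("Clade partition:", length(x), "clade(s)\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %d tips\n", nm, length(x[[nm]])))
  }
  invisible(x)
}
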