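#' Dollo parsimony reconstruction of binary characters
#'
#' Reconstructs the history of each binary character (domain presence,
#' orthogroup presence) on a rooted species tree under Dollo parsimony: a
#' character may originate once and be lost any number of times, but never
#' re-originate.  The gain is placed on the branch subtending the MRCA of
#' all tips carrying the character (on the root itself when that MRCA is
#' the root); losses are the branches subtending the maximal subtrees,
#' within the gain clade, whose tips all lack the character.  Under this
#' placement the loss count is the minimum over all single-gain labelings,
#' and the minimal placement is unique.
#'
#' @param tree Rooted `phylo` object.
#' @param chars Matrix with entries in \{0, 1\}, taxa as rows (row names
#'   must match the tree's tip set), characters as columns.
#' @return An object of class `dollo_reconstruction`: a list with
#'   `gain` (node number of the gain per character, NA for all-absent
#'   characters), `losses` (list of loss-branch child node numbers per
#'   character), `loss_count`, `states` (node x character 0/1 matrix over
#'   all tips and internal nodes), `labels` (deterministic node labels) and
#'   `tree`.
#' @export
dollo_reconstruct <- function(tree, chars) {
  tree <- validate_phylogeny(tree, force_rooted = TRUE)
  chars <- as.matrix(chars)
  if (is.null(rownames(chars))) stop("'chars' needs taxon row names")
  if (!setequal(rownames(chars), tree$tip.label)) {
    stop("taxon set of 'chars' does not match the tree tips")
  }
  if (anyNA(chars) || !all(chars %in% c(0, 1))) {
    stop("'chars' must contain only 0/1 entries")
  }
  if (is.null(colnames(chars))) {
    colnames(chars) <- paste0("char", seq_len(ncol(chars)))
  }
  chars <- chars[tree$tip.label, , drop = FALSE]
  storage.mode(chars) <- "integer"

  n <- ape::Ntip(tree)
  m <- tree$Nnode
  nch <- ncol(chars)
  po <- stats::reorder(tree, "postorder")$edge
  parent <- integer(n + m)
  parent[po[, 2L]] <- po[, 1L]
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[[1L]]

  # count of 1-tips and of all tips below every node
  count1 <- matrix(0L, n + m, nch)
  count1[seq_len(n), ] <- chars
  tipcount <- c(rep(1L, n), integer(m))
  for (k in seq_len(nrow(po))) {
    p <- po[k, 1L]; ch <- po[k, 2L]
    count1[p, ] <- count1[p, ] + count1[ch, ]
    tipcount[p] <- tipcount[p] + tipcount[ch]
  }

  gain <- rep(NA_integer_, nch)
  losses <- vector("list", nch)
  states <- matrix(0L, n + m, nch)
  totals <- count1[root, ]
  edge_parent <- po[, 1L]
  edge_child <- po[, 2L]
  for (j in seq_len(nch)) {
    tot <- totals[j]
    if (tot == 0L) {
      losses[[j]] <- integer(0)
      next
    }
    cand <- which(count1[, j] == tot)
    g <- cand[which.min(tipcount[cand])]  # the MRCA of all 1-tips
    gain[j] <- g
    s <- as.integer(count1[, j] > 0L)
    v <- g  # zero out strict ancestors of the gain node
    while (v != root) {
      v <- parent[v]
      s[v] <- 0L
    }
    states[, j] <- s
    losses[[j]] <- edge_child[s[edge_parent] == 1L & s[edge_child] == 0L]
  }
  stopifnot(all(states[seq_len(n), ] == chars))  # tip states must round-trip

  structure(list(
    tree = tree,
    char_ids = colnames(chars),
    gain = stats::setNames(gain, colnames(chars)),
    losses = stats::setNames(losses, colnames(chars)),
    loss_count = stats::setNames(lengths(losses), colnames(chars)),
    states = `dimnames<-`(states, list(node_labels(tree), colnames(chars))),
    labels = node_labels(tree),
    root = root
  ), class = "dollo_reconstruction")
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat(sprintf("Dollo reconstruction: %d characters on %d tips\n",
              length(x$char_ids), ape::Ntip(x$tree)))
  cat(sprintf("  gains: %d (characters absent everywhere: %d)\n",
              sum(!is.na(x$gain)), sum(is.na(x$gain))))
  cat(sprintf("  total losses: %d\n", sum(x$loss_count)))
  invisible(x)
}

# Resolve a node given as label or number to a node number.
resolve_node <- function(recon, node) {
  if (is.character(node)) {
    idx <- match(node, recon$labels)
    if (is.na(idx)) stop("unknown node label: ", node)
    return(idx)
  }
  node <- as.integer(node)
  if (node < 1L || node > nrow(recon$states)) stop("node number out of range")
  node
}

#' Ancestral repertoire at a node
#'
#' The set of characters reconstructed as present at a node, with an
#' additive total: by default each present character contributes 1; with
#' `weights`, the per-character weight (e.g. the modal extant gene count of
#' an orthogroup, giving additive gene totals at ancestral nodes).
#'
#' @param recon A [dollo_reconstruct()] result.
#' @param node Node label or number (tips included).
#' @param weights Optional numeric vector named by character ID.
#' @return List with `characters` (IDs present at the node) and `total`.
#' @export
ancestral_repertoire <- function(recon, node, weights = NULL) {
  stopifnot(inherits(recon, "dollo_reconstruction"))
  idx <- resolve_node(recon, node)
  present <- recon$char_ids[recon$states[idx, ] == 1L]
  if (is.null(weights)) {
    total <- length(present)
  } else {
    if (is.null(names(weights))) stop("'weights' must be named by character ID")
    missing <- setdiff(present, names(weights))
    if (length(missing)) stop("weights missing for: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    total <- sum(weights[present])
  }
  list(characters = present, total = total)
}

#' Gain/loss event table
#'
#' One row per reconstructed event.  A branch is identified by the label of
#' its child node (deterministic postorder labels when the tree carries
#' none).  Loss totals per branch can be aggregated by clade downstream.
#'
#' @param recon A [dollo_reconstruct()] result.
#' @return Data frame with columns `character`, `branch_child_label`,
#'   `event` (`"gain"` or `"loss"`), sorted by character then event.
#' @export
gain_loss_table <- function(recon) {
  stopifnot(inherits(recon, "dollo_reconstruction"))
  rows <- list()
  for (j in seq_along(recon$char_ids)) {
    id <- recon$char_ids[j]
    if (is.na(recon$gain[j])) next
    rows[[length(rows) + 1L]] <- data.frame(
      character = id,
      branch_child_label = recon$labels[recon$gain[j]],
      event = "gain", stringsAsFactors = FALSE)
    if (length(recon$losses[[j]])) {
      loss_labels <- sort(recon$labels[recon$losses[[j]]])
      rows[[length(rows) + 1L]] <- data.frame(
        character = id,
        branch_child_label = loss_labels,
        event = "loss", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(character = character(0), branch_child_label = character(0),
                      event = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a Dollo event table as TSV
#'
#' @param recon A [dollo_reconstruct()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gain_loss_table <- function(recon, path) {
  utils::write.table(gain_loss_table(recon), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the ancestral state matrix as TSV
#'
#' Rows keyed by node label (tips first, then internal nodes in postorder
#' label order).
#'
#' @param recon A [dollo_reconstruct()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ancestral_states <- function(recon, path) {
  df <- data.frame(node = rownames(recon$states), recon$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
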