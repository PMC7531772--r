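# Canonical correspondence analysis of the orthogroup count table
# constrained by domain counts, with a permutation pseudo-F test.

# Core projection shared by the fit and the permutation loop.
# Qbar: chi-square standardized residual table; r: row weights; X: raw
# constraint matrix (rows aligned to Qbar rows).  Returns the constrained
# inertia, the fitted table, and the effective rank of the constraints.
cca_project <- function(Qbar, r, X) {
  Xc <- sweep(X, 2, colSums(X * r))                       # weighted centring
  sds <- sqrt(colSums(Xc^2 * r))
  keep <- sds > 1e-10 * (1 + abs(colMeans(X)))
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, sds[keep], "/")
  Xw <- Xs * sqrt(r)
  if (ncol(Xw) == 0L) {
    return(list(ci = 0, fitted = Qbar * 0, rank = 0L, kept = keep, Xw = Xw))
  }
  q <- qr(Xw)
  rank <- q$rank
  if (rank < ncol(Xw)) {
    keep_cols <- q$pivot[seq_len(rank)]
    Xw <- Xw[, keep_cols, drop = FALSE]
    q <- qr(Xw)
    kept_names <- colnames(Xs)[keep_cols]
  } else {
    kept_names <- colnames(Xs)
  }
  fitted <- qr.fitted(q, Qbar)
  list(ci = sum(fitted^2), fitted = fitted, rank = rank, kept = keep,
       kept_names = kept_names, Xw = Xw)
}

# Validate and preprocess Y and X; returns the pieces every CCA entry point
# needs.
cca_prepare <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (!is.null(rownames(Y)) && !is.null(rownames(X))) {
    if (!setequal(rownames(Y), rownames(X))) {
      stop("row (taxon) sets of Y and X differ")
    }
    X <- X[rownames(Y), , drop = FALSE]
  } else if (nrow(X) != nrow(Y)) {
    stop("Y and X must have the same number of rows")
  }
  if (any(Y < 0)) stop("Y must be non-negative")
  zr <- rowSums(Y) == 0
  zc <- colSums(Y) == 0
  if (any(zr)) {
    warning(sum(zr), " all-zero row(s) dropped from Y", call. = FALSE)
    Y <- Y[!zr, , drop = FALSE]
    X <- X[!zr, , drop = FALSE]
  }
  if (any(zc)) {
    warning(sum(zc), " all-zero column(s) dropped from Y", call. = FALSE)
    Y <- Y[, !zc, drop = FALSE]
  }
  n <- nrow(Y)
  if (n < ncol(X) + 2L) stop("fewer taxa than constraints + 2")
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P)
  cw <- colSums(P)
  E <- outer(r, cw)
  Qbar <- (P - E) / sqrt(E)
  list(Y = Y, X = X, Qbar = Qbar, r = r, cw = cw, n = n,
       total_inertia = sum(Qbar^2))
}

#' Canonical correspondence analysis
#'
#' Constrained ordination of a non-negative count table `Y` (taxa x
#' orthogroups) by explanatory variables `X` (taxa x domain counts) in the
#' chi-square metric: the standardized residual table
#' `Qbar = (p_ij - p_i. p_.j) / sqrt(p_i. p_.j)` is regressed on the
#' weighted, standardized constraints, and the fitted table decomposed by
#' singular values.  Total inertia equals the Pearson chi-square statistic
#' of `Y` divided by its grand total; constrained plus residual inertia
#' equals total inertia exactly.
#'
#' All-zero rows/columns of `Y` are dropped with a warning, as are
#' collinear (or constant) constraint columns.
#'
#' @param Y Non-negative matrix, taxa x orthogroups.
#' @param X Constraint matrix, taxa x variables, rows aligned to `Y` (by
#'   name when both are named).
#' @return Object of class `cca_result`: eigenvalues, inertias, pseudo-F
#'   with `(q, n - q - 1)` degrees of freedom, and site (taxon), species
#'   (orthogroup) and biplot (constraint) scores.
#' @export
cca_fit <- function(Y, X) {
  prep <- cca_prepare(Y, X)
  proj <- cca_project(prep$Qbar, prep$r, prep$X)
  q <- proj$rank
  n <- prep$n
  ti <- prep$total_inertia
  ci <- proj$ci
  ri <- ti - ci
  pseudo_f <- if (q > 0 && ri > 0) (ci / q) / (ri / (n - q - 1)) else NA_real_
  if (q > 0L) {
    sv <- svd(proj$fitted)
    nax <- min(q, ncol(prep$Y) - 1L, n - 1L)
    eig <- (sv$d^2)[seq_len(nax)]
    eig <- eig[eig > max(1e-12 * max(eig), 0)]
    nax <- length(eig)
    site <- sweep(sv$u[, seq_len(nax), drop = FALSE] %*%
                    diag(sv$d[seq_len(nax)], nax), 1, sqrt(prep$r), "/")
    species <- sweep(sv$v[, seq_len(nax), drop = FALSE], 1, sqrt(prep$cw), "/")
    biplot <- crossprod(proj$Xw, sv$u[, seq_len(nax), drop = FALSE])
    dimnames(site) <- list(rownames(prep$Y), paste0("CCA", seq_len(nax)))
    dimnames(species) <- list(colnames(prep$Y), paste0("CCA", seq_len(nax)))
    dimnames(biplot) <- list(proj$kept_names, paste0("CCA", seq_len(nax)))
  } else {
    eig <- numeric(0)
    site <- species <- biplot <- NULL
  }
  structure(list(
    eigenvalues = eig,
    total_inertia = ti,
    constrained_inertia = ci,
    residual_inertia = ri,
    pseudo_F = pseudo_f,
    df = c(q, n - q - 1L),
    n = n,
    rank = q,
    site_scores = site,
    species_scores = species,
    biplot_scores = biplot,
    dropped_constraints = setdiff(colnames(prep$X),
                                  proj$kept_names %||% character(0))
  ), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("Canonical correspondence analysis\n")
  cat(sprintf("  total inertia %.4f = constrained %.4f + residual %.4f\n",
              x$total_inertia, x$constrained_inertia, x$residual_inertia))
  cat(sprintf("  pseudo-F(%d, %d) = %.4g\n", x$df[1], x$df[2], x$pseudo_F))
  if (length(x$eigenvalues)) {
    cat("  constrained eigenvalues:",
        paste(sprintf("%.4f", x$eigenvalues), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Permutation test of the global CCA association
#'
#' Permutes the rows of `X` jointly `n_perm` times, recomputing the
#' pseudo-F each time; `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`.
#'
#' @inheritParams cca_fit
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Seed making the permutation stream reproducible.
#' @return List with `pseudo_F`, `p`, `df`, `n_perm` and the full `fit`.
#' @export
cca_permutation_test <- function(Y, X, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  prep <- cca_prepare(Y, X)
  fit <- cca_fit(prep$Y, prep$X)
  n <- prep$n
  f_of <- function(Xp) {
    proj <- cca_project(prep$Qbar, prep$r, Xp)
    q <- proj$rank
    ri <- prep$total_inertia - proj$ci
    if (q == 0L || ri <= 0) return(-Inf)
    (proj$ci / q) / (ri / (n - q - 1))
  }
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      f_of(prep$X[sample.int(n), , drop = FALSE])
    }, numeric(1))
  })
  p <- (sum(f_perm >= fit$pseudo_F) + 1) / (n_perm + 1)
  list(pseudo_F = fit$pseudo_F, p = p, df = fit$df, n_perm = n_perm, fit = fit)
}

#' Write CCA scores as TSV files
#'
#' @param fit A [cca_fit()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_cca_scores <- function(fit, dir, prefix = "cca") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (what in c("site_scores", "species_scores", "biplot_scores")) {
    m <- fit[[what]]
    if (is.null(m)) next
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0(prefix, "_", what, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
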