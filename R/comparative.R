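# Phylogenetic signal estimators and (phylogenetic) least squares.
#
# All solvers go through the Cholesky factor of the covariance matrix; no
# explicit inverses are formed.

# Solve t(R) %*% z = x for the upper Cholesky factor R (C = t(R) %*% R),
# i.e. whiten x so that crossprod(whitened) = t(x) %*% solve(C) %*% x.
whiten <- function(R, x) backsolve(R, x, transpose = TRUE)

chol_or_stop <- function(C, what = "C") {
  tryCatch(chol(C), error = function(e) {
    stop("covariance matrix ", what, " is not positive definite: ",
         conditionMessage(e), call. = FALSE)
  })
}

align_trait <- function(y, labels, what = "y") {
  if (!is.null(names(y))) {
    if (!setequal(names(y), labels)) {
      stop("names of ", what, " do not match the tip labels")
    }
    y <- y[labels]
  } else if (length(y) != length(labels)) {
    stop("length of ", what, " does not match the number of tips")
  }
  y
}

#' Generalized least-squares (ancestral) mean of a trait
#'
#' The GLS intercept `(1' C^-1 1)^-1 1' C^-1 y`: the maximum-likelihood
#' estimate of the root state of a Brownian trait, and the mean used by
#' both signal statistics.
#'
#' @param y Trait vector (named by tip, or in the row order of `C`).
#' @param C Phylogenetic covariance matrix from [vcv_matrix()].
#' @return Scalar estimate.
#' @export
phylo_mean <- function(y, C) {
  y <- align_trait(y, rownames(C) %||% seq_along(y))
  if (length(y) != nrow(C)) stop("length(y) != dim(C)")
  R <- chol_or_stop(C)
  z1 <- whiten(R, rep(1, length(y)))
  zy <- whiten(R, y)
  sum(z1 * zy) / sum(z1 * z1)
}

#' Blomberg's K
#'
#' Ratio-based phylogenetic signal statistic: the observed ratio of the
#' trait's mean squared error about the GLS mean to its phylogenetically
#' corrected mean squared error, divided by the ratio expected under
#' Brownian motion on the tree.  K = 1 is the Brownian expectation; K < 1
#' indicates less resemblance among relatives than Brownian motion
#' predicts, K > 1 more.
#'
#' @param y Trait vector named by tip label (or in tree tip order).
#' @param tree Rooted `phylo` with branch lengths; at least 4 tips.
#' @param test If `TRUE`, attach a randomization p-value obtained by
#'   shuffling trait values across tips (`n_perm` shuffles).  Off by
#'   default.
#' @param n_perm Number of shuffles for the randomization test.
#' @param seed Seed for the randomization test.
#' @return Object of class `signal_estimate` with the point estimate and
#'   the observed/expected MSE ratios.
#' @export
blomberg_k <- function(y, tree, test = FALSE, n_perm = 999, seed = NULL) {
  tree <- validate_phylogeny(tree, force_rooted = TRUE)
  n <- ape::Ntip(tree)
  if (n < 4L) stop("Blomberg's K needs at least 4 tips")
  C <- ape::vcv(tree)
  y <- align_trait(y, rownames(C))
  k_of <- function(yy) {
    R <- chol_or_stop(C)
    z1 <- whiten(R, rep(1, n))
    zy <- whiten(R, yy)
    a <- sum(z1 * zy) / sum(z1 * z1)
    r <- yy - a
    zr <- zy - a * z1
    denom <- sum(zr^2)
    if (sum(r^2) < .Machine$double.eps * n || denom < .Machine$double.eps * n) {
      stop("constant trait: K is undefined")
    }
    observed <- sum(r^2) / denom
    expected <- (sum(diag(C)) - n / sum(z1^2)) / (n - 1)
    list(K = observed / expected, observed = observed, expected = expected)
  }
  est <- k_of(y)
  out <- structure(list(statistic = "K", estimate = est$K,
                        observed_ratio = est$observed,
                        expected_ratio = est$expected, n = n),
                   class = "signal_estimate")
  if (test) {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) k_of(sample(y))$K, numeric(1))
    })
    out$p_value <- (sum(perm >= est$K) + 1) / (n_perm + 1)
    out$n_perm <- n_perm
  }
  out
}

# Profile log-likelihood of y under Normal(a*1, sigma2 * lambda-transform(C))
# with a and sigma2 profiled out.  Returns -Inf when the transformed matrix
# is not positive definite.
lambda_loglik <- function(lam, y, C) {
  V <- lambda_transform(C, lam)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  n <- length(y)
  z1 <- whiten(R, rep(1, n))
  zy <- whiten(R, y)
  a <- sum(z1 * zy) / sum(z1 * z1)
  rss <- sum((zy - a * z1)^2)
  if (rss <= 0) return(-Inf)
  sigma2 <- rss / n
  -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximises the profile log-likelihood of the trait under a multivariate
#' normal model whose covariance is the lambda-transform of the tree's
#' Brownian covariance, over lambda in `[0, 1]`.  The search is a 21-point
#' grid followed by bounded scalar optimization in the bracketing interval;
#' ties are broken toward the grid argmax.
#'
#' @inheritParams blomberg_k
#' @param tol Convergence tolerance in lambda (default 1e-6).
#' @return Object of class `signal_estimate` with the estimate, the
#'   log-likelihood at the optimum and at both endpoints, and boundary
#'   flags.
#' @export
pagel_lambda <- function(y, tree, tol = 1e-6) {
  tree <- validate_phylogeny(tree, force_rooted = TRUE)
  n <- ape::Ntip(tree)
  if (n < 4L) stop("Pagel's lambda needs at least 4 tips")
  C <- ape::vcv(tree)
  y <- align_trait(y, rownames(C))
  ll <- function(lam) lambda_loglik(lam, y, C)
  grid <- seq(0, 1, length.out = 21)
  gll <- vapply(grid, ll, numeric(1))
  if (all(!is.finite(gll))) stop("lambda likelihood undefined on the whole grid")
  i0 <- which.max(gll)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- tryCatch(stats::optimize(ll, lower = lo, upper = hi, maximum = TRUE,
                                  tol = tol),
                  error = function(e) NULL)
  lam_hat <- grid[i0]
  ll_hat <- gll[i0]
  converged <- TRUE
  if (is.null(opt)) {
    converged <- FALSE  # grid fallback
  } else if (opt$objective > ll_hat + 1e-10) {
    lam_hat <- opt$maximum
    ll_hat <- opt$objective
  }
  structure(list(statistic = "lambda",
                 estimate = lam_hat,
                 loglik = ll_hat,
                 loglik0 = gll[1L],
                 loglik1 = gll[length(gll)],
                 at_lower_bound = lam_hat < tol,
                 at_upper_bound = lam_hat > 1 - tol,
                 converged = converged,
                 n = n),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat(sprintf("Phylogenetic signal: %s = %.4g (n = %d)\n",
              x$statistic, x$estimate, x$n))
  if (!is.null(x$loglik)) {
    cat(sprintf("  logLik at estimate / 0 / 1: %.3f / %.3f / %.3f\n",
                x$loglik, x$loglik0, x$loglik1))
  }
  if (!is.null(x$p_value)) cat(sprintf("  randomization p = %.4g\n", x$p_value))
  invisible(x)
}

# Whitened least squares shared by pgls_fit and the scan: R is the upper
# Cholesky factor of C (NULL for the identity).
gls_core <- function(y, X, R = NULL) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients")
  ty <- if (is.null(R)) y else whiten(R, y)
  tX <- if (is.null(R)) X else whiten(R, X)
  colnames(tX) <- colnames(X)  # backsolve drops dimnames
  q <- qr(tX)
  if (q$rank < p) stop("design matrix is rank deficient")
  beta <- qr.coef(q, ty)
  res <- ty - tX %*% beta
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(q))
  # undo any qr pivoting in the coefficient covariance
  piv <- q$pivot
  XtXinv <- XtXinv[order(piv), order(piv), drop = FALSE]
  vcov <- sigma2 * XtXinv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- stats::setNames(sqrt(diag(vcov)), colnames(X))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(beta = beta, se = se, t = tval, p = pval, sigma2 = sigma2, df = df,
       vcov = vcov, whitened_residuals = drop(res))
}

#' Phylogenetic generalized least squares
#'
#' Fits `y = X beta + e` with `e ~ Normal(0, sigma2 * C)`, where `C` is the
#' Brownian covariance of the supplied tree (identity when `tree = NULL`,
#' reducing the fit to ordinary least squares).  Standard errors, t
#' statistics and two-sided p-values use the Student t distribution on
#' `n - p` degrees of freedom.
#'
#' @param y Response vector, named by tip label when a tree is supplied.
#' @param X Design matrix with named columns (include an intercept column
#'   explicitly); rows aligned to `y` (by name when named).
#' @param tree Rooted `phylo` or `NULL` for an identity correlation.
#' @return Object of class `pgls_fit`.
#' @export
pgls_fit <- function(y, X, tree = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("'X' must have named columns")
  R <- NULL
  correlation <- "identity"
  if (!is.null(tree)) {
    tree <- validate_phylogeny(tree, force_rooted = TRUE)
    C <- ape::vcv(tree)
    y <- align_trait(y, rownames(C))
    if (!is.null(rownames(X))) {
      if (!setequal(rownames(X), rownames(C))) {
        stop("row names of X do not match the tip labels")
      }
      X <- X[rownames(C), , drop = FALSE]
    } else if (nrow(X) != nrow(C)) {
      stop("nrow(X) does not match the number of tips")
    }
    R <- chol_or_stop(C)
    correlation <- "Brownian motion on supplied tree"
  }
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  fit <- gls_core(y, X, R)
  structure(c(fit, list(correlation = correlation, n = length(y),
                        terms = colnames(X))),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Generalized least squares fit (correlation:", x$correlation, ")\n")
  tab <- data.frame(Estimate = x$beta, `Std.Error` = x$se, t = x$t,
                    `p.value` = x$p, check.names = FALSE)
  print(format(tab, digits = 4))
  cat(sprintf("Residual variance %.4g on %d degrees of freedom\n",
              x$sigma2, x$df))
  invisible(x)
}

#' Coefficient table of a PGLS fit
#'
#' @param fit A [pgls_fit()] result.
#' @return Data frame with estimate, SE, t and p per coefficient.
#' @export
coef_table <- function(fit) {
  data.frame(term = fit$terms, estimate = unname(fit$beta), se = unname(fit$se),
             t = unname(fit$t), p = unname(fit$p), stringsAsFactors = FALSE)
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x`: slope, intercept, r-squared and
#' the two-sided p-value of the slope.  Used for the uncorrected
#' genome-size control.
#'
#' @param y Response vector.
#' @param x Predictor vector (must have non-zero variance).
#' @return List with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
ols_r2 <- function(y, x) {
  if (length(y) != length(x)) stop("length mismatch")
  if (length(y) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = s$r.squared,
       p = unname(s$coefficients[2L, 4L]),
       n = length(y))
}

#' Per-orthogroup, per-domain PGLS scan
#'
#' For every (focal) orthogroup and every domain type, fits a PGLS of the
#' orthogroup's per-taxon gene count on that domain's per-taxon count plus
#' genome size, under Brownian covariance on the tree, and reports the
#' domain coefficient.  Counts are variance-stabilised by `log(count + 1)`
#' by default.  P-values are adjusted by Benjamini-Hochberg, jointly across
#' the whole scan by default.
#'
#' @param counts A [count_matrix()].
#' @param domains Taxa x domain-type count matrix ([tabulate_domain_counts()]).
#' @param genome_size Named per-taxon covariate (assembly length or total
#'   protein-model count, on whatever scale the user prefers); `NULL` to
#'   omit the covariate.
#' @param tree Rooted `phylo`.
#' @param focal Tag name or orthogroup IDs to scan (default every column).
#' @param transform `"log1p"` (default) or `"none"` for raw counts.
#' @param adjust `"global-BH"` (default), `"per-domain"`, or `"none"`.
#' @param alpha FDR threshold used for the significance flag.
#' @return Data frame of class `pgls_scan` with one row per orthogroup x
#'   domain: `orthogroup`, `domain`, `beta`, `se`, `t`, `p`, `q`,
#'   `transform`, `correlation`, `significant`.
#' @export
pgls_scan <- function(counts, domains, genome_size = NULL, tree,
                      focal = NULL,
                      transform = c("log1p", "none"),
                      adjust = c("global-BH", "per-domain", "none"),
                      alpha = 0.1) {
  transform <- match.arg(transform)
  adjust <- match.arg(adjust)
  tree <- validate_phylogeny(tree, force_rooted = TRUE)
  C <- ape::vcv(tree)
  taxa <- rownames(C)
  if (!all(taxa %in% rownames(counts))) stop("count matrix missing tree taxa")
  if (!all(taxa %in% rownames(domains))) stop("domain profile missing tree taxa")
  og <- if (is.null(focal)) colnames(counts) else {
    if (length(focal) == 1L && focal %in% names(count_tags(counts))) {
      count_tags(counts)[[focal]]
    } else focal
  }
  if (length(og) == 0L) stop("no orthogroups to scan")
  R <- chol_or_stop(C)
  Y <- unclass(counts)[taxa, og, drop = FALSE]
  if (transform == "log1p") Y <- log1p(Y)
  D <- domains[taxa, , drop = FALSE]
  g <- if (is.null(genome_size)) NULL else align_trait(genome_size, taxa, "genome_size")

  rows <- vector("list", ncol(Y) * ncol(D))
  k <- 0L
  for (j in seq_len(ncol(Y))) {
    for (d in seq_len(ncol(D))) {
      X <- cbind(`(Intercept)` = 1, domain = D[, d])
      if (!is.null(g)) X <- cbind(X, genome_size = g)
      fit <- tryCatch(gls_core(Y[, j], X, R), error = function(e) NULL)
      k <- k + 1L
      rows[[k]] <- if (is.null(fit)) {
        data.frame(orthogroup = og[j], domain = colnames(D)[d],
                   beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(orthogroup = og[j], domain = colnames(D)[d],
                   beta = unname(fit$beta["domain"]),
                   se = unname(fit$se["domain"]),
                   t = unname(fit$t["domain"]),
                   p = unname(fit$p["domain"]), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- switch(adjust,
                  "global-BH" = bh_fdr(out$p),
                  "per-domain" = stats::ave(out$p, out$domain, FUN = bh_fdr),
                  "none" = out$p)
  out$transform <- transform
  out$correlation <- "BM"
  out$significant <- !is.na(out$q) & out$q < alpha
  attr(out, "alpha") <- alpha
  attr(out, "significant_orthogroups") <-
    sort(unique(out$orthogroup[out$significant]))
  class(out) <- c("pgls_scan", "data.frame")
  out
}
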