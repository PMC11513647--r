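# Phylogenetically corrected comparative statistics: Brownian-motion
# covariance, Pagel's lambda by maximum likelihood with profile CI, PGLS
# residuals over log body mass, simulation-based phylogenetic ANOVA with
# post hoc letters, and phylogenetic PCA. Trees are ape "phylo" objects.

#' Brownian-motion covariance matrix of a phylogeny
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips `i` and `j`;
#' the diagonal holds root-to-tip depths. Trees without branch lengths
#' (e.g. Open Tree topologies) are first given Grafen branch lengths.
#'
#' @param tree A rooted `phylo` object.
#' @return The `n x n` covariance matrix, tips in `tree$tip.label` order.
#' @export
bm_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    tree <- ape::compute.brlen(tree, method = "Grafen")
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ape::vcv(tree)
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries by `lam`, leaving the diagonal
#' unchanged: `lam = 1` returns `C`, `lam = 0` the star-tree (diagonal)
#' covariance.
#'
#' @param C Covariance matrix.
#' @param lam Signal parameter in `[0, 1]`.
#' @return Transformed covariance matrix.
#' @export
pagel_transform <- function(C, lam) {
  if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
  Cl <- C * lam
  diag(Cl) <- diag(C)
  Cl
}

# profile GLS log-likelihood machinery (covariance sigma2 * Cl, sigma2
# profiled out at its ML value)
.gls_fit <- function(y, X, Cl) {
  R <- chol(Cl)                       # Cl = R'R
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  XtX <- crossprod(Xt)
  beta <- solve(XtX, crossprod(Xt, yt))
  rt <- yt - Xt %*% beta
  n <- length(y)
  rss <- sum(rt^2)
  sigma2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + 2 * sum(log(diag(R))) + n)
  list(beta = drop(beta), loglik = ll, sigma2_ml = sigma2_ml,
       rss = rss, XtX = XtX, residuals = drop(y - X %*% beta))
}

#' Maximum-likelihood Pagel's lambda PGLS fit
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * C_lambda)`, maximizing the
#' profile log-likelihood over `lambda` in `[0, 1]`. The 95% confidence
#' interval is the profile-likelihood interval (log-likelihood drop of
#' 1.92 units), truncated at the boundaries. At `lambda = 0` on an
#' ultrametric tree the fit reduces to ordinary least squares.
#'
#' @param y Response vector (tip order of `C`).
#' @param X Design matrix (include the intercept column).
#' @param C Brownian-motion covariance from [bm_covariance()].
#' @return Object of class `pgls_fit`: `beta`, `lambda`, `lambda_ci`,
#'   `loglik`, `sigma2`, `se`, `residuals` (original scale).
#' @export
fit_pagel_lambda <- function(y, X, C) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(C) == n, n >= 5)
  prof <- function(lam) .gls_fit(y, X, pagel_transform(C, lam))$loglik
  opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(0, prof(0)), c(opt$maximum, opt$objective), c(1, prof(1)))
  best <- cand[which.max(cand[, 2]), ]
  lam_hat <- best[1]; ll_max <- best[2]
  thr <- ll_max - stats::qchisq(0.95, df = 1) / 2   # 1.92 log-units
  ci <- c(0, 1)
  f <- function(l) prof(l) - thr
  if (f(0) < 0) {
    ci[1] <- stats::uniroot(f, c(0, lam_hat), tol = 1e-6)$root
  }
  if (f(1) < 0) {
    ci[2] <- stats::uniroot(f, c(lam_hat, 1), tol = 1e-6)$root
  }
  fit <- .gls_fit(y, X, pagel_transform(C, lam_hat))
  p <- ncol(X)
  sigma2_reml <- fit$rss / (n - p)
  se <- sqrt(diag(solve(fit$XtX)) * sigma2_reml)
  structure(list(beta = fit$beta, lambda = lam_hat,
                 lambda_ci = ci, loglik = fit$loglik,
                 sigma2 = fit$sigma2_ml, se = se,
                 residuals = fit$residuals),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (Pagel's lambda ML)\n")
  cat("  lambda =", round(x$lambda, 4),
      " 95% CI [", round(x$lambda_ci[1], 4), ",",
      round(x$lambda_ci[2], 4), "]\n")
  cat("  beta:", paste(signif(x$beta, 5), collapse = ", "), "\n")
  invisible(x)
}

#' PGLS residuals of a trait over log body mass
#'
#' Drops species with missing trait or mass, prunes the tree to the
#' remaining species, fits `trait ~ log_mass` by [fit_pagel_lambda()] and
#' returns the residuals on the original trait scale (named by species).
#'
#' @param trait Named numeric vector (names = species, matching tip labels).
#' @param log_mass Named numeric vector of log body mass.
#' @param tree A `phylo` object containing at least the complete cases.
#' @return List with `residuals` (named vector), `fit` (the `pgls_fit`) and
#'   `tree` (pruned).
#' @export
pgls_residuals <- function(trait, log_mass, tree) {
  sp <- intersect(names(trait)[!is.na(trait)],
                  names(log_mass)[!is.na(log_mass)])
  sp <- intersect(sp, tree$tip.label)
  if (length(sp) < 5) stop("fewer than 5 complete cases")
  tr <- ape::keep.tip(tree, sp)
  sp <- tr$tip.label
  C <- bm_covariance(tr)
  X <- cbind(1, log_mass[sp])
  fit <- fit_pagel_lambda(trait[sp], X, C)
  res <- stats::setNames(fit$residuals, sp)
  list(residuals = res, fit = fit, tree = tr)
}

# vectorized one-way ANOVA F for a matrix of responses (columns = datasets)
.anova_F <- function(Y, g) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  k <- nlevels(g)
  ng <- tabulate(g, k)
  Sg <- rowsum(Y, g)                       # k x m group sums
  tot <- colSums(Y)
  ssb <- colSums(Sg^2 / ng) - tot^2 / n
  sst <- colSums(Y^2) - tot^2 / n
  ssw <- pmax(sst - ssb, 0)
  msw <- ssw / (n - k)
  list(F = (ssb / (k - 1)) / msw, msw = msw, Sg = Sg, ng = ng)
}

# pairwise t statistics from group sums and MSW; returns pairs x m matrix
.pairwise_t <- function(Sg, ng, msw, pairs) {
  means <- Sg / ng
  out <- matrix(0, nrow(pairs), length(msw))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    out[i, ] <- (means[a, ] - means[b, ]) /
      sqrt(msw * (1 / ng[a] + 1 / ng[b]))
  }
  out
}

#' Simulation-based phylogenetic ANOVA with post hoc letters
#'
#' One-way ANOVA of `x` on `groups` whose null distribution accounts for
#' phylogenetic non-independence: `nsim` datasets are simulated under
#' Brownian motion on the tree (rate = REML estimate from the data under a
#' mean-only model), the F statistic is recomputed for each, and
#' `p_phylo = (1 + #{F* >= F_obs}) / (nsim + 1)`. Pairwise post hoc t
#' statistics are evaluated against the same simulated null (two-sided) and
#' summarized as a compact letter display at `alpha`.
#'
#' @param x Named numeric vector of (body-mass-corrected) trait values.
#' @param groups Factor (e.g. sociality level) in the same species order.
#' @param tree A `phylo` with the same species as tips.
#' @param nsim Number of Brownian-motion null simulations (default 1000).
#' @param seed Optional integer seed for the null simulations.
#' @param alpha Significance level for the letter display.
#' @return Object of class `phylo_anova`: `F_obs`, `df`, `p_phylo`,
#'   `p_bonferroni` (filled by the pipeline when several traits are
#'   tested), `pairwise` (p-value matrix), `letters`, `nsim`.
#' @export
phylo_anova <- function(x, groups, tree, nsim = 1000, seed = NULL,
                        alpha = 0.05) {
  stopifnot(nsim >= 100)
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 non-empty groups")
  if (!is.null(names(x))) {
    sp <- intersect(tree$tip.label, names(x))
    tree <- ape::keep.tip(tree, sp)
    ord <- match(tree$tip.label, names(x))
    x <- x[ord]
    groups <- droplevels(groups[ord])
  }
  n <- length(x)
  if (stats::var(x) <= 0) stop("degenerate (constant) response")
  obs <- .anova_F(matrix(x, ncol = 1), groups)
  F_obs <- obs$F
  C <- bm_covariance(tree)
  # REML Brownian rate under the mean-only model
  one <- rep(1, n)
  Ci <- solve(C)
  mu <- sum(Ci %*% x) / sum(Ci)
  r <- x - mu
  sig2 <- drop(crossprod(r, Ci %*% r)) / (n - 1)
  if (!is.null(seed)) set.seed(seed)
  L <- chol(sig2 * C)
  Y <- crossprod(L, matrix(stats::rnorm(n * nsim), n, nsim))
  sim <- .anova_F(Y, groups)
  p_phylo <- (1 + sum(sim$F >= F_obs)) / (nsim + 1)
  pairs <- t(utils::combn(k, 2))
  t_obs <- .pairwise_t(obs$Sg, obs$ng, obs$msw, pairs)
  t_sim <- .pairwise_t(sim$Sg, sim$ng, sim$msw, pairs)
  p_pair <- vapply(seq_len(nrow(pairs)), function(i) {
    (1 + sum(abs(t_sim[i, ]) >= abs(t_obs[i, 1]))) / (nsim + 1)
  }, numeric(1))
  pmat <- matrix(NA_real_, k, k, dimnames = list(levels(groups),
                                                 levels(groups)))
  for (i in seq_len(nrow(pairs))) {
    pmat[pairs[i, 1], pairs[i, 2]] <- pmat[pairs[i, 2], pairs[i, 1]] <-
      p_pair[i]
  }
  structure(list(F_obs = F_obs, df = c(k - 1L, n - k), p_phylo = p_phylo,
                 p_bonferroni = NA_real_, pairwise = pmat,
                 letters = cld_letters(pmat, alpha), nsim = nsim),
            class = "phylo_anova")
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat("Phylogenetic ANOVA (simulation null, nsim =", x$nsim, ")\n")
  cat("  F =", round(x$F_obs, 3), " d.f. =", paste(x$df, collapse = ", "),
      " p_phylo =", signif(x$p_phylo, 3), "\n")
  cat("  letters:", paste(names(x$letters), x$letters, sep = "=",
                          collapse = " "), "\n")
  invisible(x)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param pmat Symmetric matrix of pairwise p-values with group dimnames.
#' @param alpha Significance level.
#' @return Named character vector of letter strings per group.
#' @export
cld_letters <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  k <- length(g)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!is.na(pmat[i, j]) && pmat[i, j] < alpha) {
        new_sets <- list()
        for (s in sets) {
          if (i %in% s && j %in% s) {
            new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        # absorb: drop sets contained in another
        keep <- rep(TRUE, length(new_sets))
        for (a in seq_along(new_sets)) {
          for (b in seq_along(new_sets)) {
            if (a != b && keep[a] &&
                all(new_sets[[a]] %in% new_sets[[b]]) &&
                (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
              keep[a] <- FALSE
            }
          }
        }
        sets <- unique(new_sets[keep])
      }
    }
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- stats::setNames(rep("", k), g)
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  out
}

#' Bonferroni adjustment of p-values
#'
#' @param p Vector of p-values.
#' @return `pmin(p * length(p), 1)` via [stats::p.adjust()].
#' @export
bonferroni_adjust <- function(p) stats::p.adjust(p, method = "bonferroni")

#' Phylogenetic principal component analysis
#'
#' Computes the GLS (phylogenetic) mean `a = (1'C^-1 1)^-1 1'C^-1 X` with
#' `C` at the jointly ML-estimated Pagel's lambda, the evolutionary
#' covariance `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)`, and its
#' eigen-decomposition. Scores are `(X - 1a) V`; they are uncorrelated in
#' the `C^-1` metric. Axes with eigenvalue above 1 are retained under the
#' Kaiser criterion (meaningful when columns are standardized to unit
#' variance beforehand).
#'
#' @param X Complete numeric matrix (rows = species in tip order, columns =
#'   traits), pre-scaled to mean 0, variance 1.
#' @param tree A `phylo` whose tips match `rownames(X)` (or tip order).
#' @return Object of class `ppca`: `loadings`, `eigenvalues`, `scores`,
#'   `pct_variance`, `lambda`, `retained_axes`.
#' @export
ppca <- function(X, tree) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete; impute first")
  if (!is.null(rownames(X))) {
    stopifnot(setequal(rownames(X), tree$tip.label))
    X <- X[tree$tip.label, , drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("need at least 2 traits")
  C <- bm_covariance(tree)
  one <- rep(1, n)
  ll <- function(lam) {
    Cl <- pagel_transform(C, lam)
    R <- chol(Cl)
    Xt <- backsolve(R, X, transpose = TRUE)
    ot <- backsolve(R, one, transpose = TRUE)
    a <- crossprod(ot, Xt) / sum(ot^2)
    E <- Xt - ot %*% a
    Rml <- crossprod(E) / n
    ld <- determinant(Rml, logarithm = TRUE)
    if (ld$sign <= 0) return(-Inf)
    -0.5 * (n * p * log(2 * pi) + p * 2 * sum(log(diag(R))) +
              n * as.numeric(ld$modulus) + n * p)
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-5)
  cand <- rbind(c(0, ll(0)), c(opt$maximum, opt$objective), c(1, ll(1)))
  lam <- cand[which.max(cand[, 2]), 1]
  Cl <- pagel_transform(C, lam)
  Ci <- solve(Cl)
  a <- drop(crossprod(one, Ci %*% X)) / drop(crossprod(one, Ci %*% one))
  Xc <- sweep(X, 2, a)
  R <- crossprod(Xc, Ci %*% Xc) / (n - 1)
  eg <- eigen(R, symmetric = TRUE)
  V <- eg$vectors
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(p)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(p)))
  scores <- Xc %*% V
  structure(list(loadings = V, eigenvalues = eg$values, scores = scores,
                 pct_variance = 100 * eg$values / sum(eg$values),
                 lambda = lam,
                 retained_axes = which(eg$values > 1)),
            class = "ppca")
}

#' @export
print.ppca <- function(x, ...) {
  cat("Phylogenetic PCA (Pagel's lambda =", round(x$lambda, 3), ")\n")
  cat("  % variance:", paste(round(x$pct_variance, 2), collapse = ", "), "\n")
  cat("  retained axes (Kaiser):", paste(x$retained_axes, collapse = ", "),
      "\n")
  invisible(x)
}

#' Prune over-correlated traits by Spearman correlation
#'
#' Greedy pruning: pairs with `|rho_S| > threshold` (pairwise complete
#' observations) are resolved by dropping one member — the trait with the
#' higher missingness, ties broken by keeping the trait earlier in
#' `order`. Deterministic and independent of species (row) order.
#'
#' @param trait_table Data frame of numeric traits (columns).
#' @param threshold Spearman threshold, strict (default 0.70).
#' @param order Canonical preference order of trait names; defaults to
#'   [trait_names()] entries present, then remaining columns.
#' @return List with `kept_traits` (character) and `dropped_pairs`
#'   (data frame with `dropped`, `kept`, `rho`).
#' @export
spearman_prune <- function(trait_table, threshold = 0.70, order = NULL) {
  tt <- as.data.frame(trait_table)
  nm <- names(tt)
  stopifnot(length(nm) >= 2)
  if (is.null(order)) order <- c(intersect(trait_names(), nm),
                                 setdiff(nm, trait_names()))
  rk <- match(nm, order)
  rho <- suppressWarnings(
    stats::cor(tt, method = "spearman", use = "pairwise.complete.obs"))
  miss <- colSums(is.na(tt))
  pairs <- which(upper.tri(rho) & abs(rho) > threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- base::order(-abs(rho[pairs]), nm[pairs[, 1]], nm[pairs[, 2]])
    pairs <- pairs[ord, , drop = FALSE]
  }
  kept <- rep(TRUE, length(nm))
  dropped <- data.frame(dropped = character(0), kept = character(0),
                        rho = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (!kept[a] || !kept[b]) next
    # keep lower missingness; tie -> keep earlier in canonical order
    drop_idx <- if (miss[a] != miss[b]) {
      if (miss[a] > miss[b]) a else b
    } else if (rk[a] <= rk[b]) b else a
    keep_idx <- if (drop_idx == a) b else a
    kept[drop_idx] <- FALSE
    dropped <- rbind(dropped,
                     data.frame(dropped = nm[drop_idx], kept = nm[keep_idx],
                                rho = rho[a, b], stringsAsFactors = FALSE))
  }
  list(kept_traits = nm[kept], dropped_pairs = dropped)
}
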