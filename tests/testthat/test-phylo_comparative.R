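test_that("Brownian covariance encodes shared path lengths", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  C <- bm_covariance(tr)
  expect_equal(C["a", "b"], 1)
  expect_equal(C["a", "c"], 0)
  expect_equal(unname(diag(C)), c(2, 2, 2))
  # star tree: diagonal
  st <- star_tree(4)
  Cs <- bm_covariance(st)
  expect_equal(Cs, diag(4), ignore_attr = TRUE)
  # topology-only tree falls back to Grafen branch lengths
  topo <- ape::read.tree(text = "((a,b),c);")
  expect_silent(Ct <- bm_covariance(topo))
  expect_true(all(diag(Ct) > 0))
})

test_that("the Pagel transform scales off-diagonals only", {
  C <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(pagel_transform(C, 1), C)
  expect_equal(pagel_transform(C, 0), diag(c(2, 2)))
  expect_equal(pagel_transform(C, 0.5)[1, 2], 0.5)
  expect_error(pagel_transform(C, 1.2), "0, 1")
})

test_that("lambda = 0 on an ultrametric tree reproduces OLS exactly", {
  set.seed(61)
  st <- star_tree(30)
  x <- rnorm(30)
  y <- 1 + 0.5 * x + rnorm(30)
  C <- bm_covariance(st)
  g <- .gls_fit(y, cbind(1, x), pagel_transform(C, 0))
  ols <- coef(lm(y ~ x))
  expect_equal(unname(g$beta), unname(ols), tolerance = 1e-10)
})

test_that("maximum-likelihood lambda matches an independent estimator", {
  tr <- simulate_tree(120, seed = 63)
  y <- simulate_bm_trait(tr, sigma2 = 1, lambda_signal = 0.8, seed = 64)
  f <- fit_pagel_lambda(y, matrix(1, 120), bm_covariance(tr))
  ph <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(f$lambda, ph$lambda, tolerance = 1e-3)
  expect_true(f$lambda_ci[1] <= f$lambda && f$lambda <= f$lambda_ci[2])
})

test_that("lambda estimates separate signal from noise", {
  set.seed(65)
  lam_bm <- lam_iid <- numeric(20)
  for (i in 1:20) {
    tr <- simulate_tree(100)
    C <- bm_covariance(tr)
    lam_bm[i] <- fit_pagel_lambda(simulate_bm_trait(tr, 1, 1),
                                  matrix(1, 100), C)$lambda
    lam_iid[i] <- fit_pagel_lambda(
      stats::setNames(rnorm(100), tr$tip.label), matrix(1, 100), C)$lambda
  }
  expect_gt(median(lam_bm), 0.85)
  expect_lt(median(lam_iid), 0.1)
  expect_true(all(lam_bm >= 0 & lam_bm <= 1))
  expect_true(all(lam_iid >= 0 & lam_iid <= 1))
})

test_that("profile CI covers the generating lambda at nominal rate", {
  set.seed(67)
  hits <- logical(60)
  for (i in seq_along(hits)) {
    tr <- simulate_tree(100)
    y <- simulate_bm_trait(tr, 1, 0.7)
    f <- fit_pagel_lambda(y, matrix(1, 100), bm_covariance(tr))
    hits[i] <- f$lambda_ci[1] <= 0.7 && 0.7 <= f$lambda_ci[2]
  }
  # binomial bounds around 95% for 60 draws
  expect_gte(sum(hits), qbinom(0.005, 60, 0.95))
})

test_that("PGLS residuals behave at the analytic limits", {
  tr <- simulate_tree(50, seed = 71)
  lm_ <- simulate_bm_trait(tr, 1, 0.9, seed = 72, mean = 7)
  # trait exactly linear in log mass: residuals identically zero
  y <- 2 + 0.25 * lm_
  pg <- pgls_residuals(y, lm_, tr)
  expect_lt(max(abs(pg$residuals)), 1e-8)
  # slope recovery within 2 SE under BM noise
  set.seed(73)
  y2 <- 2 + 0.25 * lm_ + simulate_bm_trait(tr, 0.05, 1)
  pg2 <- pgls_residuals(y2, lm_, tr)
  expect_lt(abs(pg2$fit$beta[2] - 0.25), 2 * pg2$fit$se[2] + 0.05)
  # missing species are dropped and the tree pruned
  y3 <- y2; y3[1:5] <- NA
  pg3 <- pgls_residuals(y3, lm_, tr)
  expect_equal(length(pg3$residuals), 45)
  expect_equal(ape::Ntip(pg3$tree), 45)
})

test_that("phylogenetic ANOVA matches the classical F test on a star tree", {
  set.seed(75)
  st <- star_tree(60)
  x <- stats::setNames(rnorm(60), st$tip.label)
  g <- factor(rep(1:4, each = 15))
  pa <- phylo_anova(x, g, st, nsim = 3000, seed = 76)
  classical <- anova(lm(x ~ g))$"Pr(>F)"[1]
  expect_lt(abs(pa$p_phylo - classical), 0.03)
  expect_equal(pa$df, c(3L, 56L))
})

test_that("an extreme group effect is detected at the simulation floor", {
  set.seed(77)
  tr <- simulate_tree(60)
  x <- simulate_bm_trait(tr, 1, 0.5)
  g <- factor(rep(1:3, each = 20))
  x[g == 2] <- x[g == 2] + 10 * sd(x)
  pa <- phylo_anova(x, g, tr, nsim = 500, seed = 78)
  expect_lte(pa$p_phylo, 2 / 501)
  # letters separate the shifted group
  expect_false(pa$letters[["2"]] %in% pa$letters[c("1", "3")])
})

test_that("null p-values are calibrated on a non-trivial phylogeny", {
  tr <- simulate_tree(80, seed = 79)
  g <- simulate_sociality(tr, signal = 0.8, seed = 80)
  C <- bm_covariance(tr)
  L <- chol(C)
  set.seed(81)
  pvals <- replicate(150, {
    y <- stats::setNames(drop(crossprod(L, rnorm(80))), tr$tip.label)
    phylo_anova(y, g, tr, nsim = 200)$p_phylo
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("phylo_anova agrees with phytools on a shared dataset", {
  tr <- simulate_tree(50, seed = 83)
  y <- simulate_bm_trait(tr, 1, 0.9, seed = 84)
  g <- simulate_sociality(tr, n_levels = 3, signal = 0.5, seed = 85)
  mine <- phylo_anova(y, g, tr, nsim = 2000, seed = 86)
  theirs <- phytools::phylANOVA(tr, setNames(as.character(g), names(g)),
                                y, nsim = 2000, posthoc = FALSE)
  expect_equal(mine$F_obs, theirs$F, tolerance = 1e-8)
  expect_lt(abs(mine$p_phylo - theirs$Pf), 0.05)
})

test_that("Bonferroni adjustment caps scaled p-values at one", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  expect_equal(bonferroni_adjust(c(0.9, 0.5, 0.2, 0.1, 0.04))[1], 1)
})

test_that("compact letter display is consistent with pairwise significance", {
  p <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  p["a", "c"] <- p["c", "a"] <- 0.01
  l <- cld_letters(p)
  expect_false(any(strsplit(l[["a"]], "")[[1]] %in%
                     strsplit(l[["c"]], "")[[1]]))
  expect_true(any(strsplit(l[["a"]], "")[[1]] %in%
                    strsplit(l[["b"]], "")[[1]]))
  expect_true(any(strsplit(l[["b"]], "")[[1]] %in%
                    strsplit(l[["c"]], "")[[1]]))
  # no significant pairs: everyone shares one letter
  p1 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unique(cld_letters(p1)), "a")
})

test_that("phylogenetic PCA reduces to ordinary PCA on a star tree", {
  set.seed(87)
  st <- star_tree(50)
  X <- matrix(rnorm(200), 50, 4,
              dimnames = list(st$tip.label, paste0("t", 1:4)))
  Xs <- scale(X)
  pp <- ppca(Xs, st)
  pc <- prcomp(Xs, center = TRUE)
  expect_lt(abs(pp$lambda), 0.05)
  for (j in 1:4) {
    expect_gt(abs(cor(pp$loadings[, j], pc$rotation[, j])), 0.999)
  }
  expect_equal(sum(pp$pct_variance), 100)
  # Kaiser retention from the eigenvalues
  expect_equal(pp$retained_axes, which(pp$eigenvalues > 1))
  # scores are uncorrelated in the C^-1 metric
  Ci <- solve(pagel_transform(bm_covariance(st), pp$lambda))
  G <- t(pp$scores) %*% Ci %*% pp$scores
  offd <- max(abs(G[upper.tri(G)])) / max(abs(diag(G)))
  expect_lt(offd, 1e-8)
})

test_that("ppca eigenvalues agree with phytools phyl.pca", {
  tr <- simulate_tree(60, seed = 89)
  set.seed(90)
  X <- sapply(1:4, function(j) simulate_bm_trait(tr, 1, 0.9))
  X <- X + matrix(rnorm(240, 0, 0.3), 60)
  rownames(X) <- tr$tip.label
  Xs <- scale(X)
  pp <- ppca(Xs, tr)
  th <- phytools::phyl.pca(tr, Xs, method = "lambda", mode = "cov")
  expect_equal(pp$lambda, th$lambda, tolerance = 0.02)
  expect_equal(pp$eigenvalues, unname(diag(th$Eval)), tolerance = 0.02)
})

test_that("Spearman pruning drops one member per over-correlated pair", {
  set.seed(91)
  n <- 80
  a <- rnorm(n)
  tab <- data.frame(T = a + rnorm(n, 0, 0.1),       # rho ~ 0.98 with eta_e
                    eta_e = a + rnorm(n, 0, 0.1),
                    L_alpha = rnorm(n))
  out <- spearman_prune(tab)
  expect_equal(length(out$kept_traits), 2)
  expect_true("L_alpha" %in% out$kept_traits)
  expect_equal(nrow(out$dropped_pairs), 1)
  expect_gt(abs(out$dropped_pairs$rho), 0.7)
  # equal missingness: the canonical-order trait survives
  expect_true("T" %in% out$kept_traits)
  # boundary: rho exactly below/at threshold keeps both
  r <- 0.7
  tab2 <- data.frame(x = 1:20, y = c(1:14, 20, 15, 17, 16, 19, 18))
  rho <- cor(tab2$x, tab2$y, method = "spearman")
  out2 <- spearman_prune(tab2, threshold = abs(rho))
  expect_equal(length(out2$kept_traits), 2)
  # row order of the table does not matter
  perm <- sample(n)
  out3 <- spearman_prune(tab[perm, ])
  expect_equal(out3$kept_traits, out$kept_traits)
  # higher missingness loses the tie
  tab4 <- tab
  tab4$T[1:10] <- NA
  out4 <- spearman_prune(tab4)
  expect_true("eta_e" %in% out4$kept_traits)
  expect_false("T" %in% out4$kept_traits)
})
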