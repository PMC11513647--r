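# Missingness screening and regularized iterative-PCA imputation of the
# life-history trait matrix. Observed cells are never modified; only
# missing cells are filled.

#' Screen traits by missingness
#'
#' Retains traits whose fraction of missing values is strictly below
#' `max_frac` (default 0.40); traits at or above the cap are excluded from
#' imputation and multivariate analyses.
#'
#' @param trait_table Data frame of traits (columns).
#' @param max_frac Missingness cap.
#' @return Character vector of retained trait names.
#' @export
missingness_screen <- function(trait_table, max_frac = 0.40) {
  frac <- colMeans(is.na(as.data.frame(trait_table)))
  names(frac)[frac < max_frac]
}

#' Regularized iterative-PCA imputation
#'
#' Fills missing cells of `X` by the iterative principal-component
#' algorithm: (1) initialize missing cells with column means; (2) perform a
#' PCA with `ncomp` axes on the completed, column-centred matrix, shrinking
#' the leading singular values towards zero by the noise variance estimated
#' from the trailing singular values (ridge regularization); (3) replace
#' the missing cells with their low-rank reconstruction; (4) iterate to
#' convergence. Multiple imputation sets are generated by perturbing the
#' converged imputed cells with column-wise residual noise.
#'
#' @param X Numeric matrix with `NA`s; every column must have some observed
#'   values and (for stable results) < 40% missingness; every row at least
#'   one observed value.
#' @param ncomp Number of principal components (default 2, matching the
#'   retained phylogenetic PCA axes); must be below `min(dim(X))`.
#' @param tol Relative convergence tolerance on the imputed cells.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @param n_sets Number of imputation sets (the point estimate plus
#'   noise-perturbed copies).
#' @param seed Seed for the set perturbations.
#' @return Object of class `imputation_result`: `completed` (the converged
#'   matrix), `sets` (list of `n_sets` completed matrices, the first being
#'   `completed`), `n_iterations`, `converged`, `missing_mask`,
#'   `objective_trace` (observed-cell reconstruction error per iteration).
#' @export
iterative_pca_impute <- function(X, ncomp = 2, tol = 1e-6, max_iter = 1000,
                                 n_sets = 1, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(ncomp >= 1, ncomp < min(n, p))
  mask <- is.na(X)
  if (any(colSums(!mask) == 0)) stop("all-missing column")
  if (any(rowSums(!mask) == 0)) stop("all-missing row")
  if (!any(mask)) {
    return(structure(list(completed = X, sets = rep(list(X), n_sets),
                          n_iterations = 0L, converged = TRUE,
                          missing_mask = mask,
                          objective_trace = numeric(0)),
                     class = "imputation_result"))
  }
  Xc <- X
  for (j in seq_len(p)) Xc[mask[, j], j] <- mean(X[, j], na.rm = TRUE)
  obj <- numeric(0)
  converged <- FALSE
  it <- 0L
  recon <- Xc
  while (it < max_iter) {
    it <- it + 1L
    mu <- colMeans(Xc)
    Z <- sweep(Xc, 2, mu)
    sv <- svd(Z)
    d <- sv$d
    # noise variance from trailing singular values (ridge shrinkage)
    s2 <- if (length(d) > ncomp) {
      sum(d[-seq_len(ncomp)]^2) / ((n - 1) * (p - ncomp))
    } else 0
    dk <- d[seq_len(ncomp)]
    shrunk <- pmax((dk^2 - (n - 1) * s2) / dk, 0)
    recon <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
      (shrunk * t(sv$v[, seq_len(ncomp), drop = FALSE]))
    recon <- sweep(recon, 2, mu, `+`)
    obj <- c(obj, sum((X[!mask] - recon[!mask])^2))
    old <- Xc[mask]
    Xc[mask] <- recon[mask]
    delta <- sqrt(sum((Xc[mask] - old)^2) / max(sum(old^2), 1e-12))
    if (delta < tol) { converged <- TRUE; break }
  }
  sets <- vector("list", n_sets)
  sets[[1L]] <- Xc
  if (n_sets > 1L) {
    if (!is.null(seed)) set.seed(seed)
    # residual noise per column from observed cells
    sd_res <- vapply(seq_len(p), function(j) {
      r <- X[!mask[, j], j] - recon[!mask[, j], j]
      stats::sd(r)
    }, numeric(1))
    sd_res[!is.finite(sd_res)] <- 0
    for (s in 2:n_sets) {
      Xs <- Xc
      for (j in seq_len(p)) {
        idx <- which(mask[, j])
        if (length(idx)) {
          Xs[idx, j] <- Xc[idx, j] + stats::rnorm(length(idx), 0, sd_res[j])
        }
      }
      sets[[s]] <- Xs
    }
  }
  structure(list(completed = Xc, sets = sets, n_iterations = it,
                 converged = converged, missing_mask = mask,
                 objective_trace = obj),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("Iterative-PCA imputation:", sum(x$missing_mask), "cells imputed in",
      x$n_iterations, "iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n")
  invisible(x)
}

#' Compare trait covariation before and after imputation
#'
#' Pairwise Spearman correlations on the pre-imputation matrix (pairwise
#' complete observations) and the completed matrix; reports the maximum
#' absolute difference and the number of sign flips.
#'
#' @param X_pre Matrix with missing values.
#' @param X_post Completed matrix (same traits).
#' @return List with `rho_pre`, `rho_post`, `max_abs_diff`, `sign_flips`.
#' @export
covariation_check <- function(X_pre, X_post) {
  stopifnot(all(dim(X_pre) == dim(X_post)))
  rho_pre <- suppressWarnings(
    stats::cor(X_pre, method = "spearman", use = "pairwise.complete.obs"))
  rho_post <- suppressWarnings(stats::cor(X_post, method = "spearman"))
  d <- abs(rho_pre - rho_post)
  flips <- sum(sign(rho_pre[upper.tri(rho_pre)]) *
                 sign(rho_post[upper.tri(rho_post)]) < 0, na.rm = TRUE)
  list(rho_pre = rho_pre, rho_post = rho_post,
       max_abs_diff = max(d[upper.tri(d)], na.rm = TRUE),
       sign_flips = flips)
}
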