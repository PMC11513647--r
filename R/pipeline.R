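# End-to-end orchestration: selection -> annualization -> grand mean ->
# traits and summaries -> PGLS residuals over log body mass -> per-trait
# phylogenetic ANOVA with Bonferroni -> Spearman pruning, missingness
# screen, imputation -> phylogenetic PCA -> output tables and manifest.

#' Build and validate a pipeline configuration
#'
#' @param input Either a `synthetic_study` object or a list with paths
#'   `bundle` (matrix-bundle directory) and `tree` (Newick file).
#' @param output_dir Directory for the result CSVs and manifest.
#' @param seed Integer seed (required; drives the ANOVA null simulations
#'   and imputation perturbations).
#' @param nsim Null simulations per phylogenetic ANOVA.
#' @param bonferroni Apply the Bonferroni correction across traits.
#' @param spearman_threshold Pairwise Spearman pruning threshold.
#' @param missingness_cap Maximum tolerated missingness fraction per trait.
#' @param ncomp Components for the iterative-PCA imputation.
#' @param n_imputation_sets Imputation sets generated (default 20).
#' @param impute_with_auxiliary Append the complete demographic-summary
#'   columns and log body mass as auxiliary variables during imputation.
#' @param mask_rate Optional MCAR masking rate applied to the life-history
#'   trait table (defaults to the study's `mask_rate` for synthetic input,
#'   0 for bundles).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input, output_dir, seed, nsim = 1000,
                            bonferroni = TRUE, spearman_threshold = 0.70,
                            missingness_cap = 0.40, ncomp = 2,
                            n_imputation_sets = 20,
                            impute_with_auxiliary = TRUE,
                            mask_rate = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  stopifnot(nsim >= 100, spearman_threshold > 0, spearman_threshold <= 1,
            missingness_cap > 0, missingness_cap <= 1, ncomp >= 1)
  structure(list(input = input, output_dir = output_dir, seed = as.integer(seed),
                 nsim = nsim, bonferroni = bonferroni,
                 spearman_threshold = spearman_threshold,
                 missingness_cap = missingness_cap, ncomp = ncomp,
                 n_imputation_sets = n_imputation_sets,
                 impute_with_auxiliary = impute_with_auxiliary,
                 mask_rate = mask_rate),
            class = "pipeline_config")
}

# Table-1-style block membership of every analysed trait
.trait_blocks <- function() {
  list(
    "life history traits" = trait_names(),
    "vital rates" = c("sigma_bar", "gamma_bar", "rho_bar", "phi_bar"),
    "elasticities" = c("E_sigma", "E_gamma", "E_rho", "E_phi"),
    "asymptotics" = c("lam", "deviance"),
    "transients" = c("zeta", "Pi", "reactivity", "attenuation")
  )
}

#' Run the full comparative pipeline
#'
#' Executes selection, annualization, per-species grand means, trait and
#' summary derivation, body-mass-corrected PGLS residuals, per-trait
#' phylogenetic ANOVAs with Bonferroni correction and post hoc letters,
#' Spearman pruning, missingness screening, iterative-PCA imputation and
#' the phylogenetic PCA. Per-trait univariate tests use unimputed data
#' (species with missing values dropped, tree pruned per trait); only the
#' multivariate PCA uses the imputed table. Writes per-species CSVs, a
#' Table-1-style statistics CSV, post hoc letter CSVs, PCA outputs and a
#' JSON run manifest into `config$output_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all result objects (`traits`,
#'   `summaries`, `table1`, `letters`, `ppca`, `imputation`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- load ----
  if (inherits(config$input, "synthetic_study")) {
    records <- config$input$records
    tree <- config$input$tree
    mask_rate <- if (is.null(config$mask_rate)) config$input$mask_rate
                 else config$mask_rate
  } else {
    records <- read_matrix_bundle(config$input$bundle)
    tree <- ape::read.tree(config$input$tree)
    mask_rate <- if (is.null(config$mask_rate)) 0 else config$mask_rate
  }
  log_n <- list(input = length(records))

  # ---- selection ----
  sel <- select_mpms(records)
  records <- sel$retained
  log_n$selected <- length(records)

  # ---- reconcile with the tree ----
  ids <- vapply(records, `[[`, "", "species_id")
  common <- intersect(ids, tree$tip.label)
  dropped_sp <- union(setdiff(ids, common), setdiff(tree$tip.label, common))
  if (!length(common)) stop("empty species intersection with the tree")
  records <- records[ids %in% common]
  tree <- ape::keep.tip(tree, common)
  log_n$in_tree <- length(records)

  # ---- annualize + traits + summaries ----
  traits <- list(); summaries <- list()
  for (r in records) {
    m <- rescale_to_annual(r$mpm)
    tr <- compute_all_traits(m)
    tr$species_id <- r$species_id
    traits[[r$species_id]] <- tr
    sm <- demographic_summary(m)
    sm$species_id <- r$species_id
    summaries[[r$species_id]] <- sm
  }
  traits <- do.call(rbind, traits)
  summaries <- do.call(rbind, summaries)
  gate_failures <- sum(!is.na(summaries$gate_reason))

  soc <- stats::setNames(
    as_sociality(vapply(records, function(r) as.character(r$sociality), "")),
    vapply(records, `[[`, "", "species_id"))
  log_mass <- stats::setNames(
    log(vapply(records, `[[`, 0, "body_mass_g")),
    vapply(records, `[[`, "", "species_id"))

  # optional MCAR masking of the life-history trait table (synthetic runs)
  if (mask_rate > 0) {
    traits[trait_names()] <- apply_mcar(traits[trait_names()], mask_rate,
                                        seed = config$seed + 900L)
  }

  # ---- per-trait PGLS residuals + phylogenetic ANOVA ----
  blocks <- .trait_blocks()
  all_traits <- unlist(blocks, use.names = FALSE)
  tab <- list(); letters_tab <- list(); residuals_list <- list()
  for (bn in names(blocks)) {
    for (tn in blocks[[bn]]) {
      y <- if (tn %in% names(traits)) {
        stats::setNames(traits[[tn]], traits$species_id)
      } else {
        stats::setNames(summaries[[tn]], summaries$species_id)
      }
      y <- y[is.finite(y)]
      if (length(y) < 10 || stats::var(y) <= 0) next
      pg <- tryCatch(pgls_residuals(y, log_mass, tree),
                     error = function(e) NULL)
      if (is.null(pg)) next
      res <- pg$residuals
      an <- tryCatch(
        phylo_anova(res, soc[names(res)], pg$tree, nsim = config$nsim,
                    seed = config$seed + match(tn, all_traits)),
        error = function(e) NULL)
      if (is.null(an)) next
      residuals_list[[tn]] <- res
      r2 <- an$F_obs * an$df[1] / (an$F_obs * an$df[1] + an$df[2])
      tab[[tn]] <- data.frame(
        type = bn, trait = tn, n = length(res), R2 = r2, F = an$F_obs,
        df1 = an$df[1], df2 = an$df[2], p = an$p_phylo,
        p_bonferroni = NA_real_, pagel_lambda = pg$fit$lambda,
        lambda_ci_lo = pg$fit$lambda_ci[1], lambda_ci_hi = pg$fit$lambda_ci[2],
        stringsAsFactors = FALSE)
      letters_tab[[tn]] <- data.frame(
        trait = tn, level = names(an$letters), letters = unname(an$letters),
        stringsAsFactors = FALSE)
    }
  }
  table1 <- do.call(rbind, tab)
  rownames(table1) <- NULL
  if (config$bonferroni) table1$p_bonferroni <- bonferroni_adjust(table1$p)
  letters_tab <- do.call(rbind, letters_tab)

  # ---- multivariate branch: prune, screen, log, residualize, impute ----
  lh <- traits[trait_names()]
  rownames(lh) <- traits$species_id
  time_traits <- c("T", "eta_e", "var_eta_e", "L_max", "L_alpha",
                   "L_alpha_omega")   # traits sharing time units
  pr <- spearman_prune(lh[intersect(time_traits, names(lh))],
                       threshold = config$spearman_threshold)
  cand <- pr$kept_traits
  cand <- intersect(missingness_screen(lh[cand], config$missingness_cap),
                    cand)
  ppca_res <- NULL; imp <- NULL; pc_letters <- NULL; scores_sd <- NULL
  if (length(cand) >= 2) {
    # log-transform positive time-based traits, then PGLS-residualize
    Xr <- matrix(NA_real_, nrow(lh), length(cand),
                 dimnames = list(rownames(lh), cand))
    for (tn in cand) {
      y <- lh[[tn]]
      names(y) <- rownames(lh)
      y <- y[!is.na(y) & y > 0]
      y <- log(y)
      pg <- pgls_residuals(y, log_mass, tree)
      Xr[names(pg$residuals), tn] <- pg$residuals
    }
    keep_rows <- rowSums(!is.na(Xr)) > 0
    Xr <- Xr[keep_rows, , drop = FALSE]
    Xs <- scale(Xr)   # mean 0, variance 1
    aux <- NULL
    if (config$impute_with_auxiliary) {
      aux_cols <- c("sigma_bar", "gamma_bar", "rho_bar", "phi_bar",
                    "E_sigma", "E_gamma", "E_rho", "E_phi",
                    "zeta", "reactivity", "attenuation")
      aux <- as.matrix(summaries[match(rownames(Xs), summaries$species_id),
                                 aux_cols])
      aux <- cbind(aux, log_mass = log_mass[rownames(Xs)])
      ok <- colSums(is.na(aux)) == 0 &
        apply(aux, 2, function(z) stats::sd(z, na.rm = TRUE) > 0)
      aux <- aux[, ok, drop = FALSE]
      if (ncol(aux)) aux <- scale(aux)
    }
    imp_input <- if (!is.null(aux) && ncol(aux)) cbind(Xs, aux) else Xs
    imp <- iterative_pca_impute(imp_input, ncomp = config$ncomp,
                                n_sets = config$n_imputation_sets,
                                seed = config$seed + 800L)
    Xc <- imp$completed[, cand, drop = FALSE]
    tr2 <- ape::keep.tip(tree, rownames(Xc))
    ppca_res <- ppca(Xc, tr2)
    # between-set SD of scores across imputation sets (stability report)
    if (length(imp$sets) > 1) {
      sc <- lapply(imp$sets, function(S) {
        ppca(S[, cand, drop = FALSE], tr2)$scores[, 1]
      })
      scores_sd <- stats::sd(vapply(sc, stats::sd, numeric(1)))
    }
    # post hoc letters along each retained axis
    pc_letters <- list()
    for (ax in ppca_res$retained_axes) {
      sc <- stats::setNames(ppca_res$scores[, ax],
                            rownames(ppca_res$scores))
      an <- phylo_anova(sc, soc[names(sc)], tr2, nsim = config$nsim,
                        seed = config$seed + 700L + ax)
      pc_letters[[paste0("PC", ax)]] <- data.frame(
        axis = paste0("PC", ax), level = names(an$letters),
        letters = unname(an$letters), p = an$p_phylo,
        stringsAsFactors = FALSE)
    }
    pc_letters <- do.call(rbind, pc_letters)
  }

  # ---- outputs ----
  write_trait_table(traits, file.path(config$output_dir, "traits.csv"))
  utils::write.csv(summaries, file.path(config$output_dir, "summaries.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(table1, file.path(config$output_dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(letters_tab,
                   file.path(config$output_dir, "posthoc_letters.csv"),
                   row.names = FALSE)
  if (!is.null(ppca_res)) {
    utils::write.csv(as.data.frame(ppca_res$loadings),
                     file.path(config$output_dir, "ppca_loadings.csv"))
    utils::write.csv(as.data.frame(ppca_res$scores),
                     file.path(config$output_dir, "ppca_scores.csv"))
    utils::write.csv(
      data.frame(axis = seq_along(ppca_res$eigenvalues),
                 eigenvalue = ppca_res$eigenvalues,
                 pct_variance = ppca_res$pct_variance),
      file.path(config$output_dir, "ppca_variance.csv"), row.names = FALSE)
    if (!is.null(pc_letters)) {
      utils::write.csv(pc_letters,
                       file.path(config$output_dir, "ppca_letters.csv"),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    seed = config$seed, nsim = config$nsim,
    counts = log_n, gate_failures = gate_failures,
    rejections = sel$rejection_log,
    species_dropped_tree_mismatch = dropped_sp,
    pruned_traits = pr$dropped_pairs,
    ppca_traits = if (length(cand)) cand else character(0),
    ppca_lambda = if (!is.null(ppca_res)) ppca_res$lambda else NA,
    imputation_converged = if (!is.null(imp)) imp$converged else NA,
    ppca_score_sd_between_sets = scores_sd,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(traits = traits, summaries = summaries, table1 = table1,
                 letters = letters_tab, ppca = ppca_res, imputation = imp,
                 pc_letters = pc_letters, manifest = manifest))
}

#' Format per-trait fits as a Table-1-style data frame
#'
#' Orders rows into the five blocks (life history traits; vital rates;
#' elasticities; asymptotics; transients) and prints d.f. as
#' `(k - 1, n - k)`.
#'
#' @param table1 The `table1` element returned by [run_pipeline()].
#' @return Data frame with columns `type`, `trait`, `R2`, `F`, `d.f.`,
#'   `p`, `p_bonferroni`, `pagel_lambda`, `lambda_ci`.
#' @export
report_table1 <- function(table1) {
  blocks <- names(.trait_blocks())
  missing_blocks <- setdiff(blocks, unique(table1$type))
  if (length(missing_blocks)) {
    warning("empty Table-1 block(s): ", paste(missing_blocks, collapse = ", "))
  }
  table1 <- table1[order(match(table1$type, blocks)), ]
  data.frame(type = table1$type, trait = table1$trait,
             R2 = round(table1$R2, 3), F = round(table1$F, 3),
             d.f. = paste(table1$df1, table1$df2, sep = ", "),
             p = signif(table1$p, 3),
             p_bonferroni = signif(table1$p_bonferroni, 3),
             pagel_lambda = round(table1$pagel_lambda, 3),
             lambda_ci = paste0(round(table1$lambda_ci_lo, 3), "-",
                                round(table1$lambda_ci_hi, 3)),
             stringsAsFactors = FALSE)
}
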