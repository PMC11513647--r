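# Synthetic studies with known ground truth: ultrametric trees, body
# masses, a phylogenetically clustered five-level sociality continuum, and
# Lefkovitch matrix models whose life-history parameters embed allometric
# and group effects. Everything is deterministic under a fixed seed.

#' Simulate an ultrametric birth-death tree
#'
#' Wraps `ape::rphylo` and rescales all branch lengths to unit root-to-tip
#' depth. Tip labels are `sp_001, sp_002, ...`.
#'
#' @param n_tips Number of tips (at least 3).
#' @param birth,death Birth and death rates.
#' @param seed Optional integer seed.
#' @return A `phylo` object of depth 1.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  stopifnot(n_tips >= 3)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = death)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp_%03d", seq_len(n_tips))
  tr
}

#' Simulate a Brownian-motion trait with Pagel's lambda signal
#'
#' Draws one multivariate normal vector with covariance
#' `sigma2 * pagel_transform(C, lambda_signal)` where `C` is the tree's
#' Brownian covariance. `lambda_signal = 0` gives i.i.d. normals,
#' `lambda_signal = 1` pure Brownian motion.
#'
#' @param tree A `phylo` object.
#' @param sigma2 Brownian rate.
#' @param lambda_signal Signal parameter in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param mean Trait mean (root state).
#' @return Named numeric vector (tip labels).
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, lambda_signal = 1,
                              seed = NULL, mean = 0) {
  if (!is.null(seed)) set.seed(seed)
  C <- pagel_transform(bm_covariance(tree), lambda_signal)
  L <- chol(sigma2 * C)
  stats::setNames(mean + drop(crossprod(L, stats::rnorm(nrow(C)))),
                  tree$tip.label)
}

#' Simulate an ordinal sociality continuum with phylogenetic signal
#'
#' A latent Brownian liability with Pagel's-lambda signal is thresholded at
#' its empirical quantiles into `n_levels` ordered levels, so levels
#' cluster on clades when the signal is strong. Resamples (with a shifted
#' seed) in the rare event of an empty level.
#'
#' @param tree A `phylo` object.
#' @param n_levels Number of ordered levels (default 5, the sociality
#'   continuum).
#' @param signal Pagel's lambda of the latent liability.
#' @param seed Optional integer seed.
#' @return Ordered factor named by tip label, levels from
#'   [sociality_levels()] when `n_levels = 5`.
#' @export
simulate_sociality <- function(tree, n_levels = 5, signal = 0.9,
                               seed = NULL) {
  stopifnot(n_levels >= 2)
  lv <- if (n_levels == 5) sociality_levels() else paste0("level_", 1:n_levels)
  s <- if (is.null(seed)) sample.int(1e6, 1) else seed
  for (try in 1:20) {
    liab <- simulate_bm_trait(tree, sigma2 = 1, lambda_signal = signal,
                              seed = s + (try - 1L) * 1000L)
    cuts <- stats::quantile(liab, probs = seq(0, 1, length.out = n_levels + 1))
    g <- cut(liab, breaks = unique(cuts), labels = FALSE,
             include.lowest = TRUE)
    if (length(unique(g)) == n_levels) {
      return(stats::setNames(factor(lv[g], levels = lv, ordered = TRUE),
                             tree$tip.label))
    }
  }
  stop("could not produce non-empty levels")
}

#' Assemble a Lefkovitch matrix model from stage-level parameters
#'
#' Stages are ordered by development. Column `j` of `U` carries survival
#' `survival[j]`, split between advancing to stage `j + 1` (conditional
#' fraction `growth[j]`), shrinking to stage `j - 1` (conditional fraction
#' `shrinkage[j - 1]`) and stasis. `F` places `fertility[j]` offspring into
#' stage 1. When no shrinkage is present the expected life-history traits
#' of the generating chain (`eta_e`, `R0`, `p_R`, `L_alpha`) have closed
#' forms and are stored in the `truth` attribute.
#'
#' @param survival Per-stage survival probabilities, each `< 1`
#'   (length `n_stages`).
#' @param growth Conditional advance fractions for stages `1..n-1`.
#' @param fertility Per-stage fertilities (length `n_stages`).
#' @param shrinkage Optional conditional shrink fractions for stages
#'   `2..n` (default none).
#' @param P Projection interval.
#' @param species_id Identifier.
#' @return An `mpm` with attribute `truth` (list of expected traits, or
#'   `NULL` when shrinkage makes the closed forms inapplicable).
#' @export
simulate_mpm <- function(survival, growth, fertility, shrinkage = NULL,
                         P = 1, species_id = NA_character_) {
  n <- length(survival)
  stopifnot(n >= 2, length(growth) == n - 1, length(fertility) == n,
            all(survival >= 0), all(growth >= 0), all(growth <= 1),
            all(fertility >= 0))
  if (any(survival >= 1)) stop("stage survival must be < 1")
  if (is.null(shrinkage)) shrinkage <- rep(0, n - 1)
  stopifnot(length(shrinkage) == n - 1, all(shrinkage >= 0),
            all(shrinkage <= 1))
  U <- matrix(0, n, n)
  for (j in seq_len(n)) {
    g <- if (j < n) growth[j] else 0
    r <- if (j > 1) shrinkage[j - 1] else 0
    if (g + r > 1) stop("growth + shrinkage exceed 1 in stage ", j)
    if (j < n) U[j + 1, j] <- survival[j] * g
    if (j > 1) U[j - 1, j] <- survival[j] * r
    U[j, j] <- survival[j] * (1 - g - r)
  }
  F_ <- matrix(0, n, n)
  F_[1, ] <- fertility
  m <- validate_mpm(matU = U, matF = F_, P = P, species_id = species_id)
  if (all(shrinkage == 0)) {
    # closed forms of the forward chain, starting in stage 1:
    # from stage j: advance w.p. a_j, stay w.p. b_j, die otherwise
    a <- survival[-n] * growth
    b <- survival * c(1 - growth, 1)
    reach <- cumprod(c(1, a / (1 - b[-n])))       # P(ever reach stage r)
    res <- 1 / (1 - b)                            # residence time per visit
    repro <- which(fertility > 0)
    truth <- list(
      eta_e = sum(reach * res),
      R0 = sum(reach * res * fertility),
      p_R = if (length(repro)) reach[min(repro)] else 0,
      L_alpha = if (length(repro) && min(repro) > 1) {
        sum(res[seq_len(min(repro) - 1)])
      } else 0
    )
    attr(m, "truth") <- truth
  }
  m
}

#' Generate a full synthetic comparative study
#'
#' Builds a tree, log-normal body masses with phylogenetic signal, a
#' sociality continuum, and one matrix model per species whose adult
#' survival embeds a quarter-power allometry of longevity on body mass
#' (`log T = a + b log(mass) + group effect + Brownian noise`), with
#' fertility tuned so the net reproductive rate fluctuates around 1
#' (populations near demographic equilibrium). All generated models have
#' at least 4 stages, a U/F split and column survival sums below 1, so
#' they pass the study-selection criteria.
#'
#' @param n_species Number of species (default 152, the scale of the real
#'   comparative dataset).
#' @param effect_profile List with elements `group_T` (per-level additive
#'   shifts of log longevity, length 5, default all 0 = null profile),
#'   `slope` (allometric slope, default 0.25), `intercept`,
#'   `sociality_signal` (default 0.9), `bm_sigma2` (Brownian noise variance
#'   of log longevity, default 0.04).
#' @param seed Integer seed (required for reproducibility).
#' @param mask_rate Missing-at-random masking rate recorded for downstream
#'   trait tables (default 0.15; apply with [apply_mcar()]).
#' @return Object of class `synthetic_study`: `tree`, `records`, `truth`,
#'   `seed`, `mask_rate`.
#' @export
make_dataset <- function(n_species = 152,
                         effect_profile = list(),
                         seed = 1L,
                         mask_rate = 0.15) {
  ep <- utils::modifyList(
    list(group_T = rep(0, 5), slope = 0.25, intercept = -0.2,
         sociality_signal = 0.9, bm_sigma2 = 0.04,
         mass_meanlog = 7, mass_sigma2 = 4),
    effect_profile)
  tree <- simulate_tree(n_species, seed = seed)
  soc <- simulate_sociality(tree, signal = ep$sociality_signal,
                            seed = seed + 1L)
  log_mass <- simulate_bm_trait(tree, sigma2 = ep$mass_sigma2,
                                lambda_signal = 0.9, seed = seed + 2L,
                                mean = ep$mass_meanlog)
  noise <- simulate_bm_trait(tree, sigma2 = ep$bm_sigma2,
                             lambda_signal = 0.9, seed = seed + 3L)
  set.seed(seed + 4L)
  logT <- ep$intercept + ep$slope * log_mass +
    ep$group_T[as.integer(soc)] + noise
  T_target <- pmax(exp(logT), 1.25)
  s_ad <- pmin(pmax(1 - 1 / T_target, 0.05), 0.95)
  records <- vector("list", n_species)
  for (k in seq_len(n_species)) {
    s_juv <- stats::runif(3, 0.4, 0.8)
    surv <- c(s_juv, s_ad[k])
    grow <- stats::runif(3, 0.6, 0.95)
    a <- surv[-4] * grow
    b <- surv * c(1 - grow, 1)
    reach_ad <- prod(a / (1 - b[-4]))
    res_ad <- 1 / (1 - b[4])
    R0_target <- exp(stats::rnorm(1, 0, 0.25))
    fert <- c(0, 0, 0, R0_target / (reach_ad * res_ad))
    id <- tree$tip.label[k]
    m <- simulate_mpm(surv, grow, fert, species_id = id)
    m$study_duration <- round(stats::runif(1, 3, 30))
    records[[k]] <- list(species_id = id, mpm = m,
                         sociality = soc[[k]],
                         body_mass_g = exp(log_mass[[k]]),
                         log_body_mass = log_mass[[k]])
  }
  structure(list(tree = tree, records = records,
                 truth = list(T_target = stats::setNames(T_target,
                                                         tree$tip.label),
                              group_T = ep$group_T, slope = ep$slope,
                              intercept = ep$intercept,
                              sociality_signal = ep$sociality_signal,
                              sociality = soc, log_mass = log_mass),
                 seed = seed, mask_rate = mask_rate),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic comparative study:", length(x$records), "species, seed",
      x$seed, "\n")
  print(table(vapply(x$records, function(r) as.character(r$sociality), "")))
  invisible(x)
}

#' Mask cells of a trait table missing-at-random
#'
#' @param df Data frame of numeric traits.
#' @param rate Masking probability per cell.
#' @param seed Optional integer seed.
#' @return The data frame with masked cells set to `NA`.
#' @export
apply_mcar <- function(df, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_along(df)) {
    hit <- stats::runif(nrow(df)) < rate
    df[hit, j] <- NA
  }
  df
}
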