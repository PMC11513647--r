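# The 11 life-history traits derived from one (annualized) MPM.
# Undefined quantities (e.g. reproductive traits of a sterile model) are
# returned as NA and propagate downstream as missing values.

#' Canonical life-history trait names
#'
#' Order: generation time `T`, net reproductive output `R0`, mean life
#' expectancy `eta_e`, variance in life expectancy `var_eta_e`, maximum
#' longevity `L_max`, age at maturity `L_alpha`, reproductive window
#' `L_alpha_omega`, maturity probability `p_R`, survivorship shape `s_lx`,
#' reproduction shape `s_mx`, degree of parity `S`.
#'
#' @return Character vector of the 11 trait names.
#' @export
trait_names <- function() {
  c("T", "R0", "eta_e", "var_eta_e", "L_max", "L_alpha", "L_alpha_omega",
    "p_R", "s_lx", "s_mx", "S")
}

.repro_stages <- function(matF) which(colSums(as.matrix(matF)) > 0)

#' Net reproductive output R0
#'
#' The expected lifetime number of offspring of an average individual:
#' the dominant eigenvalue of `F (I - U)^-1`.
#'
#' @param matU,matF Survival and reproduction sub-matrices.
#' @return Nonnegative scalar.
#' @export
net_reproductive_rate <- function(matU, matF) {
  if (all(matF == 0)) return(0)
  R <- as.matrix(matF) %*% fundamental_matrix(matU)
  max(Re(eigen(R, only.values = TRUE)$values))
}

#' Generation time T
#'
#' The average age of reproductive individuals. Default measure
#' `T = log(R0) / log(lambda)`, consistent with the net reproductive rate
#' and population growth rate machinery; `method = "abar"` instead returns
#' the mean age of mothers at the stable structure,
#' `T = lambda v'w / (v'Fw)`. Returns `NA` (flagged undefined) when
#' `lambda = 1` and `R0 = 1` simultaneously.
#'
#' @inheritParams net_reproductive_rate
#' @param method `"R0"` (default) or `"abar"`.
#' @return Generation time in projection-interval units (years once
#'   annualized).
#' @export
generation_time <- function(matU, matF, method = c("R0", "abar")) {
  method <- match.arg(method)
  A <- as.matrix(matU) + as.matrix(matF)
  lam <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (lam <= 0) stop("nonpositive population growth rate")
  if (method == "abar") {
    es <- eigen_structure(A, check_gate = FALSE)
    denom <- sum(es$v * (as.matrix(matF) %*% es$w))
    if (denom <= 0) stop("no reproduction at stable structure")
    return(es$lam * sum(es$v * es$w) / denom)
  }
  R0 <- net_reproductive_rate(matU, matF)
  if (R0 <= 0) stop("nonpositive net reproductive output")
  if (abs(lam - 1) < 1e-10) {
    if (abs(R0 - 1) < 1e-10) return(NA_real_)  # 0/0: undefined
    stop("generation time undefined: lambda = 1 with R0 != 1")
  }
  log(R0) / log(lam)
}

#' Maximum longevity L_max
#'
#' The first age at which more than 99% of a cohort has died: the smallest
#' `x` with `lx[x]` strictly below 0.01.
#'
#' @inheritParams survivorship_schedule
#' @return Integer age in projection intervals.
#' @export
max_longevity <- function(matU, start = NULL, xmax = 1000) {
  lx <- survivorship_schedule(matU, start, xmax, stop_tol = 0)
  hit <- which(lx < 0.01)
  if (!length(hit)) {
    stop("99% cohort death not reached by age ", xmax,
         "; increase xmax")
  }
  hit[1L] - 1L
}

# absorbing-chain decomposition with reproductive stages made absorbing;
# shared by p_R, L_alpha and L_alpha_omega
.maturity_chain <- function(matU, matF, start) {
  matU <- as.matrix(matU); matF <- as.matrix(matF)
  n <- nrow(matU)
  repro <- .repro_stages(matF)
  if (!length(repro)) stop("no reproductive stage (all F columns zero)")
  if (is.null(start)) start <- default_start_distribution(matF)
  start <- .check_start(start, n)
  tr <- setdiff(seq_len(n), repro)
  cR <- start[repro]
  out <- list(repro = repro, tr = tr, cR = cR)
  if (length(tr)) {
    Q <- matU[tr, tr, drop = FALSE]
    PRT <- matU[repro, tr, drop = FALSE]
    NT <- solve(diag(length(tr)) - Q)
    cT <- start[tr]
    out$entry <- as.vector(PRT %*% (NT %*% cT))          # P(enter stage r)
    out$entry_age <- as.vector(PRT %*% (NT %*% (NT %*% cT)))  # sum age * P
  } else {
    out$entry <- numeric(0)
    out$entry_age <- numeric(0)
  }
  out$p_R <- sum(cR) + sum(out$entry)
  out
}

#' Maturity probability p_R
#'
#' The probability that an individual from the cohort entry distribution
#' reaches a reproductive stage (a column of `F` with positive sum) before
#' dying, from the absorbing chain in which reproductive stages absorb.
#'
#' @inheritParams net_reproductive_rate
#' @param start Cohort entry distribution; defaults to
#'   [default_start_distribution()].
#' @return Probability in `[0, 1]`.
#' @export
maturity_probability <- function(matU, matF, start = NULL) {
  min(.maturity_chain(matU, matF, start)$p_R, 1)
}

#' Age at maturity L_alpha
#'
#' Expected age at first entry into a reproductive stage, conditional on
#' ever reaching one (mean absorption time of the conditioned chain).
#' Individuals starting in a reproductive stage mature at age 0.
#'
#' @inheritParams maturity_probability
#' @return Age in projection intervals.
#' @export
age_at_maturity <- function(matU, matF, start = NULL) {
  ch <- .maturity_chain(matU, matF, start)
  if (ch$p_R <= 0) stop("maturity probability is zero")
  sum(ch$entry_age) / ch$p_R
}

#' Reproductive window L_alpha_omega
#'
#' Mean remaining life expectancy at the moment of first entry into a
#' reproductive stage: the entry distribution over reproductive stages
#' (conditional on maturing) mixed with the per-stage residual life
#' expectancies `colSums((I - U)^-1)`.
#'
#' @inheritParams maturity_probability
#' @return Duration in projection intervals.
#' @export
reproductive_window <- function(matU, matF, start = NULL) {
  ch <- .maturity_chain(matU, matF, start)
  if (ch$p_R <= 0) stop("maturity probability is zero")
  eta_stage <- colSums(fundamental_matrix(matU))
  d <- ch$cR + if (length(ch$entry)) ch$entry else 0
  sum(d * eta_stage[ch$repro]) / ch$p_R
}

#' Shape of age-specific survivorship s_lx
#'
#' Standardizes age to `[0, 1]` over the ages with positive survivorship
#' and log-survivorship to `g = log lx / log lx_last`, then returns
#' `0.5 - integral(g)` (trapezoid). Constant per-step survival (exponential
#' decline) maps to 0; senescent (increasingly steep) survivorship is
#' positive; the statistic is bounded in `[-0.5, +0.5]` for monotone
#' schedules.
#'
#' @param lx Survivorship vector over ages `0..length-1` with `lx[1] = 1`.
#' @return Shape statistic, or `NA` when undefined (no mortality observed).
#' @export
shape_survivorship <- function(lx) {
  stopifnot(length(lx) >= 1L, abs(lx[1L] - 1) < 1e-12)
  keep <- which(lx > 0)
  if (any(diff(keep) != 1L)) keep <- seq_len(which(diff(keep) != 1L)[1L])
  lx <- lx[keep]
  n <- length(lx)
  if (n < 3L) stop("need at least 3 ages with positive survivorship")
  if (lx[n] >= 1) return(NA_real_)  # no mortality: shape undefined
  xt <- (seq_len(n) - 1) / (n - 1)
  g <- log(lx) / log(lx[n])
  area <- sum(diff(xt) * (g[-n] + g[-1L]) / 2)
  0.5 - area
}

#' Shape of age-specific reproduction s_mx
#'
#' Compares the cumulative reproduction curve over standardized age with
#' the straight line of constant reproduction. The cumulative curve is
#' anchored at zero before the first age (grid `x = 0..n` with
#' `M(x) = sum(mx[y], y < x)`), so a constant schedule maps to exactly 0;
#' early-concentrated reproduction gives positive values and
#' late-concentrated reproduction negative values; bounded in
#' `[-0.5, +0.5]`.
#'
#' @param lx Survivorship vector (positive survivorship defines the ages
#'   over which reproduction is standardized).
#' @param mx Per-capita fertility at the same ages (`NA` where undefined).
#' @return Shape statistic.
#' @export
shape_reproduction <- function(lx, mx) {
  stopifnot(length(lx) == length(mx))
  keep <- which(lx > 0 & !is.na(mx))
  if (length(keep) < 3L) stop("need at least 3 ages with defined reproduction")
  mx <- mx[keep]
  total <- sum(mx)
  if (total <= 0) stop("zero total reproduction")
  n <- length(mx)
  M <- c(0, cumsum(mx)) / total   # grid x = 0..n, anchored at 0
  xt <- (0:n) / n
  area <- sum(diff(xt) * (M[-(n + 1L)] + M[-1L]) / 2)
  area - 0.5
}

#' Degree of parity S
#'
#' Shannon entropy (natural log) of the normalized age-distribution of
#' reproduction `p_x = lx * mx / sum(lx * mx)`. Strict semelparity (all
#' reproduction at one age) gives `S = 0`; reproduction spread uniformly
#' over `k` ages gives `log k`.
#'
#' @inheritParams shape_reproduction
#' @return Nonnegative entropy.
#' @export
degree_of_parity <- function(lx, mx) {
  stopifnot(length(lx) == length(mx))
  ok <- !is.na(mx) & lx > 0
  p <- lx[ok] * mx[ok]
  tot <- sum(p)
  if (tot <= 0) stop("zero total reproduction")
  p <- p / tot
  p <- p[p > 0]   # 0 log 0 = 0
  -sum(p * log(p)) + 0  # + 0 normalizes IEEE negative zero
}

#' Compute all 11 life-history traits of a matrix population model
#'
#' Assembles the full trait vector from the age-from-stage schedules and
#' absorbing-chain quantities. Traits whose preconditions fail (e.g. all
#' reproductive traits of a sterile model, or shapes of a schedule without
#' observable mortality) are flagged `NA` and flow downstream as missing
#' values. Shape metrics are computed on schedules truncated at the
#' `L_max` age to avoid mortality/fertility plateau artefacts.
#'
#' @param mpm An `mpm` object (annualize first with [rescale_to_annual()]
#'   so traits are in years).
#' @param start Cohort entry distribution; defaults to
#'   [default_start_distribution()].
#' @param xmax Maximum age evaluated.
#' @return One-row data frame with the columns of [trait_names()].
#' @export
compute_all_traits <- function(mpm, start = NULL, xmax = 1000) {
  stopifnot(inherits(mpm, "mpm"))
  matU <- mpm$matU; matF <- mpm$matF
  if (is.null(start)) start <- default_start_distribution(matF)
  out <- stats::setNames(as.list(rep(NA_real_, 11L)), trait_names())

  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  mom <- safe(lifespan_moments(matU, start))
  if (is.list(mom)) { out$eta_e <- mom$eta_e; out$var_eta_e <- mom$var_eta_e }
  Lmax <- safe(max_longevity(matU, start, xmax))
  out$L_max <- Lmax
  out$R0 <- safe(net_reproductive_rate(matU, matF))
  sterile <- is.na(out$R0) || out$R0 <= 0
  if (!sterile) {
    out$T <- safe(generation_time(matU, matF))
    out$p_R <- safe(maturity_probability(matU, matF, start))
    out$L_alpha <- safe(age_at_maturity(matU, matF, start))
    out$L_alpha_omega <- safe(reproductive_window(matU, matF, start))
  }

  # schedules truncated at L_max for the shape metrics
  trunc_age <- if (is.na(Lmax)) xmax else Lmax
  lx <- survivorship_schedule(matU, start, trunc_age, stop_tol = 0)
  out$s_lx <- safe(shape_survivorship(lx))
  if (!sterile) {
    mx <- fertility_schedule(matU, matF, start, trunc_age, stop_tol = 1e-12)
    length(mx) <- length(lx)
    out$s_mx <- safe(shape_reproduction(lx, mx))
    out$S <- safe(degree_of_parity(lx, mx))
  }
  as.data.frame(out, check.names = FALSE)
}
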