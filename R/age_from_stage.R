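# Age-from-stage machinery: collapse the stage-structured survival matrix U
# into age-indexed survivorship lx and fertility mx schedules, and the
# absorbing Markov-chain lifespan moments that underlie the life-history
# traits. Ages count projection intervals, age 0 = first census, so a cohort
# certain to die before the second census has life expectancy 1.

#' Default cohort entry distribution
#'
#' All mass is placed on the stage into which offspring are born, taken as
#' the row of `matF` with the largest total reproductive inflow (ties go to
#' the first such stage). Falls back to the first stage when `matF` is zero.
#'
#' @param matF Reproduction sub-matrix.
#' @return Probability vector over stages.
#' @export
default_start_distribution <- function(matF) {
  n <- nrow(matF)
  rs <- rowSums(matF)
  c0 <- numeric(n)
  c0[if (any(rs > 0)) which.max(rs) else 1L] <- 1
  c0
}

.check_start <- function(start, n) {
  stopifnot(length(start) == n, all(start >= 0))
  if (abs(sum(start) - 1) > 1e-8) stop("start distribution must sum to 1")
  start
}

#' Fundamental matrix of the survival process
#'
#' `N = (I - U)^-1`; entry `N[i, j]` is the expected number of projection
#' intervals an individual starting in stage `j` spends in stage `i` before
#' death. Requires the survival process to be transient (spectral radius of
#' `U` below 1); a stage with survival column sum 1 and no outflow makes
#' `I - U` singular and is reported by name.
#'
#' @param matU Survival/transition sub-matrix.
#' @return The fundamental matrix.
#' @export
fundamental_matrix <- function(matU) {
  matU <- as.matrix(matU)
  n <- nrow(matU)
  sr <- max(Mod(eigen(matU, only.values = TRUE)$values))
  if (sr >= 1 - 1e-12) {
    cs <- colSums(matU)
    bad <- which(cs >= 1 - 1e-12)
    stop("I - U is singular (spectral radius ", signif(sr, 6),
         "): immortal stage(s) ",
         if (length(bad)) paste(bad, collapse = ", ") else "(cyclic)",
         " with survival column sum 1")
  }
  solve(diag(n) - matU)
}

#' Age-specific survivorship schedule from a stage-structured model
#'
#' `lx[x] = 1' U^x c`: the proportion of a cohort with entry distribution
#' `c` still alive at age `x`. Iteration stops at `xmax` or once `lx`
#' drops below `stop_tol`.
#'
#' @param matU Survival/transition sub-matrix.
#' @param start Cohort entry distribution over stages; defaults to all mass
#'   on the first stage.
#' @param xmax Maximum age (projection intervals) to evaluate.
#' @param stop_tol Early-stop threshold on `lx`.
#' @return Numeric vector of survivorship at ages `0..length-1`.
#' @export
survivorship_schedule <- function(matU, start = NULL, xmax = 1000,
                                  stop_tol = 1e-7) {
  matU <- as.matrix(matU)
  n <- nrow(matU)
  if (is.null(start)) { start <- numeric(n); start[1L] <- 1 }
  start <- .check_start(start, n)
  lx <- numeric(xmax + 1L)
  x <- start
  lx[1L] <- 1
  for (k in seq_len(xmax)) {
    x <- matU %*% x
    lx[k + 1L] <- sum(x)
    if (lx[k + 1L] < stop_tol) { lx <- lx[seq_len(k + 1L)]; break }
  }
  lx
}

#' Age-specific fertility schedule from a stage-structured model
#'
#' `mx[x] = (1' F U^x c) / (1' U^x c)`: per-capita reproduction at age `x`
#' conditional on being alive. Ages where the cohort is extinct (`lx = 0`,
#' below `stop_tol`) are flagged `NA`.
#'
#' @inheritParams survivorship_schedule
#' @param matF Reproduction sub-matrix.
#' @return Numeric vector of `mx` at ages `0..length-1`, `NA` once extinct.
#' @export
fertility_schedule <- function(matU, matF, start = NULL, xmax = 1000,
                               stop_tol = 1e-7) {
  matU <- as.matrix(matU); matF <- as.matrix(matF)
  n <- nrow(matU)
  if (is.null(start)) { start <- numeric(n); start[1L] <- 1 }
  start <- .check_start(start, n)
  x <- start
  mx <- numeric(0)
  for (k in 0:xmax) {
    l <- sum(x)
    mx <- c(mx, if (l < stop_tol) NA_real_ else sum(matF %*% x) / l)
    if (l < stop_tol) break
    x <- matU %*% x
  }
  mx
}

#' Joint age schedule (lx and mx) of a matrix population model
#'
#' @param mpm An `mpm` object, or supply `matU`/`matF` directly.
#' @inheritParams fertility_schedule
#' @return Data frame with columns `age`, `lx`, `mx`.
#' @export
age_schedule <- function(mpm = NULL, matU = mpm$matU, matF = mpm$matF,
                         start = NULL, xmax = 1000, stop_tol = 1e-7) {
  if (is.null(start)) start <- default_start_distribution(matF)
  lx <- survivorship_schedule(matU, start, xmax, stop_tol)
  mx <- fertility_schedule(matU, matF, start, xmax, stop_tol)
  len <- max(length(lx), length(mx))
  length(lx) <- len; length(mx) <- len
  data.frame(age = 0:(len - 1L), lx = lx, mx = mx)
}

#' Mean and variance of cohort lifespan
#'
#' Absorbing-chain moments of the time to death, in projection intervals
#' counted from the first census: mean `eta_e = 1' N c` and variance
#' `var_eta_e = 1'(2N - I)N c - (1' N c)^2` with `N` the fundamental matrix
#' and `c` the cohort entry distribution.
#'
#' @inheritParams survivorship_schedule
#' @return List with elements `eta_e` and `var_eta_e`.
#' @export
lifespan_moments <- function(matU, start = NULL) {
  matU <- as.matrix(matU)
  n <- nrow(matU)
  if (is.null(start)) { start <- numeric(n); start[1L] <- 1 }
  start <- .check_start(start, n)
  N <- fundamental_matrix(matU)
  eta <- sum(N %*% start)
  v <- sum((2 * N - diag(n)) %*% N %*% start) - eta^2
  list(eta_e = eta, var_eta_e = max(v, 0))
}
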