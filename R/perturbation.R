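# Asymptotic eigen-structure, stable-structure-weighted vital rates,
# elasticities of lambda to vital rates, and transient metrics. Everything
# here sits behind the irreducible+primitive+ergodic gate, which guarantees
# a single real dominant eigenvalue.

#' Eigen-structure of a projection matrix
#'
#' Dominant eigenvalue `lam`, stable stage distribution `w` (right
#' eigenvector, sums to 1), reproductive values `v` (left eigenvector,
#' scaled so `v'w = 1`) and subdominant eigenvalue `lam2` (the eigenvalue
#' with second-largest modulus; of a complex-conjugate pair, the member
#' with positive imaginary part).
#'
#' @param A Projection matrix or `mpm`.
#' @param check_gate Require the irreducible+primitive+ergodic gate
#'   (default `TRUE`).
#' @return List with `lam`, `w`, `v`, `lam2`.
#' @export
eigen_structure <- function(A, check_gate = TRUE) {
  if (inherits(A, "mpm")) A <- A$matA
  A <- as.matrix(A)
  if (check_gate) {
    g <- check_ergodicity(A)
    if (!(g$irreducible && g$primitive && g$ergodic)) {
      stop("gate failure: matrix is ",
           paste(c("reducible", "imprimitive", "non-ergodic")[
             !unlist(g)], collapse = ", "))
    }
  }
  er <- eigen(A)
  i1 <- which.max(Mod(er$values))
  lam <- Re(er$values[i1])
  w <- Re(er$vectors[, i1])
  w <- w / sum(w)
  el <- eigen(t(A))
  j1 <- which.max(Mod(el$values))
  v <- Re(el$vectors[, j1])
  v <- v / sum(v * w)   # v'w = 1
  rest <- er$values[-i1]
  lam2 <- if (length(rest)) {
    cand <- rest[which(Mod(rest) > max(Mod(rest)) - 1e-12)]
    pos <- cand[Im(cand) >= 0]
    if (length(pos)) pos[1L] else cand[1L]
  } else NA_complex_
  list(lam = lam, w = w, v = v, lam2 = lam2)
}

#' Deviance of population growth rate from equilibrium
#'
#' `|1 - lambda|`: distance of the asymptotic growth rate from demographic
#' stability.
#'
#' @param lam Dominant eigenvalue.
#' @return Nonnegative scalar.
#' @export
deviance_from_equilibrium <- function(lam) abs(1 - lam)

#' Stable-structure-weighted mean vital rates
#'
#' Per-stage vital rates from the column parameterization of `U` and `F`:
#' survival `sigma_j` = column sum of `U`; growth `gamma_j` = below-diagonal
#' mass of column `j` divided by `sigma_j`; shrinkage `rho_j` =
#' above-diagonal mass divided by `sigma_j`; reproduction `phi_j` = column
#' sum of `F`. Each is averaged over stages with the stable-distribution
#' weights `w`; the survival-conditioned rates (`gamma`, `rho`) are averaged
#' over stages with `sigma_j > 0` with renormalized weights.
#'
#' @param matU,matF Sub-matrices.
#' @param w Stable stage distribution.
#' @return List with `sigma_bar`, `gamma_bar`, `rho_bar`, `phi_bar`.
#' @export
mean_vital_rates <- function(matU, matF, w) {
  matU <- as.matrix(matU); matF <- as.matrix(matF)
  n <- nrow(matU)
  stopifnot(length(w) == n)
  sig <- colSums(matU)
  lower <- upper <- numeric(n)
  for (j in seq_len(n)) {
    if (j < n) lower[j] <- sum(matU[(j + 1L):n, j])
    if (j > 1L) upper[j] <- sum(matU[1:(j - 1L), j])
  }
  gam <- rho <- numeric(n)
  ok <- sig > 0
  gam[ok] <- lower[ok] / sig[ok]
  rho[ok] <- upper[ok] / sig[ok]
  wn <- if (any(ok)) w[ok] / sum(w[ok]) else numeric(0)
  list(sigma_bar = sum(w * sig),
       gamma_bar = if (any(ok)) sum(wn * gam[ok]) else 0,
       rho_bar = if (any(ok)) sum(wn * rho[ok]) else 0,
       phi_bar = sum(w * colSums(matF)))
}

#' Elasticities of population growth rate to the four vital rates
#'
#' Element-level elasticities are `e_ij = a_ij v_i w_j / (lam v'w)`; they
#' sum to 1. Vital-rate elasticities follow from the chain rule through the
#' column parameterization of each stage: a survival perturbation rescales
#' a whole column of `U` proportionally (`E_sigma` = sum of element
#' elasticities over `U`); a reproduction perturbation rescales columns of
#' `F` (`E_phi` = sum over `F`); growth and shrinkage perturbations rescale
#' the below- (resp. above-) diagonal conditional transition mass of a
#' column with compensation on the diagonal (stasis), keeping survival
#' fixed.
#'
#' @param A Projection matrix (defaults to `matU + matF`).
#' @param matU,matF Sub-matrices.
#' @return List with the element-elasticity matrix `E_elem` and scalars
#'   `E_sigma`, `E_gamma`, `E_rho`, `E_phi`.
#' @export
elasticities <- function(matU, matF, A = matU + matF) {
  matU <- as.matrix(matU); matF <- as.matrix(matF); A <- as.matrix(A)
  es <- eigen_structure(A)
  lam <- es$lam; w <- es$w; v <- es$v   # v'w = 1
  n <- nrow(A)
  S <- outer(v, w) / lam                # sensitivity / (v'w), elast = a_ij * S / 1
  E_elem <- A * S
  E_sigma <- sum(matU * S)
  E_phi <- sum(matF * S)
  E_gamma <- 0
  E_rho <- 0
  for (j in seq_len(n)) {
    sig_j <- sum(matU[, j])
    if (sig_j <= 0) next
    if (j < n) {
      gmass <- matU[(j + 1L):n, j]
      if (sum(gmass) > 0) {
        # d lam / d eps with U[i>j, j] *(1+eps) and U[j,j] -= eps * sum(gmass)
        E_gamma <- E_gamma +
          (sum(v[(j + 1L):n] * gmass) - v[j] * sum(gmass)) * w[j] / lam
      }
    }
    if (j > 1L) {
      rmass <- matU[1:(j - 1L), j]
      if (sum(rmass) > 0) {
        E_rho <- E_rho +
          (sum(v[1:(j - 1L)] * rmass) - v[j] * sum(rmass)) * w[j] / lam
      }
    }
  }
  list(E_elem = E_elem, E_sigma = E_sigma, E_gamma = E_gamma,
       E_rho = E_rho, E_phi = E_phi)
}

#' Transient metrics of a projection matrix
#'
#' Damping ratio `zeta = lam / |lam2|` (speed of convergence to the stable
#' structure), period of oscillation `Pi = 2*pi / |arg(lam2)|` (`Inf` when
#' `lam2` is real positive, 2 when real negative), and the one-step
#' amplification envelope of the lambda-standardized matrix `A / lam`:
#' reactivity = maximum column sum, first-step attenuation = minimum column
#' sum. Reactivity >= 1 >= attenuation always, and both are invariant to
#' uniform scaling of `A`.
#'
#' @param A Projection matrix or `mpm`.
#' @param es Optional precomputed [eigen_structure()].
#' @return List with `zeta`, `Pi`, `reactivity`, `attenuation`.
#' @export
transient_metrics <- function(A, es = NULL) {
  if (inherits(A, "mpm")) A <- A$matA
  A <- as.matrix(A)
  if (is.null(es)) es <- eigen_structure(A)
  lam <- es$lam; lam2 <- es$lam2
  zeta <- lam / Mod(lam2)
  theta <- abs(Arg(lam2))
  Pi <- if (theta < 1e-12) Inf else 2 * pi / theta
  Ahat <- A / lam
  cs <- colSums(Ahat)
  list(zeta = zeta, Pi = Pi, reactivity = max(cs), attenuation = min(cs))
}

#' Full demographic summary of one matrix population model
#'
#' Population growth rate, deviance from equilibrium, stable-structure-
#' weighted vital rates, vital-rate elasticities and transient metrics.
#' Matrices failing the irreducible+primitive+ergodic gate return `NA` for
#' every field with the failure reason in `gate_reason`; the gate does not
#' apply to life-history traits, which depend on `U` and `F` only.
#'
#' @param mpm An `mpm` object.
#' @return One-row data frame with columns `lam`, `deviance`, `sigma_bar`,
#'   `gamma_bar`, `rho_bar`, `phi_bar`, `E_sigma`, `E_gamma`, `E_rho`,
#'   `E_phi`, `zeta`, `Pi`, `reactivity`, `attenuation`, `gate_reason`.
#' @export
demographic_summary <- function(mpm) {
  stopifnot(inherits(mpm, "mpm"))
  cols <- c("lam", "deviance", "sigma_bar", "gamma_bar", "rho_bar", "phi_bar",
            "E_sigma", "E_gamma", "E_rho", "E_phi",
            "zeta", "Pi", "reactivity", "attenuation")
  out <- stats::setNames(as.list(rep(NA_real_, length(cols))), cols)
  g <- check_ergodicity(mpm$matA)
  if (!(g$irreducible && g$primitive && g$ergodic)) {
    out$gate_reason <- paste(c("reducible", "imprimitive", "non-ergodic")[
      !unlist(g)], collapse = ",")
    return(as.data.frame(out, check.names = FALSE))
  }
  es <- eigen_structure(mpm$matA, check_gate = FALSE)
  vr <- mean_vital_rates(mpm$matU, mpm$matF, es$w)
  el <- elasticities(mpm$matU, mpm$matF, mpm$matA)
  tm <- transient_metrics(mpm$matA, es)
  out <- c(list(lam = es$lam, deviance = deviance_from_equilibrium(es$lam)),
           vr, el[c("E_sigma", "E_gamma", "E_rho", "E_phi")], tm)
  out$gate_reason <- NA_character_
  as.data.frame(out, check.names = FALSE)
}
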