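# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's analytic code paths: cohort fates are simulated
# individual-by-individual, and vital-rate elasticities are obtained by
# central finite differences on the perturbed matrices.

# two-stage Leslie matrix with lambda = (1 + sqrt(5)) / 2
golden_leslie <- function() {
  list(U = matrix(c(0, 0.5, 0, 0), 2),
       F = matrix(c(1, 0, 2, 0), 2),
       A = matrix(c(1, 0.5, 2, 0), 2))
}

# random U/F pair passing the irreducible+primitive+ergodic gate;
# column survival sums capped at `max_surv`
rand_gated_mpm <- function(n = sample(3:5, 1), max_surv = 0.9) {
  repeat {
    U <- matrix(runif(n * n, 0, 0.3), n)
    cs <- colSums(U)
    U <- sweep(U, 2, pmax(cs / max_surv, 1), "/")
    F_ <- matrix(0, n, n)
    F_[1, n] <- runif(1, 0.5, 2)
    if (runif(1) < 0.5) F_[1, n - 1] <- runif(1, 0, 1)
    A <- U + F_
    if (passes_gate(A)) return(list(U = U, F = F_, A = A))
  }
}

# individual-based cohort simulation: lifespans (censuses alive) and
# whether a reproductive stage was ever occupied before death
mc_cohort <- function(matU, matF, start, n_ind, max_age = 5000) {
  n <- nrow(matU)
  repro <- which(colSums(matF) > 0)
  state <- sample.int(n, n_ind, replace = TRUE, prob = start)
  alive <- rep(TRUE, n_ind)
  lifespan <- integer(n_ind)
  reproduced <- state %in% repro
  death_p <- pmax(1 - colSums(matU), 0)
  age <- 0L
  while (any(alive) && age < max_age) {
    age <- age + 1L
    idx <- which(alive)
    st0 <- state[idx]   # snapshot: one transition per individual per step
    for (j in unique(st0)) {
      jj <- idx[st0 == j]
      dest <- sample.int(n + 1L, length(jj), replace = TRUE,
                         prob = c(matU[, j], death_p[j]))
      died <- dest == n + 1L
      lifespan[jj[died]] <- age
      alive[jj[died]] <- FALSE
      surv <- jj[!died]
      state[surv] <- dest[!died]
      reproduced[surv] <- reproduced[surv] | state[surv] %in% repro
    }
  }
  lifespan[alive] <- max_age
  m2 <- stats::var(lifespan)
  m4 <- mean((lifespan - mean(lifespan))^4)
  list(eta = mean(lifespan),
       se_eta = stats::sd(lifespan) / sqrt(n_ind),
       var = m2,
       se_var = sqrt(pmax(m4 - m2^2, 0) / n_ind),
       p_R = mean(reproduced),
       se_pR = sqrt(mean(reproduced) * (1 - mean(reproduced)) / n_ind),
       lifespans = lifespan)
}

# central finite differences of lambda under the vital-rate column
# parameterization: survival scales a U column, growth/shrinkage scale the
# below-/above-diagonal conditional mass with stasis compensation,
# reproduction scales F
fd_vital_elasticities <- function(matU, matF, h = 1e-6) {
  n <- nrow(matU)
  lam_of <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))
  lam0 <- lam_of(matU + matF)
  perturb <- function(dir, eps) {
    U2 <- matU
    for (j in seq_len(n)) {
      if (sum(matU[, j]) <= 0) next
      if (dir == "sigma") U2[, j] <- matU[, j] * (1 + eps)
      if (dir == "gamma" && j < n) {
        g <- matU[(j + 1):n, j]
        U2[(j + 1):n, j] <- g * (1 + eps)
        U2[j, j] <- U2[j, j] - eps * sum(g)
      }
      if (dir == "rho" && j > 1) {
        r <- matU[1:(j - 1), j]
        U2[1:(j - 1), j] <- r * (1 + eps)
        U2[j, j] <- U2[j, j] - eps * sum(r)
      }
    }
    F2 <- if (dir == "phi") matF * (1 + eps) else matF
    if (dir == "phi") U2 <- matU
    lam_of(U2 + F2)
  }
  vapply(c(sigma = "sigma", gamma = "gamma", rho = "rho", phi = "phi"),
         function(d) (perturb(d, h) - perturb(d, -h)) / (2 * h) / lam0,
         numeric(1))
}

# random strictly decreasing survivorship schedule: per-age survival
# probabilities in (0, 1), 5-200 ages
rand_monotone_lx <- function() {
  len <- sample(5:200, 1)
  cumprod(c(1, runif(len - 1, 0.01, 0.99)))
}

# star tree with unit branch lengths (phylogeny-free limit)
star_tree <- function(n) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, n)
  tr$tip.label <- sprintf("sp_%03d", seq_len(n))
  tr
}
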