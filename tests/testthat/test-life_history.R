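test_that("net reproductive rate matches fundamental-matrix closed forms", {
  U <- matrix(c(0, 0.5, 0, 0), 2)
  expect_equal(net_reproductive_rate(U, matrix(c(0, 0, 2, 0), 2)), 1)
  gl <- golden_leslie()
  expect_equal(net_reproductive_rate(gl$U, gl$F), 2)
  expect_equal(net_reproductive_rate(U, matrix(0, 2, 2)), 0)
})

test_that("generation time follows log R0 / log lambda with guards", {
  gl <- golden_leslie()
  expect_equal(generation_time(gl$U, gl$F), log(2) / log((1 + sqrt(5)) / 2),
               tolerance = 1e-10)
  # single stage reproducing immediately: lambda = R0, so T = 1
  expect_equal(generation_time(matrix(0), matrix(1.5)), 1, tolerance = 1e-9)
  # lambda = 1 and R0 = 1 simultaneously: flagged undefined
  F1 <- matrix(c(0, 0, 1 / 0.9, 0), 2)
  U1 <- matrix(c(0, 0.9, 0, 0), 2)
  expect_true(is.na(suppressWarnings(generation_time(U1, F1))))
  # the mean-age-of-mothers variant is positive and close for a Leslie model
  expect_gt(generation_time(gl$U, gl$F, method = "abar"), 1)
})

test_that("maximum longevity is the first age with lx strictly below 1%", {
  expect_equal(max_longevity(matrix(0.5)), 7)
  # 0.1^2 = 0.01 is not < 0.01; strict inequality pushes to age 3
  expect_equal(max_longevity(matrix(0.1)), 3)
  expect_equal(max_longevity(matrix(0)), 1)
  expect_error(max_longevity(matrix(0.999), xmax = 3), "xmax")
})

test_that("maturity probability and age follow the absorbing chain", {
  U <- matrix(c(0, 0.5, 0, 0), 2)
  F_ <- matrix(c(0, 0, 2, 0), 2)
  expect_equal(maturity_probability(U, F_, c(1, 0)), 0.5)
  expect_equal(age_at_maturity(U, F_, c(1, 0)), 1)
  # start stage itself reproductive
  Fs <- matrix(c(1, 0, 0, 0), 2)
  expect_equal(maturity_probability(U, Fs, c(1, 0)), 1)
  expect_equal(age_at_maturity(U, Fs, c(1, 0)), 0)
  # two-step chain 0.5 then 0.4 into the reproductive stage
  U3 <- matrix(0, 3, 3); U3[2, 1] <- 0.5; U3[3, 2] <- 0.4
  F3 <- matrix(0, 3, 3); F3[1, 3] <- 1
  expect_equal(maturity_probability(U3, F3, c(1, 0, 0)), 0.2)
  # maturation at age 1 or 2 with equal conditional probability -> 1.5
  U4 <- matrix(0, 3, 3)
  U4[3, 1] <- 0.25          # direct to reproductive stage at age 1
  U4[2, 1] <- 0.5           # or via the middle stage ...
  U4[3, 2] <- 0.5           # ... reaching it at age 2
  F4 <- matrix(0, 3, 3); F4[1, 3] <- 1
  expect_equal(maturity_probability(U4, F4, c(1, 0, 0)), 0.5)
  expect_equal(age_at_maturity(U4, F4, c(1, 0, 0)), 1.5)
  expect_error(maturity_probability(U, matrix(0, 2, 2), c(1, 0)),
               "no reproductive stage")
})

test_that("reproductive window mixes residual expectancies at maturity", {
  # maturing stage with no survival afterwards: one reproductive interval
  U <- matrix(c(0, 0.5, 0, 0), 2)
  F_ <- matrix(c(0, 0, 2, 0), 2)
  expect_equal(reproductive_window(U, F_, c(1, 0)), 1)
  # self-loop survival 0.5 in the reproductive stage: geometric residence 2
  U2 <- matrix(c(0, 0.5, 0, 0.5), 2)
  expect_equal(reproductive_window(U2, F_, c(1, 0)), 2)
  # two reproductive stages entered with probs .6/.4, expectancies 2/5
  U3 <- matrix(0, 3, 3)
  U3[2, 1] <- 0.6; U3[3, 1] <- 0.4
  U3[2, 2] <- 0.5           # residence 2
  U3[3, 3] <- 0.8           # residence 5
  F3 <- matrix(0, 3, 3); F3[1, 2] <- 1; F3[1, 3] <- 1
  expect_equal(reproductive_window(U3, F3, c(1, 0, 0)), 0.6 * 2 + 0.4 * 5)
})

test_that("survivorship shape anchors: constant, rectangular, Type III", {
  expect_lt(abs(shape_survivorship(0.8^(0:20))), 1e-6)
  expect_lt(abs(shape_survivorship(c(rep(1, 100), 1e-6)) - 0.5), 0.01)
  expect_lt(shape_survivorship(c(1, 0.2, 0.1, 0.08, 0.07, 0.065)), 0)
  expect_true(is.na(shape_survivorship(rep(1, 10))))  # no mortality
  expect_error(shape_survivorship(c(1, 0.5)), "3 ages")
})

test_that("reproduction shape anchors: constant, semelparous, increasing", {
  lx50 <- 0.95^(0:49)
  expect_lt(abs(shape_reproduction(lx50, rep(1, 50))), 1e-3)
  lx100 <- 0.99^(0:99)
  mx_semel <- c(1, rep(0, 99))
  expect_lt(abs(shape_reproduction(lx100, mx_semel) - 0.5), 0.01)
  expect_lt(shape_reproduction(lx50, seq(0, 1, length.out = 50)), 0)
  expect_error(shape_reproduction(lx50, rep(0, 50)), "zero total")
})

test_that("degree of parity is entropy of the reproduction distribution", {
  lx <- 0.9^(0:9)
  expect_equal(degree_of_parity(lx, c(0, 2, rep(0, 8))), 0)
  # uniform lx * mx over two ages
  expect_equal(degree_of_parity(c(1, 1, 1), c(0, 1, 1)), log(2))
  # uniform over k ages
  k <- 5
  expect_equal(degree_of_parity(rep(1, k), rep(2, k)), log(k))
})

test_that("shape metrics stay within [-0.5, 0.5] on random monotone schedules", {
  set.seed(77)
  for (i in 1:300) {
    s <- shape_survivorship(rand_monotone_lx())
    expect_gte(s, -0.5); expect_lte(s, 0.5)
    lx <- rand_monotone_lx()
    m <- shape_reproduction(lx, runif(length(lx), 0, 2))
    expect_gte(m, -0.5); expect_lte(m, 0.5)
  }
})

test_that("shape of survivorship is invariant to time-unit rescaling", {
  # same exponential decline sampled at double resolution
  s1 <- shape_survivorship(0.8^(0:20))
  s2 <- shape_survivorship(0.8^(seq(0, 20, by = 0.5)))
  expect_lt(abs(s1 - s2), 1e-6)
})

test_that("maturity probability agrees with cohort simulation", {
  set.seed(19)
  for (i in 1:4) {
    m <- rand_gated_mpm()
    start <- default_start_distribution(m$F)
    p <- maturity_probability(m$U, m$F, start)
    mc <- mc_cohort(m$U, m$F, start, n_ind = 40000)
    expect_lt(abs(p - mc$p_R), 3 * mc$se_pR + 1e-9)
  }
})

test_that("Leslie matrices built from explicit schedules round-trip", {
  # age-classified model: survival p_x, fertility f_x at ages 1..4
  p <- c(0.8, 0.6, 0.4)
  f <- c(0, 0.5, 1, 2)
  n <- 4
  U <- matrix(0, n, n); U[cbind(2:n, 1:(n - 1))] <- p
  F_ <- matrix(0, n, n); F_[1, ] <- f
  lx_direct <- c(1, cumprod(p))
  start <- c(1, 0, 0, 0)
  lx <- survivorship_schedule(U, start, xmax = n, stop_tol = 0)
  expect_equal(lx[1:n], lx_direct[1:n])
  mx <- fertility_schedule(U, F_, start, xmax = n - 1)
  expect_equal(mx[1:n], f)
  # R0 = sum lx * mx over ages
  expect_equal(net_reproductive_rate(U, F_), sum(lx_direct * f),
               tolerance = 1e-10)
  mom <- lifespan_moments(U, start)
  expect_equal(mom$eta_e, sum(lx_direct))
})

test_that("compute_all_traits assembles and flags consistently", {
  gl <- golden_leslie()
  m <- validate_mpm(matU = gl$U, matF = gl$F)
  tr <- compute_all_traits(m)
  expect_equal(tr$R0, 2)
  expect_equal(tr$T, log(2) / log((1 + sqrt(5)) / 2), tolerance = 1e-9)
  expect_equal(tr$eta_e, 1.5)
  expect_equal(tr$p_R, 1)      # offspring enter stage 1, itself reproductive
  expect_equal(tr$L_alpha, 0)
  # sterile model: reproductive traits flagged missing
  m0 <- validate_mpm(matU = gl$U, matF = matrix(0, 2, 2))
  tr0 <- compute_all_traits(m0)
  expect_equal(tr0$R0, 0)
  expect_true(all(is.na(unlist(tr0[c("T", "p_R", "L_alpha",
                                     "L_alpha_omega", "s_mx", "S")]))))
  expect_false(is.na(tr0$eta_e))
  # single-stage geometric model: constant mx so shapes near 0
  m1 <- validate_mpm(matU = matrix(0.5), matF = matrix(1))
  tr1 <- compute_all_traits(m1)
  expect_lt(abs(tr1$s_lx), 1e-6)
  expect_lt(abs(tr1$s_mx), 1e-6)
  # S = entropy of geometric p_x truncated at L_max
  lx <- 0.5^(0:tr1$L_max)
  p_x <- lx / sum(lx)
  expect_equal(tr1$S, -sum(p_x * log(p_x)), tolerance = 1e-8)
  # positivity invariants for a primitive fertile model
  expect_gt(tr$T, 0); expect_gt(tr$R0, 0); expect_gt(tr$eta_e, 0)
})
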