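# BJ / GBJ statistics, boundary-crossing p-values, comparison kernels.

test_that("z_from_pvalue is the two-sided quantile transform", {
  expect_equal(z_from_pvalue(1), 0)
  expect_equal(z_from_pvalue(0.05), 1.95996, tolerance = 1e-5)
  for (p in c(0.5, 0.01, 1e-8)) {
    expect_equal(2 * pnorm(-z_from_pvalue(p)), p, tolerance = 1e-12)
  }
  expect_error(z_from_pvalue(0), "0, 1")
  expect_error(z_from_pvalue(1.2), "0, 1")
})

test_that("mu_hat solves the exceedance equation and matches a grid search", {
  # defining equation residual at the root
  mu <- mu_hat(3, 10, 2.0)
  f <- function(m_) pnorm(2 - m_, lower.tail = FALSE) + pnorm(-2 - m_) - 0.3
  expect_lt(abs(f(mu)), 1e-10)
  # independent two-stage grid-search oracle
  grid <- seq(1e-4, 20, by = 1e-3)
  coarse <- grid[which.min(abs(f(grid)))]
  fine <- seq(coarse - 2e-3, coarse + 2e-3, by = 1e-6)
  expect_equal(mu, fine[which.min(abs(f(fine)))], tolerance = 2e-6)
  # monotonicity of the exceedance probability in mu
  mus <- seq(0, 6, by = 0.25)
  probs <- pnorm(2 - mus, lower.tail = FALSE) + pnorm(-2 - mus)
  expect_true(all(diff(probs) > 0))
  # boundary case mu = 0 is excluded by the indicator precondition
  expect_error(mu_hat(1, 10, qnorm(1 - 0.05)), "indicator")
})

test_that("BJ statistic matches direct rank-term evaluation", {
  # indicator never triggers: statistic is 0
  expect_equal(bj_statistic(c(0.1, 0.2)), 0)
  # m = 4, one big |Z|: only rank 1 qualifies
  z <- c(3.0, 0.5, 0.4, 0.3)
  direct <- log(dbinom(1, 4, 1 / 4) / dbinom(1, 4, 2 * pnorm(-3)))
  expect_equal(bj_statistic(z), direct, tolerance = 1e-12)
  # increasing the largest |Z| never decreases the statistic
  set.seed(12)
  for (r in 1:20) {
    zr <- rnorm(6)
    t1 <- bj_statistic(zr)
    zr[which.max(abs(zr))] <- max(abs(zr)) * 1.5
    expect_gte(bj_statistic(zr) + 1e-12, t1)
  }
  # permutation invariance
  z <- rnorm(7)
  expect_equal(bj_statistic(z), bj_statistic(z[sample(7)]))
})

test_that("independent crossing probability is exact", {
  expect_equal(crossing_pvalue_independent(c(Inf, Inf), 5), 0)
  expect_equal(crossing_pvalue_independent(c(0, 0), 5), 1)
  g <- 1.5
  expect_equal(crossing_pvalue_independent(g, 1), 2 * pnorm(-g),
               tolerance = 1e-12)
  # Monte-Carlo oracle at m = 5
  p <- crossing_pvalue_independent(c(2.4, 1.9), 5)
  mc <- mc_crossing(2e5, 5, c(2.4, 1.9), rho = 0, seed = 31)
  expect_lt(abs(p - mc), 3 * binom_se(mc, 2e5))
  # misordered boundary is an internal error
  expect_error(crossing_pvalue_independent(c(1.5, 2.4), 5), "monotone")
})

test_that("BJ p-values are calibrated, monotone, and 1 at zero", {
  expect_equal(bj_pvalue(0, 10), 1)
  ts <- seq(0.5, 8, by = 0.5)
  ps <- bj_pvalue(ts, 12)
  expect_true(all(diff(ps) < 0))
  # null calibration at m = 30
  set.seed(33)
  Z <- rexch_absz(1e4, 30, 0)
  Zs <- matrix(Z[order(row(Z), -Z)], ncol = 30, byrow = TRUE)
  tv <- pmax(apply(gwmed:::bj_terms(Zs, 30), 1, max), 0)
  pv <- gwmed:::bj_pvalue_vec(tv, 30)
  rej <- mean(pv < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.06)
})

test_that("GBJ reduces exactly to BJ at the identity correlation", {
  set.seed(14)
  for (r in 1:100) {
    m <- sample(2:8, 1)
    z <- rnorm(m) * 1.7
    tb <- bj_statistic(z)
    expect_equal(gbj_statistic(z, diag(m)), tb, tolerance = 1e-10)
    expect_equal(gbj_pvalue(tb, diag(m)), bj_pvalue(tb, m),
                 tolerance = 1e-8)
  }
})

test_that("factor count law matches Monte-Carlo exceedance counts", {
  set.seed(15)
  m <- 10; rho <- 0.3; t <- 1.5
  Z <- rexch_absz(1e6, m, rho)
  S <- rowSums(Z >= t)
  for (j in 1:3) {
    mcp <- mean(S == j)
    th <- gwmed:::count_pmf(j, m, t, 0, rho, nodes = 60)
    expect_lt(abs(th - mcp), 3 * binom_se(mcp, 1e6))
  }
})

test_that("GBJ under exchangeable correlation matches Monte Carlo", {
  set.seed(16)
  m <- 5; rho <- 0.3
  corr <- matrix(rho, m, m); diag(corr) <- 1
  z <- c(2.8, 1.4, 0.3, -0.5, 1.0)
  tg <- gbj_statistic(z, corr)
  pg <- gbj_pvalue(tg, corr)
  # oracle: crossing frequency of the inverted boundary under the factor draw
  ts <- gwmed:::gbj_invert_rank(tg, 1, m, rho, nodes = 60)
  ts <- c(ts, gwmed:::gbj_invert_rank(tg, 2, m, rho, nodes = 60))
  mc <- mc_crossing(5e5, m, ts, rho = rho, seed = 61)
  expect_lt(abs(pg - mc), 3 * binom_se(mc, 5e5))
})

test_that("GBJ is invariant to coordinate sign flips and permutations", {
  set.seed(17)
  m <- 6
  A <- matrix(rnorm(m * m), m); corr <- cov2cor(crossprod(A))
  z <- rnorm(m) * 1.5
  t0 <- gbj_statistic(z, corr)
  # flip coordinate 2
  fl <- diag(m); fl[2, 2] <- -1
  expect_equal(gbj_statistic(drop(fl %*% z), fl %*% corr %*% fl), t0,
               tolerance = 1e-12)
  pr <- sample(m)
  expect_equal(gbj_statistic(z[pr], corr[pr, pr]), t0, tolerance = 1e-12)
})

test_that("GBJ null calibration at m = 30, rho = 0.3 is near-nominal", {
  set.seed(18)
  nrep <- 4000
  m <- 30; rho <- 0.3
  Z <- rexch_absz(nrep, m, rho)
  Zs <- matrix(Z[order(row(Z), -Z)], ncol = m, byrow = TRUE)
  tv <- pmax(apply(gwmed:::gbj_terms(Zs, m, rep(rho, nrep)), 1, max), 0)
  pv <- gwmed:::gbj_pvalue_vec(tv, m, rep(rho, nrep))
  expect_lte(mean(pv < 0.01), 0.015)
  expect_gte(mean(pv < 0.01), 0.004)
})

test_that("comparison kernels: minP closed forms and HC oracle", {
  z1 <- qnorm(1 - 0.01 / 2)
  expect_equal(hc_ghc_minp(z1, "minP")$p.value, 0.01, tolerance = 1e-10)
  z <- c(z1, rep(0.1, 9))
  expect_equal(hc_ghc_minp(z, "minP")$p.value, 1 - 0.99^10, tolerance = 1e-10)
  expect_equal(1 - 0.99^10, 0.09562, tolerance = 1e-4)
  # HC p-value via the crossing recursion vs Monte Carlo at m = 5
  z5 <- c(2.2, 1.1, 0.4, 1.8, 0.2)
  hc <- hc_ghc_minp(z5, "HC")
  set.seed(62)
  pv <- matrix(2 * pnorm(-rexch_absz(2e5, 5, 0)), 2e5)
  pvs <- matrix(pv[order(row(pv), pv)], ncol = 5, byrow = TRUE)
  js <- 1:2
  hstat <- do.call(pmax, lapply(js, function(j) {
    sqrt(5) * (j / 5 - pvs[, j]) / sqrt(pvs[, j] * (1 - pvs[, j]))
  }))
  mc <- mean(hstat >= hc$statistic)
  expect_lt(abs(hc$p.value - mc), 3 * binom_se(mc, 2e5))
  # GHC needs a correlation matrix
  expect_error(hc_ghc_minp(z5, "GHC"), "correlation")
})
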