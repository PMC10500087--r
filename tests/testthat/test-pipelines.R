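# Decorrelation transform, hybrid combination, FDR, and the scan engine.

test_that("decorrelation of a diagonal residual covariance is a signed permutation", {
  fit <- demo_fit()
  fit$resid_cov_m <- diag(c(0.5, 2.0, 1.2, 0.1))
  dc <- decorrelate(fit)
  ord <- order(c(0.5, 2.0, 1.2, 0.1), decreasing = TRUE)
  expect_equal(dc$eigenvalues, c(0.5, 2.0, 1.2, 0.1)[ord])
  # each row of u selects exactly one original coordinate with weight +1
  expect_equal(abs(dc$u), diag(4)[ord, ], tolerance = 1e-12)
  expect_true(all(apply(dc$u, 1, max) == 1))
})

test_that("transformed mediators have orthogonal model residuals", {
  set.seed(19)
  cfg <- simulation_config(n = 2000, g = 1, m = 5, rho = 0.5, prop_active = 0,
                           seed = 19)
  ge <- generate_experiment(cfg)
  fit <- fit_graph(ge$design, 1)
  dc <- decorrelate(fit, ge$design$M[, ge$design$graphs[[1]]])
  W <- cbind(1, ge$design$S[, 1], ge$design$X[[1]])
  Pres <- dc$P - W %*% solve(crossprod(W), crossprod(W, dc$P))
  cmat <- cov2cor(crossprod(Pres))
  expect_lt(max(abs(cmat[upper.tri(cmat)])), 1e-8)
  # rows of u are orthogonal
  expect_equal(dc$u %*% t(dc$u), diag(5), tolerance = 1e-10)
})

test_that("decorrelation preserves the null in expectation and keeps a, b independent", {
  set.seed(20)
  reps <- 400
  ab <- matrix(0, reps, 2)
  a_pool <- b_pool <- numeric(0)
  for (r in seq_len(reps)) {
    n <- 500
    S <- rnorm(n); X <- matrix(rnorm(n), n, 1)
    E <- sqrt(0.5) * rnorm(n) + sqrt(0.5) * matrix(rnorm(n * 3), n, 3)
    M <- E + as.vector(X)
    colnames(M) <- paste0("m", 1:3)
    Y <- matrix(S + as.vector(X) + rnorm(n), n, 1, dimnames = list(NULL, "g"))
    des <- mediation_design(S, M, Y,
                            data.frame(graph = "g", mediator = colnames(M)),
                            covariates = X)
    ps <- gwmed:::decor_path_stats(fit_graph(des, 1))
    ab[r, ] <- c(mean(ps$a), mean(ps$b))
    a_pool <- c(a_pool, ps$a)
    b_pool <- c(b_pool, ps$b)
  }
  expect_lt(abs(mean(ab[, 1])), 3 * sd(ab[, 1]) / sqrt(reps))
  expect_lt(abs(mean(ab[, 2])), 3 * sd(ab[, 2]) / sqrt(reps))
  # paired exposure-side and outcome-side statistics are uncorrelated
  expect_lt(abs(cor(a_pool, b_pool)), 3 / sqrt(length(a_pool)))
})

test_that("collective sign follows the printed strict indicator", {
  expect_equal(collective_sign(c(1, -2)), -1)
  expect_equal(collective_sign(c(0, 0)), 1)
  expect_equal(collective_sign(5), 1)
})

test_that("ACAT hybrid identities hold exactly", {
  for (p in c(0.9, 0.5, 0.01, 1e-6)) {
    expect_equal(acat_hybrid(p, p), p, tolerance = 1e-10)
  }
  expect_equal(acat_hybrid(0.037, 0.8, w_decor = 1, w_multi = 0), 0.037,
               tolerance = 1e-10)
  # p = 0.5 contributes nothing to the Cauchy sum
  expect_equal(acat_hybrid(0.5, 0.2, 1, 1),
               0.5 - atan(tan(0.3 * pi) / 2) / pi, tolerance = 1e-12)
  # swap invariance with equal weights
  expect_equal(acat_hybrid(0.01, 0.3), acat_hybrid(0.3, 0.01))
  expect_error(acat_hybrid(0.1, 0.2, 0, 0), "weights")
})

test_that("BH q-values and discovery flags follow the step-up rule", {
  r <- bh_fdr(rep(1, 5), 0.1)
  expect_false(any(r$discovery))
  r2 <- bh_fdr(c(0.001, 0.9, 0.9, 0.9), 0.1)
  expect_equal(sum(r2$discovery), 1)
  expect_equal(r2$q[1], 0.004)
  p <- runif(50)
  q <- bh_fdr(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("single-mediator graphs reduce both approaches to the path test", {
  set.seed(21)
  cfg <- simulation_config(n = 400, g = 150, m = 1, rho = 0,
                           null_type = "complete", seed = 21)
  ge <- generate_experiment(cfg)
  scan <- mediation_scan(ge$design, approach = "all", test = "composite")
  z_a <- vapply(gwmed:::fit_all_graphs(ge$design), `[[`, numeric(1),
                "z_alpha")
  # multivariate graph statistic is the signed path z itself
  expect_equal(abs(scan$results$a_multi), abs(z_a), tolerance = 1e-6)
  expect_equal(sign(scan$results$a_multi), sign(z_a))
  # decorrelation p equals the graph-level composite p with matching pools
  direct <- p_composite(scan$results$a_multi, scan$results$b_multi,
                        scan$variances$multi, method = "grid")
  expect_equal(scan$results$p_multi, direct, tolerance = 1e-9)
  # with one path per graph the two pipelines see identical statistics
  expect_equal(scan$results$p_decor, scan$results$p_multi, tolerance = 1e-6)
})

test_that("a failing graph is flagged without aborting the scan", {
  set.seed(22)
  cfg <- simulation_config(n = 200, g = 120, m = 2, rho = 0,
                           null_type = "complete", seed = 22)
  ge <- generate_experiment(cfg)
  d <- ge$design
  d$M[, d$graphs[[3]][2]] <- d$M[, d$graphs[[3]][1]]  # collinear pair
  scan <- mediation_scan(d, approach = "all", test = "composite")
  expect_false(scan$results$ok[3])
  expect_match(scan$results$note[3], "singular")
  expect_true(is.na(scan$results$p_decor[3]))
  expect_true(all(scan$results$ok[-3]))
  expect_true(all(is.finite(scan$results$p_hybrid[-3])))
})

test_that("scan results expose QQ columns and survive the summary path", {
  set.seed(23)
  cfg <- simulation_config(n = 300, g = 150, m = 3, rho = 0.3,
                           null_type = "complete", seed = 23)
  ge <- generate_experiment(cfg)
  scan <- mediation_scan(ge$design)
  qq <- qq_data(scan)
  expect_setequal(unique(qq$approach), c("decor", "multi", "hybrid"))
  expect_true(all(is.finite(qq$expected)))
  s <- summary(scan)
  expect_true(all(s$overlap <= max(s$discoveries, 0) + 1e-9))
  expect_output(print(s), "Mediation scan")
})

test_that("hybrid equals the better-arm behavior under extreme weights", {
  set.seed(24)
  p1 <- runif(20); p2 <- runif(20)
  expect_equal(acat_hybrid(p1, p2, 1, 0), p1, tolerance = 1e-9)
  expect_equal(acat_hybrid(p1, p2, 0, 1), p2, tolerance = 1e-9)
})
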