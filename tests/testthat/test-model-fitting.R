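# Per-graph OLS fitting: oracles, invariances, error contracts.

test_that("wald_z divides estimate by a positive standard error", {
  expect_equal(wald_z(1.0, 1.0), 1.0)
  expect_equal(wald_z(0, 3.7), 0)
  expect_equal(wald_z(-2.4, 1.2), -2.0)
  expect_error(wald_z(1, 0), "positive")
  expect_error(wald_z(1, -1), "positive")
})

test_that("coefficients and SEs match a hand-worked normal-equations solution", {
  # tiny printed dataset: n = 6, two mediators, one covariate
  S <- c(-1.2, 0.4, 1.1, -0.3, 0.9, -0.8)
  X <- matrix(c(0.5, -0.1, 0.3, 1.2, -0.7, 0.2), 6, 1,
              dimnames = list(NULL, "x1"))
  M <- matrix(c(0.31, -0.42, 1.05, -0.12, 0.88, -0.66,
                -0.25, 0.17, 0.44, -0.91, 0.52, 0.08), 6, 2,
              dimnames = list(NULL, c("m1", "m2")))
  Y <- matrix(c(0.40, -0.35, 1.21, -0.58, 1.02, -0.77), 6, 1,
              dimnames = list(NULL, "g1"))
  des <- mediation_design(S, M, Y,
                          mapping = data.frame(graph = "g1",
                                               mediator = c("m1", "m2")),
                          covariates = X)
  fit <- fit_graph(des, "g1")

  # independent oracle: explicit normal equations
  W <- cbind(1, S, X)
  alpha_or <- solve(crossprod(W), crossprod(W, M))[2, ]
  expect_equal(unname(fit$alpha_hat), unname(alpha_or), tolerance = 1e-12)
  Mres <- M - W %*% solve(crossprod(W), crossprod(W, M))
  sig_m <- crossprod(Mres) / (6 - 3)
  se_or <- sqrt(diag(sig_m) * solve(crossprod(W))[2, 2])
  expect_equal(unname(fit$alpha_se), unname(se_or), tolerance = 1e-12)
  expect_equal(unname(fit$resid_cov_m), unname(sig_m), tolerance = 1e-12)

  D <- cbind(1, S, M, X)
  beta_full <- solve(crossprod(D), crossprod(D, Y))
  expect_equal(unname(fit$beta_hat), unname(beta_full[3:4]), tolerance = 1e-12)
  expect_equal(unname(fit$beta_S), unname(beta_full[2]), tolerance = 1e-12)
  rss <- sum((Y - D %*% beta_full)^2)
  cov_b <- rss / (6 - 5) * solve(crossprod(D))
  expect_equal(unname(fit$beta_se), unname(sqrt(diag(cov_b)[3:4])),
               tolerance = 1e-10)
  expect_equal(unname(fit$corr_beta), unname(stats::cov2cor(cov_b[3:4, 3:4])),
               tolerance = 1e-10)
})

test_that("noiseless data are interpolated exactly", {
  set.seed(41)
  n <- 50
  S <- rnorm(n)
  X <- matrix(rnorm(n), n, 1)
  alpha <- c(0.7, -1.3)
  beta <- c(0.5, 2.0)
  # mediator variation orthogonal to the design: zero-residual coefficient
  # recovery while the outcome design stays full rank
  W <- cbind(1, S, X)
  E <- matrix(rnorm(2 * n), n, 2)
  E <- E - W %*% solve(crossprod(W), crossprod(W, E))
  M <- outer(S, alpha) + as.vector(X) + E
  Y <- matrix(2 * S + M %*% beta + as.vector(X), n, 1)   # exact Y
  colnames(M) <- c("m1", "m2"); colnames(Y) <- "g1"
  des <- mediation_design(S, M, Y,
                          data.frame(graph = "g1", mediator = c("m1", "m2")),
                          covariates = X)
  fit <- fit_graph(des, 1)
  expect_equal(unname(fit$alpha_hat), alpha, tolerance = 1e-12)
  expect_equal(unname(fit$beta_hat), beta, tolerance = 1e-9)
  expect_equal(unname(fit$beta_S), 2, tolerance = 1e-9)
})

test_that("permuting mediator columns permutes estimates conformally", {
  set.seed(7)
  cfg <- simulation_config(n = 200, g = 1, m = 4, rho = 0.3, prop_active = 1,
                           h = 2, signal_mu = 0.3, seed = 7)
  ge <- generate_experiment(cfg)
  d <- ge$design
  fit <- fit_graph(d, 1)
  perm <- c(3, 1, 4, 2)
  M2 <- d$M[, perm]
  des2 <- mediation_design(d$S[, 1], M2, d$Y,
                           data.frame(graph = colnames(d$Y)[1],
                                      mediator = colnames(M2)),
                           covariates = d$X[[1]])
  fit2 <- fit_graph(des2, 1)
  expect_equal(unname(fit2$alpha_hat), unname(fit$alpha_hat[perm]))
  expect_equal(unname(fit2$beta_hat), unname(fit$beta_hat[perm]))
  expect_equal(unname(fit2$resid_cov_m), unname(fit$resid_cov_m[perm, perm]))
  expect_equal(unname(fit2$corr_beta), unname(fit$corr_beta[perm, perm]))
})

test_that("rank-deficient and undersized designs are rejected explicitly", {
  set.seed(11)
  n <- 30
  S <- rnorm(n)
  M <- cbind(m1 = rnorm(n), m2 = rnorm(n))
  M <- cbind(M, m3 = M[, "m1"] + M[, "m2"])  # exactly collinear
  Y <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "g1"))
  des <- mediation_design(S, M, Y,
                          data.frame(graph = "g1",
                                     mediator = c("m1", "m2", "m3")))
  expect_error(fit_graph(des, 1), "singular")

  Mbig <- matrix(rnorm(n * 29), n, 29)
  colnames(Mbig) <- paste0("m", 1:29)
  des2 <- mediation_design(S, Mbig, Y,
                           data.frame(graph = "g1", mediator = colnames(Mbig)))
  expect_error(fit_graph(des2, 1), "insufficient sample")
})

test_that("estimates are unbiased with nominal CI coverage, z scores null-standard", {
  set.seed(101)
  reps <- 400
  alpha <- c(0.4, -0.2, 0.1)
  beta <- c(-0.3, 0.25, 0.15)
  bias_a <- matrix(0, reps, 3)
  bias_b <- matrix(0, reps, 3)
  cover <- 0
  n <- 250
  for (r in seq_len(reps)) {
    S <- rnorm(n)
    X <- matrix(rnorm(2 * n), n, 2)
    M <- outer(S, alpha) + rowSums(X) + matrix(rnorm(3 * n), n, 3)
    colnames(M) <- paste0("m", 1:3)
    Y <- matrix(S + M %*% beta + rowSums(X) + rnorm(n), n, 1,
                dimnames = list(NULL, "g1"))
    des <- mediation_design(S, M, Y,
                            data.frame(graph = "g1", mediator = colnames(M)),
                            covariates = X)
    fit <- fit_graph(des, 1)
    bias_a[r, ] <- fit$alpha_hat - alpha
    bias_b[r, ] <- fit$beta_hat - beta
    cover <- cover + sum(abs(fit$alpha_hat - alpha) <= 1.96 * fit$alpha_se,
                         abs(fit$beta_hat - beta) <= 1.96 * fit$beta_se)
  }
  mce_a <- apply(bias_a, 2, sd) / sqrt(reps)
  mce_b <- apply(bias_b, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(bias_a)) <= 3 * mce_a))
  expect_true(all(abs(colMeans(bias_b)) <= 3 * mce_b))
  coverage <- cover / (reps * 6)
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)

  # null z_alpha statistics are standard normal
  set.seed(102)
  cfg <- simulation_config(n = 400, g = 2500, m = 4, rho = 0,
                           null_type = "complete", seed = 102)
  ge <- generate_experiment(cfg)
  z <- unlist(lapply(gwmed:::fit_all_graphs(ge$design), `[[`, "z_alpha"))
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})
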