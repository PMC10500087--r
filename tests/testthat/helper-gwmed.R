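# Shared test utilities: Monte-Carlo oracles and cached genome-scale runs.

binom_se <- function(p, n) sqrt(p * (1 - p) / n)

# exchangeable |Z| draws via the one-factor representation (exact for rho >= 0)
rexch_absz <- function(nrep, m, rho) {
  Z <- matrix(stats::rnorm(nrep * m), nrep, m)
  if (rho > 0) Z <- sqrt(rho) * stats::rnorm(nrep) + sqrt(1 - rho) * Z
  abs(Z)
}

# Monte-Carlo boundary-crossing frequency: P(exists j: |Z|_(m-j+1) >= g_j),
# computed by exceedance counting (no sorting needed).
mc_crossing <- function(nrep, m, thresholds, rho = 0, seed = 1) {
  set.seed(seed)
  Z <- rexch_absz(nrep, m, rho)
  cross <- rep(FALSE, nrep)
  for (j in seq_along(thresholds)) {
    cross <- cross | (rowSums(Z >= thresholds[j]) >= j)
  }
  mean(cross)
}

# Cache for the genome-scale complete-null experiments shared by several
# acceptance checks (one independent, one correlated; both expensive).
acc_cache <- new.env(parent = emptyenv())

genome_null_scan <- function(rho, seed = 5) {
  key <- sprintf("null_rho%s_seed%d", rho, seed)
  if (is.null(acc_cache[[key]])) {
    cfg <- simulation_config(n = 1000, g = 10000, m = 30, rho = rho,
                             null_type = "complete", seed = seed)
    acc_cache[[key]] <- simulate_scan(cfg, approach = "all",
                                      test = "composite")
  }
  acc_cache[[key]]
}

# small fitted graph on simulated data, reused across unit tests
demo_fit <- function(seed = 3, n = 400, m = 4, rho = 0.4) {
  set.seed(seed)
  cfg <- simulation_config(n = n, g = 1, m = m, rho = rho, prop_active = 0,
                           seed = seed)
  ge <- generate_experiment(cfg)
  fit_graph(ge$design, 1)
}
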