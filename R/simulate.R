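# Synthetic genome-wide experiments: exchangeably correlated mediator blocks,
# sparse signal placement, null scenarios, and the calibration / power study
# runners.
#
# Generation is deterministic given the config seed and is organized in
# fixed-size graph chunks (GEN_CHUNK graphs): the shared exposure, covariates,
# truth assignment and one sub-seed per chunk are drawn first, then each chunk
# is generated from its own sub-seed. The chunked scan runner therefore
# reproduces exactly the experiment that generate_experiment() would
# materialize, without ever holding the full mediator matrix in memory.

GEN_CHUNK <- 500L

#' Configuration of a synthetic genome-wide mediation experiment
#'
#' Defaults follow the general simulation setting used throughout the
#' calibration and power studies: 1000 individuals, 10000 mechanisms with 30
#' potential mediators each, exchangeable residual correlation 0.3, two
#' standard normal covariates, unit nuisance coefficients, 10% active
#' mechanisms, and active-path signals drawn from Normal(mu, v).
#'
#' @param n individuals.
#' @param g causal graphs (mechanisms).
#' @param m mediators per graph.
#' @param rho exchangeable correlation of the mediator-model residuals; must
#'   lie in `(-1/(m-1), 1)` so the matrix is positive definite.
#' @param prop_active fraction of graphs carrying mediation effects.
#' @param h active paths per active graph.
#' @param signal_mu,signal_v mean and variance of the Normal signal law for
#'   the nonzero `alpha_S` and `beta_M` coefficients (`v = 0` gives the
#'   constant, direction-consistent pattern; `mu = 0, v > 0` the diverse
#'   pattern).
#' @param null_type `"alternative"` (active graphs have both effects), or a
#'   null scenario: `"complete"` (all effects zero), `"one_sided"` (each
#'   affected graph has only alpha or only beta signals), `"disjoint"`
#'   (alpha and beta signals on disjoint path subsets).
#' @param beta_S,alpha_X,beta_X nuisance coefficients (direct effect and
#'   covariate effects), all 1 by default.
#' @param n_covariates number of standard normal covariates.
#' @param shared_exposure if `FALSE` (default) each mechanism draws its own
#'   exposure and covariates, making the graphs fully independent — the
#'   procedure of the calibration and power studies. `TRUE` draws one
#'   exposure/covariate set for all graphs (a cohort-style experiment whose
#'   files can round-trip through [read_experiment]).
#' @param seed mandatory integer seed; every random draw derives from it.
#' @return an object of class `"simulation_config"`.
#' @export
simulation_config <- function(n = 1000, g = 10000, m = 30, rho = 0.3,
                              prop_active = 0.1, h = 1,
                              signal_mu = 0.05, signal_v = 0,
                              null_type = c("alternative", "complete",
                                            "one_sided", "disjoint"),
                              beta_S = 1, alpha_X = 1, beta_X = 1,
                              n_covariates = 2, shared_exposure = FALSE,
                              seed) {
  null_type <- match.arg(null_type)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("a scalar integer `seed` is mandatory", call. = FALSE)
  }
  stopifnot(n >= 4, g >= 1, m >= 1, prop_active >= 0, prop_active <= 1,
            h >= 0, h <= m, signal_v >= 0, n_covariates >= 0)
  if (m > 1 && (rho <= -1 / (m - 1) || rho >= 1)) {
    stop("`rho` must lie in (-1/(m-1), 1) for a positive definite ",
         "correlation matrix", call. = FALSE)
  }
  if (null_type == "disjoint") {
    if (m < 2) stop("the disjoint scenario needs m >= 2", call. = FALSE)
    if (2 * h > m) stop("the disjoint scenario needs 2*h <= m", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), g = as.integer(g), m = as.integer(m), rho = rho,
         prop_active = prop_active, h = as.integer(h),
         signal_mu = signal_mu, signal_v = signal_v, null_type = null_type,
         beta_S = beta_S, alpha_X = alpha_X, beta_X = beta_X,
         n_covariates = as.integer(n_covariates),
         shared_exposure = isTRUE(shared_exposure), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation config:", x$g, "graphs x", x$m, "mediators, n =", x$n, "\n")
  cat("  rho =", x$rho, " scenario:", x$null_type, "\n")
  if (x$null_type != "complete") {
    cat(sprintf("  active: %g%% of graphs, h = %d paths, signal N(%g, %g)\n",
                100 * x$prop_active, x$h, x$signal_mu, x$signal_v))
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Shared draws: truth labels, per-chunk sub-seeds, and (in shared-exposure
# mode) the common exposure and covariates.
sim_shared <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n; g <- cfg$g; m <- cfg$m
  if (cfg$shared_exposure) {
    S <- stats::rnorm(n)
    X <- matrix(stats::rnorm(n * cfg$n_covariates), n, cfg$n_covariates)
  } else {
    S <- NULL
    X <- NULL
  }
  alpha <- matrix(0, g, m)
  beta <- matrix(0, g, m)
  n_active <- round(g * cfg$prop_active)
  active <- rep(FALSE, g)
  paths <- vector("list", g)
  if (cfg$null_type != "complete" && n_active > 0 && cfg$h > 0) {
    act_ids <- sort(sample.int(g, n_active))
    active[act_ids] <- TRUE
    draw_sig <- function(k) {
      stats::rnorm(k, cfg$signal_mu, sqrt(cfg$signal_v))
    }
    for (i in act_ids) {
      if (cfg$null_type == "disjoint") {
        sel <- sample.int(m, 2 * cfg$h)
        pa <- sel[seq_len(cfg$h)]
        pb <- sel[cfg$h + seq_len(cfg$h)]
        alpha[i, pa] <- draw_sig(cfg$h)
        beta[i, pb] <- draw_sig(cfg$h)
        paths[[i]] <- sort(sel)
      } else {
        sel <- sort(sample.int(m, cfg$h))
        paths[[i]] <- sel
        if (cfg$null_type == "one_sided") {
          if (stats::runif(1) < 0.5) {
            alpha[i, sel] <- draw_sig(cfg$h)
          } else {
            beta[i, sel] <- draw_sig(cfg$h)
          }
        } else {
          alpha[i, sel] <- draw_sig(cfg$h)
          beta[i, sel] <- draw_sig(cfg$h)
        }
      }
    }
  }
  n_chunks <- ceiling(g / GEN_CHUNK)
  chunk_seeds <- sample.int(.Machine$integer.max - 1L, n_chunks)
  # graphs with mediation effects: both sides nonzero on a shared path
  mediated <- active & cfg$null_type == "alternative"
  truth <- list(active = mediated, affected = active, paths = paths,
                alpha = alpha, beta = beta)
  list(S = S, X = X, truth = truth, chunk_seeds = chunk_seeds,
       n_chunks = n_chunks)
}

# indices of the graphs in chunk ci
chunk_ids <- function(cfg, ci) {
  from <- (ci - 1L) * GEN_CHUNK + 1L
  seq.int(from, min(ci * GEN_CHUNK, cfg$g))
}

# Generate the mediator blocks and outcomes of one chunk; returns a
# mediation_design for those graphs. In the default per-mechanism mode each
# graph draws its own exposure and covariates (S, X, then mediator noise,
# factor, outcome noise), making graphs fully independent.
sim_chunk_design <- function(cfg, shared, ci) {
  ids <- chunk_ids(cfg, ci)
  n <- cfg$n; m <- cfg$m; q <- cfg$n_covariates
  set.seed(shared$chunk_seeds[ci])
  M <- matrix(0, n, length(ids) * m)
  Y <- matrix(0, n, length(ids))
  if (!cfg$shared_exposure) {
    S_mat <- matrix(0, n, length(ids))
    X_list <- vector("list", length(ids))
  }
  # negative exchangeable correlation needs the explicit Cholesky root;
  # nonnegative rho uses the cheaper one-factor representation
  R_neg <- if (cfg$rho < 0 && m > 1) {
    Sig <- matrix(cfg$rho, m, m); diag(Sig) <- 1
    chol(Sig)
  } else NULL
  for (k in seq_along(ids)) {
    i <- ids[k]
    if (cfg$shared_exposure) {
      Si <- shared$S
      Xi <- shared$X
    } else {
      Si <- stats::rnorm(n)
      Xi <- matrix(stats::rnorm(n * q), n, q)
    }
    Xsum_m <- if (q > 0) drop(Xi %*% rep(cfg$alpha_X, q)) else 0
    Xsum_y <- if (q > 0) drop(Xi %*% rep(cfg$beta_X, q)) else 0
    E <- matrix(stats::rnorm(n * m), n, m)
    if (cfg$rho > 0 && m > 1) {
      W <- stats::rnorm(n)
      E <- sqrt(cfg$rho) * W + sqrt(1 - cfg$rho) * E
    } else if (!is.null(R_neg)) {
      E <- E %*% R_neg
    }
    Mi <- outer(Si, shared$truth$alpha[i, ]) + Xsum_m + E
    ey <- stats::rnorm(n)
    Y[, k] <- cfg$beta_S * Si + drop(Mi %*% shared$truth$beta[i, ]) +
      Xsum_y + ey
    M[, (k - 1) * m + seq_len(m)] <- Mi
    if (!cfg$shared_exposure) {
      S_mat[, k] <- Si
      X_list[[k]] <- Xi
    }
  }
  gnames <- sprintf("G%05d", ids)
  colnames(Y) <- gnames
  colnames(M) <- paste0(rep(gnames, each = m), "_M", seq_len(m))
  graphs <- split(seq_len(length(ids) * m), rep(gnames, each = m))
  graphs <- graphs[gnames]
  if (cfg$shared_exposure) {
    structure(
      list(S = shared$S, X = shared$X, M = M, Y = Y, graphs = graphs,
           n = n, q = q, g = length(ids), mode = "shared"),
      class = "mediation_design"
    )
  } else {
    structure(
      list(S = S_mat, X = X_list, M = M, Y = Y, graphs = graphs,
           n = n, q = q, g = length(ids), mode = "per_graph"),
      class = "mediation_design"
    )
  }
}

#' Generate a synthetic genome-wide experiment
#'
#' Draws the exposure and covariates from N(0, 1), mediator residuals from a
#' multivariate normal with exchangeable correlation `rho`, assigns the
#' active graphs and paths, and generates outcomes from the outcome model.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [simulation_config].
#' @return list with `design` (a [mediation_design]) and `truth` (per-graph
#'   labels: `active` = graphs with a true mediation effect, `affected` =
#'   graphs carrying any signal, `paths`, and the `alpha`, `beta` coefficient
#'   matrices).
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  shared <- sim_shared(cfg)
  chunks <- lapply(seq_len(shared$n_chunks), function(ci) {
    sim_chunk_design(cfg, shared, ci)
  })
  M <- do.call(cbind, lapply(chunks, `[[`, "M"))
  Y <- do.call(cbind, lapply(chunks, `[[`, "Y"))
  offs <- cumsum(c(0, vapply(chunks, function(d) ncol(d$M), numeric(1))))
  graphs <- list()
  for (ci in seq_along(chunks)) {
    graphs <- c(graphs, lapply(chunks[[ci]]$graphs, `+`, offs[ci]))
  }
  if (cfg$shared_exposure) {
    S <- shared$S
    X <- shared$X
    mode <- "shared"
  } else {
    S <- do.call(cbind, lapply(chunks, `[[`, "S"))
    X <- do.call(c, lapply(chunks, `[[`, "X"))
    mode <- "per_graph"
  }
  design <- structure(
    list(S = S, X = X, M = M, Y = Y, graphs = graphs,
         n = cfg$n, q = cfg$n_covariates, g = cfg$g, mode = mode),
    class = "mediation_design"
  )
  list(design = design, truth = shared$truth)
}

#' Generate a null-scenario experiment
#'
#' @param cfg a [simulation_config]; its `null_type` is overridden.
#' @param which `"complete"` (all effects zero), `"one_sided"` (affected
#'   graphs have only exposure-mediator or only mediator-outcome signals) or
#'   `"disjoint"` (the two signal sets live on disjoint paths).
#' @return as [generate_experiment]; under every null scenario
#'   `truth$active` is all-FALSE.
#' @export
generate_null_scenario <- function(cfg, which = c("complete", "one_sided",
                                                  "disjoint")) {
  which <- match.arg(which)
  cfg2 <- cfg
  cfg2$null_type <- which
  if (which == "disjoint") {
    if (cfg$m < 2) stop("the disjoint scenario needs m >= 2", call. = FALSE)
    if (2 * cfg$h > cfg$m) {
      stop("the disjoint scenario needs 2*h <= m", call. = FALSE)
    }
  }
  generate_experiment(cfg2)
}

# ---------------------------------------------------------------------------
# Chunked genome scan of a simulated experiment: identical output to
# mediation_scan(generate_experiment(cfg)$design, ...) but with bounded
# memory. Runs the per-graph stage chunk by chunk, then pools.
# ---------------------------------------------------------------------------
sim_stage <- function(cfg, approaches = c("decor", "multi"),
                      stat_multi = "GBJ", drop_tol = 1e-8,
                      nodes = 32, tol_t = 1e-6, verbose = FALSE) {
  shared <- sim_shared(cfg)
  metas <- vector("list", shared$n_chunks)
  decors <- vector("list", shared$n_chunks)
  multis <- vector("list", shared$n_chunks)
  for (ci in seq_len(shared$n_chunks)) {
    des <- sim_chunk_design(cfg, shared, ci)
    fits <- fit_all_safe(des)
    st <- graph_stage(fits, approaches, stat_multi, drop_tol, nodes, tol_t)
    metas[[ci]] <- st$meta
    if (!is.null(st$decor)) decors[[ci]] <- st$decor
    if (!is.null(st$multi)) multis[[ci]] <- st$multi
    if (verbose) {
      message("chunk ", ci, "/", shared$n_chunks, " done")
    }
  }
  stage <- list(meta = do.call(rbind, metas))
  if ("decor" %in% approaches) stage$decor <- do.call(c, decors)
  if ("multi" %in% approaches) stage$multi <- do.call(rbind, multis)
  list(stage = stage, truth = shared$truth)
}

#' Simulate an experiment and scan it with bounded memory
#'
#' Equivalent to `mediation_scan(generate_experiment(cfg)$design, ...)` but
#' generates, fits and reduces the experiment in graph chunks, so genome-scale
#' configurations (e.g. 10000 graphs x 30 mediators x 1000 individuals) never
#' materialize the full mediator matrix.
#'
#' @inheritParams mediation_scan
#' @param cfg a [simulation_config].
#' @param verbose report chunk progress.
#' @return a `"mediation_scan"` object with the truth labels attached as
#'   attribute `"truth"`.
#' @export
simulate_scan <- function(cfg, approach = c("all", "decorrelation",
                                            "multivariate", "hybrid"),
                          test = c("composite", "js", "sobel"),
                          stat_decor = "BJ", stat_multi = "GBJ",
                          drop_tol = 1e-8, fdr_cutoff = 0.1,
                          acat_weights = c(1, 1), min_pool = 100,
                          verbose = FALSE) {
  approach <- match.arg(approach)
  test <- match.arg(test)
  needs <- switch(approach, decorrelation = "decor", multivariate = "multi",
                  c("decor", "multi"))
  ss <- sim_stage(cfg, needs, stat_multi, drop_tol, verbose = verbose)
  fin <- finish_scan(ss$stage, approach, test, stat_decor, stat_multi,
                     min_pool, fdr_cutoff, acat_weights)
  structure(
    list(results = fin$results, variances = fin$variances,
         settings = list(approach = approach, test = test,
                         stat_decor = stat_decor, stat_multi = stat_multi,
                         drop_tol = drop_tol, fdr_cutoff = fdr_cutoff,
                         acat_weights = acat_weights),
         n = cfg$n, g = cfg$g, call = match.call(), truth = ss$truth),
    class = "mediation_scan"
  )
}

#' Genome-wide type I error study
#'
#' Runs replicate null experiments and reports pooled empirical rejection
#' proportions of the graph-level p-values, per approach and nominal level,
#' with binomial standard errors.
#'
#' @param cfg a [simulation_config]; `null_type` should be a null scenario
#'   (it is set to `"complete"` if left at `"alternative"`).
#' @param alphas nominal significance levels.
#' @param replicates number of replicate experiments (replicate `r` uses seed
#'   `cfg$seed + r - 1`).
#' @param test mediation test used at path/graph level.
#' @param stat_decor,stat_multi integration statistics.
#' @param verbose report progress.
#' @return data frame: `method`, `test`, `level`, `rate`, `se`, `n_tests`,
#'   `replicates`.
#' @export
type1_study <- function(cfg, alphas = c(0.01, 0.001), replicates = 1,
                        test = "composite", stat_decor = "BJ",
                        stat_multi = "GBJ", verbose = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$null_type == "alternative") cfg$null_type <- "complete"
  if (min(alphas) * replicates * cfg$g < 50) {
    warning("fewer than 50 expected rejections at the smallest level; ",
            "rates will be noisy", call. = FALSE)
  }
  counts <- list(decor = numeric(length(alphas)),
                 multi = numeric(length(alphas)))
  n_tests <- 0
  for (r in seq_len(replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    scan <- simulate_scan(cfg_r, approach = "all", test = test,
                          stat_decor = stat_decor, stat_multi = stat_multi,
                          verbose = verbose)
    res <- scan$results
    keep <- res$ok
    n_tests <- n_tests + sum(keep)
    for (a in seq_along(alphas)) {
      counts$decor[a] <- counts$decor[a] +
        sum(res$p_decor[keep] <= alphas[a], na.rm = TRUE)
      counts$multi[a] <- counts$multi[a] +
        sum(res$p_multi[keep] <= alphas[a], na.rm = TRUE)
    }
  }
  methods <- c(decor = paste0("decorrelation-", stat_decor),
               multi = paste0("multivariate-", stat_multi))
  out <- do.call(rbind, lapply(names(methods), function(k) {
    rate <- counts[[k]] / n_tests
    data.frame(method = methods[[k]], test = test, level = alphas,
               rate = rate, se = sqrt(rate * (1 - rate) / n_tests),
               n_tests = n_tests, replicates = replicates)
  }))
  rownames(out) <- NULL
  out
}

#' Genome-wide power study
#'
#' Simulates alternative experiments over a grid of mechanism-level sparsity
#' (`h` active paths) and signal patterns, and reports the fraction of truly
#' active graphs detected at the given significance level for each approach
#' and mediation test.
#'
#' @param cfg base [simulation_config] (its `h`, `signal_mu`, `signal_v` are
#'   overridden by the grid).
#' @param h_values vector of active-path counts.
#' @param patterns named list of `c(mu, v)` signal laws; defaults to the
#'   consistent `(0.05, 0)`, diverse `(0, 0.1)` and mixed `(0.05, 0.1)`
#'   patterns.
#' @param level significance level for detection.
#' @param tests mediation tests to evaluate.
#' @param robust_var use the robust genome-wide variance estimator (default
#'   `TRUE` here: under the alternative, the strong statistics of active
#'   graphs contaminate the plain sample variance, whereas the composite test
#'   needs the scale of the null component; the median-absolute-deviation
#'   estimator recovers it).
#' @param verbose report progress.
#' @return data frame: `pattern`, `h`, `approach`, `test`, `power`, `se`,
#'   `n_active`.
#' @export
power_study <- function(cfg, h_values = c(1, 2, 4, 8),
                        patterns = list(consistent = c(0.05, 0),
                                        diverse = c(0, 0.1),
                                        mixed = c(0.05, 0.1)),
                        level = 0.01, tests = "composite",
                        robust_var = TRUE, verbose = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  cfg$null_type <- "alternative"
  rows <- list()
  for (pat in names(patterns)) {
    for (h in h_values) {
      cfg_h <- cfg
      cfg_h$h <- as.integer(h)
      cfg_h$signal_mu <- patterns[[pat]][1]
      cfg_h$signal_v <- patterns[[pat]][2]
      ss <- sim_stage(cfg_h, c("decor", "multi"), "GBJ", verbose = verbose)
      act <- ss$truth$active & ss$stage$meta$ok
      n_act <- sum(act)
      for (tst in tests) {
        fin <- finish_scan(ss$stage, "all", tst, "BJ", "GBJ",
                           robust_var = robust_var)
        res <- fin$results
        for (ap in c("decor", "multi", "hybrid")) {
          p <- res[[paste0("p_", ap)]][act]
          pw <- mean(p < level, na.rm = TRUE)
          rows[[length(rows) + 1]] <- data.frame(
            pattern = pat, h = h, approach = ap, test = tst, power = pw,
            se = sqrt(pw * (1 - pw) / n_act), n_active = n_act)
        }
      }
      if (verbose) message("pattern ", pat, ", h = ", h, " done")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
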