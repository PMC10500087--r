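# Genome-wide testing pipelines: the decorrelation approach (path-level
# composite p-values integrated by BJ), the multivariate approach (graph-level
# GBJ statistics fed to the composite test), and the ACAT hybrid.
#
# The engine runs in two stages so that experiments larger than memory can be
# processed in graph chunks: a per-graph stage that reduces each fitted graph
# to a handful of numbers, and a genome-wide stage that pools them (variance
# estimation must see the whole experiment).

#' Decorrelate the mediators of a fitted graph
#'
#' Eigendecomposition of the mediator-model residual covariance. The rows of
#' `u` (transposed eigenvectors) map mediators to decorrelated mediators
#' `P = M u'` whose model residuals have a diagonal covariance; components
#' with relative eigenvalue below `drop_tol` are dropped, reducing the path
#' dimension. Eigenvector signs are fixed so the largest-magnitude component
#' is positive.
#'
#' @param fit a [fit_graph] result.
#' @param mediators optional `n x m_i` mediator matrix; when supplied the
#'   transformed mediators `P` are returned as well.
#' @param drop_tol relative eigenvalue threshold below which components are
#'   dropped.
#' @return list with `u` (`p_i x m_i`), `eigenvalues` (all `m_i`,
#'   nonincreasing), `kept` (`p_i`), and `P` (`n x p_i`, if `mediators` was
#'   given).
#' @export
decorrelate <- function(fit, mediators = NULL, drop_tol = 1e-8) {
  stopifnot(inherits(fit, "graph_fit"))
  eig <- eigen(fit$resid_cov_m, symmetric = TRUE)
  vals <- eig$values
  if (vals[1] <= 0) {
    stop("graph '", fit$graph, "': degenerate residual covariance",
         call. = FALSE)
  }
  keep <- which(vals >= drop_tol * vals[1] & vals > 0)
  if (!length(keep)) {
    stop("graph '", fit$graph, "': all eigenvalues below the drop threshold",
         call. = FALSE)
  }
  V <- eig$vectors[, keep, drop = FALSE]
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  V <- sweep(V, 2, flip, "*")
  out <- list(u = t(V), eigenvalues = vals, kept = length(keep))
  if (!is.null(mediators)) out$P <- as.matrix(mediators) %*% V
  out
}

# Path-level standardized statistics after decorrelation. Uses the shared-
# design algebra: the decorrelated mediator model coefficients are V' alpha,
# with residual variances equal to the eigenvalues, and the decorrelated
# outcome-model coefficient covariance is diagonal because the residualized
# crossproduct M~'M~ equals df_m * resid_cov_m exactly.
decor_path_stats <- function(fit, drop_tol = 1e-8) {
  dc <- decorrelate(fit, drop_tol = drop_tol)
  V <- t(dc$u)
  lam <- dc$eigenvalues[seq_len(dc$kept)]
  p_i <- dc$kept
  alpha_t <- drop(crossprod(V, fit$alpha_hat))
  se_alpha <- sqrt(lam * fit$c_ss)
  bty <- drop(crossprod(V, fit$mxy))
  denom <- fit$df_m * lam
  beta_t <- bty / denom
  df_yp <- fit$n - (p_i + fit$q + 2)
  sigma2 <- max(fit$yty - sum(bty^2 / denom), 0) / df_yp
  se_beta <- sqrt(sigma2 / denom)
  list(a = alpha_t / se_alpha, b = beta_t / se_beta, p_kept = p_i)
}

#' Collective direction of a coefficient vector
#'
#' `+1` unless the coefficient sum is strictly negative (`1 - 2 * I(sum < 0)`).
#'
#' @param theta numeric vector.
#' @return `-1` or `+1`.
#' @export
collective_sign <- function(theta) {
  if (sum(theta) < 0) -1 else 1
}

#' Cauchy-combination (ACAT) hybrid of two mediation p-values
#'
#' Combines the decorrelation and multivariate p-values without estimating
#' their dependence: `T = w1 tan((0.5 - p1) pi) + w2 tan((0.5 - p2) pi)`,
#' p-value `1/2 - arctan(T / (w1 + w2)) / pi`. Inputs are clamped to
#' `[1e-15, 1 - 1e-15]` before the tangent transform.
#'
#' @param p_decor,p_multi p-value vectors.
#' @param w_decor,w_multi nonnegative weights (not both zero); equal by
#'   default since no prior knowledge is assumed.
#' @return combined p-values; with equal weights and `p_decor = p_multi = p`
#'   the result is `p`.
#' @export
acat_hybrid <- function(p_decor, p_multi, w_decor = 1, w_multi = 1) {
  if (w_decor < 0 || w_multi < 0 || (w_decor == 0 && w_multi == 0)) {
    stop("weights must be nonnegative and not both zero", call. = FALSE)
  }
  clamp <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-15)
  t_acat <- w_decor * tan((0.5 - clamp(p_decor)) * pi) +
    w_multi * tan((0.5 - clamp(p_multi)) * pi)
  0.5 - atan(t_acat / (w_decor + w_multi)) / pi
}

#' Benjamini-Hochberg q-values and discovery flags
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NA allowed: flagged
#'   non-discoveries).
#' @param cutoff FDR level for the discovery flags.
#' @return data frame with columns `p`, `q`, `discovery`.
#' @export
bh_fdr <- function(pvals, cutoff = 0.1) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  q <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, q = q, discovery = !is.na(q) & q <= cutoff)
}

# Fit all graphs, converting per-graph failures into flagged placeholders so
# one bad graph cannot abort a genome-wide scan.
fit_all_safe <- function(design) {
  per <- identical(design$mode, "per_graph")
  sh <- if (!per) shared_design(design)
  lapply(seq_len(design$g), function(i) {
    tryCatch(
      fit_graph_core(design, if (per) graph_w_bundle(design, i) else sh, i),
      error = function(e) {
        structure(list(), class = "gwmed_failed_fit",
                  graph = names(design$graphs)[i],
                  message = conditionMessage(e))
      })
  })
}

# ---------------------------------------------------------------------------
# Stage 1: per-graph reductions (safe to run chunk by chunk).
# ---------------------------------------------------------------------------
# Returns list(meta, decor, multi):
#   meta  : data.frame(graph, m, p_kept, ok, note)
#   decor : list of per-graph list(a, b) path statistics
#   multi : data.frame(p_alpha, p_beta, sign_a, sign_b)
graph_stage <- function(fits, approaches = c("decor", "multi"),
                        stat_multi = "GBJ", drop_tol = 1e-8,
                        nodes = 32, tol_t = 1e-6) {
  g <- length(fits)
  ok <- !vapply(fits, inherits, logical(1), "gwmed_failed_fit")
  meta <- data.frame(
    graph = vapply(seq_len(g), function(i) {
      if (ok[i]) fits[[i]]$graph else attr(fits[[i]], "graph")
    }, character(1)),
    m = NA_integer_, p_kept = NA_integer_, ok = ok,
    note = vapply(seq_len(g), function(i) {
      if (ok[i]) "" else attr(fits[[i]], "message")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  meta$m[ok] <- vapply(fits[ok], `[[`, integer(1) * 1, "m")
  out <- list(meta = meta)

  if ("decor" %in% approaches) {
    decor <- vector("list", g)
    for (i in which(ok)) {
      decor[[i]] <- tryCatch(decor_path_stats(fits[[i]], drop_tol),
                             error = function(e) NULL)
      if (is.null(decor[[i]])) {
        meta$ok[i] <- FALSE
        meta$note[i] <- "decorrelation failed"
      } else {
        meta$p_kept[i] <- decor[[i]]$p_kept
      }
    }
    out$decor <- decor
    out$meta <- meta
  }

  if ("multi" %in% approaches) {
    pa <- pb <- rep(NA_real_, g)
    sa <- sb <- rep(NA_real_, g)
    idx <- which(meta$ok)
    if (stat_multi == "GBJ") {
      # vectorize across graphs sharing the same m
      for (mm in unique(meta$m[idx])) {
        ii <- idx[meta$m[idx] == mm]
        za <- matrix(0, length(ii), mm)
        zb <- matrix(0, length(ii), mm)
        ra <- rb <- numeric(length(ii))
        for (k in seq_along(ii)) {
          f <- fits[[ii[k]]]
          za[k, ] <- sort(abs(f$z_alpha), decreasing = TRUE)
          zb[k, ] <- sort(abs(f$z_beta), decreasing = TRUE)
          ra[k] <- effective_correlation(f$corr_alpha)
          rb[k] <- effective_correlation(f$corr_beta)
          sa[ii[k]] <- collective_sign(f$alpha_hat)
          sb[ii[k]] <- collective_sign(f$beta_hat)
        }
        if (mm == 1) {
          pa[ii] <- pmin(1, 2 * stats::pnorm(-za[, 1]))
          pb[ii] <- pmin(1, 2 * stats::pnorm(-zb[, 1]))
        } else {
          ta <- pmax(apply(gbj_terms(za, mm, ra, nodes), 1, max), 0)
          tb <- pmax(apply(gbj_terms(zb, mm, rb, nodes), 1, max), 0)
          pa[ii] <- gbj_pvalue_vec(ta, mm, ra, nodes, tol_t)
          pb[ii] <- gbj_pvalue_vec(tb, mm, rb, nodes, tol_t)
        }
      }
    } else {
      for (i in idx) {
        f <- fits[[i]]
        resa <- hc_ghc_minp(f$z_alpha, stat_multi, f$corr_alpha, nodes)
        resb <- hc_ghc_minp(f$z_beta, stat_multi, f$corr_beta, nodes)
        pa[i] <- resa$p.value
        pb[i] <- resb$p.value
        sa[i] <- collective_sign(f$alpha_hat)
        sb[i] <- collective_sign(f$beta_hat)
      }
    }
    out$multi <- data.frame(p_alpha = pa, p_beta = pb,
                            sign_a = sa, sign_b = sb)
  }
  out
}

# path-level test p-value dispatcher
path_test_p <- function(test, a, b, vars) {
  switch(test,
         composite = p_composite(a, b, vars, method = "grid"),
         js = p_joint_significance(a, b),
         sobel = p_sobel(a, b),
         stop("unknown test: ", test, call. = FALSE))
}

# ---------------------------------------------------------------------------
# Stage 2: genome-wide pooling and graph-level p-values.
# ---------------------------------------------------------------------------
finish_scan <- function(stage, approach, test, stat_decor, stat_multi,
                        min_pool = 100, fdr_cutoff = 0.1,
                        acat_weights = c(1, 1), nodes = 32, tol_t = 1e-6,
                        robust_var = FALSE) {
  meta <- stage$meta
  g <- nrow(meta)
  res <- data.frame(graph = meta$graph, m = meta$m, p_kept = meta$p_kept,
                    ok = meta$ok, note = meta$note, stringsAsFactors = FALSE)
  vars_out <- list()

  if (approach %in% c("decorrelation", "all", "hybrid")) {
    okd <- which(meta$ok & !vapply(stage$decor, is.null, logical(1)))
    a_all <- unlist(lapply(stage$decor[okd], `[[`, "a"), use.names = FALSE)
    b_all <- unlist(lapply(stage$decor[okd], `[[`, "b"), use.names = FALSE)
    vars <- estimate_variances(a_all, b_all, min_k = min_pool,
                               robust = robust_var)
    vars_out$decor <- vars
    p_path <- path_test_p(test, a_all, b_all, vars)
    z_path <- z_from_pvalue(pmax(p_path, PVAL_FLOOR))
    lens <- vapply(stage$decor[okd], `[[`, numeric(1), "p_kept")
    ends <- cumsum(lens)
    starts <- ends - lens + 1
    p_decor <- rep(NA_real_, g)
    if (stat_decor == "BJ") {
      # group by path count for vectorized statistic + p-value
      tvals <- numeric(length(okd))
      for (k in seq_along(okd)) {
        zi <- z_path[starts[k]:ends[k]]
        tvals[k] <- bj_statistic(zi)
      }
      for (mm in unique(lens)) {
        sel <- which(lens == mm)
        p_decor[okd[sel]] <- bj_pvalue_vec(tvals[sel], mm)
      }
    } else {
      for (k in seq_along(okd)) {
        zi <- z_path[starts[k]:ends[k]]
        p_decor[okd[k]] <- hc_ghc_minp(zi, stat_decor)$p.value
      }
    }
    res$p_decor <- p_decor
  }

  if (approach %in% c("multivariate", "all", "hybrid")) {
    mu <- stage$multi
    okm <- which(meta$ok & !is.na(mu$p_alpha))
    a_g <- mu$sign_a[okm] * z_from_pvalue(pmax(mu$p_alpha[okm], PVAL_FLOOR))
    b_g <- mu$sign_b[okm] * z_from_pvalue(pmax(mu$p_beta[okm], PVAL_FLOOR))
    vars_m <- estimate_variances(a_g, b_g, min_k = min_pool,
                                 robust = robust_var)
    vars_out$multi <- vars_m
    p_multi <- rep(NA_real_, g)
    p_multi[okm] <- path_test_p(test, a_g, b_g, vars_m)
    res$a_multi <- res$b_multi <- rep(NA_real_, g)
    res$a_multi[okm] <- a_g
    res$b_multi[okm] <- b_g
    res$p_multi <- p_multi
  }

  if (approach %in% c("hybrid", "all")) {
    res$p_hybrid <- acat_hybrid(res$p_decor, res$p_multi,
                                acat_weights[1], acat_weights[2])
  }

  for (col in intersect(c("p_decor", "p_multi", "p_hybrid"), names(res))) {
    fdr <- bh_fdr(res[[col]], fdr_cutoff)
    res[[sub("p_", "q_", col)]] <- fdr$q
    res[[sub("p_", "disc_", col)]] <- fdr$discovery
  }
  list(results = res, variances = vars_out)
}

#' Genome-wide multimediator mediation scan
#'
#' Fits every causal graph of the experiment and tests each for a mediation
#' effect with the selected approach(es):
#' \describe{
#'   \item{decorrelation}{transform each graph's mediators so the path-level
#'     estimators are uncorrelated, compute path-level mediation p-values
#'     (pooling the genome-wide variance estimates), and integrate them per
#'     graph with a Berk-Jones statistic (favors sparse, direction-consistent
#'     signals).}
#'   \item{multivariate}{integrate each graph's correlated coefficient
#'     vectors into generalized Berk-Jones statistics first, sign-transform
#'     their p-values into graph-level normal scores, and apply the mediation
#'     test at graph level (favors dense or direction-diverse signals).}
#'   \item{hybrid}{Cauchy combination of the two (robust default when the
#'     signal pattern is unknown).}
#' }
#'
#' @param design a [mediation_design].
#' @param approach `"all"` (default) runs both approaches plus the hybrid;
#'   or one of `"decorrelation"`, `"multivariate"`, `"hybrid"`.
#' @param test path/graph-level mediation test: `"composite"` (default,
#'   calibrated under the composite null), `"js"` (joint significance) or
#'   `"sobel"` (normality-based).
#' @param stat_decor statistic integrating decorrelated paths: `"BJ"`
#'   (default), `"HC"` or `"minP"`.
#' @param stat_multi statistic integrating correlated coefficient vectors:
#'   `"GBJ"` (default), `"GHC"` or `"minP"` (both flagged: may inflate type I
#'   error for correlated mediators under one-sided nulls).
#' @param drop_tol relative eigenvalue threshold of [decorrelate].
#' @param fdr_cutoff Benjamini-Hochberg discovery cutoff.
#' @param acat_weights length-2 nonnegative weights of the hybrid.
#' @param min_pool guard for genome-wide variance estimation (see
#'   [estimate_variances]).
#' @param robust_var use the robust variance estimator.
#' @return an object of class `"mediation_scan"`: list with `results` (one
#'   row per graph: p-values, q-values, discovery flags, diagnostics),
#'   `variances`, and the call settings.
#' @export
mediation_scan <- function(design,
                           approach = c("all", "decorrelation",
                                        "multivariate", "hybrid"),
                           test = c("composite", "js", "sobel"),
                           stat_decor = c("BJ", "HC", "minP"),
                           stat_multi = c("GBJ", "GHC", "minP"),
                           drop_tol = 1e-8, fdr_cutoff = 0.1,
                           acat_weights = c(1, 1), min_pool = 100,
                           robust_var = FALSE) {
  stopifnot(inherits(design, "mediation_design"))
  approach <- match.arg(approach)
  test <- match.arg(test)
  stat_decor <- match.arg(stat_decor)
  stat_multi <- match.arg(stat_multi)
  if (stat_multi %in% c("GHC", "minP")) {
    warning("GHC/minP multivariate statistics can inflate type I error for ",
            "correlated mediators under one-sided nulls; GBJ is the ",
            "recommended default", call. = FALSE)
  }
  fits <- fit_all_safe(design)
  needs <- switch(approach, decorrelation = "decor", multivariate = "multi",
                  c("decor", "multi"))
  stage <- graph_stage(fits, needs, stat_multi, drop_tol)
  fin <- finish_scan(stage, approach, test, stat_decor, stat_multi,
                     min_pool, fdr_cutoff, acat_weights)
  structure(
    list(results = fin$results, variances = fin$variances,
         settings = list(approach = approach, test = test,
                         stat_decor = stat_decor, stat_multi = stat_multi,
                         drop_tol = drop_tol, fdr_cutoff = fdr_cutoff,
                         acat_weights = acat_weights),
         n = design$n, g = design$g, call = match.call()),
    class = "mediation_scan"
  )
}

#' Run the decorrelation approach
#'
#' Convenience wrapper around [mediation_scan] with
#' `approach = "decorrelation"`.
#'
#' @inheritParams mediation_scan
#' @param stat path-integration statistic: `"BJ"`, `"HC"` or `"minP"`.
#' @return a `"mediation_scan"` object.
#' @export
run_decorrelation <- function(design, test = "composite", stat = "BJ",
                              drop_tol = 1e-8, ...) {
  mediation_scan(design, approach = "decorrelation", test = test,
                 stat_decor = stat, drop_tol = drop_tol, ...)
}

#' Run the multivariate approach
#'
#' Convenience wrapper around [mediation_scan] with
#' `approach = "multivariate"`.
#'
#' @inheritParams mediation_scan
#' @param stat coefficient-integration statistic: `"GBJ"`, `"GHC"` or
#'   `"minP"`.
#' @return a `"mediation_scan"` object.
#' @export
run_multivariate <- function(design, test = "composite", stat = "GBJ", ...) {
  mediation_scan(design, approach = "multivariate", test = test,
                 stat_multi = stat, ...)
}

#' @export
print.mediation_scan <- function(x, ...) {
  cat("Genome-wide mediation scan:", x$g, "graphs, n =", x$n, "\n")
  cat("  approach:", x$settings$approach, " test:", x$settings$test, "\n")
  for (col in intersect(c("disc_decor", "disc_multi", "disc_hybrid"),
                        names(x$results))) {
    cat(sprintf("  discoveries (%s, FDR <= %g): %d\n",
                sub("disc_", "", col), x$settings$fdr_cutoff,
                sum(x$results[[col]], na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.mediation_scan <- function(object, ...) {
  res <- object$results
  pcols <- intersect(c("p_decor", "p_multi", "p_hybrid"), names(res))
  dcols <- sub("p_", "disc_", pcols)
  disc <- lapply(dcols, function(cn) which(res[[cn]]))
  names(disc) <- sub("disc_", "", dcols)
  overlap <- outer(seq_along(disc), seq_along(disc),
                   Vectorize(function(i, j) length(intersect(disc[[i]], disc[[j]]))))
  dimnames(overlap) <- list(names(disc), names(disc))
  out <- list(
    g = object$g, n = object$n, settings = object$settings,
    n_failed = sum(!res$ok),
    discoveries = vapply(disc, length, integer(1)),
    overlap = overlap,
    variances = object$variances
  )
  class(out) <- "summary.mediation_scan"
  out
}

#' @export
print.summary.mediation_scan <- function(x, ...) {
  cat("Mediation scan of", x$g, "graphs (n =", x$n, ")\n")
  if (x$n_failed > 0) cat("  failed graphs:", x$n_failed, "\n")
  cat("  discoveries at FDR <=", x$settings$fdr_cutoff, ":\n")
  print(x$discoveries)
  if (length(x$discoveries) > 1) {
    cat("  overlap:\n")
    print(x$overlap)
  }
  invisible(x)
}

#' QQ plot of genome-wide mediation p-values
#'
#' Observed versus expected `-log10` p-values for each computed approach.
#'
#' @param x a `"mediation_scan"`.
#' @param ... passed to [graphics::plot].
#' @export
plot.mediation_scan <- function(x, ...) {
  res <- x$results
  pcols <- intersect(c("p_decor", "p_multi", "p_hybrid"), names(res))
  cols <- c(p_decor = "#1b9e77", p_multi = "#d95f02", p_hybrid = "#7570b3")
  first <- TRUE
  for (cn in pcols) {
    p <- sort(res[[cn]][!is.na(res[[cn]])])
    if (!length(p)) next
    expd <- -log10((seq_along(p) - 0.5) / length(p))
    obs <- -log10(pmax(p, PVAL_FLOOR))
    if (first) {
      graphics::plot(expd, obs, pch = 16, cex = 0.5, col = cols[cn],
                     xlab = expression(-log[10] ~ "expected p"),
                     ylab = expression(-log[10] ~ "observed p"), ...)
      graphics::abline(0, 1, lty = 2)
      first <- FALSE
    } else {
      graphics::points(expd, obs, pch = 16, cex = 0.5, col = cols[cn])
    }
  }
  graphics::legend("topleft", legend = sub("p_", "", pcols),
                   col = cols[pcols], pch = 16, bty = "n")
  invisible(x)
}

#' Expected/observed QQ columns for external plotting
#'
#' @param scan a `"mediation_scan"`.
#' @return data frame with `approach`, `graph`, `expected` and `observed`
#'   `-log10` p-values.
#' @export
qq_data <- function(scan) {
  res <- scan$results
  pcols <- intersect(c("p_decor", "p_multi", "p_hybrid"), names(res))
  do.call(rbind, lapply(pcols, function(cn) {
    keep <- !is.na(res[[cn]])
    p <- res[[cn]][keep]
    r <- rank(p, ties.method = "first")
    data.frame(approach = sub("p_", "", cn), graph = res$graph[keep],
               expected = -log10((r - 0.5) / length(p)),
               observed = -log10(pmax(p, PVAL_FLOOR)))
  }))
}
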