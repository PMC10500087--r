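# Experiment container and per-graph regression fitting.
#
# Each causal graph i couples an exposure S, a block of m_i mediators M^i and
# an outcome Y^i, with shared covariates X:
#   mediator model:  M^i = alpha_S * S + alpha_X' X + e_m,  e_m ~ MVN(0, Sigma_m)
#   outcome model:   Y^i = beta_S * S + beta_M' M^i + beta_X' X + e_y
# Intercepts are always included. Both models are fit by ordinary least
# squares; all graphs share the exposure/covariate design, so the projection
# on [1, S, X] is computed once per experiment.

#' Construct a genome-wide mediation experiment
#'
#' Bundles the exposure, covariates, mediator matrix, outcome matrix and the
#' graph membership mapping into a validated design object.
#'
#' @param exposure numeric vector of length `n`.
#' @param mediators numeric `n x M` matrix with column names; each column is a
#'   mediator belonging to exactly one graph.
#' @param outcomes numeric `n x g` matrix, one named column per graph.
#' @param mapping data frame with columns `graph` and `mediator` assigning
#'   mediator columns (by name or index) to graphs (by outcome column name or
#'   index).
#' @param covariates optional numeric `n x q` matrix (default: none).
#' @return an object of class `"mediation_design"` with elements `S`, `X`,
#'   `M`, `Y`, `graphs` (list of per-graph mediator column indices), `n`, `q`,
#'   `g`.
#' @export
mediation_design <- function(exposure, mediators, outcomes, mapping,
                             covariates = NULL) {
  S <- as.numeric(exposure)
  n <- length(S)
  M <- as.matrix(mediators)
  Y <- as.matrix(outcomes)
  X <- if (is.null(covariates)) {
    matrix(numeric(0), n, 0)
  } else {
    as.matrix(covariates)
  }
  if (nrow(M) != n || nrow(Y) != n || nrow(X) != n) {
    stop("exposure, covariates, mediators and outcomes must describe the ",
         "same n individuals", call. = FALSE)
  }
  if (anyNA(S) || anyNA(M) || anyNA(Y) || anyNA(X)) {
    stop("missing values are not allowed; apply complete-case filtering ",
         "before constructing the design", call. = FALSE)
  }
  if (is.null(colnames(M))) colnames(M) <- paste0("M", seq_len(ncol(M)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("G", seq_len(ncol(Y)))
  stopifnot(is.data.frame(mapping), all(c("graph", "mediator") %in% names(mapping)))

  med_id <- mapping$mediator
  med_idx <- if (is.numeric(med_id)) as.integer(med_id) else match(as.character(med_id), colnames(M))
  gr_id <- mapping$graph
  gr_idx <- if (is.numeric(gr_id)) as.integer(gr_id) else match(as.character(gr_id), colnames(Y))
  if (anyNA(gr_idx)) {
    stop("mapping refers to unknown graphs: ",
         paste(unique(gr_id[is.na(gr_idx)]), collapse = ", "), call. = FALSE)
  }
  missing_med <- is.na(med_idx)
  if (any(missing_med)) {
    dropped <- unique(gr_idx[missing_med])
    warning("dropping ", length(dropped),
            " graph(s) whose mediator columns are absent: ",
            paste(colnames(Y)[dropped], collapse = ", "), call. = FALSE)
    keep <- !(gr_idx %in% dropped)
    gr_idx <- gr_idx[keep]
    med_idx <- med_idx[keep]
  }
  if (!length(gr_idx)) stop("no graphs left after validation", call. = FALSE)
  if (anyDuplicated(med_idx)) {
    stop("mediator columns must belong to exactly one graph", call. = FALSE)
  }
  graphs <- split(med_idx, colnames(Y)[gr_idx])
  graphs <- graphs[intersect(colnames(Y), names(graphs))]  # stable order
  structure(
    list(S = S, X = X, M = M, Y = Y, graphs = graphs,
         n = n, q = ncol(X), g = length(graphs), mode = "shared"),
    class = "mediation_design"
  )
}

# Exposure/covariate design of graph idx. Real-data designs share one
# exposure and covariate set ("shared" mode); simulated experiments follow
# the study procedure of drawing S and X independently per mechanism
# ("per_graph" mode), in which S is an n x g matrix and X a list of g
# matrices.
graph_w_bundle <- function(design, idx) {
  if (identical(design$mode, "per_graph")) {
    W <- cbind(`(Intercept)` = 1, S = design$S[, idx], design$X[[idx]])
  } else {
    W <- cbind(`(Intercept)` = 1, S = design$S, design$X)
  }
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    stop("exposure/covariate design is rank deficient", call. = FALSE)
  }
  WtWinv <- chol2inv(qr.R(qrW))
  list(W = W, qr = qrW, c_ss = WtWinv[2, 2], df_m = design$n - ncol(W),
       p_w = ncol(W))
}

#' @export
print.mediation_design <- function(x, ...) {
  m_i <- lengths(x$graphs)
  cat("Genome-wide mediation experiment",
      if (identical(x$mode, "per_graph")) "(independent mechanisms)", "\n")
  cat("  individuals:", x$n, "  covariates:", x$q, "\n")
  cat("  graphs:", x$g, "  mediators/graph:",
      paste(range(m_i), collapse = "-"), "\n")
  invisible(x)
}

# Shared-mode design pieces, computed once per experiment.
shared_design <- function(design) {
  stopifnot(!identical(design$mode, "per_graph"))
  graph_w_bundle(design, 1L)
}

#' Fit the mediator and outcome regressions of one causal graph
#'
#' Ordinary least squares for the multivariate mediator model `M^i ~ S + X`
#' and the outcome model `Y^i ~ S + M^i + X` (intercepts included). Residual
#' covariance of the mediator model uses the degrees-of-freedom-corrected
#' denominator `n - (q + 2)`. Because all mediators in a graph share the same
#' design, the correlation between the exposure-effect estimators equals the
#' residual correlation; the mediator-effect estimator correlation comes from
#' the `beta_M` block of the outcome-model coefficient covariance.
#'
#' @param design a [mediation_design].
#' @param graph_id graph name (outcome column name) or index.
#' @return an object of class `"graph_fit"` with the estimates `alpha_hat`,
#'   `beta_hat`, standard errors, `beta_S`, the residual covariance
#'   `resid_cov_m`, standardized vectors `z_alpha`, `z_beta`, and estimator
#'   correlation matrices `corr_alpha`, `corr_beta`.
#' @export
fit_graph <- function(design, graph_id) {
  stopifnot(inherits(design, "mediation_design"))
  idx <- if (is.numeric(graph_id)) graph_id else match(graph_id, names(design$graphs))
  if (is.na(idx) || idx < 1 || idx > design$g) {
    stop("unknown graph: ", graph_id, call. = FALSE)
  }
  fit_graph_core(design, graph_w_bundle(design, idx), idx)
}

# Core per-graph fit; `sh` is the shared_design() of the experiment.
fit_graph_core <- function(design, sh, idx) {
  gname <- names(design$graphs)[idx]
  cols <- design$graphs[[idx]]
  m_i <- length(cols)
  n <- design$n
  q <- design$q
  if (m_i + q + 2 >= n) {
    stop("graph '", gname, "': insufficient sample size (m + q + 2 = ",
         m_i + q + 2, " >= n = ", n, ")", call. = FALSE)
  }
  M <- design$M[, cols, drop = FALSE]
  Y <- design$Y[, idx]

  # mediator model: coefficients via the shared QR, residuals by projection
  coef_m <- qr.coef(sh$qr, M)                      # (q+2) x m_i
  Mres <- qr.resid(sh$qr, M)
  resid_cov <- crossprod(Mres) / sh$df_m
  alpha_hat <- coef_m[2, ]
  alpha_se <- sqrt(pmax(diag(resid_cov) * sh$c_ss, 0))
  if (any(alpha_se == 0)) {
    stop("graph '", gname, "': degenerate mediator (zero residual variance)",
         call. = FALSE)
  }

  # outcome model via Frisch-Waugh: residualize Y and M on W, then OLS of
  # Y-residuals on M-residuals gives beta_M and its covariance block
  Yres <- qr.resid(sh$qr, Y)
  MtM <- crossprod(Mres)
  R <- tryCatch(chol(MtM), error = function(e) NULL)
  # pivot-ratio estimate of the crossproduct condition number; exact
  # collinearity that survives chol() through rounding is caught here
  if (!is.null(R)) {
    d <- diag(R)
    if ((max(d) / min(d))^2 > 1e10) R <- NULL
  }
  if (is.null(R)) {
    stop("graph '", gname, "': singular or near-singular outcome design",
         call. = FALSE)
  }
  mxy <- crossprod(Mres, Yres)
  beta_hat <- drop(chol2inv(R) %*% mxy)
  df_y <- n - (m_i + q + 2)
  yty <- sum(Yres^2)
  rss <- yty - sum(beta_hat * mxy)
  sigma_y2 <- max(rss, 0) / df_y
  cov_beta <- sigma_y2 * chol2inv(R)
  beta_se <- sqrt(pmax(diag(cov_beta), 0))
  if (any(beta_se == 0)) {
    stop("graph '", gname, "': degenerate outcome fit", call. = FALSE)
  }
  # direct effect: S coefficient of the full outcome model
  coef_w_y <- qr.coef(sh$qr, Y - M %*% beta_hat)
  beta_S <- coef_w_y[2]

  structure(
    list(graph = gname, m = m_i, n = n, q = q,
         alpha_hat = alpha_hat, alpha_se = alpha_se,
         beta_hat = beta_hat, beta_se = beta_se, beta_S = beta_S,
         resid_cov_m = resid_cov,
         z_alpha = alpha_hat / alpha_se, z_beta = beta_hat / beta_se,
         corr_alpha = stats::cov2cor(resid_cov),
         corr_beta = stats::cov2cor(cov_beta),
         sigma_y2 = sigma_y2, df_m = sh$df_m, df_y = df_y,
         c_ss = sh$c_ss, mxy = drop(mxy), yty = yty),
    class = "graph_fit"
  )
}

# Fit every graph (or a subset); the shared projection is reused when the
# experiment has a single exposure/covariate design.
fit_all_graphs <- function(design, ids = seq_len(design$g)) {
  per <- identical(design$mode, "per_graph")
  sh <- if (!per) shared_design(design)
  lapply(ids, function(i) {
    fit_graph_core(design, if (per) graph_w_bundle(design, i) else sh, i)
  })
}

#' @export
print.graph_fit <- function(x, ...) {
  cat("Graph", x$graph, "fit:", x$m, "mediator path(s), n =", x$n, "\n")
  tab <- data.frame(alpha = x$alpha_hat, se_alpha = x$alpha_se,
                    beta = x$beta_hat, se_beta = x$beta_se)
  rownames(tab) <- names(x$alpha_hat)
  print(tab, digits = 4)
  cat("direct effect beta_S =", format(x$beta_S, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.graph_fit <- function(object, ...) {
  cbind(alpha_S = object$alpha_hat, beta_M = object$beta_hat)
}
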