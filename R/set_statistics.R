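# Per-graph signal-integration statistics: Berk-Jones (independent paths),
# generalized Berk-Jones (correlated Z), and the HC/GHC/minP comparison
# kernels, with exact / quadrature-based boundary-crossing p-values.

PVAL_FLOOR <- 1e-300

#' Two-sided p-value to |Z| transform
#'
#' Maps a p-value to the standard normal quantile `qnorm(1 - p/2)`, the |Z|
#' value whose two-sided tail equals `p`. Inputs below 1e-300 are clamped.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return nonnegative |Z| values.
#' @export
z_from_pvalue <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p <- pmax(p, PVAL_FLOOR)
  stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Shifted-mean solution for the Berk-Jones numerator
#'
#' Solves for the positive mean `mu` at which a `N(mu, 1)` variable has
#' two-sided exceedance probability `j/m` at threshold `t`, i.e. the root of
#' `j/m = 1 - (pnorm(t - mu) - pnorm(-t - mu))`. The root exists and is unique
#' when the indicator condition `2 * pnorm(-t) < j/m` holds.
#'
#' @param j integer rank, `1 <= j <= m`.
#' @param m number of paths in the graph.
#' @param t nonnegative threshold on the |Z| scale.
#' @return the positive root, to absolute equation accuracy 1e-10.
#' @export
mu_hat <- function(j, m, t) {
  stopifnot(length(j) == 1, length(m) == 1, length(t) == 1,
            j >= 1, j <= m, t >= 0)
  target <- j / m
  if (2 * stats::pnorm(-t) >= target) {
    stop("indicator condition fails: 2*pnorm(-t) must be < j/m", call. = FALSE)
  }
  f <- function(mu) {
    stats::pnorm(t - mu, lower.tail = FALSE) + stats::pnorm(-t - mu) - target
  }
  root <- stats::uniroot(f, c(0, t + 10), tol = 1e-13)$root
  stopifnot(abs(f(root)) <= 1e-10)
  root
}

# Vectorized exceedance probability of |N(mu,1)| at threshold t.
two_sided_exceed <- function(t, mu = 0) {
  stats::pnorm(t - mu, lower.tail = FALSE) + stats::pnorm(-t - mu)
}

# Vectorized Newton solver for mu_hat: one rank j (scalar), vector t.
# Guarded by bisection brackets; used on the genome-scale path.
mu_hat_vec <- function(j, m, t, tol = 1e-11) {
  target <- j / m
  lo <- rep(0, length(t))
  hi <- t + 10
  mu <- pmax(t - stats::qnorm(1 - target), 0.5 * t)  # decent start
  mu <- pmin(pmax(mu, lo), hi)
  for (iter in 1:60) {
    ft <- two_sided_exceed(t, mu) - target
    lo[ft < 0] <- mu[ft < 0]
    hi[ft > 0] <- mu[ft > 0]
    deriv <- stats::dnorm(t - mu) - stats::dnorm(t + mu)
    step <- ft / pmax(deriv, 1e-300)
    mu_new <- mu - step
    bad <- !is.finite(mu_new) | mu_new <= lo | mu_new >= hi
    mu_new[bad] <- (lo[bad] + hi[bad]) / 2
    if (max(abs(mu_new - mu)) < tol) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  mu
}

# ---------------------------------------------------------------------------
# Exact boundary-crossing probability for independent standard normals.
#
# Event: exists j with |Z|_(m-j+1) >= g_j, i.e. at least j of the m two-sided
# p-values fall below c_j = 2*pnorm(-g_j). Computed as 1 minus the
# non-crossing probability by the exact O(m^2) order-statistic recursion:
# track the count of p-values below each successive threshold.
# `cs` is a matrix (rows = instances, cols = ranks 1..J), nondecreasing along
# each row; caps[j] = j - 1 is the largest allowed count at threshold j.
# ---------------------------------------------------------------------------
noncross_prob <- function(cs, m, caps = seq_len(ncol(cs)) - 1L) {
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
  J <- ncol(cs)
  nr <- nrow(cs)
  if (any(cs < 0) || any(cs > 1)) stop("thresholds must be probabilities")
  if (any(cs[, -1, drop = FALSE] - cs[, -J, drop = FALSE] < -1e-12)) {
    stop("internal error: non-monotone crossing boundary", call. = FALSE)
  }
  smax <- max(caps)
  # A[, s+1] = P(exactly s p-values below c_k, counts within caps so far)
  A <- matrix(0, nr, smax + 1)
  for (s in 0:min(caps[1], smax)) {
    A[, s + 1] <- stats::dbinom(s, m, cs[, 1])
  }
  if (J >= 2) {
    for (k in 1:(J - 1)) {
      r <- (cs[, k + 1] - cs[, k]) / (1 - cs[, k])
      r[!is.finite(r)] <- 0        # c_k == 1: no mass left above
      r <- pmin(pmax(r, 0), 1)
      lr <- log(r)
      l1r <- log1p(-r)
      B <- matrix(0, nr, smax + 1)
      for (s in 0:caps[k + 1]) {
        acc <- 0
        for (u in 0:min(s, caps[k])) {
          # Binomial(m - u, r) pmf at s - u, in log space for speed;
          # the s == u case avoids 0 * log(0).
          lp <- if (s == u) {
            (m - s) * l1r
          } else {
            lchoose(m - u, s - u) + (s - u) * lr + (m - s) * l1r
          }
          acc <- acc + A[, u + 1] * exp(lp)
        }
        B[, s + 1] <- acc
      }
      A <- B
    }
  }
  rowSums(A)
}

#' Exact crossing p-value for an order-statistic boundary (independent case)
#'
#' Probability that for some rank `j`, the `j`-th largest of `m` i.i.d.
#' standard normal magnitudes reaches the threshold `g_j`. Thresholds must be
#' nonincreasing in `j` (the usable boundary produced by inverting a
#' supremum-type statistic). Computed by an exact `O(m^2)` recursion over the
#' counts of two-sided p-values below the transformed boundary.
#'
#' @param thresholds numeric vector `g_1 >= g_2 >= ...` on the |Z| scale
#'   (length at most `m`; `Inf` entries are allowed and never cross).
#' @param m number of independent standard normal variables.
#' @return the crossing probability in `[0, 1]`.
#' @export
crossing_pvalue_independent <- function(thresholds, m) {
  stopifnot(m >= 1, length(thresholds) >= 1, length(thresholds) <= m)
  cs <- 2 * stats::pnorm(-thresholds)
  if (any(diff(cs) < -1e-12)) {
    stop("internal error: non-monotone usable boundary", call. = FALSE)
  }
  cs <- cummax(pmin(pmax(cs, 0), 1))
  1 - noncross_prob(matrix(cs, nrow = 1), m)
}

# ---------------------------------------------------------------------------
# Berk-Jones statistic, independent paths.
# Numerator success probability is j/m exactly (the shifted mean is defined to
# match the observed exceedance count), so each rank term is the binomial
# log-likelihood ratio m * KL(j/m || c_j) with c_j = 2*pnorm(-|Z|_(m-j+1)).
# ---------------------------------------------------------------------------
log_dbinom <- function(x, n, p) {
  lchoose(n, x) + x * log(p) + (n - x) * log1p(-p)
}

# rank terms for a matrix of |Z| sorted decreasingly (rows = graphs)
bj_terms <- function(zsort_desc, m) {
  J <- max(1L, m %/% 2L)
  js <- seq_len(J)
  cobs <- 2 * stats::pnorm(-zsort_desc[, js, drop = FALSE])
  terms <- matrix(0, nrow(zsort_desc), J)
  for (j in js) {
    q <- j / m
    terms[, j] <- log_dbinom(j, m, q) - log_dbinom(j, m, cobs[, j])
  }
  ok <- sweep(cobs, 2, js / m, "<")
  terms[!ok] <- -Inf
  terms
}

#' Berk-Jones statistic for independent path Z statistics
#'
#' Supremum over ranks `j = 1, ..., floor(m/2)` of the log ratio of binomial
#' probabilities of observing `j` exceedances at threshold `|Z|_(m-j+1)` under
#' the fitted shifted mean versus the null, restricted to ranks where the
#' indicator `2*pnorm(-|Z|_(m-j+1)) < j/m` holds; 0 if no rank qualifies.
#' For `m = 1` the statistic is `|z|` itself and its p-value is the two-sided
#' normal tail.
#'
#' @param z numeric vector of path Z statistics (length `m >= 1`).
#' @return the nonnegative BJ statistic.
#' @export
bj_statistic <- function(z) {
  m <- length(z)
  if (m == 0) stop("empty Z vector", call. = FALSE)
  stopifnot(all(is.finite(z)))
  if (m == 1) return(abs(z))
  zs <- matrix(sort(abs(z), decreasing = TRUE), 1)
  t <- max(bj_terms(zs, m))
  max(t, 0)
}

# Invert the BJ rank-j term at level t_obs: the p-scale threshold c < j/m with
# m * KL(j/m || c) = t_obs.  Vectorized bisection in log(c); rows = instances.
bj_invert_rank <- function(t_obs, j, m) {
  q <- j / m
  rhs <- j * log(q) + (m - j) * log1p(-q) - t_obs
  lo <- rep(log(1e-310), length(t_obs))
  hi <- rep(log(q), length(t_obs))
  f <- function(x) {
    c_ <- exp(x)
    j * x + (m - j) * log1p(-c_) - rhs
  }
  for (iter in 1:80) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    up <- fm < 0          # f increasing in x; f<0 => root above
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  exp((lo + hi) / 2)
}

# Genome-scale BJ p-values: t_obs vector, common m. Exact recursion.
bj_pvalue_vec <- function(t_obs, m) {
  out <- rep(1, length(t_obs))
  if (m == 1) {
    return(pmin(1, 2 * stats::pnorm(-t_obs)))
  }
  pos <- which(t_obs > 0)
  if (!length(pos)) return(out)
  J <- m %/% 2L
  cs <- matrix(0, length(pos), J)
  for (j in seq_len(J)) cs[, j] <- bj_invert_rank(t_obs[pos], j, m)
  cs <- rowCummax(cs)   # enforce monotone boundary (numerical)
  out[pos] <- pmin(1, pmax(0, 1 - noncross_prob(cs, m)))
  out
}

#' P-value of the Berk-Jones statistic (independent paths)
#'
#' Inverts each rank term of the BJ objective at the observed level to obtain
#' the order-statistic boundary, then evaluates the exact boundary-crossing
#' probability for `m` i.i.d. standard normals.
#'
#' @param t_obs observed BJ statistic (nonnegative scalar or vector).
#' @param m number of paths.
#' @return p-value(s) in `[0, 1]`; `t_obs = 0` gives 1.
#' @export
bj_pvalue <- function(t_obs, m) {
  stopifnot(all(t_obs >= 0), m >= 1)
  bj_pvalue_vec(t_obs, m)
}

# ---------------------------------------------------------------------------
# Correlated count law: one-factor Gaussian working model.
#
# Z_i = mu + sqrt(rho_eff) W + sqrt(1 - rho_eff) e_i with W, e_i iid N(0,1).
# Conditionally on W the exceedance indicators are independent, so exceedance
# counts are binomial mixtures integrated over W by Gauss-Hermite quadrature.
# rho_eff = sqrt(mean of squared off-diagonal correlations): exact for
# exchangeable correlation, matches the count variance to second order in the
# correlations otherwise (|Z| exceedance covariances are quadratic in the
# pairwise correlation near zero), and is invariant to sign flips of
# individual coordinates.
# ---------------------------------------------------------------------------
gh_nodes <- function(n = 40) {
  key <- paste0("gh", n)
  if (is.null(.gwmed[[key]])) {
    gh <- pracma::gaussHermite(n)
    x <- sqrt(2) * gh$x
    w <- gh$w / sqrt(pi)
    keep <- w > 1e-13          # prune numerically irrelevant tail nodes
    .gwmed[[key]] <- list(x = x[keep], w = w[keep] / sum(w[keep]))
  }
  .gwmed[[key]]
}

check_corr <- function(corr) {
  if (is.null(corr)) return(invisible(NULL))
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop("`corr` must be a square matrix", call. = FALSE)
  }
  if (max(abs(corr - t(corr))) > 1e-8 || max(abs(diag(corr) - 1)) > 1e-8) {
    stop("`corr` must be symmetric with unit diagonal", call. = FALSE)
  }
  if (nrow(corr) > 1 && min(eigen(corr, symmetric = TRUE,
                                  only.values = TRUE)$values) < -1e-8) {
    stop("`corr` must be positive semidefinite", call. = FALSE)
  }
  invisible(NULL)
}

#' Effective exchangeable correlation of a correlation matrix
#'
#' Root mean square of the off-diagonal entries: the one-factor working
#' correlation to which the count law of |Z| exceedances is matched. Exact
#' under exchangeable correlation; invariant to coordinate sign flips.
#'
#' @param corr correlation matrix (or `NULL` for independence).
#' @return scalar in `[0, 1)`.
#' @export
effective_correlation <- function(corr) {
  if (is.null(corr) || nrow(corr) == 1) return(0)
  off <- corr[upper.tri(corr)]
  min(sqrt(mean(off^2)), 0.999)
}

# conditional exceedance probability given factor value w (vectorized over
# any argument): P(|Z| >= t | W = w) with Z = mu + sqrt(rho) w + sqrt(1-rho) e
cond_exceed <- function(t, mu, rho, w) {
  s <- sqrt(rho)
  r <- sqrt(1 - rho)
  shift <- mu + s * w
  stats::pnorm((t - shift) / r, lower.tail = FALSE) +
    stats::pnorm((-t - shift) / r)
}

# P(S(t) = j) under the factor model; t, mu, rho vectors (instances), j,m
# scalars. Returns vector over instances.
count_pmf <- function(j, m, t, mu, rho, nodes = 40) {
  gh <- gh_nodes(nodes)
  out <- numeric(length(t))
  ind <- rho < 1e-12
  if (any(ind)) {
    out[ind] <- stats::dbinom(j, m, two_sided_exceed(t[ind], mu[ind]))
  }
  if (any(!ind)) {
    idx <- which(!ind)
    acc <- 0
    for (k in seq_along(gh$x)) {
      q <- cond_exceed(t[idx], mu[idx], rho[idx], gh$x[k])
      acc <- acc + gh$w[k] * stats::dbinom(j, m, q)
    }
    out[idx] <- acc
  }
  out
}

# GBJ rank terms for matrices: zsort (rows = graphs, sorted desc), rho vector.
gbj_terms <- function(zsort_desc, m, rho, nodes = 40) {
  J <- max(1L, m %/% 2L)
  g <- nrow(zsort_desc)
  terms <- matrix(-Inf, g, J)
  # |Z|_(m-j+1) is the j-th largest value: column j of the descending sort
  for (j in seq_len(J)) {
    t_j <- zsort_desc[, j]
    ok <- 2 * stats::pnorm(-t_j) < j / m
    if (!any(ok)) next
    idx <- which(ok)
    mu <- mu_hat_vec(j, m, t_j[idx])
    num <- count_pmf(j, m, t_j[idx], mu, rho[idx], nodes)
    den <- count_pmf(j, m, t_j[idx], rep(0, length(idx)), rho[idx], nodes)
    # floor against underflow of the null pmf at extreme thresholds
    terms[idx, j] <- log(pmax(num, 1e-300)) - log(pmax(den, 1e-300))
  }
  terms
}

#' Generalized Berk-Jones statistic for correlated path Z statistics
#'
#' Extends [bj_statistic] to correlated Z vectors: the exceedance-count
#' probabilities in each rank term are evaluated under a one-factor Gaussian
#' working model moment-matched to the correlation matrix (see
#' [effective_correlation]). Reduces exactly to the BJ statistic when the
#' correlation matrix is the identity.
#'
#' @param z numeric vector of path Z statistics.
#' @param corr `m x m` correlation matrix of `z`.
#' @param nodes number of Gauss-Hermite nodes for the factor integral.
#' @return the nonnegative GBJ statistic.
#' @export
gbj_statistic <- function(z, corr, nodes = 60) {
  m <- length(z)
  if (m == 0) stop("empty Z vector", call. = FALSE)
  check_corr(corr)
  stopifnot(nrow(corr) == m, all(is.finite(z)))
  if (m == 1) return(abs(z))
  rho <- effective_correlation(corr)
  zs <- matrix(sort(abs(z), decreasing = TRUE), 1)
  t <- max(gbj_terms(zs, m, rho, nodes))
  max(t, 0)
}

# row-wise cumulative maximum without apply()
rowCummax <- function(x) {
  if (ncol(x) >= 2) {
    for (j in 2:ncol(x)) x[, j] <- pmax(x[, j], x[, j - 1])
  }
  x
}

# Invert the GBJ rank-j term at level t_obs (vector) for given rho (vector):
# find threshold t (|Z| scale) with term_j(t) = t_obs, t above the indicator
# boundary. Bisection; the term is increasing in t.
gbj_invert_rank <- function(t_obs, j, m, rho, nodes = 40, tol_t = 1e-10) {
  tmin <- stats::qnorm(j / (2 * m), lower.tail = FALSE)  # indicator boundary
  term_at <- function(t, rho_) {
    mu <- mu_hat_vec(j, m, t, tol = 1e-9)
    num <- count_pmf(j, m, t, mu, rho_, nodes)
    den <- count_pmf(j, m, t, rep(0, length(t)), rho_, nodes)
    log(pmax(num, 1e-300)) - log(pmax(den, 1e-300))
  }
  n <- length(t_obs)
  lo <- rep(tmin + 1e-9, n)
  hi <- rep(tmin + 2, n)
  flo <- term_at(lo, rho) - t_obs
  fhi <- term_at(hi, rho) - t_obs
  # expand upper bracket until the term exceeds t_obs (subset-aware)
  need <- which(fhi < 0)
  for (iter in 1:60) {
    if (!length(need)) break
    hi[need] <- hi[need] + 2
    fhi[need] <- term_at(hi[need], rho[need]) - t_obs[need]
    need <- need[fhi[need] < 0]
  }
  if (length(need)) {
    # statistic beyond the representable term range: boundary is effectively
    # at the far end (crossing probability vanishes for this rank)
    lo[need] <- hi[need]
    flo[need] <- fhi[need]
  }
  # Illinois false position on the monotone term
  active <- seq_len(n)
  side <- integer(n)              # last endpoint replaced: -1 lo, +1 hi
  for (iter in 1:60) {
    a <- active
    x <- hi[a] - fhi[a] * (hi[a] - lo[a]) / (fhi[a] - flo[a])
    bad <- !is.finite(x) | x <= lo[a] | x >= hi[a]
    x[bad] <- (lo[a[bad]] + hi[a[bad]]) / 2
    fx <- term_at(x, rho[a]) - t_obs[a]
    neg <- fx < 0
    i_lo <- a[neg]; i_hi <- a[!neg]
    # Illinois halving of the stagnant endpoint
    fhi[i_lo] <- ifelse(side[i_lo] == -1L, fhi[i_lo] / 2, fhi[i_lo])
    flo[i_hi] <- ifelse(side[i_hi] == 1L, flo[i_hi] / 2, flo[i_hi])
    lo[i_lo] <- x[neg]; flo[i_lo] <- fx[neg]; side[i_lo] <- -1L
    hi[i_hi] <- x[!neg]; fhi[i_hi] <- fx[!neg]; side[i_hi] <- 1L
    active <- a[abs(fx) > 1e-9 & (hi[a] - lo[a]) > tol_t]
    if (!length(active)) break
  }
  (lo + hi) / 2
}

# Genome-scale GBJ p-values: t_obs and rho vectors, common m.
# tol_t controls boundary-inversion accuracy; the default matches the exported
# scalar function, the pipelines use a coarser (still far sub-Monte-Carlo)
# tolerance for speed.
gbj_pvalue_vec <- function(t_obs, m, rho, nodes = 40, tol_t = 1e-10) {
  out <- rep(1, length(t_obs))
  if (m == 1) return(pmin(1, 2 * stats::pnorm(-t_obs)))
  pos <- which(t_obs > 0)
  if (!length(pos)) return(out)
  J <- m %/% 2L
  rho_p <- rho[pos]
  ind <- rho_p < 1e-12
  if (any(ind)) {
    # with no correlation the rank terms are the BJ terms: invert exactly
    out[pos[ind]] <- bj_pvalue_vec(t_obs[pos[ind]], m)
  }
  if (any(!ind)) {
    idx <- which(!ind)
    ts <- matrix(0, length(idx), J)
    for (j in seq_len(J)) {
      ts[, j] <- gbj_invert_rank(t_obs[pos[idx]], j, m, rho_p[idx], nodes, tol_t)
    }
    # crossing probability: mix the exact independent recursion over the factor
    gh <- gh_nodes(nodes)
    acc <- 0
    for (k in seq_along(gh$x)) {
      cs <- matrix(0, length(idx), J)
      for (j in seq_len(J)) {
        cs[, j] <- cond_exceed(ts[, j], 0, rho_p[idx], gh$x[k])
      }
      acc <- acc + gh$w[k] * noncross_prob(rowCummax(cs), m)
    }
    out[pos[idx]] <- 1 - acc
  }
  pmin(1, pmax(0, out))
}

#' P-value of the generalized Berk-Jones statistic
#'
#' Boundary inversion as in [bj_pvalue]; the crossing probability is evaluated
#' under the moment-matched one-factor count law (exact conditional
#' independence given the latent factor, integrated by Gauss-Hermite
#' quadrature). With an identity correlation matrix this agrees with
#' [bj_pvalue].
#'
#' @param t_obs observed GBJ statistic (nonnegative).
#' @param corr `m x m` correlation matrix of the Z vector.
#' @param nodes number of Gauss-Hermite nodes.
#' @return p-value in `[0, 1]`.
#' @export
gbj_pvalue <- function(t_obs, corr, nodes = 60) {
  stopifnot(all(t_obs >= 0))
  check_corr(corr)
  m <- nrow(corr)
  rho <- rep(effective_correlation(corr), length(t_obs))
  gbj_pvalue_vec(t_obs, m, rho, nodes)
}

# ---------------------------------------------------------------------------
# Comparison kernels: higher criticism, generalized higher criticism, minP.
# Non-default; retained for benchmarking against the BJ/GBJ defaults.
# ---------------------------------------------------------------------------

# factor-model count standard deviation at marginal exceedance prob c
ghc_count_sd <- function(c_, m, rho, nodes = 40) {
  t <- stats::qnorm(c_ / 2, lower.tail = FALSE)
  if (rho < 1e-12) return(sqrt(m * c_ * (1 - c_)))
  gh <- gh_nodes(nodes)
  q <- outer(t, gh$x, function(tt, w) cond_exceed(tt, 0, rho, w))
  pair <- drop(q^2 %*% gh$w)   # P(two fixed coordinates both exceed)
  v <- m * c_ * (1 - c_) + m * (m - 1) * (pair - c_^2)
  sqrt(pmax(v, 1e-12))
}

#' Higher criticism, generalized higher criticism and minimum-p statistics
#'
#' Comparison kernels for graph-level signal integration. `HC` is the
#' standard higher-criticism supremum over ranks `j <= m/2`; `GHC` replaces
#' the binomial count standard deviation with the moment-matched correlated
#' one; `minP` is the minimum two-sided p-value, with p-value
#' `1 - (1 - p_min)^m` under independence or its factor-model analogue under
#' correlation. GHC and minP under correlation can be anticonservative for
#' one-sided nulls; BJ/GBJ are the defaults in the pipelines.
#'
#' @param z numeric vector of path Z statistics.
#' @param which one of `"HC"`, `"GHC"`, `"minP"`.
#' @param corr optional correlation matrix (required for `GHC`).
#' @param nodes number of Gauss-Hermite nodes used under correlation.
#' @return list with elements `statistic` and `p.value`.
#' @export
hc_ghc_minp <- function(z, which = c("HC", "GHC", "minP"), corr = NULL,
                        nodes = 60) {
  which <- match.arg(which)
  m <- length(z)
  stopifnot(m >= 1, all(is.finite(z)))
  check_corr(corr)
  if (!is.null(corr)) stopifnot(nrow(corr) == m)
  if (which == "GHC" && is.null(corr)) {
    stop("GHC requires a correlation matrix", call. = FALSE)
  }
  rho <- if (is.null(corr)) 0 else effective_correlation(corr)
  pv <- sort(pmax(2 * stats::pnorm(-abs(z)), PVAL_FLOOR))
  if (which == "minP") {
    pmin_ <- pv[1]
    if (rho < 1e-12) {
      pval <- 1 - (1 - pmin_)^m
    } else {
      gh <- gh_nodes(nodes)
      t1 <- stats::qnorm(pmin_ / 2, lower.tail = FALSE)
      q <- cond_exceed(rep(t1, length(gh$x)), 0, rho, gh$x)
      pval <- 1 - sum(gh$w * (1 - q)^m)
    }
    return(list(statistic = pmin_, p.value = min(max(pval, 0), 1)))
  }
  J <- max(1L, m %/% 2L)
  js <- seq_len(J)
  stat_terms <- if (which == "HC") {
    sqrt(m) * (js / m - pv[js]) / sqrt(pv[js] * (1 - pv[js]))
  } else {
    (js - m * pv[js]) / ghc_count_sd(pv[js], m, rho, nodes)
  }
  h <- max(stat_terms)
  if (h <= 0) return(list(statistic = h, p.value = 1))
  # invert each rank term at level h to a p-scale boundary c_j < j/m
  cs <- numeric(J)
  for (j in js) {
    f <- function(c_) {
      if (which == "HC") {
        sqrt(m) * (j / m - c_) / sqrt(c_ * (1 - c_)) - h
      } else {
        (j - m * c_) / ghc_count_sd(c_, m, rho, nodes) - h
      }
    }
    # f is decreasing in c_; f(j/m) < 0. If even c -> 0 cannot reach h, the
    # rank never binds: put the boundary at 0 (never crossed).
    if (f(1e-305) < 0) {
      cs[j] <- 0
    } else {
      cs[j] <- stats::uniroot(f, c(1e-305, j / m - 1e-12), tol = 1e-14)$root
    }
  }
  cs <- cummax(cs)
  if (rho < 1e-12) {
    pval <- 1 - noncross_prob(matrix(cs, 1), m)
  } else {
    gh <- gh_nodes(nodes)
    ts <- stats::qnorm(cs / 2, lower.tail = FALSE)
    acc <- 0
    for (k in seq_along(gh$x)) {
      ck <- cond_exceed(ts, 0, rho, gh$x[k])
      ck[cs == 0] <- 0
      acc <- acc + gh$w[k] * noncross_prob(matrix(cummax(ck), 1), m)
    }
    pval <- 1 - acc
  }
  list(statistic = h, p.value = min(max(pval, 0), 1))
}
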