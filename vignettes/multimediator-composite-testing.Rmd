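---
title: "Genome-wide multimediator testing with the composite test"
author: "gwmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide multimediator testing with the composite test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A genome-wide mediation experiment asks, for each of thousands of candidate
mechanisms, whether an exposure $S$ (say, smoking status) influences an
outcome $Y^i$ (expression of gene $i$) *through* a block of intermediate
variables $M^i = (M^{i1}, \dots, M^{im_i})$ (methylation probes mapped to
that gene). Each mechanism is a causal graph with two linear models,

$$
M^i = \alpha_S^i S + \alpha_X^i{}^\top X + \epsilon_m,\quad
\epsilon_m \sim \mathrm{MVN}(0, \Sigma_m),
$$
$$
Y^i = \beta_S^i S + \beta_M^i{}^\top M^i + \beta_X^i{}^\top X + \epsilon_y,
\quad \epsilon_y \sim N(0, \sigma_y^2),
$$

fit by ordinary least squares with intercepts (real data are not centered;
the displayed equations omit the intercepts only for brevity). A mediation
effect exists only when **both** $\alpha_S$ and $\beta_M$ are nonzero, so the
null is the *composite* union
$H_0: \alpha_S = 0 \cup \beta_M = 0$ — a mixture of three simple nulls
(both zero; $\alpha$ only; $\beta$ only) with unknown proportions. Standard
tests are conservative under this null: Sobel's normality-based test because
the product $\hat\alpha\hat\beta$ concentrates at zero when the complete
null dominates, the joint-significance test because it is an
intersection-union test. After false-discovery-rate correction that
conservatism destroys power in sparse genome-wide settings.

## The composite test

Let $a$ and $b$ be the standardized (Wald) statistics of $\hat\alpha_S$ and
$\hat\beta_M$ for one path. Under the respective simple nulls each is
asymptotically standard normal, and under no-unmeasured-confounding
assumptions they are independent. The three path-level p-values are

* Sobel: $p_N = 2\Phi\!\left(-|ab|/\sqrt{a^2+b^2}\right)$;
* joint significance: $p_{JS} = 2\max\{\Phi(-|a|), \Phi(-|b|)\}$;
* composite: with $F(z) = P(|Z_1 Z_2| \ge |z|)$ the tail of the standard
  normal product distribution (density $K_0(|x|)/\pi$),
  $$
  p_{comp} = F\!\left(\tfrac{ab}{\sqrt{\widehat{\mathrm{Var}}(a)}}\right)
           + F\!\left(\tfrac{ab}{\sqrt{\widehat{\mathrm{Var}}(b)}}\right)
           - F(ab).
  $$

The genome-wide variances $\widehat{\mathrm{Var}}(a)$,
$\widehat{\mathrm{Var}}(b)$ absorb the unknown mixture of simple nulls: they
can only be estimated on a large collection of analogous tests (all paths of
an experiment), which is why the composite test is a genome-scale method.
Two readings of the variance scaling are typographically possible; we adopt
division of the product by the *square root* of the variance, i.e.
$F(\cdot; v)$ is the tail of the product of $N(0, v)$ and $N(0, 1)$
variables. Under this reading the three terms collapse to $F(ab)$ at
$v = 1$ and the path-level p-values are uniform under the complete null —
both properties are asserted in the test suite; the alternative reading
(dividing by the variance itself) over-corrects and fails null uniformity
whenever the estimates exceed 1.

Numerical choices: $F$ is computed by adaptive quadrature of the Bessel
density (absolute error below $10^{-10}$, exponentially scaled for large
arguments), and genome-scale calls interpolate a 3000-point log-spaced grid
with a monotone Hermite spline (absolute error below $10^{-8}$, verified
against quadrature in the tests). P-values are floored at $10^{-300}$ before
any quantile transform. A path with $a = b = 0$ gets $p = 1$ by the limit
convention. Variance estimates are floored at 1, their value under a
dominant complete null, so sampling noise can never make the test
anti-conservative through a variance below 1.

### Variance estimation under alternatives

The default estimator is the sample variance of the pooled statistics,
estimated **once per experiment** (path-level pool for the decorrelation
approach, graph-level pool for the multivariate approach). Under a complete
null this is the right scale. Under alternatives with strongly active
graphs, however, the plain variance is contaminated by the active tail —
in the diverse-signal study regime we measured pooled variances near 76
where the null component has variance near 1, which crushes power precisely
for the approach that concentrates signal into few large statistics. The
composite test's variance is meant to capture the *null-mixture* scale, so
`power_study()` defaults to the robust $(1.4826\,\mathrm{MAD})^2$ estimator,
which ignores a minority of strong alternatives; calibration studies keep
the plain estimator (nothing to contaminate under the null). Both are
available everywhere via `robust_var`.

## Integrating paths within a graph

### Decorrelation approach

Within a graph the $m_i$ estimators are correlated because the mediators
are. The decorrelation approach eigendecomposes the mediator-model residual
covariance $\hat\Sigma_m = V \Lambda V^\top$ and replaces $M^i$ with
$P^i = M^i V$ (rows of the transform $u = V^\top$). Because all mediators
share one design matrix, the residualized crossproduct satisfies
$\tilde M^\top \tilde M = (n - q - 2)\, \hat\Sigma_m$ *exactly*, so after
the transform both the mediator-model and the outcome-model coefficient
covariances are exactly diagonal in sample — the refit on $P$ is carried
out algebraically, and the package asserts equality with an explicit `lm()`
refit to $10^{-15}$. Components with eigenvalue below
`drop_tol` $\times\ \lambda_{\max}$ (default $10^{-8}$, i.e. essentially
only numerically null dimensions) are dropped; eigenvector signs are fixed
so the largest-magnitude component is positive (labeling only). Path
p-values ($p_{comp}$ by default) are transformed to folded normal scores
$Z = \Phi^{-1}(1 - p/2)$ and integrated per graph by the Berk–Jones
statistic

$$
T_{BJ} = \max_{1 \le j \le m/2}
  \log \frac{\Pr\{S(|Z|_{(m-j+1)}) = j \mid E Z = \hat\mu_{j,m}\}}
            {\Pr\{S(|Z|_{(m-j+1)}) = j \mid E Z = 0\}}
  \cdot I\{2\bar\Phi(|Z|_{(m-j+1)}) < j/m\},
$$

where $S(t)$ counts paths with $|Z| \ge t$ (binomial under independence)
and $\hat\mu_{j,m} > 0$ solves
$j/m = \bar\Phi(t - \mu) + \Phi(-t - \mu)$ at $t = |Z|_{(m-j+1)}$. Since
$\hat\mu$ matches the observed exceedance fraction by construction, the
numerator success probability is exactly $j/m$ — the statistic needs no
root-finding, although `mu_hat()` is exported (and used under correlation).
Ties in $|Z|$ keep stable original order; an exact tie on the indicator
boundary is excluded (strict inequality). For $m = 1$ the statistic is
$|Z|$ itself with the two-sided normal p-value.

The BJ p-value inverts each rank term (bisection on the binomial
log-likelihood ratio, which is monotone; tolerance near machine precision)
into an order-statistic boundary and evaluates the exact $O(m^2)$
recursion for the probability that uniform order statistics cross it. The
recursion is exact for independent paths — which the decorrelation step
guarantees.

### Multivariate approach

Alternatively, the correlated coefficient vectors are integrated first:
$T_\alpha = \mathrm{GBJ}(Z_\alpha, \Sigma_\alpha)$ and
$T_\beta = \mathrm{GBJ}(Z_\beta, \Sigma_\beta)$, where $\Sigma_\alpha$ is
the residual correlation (shared design) and $\Sigma_\beta$ the correlation
of the $\hat\beta_M$ block of the outcome-model coefficient covariance. The
generalized Berk–Jones statistic replaces the binomial count law with a
correlated one. We model the count $S(t)$ by a **one-factor Gaussian
working model**: $Z_j = \mu + \sqrt{\rho_{\mathrm{eff}}} W +
\sqrt{1 - \rho_{\mathrm{eff}}}\,\varepsilon_j$, under which the count is a
binomial mixture over the latent factor, integrated by Gauss–Hermite
quadrature (60 nodes for scalar calls, 32 in the genome pipeline). The
effective correlation $\rho_{\mathrm{eff}}$ is the root mean square of the
off-diagonal correlations: exact for exchangeable matrices (the simulation
regime), correct to second order in the correlations otherwise (exceedance
covariances of $|Z|$ are quadratic in the pairwise correlation near zero),
and invariant to coordinate sign flips. The shifted mean $\hat\mu_{j,m}$
keeps its marginal definition, matching the cited construction of the
statistic. With an identity correlation the GBJ statistic and p-value
reduce *exactly* to BJ (asserted to $10^{-8}$). The GBJ p-value mixes the
exact independent crossing recursion over the factor — exact under
exchangeable correlation, an approximation otherwise; both the count pmf
and small-$m$ crossing probabilities are held to million-replicate
Monte-Carlo oracles in the tests.

A consequence worth stating: with an accurately computed GBJ p-value the
multivariate pipeline is calibrated close to the nominal level under the
complete null (about 0.0096–0.0098 at the 1% level in the bundled
genome-scale checks), whereas published approximations of this p-value are
known to be somewhat conservative; users comparing against such
implementations should expect our rejection rates to sit nearer nominal.

Graph-level scores are then
$a^i = \mathrm{sign}(\hat\alpha_S^i)\,\Phi^{-1}(1 - p_\alpha^i/2)$ (same
for $b^i$), with the collective sign $1 - 2I(\sum_j \hat\theta_j < 0)$
(an exactly zero sum maps to $+1$, the printed strict indicator), and the
composite test is applied at graph level with variances pooled over the
$g$ graphs.

### Hybrid

The Cauchy combination
$T = w_1 \tan\{(0.5 - p_{decor})\pi\} + w_2 \tan\{(0.5 - p_{multi})\pi\}$,
$p = \tfrac12 - \arctan\{T/(w_1 + w_2)\}/\pi$, combines the two dependent
p-values without estimating their dependence. Default weights are equal
(no prior knowledge assumed); inputs are clamped to
$[10^{-15}, 1 - 10^{-15}]$. The decorrelation approach favors
direction-consistent signals (they concentrate in the leading
decorrelated components), the multivariate approach favors diverse or
dense signals; the hybrid tracks the better arm at a bounded cost.

### Comparison kernels

`hc_ghc_minp()` provides higher criticism (Donoho–Jin form over
$j \le m/2$), a generalized HC using the factor-model count variance, and
minP ($1 - (1 - p_{\min})^m$ under independence, factor-model analogue
under correlation). They are benchmarking kernels, not defaults: under
one-sided nulls with correlated mediators GHC and minP can be
anti-conservative, and the pipelines warn when they are selected.

## The simulation engine

`simulation_config()` defaults encode the study conditions: $n = 1000$
individuals, $g = 10000$ mechanisms, $m = 30$ mediators with exchangeable
residual correlation $\rho = 0.3$, two standard normal covariates, unit
nuisance coefficients ($\beta_S = \alpha_X = \beta_X = 1$), 10% active
mechanisms with $h$ active paths whose coefficients follow
$N(\mu, v)$ ($v$ a variance; consistent pattern $\mu=0.05, v=0$, diverse
$\mu=0, v=0.1$, mixed $\mu=0.05, v=0.1$). Null scenarios: complete (all
zero), one-sided (each affected graph has only $\alpha$ or only $\beta$
signals, side chosen by a fair seeded coin — the alternative's signal law
with one side zeroed), and disjoint ($\alpha$ and $\beta$ on disjoint path
subsets; treated as an alternative by both approaches when mediators are
correlated, and flagged, not special-cased).

Generation is deterministic given the seed and organized in fixed chunks of
500 graphs with derived sub-seeds, so `simulate_scan()` can run a full
genome-scale experiment in bounded memory while reproducing exactly the
experiment `generate_experiment()` would materialize (asserted in the
tests). Active graphs and paths are chosen by seeded sampling without
replacement; the active fraction is exact whenever $g \cdot$`prop_active`
is integral.

What the generator emulates: the linear-Gaussian structure, exchangeable
within-graph residual correlation, sparse signal placement, and
genome-scale multiplicity. What it does not: non-Gaussian noise, binary or
survival outcomes, exposure–mediator interactions, measurement error,
between-graph sharing of mediators, or realistic methylation marginals.
Passing calibration here shows the machinery is correct under the model's
own assumptions, not that real methylation data satisfy them.

## Study sizes used by the bundled checks

The acceptance script analyzes one complete-null experiment per correlation
setting at the full $n = 1000$, $g = 10^4$, $m = 30$ (rejection
proportions at the 1% and 0.1% levels; binomial SE $\approx 0.001$ at the
1% level). The power-ordering check uses $g = 4000$ graphs (400 active),
$h = 2$, all three signal patterns at the 1% level — large enough to
resolve the orderings among the composite, joint-significance and Sobel
tests at three-standard-error separation while keeping the whole suite
comfortably inside a half-hour on one CPU. Million-replicate Monte-Carlo oracles back
the set-statistic p-values at $m \le 6$; smaller fixed-seed replications
back the distributional property tests.

## Known limitations

* The factor-model count law is exact only for exchangeable correlation;
  for strongly non-exchangeable matrices the GBJ p-value is an
  approximation (guarded by Monte-Carlo oracles at small $m$).
* The composite test's calibration rests on genome-scale variance pooling;
  experiments with fewer than ~100 paths are refused by default
  (`min_pool`).
* Estimated decorrelation introduces $O(m/n)$ scale noise into the path
  statistics; the genome-wide variance estimates absorb it (measured
  calibration at $g = 10^4$ is within Monte-Carlo error of nominal), but
  for $m$ approaching $n$ the OLS machinery itself breaks down and fits
  are refused.
* Binary outcomes, survival outcomes and exposure–mediator interactions
  are out of scope; the models are linear-Gaussian throughout.
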