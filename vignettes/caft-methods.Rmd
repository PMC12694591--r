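---
title: "Compositional AFT models for microbiome differential abundance"
author: "caft package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional AFT models for microbiome differential abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caft)
```

## The problem

Microbiome count tables are compositional (the library size $N_i$ of
sample $i$ reflects PCR and sequencing efficiency, not microbial load),
extremely sparse (often more than half the cells are zero), and each
taxon's counts carry an unknown multiplicative measurement bias. Methods
that log-transform relative abundances must do something about the zeros,
and the usual remedy -- adding a pseudocount -- does not scale with taxon
abundance and can manufacture associations when the zero pattern itself
correlates with the covariate of interest.

This package takes a different route: a zero count means the taxon's
relative abundance lies below the sample's detection limit $1/N_i$, so
the negative log relative abundance is *right-censored* at $\log N_i$.
Differential abundance analysis then becomes censored (survival-type)
regression, with no pseudocounts anywhere.

## The model

Write $C_{ij}$ for the count of taxon $j$ in sample $i$,
$N_i = \sum_j C_{ij}$, $\hat\pi_{ij} = C_{ij}/N_i$, and

$$\tau_{ij} = \begin{cases} -\log \hat\pi_{ij} & C_{ij} > 0\\
\log N_i & C_{ij} = 0 \end{cases}
\qquad
\Delta_i^{(j)} = 1\{C_{ij} > 0\}.$$

The censored log-linear (accelerated failure time) model is

$$\tau_{ij} = \gamma_j - X_{i\cdot}\beta_j + \alpha_i + \epsilon_{ij},$$

with $X$ an $N \times K$ covariate matrix that is column-centered and
contains no intercept (there is an explicit taxon intercept $\gamma_j$,
which also absorbs the taxon's multiplicative measurement bias), and
$\alpha_i$ a per-sample normalization term treated as a random effect.
Because $\alpha_i$ is shared by all taxa, it perturbs every taxon's
fitted coefficient the same way, so *differences* of coefficients across
taxa -- like odds ratios -- are free of both the normalization and the
per-taxon bias. All inference in this package is therefore about
$\beta_j$ relative to a compositional reference (below).

Note the sign convention: the response is the *negative* log relative
abundance, so on the $\tau$ scale a taxon that increases with a covariate
has a negative coefficient. `run_caft()` reports `beta.*` columns on the
$\tau$ scale and `effect.*` columns as sign-flipped differences from the
reference, so that positive effects mean enrichment.

## Estimation: the Gehan rank objective

With residuals $e_i(\beta) = \tau_i - X_{i\cdot}\beta$, the Gehan-type
score is

$$S(\beta) = \sum_i \left(R_{i+} - R_{+i}\right) X_{i\cdot}^T,
\qquad
R_{ii'} = \Delta_i\left[\tfrac12 1\{e_i < e_{i'}\} +
\tfrac12 1\{e_i \le e_{i'}\}\right],$$

a sum of covariate differences over ordered residual pairs whose smaller
member is uncensored. $S$ is the (sub)gradient of the non-negative convex
piecewise-linear objective

$$G(\beta) = \sum_{i:\,\Delta_i = 1}\ \sum_{i'} \max\{0,\ e_{i'} - e_i\},$$

so estimation is a deterministic convex minimization. Ties contribute
one half to the score indicator and zero to the objective. This estimator
was selected for its good behavior at the very high censoring fractions
(60--90% zeros) typical of microbiome data; Buckley--James-type
least-squares analogues are avoided because their estimating equations
can have multiple roots.

### The solver

$G$ is piecewise linear, so gradient methods stall on kinks. Along any
line $\beta + t v$ the objective is a one-dimensional piecewise-linear
convex function whose derivative jumps by $|c_p|$ at kinks
$t_p = d_p / c_p$ (one per contributing residual pair); its exact
minimizer is found by a weighted-median scan over the sorted kinks in
$O(P \log P)$. The fitting routine is:

* $K = 1$ (and every restricted fit with one free nuisance coordinate):
  a single exact scan -- no iteration at all;
* $K \ge 2$: deterministic sweeps of exact line searches over the
  coordinate directions plus the pairwise diagonals, followed by a
  Nelder--Mead polish and one final sweep. Starting point is
  $\beta = 0$; there is no randomness anywhere in estimation.

When the minimizing set along a line is a flat interval the midpoint is
reported (this matters because the compositional reference is a median
over taxa of such estimates); a direction along which $G$ is flat to
infinity is flagged and the fit marked non-converged. Convergence is
declared when a sweep improves the objective by less than
$10^{-10}(1+G)$ and moves the parameters by less than $10^{-8}$
(`gehan_control()`).

The per-pair computations are $O(N^2)$ dense and implemented in C++;
at the sample sizes these models are used at (tens to a few thousand
samples) this is faster and simpler than the sparse bookkeeping an
$O(N \log N)$ scheme would need.

If an intercept estimate is wanted, `estimate_intercept_km()` returns the
median of the Kaplan--Meier curve of the residuals (the smallest residual
where the product-limit survival function reaches 0.5); under censoring
so heavy that the curve never gets there it returns `NA` rather than
failing.

## Inference: restricted score tests

Wald tests would require differentiating the step function $S$; instead,
tests of $H_0: \Gamma \beta_j = b$ ($\Gamma$ of full row rank $d$) are
score tests evaluated at the restricted estimate. With $\Lambda$ an
orthonormal basis of the null space of $\Gamma$ (computed by SVD with a
fixed sign convention), the restricted fit minimizes $G$ over
$\beta = \Gamma^- b + \Lambda^- \lambda$ -- still convex because the map
is affine. The variance of the score is estimated by the rank estimator

$$\hat V = \hat\sigma^2 (X - \bar X)^T (X - \bar X),
\qquad
\hat\sigma^2 = \frac1N \sum_i \left(R_{i+} - R_{+i}\right)^2,$$

which is the permutation variance of $\sum_i a_i X_{i\cdot}$ with
$a_i = R_{i+} - R_{+i}$ held fixed, and the statistic is

$$T = S_\gamma^T\left[\hat V_{\gamma\gamma} -
\hat V_{\gamma\lambda}\hat V_{\lambda\lambda}^{-}
\hat V_{\lambda\gamma}\right]^{-1} S_\gamma,
\qquad S_\gamma = \Gamma S,$$

referred to $\chi^2_d$. When the null is simple ($\Lambda$ empty) this is
$S^T \hat V^{-1} S$. The scaling was validated by simulation: under
null data from the censored log-linear model the empirical distribution
of $T$ is indistinguishable from $\chi^2_1$ (Kolmogorov--Smirnov) and the
type I error at $\alpha = 0.05$ sits within Monte-Carlo error of 0.05;
this calibration check is part of the test suite, and a dimensional
argument gives the same answer (both $S$ under $H_0$ and $\hat V^{1/2}$
are of order $N^{3/2}$, so no extra $1/N$ factor belongs in $T$).

A martingale-based ("Cox") variance estimator for the same score exists
in the survival literature; the rank estimator above is this package's
default and only implementation (`cox_variance()` is a documented stub),
as it is simpler and better behaved at high censoring.

## The compositional reference

Only coefficient differences are interpretable, so each taxon is tested
against a reference that stands in for a "null taxon". Assuming fewer
than half the taxa are truly associated, the median over taxa of the
unrestricted estimates, $\tilde\beta^{(m)}$, estimates the null value;
each taxon is then tested with $b = \Gamma\tilde\beta^{(m)}$. For $d = 1$
this is the ordinary sample median (even counts: mean of the two central
order statistics); for $d \ge 2$ it is the affine-equivariant spatial
median computed by a transformation--retransformation iteration (Tyler
shape about the current center, Weiszfeld spatial median of the whitened
cloud, retransform; tolerance $10^{-8}$, at most 500 outer iterations,
componentwise-median fallback with a warning). The median is taken over
the *interest* components only -- those are the only components entering
$b$ -- and over taxa whose unrestricted fits converged, since failed fits
carry no information and would poison the reference.

The reference is treated as **fixed** in every test. That is justified
when many taxa contribute; below 50 contributing taxa the package warns.
A modal (rather than median) reference is a reasonable alternative used
by related methods; it is not implemented here, and the `caft_control()`
surface reserves no behavior for it beyond the rank-median default.

## The pipeline

`run_caft()` chains: library-size filter (default: samples with depth
below 3000 removed; the boundary sample at exactly 3000 is kept, with a
`library_boundary = "drop"` switch), prevalence filter (default: taxa
present in fewer than 10% of samples removed; the simulation protocol in
this package uses 6%), covariate encoding (binary factors to 0/1 by
sorted level order -- logged, because the coefficient sign depends on
it) and centering, per-taxon unrestricted fits, the reference median,
per-taxon restricted score tests, and Benjamini--Hochberg adjustment
(failed taxa carry `NA` p-values and are excluded from the BH
denominator by default; `na_in_m = TRUE` counts them). Library sizes are
computed *before* taxon filtering and deliberately not recomputed
afterwards: the censoring bound $\log N_i$ is the sequencing depth, a
property of the sample, not of the post-filter subtotal
(`recompute_library = TRUE` restores the naive behavior). Filters are
applied samples-first by default; `filter_order = "taxa_first"` reverses
them reproducibly.

## The community simulator

`simulate_study()` generates ground-truthed studies for validating
operating characteristics:

* **Baseline composition** `make_baseline()`: $\pi^0 \propto \exp(Z)$,
  sorted decreasing, with $Z$ a deterministic geometric rank decay plus
  i.i.d. Gaussian jitter, both scaled by `heavy_tail_sd`. A pure i.i.d.
  log-normal baseline spread wide enough to reach realistic sparsity
  concentrates 60--97% of the community in a single taxon in most seeds
  -- no real 16S template looks like that and the resulting communities
  have almost no analyzable taxa -- hence the stabilized profile. The
  defaults (`heavy_tail_sd = 1`, `profile_span = 44`) were fixed once so
  that default studies land in the 80--90% zero-cell range typical of
  16S feature tables (realized: about 84%, top-taxon share about 0.27,
  roughly 70 of 300 taxa surviving a 6% prevalence filter at $n = 100$).
* **Design**: two binary covariates balanced over the four cells of
  $\{0,1\}^2$ (exactly $n/4$ each), row order randomized.
* **Effects and bias**: per-sample compositions
  $\tilde\pi_{ij} \propto \omega_j^b\,
  e^{\beta_{j1}x_{i1} + \beta_{j2}x_{i2} + \epsilon_{ij}}\ \pi^0_j$,
  with bias factors $\omega_j \sim U(2, 10)$ redrawn each replicate,
  bias exponent $b \in \{0, 1, 2\}$, and biological noise
  $\epsilon_{ij} \sim N(0, \texttt{dispersion\_sd}^2)$,
  `dispersion_sd = 1` by default. The dispersion term *is* the residual
  of the censored log-linear model: without it, abundant taxa would have
  essentially noise-free responses, their coefficient standard errors
  would collapse toward zero, and any estimation error in the fixed
  median reference would produce arbitrarily large score statistics --
  data that neither the model above nor real communities produce. A
  log-scale SD of 1 is a typical magnitude for between-sample variation
  of a taxon's relative abundance in 16S data.
* **Causal taxa**: `n_causal` ($m \ge 10$) drawn from the 50 most
  abundant baseline taxa; 5 associated with both covariates, 5 with
  $x_2$ only, the remaining $m - 10$ with $x_1$ only; all
  $x_1$-associated taxa share `beta1` and all $x_2$-associated taxa
  share `beta2`. A custom `beta_matrix` overrides the assignment.
* **Counts**: library sizes resampled from a pool (default log-uniform
  3000..50000, respecting the 3000-depth filter floor), then exact
  multinomial draws by sequential conditional-binomial inversion from a
  uniform matrix drawn *before* any counts. Because every latent draw
  (baseline, design, $\omega$, depths, dispersion, count uniforms)
  happens in a fixed order before count generation, two studies with the
  same seed that differ only in `bias_exponent` are coupled cell by cell
  (common random numbers), which is what paired bias-robustness
  comparisons need. The marginal law of each study is unchanged.

What the simulator does **not** emulate: taxon--taxon correlation
(counts are conditionally independent given the composition and depth;
copula-based correlation machinery is a fidelity upgrade, not a
correctness requirement for marginal per-taxon tests), longitudinal
designs, and template-estimated baselines -- though `baseline` and
`library_size_pool` accept user-supplied values estimated from real
data. Passing tests on this generator therefore demonstrate correct
behavior under realistic sparsity, bias, and marginal dispersion, not
under strong inter-taxon dependence.

## Simulation protocol and problem sizes

The package's own operating-characteristic checks (test suite and
`scripts/acceptance.R`) use a scaled-down version of a standard
benchmarking design: 50 replicates of $n = 100$ samples, $J = 300$ taxa,
$m = 10$ causal, $\beta_1 = \beta_2 = 1$, no bias, 6% prevalence filter,
testing $x_1$ adjusted for $x_2$. Reported are the average fraction of
truly $x_1$-null analyzed taxa with $p \le 0.05$ (type I error) and the
average false-discovery proportion among BH detections at target 0.05.
Fifty replicates keep the full check under a few minutes on one core
while still giving Monte-Carlo standard errors of about 0.003 on the
type I error. Null calibration of the score statistic itself is checked
separately with 1000 single-taxon replicates at $n = 100$.

## Numerical choices and edge cases

* Ties in residuals: half weight in the score, zero in the objective.
* Moore--Penrose inverses via SVD, relative tolerance $10^{-12}$;
  ill-conditioned nuisance variance blocks (condition number beyond
  $10^{10}$) trigger a warning.
* A taxon with no uncensored observation raises a typed
  `caft_not_estimable` error (the pipeline records `NA` and moves on).
* An exactly zero interest score gives $T = 0$, $p = 1$, even when the
  variance is degenerate.
* A singular Schur complement yields an `NA` p-value rather than a
  crash; such taxa are excluded from the BH denominator by default.
* Comparison boundaries are pinned by tests: depth filter keeps a sample
  at exactly the threshold, prevalence filter keeps a taxon at exactly
  the threshold fraction.

## Known limitations

* The fixed-reference simplification understates variability when few
  taxa are analyzed (warning below 50); with very few taxa, or at high
  taxonomic levels where many taxa are truly associated, the
  median-is-null assumption itself can fail.
* Paired runs of the simulator under different bias exponents share all
  latent structure, but re-drawn counts under a 4--100$\times$
  per-taxon reweighting necessarily change presence patterns; paired
  per-taxon p-values therefore correlate strongly (Spearman around 0.8)
  but not perfectly, even though the *operating characteristics* (type
  I error, FDR) are indistinguishable between bias settings.
* Inference is asymptotic in the number of samples; with very few
  uncensored observations per taxon the $\chi^2$ calibration degrades
  (the prevalence filter exists precisely to remove such taxa).

## A worked micro-example

Two samples, one uncensored pair, one centered binary covariate:
residuals $e = (0, 1)$, $\Delta = (1, 1)$, $X = (-0.5, 0.5)^T$ give
$S = -1$, $\hat\sigma^2 = 1$, $\hat V = 0.5$, and $T = (-1)^2/0.5 = 2$
on one degree of freedom:

```{r micro}
tx <- structure(list(tau = c(0, 1), delta = c(1L, 1L),
                     taxon_id = "t", n_present = 2L),
                class = "caft_censored")
X <- matrix(c(-0.5, 0.5), 2, 1, dimnames = list(NULL, "x"))
st <- score_test(tx, design_matrix(X), contrast_spec(1, b = 0))
c(score = unname(st$score), sigma2 = st$sigma2,
  stat = st$statistic, df = st$df)
```

## A small end-to-end run

```{r pipeline}
sim <- simulate_study(n_samples = 100, n_taxa = 200, n_causal = 10,
                      beta1 = 2, seed = 11)
res <- run_caft(sim$table, sim$metadata, interest = "x1", adjust = "x2",
                control = caft_control(min_presence_frac = 0.06),
                verbose = FALSE)
res
head(res$results[order(res$results$pvalue),
                 c("taxon_id", "effect.x1", "stat", "pvalue", "qvalue")])
```
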