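# caft

Compositional differential abundance analysis for microbiome count
tables, treating zero counts as censored observations.

## The problem and the approach

Microbiome feature tables are compositional (total read counts reflect
technical efficiency, not microbial load), extremely sparse, and subject
to unknown multiplicative per-taxon measurement bias. Log-linear
compositional models need something to do with the zeros, and
pseudocounts — the common fix — do not scale with taxon abundance and can
create spurious associations.

`caft` instead reads a zero count as "relative abundance below the
detection limit 1/N_i" and treats the negative log relative abundance

    tau_ij = -log(C_ij / N_i)   if C_ij > 0,   censored at log N_i otherwise

as a right-censored response in an accelerated failure time (AFT) model

    tau_ij = gamma_j - X_i beta_j + alpha_i + eps_ij ,

with centered covariates `X` (no intercept column), a taxon intercept
`gamma_j` that absorbs the taxon's multiplicative bias, and a per-sample
normalization `alpha_i` shared by all taxa. Per taxon, `beta_j` is
estimated by minimizing the convex piecewise-linear Gehan rank objective

    G(beta) = sum over pairs with Delta_i = 1 of max(0, e_i'(beta) - e_i(beta)) ,

whose subgradient is the Gehan score `S(beta) = sum_i (R_i+ - R_+i) X_i`.
Each taxon is then tested against a compositional reference — the
(spatial) median of the per-taxon estimates, a null value under the
assumption that fewer than half the taxa are truly associated — with a
restricted score test

    T = S_g' [ V_gg - V_gl V_ll^- V_lg ]^(-1) S_g   ~   chi-square(d),

where `V = sigma2 * (X - Xbar)'(X - Xbar)` is a rank-based variance
estimator with `sigma2 = (1/N) sum_i (R_i+ - R_+i)^2`. Benjamini–Hochberg
controls the FDR across taxa. A ground-truthed community simulator
(sparse heavy-tailed compositions, multiplicative bias factors,
multiplicative covariate effects, multinomial counts at resampled
depths) is included so every operating characteristic is testable
without any external data.

## Worked example

Simulate a 100-sample, 200-taxon study with 10 causal taxa (effect size
2 on the log relative abundance scale for the x1-associated ones), then
test `x1` adjusted for `x2`:

```r
library(caft)
sim <- simulate_study(n_samples = 100, n_taxa = 200, n_causal = 10,
                      beta1 = 2, seed = 11)
res <- run_caft(sim$table, sim$metadata, interest = "x1", adjust = "x2",
                control = caft_control(min_presence_frac = 0.06),
                verbose = FALSE)
res
#> CAFT analysis: 100 samples, 50 taxa (zero fraction 27.4%)
#> reference (median of interest coefficients): x1 = 0.0811
#> 5 / 50 taxa detected at FDR 0.05
head(res$results[order(res$results$pvalue),
                 c("taxon_id", "effect.x1", "stat", "pvalue", "qvalue")], 5)
#>    taxon_id effect.x1      stat       pvalue       qvalue
#> 22  taxon22 1.8689830 40.542982 1.923381e-10 9.616905e-09
#> 34  taxon34 1.6673328 34.725792 3.795693e-09 9.489233e-08
#> 41  taxon41 1.5335011 30.819482 2.831806e-08 4.719676e-07
#> 40  taxon40 1.6817326 27.275373 1.764445e-07 2.205556e-06
#> 48  taxon49 1.0571683 12.355911 4.395923e-04 4.395923e-03
sim$truth$causal_x1
#> [1] "taxon22" "taxon34" "taxon40" "taxon41" "taxon49"
```

The five detections are exactly the five truly x1-associated taxa that
survived the prevalence filter. `effect.x1` is the taxon's coefficient
relative to the compositional reference, oriented so positive values
mean higher relative abundance with increasing covariate; the recovered
effects sit near the simulated value 2, attenuated for the
lowest-abundance causal taxon. 200 simulated taxa reduce to 50 analyzed
ones here because the community is realistically sparse (about 84% zero
cells before filtering) and taxa present in fewer than 6% of samples
carry no testable signal.

Real data come in through `read_count_table()` (TSV/CSV, taxa as rows by
default, or BIOM) and `read_metadata()`; results go out through
`write_results()` (TSV plus a JSON sidecar recording filters, the
reference value and the seed). A thin command-line wrapper with `run`,
`simulate` and `benchmark` subcommands is installed at
`system.file("cli", "caft", package = "caft")`.

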