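#' Heavy-tailed baseline relative abundances
#'
#' Generates a synthetic baseline composition as normalized `exp(Z)`,
#' sorted in decreasing order, where `Z` combines a deterministic
#' geometric rank decay with i.i.d. Gaussian jitter:
#' `Z_j = heavy_tail_sd * (e_j - profile_span * (j-1)/(J-1))`,
#' `e_j ~ N(0, 1)`. The rank decay keeps the dominance structure stable
#' across seeds (a pure i.i.d. log-normal baseline occasionally puts over
#' 90% of the community into a single taxon, which no real 16S template
#' resembles), while the jitter varies the realized ranks. With
#' `heavy_tail_sd = 0` the composition is uniform. The defaults
#' (`heavy_tail_sd = 1`, `profile_span = 44`) were chosen once so that,
#' with the default library-size pool (log-uniform in 3000..50000), 300
#' taxa and the generator's default biological dispersion, simulated
#' tables land in the 80-90% zero-cell range typical of 16S feature
#' tables; the baseline is a stand-in for one estimated from a real
#' template dataset (see [simulate_study()]'s `baseline` argument).
#'
#' @param J number of taxa (>= 20).
#' @param heavy_tail_sd overall log-scale spread; scales both the rank
#'   profile and the jitter (0 gives the uniform composition).
#' @param profile_span log-abundance range of the deterministic rank decay
#'   at `heavy_tail_sd = 1`.
#' @param seed optional integer seed.
#' @return probability vector of length `J`, decreasing, summing to 1.
#' @export
make_baseline <- function(J, heavy_tail_sd = 1, profile_span = 44,
                          seed = NULL) {
  stopifnot(J >= 20, heavy_tail_sd >= 0, profile_span >= 0)
  with_seed(seed, {
    z <- heavy_tail_sd *
      (rnorm(J) - profile_span * (seq_len(J) - 1) / (J - 1))
    p <- exp(z - max(z))
    sort(p / sum(p), decreasing = TRUE)
  })
}

#' Balanced two-factor binary design
#'
#' Two binary covariates `x1`, `x2` with exactly `n/4` samples in each of
#' the four cells of `{0,1}^2` (so the covariates are exactly orthogonal);
#' row order is randomized under the seed.
#'
#' @param n number of samples, divisible by 4.
#' @param seed optional integer seed.
#' @return data frame with columns `sample_id`, `x1`, `x2`.
#' @export
design_matrix_balanced <- function(n, seed = NULL) {
  if (n %% 4 != 0) caft_stop("n must be divisible by 4", "caft_bad_input")
  cells <- expand.grid(x1 = c(0, 1), x2 = c(0, 1))
  df <- cells[rep(seq_len(4), each = n / 4), ]
  ord <- with_seed(seed, sample.int(n))
  df <- df[ord, ]
  data.frame(sample_id = paste0("sample", seq_len(n)),
             x1 = df$x1, x2 = df$x2, row.names = NULL)
}

#' Per-sample perturbed composition
#'
#' Applies taxon-specific multiplicative bias and multiplicative covariate
#' effects to a baseline composition:
#' `pi_tilde_j  proportional to  omega_j^b * exp(beta_j1 x1 + beta_j2 x2) * pi0_j`,
#' renormalized to sum to one. A bias factor shared by all taxa cancels
#' under the renormalization.
#'
#' @param pi0 baseline probability vector (length J).
#' @param omega positive bias factors (length J).
#' @param bias_exponent integer exponent `b` (0 disables bias).
#' @param beta_matrix J x 2 matrix of true effects on log relative
#'   abundance.
#' @param x_i length-2 covariate vector for the sample.
#' @return probability vector of length J.
#' @export
perturbed_abundance <- function(pi0, omega, bias_exponent, beta_matrix, x_i) {
  beta_matrix <- as.matrix(beta_matrix)
  stopifnot(length(omega) == length(pi0), nrow(beta_matrix) == length(pi0),
            ncol(beta_matrix) == 2, length(x_i) == 2)
  w <- omega^bias_exponent * exp(as.vector(beta_matrix %*% x_i)) * pi0
  w / sum(w)
}

# Exact multinomial draw by sequential conditional-binomial inversion:
# C_j | C_1..C_{j-1} ~ Binomial(size - sum_prev, p_j / p_rest), inverted
# through the supplied uniforms. Coupling studies through a shared uniform
# matrix makes paired simulations comparable cell by cell.
qmultinom_seq <- function(u, size, prob) {
  J <- length(prob)
  out <- integer(J)
  rem <- size
  prest <- 1
  for (j in seq_len(J - 1L)) {
    if (rem == 0L || prest <= 0) break
    pj <- min(max(prob[j] / prest, 0), 1)
    out[j] <- stats::qbinom(u[j], rem, pj)
    rem <- rem - out[j]
    prest <- prest - prob[j]
  }
  if (rem > 0L) out[J] <- rem
  out
}

#' Simulate a sparse two-covariate microbiome study
#'
#' Generates a synthetic community study with known ground truth: a
#' heavy-tailed baseline composition, per-replicate uniform bias factors
#' `omega_j ~ U(bias_range)`, a balanced binary design in `(x1, x2)`,
#' multiplicative covariate effects on relative abundance, library sizes
#' resampled with replacement from a pool, and multinomial counts per
#' sample. Causal taxa are drawn without replacement from the 50 most
#' abundant baseline taxa, split as 5 associated with both covariates, 5
#' with `x2` only, and `n_causal - 10` with `x1` only; all `x2`-associated
#' taxa get effect `beta2`, all `x1`-associated taxa effect `beta1`.
#' Setting `beta1 = 0` (or `beta2 = 0`) makes the corresponding causal set
#' empty in the returned truth, since causality is defined by a non-zero
#' effect.
#'
#' @param n_samples samples (divisible by 4).
#' @param n_taxa taxa J (>= 20).
#' @param n_causal number of designated causal taxa, between 10 and 50.
#' @param beta1,beta2 effect sizes on log relative abundance.
#' @param bias_exponent integer in `{0, 1, 2}`.
#' @param bias_range range of the uniform bias factors (default 2..10).
#' @param library_size_pool integer pool resampled with replacement; the
#'   default draws log-uniform depths in 3000..50000.
#' @param baseline optional baseline composition (else [make_baseline()]
#'   with `heavy_tail_sd`).
#' @param heavy_tail_sd passed to [make_baseline()]; the study-level
#'   default is tuned jointly with `dispersion_sd` so realized tables have
#'   80-90% zero cells.
#' @param dispersion_sd per-sample, per-taxon lognormal dispersion of the
#'   composition (log-scale SD): each sample's abundances are multiplied
#'   by `exp(N(0, dispersion_sd^2))` noise before renormalization. This is
#'   the residual term of the censored log-linear model; 0 gives
#'   conditionally multinomial counts with no biological variability.
#' @param beta_matrix optional J x 2 matrix of true effects, overriding the
#'   causal-taxon assignment entirely (rows follow the abundance-sorted
#'   taxon order; `n_causal`, `beta1`, `beta2` are then ignored and the
#'   truth is derived from the non-zero rows).
#' @param seed integer seed; the full study is reproducible from it.
#' @return list with `table` (a [count_table()]), `metadata` (data frame
#'   `sample_id`, `x1`, `x2`), and `truth` (class `caft_sim_truth`:
#'   `causal_x1`, `causal_x2`, `beta_matrix`, `omega`, `baseline`).
#' @export
simulate_study <- function(n_samples = 100, n_taxa = 300, n_causal = 10,
                           beta1 = 1, beta2 = 1, bias_exponent = 0,
                           bias_range = c(2, 10), library_size_pool = NULL,
                           baseline = NULL, heavy_tail_sd = 1,
                           dispersion_sd = 1, beta_matrix = NULL,
                           seed = NULL) {
  if (is.null(beta_matrix)) {
    if (n_causal > 50)
      caft_stop("at most 50 causal taxa (drawn from the top-50 abundant)",
                "caft_bad_input")
    if (n_causal < 10)
      caft_stop("the 5/5/(m-10) causal split needs n_causal >= 10",
                "caft_bad_input")
  }
  stopifnot(bias_exponent %in% 0:2)
  with_seed(seed, {
    J <- n_taxa
    pi0 <- if (is.null(baseline)) {
      make_baseline(J, heavy_tail_sd)
    } else {
      stopifnot(length(baseline) == J, all(baseline > 0))
      sort(baseline / sum(baseline), decreasing = TRUE)
    }
    taxon_ids <- paste0("taxon", seq_len(J))
    meta <- design_matrix_balanced(n_samples)
    omega <- runif(J, bias_range[1], bias_range[2])

    if (is.null(beta_matrix)) {
      top <- min(50L, J) # baseline is sorted: most abundant taxa come first
      if (n_causal > top)
        caft_stop("n_causal exceeds the abundant-taxon pool", "caft_bad_input")
      causal <- sample(seq_len(top), n_causal)
      both <- causal[1:5]
      x2_only <- causal[6:10]
      x1_only <- if (n_causal > 10) causal[11:n_causal] else integer(0)
      beta_matrix <- matrix(0, J, 2, dimnames = list(taxon_ids, c("x1", "x2")))
      beta_matrix[c(both, x1_only), 1] <- beta1
      beta_matrix[c(both, x2_only), 2] <- beta2
    } else {
      beta_matrix <- as.matrix(beta_matrix)
      stopifnot(nrow(beta_matrix) == J, ncol(beta_matrix) == 2)
      dimnames(beta_matrix) <- list(taxon_ids, c("x1", "x2"))
    }

    pool <- library_size_pool
    N <- if (is.null(pool)) {
      round(exp(runif(n_samples, log(3000), log(50000))))
    } else {
      # index the pool explicitly: sample(x, ...) on a length-1 pool would
      # expand to 1:x
      pool[sample.int(length(pool), n_samples, replace = TRUE)]
    }
    # All latent noise is drawn before any counts, in a fixed order, so two
    # studies simulated from the same seed but different bias settings share
    # their baseline, design, bias factors, depths, biological noise, and
    # count-level uniforms (common-random-number pairing). Counts are then a
    # deterministic transform, drawn by sequential conditional-binomial
    # inversion, which samples the exact multinomial law.
    eps_mat <- if (dispersion_sd > 0) {
      matrix(rnorm(n_samples * J, 0, dispersion_sd), n_samples, J)
    } else matrix(0, n_samples, J)
    u_mat <- matrix(runif(n_samples * J), n_samples, J)
    counts <- matrix(0L, n_samples, J,
                     dimnames = list(meta$sample_id, taxon_ids))
    for (i in seq_len(n_samples)) {
      # per-sample biological variability of the composition: the residual
      # term of the censored log-linear model, multiplicative on abundance
      pit <- perturbed_abundance(pi0 * exp(eps_mat[i, ]), omega,
                                 bias_exponent, beta_matrix,
                                 c(meta$x1[i], meta$x2[i]))
      counts[i, ] <- qmultinom_seq(u_mat[i, ], N[i], pit)
    }
    truth <- structure(list(
      causal_x1 = taxon_ids[which(beta_matrix[, 1] != 0)],
      causal_x2 = taxon_ids[which(beta_matrix[, 2] != 0)],
      beta_matrix = beta_matrix, omega = setNames(omega, taxon_ids),
      baseline = setNames(pi0, taxon_ids),
      bias_exponent = bias_exponent), class = "caft_sim_truth")
    list(table = count_table(counts, library_sizes = N),
         metadata = meta, truth = truth)
  })
}
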