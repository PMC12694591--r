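# Independent brute-force oracles and small-data generators used across the
# suite. These deliberately re-derive quantities from their defining double
# sums in plain R, independent of the package's computation path.

make_censored <- function(tau, delta, id = "t") {
  structure(list(tau = as.numeric(tau), delta = as.integer(delta),
                 taxon_id = id, n_present = sum(delta != 0)),
            class = "caft_censored")
}

# Gehan score as the explicit double sum over ordered pairs
brute_score <- function(beta, tau, delta, X) {
  X <- as.matrix(X)
  e <- as.vector(tau - X %*% beta)
  n <- length(tau)
  S <- numeric(ncol(X))
  for (i in seq_len(n)) {
    if (delta[i] == 0) next
    for (k in seq_len(n)) {
      I <- 0.5 * (e[i] < e[k]) + 0.5 * (e[i] <= e[k])
      S <- S + I * (X[i, ] - X[k, ])
    }
  }
  unname(S)
}

# Gehan objective as pair enumeration
brute_objective <- function(beta, tau, delta, X) {
  X <- as.matrix(X)
  e <- as.vector(tau - X %*% beta)
  n <- length(tau)
  g <- 0
  for (i in seq_len(n)) {
    if (delta[i] == 0) next
    for (k in seq_len(n)) g <- g + max(0, e[k] - e[i])
  }
  g
}

# random small censored-regression instance
random_instance <- function(n_max = 8, K = NULL) {
  n <- sample(3:n_max, 1)
  if (is.null(K)) K <- sample(1:2, 1)
  X <- matrix(rnorm(n * K), n, K)
  X <- scale(X, scale = FALSE)
  colnames(X) <- paste0("x", seq_len(K))
  # rounded responses induce ties with positive probability
  tau <- round(rnorm(n), 1)
  delta <- rbinom(n, 1, 0.7)
  if (all(delta == 0)) delta[sample(n, 1)] <- 1
  list(tau = tau, delta = delta, X = X, n = n, K = K)
}

# Data from the censored log-linear model: tau = gamma - X beta_model + eps,
# right-censored at the cens_q quantile. Note the model's sign convention:
# a positive beta_model lowers tau, so the regression coefficient on the
# tau scale (what the Gehan fit estimates) is -beta_model.
sim_aft <- function(n, beta_model, gamma = 1, cens_q = 0.6,
                    noise = function(n) rlogis(n) * 0.8,
                    binary = TRUE) {
  K <- length(beta_model)
  X <- if (binary) matrix(rbinom(n * K, 1, 0.5), n, K)
       else matrix(rnorm(n * K), n, K)
  X <- scale(X, scale = FALSE)
  colnames(X) <- paste0("x", seq_len(K))
  tau_star <- gamma - as.vector(X %*% beta_model) + noise(n)
  cmax <- as.numeric(quantile(tau_star, cens_q))
  delta <- as.integer(tau_star <= cmax)
  list(taxon = make_censored(pmin(tau_star, cmax), delta),
       X = X, design = design_matrix(X))
}

# Shared scaled-down simulation study (no-bias scenario), memoised so the
# type I error and FDR checks reuse one set of runs.
fig1_cache <- new.env(parent = emptyenv())
fig1_runs <- function(n_replicates = 50, seed = 1) {
  key <- paste0("r", n_replicates, "s", seed)
  if (!is.null(fig1_cache[[key]])) return(fig1_cache[[key]])
  perf <- caft_benchmark(n_replicates = n_replicates, seed = seed,
                         n_samples = 100, n_taxa = 300, n_causal = 10,
                         beta1 = 1, beta2 = 1, bias_exponent = 0,
                         control = caft_control(min_presence_frac = 0.06),
                         keep_runs = TRUE)
  fig1_cache[[key]] <- perf
  perf
}
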