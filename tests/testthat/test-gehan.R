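test_that("rank matrix follows the half-tie comparison rule", {
  R <- rank_matrix(c(0, 1), c(1, 1))
  expect_equal(R, matrix(c(0.5, 0, 1, 0.5), 2, 2))
  expect_equal(rowSums(R), c(1.5, 0.5))
  expect_equal(colSums(R), c(0.5, 1.5))
  # all ties, all observed: every entry one half
  expect_equal(rank_matrix(rep(2, 3), rep(1, 3)), matrix(0.5, 3, 3))
  # all censored: zero matrix
  expect_equal(rank_matrix(c(1, 2, 3), rep(0, 3)), matrix(0, 3, 3))
})

test_that("score and objective equal their brute-force double sums", {
  set.seed(101)
  for (r in 1:120) {
    inst <- random_instance()
    tx <- make_censored(inst$tau, inst$delta)
    beta <- rnorm(inst$K)
    expect_equal(gehan_score(beta, tx, inst$X),
                 brute_score(beta, inst$tau, inst$delta, inst$X))
    expect_equal(gehan_objective(beta, tx, inst$X),
                 brute_objective(beta, inst$tau, inst$delta, inst$X))
  }
})

test_that("two-point worked example pins score, objective, and sign", {
  tx <- make_censored(c(0, 1), c(1, 1))
  X <- matrix(c(-0.5, 0.5), 2, 1, dimnames = list(NULL, "x"))
  expect_equal(gehan_score(0, tx, X), -1)
  expect_equal(gehan_objective(0, tx, X), 1)
  # the row/column-sum form J = sum_i a_i e_i evaluates to -G here
  R <- rank_matrix(c(0, 1), c(1, 1))
  J <- sum((rowSums(R) - colSums(R)) * c(0, 1))
  expect_equal(J, -gehan_objective(0, tx, X))
})

test_that("objective is convex and its slope between kinks equals the score", {
  set.seed(17)
  for (r in 1:30) {
    inst <- random_instance(n_max = 7)
    tx <- make_censored(inst$tau, inst$delta)
    b1 <- rnorm(inst$K); b2 <- rnorm(inst$K); t <- runif(1)
    expect_lte(gehan_objective(t * b1 + (1 - t) * b2, tx, inst$X),
               t * gehan_objective(b1, tx, inst$X) +
                 (1 - t) * gehan_objective(b2, tx, inst$X) + 1e-10)
  }
  # finite-difference slope at a generic (almost surely non-kink) point
  set.seed(18)
  for (r in 1:20) {
    inst <- random_instance(n_max = 7, K = 1)
    tx <- make_censored(inst$tau + rnorm(inst$n) * 0.01, inst$delta)
    b0 <- rnorm(1); h <- 1e-7
    slope <- (gehan_objective(b0 + h, tx, inst$X) -
              gehan_objective(b0 - h, tx, inst$X)) / (2 * h)
    expect_equal(slope, gehan_score(b0, tx, inst$X), tolerance = 1e-5)
  }
})

test_that("score is invariant to the comparison-matrix diagonal and to
           constant column shifts", {
  set.seed(23)
  inst <- random_instance(n_max = 8, K = 2)
  tx <- make_censored(inst$tau, inst$delta)
  e <- inst$tau # residuals at beta = 0
  R <- rank_matrix(e, inst$delta)
  a <- rowSums(R) - colSums(R)
  R0 <- R; diag(R0) <- 0
  expect_equal(a, rowSums(R0) - colSums(R0))
  expect_equal(sum(a), 0)
  # therefore adding a constant to a covariate column leaves S unchanged
  Xs <- inst$X; Xs[, 1] <- Xs[, 1] + 3.7
  expect_equal(as.vector(crossprod(Xs, a)),
               as.vector(crossprod(inst$X, a)) + c(0, 0) + c(3.7 * sum(a), 0))
  expect_equal(gehan_score(c(0, 0), tx, inst$X),
               as.vector(crossprod(inst$X, a)))
})

test_that("without censoring a binary-covariate score at zero is the
           generalized Wilcoxon two-sample statistic", {
  set.seed(31)
  n <- 16
  g <- rbinom(n, 1, 0.5); g[1] <- 0; g[2] <- 1
  x <- g - mean(g)
  tau <- round(rnorm(n), 1)
  tx <- make_censored(tau, rep(1, n))
  S <- gehan_score(0, tx, matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  # direct two-sample pair count: cross-group pairs only (within-group
  # covariate differences vanish), ties counted half
  W <- 0
  for (i in which(g == 1)) for (k in which(g == 0)) {
    W <- W + (0.5 * (tau[i] < tau[k]) + 0.5 * (tau[i] <= tau[k])) -
         (0.5 * (tau[k] < tau[i]) + 0.5 * (tau[k] <= tau[i]))
  }
  expect_equal(S, unname(W))
})

test_that("one-covariate fit matches a grid-search minimizer", {
  set.seed(41)
  n <- 20
  x <- rbinom(n, 1, 0.5); x[1:2] <- c(0, 1)
  X <- matrix(x - mean(x), ncol = 1, dimnames = list(NULL, "x"))
  tau <- 1 + 0.8 * X[, 1] + rnorm(n)
  tx <- make_censored(tau, rep(1, n))
  fit <- fit_unrestricted(tx, design_matrix(X))
  grid <- seq(-3, 3, by = 1e-3)
  gv <- vapply(grid, function(b) gehan_objective(b, tx, X), numeric(1))
  expect_lte(fit$objective_value, min(gv) + 1e-8)
  # grid minimizers form a flat set; the reported estimate lies inside it
  flat <- range(grid[gv <= min(gv) + 1e-8])
  expect_gte(fit$beta_hat, flat[1] - 2e-3)
  expect_lte(fit$beta_hat, flat[2] + 2e-3)
})

test_that("coefficients are recovered from censored log-linear data", {
  set.seed(51)
  dat <- sim_aft(500, beta_model = c(1, -0.5), cens_q = 0.6)
  fit <- fit_unrestricted(dat$taxon, dat$design)
  # the tau-scale coefficient is minus the model effect; 3 MC SD ~ 0.43
  expect_lt(max(abs(fit$beta_hat - c(-1, 0.5))), 0.43)
  expect_true(fit$converged)
  # location shift of the response leaves the estimate unchanged
  tx2 <- make_censored(dat$taxon$tau + 5, dat$taxon$delta)
  fit2 <- fit_unrestricted(tx2, dat$design)
  expect_equal(fit2$beta_hat, fit$beta_hat, tolerance = 1e-8)
})

test_that("restricted fits honor their constraints and recover nuisances", {
  # fully specified null: K = 1, Gamma = 1 => beta fixed at b
  tx <- make_censored(c(0.2, 1.4, 2.0, 0.9), c(1, 1, 0, 1))
  X1 <- matrix(c(-0.5, 0.5, -0.5, 0.5), ncol = 1, dimnames = list(NULL, "x"))
  rf <- fit_restricted(tx, design_matrix(X1), contrast_spec(1, b = 0.7))
  expect_equal(unname(rf$beta_hat), 0.7)

  # K = 2, constrain the first coefficient, recover the second
  set.seed(61)
  n <- 500
  X <- scale(matrix(rbinom(n * 2, 1, 0.5), n, 2), scale = FALSE)
  colnames(X) <- c("x1", "x2")
  tau_s <- 1 + as.vector(X %*% c(0, 1)) + rlogis(n) * 0.8
  cm <- as.numeric(quantile(tau_s, 0.7))
  txn <- make_censored(pmin(tau_s, cm), as.integer(tau_s <= cm))
  rf2 <- fit_restricted(txn, design_matrix(X),
                        contrast_spec(matrix(c(1, 0), 1, 2), b = 0))
  expect_equal(unname(rf2$beta_hat[1]), 0)
  expect_lt(abs(rf2$beta_hat[2] - 1), 0.44) # 3 MC SD

  # equality-of-coefficients contrast in K = 3
  set.seed(62)
  X3 <- scale(matrix(rnorm(60), 20, 3), scale = FALSE)
  colnames(X3) <- c("a", "b", "c")
  tx3 <- make_censored(rnorm(20), rbinom(20, 1, 0.8))
  rf3 <- fit_restricted(tx3, design_matrix(X3),
                        contrast_spec(matrix(c(1, -1, 0), 1, 3), b = 0))
  expect_equal(unname(rf3$beta_hat[1] - rf3$beta_hat[2]), 0,
               tolerance = 1e-10)
})

test_that("all-censored taxa are rejected as not estimable", {
  tx <- make_censored(c(3, 3, 3), c(0, 0, 0))
  X <- matrix(c(-1, 0, 1), ncol = 1, dimnames = list(NULL, "x"))
  expect_error(fit_unrestricted(tx, design_matrix(X)),
               class = "caft_not_estimable")
})

test_that("Kaplan-Meier intercept matches product-limit medians", {
  X <- matrix(c(-1, 0, 1), ncol = 1, dimnames = list(NULL, "x"))
  d <- design_matrix(X)
  # no censoring: plain median of the residuals
  tx <- make_censored(c(1, 2, 3), c(1, 1, 1))
  expect_equal(estimate_intercept_km(tx, d, 0), 2)
  # hand product-limit computation, N = 6, interleaved censoring:
  # events at 1, 3, 5; censored at 2, 4, 6
  # S(1) = 5/6; S(3) = 5/6 * 3/4 = 0.625; S(5) = 0.625 * 1/2 = 0.3125
  # smallest time with S <= 0.5 is 5
  X6 <- matrix(seq(-2.5, 2.5, by = 1) / 10, ncol = 1,
               dimnames = list(NULL, "x"))
  tx6 <- make_censored(1:6, c(1, 0, 1, 0, 1, 0))
  expect_equal(estimate_intercept_km(tx6, design_matrix(X6), 0), 5)
  # heavy censoring: curve never reaches one half -> NA, no error
  tx_h <- make_censored(c(1, 2, 3, 4), c(1, 0, 0, 0))
  X4 <- matrix(c(-1.5, -0.5, 0.5, 1.5), ncol = 1, dimnames = list(NULL, "x"))
  expect_true(is.na(estimate_intercept_km(tx_h, design_matrix(X4), 0)))
  # single uncensored value after all censoring times: the curve drops to
  # zero there, so the median is that value
  tx1 <- make_censored(c(1, 2, 2.5), c(0, 0, 1))
  expect_equal(estimate_intercept_km(tx1, d, 0), 2.5)
})

test_that("a shared offset in the covariate span shifts every taxon's
           estimate identically", {
  set.seed(71)
  n <- 30
  X <- scale(matrix(rnorm(n * 2), n, 2), scale = FALSE)
  colnames(X) <- c("x1", "x2")
  d <- design_matrix(X)
  cshift <- c(0.6, -1.1)
  alpha <- as.vector(X %*% cshift)
  for (r in 1:4) {
    tau <- rnorm(n, sd = 2)
    f0 <- fit_unrestricted(make_censored(tau, rep(1, n)), d)
    f1 <- fit_unrestricted(make_censored(tau + alpha, rep(1, n)), d)
    expect_equal(f1$beta_hat - f0$beta_hat, setNames(cshift, c("x1", "x2")),
                 tolerance = 1e-6)
  }
})
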