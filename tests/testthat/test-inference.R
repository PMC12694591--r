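test_that("rank scale factor matches direct summation", {
  R <- matrix(c(0.5, 0, 1, 0.5), 2, 2)
  expect_equal(rank_sigma2(R), 1) # (1/2)(1^2 + 1^2)
  expect_equal(rank_sigma2(matrix(0, 3, 3)), 0)
  set.seed(5)
  for (r in 1:20) {
    n <- sample(2:6, 1)
    R <- matrix(runif(n * n), n, n)
    direct <- sum((rowSums(R) - colSums(R))^2) / n
    expect_equal(rank_sigma2(R), direct)
  }
})

test_that("rank variance is the scaled covariate cross-product", {
  X <- matrix(c(-0.5, 0.5), 2, 1, dimnames = list(NULL, "x"))
  expect_equal(unname(rank_variance(1, X)), matrix(0.5))
  expect_equal(unname(rank_variance(0, X)), matrix(0))
  # orthogonal centered columns give a diagonal matrix
  Xo <- cbind(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1))
  V <- rank_variance(2, Xo)
  expect_equal(unname(V), diag(c(8, 8)))
  # positive semidefinite on random designs
  set.seed(6)
  for (r in 1:10) {
    Xr <- matrix(rnorm(24), 8, 3)
    ev <- eigen(rank_variance(runif(1), Xr), symmetric = TRUE)$values
    expect_true(all(ev > -1e-10))
  }
})

test_that("contrast complement yields an orthonormal null-space basis", {
  ct <- contrast_complement(matrix(c(1, -1, 0), 1, 3))
  L <- ct$Lambda
  expect_equal(dim(L), c(2, 3))
  expect_equal(unname(ct$Gamma %*% t(L)), matrix(0, 1, 2))
  expect_equal(unname(tcrossprod(L)), diag(2))
  # row space equals span{(1,1,0)/sqrt(2), (0,0,1)}
  P_expected <- crossprod(rbind(c(1, 1, 0) / sqrt(2), c(0, 0, 1)))
  expect_equal(crossprod(L), P_expected)

  # square full-rank Gamma: empty complement (simple null)
  expect_equal(nrow(contrast_complement(diag(2))$Lambda), 0)
  # selector contrast
  expect_equal(unname(contrast_complement(matrix(c(1, 0), 1, 2))$Lambda),
               matrix(c(0, 1), 1, 2))
  expect_error(contrast_spec(matrix(c(1, 1, 2, 2), 2, 2)),
               class = "caft_bad_input")
  # deterministic across calls and orthonormal for random contrasts
  set.seed(8)
  for (r in 1:10) {
    K <- sample(3:5, 1); d <- sample(1:(K - 1), 1)
    G <- matrix(rnorm(d * K), d, K)
    c1 <- contrast_complement(G); c2 <- contrast_complement(G)
    expect_identical(c1$Lambda, c2$Lambda)
    expect_equal(unname(tcrossprod(c1$Lambda)), diag(K - d))
    expect_lt(max(abs(G %*% t(c1$Lambda))), 1e-10)
  }
})

test_that("worked two-sample instance gives T = 2 on one degree of freedom", {
  tx <- make_censored(c(0, 1), c(1, 1))
  X <- matrix(c(-0.5, 0.5), 2, 1, dimnames = list(NULL, "x"))
  st <- score_test(tx, design_matrix(X), contrast_spec(1, b = 0))
  expect_equal(unname(st$score), -1)
  expect_equal(st$sigma2, 1)
  expect_equal(unname(st$variance), matrix(0.5))
  expect_equal(st$statistic, 2)
  expect_equal(st$df, 1L)
  expect_equal(st$p_value, pchisq(2, 1, lower.tail = FALSE))
})

test_that("zero score yields a null statistic and p-value one", {
  # symmetric ties: every comparison cancels
  tx <- make_censored(c(1, 1), c(1, 1))
  X <- matrix(c(-0.5, 0.5), 2, 1, dimnames = list(NULL, "x"))
  st <- score_test(tx, design_matrix(X), contrast_spec(1, b = 0))
  expect_equal(st$statistic, 0)
  expect_equal(st$p_value, 1)
})

test_that("statistic is invariant to invertible reparameterizations of the
           null and reduces to the simple form", {
  set.seed(13)
  dat <- sim_aft(80, beta_model = c(0.5, -0.3, 0.2), cens_q = 0.7,
                 binary = FALSE)
  G <- matrix(c(1, 0, 0,
                0, 1, 0), 2, 3, byrow = TRUE)
  b <- c(-0.4, 0.35)
  st <- score_test(dat$taxon, dat$design, contrast_spec(G, b = b))
  # invertible row mixing of (Gamma, b) leaves T unchanged
  A <- matrix(c(2, 1, -1, 3), 2, 2)
  st2 <- score_test(dat$taxon, dat$design,
                    contrast_spec(A %*% G, b = as.vector(A %*% b)))
  expect_equal(st2$statistic, st$statistic, tolerance = 1e-6)
  expect_equal(st2$df, st$df)

  # simple null: the Schur form collapses to S' V^{-1} S
  Gs <- diag(3)
  bs <- c(-0.4, 0.35, 0.1)
  sts <- score_test(dat$taxon, dat$design, contrast_spec(Gs, b = bs))
  S <- sts$score; V <- sts$variance
  expect_equal(sts$statistic, drop(t(S) %*% solve(V, S)))
  expect_equal(sts$df, 3L)
})

test_that("restricted score statistic is chi-squared calibrated under the
           null", {
  set.seed(19)
  nrep <- 400
  Ts <- numeric(nrep)
  ctr <- contrast_spec(matrix(c(1, 0), 1, 2), b = -0.5)
  for (r in seq_len(nrep)) {
    dat <- sim_aft(60, beta_model = c(0.5, -0.7), cens_q = 0.65)
    Ts[r] <- score_test(dat$taxon, dat$design, ctr)$statistic
  }
  expect_gt(stats::ks.test(Ts, pchisq, df = 1)$p.value, 0.01)
  p <- pchisq(Ts, 1, lower.tail = FALSE)
  expect_lt(abs(mean(p <= 0.05) - 0.05), 2 * sqrt(0.05 * 0.95 / nrep) + 1e-9)
})

test_that("the Cox score variance is a documented stub", {
  expect_error(cox_variance(NULL, NULL, NULL),
               class = "caft_not_implemented")
  expect_error(caft_control(variance_estimator = "cox"),
               class = "caft_not_implemented")
})
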