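#' Linear contrast specification for score tests
#'
#' Describes a composite null hypothesis `Gamma beta = b` for a K-vector of
#' AFT coefficients, where `Gamma` is d x K of full row rank. `Lambda`, a
#' (K-d) x K matrix with orthonormal rows spanning the null space of
#' `Gamma`, parameterizes the nuisance directions; it is computed by
#' [contrast_complement()] unless supplied. Moore-Penrose inverses of both
#' matrices are cached for restricted fitting.
#'
#' @param Gamma numeric d x K matrix (a vector is treated as one row).
#' @param b numeric right-hand side of length d (default zeros).
#' @param Lambda optional null-space basis with orthonormal rows.
#' @return object of class `caft_contrast` with `Gamma`, `b`, `Lambda`,
#'   `Gamma_pinv`, `Lambda_pinv`, `d`, `K`.
#' @export
contrast_spec <- function(Gamma, b = NULL, Lambda = NULL) {
  if (is.null(dim(Gamma))) Gamma <- matrix(Gamma, nrow = 1)
  Gamma <- as.matrix(Gamma)
  d <- nrow(Gamma); K <- ncol(Gamma)
  if (d > K) caft_stop("more constraints than parameters", "caft_bad_input")
  if (qr(Gamma)$rank < d)
    caft_stop("Gamma must have full row rank", "caft_bad_input")
  if (is.null(b)) b <- numeric(d)
  if (length(b) != d) caft_stop("length(b) must equal nrow(Gamma)", "caft_bad_input")
  if (is.null(Lambda)) Lambda <- null_space_basis(Gamma)
  Lambda <- as.matrix(Lambda)
  if (nrow(Lambda) > 0) {
    if (max(abs(Gamma %*% t(Lambda))) > 1e-10)
      caft_stop("Gamma and Lambda are not orthogonal", "caft_bad_input")
    if (max(abs(tcrossprod(Lambda) - diag(nrow(Lambda)))) > 1e-8)
      caft_stop("Lambda rows must be orthonormal", "caft_bad_input")
  }
  structure(list(Gamma = Gamma, b = as.numeric(b), Lambda = Lambda,
                 Gamma_pinv = mp_pinv(Gamma), Lambda_pinv = mp_pinv(Lambda),
                 d = d, K = K),
            class = "caft_contrast")
}

# Moore-Penrose pseudoinverse via SVD, relative tolerance 1e-12 on the
# singular values. For an empty matrix returns the conformable empty map.
mp_pinv <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) == 0L || ncol(M) == 0L) return(matrix(0, ncol(M), nrow(M)))
  s <- svd(M)
  tol <- 1e-12 * max(s$d)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

null_space_basis <- function(Gamma) {
  d <- nrow(Gamma); K <- ncol(Gamma)
  if (d == K) return(matrix(0, 0, K))
  sv <- svd(Gamma, nu = 0, nv = K)
  basis <- t(sv$v[, (d + 1):K, drop = FALSE])
  # canonical sign: first entry of non-negligible magnitude in each row positive
  for (r in seq_len(nrow(basis))) {
    nz <- which(abs(basis[r, ]) > 1e-10)[1]
    if (!is.na(nz) && basis[r, nz] < 0) basis[r, ] <- -basis[r, ]
  }
  basis
}

#' Orthonormal complement of a contrast matrix
#'
#' Returns a full [contrast_spec()] whose `Lambda` has orthonormal rows
#' spanning the null space of `Gamma` (deterministic SVD basis with a fixed
#' sign convention). For square full-rank `Gamma` the complement is empty
#' and the associated null hypothesis is simple.
#'
#' @param Gamma numeric d x K matrix of full row rank.
#' @param b optional right-hand side.
#' @return a `caft_contrast` object.
#' @export
contrast_complement <- function(Gamma, b = NULL) {
  contrast_spec(Gamma, b = b)
}

#' Rank-based scale factor of the Gehan score
#'
#' `sigma2 = (1/N) sum_i (R_{i+} - R_{+i})^2` computed from a Gehan
#' comparison matrix; the empirical second moment of the rank weights that
#' multiply the covariates in the score.
#'
#' @param R a square comparison matrix as from [rank_matrix()].
#' @return non-negative scalar.
#' @export
rank_sigma2 <- function(R) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R))
  a <- rowSums(R) - colSums(R)
  mean(a^2)
}

#' Rank estimator of the score variance
#'
#' `V = sigma2 * (X - Xbar)^T (X - Xbar)`: the variance-covariance of the
#' Gehan score implied by independence of the rank weights and the
#' covariates at the fitted point. For a column-centered design this is
#' `sigma2 * X^T X`. Always symmetric positive semidefinite.
#'
#' @param sigma2 non-negative scalar from [rank_sigma2()].
#' @param design a [design_matrix()] object or numeric matrix.
#' @return K x K matrix.
#' @export
rank_variance <- function(sigma2, design) {
  stopifnot(sigma2 >= 0)
  X <- if (inherits(design, "caft_design")) design$X else as.matrix(design)
  Xc <- sweep(X, 2, colMeans(X))
  V <- sigma2 * crossprod(Xc)
  (V + t(V)) / 2
}

#' Restricted score test for one taxon
#'
#' Tests `H0: Gamma beta = b` for the censored AFT coefficients of one
#' taxon. The nuisance coordinates are estimated by the restricted Gehan
#' fit, the score `S` and rank variance `V` are evaluated at the restricted
#' solution, and the statistic is the quadratic form of the interest block
#' of the score in the inverse of its Schur-complement variance:
#' `T = S_g' [V_gg - V_gl V_ll^- V_lg]^{-1} S_g` with `S_g = Gamma S`,
#' `V_gg = Gamma V Gamma'` and so on; when the null is simple (`Lambda`
#' empty) this reduces to `T = S' V^{-1} S`. `T` is referred to a
#' chi-squared distribution with `d` degrees of freedom.
#'
#' @param taxon a [to_censored()] object.
#' @param design a [design_matrix()] object.
#' @param contrast a [contrast_spec()] object.
#' @param options a [gehan_control()] list.
#' @param lambda_start optional warm start for the restricted fit.
#' @return object of class `caft_score_test`: `taxon_id`,
#'   `beta_restricted`, `score`, `variance`, `statistic`, `df`, `p_value`,
#'   `converged`, plus the restricted `fit`.
#' @export
score_test <- function(taxon, design, contrast,
                       options = gehan_control(), lambda_start = NULL) {
  design <- as_design(design)
  fit <- fit_restricted(taxon, design, contrast, options = options,
                        lambda_start = lambda_start)
  e <- residuals_at(fit$beta_hat, taxon, design)
  a <- caft_rowcol_diff_cpp(e, taxon$delta)
  S <- as.vector(crossprod(design$X, a))
  sigma2 <- mean(a^2)
  V <- rank_variance(sigma2, design)
  Sg <- as.vector(contrast$Gamma %*% S)
  d <- contrast$d
  if (nrow(contrast$Lambda) == 0L) {
    Vschur <- V
  } else {
    Vgg <- contrast$Gamma %*% V %*% t(contrast$Gamma)
    Vgl <- contrast$Gamma %*% V %*% t(contrast$Lambda)
    Vll <- contrast$Lambda %*% V %*% t(contrast$Lambda)
    if (nrow(Vll) > 0) {
      ev <- eigen(Vll, symmetric = TRUE, only.values = TRUE)$values
      if (max(ev) > 0 && min(ev) < max(ev) / 1e10)
        warning("nuisance variance block is ill-conditioned", call. = FALSE)
    }
    Vschur <- Vgg - Vgl %*% mp_pinv(Vll) %*% t(Vgl)
  }
  stat <- if (all(Sg == 0)) 0 else # zero score: no evidence, even if V degenerate
    tryCatch(drop(t(Sg) %*% solve(Vschur, Sg)), error = function(e) NA_real_)
  if (!is.na(stat) && stat < 0) stat <- 0 # numerically zero quadratic forms
  p <- if (is.na(stat)) NA_real_ else pchisq(stat, df = d, lower.tail = FALSE)
  structure(list(taxon_id = taxon$taxon_id,
                 beta_restricted = fit$beta_hat,
                 score = setNames(S, design$covariate_names),
                 variance = V, sigma2 = sigma2,
                 statistic = stat, df = d, p_value = p,
                 converged = fit$converged, fit = fit),
            class = "caft_score_test")
}

#' Cox-model variance of the Gehan score (not implemented)
#'
#' A martingale-representation variance estimator for the Gehan score
#' exists in the survival literature, but the rank estimator
#' ([rank_variance()]) is this package's default and only implementation;
#' it has better operating characteristics at the censoring levels typical
#' of microbiome data.
#'
#' @param taxon,design,beta unused.
#' @export
cox_variance <- function(taxon, design, beta) {
  caft_stop(paste0("the Cox-model score variance is not implemented; ",
                   "use the rank estimator (rank_variance)"),
            "caft_not_implemented")
}
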