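#' Centered design matrix for rank-based AFT fitting
#'
#' The censored log-linear model carries an explicit taxon-specific
#' intercept, so the design must not contain a constant column and every
#' column must be centered (sum to zero). This constructor centers, checks
#' rank, and records which columns are covariates of interest.
#'
#' @param X numeric matrix or data frame of covariates (samples in rows).
#' @param interest names (or indices) of the columns under test; the rest
#'   are adjustment covariates.
#' @return an object of class `caft_design`: list with `X` (centered
#'   matrix), `covariate_names`, `interest_indices`.
#' @export
design_matrix <- function(X, interest = colnames(X)) {
  X <- as.matrix(X)
  if (!is.numeric(X)) caft_stop("covariates must be numeric", "caft_bad_input")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  attr(Xc, "scaled:center") <- NULL
  if (any(apply(Xc, 2, function(v) all(abs(v) < 1e-12))))
    caft_stop("constant covariate column (the model has an implicit intercept)",
              "caft_bad_input")
  if (qr(Xc)$rank < ncol(Xc))
    caft_stop("design matrix is rank deficient after centering", "caft_bad_input")
  if (is.character(interest)) {
    idx <- match(interest, colnames(Xc))
    if (any(is.na(idx)))
      caft_stop(paste0("unknown covariate: ", interest[is.na(idx)][1]),
                "caft_bad_input")
  } else idx <- as.integer(interest)
  structure(list(X = Xc, covariate_names = colnames(Xc),
                 interest_indices = idx),
            class = "caft_design")
}

as_design <- function(X) {
  if (inherits(X, "caft_design")) X else design_matrix(X)
}

#' Gehan comparison matrix
#'
#' Builds the N x N matrix `R[i, i'] = delta_i * (1(e_i < e_i') +
#' 0.5 * 1(e_i == e_i'))`, whose row/column sum differences drive the Gehan
#' score and the rank variance estimator. Mostly useful for inspection and
#' testing; the fitting code computes the row/column differences directly.
#'
#' @param residuals numeric vector of AFT residuals `e_i = tau_i - X_i beta`.
#' @param delta 0/1 censoring indicators (1 = observed).
#' @return a dense N x N matrix.
#' @export
rank_matrix <- function(residuals, delta) {
  stopifnot(length(residuals) == length(delta))
  lt <- outer(residuals, residuals, "<")
  eq <- outer(residuals, residuals, "==")
  delta * (lt + 0.5 * eq)
}

residuals_at <- function(beta, taxon, design) {
  taxon$tau - as.vector(design$X %*% beta)
}

#' Gehan score function
#'
#' Evaluates `S(beta) = sum_i (R_{i+} - R_{+i}) X_i`, the rank-based
#' estimating function of the censored AFT model; identical to the double
#' sum over ordered residual pairs with the smaller member uncensored.
#' `S` is a step function of `beta` and equals the subgradient of
#' [gehan_objective()] wherever that objective is differentiable.
#'
#' @param beta coefficient vector (length K).
#' @param taxon a [to_censored()] object.
#' @param design a [design_matrix()] object (or plain centered matrix).
#' @return numeric K-vector.
#' @export
gehan_score <- function(beta, taxon, design) {
  design <- as_design(design)
  e <- residuals_at(beta, taxon, design)
  a <- caft_rowcol_diff_cpp(e, taxon$delta)
  as.vector(crossprod(design$X, a))
}

#' Gehan convex objective
#'
#' `G(beta) = sum_{i: delta_i = 1} sum_{i'} max(0, e_{i'} - e_i)`, the
#' non-negative convex piecewise-linear dispersion whose minimizers solve
#' the Gehan score equation. The row/column-sum form
#' `J(beta) = sum_i (R_{i+} - R_{+i}) e_i` evaluates to `-G(beta)`; the
#' package minimizes the non-negative convex form `G`.
#'
#' @inheritParams gehan_score
#' @return a non-negative scalar.
#' @export
gehan_objective <- function(beta, taxon, design) {
  design <- as_design(design)
  e <- residuals_at(beta, taxon, design)
  caft_objective_cpp(e, taxon$delta)
}

#' Solver options for Gehan fits
#'
#' @param tol_objective relative objective-improvement tolerance for
#'   declaring convergence of the direction-search sweeps.
#' @param tol_beta absolute parameter-change tolerance.
#' @param max_sweeps maximum number of full direction sweeps.
#' @param polish run a Nelder-Mead polish from the sweep solution when the
#'   parameter dimension exceeds one (guards against stalling of axis
#'   searches at kinks of the piecewise-linear objective).
#' @return a list of class `caft_solver_options`.
#' @export
gehan_control <- function(tol_objective = 1e-10, tol_beta = 1e-8,
                          max_sweeps = 60, polish = TRUE) {
  structure(list(tol_objective = tol_objective, tol_beta = tol_beta,
                 max_sweeps = max_sweeps, polish = polish),
            class = "caft_solver_options")
}

# Exact minimization of G along beta + t v. Returns list(t, status).
line_min <- function(beta, v, taxon, design) {
  w <- as.vector(design$X %*% v)
  if (all(w == 0)) return(list(t = 0, status = 2L))
  e <- residuals_at(beta, taxon, design)
  res <- caft_line_min_cpp(e, w, taxon$delta)
  list(t = res$t, status = as.integer(res$status))
}

# Direction set: coordinates plus pairwise diagonals (helps the sweep
# escape kink corners of the piecewise-linear objective).
sweep_directions <- function(K) {
  dirs <- lapply(seq_len(K), function(k) { v <- numeric(K); v[k] <- 1; v })
  if (K >= 2) {
    for (a in seq_len(K - 1)) for (b in seq((a + 1), K)) {
      v <- numeric(K); v[a] <- 1; v[b] <- 1; dirs[[length(dirs) + 1]] <- v
      v[b] <- -1; dirs[[length(dirs) + 1]] <- v
    }
  }
  dirs
}

# Shared solver: minimize G(beta0 + M lambda) over lambda (M a K x q map).
# Used with M = I for unrestricted fits and M = the null-space basis for
# restricted fits. Deterministic: fixed start, fixed direction order.
minimize_gehan <- function(taxon, design, beta0, M, lambda0, options) {
  q <- ncol(M)
  obj <- function(lambda)
    gehan_objective(beta0 + as.vector(M %*% lambda), taxon, design)
  lambda <- lambda0
  G <- obj(lambda)
  flat <- FALSE
  if (q == 0L) {
    return(list(lambda = lambda, objective = G, converged = TRUE, flat = FALSE))
  }
  dirs <- sweep_directions(q)
  converged <- FALSE
  for (sweep in seq_len(options$max_sweeps)) {
    moved <- 0
    for (v in dirs) {
      ls <- line_min(beta0 + as.vector(M %*% lambda), as.vector(M %*% v),
                     taxon, design)
      # status 2: objective constant along v (t = 0) or flat beyond the
      # last kink (minimizer not unique) -- either way not a unique optimum
      if (ls$status == 2L) flat <- TRUE
      if (ls$t != 0) {
        cand <- lambda + ls$t * v
        Gc <- obj(cand)
        if (Gc <= G) {
          moved <- max(moved, abs(ls$t) * max(abs(v)), G - Gc)
          lambda <- cand
          G <- Gc
        }
      }
    }
    if (moved <= options$tol_objective * (1 + G) + options$tol_beta) {
      converged <- TRUE
      break
    }
  }
  if (options$polish && q >= 2L) {
    pol <- optim(lambda, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
    if (pol$value < G - options$tol_objective * (1 + G)) {
      lambda <- pol$par
      G <- pol$value
      # one more exact sweep from the polished point
      for (v in dirs) {
        ls <- line_min(beta0 + as.vector(M %*% lambda), as.vector(M %*% v),
                       taxon, design)
        if (ls$t != 0) {
          cand <- lambda + ls$t * v
          Gc <- obj(cand)
          if (Gc <= G) { lambda <- cand; G <- Gc }
        }
      }
    }
  }
  list(lambda = lambda, objective = G, converged = converged, flat = flat)
}

new_gehan_fit <- function(beta, taxon, design, fit, lambda = NULL) {
  structure(list(beta_hat = setNames(as.numeric(beta), design$covariate_names),
                 objective_value = fit$objective,
                 score_at_solution = gehan_score(beta, taxon, design),
                 converged = fit$converged && !fit$flat,
                 flat_direction = fit$flat,
                 lambda_hat = lambda,
                 n_effective = sum(taxon$delta),
                 taxon_id = taxon$taxon_id),
            class = "caft_gehan_fit")
}

#' Unrestricted Gehan fit for one taxon
#'
#' Minimizes the convex piecewise-linear Gehan objective by deterministic
#' exact line searches (weighted-median scans over the objective's kinks)
#' over a fixed direction set, with an optional Nelder-Mead polish for
#' multi-dimensional fits. Starting point is `beta = 0`; no randomness.
#' When the minimizer is a flat interval in a one-dimensional search the
#' midpoint is reported.
#'
#' @param taxon a [to_censored()] object.
#' @param design a [design_matrix()] object (or centered matrix).
#' @param options a [gehan_control()] list.
#' @return an object of class `caft_gehan_fit`: `beta_hat`,
#'   `objective_value`, `score_at_solution`, `converged`, `n_effective`.
#' @export
fit_unrestricted <- function(taxon, design, options = gehan_control()) {
  design <- as_design(design)
  K <- ncol(design$X)
  if (sum(taxon$delta) == 0L)
    caft_stop(paste0("taxon ", taxon$taxon_id,
                     " has no uncensored observations"), "caft_not_estimable")
  fit <- minimize_gehan(taxon, design, beta0 = numeric(K), M = diag(K),
                        lambda0 = numeric(K), options = options)
  if (fit$flat)
    warning("flat objective direction for taxon ", taxon$taxon_id,
            "; coefficients not uniquely determined", call. = FALSE)
  new_gehan_fit(fit$lambda, taxon, design, fit)
}

#' Restricted Gehan fit under a linear constraint
#'
#' Minimizes the Gehan objective over the affine set `Gamma beta = b`,
#' parameterized as `beta = Gamma^- b + Lambda^- lambda` with `lambda` the
#' free nuisance coordinates (Moore-Penrose inverses; `Lambda` has
#' orthonormal rows spanning the null space of `Gamma`). The map is affine,
#' so the restricted problem stays convex.
#'
#' @param taxon a [to_censored()] object.
#' @param design a [design_matrix()] object.
#' @param contrast a [contrast_spec()] object carrying `Gamma`, `b`,
#'   `Lambda`.
#' @param options a [gehan_control()] list.
#' @param lambda_start optional warm start for the nuisance coordinates.
#' @return a `caft_gehan_fit` whose `beta_hat` satisfies
#'   `Gamma beta_hat = b` to numerical tolerance; `lambda_hat` holds the
#'   fitted nuisance coordinates.
#' @export
fit_restricted <- function(taxon, design, contrast,
                           options = gehan_control(), lambda_start = NULL) {
  design <- as_design(design)
  K <- ncol(design$X)
  if (ncol(contrast$Gamma) != K)
    caft_stop("contrast dimension does not match design", "caft_bad_input")
  if (sum(taxon$delta) == 0L)
    caft_stop(paste0("taxon ", taxon$taxon_id,
                     " has no uncensored observations"), "caft_not_estimable")
  beta0 <- as.vector(contrast$Gamma_pinv %*% contrast$b)
  M <- contrast$Lambda_pinv # K x (K - d); empty when the null is simple
  q <- ncol(M)
  lambda0 <- if (!is.null(lambda_start)) lambda_start else numeric(q)
  fit <- minimize_gehan(taxon, design, beta0 = beta0, M = M,
                        lambda0 = lambda0, options = options)
  beta <- beta0 + as.vector(M %*% fit$lambda)
  new_gehan_fit(beta, taxon, design, fit, lambda = fit$lambda)
}

#' Kaplan-Meier estimate of the taxon intercept
#'
#' The Gehan score does not involve the intercept. When one is wanted, it
#' is estimated as the median of the Kaplan-Meier curve of the residuals
#' `tau_i - X_i beta` with the taxon's censoring indicators: the smallest
#' residual at which the product-limit survival function drops to 0.5 or
#' below. Under heavy censoring the curve may never reach 0.5, in which
#' case `NA` is returned rather than an error.
#'
#' @param taxon a [to_censored()] object.
#' @param design a [design_matrix()] object.
#' @param beta fitted coefficient vector.
#' @return scalar intercept estimate, or `NA_real_` if the survival curve
#'   never reaches 0.5.
#' @export
estimate_intercept_km <- function(taxon, design, beta) {
  design <- as_design(design)
  if (sum(taxon$delta) == 0L)
    caft_stop("no uncensored residuals", "caft_not_estimable")
  e <- residuals_at(beta, taxon, design)
  km <- survival::survfit(survival::Surv(e, taxon$delta) ~ 1)
  drop <- which(km$surv <= 0.5 + 1e-12)
  if (length(drop) == 0L) return(NA_real_)
  km$time[drop[1]]
}
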