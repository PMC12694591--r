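#' Panel of per-taxon coefficient estimates
#'
#' Collects the unrestricted Gehan estimates across taxa; rows flagged as
#' invalid (failed or non-converged fits) are excluded from reference
#' computations. At least three valid rows are required downstream.
#'
#' @param betas J x K numeric matrix, one row per taxon.
#' @param fitted_flags logical vector marking rows from valid fits.
#' @param taxon_ids optional row identifiers.
#' @return object of class `caft_panel`.
#' @export
coefficient_panel <- function(betas, fitted_flags = NULL, taxon_ids = NULL) {
  betas <- as.matrix(betas)
  if (is.null(fitted_flags)) fitted_flags <- rep(TRUE, nrow(betas))
  fitted_flags <- as.logical(fitted_flags) & !apply(betas, 1, anyNA)
  if (is.null(taxon_ids)) taxon_ids <- rownames(betas)
  structure(list(betas = betas, fitted_flags = fitted_flags,
                 taxon_ids = taxon_ids),
            class = "caft_panel")
}

#' Spatial median of per-taxon coefficients
#'
#' The compositional null reference is the median of the per-taxon
#' coefficient estimates over the selected components. For a single
#' component this is the ordinary sample median (even counts: mean of the
#' two central order statistics). For two or more components it is the
#' affine-equivariant spatial median of Hettmansperger-Randles type,
#' computed by an iterative transformation-retransformation scheme: the
#' data are whitened by the Tyler shape matrix about the current center,
#' the ordinary (Weiszfeld) spatial median of the whitened cloud is found,
#' and the center is retransformed; iterated to tolerance 1e-8 with at
#' most 500 outer iterations. Deterministic. On non-convergence the
#' componentwise median is returned with a warning.
#'
#' @param panel a [coefficient_panel()] (or plain matrix).
#' @param dims indices of the components over which to take the median
#'   (default all columns).
#' @return numeric vector of length `length(dims)`.
#' @export
spatial_median <- function(panel, dims = NULL) {
  if (!inherits(panel, "caft_panel")) panel <- coefficient_panel(panel)
  B <- panel$betas[panel$fitted_flags, , drop = FALSE]
  if (nrow(B) < 3L)
    caft_stop("fewer than 3 valid coefficient rows for the reference median",
              "caft_bad_input")
  if (is.null(dims)) dims <- seq_len(ncol(B))
  B <- B[, dims, drop = FALSE]
  if (ncol(B) == 1L) return(median(B[, 1]))
  hr_median(B)
}

# Weiszfeld iteration for the ordinary spatial (L1) median, with the
# standard guard for iterates landing on a data point.
weiszfeld <- function(Y, tol = 1e-10, maxit = 1000) {
  theta <- colMeans(Y)
  for (it in seq_len(maxit)) {
    D <- sqrt(rowSums(sweep(Y, 2, theta)^2))
    on_pt <- D < 1e-12
    w <- ifelse(on_pt, 0, 1 / pmax(D, 1e-300))
    if (all(w == 0)) return(theta)
    theta_new <- colSums(Y * w) / sum(w)
    if (sqrt(sum((theta_new - theta)^2)) < tol * (1 + sqrt(sum(theta^2)))) {
      return(theta_new)
    }
    theta <- theta_new
  }
  theta
}

# Tyler shape matrix about a fixed center, normalized to trace p.
tyler_shape <- function(Y, center, tol = 1e-9, maxit = 200) {
  p <- ncol(Y)
  Z <- sweep(Y, 2, center)
  keep <- rowSums(Z^2) > 1e-24
  Z <- Z[keep, , drop = FALSE]
  V <- diag(p)
  for (it in seq_len(maxit)) {
    Vi <- solve(V)
    q <- rowSums((Z %*% Vi) * Z)
    W <- crossprod(Z / q, Z) * p / nrow(Z)
    W <- W * p / sum(diag(W))
    if (max(abs(W - V)) < tol) return(W)
    V <- W
  }
  V
}

# Hettmansperger-Randles style affine-equivariant spatial median via
# transformation-retransformation with the Tyler shape.
hr_median <- function(B, tol = 1e-8, maxit = 500) {
  p <- ncol(B)
  theta <- apply(B, 2, median)
  ok <- FALSE
  for (it in seq_len(maxit)) {
    V <- tryCatch(tyler_shape(B, theta), error = function(e) NULL)
    if (is.null(V)) break
    Rchol <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(Rchol)) break
    Y <- sweep(B, 2, theta) %*% solve(Rchol) # whiten
    m <- weiszfeld(Y)
    theta_new <- theta + as.vector(m %*% Rchol)
    if (sqrt(sum((theta_new - theta)^2)) < tol * (1 + sqrt(sum(theta^2)))) {
      theta <- theta_new; ok <- TRUE; break
    }
    theta <- theta_new
  }
  if (!ok) {
    warning("affine-equivariant spatial median did not converge; ",
            "falling back to the componentwise median", call. = FALSE)
    return(apply(B, 2, median))
  }
  theta
}

#' Attach the compositional null right-hand side to a contrast
#'
#' Sets `b = Gamma_interest beta_m` where `beta_m` is the (spatial) median
#' over taxa of the interest components of the unrestricted estimates. The
#' reference is treated as a *fixed* quantity in all downstream tests (its
#' sampling variability is ignored, which is justified when the number of
#' taxa is large; a warning is emitted below 50 valid taxa).
#'
#' @param panel a [coefficient_panel()] of unrestricted estimates
#'   (columns in design order).
#' @param contrast a [contrast_spec()] whose `Gamma` selects the interest
#'   components (one selector row per tested component).
#' @return the contrast with `b` replaced by the reference value; the
#'   reference vector is attached as attribute `"reference"`.
#' @export
build_null_rhs <- function(panel, contrast) {
  if (!inherits(panel, "caft_panel")) panel <- coefficient_panel(panel)
  n_valid <- sum(panel$fitted_flags)
  if (n_valid < 3L)
    caft_stop("fewer than 3 valid taxa to form the reference", "caft_bad_input")
  if (n_valid < 50L)
    warning("only ", n_valid, " taxa contribute to the reference median; ",
            "treating it as fixed may be optimistic", call. = FALSE)
  # median over the interest components only: those are what enter b
  proj <- panel$betas %*% t(contrast$Gamma)
  ref <- spatial_median(coefficient_panel(proj, panel$fitted_flags))
  out <- contrast_spec(contrast$Gamma, b = as.numeric(ref),
                       Lambda = contrast$Lambda)
  attr(out, "reference") <- as.numeric(ref)
  out
}
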