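#' Benjamini-Hochberg adjustment with NA pass-through
#'
#' Standard step-up BH adjusted p-values via [stats::p.adjust()], with
#' unavailable entries passed through unchanged and excluded from the
#' number of tests `m` (taxa whose fit failed carry no test).
#'
#' @param p_values numeric vector in `[0, 1]`, possibly with `NA`s.
#' @param na_in_m if `TRUE`, `NA` entries still count toward `m`.
#' @return adjusted values, same length and order; `NA` where input was `NA`.
#' @export
bh_adjust <- function(p_values, na_in_m = FALSE) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    caft_stop("p-values must lie in [0, 1]", "caft_bad_input")
  out <- rep(NA_real_, length(p_values))
  m <- if (na_in_m) length(p_values) else sum(ok)
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH", n = max(m, 1L))
  out
}

#' Analysis settings for the CAFT pipeline
#'
#' @param min_library minimum library size; samples below are removed
#'   before anything else.
#' @param library_boundary `"keep"` retains samples at exactly
#'   `min_library`; `"drop"` removes them too.
#' @param min_presence_frac prevalence filter: keep taxa present in at
#'   least this fraction of samples (default 0.1; simulation studies in
#'   this package use 0.06 or 0.20).
#' @param filter_order `"samples_first"` (default, the documented pipeline
#'   order) or `"taxa_first"`.
#' @param recompute_library recompute library sizes after taxon filtering
#'   (default `FALSE`: the censoring bound reflects sequencing depth).
#' @param fdr_threshold nominal FDR for the `detected` flag.
#' @param variance_estimator only `"rank"` is implemented.
#' @param na_in_m count failed taxa in the BH denominator.
#' @param warm_start reuse each taxon's unrestricted fit to start its
#'   restricted fit.
#' @param solver a [gehan_control()] list.
#' @return a list of class `caft_control`.
#' @export
caft_control <- function(min_library = 3000,
                         library_boundary = c("keep", "drop"),
                         min_presence_frac = 0.1,
                         filter_order = c("samples_first", "taxa_first"),
                         recompute_library = FALSE,
                         fdr_threshold = 0.05,
                         variance_estimator = c("rank", "cox"),
                         na_in_m = FALSE,
                         warm_start = TRUE,
                         solver = gehan_control()) {
  variance_estimator <- match.arg(variance_estimator)
  if (variance_estimator == "cox")
    caft_stop("the Cox score variance is not implemented; use 'rank'",
              "caft_not_implemented")
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  structure(list(min_library = min_library,
                 library_boundary = match.arg(library_boundary),
                 min_presence_frac = min_presence_frac,
                 filter_order = match.arg(filter_order),
                 recompute_library = recompute_library,
                 fdr_threshold = fdr_threshold,
                 variance_estimator = variance_estimator,
                 na_in_m = na_in_m, warm_start = warm_start,
                 solver = solver),
            class = "caft_control")
}

# Encode covariate columns numerically: numeric kept as is; two-level
# factors/characters mapped to 0/1 by sorted level order (logged, since the
# coefficient sign depends on it); multi-level factors expanded to
# treatment-coded columns against the first sorted level.
encode_covariates <- function(metadata, covariates, verbose = TRUE) {
  cols <- list()
  for (nm in covariates) {
    v <- metadata[[nm]]
    if (is.null(v)) caft_stop(paste0("covariate not in metadata: ", nm),
                              "caft_bad_input")
    if (anyNA(v))
      caft_stop(paste0("missing values in covariate ", nm), "caft_bad_input")
    if (is.numeric(v)) { cols[[nm]] <- as.numeric(v); next }
    lev <- sort(unique(as.character(v)))
    if (length(lev) < 2)
      caft_stop(paste0("covariate ", nm, " is constant"), "caft_bad_input")
    if (length(lev) == 2) {
      if (verbose)
        message("covariate ", nm, ": '", lev[1], "' -> 0, '", lev[2], "' -> 1")
      cols[[nm]] <- as.numeric(as.character(v) == lev[2])
    } else {
      for (l in lev[-1]) cols[[paste0(nm, ".", l)]] <-
          as.numeric(as.character(v) == l)
      if (verbose)
        message("covariate ", nm, ": treatment-coded against level '",
                lev[1], "'")
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}

#' Run the full CAFT differential-abundance analysis
#'
#' Pipeline: (1) library-size and prevalence filters; (2) numeric encoding
#' and centering of covariates; (3) per-taxon unrestricted Gehan fit of the
#' censored AFT model; (4) compositional reference = (spatial) median over
#' taxa of the interest coefficients; (5) per-taxon restricted fit and
#' score test of `H0: beta_interest = reference`; (6) Benjamini-Hochberg
#' adjustment. Coefficients are on the negative-log-relative-abundance
#' scale; the reported `effect.*` columns are sign-flipped differences from
#' the reference, so a positive effect means higher relative abundance with
#' increasing covariate.
#'
#' @param table a [count_table()] object.
#' @param metadata data frame with a `sample_id` column (or matching
#'   `id_column`) covering every sample in the table.
#' @param interest names of covariates under test.
#' @param adjust names of adjustment covariates (default none).
#' @param control a [caft_control()] list.
#' @param id_column name of the sample-id column in `metadata`.
#' @param verbose emit per-stage progress messages.
#' @return object of class `caft_result`: a list with `results` (data
#'   frame: `taxon_id`, `beta.*`, `effect.*`, `stat`, `df`, `pvalue`,
#'   `qvalue`, `detected`, `converged`, `n_present`), `reference`,
#'   `control`, `design`, `n_samples`, `n_taxa`, `zero_fraction`.
#' @export
run_caft <- function(table, metadata, interest, adjust = character(0),
                     control = caft_control(), id_column = "sample_id",
                     verbose = TRUE) {
  stopifnot(inherits(table, "caft_count_table"))
  say <- function(...) if (verbose) message("caft: ", ...)

  do_samples <- function(tb) filter_samples(tb, control$min_library,
                                            boundary = control$library_boundary)
  do_taxa <- function(tb) filter_taxa(tb, control$min_presence_frac,
                                      recompute_library = control$recompute_library)
  table <- if (control$filter_order == "samples_first")
    do_taxa(do_samples(table)) else do_samples(do_taxa(table))
  say(length(table$sample_ids), " samples and ", length(table$taxon_ids),
      " taxa after filtering; zero fraction ",
      sprintf("%.1f%%", 100 * zero_fraction(table)))
  if (length(table$taxon_ids) < 3L)
    caft_stop("fewer than 3 taxa after filtering", "caft_empty")

  # align metadata to table samples
  if (!id_column %in% names(metadata))
    caft_stop(paste0("metadata lacks id column '", id_column, "'"),
              "caft_bad_input")
  idx <- match(table$sample_ids, as.character(metadata[[id_column]]))
  if (anyNA(idx))
    caft_stop(paste0("samples missing from metadata: ",
                     paste(utils::head(table$sample_ids[is.na(idx)], 5),
                           collapse = ", ")), "caft_bad_input")
  if (length(idx) < nrow(metadata))
    say("metadata covers ", nrow(metadata), " samples; using the ",
        length(idx), " present in the count table")
  metadata <- metadata[idx, , drop = FALSE]

  if (length(intersect(interest, adjust)))
    caft_stop("interest and adjustment covariates overlap", "caft_bad_input")
  Xraw <- encode_covariates(metadata, c(interest, adjust), verbose = verbose)
  interest_cols <- which(colnames(Xraw) %in% colnames(
    encode_covariates(metadata, interest, verbose = FALSE)))
  design <- design_matrix(Xraw, interest = interest_cols)
  K <- ncol(design$X)
  d <- length(interest_cols)

  taxa <- table$taxon_ids
  J <- length(taxa)
  say("fitting ", J, " unrestricted Gehan models (K = ", K, ")")
  cens <- lapply(taxa, function(tx) to_censored(table, tx))
  fits <- lapply(cens, function(cz) {
    tryCatch(withCallingHandlers(
      fit_unrestricted(cz, design, options = control$solver),
      warning = function(w) invokeRestart("muffleWarning")),
      caft_not_estimable = function(e) NULL)
  })
  betas <- t(vapply(fits, function(f)
    if (is.null(f)) rep(NA_real_, K) else f$beta_hat, numeric(K)))
  ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  panel <- coefficient_panel(betas, ok, taxon_ids = taxa)

  Gamma <- diag(K)[design$interest_indices, , drop = FALSE]
  contrast0 <- contrast_spec(Gamma)
  contrast <- build_null_rhs(panel, contrast0)
  reference <- attr(contrast, "reference")
  say("compositional reference (median of interest coefficients): ",
      paste(sprintf("%.4f", reference), collapse = ", "))

  say("running restricted score tests")
  tests <- vector("list", J)
  for (j in seq_len(J)) {
    if (is.null(fits[[j]])) next
    ls0 <- if (control$warm_start && nrow(contrast$Lambda) > 0)
      as.vector(contrast$Lambda %*% fits[[j]]$beta_hat) else NULL
    tests[[j]] <- tryCatch(withCallingHandlers(
      score_test(cens[[j]], design, contrast, options = control$solver,
                 lambda_start = ls0),
      warning = function(w) invokeRestart("muffleWarning")),
      caft_not_estimable = function(e) NULL)
  }
  pvals <- vapply(tests, function(t)
    if (is.null(t)) NA_real_ else t$p_value, numeric(1))
  stats <- vapply(tests, function(t)
    if (is.null(t)) NA_real_ else t$statistic, numeric(1))
  qvals <- bh_adjust(pvals, na_in_m = control$na_in_m)

  res <- data.frame(taxon_id = taxa, stringsAsFactors = FALSE)
  for (k in seq_len(K))
    res[[paste0("beta.", design$covariate_names[k])]] <- betas[, k]
  for (i in seq_len(d)) {
    nm <- design$covariate_names[design$interest_indices[i]]
    res[[paste0("effect.", nm)]] <-
      -(betas[, design$interest_indices[i]] - reference[i])
  }
  res$stat <- stats
  res$df <- d
  res$pvalue <- pvals
  res$qvalue <- qvals
  res$detected <- !is.na(qvals) & qvals <= control$fdr_threshold
  res$converged <- ok & vapply(tests, function(t)
    !is.null(t) && t$converged, logical(1))
  res$n_present <- vapply(cens, function(cz) cz$n_present, numeric(1))
  say(sum(res$detected), " taxa detected at FDR ", control$fdr_threshold)

  structure(list(results = res, reference = setNames(
    reference, design$covariate_names[design$interest_indices]),
    control = control, design = design,
    n_samples = length(table$sample_ids), n_taxa = J,
    zero_fraction = zero_fraction(table)),
    class = "caft_result")
}

#' @export
print.caft_result <- function(x, ...) {
  cat(sprintf("CAFT analysis: %d samples, %d taxa (zero fraction %.1f%%)\n",
              x$n_samples, x$n_taxa, 100 * x$zero_fraction))
  cat("reference (median of interest coefficients): ",
      paste(sprintf("%s = %.4f", names(x$reference), x$reference),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("%d / %d taxa detected at FDR %.2g\n",
              sum(x$results$detected), nrow(x$results),
              x$control$fdr_threshold))
  invisible(x)
}

#' Operating characteristics against simulator truth
#'
#' Summarizes one or more CAFT runs on simulated data: the per-replicate
#' fraction of truly `x1`-null analyzed taxa with `p <= alpha` (type I
#' error), the false-discovery proportion among BH detections at
#' `fdr_target` (0 when nothing is detected), and the fraction of
#' `x1`-causal analyzed taxa detected (sensitivity), averaged over
#' replicates.
#'
#' @param results a `caft_result` or list of them.
#' @param truth a `caft_sim_truth` or list of them (same length).
#' @param alpha significance level for the type I error.
#' @param fdr_target BH target for FDR/sensitivity.
#' @return object of class `caft_performance`: `type_i_error`,
#'   `fdr_empirical`, `sensitivity`, `n_replicates`, `alpha`,
#'   `fdr_target`, and the `per_replicate` data frame.
#' @export
evaluate_performance <- function(results, truth, alpha = 0.05,
                                 fdr_target = 0.05) {
  if (inherits(results, "caft_result")) results <- list(results)
  if (inherits(truth, "caft_sim_truth")) truth <- list(truth)
  stopifnot(length(results) == length(truth))
  per <- lapply(seq_along(results), function(r) {
    res <- results[[r]]$results
    causal <- truth[[r]]$causal_x1
    is_causal <- res$taxon_id %in% causal
    tested <- !is.na(res$pvalue)
    nullt <- tested & !is_causal
    t1 <- if (any(nullt)) mean(res$pvalue[nullt] <= alpha) else NA_real_
    q <- bh_adjust(res$pvalue)
    det <- !is.na(q) & q <= fdr_target
    fdp <- if (any(det)) mean(!is_causal[det]) else 0
    sens <- if (any(tested & is_causal))
      mean(det[tested & is_causal]) else NA_real_
    data.frame(replicate = r, type_i = t1, fdp = fdp, sensitivity = sens)
  })
  per <- do.call(rbind, per)
  structure(list(type_i_error = mean(per$type_i, na.rm = TRUE),
                 fdr_empirical = mean(per$fdp, na.rm = TRUE),
                 sensitivity = mean(per$sensitivity, na.rm = TRUE),
                 n_replicates = nrow(per), alpha = alpha,
                 fdr_target = fdr_target, per_replicate = per),
            class = "caft_performance")
}

#' @export
print.caft_performance <- function(x, ...) {
  cat(sprintf(paste0("CAFT performance over %d replicates:\n",
                     "  type I error (alpha = %.2g): %.4f\n",
                     "  empirical FDR (target %.2g): %.4f\n",
                     "  sensitivity: %.4f\n"),
              x$n_replicates, x$alpha, x$type_i_error,
              x$fdr_target, x$fdr_empirical, x$sensitivity))
  invisible(x)
}

#' Simulate-analyze-evaluate benchmark loop
#'
#' Repeatedly simulates a study with [simulate_study()], analyzes it with
#' [run_caft()] (testing `x1` adjusted for `x2`), and scores the result
#' against the ground truth. Replicate `r` uses seed `seed + r - 1`, so a
#' whole benchmark is reproducible from its starting seed.
#'
#' @param n_replicates number of simulation replicates.
#' @param seed starting seed.
#' @param alpha,fdr_target evaluation settings.
#' @param control a [caft_control()]; the default uses the 6% prevalence
#'   filter of the package's simulation protocol.
#' @param keep_runs also return the per-replicate result objects.
#' @param verbose progress messages.
#' @param ... passed to [simulate_study()] (`n_samples`, `n_taxa`,
#'   `beta1`, `bias_exponent`, ...).
#' @return a `caft_performance` object; with `keep_runs = TRUE` the runs
#'   and truths are attached as attributes.
#' @export
caft_benchmark <- function(n_replicates = 50, seed = 1, alpha = 0.05,
                           fdr_target = 0.05,
                           control = caft_control(min_presence_frac = 0.06),
                           keep_runs = FALSE, verbose = FALSE, ...) {
  runs <- vector("list", n_replicates)
  truths <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_study(seed = seed + r - 1, ...)
    runs[[r]] <- run_caft(sim$table, sim$metadata, interest = "x1",
                          adjust = "x2", control = control, verbose = FALSE)
    truths[[r]] <- sim$truth
    if (verbose) message("replicate ", r, "/", n_replicates, " done")
  }
  perf <- evaluate_performance(runs, truths, alpha = alpha,
                               fdr_target = fdr_target)
  if (keep_runs) {
    attr(perf, "runs") <- runs
    attr(perf, "truths") <- truths
  }
  perf
}
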