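#' Construct a microbiome count table
#'
#' Bundles a non-negative integer count matrix with sample and taxon
#' identifiers and per-sample library sizes. Counts are stored internally as
#' a samples x taxa matrix regardless of input orientation. Library sizes
#' are the row sums of the full table at construction time; they are the
#' sequencing depths that define the detection limit `1/N_i` for each
#' sample and are deliberately *not* recomputed when taxa are later
#' filtered out (see [filter_taxa()]).
#'
#' @param counts integer matrix of read counts. By default rows are samples
#'   and columns are taxa; set `taxa_as_rows = TRUE` for the common
#'   OTU-table orientation (taxa in rows).
#' @param taxa_as_rows logical; if `TRUE`, `counts` is transposed on input.
#' @param sample_ids,taxon_ids optional identifier vectors; defaults are
#'   taken from dimnames or generated.
#' @param library_sizes optional per-sample depths; defaults to row sums.
#'   Supplying them explicitly preserves pre-filtering depths.
#' @return an object of class `caft_count_table` with elements `counts`
#'   (samples x taxa integer matrix), `sample_ids`, `taxon_ids`,
#'   `library_sizes`.
#' @export
count_table <- function(counts, taxa_as_rows = FALSE,
                        sample_ids = NULL, taxon_ids = NULL,
                        library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (taxa_as_rows) counts <- t(counts)
  if (any(is.na(counts))) caft_stop("counts contain missing values", "caft_bad_input")
  if (any(counts < 0)) caft_stop("counts must be non-negative", "caft_bad_input")
  if (any(counts != round(counts)))
    caft_stop("counts must be integers (no normalized or fractional tables)",
              "caft_bad_input")
  storage.mode(counts) <- "double" # holds integers exactly; avoids overflow on sums
  if (is.null(sample_ids)) sample_ids <- rownames(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- colnames(counts)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (anyDuplicated(sample_ids))
    caft_stop(paste0("duplicated sample id: ",
                     sample_ids[duplicated(sample_ids)][1]), "caft_bad_input")
  if (anyDuplicated(taxon_ids))
    caft_stop(paste0("duplicated taxon id: ",
                     taxon_ids[duplicated(taxon_ids)][1]), "caft_bad_input")
  if (length(sample_ids) != nrow(counts) || length(taxon_ids) != ncol(counts))
    caft_stop("identifier lengths do not match count matrix", "caft_bad_input")
  if (is.null(library_sizes)) library_sizes <- rowSums(counts)
  if (length(library_sizes) != nrow(counts) || any(library_sizes <= 0))
    caft_stop("library sizes must be positive, one per sample", "caft_bad_input")
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(list(counts = counts, sample_ids = sample_ids,
                 taxon_ids = taxon_ids,
                 library_sizes = setNames(as.numeric(library_sizes), sample_ids)),
            class = "caft_count_table")
}

#' @export
print.caft_count_table <- function(x, ...) {
  cat(sprintf("caft count table: %d samples x %d taxa\n",
              length(x$sample_ids), length(x$taxon_ids)))
  cat(sprintf("  library sizes: %s..%s (median %s)\n",
              format(min(x$library_sizes)), format(max(x$library_sizes)),
              format(median(x$library_sizes))))
  cat(sprintf("  zero cells: %.1f%%\n", 100 * zero_fraction(x)))
  invisible(x)
}

#' @export
dim.caft_count_table <- function(x) dim(x$counts)

#' Fraction of zero cells in a count table
#'
#' @param table a [count_table()] object.
#' @return the proportion of zero entries, in `[0, 1]`.
#' @export
zero_fraction <- function(table) {
  stopifnot(inherits(table, "caft_count_table"))
  if (length(table$counts) == 0L) caft_stop("empty count table", "caft_empty")
  mean(table$counts == 0)
}

#' Remove shallow samples from a count table
#'
#' Retains samples whose library size meets a minimum sequencing depth.
#' Depth comparisons use the library sizes carried by the table (the
#' original row sums), not any post-filtering subtotal.
#'
#' @param table a [count_table()] object.
#' @param min_library minimum depth (>= 1).
#' @param boundary `"keep"` retains samples with `N == min_library`
#'   (samples strictly below the threshold are removed); `"drop"` removes
#'   them as well (`N <= min_library` excluded).
#' @return the filtered `caft_count_table`; sample order preserved.
#' @export
filter_samples <- function(table, min_library = 3000,
                           boundary = c("keep", "drop")) {
  stopifnot(inherits(table, "caft_count_table"), min_library >= 1)
  boundary <- match.arg(boundary)
  keep <- if (boundary == "keep") table$library_sizes >= min_library
          else table$library_sizes > min_library
  if (!any(keep))
    caft_stop("no samples meet the library-size threshold", "caft_empty")
  subset_table(table, samples = which(keep))
}

#' Remove rare taxa from a count table
#'
#' Retains taxa that are present (non-zero) in at least a given fraction of
#' the current samples. Taxa absent from every sample are always removed.
#' Library sizes are not recomputed: the censoring bound `log N_i` must
#' reflect sequencing depth, not the post-filter subtotal (a
#' `recompute_library` switch is available but off by default).
#'
#' @param table a [count_table()] object.
#' @param min_presence_frac required presence fraction in `(0, 1]`; a taxon
#'   present in exactly that fraction of samples is kept.
#' @param recompute_library logical; if `TRUE`, library sizes are reset to
#'   the row sums of the filtered table.
#' @return the filtered `caft_count_table` (possibly with zero taxa).
#' @export
filter_taxa <- function(table, min_presence_frac = 0.1,
                        recompute_library = FALSE) {
  stopifnot(inherits(table, "caft_count_table"),
            min_presence_frac > 0, min_presence_frac <= 1)
  if (length(table$sample_ids) == 0L) caft_stop("empty count table", "caft_empty")
  presence <- colMeans(table$counts > 0)
  keep <- presence >= min_presence_frac & presence > 0
  out <- subset_table(table, taxa = which(keep))
  if (recompute_library) {
    out$library_sizes <- setNames(rowSums(out$counts), out$sample_ids)
    if (any(out$library_sizes <= 0))
      caft_stop("recomputed library sizes include zero; filter samples first",
                "caft_empty")
  }
  out
}

subset_table <- function(table, samples = NULL, taxa = NULL) {
  if (!is.null(samples)) {
    table$counts <- table$counts[samples, , drop = FALSE]
    table$sample_ids <- table$sample_ids[samples]
    table$library_sizes <- table$library_sizes[samples]
  }
  if (!is.null(taxa)) {
    table$counts <- table$counts[, taxa, drop = FALSE]
    table$taxon_ids <- table$taxon_ids[taxa]
  }
  table
}

#' Censoring transform for one taxon
#'
#' Converts counts for one taxon into the censored negative log relative
#' abundance used by the accelerated failure time model: with
#' `pi_hat = C_ij / N_i`, the response is `tau_ij = -log(pi_hat)` when
#' `C_ij > 0`, and a zero count is right-censored at the detection limit,
#' `tau_ij = log(N_i)` with censoring indicator `delta = 0`. Natural
#' logarithms throughout.
#'
#' @param table a [count_table()] object.
#' @param taxon a taxon identifier present in the table.
#' @return an object of class `caft_censored` with fields `tau`, `delta`
#'   (1 = observed, 0 = censored), `taxon_id`, and `n_present`.
#' @export
to_censored <- function(table, taxon) {
  stopifnot(inherits(table, "caft_count_table"))
  j <- match(as.character(taxon), table$taxon_ids)
  if (is.na(j)) caft_stop(paste0("unknown taxon id: ", taxon), "caft_bad_input")
  cj <- table$counts[, j]
  N <- table$library_sizes
  delta <- as.integer(cj > 0)
  tau <- ifelse(delta == 1L, -log(cj / N), log(N))
  structure(list(tau = as.numeric(tau), delta = delta,
                 taxon_id = table$taxon_ids[j],
                 n_present = sum(delta)),
            class = "caft_censored")
}
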