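#' Read a count table from TSV/CSV or BIOM
#'
#' Delimited tables must have a header row and an id column in the first
#' position; the delimiter is taken from the file extension (`.csv` =>
#' comma, otherwise tab). `.biom` files (JSON or HDF5 dialect) are read via
#' the biomformat package and converted. Non-integer or negative entries
#' are rejected; duplicated identifiers raise an error naming the
#' offender. The default orientation is taxa as rows (the dominant
#' OTU-table convention).
#'
#' @param path file path.
#' @param taxa_as_rows orientation of a delimited table (ignored for BIOM
#'   files, where observations are always taxa in rows).
#' @return a [count_table()] object (samples x taxa internally).
#' @export
read_count_table <- function(path, taxa_as_rows = TRUE) {
  if (!file.exists(path)) caft_stop(paste0("file not found: ", path),
                                    "caft_bad_input")
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      caft_stop("reading BIOM files requires the biomformat package",
                "caft_bad_input")
    bm <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(bm)) # observations (taxa) x samples
    return(count_table(m, taxa_as_rows = TRUE))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "",
                   quote = "\"")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    caft_stop(paste0("duplicated ", if (taxa_as_rows) "taxon" else "sample",
                     " id: ", ids[duplicated(ids)][1]), "caft_bad_input")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    caft_stop("count table contains non-numeric entries", "caft_bad_input")
  rownames(m) <- ids
  count_table(m, taxa_as_rows = taxa_as_rows)
}

#' Write a count table to TSV
#'
#' Written taxa-as-rows with an `taxon_id` header on the id column;
#' [read_count_table()] on the output round-trips the object.
#'
#' @param table a [count_table()] object.
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "caft_count_table"))
  m <- t(table$counts)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV/CSV path (delimiter from extension).
#' @param sample_id_column name of the sample identifier column.
#' @return data frame with the id column coerced to character.
#' @export
read_metadata <- function(path, sample_id_column = "sample_id") {
  if (!file.exists(path)) caft_stop(paste0("file not found: ", path),
                                    "caft_bad_input")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "", quote = "\"")
  if (!sample_id_column %in% names(df))
    caft_stop(paste0("metadata lacks column '", sample_id_column, "'"),
              "caft_bad_input")
  df[[sample_id_column]] <- as.character(df[[sample_id_column]])
  if (anyDuplicated(df[[sample_id_column]]))
    caft_stop("duplicated sample ids in metadata", "caft_bad_input")
  df
}

#' Write CAFT results as TSV with a JSON run-metadata sidecar
#'
#' The results table is written with its stable column order; a
#' `<path>.meta.json` sidecar records filters, the compositional reference
#' value, dimensions and the FDR threshold.
#'
#' @param result a `caft_result` from [run_caft()].
#' @param path output TSV path.
#' @param seed optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, seed = NULL) {
  stopifnot(inherits(result, "caft_result"))
  write.table(result$results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(
    n_samples = result$n_samples, n_taxa = result$n_taxa,
    zero_fraction = result$zero_fraction,
    reference = as.list(result$reference),
    filters = list(min_library = result$control$min_library,
                   library_boundary = result$control$library_boundary,
                   min_presence_frac = result$control$min_presence_frac,
                   filter_order = result$control$filter_order),
    fdr_threshold = result$control$fdr_threshold,
    variance_estimator = result$control$variance_estimator,
    seed = seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
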