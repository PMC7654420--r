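#' Read a gene-by-sample expression matrix from TSV/CSV
#'
#' Reads a delimited text file into the canonical genes-in-rows orientation.
#' The first column holds feature (gene or probe) identifiers and the header
#' row holds sample identifiers; `orientation = "samples_in_rows"` reads the
#' transposed dialect. Every data cell must parse as a finite number: missing
#' or malformed cells are an error (no imputation), reported with their row
#' and column identifiers.
#'
#' Duplicate identifiers on either axis are rejected here; duplicated probes
#' or repeated patient records must be resolved explicitly through
#' [collapse_duplicates()] with a mapping, never silently at read time.
#'
#' @param path Path to the file.
#' @param format `"tsv"`, `"csv"`, or `"auto"` (by file extension, default).
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return A numeric matrix, genes in rows, with unique `rownames` (gene ids)
#'   and `colnames` (sample ids).
#' @export
read_expression <- function(path,
                            format = c("auto", "tsv", "csv"),
                            orientation = c("genes_in_rows", "samples_in_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- switch(format,
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
    tsv = "\t",
    csv = ","
  )
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, check.names = FALSE,
    colClasses = "character", quote = "\"", comment.char = ""
  )
  if (ncol(raw) < 2L) stop("expression file needs an id column plus >=1 data column: ", path)
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  if (anyDuplicated(col_ids)) {
    stop(
      "duplicate column identifiers in ", path, ": ",
      paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "),
      " (resolve duplicates with collapse_duplicates() and an explicit mapping)"
    )
  }
  if (anyDuplicated(row_ids)) {
    stop(
      "duplicate row identifiers in ", path, ": ",
      paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
      " (resolve duplicates with collapse_duplicates() and an explicit mapping)"
    )
  }
  vals <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(row_ids, col_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(
      "non-numeric or missing cell in ", path, " at row '",
      row_ids[bad[1L, 1L]], "', column '", col_ids[bad[1L, 2L]], "'"
    )
  }
  if (orientation == "samples_in_rows") vals <- t(vals)
  vals
}

#' Read a clinical table with survival times
#'
#' Expects columns `sample_id`, `time`, `event` plus optional covariates
#' (`age`, `gender`, `grade`, `stage`, ...). Times are converted to years
#' internally (the 1-year ROC horizon fixes the natural unit); the unit of
#' the file is declared via `time_unit`, not guessed.
#'
#' @param path Path to the TSV/CSV file.
#' @param time_unit Unit of the `time` column: `"years"`, `"months"`, `"days"`.
#' @param format `"tsv"`, `"csv"`, or `"auto"` (default, by extension).
#' @return A `data.frame` with `sample_id`, `time` (years), integer `event`
#'   (1 = dead, 0 = censored) and any covariate columns.
#' @export
read_clinical <- function(path, time_unit = c("years", "months", "days"),
                          format = c("auto", "tsv", "csv")) {
  time_unit <- match.arg(time_unit)
  format <- match.arg(format)
  if (!file.exists(path)) stop("clinical file not found: ", path)
  sep <- switch(format,
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
    tsv = "\t",
    csv = ","
  )
  clin <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "\"")
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(clin))
  if (length(miss) > 0L) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  clin$sample_id <- as.character(clin$sample_id)
  clin$time <- as.numeric(clin$time)
  clin$event <- as.integer(clin$event)
  validate_clinical(clin)
  clin$time <- clin$time / switch(time_unit, years = 1, months = 12, days = 365.25)
  clin
}

validate_clinical <- function(clin) {
  if (anyDuplicated(clin$sample_id)) {
    stop("duplicate sample_id in clinical table: ",
         paste(unique(clin$sample_id[duplicated(clin$sample_id)]), collapse = ", "))
  }
  if (any(!is.finite(clin$time)) || any(clin$time <= 0)) {
    stop("clinical times must be finite and > 0")
  }
  if (!all(clin$event %in% c(0L, 1L))) stop("event must be 0 (censored) or 1 (dead)")
  invisible(clin)
}

#' Read a gene list (one symbol per line)
#'
#' Lines starting with `#` and blank lines are ignored; duplicates are
#' collapsed. Matching downstream is case-sensitive exact string equality.
#'
#' @param path Path to the plain-text list.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x <- unique(x[nzchar(x)])
  if (length(x) == 0L) stop("gene list is empty: ", path)
  x
}

#' Collapse duplicate probes and repeated patient records by averaging
#'
#' Multiple probes mapping to one gene are replaced by their arithmetic mean
#' per sample; multiple expression records of one patient are replaced by
#' their per-gene mean. Identity (no-op) collapsing is the default on each
#' axis.
#'
#' @param m Numeric genes-x-samples matrix with row/column names.
#' @param gene_map Named character vector `probe -> gene`, or `NULL` for
#'   identity. Every row of `m` must appear among its names.
#' @param sample_map Named character vector `record -> patient`, or `NULL`
#'   for identity. Every column of `m` must appear among its names.
#' @return Numeric matrix with unique gene rows and patient columns, in
#'   first-appearance order of the mapped ids.
#' @export
collapse_duplicates <- function(m, gene_map = NULL, sample_map = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (!is.null(gene_map)) {
    missing_rows <- setdiff(rownames(m), names(gene_map))
    if (length(missing_rows) > 0L) {
      stop("probes absent from gene_map: ", paste(utils::head(missing_rows, 5L), collapse = ", "))
    }
    grp <- factor(gene_map[rownames(m)], levels = unique(gene_map[rownames(m)]))
    m <- rowsum(m, grp, reorder = FALSE) / as.vector(table(grp))
  }
  if (!is.null(sample_map)) {
    missing_cols <- setdiff(colnames(m), names(sample_map))
    if (length(missing_cols) > 0L) {
      stop("records absent from sample_map: ", paste(utils::head(missing_cols, 5L), collapse = ", "))
    }
    grp <- factor(sample_map[colnames(m)], levels = unique(sample_map[colnames(m)]))
    m <- t(rowsum(t(m), grp, reorder = FALSE) / as.vector(table(grp)))
  }
  m
}

#' Restrict an expression matrix to a gene list
#'
#' Keeps the genes present in both the matrix and the list, preserving the
#' matrix's gene order; sample columns are untouched.
#'
#' @param m Genes-x-samples matrix.
#' @param genes Character vector of gene symbols (e.g. an immune-gene list).
#' @return The restricted matrix.
#' @export
restrict_to_gene_list <- function(m, genes) {
  keep <- rownames(m) %in% genes
  if (!any(keep)) stop("no genes in the matrix match the gene list")
  m[keep, , drop = FALSE]
}

#' Align an expression matrix and a clinical table on shared samples
#'
#' Both returns are restricted to the intersection of sample ids and put in
#' the same order (the expression matrix's column order restricted to the
#' intersection), so row `i` of the clinical table describes column `i` of
#' the matrix.
#'
#' @param m Genes-x-samples matrix.
#' @param clin Clinical `data.frame` with a `sample_id` column.
#' @return `list(expression = , clinical = )`.
#' @export
align_cohort <- function(m, clin) {
  shared <- intersect(colnames(m), clin$sample_id)
  if (length(shared) == 0L) stop("expression and clinical tables share no samples")
  ord <- colnames(m)[colnames(m) %in% shared]
  clin2 <- clin[match(ord, clin$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expression = m[, ord, drop = FALSE], clinical = clin2)
}
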