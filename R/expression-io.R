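#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; all remaining cells must be numeric (missing values are an
#' error, not imputed). Duplicate gene identifiers are handled according to
#' `collapse`: `"median"` collapses duplicates to the per-sample median (the
#' rule used for multiple array probe sets mapping to one gene), `"error"`
#' refuses them.
#'
#' @param path File path.
#' @param collapse Duplicate-gene policy: `"median"` or `"error"`.
#' @return Numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression <- function(path, collapse = c("median", "error")) {
  collapse <- match.arg(collapse)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("expression file is empty: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (length(sample_ids) < 1L) stop("no sample columns in ", path)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(body)
  bad <- which(widths != length(sample_ids) + 1L)
  if (length(bad)) {
    stop(sprintf("ragged row at line %d of %s (expected %d fields, got %d)",
                 bad[1] + 1L, path, length(sample_ids) + 1L, widths[bad[1]]))
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    suppressWarnings(row <- as.numeric(body[[i]][-1]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1]
      stop(sprintf("non-numeric or blank cell at line %d, column '%s' (gene '%s') of %s",
                   i + 1L, sample_ids[j], gene_ids[i], path))
    }
    vals[i, ] <- row
  }
  if (anyDuplicated(gene_ids)) {
    if (collapse == "error") {
      stop("duplicate gene ids in ", path, ": ",
           paste(head(unique(gene_ids[duplicated(gene_ids)])), collapse = ", "))
    }
    vals <- collapse_duplicate_genes(vals)
  }
  vals
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  check_expression(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grngpea %s expression genes=%d samples=%d",
                     as.character(packageVersion("grngpea")),
                     nrow(m), ncol(m)), con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 15), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

check_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyNA(m)) stop("expression matrix contains missing values")
  invisible(m)
}

#' Natural-log transform counts as log(1 + x)
#'
#' The standard variance-stabilizing transform applied to normalized RNAseq
#' count values before correlation-based network inference.
#'
#' @param m Numeric expression matrix with non-negative values.
#' @return Matrix of the same shape with each value `x` replaced by
#'   `log(1 + x)`.
#' @export
log1p_transform <- function(m) {
  check_expression(m)
  if (any(m < 0)) stop("log1p_transform requires non-negative values")
  log1p(m)
}

#' Remove genes with zero standard deviation
#'
#' Constant genes carry no dependency information and break the Pearson
#' correlation; they are removed before inference. Row order is preserved.
#'
#' @param m Numeric expression matrix.
#' @return The submatrix of rows with sample standard deviation > 0.
#' @export
drop_zero_sd_genes <- function(m) {
  check_expression(m)
  sds <- apply(m, 1, sd)
  keep <- sds > 0
  if (!any(keep)) stop("all genes have zero standard deviation")
  m[keep, , drop = FALSE]
}

#' Collapse duplicate gene rows by the per-sample median
#'
#' When several rows (e.g. probe sets) share a gene identifier, each sample's
#' value becomes the median over the duplicate rows. Gene order follows the
#' first occurrence of each identifier.
#'
#' @param m Numeric expression matrix (duplicate rownames allowed).
#' @param stat Collapse statistic; only `"median"` is supported.
#' @return Matrix with one row per unique gene identifier.
#' @export
collapse_duplicate_genes <- function(m, stat = "median") {
  if (!identical(stat, "median")) {
    stop("unsupported collapse statistic: ", stat)
  }
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  ids <- rownames(m)
  if (is.null(ids)) stop("expression matrix needs gene rownames")
  if (!anyDuplicated(ids)) return(m)
  uniq <- unique(ids)
  out <- matrix(NA_real_, nrow = length(uniq), ncol = ncol(m),
                dimnames = list(uniq, colnames(m)))
  for (g in uniq) {
    rows <- m[ids == g, , drop = FALSE]
    out[g, ] <- if (nrow(rows) == 1L) rows[1, ] else apply(rows, 2, median)
  }
  out
}
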