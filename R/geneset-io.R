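#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene identifiers); members
#'   are deduplicated.
#' @param kind Provenance label: `"functional"`, `"family"` or `"genomic"`.
#' @param description Optional named character vector of per-set descriptions
#'   (for genomic windows: `"chrom:start-end"`).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, kind = c("functional", "family", "genomic"),
                                description = NULL) {
  kind <- match.arg(kind)
  if (length(sets) == 0L) {
    return(structure(list(sets = setNames(list(), character()), kind = kind,
                          description = setNames(character(), character())),
                     class = "gene_set_collection"))
  }
  if (is.null(names(sets)) || any(names(sets) == "") || anyDuplicated(names(sets))) {
    stop("sets must have unique non-empty names")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) < 1L)) stop("gene sets must have at least one member")
  if (is.null(description)) {
    description <- setNames(rep("", length(sets)), names(sets))
  }
  description <- description[names(sets)]
  description[is.na(description)] <- ""
  names(description) <- names(sets)
  structure(list(sets = sets, kind = kind, description = description),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection (%s): %d sets, sizes %s\n", x$kind,
              length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a line are deduplicated.
#'
#' @param path File path.
#' @param kind Provenance label attached to the collection.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, kind = "functional") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("GMT set with no members at line %d of %s", bad[1], path))
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  gene_set_collection(setNames(sets, nms), kind = kind,
                      description = setNames(desc, nms))
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A `gene_set_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene genomic coordinates from a BED-like TSV
#'
#' Four columns: chromosome, start, end, gene identifier. Coordinates are
#' 0-based half-open (BED convention); pass `one_based = TRUE` to convert a
#' 1-based inclusive dialect at the boundary.
#'
#' @param path File path.
#' @param one_based Whether the file uses 1-based inclusive coordinates.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_annotation <- function(path, one_based = FALSE) {
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "gene_id"),
                    colClasses = c("character", "numeric", "numeric", "character"))
  if (one_based) raw$start <- raw$start - 1
  ann <- data.frame(gene_id = raw$gene_id, chrom = raw$chrom,
                    start = raw$start, end = raw$end,
                    stringsAsFactors = FALSE)
  check_annotation(ann)
  ann
}

#' Write gene coordinates to a BED-like TSV
#'
#' @param ann Annotation data frame (`gene_id`, `chrom`, `start`, `end`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  check_annotation(ann)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grngpea %s annotation genes=%d (0-based half-open)",
                     as.character(packageVersion("grngpea")), nrow(ann)), con)
  write.table(ann[, c("chrom", "start", "end", "gene_id")], con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_annotation <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("gene_id", "chrom", "start", "end") %in% names(ann)))
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotation")
  if (any(ann$start < 0)) stop("negative start coordinate")
  if (any(ann$start >= ann$end)) stop("annotation requires start < end")
  invisible(ann)
}
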