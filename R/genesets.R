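#' Gene sets of co-located genes from genomic sliding windows
#'
#' Tiles every chromosome with windows of `window_bp` starting at
#' 0, `step_bp`, `2*step_bp`, ... A gene belongs to a window iff its start
#' coordinate lies in `[w, w + window_bp)`; with the default 1 Mb windows
#' every 500 kb, every gene falls in exactly two windows except within the
#' first step of a chromosome. Windows with fewer than `min_genes` members
#' are dropped. The window location is recorded in the set description as
#' `"chrom:start-end"`.
#'
#' @param ann Annotation data frame (`gene_id`, `chrom`, `start`, `end`).
#' @param window_bp Window size in bp (default 1 Mb).
#' @param step_bp Step between window starts (default 500 kb); must be
#'   smaller than `window_bp`.
#' @param min_genes Minimum members for a window to be kept.
#' @return A `gene_set_collection` of kind `"genomic"`.
#' @export
window_gene_sets <- function(ann, window_bp = 1000000L, step_bp = 500000L,
                             min_genes = 3L) {
  check_annotation(ann)
  if (!nrow(ann)) stop("empty annotation")
  if (!(window_bp > step_bp && step_bp > 0)) {
    stop("window_bp must exceed step_bp and step_bp must be positive")
  }
  sets <- list(); desc <- character()
  for (chr in unique(ann$chrom)) {
    sub <- ann[ann$chrom == chr, , drop = FALSE]
    max_start <- max(sub$start)
    w_starts <- seq(0, max_start, by = step_bp)
    for (w in w_starts) {
      members <- sub$gene_id[sub$start >= w & sub$start < w + window_bp]
      if (length(members) >= min_genes) {
        nm <- sprintf("%s_w%010d", chr, as.integer(w))
        sets[[nm]] <- members
        desc[nm] <- sprintf("%s:%d-%d", chr, as.integer(w),
                            as.integer(w + window_bp))
      }
    }
  }
  if (!length(sets)) stop("no window contains >= ", min_genes, " genes")
  gene_set_collection(sets, kind = "genomic", description = desc)
}

#' Filter a gene-set collection against a universe and size bounds
#'
#' Members are first intersected with `universe` (so enrichment only counts
#' testable genes), then sets outside `[min_genes, max_genes)` are dropped;
#' the upper bound is exclusive, matching the usual "fewer than 1000 genes"
#' convention for functional terms.
#'
#' @param collection A `gene_set_collection`.
#' @param min_genes Minimum (inclusive) set size after intersection.
#' @param max_genes Exclusive upper bound on set size (`Inf` for none).
#' @param universe Optional character vector of admissible gene identifiers.
#' @return The filtered `gene_set_collection`; the number of dropped sets is
#'   attached as attribute `n_dropped`.
#' @export
filter_collection <- function(collection, min_genes = 3L, max_genes = Inf,
                              universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (min_genes < 1L) stop("min_genes must be >= 1")
  sets <- collection$sets
  if (!is.null(universe)) {
    sets <- lapply(sets, function(s) intersect(s, universe))
  }
  sizes <- lengths(sets)
  keep <- sizes >= min_genes & sizes < max_genes
  out <- gene_set_collection(
    sets[keep], kind = collection$kind,
    description = collection$description[names(sets)[keep]]
  )
  attr(out, "n_dropped") <- sum(!keep)
  out
}
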