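#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Resolve gene symbols to stable identifiers
#'
#' Maps gene symbols to gene ids through an annotation table. When a symbol
#' maps to several ids, the first match in annotation order wins (the
#' ambiguity is surfaced by [validate_bundle()]).
#'
#' @param symbols character vector of gene symbols.
#' @param annotation data frame with columns `gene_id`, `gene_name`.
#' @return character vector of gene ids, `NA` where a symbol is unresolvable.
#' @export
resolve_symbols <- function(symbols, annotation) {
  idx <- match(symbols, annotation$gene_name)
  ids <- annotation$gene_id[idx]
  names(ids) <- symbols
  ids
}

# padj with NA treated as 1 (conservative: filtered genes are never DE)
effective_padj <- function(de) {
  p <- de$padj
  p[is.na(p)] <- 1
  p
}

#' Identify differentially expressed genes
#'
#' DE calling rule used throughout the package: `padj <= de_threshold`,
#' with missing `padj` treated as 1. Direction is the sign of `log2fc`.
#'
#' @param de DE result table (`gene_id`, `log2fc`, `pvalue`, `padj`).
#' @param de_threshold adjusted p-value cutoff (default 0.05).
#' @return data frame with `gene_id`, `log2fc`, logical `is_de` and
#'   `direction` in `{-1, 0, 1}`.
#' @export
de_status <- function(de, de_threshold = 0.05) {
  data.frame(
    gene_id = de$gene_id,
    log2fc = de$log2fc,
    is_de = effective_padj(de) <= de_threshold,
    direction = sign(de$log2fc),
    stringsAsFactors = FALSE
  )
}

# deterministic ranking of genesets: gs_pvalue ascending, ties by larger
# gs_de_count, then lexicographic gs_id
geneset_order <- function(enrichment) {
  de_count <- enrichment$gs_de_count
  if (is.null(de_count)) de_count <- rep(0L, nrow(enrichment))
  de_count[is.na(de_count)] <- 0L
  order(enrichment$gs_pvalue, -de_count, enrichment$gs_id)
}

#' Select the top genesets by significance
#'
#' @param enrichment an enrichment table.
#' @param n_gs number of genesets to keep; clamped (with a warning) to the
#'   table size.
#' @return the `n_gs` most significant rows, ties broken by larger
#'   `gs_de_count` then lexicographic `gs_id`.
#' @export
top_genesets <- function(enrichment, n_gs) {
  if (n_gs < 1) stopf("n_gs must be >= 1")
  if (n_gs > nrow(enrichment)) {
    warnf("n_gs = %d exceeds table size %d; clamping", n_gs, nrow(enrichment))
    n_gs <- nrow(enrichment)
  }
  enrichment[geneset_order(enrichment)[seq_len(n_gs)], , drop = FALSE]
}
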