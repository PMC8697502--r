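# Every visual summary is backed by a plot_data object: the coordinates,
# orderings and labels are the tested surface; rendering is a thin layer on
# top and never alters the data.

new_plot_data <- function(kind, data, labels = character(0),
                          aesthetics = list(), extra = list()) {
  structure(c(list(kind = kind, data = data, labels = labels,
                   aesthetics = aesthetics), extra),
            class = "plot_data")
}

#' @export
print.plot_data <- function(x, ...) {
  n <- if (is.matrix(x$data)) paste(dim(x$data), collapse = " x ")
       else nrow(x$data)
  cat(sprintf("plot_data '%s': %s records, %d labels\n", x$kind, n,
              length(x$labels)))
  invisible(x)
}

#' Geneset volcano plot data
#'
#' One point per geneset: x = chosen aggregate score, y = -log10 of the
#' harmonized p-value, size = `gs_de_count`. The `n_labels` smallest
#' p-values are labeled. Genesets with a missing score are excluded with a
#' warning.
#'
#' @param enrichment an [enrichment_table()] with scores computed.
#' @param x `"z_score"` or `"aggr_score"`.
#' @param n_labels number of genesets to label (default 5).
#' @return a `plot_data` with columns gs_id, x, y, size.
#' @export
gs_volcano_data <- function(enrichment, x = c("z_score", "aggr_score"),
                            n_labels = 5) {
  x <- match.arg(x)
  if (all(is.na(enrichment[[x]])))
    stopf("column '%s' is empty: run compute_aggregate_scores() first", x)
  keep <- !is.na(enrichment[[x]])
  if (!all(keep))
    warnf("excluding %d geneset(s) with missing %s", sum(!keep), x)
  enr <- enrichment[keep, , drop = FALSE]
  df <- data.frame(gs_id = enr$gs_id,
                   x = enr[[x]],
                   y = -log10(enr$gs_pvalue),
                   size = enr$gs_de_count,
                   stringsAsFactors = FALSE)
  labels <- enr$gs_id[geneset_order(enr)][seq_len(min(n_labels, nrow(enr)))]
  new_plot_data("gs_volcano", df, labels,
                aesthetics = list(x = x, y = "neg_log10_p", size = "gs_de_count"))
}

#' Per-gene contribution strip data
#'
#' One point per (geneset, DE member): x = the member's log2 fold change,
#' y = the geneset's row index in significance order. A gene belonging to
#' several of the top sets contributes one point per set; a set with no DE
#' member keeps its (pointless) row.
#'
#' @param enrichment an [enrichment_table()].
#' @param de DE result table.
#' @param annotation gene annotation table.
#' @param n_gs number of top genesets (default 15).
#' @param de_threshold adjusted p-value cutoff.
#' @return a `plot_data`; `data` has gs_id, gene_id, symbol, x (log2fc),
#'   y (row index); extra element `rows` gives the row order.
#' @export
enhanced_table_data <- function(enrichment, de, annotation, n_gs = 15,
                                de_threshold = 0.05) {
  enr <- top_genesets(enrichment, n_gs)
  st <- de_status(de, de_threshold)
  pts <- do.call(rbind, lapply(seq_len(nrow(enr)), function(k) {
    ids <- resolve_symbols(enr$gs_genes[[k]], annotation)
    ids <- unique(ids[!is.na(ids)])
    idx <- match(ids, st$gene_id)
    ok <- !is.na(idx) & st$is_de[idx]
    if (!any(ok)) return(NULL)
    data.frame(gs_id = enr$gs_id[k], gene_id = ids[ok],
               symbol = annotation$gene_name[match(ids[ok], annotation$gene_id)],
               x = st$log2fc[idx[ok]], y = k, stringsAsFactors = FALSE)
  }))
  if (is.null(pts))
    pts <- data.frame(gs_id = character(0), gene_id = character(0),
                      symbol = character(0), x = numeric(0), y = integer(0))
  new_plot_data("enhanced_table", pts,
                aesthetics = list(x = "log2fc", y = "geneset_rank"),
                extra = list(rows = enr$gs_id))
}

#' Geneset score heatmap data
#'
#' Passes the geneset-by-sample score matrix through unchanged and attaches
#' row/column orders: average-linkage hierarchical clustering on euclidean
#' distance when requested, otherwise the input order.
#'
#' @param scores a `geneset_scores` from [compute_geneset_scores()].
#' @param cluster_rows,cluster_cols cluster the respective margin.
#' @return a `plot_data` with `data` = the matrix, `row_order`, `col_order`.
#' @export
scores_heatmap_data <- function(scores, cluster_rows = TRUE,
                                cluster_cols = TRUE) {
  m <- scores$values
  if (nrow(m) == 0) stopf("empty score matrix")
  row_order <- seq_len(nrow(m))
  col_order <- seq_len(ncol(m))
  if (cluster_rows && nrow(m) > 1)
    row_order <- stats::hclust(stats::dist(m), method = "average")$order
  if (cluster_cols && ncol(m) > 1)
    col_order <- stats::hclust(stats::dist(t(m)), method = "average")$order
  new_plot_data("scores_heatmap", m,
                aesthetics = list(fill = "geneset_score"),
                extra = list(row_order = row_order, col_order = col_order))
}

#' Geneset-by-gene membership/effect matrix data
#'
#' Matrix with one row per top geneset and one column per gene in the union
#' of their DE members; a cell holds the member's log2 fold change, or NA
#' when the gene is not a member of that set. Columns are ordered by the
#' number of sets containing the gene, descending (ties by gene id), which
#' exposes the redundancy between sets.
#'
#' @inheritParams enhanced_table_data
#' @return a `plot_data` with `data` = genesets x genes matrix.
#' @export
summary_heat_data <- function(enrichment, de, annotation, n_gs = 15,
                              de_threshold = 0.05) {
  etd <- enhanced_table_data(enrichment, de, annotation, n_gs, de_threshold)
  pts <- etd$data
  rows <- etd$rows
  genes <- unique(pts$gene_id)
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(genes),
              dimnames = list(rows, genes))
  if (nrow(pts) > 0)
    m[cbind(match(pts$gs_id, rows), match(pts$gene_id, genes))] <- pts$x
  n_sets <- colSums(!is.na(m))
  ord <- order(-n_sets, colnames(m))
  m <- m[, ord, drop = FALSE]
  new_plot_data("summary_heat", m, aesthetics = list(fill = "log2fc"))
}

#' Signature volcano plot data for one geneset
#'
#' All DE-table genes with a non-missing adjusted p-value form the
#' background (x = log2fc, y = -log10 padj); the geneset's resolved members
#' are flagged and labeled.
#'
#' @param bundle a [geneset_bundle()].
#' @param gs_id the geneset to highlight.
#' @return a `plot_data` with columns gene_id, symbol, x, y, is_member.
#' @export
signature_volcano_data <- function(bundle, gs_id) {
  k <- match(gs_id, bundle$enrichment$gs_id)
  if (is.na(k)) stopf("unknown geneset id '%s'", gs_id)
  de <- bundle$de
  miss <- is.na(de$padj)
  if (any(miss))
    warnf("excluding %d gene(s) with missing padj from the volcano", sum(miss))
  de <- de[!miss, , drop = FALSE]
  ids <- resolve_symbols(bundle$enrichment$gs_genes[[k]], bundle$annotation)
  ids <- unique(ids[!is.na(ids)])
  df <- data.frame(
    gene_id = de$gene_id,
    symbol = bundle$annotation$gene_name[match(de$gene_id,
                                               bundle$annotation$gene_id)],
    x = de$log2fc, y = -log10(de$padj),
    is_member = de$gene_id %in% ids,
    stringsAsFactors = FALSE)
  new_plot_data("signature_volcano", df, labels = df$gene_id[df$is_member],
                aesthetics = list(x = "log2fc", y = "neg_log10_padj"),
                extra = list(gs_id = gs_id, n_members_resolved = length(ids)))
}

#' Signature heatmap data for one geneset
#'
#' Members-by-samples matrix of transformed expression, optionally
#' row-standardized, with the sample condition carried as annotation.
#'
#' @param bundle a [geneset_bundle()].
#' @param gs_id the geneset.
#' @param transformed matrix from [transform_counts()] (computed from the
#'   bundle when omitted).
#' @param standardize row-standardize (mean 0, sd 1 for non-constant rows).
#' @return a `plot_data` with `data` = members x samples matrix and a
#'   `sample_annotation` extra.
#' @export
signature_heatmap_data <- function(bundle, gs_id, transformed = NULL,
                                   standardize = FALSE) {
  k <- match(gs_id, bundle$enrichment$gs_id)
  if (is.na(k)) stopf("unknown geneset id '%s'", gs_id)
  if (is.null(transformed)) transformed <- transform_counts(bundle)
  ids <- resolve_symbols(bundle$enrichment$gs_genes[[k]], bundle$annotation)
  ids <- unique(ids[!is.na(ids)])
  ids <- ids[ids %in% rownames(transformed)]
  if (length(ids) == 0) stopf("geneset '%s' has no resolvable member", gs_id)
  m <- transformed[ids, , drop = FALSE]
  if (standardize) m <- compute_gene_z(m)$values
  cond <- bundle$samples[[1]]
  names(cond) <- rownames(bundle$samples)
  new_plot_data("signature_heatmap", m,
                aesthetics = list(fill = if (standardize) "z" else "transformed"),
                extra = list(gs_id = gs_id, sample_annotation = cond,
                             standardized = standardize))
}

#' Spider (radar) plot data across one or more enrichment tables
#'
#' Axes are the union of the top `n_gs` geneset ids across all inputs,
#' aligned by `gs_id`; one trace per input. A geneset missing from one
#' input contributes value 0 on that trace, flagged in the companion
#' `present` matrix.
#'
#' @param enrichments a single [enrichment_table()] or a (named) list.
#' @param n_gs top genesets per input (default 10).
#' @param value `"neg_log10_p"` or `"z_score"`.
#' @return a `plot_data` with `data` = traces x axes matrix and `present`
#'   logical matrix.
#' @export
spider_data <- function(enrichments, n_gs = 10,
                        value = c("neg_log10_p", "z_score")) {
  value <- match.arg(value)
  if (inherits(enrichments, "enrichment_table"))
    enrichments <- list(enrichments)
  if (is.null(names(enrichments)))
    names(enrichments) <- paste0("scenario_", seq_along(enrichments))
  tops <- lapply(enrichments, top_genesets, n_gs = n_gs)
  axes <- unique(unlist(lapply(tops, `[[`, "gs_id")))
  if (length(axes) == 0) stopf("empty union of top genesets")
  vals <- present <- matrix(0, nrow = length(enrichments), ncol = length(axes),
                            dimnames = list(names(enrichments), axes))
  for (t in seq_along(enrichments)) {
    e <- enrichments[[t]]
    idx <- match(axes, e$gs_id)
    v <- if (value == "neg_log10_p") -log10(e$gs_pvalue[idx]) else e$z_score[idx]
    v[is.na(v)] <- 0
    vals[t, ] <- v
    present[t, ] <- !is.na(idx)
  }
  new_plot_data("spider", vals, aesthetics = list(r = value),
                extra = list(present = present == 1))
}

#' Serialize plot data to JSON
#'
#' @param pd a `plot_data`.
#' @param path optional output path; when omitted the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
plot_data_to_json <- function(pd, path = NULL) {
  obj <- unclass(pd)
  if (is.matrix(obj$data)) {
    obj$data <- list(rows = rownames(obj$data), cols = colnames(obj$data),
                     values = unname(apply(obj$data, 1, function(r) r,
                                           simplify = FALSE)))
  }
  json <- jsonlite::toJSON(obj, dataframe = "columns", digits = I(17),
                           na = "null", null = "null", auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Render plot data to a static figure
#'
#' A minimal static rendering of any `plot_data` (scatter kinds as points,
#' matrix kinds as a filled image) written to SVG, PNG or PDF based on the
#' file extension. The plot data itself is never modified. Requires
#' ggplot2 for scatter kinds.
#'
#' @param pd a `plot_data`.
#' @param path output figure path (.svg, .png or .pdf).
#' @return `path`, invisibly.
#' @export
render_plot_data <- function(pd, path) {
  ext <- tolower(tools::file_ext(path))
  open_dev <- switch(ext,
    svg = function() grDevices::svg(path, width = 7, height = 5),
    png = function() grDevices::png(path, width = 700, height = 500),
    pdf = function() grDevices::pdf(path, width = 7, height = 5),
    stopf("unsupported figure format '%s'", ext))
  open_dev()
  on.exit(grDevices::dev.off())
  if (is.matrix(pd$data)) {
    m <- pd$data
    graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    axes = FALSE, main = pd$kind)
  } else {
    df <- pd$data
    graphics::plot(df$x, df$y, pch = 19,
                   xlab = pd$aesthetics$x %||% "x",
                   ylab = pd$aesthetics$y %||% "y", main = pd$kind)
  }
  invisible(path)
}
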