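#' Geneset direction Z-score and aggregated effect size
#'
#' Fills two geneset-level summaries that inject DE information into the
#' enrichment table: the direction Z-score
#' `z = (up - down) / sqrt(up + down)` over the geneset's up- and
#' down-regulated DE members, and an aggregated effect size (mean or median
#' log2 fold change over the geneset's DE members). Genesets with no DE
#' member get missing scores.
#'
#' @param enrichment an [enrichment_table()].
#' @param de DE result table.
#' @param annotation gene annotation table.
#' @param de_threshold adjusted p-value cutoff (default 0.05).
#' @param aggr aggregation for the effect size: `"mean"` or `"median"`.
#' @return the enrichment table with `z_score` and `aggr_score` filled
#'   (and `up_count`/`down_count` if not already present).
#' @export
compute_aggregate_scores <- function(enrichment, de, annotation,
                                     de_threshold = 0.05,
                                     aggr = c("mean", "median")) {
  aggr <- match.arg(aggr)
  aggr_fun <- if (aggr == "mean") mean else stats::median
  if (is.null(enrichment$up_count) || anyNA(enrichment$up_count) ||
      anyNA(enrichment$down_count))
    enrichment <- attach_membership_counts(enrichment, de, annotation,
                                           de_threshold)
  tot <- enrichment$up_count + enrichment$down_count
  enrichment$z_score <- ifelse(
    tot > 0,
    (enrichment$up_count - enrichment$down_count) / sqrt(tot),
    NA_real_)
  st <- de_status(de, de_threshold)
  enrichment$aggr_score <- vapply(seq_len(nrow(enrichment)), function(k) {
    ids <- resolve_symbols(enrichment$gs_genes[[k]], annotation)
    idx <- match(ids[!is.na(ids)], st$gene_id)
    idx <- idx[!is.na(idx)]
    idx <- idx[st$is_de[idx]]
    if (length(idx) == 0) return(NA_real_)
    aggr_fun(st$log2fc[idx])
  }, numeric(1))
  enrichment
}

# DESeq-style median-of-ratios size factors on the raw count matrix
median_of_ratios <- function(counts) {
  if (any(colSums(counts) == 0)) stopf("all-zero sample column: size factor undefined")
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)  # genes with a zero anywhere drop out of the reference
  if (!any(use))
    stopf("no gene with all-positive counts: cannot compute size factors")
  apply(counts, 2, function(cnts) {
    exp(stats::median(log(cnts[use]) - log_geo[use]))
  })
}

#' Transform counts toward homoscedasticity
#'
#' Default `shifted_log`: `log2(count / size_factor + 1)` with
#' median-of-ratios size factors — a monotone per-gene transform whose
#' output is roughly homoscedastic, standing in for a dispersion-model-based
#' variance stabilizing transform. `custom` passes a user-supplied
#' pre-transformed matrix through (same dimnames as the counts).
#'
#' @param x a [geneset_bundle()] or a counts matrix.
#' @param method `"shifted_log"` or `"custom"`.
#' @param custom_matrix pre-transformed matrix for `method = "custom"`.
#' @return numeric matrix with attribute `transform_name`.
#' @export
transform_counts <- function(x, method = c("shifted_log", "custom"),
                             custom_matrix = NULL) {
  method <- match.arg(method)
  counts <- if (inherits(x, "geneset_bundle")) x$counts else as.matrix(x)
  if (method == "custom") {
    if (is.null(custom_matrix)) stopf("method = 'custom' needs custom_matrix")
    if (!identical(dimnames(custom_matrix), dimnames(counts)))
      stopf("custom matrix dimnames must match the counts matrix")
    if (any(!is.finite(custom_matrix))) stopf("custom matrix must be finite")
    out <- custom_matrix
    attr(out, "transform_name") <- "custom"
    return(out)
  }
  sf <- median_of_ratios(counts)
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  attr(out, "transform_name") <- "shifted_log"
  attr(out, "size_factors") <- sf
  out
}

#' Row-standardize a transformed expression matrix
#'
#' Computes `Z[i, j] = (T[i, j] - mean_i) / sd_i` per gene, with the sample
#' (n - 1) standard deviation. Constant rows (sd = 0) are set to all-zero
#' and flagged rather than producing NaN.
#'
#' @param transformed matrix from [transform_counts()] (genes x samples).
#' @return a `gene_z` list: `values` (the Z matrix), `row_means`, `row_sds`,
#'   and `constant_rows` (character vector of flagged gene ids).
#' @export
compute_gene_z <- function(transformed) {
  if (ncol(transformed) < 2) stopf("need at least 2 samples to standardize")
  m <- rowMeans(transformed)
  s <- apply(transformed, 1, stats::sd)
  const <- s == 0
  z <- (transformed - m) / ifelse(const, 1, s)
  z[const, ] <- 0
  structure(
    list(values = z, row_means = m, row_sds = s,
         constant_rows = rownames(transformed)[const]),
    class = "gene_z")
}

#' Sample-wise geneset activity scores
#'
#' For each geneset k and sample j, the score `GS[k, j]` is the arithmetic
#' mean of the standardized expression `Z[i, j]` over the geneset's members
#' `P_k`. By default `P_k` is the set of DE members (the members that pass
#' the DE threshold); `members = "all"` averages over all resolvable
#' members. Genesets with no resolvable member are dropped with a warning.
#'
#' @param genez a `gene_z` object from [compute_gene_z()].
#' @param enrichment an [enrichment_table()].
#' @param de DE result table.
#' @param annotation gene annotation table.
#' @param de_threshold adjusted p-value cutoff (default 0.05).
#' @param members `"de_only"` (default) or `"all"`.
#' @return a `geneset_scores` list: `values` (genesets x samples matrix) and
#'   `members_used` (list of gene ids averaged per retained geneset).
#' @export
compute_geneset_scores <- function(genez, enrichment, de, annotation,
                                   de_threshold = 0.05,
                                   members = c("de_only", "all")) {
  members <- match.arg(members)
  if (nrow(enrichment) == 0) stopf("empty enrichment table")
  z <- genez$values
  st <- de_status(de, de_threshold)
  de_ids <- st$gene_id[st$is_de]
  used <- lapply(enrichment$gs_genes, function(sym) {
    ids <- resolve_symbols(sym, annotation)
    ids <- unique(ids[!is.na(ids)])
    ids <- ids[ids %in% rownames(z)]
    if (members == "de_only") ids <- ids[ids %in% de_ids]
    ids
  })
  names(used) <- enrichment$gs_id
  keep <- lengths(used) > 0
  if (!all(keep))
    warnf("dropping %d geneset(s) with no resolvable %smember",
          sum(!keep), if (members == "de_only") "DE " else "")
  if (!any(keep)) stopf("no geneset with resolvable members")
  used <- used[keep]
  vals <- t(vapply(used, function(ids) colMeans(z[ids, , drop = FALSE]),
                   numeric(ncol(z))))
  dimnames(vals) <- list(names(used), colnames(z))
  structure(list(values = vals, members_used = used),
            class = "geneset_scores")
}

#' Export a geneset score matrix as TSV
#'
#' @param scores a `geneset_scores` object.
#' @param path output path (genesets x samples, header = sample ids).
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  df <- data.frame(gs_id = rownames(scores$values), scores$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
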