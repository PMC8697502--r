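#' Harmonized enrichment table
#'
#' Validates and classes a data frame of geneset enrichment results in the
#' harmonized schema. Required columns: `gs_id` (unique identifier),
#' `gs_description`, `gs_pvalue` in (0, 1], and `gs_genes`, a list column of
#' member gene symbols. Optional columns: `gs_de_count`, `gs_bg_count`,
#' `z_score`, `aggr_score`, `up_count`, `down_count`.
#'
#' @param df data frame in the harmonized schema.
#' @return the data frame with class `enrichment_table`.
#' @export
enrichment_table <- function(df) {
  req <- c("gs_id", "gs_description", "gs_pvalue", "gs_genes")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stopf("enrichment table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gs_id))
    stopf("duplicated gs_id: %s",
          paste(unique(df$gs_id[duplicated(df$gs_id)]), collapse = ", "))
  if (!is.list(df$gs_genes)) df$gs_genes <- as.list(df$gs_genes)
  bad_p <- !is.na(df$gs_pvalue) & (df$gs_pvalue <= 0 | df$gs_pvalue > 1)
  if (any(bad_p))
    stopf("gs_pvalue outside (0,1] for: %s",
          paste(df$gs_id[bad_p], collapse = ", "))
  for (col in c("gs_de_count", "gs_bg_count", "z_score", "aggr_score",
                "up_count", "down_count")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_real_, nrow(df))
  }
  # consistency of the direction Z-score with its closed form, where present
  have <- !is.na(df$z_score) & !is.na(df$up_count) & !is.na(df$down_count) &
    (df$up_count + df$down_count) > 0
  if (any(have)) {
    expect <- (df$up_count[have] - df$down_count[have]) /
      sqrt(df$up_count[have] + df$down_count[have])
    if (any(abs(df$z_score[have] - expect) > 1e-9))
      stopf("z_score inconsistent with (up_count - down_count)/sqrt(up_count + down_count)")
  }
  rownames(df) <- NULL
  class(df) <- unique(c("enrichment_table", class(df)))
  df
}

#' Bundle the four inputs of an interpretation session
#'
#' Combines the expression matrix with its sample table, the
#' differential-expression results, the (harmonized) enrichment table and
#' the gene annotation into one unit that downstream functions consume.
#'
#' @param counts numeric matrix of non-negative counts, rows = gene ids,
#'   columns = sample ids.
#' @param samples data frame of sample metadata; rownames (or a `sample_id`
#'   column) must equal the column names of `counts`; needs at least one
#'   categorical covariate (e.g. `condition`).
#' @param de data frame with `gene_id`, `log2fc` (alias `log2FoldChange`
#'   accepted), `pvalue`, `padj`.
#' @param enrichment an [enrichment_table()] (coerced if a plain data frame).
#' @param annotation data frame with `gene_id`, `gene_name`.
#' @return an object of class `geneset_bundle`.
#' @export
geneset_bundle <- function(counts, samples, de, enrichment, annotation) {
  if (missing(counts) || missing(samples) || missing(de) ||
      missing(enrichment) || missing(annotation))
    stopf("all of counts, samples, de, enrichment, annotation are required")
  counts <- as.matrix(counts)
  if (is.integer(counts)) storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stopf("duplicated gene ids in counts")
  if (anyDuplicated(colnames(counts))) stopf("duplicated sample ids in counts")
  if (anyNA(counts)) stopf("counts contain missing values")
  if (any(counts < 0)) stopf("counts contain negative values")

  samples <- as.data.frame(samples)
  if ("sample_id" %in% names(samples)) rownames(samples) <- samples$sample_id
  if (!identical(sort(rownames(samples)), sort(colnames(counts))))
    stopf("sample table keys do not match counts column names")
  samples <- samples[colnames(counts), , drop = FALSE]

  de <- as.data.frame(de)
  if (!"log2fc" %in% names(de) && "log2FoldChange" %in% names(de))
    names(de)[names(de) == "log2FoldChange"] <- "log2fc"
  req <- c("gene_id", "log2fc", "pvalue", "padj")
  miss <- setdiff(req, names(de))
  if (length(miss) > 0)
    stopf("DE table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(de$gene_id)) stopf("duplicated gene_id in DE table")
  for (col in c("pvalue", "padj")) {
    bad <- !is.na(de[[col]]) & (de[[col]] <= 0 | de[[col]] > 1)
    if (any(bad)) stopf("%s outside (0,1] for gene(s): %s", col,
                        paste(de$gene_id[bad], collapse = ", "))
  }
  if (any(!is.na(de$log2fc) & !is.finite(de$log2fc)))
    stopf("non-finite log2fc in DE table")

  annotation <- as.data.frame(annotation)
  if (!all(c("gene_id", "gene_name") %in% names(annotation)))
    stopf("annotation needs gene_id and gene_name columns")
  if (anyDuplicated(annotation$gene_id)) stopf("duplicated gene_id in annotation")
  if (any(!nzchar(annotation$gene_id))) stopf("empty gene_id in annotation")

  rownames(de) <- NULL
  rownames(annotation) <- NULL

  if (nrow(de) > 0 && length(intersect(de$gene_id, rownames(counts))) == 0)
    stopf("no overlap between DE gene ids and expression rows: mismatched identifier universes")

  enrichment <- enrichment_table(as.data.frame(enrichment))

  structure(
    list(counts = counts, samples = samples, de = de,
         enrichment = enrichment, annotation = annotation),
    class = "geneset_bundle"
  )
}

#' @export
print.geneset_bundle <- function(x, ...) {
  d <- describe_bundle(x)
  cat(sprintf(
    "geneset_bundle: %d genes x %d samples, %d DE (padj <= 0.05), %d genesets\n",
    d$n_genes, d$n_samples, d$n_de, d$n_genesets))
  invisible(x)
}

#' Validate a bundle's cross-references
#'
#' Checks that every DE gene id occurs in the expression rows, that every
#' geneset member symbol resolves through the annotation, and reports
#' duplicate symbol-to-id mappings and empty genesets. In lax mode (the
#' default) unresolvable symbols are dropped from `gs_genes` and the repaired
#' bundle is returned in the report; in strict mode any problem aborts.
#'
#' @param bundle a [geneset_bundle()].
#' @param strict abort on any inconsistency instead of repairing.
#' @return a `bundle_validation` list with elements `unmatched_de_ids`,
#'   `unresolved_symbols`, `duplicated_symbols`, `empty_genesets`,
#'   `n_dropped_symbols` and `bundle` (the lax-repaired bundle).
#' @export
validate_bundle <- function(bundle, strict = FALSE) {
  if (!inherits(bundle, "geneset_bundle")) stopf("not a geneset_bundle")
  unmatched <- setdiff(bundle$de$gene_id, rownames(bundle$counts))
  dup_sym <- unique(bundle$annotation$gene_name[duplicated(bundle$annotation$gene_name)])
  all_sym <- unique(unlist(bundle$enrichment$gs_genes))
  unresolved <- setdiff(all_sym, bundle$annotation$gene_name)
  empty_gs <- bundle$enrichment$gs_id[lengths(bundle$enrichment$gs_genes) == 0]

  if (strict) {
    if (length(unmatched) > 0)
      stopf("DE gene id(s) absent from expression rows: %s",
            paste(utils::head(unmatched, 5), collapse = ", "))
    if (length(unresolved) > 0)
      stopf("unresolvable geneset symbol(s): %s",
            paste(utils::head(unresolved, 5), collapse = ", "))
  }

  n_dropped <- 0L
  repaired <- bundle
  if (length(unresolved) > 0) {
    before <- sum(lengths(repaired$enrichment$gs_genes))
    repaired$enrichment$gs_genes <- lapply(
      repaired$enrichment$gs_genes,
      function(g) g[g %in% bundle$annotation$gene_name])
    n_dropped <- before - sum(lengths(repaired$enrichment$gs_genes))
    # keep gs_de_count consistent where it mirrored the member list
    eq <- !is.na(bundle$enrichment$gs_de_count) &
      bundle$enrichment$gs_de_count == lengths(bundle$enrichment$gs_genes)
    repaired$enrichment$gs_de_count[eq] <- lengths(repaired$enrichment$gs_genes)[eq]
    warnf("dropped %d unresolvable symbol occurrence(s) from gs_genes", n_dropped)
  }

  structure(
    list(unmatched_de_ids = unmatched,
         unresolved_symbols = unresolved,
         duplicated_symbols = dup_sym,
         empty_genesets = empty_gs,
         n_dropped_symbols = n_dropped,
         bundle = repaired),
    class = "bundle_validation")
}

#' @export
print.bundle_validation <- function(x, ...) {
  cat(sprintf("bundle validation: %d unmatched DE ids, %d unresolved symbols, %d duplicated symbols, %d empty genesets\n",
              length(x$unmatched_de_ids), length(x$unresolved_symbols),
              length(x$duplicated_symbols), length(x$empty_genesets)))
  invisible(x)
}

#' Summarize a bundle
#'
#' @param bundle a [geneset_bundle()].
#' @param de_threshold adjusted p-value cutoff used for the DE count.
#' @return list with `n_genes`, `n_samples`, `n_de`, `n_genesets`.
#' @export
describe_bundle <- function(bundle, de_threshold = 0.05) {
  list(
    n_genes = nrow(bundle$counts),
    n_samples = ncol(bundle$counts),
    n_de = sum(effective_padj(bundle$de) <= de_threshold),
    n_genesets = nrow(bundle$enrichment)
  )
}

BUNDLE_SCHEMA_VERSION <- "1.0"

df_to_cols <- function(df) {
  out <- lapply(names(df), function(n) df[[n]])
  names(out) <- names(df)
  out
}

#' Serialize a bundle to a single JSON file
#'
#' The file is a versioned UTF-8 JSON container with column-ordered tables;
#' [read_bundle()] reproduces the bundle exactly (values, orders, ids).
#'
#' @param bundle a [geneset_bundle()] (must validate in lax mode).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  validate_bundle(bundle, strict = FALSE)
  obj <- list(
    schema_version = BUNDLE_SCHEMA_VERSION,
    counts = list(
      gene_id = rownames(bundle$counts),
      sample_id = colnames(bundle$counts),
      values = unname(apply(bundle$counts, 1, function(r) r, simplify = FALSE))
    ),
    samples = c(list(sample_id = rownames(bundle$samples)),
                df_to_cols(bundle$samples)),
    de = df_to_cols(bundle$de),
    enrichment = df_to_cols(as.data.frame(bundle$enrichment)),
    annotation = df_to_cols(bundle$annotation)
  )
  # I(17) significant digits: doubles survive the round trip bit-exactly
  json <- jsonlite::toJSON(obj, digits = I(17), na = "null", null = "null",
                           auto_unbox = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a serialized bundle
#'
#' @param path path to a JSON file written by [write_bundle()].
#' @return a [geneset_bundle()].
#' @export
read_bundle <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e) stopf("malformed bundle file '%s': %s",
                                            path, conditionMessage(e)))
  if (is.null(obj$schema_version))
    stopf("bundle file '%s' lacks a schema_version field", path)
  if (!identical(obj$schema_version, BUNDLE_SCHEMA_VERSION))
    stopf("bundle schema version mismatch: file has '%s', expected '%s'",
          obj$schema_version, BUNDLE_SCHEMA_VERSION)
  gid <- obj$counts$gene_id
  sid <- obj$counts$sample_id
  if (length(obj$counts$values) != length(gid))
    stopf("counts matrix has %d rows but %d gene ids declared",
          length(obj$counts$values), length(gid))
  if (any(lengths(obj$counts$values) != length(sid)))
    stopf("counts matrix row length does not match declared sample count")
  counts <- do.call(rbind, lapply(obj$counts$values, unlist))
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(gid, sid)

  null_to_na <- function(x) {
    x[vapply(x, is.null, logical(1))] <- NA
    unlist(x)
  }
  cols_to_df <- function(cols, listcols = character(0)) {
    out <- lapply(names(cols), function(n) {
      if (n %in% listcols) {
        lapply(cols[[n]], function(g) as.character(unlist(g)))
      } else {
        v <- null_to_na(cols[[n]])
        # all-null columns come back logical, and whole-number doubles come
        # back integer; the schema's non-id columns are numeric
        if ((is.logical(v) && all(is.na(v))) || is.integer(v))
          v <- as.numeric(v)
        v
      }
    })
    names(out) <- names(cols)
    # data.frame() would unwrap list columns; build by hand
    nr <- length(out[[1]])
    structure(out, row.names = c(NA_integer_, -nr), class = "data.frame")
  }
  samples <- cols_to_df(obj$samples)
  rownames(samples) <- samples$sample_id
  samples$sample_id <- NULL
  de <- cols_to_df(obj$de)
  enr <- cols_to_df(obj$enrichment, listcols = "gs_genes")
  ann <- cols_to_df(obj$annotation)
  geneset_bundle(counts, samples, de, enr, ann)
}
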