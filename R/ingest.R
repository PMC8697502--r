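# Built-in dialect specifications for the supported enrichment tools.
# Each spec maps source columns onto the harmonized schema and records the
# member-gene separator and any "k/n"-style ratio column. These are data,
# not code: a user can start from dialect_spec() and edit any field.
.dialects <- list(
  topgo = list(
    name = "topgo",
    column_map = c(gs_id = "GO.ID", gs_description = "Term",
                   gs_bg_count = "Annotated", gs_de_count = "Significant",
                   gs_pvalue = "p.value_elim", gs_genes = "genes"),
    gene_separator = ",",
    ratio_columns = NULL,
    pvalue_kind = "raw"
  ),
  clusterprofiler = list(
    name = "clusterprofiler",
    column_map = c(gs_id = "ID", gs_description = "Description",
                   gs_pvalue = "p.adjust", gs_genes = "geneID"),
    gene_separator = "/",
    ratio_columns = "GeneRatio",
    pvalue_kind = "adjusted"
  ),
  david = list(
    name = "david",
    column_map = c(gs_id = "Term", gs_de_count = "Count",
                   gs_pvalue = "PValue", gs_genes = "Genes"),
    gene_separator = ",",
    id_description_split = "~",
    ratio_columns = NULL,
    pvalue_kind = "raw"
  ),
  enrichr = list(
    name = "enrichr",
    column_map = c(gs_id = "Term", gs_description = "Term",
                   gs_pvalue = "Adjusted.P.value", gs_genes = "Genes"),
    gene_separator = ";",
    ratio_columns = "Overlap",
    pvalue_kind = "adjusted"
  ),
  gprofiler = list(
    name = "gprofiler",
    column_map = c(gs_id = "term_id", gs_description = "term_name",
                   gs_pvalue = "p_value", gs_bg_count = "term_size",
                   gs_de_count = "intersection_size", gs_genes = "intersection"),
    gene_separator = ",",
    ratio_columns = NULL,
    pvalue_kind = "adjusted"
  ),
  fgsea = list(
    name = "fgsea",
    column_map = c(gs_id = "pathway", gs_pvalue = "padj",
                   gs_bg_count = "size", gs_genes = "leadingEdge"),
    gene_separator = ",",
    ratio_columns = NULL,
    pvalue_kind = "adjusted"
  ),
  generic = list(
    name = "generic",
    column_map = c(gs_id = "gs_id", gs_description = "gs_description",
                   gs_pvalue = "gs_pvalue", gs_genes = "gs_genes"),
    gene_separator = ",",
    ratio_columns = NULL,
    pvalue_kind = "as_provided"
  )
)

#' List supported enrichment-tool dialects
#' @return character vector of dialect names.
#' @export
list_dialects <- function() names(.dialects)

#' Retrieve (and optionally customize) a dialect specification
#'
#' A dialect spec describes how one enrichment tool's tabular output maps
#' onto the harmonized schema: a `column_map` (target -> source column),
#' the separator used inside the member-gene field, and optional "k/n" ratio
#' columns. Override any field via `...`.
#'
#' @param name one of [list_dialects()].
#' @param ... named overrides, e.g. `gene_separator = ";"`.
#' @return a `dialect_spec` list.
#' @export
dialect_spec <- function(name, ...) {
  if (!name %in% names(.dialects))
    stopf("unknown dialect '%s'; supported: %s", name,
          paste(names(.dialects), collapse = ", "))
  spec <- .dialects[[name]]
  dots <- list(...)
  spec[names(dots)] <- dots
  class(spec) <- "dialect_spec"
  spec
}

split_genes <- function(x, sep) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    trimws(strsplit(s, sep, fixed = TRUE)[[1]])
  })
}

parse_ratio <- function(x) {
  parts <- strsplit(as.character(x), "/", fixed = TRUE)
  k <- as.integer(vapply(parts, `[`, character(1), 1))
  n <- as.integer(vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                         character(1)))
  list(k = k, n = n)
}

#' Convert a tool-native enrichment table to the harmonized schema
#'
#' The "shaker" entry point: takes the raw tabular export of one of the
#' supported enrichment tools and returns a harmonized
#' [enrichment_table()]. Member-gene fields are split on the dialect's
#' separator with whitespace trimmed; "k/n" ratio columns are parsed into
#' `gs_de_count` / `gs_bg_count`; rows with unparseable p-values are dropped
#' with a warning. The harmonized `gs_pvalue` carries the tool's adjusted
#' p-value where one exists, else the raw one; which was used is recorded in
#' the `pvalue_kind` attribute.
#'
#' @param table data frame in the tool's native export format.
#' @param dialect a dialect name or a [dialect_spec()].
#' @param case_insensitive uppercase gene symbols (default keeps case:
#'   mouse symbols are mixed-case).
#' @return an [enrichment_table()] with attribute `pvalue_kind`.
#' @export
shake <- function(table, dialect = "generic", case_insensitive = FALSE) {
  if (is.character(dialect)) dialect <- dialect_spec(dialect)
  cm <- dialect$column_map
  need <- unname(cm[c("gs_id", "gs_pvalue", "gs_genes")])
  miss <- setdiff(c(need, dialect$ratio_columns), names(table))
  if (length(miss) > 0)
    stopf("missing column(s) for dialect '%s': %s", dialect$name,
          paste(miss, collapse = ", "))

  # generic dialect passes an already-harmonized table through untouched
  if (identical(dialect$name, "generic") && is.list(table$gs_genes) &&
      !is.character(table$gs_genes)) {
    return(enrichment_table(as.data.frame(table)))
  }

  out <- data.frame(gs_id = as.character(table[[cm[["gs_id"]]]]),
                    stringsAsFactors = FALSE)
  if (!is.null(dialect$id_description_split)) {
    parts <- strsplit(out$gs_id, dialect$id_description_split, fixed = TRUE)
    out$gs_id <- vapply(parts, `[`, character(1), 1)
    out$gs_description <- vapply(
      parts, function(p) if (length(p) > 1) paste(p[-1], collapse = dialect$id_description_split)
      else p[1], character(1))
  } else if (!is.na(cm["gs_description"]) && "gs_description" %in% names(cm) &&
             cm[["gs_description"]] %in% names(table)) {
    out$gs_description <- as.character(table[[cm[["gs_description"]]]])
  } else {
    out$gs_description <- out$gs_id  # e.g. fgsea has no description column
  }
  out$gs_pvalue <- suppressWarnings(as.numeric(table[[cm[["gs_pvalue"]]]]))
  genes <- split_genes(as.character(table[[cm[["gs_genes"]]]]),
                       dialect$gene_separator)
  if (case_insensitive) genes <- lapply(genes, toupper)
  out$gs_genes <- genes

  if (!is.null(dialect$ratio_columns)) {
    r <- parse_ratio(table[[dialect$ratio_columns[1]]])
    out$gs_de_count <- r$k
    out$gs_bg_count <- r$n
  } else {
    out$gs_de_count <-
      if (!is.na(cm["gs_de_count"] %||% NA) && "gs_de_count" %in% names(cm) &&
          cm[["gs_de_count"]] %in% names(table))
        as.integer(table[[cm[["gs_de_count"]]]])
      else lengths(genes)
    out$gs_bg_count <-
      if ("gs_bg_count" %in% names(cm) && cm[["gs_bg_count"]] %in% names(table))
        as.integer(table[[cm[["gs_bg_count"]]]])
      else NA_integer_
  }

  bad <- is.na(out$gs_pvalue)
  if (any(bad)) {
    warnf("dropping %d row(s) with unparseable p-values", sum(bad))
    out <- out[!bad, , drop = FALSE]
  }
  res <- enrichment_table(out)
  attr(res, "pvalue_kind") <- dialect$pvalue_kind
  res
}

#' Read a geneset collection from a GMT file
#'
#' GMT (gene matrix transposed): one geneset per tab-separated line —
#' name, description, then member genes.
#'
#' @param path path to a GMT file.
#' @return a `geneset_collection` data frame (`gs_id`, `gs_description`,
#'   list column `gs_genes`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warnf("empty GMT file: %s", path)
    out <- data.frame(gs_id = character(0), gs_description = character(0))
    out$gs_genes <- list()
    class(out) <- c("geneset_collection", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stopf("GMT parse error: line %d has fewer than 3 fields", short[1])
  out <- data.frame(
    gs_id = vapply(fields, `[`, character(1), 1),
    gs_description = vapply(fields, `[`, character(1), 2),
    stringsAsFactors = FALSE)
  out$gs_genes <- lapply(fields, function(f) trimws(f[-(1:2)]))
  if (anyDuplicated(out$gs_id)) stopf("duplicated geneset names in GMT")
  class(out) <- c("geneset_collection", "data.frame")
  out
}

#' Write a geneset collection to a GMT file
#'
#' @param collection a `geneset_collection` (or any data frame with
#'   `gs_id`, `gs_description`, `gs_genes`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$gs_id[i], collection$gs_description[i],
            collection$gs_genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Count up- and down-regulated DE members per geneset
#'
#' For each geneset, resolves its member symbols through the annotation and
#' counts members that are DE (padj <= threshold, missing padj treated as 1)
#' upward (log2fc > 0) and downward (log2fc < 0). A member with log2fc
#' exactly 0 counts in neither direction.
#'
#' @param enrichment an [enrichment_table()].
#' @param de DE result table.
#' @param annotation gene annotation table.
#' @param de_threshold adjusted p-value cutoff (default 0.05).
#' @return the enrichment table with `up_count`, `down_count` filled;
#'   `gs_de_count` is filled with `up_count + down_count` where missing.
#' @export
attach_membership_counts <- function(enrichment, de, annotation,
                                     de_threshold = 0.05) {
  if (nrow(de) == 0) stopf("empty DE table")
  st <- de_status(de, de_threshold)
  per_set <- lapply(enrichment$gs_genes, function(sym) {
    ids <- resolve_symbols(sym, annotation)
    idx <- match(ids[!is.na(ids)], st$gene_id)
    idx <- idx[!is.na(idx)]
    c(up = sum(st$is_de[idx] & st$direction[idx] > 0),
      down = sum(st$is_de[idx] & st$direction[idx] < 0))
  })
  enrichment$up_count <- vapply(per_set, `[[`, numeric(1), "up")
  enrichment$down_count <- vapply(per_set, `[[`, numeric(1), "down")
  fill <- is.na(enrichment$gs_de_count)
  enrichment$gs_de_count[fill] <-
    enrichment$up_count[fill] + enrichment$down_count[fill]
  enrichment
}
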