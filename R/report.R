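#' Bookmark container for genes and genesets of interest
#'
#' @return an empty `bookmarks` object (ordered, duplicate-free id lists).
#' @export
bookmarks <- function() {
  structure(list(genes = character(0), genesets = character(0)),
            class = "bookmarks")
}

#' Add a bookmark
#'
#' Appends an id to the gene or geneset bookmark list, preserving insertion
#' order; re-adding an existing id is a no-op.
#'
#' @param bm a [bookmarks()] object.
#' @param kind `"gene"` or `"geneset"`.
#' @param id gene id or geneset id; must resolve in `bundle` when one is
#'   supplied.
#' @param bundle optional [geneset_bundle()] used to check resolvability.
#' @return the updated `bookmarks`.
#' @export
bookmark <- function(bm, kind = c("gene", "geneset"), id, bundle = NULL) {
  kind <- match.arg(kind)
  if (!is.null(bundle)) {
    known <- if (kind == "gene") rownames(bundle$counts)
             else bundle$enrichment$gs_id
    if (!id %in% known) stopf("cannot bookmark unknown %s id '%s'", kind, id)
  }
  slot <- if (kind == "gene") "genes" else "genesets"
  if (!id %in% bm[[slot]]) bm[[slot]] <- c(bm[[slot]], id)
  bm
}

#' Remove a bookmark
#'
#' @inheritParams bookmark
#' @return the updated `bookmarks`; removing an absent id warns and is a
#'   no-op.
#' @export
remove_bookmark <- function(bm, kind = c("gene", "geneset"), id) {
  kind <- match.arg(kind)
  slot <- if (kind == "gene") "genes" else "genesets"
  if (!id %in% bm[[slot]]) {
    warnf("id '%s' is not bookmarked; nothing removed", id)
    return(bm)
  }
  bm[[slot]] <- setdiff(bm[[slot]], id)
  bm
}

#' Clear all bookmarks
#' @param bm a [bookmarks()] object.
#' @return an empty `bookmarks`.
#' @export
clear_bookmarks <- function(bm) bookmarks()

#' @export
print.bookmarks <- function(x, ...) {
  cat(sprintf("bookmarks: %d gene(s), %d geneset(s)\n",
              length(x$genes), length(x$genesets)))
  invisible(x)
}

# ---- deterministic inline-SVG figure emitters -------------------------------
# The report must be byte-reproducible given a pinned timestamp, so figures
# are emitted as plain SVG text built from plot_data with fixed-format
# numbers — no graphics device involved.

fmt <- function(x) sprintf("%.4f", x)

svg_open <- function(w, h, title) {
  sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d"',
                 ' viewBox="0 0 %d %d"><title>%s</title>',
                 '<rect width="%d" height="%d" fill="white"/>'),
          w, h, w, h, title, w, h)
}

scale_lin <- function(x, from, to) {
  if (diff(range(from)) == 0) return(rep(mean(to), length(x)))
  to[1] + (x - from[1]) / (from[2] - from[1]) * (to[2] - to[1])
}

svg_scatter <- function(df, title, highlight = rep(FALSE, nrow(df)),
                        w = 480, h = 320) {
  pad <- 30
  xr <- range(df$x, finite = TRUE)
  yr <- range(df$y, finite = TRUE)
  px <- scale_lin(df$x, xr, c(pad, w - pad))
  py <- scale_lin(df$y, yr, c(h - pad, pad))
  pts <- paste0(sprintf('<circle cx="%s" cy="%s" r="%d" fill="%s" fill-opacity="0.7"/>',
                        fmt(px), fmt(py), ifelse(highlight, 4L, 2L),
                        ifelse(highlight, "#d7301f", "#636363")),
                collapse = "")
  paste0(svg_open(w, h, title), pts, "</svg>")
}

svg_heat <- function(m, title, w = 480, h = 320) {
  pad <- 4
  nr <- nrow(m); nc <- ncol(m)
  cw <- (w - 2 * pad) / nc
  ch <- (h - 2 * pad) / nr
  rng <- range(m, finite = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-1, 1)
  cells <- character(0)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- m[i, j]
      col <- if (is.na(v)) "#eeeeee" else {
        t <- (v - rng[1]) / (rng[2] - rng[1])
        sprintf("#%02x%02x%02x", round(255 * t), round(64 + 64 * t),
                round(255 * (1 - t)))
      }
      cells <- c(cells, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        fmt(pad + (j - 1) * cw), fmt(pad + (i - 1) * ch),
        fmt(cw), fmt(ch), col))
    }
  }
  paste0(svg_open(w, h, title), paste0(cells, collapse = ""), "</svg>")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 25) {
  df <- utils::head(df, max_rows)
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) df[[col]] <- sprintf("%.4g", df[[col]])
  head_row <- paste0("<th>", html_escape(names(df)), "</th>", collapse = "")
  body <- paste0(vapply(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>", html_escape(as.character(unlist(df[i, ]))),
                          "</td>", collapse = ""), "</tr>")
  }, character(1)), collapse = "")
  paste0("<table><tr>", head_row, "</tr>", body, "</table>")
}

# external resource links built from ids; generated, never fetched
gene_links <- function(symbol, gene_id) {
  sprintf(paste0(
    '<a href="https://www.ncbi.nlm.nih.gov/gene/?term=%s">NCBI</a> | ',
    '<a href="https://www.genecards.org/cgi-bin/carddisp.pl?gene=%s">GeneCards</a> | ',
    '<a href="https://gtexportal.org/home/gene/%s">GTEx</a>'),
    symbol, symbol, symbol)
}

geneset_links <- function(gs_id) {
  if (grepl("^GO:", gs_id))
    sprintf('<a href="http://amigo.geneontology.org/amigo/term/%s">AmiGO</a>', gs_id)
  else ""
}

# rolling polynomial hash over the serialized config: a stable short
# fingerprint without external hashing dependencies (exact in doubles)
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2)[-(1:14)])
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 67108859
  sprintf("%08x", h)
}

#' Assemble the self-contained HTML session report
#'
#' Renders a single HTML file containing the bundle summary, one section
#' per bookmarked geneset (description, member table, signature heatmap and
#' volcano as inline SVG), one section per bookmarked gene (DE row,
#' expression-by-condition figure, external database links), and a
#' reproducibility appendix embedding the configuration, its hash, and the
#' exact command that regenerates every figure's plot data. With a pinned
#' `timestamp` the output is byte-deterministic.
#'
#' @param bundle a valid [geneset_bundle()].
#' @param bm a [bookmarks()] object (possibly empty).
#' @param config named list of analysis settings (de_threshold, aggr, ...);
#'   recorded verbatim in the appendix. `config$bundle_path` is used in the
#'   embedded reproduction commands.
#' @param out_path output HTML file.
#' @param timestamp optional fixed timestamp string; default is wall-clock
#'   time (which breaks byte-reproducibility, by design).
#' @return `out_path`, invisibly.
#' @export
happy_hour <- function(bundle, bm = bookmarks(), config = list(),
                       out_path, timestamp = NULL) {
  validate_bundle(bundle)
  de_threshold <- config$de_threshold %||% 0.05
  ts <- timestamp %||% format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
  d <- describe_bundle(bundle, de_threshold)
  bundle_path <- config$bundle_path %||% "bundle.json"

  enr <- bundle$enrichment
  if (length(bm$genesets) > 0 && anyNA(enr$z_score))
    enr <- compute_aggregate_scores(enr, bundle$de, bundle$annotation,
                                    de_threshold)
  transformed <- if (length(bm$genesets) > 0) transform_counts(bundle) else NULL

  parts <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>Enrichment interpretation report</title>",
    "<style>body{font-family:sans-serif;max-width:900px;margin:auto}",
    "table{border-collapse:collapse}td,th{border:1px solid #ccc;padding:2px 6px;font-size:12px}",
    "h2{border-bottom:1px solid #999}</style></head><body>",
    "<h1>Enrichment interpretation report</h1>",
    sprintf("<p>Generated: %s</p>", html_escape(ts)),
    "<h2>Bundle summary</h2>",
    sprintf("<p>%d genes &times; %d samples; %d DE genes at padj &le; %s; %d genesets.</p>",
            d$n_genes, d$n_samples, d$n_de, format(de_threshold), d$n_genesets)
  )

  snippets <- character(0)
  if (length(bm$genesets) == 0 && length(bm$genes) == 0) {
    parts <- c(parts, "<p><em>No bookmarks were recorded in this session.</em></p>")
  }

  for (gs in bm$genesets) {
    k <- match(gs, enr$gs_id)
    members <- enr$gs_genes[[k]]
    ids <- resolve_symbols(members, bundle$annotation)
    mem_df <- data.frame(symbol = members, gene_id = unname(ids))
    st <- de_status(bundle$de, de_threshold)
    idx <- match(mem_df$gene_id, st$gene_id)
    mem_df$log2fc <- st$log2fc[idx]
    mem_df$is_de <- st$is_de[idx]
    hm <- signature_heatmap_data(bundle, gs, transformed, standardize = TRUE)
    vo <- signature_volcano_data(bundle, gs)
    snippets <- c(snippets,
      snippet_for("signature_volcano_data",
                  utils::modifyList(config,
                                    list(gs_id = gs,
                                         bundle_path = bundle_path,
                                         out = sprintf("signature_volcano_%s.json", gs)))))
    parts <- c(parts,
      sprintf('<h2 class="section-geneset">Geneset %s</h2>', html_escape(gs)),
      sprintf("<p>%s %s</p>", html_escape(enr$gs_description[k]),
              geneset_links(gs)),
      sprintf("<p>p = %.3g, z = %s</p>", enr$gs_pvalue[k],
              ifelse(is.na(enr$z_score[k]), "NA", fmt(enr$z_score[k]))),
      html_table(mem_df),
      svg_heat(hm$data, sprintf("signature heatmap %s", gs)),
      svg_scatter(vo$data, sprintf("signature volcano %s", gs),
                  highlight = vo$data$is_member))
  }

  for (g in bm$genes) {
    sym <- bundle$annotation$gene_name[match(g, bundle$annotation$gene_id)]
    de_row <- bundle$de[bundle$de$gene_id == g, , drop = FALSE]
    cond <- factor(bundle$samples[[1]])
    expr_df <- data.frame(x = as.numeric(cond), y = bundle$counts[g, ])
    parts <- c(parts,
      sprintf('<h2 class="section-gene">Gene %s (%s)</h2>',
              html_escape(g), html_escape(sym %||% "")),
      if (nrow(de_row) > 0) html_table(de_row) else "<p>not in DE table</p>",
      sprintf("<p>%s</p>", gene_links(sym, g)),
      svg_scatter(expr_df, sprintf("expression by condition %s", g)))
  }

  cfg_json <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                            digits = NA, null = "null"))
  parts <- c(parts,
    "<h2>Reproducibility appendix</h2>",
    sprintf("<p>Configuration (hash <code>%s</code>):</p>", config_hash(config)),
    sprintf("<pre>%s</pre>", html_escape(cfg_json)),
    if (length(snippets) > 0)
      c("<p>Regenerate each figure's plot data with:</p>",
        sprintf("<pre>%s</pre>", html_escape(snippets))),
    "</body></html>")

  con <- file(out_path, open = "wb")
  on.exit(close(con))
  writeLines(parts, con, useBytes = TRUE)
  invisible(out_path)
}

# ---- reproducible code snippets --------------------------------------------

snippet_ops <- function() c(
  "gs_volcano_data", "enhanced_table_data", "summary_heat_data",
  "signature_volcano_data", "spider_data", "scores_heatmap_data")

#' Command reproducing one plot-data artifact
#'
#' Returns a shell command (one `Rscript -e` invocation against the
#' installed package) that recomputes the named summary from the serialized
#' bundle in `config$bundle_path` and writes its plot data as JSON to
#' `config$out`. Running the command against the same bundle reproduces
#' the artifact bit-exactly. The config hash is embedded as a comment.
#'
#' @param op_name one of the plot-data builders (see `snippet_ops`).
#' @param config named list; recognized keys: `bundle_path`, `out`,
#'   `de_threshold`, `aggr`, `x`, `n_gs`, `n_labels`, `gs_id`, `members`.
#' @return a single character string.
#' @export
snippet_for <- function(op_name, config = list()) {
  if (!op_name %in% snippet_ops())
    stopf("unknown operation '%s'; snippets exist for: %s", op_name,
          paste(snippet_ops(), collapse = ", "))
  bp <- config$bundle_path %||% "bundle.json"
  out <- config$out %||% paste0(op_name, ".json")
  thr <- config$de_threshold %||% 0.05
  aggr <- config$aggr %||% "mean"
  body <- switch(op_name,
    gs_volcano_data = sprintf(
      'e <- compute_aggregate_scores(b$enrichment, b$de, b$annotation, de_threshold=%s, aggr="%s"); pd <- gs_volcano_data(e, x="%s", n_labels=%d)',
      format(thr), aggr, config$x %||% "z_score", config$n_labels %||% 5L),
    enhanced_table_data = sprintf(
      'pd <- enhanced_table_data(b$enrichment, b$de, b$annotation, n_gs=%d, de_threshold=%s)',
      config$n_gs %||% 15L, format(thr)),
    summary_heat_data = sprintf(
      'pd <- summary_heat_data(b$enrichment, b$de, b$annotation, n_gs=%d, de_threshold=%s)',
      config$n_gs %||% 15L, format(thr)),
    signature_volcano_data = sprintf(
      'pd <- signature_volcano_data(b, "%s")', config$gs_id %||% ""),
    spider_data = sprintf(
      'e <- compute_aggregate_scores(b$enrichment, b$de, b$annotation, de_threshold=%s, aggr="%s"); pd <- spider_data(e, n_gs=%d)',
      format(thr), aggr, config$n_gs %||% 10L),
    scores_heatmap_data = sprintf(
      'z <- compute_gene_z(transform_counts(b)); s <- compute_geneset_scores(z, b$enrichment, b$de, b$annotation, de_threshold=%s, members="%s"); pd <- scores_heatmap_data(s)',
      format(thr), config$members %||% "de_only"))
  sprintf(
    "Rscript -e 'library(pathsift); b <- read_bundle(\"%s\"); %s; plot_data_to_json(pd, \"%s\")' # config %s",
    bp, body, out, config_hash(config))
}
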