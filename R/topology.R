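#' Bipartite gene-geneset membership graph
#'
#' Builds the graph connecting the top `n_gs` most significant genesets to
#' their DE member genes. Geneset nodes carry `description` and `z_score`;
#' gene nodes carry `symbol` and `log2fc` (for continuous divergent
#' coloring downstream). Edges are unweighted membership links.
#'
#' @param bundle a [geneset_bundle()].
#' @param n_gs number of top genesets to include (default 15; ties broken
#'   by larger `gs_de_count`, then lexicographic `gs_id`).
#' @param de_threshold adjusted p-value cutoff for member inclusion.
#' @return an [igraph::igraph] with vertex attributes `type_label`
#'   (`"geneset"`/`"gene"`), `description`, `z_score`, `symbol`, `log2fc`.
#' @export
build_gene_geneset_graph <- function(bundle, n_gs = 15, de_threshold = 0.05) {
  enr <- top_genesets(bundle$enrichment, n_gs)
  if (anyNA(enr$z_score))
    enr <- compute_aggregate_scores(enr, bundle$de, bundle$annotation,
                                    de_threshold)
  st <- de_status(bundle$de, de_threshold)
  members <- lapply(enr$gs_genes, function(sym) {
    ids <- resolve_symbols(sym, bundle$annotation)
    ids <- unique(ids[!is.na(ids)])
    idx <- match(ids, st$gene_id)
    ids[!is.na(idx) & st$is_de[idx]]
  })
  gene_ids <- unique(unlist(members))
  edges <- do.call(rbind, lapply(seq_along(members), function(k) {
    if (length(members[[k]]) == 0) return(NULL)
    cbind(enr$gs_id[k], members[[k]])
  }))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nrow(enr), name = enr$gs_id,
                            type_label = "geneset",
                            description = enr$gs_description,
                            z_score = enr$z_score,
                            symbol = NA_character_, log2fc = NA_real_)
  if (length(gene_ids) > 0) {
    sym <- bundle$annotation$gene_name[match(gene_ids, bundle$annotation$gene_id)]
    lfc <- st$log2fc[match(gene_ids, st$gene_id)]
    g <- igraph::add_vertices(g, length(gene_ids), name = gene_ids,
                              type_label = "gene",
                              description = NA_character_,
                              z_score = NA_real_,
                              symbol = sym, log2fc = lfc)
  }
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  # bipartite marker used by igraph projections
  igraph::V(g)$type <- igraph::V(g)$type_label == "gene"
  g
}

#' Pairwise geneset similarity matrix
#'
#' Computes a square symmetric similarity matrix over the genesets'
#' member lists: Jaccard `|A n B| / |A u B|`, overlap coefficient
#' `|A n B| / min(|A|, |B|)`, or Cohen's kappa — the chance-corrected
#' agreement of the two membership indicator vectors over a gene universe
#' of `universe_size` genes.
#'
#' @param enrichment an [enrichment_table()] (or geneset collection).
#' @param measure `"jaccard"`, `"overlap"` or `"kappa"`.
#' @param universe_size total number of genes in the universe; required for
#'   kappa and must be at least the size of the union of memberships.
#' @return symmetric numeric matrix with `gs_id` dimnames and attribute
#'   `measure`.
#' @export
geneset_similarity <- function(enrichment, measure = c("jaccard", "overlap", "kappa"),
                               universe_size = NULL) {
  measure <- match.arg(measure)
  sets <- lapply(enrichment$gs_genes, unique)
  names(sets) <- enrichment$gs_id
  n <- length(sets)
  if (n < 2) stopf("need at least 2 genesets")
  if (measure == "kappa") {
    if (is.null(universe_size)) stopf("kappa requires universe_size")
    union_all <- length(unique(unlist(sets)))
    if (universe_size < union_all)
      stopf("universe_size (%d) smaller than union of memberships (%d)",
            universe_size, union_all)
  }
  sim <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  sizes <- lengths(sets)
  for (a in seq_len(n)) {
    for (b in a:n) {
      i <- length(intersect(sets[[a]], sets[[b]]))
      v <- switch(measure,
        jaccard = {
          u <- sizes[a] + sizes[b] - i
          if (u == 0) 1 else i / u
        },
        overlap = {
          m <- min(sizes[a], sizes[b])
          if (m == 0) 1 else i / m
        },
        kappa = {
          N <- universe_size
          n11 <- i
          n10 <- sizes[a] - i
          n01 <- sizes[b] - i
          n00 <- N - n11 - n10 - n01
          po <- (n11 + n00) / N
          pe <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / N^2
          if (pe == 1) 1 else (po - pe) / (1 - pe)
        })
      sim[a, b] <- sim[b, a] <- v
    }
  }
  attr(sim, "measure") <- measure
  sim
}

#' Enrichment map: geneset similarity graph
#'
#' Nodes are the top `n_gs` genesets (attributes: `gs_pvalue`, `z_score`,
#' `size` = `gs_de_count`); weighted edges connect genesets whose
#' similarity is at least `edge_threshold`.
#'
#' @param enrichment an [enrichment_table()] (scores already computed if
#'   `z_score` coloring is wanted).
#' @param n_gs number of top genesets (default 15).
#' @param measure similarity measure (default `"overlap"`).
#' @param edge_threshold minimum similarity for an edge (default 0.25).
#' @param universe_size passed to [geneset_similarity()] for kappa.
#' @return an [igraph::igraph] with edge attribute `weight`.
#' @export
build_enrichment_map <- function(enrichment, n_gs = 15,
                                 measure = c("overlap", "jaccard", "kappa"),
                                 edge_threshold = 0.25, universe_size = NULL) {
  measure <- match.arg(measure)
  lo <- if (measure == "kappa") -1 else 0
  if (edge_threshold < lo || edge_threshold > 1)
    stopf("edge_threshold %g outside the range [%g, 1] of measure '%s'",
          edge_threshold, lo, measure)
  enr <- top_genesets(enrichment, n_gs)
  sim <- geneset_similarity(enr, measure, universe_size)
  # edges built explicitly so that weight-0 pairs survive a 0 threshold
  pairs <- which(upper.tri(sim) & sim >= edge_threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(sim), name = rownames(sim))
  if (nrow(pairs) > 0) {
    g <- igraph::add_edges(
      g, rbind(rownames(sim)[pairs[, 1]], rownames(sim)[pairs[, 2]]),
      weight = sim[pairs])
  }
  igraph::V(g)$gs_pvalue <- enr$gs_pvalue[match(igraph::V(g)$name, enr$gs_id)]
  igraph::V(g)$z_score <- enr$z_score[match(igraph::V(g)$name, enr$gs_id)]
  igraph::V(g)$size <- enr$gs_de_count[match(igraph::V(g)$name, enr$gs_id)]
  igraph::V(g)$description <-
    enr$gs_description[match(igraph::V(g)$name, enr$gs_id)]
  g
}

#' Community detection on an enrichment map
#'
#' Labels every geneset node with a community and picks, per community, the
#' representative geneset (lowest `gs_pvalue`, ties by `gs_id`). Methods:
#' greedy modularity optimization or label propagation (seeded).
#'
#' @param map graph from [build_enrichment_map()].
#' @param method `"greedy_modularity"` or `"label_propagation"`.
#' @param seed RNG seed (label propagation is stochastic).
#' @return the graph with vertex attribute `community` and a
#'   `representatives` attribute: data frame (community, gs_id, n_members).
#' @export
detect_communities <- function(map, method = c("greedy_modularity",
                                               "label_propagation"),
                               seed = 42) {
  method <- match.arg(method)
  if (igraph::vcount(map) == 0) stopf("empty graph")
  set.seed(seed)
  comm <- switch(method,
    greedy_modularity = igraph::cluster_fast_greedy(map),
    label_propagation = igraph::cluster_label_prop(map))
  memb <- igraph::membership(comm)
  igraph::V(map)$community <- as.integer(memb)
  pv <- igraph::V(map)$gs_pvalue
  nm <- igraph::V(map)$name
  reps <- do.call(rbind, lapply(sort(unique(as.integer(memb))), function(cl) {
    in_cl <- which(memb == cl)
    best <- in_cl[order(pv[in_cl], nm[in_cl])][1]
    data.frame(community = cl, gs_id = nm[best], n_members = length(in_cl),
               stringsAsFactors = FALSE)
  }))
  attr(map, "representatives") <- reps
  map
}

#' Disparity-filter backbone of a bipartite projection
#'
#' Projects the bipartite gene-geneset graph onto one node type (edge
#' weight = number of shared neighbors of the other type), then keeps only
#' the statistically salient edges: for an endpoint of degree k and
#' strength s, an edge of weight w has p = w/s and score `(1 - p)^(k - 1)`;
#' the edge is retained if the score is below `alpha` at either endpoint.
#' Degree-1 endpoints always retain their single edge.
#'
#' @param graph bipartite graph from [build_gene_geneset_graph()].
#' @param side `"geneset"` or `"gene"`: which projection to backbone.
#' @param alpha significance threshold in (0, 1].
#' @return weighted unipartite [igraph::igraph] of the retained edges (all
#'   projection vertices kept; edge attribute `weight` = shared-neighbor
#'   count).
#' @export
extract_backbone <- function(graph, side = c("geneset", "gene"), alpha = 0.05) {
  side <- match.arg(side)
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (is.null(igraph::V(graph)$type))
    stopf("input graph is not bipartite (no type attribute)")
  proj <- igraph::bipartite_projection(graph, multiplicity = TRUE)
  # proj1 = type FALSE (genesets), proj2 = type TRUE (genes)
  p <- if (side == "geneset") proj$proj1 else proj$proj2
  if (igraph::ecount(p) == 0) return(p)
  ends <- igraph::ends(p, igraph::E(p), names = FALSE)
  w <- igraph::E(p)$weight
  deg <- igraph::degree(p)
  str <- igraph::strength(p)
  edge_score <- function(node, w_e) {
    k <- deg[node]
    if (k <= 1) return(-Inf)  # degree-1 endpoints always keep their edge
    (1 - w_e / str[node])^(k - 1)
  }
  keep <- vapply(seq_along(w), function(e) {
    edge_score(ends[e, 1], w[e]) < alpha || edge_score(ends[e, 2], w[e]) < alpha
  }, logical(1))
  igraph::subgraph_from_edges(p, igraph::E(p)[keep], delete.vertices = FALSE)
}

#' Export a graph to GraphML or DOT
#'
#' @param graph an igraph object.
#' @param path output file; format inferred from the extension
#'   (`.graphml` or `.dot`/`.gv`) unless given.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path,
                             format = c("auto", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("dot", "gv")) "dot" else "graphml"
  }
  igraph::write_graph(graph, path, format = format)
  invisible(path)
}
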