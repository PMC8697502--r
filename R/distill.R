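#' Kappa-based fuzzy clustering of redundant genesets
#'
#' DAVID-style fuzzy heuristic. (1) A kappa similarity matrix is computed
#' over the genesets. (2) Each geneset seeds a candidate cluster of itself
#' plus all neighbors with kappa at or above `similarity_threshold`; the
#' seed is kept when it has at least `seed_size` neighbors and more than
#' half of all within-seed pairs also clear the threshold. (3) Seeds
#' sharing at least a `multilinkage` fraction of members (relative to the
#' smaller seed) are merged iteratively to a fixpoint. (4) Genesets in no
#' surviving cluster become singletons. Fuzzy: a geneset may belong to
#' several clusters. The cluster representative is the member with the
#' lowest `gs_pvalue` (ties by `gs_id`).
#'
#' @param enrichment an [enrichment_table()] with at least 2 non-empty
#'   genesets.
#' @param similarity_threshold kappa threshold in (0, 1] (default 0.35).
#' @param seed_size minimum neighbor count for a valid seed (default 3).
#' @param multilinkage merge fraction in (0, 1] (default 0.5).
#' @param universe_size kappa universe; default is the size of the union
#'   of all member lists.
#' @param hard force hard assignment: each geneset keeps only the cluster
#'   whose representative it agrees with best (highest kappa).
#' @return a `cluster_assignment` data frame (`gs_id`, `cluster_id`,
#'   `status` in Representative/Member) with the parameters as attributes.
#' @export
fuzzy_cluster_genesets <- function(enrichment, similarity_threshold = 0.35,
                                   seed_size = 3, multilinkage = 0.5,
                                   universe_size = NULL, hard = FALSE) {
  if (similarity_threshold <= 0 || similarity_threshold > 1)
    stopf("similarity_threshold must be in (0, 1]")
  if (multilinkage <= 0 || multilinkage > 1)
    stopf("multilinkage must be in (0, 1]")
  nonempty <- lengths(enrichment$gs_genes) > 0
  enr <- enrichment[nonempty, , drop = FALSE]
  if (nrow(enr) < 2) stopf("need at least 2 genesets with non-empty gs_genes")
  if (is.null(universe_size))
    universe_size <- length(unique(unlist(enr$gs_genes)))
  kap <- geneset_similarity(enr, "kappa", universe_size = universe_size)
  n <- nrow(kap)

  seeds <- list()
  for (g in seq_len(n)) {
    nb <- setdiff(which(kap[g, ] >= similarity_threshold), g)
    if (length(nb) < seed_size) next
    s <- sort(c(g, nb))
    pairs <- utils::combn(s, 2)
    frac <- mean(kap[cbind(pairs[1, ], pairs[2, ])] >= similarity_threshold)
    if (frac > 0.5) seeds[[length(seeds) + 1]] <- s
  }
  seeds <- unique(seeds)

  # iterative multilinkage merging to fixpoint
  repeat {
    merged <- FALSE
    if (length(seeds) > 1) {
      for (a in seq_along(seeds)) {
        for (b in seq_along(seeds)) {
          if (b <= a) next
          shared <- length(intersect(seeds[[a]], seeds[[b]]))
          if (shared / min(length(seeds[[a]]), length(seeds[[b]])) >= multilinkage) {
            seeds[[a]] <- sort(union(seeds[[a]], seeds[[b]]))
            seeds[[b]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }

  clustered <- sort(unique(unlist(seeds)))
  singles <- setdiff(seq_len(n), clustered)
  clusters <- c(seeds, as.list(singles))
  # stable numbering: by best (lowest) p-value inside the cluster, then id
  pv <- enr$gs_pvalue
  ids <- enr$gs_id
  key <- vapply(clusters, function(cl) {
    best <- cl[order(pv[cl], ids[cl])][1]
    sprintf("%.17g|%s", pv[best], ids[best])
  }, character(1))
  clusters <- clusters[order(key)]

  rows <- do.call(rbind, lapply(seq_along(clusters), function(ci) {
    cl <- clusters[[ci]]
    rep_i <- cl[order(pv[cl], ids[cl])][1]
    data.frame(gs_id = ids[cl], cluster_id = ci,
               status = ifelse(cl == rep_i, "Representative", "Member"),
               stringsAsFactors = FALSE)
  }))
  if (hard) {
    reps <- rows$gs_id[rows$status == "Representative"]
    rep_of <- reps[rows$cluster_id[rows$status == "Representative"]]
    keep <- vapply(unique(rows$gs_id), function(id) {
      cand <- which(rows$gs_id == id)
      if (length(cand) == 1) return(cand)
      agree <- kap[id, rep_of[rows$cluster_id[cand]]]
      cand[order(-agree, rows$cluster_id[cand])][1]
    }, integer(1))
    rows <- rows[sort(keep), , drop = FALSE]
  }
  rownames(rows) <- NULL
  structure(rows, class = c("cluster_assignment", "data.frame"),
            similarity_threshold = similarity_threshold,
            seed_size = seed_size, multilinkage = multilinkage,
            universe_size = universe_size)
}

#' Greedy overlap-based reduction of redundant genesets
#'
#' Walks the genesets in increasing `gs_pvalue` order and drops any whose
#' overlap coefficient with an already-retained geneset reaches
#' `overlap_threshold`. Of two identical genesets, only the more
#' significant one survives; pairwise-disjoint sets are all retained.
#'
#' @param enrichment an [enrichment_table()].
#' @param overlap_threshold in (0, 1] (default 0.75).
#' @return the retained subset, in significance order.
#' @export
reduce_by_overlap <- function(enrichment, overlap_threshold = 0.75) {
  if (overlap_threshold <= 0 || overlap_threshold > 1)
    stopf("overlap_threshold must be in (0, 1]")
  ord <- geneset_order(enrichment)
  sets <- lapply(enrichment$gs_genes, unique)
  retained <- integer(0)
  for (k in ord) {
    redundant <- any(vapply(retained, function(r) {
      i <- length(intersect(sets[[k]], sets[[r]]))
      m <- min(length(sets[[k]]), length(sets[[r]]))
      ov <- if (m == 0) 1 else i / m
      ov >= overlap_threshold
    }, logical(1)))
    if (!redundant) retained <- c(retained, k)
  }
  enrichment[retained, , drop = FALSE]
}

#' Classical MDS layout of genesets
#'
#' Embeds the genesets in two dimensions by classical metric
#' multidimensional scaling of the dissimilarity `1 - similarity`;
#' coordinates are centered at the origin. An optional Z-score vector is
#' carried along as a point attribute for coloring.
#'
#' @param similarity symmetric similarity matrix from
#'   [geneset_similarity()].
#' @param z_scores optional numeric vector named by `gs_id`.
#' @return data frame (`gs_id`, `dim1`, `dim2`, `z_score`).
#' @export
geneset_mds <- function(similarity, z_scores = NULL) {
  if (!isSymmetric(unname(as.matrix(similarity))))
    stopf("similarity matrix must be symmetric")
  n <- nrow(similarity)
  if (n < 2) stopf("need at least 2 genesets")
  d <- 1 - similarity
  coords <- stats::cmdscale(stats::as.dist(d), k = min(2, n - 1))
  while (ncol(coords) < 2) coords <- cbind(coords, rep(0, n))
  out <- data.frame(gs_id = rownames(similarity),
                    dim1 = coords[, 1], dim2 = coords[, 2],
                    stringsAsFactors = FALSE)
  out$z_score <- if (is.null(z_scores)) NA_real_ else
    unname(z_scores[match(out$gs_id, names(z_scores))])
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering dendrogram of genesets
#'
#' Agglomerative clustering on the dissimilarity `1 - similarity` with
#' average or complete linkage; leaves are `gs_id`s, merge heights are
#' monotone.
#'
#' @param similarity symmetric similarity matrix.
#' @param linkage `"average"` or `"complete"`.
#' @return an [stats::hclust] object.
#' @export
geneset_dendrogram <- function(similarity, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (nrow(similarity) < 2) stopf("need at least 2 genesets")
  stats::hclust(stats::as.dist(1 - similarity), method = linkage)
}

#' Export a dendrogram as Newick
#'
#' Leaf names are `gs_id`s; branch lengths are merge-height differences.
#'
#' @param hc an [stats::hclust] from [geneset_dendrogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Export a cluster assignment as TSV
#'
#' @param assignment a `cluster_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
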