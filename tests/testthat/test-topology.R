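test_that("bipartite graph has the right nodes, edges and attributes", {
  ann <- data.frame(gene_id = letters[1:4], gene_name = LETTERS[1:4])
  counts <- matrix(5, 4, 4, dimnames = list(letters[1:4], paste0("s", 1:4)))
  samples <- data.frame(condition = rep(c("x", "y"), 2),
                        row.names = paste0("s", 1:4))
  de <- data.frame(gene_id = letters[1:4], log2fc = c(1, 2, -1, 0.5),
                   pvalue = 0.001, padj = 0.01)
  enr <- enr_from_sets(list(G1 = c("A", "B", "C"), G2 = c("B", "C", "D")),
                       c(0.001, 0.002))
  b <- geneset_bundle(counts, samples, de, enr, ann)
  g <- build_gene_geneset_graph(b, n_gs = 2)
  expect_equal(igraph::vcount(g), 6)  # 2 sets + 4 genes
  expect_equal(igraph::ecount(g), 6)
  # strictly bipartite
  ends <- igraph::ends(g, igraph::E(g))
  tl <- igraph::V(g)$type_label
  names(tl) <- igraph::V(g)$name
  expect_true(all(tl[ends[, 1]] != tl[ends[, 2]]))
  # geneset degree = resolved DE member count
  expect_identical(unname(igraph::degree(g, c("G1", "G2"))), c(3, 3))
  # gene attributes for coloring
  expect_equal(igraph::V(g)[["b"]]$log2fc, 2)

  # disjoint sets give two components; n_gs = 1 is a star
  enr2 <- enr_from_sets(list(G1 = c("A", "B"), G2 = c("C", "D")),
                        c(0.001, 0.002))
  b2 <- geneset_bundle(counts, samples, de, enr2, ann)
  g2 <- build_gene_geneset_graph(b2, n_gs = 2)
  expect_equal(igraph::count_components(g2), 2)
  g1 <- build_gene_geneset_graph(b2, n_gs = 1)
  expect_identical(unname(igraph::degree(g1, "G1")),
                   as.numeric(igraph::vcount(g1) - 1))
  expect_warning(build_gene_geneset_graph(b2, n_gs = 99), "clamp")
})

test_that("similarity measures match their definitions", {
  enr <- enr_from_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")),
                       c(0.01, 0.02))
  expect_equal(geneset_similarity(enr, "jaccard")["A", "B"], 0.5)
  expect_equal(geneset_similarity(enr, "overlap")["A", "B"], 2 / 3)
  # hand-computed 2x2 kappa oracle: universe 10, |A|=|B|=5, 4 shared
  enr2 <- enr_from_sets(list(A = paste0("g", 1:5), B = paste0("g", c(1:4, 6))),
                        c(0.01, 0.02))
  kap <- geneset_similarity(enr2, "kappa", universe_size = 10)
  expect_equal(kap["A", "B"], 0.6, tolerance = 1e-12)
  expect_error(geneset_similarity(enr2, "kappa"), "universe_size")
  expect_error(geneset_similarity(enr2, "kappa", universe_size = 3), "smaller")
})

test_that("similarity matrices are symmetric with correct diagonals", {
  for (s in 1:5) {
    set.seed(s)
    sets <- lapply(1:8, function(i) sample(paste0("g", 1:40), sample(3:12, 1)))
    names(sets) <- paste0("S", 1:8)
    enr <- enr_from_sets(sets)
    for (m in c("jaccard", "overlap", "kappa")) {
      sim <- geneset_similarity(enr, m, universe_size = 40)
      expect_true(isSymmetric(unname(sim)))
      expect_equal(unname(diag(sim)), rep(1, 8))
      rng <- if (m == "kappa") c(-1, 1) else c(0, 1)
      expect_true(all(sim >= rng[1] - 1e-12 & sim <= rng[2] + 1e-12))
    }
  }
})

test_that("enrichment map edges respect the threshold, monotonically", {
  enr <- two_block_enrichment(1)
  counts <- sapply(c(0, 0.25, 0.5, 0.8, 1), function(t)
    igraph::ecount(build_enrichment_map(enr, n_gs = 12, "overlap",
                                        edge_threshold = t)))
  expect_true(all(diff(counts) <= 0))
  # threshold 0 (jaccard): complete graph
  full <- build_enrichment_map(enr, n_gs = 12, "jaccard", edge_threshold = 0)
  expect_equal(igraph::ecount(full), choose(12, 2))
  expect_true(all(igraph::E(full)$weight >= 0))
  # identical member lists give edge weight 1; others drop at threshold 1
  twin <- enr_from_sets(list(A = c("x", "y"), B = c("x", "y"),
                             C = c("p", "q")), c(0.01, 0.02, 0.03))
  m1 <- build_enrichment_map(twin, n_gs = 3, "jaccard", edge_threshold = 1)
  expect_equal(igraph::ecount(m1), 1)
  expect_equal(igraph::E(m1)$weight, 1)
  expect_error(build_enrichment_map(enr, 12, "jaccard", edge_threshold = 1.5),
               "outside")
})

test_that("community detection partitions nodes and picks representatives", {
  # two disconnected near-cliques must separate under both methods
  enr <- two_block_enrichment(3)
  em <- build_enrichment_map(enr, n_gs = 12, "overlap", edge_threshold = 0.25)
  for (method in c("greedy_modularity", "label_propagation")) {
    out <- detect_communities(em, method, seed = 1)
    memb <- igraph::V(out)$community
    expect_false(anyNA(memb))
    reps <- attr(out, "representatives")
    expect_identical(sort(unique(memb)), reps$community)
    # representative = lowest p in its community
    pv <- igraph::V(out)$gs_pvalue
    for (i in seq_len(nrow(reps))) {
      in_cl <- memb == reps$community[i]
      expect_equal(pv[igraph::V(out)$name == reps$gs_id[i]], min(pv[in_cl]))
    }
  }
  # a singleton node is its own community and representative
  lone <- enr_from_sets(list(A = c("x", "y"), B = c("x", "y"),
                             C = c("p", "q")), c(0.01, 0.02, 0.03))
  em2 <- build_enrichment_map(lone, 3, "jaccard", edge_threshold = 0.5)
  out2 <- detect_communities(em2, "greedy_modularity")
  reps2 <- attr(out2, "representatives")
  expect_true("C" %in% reps2$gs_id)
  expect_identical(reps2$n_members[reps2$gs_id == "C"], 1L)
})

test_that("projection weights equal brute-force pairwise intersections", {
  for (s in 1:3) {
    fx <- generate_fixture(fixture_spec(n_genes = 80, n_genesets = 12,
                                        geneset_size_range = c(4, 10),
                                        frac_de = 0.3, seed = s))
    b <- fx$bundle
    g <- suppressWarnings(build_gene_geneset_graph(b, n_gs = 12))
    proj <- igraph::bipartite_projection(g, multiplicity = TRUE)$proj1
    # oracle: incidence %*% t(incidence) off-diagonal
    inc <- as.matrix(igraph::as_biadjacency_matrix(g))
    w_oracle <- inc %*% t(inc)
    for (e in seq_len(igraph::ecount(proj))) {
      uv <- igraph::ends(proj, e)
      expect_equal(igraph::E(proj)$weight[e], w_oracle[uv[1], uv[2]])
    }
    # zero intersections produce no projection edge
    expect_equal(igraph::ecount(proj),
                 sum(w_oracle[upper.tri(w_oracle)] > 0))
  }
})

test_that("disparity filter scores and conventions", {
  # star of 4 equal-weight edges around a hub: score = 0.75^3 at the hub
  ann <- data.frame(gene_id = letters[1:9], gene_name = LETTERS[1:9])
  counts <- matrix(5, 9, 2, dimnames = list(letters[1:9], c("s1", "s2")))
  samples <- data.frame(condition = c("x", "y"), row.names = c("s1", "s2"))
  de <- data.frame(gene_id = letters[1:9], log2fc = 1, pvalue = 0.001,
                   padj = 0.01)
  # hub set H shares exactly one gene with each of 4 others; the others are
  # pairwise disjoint
  sets <- list(H = c("A", "B", "C", "D"),
               P = c("A", "E"), Q = c("B", "F"), R = c("C", "G"),
               S = c("D", "H"))
  enr <- enr_from_sets(sets, c(0.001, 0.01, 0.02, 0.03, 0.04))
  b <- geneset_bundle(counts, samples, de, enr, ann)
  g <- build_gene_geneset_graph(b, n_gs = 5)
  bb_loose <- extract_backbone(g, "geneset", alpha = 0.43)
  bb_tight <- extract_backbone(g, "geneset", alpha = 0.42)
  # each spoke has degree 1 at its outer endpoint -> always retained
  expect_equal(igraph::ecount(bb_loose), 4)
  expect_equal(igraph::ecount(bb_tight), 4)
  expect_error(extract_backbone(g, "geneset", alpha = 0), "alpha")

  # backbone edge set monotone non-decreasing in alpha
  fx <- generate_fixture(fixture_spec(n_genes = 80, n_genesets = 15,
                                      geneset_size_range = c(4, 10),
                                      frac_de = 0.3, seed = 7))
  gg <- suppressWarnings(build_gene_geneset_graph(fx$bundle, n_gs = 15))
  sizes <- vapply(c(0.05, 0.2, 0.5, 1),
                  function(a) igraph::ecount(extract_backbone(gg, "geneset", a)),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("graphs export to GraphML and DOT", {
  fx <- generate_fixture(fixture_spec(n_genes = 60, n_genesets = 6,
                                      geneset_size_range = c(3, 6), seed = 2))
  g <- suppressWarnings(build_gene_geneset_graph(fx$bundle, n_gs = 5))
  gml <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_graph_file(g, gml)
  write_graph_file(g, dot)
  expect_true(any(grepl("graphml", readLines(gml, n = 3))))
  expect_true(any(grepl("graph", readLines(dot, n = 3))))
})
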