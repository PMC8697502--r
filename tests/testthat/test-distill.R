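test_that("fuzzy clustering: degenerate and planted cases", {
  # identical sets: one cluster, most significant is Representative
  same <- enr_from_sets(list(A = c("x", "y", "z"), B = c("x", "y", "z"),
                             C = c("x", "y", "z")), c(0.02, 0.001, 0.03))
  cl <- fuzzy_cluster_genesets(same, seed_size = 1, universe_size = 50)
  expect_identical(max(cl$cluster_id), 1L)
  expect_identical(cl$gs_id[cl$status == "Representative"], "B")

  # pairwise disjoint small sets: kappa <= 0, all singletons
  disj <- enr_from_sets(list(A = c("a1", "a2"), B = c("b1", "b2"),
                             C = c("c1", "c2")), c(0.01, 0.02, 0.03))
  cl2 <- fuzzy_cluster_genesets(disj, universe_size = 100)
  expect_identical(nrow(cl2), 3L)
  expect_identical(length(unique(cl2$cluster_id)), 3L)
  expect_true(all(cl2$status == "Representative"))

  # planted 6-set two-block structure (seed_size 2 fits 3-set blocks):
  # exactly 2 multi-member clusters, verified against the brute-force
  # expectation that each block clusters together
  set.seed(5)
  poolA <- sprintf("a%02d", 1:12); poolB <- sprintf("b%02d", 1:12)
  sets <- c(lapply(1:3, function(i) sample(poolA, 10)),
            lapply(1:3, function(i) sample(poolB, 10)))
  names(sets) <- sprintf("S%d", 1:6)
  enr <- enr_from_sets(sets)
  cl3 <- fuzzy_cluster_genesets(enr, similarity_threshold = 0.35,
                                seed_size = 2, multilinkage = 0.5)
  sizes <- table(cl3$cluster_id)
  expect_identical(sum(sizes > 1), 2L)
  blocks <- split(cl3$gs_id, cl3$cluster_id)
  multi <- blocks[lengths(blocks) > 1]
  expect_setequal(sort(unlist(lapply(multi, sort))),
                  sprintf("S%d", 1:6))
  for (bl in multi)
    expect_identical(length(unique(substr(sort(bl), 1, 1))), 1L)

  expect_error(fuzzy_cluster_genesets(enr, similarity_threshold = 2), "0, 1")
})

test_that("fuzzy clustering is deterministic and order-invariant", {
  enr <- two_block_enrichment(8)
  a <- fuzzy_cluster_genesets(enr)
  b <- fuzzy_cluster_genesets(enr)
  expect_identical(a, b)
  perm <- enr[c(7:12, 1:6), , drop = FALSE]
  p <- fuzzy_cluster_genesets(perm)
  key <- function(cl) {
    grp <- split(cl$gs_id, cl$cluster_id)
    sort(vapply(grp, function(g) paste(sort(g), collapse = "|"), ""))
  }
  expect_identical(unname(key(a)), unname(key(p)))
})

test_that("hard assignment keeps each geneset exactly once", {
  enr <- two_block_enrichment(2)
  h <- fuzzy_cluster_genesets(enr, hard = TRUE)
  expect_identical(anyDuplicated(h$gs_id), 0L)
  expect_setequal(h$gs_id, enr$gs_id)
})

test_that("reduce_by_overlap: identity, disjoint, chain and maximality", {
  twin <- enr_from_sets(list(A = c("x", "y"), B = c("x", "y")), c(0.02, 0.01))
  kept <- reduce_by_overlap(twin, 0.75)
  expect_identical(kept$gs_id, "B")  # the more significant of two identical

  disj <- enr_from_sets(list(A = c("a", "b"), B = c("c", "d"),
                             C = c("e", "f")), c(0.01, 0.02, 0.03))
  expect_identical(nrow(reduce_by_overlap(disj, 0.1)), 3L)

  # chain A ~ B ~ C with overlap(A, C) below threshold: B dropped
  chain <- enr_from_sets(
    list(A = c("g1", "g2", "g3", "g4"),
         B = c("g3", "g4", "g5", "g6"),
         C = c("g5", "g6", "g7", "g8")),
    c(0.001, 0.01, 0.02))
  out <- reduce_by_overlap(chain, 0.5)
  expect_identical(out$gs_id, c("A", "C"))

  # greedy maximality: every dropped set overlaps some retained set
  for (s in 1:5) {
    set.seed(s)
    sets <- lapply(1:10, function(i) sample(paste0("g", 1:25), sample(4:10, 1)))
    names(sets) <- paste0("S", 1:10)
    enr <- enr_from_sets(sets)
    ret <- reduce_by_overlap(enr, 0.6)
    dropped <- setdiff(enr$gs_id, ret$gs_id)
    ov <- function(a, b) length(intersect(a, b)) / min(length(a), length(b))
    for (d in dropped) {
      overlaps <- vapply(ret$gs_id, function(r)
        ov(enr$gs_genes[[match(d, enr$gs_id)]],
           enr$gs_genes[[match(r, enr$gs_id)]]), numeric(1))
      expect_true(any(overlaps >= 0.6))
    }
  }
  expect_error(reduce_by_overlap(disj, 0), "0, 1")
})

test_that("two-point and planted-coordinate MDS", {
  sim <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  out <- geneset_mds(sim)
  expect_equal(abs(out$dim1), c(0.2, 0.2), tolerance = 1e-9)
  expect_equal(out$dim2, c(0, 0))

  # identical sets -> coincident points
  sim2 <- matrix(1, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  out2 <- geneset_mds(sim2)
  expect_equal(max(dist(out2[, c("dim1", "dim2")])), 0, tolerance = 1e-9)

  # dissimilarities constructed from planted 2D coordinates are reproduced
  set.seed(1)
  xy <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(xy))
  d <- d / max(d)
  sim3 <- 1 - d
  dimnames(sim3) <- list(paste0("P", 1:6), paste0("P", 1:6))
  out3 <- geneset_mds(sim3)
  dhat <- as.matrix(dist(out3[, c("dim1", "dim2")]))
  stress <- sqrt(sum((d - dhat)^2) / sum(d^2))
  expect_lt(stress, 0.05)

  expect_error(geneset_mds(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("MDS layout is permutation-invariant up to rotation/reflection", {
  enr <- two_block_enrichment(4)
  sim <- geneset_similarity(enr, "jaccard")
  a <- geneset_mds(sim)
  perm <- sample(nrow(sim))
  b <- geneset_mds(sim[perm, perm])
  X <- as.matrix(a[match(b$gs_id, a$gs_id), c("dim1", "dim2")])
  Y <- as.matrix(b[, c("dim1", "dim2")])
  # Procrustes: optimal orthogonal alignment residual ~ 0
  s <- svd(t(Y) %*% X)
  R <- s$u %*% t(s$v)
  expect_lt(max(abs(Y %*% R - X)), 1e-6)
})

test_that("dendrogram merges nearest pairs with monotone heights", {
  sim <- matrix(c(1, 0.9, 0.1,
                  0.9, 1, 0.1,
                  0.1, 0.1, 1), 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- geneset_dendrogram(sim, "average")
  expect_equal(hc$height[1], 0.1, tolerance = 1e-12)  # (A,B) first at d 0.1
  expect_identical(sort(hc$labels[-hc$merge[1, ]]), c("A", "B"))
  expect_true(all(diff(hc$height) >= 0))

  # identical sets merge at height 0
  sim2 <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(geneset_dendrogram(sim2)$height, 0)

  # average-linkage heights match a brute-force agglomeration on 5 sets
  set.seed(3)
  sets <- lapply(1:5, function(i) sample(paste0("g", 1:15), 6))
  names(sets) <- paste0("S", 1:5)
  sim3 <- geneset_similarity(enr_from_sets(sets), "jaccard")
  hc3 <- geneset_dendrogram(sim3, "average")
  # oracle: naive repeated merging with UPGMA averaging over original members
  d <- 1 - sim3; diag(d) <- NA
  groups <- as.list(rownames(d))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (j <= i) next
      dd <- mean(d[groups[[i]], groups[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  expect_equal(hc3$height, heights, tolerance = 1e-12)

  expect_error(geneset_dendrogram(sim3, "ward"), "average")

  # newick export preserves the leaves
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc3, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, rownames(sim3))
})

test_that("cluster assignments export as TSV", {
  enr <- two_block_enrichment(6)
  cl <- fuzzy_cluster_genesets(enr)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_clusters_tsv(cl, tsv)
  back <- read.delim(tsv)
  expect_identical(nrow(back), nrow(cl))
  expect_identical(names(back), c("gs_id", "cluster_id", "status"))
})
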