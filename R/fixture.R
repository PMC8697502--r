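#' Specification of a synthetic test dataset
#'
#' Describes a two-group RNA-seq-like experiment with planted DE genes and
#' planted enriched genesets. Defaults describe a desk-scale but realistic
#' bulk experiment: 500 genes, 4 vs 4 samples, negative-binomial counts
#' with log-normal baselines and dispersion 0.1, 10% DE genes with a
#' planted |log2FC| of 2, 40 genesets of 10-30 members of which 4 are
#' preferentially drawn (>= 70% of members) from the up-regulated DE pool.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group samples per group (two groups).
#' @param n_genesets number of genesets.
#' @param geneset_size_range inclusive (min, max) member counts.
#' @param frac_de fraction of genes with a planted effect, in (0, 1).
#' @param lfc_effect mean planted |log2 fold change|.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param n_planted_enriched number of genesets planted as enriched.
#' @param seed RNG seed fixing every downstream draw.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 500, n_samples_per_group = 4,
                         n_genesets = 40, geneset_size_range = c(10, 30),
                         frac_de = 0.1, lfc_effect = 2, nb_dispersion = 0.1,
                         n_planted_enriched = 4, seed = 1) {
  if (n_genes < 1 || n_samples_per_group < 1 || n_genesets < 1)
    stopf("counts in a fixture spec must be >= 1")
  if (frac_de <= 0 || frac_de >= 1) stopf("frac_de must be in (0, 1)")
  if (max(geneset_size_range) > n_genes)
    stopf("geneset_size_range exceeds n_genes")
  structure(list(n_genes = n_genes,
                 n_samples_per_group = n_samples_per_group,
                 n_genesets = n_genesets,
                 geneset_size_range = geneset_size_range,
                 frac_de = frac_de, lfc_effect = lfc_effect,
                 nb_dispersion = nb_dispersion,
                 n_planted_enriched = n_planted_enriched,
                 seed = seed),
            class = "fixture_spec")
}

# simple per-gene two-group Welch test on shifted-log values; fills the DE
# table of the fixture (any consistent test would do here)
two_group_test <- function(counts, group) {
  tr <- transform_counts(counts)
  g1 <- group == levels(factor(group))[1]
  res <- t(apply(tr, 1, function(v) {
    a <- v[g1]; b <- v[!g1]
    lfc <- mean(b) - mean(a)
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) 1
         else tryCatch(stats::t.test(b, a)$p.value, error = function(e) 1)
    c(lfc, p)
  }))
  p <- pmin(pmax(res[, 2], .Machine$double.xmin), 1)
  data.frame(gene_id = rownames(counts), log2fc = res[, 1],
             pvalue = p, padj = pmin(stats::p.adjust(p, "BH"), 1),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic bundle with known truth
#'
#' Draws negative-binomial counts with log-normal per-gene baselines;
#' plants a multiplicative `2^(+/- lfc_effect)` group effect on a `frac_de`
#' fraction of genes (random sign); fills the DE table by a two-group test
#' on the simulated counts; samples genesets from the gene universe, with
#' `n_planted_enriched` sets drawn preferentially (>= 70% of members) from
#' the up-regulated planted pool; and fills the enrichment p-values by a
#' one-sided hypergeometric tail on the DE-member overlap (fixture support
#' only — this is not a shipped analysis method). The truth (planted DE
#' genes, planted enriched sets) is returned and, when `out_dir` is given,
#' written alongside the inputs (TSV tables, GMT, bundle JSON, truth JSON).
#'
#' @param spec a [fixture_spec()].
#' @param out_dir optional directory to materialize the fixture into.
#' @return list with `bundle` (a [geneset_bundle()]), `truth`
#'   (`planted_de_up`, `planted_de_down`, `planted_enriched`), and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), out_dir = NULL) {
  set.seed(spec$seed)
  ng <- spec$n_genes
  ns <- 2 * spec$n_samples_per_group
  gene_id <- sprintf("GENE%04d", seq_len(ng))
  gene_name <- sprintf("Sym%04d", seq_len(ng))
  sample_id <- sprintf("sample_%02d", seq_len(ns))
  group <- rep(c("control", "treated"), each = spec$n_samples_per_group)

  base_mu <- 2^stats::rnorm(ng, mean = 5, sd = 1.5)
  n_de <- max(1, round(spec$frac_de * ng))
  de_idx <- sample.int(ng, n_de)
  sign_up <- stats::runif(n_de) < 0.5
  lfc <- numeric(ng)
  lfc[de_idx] <- ifelse(sign_up, spec$lfc_effect, -spec$lfc_effect)

  mu <- cbind(matrix(base_mu, ng, spec$n_samples_per_group),
              matrix(base_mu * 2^lfc, ng, spec$n_samples_per_group))
  size <- 1 / spec$nb_dispersion
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu, size = size), ng, ns,
                   dimnames = list(gene_id, sample_id))

  samples <- data.frame(condition = group, row.names = sample_id)
  de <- two_group_test(counts, group)

  up_pool <- gene_name[de_idx[sign_up]]
  sizes <- sample(seq(spec$geneset_size_range[1], spec$geneset_size_range[2]),
                  spec$n_genesets, replace = TRUE)
  planted <- seq_len(min(spec$n_planted_enriched, spec$n_genesets))
  gs_genes <- lapply(seq_len(spec$n_genesets), function(k) {
    sz <- sizes[k]
    if (k %in% planted && length(up_pool) > 0) {
      n_from_pool <- min(length(up_pool), ceiling(0.7 * sz))
      pool_part <- sample(up_pool, n_from_pool)
      rest <- sample(setdiff(gene_name, pool_part), sz - n_from_pool)
      sample(c(pool_part, rest))
    } else {
      sample(gene_name, sz)
    }
  })
  gs_id <- sprintf("GS%03d", seq_len(spec$n_genesets))

  # hypergeometric tail on DE overlap (fixture filler only)
  de_set <- gene_name[match(de$gene_id[effective_padj(de) <= 0.05], gene_id)]
  K <- length(de_set)
  pvals <- vapply(gs_genes, function(g) {
    x <- length(intersect(g, de_set))
    stats::phyper(x - 1, K, ng - K, length(g), lower.tail = FALSE)
  }, numeric(1))
  pvals <- pmax(pvals, .Machine$double.xmin)

  enr <- data.frame(gs_id = gs_id,
                    gs_description = sprintf("synthetic geneset %s", gs_id),
                    gs_pvalue = pvals, stringsAsFactors = FALSE)
  enr$gs_genes <- gs_genes
  enr <- enrichment_table(enr)

  annotation <- data.frame(gene_id = gene_id, gene_name = gene_name,
                           stringsAsFactors = FALSE)
  bundle <- geneset_bundle(counts, samples, de, enr, annotation)
  truth <- list(planted_de_up = gene_id[de_idx[sign_up]],
                planted_de_down = gene_id[de_idx[!sign_up]],
                planted_enriched = gs_id[planted])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(out_dir, f)
    utils::write.table(data.frame(gene_id = gene_id, counts,
                                  check.names = FALSE),
                       fp("counts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(sample_id = sample_id, samples),
                       fp("samples.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(de, fp("de.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(annotation, fp("annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gmt <- enr[, c("gs_id", "gs_description")]
    gmt$gs_genes <- enr$gs_genes
    write_gmt(gmt, fp("genesets.gmt"))
    flat <- as.data.frame(enr)
    flat$gs_genes <- vapply(flat$gs_genes, paste, character(1), collapse = ",")
    utils::write.table(flat, fp("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_bundle(bundle, fp("bundle.json"))
    jsonlite::write_json(truth, fp("truth.json"), auto_unbox = FALSE)
  }
  list(bundle = bundle, truth = truth, spec = spec)
}
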