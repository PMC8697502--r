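# Hand-built deterministic micro-bundle used across the unit tests:
# 6 genes x 4 samples (2 conditions), 3 genesets, known DE structure.
tiny_bundle <- function() {
  gene_id <- paste0("g", 1:6)
  sym <- paste0("S", 1:6)
  counts <- matrix(c(10, 12, 40, 44,
                     5, 6, 20, 22,
                     100, 90, 95, 105,
                     0, 1, 8, 9,
                     50, 55, 12, 10,
                     7, 7, 7, 7),
                   nrow = 6, byrow = TRUE,
                   dimnames = list(gene_id, paste0("s", 1:4)))
  samples <- data.frame(condition = c("ctl", "ctl", "trt", "trt"),
                        row.names = paste0("s", 1:4))
  de <- data.frame(gene_id = gene_id,
                   log2fc = c(2, 1, 0, 1.5, -2.2, 0.1),
                   pvalue = c(1e-4, 1e-3, 0.9, 1e-3, 1e-4, 0.8),
                   padj = c(1e-3, 0.01, 0.95, 0.01, 1e-3, NA))
  enr <- data.frame(gs_id = c("GS_A", "GS_B", "GS_C"),
                    gs_description = c("up set", "mixed set", "dull set"),
                    gs_pvalue = c(0.001, 0.01, 0.5))
  enr$gs_genes <- list(c("S1", "S2", "S4"), c("S1", "S5"), c("S3", "S6"))
  annotation <- data.frame(gene_id = gene_id, gene_name = sym)
  geneset_bundle(counts, samples, de, enrichment_table(enr), annotation)
}

# The same logical 3-set enrichment result written in every tool dialect.
# p-values are chosen identical across raw/adjusted columns so that the
# harmonized tables coincide.
dialect_fixture <- function() {
  ids <- c("GO:0000001", "GO:0000002", "GO:0000003")
  desc <- c("alpha process", "beta process", "gamma process")
  p <- c(0.001, 0.02, 0.2)
  genes <- list(c("TP53", "MDM2", "CDKN1A"), c("BAX", "BCL2"),
                c("EGFR", "KRAS", "MYC", "TP53"))
  k <- lengths(genes)
  n_bg <- c(120, 80, 200)
  list(
    topgo = data.frame(GO.ID = ids, Term = desc, Annotated = n_bg,
                       Significant = k, p.value_elim = p,
                       genes = vapply(genes, paste, "", collapse = ","),
                       check.names = FALSE),
    clusterprofiler = data.frame(
      ID = ids, Description = desc, GeneRatio = sprintf("%d/%d", k, n_bg),
      pvalue = p / 2, p.adjust = p,
      geneID = vapply(genes, paste, "", collapse = "/")),
    david = data.frame(
      Category = "GOTERM_BP", Term = paste0(ids, "~", desc), Count = k,
      PValue = p, Genes = vapply(genes, paste, "", collapse = ", ")),
    enrichr = data.frame(
      Term = ids, Overlap = sprintf("%d/%d", k, n_bg), P.value = p / 2,
      Adjusted.P.value = p,
      Genes = vapply(genes, paste, "", collapse = ";"),
      check.names = FALSE),
    gprofiler = data.frame(
      term_id = ids, term_name = desc, p_value = p, term_size = n_bg,
      intersection_size = k,
      intersection = vapply(genes, paste, "", collapse = ",")),
    fgsea = data.frame(
      pathway = ids, pval = p / 2, padj = p, size = n_bg,
      leadingEdge = vapply(genes, paste, "", collapse = ","))
  )
}

# enrichment table built directly from geneset member lists
enr_from_sets <- function(sets, pvalues = NULL) {
  if (is.null(pvalues)) pvalues <- seq(0.001, 0.05, length.out = length(sets))
  df <- data.frame(gs_id = names(sets),
                   gs_description = paste("set", names(sets)),
                   gs_pvalue = pvalues)
  df$gs_genes <- unname(sets)
  enrichment_table(df)
}

# planted two-block geneset structure: 6 sets from pool A, 6 from pool B
two_block_enrichment <- function(seed) {
  set.seed(seed)
  poolA <- sprintf("A%02d", 1:30)
  poolB <- sprintf("B%02d", 1:30)
  sets <- c(lapply(1:6, function(i) sample(poolA, 20)),
            lapply(1:6, function(i) sample(poolB, 20)))
  names(sets) <- sprintf("GS%02d", 1:12)
  enr_from_sets(sets, pvalues = round(stats::runif(12, 1e-5, 0.01), 8))
}
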