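#!/usr/bin/env Rscript

# Stage 4: DiSTATIS compromise analysis of the community transcriptomes.
#
# Per day: rlog-transform the counts, take each retained taxon's most
# variable genes, build one Euclidean sample-distance table per taxon, and
# compute the DiSTATIS compromise (RV-weighted consensus of the tables).
# The compromise scores are clustered by k-means with Krzanowski-Lai
# selection of k, treatment separation is tested by PERMANOVA on the axes
# explaining 99% of compromise variance, and dispersion homogeneity by
# PERMDISP; per-sample uncertainty comes from 1000 table bootstraps.

suppressMessages(library(coevocomm))
dir.create("results/ordination", showWarnings = FALSE, recursive = TRUE)
seed <- 4540

em <- read_count_matrix("results/data/counts.tsv", "results/data/gene_taxa.tsv",
                        "results/data/sample_meta.tsv", "results/data/relabund.tsv")
keep <- taxon_inclusion(em, threshold = 0.005)
em <- subset_expression(em, genes = names(em$gene_taxon)[em$gene_taxon %in% keep])

for (d in sort(unique(em$sample_meta$day))) {
  emd <- subset_expression(em, samples =
    em$sample_meta$sample_id[em$sample_meta$day == d])
  sf <- within_taxon_size_factors(emd)
  phi <- estimate_dispersions(emd, sf)
  rl <- rlog_transform(emd, sf, phi)
  sets <- suppressWarnings(select_top_variable(rl, emd, n = 100))
  res <- distatis(expression_distances(rl, sets))
  message(sprintf("day %d: compromise axis 1 explains %.0f%%, axis 2 %.0f%% of variance",
                  d, 100 * res$tau[1], 100 * res$tau[2]))

  cl <- kmeans_kl(res$F[, 1:2], k_range = 2:6, seed = seed + d)
  meta <- emd$sample_meta[rownames(res$F), ]
  grp <- paste0(ifelse(meta$predation, "pred", "free"), "_",
                ifelse(meta$coevolved_prey, "coevo", "anc"))
  pmv <- permanova(res, grp, B = 999, seed = seed + 10 + d)
  pdp <- permdisp(res, grp, B = 999, seed = seed + 20 + d)
  boot <- bootstrap_compromise(res, B = 1000, seed = seed + 30 + d)
  message(sprintf("day %d: k-means selects k = %d; PERMANOVA F = %.2f (R2 = %.2f, p = %.3g); PERMDISP p = %.3g",
                  d, cl$k, pmv$F, pmv$R2, pmv$p, pdp$p))

  write_tsv(data.frame(sample = rownames(res$F), res$F[, 1:min(4, ncol(res$F))],
                       cluster = cl$labels, group = grp, check.names = FALSE),
            sprintf("results/ordination/compromise_day%d.tsv", d))
  write_tsv(data.frame(table = names(res$alpha), alpha = unname(res$alpha)),
            sprintf("results/ordination/alpha_day%d.tsv", d))
  write_tsv(boot$ellipses, sprintf("results/ordination/ellipses_day%d.tsv", d))
  write_tsv(data.frame(test = c("permanova", "permdisp"),
                       F = c(pmv$F, pdp$F), p = c(pmv$p, pdp$p),
                       R2 = c(pmv$R2, NA), tau1 = res$tau[1], tau2 = res$tau[2],
                       k_selected = cl$k),
            sprintf("results/ordination/permtests_day%d.tsv", d))
}
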