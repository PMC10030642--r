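#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study data used by the downstream analyses.
#
# Emulates a predator-prey coevolution community experiment: three replicate
# evolved populations of a focal prey bacterium resequenced against their
# ancestor, and a multi-species community transcriptome sampled under a 2x2
# factorial design (ciliate predation x coevolved focal prey) with three
# replicates on two sampling days. Ten genes carry genuinely enriched
# mutations (targets of parallel selection) and 60 community genes respond
# only to the predation x coevolution interaction; one taxon's abundance
# also shifts with predation, creating the confound the within-taxon
# normalization exists to remove.

suppressMessages(library(coevocomm))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20260920 %% 100000

## genomes and mutations -------------------------------------------------------
mut_spec <- mutation_sim_spec(n_populations = 3, genome_length = 1e6,
                              n_genes = 1000, n_per_pop = 100,
                              target_genes = sprintf("g%04d", seq(50, 950, 100)),
                              theta = 20, seed = seed)
catalog <- simulate_genome(mut_spec)
mutations <- simulate_mutations(catalog, mut_spec)
write_gene_models(catalog, "results/data/genome.gff3")
write_variant_vcf(mutations, "results/data/vcf", catalog$contig_lengths)
write_mutation_table(mutations, "results/data/mutations.tsv", seed = seed)

message(sprintf("genome: %d genes over %.0f bp (mean length %.0f bp)",
                nrow(catalog$genes), catalog$genome_length,
                mean_gene_length(catalog)))
message(sprintf("mutations: %d records across %d populations (%d in target genes)",
                nrow(mutations), length(unique(mutations$population_id)),
                sum(vapply(mutations$gene_ids, function(g)
                  any(g %in% mut_spec$target_genes), logical(1)))))

## community transcriptomes ----------------------------------------------------
interaction_genes <- sprintf("t%02d_g%04d", rep(1:6, each = 10), rep(1:10, 6))
down_genes <- sprintf("t%02d_g%04d", rep(1:6, each = 10), rep(11:20, 6))
comm_spec <- community_sim_spec(
  n_taxa = 6, genes_per_taxon = 250, n_replicates = 3, days = c(4L, 45L),
  effects = rbind(
    data.frame(gene = interaction_genes, coef = "interaction", lfc = 3),
    data.frame(gene = down_genes, coef = "interaction", lfc = -3)),
  abundance_shifts = data.frame(taxon = "t06", coef = "predation", fold = 3),
  seed = seed + 1)
em <- simulate_community(comm_spec)
write_count_matrix(em, "results/data/counts.tsv", "results/data/gene_taxa.tsv",
                   "results/data/sample_meta.tsv", "results/data/relabund.tsv",
                   seed = seed + 1)
message(sprintf("community: %d genes x %d samples, %d taxa; %d interaction-responsive genes",
                nrow(em$counts), ncol(em$counts),
                length(unique(em$gene_taxon)), length(interaction_genes) * 2))
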