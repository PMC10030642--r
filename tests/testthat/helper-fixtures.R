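# Small fixtures built in code, shared across test files.

toy_catalog <- function() {
  gene_catalog(data.frame(gene_id = c("gA", "gB", "gC"),
                          contig = "chr1",
                          start = c(11L, 18L, 101L),
                          end = c(20L, 40L, 200L),
                          strand = c("+", "-", "+")),
               c(chr1 = 1000L))
}

# equal-length genes tiling the genome end to end (no intergenic space)
tiling_catalog <- function(G = 10, L = 100) {
  start <- seq(1L, by = L, length.out = G)
  gene_catalog(data.frame(gene_id = sprintf("g%03d", seq_len(G)),
                          contig = "chr1", start = start,
                          end = start + L - 1L, strand = "+"),
               c(chr1 = as.integer(G * L)))
}

toy_mutations <- function(pop, pos, alt = "T", freq = 0.5, contig = "chr1",
                          catalog = NULL) {
  n <- max(length(pop), length(pos), length(alt), length(freq))
  tab <- mutation_table(data.frame(
    population_id = rep_len(pop, n), contig = rep_len(contig, n),
    position = rep_len(pos, n), ref_allele = "A",
    alt_allele = rep_len(alt, n), frequency = rep_len(freq, n),
    mutation_class = "substitution",
    gene_ids = I(replicate(n, character(0), simplify = FALSE))))
  if (!is.null(catalog)) tab <- assign_genes(tab, catalog)
  tab
}

toy_expression <- function(counts, taxa, relabund = NULL) {
  ns <- ncol(counts)
  meta <- data.frame(sample_id = colnames(counts),
                     predation = rep(c(FALSE, TRUE), length.out = ns),
                     coevolved_prey = rep(c(FALSE, FALSE, TRUE, TRUE), length.out = ns),
                     day = 4L, replicate = seq_len(ns))
  if (is.null(relabund)) {
    ut <- sort(unique(taxa))
    relabund <- matrix(1 / length(ut), length(ut), ns,
                       dimnames = list(ut, colnames(counts)))
  }
  expression_matrix(counts, stats::setNames(taxa, rownames(counts)), meta, relabund)
}

# planted up/down interaction effects spread over the first genes of each taxon
planted_effects <- function(n_taxa, per_taxon, lfc = 3) {
  up <- sprintf("t%02d_g%04d", rep(seq_len(n_taxa), each = per_taxon),
                rep(seq_len(per_taxon), n_taxa))
  dn <- sprintf("t%02d_g%04d", rep(seq_len(n_taxa), each = per_taxon),
                rep(per_taxon + seq_len(per_taxon), n_taxa))
  rbind(data.frame(gene = up, coef = "interaction", lfc = lfc),
        data.frame(gene = dn, coef = "interaction", lfc = -lfc))
}
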