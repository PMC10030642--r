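#' Specification for simulated mutation data
#'
#' Describes a single-contig genome and the per-population mutation process
#' used to validate the parallelism statistics. Mutations land uniformly per
#' base pair under the null; sites inside `target_genes` are up-weighted by
#' the enrichment multiplier `theta`, so `theta = 1` recovers the uniform
#' null exactly.
#'
#' @param n_populations number of replicate evolved populations R.
#' @param genome_length genome size in bp (single contig).
#' @param n_genes number of genes G.
#' @param gene_length_mean,gene_length_shape mean (bp) and gamma shape of the
#'   gene length distribution; `shape = Inf` gives equal lengths.
#' @param n_per_pop mutations drawn per population (recycled to length R).
#' @param target_genes gene ids receiving enrichment (may be integer indices).
#' @param theta per-bp rate multiplier >= 1 inside target genes.
#' @param freq_range range of the uniform allele frequency distribution; the
#'   default (0.05, 1) straddles the 20% detection filter so that filtering
#'   is exercised.
#' @param seed integer seed; all draws flow from one seeded stream per call.
#' @return object of class `mutation_sim_spec`.
#' @export
mutation_sim_spec <- function(n_populations = 3, genome_length = 1e6,
                              n_genes = 1000, gene_length_mean = 900,
                              gene_length_shape = 10, n_per_pop = 50,
                              target_genes = character(0), theta = 1,
                              freq_range = c(0.05, 1), seed = 1) {
  stopifnot(n_populations >= 1, genome_length >= 1, n_genes >= 1,
            theta >= 1, length(freq_range) == 2,
            freq_range[1] > 0, freq_range[2] <= 1, freq_range[1] <= freq_range[2])
  structure(list(n_populations = as.integer(n_populations),
                 genome_length = as.numeric(genome_length),
                 n_genes = as.integer(n_genes),
                 gene_length_mean = gene_length_mean,
                 gene_length_shape = gene_length_shape,
                 n_per_pop = rep_len(as.integer(n_per_pop), n_populations),
                 target_genes = target_genes, theta = theta,
                 freq_range = freq_range, seed = as.integer(seed)),
            class = "mutation_sim_spec")
}

#' Simulate a single-contig gene catalog
#'
#' Gene lengths are gamma-distributed with the stated mean and shape
#' (rounded, floored at 30 bp). Genes are placed left to right, separated by
#' random intergenic gaps obtained by spreading the residual genome length
#' uniformly over the G+1 gaps. Deterministic under the spec seed.
#'
#' @param spec a [mutation_sim_spec()].
#' @return a [gene_catalog()].
#' @export
simulate_genome <- function(spec) {
  with_seed(spec$seed, {
    G <- spec$n_genes
    len <- if (is.infinite(spec$gene_length_shape)) {
      rep(round(spec$gene_length_mean), G)
    } else {
      pmax(30L, as.integer(round(stats::rgamma(G, shape = spec$gene_length_shape,
                                               rate = spec$gene_length_shape /
                                                 spec$gene_length_mean))))
    }
    slack <- spec$genome_length - sum(as.numeric(len))
    if (slack < 0) stop("total gene length exceeds genome_length")
    gaps <- if (slack == 0) rep(0L, G + 1L) else {
      stats::rmultinom(1, slack, prob = rep(1, G + 1L))[, 1]
    }
    ## left-to-right placement: gap_i precedes gene_i
    start <- integer(G)
    pos <- 0L
    for (i in seq_len(G)) {
      pos <- pos + gaps[i]
      start[i] <- pos + 1L
      pos <- pos + len[i]
    }
    genes <- data.frame(gene_id = sprintf("g%04d", seq_len(G)),
                        contig = "chr1", start = start,
                        end = start + len - 1L,
                        strand = rep(c("+", "-"), length.out = G),
                        stringsAsFactors = FALSE)
    gene_catalog(genes, c(chr1 = as.integer(spec$genome_length)),
                 genome_id = "synthetic")
  })
}

#' Simulate per-population mutations over a gene catalog
#'
#' Each population draws its stated number of mutation events; a site is
#' chosen with probability proportional to 1 per bp, multiplied by `theta`
#' inside target genes. Repeated hits at the same site within a population
#' collapse to one record. Frequencies are uniform on `freq_range`; the
#' mutation class is substitution/deletion/insertion with probabilities
#' 0.8/0.1/0.1 and alleles are arbitrary nucleotide strings of the matching
#' shape.
#'
#' @param catalog a [gene_catalog()] (single contig).
#' @param spec a [mutation_sim_spec()].
#' @return a [mutation_table()] with gene assignments.
#' @export
simulate_mutations <- function(catalog, spec) {
  stopifnot(length(catalog$contig_lengths) == 1L)
  contig <- names(catalog$contig_lengths)
  L <- as.numeric(catalog$contig_lengths[[1]])
  tg <- spec$target_genes
  if (is.numeric(tg)) tg <- catalog$genes$gene_id[tg]
  if (length(setdiff(tg, catalog$genes$gene_id))) {
    stop("target_genes not in catalog")
  }
  ## weighted segments: target genes at theta per bp, the rest of the genome
  ## (intergenic + non-target genes) at 1 per bp
  g <- catalog$genes[catalog$genes$gene_id %in% tg, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  bg <- setdiff_intervals(L, g$start, g$end)
  seg <- rbind(if (nrow(g)) data.frame(start = g$start, end = g$end, w = spec$theta),
               data.frame(start = bg$start, end = bg$end, w = 1))
  seg <- seg[seg$end >= seg$start, , drop = FALSE]
  seg$len <- seg$end - seg$start + 1
  seg$weight <- seg$len * seg$w
  with_seed(spec$seed, {
    recs <- lapply(seq_len(spec$n_populations), function(r) {
      n <- spec$n_per_pop[r]
      if (n == 0L) return(NULL)
      idx <- sample.int(nrow(seg), n, replace = TRUE, prob = seg$weight)
      pos <- seg$start[idx] + floor(stats::runif(n) * seg$len[idx])
      pos <- unique(as.integer(pos))
      n <- length(pos)
      cls <- sample(c("substitution", "deletion", "insertion"), n,
                    replace = TRUE, prob = c(0.8, 0.1, 0.1))
      nt <- c("A", "C", "G", "T")
      ref <- sample(nt, n, replace = TRUE)
      alt <- vapply(seq_len(n), function(i) {
        switch(cls[i],
               substitution = sample(setdiff(nt, ref[i]), 1),
               deletion = { ref[i] <<- paste0(ref[i], sample(nt, 1)); substr(ref[i], 1, 1) },
               insertion = paste0(ref[i], sample(nt, 1)))
      }, "")
      data.frame(population_id = sprintf("pop%d", r), contig = contig,
                 position = pos, ref_allele = ref, alt_allele = alt,
                 frequency = stats::runif(n, spec$freq_range[1], spec$freq_range[2]),
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    if (is.null(recs)) {
      recs <- data.frame(population_id = character(), contig = character(),
                         position = integer(), ref_allele = character(),
                         alt_allele = character(), frequency = numeric(),
                         stringsAsFactors = FALSE)
    }
    recs$mutation_class <- classify_mutation(recs$ref_allele, recs$alt_allele)
    recs$gene_ids <- replicate(nrow(recs), character(0), simplify = FALSE)
    assign_genes(mutation_table(recs), catalog)
  })
}

## Complement of a set of sorted disjoint [start, end] intervals in [1, L].
setdiff_intervals <- function(L, starts, ends) {
  if (length(starts) == 0L) return(data.frame(start = 1, end = L))
  s <- c(1, ends + 1)
  e <- c(starts - 1, L)
  keep <- e >= s
  data.frame(start = s[keep], end = e[keep])
}

#' Specification for simulated community transcriptomes
#'
#' Describes a multi-taxon negative binomial count model with the structure
#' the species-resolved analysis assumes: the expected count of gene g in
#' sample s is `libsize_s * A[taxon(g), s] * q_g * 2^(design effects)`,
#' where `A` is the compositional taxon abundance, `q_g` the within-taxon
#' relative expression and the design effects are log2 fold changes tied to
#' the predation, coevolved-prey or interaction coefficient of the 2x2
#' factorial. The amplicon relative abundance table is `A` observed with
#' Dirichlet noise, so the abundance covariate can be studied with and
#' without measurement error.
#'
#' @param n_taxa number of taxa S.
#' @param genes_per_taxon genes per taxon (recycled).
#' @param n_replicates replicates per design cell (per day).
#' @param days integer vector of sampling days.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of raw
#'   within-taxon expression weights (normalized to sum 1 per taxon).
#' @param dispersion_shape,dispersion_mean gamma model of the per-gene NB
#'   dispersion phi_g (variance = mu + phi mu^2).
#' @param libsize_mean,libsize_cv library size distribution (log-normal).
#' @param abundance_shifts data.frame(taxon, coef, fold) of taxon abundance
#'   multipliers applied where the design coefficient is active
#'   (`coef` in predation/coevolved_prey/interaction); the confounder the
#'   within-taxon normalization must cancel.
#' @param effects data.frame(gene, coef, lfc) of true expression effects in
#'   log2 units (gene ids or "taxonIndex:geneIndex" labels, see details).
#' @param dirichlet_conc Dirichlet concentration of amplicon noise; large
#'   values mean little measurement error.
#' @param seed integer seed.
#' @return object of class `community_sim_spec`.
#' @export
community_sim_spec <- function(n_taxa = 4, genes_per_taxon = 150,
                               n_replicates = 3, days = c(4L, 45L),
                               baseline_meanlog = 5, baseline_sdlog = 1,
                               dispersion_shape = 4, dispersion_mean = 0.05,
                               libsize_mean = 3e5, libsize_cv = 0.15,
                               abundance_shifts = NULL, effects = NULL,
                               dirichlet_conc = 5000, seed = 1) {
  stopifnot(n_taxa >= 1, n_replicates >= 1, dirichlet_conc > 0)
  structure(list(n_taxa = as.integer(n_taxa),
                 genes_per_taxon = rep_len(as.integer(genes_per_taxon), n_taxa),
                 n_replicates = as.integer(n_replicates), days = as.integer(days),
                 baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
                 dispersion_shape = dispersion_shape, dispersion_mean = dispersion_mean,
                 libsize_mean = libsize_mean, libsize_cv = libsize_cv,
                 abundance_shifts = abundance_shifts, effects = effects,
                 dirichlet_conc = dirichlet_conc, seed = as.integer(seed)),
            class = "community_sim_spec")
}

#' Simulate a community expression matrix
#'
#' @param spec a [community_sim_spec()].
#' @return an [expression_matrix()] with attributes `truth` (list with the
#'   per-gene dispersions, expected means, effect table and abundance matrix)
#'   for use in recovery tests.
#' @export
simulate_community <- function(spec) {
  with_seed(spec$seed, {
    S <- spec$n_taxa
    taxa <- sprintf("t%02d", seq_len(S))
    genes <- unlist(lapply(seq_len(S), function(t) {
      sprintf("%s_g%04d", taxa[t], seq_len(spec$genes_per_taxon[t]))
    }))
    gene_taxon <- stats::setNames(rep(taxa, spec$genes_per_taxon), genes)
    design <- expand.grid(replicate = seq_len(spec$n_replicates),
                          coevolved_prey = c(FALSE, TRUE),
                          predation = c(FALSE, TRUE),
                          day = spec$days, KEEP.OUT.ATTRS = FALSE)
    design$sample_id <- sprintf("s%02d_P%d_C%d_r%d_d%d", seq_len(nrow(design)),
                                design$predation, design$coevolved_prey,
                                design$replicate, design$day)
    ns <- nrow(design)
    ## compositional taxon abundance per sample
    A <- matrix(1, S, ns, dimnames = list(taxa, design$sample_id))
    if (!is.null(spec$abundance_shifts)) {
      for (i in seq_len(nrow(spec$abundance_shifts))) {
        sh <- spec$abundance_shifts[i, ]
        on <- coef_indicator(as.character(sh$coef), design)
        A[as.character(sh$taxon), on] <- A[as.character(sh$taxon), on] * sh$fold
      }
    }
    A <- sweep(A, 2, colSums(A), "/")
    ## within-taxon relative expression
    q <- stats::rlnorm(length(genes), spec$baseline_meanlog, spec$baseline_sdlog)
    names(q) <- genes
    q <- q / stats::ave(q, gene_taxon[genes], FUN = sum)
    phi <- stats::rgamma(length(genes), shape = spec$dispersion_shape,
                         rate = spec$dispersion_shape / spec$dispersion_mean)
    names(phi) <- genes
    lib <- stats::rlnorm(ns, log(spec$libsize_mean) - 0.5 * log(1 + spec$libsize_cv^2),
                         sqrt(log(1 + spec$libsize_cv^2)))
    ## log2 effect matrix genes x samples
    eff <- matrix(0, length(genes), ns, dimnames = list(genes, design$sample_id))
    if (!is.null(spec$effects)) {
      for (i in seq_len(nrow(spec$effects))) {
        e <- spec$effects[i, ]
        on <- coef_indicator(as.character(e$coef), design)
        eff[as.character(e$gene), on] <- eff[as.character(e$gene), on] + e$lfc
      }
    }
    mu <- sweep(2^eff * q, 2, lib, "*") * A[gene_taxon[genes], , drop = FALSE]
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / pmax(phi, 1e-8)),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    ## amplicon observation of A with Dirichlet noise
    rel <- vapply(seq_len(ns), function(s) {
      g <- stats::rgamma(S, shape = A[, s] * spec$dirichlet_conc, rate = 1)
      g / sum(g)
    }, numeric(S))
    rel <- matrix(rel, nrow = S, dimnames = dimnames(A))
    em <- expression_matrix(counts, gene_taxon,
                            design[, c("sample_id", "predation", "coevolved_prey",
                                       "day", "replicate")], rel)
    attr(em, "truth") <- list(A = A, q = q, phi = phi, libsize = lib,
                              effects = spec$effects, mu = mu)
    em
  })
}

## Indicator of the samples where a design coefficient is active.
coef_indicator <- function(coef, design) {
  switch(coef,
         predation = design$predation,
         coevolved_prey = design$coevolved_prey,
         interaction = design$predation & design$coevolved_prey,
         stop("unknown design coefficient: ", coef))
}

#' Simulate a gene-to-pathway map
#'
#' Assigns genes to `n_pathways` pathways of random size; a fraction of
#' genes stays unannotated, as is typical of KEGG-style annotations.
#'
#' @param genes gene universe.
#' @param n_pathways number of pathways.
#' @param mean_size mean pathway size.
#' @param seed integer seed.
#' @return a [pathway_map()].
#' @export
simulate_pathways <- function(genes, n_pathways = 20, mean_size = 15, seed = 1) {
  with_seed(seed, {
    sets <- lapply(seq_len(n_pathways), function(i) {
      k <- max(2L, stats::rpois(1, mean_size))
      sample(genes, min(k, length(genes)))
    })
    names(sets) <- sprintf("map%05d", seq_len(n_pathways))
    pathway_map(sets, universe = genes)
  })
}
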