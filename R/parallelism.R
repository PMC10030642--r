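#' Filter variants before parallelism analysis
#'
#' Two explicit filters, applied in order: (i) sites fixed in the ancestor
#' (frequency >= `ancestor_fixed`) are removed from every population, so
#' pre-existing fixed differences from the reference never count as evolved
#' changes; (ii) records below the detection frequency `min_freq` are
#' dropped. Removal counts are reported via `message()`.
#'
#' @param table a [mutation_table()] of evolved populations.
#' @param ancestor a [mutation_table()] for the ancestor clone (may be empty).
#' @param min_freq minimum retained allele frequency (default 0.2: variants
#'   at or above 20% are kept).
#' @param ancestor_fixed frequency at which an ancestor variant counts as
#'   fixed (default 0.95).
#' @return the filtered [mutation_table()].
#' @export
filter_variants <- function(table, ancestor = NULL, min_freq = 0.2,
                            ancestor_fixed = 0.95) {
  if (!is.numeric(min_freq) || min_freq < 0 || min_freq > 1) {
    stop("min_freq must lie in [0, 1]")
  }
  n0 <- nrow(table)
  if (!is.null(ancestor) && nrow(ancestor)) {
    fixed <- ancestor[ancestor$frequency >= ancestor_fixed, , drop = FALSE]
    key <- paste(table$contig, table$position, table$alt_allele, sep = "\r")
    fkey <- paste(fixed$contig, fixed$position, fixed$alt_allele, sep = "\r")
    table <- table[!key %in% fkey, , drop = FALSE]
  }
  n_anc <- n0 - nrow(table)
  table <- table[table$frequency >= min_freq, , drop = FALSE]
  message(sprintf("filter_variants: removed %d ancestor-fixed and %d low-frequency of %d records",
                  n_anc, n0 - n_anc - nrow(table), n0))
  class(table) <- c("mutation_table", "data.frame")
  table
}

#' Nucleotide-level parallelism
#'
#' Nucleotide multiplicity is the number of replicate populations carrying a
#' mutation at the same site. By default "the same" requires a matching
#' alternative allele (an identical mutation); `match_alt = FALSE` relaxes
#' this to position only. `N_k` counts sites with multiplicity >= k.
#'
#' @param table a filtered [mutation_table()].
#' @param R number of replicate populations.
#' @param match_alt require identical alt alleles (default TRUE).
#' @return object of class `site_parallelism`: data.frame `sites` (contig,
#'   position, alt_allele, multiplicity) and vector `N_k` for k = 1..R.
#' @export
identical_site_parallelism <- function(table, R, match_alt = TRUE) {
  npop <- length(unique(table$population_id))
  if (R < npop) stop("R smaller than the number of observed populations")
  if (nrow(table) == 0L) {
    return(structure(list(sites = data.frame(contig = character(),
                                             position = integer(),
                                             alt_allele = character(),
                                             multiplicity = integer()),
                          N_k = stats::setNames(rep(0L, R), paste0("N", seq_len(R))),
                          R = R), class = "site_parallelism"))
  }
  key <- if (match_alt) {
    paste(table$contig, table$position, table$alt_allele, sep = "\r")
  } else {
    paste(table$contig, table$position, sep = "\r")
  }
  ## a population contributes at most once per site
  u <- !duplicated(paste(table$population_id, key, sep = "\r"))
  mult <- table(key[u])
  ord <- !duplicated(key)
  sites <- data.frame(contig = table$contig[ord], position = table$position[ord],
                      alt_allele = if (match_alt) table$alt_allele[ord] else NA_character_,
                      multiplicity = as.integer(mult[key[ord]]),
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$contig, sites$position, sites$alt_allele), , drop = FALSE]
  rownames(sites) <- NULL
  N_k <- vapply(seq_len(R), function(k) sum(sites$multiplicity >= k), integer(1))
  structure(list(sites = sites, N_k = stats::setNames(N_k, paste0("N", seq_len(R))),
                 R = R), class = "site_parallelism")
}

#' Null model for nucleotide multiplicity
#'
#' Under uniform placement of `n_r` mutations per population over a genome
#' of `L` sites, a site is hit by population r with probability
#' `1 - (1 - 1/L)^{n_r}`. The expected number of sites with multiplicity
#' >= k follows in closed form from the Poisson-binomial distribution over
#' populations; a Monte-Carlo simulation of the same process yields a
#' p-value for an observed `N_k`.
#'
#' @param genome_length L in bp.
#' @param n_per_pop integer vector of per-population mutation counts.
#' @param k multiplicity threshold.
#' @param observed_Nk observed number of sites with multiplicity >= k
#'   (optional; required for the p-value).
#' @param B Monte-Carlo replicates (>= 1000 recommended; 0 skips simulation).
#' @param seed integer seed for the simulation.
#' @return list with `expected_Nk` (closed form), and when simulated:
#'   `mc_expected_Nk`, `mc_se`, and `p_value` with the +1 correction.
#' @export
nucleotide_null <- function(genome_length, n_per_pop, k, observed_Nk = NULL,
                            B = 10000, seed = 1) {
  R <- length(n_per_pop)
  if (k > R) stop("k exceeds the number of populations")
  L <- as.numeric(genome_length)
  p_r <- 1 - (1 - 1 / L)^n_per_pop
  ## Poisson-binomial tail P(multiplicity >= k) by polynomial convolution
  pmf <- 1
  for (p in p_r) pmf <- convolve_bernoulli(pmf, p)
  p_ge_k <- sum(pmf[(k + 1):(R + 1)])
  out <- list(expected_Nk = L * p_ge_k, k = k)
  if (B > 0) {
    sims <- with_seed(seed, {
      ## one (replicate, site) key per population-unique hit, all B at once
      keys <- unlist(lapply(seq_len(R), function(r) {
        n <- n_per_pop[r]
        site <- sample.int(L, B * n, replace = TRUE)
        b <- rep(seq_len(B), each = n)
        unique((b - 1) * L + site)
      }))
      uk <- unique(keys)
      mult <- tabulate(match(keys, uk))
      hit <- uk[mult >= k]
      tabulate(floor((hit - 1) / L) + 1, nbins = B)
    })
    out$mc_expected_Nk <- mean(sims)
    out$mc_se <- stats::sd(sims) / sqrt(B)
    if (!is.null(observed_Nk)) {
      out$p_value <- (1 + sum(sims >= observed_Nk)) / (B + 1)
    }
    out$sims <- sims
  }
  out
}

## pmf of a sum of independent Bernoullis, extended by one trial.
convolve_bernoulli <- function(pmf, p) {
  c(pmf * (1 - p), 0) + c(0, pmf * p)
}

#' Gene multiplicity table
#'
#' Gene multiplicity rescales the mutation count of gene i across all
#' replicates by the ratio of the mean gene length to the gene's length:
#' `m_i = n_i * (Lbar / L_i)`, so that all genes share the null expectation
#' `mbar = n_tot / G` under uniform length-proportional mutation over genic
#' space. The log-likelihood excess of the observed configuration over that
#' null is `Delta_l = sum_i n_i log(m_i / mbar)`, which equals
#' `n_tot * KL(phat || p0)` when each variant hits one gene (a variant
#' overlapping several genes increments each gene's `n_i`, while `n_tot`
#' counts unique variants; intergenic variants are excluded).
#'
#' @param table a filtered [mutation_table()] with gene assignments.
#' @param catalog a [gene_catalog()].
#' @return object of class `gene_multiplicity_table`: data.frame `genes`
#'   (gene_id, length, n_i, m_i, delta_l) plus globals `n_tot`, `G`,
#'   `mean_length`, `m_bar`, `delta_l_total`.
#' @export
gene_multiplicity <- function(table, catalog) {
  G <- nrow(catalog$genes)
  if (G == 0L) stop("empty gene catalog")
  hits <- unlist(table$gene_ids)
  n_i <- stats::setNames(rep(0L, G), catalog$genes$gene_id)
  if (length(hits)) {
    tb <- table(hits)
    n_i[names(tb)] <- as.integer(tb)
  }
  genic <- lengths(table$gene_ids) > 0
  n_tot <- sum(genic)
  Lbar <- mean(catalog$genes$length)
  m_i <- n_i * (Lbar / catalog$genes$length)
  m_bar <- n_tot / G
  dl <- ifelse(n_i > 0, n_i * log(m_i / m_bar), 0)
  genes <- data.frame(gene_id = catalog$genes$gene_id,
                      length = catalog$genes$length,
                      n_i = as.integer(n_i), m_i = m_i, delta_l = dl,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, n_tot = n_tot, G = G, mean_length = Lbar,
                 m_bar = m_bar, delta_l_total = sum(dl),
                 total_genic_length = sum(as.numeric(catalog$genes$length))),
            class = "gene_multiplicity_table")
}

#' @export
print.gene_multiplicity_table <- function(x, ...) {
  cat(sprintf("gene_multiplicity_table: G=%d genes, n_tot=%d genic mutations, delta_l=%.3f\n",
              x$G, x$n_tot, x$delta_l_total))
  invisible(x)
}

#' Per-gene enrichment p-values
#'
#' Tests each gene's mutation count against the uniform length-proportional
#' null over genic space. `method = "poisson"` uses the analytic survival
#' function `P(N >= n_i)` with `N ~ Poisson(n_tot * L_i / sum(L))` (no
#' mid-p); `method = "montecarlo"` re-places `n_tot` mutations over genes
#' with length weights B times and applies the +1-corrected empirical tail.
#'
#' @param gm a [gene_multiplicity()] result.
#' @param method `"poisson"` or `"montecarlo"`.
#' @param B Monte-Carlo replicates.
#' @param seed integer seed.
#' @return `gm` with a `p` column added to `gm$genes`.
#' @export
gene_pvalues <- function(gm, method = c("poisson", "montecarlo"), B = 10000,
                         seed = 1) {
  method <- match.arg(method)
  lam <- gm$n_tot * gm$genes$length / gm$total_genic_length
  gm$genes$p <- if (method == "poisson") {
    stats::ppois(gm$genes$n_i - 1L, lam, lower.tail = FALSE)
  } else {
    cnt <- with_seed(seed, stats::rmultinom(B, gm$n_tot,
                                            prob = gm$genes$length))
    (1 + rowSums(cnt >= gm$genes$n_i)) / (B + 1)
  }
  gm$p_method <- method
  gm
}

#' Null ensemble of per-gene p-value vectors
#'
#' Simulates `B` datasets of `n_tot` mutations placed uniformly (length
#' weighted) over the catalog genes and computes each dataset's full p-value
#' vector with the same method as the observed analysis. Feeds
#' [fdr_critical_p()].
#'
#' @param gm a [gene_multiplicity()] result (supplies lengths and n_tot).
#' @param B number of null datasets.
#' @param method p-value method, as in [gene_pvalues()].
#' @param seed integer seed.
#' @return matrix G x B of null p-values.
#' @export
parallelism_null_pvalues <- function(gm, B = 1000, method = "poisson", seed = 1) {
  lam <- gm$n_tot * gm$genes$length / gm$total_genic_length
  with_seed(seed, {
    cnt <- stats::rmultinom(B, gm$n_tot, prob = gm$genes$length)
    stats::ppois(cnt - 1L, lam, lower.tail = FALSE)
  })
}

#' Critical p-value controlling the empirical-null FDR
#'
#' Scans the unique observed p-values in increasing order; at each candidate
#' threshold t the estimated FDR is the mean number of null p-values <= t
#' per simulated dataset divided by the observed discovery count. The
#' critical value p* is the largest t with estimated FDR below `fdr`; when
#' no threshold qualifies, p* = 0 and nothing is flagged.
#'
#' @param p_obs observed p-values.
#' @param null_p matrix of null p-values (genes x simulations), e.g. from
#'   [parallelism_null_pvalues()].
#' @param fdr target false discovery rate, in (0, 1).
#' @return list with `p_star`, logical `significant`, and the scan table
#'   `thresholds` (t, expected null discoveries, observed discoveries, FDR).
#' @export
fdr_critical_p <- function(p_obs, null_p, fdr = 0.05) {
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  ts <- sort(unique(p_obs))
  B <- ncol(null_p)
  scan <- vapply(ts, function(t) {
    e_null <- sum(null_p <= t) / B
    n_obs <- sum(p_obs <= t)
    c(e_null, n_obs, e_null / max(1, n_obs))
  }, numeric(3))
  ok <- scan[3, ] < fdr
  p_star <- if (any(ok)) max(ts[ok]) else 0
  list(p_star = p_star,
       significant = p_obs <= p_star & p_star > 0,
       thresholds = data.frame(t = ts, expected_null = scan[1, ],
                               observed = scan[2, ], fdr_hat = scan[3, ]))
}

#' Detect genes under parallel evolution
#'
#' Convenience wrapper: gene multiplicity, per-gene p-values, a seeded null
#' ensemble, and the critical-p FDR procedure.
#'
#' @param table filtered [mutation_table()].
#' @param catalog a [gene_catalog()].
#' @param fdr target FDR (default 0.05).
#' @param method p-value method ([gene_pvalues()]).
#' @param B null ensemble size.
#' @param seed integer seed.
#' @return a [gene_multiplicity()] result with `p` and `significant` columns
#'   and attributes `p_star` and `fdr`.
#' @export
detect_parallel_genes <- function(table, catalog, fdr = 0.05,
                                  method = "poisson", B = 1000, seed = 1) {
  gm <- gene_multiplicity(table, catalog)
  gm <- gene_pvalues(gm, method = method, B = B, seed = seed)
  nullp <- parallelism_null_pvalues(gm, B = B, method = method,
                                    seed = derive_seed(seed, "null-ensemble"))
  crit <- fdr_critical_p(gm$genes$p, nullp, fdr = fdr)
  gm$genes$significant <- crit$significant
  gm$p_star <- crit$p_star
  gm$fdr <- fdr
  gm
}
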