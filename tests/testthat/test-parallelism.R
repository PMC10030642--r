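test_that("variant filters apply the frequency and ancestor-fixed rules", {
  cat1 <- toy_catalog()
  tab <- toy_mutations(c("p1", "p1", "p2", "p3"), c(12L, 19L, 12L, 12L),
                       freq = c(0.19, 0.5, 0.8, 0.95), catalog = cat1)
  out <- suppressMessages(filter_variants(tab, min_freq = 0.2))
  expect_equal(nrow(out), 3L) # the 0.19 record is below the 20% rule
  expect_false(any(out$frequency < 0.2))

  # a site fixed in the ancestor disappears from every population
  anc <- toy_mutations("anc", 12L, freq = 0.99)
  out2 <- suppressMessages(filter_variants(tab, anc, min_freq = 0))
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$position, 19L)
  # an ancestor variant below the fixed threshold removes nothing
  anc_low <- toy_mutations("anc", 12L, freq = 0.5)
  expect_equal(nrow(suppressMessages(filter_variants(tab, anc_low, min_freq = 0))), 4L)

  # identity under no-op settings
  out3 <- suppressMessages(filter_variants(tab, min_freq = 0))
  expect_equal(as.data.frame(out3), as.data.frame(tab))
  expect_error(filter_variants(tab, min_freq = 1.2), "min_freq")
})

test_that("nucleotide multiplicity groups sites by alt allele", {
  tab <- rbind(toy_mutations(c("p1", "p2", "p3"), 100L, alt = "T"),
               toy_mutations(c("p1", "p2"), 200L, alt = c("G", "C")),
               toy_mutations("p3", 300L, alt = "T"))
  class(tab) <- c("mutation_table", "data.frame")
  sp <- identical_site_parallelism(tab, R = 3)
  # brute-force oracle: count populations per (position, alt)
  key <- paste(tab$position, tab$alt_allele)
  oracle <- tapply(tab$population_id, key, function(p) length(unique(p)))
  expect_equal(sort(sp$sites$multiplicity), sort(as.integer(oracle)),
               ignore_attr = TRUE)
  expect_equal(unname(sp$N_k), c(4L, 1L, 1L)) # 4 sites, one shared by all three
  # position-only mode merges the two alts at 200
  sp2 <- identical_site_parallelism(tab, R = 3, match_alt = FALSE)
  expect_equal(unname(sp2$N_k), c(3L, 2L, 1L))
  # degenerate inputs
  expect_equal(unname(identical_site_parallelism(tab[0, ], R = 3)$N_k), rep(0L, 3))
  expect_error(identical_site_parallelism(tab, R = 2), "smaller")
})

test_that("nucleotide null expectation matches union bound and Monte Carlo", {
  # k = 1: E[N_1] ~ sum n_r when L >> n
  nn1 <- nucleotide_null(1e7, c(10, 10, 10), k = 1, B = 0)
  expect_equal(nn1$expected_Nk, 30, tolerance = 1e-4)
  # closed form vs simulation at L = 1000, n = (10, 10, 10), k = 2
  nn2 <- nucleotide_null(1000, c(10, 10, 10), k = 2, observed_Nk = 0,
                         B = 20000, seed = 42)
  expect_equal(nn2$expected_Nk, 0.2953, tolerance = 1e-3)
  expect_lt(abs(nn2$mc_expected_Nk - nn2$expected_Nk), 3 * nn2$mc_se)
  # N_2 = 0 observed is the least extreme outcome: p = 1
  expect_equal(nn2$p_value, 1)
  expect_error(nucleotide_null(1000, c(10, 10), k = 3), "exceeds")
})

test_that("gene multiplicity follows the length-ratio definition", {
  # two genes, lengths 100 and 200 (mean 150)
  cat1 <- gene_catalog(data.frame(gene_id = c("gA", "gB"), contig = "c",
                                  start = c(1L, 101L), end = c(100L, 300L),
                                  strand = "+"), c(c = 300L))
  tab <- toy_mutations("p1", c(10L, 20L, 30L, 40L, 150L, 160L, 170L),
                       contig = "c", catalog = cat1)
  gm <- gene_multiplicity(tab, cat1)
  expect_equal(gm$n_tot, 7)
  expect_equal(gm$m_bar, 3.5)
  # n_A = 4, L_A = 100, Lbar = 150 -> m_A = 6; n_B = 3, L_B = 200 -> m_B = 2.25
  expect_equal(gm$genes$m_i, c(4 * 1.5, 3 * 0.75))
  expect_equal(gm$delta_l_total,
               4 * log(6 / 3.5) + 3 * log(2.25 / 3.5))
  expect_error(gene_multiplicity(tab, gene_catalog(
    data.frame(gene_id = character(), contig = character(), start = integer(),
               end = integer(), strand = character()), c(c = 300L))), "empty")
})

test_that("a gene with mean length and the uniform spread give the stated multiplicities", {
  cat1 <- tiling_catalog(G = 4, L = 100)
  # gene of length Lbar with 4 mutations: m_i = 4
  tab <- toy_mutations("p1", c(5L, 25L, 45L, 65L), catalog = cat1)
  gm <- gene_multiplicity(tab, cat1)
  expect_equal(gm$genes$m_i[1], 4)
  # perfectly even spread over equal-length genes: delta_l = 0
  tab2 <- toy_mutations("p1", c(50L, 150L, 250L, 350L), catalog = cat1)
  gm2 <- gene_multiplicity(tab2, cat1)
  expect_equal(gm2$delta_l_total, 0)
  expect_equal(gm2$genes$m_i, rep(1, 4))
})

test_that("the likelihood excess equals n_tot times the KL divergence and is nonnegative", {
  cat1 <- tiling_catalog(G = 20, L = 50)
  for (s in 1:25) {
    spec <- mutation_sim_spec(n_populations = 3, genome_length = 1000,
                              n_genes = 20, n_per_pop = 30,
                              theta = sample(c(1, 5, 20), 1), target_genes = "g001",
                              seed = 700 + s)
    gm <- gene_multiplicity(simulate_mutations(cat1, spec), cat1)
    expect_gte(gm$delta_l_total, 0)
    p_hat <- gm$genes$n_i / gm$n_tot
    p_null <- gm$genes$length / sum(gm$genes$length)
    kl <- sum(ifelse(p_hat > 0, p_hat * log(p_hat / p_null), 0))
    expect_equal(gm$delta_l_total, gm$n_tot * kl, tolerance = 1e-12)
  }
})

test_that("multi-gene overlaps increment every overlapping gene but n_tot counts unique variants", {
  cat1 <- toy_catalog() # gA and gB overlap on 18-20
  tab <- toy_mutations("p1", c(19L, 120L), catalog = cat1)
  gm <- gene_multiplicity(tab, cat1)
  expect_equal(gm$genes$n_i[gm$genes$gene_id %in% c("gA", "gB")], c(1L, 1L))
  expect_equal(gm$n_tot, 2)
})

test_that("Poisson tail p-values match the direct summation oracle and Monte Carlo", {
  cat1 <- tiling_catalog(G = 4, L = 100)
  tab <- toy_mutations("p1", c(5L, 6L, 105L), catalog = cat1)
  gm <- gene_pvalues(gene_multiplicity(tab, cat1), method = "poisson")
  # n_tot = 3 over 4 equal genes: lambda = 0.75 each
  lam <- 0.75
  oracle <- function(n) 1 - sum(exp(-lam) * lam^(0:(n - 1)) / factorial(0:(n - 1)))
  expect_equal(gm$genes$p, c(oracle(2), oracle(1), 1, 1), tolerance = 1e-12)
  # the lambda = 0.5, n = 2 textbook value
  expect_equal(stats::ppois(1, 0.5, lower.tail = FALSE), 0.09020401, tolerance = 1e-7)

  # Monte-Carlo agreement on a 50-gene instance
  cat2 <- tiling_catalog(G = 50, L = 100)
  spec <- mutation_sim_spec(n_populations = 3, genome_length = 5000, n_genes = 50,
                            n_per_pop = 40, seed = 77)
  gmc <- gene_multiplicity(simulate_mutations(cat2, spec), cat2)
  pp <- gene_pvalues(gmc, "poisson")$genes$p
  B <- 20000
  pm <- gene_pvalues(gmc, "montecarlo", B = B, seed = 5)$genes$p
  se <- sqrt(pp * (1 - pp) / B) + 1 / B
  expect_true(all(abs(pm - pp) < 3 * se + 3 / B))
  expect_error(gene_pvalues(gmc, "bogus"), "arg")
})

test_that("the critical-p scan controls the empirical-null FDR on toy cases", {
  # all observed p = 1: nothing can be called
  nullp <- matrix(runif(500), 50, 10)
  res <- fdr_critical_p(rep(1, 50), nullp, fdr = 0.05)
  expect_equal(res$p_star, 0)
  expect_false(any(res$significant))

  # two tiny p-values against a null whose minimum is ~0.02
  p_obs <- c(1e-6, 1e-6, 0.3, 0.6, 0.9)
  nullp2 <- withr::with_seed(8, matrix(runif(5 * 200, min = 0.02, max = 1), 5, 200))
  res2 <- fdr_critical_p(p_obs, nullp2, fdr = 0.05)
  expect_equal(sum(res2$significant), 2L)
  expect_true(all(which(res2$significant) == c(1, 2)))
  # brute-force oracle over all candidate thresholds
  for (t in sort(unique(p_obs))) {
    fdr_t <- mean(colSums(nullp2 <= t)) / max(1, sum(p_obs <= t))
    row <- res2$thresholds[res2$thresholds$t == t, ]
    expect_equal(row$fdr_hat, fdr_t)
  }

  # fdr close to 1 admits everything below p = 1
  res3 <- fdr_critical_p(c(0.2, 0.5, 1), matrix(runif(300), 3), fdr = 0.999)
  expect_equal(sum(res3$significant), 2L)
  expect_error(fdr_critical_p(p_obs, nullp2, fdr = 0), "fdr")
})

test_that("detect_parallel_genes flags enriched genes and spares the background", {
  cat1 <- tiling_catalog(G = 100, L = 1000)
  spec <- mutation_sim_spec(n_populations = 3, genome_length = 1e5,
                            n_genes = 100, n_per_pop = 60,
                            target_genes = sprintf("g%03d", 1:3), theta = 30,
                            seed = 9)
  mt <- simulate_mutations(cat1, spec)
  gm <- detect_parallel_genes(mt, cat1, fdr = 0.05, B = 500, seed = 10)
  sig <- gm$genes$gene_id[gm$genes$significant]
  expect_true(all(sprintf("g%03d", 1:3) %in% sig))
  expect_lte(length(setdiff(sig, sprintf("g%03d", 1:3))), 1)
})
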