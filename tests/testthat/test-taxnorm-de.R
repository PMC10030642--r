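test_that("within-taxon size factors have geometric mean one and scale as derived", {
  counts <- matrix(c(60L, 40L, 240L, 160L,   # tA totals 100, 400
                     10L, 10L, 10L, 10L), 4, 2, byrow = FALSE,
                   dimnames = list(c("a1", "a2", "b1", "b2"), c("s1", "s2")))
  counts <- matrix(c(60L, 240L, 40L, 160L, 10L, 10L, 10L, 10L), 4, 2,
                   byrow = TRUE, dimnames = list(c("a1", "a2", "b1", "b2"),
                                                 c("s1", "s2")))
  em <- toy_expression(counts, c("tA", "tA", "tB", "tB"))
  sf <- within_taxon_size_factors(em)
  expect_equal(unname(sf$sf["tA", ]), c(0.5, 2.0)) # totals 100, 400
  expect_equal(unname(sf$sf["tB", ]), c(1, 1))
  expect_equal(apply(sf$sf, 1, function(x) exp(mean(log(x)))),
               c(tA = 1, tB = 1), tolerance = 1e-9)

  # multiplying one taxon-sample by c moves only that factor; normalized
  # counts of that taxon-sample are unchanged (algebraic oracle)
  counts2 <- counts
  counts2[c("a1", "a2"), "s2"] <- counts2[c("a1", "a2"), "s2"] * 3L
  em2 <- toy_expression(counts2, c("tA", "tA", "tB", "tB"))
  sf2 <- within_taxon_size_factors(em2)
  # geometric-mean renormalization spreads a sqrt(3) over both samples
  expect_equal(sf2$sf["tA", "s2"] / sf$sf["tA", "s2"], 3 / sqrt(3))
  nc1 <- normalized_counts(em, sf)
  nc2 <- normalized_counts(em2, sf2)
  expect_equal(nc2["a1", "s2"] / nc1["a1", "s2"], sqrt(3), tolerance = 1e-9)

  # all-zero taxon errors; zero taxon-sample is excluded
  counts3 <- counts; counts3[c("b1", "b2"), ] <- 0L
  expect_error(within_taxon_size_factors(
    toy_expression(counts3, c("tA", "tA", "tB", "tB"))), "tB")
  counts4 <- counts; counts4[c("b1", "b2"), "s1"] <- 0L
  sf4 <- within_taxon_size_factors(toy_expression(counts4, c("tA", "tA", "tB", "tB")))
  expect_true(is.na(sf4$sf["tB", "s1"]))
  expect_equal(sf4$excluded, data.frame(taxon = "tB", sample = "s1"))
})

test_that("dispersion estimates recover the simulation truth and respect the Poisson floor", {
  em <- simulate_community(community_sim_spec(n_taxa = 2, genes_per_taxon = 400,
                                              days = 4L, dispersion_shape = 1e6,
                                              dispersion_mean = 0.1, seed = 14))
  sf <- within_taxon_size_factors(em)
  phi <- estimate_dispersions(em, sf)
  hi <- rowMeans(normalized_counts(em, sf)) > 100
  expect_gt(median(phi[hi]), 0.05)
  expect_lt(median(phi[hi]), 0.2)

  # constant gene: moment estimate exactly zero, final value on the trend
  counts <- matrix(50L, 6, 4, dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  counts[6, ] <- c(47L, 52L, 49L, 50L)
  em0 <- toy_expression(counts, rep("tA", 6))
  phi0 <- estimate_dispersions(em0, within_taxon_size_factors(em0),
                               pool_cells = FALSE)
  expect_equal(unname(attr(phi0, "phihat")[1]), 0)
  trend <- attr(phi0, "trend")
  expect_lte(phi0[[1]], trend(50) + 1e-12)
})

test_that("the NB GLM recovers planted effects and rejects bad designs", {
  eff <- planted_effects(2, 8, lfc = 3)
  em <- simulate_community(community_sim_spec(n_taxa = 2, genes_per_taxon = 250,
                                              days = 4L, seed = 15, effects = eff))
  de <- run_de(em)
  up <- eff$gene[eff$lfc > 0]; dn <- eff$gene[eff$lfc < 0]
  # sum scaling absorbs the planted genes' share of the taxon total, so a
  # modest downward bias of the recovered effect magnitude is expected
  expect_equal(median(de$table$lfc_mle[de$table$gene_id %in% up]), 3,
               tolerance = 0.17)
  expect_equal(median(de$table$lfc_mle[de$table$gene_id %in% dn]), -3,
               tolerance = 0.17)
  expect_gt(mean(de$table$de[de$table$gene_id %in% c(up, dn)]), 0.6)
  expect_lt(mean(de$table$de[!de$table$gene_id %in% c(up, dn)]), 0.01)
  # adjusted p never drops below raw p and is monotone in it
  tab <- de$table[de$table$converged, ]
  expect_true(all(tab$padj >= tab$pvalue - 1e-12))
  o <- order(tab$pvalue)
  expect_true(all(diff(tab$padj[o]) >= -1e-12))

  # unknown contrast and rank-deficient designs fail loudly
  expect_error(run_de(em, contrast = "nope"), "not a column")
  em_bad <- em
  em_bad$sample_meta$coevolved_prey <- em_bad$sample_meta$predation
  expect_error(fit_nb_de(em_bad, within_taxon_size_factors(em_bad),
                         estimate_dispersions(em_bad, within_taxon_size_factors(em_bad))),
               "rank deficient")
})

test_that("abundance confounding is cancelled by WTSS offsets plus the covariate", {
  cs <- community_sim_spec(n_taxa = 4, genes_per_taxon = 120, days = 4L, seed = 16,
    abundance_shifts = data.frame(taxon = "t01", coef = "predation", fold = 4))
  em <- simulate_community(cs)
  w <- run_de(em, contrast = "predationTRUE")
  nv <- run_de(em, normalization = "library", covariate = "none",
               contrast = "predationTRUE")
  t1g <- names(em$gene_taxon)[em$gene_taxon == "t01"]
  expect_equal(sum(w$table$padj[w$table$gene_id %in% t1g] < 0.1, na.rm = TRUE), 0L)
  expect_gt(sum(nv$table$padj[nv$table$gene_id %in% t1g] < 0.1, na.rm = TRUE), 0L)
  # the naive analysis sees roughly the compositional fold change
  expect_gt(median(nv$table$lfc_mle[nv$table$gene_id %in% t1g]), 0.8)
  expect_lt(abs(median(w$table$lfc_mle[w$table$gene_id %in% t1g])), 0.3)
})

test_that("LFC shrinkage preserves strong signals and collapses weak ones", {
  de <- structure(list(table = data.frame(
    gene_id = paste0("g", 1:6), taxon = "tA", baseMean = 100,
    lfc_mle = c(6, -6, 0, 0.4, 3, -0.2), se = c(0.2, 0.2, 0.3, 0.5, 0.4, 0.1),
    stat = 1, pvalue = 0.5, converged = TRUE, padj = 0.5)),
    class = "de_result")
  out <- shrink_lfc(de, prior_scale = 0.5)
  tab <- out$table
  expect_equal(tab$lfc_shrunk[1], 6, tolerance = 0.01)
  expect_equal(tab$lfc_shrunk[2], -6, tolerance = 0.01)
  expect_identical(tab$lfc_shrunk[3], 0)
  expect_lt(abs(tab$lfc_shrunk[4]), abs(tab$lfc_mle[4]))
  expect_true(all(abs(tab$lfc_shrunk) <= abs(tab$lfc_mle) + 1e-9))
  # posterior mode matches an independent two-stage grid-search oracle
  grid_mode <- function(bhat, se, tau) {
    obj <- function(b) (b - bhat)^2 / (2 * se^2) + log(1 + (b / tau)^2)
    g1 <- seq(min(0, bhat), max(0, bhat), length.out = 4001)
    b1 <- g1[which.min(obj(g1))]
    g2 <- seq(b1 - 2e-3, b1 + 2e-3, by = 1e-6)
    g2[which.min(obj(g2))]
  }
  for (i in c(1, 4, 5, 6)) {
    expect_equal(tab$lfc_shrunk[i],
                 grid_mode(tab$lfc_mle[i], tab$se[i], 0.5), tolerance = 1e-5)
  }
})

test_that("the regularized log transform shrinks toward the gene intercept", {
  counts <- matrix(c(100L, 200L, 400L, 800L,
                     64L, 64L, 64L, 64L,
                     0L, 5L, 1L, 3L), 3, 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  em <- toy_expression(counts, rep("tA", 3))
  sf <- library_size_factors(em)
  sf$sf[] <- 1
  # phi = 0: rlog equals the plain shifted log
  phi0 <- stats::setNames(rep(0, 3), rownames(counts))
  rl0 <- rlog_transform(em, sf, phi0)
  expect_equal(rl0$mat, log2(counts + 0.5), ignore_attr = TRUE)
  # positive dispersion: variance never exceeds the unshrunk variance,
  # equal-count genes stay exactly constant, and order is preserved
  phi <- stats::setNames(c(0.05, 0.05, 2), rownames(counts))
  rl <- rlog_transform(em, sf, phi)
  y <- log2(counts + 0.5)
  for (g in rownames(counts)) {
    expect_lte(var(rl$mat[g, ]), var(y[g, ]) + 1e-12)
    expect_equal(order(rl$mat[g, ]), order(y[g, ]))
  }
  expect_equal(unname(rl$mat[2, ]), rep(log2(64.5), 4))
  expect_lt(diff(range(rl$mat[3, ])), diff(range(y[3, ])))
})

test_that("top-variable selection is stable and per taxon", {
  em <- simulate_community(community_sim_spec(n_taxa = 2, genes_per_taxon = 40,
                                              days = 4L, seed = 17))
  sf <- within_taxon_size_factors(em)
  rl <- rlog_transform(em, sf, estimate_dispersions(em, sf))
  sel <- select_top_variable(rl, em, n = 10)
  expect_named(sel, c("t01", "t02"))
  expect_true(all(lengths(sel) == 10))
  expect_true(all(em$gene_taxon[sel$t01] == "t01"))
  # permuting samples does not change the selection
  perm <- rev(colnames(em$counts))
  rl2 <- rl; rl2$mat <- rl2$mat[, perm]
  expect_identical(select_top_variable(rl2, em, n = 10), sel)
  # n larger than the taxon warns and keeps everything
  w <- capture_warnings(sel_all <- select_top_variable(rl, em, n = 100))
  expect_match(w, "fewer than n", all = TRUE)
  expect_length(w, 2)
  expect_true(all(lengths(sel_all) == 40))
})

test_that("taxon inclusion applies the strict every-sample share rule", {
  counts <- matrix(c(400L, 400L, 400L, 400L,
                     598L, 592L, 594L, 596L,
                     2L, 10L, 6L, 6L), 3, 4, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  em <- toy_expression(counts, c("tA", "tB", "tC"))
  # tC is at 0.2% in s1 (2/1000) but ~1% elsewhere: excluded
  expect_setequal(taxon_inclusion(em, 0.005), c("tA", "tB"))
  expect_setequal(taxon_inclusion(em, 0.005, scope = "mean"), c("tA", "tB", "tC"))
  expect_setequal(taxon_inclusion(em, 0), c("tA", "tB", "tC"))
  em1 <- toy_expression(counts[1, , drop = FALSE], "tA",
                        relabund = matrix(1, 1, 4, dimnames = list("tA", paste0("s", 1:4))))
  expect_equal(taxon_inclusion(em1, 0.9), "tA")
})

test_that("hypergeometric enrichment matches exact tail sums", {
  pm <- pathway_map(list(pw1 = letters[1:5], pw2 = letters[1:10]),
                    universe = letters[1:10])
  enr <- hypergeom_enrichment(letters[1:4], letters[1:10], pm)
  # N=10, K=5, n=4, x=4: P(X>=4) = choose(5,4)*choose(5,0)/choose(10,4) = 5/210
  expect_equal(enr$p[enr$pathway_id == "pw1"], 5 / 210, tolerance = 1e-12)
  # pathway equal to the universe is never enriched: p = 1
  expect_equal(enr$p[enr$pathway_id == "pw2"], 1)
  # x = 0 gives p = 1 by the survival convention
  enr0 <- hypergeom_enrichment(c("f", "g"), letters[1:10],
                               pathway_map(list(pw = c("a", "b"))))
  expect_equal(enr0$p, 1)
  expect_error(hypergeom_enrichment("a", character(0), pm), "empty")
  expect_error(hypergeom_enrichment("zz", letters[1:10], pm), "outside")
})
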