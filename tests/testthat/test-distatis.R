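# random PSD distance tables via random coordinate clouds
random_tables <- function(K, n, p = 3, seed = 1) {
  withr::with_seed(seed, {
    tabs <- lapply(seq_len(K), function(k) {
      X <- matrix(rnorm(n * p), n, p,
                  dimnames = list(paste0("s", seq_len(n)), NULL))
      as.matrix(dist(X))
    })
    names(tabs) <- paste0("T", seq_len(K))
    distance_set(tabs)
  })
}

test_that("expression distances are Euclidean with validated structure", {
  mat <- matrix(c(0, 3, 4, 0), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ds <- expression_distances(mat, list(tA = c("g1", "g2")))
  expect_equal(ds$tA["s1", "s2"], 5) # the 3-4-5 triangle
  expect_equal(diag(ds$tA), c(s1 = 0, s2 = 0))
  # identical sample columns are at distance zero
  m2 <- cbind(mat, s3 = mat[, "s2"])
  ds2 <- expression_distances(m2, list(tA = c("g1", "g2")))
  expect_equal(ds2$tA["s2", "s3"], 0)
  # triangle inequality on random data (exhaustive over triples)
  dn <- random_tables(1, 7, seed = 3)[[1]]
  for (i in 1:7) for (j in 1:7) for (k in 1:7) {
    expect_lte(dn[i, j], dn[i, k] + dn[k, j] + 1e-12)
  }
  # mismatched samples are rejected
  bad <- list(a = dn, b = dn[c(2:7, 1), c(2:7, 1)])
  expect_error(distance_set(bad), "sample mismatch")
})

test_that("cross products recover centered inner products and normalize to unit eigenvalue", {
  # points on a line at 0, 1, 2
  x <- c(0, 1, 2)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("s", 1:3), paste0("s", 1:3))
  cp <- cross_product(D)
  xc <- x - mean(x)
  expect_equal(unname(cp$S_raw), outer(xc, xc), tolerance = 1e-12)
  expect_equal(eigen(cp$S, symmetric = TRUE)$values[1], 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(cp$S_raw)), rep(0, 3), tolerance = 1e-12)
  # degenerate all-zero table
  D0 <- matrix(0, 3, 3, dimnames = dimnames(D))
  expect_error(cross_product(D0), "degenerate")
})

test_that("table weights are uniform for identical tables and downweight the odd one out", {
  ds <- random_tables(1, 6, seed = 5)
  S <- cross_product(ds[[1]])$S
  tw <- table_weights(list(a = S, b = S, c = S, d = S))
  expect_equal(unname(tw$alpha), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(unname(diag(tw$C)), rep(1, 4))
  expect_equal(sum(tw$alpha), 1)

  # two congruent structures plus an unrelated one: the outsider gets the
  # smallest weight (eigen-decomposition oracle on the constructed C)
  ds2 <- random_tables(2, 10, p = 4, seed = 6)
  S1 <- cross_product(ds2[[1]])$S
  S2 <- cross_product(as.matrix(dist(2 * cmdscale(ds2[[1]], k = 4))))$S
  S3 <- cross_product(ds2[[2]])$S
  tw2 <- table_weights(list(x = S1, y = S2, z = S3))
  expect_equal(which.min(tw2$alpha), c(z = 3L))
})

test_that("with identical tables DiSTATIS reduces to classical MDS", {
  ds <- random_tables(1, 8, p = 3, seed = 7)
  D <- ds[[1]]
  dset <- distance_set(list(a = D, b = D, c = D, d = D))
  res <- distatis(dset)
  expect_equal(unname(res$alpha), rep(0.25, 4), tolerance = 1e-12)
  mds <- cmdscale(D, k = 3)
  l1 <- cross_product(D)$lambda1
  for (j in 1:3) {
    ref <- mds[, j] / sqrt(l1)
    dev <- min(max(abs(res$F[, j] - ref)), max(abs(res$F[, j] + ref)))
    expect_lt(dev, 1e-8)
  }
  expect_equal(sum(res$tau), 1, tolerance = 1e-12)
})

test_that("the barycentric identity and order invariance hold on random inputs", {
  for (s in 1:5) {
    dset <- random_tables(4, 9, seed = 20 + s)
    res <- distatis(dset)
    recon <- Reduce(`+`, Map(`*`, res$partial, as.list(res$alpha)))
    expect_lt(max(abs(recon - res$F)), 1e-10)
    expect_true(all(res$eigenvalues > -1e-9))
    # permuting table order changes scores at most by axis sign
    res2 <- distatis(distance_set(dset[c(3, 1, 4, 2)]))
    for (j in seq_len(ncol(res$F))) {
      dev <- min(max(abs(res2$F[, j] - res$F[, j])),
                 max(abs(res2$F[, j] + res$F[, j])))
      expect_lt(dev, 1e-8)
    }
  }
})

test_that("bootstrap ellipses collapse for identical tables and are seed-stable", {
  ds <- random_tables(1, 6, seed = 9)
  D <- ds[[1]]
  same <- distatis(distance_set(list(a = D, b = D, c = D, d = D)))
  bt <- bootstrap_compromise(same, B = 120, seed = 2)
  expect_lt(max(bt$ellipses$area), 1e-16)
  # deterministic under the seed, and centered near the compromise scores
  mixed <- distatis(random_tables(5, 6, seed = 10))
  b1 <- bootstrap_compromise(mixed, B = 200, seed = 3)
  b2 <- bootstrap_compromise(mixed, B = 200, seed = 3)
  expect_identical(b1$ellipses, b2$ellipses)
  expect_lt(max(abs(b1$ellipses$center1 - mixed$F[, 1])), 0.3)
  expect_error(bootstrap_compromise(distatis(distance_set(list(a = D, b = D)))),
               "at least 3")
})

test_that("the Krzanowski-Lai index picks out three well-separated blobs", {
  X <- withr::with_seed(11, {
    ctr <- rbind(c(0, 0), c(12, 0), c(0, 12))
    do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(rnorm(16, sd = 0.4), 8, 2), 2, ctr[i, ], "+")
    }))
  })
  cl <- kmeans_kl(X, k_range = 2:6, seed = 12)
  expect_equal(cl$k, 3L)
  expect_equal(length(unique(cl$labels[1:8])), 1L)
  # W_k is nonincreasing in k
  expect_true(all(diff(cl$wss) <= 1e-8))
  expect_error(kmeans_kl(X[1:4, ], k_range = 2:6), "k_range")
})

test_that("PERMANOVA matches exhaustive enumeration and vegan on reference cases", {
  # two groups of three, far apart: only the true split and its mirror reach
  # the observed F, so the enumeration p-value is 2/20
  X <- rbind(matrix(rnorm(6, sd = 0.1), 3, 2),
             matrix(rnorm(6, sd = 0.1) + 10, 3, 2))
  X <- withr::with_seed(13, X * 1) # fix the cloud
  rownames(X) <- paste0("s", 1:6)
  grp <- rep(c("a", "b"), each = 3)
  ex <- permanova(X, grp, exhaustive = TRUE)
  expect_equal(ex$p, 2 / 20)
  expect_equal(ex$B, 20)
  # sampled permutations approach the same p
  pm <- permanova(X, grp, B = 1999, seed = 14)
  expect_lt(abs(pm$p - 0.1), 0.03)
  # pseudo-F and R2 agree with vegan::adonis2
  skip_if_not_installed("vegan")
  Y <- withr::with_seed(15, matrix(rnorm(24), 8, 3,
                                   dimnames = list(paste0("s", 1:8), NULL)))
  g2 <- rep(c("a", "b"), each = 4)
  mine <- permanova(dist(Y), g2, B = 99, seed = 1)
  ref <- vegan::adonis2(dist(Y) ~ g2, permutations = 99)
  expect_equal(mine$F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  expect_error(permanova(dist(Y), c("a", rep("b", 7)), B = 9), "singleton")
})

test_that("identical point clouds under shuffled labels give large PERMANOVA p", {
  Y <- withr::with_seed(16, matrix(rnorm(40), 10, 4,
                                   dimnames = list(paste0("s", 1:10), NULL)))
  g <- rep(c("a", "b"), 5)
  res <- permanova(dist(Y), g, B = 499, seed = 17)
  expect_gt(res$p, 0.1)
  expect_lt(res$R2, 0.35)
})

test_that("PERMDISP detects dispersion differences and matches the vegan F", {
  # equal dispersion by construction
  Y0 <- withr::with_seed(18, rbind(matrix(rnorm(20), 10, 2),
                                   matrix(rnorm(20) + 5, 10, 2)))
  rownames(Y0) <- paste0("s", 1:20)
  g <- rep(c("a", "b"), each = 10)
  eq <- permdisp(dist(Y0), g, B = 499, seed = 19)
  expect_gt(eq$p, 0.05)
  # one tight group vs one spread group
  Y1 <- withr::with_seed(20, rbind(matrix(rnorm(20, sd = 0.05), 10, 2),
                                   matrix(rnorm(20, sd = 3) + 5, 10, 2)))
  rownames(Y1) <- paste0("s", 1:20)
  ne <- permdisp(dist(Y1), g, B = 499, seed = 21)
  expect_lt(ne$p, 0.01)
  expect_error(permdisp(dist(Y1), rep("a", 20)), "two groups")
  skip_if_not_installed("vegan")
  bd <- vegan::betadisper(dist(Y1), g, type = "centroid")
  ref <- anova(bd)$`F value`[1]
  expect_equal(ne$F, ref, tolerance = 1e-6)
})
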