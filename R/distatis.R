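#' Per-taxon expression distance tables
#'
#' Pairwise Euclidean distances between sample columns of each taxon's rlog
#' submatrix; the input tables of the DiSTATIS compromise.
#'
#' @param rlog an [rlog_transform()] result (or plain matrix).
#' @param gene_sets named list taxon -> gene ids (e.g. from
#'   [select_top_variable()]).
#' @return object of class `distance_set`: named list of symmetric matrices
#'   with zero diagonals and shared sample ordering.
#' @export
expression_distances <- function(rlog, gene_sets) {
  mat <- if (inherits(rlog, "rlog_matrix")) rlog$mat else rlog
  tabs <- lapply(gene_sets, function(g) {
    as.matrix(stats::dist(t(mat[g, , drop = FALSE])))
  })
  distance_set(tabs)
}

#' Validate a set of distance tables
#' @param tables named list of symmetric nonnegative matrices with zero
#'   diagonal and identical dimnames.
#' @return object of class `distance_set`.
#' @export
distance_set <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  ref <- colnames(tables[[1]])
  for (nm in names(tables)) {
    D <- tables[[nm]]
    if (!isSymmetric(unname(D), tol = 1e-8)) stop("table '", nm, "' is not symmetric")
    if (any(abs(diag(D)) > 1e-10)) stop("table '", nm, "' has nonzero diagonal")
    if (any(D < -1e-12)) stop("table '", nm, "' has negative distances")
    if (!identical(colnames(D), ref)) stop("sample mismatch in table '", nm, "'")
  }
  structure(tables, class = "distance_set")
}

#' Double-centered, normalized cross-product matrix
#'
#' Converts a squared-distance table to its inner-product form
#' `S = -1/2 Xi D2 Xi'` with the centering operator `Xi = I - 1 m'` for
#' uniform masses m = 1/n (the classical MDS transform), then scales by the
#' first eigenvalue so every table has largest eigenvalue 1.
#'
#' @param D symmetric distance matrix.
#' @return list with `S` (normalized), `S_raw`, `lambda1`.
#' @export
cross_product <- function(D) {
  n <- nrow(D)
  m <- rep(1 / n, n)
  Xi <- diag(n) - matrix(1, n, 1) %*% t(m)
  S <- -0.5 * Xi %*% (D^2) %*% t(Xi)
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(D)
  l1 <- eigen(S, symmetric = TRUE, only.values = TRUE)$values[1]
  if (l1 <= 1e-12) stop("degenerate distance table: first eigenvalue is not positive")
  list(S = S / l1, S_raw = S, lambda1 = l1)
}

#' RV congruence matrix and table weights
#'
#' The congruence between two normalized cross-product tables is their RV
#' coefficient `<S_j, S_k> / (||S_j|| ||S_k||)`. Table weights alpha are the
#' first eigenvector of the congruence matrix, sign-fixed nonnegative and
#' scaled to sum 1; they define the compromise as the alpha-weighted sum of
#' tables.
#'
#' @param S_list list of normalized cross-product matrices.
#' @return list with `C` (K x K) and `alpha` (sums to 1).
#' @export
table_weights <- function(S_list) {
  K <- length(S_list)
  stopifnot(K >= 2)
  C <- matrix(1, K, K, dimnames = list(names(S_list), names(S_list)))
  nrm <- vapply(S_list, function(S) sqrt(sum(S * S)), numeric(1))
  for (j in seq_len(K - 1)) for (k in (j + 1):K) {
    C[j, k] <- C[k, j] <- sum(S_list[[j]] * S_list[[k]]) / (nrm[j] * nrm[k])
  }
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8)) v <- pmax(v, 0)
  alpha <- v / sum(v)
  list(C = C, alpha = stats::setNames(alpha, names(S_list)))
}

#' DiSTATIS compromise and factor scores
#'
#' The compromise `S+ = sum_k alpha_k S_k` is eigendecomposed; compromise
#' factor scores are `F = V Lambda^(1/2)` and each table's partial factor
#' scores are its projection `F_k = S_k V Lambda^(-1/2)` onto the compromise
#' axes, so the alpha-weighted mean of partial scores recovers F exactly.
#' Eigenvector signs follow the convention that each axis's largest-
#' magnitude loading is positive.
#'
#' @param S_list list of normalized cross-product matrices.
#' @param alpha table weights summing to 1 (from [table_weights()]).
#' @param tol negative-eigenvalue tolerance; more negative values error.
#' @return object of class `distatis_result`: `F` (samples x dims), `partial`
#'   (list of F_k), `eigenvalues`, `tau` (explained variance fractions),
#'   `alpha`, `C`, `S_plus`, `V`.
#' @export
compromise <- function(S_list, alpha, tol = 1e-9) {
  stopifnot(length(S_list) == length(alpha))
  S_plus <- Reduce(`+`, Map(`*`, S_list, as.list(alpha)))
  ev <- eigen(S_plus, symmetric = TRUE)
  if (any(ev$values < -tol)) stop("compromise has negative eigenvalues; inputs are not PSD")
  keep <- which(ev$values > max(ev$values) * 1e-12)
  lam <- ev$values[keep]
  V <- ev$vectors[, keep, drop = FALSE]
  ## sign convention: largest |loading| positive per axis
  for (j in seq_along(keep)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  Fs <- V %*% diag(sqrt(lam), length(lam))
  rn <- rownames(S_list[[1]])
  dimnames(Fs) <- list(rn, paste0("F", seq_along(lam)))
  partial <- lapply(S_list, function(S) {
    P <- S %*% V %*% diag(1 / sqrt(lam), length(lam))
    dimnames(P) <- dimnames(Fs)
    P
  })
  structure(list(F = Fs, partial = partial, eigenvalues = lam,
                 tau = lam / sum(lam), alpha = alpha, S_plus = S_plus, V = V),
            class = "distatis_result")
}

#' Full DiSTATIS analysis of a distance set
#'
#' @param dset a [distance_set()] (K >= 2 tables).
#' @return a [compromise()] result, with the normalized cross-products kept
#'   as attribute `S_list`.
#' @export
distatis <- function(dset) {
  S_list <- lapply(dset, function(D) cross_product(D)$S)
  tw <- table_weights(S_list)
  res <- compromise(S_list, tw$alpha)
  res$C <- tw$C
  attr(res, "S_list") <- S_list
  res
}

#' @export
print.distatis_result <- function(x, ...) {
  cat(sprintf("distatis_result: %d samples, %d tables; tau1=%.1f%%, tau2=%.1f%%\n",
              nrow(x$F), length(x$partial), 100 * x$tau[1],
              if (length(x$tau) > 1) 100 * x$tau[2] else 0))
  invisible(x)
}

#' Bootstrap prediction ellipses for compromise scores
#'
#' Resamples the K tables with replacement, recomputes table weights and the
#' compromise, projects each bootstrap compromise onto the reference axes,
#' and summarizes the per-sample cloud on the first two axes by a 95%
#' normal-approximation prediction ellipse.
#'
#' @param res a [distatis()] result (with `S_list` attribute) or a list of
#'   normalized cross-products via `S_list`.
#' @param B bootstrap replicates (default 1000; < 100 warns).
#' @param seed integer seed.
#' @param level ellipse coverage (default 0.95).
#' @param dims two axis indices (default 1:2).
#' @return list with `scores` (B x n x 2 array) and `ellipses` data.frame
#'   (sample, center1, center2, r1, r2, angle, area).
#' @export
bootstrap_compromise <- function(res, B = 1000, seed = 1, level = 0.95,
                                 dims = 1:2) {
  S_list <- attr(res, "S_list")
  stopifnot(!is.null(S_list), length(dims) == 2)
  K <- length(S_list)
  if (K < 3) stop("table bootstrap needs at least 3 tables")
  if (B < 100) warning("B < 100 gives unstable ellipses")
  n <- nrow(res$F)
  V <- res$V[, dims, drop = FALSE]
  ilam <- 1 / sqrt(res$eigenvalues[dims])
  arr <- with_seed(seed, {
    a <- array(NA_real_, c(B, n, 2))
    for (b in seq_len(B)) {
      idx <- sample.int(K, K, replace = TRUE)
      Sb <- S_list[idx]
      ab <- if (length(unique(idx)) == 1L) rep(1 / K, K) else table_weights(Sb)$alpha
      Sp <- Reduce(`+`, Map(`*`, Sb, as.list(ab)))
      a[b, , ] <- Sp %*% V %*% diag(ilam, 2)
    }
    a
  })
  q <- stats::qchisq(level, df = 2)
  ell <- lapply(seq_len(n), function(i) {
    X <- arr[, i, , drop = TRUE]
    ctr <- colMeans(X)
    Sg <- stats::cov(X)
    e <- eigen(Sg, symmetric = TRUE)
    r <- sqrt(pmax(e$values, 0) * q)
    data.frame(sample = rownames(res$F)[i], center1 = ctr[1], center2 = ctr[2],
               r1 = r[1], r2 = r[2],
               angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
               area = pi * r[1] * r[2], stringsAsFactors = FALSE)
  })
  list(scores = arr, ellipses = do.call(rbind, ell), level = level, dims = dims)
}

#' K-means clustering with Krzanowski-Lai selection of k
#'
#' Runs seeded multi-restart k-means over a candidate range and picks the
#' number of clusters maximizing the Krzanowski-Lai index
#' `KL(k) = |DIFF(k) / DIFF(k+1)|` with
#' `DIFF(k) = (k-1)^(2/p) W_{k-1} - k^(2/p) W_k`, where `W_k` is the total
#' within-cluster sum of squares and p the dimensionality.
#'
#' @param F matrix of scores (samples x dims), e.g. compromise scores.
#' @param k_range candidate cluster numbers (default 2..min(8, n-2)).
#' @param nstart restarts per k (default 25).
#' @param seed integer seed.
#' @return object of class `cluster_result`: `labels`, `k`, `kl` (index per
#'   candidate), `wss` (W_k for the scanned range).
#' @export
kmeans_kl <- function(F, k_range = NULL, nstart = 25, seed = 1) {
  F <- as.matrix(F)
  n <- nrow(F)
  k_range <- k_range %||% (2:max(2, min(8, n - 2)))
  if (min(k_range) < 2 || max(k_range) > n - 2) {
    stop("k_range must lie within [2, n-2]")
  }
  p <- ncol(F)
  ks <- (min(k_range) - 1):(max(k_range) + 1)
  with_seed(seed, {
    fits <- lapply(ks, function(k) {
      if (k == 1) {
        list(tot.withinss = sum(scale(F, scale = FALSE)^2),
             cluster = rep(1L, n))
      } else {
        stats::kmeans(F, centers = k, nstart = nstart, iter.max = 50)
      }
    })
    names(fits) <- ks
    W <- vapply(fits, function(f) f$tot.withinss, numeric(1))
    DIFF <- function(k) {
      (k - 1)^(2 / p) * W[[as.character(k - 1)]] - k^(2 / p) * W[[as.character(k)]]
    }
    kl <- vapply(k_range, function(k) abs(DIFF(k) / DIFF(k + 1)), numeric(1))
    names(kl) <- k_range
    k_best <- k_range[which.max(kl)]
    structure(list(labels = fits[[as.character(k_best)]]$cluster, k = k_best,
                   kl = kl, wss = W), class = "cluster_result")
  })
}

## Pairwise squared-distance decomposition shared by the permutation tests.
dist_matrix_of <- function(x, variance_cutoff = 0.99) {
  if (inherits(x, "distatis_result")) {
    nd <- which(cumsum(x$tau) >= variance_cutoff)[1]
    as.matrix(stats::dist(x$F[, seq_len(nd), drop = FALSE]))
  } else if (inherits(x, "dist")) {
    as.matrix(x)
  } else if (is.matrix(x) && isSymmetric(unname(x), tol = 1e-8) &&
             all(abs(diag(x)) < 1e-10)) {
    x
  } else {
    as.matrix(stats::dist(x))
  }
}

permanova_F <- function(D2, groups) {
  N <- nrow(D2)
  a <- length(unique(groups))
  SS_T <- sum(D2[upper.tri(D2)]) / N
  SS_W <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    SS_W <- SS_W + sum(D2[i, i][upper.tri(D2[i, i, drop = FALSE])]) / length(i)
  }
  SS_A <- SS_T - SS_W
  Fstat <- (SS_A / (a - 1)) / (SS_W / (N - a))
  c(F = Fstat, R2 = SS_A / SS_T)
}

#' Permutational multivariate ANOVA (PERMANOVA)
#'
#' Pseudo-F from the squared-distance decomposition
#' (`SS_total = sum d^2 / N`, within-group analogues), with a permutation
#' p-value over free relabelings of the samples. When applied to a
#' [distatis()] result, distances are Euclidean on the compromise scores of
#' the leading axes cumulatively explaining `variance_cutoff` of variance.
#' `exhaustive = TRUE` enumerates every distinct assignment of the group
#' sizes (two-group designs) and reports the exact enumeration p-value.
#'
#' @param x a `distatis_result`, `dist`, distance matrix, or coordinate
#'   matrix.
#' @param groups group labels (>= 2 groups, each with >= 2 members).
#' @param B permutations (default 999).
#' @param seed integer seed.
#' @param variance_cutoff compromise variance retained (default 0.99).
#' @param exhaustive enumerate all assignments instead of sampling.
#' @return object of class `perm_test`: `F`, `R2`, `p`, `B`, `method`,
#'   `group_sizes`.
#' @export
permanova <- function(x, groups, B = 999, seed = 1, variance_cutoff = 0.99,
                      exhaustive = FALSE) {
  D <- dist_matrix_of(x, variance_cutoff)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("singleton group(s): ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  D2 <- D^2
  obs <- permanova_F(D2, groups)
  if (exhaustive) {
    if (length(sizes) != 2) stop("exhaustive enumeration supports two groups")
    n <- length(groups)
    g1 <- names(sizes)[1]
    combs <- utils::combn(n, sizes[[1]])
    Fs <- apply(combs, 2, function(idx) {
      gl <- rep(names(sizes)[2], n)
      gl[idx] <- g1
      permanova_F(D2, gl)[["F"]]
    })
    p <- sum(Fs >= obs[["F"]] - 1e-12) / ncol(combs)
    B_used <- ncol(combs)
    method <- "exhaustive"
  } else {
    Fs <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        permanova_F(D2, sample(groups))[["F"]]
      }, numeric(1))
    })
    p <- (1 + sum(Fs >= obs[["F"]] - 1e-12)) / (B + 1)
    B_used <- B
    method <- "permutation"
  }
  structure(list(F = obs[["F"]], R2 = obs[["R2"]], p = p, B = B_used,
                 method = method, group_sizes = as.vector(sizes),
                 test = "permanova"), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: F=%.3f%s, p=%.4g (%s, B=%d)\n", x$test, x$F,
              if (!is.null(x$R2)) sprintf(", R2=%.3f", x$R2) else "",
              x$p, x$method, x$B))
  invisible(x)
}

#' Permutational test of multivariate dispersion (PERMDISP)
#'
#' Embeds the distance matrix by principal coordinates, computes each
#' sample's Euclidean distance to its group centroid, and tests equality of
#' mean dispersion across groups by the ANOVA F statistic with a
#' permutation p-value over relabelings of the centroid distances.
#'
#' @inheritParams permanova
#' @return object of class `perm_test` with `F`, `p`, `B` and per-group
#'   `dispersion` means.
#' @export
permdisp <- function(x, groups, B = 999, seed = 1, variance_cutoff = 0.99) {
  D <- dist_matrix_of(x, variance_cutoff)
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("singleton group(s): ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  n <- nrow(D)
  ## principal coordinates (distances here are Euclidean, eigenvalues >= 0)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- ev$values > max(ev$values, 0) * 1e-10
  X <- ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev$values[keep]), sum(keep))
  z <- vapply(seq_len(n), function(i) {
    ctr <- colMeans(X[groups == groups[i], , drop = FALSE])
    sqrt(sum((X[i, ] - ctr)^2))
  }, numeric(1))
  f_of <- function(zz, gl) {
    m <- stats::aov(zz ~ factor(gl))
    summary(m)[[1]]$`F value`[1]
  }
  Fobs <- f_of(z, groups)
  Fs <- with_seed(seed, vapply(seq_len(B), function(b) f_of(sample(z), groups),
                               numeric(1)))
  p <- (1 + sum(Fs >= Fobs - 1e-12)) / (B + 1)
  disp <- tapply(z, groups, mean)
  structure(list(F = Fobs, R2 = NULL, p = p, B = B, method = "permutation",
                 group_sizes = as.vector(sizes), dispersion = disp,
                 test = "permdisp"), class = "perm_test")
}
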