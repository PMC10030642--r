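#' Within-taxon sum scaling size factors
#'
#' Community transcriptome counts confound expression with taxon abundance:
#' when a species blooms, every one of its genes gains reads. Within-taxon
#' sum scaling (WTSS) removes this signal by normalizing each gene against
#' its own taxon's total counts. The size factor of taxon t in sample s is
#' `s_{t,s} = T_{t,s} / geomean_s(T_{t,.})` where `T_{t,s}` is the taxon
#' total, so factors have geometric mean 1 across samples within each taxon.
#' Taxon-samples with zero totals get an NA factor and are excluded from
#' that taxon's tests downstream.
#'
#' @param em an [expression_matrix()].
#' @return object of class `size_factor_set`: matrix `sf` (taxa x samples),
#'   data.frame `excluded` of zero-total taxon-samples, and `taxon_totals`.
#' @export
within_taxon_size_factors <- function(em) {
  tot <- rowsum(em$counts, em$gene_taxon, reorder = TRUE)
  zero_rows <- rowSums(tot) == 0
  if (any(zero_rows)) {
    stop("taxon with zero counts in every sample: ",
         paste(rownames(tot)[zero_rows], collapse = ", "))
  }
  sf <- t(apply(tot, 1, function(x) {
    gm <- geom_mean(x[x > 0])
    ifelse(x > 0, x / gm, NA_real_)
  }))
  dimnames(sf) <- dimnames(tot)
  excl <- which(is.na(sf), arr.ind = TRUE)
  excluded <- data.frame(taxon = rownames(sf)[excl[, 1]],
                         sample = colnames(sf)[excl[, 2]],
                         stringsAsFactors = FALSE)
  structure(list(sf = sf, excluded = excluded, taxon_totals = tot),
            class = "size_factor_set")
}

#' Library-size size factors (naive alternative)
#'
#' Total-count normalization ignoring taxon identity: one factor per sample,
#' total counts over their geometric mean, replicated across taxa. Provided
#' as the comparison baseline that within-taxon sum scaling improves on.
#'
#' @param em an [expression_matrix()].
#' @return a `size_factor_set` whose rows are identical across taxa.
#' @export
library_size_factors <- function(em) {
  lib <- colSums(em$counts)
  f <- lib / geom_mean(lib[lib > 0])
  taxa <- sort(unique(em$gene_taxon))
  sf <- matrix(rep(f, each = length(taxa)), nrow = length(taxa),
               dimnames = list(taxa, colnames(em$counts)))
  structure(list(sf = sf, excluded = data.frame(taxon = character(),
                                                sample = character()),
                 taxon_totals = rowsum(em$counts, em$gene_taxon, reorder = TRUE)),
            class = "size_factor_set")
}

## Per-gene size factor rows aligned with the count matrix.
gene_size_factors <- function(em, sf) {
  sf$sf[em$gene_taxon[rownames(em$counts)], , drop = FALSE]
}

#' Normalized counts
#' @param em an [expression_matrix()].
#' @param sf a `size_factor_set`.
#' @return matrix of counts divided by their taxon-sample size factor.
#' @export
normalized_counts <- function(em, sf) {
  em$counts / gene_size_factors(em, sf)
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Method-of-moments gene-wise estimates
#' `phihat_g = max(0, (var_g - mean_g) / mean_g^2)` on normalized counts,
#' a robust 1/mu + b mean-dispersion trend fitted across genes, and an
#' empirical-Bayes shrink of `log phihat` toward the trend with weight
#' given by the ratio of sampling variance to total variance of the
#' log residuals. Genes whose moment estimate is zero (at or below the
#' Poisson limit) take the trend value directly.
#'
#' The gene-wise variance is the pooled within-cell variance of the design
#' cells (predation x coevolved prey x day), so treatment effects do not
#' masquerade as biological dispersion; with `pool_cells = FALSE` the plain
#' across-sample variance is used instead.
#'
#' @param em an [expression_matrix()].
#' @param sf a `size_factor_set`.
#' @param min_mu minimum normalized mean for a gene to inform the trend fit.
#' @param pool_cells pool variances within design cells (default TRUE).
#' @return numeric vector `phi_g` (named by gene) with attributes `phihat`,
#'   `trend` (function of mu) and `trend_coef`.
#' @export
estimate_dispersions <- function(em, sf, min_mu = 1, pool_cells = TRUE) {
  nc <- normalized_counts(em, sf)
  n_eff <- rowSums(!is.na(nc))
  cell <- interaction(em$sample_meta$predation, em$sample_meta$coevolved_prey,
                      em$sample_meta$day, drop = TRUE)
  df_resid <- ncol(nc) - length(unique(cell))
  if (pool_cells && df_resid < 3L) {
    stop("fewer than 3 residual degrees of freedom; pool samples (pool_cells = FALSE) or add replicates")
  }
  if (min(n_eff) < 3L) stop("fewer than 3 usable samples; pool samples before estimating dispersions")
  mu <- rowMeans(nc, na.rm = TRUE)
  v <- if (pool_cells) {
    ## pooled within-cell variance: residual SS around cell means
    cs <- vapply(levels(cell), function(l) {
      x <- nc[, cell == l, drop = FALSE]
      rowSums((x - rowMeans(x, na.rm = TRUE))^2, na.rm = TRUE)
    }, numeric(nrow(nc)))
    rowSums(cs) / df_resid
  } else {
    apply(nc, 1, stats::var, na.rm = TRUE)
  }
  phihat <- pmax(0, (v - mu) / mu^2)
  use <- mu >= min_mu & phihat > 0
  if (sum(use) >= 10) {
    fit <- tryCatch(MASS::rlm(phihat[use] ~ I(1 / mu[use]), maxit = 50),
                    error = function(e) stats::lm(phihat[use] ~ I(1 / mu[use])))
    b <- max(stats::coef(fit)[1], 1e-4)
    a <- max(stats::coef(fit)[2], 0)
  } else {
    b <- max(mean(phihat[use]) %||% 0.01, 1e-4, na.rm = TRUE)
    a <- 0
  }
  trend <- function(m) a / m + b
  ltr <- log(trend(mu))
  lphi <- log(pmax(phihat, 1e-8))
  resid <- (lphi - ltr)[use]
  samp_var <- 2 / pmax(if (pool_cells) df_resid else mean(n_eff) - 1, 1)
  prior_var <- max(stats::mad(resid)^2 - samp_var, 0.1)
  w <- samp_var / (samp_var + prior_var)
  phi <- exp((1 - w) * lphi + w * ltr)
  phi[phihat == 0] <- trend(mu[phihat == 0])
  phi <- stats::setNames(pmin(phi, 10), rownames(nc))
  attr(phi, "phihat") <- phihat
  attr(phi, "trend") <- trend
  attr(phi, "trend_coef") <- c(a = a, b = b)
  attr(phi, "shrink_weight") <- w
  phi
}

## Build the per-taxon design matrix: treatment formula on sample_meta plus
## the centered log2 relative abundance covariate of that taxon.
taxon_design_matrix <- function(em, taxon, samples,
                                design = ~ predation * coevolved_prey,
                                covariate = c("log2_relabund", "none"),
                                pseudo = 1e-6) {
  covariate <- match.arg(covariate)
  meta <- em$sample_meta[samples, , drop = FALSE]
  mm <- stats::model.matrix(design, data = meta)
  if (covariate == "log2_relabund") {
    ra <- log2(em$taxon_relabund[taxon, samples] + pseudo)
    ra <- ra - mean(ra)
    if (stats::sd(ra) > 1e-10) {
      mm <- cbind(mm, log2_relabund = ra)
    }
  }
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("design matrix rank deficient for taxon '", taxon,
         "'; aliased columns: ", paste(aliased, collapse = ", "))
  }
  mm
}

#' Negative binomial GLM differential expression
#'
#' Fits one NB GLM per gene (log link, fixed gene-wise dispersion, offsets
#' `log s_{t,s}` from within-taxon sum scaling) with the treatment design
#' plus, by default, the centered `log2(relabund + 1e-6)` of the gene's
#' taxon as abundance covariate, and reports the Wald test of the requested
#' coefficient. Because the dispersion and hence the standard error are
#' estimated from few samples, the Wald statistic is referred to a Student-t
#' distribution with the fit's residual degrees of freedom rather than the
#' normal limit. P-values are adjusted by Benjamini-Hochberg jointly across
#' all tested genes of all taxa (per-taxon adjustment available).
#'
#' @param em an [expression_matrix()] (typically one day).
#' @param sf a `size_factor_set`.
#' @param phi per-gene dispersions from [estimate_dispersions()].
#' @param design treatment design formula on the sample metadata.
#' @param contrast name of the tested model matrix coefficient, e.g.
#'   `"predationTRUE:coevolved_preyTRUE"` for the interaction.
#' @param covariate `"log2_relabund"` (default) or `"none"`.
#' @param adjust_scope `"joint"` (default) or `"per_taxon"` BH adjustment.
#' @param max_iter IRLS iteration cap; non-converged genes are flagged
#'   untestable and excluded from the adjustment.
#' @return object of class `de_result`: data.frame `table` with gene_id,
#'   taxon, baseMean, lfc_mle (log2), se (log2), stat, pvalue, padj; plus
#'   the model description. `lfc_shrunk` and the `de` flag are added by
#'   [shrink_lfc()].
#' @export
fit_nb_de <- function(em, sf, phi, design = ~ predation * coevolved_prey,
                      contrast = "predationTRUE:coevolved_preyTRUE",
                      covariate = c("log2_relabund", "none"),
                      adjust_scope = c("joint", "per_taxon"), max_iter = 50) {
  covariate <- match.arg(covariate)
  adjust_scope <- match.arg(adjust_scope)
  keep <- rowSums(em$counts) > 0
  genes <- rownames(em$counts)[keep]
  gsf <- gene_size_factors(em, sf)
  res <- vector("list", length(genes))
  names(res) <- genes
  mm_cache <- list()
  for (g in genes) {
    tx <- em$gene_taxon[[g]]
    samples <- colnames(em$counts)[!is.na(sf$sf[tx, ])]
    if (is.null(mm_cache[[tx]])) {
      mm_cache[[tx]] <- taxon_design_matrix(em, tx, samples, design, covariate)
    }
    mm <- mm_cache[[tx]]
    if (!contrast %in% colnames(mm)) {
      stop("contrast '", contrast, "' is not a column of the design matrix; columns: ",
           paste(colnames(mm), collapse = ", "))
    }
    y <- em$counts[g, samples]
    off <- log(sf$sf[tx, samples])
    theta <- min(1 / max(phi[[g]], 1e-8), 1e8)
    fit <- tryCatch(suppressWarnings(
      stats::glm.fit(mm, y, offset = off,
                     family = MASS::negative.binomial(theta = theta),
                     control = list(maxit = max_iter))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      res[[g]] <- data.frame(gene_id = g, taxon = tx,
                             baseMean = mean(y / exp(off)), lfc_mle = NA_real_,
                             se = NA_real_, stat = NA_real_, pvalue = NA_real_,
                             converged = FALSE, stringsAsFactors = FALSE)
      next
    }
    p <- fit$rank
    covmat <- tryCatch(chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]),
                       error = function(e) NULL)
    ci <- match(contrast, colnames(mm))
    beta <- fit$coefficients[ci]
    se <- if (is.null(covmat)) NA_real_ else sqrt(covmat[ci, ci])
    z <- beta / se
    df_resid <- max(length(y) - p, 1L)
    res[[g]] <- data.frame(gene_id = g, taxon = tx,
                           baseMean = mean(y / exp(off)),
                           lfc_mle = beta / log(2), se = se / log(2),
                           stat = z, pvalue = 2 * stats::pt(-abs(z), df_resid),
                           converged = TRUE, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  tab$padj <- NA_real_
  ok <- tab$converged & !is.na(tab$pvalue)
  if (adjust_scope == "joint") {
    tab$padj[ok] <- stats::p.adjust(tab$pvalue[ok], method = "BH")
  } else {
    for (tx in unique(tab$taxon)) {
      sel <- ok & tab$taxon == tx
      tab$padj[sel] <- stats::p.adjust(tab$pvalue[sel], method = "BH")
    }
  }
  structure(list(table = tab, design = design, contrast = contrast,
                 covariate = covariate, adjust_scope = adjust_scope),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d genes, contrast '%s'%s\n", nrow(x$table), x$contrast,
              if ("de" %in% names(x$table)) sprintf(", %d flagged DE", sum(x$table$de, na.rm = TRUE)) else ""))
  invisible(x)
}

#' Shrink log fold changes with a heavy-tailed prior
#'
#' Posterior-mode moderation of the MLE log2 fold changes under a Cauchy
#' (Student-t, df 1) prior centered at zero. The prior scale is estimated
#' from the exceedance of the MLE LFCs over their standard errors
#' (`sqrt(max(lfc^2 - se^2, 0))`, median of the positive values), floored at
#' 0.05 when no gene exceeds its SE. Because the prior is heavy-tailed,
#' strong signals are left almost untouched while noisy estimates shrink
#' hard. Also sets the DE flag: `padj < padj_threshold` and
#' `|lfc_shrunk| > lfc_threshold`.
#'
#' @param de a [fit_nb_de()] result.
#' @param padj_threshold adjusted p-value threshold (default 0.1).
#' @param lfc_threshold absolute shrunken log2 fold change threshold
#'   (default 2; the flag requires strictly greater).
#' @param prior_scale optional fixed prior scale, bypassing estimation.
#' @return the `de_result` with `lfc_shrunk` and `de` columns and a
#'   `prior_scale` element.
#' @export
shrink_lfc <- function(de, padj_threshold = 0.1, lfc_threshold = 2,
                       prior_scale = NULL) {
  tab <- de$table
  ok <- tab$converged & !is.na(tab$lfc_mle) & !is.na(tab$se) & tab$se > 0
  if (is.null(prior_scale)) {
    exc <- sqrt(pmax(tab$lfc_mle[ok]^2 - tab$se[ok]^2, 0))
    exc <- exc[exc > 0]
    prior_scale <- if (length(exc) >= 3) max(stats::median(exc), 0.05) else 0.05
    if (length(exc) < 3) message("shrink_lfc: no informative LFC exceedances; prior scale floored at 0.05")
  }
  post_mode <- function(bhat, se) {
    obj <- function(b) (b - bhat)^2 / (2 * se^2) + log(1 + (b / prior_scale)^2)
    lo <- min(0, bhat); hi <- max(0, bhat)
    if (hi - lo < 1e-12) return(bhat)
    grid <- seq(lo, hi, length.out = 101)
    i <- which.min(vapply(grid, obj, numeric(1)))
    step <- (hi - lo) / 100
    stats::optimize(obj, c(max(lo, grid[i] - step), min(hi, grid[i] + step)))$minimum
  }
  tab$lfc_shrunk <- NA_real_
  tab$lfc_shrunk[ok] <- vapply(which(ok), function(i) {
    post_mode(tab$lfc_mle[i], tab$se[i])
  }, numeric(1))
  tab$de <- !is.na(tab$padj) & tab$padj < padj_threshold &
    !is.na(tab$lfc_shrunk) & abs(tab$lfc_shrunk) > lfc_threshold
  de$table <- tab
  de$prior_scale <- prior_scale
  de$padj_threshold <- padj_threshold
  de$lfc_threshold <- lfc_threshold
  de
}

#' Regularized log transform
#'
#' Shrinkage-stabilized log2 of normalized counts: with
#' `y_{g,s} = log2((K_{g,s} + 0.5) / s_{t(g),s})` and per-gene intercept
#' `beta_g0 = mean_s y_{g,s}`, the transform is
#' `rlog_{g,s} = beta_g0 + w_g (y_{g,s} - beta_g0)` where
#' `w_g = 1 / (1 + phi_g c)`. The global constant c is the median positive
#' normalized count, so low-count genes (whose trend dispersion is large)
#' shrink strongly toward their intercept while well-measured genes stay
#' close to the plain log scale.
#'
#' @param em an [expression_matrix()].
#' @param sf a `size_factor_set`.
#' @param phi per-gene dispersions.
#' @return object of class `rlog_matrix`: matrix `mat`, vector `intercept`,
#'   vector `weights`, constant `c`.
#' @export
rlog_transform <- function(em, sf, phi) {
  gsf <- gene_size_factors(em, sf)
  y <- log2((em$counts + 0.5) / gsf)
  b0 <- rowMeans(y, na.rm = TRUE)
  nc <- em$counts / gsf
  cc <- stats::median(nc[nc > 0], na.rm = TRUE)
  w <- 1 / (1 + unname(phi[rownames(em$counts)]) * cc)
  mat <- b0 + w * (y - b0)
  dimnames(mat) <- dimnames(em$counts)
  structure(list(mat = mat, intercept = b0, weights = stats::setNames(w, rownames(mat)),
                 c = cc), class = "rlog_matrix")
}

#' Select the most variable genes per taxon
#'
#' Ranks genes within each taxon by their across-sample variance of rlog
#' values and keeps the top `n`; ties break by gene id so the selection is
#' stable under sample reordering. A taxon with fewer than `n` genes keeps
#' them all, with a warning.
#'
#' @param rlog an [rlog_transform()] result.
#' @param em the matching [expression_matrix()].
#' @param n genes per taxon (default 500).
#' @return named list taxon -> character vector of gene ids.
#' @export
select_top_variable <- function(rlog, em, n = 500) {
  stopifnot(n >= 1)
  v <- apply(rlog$mat, 1, stats::var, na.rm = TRUE)
  out <- lapply(split(names(v), em$gene_taxon[names(v)]), function(g) {
    if (length(g) < n) {
      warning("taxon with fewer than n genes; keeping all ", length(g))
    }
    g[order(-v[g], g)][seq_len(min(n, length(g)))]
  })
  out
}

#' Taxa passing the per-sample inclusion threshold
#'
#' Keeps taxa whose share of total counts is strictly greater than
#' `threshold` in every sample (default 0.5%), mirroring the inclusion rule
#' for species-resolved transcriptomes.
#'
#' @param em an [expression_matrix()].
#' @param threshold fraction in [0, 1).
#' @param scope `"every_sample"` (default) or `"mean"` across samples.
#' @return character vector of retained taxa.
#' @export
taxon_inclusion <- function(em, threshold = 0.005,
                            scope = c("every_sample", "mean")) {
  stopifnot(threshold >= 0, threshold < 1)
  scope <- match.arg(scope)
  tot <- rowsum(em$counts, em$gene_taxon, reorder = TRUE)
  share <- sweep(tot, 2, colSums(em$counts), "/")
  keep <- if (scope == "every_sample") {
    apply(share > threshold, 1, all)
  } else {
    rowMeans(share) > threshold
  }
  if (threshold == 0) keep <- rowSums(tot) > 0
  rownames(tot)[keep]
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway with K genes in a universe of N, of which the DE set
#' draws n, the p-value is the hypergeometric tail `P(X >= x)` for the x
#' observed hits, BH-adjusted across pathways.
#'
#' @param de_genes character vector of differentially expressed genes
#'   (must be a subset of `universe`).
#' @param universe character vector of tested genes.
#' @param pathways a [pathway_map()].
#' @param padj_threshold enrichment call threshold (default 0.05).
#' @return data.frame with pathway_id, x, n, K, N, p, padj, enriched.
#' @export
hypergeom_enrichment <- function(de_genes, universe, pathways,
                                 padj_threshold = 0.05) {
  if (length(universe) == 0L) stop("empty gene universe")
  if (length(setdiff(de_genes, universe))) stop("de_genes outside the universe")
  N <- length(unique(universe))
  n <- length(unique(de_genes))
  rows <- lapply(names(pathways$sets), function(pw) {
    set <- intersect(pathways$sets[[pw]], universe)
    K <- length(set)
    x <- length(intersect(set, de_genes))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pw, x = x, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$padj < padj_threshold
  out[order(out$p), ]
}

#' One-call differential expression pipeline for one day
#'
#' Size factors (WTSS or library), dispersions, NB GLM Wald tests and LFC
#' shrinkage, for the subset of samples on `day` (all samples when NULL).
#'
#' @param em an [expression_matrix()].
#' @param day optional day to subset.
#' @param normalization `"wtss"` (default) or `"library"`.
#' @inheritParams fit_nb_de
#' @inheritParams shrink_lfc
#' @return a completed `de_result` (with `sf` and `phi` attached).
#' @export
run_de <- function(em, day = NULL, normalization = c("wtss", "library"),
                   design = ~ predation * coevolved_prey,
                   contrast = "predationTRUE:coevolved_preyTRUE",
                   covariate = c("log2_relabund", "none"),
                   adjust_scope = "joint",
                   padj_threshold = 0.1, lfc_threshold = 2) {
  normalization <- match.arg(normalization)
  covariate <- match.arg(covariate)
  if (!is.null(day)) {
    em <- subset_expression(em, samples =
      em$sample_meta$sample_id[em$sample_meta$day == day])
  }
  sf <- if (normalization == "wtss") within_taxon_size_factors(em) else library_size_factors(em)
  phi <- estimate_dispersions(em, sf)
  de <- fit_nb_de(em, sf, phi, design = design, contrast = contrast,
                  covariate = covariate, adjust_scope = adjust_scope)
  de <- shrink_lfc(de, padj_threshold = padj_threshold, lfc_threshold = lfc_threshold)
  de$sf <- sf
  de$phi <- phi
  de
}
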