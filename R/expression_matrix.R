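#' Community expression matrix
#'
#' Gene-by-sample read counts for a multi-species community transcriptome,
#' together with the gene-to-taxon map, the sample metadata of the 2x2
#' factorial design (ciliate predation x focal-prey coevolution, replicated,
#' sampled on several days) and the amplicon-derived taxon relative
#' abundance table used as a model covariate.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param gene_taxon named character vector mapping every gene to one taxon.
#' @param sample_meta data.frame with columns `sample_id`, `predation`
#'   (logical), `coevolved_prey` (logical), `day` (integer), `replicate`.
#' @param taxon_relabund numeric matrix, taxa x samples; columns sum to 1.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_taxon, sample_meta, taxon_relabund) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  gene_taxon <- stats::setNames(as.character(gene_taxon), names(gene_taxon))
  missing_genes <- setdiff(rownames(counts), names(gene_taxon))
  if (length(missing_genes)) {
    stop("gene(s) absent from taxon map: ", paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  gene_taxon <- gene_taxon[rownames(counts)]
  stopifnot(is.data.frame(sample_meta),
            all(c("sample_id", "predation", "coevolved_prey", "day", "replicate")
                %in% names(sample_meta)))
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  sample_meta$predation <- as.logical(sample_meta$predation)
  sample_meta$coevolved_prey <- as.logical(sample_meta$coevolved_prey)
  sample_meta$day <- as.integer(sample_meta$day)
  if (!setequal(sample_meta$sample_id, colnames(counts)) ||
      !setequal(colnames(taxon_relabund), colnames(counts))) {
    off <- unique(c(setdiff(sample_meta$sample_id, colnames(counts)),
                    setdiff(colnames(counts), sample_meta$sample_id),
                    setdiff(colnames(taxon_relabund), colnames(counts)),
                    setdiff(colnames(counts), colnames(taxon_relabund))))
    stop("sample ids do not align across counts/meta/relabund; offenders: ",
         paste(off, collapse = ", "))
  }
  rownames(sample_meta) <- sample_meta$sample_id
  sample_meta <- sample_meta[colnames(counts), , drop = FALSE]
  taxon_relabund <- as.matrix(taxon_relabund)[, colnames(counts), drop = FALSE]
  csums <- colSums(taxon_relabund)
  if (any(abs(csums - 1) > 1e-9)) {
    stop("relative abundance columns must sum to 1; offenders: ",
         paste(colnames(taxon_relabund)[abs(csums - 1) > 1e-9], collapse = ", "))
  }
  missing_taxa <- setdiff(unique(gene_taxon), rownames(taxon_relabund))
  if (length(missing_taxa)) {
    stop("taxon/taxa without relative abundance rows: ",
         paste(missing_taxa, collapse = ", "))
  }
  structure(list(counts = counts, gene_taxon = gene_taxon,
                 sample_meta = sample_meta, taxon_relabund = taxon_relabund),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples, %d taxa, days %s\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$gene_taxon)),
              paste(sort(unique(x$sample_meta$day)), collapse = "/")))
  invisible(x)
}

#' Subset an expression matrix by samples and/or genes
#' @param em an [expression_matrix()].
#' @param samples,genes character vectors (NULL keeps all).
#' @return an [expression_matrix()].
#' @export
subset_expression <- function(em, samples = NULL, genes = NULL) {
  samples <- samples %||% colnames(em$counts)
  genes <- genes %||% rownames(em$counts)
  counts <- em$counts[genes, samples, drop = FALSE]
  rel <- em$taxon_relabund[, samples, drop = FALSE]
  rel <- sweep(rel, 2, colSums(rel), "/")
  expression_matrix(counts, em$gene_taxon[genes],
                    em$sample_meta[samples, , drop = FALSE], rel)
}

#' Read a community expression matrix from four TSV files
#'
#' @param counts_path genes x samples integer TSV (first column `gene_id`).
#' @param taxon_path two-column TSV `gene_id`, `taxon_id`.
#' @param meta_path sample metadata TSV (`sample_id`, `predation`,
#'   `coevolved_prey`, `day`, `replicate`).
#' @param relabund_path taxa x samples TSV of fractions (first column
#'   `taxon_id`); columns must sum to 1.
#' @return an [expression_matrix()].
#' @export
read_count_matrix <- function(counts_path, taxon_path, meta_path, relabund_path) {
  cdf <- read_tsv(counts_path)
  cm <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(cm) <- as.character(cdf[[1]])
  if (any(cm != round(cm))) stop("non-integer count in ", counts_path)
  tdf <- read_tsv(taxon_path)
  gene_taxon <- stats::setNames(as.character(tdf[[2]]), as.character(tdf[[1]]))
  meta <- read_tsv(meta_path)
  rdf <- read_tsv(relabund_path)
  rel <- as.matrix(rdf[, -1, drop = FALSE])
  rownames(rel) <- as.character(rdf[[1]])
  expression_matrix(cm, gene_taxon, meta, rel)
}

#' Write a community expression matrix as four TSV files
#'
#' Inverse of [read_count_matrix()]; the round trip is the identity.
#'
#' @param em an [expression_matrix()].
#' @param counts_path,taxon_path,meta_path,relabund_path output files.
#' @param seed optional seed recorded in the provenance comments.
#' @return invisible list of paths.
#' @export
write_count_matrix <- function(em, counts_path, taxon_path, meta_path,
                               relabund_path, seed = NULL) {
  cmt <- if (!is.null(seed)) sprintf("seed=%d", as.integer(seed))
  write_tsv(data.frame(gene_id = rownames(em$counts), em$counts,
                       check.names = FALSE), counts_path, cmt)
  write_tsv(data.frame(gene_id = names(em$gene_taxon),
                       taxon_id = unname(em$gene_taxon)), taxon_path, cmt)
  write_tsv(em$sample_meta, meta_path, cmt)
  write_tsv(data.frame(taxon_id = rownames(em$taxon_relabund),
                       em$taxon_relabund, check.names = FALSE), relabund_path, cmt)
  invisible(list(counts = counts_path, taxon = taxon_path, meta = meta_path,
                 relabund = relabund_path))
}

#' Pathway map
#'
#' Pathway-to-gene sets for over-representation tests, in the style of KEGG
#' pathway groupings.
#'
#' @param sets named list of character vectors (pathway id -> gene ids).
#' @param names optional named character vector of pathway display names.
#' @param universe optional gene universe; every mapped gene must belong to it.
#' @return object of class `pathway_map`.
#' @export
pathway_map <- function(sets, names = NULL, universe = NULL) {
  stopifnot(is.list(sets), !is.null(base::names(sets)))
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  if (!is.null(universe)) {
    stray <- setdiff(unlist(sets), universe)
    if (length(stray)) stop("pathway genes outside the supplied universe: ",
                            paste(utils::head(stray, 5), collapse = ", "))
  }
  structure(list(sets = sets,
                 names = names %||% stats::setNames(base::names(sets), base::names(sets))),
            class = "pathway_map")
}

#' Read a two-column gene-to-pathway TSV into a pathway map
#' @param path TSV with columns `pathway_id`, `gene_id` (optional `pathway_name`).
#' @param universe optional gene universe for validation.
#' @return a [pathway_map()].
#' @export
read_pathway_map <- function(path, universe = NULL) {
  df <- read_tsv(path)
  sets <- split(as.character(df$gene_id), as.character(df$pathway_id))
  nm <- if ("pathway_name" %in% names(df)) {
    u <- !duplicated(df$pathway_id)
    stats::setNames(as.character(df$pathway_name[u]), as.character(df$pathway_id[u]))
  }
  pathway_map(sets, names = nm, universe = universe)
}
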