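#' Gene catalog
#'
#' A validated container for the gene models of a reference genome: one row
#' per gene with 1-based inclusive coordinates, as in GFF3/VCF. Gene lengths
#' `L_i = end - start + 1` are the basis of the length-normalized null models
#' used by the parallelism statistics.
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (`+`/`-`).
#' @param contig_lengths named integer vector of contig lengths (bp).
#' @param genome_id optional genome label.
#' @return object of class `gene_catalog` with elements `genome_id`,
#'   `contig_lengths`, `genome_length` and `genes` (with a `length` column).
#' @export
gene_catalog <- function(genes, contig_lengths, genome_id = "genome") {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "contig", "start", "end", "strand") %in% names(genes)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$contig <- as.character(genes$contig)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in catalog: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (any(genes$start < 1L)) stop("gene with start < 1")
  if (!all(genes$strand %in% c("+", "-", "*"))) stop("strand must be '+', '-' or '*'")
  contig_lengths <- stats::setNames(as.integer(contig_lengths), names(contig_lengths))
  miss <- setdiff(genes$contig, names(contig_lengths))
  if (length(miss)) stop("genes on contigs without a stated length: ",
                         paste(miss, collapse = ", "))
  over <- genes$end > contig_lengths[genes$contig]
  if (any(over)) stop("gene beyond contig end: ",
                      paste(genes$gene_id[over], collapse = ", "))
  genes$length <- genes$end - genes$start + 1L
  structure(list(genome_id = genome_id,
                 contig_lengths = contig_lengths,
                 genome_length = sum(as.numeric(contig_lengths)),
                 genes = genes[, c("gene_id", "contig", "start", "end",
                                   "strand", "length")]),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog '%s': %d genes on %d contig(s), %.0f bp, mean gene length %.1f bp\n",
              x$genome_id, nrow(x$genes), length(x$contig_lengths),
              x$genome_length, mean(x$genes$length)))
  invisible(x)
}

#' Mean gene length of a catalog
#' @param catalog a [gene_catalog()].
#' @return mean of gene lengths in bp.
#' @export
mean_gene_length <- function(catalog) mean(catalog$genes$length)

## GRanges view of the catalog, for coordinate-overlap queries.
catalog_granges <- function(catalog) {
  g <- catalog$genes
  GenomicRanges::GRanges(seqnames = g$contig,
                         ranges = IRanges::IRanges(start = g$start, end = g$end),
                         gene_id = g$gene_id)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` features (falling back to `CDS` when no `gene` features are
#' present) into a [gene_catalog()]. Gene identifiers are taken from the
#' `ID`, `locus_tag` or `Name` attribute, in that order. Contig lengths come
#' from `##sequence-region` pragmas when present, otherwise from the maximum
#' feature end per contig.
#'
#' @param path GFF3 file.
#' @param feature_type feature types to treat as genes, in preference order.
#' @param genome_id genome label stored in the catalog.
#' @return a [gene_catalog()].
#' @export
read_gene_models <- function(path, feature_type = c("gene", "CDS"),
                             genome_id = basename(path)) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  sel <- NULL
  for (ft in feature_type) {
    sel <- gr[!is.na(S4Vectors::mcols(gr)$type) & S4Vectors::mcols(gr)$type == ft]
    if (length(sel)) break
  }
  if (is.null(sel) || length(sel) == 0L) {
    warning("no ", paste(feature_type, collapse = "/"), " features in '", path,
            "'; returning empty catalog")
    sel <- gr[0]
  }
  mc <- S4Vectors::mcols(sel)
  ids <- as.character(mc$ID %||% rep(NA_character_, length(sel)))
  for (alt in c("locus_tag", "Name")) {
    if (alt %in% names(mc)) ids <- ifelse(is.na(ids), as.character(mc[[alt]]), ids)
  }
  if (length(sel) && anyNA(ids)) stop("GFF3 feature without ID/locus_tag/Name attribute")
  sl <- read_sequence_regions(path)
  contigs <- unique(c(as.character(GenomicRanges::seqnames(sel)), names(sl)))
  clen <- vapply(contigs, function(ct) {
    if (ct %in% names(sl)) return(sl[[ct]])
    hits <- as.character(GenomicRanges::seqnames(gr)) == ct
    if (any(hits)) max(GenomicRanges::end(gr)[hits]) else 0L
  }, integer(1))
  genes <- data.frame(gene_id = ids,
                      contig = as.character(GenomicRanges::seqnames(sel)),
                      start = GenomicRanges::start(sel),
                      end = GenomicRanges::end(sel),
                      strand = as.character(GenomicRanges::strand(sel)),
                      stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "*"
  if (length(clen) == 0L) clen <- c(genome = 0L)
  gene_catalog(genes, clen, genome_id = genome_id)
}

## Contig lengths from ##sequence-region pragmas ("name start end").
read_sequence_regions <- function(path) {
  lines <- grep("^##sequence-region", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(trimws(sub("^##sequence-region\\s+", "", lines)), "\\s+")
  stats::setNames(vapply(parts, function(p) as.integer(p[3]), integer(1)),
                  vapply(parts, `[`, "", 1))
}

#' Write a gene catalog as GFF3
#'
#' @param catalog a [gene_catalog()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(catalog, path) {
  g <- catalog$genes
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ct in names(catalog$contig_lengths)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ct, catalog$contig_lengths[[ct]]), con)
  }
  if (nrow(g)) {
    writeLines(sprintf("%s\tcoevocomm\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig, g$start, g$end,
                       ifelse(g$strand %in% c("+", "-"), g$strand, "."),
                       g$gene_id), con)
  }
  invisible(path)
}
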