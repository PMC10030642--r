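#' Mutation table
#'
#' Per-population variant records with allele frequencies and gene
#' assignments. One row per (population, contig, position, alt allele); a
#' variant overlapping several genes carries all of them in its `gene_ids`
#' list column. Records below a frequency filter are kept at construction:
#' filtering is an explicit pipeline stage ([filter_variants()]).
#'
#' @param records data.frame with columns `population_id`, `contig`,
#'   `position`, `ref_allele`, `alt_allele`, `frequency`, `mutation_class`
#'   and a list column `gene_ids` (character vectors, possibly empty).
#' @return object of class `mutation_table` (a data.frame).
#' @export
mutation_table <- function(records) {
  cols <- c("population_id", "contig", "position", "ref_allele", "alt_allele",
            "frequency", "mutation_class", "gene_ids")
  stopifnot(is.data.frame(records), all(cols %in% names(records)))
  x <- as.data.frame(records, stringsAsFactors = FALSE)[cols]
  x$position <- as.integer(x$position)
  x$frequency <- as.numeric(x$frequency)
  if (!is.list(x$gene_ids)) x$gene_ids <- as.list(as.character(x$gene_ids))
  if (nrow(x)) {
    if (any(!is.finite(x$frequency)) || any(x$frequency <= 0 | x$frequency > 1)) {
      stop("frequencies must lie in (0, 1]")
    }
    if (!all(x$mutation_class %in% c("substitution", "deletion", "insertion"))) {
      stop("mutation_class must be substitution/deletion/insertion")
    }
    key <- paste(x$population_id, x$contig, x$position, x$alt_allele, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate (population, contig, position, alt) record")
  }
  class(x) <- c("mutation_table", "data.frame")
  x
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("mutation_table: %d records, %d population(s)\n",
              nrow(x), length(unique(x$population_id))))
  if (nrow(x)) print.data.frame(utils::head(transform(x, gene_ids =
    vapply(gene_ids, paste, "", collapse = ",")), 6))
  invisible(x)
}

## Classify an allele pair by length arithmetic.
classify_mutation <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "substitution",
         ifelse(nchar(ref) > nchar(alt), "deletion", "insertion"))
}

#' Assign variants to genes by coordinate overlap
#'
#' Each record receives the ids of every catalog gene whose interval
#' (1-based inclusive) contains its position. Records on contigs absent from
#' the catalog keep an empty assignment, with a warning.
#'
#' @param table a [mutation_table()].
#' @param catalog a [gene_catalog()].
#' @return the table with `gene_ids` replaced.
#' @export
assign_genes <- function(table, catalog) {
  if (nrow(table) == 0L) return(table)
  unknown <- setdiff(unique(table$contig), names(catalog$contig_lengths))
  if (length(unknown)) {
    warning("contig(s) absent from catalog, records kept without gene assignment: ",
            paste(unknown, collapse = ", "))
  }
  vr <- GenomicRanges::GRanges(table$contig,
                               IRanges::IRanges(table$position, table$position))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vr, catalog_granges(catalog)))
  ids <- catalog$genes$gene_id
  gl <- split(ids[S4Vectors::subjectHits(hits)],
              factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(table))))
  table$gene_ids <- unname(lapply(gl, function(g) sort(unique(as.character(g)))))
  table
}

#' Read per-population VCFs into a mutation table
#'
#' One VCF per evolved population. Alternative-allele frequency is taken
#' from the `AF` INFO field when present, otherwise derived from the first
#' sample's `AD` allele depths; a record with neither is an error. Gene
#' assignment is by coordinate overlap against `catalog`.
#'
#' @param paths named character vector of VCF paths; names are population ids
#'   (unnamed paths use the file base name).
#' @param catalog a [gene_catalog()] for gene assignment, or NULL to skip.
#' @return a [mutation_table()].
#' @export
read_variant_table <- function(paths, catalog = NULL) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- ifelse(names(paths) %||% rep("", length(paths)) == "",
                           sub("\\.vcf(\\.gz)?$", "", basename(paths)),
                           names(paths))
  }
  recs <- lapply(names(paths), function(pop) {
    v <- vcfR::read.vcfR(paths[[pop]], verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) return(NULL)
    af <- suppressWarnings(vcfR::extract.info(v, "AF", as.numeric = FALSE))
    ad <- if (ncol(v@gt %||% matrix(nrow = 0, ncol = 0)) >= 2L) {
      suppressWarnings(vcfR::extract.gt(v, "AD")[, 1])
    } else rep(NA_character_, nrow(fix))
    out <- lapply(seq_len(nrow(fix)), function(i) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      freq <- if (!is.null(af) && !is.na(af[i])) {
        as.numeric(strsplit(af[i], ",", fixed = TRUE)[[1]])
      } else if (!is.na(ad[i])) {
        d <- as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1]])
        if (sum(d) <= 0) NA_real_ else d[-1] / sum(d)
      } else NA_real_
      if (anyNA(freq)) {
        stop(sprintf("no frequency information (AF or AD) for %s:%s in population '%s'",
                     fix$CHROM[i], fix$POS[i], pop))
      }
      if (length(freq) < length(alts)) freq <- rep_len(freq, length(alts))
      data.frame(population_id = pop, contig = fix$CHROM[i],
                 position = as.integer(fix$POS[i]), ref_allele = fix$REF[i],
                 alt_allele = alts, frequency = freq[seq_along(alts)],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
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
  tab <- mutation_table(recs)
  if (!is.null(catalog)) tab <- assign_genes(tab, catalog)
  tab
}

#' Serialize / restore a mutation table as TSV
#'
#' `gene_ids` are comma-joined; the round trip through
#' [write_mutation_table()] and [read_mutation_table()] is the identity.
#'
#' @param table a [mutation_table()].
#' @param path file path.
#' @param seed optional seed recorded in the provenance comment.
#' @return `path` (write) or a [mutation_table()] (read).
#' @export
write_mutation_table <- function(table, path, seed = NULL) {
  df <- as.data.frame(table)
  df$gene_ids <- vapply(df$gene_ids, paste, "", collapse = ",")
  write_tsv(df, path, comment = if (!is.null(seed)) sprintf("seed=%d", as.integer(seed)))
}

#' @rdname write_mutation_table
#' @export
read_mutation_table <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  df$position <- as.integer(df$position)
  df$frequency <- as.numeric(df$frequency)
  df$gene_ids[is.na(df$gene_ids)] <- ""
  df$gene_ids <- lapply(strsplit(df$gene_ids, ",", fixed = TRUE),
                        function(g) g[nzchar(g)])
  mutation_table(df)
}

#' Write per-population VCF files
#'
#' One minimal VCF 4.2 file per population with the allele frequency in the
#' `AF` INFO field; inverse of [read_variant_table()] for the fields that
#' table carries.
#'
#' @param table a [mutation_table()].
#' @param dir output directory (created if needed).
#' @param contig_lengths optional named contig lengths for the header.
#' @return named vector of paths (by population), invisibly.
#' @export
write_variant_vcf <- function(table, dir, contig_lengths = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pops <- unique(table$population_id)
  paths <- stats::setNames(file.path(dir, paste0(pops, ".vcf")), pops)
  for (pop in pops) {
    x <- table[table$population_id == pop, , drop = FALSE]
    x <- x[order(x$contig, x$position, x$alt_allele), , drop = FALSE]
    con <- file(paths[[pop]], "wt")
    writeLines("##fileformat=VCFv4.2", con)
    for (ct in names(contig_lengths %||% c())) {
      writeLines(sprintf("##contig=<ID=%s,length=%d>", ct, contig_lengths[[ct]]), con)
    }
    writeLines('##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">', con)
    writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
    if (nrow(x)) {
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s", x$contig, x$position,
                         x$ref_allele, x$alt_allele,
                         format(x$frequency, digits = 6, trim = TRUE)), con)
    }
    close(con)
  }
  invisible(paths)
}
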