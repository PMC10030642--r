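#' Pipeline run configuration
#'
#' Validates and completes a configuration for [run_all()]. Defaults follow
#' the analysis conventions used throughout the package: variants kept at or
#' above 20% frequency, parallel-gene FDR 0.05, DE adjusted p < 0.1 with
#' |log2 fold change| > 2, enrichment adjusted p < 0.05, top 500 variable
#' genes per taxon, taxon inclusion above 0.5% of reads in every sample, and
#' a 99% compromise-variance cutoff for PERMANOVA. One global seed drives
#' the run; per-stage seeds are derived deterministically from it and the
#' stage name, so any stage can be reproduced in isolation.
#'
#' @param config named list or path to a YAML file; entries override the
#'   defaults. Recognized groups: `mutation_sim` and `community_sim`
#'   (argument lists for [mutation_sim_spec()] / [community_sim_spec()]),
#'   `thresholds`, `seed`, and optional input paths `inputs$vcfs`,
#'   `inputs$gff`, `inputs$counts`/`taxa`/`meta`/`relabund` to analyze real
#'   data instead of simulating.
#' @return object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  thr <- list(min_freq = 0.2, ancestor_fixed = 0.95, fdr = 0.05,
              de_padj = 0.1, de_lfc = 2, enrich_padj = 0.05, top_n = 500,
              taxon_inclusion = 0.005, variance_cutoff = 0.99,
              null_ensemble_B = 1000, bootstrap_B = 500, perm_B = 999)
  thr[names(config$thresholds %||% list())] <- config$thresholds
  with(thr, stopifnot(min_freq >= 0, min_freq <= 1, fdr > 0, fdr < 1,
                      de_padj > 0, de_padj < 1, de_lfc >= 0,
                      enrich_padj > 0, enrich_padj < 1, top_n >= 1,
                      taxon_inclusion >= 0, taxon_inclusion < 1,
                      variance_cutoff > 0, variance_cutoff <= 1))
  cfg <- list(seed = as.integer(config$seed %||% 1L),
              thresholds = thr,
              mutation_sim = config$mutation_sim %||% list(),
              community_sim = config$community_sim %||% list(),
              inputs = config$inputs %||% NULL)
  if (!is.null(cfg$inputs)) {
    paths <- unlist(cfg$inputs, use.names = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("configured input path(s) do not exist: ",
                              paste(missing, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order: (1) simulate genome and
#' mutations (or read VCF/GFF3 inputs), (2) parallel-evolution detection,
#' (3) simulate the community expression matrix (or read the count TSVs),
#' (4) per-day differential expression with within-taxon sum scaling plus
#' pathway enrichment, (5) per-day rlog, DiSTATIS, clustering and
#' permutation tests. All result tables are written as TSV under `outdir`
#' together with a provenance manifest (`manifest.json`) recording the
#' config hash, seeds, package version and per-stage row counts. Reruns
#' with the same config produce byte-identical outputs.
#'
#' @param config a [run_config()] (or list/path coerced by it).
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly; stage results as attribute `results`.
#' @export
run_all <- function(config = run_config(), outdir = "coevocomm_run") {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  thr <- config$thresholds
  cfg_hash <- fnv_hash(paste(deparse(unclass(config)), collapse = ""))
  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   package_version = as.character(utils::packageVersion("coevocomm")),
                   stages = list())
  log_stage <- function(name, rows) {
    manifest$stages[[name]] <<- list(rows = rows,
                                     seed = derive_seed(config$seed, name))
    message(sprintf("[%s] done (%d rows)", name, rows))
  }
  results <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  ## stage 1: mutation inputs
  mutation_spec <- do.call(mutation_sim_spec,
                           utils::modifyList(list(seed = derive_seed(config$seed, "simulate_genome")),
                                             config$mutation_sim))
  results$catalog <- run_stage("simulate_genome", {
    if (!is.null(config$inputs$gff)) {
      read_gene_models(config$inputs$gff)
    } else {
      simulate_genome(mutation_spec)
    }
  })
  write_gene_models(results$catalog, file.path(outdir, "gene_catalog.gff3"))
  log_stage("simulate_genome", nrow(results$catalog$genes))

  results$mutations <- run_stage("simulate_mutations", {
    if (!is.null(config$inputs$vcfs)) {
      read_variant_table(config$inputs$vcfs, results$catalog)
    } else {
      simulate_mutations(results$catalog, mutation_spec)
    }
  })
  write_mutation_table(results$mutations, file.path(outdir, "mutations.tsv"),
                       seed = config$seed)
  log_stage("simulate_mutations", nrow(results$mutations))

  ## stage 2: parallelism
  results$parallelism <- run_stage("parallelism", {
    filt <- suppressMessages(filter_variants(results$mutations,
                                             min_freq = thr$min_freq,
                                             ancestor_fixed = thr$ancestor_fixed))
    R <- length(unique(results$mutations$population_id))
    site <- identical_site_parallelism(filt, R = max(R, 1))
    gm <- detect_parallel_genes(filt, results$catalog, fdr = thr$fdr,
                                B = thr$null_ensemble_B,
                                seed = derive_seed(config$seed, "parallelism"))
    list(filtered = filt, site = site, genes = gm)
  })
  write_tsv(results$parallelism$site$sites, file.path(outdir, "site_parallelism.tsv"))
  write_tsv(results$parallelism$genes$genes, file.path(outdir, "gene_multiplicity.tsv"))
  jsonlite::write_json(list(n_tot = results$parallelism$genes$n_tot,
                            delta_l = results$parallelism$genes$delta_l_total,
                            p_star = results$parallelism$genes$p_star,
                            N_k = as.list(results$parallelism$site$N_k),
                            seed = derive_seed(config$seed, "parallelism")),
                       file.path(outdir, "parallelism_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("parallelism", nrow(results$parallelism$genes$genes))

  ## stage 3: community expression
  results$em <- run_stage("simulate_community", {
    if (!is.null(config$inputs$counts)) {
      read_count_matrix(config$inputs$counts, config$inputs$taxa,
                        config$inputs$meta, config$inputs$relabund)
    } else {
      cs <- do.call(community_sim_spec,
                    utils::modifyList(list(seed = derive_seed(config$seed, "simulate_community")),
                                      config$community_sim))
      simulate_community(cs)
    }
  })
  write_count_matrix(results$em,
                     file.path(outdir, "counts.tsv"), file.path(outdir, "gene_taxa.tsv"),
                     file.path(outdir, "sample_meta.tsv"), file.path(outdir, "relabund.tsv"),
                     seed = config$seed)
  log_stage("simulate_community", nrow(results$em$counts))

  ## stages 4-5 run per day
  days <- sort(unique(results$em$sample_meta$day))
  results$de <- list()
  results$distatis <- list()
  de_rows <- 0; ord_rows <- 0
  for (d in days) {
    tag <- sprintf("day%d", d)
    de <- run_stage("de", {
      keep_taxa <- taxon_inclusion(results$em, thr$taxon_inclusion)
      emd <- subset_expression(results$em,
        samples = results$em$sample_meta$sample_id[results$em$sample_meta$day == d],
        genes = names(results$em$gene_taxon)[results$em$gene_taxon %in% keep_taxa])
      run_de(emd, padj_threshold = thr$de_padj, lfc_threshold = thr$de_lfc)
    })
    results$de[[tag]] <- de
    write_tsv(de$table, file.path(outdir, sprintf("de_results_%s.tsv", tag)))
    write_tsv(data.frame(taxon = rownames(de$sf$sf), de$sf$sf, check.names = FALSE),
              file.path(outdir, sprintf("size_factors_%s.tsv", tag)))
    de_rows <- de_rows + nrow(de$table)

    enr <- run_stage("enrichment", {
      universe <- de$table$gene_id[de$table$converged]
      pw <- simulate_pathways(universe, seed = derive_seed(config$seed, "pathways"))
      hypergeom_enrichment(de$table$gene_id[de$table$de & de$table$converged],
                           universe, pw, padj_threshold = thr$enrich_padj)
    })
    write_tsv(enr, file.path(outdir, sprintf("enrichment_%s.tsv", tag)))

    ord <- run_stage("distatis", {
      emd <- subset_expression(results$em,
        samples = results$em$sample_meta$sample_id[results$em$sample_meta$day == d])
      rl <- rlog_transform(emd, de$sf, de$phi)
      sets <- suppressWarnings(select_top_variable(rl, emd, n = thr$top_n))
      dset <- expression_distances(rl, sets)
      res <- distatis(dset)
      nd <- nrow(res$F)
      cl <- kmeans_kl(res$F[, seq_len(min(3, ncol(res$F))), drop = FALSE],
                      k_range = 2:max(2, min(6, nd - 2)),
                      seed = derive_seed(config$seed, paste0("kmeans-", tag)))
      meta <- emd$sample_meta[rownames(res$F), ]
      grp <- paste0("P", meta$predation, "_C", meta$coevolved_prey)
      pmv <- permanova(res, grp, B = thr$perm_B,
                       seed = derive_seed(config$seed, paste0("permanova-", tag)),
                       variance_cutoff = thr$variance_cutoff)
      pdp <- permdisp(res, grp, B = thr$perm_B,
                      seed = derive_seed(config$seed, paste0("permdisp-", tag)))
      boot <- bootstrap_compromise(res, B = thr$bootstrap_B,
                                   seed = derive_seed(config$seed, paste0("boot-", tag)))
      list(rlog = rl, distatis = res, clusters = cl, permanova = pmv,
           permdisp = pdp, ellipses = boot$ellipses)
    })
    results$distatis[[tag]] <- ord
    write_tsv(data.frame(sample = rownames(ord$distatis$F), ord$distatis$F,
                         cluster = ord$clusters$labels, check.names = FALSE),
              file.path(outdir, sprintf("compromise_scores_%s.tsv", tag)))
    write_tsv(data.frame(table = names(ord$distatis$alpha),
                         alpha = unname(ord$distatis$alpha)),
              file.path(outdir, sprintf("alpha_%s.tsv", tag)))
    write_tsv(ord$ellipses, file.path(outdir, sprintf("ellipses_%s.tsv", tag)))
    write_tsv(data.frame(test = c("permanova", "permdisp"),
                         F = c(ord$permanova$F, ord$permdisp$F),
                         p = c(ord$permanova$p, ord$permdisp$p),
                         tau1 = ord$distatis$tau[1],
                         k = ord$clusters$k),
              file.path(outdir, sprintf("permtests_%s.tsv", tag)))
    ord_rows <- ord_rows + nrow(ord$distatis$F)
  }
  log_stage("de", de_rows)
  log_stage("distatis", ord_rows)

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- manifest
  attr(out, "results") <- results
  invisible(out)
}
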