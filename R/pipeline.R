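# End-to-end orchestration of the simulated pipeline: cohort simulation and
# burden testing; reporter-ion simulation, quantification, significance
# calling and Venn separation; enrichment of the common core; semantic
# scoring of the unique sets; qPCR expression statistics. Artifacts land in
# a plain directory with a JSON manifest.

#' Pipeline configuration
#'
#' Bundles the cross-stage constants. The defaults are the analysis
#' cut-offs used throughout the package: significance at 2 SD, enrichment
#' requiring at least 2 proteins at P <= 0.05, and the 0.1 cosine
#' implicit-association threshold.
#'
#' @param z_threshold Differential-call limit in SD units.
#' @param min_k,alpha Enrichment filters.
#' @param cosine_threshold Minimum qualifying gene-term cosine.
#' @param latent_dim LSI dimensionality cap.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param cohort,itraq Optional stage configs (defaults generated from
#'   \code{seed}).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(z_threshold = 2, min_k = 2, alpha = 0.05,
                            cosine_threshold = 0.1, latent_dim = 100,
                            seed = 1L, cohort = NULL, itraq = NULL) {
  seed <- as.integer(seed)
  # distinct, stable sub-seeds below 2^31
  sub <- (seed * 7919L + c(1L, 2L, 3L, 4L, 5L)) %% .Machine$integer.max
  if (is.null(cohort)) cohort <- cohort_sim_config(seed = sub[1])
  if (is.null(itraq)) {
    itraq <- itraq_sim_config(
      n_proteins = 300, psms_per_protein = 3,
      planted_common = 1:20, common_effect = 2,
      planted_unique = list(FLNC = 21:35, GRN = 36:50, VCP = 51:65),
      unique_effect = 2, planted_contra = 66:75, contra_effect = 2,
      noise_sd = 0.2, missing_rate = 0.05, seed = sub[2])
  }
  structure(list(z_threshold = z_threshold, min_k = min_k, alpha = alpha,
                 cosine_threshold = cosine_threshold,
                 latent_dim = latent_dim, seed = seed,
                 corpus_seed = sub[3], genesets_seed = sub[4],
                 qpcr_seed = sub[5], cohort = cohort, itraq = itraq),
            class = "pipeline_config")
}

#' Run the simulated pipeline end to end
#'
#' Executes the stages in dependency order on fully simulated inputs and
#' writes each stage's artifact (TSV/JSON) plus a reproducibility manifest
#' to \code{out_dir}. Reruns with the same configuration produce identical
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- burden stage -----------------------------------------------------
  cohort <- simulate_cohort(config$cohort)
  write_tsv(cohort, file.path(out_dir, "cohort_variants.tsv"))
  carriers <- collapse_carriers(cohort, band = "rare",
                                n_controls = config$cohort$n_controls)
  burden <- burden_test(carriers[["case_carriers"]], config$cohort$n_cases,
                        carriers[["control_carriers"]],
                        config$cohort$n_controls)
  write_burden_json(burden, file.path(out_dir, "burden.json"))

  # -- proteomics stage -------------------------------------------------
  sim <- simulate_itraq(config$itraq)
  write_tsv(sim$psms, file.path(out_dir, "psms.tsv"))
  write_channel_design(config$itraq$design, file.path(out_dir, "design.json"))
  quants <- quantify_proteins(filter_psms(sim$psms, config$itraq$design),
                              config$itraq$design)
  called <- call_differential(quants, z_threshold = config$z_threshold)
  write_quants(called, file.path(out_dir, "protein_quants.tsv"))
  part <- venn_partition(significant_sets(called))
  write_partition_json(part, file.path(out_dir, "venn_partition.json"))
  core <- common_coherent(part)
  uniq <- unique_sets(part)

  # -- enrichment stage (background = all quantified proteins) ----------
  background <- unique(quants$protein)
  enrichment <- empty_enrichment()
  if (nrow(core) >= config$min_k) {
    sets <- simulate_genesets(background, core$protein,
                              seed = config$genesets_seed)
    write_gmt(sets, file.path(out_dir, "genesets.gmt"))
    enrichment <- enrich(core$protein, background, sets,
                         min_k = config$min_k, alpha = config$alpha)
  }
  utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- semantic stage: score unique sets against interrogation terms ----
  terms <- c("neurodegeneration", "dementia", "frontotemporal", "aging")
  flnc_genes <- uniq[["FLNC"]]$protein
  planted <- if (length(flnc_genes)) {
    do.call(rbind, lapply(terms, function(tm) {
      data.frame(gene = flnc_genes, term = tm, rate = 0.6,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  all_genes <- unique(unlist(lapply(uniq, `[[`, "protein")))
  semantic <- NULL
  if (length(all_genes)) {
    corpus_cfg <- corpus_sim_config(
      n_documents = max(120L, 4L * length(all_genes)), genes = all_genes,
      vocabulary = c(terms, sprintf("filler%02d", 1:20)),
      planted_links = planted, background_rate = 0.05,
      seed = config$corpus_seed)
    corpus <- simulate_corpus(corpus_cfg)
    write_corpus(corpus, file.path(out_dir, "corpus.jsonl"))
    model <- build_lsi(corpus, latent_dim = config$latent_dim)
    semantic <- do.call(rbind, lapply(names(uniq), function(ds) {
      genes <- uniq[[ds]]$protein
      if (!length(genes)) return(NULL)
      sc <- dataset_score(model, genes, terms,
                          cosine_threshold = config$cosine_threshold,
                          dataset_id = ds)
      cbind(sc$per_term, combined_score = sc$combined_score)
    }))
    utils::write.table(semantic, file.path(out_dir, "semantic_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- expression stage -------------------------------------------------
  ct <- simulate_qpcr(seed = config$qpcr_seed)
  write_tsv(ct, file.path(out_dir, "ct_table.tsv"))
  levels <- normalize_expression(ct, targets = c("FLNC_long", "FLNC_short"))
  groups <- unique(levels$group)
  expression <- do.call(rbind, lapply(unique(levels$gene), function(g) {
    va <- levels$level[levels$gene == g & levels$group == groups[1]]
    vb <- levels$level[levels$gene == g & levels$group == groups[2]]
    cmp <- group_compare(va, vb)
    data.frame(gene = g, fold_change = mean(vb) / mean(va),
               p_value = cmp$p_value, stars = cmp$stars,
               method = cmp$method, stringsAsFactors = FALSE)
  }))
  utils::write.table(expression, file.path(out_dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "ftdconv",
    version = as.character(utils::packageVersion("ftdconv")),
    seed = config$seed,
    parameters = list(z_threshold = config$z_threshold, min_k = config$min_k,
                      alpha = config$alpha,
                      cosine_threshold = config$cosine_threshold,
                      latent_dim = config$latent_dim),
    cohort = unclass(config$cohort),
    itraq_n_proteins = config$itraq$n_proteins,
    artifacts = sort(list.files(out_dir))
  )
  manifest$artifacts <- sort(c(manifest$artifacts, "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(burden = burden, quants = called, partition = part,
                 common_core = core, unique_sets = uniq,
                 enrichment = enrichment, semantic = semantic,
                 expression = expression, manifest = manifest))
}
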