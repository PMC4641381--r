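# Seeded generators for every input the pipeline consumes: cohort variant
# tables, 8-plex reporter-ion PSM tables, gene-linked literature corpora,
# gene-set (GMT) annotations and qPCR Ct tables. All generators draw from
# R's default Mersenne-Twister stream via an isolated seed so identical
# configurations reproduce identical outputs.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single value in [0, 1]", call. = FALSE)
  }
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop("`", name, "` must be a positive integer", call. = FALSE)
  }
}

#' Configuration for the cohort variant-table simulator
#'
#' @param n_cases,n_controls Cohort sizes (defaults match a mid-size
#'   case-control resequencing study: 529 patients, 920 controls).
#' @param carrier_freq_cases,carrier_freq_controls Probability that an
#'   individual carries at least one rare variant (defaults 0.113 / 0.079).
#' @param n_genes Number of genes across which variants are scattered.
#' @param multi_variant_rate Fraction of control carriers given 2-3 distinct
#'   variants, exercising the carrier-collapsing rule.
#' @param seed Integer seed.
#' @return A \code{cohort_sim_config} list.
#' @export
cohort_sim_config <- function(n_cases = 529, n_controls = 920,
                              carrier_freq_cases = 0.113,
                              carrier_freq_controls = 0.079,
                              n_genes = 1, multi_variant_rate = 0.03,
                              seed = 1L) {
  check_count(n_cases, "n_cases"); check_count(n_controls, "n_controls")
  check_prob(carrier_freq_cases, "carrier_freq_cases")
  check_prob(carrier_freq_controls, "carrier_freq_controls")
  check_count(n_genes, "n_genes")
  check_prob(multi_variant_rate, "multi_variant_rate")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 carrier_freq_cases = carrier_freq_cases,
                 carrier_freq_controls = carrier_freq_controls,
                 n_genes = as.integer(n_genes),
                 multi_variant_rate = multi_variant_rate,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a cohort variant table
#'
#' Each individual independently carries at least one rare variant with the
#' configured cohort frequency; carriers are heterozygous (one mutated allele
#' each). A configured fraction of control carriers receives 2-3 distinct
#' variants so that carrier collapsing is exercised. Variant ids are drawn
#' from a large pool so per-variant counts stay rare; each variant's MAF is
#' computed from its simulated allele count over all \code{2 * (n_cases +
#' n_controls)} chromosomes.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A variant observation \code{data.frame} (columns
#'   \code{individual_id}, \code{cohort}, \code{gene}, \code{variant_id},
#'   \code{maf}, \code{domain}) with attribute \code{truth}: a list with the
#'   carrier id vectors \code{case_carriers} and \code{control_carriers}.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(cfg$seed, {
    pool_size <- max(500L, 20L * cfg$n_genes)
    pool_gene <- sprintf("GENE%02d", 1 + (seq_len(pool_size) - 1L) %% cfg$n_genes)
    pool_id <- sprintf("p.V%dI", 100L + seq_len(pool_size))
    pool_domain <- sprintf("Ig %d", 1 + (seq_len(pool_size) - 1L) %% 24L)

    case_ids <- sprintf("CASE%04d", seq_len(cfg$n_cases))
    ctrl_ids <- sprintf("CTRL%04d", seq_len(cfg$n_controls))
    case_carrier <- case_ids[stats::runif(cfg$n_cases) < cfg$carrier_freq_cases]
    ctrl_carrier <- ctrl_ids[stats::runif(cfg$n_controls) < cfg$carrier_freq_controls]

    n_var_case <- rep(1L, length(case_carrier))
    multi <- stats::runif(length(ctrl_carrier)) < cfg$multi_variant_rate
    n_var_ctrl <- ifelse(multi, sample(2:3, length(ctrl_carrier), replace = TRUE), 1L)

    mk_rows <- function(ids, nvar, cohort) {
      if (!length(ids)) {
        return(data.frame(individual_id = character(), cohort = character(),
                          gene = character(), variant_id = character(),
                          domain = character(), stringsAsFactors = FALSE))
      }
      idx <- unlist(lapply(nvar, function(k) sample.int(pool_size, k)))
      data.frame(individual_id = rep(ids, nvar), cohort = cohort,
                 gene = pool_gene[idx], variant_id = pool_id[idx],
                 domain = pool_domain[idx], stringsAsFactors = FALSE)
    }
    df <- rbind(mk_rows(case_carrier, n_var_case, "patient"),
                mk_rows(ctrl_carrier, n_var_ctrl, "control"))
    allele_counts <- table(df$variant_id)
    total_chrom <- 2 * (cfg$n_cases + cfg$n_controls)
    df$maf <- as.numeric(allele_counts[df$variant_id]) / total_chrom
    df <- df[, c("individual_id", "cohort", "gene", "variant_id", "maf", "domain")]
    rownames(df) <- NULL
    attr(df, "truth") <- list(case_carriers = case_carrier,
                              control_carriers = ctrl_carrier)
    df
  })
}

#' Configuration for the 8-plex reporter-ion PSM simulator
#'
#' Planted effect sets must be disjoint; effects are in log2 units.
#' \code{planted_common} proteins receive the same effect in every non-control
#' comparison; \code{planted_unique} is a named list (one entry per
#' comparison group) of protein index vectors; \code{planted_contra} proteins
#' get \code{+effect} in the first non-control group and \code{-effect} in
#' the others.
#'
#' @param design A [channel_design()] (default: the 3-control / 1-FLNC /
#'   2-GRN / 2-VCP layout).
#' @param n_proteins,psms_per_protein Problem size.
#' @param planted_common Integer vector of protein indices.
#' @param common_effect Signed log2 effect for the common set (default +2).
#' @param planted_unique Named list of index vectors, names = non-control
#'   groups.
#' @param unique_effect Signed log2 effect for unique sets (default +2).
#' @param planted_contra Integer vector of protein indices.
#' @param contra_effect Magnitude of the opposed log2 effects (default 2).
#' @param noise_sd Lognormal reporter noise, in log2 units (> 0).
#' @param missing_rate Fraction of PSMs with one channel knocked out
#'   (missing-completely-at-random).
#' @param seed Integer seed.
#' @return An \code{itraq_sim_config} list.
#' @export
itraq_sim_config <- function(design = channel_design(), n_proteins = 200,
                             psms_per_protein = 3,
                             planted_common = integer(), common_effect = 2,
                             planted_unique = list(), unique_effect = 2,
                             planted_contra = integer(), contra_effect = 2,
                             noise_sd = 0.2, missing_rate = 0,
                             seed = 1L) {
  stopifnot(inherits(design, "channel_design"))
  check_count(n_proteins, "n_proteins")
  check_count(psms_per_protein, "psms_per_protein")
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be > 0", call. = FALSE)
  }
  check_prob(missing_rate, "missing_rate")
  groups <- setdiff(unique(design$group_of), "control")
  if (length(planted_unique)) {
    if (is.null(names(planted_unique)) ||
        !all(names(planted_unique) %in% groups)) {
      stop("`planted_unique` must be named by non-control groups", call. = FALSE)
    }
  }
  all_planted <- c(planted_common, unlist(planted_unique, use.names = FALSE),
                   planted_contra)
  if (anyDuplicated(all_planted)) {
    stop("planted protein sets must be disjoint", call. = FALSE)
  }
  if (length(all_planted) && max(all_planted) > n_proteins) {
    stop("planted protein index exceeds `n_proteins`", call. = FALSE)
  }
  structure(list(design = design, n_proteins = as.integer(n_proteins),
                 psms_per_protein = as.integer(psms_per_protein),
                 planted_common = as.integer(planted_common),
                 common_effect = common_effect,
                 planted_unique = lapply(planted_unique, as.integer),
                 unique_effect = unique_effect,
                 planted_contra = as.integer(planted_contra),
                 contra_effect = contra_effect,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "itraq_sim_config")
}

#' Simulate an 8-plex reporter-ion PSM table with planted effects
#'
#' Reporter intensities are lognormal around protein-by-channel means: a
#' baseline protein abundance, multiplied by \code{2^effect} in channels
#' whose group carries a planted effect, times multiplicative noise with the
#' configured log2 standard deviation. Optionally one channel per PSM is
#' knocked out at random to exercise the eight-channel completeness filter.
#'
#' @param cfg An [itraq_sim_config()].
#' @return List with \code{psms} (a PSM \code{data.frame}: \code{peptide},
#'   \code{protein}, one intensity column per channel) and \code{truth} (a
#'   \code{data.frame} with \code{protein}, \code{class} in
#'   \code{none/common/unique/contra}, \code{group} and per-group log2
#'   effects).
#' @export
simulate_itraq <- function(cfg) {
  stopifnot(inherits(cfg, "itraq_sim_config"))
  design <- cfg$design
  if (length(design$channels) != 8L) {
    stop("design must have exactly 8 channels", call. = FALSE)
  }
  groups <- setdiff(unique(design$group_of), "control")
  with_seed(cfg$seed, {
    proteins <- sprintf("PROT%04d", seq_len(cfg$n_proteins))
    # per-protein, per-group log2 effect matrix
    eff <- matrix(0, cfg$n_proteins, length(groups),
                  dimnames = list(proteins, groups))
    class_of <- rep("none", cfg$n_proteins)
    if (length(cfg$planted_common)) {
      eff[cfg$planted_common, ] <- cfg$common_effect
      class_of[cfg$planted_common] <- "common"
    }
    for (g in names(cfg$planted_unique)) {
      idx <- cfg$planted_unique[[g]]
      eff[idx, g] <- cfg$unique_effect
      class_of[idx] <- "unique"
    }
    if (length(cfg$planted_contra)) {
      eff[cfg$planted_contra, 1] <- cfg$contra_effect
      eff[cfg$planted_contra, -1] <- -cfg$contra_effect
      class_of[cfg$planted_contra] <- "contra"
    }
    unique_group <- rep(NA_character_, cfg$n_proteins)
    for (g in names(cfg$planted_unique)) unique_group[cfg$planted_unique[[g]]] <- g

    n_psm <- cfg$n_proteins * cfg$psms_per_protein
    prot_idx <- rep(seq_len(cfg$n_proteins), each = cfg$psms_per_protein)
    base <- 2^stats::rnorm(n_psm, mean = 14, sd = 1)  # PSM-level abundance

    ch <- design$channels
    grp <- design$group_of
    inten <- matrix(NA_real_, n_psm, 8, dimnames = list(NULL, paste0("i", ch)))
    ln2sd <- cfg$noise_sd  # noise sd stated in log2 units
    for (j in seq_along(ch)) {
      g <- grp[j]
      shift <- if (g == "control") 0 else eff[prot_idx, g]
      inten[, j] <- base * 2^(shift + stats::rnorm(n_psm, 0, ln2sd))
    }
    if (cfg$missing_rate > 0) {
      knock <- stats::runif(n_psm) < cfg$missing_rate
      drop_ch <- sample.int(8, n_psm, replace = TRUE)
      inten[cbind(which(knock), drop_ch[knock])] <- NA_real_
    }
    psms <- data.frame(peptide = sprintf("PEP%06d", seq_len(n_psm)),
                       protein = proteins[prot_idx], stringsAsFactors = FALSE)
    psms <- cbind(psms, as.data.frame(inten))
    truth <- data.frame(protein = proteins, class = class_of,
                        group = unique_group, stringsAsFactors = FALSE)
    truth <- cbind(truth, as.data.frame(eff))
    list(psms = psms, truth = truth)
  })
}

#' Configuration for the gene-linked corpus simulator
#'
#' @param n_documents Number of documents (each linked to one gene).
#' @param genes Gene symbols to cycle documents over.
#' @param vocabulary Non-empty character vector of background terms.
#' @param planted_links \code{data.frame} with columns \code{gene},
#'   \code{term}, \code{rate}: per-document probability that \code{term}
#'   occurs in documents linked to \code{gene}.
#' @param background_rate Per-document probability of any vocabulary term
#'   occurring by chance; must be below every planted rate.
#' @param seed Integer seed.
#' @return A \code{corpus_sim_config} list.
#' @export
corpus_sim_config <- function(n_documents = 200,
                              genes = sprintf("GENE%02d", 1:10),
                              vocabulary = sprintf("term%02d", 1:40),
                              planted_links = NULL,
                              background_rate = 0.05, seed = 1L) {
  check_count(n_documents, "n_documents")
  if (!length(vocabulary)) stop("`vocabulary` must be non-empty", call. = FALSE)
  check_prob(background_rate, "background_rate")
  if (!is.null(planted_links)) {
    stopifnot(is.data.frame(planted_links),
              all(c("gene", "term", "rate") %in% names(planted_links)))
    if (any(planted_links$rate <= background_rate)) {
      stop("planted co-occurrence rates must exceed `background_rate`",
           call. = FALSE)
    }
  }
  structure(list(n_documents = as.integer(n_documents), genes = genes,
                 vocabulary = vocabulary, planted_links = planted_links,
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "corpus_sim_config")
}

#' Simulate a gene-linked document corpus
#'
#' Documents are bags of terms. Every document is linked to one gene (cycled
#' over \code{genes}) and always contains that gene's symbol as a token; each
#' vocabulary term occurs with \code{background_rate}, raised to the planted
#' rate for (gene, term) pairs in \code{planted_links}.
#'
#' @param cfg A [corpus_sim_config()].
#' @return \code{data.frame} with columns \code{doc_id}, \code{text},
#'   \code{genes} (list column of linked symbols).
#' @export
simulate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "corpus_sim_config"))
  with_seed(cfg$seed, {
    gene_of <- rep_len(cfg$genes, cfg$n_documents)
    docs <- character(cfg$n_documents)
    for (i in seq_len(cfg$n_documents)) {
      rate <- rep(cfg$background_rate, length(cfg$vocabulary))
      names(rate) <- cfg$vocabulary
      pl <- cfg$planted_links
      if (!is.null(pl)) {
        hit <- pl$gene == gene_of[i] & pl$term %in% cfg$vocabulary
        rate[pl$term[hit]] <- pl$rate[hit]
      }
      present <- cfg$vocabulary[stats::runif(length(rate)) < rate]
      docs[i] <- paste(c(tolower(gene_of[i]), present), collapse = " ")
    }
    out <- data.frame(doc_id = sprintf("DOC%05d", seq_len(cfg$n_documents)),
                      text = docs, stringsAsFactors = FALSE)
    out$genes <- as.list(gene_of)
    out
  })
}

#' Simulate a gene-set (GMT) annotation with one planted enriched term
#'
#' Background genes are partitioned into random sets; one extra planted term
#' is built to overlap a designated query heavily (emulating a genuinely
#' enriched pathway).
#'
#' @param background Character vector of background gene symbols.
#' @param query Character vector, subset of \code{background}; genes the
#'   planted term should hit.
#' @param n_sets Number of random decoy sets.
#' @param set_size Size of each decoy set.
#' @param planted_hits How many query genes the planted term contains.
#' @param planted_size Total size of the planted term.
#' @param seed Integer seed.
#' @return Named list of gene vectors (names = term ids); the planted term is
#'   \code{"PLANTED_TERM"}.
#' @export
simulate_genesets <- function(background, query, n_sets = 20, set_size = 15,
                              planted_hits = min(8L, length(query)),
                              planted_size = max(planted_hits, 10L),
                              seed = 1L) {
  stopifnot(all(query %in% background))
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      sample(background, min(set_size, length(background)))
    })
    names(sets) <- sprintf("DECOY_%03d", seq_len(n_sets))
    planted <- c(sample(query, planted_hits),
                 sample(setdiff(background, query),
                        planted_size - planted_hits))
    sets$PLANTED_TERM <- planted
    sets
  })
}

#' Simulate a qPCR Ct table with a group effect on target genes
#'
#' Housekeeping genes are flat across groups; target genes shift Ct by
#' \code{-log2(fold_change)} cycles (per doubling-efficiency convention) in
#' the affected group. Measurements come in duplicate with Gaussian technical
#' noise on the cycle scale.
#'
#' @param n_per_group Samples per group.
#' @param groups Two group labels (second group carries the effect).
#' @param targets Target gene names.
#' @param housekeeping Housekeeping gene names.
#' @param fold_change Expression fold change of targets in the second group.
#' @param ct_sd Technical noise SD in cycles.
#' @param seed Integer seed.
#' @return \code{data.frame} with columns \code{sample_id}, \code{group},
#'   \code{gene}, \code{replicate}, \code{ct}.
#' @export
simulate_qpcr <- function(n_per_group = 6, groups = c("control", "carrier"),
                          targets = c("FLNC_long", "FLNC_short"),
                          housekeeping = c("GAPDH", "ACTB"),
                          fold_change = 4, ct_sd = 0.15, seed = 1L) {
  stopifnot(length(groups) == 2L, fold_change > 0)
  with_seed(seed, {
    samples <- data.frame(
      sample_id = sprintf("S%03d", seq_len(2 * n_per_group)),
      group = rep(groups, each = n_per_group), stringsAsFactors = FALSE)
    genes <- c(targets, housekeeping)
    base_ct <- stats::setNames(stats::runif(length(genes), 20, 26), genes)
    rows <- expand.grid(sample_id = samples$sample_id, gene = genes,
                        replicate = 1:2, stringsAsFactors = FALSE)
    rows$group <- samples$group[match(rows$sample_id, samples$sample_id)]
    shift <- ifelse(rows$gene %in% targets & rows$group == groups[2],
                    -log2(fold_change), 0)
    rows$ct <- base_ct[rows$gene] + shift + stats::rnorm(nrow(rows), 0, ct_sd)
    rows[, c("sample_id", "group", "gene", "replicate", "ct")]
  })
}

#' Write a variant table, PSM table or Ct table as TSV
#'
#' @param df Data frame to write (list columns are collapsed with commas).
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  flat <- df
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ",")
    }
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-linked corpus as JSON lines
#'
#' One JSON object per line: \code{\{"doc_id": ..., "text": ...,
#' "genes": [...]\}}.
#'
#' @param corpus Corpus \code{data.frame} (see [simulate_corpus()]).
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(doc_id = jsonlite::unbox(corpus$doc_id[i]),
                          text = jsonlite::unbox(corpus$text[i]),
                          genes = unlist(corpus$genes[i])))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-linked corpus from JSON lines
#'
#' @param path Path to a JSON-lines corpus file.
#' @return Corpus \code{data.frame} with a \code{genes} list column.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(doc_id = vapply(recs, `[[`, character(1), "doc_id"),
             text = vapply(recs, `[[`, character(1), "text"),
             genes = I(lapply(recs, function(r) as.character(r$genes))),
             stringsAsFactors = FALSE)
}
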