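# Generators: seeded determinism, degenerate configurations, convergence of
# marginal frequencies, and consistency of truth labels with generated data.

test_that("generators are byte-identical under a fixed seed", {
  cfg <- cohort_sim_config(n_cases = 50, n_controls = 80, seed = 42L)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))

  icfg <- itraq_sim_config(n_proteins = 20, psms_per_protein = 2,
                           planted_common = 1:2, seed = 42L)
  expect_identical(simulate_itraq(icfg), simulate_itraq(icfg))

  ccfg <- corpus_sim_config(n_documents = 30, seed = 42L)
  expect_identical(simulate_corpus(ccfg), simulate_corpus(ccfg))

  expect_identical(simulate_qpcr(seed = 9L), simulate_qpcr(seed = 9L))
  expect_identical(simulate_genesets(letters, letters[1:5], seed = 3L),
                   simulate_genesets(letters, letters[1:5], seed = 3L))
})

test_that("degenerate rates behave as configured", {
  cfg <- cohort_sim_config(n_cases = 40, n_controls = 40,
                           carrier_freq_cases = 0,
                           carrier_freq_controls = 0.5, seed = 1L)
  tab <- simulate_cohort(cfg)
  expect_equal(sum(tab$cohort == "patient"), 0)
  expect_gt(sum(tab$cohort == "control"), 0)

  # background 0 with one planted pair: term occurs only in that gene's docs
  pl <- data.frame(gene = "GENE01", term = "term07", rate = 0.9,
                   stringsAsFactors = FALSE)
  ccfg <- corpus_sim_config(n_documents = 60, background_rate = 0,
                            planted_links = pl, seed = 5L)
  corpus <- simulate_corpus(ccfg)
  has_term <- grepl("\\bterm07\\b", corpus$text)
  linked <- vapply(corpus$genes, function(g) "GENE01" %in% g, logical(1))
  expect_true(all(linked[has_term]))
  expect_gt(sum(has_term), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_sim_config(carrier_freq_cases = 1.2), "\\[0, 1\\]")
  expect_error(cohort_sim_config(n_cases = 0), "positive integer")
  expect_error(itraq_sim_config(noise_sd = 0), "noise_sd")
  expect_error(itraq_sim_config(planted_common = 1:3,
                                planted_contra = 3:4), "disjoint")
  expect_error(itraq_sim_config(n_proteins = 5, planted_common = 6),
               "exceeds")
  expect_error(corpus_sim_config(vocabulary = character()), "non-empty")
  expect_error(
    corpus_sim_config(planted_links = data.frame(
      gene = "G", term = "t", rate = 0.01), background_rate = 0.05),
    "exceed")
})

test_that("case carrier frequency converges to the configured rate", {
  # 500 replicates at the default cohort regime; the replicate-mean carrier
  # frequency must sit within 3 binomial standard errors of 0.113.
  p <- 0.113; n <- 529; reps <- 500
  freqs <- vapply(seq_len(reps), function(i) {
    cfg <- cohort_sim_config(seed = 1000L + i)
    tab <- simulate_cohort(cfg)
    length(unique(tab$individual_id[tab$cohort == "patient"])) / n
  }, numeric(1))
  se_mean <- sqrt(p * (1 - p) / (n * reps))
  expect_lt(abs(mean(freqs) - p), 3 * se_mean)
})

test_that("reporter simulation obeys the null, planted and missingness models", {
  # null: expected log2 ratios ~ 0
  null_cfg <- itraq_sim_config(n_proteins = 300, psms_per_protein = 2,
                               noise_sd = 0.2, seed = 11L)
  sim <- simulate_itraq(null_cfg)
  q <- quantify_proteins(filter_psms(sim$psms, null_cfg$design),
                         null_cfg$design)
  se <- sd(q$log2_ratio) / sqrt(nrow(q))
  expect_lt(abs(mean(q$log2_ratio)), 3 * se)

  # planted +2 common effect recovered within 0.2 on average (>= 100 proteins)
  pl_cfg <- itraq_sim_config(n_proteins = 150, psms_per_protein = 3,
                             planted_common = 1:120, common_effect = 2,
                             noise_sd = 0.2, seed = 12L)
  sim2 <- simulate_itraq(pl_cfg)
  q2 <- quantify_proteins(filter_psms(sim2$psms, pl_cfg$design),
                          pl_cfg$design)
  planted <- sim2$truth$protein[sim2$truth$class == "common"]
  est <- q2$log2_ratio[q2$protein %in% planted]
  expect_lt(abs(mean(est) - 2), 0.2)

  # 10% missingness: fraction failing the 8-channel filter within 3 SEs
  miss_cfg <- itraq_sim_config(n_proteins = 500, psms_per_protein = 2,
                               missing_rate = 0.10, seed = 13L)
  sim3 <- simulate_itraq(miss_cfg)
  kept <- filter_psms(sim3$psms, miss_cfg$design)
  frac_fail <- 1 - nrow(kept) / nrow(sim3$psms)
  se_fail <- sqrt(0.1 * 0.9 / nrow(sim3$psms))
  expect_lt(abs(frac_fail - 0.10), 3 * se_fail)
})

test_that("truth labels are consistent with generated data", {
  cfg <- cohort_sim_config(n_cases = 100, n_controls = 150, seed = 21L)
  tab <- simulate_cohort(cfg)
  truth <- attr(tab, "truth")
  expect_setequal(truth$case_carriers,
                  unique(tab$individual_id[tab$cohort == "patient"]))
  expect_setequal(truth$control_carriers,
                  unique(tab$individual_id[tab$cohort == "control"]))

  icfg <- itraq_sim_config(n_proteins = 30, psms_per_protein = 2,
                           planted_common = 1:3,
                           planted_unique = list(GRN = 4:5),
                           planted_contra = 6:7, seed = 22L)
  sim <- simulate_itraq(icfg)
  planted <- sim$truth$protein[sim$truth$class != "none"]
  expect_true(all(planted %in% sim$psms$protein))
})

test_that("corpus and table serialization round-trips", {
  ccfg <- corpus_sim_config(n_documents = 12, seed = 3L)
  corpus <- simulate_corpus(ccfg)
  path <- tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_equal(back$doc_id, corpus$doc_id)
  expect_equal(back$text, corpus$text)
  expect_equal(lapply(back$genes, identity), corpus$genes)

  vpath <- tempfile(fileext = ".tsv")
  cohort <- simulate_cohort(cohort_sim_config(n_cases = 30, n_controls = 30,
                                              seed = 4L))
  write_tsv(cohort, vpath)
  back2 <- read_variants(vpath)
  expect_equal(back2$individual_id, cohort$individual_id)
  expect_equal(back2$maf, cohort$maf, tolerance = 1e-12)
})
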