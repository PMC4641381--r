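# Tokenization, TF-IDF + truncated SVD model, gene-term cosines with the
# implicit threshold, size-adjusted dataset scores, word frequencies.

corpus_df <- function(ids, texts, genes) {
  data.frame(doc_id = ids, text = texts, genes = I(genes),
             stringsAsFactors = FALSE)
}

# deterministic full-term-rank corpus: one singleton document per term plus
# mixtures; more documents than vocabulary terms
full_rank_corpus <- function() {
  vocab <- c("actin", "dendrite", "synapse", "tangle", "vesicle")
  singletons <- corpus_df(paste0("S", seq_along(vocab)), vocab,
                          as.list(rep("GBG", length(vocab))))
  mixtures <- corpus_df(
    c("M1", "M2", "M3", "M4"),
    c("actin dendrite dendrite", "synapse vesicle actin",
      "tangle tangle synapse", "dendrite synapse vesicle actin"),
    list("GA", "GA", "GB", "GB"))
  rbind(singletons, mixtures)
}

test_that("tokenization lower-cases, splits and removes stop words", {
  toks <- lsi_tokenize("The Cytoskeleton, and its Dendrites!")
  expect_equal(toks[[1]], c("cytoskeleton", "dendrites"))
  expect_equal(lsi_tokenize("", )[[1]], character(0))
})

test_that("full-rank latent cosines equal raw TF-IDF cosines", {
  corpus <- full_rank_corpus()
  model <- build_lsi(corpus, latent_dim = 5)
  expect_equal(model$latent_dim, 5)
  oracle <- oracle_tfidf(lsi_tokenize(corpus$text))
  for (g in c("GA", "GB")) {
    linked <- vapply(corpus$genes, function(gs) g %in% gs, logical(1))
    centroid_raw <- rowMeans(oracle$x[, linked, drop = FALSE])
    for (term in c("actin", "dendrite", "tangle", "synapse vesicle")) {
      toks <- lsi_tokenize(term)[[1]]
      q <- numeric(length(oracle$vocab)); names(q) <- oracle$vocab
      tb <- table(toks[toks %in% oracle$vocab])
      q[names(tb)] <- (1 + log(as.numeric(tb))) * oracle$idf[names(tb)]
      raw <- max(0, oracle_cosine(centroid_raw, q))
      got <- gene_term_cosine(model, g, term)$cosine
      expect_equal(got, raw, tolerance = 1e-10)
    }
  }
})

test_that("random full-rank corpora also match the dense oracle", {
  set.seed(101)
  vocab <- paste0("w", 1:6)
  for (rep in 1:5) {
    texts <- c(vocab,  # singleton docs guarantee full term rank
               replicate(4, paste(sample(vocab, sample(2:5, 1), replace = TRUE),
                                  collapse = " ")))
    genes <- c(as.list(rep("GX", 6)), as.list(sample(c("GX", "GY"), 4,
                                                     replace = TRUE)))
    corpus <- corpus_df(paste0("D", seq_along(texts)), texts, genes)
    model <- build_lsi(corpus, latent_dim = 6)
    oracle <- oracle_tfidf(lsi_tokenize(corpus$text))
    linked <- vapply(corpus$genes, function(gs) "GY" %in% gs, logical(1))
    if (!any(linked)) next
    centroid_raw <- rowMeans(oracle$x[, linked, drop = FALSE])
    term <- sample(vocab, 1)
    q <- numeric(6); names(q) <- oracle$vocab
    q[term] <- (1 + log(1)) * oracle$idf[term]
    expect_equal(gene_term_cosine(model, "GY", term)$cosine,
                 max(0, oracle_cosine(centroid_raw, q)), tolerance = 1e-10)
  }
})

test_that("degenerate and boundary cases behave as documented", {
  # identical documents: rank 1, collinear representations, clip warning
  corpus <- corpus_df(c("D1", "D2", "D3"), rep("actin synapse actin", 3),
                      list("G1", "G1", "G2"))
  expect_warning(model <- build_lsi(corpus, latent_dim = 3), "clipped")
  expect_equal(model$latent_dim, 1)

  # gene whose only document is exactly the query term -> cosine 1
  corpus2 <- rbind(corpus_df("D1", "cytoskeleton", list("G1")),
                   corpus_df("D2", "synapse vesicle", list("G2")),
                   corpus_df("D3", "vesicle", list("G2")),
                   corpus_df("D4", "synapse", list("G2")))
  model2 <- build_lsi(corpus2, latent_dim = 3)
  expect_equal(gene_term_cosine(model2, "G1", "cytoskeleton")$cosine, 1,
               tolerance = 1e-10)
  # orthogonal term (no shared tokens with the gene's documents) -> 0
  expect_equal(gene_term_cosine(model2, "G2", "cytoskeleton")$cosine, 0,
               tolerance = 1e-10)

  # fully out-of-vocabulary term: score 0 with warning
  expect_warning(res <- gene_term_cosine(model2, "G1", "zzzz"), "vocabulary")
  expect_equal(res$cosine, 0)
  expect_false(res$implicit)

  expect_error(gene_term_cosine(model2, "NOGENE", "synapse"), "linked")
})

test_that("planted gene-term links score as implicit associations", {
  hits <- 0; beats_random <- 0
  for (s in 1:50) {
    pl <- data.frame(gene = "GENE01", term = "term01", rate = 0.8,
                     stringsAsFactors = FALSE)
    cfg <- corpus_sim_config(n_documents = 120,
                             genes = sprintf("GENE%02d", 1:6),
                             vocabulary = sprintf("term%02d", 1:30),
                             planted_links = pl, background_rate = 0.05,
                             seed = 200L + s)
    corpus <- simulate_corpus(cfg)
    model <- suppressWarnings(build_lsi(corpus))
    planted <- gene_term_cosine(model, "GENE01", "term01")$cosine
    random <- gene_term_cosine(model, "GENE01", "term17")$cosine
    hits <- hits + (planted >= 0.1)
    beats_random <- beats_random + (planted > random)
  }
  expect_gte(hits / 50, 0.95)
  expect_gte(beats_random / 50, 0.95)
})

test_that("dataset scores threshold, normalize and sum as specified", {
  corpus <- full_rank_corpus()
  model <- build_lsi(corpus, latent_dim = 5)
  genes <- c("GA", "GB")
  terms <- c("actin", "tangle")
  sc <- dataset_score(model, genes, terms, dataset_id = "demo")
  expect_equal(nrow(sc$per_term), 2)
  expect_equal(sc$combined_score, sum(sc$per_term$size_adjusted_score))

  # all cosines below the threshold -> zero totals
  high <- dataset_score(model, genes, terms, cosine_threshold = 1.01)
  expect_equal(high$per_term$total_score, c(0, 0))

  # duplicating every gene leaves the size-adjusted score unchanged
  dup <- dataset_score(model, rep(genes, 2), terms)
  expect_equal(dup$per_term$size_adjusted_score,
               sc$per_term$size_adjusted_score, tolerance = 1e-12)

  # permutation invariance in genes and terms
  perm <- dataset_score(model, rev(genes), rev(terms))
  expect_equal(sort(perm$per_term$size_adjusted_score),
               sort(sc$per_term$size_adjusted_score), tolerance = 1e-12)
  expect_equal(perm$combined_score, sc$combined_score, tolerance = 1e-12)
})

test_that("linked datasets outscore unlinked ones on planted corpora", {
  wins <- 0
  terms <- c("term01", "term02")
  for (s in 1:50) {
    pl <- do.call(rbind, lapply(terms, function(tm) {
      data.frame(gene = c("A1", "A2", "A3"), term = tm, rate = 0.7,
                 stringsAsFactors = FALSE)
    }))
    cfg <- corpus_sim_config(n_documents = 90,
                             genes = c("A1", "A2", "A3", "B1", "B2", "B3"),
                             vocabulary = sprintf("term%02d", 1:20),
                             planted_links = pl, background_rate = 0.05,
                             seed = 300L + s)
    model <- suppressWarnings(build_lsi(simulate_corpus(cfg)))
    a <- dataset_score(model, c("A1", "A2", "A3"), terms)$combined_score
    b <- dataset_score(model, c("B1", "B2", "B3"), terms)$combined_score
    wins <- wins + (a > b)
  }
  expect_gte(wins / 50, 0.95)
})

test_that("word frequencies count, rank and conserve tokens", {
  wf <- word_frequencies("cytoskeleton cytoskeleton synapse")
  expect_equal(wf$word, c("cytoskeleton", "synapse"))
  expect_equal(wf$count, c(2L, 1L))

  expect_equal(nrow(word_frequencies(character())), 0)
  expect_equal(nrow(word_frequencies("the and of")), 0)  # all stop words

  docs <- c("actin synapse actin", "tangle the synapse")
  wf2 <- word_frequencies(docs)
  toks <- unlist(lsi_tokenize(docs))
  expect_equal(sum(wf2$count), length(toks))  # conservation
  # ties broken alphabetically
  expect_equal(wf2$word, c("actin", "synapse", "tangle"))
  expect_equal(nrow(word_frequencies(docs, top_k = 2)), 2)
})
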