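# Latent semantic indexing over a gene-linked corpus: TF-IDF weighting,
# truncated SVD, gene-centroid pseudo-documents, gene-term cosine scores
# with the 0.1 implicit-association threshold, size-adjusted dataset totals
# and word-frequency tables for word-cloud style summaries.

#' Default stop-word list
#'
#' The versioned English stop-word list shipped with the package
#' (\code{inst/extdata/stopwords.txt}).
#'
#' @return Character vector of stop words.
#' @export
lsi_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "ftdconv")
  readLines(path)
}

#' Tokenize text for semantic indexing
#'
#' Lower-cases, splits on non-alphanumeric characters and removes stop
#' words and empty tokens.
#'
#' @param text Character vector.
#' @param stopwords Stop-word list (default [lsi_stopwords()]).
#' @return List of character token vectors, one per input element.
#' @export
lsi_tokenize <- function(text, stopwords = lsi_stopwords()) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t) & !(t %in% stopwords)])
}

tfidf_matrix <- function(token_lists, vocabulary = NULL) {
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(token_lists, use.names = FALSE)))
  }
  n_docs <- length(token_lists)
  counts <- matrix(0, length(vocabulary), n_docs,
                   dimnames = list(vocabulary, NULL))
  for (j in seq_len(n_docs)) {
    tab <- table(token_lists[[j]])
    tab <- tab[names(tab) %in% vocabulary]
    counts[names(tab), j] <- as.numeric(tab)
  }
  df <- rowSums(counts > 0)
  idf <- log((1 + n_docs) / (1 + df)) + 1  # smoothed IDF
  tf <- counts
  tf[tf > 0] <- 1 + log(tf[tf > 0])        # log-scaled TF
  x <- tf * idf
  # L2-normalize documents so cosine geometry is scale-free
  norms <- sqrt(colSums(x^2))
  nz <- norms > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, norms[nz], "/")
  list(x = x, idf = idf, vocabulary = vocabulary)
}

#' Build a latent semantic indexing model
#'
#' Tokenizes the corpus, builds a TF-IDF term-document matrix (log-scaled
#' term frequency, smoothed inverse document frequency, L2-normalized
#' documents) and computes its rank-\code{latent_dim} truncated singular
#' value decomposition. Each gene is represented as a pseudo-document: the
#' centroid of its linked documents in the latent space. A
#' \code{latent_dim} exceeding the matrix rank is clipped with a warning.
#'
#' Note the weighting is corpus-dependent: removing any document (even one
#' unlinked to genes) changes document counts, hence IDF, hence scores.
#'
#' @param corpus Corpus \code{data.frame} with columns \code{doc_id},
#'   \code{text}, \code{genes} (list column), as from [simulate_corpus()] or
#'   [read_corpus()].
#' @param latent_dim Target latent dimensionality (default
#'   \code{min(100, rank)}).
#' @param stopwords Stop-word list.
#' @return An \code{lsi_model}: list with \code{vocabulary}, \code{idf},
#'   \code{u} (term loadings), \code{d} (singular values), \code{doc_latent}
#'   (latent_dim x docs), \code{gene_latent} (latent_dim x genes),
#'   \code{latent_dim}.
#' @export
build_lsi <- function(corpus, latent_dim = 100, stopwords = lsi_stopwords()) {
  stopifnot(is.data.frame(corpus), nrow(corpus) > 0, latent_dim >= 1)
  toks <- lsi_tokenize(corpus$text, stopwords)
  tw <- tfidf_matrix(toks)
  x <- tw$x
  sv <- svd(x)
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank == 0L) stop("corpus has no usable tokens", call. = FALSE)
  if (latent_dim > rank) {
    warning("latent_dim ", latent_dim, " exceeds matrix rank ", rank,
            "; clipped")
    latent_dim <- rank
  }
  d <- seq_len(latent_dim)
  u <- sv$u[, d, drop = FALSE]
  rownames(u) <- tw$vocabulary
  doc_latent <- t(u) %*% x  # latent_dim x docs (= D V' for full rank)
  colnames(doc_latent) <- corpus$doc_id

  genes <- unique(unlist(corpus$genes, use.names = FALSE))
  gene_latent <- vapply(genes, function(g) {
    linked <- vapply(corpus$genes, function(gs) g %in% gs, logical(1))
    rowMeans(doc_latent[, linked, drop = FALSE])
  }, numeric(latent_dim))
  gene_latent <- matrix(gene_latent, nrow = latent_dim,
                        dimnames = list(NULL, genes))

  structure(list(vocabulary = tw$vocabulary, idf = tw$idf, u = u,
                 d = sv$d[d], doc_latent = doc_latent,
                 gene_latent = gene_latent, latent_dim = latent_dim,
                 stopwords = stopwords),
            class = "lsi_model")
}

query_vector <- function(model, term) {
  toks <- lsi_tokenize(term, model$stopwords)[[1]]
  toks <- toks[toks %in% model$vocabulary]
  q <- numeric(length(model$vocabulary))
  names(q) <- model$vocabulary
  if (length(toks)) {
    tab <- table(toks)
    q[names(tab)] <- (1 + log(as.numeric(tab))) * model$idf[names(tab)]
    nrm <- sqrt(sum(q^2))
    if (nrm > 0) q <- q / nrm
  }
  q
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Gene-to-term cosine association score
#'
#' Cosine similarity between the gene's latent centroid and the
#' interrogation term's query vector projected into the latent space.
#' Negative cosines are clipped to 0 so scores live in \code{[0, 1]}; scores
#' of at least 0.1 are flagged as (at least) implicit associations. A term
#' entirely out of vocabulary scores 0 with a warning.
#'
#' @param model An [build_lsi()] model.
#' @param gene Gene symbol (must have at least one linked document).
#' @param term Interrogation term (free text; tokenized like the corpus).
#' @return \code{data.frame} with columns \code{gene}, \code{term},
#'   \code{cosine}, \code{implicit}.
#' @export
gene_term_cosine <- function(model, gene, term) {
  stopifnot(inherits(model, "lsi_model"))
  if (!gene %in% colnames(model$gene_latent)) {
    stop("gene ", gene, " has no linked documents in the model", call. = FALSE)
  }
  q <- query_vector(model, term)
  if (all(q == 0)) {
    warning("term '", term, "' is fully out of vocabulary; score 0")
    cs <- 0
  } else {
    q_lat <- as.numeric(t(model$u) %*% q)
    cs <- max(0, cosine(model$gene_latent[, gene], q_lat))
  }
  data.frame(gene = gene, term = term, cosine = cs, implicit = cs >= 0.1,
             stringsAsFactors = FALSE)
}

#' Size-adjusted semantic score of a gene set for interrogation terms
#'
#' For each term, sums the gene-term cosines that reach the implicit
#' threshold over the dataset's genes (\code{total_score}) and divides by
#' the number of genes (\code{size_adjusted_score}), so datasets of
#' different sizes are comparable. The combined dataset score is the sum
#' over terms of the size-adjusted scores.
#'
#' @param model An [build_lsi()] model.
#' @param genes Character vector of gene symbols (non-empty; genes without
#'   linked documents contribute 0).
#' @param terms Character vector of interrogation terms.
#' @param cosine_threshold Minimum cosine for a gene to contribute
#'   (default 0.1, the implicit-association limit).
#' @param dataset_id Optional label for the gene set.
#' @return List with \code{per_term} (a \code{data.frame}: \code{dataset_id},
#'   \code{term}, \code{total_score}, \code{size_adjusted_score}) and
#'   \code{combined_score}.
#' @export
dataset_score <- function(model, genes, terms, cosine_threshold = 0.1,
                          dataset_id = "dataset") {
  stopifnot(inherits(model, "lsi_model"), length(genes) > 0)
  per_term <- do.call(rbind, lapply(terms, function(tm) {
    cs <- vapply(genes, function(g) {
      if (!g %in% colnames(model$gene_latent)) return(0)
      suppressWarnings(gene_term_cosine(model, g, tm)$cosine)
    }, numeric(1))
    qualifying <- cs[cs >= cosine_threshold]
    total <- sum(qualifying)
    data.frame(dataset_id = dataset_id, term = tm, total_score = total,
               size_adjusted_score = total / length(genes),
               stringsAsFactors = FALSE)
  }))
  list(per_term = per_term,
       combined_score = sum(per_term$size_adjusted_score))
}

#' Word-frequency table for word-cloud style summaries
#'
#' Counts non-stop-word tokens over the supplied documents, ranked by
#' descending count with alphabetical tie-breaking.
#'
#' @param documents Character vector of texts.
#' @param top_k Optionally keep only the \code{top_k} most frequent words.
#' @param stopwords Stop-word list.
#' @return \code{data.frame} with columns \code{word}, \code{count}.
#' @export
word_frequencies <- function(documents, top_k = Inf,
                             stopwords = lsi_stopwords()) {
  toks <- unlist(lsi_tokenize(documents, stopwords), use.names = FALSE)
  if (!length(toks)) {
    return(data.frame(word = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(toks)
  out <- data.frame(word = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$word), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
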