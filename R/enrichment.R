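# Over-representation analysis against user-supplied gene sets: one-sided
# hypergeometric enrichment p-values (optionally the EASE-penalized variant),
# fold-enrichment factors, and the hybrid score
# (-log10 p) * fold enrichment * hit count.

#' Read gene sets from a GMT file
#'
#' GMT: one tab-separated line per set, \code{term_id}, \code{description},
#' then member gene symbols. Symbols are upper-cased to canonical form.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; names are term ids, attribute
#'   \code{description} carries the per-term descriptions.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to term id).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided hypergeometric enrichment p-value
#'
#' Probability of observing at least \code{k} members of a size-\code{K} term
#' in a size-\code{n} query drawn from a size-\code{N} background,
#' \code{P(X >= k)} with \code{X ~ Hypergeometric(K, N - K, n)}. The EASE
#' variant (the conservative DAVID-style penalization) removes one hit and
#' computes \code{P(X >= k - 1)} on the same margins.
#'
#' @param k Hits in the query. @param K Term size in the background.
#' @param n Query size. @param N Background size.
#' @param ease Use the EASE penalization (default \code{FALSE}).
#' @return p-value in \code{(0, 1]}.
#' @export
term_pvalue <- function(k, K, n, N, ease = FALSE) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  kk <- if (ease) max(k - 1L, 0L) else k
  # upper tail P(X >= kk) = P(X > kk - 1)
  stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Hybrid enrichment score
#'
#' Single-index summary of a term's enrichment: the product of the negative
#' log10 enrichment probability, the fold-enrichment factor and the number
#' of query proteins populating the term.
#'
#' @param p Enrichment p-value in \code{(0, 1]}.
#' @param enrichment_factor Fold enrichment \code{(k/n) / (K/N)}.
#' @param k Number of query proteins in the term.
#' @return Non-negative score; \code{p = 1} gives 0.
#' @examples
#' hybrid_score(0.01, 2.5, 4)  # 20
#' @export
hybrid_score <- function(p, enrichment_factor, k) {
  if (any(p <= 0)) stop("p must be in (0, 1]", call. = FALSE)
  stopifnot(all(enrichment_factor >= 0), all(k >= 0))
  (-log10(p)) * enrichment_factor * k
}

#' Over-representation analysis of a query against gene sets
#'
#' Tests each gene set for over-representation in the query relative to the
#' background, applying the field-standard filters: at least \code{min_k}
#' query proteins in the term and enrichment p-value at most \code{alpha}.
#' Results are ranked by hybrid score (descending), ties broken by term id.
#'
#' @param query Character vector of gene symbols (subset of
#'   \code{background}).
#' @param background Character vector: the universe of quantified genes.
#' @param sets Named list of gene vectors (e.g. from [read_gmt()]).
#' @param min_k Minimum query hits per term (default 2).
#' @param alpha Maximum enrichment p-value (default 0.05).
#' @param ease Use the EASE-penalized p-value (default \code{FALSE}).
#' @param adjust P-value adjustment across terms before the \code{alpha}
#'   filter: \code{"none"} (default, a raw-p filter) or \code{"BH"}.
#' @return \code{data.frame} with columns \code{term_id}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{p_adjusted},
#'   \code{enrichment_factor}, \code{hybrid_score}.
#' @export
enrich <- function(query, background, sets, min_k = 2, alpha = 0.05,
                   ease = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  query <- unique(toupper(query))
  background <- unique(toupper(background))
  offenders <- setdiff(query, background)
  if (length(offenders)) {
    stop("query gene(s) absent from background: ",
         paste(utils::head(offenders, 10), collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  n <- length(query)
  res <- lapply(names(sets), function(id) {
    members <- intersect(unique(toupper(sets[[id]])), background)
    K <- length(members)
    k <- length(intersect(members, query))
    if (K == 0L) return(NULL)
    p <- term_pvalue(k, K, n, N, ease = ease)
    ef <- if (n > 0 && k > 0) (k / n) / (K / N) else 0
    data.frame(term_id = id, k = k, K = K, n = n, N = N, p = p,
               enrichment_factor = ef, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) return(empty_enrichment())
  res$p_adjusted <- if (adjust == "BH") stats::p.adjust(res$p, "BH") else res$p
  res$hybrid_score <- hybrid_score(res$p, res$enrichment_factor, res$k)
  keep <- res$k >= min_k & res$p_adjusted <= alpha
  res <- res[keep, , drop = FALSE]
  res <- res[order(-res$hybrid_score, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("term_id", "k", "K", "n", "N", "p", "p_adjusted",
          "enrichment_factor", "hybrid_score")]
}

empty_enrichment <- function() {
  data.frame(term_id = character(), k = integer(), K = integer(),
             n = integer(), N = integer(), p = numeric(),
             p_adjusted = numeric(), enrichment_factor = numeric(),
             hybrid_score = numeric(), stringsAsFactors = FALSE)
}
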