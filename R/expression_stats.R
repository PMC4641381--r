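# Relative expression quantification with geometric-mean housekeeping
# normalization (the multi-reference-gene convention) and two-sided
# Mann-Whitney group comparison, exact for small untied samples.

#' Read a qPCR Ct table
#'
#' Tab-separated with header \code{sample_id}, \code{group}, \code{gene},
#' \code{replicate}, \code{ct}.
#'
#' @param path Path to the TSV file.
#' @return Ct \code{data.frame}.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "ct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("Ct table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (any(df$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  df
}

#' Housekeeping-normalized relative expression levels
#'
#' Technical replicates are averaged per (sample, gene); relative quantities
#' are computed as \code{efficiency^(minCt_gene - Ct)} (each gene anchored at
#' its lowest observed mean Ct, so the best-expressed sample scores 1); the
#' per-sample normalization factor is the geometric mean of the housekeeping
#' genes' relative quantities; the normalized level is the target quantity
#' divided by that factor. Samples missing any housekeeping gene are
#' excluded with a warning.
#'
#' @param table Ct \code{data.frame} (see [read_ct_table()]).
#' @param targets Target gene names.
#' @param housekeeping Reference gene names (default GAPDH and ACTB).
#' @param efficiency Amplification efficiency per cycle (default 2, perfect
#'   doubling).
#' @return \code{data.frame} with columns \code{sample_id}, \code{group},
#'   \code{gene}, \code{level}.
#' @export
normalize_expression <- function(table, targets,
                                 housekeeping = c("GAPDH", "ACTB"),
                                 efficiency = 2.0) {
  stopifnot(efficiency > 1)
  need <- c(targets, housekeeping)
  table <- table[table$gene %in% need, , drop = FALSE]
  if (!all(housekeeping %in% table$gene)) {
    stop("housekeeping gene(s) absent from table: ",
         paste(setdiff(housekeeping, table$gene), collapse = ", "),
         call. = FALSE)
  }
  agg <- stats::aggregate(ct ~ sample_id + group + gene, table, mean)
  # exclude samples without a full housekeeping panel
  ok <- vapply(unique(agg$sample_id), function(s) {
    all(housekeeping %in% agg$gene[agg$sample_id == s])
  }, logical(1))
  bad <- unique(agg$sample_id)[!ok]
  if (length(bad)) {
    warning("excluding sample(s) missing housekeeping measurements: ",
            paste(bad, collapse = ", "))
    agg <- agg[!agg$sample_id %in% bad, , drop = FALSE]
  }
  min_ct <- tapply(agg$ct, agg$gene, min)
  agg$q <- as.numeric(efficiency^(min_ct[agg$gene] - agg$ct))
  nf <- tapply(agg$q[agg$gene %in% housekeeping],
               agg$sample_id[agg$gene %in% housekeeping],
               function(x) exp(mean(log(x))))
  out <- agg[agg$gene %in% targets, , drop = FALSE]
  out$level <- as.numeric(out$q / as.numeric(nf[out$sample_id]))
  rownames(out) <- NULL
  out[, c("sample_id", "group", "gene", "level")]
}

#' Two-sided Mann-Whitney U comparison of two groups
#'
#' Uses the exact null distribution of the U statistic when both groups have
#' at most \code{exact_limit} observations and the data contain no ties;
#' otherwise the normal approximation with midranks and tie correction (no
#' continuity correction). Significance stars follow the usual convention:
#' \code{*} for p < 0.05, \code{**} for p < 0.01, \code{***} for p < 0.001.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_limit Largest per-group size for the exact path (default 8).
#' @return List with \code{u}, \code{p_value}, \code{stars}, \code{method}.
#' @export
group_compare <- function(a, b, exact_limit = 8L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty",
                                     call. = FALSE)
  m <- length(a); n <- length(b)
  ranks <- rank(c(a, b))
  u <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && m <= exact_limit && n <= exact_limit) {
    p <- 2 * min(stats::pwilcox(u, m, n),
                 stats::pwilcox(u - 1, m, n, lower.tail = FALSE))
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- m * n / 2
    tie_tab <- table(c(a, b))
    nn <- m + n
    sigma2 <- m * n / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(u = u, p_value = p, stars = significance_stars(p), method = method)
}

#' Significance stars for p-values
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: \code{***} (p < 0.001), \code{**} (p < 0.01),
#'   \code{*} (p < 0.05) or \code{""}.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
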