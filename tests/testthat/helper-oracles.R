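# Independent oracles and small fixture builders shared across test files.
# Oracles deliberately avoid the code paths they check: brute-force
# enumeration for the hypergeometric tail, full permutation enumeration for
# the Mann-Whitney test, dense TF-IDF cosine for the LSI model, and the
# closed-form Pearson statistic for the 2x2 table.

# P(X >= k) for X ~ Hypergeometric(K successes, N - K failures, n draws),
# by direct summation of binomial-coefficient mass.
oracle_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- k:hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Two-sided exact Mann-Whitney p-value by enumerating all assignments of
# the pooled observations to the two groups (requires no ties).
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  })
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Dense TF-IDF document matrix + cosine, mirroring the documented weighting
# (log-scaled TF, smoothed IDF, L2-normalized documents) without any SVD.
oracle_tfidf <- function(token_lists) {
  vocab <- sort(unique(unlist(token_lists)))
  n <- length(token_lists)
  counts <- sapply(token_lists, function(t) {
    v <- numeric(length(vocab)); names(v) <- vocab
    tb <- table(t); v[names(tb)] <- as.numeric(tb); v
  })
  counts <- matrix(counts, nrow = length(vocab), dimnames = list(vocab, NULL))
  idf <- log((1 + n) / (1 + rowSums(counts > 0))) + 1
  tf <- counts; tf[tf > 0] <- 1 + log(tf[tf > 0])
  x <- tf * idf
  nrm <- sqrt(colSums(x^2)); nz <- nrm > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, nrm[nz], "/")
  list(x = x, vocab = vocab, idf = idf)
}

oracle_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
}

# Pearson chi-squared for a 2x2 table, closed form.
oracle_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# One-PSM builder: named intensities in channel order 113..119, 121.
make_psm <- function(protein, intensities, peptide = "PEP1") {
  stopifnot(length(intensities) == 8)
  df <- data.frame(peptide = peptide, protein = protein,
                   stringsAsFactors = FALSE)
  ints <- as.list(intensities)
  names(ints) <- paste0("i", c(113:119, 121))
  cbind(df, as.data.frame(ints))
}

default_design <- channel_design()

# A toy variant table: three rows, one shared variant.
toy_variants <- function() {
  data.frame(
    individual_id = c("P1", "P2", "P3"),
    cohort = "patient", gene = "FLNC",
    variant_id = c("p.A1B", "p.A1B", "p.C2D"),
    maf = c(0.001, 0.001, 0.002), domain = NA_character_,
    stringsAsFactors = FALSE)
}
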