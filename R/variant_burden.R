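# Rare-variant gene-burden analysis: MAF banding, carrier collapsing and the
# allele-based 2x2 chi-squared test with odds ratio and Woolf confidence
# interval.

#' Classify variants into minor-allele-frequency bands
#'
#' Partitions the MAF interval \code{[0, 1]} into the three bands used for
#' burden analysis: \code{rare} (MAF < 1\%), \code{low_frequency}
#' (1\% <= MAF <= 5\%, both boundaries inclusive) and \code{frequent}
#' (MAF > 5\%).
#'
#' @param maf Numeric vector of minor allele frequencies in \code{[0, 1]}.
#' @return Factor with levels \code{rare}, \code{low_frequency},
#'   \code{frequent}, same length as \code{maf}.
#' @examples
#' classify_frequency(c(0.005, 0.03, 0.2))
#' @export
classify_frequency <- function(maf) {
  if (!is.numeric(maf)) stop("`maf` must be numeric", call. = FALSE)
  bad <- !is.na(maf) & (maf < 0 | maf > 1)
  if (any(bad)) {
    stop("MAF outside [0, 1]: ", paste(utils::head(maf[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  band <- ifelse(maf < 0.01, "rare",
                 ifelse(maf <= 0.05, "low_frequency", "frequent"))
  factor(band, levels = c("rare", "low_frequency", "frequent"))
}

#' Read a cohort variant table
#'
#' Expects a tab-separated file with header columns \code{individual_id},
#' \code{cohort}, \code{gene}, \code{variant_id}, \code{maf}, \code{domain}.
#' \code{cohort} must be \code{patient} or \code{control}; \code{maf} and
#' \code{domain} may be empty.
#'
#' @param path Path to the TSV file.
#' @return A \code{data.frame} of variant-carrier observations.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("individual_id", "cohort", "gene", "variant_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("variant table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"maf" %in% names(df)) df$maf <- NA_real_
  if (!"domain" %in% names(df)) df$domain <- NA_character_
  df$maf <- as.numeric(df$maf)
  validate_variants(df)
  df
}

validate_variants <- function(df) {
  unknown <- setdiff(unique(df$cohort), c("patient", "control"))
  if (length(unknown)) {
    stop("unknown cohort label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$individual_id, df$variant_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (individual_id, variant_id) rows in variant table",
         call. = FALSE)
  }
  invisible(df)
}

#' Collapse variant carriers per cohort
#'
#' Counts, per cohort, the number of individuals carrying at least one variant
#' in the requested MAF band. An individual with several qualifying variants
#' contributes exactly one mutated allele (carrier collapsing; phase is
#' typically unknown, so multi-variant carriers are not double counted).
#'
#' Observations with missing MAF have their MAF imputed from control-cohort
#' allele counts: carriers of the variant among controls divided by
#' \code{2 * n_controls} (controls approximate the population frequency).
#' When \code{n_controls} must be known for that imputation it is taken as
#' the number of distinct control individuals in \code{observations} unless
#' supplied.
#'
#' @param observations Variant observation \code{data.frame} (see
#'   [read_variants()]).
#' @param band Band to collapse on: \code{"rare"}, \code{"low_frequency"} or
#'   \code{"frequent"}.
#' @param n_controls Number of control individuals in the full cohort, used
#'   only for MAF imputation; defaults to the distinct control ids observed.
#' @return Named integer vector \code{c(case_carriers, control_carriers)}.
#' @export
collapse_carriers <- function(observations, band = "rare", n_controls = NULL) {
  band <- match.arg(band, c("rare", "low_frequency", "frequent"))
  df <- observations
  if (nrow(df) == 0L) {
    return(c(case_carriers = 0L, control_carriers = 0L))
  }
  validate_variants(df)
  if (is.null(n_controls)) {
    n_controls <- length(unique(df$individual_id[df$cohort == "control"]))
  }
  if (is.null(df$maf)) df$maf <- NA_real_
  need <- is.na(df$maf)
  if (any(need)) {
    ctrl <- df[df$cohort == "control", , drop = FALSE]
    counts <- table(ctrl$variant_id)
    imputed <- as.numeric(counts[df$variant_id[need]])
    imputed[is.na(imputed)] <- 0
    df$maf[need] <- if (n_controls > 0) imputed / (2 * n_controls) else 0
  }
  df$band <- classify_frequency(df$maf)
  keep <- df[df$band == band, , drop = FALSE]
  c(case_carriers = length(unique(keep$individual_id[keep$cohort == "patient"])),
    control_carriers = length(unique(keep$individual_id[keep$cohort == "control"])))
}

#' Allele-based 2x2 gene-burden test
#'
#' Builds the allele-level 2x2 table from collapsed carrier counts under a
#' heterozygous-carrier assumption (one mutated allele per carrier, so each
#' cohort contributes \code{2 * N} chromosomes: \code{carriers} mutated and
#' \code{2 * N - carriers} wild type) and computes the Pearson chi-squared
#' statistic (df = 1, no continuity correction), its two-sided p-value, the
#' odds ratio and the Woolf (log-odds) 95\% confidence interval
#' \code{exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))}.
#'
#' Carrier frequencies are reported as \code{carriers / N} in percent. When
#' any allele-table cell is zero the odds ratio and confidence interval are
#' undefined and flagged as such (no silent continuity correction).
#'
#' @param case_carriers,n_cases Carrier count and cohort size for cases.
#' @param control_carriers,n_controls Carrier count and cohort size for
#'   controls.
#' @param conf_level Confidence level for the Woolf interval (default 0.95).
#' @return An object of class \code{burden_result}: a list with the 2x2 cells
#'   \code{a, b, c, d}, carrier frequencies in percent, \code{chi2},
#'   \code{p_value}, \code{odds_ratio}, \code{ci_low}, \code{ci_high} and
#'   \code{or_defined}.
#' @examples
#' burden_test(60, 529, 73, 920)
#' @export
burden_test <- function(case_carriers, n_cases, control_carriers, n_controls,
                        conf_level = 0.95) {
  stopifnot(length(case_carriers) == 1L, length(control_carriers) == 1L)
  if (n_cases <= 0 || n_controls <= 0) {
    stop("cohort sizes must be positive", call. = FALSE)
  }
  if (case_carriers < 0 || control_carriers < 0 ||
      case_carriers > n_cases || control_carriers > n_controls) {
    stop("carrier counts must lie in [0, cohort size]", call. = FALSE)
  }
  a <- case_carriers
  b <- 2 * n_cases - case_carriers
  c_ <- control_carriers
  d <- 2 * n_controls - control_carriers

  # Pearson chi-squared on the allele table, closed form, df = 1.
  n <- a + b + c_ + d
  num <- n * (a * d - b * c_)^2
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- if (den > 0) num / den else NA_real_
  p <- if (is.na(chi2)) NA_real_ else stats::pchisq(chi2, df = 1, lower.tail = FALSE)

  or_defined <- all(c(a, b, c_, d) > 0)
  if (or_defined) {
    or <- (a * d) / (b * c_)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    ci <- exp(log(or) + c(-1, 1) * z * se)
  } else {
    or <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }

  structure(list(
    case_carriers = as.integer(case_carriers), n_cases = as.integer(n_cases),
    control_carriers = as.integer(control_carriers),
    n_controls = as.integer(n_controls),
    a = a, b = b, c = c_, d = d,
    case_freq_pct = 100 * case_carriers / n_cases,
    control_freq_pct = 100 * control_carriers / n_controls,
    chi2 = chi2, p_value = p,
    odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
    or_defined = or_defined, conf_level = conf_level
  ), class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Rare-variant gene-burden test (allele-based 2x2, Pearson chi-squared)\n")
  cat(sprintf("  cases:    %d/%d carriers (%.1f%%)\n",
              x$case_carriers, x$n_cases, x$case_freq_pct))
  cat(sprintf("  controls: %d/%d carriers (%.1f%%)\n",
              x$control_carriers, x$n_controls, x$control_freq_pct))
  cat(sprintf("  chi2 = %.3f (df = 1), P = %.4f\n", x$chi2, x$p_value))
  if (x$or_defined) {
    cat(sprintf("  OR = %.2f, %d%% CI %.2f-%.2f (Woolf)\n", x$odds_ratio,
                round(100 * x$conf_level), x$ci_low, x$ci_high))
  } else {
    cat("  OR undefined (zero cell in allele table)\n")
  }
  invisible(x)
}

#' Summarize a patient-only variant table
#'
#' For a table restricted to variants absent from controls, counts the number
#' of distinct variants and the number of carriers (one carrier per row).
#'
#' @param table Variant observation \code{data.frame}; every row is one
#'   carrier of one variant. Duplicate (individual, variant) rows are an
#'   input error.
#' @return Named integer vector \code{c(n_unique_variants, n_carriers)}.
#' @export
summarize_patient_only <- function(table) {
  if (nrow(table) == 0L) {
    return(c(n_unique_variants = 0L, n_carriers = 0L))
  }
  key <- paste(table$individual_id, table$variant_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (individual_id, variant_id) rows", call. = FALSE)
  }
  c(n_unique_variants = length(unique(table$variant_id)),
    n_carriers = nrow(table))
}

#' Serialize a burden result to JSON
#'
#' @param x A \code{burden_result}.
#' @param path Output file path.
#' @export
write_burden_json <- function(x, path) {
  stopifnot(inherits(x, "burden_result"))
  out <- unclass(x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
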