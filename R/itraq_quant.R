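# 8-plex isobaric reporter-ion quantification: channel design handling, the
# eight-channel completeness filter, PSM-to-protein log2 ratio aggregation
# and the +/- 2 SD differential-significance rule.

VALID_CHANNELS <- c("113", "114", "115", "116", "117", "118", "119", "121")

#' Define an 8-plex channel design
#'
#' Maps each of the eight isobaric labels (113-119 and 121; label 120 is not
#' part of the 8-plex kit) to a sample group. The default reproduces a
#' 3-control / 1-FLNC / 2-GRN / 2-VCP brain-tissue layout: controls on
#' 113-115, FLNC on 116, GRN on 117-118, VCP on 119 and 121.
#'
#' @param group_of Named character vector: names are channel labels, values
#'   are group names. Must cover exactly the eight valid labels and include a
#'   non-empty \code{control} group.
#' @return A \code{channel_design} object (list with \code{channels} and
#'   \code{group_of}).
#' @export
channel_design <- function(group_of = c(
  "113" = "control", "114" = "control", "115" = "control",
  "116" = "FLNC", "117" = "GRN", "118" = "GRN",
  "119" = "VCP", "121" = "VCP")) {
  chans <- names(group_of)
  if (length(group_of) != 8L || !setequal(chans, VALID_CHANNELS)) {
    stop("design must map exactly the 8 labels ",
         paste(VALID_CHANNELS, collapse = ", "),
         " (label 120 does not exist in the 8-plex kit)", call. = FALSE)
  }
  if (!any(group_of == "control")) {
    stop("design must contain a non-empty control group", call. = FALSE)
  }
  group_of <- group_of[VALID_CHANNELS]  # canonical order
  structure(list(channels = VALID_CHANNELS, group_of = unname(group_of)),
            class = "channel_design")
}

#' Read / write a channel design as JSON
#'
#' The file holds one object mapping channel label to group, e.g.
#' \code{\{"113": "control", ...\}}.
#'
#' @param path File path.
#' @return [read_channel_design()] returns a \code{channel_design}.
#' @export
read_channel_design <- function(path) {
  m <- jsonlite::fromJSON(path)
  channel_design(unlist(m))
}

#' @rdname read_channel_design
#' @param design A \code{channel_design}.
#' @export
write_channel_design <- function(design, path) {
  stopifnot(inherits(design, "channel_design"))
  m <- as.list(stats::setNames(design$group_of, design$channels))
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a PSM table
#'
#' Tab-separated with header \code{peptide}, \code{protein} and one intensity
#' column per channel (\code{i113} ... \code{i121}); empty cells are missing
#' intensities.
#'
#' @param path Path to the TSV file.
#' @return PSM \code{data.frame}.
#' @export
read_psms <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("peptide", "protein", paste0("i", VALID_CHANNELS))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("PSM table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df
}

intensity_cols <- function(design) paste0("i", design$channels)

#' Keep only PSMs with all eight reporter channels
#'
#' Retains exactly the PSMs whose eight reporter intensities are present and
#' strictly positive (the completeness rule for quantification); input order
#' is preserved.
#'
#' @param psms PSM \code{data.frame}.
#' @param design A [channel_design()].
#' @return Filtered PSM \code{data.frame}.
#' @export
filter_psms <- function(psms, design) {
  stopifnot(inherits(design, "channel_design"))
  cols <- intensity_cols(design)
  missing_cols <- setdiff(cols, names(psms))
  if (length(missing_cols)) {
    stop("PSM table lacks channel column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- grep("^i[0-9]+$", names(psms), value = TRUE)
  unknown <- setdiff(extra, cols)
  if (length(unknown)) {
    stop("PSM table references unknown channel(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(psms[, cols])
  keep <- rowSums(is.na(m) | m <= 0) == 0L
  psms[keep, , drop = FALSE]
}

geomean <- function(x) exp(mean(log(x)))

#' Protein-level log2 ratios per comparison group
#'
#' For each PSM and each non-control group, the ratio is the geometric mean
#' of the group's reporter channels over the geometric mean of the control
#' channels; the protein-level estimate is the median (or mean) over its
#' PSMs of the log2 ratios. The result is independent of PSM row order and
#' of any uniform rescaling of a PSM's channels.
#'
#' @param psms Filtered PSM \code{data.frame} (see [filter_psms()]).
#' @param design A [channel_design()].
#' @param aggregate \code{"median"} (default, robust) or \code{"mean"}.
#' @return \code{data.frame} with columns \code{protein}, \code{comparison},
#'   \code{log2_ratio}, \code{n_psms}.
#' @export
quantify_proteins <- function(psms, design, aggregate = c("median", "mean")) {
  stopifnot(inherits(design, "channel_design"))
  aggregate <- match.arg(aggregate)
  if (nrow(psms) == 0L) {
    return(data.frame(protein = character(), comparison = character(),
                      log2_ratio = numeric(), n_psms = integer(),
                      stringsAsFactors = FALSE))
  }
  cols <- intensity_cols(design)
  m <- as.matrix(psms[, cols])
  if (anyNA(m) || any(m <= 0)) {
    stop("quantify_proteins() expects filtered PSMs (all 8 channels > 0); ",
         "run filter_psms() first", call. = FALSE)
  }
  logm <- log2(m)
  ctrl <- design$group_of == "control"
  ctrl_mean <- rowMeans(logm[, ctrl, drop = FALSE])
  groups <- setdiff(unique(design$group_of), "control")
  agg_fun <- if (aggregate == "median") stats::median else mean
  out <- do.call(rbind, lapply(groups, function(g) {
    grp_mean <- rowMeans(logm[, design$group_of == g, drop = FALSE])
    lr <- grp_mean - ctrl_mean  # log2 of geometric-mean ratio
    agg <- tapply(lr, psms$protein, agg_fun)
    data.frame(protein = names(agg), comparison = g,
               log2_ratio = as.numeric(agg),
               n_psms = as.integer(table(psms$protein)[names(agg)]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$comparison, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call differentially regulated proteins by the 2-SD rule
#'
#' Per comparison, computes the mean and sample standard deviation (n - 1
#' denominator) of the protein log2 ratios and flags proteins whose ratio
#' deviates from the mean by strictly more than \code{z_threshold} standard
#' deviations (boundary values are not significant). Direction is relative
#' to the comparison mean: \code{up} above it, \code{down} below it; proteins
#' not significant get direction \code{none}.
#'
#' @param quants Output of [quantify_proteins()].
#' @param z_threshold Significance limit in SD units (default 2, i.e. the
#'   approximate 95\% confidence limits of the ratio distribution).
#' @return \code{quants} with added columns \code{z_score},
#'   \code{significant}, \code{direction}.
#' @export
call_differential <- function(quants, z_threshold = 2) {
  stopifnot(is.data.frame(quants), z_threshold > 0)
  quants$z_score <- NA_real_
  quants$significant <- FALSE
  quants$direction <- "none"
  for (g in unique(quants$comparison)) {
    idx <- quants$comparison == g
    x <- quants$log2_ratio[idx]
    if (sum(idx) < 3L) {
      warning("comparison ", g, " has < 3 proteins; no calls made")
      next
    }
    mu <- mean(x)
    sigma <- stats::sd(x)
    if (sigma == 0) {
      warning("zero ratio dispersion in comparison ", g, "; no calls made")
      quants$z_score[idx] <- 0
      next
    }
    z <- (x - mu) / sigma
    sig <- abs(z) > z_threshold
    quants$z_score[idx] <- z
    quants$significant[idx] <- sig
    quants$direction[idx] <- ifelse(sig, ifelse(z > 0, "up", "down"), "none")
  }
  quants
}

#' Write a protein-quant table as TSV
#'
#' @param quants Output of [call_differential()].
#' @param path Output path.
#' @export
write_quants <- function(quants, path) {
  utils::write.table(quants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
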