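# Venn-style partition of per-comparison significant protein lists into the
# 7 regions of a 3-set diagram, with up/down/contra regulation classes, and
# extraction of the common coherent core and the per-comparison unique sets.

#' Partition significant proteins across comparisons
#'
#' Assigns every significant protein to the exact set of comparisons in
#' which it is significant (one of the 7 regions of a 3-set Venn diagram)
#' and classifies its regulation: \code{up} or \code{down} when all its
#' directions agree, \code{contra} when any two comparisons disagree (one
#' disagreeing pair suffices to break coherence).
#'
#' @param sig Named list, one element per comparison, each a
#'   \code{data.frame} with columns \code{protein} and \code{direction}
#'   (values \code{up}/\code{down}; \code{none} is an input error). Typically
#'   built by splitting the significant rows of [call_differential()] by
#'   comparison.
#' @return A \code{venn_partition}: a \code{data.frame} with columns
#'   \code{protein}, \code{region} (comparison names joined by \code{"+"},
#'   in the input's comparison order), \code{n_regions} and \code{class},
#'   plus attribute \code{comparisons}.
#' @export
venn_partition <- function(sig) {
  stopifnot(is.list(sig), !is.null(names(sig)), all(nzchar(names(sig))))
  comparisons <- names(sig)
  for (g in comparisons) {
    df <- sig[[g]]
    stopifnot(is.data.frame(df), all(c("protein", "direction") %in% names(df)))
    if (anyDuplicated(df$protein)) {
      stop("duplicate proteins in significant list for ", g, call. = FALSE)
    }
    if (any(!df$direction %in% c("up", "down"))) {
      stop("direction must be 'up' or 'down' in significant list for ", g,
           call. = FALSE)
    }
  }
  proteins <- unique(unlist(lapply(sig, `[[`, "protein"), use.names = FALSE))
  if (!length(proteins)) {
    out <- data.frame(protein = character(), region = character(),
                      n_regions = integer(), class = character(),
                      stringsAsFactors = FALSE)
    attr(out, "comparisons") <- comparisons
    class(out) <- c("venn_partition", class(out))
    return(out)
  }
  membership <- sapply(comparisons, function(g) proteins %in% sig[[g]]$protein)
  membership <- matrix(membership, nrow = length(proteins),
                       dimnames = list(proteins, comparisons))
  dir_of <- sapply(comparisons, function(g) {
    d <- sig[[g]]
    d$direction[match(proteins, d$protein)]
  })
  dir_of <- matrix(dir_of, nrow = length(proteins),
                   dimnames = list(proteins, comparisons))
  region <- apply(membership, 1, function(m) {
    paste(comparisons[m], collapse = "+")
  })
  cls <- vapply(seq_along(proteins), function(i) {
    d <- dir_of[i, membership[i, ]]
    if (length(unique(d)) > 1L) "contra" else unique(d)
  }, character(1))
  out <- data.frame(protein = proteins, region = unname(region),
                    n_regions = unname(rowSums(membership)),
                    class = cls, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "comparisons") <- comparisons
  class(out) <- c("venn_partition", class(out))
  out
}

#' Significant-rows helper: split a called quant table by comparison
#'
#' @param quants Output of [call_differential()].
#' @return Named list of significant-protein \code{data.frame}s suitable for
#'   [venn_partition()].
#' @export
significant_sets <- function(quants) {
  sig <- quants[quants$significant, c("protein", "comparison", "direction")]
  split(sig[, c("protein", "direction")], sig$comparison)
}

#' Common coherently regulated core
#'
#' Proteins significant in every comparison with agreeing direction (class
#' not \code{contra}).
#'
#' @param partition A [venn_partition()].
#' @return \code{data.frame} with columns \code{protein}, \code{direction}.
#' @export
common_coherent <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  comparisons <- attr(partition, "comparisons")
  keep <- partition$n_regions == length(comparisons) &
    partition$class != "contra"
  data.frame(protein = partition$protein[keep],
             direction = partition$class[keep], stringsAsFactors = FALSE)
}

#' Per-comparison unique protein sets
#'
#' Proteins significant in exactly one comparison, returned per comparison
#' with their direction.
#'
#' @param partition A [venn_partition()].
#' @return Named list of \code{data.frame}s (\code{protein},
#'   \code{direction}), one per comparison, empty where no unique proteins
#'   exist.
#' @export
unique_sets <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  comparisons <- attr(partition, "comparisons")
  out <- lapply(comparisons, function(g) {
    keep <- partition$n_regions == 1L & partition$region == g
    data.frame(protein = partition$protein[keep],
               direction = partition$class[keep], stringsAsFactors = FALSE)
  })
  stats::setNames(out, comparisons)
}

#' Export a Venn partition as JSON
#'
#' Writes the 7 regions with their protein/class assignments.
#'
#' @param partition A [venn_partition()].
#' @param path Output path.
#' @export
write_partition_json <- function(partition, path) {
  stopifnot(inherits(partition, "venn_partition"))
  regions <- split(partition[, c("protein", "class")], partition$region)
  jsonlite::write_json(regions, path, auto_unbox = FALSE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
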