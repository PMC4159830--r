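#' Tags-per-million normalization
#'
#' \code{tpm = count / clean_total * 1e6}, the library-size normalization of
#' DGE tag counts.
#'
#' @param counts numeric vector or matrix of tag counts.
#' @param cleanTotal clean-tag library size(s); for a matrix, one per column.
#' @return numeric of the same shape as \code{counts}.
#' @export
tpmNormalize <- function(counts, cleanTotal) {
  if (any(cleanTotal < 1)) stop("'cleanTotal' must be >= 1", call. = FALSE)
  if (is.matrix(counts)) {
    if (length(cleanTotal) != ncol(counts)) {
      stop("one clean total per column required", call. = FALSE)
    }
    sweep(counts, 2, cleanTotal, "/") * 1e6
  } else {
    counts / cleanTotal * 1e6
  }
}

#' Assemble a trio expression container from per-library mapping results
#'
#' Builds a \linkS4class{DgeExperiment} over the full gene universe of the
#' gene map.  The \code{counts} assay holds sense-strand unambiguous tag
#' counts (the expression measure); antisense tallies and per-library
#' mapping summaries are kept in \code{metadata()}.
#'
#' @param mapResults named list of \code{\link{mapTags}} results, typically
#'   \code{list(P = , M = , F1 = )}.
#' @param cleanTotals named numeric of clean-tag totals, same names.
#' @param geneMap data.frame with a \code{gene_id} column defining the gene
#'   universe.
#' @return a \linkS4class{DgeExperiment}.
#' @export
buildExpressionSet <- function(mapResults, cleanTotals, geneMap) {
  libs <- names(mapResults)
  if (is.null(libs) || !setequal(libs, names(cleanTotals))) {
    stop("'mapResults' and 'cleanTotals' must share names", call. = FALSE)
  }
  cleanTotals <- cleanTotals[libs]
  genes <- sort(unique(geneMap$gene_id))
  cnt <- sapply(libs, function(l) {
    gc <- mapResults[[l]]$geneCounts
    out <- setNames(numeric(length(genes)), genes)
    known <- intersect(gc$gene_id, genes)
    out[known] <- gc$count_sense[match(known, gc$gene_id)]
    out
  })
  anti <- sapply(libs, function(l) {
    gc <- mapResults[[l]]$geneCounts
    out <- setNames(numeric(length(genes)), genes)
    known <- intersect(gc$gene_id, genes)
    out[known] <- gc$count_antisense[match(known, gc$gene_id)]
    out
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt, tpm = tpmNormalize(cnt, cleanTotals)),
    colData = S4Vectors::DataFrame(clean_total = unname(cleanTotals),
                                   row.names = libs),
    metadata = list(
      mappingSummary = lapply(mapResults, `[[`, "summary"),
      antisenseCounts = anti)
  )
  methods::new("DgeExperiment", se)
}

#' Genes detected in every library / in any library
#'
#' "Collectively expressed" is the union of genes with at least
#' \code{minCount} sense unambiguous tags across libraries; "expressed in
#' all" is the intersection.
#'
#' @param x a \linkS4class{DgeExperiment}.
#' @param minCount detection floor (tags).
#' @return character vector of gene ids.
#' @export
collectivelyExpressed <- function(x, minCount = 1) {
  cnt <- SummarizedExperiment::assay(x, "counts")
  rownames(cnt)[rowSums(cnt >= minCount) >= 1]
}

#' @rdname collectivelyExpressed
#' @export
expressedInAll <- function(x, minCount = 1) {
  cnt <- SummarizedExperiment::assay(x, "counts")
  rownames(cnt)[rowSums(cnt >= minCount) == ncol(cnt)]
}

#' Sequencing saturation curve
#'
#' Walks a tag stream in order and reports, at every \code{step} tags (plus
#' the final depth), the number of distinct tags seen and (when a library is
#' supplied) the number of genes detected through unambiguous mapping.  Both
#' curves are monotone nondecreasing.
#'
#' @param tags character vector, the tag stream in sequencing order.
#' @param step reporting interval in tags.
#' @param library optional \linkS4class{TagLibrary} for the gene curve.
#' @param maxMismatch mismatch allowance for the gene curve.
#' @return data.frame: \code{depth}, \code{distinct_tags},
#'   \code{genes_detected} (NA without a library).
#' @export
saturationCurve <- function(tags, step, library = NULL, maxMismatch = 1) {
  if (step < 1) stop("'step' must be >= 1", call. = FALSE)
  n <- length(tags)
  at <- unique(c(seq(step, n, by = step), n))
  first <- !duplicated(tags)
  cum_distinct <- cumsum(first)
  out <- data.frame(depth = at, distinct_tags = cum_distinct[at],
                    genes_detected = NA_integer_)
  if (!is.null(library) && n) {
    distinct <- tags[first]
    cts <- methods::new("CleanTagSet",
      tags = data.frame(tag = sort(distinct),
                        count = rep(1L, length(distinct))),
      rawTotal = length(distinct), cleanTotal = length(distinct),
      report = c(empty_tag = 0, bad_length = 0, contains_n = 0,
                 no_catg_prefix = 0))
    asg <- mapTags(cts, library, maxMismatch = maxMismatch)$assignments
    gene_of <- asg$gene_id[match(tags, asg$tag)]
    gene_of[asg$status[match(tags, asg$tag)] != "unambiguous"] <- NA
    newgene <- !is.na(gene_of) & !duplicated(gene_of)
    out$genes_detected <- cumsum(newgene)[at]
  }
  out
}

#' Sense/antisense strand accounting
#'
#' Counts genes detected by unambiguous tags on the sense strand, on the
#' antisense strand, and on both, and reports the presence-based
#' sense:antisense gene ratio (NA when no gene has antisense tags).
#'
#' @param assignments the \code{assignments} data.frame from
#'   \code{\link{mapTags}} (one library).
#' @return list with \code{n_sense}, \code{n_antisense}, \code{n_both} and
#'   \code{ratio}.
#' @export
strandReport <- function(assignments) {
  un <- assignments[assignments$status == "unambiguous", , drop = FALSE]
  sense_g <- unique(un$gene_id[un$strand %in% c("sense", "both")])
  anti_g <- unique(un$gene_id[un$strand %in% c("antisense", "both")])
  list(n_sense = length(sense_g), n_antisense = length(anti_g),
       n_both = length(intersect(sense_g, anti_g)),
       ratio = if (length(anti_g)) length(sense_g) / length(anti_g)
               else NA_real_)
}
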