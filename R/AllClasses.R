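#' Virtual CATG+17 tag library
#'
#' Index of every CATG + 17 nt (21-mer) signature occurring in a reference
#' transcriptome, on both strands.  A tag key is \emph{unambiguous} when all
#' of its hits fall in a single gene; a tag present on both strands of the
#' same gene is still unambiguous.
#'
#' @slot hits data.frame with one row per tag occurrence: \code{tag},
#'   \code{gene_id}, \code{transcript_id}, \code{pos} (0-based start of the
#'   CATG on the indexed strand's sequence), \code{strand}
#'   (\code{"sense"}/\code{"antisense"}).
#' @slot tagInfo data.frame with one row per distinct tag key: \code{tag},
#'   \code{n_genes}, \code{unambiguous}, \code{gene_id} (NA when ambiguous),
#'   \code{sense}, \code{antisense} (logical: strand presence for the
#'   assigned gene; NA when ambiguous).
#'
#' @exportClass TagLibrary
setClass("TagLibrary",
  representation(hits = "data.frame", tagInfo = "data.frame")
)

setValidity("TagLibrary", function(object) {
  msgs <- character()
  tg <- object@tagInfo$tag
  if (length(tg)) {
    if (any(nchar(tg) != 21L)) msgs <- c(msgs, "all tag keys must have length 21")
    if (!all(startsWith(tg, "CATG"))) msgs <- c(msgs, "all tag keys must start with CATG")
    if (anyDuplicated(tg)) msgs <- c(msgs, "tag keys must be unique")
  }
  if (!all(object@hits$strand %in% c("sense", "antisense"))) {
    msgs <- c(msgs, "strand must be 'sense' or 'antisense'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Cleaned tag multiset for one library
#'
#' Distinct 21-mer tags with copy numbers surviving adaptor trimming, the
#' CATG-prefix and length rules, and N filtering, plus the cleaning report.
#'
#' @slot tags data.frame: \code{tag}, \code{count}.
#' @slot rawTotal total number of input reads.
#' @slot cleanTotal total number of clean tags (the library size N used for
#'   TPM and the exact test).
#' @slot report named integer vector of rejection classes:
#'   \code{empty_tag}, \code{contains_n}, \code{bad_length},
#'   \code{no_catg_prefix}.
#'
#' @exportClass CleanTagSet
setClass("CleanTagSet",
  representation(tags = "data.frame", rawTotal = "numeric",
                 cleanTotal = "numeric", report = "numeric")
)

setValidity("CleanTagSet", function(object) {
  msgs <- character()
  if (object@cleanTotal > object@rawTotal) {
    msgs <- c(msgs, "cleanTotal must be <= rawTotal")
  }
  if (nrow(object@tags)) {
    if (nrow(object@tags) > object@cleanTotal) {
      msgs <- c(msgs, "distinct count must be <= cleanTotal")
    }
    if (abs(sum(object@tags$count) - object@cleanTotal) > 1e-8) {
      msgs <- c(msgs, "tag copy numbers must sum to cleanTotal")
    }
    if (any(grepl("[^ACGT]", object@tags$tag))) {
      msgs <- c(msgs, "clean tags must contain only ACGT")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Gene-level tag expression container for a parent/parent/hybrid trio
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{counts} (sense
#' unambiguous tag counts) and \code{tpm} (tags per million clean tags);
#' \code{colData} carries \code{clean_total} per library and the mapping
#' summary lives in \code{metadata(x)$mappingSummary}.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass DgeExperiment
setClass("DgeExperiment", contains = "SummarizedExperiment")

setValidity("DgeExperiment", function(object) {
  msgs <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "tpm") %in% a)) {
    msgs <- c(msgs, "assays 'counts' and 'tpm' are required")
  }
  if (!"clean_total" %in% colnames(SummarizedExperiment::colData(object))) {
    msgs <- c(msgs, "colData column 'clean_total' is required")
  } else if (all(c("counts", "tpm") %in% a)) {
    cnt <- SummarizedExperiment::assay(object, "counts")
    tpm <- SummarizedExperiment::assay(object, "tpm")
    N <- object$clean_total
    if (any(N < 1)) msgs <- c(msgs, "clean_total must be >= 1")
    else {
      expect <- sweep(cnt, 2, N, "/") * 1e6
      if (max(abs(expect - tpm)) > 1e-6) {
        msgs <- c(msgs, "tpm must equal counts / clean_total * 1e6")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})
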