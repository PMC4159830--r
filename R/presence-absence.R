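## Presence-absence expression patterns across the trio and PAV gene
## cross-referencing.

PRESENCE_CLASSES <- c(
  "present_in_all",
  "P_only_present_hybrid", "P_only_absent_hybrid",
  "M_only_present_hybrid", "M_only_absent_hybrid",
  "absent_parents_present_hybrid",
  "present_in_both_parents_other",
  "absent_in_all")

#' Classify genes by detectable-expression pattern across the trio
#'
#' A gene is "present" in a library when its sense unambiguous tag count is
#' at least \code{minCount} (the detection floor; the published analysis
#' used any detected tag, i.e. 1).  The eight classes partition all genes;
#' the presence-absence universe of interest comprises genes absent in at
#' least one parent yet present somewhere in the trio.
#'
#' @param x a \linkS4class{DgeExperiment} with columns "P", "M", "F1".
#' @param minCount presence threshold in tags (>= 1).
#' @return data.frame per gene: \code{gene_id}, \code{present_P},
#'   \code{present_M}, \code{present_F1}, \code{class}.
#' @export
classifyPresence <- function(x, minCount = 1) {
  stopifnot(all(c("P", "M", "F1") %in% colnames(x)), minCount >= 1)
  cnt <- SummarizedExperiment::assay(x, "counts")
  p <- cnt[, "P"] >= minCount
  m <- cnt[, "M"] >= minCount
  f1 <- cnt[, "F1"] >= minCount
  cls <- ifelse(p & m & f1, "present_in_all",
         ifelse(p & !m & f1, "P_only_present_hybrid",
         ifelse(p & !m & !f1, "P_only_absent_hybrid",
         ifelse(!p & m & f1, "M_only_present_hybrid",
         ifelse(!p & m & !f1, "M_only_absent_hybrid",
         ifelse(!p & !m & f1, "absent_parents_present_hybrid",
         ifelse(p & m & !f1, "present_in_both_parents_other",
                "absent_in_all")))))))
  data.frame(gene_id = rownames(cnt), present_P = p, present_M = m,
             present_F1 = f1, class = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Presence-absence summary table (hybrid x parental-pattern cells)
#'
#' Cross-tabulates genes absent in at least one parent (but present
#' somewhere in the trio) by hybrid presence, with column totals,
#' percentages of the summary universe, a grand total, and the
#' hybrid present:absent ratio per parental pattern.
#'
#' @param presence output of \code{\link{classifyPresence}}, or a named
#'   numeric vector of the six cell counts
#'   (\code{P_only_present_hybrid}, \code{P_only_absent_hybrid},
#'   \code{M_only_present_hybrid}, \code{M_only_absent_hybrid},
#'   \code{absent_parents_present_hybrid}, and optionally
#'   \code{absent_in_all} which contributes 0).
#' @return list with \code{table} (rows: hybrid present/absent/total;
#'   columns: present-in-P-only, present-in-M-only, absent-in-both-parents;
#'   plus \code{pct_*} columns as percent of the universe), \code{total}
#'   (the universe size) and \code{hybrid_ratio} (present:absent ratio per
#'   parental pattern, NA when no gene is absent in the hybrid).
#' @export
presenceSummary <- function(presence) {
  if (is.data.frame(presence)) {
    cellcount <- function(k) sum(presence$class == k)
  } else {
    cellcount <- function(k) {
      v <- presence[k]
      if (is.na(v)) 0 else unname(v)
    }
  }
  cells <- matrix(c(
    cellcount("P_only_present_hybrid"), cellcount("M_only_present_hybrid"),
    cellcount("absent_parents_present_hybrid"),
    cellcount("P_only_absent_hybrid"), cellcount("M_only_absent_hybrid"),
    0), nrow = 2, byrow = TRUE,
    dimnames = list(c("present_in_hybrid", "absent_in_hybrid"),
                    c("P_only", "M_only", "absent_both_parents")))
  coltot <- colSums(cells)
  total <- sum(cells)
  tab <- rbind(cells, total = coltot)
  pct <- if (total > 0) tab / total * 100 else tab * NA_real_
  colnames(pct) <- paste0("pct_", colnames(tab))
  ratio <- ifelse(cells[2, ] > 0, cells[1, ] / cells[2, ], NA_real_)
  list(table = cbind(as.data.frame(tab), as.data.frame(pct)),
       total = total, hybrid_ratio = ratio)
}

#' Cross-reference a presence/absence-variation (PAV) gene list
#'
#' For each gene of a PAV list (genes present in one parental genome and
#' absent from the other), reports whether it was detected by tags at all,
#' its trio presence pattern, where the hybrid's expression sits relative to
#' the parents (in TPM), whether it shows the single-parent-plus-hybrid
#' complementation pattern, and its gene-action category when classified.
#'
#' @param presence output of \code{\link{classifyPresence}}.
#' @param x the \linkS4class{DgeExperiment}.
#' @param pavList data.frame: \code{gene_id}, \code{present_in_genome}
#'   (\code{"P"} or \code{"M"}).
#' @param geneAction optional \code{calls} data.frame from
#'   \code{\link{callGeneAction}}.
#' @return list with \code{report} (one row per resolvable PAV gene),
#'   \code{unresolved} (ids absent from the experiment) and \code{summary}
#'   (named counts: n_pav, n_detected, pct_detected, n_single_parent_hybrid,
#'   n_hybrid_only, n_not_expressed).
#' @export
pavCrossref <- function(presence, x, pavList, geneAction = NULL) {
  stopifnot(is.data.frame(pavList), "gene_id" %in% names(pavList))
  ids <- unique(pavList$gene_id)
  known <- ids[ids %in% presence$gene_id]
  unresolved <- setdiff(ids, known)
  if (length(unresolved)) {
    warning(length(unresolved), " PAV gene id(s) not in the gene universe")
  }
  pr <- presence[match(known, presence$gene_id), , drop = FALSE]
  tpm <- SummarizedExperiment::assay(x, "tpm")[known, , drop = FALSE]
  detected <- pr$present_P | pr$present_M | pr$present_F1
  relation <- ifelse(!detected, "not_expressed",
    ifelse(tpm[, "F1"] == tpm[, "P"] | tpm[, "F1"] == tpm[, "M"],
           "equal_to_one_parent",
    ifelse(tpm[, "F1"] > pmax(tpm[, "P"], tpm[, "M"]), "above_both",
    ifelse(tpm[, "F1"] < pmin(tpm[, "P"], tpm[, "M"]), "below_both",
           "between"))))
  complement <- pr$class %in% c("P_only_present_hybrid",
                                "M_only_present_hybrid")
  category <- rep(NA_character_, length(known))
  if (!is.null(geneAction)) {
    hit <- match(known, geneAction$gene_id)
    category <- geneAction$category[hit]
  }
  report <- data.frame(
    gene_id = known,
    present_in_genome = pavList$present_in_genome[match(known,
                                                        pavList$gene_id)],
    detected = detected, class = pr$class,
    f1_relation = relation,
    single_parent_plus_hybrid = complement,
    gene_action = category, row.names = NULL, stringsAsFactors = FALSE)
  summary <- c(
    n_pav = length(ids),
    n_detected = sum(detected),
    pct_detected = if (length(ids)) sum(detected) / length(ids) * 100
                   else NA_real_,
    n_single_parent_hybrid = sum(complement),
    n_hybrid_only = sum(pr$class == "absent_parents_present_hybrid"),
    n_not_expressed = sum(!detected))
  list(report = report, unresolved = unresolved, summary = summary)
}
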