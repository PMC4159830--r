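## Mode-of-gene-action classification for an inbred/inbred/hybrid trio:
## additivity, high-/low-parent dominance, over-/under-dominance, other.

GENE_ACTION_CATEGORIES <- c("additivity", "HPD", "LPD", "ODO", "UDO", "other")

#' F1-versus-midparent contrast via a pseudo-library exact test
#'
#' The midparent expectation is materialized as a pseudo-library of size
#' \code{N_MP = round((N_p + N_m)/2)} with counts
#' \code{round((p/N_p + m/N_m)/2 * N_MP)}, and tested against the F1 counts
#' with \code{\link{exactCountTest}}.  Significance for this contrast
#' defaults to the FDR rule alone (\code{lfcThreshold = 0}): a dominant
#' gene's F1 level can never exceed the midparent by 2-fold (the ratio is
#' bounded by \code{2f/(1+f)}), so an absolute-fold filter here would
#' misread all dominance as additivity.
#'
#' @param f1Count,pCount,mCount per-gene tag counts (vectors).
#' @param Nf1,Np,Nm clean-tag library sizes.
#' @param fdrThreshold,lfcThreshold significance rule for this contrast.
#' @param pseudoTags zero-replacement pseudo-count in tags.
#' @param geneIds optional gene identifiers.
#' @return data.frame shaped like \code{\link{callDifferential}} output with
#'   contrast \code{"F1-vs-MP"}; the ratio is F1 over midparent.
#' @export
midparentContrast <- function(f1Count, pCount, mCount, Nf1, Np, Nm,
                              fdrThreshold = 0.001, lfcThreshold = 0,
                              pseudoTags = 0.5, geneIds = NULL) {
  n <- length(f1Count)
  if (length(pCount) != n || length(mCount) != n) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  if (any(f1Count + pCount + mCount == 0)) {
    stop("genes with all-zero counts must be excluded upstream",
         call. = FALSE)
  }
  Nmp <- round((Np + Nm) / 2)
  mpCount <- round((pCount / Np + mCount / Nm) / 2 * Nmp)
  p <- exactCountTest(mpCount, f1Count, Nmp, Nf1)
  tpm_mp <- tpmNormalize(mpCount, Nmp)
  tpm_f1 <- tpmNormalize(f1Count, Nf1)
  lfc <- log2Ratio(tpm_mp, tpm_f1, Nmp, Nf1, pseudoTags)
  fdr <- bhAdjust(p)
  sig <- significanceCall(fdr, lfc, fdrThreshold, lfcThreshold)
  data.frame(
    gene_id = geneIds %||% as.character(seq_len(n)),
    contrast = "F1-vs-MP",
    count_den = mpCount, count_num = f1Count,
    N_den = Nmp, N_num = Nf1,
    tpm_den = tpm_mp, tpm_num = tpm_f1,
    log2_ratio = lfc, p_value = p, fdr = fdr,
    significant = sig$significant, direction = sig$direction,
    row.names = NULL, stringsAsFactors = FALSE)
}

patternString <- function(category, f1vp_sig, f1vm_sig, pvm_sig,
                          tpmP, tpmM, labels) {
  P <- labels[["P"]]; M <- labels[["M"]]; F1 <- labels[["F1"]]
  ap <- "\u2248"
  # ascending parent pair; exact tie lists P first
  if (tpmP > tpmM) { lo <- M; hi <- P } else { lo <- P; hi <- M }
  psep <- if (isTRUE(pvm_sig)) "<" else ap
  switch(category,
    additivity = paste(F1, ap, "midparent"),
    HPD = paste(lo, "<", F1, ap, hi),
    LPD = paste(lo, ap, F1, "<", hi),
    ODO = paste(lo, psep, hi, "<", F1),
    UDO = paste(F1, "<", lo, psep, hi),
    other = if (f1vp_sig && f1vm_sig) paste(lo, "<", F1, "<", hi)
            else paste(F1, "vs", lo, psep, hi, "(mixed)")
  )
}

#' Classify per-gene mode of gene action from three contrasts
#'
#' Decision order: (1) F1 not significantly different from the midparent:
#' additivity; (2) F1 significantly above both parents: over-dominance
#' (ODO); (3) significantly below both: under-dominance (UDO); (4)
#' significant against exactly one parent: high-parent dominance (HPD) when
#' the parent F1 matches is the higher-expressed one, low-parent dominance
#' (LPD) when it is the lower (parents ranked by TPM; an exact tie goes to
#' "other"); (5) anything else (e.g. strictly intermediate between
#' significantly different parents): other.
#'
#' @param f1vp,f1vm calls from \code{\link{callDifferential}} for F1 vs each
#'   parent, row-aligned on the same genes.
#' @param f1vmp call from \code{\link{midparentContrast}}, row-aligned.
#' @param pvm optional parent-vs-parent call used only for the pattern
#'   string.
#' @param parentLabels display names for the pattern string.
#' @return data.frame: \code{gene_id}, \code{category}, \code{pattern}.
#' @export
classifyGeneAction <- function(f1vp, f1vm, f1vmp, pvm = NULL,
                               parentLabels = c(P = "B73", M = "Mo17",
                                                F1 = "F1")) {
  if (!identical(f1vp$gene_id, f1vm$gene_id) ||
      !identical(f1vp$gene_id, f1vmp$gene_id)) {
    stop("contrast tables must be aligned on the same genes", call. = FALSE)
  }
  okp <- grepl("-vs-P$", f1vp$contrast[1] %||% "F1-vs-P")
  okm <- grepl("-vs-M$", f1vm$contrast[1] %||% "F1-vs-M")
  okmp <- all(f1vmp$contrast == "F1-vs-MP")
  if (!(okp && okm && okmp)) {
    stop("contrast labels inconsistent with (F1-vs-P, F1-vs-M, F1-vs-MP)",
         call. = FALSE)
  }
  if (!all(c("P", "M", "F1") %in% names(parentLabels))) {
    parentLabels <- c(parentLabels, F1 = "F1")
  }
  n <- nrow(f1vp)
  tpmP <- f1vp$tpm_den
  tpmM <- f1vm$tpm_den
  sp <- f1vp$significant; sm <- f1vm$significant
  up_p <- sp & f1vp$direction == "up"; dn_p <- sp & f1vp$direction == "down"
  up_m <- sm & f1vm$direction == "up"; dn_m <- sm & f1vm$direction == "down"
  category <- character(n)
  for (i in seq_len(n)) {
    category[i] <-
      if (!f1vmp$significant[i]) "additivity"
      else if (up_p[i] && up_m[i]) "ODO"
      else if (dn_p[i] && dn_m[i]) "UDO"
      else if (xor(sp[i], sm[i])) {
        if (tpmP[i] == tpmM[i]) "other"
        else {
          matched_is_high <- if (sp[i]) tpmM[i] > tpmP[i] else tpmP[i] > tpmM[i]
          if (matched_is_high) "HPD" else "LPD"
        }
      } else "other"
  }
  pattern <- vapply(seq_len(n), function(i) {
    patternString(category[i], sp[i], sm[i],
                  if (is.null(pvm)) NA else pvm$significant[i],
                  tpmP[i], tpmM[i], parentLabels)
  }, character(1))
  data.frame(gene_id = f1vp$gene_id, category = category, pattern = pattern,
             stringsAsFactors = FALSE)
}

#' Full gene-action analysis of a trio experiment
#'
#' Runs the three pairwise contrasts (F1 vs P, F1 vs M, P vs M), restricts
#' to the differential universe (genes significant in at least one pairwise
#' contrast), computes the midparent contrast over that universe, and
#' classifies every universe gene.
#'
#' @param x a \linkS4class{DgeExperiment} with columns "P", "M", "F1".
#' @param fdrThreshold,lfcThreshold pairwise significance rule.
#' @param mpLfcThreshold fold cutoff for the midparent contrast (default 0;
#'   see \code{\link{midparentContrast}}).
#' @param pseudoTags zero-replacement pseudo-count in tags.
#' @param parentLabels display names for pattern strings.
#' @return list with \code{calls} (per-gene category, pattern, and the
#'   underlying contrast statistics), \code{contrasts} (the three pairwise
#'   call tables) and \code{summary} (\code{\link{summarizeGeneAction}}).
#' @export
callGeneAction <- function(x, fdrThreshold = 0.001, lfcThreshold = 1,
                           mpLfcThreshold = 0, pseudoTags = 0.5,
                           parentLabels = c(P = "B73", M = "Mo17",
                                            F1 = "F1")) {
  stopifnot(all(c("P", "M", "F1") %in% colnames(x)))
  f1vp <- callDifferential(x, "F1", "P", fdrThreshold, lfcThreshold,
                           pseudoTags)
  f1vm <- callDifferential(x, "F1", "M", fdrThreshold, lfcThreshold,
                           pseudoTags)
  pvm <- callDifferential(x, "P", "M", fdrThreshold, lfcThreshold,
                          pseudoTags)
  sig_any <- unique(c(f1vp$gene_id[f1vp$significant],
                      f1vm$gene_id[f1vm$significant],
                      pvm$gene_id[pvm$significant]))
  universe <- sort(sig_any)
  cnt <- SummarizedExperiment::assay(x, "counts")[universe, , drop = FALSE]
  N <- setNames(x$clean_total, colnames(x))
  f1vmp <- midparentContrast(cnt[, "F1"], cnt[, "P"], cnt[, "M"],
                             N["F1"], N["P"], N["M"],
                             fdrThreshold = fdrThreshold,
                             lfcThreshold = mpLfcThreshold,
                             pseudoTags = pseudoTags, geneIds = universe)
  align <- function(tab) tab[match(universe, tab$gene_id), , drop = FALSE]
  f1vp_u <- align(f1vp); f1vm_u <- align(f1vm); pvm_u <- align(pvm)
  rownames(f1vp_u) <- rownames(f1vm_u) <- rownames(pvm_u) <- NULL
  calls <- classifyGeneAction(f1vp_u, f1vm_u, f1vmp, pvm = pvm_u,
                              parentLabels = parentLabels)
  stats <- function(tab, prefix) {
    out <- tab[, c("log2_ratio", "p_value", "fdr", "significant")]
    names(out) <- paste0(prefix, "_", names(out))
    out
  }
  calls <- cbind(calls, stats(f1vp_u, "F1vP"), stats(f1vm_u, "F1vM"),
                 stats(f1vmp, "F1vMP"))
  list(calls = calls,
       contrasts = list(F1vP = f1vp, F1vM = f1vm, PvM = pvm, F1vMP = f1vmp),
       summary = summarizeGeneAction(calls))
}

#' Gene-action category summary (counts, shares and identities)
#'
#' Builds the standard reporting table from per-gene calls or from a named
#' count vector: total tested genes, additivity, non-additivity (the sum of
#' HPD, LPD, ODO, UDO and other), each category's count and its percentage
#' of the total.
#'
#' @param calls data.frame with a \code{category} column, or a named numeric
#'   vector of category counts (names among
#'   \code{additivity, HPD, LPD, ODO, UDO, other}).
#' @return data.frame: \code{class}, \code{n}, \code{pct} (percent of
#'   total, unrounded).
#' @export
summarizeGeneAction <- function(calls) {
  if (is.data.frame(calls)) {
    counts <- table(factor(calls$category, levels = GENE_ACTION_CATEGORIES))
    counts <- setNames(as.numeric(counts), names(counts))
  } else {
    counts <- setNames(numeric(length(GENE_ACTION_CATEGORIES)),
                       GENE_ACTION_CATEGORIES)
    if (!all(names(calls) %in% GENE_ACTION_CATEGORIES)) {
      stop("unknown category name in counts", call. = FALSE)
    }
    counts[names(calls)] <- calls
  }
  nonadd <- sum(counts[c("HPD", "LPD", "ODO", "UDO", "other")])
  total <- counts[["additivity"]] + nonadd
  n <- c(total = total, additivity = counts[["additivity"]],
         non_additivity = nonadd, counts[c("HPD", "LPD", "ODO", "UDO",
                                           "other")])
  data.frame(class = names(n), n = unname(n),
             pct = if (total > 0) unname(n) / total * 100 else NA_real_,
             stringsAsFactors = FALSE)
}
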