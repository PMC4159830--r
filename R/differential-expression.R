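## Audic-Claverie exact test for tag counts from two libraries, BH control,
## log2 expression ratios, and the per-contrast significance rule.

## log pmf of the conditional distribution p(j | a) for library-size ratio
## r = Nb/Na:  p(j|a) = r^j (a+j)! / (a! j! (1+r)^(a+j+1))
acLogPmf <- function(j, a, logr, log1pr) {
  j * logr + lgamma(a + j + 1) - lgamma(a + 1) - lgamma(j + 1) -
    (a + j + 1) * log1pr
}

## Two-sided p for one (x, y, N1, N2) quadruple, canonical orientation
## already applied (we condition on count `a` from library `Na`).
acTwoSided1 <- function(a, b, Na, Nb) {
  r <- Nb / Na
  logr <- log(r)
  log1pr <- log1p(r)
  mu <- r * (a + 1)                      # mean of the conditional law
  sdv <- sqrt(r * (a + 1) * (1 + r))
  if (b <= mu) {
    loglower <- logSumExp(acLogPmf(0:b, a, logr, log1pr))
    plower <- exp(loglower)
    pupper <- 1 - plower + exp(acLogPmf(b, a, logr, log1pr))
  } else {
    jend <- ceiling(b + 20 * sdv + 50)
    logupper <- logSumExp(acLogPmf(b:jend, a, logr, log1pr))
    pupper <- exp(logupper)
    plower <- 1 - pupper + exp(acLogPmf(b, a, logr, log1pr))
  }
  min(1, 2 * min(plower, pupper))
}

#' Exact two-library tag-count test (Audic-Claverie)
#'
#' Tests whether counts \code{x} (library size \code{N1}) and \code{y}
#' (library size \code{N2}) of the same gene are compatible with equal
#' expression, using the conditional law
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}}
#' evaluated in log-gamma space.  The two-sided p doubles the smaller tail
#' (point mass included), capped at 1.  The computation conditions on the
#' smaller of the two counts (ties broken towards the larger library), a
#' canonical orientation that makes the result exactly invariant under
#' swapping \code{(x, N1)} with \code{(y, N2)}.
#'
#' @param x,y nonnegative integer counts (vectorized).
#' @param N1,N2 library sizes (>= 1).
#' @return vector of two-sided p-values in (0, 1].
#' @export
exactCountTest <- function(x, y, N1, N2) {
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  if (any(x < 0 | y < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(N1 < 1 | N2 < 1)) stop("library sizes must be >= 1", call. = FALSE)
  vapply(seq_len(n), function(i) {
    swap <- y[i] < x[i] || (y[i] == x[i] && N2[i] > N1[i])
    if (swap) acTwoSided1(y[i], x[i], N2[i], N1[i])
    else acTwoSided1(x[i], y[i], N1[i], N2[i])
  }, numeric(1))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted values \code{q_(i) = min_{j >= i} p_(j) m / j}, capped at
#' 1 and mapped back to input order (delegates to
#' \code{stats::p.adjust(method = "BH")}).
#'
#' @param p vector of p-values in [0, 1].
#' @return FDR-adjusted values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' log2 expression ratio with zero-count pseudo-tags
#'
#' \code{log2((tpmB + pseudoB) / (tpmA + pseudoA))}, where the pseudo value
#' (the TPM of \code{pseudoTags} tags in the corresponding library) is added
#' only to sides that are exactly zero.  Genes with both sides zero should be
#' excluded upstream.
#'
#' @param tpmA,tpmB TPM values (vectorized); the ratio is B over A.
#' @param cleanTotalA,cleanTotalB clean-tag library sizes used to convert
#'   \code{pseudoTags} to TPM.
#' @param pseudoTags pseudo-count in tags (default 0.5).
#' @return vector of log2 ratios.
#' @export
log2Ratio <- function(tpmA, tpmB, cleanTotalA = 1e6, cleanTotalB = 1e6,
                      pseudoTags = 0.5) {
  if (any(tpmA < 0 | tpmB < 0)) stop("TPM must be nonnegative", call. = FALSE)
  pa <- pseudoTags / cleanTotalA * 1e6
  pb <- pseudoTags / cleanTotalB * 1e6
  log2((tpmB + pb * (tpmB == 0)) / (tpmA + pa * (tpmA == 0)))
}

significanceCall <- function(fdr, lfc, fdrThreshold, lfcThreshold) {
  sig <- fdr <= fdrThreshold & abs(lfc) >= lfcThreshold
  direction <- ifelse(!sig, "none", ifelse(lfc > 0, "up", "down"))
  list(significant = sig, direction = direction)
}

#' Differential-expression calls for one pairwise contrast
#'
#' Tests every gene with a nonzero count in at least one of the two
#' libraries with \code{\link{exactCountTest}}, adjusts with
#' \code{\link{bhAdjust}} across all tested genes of the contrast, and
#' applies the significance rule \code{FDR <= fdrThreshold} and
#' \code{|log2 ratio| >= lfcThreshold}.  The ratio is numerator over
#' denominator.
#'
#' @param x a \linkS4class{DgeExperiment}.
#' @param numerator,denominator column names of \code{x} (e.g. "F1", "P").
#' @param fdrThreshold FDR cutoff (default 0.001, the stringent published
#'   rule; 0.05 is the other convention in circulation).
#' @param lfcThreshold |log2 ratio| cutoff (default 1).
#' @param pseudoTags zero-replacement pseudo-count in tags.
#' @return data.frame with one row per tested gene: \code{gene_id},
#'   \code{contrast}, \code{count_den}, \code{count_num}, \code{N_den},
#'   \code{N_num}, \code{tpm_den}, \code{tpm_num}, \code{log2_ratio},
#'   \code{p_value}, \code{fdr}, \code{significant}, \code{direction}.
#' @export
callDifferential <- function(x, numerator, denominator,
                             fdrThreshold = 0.001, lfcThreshold = 1,
                             pseudoTags = 0.5) {
  if (!all(c(numerator, denominator) %in% colnames(x))) {
    stop("unknown contrast label: ", numerator, " vs ", denominator,
         call. = FALSE)
  }
  cnt <- SummarizedExperiment::assay(x, "counts")
  tpm <- SummarizedExperiment::assay(x, "tpm")
  N <- setNames(x$clean_total, colnames(x))
  a <- cnt[, denominator]; b <- cnt[, numerator]
  keep <- a + b > 0
  a <- a[keep]; b <- b[keep]
  p <- exactCountTest(a, b, N[denominator], N[numerator])
  lfc <- log2Ratio(tpm[keep, denominator], tpm[keep, numerator],
                   N[denominator], N[numerator], pseudoTags)
  fdr <- bhAdjust(p)
  sig <- significanceCall(fdr, lfc, fdrThreshold, lfcThreshold)
  data.frame(
    gene_id = rownames(cnt)[keep],
    contrast = paste0(numerator, "-vs-", denominator),
    count_den = a, count_num = b,
    N_den = unname(N[denominator]), N_num = unname(N[numerator]),
    tpm_den = tpm[keep, denominator], tpm_num = tpm[keep, numerator],
    log2_ratio = lfc, p_value = p, fdr = fdr,
    significant = sig$significant, direction = sig$direction,
    row.names = NULL, stringsAsFactors = FALSE)
}
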