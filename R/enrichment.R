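## Hypergeometric over-representation of gene sets against flat term
## annotations, with BH-corrected p-values and Storey q-values.

#' Hypergeometric upper-tail probability
#'
#' \code{P(X >= k)} when drawing \code{n} genes from a universe of \code{N}
#' of which \code{K} carry the term (exact tail, evaluated in log space via
#' R's stable hypergeometric tail).
#'
#' @param k annotated genes observed in the query set.
#' @param K annotated genes in the universe.
#' @param n query-set size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
  ln <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, ln); K <- rep_len(K, ln)
  n <- rep_len(n, ln); N <- rep_len(N, ln)
  if (any(k < 0 | n < 0 | K < 0 | N < 0) || any(k > n) || any(n > N) ||
      any(K > N) || any(k > K)) {
    stop("require 0 <= k <= min(K, n), n <= N, K <= N", call. = FALSE)
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Storey q-values with fixed-lambda pi0 plug-in
#'
#' Estimates the proportion of true nulls as
#' \code{pi0 = min(1, #\{p > lambda\} / (m (1 - lambda)))} and converts
#' p-values to q-values by the step-up rule
#' \code{q_(i) = min_{j >= i} pi0 m p_(j) / j}, capped at 1.  With
#' \code{pi0 = 1} the q-values coincide exactly with
#' \code{\link{bhAdjust}}.
#'
#' @param p vector of p-values in [0, 1].
#' @param lambda tuning parameter in [0, 1) (default 0.5).
#' @param pi0 optional override of the estimate (e.g. 1 to reduce to BH).
#' @return list with \code{qvalues} (input order) and \code{pi0}.
#' @export
storeyQvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (lambda < 0 || lambda >= 1) stop("'lambda' must be in [0, 1)",
                                      call. = FALSE)
  m <- length(p)
  if (is.null(pi0)) {
    n_above <- sum(p > lambda)
    if (n_above == 0L) {
      warning("no p-values above lambda; falling back to pi0 = 1")
      pi0 <- 1
    } else {
      pi0 <- min(1, n_above / (m * (1 - lambda)))
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m / (m:1) * p[o]))[ro]
  list(qvalues = q, pi0 = pi0)
}

#' Term over-representation analysis of a gene set
#'
#' Hypergeometric upper-tail test of every annotation term with at least
#' one query hit, against the supplied gene universe.  Both BH-adjusted
#' p-values and Storey q-values are always computed; the \code{significant}
#' column follows \code{method} (BH for GO-style analyses, Storey q for
#' pathway-style analyses, both at \code{alpha}).
#'
#' @param queryGenes character vector of gene ids (duplicates collapse).
#' @param annotation data.frame: \code{gene_id}, \code{term_id}.
#' @param universeGenes character vector defining the testable universe;
#'   query genes outside it are dropped with a warning.
#' @param termNames optional data.frame: \code{term_id}, \code{term_name}.
#' @param method "BH" or "storey".
#' @param alpha significance level on the chosen scale.
#' @param lambda Storey tuning parameter.
#' @return data.frame sorted by p: \code{term_id}, \code{term_name},
#'   \code{K}, \code{n}, \code{k}, \code{N}, \code{p_value}, \code{fdr},
#'   \code{q_value}, \code{pi0}, \code{significant}.
#' @export
enrichTerms <- function(queryGenes, annotation, universeGenes,
                        termNames = NULL, method = c("BH", "storey"),
                        alpha = 0.05, lambda = 0.5) {
  method <- match.arg(method)
  universe <- unique(universeGenes)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  query <- unique(queryGenes)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  ann <- unique(annotation[annotation$gene_id %in% universe,
                           c("gene_id", "term_id")])
  N <- length(universe)
  n <- length(query)
  Ktab <- table(ann$term_id)
  ktab <- table(ann$term_id[ann$gene_id %in% query])
  terms <- names(ktab)[ktab >= 1]          # only terms with a query hit
  K <- as.numeric(Ktab[terms])
  k <- as.numeric(ktab[terms])
  p <- hypergeomUpperTail(k, K, n, N)
  fdr <- bhAdjust(p)
  st <- storeyQvalues(p, lambda = lambda)
  out <- data.frame(
    term_id = terms,
    term_name = if (is.null(termNames)) NA_character_
                else termNames$term_name[match(terms, termNames$term_id)],
    K = K, n = n, k = k, N = N,
    p_value = p, fdr = fdr, q_value = st$qvalues, pi0 = st$pi0,
    stringsAsFactors = FALSE)
  out$significant <- if (method == "BH") out$fdr < alpha
                     else out$q_value < alpha
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
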