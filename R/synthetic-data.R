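## Synthetic DGE study generator: reference transcriptome, per-gene gene-action
## truth for a parent/parent/hybrid trio, and seeded 35-nt tag libraries.

GENE_ACTION_MODES <- c("additive", "HPD", "LPD", "ODO", "UDO", "other",
                       "absent_in_P", "absent_in_M", "absent_in_both_parents")

#' Default mode mixture for the synthetic trio
#'
#' Proportions of gene-action modes among simulated genes, matching the
#' published B73 x Mo17 ear differential-gene composition (roughly 9\%
#' additive, 23\% high-parent dominant, 30\% low-parent dominant, 13\%
#' over-dominant, 23\% under-dominant, 2\% other).
#'
#' @return named numeric vector summing to 1.
#' @export
defaultModeProportions <- function() {
  c(additive = 0.09, HPD = 0.23, LPD = 0.30, ODO = 0.13, UDO = 0.23,
    other = 0.02)
}

#' Simulate a reference transcriptome with CATG+17 tag structure
#'
#' Generates \code{nGenes} random transcripts.  Each transcript's canonical
#' tag is the 21-mer (\code{CATG} + 17 nt) at the 3'-most CATG site of the
#' sense strand that has at least 17 nt downstream: the fragment an
#' NlaIII/MmeI library would sequence from the bead-bound 3' end.  A fraction
#' \code{fracNoCatg} of genes is constructed (by iterated substitution) to
#' contain no CATG at all; such genes can never be detected by tag
#' sequencing.
#'
#' @param nGenes number of genes (one transcript each).
#' @param lengthRange integer pair, transcript length range in nt.
#' @param gc target GC content.
#' @param fracNoCatg fraction of genes carrying no CATG site.
#' @param seed integer seed; all outputs are byte-identical for a fixed seed.
#' @return list with \code{genes} (data.frame: \code{gene_id},
#'   \code{transcript_id}, \code{length}, \code{n_catg_sites},
#'   \code{canonical_tag}, \code{canonical_pos} 0-based), \code{sequences}
#'   (named \link[Biostrings]{DNAStringSet}) and \code{geneMap} (data.frame
#'   \code{gene_id}, \code{transcript_id}).
#' @export
simulateTranscriptome <- function(nGenes, lengthRange = c(300L, 3000L),
                                  gc = 0.47, fracNoCatg = 0.05, seed) {
  if (nGenes < 1L) stop("'nGenes' must be >= 1", call. = FALSE)
  if (fracNoCatg < 0 || fracNoCatg >= 1) {
    stop("'fracNoCatg' must be in [0, 1)", call. = FALSE)
  }
  assertScalarNumber(gc, "gc", 0, 1)
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || any(lengthRange < 25L) ||
      lengthRange[1] > lengthRange[2]) {
    stop("'lengthRange' must be an increasing pair of lengths >= 25",
         call. = FALSE)
  }
  withSeed(seed, {
    lens <- sample(seq(lengthRange[1], lengthRange[2]), nGenes, replace = TRUE)
    seqs <- randomDna(lens, gc)
    n_nocatg <- round(fracNoCatg * nGenes)
    nocatg_idx <- if (n_nocatg > 0) sample(nGenes, n_nocatg) else integer()
    for (i in nocatg_idx) {
      s <- seqs[i]
      repeat {
        hit <- regexpr("CATG", s, fixed = TRUE)
        if (hit == -1L) break
        # knock out the site by replacing its C with a different base
        substr(s, hit, hit) <- sample(c("A", "G", "T"), 1)
      }
      seqs[i] <- s
    }
    with_idx <- setdiff(seq_len(nGenes), nocatg_idx)
    for (i in with_idx) {
      # guarantee at least one CATG with a full 17-nt overhang
      while (!grepl("CATG", substr(seqs[i], 1, lens[i] - 17L), fixed = TRUE)) {
        p <- sample(lens[i] - 20L, 1)
        substr(seqs[i], p, p + 3L) <- "CATG"
      }
    }
    gene_id <- sprintf("GENE%05d", seq_len(nGenes))
    transcript_id <- paste0(gene_id, "_T01")
    sites <- gregexpr("CATG", seqs, fixed = TRUE)
    n_sites <- vapply(sites, function(s) sum(s > 0), integer(1))
    canon <- rep(NA_character_, nGenes)
    canon_pos <- rep(NA_integer_, nGenes)
    for (i in seq_len(nGenes)) {
      el <- sites[[i]][sites[[i]] > 0 & sites[[i]] + 20L <= lens[i]]
      if (length(el)) {
        p <- max(el)
        canon[i] <- substr(seqs[i], p, p + 20L)
        canon_pos[i] <- p - 1L
      }
    }
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- transcript_id
    list(
      genes = data.frame(gene_id = gene_id, transcript_id = transcript_id,
                         length = lens, n_catg_sites = n_sites,
                         canonical_tag = canon, canonical_pos = canon_pos,
                         stringsAsFactors = FALSE),
      sequences = dna,
      geneMap = data.frame(gene_id = gene_id, transcript_id = transcript_id,
                           stringsAsFactors = FALSE)
    )
  })
}

## Per-gene trio expression pattern for one mode.  `b` is the gene's base
## abundance, `f` the fold effect, `phigh` TRUE when P is the high parent.
## Returns c(P, M, F1); relations are exact by construction.
modePattern <- function(mode, b, f, phigh) {
  lo <- b
  hi <- b * f
  switch(mode,
    additive = {
      pm <- if (phigh) c(hi, lo) else c(lo, hi)
      c(pm, mean(pm))
    },
    HPD = {
      pm <- if (phigh) c(hi, lo) else c(lo, hi)
      c(pm, max(pm))
    },
    LPD = {
      pm <- if (phigh) c(hi, lo) else c(lo, hi)
      c(pm, min(pm))
    },
    ODO = c(b, b, b * f),
    UDO = c(b, b, b / f),
    other = {
      # F1 strictly intermediate yet >= f-fold from either parent and the
      # midparent: parents separated by f^3, F1 one f above the low parent
      pm <- if (phigh) c(b * f^3, b) else c(b, b * f^3)
      c(pm, b * f)
    },
    absent_in_P = c(0, b, b / 2),
    absent_in_M = c(b, 0, b / 2),
    absent_in_both_parents = c(0, 0, b),
    stop("unknown mode: ", mode, call. = FALSE)
  )
}

## Equality-constrained minimum-norm rebalancing: scale whole gene trios by a
## per-stratum factor so that the three genotype totals coincide, leaving all
## within-gene relations untouched.  Returns per-gene factors, or NULL when
## the mode mixture makes equal totals unattainable.
balanceGenotypeTotals <- function(tpm, stratum) {
  S <- vapply(split(seq_len(nrow(tpm)), stratum),
              function(ii) colSums(tpm[ii, , drop = FALSE]), numeric(3))
  if (is.null(dim(S))) S <- matrix(S, nrow = 3)
  target <- rep(mean(rowSums(S)), 3)
  rhs <- target - rowSums(S)
  SS <- S %*% t(S)
  sv <- svd(SS)
  keep <- sv$d > max(sv$d) * 1e-10
  if (!any(keep)) return(NULL)
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  u <- 1 + drop(t(S) %*% (pinv %*% rhs))
  if (any(u <= 0)) return(NULL)
  resid <- S %*% u - target
  if (max(abs(resid)) > 1e-6 * target[1]) return(NULL)
  u[match(stratum, colnames(S))]
}

#' Assign gene-action modes and true TPM profiles to simulated genes
#'
#' Draws a gene-action mode per gene from \code{modeProportions} and
#' constructs true TPM values for the two parents (P, M) and their hybrid
#' (F1) that satisfy the mode definitions exactly: additive genes have
#' F1 = (P+M)/2, dominant genes match one parent, over-/under-dominant genes
#' sit \code{foldEffect}-fold above/below both parents.  Because TPM is a
#' composition (each genotype must total one million), a rebalancing step
#' rescales whole gene trios per mode-orientation stratum so that the three
#' genotype totals agree exactly while every within-gene relation is
#' preserved; mixtures for which equal totals are unattainable (e.g. all
#' genes over-dominant) fall back to independent per-genotype rescaling, in
#' which case relations hold exactly only before rescaling.
#'
#' @param genes the \code{genes} data.frame from
#'   \code{\link{simulateTranscriptome}}.
#' @param modeProportions named vector over modes, summing to 1 (see
#'   \code{\link{defaultModeProportions}}; also supports
#'   \code{absent_in_P}, \code{absent_in_M}, \code{absent_in_both_parents}).
#' @param tpmRange base-abundance range (log-uniform draw), in TPM.
#' @param foldEffect fold separation (>= 2) between "different" expression
#'   levels, guaranteeing |log2 ratio| >= 1.
#' @param seed integer seed.
#' @param rescale rescale each genotype's truth to sum to 1e6 (default).
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{assigned_mode}, \code{true_tpm_P/M/F1}, \code{detectable};
#'   attribute \code{balanced} says whether exact rebalancing succeeded.
#' @export
assignGeneActionProfiles <- function(genes,
                                     modeProportions = defaultModeProportions(),
                                     tpmRange = c(20, 2000), foldEffect = 4,
                                     seed, rescale = TRUE) {
  if (abs(sum(modeProportions) - 1) > 1e-9) {
    stop("'modeProportions' must sum to 1", call. = FALSE)
  }
  if (!all(names(modeProportions) %in% GENE_ACTION_MODES)) {
    stop("unknown mode in 'modeProportions'", call. = FALSE)
  }
  if (foldEffect < 2) stop("'foldEffect' must be >= 2", call. = FALSE)
  if (tpmRange[1] <= 0 || tpmRange[1] > tpmRange[2]) {
    stop("'tpmRange' must be a positive increasing pair", call. = FALSE)
  }
  n <- nrow(genes)
  withSeed(seed, {
    mode <- sample(names(modeProportions), n, replace = TRUE,
                   prob = modeProportions)
    b <- exp(runif(n, log(tpmRange[1]), log(tpmRange[2])))
    phigh <- runif(n) < 0.5
    tpm <- t(vapply(seq_len(n), function(i) {
      modePattern(mode[i], b[i], foldEffect, phigh[i])
    }, numeric(3)))
    colnames(tpm) <- c("P", "M", "F1")
    balanced <- FALSE
    if (rescale) {
      u <- balanceGenotypeTotals(tpm, paste0(mode, ifelse(phigh, "+", "-")))
      if (!is.null(u)) {
        tpm <- tpm * u
        tpm <- tpm * (1e6 / sum(tpm[, "P"]))
        balanced <- TRUE
      } else {
        # mixture cannot have equal totals: rescale genotypes independently
        tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
      }
    }
    out <- data.frame(gene_id = genes$gene_id, assigned_mode = mode,
                      true_tpm_P = tpm[, "P"], true_tpm_M = tpm[, "M"],
                      true_tpm_F1 = tpm[, "F1"],
                      detectable = !is.na(genes$canonical_tag),
                      stringsAsFactors = FALSE)
    attr(out, "balanced") <- balanced
    out
  })
}

#' Draw per-gene tag counts for one library
#'
#' Multinomial sampling of \code{depth} tags over the detectable genes
#' (canonical tag defined, true TPM > 0), with probabilities proportional to
#' the genotype's true TPM.  This is the count marginal of
#' \code{\link{simulateLibrary}}: with a zero error rate the full read path
#' tallies to exactly these counts.
#'
#' @param truth truth table from \code{\link{assignGeneActionProfiles}}.
#' @param genotype one of "P", "M", "F1".
#' @param depth library depth (number of tags).
#' @param seed integer seed.
#' @return named integer vector of sampled counts over all genes.
#' @export
simulateCounts <- function(truth, genotype = c("P", "M", "F1"),
                           depth = 4200000, seed) {
  genotype <- match.arg(genotype)
  if (depth < 1) stop("'depth' must be >= 1", call. = FALSE)
  tpm <- truth[[paste0("true_tpm_", genotype)]]
  ok <- truth$detectable & tpm > 0
  counts <- setNames(integer(nrow(truth)), truth$gene_id)
  if (!any(ok)) return(counts)
  withSeed(seed, {
    counts[ok] <- drop(rmultinom(1, size = depth, prob = tpm[ok] / sum(tpm[ok])))
  })
  counts
}

DEFAULT_ADAPTOR3 <- "TCGTATGCCGTCTTCTGCTTG"

#' Simulate one raw 35-nt tag library
#'
#' Emits \code{depth} reads of 35 nt: the gene's canonical 21-mer tag
#' followed by 14 nt of 3' adaptor.  A per-read Bernoulli draw with
#' probability \code{antisenseFraction} instead takes a CATG+17 tag from the
#' transcript's reverse-complement strand (falling back to the sense tag when
#' the antisense strand has no eligible CATG).  Each base is then substituted
#' independently with probability \code{errorRate}.  Reads are emitted in
#' shuffled order.
#'
#' @param truth truth table from \code{\link{assignGeneActionProfiles}}.
#' @param transcriptome result of \code{\link{simulateTranscriptome}}.
#' @param genotype one of "P", "M", "F1".
#' @param depth number of reads (default 4.2 million, the study depth).
#' @param errorRate per-base substitution probability.
#' @param antisenseFraction per-read antisense probability.
#' @param seed integer seed.
#' @param adaptor3 3' adaptor sequence; its first 14 nt fill the read.
#' @return list with \code{reads} (character vector of 35-mers),
#'   \code{counts} (named per-gene true sampled counts) and
#'   \code{genotype}.
#' @export
simulateLibrary <- function(truth, transcriptome, genotype = c("P", "M", "F1"),
                            depth = 4200000, errorRate = 0.01,
                            antisenseFraction = 0.05, seed,
                            adaptor3 = DEFAULT_ADAPTOR3) {
  genotype <- match.arg(genotype)
  assertScalarNumber(errorRate, "errorRate", 0, 1)
  assertScalarNumber(antisenseFraction, "antisenseFraction", 0, 1)
  genes <- transcriptome$genes
  filler <- substr(adaptor3, 1L, 14L)
  if (nchar(filler) < 14L) stop("'adaptor3' must be >= 14 nt", call. = FALSE)
  withSeed(seed, {
    counts <- {
      tpm <- truth[[paste0("true_tpm_", genotype)]]
      ok <- truth$detectable & tpm > 0
      cnt <- setNames(integer(nrow(truth)), truth$gene_id)
      if (any(ok)) {
        cnt[ok] <- drop(rmultinom(1, depth, tpm[ok] / sum(tpm[ok])))
      }
      cnt
    }
    expressed <- which(counts > 0)
    tags <- rep(genes$canonical_tag[match(names(counts)[expressed],
                                          genes$gene_id)],
                counts[expressed])
    gene_of_read <- rep(names(counts)[expressed], counts[expressed])
    n <- length(tags)
    if (n && antisenseFraction > 0) {
      as_flag <- runif(n) < antisenseFraction
      if (any(as_flag)) {
        as_genes <- unique(gene_of_read[as_flag])
        rcseq <- reverseComplement1(as.character(
          transcriptome$sequences[genes$transcript_id[
            match(as_genes, genes$gene_id)]]))
        as_tags <- lapply(seq_along(as_genes), function(i) {
          s <- rcseq[i]
          el <- gregexpr("CATG", s, fixed = TRUE)[[1]]
          el <- el[el > 0 & el + 20L <= nchar(s)]
          if (!length(el)) return(character())
          substring(s, el, el + 20L)
        })
        names(as_tags) <- as_genes
        for (g in as_genes) {
          ii <- which(as_flag & gene_of_read == g)
          pool <- as_tags[[g]]
          if (length(pool)) {
            tags[ii] <- pool[sample.int(length(pool), length(ii),
                                        replace = TRUE)]
          } # else: antisense strand has no eligible CATG; keep sense tag
        }
      }
    }
    reads <- paste0(tags, filler)
    if (n && errorRate > 0) {
      nerr <- rbinom(n, 35L, errorRate)
      hit <- which(nerr > 0L)
      for (i in hit) {
        pos <- sample.int(35L, nerr[i])
        for (p in pos) {
          old <- substr(reads[i], p, p)
          substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, old), 1)
        }
      }
    }
    if (n) reads <- reads[sample.int(n)]
    list(reads = reads, counts = counts, genotype = genotype)
  })
}

#' Simulate a full parent/parent/hybrid trio of tag libraries
#'
#' Convenience wrapper generating the three libraries from one truth table
#' with genotype-specific sub-seeds derived from \code{seed}.
#'
#' @inheritParams simulateLibrary
#' @return named list of \code{\link{simulateLibrary}} results
#'   (\code{P}, \code{M}, \code{F1}).
#' @export
simulateTrio <- function(truth, transcriptome, depth = 4200000,
                         errorRate = 0.01, antisenseFraction = 0.05, seed,
                         adaptor3 = DEFAULT_ADAPTOR3) {
  gts <- c("P", "M", "F1")
  out <- lapply(seq_along(gts), function(k) {
    simulateLibrary(truth, transcriptome, gts[k], depth = depth,
                    errorRate = errorRate,
                    antisenseFraction = antisenseFraction,
                    seed = as.integer(seed) + k, adaptor3 = adaptor3)
  })
  names(out) <- gts
  out
}
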