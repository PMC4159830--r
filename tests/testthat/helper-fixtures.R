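# Shared in-code fixtures.

# A DgeExperiment straight from a count matrix (columns P, M, F1).
makeTrioExperiment <- function(counts, cleanTotals = colSums(counts)) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts,
                  tpm = tpmNormalize(counts, cleanTotals)),
    colData = S4Vectors::DataFrame(clean_total = unname(cleanTotals),
                                   row.names = colnames(counts)))
  methods::new("DgeExperiment", se)
}

# A CleanTagSet from bare tag sequences with copy numbers.
makeCleanTagSet <- function(tags, counts = rep(1L, length(tags))) {
  o <- order(tags)
  methods::new("CleanTagSet",
    tags = data.frame(tag = tags[o], count = as.integer(counts[o])),
    rawTotal = sum(counts), cleanTotal = sum(counts),
    report = c(empty_tag = 0, bad_length = 0, contains_n = 0,
               no_catg_prefix = 0))
}

# Random CATG-prefixed 21-mers.
randomTags <- function(n, seed) {
  heterosisDGE:::withSeed(seed, {
    vapply(seq_len(n), function(i) {
      paste0("CATG", paste(sample(c("A", "C", "G", "T"), 17, TRUE),
                           collapse = ""))
    }, character(1))
  })
}

# Substitute one position of a tag with a different base.
mutateTag <- function(tag, pos, to = NULL) {
  old <- substr(tag, pos, pos)
  if (is.null(to)) to <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(tag, pos, pos) <- to
  tag
}

# Null trio truth: identical true TPM in all genotypes.
nullTruth <- function(n, seed, tpmRange = c(20, 2000)) {
  heterosisDGE:::withSeed(seed, {
    tpm <- exp(runif(n, log(tpmRange[1]), log(tpmRange[2])))
    tpm <- tpm / sum(tpm) * 1e6
    data.frame(gene_id = sprintf("G%05d", seq_len(n)),
               assigned_mode = "additive",
               true_tpm_P = tpm, true_tpm_M = tpm, true_tpm_F1 = tpm,
               detectable = TRUE, stringsAsFactors = FALSE)
  })
}
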