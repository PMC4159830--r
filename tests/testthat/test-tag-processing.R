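FILL <- substr(heterosisDGE:::DEFAULT_ADAPTOR3, 1, 14)

test_that("read cleaning applies the trim/length/N/prefix rules", {
  tag <- "CATGACGTACGTACGTACGTA"
  reads <- c(
    paste0(tag, FILL),                                   # clean
    paste0(FILL, "ACGTACGTACGTACGTACGTA"),               # adaptor at pos 1
    paste0("CATGACGTACGTNCGTACGTA", FILL),               # N inside tag
    paste0("AATGACGTACGTACGTACGTA", FILL),               # no CATG prefix
    paste0("CATGAC", FILL, "GTACGTACGTACGTA")            # early adaptor
  )
  cts <- extractCleanTags(reads)
  expect_equal(rawTotal(cts), 5)
  expect_equal(cleanTotal(cts), 1)
  expect_identical(tagCounts(cts)$tag, tag)
  rep <- cleaningReport(cts)
  expect_equal(unname(rep["empty_tag"]), 1)
  expect_equal(unname(rep["contains_n"]), 1)
  expect_equal(unname(rep["no_catg_prefix"]), 1)
  expect_equal(unname(rep["bad_length"]), 1)
  # empty stream is a zeroed report, not an error
  e <- extractCleanTags(character())
  expect_equal(cleanTotal(e), 0)
  expect_equal(sum(cleaningReport(e)), 0)
  # reads with no adaptor at all are truncated to 21 nt
  noad <- paste0(tag, "AAAAAAAAAAAAAA")
  expect_equal(tagCounts(extractCleanTags(noad))$tag, tag)
})

test_that("virtual library indexes every eligible CATG on both strands", {
  s <- "AAACATGTTTTTTTTTTTTTTTTTAA"
  dna <- Biostrings::DNAStringSet(c(t1 = s))
  gm <- data.frame(gene_id = "g1", transcript_id = "t1")
  lib <- buildVirtualLibrary(dna, gm)
  # one sense CATG with a full overhang; the reverse complement's CATG sits
  # too close to its end to yield a key
  expect_equal(nTags(lib), 1)
  expect_identical(tagKeys(lib), substr(s, 4, 24))
  expect_identical(tagHits(lib)$strand, "sense")
  expect_equal(tagHits(lib)$pos, 3)        # 0-based
  # a CATG with less than 17 nt downstream is skipped
  lib0 <- buildVirtualLibrary(
    Biostrings::DNAStringSet(c(t1 = "AAACATGTTTTT")), gm)
  expect_equal(nTags(lib0), 0)
  # two genes sharing a 21-mer -> ambiguous key
  sh <- paste0("CATG", strrep("AC", 8), "T")
  dna2 <- Biostrings::DNAStringSet(c(
    t1 = paste0("GG", sh, strrep("G", 30)),
    t2 = paste0("TT", sh, strrep("G", 28))))
  gm2 <- data.frame(gene_id = c("g1", "g2"), transcript_id = c("t1", "t2"))
  lib2 <- buildVirtualLibrary(dna2, gm2)
  info <- lib2@tagInfo
  expect_false(info$unambiguous[info$tag == sh])
  expect_equal(info$n_genes[info$tag == sh], 2)
  # FASTA/gene-map mismatch names the offending record
  expect_error(buildVirtualLibrary(dna, data.frame(gene_id = "g1",
                                                   transcript_id = "tX")),
               "t1")
  # simulator canonical tags are always present as keys
  tx <- simulateTranscriptome(80, seed = 19)
  libS <- buildVirtualLibrary(tx$sequences, tx$geneMap)
  canon <- tx$genes$canonical_tag[!is.na(tx$genes$canonical_tag)]
  expect_true(all(canon %in% tagKeys(libS)))
})

test_that("tiered mapping resolves exact, 1-mismatch, ambiguous and unknown tags", {
  keys <- randomTags(10, seed = 101)
  seqs <- setNames(paste0("GG", keys, strrep("A", 20)),
                   paste0("t", 1:10))
  gm <- data.frame(gene_id = paste0("g", 1:10),
                   transcript_id = paste0("t", 1:10))
  lib <- buildVirtualLibrary(Biostrings::DNAStringSet(seqs), gm)
  q_exact <- keys[1]
  q_mm <- mutateTag(keys[2], 10)
  q_far <- mutateTag(mutateTag(keys[3], 10), 15)
  cts <- makeCleanTagSet(c(q_exact, q_mm, q_far), c(5L, 3L, 2L))
  res <- mapTags(cts, lib)
  asg <- res$assignments
  expect_identical(asg$status[asg$tag == q_exact], "unambiguous")
  expect_identical(asg$gene_id[asg$tag == q_exact], "g1")
  expect_equal(asg$tier[asg$tag == q_exact], 0L)
  expect_identical(asg$status[asg$tag == q_mm], "unambiguous")
  expect_identical(asg$gene_id[asg$tag == q_mm], "g2")
  expect_equal(asg$tier[asg$tag == q_mm], 1L)
  expect_identical(asg$status[asg$tag == q_far], "unknown")
  # gene counts follow copy numbers of sense unambiguous tags
  gc <- res$geneCounts
  expect_equal(gc$count_sense[gc$gene_id == "g1"], 5)
  expect_equal(gc$count_sense[gc$gene_id == "g2"], 3)
  # partition identity: unambiguous + ambiguous + unknown = clean total
  s <- res$summary
  expect_equal(s["unambiguous", "total"] + s["ambiguous", "total"] +
                 s["unknown", "total"], cleanTotal(cts))
  # agreement with the exhaustive mapper, including tier rules
  bf <- bruteForceMapTags(cts, lib)
  expect_equal(asg[order(asg$tag), c("tag", "tier", "status", "gene_id")],
               bf[order(bf$tag), c("tag", "tier", "status", "gene_id")],
               ignore_attr = TRUE)
})

test_that("tier rules: exact hits pre-empt mismatches; multi-gene distance-1 is ambiguous", {
  base <- randomTags(1, seed = 55)
  tagA <- base                       # gene A's key
  tagB <- mutateTag(base, 8)         # gene B differs at one position
  seqs <- setNames(c(paste0("CC", tagA, strrep("T", 18)),
                     paste0("AA", tagB, strrep("T", 18))), c("tA", "tB"))
  gm <- data.frame(gene_id = c("gA", "gB"), transcript_id = c("tA", "tB"))
  lib <- buildVirtualLibrary(Biostrings::DNAStringSet(seqs), gm)
  # a tag exactly matching A (and 1-mismatch from B) is unambiguous for A
  res <- mapTags(makeCleanTagSet(tagA), lib)
  expect_identical(res$assignments$status, "unambiguous")
  expect_identical(res$assignments$gene_id, "gA")
  # a tag at distance 1 from both keys and exact to neither is ambiguous
  mid <- mutateTag(base, 8, to = setdiff(c("A", "C", "G", "T"),
    c(substr(tagA, 8, 8), substr(tagB, 8, 8)))[1])
  res2 <- mapTags(makeCleanTagSet(mid), lib)
  expect_identical(res2$assignments$status, "ambiguous")
  expect_true(is.na(res2$assignments$gene_id))
  # with maxMismatch = 0 the same tag is unknown
  res3 <- mapTags(makeCleanTagSet(mid), lib, maxMismatch = 0)
  expect_identical(res3$assignments$status, "unknown")
})

test_that("error-free simulated libraries tally to their sampled counts", {
  tx <- simulateTranscriptome(60, fracNoCatg = 0.05, seed = 71)
  tr <- assignGeneActionProfiles(tx$genes, seed = 72)
  lib <- buildVirtualLibrary(tx$sequences, tx$geneMap)
  sim <- simulateLibrary(tr, tx, "F1", depth = 20000, errorRate = 0,
                         antisenseFraction = 0, seed = 73)
  cts <- extractCleanTags(sim$reads)
  expect_equal(cleanTotal(cts), 20000)
  res <- mapTags(cts, lib)
  got <- setNames(res$geneCounts$count_sense, res$geneCounts$gene_id)
  truecnt <- sim$counts[sim$counts > 0]
  # canonical tags are distinct here, so every gene's unambiguous sense
  # count equals its sampled truth
  expect_true(all(names(truecnt) %in% names(got)))
  expect_equal(unname(got[names(truecnt)]), unname(truecnt))
})

test_that("TPM normalization and the expression container hold their identities", {
  expect_equal(tpmNormalize(5, 1e6), 5)
  expect_equal(tpmNormalize(0, 123456), 0)
  cnt <- matrix(c(10, 0, 5, 2, 8, 1), ncol = 3,
                dimnames = list(c("g1", "g2"), c("P", "M", "F1")))
  tot <- c(P = 100, M = 50, F1 = 200)
  tpm <- tpmNormalize(cnt, tot)
  expect_equal(colSums(tpm), colSums(cnt) / tot * 1e6, ignore_attr = TRUE)
  expect_true(all(colSums(tpm) <= 1e6 + 1e-9))
  se <- makeTrioExperiment(cnt, tot)
  expect_s4_class(se, "DgeExperiment")
  expect_equal(unname(libSizes(se)), unname(tot))
  # the validity method rejects inconsistent TPM
  broken <- se
  SummarizedExperiment::assay(broken, "tpm")[1, 1] <- 999
  expect_error(methods::validObject(broken), "tpm")
})

test_that("saturation curves are monotone and flatten on simulated data", {
  expect_equal(saturationCurve(rep("CATGAAAAAAAAAAAAAAAAA", 50), 10)$distinct_tags,
               rep(1, 5))
  tx <- simulateTranscriptome(300, seed = 81)
  tr <- assignGeneActionProfiles(tx$genes, seed = 82)
  cnt <- simulateCounts(tr, "P", depth = 1e6, seed = 83)
  tags <- rep(tx$genes$canonical_tag[match(names(cnt), tx$genes$gene_id)],
              cnt)
  tags <- heterosisDGE:::withSeed(84, sample(tags))
  lib <- buildVirtualLibrary(tx$sequences, tx$geneMap)
  sat <- saturationCurve(tags, step = 5e4, library = lib)
  expect_true(all(diff(sat$distinct_tags) >= 0))
  expect_true(all(diff(sat$genes_detected) >= 0))
  # last 10% of sequencing discovers almost no new genes
  last10 <- sat$depth >= 0.9 * length(tags)
  gained <- max(sat$genes_detected[last10]) - min(sat$genes_detected[last10])
  expect_lt(gained, 0.01 * nrow(tx$genes))
})

test_that("strand accounting counts gene-level sense/antisense presence", {
  # hand-built: gA sense-only, gB antisense-only, gC both
  asg <- data.frame(
    tag = sprintf("CATG%017d", 1:6),
    count = c(10, 1, 3, 7, 2, 100),
    tier = 0L,
    status = c("unambiguous", "unambiguous", "unambiguous", "unambiguous",
               "ambiguous", "unknown"),
    gene_id = c("gA", "gB", "gC", "gC", NA, NA),
    strand = c("sense", "antisense", "sense", "antisense", NA, NA))
  sr <- strandReport(asg)
  expect_equal(sr$n_sense, 2)
  expect_equal(sr$n_antisense, 2)
  expect_equal(sr$n_both, 1)
  expect_equal(sr$ratio, 1)
  # presence-based: scaling copy numbers leaves the ratio unchanged
  asg2 <- asg; asg2$count <- asg2$count * 37
  expect_equal(strandReport(asg2)$ratio, sr$ratio)
  # no antisense genes -> NA ratio
  expect_true(is.na(strandReport(asg[1, ])$ratio))
})
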