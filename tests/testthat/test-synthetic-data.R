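test_that("transcriptome simulation is deterministic and honours the CATG design", {
  tx <- simulateTranscriptome(60, fracNoCatg = 0.1, seed = 7)
  expect_equal(nrow(tx$genes), 60)
  # exactly round(frac * n) genes carry no CATG site at all
  expect_equal(sum(tx$genes$n_catg_sites == 0), 6)
  expect_true(all(is.na(tx$genes$canonical_tag[tx$genes$n_catg_sites == 0])))
  with_tag <- !is.na(tx$genes$canonical_tag)
  expect_true(all(startsWith(tx$genes$canonical_tag[with_tag], "CATG")))
  expect_true(all(nchar(tx$genes$canonical_tag[with_tag]) == 21))
  # canonical tag is a substring of its transcript at the recorded position
  for (i in which(with_tag)[1:10]) {
    s <- as.character(tx$sequences[[tx$genes$transcript_id[i]]])
    p <- tx$genes$canonical_pos[i] + 1L
    expect_identical(substr(s, p, p + 20L), tx$genes$canonical_tag[i])
    # 3'-most eligible CATG: no later CATG leaves a 17-nt overhang
    later <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    later <- later[later > p & later + 20L <= nchar(s)]
    expect_length(later, 0)
  }
  # byte-identical FASTA across repeated calls with the same seed
  tx2 <- simulateTranscriptome(60, fracNoCatg = 0.1, seed = 7)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(tx$sequences, f1)
  Biostrings::writeXStringSet(tx2$sequences, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  tx3 <- simulateTranscriptome(60, fracNoCatg = 0.1, seed = 8)
  expect_false(identical(as.character(tx$sequences),
                         as.character(tx3$sequences)))
  # single-gene degenerate case
  one <- simulateTranscriptome(1, fracNoCatg = 0, seed = 7)
  expect_identical(substr(one$genes$canonical_tag, 1, 4), "CATG")
  expect_equal(nchar(one$genes$canonical_tag), 21)
  expect_error(simulateTranscriptome(0, seed = 1), "nGenes")
  expect_error(simulateTranscriptome(5, fracNoCatg = 1, seed = 1),
               "fracNoCatg")
})

test_that("gene-action profiles satisfy the mode relations exactly", {
  tx <- simulateTranscriptome(400, seed = 3)
  tr <- assignGeneActionProfiles(tx$genes, seed = 5)
  expect_true(attr(tr, "balanced"))
  # compositions: each genotype totals one million
  for (g in c("P", "M", "F1")) {
    expect_equal(sum(tr[[paste0("true_tpm_", g)]]), 1e6, tolerance = 1e-6)
  }
  P <- tr$true_tpm_P; M <- tr$true_tpm_M; F1 <- tr$true_tpm_F1
  md <- tr$assigned_mode
  expect_equal(F1[md == "additive"],
               (P[md == "additive"] + M[md == "additive"]) / 2)
  expect_equal(F1[md == "HPD"], pmax(P, M)[md == "HPD"])
  expect_equal(F1[md == "LPD"], pmin(P, M)[md == "LPD"])
  expect_true(all(F1[md == "ODO"] > pmax(P, M)[md == "ODO"]))
  expect_true(all(F1[md == "UDO"] < pmin(P, M)[md == "UDO"]))
  # recounting the emitted table reproduces the recorded multinomial draw
  tr2 <- assignGeneActionProfiles(tx$genes, seed = 5)
  expect_identical(table(tr$assigned_mode), table(tr2$assigned_mode))
  expect_error(
    assignGeneActionProfiles(tx$genes, modeProportions = c(additive = 0.5),
                             seed = 1),
    "sum to 1")
})

test_that("degenerate mode mixtures behave as constructed", {
  tx <- simulateTranscriptome(50, fracNoCatg = 0, seed = 2)
  # all-additive: relation survives rescaling
  tr <- assignGeneActionProfiles(tx$genes,
                                 modeProportions = c(additive = 1),
                                 seed = 4)
  expect_equal(tr$true_tpm_F1, (tr$true_tpm_P + tr$true_tpm_M) / 2)
  expect_equal(sum(tr$true_tpm_F1), 1e6, tolerance = 1e-6)
  # all-ODO: equal totals are unattainable; the construction guarantees the
  # fold relation before rescaling
  raw <- assignGeneActionProfiles(tx$genes, modeProportions = c(ODO = 1),
                                  foldEffect = 4, seed = 4, rescale = FALSE)
  expect_true(all(raw$true_tpm_F1 >=
                  4 * pmax(raw$true_tpm_P, raw$true_tpm_M) - 1e-9))
  scl <- assignGeneActionProfiles(tx$genes, modeProportions = c(ODO = 1),
                                  foldEffect = 4, seed = 4)
  expect_false(attr(scl, "balanced"))
  expect_equal(sum(scl$true_tpm_F1), 1e6, tolerance = 1e-6)
  # absent modes zero out the right genotype
  trA <- assignGeneActionProfiles(tx$genes,
    modeProportions = c(absent_in_P = 0.3, absent_in_M = 0.3,
                        absent_in_both_parents = 0.2, additive = 0.2),
    seed = 9)
  md <- trA$assigned_mode
  expect_true(all(trA$true_tpm_P[md %in%
    c("absent_in_P", "absent_in_both_parents")] == 0))
  expect_true(all(trA$true_tpm_M[md %in%
    c("absent_in_M", "absent_in_both_parents")] == 0))
  expect_true(all(trA$true_tpm_F1[md == "absent_in_both_parents"] > 0))
})

test_that("library sampling follows the multinomial model", {
  n <- 100
  tpm <- rep(1e6 / n, n)
  tpm[1] <- 1000
  tpm <- tpm / sum(tpm) * 1e6
  truth <- data.frame(gene_id = sprintf("G%03d", 1:n),
                      assigned_mode = "additive", true_tpm_P = tpm,
                      true_tpm_M = tpm, true_tpm_F1 = tpm,
                      detectable = TRUE)
  cnt <- simulateCounts(truth, "P", depth = 4.2e6, seed = 31)
  expect_equal(sum(cnt), 4.2e6)
  # binomial moments: observed count within 4 sd of depth * tpm / 1e6
  expe <- 4.2e6 * tpm[1] / 1e6
  sdv <- sqrt(4.2e6 * (tpm[1] / 1e6) * (1 - tpm[1] / 1e6))
  expect_lt(abs(cnt[1] - expe), 4 * sdv)
  # chi-square goodness of fit not rejected at alpha = 0.001
  cnt1m <- simulateCounts(truth, "P", depth = 1e6, seed = 32)
  ex <- 1e6 * tpm / 1e6
  X2 <- sum((cnt1m - ex)^2 / ex)
  expect_lt(X2, qchisq(0.999, df = n - 1))
  # determinism
  expect_identical(cnt, simulateCounts(truth, "P", depth = 4.2e6, seed = 31))
})

test_that("read emission matches its declared error and strand model", {
  tx <- simulateTranscriptome(1, fracNoCatg = 0, seed = 13)
  truth <- data.frame(gene_id = tx$genes$gene_id, assigned_mode = "additive",
                      true_tpm_P = 1e6, true_tpm_M = 1e6, true_tpm_F1 = 1e6,
                      detectable = TRUE)
  # degenerate multinomial: every error-free read starts with the tag
  lib <- simulateLibrary(truth, tx, "P", depth = 100, errorRate = 0,
                         antisenseFraction = 0, seed = 21)
  expect_length(lib$reads, 100)
  expect_true(all(nchar(lib$reads) == 35))
  expect_true(all(startsWith(lib$reads, tx$genes$canonical_tag)))
  expect_equal(unname(lib$counts[tx$genes$gene_id]), 100)
  # binomial substitution tail: P(>= 2 errors in the 21-mer)
  n <- 30000
  libE <- simulateLibrary(truth, tx, "P", depth = n, errorRate = 0.01,
                          antisenseFraction = 0, seed = 22)
  tagm <- matrix(unlist(strsplit(substr(libE$reads, 1, 21), "")),
                 nrow = 21)
  ref <- strsplit(tx$genes$canonical_tag, "")[[1]]
  nmm <- colSums(tagm != ref)
  p2 <- 1 - (0.99^21 + 21 * 0.01 * 0.99^20)
  sd2 <- sqrt(p2 * (1 - p2) / n)
  expect_lt(abs(mean(nmm >= 2) - p2), 4 * sd2)
  # determinism of the read stream
  libE2 <- simulateLibrary(truth, tx, "P", depth = n, errorRate = 0.01,
                           antisenseFraction = 0, seed = 22)
  expect_identical(libE$reads, libE2$reads)
})
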