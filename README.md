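# heterosisDGE

Digital gene expression (DGE) tag profiling of a maize heterotic cross:
two inbred parents (B73-like "P", Mo17-like "M") and their F1 hybrid, each
sequenced as a library of 35-bp NlaIII/MmeI tags.  `heterosisDGE` turns raw
tag reads into per-gene differential-expression calls, classifies every
differential gene's **mode of gene action** (additivity, high-/low-parent
dominance, over-/under-dominance), reports presence–absence expression
patterns and PAV (presence/absence variation) complementation, and tests
gene sets for term enrichment.  A fully seeded synthetic-data generator
emulates the whole study design with ground truth, so every stage is
testable without any sequencing download.

It is written for transcriptomics researchers and method developers who work
with tag-based expression protocols (DGE/SAGE-family), and follows
Bioconductor conventions: the central container is a
`SummarizedExperiment` subclass, sequences go through `Biostrings`, and the
analysis surface is plain camelCase functions.

## The method

**Tags.** NlaIII cuts transcripts at their 3'-most `CATG`; MmeI cuts 17 bp
downstream, so each transcript is represented by a 21-mer `CATG`+17 nt
signature sequenced inside a 35-bp read.  Reads are trimmed at the 3'
adaptor, filtered (length 21, `CATG` prefix, no `N`), and mapped against a
*virtual library* of all `CATG`+17 sequences of the reference transcriptome
(both strands), exactly first, then allowing one mismatch; tags hitting
more than one gene are excluded as ambiguous.  Gene expression is the
sense-strand unambiguous tag count, normalized to TPM (tags per million
clean tags): `tpm = count / N * 1e6`.

**Differential expression.** Two libraries are compared per gene with the
Audic–Claverie exact test.  Conditional on count *x* from a library of size
*N1*, the count *y* from a library of size *N2* follows

    p(y|x) = (N2/N1)^y * (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) )

and the two-sided p doubles the smaller tail.  Benjamini–Hochberg step-up
controls the FDR per contrast; a gene is *significant* when
`FDR <= 0.001` and `|log2 ratio| >= 1` (both thresholds configurable; 0.05
is the other convention in circulation for the FDR).

**Gene action.** For genes differential in at least one pairwise contrast
(F1 vs P, F1 vs M, P vs M), the hybrid is also tested against the
*midparent* (P+M)/2, realized as a pseudo-library of size
`round((N_P+N_M)/2)`.  Decision order: F1 ≈ midparent → additivity;
F1 significantly above (below) both parents → over-dominance ODO
(under-dominance UDO); significant against exactly one parent → HPD when
F1 matches the higher-expressed parent, LPD when it matches the lower;
anything else → other.

**Presence–absence and enrichment.** A gene is "present" in a library at
≥ 1 sense unambiguous tag (configurable floor); genes silent in one or both
parents are cross-tabulated against hybrid presence and against a PAV gene
list.  Gene sets are tested per annotation term with the hypergeometric
upper tail, corrected with BH and with Storey q-values
(`pi0 = min(1, #{p > λ} / (m(1−λ))`, λ = 0.5 by default).

## Worked example

```r
library(heterosisDGE)

cfg <- pipelineConfig(simulation = list(n_genes = 500, depth = 2e5), seed = 42)
bundle <- runPipeline(cfg)
print(bundle$geneAction$summary, row.names = FALSE)
```

```
[heterosisDGE] P: 200000 reads -> 191986 clean tags (14510 distinct)
[heterosisDGE] M: 200000 reads -> 192067 clean tags (15283 distinct)
[heterosisDGE] F1: 200000 reads -> 191924 clean tags (14320 distinct)
[heterosisDGE] virtual library: 5948 CATG+17 keys
[heterosisDGE] differential universe: 438 genes
          class   n        pct
          total 438 100.000000
     additivity 108  24.657534
 non_additivity 330  75.342466
            HPD  86  19.634703
            LPD 119  27.168950
            ODO  51  11.643836
            UDO  65  14.840183
          other   9   2.054795
```

Reading this: of 500 simulated genes, 438 were differential between at
least two genotypes at this (deliberately shallow) 200k-tag depth; 75% of
them departed from the midparent expectation, split across the four
dominance/overdominance classes.  At the study's full depth of 4.2 million
tags per library the classifier recovers > 99% of the simulated modes (see
`scripts/acceptance.R`).  Per-gene calls are in
`bundle$geneAction$calls` (with pattern strings such as
`"Mo17 < F1 ≈ B73"`), presence–absence patterns in `bundle$presence`, and
the strand report in `bundle$strand` — here the F1 library detected 472
genes on the sense and 393 on the antisense strand (ratio 1.20).

Real data run the same way: pass `reads = list(P = , M = , F1 = )`
(FASTQ or one-read-per-line text, optionally gzipped) plus a reference
FASTA and a gene map TSV instead of the `simulation` block, or drive
everything from a YAML file via `readPipelineConfig()`.

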