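---
title: "Models and methods in heterosisDGE"
author: "heterosisDGE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in heterosisDGE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterosisDGE)
```

# Scope

`heterosisDGE` analyses digital gene expression (DGE) tag libraries from a
maize-style heterotic trio — two inbred parents P and M and their F1
hybrid — from raw 35-nt reads to per-gene modes of gene action,
presence–absence expression patterns, and term enrichment.  This vignette
explains the underlying models, the defaults and why they were chosen, the
synthetic-data generator and its limits, and the numerical decisions that
would otherwise be invisible in the API.

# The tag model

NlaIII recognizes `CATG` and the bead-bound 3' fragment protocol leaves the
3'-most `CATG` of each transcript attached; MmeI then cuts 17 bp
downstream.  Every transcript is therefore represented by one canonical
21-mer (`CATG` + 17 nt), carried inside a 35-nt read together with 14 nt of
3' adaptor.

Two views of this model coexist deliberately:

* the **simulator** emits only the canonical tag per transcript (the
  fragment the chemistry actually sequences), with the canonical site
  defined as the 3'-most `CATG` that still has 17 nt downstream — a `CATG`
  closer to the 3' end than 17 nt cannot yield a full-length tag;
* the **virtual library** (`buildVirtualLibrary()`) indexes *every*
  `CATG`+17 occurrence on *both* strands, because real reads include
  antisense transcription and internal sites, and the mapper must be able
  to tell all of them apart.

Cleaning (`extractCleanTags()`) trims each read at the first occurrence of
the adaptor (its leading 14 nt — the part that fits in a 35-nt read), or
truncates to 21 nt when no adaptor is found, then keeps tags that are
exactly 21 nt, start with `CATG` and contain no `N`.  There is no
quality-score filtering beyond the `N` rule; the protocol's published
filtering stops there too.  An adaptor at position 1 is an "empty tag"; all
rejection classes are tallied in the cleaning report.

Mapping (`mapTags()`) is tiered: exact key lookup first; only tags with no
exact hit are compared at Hamming distance 1.  Tiering prevents a
sequencing error from overriding an exact hit, and makes a tag that matches
gene A exactly but gene B at one mismatch unambiguous for A.  Since both
clean tags and library keys start with `CATG`, a single mismatch can only
occur in positions 5–21; the production mapper exploits this, while the
shipped exhaustive reference mapper (`bruteForceMapTags()`, C++) compares
all 21 positions and is used to verify the shortcut.  The union of genes
hit at the accepted tier decides the tag's fate: one gene → unambiguous,
several → ambiguous (mapped but never counted), none → unknown.  The
identity `unambiguous + ambiguous + unknown = clean total` holds by
construction and is asserted in the tests.

Expression counts use **sense-strand unambiguous tags only**; antisense
tags are tallied separately for the strand report.  The protocol detects
antisense transcription, but gene expression is a sense-strand quantity and
no merge rule for the two strands is established — keeping them separate is
the conservative choice.  A tag hitting both strands of the *same* gene is
still unambiguous and counts as sense.  TPM is
`count / clean_total * 1e6`.  Transcript coordinates are 0-based on the
indexed strand's sequence; genome-positional mapping is out of scope.

# The exact test

Tag counts from two libraries are compared with the Audic–Claverie
conditional law: given count $x$ from a library of $N_1$ tags, the count
$y$ from a library of $N_2$ tags has

$$ p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
   \frac{(x+y)!}{x!\,y!\,\bigl(1+N_2/N_1\bigr)^{x+y+1}} , $$

the standard test for two-library tag counts in this protocol family (the
trio design pools biological replicates into one library per genotype, so
no replicate dispersion is estimable — see Limitations).  The two-sided p
doubles the smaller tail, point mass included, capped at 1.

Numerical decisions:

* **Log-gamma evaluation.** All pmf terms are computed in log space; tails
  are accumulated with log-sum-exp.  The *smaller* tail is always summed
  directly (never obtained as `1 − larger`), so p-values far below machine
  epsilon remain accurate — the brute-force equivalence test runs at
  relative tolerance 1e-10 down to p ≈ 1e-24.
* **Canonical conditioning.** The doubled-tail construction is not
  symmetric under swapping $(x, N_1)$ with $(y, N_2)$ if one conditions
  naively on the first argument.  `exactCountTest()` therefore conditions
  on the smaller of the two counts (ties broken towards the larger
  library), a deterministic canonical orientation that makes the swap an
  exact no-op and reproduces the closed form
  $p = 2\,(1/2)^{y}$ for $x = 0$ and $N_1 = N_2$.
* **Truncation.** Upper tails are summed from $y$ until terms fall below
  the accumulated tail by a factor 1e-15 and past the conditional mode,
  bounded by a 20-standard-deviation window.

Multiple testing uses Benjamini–Hochberg step-up per contrast
(`bhAdjust()`, delegating to `stats::p.adjust`).  The default significance
rule is `FDR <= 0.001` **and** `|log2 ratio| >= 1`.  The source protocol
states both a 5% FDR and the 0.001 rule without reconciling them; both are
plain configuration here, with 0.001 as the default because it is the rule
the published gene lists actually used.

Log2 ratios add a pseudo-count only to sides that are exactly zero: 0.5
tags converted to TPM in the corresponding library
(`0.5 / N * 1e6`).  Nonzero values are never shifted, so finite ratios are
exact; genes with zero counts in both libraries are excluded upstream.

# Gene action

Genes differential in at least one pairwise contrast (F1 vs P, F1 vs M,
P vs M) form the classification universe.  For those genes the hybrid is
tested against the midparent $(P+M)/2$, materialized as a pseudo-library:
$N_{MP} = \mathrm{round}((N_P+N_M)/2)$ with counts
$\mathrm{round}\bigl((p/N_P + m/N_M)/2 \cdot N_{MP}\bigr)$.  The BH
adjustment for this contrast runs over the universe genes, the set actually
being classified.

Decision order (first match wins):

1. F1 **not** significantly different from the midparent → `additivity`;
2. F1 significantly above both parents → `ODO`;
3. significantly below both → `UDO`;
4. significant against exactly one parent → `HPD` if the parent F1
   matches is the higher-expressed one (by TPM point estimate), `LPD` if
   the lower; an exact parental TPM tie with one significant contrast is
   `other`;
5. anything else (e.g. strictly intermediate between significantly
   different parents) → `other`.

**Why the midparent contrast uses the FDR rule alone.**  A dominant gene's
F1 equals one parent, so its ratio to the midparent is $2f/(1+f) < 2$ no
matter how large the parental fold $f$ is.  An absolute
$|\log_2| \ge 1$ filter on the midparent contrast is therefore
*unsatisfiable* for every dominance gene and would relabel all of them as
additive — contradicting both the published composition of the cross
(91% non-additive, mostly dominance) and this package's own recovery
checks.  The fold filter stays where it discriminates, on the pairwise
contrasts; the midparent call defaults to `lfcThreshold = 0`
(configurable in `midparentContrast()` / `callGeneAction()`).

The classifier is rank-based, not label-based: swapping the parent columns
maps every category onto itself.  Pattern strings
(`"Mo17 < F1 ≈ B73"`) are derived from the two F1–parent calls, the
parent–parent call, and the TPM ordering, with the tied genotype printed
next to its partner.

# The synthetic generator

`simulateTranscriptome()` draws random transcripts (default 300–3000 nt,
GC 0.47 — a plant-transcriptome-like composition), forcing a configurable
fraction (default 5%) to contain no `CATG` at all by iterated substitution;
such genes are undetectable by construction, mirroring the fraction of real
transcripts NlaIII cannot tag.  All remaining genes are guaranteed an
eligible canonical site.

`assignGeneActionProfiles()` draws a mode per gene — default mixture
additive 0.09, HPD 0.23, LPD 0.30, ODO 0.13, UDO 0.23, other 0.02, the
composition of the published differential set — and a base abundance
log-uniform in `tpmRange` (default 20–2000 TPM).  Within a gene the trio
pattern is exact: additive F1 is the arithmetic midparent; HPD/LPD equal
the higher/lower parent, parents separated by `foldEffect` (default 4);
ODO/UDO place F1 `foldEffect`-fold above/below two equal parents (matching
the published over/under-dominant patterns, where the parents are
similar); `other` genes are strictly intermediate with parents separated
by `foldEffect^3`.  `absent_in_P/M` modes zero one parent with F1 at the
midparent; `absent_in_both_parents` expresses only in the hybrid.

**Compositional balancing.**  TPM is a composition: each genotype must
total $10^6$.  With mode proportions fixed, the three genotype totals of
the raw patterns generally differ (over-dominant genes inflate the F1
total), and per-genotype renormalization would distort every within-gene
relation — turning exact additivity into an apparent shift that deep
sequencing would flag.  The generator therefore rescales whole gene trios
by a per-stratum factor (strata = mode × orientation), solving an
equality-constrained minimum-norm problem so that the three totals agree
exactly while all within-gene relations are preserved bit-for-bit; a
single global factor then sets the totals to $10^6$.  Mixtures for which
equal totals are mathematically unattainable (e.g. every gene
over-dominant) fall back to independent per-genotype rescaling, and the
returned object records this in its `balanced` attribute.

`simulateLibrary()` samples gene counts multinomially over detectable
genes, emits reads as canonical tag + 14 nt adaptor, flips a per-read coin
(default 0.05) to draw the tag from the transcript's antisense strand
instead (falling back to sense where the antisense strand has no eligible
site), substitutes each base independently with probability `errorRate`
(default 0.01), and shuffles the stream.  `simulateCounts()` exposes the
count marginal directly; at `errorRate = 0` the full read path tallies to
exactly those counts, which the test suite asserts.  Every stochastic
operation takes an explicit integer seed and restores the caller's RNG
state; fixed seeds give byte-identical outputs.

What the simulator does **not** emulate: sequence-composition biases, PCR
duplication structure, quality-score profiles, chloroplast/mitochondrial
contamination, genuine antisense biology (the per-read antisense coin only
exercises strand accounting; the published 1.3:1 sense:antisense ratio is
an observation, not a target), and real mismatch structure between the
B73 and Mo17 haplotypes.  Passing the recovery tests shows the estimator
chain is correct under its own model, not that real libraries meet that
model.

# Presence–absence and PAV

"No detectable expression" means zero sense unambiguous tags; the floor is
configurable (`minCount`, default 1) and raising it can only remove
presence, which the tests assert as a monotonicity property.  The
presence–absence summary cross-tabulates genes silent in at least one
parent (but present somewhere in the trio) against hybrid presence, with
percentages and hybrid present:absent ratios.  `pavCrossref()` joins a PAV
gene list (`gene_id`, donor genome) against the trio: detection by tags,
presence pattern, where the hybrid sits relative to the parents, the
single-parent-plus-hybrid complementation flag, and the gene-action
category when classified.  Genes absent from both parents yet expressed in
the hybrid are reported as such, without interpretation.

# Enrichment

`enrichTerms()` tests terms with at least one query hit using the exact
hypergeometric upper tail (via R's stable `phyper`), over an explicit gene
universe; annotations are flat two-column tables and no ontology-graph
propagation is performed (the original analysis used flat term
assignments).  Both BH-adjusted p-values and Storey q-values are always
computed; GO-style analyses conventionally read the BH column and
pathway-style analyses the q column.  The π0 plug-in uses a fixed
λ = 0.5 (`pi0 = min(1, #\{p > λ\}/(m(1−λ)))`); the smoother-based
estimator is deliberately out of scope, and `pi0 = 1` reduces q-values to
BH exactly.  When two contrasts' gene sets are of interest, each set and
their union are enriched independently rather than merged by an
unspecified rule.

# Problem sizes used in the checks

The shipped suites were sized as follows: oracle equivalence for the exact
test over the full 0–50 × 0–50 count grid; hypergeometric enumeration for
every parameterization with N ≤ 30; mapper-versus-oracle on a
10,000-key library with 10,000 mixed queries; parameter recovery on 2000
genes at 4.2 million tags per library (the study depth) across three
seeds; null control over 20 replicate trios of 2000 genes at the same
depth; end-to-end read-level runs at 20,000–200,000 tags, where the
read path is proven exactly equal to the count path at zero error rate.

# Limitations

* One library per genotype: no replicate-aware dispersion modelling, so
  the exact test treats biological variation as sampling noise — calls on
  real data are anti-conservative to an unknown degree.
* The midparent pseudo-library halves the sampling variance of a real
  library of that size; the test for additivity is correspondingly
  conservative.
* Parent ranking for HPD/LPD uses TPM point estimates; genes with nearly
  equal parents can flip categories under resampling.
* No allele-specific expression, epistasis modelling, genome-positional
  mapping, or PAV discovery from genome sequence.
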