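---
title: "Methods: lncRNA discovery and pathway analysis with lncpath"
author: "lncpath authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery and pathway analysis with lncpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpath)
```

## Scope

`lncpath` implements a complete discovery-and-function pipeline for plant
long non-coding RNAs (lncRNAs), shaped around the biology of allotetraploid
tobacco and its root-specific nicotine biosynthesis programme. Given
assembled transcript models, a reference annotation, a genome (optionally
with the two parental subgenomes), mature miRNA sequences and an expression
matrix, it classifies transcripts into lincRNA / NAT / incRNA, characterises
their sequences and expression, predicts miRNA precursors and endogenous
target mimics (eTMs), assigns cis and trans targets, detects weighted
co-expression modules, tests a before/after induction contrast, and
extracts a pathway-focused lncRNA–gene sub-network. A ground-truthed
synthetic data generator makes every stage testable end to end without any
external download.

## The identification cascade

Assembled transcripts pass a fixed filter cascade; the first failed filter
is recorded per transcript:

1. **Sense overlap** — any exonic overlap, on the same strand, with an
   annotated protein-coding exon removes the transcript (it is a fragment
   or isoform of a known gene).
2. **Length** — spliced length below 200 nt. A transcript of exactly
   200 nt is kept.
3. **ORF size** — a longest open reading frame above 120 amino acids
   (360 nt, the stop codon counted in the length; exactly 120 aa is
   kept). The ORF scan runs on the given strand only, in all three
   frames, requires an in-frame stop, and breaks ties by the smallest
   start. Codons containing `N` never match ATG or a stop.
4. **Protein similarity** — membership in a supplied table of transcripts
   with significant protein hits (the output of a BLASTX-style search,
   provided as input rather than run in-package).
5. **Coding potential** — two supplied per-transcript scores (e.g. CPC
   and PLEK); survival requires both to be strictly negative, so a score
   of exactly zero rejects.

Survivors are classified by position relative to the annotation, with the
precedence **NAT > incRNA > lincRNA**: any exonic overlap (at least 1 bp,
configurable) with an opposite-strand gene makes a NAT, whose linked gene
is the opposite-strand gene with the largest overlap; a transcript
entirely inside a single intron of a same-strand gene is an incRNA linked
to its host; everything else is a lincRNA. Antisense overlap wins over
intron containment because it is the stronger positional signal.
Transcripts are grouped into loci by shared strand and at least 1 bp of
exonic overlap (transitively), and a locus is *high-confidence* when its
TPM — the maximum over member transcripts — strictly exceeds 1 in at
least one sample.

## Characterisation

Expression is quantified as TPM (`compute_tpm`): per column, counts are
divided by feature length and rescaled so each column sums to one
million. Tissue specificity uses arithmetic per-tissue means of TPM (the
aggregation is configurable): a feature is *tissue-specific* when its top
tissue mean strictly exceeds twice the second-largest mean and also
exceeds 1 TPM. The expression floor prevents all-zero features from being
called specific. The heatmap transformation divides each row by its
second-largest value, so exactly one entry per row exceeds 1 when the row
maximum is unique.

Subgenome-of-origin calls replace an alignment best-hit assignment with a
canonical k-mer containment score (k = 31 by default, both strands
indexed): the call goes to the parental reference containing the larger
fraction of the query's k-mers, with ties (including queries shorter than
k) unassigned. The surrogate is validated in the test suite against a
local-alignment best-hit oracle; at mutation distances above roughly 6%
no intact 31-mer survives a ~260 nt query, so distant queries fall to
`unassigned` rather than being called wrongly — precomputed best-hit
tables can be substituted where alignment calls are preferred. Class-level
asymmetry between the subgenomes is tested with Pearson's chi-square
(no continuity correction, df = 1 for the 2x2 table). Reported
percentages use "half-up" rounding to 2 decimals throughout
(`round_half_up`), not banker's rounding.

## miRNA precursors and target mimics

Precursor detection is a two-stage rule. Stage 1 scans each lncRNA
(given strand, ungapped) for windows within Hamming distance 2 of a
mature miRNA. Stage 2 checks hairpin plausibility: the maximum
base-pairing score (Nussinov dynamic programme; Watson-Crick pairs plus
the G:U wobble, minimum loop 3) of the site with 80 nt of flank on each
side must reach half the flank length (40 pairs). Maximum pairing is a
deliberately simple structural surrogate — it is not a thermodynamic
folding energy and not a covariance-model family assignment; it asks
only whether the region *can* form an extended stem.

An eTM site pairs with the miRNA like a cleavage target except for a
short unpaired bulge on the lncRNA side opposite the cleavage site,
which blocks slicing. The rule set (each number a configuration key):
perfect Watson-Crick pairing at miRNA positions 2–8 (the seed); a
lncRNA-side bulge of 2–5 nt inserted after a miRNA position in 9–11;
at most 3 mismatches outside the seed with G:U wobbles free; and a
bulge-free perfect complement is never reported (it is a cleavage
target, not a mimic). Overlapping candidate sites for one lncRNA–miRNA
pair are deduplicated keeping fewest mismatches, then the smallest
bulge, then the leftmost site. Because these thresholds are a documented
surrogate for an external predictor whose exact settings are not public,
absolute site counts on real data are not comparable across tools — the
planted-site recovery tests define the rule set's intended behaviour.

## cis and trans targets

A lincRNA and a gene on the same chromosome are a **cis** pair when their
genomic-span midpoints lie strictly within 100 kb; the relation
(upstream / downstream / overlapping) is oriented by the gene's strand,
and a bin summary counts non-overlapping pairs with edge distance within
5 kb. Span midpoints (rather than exon-model midpoints) make the distance
robust to isoform differences. NATs and incRNAs target their host genes
directly. **Trans** pairs require `|r| > 0.9` (Pearson, strict) across
the co-expression samples, after excluding pairs already explained in
cis; the signed correlation is kept so positive and negative pairs can be
counted separately. The absolute-value reading of the cutoff follows from
the existence of negatively correlated pairs in this kind of analysis.

## Co-expression network

The network is unsigned WGCNA-style: adjacency `|r|^power` (default
power 9) with zero diagonal, topological overlap

TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),  l_ij = Σ_u a_iu a_uj,

and average-linkage hierarchical clustering of `1 − TOM`. Modules come
from a **static** cut at 0.995 of the maximum merge height — a
deterministic, documented replacement for the dynamic tree-cut heuristic;
the cut height is a configuration key. Clusters below 30 members fall
into the reserved `grey` bucket; surviving modules are labelled by
decreasing size from the conventional colour list. Eigengenes are first
right singular vectors of the row-standardised module submatrix, with the
sign fixed to correlate non-negatively with the mean standardised profile
(SVD signs are otherwise arbitrary); modules whose eigengene
dissimilarity `1 − cor` is strictly below 0.25 are merged iteratively
(closest pair first, deterministic tie-breaks) to a fixpoint.
Module–trait association is the Pearson correlation of the eigengene
with a trait indicator, with the usual t-transform p-value on n − 2 df.

Soft-threshold selection fits `log10 p(k)` against `log10 k` over 10
equal-width connectivity bins and reports the signed fit index (negative
when the slope is positive); the chosen power is the smallest reaching
the 0.8 target, else the argmax. Equal-width bins are essential: with
equal-count bins p(k) is constant by construction and the regression
carries no information.

## Differential expression, enrichment, qPCR

The tissue screen is a classical one-way ANOVA per feature (vectorised),
keeping features with p < 0.001 (strict). Features with zero within-group
variance but unequal means get p = 0 by convention and are flagged. The
induction ("topping") contrast uses a Welch t-test on
`log2(TPM + 0.01)` — the simplest defensible replicate test, with the
pseudocount configurable; the fold change is computed on raw means with
the same pseudocount. A feature is a DEG when the larger condition mean
exceeds 1 TPM and p < 0.05; it is *induced* when additionally
log2FC > 1 and the Benjamini–Hochberg adjusted p (interpreted as the
`p.adjust` of the standard toolchain) is below 0.05. All inequalities
are strict. Enrichment is the hypergeometric upper tail
`P(X ≥ k)` per term with BH correction across terms. qPCR fold changes
use 2^−ΔΔCt with replicate Ct values averaged first; the statistic is
invariant to adding a constant to every Ct.

## Sub-network extraction

The trait-specific module (largest positive eigengene–trait correlation;
ties to the first label, no positive correlation is an error) is mined
for lncRNAs whose expression correlates above 0.85 (strict) with at
least one pathway gene in the module; each passing pair is an edge. The
PCC is computed across all samples of the co-expression dataset, not
only trait-positive samples, mirroring how the module itself was built.
NATs hosted on pathway genes enter regardless of module membership.
Edges carry an `lnc_induced` flag from the induction contrast, and nodes
are ranked by degree with ties broken by id. The pathway gene list is
always an input table, never hard-coded.

## The synthetic data generator

`simulate_genome()` plants every structure the pipeline is meant to
find, so recovery can be asserted exactly:

* **Genome** — template chromosomes carry coding genes (1–4 exons; a
  contiguous CDS of 411 nt, so the ORF filter sees > 360 nt) and
  intergenic lincRNAs, with NATs planted antisense across an exon/intron
  junction of host genes and incRNAs inside a large intron. Non-coding
  scaffold sequence interleaves random 60-mers with a 12 nt cassette
  containing a stop codon in all three frames, bounding any spurious ORF
  far below 360 nt.
* **Subgenomes** — the T chromosomes are the templates; the S
  chromosomes are copies mutated at `subgenome_divergence` (default 3%)
  outside functional elements (CDS, planted miRNA sites). Every
  transcript's exonic footprint is guaranteed to differ between the
  copies in at least one base, so subgenome truth is exactly
  recoverable; at divergence 0 the copies are identical and every call
  is an unassigned tie.
* **miRNA elements** — mature miRNAs are generated first; one lincRNA
  per miRNA embeds the exact mature sequence inside a constructed
  51-bp stem (detection truth exact), and one embeds an eTM site built
  from the reverse complement with a 3 nt bulge after miRNA position 10.
* **Expression** — log-normal baselines (meanlog 3, sdlog 1 on the TPM
  scale, reproducing the long-tailed low-expression regime), plus on the
  log2 scale: a shared per-sample module eigensignal, tissue-specific
  boosts, the topping effect in `after` samples, and iid Gaussian noise.
  Columns are then normalised to TPM. Module *m* anchors to tissue *m*
  (module `M1` to root, the root-specific module the sub-network stage
  expects) with amplitude 2.2 log2 units; anchoring modules to distinct
  tissues mirrors the tissue-specific module structure real plant
  co-expression networks show, keeps planted eigengenes near-orthogonal
  (so the static cut separates them), and makes the ANOVA screen retain
  members. Per-sample eigensignal jitter (sd 0.35) applies only to the
  multi-tissue survey samples: the topping contrast models a controlled
  experiment whose replicates differ only by measurement noise.
* **Defaults** — 200 coding genes, 16 lincRNAs, 8 NATs, 6 incRNAs,
  4 miRNAs on 2 chromosomes per subgenome of 150 kb; 5 tissues x 4
  replicates plus 3 + 3 topping samples; 3 modules of 30–40 members;
  15% tissue-specific features at fold 4; topping effect 2 log2 units;
  noise 0.2. The background size matters: with too few background
  features, TPM column normalisation induces visible anticorrelation
  between modules (mass added by one module's anchor tissue depresses
  every other feature there), which at desk scale can fuse planted
  modules under the static cut. Two hundred coding genes dilute this
  coupling to a negligible level while keeping the full pipeline run
  under a minute.

What passing tests on this generator do **not** show: robustness to
read-level noise, isoform complexity (one isoform per locus by design),
assembly artefacts, library-composition biases beyond simple TPM
coupling, or the behaviour of the coding-potential scores themselves
(they are supplied as tables, planted as cleanly separable here).

## Numerical conventions

* Percentages are half-up rounded to 2 decimals; counts are exact.
* All threshold comparisons are strict unless documented otherwise;
  boundary cases (length exactly 200 nt, ORF exactly 120 aa, score
  exactly 0, TPM exactly 1, PCC exactly at a cutoff) are pinned by unit
  tests.
* Welch tests with zero pooled variance return p = 1 on equal means and
  p = 0 (flagged) otherwise.
* The eigengene sign convention and all clustering tie-breaks are
  deterministic, so a pipeline rerun on the same inputs is
  byte-identical (asserted in the test suite on full-run manifests).
* Test-suite and acceptance problem sizes: the module-recovery benchmark
  averages the adjusted Rand index over 5 seeds at noise 0.3 (about 110
  planted members over 3 modules per seed); the induction benchmark uses
  11 planted features at effect 2.0, noise 0.1, 3 replicates; the null
  calibration uses 1000 features; oracle-equivalence suites use 100+
  random instances per primitive.

## Known limitations

* The static tree cut needs a clear within/between dissimilarity gap; on
  real, messy expression data the dynamic tree-cut algorithm of the
  reference implementation will split modules this package leaves merged
  (or vice versa). The cut height is exposed for tuning.
* The k-mer subgenome score saturates to `unassigned` for queries beyond
  ~6% divergence from both references at k = 31; use a smaller k or a
  precomputed best-hit table for distant material.
* The precursor hairpin check maximises base pairs, not free energy; AU-
  rich stems are over-credited relative to a thermodynamic model.
* Hypergeometric enrichment treats terms independently (no ontology
  DAG propagation, no pathway topology).
* The asymptotic chi-square p-value sits below the exact conditional
  tail for very small tables; the test suite documents the mid-p
  agreement at n = 40.
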