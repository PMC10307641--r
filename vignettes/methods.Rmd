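---
title: "Models and methods behind riboallele"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riboallele}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboallele)
library(dplyr)
```

`riboallele` analyses ribosome profiling and RNA-seq read tables from
F1-hybrid early mouse embryos (C57BL/6J mother x CAST/EiJ father) at
single-embryo input scale. The two central difficulties at that scale are
(i) distinguishing maternal from paternal transcripts through
strain-distinguishing SNPs when the per-read sequencing error rate is of
the same order as the early-embryo paternal signal, and (ii) quantifying
translation efficiency from sparse, compositional count data. This
vignette explains the models implemented, the tunable parameters, the
synthetic-data generator used to validate them, and the numerical choices
made where the design was genuinely open.

## The synthetic-data generator

Every statistical routine in the package is validated by parameter
recovery on simulated data, so the generator is first-class, tested code.
It emulates the structure the downstream stages rely on:

* **Transcriptome**: one transcript per gene (isoforms are out of scope),
  0-based half-open coordinates, 5'UTR / CDS / 3'UTR lengths drawn from
  configurable ranges (CDS a multiple of 3, `ATG` at the start, a stop
  codon at the end), log-normal expression weights, and Poisson-placed
  strain SNPs at a configurable density per kilobase. The maternal allele
  is the transcript base; the paternal allele is a different base.
* **Ribosome footprints**: lengths 29-35 nt from a peaked distribution;
  a per-length A-site offset (defaults 14-17 nt); the A-site lands on a
  codon boundary with probability `frame_fidelity` (default 0.85, the
  remainder split evenly over the other two frames) and uniformly over
  CDS codons otherwise. Optional multiplicative weights (`start_bias`,
  `stop_bias`) enrich the initiation and termination codons, emulating
  ribosome pausing; they default to off, and stop-site enrichment is what
  makes A-site calibration identifiable, so QC-focused simulations turn
  `stop_bias` on.
* **Parent-of-origin**: each molecule is paternal with the stage's
  configured probability. The default six-stage design uses 0% for GV and
  MII oocytes (oocytes carry only maternal transcripts), 7.1% at the
  two-cell and 47.7% at the eight-cell stage — the aggregate values the
  allele-specific analysis is expected to recover — and interpolating
  values of 1% (one-cell) and 30% (four-cell), chosen once as consistent
  with a steady increase across cleavage stages; neither intermediate
  value is asserted by any test. Per-gene overrides plant allele-biased,
  monoallelic, or modality-discordant genes.
* **Sequencing error**: with probability `error_pct`/100 per SNP-covering
  read, the observed base at every covered SNP is replaced by one of the
  three other bases uniformly. The error indicator is drawn per read, not
  per base, because the error statistic it must reproduce ("fraction of
  reads with non-maternal sequence") is read-level. Defaults are 2.67%
  (ribosome profiling) and 0.40% (RNA-seq), the MII-derived estimates the
  package's own estimator reproduces.
* **PCR duplication**: Poisson-distributed extra copies sharing UMI and
  coordinates. UMIs are uniform 12-mers; at the simulated scales
  (thousands of molecules per gene against a 4^12 space) the collision
  probability is negligible and is ignored.

What the generator deliberately does **not** model: sequencing-quality
score profiles, positional/fragment bias, isoform structure, and
alignment artefacts. Passing recovery tests therefore demonstrates the
correctness of the estimators under their own assumptions, not robustness
to every artefact of real libraries — with one exception, the MII
paternal-read filter, which exists precisely because real alignments
produce error-prone positions and is exercised with contaminated
fixtures.

All randomness derives from one master seed, sub-seeded per (stage,
modality, replicate) stream, so replicate libraries are independent and
results do not depend on execution order.

## Footprint quality control

**A-site calibration.** For each footprint length, 5'-end counts are
aggregated relative to the stop codon's first nucleotide; the offset is
the distance from the highest peak strictly upstream of the stop
(search window -40..-1 nt; the window is a parameter because very long
offsets are biologically implausible rather than impossible). Ties break
toward the peak closest to the stop. A length with no upstream signal is
an error, not a guessed offset.

**Reading-frame statistic.** A footprint's frame is
`(5' position − CDS start) mod 3`. Footprints are grouped by length and
3'-end sequence context (2 nt upstream of the 3' end, 1 nt downstream) —
context grouping absorbs nuclease/ligation sequence preference — and each
group's frame triplet is cyclically shifted so its maximum comes first
before summing into the adjusted triplet (T0, T1, T2), which is tested
against uniformity with a chi-squared statistic on 2 degrees of freedom.
Two consequences of the max-first shift are worth knowing: for a single
group the statistic is permutation-invariant and keeps its exact null
distribution, while summing many shifted groups inflates T0 relative to a
plain multinomial — the test suite therefore checks calibration on a
single-group design. Footprints whose 3'-end context would run off the
transcript are excluded and tallied.

**Region occupancy.** Footprints are assigned to 5'UTR/CDS/3'UTR by their
A-site; RNA-seq reads by their 5' end (a deterministic, boundary-unambiguous
rule; the CDS interval is half-open). The occupancy-weighted region length
percentages weight each transcript's region-length ratios by its footprint
count and normalise the three sums to 100.

## Translation efficiency

Counts are converted to CDS densities (count / CDS length; any constant
scaling cancels downstream) and normalised per sample with the centred
log-ratio, `clr(g) = ln(g / M)` with `M` the geometric mean over genes
with non-zero values. Zeros are excluded from `M` and stay undefined
(`NA`) — no pseudocount is added, because the clr of a composition is
defined only on its support and a pseudocount would shift every other
gene's value. clr values are averaged across the replicates where the
gene is defined, and

* `te_log = clr_ribo − clr_rna`,
* `te = exp(te_log)`.

The ratio of normalised occupancy to expression is computed on the
exponential scale: a literal ratio of clr values would be ill-defined
whenever a clr is negative or zero, whereas `exp(clr difference)` is the
unique ratio-scale quantity consistent with the log-scale difference.
Confidence intervals come from a percentile bootstrap over replicate
labels, resampled independently per modality. Percentile intervals are
asymptotic in the number of replicates: the suite demonstrates ~90%+
empirical coverage at eight replicates per modality, and coverage is
expected to degrade at the two-to-four replicates typical of single-embryo
experiments — intervals there should be read as stability indicators, not
exact 95% statements.

The poly(A) association groups genes into six equal-count bins by mean
tail length (stable tie-break by gene identifier) and reports per-bin
boxplot statistics plus a Spearman correlation on the unbinned pairs.

## Allele-specific analysis

**Error estimation.** MII oocyte transcripts are purely maternal, so the
fraction of MII SNP observations that are non-maternal estimates the
sequencing error rate per modality.

**Error-corrected paternal ratio.** With true paternal percentage `c` and
error percentage `e`, a random-substitution model gives the observed
paternal percentage

`obs = c (100 − e)/100 + (100 − c) e/300`,

whose inversion is `corrected = (300 obs − 100 e)/(300 − 4 e)`. Two
details matter. First, the model's `obs` counts paternal observations out
of **all** SNP observations — maternal, paternal, and third-base
("other") — and the package computes aggregate observed ratios that way;
putting only maternal+paternal in the denominator breaks the inversion by
about a percentage point at eight-cell signal levels, which is twice the
package's own round-trip tolerance. Second, `obs = 25` is a fixed point
for every `e` (a fully random base shows any given allele a quarter of
the time), and the formula requires `e < 75`. Corrected values are
clamped to [0, 100] with an explicit flag. Gene-level ratios use the unit
pseudocount form `100 (p+1)/(p+1+m+1)` so sparse genes stay strictly
inside (0, 100).

Per-stage summaries correct each replicate's pooled ratio separately and
report the mean and standard error across replicates.

**Differential allelic engagement** (ribosome occupancy vs RNA
expression, per stage) proceeds: pool parent-of-origin reads per gene
across replicates and SNPs; keep genes with more than 10 such reads in
both modalities and at least 3 maternal and 3 paternal reads (enforced on
the counts pooled across modalities — the sparser reading would doubly
penalise low-input libraries); Yates-corrected two-sample proportion
test; discard genes whose 95% CI for the difference overlaps
(−0.05, 0.05); Benjamini-Hochberg, keep FDR < 0.2; drop genes with any
paternal MII reads (error-prone positions); and finally require the whole
chain to succeed in at least 66% of 100 replicate-label bootstrap
resamples. The proportion test is implemented in the package (capped
continuity correction, so identical proportions give a statistic of
exactly zero) and is checked against an independent reference
implementation in the tests.

**Allelic-bias classification** (RNA, four- and eight-cell stages): genes
with at least 10 parent-of-origin reads are classified by resampling
replicate labels 1,000 times, pooling reads over replicates and SNPs, and
computing the raw paternal fraction — raw, not pseudocounted, inside the
bootstrap, matching the ratio-of-supporting-reads definition; the
pseudocounted form is reserved for the per-SNP concordance tier. A gene
is paternally biased if the fraction exceeds 0.7 in at least 800
resamples; maternal bias mirrors the rule at 0.3. Genes whose pooled
counts contain a single allele are flagged monoallelic, and biased genes
where at least 60% of SNPs individually agree with the direction earn a
high-confidence flag. Group comparisons of translation efficiency use
two-sided Wilcoxon rank-sum tests with the fold change reported as the
ratio of group medians, and covariate-matched biallelic controls are
selected by seeded greedy nearest-neighbour matching on standardized log
RNA abundance and log CDS length, with Kolmogorov-Smirnov balance
diagnostics.

## Proteome integration

Reliability of each modality is the mean pairwise Spearman correlation
between replicates (0.53 translation efficiency, 0.71 ribosome profiling,
0.79 RNA-seq, 0.80 mass spectrometry as shipped defaults). Observed
cross-modality Spearman correlations are disattenuated by dividing by the
geometric mean of the two reliabilities — the classical correction for
attenuation — and capped at ±1 with a flag. Undefined entries are dropped
pairwise per grid cell, each cell reports its gene count, and cells under
30 shared genes are flagged unreliable rather than hidden.

## SNP effects on RBP motifs and uORFs

A position weight matrix scores a window by the min-max-normalised sum of
per-position weights (1 for the per-position argmax sequence, 0 for the
argmin; invariant to affine rescaling of the matrix). For a SNP, every
motif-length window overlapping it is scored on both alleles; because the
score is additive, the allelic difference reduces to the weight gap at
the SNP's in-motif position, and the signed difference with the largest
magnitude across windows represents the (SNP, PWM) pair. This exhaustive
scan is the self-contained equivalent of intersecting precomputed motif
instances. SNPs within 5 nt of another SNP are removed first (their
windows would confound two substitutions). Per RBP the worst-affected PWM
is kept; RBPs sharing a consensus at the same SNP collapse to one
comma-joined annotation with the median difference; differences are
standardized globally as (x − median)/IQR — globally rather than per RBP,
since the selection rule addresses a single distribution of standardized
differences — and SNPs at or above the 95th percentile of the absolute
standardized difference are flagged. A shipped exclusion list drops RBPs
without a mouse homologue or detectable embryonic expression.

The uORF scan tests the 9-nt window centred on each 5'UTR SNP against the
non-canonical initiation-context pattern
`[ATCG]+[AG][ATCG]{2}[ACG]TG[AG][ATCG]+` under each allele, reporting
SNPs where either allele matches, and can annotate matches with a
user-supplied context-to-efficiency lookup.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → preprocess → QC → translation
efficiency → allele-specific analysis → integration → variant effects.
All intermediates are TSV with a header carrying the package version,
master seed and a configuration content hash; reruns with the same
configuration are byte-identical. Deduplication keys are (gene, position,
length, UMI) for footprints — the stricter reading, since the footprint
length is part of the molecule's identity — and (gene, UMI) for RNA-seq,
i.e. per-gene UMI collapsing irrespective of position. VCF input follows
REF = maternal, ALT = paternal with 1-based positions converted at the
boundary; multi-allelic records are skipped with a warning.

## Problem sizes used in the checks

The packaged validation works at desk scale, chosen to exercise each
estimator's operating regime: error-rate recovery uses 2x10^5 (ribo) and
5x10^5 (RNA) single-SNP reads, where three binomial standard deviations
are ~0.11 and ~0.027 percentage points; paternal-ratio round trips use
10^5 reads (tolerance 0.5 percentage points); the null false-positive
check for differential engagement uses 500 genes with 25 bootstrap
resamples; bias classification uses the full 1,000 resamples; and planted
translation-efficiency effects (2x and 0.55x) are recovered within 10%
from five replicates of 5x10^4 reads with identical transcript geometry,
which removes length-ratio confounding from the group comparison.

## Known limitations

* Headline biological results of the original study (specific gene
  counts, proteome correlations) depend on the real embryo datasets and
  are not reproduced by simulation; the package validates the machinery,
  not the biology.
* One transcript per gene; no isoform-aware assignment.
* The bootstrap intervals undercover below ~5 replicates (see above).
* The motif scanner assumes additive, position-independent PWMs and does
  not model RNA secondary structure.
* The monoallelic flag requires an exact zero count for one allele, so
  with sequencing error it is practically restricted to modest-coverage
  genes — as in the source procedure.
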