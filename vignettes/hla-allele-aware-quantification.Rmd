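---
title: "Allele-aware quantification of HLA class I: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-aware quantification of HLA class I: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaquant)
```

# Why a personalized reference

The classical HLA class I genes are the most polymorphic loci in the human
genome, yet any two alleles of a gene are nearly identical over most of
their length. Two consequences drive everything in this package. First, a
universal reference systematically miscounts HLA reads and peptides, so
RNA and protein evidence must be interpreted against each patient's own
genotype. Second, only reads and peptides overlapping the *variable*
positions can distinguish genes from each other or alleles from each
other; the shared remainder is informative about the gene total but not
about either allele.

`hlaquant` therefore works in three tiers of specificity: gene-level
(peptides specific to one HLA gene and matching the sample genotype),
allele-level (peptides occurring in exactly one of the sample's two
alleles), and everything else (discarded: peptides that also occur in a
non-HLA protein, or in more than one HLA gene).

# Nomenclature

Alleles are named in IMGT/WMDA style, `GENE*group:protein[:synonym][P]`,
e.g. `A*24:02P`. All genotype-level work happens at two-field
(protein-level) resolution; `to_two_field()` drops the synonym field and,
when a P-group table is supplied, sets the P flag from it — without a
table the input flag is preserved, because inventing equivalence classes
silently would corrupt genotype comparisons. Canonical rendering zero-pads
numeric fields to two digits; parsing and rendering are mutually inverse
on canonical names. The allele group (`B*15`) is the unit of the
population-frequency analysis.

# Genotyping model

The genotyper is a deliberately transparent stand-in for de Bruijn graph
pseudoalignment followed by EM-based genotype selection: a read is
*compatible* with a candidate allele coding sequence iff every k-mer of
the read (default k = 31) occurs in that sequence. Genotype selection is
greedy and iterative: pick the allele compatible with the most reads, then
the allele explaining the most additional reads, then re-rank each member
of the pair against the other until the pair is stable. All ties break by
canonical name order so calls are fully deterministic.

Homozygosity is decided from reads that distinguish the pair: with `n1`
and `n2` reads compatible with exactly one of the two selected alleles,
the call is homozygous when `min/max < 0.15`. The comparison is strict at
the boundary (a ratio of exactly 0.15 stays heterozygous); the threshold
is a parameter everywhere it is used. When no read distinguishes the pair
the call degenerates to the top-ranked allele with a warning.

Paired tumor/normal genotypes are then classified by `detect_loh()`:

* `concordant` — equal as unordered pairs;
* `loh` — normal heterozygous, tumor homozygous for one of the normal
  alleles; the other normal allele is reported as lost;
* `reverse_discrepancy` — tumor heterozygous, normal homozygous; this is
  the biologically implausible direction (a somatic *gain* of an allele)
  and is kept separate rather than folded into LOH;
* `other_discrepancy` — anything else.

A note on the published discrepancy table shipped with the package: its
footnote describes LOH with tumor and normal swapped relative to the table
contents and the surrounding text. The package follows the table and text
(tumor homozygous = LOH); the one row in the opposite direction is exactly
what `reverse_discrepancy` captures.

Allele imbalance uses the published rule verbatim: on the linear scale,
the tumor minor/major expression ratio must be `< 0.5` and the tumor
major/minor fold must be `>= 1.5x` the normal major/minor fold, both
parameters configurable. Expression must be strictly positive — upstream
code adds pseudocounts before linearizing.

# RNA quantification

Reads compatible with exactly one genotype allele count fully towards it.
Reads compatible with both are apportioned **proportionally to the unique
counts** — the EM fixed point for a two-sequence reference (if `u1`, `u2`
are unique counts and `s` shared, the stationary solution assigns
`s * u1/(u1+u2)` to allele 1). An `"even"` 50/50 split is available as an
option; it corresponds to a single EM step from a uniform start and
shrinks allele ratios towards 1 whenever a large fraction of reads falls
in conserved regions, which is why it is not the default: the imbalance
analysis depends on the allele ratio being recovered without that bias.

Normalization is `log2(count / size_factor + 1)` with size factors either
proportional to the library size (default) or DESeq-style median-of-ratios
when all features are observed everywhere. This is a variance-tamed log
scale rather than a full variance-stabilizing transformation; the method
is recorded in the matrix metadata so a heavier transform can be slotted
in without touching downstream code. Gene totals for heterozygous samples
are `log2(2^a1 + 2^a2)` (hence between `max(a1, a2)` and `max + 1`);
homozygous samples carry the single allele value unchanged.

# MS quantification

The pipeline starts from identified PSM tables — spectral search is out of
scope by design, and a documented TSV contract (peptide, plex, fraction,
charge, scan, expectation, one column per reporter channel) defines the
hand-off. Filtering keeps PSMs with expectation strictly below 0.001 and
at least one positive reporter. Modified peptides are expected to arrive
stripped to their sequence; charges, scans and chromatographic fractions
are summed per peptide, per plex, per channel.

Quantification is relative to the pooled reference channel of each plex:
`log2((sample + floor) / (reference + floor))`, floor 0 by default with an
explicit error on zero references (the synthetic generator never emits
zero reference intensities, and real pooled references are mixtures of
many samples, so a zero is a data defect worth surfacing rather than
hiding). Peptide-level analyses then median-center each sample across its
quantified peptides; the whole-proteome table is instead median-centered
per protein across samples (`median_center_rows()`). These are distinct
operations and are never applied together.

Peptide specificity is exact substring matching against the
provenance-tagged search database (standard proteome + all HLA alleles +
contaminants). Isoleucine and leucine are treated as distinct residues by
default — genotype matching is defined as 100% sequence identity — with an
`il_equivalent` switch for sensitivity analysis, since mass spectrometry
cannot distinguish the two residues. No isotope-impurity correction is
applied to TMT channels, and no FDR machinery is included; both belong to
the upstream search engine.

# Cohort statistics

Per-patient tumor/normal differential expression uses Welch's two-sample
t-test over eligible (gene-specific, genotype-matched) peptide log-ratios;
the pooled-variance test is available via a flag. The peptide populations
in tumor and normal are different physical measurements, which is why an
unpaired test is used at this level (the *paired* t-test appears one level
up, comparing per-sample matched vs unmatched peptide medians across
samples). Benjamini-Hochberg adjustment is applied per gene across the
patients of a study; the scope is a documented choice, since "multiple
testing adjusted" alone does not pin it down.

Allele-level fold changes are restricted to patients whose gene-level test
was significant and to alleles with at least three unique allele-specific
peptides in both tissues. Flags compare linear fold changes: `flag20` for
a departure from 1 beyond 20% in either direction, `flag30` for
overexpression beyond 30%.

Allele-group enrichment tests the observed group count among `2 x
patients` alleles with a two-sided exact binomial test against the
ancestry-weighted expected frequency, BH-adjusted within gene; a group is
enriched when adjusted p < 0.05 *and* the observed frequency exceeds the
expected by more than 50%. The binomial model is the minimal choice given
that each patient contributes two independent draws under Hardy-Weinberg;
population expected frequencies are a required input, never bundled,
because their provenance (registry tables, ancestry composition) is
cohort-specific.

The variance partition fits `protein ~ rna` and `protein ~ rna + score`
by ordinary least squares and reports both R² values, the score
coefficient with its standard error, and the correlation of the base
model's residuals with the score; rank-deficient design matrices are
flagged rather than silently dropped.

# The synthetic cohort generator

The generator exists so that every claim the package makes can be
exercised with known ground truth. What it emulates, and how:

* **Sequence structure** (`make_allele_db`): one ~365-residue base protein
  per gene, derived from a common ancestor at ~5% divergence between genes
  and ~2% between alleles of a gene. This reproduces the constraints that
  matter: most tryptic peptides are shared within a gene, some cross gene
  boundaries (exercising the multi-gene discard rule), and each allele
  keeps at least one unique peptide (checked, with bounded retries). A
  zero substitution rate produces identical alleles — the degenerate
  fixture for discard-path tests. Coding sequences are deterministic
  back-translations, so nucleotide and protein tiers stay consistent.
* **Genotypes** (`make_cohort`): allele-wise i.i.d. draws from per-gene
  frequencies, so homozygosity follows Hardy-Weinberg (Σp²). Injected
  events per heterozygous gene are mutually exclusive: LOH collapses the
  tumor genotype to one uniformly chosen allele; imbalance records a
  minor/major factor drawn from (0.15, 0.30) — comfortably inside the
  published detection rule (< 0.5 and 1.5-fold margin) so that noiseless
  recovery is exact.
* **RNA** (`make_rna`): expected per-gene counts scaled by injected tumor
  fold changes, split between alleles (evenly, or by the imbalance
  factor), negative-binomial at the given dispersion. Dispersion 0 is the
  deterministic limit (counts = rounded expectations). Optional read
  simulation draws uniform windows from the allele cds with uniform
  substitution errors.
* **TMT PSM tables** (`make_psm_tables`): detection is Bernoulli per
  (peptide, plex), not per sample, because isobaric identification is
  plex-level — this reproduces the real phenomenon that genotype-specific
  peptides of one sample are harder to detect unless shared with other
  plex members. The pooled reference channel is the arithmetic mean of
  member abundances. Reporter intensities are proportional to the sample's
  true abundance of the carrier alleles plus a small co-isolation
  background (default 2% of base abundance) with log-normal noise; the
  background is what gives unmatched peptides compressed-but-nonzero
  signal, as in real TMT data, and is also the reason recovered fold
  changes are mildly compressed (~0.02 on the log2 scale at defaults). A
  constant-abundance background proteome (default 30 proteins) anchors the
  per-sample median centering the way the bulk proteome does in a real
  study. Optional decoy rows carry expectation values at or above 0.001,
  so the confidence filter removes exactly them.

What it does **not** emulate: real IMGT sequences or population allele
frequencies, spectrum-level effects (m/z, fragmentation, co-eluting
precursors beyond the constant background), search-engine score
distributions, isotope impurity, batch effects between plexes, or tumor
purity/heterogeneity. Passing tests therefore demonstrate the correctness
and statistical calibration of the *analysis*, not the error profile of
any particular instrument or cohort.

# Problem sizes and numerical choices in the test suite

The test suite runs entire cohorts end to end, sized for a development
machine: property checks use 6-25 patients with 300-1000 reads per gene;
the Hardy-Weinberg checks use 400-800 patients (genotypes only, which are
cheap); the fold-change recovery check uses 20 patients x 3 genes so the
median error is estimated over ~60 patient-gene values; the
matched-vs-unmatched calibration uses 100 replicates of 100 samples
simulated directly at the peptide-ratio level. LOH recovery and imbalance
recovery are validated in separate noiseless scenarios: strong expression
imbalance intentionally *looks* homozygous to an RNA-level genotyper when
the minor allele fraction approaches the homozygosity threshold, so the
two event types are injected separately where exact 100% sensitivity and
specificity are asserted — mirroring how the published definitions keep
"imbalanced" conditional on a heterozygous call in both tissues.

Other numerical choices: strict `<` at the 0.15 homozygosity and 0.001
expectation boundaries (documented above); pseudocount 1 before logs so a
zero count maps to 0; intensity floor 0 with explicit errors; ties in
rank-based statistics handled by average ranks via the standard
implementations; every tie-break on names is lexicographic on canonical
strings.

# Known limitations

* The genotyper considers boolean k-mer compatibility, not abundance-aware
  EM over the full candidate set; with very similar candidate alleles and
  shallow coverage it will be less sensitive than a full pseudoalignment
  EM. It is, in exchange, exactly reproducible and auditable.
* Allele-level protein estimates rest on few peptides for HLA-B/C-like
  homology structures; the three-peptide rule guards the fold-change
  analysis but cannot create information that is not there.
* The expectation-value filter trusts the upstream search engine's score
  calibration; no decoy-based FDR is recomputed.
* P-group membership is taken from an explicit table when provided and
  never inferred from sequence.
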