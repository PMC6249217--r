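---
title: "Methods: time-resolved multi-omic analysis of organ development"
author: "devomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved multi-omic analysis of organ development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devomics)
```

# Scope

`devomics` implements the computational core of a time-resolved,
label-free proteome + transcriptome study of a developing organ sampled at
15 timepoints (embryonic days E12.5-E18.5, postnatal days D1-D5, postnatal
weeks W1-W8) with 3 biological replicates each. Five stages are covered:

1. **Splice-junction proteogenomics** — building a peptide search database
   from novel junctions in assembled transcripts, and matching observed
   peptide-spectrum matches (PSMs) back to it.
2. **Quantification** — iBAQ-based iFOT label-free quantification with
   tiered identification filters.
3. **Phase analysis** — partitioning timepoints into developmental phases,
   phase-wise differential expression, coexpression grouping, gene-set
   enrichment.
4. **Integration** — protein-RNA correlation and development-vs-cancer
   overlap statistics.
5. **Synthetic data** — a ground-truthed generator for every input, so the
   whole pipeline is testable without any external download.

Spectrum-level search, read alignment and transcript assembly are out of
scope: the pipeline consumes PSM tables and assembled-transcript GTFs.

# Junction-peptide database construction

An assembled transcript's consecutive exon pair defines a *junction key*:
the genomic (left-exon end, right-exon start) boundary pair on a strand.
Junctions are classified against the annotation:

* **known** — the key exists among annotated junctions;
* **novel_candidate** — the key is unannotated *and* exactly one flanking
  exon matches an annotated exon (an unannotated exon joined to a known
  exon);
* **rejected** — anything else (both exons novel, or both known but joined
  by an unannotated key). Rejected junctions are retained in the output
  table rather than silently discarded.

The exon-match predicate is exact boundary identity
(chromosome, start, end, strand) by default; a containment/overlap mode is
available (`exon_match = "overlap"`). Exact matching is the reproducible
choice; which predicate the original analyses of this kind use is rarely
stated.

Each `novel_candidate` is in-silico spliced (full exon sequences
concatenated in transcript order, reverse-complemented on the minus
strand), translated in all three reading frames, and digested with the
literal trypsin rule: cleavage after every K and R, zero missed cleavages,
**no proline exception** (a `proline_rule` flag enables the conventional
KP/RP skip). Peptides are kept when they

* contain no stop (`*`) and no ambiguous residue (`X`; codons containing N
  translate to X and are dropped — conservative, keeps the FASTA
  searchable),
* are at least 7 residues long (the usual minimum search length),
* **span the splice boundary** with at least one residue on each side — a
  residue belongs to the donor side when its codon *starts* at or before
  the boundary nucleotide (a codon straddling the boundary counts as
  donor-side; the peptide must then still contain a residue starting after
  the boundary, so spanning evidence is always two-sided),
* are not exact substrings of the reference proteome. I and L are treated
  as distinct characters by default (search engines compare sequence
  databases literally); `il_equivalent = TRUE` collapses them.

A `max_context` cap (600 nt per exon, adjacent to the boundary) guards
pathological exons; because only boundary-spanning peptides are kept, the
cap cannot change the result for peptides up to 200 residues.

PSM matching back to the junction FASTA keeps identifications with ion
score **strictly greater than 30**, re-checks novelty against the
reference proteome, and aggregates precursor intensity per
(peptide, sample). FDR estimation belongs to the upstream search engine
and is not reimplemented.

## The independent oracle

`enumerate_junction_peptides_naive()` recomputes the expected peptide set
of any junction list by brute force: its own reverse complement, its own
codon table, and enumeration of *every substring* of every frame's
translation with explicit full-trypticity checks — no code shared with the
production builder. The synthetic generator uses only the oracle to write
its ground truth, so builder-vs-truth comparisons are never
self-confirming.

# Quantification and identification filters

For protein $i$ in sample $s$:

$$\mathrm{iBAQ}_{is} = \frac{\sum_{p \in \mathrm{peptides}(i,s)} I_{ps}}
{\#\{\text{tryptic peptides of } i \text{ with } 7 \le \ell \le 30\}},
\qquad
\mathrm{iFOT}_{is} = 10^5 \cdot
\frac{\mathrm{iBAQ}_{is}}{\sum_j \mathrm{iBAQ}_{js}}.$$

Numerical choices:

* The observable-peptide length window $[7, 30]$ follows the original iBAQ
  convention and is configurable (`len_range`); whether the emulated study
  bounded peptide lengths is not stated.
* Peptides shared between accessions are excluded from the intensity sums
  by default (`shared = "exclude"`); attributing them to every parent is
  available. Proteins with zero theoretical peptides are flagged
  non-quantifiable rather than silently zero.
* Missing (protein, sample) evidence is 0 — missing values are substituted
  with zeros throughout.
* Per-sample iFOT values sum to $10^5$ exactly; this is asserted at
  relative tolerance $10^{-9}$ in the tests.

The tiered filters mirror the usual dataset nesting: all identifications
(tier 1); accessions with at least one unique peptide (a sequence mapping
to exactly one accession) *and* two strict peptides (best ion score
$\ge 20$) (tier 2); features observed in at least 2 of 3 replicates at
one or more timepoints (tier 3); and the *core proteome*, detected at
every timepoint. The phrase "one unique and two strict peptides" is
ambiguous about whether the unique peptide may count toward the two; the
default lets a qualifying unique peptide count
(`strict_includes_unique = TRUE`), and the stricter reading is a switch.
Both filters are monotone: adding evidence never removes an accession.

# Phase analysis

**Partitioning.** Samples are clustered on the distance
$1 - \rho_\mathrm{Spearman}$ with average linkage and the tree is cut at
$k = 3$. All 45 replicate columns are clustered by default; the partition
is accepted (`stable = TRUE`) only when (a) all replicates of each
timepoint land in one cluster and (b) clusters form contiguous blocks in
developmental order. Averaging replicates first (`collapse = TRUE`) is the
config alternative. Rank correlation was chosen because inter-experiment
agreement in this data type is conventionally summarized by Spearman
coefficients and because it is invariant to the heavy-tailed intensity
scale; Ward linkage is reserved for gene coexpression. PCA scores (on
row-z-scored profiles, so the result is scale-free) are returned for
secondary confirmation, and the agreement between the tree cut and a
k-means run on the top-2 principal components is reported as an adjusted
Rand index. `hclust` and deterministic seeding make repeated runs
identical on fixed input.

**Differential expression.** Per-feature one-way ANOVA across phase
groups, replicates as observations, on log10 values, followed by
Benjamini-Hochberg adjustment over all testable features; rows with zero
total variance are untestable and excluded from the BH denominator. The
row-wise F statistic is computed vectorized over the matrix and is
verified in the tests against `stats::oneway.test(var.equal = TRUE)` row
by row. The default significance threshold is FDR < 0.01.

**Coexpression.** "Semi-supervised" grouping is interpreted as: restrict
to ANOVA-significant features, then unsupervised Ward clustering
(`ward.D2`, Euclidean distance on row z-scores), cut at the requested
number of groups (3 for proteins, 4 for RNA in the emulated design), with
groups relabeled in the temporal order of their mean-profile peak. This
interpretation is a documented choice, not a claim about the original
procedure.

**Enrichment.** Standard one-sided hypergeometric over-representation per
GMT gene set with BH adjustment across sets; the KEGG/GO databases
themselves are inputs, not dependencies.

# Integration

**Protein-RNA correlation.** Replicate columns are collapsed to timepoint
means on the intensity scale (zeros are observed values), means are
log10-transformed with a pseudocount of half the smallest nonzero value,
z-scored per gene across the 15 timepoints, and the Pearson correlation
between the two z-vectors is reported per gene together with the cohort
median. Collapsing *before* the log transform matters: a dropout zero
averaged into a timepoint mean shifts it by at most a factor
$n_\mathrm{rep}/(n_\mathrm{rep}-1)$, whereas log-transforming first turns
the same zero into an outlier several orders of magnitude low. Genes with
zero variance in either modality are excluded.

**Overlap statistics.** The development-vs-cancer overlap within a pathway
uses the exact two-sided ("minimum-likelihood") hypergeometric convention:
the p-value sums the probabilities of all overlap values whose point
probability does not exceed the observed one (with a $1 + 10^{-7}$ tie
tolerance). Doubling the smaller tail is available
(`method = "double"`). The minimum-likelihood convention was chosen
because it is the standard exact two-sided test and is verifiable by
enumeration — the tests compare it against a binomial-coefficient
enumeration for every parameter combination with $N \le 30$. Both altered
sets are intersected with the pathway-restricted universe (genes detected
in both studies) first; an empty restricted universe yields an undefined,
flagged result rather than an error, mirroring the small-pathway caveat of
this kind of analysis. Homology mapping between the cancer and development
identifier spaces is consumed as an input table, never inferred.

# The synthetic-data generator

The generator defines the study conditions; its defaults are fixed once
and encode the emulated design.

**Genome.** Gene models are built protein-first: a random amino-acid
sequence is reverse-translated through random synonymous codons and split
into 2-5 exons with 60-200 nt introns, placed on random background
chromosomes on both strands, so the reference proteome is exactly the
frame-0 translation of the annotated CDS. Novel junctions are implanted by
joining a randomly chosen annotated exon to a 30-90 nt exon placed in a
reserved transcript-downstream flank; the assembled GTF contains the
annotated models (known junctions) plus these two-exon transcripts. The
ground-truth peptide set is computed by the brute-force oracle.

**Time course.** Per gene $g$, timepoint $t$, replicate $r$, on the log10
scale:

$$y_{gtr} = b_g + s_{gt} + \delta_g\,\mathbb{1}[\mathrm{phase}(t) =
\mathrm{peak}_g] + \varepsilon_{gtr},$$

with baseline $b_g \sim U(0, 8)$ (8 orders of magnitude of dynamic
range), a smooth AR(1) temporal signal $s_{gt}$ (marginal SD 1, lag-1
autocorrelation 0.85 — developmental trajectories are smooth, which is
also what makes temporally adjacent samples correlate at 0.8-0.99 as real
data does), replicate noise $\varepsilon \sim N(0, \sigma^2)$ with
$\sigma = 0.25$ (about 60% CV, typical for label-free replicates), and an
implanted phase effect $\delta_g = \mathrm{effect} \times \sigma$ (a
*standardized* shift, so "effect 3, noise 1" is a 3-SD shift in any
units) for a fraction of genes peaking in one of the three reference
phases Ph1 = E12.5-E16.5, Ph2 = E17.5-W2, Ph3 = W3-W8. The differential
fraction defaults to 0.56, matching the reported proportion of
phase-differential proteins among analyzed gene products in the emulated
study.

**Missingness.** Dropout is Bernoulli per (gene, sample) at rate 0.1 and
zeros substitute missing values. It is intensity-independent by default —
the mechanism in real data is uncharacterized, so both options are
exposed rather than asserted. The `dropout_bias` option concentrates
missingness at low abundance (quadratic in descending abundance rank,
mean rate preserved), reflecting the steep detection curves of MS
instruments; structured missingness is what preserves the high
adjacent-sample rank correlations seen in real filtered data, and the
corresponding property check runs under this option.

**Dynamic-range calibration.** After noise, effects and dropout, the
nonzero log10 values of each matrix are affinely rescaled so the realized
dynamic range equals the configured 8 orders exactly. An affine map on the
log scale preserves correlations, standardized effect sizes and clustering
structure, so this calibration pins the dynamic-range property without
touching any statistical property under test.

**Protein-RNA coupling.** The RNA timepoint profile is built from the
z-scored protein signal through a Gaussian copula,
$z_R = \rho' z_P + \sqrt{1 - \rho'^2}\, z_\perp$ with $z_\perp$
orthogonalized against $z_P$. The coefficient $\rho'$ is inflated
analytically to undo the attenuation the measurement pipeline introduces:
the delta-method variance of the log of a mean of log-normal replicates,
the variance contributed by dropout through the binomial survivor count,
and the first-order finite-sample bias of the Pearson estimator over 15
points. These corrections are derived, not fitted; parameter-recovery
tests confirm the realized median correlation lands within 0.05 of targets
0.2, 0.55 and 0.8 at 3,000 genes.

**PSM tables.** Per-protein tryptic peptides (length 7-30) receive
log-normal intensities across the configured dynamic range and
Gamma-distributed ion scores (shape 8, rate 0.32; mean 25), giving
closed-form tail probabilities for the score filters and mass on both
sides of the 20 and 30 cutoffs. A quarter of proteins are made ubiquitous
(the implanted core proteome); 15% receive one peptide shared with a
second accession (flagged non-unique); a configurable fraction of the
expected junction peptides appears with scores straddling 30.

**Calibration sims for the ANOVA.** The null and power checks run with
`temporal_sd = 0` and `dropout_rate = 0`: a clean exchangeable null. The
smooth temporal signal is deliberately excluded there because variation
shared across replicates violates the one-way ANOVA null even with no
phase effect — a real limitation of phase-wise ANOVA on time courses,
worth knowing when interpreting q-values on real data.

**What the generator does not emulate.** No spectra, no reads, no
peptide-level FDR structure, no batch effects, no compositional coupling
between proteins, no isoform-level quantification ambiguity, and
missingness mechanisms far simpler than reality. Passing tests demonstrate
the correctness and calibration of the *methods*, not performance
guarantees on real data.

# Problem sizes used in the checks

The package's verification suite uses toy genomes of 5-30 genes with up to
10 implanted junctions (junction stages are exact-equality checks against
the oracle), 1,000-gene matrices over 100 seeds for phase recovery,
5,000-gene matrices for FDR/power calibration, 3,000 genes for
correlation recovery, and the exhaustive $N \le 30$ grid for the
two-sided hypergeometric. These sizes give stable Monte-Carlo estimates
while keeping the default suite fast.

# Known limitations

* The junction classifier requires exact exon-boundary matches by default;
  assembled exons with slightly shifted boundaries (common with real
  assemblers) fall back to `rejected` unless `exon_match = "overlap"`.
* Phase partitioning assumes contiguous phases in developmental order; a
  biology with recurrent regimes would be flagged unstable rather than
  modeled.
* One-way ANOVA treats replicates as exchangeable observations within a
  phase; temporal autocorrelation within phases inflates its statistic
  (see the calibration note above).
* The iFOT normalization makes values compositional; correlations between
  proteins inherit the usual closure artifacts.
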