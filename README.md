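# devomics

Time-resolved multi-omic analysis of organ development: splice-junction
proteogenomics, iBAQ/iFOT label-free quantification, temporal phase
discovery, and protein–RNA / development–cancer integration — with a
fully ground-truthed synthetic-data generator so every stage is testable
offline.

## The problem

Developmental atlases profile an organ's proteome and transcriptome at
many timepoints (here: 15 stages from embryonic day E12.5 to postnatal
week W8, three biological replicates each). Turning the raw measurements
into biology requires a chain of specialized steps that are usually
scattered across ad-hoc scripts:

* **Novel splice-junction peptides.** Assembled transcripts contain
  junctions absent from the annotation. Joining a known exon to an
  unannotated exon, splicing in silico, translating in 3 frames and
  digesting with trypsin (no missed cleavages, no stop codons, minimum 7
  residues, not a substring of the reference proteome, spanning the
  boundary with ≥1 residue on each side) yields a peptide FASTA that MS
  search engines can use to validate novel transcripts at the protein
  level. Matches are accepted at ion score > 30.
* **Label-free quantification.** iBAQ = summed precursor intensity of a
  protein's peptides divided by its count of theoretically observable
  tryptic peptides (length 7–30); FOT = iBAQ / total iBAQ in the sample;
  iFOT = FOT × 10⁵, so every sample sums to 10⁵. Tiered filters retain
  accessions with ≥1 unique peptide and ≥2 strict peptides (ion score
  ≥ 20), then features seen in ≥2 of 3 replicates at some timepoint.
* **Phase structure.** Hierarchical clustering (1 − Spearman ρ, average
  linkage) plus PCA partitions the 15 timepoints into contiguous phases
  (reference: Ph1 E12.5–E16.5, Ph2 E17.5–W2, Ph3 W3–W8); one-way ANOVA
  with Benjamini–Hochberg adjustment (FDR < 0.01) finds phase-differential
  genes; Ward clustering groups coexpression profiles; hypergeometric
  tests score gene-set enrichment.
* **Integration.** Per-gene Pearson correlation of z-scored protein and
  RNA timepoint profiles; exact two-tailed (minimum-likelihood)
  hypergeometric tests for the overlap of development-altered and
  cancer-altered genes within pathways.

`devomics` packages this chain as composable, tested R functions for
anyone analysing time-course proteogenomic data or benchmarking such
pipelines.

## Worked example

```r
library(devomics)

## a toy study with known ground truth
cfg <- sim_config(seed = 7, n_genes = 40, n_novel_junctions = 4)
sim <- simulate_genome(cfg)

## junction database: classify, splice, translate, digest, filter
db <- build_junction_db(sim$genome, sim$annotation, sim$assembled, sim$proteome)
table(db$candidates$status)
#>           known novel_candidate
#>             101               4
head(db$peptides[, c("sequence", "frame", "junction_offset", "gene_id")], 3)
#>                       sequence frame junction_offset gene_id
#> 1 LALHDAHDECLAVHQMTAVVPGLASPNA     1               2   G0008
#> 2                LFHDMPSCLVFHR     0               1   G0030
#> 3            YSGSGCALLTNYSTTCR     1              12   G0030
setequal(db$peptides$sequence, sim$truth$expected_junction_peptides)
#> [1] TRUE

## quantification tiers from a simulated PSM table
p <- simulate_psm_table(sim, cfg)
ds <- build_datasets(p$psms[!p$psms$is_junction, ], sim$proteome)
ds$counts
#> dataset1 dataset2 dataset3
#>       40       39       39

## phase discovery on a simulated time course
tc <- simulate_timecourse(sim_config(seed = 7, n_genes = 600,
                                     noise_sd = 1, phase_effect_size = 3))
pp <- partition_phases(tc$protein, k = 3)
pp
#> phase_partition: 3 phases over 15 timepoints (stable)
#>   Ph1: E12.5 E13.5 E14.5 E15.5 E16.5
#>   Ph2: E17.5 E18.5 D1 D3 D5 W1 W2
#>   Ph3: W3 W6 W8
#>   HC vs k-means(top-2 PCs) ARI: 1.000

## differential expression and protein-RNA correlation
de <- anova_bh(qm_log10(tc$protein), pp, fdr = 0.01)
sum(de$significant)
#> [1] 118
protein_rna_correlation(tc$protein, tc$rna)$median_r
#> [1] 0.735
```

The partition above recovers the implanted reference phase boundaries
exactly. Of the 118 significant genes, 109 carry an implanted phase shift
(the remainder are false positives admitted by the 1% FDR under this
noise level and missingness); the median correlation reflects the
configured protein–RNA coupling at this noise level.

## Package layout

* `R/sim-*.R` — synthetic genome/annotation, PSM tables, time-course
  matrices (ground truth included).
* `R/junction-db.R`, `R/oracle.R` — junction classification, splicing,
  translation, digestion, FASTA construction, PSM matching; plus the
  independent brute-force oracle used for truth and tests.
* `R/quantify.R` — iBAQ, iFOT, identification filter tiers, core
  proteome.
* `R/phase-analysis.R` — sample correlations, phase partitioning, ANOVA +
  BH, Ward coexpression, GMT enrichment.
* `R/integration.R` — FPKM filtering, isoform DE, protein–RNA
  correlation, two-tailed hypergeometric overlap tests, cancer-to-phase
  mapping.
* `vignettes/devomics-methods.Rmd` — the model, parameter and design
  documentation.
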