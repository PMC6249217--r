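# Shared fixtures, all built in code at test time.

# a minimal hand-written exon table: two transcripts on chr1 (+/-), one
# single-exon transcript
toy_exons <- function() {
  data.frame(
    chrom = "chr1",
    start = c(100L, 300L, 500L, 700L, 1000L),
    end = c(200L, 400L, 600L, 800L, 1100L),
    strand = c("+", "+", "-", "-", "+"),
    transcript_id = c("txA", "txA", "txB", "txB", "txC"),
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    stringsAsFactors = FALSE)
}

write_toy_gtf <- function(exons = toy_exons()) {
  path <- tempfile(fileext = ".gtf")
  lines <- sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$chrom, exons$start, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id)
  writeLines(lines, path)
  path
}

# quant_matrix over 2 timepoints x 3 replicates from a plain value matrix
toy_qm <- function(values, tps = c("E12.5", "W8"), unit = "iFOT") {
  cols <- as.vector(outer(tps, 1:3, function(t, r) paste0(t, "_", r)))
  m <- matrix(values, nrow = length(values) / length(cols), ncol = length(cols),
              byrow = TRUE, dimnames = list(NULL, cols))
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  quant_matrix(m, unit = unit)
}

# small PSM table builder
psm_row <- function(peptide, accessions, score, intensity = 1000,
                    sample = "E12.5_1") {
  data.frame(peptide = peptide, accessions = accessions, ion_score = score,
             intensity = intensity, sample = sample, stringsAsFactors = FALSE)
}

# random amino-acid string (may include K/R cleavage sites)
random_aa <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I",
                                      "K", "L", "M", "N", "P", "Q", "R", "S",
                                      "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
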