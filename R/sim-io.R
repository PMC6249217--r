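# Writers for the simulated study: FASTA / GTF / TSV / JSON files with
# deterministic content so identical configurations give byte-identical
# outputs.

.write_gtf <- function(exons, path, source = "devomics") {
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$chrom, source, exons$start, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated study to disk
#'
#' Serializes a [simulate_all()] bundle (or the output of the individual
#' generators) into plain-text files: genome FASTA, annotation and
#' assembled-transcript GTF (1-based inclusive, `exon` features with
#' `gene_id`/`transcript_id` attributes), reference proteome FASTA, PSM TSV,
#' protein and RNA matrix TSVs (`<timepoint>_<rep>` columns) and the ground
#' truth as JSON.
#'
#' @param sim Bundle from [simulate_all()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    assembled = file.path(dir, "assembled.gtf"),
    proteome = file.path(dir, "proteome.fa"),
    psms = file.path(dir, "psms.tsv"),
    protein = file.path(dir, "protein_matrix.tsv"),
    rna = file.path(dir, "rna_matrix.tsv"),
    truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(sim$genome$genome, paths["genome"], width = 80L)
  .write_gtf(sim$genome$annotation$exons, paths["annotation"],
             source = "annotation")
  .write_gtf(sim$genome$assembled, paths["assembled"], source = "assembled")
  Biostrings::writeXStringSet(sim$genome$proteome, paths["proteome"],
                              width = 80L)
  utils::write.table(sim$psms, paths["psms"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_quant_matrix(sim$protein, paths["protein"])
  write_quant_matrix(sim$rna, paths["rna"])
  truth <- sim$truth
  truth$peak_phase <- as.list(truth$peak_phase)
  truth$phase_assignment <- as.list(truth$phase_assignment)
  truth$rna_protein_rho <- as.list(truth$rna_protein_rho)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(paths)
}
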