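# Toy genome + annotation synthesis with implanted novel splice junctions.
# Gene models are built protein-first (random amino-acid sequence,
# reverse-translated through random synonymous codons, split into exons), so
# the reference proteome is exactly the translation of the annotated CDS.

.aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# codons per amino acid (sense codons only), derived from the standard code
.codons_by_aa <- local({
  tab <- .codon_table[.codon_table != "*"]
  split(names(tab), unname(tab))
})

.reverse_translate <- function(aa) {
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(res, function(a) {
    opts <- .codons_by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

.rev_comp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate a toy genome, annotation and reference proteome
#'
#' Generates multi-exon gene models on both strands of `n_chromosomes`
#' random chromosomes, a reference proteome obtained by translating the
#' annotated CDS, an assembled-transcript set (copies of the annotated
#' transcripts plus `n_novel_junctions` two-exon transcripts each joining an
#' annotated exon to an unannotated exon), and the ground truth: the
#' implanted junction table and the expected junction peptides computed by
#' the independent brute-force oracle
#' ([enumerate_junction_peptides_naive()]), never by the production builder.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   (list of `exons` and `junction_keys`, as [load_annotation()]),
#'   `assembled` (exon data.frame), `proteome`
#'   ([Biostrings::AAStringSet] named by gene), and `truth` (list:
#'   `implanted_junctions` data.frame, `expected_junction_peptides`
#'   character vector).
#' @export
#' @examples
#' sim <- simulate_genome(sim_config(seed = 7, n_genes = 6,
#'                                   n_novel_junctions = 2))
#' sim$truth$implanted_junctions
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  if (config$n_novel_junctions > n)
    stop("more novel junctions requested than genes")
  gene_ids <- sprintf("G%04d", seq_len(n))

  zone <- 130L  # reserved flank per gene for implanting unannotated exons
  genes <- lapply(seq_len(n), function(i) {
    n_exons <- sample(2:5, 1L)
    aa_lens <- sample(15:60, n_exons, replace = TRUE)
    protein <- paste(sample(.aa_alphabet, sum(aa_lens), replace = TRUE),
                     collapse = "")
    exon_aa <- substring(protein, cumsum(aa_lens) - aa_lens + 1L,
                         cumsum(aa_lens))
    exon_nt <- vapply(exon_aa, .reverse_translate, character(1),
                      USE.NAMES = FALSE)
    introns <- if (n_exons > 1L) sample(60:200, n_exons - 1L, replace = TRUE)
               else integer(0)
    strand <- sample(c("+", "-"), 1L)
    span <- sum(nchar(exon_nt)) + sum(introns)
    list(protein = protein, exon_nt = exon_nt, introns = introns,
         strand = strand, span = span,
         need = span + 2L * zone + sample(150:400, 1L))
  })

  chrom_of <- rep(seq_len(config$n_chromosomes), length.out = n)
  need_per_chrom <- vapply(seq_len(config$n_chromosomes), function(ch)
    sum(vapply(genes[chrom_of == ch], `[[`, numeric(1), "need")) + 200L,
    numeric(1))
  chrom_len <- config$chromosome_length
  if (is.null(chrom_len)) {
    chrom_len <- as.integer(max(need_per_chrom))
  } else if (any(need_per_chrom > chrom_len)) {
    stop("chromosome_length ", chrom_len, " too short for ", n,
         " genes (need up to ", max(need_per_chrom), " nt)")
  }
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_seq <- lapply(seq_len(config$n_chromosomes), function(ch)
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE))
  names(chrom_seq) <- chrom_names

  cursor <- stats::setNames(rep(100L, config$n_chromosomes), chrom_names)
  ann_rows <- list()
  zones <- list()  # per gene: the flank available for a novel exon
  for (i in seq_len(n)) {
    g <- genes[[i]]
    ch <- chrom_names[chrom_of[i]]
    zl_start <- cursor[ch]
    gene_start <- zl_start + zone
    # genomic exon blocks: transcript order for '+', reversed + revcomp for '-'
    blocks <- if (g$strand == "+") g$exon_nt else
      vapply(rev(g$exon_nt), .rev_comp_chr, character(1), USE.NAMES = FALSE)
    pos <- gene_start
    m <- length(blocks)
    intr <- if (g$strand == "+") g$introns else rev(g$introns)
    starts <- integer(m); ends <- integer(m)
    for (b in seq_len(m)) {
      w <- nchar(blocks[b])
      starts[b] <- pos; ends[b] <- pos + w - 1L
      chrom_seq[[ch]][pos:(pos + w - 1L)] <-
        strsplit(blocks[b], "", fixed = TRUE)[[1]]
      pos <- pos + w + if (b < m) intr[b] else 0L
    }
    gene_end <- ends[m]
    cursor[ch] <- gene_end + 1L + zone + (g$need - g$span - 2L * zone)
    # exon rows in transcript order (reverse genomic order on '-')
    ord <- if (g$strand == "+") seq_len(m) else rev(seq_len(m))
    ann_rows[[i]] <- data.frame(
      chrom = ch, start = starts[ord], end = ends[ord], strand = g$strand,
      transcript_id = sprintf("T%04d", i), gene_id = gene_ids[i],
      stringsAsFactors = FALSE)
    zones[[i]] <- list(
      left = c(zl_start, gene_start - 1L),
      right = c(gene_end + 1L, gene_end + zone),
      chrom = ch)
  }
  annotation_exons <- do.call(rbind, ann_rows)
  rownames(annotation_exons) <- NULL

  # implant novel junctions: annotated donor exon joined to an exon placed
  # in the gene's reserved flank (transcript-downstream side)
  novel_rows <- list()
  junc_rows <- list()
  if (config$n_novel_junctions > 0L) {
    host <- sample.int(n, config$n_novel_junctions)
    for (j in seq_along(host)) {
      i <- host[j]
      g <- genes[[i]]
      ex <- ann_rows[[i]]
      donor <- ex[sample.int(nrow(ex), 1L), ]
      z <- zones[[i]][[if (g$strand == "+") "right" else "left"]]
      len <- sample(30:90, 1L)
      off <- sample.int(zone - len - 1L, 1L)
      nstart <- z[1] + off - 1L
      nend <- nstart + len - 1L
      novel_rows[[j]] <- data.frame(
        chrom = donor$chrom,
        start = c(donor$start, nstart), end = c(donor$end, nend),
        strand = g$strand, transcript_id = sprintf("ASMJ%03d", j),
        gene_id = gene_ids[i], stringsAsFactors = FALSE)
      junc_rows[[j]] <- data.frame(
        chrom = donor$chrom, strand = g$strand,
        donor_start = donor$start, donor_end = donor$end,
        acceptor_start = nstart, acceptor_end = nend,
        gene_id = gene_ids[i], transcript_id = sprintf("ASMJ%03d", j),
        key = if (g$strand == "+")
          .junction_key(donor$chrom, donor$end, nstart, "+")
        else .junction_key(donor$chrom, nend, donor$start, "-"),
        stringsAsFactors = FALSE)
    }
  }

  genome_chr <- vapply(chrom_seq, paste, character(1), collapse = "")
  genome <- Biostrings::DNAStringSet(genome_chr)
  names(genome) <- chrom_names
  proteome <- Biostrings::AAStringSet(
    vapply(genes, `[[`, character(1), "protein"))
  names(proteome) <- gene_ids

  # assembled transcripts: annotated models (known junctions) + novel joins
  asm_known <- annotation_exons
  asm_known$transcript_id <- paste0("asm_", asm_known$transcript_id)
  assembled <- rbind(asm_known, do.call(rbind, novel_rows))
  rownames(assembled) <- NULL

  implanted <- if (length(junc_rows)) do.call(rbind, junc_rows) else
    data.frame(chrom = character(), strand = character(),
               donor_start = integer(), donor_end = integer(),
               acceptor_start = integer(), acceptor_end = integer(),
               gene_id = character(), transcript_id = character(),
               key = character(), stringsAsFactors = FALSE)
  expected <- enumerate_junction_peptides_naive(
    genome_chr, implanted, as.character(proteome),
    min_len = config$min_peptide_length)

  list(genome = genome,
       annotation = list(exons = annotation_exons,
                         junction_keys = transcript_junctions(annotation_exons)$key),
       assembled = assembled,
       proteome = proteome,
       truth = list(implanted_junctions = implanted,
                    expected_junction_peptides = expected))
}
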