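# Brute-force junction-peptide enumeration, kept deliberately independent of
# the production builder in junction-db.R: its own reverse complement, its
# own codon table, and substring enumeration instead of digestion. Used to
# compute the expected peptide set of implanted junctions (synthetic ground
# truth) and as the equivalence oracle in tests.

.naive_codons <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

.naive_revcomp <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", toupper(s))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

.naive_exon_seq <- function(genome_chr, start, end, strand) {
  s <- substring(genome_chr, start, end)
  if (strand == "-") s <- .naive_revcomp(s)
  s
}

#' Brute-force enumeration of expected junction peptides
#'
#' Independent oracle for the junction-peptide builder: for every candidate
#' junction it splices the two exon sequences, walks every reading frame,
#' enumerates every substring of the translation, and keeps substrings that
#' are fully tryptic (preceded by K/R or the protein start, ending in K/R or
#' at the protein end, no internal K/R), contain no stop or ambiguous
#' residue, are at least `min_len` long, span the splice boundary with at
#' least one residue on each side (a residue is donor-side when its codon
#' starts at or before the boundary nucleotide), and are not substrings of
#' the reference proteome.
#'
#' @param genome Named character vector (or coercible
#'   [Biostrings::DNAStringSet]) of chromosome sequences.
#' @param junctions Data.frame with chrom, strand, donor_start, donor_end,
#'   acceptor_start, acceptor_end (one row per junction).
#' @param ref_proteome Character vector of reference protein sequences.
#' @param min_len Minimum peptide length (default 7).
#' @param max_context Nucleotides of each exon kept adjacent to the boundary.
#' @return Sorted character vector of unique expected peptide sequences.
#' @export
enumerate_junction_peptides_naive <- function(genome, junctions, ref_proteome,
                                              min_len = 7L,
                                              max_context = 600L) {
  genome <- vapply(as.list(genome), as.character, character(1))
  ref_proteome <- as.character(ref_proteome)
  found <- character(0)
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, ]
    don <- .naive_exon_seq(genome[[j$chrom]], j$donor_start, j$donor_end,
                           j$strand)
    acc <- .naive_exon_seq(genome[[j$chrom]], j$acceptor_start,
                           j$acceptor_end, j$strand)
    if (nchar(don) > max_context)
      don <- substring(don, nchar(don) - max_context + 1L)
    if (nchar(acc) > max_context)
      acc <- substring(acc, 1L, max_context)
    nt <- paste0(don, acc)
    b <- nchar(don)
    for (f in 0:2) {
      n_codons <- (nchar(nt) - f) %/% 3L
      if (n_codons < 1L) next
      codons <- substring(nt, f + 1L + 3L * (0:(n_codons - 1L)),
                          f + 3L * (1:n_codons))
      aa <- unname(.naive_codons[codons])
      aa[is.na(aa)] <- "X"
      prot <- paste(aa, collapse = "")
      # every substring, checked for full trypticity
      for (s in seq_len(n_codons)) {
        for (e in s:n_codons) {
          len <- e - s + 1L
          if (len < min_len) next
          frag <- substring(prot, s, e)
          if (grepl("[*X]", frag)) next
          prev_ok <- s == 1L || substring(prot, s - 1L, s - 1L) %in% c("K", "R")
          last <- substring(frag, len, len)
          end_ok <- e == n_codons || last %in% c("K", "R")
          if (!prev_ok || !end_ok) next
          internal <- substring(frag, 1L, len - 1L)
          if (grepl("[KR]", internal)) next
          codon_starts <- f + 3L * (s:e - 1L) + 1L
          left <- sum(codon_starts <= b)
          if (left < 1L || left > len - 1L) next
          if (any(vapply(ref_proteome,
                         function(rp) grepl(frag, rp, fixed = TRUE),
                         logical(1)))) next
          found <- c(found, frag)
        }
      }
    }
  }
  sort(unique(found))
}
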