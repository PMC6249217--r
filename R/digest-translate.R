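#' Fully tryptic in-silico digestion
#'
#' Cleaves an amino-acid string after every K and R (trypsin, zero missed
#' cleavages). By default there is no proline exception; set
#' `proline_rule = TRUE` to skip cleavage before P (conventional KP/RP rule).
#' The concatenation of the returned fragments always equals the input.
#'
#' @param aa Amino-acid string (may contain `*` for stop codons and `X` for
#'   untranslatable codons).
#' @param proline_rule Logical; suppress cleavage when the next residue is P.
#' @return Character vector of fragments in order; `character(0)` for an
#'   empty input.
#' @export
#' @examples
#' tryptic_digest("MKRACDEK")   # "MK" "R" "ACDEK"
#' tryptic_digest("AKPGGR")     # "AK" "PGGR" (no proline exception)
#' tryptic_digest("AKPGGR", proline_rule = TRUE)  # "AKPGGR"
tryptic_digest <- function(aa, proline_rule = FALSE) {
  stopifnot(is.character(aa), length(aa) == 1L)
  n <- nchar(aa)
  if (n == 0L) return(character(0))
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  cut_after <- res %in% c("K", "R")
  if (proline_rule) {
    next_p <- c(res[-1] == "P", FALSE)
    cut_after <- cut_after & !next_p
  }
  cut_after[n] <- FALSE
  ends <- c(which(cut_after), n)
  starts <- c(1L, head(ends, -1L) + 1L)
  substring(aa, starts, ends)
}

# codon -> amino acid lookup, standard genetic code; any codon containing a
# character outside ACGT (e.g. N) translates to "X"
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- as.character(gc)
  names(tab) <- names(gc)
  tab
})

.translate_frame <- function(nt, frame) {
  n <- nchar(nt)
  usable <- n - frame
  n_codons <- usable %/% 3L
  if (n_codons <= 0L) return("")
  codons <- substring(nt, frame + 1L + 3L * (seq_len(n_codons) - 1L),
                      frame + 3L * seq_len(n_codons))
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Three-frame translation
#'
#' Translates a nucleotide string in frames 0, 1 and 2 using the standard
#' genetic code. Stop codons translate to `*`; codons containing characters
#' outside A/C/G/T (e.g. N) translate to `X`; the incomplete tail codon is
#' truncated. Frame f has length `floor((n - f) / 3)`.
#'
#' @param nt Nucleotide string over the alphabet A, C, G, T, N (case
#'   insensitive).
#' @return Named character vector of length 3 (`frame0`, `frame1`, `frame2`).
#' @export
#' @examples
#' translate_3frames("ATGAAACGT")  # "MKR", "*N", "ET"
translate_3frames <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- toupper(nt)
  out <- vapply(0:2, function(f) .translate_frame(nt, f), character(1))
  names(out) <- paste0("frame", 0:2)
  out
}

#' Count theoretically observable tryptic peptides
#'
#' The iBAQ denominator: the number of fully tryptic fragments of a protein
#' whose length falls in `len_range` (default 7-30 residues, the convention
#' of the original iBAQ scheme).
#'
#' @param sequence Protein amino-acid string.
#' @param len_range Length-2 numeric vector, inclusive residue-length bounds.
#' @return Integer count.
#' @export
#' @examples
#' theoretical_peptide_count("MKAAAAAAK")  # 1 (only AAAAAAK is in [7, 30])
theoretical_peptide_count <- function(sequence, len_range = c(7L, 30L)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty protein sequence")
  frags <- tryptic_digest(sequence)
  len <- nchar(frags)
  sum(len >= len_range[1] & len <= len_range[2])
}
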