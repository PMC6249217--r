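# Splice-junction proteogenomics: classify novel junctions from assembled
# transcripts, in-silico splice + 3-frame translate, digest into fully
# tryptic peptides, filter against the reference proteome, emit a search
# FASTA, and match observed PSMs back to junction peptides.

.junction_key <- function(chrom, left_end, right_start, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(left_end),
          as.integer(right_start), strand)
}

.as_exon_df <- function(x) {
  need <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  stopifnot(is.data.frame(x), all(need %in% names(x)))
  stopifnot(all(x$start <= x$end), all(x$strand %in% c("+", "-")))
  x
}

#' Load exons and junction keys from a GTF annotation
#'
#' Reads `exon` features from a GTF file (1-based inclusive coordinates) and
#' derives the set of annotated junction keys from consecutive exons within
#' each transcript. A junction key is the genomic (left-exon end, right-exon
#' start) boundary pair on a chromosome/strand; the transcript orientation is
#' recorded separately, so plus- and minus-strand junctions with the same
#' genomic boundaries but different strands have different keys.
#'
#' @param gtf Path to a GTF file whose exon features carry `transcript_id`
#'   and `gene_id` attributes.
#' @return List with `exons` (data.frame: chrom, start, end, strand,
#'   transcript_id, gene_id) and `junction_keys` (character vector).
#' @export
load_annotation <- function(gtf) {
  gr <- tryCatch(rtracklayer::import(gtf, format = "gtf"),
                 error = function(e) stop("failed to parse GTF '", gtf, "': ",
                                          conditionMessage(e), call. = FALSE))
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", gtf)
  ex <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    stringsAsFactors = FALSE)
  if (anyNA(ex$transcript_id))
    stop("exon feature(s) without transcript_id in ", gtf)
  list(exons = ex, junction_keys = transcript_junctions(ex)$key)
}

#' Enumerate junctions from exon chains
#'
#' For each transcript, exons are sorted by genomic position and each pair of
#' consecutive exons contributes one junction. The donor exon is the
#' transcript-upstream exon (the genomically left exon on `+`, the right exon
#' on `-`).
#'
#' @param exons Exon data.frame (chrom, start, end, strand, transcript_id,
#'   gene_id).
#' @return Data.frame with one row per junction: chrom, strand,
#'   donor/acceptor coordinates, transcript and gene identifiers, and `key`.
#' @export
transcript_junctions <- function(exons) {
  exons <- .as_exon_df(exons)
  out <- lapply(split(exons, exons$transcript_id), function(tx) {
    if (length(unique(tx$chrom)) > 1L)
      stop("exon chain of transcript ", tx$transcript_id[1],
           " crosses chromosomes")
    if (length(unique(tx$strand)) > 1L)
      stop("exon chain of transcript ", tx$transcript_id[1],
           " mixes strands")
    if (nrow(tx) < 2L) return(NULL)
    tx <- tx[order(tx$start), ]
    i <- seq_len(nrow(tx) - 1L)
    left <- tx[i, ]
    right <- tx[i + 1L, ]
    minus <- tx$strand[1] == "-"
    data.frame(
      chrom = tx$chrom[1], strand = tx$strand[1],
      donor_start = if (minus) right$start else left$start,
      donor_end = if (minus) right$end else left$end,
      acceptor_start = if (minus) left$start else right$start,
      acceptor_end = if (minus) left$end else right$end,
      transcript_id = tx$transcript_id[1],
      gene_id = tx$gene_id[1],
      key = .junction_key(tx$chrom[1], left$end, right$start, tx$strand[1]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), strand = character(),
                      donor_start = integer(), donor_end = integer(),
                      acceptor_start = integer(), acceptor_end = integer(),
                      transcript_id = character(), gene_id = character(),
                      key = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.exon_matches_annotation <- function(chrom, start, end, strand, ann_exons,
                                     mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  same <- ann_exons$chrom == chrom & ann_exons$strand == strand
  if (mode == "exact") {
    any(same & ann_exons$start == start & ann_exons$end == end)
  } else {
    any(same & ann_exons$start <= end & ann_exons$end >= start)
  }
}

#' Classify assembled junctions against an annotation
#'
#' Each junction in the assembled exon chains is labeled `known` when its
#' genomic junction key exists in the annotation, `novel_candidate` when the
#' key is unannotated and exactly one of the two flanking exons matches an
#' annotated exon (an unannotated exon joined to a known exon), and
#' `rejected` otherwise (both exons novel, or both known but joined by an
#' unannotated key is still a candidate only if exactly one matches - with
#' both matching it is rejected).
#'
#' @param assembled Exon data.frame of assembled transcripts.
#' @param annotation List from [load_annotation()] (or a list with `exons`
#'   and `junction_keys`).
#' @param exon_match `"exact"` (boundary identity, default) or `"overlap"`
#'   (any same-strand overlap counts as known).
#' @return Data.frame of junction candidates: columns of
#'   [transcript_junctions()] plus `donor_known`, `acceptor_known`,
#'   `known_gene_id` (gene of the matched known exon, `NA` otherwise) and
#'   `status`.
#' @export
classify_junctions <- function(assembled, annotation,
                               exon_match = c("exact", "overlap")) {
  exon_match <- match.arg(exon_match)
  ann_ex <- .as_exon_df(annotation$exons)
  ann_keys <- annotation$junction_keys
  jn <- transcript_junctions(assembled)
  if (!nrow(jn)) {
    jn$donor_known <- logical(); jn$acceptor_known <- logical()
    jn$known_gene_id <- character(); jn$status <- character()
    return(jn)
  }
  jn$donor_known <- mapply(.exon_matches_annotation, jn$chrom,
                           jn$donor_start, jn$donor_end, jn$strand,
                           MoreArgs = list(ann_exons = ann_ex, mode = exon_match))
  jn$acceptor_known <- mapply(.exon_matches_annotation, jn$chrom,
                              jn$acceptor_start, jn$acceptor_end, jn$strand,
                              MoreArgs = list(ann_exons = ann_ex, mode = exon_match))
  key_known <- jn$key %in% ann_keys
  jn$status <- ifelse(key_known, "known",
               ifelse(xor(jn$donor_known, jn$acceptor_known),
                      "novel_candidate", "rejected"))
  known_gene <- function(i) {
    if (jn$status[i] != "novel_candidate") return(NA_character_)
    kstart <- if (jn$donor_known[i]) jn$donor_start[i] else jn$acceptor_start[i]
    kend <- if (jn$donor_known[i]) jn$donor_end[i] else jn$acceptor_end[i]
    hit <- ann_ex$chrom == jn$chrom[i] & ann_ex$strand == jn$strand[i] &
      (if (exon_match == "exact") ann_ex$start == kstart & ann_ex$end == kend
       else ann_ex$start <= kend & ann_ex$end >= kstart)
    if (any(hit)) ann_ex$gene_id[which(hit)[1]] else NA_character_
  }
  jn$known_gene_id <- vapply(seq_len(nrow(jn)), known_gene, character(1))
  jn
}

.fetch_exon_seq <- function(genome, chrom, start, end, strand) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not in genome")
  if (start < 1L || end > length(genome[[chrom]]) || start > end)
    stop("exon coordinates [", start, ", ", end, "] out of bounds on ", chrom)
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' In-silico splice a junction candidate
#'
#' Concatenates the donor and acceptor exon sequences in transcript order
#' (reverse-complemented for minus-strand junctions so the output is
#' transcript-oriented). Exons longer than `max_context` are trimmed to the
#' `max_context` nucleotides adjacent to the splice boundary; only
#' boundary-spanning peptides are retained downstream, so the cap is
#' behavior-neutral for peptides shorter than `max_context / 3` residues.
#'
#' @param candidate One-row data.frame (or list) with chrom, strand,
#'   donor_start, donor_end, acceptor_start, acceptor_end.
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @param max_context Maximum nucleotides of each exon kept around the
#'   boundary (default 600).
#' @return List with `seq` (transcript-oriented nucleotide string) and
#'   `boundary` (number of donor nucleotides; the splice point lies between
#'   positions `boundary` and `boundary + 1`).
#' @export
splice_junction_sequence <- function(candidate, genome, max_context = 600L) {
  don <- .fetch_exon_seq(genome, candidate$chrom, candidate$donor_start,
                         candidate$donor_end, candidate$strand)
  acc <- .fetch_exon_seq(genome, candidate$chrom, candidate$acceptor_start,
                         candidate$acceptor_end, candidate$strand)
  if (nchar(don) > max_context)
    don <- substring(don, nchar(don) - max_context + 1L, nchar(don))
  if (nchar(acc) > max_context)
    acc <- substring(acc, 1L, max_context)
  list(seq = paste0(don, acc), boundary = nchar(don))
}

.in_reference <- function(peptides, ref_seqs, il_equivalent = FALSE) {
  if (il_equivalent) {
    peptides <- chartr("L", "I", peptides)
    ref_seqs <- chartr("L", "I", ref_seqs)
  }
  vapply(peptides, function(p) any(grepl(p, ref_seqs, fixed = TRUE)),
         logical(1), USE.NAMES = FALSE)
}

#' Select junction-spanning tryptic peptides
#'
#' Translates a spliced junction sequence in all three frames, digests each
#' frame into fully tryptic fragments (zero missed cleavages), and keeps
#' fragments that (a) contain no stop (`*`) and no untranslatable codon
#' (`X`), (b) are at least `min_len` residues long, (c) span the splice
#' boundary with at least one residue on each side, and (d) are not exact
#' substrings of the reference proteome. A residue belongs to the donor side
#' when its codon starts at or before the boundary nucleotide.
#'
#' @param nt Transcript-oriented spliced nucleotide string.
#' @param boundary Donor length in nucleotides (from
#'   [splice_junction_sequence()]).
#' @param ref_proteome Character vector or [Biostrings::AAStringSet] of
#'   reference protein sequences.
#' @param min_len Minimum peptide length in residues (default 7).
#' @param proline_rule Passed to [tryptic_digest()].
#' @param il_equivalent Treat I and L as indistinguishable in the
#'   reference-novelty check (default FALSE: literal comparison).
#' @return Data.frame with `sequence`, `frame` (0/1/2) and `junction_offset`
#'   (residues on the donor side).
#' @export
select_junction_peptides <- function(nt, boundary, ref_proteome, min_len = 7L,
                                     proline_rule = FALSE,
                                     il_equivalent = FALSE) {
  ref_seqs <- as.character(ref_proteome)
  if (!length(ref_seqs)) stop("reference proteome is empty")
  aa3 <- translate_3frames(nt)
  rows <- list()
  for (f in 0:2) {
    aa <- aa3[[f + 1L]]
    if (!nchar(aa)) next
    frags <- tryptic_digest(aa, proline_rule = proline_rule)
    pos_end <- cumsum(nchar(frags))
    pos_start <- pos_end - nchar(frags) + 1L
    for (k in seq_along(frags)) {
      frag <- frags[k]
      len <- nchar(frag)
      if (len < min_len) next
      if (grepl("*", frag, fixed = TRUE) || grepl("X", frag, fixed = TRUE)) next
      # codon start of residue i (1-based in frame f): f + 3*(i-1) + 1
      codon_starts <- f + 3L * (seq.int(pos_start[k], pos_end[k]) - 1L) + 1L
      left <- sum(codon_starts <= boundary)
      if (left < 1L || left > len - 1L) next
      rows[[length(rows) + 1L]] <-
        data.frame(sequence = frag, frame = f, junction_offset = left,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(), frame = integer(),
               junction_offset = integer(), stringsAsFactors = FALSE)
  if (nrow(out))
    out <- out[!.in_reference(out$sequence, ref_seqs, il_equivalent), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a splice-junction peptide database
#'
#' End-to-end construction: classify assembled junctions, in-silico splice
#' each `novel_candidate`, 3-frame translate, digest, filter, and collect the
#' unique junction peptides. Identical peptide sequences arising from several
#' junctions are deduplicated, retaining all parent annotations.
#'
#' @param genome [Biostrings::DNAStringSet] named by chromosome.
#' @param annotation Result of [load_annotation()] (list with `exons` and
#'   `junction_keys`).
#' @param assembled Exon data.frame of assembled transcripts.
#' @param ref_proteome Character vector or [Biostrings::AAStringSet].
#' @param min_len,proline_rule,il_equivalent,max_context,exon_match See the
#'   respective stage functions.
#' @return List with `candidates` (classified junction table), `peptides`
#'   (data.frame: sequence, frame, junction_offset, chrom, donor_end,
#'   acceptor_start, strand, gene_id, fasta_id) and `fasta`
#'   ([Biostrings::AAStringSet] ready for [write_junction_fasta()]).
#' @export
build_junction_db <- function(genome, annotation, assembled, ref_proteome,
                              min_len = 7L, proline_rule = FALSE,
                              il_equivalent = FALSE, max_context = 600L,
                              exon_match = c("exact", "overlap")) {
  cand <- classify_junctions(assembled, annotation, exon_match = exon_match)
  novel <- cand[cand$status == "novel_candidate", , drop = FALSE]
  peps <- lapply(seq_len(nrow(novel)), function(i) {
    cj <- novel[i, ]
    sp <- splice_junction_sequence(cj, genome, max_context = max_context)
    sel <- select_junction_peptides(sp$seq, sp$boundary, ref_proteome,
                                    min_len = min_len,
                                    proline_rule = proline_rule,
                                    il_equivalent = il_equivalent)
    if (!nrow(sel)) return(NULL)
    sel$chrom <- cj$chrom
    sel$donor_end <- cj$donor_end
    sel$acceptor_start <- cj$acceptor_start
    sel$strand <- cj$strand
    sel$gene_id <- cj$known_gene_id
    sel
  })
  peps <- do.call(rbind, peps)
  if (is.null(peps))
    peps <- data.frame(sequence = character(), frame = integer(),
                       junction_offset = integer(), chrom = character(),
                       donor_end = integer(), acceptor_start = integer(),
                       strand = character(), gene_id = character(),
                       stringsAsFactors = FALSE)
  if (nrow(peps)) {
    peps$fasta_id <- sprintf("jp|%s:%d-%d|%s|f%d|%s", peps$chrom,
                             peps$donor_end, peps$acceptor_start,
                             peps$strand, peps$frame, peps$gene_id)
    # deduplicate identical sequences, retain all parent annotations
    first <- !duplicated(peps$sequence)
    parents <- tapply(peps$fasta_id, peps$sequence, paste, collapse = ";")
    peps <- peps[first, , drop = FALSE]
    peps$parents <- as.character(parents[peps$sequence])
    rownames(peps) <- NULL
  } else {
    peps$fasta_id <- character()
    peps$parents <- character()
  }
  list(candidates = cand, peptides = peps,
       fasta = build_junction_fasta(peps))
}

#' Assemble the junction-peptide FASTA
#'
#' One entry per unique peptide; the header encodes chromosome, donor and
#' acceptor boundaries, strand, frame and the parent gene of the known exon
#' (additional parents of deduplicated peptides are appended).
#'
#' @param peptides Peptide data.frame from [build_junction_db()].
#' @return [Biostrings::AAStringSet] named by FASTA identifier.
#' @export
build_junction_fasta <- function(peptides) {
  if (!nrow(peptides)) return(Biostrings::AAStringSet())
  ids <- if ("parents" %in% names(peptides)) peptides$parents else
    peptides$fasta_id
  if (anyDuplicated(ids)) stop("duplicate FASTA identifiers generated")
  out <- Biostrings::AAStringSet(peptides$sequence)
  names(out) <- ids
  out
}

#' @rdname build_junction_fasta
#' @param fasta [Biostrings::AAStringSet] (e.g. from [build_junction_db()]).
#' @param path Output path.
#' @export
write_junction_fasta <- function(fasta, path) {
  Biostrings::writeXStringSet(fasta, path, width = 80L)
  invisible(path)
}

#' Match PSMs to a junction-peptide database
#'
#' Keeps peptide-spectrum matches whose sequence is present in the junction
#' database, whose ion score is strictly greater than `score_threshold`
#' (default 30), and whose sequence is not a substring of the reference
#' proteome; intensities are then aggregated per (peptide, sample).
#'
#' @param psms PSM data.frame with columns `peptide`, `ion_score`,
#'   `intensity`, `sample`.
#' @param junction_peptides Character vector of junction peptide sequences
#'   (or the `peptides` data.frame from [build_junction_db()]).
#' @param ref_proteome Reference proteome sequences for the novelty re-check.
#' @param score_threshold Ion-score cutoff; strictly-greater comparison.
#' @param il_equivalent Passed to the reference-substring check.
#' @return List with `long` (data.frame peptide, sample, intensity, n_psms)
#'   and `matrix` (peptide x sample intensity matrix). Empty inputs yield
#'   empty outputs.
#' @export
match_psms_to_junctions <- function(psms, junction_peptides, ref_proteome,
                                    score_threshold = 30,
                                    il_equivalent = FALSE) {
  if (is.data.frame(junction_peptides))
    junction_peptides <- junction_peptides$sequence
  keep <- psms$peptide %in% junction_peptides &
    psms$ion_score > score_threshold
  hits <- psms[keep, , drop = FALSE]
  if (nrow(hits)) {
    novel <- !.in_reference(unique(hits$peptide), as.character(ref_proteome),
                            il_equivalent)
    ok_pep <- unique(hits$peptide)[novel]
    hits <- hits[hits$peptide %in% ok_pep, , drop = FALSE]
  }
  if (!nrow(hits)) {
    long <- data.frame(peptide = character(), sample = character(),
                       intensity = numeric(), n_psms = integer(),
                       stringsAsFactors = FALSE)
    return(list(long = long,
                matrix = matrix(numeric(), 0, 0)))
  }
  agg <- stats::aggregate(intensity ~ peptide + sample, data = hits, FUN = sum)
  cnt <- stats::aggregate(intensity ~ peptide + sample, data = hits,
                          FUN = length)
  agg$n_psms <- cnt$intensity
  samples <- sort(unique(agg$sample))
  pepu <- sort(unique(agg$peptide))
  m <- matrix(0, length(pepu), length(samples),
              dimnames = list(pepu, samples))
  m[cbind(match(agg$peptide, pepu), match(agg$sample, samples))] <-
    agg$intensity
  list(long = agg[order(agg$peptide, agg$sample), ], matrix = m)
}
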