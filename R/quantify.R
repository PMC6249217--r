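# Label-free quantification: iBAQ per protein and sample from PSM-level
# precursor intensities, iFOT normalization to 1e5 per sample, and the
# tiered identification filters (high-quality IDs, replicate consistency,
# core proteome).

.psm_required <- c("peptide", "accessions", "ion_score", "intensity", "sample")

.check_psms <- function(psms) {
  stopifnot(is.data.frame(psms), all(.psm_required %in% names(psms)))
  stopifnot(all(psms$ion_score >= 0), all(psms$intensity >= 0))
  psms
}

.psm_accession_list <- function(psms) strsplit(psms$accessions, ";", fixed = TRUE)

#' Per-protein, per-sample iBAQ from a PSM table
#'
#' iBAQ = summed precursor intensity (AUC) of the peptides attributed to a
#' protein in one sample, divided by the protein's count of theoretically
#' observable tryptic peptides. Peptides shared between several accessions
#' are excluded from the sums by default (`shared = "exclude"`);
#' `shared = "all"` attributes a shared peptide's intensity to every parent.
#' Proteins with zero theoretical peptides are non-quantifiable and reported
#' as `NA` rows. Absent (protein, sample) evidence yields 0 (missing values
#' are substituted with zeros).
#'
#' @param psms PSM data.frame with columns `peptide`, `accessions`
#'   (";"-separated), `ion_score`, `intensity`, `sample`.
#' @param proteome Named character vector or [Biostrings::AAStringSet] of
#'   protein sequences (names = accessions), used for the theoretical
#'   peptide counts.
#' @param shared `"exclude"` (default) or `"all"`.
#' @param len_range iBAQ observable-peptide length bounds, default `c(7, 30)`.
#' @return Numeric matrix, proteins x samples, of iBAQ values (rows = all
#'   accessions appearing in `psms`, in sorted order).
#' @export
compute_ibaq <- function(psms, proteome, shared = c("exclude", "all"),
                         len_range = c(7L, 30L)) {
  shared <- match.arg(shared)
  psms <- .check_psms(psms)
  proteome <- vapply(as.list(proteome), as.character, character(1))
  accs <- .psm_accession_list(psms)
  n_parents <- lengths(accs)
  if (shared == "exclude") {
    keep <- n_parents == 1L
    long <- data.frame(accession = unlist(accs[keep]),
                       sample = psms$sample[keep],
                       intensity = psms$intensity[keep],
                       stringsAsFactors = FALSE)
  } else {
    long <- data.frame(accession = unlist(accs),
                       sample = rep(psms$sample, n_parents),
                       intensity = rep(psms$intensity, n_parents),
                       stringsAsFactors = FALSE)
  }
  all_acc <- sort(unique(unlist(accs)))
  samples <- sort(unique(psms$sample))
  m <- matrix(0, length(all_acc), length(samples),
              dimnames = list(all_acc, samples))
  if (nrow(long)) {
    agg <- stats::aggregate(intensity ~ accession + sample, long, sum)
    m[cbind(match(agg$accession, all_acc), match(agg$sample, samples))] <-
      agg$intensity
  }
  missing_seq <- setdiff(all_acc, names(proteome))
  if (length(missing_seq))
    stop("no proteome sequence for accession(s): ",
         paste(utils::head(missing_seq, 5), collapse = ", "))
  tpc <- vapply(proteome[all_acc], theoretical_peptide_count, integer(1),
                len_range = len_range)
  quantifiable <- tpc > 0L
  m[quantifiable, ] <- m[quantifiable, , drop = FALSE] / tpc[quantifiable]
  m[!quantifiable, ] <- NA_real_
  m
}

#' iFOT normalization
#'
#' The fraction of total (FOT) is a protein's iBAQ divided by the total iBAQ
#' of all identified proteins in the sample; iFOT is the FOT multiplied by
#' 1e5. Zeros are preserved; each sample's iFOT values sum to 1e5 exactly
#' (up to floating point).
#'
#' @param ibaq Numeric vector (one sample) or matrix (proteins x samples) of
#'   iBAQ values; `NA` rows (non-quantifiable proteins) are dropped.
#' @param scale Multiplier applied to the fraction of total (default 1e5).
#' @return iFOT vector or matrix matching the input shape (without `NA`
#'   rows).
#' @export
#' @examples
#' compute_ifot(c(A = 3, B = 1))  # 75000, 25000
compute_ifot <- function(ibaq, scale = 1e5) {
  if (is.matrix(ibaq)) {
    ibaq <- ibaq[stats::complete.cases(ibaq), , drop = FALSE]
    totals <- colSums(ibaq)
    if (any(totals <= 0))
      stop("sample(s) with no positive iBAQ: ",
           paste(colnames(ibaq)[totals <= 0], collapse = ", "))
    return(sweep(ibaq, 2, totals, "/") * scale)
  }
  ibaq <- ibaq[!is.na(ibaq)]
  total <- sum(ibaq)
  if (total <= 0) stop("no positive iBAQ value to normalize")
  ibaq / total * scale
}

#' High-quality identification filter
#'
#' Keeps accessions identified with at least `min_unique` unique peptide
#' sequences (sequences mapping to exactly one accession) and at least
#' `min_strict` strict peptide sequences (best ion score >= `strict_score`).
#' By default a unique peptide whose score qualifies also counts toward the
#' strict tally (`strict_includes_unique = TRUE`); the stricter reading
#' (two strict peptides in addition to the unique one) is available.
#'
#' @param psms PSM data.frame (see [compute_ibaq()]).
#' @param min_unique,min_strict Count thresholds (defaults 1 and 2).
#' @param strict_score Ion-score threshold defining a strict peptide
#'   (default 20, `>=` comparison).
#' @param strict_includes_unique Logical, see above.
#' @return Character vector of accessions passing the filter.
#' @export
filter_high_quality <- function(psms, min_unique = 1L, min_strict = 2L,
                                strict_score = 20,
                                strict_includes_unique = TRUE) {
  psms <- .check_psms(psms)
  accs <- .psm_accession_list(psms)
  n_parents <- lengths(accs)
  long <- data.frame(accession = unlist(accs),
                     peptide = rep(psms$peptide, n_parents),
                     score = rep(psms$ion_score, n_parents),
                     unique_pep = rep(n_parents == 1L, n_parents),
                     stringsAsFactors = FALSE)
  # best score per (accession, peptide sequence)
  key <- paste(long$accession, long$peptide, sep = "\r")
  best <- tapply(long$score, key, max)
  uniq <- tapply(long$unique_pep, key, any)
  acc_of <- sub("\r.*$", "", names(best))
  keep <- vapply(split(seq_along(best), acc_of), function(idx) {
    n_unique <- sum(uniq[idx])
    strict <- best[idx] >= strict_score
    n_strict <- if (strict_includes_unique) sum(strict) else
      sum(strict & !uniq[idx])
    n_unique >= min_unique && n_strict >= min_strict
  }, logical(1))
  sort(names(keep)[keep])
}

#' Replicate-consistency filter
#'
#' Keeps features observed (nonzero) in at least `min_reps` replicates
#' within at least one timepoint. Timepoints carrying a different number of
#' replicates than `of` trigger a warning and the rule is applied to the
#' replicates available.
#'
#' @param qm A [quant_matrix()].
#' @param min_reps Minimum replicates with a nonzero value (default 2).
#' @param of Expected replicates per timepoint (default 3).
#' @return A `quant_matrix` restricted to the passing features.
#' @export
filter_replicate_consistency <- function(qm, min_reps = 2L, of = 3L) {
  stopifnot(inherits(qm, "quant_matrix"))
  tp <- qm$samples$timepoint
  counts <- table(tp)
  if (any(counts != of))
    warning("timepoint(s) with != ", of, " replicates: ",
            paste(names(counts)[counts != of], collapse = ", "),
            "; rule applied to available replicates")
  det <- detected_per_timepoint(qm, min_reps = min_reps)
  qm[rowSums(det) >= 1L, ]
}

#' Per-timepoint detection table
#'
#' @param qm A [quant_matrix()].
#' @param min_reps Replicate threshold defining detection at a timepoint.
#' @return Logical matrix, features x timepoints: detected (nonzero in at
#'   least `min_reps` replicates) or not.
#' @export
detected_per_timepoint <- function(qm, min_reps = 2L) {
  stopifnot(inherits(qm, "quant_matrix"))
  tps <- qm$timepoint_order
  out <- vapply(tps, function(t) {
    cols <- which(qm$samples$timepoint == t)
    rowSums(qm$values[, cols, drop = FALSE] > 0) >= min_reps
  }, logical(nrow(qm$values)))
  if (nrow(qm$values) == 1L)
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(qm$values), tps))
  out
}

#' Core proteome across all timepoints
#'
#' Features detected (per the replicate rule) at every timepoint - the
#' always-present core of the developmental proteome.
#'
#' @param qm A [quant_matrix()] with all timepoints present.
#' @param min_reps Replicate threshold per timepoint (default 2).
#' @return Character vector of feature identifiers.
#' @export
core_proteome <- function(qm, min_reps = 2L) {
  det <- detected_per_timepoint(qm, min_reps = min_reps)
  rownames(det)[rowSums(det) == ncol(det)]
}

#' Quantify a PSM table into an iFOT matrix
#'
#' Convenience pipeline: iBAQ per protein and sample, iFOT normalization,
#' and packaging into a [quant_matrix()].
#'
#' @inheritParams compute_ibaq
#' @param accessions Optional accession subset (e.g. from
#'   [filter_high_quality()]).
#' @return A `quant_matrix` with unit `"iFOT"`.
#' @export
quantify_psms <- function(psms, proteome, accessions = NULL,
                          shared = c("exclude", "all"),
                          len_range = c(7L, 30L)) {
  ibaq <- compute_ibaq(psms, proteome, shared = shared, len_range = len_range)
  if (!is.null(accessions))
    ibaq <- ibaq[rownames(ibaq) %in% accessions, , drop = FALSE]
  ifot <- compute_ifot(ibaq)
  quant_matrix(ifot, unit = "iFOT")
}

#' Tiered filtering audit
#'
#' Applies the identification filter tiers in order - all identifications,
#' high-quality IDs, replicate-consistent IDs - and reports the accession
#' count at each tier. The tiers are nested by construction.
#'
#' @param psms PSM data.frame.
#' @param proteome Named protein sequences.
#' @param min_reps Replicate-consistency threshold.
#' @param ... Passed to [filter_high_quality()].
#' @return List with `dataset1`, `dataset2`, `dataset3` (accession vectors),
#'   `matrix` (the dataset3 `quant_matrix`) and `counts`.
#' @export
build_datasets <- function(psms, proteome, min_reps = 2L, ...) {
  psms <- .check_psms(psms)
  d1 <- sort(unique(unlist(.psm_accession_list(psms))))
  d2 <- filter_high_quality(psms, ...)
  qm2 <- quantify_psms(psms, proteome, accessions = d2)
  qm3 <- suppressWarnings(filter_replicate_consistency(qm2, min_reps = min_reps))
  d3 <- rownames(qm3$values)
  list(dataset1 = d1, dataset2 = d2, dataset3 = d3, matrix = qm3,
       counts = c(dataset1 = length(d1), dataset2 = length(d2),
                  dataset3 = length(d3)))
}
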