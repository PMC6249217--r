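# Transcriptome-side filtering, isoform differential expression,
# protein-RNA correlation on z-scores, the two-tailed hypergeometric
# development-vs-cancer overlap test, and phase mapping of cancer gene
# lists.

#' Expressed-feature filter on FPKM
#'
#' Keeps rows whose maximum across columns meets the threshold (`>=` by
#' default; `strict = TRUE` uses `>`).
#'
#' @param x Matrix or [quant_matrix()] of FPKM values (non-negative).
#' @param threshold Expression threshold (default 1).
#' @param strict Use a strict `>` comparison instead of `>=`.
#' @return Object of the same type restricted to the expressed rows.
#' @export
fpkm_filter <- function(x, threshold = 1, strict = FALSE) {
  v <- if (inherits(x, "quant_matrix")) x$values else as.matrix(x)
  if (any(v < 0)) stop("FPKM values must be non-negative")
  mx <- apply(v, 1, max)
  keep <- if (strict) mx > threshold else mx >= threshold
  if (inherits(x, "quant_matrix")) x[keep] else v[keep, , drop = FALSE]
}

#' Isoform-level differential expression
#'
#' Applies the FPKM expression filter, then the one-way ANOVA +
#' Benjamini-Hochberg machinery of [anova_bh()] to isoform rows.
#'
#' @param qm Isoform [quant_matrix()] (FPKM).
#' @param partition Phase partition (see [anova_bh()]).
#' @param fdr BH threshold (default 0.05).
#' @param fpkm_threshold,strict Passed to [fpkm_filter()].
#' @param log10 Log10-transform (with pseudocount) before testing, default
#'   TRUE.
#' @return Data.frame as [anova_bh()], restricted to expressed isoforms.
#' @export
isoform_de <- function(qm, partition, fdr = 0.05, fpkm_threshold = 1,
                       strict = FALSE, log10 = TRUE) {
  expressed <- fpkm_filter(qm, threshold = fpkm_threshold, strict = strict)
  if (!nrow(expressed$values)) stop("no isoform passes the expression filter")
  if (log10) expressed <- qm_log10(expressed)
  anova_bh(expressed, partition, fdr = fdr)
}

#' Protein-RNA correlation on z-scored timepoint profiles
#'
#' For every gene present in both matrices, replicate columns are collapsed
#' to timepoint means (zero-substituted missing values are treated as
#' observed), profiles are log10-transformed (optional) and z-scored across
#' timepoints, and the Pearson correlation between the protein and RNA
#' z-vectors is reported together with the cohort median. Genes with zero
#' variance in either modality are excluded.
#'
#' @param protein,rna [quant_matrix()] objects sharing timepoints.
#' @param log10 Log10-transform (with pseudocount) before z-scoring
#'   (default TRUE; appropriate for intensity-scale input).
#' @param min_timepoints Minimum shared timepoints required (default 3).
#' @return List with `records` (data.frame gene, r, n) and `median_r`.
#' @export
protein_rna_correlation <- function(protein, rna, log10 = TRUE,
                                    min_timepoints = 3L) {
  stopifnot(inherits(protein, "quant_matrix"), inherits(rna, "quant_matrix"))
  if (!identical(protein$timepoint_order, rna$timepoint_order))
    stop("protein and RNA matrices must share the timepoint set and order")
  if (length(protein$timepoint_order) < min_timepoints)
    stop("need at least ", min_timepoints, " timepoints")
  pm <- collapse_replicates(protein)
  rm_ <- collapse_replicates(rna)
  if (log10) {
    # collapse on the intensity scale first (zeros are observed values),
    # then log-transform the timepoint means with a pseudocount
    lg <- function(m) {
      nz <- m[m > 0]
      if (!length(nz)) stop("matrix has no nonzero values")
      base::log10(m + min(nz) / 2)
    }
    pm <- lg(pm)
    rm_ <- lg(rm_)
  }
  genes <- intersect(rownames(pm), rownames(rm_))
  if (!length(genes)) stop("no genes shared between the two matrices")
  sp <- apply(pm[genes, , drop = FALSE], 1, stats::sd)
  sr <- apply(rm_[genes, , drop = FALSE], 1, stats::sd)
  ok <- sp > 0 & sr > 0
  genes <- genes[ok]
  r <- vapply(genes, function(g)
    stats::cor(pm[g, ], rm_[g, ], method = "pearson"), numeric(1))
  records <- data.frame(gene = genes, r = unname(r),
                        n = length(protein$timepoint_order),
                        stringsAsFactors = FALSE)
  list(records = records, median_r = stats::median(records$r))
}

#' Two-tailed hypergeometric p-value
#'
#' Exact two-sided test of the overlap `k` between a size-`K` and a size-`n`
#' subset of a size-`N` universe. The default minimum-likelihood convention
#' sums the probabilities of all overlap values whose point probability does
#' not exceed that of the observed table; `method = "double"` doubles the
#' smaller one-sided tail (capped at 1).
#'
#' @param k Observed overlap.
#' @param K First set size.
#' @param n Second set size.
#' @param N Universe size.
#' @param method `"minlik"` (default) or `"double"`.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' phyper_twotail(5, 5, 5, 10)
phyper_twotail <- function(k, K, n, N, method = c("minlik", "double")) {
  method <- match.arg(method)
  stopifnot(K <= N, n <= N, k <= min(K, n), k >= max(0, K + n - N))
  support <- max(0, K + n - N):min(K, n)
  d <- stats::dhyper(support, K, N - K, n)
  d0 <- stats::dhyper(k, K, N - K, n)
  if (method == "minlik") {
    min(1, sum(d[d <= d0 * (1 + 1e-7)]))
  } else {
    lo <- stats::phyper(k, K, N - K, n)                     # P(X <= k)
    hi <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)  # P(X >= k)
    min(1, 2 * min(lo, hi))
  }
}

#' Development-vs-cancer overlap test within a pathway
#'
#' Tests whether the development-altered and cancer-altered gene sets
#' overlap more (or less) than expected within a pathway. Both sets are
#' intersected with the pathway-restricted universe first; the two-tailed
#' hypergeometric p-value (minimum-likelihood convention by default) is
#' reported with its -log10.
#'
#' @param dev_altered,cancer_altered Character vectors of altered genes.
#' @param pathway_genes Pathway membership.
#' @param universe Detected-gene universe (genes measured in both studies);
#'   the effective universe is `intersect(pathway_genes, universe)`. Pass
#'   `universe = NULL` with `global = TRUE` semantics by supplying the
#'   global universe directly.
#' @param method Passed to [phyper_twotail()].
#' @return One-row data.frame: `N`, `K` (dev), `n` (cancer), `k` (overlap),
#'   `p`, `minus_log10_p`, `defined`. When the pathway-restricted universe
#'   is empty the test is undefined and flagged (`defined = FALSE`).
#' @export
pathway_overlap_test <- function(dev_altered, cancer_altered, pathway_genes,
                                 universe, method = c("minlik", "double")) {
  U <- intersect(unique(pathway_genes), unique(universe))
  if (!length(U))
    return(data.frame(N = 0L, K = 0L, n = 0L, k = 0L, p = NA_real_,
                      minus_log10_p = NA_real_, defined = FALSE))
  dv <- intersect(unique(dev_altered), U)
  cv <- intersect(unique(cancer_altered), U)
  k <- length(intersect(dv, cv))
  p <- phyper_twotail(k, length(dv), length(cv), length(U), method = method)
  data.frame(N = length(U), K = length(dv), n = length(cv), k = k, p = p,
             minus_log10_p = -log10(p), defined = TRUE)
}

#' Map a cancer gene list onto developmental phases
#'
#' Intersects a cancer-altered gene list (optionally translated through a
#' homology map) with phase-assigned coexpression groups, reporting counts
#' and fractions per phase together with the z-scored timepoint profiles of
#' the overlapping genes.
#'
#' @param cancer_genes Character vector of cancer-altered gene identifiers.
#' @param gene_phases Named vector mapping development genes to phase/group
#'   labels (e.g. from [coexpress_clusters()], or `"Ph1"`-style labels).
#' @param qm Optional [quant_matrix()] supplying the profiles of the mapped
#'   genes.
#' @param homology_map Optional 2-column data.frame (cancer identifier,
#'   development identifier) applied before intersection.
#' @return List with `counts`, `fractions` (per phase label), `mapped`
#'   (genes found), `unmapped` (identifiers without a counterpart) and
#'   `profiles` (z-scored gene x timepoint matrix, or NULL).
#' @export
map_cancer_to_phases <- function(cancer_genes, gene_phases, qm = NULL,
                                 homology_map = NULL) {
  cancer_genes <- unique(cancer_genes)
  ids <- cancer_genes
  if (!is.null(homology_map)) {
    m <- match(cancer_genes, homology_map[[1]])
    ids <- homology_map[[2]][m]
  }
  known <- !is.na(ids) & ids %in% names(gene_phases)
  mapped <- ids[known]
  unmapped <- cancer_genes[!known]
  phases <- sort(unique(unname(gene_phases)))
  counts <- vapply(phases, function(ph)
    sum(gene_phases[mapped] == ph), integer(1))
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else counts * 0
  profiles <- NULL
  if (!is.null(qm) && length(mapped)) {
    tpm <- collapse_replicates(qm)
    present <- intersect(mapped, rownames(tpm))
    if (length(present)) {
      pm <- tpm[present, , drop = FALSE]
      s <- apply(pm, 1, stats::sd)
      profiles <- .zscore_rows(pm[s > 0, , drop = FALSE])
    }
  }
  list(counts = counts, fractions = fractions, mapped = mapped,
       unmapped = unmapped, profiles = profiles)
}
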