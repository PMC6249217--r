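# Temporal structure discovery: sample correlation, hierarchical-clustering
# + PCA phase partitioning, row-wise one-way ANOVA with Benjamini-Hochberg
# adjustment, Ward coexpression grouping, and GMT-based over-representation.

#' Sample-sample correlation matrix
#'
#' Inter-experiment correlations (Spearman by default) between sample
#' columns. Constant columns have undefined correlations; affected pairs are
#' returned as `NA` with a warning.
#'
#' @param qm A [quant_matrix()] (or plain matrix, features x samples).
#' @param method Correlation method, default `"spearman"`.
#' @return Symmetric samples x samples correlation matrix with unit diagonal.
#' @export
sample_correlation_matrix <- function(qm, method = "spearman") {
  v <- if (inherits(qm, "quant_matrix")) qm$values else as.matrix(qm)
  if (ncol(v) < 2L) stop("need at least 2 samples")
  const <- apply(v, 2, function(x) stats::sd(x) == 0 || is.na(stats::sd(x)))
  cc <- suppressWarnings(stats::cor(v, method = method))
  if (any(const)) {
    warning("constant sample column(s): ",
            paste(colnames(v)[const], collapse = ", "),
            "; correlations undefined (NA)")
    cc[const, ] <- NA; cc[, const] <- NA
  }
  diag(cc) <- 1
  cc
}

.zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  (m - mu) / s
}

.contiguous_partition <- function(cluster_by_tp) {
  runs <- rle(as.vector(unname(cluster_by_tp)))
  !anyDuplicated(runs$values)
}

#' Partition timepoints into developmental phases
#'
#' Unsupervised hierarchical clustering (distance `1 - Spearman rho`,
#' average linkage by default) on the sample columns, cut at `k` clusters,
#' with principal-component scores returned for secondary confirmation. By
#' default all replicate columns are clustered and the partition is accepted
#' only when the replicates of every timepoint fall in a single cluster
#' (replicate coherence) and clusters form contiguous blocks in
#' developmental order; `collapse = TRUE` averages replicates per timepoint
#' before clustering. A k-means run on the top-2 PC scores is compared
#' against the tree cut (adjusted Rand index) as a stability report.
#'
#' @param qm A [quant_matrix()].
#' @param k Number of phases (default 3).
#' @param method Correlation method for the distance (default
#'   `"spearman"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`; Ward is reserved for gene coexpression).
#' @param collapse Average replicates per timepoint before clustering.
#' @return An object of class `phase_partition`: list with `assignment`
#'   (named vector timepoint -> `Ph1`..`Phk`, ordered by development),
#'   `stable` (replicate coherence and contiguity both hold), `coherent`,
#'   `contiguous`, `hclust`, `pca` (scores matrix), `kmeans_agreement`
#'   (ARI between tree cut and k-means on top-2 PCs) and `k`.
#' @export
partition_phases <- function(qm, k = 3L, method = "spearman",
                             linkage = "average", collapse = FALSE) {
  stopifnot(inherits(qm, "quant_matrix"))
  tp_order <- qm$timepoint_order
  if (k > length(tp_order)) stop("k exceeds the number of timepoints")
  if (k < 2L) stop("k must be >= 2")
  v <- if (collapse) collapse_replicates(qm) else qm$values
  col_tp <- if (collapse) colnames(v) else qm$samples$timepoint
  cc <- suppressWarnings(stats::cor(v, method = method))
  if (anyNA(cc)) stop("undefined sample correlations (constant columns?)")
  hc <- stats::hclust(stats::as.dist(1 - cc), method = linkage)
  cl <- stats::cutree(hc, k = k)
  # replicate coherence: all columns of a timepoint in one cluster
  tp_cluster <- tapply(cl, col_tp, function(x) {
    ux <- unique(x)
    if (length(ux) == 1L) ux else NA_integer_
  })
  coherent <- !anyNA(tp_cluster)
  if (!coherent) {
    # majority vote fallback so an assignment is always reported
    tp_cluster <- tapply(cl, col_tp, function(x)
      as.integer(names(which.max(table(x)))))
  }
  tp_cluster <- c(tp_cluster[tp_order])
  contiguous <- .contiguous_partition(tp_cluster)
  # phases labeled in developmental order of first appearance
  first_seen <- unique(unname(tp_cluster))
  phase_label <- stats::setNames(paste0("Ph", seq_along(first_seen)),
                                 first_seen)
  assignment <- stats::setNames(
    unname(phase_label[as.character(tp_cluster)]), tp_order)
  # PCA on samples over row-z-scored profiles (scale-free), top-2 k-means
  # cross-check
  rs <- apply(v, 1, stats::sd)
  vz <- if (any(rs > 0)) .zscore_rows(v[rs > 0, , drop = FALSE]) else
    v - rowMeans(v)
  pca <- stats::prcomp(t(vz), center = TRUE, scale. = FALSE)
  km <- stats::kmeans(pca$x[, seq_len(min(2L, ncol(pca$x))), drop = FALSE],
                      centers = k, nstart = 25L)
  ari <- mclust::adjustedRandIndex(cl, km$cluster)
  structure(list(assignment = assignment, stable = coherent && contiguous,
                 coherent = coherent, contiguous = contiguous,
                 hclust = hc, pca = pca$x, kmeans_agreement = ari, k = k),
            class = "phase_partition")
}

#' @export
print.phase_partition <- function(x, ...) {
  cat(sprintf("phase_partition: %d phases over %d timepoints (%s)\n",
              x$k, length(x$assignment),
              if (x$stable) "stable" else "UNSTABLE"))
  for (ph in unique(x$assignment))
    cat(sprintf("  %s: %s\n", ph,
                paste(names(x$assignment)[x$assignment == ph],
                      collapse = " ")))
  cat(sprintf("  HC vs k-means(top-2 PCs) ARI: %.3f\n", x$kmeans_agreement))
  invisible(x)
}

# vectorized one-way ANOVA across matrix rows; groups is a factor over
# columns. Returns F, p and group means. Cross-checked against
# stats::oneway.test(var.equal = TRUE) in the test suite.
.row_anova <- function(m, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- ncol(m)
  if (k < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  gm <- vapply(levels(groups), function(g)
    rowMeans(m[, groups == g, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1L) gm <- matrix(gm, 1L, k, dimnames = list(rownames(m), levels(groups)))
  ng <- as.vector(table(groups))
  grand <- rowMeans(m)
  ssb <- as.vector((gm - grand)^2 %*% ng)
  tot <- rowSums((m - grand)^2)
  ssw <- tot - ssb
  df1 <- k - 1L
  df2 <- n - k
  Fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  # zero within-group variance with a real between-group difference
  p[ssw <= 0 & ssb > 1e-12 * pmax(tot, 1)] <- 0
  list(F = Fstat, p = p, group_means = gm, ssb = ssb, ssw = ssw, tot = tot)
}

#' Phase-wise differential expression (one-way ANOVA + BH)
#'
#' Per-feature one-way ANOVA across phase groups (replicate columns as
#' observations) followed by Benjamini-Hochberg adjustment over all testable
#' features. Features with zero variance everywhere are untestable and are
#' excluded from the BH denominator.
#'
#' @param qm A [quant_matrix()]; typically log-scale values.
#' @param partition A `phase_partition` (or named timepoint -> phase
#'   vector).
#' @param fdr Significance threshold on the BH-adjusted q value (default
#'   0.01).
#' @return Data.frame with `gene`, `F`, `p`, `q`, `phase` (group of maximal
#'   mean), `significant`; untestable features carry `NA` statistics.
#' @export
anova_bh <- function(qm, partition, fdr = 0.01) {
  stopifnot(inherits(qm, "quant_matrix"))
  assignment <- if (inherits(partition, "phase_partition"))
    partition$assignment else partition
  groups <- assignment[qm$samples$timepoint]
  if (anyNA(groups)) stop("timepoint(s) missing from the phase assignment")
  res <- .row_anova(qm$values, groups)
  testable <- res$tot > 0
  q <- rep(NA_real_, length(res$p))
  q[testable] <- stats::p.adjust(res$p[testable], method = "BH")
  top <- colnames(res$group_means)[max.col(res$group_means,
                                           ties.method = "first")]
  out <- data.frame(gene = rownames(qm$values),
                    F = ifelse(testable, res$F, NA_real_),
                    p = ifelse(testable, res$p, NA_real_),
                    q = q,
                    phase = top,
                    significant = !is.na(q) & q < fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ward coexpression grouping
#'
#' Groups features by their temporal profile: rows are z-scored across
#' samples, clustered by Ward's method (`ward.D2` on Euclidean distance) and
#' the tree is cut into `n_groups`. Groups are relabeled in the temporal
#' order of their mean-profile peak.
#'
#' @param qm A [quant_matrix()] (typically restricted to differentially
#'   expressed features; zero-variance rows are not clusterable and raise an
#'   error).
#' @param n_groups Number of coexpression groups (e.g. 3 for proteins, 4 for
#'   RNA).
#' @return Named integer vector of group labels (1..n_groups) per feature,
#'   with attribute `"peak_timepoint"` giving each group's peak.
#' @export
coexpress_clusters <- function(qm, n_groups) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (n_groups > nrow(qm$values)) stop("n_groups exceeds the feature count")
  s <- apply(qm$values, 1, stats::sd)
  if (any(s == 0)) stop("zero-variance feature(s) cannot be z-scored: ",
                        paste(utils::head(rownames(qm$values)[s == 0], 5),
                              collapse = ", "))
  z <- .zscore_rows(qm$values)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cl <- stats::cutree(hc, k = n_groups)
  # order groups by the timepoint index of the mean-profile peak
  tpm <- collapse_replicates(quant_matrix(
    z - min(z), timepoint = qm$samples$timepoint,
    replicate = qm$samples$replicate, unit = "z",
    timepoint_order = qm$timepoint_order))
  peaks <- vapply(seq_len(n_groups), function(g) {
    prof <- colMeans(tpm[cl == g, , drop = FALSE])
    which.max(prof)
  }, integer(1))
  relabel <- match(seq_len(n_groups), order(peaks, seq_len(n_groups)))
  out <- stats::setNames(relabel[cl], rownames(qm$values))
  attr(out, "peak_timepoint") <- qm$timepoint_order[peaks[order(peaks)]]
  out
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Hypergeometric over-representation test over GMT gene sets
#'
#' One-sided over-representation p-value per gene set (probability of an
#' overlap at least as large under hypergeometric sampling from the
#' universe), BH-adjusted across sets. Sets are intersected with the
#' universe first.
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param gmt Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector: the gene universe.
#' @return Data.frame with `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, sorted by p.
#' @export
enrich_gmt <- function(query, gmt, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  rows <- lapply(names(gmt), function(nm) {
    set <- intersect(unique(gmt[[nm]]), universe)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1L, length(set),
                       length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               query_size = length(query),
               universe_size = length(universe), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}
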