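#' Quantification matrix with sample metadata
#'
#' Container for a gene/protein-by-sample abundance table (iFOT, FPKM or
#' intensity) with replicate and timepoint metadata. Missing observations are
#' represented as zeros; all values are non-negative. Column names follow the
#' `<timepoint>_<replicate>` convention.
#'
#' @param values Numeric matrix, rows = genes/proteins, columns = samples.
#' @param timepoint Character vector of timepoint labels per column. If
#'   `NULL`, parsed from column names of the form `<timepoint>_<rep>`.
#' @param replicate Integer vector of replicate indices per column (parsed
#'   from column names when `NULL`).
#' @param unit Abundance unit tag, e.g. `"iFOT"`, `"FPKM"`, `"intensity"`,
#'   `"log10"`.
#' @param timepoint_order Character vector giving the developmental order of
#'   timepoints; defaults to the canonical order for the labels present.
#'
#' @return An object of class `quant_matrix`: a list with elements `values`,
#'   `samples` (data.frame with `sample`, `timepoint`, `replicate`),
#'   `unit` and `timepoint_order`.
#' @export
#' @examples
#' m <- matrix(runif(12), 2, 6,
#'   dimnames = list(c("g1", "g2"), c("E12.5_1", "E12.5_2", "E12.5_3",
#'                                    "W8_1", "W8_2", "W8_3")))
#' qm <- quant_matrix(m, unit = "iFOT")
#' qm
quant_matrix <- function(values, timepoint = NULL, replicate = NULL,
                         unit = "intensity", timepoint_order = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) && is.null(timepoint))
    stop("need column names '<timepoint>_<rep>' or explicit timepoint vector")
  if (any(values < 0, na.rm = TRUE))
    stop("quant_matrix values must be non-negative (missing values are zeros)")
  if (is.null(timepoint)) {
    timepoint <- sub("_[^_]+$", "", colnames(values))
  }
  if (is.null(replicate)) {
    if (!is.null(colnames(values))) {
      rep_str <- sub("^.*_", "", colnames(values))
      replicate <- suppressWarnings(as.integer(rep_str))
      if (anyNA(replicate)) replicate <- stats::ave(
        seq_along(timepoint), timepoint, FUN = seq_along)
    } else {
      replicate <- stats::ave(seq_along(timepoint), timepoint, FUN = seq_along)
    }
  }
  if (is.null(colnames(values)))
    colnames(values) <- paste0(timepoint, "_", replicate)
  if (is.null(timepoint_order)) {
    canonical <- stomach_timepoints()
    timepoint_order <- if (all(timepoint %in% canonical)) {
      canonical[canonical %in% timepoint]
    } else unique(timepoint)
  }
  stopifnot(length(timepoint) == ncol(values),
            length(replicate) == ncol(values),
            all(timepoint %in% timepoint_order))
  structure(
    list(values = values,
         samples = data.frame(sample = colnames(values),
                              timepoint = timepoint,
                              replicate = as.integer(replicate),
                              stringsAsFactors = FALSE),
         unit = unit,
         timepoint_order = timepoint_order),
    class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat(sprintf("timepoints: %s\n", paste(x$timepoint_order, collapse = " ")))
  nz <- x$values[x$values > 0]
  if (length(nz))
    cat(sprintf("nonzero range: %.3g .. %.3g (%.2f orders of magnitude)\n",
                min(nz), max(nz), log10(max(nz) / min(nz))))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' @export
as.matrix.quant_matrix <- function(x, ...) x$values

#' Subset a quant_matrix by feature
#'
#' @param x A `quant_matrix`.
#' @param i Row (feature) index or names.
#' @param ... Unused.
#' @return A `quant_matrix` restricted to the selected features.
#' @export
`[.quant_matrix` <- function(x, i, ...) {
  quant_matrix(x$values[i, , drop = FALSE],
               timepoint = x$samples$timepoint,
               replicate = x$samples$replicate,
               unit = x$unit, timepoint_order = x$timepoint_order)
}

#' Collapse replicates to per-timepoint means
#'
#' Arithmetic mean across replicate columns within each timepoint. Zeros
#' (substituted missing values) are treated as observed values.
#'
#' @param qm A `quant_matrix`.
#' @param fun Summary function, default `mean` (documented alternative:
#'   `median`).
#' @return A numeric matrix, rows = features, columns = timepoints in
#'   developmental order.
#' @export
collapse_replicates <- function(qm, fun = mean) {
  stopifnot(inherits(qm, "quant_matrix"))
  tps <- qm$timepoint_order
  out <- vapply(tps, function(tp) {
    cols <- which(qm$samples$timepoint == tp)
    apply(qm$values[, cols, drop = FALSE], 1, fun)
  }, numeric(nrow(qm$values)))
  if (nrow(qm$values) == 1L) out <- matrix(out, nrow = 1L,
                                           dimnames = list(rownames(qm$values), tps))
  out
}

#' Log10-transform a quant_matrix with a pseudocount
#'
#' Applies `log10(x + pseudocount)` so that zero-substituted missing values
#' map just below the detection floor. The default pseudocount is half the
#' smallest nonzero value in the matrix.
#'
#' @param qm A `quant_matrix` on an intensity-like scale.
#' @param pseudocount Positive number; default half the minimum nonzero value.
#' @return A `quant_matrix` with unit `"log10"`. Values are shifted to be
#'   non-negative (the transform subtracts the minimum), preserving all
#'   differences on the log scale.
#' @export
qm_log10 <- function(qm, pseudocount = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  v <- qm$values
  nz <- v[v > 0]
  if (!length(nz)) stop("matrix has no nonzero values")
  if (is.null(pseudocount)) pseudocount <- min(nz) / 2
  lv <- log10(v + pseudocount)
  lv <- lv - min(lv)
  quant_matrix(lv, timepoint = qm$samples$timepoint,
               replicate = qm$samples$replicate, unit = "log10",
               timepoint_order = qm$timepoint_order)
}

#' Write / read a quant_matrix as TSV
#'
#' The TSV has features in rows and `<timepoint>_<rep>` sample columns; the
#' first column (`feature`) carries the feature identifier.
#'
#' @param qm A `quant_matrix`.
#' @param path Output file path.
#' @return `write_quant_matrix` returns `path` invisibly; `read_quant_matrix`
#'   returns a `quant_matrix`.
#' @export
write_quant_matrix <- function(qm, path) {
  stopifnot(inherits(qm, "quant_matrix"))
  df <- data.frame(feature = rownames(qm$values), qm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_matrix
#' @param unit Unit tag to attach on read.
#' @export
read_quant_matrix <- function(path, unit = "intensity") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  quant_matrix(m, unit = unit)
}
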