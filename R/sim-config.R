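#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the synthetic multi-omic study in one validated
#' object. The defaults encode the emulated study design: 15 developmental
#' timepoints with 3 biological replicates, an abundance range of about 8
#' orders of magnitude, a three-phase temporal structure at the reference
#' boundaries, and a median protein-RNA correlation target of 0.55.
#'
#' @param seed Integer seed; identical configurations produce byte-identical
#'   outputs.
#' @param n_genes Number of simulated genes (gene universe for the genome
#'   and the time-course matrices).
#' @param n_chromosomes Number of chromosomes in the toy genome.
#' @param chromosome_length Chromosome length in nucleotides; `NULL`
#'   (default) sizes chromosomes automatically for `n_genes`. An explicit
#'   value that cannot hold the requested genes raises a sizing error.
#' @param n_novel_junctions Number of implanted novel splice junctions.
#' @param abundance_log10_range Orders of magnitude spanned by nonzero
#'   intensities (default 8).
#' @param dropout_rate Per-(feature, sample) missingness probability in
#'   `[0, 1)`; missing values are substituted with zeros.
#' @param dropout_bias Logical; bias dropout toward low-abundance values
#'   (missingness probability scales linearly with descending abundance
#'   rank, preserving the mean rate). Default `FALSE`
#'   (missing-at-random).
#' @param phase_effect_size Standardized mean shift implanted in
#'   differentially expressed genes: the per-phase offset equals
#'   `phase_effect_size * noise_sd` on the log10 scale.
#' @param noise_sd Replicate noise standard deviation on the log10 scale
#'   (default 0.25, about a 60 percent coefficient of variation).
#' @param de_fraction Fraction of genes carrying an implanted phase effect
#'   (default 0.56, matching the reported proportion of phase-differential
#'   proteins among the analyzed gene products in the emulated study).
#' @param temporal_sd Standard deviation of the smooth per-gene temporal
#'   signal (log10 scale).
#' @param ar_phi Lag-1 autocorrelation of the temporal signal across
#'   adjacent timepoints.
#' @param rna_protein_rho Target per-gene protein-RNA correlation (scalar
#'   or per-gene vector), in `[-1, 1]`.
#' @param n_timepoints Number of timepoints; 15 uses the canonical labels,
#'   other values (stress tests) use generic `T01..` labels.
#' @param n_replicates Replicates per timepoint (default 3).
#' @param calibrate_range Affinely rescale log10 abundances after noise and
#'   dropout so the realized nonzero dynamic range equals
#'   `abundance_log10_range` exactly (default TRUE).
#' @param junction_fraction Fraction of expected junction peptides included
#'   in the simulated PSM table.
#' @param shared_fraction Fraction of proteins given one additional peptide
#'   shared with a second accession.
#' @param score_shape,score_rate Gamma parameters of the simulated ion-score
#'   distribution (closed-form tail: `pgamma(s, shape, rate, lower = FALSE)`).
#' @param min_peptide_length Minimum peptide length (default 7).
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 8, n_novel_junctions = 2)
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_chromosomes = 2L,
                       chromosome_length = NULL,
                       n_novel_junctions = 5L,
                       abundance_log10_range = 8,
                       dropout_rate = 0.1,
                       dropout_bias = FALSE,
                       phase_effect_size = 3,
                       noise_sd = 0.25,
                       de_fraction = 0.56,
                       temporal_sd = 1,
                       ar_phi = 0.85,
                       rna_protein_rho = 0.55,
                       n_timepoints = 15L,
                       n_replicates = 3L,
                       calibrate_range = TRUE,
                       junction_fraction = 0.6,
                       shared_fraction = 0.15,
                       score_shape = 8,
                       score_rate = 0.32,
                       min_peptide_length = 7L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = if (is.null(chromosome_length)) NULL
                                  else as.integer(chromosome_length),
              n_novel_junctions = as.integer(n_novel_junctions),
              abundance_log10_range = abundance_log10_range,
              dropout_rate = dropout_rate, dropout_bias = isTRUE(dropout_bias),
              phase_effect_size = phase_effect_size, noise_sd = noise_sd,
              de_fraction = de_fraction, temporal_sd = temporal_sd,
              ar_phi = ar_phi, rna_protein_rho = rna_protein_rho,
              n_timepoints = as.integer(n_timepoints),
              n_replicates = as.integer(n_replicates),
              calibrate_range = isTRUE(calibrate_range),
              junction_fraction = junction_fraction,
              shared_fraction = shared_fraction,
              score_shape = score_shape, score_rate = score_rate,
              min_peptide_length = as.integer(min_peptide_length))
  stopifnot(cfg$n_genes >= 1L, cfg$n_chromosomes >= 1L,
            cfg$n_novel_junctions >= 0L,
            cfg$abundance_log10_range > 0,
            cfg$dropout_rate >= 0, cfg$dropout_rate < 1,
            cfg$noise_sd >= 0, cfg$temporal_sd >= 0,
            cfg$ar_phi >= 0, cfg$ar_phi < 1,
            all(abs(cfg$rna_protein_rho) <= 1),
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$n_timepoints >= 3L, cfg$n_replicates >= 1L,
            cfg$junction_fraction >= 0, cfg$junction_fraction <= 1,
            cfg$score_shape > 0, cfg$score_rate > 0,
            cfg$min_peptide_length >= 1L)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: seed %d, %d genes, %d x %d samples, ",
                     "%d novel junctions\n"),
              x$seed, x$n_genes, x$n_timepoints, x$n_replicates,
              x$n_novel_junctions))
  invisible(x)
}

# timepoint labels for a config: canonical when 15, generic otherwise
.sim_timepoints <- function(config) {
  if (config$n_timepoints == 15L) stomach_timepoints()
  else sprintf("T%02d", seq_len(config$n_timepoints))
}

# reference phase partition for a config's timepoints
.sim_phases <- function(config) {
  tp <- .sim_timepoints(config)
  if (config$n_timepoints == 15L) return(reference_phases())
  cuts <- round(seq(0, config$n_timepoints, length.out = 4L))
  phase <- rep(paste0("Ph", 1:3), times = diff(cuts))
  stats::setNames(phase, tp)
}
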