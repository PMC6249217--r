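# Simulated search output (PSM tables) and time-course abundance matrices
# with ground truth, emulating the statistical structure of the study
# design: 15 timepoints x 3 replicates, ~8 orders of magnitude of dynamic
# range, zero-substituted missingness, three temporal phase blocks, and a
# tunable protein-RNA coupling.

#' Simulate a peptide-spectrum-match table
#'
#' Emulates a search-engine output over the simulated proteome: per-protein
#' tryptic peptides carrying precursor intensities (log-normal across the
#' configured dynamic range), Gamma-distributed ion scores (continuous, with
#' mass below 20 and in (20, 30]), sample assignments (timepoint x
#' replicate), shared-peptide rows (two accessions, flagged non-unique) and,
#' for a configurable fraction of the expected junction peptides, junction
#' PSMs with scores straddling 30.
#'
#' A fraction of proteins is made ubiquitous (evidence in every sample);
#' these accessions are recorded in the truth as the implanted core
#' proteome.
#'
#' @param sim Result of [simulate_genome()] (provides the proteome and the
#'   expected junction peptides).
#' @param config A [sim_config()].
#' @return List with `psms` (data.frame: peptide, accessions, ion_score,
#'   intensity, sample, timepoint, replicate, is_unique, is_junction) and
#'   `truth` (list: `core_accessions`, `shared_peptides`,
#'   `junction_peptides_included`, `score_tail_p20` - the closed-form
#'   probability that a non-junction score is >= 20).
#' @export
simulate_psm_table <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  proteome <- as.character(sim$proteome)
  tps <- .sim_timepoints(config)
  samples <- as.vector(outer(tps, seq_len(config$n_replicates),
                             function(t, r) paste0(t, "_", r)))
  n_prot <- length(proteome)
  core <- sort(sample(names(proteome), max(1L, round(0.25 * n_prot))))

  rows <- vector("list", n_prot)
  for (i in seq_len(n_prot)) {
    acc <- names(proteome)[i]
    frags <- tryptic_digest(proteome[[i]])
    frags <- unique(frags[nchar(frags) >= config$min_peptide_length &
                          nchar(frags) <= 30L])
    if (!length(frags)) next
    peps <- frags[sample.int(length(frags), min(length(frags), 6L))]
    base <- stats::runif(1, 0, config$abundance_log10_range)
    pep_off <- stats::rnorm(length(peps), 0, 0.3)
    if (acc %in% core) {
      tp_on <- rep(TRUE, length(tps))
      rep_on <- matrix(TRUE, length(tps), config$n_replicates)
    } else {
      tp_on <- stats::runif(length(tps)) < 0.6
      rep_on <- matrix(stats::runif(length(tps) * config$n_replicates) < 0.9,
                       length(tps), config$n_replicates)
    }
    out <- list()
    for (t in which(tp_on)) for (r in which(rep_on[t, ])) {
      inten <- 10^(base + pep_off + stats::rnorm(length(peps), 0, 0.2))
      out[[length(out) + 1L]] <- data.frame(
        peptide = peps, accessions = acc,
        ion_score = stats::rgamma(length(peps), config$score_shape,
                                  config$score_rate),
        intensity = inten,
        sample = paste0(tps[t], "_", r), timepoint = tps[t],
        replicate = r, stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, out)
  }
  psms <- do.call(rbind, rows)

  # shared peptides: borrow one peptide from a partner protein and list both
  shared_peps <- character(0)
  n_shared <- round(config$shared_fraction * n_prot)
  if (n_shared > 0L && n_prot >= 2L) {
    owners <- sample(names(proteome), n_shared)
    partners <- vapply(owners, function(a)
      sample(setdiff(names(proteome), a), 1L), character(1))
    sh <- list()
    for (s in seq_len(n_shared)) {
      frags <- tryptic_digest(proteome[[owners[s]]])
      frags <- unique(frags[nchar(frags) >= config$min_peptide_length &
                            nchar(frags) <= 30L])
      if (!length(frags)) next
      pep <- frags[sample.int(length(frags), 1L)]
      smp <- sample(samples, min(length(samples), 5L))
      sh[[length(sh) + 1L]] <- data.frame(
        peptide = pep,
        accessions = paste(sort(c(owners[s], partners[s])), collapse = ";"),
        ion_score = stats::rgamma(length(smp), config$score_shape,
                                  config$score_rate),
        intensity = 10^stats::runif(length(smp), 1,
                                    config$abundance_log10_range - 1),
        sample = smp, timepoint = sub("_[^_]+$", "", smp),
        replicate = as.integer(sub("^.*_", "", smp)),
        stringsAsFactors = FALSE)
      shared_peps <- c(shared_peps, pep)
    }
    psms <- rbind(psms, do.call(rbind, sh))
  }

  # junction PSMs: a fraction of the expected junction peptides, ion scores
  # straddling the 30 cutoff
  jp <- sim$truth$expected_junction_peptides
  n_j <- round(config$junction_fraction * length(jp))
  jp_in <- character(0)
  if (n_j > 0L) {
    jp_in <- sort(sample(jp, n_j))
    jrows <- lapply(seq_along(jp_in), function(s) {
      smp <- sample(samples, min(length(samples), 4L))
      data.frame(peptide = jp_in[s],
                 accessions = sprintf("jp%03d", s),
                 ion_score = pmax(1, stats::rnorm(length(smp), 30, 6)),
                 intensity = 10^stats::runif(length(smp), 1, 5),
                 sample = smp, timepoint = sub("_[^_]+$", "", smp),
                 replicate = as.integer(sub("^.*_", "", smp)),
                 stringsAsFactors = FALSE)
    })
    psms <- rbind(psms, do.call(rbind, jrows))
  }
  psms$is_unique <- !grepl(";", psms$accessions, fixed = TRUE)
  psms$is_junction <- psms$peptide %in% jp_in
  rownames(psms) <- NULL

  list(psms = psms,
       truth = list(core_accessions = core,
                    shared_peptides = unique(shared_peps),
                    junction_peptides_included = jp_in,
                    score_tail_p20 = stats::pgamma(
                      20, config$score_shape, config$score_rate,
                      lower.tail = FALSE)))
}

# variance of log10(mean of n log-normal replicates), delta-method
.log_mean_noise_var <- function(noise_sd_log10, n_rep) {
  s2 <- (noise_sd_log10 * log(10))^2
  (exp(s2) - 1) / n_rep / log(10)^2
}

# variance contributed to log10(replicate mean) by zero-substituted dropout:
# with k of m replicates surviving the mean scales by k/m (conditional on at
# least one survivor)
.log_mean_dropout_var <- function(dropout_rate, n_rep) {
  if (dropout_rate <= 0) return(0)
  k <- seq_len(n_rep)
  pk <- stats::dbinom(k, n_rep, 1 - dropout_rate)
  pk <- pk / sum(pk)
  lk <- log10(k / n_rep)
  sum(pk * lk^2) - sum(pk * lk)^2
}

#' Simulate protein and RNA time-course matrices
#'
#' Per-gene model on the log10 scale: a uniform baseline spanning the
#' configured dynamic range, a smooth AR(1) temporal signal shared by all
#' replicates, an additive per-phase shift of `phase_effect_size * noise_sd`
#' for the implanted differentially expressed genes (each peaking in one
#' phase of the reference partition), and independent replicate noise. The
#' RNA timepoint profile is coupled to the protein profile through a
#' Gaussian copula on z-scores whose coefficient is inflated to compensate
#' the attenuation caused by replicate noise, so that the realized
#' protein-RNA correlation (computed from replicate-collapsed log profiles)
#' targets `rna_protein_rho`. Dropout is applied per (gene, sample) and
#' missing values are substituted with zeros; finally the nonzero log10
#' values of each matrix are affinely recalibrated so the realized dynamic
#' range equals `abundance_log10_range` (affine maps preserve correlations,
#' standardized effect sizes and clustering structure).
#'
#' @param config A [sim_config()].
#' @return List with `protein` and `rna` ([quant_matrix()] objects,
#'   intensity scale) and `truth` (list: `phase_assignment`, `de_genes`,
#'   `peak_phase`, `rna_protein_rho`).
#' @export
#' @examples
#' tc <- simulate_timecourse(sim_config(seed = 3, n_genes = 50))
#' tc$protein
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(config$seed + 2L)
  n <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  tps <- .sim_timepoints(config)
  phases <- .sim_phases(config)
  n_tp <- length(tps)
  n_rep <- config$n_replicates
  shift <- config$phase_effect_size * config$noise_sd

  de <- sort(sample(genes, round(config$de_fraction * n)))
  peak <- stats::setNames(sample(unique(unname(phases)), length(de),
                                 replace = TRUE), de)
  rho <- rep_len(config$rna_protein_rho, n)

  # temporal signal: AR(1) across ordered timepoints, marginal sd temporal_sd
  ar1 <- function(n_genes) {
    z <- matrix(0, n_genes, n_tp)
    z[, 1] <- stats::rnorm(n_genes)
    for (t in 2:n_tp)
      z[, t] <- config$ar_phi * z[, t - 1] +
        sqrt(1 - config$ar_phi^2) * stats::rnorm(n_genes)
    z * config$temporal_sd
  }
  signal_p <- ar1(n)
  rownames(signal_p) <- genes
  if (length(de) && shift != 0) {
    ph_idx <- matrix(rep(unname(phases[tps]), each = length(de)),
                     nrow = length(de))
    signal_p[de, ] <- signal_p[de, , drop = FALSE] +
      shift * (ph_idx == peak[de])
  }

  # RNA timepoint signal via copula on z-scored protein signal, with the
  # copula coefficient inflated to undo replicate-noise attenuation
  noise_var_eff <- .log_mean_noise_var(config$noise_sd, n_rep) +
    .log_mean_dropout_var(config$dropout_rate, n_rep)
  sd_s <- apply(signal_p, 1, stats::sd)
  signal_r <- matrix(0, n, n_tp, dimnames = list(genes, tps))
  eta <- matrix(stats::rnorm(n * n_tp), n, n_tp)
  for (i in seq_len(n)) {
    if (sd_s[i] > 0) {
      zs <- as.vector(scale(signal_p[i, ]))
      ec <- eta[i, ] - mean(eta[i, ])
      res <- ec - (sum(ec * zs) / sum(zs^2)) * zs
      zperp <- as.vector(scale(res))
      v <- noise_var_eff / sd_s[i]^2
      # attenuation compensation plus the first-order finite-sample bias of
      # the Pearson estimator over n_tp points
      bias <- 1 - (1 - rho[i]^2) / (2 * (n_tp - 1))
      rr <- max(-1, min(1, rho[i] * (1 + v) / bias))
      signal_r[i, ] <- sd_s[i] * (rr * zs + sqrt(1 - rr^2) * zperp)
    } else {
      signal_r[i, ] <- config$temporal_sd * as.vector(scale(eta[i, ]))
      if (config$temporal_sd == 0) signal_r[i, ] <- 0
    }
  }

  base_p <- stats::runif(n, 0, config$abundance_log10_range)
  base_r <- stats::runif(n, 0, config$abundance_log10_range)

  build <- function(base, signal) {
    cols <- as.vector(outer(tps, seq_len(n_rep),
                            function(t, r) paste0(t, "_", r)))
    m <- matrix(0, n, n_tp * n_rep, dimnames = list(genes, cols))
    for (r in seq_len(n_rep)) {
      noise <- matrix(stats::rnorm(n * n_tp, 0, config$noise_sd), n, n_tp)
      m[, paste0(tps, "_", r)] <- base + signal + noise
    }
    m
  }
  log_p <- build(base_p, signal_p)
  log_r <- build(base_r, signal_r)

  apply_dropout <- function(lm_) {
    if (config$dropout_rate <= 0) return(10^lm_)
    p <- config$dropout_rate
    if (config$dropout_bias) {
      # detection failure concentrates sharply at low abundance (MS
      # detection curves are steep); quadratic in descending abundance
      # rank, mean rate preserved (E[3(1-u)^2] = 1)
      rk <- rank(lm_) / length(lm_)          # 0..1, high = abundant
      pr <- pmin(1, 3 * p * (1 - rk)^2)
      drop <- stats::runif(length(lm_)) < pr
    } else {
      drop <- stats::runif(length(lm_)) < p
    }
    v <- 10^lm_
    v[drop] <- 0
    v
  }
  calibrate <- function(v) {
    if (!config$calibrate_range) return(v)
    nz <- v > 0
    if (!any(nz)) return(v)
    lv <- log10(v[nz])
    if (max(lv) == min(lv)) return(v)
    v[nz] <- 10^((lv - min(lv)) *
                   (config$abundance_log10_range / (max(lv) - min(lv))))
    v
  }
  prot <- calibrate(apply_dropout(log_p))
  rna <- calibrate(apply_dropout(log_r))

  list(protein = quant_matrix(prot, unit = "iFOT", timepoint_order = tps),
       rna = quant_matrix(rna, unit = "FPKM", timepoint_order = tps),
       truth = list(phase_assignment = phases, de_genes = de,
                    peak_phase = peak,
                    rna_protein_rho = stats::setNames(rho, genes)))
}

#' Run the full synthetic study
#'
#' Generates the genome bundle, the PSM table and the time-course matrices
#' from a single configuration, merging the per-stage ground truths.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (the [simulate_genome()] bundle), `psms`,
#'   `protein`, `rna` and the merged `truth`.
#' @export
simulate_all <- function(config) {
  g <- simulate_genome(config)
  p <- simulate_psm_table(g, config)
  tc <- simulate_timecourse(config)
  list(genome = g, psms = p$psms, protein = tc$protein, rna = tc$rna,
       truth = c(g$truth, p$truth, tc$truth))
}
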