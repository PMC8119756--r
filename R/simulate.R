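lognormal_params <- function(mean, sd) {
  # moment-match a lognormal to a target mean and SD
  sdlog2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Configuration of a synthetic low-biomass study
#'
#' Defines a paired two-sample-type study (meconium and amniotic fluid
#' specimens from the same cow-calf couples, plus empty-instrument field
#' controls) with the contamination structure the pipeline assumes:
#'
#' * contaminant taxa (reagent/environmental DNA) draw per-sample absolute
#'   loads from a shared lognormal in specimens AND field controls, so their
#'   expected load — and hence prevalence and relative abundance — is the
#'   same in both groups;
#' * signal taxa occur only in specimens, each independently present with
#'   `signal_presence_prob` and a lognormal load; each sample type has its
#'   own signal pool, sharing a `signal_overlap` fraction of taxa;
#' * per-sample composition is the normalised load vector; counts are
#'   Dirichlet-multinomial with overdispersion `dm_overdispersion` at a
#'   lognormal sequencing depth.
#'
#' Default depths are moment-matched to the raw per-group read-count means
#' and SDs of the emulated study design (e.g. about 92,000 reads for
#' meconium specimens); qPCR backgrounds are matched to the field-control
#' copy-number means/SDs (980 and 1,610) and the signal scale is derived so
#' specimen copy numbers average about 4,350 (meconium) and 3,170 (amnion).
#'
#' @param seed Integer seed; identical seeds give identical studies.
#' @param n_pairs Number of cow-calf couples (one specimen per type each).
#' @param n_controls Named integer vector: field controls per sample type.
#' @param k_contaminant,k_signal Numbers of contaminant taxa (shared) and of
#'   signal taxa per sample type.
#' @param signal_overlap Fraction of signal taxa shared between the two
#'   sample types' pools (0 = disjoint, 1 = identical). The default 0.5
#'   gives the types distinct communities while leaving shared features
#'   for paired-correlation analyses, mirroring designs where both
#'   contrasts are informative.
#' @param contam_base_logmean,contam_base_logsd Lognormal parameters of the
#'   per-taxon contaminant base load.
#' @param contam_sample_logsd Per-sample lognormal jitter of contaminant
#'   loads.
#' @param signal_base_logmean,signal_base_logsd,signal_sample_logsd As
#'   above, for signal taxa.
#' @param signal_presence_prob Probability a signal taxon of the pool is
#'   present in a given specimen.
#' @param signal_leak Probability a signal taxon leaks into a field control
#'   (default 0; probes filter specificity).
#' @param dm_overdispersion Dirichlet-multinomial overdispersion in (0, 1);
#'   values near 0 approach the multinomial.
#' @param depth_mean,depth_sd Named lists (`meconium`, `amnion`, each with
#'   `specimen` and `field_control`) of depth means and SDs.
#' @param qpcr_background_mean,qpcr_background_sd Named vectors per sample
#'   type: field-control copy-number mean and SD.
#' @param qpcr_specimen_mean Named vector per sample type: target mean
#'   specimen copy number, from which the signal scale is derived.
#' @param qpcr_noise_logsd Lognormal measurement noise (log-SD) on the
#'   qPCR signal term.
#' @param frac_unclassified_genus Fraction of synthetic taxa left
#'   unclassified at genus rank (classified to family only).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1,
    n_pairs = 23,
    n_controls = c(meconium = 11, amnion = 8),
    k_contaminant = 60,
    k_signal = 30,
    signal_overlap = 0.5,
    contam_base_logmean = log(100),
    contam_base_logsd = 1,
    contam_sample_logsd = 0.6,
    signal_base_logmean = log(100) - 1.04,
    signal_base_logsd = 0.8,
    signal_sample_logsd = 1.2,
    signal_presence_prob = 0.3,
    signal_leak = 0,
    dm_overdispersion = 0.02,
    depth_mean = list(meconium = c(specimen = 92266, field_control = 126800),
                      amnion = c(specimen = 127797, field_control = 136488)),
    depth_sd = list(meconium = c(specimen = 36235, field_control = 21164),
                    amnion = c(specimen = 22376, field_control = 12663)),
    qpcr_background_mean = c(meconium = 980, amnion = 1610),
    qpcr_background_sd = c(meconium = 850, amnion = 790),
    qpcr_specimen_mean = c(meconium = 4350, amnion = 3170),
    qpcr_noise_logsd = 0.1,
    frac_unclassified_genus = 0.2) {
  stopifnot(n_pairs >= 1, k_signal >= 0,
            signal_overlap >= 0, signal_overlap <= 1,
            signal_presence_prob >= 0, signal_presence_prob <= 1,
            signal_leak >= 0, signal_leak <= 1,
            dm_overdispersion > 0, dm_overdispersion < 1)
  if (k_contaminant == 0 && any(n_controls > 0)) {
    abort("k_contaminant = 0 with field controls requested: controls would be empty.")
  }
  # expected total signal load per specimen, used to calibrate the qPCR
  # scale; the per-sample lognormal jitter has mean 1, so only the
  # taxon-level spread enters the expectation
  e_signal_total <- k_signal * signal_presence_prob *
    exp(signal_base_logmean + signal_base_logsd^2 / 2)
  qpcr_signal_scale <- if (e_signal_total > 0) {
    setNames(pmax(0, (qpcr_specimen_mean - qpcr_background_mean) / e_signal_total),
             names(qpcr_specimen_mean))
  } else {
    setNames(rep(0, length(qpcr_specimen_mean)), names(qpcr_specimen_mean))
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic low-biomass study: %d pairs, controls [%s], %d contaminant + 2x%d signal taxa (seed %d)\n",
    x$n_pairs, paste(names(x$n_controls), x$n_controls, collapse = ", "),
    x$k_contaminant, x$k_signal, x$seed))
  invisible(x)
}

# One Dirichlet-multinomial draw per column of `p` (features x samples).
rdirichlet_multinom <- function(p, depths, theta) {
  conc <- (1 - theta) / theta
  out <- matrix(0L, nrow(p), ncol(p))
  for (j in seq_len(ncol(p))) {
    alpha <- p[, j] * conc
    g <- rgamma(length(alpha), shape = alpha)
    g[alpha == 0] <- 0
    if (sum(g) == 0) g[which.max(p[, j])] <- 1
    out[, j] <- rmultinom(1, size = depths[j], prob = g / sum(g))
  }
  out
}

#' Simulate a low-biomass paired study
#'
#' Draws a complete synthetic study from a [simulation_config()]: feature
#' table (specimens and field controls of both sample types), sample
#' metadata, synthetic taxonomy, ground-truth feature labels, per-sample
#' true signal/contaminant loads, and qPCR copy numbers
#' (via [simulate_qpcr()]).
#'
#' @param config A [simulation_config()].
#' @return A `simulated_study` list: `table`, `metadata`, `taxonomy`,
#'   `ground_truth` (tibble `feature_id`, `truth`), `true_loads` (tibble
#'   `sample_id`, `signal_load`, `contaminant_load`), `qpcr` (tibble
#'   `sample_id`, `copies`), and the `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_study_impl(config)) |>
    simulate_qpcr(config)
}

simulate_study_impl <- function(cf) {
  types <- c("meconium", "amnion")
  # --- features -----------------------------------------------------------
  n_shared <- round(cf$signal_overlap * cf$k_signal)
  n_unique <- cf$k_signal - n_shared
  contam_ids <- sprintf("ASV_C%03d", seq_len(cf$k_contaminant))
  shared_ids <- if (n_shared) sprintf("ASV_S%03d", seq_len(n_shared)) else character()
  mec_ids <- c(shared_ids,
               if (n_unique) sprintf("ASV_M%03d", seq_len(n_unique)) else character())
  amn_ids <- c(shared_ids,
               if (n_unique) sprintf("ASV_A%03d", seq_len(n_unique)) else character())
  signal_ids <- unique(c(mec_ids, amn_ids))
  feature_ids <- c(contam_ids, signal_ids)
  pools <- list(meconium = mec_ids, amnion = amn_ids)
  contam_base <- rlnorm(cf$k_contaminant, cf$contam_base_logmean, cf$contam_base_logsd)
  signal_base <- setNames(
    rlnorm(length(signal_ids), cf$signal_base_logmean, cf$signal_base_logsd),
    signal_ids)
  # --- samples ------------------------------------------------------------
  md <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("M%02d", seq_len(cf$n_pairs)),
                   sample_class = "specimen", sample_type = "meconium",
                   pair_id = sprintf("cow%02d", seq_len(cf$n_pairs))),
    tibble::tibble(sample_id = sprintf("A%02d", seq_len(cf$n_pairs)),
                   sample_class = "specimen", sample_type = "amnion",
                   pair_id = sprintf("cow%02d", seq_len(cf$n_pairs))),
    tibble::tibble(sample_id = sprintf("MC%02d", seq_len(cf$n_controls[["meconium"]])),
                   sample_class = "field_control", sample_type = "meconium",
                   pair_id = NA_character_),
    tibble::tibble(sample_id = sprintf("AC%02d", seq_len(cf$n_controls[["amnion"]])),
                   sample_class = "field_control", sample_type = "amnion",
                   pair_id = NA_character_))
  n_samples <- nrow(md)
  # --- loads --------------------------------------------------------------
  loads <- matrix(0, length(feature_ids), n_samples,
                  dimnames = list(feature_ids, md$sample_id))
  for (j in seq_len(n_samples)) {
    loads[contam_ids, j] <- contam_base *
      rlnorm(cf$k_contaminant, -cf$contam_sample_logsd^2 / 2, cf$contam_sample_logsd)
    pool <- pools[[md$sample_type[j]]]
    if (length(pool)) {
      pr <- if (md$sample_class[j] == "specimen") cf$signal_presence_prob else cf$signal_leak
      present <- stats::runif(length(pool)) < pr
      if (any(present)) {
        on <- pool[present]
        loads[on, j] <- signal_base[on] *
          rlnorm(length(on), -cf$signal_sample_logsd^2 / 2, cf$signal_sample_logsd)
      }
    }
  }
  # --- counts -------------------------------------------------------------
  depths <- numeric(n_samples)
  for (j in seq_len(n_samples)) {
    pars <- lognormal_params(cf$depth_mean[[md$sample_type[j]]][[md$sample_class[j]]],
                             cf$depth_sd[[md$sample_type[j]]][[md$sample_class[j]]])
    depths[j] <- max(1, round(rlnorm(1, pars["meanlog"], pars["sdlog"])))
  }
  p <- sweep(loads, 2, colSums(loads), "/")
  counts <- rdirichlet_multinom(p, depths, cf$dm_overdispersion)
  dimnames(counts) <- dimnames(loads)
  table <- dplyr::bind_cols(tibble::tibble(feature_id = feature_ids),
                            tibble::as_tibble(counts))
  # --- synthetic taxonomy -------------------------------------------------
  phyla <- c("Proteobacteria", "Firmicutes", "Bacteroidetes", "Actinobacteria")
  k <- length(feature_ids)
  phylum <- sample(phyla, k, replace = TRUE)
  family <- paste0("Family_", sprintf("%02d", sample.int(20, k, replace = TRUE)))
  genus <- paste0("Genus_", sub("^ASV_", "", feature_ids))
  unclassified <- stats::runif(k) < cf$frac_unclassified_genus
  genus[unclassified] <- NA_character_
  taxonomy <- tibble::tibble(
    feature_id = feature_ids, kingdom = "Bacteria", phylum = phylum,
    class = paste0(phylum, "_class"), order = paste0(family, "_order"),
    family = family, genus = genus)
  structure(list(
    table = validate_feature_table(table),
    metadata = validate_sample_metadata(md),
    taxonomy = taxonomy,
    ground_truth = tibble::tibble(
      feature_id = feature_ids,
      truth = ifelse(feature_ids %in% contam_ids, "contaminant", "signal")),
    true_loads = tibble::tibble(
      sample_id = md$sample_id,
      signal_load = unname(colSums(loads[signal_ids, , drop = FALSE])),
      contaminant_load = unname(colSums(loads[contam_ids, , drop = FALSE]))),
    config = cf
  ), class = "simulated_study")
}

#' Simulate qPCR copy numbers for a study
#'
#' Specimen copy numbers are `signal_scale * total true signal load *
#' lognormal noise + background draw`; field-control copy numbers are a
#' background draw only. Backgrounds are lognormal, moment-matched to the
#' configured per-type control mean/SD; the signal scale is the calibration
#' derived in [simulation_config()]. Uses its own seed stream
#' (`config$seed + 1`), so regenerating qPCR values does not perturb the
#' count table.
#'
#' @param study A `simulated_study` (the `qpcr` field is (re)filled).
#' @param config A [simulation_config()]; defaults to the study's own.
#' @return The study, with `qpcr` set to a tibble (`sample_id`, `copies`).
#' @export
simulate_qpcr <- function(study, config = study$config) {
  md <- study$metadata
  loads <- study$true_loads
  copies <- withr::with_seed(config$seed + 1L, {
    vapply(seq_len(nrow(md)), function(j) {
      ty <- md$sample_type[j]
      bg_pars <- lognormal_params(config$qpcr_background_mean[[ty]],
                                  config$qpcr_background_sd[[ty]])
      bg <- rlnorm(1, bg_pars["meanlog"], bg_pars["sdlog"])
      if (md$sample_class[j] == "specimen") {
        noise <- rlnorm(1, -config$qpcr_noise_logsd^2 / 2, config$qpcr_noise_logsd)
        config$qpcr_signal_scale[[ty]] * loads$signal_load[j] * noise + bg
      } else {
        bg
      }
    }, numeric(1))
  })
  study$qpcr <- tibble::tibble(sample_id = md$sample_id, copies = copies)
  study
}

#' Render simulated qPCR as plate-format measurements
#'
#' Expresses the study's simulated copy numbers as Cq values under an ideal
#' standard curve (slope -log2(10)/... i.e. -3.3219 by default), together
#' with a 10-fold standard dilution series and no-template controls, in the
#' CSV layout [read_qpcr()] expects — so the full quantification path
#' (curve fit, Cq inversion, replicate averaging) can be exercised on
#' synthetic data.
#'
#' @param study A `simulated_study` with `qpcr` filled.
#' @param slope,intercept Standard-curve parameters used to encode Cq.
#' @param replicates Technical replicates per sample.
#' @param cq_noise_sd Normal jitter (cycles) added per replicate, seeded
#'   from `config$seed + 2`.
#' @return A qPCR tibble (`run_id`, `sample_id`, `role`, `copies`, `cq`,
#'   `replicate`).
#' @export
simulate_qpcr_runs <- function(study, slope = -1 / log10(2), intercept = 38,
                               replicates = 2, cq_noise_sd = 0.05) {
  stds <- 10^(7:2)
  md <- study$metadata
  rows <- withr::with_seed(study$config$seed + 2L, {
    purrr::map(unique(md$sample_type), function(ty) {
      ids <- md$sample_id[md$sample_type == ty]
      measured <- study$qpcr$copies[match(ids, study$qpcr$sample_id)]
      cq_vals <- intercept + slope * log10(rep(measured, each = replicates)) +
        rnorm(length(ids) * replicates, 0, cq_noise_sd)
      unk <- tidyr::expand_grid(sample_id = ids, replicate = seq_len(replicates)) |>
        dplyr::mutate(run_id = paste0("run_", ty), role = "unknown",
                      copies = NA_real_, cq = cq_vals)
      std <- tibble::tibble(run_id = paste0("run_", ty),
                            sample_id = paste0("std_", seq_along(stds)),
                            role = "standard", copies = stds,
                            cq = intercept + slope * log10(stds),
                            replicate = 1L)
      ntc <- tibble::tibble(run_id = paste0("run_", ty), sample_id = "ntc",
                            role = "ntc", copies = NA_real_, cq = NA_real_,
                            replicate = 1L)
      dplyr::bind_rows(std, unk[names(std)], ntc)
    })
  })
  dplyr::bind_rows(rows)
}

#' Write a simulated study to plain-text files
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "feature_table.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             qpcr = file.path(dir, "qpcr.csv"),
             ground_truth = file.path(dir, "ground_truth.tsv"))
  write_feature_table(study$table, paths["table"])
  write_sample_metadata(study$metadata, paths["metadata"])
  write_taxonomy(study$taxonomy, paths["taxonomy"])
  readr::write_csv(study$qpcr, paths["qpcr"], progress = FALSE)
  readr::write_tsv(study$ground_truth, paths["ground_truth"], progress = FALSE)
  invisible(paths)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated low-biomass study: %d features x %d samples (seed %d)\n",
              nrow(x$table), ncol(x$table) - 1, x$config$seed))
  print(x$config)
  invisible(x)
}
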