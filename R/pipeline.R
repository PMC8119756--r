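#' Configuration of an end-to-end pipeline run
#'
#' @param table,metadata,taxonomy Paths to the feature table, sample
#'   metadata and taxonomy TSVs.
#' @param qpcr Optional path to a plate-format qPCR CSV ([read_qpcr()]);
#'   `NULL` skips the quantification stage.
#' @param out_dir Output directory.
#' @param params [decontam_params()] for the contaminant filter.
#' @param rank Taxonomic rank for diversity analyses (default `"genus"`).
#' @param n_perm Permutations for PERMANOVA/permdisp (default 9999).
#' @param seed Seed for all permutation tests.
#' @param unit_scale qPCR reporting-unit multiplier.
#' @param min_total Count threshold for [select_shared_features()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(table, metadata, taxonomy, qpcr = NULL,
                            out_dir = "lowbiom_out",
                            params = decontam_params(), rank = "genus",
                            n_perm = 9999, seed = 1, unit_scale = 1,
                            min_total = 100) {
  structure(list(table = table, metadata = metadata, taxonomy = taxonomy,
                 qpcr = qpcr, out_dir = out_dir, params = params,
                 rank = rank, n_perm = n_perm, seed = seed,
                 unit_scale = unit_scale, min_total = min_total),
            class = "pipeline_config")
}

#' Run the full low-biomass analysis pipeline
#'
#' Executes, in order: contaminant filtering per sample type
#' ([apply_decontamination()]); qPCR quantification and specimen-vs-control
#' comparison when qPCR data are supplied; rank aggregation and Shannon
#' diversity; Bray-Curtis distances, PCoA, PERMANOVA and dispersion
#' homogeneity contrasting the sample types; and paired Spearman
#' correlations between the two sample types over shared abundant features.
#' All results are written as TSV/JSON under `config$out_dir`, with a
#' `manifest.json` recording inputs (with MD5 hashes), parameters, seed and
#' completed stages; on error the manifest is still written with a `FAILED`
#' marker naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted result objects
#'   (`decontam`, `qpcr_comparison`, `shannon`, `distance`, `pcoa`,
#'   `permanova`, `permdisp`, `paired`) and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    inputs = purrr::map(
      purrr::compact(config[c("table", "metadata", "taxonomy", "qpcr")]),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    parameters = list(
      prevalence_ratio = config$params$prevalence_ratio,
      abundance_ratio = config$params$abundance_ratio,
      min_sample_reads = config$params$min_sample_reads,
      presence_threshold = config$params$presence_threshold,
      logic = config$params$logic,
      rank = config$rank, n_perm = config$n_perm, seed = config$seed,
      unit_scale = config$unit_scale, min_total = config$min_total),
    package_version = as.character(utils::packageVersion("lowbiom")),
    stages = character())
  results <- list()
  stage <- "load_inputs"
  out <- function(...) file.path(config$out_dir, ...)
  write_manifest <- function(failed = NULL) {
    if (!is.null(failed)) manifest$FAILED <<- failed
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  tryCatch({
    table <- read_feature_table(config$table)
    metadata <- read_sample_metadata(config$metadata)
    taxonomy <- read_taxonomy(config$taxonomy)
    align_metadata(table, metadata)
    manifest$stages <- c(manifest$stages, stage)

    stage <- "decontam"
    report <- apply_decontamination(table, metadata, config$params)
    results$decontam <- report
    readr::write_tsv(tidy(report), out("contam_stats.tsv"), progress = FALSE)
    readr::write_tsv(report$samples, out("read_accounting.tsv"), progress = FALSE)
    for (st in names(report$retained)) {
      write_feature_table(report$retained[[st]],
                          out(paste0("retained_", st, ".tsv")))
    }
    manifest$stages <- c(manifest$stages, stage)

    if (!is.null(config$qpcr)) {
      stage <- "qpcr"
      qpcr <- read_qpcr(config$qpcr)
      copies <- quantify_qpcr(qpcr, unit_scale = config$unit_scale)
      readr::write_tsv(copies, out("qpcr_copies.tsv"), progress = FALSE)
      cmp <- compare_copy_numbers(copies, metadata)
      results$qpcr_comparison <- cmp
      jsonlite::write_json(cmp, out("qpcr_comparison.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      manifest$stages <- c(manifest$stages, stage)
    }

    stage <- "diversity"
    types <- names(report$retained)
    merged <- purrr::reduce(report$retained, function(a, b) {
      dplyr::full_join(a, b, by = "feature_id")
    })
    merged[is.na(merged)] <- 0
    merged <- validate_feature_table(merged)
    merged <- merged[rowSums(counts_matrix(merged)) > 0, ]
    agg <- aggregate_by_rank(merged, taxonomy, config$rank)
    sh <- shannon_diversity(agg)
    results$shannon <- sh
    readr::write_tsv(sh, out("shannon.tsv"), progress = FALSE)
    manifest$stages <- c(manifest$stages, stage)

    stage <- "ordination"
    d <- bray_curtis(merged)
    results$distance <- d
    write_distance_matrix(d, out("bray_curtis.tsv"))
    ord <- pcoa(d)
    results$pcoa <- ord
    readr::write_tsv(ord$coordinates, out("pcoa_coordinates.tsv"), progress = FALSE)
    manifest$stages <- c(manifest$stages, stage)

    stage <- "compare"
    md <- align_metadata(merged, metadata)
    labels <- md$sample_type
    if (length(unique(labels)) >= 2) {
      pm <- permanova(d, labels, n_perm = config$n_perm, seed = config$seed)
      results$permanova <- pm
      pd <- permdisp(d, labels, n_perm = config$n_perm, seed = config$seed)
      results$permdisp <- pd
      jsonlite::write_json(list(permanova = tidy(pm),
                                permdisp = glance(pd)),
                           out("comparison.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    manifest$stages <- c(manifest$stages, stage)

    stage <- "paired_correlation"
    if (length(types) == 2) {
      ta <- report$retained[[types[1]]]
      tb <- report$retained[[types[2]]]
      feats <- select_shared_features(ta, tb, min_total = config$min_total)
      if (length(feats) >= 3) {
        pc <- paired_spearman(ta, tb, metadata, features = feats)
        results$paired <- pc
        readr::write_tsv(pc, out("paired_spearman.tsv"), progress = FALSE)
        jsonlite::write_json(list(rho_avg = rho_average(pc),
                                  n_features = length(feats)),
                             out("paired_summary.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
    manifest$stages <- c(manifest$stages, stage)
    write_manifest()
  }, error = function(e) {
    write_manifest(failed = list(stage = stage, message = conditionMessage(e)))
    abort(paste0("Pipeline failed at stage '", stage, "': ", conditionMessage(e)))
  })
  invisible(list(results = results, manifest = manifest))
}
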