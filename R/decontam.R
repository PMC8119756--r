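#' Parameters of the field-control contaminant filter
#'
#' The filter removes a feature from a sample type's specimens when, within
#' that sample type, BOTH hold:
#'
#' * prevalence in specimens <= `prevalence_ratio` x prevalence in field
#'   controls, and
#' * mean relative abundance in specimens <= `abundance_ratio` x mean
#'   relative abundance in field controls.
#'
#' Prevalence is the fraction of the group's samples with count >=
#' `presence_threshold`; relative abundance is count / sample depth, and the
#' mean is taken over all samples of the group, zeros included. After
#' feature removal, specimens whose remaining depth is strictly below
#' `min_sample_reads` are dropped.
#'
#' @param prevalence_ratio Positive multiplier on control prevalence
#'   (default 2).
#' @param abundance_ratio Positive multiplier on control mean relative
#'   abundance (default 10).
#' @param min_sample_reads Post-filter read-depth cutoff; samples with fewer
#'   reads (strictly) are dropped (default 500).
#' @param presence_threshold Minimum count for a feature to count as present
#'   (default 1).
#' @param logic `"and"` (default; both criteria required for removal) or
#'   `"or"` (either suffices), the latter for sensitivity analysis.
#' @return A `decontam_params` list.
#' @export
decontam_params <- function(prevalence_ratio = 2, abundance_ratio = 10,
                            min_sample_reads = 500, presence_threshold = 1,
                            logic = c("and", "or")) {
  logic <- match.arg(logic)
  stopifnot(prevalence_ratio > 0, abundance_ratio > 0,
            min_sample_reads >= 0, presence_threshold >= 1)
  structure(list(prevalence_ratio = prevalence_ratio,
                 abundance_ratio = abundance_ratio,
                 min_sample_reads = min_sample_reads,
                 presence_threshold = presence_threshold,
                 logic = logic),
            class = "decontam_params")
}

#' Per-feature contamination statistics for one sample type
#'
#' Computes, for every feature and within one sample type, prevalence and
#' mean relative abundance in specimens and in field controls, evaluates the
#' two filter criteria, and flags removals. Statistics are computed once on
#' the input table (single pass); they are never recomputed on a filtered
#' table.
#'
#' @param table A feature-table tibble holding specimens and field controls.
#' @param metadata Sample metadata ([read_sample_metadata()]).
#' @param sample_type The sample type to evaluate (e.g. `"meconium"`).
#' @param params A [decontam_params()] object.
#' @return A tibble with one row per feature: `feature_id`,
#'   `prev_specimen`, `prev_control`, `mean_relabund_specimen`,
#'   `mean_relabund_control`, `prevalence_criterion`, `abundance_criterion`,
#'   `removed`.
#' @export
compute_contam_stats <- function(table, metadata, sample_type,
                                 params = decontam_params()) {
  table <- validate_feature_table(table)
  md <- align_metadata(table, metadata)
  spec <- md$sample_id[md$sample_type == sample_type & md$sample_class == "specimen"]
  ctrl <- md$sample_id[md$sample_type == sample_type & md$sample_class == "field_control"]
  if (!length(spec)) {
    abort(paste0("No specimens of sample_type '", sample_type, "' in table."))
  }
  if (!length(ctrl)) {
    abort(paste0("No field controls of sample_type '", sample_type,
                 "': the contaminant filter is undefined without controls."))
  }
  m <- counts_matrix(table)
  group_stats <- function(ids) {
    g <- m[, ids, drop = FALSE]
    depth <- colSums(g)
    rel <- sweep(g, 2, ifelse(depth > 0, depth, 1), "/")
    rel[, depth == 0] <- 0
    list(prev = rowMeans(g >= params$presence_threshold),
         mra = rowMeans(rel))
  }
  s <- group_stats(spec)
  c_ <- group_stats(ctrl)
  prev_crit <- s$prev <= params$prevalence_ratio * c_$prev
  abund_crit <- s$mra <= params$abundance_ratio * c_$mra
  removed <- if (params$logic == "and") prev_crit & abund_crit else prev_crit | abund_crit
  tibble::tibble(
    feature_id = rownames(m),
    prev_specimen = unname(s$prev),
    prev_control = unname(c_$prev),
    mean_relabund_specimen = unname(s$mra),
    mean_relabund_control = unname(c_$mra),
    prevalence_criterion = unname(prev_crit),
    abundance_criterion = unname(abund_crit),
    removed = unname(removed)
  )
}

#' Apply the contaminant filter per sample type
#'
#' Runs [compute_contam_stats()] independently for each sample type present
#' among the specimens, removes flagged features from that type's specimens,
#' and then drops any specimen whose remaining read depth is strictly below
#' `min_sample_reads`. Field controls inform only their own sample type and
#' are not carried into the retained tables.
#'
#' @inheritParams compute_contam_stats
#' @param sample_types Sample types to filter; defaults to every type with
#'   at least one specimen.
#' @return A `decontam_report` object: a list with
#'   * `stats` — per-type, per-feature statistics (tidy tibble),
#'   * `retained` — named list of retained feature tables (specimens only,
#'     removed features and dropped samples excluded),
#'   * `pre_dropout` — like `retained` but before the depth dropout,
#'   * `samples` — per-specimen `reads_before`/`reads_after`/`dropped`,
#'   * `params` — the parameters used.
#' @export
#' @seealso [tidy.decontam_report()], [glance.decontam_report()],
#'   [autoplot.decontam_report()]
apply_decontamination <- function(table, metadata, params = decontam_params(),
                                  sample_types = NULL) {
  table <- validate_feature_table(table)
  md <- align_metadata(table, metadata)
  if (is.null(sample_types)) {
    sample_types <- sort(unique(md$sample_type[md$sample_class == "specimen"]))
  }
  per_type <- purrr::map(sample_types, function(st) {
    stats <- compute_contam_stats(table, md, st, params)
    spec_ids <- md$sample_id[md$sample_type == st & md$sample_class == "specimen"]
    spec_tbl <- select_samples(table, spec_ids)
    before <- sample_depths(spec_tbl)
    kept <- spec_tbl[!stats$removed[match(spec_tbl$feature_id, stats$feature_id)], ]
    after <- sample_depths(kept)
    dropped <- after$sample_id[after$depth < params$min_sample_reads]
    retained <- select_samples(kept, setdiff(after$sample_id, dropped))
    list(
      stats = dplyr::mutate(stats, sample_type = st, .before = 1),
      samples = tibble::tibble(
        sample_type = st, sample_id = before$sample_id,
        reads_before = before$depth, reads_after = after$depth,
        dropped = before$sample_id %in% dropped),
      pre_dropout = kept,
      retained = retained
    )
  })
  names(per_type) <- sample_types
  structure(list(
    stats = dplyr::bind_rows(purrr::map(per_type, "stats")),
    samples = dplyr::bind_rows(purrr::map(per_type, "samples")),
    retained = purrr::map(per_type, "retained"),
    pre_dropout = purrr::map(per_type, "pre_dropout"),
    params = params
  ), class = "decontam_report")
}

#' Features flagged as contaminants
#'
#' @param report A `decontam_report`.
#' @param sample_type Restrict to one sample type (default: all).
#' @return Character vector of removed feature identifiers.
#' @export
removed_features <- function(report, sample_type = NULL) {
  st <- report$stats
  if (!is.null(sample_type)) st <- st[st$sample_type == sample_type, ]
  unique(st$feature_id[st$removed])
}

#' @export
print.decontam_report <- function(x, ...) {
  g <- glance(x)
  cat("Field-control contaminant filter",
      sprintf("(prevalence ratio %.3g, abundance ratio %.3g, min reads %d, %s)\n",
              x$params$prevalence_ratio, x$params$abundance_ratio,
              as.integer(x$params$min_sample_reads), toupper(x$params$logic)))
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %s: %d/%d features removed; %d/%d specimens dropped (<%d reads)\n",
                g$sample_type[i], g$n_removed[i], g$n_features[i],
                g$n_dropped[i], g$n_specimens[i],
                as.integer(x$params$min_sample_reads)))
  }
  invisible(x)
}

#' Tidy and summarise a decontamination report
#'
#' `tidy()` returns the per-feature statistics; `glance()` one row per
#' sample type with removal and dropout totals and mean read depths before
#' and after filtering (the read-accounting view of the report).
#'
#' @param x A `decontam_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy decontam_report
#' @export
tidy.decontam_report <- function(x, ...) x$stats

#' @rdname tidy.decontam_report
#' @method glance decontam_report
#' @export
glance.decontam_report <- function(x, ...) {
  x$stats |>
    dplyr::group_by(.data$sample_type) |>
    dplyr::summarise(n_features = dplyr::n(), n_removed = sum(.data$removed)) |>
    dplyr::left_join(
      x$samples |>
        dplyr::group_by(.data$sample_type) |>
        dplyr::summarise(n_specimens = dplyr::n(),
                         n_dropped = sum(.data$dropped),
                         mean_reads_before = mean(.data$reads_before),
                         sd_reads_before = sd(.data$reads_before),
                         mean_reads_after = mean(.data$reads_after),
                         sd_reads_after = sd(.data$reads_after)),
      by = "sample_type")
}

#' @rdname tidy.decontam_report
#' @param object A `decontam_report`.
#' @method autoplot decontam_report
#' @export
autoplot.decontam_report <- function(object, ...) {
  df <- dplyr::mutate(object$stats,
                      status = ifelse(.data$removed, "removed", "retained"))
  eps_p <- 0.01  # log-scale offset so zero prevalence is plottable
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$prev_control + eps_p, y = .data$prev_specimen + eps_p,
    colour = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = log10(object$params$prevalence_ratio),
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~sample_type) +
    ggplot2::labs(x = "prevalence in field controls",
                  y = "prevalence in specimens", colour = NULL,
                  title = "Field-control contaminant filter: prevalence criterion") +
    ggplot2::theme_minimal()
}

#' Drop features seen exactly once in total
#'
#' Convenience pre-filter mirroring upstream singleton removal; the main
#' filter assumes singleton/organelle cleanup happened during denoising.
#'
#' @param table A feature-table tibble.
#' @return The table without features whose total count is 1.
#' @export
drop_singletons <- function(table) {
  table[rowSums(counts_matrix(table)) != 1, ]
}
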