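TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Read taxonomy assignments
#'
#' Reads a two-column TSV (`feature_id`, `lineage`) of ranked lineages.
#' Lineages are semicolon-delimited, kingdom first, with optional QIIME/SILVA
#' style rank prefixes (`k__`, `d__`, `p__`, ... stripped on parse). Entries
#' beyond genus are ignored; missing or empty entries mean "unclassified at
#' that rank". Features absent from the file are treated as unclassified at
#' every rank by downstream consumers.
#'
#' @param path Path to the taxonomy TSV.
#' @return A tibble with columns `feature_id`, `kingdom`, ..., `genus`
#'   (`NA` = unclassified).
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(tx) < 2) abort("Taxonomy file needs feature_id and lineage columns.")
  parse_lineages(tx[[1]], tx[[2]])
}

#' @rdname read_taxonomy
#' @param feature_id Character vector of feature identifiers.
#' @param lineage Character vector of semicolon-delimited lineages.
#' @export
parse_lineages <- function(feature_id, lineage) {
  if (anyDuplicated(feature_id)) abort("Duplicated feature_id in taxonomy.")
  parts <- strsplit(ifelse(is.na(lineage), "", lineage), ";", fixed = TRUE)
  clean <- purrr::map(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-zA-Z]__", "", p)
    p[p == ""] <- NA_character_
    length(p) <- length(TAXONOMIC_RANKS)   # pad/truncate to kingdom..genus
    p
  })
  m <- do.call(rbind, clean)
  if (is.null(m)) m <- matrix(NA_character_, 0, length(TAXONOMIC_RANKS))
  colnames(m) <- TAXONOMIC_RANKS
  dplyr::bind_cols(tibble::tibble(feature_id = as.character(feature_id)),
                   tibble::as_tibble(m))
}

#' @rdname read_taxonomy
#' @param taxonomy A taxonomy tibble as returned by [read_taxonomy()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  ranks <- as.matrix(taxonomy[TAXONOMIC_RANKS])
  lineage <- apply(ranks, 1, function(r) {
    r[is.na(r)] <- ""
    paste(r, collapse = ";")
  })
  readr::write_tsv(tibble::tibble(feature_id = taxonomy$feature_id, lineage = lineage),
                   path, progress = FALSE)
  invisible(path)
}

# Label each feature at `rank`: the full classified prefix down to rank, or
# "unclassified <deepest classified parent>" when the rank entry is empty.
rank_labels <- function(feature_id, taxonomy, rank) {
  idx <- match(rank, TAXONOMIC_RANKS)
  tx <- taxonomy[match(feature_id, taxonomy$feature_id), TAXONOMIC_RANKS[seq_len(idx)],
                 drop = FALSE]
  m <- as.matrix(tx)
  apply(m, 1, function(r) {
    # a gap in the middle of the lineage truncates the classified prefix
    classified <- which(!is.na(r))
    depth <- if (length(classified)) min(which(c(is.na(r), TRUE))) - 1L else 0L
    if (depth == length(r)) {
      paste(r, collapse = "; ")
    } else if (depth == 0L) {
      "unclassified"
    } else {
      paste0(paste(r[seq_len(depth)], collapse = "; "), "; unclassified ", r[depth])
    }
  })
}

#' Aggregate a feature table to a taxonomic rank
#'
#' Features sharing the same classified lineage prefix down to `rank` are
#' summed. Features unclassified at `rank` are pooled under their deepest
#' classified parent (labelled `"unclassified <parent>"`) rather than
#' dropped, so per-sample read depth is conserved exactly. The returned
#' `feature_id` is the terminal rank name (or the unclassified label);
#' when two lineages share a terminal name the full prefix is kept to keep
#' identifiers unique.
#'
#' @param table A feature-table tibble.
#' @param taxonomy A taxonomy tibble ([read_taxonomy()]); features missing
#'   from it are unclassified at all ranks.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return A feature-table tibble with one row per taxon at `rank`.
#' @export
#' @examples
#' ft <- feature_table(c("a", "b"), S1 = c(3L, 4L))
#' tax <- parse_lineages(c("a", "b"),
#'   c("Bacteria;Proteobacteria;;;;Pseudomonas",
#'     "Bacteria;Proteobacteria;;;;Pseudomonas"))
#' aggregate_by_rank(ft, tax, "genus")
aggregate_by_rank <- function(table, taxonomy, rank = "genus") {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  table <- validate_feature_table(table)
  labels <- rank_labels(table$feature_id, taxonomy, rank)
  m <- rowsum(counts_matrix(table), group = labels)
  full <- rownames(m)
  terminal <- vapply(strsplit(full, "; ", fixed = TRUE), function(p) p[length(p)], "")
  dup <- terminal %in% terminal[duplicated(terminal)]
  ids <- ifelse(dup, full, terminal)
  out <- dplyr::bind_cols(tibble::tibble(feature_id = ids), tibble::as_tibble(m))
  attr(out, "rank_lineage") <- tibble::tibble(feature_id = ids, lineage = full)
  validate_feature_table(out)
}

#' Taxonomy for a rank-aggregated table
#'
#' Collapses a feature-level taxonomy to the taxa produced by
#' [aggregate_by_rank()] at `rank`, so aggregated tables can themselves be
#' re-aggregated at a coarser rank.
#'
#' @inheritParams aggregate_by_rank
#' @return A taxonomy tibble whose `feature_id`s match the aggregated table.
#' @export
collapse_taxonomy <- function(table, taxonomy, rank = "genus") {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  agg <- aggregate_by_rank(table, taxonomy, rank)
  map <- attr(agg, "rank_lineage")
  idx <- match(rank, TAXONOMIC_RANKS)
  rows <- purrr::map2(map$feature_id, map$lineage, function(id, lin) {
    parts <- strsplit(lin, "; ", fixed = TRUE)[[1]]
    ranks <- rep(NA_character_, length(TAXONOMIC_RANKS))
    keep <- !startsWith(parts, "unclassified") & parts != "unclassified"
    n <- if (all(keep)) length(parts) else min(which(!keep)) - 1L
    if (n > 0) ranks[seq_len(n)] <- parts[seq_len(n)]
    tibble::tibble(feature_id = id, !!!setNames(as.list(ranks), TAXONOMIC_RANKS))
  })
  dplyr::bind_rows(rows)
}
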