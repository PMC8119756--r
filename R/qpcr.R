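#' Read qPCR results
#'
#' Expects a CSV with columns `run_id`, `sample_id`, `role` (one of
#' `unknown`, `standard`, `ntc`), `copies` (known input copies, standards
#' only), `cq` and `replicate`. An empty or `NA` `cq` marks a non-detected
#' reaction.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the columns above.
#' @export
read_qpcr <- function(path) {
  q <- readr::read_csv(path, col_types = readr::cols(
    run_id = readr::col_character(), sample_id = readr::col_character(),
    role = readr::col_character(), copies = readr::col_double(),
    cq = readr::col_double(), replicate = readr::col_integer()),
    progress = FALSE)
  bad <- setdiff(unique(q$role), c("unknown", "standard", "ntc"))
  if (length(bad)) abort(paste0("Unknown qPCR role(s): ", paste(bad, collapse = ", ")))
  q
}

#' @rdname read_qpcr
#' @param qpcr A qPCR tibble.
#' @export
write_qpcr <- function(qpcr, path) {
  readr::write_csv(qpcr, path, progress = FALSE)
  invisible(path)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(input copies) over a standard
#' dilution series. The amplification efficiency is `10^(-1/slope) - 1`
#' (1.0 = perfect doubling per cycle, slope -3.3219).
#'
#' @param data Optional data frame holding the series.
#' @param copies Known input copy numbers (tidy-selected from `data` when
#'   given), all positive, at least 3 distinct values.
#' @param cq Measured quantification cycles.
#' @return A `standard_curve` object with `slope`, `intercept`, `r_squared`
#'   and `efficiency`; supports `tidy()`, `glance()` and `predict()`.
#' @export
#' @examples
#' std <- tibble::tibble(copies = 10^(7:2), cq = 10 + 3.3219 * (7 - log10(copies)))
#' fit_standard_curve(std, copies, cq)
fit_standard_curve <- function(data = NULL, copies, cq) {
  if (!is.null(data)) {
    copies <- rlang::eval_tidy(rlang::enquo(copies), data)
    cq <- rlang::eval_tidy(rlang::enquo(cq), data)
  }
  ok <- is.finite(copies) & is.finite(cq)
  copies <- copies[ok]; cq <- cq[ok]
  if (length(copies) < 3) abort("A standard curve needs at least 3 dilution points.")
  if (any(copies <= 0)) abort("Standard copies must be positive.")
  x <- log10(copies)
  if (isTRUE(all.equal(var(x), 0)) || var(x) == 0) {
    abort("Standard series has zero variance in log10(copies).")
  }
  fit <- lm(cq ~ x)
  slope <- unname(coef(fit)[2])
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    efficiency = 10^(-1 / slope) - 1,
    n_points = length(x),
    fit = fit
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.4f %+.4f * log10(copies)\n  efficiency %.3f, r^2 %.4f, %d points\n",
    x$intercept, x$slope, x$efficiency, x$r_squared, x$n_points))
  invisible(x)
}

#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 efficiency = x$efficiency, r_squared = x$r_squared,
                 n_points = x$n_points)
}

#' Convert Cq values to absolute copy numbers
#'
#' Inverts the standard curve: `copies = unit_scale * 10^((cq - intercept)
#' / slope)`. `unit_scale` rescales reaction copies to the reporting unit
#' (e.g. copies per sampling swab or per 100 ul of fluid). Non-detected
#' reactions (`NA` Cq) map to `NA` by default or to 0 under
#' `nd_policy = "zero"`.
#'
#' @param cq Numeric vector of quantification cycles (`NA` = not detected).
#' @param curve A [fit_standard_curve()] object.
#' @param unit_scale Positive multiplier to the reporting unit (default 1).
#' @param nd_policy `"na"` or `"zero"` for non-detected reactions.
#' @return Numeric vector of copy numbers per reporting unit.
#' @export
cq_to_copies <- function(cq, curve, unit_scale = 1, nd_policy = c("na", "zero")) {
  nd_policy <- match.arg(nd_policy)
  stopifnot(inherits(curve, "standard_curve"), unit_scale > 0)
  if (any(is.infinite(cq) | is.nan(cq))) abort("Cq values must be finite or NA.")
  out <- unit_scale * 10^((cq - curve$intercept) / curve$slope)
  if (nd_policy == "zero") out[is.na(cq)] <- 0
  out
}

#' Absolute quantification of qPCR unknowns
#'
#' Fits one standard curve per run, converts each unknown reaction's Cq to
#' copies, and aggregates technical replicates per sample (mean of copies by
#' default, or mean of Cq first). Non-detected reactions are excluded by
#' default; under `nd_policy = "zero"` they enter the replicate mean as 0.
#'
#' @param qpcr A qPCR tibble ([read_qpcr()]).
#' @param unit_scale Multiplier to the reporting unit (default 1).
#' @param replicate_agg `"copies"` (mean of replicate copies, default) or
#'   `"cq"` (mean replicate Cq, then convert).
#' @param nd_policy `"exclude"` (default) or `"zero"` for non-detections.
#' @return A tibble: `sample_id`, `run_id`, `copies` (per reporting unit),
#'   `n_replicates`. Curves are attached as attribute `"curves"`.
#' @export
quantify_qpcr <- function(qpcr, unit_scale = 1,
                          replicate_agg = c("copies", "cq"),
                          nd_policy = c("exclude", "zero")) {
  replicate_agg <- match.arg(replicate_agg)
  nd_policy <- match.arg(nd_policy)
  runs <- split(qpcr, qpcr$run_id)
  res <- purrr::map(runs, function(run) {
    std <- run[run$role == "standard", ]
    if (nrow(std) < 3) {
      abort(paste0("Run '", run$run_id[1], "' has fewer than 3 standard points."))
    }
    curve <- fit_standard_curve(std, copies, cq)
    unk <- run[run$role == "unknown", ]
    per_sample <- split(unk, unk$sample_id)
    rows <- purrr::map(per_sample, function(s) {
      cqs <- s$cq
      if (nd_policy == "exclude") cqs <- cqs[!is.na(cqs)]
      copies <- if (replicate_agg == "cq") {
        if (length(cqs[!is.na(cqs)])) {
          cq_to_copies(mean(cqs, na.rm = TRUE), curve, unit_scale)
        } else NA_real_
      } else {
        mean(cq_to_copies(cqs, curve, unit_scale,
                          nd_policy = if (nd_policy == "zero") "zero" else "na"),
             na.rm = TRUE)
      }
      tibble::tibble(sample_id = s$sample_id[1], run_id = s$run_id[1],
                     copies = copies, n_replicates = nrow(s))
    })
    list(curve = curve, table = dplyr::bind_rows(rows))
  })
  out <- dplyr::bind_rows(purrr::map(res, "table"))
  attr(out, "curves") <- purrr::map(res, "curve")
  out
}

#' Compare copy numbers between specimens and field controls
#'
#' Joins quantified copy numbers to sample metadata and runs the two-tailed
#' Mann-Whitney U test ([mann_whitney_u()]) of specimens against field
#' controls, per sample type.
#'
#' @param copies A tibble with `sample_id` and `copies`
#'   ([quantify_qpcr()] output, or simulated copy numbers).
#' @param metadata Sample metadata.
#' @param sample_types Types to test; default all with both groups present.
#' @return A tibble with one row per sample type: group sizes, means, SDs,
#'   the U statistic, method and two-tailed p-value.
#' @export
compare_copy_numbers <- function(copies, metadata, sample_types = NULL) {
  md <- validate_sample_metadata(metadata)
  df <- dplyr::inner_join(copies, md, by = "sample_id")
  if (is.null(sample_types)) sample_types <- sort(unique(df$sample_type))
  purrr::map(sample_types, function(st) {
    d <- df[df$sample_type == st & !is.na(df$copies), ]
    x <- d$copies[d$sample_class == "specimen"]
    y <- d$copies[d$sample_class == "field_control"]
    cmp <- mann_whitney_u(x, y)
    tibble::tibble(sample_type = st,
                   n_specimen = length(x), n_control = length(y),
                   mean_specimen = mean(x), sd_specimen = sd(x),
                   mean_control = mean(y), sd_control = sd(y),
                   u_statistic = cmp$u_statistic, method = cmp$method,
                   p_two_tailed = cmp$p_two_tailed)
  }) |> dplyr::bind_rows()
}
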