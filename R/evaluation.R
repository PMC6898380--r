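#' Distance-stratified Pearson correlation curve
#'
#' Pairs are grouped by genomic distance and the Pearson correlation of
#' true versus predicted counts is computed within each distance bin.
#' Bins with fewer than `min_pairs` pairs, or with zero variance in either
#' vector, are reported as undefined (`r = NA`). Pairs unmeasured in the
#' truth are excluded.
#'
#' @param truth Either a [contact_table()] of true counts, or a tibble that
#'   already carries `count`, `predicted` and `distance_bins` columns (e.g.
#'   `run_cv()$predictions`), in which case `pred` is omitted.
#' @param pred A [contact_table()] of predicted counts matched to `truth`
#'   by coordinates.
#' @param bin_width Width of a distance stratum, in bin units (default 1:
#'   one stratum per resolution unit).
#' @param max_distance_bins Optional truncation radius in bins.
#' @param min_pairs Minimum pairs for a defined correlation (default 3).
#' @return A tibble of class `correlation_curve` with columns
#'   `distance_bins` (stratum upper edge, bin units), `distance_bp`, `r`,
#'   `n_pairs`, `defined`.
#' @export
distance_stratified_correlation <- function(truth, pred = NULL, bin_width = 1,
                                            max_distance_bins = NULL,
                                            min_pairs = 3) {
  check_scalar_number(bin_width, "bin_width", positive = TRUE)
  if (is.null(pred)) {
    check_columns(truth, c("count", "predicted", "distance_bins"), "truth")
    df <- as_tibble(truth)
    res <- attr(truth, "resolution") %||% 1
  } else {
    res <- contact_resolution(truth)
    df <- as_tibble(truth) |>
      filter(.data$measured) |>
      select("chrom", "start1", "start2", "count") |>
      inner_join(
        as_tibble(pred) |> select("chrom", "start1", "start2", predicted = "count"),
        by = c("chrom", "start1", "start2")
      ) |>
      mutate(distance_bins = (.data$start2 - .data$start1) / res)
  }
  if (!is.null(max_distance_bins)) {
    df <- df |> filter(.data$distance_bins <= max_distance_bins)
  }
  if (nrow(df) == 0L) {
    stop_arg("no common measured pairs between truth and prediction")
  }
  curve <- df |>
    mutate(stratum = ceiling(.data$distance_bins / bin_width)) |>
    group_by(.data$stratum) |>
    summarise(
      n_pairs = dplyr::n(),
      r = if (dplyr::n() >= min_pairs &&
              sd(.data$count) > 0 && sd(.data$predicted) > 0) {
        cor(.data$count, .data$predicted)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    mutate(
      distance_bins = .data$stratum * bin_width,
      distance_bp = .data$distance_bins * res,
      defined = !is.na(.data$r)
    ) |>
    select("distance_bins", "distance_bp", "r", "n_pairs", "defined") |>
    arrange(.data$distance_bins)
  class(curve) <- c("correlation_curve", class(curve))
  curve
}

#' Trapezoidal AUC of a correlation curve
#'
#' The curve f of per-distance-bin correlations is summarized as
#' `AUC = 1/(2(n-1)) * sum(f(i) + f(i+1))`, the trapezoidal rule with unit
#' spacing divided by the number of intervals, so a constant curve at c has
#' AUC c and the score lives in \[-1, 1\]. Undefined bins are linearly
#' interpolated from their neighbors (constant-extended at the ends) before
#' integration; the curve's `defined` column records which bins those were.
#'
#' @param curve A `correlation_curve` (or any tibble with an `r` column),
#'   or a plain numeric vector of correlations.
#' @return A single number in \[-1, 1\].
#' @export
correlation_auc <- function(curve) {
  f <- if (is.numeric(curve)) curve else {
    check_columns(curve, "r", "curve")
    curve$r
  }
  n <- length(f)
  if (n < 2L) {
    stop_arg("AUC needs at least 2 distance bins (got %d)", n)
  }
  if (anyNA(f)) {
    if (all(is.na(f))) {
      stop_arg("every distance bin is undefined; AUC cannot be computed")
    }
    idx <- seq_len(n)
    f <- approx(idx[!is.na(f)], f[!is.na(f)], xout = idx, rule = 2)$y
  }
  sum(f[-n] + f[-1L]) / (2 * (n - 1L))
}

#' Write a correlation curve as TSV
#'
#' @param curve A `correlation_curve`.
#' @param path Output file.
#' @export
write_correlation_curve <- function(curve, path) {
  readr::write_tsv(
    as_tibble(curve)[, c("distance_bp", "r", "n_pairs")], path,
    progress = FALSE
  )
  invisible(path)
}
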