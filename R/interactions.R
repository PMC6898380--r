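#' Per-distance-bin background statistics
#'
#' For the binomial interaction caller, pairs are stratified by genomic
#' distance; within stratum i, `M` is the number of measured pairs, the
#' per-pair interaction probability is `m = 1/M` (uniform-contact null) and
#' `n` is the total (integer-rounded) observed count. Only measured pairs
#' contribute; empty strata are absent.
#'
#' @param table A [contact_table()].
#' @param bin_width Stratum width in resolution units (default 1).
#' @return Tibble `(stratum, M, n, m)`.
#' @export
distance_bin_stats <- function(table, bin_width = 1) {
  check_scalar_number(bin_width, "bin_width", positive = TRUE)
  res <- contact_resolution(table)
  as_tibble(table) |>
    filter(.data$measured) |>
    mutate(
      stratum = ceiling((.data$start2 - .data$start1) / res / bin_width)
    ) |>
    group_by(.data$stratum) |>
    summarise(
      M = dplyr::n(),
      n = sum(round_half_up(.data$count)),
      .groups = "drop"
    ) |>
    mutate(m = 1 / .data$M)
}

#' Upper-tail binomial p-value
#'
#' The probability of observing `k` or more successes out of `n` trials at
#' success probability `m`:
#' `p = sum_{j=k}^{n} C(n, j) m^j (1-m)^{n-j}`, evaluated through the
#' complementary binomial distribution function. Vectorized over `k`, `n`,
#' `m`.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Total stratum count(s).
#' @param m Success probability in (0, 1].
#' @return p-value(s) in \[0, 1\]; `k = 0` gives exactly 1.
#' @export
binomial_pvalue <- function(k, n, m) {
  if (any(m <= 0 | m > 1)) {
    stop_arg("`m` must lie in (0, 1]")
  }
  if (any(k < 0) || any(k > n)) {
    stop_arg("`k` must satisfy 0 <= k <= n")
  }
  pbinom(k - 1, size = n, prob = m, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' The step-up false-discovery-rate correction
#' `q_(i) = min_{j >= i} min(1, p_(j) * m / j)`, returned in the input
#' order.
#'
#' @param pvalues Numeric p-values.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Call significant interactions with the binomial model
#'
#' Rounds the (normalized, real-valued) counts to integers, computes
#' per-stratum background statistics, assigns each measured pair an
#' upper-tail binomial p-value, corrects across all tested pairs with
#' Benjamini-Hochberg, and flags pairs with `q < q_threshold`. A percentile
#' rank by q-value (`top_pct`, ties shared) supports top-percent overlap
#' analyses.
#'
#' @param table A [contact_table()]; only measured pairs are tested.
#' @param q_threshold Significance threshold on the q-value (default 0.05).
#' @param bin_width Distance stratum width in resolution units (default 1).
#' @return Tibble of class `interaction_calls`: coordinates, `count`, the
#'   rounded count `k`, `distance_bins`, `p`, `q`, `significant`, `top_pct`.
#' @export
call_significant <- function(table, q_threshold = 0.05, bin_width = 1) {
  if (q_threshold < 0 || q_threshold > 1) {
    stop_arg("`q_threshold` must lie in [0, 1]")
  }
  res <- contact_resolution(table)
  stats <- distance_bin_stats(table, bin_width = bin_width)
  calls <- as_tibble(table) |>
    filter(.data$measured) |>
    mutate(
      distance_bins = (.data$start2 - .data$start1) / res,
      stratum = ceiling(.data$distance_bins / bin_width),
      k = round_half_up(.data$count)
    ) |>
    inner_join(stats, by = "stratum") |>
    mutate(
      p = binomial_pvalue(.data$k, .data$n, .data$m),
      q = bh_adjust(.data$p),
      significant = .data$q < q_threshold,
      top_pct = 100 * rank(.data$q, ties.method = "max") / dplyr::n()
    ) |>
    select(
      "chrom", "start1", "start2", "count", "k", "distance_bins",
      "p", "q", "significant", "top_pct"
    )
  attr(calls, "resolution") <- res
  attr(calls, "q_threshold") <- q_threshold
  class(calls) <- c("interaction_calls", class(calls))
  calls
}

#' Write interaction calls as TSV
#'
#' @param calls An `interaction_calls` tibble.
#' @param path Output file.
#' @export
write_interaction_calls <- function(calls, path) {
  readr::write_tsv(
    as_tibble(calls)[, c(
      "chrom", "start1", "start2", "count", "p", "q", "significant"
    )],
    path,
    progress = FALSE
  )
  invisible(path)
}

bin_orientations <- function(motifs, resolution, purity_threshold) {
  motifs |>
    filter(.data$purity >= purity_threshold) |>
    mutate(
      bin = floor(floor((.data$start + .data$end) / 2) / resolution) * resolution
    ) |>
    group_by(.data$chrom, .data$bin) |>
    summarise(
      has_plus = any(.data$strand == "+"),
      has_minus = any(.data$strand == "-"),
      .groups = "drop"
    )
}

#' Classify pairs by CTCF motif orientation
#'
#' After filtering motifs to high confidence (`purity >= purity_threshold`)
#' and assigning them to bins by midpoint, each pair is labeled with one of
#' the four orientation configurations `++`, `+-`, `-+`, `--` -- `+-` being
#' the convergent configuration characteristic of true loops (forward-strand
#' motif on R1, reverse-strand on R2). Pairs where either region lacks a
#' qualifying motif, or where a region carries motifs in both orientations,
#' are excluded (`NA`).
#'
#' @param pairs Pair tibble (`chrom`, `start1`, `start2`).
#' @param motifs Signed motif tibble (see [read_motif_bed()]).
#' @param resolution Bin width in bp.
#' @param purity_threshold Minimum motif purity (default 0.9).
#' @return `pairs` with a `config` character column (`NA` = excluded).
#' @export
classify_orientation <- function(pairs, motifs, resolution,
                                 purity_threshold = 0.9) {
  check_columns(pairs, c("chrom", "start1", "start2"), "pairs")
  orient <- bin_orientations(motifs, resolution, purity_threshold) |>
    mutate(sign = case_when(
      .data$has_plus & .data$has_minus ~ "both",
      .data$has_plus ~ "+",
      .data$has_minus ~ "-"
    )) |>
    select("chrom", "bin", "sign")
  out <- pairs |>
    left_join(orient, by = c("chrom", start1 = "bin")) |>
    rename(sign1 = "sign") |>
    left_join(orient, by = c("chrom", start2 = "bin")) |>
    rename(sign2 = "sign") |>
    mutate(
      config = ifelse(
        is.na(.data$sign1) | is.na(.data$sign2) |
          .data$sign1 == "both" | .data$sign2 == "both",
        NA_character_,
        paste0(.data$sign1, .data$sign2)
      )
    ) |>
    select(-"sign1", -"sign2")
  out
}

#' Orientation-configuration enrichment of significant pairs
#'
#' Quantifies whether a motif-orientation configuration (by default the
#' convergent `+-`) is over-represented among significant interactions,
#' relative to all configuration-carrying pairs in the background:
#' with `q` significant pairs of the configuration among `k` significant
#' configuration-carrying pairs, and `m` of `S` in the background,
#' `fold = (q/k) / (m/S)` and the p-value is the upper-tail hypergeometric
#' probability of observing `q` or more.
#'
#' @param significant Pair tibble with a `config` column (the significant
#'   set, a subset of the background).
#' @param background Pair tibble with a `config` column (the universe of
#'   tested pairs).
#' @param config Configuration to test (default `"+-"`).
#' @return One-row tibble `(config, q, k, m, S, fold, p)`; `fold` is `NA`
#'   (flagged by a warning) when `k` or `m` is zero.
#' @export
config_enrichment <- function(significant, background, config = "+-") {
  check_columns(significant, "config", "significant")
  check_columns(background, "config", "background")
  sig <- significant |> filter(!is.na(.data$config))
  bg <- background |> filter(!is.na(.data$config))
  q <- sum(sig$config == config)
  k <- nrow(sig)
  m <- sum(bg$config == config)
  s <- nrow(bg)
  if (k == 0L || m == 0L) {
    warn("configuration enrichment undefined (no qualifying pairs)")
    fold <- NA_real_
    p <- NA_real_
  } else {
    fold <- (q / k) / (m / s)
    p <- phyper(q - 1, m, s - m, k, lower.tail = FALSE)
  }
  tibble(config = config, q = q, k = k, m = m, S = s, fold = fold, p = p)
}

pair_key <- function(x) {
  paste(x$chrom, x$start1, x$start2)
}

#' ChIA-PET (external interaction) fold enrichment
#'
#' Compares the fraction of significant pairs supported by an external
#' interaction set (anchors matched at the working resolution, both
#' orientations tried) with the fraction expected by chance:
#' `fold = (n1/n2) / (m1/m2)` where `n1` = significant pairs overlapping the
#' external set, `n2` = significant pairs, `m1` = external pairs mappable to
#' any universe pair and `m2` = universe size.
#'
#' @param significant Pair tibble (`chrom`, `start1`, `start2`).
#' @param external External interaction pairs mapped to the same bin grid
#'   (see [map_interactions_to_bins()]).
#' @param universe Pair tibble of all testable pairs (the background).
#' @return One-row tibble `(n1, n2, m1, m2, fold)`.
#' @export
chiapet_enrichment <- function(significant, external, universe) {
  for (nm in c("significant", "external", "universe")) {
    check_columns(get(nm), c("chrom", "start1", "start2"), nm)
  }
  ext_keys <- unique(c(
    pair_key(external),
    paste(external$chrom, external$start2, external$start1)
  ))
  n1 <- sum(pair_key(significant) %in% ext_keys)
  n2 <- nrow(significant)
  m1 <- sum(pair_key(universe) %in% ext_keys)
  m2 <- nrow(universe)
  fold <- if (n2 == 0L || m1 == 0L) NA_real_ else (n1 / n2) / (m1 / m2)
  tibble(n1 = n1, n2 = n2, m1 = m1, m2 = m2, fold = fold)
}

#' Overlap statistics of two interaction sets
#'
#' Pairs are identified by coordinates; the Jaccard index is
#' `|A intersect B| / |A union B|`.
#'
#' @param a,b Pair tibbles (`chrom`, `start1`, `start2`).
#' @return One-row tibble `(n_a, n_b, n_common, jaccard)`.
#' @export
set_overlap <- function(a, b) {
  ka <- unique(pair_key(a))
  kb <- unique(pair_key(b))
  n_common <- length(intersect(ka, kb))
  n_union <- length(union(ka, kb))
  tibble(
    n_a = length(ka), n_b = length(kb), n_common = n_common,
    jaccard = if (n_union == 0L) NA_real_ else n_common / n_union
  )
}
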