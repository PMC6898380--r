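#' Directionality index of each bin
#'
#' For each bin, let A be the total contact count between the bin and bins
#' within `window_bp` upstream, and B the total downstream; with
#' E = (A + B)/2 the directionality index is the signed chi-square-style
#' statistic `DI = sign(B - A) * ((A - E)^2/E + (B - E)^2/E)`, 0 when
#' A = B or both sums vanish. Positive DI marks downstream bias (typical of
#' domain starts), negative DI upstream bias (domain ends).
#'
#' @param table A [contact_table()] (the symmetric view is implied: an
#'   upper-triangle record contributes downstream mass to its R1 bin and
#'   upstream mass to its R2 bin).
#' @param window_bp Window size in bp (default 2 Mb).
#' @param bins Optional bin tibble; defaults to the grid spanned by the
#'   table (bins without contacts get DI 0).
#' @return Tibble of class `di_profile`: `chrom`, `start`, `upstream`,
#'   `downstream`, `di`.
#' @export
directionality_index <- function(table, window_bp = 2e6, bins = NULL) {
  res <- contact_resolution(table)
  if (window_bp < res) {
    stop_arg("`window_bp` must be at least one resolution unit")
  }
  if (is.null(bins)) {
    bins <- as_tibble(table) |>
      group_by(.data$chrom) |>
      summarise(last = max(.data$start2), .groups = "drop")
    bins <- bin_genome(
      setNames(bins$last + res, bins$chrom),
      resolution = res
    )
  }
  within <- as_tibble(table) |>
    filter(
      .data$measured,
      .data$start2 - .data$start1 <= window_bp,
      .data$start1 != .data$start2
    )
  down <- within |>
    group_by(.data$chrom, start = .data$start1) |>
    summarise(downstream = sum(.data$count), .groups = "drop")
  up <- within |>
    group_by(.data$chrom, start = .data$start2) |>
    summarise(upstream = sum(.data$count), .groups = "drop")
  out <- bins |>
    select("chrom", "start") |>
    left_join(up, by = c("chrom", "start")) |>
    left_join(down, by = c("chrom", "start")) |>
    mutate(
      upstream = ifelse(is.na(.data$upstream), 0, .data$upstream),
      downstream = ifelse(is.na(.data$downstream), 0, .data$downstream)
    )
  a <- out$upstream
  b <- out$downstream
  e <- (a + b) / 2
  di <- ifelse(
    e > 0 & a != b,
    sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e),
    0
  )
  out$di <- di
  attr(out, "resolution") <- res
  attr(out, "window_bp") <- window_bp
  class(out) <- c("di_profile", class(out))
  out
}

runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  tibble(value = r$values, start = ends - r$lengths + 1L, end = ends)
}

#' Segment a DI profile into topological domains
#'
#' The DI series is segmented with a 3-state Gaussian-emission hidden
#' Markov model (EM with 10 seeded restarts, maximum-likelihood Viterbi
#' decoding); states are labeled upstream / none / downstream by the rank
#' of their fitted means. A domain extends from the first bin of a
#' downstream-biased run to the last bin of the last upstream-biased run
#' before the next downstream run (the conventional boundary rule); with
#' `literal = TRUE` a domain is instead just the contiguous downstream-
#' biased stretch. Domains shorter than `min_size` bins are discarded.
#'
#' @param di A `di_profile` from [directionality_index()].
#' @param min_size Minimum domain length in bins (default 3).
#' @param literal Use the literal "contiguous downstream states" definition.
#' @param seed Integer seed for the EM restarts.
#' @return Tibble of class `tad_set`: `chrom`, `start_bin`, `end_bin`
#'   (half-open bin indices), `start_bp`, `end_bp`.
#' @export
segment_domains <- function(di, min_size = 3, literal = FALSE, seed = 1) {
  check_columns(di, c("chrom", "start", "di"), "di")
  if (nrow(di) < 10L) {
    stop_arg("need at least 10 bins to segment (got %d)", nrow(di))
  }
  res <- attr(di, "resolution") %||%
    (sort(unique(di$start))[2L] - sort(unique(di$start))[1L])
  empty <- tibble(
    chrom = character(), start_bin = integer(), end_bin = integer(),
    start_bp = numeric(), end_bp = numeric()
  )
  per_chrom <- function(d) {
    # the DI is a signed chi-square-style statistic with heavy tails;
    # Gaussian emissions are fitted on the variance-stabilized signed
    # square-root scale (sign and state ordering are unaffected)
    x <- sign(d$di) * sqrt(abs(d$di))
    if (sd(x) == 0) {
      return(empty)
    }
    model <- hmm_fit(x, k = 3L, seed = seed)
    states <- hmm_viterbi(x, model)
    # states by fitted mean: 1 = upstream bias (most negative), 3 = downstream
    lab <- c("U", "N", "D")[match(seq_len(3L), order(model$means))]
    state_lab <- lab[states]
    runs <- runs_of(state_lab)
    doms <- list()
    d_runs <- which(runs$value == "D")
    for (i in d_runs) {
      if (literal) {
        doms <- c(doms, list(c(runs$start[i], runs$end[i])))
        next
      }
      # extend to the end of the last upstream run before the next D run
      nxt_d <- d_runs[d_runs > i]
      limit <- if (length(nxt_d) > 0) runs$start[nxt_d[1L]] - 1L else nrow(d)
      u_runs <- which(
        runs$value == "U" & runs$start > runs$end[i] & runs$end <= limit
      )
      if (length(u_runs) > 0L) {
        doms <- c(doms, list(c(runs$start[i], runs$end[max(u_runs)])))
      }
    }
    if (length(doms) == 0L) {
      return(empty)
    }
    out <- tibble(
      chrom = d$chrom[[1L]],
      start_bin = vapply(doms, `[[`, integer(1L), 1L) - 1L,
      end_bin = vapply(doms, `[[`, integer(1L), 2L)
    ) |>
      filter(.data$end_bin - .data$start_bin >= min_size) |>
      mutate(
        start_bp = d$start[.data$start_bin + 1L],
        end_bp = d$start[.data$end_bin] + res
      )
    out
  }
  out <- di |>
    as_tibble() |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    group_split() |>
    map(per_chrom) |>
    list_rbind()
  attr(out, "resolution") <- res
  class(out) <- c("tad_set", class(out))
  out
}

#' Write a TAD set as BED intervals
#'
#' @param tads A `tad_set`.
#' @param path Output file.
#' @export
write_tad_bed <- function(tads, path) {
  readr::write_tsv(
    as_tibble(tads)[, c("chrom", "start_bp", "end_bp")], path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Bidirectional best-match TAD similarity
#'
#' Every domain in set A is matched to the domain in set B with the highest
#' Jaccard coefficient on bin sets and those coefficients are averaged; the
#' symmetric pass (B against A) is averaged the same way; the similarity is
#' the mean of the two averages. 1 means the sets coincide, 0 that no
#' domain overlaps any other.
#'
#' @param tads_a,tads_b `tad_set` tibbles on the same bin grid.
#' @return A number in \[0, 1\]; `NA` (with a warning) when either set is
#'   empty.
#' @export
tad_similarity <- function(tads_a, tads_b) {
  check_columns(tads_a, c("start_bin", "end_bin"), "tads_a")
  check_columns(tads_b, c("start_bin", "end_bin"), "tads_b")
  if (nrow(tads_a) == 0L || nrow(tads_b) == 0L) {
    warn("TAD similarity undefined: at least one set is empty")
    return(NA_real_)
  }
  best_match_avg <- function(a, b) {
    mean(vapply(seq_len(nrow(a)), function(i) {
      max(interval_jaccard(
        a$start_bin[i], a$end_bin[i], b$start_bin, b$end_bin
      ))
    }, numeric(1L)))
  }
  (best_match_avg(tads_a, tads_b) + best_match_avg(tads_b, tads_a)) / 2
}
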