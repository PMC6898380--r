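#' Aggregate base-pair coverage into per-bin signal
#'
#' The per-bin value is the mean per-bp coverage over the bin, i.e. the sum
#' of coverage mass falling inside the bin divided by the bin width. Input
#' coverage is given as half-open bp intervals with a constant value.
#'
#' @param coverage Tibble with columns `chrom`, `start`, `end`, `value`
#'   (bp intervals, value >= 0).
#' @param resolution Bin width in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   coverage extending past a chromosome end is clipped with a warning,
#'   and trailing empty bins are materialized as zeros.
#' @return Long track tibble with columns `chrom`, `start`, `value`.
#' @export
aggregate_signal <- function(coverage, resolution, chrom_lengths = NULL) {
  check_scalar_number(resolution, "resolution", positive = TRUE)
  check_columns(coverage, c("chrom", "start", "end", "value"), "coverage")
  if (any(coverage$value < 0)) {
    stop_arg("coverage values must be non-negative")
  }
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[coverage$chrom])
    over <- !is.na(lim) & coverage$end > lim
    if (any(over)) {
      warn(sprintf(
        "%d coverage interval(s) extend past the chromosome end; clipped",
        sum(over)
      ))
      coverage$end[over] <- lim[over]
      coverage <- coverage[coverage$start < coverage$end, , drop = FALSE]
    }
  }
  per_chrom <- function(cv, chrom) {
    n_bins <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      ceiling(chrom_lengths[[chrom]] / resolution)
    } else {
      ceiling(max(cv$end) / resolution)
    }
    bin_first <- floor(cv$start / resolution)
    bin_last <- floor((cv$end - 1) / resolution)
    reps <- bin_last - bin_first + 1L
    idx <- rep(seq_len(nrow(cv)), reps)
    bin <- bin_first[idx] + sequence(reps) - 1
    ov <- pmin(cv$end[idx], (bin + 1) * resolution) -
      pmax(cv$start[idx], bin * resolution)
    mass <- tapply(cv$value[idx] * ov, factor(bin, levels = 0:(n_bins - 1)), sum)
    tibble(
      chrom = chrom,
      start = (0:(n_bins - 1)) * resolution,
      value = as.numeric(ifelse(is.na(mass), 0, mass)) / resolution
    )
  }
  coverage |>
    group_by(.data$chrom) |>
    group_split() |>
    map(~ per_chrom(.x, .x$chrom[[1L]])) |>
    list_rbind()
}

#' Depth-normalize a signal track
#'
#' Scales aggregated signal to counts-per-million mapped reads so that
#' tracks are comparable across datasets and cell lines.
#'
#' @param track Long track tibble with a `value` column.
#' @param total_mapped Total mapped reads for the dataset.
#' @return The track with `value` scaled by `1e6 / total_mapped`.
#' @export
depth_normalize <- function(track, total_mapped) {
  check_scalar_number(total_mapped, "total_mapped", positive = TRUE)
  check_columns(track, "value", "track")
  track$value <- track$value * 1e6 / total_mapped
  track
}

#' Collapse replicate tracks by the element-wise median
#'
#' @param tracks List of track tibbles sharing an identical `(chrom, start)`
#'   grid.
#' @return A single track with the per-bin median value.
#' @export
combine_replicates <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0L) {
    stop_arg("`tracks` must be a non-empty list of tracks")
  }
  ref <- tracks[[1L]]
  check_columns(ref, c("chrom", "start", "value"), "tracks[[1]]")
  for (t in tracks[-1L]) {
    check_columns(t, c("chrom", "start", "value"), "replicate")
    if (!identical(ref$chrom, t$chrom) || !identical(ref$start, t$start)) {
      stop_arg("replicate tracks are on mismatched bin grids")
    }
  }
  vals <- vapply(tracks, function(t) t$value, numeric(nrow(ref)))
  out <- ref
  out$value <- apply(as.matrix(vals), 1L, median)
  out
}

#' Summed motif purity per bin
#'
#' Each motif is assigned to the bin containing its midpoint; the bin value
#' is the sum of purity scores of its motifs. Strand is deliberately ignored
#' here -- orientation only matters for loop-configuration analysis.
#'
#' @param motifs Motif tibble (see [read_motif_bed()]).
#' @param resolution Bin width in bp.
#' @param bins Optional bin tibble; bins without motifs get value 0. When
#'   omitted, bins tile from 0 to the last motif.
#' @return Long track tibble `chrom`, `start`, `value`.
#' @export
motif_bin_score <- function(motifs, resolution, bins = NULL) {
  check_scalar_number(resolution, "resolution", positive = TRUE)
  check_columns(motifs, c("chrom", "start", "end", "purity"), "motifs")
  if (is.null(bins)) {
    if (nrow(motifs) == 0L) {
      return(tibble(chrom = character(), start = numeric(), value = numeric()))
    }
    bins <- motifs |>
      group_by(.data$chrom) |>
      summarise(len = max(.data$end), .groups = "drop")
    bins <- bin_genome(setNames(bins$len, bins$chrom), resolution)
  }
  mid <- floor((motifs$start + motifs$end) / 2)
  scored <- tibble(
    chrom = motifs$chrom,
    start = floor(mid / resolution) * resolution,
    purity = motifs$purity
  ) |>
    group_by(.data$chrom, .data$start) |>
    summarise(value = sum(.data$purity), .groups = "drop")
  bins |>
    select("chrom", "start") |>
    left_join(scored, by = c("chrom", "start")) |>
    mutate(value = ifelse(is.na(.data$value), 0, .data$value))
}

feature_name <- function(dataset, role, cell) {
  paste(dataset, role, cell, sep = "_")
}

#' Encode region pairs as feature vectors
#'
#' Implements the three pair encodings plus the distance feature:
#' * `"pair"` (PAIR-CONCAT): the two end-region signal vectors concatenated
#'   (28 columns for 14 datasets);
#' * `"window"`: additionally the mean signal over the bins strictly between
#'   R1 and R2 (42 columns); for adjacent pairs the window is empty and is
#'   defined as the mean of the two end-bin values;
#' * `"multicell"`: WINDOW blocks from every (non-excluded) cell line
#'   concatenated (210 columns for 5 cell lines);
#' * `"distance"`: no signal columns, the distance-only baseline.
#'
#' `Distance` (in bin units) is always appended as the final column. Columns
#' follow a canonical order -- datasets alphabetical, roles R1/R2/W, cell
#' lines alphabetical -- so the encoding never depends on input file order.
#'
#' @param pairs Pair tibble from [enumerate_pairs()] (columns `chrom`,
#'   `start1`, `start2`, `distance_bins`).
#' @param signals Long signal tibble (`chrom`, `start`, `dataset`, `cell`,
#'   `value`) covering every bin referenced by `pairs`.
#' @param mode One of `"window"`, `"pair"`, `"multicell"`, `"distance"`.
#' @param cell Cell line supplying the signals for `"pair"`/`"window"`.
#' @param exclude_cells Cell lines whose signals are dropped in
#'   `"multicell"` mode (cross-cell prediction excludes the test cell line).
#' @return A tibble with the pair identifier columns followed by the feature
#'   columns; the model columns are recorded in the `feature_names`
#'   attribute and the per-column metadata in `feature_info`.
#' @export
encode_pairs <- function(pairs, signals = NULL,
                         mode = c("window", "pair", "multicell", "distance"),
                         cell = NULL, exclude_cells = NULL) {
  mode <- match.arg(mode)
  check_columns(pairs, c("chrom", "start1", "start2", "distance_bins"), "pairs")
  out <- as_tibble(pairs)[, c("chrom", "start1", "start2", "distance_bins")]
  info <- tibble(
    name = character(), dataset = character(),
    role = character(), cell = character()
  )
  if (mode != "distance") {
    if (is.null(signals)) {
      stop_arg("`signals` are required for mode '%s'", mode)
    }
    check_columns(signals, c("chrom", "start", "dataset", "cell", "value"), "signals")
    cells <- if (mode == "multicell") {
      setdiff(sort(unique(signals$cell)), exclude_cells)
    } else {
      if (is.null(cell)) {
        cell <- unique(signals$cell)
        if (length(cell) != 1L) {
          stop_arg("`cell` must be given when `signals` span several cell lines")
        }
      }
      cell
    }
    if (length(cells) == 0L) {
      stop_arg("no cell lines left after exclusion")
    }
    roles <- if (mode == "pair") c("R1", "R2") else c("R1", "R2", "W")
    datasets <- sort(unique(signals$dataset))
    blocks <- list()
    for (cl in cells) {
      cs <- signals |> filter(.data$cell == cl)
      if (nrow(cs) == 0L) {
        stop_arg("no signal tracks for cell line '%s'", cl)
      }
      wide <- cs |>
        select("chrom", "start", "dataset", "value") |>
        pivot_wider(names_from = "dataset", values_from = "value") |>
        arrange(.data$chrom, .data$start)
      miss_ds <- setdiff(datasets, names(wide))
      if (length(miss_ds) > 0L) {
        stop_arg(
          "missing track(s): %s",
          paste(sprintf("(%s, %s)", miss_ds, cl), collapse = ", ")
        )
      }
      res <- diff(sort(unique(wide$start)))
      res <- if (length(res) > 0) min(res) else 1
      idx1 <- match(paste(out$chrom, out$start1), paste(wide$chrom, wide$start))
      idx2 <- match(paste(out$chrom, out$start2), paste(wide$chrom, wide$start))
      if (anyNA(idx1) || anyNA(idx2)) {
        stop_arg(
          "%d pair(s) reference bins absent from the signal tracks of '%s'",
          sum(is.na(idx1) | is.na(idx2)), cl
        )
      }
      mat <- as.matrix(wide[, datasets, drop = FALSE])
      if (anyNA(mat)) {
        stop_arg("signal tracks for cell line '%s' contain missing bins", cl)
      }
      r1 <- mat[idx1, , drop = FALSE]
      r2 <- mat[idx2, , drop = FALSE]
      block <- list(R1 = r1, R2 = r2)
      if ("W" %in% roles) {
        # window mean over bins strictly between R1 and R2, via cumulative
        # sums; adjacent pairs fall back to the mean of the two end bins
        cs_mat <- apply(mat, 2L, cumsum)
        cs_mat <- rbind(0, cs_mat)
        d <- out$distance_bins
        wsum <- cs_mat[idx2, , drop = FALSE] - cs_mat[idx1 + 1L, , drop = FALSE]
        w <- wsum / pmax(d - 1, 1)
        adj <- d == 1
        if (any(adj)) {
          w[adj, ] <- (r1[adj, , drop = FALSE] + r2[adj, , drop = FALSE]) / 2
        }
        block$W <- w
      }
      for (role in roles) {
        m <- block[[role]]
        colnames(m) <- feature_name(datasets, role, cl)
        blocks[[paste(cl, role)]] <- m
        info <- bind_rows(info, tibble(
          name = colnames(m), dataset = datasets, role = role, cell = cl
        ))
      }
    }
    feat <- do.call(cbind, blocks)
    ord <- order(info$dataset, match(info$role, c("R1", "R2", "W")), info$cell)
    info <- info[ord, ]
    feat <- feat[, info$name, drop = FALSE]
    out <- bind_cols(out, as_tibble(feat))
  }
  out$Distance <- as.numeric(pairs$distance_bins)
  info <- bind_rows(info, tibble(
    name = "Distance", dataset = NA_character_,
    role = "Distance", cell = NA_character_
  ))
  attr(out, "feature_names") <- info$name
  attr(out, "feature_info") <- info
  attr(out, "mode") <- mode
  out
}

#' Model feature columns of an encoded pair table
#'
#' @param x Output of [encode_pairs()].
#' @return Character vector of feature column names (including `Distance`).
#' @export
feature_names <- function(x) {
  fn <- attr(x, "feature_names")
  if (is.null(fn)) {
    fn <- setdiff(names(x), c("chrom", "start1", "start2", "distance_bins", "count", "measured"))
  }
  fn
}
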