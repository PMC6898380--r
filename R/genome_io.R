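#' Build a contact table
#'
#' A contact table is the package's sparse representation of a Hi-C matrix:
#' one row per region pair in the upper triangle (including the diagonal for
#' aggregated resolutions), with a non-negative (normalized) contact count.
#' Rows given with `start2 < start1` are silently canonicalized so that the
#' region with the smaller coordinate is always R1.
#'
#' @param x A data frame with columns `chrom`, `start1`, `start2`, `count`
#'   and optionally `measured` (logical, defaults to `TRUE`). Starts are
#'   0-based bp offsets and must sit on the bin grid.
#' @param resolution Bin width in bp.
#' @return A tibble of class `contact_table` with a `resolution` attribute.
#' @examples
#' contact_table(
#'   data.frame(chrom = "chr1", start1 = 0, start2 = 10000, count = 4),
#'   resolution = 5000
#' )
#' @export
contact_table <- function(x, resolution) {
  check_scalar_number(resolution, "resolution", positive = TRUE)
  x <- as_tibble(x)
  check_columns(x, c("chrom", "start1", "start2", "count"), "x")
  if (!"measured" %in% names(x)) x$measured <- TRUE
  if (any(is.na(x$count)) || any(x$count < 0)) {
    stop_arg("contact counts must be non-negative and non-missing")
  }
  off_grid <- x$start1 %% resolution != 0 | x$start2 %% resolution != 0
  if (any(off_grid)) {
    stop_arg(
      "%d record(s) have starts off the %d bp bin grid",
      sum(off_grid), resolution
    )
  }
  if (any(x$start1 < 0 | x$start2 < 0)) {
    stop_arg("bin starts must be non-negative")
  }
  swap <- x$start2 < x$start1
  if (any(swap)) {
    tmp <- x$start1[swap]
    x$start1[swap] <- x$start2[swap]
    x$start2[swap] <- tmp
  }
  key <- paste(x$chrom, x$start1, x$start2)
  if (anyDuplicated(key)) {
    stop_arg("duplicate region pairs in contact table")
  }
  x <- x |>
    select("chrom", "start1", "start2", "count", "measured") |>
    arrange(.data$chrom, .data$start1, .data$start2)
  attr(x, "resolution") <- resolution
  class(x) <- c("contact_table", class(x))
  x
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf(
    "# Contact table: %d pairs at %d bp resolution (%d measured)\n",
    nrow(x), contact_resolution(x), sum(x$measured)
  ))
  NextMethod()
}

#' Resolution of a contact table or bin set
#'
#' @param x An object carrying a `resolution` attribute (a [contact_table()],
#'   the output of [bin_genome()], ...).
#' @return Bin width in bp.
#' @export
contact_resolution <- function(x) {
  res <- attr(x, "resolution")
  if (is.null(res)) {
    stop_arg("object carries no `resolution` attribute")
  }
  res
}

#' Tile chromosomes into fixed-width bins
#'
#' Coordinates are 0-based and half-open; each chromosome of length L gets
#' `ceiling(L / resolution)` bins tiling `[0, L)`, identified by their start.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param resolution Bin width in bp.
#' @return A tibble with columns `chrom` and `start` and a `resolution`
#'   attribute.
#' @examples
#' bin_genome(c(chr1 = 12000), resolution = 5000)
#' @export
bin_genome <- function(chrom_lengths, resolution) {
  check_scalar_number(resolution, "resolution", positive = TRUE)
  if (length(chrom_lengths) == 0L || is.null(names(chrom_lengths)) ||
      any(!nzchar(names(chrom_lengths)))) {
    stop_arg("`chrom_lengths` must be a named vector of lengths")
  }
  if (any(chrom_lengths <= 0)) {
    stop_arg("chromosome lengths must be positive")
  }
  bins <- imap(chrom_lengths, function(len, chrom) {
    tibble(
      chrom = chrom,
      start = seq(0, by = resolution, length.out = ceiling(len / resolution))
    )
  }) |> list_rbind()
  attr(bins, "resolution") <- resolution
  bins
}

#' Enumerate region pairs within a distance radius
#'
#' All pairs (i, j) of bins from a single chromosome with
#' `1 <= j - i <= max_distance_bins`, i.e. the upper triangle of the contact
#' matrix out to the radius. Distances are reported in bin units.
#'
#' @param bins Output of [bin_genome()] restricted to one chromosome.
#' @param max_distance_bins Radius in bins (200 for 1 Mb at 5 kb).
#' @param resolution Bin width; defaults to the attribute on `bins`.
#' @return Tibble with columns `chrom`, `start1`, `start2`, `distance_bins`.
#' @export
enumerate_pairs <- function(bins, max_distance_bins,
                            resolution = contact_resolution(bins)) {
  check_scalar_number(max_distance_bins, "max_distance_bins", positive = TRUE)
  check_columns(bins, c("chrom", "start"), "bins")
  if (length(unique(bins$chrom)) > 1L) {
    stop_arg("`bins` must come from a single chromosome")
  }
  starts <- sort(bins$start)
  n <- length(starts)
  d_max <- min(max_distance_bins, n - 1L)
  if (n < 2L || d_max < 1L) {
    return(tibble(
      chrom = character(), start1 = numeric(), start2 = numeric(),
      distance_bins = integer()
    ))
  }
  pieces <- lapply(seq_len(d_max), function(g) {
    tibble(
      chrom = bins$chrom[[1L]],
      start1 = starts[seq_len(n - g)],
      start2 = starts[seq_len(n - g) + g],
      distance_bins = g
    )
  })
  out <- list_rbind(pieces) |> arrange(.data$start1, .data$start2)
  attr(out, "resolution") <- resolution
  out
}

#' Genomic distance of pairs in bp
#'
#' @param pairs A tibble with `distance_bins` (or `start1`/`start2`).
#' @param resolution Bin width in bp.
#' @return Numeric vector of distances in bp.
#' @export
distance_bp <- function(pairs, resolution = contact_resolution(pairs)) {
  if ("distance_bins" %in% names(pairs)) {
    return(pairs$distance_bins * resolution)
  }
  pairs$start2 - pairs$start1
}

read_table_guess_header <- function(path, n_cols, col_types) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop_parse("file '%s' is empty", path)
  }
  fields <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  has_header <- length(fields) >= 2L && is.na(suppressWarnings(as.numeric(fields[[2L]])))
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_names = FALSE, skip = if (has_header) 1L else 0L,
    col_types = col_types, progress = FALSE
  ))
  list(data = x, skip = if (has_header) 1L else 0L)
}

#' Read / write sparse contact count files
#'
#' The on-disk format is tab-delimited `(chrom, start1, start2, count)` with
#' an optional header. Lower-triangle rows are reflected to the upper
#' triangle on read.
#'
#' @param path File path.
#' @param resolution Bin width in bp.
#' @param offset Constant subtracted from both starts on read, for input
#'   files using 1-based coordinates (`offset = 1`). Default 0.
#' @return [read_contact_table()] returns a [contact_table()];
#'   [write_contact_table()] returns `path` invisibly.
#' @export
read_contact_table <- function(path, resolution, offset = 0) {
  parsed <- read_table_guess_header(path, 4L, "cnnn")
  x <- parsed$data
  if (ncol(x) < 4L) {
    stop_parse("contact file '%s' must have 4 tab-delimited columns", path)
  }
  names(x)[1:4] <- c("chrom", "start1", "start2", "count")
  bad <- which(is.na(x$start1) | is.na(x$start2) | is.na(x$count))
  if (length(bad) > 0L) {
    stop_parse(
      "malformed contact record at line %d of '%s'",
      bad[[1L]] + parsed$skip, path
    )
  }
  neg <- which(x$count < 0)
  if (length(neg) > 0L) {
    stop_parse(
      "negative count at line %d of '%s'", neg[[1L]] + parsed$skip, path
    )
  }
  x$start1 <- x$start1 - offset
  x$start2 <- x$start2 - offset
  contact_table(x[, 1:4], resolution = resolution)
}

#' @param table A [contact_table()]. Only measured pairs are written.
#' @rdname read_contact_table
#' @export
write_contact_table <- function(table, path) {
  out <- table |>
    as_tibble() |>
    filter(.data$measured) |>
    select("chrom", "start1", "start2", "count")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write per-bin signal tables
#'
#' Signal tables are TSV with a header: `chrom`, `start`, then one column
#' per dataset (the dataset name). Values are depth-normalized aggregated
#' signals. The long (tidy) form used throughout the package has columns
#' `chrom`, `start`, `dataset`, `cell`, `value`.
#'
#' @param path File path.
#' @param cell Cell-line label attached to every track (the file format is
#'   per cell line).
#' @return A long tibble of signal tracks.
#' @export
read_signal_table <- function(path, cell = NA_character_) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    start = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  check_columns(x, c("chrom", "start"), basename(path))
  datasets <- setdiff(names(x), c("chrom", "start"))
  if (length(datasets) == 0L) {
    stop_parse("signal table '%s' has no dataset columns", path)
  }
  for (d in datasets) {
    v <- suppressWarnings(as.numeric(x[[d]]))
    if (any(is.na(v) & !is.na(x[[d]]))) {
      stop_parse("non-numeric value in dataset column '%s' of '%s'", d, path)
    }
    x[[d]] <- v
  }
  x |>
    pivot_longer(all_of(datasets), names_to = "dataset", values_to = "value") |>
    mutate(cell = cell, .before = "value") |>
    arrange(.data$dataset, .data$chrom, .data$start)
}

#' @param signals Long signal tibble for a single cell line.
#' @rdname read_signal_table
#' @export
write_signal_table <- function(signals, path) {
  check_columns(signals, c("chrom", "start", "dataset", "value"), "signals")
  wide <- signals |>
    select("chrom", "start", "dataset", "value") |>
    pivot_wider(names_from = "dataset", values_from = "value") |>
    arrange(.data$chrom, .data$start)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read / write signed motif calls
#'
#' BED6 with the score column holding the motif purity (in [0.5, 1]) and a
#' mandatory `+`/`-` strand: unsigned motifs are rejected because loop
#' orientation analysis requires the sign.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `purity`,
#'   `strand`.
#' @export
read_motif_bed <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "purity", "strand"),
    col_types = "cnncnc", progress = FALSE
  )
  if (any(is.na(x$start) | is.na(x$end) | is.na(x$purity))) {
    stop_parse("malformed motif record in '%s'", path)
  }
  if (any(!x$strand %in% c("+", "-"))) {
    stop_parse(
      "motif file '%s' contains unsigned strands; signed motifs are required",
      path
    )
  }
  if (any(x$start >= x$end)) {
    stop_parse("motif with start >= end in '%s'", path)
  }
  if (any(x$purity < 0.5 | x$purity > 1)) {
    stop_parse("motif purity outside [0.5, 1] in '%s'", path)
  }
  x
}

#' @param motifs Motif tibble as returned by [read_motif_bed()].
#' @rdname read_motif_bed
#' @export
write_motif_bed <- function(motifs, path) {
  check_columns(motifs, c("chrom", "start", "end", "purity", "strand"), "motifs")
  out <- motifs |>
    mutate(name = if ("name" %in% names(motifs)) .data$name else "motif") |>
    select("chrom", "start", "end", "name", "purity", "strand")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read BEDPE-like interaction pairs
#'
#' Six-column pairs (`chrom1, start1, end1, chrom2, start2, end2`) with any
#' trailing columns ignored; used for external validation sets such as
#' ChIA-PET interactions.
#'
#' @param path File path.
#' @param provenance Free-text label stored on the result (e.g. "ChIA-PET").
#' @return Tibble of anchor intervals with a `provenance` attribute.
#' @export
read_bedpe <- function(path, provenance = NA_character_) {
  x <- suppressWarnings(readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    X1 = readr::col_character(), X4 = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE))
  if (ncol(x) < 6L) {
    stop_parse("BEDPE file '%s' must have at least 6 columns", path)
  }
  x <- x[, 1:6]
  names(x) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (any(is.na(x$start1) | is.na(x$start2))) {
    stop_parse("malformed BEDPE record in '%s'", path)
  }
  attr(x, "provenance") <- provenance
  x
}

#' Map interval pairs onto the working bin grid
#'
#' Each anchor is assigned to the bin containing its midpoint; pairs are
#' normalized to the upper triangle and de-duplicated.
#'
#' @param x BEDPE-like tibble from [read_bedpe()] (or any tibble with the
#'   same anchor columns).
#' @param resolution Bin width in bp.
#' @return Tibble with `chrom`, `start1`, `start2` at the working resolution.
#' @export
map_interactions_to_bins <- function(x, resolution) {
  check_columns(x, c("chrom1", "start1", "end1", "chrom2", "start2", "end2"), "x")
  check_scalar_number(resolution, "resolution", positive = TRUE)
  mid1 <- floor((x$start1 + x$end1) / 2)
  mid2 <- floor((x$start2 + x$end2) / 2)
  b1 <- floor(mid1 / resolution) * resolution
  b2 <- floor(mid2 / resolution) * resolution
  out <- tibble(
    chrom = x$chrom1,
    start1 = pmin(b1, b2),
    start2 = pmax(b1, b2)
  ) |>
    filter(x$chrom1 == x$chrom2) |>
    distinct()
  attr(out, "resolution") <- resolution
  out
}

#' Aggregate a contact table to a coarser resolution
#'
#' Each coarse count is the sum of the constituent fine counts: every
#' upper-triangle fine cell maps to exactly one coarse cell, so total count
#' mass is conserved. Fine pairs whose coarse images coincide land on the
#' coarse diagonal and are kept (`start1 == start2`).
#'
#' @param table A [contact_table()].
#' @param factor Integer >= 1; output resolution is `factor` times the input
#'   resolution.
#' @return A [contact_table()] at the coarser resolution.
#' @export
aggregate_resolution <- function(table, factor) {
  check_scalar_number(factor, "factor", positive = TRUE)
  if (factor != as.integer(factor) || factor < 1) {
    stop_arg("`factor` must be a positive integer")
  }
  factor <- as.integer(factor)
  res <- contact_resolution(table)
  if (factor == 1L) {
    return(table)
  }
  coarse <- res * factor
  out <- table |>
    as_tibble() |>
    mutate(
      start1 = floor(.data$start1 / coarse) * coarse,
      start2 = floor(.data$start2 / coarse) * coarse
    ) |>
    group_by(.data$chrom, .data$start1, .data$start2) |>
    summarise(
      count = sum(.data$count), measured = any(.data$measured),
      .groups = "drop"
    )
  contact_table(out, resolution = coarse)
}
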