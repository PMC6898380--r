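#' Simulation configuration
#'
#' Bundles every knob of the synthetic Hi-C study generator. The defaults
#' describe the regime the toolkit targets: a 10 Mb chromosome at 5 kb
#' resolution (2,000 bins), 14 regulatory datasets measured in 5 cell
#' lines, contact counts with power-law distance decay modulated by a small
#' number of informative signals, planted topological domains, and planted
#' loops anchored at convergent signed motifs.
#'
#' @param n_bins Number of bins (default 2000).
#' @param resolution Bin width in bp (default 5000).
#' @param n_datasets Number of regulatory datasets (default 14, named
#'   `d01`..`d14`).
#' @param n_cells Number of cell lines (default 5, named `cellA`..`cellE`).
#' @param max_distance_bins Pair radius in bins (default 200 = 1 Mb).
#' @param alpha Power-law distance-decay exponent (default 1).
#' @param base_count Expected count at distance one bin before modulation
#'   (default 100).
#' @param weights Tibble `(dataset, w_end, w_window)` of generative weights
#'   on the standardized log-signals; datasets absent from the table have
#'   zero weight. Defaults: `d01`/`d02` act through their end regions,
#'   `d03` through the intervening window.
#' @param rho Cross-cell-line correlation of matched log-signal tracks, in
#'   \[0, 1\] (default 0.75).
#' @param signal_meanlog,signal_sdlog Log-normal signal parameters.
#' @param tad_n,tad_size,tad_boost Planted domains: how many, the size range
#'   in bins, and the multiplicative boost for within-domain pairs
#'   (defaults 25 domains of 30-80 bins, boost 3).
#' @param loop_n,loop_boost,loop_distance Planted loops: how many, their
#'   count boost, and their anchor-distance range in bins (defaults 40
#'   loops, boost 8, 20-150 bins).
#' @param domain_dataset,domain_signal Dataset whose log-signal is raised by
#'   `domain_signal` inside planted domains (default `"d01"`, 1): chromatin
#'   marks and architectural proteins track domain structure in real data,
#'   and this coupling is what lets count predictors recover domains.
#' @param motif_decoy_rate Expected decoy motifs per bin (default 0.3).
#' @param coverage Fraction of pairs that are "measured" (default 0.85).
#' @param dispersion Noise scale: counts get additive Gaussian noise with
#'   standard deviation `dispersion * sqrt(mu)`, truncated at zero.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_bins = 2000, resolution = 5000, n_datasets = 14,
                       n_cells = 5, max_distance_bins = 200,
                       alpha = 1, base_count = 100,
                       weights = tibble(
                         dataset = c("d01", "d02", "d03"),
                         w_end = c(0.3, 0.25, 0),
                         w_window = c(0, 0, 0.3)
                       ),
                       rho = 0.75,
                       signal_meanlog = 0, signal_sdlog = 1,
                       tad_n = 25, tad_size = c(30, 80), tad_boost = 3,
                       loop_n = 40, loop_boost = 8,
                       loop_distance = c(20, 150),
                       domain_dataset = "d01", domain_signal = 1,
                       motif_decoy_rate = 0.3, coverage = 0.85,
                       dispersion = 1) {
  stopifnot(rho >= 0, rho <= 1, alpha >= 0, base_count > 0, coverage > 0,
            coverage <= 1, dispersion >= 0, tad_boost >= 1, loop_boost >= 1)
  datasets <- sprintf("d%02d", seq_len(n_datasets))
  # weight rows for datasets that do not exist at this n_datasets are moot
  weights <- weights[weights$dataset %in% datasets, , drop = FALSE]
  structure(
    list(
      n_bins = n_bins, resolution = resolution, n_datasets = n_datasets,
      n_cells = n_cells, max_distance_bins = max_distance_bins,
      alpha = alpha, base_count = base_count, weights = weights,
      rho = rho, signal_meanlog = signal_meanlog,
      signal_sdlog = signal_sdlog,
      tad_n = tad_n, tad_size = tad_size, tad_boost = tad_boost,
      loop_n = loop_n, loop_boost = loop_boost,
      loop_distance = loop_distance,
      domain_dataset = domain_dataset, domain_signal = domain_signal,
      motif_decoy_rate = motif_decoy_rate, coverage = coverage,
      dispersion = dispersion,
      datasets = datasets,
      cells = paste0("cell", LETTERS[seq_len(n_cells)]),
      chrom = "chrS"
    ),
    class = "sim_config"
  )
}

#' Simulate correlated regulatory signal tracks
#'
#' One log-normal track per (dataset, cell line): each dataset has a latent
#' per-bin profile shared across cell lines, mixed with cell-specific noise
#' so that the log-signals of matched datasets correlate at `rho` across
#' cell lines. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param truth Optional `sim_truth`; when supplied, the configured
#'   `domain_dataset`'s log-signal is raised by `domain_signal` inside the
#'   planted domains (in every cell line -- domain structure is largely
#'   shared across cell types).
#' @param seed Integer seed.
#' @return Long signal tibble (`chrom`, `start`, `dataset`, `cell`,
#'   `value`).
#' @export
simulate_signals <- function(config, truth = NULL, seed = 1) {
  n <- config$n_bins
  domain_shift <- numeric(n)
  if (!is.null(truth) && config$domain_signal != 0 &&
      config$domain_dataset %in% config$datasets && nrow(truth$tads) > 0L) {
    for (r in seq_len(nrow(truth$tads))) {
      idx <- (truth$tads$start_bin[r] + 1L):truth$tads$end_bin[r]
      domain_shift[idx] <- config$domain_signal
    }
  }
  with_seed(seed, {
    rows <- list()
    for (d in seq_len(config$n_datasets)) {
      shared <- rnorm(n)
      shift <- if (config$datasets[d] == config$domain_dataset) {
        domain_shift
      } else {
        0
      }
      for (c in seq_len(config$n_cells)) {
        z <- sqrt(config$rho) * shared + sqrt(1 - config$rho) * rnorm(n) +
          shift
        rows[[length(rows) + 1L]] <- tibble(
          chrom = config$chrom,
          start = (seq_len(n) - 1) * config$resolution,
          dataset = config$datasets[d],
          cell = config$cells[c],
          value = exp(config$signal_meanlog + config$signal_sdlog * z)
        )
      }
    }
    list_rbind(rows)
  })
}

#' Plant ground-truth domains and loops
#'
#' Draws non-overlapping domain intervals and loop anchor pairs; every loop
#' gets a convergent motif pair at its anchors when motifs are simulated.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `sim_truth` with `tads` (a `tad_set`-shaped
#'   tibble), `loops` (pair tibble) and the generative `weights`.
#' @export
simulate_truth <- function(config, seed = 1) {
  n <- config$n_bins
  res <- config$resolution
  with_seed(seed + 1L, {
    # tile domains left to right with random sizes and small gaps, then
    # keep a random subset of tad_n
    doms <- list()
    pos <- sample(2:8, 1L)
    while (pos + config$tad_size[1L] < n) {
      len <- sample(seq(config$tad_size[1L], config$tad_size[2L]), 1L)
      end <- min(pos + len, n)
      doms[[length(doms) + 1L]] <- c(pos, end)
      pos <- end + sample(2:8, 1L)
    }
    if (length(doms) > config$tad_n) {
      doms <- doms[sort(sample(length(doms), config$tad_n))]
    }
    tads <- tibble(
      chrom = config$chrom,
      start_bin = vapply(doms, `[[`, numeric(1L), 1L),
      end_bin = vapply(doms, `[[`, numeric(1L), 2L)
    ) |>
      mutate(start_bp = .data$start_bin * res, end_bp = .data$end_bin * res)
    class(tads) <- c("tad_set", class(tads))
    attr(tads, "resolution") <- res
    loops <- tibble(
      b1 = sample(seq_len(n - config$loop_distance[1L]), config$loop_n * 3L,
                  replace = TRUE)
    ) |>
      mutate(
        gap = sample(
          seq(config$loop_distance[1L], config$loop_distance[2L]),
          dplyr::n(), replace = TRUE
        ),
        b2 = .data$b1 + .data$gap
      ) |>
      filter(.data$b2 <= n) |>
      distinct(.data$b1, .data$b2) |>
      head(config$loop_n) |>
      transmute(
        chrom = config$chrom,
        start1 = (.data$b1 - 1) * res,
        start2 = (.data$b2 - 1) * res
      )
    structure(
      list(tads = tads, loops = loops, weights = config$weights),
      class = "sim_truth"
    )
  })
}

standardized_log <- function(values) {
  z <- log(values)
  (z - mean(z)) / max(sd(z), 1e-12)
}

#' Simulate a contact table from signals and planted structure
#'
#' The expected count of a pair at distance d bins is
#' `base_count * d^(-alpha) * exp(signal effect) * tad_boost * loop_boost`,
#' where the signal effect is a weighted sum of the standardized
#' log-signals of the chosen cell line (end-region weights act on the mean
#' of the two anchor bins, window weights on the mean over intervening
#' bins), the TAD boost applies to pairs within a planted domain and the
#' loop boost to planted anchor pairs. Observed counts add truncated
#' Gaussian noise with standard deviation `dispersion * sqrt(mu)`; a random
#' `coverage` fraction of pairs is marked measured.
#'
#' @param config A [sim_config()].
#' @param signals Long signal tibble from [simulate_signals()].
#' @param truth A `sim_truth` from [simulate_truth()].
#' @param cell Cell line whose signals drive the counts.
#' @param seed Integer seed.
#' @return A [contact_table()] carrying all enumerated pairs (unmeasured
#'   pairs have `measured = FALSE`).
#' @export
simulate_contacts <- function(config, signals, truth, cell, seed = 1) {
  res <- config$resolution
  bins <- tibble(
    chrom = config$chrom,
    start = (seq_len(config$n_bins) - 1) * res
  )
  attr(bins, "resolution") <- res
  pairs <- enumerate_pairs(bins, config$max_distance_bins)
  d <- pairs$distance_bins
  mu <- config$base_count * d^(-config$alpha)
  w <- config$weights
  if (nrow(w) > 0L) {
    cs <- signals |> filter(.data$cell == !!cell)
    if (nrow(cs) == 0L) {
      stop_arg("no signals for cell line '%s'", cell)
    }
    effect <- numeric(nrow(pairs))
    i1 <- pairs$start1 / res + 1L
    i2 <- pairs$start2 / res + 1L
    for (r in seq_len(nrow(w))) {
      tr <- cs |>
        filter(.data$dataset == w$dataset[r]) |>
        arrange(.data$start)
      z <- standardized_log(tr$value)
      # every generative covariate is scaled to unit variance so the stated
      # weights are comparable: end covariate (z1 + z2)/sqrt(2), window
      # covariate = window sum / sqrt(#window bins)
      if (w$w_end[r] != 0) {
        effect <- effect + w$w_end[r] * (z[i1] + z[i2]) / sqrt(2)
      }
      if (w$w_window[r] != 0) {
        csz <- c(0, cumsum(z))
        wcov <- (csz[i2] - csz[i1 + 1L]) / sqrt(pmax(d - 1, 1))
        adj <- d == 1
        wcov[adj] <- (z[i1[adj]] + z[i2[adj]]) / sqrt(2)
        effect <- effect + w$w_window[r] * wcov
      }
    }
    mu <- mu * exp(effect)
  }
  if (nrow(truth$tads) > 0L) {
    b1 <- pairs$start1 / res
    b2 <- pairs$start2 / res
    in_tad <- rep(FALSE, nrow(pairs))
    for (r in seq_len(nrow(truth$tads))) {
      in_tad <- in_tad |
        (b1 >= truth$tads$start_bin[r] & b2 < truth$tads$end_bin[r])
    }
    mu[in_tad] <- mu[in_tad] * config$tad_boost
  }
  if (nrow(truth$loops) > 0L) {
    is_loop <- pair_key(pairs) %in% pair_key(truth$loops)
    mu[is_loop] <- mu[is_loop] * config$loop_boost
  }
  with_seed(seed + 2L, {
    noise <- rnorm(length(mu), 0, 1) * config$dispersion * sqrt(mu)
    count <- pmax(mu + noise, 0)
    measured <- runif(length(mu)) < config$coverage
    contact_table(
      pairs |> mutate(count = count, measured = measured),
      resolution = res
    )
  })
}

#' Simulate signed motif calls
#'
#' Plants a convergent motif pair (forward strand at the R1 anchor, reverse
#' at R2, purity in \[0.9, 1\]) at every ground-truth loop, plus uniformly
#' scattered decoy motifs with random strand and purity in \[0.5, 1\].
#'
#' @param config A [sim_config()].
#' @param truth A `sim_truth`.
#' @param seed Integer seed.
#' @return Motif tibble in the [read_motif_bed()] layout.
#' @export
simulate_motifs <- function(config, truth, seed = 1) {
  res <- config$resolution
  with_seed(seed + 3L, {
    anchor_motif <- function(start_bp, strand) {
      offset <- sample(seq(10, res - 30), length(start_bp), replace = TRUE)
      tibble(
        chrom = config$chrom,
        start = start_bp + offset,
        end = start_bp + offset + 19,
        name = "CTCF",
        purity = runif(length(start_bp), 0.9, 1),
        strand = strand
      )
    }
    planted <- bind_rows(
      anchor_motif(truth$loops$start1, "+"),
      anchor_motif(truth$loops$start2, "-")
    )
    n_decoys <- rbinom(1L, config$n_bins * 10L, config$motif_decoy_rate / 10)
    decoys <- tibble(
      chrom = config$chrom,
      start = sample(seq_len(config$n_bins * res - 30), n_decoys),
      name = "CTCF",
      purity = runif(n_decoys, 0.5, 1),
      strand = sample(c("+", "-"), n_decoys, replace = TRUE)
    ) |>
      mutate(end = .data$start + 19, .after = "start")
    bind_rows(planted, decoys) |> arrange(.data$start)
  })
}

#' Simulate an external validation interaction set
#'
#' A stand-in for a ChIA-PET or 5C experiment: each planted loop is
#' recovered independently with probability `recall`, and
#' `round(fpr * loop_n)` false pairs drawn from non-loop pairs are added.
#'
#' @param config A [sim_config()].
#' @param truth A `sim_truth`.
#' @param recall Per-loop recovery probability.
#' @param fpr False pairs as a fraction of the planted loop count.
#' @param seed Integer seed.
#' @return Pair tibble (`chrom`, `start1`, `start2`) with a `provenance`
#'   attribute `"synthetic external"`.
#' @export
simulate_external_set <- function(config, truth, recall = 0.8, fpr = 0.2,
                                  seed = 1) {
  stopifnot(recall >= 0, recall <= 1, fpr >= 0)
  res <- config$resolution
  with_seed(seed + 4L, {
    keep <- runif(nrow(truth$loops)) < recall
    hits <- truth$loops[keep, ]
    n_false <- round(fpr * nrow(truth$loops))
    false <- tibble(
      b1 = sample(config$n_bins - config$loop_distance[1L], n_false * 2L,
                  replace = TRUE),
      gap = sample(
        seq(config$loop_distance[1L], config$loop_distance[2L]),
        n_false * 2L, replace = TRUE
      )
    ) |>
      transmute(
        chrom = config$chrom,
        start1 = (.data$b1 - 1) * res,
        start2 = (.data$b1 + .data$gap - 1) * res
      ) |>
      filter(.data$start2 < config$n_bins * res) |>
      anti_join(truth$loops, by = c("chrom", "start1", "start2")) |>
      distinct() |>
      head(n_false)
    out <- bind_rows(hits, false) |> arrange(.data$start1, .data$start2)
    attr(out, "provenance") <- "synthetic external"
    out
  })
}

#' Simulate a complete study
#'
#' One call producing everything the pipeline consumes: correlated signal
#' tracks for every cell line, a contact table per requested cell line,
#' signed motifs, an external validation set, and the ground truth.
#'
#' @param config A [sim_config()].
#' @param cells Cell lines to generate contact tables for (default: the
#'   first one).
#' @param seed Integer seed.
#' @return List of class `sim_study` with `signals`, `contacts` (named list
#'   of contact tables), `motifs`, `external`, `truth`, `bins`, `config`.
#' @export
simulate_hic_study <- function(config = sim_config(),
                               cells = config$cells[1L], seed = 1) {
  truth <- simulate_truth(config, seed = seed)
  signals <- simulate_signals(config, truth = truth, seed = seed)
  contacts <- lapply(seq_along(cells), function(i) {
    simulate_contacts(config, signals, truth, cells[i], seed = seed + 10L * i)
  })
  names(contacts) <- cells
  bins <- tibble(
    chrom = config$chrom,
    start = (seq_len(config$n_bins) - 1) * config$resolution
  )
  attr(bins, "resolution") <- config$resolution
  structure(
    list(
      signals = signals,
      contacts = contacts,
      motifs = simulate_motifs(config, truth, seed = seed),
      external = simulate_external_set(config, truth, seed = seed),
      truth = truth,
      bins = bins,
      config = config
    ),
    class = "sim_study"
  )
}
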