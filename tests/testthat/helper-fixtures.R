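# Shared fixture builders and independent oracles.

# A random contact table on n contiguous bins of one chromosome.
random_contact_table <- function(n_bins = 20, resolution = 5000,
                                 max_dist = 10, seed = 1) {
  bins <- bin_genome(setNames(n_bins * resolution, "chrT"), resolution)
  pairs <- enumerate_pairs(bins, max_dist)
  withr::with_seed(seed, {
    contact_table(
      dplyr::mutate(pairs, count = round(runif(nrow(pairs), 0, 50), 3)),
      resolution = resolution
    )
  })
}

# Brute-force double-loop pair enumeration (the oracle for enumerate_pairs).
brute_force_pairs <- function(starts, max_dist, resolution) {
  out <- list()
  n <- length(starts)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && (j - i) <= max_dist) {
        out[[length(out) + 1L]] <- c(starts[i], starts[j])
      }
    }
  }
  do.call(rbind, out)
}

# Independent path-feature tally: route every example to its leaf with
# ranger's own terminal-node prediction, then walk the stored tree
# structure from the root to that leaf and record the split features.
# Used as the oracle for decision_paths()/usage_importance().
oracle_path_tally <- function(forest, newdata) {
  df <- as.data.frame(newdata[, forest$feature_names, drop = FALSE])
  term <- predict(
    forest$ranger, df,
    type = "terminalNodes", num.threads = 1L
  )$predictions
  total <- 0L
  counts <- integer(0)
  for (t in seq_len(forest$trees)) {
    ti <- ranger::treeInfo(forest$ranger, t)
    parent <- integer(nrow(ti))
    internal <- which(!ti$terminal)
    parent[ti$leftChild[internal] + 1L] <- ti$nodeID[internal] + 1L
    parent[ti$rightChild[internal] + 1L] <- ti$nodeID[internal] + 1L
    parent[1L] <- 0L
    for (i in seq_len(nrow(df))) {
      node <- term[i, t] + 1L
      while (node != 1L) {
        node <- parent[node]
        f <- ti$splitvarName[node]
        counts[f] <- (if (is.na(counts[f])) 0L else counts[f]) + 1L
        total <- total + 1L
      }
    }
  }
  list(counts = counts, total = total)
}

# A small multi-cell signal fixture: `n_ds` datasets x `cells` on n_bins.
toy_signals <- function(n_bins = 12, resolution = 5000, n_ds = 3,
                        cells = c("cellA", "cellB"), seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(
      start = (seq_len(n_bins) - 1) * resolution,
      dataset = sprintf("d%02d", seq_len(n_ds)),
      cell = cells,
      stringsAsFactors = FALSE
    )
    tibble::tibble(
      chrom = "chrT",
      start = grid$start,
      dataset = grid$dataset,
      cell = grid$cell,
      value = round(runif(nrow(grid), 0.1, 10), 4)
    )
  })
}
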