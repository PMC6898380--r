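#' Out-of-bag permutation importance
#'
#' For every feature, its column is permuted and the increase in per-tree
#' out-of-bag mean squared error (relative to the unpermuted baseline) is
#' averaged over trees. Features the forest never consults score about zero;
#' the permutation is seeded, so scores are reproducible.
#'
#' @param forest A `hicreg_forest` trained with its bootstrap bookkeeping
#'   (the default).
#' @param x The training feature table (same rows the forest was trained on).
#' @param y The training response.
#' @param seed Integer seed for the permutations.
#' @return Tibble `(feature, importance)` sorted by decreasing importance.
#' @export
oob_importance <- function(forest, x, y, seed = 1) {
  df <- forest_frame(x, forest$feature_names)
  n <- nrow(df)
  if (n != length(y) || n != forest$n_train) {
    stop_arg("`x`/`y` must be the forest's training data")
  }
  inbag <- forest$ranger$inbag.counts
  oob_sets <- lapply(inbag, function(cnt) which(cnt == 0L))
  per_tree_mse <- function(data) {
    preds <- predict(
      forest$ranger, data,
      num.threads = 1L, predict.all = TRUE
    )$predictions
    vapply(seq_along(oob_sets), function(t) {
      idx <- oob_sets[[t]]
      if (length(idx) == 0L) return(NA_real_)
      mean((preds[idx, t] - y[idx])^2)
    }, numeric(1L))
  }
  base <- per_tree_mse(df)
  scores <- vapply(seq_along(forest$feature_names), function(j) {
    perm <- with_seed(seed + j, sample(n))
    dperm <- df
    dperm[[j]] <- df[[j]][perm]
    mean(per_tree_mse(dperm) - base, na.rm = TRUE)
  }, numeric(1L))
  tibble(feature = forest$feature_names, importance = scores) |>
    arrange(desc(.data$importance))
}

#' Usage-count feature importance
#'
#' The importance of a feature is the total number of times it appears on
#' the root-to-leaf path of any test example in any tree -- an exact integer
#' tally over [decision_paths()] output, conventionally computed on the
#' hard test pairs.
#'
#' @param paths Tibble from [decision_paths()].
#' @param features Optional full feature list; features never used get an
#'   explicit zero count.
#' @return Tibble `(feature, count)` sorted by decreasing count.
#' @export
usage_importance <- function(paths, features = NULL) {
  check_columns(paths, "feature", "paths")
  out <- paths |>
    count(.data$feature, name = "count") |>
    arrange(desc(.data$count), .data$feature)
  if (!is.null(features)) {
    out <- tibble(feature = features) |>
      left_join(out, by = "feature") |>
      mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) |>
      arrange(desc(.data$count), .data$feature)
  }
  out
}

#' Pairwise feature co-occurrence on decision paths
#'
#' Counts, for each test example, how often an unordered pair of distinct
#' features co-occurs on a root-to-leaf path, summed over trees: a path
#' contributes one count per pair of path positions holding different
#' features (so a path `A, A, B` yields count 2 for the pair `A|B`).
#' Rows are restricted to the examples with the lowest `top_fraction` of
#' absolute prediction error, the subset on which per-pair feature analysis
#' is run.
#'
#' @param paths Tibble from [decision_paths()].
#' @param errors Numeric vector of prediction errors, indexed by the
#'   `example` ids appearing in `paths` (absolute values are taken).
#' @param top_fraction Fraction of lowest-|error| examples kept, in (0, 1].
#' @return An integer matrix of class `usage_matrix`: rows = selected
#'   examples (rownames are example ids), columns = feature pairs named
#'   `"f|g"` with f < g alphabetically.
#' @export
pairwise_usage <- function(paths, errors, top_fraction = 0.05) {
  check_columns(paths, c("example", "tree", "feature"), "paths")
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    stop_arg("`top_fraction` must lie in (0, 1]")
  }
  examples <- sort(unique(paths$example))
  err <- abs(errors[examples])
  n_keep <- max(1L, ceiling(top_fraction * length(examples)))
  keep <- examples[order(err, examples)][seq_len(n_keep)]
  occ <- paths |>
    filter(.data$example %in% keep) |>
    count(.data$example, .data$tree, .data$feature, name = "n_occ")
  pairs <- occ |>
    inner_join(occ, by = c("example", "tree"), relationship = "many-to-many") |>
    filter(.data$feature.x < .data$feature.y) |>
    mutate(count = .data$n_occ.x * .data$n_occ.y) |>
    group_by(.data$example, f1 = .data$feature.x, f2 = .data$feature.y) |>
    summarise(count = sum(.data$count), .groups = "drop")
  col_names <- sort(unique(paste(pairs$f1, pairs$f2, sep = "|")))
  mat <- matrix(
    0L, nrow = length(keep), ncol = length(col_names),
    dimnames = list(as.character(sort(keep)), col_names)
  )
  if (nrow(pairs) > 0L) {
    mat[cbind(
      match(as.character(pairs$example), rownames(mat)),
      match(paste(pairs$f1, pairs$f2, sep = "|"), col_names)
    )] <- pairs$count
  }
  structure(mat,
    class = c("usage_matrix", class(mat)),
    selection = sprintf("lowest %.0f%% absolute error", 100 * top_fraction)
  )
}

nmf_objective <- function(x, u, v) {
  sum((x - u %*% v)^2)
}

# One block-coordinate sweep of alternating non-negative least squares:
# each factor column is minimized exactly in closed form under the
# non-negativity constraint, so the objective can never increase.
nmf_sweep <- function(x, u, v, eps = 1e-12) {
  xvt <- x %*% t(v)
  vvt <- v %*% t(v)
  for (c in seq_len(ncol(u))) {
    num <- xvt[, c] - u %*% vvt[, c] + u[, c] * vvt[c, c]
    u[, c] <- pmax(0, num / max(vvt[c, c], eps))
  }
  utx <- t(u) %*% x
  utu <- t(u) %*% u
  for (c in seq_len(nrow(v))) {
    num <- utx[c, ] - utu[c, ] %*% v + utu[c, c] * v[c, ]
    v[c, ] <- pmax(0, num / max(utu[c, c], eps))
  }
  list(u = u, v = v)
}

#' Non-negative matrix factorization bi-clustering
#'
#' Factorizes a non-negative usage matrix `X ~ U V` (`U`: examples-by-k,
#' `V`: k-by-feature-pairs) by alternating non-negative least squares with
#' block coordinate descent, so the squared reconstruction error is
#' non-increasing over iterations. Ten random restarts are run and the
#' factorization with the lowest objective kept. Rows of U are normalized
#' to sum to one and columns of V to sum to one; examples and feature pairs
#' are assigned to the cluster of their largest normalized loading, ties
#' broken by the lowest cluster index.
#'
#' @param x Non-negative matrix (e.g. from [pairwise_usage()]); all-zero
#'   rows must be filtered out beforehand.
#' @param k Number of factors (default 5).
#' @param seed Integer seed for the restarts.
#' @param max_iter Maximum sweeps per restart.
#' @param tol Relative objective-change convergence threshold.
#' @param n_restarts Number of random restarts (default 10).
#' @return Object of class `hicreg_nmf` with elements `u`, `v`, `u_norm`,
#'   `v_norm`, `row_cluster`, `col_cluster`, `objective` (trace of the best
#'   restart), `converged`, `k`.
#' @export
nmf_bicluster <- function(x, k = 5, seed = 1, max_iter = 500, tol = 1e-10,
                          n_restarts = 10) {
  x <- as.matrix(x)
  if (any(x < 0)) {
    stop_arg("`x` must be non-negative")
  }
  if (k > min(dim(x))) {
    stop_arg("`k` (%d) exceeds the smallest matrix dimension (%d)", k, min(dim(x)))
  }
  if (any(rowSums(x) == 0)) {
    stop_arg("`x` contains all-zero rows; filter them before factorizing")
  }
  best <- NULL
  scale0 <- sqrt(mean(x) / k)
  for (r in seq_len(n_restarts)) {
    u <- with_seed(seed + r, matrix(runif(nrow(x) * k), nrow(x), k)) * scale0
    v <- with_seed(seed + 1000L + r, matrix(runif(k * ncol(x)), k, ncol(x))) * scale0
    obj <- nmf_objective(x, u, v)
    trace <- obj
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      sw <- nmf_sweep(x, u, v)
      u <- sw$u
      v <- sw$v
      obj_new <- nmf_objective(x, u, v)
      trace <- c(trace, obj_new)
      if (abs(obj - obj_new) <= tol * max(obj, 1e-300)) {
        converged <- TRUE
        obj <- obj_new
        break
      }
      obj <- obj_new
    }
    if (is.null(best) || obj < best$objective_final) {
      best <- list(
        u = u, v = v, objective = trace,
        objective_final = obj, converged = converged
      )
    }
  }
  u <- best$u
  v <- best$v
  rownames(u) <- rownames(x)
  colnames(v) <- colnames(x)
  row_sums <- rowSums(u)
  col_sums <- colSums(v)
  u_norm <- u / ifelse(row_sums > 0, row_sums, 1)
  v_norm <- sweep(v, 2L, ifelse(col_sums > 0, col_sums, 1), "/")
  structure(
    list(
      u = u, v = v, u_norm = u_norm, v_norm = v_norm,
      row_cluster = max.col(u_norm, ties.method = "first"),
      col_cluster = max.col(t(v_norm), ties.method = "first"),
      objective = best$objective,
      converged = best$converged,
      k = k, seed = seed
    ),
    class = "hicreg_nmf"
  )
}

#' @export
print.hicreg_nmf <- function(x, ...) {
  cat(sprintf(
    "NMF bi-clustering: k = %d, final objective %.4g (%s)\n",
    x$k, tail(x$objective, 1L),
    if (x$converged) "converged" else "max iterations reached"
  ))
  invisible(x)
}

#' Marginal pair counts of a usage matrix
#'
#' Column sums of a [pairwise_usage()] matrix, unpacked into an edge list.
#'
#' @param x A `usage_matrix` (or any matrix with `"f|g"` column names).
#' @param columns Optional subset of columns (e.g. the feature pairs of one
#'   NMF cluster).
#' @return Tibble `(feature1, feature2, count)`.
#' @export
pair_counts <- function(x, columns = NULL) {
  if (!is.null(columns)) x <- x[, columns, drop = FALSE]
  totals <- colSums(x)
  parts <- strsplit(names(totals), "|", fixed = TRUE)
  tibble(
    feature1 = vapply(parts, `[[`, "", 1L),
    feature2 = vapply(parts, `[[`, "", 2L),
    count = as.numeric(totals)
  ) |>
    filter(.data$count > 0) |>
    arrange(desc(.data$count))
}

#' Feature co-occurrence network
#'
#' Builds the node/edge representation of pairwise feature usage: edges are
#' weighted by the pair co-occurrence count, node size is the feature's
#' marginal co-occurrence count (the sum of its incident edge weights).
#' Optionally only the heaviest `top_edges` edges are kept (node sizes are
#' computed on the supplied counts before filtering).
#'
#' @param counts Tibble `(feature1, feature2, count)` from [pair_counts()].
#' @param top_edges Number of heaviest edges to keep (default all). Ties at
#'   the cutoff are broken alphabetically for determinism.
#' @return List of class `cooccurrence_network` with `nodes`
#'   (`feature`, `size`) and `edges` (`from`, `to`, `weight`).
#' @export
cooccurrence_network <- function(counts, top_edges = Inf) {
  check_columns(counts, c("feature1", "feature2", "count"), "counts")
  sizes <- tibble(
    feature = c(counts$feature1, counts$feature2),
    w = rep(counts$count, 2L)
  ) |>
    group_by(.data$feature) |>
    summarise(size = sum(.data$w), .groups = "drop")
  edges <- counts |>
    arrange(desc(.data$count), .data$feature1, .data$feature2) |>
    head(n = if (is.finite(top_edges)) top_edges else nrow(counts)) |>
    select(from = "feature1", to = "feature2", weight = "count")
  nodes <- sizes |>
    filter(.data$feature %in% c(edges$from, edges$to)) |>
    arrange(desc(.data$size))
  structure(
    list(nodes = nodes, edges = edges),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "Feature co-occurrence network: %d nodes, %d edges\n",
    nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Write a network in simple-interaction format
#'
#' One line per edge: `from<TAB>co-occurs<TAB>to`, the plain-text graph
#' format Cytoscape and friends import directly.
#'
#' @param network A `cooccurrence_network`.
#' @param path Output file.
#' @export
write_sif <- function(network, path) {
  writeLines(
    sprintf("%s\tco-occurs\t%s", network$edges$from, network$edges$to),
    path
  )
  invisible(path)
}
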