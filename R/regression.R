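#' Randomly partition regions into cross-validation folds
#'
#' Regions (bins), not pairs, are the cross-validation unit: pairs with both
#' ends in the held-out region set share no region with any training pair
#' and are therefore "hard" test examples by construction.
#'
#' @param bins Bin tibble (`chrom`, `start`).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return The bins with an integer `fold` column.
#' @export
split_regions_cv <- function(bins, n_folds = 5, seed = 1) {
  check_columns(bins, c("chrom", "start"), "bins")
  n <- nrow(bins)
  if (n < n_folds) {
    stop_arg("need at least %d bins for %d folds", n_folds, n_folds)
  }
  out <- bins
  out$fold <- unsplit(
    lapply(split(seq_len(n), bins$chrom), function(idx) {
      with_seed(seed, sample(rep(seq_len(n_folds), length.out = length(idx))))
    }),
    bins$chrom
  )
  out
}

forest_frame <- function(x, features = NULL) {
  if (is.matrix(x)) x <- as_tibble(x)
  features <- features %||% feature_names(x)
  missing <- setdiff(features, names(x))
  if (length(missing) > 0L) {
    stop_arg(
      "feature column(s) absent from the data: %s",
      paste(missing, collapse = ", ")
    )
  }
  as.data.frame(x[, features, drop = FALSE])
}

#' Train a random-forest count regressor
#'
#' An ensemble of `trees` regression trees, each grown on a bootstrap sample
#' with a random subset of `ceiling(mtry_fraction * P)` candidate features
#' at every split (variance reduction split criterion). The fitted object
#' retains the per-tree bootstrap counts and the full tree structure, so
#' out-of-bag importance and per-example decision paths can be recomputed
#' exactly.
#'
#' @param x Feature table ([encode_pairs()] output, or any data frame whose
#'   model columns are listed in a `feature_names` attribute / all columns).
#' @param y Numeric response (contact counts), one per row of `x`.
#' @param trees Number of trees (default 20).
#' @param mtry_fraction Fraction of features tried per split (default 1/3).
#' @param min_leaf Minimum node size before splitting stops (default 5).
#' @param seed Integer seed; the same seed gives an identical forest.
#' @return An object of class `hicreg_forest`.
#' @export
train_forest <- function(x, y, trees = 20, mtry_fraction = 1 / 3,
                         min_leaf = 5, seed = 1) {
  df <- forest_frame(x)
  if (nrow(df) != length(y)) {
    stop_arg("`x` has %d rows but `y` has %d values", nrow(df), length(y))
  }
  if (nrow(df) < 2L) {
    stop_arg("need at least 2 training examples")
  }
  p <- ncol(df)
  fit <- ranger::ranger(
    x = df, y = y,
    num.trees = trees,
    mtry = max(1L, ceiling(mtry_fraction * p)),
    min.node.size = min_leaf,
    seed = seed,
    num.threads = 1L,
    keep.inbag = TRUE
  )
  structure(
    list(
      ranger = fit,
      feature_names = names(df),
      trees = trees,
      mtry_fraction = mtry_fraction,
      min_leaf = min_leaf,
      seed = seed,
      n_train = nrow(df)
    ),
    class = "hicreg_forest"
  )
}

#' @export
print.hicreg_forest <- function(x, ...) {
  cat(sprintf(
    "Random-forest count regressor: %d trees, %d features, %d training pairs\n",
    x$trees, length(x$feature_names), x$n_train
  ))
  cat(sprintf("  OOB mean squared error: %.4g\n", x$ranger$prediction.error))
  invisible(x)
}

#' Predict contact counts
#'
#' The forest prediction is the mean of the per-tree leaf means.
#'
#' @param object A `hicreg_forest`.
#' @param newdata Feature table with the forest's feature columns.
#' @param per_tree Return the n-by-T matrix of per-tree predictions instead
#'   of their mean.
#' @param ... Unused.
#' @return Numeric vector of predicted counts (or a matrix if `per_tree`).
#' @export
predict.hicreg_forest <- function(object, newdata, per_tree = FALSE, ...) {
  df <- forest_frame(newdata, object$feature_names)
  pred <- predict(
    object$ranger, df,
    num.threads = 1L, predict.all = per_tree
  )$predictions
  pred
}

#' Root-to-leaf decision paths of test examples
#'
#' For every example and every tree, the sequence of split features visited
#' from the root to the leaf (with repetition, in root-to-leaf order). This
#' is the raw material for the usage-count and pairwise co-occurrence
#' importance analyses.
#'
#' @param forest A `hicreg_forest`.
#' @param newdata Feature table.
#' @return Tibble with columns `example`, `tree`, `depth`, `feature`; one
#'   row per internal node visited. Examples routed straight to a leaf
#'   (depth-0 trees) contribute no rows.
#' @export
decision_paths <- function(forest, newdata) {
  df <- forest_frame(newdata, forest$feature_names)
  xmat <- as.matrix(df)
  n <- nrow(xmat)
  out <- vector("list", forest$trees)
  for (t in seq_len(forest$trees)) {
    ti <- ranger::treeInfo(forest$ranger, t)
    left <- ti$leftChild + 1L
    right <- ti$rightChild + 1L
    split_var <- match(ti$splitvarName, forest$feature_names)
    split_val <- ti$splitval
    terminal <- ti$terminal
    node <- rep(1L, n)
    active <- which(!terminal[node])
    depth <- 0L
    rows <- list()
    while (length(active) > 0L) {
      depth <- depth + 1L
      nd <- node[active]
      f <- split_var[nd]
      rows[[depth]] <- tibble(
        example = active, tree = t, depth = depth,
        feature = forest$feature_names[f]
      )
      go_left <- xmat[cbind(active, f)] <= split_val[nd]
      node[active] <- ifelse(go_left, left[nd], right[nd])
      active <- active[!terminal[node[active]]]
    }
    out[[t]] <- list_rbind(rows)
  }
  empty <- tibble(
    example = integer(), tree = integer(), depth = integer(),
    feature = character()
  )
  bind_rows(empty, list_rbind(out)) |>
    arrange(.data$example, .data$tree, .data$depth)
}

#' Region-held-out cross-validated prediction
#'
#' Bins are partitioned into `n_folds` region sets; for each fold a forest
#' is trained on all measured pairs with both ends in the training regions
#' and predicts the measured pairs with both ends in the held-out set (hard
#' pairs -- they share no region with the training data). Predictions from
#' the five folds are concatenated, so each hard pair is predicted exactly
#' once.
#'
#' @param table A [contact_table()] of measured training counts.
#' @param signals Long signal tibble for the encoding (not needed for
#'   `mode = "distance"`).
#' @param mode Feature encoding passed to [encode_pairs()].
#' @param cell,exclude_cells Passed to [encode_pairs()].
#' @param bins Bin tibble; defaults to the grid spanned by `signals` (or by
#'   the contact table for the distance-only mode).
#' @param max_distance_bins Pair radius in bins (default 200: 1 Mb at 5 kb).
#' @param n_folds,trees,mtry_fraction,min_leaf Model settings.
#' @param max_train_pairs Optional cap on training pairs per fold; when
#'   exceeded, a distance-preserving subsample of this size is used.
#' @param include_easy Also predict "easy" mixed pairs (one end held out,
#'   assigned to the fold holding out R1); they are flagged `hard = FALSE`
#'   and excluded from headline metrics.
#' @param seed Integer seed controlling the fold split, subsampling and the
#'   per-fold forests.
#' @return An object of class `hicreg_cv`: a list with `predictions` (one
#'   row per predicted pair: true `count`, `predicted`, `fold`, `hard`),
#'   `models` (the per-fold forests) and the run configuration.
#' @export
run_cv <- function(table, signals = NULL,
                   mode = c("window", "pair", "multicell", "distance"),
                   cell = NULL, exclude_cells = NULL, bins = NULL,
                   max_distance_bins = 200, n_folds = 5, trees = 20,
                   mtry_fraction = 1 / 3, min_leaf = 5,
                   max_train_pairs = Inf, include_easy = FALSE, seed = 1) {
  mode <- match.arg(mode)
  res <- contact_resolution(table)
  if (is.null(bins)) {
    bins <- if (!is.null(signals)) {
      distinct(signals[, c("chrom", "start")]) |> arrange(.data$chrom, .data$start)
    } else {
      tibble(
        chrom = table$chrom[[1L]],
        start = seq(0, max(table$start2), by = res)
      )
    }
    attr(bins, "resolution") <- res
  }
  folds <- split_regions_cv(bins, n_folds = n_folds, seed = seed)
  pairs <- enumerate_pairs(bins, max_distance_bins, resolution = res)
  measured <- pairs |>
    inner_join(
      as_tibble(table) |> filter(.data$measured) |>
        select("chrom", "start1", "start2", "count"),
      by = c("chrom", "start1", "start2")
    )
  n_unmatched <- sum(table$measured) - nrow(measured)
  if (n_unmatched > 0L) {
    inform(sprintf(
      "%d measured pair(s) fall outside the bin grid or radius and were dropped",
      n_unmatched
    ))
  }
  fold_of <- setNames(folds$fold, paste(folds$chrom, folds$start))
  f1 <- unname(fold_of[paste(measured$chrom, measured$start1)])
  f2 <- unname(fold_of[paste(measured$chrom, measured$start2)])
  models <- vector("list", n_folds)
  preds <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    train_idx <- which(f1 != k & f2 != k)
    test_idx <- which(f1 == k & f2 == k)
    hard <- rep(TRUE, length(test_idx))
    if (include_easy) {
      easy_idx <- which(f1 == k & f2 != k)
      hard <- c(hard, rep(FALSE, length(easy_idx)))
      test_idx <- c(test_idx, easy_idx)
    }
    if (length(train_idx) < 2L || length(test_idx) == 0L) {
      stop_arg("fold %d has too few training or test pairs", k)
    }
    if (length(train_idx) > max_train_pairs) {
      keep <- stratified_subsample_idx(
        measured$distance_bins[train_idx], max_train_pairs, seed + 100L + k
      )
      train_idx <- train_idx[keep]
    }
    x_train <- encode_pairs(
      measured[train_idx, ], signals,
      mode = mode, cell = cell, exclude_cells = exclude_cells
    )
    x_test <- encode_pairs(
      measured[test_idx, ], signals,
      mode = mode, cell = cell, exclude_cells = exclude_cells
    )
    models[[k]] <- train_forest(
      x_train, measured$count[train_idx],
      trees = trees, mtry_fraction = mtry_fraction,
      min_leaf = min_leaf, seed = seed + k
    )
    preds[[k]] <- measured[test_idx, ] |>
      mutate(
        predicted = predict(models[[k]], x_test),
        fold = k, hard = hard
      )
  }
  structure(
    list(
      predictions = list_rbind(preds),
      models = models,
      folds = folds,
      mode = mode,
      resolution = res,
      n_folds = n_folds,
      seed = seed
    ),
    class = "hicreg_cv"
  )
}

#' @export
print.hicreg_cv <- function(x, ...) {
  cat(sprintf(
    "Region-held-out CV (%d folds, %s encoding): %d predicted pairs (%d hard)\n",
    x$n_folds, x$mode, nrow(x$predictions), sum(x$predictions$hard)
  ))
  invisible(x)
}

#' Transfer fold models to a new chromosome or cell line
#'
#' Every target pair gets one prediction per fold model; the final predicted
#' count is their average. Used unchanged for cross-chromosome and
#' cross-cell-line prediction.
#'
#' @param models List of `hicreg_forest` fold models (>= 1).
#' @param x_target Encoded feature table for the target pairs, with the same
#'   feature schema the models were trained on.
#' @return Numeric vector of averaged predictions.
#' @export
predict_transfer <- function(models, x_target) {
  if (!is.list(models) || length(models) < 1L) {
    stop_arg("`models` must contain at least one forest")
  }
  per_model <- vapply(
    models, function(m) predict(m, x_target),
    numeric(nrow(x_target))
  )
  rowMeans(as.matrix(per_model))
}

#' Average predictions across training cell lines
#'
#' The cross-cell ensemble: element-wise mean of the prediction vectors
#' obtained from models trained on each available training cell line.
#'
#' @param predictions List of equal-length numeric prediction vectors.
#' @return Numeric vector of ensemble predictions.
#' @export
ensemble_average <- function(predictions) {
  if (!is.list(predictions) || length(predictions) < 1L) {
    stop_arg("`predictions` must be a non-empty list")
  }
  lens <- lengths(predictions)
  if (length(unique(lens)) != 1L) {
    stop_arg("prediction vectors have unequal lengths")
  }
  rowMeans(vapply(predictions, identity, numeric(lens[[1L]])))
}

#' Distance-only baseline
#'
#' A random forest trained on the single `Distance` column, in the same
#' region-held-out CV protocol; the reference that any signal-driven model
#' must beat.
#'
#' @inheritParams run_cv
#' @param ... Passed on to [run_cv()].
#' @return A `hicreg_cv` object.
#' @export
baseline_distance_only <- function(table, bins = NULL, seed = 1, ...) {
  run_cv(table, signals = NULL, mode = "distance", bins = bins, seed = seed, ...)
}

#' Count-transfer baseline
#'
#' Copies the source cell line's measured count onto every target pair at
#' identical coordinates; target pairs absent from the source are returned
#' unmeasured (`NA` prediction).
#'
#' @param source A [contact_table()] from the training cell line.
#' @param target_pairs Pair tibble (`chrom`, `start1`, `start2`).
#' @param resolution Resolution of the target pairs; must match the source.
#' @return `target_pairs` with a `predicted` column.
#' @export
baseline_transfer_count <- function(source, target_pairs,
                                    resolution = contact_resolution(source)) {
  if (resolution != contact_resolution(source)) {
    stop_arg("source and target resolutions differ")
  }
  target_pairs |>
    left_join(
      as_tibble(source) |> filter(.data$measured) |>
        select("chrom", "start1", "start2", predicted = "count"),
      by = c("chrom", "start1", "start2")
    )
}

#' Ordinary least-squares baseline
#'
#' Linear regression on the same feature columns the forest sees.
#'
#' @param x Feature table.
#' @param y Numeric response.
#' @return Object of class `hicreg_linear` with `coefficients` (including
#'   the intercept) and a [predict()] method.
#' @export
baseline_linear <- function(x, y) {
  df <- forest_frame(x)
  mm <- cbind(`(Intercept)` = 1, as.matrix(df))
  fit <- lm.fit(mm, y)
  structure(
    list(coefficients = fit$coefficients, feature_names = names(df)),
    class = "hicreg_linear"
  )
}

#' @export
predict.hicreg_linear <- function(object, newdata, ...) {
  df <- forest_frame(newdata, object$feature_names)
  mm <- cbind(1, as.matrix(df))
  drop(mm %*% ifelse(is.na(object$coefficients), 0, object$coefficients))
}
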