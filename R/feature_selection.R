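mtg_objective <- function(xs, ys, w, lambda) {
  loss <- 0
  for (c in seq_along(xs)) {
    loss <- loss + 0.5 * sum((xs[[c]] %*% w[, c] - ys[[c]])^2)
  }
  loss + lambda * sum(sqrt(rowSums(w^2)))
}

row_soft_threshold <- function(w, thr) {
  norms <- sqrt(rowSums(w^2))
  shrink <- pmax(0, 1 - thr / pmax(norms, 1e-300))
  w * shrink
}

#' Multi-task group-lasso regression
#'
#' Jointly fits one linear model per task (cell line) under a row-wise
#' l1/l2 penalty: the objective is
#' `1/2 * sum_c ||X_c W[, c] - Y_c||^2 + lambda * sum_f ||W[f, ]||_2`,
#' minimized by proximal gradient descent (ISTA) with row-wise block
#' soft-thresholding. The penalty zeroes entire rows of W, so a feature is
#' either selected for all tasks or for none.
#'
#' Features are standardized (and responses centered) inside the solver by
#' default -- a group-lasso lambda grid is only meaningful on a common
#' scale -- and the weights are returned on the original scale.
#'
#' @param xs List of design matrices, one per task, sharing column names.
#' @param ys List of numeric responses matching `xs`.
#' @param lambda Non-negative regularization strength.
#' @param standardize Standardize features / center responses internally.
#' @param tol Relative objective-change convergence threshold.
#' @param max_iter Maximum proximal iterations.
#' @return Object of class `mtg_lasso`: `w` (features x tasks, original
#'   scale), `intercepts`, `support` (features with a nonzero row),
#'   `objective` (per-iteration trace, non-increasing), `converged`,
#'   `lambda`.
#' @export
fit_mtg_lasso <- function(xs, ys, lambda, standardize = TRUE,
                          tol = 1e-6, max_iter = 1e4) {
  if (!is.list(xs) || !is.list(ys) || length(xs) != length(ys)) {
    stop_arg("`xs` and `ys` must be lists of equal length")
  }
  if (lambda < 0) {
    stop_arg("`lambda` must be non-negative")
  }
  k <- length(xs)
  feats <- colnames(xs[[1L]]) %||% paste0("f", seq_len(ncol(xs[[1L]])))
  p <- length(feats)
  xs <- lapply(xs, function(x) {
    x <- as.matrix(x)
    if (ncol(x) != p) stop_arg("design matrices have differing feature sets")
    x
  })
  centers <- scales <- vector("list", k)
  y_means <- numeric(k)
  xs_s <- xs
  ys_s <- ys
  if (standardize) {
    for (c in seq_len(k)) {
      mu <- colMeans(xs[[c]])
      sdev <- apply(xs[[c]], 2L, sd)
      sdev[sdev == 0 | is.na(sdev)] <- 1
      xs_s[[c]] <- sweep(sweep(xs[[c]], 2L, mu), 2L, sdev, "/")
      ys_s[[c]] <- ys[[c]] - mean(ys[[c]])
      centers[[c]] <- mu
      scales[[c]] <- sdev
      y_means[c] <- mean(ys[[c]])
    }
  } else {
    for (c in seq_len(k)) {
      centers[[c]] <- rep(0, p)
      scales[[c]] <- rep(1, p)
    }
  }
  lip <- max(vapply(xs_s, function(x) norm(x, type = "2")^2, numeric(1L)))
  step <- 1 / max(lip, 1e-300)
  w <- matrix(0, p, k, dimnames = list(feats, names(xs)))
  obj <- mtg_objective(xs_s, ys_s, w, lambda)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    grad <- vapply(
      seq_len(k),
      function(c) drop(crossprod(xs_s[[c]], xs_s[[c]] %*% w[, c] - ys_s[[c]])),
      numeric(p)
    )
    w <- row_soft_threshold(w - step * grad, step * lambda)
    obj_new <- mtg_objective(xs_s, ys_s, w, lambda)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * max(abs(obj), 1e-300)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  if (!converged) {
    warn(sprintf("MTG-LASSO did not converge in %d iterations", max_iter))
  }
  w_orig <- w
  intercepts <- numeric(k)
  for (c in seq_len(k)) {
    w_orig[, c] <- w[, c] / scales[[c]]
    intercepts[c] <- (if (standardize) y_means[c] else 0) -
      sum(centers[[c]] * w_orig[, c])
  }
  structure(
    list(
      w = w_orig, w_std = w, intercepts = intercepts,
      support = feats[rowSums(w != 0) > 0],
      objective = trace, converged = converged,
      lambda = lambda, standardize = standardize
    ),
    class = "mtg_lasso"
  )
}

#' @export
print.mtg_lasso <- function(x, ...) {
  cat(sprintf(
    "Multi-task group lasso: lambda = %g, %d/%d features selected (%s)\n",
    x$lambda, length(x$support), nrow(x$w),
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' @export
predict.mtg_lasso <- function(object, xs, ...) {
  lapply(seq_along(xs), function(c) {
    drop(as.matrix(xs[[c]])[, rownames(object$w), drop = FALSE] %*%
      object$w[, c]) + object$intercepts[c]
  })
}

#' Regularization path with cross-validated AUC
#'
#' For each lambda on the grid, the group lasso is fitted on each of
#' `n_folds` row-folds per task; the reported support at that lambda is the
#' set of features selected in every fold, and predictive quality is the
#' mean (over folds and tasks) distance-stratified correlation AUC on the
#' held-out rows. The support size is non-increasing in lambda, and the
#' caller picks lambda at the AUC elbow.
#'
#' @param xs,ys As in [fit_mtg_lasso()].
#' @param distance_bins List of per-task distance vectors (bin units),
#'   aligned with the rows of `xs`, used for the stratified AUC.
#' @param lambda_grid Numeric grid (default 8 points log-spaced on
#'   \[0.01, 0.2\]).
#' @param n_folds Folds (default 5).
#' @param seed Integer seed for the fold split.
#' @param ... Passed to [fit_mtg_lasso()].
#' @return Tibble with one row per lambda: `lambda`, `support` (list column,
#'   the across-fold intersection), `fold_supports` (list of per-fold
#'   supports), `n_features`, `auc`.
#' @export
lambda_path <- function(xs, ys, distance_bins,
                        lambda_grid = exp(seq(log(0.01), log(0.2), length.out = 8)),
                        n_folds = 5, seed = 1, ...) {
  k <- length(xs)
  folds <- lapply(seq_len(k), function(c) {
    with_seed(seed + c, sample(rep(seq_len(n_folds), length.out = nrow(xs[[c]]))))
  })
  rows <- lapply(sort(lambda_grid), function(lam) {
    supports <- vector("list", n_folds)
    aucs <- numeric(0)
    for (f in seq_len(n_folds)) {
      xs_tr <- lapply(seq_len(k), function(c) xs[[c]][folds[[c]] != f, , drop = FALSE])
      ys_tr <- lapply(seq_len(k), function(c) ys[[c]][folds[[c]] != f])
      fit <- fit_mtg_lasso(xs_tr, ys_tr, lambda = lam, ...)
      supports[[f]] <- fit$support
      for (c in seq_len(k)) {
        te <- folds[[c]] == f
        pred <- drop(as.matrix(xs[[c]][te, , drop = FALSE]) %*% fit$w[, c]) +
          fit$intercepts[c]
        curve <- tryCatch(
          distance_stratified_correlation(tibble(
            count = ys[[c]][te], predicted = pred,
            distance_bins = distance_bins[[c]][te]
          )),
          error = function(e) NULL
        )
        if (!is.null(curve) && nrow(curve) >= 2L && any(curve$defined)) {
          aucs <- c(aucs, correlation_auc(curve))
        }
      }
    }
    tibble(
      lambda = lam,
      support = list(Reduce(intersect, supports)),
      fold_supports = list(supports),
      n_features = length(Reduce(intersect, supports)),
      auc = if (length(aucs) > 0) mean(aucs) else NA_real_
    )
  })
  list_rbind(rows)
}

#' Greedy random-forest refinement of a dataset set
#'
#' Starting from an initial dataset list, repeatedly picks (at random)
#' between adding and removing a dataset, retrains a random forest on a
#' distance-preserving 10% subsample of the training pairs for every
#' candidate move, and accepts the best move only if the held-out mean
#' squared error improves. Stops when no move improves or after `max_iter`
#' iterations. `Distance` is always kept.
#'
#' @param x_train,y_train Training feature table and response.
#' @param x_test,y_test Held-out feature table and response used to score
#'   candidate moves.
#' @param dataset_of Named character vector mapping every feature column to
#'   its dataset (`Distance` maps to `"Distance"`).
#' @param initial Character vector of starting datasets (non-empty).
#' @param subsample_fraction Training subsample per retrain (default 0.1).
#' @param trees,min_leaf Forest settings for candidate evaluation.
#' @param max_iter Maximum accepted/attempted iterations (default 20).
#' @param seed Integer seed.
#' @return List with `selected` (final dataset vector) and `trace` (one row
#'   per iteration: action, dataset, heldout error).
#' @export
greedy_refine <- function(x_train, y_train, x_test, y_test, dataset_of,
                          initial, subsample_fraction = 0.1,
                          trees = 20, min_leaf = 5, max_iter = 20, seed = 1) {
  if (length(initial) == 0L) {
    stop_arg("`initial` dataset set must be non-empty")
  }
  all_datasets <- setdiff(unique(dataset_of), "Distance")
  current <- setdiff(unique(initial), "Distance")
  cols_for <- function(datasets) {
    names(dataset_of)[dataset_of %in% c(datasets, "Distance")]
  }
  dist_tr <- x_train$Distance
  sub_idx <- stratified_subsample_idx(
    dist_tr, max(2L, round(subsample_fraction * nrow(x_train))), seed
  )
  score <- function(datasets, move_seed) {
    cols <- cols_for(datasets)
    fit <- train_forest(
      as_tibble(x_train)[sub_idx, cols, drop = FALSE], y_train[sub_idx],
      trees = trees, min_leaf = min_leaf, seed = move_seed
    )
    mean((predict(fit, as_tibble(x_test)[, cols, drop = FALSE]) - y_test)^2)
  }
  current_err <- score(current, seed)
  trace <- list(tibble(
    iter = 0L, action = "init", dataset = NA_character_, error = current_err
  ))
  for (it in seq_len(max_iter)) {
    action <- with_seed(seed + it, sample(c("add", "remove"), 1L))
    candidates <- if (action == "add") {
      setdiff(all_datasets, current)
    } else if (length(current) > 1L) {
      current
    } else {
      character()
    }
    if (length(candidates) == 0L) next
    errs <- vapply(candidates, function(d) {
      set <- if (action == "add") c(current, d) else setdiff(current, d)
      score(set, seed + it)
    }, numeric(1L))
    best <- which.min(errs)
    if (errs[best] < current_err) {
      d <- candidates[best]
      current <- if (action == "add") c(current, d) else setdiff(current, d)
      current_err <- errs[best]
      trace <- c(trace, list(tibble(
        iter = it, action = action, dataset = d, error = current_err
      )))
    } else {
      trace <- c(trace, list(tibble(
        iter = it, action = paste0("no-", action),
        dataset = NA_character_, error = current_err
      )))
    }
  }
  list(
    selected = c("Distance", sort(current)),
    trace = list_rbind(trace)
  )
}

#' Aggregate dataset selection frequencies into a final ranking
#'
#' Within each cell line, datasets are ranked by decreasing selection
#' frequency (ties broken alphabetically); ranks are averaged across cell
#' lines and the `top_k` best datasets returned. `Distance` is always
#' retained and does not consume a slot.
#'
#' @param reports Tibble `(cell, dataset, frequency)` with frequencies in
#'   \[0, 1\] (fraction of runs selecting the dataset).
#' @param top_k Number of datasets to keep.
#' @return Tibble `(dataset, avg_rank, selected)` sorted by average rank,
#'   with the chosen dataset vector (including `Distance`) in the
#'   `selected_datasets` attribute.
#' @export
rank_datasets <- function(reports, top_k) {
  check_columns(reports, c("cell", "dataset", "frequency"), "reports")
  ranked <- reports |>
    filter(.data$dataset != "Distance") |>
    group_by(.data$cell) |>
    arrange(desc(.data$frequency), .data$dataset, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    group_by(.data$dataset) |>
    summarise(avg_rank = mean(.data$rank), .groups = "drop") |>
    arrange(.data$avg_rank, .data$dataset) |>
    mutate(selected = row_number() <= top_k)
  attr(ranked, "selected_datasets") <-
    c("Distance", ranked$dataset[ranked$selected])
  ranked
}
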