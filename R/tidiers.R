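#' Tidy a fitted forest
#'
#' One row per feature with the number of splits using it across the
#' ensemble -- a quick training-side usage summary (the test-side analyses
#' live in [usage_importance()] and friends).
#'
#' @param x A `hicreg_forest`.
#' @param ... Unused.
#' @return Tibble `(feature, n_splits)`.
#' @export
tidy.hicreg_forest <- function(x, ...) {
  splits <- unlist(lapply(seq_len(x$trees), function(t) {
    ti <- ranger::treeInfo(x$ranger, t)
    ti$splitvarName[!ti$terminal]
  }))
  tibble(feature = x$feature_names) |>
    left_join(
      tibble(feature = splits) |> count(.data$feature, name = "n_splits"),
      by = "feature"
    ) |>
    mutate(n_splits = ifelse(is.na(.data$n_splits), 0L, .data$n_splits)) |>
    arrange(desc(.data$n_splits))
}

#' @export
glance.hicreg_forest <- function(x, ...) {
  tibble(
    trees = x$trees,
    n_features = length(x$feature_names),
    n_train = x$n_train,
    mtry_fraction = x$mtry_fraction,
    min_leaf = x$min_leaf,
    oob_mse = x$ranger$prediction.error,
    oob_r_squared = x$ranger$r.squared
  )
}

#' @export
tidy.hicreg_cv <- function(x, ...) {
  as_tibble(x$predictions)
}

#' @export
glance.hicreg_cv <- function(x, ...) {
  hard <- x$predictions |> filter(.data$hard)
  curve <- distance_stratified_correlation(hard)
  tibble(
    mode = x$mode,
    n_folds = x$n_folds,
    n_pairs = nrow(x$predictions),
    n_hard = nrow(hard),
    auc = correlation_auc(curve),
    overall_r = cor(hard$count, hard$predicted)
  )
}

#' @export
tidy.mtg_lasso <- function(x, ...) {
  as_tibble(x$w, rownames = "feature") |>
    pivot_longer(-"feature", names_to = "task", values_to = "estimate")
}

#' @export
glance.mtg_lasso <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    n_selected = length(x$support),
    iterations = length(x$objective) - 1L,
    objective = tail(x$objective, 1L),
    converged = x$converged
  )
}

#' @export
tidy.hicreg_nmf <- function(x, ...) {
  bind_rows(
    tibble(
      kind = "example",
      id = rownames(x$u) %||% as.character(seq_len(nrow(x$u))),
      cluster = x$row_cluster
    ),
    tibble(
      kind = "feature_pair",
      id = colnames(x$v) %||% as.character(seq_len(ncol(x$v))),
      cluster = x$col_cluster
    )
  )
}

#' @export
glance.hicreg_nmf <- function(x, ...) {
  tibble(
    k = x$k,
    objective = tail(x$objective, 1L),
    iterations = length(x$objective) - 1L,
    converged = x$converged
  )
}
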