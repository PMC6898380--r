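test_that("region folds partition bins and are seed-reproducible", {
  bins <- bin_genome(c(chrT = 100 * 5000), 5000)
  f1 <- split_regions_cv(bins, n_folds = 5, seed = 42)
  f2 <- split_regions_cv(bins, n_folds = 5, seed = 42)
  expect_identical(f1, f2)
  expect_equal(unname(table(f1$fold)), rep(20L, 5), ignore_attr = TRUE)
  expect_error(split_regions_cv(bins[1:3, ], n_folds = 5),
               class = "hicreg_argument_error")
})

test_that("cross-validated test pairs share no region with training pairs", {
  tab <- random_contact_table(n_bins = 60, max_dist = 15, seed = 2)
  bins <- bin_genome(c(chrT = 60 * 5000), 5000)
  cv <- run_cv(tab, mode = "distance", bins = bins, trees = 3, seed = 9)
  folds <- cv$folds
  for (k in seq_len(5)) {
    test_bins <- folds$start[folds$fold == k]
    train_bins <- folds$start[folds$fold != k]
    test_pairs <- cv$predictions |> dplyr::filter(fold == k)
    # exhaustive set-intersection oracle: hard pairs live entirely in the
    # held-out region set
    expect_true(all(test_pairs$start1 %in% test_bins))
    expect_true(all(test_pairs$start2 %in% test_bins))
    expect_false(any(c(test_pairs$start1, test_pairs$start2) %in% train_bins))
  }
})

test_that("forests are deterministic and recover simple generative structure", {
  withr::with_seed(5, {
    x <- tibble::tibble(a = runif(1000), b = runif(1000), c = runif(1000))
  })
  # constant response -> constant prediction
  f_const <- train_forest(x[1:50, ], rep(7, 50), trees = 5, seed = 1)
  expect_equal(unname(predict(f_const, x[1:10, ])), rep(7, 10))

  # step function of one feature: held-out R^2 > 0.95
  y <- ifelse(x$a > 0.5, 10, 0)
  fit <- train_forest(x[1:800, ], y[1:800], trees = 20, seed = 3)
  pred <- predict(fit, x[801:1000, ])
  r2 <- 1 - mean((pred - y[801:1000])^2) / var(y[801:1000])
  expect_gt(r2, 0.95)

  # identical seed -> identical forest predictions; different seed differs
  fit2 <- train_forest(x[1:800, ], y[1:800], trees = 20, seed = 3)
  expect_identical(predict(fit, x[801:1000, ]), predict(fit2, x[801:1000, ]))
  expect_error(train_forest(x[1:10, ], y[1:5]), class = "hicreg_argument_error")
})

test_that("decision paths match an independent tree-walk oracle", {
  withr::with_seed(11, {
    x <- tibble::tibble(
      Distance = runif(300), s1 = runif(300), s2 = runif(300)
    )
    y <- 5 * x$Distance + x$s1 + rnorm(300, 0, 0.1)
  })
  fit <- train_forest(x, y, trees = 7, seed = 2)
  newx <- x[1:40, ]
  paths <- decision_paths(fit, newx)

  oracle <- oracle_path_tally(fit, newx)
  expect_equal(nrow(paths), oracle$total)
  got <- usage_importance(paths)
  for (f in names(oracle$counts)) {
    expect_equal(got$count[got$feature == f], unname(oracle$counts[f]))
  }
  # paths list features in root-to-leaf order with repetition
  expect_true(all(paths$depth >= 1))
  expect_equal(anyDuplicated(paths[, c("example", "tree", "depth")]), 0L)

  # single-feature forest: every path node splits on that feature
  fit1 <- train_forest(x[, "Distance", drop = FALSE], y, trees = 3, seed = 2)
  p1 <- decision_paths(fit1, x[1:10, "Distance", drop = FALSE])
  expect_true(all(p1$feature == "Distance"))

  # depth-0 trees (min_leaf beyond n) yield no path rows
  f0 <- train_forest(x[1:20, ], y[1:20], trees = 3, min_leaf = 50, seed = 1)
  expect_equal(nrow(decision_paths(f0, x[1:5, ])), 0L)
  expect_error(predict(fit, x[, 1:2]), "s2", class = "hicreg_argument_error")
})

test_that("run_cv predicts each measured hard pair exactly once", {
  tab <- random_contact_table(n_bins = 50, max_dist = 12, seed = 8)
  bins <- bin_genome(c(chrT = 50 * 5000), 5000)
  cv <- run_cv(tab, mode = "distance", bins = bins, trees = 3, seed = 4)
  folds <- cv$folds
  fold_of <- setNames(folds$fold, folds$start)
  hard <- tab |>
    dplyr::filter(
      measured,
      fold_of[as.character(start1)] == fold_of[as.character(start2)]
    )
  expect_equal(nrow(cv$predictions), nrow(hard))
  expect_equal(anyDuplicated(cv$predictions[, c("start1", "start2")]), 0L)
  expect_true(all(cv$predictions$hard))

  cv2 <- run_cv(tab, mode = "distance", bins = bins, trees = 3, seed = 4)
  expect_identical(cv$predictions, cv2$predictions)

  easy <- run_cv(tab, mode = "distance", bins = bins, trees = 3, seed = 4,
                 include_easy = TRUE)
  expect_gt(nrow(easy$predictions), nrow(cv$predictions))
  expect_false(all(easy$predictions$hard))
})

test_that("noiseless signal-driven counts are recovered with high AUC", {
  cfg <- sim_config(
    n_bins = 250, n_datasets = 4, n_cells = 1, max_distance_bins = 25,
    dispersion = 0, coverage = 1, tad_n = 0, loop_n = 0,
    weights = tibble::tibble(dataset = "d01", w_end = 0.5, w_window = 0)
  )
  st <- simulate_hic_study(cfg, seed = 21)
  cv <- run_cv(st$contacts[[1]], st$signals, mode = "window", cell = "cellA",
               max_distance_bins = 25, seed = 3)
  expect_gt(glance(cv)$auc, 0.9)
})

test_that("transfer and ensemble averaging equal the brute-force mean", {
  withr::with_seed(13, {
    x <- tibble::tibble(a = runif(120), b = runif(120))
    y <- 3 * x$a + rnorm(120, 0, 0.05)
  })
  models <- lapply(1:5, function(s) {
    train_forest(x, y, trees = 4, seed = s)
  })
  newx <- x[1:30, ]
  got <- predict_transfer(models, newx)
  oracle <- rowMeans(sapply(models, function(m) predict(m, newx)))
  expect_equal(got, oracle)

  same <- predict_transfer(models[c(1, 1, 1)], newx)
  expect_equal(same, unname(predict(models[[1]], newx)))
  expect_error(predict_transfer(list(), newx), class = "hicreg_argument_error")

  expect_equal(
    ensemble_average(list(rep(1, 4), rep(2, 4), rep(6, 4))),
    rep(3, 4)
  )
  expect_error(ensemble_average(list(1:3, 1:4)),
               class = "hicreg_argument_error")
})

test_that("baselines behave as documented", {
  # TransferCount with source == target reproduces counts exactly
  tab <- random_contact_table(n_bins = 30, max_dist = 8, seed = 14)
  pairs <- tab |> dplyr::select(chrom, start1, start2)
  tc <- baseline_transfer_count(tab, pairs)
  expect_equal(tc$predicted, tab$count)
  expect_error(baseline_transfer_count(tab, pairs, resolution = 10000),
               class = "hicreg_argument_error")

  # distance-only forest recovers counts that are a pure function of distance
  bins <- bin_genome(c(chrT = 80 * 5000), 5000)
  p80 <- enumerate_pairs(bins, 15)
  pure <- contact_table(
    p80 |> dplyr::mutate(count = 100 / distance_bins),
    resolution = 5000
  )
  cvd <- run_cv(pure, mode = "distance", bins = bins, trees = 10, seed = 6)
  rel_err <- abs(cvd$predictions$predicted - cvd$predictions$count) /
    cvd$predictions$count
  expect_lt(median(rel_err), 0.05)

  # linear baseline recovers generative weights (normal-equations oracle)
  withr::with_seed(15, {
    x <- tibble::tibble(a = runif(200), b = runif(200), c = runif(200))
    y <- 2 + 3 * x$a - 1.5 * x$b + rnorm(200, 0, 1e-8)
  })
  fit <- baseline_linear(x, y)
  mm <- cbind(1, as.matrix(x))
  beta <- solve(t(mm) %*% mm, t(mm) %*% y)
  expect_equal(unname(fit$coefficients), unname(drop(beta)), tolerance = 1e-6)
  expect_equal(unname(coef(fit)["a"]), 3, tolerance = 1e-4)
  expect_equal(predict(fit, x), drop(mm %*% beta), tolerance = 1e-6)
})
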