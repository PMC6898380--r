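test_that("OOB permutation importance isolates the informative feature", {
  withr::with_seed(17, {
    x <- tibble::tibble(
      x1 = runif(400), x2 = runif(400), x3 = runif(400), x4 = runif(400)
    )
    y <- 8 * sin(pi * x$x1) + rnorm(400, 0, 0.2)
  })
  fit <- train_forest(x, y, trees = 20, seed = 4)
  imp <- oob_importance(fit, x, y, seed = 2)
  scores <- setNames(imp$importance, imp$feature)
  expect_equal(imp$feature[1], "x1")
  expect_gt(scores["x1"], 2 * max(scores[c("x2", "x3", "x4")]))
  # noise features score near zero relative to the informative one
  expect_lt(max(abs(scores[c("x2", "x3", "x4")])), 0.2 * scores["x1"])
  expect_identical(oob_importance(fit, x, y, seed = 2), imp)
  expect_error(oob_importance(fit, x[1:10, ], y[1:10]),
               class = "hicreg_argument_error")
})

test_that("usage counts conserve total path-node visits", {
  withr::with_seed(19, {
    x <- tibble::tibble(a = runif(200), b = runif(200), Distance = runif(200))
    y <- 4 * x$a + 2 * x$Distance + rnorm(200, 0, 0.1)
  })
  fit <- train_forest(x, y, trees = 6, seed = 3)
  paths <- decision_paths(fit, x[1:30, ])
  ui <- usage_importance(paths, features = fit$feature_names)
  expect_equal(sum(ui$count), nrow(paths))
  oracle <- oracle_path_tally(fit, x[1:30, ])
  expect_equal(sum(ui$count), oracle$total)
  # unused features appear with explicit zeros
  never <- setdiff(fit$feature_names, paths$feature)
  expect_true(all(ui$count[ui$feature %in% never] == 0))
})

test_that("pairwise co-occurrence matches the exhaustive position-pair tally", {
  # path [A, B] in one tree -> pair A|B counted once
  p1 <- tibble::tibble(
    example = 1L, tree = 1L, depth = 1:2, feature = c("A", "B")
  )
  m1 <- pairwise_usage(p1, errors = c(0.1), top_fraction = 1)
  expect_equal(unname(m1[1, "A|B"]), 1L)

  # path [A, A, B]: every position pair with distinct features counts
  p2 <- tibble::tibble(
    example = 1L, tree = 1L, depth = 1:3, feature = c("A", "A", "B")
  )
  m2 <- pairwise_usage(p2, errors = c(0.1), top_fraction = 1)
  expect_equal(unname(m2[1, "A|B"]), 2L)

  # random paths against a brute-force double loop over path positions
  withr::with_seed(23, {
    paths <- tibble::tibble(
      example = rep(1:6, each = 10),
      tree = rep(rep(1:2, each = 5), 6),
      depth = rep(1:5, 12),
      feature = sample(LETTERS[1:4], 60, replace = TRUE)
    )
  })
  errors <- rep(0.5, 6)
  got <- pairwise_usage(paths, errors, top_fraction = 1)
  oracle <- list()
  for (ex in 1:6) {
    for (tr in 1:2) {
      fs <- paths$feature[paths$example == ex & paths$tree == tr]
      for (i in seq_along(fs)) {
        for (j in seq_along(fs)) {
          if (i < j && fs[i] != fs[j]) {
            key <- paste(ex, paste(sort(c(fs[i], fs[j])), collapse = "|"))
            oracle[[key]] <- (oracle[[key]] %||% 0L) + 1L
          }
        }
      }
    }
  }
  for (key in names(oracle)) {
    parts <- strsplit(key, " ")[[1]]
    expect_equal(unname(got[parts[1], parts[2]]), oracle[[key]])
  }
  expect_equal(sum(got), sum(unlist(oracle)))

  # the 5%-lowest-error filter keeps the right examples
  err6 <- c(0.9, 0.1, 0.8, 0.7, 0.6, 0.5)
  top2 <- pairwise_usage(paths, err6, top_fraction = 1 / 3)
  expect_equal(rownames(top2), c("2", "6"))
  expect_error(pairwise_usage(paths, err6, top_fraction = 0),
               class = "hicreg_argument_error")
})

test_that("NMF recovers planted rank-5 biclusters to numerical precision", {
  withr::with_seed(29, {
    u0 <- matrix(0, 50, 5)
    v0 <- matrix(0, 5, 40)
    row_block <- rep(1:5, each = 10)
    col_block <- rep(1:5, each = 8)
    for (c in 1:5) {
      u0[row_block == c, c] <- runif(10, 1, 2)
      v0[c, col_block == c] <- runif(8, 1, 2)
    }
  })
  x <- u0 %*% v0
  fit <- nmf_bicluster(x, k = 5, seed = 7)
  rel_err <- sqrt(tail(fit$objective, 1)) / sqrt(sum(x^2))
  expect_lt(rel_err, 1e-6)
  # planted blocks recovered: rows/cols of one block share a cluster and
  # blocks map to distinct clusters
  expect_equal(length(unique(tapply(fit$row_cluster, row_block, unique))), 5L)
  expect_equal(
    unname(tapply(fit$col_cluster, col_block, unique)[row_block[c(1, 11, 21, 31, 41)]]),
    unname(tapply(fit$row_cluster, row_block, unique))
  )

  expect_equal(rowSums(fit$u_norm), rep(1, 50), tolerance = 1e-12)
  expect_equal(colSums(fit$v_norm), rep(1, 40), tolerance = 1e-12)
  expect_true(all(diff(fit$objective) <= 1e-8 * max(fit$objective[1], 1)))
  fit2 <- nmf_bicluster(x, k = 5, seed = 7)
  expect_identical(fit$u, fit2$u)
  expect_error(nmf_bicluster(x, k = 100), class = "hicreg_argument_error")
  expect_error(nmf_bicluster(rbind(x, 0), k = 2),
               class = "hicreg_argument_error")
})

test_that("NMF objective is monotone on noisy matrices too", {
  withr::with_seed(31, {
    x <- matrix(rpois(600, 3), 30, 20)
    x <- x[rowSums(x) > 0, ]
  })
  fit <- nmf_bicluster(x, k = 4, seed = 2, n_restarts = 3, max_iter = 100)
  expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[1]))
})

test_that("co-occurrence networks marginalize and filter edges correctly", {
  counts <- tibble::tibble(
    feature1 = c("A", "A", "B"),
    feature2 = c("B", "C", "C"),
    count = c(5, 3, 1)
  )
  net <- cooccurrence_network(counts)
  expect_equal(nrow(net$edges), 3L)
  sizes <- setNames(net$nodes$size, net$nodes$feature)
  expect_equal(unname(sizes[c("A", "B", "C")]), c(8, 6, 4))

  # node size equals the sum of incident edge weights
  for (f in names(sizes)) {
    inc <- counts$count[counts$feature1 == f | counts$feature2 == f]
    expect_equal(unname(sizes[f]), sum(inc))
  }

  # top_edges keeps exactly the heaviest edges (sort oracle)
  top2 <- cooccurrence_network(counts, top_edges = 2)
  expect_equal(top2$edges$weight, sort(counts$count, decreasing = TRUE)[1:2])

  single <- cooccurrence_network(counts[1, ])
  expect_equal(nrow(single$edges), 1L)
  expect_equal(nrow(single$nodes), 2L)

  path <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, path)
  expect_equal(readLines(path), c("A\tco-occurs\tB", "A\tco-occurs\tC",
                                  "B\tco-occurs\tC"))
})

test_that("usage rankings are stable between all and lowest-error examples", {
  withr::with_seed(37, {
    x <- tibble::as_tibble(setNames(
      as.data.frame(matrix(runif(300 * 8), 300, 8)),
      c(paste0("s", 1:7), "Distance")
    ))
    y <- 5 * x$s1 + 2 * x$s2 + 3 * x$Distance + rnorm(300, 0, 0.2)
  })
  fit <- train_forest(x, y, trees = 10, seed = 5)
  newx <- x[1:150, ]
  paths <- decision_paths(fit, newx)
  err <- abs(predict(fit, newx) - y[1:150])
  all_counts <- usage_importance(paths, features = fit$feature_names)
  low_idx <- order(err)[1:30]
  low_counts <- usage_importance(
    paths |> dplyr::filter(example %in% low_idx),
    features = fit$feature_names
  )
  merged <- dplyr::inner_join(all_counts, low_counts, by = "feature")
  expect_gt(cor(merged$count.x, merged$count.y, method = "spearman"), 0.8)
})
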