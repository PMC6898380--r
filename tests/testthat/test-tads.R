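test_that("directionality index matches the hand-evaluated formula", {
  # mirror-symmetric matrix -> DI identically zero
  bins <- bin_genome(c(c = 30 * 5000), 5000)
  pairs <- enumerate_pairs(bins, 29)
  sym <- contact_table(
    pairs |> dplyr::mutate(count = 10 / distance_bins),
    resolution = 5000
  )
  di_sym <- directionality_index(sym, window_bp = 5e4)
  inner <- di_sym$di[11:20]  # bins with full 10-bin windows on both sides
  expect_equal(inner, rep(0, 10))

  # all mass downstream of the first bin -> positive DI there
  expect_gt(di_sym$di[1], 0)
  expect_lt(di_sym$di[30], 0)

  # 30-bin toy matrix against a dense per-bin oracle
  tab <- random_contact_table(n_bins = 30, max_dist = 29, seed = 12)
  w_bp <- 5e4
  di <- directionality_index(tab, window_bp = w_bp)
  df <- as_tibble(tab)
  for (b in c(1, 5, 15, 28, 30)) {
    s <- (b - 1) * 5000
    a_up <- sum(df$count[df$start2 == s & s - df$start1 <= w_bp])
    b_down <- sum(df$count[df$start1 == s & df$start2 - s <= w_bp])
    e <- (a_up + b_down) / 2
    expected <- if (e > 0 && a_up != b_down) {
      sign(b_down - a_up) * ((a_up - e)^2 / e + (b_down - e)^2 / e)
    } else {
      0
    }
    expect_equal(di$di[b], expected)
  }
  expect_error(directionality_index(tab, window_bp = 100),
               class = "hicreg_argument_error")
})

test_that("segmentation finds planted domains and ignores flat profiles", {
  # DI identically zero -> no domains
  flat <- tibble::tibble(chrom = "c", start = (0:49) * 5000, di = 0)
  attr(flat, "resolution") <- 5000
  expect_equal(nrow(segment_domains(flat)), 0L)
  expect_error(
    segment_domains(tibble::tibble(chrom = "c", start = 0, di = 1)),
    class = "hicreg_argument_error"
  )

  # block-diagonal matrix with 5 planted domains
  res <- 5000
  n <- 120
  doms <- tibble::tibble(start_bin = c(5, 30, 55, 78, 100),
                         end_bin = c(25, 50, 75, 95, 118))
  bins <- bin_genome(c(c = n * res), res)
  pairs <- enumerate_pairs(bins, 30)
  b1 <- pairs$start1 / res
  b2 <- pairs$start2 / res
  inside <- rep(FALSE, nrow(pairs))
  for (r in seq_len(nrow(doms))) {
    inside <- inside | (b1 >= doms$start_bin[r] & b2 < doms$end_bin[r])
  }
  withr::with_seed(21, {
    counts <- (50 / pairs$distance_bins) * ifelse(inside, 5, 1) *
      exp(rnorm(nrow(pairs), 0, 0.1))
  })
  tab <- contact_table(pairs |> dplyr::mutate(count = counts), res)
  di <- directionality_index(tab, window_bp = 1e5)
  tads <- segment_domains(di, seed = 2)
  # boundaries recovered within one bin (chromosome-edge domains can be
  # pulled to the ends, a known edge artifact of the directionality index)
  start_hits <- sum(sapply(doms$start_bin, function(s) {
    any(abs(tads$start_bin - s) <= 1)
  }))
  end_hits <- sum(sapply(doms$end_bin, function(e) {
    any(abs(tads$end_bin - e) <= 1)
  }))
  expect_gte(start_hits + end_hits, 8)
  expect_gt(tad_similarity(doms, tads), 0.8)

  # deterministic given the seed
  expect_identical(tads, segment_domains(di, seed = 2))
  # literal variant only keeps downstream-biased stretches: never longer
  lit <- segment_domains(di, seed = 2, literal = TRUE)
  expect_lte(sum(lit$end_bin - lit$start_bin), sum(tads$end_bin - tads$start_bin))
})

test_that("TAD similarity is the bidirectional best-match average", {
  a <- tibble::tibble(start_bin = c(0, 20), end_bin = c(10, 40))
  expect_equal(tad_similarity(a, a), 1)

  b <- tibble::tibble(start_bin = c(50, 80), end_bin = c(60, 90))
  expect_equal(tad_similarity(a, b), 0)

  one_a <- tibble::tibble(start_bin = 0, end_bin = 10)
  one_b <- tibble::tibble(start_bin = 5, end_bin = 15)
  expect_equal(tad_similarity(one_a, one_b), 1 / 3)

  # symmetric and invariant to row order
  withr::with_seed(31, {
    ra <- tibble::tibble(start_bin = c(0, 15, 40), end_bin = c(12, 30, 55))
    rb <- tibble::tibble(start_bin = c(2, 18, 42, 70), end_bin = c(13, 33, 50, 80))
  })
  expect_equal(tad_similarity(ra, rb), tad_similarity(rb, ra))
  expect_equal(tad_similarity(ra[c(3, 1, 2), ], rb), tad_similarity(ra, rb))

  expect_warning(sim <- tad_similarity(ra[0, ], rb), "empty")
  expect_true(is.na(sim))

  # asymmetric sets: hand-computed average of the two directional averages
  a2 <- tibble::tibble(start_bin = c(0, 10), end_bin = c(10, 20))
  b2 <- tibble::tibble(start_bin = 0, end_bin = 10)
  # A -> B: (1 + 0) / 2 ; B -> A: 1 ; overall (0.5 + 1) / 2
  expect_equal(tad_similarity(a2, b2), 0.75)
})

test_that("domains from true and predicted counts agree above shuffled baseline", {
  cfg <- sim_config(n_bins = 400, n_datasets = 3, n_cells = 1,
                    max_distance_bins = 60, tad_n = 8, tad_size = c(20, 40),
                    loop_n = 5)
  st <- simulate_hic_study(cfg, seed = 17)
  tab <- st$contacts[[1]]
  cv <- run_cv(tab, st$signals, mode = "window", cell = "cellA",
               max_distance_bins = 60, include_easy = TRUE, seed = 4)
  pred_tab <- contact_table(
    cv$predictions |>
      dplyr::select(chrom, start1, start2, count = predicted),
    resolution = 5000
  )
  di_true <- directionality_index(tab, window_bp = 2e5)
  di_pred <- directionality_index(pred_tab, window_bp = 2e5)
  tads_true <- segment_domains(di_true, seed = 1)
  tads_pred <- segment_domains(di_pred, seed = 1)
  agree <- tad_similarity(tads_true, tads_pred)

  # shuffled null: same domain sizes at random positions, averaged
  sizes <- tads_true$end_bin - tads_true$start_bin
  withr::with_seed(5, {
    null_sims <- replicate(20, {
      starts <- sort(sample(0:(400 - max(sizes)), nrow(tads_true)))
      shuffled <- tibble::tibble(
        start_bin = starts, end_bin = starts + sample(sizes)
      )
      tad_similarity(shuffled, tads_pred)
    })
  })
  expect_gt(agree, mean(null_sims))
  expect_gt(agree, 0.3)
})
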