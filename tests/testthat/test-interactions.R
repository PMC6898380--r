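test_that("distance-bin statistics count only measured pairs", {
  tab <- contact_table(
    tibble::tibble(
      chrom = "c",
      start1 = c(0, 5000, 10000, 15000, 0, 5000),
      start2 = c(5000, 10000, 15000, 20000, 10000, 15000),
      count = c(4.4, 2.6, 3.0, 1.2, 9.0, 7.0),
      measured = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
    ),
    resolution = 5000
  )
  st <- distance_bin_stats(tab)
  expect_equal(st$stratum, c(1, 2))
  expect_equal(st$M, c(4L, 1L))
  expect_equal(st$m, c(0.25, 1))
  # n sums half-up-rounded counts (4.4 -> 4, 2.6 -> 3, 3.0 -> 3, 1.2 -> 1)
  expect_equal(st$n, c(4 + 3 + 3 + 1, 9))
  empty_bins <- setdiff(1:4, st$stratum)
  expect_true(all(empty_bins %in% c(3, 4)))
})

test_that("binomial p-values match brute-force tail summation to 1e-12", {
  expect_equal(binomial_pvalue(0, 10, 0.3), 1)
  expect_equal(binomial_pvalue(1, 1, 0.5), 0.5)

  # exact summation with rational-friendly small n (binomial coefficients
  # and powers exact in double precision)
  brute_small <- function(k, n, m) {
    sum(sapply(k:n, function(j) choose(n, j) * m^j * (1 - m)^(n - j)))
  }
  expect_equal(binomial_pvalue(3, 10, 0.1), brute_small(3, 10, 0.1),
               tolerance = 1e-14)
  withr::with_seed(3, {
    for (i in 1:100) {
      n <- sample(1:40, 1)
      k <- sample(0:n, 1)
      m <- runif(1, 0.01, 1)
      expect_equal(binomial_pvalue(k, n, m), brute_small(k, n, m),
                   tolerance = 1e-12)
    }
  })

  # log-space summation oracle at larger n
  brute_log <- function(k, n, m) {
    lt <- lchoose(n, k:n) + (k:n) * log(m) + (n - (k:n)) * log1p(-m)
    exp(max(lt) + log(sum(exp(lt - max(lt)))))
  }
  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(100:2000, 1)
      m <- runif(1, 0.001, 0.5)
      k <- sample(0:n, 1)
      p <- binomial_pvalue(k, n, m)
      if (p > 1e-280) {
        expect_equal(p, brute_log(k, n, m), tolerance = 1e-10)
      }
    }
  })

  # monotone non-increasing in k
  ks <- 0:50
  expect_true(all(diff(binomial_pvalue(ks, 50, 0.2)) <= 0))
  expect_error(binomial_pvalue(5, 3, 0.1), class = "hicreg_argument_error")
  expect_error(binomial_pvalue(1, 3, 0), class = "hicreg_argument_error")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  # hand computation: q_(i) = min over j >= i of p_(j) * m / j, capped at 1
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  expect_equal(bh_adjust(p), c(0.005, 0.02, 0.05125, 0.05125, 0.9))
  withr::with_seed(7, ps <- runif(50))
  qs <- bh_adjust(ps)
  expect_true(all(qs[order(ps)] == cummax(qs[order(ps)])))
  expect_true(all(qs >= ps))
})

test_that("significance calling recovers planted loops and nothing under null", {
  # all counts equal -> nothing significant
  bins <- bin_genome(c(c = 40 * 5000), 5000)
  flat <- contact_table(
    enumerate_pairs(bins, 10) |> dplyr::mutate(count = 5),
    resolution = 5000
  )
  calls <- call_significant(flat)
  expect_equal(sum(calls$significant), 0L)
  expect_equal(nrow(calls), sum(flat$measured))
  expect_equal(sum(call_significant(flat, q_threshold = 0)$significant), 0L)

  # planted high-count loops dominate the significant set
  withr::with_seed(9, {
    spiked <- enumerate_pairs(bins, 10) |>
      dplyr::mutate(count = rpois(dplyr::n(), 5))
  })
  loop_rows <- c(10, 100, 200)
  spiked$count[loop_rows] <- 80
  calls2 <- call_significant(contact_table(spiked, 5000))
  sig <- calls2 |> dplyr::filter(significant)
  expect_true(nrow(sig) >= 3)
  loop_keys <- paste(spiked$start1[loop_rows], spiked$start2[loop_rows])
  expect_true(all(loop_keys %in% paste(sig$start1, sig$start2)))
})

test_that("orientation configurations follow the convergent-loop rules", {
  motifs <- tibble::tibble(
    chrom = "c",
    start = c(100, 5100, 10100, 10200, 15100, 20100),
    end = c(119, 5119, 10119, 10219, 15119, 20119),
    name = "CTCF",
    purity = c(0.95, 0.92, 0.91, 0.93, 0.95, 0.55),
    strand = c("+", "-", "+", "-", "-", "-")
  )
  pairs <- tibble::tibble(
    chrom = "c",
    start1 = c(0, 0, 10000, 0, 15000),
    start2 = c(5000, 15000, 15000, 20000, 20000)
  )
  cls <- classify_orientation(pairs, motifs, 5000)
  expect_equal(cls$config, c("+-", "+-", NA, NA, NA))
  # bin 10000 has both orientations -> excluded; bin 20000 only a low-purity
  # motif -> excluded
  lowered <- classify_orientation(pairs, motifs, 5000, purity_threshold = 0.5)
  expect_equal(lowered$config[5], "--")
})

test_that("fold enrichment identities hold for configs and external sets", {
  mk <- function(n_conf, n_other, sig_conf, sig_other) {
    bg <- tibble::tibble(config = c(rep("+-", n_conf), rep("++", n_other)))
    sig <- tibble::tibble(config = c(rep("+-", sig_conf), rep("++", sig_other)))
    config_enrichment(sig, bg)
  }
  # proportional null -> fold exactly 1
  expect_equal(mk(100, 300, 10, 30)$fold, 1)
  expect_equal(mk(100, 300, 20, 20)$fold, 2)
  expect_warning(
    res <- config_enrichment(
      tibble::tibble(config = character()),
      tibble::tibble(config = "+-")
    ),
    "undefined"
  )
  expect_true(is.na(res$fold))

  # hypergeometric tail against exhaustive enumeration at S = 18, m = 6
  s_total <- 18
  m <- 6
  k <- 5
  pool <- c(rep(TRUE, m), rep(FALSE, s_total - m))
  combos <- combn(s_total, k)
  for (q in 0:4) {
    exhaustive <- mean(colSums(matrix(pool[combos], nrow = k)) >= q)
    p <- stats::phyper(q - 1, m, s_total - m, k, lower.tail = FALSE)
    expect_equal(p, exhaustive, tolerance = 1e-12)
  }
  # and the same tail probability through config_enrichment itself
  sig <- tibble::tibble(config = c(rep("+-", 3), rep("++", 2)))
  bg <- tibble::tibble(config = c(rep("+-", 6), rep("++", 12)))
  res <- config_enrichment(sig, bg)
  exhaustive <- mean(colSums(matrix(pool[combos], nrow = k)) >= 3)
  expect_equal(res$p, exhaustive, tolerance = 1e-12)

  # external-set enrichment identities
  uni <- tibble::tibble(
    chrom = "c", start1 = (0:19) * 5000, start2 = (0:19) * 5000 + 10000
  )
  ext <- uni[1:4, ]
  sig1 <- uni[1:2, ]
  expect_equal(chiapet_enrichment(sig1, ext, uni)$fold, (2 / 2) / (4 / 20))
  # proportional null -> 1
  sig_prop <- uni[c(1, 5, 9, 13, 17), ]
  expect_equal(chiapet_enrichment(sig_prop, ext, uni)$fold, 1)
  none <- chiapet_enrichment(uni[10, ], ext, uni)
  expect_equal(none$fold, 0)
  # anchor order must not matter
  flipped <- ext |> dplyr::rename(start1 = start2, start2 = start1)
  expect_equal(chiapet_enrichment(sig1, flipped, uni)$n1, 2)
})

test_that("set overlap and Jaccard behave combinatorially", {
  a <- tibble::tibble(chrom = "c", start1 = (1:10) * 5000,
                      start2 = (1:10) * 5000 + 5000)
  expect_equal(set_overlap(a, a)$jaccard, 1)
  b <- a |> dplyr::mutate(start2 = start2 + 50000)
  expect_equal(set_overlap(a, b)$jaccard, 0)

  # random halves of a shared pool concentrate near Jaccard 1/3
  pool <- tibble::tibble(chrom = "c", start1 = (1:4000) * 5000,
                         start2 = (1:4000) * 5000 + 5000)
  withr::with_seed(11, {
    ja <- replicate(20, {
      s1 <- pool[sample(4000, 2000), ]
      s2 <- pool[sample(4000, 2000), ]
      set_overlap(s1, s2)$jaccard
    })
  })
  expect_lt(abs(mean(ja) - 1 / 3), 0.02)
})
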