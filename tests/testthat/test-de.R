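test_that("TPM normalization is exact, flags detection, and is scale invariant", {
  counts <- tibble::tibble(feature_name = c("a", "b", "c"),
                           stage = "AM", count = c(0, 10, 50))
  tpm <- compute_tpm(counts, c(AM = 1e6))
  expect_equal(tpm$tpm, c(0, 10, 50))
  expect_equal(tpm$detected, c(FALSE, TRUE, TRUE))
  tpm2 <- compute_tpm(dplyr::mutate(counts, count = count * 5),
                      c(AM = 5e6))
  expect_equal(tpm2$tpm, tpm$tpm)   # multiplying counts and total by k
  counts$stage <- "XX"
  expect_error(compute_tpm(counts, c(AM = 1e6)), "positive library total")
  expect_error(compute_tpm(dplyr::mutate(counts, stage = "AM"), c(AM = 0)),
               "positive library total")
})

test_that("exact count test matches a direct-summation oracle to 1e-12 relative", {
  expect_equal(exact_count_test(50, 1e6, 50, 1e6), 1)
  ## strongly imbalanced case against the independent oracle
  p <- exact_count_test(0, 1e6, 100, 1e6)
  expect_equal(p, direct_binom_p(0, 1e6, 100, 1e6), tolerance = 1e-12)
  expect_equal(p, binom.test(0, 100, 0.5)$p.value, tolerance = 1e-12)
  ## random cases, unequal totals, vectorized
  set.seed(71)
  a <- rpois(50, 40); b <- rpois(50, 60)
  ta <- 2e6; tb <- 3.5e6
  got <- exact_count_test(a, ta, b, tb)
  want <- mapply(direct_binom_p, a, ta, b, tb)
  expect_equal(got, want, tolerance = 1e-12)
  bt <- mapply(function(x, n) binom.test(x, n, ta / (ta + tb))$p.value,
               a, a + b)
  expect_equal(got, bt, tolerance = 1e-10)
})

test_that("exact count test is symmetric, bounded and monotone in imbalance", {
  set.seed(72)
  a <- rpois(30, 30); b <- rpois(30, 30)
  expect_equal(exact_count_test(a, 1e6, b, 2e6),
               exact_count_test(b, 2e6, a, 1e6))
  p <- exact_count_test(a, 1e6, b, 1e6)
  expect_true(all(p > 0 & p <= 1))
  ## fixed total 100, growing imbalance: p non-increasing
  k <- 0:50
  pk <- exact_count_test(50 - k, 1e6, 50 + k, 1e6)
  expect_true(all(diff(pk) <= 1e-12))
})

test_that("the three-criterion filter applies strict thresholds and direction", {
  ## published adult-stage switch: AF 55.1 vs AM 0.5 TPM
  fc <- (55.1 + 0.1) / (0.5 + 0.1)
  r <- de_filter(fc, 0.001, 55.1)
  expect_true(r$passes)
  expect_equal(r$direction, "up")
  expect_false(de_filter(2.0, 0.001, 100)$passes)    # FC exactly 2 fails
  expect_false(de_filter(5, 0.2, 100)$passes)        # p criterion
  expect_false(de_filter(5, 0.001, 10)$passes)       # TPM exactly 10 fails
  expect_true(de_filter(0.4, 0.001, 100)$passes)     # down-regulation
  expect_equal(de_filter(0.4, 0.001, 100)$direction, "down")
})

test_that("the filter is monotone in fold change, p and TPM", {
  set.seed(73)
  for (i in 1:200) {
    fc <- exp(runif(1, -3, 3)); p <- runif(1); tpm <- runif(1, 0, 100)
    base <- de_filter(fc, p, tpm)$passes
    better <- de_filter(ifelse(fc >= 1, fc * 1.5, fc / 1.5), p * 0.5,
                        tpm * 1.5)$passes
    expect_true(!base || better)
  }
})

test_that("contrasts recover planted regulation without false positives", {
  set.seed(74)
  n_null <- 50
  tot <- c(A = 1e6, B = 1e6)
  base <- rpois(n_null + 5, 200)
  counts_a <- rpois(n_null + 5, base)
  counts_b <- rpois(n_null + 5, base * c(rep(8, 5), rep(1, n_null)))
  counts <- dplyr::bind_rows(
    tibble::tibble(feature_name = paste0("f", seq_along(base)), stage = "A",
                   count = counts_a),
    tibble::tibble(feature_name = paste0("f", seq_along(base)), stage = "B",
                   count = counts_b))
  de <- run_contrasts(counts, tot, "A:B")
  called <- dplyr::filter(tidy(de), passes)
  expect_setequal(called$feature_name, paste0("f", 1:5))
  expect_true(all(called$direction == "up"))
  ## self-contrast: nothing passes
  self <- run_contrasts(counts, tot, "A:A")
  expect_equal(sum(tidy(self)$passes), 0)
  ## unknown stage label
  expect_error(run_contrasts(counts, tot, "A:ZZ"), "unknown stage")
  ## features absent from one stage get count 0, not dropped
  miss <- dplyr::filter(counts, !(feature_name == "f1" & stage == "A"))
  de2 <- run_contrasts(miss, tot, "A:B")
  expect_equal(tidy(de2)$count_a[tidy(de2)$feature_name == "f1"], 0)
})

test_that("tidy, glance and autoplot expose the DE results", {
  counts <- tidyr::expand_grid(feature_name = c("x", "y"),
                               stage = c("A", "B")) |>
    dplyr::mutate(count = c(100, 800, 50, 55))
  de <- run_contrasts(counts, c(A = 1e6, B = 1e6), "A:B")
  td <- tidy(de)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("fold_change", "p_value", "max_tpm", "passes") %in%
                    names(td)))
  gl <- glance(de)
  expect_equal(gl$n_features, 2)
  expect_s3_class(autoplot(de), "ggplot")
  expect_output(print(de), "mir_de")
})

test_that("Benjamini-Hochberg adjustment is available but off by default", {
  counts <- tidyr::expand_grid(feature_name = paste0("f", 1:20),
                               stage = c("A", "B")) |>
    dplyr::mutate(count = rep(c(100, 140), 20))
  raw <- tidy(run_contrasts(counts, c(A = 1e6, B = 1e6), "A:B"))
  adj <- tidy(run_contrasts(counts, c(A = 1e6, B = 1e6), "A:B",
                            adjust = "BH"))
  expect_true(all(adj$p_value >= raw$p_value))
})
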