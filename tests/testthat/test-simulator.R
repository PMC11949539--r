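test_that("synthetic populations carry exact presence counts", {
  expect_identical(sum(make_population(10, 0.5)), 5)
  expect_identical(sum(make_population(1000, 0.5)), 500)
  expect_identical(sum(make_population(100, 0)), 0)
  expect_error(make_population(100, 1.2), "proportion")
  expect_error(make_population(0, 0.5), "positive integer")
})

test_that("expected_se matches the finite-population closed form", {
  expect_identical(expected_se(0.4, 50, 50), 0)
  expect_lt(abs(expected_se(0.5, 1, 1e7) - 50), 1e-3)
  expect_identical(expected_se(0.3, 7, 40), expected_se(0.7, 7, 40))
  expect_error(expected_se(0.5, 51, 50), "cannot exceed")
  expect_error(expected_se(1.5, 1, 50), "\\[0, 1\\]")
})

test_that("single-draw prevalence spread matches the closed-form SE", {
  pop <- make_population(50, 0.4)
  k <- 10
  draws <- vapply(seq_len(8000), function(i)
    resample_prevalence_curve(pop,
      stability_params(n_replicates = 1, seed = 5000 + i))$means[k],
    numeric(1))
  target <- expected_se(0.4, k, 50)
  expect_lt(abs(mean(draws) - 40), 4 * target / sqrt(8000))
  expect_lt(abs(sd(draws) / target - 1), 0.05)
})

test_that("run_single records the estimator outcome and its error", {
  rec <- run_single(100, 1, stability_params(seed = 1))
  expect_identical(rec$stability_point, 10L)  # constant curve
  expect_identical(rec$abs_error_pp, 0)
  short <- run_single(5, 0.4, stability_params(seed = 1))
  expect_true(is.na(short$stability_point))
  expect_true(is.na(short$abs_error_pp))
  smoke <- run_default_grid(seed = 4, sizes = 100, prevalences = 0.5,
                            replicates = 10)
  expect_identical(nrow(smoke), 1L)
  expect_true(all(c("population_size", "stability_point",
                    "abs_error_pp") %in% names(smoke)))
})

test_that("grid records satisfy their invariants and reproduce under a seed", {
  g1 <- run_default_grid(seed = 99, sizes = c(100, 1000),
                         prevalences = c(0.1, 0.5, 0.9),
                         replicates = c(10, 50))
  g2 <- run_default_grid(seed = 99, sizes = c(100, 1000),
                         prevalences = c(0.1, 0.5, 0.9),
                         replicates = c(10, 50))
  expect_identical(g1, g2)
  ok <- !is.na(g1$stability_point)
  expect_true(all(is.na(g1$abs_error_pp) == !ok))
  expect_true(all(g1$abs_error_pp[ok] >= 0))
  expect_true(all(g1$stability_point[ok] >= g1$successive_points[ok]))
  expect_true(all(g1$stability_point[ok] <= g1$population_size[ok]))
  expect_identical(attr(g1, "mode"), "nested")
})

test_that("stricter detector settings demand more samples in the sweep", {
  sweep <- run_parameter_sweep(seed = 55)
  expect_identical(nrow(sweep), 36L)
  mean_at <- function(x = NULL, y = NULL, z = NULL) {
    keep <- rep(TRUE, nrow(sweep))
    if (!is.null(x)) keep <- keep & sweep$successive_points == x
    if (!is.null(y)) keep <- keep & sweep$mean_diff_threshold == y
    if (!is.null(z)) keep <- keep & sweep$delta_threshold == z
    mean(ifelse(is.na(sweep$stability_point[keep]),
                sweep$population_size[keep],
                sweep$stability_point[keep]))
  }
  expect_gt(mean_at(x = 50), mean_at(x = 10))
  expect_gte(mean_at(z = 0.5), mean_at(z = 2))
  # the loosest combination needs the fewest samples (up to run noise)
  loosest <- sweep$stability_point[sweep$successive_points == 2 &
                                     sweep$mean_diff_threshold == 10 &
                                     sweep$delta_threshold == 2]
  expect_lte(loosest, min(sweep$stability_point, na.rm = TRUE) + 2)
})

test_that("repeat runs summarise run-to-run spread honestly", {
  rs <- repeat_runs(300, 1, runs = 10, seed = 6)
  expect_identical(rs$mean_stability_point, 10)
  expect_identical(rs$sd_stability_point, 0)
  expect_identical(rs$na_count, 0L)
  one <- repeat_runs(300, 0.3, runs = 1, seed = 6)
  expect_identical(one$sd_stability_point, 0)
  expect_true(one$degenerate_sd)
  expect_error(repeat_runs(300, 0.3, runs = 0), "positive integer")
})

test_that("prevalence p and 1 - p are statistically interchangeable", {
  runs <- 100
  lo <- repeat_runs(500, 0.2, runs = runs, seed = 81)$stability_points
  hi <- repeat_runs(500, 0.8, runs = runs, seed = 82)$stability_points
  expect_gt(stats::wilcox.test(lo, hi, exact = FALSE)$p.value, 0.01)
})

test_that("mid prevalence is harder to pin down than rare species", {
  mid <- repeat_runs(1000, 0.5, runs = 25, seed = 7)$mean_stability_point
  rare <- repeat_runs(1000, 0.1, runs = 25, seed = 8)$mean_stability_point
  expect_gte(mid, rare)
})
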