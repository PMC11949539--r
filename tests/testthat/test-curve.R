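test_that("constant columns give constant curves in both modes", {
  for (mode in c("nested", "independent")) {
    cv <- resample_prevalence_curve(rep(1, 4), stability_params(seed = 3),
                                    mode = mode)
    expect_identical(cv$means, rep(100, 4))
    cv0 <- resample_prevalence_curve(rep(0, 6), stability_params(seed = 3),
                                     mode = mode)
    expect_identical(cv0$means, rep(0, 6))
  }
})

test_that("the full-size subsample reproduces the observed prevalence exactly", {
  col <- c(1, 0, 0, 1, 0)
  for (seed in c(1, 7, 12345)) {
    for (mode in c("nested", "independent")) {
      cv <- resample_prevalence_curve(col, stability_params(seed = seed),
                                      mode = mode)
      expect_identical(cv$means[5], 40)
      expect_identical(cv$observed_prevalence, 40)
    }
  }
  # holds for arbitrary binary columns too, bit-exactly
  set.seed(41)
  for (i in 1:10) {
    col <- rbinom(sample(5:40, 1), 1, runif(1))
    cv <- resample_prevalence_curve(col, stability_params(seed = i))
    expect_identical(cv$means[cv$k_max], 100 * sum(col) / length(col))
  }
})

test_that("subsample means match the exhaustive enumeration oracle", {
  col <- c(1, 1, 0, 0)
  oracle <- enumerate_subset_moments(col, 2)  # mean 0.5, var 1/12
  n <- 10000
  cv <- resample_prevalence_curve(col,
                                  stability_params(n_replicates = n,
                                                   seed = 8))
  mc_se <- 100 * sqrt(oracle$var / n)
  expect_lt(abs(cv$means[2] - 100 * oracle$mean), 3 * mc_se)
})

test_that("replicate means are unbiased for the observed proportion at every k", {
  col <- c(rep(1, 7), rep(0, 13))  # p_obs = 35 %
  n_curves <- 40
  n_rep <- 250
  acc <- numeric(length(col))
  for (i in seq_len(n_curves)) {
    cv <- resample_prevalence_curve(
      col, stability_params(n_replicates = n_rep, seed = 1000 + i))
    acc <- acc + cv$means
  }
  grand <- acc / n_curves
  total <- n_curves * n_rep
  se <- expected_se(0.35, seq_along(col), length(col)) / sqrt(total)
  expect_identical(grand[length(col)], 35)          # census: exact
  inner <- seq_len(length(col) - 1)
  expect_true(all(abs(grand[inner] - 35) < 4 * se[inner]))
})

test_that("missing entries are dropped and empty/invalid columns error", {
  cv <- resample_prevalence_curve(c(1, NA, 0, NA, 1),
                                  stability_params(seed = 2))
  expect_identical(cv$k_max, 3L)
  expect_error(resample_prevalence_curve(c(NA, NA), stability_params()),
               "no data")
  expect_error(resample_prevalence_curve(c(1, 2, 0), stability_params()),
               "non-binary.*position 2")
})

test_that("successive differences follow their closed form", {
  expect_identical(unname(successive_differences(rep(50, 8))), rep(0, 7))
  expect_identical(unname(successive_differences(c(60, 55, 53))), c(5, 2))
  k <- 1:30
  m <- 50 + 10 / k
  expect_equal(unname(successive_differences(m)),
               10 / ((k[-1] - 1) * k[-1]))
  expect_length(successive_differences(42), 0)
})
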