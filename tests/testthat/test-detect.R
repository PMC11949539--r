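test_that("a constant curve stabilises at the first window", {
  res <- detect_stability(rep(50, 30))
  expect_identical(res$stability_point, 10L)  # end of window starting at 1
  expect_identical(res$window_start, 1L)
  expect_identical(res$estimated_prevalence, 50)
  expect_identical(res$window_delta, 0)
  expect_identical(res$diagnostic, "ok")
  start <- detect_stability(rep(50, 30), point = "window_start")
  expect_identical(start$stability_point, 1L)
})

test_that("curves shorter than the window are undetermined, not errors", {
  res <- detect_stability(c(50, 51, 49, 50, 50))
  expect_true(is.na(res$stability_point))
  expect_true(is.na(res$estimated_prevalence))
  expect_identical(res$diagnostic, "short_curve")
  expect_identical(res$tail_prevalence, 50)
})

test_that("detection agrees with the brute-force window-scan oracle", {
  params <- stability_params()
  curves <- c(list(50 + 10 / (1:30)),
              lapply(1:8, function(i) make_noisy_curve(120, seed = 70 + i)))
  for (m in curves) {
    for (point in c("window_end", "window_start")) {
      for (ci in c("later", "earlier")) {
        for (wu in c("means", "differences")) {
          got <- detect_stability(m, params, point = point,
                                  correction_index = ci, window_unit = wu)
          want <- brute_force_detect(m, 10, 2, 1, point = point,
                                     correction_index = ci,
                                     window_unit = wu)
          expect_identical(got$stability_point,
                           if (is.na(want)) NA_integer_ else
                             as.integer(want))
          if (!is.na(want))
            expect_identical(got$estimated_prevalence, m[want])
        }
      }
    }
  }
})

test_that("first qualifying window wins", {
  # drop of 1 pp at k = 10 blocks every window crossing it
  m <- c(rep(50, 9), rep(49, 20))
  res <- detect_stability(m)
  expect_identical(res$window_start, 10L)
  expect_identical(res$stability_point, 19L)
  expect_identical(res$estimated_prevalence, 49)
})

test_that("threshold comparisons are strict: ties fail", {
  m <- rep(50, 20)
  m[5] <- 52
  loose_y <- stability_params(mean_diff_threshold = 100,
                              delta_threshold = 2)
  res <- detect_stability(m, loose_y)
  expect_identical(res$window_start, 6L)  # windows containing k=5 tie at z
  just_over <- stability_params(mean_diff_threshold = 100,
                                delta_threshold = 2 + 1e-9)
  expect_identical(detect_stability(m, just_over)$window_start, 1L)
})

test_that("stability point is monotone in window length and thresholds", {
  as_inf <- function(r) if (is.na(r$stability_point)) Inf else
    r$stability_point
  for (seed in c(301, 302, 303)) {
    m <- make_noisy_curve(150, seed = seed)
    # longer windows never stabilise earlier (compare window starts)
    starts <- vapply(c(2, 5, 10, 15), function(x) {
      r <- detect_stability(m, stability_params(successive_points = x),
                            point = "window_start")
      if (is.na(r$stability_point)) Inf else as.numeric(r$stability_point)
    }, numeric(1))
    expect_true(all(diff(starts) >= 0))
    # tighter y never stabilises earlier
    pts_y <- vapply(c(4, 2, 1, 0.5), function(y)
      as_inf(detect_stability(m,
        stability_params(mean_diff_threshold = y))), numeric(1))
    expect_true(all(diff(pts_y) >= 0))
    # tighter z never stabilises earlier
    pts_z <- vapply(c(2, 1, 0.5, 0.25), function(z)
      as_inf(detect_stability(m,
        stability_params(delta_threshold = z))), numeric(1))
    expect_true(all(diff(pts_z) >= 0))
  }
})

test_that("parameter validation rejects nonsense", {
  expect_error(stability_params(n_replicates = 0), "positive integer")
  expect_error(stability_params(successive_points = 1), "at least 2")
  expect_error(stability_params(mean_diff_threshold = -2), "positive")
  expect_error(stability_params(delta_threshold = 0), "positive")
  expect_error(detect_stability(numeric(0)), "empty curve")
})
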