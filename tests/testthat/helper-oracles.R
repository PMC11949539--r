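# Independent oracles, written separately from the package internals.

# Brute-force stability detector: re-evaluates both window criteria for
# every start position with plain loops.
brute_force_detect <- function(m, x, y, z, point = "window_end",
                               correction_index = "later",
                               window_unit = "means") {
  L <- if (window_unit == "means") x else x + 1
  if (length(m) < L) return(NA_integer_)
  for (s in seq_len(length(m) - L + 1)) {
    pairs_ok <- TRUE
    for (j in seq(s + 1, s + L - 1)) {
      k <- if (correction_index == "later") j else j - 1
      if (!(abs(m[j] - m[j - 1]) < y / sqrt(k))) {
        pairs_ok <- FALSE
        break
      }
    }
    if (!pairs_ok) next
    w <- m[s:(s + L - 1)]
    if (max(w) - min(w) < z)
      return(if (point == "window_end") s + L - 1 else s)
  }
  NA_integer_
}

# Exact mean and variance of the proportion of 1s in a uniform size-k
# subset without replacement, by exhaustive enumeration.
enumerate_subset_moments <- function(column, k) {
  props <- apply(utils::combn(length(column), k), 2,
                 function(idx) mean(column[idx]))
  list(mean = mean(props), var = mean(props^2) - mean(props)^2)
}

# A reproducible noisy-but-flattening curve for detector property tests.
make_noisy_curve <- function(k_max, seed, p = 0.5, n = 30) {
  cv <- resample_prevalence_curve(
    make_population(k_max, p),
    stability_params(n_replicates = n, seed = seed))
  cv$means
}

# Minimal two-group occurrence CSV on disk; returns its path.
write_demo_csv <- function(path = tempfile(fileext = ".csv")) {
  tab <- make_fixture_table(data.frame(
    group = c("H1", "H1", "H2"),
    species = c("spA", "spB", "spA"),
    k_max = c(40, 40, 30),
    ones = c(10, 36, 15)), seed = 99)
  df <- data.frame(host = tab$group, tab$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  path
}
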