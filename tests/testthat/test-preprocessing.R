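test_that("count series constructor enforces its invariants", {
  expect_error(count_series("w", c(0, 4, 4), c(1, 2, 3)), "increasing")
  expect_error(count_series("w", c(0, 4), c(1, -2)), "non-negative")
  expect_error(count_series("w", c(0, 4), c(1, 2, 3)), "equal length")
})

test_that("clean series under the cap are unchanged by truncation", {
  s <- series_from_truth(typical_params(N_max = 2.4e4))
  out <- truncate_series(s)
  expect_equal(out$counts, s$counts)
  expect_true(attr(out, "usable"))
  expect_true(is.na(attr(out, "trunc_index")))
})

test_that("series are truncated at the count cap", {
  tt <- seq(0, 40, 4)
  N <- c(5000, 9000, 15000, 21000, 25000, 27000, 29000, 31000, 33000, 35000, 36000)
  out <- truncate_series(count_series("w", tt, N), cap = 30000)
  expect_equal(max(out$counts), 29000)
  expect_equal(length(out$counts), 7)
})

test_that("a single-step drop beyond the threshold truncates", {
  tt <- seq(0, 40, 4)
  N <- c(12000, 11500, 11000, 10500, 10000, 4000, 3800, 3600, 3400, 3200, 3000)
  out <- truncate_series(count_series("w", tt, N), drop_fraction = 0.5)
  expect_equal(out$counts[length(out$counts)], 10000)  # ends before the 60% drop
})

test_that("repeated discontinuities truncate at the first one", {
  set.seed(1)
  tt <- seq(0, 200, 4)
  N <- 5000 + 20 * tt + rnorm(length(tt), 0, 10)
  N[20:length(N)] <- N[20:length(N)] * 0.75
  N[35:length(N)] <- N[35:length(N)] * 0.75
  out <- truncate_series(count_series("w", tt, N))
  expect_lte(length(out$counts), 19)
})

test_that("smooth series yield no detected discontinuities", {
  tt <- seq(0, 400, 4)
  N <- 30000 / (1 + 14 * exp(-0.02 * tt))  # smooth logistic
  expect_length(detect_discontinuities(count_series("w", tt, N)), 0)
})

test_that("injected drops are detected at their indices", {
  set.seed(42)
  tt <- seq(0, 400, 4)
  base <- 4000 + 30 * tt + rnorm(length(tt), 0, 15)
  one <- base
  one[60:length(one)] <- one[60:length(one)] * 0.7
  d1 <- detect_discontinuities(count_series("w", tt, one))
  expect_equal(d1, 60L)
  two <- one
  two[85:length(two)] <- two[85:length(two)] * 1.35
  d2 <- detect_discontinuities(count_series("w", tt, two))
  expect_equal(d2, c(60L, 85L))
})

test_that("alpha is 1 on smooth constant and linear series", {
  tt <- seq(0, 100, 4)
  s_const <- count_series("w", tt, rep(5000, length(tt)))
  out <- normalize_discontinuity(s_const, 10)
  expect_equal(attr(out, "alpha"), 1)
  expect_equal(out$counts, s_const$counts)
  s_lin <- count_series("w", tt, 2000 + 37 * tt)
  out_lin <- normalize_discontinuity(s_lin, 12)
  expect_equal(attr(out_lin, "alpha"), 1, tolerance = 1e-12)
  expect_equal(out_lin$counts, s_lin$counts, tolerance = 1e-9)
})

test_that("a pure multiplicative jump is removed exactly", {
  tt <- seq(0, 200, 4)
  # exact on a linear trend (the smoothness conditions hold exactly there)
  lin_N <- 4000 + 30 * tt
  for (a in c(0.7, 1.3, 1 / 0.6)) {
    obs <- lin_N
    d <- 25L
    obs[seq_len(d - 1)] <- lin_N[seq_len(d - 1)] * a
    out <- normalize_discontinuity(count_series("w", tt, obs), d)
    expect_equal(attr(out, "alpha"), a, tolerance = 1e-12)
    expect_equal(out$counts, lin_N, tolerance = 1e-12)
  }
  # near-exact on a slowly curving series (error is second order in the step)
  exp_N <- 3000 * exp(0.004 * tt)
  obs <- exp_N
  obs[seq_len(24)] <- exp_N[seq_len(24)] * 0.7
  out <- normalize_discontinuity(count_series("w", tt, obs), 25L)
  expect_equal(attr(out, "alpha"), 0.7, tolerance = 1e-4)
  expect_equal(out$counts, exp_N, tolerance = 1e-4)
})

test_that("normalization is idempotent: no discontinuity remains afterwards", {
  set.seed(5)
  tt <- seq(0, 400, 4)
  true_N <- 4000 + 25 * tt + rnorm(length(tt), 0, 10)
  obs <- true_N
  d <- 50L
  obs[seq_len(d - 1)] <- obs[seq_len(d - 1)] * 1.35
  s <- count_series("w", tt, obs)
  expect_equal(detect_discontinuities(s), d)
  out <- normalize_discontinuity(s, d)
  expect_length(detect_discontinuities(out), 0)
})

test_that("preprocess_series normalizes small drops and truncates large ones", {
  set.seed(8)
  tt <- seq(0, 400, 4)
  true_N <- 4000 + 25 * tt + rnorm(length(tt), 0, 10)
  # 30% loss: normalized
  small <- true_N
  small[seq_len(49)] <- small[seq_len(49)] / 0.7
  s_small <- preprocess_series(count_series("w", tt, small))
  expect_equal(attr(s_small, "action"), "normalized")
  expect_equal(attr(s_small, "alpha"), 1 / 0.7, tolerance = 0.05)
  expect_equal(length(s_small$counts), length(tt))
  # 60% loss: truncated
  big <- true_N
  big[50:length(big)] <- big[50:length(big)] * 0.4
  s_big <- preprocess_series(count_series("w", tt, big))
  expect_equal(attr(s_big, "action"), "truncated")
  expect_lte(length(s_big$counts), 49)
})

test_that("truncation output is a prefix of the input", {
  set.seed(3)
  tt <- seq(0, 300, 4)
  N <- pmax(0, 20000 + 150 * tt + rnorm(length(tt), 0, 500))
  out <- truncate_series(count_series("w", tt, N), cap = 40000)
  k <- length(out$counts)
  expect_equal(out$times, tt[seq_len(k)])
  expect_equal(out$counts, N[seq_len(k)])
})

test_that("counts CSV round-trips through write and read", {
  wells <- generate_plate(list(g1 = list(
    ranges = parameter_ranges(), p_nonrecovering = 0.5)),
    n_replicates = 3, t_end = 200, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts_csv(wells, path)
  back <- read_counts_csv(path)
  expect_setequal(names(back), names(wells))
  w <- names(wells)[1]
  expect_equal(back[[w]]$counts, wells[[w]]$series$counts)
})
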