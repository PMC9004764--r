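test_that("AIC evaluates its closed form", {
  expect_equal(compute_aic(1, 100, 6), 12)
  expect_equal(compute_aic(exp(1), 50, 4), 58)
  # delta between p = 6 and p = 4 candidates at equal n
  n <- 120; r1 <- 2.5; r2 <- 3.1
  expect_equal(compute_aic(r1, n, 6) - compute_aic(r2, n, 4),
               4 + n * log(r1 / r2))
  expect_warning(aic0 <- compute_aic(0, 10, 2), "perfect fit")
  expect_identical(aic0, -Inf)
  expect_error(compute_aic(1, 4, 6))
})

test_that("minimum-AIC selection and tie-breaking are deterministic", {
  mk <- function(aic, p, form, n = 100) {
    structure(list(variant = model_variant(form), aic = aic, p = p, n = n,
                   rss = exp((aic - 2 * p) / n), recovered = TRUE,
                   converged = TRUE),
              class = "calibration_result")
  }
  sel <- select_model(list(mk(10, 6, "exponential"), mk(20, 4, "constant")))
  expect_equal(sel$selected, 1)
  expect_equal(sel$delta_aic, c(0, 10))
  # exact tie: fewer parameters win
  tie <- select_model(list(mk(15, 6, "exponential"), mk(15, 4, "constant")))
  expect_equal(tie$best$variant$k_form, "constant")
  # equal p tie: simpler death-rate form wins
  tie2 <- select_model(list(mk(15, 6, "exponential"), mk(15, 6, "linear")))
  expect_equal(tie2$best$variant$k_form, "linear")
  # mixed n is refused
  expect_error(select_model(list(mk(10, 6, "exponential"),
                                 mk(12, 4, "constant", n = 90))),
               "not comparable")
  # adding a strictly worse candidate never changes the winner
  sel3 <- select_model(list(mk(10, 6, "exponential"), mk(20, 4, "constant"),
                            mk(50, 6, "linear")))
  expect_equal(sel3$best$variant$k_form, "exponential")
})

test_that("perfect estimates give PCC one and shuffled estimates near zero", {
  set.seed(2)
  truth <- runif(60, 0.01, 0.3)
  expect_equal(cor(truth, truth), 1)
  expect_lt(abs(cor(truth, sample(truth))), 0.35)
})

test_that("identifiability study reports PCC per parameter and dataset", {
  spec <- dataset_spec("A", n_series = 10, noise_frac = 0.02, seed = 21,
                       t_end = 600)
  ds <- generate_dataset(spec)
  rep <- identifiability_study(list(ds), variant_ids = c(1, 3),
                               n_starts = 6, seed = 2)
  pcc <- rep$pcc
  expect_true(all(pcc$pcc >= -1 & pcc$pcc <= 1, na.rm = TRUE))
  # the matched variant recovers the resistant fraction strongly
  fr_row <- pcc[pcc$variant_id == 1 & pcc$parameter == "f_r", ]
  expect_gt(fr_row$pcc, 0.85)
})

test_that("matched-variant fits recover parameters across a dataset", {
  spec <- dataset_spec("F", n_series = 8, noise_frac = 0, seed = 31,
                       t_end = 720)
  ds <- generate_dataset(spec)  # constant form, t_r > 0
  v <- model_variant("constant")
  est <- t(vapply(ds$series, function(s) {
    fit <- calibrate(s$series, v, t_r_input = s$truth$t_r, recovered = TRUE,
                     n_starts = 8, seed = 3)
    c(fit$params$f_r, s$truth$f_r, fit$params$k_d, s$truth$k_d)
  }, numeric(4)))
  expect_gt(cor(est[, 1], est[, 2]), 0.999)
  expect_gt(cor(est[, 3], est[, 4]), 0.999)
})

test_that("nested variants preserve the RSS ordering within tolerance", {
  set.seed(12)
  ranges <- parameter_ranges()
  vs <- standard_variants()
  for (i in 1:5) {
    truth <- draw_parameters(ranges, tr_nonzero = FALSE)
    s <- series_from_truth(truth, "exponential", noise_sd = 100,
                           seed = 40 + i)
    f1 <- calibrate(s, vs[[1]], t_r_input = 0, recovered = classify_recovery(s),
                    n_starts = 8, seed = 7)
    f3 <- calibrate(s, vs[[3]], t_r_input = 0, recovered = classify_recovery(s),
                    n_starts = 8, seed = 7)
    # model 3 is nested in model 1 (t_d -> 0); allow optimizer slack
    expect_lte(f1$rss, f3$rss * 1.02)
  }
})

test_that("LOOCV on identical noise-free replicates has full coverage", {
  truth <- typical_params()
  s <- series_from_truth(truth, "exponential")
  group <- list(a = s, b = s, c = s, d = s)
  out <- loocv(group, model_variant("exponential"),
               t_r_inputs = c(a = 150, b = 150, c = 150, d = 150),
               n_starts = 4, seed = 2)
  expect_equal(out$coverage, 1)
})

test_that("LOOCV coverage is near nominal under matched noise", {
  set.seed(77)
  truth <- typical_params(f_r = 0.05, g_r = 0.02, t_r = 100)
  noise_sd <- 150
  group <- lapply(1:10, function(i)
    series_from_truth(truth, "exponential", noise_sd = noise_sd,
                      seed = 700 + i, well_id = paste0("w", i)))
  names(group) <- paste0("w", 1:10)
  out <- loocv(group, model_variant("exponential"),
               t_r_inputs = setNames(rep(100, 10), names(group)),
               n_starts = 6, seed = 3)
  expect_gt(out$coverage, 0.90)
  expect_lte(out$coverage, 1.0)
})

test_that("LOOCV flags a grossly different held-out well", {
  truth <- typical_params(f_r = 0.05, g_r = 0.02, t_r = 100)
  odd <- typical_params(f_r = 0.3, g_r = 0.04, t_r = 0, k_d = 0.02)
  group <- c(lapply(1:5, function(i)
    series_from_truth(truth, "exponential", noise_sd = 100, seed = 80 + i,
                      well_id = paste0("w", i))),
    list(series_from_truth(odd, "exponential", noise_sd = 100, seed = 99,
                           well_id = "odd")))
  names(group) <- c(paste0("w", 1:5), "odd")
  out <- loocv(group, model_variant("exponential"),
               t_r_inputs = setNames(c(rep(100, 5), 0), names(group)),
               n_starts = 6, seed = 4)
  cov_odd <- mean(out$detail$inside[out$detail$well_id == "odd"])
  cov_rest <- mean(out$detail$inside[out$detail$well_id != "odd"])
  expect_lt(cov_odd, cov_rest - 0.2)
})

test_that("group size below three is refused", {
  s <- series_from_truth(typical_params())
  expect_error(loocv(list(a = s, b = s), model_variant("exponential")),
               ">= 3")
})

test_that("LOOCV summaries tabulate coverage by condition and recovery", {
  truth <- typical_params(f_r = 0.05, g_r = 0.03, t_r = 80)
  group <- lapply(1:4, function(i)
    series_from_truth(truth, "exponential", noise_sd = 100, seed = 900 + i,
                      well_id = paste0("w", i)))
  names(group) <- paste0("w", 1:4)
  out <- loocv(group, model_variant("exponential"),
               t_r_inputs = setNames(rep(80, 4), names(group)),
               n_starts = 4, seed = 5)
  tab <- loocv_summary(list(demo = out))
  expect_true("demo" %in% tab$condition)
  expect_true(all(tab$pct_within_ci >= 0 & tab$pct_within_ci <= 100))
  expect_equal(tab$points_evaluated[tab$condition == "demo"], out$n_points)
})
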