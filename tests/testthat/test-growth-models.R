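test_that("death rate forms evaluate correctly at landmarks", {
  p <- typical_params(g_0 = 0.03, k_d = 0.05, t_d = 40)
  # at drug onset the population is still growing at g_0
  expect_equal(death_rate(0, p, "exponential"), -0.03)
  expect_equal(death_rate(0, p, "linear"), -0.03)
  # long-time limits reach the maximum death rate
  expect_equal(death_rate(1e6, p, "exponential"), 0.05, tolerance = 1e-10)
  expect_equal(death_rate(40, p, "linear"), 0.05)
  expect_equal(death_rate(100, p, "linear"), 0.05)
  # mid-ramp value of the linear form: k_d - (g_0 + k_d)/2
  expect_equal(death_rate(20, p, "linear"), 0.05 - 0.08 * 0.5)
  expect_equal(death_rate(c(0, 10, 20), p, "constant"), rep(0.05, 3))
  expect_error(death_rate(-1, p, "constant"), "t >= 0")
})

test_that("death rate is continuous across the ramp for delayed forms", {
  p <- typical_params(t_d = 30)
  tt <- seq(29.9, 30.1, by = 0.01)
  for (form in c("exponential", "linear")) {
    k <- death_rate(tt, p, form)
    expect_lt(max(abs(diff(k))), 1e-3)
  }
})

test_that("pure sensitive decay matches closed forms", {
  # constant k: plain exponential decay
  p <- model_params(0, 0, 0, k_d = 0.02, t_d = 1, g_0 = 0, N_max = 1e9,
                    N0 = 1000)
  tr <- simulate_trajectory(p, model_variant("constant"), seq(0, 50, 1))
  expect_equal(tr$N[tr$time_h == 50], 1000 * exp(-1), tolerance = 1e-10)
  # exponential death delay: analytic quadrature of the kill kernel
  p2 <- model_params(0, 0, 0, k_d = 0.05, t_d = 40, g_0 = 0.03, N_max = 1e9,
                     N0 = 2000)
  tt <- seq(0, 400, 4)
  tr2 <- simulate_trajectory(p2, model_variant("exponential"), tt)
  S_exact <- 2000 * exp(-0.05 * tt + (0.03 + 0.05) * 40 * (1 - exp(-tt / 40)))
  expect_equal(tr2$S, S_exact, tolerance = 1e-12)
  expect_equal(tr2$N, S_exact, tolerance = 1e-12)
})

test_that("pure resistant logistic growth matches the exponential limit", {
  p <- model_params(1, 0.02, 0, 0.01, 1, 0, N_max = 1e9, N0 = 1000)
  tr <- simulate_trajectory(p, model_variant("constant"), seq(0, 50, 1))
  expect_equal(tr$N[51], 1000 * exp(1), tolerance = 1e-4)
})

test_that("trajectories conserve N = S + R and respect compartment signs", {
  set.seed(7)
  ranges <- parameter_ranges()
  for (i in 1:10) {
    truth <- draw_parameters(ranges, tr_nonzero = TRUE)
    form <- sample(c("exponential", "linear", "constant"), 1)
    tr <- simulate_trajectory(truth, model_variant(form), default_grid())
    expect_equal(tr$N, tr$S + tr$R, tolerance = 1e-12)
    expect_true(all(tr$S >= 0) && all(tr$R >= 0))
    # R constant during the arrest period
    pre <- tr$R[tr$time_h < truth$t_r]
    if (length(pre) > 1)
      expect_equal(max(abs(diff(pre))), 0)
  }
})

test_that("f_r = 0 with always-positive kill rate gives decreasing N", {
  p <- model_params(0, 0, 0, k_d = 0.05, t_d = 1, g_0 = 0, N_max = 1e9,
                    N0 = 2000)
  tr <- simulate_trajectory(p, model_variant("constant"), default_grid(400))
  expect_true(all(diff(tr$N) < 0))
})

test_that("integrator matches fine-grid forward Euler on random draws", {
  set.seed(11)
  ranges <- parameter_ranges()
  for (i in 1:8) {
    truth <- draw_parameters(ranges, tr_nonzero = (i %% 2 == 0))
    form <- c("exponential", "linear", "constant")[(i %% 3) + 1]
    tt <- default_grid(320, 8)
    fast <- simulate_trajectory(truth, model_variant(form), tt)
    ref <- euler_oracle(truth, form, tt, h = 0.01)
    rel <- abs(fast$N - ref$N) / pmax(ref$N, 1)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("default integrator agrees with the adaptive lsoda path", {
  set.seed(13)
  ranges <- parameter_ranges()
  for (form in c("exponential", "linear", "constant")) {
    truth <- draw_parameters(ranges, tr_nonzero = TRUE)
    tt <- default_grid()
    a <- simulate_trajectory(truth, model_variant(form), tt)
    b <- simulate_trajectory(truth, model_variant(form), tt, method = "lsoda")
    expect_lt(max(abs(a$N - b$N) / pmax(b$N, 1)), 1e-5)
  }
})

test_that("exponential death delay converges to constant-k as t_d -> 0", {
  base <- typical_params()
  tt <- default_grid()
  ref <- simulate_trajectory(base, model_variant("constant"), tt)
  small <- typical_params(t_d = 1e-4)
  tr <- simulate_trajectory(small, model_variant("exponential"), tt, h_max = 0.05)
  expect_lt(max(abs(tr$N - ref$N) / pmax(ref$N, 1)), 1e-3)
})

test_that("critical time follows the first-crossing rule", {
  traj <- data.frame(time_h = c(0, 24, 48), N = c(1000, 1500, 2100))
  ct <- critical_time_of_trajectory(traj, 1000)
  expect_equal(ct$critical_time_h, 48)
  expect_false(ct$non_recovering)
})

test_that("pure decay never reaches doubling and is non-recovering", {
  p <- model_params(0, 0, 0, k_d = 0.03, t_d = 1, g_0 = 0, N_max = 1e9,
                    N0 = 2000)
  tr <- simulate_trajectory(p, model_variant("constant"), default_grid())
  ct <- critical_time_of_trajectory(tr, 2000, params = p,
                                    variant = model_variant("constant"))
  expect_true(ct$non_recovering)
  expect_true(is.na(ct$critical_time_h))
})

test_that("simulated logistic crossing matches the analytic doubling time", {
  # f_r = 1, t_r = 0: N follows pure logistic growth with known crossing time
  g_r <- 0.02; N0 <- 2000; N_max <- 3e4
  p <- model_params(1, g_r, 0, 0.01, 1, 0, N_max, N0)
  tt <- default_grid(800, 4)
  tr <- simulate_trajectory(p, model_variant("constant"), tt)
  t_star <- (1 / g_r) * log(2 * (N_max - N0) / (N_max - 2 * N0))
  ct <- critical_time_of_trajectory(tr, N0)
  expect_lte(abs(ct$critical_time_h - t_star), 4)  # within one grid step
})

test_that("projection extends past the recorded horizon to one year", {
  p <- typical_params(f_r = 0.001, g_r = 0.006, t_r = 300)
  tt <- default_grid(720)
  tr <- simulate_trajectory(p, model_variant("exponential"), tt)
  expect_true(all(tr$N < 2 * p$N0))  # no crossing within the record
  ct <- critical_time_of_trajectory(tr, p$N0, params = p,
                                    variant = model_variant("exponential"))
  expect_false(ct$non_recovering)
  expect_equal(ct$source, "projected")
  expect_gt(ct$critical_time_h, 720)
  expect_lte(ct$critical_time_h, 8760)
})

test_that("trajectory CSV round-trips", {
  p <- typical_params()
  tr <- simulate_trajectory(p, model_variant("exponential"), default_grid(100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories_csv(list(a = tr), path)
  back <- read.csv(path)
  expect_equal(back$N, tr$N)
  expect_equal(unique(back$well_id), "a")
})
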