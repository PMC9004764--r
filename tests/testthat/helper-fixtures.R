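# Shared fixtures built in code at test time.

default_grid <- function(t_end = 720, dt = 4) seq(0, t_end, by = dt)

typical_params <- function(...) {
  p <- list(f_r = 0.05, g_r = 0.025, t_r = 150, k_d = 0.06, t_d = 30,
            g_0 = 0.02, N_max = 4e4, N0 = 2000)
  p[names(list(...))] <- list(...)
  do.call(model_params, p)
}

# noiseless series simulated from known truth
series_from_truth <- function(truth, k_form = "exponential", t_end = 720,
                              dt = 4, noise_sd = 0, seed = NULL,
                              well_id = "w1") {
  if (!is.null(seed)) set.seed(seed)
  grid <- default_grid(t_end, dt)
  traj <- simulate_trajectory(truth, model_variant(k_form), grid)
  counts <- traj$N
  if (noise_sd > 0) counts <- pmax(0, counts + rnorm(length(grid), 0, noise_sd))
  count_series(well_id, grid, counts)
}

# forward-Euler oracle on the full coupled system, fixed fine step
euler_oracle <- function(params, k_form, times, h = 0.01) {
  S <- (1 - params$f_r) * params$N0
  R <- params$f_r * params$N0
  out_S <- numeric(length(times)); out_R <- numeric(length(times))
  out_S[1] <- S; out_R[1] <- R
  kf <- function(t) {
    kd <- params$k_d; td <- params$t_d; g0 <- params$g_0
    switch(k_form,
           exponential = kd - (g0 + kd) * exp(-t / td),
           linear = if (t < td) kd - (g0 + kd) * (1 - t / td) else kd,
           constant = kd)
  }
  ti <- 2
  t <- times[1]
  while (ti <= length(times)) {
    h_step <- min(h, times[ti] - t)
    grow <- if (t >= params$t_r) 1 else 0
    dR <- params$g_r * R * (1 - (R + S) / params$N_max) * grow
    dS <- -kf(t) * S
    S <- S + h_step * dS
    R <- R + h_step * dR
    t <- t + h_step
    if (abs(t - times[ti]) < 1e-9) {
      out_S[ti] <- S; out_R[ti] <- R
      ti <- ti + 1
    }
  }
  data.frame(time_h = times, S = out_S, R = out_R, N = out_S + out_R)
}

# brute-force density-reachability clustering oracle (small inputs only)
dbscan_oracle <- function(points, eps, min_pts) {
  n <- nrow(points)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(points))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  # density-connected components over core points, then attach border points
  labels <- integer(n)
  cl <- 0L
  repeat {
    seed_pt <- which(core & labels == 0L)
    if (length(seed_pt) == 0) break
    cl <- cl + 1L
    members <- seed_pt[1]
    repeat {
      grown <- unique(unlist(nb[members[core[members]]]))
      grown <- union(members, grown)
      if (length(grown) == length(members)) break
      members <- grown
    }
    labels[members[labels[members] == 0L]] <- cl
  }
  labels
}
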