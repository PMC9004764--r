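#' Default physiological parameter ranges
#'
#' Uniform sampling bounds used both to generate identifiability datasets and
#' (widened) as calibration bounds. The defaults describe wells seeded at
#' about 2,000 cells that reach confluence of a few times 10^4 cells in
#' roughly four days untreated, die at up to 0.1/h under drug, and arrest for
#' 50-400 h when a proliferation delay is present.
#'
#' @param f_r,g_r,t_r,k_d,t_d,g_0,N_max Numeric `c(low, high)` bounds.
#' @param N0 Initial cell count (fixed, not sampled, by default).
#' @return An object of class `parameter_ranges` (named list of 2-vectors,
#'   plus scalar `N0`).
#' @export
parameter_ranges <- function(f_r = c(1e-3, 0.3),
                             g_r = c(0.005, 0.04),
                             t_r = c(50, 400),
                             k_d = c(0.005, 0.10),
                             t_d = c(5, 100),
                             g_0 = c(0.005, 0.04),
                             N_max = c(2e4, 6e4),
                             N0 = 2000) {
  r <- list(f_r = f_r, g_r = g_r, t_r = t_r, k_d = k_d, t_d = t_d,
            g_0 = g_0, N_max = N_max, N0 = N0)
  for (nm in setdiff(names(r), "N0")) {
    b <- r[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] > b[2])
      stop("invalid bounds for ", nm, call. = FALSE)
  }
  structure(r, class = "parameter_ranges")
}

#' Identifiability dataset specification
#'
#' The identifiability study uses six datasets labelled A-F, one for each
#' combination of ground-truth death-delay form (exponential, linear,
#' constant) and presence of a proliferation delay. Labels A-C have
#' `t_r = 0`; D-F have `t_r > 0` drawn from its range.
#'
#' @param label One of `"A"`..`"F"`; fixes `k_form` and `tr_nonzero`.
#' @param n_series Number of time series to generate.
#' @param noise_frac Additive Gaussian noise sd, as a fraction of the
#'   initial (seeding) cell count; the noise is homoscedastic along the
#'   series, as for a counting error fixed by the imaging setup.
#' @param seed Integer seed.
#' @param t_end,dt Sampling grid: `seq(0, t_end, dt)` hours.
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(label, n_series = 1000, noise_frac = 0.01,
                         seed = 1L, t_end = 720, dt = 4) {
  tab <- dataset_label_table()
  if (!label %in% tab$label) stop("label must be one of A..F", call. = FALSE)
  row <- tab[tab$label == label, ]
  structure(list(label = label, k_form = row$k_form,
                 tr_nonzero = row$tr_nonzero, n_series = n_series,
                 noise_frac = noise_frac, seed = as.integer(seed),
                 t_end = t_end, dt = dt),
            class = "dataset_spec")
}

#' Bijection between dataset labels A-F and generating assumptions
#' @return Data frame with columns `label`, `k_form`, `tr_nonzero`.
#' @export
dataset_label_table <- function() {
  data.frame(label = LETTERS[1:6],
             k_form = rep(c("exponential", "linear", "constant"), 2),
             tr_nonzero = rep(c(FALSE, TRUE), each = 3))
}

#' Draw one ground-truth parameter set
#'
#' Independent uniform draws within the given bounds; `t_r` is forced to 0
#' when the dataset assumes no proliferation delay.
#'
#' @param ranges A [parameter_ranges()].
#' @param tr_nonzero Logical; draw `t_r` from its range (else 0).
#' @return A [model_params()] object.
#' @export
draw_parameters <- function(ranges, tr_nonzero = TRUE) {
  u <- function(b) stats::runif(1, b[1], b[2])
  model_params(f_r = u(ranges$f_r),
               g_r = u(ranges$g_r),
               t_r = if (tr_nonzero) u(ranges$t_r) else 0,
               k_d = u(ranges$k_d),
               t_d = u(ranges$t_d),
               g_0 = u(ranges$g_0),
               N_max = u(ranges$N_max),
               N0 = ranges$N0)
}

#' Generate an identifiability dataset with known ground truth
#'
#' Each series is a noiseless model trajectory sampled on the configured grid
#' plus i.i.d. additive Gaussian measurement noise (sd = `noise_frac` times
#' the seeding count), floored at 0 cells.
#'
#' @param spec A [dataset_spec()].
#' @param ranges A [parameter_ranges()].
#' @return A list with elements `spec` and `series`; `series` is a list of
#'   `list(truth = model_params, series = count_series)`.
#' @export
generate_dataset <- function(spec, ranges = parameter_ranges()) {
  set.seed(spec$seed)
  grid <- seq(0, spec$t_end, by = spec$dt)
  variant <- model_variant(spec$k_form, "input", "calibrated")
  out <- vector("list", spec$n_series)
  for (i in seq_len(spec$n_series)) {
    truth <- draw_parameters(ranges, spec$tr_nonzero)
    traj <- simulate_trajectory(truth, variant, grid)
    sd_i <- spec$noise_frac * truth$N0
    counts <- pmax(0, traj$N + stats::rnorm(length(grid), 0, sd_i))
    out[[i]] <- list(
      truth = truth,
      series = count_series(sprintf("%s%04d", spec$label, i), grid, counts))
  }
  list(spec = spec, series = out)
}

#' Generate a synthetic experiment plate
#'
#' Emulates a longitudinal drug-response experiment: wells seeded near 2,000
#' cells (with 10\% jitter), each treatment group drawing its ground-truth
#' parameters from a configured distribution, a configured probability of a
#' non-recovering well (`f_r = 0`), and optional injected media-handling
#' count discontinuities (multiplicative drop at a given time) for
#' preprocessing tests.
#'
#' @param schedule_map Named list of treatment groups. Each element is a list
#'   with fields `ranges` (a [parameter_ranges()]), `p_nonrecovering`
#'   (probability in `[0,1]`), optional `tr_nonzero` (default `TRUE`),
#'   optional `k_form` (default `"exponential"`), and optional `drop` (a list
#'   `list(time_h=, factor=)` injecting a multiplicative discontinuity).
#' @param n_replicates Wells per group.
#' @param noise_frac Measurement noise sd as a fraction of the seeding
#'   count (homoscedastic).
#' @param t_end,dt Sampling grid (hours).
#' @param seed Integer seed.
#' @return A list of wells; each is `list(well_id, group, truth,
#'   non_recovering, t_r, series)`.
#' @export
generate_plate <- function(schedule_map, n_replicates = 12,
                           noise_frac = 0.01, t_end = 720, dt = 4,
                           seed = 1L) {
  if (length(schedule_map) == 0) stop("schedule_map is empty", call. = FALSE)
  set.seed(seed)
  grid <- seq(0, t_end, by = dt)
  wells <- list()
  for (gname in names(schedule_map)) {
    g <- schedule_map[[gname]]
    k_form <- g$k_form %||% "exponential"
    tr_nonzero <- g$tr_nonzero %||% TRUE
    variant <- model_variant(k_form, "input", "calibrated")
    for (r in seq_len(n_replicates)) {
      truth <- draw_parameters(g$ranges, tr_nonzero)
      truth$N0 <- g$ranges$N0 * stats::runif(1, 0.9, 1.1)
      nonrec <- stats::runif(1) < g$p_nonrecovering
      if (nonrec) {
        truth$f_r <- 0
        truth$g_r <- 0
      }
      validate_model_params(truth)
      traj <- simulate_trajectory(truth, variant, grid)
      sd_i <- noise_frac * truth$N0
      counts <- pmax(0, traj$N + stats::rnorm(length(grid), 0, sd_i))
      if (!is.null(g$drop)) {
        before <- grid < g$drop$time_h
        counts[before] <- counts[before] / g$drop$factor
      }
      id <- sprintf("%s_w%02d", gname, r)
      wells[[id]] <- list(well_id = id, group = gname, truth = truth,
                          non_recovering = nonrec, t_r = truth$t_r,
                          series = count_series(id, grid, counts))
    }
  }
  wells
}

#' Generate synthetic nuclei-centroid frames
#'
#' Emulates per-frame nuclei centroid lists around a proliferation-delay
#' event: before `t_r` a sparse, spatially uniform background of
#' arrested/dying cells whose count decays; from `t_r` onward a compact
#' Gaussian cluster appears at a random location and its point count doubles
#' every `doubling_h` hours.
#'
#' @param t_r Onset of regrowth (hours after treatment).
#' @param frame_interval Hours between frames.
#' @param t_end Last frame time (hours).
#' @param arena Side length of the square field of view (microns).
#' @param n_background Initial number of background nuclei.
#' @param background_halflife Decay half-life of the background count (hours).
#' @param cluster_sd Cluster spatial spread (microns).
#' @param cluster_start Cluster size at onset (points).
#' @param doubling_h Cluster doubling time (hours).
#' @param seed Integer seed.
#' @return A `frame_set`: list with `times` and `frames` (list of two-column
#'   matrices of centroids in microns).
#' @export
generate_frames <- function(t_r, frame_interval = 4, t_end = 480,
                            arena = 1200, n_background = 40,
                            background_halflife = 150, cluster_sd = 25,
                            cluster_start = 12, doubling_h = 48, seed = 1L) {
  stopifnot(t_r >= 0)
  set.seed(seed)
  times <- seq(0, t_end, by = frame_interval)
  center <- stats::runif(2, 0.25 * arena, 0.75 * arena)
  frames <- lapply(times, function(t) {
    nb <- stats::rpois(1, n_background * 2^(-t / background_halflife))
    pts <- cbind(stats::runif(nb, 0, arena), stats::runif(nb, 0, arena))
    if (t >= t_r) {
      nc <- round(cluster_start * 2^((t - t_r) / doubling_h))
      cl <- cbind(stats::rnorm(nc, center[1], cluster_sd),
                  stats::rnorm(nc, center[2], cluster_sd))
      pts <- rbind(pts, cl)
    }
    colnames(pts) <- c("x_um", "y_um")
    pts
  })
  structure(list(times = times, frames = frames), class = "frame_set")
}

#' Write a list of wells to a counts CSV
#' @param wells Output of [generate_plate()] (or any list with `series`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(wells, path) {
  rows <- do.call(rbind, lapply(wells, function(w) {
    s <- w$series
    data.frame(well_id = s$well_id, time_h = s$times, count = s$counts)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a frame set to a frames CSV
#' @param well_id Well identifier recorded in the CSV.
#' @param fs A `frame_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frames_csv <- function(well_id, fs, path) {
  rows <- do.call(rbind, lapply(seq_along(fs$times), function(i) {
    p <- fs$frames[[i]]
    if (nrow(p) == 0) return(NULL)
    data.frame(well_id = well_id, time_h = fs$times[i],
               x_um = p[, 1], y_um = p[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
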