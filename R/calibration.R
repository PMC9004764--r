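#' Classify a well as recovering or non-recovering
#'
#' A well has recovered when a sustained rise follows the series minimum:
#' at least `k` points come after the minimum, the robust (Theil-Sen) slope
#' of the post-minimum segment is positive, and the final count exceeds the
#' minimum by at least `rise_fraction` (and by a small absolute floor,
#' `rise_floor_frac` of the initial count, so that noise around an empty well
#' is not mistaken for regrowth). The minimum is located on a 3-point running
#' median so single-frame dropouts do not anchor it.
#'
#' @param series A preprocessed [count_series()].
#' @param k Minimum number of post-minimum points.
#' @param rise_fraction Required relative rise above the minimum.
#' @param rise_floor_frac Required absolute rise, as a fraction of the first
#'   count.
#' @return `TRUE` (recovering), `FALSE` (non-recovering), or `NA` if the
#'   series is too short to judge.
#' @export
classify_recovery <- function(series, k = 5, rise_fraction = 0.2,
                              rise_floor_frac = 0.02) {
  N <- series$counts
  n <- length(N)
  if (n < k + 2) return(NA)
  sm <- stats::runmed(N, 3)
  i_min <- which.min(sm)
  tail_idx <- i_min:n
  if (length(tail_idx) < k + 1) return(FALSE)
  slope <- theil_sen_slope(series$times[tail_idx], N[tail_idx])
  minval <- sm[i_min]
  final <- stats::median(N[max(1, n - 2):n])
  rise_ok <- final >= (1 + rise_fraction) * minval &&
    (final - minval) >= rise_floor_frac * N[1]
  isTRUE(slope > 0 && rise_ok)
}

# median of pairwise slopes; subsamples long series for speed
theil_sen_slope <- function(x, y, max_points = 60) {
  n <- length(x)
  if (n > max_points) {
    keep <- round(seq(1, n, length.out = max_points))
    x <- x[keep]; y <- y[keep]
    n <- max_points
  }
  cmb <- utils::combn(n, 2)
  stats::median((y[cmb[2, ]] - y[cmb[1, ]]) / (x[cmb[2, ]] - x[cmb[1, ]]))
}

default_calibration_bounds <- function(ranges = parameter_ranges(),
                                       t_max = 720) {
  # generating ranges widened x2 on each side (fractions capped at their
  # natural limits); positive lower bounds are kept so rate-like parameters
  # can be optimized on the log scale
  widen <- function(b, lo_min = 0, hi_max = Inf)
    c(max(lo_min, b[1] / 2), min(hi_max, b[2] * 2))
  list(f_r = c(max(1e-4, ranges$f_r[1] / 2), min(1, ranges$f_r[2] * 2)),
       g_r = widen(ranges$g_r),
       t_r = c(0, t_max),
       k_d = widen(ranges$k_d),
       t_d = c(max(0.5, ranges$t_d[1] / 2), ranges$t_d[2] * 2),
       g_0 = widen(ranges$g_0),
       N_max = widen(ranges$N_max))
}

# parameters optimized on the log10 scale (positive, span decades);
# t_r stays linear (its lower bound is 0)
LOG_SCALE_PARAMS <- c("f_r", "g_r", "k_d", "t_d", "g_0", "N_max")

to_opt_scale <- function(x, nm) ifelse(nm %in% LOG_SCALE_PARAMS, log10(x), x)
from_opt_scale <- function(x, nm) ifelse(nm %in% LOG_SCALE_PARAMS, 10^x, x)

#' Fit a model variant to one count series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) on raw counts,
#' `sum_i (N_model(t_i) - N_i)^2`, over the variant's free parameters, on
#' the log10 scale for the positive parameters. Global search combines a
#' data-driven heuristic start, an RSS-screened Latin-hypercube pool, and
#' (for the delay forms) a profile pass over pinned `t_d` values; the best
#' residual sum of squares wins. `N0` is fixed to the first observed count.
#' Non-recovering series are fitted with `f_r` and `g_r` frozen at zero
#' (only the death-side parameters are free).
#'
#' @param series A preprocessed [count_series()].
#' @param variant A [model_variant()].
#' @param t_r_input Measured proliferation delay (hours); required when
#'   `variant$tr_mode == "input"` and the series is recovering.
#' @param recovered Logical from [classify_recovery()]; `NA` treated as
#'   recovering.
#' @param bounds Named list of `c(low, high)` per parameter; defaults to the
#'   generating ranges widened x2.
#' @param n_starts Number of multi-start initial points polished by LM.
#' @param screen If `TRUE` (default), rank a large Latin-hypercube pool by
#'   RSS and polish the best `n_starts` points; if `FALSE`, polish the
#'   data-driven heuristic start plus unscreened Latin-hypercube points.
#' @param extra_starts Optional list of additional start points, each a
#'   named list/vector covering (at least) the variant's free parameters —
#'   e.g. the solution of a related variant, whose optimum is usually an
#'   excellent start for this one.
#' @param nmax_fixed Carrying capacity used when `variant$nmax_mode ==
#'   "fixed"` (cells).
#' @param seed Seed for the Latin-hypercube start sample.
#' @param h_max Integrator sub-step (hours); passed to
#'   [simulate_trajectory()].
#' @return A `calibration_result`: list with `variant`, `params`
#'   ([model_params()]), `rss`, `n`, `p`, `aic`, `recovered`, `converged`,
#'   `n_starts_used`.
#' @export
calibrate <- function(series, variant, t_r_input = NULL, recovered = TRUE,
                      bounds = NULL, n_starts = 20, screen = TRUE,
                      extra_starts = NULL, nmax_fixed = 30000, seed = 1L,
                      h_max = 1) {
  tt <- series$times
  N <- series$counts
  n <- length(N)
  if (n < 5) stop("series too short to calibrate", call. = FALSE)
  if (is.na(recovered)) recovered <- TRUE
  if (variant$tr_mode == "input" && recovered && is.null(t_r_input))
    stop("variant with tr_mode='input' requires t_r_input", call. = FALSE)
  if (is.null(bounds))
    bounds <- default_calibration_bounds(t_max = max(tt))
  N0 <- max(N[1], 1)
  free <- free_param_names(variant, recovered = recovered)
  lower <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))
  lo_t <- to_opt_scale(lower, free)
  up_t <- to_opt_scale(upper, free)

  fixed_tr <- switch(variant$tr_mode,
                     input = if (recovered) t_r_input else 0,
                     zero = 0, calibrated = NA_real_)
  tr_guess <- if (is.finite(fixed_tr %||% NA_real_)) fixed_tr else 0
  build_params <- function(th) {
    g <- function(nm, default) if (nm %in% free) th[[nm]] else default
    model_params(
      f_r = if (recovered) g("f_r", 0) else 0,
      g_r = if (recovered) g("g_r", 0) else 0,
      t_r = if ("t_r" %in% free) th[["t_r"]] else fixed_tr,
      k_d = g("k_d", 0.02),
      t_d = g("t_d", 1),
      g_0 = g("g_0", 0),
      N_max = max(if ("N_max" %in% free) th[["N_max"]] else nmax_fixed,
                  N0 + 1),
      N0 = N0)
  }
  resid_fn <- function(th_t) {
    th <- from_opt_scale(th_t, free)
    names(th) <- free
    p <- build_params(as.list(th))
    m <- .sim_rs_cpp(tt, p$f_r, p$g_r, p$t_r, p$k_d, p$t_d, p$g_0,
                     p$N_max, p$N0, k_form_code(variant$k_form), h_max)
    m[, 3] - N
  }
  run_lm <- function(start, lo = lo_t, up = up_t, maxiter = 200) {
    st <- pmin(pmax(to_opt_scale(start, free), lo), up)
    tryCatch(
      suppressWarnings(  # exploratory starts may legitimately hit maxiter
        minpack.lm::nls.lm(par = st, lower = lo, upper = up,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-10, ptol = 1e-10,
                             maxiter = maxiter))),
      error = function(e) NULL)
  }

  if (screen) {
    # global screening: score a large Latin-hypercube pool by RSS (one cheap
    # simulation each) and polish only the most promising points with LM
    n_pool <- 40L + 15L * length(free)
    pool <- calibration_starts(free, lower, upper, series, n_pool, seed,
                                 t_r_guess = tr_guess)
    pool_rss <- vapply(pool, function(st)
      sum(resid_fn(pmin(pmax(to_opt_scale(st, free), lo_t), up_t))^2),
      numeric(1))
    # polish a rank-stratified subset: the best-scoring points find the
    # dominant basin quickly, while points spread across the ranking keep
    # basin diversity (pure greedy screening can drop every start into one
    # shallow local basin)
    ord <- order(pool_rss)
    n_top <- min(max(2L, ceiling(n_starts / 3)), n_starts)
    keep <- ord[seq_len(n_top)]
    if (n_starts > n_top) {
      strat <- ord[unique(round(seq(n_top + 1, ceiling(0.7 * n_pool),
                                    length.out = n_starts - n_top)))]
      keep <- c(keep, strat)
    }
    starts <- pool[keep[seq_len(min(n_starts, length(keep)))]]
    # the death-delay landscape is multimodal along t_d (confounded with
    # k_d and g_0); profile the objective over a log grid of pinned t_d
    # values (inner LM over the remaining parameters), then release t_d
    # from the best profile points during the main polish
    if ("t_d" %in% free) {
      h <- heuristic_start(free, lower, upper, series,
                           t_r_guess = tr_guess) %||% starts[[1]]
      i_td <- match("t_d", free)
      td_grid <- 10^seq(log10(lower[["t_d"]]), log10(upper[["t_d"]]),
                        length.out = 8)
      prof <- lapply(td_grid, function(td) {
        st <- h
        st[["t_d"]] <- td
        lo_p <- lo_t; up_p <- up_t
        lo_p[i_td] <- up_p[i_td] <- log10(td)
        fit <- run_lm(st, lo_p, up_p, maxiter = 60)
        if (is.null(fit)) return(NULL)
        list(par = stats::setNames(from_opt_scale(fit$par, free), free),
             rss = sum(fit$fvec^2))
      })
      prof <- prof[!vapply(prof, is.null, logical(1))]
      if (length(prof) > 0) {
        ord_p <- order(vapply(prof, function(p) p$rss, numeric(1)))
        prof_starts <- lapply(prof[ord_p[seq_len(min(3, length(prof)))]],
                              function(p) p$par)
        n_keep <- max(n_starts - length(prof_starts), 2L)
        starts <- c(prof_starts, starts[seq_len(min(n_keep, length(starts)))])
      }
    }
  } else {
    # plain multi-start: the data-driven heuristic start first, then
    # unscreened Latin-hypercube points
    starts <- calibration_starts(free, lower, upper, series,
                                 max(n_starts - 1L, 1L), seed,
                                 t_r_guess = tr_guess)
    starts <- starts[seq_len(min(n_starts, length(starts)))]
  }
  if (!is.null(extra_starts)) {
    conv <- lapply(extra_starts, function(es) {
      es <- unlist(es)
      if (!all(free %in% names(es))) return(NULL)
      stats::setNames(pmin(pmax(es[free], lower), upper), free)
    })
    starts <- c(conv[!vapply(conv, is.null, logical(1))], starts)
  }
  best <- NULL
  n_used <- 0L
  for (st in starts) {
    n_used <- n_used + 1L
    fit <- run_lm(st)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(variant = variant, params = NULL, rss = NA_real_,
                          n = n, p = length(free), aic = NA_real_,
                          recovered = recovered, converged = FALSE,
                          n_starts_used = n_used),
                     class = "calibration_result"))
  }
  th <- as.list(stats::setNames(from_opt_scale(best$fit$par, free), free))
  params <- build_params(th)
  p_free <- length(free)
  structure(list(variant = variant, params = params, rss = best$rss,
                 n = n, p = p_free,
                 aic = compute_aic(best$rss, n, p_free),
                 recovered = recovered,
                 converged = best$fit$info %in% 1:4,
                 n_starts_used = n_used),
            class = "calibration_result")
}

# Latin-hypercube candidate points within bounds (log-uniform for rate-like
# parameters), plus a data-driven heuristic start: before saturation the
# no-delay model is bi-exponential, N(t) ~ N0[(1-f_r)e^(-k t) + f_r e^(g_r t)],
# so a log-linear fit to the regrowth tail estimates f_r and g_r and the
# early decay estimates k_d.
calibration_starts <- function(free, lower, upper, series, n_starts, seed,
                               t_r_guess = 0) {
  n_lhs <- max(n_starts, 1L)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  u <- lhs::randomLHS(n_lhs, length(free))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  lo_t <- to_opt_scale(lower, free)
  up_t <- to_opt_scale(upper, free)
  starts <- lapply(seq_len(n_lhs), function(i)
    stats::setNames(from_opt_scale(lo_t + u[i, ] * (up_t - lo_t), free),
                    free))
  h <- heuristic_start(free, lower, upper, series, t_r_guess = t_r_guess)
  if (!is.null(h)) starts <- c(list(h), starts)
  starts
}

heuristic_start <- function(free, lower, upper, series, t_r_guess = 0) {
  N <- series$counts
  tt <- series$times
  n <- length(N)
  if (n < 10) return(NULL)
  clamp <- function(x, nm) {
    if (!is.finite(x)) x <- sqrt(lower[[nm]] * max(upper[[nm]], 1e-12))
    min(max(x, lower[[nm]]), upper[[nm]])
  }
  h <- stats::setNames(from_opt_scale(
    (to_opt_scale(lower, free) + to_opt_scale(upper, free)) / 2, free), free)
  sm <- pmax(stats::runmed(N, 3), 0.5)
  logN <- log(sm)
  i_min <- which.min(sm)
  # early decay: log-slope over the first points down to the minimum
  early <- seq_len(max(min(i_min, 12L), 4L))
  sl_early <- stats::coef(stats::lm(logN[early] ~ tt[early]))[2]
  if ("k_d" %in% free) h[["k_d"]] <- clamp(-sl_early, "k_d")
  if ("g_0" %in% free) h[["g_0"]] <- clamp(abs(sl_early), "g_0")
  # regrowth: steepest windowed log-slope after the minimum estimates g_r;
  # back-extrapolating that window to the end of arrest estimates f_r
  # (tail-only fits fail once the series saturates at carrying capacity)
  if (all(c("f_r", "g_r") %in% free) && n - i_min >= 8) {
    w <- 8L
    idx <- i_min:(n - w)
    if (length(idx) >= 1) {
      slopes <- vapply(idx, function(i) {
        j <- i:(i + w)
        stats::coef(stats::lm(logN[j] ~ tt[j]))[2]
      }, numeric(1))
      i_best <- idx[which.max(slopes)]
      g_est <- max(slopes)
      if (is.finite(g_est) && g_est > 0) {
        h[["g_r"]] <- clamp(g_est, "g_r")
        t_mid <- tt[i_best + w %/% 2]
        N_mid <- sm[i_best + w %/% 2]
        f_est <- N_mid * exp(-g_est * (t_mid - t_r_guess)) / max(N[1], 1)
        h[["f_r"]] <- clamp(f_est, "f_r")
      }
    }
  }
  if ("N_max" %in% free)
    h[["N_max"]] <- clamp(1.5 * max(N), "N_max")
  h
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration (%s k, t_r %s, N_max %s): rss = %.4g, n = %d, p = %d, AIC = %.2f\n",
              x$variant$k_form, x$variant$tr_mode, x$variant$nmax_mode,
              x$rss, x$n, x$p, x$aic))
  cat(sprintf("  recovered = %s, converged = %s (%d starts)\n",
              x$recovered, x$converged, x$n_starts_used))
  invisible(x)
}

#' Calibration results table
#' @param results List of `calibration_result` objects, optionally named by
#'   well id.
#' @return Data frame with one row per result: well id, variant fields,
#'   parameters, rss, n, p, aic, recovered, converged.
#' @export
calibration_table <- function(results) {
  ids <- names(results) %||% as.character(seq_along(results))
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    p <- r$params
    data.frame(well_id = ids[i], k_form = r$variant$k_form,
               tr_mode = r$variant$tr_mode, nmax_mode = r$variant$nmax_mode,
               f_r = p$f_r %||% NA, g_r = p$g_r %||% NA,
               t_r = p$t_r %||% NA, k_d = p$k_d %||% NA,
               t_d = p$t_d %||% NA, g_0 = p$g_0 %||% NA,
               N_max = p$N_max %||% NA, N0 = p$N0 %||% NA,
               rss = r$rss, n = r$n, p = r$p, aic = r$aic,
               recovered = r$recovered, converged = r$converged)
  }))
}
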