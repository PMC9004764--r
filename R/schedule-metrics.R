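#' Critical time for one well
#'
#' The critical time is when a population first reaches twice its count at
#' the start of the final drug exposure. If the observed series crosses the
#' doubling level, the observed crossing time is returned; otherwise the
#' fitted model of the selected variant is projected out to one year
#' (8760 h) and the projected crossing is used; wells whose projection never
#' doubles within a year are non-recovering.
#'
#' @param series A preprocessed [count_series()].
#' @param fit The selected variant's `calibration_result` for this well.
#' @param grid_h Projection grid spacing (hours).
#' @return A `critical_time_result`: list with `well_id`,
#'   `critical_time_h` (`NA` when non-recovering), `source` (`"observed"` or
#'   `"projected"`), `non_recovering`.
#' @export
critical_time_for_well <- function(series, fit, grid_h = 4) {
  n0 <- series$counts[series$treatment_time_index]
  hit <- which(series$counts >= 2 * n0)
  if (length(hit) > 0) {
    return(structure(list(well_id = series$well_id,
                          critical_time_h = series$times[hit[1]],
                          source = "observed", non_recovering = FALSE),
                     class = "critical_time_result"))
  }
  if (!is.null(fit$params)) {
    ct <- critical_time_of_trajectory(
      data.frame(time_h = series$times, N = series$counts), n0,
      params = fit$params, variant = fit$variant, grid_h = grid_h)
    return(structure(list(well_id = series$well_id,
                          critical_time_h = ct$critical_time_h,
                          source = ct$source,
                          non_recovering = ct$non_recovering),
                     class = "critical_time_result"))
  }
  structure(list(well_id = series$well_id, critical_time_h = NA_real_,
                 source = "projected", non_recovering = TRUE),
            class = "critical_time_result")
}

#' Fraction of non-recovering replicates in a treatment group
#'
#' @param results List of `critical_time_result` (or any list with a logical
#'   `non_recovering` field) for the group's wells.
#' @return List with `fraction`, `percent`, `n_nonrecovering`, `n`.
#' @export
nonrecovering_fraction <- function(results) {
  if (length(results) == 0) stop("empty group", call. = FALSE)
  nr <- vapply(results, function(r) isTRUE(r$non_recovering), logical(1))
  list(fraction = mean(nr), percent = 100 * mean(nr),
       n_nonrecovering = sum(nr), n = length(nr))
}

#' Compare schedule groups on a critical-time-like metric
#'
#' Computes, per group, the mean over recovering replicates, a percentile
#' bootstrap 95\% confidence interval of that mean, and the percent change
#' relative to a designated reference group.
#'
#' @param groups Named list; each element is a numeric vector of per-well
#'   metric values with `NA` for non-recovering wells (excluded).
#' @param reference Name of the reference group for percent changes.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return Data frame with `group`, `n`, `n_nonrecovering`, `mean`,
#'   `ci_lo`, `ci_hi`, `pct_change_vs_ref`.
#' @export
compare_schedules <- function(groups, reference = names(groups)[1],
                              n_boot = 2000, seed = 1L) {
  stopifnot(length(groups) >= 2, reference %in% names(groups))
  set.seed(seed)
  summ <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    xr <- x[!is.na(x)]
    m <- if (length(xr) > 0) mean(xr) else NA_real_
    if (length(xr) >= 2) {
      boots <- replicate(n_boot, mean(sample(xr, length(xr), replace = TRUE)))
      ci <- stats::quantile(boots, c(0.025, 0.975))
    } else ci <- c(NA_real_, NA_real_)
    data.frame(group = g, n = length(x), n_nonrecovering = sum(is.na(x)),
               mean = m, ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, summ)
  rownames(out) <- NULL
  ref_mean <- out$mean[out$group == reference]
  out$pct_change_vs_ref <- 100 * (out$mean / ref_mean - 1)
  out
}
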