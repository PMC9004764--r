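#' Construct a count series
#'
#' One replicate well's longitudinal cell-count trajectory on a
#' treatment-aligned time axis (t = 0 is the beginning of the final drug
#' exposure).
#'
#' @param well_id Well identifier.
#' @param times Strictly increasing times (hours).
#' @param counts Non-negative cell counts, same length as `times`.
#' @param treatment_time_index Index of the t = 0 alignment point.
#' @return An object of class `count_series`.
#' @export
count_series <- function(well_id, times, counts, treatment_time_index = 1L) {
  if (length(times) != length(counts))
    stop("times and counts must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(well_id = well_id, times = as.numeric(times),
                 counts = as.numeric(counts),
                 treatment_time_index = as.integer(treatment_time_index)),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("count_series '%s': %d points, %.0f-%.0f h, N0 = %.0f\n",
              x$well_id, length(x$times), min(x$times), max(x$times),
              x$counts[1]))
  invisible(x)
}

#' Detect count discontinuities
#'
#' Flags indices where the count jumps away from its local linear trend:
#' index `d` is flagged when the residual between `N_d` and the linear
#' extrapolation from the two preceding points exceeds `theta` times the
#' local noise scale (a robust MAD of one-step extrapolation residuals).
#'
#' A candidate must also jump by at least `min_rel` relative to its predicted
#' value, so that smooth curvature on a low-noise series is never flagged:
#' media-handling events move counts by tens of percent, curvature by a
#' fraction of one.
#'
#' @param series A [count_series()], at least 5 points.
#' @param theta Detection threshold in noise-scale units.
#' @param min_rel Minimum relative deviation from the local trend.
#' @return Integer vector of discontinuity indices (possibly empty).
#' @export
detect_discontinuities <- function(series, theta = 5, min_rel = 0.1) {
  n <- length(series$counts)
  if (n < 5) stop("need at least 5 points", call. = FALSE)
  tt <- series$times; N <- series$counts
  idx <- 3:n
  slope <- (N[idx - 1] - N[idx - 2]) / (tt[idx - 1] - tt[idx - 2])
  pred <- N[idx - 1] + slope * (tt[idx] - tt[idx - 1])
  resid <- N[idx] - pred
  scale <- stats::mad(resid, center = 0)
  if (scale <= 0) scale <- max(1e-8, 1e-6 * max(N))
  rel <- abs(resid) / pmax(abs(pred), 1)
  hits <- idx[abs(resid) > theta * scale & rel > min_rel]
  # a genuine jump also perturbs the extrapolation at the next index;
  # keep only the leading index of adjacent runs
  if (length(hits) > 1) hits <- hits[c(TRUE, diff(hits) > 1)]
  as.integer(hits)
}

#' Truncate a count series
#'
#' Applies the data-quality truncation rules: the series ends at the last
#' point before (i) the count first exceeds `cap` cells, (ii) a single-step
#' relative drop larger than `drop_fraction`, or (iii) the first of a set of
#' repeated detected discontinuities (>= `max_discontinuities`), whichever
#' comes first.
#'
#' @param series A [count_series()].
#' @param cap Count ceiling (cells); counting saturates near confluence.
#' @param drop_fraction Maximum tolerated single-step relative drop.
#' @param max_discontinuities Number of detected discontinuities regarded as
#'   "repeated" (unreliable counting).
#' @return A [count_series()] prefix of the input, with attribute `usable`
#'   (`FALSE` when fewer than 3 points survive) and `trunc_index` (last kept
#'   index in the original series, or `NA` if untruncated).
#' @export
truncate_series <- function(series, cap = 30000, drop_fraction = 0.5,
                            max_discontinuities = 2L) {
  stopifnot(cap > 0, drop_fraction > 0, drop_fraction < 1)
  N <- series$counts
  n <- length(N)
  end <- n
  over <- which(N > cap)
  if (length(over) > 0) end <- min(end, over[1] - 1L)
  rel_drop <- c(0, ifelse(N[-n] > 0, (N[-n] - N[-1]) / N[-n], 0))
  big <- which(rel_drop > drop_fraction)
  if (length(big) > 0) end <- min(end, big[1] - 1L)
  if (n >= 5) {
    disc <- detect_discontinuities(series)
    disc <- disc[disc <= end]
    if (length(disc) >= max_discontinuities)
      end <- min(end, disc[1] - 1L)
  }
  end <- max(end, 0L)
  out <- count_series(series$well_id, series$times[seq_len(end)],
                      N[seq_len(end)], series$treatment_time_index)
  attr(out, "usable") <- end >= 3
  attr(out, "trunc_index") <- if (end < n) end else NA_integer_
  out
}

#' Normalize a single count discontinuity
#'
#' Divides all counts before index `d` by a constant `alpha` chosen so the
#' first and second derivatives of the count curve are smooth across the
#' discontinuity:
#' \deqn{\alpha = \frac{(N_{d-1}-N_{d-2})/(t_{d-1}-t_{d-2}) +
#'   2N_{d-1}/(t_d-t_{d-1})}{2N_d/(t_d-t_{d-1}) +
#'   (N_d-N_{d+1})/(t_{d+1}-t_d)}}
#' On a smooth series `alpha = 1`; a pure multiplicative jump of factor `a`
#' applied to the pre-discontinuity counts is removed exactly (`alpha = a`).
#'
#' @param series A [count_series()].
#' @param d Discontinuity index (`2 <= d <= length - 1`, needs neighbours
#'   `d-2 .. d+1`).
#' @return The normalized [count_series()] with attribute `alpha`; if the
#'   computed `alpha` is non-positive or non-finite the input is returned
#'   truncated at `d - 1` with attribute `alpha = NA`.
#' @export
normalize_discontinuity <- function(series, d) {
  n <- length(series$counts)
  if (d < 3 || d > n - 1)
    stop("d must satisfy 3 <= d <= length - 1", call. = FALSE)
  tt <- series$times; N <- series$counts
  num <- (N[d - 1] - N[d - 2]) / (tt[d - 1] - tt[d - 2]) +
    2 * N[d - 1] / (tt[d] - tt[d - 1])
  den <- 2 * N[d] / (tt[d] - tt[d - 1]) +
    (N[d] - N[d + 1]) / (tt[d + 1] - tt[d])
  alpha <- num / den
  if (!is.finite(alpha) || alpha <= 0) {
    out <- count_series(series$well_id, tt[seq_len(d - 1)],
                        N[seq_len(d - 1)], series$treatment_time_index)
    attr(out, "alpha") <- NA_real_
    return(out)
  }
  N2 <- N
  N2[seq_len(d - 1)] <- N[seq_len(d - 1)] / alpha
  out <- count_series(series$well_id, tt, N2, series$treatment_time_index)
  attr(out, "alpha") <- alpha
  out
}

#' Preprocess one count series
#'
#' Applies the full cleaning policy: detect discontinuities; a single
#' discontinuity that loses no more than half the cells is normalized away
#' (division of the earlier segment by `alpha`), anything worse truncates;
#' then the cap and drop truncation rules are applied.
#'
#' @param series A [count_series()].
#' @param cap,drop_fraction,theta See [truncate_series()] and
#'   [detect_discontinuities()].
#' @return A cleaned [count_series()] with attributes `usable`, `alpha`
#'   (`NA` if no normalization), `action` (one of `"none"`, `"normalized"`,
#'   `"truncated"`, `"normalized+truncated"`).
#' @export
preprocess_series <- function(series, cap = 30000, drop_fraction = 0.5,
                              theta = 5) {
  action <- "none"
  alpha <- NA_real_
  s <- series
  if (length(s$counts) >= 5) {
    disc <- detect_discontinuities(s, theta = theta)
    if (length(disc) == 1) {
      d <- disc[1]
      if (d >= 3 && d <= length(s$counts) - 1) {
        lost <- (s$counts[d - 1] - s$counts[d]) / s$counts[d - 1]
        if (is.finite(lost) && lost < drop_fraction) {
          s2 <- normalize_discontinuity(s, d)
          if (is.finite(attr(s2, "alpha"))) {
            alpha <- attr(s2, "alpha")
            s <- s2
            action <- "normalized"
          }
        }
      }
    }
  }
  out <- truncate_series(s, cap = cap, drop_fraction = drop_fraction)
  if (!is.na(attr(out, "trunc_index")))
    action <- if (action == "normalized") "normalized+truncated" else "truncated"
  attr(out, "alpha") <- alpha
  attr(out, "action") <- action
  out
}

#' Read a counts CSV into count series
#' @param path CSV with columns `well_id`, `time_h`, `count`.
#' @return Named list of [count_series()].
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "time_h", "count")
  if (!all(need %in% names(df)))
    stop("counts CSV must have columns well_id, time_h, count", call. = FALSE)
  out <- lapply(split(df, df$well_id), function(d) {
    d <- d[order(d$time_h), ]
    count_series(d$well_id[1], d$time_h, d$count)
  })
  out[order(names(out))]
}

#' Per-well preprocessing report
#' @param series_list Named list of raw [count_series()].
#' @param ... Passed to [preprocess_series()].
#' @return A list with `series` (cleaned list) and `report` (data frame with
#'   `well_id`, `action`, `alpha`, `trunc_index`, `usable`).
#' @export
preprocess_wells <- function(series_list, ...) {
  cleaned <- lapply(series_list, preprocess_series, ...)
  report <- do.call(rbind, lapply(cleaned, function(s) {
    data.frame(well_id = s$well_id,
               action = attr(s, "action"),
               alpha = attr(s, "alpha"),
               trunc_index = attr(s, "trunc_index") %||% NA_integer_,
               usable = isTRUE(attr(s, "usable")))
  }))
  rownames(report) <- NULL
  list(series = cleaned, report = report)
}
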