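#' Density-based clustering of one frame (DBSCAN)
#'
#' Classical density-reachability clustering: a core point has at least
#' `min_pts` neighbours (itself included) within `eps`; clusters are maximal
#' density-connected sets grown from core points; remaining points are noise.
#' Implemented directly over the pairwise distance matrix, which is ample for
#' per-frame nuclei counts (hundreds of points).
#'
#' @param points Two-column matrix of centroids (microns).
#' @param eps Neighbourhood radius (microns).
#' @param min_pts Minimum neighbourhood size for a core point (>= 2).
#' @return Integer vector of cluster labels, 0 for noise.
#' @export
cluster_frame <- function(points, eps, min_pts) {
  stopifnot(eps > 0, min_pts >= 2)
  n <- nrow(points)
  if (is.null(n) || n == 0) return(integer(0))
  d <- as.matrix(stats::dist(points))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (!core[j]) next
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Detect the proliferation delay from centroid frames
#'
#' Scans forward for the first frame containing a density cluster of at least
#' `min_cluster_size` points (the regrowing patch), then tracks that cluster
#' backward frame-by-frame: at each earlier frame, points within a search
#' radius of the previous cluster centroid are re-clustered, and the track
#' ends at the first frame in which no qualifying cluster remains. The
#' proliferation delay is the difference between that frame's time and the
#' treatment time, floored at zero.
#'
#' @param frames A `frame_set` from [generate_frames()] or
#'   [read_frames_csv()].
#' @param treatment_time Time of initial treatment (hours).
#' @param eps DBSCAN neighbourhood radius (microns).
#' @param min_pts DBSCAN core-point threshold.
#' @param min_cluster_size Minimum size of the initial "sufficiently large"
#'   cluster.
#' @param search_factor Backward search radius as a multiple of the current
#'   cluster radius.
#' @return List with `t_r_h` (hours, `NA` if undetected), `detected`
#'   (logical), and `onset_frame` (index of the earliest frame holding the
#'   cluster).
#' @export
detect_tr <- function(frames, treatment_time = 0, eps = 60, min_pts = 4,
                      min_cluster_size = 10, search_factor = 2) {
  if (length(frames$frames) == 0) stop("empty frame set", call. = FALSE)
  nf <- length(frames$times)
  first <- NA_integer_
  centroid <- NULL
  radius <- NULL
  for (i in seq_len(nf)) {
    pts <- frames$frames[[i]]
    if (is.null(pts) || nrow(pts) < min_cluster_size) next
    lab <- cluster_frame(pts, eps, min_pts)
    sizes <- table(lab[lab > 0])
    big <- sizes[sizes >= min_cluster_size]
    if (length(big) > 0) {
      cl <- as.integer(names(big)[which.max(big)])
      sel <- pts[lab == cl, , drop = FALSE]
      centroid <- colMeans(sel)
      radius <- max(sqrt(rowSums(sweep(sel, 2, centroid)^2)))
      first <- i
      break
    }
  }
  if (is.na(first))
    return(list(t_r_h = NA_real_, detected = FALSE, onset_frame = NA_integer_))
  onset <- first
  if (first > 1) {
    for (i in seq(first - 1, 1)) {
      pts <- frames$frames[[i]]
      found <- FALSE
      if (!is.null(pts) && nrow(pts) >= min_pts) {
        r_search <- max(search_factor * radius, eps)
        near <- sqrt((pts[, 1] - centroid[1])^2 +
                       (pts[, 2] - centroid[2])^2) <= r_search
        sub <- pts[near, , drop = FALSE]
        if (nrow(sub) >= min_pts) {
          lab <- cluster_frame(sub, eps, min_pts)
          if (any(lab > 0)) {
            cl <- as.integer(names(which.max(table(lab[lab > 0]))))
            sel <- sub[lab == cl, , drop = FALSE]
            centroid <- colMeans(sel)
            radius <- max(sqrt(rowSums(sweep(sel, 2, centroid)^2)), eps / 2)
            found <- TRUE
          }
        }
      }
      if (!found) {
        # cluster no longer present: delay runs to this frame's time
        return(list(t_r_h = max(frames$times[i] - treatment_time, 0),
                    detected = TRUE, onset_frame = i + 1L))
      }
      onset <- i
    }
  }
  # cluster present from the first frame on
  list(t_r_h = max(frames$times[onset] - treatment_time, 0),
       detected = TRUE, onset_frame = onset)
}

#' Read a frames CSV into per-well frame sets
#' @param path CSV with columns `well_id`, `time_h`, `x_um`, `y_um`.
#' @return Named list of `frame_set` objects.
#' @export
read_frames_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "time_h", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("frames CSV must have columns well_id, time_h, x_um, y_um",
         call. = FALSE)
  lapply(split(df, df$well_id), function(d) {
    times <- sort(unique(d$time_h))
    frames <- lapply(times, function(t) {
      sub <- d[d$time_h == t, ]
      as.matrix(sub[, c("x_um", "y_um")])
    })
    structure(list(times = times, frames = frames), class = "frame_set")
  })
}

#' Detect proliferation delays for many wells, with manual overrides
#'
#' @param frame_sets Named list of `frame_set` objects.
#' @param overrides Optional named numeric vector mapping well id to a
#'   manually determined `t_r` (hours); overrides supersede detection.
#' @param ... Passed to [detect_tr()] (per-plate DBSCAN settings).
#' @return Data frame with `well_id`, `t_r_h`, `detected`, `override`.
#' @export
detect_tr_wells <- function(frame_sets, overrides = NULL, ...) {
  out <- do.call(rbind, lapply(names(frame_sets), function(id) {
    if (!is.null(overrides) && id %in% names(overrides))
      return(data.frame(well_id = id, t_r_h = unname(overrides[[id]]),
                        detected = TRUE, override = TRUE))
    r <- detect_tr(frame_sets[[id]], ...)
    data.frame(well_id = id, t_r_h = r$t_r_h, detected = r$detected,
               override = FALSE)
  }))
  rownames(out) <- NULL
  out
}
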