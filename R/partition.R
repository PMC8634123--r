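# Plain DBSCAN on a small point matrix. Returns integer labels: 0 = noise,
# 1..k = clusters. O(n^2) distances; tracks are at most a few hundred
# frames long so this is never the bottleneck.
dbscan_labels <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Partition one track into dwell states and moving tracklets
#'
#' Saltatory migration alternates pauses (dwell states) with bouts of
#' locomotion (moving tracklets). The partition embeds each recorded point
#' as `(x, y, frame * t_scale)` — time is converted to a spatial
#' equivalent — and runs density-based clustering (DBSCAN) with radius
#' `eps`: dense spatiotemporal neighbourhoods are pause candidates, noise
#' points are locomotion. Candidate clusters are then split into temporally
#' contiguous episodes (a dwell state is a pause episode, not a revisited
#' place); single-point fragments are relabelled moving, and single moving
#' points wedged against a dwell state are absorbed into it. Moving
#' tracklets are the maximal remaining runs of consecutive moving points
#' with at least 2 points.
#'
#' @param track A single track (data frame with `frame`, `x`, `y`).
#' @param t_scale Spatial equivalent of one frame (um per frame, default
#'   1.1) used for the time axis of the embedding.
#' @param eps DBSCAN neighbourhood radius in um (default 3.3).
#' @param min_pts Minimum neighbourhood size for a core point (default 4),
#'   i.e. a dwell must persist about `min_pts` frames to register.
#' @return An object of class `saltatr_partition`: a list with `labels`
#'   (per-point: `"dwell"`/`"moving"`), `state_id` (per-point dwell-state id
#'   or `NA`), `dwell_states` (tibble: `state`, `start_frame`, `end_frame`,
#'   `n_points`, `centroid_x`, `centroid_y`, `diameter`), and
#'   `moving_tracklets` (list of point-index vectors).
#' @examples
#' tr <- simulate_track("saltatory", n_frames = 30, seed = 4)
#' partition_track(tr)
#' @export
partition_track <- function(track, t_scale = 1.1, eps = 3.3, min_pts = 4) {
  stopifnot(eps > 0, t_scale >= 0, min_pts >= 2)
  track <- check_one_track(track)
  n <- nrow(track)
  emb <- cbind(track$x, track$y, track$frame * t_scale)
  raw <- dbscan_labels(emb, eps = eps, min_pts = min_pts)

  # split non-contiguous clusters into contiguous episodes
  state <- rep(NA_integer_, n)
  next_state <- 0L
  for (cl in setdiff(unique(raw), 0L)) {
    idx <- which(raw == cl)
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    for (r in runs) {
      if (length(r) < 2) next  # 1-point fragment -> moving
      next_state <- next_state + 1L
      state[r] <- next_state
    }
  }

  # absorb single moving points wedged against a dwell state
  moving_idx <- which(is.na(state))
  if (length(moving_idx) > 0) {
    runs <- split(moving_idx, cumsum(c(1L, diff(moving_idx) != 1L)))
    for (r in runs) {
      if (length(r) != 1L) next
      i <- r
      prev_s <- if (i > 1) state[i - 1] else NA_integer_
      next_s <- if (i < n) state[i + 1] else NA_integer_
      if (!is.na(prev_s)) state[i] <- prev_s
      else if (!is.na(next_s)) state[i] <- next_s
    }
  }

  # renumber states in temporal order
  first_seen <- unique(state[!is.na(state)])
  state <- match(state, first_seen)

  dwell_states <- if (length(first_seen) > 0) {
    purrr::map_dfr(seq_along(first_seen), function(s) {
      idx <- which(state == s)
      pts <- track[idx, , drop = FALSE]
      diam <- if (length(idx) > 1) max(dist(cbind(pts$x, pts$y))) else 0
      tibble(state = s, start_frame = pts$frame[1],
             end_frame = pts$frame[length(idx)], n_points = length(idx),
             centroid_x = mean(pts$x), centroid_y = mean(pts$y),
             diameter = diam)
    })
  } else {
    tibble(state = integer(), start_frame = numeric(), end_frame = numeric(),
           n_points = integer(), centroid_x = numeric(),
           centroid_y = numeric(), diameter = numeric())
  }

  moving_idx <- which(is.na(state))
  tracklets <- list()
  if (length(moving_idx) > 0) {
    runs <- split(moving_idx, cumsum(c(1L, diff(moving_idx) != 1L)))
    tracklets <- unname(runs[vapply(runs, length, integer(1)) >= 2])
  }

  structure(list(
    labels = ifelse(is.na(state), "moving", "dwell"),
    state_id = state,
    dwell_states = dwell_states,
    moving_tracklets = tracklets,
    params = list(t_scale = t_scale, eps = eps, min_pts = min_pts)
  ), class = "saltatr_partition")
}

#' @export
print.saltatr_partition <- function(x, ...) {
  cat(sprintf("Track partition: %d dwell state(s), %d moving tracklet(s), %d points\n",
              nrow(x$dwell_states), length(x$moving_tracklets),
              length(x$labels)))
  invisible(x)
}

#' Partition-derived descriptors
#'
#' Summarises a [partition_track()] result into the partition feature
#' class: dwell-state counts, relative and mean dwell durations, mean dwell
#' diameter, and moving-tracklet counts, durations, lengths, speeds,
#' turning and confinement. Episode duration is the episode's point count
#' times the frame interval; relative durations are point-count fractions
#' of the whole track. Tracklet speed/turning/confinement are means over
#' tracklets of each tracklet's own mean (tracklets with fewer than 3
#' points contribute no turning value). Empty categories yield 0 by the
#' registry's degenerate rules.
#'
#' @param partition A `saltatr_partition` for the same track.
#' @param track The single track the partition was computed from.
#' @param frame_interval Minutes per frame.
#' @return A one-row tibble of the 11 partition descriptors.
#' @export
partition_features <- function(partition, track, frame_interval = 20) {
  track <- check_one_track(track)
  n <- nrow(track)
  stopifnot(length(partition$labels) == n)
  ds <- partition$dwell_states
  n_dwell_pts <- sum(partition$labels == "dwell")
  tl <- partition$moving_tracklets
  tl_stats <- if (length(tl) > 0) {
    purrr::map_dfr(tl, function(idx) {
      sub <- track[idx, , drop = FALSE]
      tibble(
        n_points = length(idx),
        length = path_length(sub),
        speed = mean_speed(sub, frame_interval),
        dc = if (length(idx) >= 3) mean_or_na(turning_angles(sub)) else NA_real_,
        confinement = confinement_ratio(sub)
      )
    })
  } else NULL
  dc_vals <- if (!is.null(tl_stats)) tl_stats$dc[!is.na(tl_stats$dc)] else numeric(0)
  tibble(
    dwell_state_count = nrow(ds),
    dwell_duration_total_relative = n_dwell_pts / n,
    dwell_duration_mean = if (nrow(ds) > 0) mean(ds$n_points) * frame_interval else 0,
    dwell_diameter_mean = if (nrow(ds) > 0) mean(ds$diameter) else 0,
    moving_tracklet_count = length(tl),
    moving_duration_total_relative = sum(partition$labels == "moving") / n,
    moving_tracklet_duration_mean =
      if (!is.null(tl_stats)) mean(tl_stats$n_points) * frame_interval else 0,
    moving_tracklet_length_mean =
      if (!is.null(tl_stats)) mean(tl_stats$length) else 0,
    moving_tracklet_speed_mean =
      if (!is.null(tl_stats)) mean(tl_stats$speed) else 0,
    moving_tracklet_dc_mean = if (length(dc_vals) > 0) mean(dc_vals) else 0,
    moving_tracklet_confinement_mean =
      if (!is.null(tl_stats)) mean(tl_stats$confinement) else 0
  )
}

mean_speed <- function(track, frame_interval) {
  s <- step_vectors(track)
  mean(sqrt(s[, "dx"]^2 + s[, "dy"]^2) / (s[, "dframe"] * frame_interval))
}

mean_or_na <- function(v) if (length(v) == 0) NA_real_ else mean(v)

#' Ramer-Douglas-Peucker polyline simplification of a track
#'
#' Recursively simplifies the `(x, y)` polyline (time is ignored): the
#' first and last points are always kept, and within each span the point
#' of maximum perpendicular distance from the chord's infinite line is
#' kept whenever that distance exceeds `eps`. The retained nodes mark the
#' track's major directional changes.
#'
#' @param track A single track (data frame with `frame`, `x`, `y`).
#' @param eps Tolerance in um (> 0).
#' @return An object of class `saltatr_rdp`: list with `node_index`
#'   (strictly increasing point indices, endpoints included) and `eps`.
#' @examples
#' tr <- data.frame(frame = 0:2, x = c(0, 5, 5), y = c(0, 0, 5))
#' rdp_simplify(tr, eps = 0.5)$node_index
#' @export
rdp_simplify <- function(track, eps) {
  stopifnot(eps > 0)
  track <- check_one_track(track)
  x <- track$x; y <- track$y
  n <- length(x)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    span <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i0 <- span[1]; i1 <- span[2]
    if (i1 - i0 < 2) next
    inner <- (i0 + 1):(i1 - 1)
    dd <- point_line_dist(x[inner], y[inner], x[i0], y[i0], x[i1], y[i1])
    m <- which.max(dd)
    if (dd[m] > eps) {
      im <- inner[m]
      keep[im] <- TRUE
      stack <- c(stack, list(c(i0, im)), list(c(im, i1)))
    }
  }
  structure(list(node_index = which(keep), eps = eps), class = "saltatr_rdp")
}

# perpendicular distance from points to the infinite line through (x0,y0),
# (x1,y1); falls back to point distance when the anchors coincide
point_line_dist <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  abs(dx * (y0 - py) - dy * (x0 - px)) / len
}

#' RDP-derived descriptors
#'
#' Summarises an [rdp_simplify()] result: number of retained nodes, mean
#' straight-line length and mean duration of node-to-node segments, mean
#' unsigned turn angle at interior nodes (0 when there are none), and the
#' compression ratio nodes/points.
#'
#' @param rdp A `saltatr_rdp` result for the same track.
#' @param track The single track it was computed from.
#' @param frame_interval Minutes per frame.
#' @return A one-row tibble of the 5 RDP descriptors.
#' @export
rdp_features <- function(rdp, track, frame_interval = 20) {
  track <- check_one_track(track)
  idx <- rdp$node_index
  nodes <- track[idx, , drop = FALSE]
  seg_len <- sqrt(diff(nodes$x)^2 + diff(nodes$y)^2)
  seg_dur <- diff(nodes$frame) * frame_interval
  turn <- if (length(idx) >= 3) turning_angles(nodes) else numeric(0)
  tibble(
    node_count = length(idx),
    segment_length_mean = mean(seg_len),
    segment_duration_mean = mean(seg_dur),
    turn_angle_mean = if (length(turn) > 0) mean(turn) else 0,
    compression_ratio = length(idx) / nrow(track)
  )
}

#' Per-point dwell/moving labels for a whole track table
#'
#' Convenience wrapper running [partition_track()] over every track and
#' returning the per-point state labels alongside the input rows.
#'
#' @param tracks A track table.
#' @param t_scale,eps,min_pts See [partition_track()].
#' @return The track table with columns `phase` (`"dwell"`/`"moving"`) and
#'   `dwell_state` (episode id within track, `NA` while moving) appended.
#' @export
partition_tracks <- function(tracks, t_scale = 1.1, eps = 3.3, min_pts = 4) {
  tracks <- as_tracks(tracks)
  per_track <- split_tracks(tracks)
  lab <- purrr::map_dfr(names(per_track), function(id) {
    p <- partition_track(per_track[[id]], t_scale, eps, min_pts)
    tibble(track_id = id, frame = per_track[[id]]$frame,
           phase = p$labels, dwell_state = p$state_id)
  })
  left_join(tracks, lab, by = c("track_id", "frame"))
}
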