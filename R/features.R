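#' The default descriptor registry
#'
#' The package describes each track by 48 named descriptors, organised into
#' feature classes: path length and duration, net displacement, pairwise
#' diameter statistics, instantaneous speed statistics, directional-change
#' statistics and threshold counts, the time-averaged velocity vector, the
#' gyration tensor, confinement ratio, mean straight-line speed, the
#' dwell/moving partition statistics, and polyline-simplification (RDP)
#' statistics at two spatial scales (0.5 um and 3 um).
#'
#' @return A tibble with columns `name`, `class`, `unit` and `degenerate`
#'   (the rule applied when a track is too short or too still for the
#'   descriptor to be defined; descriptors are imputed, never missing).
#' @export
feature_registry <- function() {
  reg <- tibble::tribble(
    ~name, ~class, ~unit, ~degenerate,
    "total_path_length", "track_length", "um", "none",
    "duration", "track_duration", "min", "none",
    "net_displacement", "net", "um", "none",
    "track_diameter_max", "track_diameter_stats", "um", "none",
    "track_diameter_mean", "track_diameter_stats", "um", "none",
    "track_diameter_median", "track_diameter_stats", "um", "none",
    "speed_mean", "speed_stats", "um/min", "none",
    "speed_median", "speed_stats", "um/min", "none",
    "speed_std", "speed_stats", "um/min", "none",
    "speed_min", "speed_stats", "um/min", "none",
    "speed_max", "speed_stats", "um/min", "none",
    "dc_mean", "directional_change_stats", "deg", "0 if < 2 nonzero steps",
    "dc_median", "directional_change_stats", "deg", "0 if < 2 nonzero steps",
    "dc_std", "directional_change_stats", "deg", "0 if < 2 nonzero steps",
    "dc_max", "directional_change_stats", "deg", "0 if < 2 nonzero steps",
    "dc_prop_gt20", "directional_change_count", "fraction", "0 if no angles",
    "dc_prop_gt45", "directional_change_count", "fraction", "0 if no angles",
    "dc_prop_gt90", "directional_change_count", "fraction", "0 if no angles",
    "velocity_avg_magnitude", "velocity_average", "um/min", "none",
    "velocity_avg_angle", "velocity_average", "deg", "0 if zero net displacement",
    "gyration_radius", "gyration_tensor", "um", "none",
    "gyration_tensor_major_axis_length", "gyration_tensor", "um", "none",
    "gyration_tensor_minor_axis_length", "gyration_tensor", "um", "none",
    "gyration_asphericity", "gyration_tensor", "dimensionless", "0 if degenerate tensor",
    "gyration_orientation", "gyration_tensor", "deg", "0 if degenerate tensor",
    "confinement_ratio", "confinement_ratio", "dimensionless", "0 if zero path length",
    "mean_straight_line_speed", "mean_straight_line_speed", "um/min", "none",
    "dwell_state_count", "partition", "count", "none",
    "dwell_duration_total_relative", "partition", "fraction", "none",
    "dwell_duration_mean", "partition", "min", "0 if no dwell states",
    "dwell_diameter_mean", "partition", "um", "0 if no dwell states",
    "moving_tracklet_count", "partition", "count", "none",
    "moving_duration_total_relative", "partition", "fraction", "none",
    "moving_tracklet_duration_mean", "partition", "min", "0 if no tracklets",
    "moving_tracklet_length_mean", "partition", "um", "0 if no tracklets",
    "moving_tracklet_speed_mean", "partition", "um/min", "0 if no tracklets",
    "moving_tracklet_dc_mean", "partition", "deg", "0 if no tracklet has >= 3 points",
    "moving_tracklet_confinement_mean", "partition", "dimensionless", "0 if no tracklets"
  )
  rdp <- do.call(rbind, lapply(c("rdp05", "rdp3"), function(p) {
    tibble(
      name = paste0(p, "_", c("node_count", "segment_length_mean",
                              "segment_duration_mean", "turn_angle_mean",
                              "compression_ratio")),
      class = "rdp_simplification",
      unit = c("count", "um", "min", "deg", "dimensionless"),
      degenerate = c("none", "none", "none", "0 if no interior nodes", "none")
    )
  }))
  out <- rbind(reg, rdp)
  stopifnot(nrow(out) == 48L, !anyDups(out$name))
  out
}

anyDups <- function(x) any(duplicated(x))

# ---- single-track primitives -------------------------------------------
# each takes a data frame with columns frame, x, y, sorted by frame

check_one_track <- function(track) {
  if ("track_id" %in% names(track) && length(unique(track$track_id)) > 1) {
    abort("expected a single track; got several track_ids",
          class = "saltatr_format_error")
  }
  track <- as.data.frame(track)[, c("frame", "x", "y")]
  track[order(track$frame), , drop = FALSE]
}

step_vectors <- function(track) {
  cbind(dx = diff(track$x), dy = diff(track$y), dframe = diff(track$frame))
}

#' Elementary whole-track descriptors
#'
#' `path_length()` is the summed Euclidean length of all consecutive steps;
#' `net_displacement()` the straight-line distance between first and last
#' point; `track_duration()` the elapsed time `(last frame - first frame) *
#' frame_interval`; `confinement_ratio()` the ratio net/path (1 for
#' perfectly straight monotone motion, 0 for a closed loop, and defined as
#' 0 when the path length is 0); `mean_straight_line_speed()` is
#' net displacement over duration.
#'
#' @param track A single track: a data frame with columns `frame`, `x`, `y`.
#' @param frame_interval Minutes per frame.
#' @return A single numeric value (um, min, um/min or dimensionless).
#' @export
path_length <- function(track) {
  track <- check_one_track(track)
  s <- step_vectors(track)
  sum(sqrt(s[, "dx"]^2 + s[, "dy"]^2))
}

#' @rdname path_length
#' @export
net_displacement <- function(track) {
  track <- check_one_track(track)
  n <- nrow(track)
  sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2)
}

#' @rdname path_length
#' @export
track_duration <- function(track, frame_interval = 20) {
  track <- check_one_track(track)
  (track$frame[nrow(track)] - track$frame[1]) * frame_interval
}

#' @rdname path_length
#' @export
confinement_ratio <- function(track) {
  pl <- path_length(track)
  if (pl == 0) return(0)
  net_displacement(track) / pl
}

#' @rdname path_length
#' @export
mean_straight_line_speed <- function(track, frame_interval = 20) {
  net_displacement(track) / track_duration(track, frame_interval)
}

#' Pairwise-diameter statistics of a track
#'
#' Computes all pairwise Euclidean distances between recorded positions;
#' the maximum is the track diameter.
#'
#' @inheritParams path_length
#' @return A tibble with `track_diameter_max`, `track_diameter_mean`,
#'   `track_diameter_median`.
#' @export
diameter_stats <- function(track) {
  track <- check_one_track(track)
  d <- as.vector(dist(cbind(track$x, track$y)))
  tibble(track_diameter_max = max(d), track_diameter_mean = mean(d),
         track_diameter_median = median(d))
}

#' Instantaneous-speed statistics of a track
#'
#' Instantaneous speed between consecutive recorded points is the step
#' length divided by the actual elapsed time (frame gaps widen the time
#' base rather than being interpolated). The standard deviation is the
#' population (1/n) form.
#'
#' @inheritParams path_length
#' @return A tibble with `speed_mean`, `speed_median`, `speed_std`,
#'   `speed_min`, `speed_max` in um/min.
#' @export
speed_stats <- function(track, frame_interval = 20) {
  track <- check_one_track(track)
  s <- step_vectors(track)
  v <- sqrt(s[, "dx"]^2 + s[, "dy"]^2) / (s[, "dframe"] * frame_interval)
  tibble(speed_mean = mean(v), speed_median = median(v),
         speed_std = pop_sd(v), speed_min = min(v), speed_max = max(v))
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

# unsigned turning angles (deg, in [0, 180]) between consecutive nonzero steps
turning_angles <- function(track) {
  s <- step_vectors(check_one_track(track))
  len <- sqrt(s[, "dx"]^2 + s[, "dy"]^2)
  keep <- len > 0
  dx <- s[keep, "dx"]; dy <- s[keep, "dy"]
  if (length(dx) < 2) return(numeric(0))
  i <- seq_len(length(dx) - 1)
  dot <- dx[i] * dx[i + 1] + dy[i] * dy[i + 1]
  crs <- dx[i] * dy[i + 1] - dy[i] * dx[i + 1]
  atan2(abs(crs), dot) * 180 / pi
}

#' Directional-change statistics and threshold counts
#'
#' The directional change at an interior point is the unsigned angle (0-180
#' degrees) between the incoming and outgoing displacement vectors;
#' zero-length displacements are skipped. `directional_change_count()`
#' reports, for each threshold, the proportion of angles strictly greater
#' than it.
#'
#' @inheritParams path_length
#' @param thresholds Angle thresholds in degrees.
#' @return Tibbles of the per-track statistics; all values 0 when fewer
#'   than two nonzero steps exist.
#' @export
directional_change_stats <- function(track) {
  a <- turning_angles(track)
  if (length(a) == 0) {
    return(tibble(dc_mean = 0, dc_median = 0, dc_std = 0, dc_max = 0))
  }
  tibble(dc_mean = mean(a), dc_median = median(a), dc_std = pop_sd(a),
         dc_max = max(a))
}

#' @rdname directional_change_stats
#' @export
directional_change_count <- function(track, thresholds = c(20, 45, 90)) {
  a <- turning_angles(track)
  props <- if (length(a) == 0) rep(0, length(thresholds)) else {
    vapply(thresholds, function(th) mean(a > th), numeric(1))
  }
  out <- as.list(props)
  names(out) <- paste0("dc_prop_gt", thresholds)
  as_tibble(out)
}

#' Time-averaged velocity vector
#'
#' The average velocity of a track — the per-step velocity vectors weighted
#' by their time spans — equals the net displacement vector divided by the
#' track duration. Reported as magnitude (um/min) and direction
#' (counter-clockwise from +x, in `[0, 360)`; 0 by convention when the net
#' displacement is zero).
#'
#' @inheritParams path_length
#' @return A tibble with `velocity_avg_magnitude`, `velocity_avg_angle`.
#' @export
velocity_average <- function(track, frame_interval = 20) {
  track <- check_one_track(track)
  n <- nrow(track)
  dur <- (track$frame[n] - track$frame[1]) * frame_interval
  vx <- (track$x[n] - track$x[1]) / dur
  vy <- (track$y[n] - track$y[1]) / dur
  mag <- sqrt(vx^2 + vy^2)
  ang <- if (mag == 0) 0 else (atan2(vy, vx) * 180 / pi) %% 360
  tibble(velocity_avg_magnitude = mag, velocity_avg_angle = ang)
}

#' Gyration-tensor shape descriptors
#'
#' The gyration tensor is the (population) second-moment tensor of the
#' track's positions about their centroid. With eigenvalues
#' `l1 >= l2 >= 0`: the radius of gyration is `sqrt(l1 + l2)`; the major
#' and minor axis lengths use the full-ellipse-axis convention `2*sqrt(l)`;
#' asphericity is `(l1 - l2)/(l1 + l2)` (1 for a perfectly linear track, 0
#' for an isotropic one, and defined 0 when both eigenvalues vanish);
#' orientation is the principal-axis angle in `[0, 180)` degrees.
#'
#' @inheritParams path_length
#' @return A tibble with `gyration_radius`,
#'   `gyration_tensor_major_axis_length`,
#'   `gyration_tensor_minor_axis_length`, `gyration_asphericity`,
#'   `gyration_orientation`.
#' @export
gyration_tensor_features <- function(track) {
  track <- check_one_track(track)
  xc <- track$x - mean(track$x)
  yc <- track$y - mean(track$y)
  n <- nrow(track)
  txx <- mean(xc^2); tyy <- mean(yc^2); txy <- mean(xc * yc)
  e <- eigen(matrix(c(txx, txy, txy, tyy), 2, 2), symmetric = TRUE)
  l1 <- max(e$values[1], 0); l2 <- max(e$values[2], 0)
  tot <- l1 + l2
  orient <- if (l1 == 0) 0 else {
    v <- e$vectors[, 1]
    (atan2(v[2], v[1]) * 180 / pi) %% 180
  }
  tibble(
    gyration_radius = sqrt(tot),
    gyration_tensor_major_axis_length = 2 * sqrt(l1),
    gyration_tensor_minor_axis_length = 2 * sqrt(l2),
    gyration_asphericity = if (tot == 0) 0 else (l1 - l2) / tot,
    gyration_orientation = orient
  )
}

#' Compute the full per-track descriptor table
#'
#' Evaluates the complete 48-descriptor registry (see [feature_registry()])
#' for every track: whole-track geometry, speed and turning statistics, the
#' gyration tensor, the dwell/moving partition statistics
#' ([partition_track()]) and the RDP simplification statistics
#' ([rdp_simplify()]) at each requested epsilon. Degenerate cases follow
#' the registry's imputation rules, so the result never contains missing
#' values and is ready for clustering.
#'
#' @param tracks A track table (validated with [as_tracks()]).
#' @param frame_interval Minutes per frame (default 20; overridden by a
#'   `frame_interval` attribute on `tracks` if present).
#' @param partition_params List with `t_scale`, `eps`, `min_pts` for the
#'   spatiotemporal dwell partition (defaults 1.1, 3.3, 4).
#' @param rdp_eps Numeric vector of two RDP tolerances in um (default
#'   `c(0.5, 3)`), reported under prefixes `rdp05_` and `rdp3_`.
#' @param dc_thresholds Directional-change count thresholds in degrees.
#' @return A tibble with one row per track: `track_id`, `group`, then the
#'   48 descriptor columns in registry order.
#' @examples
#' tr <- simulate_track("saltatory", n_frames = 24, seed = 2)
#' compute_features(tr)
#' @export
compute_features <- function(tracks, frame_interval = NULL,
                             partition_params = list(t_scale = 1.1, eps = 3.3,
                                                     min_pts = 4),
                             rdp_eps = c(0.5, 3),
                             dc_thresholds = c(20, 45, 90)) {
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval") %||% 20
  tracks <- as_tracks(tracks)
  stopifnot(length(rdp_eps) == 2)
  groups <- track_groups(tracks)
  per_track <- split_tracks(tracks)
  rdp_prefix <- c("rdp05_", "rdp3_")
  rows <- purrr::imap(per_track, function(tr, id) {
    part <- partition_track(tr, t_scale = partition_params$t_scale,
                            eps = partition_params$eps,
                            min_pts = partition_params$min_pts)
    rdp <- purrr::map2(rdp_eps, rdp_prefix, function(eps, pre) {
      res <- rdp_simplify(tr, eps = eps)
      out <- rdp_features(res, tr, frame_interval = frame_interval)
      names(out) <- paste0(pre, names(out))
      out
    })
    dplyr::bind_cols(
      tibble(track_id = id,
             total_path_length = path_length(tr),
             duration = track_duration(tr, frame_interval),
             net_displacement = net_displacement(tr)),
      diameter_stats(tr),
      speed_stats(tr, frame_interval),
      directional_change_stats(tr),
      directional_change_count(tr, dc_thresholds),
      velocity_average(tr, frame_interval),
      gyration_tensor_features(tr),
      tibble(confinement_ratio = confinement_ratio(tr),
             mean_straight_line_speed = mean_straight_line_speed(tr, frame_interval)),
      partition_features(part, tr, frame_interval = frame_interval),
      rdp[[1]], rdp[[2]]
    )
  })
  out <- bind_rows(rows)
  out <- left_join(out, groups, by = "track_id")
  reg <- feature_registry()
  out <- out[, c("track_id", "group", reg$name)]
  stopifnot(!anyNA(out[, reg$name]))
  as_tibble(out)
}
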