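#' Validate and normalise a track table
#'
#' A track table is an ordinary data frame holding one row per tracked
#' position, with columns `track_id` (character), `frame` (0-based integer
#' frame index), `x` and `y` (micrometres), and optionally `group`
#' (treatment-group label, defaulting to `"control"`). Time in minutes is
#' `frame * frame_interval`. All of the package's verbs consume and return
#' this shape, so calls chain with the pipe.
#'
#' @param tracks A data frame with columns `track_id`, `frame`, `x`, `y`
#'   and optionally `group`.
#' @param default_group Group label attached to tracks that carry none.
#'
#' @return A tibble sorted by `track_id` then `frame`, with a `group`
#'   column guaranteed present.
#'
#' @details Invariants enforced: at least 2 points per track, strictly
#'   increasing frame index within a track (duplicate `(track_id, frame)`
#'   pairs are an integrity error), finite coordinates. Frame gaps are
#'   permitted; rate-like quantities always use the actual time difference
#'   between retained points.
#'
#' @examples
#' tr <- tibble::tibble(track_id = "a", frame = 0:2, x = c(0, 3, 6), y = c(0, 4, 8))
#' as_tracks(tr)
#' @export
as_tracks <- function(tracks, default_group = "control") {
  required <- c("track_id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(tracks))
  if (length(missing_cols) > 0) {
    abort(paste0("track table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "saltatr_format_error")
  }
  tracks <- as_tibble(tracks)
  tracks$track_id <- as.character(tracks$track_id)
  for (col in c("frame", "x", "y")) {
    v <- tracks[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      abort(paste0("non-numeric value in column '", col, "'",
                   if (length(bad) > 0) paste0(" at row ", bad[1]) else ""),
            class = "saltatr_parse_error")
    }
  }
  if (!all(is.finite(tracks$x)) || !all(is.finite(tracks$y))) {
    abort("non-finite coordinate in track table", class = "saltatr_parse_error")
  }
  if (!("group" %in% names(tracks))) {
    tracks$group <- default_group
  } else {
    tracks$group[is.na(tracks$group)] <- default_group
  }
  dup <- duplicated(tracks[, c("track_id", "frame")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(paste0("duplicate (track_id, frame) pair: track '",
                 tracks$track_id[i], "', frame ", tracks$frame[i],
                 " (row ", i, ")"),
          class = "saltatr_integrity_error")
  }
  tracks <- arrange(tracks, .data$track_id, .data$frame)
  n_pts <- table(tracks$track_id)
  if (any(n_pts < 2)) {
    abort(paste0("track(s) with fewer than 2 points: ",
                 paste(names(n_pts)[n_pts < 2], collapse = ", ")),
          class = "saltatr_integrity_error")
  }
  tracks
}

#' Per-track group labels
#'
#' @param tracks A track table (see [as_tracks()]).
#' @return A tibble with one row per track: `track_id`, `group`.
#' @export
track_groups <- function(tracks) {
  distinct(as_tibble(tracks), .data$track_id, .data$group)
}

#' Number of points per track
#'
#' @param tracks A track table.
#' @return A tibble with `track_id` and `n_frames` (number of recorded points).
#' @export
track_lengths <- function(tracks) {
  summarise(group_by(as_tibble(tracks), .data$track_id),
            n_frames = dplyr::n(), .groups = "drop")
}

# Split a validated track table into a named list of per-track data frames
# (frame, x, y), each sorted by frame. Internal workhorse for per-track maps.
split_tracks <- function(tracks) {
  tracks <- arrange(as_tibble(tracks), .data$track_id, .data$frame)
  split(tracks[, c("frame", "x", "y")], tracks$track_id)
}
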