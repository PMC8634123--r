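#' Smooth track coordinates with a centred moving average
#'
#' Applies a centred moving average of odd width to the `x` and `y`
#' coordinates of every track. Near track ends the half-width shrinks
#' symmetrically to what fits, so the first and last points are unchanged
#' and collinear equidistant tracks are exact fixed points of the filter.
#' Frame indices are never altered.
#'
#' @param tracks A track table.
#' @param window Odd window width in frames; `1` is the identity.
#' @return The smoothed track table.
#' @export
smooth_tracks <- function(tracks, window = 3) {
  if (window %% 2 == 0 || window < 1) {
    abort("smoothing window must be odd and >= 1",
          class = "saltatr_config_error")
  }
  if (window == 1) return(as_tibble(tracks))
  h <- (window - 1) / 2
  smooth_one <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(i) {
      hi <- min(h, i - 1, n - i)
      mean(v[(i - hi):(i + hi)])
    }, numeric(1))
  }
  tracks <- arrange(as_tibble(tracks), .data$track_id, .data$frame)
  tracks |>
    group_by(.data$track_id) |>
    mutate(x = smooth_one(.data$x), y = smooth_one(.data$y)) |>
    ungroup()
}

new_filter_report <- function(n_input, removed_ids, rule) {
  structure(
    list(n_input = n_input, n_removed = length(removed_ids),
         n_retained = n_input - length(removed_ids),
         removed_ids = removed_ids, rule = rule),
    class = "saltatr_filter_report"
  )
}

#' @export
print.saltatr_filter_report <- function(x, ...) {
  cat(sprintf("Track filter [%s]: %d in, %d removed, %d retained\n",
              x$rule, x$n_input, x$n_removed, x$n_retained))
  invisible(x)
}

#' Retrieve the filter report attached to a filtered track table
#'
#' @param tracks A track table returned by [filter_min_frames()] or
#'   [filter_non_moving()].
#' @return A `saltatr_filter_report` with fields `n_input`, `n_removed`,
#'   `n_retained`, `removed_ids`, `rule`.
#' @export
filter_report <- function(tracks) {
  rep <- attr(tracks, "filter_report")
  if (is.null(rep)) abort("no filter report attached to this track table")
  rep
}

#' Exclude tracks shorter than a minimum number of frames
#'
#' Short tracks carry too little information for the descriptor set and are
#' removed before feature computation. The default of 12 recorded frames
#' corresponds to 240 min at the default 20 min frame interval.
#'
#' @param tracks A track table.
#' @param min_frames Minimum number of recorded points a track must have to
#'   be retained (default 12).
#' @return The retained tracks, with a [filter_report()] attached as an
#'   attribute.
#' @export
filter_min_frames <- function(tracks, min_frames = 12) {
  stopifnot(min_frames >= 2)
  tracks <- as_tibble(tracks)
  len <- track_lengths(tracks)
  removed <- len$track_id[len$n_frames < min_frames]
  out <- filter(tracks, !.data$track_id %in% removed)
  attr(out, "frame_interval") <- attr(tracks, "frame_interval")
  attr(out, "filter_report") <-
    new_filter_report(nrow(len), removed,
                      sprintf("min_frames >= %d", min_frames))
  out
}

#' Exclude non-moving tracks by spatial-extent thresholds
#'
#' Stationary cells produce tracks whose overall spatial extent stays small
#' even over long recordings. A track is called moving — and retained — only
#' if its maximum diameter and the major axis of its gyration tensor both
#' reach their thresholds (15 um and 5 um by default); `combine = "either"`
#' relaxes this so that passing one threshold suffices.
#'
#' @param tracks A track table.
#' @param features A feature table containing `track_diameter_max` and
#'   `gyration_tensor_major_axis_length` for every track.
#' @param diameter_max_threshold Minimum track diameter (um) to count as
#'   moving (default 15).
#' @param major_axis_threshold Minimum gyration-tensor major axis length
#'   (um) to count as moving (default 5).
#' @param combine `"both"` (retain only if both thresholds are met; default)
#'   or `"either"`.
#' @return The retained tracks, with a [filter_report()] attached.
#' @export
filter_non_moving <- function(tracks, features,
                              diameter_max_threshold = 15,
                              major_axis_threshold = 5,
                              combine = c("both", "either")) {
  combine <- match.arg(combine)
  needed <- c("track_diameter_max", "gyration_tensor_major_axis_length")
  if (!all(needed %in% names(features))) {
    abort(paste0("feature table must contain: ",
                 paste(needed, collapse = ", ")),
          class = "saltatr_format_error")
  }
  tracks <- as_tibble(tracks)
  ids <- unique(tracks$track_id)
  feats <- features[match(ids, features$track_id), ]
  if (anyNA(feats$track_id)) {
    abort("feature table lacks rows for some tracks",
          class = "saltatr_format_error")
  }
  pass_d <- feats$track_diameter_max >= diameter_max_threshold
  pass_g <- feats$gyration_tensor_major_axis_length >= major_axis_threshold
  moving <- if (combine == "both") pass_d & pass_g else pass_d | pass_g
  removed <- ids[!moving]
  out <- filter(tracks, !.data$track_id %in% removed)
  attr(out, "frame_interval") <- attr(tracks, "frame_interval")
  attr(out, "filter_report") <-
    new_filter_report(length(ids), removed,
                      sprintf("moving: diameter_max >= %g %s major_axis >= %g",
                              diameter_max_threshold,
                              if (combine == "both") "AND" else "OR",
                              major_axis_threshold))
  out
}
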