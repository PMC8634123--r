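#' Mean-squared displacement of one track
#'
#' Time-averaged MSD with overlapping windows:
#' `MSD(tau) = mean over t of |r(t + tau) - r(t)|^2`, evaluated at lags
#' that are multiples of the frame interval. Pairs spanning a frame gap
#' are simply absent from the average (no interpolation).
#'
#' @param track A single track (data frame with `frame`, `x`, `y`).
#' @param frame_interval Minutes per frame.
#' @param max_lag Largest lag in minutes (default 1440, i.e. 24 h).
#' @return A tibble with `lag` (min), `value` (um^2) and `n_pairs`; lags
#'   with no valid pair are dropped.
#' @examples
#' tr <- simulate_track("ballistic", n_frames = 24, speed = 0.1,
#'                      jitter_sd = 0, seed = 1)
#' msd_curve(tr)
#' @export
msd_curve <- function(track, frame_interval = 20, max_lag = 1440) {
  track <- check_one_track(track)
  f <- track$frame
  span <- f[length(f)] - f[1]
  k_max <- min(floor(max_lag / frame_interval), span)
  idx <- match(seq(min(f), max(f)), f)  # frame -> row, NA at gaps
  rows <- purrr::map_dfr(seq_len(k_max), function(k) {
    i <- idx[seq_len(length(idx) - k)]
    j <- idx[(k + 1):length(idx)]
    ok <- !is.na(i) & !is.na(j)
    if (!any(ok)) return(NULL)
    d2 <- (track$x[j[ok]] - track$x[i[ok]])^2 +
          (track$y[j[ok]] - track$y[i[ok]])^2
    tibble(lag = k * frame_interval, value = mean(d2), n_pairs = sum(ok))
  })
  rows
}

#' Velocity autocorrelation of one track
#'
#' Step velocities are taken between consecutive recorded frames (steps
#' spanning gaps are skipped). The curve is normalised per track by the
#' mean squared step speed, `VAC(tau) = <v(t).v(t+tau)> / <|v|^2>`, so
#' `VAC(0) = 1`; for a straight constant-velocity track the curve stays at
#' 1, and perfect per-frame reversal gives -1 at one frame interval.
#'
#' @inheritParams msd_curve
#' @return A tibble with `lag` (min, starting at 0), `value`
#'   (dimensionless) and `n_pairs`. If all step velocities are zero the
#'   curve is all 0 and carries attribute `zero_velocity = TRUE`.
#' @export
vac_curve <- function(track, frame_interval = 20, max_lag = 1440) {
  track <- check_one_track(track)
  f <- track$frame
  grid <- seq(min(f), max(f))
  idx <- match(grid, f)
  n_step <- length(grid) - 1
  vx <- rep(NA_real_, n_step); vy <- rep(NA_real_, n_step)
  ok <- !is.na(idx[-length(idx)]) & !is.na(idx[-1])
  vx[ok] <- (track$x[idx[-1][ok]] - track$x[idx[-length(idx)][ok]]) / frame_interval
  vy[ok] <- (track$y[idx[-1][ok]] - track$y[idx[-length(idx)][ok]]) / frame_interval
  norm <- mean(vx[ok]^2 + vy[ok]^2)
  k_max <- min(floor(max_lag / frame_interval), n_step - 1)
  if (!is.finite(norm) || norm == 0) {
    out <- tibble(lag = (0:max(k_max, 0)) * frame_interval, value = 0,
                  n_pairs = 0L)
    attr(out, "zero_velocity") <- TRUE
    return(out)
  }
  rows <- purrr::map_dfr(0:k_max, function(k) {
    i <- seq_len(n_step - k)
    j <- i + k
    keep <- !is.na(vx[i]) & !is.na(vx[j])
    if (!any(keep)) return(NULL)
    dot <- vx[i[keep]] * vx[j[keep]] + vy[i[keep]] * vy[j[keep]]
    tibble(lag = k * frame_interval, value = mean(dot) / norm,
           n_pairs = sum(keep))
  })
  rows
}

#' Per-track lag curves for a whole track table
#'
#' @param tracks A track table.
#' @param type `"msd"` or `"vac"`.
#' @inheritParams msd_curve
#' @return A long tibble: `track_id`, `lag`, `value`, `n_pairs`.
#' @export
lag_curves <- function(tracks, type = c("msd", "vac"), frame_interval = NULL,
                       max_lag = 1440) {
  type <- match.arg(type)
  frame_interval <- frame_interval %||% attr(tracks, "frame_interval") %||% 20
  fn <- if (type == "msd") msd_curve else vac_curve
  per_track <- split_tracks(as_tracks(tracks))
  out <- purrr::imap_dfr(per_track, function(tr, id) {
    cv <- fn(tr, frame_interval = frame_interval, max_lag = max_lag)
    if (nrow(cv) == 0) return(NULL)
    cv$track_id <- id
    cv
  })
  out <- out[, c("track_id", "lag", "value", "n_pairs")]
  attr(out, "type") <- type
  out
}

#' Average lag curves within labelled groups of tracks
#'
#' Unweighted mean of per-track curves at each lag, per label (e.g. per
#' migration-mode cluster). Lags supported by fewer than `min_tracks`
#' contributing tracks are dropped, so cluster means are never carried by
#' one or two unusually long tracks.
#'
#' @param curves Long per-track curves from [lag_curves()].
#' @param labels A data frame with `track_id` and a label column (its name
#'   is taken from `label_col`), or `NULL` to average all tracks together.
#' @param label_col Name of the label column in `labels`.
#' @param min_tracks Minimum number of contributing tracks per lag.
#' @return A tibble `label`, `lag`, `value`, `n_tracks` of class
#'   `saltatr_lag_curves`.
#' @export
aggregate_curves <- function(curves, labels = NULL, label_col = "label",
                             min_tracks = 3) {
  curves <- as_tibble(curves)
  if (is.null(labels)) {
    curves$label <- "all"
  } else {
    lab <- as_tibble(labels)[, c("track_id", label_col)]
    names(lab) <- c("track_id", "label")
    unmatched <- setdiff(curves$track_id, lab$track_id)
    if (length(unmatched) > 0) {
      warn(paste0(length(unmatched), " track(s) without a label omitted"))
    }
    curves <- dplyr::inner_join(curves, lab, by = "track_id")
  }
  out <- curves |>
    group_by(.data$label, .data$lag) |>
    summarise(value = mean(.data$value), n_tracks = dplyr::n(),
              .groups = "drop") |>
    filter(.data$n_tracks >= min_tracks) |>
    arrange(.data$label, .data$lag)
  type <- attr(curves, "type")
  structure(out, type = type, class = c("saltatr_lag_curves", class(out)))
}

#' Log-log slope of an MSD curve
#'
#' Least-squares slope of `log(MSD)` against `log(lag)`, the anomalous
#' diffusion exponent alpha: about 2 for ballistic motion, about 1 for a
#' random walk, below 1 for confined motion.
#'
#' @param curve A lag-curve tibble (`lag`, `value`).
#' @param fit_range Optional numeric length-2 vector of minimum and
#'   maximum lag (min) to fit within; `NULL` uses the whole curve.
#' @return The fitted exponent (numeric scalar).
#' @export
fit_msd_exponent <- function(curve, fit_range = NULL) {
  curve <- as_tibble(curve)
  if (!is.null(fit_range)) {
    curve <- filter(curve, .data$lag >= fit_range[1], .data$lag <= fit_range[2])
  }
  curve <- filter(curve, .data$value > 0, .data$lag > 0)
  if (nrow(curve) < 3) {
    abort("fewer than 3 positive (lag, MSD) points to fit",
          class = "saltatr_config_error")
  }
  unname(coef(lm(log(value) ~ log(lag), data = curve))[2])
}
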