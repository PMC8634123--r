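#' Simulate a single cell track under a known motion model
#'
#' Generates a 2D centroid track under one of six motion models, so that
#' every downstream stage (filtering, features, partitioning, clustering,
#' statistics) can be tested against planted ground truth. Defaults emulate
#' time-lapse imaging of migrating neurons at one frame per 20 minutes.
#'
#' @param model One of `"ballistic"`, `"random_walk"`, `"persistent_walk"`,
#'   `"saltatory"`, `"confined"`, `"stationary"`.
#' @param n_frames Number of recorded frames (>= 2). Default 72 (24 h at
#'   20 min/frame).
#' @param frame_interval Minutes per frame (default 20).
#' @param speed Locomotion speed in um/min for ballistic motion and for the
#'   run phases of saltatory motion.
#' @param heading Initial heading in degrees (counter-clockwise from +x);
#'   `NULL` draws it uniformly.
#' @param step_sd Per-axis standard deviation of one frame's Gaussian step
#'   (um), for the walk models.
#' @param persistence AR(1) weight in `[0, 1)` coupling each step of a
#'   persistent walk to the previous step.
#' @param run_frames_mean,dwell_frames_mean Mean lengths (frames) of the
#'   geometrically distributed run and dwell episodes of saltatory motion.
#' @param tether_sd Stationary spatial scale (um) of the mean-reverting
#'   confined walk.
#' @param jitter_sd Per-axis localisation jitter (um) added to ballistic
#'   positions, dwell phases and stationary tracks.
#' @param seed Integer seed; the track is a deterministic function of it.
#' @param track_id Identifier for the generated track.
#' @param origin Numeric length-2 start position (um).
#'
#' @return A track table with columns `track_id`, `frame`, `x`, `y`, and
#'   `state` (`"run"`/`"dwell"` for saltatory tracks, `NA` otherwise). The
#'   model name is attached as attribute `model`.
#'
#' @details Model definitions:
#' * ballistic: constant velocity `speed` along `heading` plus isotropic
#'   Gaussian jitter on each recorded position.
#' * random_walk: iid Gaussian steps, per-axis sd `step_sd`.
#' * persistent_walk: AR(1) steps, `s_i = p s_(i-1) + e_i` with
#'   `sd(e) = step_sd * sqrt(1 - p^2)`, so the stationary step sd is
#'   `step_sd`.
#' * saltatory: alternating run (ballistic at `speed`, fresh random heading
#'   per run) and dwell (jitter about the pause point) episodes whose
#'   lengths are geometric with the given means (memoryless switching).
#' * confined: mean-reverting Gaussian walk around the origin whose
#'   stationary per-axis sd is `tether_sd`.
#' * stationary: pure jitter about the origin.
#' @examples
#' simulate_track("saltatory", n_frames = 36, seed = 1)
#' @export
simulate_track <- function(model = c("ballistic", "random_walk",
                                     "persistent_walk", "saltatory",
                                     "confined", "stationary"),
                           n_frames = 72, frame_interval = 20,
                           speed = 0.5, heading = NULL, step_sd = 2,
                           persistence = 0.7, run_frames_mean = 6,
                           dwell_frames_mean = 6, tether_sd = 5,
                           jitter_sd = 0.5, seed = NULL,
                           track_id = "sim_1", origin = c(0, 0)) {
  model <- match.arg(model)
  stopifnot(n_frames >= 2, frame_interval > 0, speed >= 0, step_sd >= 0,
            persistence >= 0, persistence < 1, run_frames_mean >= 1,
            dwell_frames_mean >= 1, tether_sd >= 0, jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(heading)) heading <- runif(1, 0, 360)
  n <- n_frames
  state <- rep(NA_character_, n)
  step_len <- speed * frame_interval  # um per frame while locomoting

  if (model == "ballistic") {
    dir <- c(cos(heading * pi / 180), sin(heading * pi / 180))
    t_idx <- 0:(n - 1)
    x <- origin[1] + t_idx * step_len * dir[1]
    y <- origin[2] + t_idx * step_len * dir[2]
    if (jitter_sd > 0) {
      x <- x + rnorm(n, 0, jitter_sd)
      y <- y + rnorm(n, 0, jitter_sd)
    }
  } else if (model == "random_walk") {
    x <- origin[1] + cumsum(c(0, rnorm(n - 1, 0, step_sd)))
    y <- origin[2] + cumsum(c(0, rnorm(n - 1, 0, step_sd)))
  } else if (model == "persistent_walk") {
    innov_sd <- step_sd * sqrt(1 - persistence^2)
    sx <- numeric(n - 1); sy <- numeric(n - 1)
    sx[1] <- rnorm(1, 0, step_sd); sy[1] <- rnorm(1, 0, step_sd)
    for (i in seq_len(n - 2)) {
      sx[i + 1] <- persistence * sx[i] + rnorm(1, 0, innov_sd)
      sy[i + 1] <- persistence * sy[i] + rnorm(1, 0, innov_sd)
    }
    x <- origin[1] + cumsum(c(0, sx))
    y <- origin[2] + cumsum(c(0, sy))
  } else if (model == "saltatory") {
    x <- numeric(n); y <- numeric(n)
    x[1] <- origin[1]; y[1] <- origin[2]
    # long-run occupancy of the two-state chain decides the initial state
    p_run <- run_frames_mean / (run_frames_mean + dwell_frames_mean)
    cur <- if (runif(1) < p_run) "run" else "dwell"
    remaining <- rgeom(1, 1 / (if (cur == "run") run_frames_mean else dwell_frames_mean)) + 1
    dir <- runif(1, 0, 2 * pi)
    anchor <- origin
    state[1] <- cur
    if (cur == "dwell") anchor <- c(x[1], y[1])
    for (i in 2:n) {
      if (remaining == 0) {
        cur <- if (cur == "run") "dwell" else "run"
        remaining <- rgeom(1, 1 / (if (cur == "run") run_frames_mean else dwell_frames_mean)) + 1
        if (cur == "run") dir <- runif(1, 0, 2 * pi)
        if (cur == "dwell") anchor <- c(x[i - 1], y[i - 1])
      }
      if (cur == "run") {
        x[i] <- x[i - 1] + step_len * cos(dir) + rnorm(1, 0, jitter_sd)
        y[i] <- y[i - 1] + step_len * sin(dir) + rnorm(1, 0, jitter_sd)
      } else {
        x[i] <- anchor[1] + rnorm(1, 0, jitter_sd)
        y[i] <- anchor[2] + rnorm(1, 0, jitter_sd)
      }
      state[i] <- cur
      remaining <- remaining - 1
    }
  } else if (model == "confined") {
    # AR(1) toward the origin with stationary per-axis sd = tether_sd
    a <- if (tether_sd > 0 && step_sd < tether_sd) {
      sqrt(1 - (step_sd / tether_sd)^2)
    } else 0
    x <- numeric(n); y <- numeric(n)
    x[1] <- origin[1]; y[1] <- origin[2]
    for (i in 2:n) {
      x[i] <- origin[1] + a * (x[i - 1] - origin[1]) + rnorm(1, 0, step_sd)
      y[i] <- origin[2] + a * (y[i - 1] - origin[2]) + rnorm(1, 0, step_sd)
    }
  } else { # stationary
    x <- origin[1] + rnorm(n, 0, jitter_sd)
    y <- origin[2] + rnorm(n, 0, jitter_sd)
    x[1] <- origin[1]; y[1] <- origin[2]
  }

  out <- tibble(track_id = track_id, frame = 0:(n - 1), x = x, y = y,
                state = state)
  attr(out, "model") <- model
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Simulate a cohort of tracks across treatment groups
#'
#' Expands a cohort specification (one row per group x motion model) into a
#' single track table with group labels and a ground-truth table. One global
#' seed deterministically spawns per-track child seeds, so the cohort is
#' reproducible regardless of generation order.
#'
#' @param spec A data frame with columns `group`, `model`, `n` (tracks to
#'   generate) and optionally any of [simulate_track()]'s numeric parameters
#'   (`n_frames`, `speed`, `step_sd`, `persistence`, `run_frames_mean`,
#'   `dwell_frames_mean`, `tether_sd`, `jitter_sd`) to override per row.
#' @param frame_interval Minutes per frame (default 20).
#' @param seed Global integer seed.
#'
#' @return A track table (`track_id`, `frame`, `x`, `y`, `group`, `state`)
#'   with attribute `truth`: a tibble of `track_id`, `group`, `model`,
#'   `n_frames`, `seed` per track. Retrieve it with [cohort_truth()].
#' @examples
#' spec <- tibble::tibble(group = "control",
#'                        model = c("ballistic", "stationary"), n = c(3, 2))
#' tr <- simulate_cohort(spec, seed = 7)
#' cohort_truth(tr)
#' @export
simulate_cohort <- function(spec, frame_interval = 20, seed = 1) {
  stopifnot(all(c("group", "model", "n") %in% names(spec)), all(spec$n >= 1))
  spec <- as_tibble(spec)
  total <- sum(spec$n)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, total)
  par_cols <- intersect(names(spec),
                        c("n_frames", "speed", "step_sd", "persistence",
                          "run_frames_mean", "dwell_frames_mean",
                          "tether_sd", "jitter_sd"))
  k <- 0L
  pieces <- vector("list", total)
  truth <- vector("list", total)
  for (r in seq_len(nrow(spec))) {
    for (j in seq_len(spec$n[r])) {
      k <- k + 1L
      args <- list(model = spec$model[r], frame_interval = frame_interval,
                   seed = child_seeds[k],
                   track_id = sprintf("%s_%s_%d_%04d", spec$group[r],
                                      spec$model[r], r, j))
      for (pc in par_cols) if (!is.na(spec[[pc]][r])) args[[pc]] <- spec[[pc]][r]
      tr <- do.call(simulate_track, args)
      tr$group <- spec$group[r]
      pieces[[k]] <- tr
      truth[[k]] <- tibble(track_id = tr$track_id[1], group = spec$group[r],
                           model = spec$model[r], n_frames = nrow(tr),
                           seed = child_seeds[k])
    }
  }
  out <- bind_rows(pieces)
  out <- out[, c("track_id", "frame", "x", "y", "group", "state")]
  attr(out, "truth") <- bind_rows(truth)
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Ground-truth table of a simulated cohort
#'
#' @param tracks A track table produced by [simulate_cohort()].
#' @return The per-track ground-truth tibble stored by the simulator.
#' @export
cohort_truth <- function(tracks) {
  truth <- attr(tracks, "truth")
  if (is.null(truth)) {
    abort("no ground-truth table attached; was this cohort simulated?",
          class = "saltatr_config_error")
  }
  truth
}
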