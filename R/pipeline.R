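#' Configuration for the full screening pipeline
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' sampling (20 min/frame), minimum track length (12 frames = 240 min),
#' non-moving thresholds (15 um diameter, 5 um gyration major axis),
#' dwell-partition parameters (t_scale 1.1, eps 3.3 um, min_pts 4), RDP
#' tolerances (0.5 and 3 um), clustering (k = 10, 20 restarts, 95%
#' explained variance), descriptor grouping (9 groups), screening alpha
#' (0.05), and the RNG seed.
#'
#' @param frame_interval Minutes per frame.
#' @param min_frames Minimum recorded points per track.
#' @param diameter_max_threshold,major_axis_threshold Non-moving filter
#'   thresholds (um).
#' @param combine `"both"`/`"either"` rule of [filter_non_moving()].
#' @param t_scale,eps,min_pts Dwell-partition parameters.
#' @param rdp_eps Two RDP tolerances (um).
#' @param k,n_init,variance_threshold Mode-clustering parameters.
#' @param feature_group_count Descriptor-dendrogram group count.
#' @param alpha Screening significance level.
#' @param control_label Control group label.
#' @param reference_group Clustering anchor; `NULL` clusters all groups
#'   together (unanchored check). Defaults to `control_label`.
#' @param mode_map Optional cluster-to-mode map (see [default_mode_map()]).
#' @param max_lag Largest MSD/VAC lag in minutes (default 1440 = 24 h).
#' @param seed Integer seed for all randomness in the run.
#' @return A list of class `saltatr_config`.
#' @export
pipeline_config <- function(frame_interval = 20, min_frames = 12,
                            diameter_max_threshold = 15,
                            major_axis_threshold = 5,
                            combine = "both",
                            t_scale = 1.1, eps = 3.3, min_pts = 4,
                            rdp_eps = c(0.5, 3),
                            k = 10, n_init = 20, variance_threshold = 0.95,
                            feature_group_count = 9,
                            alpha = 0.05, control_label = "control",
                            reference_group = control_label,
                            mode_map = NULL, max_lag = 1440, seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "saltatr_config")
}

#' Run the full migration screen
#'
#' Orchestrates the standard analysis: validate tracks, drop short tracks,
#' compute the 48-descriptor table, drop non-moving tracks, fit the
#' control-anchored mode model, speed-order its clusters, assign every
#' track, tabulate mode composition and fold changes, screen per-feature
#' treatment effects, and aggregate MSD/VAC curves per mode. The run is
#' deterministic for a fixed config seed, and a manifest records the
#' parameters and the track counts entering and leaving each stage.
#'
#' @param tracks A track table with group labels.
#' @param config A [pipeline_config()].
#' @return A list of class `saltatr_analysis` with elements `features`
#'   (moving tracks only), `filter_reports`, `model`, `assignments`,
#'   `composition`, `stats` (`NULL` if only one group), `msd`, `vac`,
#'   `feature_groups`, `manifest`, `config`.
#' @examples
#' \donttest{
#' spec <- tibble::tibble(group = "control",
#'                        model = c("ballistic", "saltatory", "confined"),
#'                        n = 15)
#' res <- run_pipeline(simulate_cohort(spec, seed = 1),
#'                     pipeline_config(k = 3, seed = 1))
#' res$composition
#' }
#' @export
run_pipeline <- function(tracks, config = pipeline_config()) {
  stopifnot(inherits(config, "saltatr_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), class = "saltatr_pipeline_error")
    })
  }
  tracks <- stage("validate", as_tracks(tracks))
  n_input <- length(unique(tracks$track_id))

  tracks_len <- stage("min_frames_filter",
                      filter_min_frames(tracks, config$min_frames))
  rep_len <- filter_report(tracks_len)

  feats_all <- stage("features", compute_features(
    tracks_len, frame_interval = config$frame_interval,
    partition_params = list(t_scale = config$t_scale, eps = config$eps,
                            min_pts = config$min_pts),
    rdp_eps = config$rdp_eps))

  tracks_mov <- stage("non_moving_filter", filter_non_moving(
    tracks_len, feats_all,
    diameter_max_threshold = config$diameter_max_threshold,
    major_axis_threshold = config$major_axis_threshold,
    combine = config$combine))
  rep_mov <- filter_report(tracks_mov)
  feats <- filter(feats_all,
                  .data$track_id %in% unique(tracks_mov$track_id))

  if (!is.null(config$reference_group) &&
      !config$reference_group %in% feats$group) {
    abort(paste0("anchored clustering needs reference group '",
                 config$reference_group, "' among the moving tracks; ",
                 "set reference_group = NULL to cluster all groups"),
          class = "saltatr_config_error")
  }
  model <- stage("cluster_fit", fit_reference_model(
    feats, reference_group = config$reference_group, k = config$k,
    n_init = config$n_init, variance_threshold = config$variance_threshold,
    seed = config$seed, mode_map = config$mode_map))
  model <- stage("cluster_reorder", reorder_clusters(model))
  assignments <- stage("assign", assign_clusters(feats, model))
  composition <- stage("composition",
                       mode_composition(assignments, config$control_label))

  stats <- NULL
  n_groups <- length(unique(feats$group))
  if (n_groups >= 2) {
    stats <- stage("stats", compare_groups(
      feats, control_label = config$control_label, alpha = config$alpha))
  }

  curves_msd <- stage("msd", lag_curves(
    tracks_mov, "msd", frame_interval = config$frame_interval,
    max_lag = config$max_lag))
  curves_vac <- stage("vac", lag_curves(
    tracks_mov, "vac", frame_interval = config$frame_interval,
    max_lag = config$max_lag))
  lab <- assignments[, c("track_id", "mode")]
  msd <- stage("msd_aggregate",
               aggregate_curves(curves_msd, lab, label_col = "mode"))
  vac <- stage("vac_aggregate",
               aggregate_curves(curves_vac, lab, label_col = "mode"))

  feature_groups <- stage("feature_dendrogram",
                          feature_dendrogram_groups(
                            feats, config$feature_group_count))

  manifest <- tibble(
    stage = c("input", "min_frames_filter", "non_moving_filter",
              "reference_fit"),
    n_tracks = c(n_input, rep_len$n_retained, rep_mov$n_retained,
                 length(model$reference$track_id)),
    n_removed = c(NA, rep_len$n_removed, rep_mov$n_removed, NA),
    rule = c(NA, rep_len$rule, rep_mov$rule,
             if (is.null(config$reference_group)) "all groups"
             else config$reference_group)
  )

  structure(list(
    features = feats, filter_reports = list(min_frames = rep_len,
                                            non_moving = rep_mov),
    model = model, assignments = assignments, composition = composition,
    stats = stats, msd = msd, vac = vac, feature_groups = feature_groups,
    manifest = manifest, config = config
  ), class = "saltatr_analysis")
}

#' @export
print.saltatr_analysis <- function(x, ...) {
  cat("Migration screen\n")
  cat(sprintf("  tracks: %d in, %d after length filter, %d moving\n",
              x$manifest$n_tracks[1], x$manifest$n_tracks[2],
              x$manifest$n_tracks[3]))
  cat(sprintf("  model: k = %d, %d PCs (%.1f%% variance)\n",
              x$model$k, x$model$n_components,
              100 * x$model$explained_variance))
  if (!is.null(x$stats)) {
    cat(sprintf("  screening: %d significant (feature, group) effects\n",
                sum(x$stats$significant)))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `saltatr_analysis`.
#' @param ... Unused.
#' @return A tibble with the stage counts and model dimensions.
#' @method glance saltatr_analysis
#' @export
glance.saltatr_analysis <- function(x, ...) {
  tibble(n_input = x$manifest$n_tracks[1],
         n_after_length_filter = x$manifest$n_tracks[2],
         n_moving = x$manifest$n_tracks[3],
         n_reference = x$manifest$n_tracks[4],
         k = x$model$k, n_components = x$model$n_components,
         n_significant = if (is.null(x$stats)) NA_integer_
                         else sum(x$stats$significant))
}
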