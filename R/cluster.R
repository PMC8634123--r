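feature_matrix <- function(features, feature_names) {
  missing_cols <- setdiff(feature_names, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table is missing descriptor(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "saltatr_format_error")
  }
  m <- as.matrix(features[, feature_names])
  rownames(m) <- features$track_id
  storage.mode(m) <- "double"
  m
}

# Lloyd K-means, best of n_init restarts; single starts that collapse to an
# empty cluster are discarded and retried on the running RNG stream.
best_kmeans <- function(x, k, n_init, max_tries = 10 * n_init) {
  best <- NULL
  done <- 0
  tries <- 0
  while (done < n_init && tries < max_tries) {
    tries <- tries + 1
    fit <- tryCatch(
      suppressWarnings(kmeans(x, centers = k, iter.max = 1000,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) next
    done <- done + 1
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) {
    abort("K-means failed for every restart (k too large for the data?)",
          class = "saltatr_config_error")
  }
  best
}

#' Fit the control-anchored migration-mode model
#'
#' Fits the full normalisation + projection + clustering stack on the
#' reference (control) tracks only: descriptors are z-scored with the
#' reference group's means and standard deviations (population form, so
#' duplicating rows changes nothing), projected by PCA onto the smallest
#' number of components reaching the explained-variance threshold, and
#' clustered by K-means (Lloyd, squared Euclidean) keeping the lowest
#' inertia over `n_init` restarts. Treated tracks are later normalised and
#' projected with these same reference parameters and assigned to the
#' nearest centre ([assign_clusters()]), so treatment effects show up as
#' shifts in cluster occupancy, not as shifts of the cluster definitions.
#'
#' @param features A feature table from [compute_features()].
#' @param reference_group Group label to anchor on (default `"control"`);
#'   `NULL` fits on all tracks regardless of group (the unanchored check).
#' @param k Number of clusters (default 10).
#' @param n_init Number of K-means restarts (default 20).
#' @param variance_threshold Minimum cumulative explained variance for the
#'   retained components (default 0.95).
#' @param seed Integer seed making the fit deterministic.
#' @param mode_map Optional named character vector mapping cluster ids
#'   (after [reorder_clusters()]) to mode names; `NULL` installs the
#'   default Directed/Exploratory/Confined split.
#' @return An object of class `saltatr_mode_model`.
#' @details Descriptors with zero variance in the reference rows cannot be
#'   z-scored and are dropped with a warning.
#' @export
fit_reference_model <- function(features, reference_group = "control",
                                k = 10, n_init = 20,
                                variance_threshold = 0.95, seed = 1,
                                mode_map = NULL) {
  stopifnot(k >= 2, n_init >= 1,
            variance_threshold > 0, variance_threshold <= 1)
  features <- as_tibble(features)
  reg_names <- intersect(feature_registry()$name, names(features))
  ref <- if (is.null(reference_group)) features else {
    filter(features, .data$group == reference_group)
  }
  if (nrow(ref) < k) {
    abort(sprintf("reference group has %d tracks but k = %d", nrow(ref), k),
          class = "saltatr_config_error")
  }
  m_ref <- feature_matrix(ref, reg_names)
  mu <- colMeans(m_ref)
  sdev <- apply(m_ref, 2, pop_sd)
  drop <- sdev <= 0
  if (any(drop)) {
    warn(paste0("dropping zero-variance descriptor(s) in the reference: ",
                paste(reg_names[drop], collapse = ", ")))
  }
  keep <- reg_names[!drop]
  z <- sweep(sweep(m_ref[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  pca <- prcomp(z, center = FALSE, scale. = FALSE)
  evr <- pca$sdev^2 / sum(pca$sdev^2)
  n_comp <- which(cumsum(evr) >= variance_threshold)[1]
  scores <- z %*% pca$rotation[, seq_len(n_comp), drop = FALSE]
  set.seed(seed)
  km <- best_kmeans(scores, k = k, n_init = n_init)
  model <- structure(list(
    reference_group = reference_group,
    feature_names = keep,
    center = mu[keep], scale = sdev[keep],
    rotation = pca$rotation[, seq_len(n_comp), drop = FALSE],
    n_components = n_comp,
    explained_variance = cumsum(evr)[n_comp],
    centers = km$centers,
    k = k,
    inertia = km$tot.withinss,
    mode_map = mode_map %||% default_mode_map(k),
    reference = list(track_id = ref$track_id,
                     labels = unname(km$cluster),
                     features = ref),
    params = list(n_init = n_init, variance_threshold = variance_threshold,
                  seed = seed)
  ), class = "saltatr_mode_model")
  model
}

#' Default cluster-to-mode map
#'
#' Migration modes group clusters into three behavioural categories:
#' Directed (fast, straight), Exploratory (fast but turning and pausing)
#' and Confined (slow, spatially restricted). After speed-ordering the
#' clusters ([reorder_clusters()]), the default map assigns the fastest
#' ~40% of clusters to Directed and splits the remainder evenly between
#' Exploratory and Confined; with `k = 10` that is clusters 1-4, 5-7 and
#' 8-10. The boundaries are a manual modelling choice — pass your own map
#' to override.
#'
#' @param k Number of clusters.
#' @return Named character vector: names are cluster ids `1..k`, values
#'   are mode names.
#' @export
default_mode_map <- function(k) {
  n_dir <- max(1, round(0.4 * k))
  n_exp <- max(1, round(0.3 * k))
  if (n_dir + n_exp >= k) { n_dir <- max(1, k - 2); n_exp <- 1 }
  modes <- c(rep("Directed", n_dir), rep("Exploratory", n_exp),
             rep("Confined", k - n_dir - n_exp))
  setNames(modes, as.character(seq_len(k)))
}

#' Assign tracks to the fitted clusters
#'
#' Normalises with the reference z-score parameters, projects into the
#' reference principal-component space, and assigns each track to the
#' nearest cluster centre (squared Euclidean; ties go to the lowest
#' cluster id).
#'
#' @param features A feature table whose descriptor columns match the model.
#' @param model A `saltatr_mode_model` from [fit_reference_model()].
#' @return A tibble `track_id`, `group`, `cluster`, `mode`.
#' @export
assign_clusters <- function(features, model) {
  features <- as_tibble(features)
  m <- feature_matrix(features, model$feature_names)
  z <- sweep(sweep(m, 2, model$center), 2, model$scale, "/")
  scores <- z %*% model$rotation
  d2 <- outer(rowSums(scores^2), rowSums(model$centers^2), "+") -
    2 * scores %*% t(model$centers)
  cl <- apply(d2, 1, which.min)  # which.min takes the lowest index on ties
  tibble(track_id = features$track_id, group = features$group,
         cluster = as.integer(cl),
         mode = unname(model$mode_map[as.character(cl)]))
}

#' Inertia profile over a range of cluster counts
#'
#' Runs the reference pipeline (z-score, PCA) once and K-means for each
#' candidate `k`, reporting the best-of-restarts within-cluster sum of
#' squares. The profile supports the elbow heuristic; no k is chosen
#' automatically.
#'
#' @inheritParams fit_reference_model
#' @param k_range Integer vector of candidate cluster counts.
#' @return A tibble `k`, `inertia`.
#' @export
elbow_scan <- function(features, k_range = 2:15, reference_group = "control",
                       n_init = 20, variance_threshold = 0.95, seed = 1) {
  features <- as_tibble(features)
  reg_names <- intersect(feature_registry()$name, names(features))
  ref <- if (is.null(reference_group)) features else {
    filter(features, .data$group == reference_group)
  }
  m_ref <- feature_matrix(ref, reg_names)
  mu <- colMeans(m_ref)
  sdev <- apply(m_ref, 2, pop_sd)
  keep <- sdev > 0
  z <- sweep(sweep(m_ref[, keep, drop = FALSE], 2, mu[keep]), 2,
             sdev[keep], "/")
  pca <- prcomp(z, center = FALSE, scale. = FALSE)
  evr <- pca$sdev^2 / sum(pca$sdev^2)
  n_comp <- which(cumsum(evr) >= variance_threshold)[1]
  scores <- z %*% pca$rotation[, seq_len(n_comp), drop = FALSE]
  stopifnot(max(k_range) <= nrow(scores))
  set.seed(seed)
  purrr::map_dfr(k_range, function(k) {
    km <- if (k < nrow(scores)) best_kmeans(scores, k, n_init) else {
      # k = n: every point its own centre
      list(tot.withinss = 0)
    }
    tibble(k = k, inertia = km$tot.withinss)
  })
}

#' Reorder cluster ids by a reference-cluster statistic
#'
#' Pure relabelling: cluster ids are permuted so that cluster 1 has the
#' highest reference-group mean of the ordering feature (mean speed by
#' default, putting Directed-like clusters first), leaving assignments
#' unchanged up to the permutation. Idempotent.
#'
#' @param model A `saltatr_mode_model`.
#' @param by Descriptor name used as the ordering key.
#' @param decreasing Order direction (default `TRUE`).
#' @return The model with permuted centres and reference labels.
#' @export
reorder_clusters <- function(model, by = "speed_mean", decreasing = TRUE) {
  ref_feat <- model$reference$features
  if (!by %in% names(ref_feat)) {
    abort(paste0("ordering feature not in reference table: ", by),
          class = "saltatr_config_error")
  }
  key <- vapply(seq_len(model$k), function(cl) {
    mean(ref_feat[[by]][model$reference$labels == cl])
  }, numeric(1))
  key[is.nan(key)] <- -Inf
  perm <- order(key, decreasing = decreasing)  # perm[new] = old
  inv <- match(seq_len(model$k), perm)         # inv[old] = new
  model$centers <- model$centers[perm, , drop = FALSE]
  rownames(model$centers) <- NULL
  model$reference$labels <- inv[model$reference$labels]
  model
}

#' Group correlated descriptors by hierarchical clustering
#'
#' Clusters the descriptors (not the tracks): Ward minimum-variance
#' agglomeration on the Euclidean distances between z-scored descriptor
#' profiles across tracks, cut into exactly `n_groups` flat groups.
#' Strongly co-varying descriptors (e.g. the speed family) land in the
#' same group, giving a compact functional organisation of the registry.
#'
#' @param features A feature table.
#' @param n_groups Number of descriptor groups (default 9).
#' @return A tibble `feature`, `feature_group`.
#' @export
feature_dendrogram_groups <- function(features, n_groups = 9) {
  features <- as_tibble(features)
  reg_names <- intersect(feature_registry()$name, names(features))
  if (length(reg_names) < n_groups) {
    abort("fewer descriptors than requested groups",
          class = "saltatr_config_error")
  }
  m <- feature_matrix(features, reg_names)
  sdev <- apply(m, 2, pop_sd)
  z <- sweep(sweep(m, 2, colMeans(m)), 2, pmax(sdev, 1e-12), "/")
  hc <- hclust(dist(t(z)), method = "ward.D2")
  grp <- cutree(hc, k = n_groups)
  tibble(feature = names(grp), feature_group = unname(grp))
}

#' Mode composition per treatment group
#'
#' Tabulates the proportion of each group's tracks falling into each
#' migration mode and the fold change of those proportions relative to the
#' control group. Composition shifts are reported descriptively (no
#' hypothesis test).
#'
#' @param assignments A tibble with `track_id`, `group`, `mode` (from
#'   [assign_clusters()]).
#' @param control_label Label of the control group (default `"control"`).
#' @return A tibble `group`, `mode`, `n`, `prop`, `fold_change` (fold
#'   change `NA` with a warning when the control group is absent).
#' @export
mode_composition <- function(assignments, control_label = "control") {
  assignments <- as_tibble(assignments)
  modes <- unique(assignments$mode)
  comp <- assignments |>
    count(.data$group, .data$mode) |>
    tidyr::complete(group = unique(assignments$group), mode = modes,
                    fill = list(n = 0L)) |>
    group_by(.data$group) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup()
  if (!control_label %in% comp$group) {
    warn("control group absent; fold changes omitted")
    comp$fold_change <- NA_real_
    return(comp)
  }
  ctrl <- comp |> filter(.data$group == control_label) |>
    select("mode", ctrl_prop = "prop")
  comp |>
    left_join(ctrl, by = "mode") |>
    mutate(fold_change = ifelse(.data$ctrl_prop > 0,
                                .data$prop / .data$ctrl_prop, NA_real_)) |>
    select(-"ctrl_prop")
}

#' @export
print.saltatr_mode_model <- function(x, ...) {
  cat(sprintf(paste0("Migration-mode model: k = %d clusters on %d PCs ",
                     "(%.1f%% variance), %d reference tracks%s\n"),
              x$k, x$n_components, 100 * x$explained_variance,
              length(x$reference$track_id),
              if (is.null(x$reference_group)) " (unanchored)"
              else paste0(" ('", x$reference_group, "')")))
  invisible(x)
}

#' Tidy a migration-mode model
#'
#' @param x A `saltatr_mode_model`.
#' @param ... Unused.
#' @return One row per cluster: id, mode, number of reference tracks and
#'   their mean speed.
#' @method tidy saltatr_mode_model
#' @export
tidy.saltatr_mode_model <- function(x, ...) {
  ref <- x$reference
  purrr::map_dfr(seq_len(x$k), function(cl) {
    in_cl <- ref$labels == cl
    tibble(cluster = cl, mode = unname(x$mode_map[as.character(cl)]),
           n_reference = sum(in_cl),
           speed_mean = if (any(in_cl)) mean(ref$features$speed_mean[in_cl])
                        else NA_real_)
  })
}

#' @rdname tidy.saltatr_mode_model
#' @method glance saltatr_mode_model
#' @export
glance.saltatr_mode_model <- function(x, ...) {
  tibble(k = x$k, n_components = x$n_components,
         explained_variance = x$explained_variance,
         inertia = x$inertia,
         n_reference = length(x$reference$track_id),
         n_features = length(x$feature_names))
}
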