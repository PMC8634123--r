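#' Per-feature treatment screening statistics
#'
#' For every descriptor, first a Kruskal-Wallis test across all groups
#' (chi-square approximation with tie correction), then a two-sided
#' Mann-Whitney U test of each treatment group against the control with
#' Bonferroni correction over the treatment comparisons of that feature.
#' The effect size is the log2 ratio of the treatment's central value
#' (median by default) to the control's — positive when treatment raises
#' the descriptor. Circular descriptors (`velocity_avg_angle`,
#' `gyration_orientation`) and any feature with a non-positive central
#' value have no meaningful log-ratio and are flagged undefined rather
#' than fabricated.
#'
#' @param features A feature table with a `group` column.
#' @param control_label Control group label (default `"control"`).
#' @param alpha Significance level after correction (default 0.05).
#' @param center `"median"` (default) or `"mean"` central value for the
#'   effect ratio.
#' @return A tibble of class `saltatr_group_stats`: one row per
#'   (feature, treatment group) with `effect_log2`, `effect_defined`,
#'   `p_kruskal` (per feature), `p_raw`, `p_bonferroni`, `significant`,
#'   `stars` (`*`, `**`, `***` at 0.05/0.01/0.001 on the corrected p).
#' @details Groups with fewer than 2 tracks are skipped with a warning.
#'   A descriptor constant across all tracks gets `p = 1` and a flag.
#' @export
compare_groups <- function(features, control_label = "control",
                           alpha = 0.05, center = c("median", "mean")) {
  center <- match.arg(center)
  features <- as_tibble(features)
  if (!control_label %in% features$group) {
    abort(paste0("control group '", control_label, "' not present"),
          class = "saltatr_config_error")
  }
  cfun <- if (center == "median") median else mean
  reg_names <- intersect(feature_registry()$name, names(features))
  circular <- c("velocity_avg_angle", "gyration_orientation")
  sizes <- table(features$group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("group(s) with < 2 tracks skipped: ",
                paste(small, collapse = ", ")))
  }
  groups <- setdiff(names(sizes)[sizes >= 2], control_label)
  if (length(groups) == 0) {
    abort("no treatment group with >= 2 tracks", class = "saltatr_config_error")
  }
  use <- features$group %in% c(control_label, groups)
  features <- features[use, ]
  n_comp <- length(groups)

  out <- purrr::map_dfr(reg_names, function(feat) {
    v <- features[[feat]]
    g <- features$group
    constant <- pop_sd(v) == 0
    p_kw <- if (constant) 1 else {
      suppressWarnings(kruskal.test(v, factor(g))$p.value)
    }
    ctrl_v <- v[g == control_label]
    ctrl_c <- cfun(ctrl_v)
    purrr::map_dfr(groups, function(gr) {
      tr_v <- v[g == gr]
      p_raw <- if (constant) 1 else {
        suppressWarnings(wilcox.test(tr_v, ctrl_v, alternative = "two.sided",
                                     correct = TRUE)$p.value)
      }
      tr_c <- cfun(tr_v)
      defined <- !(feat %in% circular) && tr_c > 0 && ctrl_c > 0
      p_bonf <- min(1, p_raw * n_comp)
      tibble(
        feature = feat, group = gr,
        effect_log2 = if (defined) log2(tr_c / ctrl_c) else NA_real_,
        effect_defined = defined,
        center_treatment = tr_c, center_control = ctrl_c,
        p_kruskal = p_kw, p_raw = p_raw, p_bonferroni = p_bonf,
        significant = p_bonf < alpha,
        stars = stars_for(p_bonf),
        constant_feature = constant
      )
    })
  })
  structure(out, control_label = control_label, alpha = alpha,
            center = center,
            class = c("saltatr_group_stats", class(out)))
}

stars_for <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}

#' Control-normalised effect matrix with significance mask
#'
#' Reshapes a [compare_groups()] result into the screening heatmap: a
#' feature x group matrix of log2 effects and a parallel logical mask that
#' is `TRUE` where the corrected p-value stays above alpha (entries to
#' grey out) or where the effect is undefined.
#'
#' @param stats A `saltatr_group_stats` result.
#' @return A list with matrices `effect` and `masked` (same dimnames).
#' @export
effect_matrix <- function(stats) {
  wide_e <- tidyr::pivot_wider(as_tibble(stats)[, c("feature", "group", "effect_log2")],
                               names_from = "group", values_from = "effect_log2")
  wide_m <- tidyr::pivot_wider(
    mutate(as_tibble(stats), masked = !.data$significant | !.data$effect_defined)[,
      c("feature", "group", "masked")],
    names_from = "group", values_from = "masked")
  eff <- as.matrix(wide_e[, -1]); rownames(eff) <- wide_e$feature
  msk <- as.matrix(wide_m[, -1]); rownames(msk) <- wide_m$feature
  list(effect = eff, masked = msk)
}

#' Summarise a screening result
#'
#' @param x A `saltatr_group_stats` result.
#' @param ... Unused.
#' @return A one-row tibble: comparisons made, significant count, alpha.
#' @method glance saltatr_group_stats
#' @export
glance.saltatr_group_stats <- function(x, ...) {
  tibble(n_features = length(unique(x$feature)),
         n_groups = length(unique(x$group)),
         n_significant = sum(x$significant),
         alpha = attr(x, "alpha"),
         center = attr(x, "center"))
}
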