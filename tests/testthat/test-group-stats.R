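# hand rank-sum oracles on tiny samples
kw_oracle <- function(groups) {
  v <- unlist(groups)
  r <- rank(v)
  n <- length(v)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(groups), function(i) {
      ri <- r[idx == i]
      length(ri) * (mean(ri) - (n + 1) / 2)^2
    }, numeric(1)))
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

u_oracle <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

test_that("Kruskal-Wallis H on the three-group toy equals the rank oracle", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(kw_oracle(groups), 7.2)
  kt <- kruskal.test(unlist(groups), factor(rep(1:3, each = 3)))
  expect_equal(unname(kt$statistic), 7.2)
  expect_equal(unname(kt$statistic), kw_oracle(groups))
})

test_that("the Mann-Whitney U statistic matches exhaustive pair counting", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(u_oracle(x, y), 0)
  expect_equal(unname(wilcox.test(x, y)$statistic), u_oracle(x, y))
  set.seed(20)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(6)
    expect_equal(unname(wilcox.test(a, b)$statistic), u_oracle(a, b))
  }
})

# small synthetic feature tables for screening tests: only a handful of
# descriptors vary; the rest are noise so nothing is constant
stats_features <- function(per_group, seed = 1, transform = identity) {
  set.seed(seed)
  reg <- feature_registry()$name
  n <- sum(lengths(per_group) > 0) * 0 + sum(vapply(per_group, length, integer(1)))
  sizes <- vapply(per_group, length, integer(1))
  m <- matrix(abs(rnorm(sum(sizes) * length(reg), mean = 5)),
              sum(sizes), length(reg), dimnames = list(NULL, reg))
  ft <- tibble::as_tibble(m)
  ft$track_id <- sprintf("s%04d", seq_len(sum(sizes)))
  ft$group <- rep(names(per_group), sizes)
  ft
}

test_that("log2 effects follow exact fold changes and the mask logic", {
  set.seed(30)
  base <- abs(rnorm(50, 10, 1))
  reg <- feature_registry()$name
  mk <- function(vals, group, off) {
    m <- matrix(abs(rnorm(length(vals) * length(reg), 5)),
                length(vals), length(reg), dimnames = list(NULL, reg))
    ft <- tibble::as_tibble(m)
    ft$speed_mean <- vals
    ft$track_id <- sprintf("%s%03d", group, seq_along(vals))
    ft$group <- group
    ft
  }
  ft <- dplyr::bind_rows(mk(base, "control"), mk(2 * base, "double"),
                         mk(base / 4, "quarter"), mk(base, "same"))
  st <- compare_groups(ft)
  sm <- dplyr::filter(st, feature == "speed_mean")
  expect_equal(sm$effect_log2[sm$group == "double"], 1)
  expect_equal(sm$effect_log2[sm$group == "quarter"], -2)
  expect_equal(sm$effect_log2[sm$group == "same"], 0)
  expect_false(sm$significant[sm$group == "same"])
  expect_true(all(sm$significant[sm$group %in% c("double", "quarter")]))

  # circular descriptors are never given a log-ratio
  expect_true(all(!st$effect_defined[st$feature == "velocity_avg_angle"]))

  em <- effect_matrix(st)
  expect_equal(dim(em$effect), c(48, 3))
  expect_equal(dim(em$masked), dim(em$effect))
  expect_true(all(em$masked[!is.na(em$effect) & abs(em$effect) < 1e-12]))
})

test_that("a large constant shift is detected after Bonferroni correction", {
  ft <- stats_features(list(control = 1:50, shifted = 1:50), seed = 31)
  ft$speed_mean[ft$group == "shifted"] <- ft$speed_mean[ft$group == "shifted"] + 10
  st <- compare_groups(ft)
  row <- dplyr::filter(st, feature == "speed_mean", group == "shifted")
  expect_lt(row$p_bonferroni, 0.001)
  expect_equal(row$stars, "***")
})

test_that("Bonferroni significance is a subset of uncorrected significance", {
  ft <- stats_features(list(control = 1:25, a = 1:25, b = 1:25, c = 1:25),
                       seed = 32)
  st <- compare_groups(ft)
  expect_true(all(st$p_bonferroni >= st$p_raw))
  expect_true(all(st$p_bonferroni <= pmin(1, st$p_raw * 3 + 1e-12)))
  expect_true(all(which(st$p_bonferroni < 0.05) %in% which(st$p_raw < 0.05)))
})

test_that("effects are antisymmetric under swapping treatment and control", {
  ft <- stats_features(list(control = 1:20, drug = 1:20), seed = 33)
  st1 <- compare_groups(ft)
  ft_sw <- dplyr::mutate(ft, group = ifelse(group == "control", "drug", "control"))
  st2 <- compare_groups(ft_sw)
  defined <- st1$effect_defined & st2$effect_defined
  expect_equal(st1$effect_log2[defined], -st2$effect_log2[defined])
  expect_equal(st1$p_raw, st2$p_raw, tolerance = 1e-12)
})

test_that("results are invariant to row order and to unrelated groups", {
  ft <- stats_features(list(control = 1:20, a = 1:20), seed = 34)
  st <- compare_groups(ft)
  st_perm <- compare_groups(ft[sample(nrow(ft)), ])
  expect_equal(as.data.frame(st), as.data.frame(st_perm))

  ft_extra <- dplyr::bind_rows(ft, stats_features(list(zzz = 1:15), seed = 35))
  st_extra <- compare_groups(ft_extra)
  a_rows <- as.data.frame(dplyr::filter(st_extra, group == "a"))
  # p_raw and effects vs control unchanged by the unrelated group; only the
  # Bonferroni factor and the omnibus test see it
  expect_equal(a_rows$p_raw, st$p_raw)
  expect_equal(a_rows$effect_log2, st$effect_log2)
})

test_that("degenerate inputs are flagged, not fabricated", {
  ft <- stats_features(list(control = 1:10, a = 1:10), seed = 36)
  ft$confinement_ratio <- 0.5  # constant across all tracks
  st <- compare_groups(ft)
  row <- dplyr::filter(st, feature == "confinement_ratio")
  expect_equal(row$p_raw, 1)
  expect_equal(row$p_kruskal, 1)
  expect_true(row$constant_feature)

  expect_error(compare_groups(dplyr::mutate(ft, group = "x")),
               class = "saltatr_config_error")
  expect_warning(
    compare_groups(dplyr::bind_rows(
      ft, dplyr::mutate(ft[1, ], group = "tiny", track_id = "only"))),
    "skipped")
})
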