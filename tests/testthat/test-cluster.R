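# Synthetic feature tables with planted blobs: every descriptor gets unit
# Gaussian noise and each blob a random centre offset across all
# descriptors (scale 10 noise sds), plus a monotone speed_mean shift so the
# blobs have a known speed order for the reordering tests.
make_blob_features <- function(n_per = 30, n_blobs = 3, sep = 10,
                               seed = 1, group = "control") {
  set.seed(seed)
  reg <- feature_registry()$name
  n <- n_per * n_blobs
  centers <- matrix(rnorm(n_blobs * length(reg), 0, sep), n_blobs,
                    length(reg))
  centers[, match("speed_mean", reg)] <- sep * 4 * (n_blobs - seq_len(n_blobs))
  blob <- rep(seq_len(n_blobs), each = n_per)
  m <- centers[blob, ] + matrix(rnorm(n * length(reg)), n, length(reg))
  colnames(m) <- reg
  out <- tibble::as_tibble(m)
  out$track_id <- sprintf("t%04d", seq_len(n))
  out$group <- group
  out$.blob <- blob
  out[, c("track_id", "group", ".blob", reg)]
}

test_that("well-separated blobs are recovered exactly and deterministically", {
  ft <- make_blob_features(30, seed = 5)
  m1 <- fit_reference_model(ft, k = 3, seed = 7)
  lab <- assign_clusters(ft, m1)
  expect_equal(adjusted_rand_index(lab$cluster, ft$.blob), 1)

  m2 <- fit_reference_model(ft, k = 3, seed = 7)
  expect_identical(m1$centers, m2$centers)

  # reference rows keep the labels the fit produced
  expect_equal(lab$cluster[match(m1$reference$track_id, lab$track_id)],
               m1$reference$labels)
})

test_that("the internal adjusted Rand index agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:20) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("duplicating every reference row leaves the model unchanged", {
  ft <- make_blob_features(25, seed = 6)
  m1 <- fit_reference_model(ft, k = 3, seed = 3)
  ft2 <- dplyr::bind_rows(ft, dplyr::mutate(ft, track_id = paste0(track_id, "_dup")))
  m2 <- fit_reference_model(ft2, k = 3, seed = 3)
  expect_equal(m1$center, m2$center)     # population moments are duplication-proof
  expect_equal(m1$scale, m2$scale)
  expect_equal(m1$n_components, m2$n_components)
  # same centers up to cluster permutation, compared in z-space because the
  # principal-axis signs are arbitrary
  cz1 <- m1$centers %*% t(m1$rotation)
  cz2 <- m2$centers %*% t(m2$rotation)
  d <- as.matrix(dist(rbind(cz1, cz2)))[1:3, 4:6]
  expect_lt(max(apply(d, 1, min)), 1e-6)
  # and the induced partition of the original rows is identical
  expect_equal(adjusted_rand_index(
    assign_clusters(ft, m1)$cluster, assign_clusters(ft, m2)$cluster), 1)
})

test_that("an observation at a center is assigned to that cluster", {
  ft <- make_blob_features(20, seed = 8)
  m <- fit_reference_model(ft, k = 3, seed = 2)
  # invert the projection for a synthetic row exactly at center 2
  z <- m$rotation %*% m$centers[2, ]           # least-norm preimage in z-space
  raw <- z * m$scale + m$center
  row <- ft[1, ]
  row[, m$feature_names] <- as.list(raw)
  row$track_id <- "at_center"
  expect_equal(assign_clusters(row, m)$cluster, 2L)
})

test_that("the explained-variance rule picks the smallest sufficient rank", {
  ft <- make_blob_features(40, seed = 9)
  m95 <- fit_reference_model(ft, k = 3, variance_threshold = 0.95, seed = 1)
  m50 <- fit_reference_model(ft, k = 3, variance_threshold = 0.50, seed = 1)
  expect_gte(m95$explained_variance, 0.95)
  expect_lte(m50$n_components, m95$n_components)
})

test_that("inertia decreases with k and the elbow sits at the planted blob count", {
  ft <- make_blob_features(20, seed = 10)
  scan <- elbow_scan(ft, k_range = c(2:6, nrow(ft)), n_init = 5, seed = 4)
  expect_true(all(diff(scan$inertia) <= 1e-8))
  expect_equal(scan$inertia[scan$k == nrow(ft)], 0)
  drops <- -diff(scan$inertia[1:5]) / pmax(scan$inertia[1:4], 1e-12)
  expect_equal(scan$k[which.max(drops) + 1], 3)
})

test_that("cluster reordering is a pure idempotent relabeling by speed", {
  ft <- make_blob_features(20, seed = 12)
  m <- fit_reference_model(ft, k = 3, seed = 5)
  mo <- reorder_clusters(m)
  # fastest blob (largest speed_mean offset) becomes cluster 1
  ref_speed <- vapply(1:3, function(cl) {
    mean(mo$reference$features$speed_mean[mo$reference$labels == cl])
  }, numeric(1))
  expect_true(all(diff(ref_speed) < 0))
  mo2 <- reorder_clusters(mo)
  expect_identical(mo$centers, mo2$centers)
  expect_identical(mo$reference$labels, mo2$reference$labels)
  # relabeling never changes the partition
  expect_equal(
    adjusted_rand_index(assign_clusters(ft, m)$cluster,
                        assign_clusters(ft, mo)$cluster), 1)
})

test_that("z-scoring absorbs affine rescaling of any single descriptor", {
  ft <- make_blob_features(20, seed = 13)
  m <- fit_reference_model(ft, k = 3, seed = 6)
  ft2 <- dplyr::mutate(ft, gyration_radius = 1000 * gyration_radius + 5)
  m2 <- fit_reference_model(ft2, k = 3, seed = 6)
  expect_equal(assign_clusters(ft, m)$cluster, assign_clusters(ft2, m2)$cluster)
})

test_that("correlated descriptors co-group in the feature dendrogram", {
  set.seed(14)
  ft <- make_blob_features(40, seed = 14)
  # speed_median made an exact affine copy of speed_mean
  ft$speed_median <- 2 * ft$speed_mean + 1
  grp <- feature_dendrogram_groups(ft, n_groups = 9)
  expect_equal(nrow(grp), 48)
  expect_equal(length(unique(grp$feature_group)), 9)
  expect_equal(grp$feature_group[grp$feature == "speed_mean"],
               grp$feature_group[grp$feature == "speed_median"])
})

test_that("planted orthogonal descriptor blocks are recovered exactly", {
  set.seed(15)
  reg <- feature_registry()$name
  n <- 120
  block <- rep(1:9, length.out = 48)  # planted grouping of the 48 descriptors
  latent <- matrix(rnorm(n * 9), n, 9)
  m <- sapply(seq_along(reg), function(j) {
    latent[, block[j]] + rnorm(n, 0, 0.01)
  })
  colnames(m) <- reg
  ft <- tibble::as_tibble(m)
  ft$track_id <- sprintf("t%03d", 1:n)
  ft$group <- "control"
  grp <- feature_dendrogram_groups(ft, n_groups = 9)
  expect_equal(adjusted_rand_index(grp$feature_group[match(reg, grp$feature)],
                                   block), 1)
})

test_that("mode composition proportions and fold changes are exact", {
  asg <- tibble::tibble(
    track_id = as.character(1:20),
    group = rep(c("control", "drug"), each = 10),
    mode = c(rep("Directed", 4), rep("Exploratory", 3), rep("Confined", 3),
             rep("Directed", 2), rep("Exploratory", 5), rep("Confined", 3)))
  comp <- mode_composition(asg)
  expect_equal(sum(comp$prop[comp$group == "control"]), 1)
  expect_equal(sum(comp$prop[comp$group == "drug"]), 1)
  expect_equal(comp$fold_change[comp$group == "drug" & comp$mode == "Directed"],
               0.5)
  expect_true(all(comp$fold_change[comp$group == "control"] == 1))

  expect_warning(mode_composition(asg, control_label = "absent"),
                 "control group absent")
})

test_that("tidy and glance summarise a fitted model", {
  ft <- make_blob_features(20, seed = 16)
  m <- reorder_clusters(fit_reference_model(ft, k = 3, seed = 1))
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$n_reference), 60)
  gl <- glance(m)
  expect_equal(gl$k, 3)
  expect_gte(gl$explained_variance, 0.95)
})
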