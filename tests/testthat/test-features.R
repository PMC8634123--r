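test_that("path, net and duration follow the 3-4-5 geometry", {
  t345 <- data.frame(frame = 0:2, x = c(0, 3, 6), y = c(0, 4, 8))
  expect_equal(path_length(t345), 10)
  expect_equal(net_displacement(t345), 10)
  expect_equal(net_displacement(square_track()), 0)
  # 13 recorded frames at 20 min span 240 min
  expect_equal(track_duration(straight_track(13)), 240)
})

test_that("diameter statistics agree with a brute-force double loop", {
  sq <- data.frame(frame = 0:3, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(diameter_stats(sq)$track_diameter_max, sqrt(2))
  two <- data.frame(frame = 0:1, x = c(0, 5), y = 0)
  ds <- diameter_stats(two)
  expect_equal(ds$track_diameter_max, 5)
  expect_equal(ds$track_diameter_mean, 5)

  tr <- random_track(20, seed = 7)
  d <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    d <- c(d, sqrt((tr$x[i] - tr$x[j])^2 + (tr$y[i] - tr$y[j])^2))
  }
  ds <- diameter_stats(tr)
  expect_identical(ds$track_diameter_max, max(d))
  expect_equal(ds$track_diameter_mean, mean(d))
  expect_equal(ds$track_diameter_median, median(d))
})

test_that("instantaneous speeds use the actual elapsed time", {
  line <- straight_track(5, step = 2)
  sp <- speed_stats(line)
  expect_equal(sp$speed_mean, 0.1)
  expect_equal(sp$speed_std, 0)

  two <- data.frame(frame = 0:2, x = c(0, 2, 6), y = 0)
  sp2 <- speed_stats(two)
  expect_equal(sp2$speed_mean, 0.15)
  expect_equal(sp2$speed_min, 0.1)
  expect_equal(sp2$speed_max, 0.2)

  # a frame gap widens the time base: frames 0 -> 2 over 4 um is 0.1 um/min
  gap <- data.frame(frame = c(0, 2), x = c(0, 4), y = c(0, 0))
  expect_equal(speed_stats(gap)$speed_mean, 0.1)
})

test_that("directional changes are unsigned interior angles", {
  expect_equal(directional_change_stats(straight_track(6))$dc_max, 0)
  expect_equal(directional_change_count(straight_track(6))$dc_prop_gt20, 0)

  sq <- square_track()
  dc <- directional_change_stats(sq)
  expect_equal(dc$dc_mean, 90)
  expect_equal(dc$dc_std, 0)
  cnt <- directional_change_count(sq)
  expect_equal(cnt$dc_prop_gt45, 1)
  expect_equal(cnt$dc_prop_gt90, 0)  # strict inequality

  back <- data.frame(frame = 0:2, x = c(0, 1, 0), y = 0)
  expect_equal(directional_change_stats(back)$dc_max, 180)
})

test_that("average velocity is the net displacement over duration", {
  b <- simulate_track("ballistic", n_frames = 10, speed = 0.1, heading = 0,
                      jitter_sd = 0, seed = 1)
  va <- velocity_average(b)
  expect_equal(va$velocity_avg_magnitude, 0.1)
  expect_equal(va$velocity_avg_angle, 0)

  loop <- velocity_average(square_track())
  expect_equal(loop$velocity_avg_magnitude, 0)
  expect_equal(loop$velocity_avg_angle, 0)

  va2 <- velocity_average(l_track())  # (0,0)->(3,0)->(3,4) over 40 min
  expect_equal(va2$velocity_avg_magnitude, 0.125)
  expect_equal(va2$velocity_avg_angle, atan2(4, 3) * 180 / pi)
})

test_that("gyration tensor matches a brute-force covariance oracle", {
  lin <- gyration_tensor_features(straight_track(8))
  expect_equal(lin$gyration_tensor_minor_axis_length, 0)
  expect_equal(lin$gyration_asphericity, 1)

  corners <- data.frame(frame = 0:3, x = c(1, -1, 1, -1), y = c(1, 1, -1, -1))
  g <- gyration_tensor_features(corners)
  expect_equal(g$gyration_radius, sqrt(2))
  expect_equal(g$gyration_asphericity, 0)
  expect_equal(g$gyration_tensor_major_axis_length, 2)

  tr <- random_track(30, seed = 9)
  xc <- tr$x - mean(tr$x); yc <- tr$y - mean(tr$y)
  n <- 30
  Tm <- matrix(c(sum(xc^2), sum(xc * yc), sum(xc * yc), sum(yc^2)) / n, 2, 2)
  ev <- sort(eigen(Tm, only.values = TRUE)$values, decreasing = TRUE)
  g2 <- gyration_tensor_features(tr)
  expect_equal((g2$gyration_tensor_major_axis_length / 2)^2, ev[1],
               tolerance = 1e-9)
  expect_equal((g2$gyration_tensor_minor_axis_length / 2)^2, ev[2],
               tolerance = 1e-9)
  expect_equal(g2$gyration_radius^2, sum(ev), tolerance = 1e-9)
})

test_that("confinement ratio and straight-line speed behave on canonical paths", {
  expect_equal(confinement_ratio(straight_track(7)), 1)
  expect_equal(confinement_ratio(l_track()), 5 / 7)
  expect_equal(confinement_ratio(square_track()), 0)
  expect_equal(mean_straight_line_speed(l_track()), 5 / 40)
  # zero path length -> defined 0
  still <- data.frame(frame = 0:2, x = 0, y = 0)
  expect_equal(confinement_ratio(still), 0)
})

test_that("the feature table is complete, ordered and deterministic", {
  spec <- tibble::tibble(group = c("control", "drug"),
                         model = c("saltatory", "confined"), n = c(4, 4),
                         n_frames = 24)
  tr <- simulate_cohort(spec, seed = 13)
  ft <- compute_features(tr)
  reg <- feature_registry()
  expect_equal(nrow(reg), 48)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_equal(names(ft), c("track_id", "group", reg$name))
  expect_equal(nrow(ft), 8)
  expect_false(anyNA(ft))

  # permuting track rows changes nothing but row order
  tr_perm <- tr[rev(seq_len(nrow(tr))), ]
  ft_perm <- compute_features(tr_perm)
  expect_equal(as.data.frame(dplyr::arrange(ft_perm, track_id)),
               as.data.frame(dplyr::arrange(ft, track_id)))

  # two identical tracks give identical rows
  dup <- dplyr::bind_rows(
    with_id(random_track(15, seed = 1), "a"),
    with_id(random_track(15, seed = 1), "b"))
  ft_dup <- compute_features(dup)
  expect_equal(as.numeric(ft_dup[1, reg$name]), as.numeric(ft_dup[2, reg$name]))
})

test_that("feature inequalities and rigid-motion invariances hold on random tracks", {
  reg <- feature_registry()
  rotating <- c("velocity_avg_angle", "gyration_orientation")
  for (seed in 1:10) {
    tr <- with_id(random_track(18, seed = seed))
    ft <- compute_features(tr)
    expect_lte(ft$confinement_ratio, 1)
    expect_lte(ft$mean_straight_line_speed, ft$speed_mean + 1e-12)
    expect_gte(ft$track_diameter_max, ft$net_displacement - 1e-12)
    expect_lte(ft$gyration_radius, ft$track_diameter_max + 1e-12)

    shifted <- dplyr::mutate(tr, x = x + 137.2, y = y - 55.9)
    ft_s <- compute_features(shifted)
    expect_equal(as.numeric(ft_s[, reg$name]), as.numeric(ft[, reg$name]),
                 tolerance = 1e-8)

    th <- 0.7
    rot <- dplyr::mutate(tr, x0 = x, x = cos(th) * x0 - sin(th) * y,
                         y = sin(th) * x0 + cos(th) * y, x0 = NULL)
    ft_r <- compute_features(rot)
    keep <- setdiff(reg$name, rotating)
    expect_equal(as.numeric(ft_r[, keep]), as.numeric(ft[, keep]),
                 tolerance = 1e-8)
  }
})
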