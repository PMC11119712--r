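# Open-field metrics: distance, habituation, centre time, bouts, fractions.

test_that("distance series handles stationary, calibrated and synthetic walks", {
  tr <- make_track(rep(5, 10), rep(5, 10))
  expect_equal(sum(distance_series(tr)), 0)

  # straight 10-px path at 10 px/cm over 10 frames -> 1 cm total
  tr2 <- pose_track(matrix(seq(0, 10, length.out = 10) / 10, ncol = 1),
                    matrix(rep(0, 10), ncol = 1), matrix(rep(1, 10), ncol = 1),
                    px_per_cm = 10, keypoints = "tail_base")
  expect_equal(sum(distance_series(tr2)), 1, tolerance = 1e-12)
  expect_error(distance_series(tr2, "snout"), "snout")

  # synthetic walk: total equals the generator's realized path length
  sess <- gen_open_field(tiny_cohort(2)[1, ], duration_s = 600, seed = 8)
  expect_equal(sum(distance_series(sess$track)),
               sess$ground_truth$realized_total_cm, tolerance = 1e-9)
  # and missing frames contribute zero, shrinking the sum
  tr3 <- sess$track
  tr3$x_cm[100:200, 1] <- NA
  expect_lt(sum(distance_series(tr3)), sess$ground_truth$realized_total_cm)
  expect_equal(attr(distance_series(tr3), "n_missing_steps"), 102)
})

test_that("binned distances conserve the total and feed percent change", {
  sess <- gen_open_field(tiny_cohort(3)[1, ], duration_s = 1800, seed = 2)
  steps <- distance_series(sess$track)
  b <- bin_distance(steps, 30)
  expect_equal(length(b$per_bin_cm), 6)
  expect_equal(sum(b$per_bin_cm), b$total_cm, tolerance = 1e-12)
  expect_equal(b$total_cm, sum(steps), tolerance = 1e-9)

  mk <- function(v) structure(list(per_bin_cm = v, total_cm = sum(v),
                                   bin_s = 300), class = "binned_distance")
  expect_equal(habituation_percent_change(mk(c(10, 5))), c(0, -50))
  expect_equal(habituation_percent_change(mk(c(7, 7, 7))), c(0, 0, 0))
  expect_equal(habituation_percent_change(mk(c(8, 10, 4))), c(0, 25, -50))
  expect_error(habituation_percent_change(mk(c(0, 5))), "baseline")
  expect_error(habituation_percent_change(mk(10)), "2 bins")
})

test_that("centre-time fraction follows occupancy geometry", {
  ar <- arena_config()
  expect_equal(center_time_fraction(make_track(rep(19, 50), rep(19, 50)), ar),
               100)
  expect_equal(center_time_fraction(make_track(rep(0.5, 50), rep(19, 50)), ar),
               0)
  # uniform occupancy with a 50% linear centre -> ~25% (area ratio)
  set.seed(99)
  fr <- replicate(40, {
    center_time_fraction(make_track(runif(2000, 0, 38), runif(2000, 0, 38)),
                         ar)
  })
  expect_lt(abs(mean(fr) - 25), 1)
})

test_that("bout segmentation merges gaps and drops short bouts as specified", {
  fps <- 30
  ls0 <- label_stream(rep(c("rearing", "sniffing", "rearing"), c(3, 2, 3)),
                      fps)
  b0 <- segment_bouts(ls0, "rearing")
  expect_equal(nrow(b0), 2)
  expect_equal(b0$end_frame - b0$start_frame + 1, c(3L, 3L))

  b1 <- segment_bouts(ls0, "rearing", gap_tol_s = 2 / fps)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$end_frame - b1$start_frame + 1, 8L)

  expect_equal(nrow(segment_bouts(ls0, "rearing", min_bout_s = 10 / fps)), 0)

  # reconstruction: with no merging/filtering, bout frames of all labels
  # partition the stream
  set.seed(5)
  lsr <- label_stream(sample(c("locomotion_turning", "sniffing", "rearing",
                               "other"), 500, replace = TRUE), fps)
  all_b <- segment_bouts(lsr)
  expect_equal(sum(all_b$end_frame - all_b$start_frame + 1), 500)
})

test_that("behaviour fractions partition and match the chain's closed form", {
  ls0 <- label_stream(rep("rearing", 100))
  expect_equal(behaviour_fraction(ls0, "rearing"), 100)

  set.seed(6)
  lsr <- label_stream(sample(c("locomotion_turning", "sniffing", "rearing",
                               "other"), 600, replace = TRUE))
  tot <- sum(sapply(levels(lsr), function(l) behaviour_fraction(lsr, l)))
  expect_equal(tot, 100, tolerance = 1e-12)

  # long synthetic stream: fraction within 2 points of the semi-Markov
  # stationary value e_j m_j / sum(e m)
  a <- tiny_cohort(4)[1, ]
  sess <- gen_open_field(a, duration_s = 3600, seed = 21)
  expfr <- sess$ground_truth$expected_label_fraction
  for (l in names(expfr)) {
    expect_lt(abs(behaviour_fraction(sess$labels, l) - 100 * expfr[[l]]), 2)
  }
})

test_that("wall-supported rearing is relabelled before analysis", {
  ar <- arena_config()  # wall margin 2 cm
  lab <- label_stream(rep("rearing", 4))
  tr <- make_track(c(19, 0.5, 37.6, 19), c(19, 19, 19, 0.5))
  out <- rearing_away_from_wall(tr, lab, ar)
  expect_equal(as.character(out), c("rearing", "other", "other", "other"))

  # margin 0 -> identity
  ar0 <- arena_config(wall_margin_cm = 0)
  expect_equal(as.character(rearing_away_from_wall(tr, lab, ar0)),
               rep("rearing", 4))
  expect_error(rearing_away_from_wall(make_track(1, 1), lab, ar), "length")
})

test_that("habituation decay is recovered from full synthetic sessions", {
  coh <- tiny_cohort(10)
  a <- coh[coh$genotype == "wildtype", ][1, ]
  errs <- sapply(1:20, function(s) {
    sess <- gen_open_field(a, duration_s = 3600, seed = s)
    b <- bin_distance(distance_series(sess$track), 30)
    fit <- fit_habituation(b)
    abs(fit$lambda - sess$ground_truth$lambda) / sess$ground_truth$lambda
  })
  expect_lt(median(errs), 0.10)
})
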