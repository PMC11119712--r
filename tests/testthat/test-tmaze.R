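# Water T-maze scoring: times, entries, dwell, accelerations, strategy,
# eligibility, swim speed.

mz <- maze_config()
fps <- 30

# straight constant-speed path from the North start to a platform arm
direct_trial <- function(speed = 20, arm = "E", hold_s = 1.5) {
  start <- c(26, 2); junc <- c(26, 42)
  plat <- if (arm == "E") c(47, 42) else c(5, 42)
  seg <- function(from, to) {
    d <- sqrt(sum((to - from)^2))
    k <- max(1, round(d / (speed / fps)))
    t <- seq_len(k) / k
    cbind(from[1] + t * (to[1] - from[1]), from[2] + t * (to[2] - from[2]))
  }
  path <- rbind(matrix(start, 1), seg(start, junc), seg(junc, plat),
                matrix(rep(plat, each = round(hold_s * fps)), ncol = 2))
  tmaze_trial(make_track(path[, 1], path[, 2], fps, "body_centre"),
              "a1", "acquisition", platform_arm = arm)
}

test_that("time to platform caps at 30 s with the guided flag", {
  tp <- time_to_platform(direct_trial(speed = 10), mz)
  # 40 cm + 16 cm at 10 cm/s = 5.6 s
  expect_false(tp$guided)
  expect_equal(tp$time_s, 5.6, tolerance = 0.1)

  slow <- time_to_platform(direct_trial(speed = 1.5), mz)
  expect_true(slow$guided)
  expect_equal(slow$time_s, 30)

  # track that ends early without reaching the platform -> truncated error
  short <- tmaze_trial(make_track(rep(26, 60), seq(2, 30, length.out = 60),
                                  fps, "body_centre"),
                       "a1", "acquisition", platform_arm = "E")
  expect_error(time_to_platform(short, mz), "truncated")
})

test_that("time normalization divides by the weight factor", {
  ctx <- structure(list(reference_weight_g = 32),
                   class = "normalization_context")
  expect_equal(normalize_time(20, 32, ctx), 20)
  expect_equal(normalize_time(20, 40, ctx), 16)
  expect_equal(normalize_time(20, 16, ctx), 40)
  # round trip with the rotarod (multiplicative) normalization
  expect_equal(normalize_latency(normalize_time(20, 40, ctx), 40, ctx), 20)
  # order within an animal is preserved
  tt <- c(5, 9, 7)
  expect_equal(order(normalize_time(tt, 40, ctx)), order(tt))
})

test_that("arm entries count junction-to-arm transitions with hysteresis", {
  expect_equal(arm_entries(direct_trial(arm = "E"), mz), 1)
  expect_equal(arm_entries(direct_trial(arm = "W"), mz), 1)

  # wrong arm, return, correct arm -> 2
  seg <- function(from, to, k) {
    t <- seq_len(k) / k
    cbind(from[1] + t * (to[1] - from[1]), from[2] + t * (to[2] - from[2]))
  }
  path <- rbind(matrix(c(26, 2), 1), seg(c(26, 2), c(26, 42), 60),
                seg(c(26, 42), c(13, 42), 20), seg(c(13, 42), c(26, 42), 20),
                seg(c(26, 42), c(47, 42), 30),
                matrix(rep(c(47, 42), each = 45), ncol = 2))
  wrong <- tmaze_trial(make_track(path[, 1], path[, 2], fps, "body_centre"),
                       "a1", "acquisition", platform_arm = "E")
  expect_equal(arm_entries(wrong, mz), 2)

  # oscillation within the 1-cm hysteresis band does not re-count
  osc_x <- c(seq(26, 32.5, length.out = 20),
             rep(c(31.5, 32.5), 10),            # wiggle around the E boundary
             seq(32.5, 47, length.out = 20))
  osc <- tmaze_trial(make_track(osc_x, rep(42, length(osc_x)), fps,
                                "body_centre"),
                     "a1", "acquisition", platform_arm = "E")
  expect_equal(arm_entries(osc, mz), 1)
})

test_that("decision-point dwell is the junction frame fraction", {
  # 30 of 120 frames inside the junction square
  x <- c(rep(10, 45), rep(26, 30), rep(47, 45))
  y <- rep(42, 120)
  tr <- tmaze_trial(make_track(x, y, fps, "body_centre"), "a1",
                    "acquisition", platform_arm = "E")
  expect_equal(decision_point_fraction(tr, mz), 25)
  # any completed trial passes through the junction
  expect_gt(decision_point_fraction(direct_trial(), mz), 0)
})

test_that("acceleration counting: initial start plus planted stop cycles", {
  expect_equal(count_accelerations(direct_trial()), 1)

  still <- tmaze_trial(make_track(rep(26, 200) + rnorm(200, 0, 0.005),
                                  rep(20, 200) + rnorm(200, 0, 0.005),
                                  fps, "body_centre"),
                       "a1", "acquisition", platform_arm = "E")
  expect_equal(count_accelerations(still), 0)

  # planted stop/start cycles from the generator: detector matches gt
  coh <- tiny_cohort(31)
  for (s in 1:25) {
    tt <- gen_tmaze_trial(coh[(s %% 4) + 1, ], "acquisition",
                          day = (s %% 3) + 1, trial_index = 1, seed = s)
    expect_equal(count_accelerations(tt), tt$ground_truth$accelerations)
  }
})

test_that("probe strategy classification and exclusions", {
  expect_equal(classify_probe("W", "W"), "allocentric")
  expect_equal(classify_probe("E", "W"), "egocentric")
  expect_equal(classify_probe("W", "E"), "egocentric")
  expect_true(is.na(classify_probe(NA, "W")))
  expect_error(classify_probe("N", "W"), "E or W")
})

test_that("reversal eligibility needs 2 of 3 unguided single-entry trials", {
  expect_true(reversal_eligible(c(1, 1, 2), c(FALSE, FALSE, FALSE)))
  expect_true(reversal_eligible(c(1, 1, 1), c(TRUE, FALSE, FALSE)))
  expect_false(reversal_eligible(c(2, 2, 1), c(FALSE, FALSE, FALSE)))
  expect_false(reversal_eligible(c(1, 1, 1), c(TRUE, TRUE, FALSE)))
  expect_error(reversal_eligible(c(1, 1), c(FALSE, FALSE, FALSE)), "length")
})

test_that("swim speed averages trials 2 and 3 only", {
  expect_equal(swim_speed(c(10, 2, 2)), 18.5)
  expect_equal(swim_speed(c(1, 2, 4)), mean(c(37 / 2, 37 / 4)))  # trial 1 ignored
  expect_error(swim_speed(c(2, 2)), "three")
  expect_error(swim_speed(c(2, 2, NA)), "three")
})

test_that("time to platform couples positively to dwell and accelerations (sign over seeds)", {
  cors <- sapply(1:50, function(seed) {
    coh <- gen_cohort(c(mutant = 2, wildtype = 2), seed = seed)
    feats <- do.call(rbind, lapply(seq_len(nrow(coh)), function(i) {
      do.call(rbind, lapply(1:3, function(day) {
        do.call(rbind, lapply(1:3, function(tr) {
          tmaze_features(gen_tmaze_trial(coh[i, ], "acquisition", day, tr,
                                         seed = seed), mz)
        }))
      }))
    }))
    c(dwell = cor(feats$time_to_platform_s, feats$decision_point_pct),
      accel = cor(feats$time_to_platform_s, feats$accelerations))
  })
  expect_gt(median(cors["dwell", ]), 0)
  expect_gt(median(cors["accel", ]), 0)
})
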