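# Synthetic generators: determinism, planted effects, ground-truth integrity.

test_that("cohort generation is deterministic and plants the weight offset", {
  c1 <- gen_cohort(c(mutant = 5, wildtype = 5), seed = 42)
  c2 <- gen_cohort(c(mutant = 5, wildtype = 5), seed = 42)
  expect_identical(c1, c2)

  # zero offset: same seed, premanifest age -> no genotype difference applied
  eff0 <- effect_spec(weight_offset_g = 0)
  c3 <- gen_cohort(c(mutant = 5, wildtype = 5), eff0, seed = 42)
  expect_equal(c3$weight_g[c3$genotype == "mutant"] -
                 c1$weight_g[c1$genotype == "mutant"],
               rep(10.48, 5))

  # law of large numbers: empirical group difference near the planted offset
  eff <- effect_spec(weight_offset_g = 10)
  big <- gen_cohort(c(mutant = 200, wildtype = 200), eff, seed = 7)
  diff <- mean(big$weight_g[big$genotype == "mutant"]) -
    mean(big$weight_g[big$genotype == "wildtype"])
  expect_lt(abs(diff - (-10)), 0.5)

  expect_equal(nrow(gen_cohort(1, seed = 1)), 2)
  expect_error(effect_spec(weight_sd_g = 0), "positive")
  expect_error(effect_spec(nonsense = 1), "unknown")
})

test_that("open-field generator: stationarity at lambda 0, label controls, bounds", {
  coh <- tiny_cohort(5)
  a <- coh[1, ]
  eff0 <- effect_spec(of_lambda = c(wildtype = 0, mutant = 0))
  # flat decay: slope of per-bin means across 100 seeds is ~0
  prof <- sapply(1:100, function(s) gen_habituation_profile(a, eff0,
                                                            n_bins = 12,
                                                            seed = s))
  mb <- rowMeans(prof)
  slope <- unname(coef(lm(mb ~ seq_along(mb)))[2])
  expect_lt(abs(slope), 10)  # cm per bin, against a 2000-cm scale

  # rearing emission 0 -> no rearing frames
  effR <- effect_spec(of_rear_emission = matrix(0, 2, 2,
                        dimnames = list(c("wildtype", "mutant"),
                                        c("M", "F"))))
  sess <- gen_open_field(a, effR, duration_s = 600, seed = 2)
  expect_false(any(as.character(sess$labels) == "rearing"))

  # reflection keeps the walk inside the arena
  sess2 <- gen_open_field(a, duration_s = 600, seed = 3)
  expect_true(all(sess2$track$x_cm >= 0 & sess2$track$x_cm <= 38))
  expect_true(all(sess2$track$y_cm >= 0 & sess2$track$y_cm <= 38))
  expect_error(gen_open_field(a, duration_s = 500), "divisible")

  # determinism
  s1 <- gen_open_field(a, duration_s = 600, seed = 9)
  s2 <- gen_open_field(a, duration_s = 600, seed = 9)
  expect_identical(s1$track$x_cm, s2$track$x_cm)
  expect_identical(as.character(s1$labels), as.character(s2$labels))
})

test_that("rotarod generator: slip planting and skill curve", {
  coh <- tiny_cohort(6)
  a <- coh[1, ]
  # slip rate 0 -> trace never below the rod bottom
  eff0 <- effect_spec(rr_slip_rate_min = c(wildtype = 0, mutant = 0))
  tr0 <- gen_rotarod_trial(a, 2, eff0, seed = 5)
  expect_true(all(tr0$paw_y > tr0$rod_bottom_y))
  expect_equal(tr0$ground_truth$n_slips, 0)

  # planted slips recorded in the ground truth
  tr <- gen_rotarod_trial(a, 2, seed = 6)
  expect_equal(length(tr$ground_truth$slip_onsets), tr$ground_truth$n_slips)

  # latency increases in expectation with training day
  lat <- function(day) {
    mean(sapply(1:200, function(s)
      gen_rotarod_trial(a, day, seed = s)$ground_truth$latency_s))
  }
  expect_gt(lat(4), lat(1))
})

test_that("t-maze generator: planted kinematics and choices", {
  coh <- tiny_cohort(7)
  a <- coh[1, ]
  mz <- maze_config()
  # no dwell, no stops -> time equals path length / swim speed
  effK <- effect_spec(tm_dwell_mean_s = c(wildtype = 0, mutant = 0),
                      tm_stop_rate = c(wildtype = 0, mutant = 0),
                      tm_p_start = 1,
                      tm_p_end = c(wildtype = 1, mutant = 1))
  tt <- gen_tmaze_trial(a, "acquisition", 1, 1, effK, seed = 4,
                        platform_arm = "E")
  gt <- tt$ground_truth
  v <- gt$swim_speed_cms
  # start (26, 2) -> junction centre (26, 42) -> platform-zone edge (x = 42)
  path_len <- (42 - 2) + (42 - 26)
  expect_equal(gt$time_to_platform_s, path_len / v, tolerance = 0.1)
  expect_equal(gt$arm_entries, 1)
  expect_equal(gt$accelerations, 1)

  # planted stop/start cycles appear in the ground truth
  eff3 <- effect_spec(tm_stop_rate = c(wildtype = 100, mutant = 100))
  t3 <- gen_tmaze_trial(a, "acquisition", 1, 1, eff3, seed = 5)
  expect_equal(t3$ground_truth$accelerations,
               1L + t3$ground_truth$n_pauses +
                 as.integer(t3$ground_truth$dwell_s > 0))
  expect_gt(t3$ground_truth$n_pauses, 3)

  # perfect learner never errs
  entries <- sapply(1:20, function(s)
    gen_tmaze_trial(a, "acquisition", 3, 1, effK, seed = s,
                    platform_arm = "W")$ground_truth$arm_entries)
  expect_true(all(entries == 1))
})

test_that("lever-task generator: flat curves, angle range, rate ordering", {
  # ceiling = floor -> flat success curve
  coh1 <- tiny_cohort(8, 1)
  effF <- effect_spec(pp_floor = 0.3, pp_ceiling = 0.3, pp_phase3_days = 5)
  lg <- gen_pipaw_log(coh1[1, ], effF, seed = 2)
  gt <- attr(lg, "ground_truth")[[1]]
  expect_true(all(abs(gt$p_day - 0.3) < 1e-12))

  # angles within the physical lever range
  lg2 <- gen_pipaw_log(coh1, effect_spec(pp_phase3_days = 3), seed = 3)
  ang <- lg2$angle_deg[lg2$kind == "lever_pull"]
  expect_true(all(ang >= 0 & ang <= 25))

  # fitted logistic rate lower for mutants on a 20-mouse cohort
  coh20 <- gen_cohort(c(mutant = 10, wildtype = 10), seed = 11)
  lg3 <- gen_pipaw_log(coh20, seed = 11)
  ref <- refine_log(lg3)
  daily <- do.call(rbind, lapply(unique(ref$clean$rfid), function(id) {
    dp <- daily_performance(run_phase_machine(
      ref$clean[ref$clean$rfid == id, ]))
    dp$genotype <- as.character(coh20$genotype[coh20$animal_id == id])
    dp
  }))
  curve <- aggregate(cbind(n_success, n_trials) ~ genotype + day, daily, sum)
  curve$success_rate <- 100 * curve$n_success / curve$n_trials
  fit_mut <- fit_success_curve(curve$day[curve$genotype == "mutant"],
                               curve$success_rate[curve$genotype == "mutant"])
  fit_wt <- fit_success_curve(curve$day[curve$genotype == "wildtype"],
                              curve$success_rate[curve$genotype == "wildtype"])
  expect_lt(fit_mut[["rate"]], fit_wt[["rate"]])
  # and the planted rates are recovered reasonably (within 15%)
  expect_lt(abs(fit_wt[["rate"]] - 0.45) / 0.45, 0.15)
  expect_lt(abs(fit_mut[["rate"]] - 0.22) / 0.22, 0.15)
})

test_that("child seeds are order-independent and stable", {
  expect_identical(child_seed(1, "a", "task", 3), child_seed(1, "a", "task", 3))
  expect_false(child_seed(1, "a") == child_seed(1, "b"))
  expect_false(child_seed(1, "a") == child_seed(2, "a"))
  # generating animal B first does not change animal A's data
  coh <- tiny_cohort(12)
  sA <- gen_open_field(coh[1, ], duration_s = 300, seed = 5)
  invisible(gen_open_field(coh[2, ], duration_s = 300, seed = 5))
  sA2 <- gen_open_field(coh[1, ], duration_s = 300, seed = 5)
  expect_identical(sA$track$x_cm, sA2$track$x_cm)
})
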