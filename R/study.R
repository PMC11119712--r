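# End-to-end seeded study: synthesise a cohort, run all four task pipelines
# and the statistics layer, optionally writing tidy CSV outputs.

#' Run a complete seeded synthetic study
#'
#' Generates a cohort (one sex x age cohort, mutant and wild-type
#' littermates), then runs the four behavioural pipelines end to end:
#'
#' * open field: one-hour session per animal; binned distance, habituation
#'   percent change, centre time, wall-corrected rearing, bout statistics;
#'   repeated-measures ANOVA of genotype x time-bin on the percent change.
#' * accelerating rotarod: 4 days x 3 trials per animal (Standard
#'   protocol); slip detection and slip rates (trials under 20 s excluded);
#'   weight-normalized latency; day-1 weight-latency correlation per
#'   genotype; genotype x day ANOVA on normalized latency.
#' * water T-maze: 3-day acquisition, probe trial, reversal for eligible
#'   animals, swim tests; weight-normalized time to platform, arm entries,
#'   decision-point dwell, accelerations; genotype x day ANOVA;
#'   feature-time correlations with a Fisher z contrast between genotypes.
#' * lever task: event log for a subset of animals per genotype; refinement,
#'   phase state machine, daily success rates and a logistic learning-curve
#'   fit per genotype.
#'
#' All randomness derives from `seed` through per-animal/per-trial child
#' seeds, so a fixed seed reproduces every output byte for byte.
#'
#' @param seed master seed.
#' @param n_mutant,n_wildtype cohort sizes (defaults 12 and 15, a manifest
#'   male cohort).
#' @param sex,age_group cohort descriptors.
#' @param effect an [effect_spec()].
#' @param of_duration_s open-field session length (default 3600 s).
#' @param n_pipaw number of animals per genotype entering the lever task
#'   (default 8).
#' @param out_dir optional directory; when given, tidy CSVs of every result
#'   table are written there.
#' @return a list of result tables and statistics (see Details).
#' @export
run_study <- function(seed = 1, n_mutant = 12, n_wildtype = 15, sex = "M",
                      age_group = "manifest", effect = effect_spec(),
                      of_duration_s = 3600, n_pipaw = 8, out_dir = NULL) {
  coh <- gen_cohort(c(mutant = n_mutant, wildtype = n_wildtype), effect,
                    seed = seed, sex = sex, age_group = age_group)
  ctx <- normalization_context(coh)
  arena <- arena_config()
  maze <- maze_config()
  fps <- effect$frame_rate_hz

  ## ---- open field ----------------------------------------------------------
  of_bins <- list(); of_sum <- list()
  for (i in seq_len(nrow(coh))) {
    a <- coh[i, ]
    sess <- gen_open_field(a, effect, duration_s = of_duration_s, seed = seed,
                           arena = arena)
    s <- summarise_open_field(sess$track, sess$labels, arena)
    nb <- length(s$binned$per_bin_cm)
    of_bins[[i]] <- data.frame(animal_id = a$animal_id,
                               genotype = as.character(a$genotype),
                               bin = seq_len(nb),
                               distance_cm = s$binned$per_bin_cm,
                               percent_change = s$percent_change,
                               rearing_pct = s$rearing_pct_bins)
    of_sum[[i]] <- data.frame(animal_id = a$animal_id,
                              genotype = as.character(a$genotype),
                              total_cm = s$total_cm,
                              center_pct = s$center_pct,
                              rearing_pct = s$rearing_pct,
                              rearing_bout_mean_s = s$rearing_bout_mean_s)
  }
  of_bins <- do.call(rbind, of_bins)
  of_sum <- do.call(rbind, of_sum)
  of_anova <- two_way_anova(of_bins, "percent_change", "genotype",
                            within = "bin", subject = "animal_id")
  of_rear_t <- t_test(of_sum$rearing_bout_mean_s[of_sum$genotype == "mutant"],
                      of_sum$rearing_bout_mean_s[of_sum$genotype == "wildtype"])

  ## ---- rotarod -------------------------------------------------------------
  rr <- list()
  for (i in seq_len(nrow(coh))) {
    a <- coh[i, ]
    for (day in 1:4) for (tr in 1:3) {
      trial <- gen_rotarod_trial(a, day, effect, seed = seed,
                                 trial_index = tr)
      lat <- trial_endpoint(trial, "standard")
      slips <- detect_slips(trial)
      sr <- slip_rate(trial, slips, latency_s = lat)
      rr[[length(rr) + 1L]] <- data.frame(
        animal_id = a$animal_id, genotype = as.character(a$genotype),
        weight_g = a$weight_g, day = day, trial_index = tr,
        latency_s = lat,
        latency_norm_s = if (age_group == "manifest")
          normalize_latency(lat, a$weight_g, ctx) else lat,
        n_slips = sr$n_slips, slip_rate_min = sr$rate_per_min,
        slip_excluded = sr$excluded)
    }
  }
  rr <- do.call(rbind, rr)
  rr_day <- stats::aggregate(
    cbind(latency_s, latency_norm_s) ~ animal_id + genotype + weight_g + day,
    data = rr, FUN = mean)
  rr_day <- rr_day[order(rr_day$animal_id, rr_day$day), ]
  rownames(rr_day) <- NULL
  d1 <- rr_day[rr_day$day == 1, ]
  rr_cor <- lapply(c("wildtype", "mutant"), function(g) {
    pr <- pearson_r(d1$weight_g[d1$genotype == g],
                    d1$latency_s[d1$genotype == g])
    data.frame(genotype = g, r = pr$r, n = pr$n, p = pr$p)
  })
  rr_cor <- do.call(rbind, rr_cor)
  rr_anova <- two_way_anova(rr_day, "latency_norm_s", "genotype",
                            within = "day", subject = "animal_id")

  ## ---- water T-maze --------------------------------------------------------
  feats <- list(); probe <- list(); swim <- list()
  arm_of <- function(a) with_seed(child_seed(seed, a$animal_id, "tmaze_arm"),
                                  sample(c("E", "W"), 1))
  for (i in seq_len(nrow(coh))) {
    a <- coh[i, ]
    arm <- arm_of(a)
    for (day in 1:3) for (tr in 1:3) {
      trial <- gen_tmaze_trial(a, "acquisition", day, tr, effect, seed,
                               maze, platform_arm = arm)
      f <- tmaze_features(trial, maze)
      f$weight_g <- a$weight_g
      f$genotype <- as.character(a$genotype)
      feats[[length(feats) + 1L]] <- f
    }
    pt <- gen_tmaze_trial(a, "probe", 3, 1, effect, seed, maze,
                          trained_arm = arm)
    probe[[length(probe) + 1L]] <- data.frame(
      animal_id = a$animal_id, genotype = as.character(a$genotype),
      trained_arm = arm, entered_arm = pt$entered_arm,
      strategy = classify_probe(pt$entered_arm, arm))
    times <- vapply(1:3, function(tr) {
      st <- gen_tmaze_trial(a, "swim_test", 1, tr, effect, seed, maze)
      pos <- cbind(st$track$x_cm[, 1], st$track$y_cm[, 1])
      (which(in_rect(pos[, 1], pos[, 2], maze$roi$decision_point))[1] - 1) /
        fps
    }, numeric(1))
    swim[[length(swim) + 1L]] <- data.frame(
      animal_id = a$animal_id, genotype = as.character(a$genotype),
      swim_speed_cms = swim_speed(times, maze$ns_arm_cm))
  }
  feats <- do.call(rbind, feats)
  probe <- do.call(rbind, probe)
  swim <- do.call(rbind, swim)
  feats$time_norm_s <- if (age_group == "manifest")
    normalize_time(feats$time_to_platform_s, feats$weight_g, ctx)
  else feats$time_to_platform_s

  d3 <- feats[feats$day == 3, ]
  elig <- unique(d3[, c("animal_id", "genotype")])
  rownames(elig) <- NULL
  elig$eligible <- vapply(elig$animal_id, function(id) {
    z <- d3[d3$animal_id == id, ]
    reversal_eligible(z$arm_entries, z$guided)
  }, logical(1))

  rev_feats <- list()
  for (i in seq_len(nrow(coh))) {
    a <- coh[i, ]
    if (!elig$eligible[elig$animal_id == a$animal_id]) next
    arm <- arm_of(a)
    rev_arm <- if (arm == "E") "W" else "E"
    for (day in 1:3) for (tr in 1:3) {
      trial <- gen_tmaze_trial(a, "reversal", day, tr, effect, seed, maze,
                               platform_arm = rev_arm)
      f <- tmaze_features(trial, maze)
      f$weight_g <- a$weight_g
      f$genotype <- as.character(a$genotype)
      rev_feats[[length(rev_feats) + 1L]] <- f
    }
  }
  rev_feats <- if (length(rev_feats)) do.call(rbind, rev_feats) else NULL
  if (!is.null(rev_feats)) {
    rev_feats$time_norm_s <- if (age_group == "manifest")
      normalize_time(rev_feats$time_to_platform_s, rev_feats$weight_g, ctx)
    else rev_feats$time_to_platform_s
  }

  tm_day <- stats::aggregate(time_norm_s ~ animal_id + genotype + day,
                             data = feats, FUN = mean)
  tm_day <- tm_day[order(tm_day$animal_id, tm_day$day), ]
  rownames(tm_day) <- NULL
  tm_anova <- two_way_anova(tm_day, "time_norm_s", "genotype",
                            within = "day", subject = "animal_id")
  tm_cor <- lapply(c("wildtype", "mutant"), function(g) {
    z <- feats[feats$genotype == g, ]
    dwell <- pearson_r(z$decision_point_pct, z$time_norm_s)
    acc <- pearson_r(z$accelerations, z$time_norm_s)
    data.frame(genotype = g, r_dwell = dwell$r, p_dwell = dwell$p,
               r_accel = acc$r, p_accel = acc$p, n = dwell$n)
  })
  tm_cor <- do.call(rbind, tm_cor)
  tm_fisher <- fisher_z_compare(tm_cor$r_accel[tm_cor$genotype == "mutant"],
                                tm_cor$n[tm_cor$genotype == "mutant"],
                                tm_cor$r_accel[tm_cor$genotype == "wildtype"],
                                tm_cor$n[tm_cor$genotype == "wildtype"])

  ## ---- lever task ----------------------------------------------------------
  pick <- function(g) utils::head(coh$animal_id[coh$genotype == g], n_pipaw)
  pp_coh <- coh[coh$animal_id %in% c(pick("mutant"), pick("wildtype")), ]
  log_raw <- gen_pipaw_log(pp_coh, effect, seed = seed)
  ref <- refine_log(log_raw)
  pp_daily <- list(); pp_trans <- list()
  for (id in unique(ref$clean$rfid)) {
    ann <- run_phase_machine(ref$clean[ref$clean$rfid == id, ])
    dp <- daily_performance(ann)
    dp$rfid <- id
    dp$genotype <- as.character(coh$genotype[coh$animal_id == id])
    pp_daily[[id]] <- dp
    tr <- attr(ann, "transitions")
    tr$rfid <- id
    pp_trans[[id]] <- tr
  }
  pp_daily <- do.call(rbind, pp_daily)
  rownames(pp_daily) <- NULL
  pp_trans <- do.call(rbind, pp_trans)
  rownames(pp_trans) <- NULL
  # pooled counts per genotype-day: lower-variance curve than mean-of-mice
  pp_curve <- stats::aggregate(cbind(n_success, n_trials) ~ genotype + day,
                               data = pp_daily, FUN = sum)
  pp_curve$success_rate <- 100 * pp_curve$n_success / pp_curve$n_trials
  pp_fit <- lapply(c("wildtype", "mutant"), function(g) {
    z <- pp_curve[pp_curve$genotype == g, ]
    cf <- fit_success_curve(z$day, z$success_rate)
    data.frame(genotype = g, t(cf))
  })
  pp_fit <- do.call(rbind, pp_fit)

  res <- list(
    cohort = coh,
    open_field = list(bins = of_bins, summary = of_sum, anova = of_anova,
                      rearing_bout_t = of_rear_t),
    rotarod = list(trials = rr, day_means = rr_day, day1_weight_cor = rr_cor,
                   anova = rr_anova),
    tmaze = list(acquisition = feats, reversal = rev_feats, probe = probe,
                 swim = swim, eligibility = elig, anova = tm_anova,
                 correlations = tm_cor, fisher_z = tm_fisher),
    pipaw = list(daily = pp_daily, transitions = pp_trans,
                 curve = pp_curve, fit = pp_fit,
                 rejects = ref$rejects)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      df <- as.data.frame(df)
      for (cn in names(df)) {
        if (inherits(df[[cn]], "POSIXct")) {
          df[[cn]] <- strftime(df[[cn]], "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
        }
      }
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    wr(coh, "cohort.csv")
    wr(of_bins, "open_field_bins.csv")
    wr(of_sum, "open_field_summary.csv")
    wr(rr, "rotarod_trials.csv")
    wr(rr_day, "rotarod_day_means.csv")
    wr(rr_cor, "rotarod_day1_weight_cor.csv")
    wr(feats, "tmaze_acquisition.csv")
    if (!is.null(rev_feats)) wr(rev_feats, "tmaze_reversal.csv")
    wr(probe, "tmaze_probe.csv")
    wr(swim, "tmaze_swim.csv")
    wr(elig, "tmaze_eligibility.csv")
    wr(pp_daily, "pipaw_daily.csv")
    wr(pp_trans, "pipaw_transitions.csv")
    wr(pp_fit, "pipaw_fit.csv")
    wr(rbind(cbind(task = "open_field", of_anova),
             cbind(task = "rotarod", rr_anova),
             cbind(task = "tmaze", tm_anova)), "stats_results.csv")
  }
  res
}
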