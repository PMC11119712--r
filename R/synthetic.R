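# Seeded synthetic cohorts and per-task inputs with planted ground truth.
#
# Every generator draws from a child seed derived by stable hashing of
# (master seed, animal id, task, trial), so the data generated for one
# animal/trial do not depend on what else was generated. Each generator
# returns the planted structure ("ground_truth") needed to score the
# corresponding detector exactly.

#' Effect specification for the synthetic cohort generators
#'
#' Collects every tunable of the synthetic study in one validated list. The
#' defaults emulate the structure of a manifest (9-12 month) knock-in cohort:
#' mutants are lighter than wild-type littermates, habituate less in the open
#' field, rear longer (males), show slightly more paw slips and a weight-
#' mediated advantage on the rotarod, dwell longer at the T-maze decision
#' point, and learn the lever-pull goal band more slowly.
#'
#' Weight acts on generated rotarod latency and T-maze time only through an
#' explicit multiplicative coupling (`latency ~ (reference_weight/weight)^b`,
#' `time ~ (weight/reference_weight)^b`), so the weight-normalization
#' procedures can be validated against a known mechanism.
#'
#' @param ... overrides of the defaults listed below; unknown names are an
#'   error.
#' @return an object of class `effect_spec`.
#' @section Parameters:
#' Cohort: `wildtype_weight_g` (42), `weight_offset_g` (10.48; the mutant
#' deficit, applied at manifest age only), `weight_sd_g` (4).
#' Open field: `of_first_bin_cm` (2000), `of_lambda` (per-bin exponential
#' habituation decay per genotype; wildtype 0.08, mutant 0.03),
#' `of_bin_noise_sd` (0.1, log scale), `of_turn_sd` (0.3 rad/frame),
#' `of_emission` (bout-start probabilities for locomotion/turning, sniffing,
#' other), `of_rear_emission` (genotype x sex matrix of rearing bout-start
#' probability), `of_bout_mean_s`, `of_rear_bout_mean_s`.
#' Rotarod: `rr_base_latency_s` (80), `rr_skill_gain_s` (25 per day),
#' `rr_genotype_factor` (wildtype 1, mutant 0.85), `rr_weight_exponent` (1),
#' `rr_latency_noise_sd` (0.12, log), `rr_slip_rate_min` (slips/min;
#' wildtype 7.5, mutant 8.1), `rr_slip_depth_cm` (0.5), `rr_slip_width_s`
#' (0.3), `rr_rotation_prob` (0.3).
#' T-maze: `tm_swim_speed_cms` (19.5), `tm_weight_exponent` (1),
#' `tm_p_start` (0.5), `tm_p_end` (wildtype 0.95, mutant 0.80),
#' `tm_dwell_mean_s` (wildtype 1.2, mutant 2.0), `tm_stop_rate`
#' (mean planted stop/start cycles; wildtype 2, mutant 2.5),
#' `tm_pause_s_range` (0.6-1.2), `tm_p_egocentric` (0.65), `tm_noise_cm` (0).
#' Lever task: `pp_floor` (0.10), `pp_ceiling` (0.40), `pp_rate` (logistic
#' slope per day; wildtype 0.45, mutant 0.22), `pp_midpoint_day` (6),
#' `pp_trials_per_day` (200-400), `pp_poke_gap_s` (180), `pp_pull_gap_s`
#' (240), `pp_phase2_angle_mean`/`sd` (10, 4), `pp_reward_window_min` (15),
#' `pp_phase3_days` (16), `pp_max_days` (60).
#' Acquisition: `frame_rate_hz` (30), `px_per_cm` (10).
#' @examples
#' eff <- effect_spec(of_lambda = c(wildtype = 0, mutant = 0))
#' @export
effect_spec <- function(...) {
  defaults <- list(
    frame_rate_hz = 30,
    px_per_cm = 10,
    # cohort
    wildtype_weight_g = 42,
    weight_offset_g = 10.48,
    weight_sd_g = 4,
    # open field
    of_first_bin_cm = 2000,
    of_lambda = c(wildtype = 0.08, mutant = 0.03),
    of_bin_noise_sd = 0.1,
    of_turn_sd = 0.3,
    of_emission = c(locomotion_turning = 0.35, sniffing = 0.30, other = 0.30),
    of_rear_emission = matrix(c(0.05, 0.05, 0.09, 0.05), nrow = 2, byrow = TRUE,
                              dimnames = list(c("wildtype", "mutant"),
                                              c("M", "F"))),
    of_bout_mean_s = c(locomotion_turning = 4, sniffing = 3, other = 2),
    of_rear_bout_mean_s = c(wildtype = 1.8, mutant = 2.8),
    of_confidence_range = c(0.85, 1),
    # rotarod
    rr_base_latency_s = 80,
    rr_skill_gain_s = 25,
    rr_genotype_factor = c(wildtype = 1, mutant = 0.85),
    rr_weight_exponent = 1,
    rr_latency_noise_sd = 0.12,
    rr_slip_rate_min = c(wildtype = 7.5, mutant = 8.1),
    rr_slip_depth_cm = 0.5,
    rr_slip_width_s = 0.3,
    rr_rotation_prob = 0.3,
    # T-maze
    tm_swim_speed_cms = 19.5,
    tm_weight_exponent = 1,
    tm_p_start = 0.5,
    tm_p_end = c(wildtype = 0.95, mutant = 0.80),
    tm_dwell_mean_s = c(wildtype = 1.2, mutant = 2.0),
    tm_stop_rate = c(wildtype = 2, mutant = 2.5),
    tm_pause_s_range = c(0.6, 1.2),
    tm_p_egocentric = 0.65,
    tm_noise_cm = 0,
    # lever task
    pp_floor = 0.10,
    pp_ceiling = 0.40,
    pp_rate = c(wildtype = 0.45, mutant = 0.22),
    pp_midpoint_day = 6,
    pp_trials_per_day = c(200, 400),
    pp_poke_gap_s = 180,
    pp_pull_gap_s = 240,
    pp_phase2_angle_mean = 10,
    pp_phase2_angle_sd = 4,
    pp_reward_window_min = 15,
    pp_phase3_days = 16,
    pp_max_days = 60
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown effect_spec parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  spec <- utils::modifyList(defaults, override)
  # validation: probabilities in [0,1], rates/scales >= 0
  probs <- c(spec$of_emission, as.numeric(spec$of_rear_emission),
             spec$tm_p_start, spec$tm_p_end, spec$tm_p_egocentric,
             spec$pp_floor, spec$pp_ceiling, spec$rr_rotation_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("effect_spec probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (spec$weight_sd_g <= 0) stop("weight_sd_g must be positive", call. = FALSE)
  if (any(spec$of_lambda < 0) || any(spec$rr_slip_rate_min < 0) ||
      any(spec$tm_stop_rate < 0) || any(spec$pp_rate < 0)) {
    stop("effect_spec rates must be non-negative", call. = FALSE)
  }
  structure(spec, class = "effect_spec")
}

# Reference weight of the generating mechanism: the expected mutant-group
# mean, which is also what normalization_context() estimates from a cohort.
.ref_weight <- function(effect, age_group) {
  off <- if (identical(as.character(age_group), "manifest"))
    effect$weight_offset_g else 0
  effect$wildtype_weight_g - off
}

#' Generate a synthetic cohort
#'
#' Draws animal weights per genotype from normal distributions with the
#' mutant mean offset below the wild-type mean (`weight_offset_g`; applied at
#' manifest age only, matching the absence of a weight phenotype in young
#' animals).
#'
#' @param n_per_group number of animals per genotype: a single count or a
#'   named vector `c(mutant = , wildtype = )`.
#' @param effect an [effect_spec()].
#' @param seed master seed.
#' @param sex,age_group,strain cohort descriptors applied to every animal.
#' @return a [cohort()] data frame.
#' @examples
#' gen_cohort(c(mutant = 12, wildtype = 15), seed = 1)
#' @export
gen_cohort <- function(n_per_group, effect = effect_spec(), seed = 1,
                       sex = "M", age_group = "manifest", strain = "B6") {
  if (length(n_per_group) == 1L && is.null(names(n_per_group))) {
    n_per_group <- c(mutant = n_per_group, wildtype = n_per_group)
  }
  if (!all(c("mutant", "wildtype") %in% names(n_per_group)) ||
      any(n_per_group < 1)) {
    stop("n_per_group must be a count >= 1 or c(mutant=, wildtype=)",
         call. = FALSE)
  }
  offset <- effect$wildtype_weight_g - .ref_weight(effect, age_group)
  with_seed(child_seed(seed, "cohort", sex, age_group), {
    w_wt <- stats::rnorm(n_per_group[["wildtype"]], effect$wildtype_weight_g,
                         effect$weight_sd_g)
    w_mut <- stats::rnorm(n_per_group[["mutant"]],
                          effect$wildtype_weight_g - offset,
                          effect$weight_sd_g)
  })
  df <- data.frame(
    animal_id = c(sprintf("mut%s%02d", sex, seq_len(n_per_group[["mutant"]])),
                  sprintf("wt%s%02d", sex, seq_len(n_per_group[["wildtype"]]))),
    genotype = rep(c("mutant", "wildtype"), n_per_group[c("mutant", "wildtype")]),
    sex = sex, age_group = age_group, strain = strain,
    weight_g = pmax(c(w_mut, w_wt), 12),
    stringsAsFactors = FALSE
  )
  cohort(df)
}

#' Per-bin habituation profile for one animal
#'
#' Expected distance in bin i is `d1 * exp(-lambda * (i - 1))` with the
#' genotype's decay rate `lambda`, multiplied by lognormal session noise.
#' This is the planted structure the habituation analysis must recover.
#'
#' @param animal one row of a [cohort()].
#' @param effect an [effect_spec()].
#' @param n_bins number of 5-min bins (12 for a one-hour session).
#' @param seed master seed.
#' @return numeric vector of per-bin distances (cm) with attribute `lambda`.
#' @export
gen_habituation_profile <- function(animal, effect = effect_spec(),
                                    n_bins = 12, seed = 1) {
  lambda <- effect$of_lambda[[as.character(animal$genotype)]]
  with_seed(child_seed(seed, animal$animal_id, "of_profile"), {
    d <- effect$of_first_bin_cm * exp(-lambda * (seq_len(n_bins) - 1)) *
      exp(stats::rnorm(n_bins, 0, effect$of_bin_noise_sd))
  })
  attr(d, "lambda") <- lambda
  d
}

# label emission probabilities and mean bout durations for one animal
.label_params <- function(animal, effect) {
  e_rear <- effect$of_rear_emission[as.character(animal$genotype),
                                    as.character(animal$sex)]
  base <- effect$of_emission / sum(effect$of_emission)
  e <- c(base * (1 - e_rear), rearing = as.numeric(e_rear))
  m <- c(effect$of_bout_mean_s,
         rearing = effect$of_rear_bout_mean_s[[as.character(animal$genotype)]])
  e <- e[.behaviour_levels]; m <- m[.behaviour_levels]
  names(e) <- names(m) <- .behaviour_levels
  list(emission = e, bout_mean_s = m,
       expected_fraction = if (sum(e * m) > 0) e * m / sum(e * m) else e)
}

#' Generate a synthetic open-field session
#'
#' Produces a bounded correlated random walk of the tail-base keypoint inside
#' the square arena whose per-bin path length follows the animal's
#' habituation profile, plus a per-frame behaviour label stream emitted by a
#' semi-Markov chain (independent bout draws with geometric durations), whose
#' long-run time fractions have the closed form
#' `e_j * m_j / sum(e * m)` recorded in the ground truth.
#'
#' @param animal one row of a [cohort()].
#' @param effect an [effect_spec()].
#' @param duration_s session length; must be divisible by `bin_s`.
#' @param seed master seed.
#' @param bin_s bin length in seconds (default 300).
#' @param arena an [arena_config()].
#' @return list with `track` ([pose_track()]), `labels` ([label_stream()])
#'   and `ground_truth` (planted lambda, per-bin target and realized
#'   distances, expected label fractions).
#' @export
gen_open_field <- function(animal, effect = effect_spec(), duration_s = 3600,
                           seed = 1, bin_s = 300, arena = arena_config()) {
  if (duration_s %% bin_s != 0) {
    stop("duration_s must be divisible by bin_s", call. = FALSE)
  }
  fps <- effect$frame_rate_hz
  n_bins <- duration_s %/% bin_s
  nf <- round(bin_s * fps)
  n <- n_bins * nf
  d_bins <- gen_habituation_profile(animal, effect, n_bins, seed)
  L <- arena$arena_side_cm
  with_seed(child_seed(seed, animal$animal_id, "of_traj"), {
    step <- rep(d_bins / nf, each = nf)
    theta <- cumsum(stats::rnorm(n, 0, effect$of_turn_sd))
    x <- reflect_fold(L / 2 + cumsum(step * cos(theta)), L)
    y <- reflect_fold(L / 2 + cumsum(step * sin(theta)), L)
    conf <- stats::runif(n, effect$of_confidence_range[1],
                         effect$of_confidence_range[2])
  })
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  bin_of_step <- rep(seq_len(n_bins), each = nf)[-1]
  realized <- as.numeric(tapply(steps, bin_of_step, sum))
  labels <- .gen_label_stream(animal, effect, n, seed)
  lp <- .label_params(animal, effect)
  track <- pose_track(matrix(x, ncol = 1), matrix(y, ncol = 1),
                      matrix(conf, ncol = 1), frame_rate_hz = fps,
                      px_per_cm = effect$px_per_cm, keypoints = "tail_base")
  list(track = track, labels = labels,
       ground_truth = list(lambda = attr(d_bins, "lambda"),
                           bin_target_cm = as.numeric(d_bins),
                           realized_bin_cm = realized,
                           realized_total_cm = sum(steps),
                           expected_label_fraction = lp$expected_fraction))
}

.gen_label_stream <- function(animal, effect, n, seed) {
  lp <- .label_params(animal, effect)
  fps <- effect$frame_rate_hz
  e <- lp$emission
  active <- e > 0
  if (!any(active)) stop("all label emission probabilities are zero",
                         call. = FALSE)
  mean_frames <- pmax(lp$bout_mean_s * fps, 1)
  with_seed(child_seed(seed, animal$animal_id, "of_labels"), {
    states <- integer(0); durs <- integer(0); total <- 0
    while (total < n) {
      k <- max(64L, ceiling((n - total) / min(mean_frames[active])))
      s <- sample(which(active), k, replace = TRUE, prob = e[active])
      d <- stats::rgeom(k, 1 / mean_frames[s]) + 1L
      states <- c(states, s); durs <- c(durs, d); total <- total + sum(d)
    }
  })
  lab <- rep(.behaviour_levels[states], durs)[seq_len(n)]
  label_stream(lab, fps)
}

#' Generate a synthetic accelerating-rotarod trial
#'
#' Latency follows a day-increasing skill curve scaled by a genotype factor
#' and the multiplicative weight coupling, truncated to the 5-300 s trial
#' window. Paw-slip events are planted at a Poisson rate as sub-rod
#' excursions of the configured depth/width in the hind-paw height traces;
#' the planted count is the ground truth for the slip detector.
#'
#' @param animal one row of a [cohort()].
#' @param day training day (1-4).
#' @param effect an [effect_spec()].
#' @param seed master seed.
#' @param trial_index trial within the day (1-3).
#' @return a [rotarod_trial()] whose `ground_truth` records the planted slip
#'   count/onsets and the drawn latency.
#' @export
gen_rotarod_trial <- function(animal, day, effect = effect_spec(), seed = 1,
                              trial_index = 1) {
  if (day < 1) stop("day must be >= 1", call. = FALSE)
  fps <- effect$frame_rate_hz
  geno <- as.character(animal$genotype)
  ref_w <- .ref_weight(effect, animal$age_group)
  with_seed(child_seed(seed, animal$animal_id, "rotarod", day, trial_index), {
    base <- effect$rr_base_latency_s + effect$rr_skill_gain_s * (day - 1)
    latency <- base * effect$rr_genotype_factor[[geno]] *
      (ref_w / animal$weight_g)^effect$rr_weight_exponent *
      exp(stats::rnorm(1, 0, effect$rr_latency_noise_sd))
    latency <- min(max(latency, 5), 300)
    nf <- round(latency * fps)
    paw_y <- matrix(1 + stats::rnorm(2 * nf, 0, 0.05), ncol = 2)
    width_f <- max(2L, round(effect$rr_slip_width_s * fps))
    gap_f <- round(0.6 * fps)
    slots <- seq(fps + 1L, nf - width_f - fps, by = width_f + gap_f)
    k <- stats::rpois(1, effect$rr_slip_rate_min[[geno]] * latency / 60)
    k <- min(k, length(slots))
    onsets <- if (k > 0) sort(sample(slots, k)) else integer(0)
    for (s in onsets) {
      idx <- s:(s + width_f - 1L)
      paw <- sample(2L, 1L)
      paw_y[idx, paw] <- pmin(-effect$rr_slip_depth_cm +
                                stats::rnorm(width_f, 0, 0.05), -0.15)
    }
    terminal <- if (stats::runif(1) < effect$rr_rotation_prob) "rotation"
                else "fall"
  })
  rotarod_trial(
    animal_id = animal$animal_id, day = day, trial_index = trial_index,
    events = data.frame(time_s = latency, kind = terminal,
                        stringsAsFactors = FALSE),
    paw_y = paw_y, rod_bottom_y = 0, frame_rate_hz = fps,
    ground_truth = list(n_slips = k, slip_onsets = onsets,
                        latency_s = latency)
  )
}

# --- T-maze path construction -----------------------------------------------

# linear segment from `from` to `to` at `speed` cm/s, excluding `from`
.tm_seg <- function(from, to, speed, fps) {
  d <- sqrt(sum((to - from)^2))
  k <- max(1L, round(d / (speed / fps)))
  t <- seq_len(k) / k
  cbind(from[1] + t * (to[1] - from[1]), from[2] + t * (to[2] - from[2]))
}

# hold position for dur_s with tiny positional jitter (sub-threshold speed)
.tm_hold <- function(at, dur_s, fps) {
  k <- max(1L, round(dur_s * fps))
  cbind(at[1] + stats::rnorm(k, 0, 0.01), at[2] + stats::rnorm(k, 0, 0.01))
}

#' Generate a synthetic water T-maze trial
#'
#' Builds a waypoint path through the maze ROIs: start arm (North for
#' acquisition/reversal, South for probe and swim tests), planted stop/start
#' pauses along the approach, a dwell at the decision point, optional
#' wrong-arm excursions governed by the correct-choice learning curve, and
#' finally the platform zone where the animal remains. Swim speed carries the
#' multiplicative weight coupling (`speed ~ (reference_weight/weight)^b`), so
#' heavier animals are slower and time to platform is removed by the divisive
#' weight normalization. Ground truth records the platform-entry frame, arm
#' entries, decision-point frames and the planted acceleration count.
#'
#' @param animal one row of a [cohort()].
#' @param phase `"acquisition"`, `"reversal"`, `"probe"` or `"swim_test"`.
#' @param day,trial_index position in the protocol (3 trials/day, 3 days per
#'   phase); they set the correct-choice probability along the learning
#'   curve.
#' @param effect an [effect_spec()].
#' @param seed master seed.
#' @param maze a [maze_config()].
#' @param platform_arm `"E"` or `"W"` (ignored for probe/swim trials).
#' @param trained_arm arm trained during acquisition (probe trials).
#' @return a [tmaze_trial()] with a `ground_truth` list.
#' @export
gen_tmaze_trial <- function(animal, phase = "acquisition", day = 1,
                            trial_index = 1, effect = effect_spec(), seed = 1,
                            maze = maze_config(), platform_arm = "E",
                            trained_arm = platform_arm) {
  phase <- match.arg(phase, c("acquisition", "reversal", "probe", "swim_test"))
  fps <- effect$frame_rate_hz
  geno <- as.character(animal$genotype)
  ref_w <- .ref_weight(effect, animal$age_group)
  v <- effect$tm_swim_speed_cms *
    (ref_w / animal$weight_g)^effect$tm_weight_exponent
  w <- maze$arm_width_cm
  xj <- maze$ew_arm_cm + w / 2            # junction centreline x
  yj <- maze$ns_arm_cm + w / 2            # junction centreline y
  north_start <- c(xj, 2)
  south_start <- c(xj, 2 * maze$ns_arm_cm + w - 2)
  junction <- c(xj, yj)
  arm_point <- function(arm, depth) {
    if (arm == "E") c(maze$ew_arm_cm + w + depth, yj)
    else c(maze$ew_arm_cm - depth, yj)
  }
  other_arm <- function(arm) if (arm == "E") "W" else "E"

  seed_i <- child_seed(seed, animal$animal_id, "tmaze", phase, day, trial_index)
  res <- with_seed(seed_i, {
    if (phase == "swim_test") {
      segs <- list(.tm_seg(south_start, junction, v, fps),
                   .tm_hold(junction, 0.5, fps))
      path <- do.call(rbind, c(list(matrix(south_start, 1)), segs))
      list(path = path, entered = NA_character_, n_wrong = 0L,
           n_pause = 0L, dwell_s = 0)
    } else if (phase == "probe") {
      ego <- stats::runif(1) < effect$tm_p_egocentric
      entered <- if (ego) other_arm(trained_arm) else trained_arm
      dwell_mean <- effect$tm_dwell_mean_s[[geno]]
      dwell_s <- if (dwell_mean > 0)
        max(0.6, stats::rgamma(1, shape = 4, scale = dwell_mean / 4)) else 0
      segs <- list(.tm_seg(south_start, junction, v, fps))
      if (dwell_s > 0) segs <- c(segs, list(.tm_hold(junction, dwell_s, fps)))
      segs <- c(segs, list(.tm_seg(junction, arm_point(entered, 8), v, fps),
                           .tm_hold(arm_point(entered, 8), 1, fps)))
      path <- do.call(rbind, c(list(matrix(south_start, 1)), segs))
      list(path = path, entered = entered, n_wrong = 0L, n_pause = 0L,
           dwell_s = dwell_s)
    } else {
      k <- min(max((day - 1) * 3 + trial_index, 1), 9)
      p_correct <- effect$tm_p_start +
        (effect$tm_p_end[[geno]] - effect$tm_p_start) * (k - 1) / 8
      n_wrong <- min(stats::rgeom(1, max(p_correct, 0.05)), 3L)
      # pauses sit on a spaced grid along the approach so each planted
      # stop/start cycle is separated by a resolvable stretch of swimming
      pause_slots <- seq(0.15, 0.85, by = 0.1)
      n_pause <- min(stats::rpois(1, effect$tm_stop_rate[[geno]]),
                     length(pause_slots))
      pause_dur <- stats::runif(n_pause, effect$tm_pause_s_range[1],
                                effect$tm_pause_s_range[2])
      dwell_mean <- effect$tm_dwell_mean_s[[geno]]
      dwell_s <- if (dwell_mean > 0)
        max(0.6, stats::rgamma(1, shape = 4, scale = dwell_mean / 4)) else 0
      # approach along North arm with embedded pauses
      ys <- sort(sample(pause_slots, n_pause)) *
        (junction[2] - north_start[2]) + north_start[2]
      segs <- list(); cur <- north_start
      for (i in seq_len(n_pause)) {
        pt <- c(xj, ys[i])
        segs <- c(segs, list(.tm_seg(cur, pt, v, fps),
                             .tm_hold(pt, pause_dur[i], fps)))
        cur <- pt
      }
      segs <- c(segs, list(.tm_seg(cur, junction, v, fps)))
      if (dwell_s > 0) segs <- c(segs, list(.tm_hold(junction, dwell_s, fps)))
      wrong <- other_arm(platform_arm)
      for (i in seq_len(n_wrong)) {
        segs <- c(segs, list(.tm_seg(junction, arm_point(wrong, 8), v, fps),
                             .tm_seg(arm_point(wrong, 8), junction, v, fps)))
      }
      plat <- arm_point(platform_arm, maze$ew_arm_cm - maze$platform_zone_cm / 2)
      segs <- c(segs, list(.tm_seg(junction, plat, v, fps),
                           .tm_hold(plat, 1.5, fps)))
      path <- do.call(rbind, c(list(matrix(north_start, 1)), segs))
      list(path = path, entered = platform_arm, n_wrong = n_wrong,
           n_pause = n_pause, dwell_s = dwell_s)
    }
  })
  path <- res$path
  if (effect$tm_noise_cm > 0) {
    path <- path + matrix(stats::rnorm(length(path), 0, effect$tm_noise_cm),
                          ncol = 2)
  }
  track <- pose_track(matrix(path[, 1], ncol = 1), matrix(path[, 2], ncol = 1),
                      matrix(1, nrow(path), 1), frame_rate_hz = fps,
                      px_per_cm = effect$px_per_cm, keypoints = "body_centre")
  dp <- maze$roi$decision_point
  gt_junction <- sum(in_rect(path[, 1], path[, 2], dp))
  gt <- list(n_wrong = res$n_wrong, arm_entries = res$n_wrong + 1L,
             n_pauses = res$n_pause, dwell_s = res$dwell_s,
             accelerations = 1L + res$n_pause + as.integer(res$dwell_s > 0),
             decision_point_frames = gt_junction,
             decision_point_pct = 100 * gt_junction / nrow(path),
             swim_speed_cms = v)
  if (phase %in% c("acquisition", "reversal")) {
    prect <- maze$roi[[paste0("platform_", platform_arm)]]
    first_in <- which(in_rect(path[, 1], path[, 2], prect))[1]
    gt$platform_frame <- first_in
    gt$time_to_platform_s <- (first_in - 1) / fps
  }
  if (phase == "swim_test") {
    first_c <- which(in_rect(path[, 1], path[, 2], dp))[1]
    gt$time_to_center_s <- (first_c - 1) / fps
  }
  tmaze_trial(track = track, animal_id = animal$animal_id, phase = phase,
              day = day, trial_index = trial_index,
              platform_arm = if (phase %in% c("acquisition", "reversal"))
                platform_arm else NA_character_,
              entered_arm = res$entered, ground_truth = gt)
}

#' Generate a synthetic home-cage lever-pulling log
#'
#' Simulates the three-phase operant task per mouse: phase 1 nose-pokes
#' (first poke per fixed 15-min window rewarded) until 100 rewarded pokes;
#' phase 2 lever pulls rewarded beyond 8 degrees until 100 successes; phase 3
#' pulls whose daily success probability follows a genotype-specific logistic
#' curve `floor + (ceiling - floor) / (1 + exp(-rate * (day - midpoint)))`,
#' with 200-400 trials per day, until the stopping rule (16 phase-3 days or
#' `n_days` total) ends testing.
#'
#' @param cohort_df a [cohort()] (RFID = animal id).
#' @param effect an [effect_spec()].
#' @param n_days maximum study duration in days (default 60).
#' @param seed master seed.
#' @return data frame of trials (`rfid`, `timestamp` (UTC POSIXct), `kind`,
#'   `angle_deg`, `rewarded`) ordered by mouse then time, with attribute
#'   `ground_truth`: per-mouse phase-transition indices and the daily
#'   success-probability curve.
#' @export
gen_pipaw_log <- function(cohort_df, effect = effect_spec(), n_days = 60,
                          seed = 1) {
  t0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  win_s <- effect$pp_reward_window_min * 60
  out <- list(); gt <- list()
  for (i in seq_len(nrow(cohort_df))) {
    animal <- cohort_df[i, ]
    geno <- as.character(animal$genotype)
    rec <- with_seed(child_seed(seed, animal$animal_id, "pipaw"), {
      # phase 1: nose pokes; rewarded = first poke per 15-min window
      tt <- numeric(0); rew <- logical(0)
      while (sum(rew) < 100) {
        add <- cumsum(stats::rexp(500, 1 / effect$pp_poke_gap_s)) +
          if (length(tt)) tt[length(tt)] else 0
        tt <- c(tt, add)
        rew <- !duplicated(floor(tt / win_s))
      }
      cut1 <- which(cumsum(rew) == 100)[1]
      t_poke <- tt[seq_len(cut1)]; rew1 <- rew[seq_len(cut1)]
      # phase 2: pulls beyond 8 degrees until 100 successes
      t2 <- numeric(0); a2 <- numeric(0)
      base_t <- t_poke[length(t_poke)]
      while (sum(a2 > 8) < 100) {
        add <- cumsum(stats::rexp(300, 1 / effect$pp_pull_gap_s)) +
          if (length(t2)) t2[length(t2)] else base_t
        t2 <- c(t2, add)
        a2 <- c(a2, pmin(pmax(stats::rnorm(300, effect$pp_phase2_angle_mean,
                                           effect$pp_phase2_angle_sd), 0), 25))
      }
      cut2 <- which(cumsum(a2 > 8) == 100)[1]
      t2 <- t2[seq_len(cut2)]; a2 <- a2[seq_len(cut2)]
      # phase 3: daily logistic success curve until stopping rule
      t3 <- numeric(0); a3 <- numeric(0); p_day <- numeric(0)
      anchor <- t2[length(t2)] + stats::rexp(1, 1 / effect$pp_pull_gap_s)
      d <- 0
      repeat {
        total_days <- (anchor + d * 86400) / 86400
        if (d >= effect$pp_phase3_days || total_days >= n_days) break
        d <- d + 1
        p <- effect$pp_floor + (effect$pp_ceiling - effect$pp_floor) /
          (1 + exp(-effect$pp_rate[[geno]] * (d - effect$pp_midpoint_day)))
        p_day <- c(p_day, p)
        ntr <- sample(seq(effect$pp_trials_per_day[1],
                          effect$pp_trials_per_day[2]), 1)
        succ <- stats::runif(ntr) < p
        ang <- ifelse(succ, stats::runif(ntr, 12, 21),
                      ifelse(stats::runif(ntr) < 0.75,
                             stats::runif(ntr, 0, 12),
                             stats::runif(ntr, 21, 25)))
        t3 <- c(t3, anchor + (d - 1) * 86400 + sort(stats::runif(ntr, 0, 86400)))
        a3 <- c(a3, ang)
      }
      list(t_poke = t_poke, rew1 = rew1, t2 = t2, a2 = a2, t3 = t3, a3 = a3,
           p_day = p_day)
    })
    n1 <- length(rec$t_poke); n2 <- length(rec$t2); n3 <- length(rec$t3)
    ts <- round(c(rec$t_poke, rec$t2, rec$t3), 3)
    df <- data.frame(
      rfid = animal$animal_id,
      timestamp = t0 + ts,
      kind = c(rep("nose_poke", n1), rep("lever_pull", n2 + n3)),
      angle_deg = c(rep(NA_real_, n1), rec$a2, rec$a3),
      rewarded = c(rec$rew1, rec$a2 > 8,
                   rec$a3 >= 12 & rec$a3 <= 21),
      stringsAsFactors = FALSE
    )
    out[[i]] <- df
    gt[[animal$animal_id]] <- list(
      phase2_start_index = n1 + 1L,
      phase3_start_index = n1 + n2 + 1L,
      n_phase3_days = length(rec$p_day),
      p_day = rec$p_day,
      rate = effect$pp_rate[[geno]],
      genotype = geno
    )
  }
  trials <- do.call(rbind, out)
  attr(trials, "ground_truth") <- gt
  trials
}

#' Write a lever-task event log as plain text
#'
#' One record per line: ISO timestamp (ms precision, UTC), RFID, event kind,
#' peak lever angle in degrees (`NA` for nose-pokes), rewarded flag (0/1).
#'
#' @param trials data frame as produced by [gen_pipaw_log()].
#' @param path output text file.
#' @seealso [read_pipaw_log()]
#' @export
write_pipaw_log <- function(trials, path) {
  lines <- sprintf("%s %s %s %s %d",
                   strftime(trials$timestamp, "%Y-%m-%dT%H:%M:%OS3",
                            tz = "UTC"),
                   trials$rfid, trials$kind,
                   ifelse(is.na(trials$angle_deg), "NA",
                          formatC(trials$angle_deg, digits = 6,
                                  format = "f")),
                   as.integer(trials$rewarded))
  writeLines(lines, path)
  invisible(path)
}
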