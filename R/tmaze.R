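# Water T-maze trial scoring.

#' Construct a water T-maze trial
#'
#' @param track a [pose_track()] of the body keypoint through the maze.
#' @param animal_id animal identifier.
#' @param phase `"acquisition"`, `"reversal"`, `"probe"` or `"swim_test"`.
#' @param day,trial_index position in the protocol.
#' @param platform_arm `"E"` or `"W"`; `NA` for probe/swim trials.
#' @param entered_arm arm chosen on a probe trial (`NA` otherwise).
#' @param ground_truth optional planted ground truth (synthetic trials).
#' @return an object of class `tmaze_trial`.
#' @export
tmaze_trial <- function(track, animal_id, phase, day = 1, trial_index = 1,
                        platform_arm = NA_character_,
                        entered_arm = NA_character_, ground_truth = NULL) {
  phase <- match.arg(phase, c("acquisition", "reversal", "probe", "swim_test"))
  if (phase %in% c("acquisition", "reversal") &&
      !platform_arm %in% c("E", "W")) {
    stop("acquisition/reversal trials need platform_arm E or W",
         call. = FALSE)
  }
  if (phase == "probe" && !is.na(platform_arm)) {
    stop("probe trials have no platform arm", call. = FALSE)
  }
  structure(list(track = track, animal_id = animal_id, phase = phase,
                 day = day, trial_index = trial_index,
                 platform_arm = platform_arm, entered_arm = entered_arm,
                 ground_truth = ground_truth),
            class = "tmaze_trial")
}

#' @export
print.tmaze_trial <- function(x, ...) {
  cat(sprintf("<tmaze_trial> %s %s day %d trial %d (%.1f s)\n",
              x$animal_id, x$phase, x$day, x$trial_index,
              n_frames(x$track) / x$track$frame_rate_hz))
  invisible(x)
}

# body position used for all ROI tests: centroid of available keypoints
.tm_position <- function(track) {
  cbind(rowMeans(track$x_cm, na.rm = TRUE), rowMeans(track$y_cm, na.rm = TRUE))
}

#' Time to reach the hidden platform
#'
#' The platform is reached at the first frame entering the platform ROI and
#' remaining there for at least 1 s (avoiding swim-through false positives).
#' Trials over 30 s were guided by the experimenter, so times are capped at
#' 30 s with `guided = TRUE`.
#'
#' @param trial a [tmaze_trial()] of the acquisition or reversal phase.
#' @param maze a [maze_config()].
#' @param cap_s guide-rule cap (default 30 s).
#' @param dwell_s required stay in the platform zone (default 1 s).
#' @return list with `time_s` and `guided`.
#' @export
time_to_platform <- function(trial, maze, cap_s = 30, dwell_s = 1) {
  if (!trial$phase %in% c("acquisition", "reversal")) {
    stop("time_to_platform applies to acquisition/reversal trials",
         call. = FALSE)
  }
  pos <- .tm_position(trial$track)
  fps <- trial$track$frame_rate_hz
  rect <- maze$roi[[paste0("platform_", trial$platform_arm)]]
  inside <- in_rect(pos[, 1], pos[, 2], rect)
  need <- max(1L, round(dwell_s * fps))
  # first frame starting a run of >= `need` frames inside (runs truncated by
  # the end of the track count if they reach it)
  r <- rle(inside)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  hit <- which(r$values & (r$lengths >= need | ends == length(inside)))
  if (!length(hit)) {
    if (length(inside) / fps < cap_s) {
      stop("track ends before reaching the platform and before the ",
           cap_s, "-s cap: truncated trial", call. = FALSE)
    }
    return(list(time_s = cap_s, guided = TRUE))
  }
  t <- (starts[hit[1]] - 1) / fps
  if (t > cap_s) list(time_s = cap_s, guided = TRUE)
  else list(time_s = t, guided = FALSE)
}

#' Weight-normalized time to platform
#'
#' Divides time to platform by the animal's weight factor
#' (`weight / reference weight`); heavier animals swim slower, and in
#' wild-type animals weight and time to platform correlate positively, so
#' the division removes the weight advantage of the lighter mutants.
#' Applied to manifest cohorts only.
#'
#' @param time_s time to platform in seconds (vectorised).
#' @param weight_g animal weight in grams.
#' @param ctx a [normalization_context()].
#' @return normalized time in seconds.
#' @examples
#' ctx <- structure(list(reference_weight_g = 32), class = "normalization_context")
#' normalize_time(20, 40, ctx)  # 16
#' @export
normalize_time <- function(time_s, weight_g, ctx) {
  time_s / (weight_g / ctx$reference_weight_g)
}

#' Number of arm entries in a trial
#'
#' Counts transitions of the body position from the decision point into
#' either choice arm. A hysteresis band of `hysteresis_cm` on the arm
#' boundary de-bounces oscillation: an entry is scored only when the animal
#' penetrates at least that far into the arm, and a new entry requires
#' returning at least that far into the junction first. Re-entries count; a
#' completed non-probe trial scores at least 1.
#'
#' @param trial a [tmaze_trial()].
#' @param maze a [maze_config()].
#' @param hysteresis_cm de-bounce band (default 1 cm).
#' @return integer count.
#' @export
arm_entries <- function(trial, maze, hysteresis_cm = 1) {
  pos <- .tm_position(trial$track)
  w_edge <- maze$ew_arm_cm                    # junction xmin
  e_edge <- maze$ew_arm_cm + maze$arm_width_cm  # junction xmax
  h <- hysteresis_cm
  ylo <- maze$roi$decision_point[3]; yhi <- maze$roi$decision_point[4]
  in_band <- pos[, 2] >= ylo & pos[, 2] <= yhi
  entries <- 0L
  state <- "junction"
  for (i in seq_len(nrow(pos))) {
    if (!in_band[i]) next
    x <- pos[i, 1]
    if (state == "junction") {
      if (x < w_edge - h || x > e_edge + h) {
        entries <- entries + 1L
        state <- "arm"
      }
    } else {
      if (x > w_edge + h && x < e_edge - h) state <- "junction"
    }
  }
  entries
}

#' Percentage of trial frames at the decision point
#'
#' The decision point is the junction square where the animal must commit to
#' an arm; hesitation there inflates time to platform.
#'
#' @param trial a [tmaze_trial()].
#' @param maze a [maze_config()].
#' @return percentage of trial frames inside the junction ROI.
#' @export
decision_point_fraction <- function(trial, maze) {
  pos <- .tm_position(trial$track)
  100 * mean(in_rect(pos[, 1], pos[, 2], maze$roi$decision_point))
}

#' Count accelerations (stop/start cycles) in a trial
#'
#' Counts transitions from a stopped state (smoothed speed below
#' `stop_speed_cms` for at least `min_stop_s`) to swimming (speed above
#' `go_speed_cms`). The animal starts the trial at rest, so the initial
#' start of swimming counts as the first acceleration; a track that never
#' reaches `go_speed_cms` scores 0.
#'
#' @param trial a [tmaze_trial()].
#' @param stop_speed_cms stopped threshold (default 2 cm/s).
#' @param go_speed_cms swimming threshold (default 6 cm/s).
#' @param min_stop_s minimum stop duration (default 0.25 s).
#' @param smooth_s boxcar smoothing window for speed (default 0.2 s).
#' @return integer count.
#' @export
count_accelerations <- function(trial, stop_speed_cms = 2, go_speed_cms = 6,
                                min_stop_s = 0.25, smooth_s = 0.2) {
  pos <- .tm_position(trial$track)
  fps <- trial$track$frame_rate_hz
  sp <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2) * fps
  sp <- smooth_boxcar(sp, round(smooth_s * fps))
  min_stop_f <- max(1L, round(min_stop_s * fps))
  count <- 0L
  stopped <- TRUE            # placed in the water at rest, which qualifies
  low_run <- 0L
  for (i in seq_along(sp)) {
    if (stopped) {
      if (sp[i] > go_speed_cms) {
        count <- count + 1L
        stopped <- FALSE
        low_run <- 0L
      }
    } else {
      if (sp[i] < stop_speed_cms) {
        low_run <- low_run + 1L
        if (low_run >= min_stop_f) stopped <- TRUE
      } else {
        low_run <- 0L
      }
    }
  }
  count
}

#' Classify the probe-trial navigation strategy
#'
#' On the probe trial the animal starts from the arm opposite to training
#' with no platform present. Entering the arm at the trained spatial location
#' indicates an allocentric (place) strategy; entering the opposite arm -
#' i.e. repeating the trained body turn from the mirrored start - indicates
#' an egocentric (response) strategy.
#'
#' @param entered_arm arm entered on the probe (`"E"`/`"W"`), or `NA` if the
#'   animal made no choice.
#' @param trained_arm platform arm during acquisition.
#' @return `"allocentric"`, `"egocentric"`, or `NA` (excluded: no choice).
#' @export
classify_probe <- function(entered_arm, trained_arm) {
  if (is.na(entered_arm)) return(NA_character_)
  if (!entered_arm %in% c("E", "W") || !trained_arm %in% c("E", "W")) {
    stop("arms must be E or W", call. = FALSE)
  }
  if (entered_arm == trained_arm) "allocentric" else "egocentric"
}

#' Reversal-phase eligibility
#'
#' An animal proceeds to the reversal phase only if it reached the platform
#' in a single arm entry, without experimenter guidance, on at least 2 of
#' the 3 trials of acquisition day 3.
#'
#' @param entries integer vector of day-3 arm entry counts (one per trial).
#' @param guided logical vector of day-3 guided flags.
#' @return `TRUE` if eligible.
#' @examples
#' reversal_eligible(c(1, 1, 2), c(FALSE, FALSE, FALSE))  # TRUE
#' reversal_eligible(c(2, 2, 1), c(FALSE, FALSE, FALSE))  # FALSE
#' @export
reversal_eligible <- function(entries, guided) {
  if (length(entries) != length(guided)) {
    stop("entries and guided must have equal length", call. = FALSE)
  }
  sum(entries == 1 & !guided) >= 2
}

#' Swimming speed from the swim-test trials
#'
#' Each swim test places the animal at the end of the South arm and times the
#' swim to the centre of the maze; speed is the path length divided by the
#' time. The first trial is discarded and the mean speed of trials 2 and 3
#' is reported.
#'
#' @param times_s vector of exactly 3 trial times (s).
#' @param distance_cm start-to-centre path length (default 37 cm, the long
#'   arm).
#' @return mean speed of trials 2 and 3 (cm/s).
#' @examples
#' swim_speed(c(3, 2, 2))  # 18.5
#' @export
swim_speed <- function(times_s, distance_cm = 37) {
  if (length(times_s) != 3 || any(is.na(times_s))) {
    stop("swim_speed requires all three swim-test trials", call. = FALSE)
  }
  mean(distance_cm / times_s[2:3])
}

#' Extract all scored features from one T-maze trial
#'
#' @param trial a [tmaze_trial()] (acquisition or reversal).
#' @param maze a [maze_config()].
#' @return one-row data frame: `animal_id`, `phase`, `day`, `trial_index`,
#'   `time_to_platform_s`, `guided`, `arm_entries`, `decision_point_pct`,
#'   `accelerations`.
#' @export
tmaze_features <- function(trial, maze = maze_config()) {
  tp <- time_to_platform(trial, maze)
  data.frame(animal_id = trial$animal_id, phase = trial$phase,
             day = trial$day, trial_index = trial$trial_index,
             time_to_platform_s = tp$time_s, guided = tp$guided,
             arm_entries = arm_entries(trial, maze),
             decision_point_pct = decision_point_fraction(trial, maze),
             accelerations = count_accelerations(trial),
             stringsAsFactors = FALSE)
}
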