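# Accelerating rotarod: protocol semantics, slip detection, weight
# normalization.

#' Construct a rotarod trial
#'
#' Holds the annotated event sequence (rotations, recoveries, a terminal
#' fall) and the hind-paw height traces in the rod frame (cm; y increases
#' upward from the rod bottom at `rod_bottom_y`).
#'
#' @param animal_id animal identifier.
#' @param day training day (1-4).
#' @param trial_index trial within the day (1-3).
#' @param events data frame with columns `time_s` and `kind`
#'   (`"rotation"`, `"recovery"`, `"fall"`); times strictly increasing, at
#'   most one fall and it must be last.
#' @param paw_y numeric matrix (frames x 2) of left/right hind paw heights,
#'   or `NULL` when no video was usable.
#' @param rod_bottom_y height of the rod bottom in the trace frame.
#' @param frame_rate_hz trace sampling rate.
#' @param max_trial_s trial cap (default 300 s, the end of the acceleration
#'   ramp).
#' @param ground_truth optional planted ground truth (synthetic trials).
#' @return an object of class `rotarod_trial`.
#' @export
rotarod_trial <- function(animal_id, day, trial_index, events,
                          paw_y = NULL, rod_bottom_y = 0, frame_rate_hz = 30,
                          max_trial_s = 300, ground_truth = NULL) {
  if (nrow(events)) {
    if (!all(events$kind %in% c("rotation", "recovery", "fall"))) {
      stop("event kinds must be rotation/recovery/fall", call. = FALSE)
    }
    if (is.unsorted(events$time_s, strictly = TRUE)) {
      stop("event times must be strictly increasing", call. = FALSE)
    }
    falls <- which(events$kind == "fall")
    if (length(falls) > 1 ||
        (length(falls) == 1 && falls != nrow(events))) {
      stop("at most one fall event is allowed and it must terminate the trial",
           call. = FALSE)
    }
  }
  structure(list(animal_id = animal_id, day = day, trial_index = trial_index,
                 events = events, paw_y = paw_y, rod_bottom_y = rod_bottom_y,
                 frame_rate_hz = frame_rate_hz, max_trial_s = max_trial_s,
                 ground_truth = ground_truth),
            class = "rotarod_trial")
}

#' @export
print.rotarod_trial <- function(x, ...) {
  cat(sprintf("<rotarod_trial> %s day %d trial %d: %d event(s)%s\n",
              x$animal_id, x$day, x$trial_index, nrow(x$events),
              if (!is.null(x$paw_y))
                sprintf(", %d trace frames", nrow(x$paw_y)) else ""))
  invisible(x)
}

#' Rod speed during the acceleration ramp
#'
#' The rod accelerates linearly from 5 to 40 rpm over 300 s and stays at
#' 40 rpm thereafter.
#'
#' @param t_s time since trial start (s), vectorised.
#' @return rotations per minute.
#' @examples
#' rod_speed(c(0, 150, 300, 400))  # 5, 22.5, 40, 40
#' @export
rod_speed <- function(t_s) {
  if (any(t_s < 0)) stop("t_s must be >= 0", call. = FALSE)
  pmin(5 + 35 * t_s / 300, 40)
}

#' Trial endpoint (latency) under either rotarod protocol
#'
#' Under the Standard protocol one rotation is treated as equivalent to a
#' fall, so the trial ends at the first rotation or the fall, whichever is
#' earlier. Under the Rotations Allowed protocol rotations are tolerated
#' until three occur consecutively (no recovery event in between); the trial
#' ends at the third rotation of such a run, or at the fall. A trial with no
#' terminating event ran to the cap and scores `max_trial_s`.
#'
#' @param trial a [rotarod_trial()].
#' @param protocol `"standard"` or `"rotations_allowed"`.
#' @return latency in seconds.
#' @examples
#' tr <- rotarod_trial("a", 1, 1,
#'   data.frame(time_s = c(50, 80), kind = c("rotation", "fall")))
#' trial_endpoint(tr, "standard")           # 50
#' trial_endpoint(tr, "rotations_allowed")  # 80
#' @export
trial_endpoint <- function(trial, protocol = c("standard",
                                               "rotations_allowed")) {
  protocol <- match.arg(protocol)
  ev <- trial$events
  if (nrow(ev) == 0 && is.null(trial$paw_y) && is.null(trial$max_trial_s)) {
    stop("cannot determine endpoint: no events, trace, or trial cap",
         call. = FALSE)
  }
  fall_t <- if (any(ev$kind == "fall")) ev$time_s[ev$kind == "fall"] else Inf
  if (protocol == "standard") {
    rot_t <- if (any(ev$kind == "rotation"))
      min(ev$time_s[ev$kind == "rotation"]) else Inf
    end <- min(fall_t, rot_t)
  } else {
    run <- 0L; end <- Inf
    for (i in seq_len(nrow(ev))) {
      if (ev$kind[i] == "rotation") {
        run <- run + 1L
        if (run == 3L) { end <- ev$time_s[i]; break }
      } else if (ev$kind[i] == "recovery") {
        run <- 0L
      } else {            # fall
        end <- ev$time_s[i]; break
      }
    }
    end <- min(end, fall_t)
  }
  if (is.infinite(end)) trial$max_trial_s else end
}

#' Detect paw-slip events in hind-paw height traces
#'
#' A slip is scored when one or both hind paws dip below the bottom of the
#' rod. An event opens when either paw's height crosses below
#' `rod_bottom_y - min_depth_cm` and closes when both paws have returned
#' above `rod_bottom_y`; events separated by less than `merge_window_s` are
#' merged to avoid double-counting jitter around the threshold.
#'
#' @param trial a [rotarod_trial()] with paw traces.
#' @param min_depth_cm minimum excursion depth below the rod bottom for an
#'   event to open (default 0: any crossing counts).
#' @param merge_window_s events closer than this are merged (default 0.2 s).
#' @return data frame of slip events: `onset_frame`, `offset_frame`
#'   (1-based, inclusive).
#' @export
detect_slips <- function(trial, min_depth_cm = 0, merge_window_s = 0.2) {
  if (is.null(trial$paw_y) || all(is.na(trial$paw_y))) {
    stop("trial has no usable paw trace", call. = FALSE)
  }
  lo <- pmin(trial$paw_y[, 1], trial$paw_y[, 2])
  rb <- trial$rod_bottom_y
  deep <- !is.na(lo) & lo < rb - min_depth_cm
  up <- !is.na(lo) & lo > rb
  n <- length(lo)
  onsets <- integer(0); offsets <- integer(0)
  open <- FALSE; start <- NA_integer_
  r <- rle(ifelse(deep, 2L, ifelse(up, 0L, 1L)))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!open && r$values[j] == 2L) {
      open <- TRUE; start <- starts[j]
    } else if (open && r$values[j] == 0L) {
      onsets <- c(onsets, start); offsets <- c(offsets, starts[j] - 1L)
      open <- FALSE
    }
  }
  if (open) { onsets <- c(onsets, start); offsets <- c(offsets, n) }
  if (length(onsets) > 1) {
    merge_f <- round(merge_window_s * trial$frame_rate_hz)
    keep_on <- onsets[1]; out_on <- integer(0); out_off <- integer(0)
    cur_off <- offsets[1]
    for (i in 2:length(onsets)) {
      if (onsets[i] - cur_off - 1L < merge_f) {
        cur_off <- offsets[i]
      } else {
        out_on <- c(out_on, keep_on); out_off <- c(out_off, cur_off)
        keep_on <- onsets[i]; cur_off <- offsets[i]
      }
    }
    onsets <- c(out_on, keep_on); offsets <- c(out_off, cur_off)
  }
  data.frame(onset_frame = onsets, offset_frame = offsets)
}

#' Paw-slip rate of a trial
#'
#' Slips per minute over the trial duration. Trials shorter than
#' `min_duration_s` (20 s) are excluded from slip-frequency analysis and
#' flagged instead of scored.
#'
#' @param trial a [rotarod_trial()].
#' @param events slip events from [detect_slips()].
#' @param latency_s trial duration; defaults to the Standard-protocol
#'   endpoint.
#' @param min_duration_s exclusion threshold (default 20 s).
#' @return one-row data frame: `n_slips`, `duration_s`, `rate_per_min`,
#'   `excluded`.
#' @export
slip_rate <- function(trial, events, latency_s = NULL, min_duration_s = 20) {
  dur <- latency_s %||% trial_endpoint(trial, "standard")
  excluded <- dur < min_duration_s
  data.frame(n_slips = nrow(events), duration_s = dur,
             rate_per_min = if (excluded) NA_real_ else
               nrow(events) / (dur / 60),
             excluded = excluded)
}

#' Weight-normalization context for a cohort
#'
#' The reference weight is the mean weight of the mutant-genotype animals in
#' the cohort (computed within one sex x age cohort, matching the per-cohort
#' analyses); each animal's factor is `weight_g / reference`.
#'
#' @param cohort_df a [cohort()] restricted to one sex x age cohort.
#' @return an object of class `normalization_context` with
#'   `reference_weight_g`.
#' @export
normalization_context <- function(cohort_df) {
  w <- cohort_df$weight_g[cohort_df$genotype == "mutant"]
  if (!length(w)) {
    stop("cohort contains no mutant animals: reference weight undefined",
         call. = FALSE)
  }
  structure(list(reference_weight_g = mean(w), n_reference = length(w)),
            class = "normalization_context")
}

#' @export
print.normalization_context <- function(x, ...) {
  cat(sprintf("<normalization_context> reference weight %.2f g (n = %d)\n",
              x$reference_weight_g, x$n_reference))
  invisible(x)
}

#' Weight-normalized rotarod latency
#'
#' Multiplies time on rotarod by the animal's weight factor
#' (`weight / reference weight`), compensating for the disadvantage of
#' heavier animals on the task. Applied to manifest cohorts only (young
#' cohorts show no weight phenotype and are analysed raw).
#'
#' @param latency_s latency in seconds (vectorised).
#' @param weight_g animal weight in grams.
#' @param ctx a [normalization_context()].
#' @return normalized latency in seconds.
#' @examples
#' ctx <- structure(list(reference_weight_g = 32), class = "normalization_context")
#' normalize_latency(100, 40, ctx)  # 125
#' @export
normalize_latency <- function(latency_s, weight_g, ctx) {
  latency_s * (weight_g / ctx$reference_weight_g)
}
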