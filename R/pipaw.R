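# Home-cage lever-pulling task: log parsing, refinement, phase state machine,
# daily performance, stopping rule.

#' Read a lever-task event log
#'
#' Parses the plain-text log written by the home-cage apparatus: one record
#' per line with ISO timestamp, RFID, event kind (`nose_poke` /
#' `lever_pull`), peak lever angle in degrees (`NA` for pokes) and a
#' rewarded flag. Trials are ordered by timestamp within each mouse;
#' malformed lines are collected into a rejects report attached as the
#' `rejects` attribute.
#'
#' @param path text log file.
#' @return data frame of raw trials (`rfid`, `timestamp`, `kind`,
#'   `angle_deg`, `rewarded`) with a `rejects` attribute (data frame of
#'   `line`, `text`, `reason`).
#' @seealso [refine_log()], [write_pipaw_log()]
#' @export
read_pipaw_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("log contains no records: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  rejects <- data.frame(line = integer(0), text = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  reject <- function(i, why) {
    rejects[nrow(rejects) + 1L, ] <<- list(i, lines[i], why)
    NULL
  }
  rows <- vector("list", length(lines))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 5) { reject(i, "wrong field count"); next }
    ts <- as.POSIXct(p[1], format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    if (is.na(ts)) { reject(i, "unparseable timestamp"); next }
    if (!p[3] %in% c("nose_poke", "lever_pull")) {
      reject(i, "unknown event kind"); next
    }
    ang <- suppressWarnings(as.numeric(p[4]))
    if (is.na(ang) && p[4] != "NA") { reject(i, "non-numeric angle"); next }
    rw <- suppressWarnings(as.integer(p[5]))
    if (is.na(rw) || !rw %in% 0:1) { reject(i, "bad rewarded flag"); next }
    rows[[i]] <- data.frame(rfid = p[2], timestamp = ts, kind = p[3],
                            angle_deg = ang, rewarded = rw == 1L,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no parseable records in: ", path, call. = FALSE)
  trials <- do.call(rbind, rows)
  trials <- trials[order(trials$rfid, trials$timestamp), ]
  rownames(trials) <- NULL
  attr(trials, "rejects") <- rejects
  trials
}

#' Refine a raw trial list
#'
#' The refinement filter drops trials with aberrant lever readings or
#' timestamps: lever-pull angles outside the physical 0-25 degree range,
#' non-finite angles on pulls, and timestamps earlier than the same mouse's
#' previous trial. Rejects are reported with reasons; clean trials pass
#' through unchanged.
#'
#' @param trials raw trial data frame from [read_pipaw_log()] or
#'   [gen_pipaw_log()].
#' @return list with `clean` (trial data frame) and `rejects` (data frame
#'   with a `reason` column).
#' @export
refine_log <- function(trials) {
  reason <- rep(NA_character_, nrow(trials))
  is_pull <- trials$kind == "lever_pull"
  bad_angle <- is_pull & (!is.finite(trials$angle_deg) |
                            trials$angle_deg < 0 | trials$angle_deg > 25)
  reason[bad_angle] <- "angle outside lever range"
  for (id in unique(trials$rfid)) {
    idx <- which(trials$rfid == id)
    if (length(idx) > 1) {
      back <- c(FALSE, diff(as.numeric(trials$timestamp[idx])) < 0)
      reason[idx[back & is.na(reason[idx])]] <- "backwards timestamp"
    }
  }
  keep <- is.na(reason)
  rejects <- trials[!keep, , drop = FALSE]
  rejects$reason <- reason[!keep]
  clean <- trials[keep, , drop = FALSE]
  rownames(clean) <- rownames(rejects) <- NULL
  list(clean = clean, rejects = rejects)
}

#' Is a lever pull successful in a given phase?
#'
#' Phase 2 rewards pulls strictly beyond 8 degrees; phase 3 rewards pulls
#' whose peak amplitude falls within the 12-21 degree goal band (closed at
#' both ends). The lever's full movement range is 25 degrees.
#'
#' @param angle_deg peak pull angle (vectorised).
#' @param phase task phase (2 or 3); phase-1 events are nose-pokes and
#'   return `NA`.
#' @param phase2_threshold,band lower threshold and goal band, configurable.
#' @return logical vector.
#' @examples
#' pull_success(c(11.9, 12, 21, 21.1), 3)  # FALSE TRUE TRUE FALSE
#' pull_success(8.0, 2)                    # FALSE (strictly beyond 8)
#' @export
pull_success <- function(angle_deg, phase, phase2_threshold = 8,
                         band = c(12, 21)) {
  if (phase == 1) return(rep(NA, length(angle_deg)))
  if (phase == 2) return(angle_deg > phase2_threshold)
  if (phase == 3) return(angle_deg >= band[1] & angle_deg <= band[2])
  stop("phase must be 1, 2 or 3", call. = FALSE)
}

#' Run the three-phase task state machine for one mouse
#'
#' Phase 1 (habituation) lasts until the 100th rewarded nose-poke; phase 2
#' (shaping, pulls beyond 8 degrees) until the 100th successful pull; phase
#' 3 (testing, 12-21 degree goal band) thereafter. Each transition applies
#' starting with the trial after the one that completed the count. A mouse
#' that never completes a count simply never transitions.
#'
#' @param trials clean trials for a single mouse, ordered by timestamp.
#' @param n_pokes,n_pulls transition counts (default 100 each).
#' @return the trials with added columns `phase` and `success`
#'   (phase-appropriate success; `NA` in phase 1 for pokes), plus attribute
#'   `transitions`: a data frame of phase entry indices and timestamps.
#' @export
run_phase_machine <- function(trials, n_pokes = 100, n_pulls = 100) {
  if (length(unique(trials$rfid)) > 1) {
    stop("run_phase_machine expects trials for a single mouse", call. = FALSE)
  }
  if (is.unsorted(as.numeric(trials$timestamp))) {
    stop("trials must be ordered by timestamp; run refine_log() first",
         call. = FALSE)
  }
  n <- nrow(trials)
  phase <- integer(n)
  success <- rep(NA, n)
  cur <- 1L; pokes <- 0L; pulls <- 0L
  trans_idx <- c(phase1 = 1L, phase2 = NA_integer_, phase3 = NA_integer_)
  for (i in seq_len(n)) {
    phase[i] <- cur
    if (cur == 1L) {
      if (trials$kind[i] == "nose_poke" && trials$rewarded[i]) {
        pokes <- pokes + 1L
        if (pokes == n_pokes) { cur <- 2L; trans_idx["phase2"] <- i + 1L }
      }
    } else if (cur == 2L) {
      if (trials$kind[i] == "lever_pull") {
        success[i] <- pull_success(trials$angle_deg[i], 2)
        if (isTRUE(success[i])) {
          pulls <- pulls + 1L
          if (pulls == n_pulls) { cur <- 3L; trans_idx["phase3"] <- i + 1L }
        }
      }
    } else {
      if (trials$kind[i] == "lever_pull") {
        success[i] <- pull_success(trials$angle_deg[i], 3)
      }
    }
  }
  trials$phase <- phase
  trials$success <- success
  attr(trials, "transitions") <- data.frame(
    phase = 1:3,
    start_index = c(1L, unname(trans_idx["phase2"]),
                    unname(trans_idx["phase3"])),
    start_time = trials$timestamp[c(1L, unname(trans_idx["phase2"]),
                                    unname(trans_idx["phase3"]))]
  )
  trials
}

#' Daily performance in the testing phase
#'
#' Bins phase-3 trials into half-open 24-h bins `[t0 + 24k, t0 + 24(k+1))`
#' anchored at the first phase-3 trial and reports trial counts and success
#' rates per bin. Empty interior bins are emitted with `n_trials = 0` and an
#' undefined rate.
#'
#' @param trials annotated trials from [run_phase_machine()] for one mouse.
#' @return data frame with `day` (1-based bin), `n_trials`, `n_success`,
#'   `success_rate` (percent).
#' @export
daily_performance <- function(trials) {
  p3 <- trials[trials$phase == 3L & trials$kind == "lever_pull", ,
               drop = FALSE]
  if (!nrow(p3)) {
    return(data.frame(day = integer(0), n_trials = integer(0),
                      n_success = integer(0), success_rate = numeric(0)))
  }
  t0 <- as.numeric(p3$timestamp[1])
  bin <- floor((as.numeric(p3$timestamp) - t0) / 86400) + 1L
  days <- seq_len(max(bin))
  n_trials <- tabulate(bin, nbins = max(bin))
  n_success <- vapply(days, function(d) sum(p3$success[bin == d]),
                      integer(1))
  data.frame(day = days, n_trials = n_trials, n_success = n_success,
             success_rate = ifelse(n_trials > 0, 100 * n_success / n_trials,
                                   NA_real_))
}

#' Apply the study stopping rule
#'
#' Testing ends at the completion of 16 (+/- 2) days in the final testing
#' phase or at 60 days in the apparatus, whichever comes first.
#'
#' @param days_in_phase3 completed days in the testing phase.
#' @param study_days total days since the mouse entered the apparatus.
#' @param phase3_limit,max_days thresholds (defaults 16 and 60).
#' @return `"stop_16d"`, `"stop_60d"` or `"active"`, with attribute
#'   `tolerance_band` giving the 16 +/- 2 day window.
#' @export
stopping_rule <- function(days_in_phase3, study_days, phase3_limit = 16,
                          max_days = 60) {
  status <- if (days_in_phase3 >= phase3_limit) "stop_16d"
            else if (study_days >= max_days) "stop_60d"
            else "active"
  structure(status, tolerance_band = c(phase3_limit - 2, phase3_limit + 2))
}

#' Fit a logistic success curve to daily success rates
#'
#' Least-squares fit of `floor + (ceiling - floor) / (1 + exp(-rate *
#' (day - midpoint)))` to per-day success rates (as fractions), used to
#' recover the learning-rate parameter from synthetic cohorts and to
#' summarise observed learning curves.
#'
#' @param day day index (1-based).
#' @param success_rate success rate per day, in percent.
#' @return named coefficient vector `floor`, `ceiling`, `rate`, `midpoint`.
#' @export
fit_success_curve <- function(day, success_rate) {
  ok <- is.finite(success_rate)
  df <- data.frame(day = day[ok], p = success_rate[ok] / 100)
  fit <- minpack.lm::nlsLM(
    p ~ fl + (ce - fl) / (1 + exp(-k * (day - mid))),
    data = df,
    start = list(fl = max(min(df$p), 1e-3), ce = min(max(df$p), 0.999),
                 k = 0.5, mid = stats::median(df$day)),
    lower = c(0, 0, 0.01, 0), upper = c(1, 1, 10, max(df$day) * 2),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  c(floor = unname(cf["fl"]), ceiling = unname(cf["ce"]),
    rate = unname(cf["k"]), midpoint = unname(cf["mid"]))
}
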