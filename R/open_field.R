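# Open-field metrics: distance/habituation, centre time, bouts, label fractions.

#' Per-frame step lengths of a keypoint
#'
#' Euclidean displacement (cm) between consecutive retained frames of the
#' tracked keypoint (tail base by default, the keypoint used for open-field
#' distance). Steps into or out of a missing (NA) frame contribute 0 and the
#' number of such dropped steps is recorded in the `n_missing_steps`
#' attribute.
#'
#' @param track a [pose_track()].
#' @param keypoint keypoint name (default `"tail_base"`).
#' @return numeric vector of length `n_frames(track) - 1` with attribute
#'   `n_missing_steps`.
#' @export
distance_series <- function(track, keypoint = "tail_base") {
  if (!keypoint %in% track$keypoints) {
    stop("keypoint not present in track: ", keypoint, call. = FALSE)
  }
  x <- track$x_cm[, keypoint]; y <- track$y_cm[, keypoint]
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  miss <- is.na(steps)
  steps[miss] <- 0
  attr(steps, "n_missing_steps") <- sum(miss)
  steps
}

#' Bin a step series into fixed time bins
#'
#' @param steps per-frame step lengths from [distance_series()].
#' @param frame_rate_hz frames per second of the source track.
#' @param bin_s bin length in seconds (default 300, i.e. 5-min bins).
#' @return an object of class `binned_distance`: list with `per_bin_cm`,
#'   `total_cm` and `bin_s`. Per-bin distances sum to the total exactly.
#' @export
bin_distance <- function(steps, frame_rate_hz, bin_s = 300) {
  nf <- round(bin_s * frame_rate_hz)
  # step i joins frames i and i+1; assign it to the bin of frame i+1
  bin <- ((seq_along(steps)) %/% nf) + 1L
  bin <- pmin(bin, max(1L, ceiling(length(steps) / nf)))
  per_bin <- as.numeric(tapply(steps, bin, sum))
  structure(list(per_bin_cm = per_bin, total_cm = sum(per_bin), bin_s = bin_s),
            class = "binned_distance")
}

#' @export
print.binned_distance <- function(x, ...) {
  cat(sprintf("<binned_distance> %d bins of %g s, total %.1f cm\n",
              length(x$per_bin_cm), x$bin_s, x$total_cm))
  invisible(x)
}

#' Percent change in per-bin distance relative to the first bin
#'
#' The habituation readout: `100 * (d_i - d_1) / d_1`, identically 0 for the
#' first bin. A smaller (more negative) trajectory over the session indicates
#' stronger habituation to the arena.
#'
#' @param b a [bin_distance()] result.
#' @return numeric vector, one value per bin; the first is exactly 0.
#' @examples
#' b <- structure(list(per_bin_cm = c(8, 10, 4), total_cm = 22, bin_s = 300),
#'                class = "binned_distance")
#' habituation_percent_change(b)  # 0, 25, -50
#' @export
habituation_percent_change <- function(b) {
  d <- b$per_bin_cm
  if (length(d) < 2) stop("need at least 2 bins", call. = FALSE)
  if (d[1] <= 0) stop("first bin distance is zero: baseline undefined",
                      call. = FALSE)
  pc <- 100 * (d - d[1]) / d[1]
  pc[1] <- 0
  pc
}

#' Estimate the habituation decay rate from binned distances
#'
#' Fits `log(d_i) = log(d_1) - lambda * (i - 1)` by least squares and returns
#' the decay rate per bin. This is the estimator whose recovery of the
#' generator's planted lambda is checked on synthetic sessions.
#'
#' @param b a [bin_distance()] result with positive bins.
#' @return list with `lambda` (per bin) and `d1_cm` (fitted first-bin
#'   distance).
#' @export
fit_habituation <- function(b) {
  d <- b$per_bin_cm
  if (any(d <= 0)) stop("all bins must be positive to fit a decay",
                        call. = FALSE)
  i <- seq_along(d) - 1
  fit <- stats::lm(log(d) ~ i)
  list(lambda = -unname(stats::coef(fit)[2]),
       d1_cm = exp(unname(stats::coef(fit)[1])))
}

#' Percentage of time spent in the arena centre zone
#'
#' Fraction of retained (non-missing) frames in which the keypoint lies
#' inside the centred square of side `center_fraction * arena_side_cm`.
#'
#' @param track a [pose_track()].
#' @param arena an [arena_config()].
#' @param keypoint keypoint used for position (default `"tail_base"`).
#' @return percentage in `[0, 100]`.
#' @export
center_time_fraction <- function(track, arena, keypoint = "tail_base") {
  if (!keypoint %in% track$keypoints) {
    stop("keypoint not present in track: ", keypoint, call. = FALSE)
  }
  x <- track$x_cm[, keypoint]; y <- track$y_cm[, keypoint]
  ok <- !is.na(x) & !is.na(y)
  L <- arena$arena_side_cm
  half <- arena$center_fraction * L / 2
  inside <- x[ok] >= L / 2 - half & x[ok] <= L / 2 + half &
    y[ok] >= L / 2 - half & y[ok] <= L / 2 + half
  100 * mean(inside)
}

#' Segment a label stream into behaviour bouts
#'
#' A bout is a maximal run of one label. Runs of the same label separated by
#' gaps of at most `gap_tol_s` of other labels are merged; merged bouts
#' shorter than `min_bout_s` are dropped.
#'
#' @param labels a [label_stream()].
#' @param label which behaviour to segment; `NULL` segments every level and
#'   concatenates the results.
#' @param min_bout_s minimum bout duration in seconds (default 0: keep all).
#' @param gap_tol_s longest within-bout interruption merged over (default 0).
#' @return data frame with columns `label`, `start_frame`, `end_frame`
#'   (1-based, inclusive) and `duration_s`.
#' @examples
#' ls <- label_stream(rep(c("rearing", "sniffing", "rearing"), c(3, 2, 3)))
#' segment_bouts(ls, "rearing")                 # two bouts of 3 frames
#' segment_bouts(ls, "rearing", gap_tol_s = 2 / 30)  # one bout of 8 frames
#' @export
segment_bouts <- function(labels, label = NULL, min_bout_s = 0,
                          gap_tol_s = 0) {
  if (min_bout_s < 0 || gap_tol_s < 0) {
    stop("min_bout_s and gap_tol_s must be >= 0", call. = FALSE)
  }
  fps <- attr(labels, "frame_rate_hz")
  if (is.null(label)) {
    out <- lapply(levels(labels), function(l) {
      segment_bouts(labels, l, min_bout_s, gap_tol_s)
    })
    return(do.call(rbind, out))
  }
  is_l <- as.character(labels) == label
  # tolerate float error in seconds -> frames conversion
  gap_tol <- floor(gap_tol_s * fps + 1e-9)
  min_frames <- max(1, ceiling(min_bout_s * fps - 1e-9))
  r <- rle(is_l)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1 && gap_tol > 0) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= gap_tol) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  dur <- runs$end - runs$start + 1L
  runs <- runs[dur >= min_frames, , drop = FALSE]
  data.frame(label = rep(label, nrow(runs)), start_frame = runs$start,
             end_frame = runs$end,
             duration_s = (runs$end - runs$start + 1L) / fps,
             stringsAsFactors = FALSE)
}

#' Fraction of time carrying a behaviour label
#'
#' Percentage of frames labelled `label`, either over the whole stream or per
#' fixed time bin.
#'
#' @param labels a [label_stream()].
#' @param label one of the stream's levels.
#' @param bin_s optional bin length in seconds; when given, one percentage is
#'   returned per bin.
#' @return a percentage, or a numeric vector of per-bin percentages.
#' @export
behaviour_fraction <- function(labels, label, bin_s = NULL) {
  if (!label %in% levels(labels)) {
    stop("unknown label: ", label, call. = FALSE)
  }
  hit <- as.character(labels) == label
  if (is.null(bin_s)) return(100 * mean(hit))
  fps <- attr(labels, "frame_rate_hz")
  nf <- round(bin_s * fps)
  bin <- ((seq_along(hit) - 1L) %/% nf) + 1L
  as.numeric(tapply(hit, bin, function(z) 100 * mean(z)))
}

#' Relabel wall-supported rearing
#'
#' Rearing frames in which the keypoint lies within `wall_margin_cm` of any
#' arena wall are relabelled `"other"`, so that subsequent fraction and bout
#' analyses quantify rearing away from the wall only.
#'
#' @param track a [pose_track()] paired with the stream (same length).
#' @param labels a [label_stream()].
#' @param arena an [arena_config()].
#' @param keypoint keypoint used for position.
#' @return a new [label_stream()].
#' @export
rearing_away_from_wall <- function(track, labels, arena,
                                   keypoint = "tail_base") {
  if (n_frames(track) != length(labels)) {
    stop("track and label stream have different lengths", call. = FALSE)
  }
  m <- arena$wall_margin_cm
  if (m == 0) return(labels)
  L <- arena$arena_side_cm
  x <- track$x_cm[, keypoint]; y <- track$y_cm[, keypoint]
  near_wall <- !is.na(x) & !is.na(y) &
    (x < m | x > L - m | y < m | y > L - m)
  lab <- as.character(labels)
  lab[lab == "rearing" & near_wall] <- "other"
  label_stream(lab, attr(labels, "frame_rate_hz"))
}

#' Summarise one open-field session
#'
#' Convenience wrapper running the full open-field pipeline for one animal:
#' binned distance, habituation percent change, centre time, wall-corrected
#' rearing fraction and rearing bout statistics.
#'
#' @param track a [pose_track()].
#' @param labels a [label_stream()] aligned to the track.
#' @param arena an [arena_config()].
#' @param bin_s bin length in seconds.
#' @return a list of the per-session metrics.
#' @export
summarise_open_field <- function(track, labels, arena = arena_config(),
                                 bin_s = 300) {
  steps <- distance_series(track)
  b <- bin_distance(steps, track$frame_rate_hz, bin_s)
  lab2 <- rearing_away_from_wall(track, labels, arena)
  bouts <- segment_bouts(lab2, "rearing")
  list(
    binned = b,
    percent_change = habituation_percent_change(b),
    total_cm = b$total_cm,
    center_pct = center_time_fraction(track, arena),
    rearing_pct = behaviour_fraction(lab2, "rearing"),
    rearing_pct_bins = behaviour_fraction(lab2, "rearing", bin_s),
    rearing_bout_mean_s = if (nrow(bouts)) mean(bouts$duration_s) else NA_real_
  )
}
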