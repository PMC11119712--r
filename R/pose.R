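# Pose tracks, label streams, arena/maze geometry, and their file formats.

.behaviour_levels <- c("locomotion_turning", "sniffing", "rearing", "other")

#' Construct a pose track
#'
#' A pose track holds per-frame keypoint coordinates with tracking
#' confidences. Coordinates are converted to centimetres once, at
#' construction, using `px_per_cm`; every downstream computation works in cm
#' so units cannot get mixed. The image convention applies (y increases
#' downward); frame index is 0-based and frame `i` occurs at time
#' `i / frame_rate_hz`.
#'
#' @param x_cm,y_cm,confidence numeric matrices, frames x keypoints.
#'   Confidence must lie in `[0, 1]` (NA allowed for missing frames).
#' @param frame_rate_hz frames per second (> 0).
#' @param px_per_cm pixel calibration used when reading/writing pixel
#'   tables (> 0).
#' @param keypoints character vector of keypoint names; defaults to the
#'   column names of `x_cm`.
#' @return an object of class `pose_track`.
#' @seealso [read_pose_table()], [clean_track()]
#' @export
pose_track <- function(x_cm, y_cm, confidence, frame_rate_hz = 30,
                       px_per_cm = 10, keypoints = colnames(x_cm)) {
  x_cm <- as.matrix(x_cm); y_cm <- as.matrix(y_cm)
  confidence <- as.matrix(confidence)
  if (is.null(keypoints)) keypoints <- paste0("kp", seq_len(ncol(x_cm)))
  if (!all(dim(x_cm) == dim(y_cm)) || !all(dim(x_cm) == dim(confidence))) {
    stop("x, y and confidence must have identical dimensions", call. = FALSE)
  }
  if (length(keypoints) != ncol(x_cm)) {
    stop("keypoints must name every coordinate column", call. = FALSE)
  }
  stopifnot_scalar_pos(frame_rate_hz, "frame_rate_hz")
  stopifnot_scalar_pos(px_per_cm, "px_per_cm")
  cf <- confidence[!is.na(confidence)]
  if (length(cf) && (any(cf < 0) || any(cf > 1))) {
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  colnames(x_cm) <- colnames(y_cm) <- colnames(confidence) <- keypoints
  structure(list(x_cm = x_cm, y_cm = y_cm, confidence = confidence,
                 keypoints = keypoints, frame_rate_hz = frame_rate_hz,
                 px_per_cm = px_per_cm),
            class = "pose_track")
}

#' Number of frames in a pose track
#' @param track a [pose_track()].
#' @export
n_frames <- function(track) nrow(track$x_cm)

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames @ %g Hz (%.1f s), keypoints: %s\n",
              n_frames(x), x$frame_rate_hz, n_frames(x) / x$frame_rate_hz,
              paste(x$keypoints, collapse = ", ")))
  invisible(x)
}

#' Flag and interpolate low-confidence frames
#'
#' Frames whose confidence falls below `confidence_min` are treated as
#' missing. Gaps no longer than `max_gap_s` are filled by linear
#' interpolation of the flanking retained frames; longer gaps are left as NA
#' and are excluded from distance sums downstream.
#'
#' @param track a [pose_track()].
#' @param confidence_min retention threshold (default 0.6, the usual
#'   post-processing cut for markerless tracker likelihoods).
#' @param max_gap_s longest gap (s) that is interpolated (default 0.5).
#' @return the track with low-confidence coordinates interpolated or NA.
#' @export
clean_track <- function(track, confidence_min = 0.6, max_gap_s = 0.5) {
  max_gap <- round(max_gap_s * track$frame_rate_hz)
  n <- n_frames(track)
  for (k in seq_along(track$keypoints)) {
    bad <- is.na(track$confidence[, k]) | track$confidence[, k] < confidence_min
    if (!any(bad)) next
    track$x_cm[bad, k] <- NA_real_
    track$y_cm[bad, k] <- NA_real_
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    fill <- rep(FALSE, n)
    for (j in which(runs$values)) {
      interior <- starts[j] > 1L && ends[j] < n
      if (runs$lengths[j] <= max_gap && interior) {
        fill[starts[j]:ends[j]] <- TRUE
      }
    }
    if (any(fill)) {
      ok <- !bad
      idx <- seq_len(n)
      track$x_cm[fill, k] <- stats::approx(idx[ok], track$x_cm[ok, k],
                                           xout = idx[fill])$y
      track$y_cm[fill, k] <- stats::approx(idx[ok], track$y_cm[ok, k],
                                           xout = idx[fill])$y
    }
  }
  track
}

#' Read a keypoint tracking table
#'
#' Reads the table dialects produced by markerless pose trackers and returns
#' a validated, centimetre-calibrated [pose_track()]. Two dialects are
#' accepted: the wide CSV with three header rows (scorer / bodyparts /
#' coords, with x, y, likelihood triplets per bodypart), and a flat long CSV
#' with columns `frame, keypoint, x, y, confidence`. Low-confidence frames
#' are interpolated or left missing via [clean_track()].
#'
#' @param path CSV file.
#' @param format `"auto"` (default), `"wide"` or `"long"`.
#' @param frame_rate_hz,px_per_cm acquisition metadata (not stored in the
#'   tracker tables themselves).
#' @param keypoints optional character vector of keypoints that must be
#'   present; a missing one raises a schema error naming it.
#' @param confidence_min,max_gap_s passed to [clean_track()]; set
#'   `confidence_min = 0` to skip interpolation.
#' @return a [pose_track()].
#' @export
read_pose_table <- function(path, format = c("auto", "wide", "long"),
                            frame_rate_hz = 30, px_per_cm = 10,
                            keypoints = NULL, confidence_min = 0.6,
                            max_gap_s = 0.5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^scorer", first)) "wide" else "long"
  }
  if (format == "wide") {
    raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(raw) < 4L) stop("wide pose table needs 3 header rows plus data",
                             call. = FALSE)
    bodyparts <- as.character(unlist(raw[2, -1]))
    coords <- as.character(unlist(raw[3, -1]))
    body <- raw[-(1:3), , drop = FALSE]
    parse_num <- function(col, what) {
      v <- suppressWarnings(as.numeric(body[[col]]))
      bad <- which(is.na(v) & !(body[[col]] %in% c("NA", "")))
      if (length(bad)) {
        stop(sprintf("non-numeric value in %s at data row %d: '%s'",
                     what, bad[1], body[[col]][bad[1]]), call. = FALSE)
      }
      v
    }
    kps <- unique(bodyparts)
    n <- nrow(body)
    x <- y <- cf <- matrix(NA_real_, n, length(kps), dimnames = list(NULL, kps))
    for (j in seq_along(bodyparts)) {
      col <- j + 1L
      val <- parse_num(col, sprintf("%s/%s", bodyparts[j], coords[j]))
      if (coords[j] == "x") x[, bodyparts[j]] <- val
      else if (coords[j] == "y") y[, bodyparts[j]] <- val
      else cf[, bodyparts[j]] <- val
    }
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("frame", "keypoint", "x", "y", "confidence")
    if (!all(need %in% names(tab))) {
      stop("long pose table must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    for (cn in c("frame", "x", "y", "confidence")) {
      v <- suppressWarnings(as.numeric(tab[[cn]]))
      bad <- which(is.na(v) & !is.na(tab[[cn]]) & tab[[cn]] != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric value in column %s at row %d", cn, bad[1]),
             call. = FALSE)
      }
      tab[[cn]] <- v
    }
    kps <- unique(tab$keypoint)
    frames <- sort(unique(tab$frame))
    n <- length(frames)
    x <- y <- cf <- matrix(NA_real_, n, length(kps), dimnames = list(NULL, kps))
    fi <- match(tab$frame, frames)
    ki <- match(tab$keypoint, kps)
    x[cbind(fi, ki)] <- tab$x
    y[cbind(fi, ki)] <- tab$y
    cf[cbind(fi, ki)] <- tab$confidence
  }
  if (!is.null(keypoints)) {
    absent <- setdiff(keypoints, kps)
    if (length(absent)) {
      stop("pose table is missing declared keypoint(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  track <- pose_track(x / px_per_cm, y / px_per_cm, cf,
                      frame_rate_hz = frame_rate_hz, px_per_cm = px_per_cm,
                      keypoints = kps)
  if (confidence_min > 0) {
    track <- clean_track(track, confidence_min, max_gap_s)
  }
  track
}

#' Write a pose track in the wide tracker dialect
#'
#' Inverse of [read_pose_table()]: coordinates are converted back to pixels
#' with the track's `px_per_cm`. Round-tripping reproduces the track to
#' floating precision.
#'
#' @param track a [pose_track()].
#' @param path output CSV path.
#' @export
write_pose_table <- function(track, path) {
  kps <- track$keypoints
  n <- n_frames(track)
  cols <- list(frame = format(seq_len(n) - 1L))
  header2 <- "bodyparts"; header3 <- "coords"
  for (k in seq_along(kps)) {
    cols[[paste0(kps[k], "_x")]] <- format(track$x_cm[, k] * track$px_per_cm,
                                           digits = 15, trim = TRUE)
    cols[[paste0(kps[k], "_y")]] <- format(track$y_cm[, k] * track$px_per_cm,
                                           digits = 15, trim = TRUE)
    cols[[paste0(kps[k], "_l")]] <- format(track$confidence[, k],
                                           digits = 15, trim = TRUE)
    header2 <- c(header2, rep(kps[k], 3))
    header3 <- c(header3, "x", "y", "likelihood")
  }
  lines <- c(
    paste(c("scorer", rep("behavephen", 3 * length(kps))), collapse = ","),
    paste(header2, collapse = ","),
    paste(header3, collapse = ","),
    do.call(paste, c(cols, sep = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct a behaviour label stream
#'
#' Per-frame behaviour class labels, as emitted by an unsupervised behaviour
#' classifier and collapsed to the four analysis classes: locomotion/turning
#' (combined, since animals alternate between them), sniffing, rearing, and
#' everything else.
#'
#' @param labels character or factor vector of per-frame labels.
#' @param frame_rate_hz frames per second (> 0).
#' @return an object of class `label_stream` (a factor with attributes).
#' @export
label_stream <- function(labels, frame_rate_hz = 30) {
  stopifnot_scalar_pos(frame_rate_hz, "frame_rate_hz")
  lab <- as.character(labels)
  bad <- setdiff(unique(lab), .behaviour_levels)
  if (length(bad)) {
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(.behaviour_levels, collapse = ", "),
         call. = FALSE)
  }
  structure(factor(lab, levels = .behaviour_levels),
            frame_rate_hz = frame_rate_hz, class = c("label_stream", "factor"))
}

#' @export
print.label_stream <- function(x, ...) {
  cat(sprintf("<label_stream> %d frames @ %g Hz\n", length(x),
              attr(x, "frame_rate_hz")))
  print(round(100 * prop.table(table(unclass_labels(x))), 1))
  invisible(x)
}

# strip class for safe factor ops
unclass_labels <- function(x) factor(as.character(x), levels = .behaviour_levels)

#' Read / write a label stream CSV (`frame,label`)
#'
#' @param path CSV file with columns `frame` and `label`.
#' @param frame_rate_hz frames per second.
#' @return [read_label_stream()] returns a [label_stream()].
#' @export
read_label_stream <- function(path, frame_rate_hz = 30) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("frame", "label") %in% names(tab))) {
    stop("label stream CSV must have columns frame,label", call. = FALSE)
  }
  label_stream(tab$label[order(tab$frame)], frame_rate_hz)
}

#' @rdname read_label_stream
#' @param labels a [label_stream()].
#' @export
write_label_stream <- function(labels, path) {
  utils::write.csv(data.frame(frame = seq_along(labels) - 1L,
                              label = as.character(labels)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Open-field arena geometry
#'
#' Square arena geometry used for centre-zone and wall-margin computations.
#' The centre zone is the centred square whose side is
#' `center_fraction * arena_side_cm` (50% linear extent by default, i.e. 25%
#' of the area).
#'
#' @param arena_side_cm side of the square arena (default 38 cm).
#' @param center_fraction linear fraction of the side defining the centre
#'   zone, in (0, 1).
#' @param wall_margin_cm distance from a wall within which rearing is scored
#'   as wall-supported (default 2 cm); must be less than half the side.
#' @return an object of class `arena_config`.
#' @export
arena_config <- function(arena_side_cm = 38, center_fraction = 0.5,
                         wall_margin_cm = 2) {
  stopifnot_scalar_pos(arena_side_cm, "arena_side_cm")
  if (center_fraction <= 0 || center_fraction >= 1) {
    stop("center_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (wall_margin_cm < 0 || wall_margin_cm >= arena_side_cm / 2) {
    stop("wall_margin_cm must be non-negative and < arena_side_cm / 2",
         call. = FALSE)
  }
  structure(list(arena_side_cm = arena_side_cm,
                 center_fraction = center_fraction,
                 wall_margin_cm = wall_margin_cm),
            class = "arena_config")
}

#' Water T-maze geometry and regions of interest
#'
#' The maze is a cross of four water-filled arms (North/South long, East/West
#' short) joined at a junction square of side equal to the arm width; the
#' junction is the "decision point" where the animal must commit to an arm.
#' Coordinates place the origin at the top-left of the maze bounding box with
#' y increasing downward (image convention); North is the top arm.
#'
#' ROIs are axis-aligned rectangles `c(xmin, xmax, ymin, ymax)`:
#' `north_arm`, `south_arm`, `east_arm`, `west_arm`, `decision_point`, and
#' platform zones `platform_E` / `platform_W` (the distal
#' `platform_zone_cm` of each choice arm).
#'
#' @param ns_arm_cm length of the North and South arms (default 37 cm).
#' @param ew_arm_cm length of the East and West arms (default 21 cm).
#' @param arm_width_cm arm width (default 10 cm).
#' @param platform_zone_cm depth of the platform zone at the distal end of a
#'   choice arm (default 10 cm).
#' @return an object of class `maze_config` with an `roi` list.
#' @export
maze_config <- function(ns_arm_cm = 37, ew_arm_cm = 21, arm_width_cm = 10,
                        platform_zone_cm = 10) {
  stopifnot_scalar_pos(ns_arm_cm, "ns_arm_cm")
  stopifnot_scalar_pos(ew_arm_cm, "ew_arm_cm")
  stopifnot_scalar_pos(arm_width_cm, "arm_width_cm")
  if (platform_zone_cm <= 0 || platform_zone_cm > ew_arm_cm) {
    stop("platform_zone_cm must lie in (0, ew_arm_cm]", call. = FALSE)
  }
  w <- arm_width_cm
  x0 <- ew_arm_cm            # junction xmin
  y0 <- ns_arm_cm            # junction ymin
  roi <- list(
    north_arm = c(x0, x0 + w, 0, y0),
    south_arm = c(x0, x0 + w, y0 + w, y0 + w + ns_arm_cm),
    west_arm = c(0, x0, y0, y0 + w),
    east_arm = c(x0 + w, x0 + w + ew_arm_cm, y0, y0 + w),
    decision_point = c(x0, x0 + w, y0, y0 + w),
    platform_W = c(0, platform_zone_cm, y0, y0 + w),
    platform_E = c(x0 + w + ew_arm_cm - platform_zone_cm,
                   x0 + w + ew_arm_cm, y0, y0 + w)
  )
  structure(list(ns_arm_cm = ns_arm_cm, ew_arm_cm = ew_arm_cm,
                 arm_width_cm = arm_width_cm,
                 platform_zone_cm = platform_zone_cm, roi = roi),
            class = "maze_config")
}

#' Read an arena or maze configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [arena_config()]
#'   or [maze_config()].
#' @return the corresponding config object.
#' @export
read_arena_config <- function(path) {
  do.call(arena_config, yaml::read_yaml(path))
}

#' @rdname read_arena_config
#' @export
read_maze_config <- function(path) {
  do.call(maze_config, yaml::read_yaml(path))
}
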