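# Shared fixtures and independent brute-force oracles.

# a minimal pose track from coordinate vectors (cm)
make_track <- function(x, y, fps = 30, keypoint = "tail_base",
                       confidence = NULL) {
  n <- length(x)
  conf <- confidence %||% rep(1, n)
  pose_track(matrix(x, ncol = 1), matrix(y, ncol = 1),
             matrix(conf, ncol = 1), frame_rate_hz = fps,
             keypoints = keypoint)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_cohort <- function(seed = 1, n = 2) {
  gen_cohort(c(mutant = n, wildtype = n), seed = seed)
}

# --- brute-force oracles (kept independent of the package internals) --------

# bout segmentation by frame-wise scanning: mark label frames, bridge gaps
# <= gap_tol frames, then collect runs >= min_frames
oracle_bouts <- function(lab, label, min_frames, gap_tol) {
  hit <- lab == label
  n <- length(hit)
  if (gap_tol > 0 && any(hit)) {
    bridged <- hit
    idx <- which(hit)
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1)) {
        gap <- idx[k + 1] - idx[k] - 1
        if (gap > 0 && gap <= gap_tol) bridged[idx[k]:idx[k + 1]] <- TRUE
      }
    }
    hit <- bridged
  }
  out <- NULL
  i <- 1
  while (i <= n) {
    if (hit[i]) {
      j <- i
      while (j < n && hit[j + 1]) j <- j + 1
      if (j - i + 1 >= min_frames) out <- rbind(out, c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# slip counting by a frame-wise threshold scan with explicit state
oracle_slips <- function(paw_y, rod_bottom, min_depth, merge_frames) {
  lo <- pmin(paw_y[, 1], paw_y[, 2])
  events <- NULL
  open <- FALSE; start <- NA
  for (i in seq_along(lo)) {
    if (!open && lo[i] < rod_bottom - min_depth) { open <- TRUE; start <- i }
    if (open && lo[i] > rod_bottom) {
      events <- rbind(events, c(start, i - 1)); open <- FALSE
    }
  }
  if (open) events <- rbind(events, c(start, length(lo)))
  if (is.null(events) || nrow(events) < 2) {
    return(if (is.null(events)) 0 else nrow(events))
  }
  merged <- events[1, , drop = FALSE]
  for (i in 2:nrow(events)) {
    if (events[i, 1] - merged[nrow(merged), 2] - 1 < merge_frames) {
      merged[nrow(merged), 2] <- events[i, 2]
    } else merged <- rbind(merged, events[i, ])
  }
  nrow(merged)
}

# rotarod endpoint by explicit event walk
oracle_endpoint <- function(kinds, times, protocol, max_s = 300) {
  if (protocol == "standard") {
    for (i in seq_along(kinds)) {
      if (kinds[i] %in% c("rotation", "fall")) return(times[i])
    }
    return(max_s)
  }
  run <- 0
  for (i in seq_along(kinds)) {
    if (kinds[i] == "fall") return(times[i])
    if (kinds[i] == "rotation") {
      run <- run + 1
      if (run == 3) return(times[i])
    }
    if (kinds[i] == "recovery") run <- 0
  }
  max_s
}

# random valid rotarod event sequence (fall, if any, terminates)
random_events <- function() {
  n <- sample(0:6, 1)
  kinds <- if (n > 0) sample(c("rotation", "recovery"), n, replace = TRUE)
           else character(0)
  if (stats::runif(1) < 0.7) kinds <- c(kinds, "fall")
  k <- length(kinds)
  if (k == 0) {
    return(data.frame(time_s = numeric(0), kind = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(time_s = sort(stats::runif(k, 1, 299)), kind = kinds,
             stringsAsFactors = FALSE)
}
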