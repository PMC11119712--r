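# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed
#'
#' Hashes a master seed together with an arbitrary key (e.g. animal id, task
#' name, trial index) into a 31-bit integer seed. Child seeds make generated
#' data for one animal/trial independent of the order in which other data are
#' generated.
#'
#' @param master integer master seed.
#' @param ... key components; coerced to character and concatenated.
#' @return an integer in `[0, 2^31 - 2]`.
#' @examples
#' child_seed(1, "m001", "open_field")
#' @export
child_seed <- function(master, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "\x1f")
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Centered boxcar smoothing with edge replication; width in frames (>= 1).
smooth_boxcar <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L || length(x) < 2L) return(x)
  half <- width %/% 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / (2 * half + 1), 2 * half + 1),
                           sides = 2))[(half + 1):(half + length(x))]
}

# rect = c(xmin, xmax, ymin, ymax); boundaries inclusive.
in_rect <- function(x, y, rect) {
  x >= rect[1] & x <= rect[2] & y >= rect[3] & y <= rect[4]
}

# Fold an unbounded coordinate into [0, L] by reflection (triangle wave).
reflect_fold <- function(z, L) {
  m <- z %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single finite positive number", name),
         call. = FALSE)
  }
  invisible(x)
}
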