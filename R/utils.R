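#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed` and
#' restores the previous state afterwards, so seeded helpers do not disturb
#' the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# per-stage seed derivation: global seed plus a fixed per-stage counter,
# kept below 2^31 so it is a valid R integer seed
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 101L + counter) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# do two polylines (closed) intersect / does one self-intersect?
# segments given as x0,y0 -> x1,y1 row-wise
segments_cross <- function(ax0, ay0, ax1, ay1, bx0, by0, bx1, by1) {
  d1 <- (bx1 - bx0) * (ay0 - by0) - (by1 - by0) * (ax0 - bx0)
  d2 <- (bx1 - bx0) * (ay1 - by0) - (by1 - by0) * (ax1 - bx0)
  d3 <- (ax1 - ax0) * (by0 - ay0) - (ay1 - ay0) * (bx0 - ax0)
  d4 <- (ax1 - ax0) * (by1 - ay0) - (ay1 - ay0) * (bx1 - ax0)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Test whether a closed polygon is simple
#'
#' Checks that no two non-adjacent edges of the closed polygon through the
#' given points (in order) intersect.
#'
#' @param pts Numeric matrix (n x 2) of vertices in order.
#' @return Logical scalar.
#' @keywords internal
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  x0 <- pts[, 1]; y0 <- pts[, 2]
  x1 <- pts[nxt, 1]; y1 <- pts[nxt, 2]
  for (i in seq_len(n - 2)) {
    # segments strictly after i, skipping the two adjacent ones
    j <- setdiff((i + 2):n, if (i == 1) n else integer(0))
    if (!length(j)) next
    if (any(segments_cross(x0[i], y0[i], x1[i], y1[i],
                           x0[j], y0[j], x1[j], y1[j]))) return(FALSE)
  }
  TRUE
}

signed_polygon_area <- function(pts) {
  n <- nrow(pts)
  nxt <- c(2:n, 1)
  sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2]) / 2
}
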