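# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected. A `NULL`
#' seed leaves the ambient stream untouched, which lets composite
#' generators drive their sub-steps from one seeded stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Coerce points to a data.frame with integer x (column) and y (row),
# 0-based. Accepts a data.frame with x/y columns or a 2-column matrix.
as_points <- function(points) {
  if (is.matrix(points)) {
    points <- data.frame(x = points[, 1L], y = points[, 2L])
  }
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    stopf("points must be a data.frame with columns x and y (or a 2-column matrix)")
  }
  data.frame(x = as.integer(points$x), y = as.integer(points$y))
}

check_points_in_bounds <- function(points, shape, what = "point") {
  h <- shape[1L]; w <- shape[2L]
  bad <- which(points$x < 0L | points$x >= w | points$y < 0L | points$y >= h)
  if (length(bad) > 0L) {
    stopf("%s %d out of bounds: (x=%d, y=%d) for a %dx%d (width x height) image",
          what, bad[1L], points$x[bad[1L]], points$y[bad[1L]], w, h)
  }
  invisible(points)
}

# Linear (column-major) index into a (height x width) grid for 0-based
# (x, y): grid[y + 1, x + 1] == grid_vec[x * h + y + 1].
points_to_index <- function(points, shape) {
  points$x * shape[1L] + points$y + 1L
}

index_to_points <- function(idx, shape) {
  h <- shape[1L]
  data.frame(x = as.integer((idx - 1L) %/% h), y = as.integer((idx - 1L) %% h))
}

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

rescale01 <- function(grid) {
  lo <- min(grid); hi <- max(grid)
  if (hi > lo) (grid - lo) / (hi - lo) else grid - lo
}
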