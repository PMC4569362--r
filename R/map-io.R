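#' Saliency maps and map ensembles
#'
#' A `saliency_map` is a real-valued 2-D grid aligned to an image: the
#' output of a saliency algorithm, a predicted judgment map, or any
#' other topographic score. The grid is a `(height x width)` matrix
#' indexed `(row, col)`; the 0-based point coordinates used throughout
#' the package map to it as `grid[y + 1, x + 1]`.
#'
#' A `map_ensemble` collects one same-shape map per image for a single
#' algorithm; dataset-level statistics (spatial bias, per-pixel rank or
#' whitening normalization) operate on ensembles.
#'
#' @param grid Numeric matrix of finite values.
#' @param image_id Identifier of the image the map scores.
#' @param algorithm_id Identifier of the producing algorithm.
#' @return A `saliency_map`.
#' @export
saliency_map <- function(grid, image_id, algorithm_id = "") {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stopf("grid must be a numeric matrix")
  }
  if (!all(is.finite(grid))) stopf("map '%s': grid has non-finite values", image_id)
  structure(list(grid = grid, image_id = as.character(image_id),
                 algorithm_id = as.character(algorithm_id)),
            class = "saliency_map")
}

#' @rdname saliency_map
#' @param maps List of `saliency_map`, all sharing one grid shape.
#' @export
map_ensemble <- function(maps, algorithm_id = "") {
  if (length(maps) < 2L) stopf("a map ensemble needs at least 2 maps")
  shapes <- vapply(maps, function(m) dim(m$grid), integer(2L))
  if (any(shapes[1L, ] != shapes[1L, 1L]) ||
      any(shapes[2L, ] != shapes[2L, 1L])) {
    stopf("all maps in an ensemble must share one shape")
  }
  names(maps) <- vapply(maps, function(m) m$image_id, character(1L))
  if (anyDuplicated(names(maps))) stopf("duplicate image_id in ensemble")
  structure(list(algorithm_id = as.character(algorithm_id), maps = maps,
                 shape = shapes[, 1L]),
            class = "map_ensemble")
}

ensemble_map <- function(ensemble, image_id) {
  m <- ensemble$maps[[image_id]]
  if (is.null(m)) {
    stopf("algorithm '%s' has no map for image '%s'",
          ensemble$algorithm_id, image_id)
  }
  m
}

#' Extract the numeric grid from a map-like object
#'
#' @param x A `saliency_map`, `density_map`, `bias_profile`, or plain
#'   matrix.
#' @return The `(height x width)` numeric matrix.
#' @export
as_grid <- function(x) UseMethod("as_grid")

#' @export
as_grid.saliency_map <- function(x) x$grid

#' @export
as_grid.density_map <- function(x) x$grid

#' @export
as_grid.bias_profile <- function(x) x$grid

#' @export
as_grid.matrix <- function(x) x

#' @export
as_grid.default <- function(x) {
  stopf("cannot interpret object of class '%s' as a map grid",
        paste(class(x), collapse = "/"))
}

#' Read a grayscale PNG saliency map
#'
#' Values are scaled to `[0, 1]` by the image bit depth (8- or 16-bit),
#' so downstream arithmetic always sees reals.
#'
#' @param path PNG file path.
#' @param image_id,algorithm_id Identifiers attached to the map.
#' @return A [saliency_map()].
#' @export
read_map <- function(path, image_id, algorithm_id = "") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    stopf("'%s' is a %d-channel image; maps must be single-channel grayscale",
          path, dim(img)[3L])
  }
  saliency_map(img, image_id = image_id, algorithm_id = algorithm_id)
}

#' Write a map as a grayscale PNG
#'
#' @param map A [saliency_map()] (or grid coercible via [as_grid()])
#'   with values in `[0, 1]`; callers rescale first.
#' @param path Output path.
#' @param depth Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, depth = 16L) {
  grid <- as_grid(map)
  if (min(grid) < 0 || max(grid) > 1) {
    stopf("map values must lie in [0, 1] before writing (range %.4g..%.4g)",
          min(grid), max(grid))
  }
  depth <- as.integer(depth)
  if (depth == 8L) {
    png::writePNG(grid, path)
  } else if (depth == 16L) {
    write_png_gray16(grid, path)
  } else {
    stopf("depth must be 8 or 16")
  }
  invisible(path)
}

#' Read a binary object mask
#'
#' Any strictly positive pixel counts as foreground.
#'
#' @param path Grayscale PNG path.
#' @return A logical `(height x width)` matrix.
#' @export
read_mask <- function(path) {
  m <- read_map(path, image_id = path)
  m$grid > 0
}
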