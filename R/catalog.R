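#' Image catalog
#'
#' A catalog records the pixel dimensions of every stimulus image so that
#' point tables can be validated against them without touching image
#' files. On disk it is a JSON object mapping `image_id` to
#' `[width, height]`.
#'
#' @param image_id Character vector of unique image identifiers.
#' @param width,height Integer pixel dimensions, each >= 1.
#' @return An `image_catalog`, a data.frame with columns `image_id`,
#'   `width`, `height`.
#' @examples
#' cat <- image_catalog(c("img1", "img2"), width = 64, height = 48)
#' catalog_shape(cat, "img1")
#' @export
image_catalog <- function(image_id, width, height) {
  image_id <- as.character(image_id)
  width <- as.integer(width)
  height <- as.integer(height)
  n <- length(image_id)
  width <- rep_len(width, n)
  height <- rep_len(height, n)
  if (anyDuplicated(image_id)) stopf("duplicate image_id in catalog")
  if (any(width < 1L) || any(height < 1L)) {
    stopf("catalog width and height must be >= 1")
  }
  structure(
    data.frame(image_id = image_id, width = width, height = height,
               stringsAsFactors = FALSE),
    class = c("image_catalog", "data.frame")
  )
}

#' @describeIn image_catalog Grid shape `c(height, width)` for one image.
#' @param catalog An `image_catalog`.
#' @export
catalog_shape <- function(catalog, image_id) {
  i <- match(image_id, catalog$image_id)
  if (is.na(i)) stopf("image_id '%s' not in catalog", image_id)
  c(catalog$height[i], catalog$width[i])
}

#' Read and write image catalogs as JSON
#'
#' @param path File path of the JSON catalog.
#' @return `read_catalog()` returns an [image_catalog()];
#'   `write_catalog()` returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(obj) == 0L) stopf("catalog '%s' is empty", path)
  dims <- do.call(rbind, obj)
  image_catalog(names(obj), width = dims[, 1L], height = dims[, 2L])
}

#' @rdname read_catalog
#' @param catalog An `image_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  obj <- lapply(seq_len(nrow(catalog)), function(i) {
    c(catalog$width[i], catalog$height[i])
  })
  names(obj) <- catalog$image_id
  jsonlite::write_json(obj, path)
  invisible(path)
}
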