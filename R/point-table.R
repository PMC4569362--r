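#' @name point_table
#' @title Selection-point tables
#'
#' @description
#' A point table holds one row per selection event: an eye-tracking
#' fixation or an explicit "most salient location" judgment. Columns are
#' `image_id`, `observer_id`, `task`, `x`, `y`, `ordinal`. Coordinates
#' are 0-based pixels with `x` the column and `y` the row; `ordinal`
#' numbers an observer's selections on an image within a task, starting
#' at 0. Tasks are restricted to the four conditions of a
#' fixation-plus-judgment study: `free_view`, `object_search`,
#' `saliency_view` (gaze tasks) and `explicit_judgment` (manual
#' selection).
#'
#' On disk a point table is a UTF-8 CSV with a header naming the six
#' columns.
NULL

#' Task vocabulary
#'
#' The four selection tasks a point table may contain.
#' @export
POINT_TASKS <- c("free_view", "object_search", "saliency_view",
                 "explicit_judgment")

#' Construct and validate a point table
#'
#' @param df A data.frame with columns `image_id`, `observer_id`,
#'   `task`, `x`, `y`, `ordinal`.
#' @param catalog Optional [image_catalog()]; when supplied every
#'   coordinate is checked against the referenced image's dimensions.
#' @return The validated table with class `point_table`.
#' @export
point_table <- function(df, catalog = NULL) {
  required <- c("image_id", "observer_id", "task", "x", "y", "ordinal")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stopf("point table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  df$image_id <- as.character(df$image_id)
  df$observer_id <- as.character(df$observer_id)
  df$task <- as.character(df$task)
  df$x <- as.integer(df$x)
  df$y <- as.integer(df$y)
  df$ordinal <- as.integer(df$ordinal)

  bad_task <- which(!df$task %in% POINT_TASKS)
  if (length(bad_task) > 0L) {
    stopf("row %d: unknown task '%s' (expected one of %s)",
          bad_task[1L], df$task[bad_task[1L]],
          paste(POINT_TASKS, collapse = ", "))
  }
  if (any(df$ordinal < 0L)) {
    stopf("row %d: ordinal must be >= 0", which(df$ordinal < 0L)[1L])
  }
  key <- paste(df$image_id, df$observer_id, df$task, df$ordinal, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("row %d: duplicate (image_id, observer_id, task, ordinal) key",
          which(duplicated(key))[1L])
  }
  if (!is.null(catalog)) {
    for (img in unique(df$image_id)) {
      rows <- df$image_id == img
      shape <- catalog_shape(catalog, img)
      sub <- df[rows, c("x", "y")]
      bad <- which(sub$x < 0L | sub$x >= shape[2L] |
                   sub$y < 0L | sub$y >= shape[1L])
      if (length(bad) > 0L) {
        r <- which(rows)[bad[1L]]
        stopf("row %d: point (x=%d, y=%d) outside %dx%d image '%s'",
              r, df$x[r], df$y[r], shape[2L], shape[1L], img)
      }
    }
  }
  class(df) <- c("point_table", "data.frame")
  df
}

#' Read a point-table CSV
#'
#' @param path CSV file with header
#'   `image_id,observer_id,task,x,y,ordinal`.
#' @inheritParams point_table
#' @return A validated [point_table()].
#' @export
read_point_table <- function(path, catalog = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  point_table(df, catalog = catalog)
}

#' Write a point table as CSV
#'
#' @param table A [point_table()] (or validatable data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_point_table <- function(table, path) {
  table <- point_table(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Rows of `table` for one (image, task); task = NULL keeps all tasks.
filter_points <- function(table, image_id, task = NULL) {
  keep <- table$image_id == image_id
  if (!is.null(task)) keep <- keep & table$task == task
  table[keep, , drop = FALSE]
}
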