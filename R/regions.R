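#' Panel region records
#'
#' Panel regions are rows of a data frame with 0-based half-open pixel
#' coordinates in the original image frame: `row_start`, `row_end`,
#' `col_start`, `col_end`, plus `depth` (recursion level that produced the
#' region) and `branch` (`"regular"` or `"irregular"`).
#'
#' @param row_start,row_end,col_start,col_end Integer vectors (recycled),
#'   0-based, half-open.
#' @param depth Recursion level (default 0).
#' @param branch Producing pipeline branch.
#' @return A `data.frame` of panel regions.
#' @export
panel_regions <- function(row_start = integer(0), row_end = integer(0),
                          col_start = integer(0), col_end = integer(0),
                          depth = 0L, branch = "regular") {
  k <- length(row_start)
  depth <- rep_len(as.integer(depth), k)
  branch <- rep_len(as.character(branch), k)
  df <- data.frame(row_start = as.integer(row_start),
                   row_end = as.integer(row_end),
                   col_start = as.integer(col_start),
                   col_end = as.integer(col_end),
                   depth = as.integer(depth),
                   branch = as.character(branch),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0)
    stopifnot(all(df$row_start >= 0), all(df$col_start >= 0),
              all(df$row_end > df$row_start), all(df$col_end > df$col_start))
  df
}

#' Crop a panel region out of an image
#'
#' @param image Grayscale matrix or RGB array.
#' @param region A single-row panel-region data frame (0-based half-open).
#' @return The sub-image.
#' @export
crop_region <- function(image, region) {
  check_image(image)
  stopifnot(nrow(region) == 1)
  rows <- (region$row_start + 1L):region$row_end
  cols <- (region$col_start + 1L):region$col_end
  if (is_gray(image)) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}

region_area <- function(region) {
  (region$row_end - region$row_start) * (region$col_end - region$col_start)
}

#' Segmentation result
#'
#' @param regions Panel-region data frame (original-frame coordinates).
#' @param crops List of sub-images, parallel to `regions`.
#' @param source_class The `panel_class` that routed the image, or NULL.
#' @param flags Character vector of warnings raised during segmentation
#'   (e.g. `"empty-result"` when no component survived the area filter).
#' @return Object of class `panel_segmentation`.
#' @keywords internal
new_segmentation <- function(regions, crops, source_class = NULL,
                             flags = character(0)) {
  structure(list(regions = regions, crops = crops,
                 source_class = source_class, flags = flags),
            class = "panel_segmentation")
}

#' @export
print.panel_segmentation <- function(x, ...) {
  br <- unique(x$regions$branch)
  cat(sprintf("panelseg segmentation: %d region(s)%s\n", nrow(x$regions),
              if (length(br)) paste0(" [", paste(br, collapse = ","), "]")
              else ""))
  if (nrow(x$regions) > 0)
    print(x$regions[, c("row_start", "row_end", "col_start", "col_end",
                        "depth")])
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
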