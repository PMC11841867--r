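#' @title Pixel-level primitives
#' @description Images are plain R objects: a grayscale image is a numeric
#'   `M x N` matrix of 8-bit intensities in `[0, 255]` (rows = image rows),
#'   a color image an `M x N x 3` array of R, G, B channels on the same
#'   scale. All public coordinates are 0-based; crops use half-open
#'   intervals, separator runs inclusive `(start, end)` pairs.
#' @name core-primitives
NULL

is_gray <- function(image) is.matrix(image)
is_rgb <- function(image) is.array(image) && length(dim(image)) == 3 &&
  dim(image)[3] == 3

check_image <- function(image) {
  if (!is_gray(image) && !is_rgb(image))
    stop("unsupported image format: expected an M x N matrix (grayscale) ",
         "or an M x N x 3 array (RGB)")
  if (any(dim(image)[1:2] < 1L)) stop("degenerate image: empty dimensions")
  invisible(image)
}

#' Convert an image to grayscale
#'
#' Applies the luminance weighting
#' `0.2989 * R + 0.5870 * G + 0.1140 * B`, rounding half-up to the nearest
#' integer and clamping to `[0, 255]`. Grayscale input passes through
#' unchanged, so the conversion is idempotent.
#'
#' @param image Grayscale matrix or RGB array (8-bit scale).
#' @return A grayscale matrix of the same height and width.
#' @examples
#' rgb <- array(0, c(2, 2, 3)); rgb[, , 1] <- 255 # pure red
#' to_grayscale(rgb)[1, 1] # 76
#' @export
to_grayscale <- function(image) {
  check_image(image)
  if (is_gray(image)) return(image)
  g <- 0.2989 * image[, , 1] + 0.5870 * image[, , 2] + 0.1140 * image[, , 3]
  g <- matrix(g, dim(image)[1], dim(image)[2]) # keep shape at size 1
  # round half-up, then clamp to the 8-bit range
  g <- floor(g + 0.5)
  g[g < 0] <- 0
  g[g > 255] <- 255
  g
}

#' Trim a symmetric border
#'
#' Removes `margin` rows/columns from every outer edge, returning the
#' `(M - 2 margin) x (N - 2 margin)` interior. Used before profile analysis
#' so the figure's own frame does not register as a separator.
#'
#' @param image Grayscale matrix or RGB array.
#' @param margin Non-negative pixel count; `2 * margin` must be smaller
#'   than both image dimensions.
#' @return The cropped image.
#' @export
trim_border <- function(image, margin) {
  check_image(image)
  margin <- as.integer(margin)
  stopifnot(margin >= 0L)
  d <- dim(image)
  if (2L * margin >= min(d[1], d[2]))
    stop("degenerate crop: margin ", margin, " too large for a ",
         d[1], " x ", d[2], " image")
  if (margin == 0L) return(image)
  rows <- (margin + 1L):(d[1] - margin)
  cols <- (margin + 1L):(d[2] - margin)
  if (is_gray(image)) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}

#' Projection profile of a grayscale image
#'
#' Sums pixel intensities along rows (`axis = "horizontal"`, one value per
#' row) or columns (`axis = "vertical"`, one value per column). With
#' `normalize = TRUE` each sum is divided by the orthogonal dimension,
#' giving the mean intensity of the row/column on the 0-255 scale, which
#' makes the separator threshold independent of image size.
#'
#' @param image Grayscale matrix.
#' @param axis `"horizontal"` (per-row) or `"vertical"` (per-column).
#' @param normalize Divide sums by the orthogonal dimension (default TRUE).
#' @return An object of class `projection_profile`: a list with `values`,
#'   `axis`, `normalized`.
#' @examples
#' m <- matrix(c(1, 3, 2, 4), 2, 2) # rows (1,2) and (3,4)
#' projection_profile(m, "horizontal", normalize = FALSE)$values # 3 7
#' @export
projection_profile <- function(image, axis = c("horizontal", "vertical"),
                               normalize = TRUE) {
  axis <- match.arg(axis)
  if (!is_gray(image)) stop("projection profiles require a grayscale image")
  if (length(image) == 0) stop("empty image")
  values <- if (axis == "horizontal") rowSums(image) else colSums(image)
  if (normalize) {
    denom <- if (axis == "horizontal") ncol(image) else nrow(image)
    values <- values / denom
  }
  structure(list(values = unname(values), axis = axis,
                 normalized = normalize),
            class = "projection_profile")
}

#' Group sorted indices into maximal contiguous runs
#'
#' @param indices Strictly increasing integer vector (0-based).
#' @return Integer matrix with columns `start`, `end` (inclusive), one row
#'   per run; zero rows when `indices` is empty.
#' @export
group_runs <- function(indices) {
  indices <- as.integer(indices)
  if (length(indices) == 0)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  stopifnot(all(diff(indices) > 0))
  brk <- which(diff(indices) > 1L)
  starts <- indices[c(1L, brk + 1L)]
  ends <- indices[c(brk, length(indices))]
  cbind(start = starts, end = ends)
}

#' Separator index set from a normalized projection profile
#'
#' Selects all positions whose mean intensity strictly exceeds
#' `T = intensity_fraction * 255` — the candidate separator rows/columns —
#' and groups them into contiguous runs.
#'
#' @param profile A normalized [projection_profile()].
#' @param config A [panelseg_config()] supplying `intensity_fraction`.
#' @return An object of class `separator_index_set`: list with 0-based
#'   `indices`, a `runs` matrix (inclusive start/end), and `axis`.
#' @export
high_intensity_indices <- function(profile, config = panelseg_config()) {
  stopifnot(inherits(profile, "projection_profile"))
  if (!profile$normalized)
    stop("high-intensity selection operates on normalized profiles")
  tt <- config$intensity_fraction * 255
  idx <- which(profile$values > tt) - 1L # to 0-based
  separator_index_set(idx, profile$axis)
}

#' Construct a separator index set directly from indices
#'
#' Useful for injecting published index vectors into the classifier.
#'
#' @param indices Sorted 0-based positions of high-intensity rows/columns.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return A `separator_index_set`.
#' @export
separator_index_set <- function(indices,
                                axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  indices <- as.integer(indices)
  stopifnot(all(indices >= 0L), !is.unsorted(indices, strictly = TRUE))
  structure(list(indices = indices, runs = group_runs(indices), axis = axis),
            class = "separator_index_set")
}

#' @export
print.separator_index_set <- function(x, ...) {
  cat(sprintf("separator_index_set (%s): %d indices in %d runs\n",
              x$axis, length(x$indices), nrow(x$runs)))
  if (nrow(x$runs) > 0) {
    lab <- apply(x$runs, 1, function(r)
      if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "-", r[2]))
    cat("  runs:", paste(lab, collapse = ", "), "\n")
  }
  invisible(x)
}
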