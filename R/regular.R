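#' Choose the first cut axis for regular segmentation
#'
#' Horizontal segmentation (cutting rows) is taken first when the
#' horizontal separator set has strictly more indices than the vertical
#' one; otherwise (including ties) vertical segmentation is chosen.
#'
#' @param hlv,vlv [separator_index_set()]s.
#' @return `"horizontal"` or `"vertical"`; signals a classed error
#'   (`panelseg_no_separator`) when both sets are empty.
#' @export
choose_direction <- function(hlv, vlv) {
  nh <- count_separators(hlv)
  nv <- count_separators(vlv)
  if (nh == 0 && nv == 0)
    stop(structure(class = c("panelseg_no_separator", "error", "condition"),
                   list(message = "no separators on either axis",
                        call = sys.call())))
  if (nh > nv) "horizontal" else "vertical"
}

#' Cut an image into segments at separator runs along one axis
#'
#' Segment *k* spans from the end of run *k - 1* (exclusive) to the start
#' of run *k* (exclusive); a final segment after the last run reaches the
#' image edge. The separator bands themselves are discarded. Each segment
#' is then shrunk by `trim` pixels on all four sides (the per-segment
#' boundary trim), and segments with either extent below
#' `config$min_panel_extent` are dropped.
#'
#' @param image Grayscale matrix (only its dimensions are used).
#' @param runs Integer matrix of inclusive `(start, end)` separator runs,
#'   0-based, sorted, within bounds along `axis`.
#' @param axis `"horizontal"` (runs are row ranges) or `"vertical"`.
#' @param config A [panelseg_config()].
#' @param trim Per-segment boundary trim in pixels (default 1).
#' @param depth Recursion depth recorded on the regions.
#' @return Panel-region data frame in the image's own frame.
#' @export
segment_axis <- function(image, runs, axis = c("horizontal", "vertical"),
                         config = panelseg_config(), trim = 1L,
                         depth = 0L) {
  axis <- match.arg(axis)
  trim <- as.integer(trim)
  extent <- if (axis == "horizontal") nrow(image) else ncol(image)
  ortho <- if (axis == "horizontal") ncol(image) else nrow(image)
  # half-open [lo, hi) intervals between consecutive runs
  lo <- c(0L, runs[, "end"] + 1L)
  hi <- c(runs[, "start"], extent)
  keep <- lo < hi
  lo <- lo[keep]; hi <- hi[keep]
  a0 <- lo + trim; a1 <- hi - trim # cut axis
  b0 <- trim; b1 <- ortho - trim   # orthogonal axis
  ok <- (a1 - a0) >= config$min_panel_extent &
    rep((b1 - b0) >= config$min_panel_extent, length(a0))
  a0 <- a0[ok]; a1 <- a1[ok]
  if (axis == "horizontal")
    panel_regions(a0, a1, b0, b1, depth = depth, branch = "regular")
  else
    panel_regions(b0, b1, a0, a1, depth = depth, branch = "regular")
}

#' Segment a regular multi-panel image
#'
#' Recursive projection-profile segmentation: the image is cut at its
#' high-intensity separator runs along the axis chosen by
#' [choose_direction()], then each resulting segment is re-analyzed and
#' cut along whichever axis its own profiles indicate, until no separator
#' remains or `max_recursion_depth` is reached. All regions are reported
#' in original-image coordinates and cropped from the original image.
#'
#' @param image Grayscale matrix or RGB array.
#' @param cls A `panel_class` for the image, or NULL to classify
#'   internally.
#' @param config A [panelseg_config()].
#' @param check_class Error unless `cls$label` is `MULTI_PANEL_REGULAR`
#'   (default TRUE).
#' @return A `panel_segmentation`.
#' @examples
#' spec <- montage_spec("grid", rows = 2, cols = 2, canvas = c(200, 200),
#'                      gutter_px = 8, seed = 1)
#' mont <- generate_montage(spec)
#' seg <- segment_regular(mont$image)
#' nrow(seg$regions) # 4
#' @export
segment_regular <- function(image, cls = NULL, config = panelseg_config(),
                            check_class = TRUE) {
  check_image(image)
  gray <- to_grayscale(image)
  if (is.null(cls)) cls <- classify_image(gray, config)
  if (check_class && cls$label != "MULTI_PANEL_REGULAR")
    stop("wrong branch: segment_regular expects a MULTI_PANEL_REGULAR ",
         "image, got ", cls$label)
  m <- config$border_trim
  root <- panel_regions(m, nrow(gray) - m, m, ncol(gray) - m,
                        depth = 0L, branch = "regular")
  out <- recurse_regular(gray, root, 0L, config)
  crops <- lapply(seq_len(nrow(out)),
                  function(i) crop_region(image, out[i, ]))
  new_segmentation(out, crops, cls)
}

# Depth-first recursion over sub-regions (original-frame coordinates).
recurse_regular <- function(gray, region, depth, config) {
  sub <- crop_region(gray, region)
  hlv <- high_intensity_indices(
    projection_profile(sub, "horizontal", TRUE), config)
  vlv <- high_intensity_indices(
    projection_profile(sub, "vertical", TRUE), config)
  no_sep <- count_separators(hlv) == 0 && count_separators(vlv) == 0
  if (no_sep || depth >= config$max_recursion_depth)
    return(emit_region(region, depth, config))
  dir <- choose_direction(hlv, vlv)
  runs <- if (dir == "horizontal") hlv$runs else vlv$runs
  children <- segment_axis(sub, runs, dir, config, trim = 1L,
                           depth = depth + 1L)
  if (nrow(children) == 0) return(emit_region(region, depth, config))
  # back to original-frame coordinates
  children$row_start <- children$row_start + region$row_start
  children$row_end <- children$row_end + region$row_start
  children$col_start <- children$col_start + region$col_start
  children$col_end <- children$col_end + region$col_start
  out <- lapply(seq_len(nrow(children)), function(i)
    recurse_regular(gray, children[i, ], depth + 1L, config))
  do.call(rbind, out)
}

emit_region <- function(region, depth, config) {
  if ((region$row_end - region$row_start) < config$min_panel_extent ||
      (region$col_end - region$col_start) < config$min_panel_extent)
    return(panel_regions())
  region$depth <- depth
  region
}
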