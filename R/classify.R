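#' Count the separator indices in an index set
#'
#' Returns the number of individual high-intensity positions (not the
#' number of contiguous runs): an index set spanning ranges 1-8 and
#' 298-311 counts 22.
#'
#' @param index_set A [separator_index_set()].
#' @return Integer count.
#' @export
count_separators <- function(index_set) {
  stopifnot(inherits(index_set, "separator_index_set"))
  length(index_set$indices)
}

# Effective line count for the regular/irregular decision: a contiguous run
# no wider than max_separator_width is one ruled separator line; a wider
# bright band is content-scale white and contributes its raw index count.
effective_line_count <- function(index_set, config) {
  runs <- index_set$runs
  if (nrow(runs) == 0) return(0L)
  widths <- runs[, "end"] - runs[, "start"] + 1L
  sum(ifelse(widths <= config$max_separator_width, 1L, widths))
}

#' Classify separator index sets into an image class
#'
#' The decision rule of the framework, applied to precomputed horizontal
#' (HLV) and vertical (VLV) separator index sets:
#' single-panel when both raw index counts are at most `threshold_single`
#' (default 0); otherwise regular multi-panel when the larger per-axis
#' *effective* line count is at most `threshold_comp` (default 5);
#' otherwise irregular multi-panel. Exposed separately so published index
#' vectors can be injected directly.
#'
#' @param hlv,vlv [separator_index_set()]s for rows and columns.
#' @param config A [panelseg_config()].
#' @return An object of class `panel_class` with fields `label` (one of
#'   `"SINGLE_PANEL"`, `"MULTI_PANEL_REGULAR"`, `"MULTI_PANEL_IRREGULAR"`),
#'   `hlv`, `vlv`, `total_horizontal`, `total_vertical` (raw index counts)
#'   and `effective_horizontal`, `effective_vertical` (run-collapsed line
#'   counts used for the regular test).
#' @export
classify_separators <- function(hlv, vlv, config = panelseg_config()) {
  stopifnot(inherits(hlv, "separator_index_set"),
            inherits(vlv, "separator_index_set"))
  th <- count_separators(hlv)
  tv <- count_separators(vlv)
  eh <- effective_line_count(hlv, config)
  ev <- effective_line_count(vlv, config)
  label <- if (th <= config$threshold_single &&
               tv <= config$threshold_single) {
    "SINGLE_PANEL"
  } else if (max(eh, ev) <= config$threshold_comp) {
    "MULTI_PANEL_REGULAR"
  } else {
    "MULTI_PANEL_IRREGULAR"
  }
  structure(list(label = label, hlv = hlv, vlv = vlv,
                 total_horizontal = th, total_vertical = tv,
                 effective_horizontal = eh, effective_vertical = ev),
            class = "panel_class")
}

#' Classify a figure as single-panel, regular or irregular multi-panel
#'
#' Runs the image-type identification stage: grayscale conversion, border
#' trim, mean-normalized row/column projection profiles, extraction of
#' high-intensity (near-white) separator rows (HLV) and columns (VLV),
#' then the threshold decision of [classify_separators()]. The returned
#' record carries the index sets for reuse by the segmenters; its
#' coordinates refer to the border-trimmed frame.
#'
#' @param image Grayscale matrix or RGB array.
#' @param config A [panelseg_config()].
#' @return A `panel_class` (see [classify_separators()]).
#' @examples
#' img <- matrix(120, 64, 64) # uniform mid-gray: no separators
#' classify_image(img)$label # "SINGLE_PANEL"
#' @export
classify_image <- function(image, config = panelseg_config()) {
  check_image(image)
  gray <- to_grayscale(image)
  trimmed <- trim_border(gray, config$border_trim)
  hp <- projection_profile(trimmed, "horizontal", normalize = TRUE)
  vp <- projection_profile(trimmed, "vertical", normalize = TRUE)
  classify_separators(high_intensity_indices(hp, config),
                      high_intensity_indices(vp, config),
                      config)
}

#' @export
print.panel_class <- function(x, ...) {
  cat("panelseg image class:", x$label, "\n")
  cat(sprintf("  horizontal separators: %d indices (%d effective lines)\n",
              x$total_horizontal, x$effective_horizontal))
  cat(sprintf("  vertical separators:   %d indices (%d effective lines)\n",
              x$total_vertical, x$effective_vertical))
  invisible(x)
}
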