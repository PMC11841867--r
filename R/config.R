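#' Framework configuration
#'
#' Bundles every tunable parameter of the classification and segmentation
#' pipeline into a validated list. All coordinates in the package are
#' 0-based with half-open crop intervals; separator runs are inclusive
#' `(start, end)` index pairs.
#'
#' @param threshold_single Maximum separator-index count (on both axes) for
#'   an image to be called single-panel. Default 0: any detected separator
#'   line means the figure is compound.
#' @param threshold_comp Maximum effective separator-line count (per axis)
#'   for a compound figure to be called a *regular* multi-panel image.
#'   Default 5: panel grids in practice have at most five straight
#'   inter-panel borders along either axis.
#' @param intensity_fraction Fraction of the 8-bit maximum defining the
#'   high-intensity threshold `T = intensity_fraction * 255` applied to
#'   mean-normalized projection profiles (strictly-greater comparison).
#'   Default 0.95: separators are near-white gutters.
#' @param border_trim Pixels removed from every outer edge before profile
#'   analysis, so a figure's own frame is not mistaken for a separator.
#'   Default 2.
#' @param max_separator_width Maximum width (pixels) of a contiguous
#'   high-intensity run that is still counted as a single ruled separator
#'   line when deciding regular vs irregular. Wider bright bands are
#'   content-scale white regions and contribute their raw index count.
#'   Default 20.
#' @param min_panel_extent Minimum side length (pixels) a cropped region
#'   must have to be kept as a panel. Default 16.
#' @param kernel_rows,kernel_cols Structuring-element size (odd) for the
#'   morphological closing in the irregular branch. Default 29 x 29.
#' @param area_fraction Minimum connected-component area, as a fraction of
#'   total image area, for the component to be extracted as a panel.
#'   Default 0.02.
#' @param max_recursion_depth Recursion bound for regular segmentation.
#'   Default 4.
#'
#' @return An object of class `panelseg_config`.
#' @examples
#' cfg <- panelseg_config()
#' cfg$threshold_comp
#' @export
panelseg_config <- function(threshold_single = 0L,
                            threshold_comp = 5L,
                            intensity_fraction = 0.95,
                            border_trim = 2L,
                            max_separator_width = 20L,
                            min_panel_extent = 16L,
                            kernel_rows = 29L,
                            kernel_cols = 29L,
                            area_fraction = 0.02,
                            max_recursion_depth = 4L) {
  cfg <- list(
    threshold_single = as.integer(threshold_single),
    threshold_comp = as.integer(threshold_comp),
    intensity_fraction = as.numeric(intensity_fraction),
    border_trim = as.integer(border_trim),
    max_separator_width = as.integer(max_separator_width),
    min_panel_extent = as.integer(min_panel_extent),
    kernel_rows = as.integer(kernel_rows),
    kernel_cols = as.integer(kernel_cols),
    area_fraction = as.numeric(area_fraction),
    max_recursion_depth = as.integer(max_recursion_depth)
  )
  class(cfg) <- "panelseg_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$threshold_single >= 0L,
    cfg$threshold_comp >= 1L,
    cfg$intensity_fraction > 0, cfg$intensity_fraction <= 1,
    cfg$border_trim >= 0L,
    cfg$max_separator_width >= 1L,
    cfg$min_panel_extent >= 1L,
    cfg$kernel_rows >= 1L, cfg$kernel_cols >= 1L,
    cfg$kernel_rows %% 2L == 1L, cfg$kernel_cols %% 2L == 1L,
    cfg$area_fraction > 0, cfg$area_fraction < 1,
    cfg$max_recursion_depth >= 1L
  )
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' Keys mirror the arguments of [panelseg_config()]; absent keys keep their
#' defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `panelseg_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(panelseg_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(panelseg_config, vals)
}

#' @export
print.panelseg_config <- function(x, ...) {
  cat("panelseg configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
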