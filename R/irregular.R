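#' Otsu threshold of a grayscale image
#'
#' Selects the intensity `t` in `[0, 255]` that maximizes the
#' between-class variance of the two-class split (`<= t` vs `> t`) of the
#' 256-bin intensity histogram. Ties are broken toward the lowest `t`.
#'
#' @param image Grayscale matrix.
#' @return Integer threshold; a constant image is a degenerate histogram
#'   and returns 0 with a warning.
#' @export
otsu_threshold <- function(image) {
  if (!is_gray(image)) stop("Otsu thresholding requires a grayscale image")
  v <- as.integer(round(image))
  if (length(unique(v)) < 2) {
    warning("degenerate histogram: image has a single intensity")
    return(0L)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  lev <- 0:255
  cw <- cumsum(counts)            # pixels with intensity <= t
  cm <- cumsum(counts * lev)      # intensity mass   <= t
  n <- cw[256L]; m_tot <- cm[256L]
  w0 <- cw[1:255]; w1 <- n - w0   # split at t = 0..254
  valid <- w0 > 0 & w1 > 0
  mu0 <- cm[1:255] / w0
  mu1 <- (m_tot - cm[1:255]) / w1
  sigma_b <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  as.integer(which.max(sigma_b) - 1L)
}

#' Binarize a grayscale image at a threshold
#'
#' Pixels `<= t` map to 0 (background), pixels `> t` to `max_value`.
#'
#' @param image Grayscale matrix.
#' @param t Threshold in `[0, 255]`.
#' @param max_value Foreground value (default 255).
#' @return Binary matrix over `{0, max_value}`.
#' @export
binarize <- function(image, t, max_value = 255) {
  if (!is_gray(image)) stop("binarize requires a grayscale image")
  stopifnot(t >= 0, t <= 255)
  out <- matrix(0, nrow(image), ncol(image))
  out[image > t] <- max_value
  out
}

# Shift matrix content by s rows (positive = take values from s rows below),
# vacated cells filled so the shift is neutral for the running max/min.
shift_rows <- function(m, s, fill) {
  n <- nrow(m)
  if (s > 0) rbind(m[-seq_len(s), , drop = FALSE],
                   matrix(fill, s, ncol(m)))
  else rbind(matrix(fill, -s, ncol(m)),
             m[seq_len(n + s), , drop = FALSE])
}

shift_cols <- function(m, s, fill) {
  n <- ncol(m)
  if (s > 0) cbind(m[, -seq_len(s), drop = FALSE],
                   matrix(fill, nrow(m), s))
  else cbind(matrix(fill, nrow(m), -s),
             m[, seq_len(n + s), drop = FALSE])
}

# Separable rectangular running max (fun = pmax, fill 0) or min
# (fun = pmin, fill 255) with the window clipped at image borders.
rect_filter <- function(m, kr, kc, fun, fill) {
  rr <- (kr - 1L) %/% 2L
  rc <- (kc - 1L) %/% 2L
  out <- m
  for (s in seq_len(rr))
    out <- fun(out, shift_rows(m, s, fill), shift_rows(m, -s, fill))
  m2 <- out
  for (s in seq_len(rc))
    out <- fun(out, shift_cols(m2, s, fill), shift_cols(m2, -s, fill))
  out
}

#' Morphological closing of a binary image
#'
#' Dilation (per-pixel maximum over a `kernel_rows x kernel_cols`
#' rectangular neighborhood, clipped at the image border) followed by
#' erosion (per-pixel minimum over the same neighborhood of the dilated
#' image). Fills holes and gaps smaller than the structuring element.
#'
#' @param binary Binary matrix over `{0, 255}`.
#' @param kernel_rows,kernel_cols Odd structuring-element dimensions.
#' @return Closed binary matrix.
#' @export
morphological_close <- function(binary, kernel_rows = 29L,
                                kernel_cols = 29L) {
  stopifnot(is_gray(binary),
            kernel_rows %% 2 == 1, kernel_cols %% 2 == 1,
            kernel_rows >= 1, kernel_cols >= 1)
  if (kernel_rows > nrow(binary) || kernel_cols > ncol(binary))
    stop("structuring element larger than the image")
  dilated <- rect_filter(binary, kernel_rows, kernel_cols, pmax, 0)
  rect_filter(dilated, kernel_rows, kernel_cols, pmin, 255)
}

#' Connected components of a binary image, with statistics
#'
#' Labels maximal 8-connected regions of foreground (`max_value`) pixels
#' and returns, per component, the bounding box and foreground pixel
#' count. Labels are contiguous from 1 in order of first raster
#' occurrence; the background is excluded.
#'
#' @param binary Binary matrix over `{0, 255}` (any non-zero value is
#'   foreground).
#' @return Data frame with columns `label`, `x`, `y` (0-based top-left of
#'   the bounding box), `w`, `h`, `area`; zero rows when the image is all
#'   background.
#' @export
connected_components <- function(binary) {
  stopifnot(is_gray(binary))
  m <- nrow(binary); n <- ncol(binary)
  mask <- binary != 0
  fg <- which(mask)
  empty <- data.frame(label = integer(0), x = integer(0), y = integer(0),
                      w = integer(0), h = integer(0), area = integer(0))
  if (length(fg) == 0) return(empty)
  pos <- integer(m * n)
  pos[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% m) + 1L
  cc <- ((fg - 1L) %/% m) + 1L
  from <- integer(0); to <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nr <- r + off[1]; ncl <- cc + off[2]
    ok <- nr >= 1L & nr <= m & ncl >= 1L & ncl <= n
    nidx <- (ncl[ok] - 1L) * m + nr[ok]
    hit <- mask[nidx]
    from <- c(from, pos[fg[ok]][hit])
    to <- c(to, pos[nidx[hit]])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(from) > 0)
    g <- igraph::add_edges(g, rbind(from, to))
  mem <- igraph::components(g)$membership
  lab <- match(mem, unique(mem)) # contiguous, raster-ordered labels
  data.frame(
    label = seq_along(unique(mem)),
    x = as.integer(tapply(cc, lab, min)) - 1L,
    y = as.integer(tapply(r, lab, min)) - 1L,
    w = as.integer(tapply(cc, lab, max)) - as.integer(tapply(cc, lab, min)) + 1L,
    h = as.integer(tapply(r, lab, max)) - as.integer(tapply(r, lab, min)) + 1L,
    area = as.integer(tapply(lab, lab, length)),
    row.names = NULL
  )
}

#' Segment an irregular multi-panel image
#'
#' The thresholding branch of the framework: grayscale conversion, Otsu
#' binarization, polarity normalization (if the majority of border pixels
#' are foreground the binary image is inverted, so panels — not the white
#' page — are foreground), morphological closing, 8-connected component
#' labeling, and extraction of each component whose foreground area
#' exceeds `area_fraction` of the image area. Bounding boxes are cropped
#' from the original image.
#'
#' @param image Grayscale matrix or RGB array.
#' @param config A [panelseg_config()].
#' @param cls Optional `panel_class` recorded on the result.
#' @return A `panel_segmentation` with branch `"irregular"`. When no
#'   component survives the area filter the whole image is returned as a
#'   single region and the result is flagged `"empty-result"` with a
#'   warning.
#' @examples
#' spec <- montage_spec("irregular", n_panels = 3, canvas = c(300, 300),
#'                      seed = 4)
#' mont <- generate_montage(spec)
#' seg <- segment_irregular(mont$image)
#' nrow(seg$regions)
#' @export
segment_irregular <- function(image, config = panelseg_config(),
                              cls = NULL) {
  check_image(image)
  gray <- to_grayscale(image)
  t <- suppressWarnings(otsu_threshold(gray))
  bin <- binarize(gray, t)
  border <- c(bin[1, ], bin[nrow(bin), ], bin[, 1], bin[, ncol(bin)])
  if (mean(border != 0) > 0.5) bin <- 255 - bin
  closed <- morphological_close(bin, config$kernel_rows, config$kernel_cols)
  stats <- connected_components(closed)
  keep <- stats[stats$area > config$area_fraction * length(gray), ,
                drop = FALSE]
  if (nrow(keep) == 0) {
    warning("no component exceeded the area threshold; ",
            "returning the whole image as one region")
    regions <- panel_regions(0L, nrow(gray), 0L, ncol(gray),
                             depth = 0L, branch = "irregular")
    crops <- list(image)
    return(new_segmentation(regions, crops, cls, flags = "empty-result"))
  }
  regions <- panel_regions(keep$y, keep$y + keep$h,
                           keep$x, keep$x + keep$w,
                           depth = 0L, branch = "irregular")
  crops <- lapply(seq_len(nrow(regions)),
                  function(i) crop_region(image, regions[i, ]))
  new_segmentation(regions, crops, cls)
}
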