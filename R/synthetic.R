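#' Specification for a synthetic figure montage
#'
#' Describes a ground-truthed synthetic figure in one of the three layout
#' classes the pipeline distinguishes: `"single"` (one full-canvas panel),
#' `"grid"` (rows x cols panels separated by uniform bright gutters, the
#' regular case), `"irregular"` (2-6 panels of varying sizes placed with
#' jitter on a white canvas, with non-uniform but generous gaps, the
#' stitched-mosaic case).
#'
#' Defaults emulate radiograph-like panels on a white page: Gaussian
#' panel texture with mean 120 and sd 30 on the 8-bit scale, so panels
#' are well separated from the white background by a global threshold.
#'
#' @param layout `"single"`, `"grid"` or `"irregular"`.
#' @param rows,cols Grid shape (grid layout).
#' @param gutter_px Gutter width in pixels (grid layout), default 8.
#' @param gutter_intensity Gutter/background intensity, default 255.
#' @param panel_texture `"gaussian-noise"`, `"uniform"` or `"blob"`.
#' @param panel_mean,panel_sd Intensity statistics of panel content.
#' @param n_panels Panel count for the irregular layout; NULL draws
#'   uniformly from 2-6 under the spec seed.
#' @param min_gap Minimum inter-panel / margin gap for the irregular
#'   layout (default 32 px: irregular mosaics are assumed to have
#'   generous whitespace, wider than the closing kernel's reach).
#' @param jitter_px Maximum random shrink/offset of irregular panels
#'   (default 12), the source of gap non-uniformity.
#' @param canvas `c(M, N)` canvas size in pixels, default 480 x 480.
#' @param seed RNG seed; identical spec (including seed) gives
#'   bit-identical output.
#' @return An object of class `montage_spec`.
#' @export
montage_spec <- function(layout = c("grid", "single", "irregular"),
                         rows = 2L, cols = 2L, gutter_px = 8L,
                         gutter_intensity = 255,
                         panel_texture = c("gaussian-noise", "uniform",
                                           "blob"),
                         panel_mean = 120, panel_sd = 30,
                         n_panels = NULL, min_gap = 32L, jitter_px = 12L,
                         canvas = c(480L, 480L), seed = 1L) {
  layout <- match.arg(layout)
  panel_texture <- match.arg(panel_texture)
  spec <- list(layout = layout, rows = as.integer(rows),
               cols = as.integer(cols), gutter_px = as.integer(gutter_px),
               gutter_intensity = as.numeric(gutter_intensity),
               panel_texture = panel_texture,
               panel_mean = as.numeric(panel_mean),
               panel_sd = as.numeric(panel_sd),
               n_panels = if (is.null(n_panels)) NULL
                          else as.integer(n_panels),
               min_gap = as.integer(min_gap),
               jitter_px = as.integer(jitter_px),
               canvas = as.integer(canvas), seed = as.integer(seed))
  stopifnot(spec$gutter_px >= 0L, spec$rows >= 1L, spec$cols >= 1L,
            spec$panel_mean >= 0, spec$panel_mean <= 255,
            spec$min_gap >= 3L, length(spec$canvas) == 2,
            all(spec$canvas >= 32L))
  class(spec) <- "montage_spec"
  spec
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

fill_texture <- function(h, w, spec) {
  px <- switch(spec$panel_texture,
    "uniform" = matrix(spec$panel_mean, h, w),
    "gaussian-noise" = matrix(round(stats::rnorm(h * w, spec$panel_mean,
                                                 spec$panel_sd)), h, w),
    "blob" = {
      base <- matrix(round(stats::rnorm(h * w, spec$panel_mean,
                                        spec$panel_sd)), h, w)
      cy <- stats::runif(1, 0.3, 0.7) * h
      cx <- stats::runif(1, 0.3, 0.7) * w
      rad <- 0.25 * min(h, w)
      d <- outer(seq_len(h) - cy, seq_len(w) - cx,
                 function(a, b) sqrt(a^2 + b^2))
      base[d < rad] <- max(0, spec$panel_mean - 70)
      base
    })
  px[px < 0] <- 0
  px[px > 255] <- 255
  px
}

# Evenly distribute `extent` pixels over k panels and k-1 gutters; returns
# 0-based half-open (start, end) per panel.
grid_cuts <- function(extent, k, gutter) {
  panel_total <- extent - (k - 1L) * gutter
  if (panel_total < k) stop("infeasible packing: gutters exceed canvas")
  cuts <- round(seq(0, panel_total, length.out = k + 1L))
  starts <- cuts[-(k + 1L)] + (seq_len(k) - 1L) * gutter
  ends <- cuts[-1L] + (seq_len(k) - 1L) * gutter
  cbind(start = as.integer(starts), end = as.integer(ends))
}

#' Generate a synthetic montage with ground truth
#'
#' @param spec A [montage_spec()].
#' @return An object of class `panel_montage`: list with `image`
#'   (grayscale matrix), `truth` (panel-region data frame, branch
#'   `"truth"`), `label` (the true image class) and `spec`.
#' @examples
#' m <- generate_montage(montage_spec("grid", rows = 2, cols = 2,
#'                                    canvas = c(256, 256), seed = 7))
#' m$label
#' nrow(m$truth) # 4
#' @export
generate_montage <- function(spec) {
  stopifnot(inherits(spec, "montage_spec"))
  with_seed(spec$seed, {
    out <- switch(spec$layout,
                  single = gen_single(spec),
                  grid = gen_grid(spec),
                  irregular = gen_irregular(spec))
    structure(c(out, list(spec = spec)), class = "panel_montage")
  })
}

gen_single <- function(spec) {
  m <- spec$canvas[1]; n <- spec$canvas[2]
  list(image = fill_texture(m, n, spec),
       truth = panel_regions(0L, m, 0L, n, branch = "truth"),
       label = "SINGLE_PANEL")
}

gen_grid <- function(spec) {
  m <- spec$canvas[1]; n <- spec$canvas[2]
  img <- matrix(spec$gutter_intensity, m, n)
  rcuts <- grid_cuts(m, spec$rows, spec$gutter_px)
  ccuts <- grid_cuts(n, spec$cols, spec$gutter_px)
  rs <- integer(0); re <- integer(0); cs <- integer(0); ce <- integer(0)
  for (i in seq_len(spec$rows)) for (j in seq_len(spec$cols)) {
    r0 <- rcuts[i, "start"]; r1 <- rcuts[i, "end"]
    c0 <- ccuts[j, "start"]; c1 <- ccuts[j, "end"]
    img[(r0 + 1):r1, (c0 + 1):c1] <- fill_texture(r1 - r0, c1 - c0, spec)
    rs <- c(rs, r0); re <- c(re, r1); cs <- c(cs, c0); ce <- c(ce, c1)
  }
  label <- if (spec$rows == 1L && spec$cols == 1L) "SINGLE_PANEL"
           else "MULTI_PANEL_REGULAR"
  list(image = img,
       truth = panel_regions(rs, re, cs, ce, branch = "truth"),
       label = label)
}

gen_irregular <- function(spec) {
  m <- spec$canvas[1]; n <- spec$canvas[2]
  gap <- spec$min_gap; jit <- spec$jitter_px
  k <- if (is.null(spec$n_panels)) sample(2:6, 1) else spec$n_panels
  stopifnot(k >= 2, k <= 9)
  n_bands <- sample(seq(max(1L, ceiling(k / 3)), min(3L, k)), 1)
  repeat {
    counts <- tabulate(sample(seq_len(n_bands), k, replace = TRUE),
                       n_bands)
    if (all(counts >= 1L & counts <= 3L)) break
  }
  band_h <- (m - (n_bands + 1L) * gap) %/% n_bands
  min_side <- 60L
  if (band_h - jit < min_side)
    stop("infeasible packing: bands too thin for the requested canvas")
  img <- matrix(spec$gutter_intensity, m, n)
  rs <- integer(0); re <- integer(0); cs <- integer(0); ce <- integer(0)
  for (b in seq_len(n_bands)) {
    band_top <- gap * b + band_h * (b - 1L)
    p <- counts[b]
    slot_w <- (n - (p + 1L) * gap) %/% p
    if (slot_w - jit < min_side)
      stop("infeasible packing: slots too narrow for the requested canvas")
    for (q in seq_len(p)) {
      slot_left <- gap * q + slot_w * (q - 1L)
      h <- band_h - sample(0:jit, 1)
      w <- slot_w - sample(0:jit, 1)
      top <- band_top + sample(0:(band_h - h), 1)
      left <- slot_left + sample(0:(slot_w - w), 1)
      img[(top + 1):(top + h), (left + 1):(left + w)] <-
        fill_texture(h, w, spec)
      rs <- c(rs, top); re <- c(re, top + h)
      cs <- c(cs, left); ce <- c(ce, left + w)
    }
  }
  list(image = img,
       truth = panel_regions(rs, re, cs, ce, branch = "truth"),
       label = "MULTI_PANEL_IRREGULAR")
}

#' @export
print.panel_montage <- function(x, ...) {
  cat(sprintf("panel_montage: %s, %d x %d, %d ground-truth panel(s)\n",
              x$label, nrow(x$image), ncol(x$image), nrow(x$truth)))
  invisible(x)
}
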