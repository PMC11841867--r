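# Independent brute-force reference implementations used to cross-check
# the package's image primitives. Deliberately naive: direct transcription
# of the defining formulas, no shared code with the implementation.

# Exhaustive Otsu: try every threshold, compute the two-class
# between-class variance from first principles.
oracle_otsu <- function(image) {
  v <- as.integer(round(image))
  best_t <- 0L
  best_var <- -Inf
  n <- length(v)
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / n
    w1 <- length(hi) / n
    vb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (vb > best_var) {
      best_var <- vb
      best_t <- t
    }
  }
  best_t
}

# Naive closing: per-pixel max over the clipped kernel window, then
# per-pixel min over the dilated image.
oracle_close <- function(binary, kr, kc) {
  rr <- (kr - 1) %/% 2
  rc <- (kc - 1) %/% 2
  m <- nrow(binary); n <- ncol(binary)
  win <- function(img, i, j, fun) {
    fun(img[max(1, i - rr):min(m, i + rr),
            max(1, j - rc):min(n, j + rc)])
  }
  dil <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) dil[i, j] <- win(binary, i, j, max)
  out <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) out[i, j] <- win(dil, i, j, min)
  out
}

# Flood-fill 8-connected labeling with per-component stats.
oracle_components <- function(binary) {
  m <- nrow(binary); n <- ncol(binary)
  lab <- matrix(0L, m, n)
  nxt <- 0L
  out <- list()
  for (j0 in 1:n) for (i0 in 1:m) {
    if (binary[i0, j0] == 0 || lab[i0, j0] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    cells <- matrix(c(i0, j0), 1, 2)
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i < 1 || i > m || j < 1 || j > n) next
        if (binary[i, j] != 0 && lab[i, j] == 0) {
          lab[i, j] <- nxt
          queue[[length(queue) + 1]] <- c(i, j)
          cells <- rbind(cells, c(i, j))
        }
      }
    }
    out[[nxt]] <- data.frame(
      x = min(cells[, 2]) - 1L, y = min(cells[, 1]) - 1L,
      w = diff(range(cells[, 2])) + 1L, h = diff(range(cells[, 1])) + 1L,
      area = nrow(cells))
  }
  list(labels = lab, stats = do.call(rbind, out))
}

# Reference axis segmentation: scan a boolean is-separator vector and
# collect the maximal non-separator stretches as (start, end) half-open.
oracle_axis_segments <- function(is_sep) {
  n <- length(is_sep)
  segs <- NULL
  start <- NA
  for (i in seq_len(n)) {
    if (!is_sep[i] && is.na(start)) start <- i - 1L
    if (is_sep[i] && !is.na(start)) {
      segs <- rbind(segs, c(start, i - 1L))
      start <- NA
    }
  }
  if (!is.na(start)) segs <- rbind(segs, c(start, n))
  segs
}

# Random 0/255 binary matrix with tunable foreground density.
random_binary <- function(m, n, p = 0.5) {
  matrix(ifelse(stats::runif(m * n) < p, 255, 0), m, n)
}
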