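sep <- function(idx, axis) separator_index_set(idx, axis)

test_that("cut direction follows the larger separator set, ties vertical", {
  expect_equal(choose_direction(sep(0:2, "horizontal"),
                                sep(5, "vertical")), "horizontal")
  expect_equal(choose_direction(sep(0:1, "horizontal"),
                                sep(0:1, "vertical")), "vertical")
  expect_error(choose_direction(sep(integer(0), "horizontal"),
                                sep(integer(0), "vertical")),
               class = "panelseg_no_separator")
})

test_that("axis segmentation cuts at runs and discards separator bands", {
  cfg <- panelseg_config()
  img <- matrix(0, 100, 40)
  runs <- cbind(start = 48L, end = 52L)
  out <- segment_axis(img, runs, "horizontal", cfg, trim = 0L)
  expect_equal(out$row_start, c(0L, 53L))
  expect_equal(out$row_end, c(48L, 100L))
  expect_equal(out$col_start, c(0L, 0L))
  expect_equal(out$col_end, c(40L, 40L))

  none <- segment_axis(img, group_runs(integer(0)), "horizontal", cfg,
                       trim = 0L)
  expect_equal(nrow(none), 1)
  expect_equal(c(none$row_start, none$row_end), c(0L, 100L))

  imgv <- matrix(0, 40, 90)
  vruns <- cbind(start = c(28L, 58L), end = c(31L, 61L))
  outv <- segment_axis(imgv, vruns, "vertical", cfg, trim = 0L)
  expect_equal(outv$col_start, c(0L, 32L, 62L))
  expect_equal(outv$col_end, c(28L, 58L, 90L))

  # default 1-px boundary trim shrinks every side
  trimmed <- segment_axis(img, runs, "horizontal", cfg)
  expect_equal(trimmed$row_start, c(1L, 54L))
  expect_equal(trimmed$row_end, c(47L, 99L))
  expect_equal(trimmed$col_start, c(1L, 1L))
  expect_equal(trimmed$col_end, c(39L, 39L))
})

test_that("axis segmentation agrees with the separator-mask scan oracle", {
  set.seed(61)
  cfg <- panelseg_config(min_panel_extent = 1)
  for (i in 1:40) {
    n <- sample(40:120, 1)
    idx <- sort(sample(0:(n - 1), sample(0:12, 1)))
    img <- matrix(0, n, 50)
    out <- segment_axis(img, group_runs(idx), "horizontal", cfg, trim = 0L)
    is_sep <- rep(FALSE, n)
    is_sep[idx + 1] <- TRUE
    ref <- oracle_axis_segments(is_sep)
    if (is.null(ref)) {
      expect_equal(nrow(out), 0)
    } else {
      expect_equal(out$row_start, as.integer(ref[, 1]))
      expect_equal(out$row_end, as.integer(ref[, 2]))
    }
  }
})

test_that("segment extents plus runs plus trims cover the parent extent", {
  cfg <- panelseg_config(min_panel_extent = 1)
  img <- matrix(0, 200, 60)
  runs <- cbind(start = c(40L, 120L), end = c(47L, 124L))
  out <- segment_axis(img, runs, "horizontal", cfg, trim = 1L)
  seg_extent <- sum(out$row_end - out$row_start)
  run_extent <- sum(runs[, "end"] - runs[, "start"] + 1L)
  trim_extent <- 2L * nrow(out)
  expect_equal(seg_extent + run_extent + trim_extent, 200L)
})

test_that("regular segmentation recovers grid panels", {
  m22 <- generate_montage(montage_spec("grid", rows = 2, cols = 2,
                                       gutter_px = 6, canvas = c(300, 300),
                                       seed = 2))
  seg <- segment_regular(m22$image)
  expect_equal(nrow(seg$regions), 4)
  rep <- match_and_score(seg$regions, m22$truth)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)

  m13 <- generate_montage(montage_spec("grid", rows = 1, cols = 3,
                                       gutter_px = 10, canvas = c(200, 420),
                                       seed = 3))
  seg13 <- segment_regular(m13$image)
  expect_equal(nrow(seg13$regions), 3)
  expect_equal(match_and_score(seg13$regions, m13$truth)$f1, 1)
})

test_that("regular segmentation rejects the wrong branch but degrades safely", {
  flat <- matrix(100, 120, 120)
  expect_error(segment_regular(flat), "wrong branch")
  seg <- segment_regular(flat, check_class = FALSE)
  expect_equal(nrow(seg$regions), 1)
  expect_equal(unname(unlist(seg$regions[1, 1:4])),
               c(2L, 118L, 2L, 118L)) # whole border-trimmed frame
})

test_that("regular segmentation regions are pairwise disjoint and in frame", {
  set.seed(71)
  for (i in 1:10) {
    r <- sample(1:3, 1); c <- sample(2:3, 1)
    mont <- generate_montage(montage_spec("grid", rows = r, cols = c,
                                          gutter_px = sample(5:20, 1),
                                          canvas = c(320, 320), seed = i))
    seg <- segment_regular(mont$image)
    reg <- seg$regions
    expect_true(all(reg$row_start >= 0 & reg$row_end <= 320 &
                      reg$col_start >= 0 & reg$col_end <= 320))
    if (nrow(reg) > 1) {
      for (a in 1:(nrow(reg) - 1)) for (b in (a + 1):nrow(reg)) {
        inter <- min(reg$row_end[a], reg$row_end[b]) -
          max(reg$row_start[a], reg$row_start[b])
        interc <- min(reg$col_end[a], reg$col_end[b]) -
          max(reg$col_start[a], reg$col_start[b])
        expect_true(inter <= 0 || interc <= 0)
      }
    }
    expect_equal(nrow(reg), r * c)
  }
})
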