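test_that("Otsu threshold separates a clean bimodal image", {
  img <- matrix(c(rep(0, 50), rep(200, 50)), 10, 10)
  t <- otsu_threshold(img)
  expect_true(t >= 0 && t < 200)
  bin <- binarize(img, t)
  expect_equal(sum(bin == 0), 50)
  expect_equal(sum(bin == 255), 50)
  expect_warning(t0 <- otsu_threshold(matrix(7, 5, 5)), "degenerate")
  expect_equal(t0, 0L)
})

test_that("Otsu equals the exhaustive between-class-variance search", {
  set.seed(81)
  for (i in 1:25) {
    img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    expect_equal(otsu_threshold(img), oracle_otsu(img))
  }
  # two-point histograms at several mixture sizes
  for (n in c(5, 50, 500)) {
    img <- matrix(c(rep(10, n), rep(240, n)), ncol = 2)
    expect_equal(otsu_threshold(img), oracle_otsu(img))
  }
})

test_that("binarization applies the strict-greater rule", {
  img <- matrix(c(0, 128, 255), 1, 3)
  expect_equal(as.vector(binarize(img, 128)), c(0, 0, 255))
  expect_equal(as.vector(binarize(img, 255)), c(0, 0, 0))
  two <- matrix(c(0, 255), 1, 2)
  expect_equal(as.vector(binarize(two, 0)), c(0, 255))
})

test_that("closing fills holes and matches the naive neighborhood oracle", {
  sq <- matrix(255, 20, 20)
  sq[10, 10] <- 0
  closed <- morphological_close(sq, 3, 3)
  expect_equal(closed[10, 10], 255)
  z <- matrix(0, 15, 15)
  expect_equal(morphological_close(z, 3, 3), z)
  expect_error(morphological_close(matrix(0, 10, 10), 29, 29), "larger")
  set.seed(91)
  for (i in 1:10) {
    b <- random_binary(32, 32, runif(1, 0.2, 0.8))
    expect_equal(morphological_close(b, 5, 5), oracle_close(b, 5, 5))
  }
  # non-square kernel
  b <- random_binary(24, 30, 0.4)
  expect_equal(morphological_close(b, 3, 7), oracle_close(b, 3, 7))
})

test_that("closing is extensive and idempotent on random binaries", {
  set.seed(101)
  for (i in 1:10) {
    b <- random_binary(40, 40, runif(1, 0.1, 0.9))
    once <- morphological_close(b, 5, 5)
    expect_true(all(once >= b))
    expect_equal(morphological_close(once, 5, 5), once)
  }
})

test_that("connected components label disjoint squares with correct stats", {
  img <- matrix(0, 20, 20)
  img[2:6, 2:6] <- 255
  img[12:16, 10:14] <- 255
  st <- connected_components(img)
  expect_equal(nrow(st), 2)
  expect_equal(st$area, c(25L, 25L))
  expect_equal(st$label, 1:2)
  expect_equal(st$x[1], 1L); expect_equal(st$y[1], 1L)
  expect_equal(st$w, c(5L, 5L)); expect_equal(st$h, c(5L, 5L))
  expect_equal(nrow(connected_components(matrix(0, 8, 8))), 0)
  # single isolated pixel is its own component
  one <- matrix(0, 5, 5); one[3, 3] <- 255
  expect_equal(connected_components(one)$area, 1L)
})

test_that("component labeling matches the flood-fill oracle", {
  set.seed(111)
  for (i in 1:15) {
    b <- random_binary(24, 24, runif(1, 0.25, 0.6))
    st <- connected_components(b)
    ref <- oracle_components(b)
    expect_equal(nrow(st), if (is.null(ref$stats)) 0 else nrow(ref$stats))
    if (nrow(st) > 0) {
      # label-permutation invariant: compare sorted stats tuples
      key <- function(d) do.call(order, d[c("x", "y", "w", "h", "area")])
      a <- st[key(st), c("x", "y", "w", "h", "area")]
      b2 <- ref$stats[key(ref$stats), ]
      rownames(a) <- rownames(b2) <- NULL
      expect_equal(a, b2)
      expect_equal(sum(st$area), sum(b != 0))
    }
  }
})

test_that("irregular segmentation extracts panels above the area threshold", {
  mont <- generate_montage(montage_spec("irregular", n_panels = 2,
                                        canvas = c(320, 320), seed = 12))
  seg <- segment_irregular(mont$image)
  expect_equal(nrow(seg$regions), 2)
  rep <- match_and_score(seg$regions, mont$truth)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_true(all(seg$regions$branch == "irregular"))
})

test_that("components below the area fraction are filtered out", {
  img <- matrix(255, 300, 300)
  img[21:120, 21:120] <- 100   # 100x100 panel, well above the 2% cutoff
  img[21:120, 181:280] <- 100  # second large panel
  img[201:230, 21:50] <- 100   # 30x30 = 900 px, below 2% of 90000 = 1800
  seg <- segment_irregular(img)
  expect_equal(nrow(seg$regions), 2)
  expect_true(all(seg$regions$row_end <= 130))
})

test_that("a single dark panel on white yields its bounding box", {
  img <- matrix(255, 200, 200)
  img[41:160, 61:180] <- 90
  seg <- segment_irregular(img)
  expect_equal(nrow(seg$regions), 1)
  expect_equal(unname(unlist(seg$regions[1, 1:4])),
               c(40L, 160L, 60L, 180L))
})

test_that("raising the area fraction never increases the region count", {
  mont <- generate_montage(montage_spec("irregular", n_panels = 5,
                                        seed = 13))
  prev <- Inf
  for (f in c(0.005, 0.02, 0.08, 0.3)) {
    n <- tryCatch(
      nrow(segment_irregular(mont$image,
                             panelseg_config(area_fraction = f))$regions),
      warning = function(w) 0L)
    expect_lte(n, prev)
    prev <- n
  }
})
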