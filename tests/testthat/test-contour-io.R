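# Segmentation, boundary tracing, resampling and contour CSV round trips.

make_disk_mask <- function(nr = 128, nc = 128, center = c(64, 64), r = 50) {
  gr <- rep(seq_len(nr), times = nc)
  gc <- rep(seq_len(nc), each = nr)
  matrix(as.numeric((gr - center[1])^2 + (gc - center[2])^2 <= r^2), nr, nc)
}

test_that("binarize recovers a bright disk and rejects degenerate images", {
  disk <- make_disk_mask()
  img <- disk * 0.8
  expect_equal(binarize(img, "otsu"), disk)
  expect_equal(binarize(img, "fixed", threshold = 0.4), disk)
  expect_error(binarize(matrix(0, 16, 16), "otsu"), "constant|foreground")
  expect_error(binarize(matrix(0, 16, 16), "fixed", threshold = 0.5),
               "empty foreground")
  expect_error(binarize(img, "fixed"), "threshold")
})

test_that("extract_contour traces the largest component CCW at sub-pixel level", {
  disk <- make_disk_mask(center = c(60, 70), r = 50)
  ct <- extract_contour(disk)
  expect_gt(polygon_area(ct), 0)
  # center in y-up coordinates: x = col, y = nr - row + 1
  ctr <- colMeans(ct)
  expect_equal(unname(ctr), c(70, 128 - 60 + 1), tolerance = 0.5)
  d <- sqrt((ct[, 1] - ctr[1])^2 + (ct[, 2] - ctr[2])^2)
  expect_true(all(abs(d - 50) < 1))

  # largest-component rule
  two <- disk
  two[5:9, 5:14] <- 1                      # 50 px blob far from the disk
  expect_equal(nrow(extract_contour(two)), nrow(ct))
  expect_equal(abs(polygon_area(extract_contour(two))),
               abs(polygon_area(ct)))

  # interior holes are ignored
  holey <- disk
  holey[55:65, 65:75] <- 0
  expect_equal(extract_contour(holey), extract_contour(disk),
               ignore_attr = TRUE)

  # border-touching component: warning + clipped flag
  edge <- make_disk_mask(center = c(5, 64), r = 20)
  expect_warning(ce <- extract_contour(edge), "border")
  expect_true(attr(ce, "clipped"))

  expect_error(extract_contour(matrix(0, 8, 8)), "foreground")
})

test_that("render -> binarize -> extract round trip stays within a pixel", {
  ct <- make_head_contour(head_params(), 256)
  img <- render_head_image(ct, render_spec(), seed = 1)
  mask <- binarize(img$channels$head, "otsu")
  expect_gt(sum(mask * img$head_mask) / sum(pmax(mask, img$head_mask)), 0.98)
  ext <- extract_contour(mask)
  # compare centered outlines (rendering translates to the image center)
  a <- sweep(ct, 2, polygon_centroid(ct))
  b <- sweep(ext, 2, polygon_centroid(ext))
  d2 <- outer(rowSums(b^2), rowSums(a^2), "+") - 2 * tcrossprod(b, a)
  expect_lt(mean(sqrt(pmax(apply(d2, 1, min), 0))), 1)
})

test_that("resample_contour spaces points uniformly in arc length", {
  sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  r8 <- resample_contour(sq, 8)
  expect_equal(r8,
               cbind(x = c(0, 50, 100, 100, 100, 50, 0, 0),
                     y = c(0, 0, 0, 50, 100, 100, 100, 50)),
               ignore_attr = TRUE)
  expect_equal(polygon_perimeter(r8), 400, tolerance = 0.5 * 4)

  # idempotence on an arc-uniform contour (equal segment lengths)
  circ <- circle_points(256, r = 40)
  expect_equal(resample_contour(circ, 256), circ, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(resample_contour(r8, 8), r8, tolerance = 1e-9)

  # uniform cumulative arc spacing along the source polygon at n = 256:
  # project each output point back onto the input and difference positions
  set.seed(8)
  blob <- random_star_contour(100)
  r256 <- resample_contour(blob, 256)
  closed <- rbind(blob, blob[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  pos <- vapply(seq_len(256), function(i) {
    p <- r256[i, ]
    best <- Inf; s <- NA_real_
    for (k in seq_len(nrow(blob))) {
      e <- closed[k + 1L, ] - closed[k, ]
      t <- sum((p - closed[k, ]) * e) / sum(e^2)
      t <- min(max(t, 0), 1)
      d <- sum((closed[k, ] + t * e - p)^2)
      if (d < best) { best <- d; s <- cum[k] + t * seg[k] }
    }
    s
  }, numeric(1))
  gaps <- diff(pos) %% per
  expect_lt(max(abs(gaps - per / 256)), 1e-6)

  expect_error(resample_contour(sq, 4), "n_points")
})

test_that("contour CSV round trip is lossless and validates its format", {
  set.seed(21)
  recs <- stats::setNames(lapply(1:10, function(i) random_star_contour(50)),
                          sprintf("sp%02d", 1:10))
  path <- tempfile(fileext = ".csv")
  write_contours(path, recs)
  back <- read_contours(path)
  expect_identical(names(back), names(recs))
  for (nm in names(recs))
    expect_equal(back[[nm]], recs[[nm]], ignore_attr = TRUE,
                 tolerance = 1e-12)

  # empty file -> empty list
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_identical(read_contours(empty), list())

  # missing column
  df <- utils::read.csv(path)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(df[, c("specimen_id", "x", "y")], bad, row.names = FALSE)
  expect_error(read_contours(bad), "point_index")

  # non-monotone point_index
  df2 <- df
  df2$point_index[2] <- 1
  utils::write.csv(df2, bad, row.names = FALSE)
  expect_error(read_contours(bad), "non-monotone")
})

test_that("image write/read round trips PNG and TIFF channels", {
  ct <- make_head_contour(head_params(), 128)
  img <- render_head_image(ct, render_spec(vacuole_count = 1), seed = 2)
  tp <- tempfile(fileext = ".tif")
  write_image(tp, img$channels)
  expect_equal(read_image(tp), img$channels$head, tolerance = 1e-4)
  pp <- tempfile(fileext = ".png")
  write_image(pp, img$head_mask)
  expect_equal(read_image(pp), img$head_mask, tolerance = 1e-4)
})
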