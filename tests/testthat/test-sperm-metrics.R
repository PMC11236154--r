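# Acrosome area, vacuole detection and prevalence summaries.

render_fixture <- function(vacuoles = 0, acro = 0.3, seed = 1) {
  ct <- make_head_contour(head_params(seed = seed), 256)
  render_head_image(ct, render_spec(vacuole_count = vacuoles,
                                    acrosome_fraction = acro), seed = seed)
}

test_that("acrosome area matches the rendered ground truth and scales with pixel size", {
  img <- render_fixture(acro = 0.35)
  m <- acrosome_area(img$channels$acrosome, img$head_mask, pixel_size = 0.2)
  expect_equal(m$positive_px, img$truth$acrosome_area_px,
               tolerance = 0.05 * img$truth$acrosome_area_px)
  expect_equal(m$area_um2, m$positive_px * 0.04)
  expect_equal(m$head_area_um2, img$truth$head_area_px * 0.04)

  m2 <- acrosome_area(img$channels$acrosome, img$head_mask, pixel_size = 0.4)
  expect_equal(m2$area_um2, 4 * m$area_um2)

  zero <- acrosome_area(img$channels$acrosome * 0, img$head_mask, 0.2)
  expect_equal(zero$area_um2, 0)

  expect_error(acrosome_area(img$channels$acrosome, img$head_mask * 0, 0.2),
               "empty head mask")
  expect_error(acrosome_area(img$channels$acrosome, img$head_mask, -1),
               "pixel_size")
})

test_that("raising the threshold never increases measured acrosome area", {
  img <- render_fixture(acro = 0.4, seed = 3)
  noisy <- img$channels$acrosome +
    with(list(), { set.seed(1); matrix(stats::runif(length(img$head_mask),
                                                    0, 0.2),
                                       nrow(img$head_mask)) })
  areas <- vapply(seq(0.05, 0.95, by = 0.1), function(th)
    acrosome_area(noisy, img$head_mask, 0.2, threshold = th)$area_um2,
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("vacuole detection recovers count and centroids and filters by area", {
  img <- render_fixture(vacuoles = 2, seed = 5)
  v <- detect_vacuoles(img$channels$nuclear, img$head_mask)
  expect_equal(v$count, 2L)
  expect_true(v$has_vacuole)
  # match detected centroids to ground truth within 2 px
  gt <- img$truth$vacuole_centers
  for (k in seq_len(2)) {
    dmin <- min(sqrt((v$centroids[, "row"] - gt[k, 1])^2 +
                     (v$centroids[, "col"] - gt[k, 2])^2))
    expect_lt(dmin, 2)
  }

  # uniform nucleus: nothing detected
  img0 <- render_fixture(vacuoles = 0, seed = 5)
  v0 <- detect_vacuoles(img0$channels$nuclear, img0$head_mask)
  expect_equal(v0$count, 0L)
  expect_false(v0$has_vacuole)

  # min_area filter excludes small vacuoles
  vbig <- detect_vacuoles(img$channels$nuclear, img$head_mask,
                          min_area = 1e4)
  expect_equal(vbig$count, 0L)

  expect_error(detect_vacuoles(img$channels$nuclear, img$head_mask * 0),
               "empty head mask")
})

test_that("detection is invariant to affine intensity rescaling", {
  img <- render_fixture(vacuoles = 2, seed = 8)
  v1 <- detect_vacuoles(img$channels$nuclear, img$head_mask)
  v2 <- detect_vacuoles(0.3 + 2.5 * img$channels$nuclear, img$head_mask)
  expect_equal(v1$count, v2$count)
  expect_equal(v1$centroids, v2$centroids)
})

test_that("prevalence and its Wilson interval match the independent oracle", {
  expect_equal(vacuole_prevalence(rep(FALSE, 100))$fraction, 0)
  p <- vacuole_prevalence(c(rep(TRUE, 33), rep(FALSE, 67)))
  expect_equal(p$fraction, 0.33)
  # prop.test without continuity correction gives the Wilson interval
  ci <- stats::prop.test(33, 100, correct = FALSE)$conf.int
  expect_equal(p$ci_lower, ci[1], tolerance = 1e-9)
  expect_equal(p$ci_upper, ci[2], tolerance = 1e-9)
  expect_error(vacuole_prevalence(logical(0)), "at least one")
})
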