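# Synthetic head contours, rendered channels and motility tracks.

test_that("noise-free contours are simple, CCW, closed and deterministic", {
  p <- head_params(noise_sd = 0)
  ct <- make_head_contour(p, 128)
  expect_equal(dim(ct), c(128L, 2L))
  expect_gt(polygon_area(ct), 0)
  expect_true(spermshape:::polygon_is_simple(ct))

  expect_identical(make_head_contour(p, 128), make_head_contour(p, 128))
  pn <- head_params(noise_sd = 1.5, seed = 99L)
  expect_identical(make_head_contour(pn, 128), make_head_contour(pn, 128))
  pn2 <- head_params(noise_sd = 1.5, seed = 100L)
  expect_false(identical(make_head_contour(pn, 128),
                         make_head_contour(pn2, 128)))
})

test_that("hookless noise-free heads are bilaterally symmetric about the body axis", {
  ct <- make_head_contour(head_params(hook_length = 0, noise_sd = 0), 128)
  # radial profile even in polar angle: point k mirrors point n - k + 2
  mirrored <- ct[c(1L, 128:2), ]
  mirrored[, 2L] <- -mirrored[, 2L]
  expect_lt(max(abs(ct - mirrored)), 1e-9)
})

test_that("hook protrusion increases with hook_length", {
  prot <- vapply(c(0, 10, 20, 30), function(hl)
    hook_protrusion(make_head_contour(head_params(hook_length = hl), 256)),
    numeric(1))
  expect_true(all(diff(prot) > 0))
})

test_that("population draws respect means, SDs, truncation and seed determinism", {
  spec <- population_spec("WT", 5, head_params(), sd = list(), seed = 3)
  pop <- make_population(spec)
  expect_length(pop, 5L)
  expect_true(all(vapply(pop, function(p)
    max(abs(p$contour - pop[[1L]]$contour)) == 0, logical(1))))

  spec2 <- population_spec("KO", 100, head_params(hook_length = 20),
                           sd = list(hook_length = 3), seed = 17)
  pop2 <- make_population(spec2)
  hl <- vapply(pop2, function(p) p$params$hook_length, numeric(1))
  expect_lt(abs(mean(hl) - 20), 3 * 3 / sqrt(100))
  expect_true(all(hl >= 20 - 9 & hl <= 20 + 9))
  expect_identical(make_population(spec2), pop2)

  expect_error(population_spec("X", 0), "n")
  expect_error(population_spec("X", 5, sd = list(nonsense = 1)), "unknown")
  expect_error(population_spec("X", 5, sd = list(hook_length = -1)), "sd")
})

test_that("rendering produces channels consistent with the requested ground truth", {
  ct <- make_head_contour(head_params(), 256)

  r0 <- render_head_image(ct, render_spec(vacuole_count = 0,
                                          acrosome_fraction = 0), seed = 1)
  expect_null(r0$truth$vacuole_centers)
  expect_equal(sum(r0$channels$acrosome), 0)
  # nuclear channel has no interior holes: uniform over the head
  expect_equal(length(unique(r0$channels$nuclear[r0$head_mask > 0])), 1L)

  r2 <- render_head_image(ct, render_spec(vacuole_count = 2,
                                          acrosome_fraction = 0.3), seed = 5)
  expect_equal(nrow(r2$truth$vacuole_centers), 2L)
  dark <- (r2$channels$nuclear < 0.5) & (r2$head_mask > 0)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(dark * 1)))
  expect_equal(max(lab), 2)
  expect_gt(r2$truth$acrosome_area_px, 0)
  expect_identical(render_head_image(ct, render_spec(vacuole_count = 2), seed = 5)$truth,
                   render_head_image(ct, render_spec(vacuole_count = 2), seed = 5)$truth)

  big <- make_head_contour(head_params(body_length = 400, body_width = 200), 128)
  expect_error(render_head_image(big, render_spec()), "fit")
})

test_that("tracks follow their models analytically", {
  tr <- make_track("straight", speed = 100, duration = 1, frame_rate = 60)
  expect_equal(nrow(tr), 61L)
  steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  expect_equal(steps, rep(100 / 60, 60), tolerance = 1e-12)

  tr0 <- make_track("straight", speed = 0)
  expect_equal(max(abs(tr0$x_um)) + max(abs(tr0$y_um)), 0)

  trs <- make_track("sinusoid", speed = 100, amplitude = 5, frequency = 10)
  path <- sum(sqrt(diff(trs$x_um)^2 + diff(trs$y_um)^2))
  chord <- sqrt((trs$x_um[61] - trs$x_um[1])^2 + (trs$y_um[61] - trs$y_um[1])^2)
  expect_gt(path, chord)

  expect_error(make_track("straight", frame_rate = 0), "frame_rate")
  expect_error(make_track("straight", duration = 0.001, frame_rate = 10),
               "2 frames")
  expect_identical(make_track("random_walk", seed = 4),
                   make_track("random_walk", seed = 4))
})
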