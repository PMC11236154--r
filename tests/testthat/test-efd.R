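# Elliptic Fourier decomposition, normalization and reconstruction.

test_that("analytic cases: circle and ellipse match closed-form/oracle values", {
  circ <- circle_points(512)
  e <- efd_decompose(circ, H = 5)
  expect_equal(unname(e$coef[1L, ]), c(1, 0, 0, 1), tolerance = 1e-3)
  expect_lt(max(abs(e$coef[-1L, ])), 1e-3)
  expect_equal(e$A0, 0, tolerance = 1e-9)
  expect_equal(e$C0, 0, tolerance = 1e-9)

  # ellipse, pre-size-normalization, against the quadrature oracle
  ell <- ellipse_points(1024, a = 2, b = 1)
  e2 <- efd_decompose(ell, H = 8)
  orc <- efd_quadrature_oracle(ell, H = 8, subdiv = 40L)
  expect_lt(max(abs(e2$coef - orc$coef)), 1e-6)
  # gross first-harmonic geometry: semi-axes recovered approximately
  # (chain-length parameterization leaks some energy into odd harmonics)
  expect_equal(unname(e2$coef[1L, "a"]), 2, tolerance = 0.1)
  expect_equal(unname(abs(e2$coef[1L, "d"])), 1, tolerance = 0.1)
  expect_lt(abs(e2$coef[1L, "b"]), 1e-9)
  expect_lt(abs(e2$coef[1L, "c"]), 1e-9)
})

test_that("decomposition matches the quadrature oracle on irregular contours", {
  set.seed(42)
  for (i in 1:3) {
    xy <- random_star_contour(256)
    e <- efd_decompose(xy, H = 10)
    orc <- efd_quadrature_oracle(xy, H = 10, subdiv = 40L)
    expect_lt(max(abs(e$coef - orc$coef)), 1e-6)
    expect_equal(e$A0, orc$A0, tolerance = 1e-6)
    expect_equal(e$C0, orc$C0, tolerance = 1e-6)
  }
})

test_that("H = 20 yields the 80-coefficient flat vector; flatten/unflatten is a bijection", {
  xy <- make_head_contour(head_params(), 256)
  v <- efd_flatten(efd_normalize(efd_decompose(xy, H = 20)))
  expect_length(v, 80L)
  expect_named(v[1:4], c("a1", "b1", "c1", "d1"))

  e1 <- efd_normalize(efd_decompose(xy, H = 1))
  expect_length(efd_flatten(e1), 4L)

  back <- efd_unflatten(v, 20)
  expect_equal(efd_flatten(back), v)
  expect_error(efd_unflatten(v[1:79], 20), "length")
})

test_that("normalization invariants hold and the unit circle is the fixed point", {
  n <- efd_normalize(efd_decompose(circle_points(512), H = 6))
  expect_equal(unname(n$coef[1L, ]), c(1, 0, 0, 1), tolerance = 1e-6)
  expect_lt(max(abs(n$coef[-1L, ])), 1e-6)

  set.seed(7)
  xy <- random_star_contour(256)
  nn <- efd_normalize(efd_decompose(xy, H = 12))
  expect_lt(abs(nn$coef[1L, "b"]), 1e-9)
  expect_lt(abs(nn$coef[1L, "c"]), 1e-9)
  expect_equal(unname(nn$coef[1L, "a"]), 1)
  expect_gt(nn$coef[1L, "d"], 0)   # CCW traversal
})

test_that("normalized vectors are invariant to similarity transforms and start shifts", {
  set.seed(123)
  for (i in 1:10) {
    xy <- random_star_contour(200)
    v0 <- efd_flatten(efd_normalize(efd_decompose(xy, H = 10)))
    xy2 <- similarity_transform(xy,
                                angle = stats::runif(1, 0, 2 * pi),
                                scale = stats::runif(1, 0.2, 5),
                                shift = sample.int(200, 1),
                                translation = stats::rnorm(2, 0, 100))
    v1 <- efd_flatten(efd_normalize(efd_decompose(xy2, H = 10)))
    expect_lt(max(abs(v0 - v1)), 1e-6)
  }
})

test_that("mirrored contours differ only in mirror-odd entries; canonical chirality unifies them", {
  set.seed(11)
  xy <- random_star_contour(256)
  xym <- cbind(-xy[, 1L], xy[, 2L])[rev(seq_len(nrow(xy))), ]
  v <- efd_flatten(efd_normalize(efd_decompose(xy, 10)))
  vm <- efd_flatten(efd_normalize(efd_decompose(xym, 10)))
  diff_entries <- names(v)[abs(v - vm) > 1e-9]
  expect_true(all(substr(diff_entries, 1L, 1L) %in% c("b", "c")))
  expect_equal(v[abs(v - vm) <= 1e-9], vm[abs(v - vm) <= 1e-9])

  vc <- efd_flatten(efd_normalize(efd_decompose(xy, 10),
                                  canonical_chirality = TRUE))
  vcm <- efd_flatten(efd_normalize(efd_decompose(xym, 10),
                                   canonical_chirality = TRUE))
  expect_lt(max(abs(vc - vcm)), 1e-6)
})

test_that("reconstruction recovers the contour and error shrinks with H", {
  ct <- make_head_contour(head_params(), 256)
  rec <- efd_reconstruct(efd_decompose(ct, H = 127), 256)
  expect_lt(hausdorff_distance(ct, rec), 0.5)

  hs <- c(1, 2, 5, 10, 20, 50, 127)
  errs <- vapply(hs, function(h)
    hausdorff_distance(ct, efd_reconstruct(efd_decompose(ct, h), 512)),
    numeric(1))
  # non-increasing up to the sampling wobble at the converged plateau
  expect_true(all(diff(errs) <= 1e-3))

  # pure first harmonic reconstructs the unit circle
  circ <- efd_reconstruct(efd_unflatten(c(1, 0, 0, 1), 1), 64)
  expect_equal(sqrt(rowSums(circ^2)), rep(1, 64), tolerance = 1e-9)

  # H = 1 reconstruction is the best-fit first-harmonic ellipse
  e1 <- efd_decompose(ct, 1)
  rec1 <- efd_reconstruct(e1, 512, include_dc = FALSE)
  expect_equal(abs(polygon_area(rec1)),
               unname(pi * abs(e1$coef[1, "a"] * e1$coef[1, "d"] -
                               e1$coef[1, "b"] * e1$coef[1, "c"])),
               tolerance = 0.01)
})

test_that("Parseval-style scaling: coefficient energy scales with the square of size", {
  set.seed(5)
  xy <- random_star_contour(128)
  e1 <- efd_decompose(xy, 10)
  e3 <- efd_decompose(xy * 3, 10)
  expect_equal(sum(e3$coef^2), 9 * sum(e1$coef^2), tolerance = 1e-9)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(efd_decompose(circle_points(64), H = 0), "H")
  expect_error(efd_decompose(matrix(c(0, 0, 0, 0, 0, 0), 3, 2), H = 2),
               "perimeter|distinct")
  e <- efd_decompose(circle_points(64), 3)
  e$coef[1L, ] <- 0
  expect_error(efd_normalize(e), "degenerate first harmonic")
  expect_error(efd_reconstruct(e, 4), "n_points")
})
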