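# Elliptic Fourier descriptors of closed contours.
#
# A closed polygon (x_i, y_i), traversed counterclockwise, is represented by
# the truncated elliptic Fourier series
#
#   x(t) = A0 + sum_n a_n cos(2 pi n t / T) + b_n sin(2 pi n t / T)
#   y(t) = C0 + sum_n c_n cos(2 pi n t / T) + d_n sin(2 pi n t / T)
#
# with t the cumulative chain (arc) length along the polygon and T its
# perimeter.  Because x(t) and y(t) are piecewise linear in t, the harmonic
# integrals have the classical closed form in the segment increments
# (Kuhl-Giardina), which is what decompose() evaluates.

#' Elliptic Fourier decomposition of a closed contour
#'
#' Computes the first `H` harmonics of the elliptic Fourier series of a
#' counterclockwise closed polygon, using the polygon's own segment lengths
#' as the chain parameterization, plus the DC offsets `A0`, `C0` (the
#' arc-length mean of the outline).
#'
#' @param contour n x 2 numeric matrix of (x, y) vertices, counterclockwise,
#'   implicitly closed. At least `2 * H + 1` points are recommended so the
#'   highest harmonic is sampled above its Nyquist rate.
#' @param H number of harmonics (>= 1); 20 is the conventional choice for
#'   sperm-head outlines, giving an 80-coefficient shape code.
#' @return An object of class `efd`: list with `H`, `coef` (H x 4 matrix,
#'   columns `a`, `b`, `c`, `d`), `A0`, `C0`, and perimeter `T`.
#' @seealso [efd_normalize()], [efd_reconstruct()], [efd_flatten()]
#' @examples
#' th <- seq(0, 2 * pi, length.out = 257)[-257]
#' circle <- cbind(cos(th), sin(th))
#' e <- efd_decompose(circle, H = 4)
#' round(e$coef[1, ], 3)  # ~ (1, 0, 0, 1)
#' @export
efd_decompose <- function(contour, H = 20L) {
  if (!is.numeric(H) || length(H) != 1L || H < 1 || H != round(H))
    stop_param("H", "must be a single integer >= 1")
  H <- as.integer(H)
  xy <- as_contour_matrix(contour, check_orientation = FALSE)

  dxy <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE]) - xy
  dt <- sqrt(rowSums(dxy^2))
  if (sum(dt) < .Machine$double.eps)
    stop("degenerate contour: zero perimeter", call. = FALSE)
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  T <- t1[length(t1)]

  n <- seq_len(H)
  w <- 2 * pi / T
  # cos/sin of n * w * t at segment ends, K x H
  c1 <- cos(outer(t1, n * w)); c0 <- cos(outer(t0, n * w))
  s1 <- sin(outer(t1, n * w)); s0 <- sin(outer(t0, n * w))
  vx <- dxy[, 1L] / dt
  vy <- dxy[, 2L] / dt
  k <- T / (2 * pi^2 * n^2)
  a <- k * colSums(vx * (c1 - c0))
  b <- k * colSums(vx * (s1 - s0))
  cc <- k * colSums(vy * (c1 - c0))
  d <- k * colSums(vy * (s1 - s0))

  # DC terms: arc-length mean of the piecewise-linear outline (exact
  # trapezoid since x, y are linear in t on each segment)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  A0 <- sum(dt * (x + xn) / 2) / T
  C0 <- sum(dt * (y + yn) / 2) / T

  structure(
    list(H = H,
         coef = cbind(a = a, b = b, c = cc, d = d),
         A0 = A0, C0 = C0, T = T),
    class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat(sprintf("Elliptic Fourier descriptors: %d harmonic%s, perimeter %.4g\n",
              x$H, if (x$H > 1) "s" else "", x$T))
  cat(sprintf("  DC offset (A0, C0) = (%.4g, %.4g)\n", x$A0, x$C0))
  cat("  first harmonic (a1, b1, c1, d1) =",
      paste(sprintf("%.4g", x$coef[1L, ]), collapse = ", "), "\n")
  invisible(x)
}

# 2x2 rotation matrix of angle theta (active, counterclockwise)
rot2 <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, -st, ct), 2L, 2L)
}

# Apply starting-point phase theta (right-multiply harmonic n by rot2(n *
# theta)), spatial rotation -psi (left-multiply by rot2(-psi)) and scale
# division to an H x 4 coefficient matrix. Vectorized over harmonics.
transform_coef <- function(coef, theta = 0, psi = 0, scale = 1,
                           mirror = FALSE) {
  a <- coef[, "a"]; b <- coef[, "b"]; cc <- coef[, "c"]; d <- coef[, "d"]
  if (mirror) {
    # x -> -x with traversal order reversed so orientation is preserved:
    # a -> -a, d -> -d per harmonic (b, c unchanged); see methods vignette
    a <- -a; d <- -d
  }
  if (theta != 0) {
    nh <- seq_along(a)
    cn <- cos(nh * theta); sn <- sin(nh * theta)
    a2 <- a * cn + b * sn; b2 <- -a * sn + b * cn
    c2 <- cc * cn + d * sn; d2 <- -cc * sn + d * cn
    a <- a2; b <- b2; cc <- c2; d <- d2
  }
  if (psi != 0) {
    cp <- cos(psi); sp <- sin(psi)
    a2 <- cp * a + sp * cc; b2 <- cp * b + sp * d
    c2 <- -sp * a + cp * cc; d2 <- -sp * b + cp * d
    a <- a2; b <- b2; cc <- c2; d <- d2
  }
  cbind(a = a, b = b, c = cc, d = d) / scale
}

# Fully normalize one candidate defined by a start-phase theta and a mirror
# flag: remove the starting-point phase, rotate the first-harmonic major
# axis onto +x, divide by the post-rotation a1. Returns list(coef, psi).
normalize_candidate <- function(coef, theta, mirror,
                                do_rotation = TRUE, do_scale = TRUE) {
  co <- transform_coef(coef, theta = theta, mirror = mirror)
  psi <- 0
  if (do_rotation) {
    psi <- atan2(co[1L, "c"], co[1L, "a"])
    co <- transform_coef(co, psi = psi)
  }
  scale <- 1
  if (do_scale) {
    scale <- co[1L, "a"]
    if (abs(scale) < .Machine$double.eps)
      stop("degenerate first harmonic: cannot size-normalize", call. = FALSE)
    co <- co / scale
  }
  list(coef = co, psi = psi, scale = scale)
}

# Lexicographic comparison of flattened coefficient vectors with a tie
# tolerance, used to break the residual two-fold normalization ambiguities
# deterministically.  Returns TRUE if v1 >= v2.
lex_ge <- function(v1, v2, tol = 1e-9) {
  d <- v1 - v2
  i <- which(abs(d) > tol)
  if (length(i) == 0L) return(TRUE)
  d[i[1L]] > 0
}

#' Kuhl-Giardina normalization of elliptic Fourier coefficients
#'
#' Removes the dependence of the coefficients on the contour's starting
#' point, spatial rotation and size, so that coefficient vectors of
#' different specimens are directly comparable.  Translation never enters:
#' the DC offsets are stored separately and excluded from the flat vector.
#'
#' The starting-point phase is
#' `theta1 = 0.5 * atan2(2 * (a1 b1 + c1 d1), a1^2 + c1^2 - b1^2 - d1^2)`,
#' applied per harmonic `n` as a right-rotation by `n * theta1`; the
#' orientation `psi1 = atan2(c1', a1')` is removed by a left-rotation, and
#' all coefficients are divided by the post-rotation `a1`.  The half-angle
#' formula leaves a two-fold ambiguity (`theta1` vs `theta1 + pi`: the
#' starting point lands on either end of the first-harmonic major axis,
#' flipping the sign of every even harmonic); both candidates satisfy
#' `a1 > 0`, so the larger coefficient vector in lexicographic order is
#' selected, which makes the result invariant to arbitrary start shifts.
#'
#' For counterclockwise contours `d1 > 0` on output; `d1` would be negative
#' only for clockwise traversal, so its sign records orientation, not the
#' handedness of the shape.  Handedness (e.g. a left- vs right-pointing
#' hook) lives in the signs of the mirror-odd coefficients and is preserved
#' by default; with `canonical_chirality = TRUE` a shape and its mirror
#' image normalize to the same vector (useful when slides may be imaged
#' flipped).
#'
#' @param coeffs an `efd` object from [efd_decompose()].
#' @param do_scale,do_rotation,do_start logical; which invariances to apply.
#' @param canonical_chirality logical; if `TRUE`, mirror images map to a
#'   single canonical vector.
#' @return An object of class `efd_norm`: the normalized coefficients plus a
#'   `normalization` record (`scale`, `psi1`, `theta1`, `mirrored`,
#'   `orientation_d1`).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 257)[-257]
#' e <- efd_normalize(efd_decompose(cbind(2 * cos(th), sin(th)), H = 3))
#' round(e$coef[1, ], 6)  # (1, 0, 0, 0.5): ellipse scaled by a1 = 2
#' @export
efd_normalize <- function(coeffs, do_scale = TRUE, do_rotation = TRUE,
                          do_start = TRUE, canonical_chirality = FALSE) {
  if (!inherits(coeffs, "efd"))
    stop_param("coeffs", "must be an 'efd' object from efd_decompose()")
  co <- coeffs$coef
  e1 <- sum(co[1L, ]^2)
  if (e1 < .Machine$double.eps)
    stop("degenerate first harmonic: zero first-harmonic energy",
         call. = FALSE)

  start_phase <- function(cm) {
    a1 <- cm[1L, "a"]; b1 <- cm[1L, "b"]
    c1 <- cm[1L, "c"]; d1 <- cm[1L, "d"]
    0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  }

  mirrors <- if (canonical_chirality) c(FALSE, TRUE) else FALSE
  cands <- list()
  for (m in mirrors) {
    com <- if (m) transform_coef(co, mirror = TRUE) else co
    theta1 <- if (do_start) start_phase(com) else 0
    thetas <- if (do_start) c(theta1, theta1 + pi) else 0
    for (th in thetas) {
      cand <- normalize_candidate(com, theta = th, mirror = FALSE,
                                  do_rotation = do_rotation,
                                  do_scale = do_scale)
      cand$theta <- th
      cand$mirror <- m
      cands[[length(cands) + 1L]] <- cand
    }
  }
  best <- cands[[1L]]
  for (cand in cands[-1L]) {
    if (!lex_ge(as.vector(t(best$coef)), as.vector(t(cand$coef))))
      best <- cand
  }

  structure(
    list(H = coeffs$H, coef = best$coef, A0 = coeffs$A0, C0 = coeffs$C0,
         T = coeffs$T,
         normalization = list(
           scale = best$scale, psi1 = best$psi, theta1 = best$theta,
           mirrored = best$mirror,
           orientation_d1 = sign(best$coef[1L, "d"]))),
    class = c("efd_norm", "efd"))
}

#' @export
print.efd_norm <- function(x, ...) {
  nz <- x$normalization
  cat(sprintf(
    "Normalized EFDs: %d harmonics (scale %.4g, psi1 %.4g rad, theta1 %.4g rad%s)\n",
    x$H, nz$scale, nz$psi1, nz$theta1,
    if (isTRUE(nz$mirrored)) ", mirrored" else ""))
  cat("  first harmonic (a1, b1, c1, d1) =",
      paste(sprintf("%.4g", x$coef[1L, ]), collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct a contour from elliptic Fourier coefficients
#'
#' Evaluates the truncated elliptic Fourier series at `n_points` uniformly
#' spaced parameter values. DC offsets are included when present (raw
#' coefficients); normalized coefficient sets reconstruct centered at the
#' origin.
#'
#' @param coeffs an `efd` or `efd_norm` object, or an H x 4 coefficient
#'   matrix.
#' @param n_points number of points to evaluate (>= 8).
#' @param include_dc logical; include the `A0`, `C0` offsets if available.
#' @return n_points x 2 matrix of (x, y), counterclockwise for
#'   counterclockwise input.
#' @export
efd_reconstruct <- function(coeffs, n_points = 256L, include_dc = TRUE) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 8)
    stop_param("n_points", "must be a single integer >= 8")
  n_points <- as.integer(n_points)
  if (is.matrix(coeffs)) {
    co <- coeffs; A0 <- 0; C0 <- 0
  } else if (inherits(coeffs, "efd")) {
    co <- coeffs$coef
    A0 <- if (include_dc && inherits(coeffs, "efd_norm")) 0 else
      if (include_dc) coeffs$A0 else 0
    C0 <- if (include_dc && inherits(coeffs, "efd_norm")) 0 else
      if (include_dc) coeffs$C0 else 0
  } else stop_param("coeffs", "must be an 'efd' object or coefficient matrix")
  H <- nrow(co)
  tt <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  arg <- outer(tt, seq_len(H))                     # n_points x H
  ca <- cos(arg); sa <- sin(arg)
  x <- A0 + ca %*% co[, "a"] + sa %*% co[, "b"]
  y <- C0 + ca %*% co[, "c"] + sa %*% co[, "d"]
  cbind(x = as.vector(x), y = as.vector(y))
}

#' Flatten normalized coefficients into the 4H shape vector
#'
#' Concatenates the per-harmonic quadruples as
#' `(a1, b1, c1, d1, a2, ..., dH)`. The DC (translation) terms are excluded,
#' so 20 harmonics yield the standard 80-coefficient shape code.
#'
#' @param coeffs an `efd` or `efd_norm` object.
#' @return Named numeric vector of length `4 * H`.
#' @export
efd_flatten <- function(coeffs) {
  if (!inherits(coeffs, "efd"))
    stop_param("coeffs", "must be an 'efd' object")
  v <- as.vector(t(coeffs$coef))
  names(v) <- paste0(rep(c("a", "b", "c", "d"), coeffs$H),
                     rep(seq_len(coeffs$H), each = 4L))
  v
}

#' Rebuild an efd object from a flat coefficient vector
#'
#' Inverse of [efd_flatten()] up to the dropped DC terms, which are set to
#' zero (reconstructions are origin-centered).
#'
#' @param vector numeric vector of length `4 * H`.
#' @param H harmonic count.
#' @return An `efd_norm` object with zero DC offsets.
#' @export
efd_unflatten <- function(vector, H = length(vector) %/% 4L) {
  if (length(vector) != 4L * H)
    stop(sprintf("coefficient vector has length %d; expected 4 * H = %d",
                 length(vector), 4L * H), call. = FALSE)
  co <- matrix(vector, ncol = 4L, byrow = TRUE)
  colnames(co) <- c("a", "b", "c", "d")
  structure(
    list(H = as.integer(H), coef = co, A0 = 0, C0 = 0, T = NA_real_,
         normalization = NULL),
    class = c("efd_norm", "efd"))
}
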