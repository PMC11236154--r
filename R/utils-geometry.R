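#' @keywords internal
"_PACKAGE"

# Shared polygon geometry helpers. Contours throughout the package are
# n x 2 numeric matrices (columns x, y) in Cartesian y-up coordinates,
# implicitly closed (last vertex connects back to the first) and oriented
# counterclockwise (positive shoelace area).

#' Signed (shoelace) area of a closed polygon
#'
#' Positive for counterclockwise vertex order in y-up coordinates.
#'
#' @param xy n x 2 numeric matrix of vertices (implicitly closed).
#' @return Signed area (squared coordinate units).
#' @export
polygon_area <- function(xy) {
  xy <- as_contour_matrix(xy, check_orientation = FALSE)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Perimeter of a closed polygon
#'
#' @inheritParams polygon_area
#' @return Total edge length including the closing edge.
#' @export
polygon_perimeter <- function(xy) {
  xy <- as_contour_matrix(xy, check_orientation = FALSE)
  d <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE]) - xy
  sum(sqrt(rowSums(d^2)))
}

# Coerce and validate a contour matrix. Drops consecutive duplicate points
# (within 1e-12) so degenerate zero-length edges never reach arc-length code.
as_contour_matrix <- function(xy, check_orientation = TRUE, min_points = 3L) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || !is.numeric(xy))
    stop("contour must be an n x 2 numeric matrix of (x, y) points",
         call. = FALSE)
  if (anyNA(xy) || any(!is.finite(xy)))
    stop("contour coordinates must be finite", call. = FALSE)
  # drop consecutive duplicates, including a duplicated closing vertex
  if (nrow(xy) > 1L) {
    d <- rowSums(abs(rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE]) - xy))
    keep <- c(TRUE, d[-length(d)] > 1e-12)
    if (d[length(d)] <= 1e-12) keep[length(keep)] <- FALSE
    xy <- xy[keep, , drop = FALSE]
  }
  if (nrow(xy) < min_points)
    stop("contour needs at least ", min_points, " distinct points",
         call. = FALSE)
  if (check_orientation && polygon_area(xy) <= 0)
    stop("contour must be counterclockwise (positive signed area)",
         call. = FALSE)
  dimnames(xy) <- list(NULL, c("x", "y"))
  xy
}

# Centroid of the polygon interior (area centroid, not vertex mean).
polygon_centroid <- function(xy) {
  xy <- as_contour_matrix(xy, check_orientation = FALSE)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps)
    return(colMeans(xy))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Symmetric Hausdorff distance between two closed polygons
#'
#' Distances are measured from the vertices of one polygon to the edges
#' (not just the vertices) of the other, so the result does not saturate at
#' half the vertex spacing. Used to compare a reconstructed contour against
#' its source polygon.
#'
#' @param a,b n x 2 numeric matrices of polygon vertices (implicitly
#'   closed).
#' @return max over both directions of the vertex-to-polygon distance.
#' @export
hausdorff_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

# max over points of `pts` of the distance to the closed polyline `poly`
directed_hausdorff <- function(pts, poly) {
  p1 <- poly
  p2 <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE])
  e <- p2 - p1
  len2 <- pmax(rowSums(e^2), .Machine$double.eps)
  # t = clamp(((pts - p1) . e) / |e|^2, 0, 1), per point x edge
  tx <- (outer(pts[, 1L], p1[, 1L], "-") * rep(e[, 1L], each = nrow(pts)) +
         outer(pts[, 2L], p1[, 2L], "-") * rep(e[, 2L], each = nrow(pts))) /
    rep(len2, each = nrow(pts))
  tx <- pmin(pmax(tx, 0), 1)
  dx <- outer(pts[, 1L], p1[, 1L], "-") - tx * rep(e[, 1L], each = nrow(pts))
  dy <- outer(pts[, 2L], p1[, 2L], "-") - tx * rep(e[, 2L], each = nrow(pts))
  max(sqrt(apply(dx^2 + dy^2, 1L, min)))
}

# Test points against a polygon with the even-odd crossing rule, vectorised
# over points (one pass per polygon edge). px, py numeric vectors.
points_in_polygon <- function(px, py, poly) {
  poly <- as_contour_matrix(poly, check_orientation = FALSE)
  n <- nrow(poly)
  inside <- logical(length(px))
  xj <- poly[n, 1L]; yj <- poly[n, 2L]
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    xj <- xi; yj <- yi
  }
  inside
}

# Does any edge pair of a simple-closed candidate polygon intersect
# (excluding adjacent edges)? O(n^2); used only in tests/validation.
polygon_is_simple <- function(xy) {
  xy <- as_contour_matrix(xy, check_orientation = FALSE)
  n <- nrow(xy)
  p1 <- xy
  p2 <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- a2 - a1; d2 <- b2 - b1
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((b1[1L] - a1[1L]) * d2[2L] - (b1[2L] - a1[2L]) * d2[1L]) / den
    u <- ((b1[1L] - a1[1L]) * d1[2L] - (b1[2L] - a1[2L]) * d1[1L]) / den
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (seg_int(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Evaluate a function with a temporary RNG seed, restoring the caller's
# RNG state afterwards so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}
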