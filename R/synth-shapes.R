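# Synthetic sperm-head shapes, rendered channels and motility tracks.
#
# The head-shape family is a star-shaped radial profile: a superellipse-like
# ovoid body (length x width) plus a localized radial bump — the apical
# hook — centered at hook_angle, with amplitude hook_length and angular
# concentration set by hook_sharpness.  Being single-valued in polar angle,
# every noise-free contour is a simple counterclockwise polygon by
# construction.  The two leading parameters (body_width, hook_length) are
# the axes of variation that shape PCA is expected to recover.

#' Parameters of a synthetic sperm head
#'
#' @param body_length,body_width ovoid body axes, px.
#' @param hook_length radial amplitude of the apical hook, px (>= 0).
#' @param hook_angle direction of the hook apex, radians.
#' @param hook_sharpness dimensionless concentration of the hook bump;
#'   larger values give a narrower, sharper hook.
#' @param noise_sd radial boundary jitter SD, px (>= 0).
#' @param seed integer RNG seed for the jitter (ignored when `noise_sd = 0`).
#' @return A `head_params` list.
#' @export
head_params <- function(body_length = 80, body_width = 45,
                        hook_length = 25, hook_angle = pi / 2,
                        hook_sharpness = 12, noise_sd = 0, seed = 1L) {
  if (!is.numeric(body_length) || body_length <= 0)
    stop_param("body_length", "must be > 0")
  if (!is.numeric(body_width) || body_width <= 0)
    stop_param("body_width", "must be > 0")
  if (!is.numeric(hook_length) || hook_length < 0)
    stop_param("hook_length", "must be >= 0")
  if (!is.numeric(hook_angle) || !is.finite(hook_angle))
    stop_param("hook_angle", "must be finite")
  if (!is.numeric(hook_sharpness) || hook_sharpness <= 0)
    stop_param("hook_sharpness", "must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_param("noise_sd", "must be >= 0")
  structure(list(body_length = body_length, body_width = body_width,
                 hook_length = hook_length, hook_angle = hook_angle,
                 hook_sharpness = hook_sharpness, noise_sd = noise_sd,
                 seed = seed),
            class = "head_params")
}

#' Generate one synthetic sperm-head contour
#'
#' Deterministic given `params$seed`. The boundary is sampled at `n_points`
#' uniformly spaced polar angles; radial Gaussian jitter (if any) is
#' smoothed with a periodic moving average so the contour stays closed and
#' simple.
#'
#' @param params a [head_params()] object.
#' @param n_points number of contour points (>= 32).
#' @return `n_points` x 2 matrix (x, y), counterclockwise, centered near the
#'   origin, with the generating `head_params` attached as attribute
#'   `"params"`.
#' @export
make_head_contour <- function(params, n_points = 256L) {
  if (!inherits(params, "head_params")) params <- do.call(head_params, params)
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 32)
    stop_param("n_points", "must be a single integer >= 32")
  n_points <- as.integer(n_points)

  phi <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  r <- head_radius(phi, params)
  if (params$noise_sd > 0) {
    jit <- with_seed(params$seed, stats::rnorm(n_points, 0, params$noise_sd))
    jit <- periodic_smooth(jit, width = max(5L, n_points %/% 32L))
    r <- pmax(r + jit, 0.1 * min(params$body_length, params$body_width))
  }
  xy <- cbind(x = r * cos(phi), y = r * sin(phi))
  attr(xy, "params") <- params
  xy
}

# Radial profile: superellipse body plus a von-Mises-shaped hook bump.
head_radius <- function(phi, params) {
  a <- params$body_length / 2
  b <- params$body_width / 2
  p <- 2.5                                 # superellipse exponent: ovoid body
  body <- (abs(cos(phi) / a)^p + abs(sin(phi) / b)^p)^(-1 / p)
  dphi <- angle_diff(phi, params$hook_angle)
  hook <- params$hook_length *
    exp(params$hook_sharpness * (cos(dphi) - 1))
  body + hook
}

angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Circular moving average of width `width` (forced odd).
periodic_smooth <- function(x, width = 5L) {
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  if (width <= 1L) return(x)
  h <- width %/% 2L
  n <- length(x)
  xx <- c(x[(n - h + 1L):n], x, x[1L:h])
  as.vector(stats::filter(xx, rep(1 / width, width), sides = 2L))[(h + 1L):(h + n)]
}

#' Hook-tip protrusion of a head contour
#'
#' Distance from the body (area) centroid to the farthest contour point in
#' the hook direction; increases monotonically with `hook_length` for
#' noise-free contours. Used as the ground-truth hook measure in parameter
#' recovery experiments.
#'
#' @param contour an n x 2 contour matrix.
#' @param hook_angle direction in which to look for the hook apex, radians;
#'   taken from the attached `head_params` when omitted.
#' @return Protrusion in the contour's coordinate units.
#' @export
hook_protrusion <- function(contour, hook_angle = NULL) {
  p <- attr(contour, "params")
  if (is.null(hook_angle)) {
    if (is.null(p)) stop_param("hook_angle",
      "required when contour has no attached head_params")
    hook_angle <- p$hook_angle
  }
  ctr <- polygon_centroid(contour)
  v <- sweep(as_contour_matrix(contour, check_orientation = FALSE), 2L, ctr)
  ang <- atan2(v[, 2L], v[, 1L])
  sel <- abs(angle_diff(ang, hook_angle)) < pi / 6
  if (!any(sel)) sel <- rep(TRUE, nrow(v))
  max(sqrt(rowSums(v[sel, , drop = FALSE]^2)))
}

#' Specification of a synthetic head population
#'
#' Per-parameter normal distributions (means from `params`, SDs from `sd`)
#' from which specimen-level head parameters are drawn, truncated to
#' `mean +/- 3 SD` and to physical bounds (positive sizes, non-negative
#' hook and noise).
#'
#' @param label group label (e.g. genotype).
#' @param n number of specimens (>= 1).
#' @param params a [head_params()] object of population means.
#' @param sd named list/vector of per-parameter SDs (any subset of
#'   `body_length`, `body_width`, `hook_length`, `hook_angle`,
#'   `hook_sharpness`); unnamed parameters are held fixed.
#' @param render a [render_spec()] or NULL.
#' @param seed integer seed.
#' @return A `population_spec` list.
#' @export
population_spec <- function(label, n, params = head_params(),
                            sd = list(), render = NULL, seed = 1L) {
  if (!is.character(label) || length(label) != 1L)
    stop_param("label", "must be a single string")
  if (!is.numeric(n) || n < 1) stop_param("n", "must be >= 1")
  sd <- as.list(sd)
  if (length(sd) && any(unlist(sd) < 0)) stop_param("sd", "SDs must be >= 0")
  bad <- setdiff(names(sd),
                 c("body_length", "body_width", "hook_length",
                   "hook_angle", "hook_sharpness"))
  if (length(bad)) stop_param("sd", paste("unknown parameter(s):",
                                          paste(bad, collapse = ", ")))
  structure(list(label = label, n = as.integer(n),
                 params = if (inherits(params, "head_params")) params
                          else do.call(head_params, params),
                 sd = sd, render = render, seed = seed),
            class = "population_spec")
}

#' Draw a population of synthetic head contours
#'
#' @param spec a [population_spec()].
#' @param n_points contour points per specimen.
#' @return A list with one element per specimen: `specimen_id`, `contour`
#'   (with attached `head_params`), and `params` (the realized ground
#'   truth).
#' @export
make_population <- function(spec, n_points = 256L) {
  if (!inherits(spec, "population_spec"))
    stop_param("spec", "must be a population_spec")
  lower <- c(body_length = 1, body_width = 1, hook_length = 0,
             hook_angle = -Inf, hook_sharpness = 0.5)
  draws <- with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(i) {
      p <- spec$params
      for (nm in names(spec$sd)) {
        s <- spec$sd[[nm]]
        if (s > 0) {
          v <- stats::rnorm(1L, p[[nm]], s)
          v <- min(max(v, p[[nm]] - 3 * s), p[[nm]] + 3 * s)
          p[[nm]] <- max(v, lower[[nm]])
        }
      }
      p$seed <- spec$seed * 1000L + i
      p
    })
  })
  lapply(seq_along(draws), function(i) {
    p <- draws[[i]]
    list(specimen_id = sprintf("%s_%03d", spec$label, i),
         contour = make_head_contour(p, n_points),
         params = p)
  })
}

#' Rendering specification for synthetic microscopy channels
#'
#' @param pixel_size micrometers per pixel (> 0).
#' @param image_shape integer (rows, cols).
#' @param vacuole_count number of nuclear vacuoles (>= 0).
#' @param vacuole_radius vacuole disk radius, px.
#' @param acrosome_fraction fraction of the head perimeter covered by the
#'   anterior acrosome crescent, in [0, 1].
#' @param channels names of the emulated channels, in order.
#' @return A `render_spec` list.
#' @export
render_spec <- function(pixel_size = 0.2, image_shape = c(160L, 160L),
                        vacuole_count = 0L, vacuole_radius = 4,
                        acrosome_fraction = 0.35,
                        channels = c("head", "nuclear", "acrosome")) {
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_param("pixel_size", "must be > 0")
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop_param("image_shape", "must be (rows, cols), each >= 8")
  if (vacuole_count < 0) stop_param("vacuole_count", "must be >= 0")
  if (vacuole_radius <= 0) stop_param("vacuole_radius", "must be > 0")
  if (acrosome_fraction < 0 || acrosome_fraction > 1)
    stop_param("acrosome_fraction", "must be in [0, 1]")
  structure(list(pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 vacuole_count = as.integer(vacuole_count),
                 vacuole_radius = vacuole_radius,
                 acrosome_fraction = acrosome_fraction,
                 channels = channels),
            class = "render_spec")
}

#' Render a head contour into multi-channel images with ground truth
#'
#' Produces a binary head mask, a nuclear channel (bright nucleus with
#' `vacuole_count` dark disks placed fully inside the eroded head by
#' rejection sampling), and an acrosome channel covering
#' `acrosome_fraction` of an anterior boundary band.  Images are matrices
#' indexed `[row, col]` with row 1 at the top; the contour's y-up
#' coordinates are mapped to rows internally.  Intensities are in [0, 1].
#'
#' @param contour n x 2 contour matrix, centered near the origin.
#' @param spec a [render_spec()].
#' @param seed RNG seed for vacuole placement.
#' @return List: `channels` (named list of matrices), `head_mask` (0/1
#'   matrix), `truth` (vacuole centers as matrix of (row, col), acrosome
#'   pixel area, head pixel area).
#' @export
render_head_image <- function(contour, spec = render_spec(), seed = 1L) {
  xy <- as_contour_matrix(contour)
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  # center the contour in the image; y-up -> row-down
  ctr <- polygon_centroid(xy)
  col0 <- (nc + 1) / 2; row0 <- (nr + 1) / 2
  pc <- xy[, 1L] - ctr[1L] + col0          # columns
  pr <- row0 - (xy[, 2L] - ctr[2L])        # rows
  if (min(pc) < 2 || max(pc) > nc - 1 || min(pr) < 2 || max(pr) > nr - 1)
    stop("contour does not fit in image_shape with a 1 px margin",
         call. = FALSE)
  poly <- cbind(pc, pr)

  grid_c <- rep(seq_len(nc), each = nr)
  grid_r <- rep(seq_len(nr), times = nc)
  inside <- points_in_polygon(grid_c, grid_r, poly)
  head_mask <- matrix(as.numeric(inside), nr, nc)

  # vacuoles: rejection-sample non-overlapping disks fully inside the head
  vac_centers <- NULL
  nuclear <- head_mask * 0.9
  if (spec$vacuole_count > 0L) {
    rad <- spec$vacuole_radius
    er <- erode_mask(head_mask, ceiling(rad) + 1L)
    cand <- which(er > 0)
    if (length(cand) == 0L)
      stop("head too small to place vacuoles of this radius", call. = FALSE)
    vac_centers <- with_seed(seed, {
      centers <- matrix(numeric(0), 0L, 2L)
      for (k in seq_len(spec$vacuole_count)) {
        ok <- FALSE
        for (attempt in seq_len(100L)) {
          idx <- cand[sample.int(length(cand), 1L)]
          rr <- (idx - 1L) %% nr + 1L
          cc <- (idx - 1L) %/% nr + 1L
          if (nrow(centers) == 0L ||
              all(sqrt((centers[, 1L] - rr)^2 + (centers[, 2L] - cc)^2) >
                  2 * rad + 1)) {
            centers <- rbind(centers, c(rr, cc))
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place non-overlapping vacuoles in 100 attempts",
                      call. = FALSE)
      }
      centers
    })
    for (k in seq_len(nrow(vac_centers))) {
      d2 <- (grid_r - vac_centers[k, 1L])^2 + (grid_c - vac_centers[k, 2L])^2
      hole <- matrix(as.numeric(d2 <= rad^2), nr, nc) * head_mask
      nuclear <- nuclear * (1 - hole) + hole * 0.1
    }
  }

  # acrosome: boundary band restricted to an arc of the requested fraction
  acro <- matrix(0, nr, nc)
  acro_area_px <- 0L
  if (spec$acrosome_fraction > 0) {
    band <- head_mask - erode_mask(head_mask, 4L)
    bidx <- which(band > 0)
    if (length(bidx)) {
      brr <- (bidx - 1L) %% nr + 1L
      bcc <- (bidx - 1L) %/% nr + 1L
      # arc selection by cumulative perimeter position of the nearest vertex
      seg <- sqrt(rowSums((rbind(poly[-1L, ], poly[1L, ]) - poly)^2))
      cum <- c(0, cumsum(seg))[seq_len(nrow(poly))]
      per <- sum(seg)
      # anterior-most boundary point (apex = topmost row) starts the arc
      apex <- which.min(poly[, 2L])
      pos <- (cum - cum[apex]) %% per
      half <- spec$acrosome_fraction * per / 2
      on_arc <- pos <= half | pos >= per - half
      d2 <- outer(brr, poly[, 2L], "-")^2 + outer(bcc, poly[, 1L], "-")^2
      nearest <- max.col(-d2, ties.method = "first")
      keep <- bidx[on_arc[nearest]]
      acro[keep] <- 0.85
      acro_area_px <- length(keep)
    }
  }

  channels <- list(head = head_mask, nuclear = nuclear, acrosome = acro)
  list(channels = channels[spec$channels],
       head_mask = head_mask,
       truth = list(vacuole_centers = vac_centers,
                    acrosome_area_px = acro_area_px,
                    head_area_px = sum(head_mask)))
}

# Binary erosion with a disc structuring element (EBImage).
erode_mask <- function(mask, radius) {
  size <- 2L * as.integer(radius) + 1L
  if (size < 3L) return(mask)
  kern <- EBImage::makeBrush(size, shape = "disc")
  as.matrix(EBImage::erode(mask, kern))
}

dilate_mask <- function(mask, radius) {
  size <- 2L * as.integer(radius) + 1L
  if (size < 3L) return(mask)
  kern <- EBImage::makeBrush(size, shape = "disc")
  as.matrix(EBImage::dilate(mask, kern))
}

#' Generate a synthetic motility track
#'
#' @param model `"straight"`, `"sinusoid"` or `"random_walk"`.
#' @param speed progressive speed, um/s.
#' @param amplitude lateral oscillation amplitude, um (sinusoid only).
#' @param frequency oscillation frequency, Hz (sinusoid only).
#' @param duration track duration, s.
#' @param frame_rate frames per second (> 0); `duration * frame_rate` must
#'   give at least 2 frames.
#' @param seed RNG seed (random walk only).
#' @return A `track` object: data.frame with `frame`, `t_seconds`, `x_um`,
#'   `y_um`, plus the generating parameters as attribute `"model"`.
#' @export
make_track <- function(model = c("straight", "sinusoid", "random_walk"),
                       speed = 100, amplitude = 5, frequency = 10,
                       duration = 1, frame_rate = 60, seed = 1L) {
  model <- match.arg(model)
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop_param("frame_rate", "must be > 0")
  n_frames <- floor(duration * frame_rate) + 1L
  if (n_frames < 2L) stop_param("duration",
    "duration * frame_rate must give at least 2 frames")
  t <- (seq_len(n_frames) - 1L) / frame_rate
  xy <- switch(model,
    straight = cbind(speed * t, 0 * t),
    sinusoid = cbind(speed * t, amplitude * sin(2 * pi * frequency * t)),
    random_walk = with_seed(seed, {
      step <- speed / frame_rate
      ang <- cumsum(stats::rnorm(n_frames - 1L, 0, 0.5))
      cbind(c(0, cumsum(step * cos(ang))), c(0, cumsum(step * sin(ang))))
    }))
  out <- data.frame(frame = seq_len(n_frames) - 1L, t_seconds = t,
                    x_um = xy[, 1L], y_um = xy[, 2L])
  attr(out, "model") <- list(model = model, speed = speed,
                             amplitude = amplitude, frequency = frequency,
                             duration = duration, frame_rate = frame_rate,
                             seed = seed)
  class(out) <- c("track", "data.frame")
  out
}
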