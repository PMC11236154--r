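# Image segmentation, boundary tracing and contour CSV I/O.
#
# Image matrices are indexed [row, col] with row 1 at the top (as read by
# png/tiff); contours live in Cartesian y-up pixel coordinates (x = column,
# y = n_rows - row + 1). The flip happens exactly once, inside
# extract_contour(), so all downstream geometry follows the mathematical
# angle convention.

#' Threshold a single-channel image into a binary head mask
#'
#' @param image numeric matrix (any intensity range).
#' @param method `"otsu"` (ignores `threshold`) or `"fixed"`.
#' @param threshold intensity cutoff, required for `method = "fixed"`.
#' @return 0/1 matrix of the same shape; foreground = head.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  image <- as.matrix(image)
  if (!is.numeric(image)) stop_param("image", "must be a numeric matrix")
  if (method == "otsu") {
    rng <- range(image)
    if (diff(rng) < .Machine$double.eps)
      stop("segmentation error: image is constant, no foreground found",
           call. = FALSE)
    scaled <- (image - rng[1L]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    mask <- (scaled > th) * 1
  } else {
    if (is.null(threshold))
      stop_param("threshold", "required for method = 'fixed'")
    mask <- (image > threshold) * 1
  }
  if (sum(mask) == 0)
    stop("segmentation error: empty foreground", call. = FALSE)
  mask
}

#' Trace the boundary of the largest foreground component
#'
#' Labels connected components, keeps the largest, and traces its outer
#' boundary as a sub-pixel closed polygon with marching squares at iso-level
#' 0.5 ([grDevices::contourLines()] on a zero-padded mask). Interior holes
#' are ignored (the largest-area iso-contour is returned). The result is in
#' Cartesian y-up pixel coordinates and counterclockwise.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return n x 2 contour matrix; attribute `"clipped"` is TRUE (with a
#'   warning) when the component touches the image border.
#' @export
extract_contour <- function(mask) {
  mask <- as.matrix(mask)
  if (sum(mask > 0) == 0)
    stop("mask has no foreground component", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image((mask > 0) * 1))
  lab <- as.matrix(lab)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  m <- (lab == keep) * 1

  nr <- nrow(m); nc <- ncol(m)
  clipped <- any(m[1L, ] > 0) || any(m[nr, ] > 0) ||
             any(m[, 1L] > 0) || any(m[, nc] > 0)
  if (clipped)
    warning("foreground touches the image border; contour is clipped",
            call. = FALSE)

  # pad with background so border-touching components still close
  mp <- matrix(0, nr + 2L, nc + 2L)
  mp[2L:(nr + 1L), 2L:(nc + 1L)] <- m
  # contourLines wants z[i, j] with x = i, y = j; use x = column index,
  # y = y-up row index so output is directly in Cartesian pixel coordinates
  zz <- t(mp[(nr + 2L):1L, ])                     # x: 1..nc+2, y: y-up
  cl <- grDevices::contourLines(x = seq_len(nc + 2L) - 1L,
                                y = seq_len(nr + 2L) - 1L,
                                z = zz, levels = 0.5)
  if (length(cl) == 0L)
    stop("no iso-contour found at level 0.5", call. = FALSE)
  areas <- vapply(cl, function(ct)
    abs(polygon_area(cbind(ct$x, ct$y))), numeric(1))
  ct <- cl[[which.max(areas)]]
  xy <- cbind(x = ct$x, y = ct$y)
  xy <- as_contour_matrix(xy, check_orientation = FALSE)
  if (polygon_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  attr(xy, "clipped") <- clipped
  xy
}

#' Resample a closed contour to uniform arc-length spacing
#'
#' Places `n_points` points equally spaced in cumulative arc length along
#' the closed polygon, starting at the original first vertex. Linear
#' interpolation along edges preserves the perimeter to well under 0.5%.
#'
#' @param contour n x 2 contour matrix.
#' @param n_points number of output points (>= 8).
#' @return `n_points` x 2 matrix; attributes of the input are preserved.
#' @export
resample_contour <- function(contour, n_points = 256L) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 8)
    stop_param("n_points", "must be a single integer >= 8")
  n_points <- as.integer(n_points)
  xy <- as_contour_matrix(contour, check_orientation = FALSE)
  closed <- rbind(xy, xy[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  per <- sum(seg)
  if (per < .Machine$double.eps)
    stop("degenerate contour: zero perimeter", call. = FALSE)
  cum <- c(0, cumsum(seg))
  s <- per * (seq_len(n_points) - 1L) / n_points
  x <- stats::approx(cum, closed[, 1L], xout = s, ties = "ordered")$y
  y <- stats::approx(cum, closed[, 2L], xout = s, ties = "ordered")$y
  out <- cbind(x = x, y = y)
  for (a in setdiff(names(attributes(xy)), c("dim", "dimnames")))
    attr(out, a) <- attr(xy, a)
  out
}

#' Write contour records to CSV
#'
#' Dialect: header `specimen_id,point_index,x,y`, x/y in Cartesian y-up
#' pixel coordinates, `point_index` starting at 1 within each specimen.
#'
#' @param path output file.
#' @param records named list of contour matrices (names = specimen ids), or
#'   the output of [make_population()].
#' @export
write_contours <- function(path, records) {
  records <- normalize_contour_records(records)
  rows <- lapply(names(records), function(id) {
    xy <- records[[id]]
    data.frame(specimen_id = id, point_index = seq_len(nrow(xy)),
               x = xy[, 1L], y = xy[, 2L])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

normalize_contour_records <- function(records) {
  if (is.matrix(records)) records <- list(contour_1 = records)
  if (length(records) && is.list(records[[1L]]) &&
      !is.null(records[[1L]]$contour)) {
    ids <- vapply(records, `[[`, character(1), "specimen_id")
    records <- stats::setNames(lapply(records, `[[`, "contour"), ids)
  }
  if (is.null(names(records)) || any(names(records) == ""))
    names(records) <- sprintf("contour_%d", seq_along(records))
  records
}

#' Read contour records from CSV
#'
#' @param path CSV file in the [write_contours()] dialect. An empty file
#'   (header only or zero bytes) yields an empty list.
#' @return Named list of contour matrices.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(list())
  needed <- c("specimen_id", "point_index", "x", "y")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("contour CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(split(df, df$specimen_id), function(g) {
    if (any(diff(g$point_index) <= 0))
      stop("contour CSV has non-monotone point_index for specimen '",
           g$specimen_id[1L], "'", call. = FALSE)
    cbind(x = g$x, y = g$y)
  })
  out[unique(df$specimen_id)]
}

#' Read a single-channel image from PNG or TIFF
#'
#' Multi-channel files are reduced to one channel (`channel` index).
#'
#' @param path image file (.png, .tif, .tiff).
#' @param channel channel index for multi-channel images.
#' @return Numeric matrix `[row, col]`, row 1 at the top.
#' @export
read_image <- function(path, channel = 1L) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (channel > length(pages))
        stop("image has only ", length(pages), " page(s); channel ",
             channel, " requested", call. = FALSE)
      pages[[channel]]
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , min(channel, dim(img)[3L])]
  img
}

#' Write one or more channels as PNG (8-bit masks) or TIFF (16-bit)
#'
#' @param path output file; for multiple channels with PNG output, one file
#'   per channel is written with the channel name appended.
#' @param channels named list of matrices with values in [0, 1], or one
#'   matrix.
#' @export
write_image <- function(path, channels) {
  if (is.matrix(channels)) channels <- list(channels)
  ext <- tolower(tools::file_ext(path))
  clamp <- function(m) pmin(pmax(m, 0), 1)
  if (ext == "tif" || ext == "tiff") {
    tiff::writeTIFF(lapply(channels, clamp), path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (length(channels) == 1L) {
      png::writePNG(clamp(channels[[1L]]), path)
    } else {
      base <- tools::file_path_sans_ext(path)
      nms <- names(channels)
      if (is.null(nms)) nms <- sprintf("ch%d", seq_along(channels))
      for (i in seq_along(channels))
        png::writePNG(clamp(channels[[i]]),
                      sprintf("%s_%s.png", base, nms[i]))
    }
  } else stop("unsupported image format: .", ext, call. = FALSE)
  invisible(path)
}
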