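# PCA over normalized EFD coefficient vectors and mean-shape
# reconstruction along principal components.

#' Assemble the specimen x coefficient matrix
#'
#' Decomposes, normalizes and flattens each contour into the 4H shape code
#' (80 numbers at the conventional H = 20).
#'
#' @param contours named list of contour matrices, or [make_population()]
#'   output.
#' @param H harmonic count.
#' @param ... passed to [efd_normalize()].
#' @return Numeric matrix, one row per specimen, `4 * H` named columns.
#' @export
coefficient_matrix <- function(contours, H = 20L, ...) {
  contours <- normalize_contour_records(contours)
  mat <- t(vapply(contours, function(xy)
    efd_flatten(efd_normalize(efd_decompose(xy, H), ...)),
    numeric(4L * H)))
  rownames(mat) <- names(contours)
  mat
}

#' Fit a shape PCA model on coefficient vectors
#'
#' Covariance PCA (mean-centered, unscaled): all coefficients share units,
#' and standardizing would inflate the near-constant entries left by
#' normalization (a1 = 1, b1 = c1 = 0). Loading signs are made
#' deterministic by forcing the largest-magnitude entry of each loading to
#' be positive.
#'
#' @param matrix specimens x 4H coefficient matrix (>= 2 rows).
#' @param n_components number of components to retain (default 2, the
#'   conventional pair for sperm-head morphology: head width and hook).
#' @return A `shape_pca` object: `mean` (length 4H), `loadings`
#'   (n_components x 4H, orthonormal rows), `sdev`, `var_explained`
#'   (fractions of total variance), `H`.
#' @export
fit_shape_pca <- function(matrix, n_components = 2L) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L)
    stop_param("matrix", "needs at least 2 specimens")
  if (ncol(matrix) %% 4L != 0L)
    stop_param("matrix", "column count must be a multiple of 4")
  total_var <- sum(apply(matrix, 2L, stats::var))
  if (total_var < .Machine$double.eps)
    stop("degenerate variance: all specimens identical", call. = FALSE)
  kmax <- min(nrow(matrix) - 1L, ncol(matrix))
  if (n_components > kmax)
    stop_param("n_components",
               sprintf("must be <= min(specimens - 1, 4H) = %d", kmax))
  p <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  k <- as.integer(n_components)
  load <- t(p$rotation[, seq_len(k), drop = FALSE])
  # deterministic sign: largest-|entry| of each loading positive
  for (i in seq_len(k)) {
    j <- which.max(abs(load[i, ]))
    if (load[i, j] < 0) load[i, ] <- -load[i, ]
  }
  structure(
    list(mean = p$center,
         loadings = load,
         sdev = p$sdev[seq_len(k)],
         var_explained = p$sdev[seq_len(k)]^2 / sum(p$sdev^2),
         H = ncol(matrix) %/% 4L,
         n = nrow(matrix)),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("Shape PCA: %d specimens, H = %d, %d component%s\n",
              x$n, x$H, length(x$sdev), if (length(x$sdev) > 1) "s" else ""))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                    100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Project coefficient vectors onto a fitted shape PCA
#'
#' @param model a `shape_pca` object.
#' @param vectors matrix of coefficient row-vectors (or a single vector).
#' @param group optional group labels recycled to the number of specimens.
#' @return data.frame with `specimen_id`, `group` and `PC1`, `PC2`, ...
#' @export
pca_scores <- function(model, vectors, group = NA_character_) {
  if (!inherits(model, "shape_pca"))
    stop_param("model", "must be a 'shape_pca' object")
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != length(model$mean))
    stop(sprintf("coefficient vectors have %d columns; model expects %d",
                 ncol(vectors), length(model$mean)), call. = FALSE)
  sc <- sweep(vectors, 2L, model$mean) %*% t(model$loadings)
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  ids <- rownames(vectors)
  if (is.null(ids)) ids <- sprintf("specimen_%d", seq_len(nrow(vectors)))
  data.frame(specimen_id = ids,
             group = rep_len(group, nrow(vectors)),
             sc, row.names = NULL)
}

#' Reconstruct the mean shape displaced along a principal component
#'
#' Rebuilds the contour of `mean + multiple_of_sd * sd(PC) * loading`,
#' the standard visualization of what a shape PC encodes;
#' `multiple_of_sd = 0` gives the grand mean shape.
#'
#' @param model a `shape_pca` object.
#' @param pc_index which component.
#' @param multiple_of_sd displacement in units of the component's score SD.
#' @param n_points points in the reconstructed contour.
#' @return n_points x 2 contour matrix (origin-centered, unit first
#'   harmonic scale).
#' @export
mean_shape <- function(model, pc_index = 1L, multiple_of_sd = 0,
                       n_points = 256L) {
  if (!inherits(model, "shape_pca"))
    stop_param("model", "must be a 'shape_pca' object")
  if (pc_index < 1L || pc_index > nrow(model$loadings))
    stop_param("pc_index", "out of range for this model")
  v <- model$mean +
    multiple_of_sd * model$sdev[pc_index] * model$loadings[pc_index, ]
  efd_reconstruct(efd_unflatten(v, model$H), n_points)
}

#' Serialize / restore a shape PCA model as JSON
#'
#' @param model a `shape_pca` object.
#' @param path output file.
#' @export
write_shape_pca <- function(model, path) {
  jsonlite::write_json(
    list(mean = model$mean, loadings = model$loadings,
         sdev = model$sdev, var_explained = model$var_explained,
         H = model$H, n = model$n),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_shape_pca
#' @param path JSON file written by [write_shape_pca()].
#' @export
read_shape_pca <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(mean = x$mean, loadings = matrix(unlist(x$loadings),
                                          nrow = length(x$sdev),
                                          byrow = FALSE),
         sdev = x$sdev, var_explained = x$var_explained,
         H = as.integer(x$H), n = as.integer(x$n)),
    class = "shape_pca")
}
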