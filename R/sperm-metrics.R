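# Per-sperm fluorescence measurements: acrosome (PNA-positive) area and
# nuclear vacuole detection, plus group prevalence summaries.

#' Quantify the PNA-positive (acrosome) area of one sperm head
#'
#' Thresholds the PNA channel within the head mask (dilated by a small
#' margin to keep boundary-hugging signal) and converts the positive pixel
#' count to square micrometers.
#'
#' @param pna_channel numeric matrix, PNA fluorescence.
#' @param head_mask 0/1 matrix of the same shape.
#' @param pixel_size micrometers per pixel (> 0).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity cutoff for `method = "fixed"`.
#' @param margin_px dilation margin applied to the head mask, px.
#' @return List: `positive_px`, `area_um2`, `head_area_um2`, `ratio`.
#' @export
acrosome_area <- function(pna_channel, head_mask, pixel_size,
                          method = c("fixed", "otsu"), threshold = 0.5,
                          margin_px = 2L) {
  method <- match.arg(method)
  pna_channel <- as.matrix(pna_channel)
  head_mask <- as.matrix(head_mask)
  if (!all(dim(pna_channel) == dim(head_mask)))
    stop_param("head_mask", "must have the same shape as pna_channel")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_param("pixel_size", "must be > 0")
  head_px <- sum(head_mask > 0)
  if (head_px == 0)
    stop("measurement error: empty head mask", call. = FALSE)
  roi <- dilate_mask((head_mask > 0) * 1, as.integer(margin_px)) > 0
  vals <- pna_channel[roi]
  pos <- if (method == "otsu") {
    rng <- range(vals)
    if (diff(rng) < .Machine$double.eps) 0L else {
      th <- EBImage::otsu(EBImage::Image((vals - rng[1L]) / diff(rng)),
                          range = c(0, 1))
      sum((vals - rng[1L]) / diff(rng) > th)
    }
  } else sum(vals > threshold)
  list(positive_px = as.integer(pos),
       area_um2 = pos * pixel_size^2,
       head_area_um2 = head_px * pixel_size^2,
       ratio = pos / head_px)
}

#' Detect nuclear vacuoles in one sperm head
#'
#' Vacuoles are connected components of pixels inside the eroded head mask
#' whose nuclear-stain intensity falls below
#' `(1 - rel_intensity_drop) * median(head intensity)`, filtered by area.
#' Relative thresholding makes detection invariant to image-wide affine
#' intensity rescaling.
#'
#' @param nuclear_channel numeric matrix, nuclear stain.
#' @param head_mask 0/1 matrix of the same shape.
#' @param min_area,max_area component area bounds, px^2; `max_area = NULL`
#'   defaults to 25% of the head area.
#' @param rel_intensity_drop required fractional intensity drop (default
#'   0.5).
#' @param erode_px head-mask erosion before the search, px (default 1).
#' @return List: `count`, `centroids` (matrix of (row, col) or NULL),
#'   `areas_px`, `has_vacuole`.
#' @export
detect_vacuoles <- function(nuclear_channel, head_mask, min_area = 4,
                            max_area = NULL, rel_intensity_drop = 0.5,
                            erode_px = 1L) {
  nuclear_channel <- as.matrix(nuclear_channel)
  head_mask <- as.matrix(head_mask)
  if (!all(dim(nuclear_channel) == dim(head_mask)))
    stop_param("head_mask", "must have the same shape as nuclear_channel")
  head_px <- sum(head_mask > 0)
  if (head_px == 0)
    stop("measurement error: empty head mask", call. = FALSE)
  if (is.null(max_area)) max_area <- 0.25 * head_px
  core <- erode_mask((head_mask > 0) * 1, as.integer(erode_px)) > 0
  med <- stats::median(nuclear_channel[head_mask > 0])
  dark <- core & (nuclear_channel < (1 - rel_intensity_drop) * med)
  if (!any(dark))
    return(list(count = 0L, centroids = NULL, areas_px = numeric(0),
                has_vacuole = FALSE))
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(dark * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area & sizes <= max_area)
  if (length(keep) == 0L)
    return(list(count = 0L, centroids = NULL, areas_px = numeric(0),
                has_vacuole = FALSE))
  cents <- t(vapply(keep, function(k) {
    idx <- which(lab == k)
    rr <- (idx - 1L) %% nrow(lab) + 1L
    cc <- (idx - 1L) %/% nrow(lab) + 1L
    c(mean(rr), mean(cc))
  }, numeric(2)))
  colnames(cents) <- c("row", "col")
  list(count = length(keep), centroids = cents,
       areas_px = sizes[keep], has_vacuole = TRUE)
}

#' Prevalence of vacuole-bearing heads with a Wilson 95% CI
#'
#' @param records list of [detect_vacuoles()] results (one per specimen),
#'   or a logical vector of per-specimen `has_vacuole` flags.
#' @param conf confidence level (default 0.95).
#' @return List: `n`, `positive`, `fraction`, `ci_lower`, `ci_upper`.
#' @export
vacuole_prevalence <- function(records, conf = 0.95) {
  flags <- if (is.logical(records)) records else
    vapply(records, function(r) isTRUE(r$has_vacuole), logical(1))
  n <- length(flags)
  if (n < 1L) stop_param("records", "needs at least one specimen")
  x <- sum(flags)
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(n = n, positive = as.integer(x), fraction = p,
       ci_lower = max(0, ctr - hw), ci_upper = min(1, ctr + hw))
}
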