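#' Geometric and intensity features of a segmented lesion
#'
#' Quantifies one lesion mask: pixel area, boundary perimeter, the major and
#' minor axis lengths of the ellipse with identical second central moments,
#' and the median and standard deviation of the lesion pixels on the
#' supplied monochrome image (conventionally the native fused red/green
#' channel, before any smoothing).
#'
#' The default perimeter is the polygonal length of the traced boundary
#' contour (8-connected chain); `perimeter_method = "crofton"` gives a
#' Crofton-style estimate from boundary crossings in four directions
#' instead.
#'
#' @param mask Logical (or 0/1) matrix, non-empty, a single connected
#'   component.
#' @param image Monochrome matrix of matching dimensions.
#' @param perimeter_method `"contour"` (default) or `"crofton"`.
#' @return A one-row tibble: `area_px`, `perimeter_px`, `major_axis_px`,
#'   `minor_axis_px`, `intensity_median`, `intensity_std`, `n_pixels`.
#' @export
compute_lesion_features <- function(mask, image,
                                    perimeter_method = c("contour", "crofton")) {
  perimeter_method <- match.arg(perimeter_method)
  if (is.numeric(mask)) mask <- mask > 0
  if (!is.matrix(mask) || !is.logical(mask)) abort("mask must be a logical matrix")
  if (!any(mask)) abort("mask is empty")
  if (!is_gray(image)) abort("image must be a monochrome matrix")
  if (!all(dim(mask) == dim(image))) abort("mask and image dimensions differ")

  area <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  # moment-equivalent ellipse: axes 4 * sqrt(eigenvalues of the coordinate
  # covariance); for a disc of radius r this gives major = minor = 2 r
  ctr <- colMeans(idx)
  dr <- idx[, 1] - ctr[1]; dc <- idx[, 2] - ctr[2]
  mu20 <- mean(dr^2); mu02 <- mean(dc^2); mu11 <- mean(dr * dc)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  lam1 <- (mu20 + mu02 + common) / 2
  lam2 <- (mu20 + mu02 - common) / 2
  major <- 4 * sqrt(pmax(lam1, 0))
  minor <- 4 * sqrt(pmax(lam2, 0))

  per <- switch(perimeter_method,
    contour = contour_perimeter(mask),
    crofton = crofton_perimeter(mask)
  )

  vals <- image[mask]
  tibble(
    area_px = area,
    perimeter_px = per,
    major_axis_px = major,
    minor_axis_px = minor,
    intensity_median = median(vals),
    intensity_std = if (length(vals) > 1) sd(vals) else 0,
    n_pixels = area
  )
}

# Polygonal length of the traced boundary (closed 8-connected contour).
contour_perimeter <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ct <- EBImage::ocontour(m)
  if (!length(ct)) return(0)
  total <- 0
  for (pts in ct) {
    if (nrow(pts) < 2) next
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
    total <- total + sum(d)
  }
  total
}

# Crofton 4-direction estimate: pi/4 * (axis crossings + diagonal
# crossings / sqrt(2)).
crofton_perimeter <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  ch <- sum(abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])) +
    sum(m[, 1]) + sum(m[, ncol(m)])
  cv <- sum(abs(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])) +
    sum(m[1, ]) + sum(m[nrow(m), ])
  d1 <- sum(abs(m[-1, -1, drop = FALSE] - m[-nrow(m), -ncol(m), drop = FALSE]))
  d2 <- sum(abs(m[-1, -ncol(m), drop = FALSE] - m[-nrow(m), -1, drop = FALSE]))
  (pi / 4) * (ch + cv + (d1 + d2) / sqrt(2))
}

#' Save the segmentation results bundle
#'
#' Writes the open-format analogue of the saved-results container: a
#' features JSON (features plus provenance: segmentation parameters, seed
#' and iteration count), the binary lesion mask as an 8-bit \{0, 255\} PNG,
#' the lesion pixel intensities as CSV, the preprocessed monochrome image as
#' PNG, and optionally an intensity histogram figure.
#'
#' @param seg A `fundus_seg` object from [segment_lesion()].
#' @param out_dir Output directory (created if missing).
#' @param name Basename for the bundle files (default `"lesion"`).
#' @param image_native Optional native monochrome image for the intensity
#'   statistics (defaults to the segmented input field).
#' @param plot Also write `<name>_histogram.png` (default FALSE).
#' @return Character vector of the written paths, invisibly.
#' @export
save_results_bundle <- function(seg, out_dir, name = "lesion",
                                image_native = NULL, plot = FALSE) {
  if (!inherits(seg, "fundus_seg")) abort("`seg` must be a fundus_seg object")
  if (is.null(seg$mask) || !any(seg$mask)) abort("segmentation mask is empty or missing")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  img <- image_native %||% seg$input
  feats <- compute_lesion_features(seg$mask, img)

  paths <- file.path(out_dir, paste0(name, c("_features.json", "_mask.png",
                                             "_intensities.csv",
                                             "_preprocessed.png")))
  payload <- list(
    features = as.list(feats),
    provenance = list(
      iterations = seg$state$iteration,
      seed_center = seg$params$seed_center,
      seed_radius = seg$params$seed_radius,
      kernel_sigma = seg$params$kernel_sigma,
      kernel_radius = seg$params$kernel_radius,
      epsilon = seg$params$epsilon, nu = seg$params$nu, mu = seg$params$mu,
      dt = seg$params$dt, filter = seg$filter
    )
  )
  jsonlite::write_json(payload, paths[1], auto_unbox = TRUE, digits = NA)
  write_fundus(seg$mask, paths[2])
  readr::write_csv(tibble(intensity = img[seg$mask]), paths[3])
  write_fundus(clip255(seg$input), paths[4])
  if (plot) {
    hp <- file.path(out_dir, paste0(name, "_histogram.png"))
    grDevices::png(hp, width = 640, height = 480)
    graphics::hist(img[seg$mask], breaks = 32, col = "firebrick",
                   main = "Lesion intensity spectrum", xlab = "Intensity")
    grDevices::dev.off()
    paths <- c(paths, hp)
  }
  invisible(paths)
}
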