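#' Enhancement parameter set
#'
#' Tunables of the image-enhancement suite.
#'
#' @param alpha,beta,gamma_offset Weights of the Gaussian-smoothing blend
#'   `dst = img * alpha + smoothed * beta + gamma_offset` (defaults 5, -5,
#'   128, which leave a constant image at mid-gray and amplify structure).
#' @param smooth_sigma_x Standard deviation, in pixels, of the Gaussian
#'   smoothing used by the blend (default 15; applied isotropically).
#' @param b_min Minimum acceptable geometric-mean brightness on \[0, 1\]
#'   (default 0.35) below which [adjust_brightness()] rescales the image.
#' @param clahe_clip,clahe_tiles CLAHE clip limit (default 2) and tile grid
#'   (default `c(8, 8)`).
#' @param crop_threshold Intensity (0--255) above which a pixel counts as
#'   non-background for the circle crop (default 10).
#' @return An `enhancement_params` list.
#' @export
enhancement_params <- function(alpha = 5, beta = -5, gamma_offset = 128,
                               smooth_sigma_x = 15, b_min = 0.35,
                               clahe_clip = 2, clahe_tiles = c(8, 8),
                               crop_threshold = 10) {
  stopifnot(smooth_sigma_x > 0, clahe_clip > 0, b_min > 0, b_min < 1,
            length(clahe_tiles) == 2, all(clahe_tiles >= 1))
  structure(list(alpha = alpha, beta = beta, gamma_offset = gamma_offset,
                 smooth_sigma_x = smooth_sigma_x, b_min = b_min,
                 clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
                 crop_threshold = crop_threshold),
            class = "enhancement_params")
}

# Circular field of view: the disc inscribed in the image frame.  Brightness
# is assessed inside it so that the black margins of fundus frames do not
# bias the estimate.
field_mask <- function(dims) {
  disc_mask(dims, (dims[1:2] + 1) / 2, min(dims[1:2]) / 2)
}

#' Geometric-mean brightness of a fundus image
#'
#' Per-pixel brightness is the channel mean normalized to \[0, 1\]; the
#' image brightness `b` is the geometric mean over pixels inside the
#' circular field of view, with zeros floored at 1/255 so the product stays
#' finite.
#'
#' @param image RGB array or grayscale matrix on \[0, 255\].
#' @param within_field Restrict to the inscribed circular field (default
#'   TRUE).
#' @return Scalar `b` in \[1/255, 1\], with attribute `floored = TRUE` when
#'   the image was entirely at the floor.
#' @export
geometric_mean_brightness <- function(image, within_field = TRUE) {
  assert_image(image)
  b <- channel_mean(image) / 255
  if (within_field) b <- b[field_mask(dim(b))]
  b <- pmax(b, 1 / 255)
  out <- exp(mean(log(b)))
  if (all(b <= 1 / 255)) {
    warn("all-black image: brightness is at the floor value")
    attr(out, "floored") <- TRUE
  }
  out
}

#' Linear brightness correction
#'
#' If the geometric-mean brightness `b` falls below `b_min`, intensities are
#' scaled by `b_min / b` (clipped to \[0, 255\]).  With
#' `standardize = TRUE` the same linear map is also applied when the image
#' is *brighter* than `b_min` (scale < 1), standardizing bright images.
#'
#' @inheritParams geometric_mean_brightness
#' @param b_min Brightness threshold on \[0, 1\].
#' @param standardize Also darken images brighter than `b_min`.
#' @return Image with the same dimensions, attribute `brightness_scale`
#'   giving the applied factor (1 when untouched).
#' @export
adjust_brightness <- function(image, b_min = 0.35, standardize = FALSE) {
  assert_image(image)
  b <- as.numeric(geometric_mean_brightness(image))
  scale <- b_min / b
  if (b >= b_min && !standardize) {
    attr(image, "brightness_scale") <- 1
    return(image)
  }
  out <- clip255(image * scale)
  attr(out, "brightness_scale") <- scale
  out
}

#' Fixed-aspect circle crop
#'
#' Removes the black margins (rows/columns whose maximum intensity is at or
#' below `threshold`), then masks the image to the disc of radius
#' `min(width, height) / 2` centered in the cropped frame and returns the
#' square bounding box of that disc, so the output always has aspect ratio
#' exactly 1.
#'
#' @inheritParams geometric_mean_brightness
#' @param threshold Background intensity threshold on \[0, 255\].
#' @return Square image (side `2 * radius`) with pixels outside the disc set
#'   to 0.
#' @export
circle_crop <- function(image, threshold = 10) {
  assert_image(image)
  lum <- channel_mean(image)
  rows <- which(apply(lum, 1, max) > threshold)
  cols <- which(apply(lum, 2, max) > threshold)
  if (!length(rows) || !length(cols)) abort("circle_crop: image is entirely background")
  rr <- rows[1]:rows[length(rows)]
  cc <- cols[1]:cols[length(cols)]
  cropped <- if (is_rgb(image)) image[rr, cc, , drop = FALSE] else image[rr, cc, drop = FALSE]
  h <- length(rr); w <- length(cc)
  side <- min(w, h)
  r0 <- floor((h - side) / 2); c0 <- floor((w - side) / 2)
  ri <- r0 + seq_len(side); ci <- c0 + seq_len(side)
  out <- if (is_rgb(image)) cropped[ri, ci, , drop = FALSE] else cropped[ri, ci, drop = FALSE]
  m <- disc_mask(c(side, side), c((side + 1) / 2, (side + 1) / 2), side / 2)
  if (is_rgb(out)) {
    for (k in 1:3) out[, , k][!m] <- 0
  } else {
    out[!m] <- 0
  }
  out
}

# Isotropic Gaussian smoothing, kernel truncated at 4 sigma, reflective
# borders; applied per channel.
gaussian_smooth <- function(image, sigma) {
  k <- ceiling(4 * sigma)
  d <- seq(-k, k)
  g <- exp(-d^2 / (2 * sigma^2))
  g <- g / sum(g)
  smooth_mat <- function(m) {
    p <- pad_reflect(m, k)
    # separable convolution via banded matrix products on the padded field
    out <- matrix(0, nrow(m), ncol(m))
    tmp <- matrix(0, nrow(m), ncol(p))
    for (i in seq_along(d)) tmp <- tmp + g[i] * p[k + seq_len(nrow(m)) + d[i], , drop = FALSE]
    for (i in seq_along(d)) out <- out + g[i] * tmp[, k + seq_len(ncol(m)) + d[i], drop = FALSE]
    out
  }
  if (is_rgb(image)) {
    for (ch in 1:3) image[, , ch] <- smooth_mat(image[, , ch])
    image
  } else {
    smooth_mat(image)
  }
}

#' Gaussian-smoothing blend
#'
#' Weighted sum of the image and its Gaussian-smoothed version,
#' `dst = img * alpha + smoothed * beta + gamma_offset`, clipped to
#' \[0, 255\].  With the defaults (5, -5, 128) a constant image maps to
#' uniform 128 and structure is strongly amplified — a high-pass "unsharp"
#' enhancement that makes faint retinal structures visible.  May be applied
#' with or without a prior [circle_crop()].
#'
#' @inheritParams geometric_mean_brightness
#' @param params An [enhancement_params()] list.
#' @return Image of the same dimensions on \[0, 255\].
#' @export
smooth_blend <- function(image, params = enhancement_params()) {
  assert_image(image)
  sm <- gaussian_smooth(image, params$smooth_sigma_x)
  clip255(image * params$alpha + sm * params$beta + params$gamma_offset)
}

# CLAHE on a [0,255] matrix.  EBImage::clahe needs dimensions divisible by
# the tile grid; pad reflectively and crop back.
clahe_mat <- function(m, clip, tiles) {
  n <- nrow(m); p <- ncol(m)
  ny <- tiles[1]; nx <- tiles[2]
  n2 <- ceiling(n / ny) * ny
  p2 <- ceiling(p / nx) * nx
  mp <- m
  if (n2 > n) mp <- rbind(mp, mp[n:(n - (n2 - n) + 1), , drop = FALSE])
  if (p2 > p) mp <- cbind(mp, mp[, p:(p - (p2 - p) + 1), drop = FALSE])
  # EBImage images are [x, y]
  eq <- EBImage::clahe(t(mp) / 255, nx = nx, ny = ny, limit = clip)
  out <- t(eq)[seq_len(n), seq_len(p), drop = FALSE] * 255
  clip255(out)
}

rgb_to_hsv_img <- function(image) {
  v <- grDevices::rgb2hsv(
    r = as.vector(image[, , 1]), g = as.vector(image[, , 2]),
    b = as.vector(image[, , 3]), maxColorValue = 255
  )
  v
}

#' Contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE in one of three modes: `gray` equalizes the channel-mean
#' (or single-channel) image; `green` equalizes the green plane; `hsv_v`
#' converts RGB to HSV, equalizes the V (value) channel and converts back,
#' preserving hue and saturation.
#'
#' @inheritParams smooth_blend
#' @param mode One of `"gray"`, `"green"`, `"hsv_v"`.
#' @return Grayscale matrix for `gray`/`green`, RGB array for `hsv_v`.
#' @export
clahe_enhance <- function(image, mode = c("gray", "green", "hsv_v"),
                          params = enhancement_params()) {
  mode <- match.arg(mode)
  assert_image(image)
  if (max(image) > 255 || min(image) < 0) {
    abort("clahe_enhance expects an 8-bit-range image on [0, 255]")
  }
  tiles <- params$clahe_tiles
  clip <- params$clahe_clip
  switch(mode,
    gray = clahe_mat(channel_mean(image), clip, tiles),
    green = {
      if (!is_rgb(image)) abort("mode 'green' needs a 3-channel image")
      clahe_mat(image[, , 2], clip, tiles)
    },
    hsv_v = {
      if (!is_rgb(image)) abort("mode 'hsv_v' needs a 3-channel image")
      hsv <- rgb_to_hsv_img(image)
      dims <- dim(image)[1:2]
      v <- matrix(hsv["v", ], dims[1], dims[2])
      v2 <- clahe_mat(v * 255, clip, tiles) / 255
      cols <- grDevices::hsv(hsv["h", ], hsv["s", ], pmin(pmax(as.vector(v2), 0), 1))
      m <- grDevices::col2rgb(cols)
      out <- array(0, dim(image))
      out[, , 1] <- matrix(m[1, ], dims[1], dims[2])
      out[, , 2] <- matrix(m[2, ], dims[1], dims[2])
      out[, , 3] <- matrix(m[3, ], dims[1], dims[2])
      out
    }
  )
}

#' Channel operations
#'
#' `split` returns the R, G and B planes (structures in fundus images show
#' the highest contrast in the green channel); `swap_rgb_bgr` reverses the
#' channel order.
#'
#' @inheritParams smooth_blend
#' @param op `"split"` or `"swap_rgb_bgr"`.
#' @return For `split`, a named list of matrices `r`, `g`, `b`; for
#'   `swap_rgb_bgr`, an RGB array with channels reversed.
#' @export
channel_ops <- function(image, op = c("split", "swap_rgb_bgr")) {
  op <- match.arg(op)
  if (!is_rgb(image)) abort("channel_ops needs a 3-channel image")
  switch(op,
    split = list(r = image[, , 1], g = image[, , 2], b = image[, , 3]),
    swap_rgb_bgr = image[, , 3:1]
  )
}
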