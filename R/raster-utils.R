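# Internal raster helpers.  Grayscale images are numeric matrices (rows =
# image y, columns = image x), RGB images are H x W x 3 arrays; intensities
# live on [0, 255] as doubles throughout.

is_rgb <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L

is_gray <- function(img) is.matrix(img) && is.numeric(img)

assert_image <- function(img, arg = "image") {
  if (!is_rgb(img) && !is_gray(img)) {
    abort(sprintf("`%s` must be a numeric matrix or an H x W x 3 array", arg))
  }
  if (!all(is.finite(img))) abort(sprintf("`%s` contains non-finite pixels", arg))
  invisible(img)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Collapse an RGB array to per-pixel mean brightness
#' @noRd
channel_mean <- function(img) {
  if (is_gray(img)) return(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

# Reflective ("symmetric") mirror extension by `k` pixels on every side.
# The mirror is periodic with period 2n, so paddings wider than the image
# are handled too.
pad_reflect <- function(m, k) {
  mirror_idx <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  n <- nrow(m); p <- ncol(m)
  ri <- mirror_idx(seq.int(1L - k, n + k), n)
  ci <- mirror_idx(seq.int(1L - k, p + k), p)
  m[ri, ci, drop = FALSE]
}

# Replicate (Neumann) extension used by the level-set finite differences:
# shift with edge value clamping.  d = c(dr, dc) shifts content so that
# out[i, j] = m[i + dr, j + dc] with clamping at the borders.
shift_clamp <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  ri <- pmin(pmax(seq_len(n) + dr, 1L), n)
  ci <- pmin(pmax(seq_len(p) + dc, 1L), p)
  m[ri, ci, drop = FALSE]
}

# Zero-padded linear convolution with a fixed odd-sized kernel, kernel FFT
# cached across calls.  Zero padding means the kernel window is truncated at
# the image border, matching a direct sum over in-image neighbours only.
# `pair()` convolves two real fields in one complex FFT (real/imaginary
# packing), which roughly halves the transform cost in the level-set loop.
make_conv <- function(dims, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  n <- dims[1]; p <- dims[2]
  P1 <- stats::nextn(n + 2L * kr, c(2, 3, 5))
  P2 <- stats::nextn(p + 2L * kc, c(2, 3, 5))
  kp <- matrix(0, P1, P2)
  kp[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  KF <- fft(kp)
  rows <- kr + seq_len(n)
  cols <- kc + seq_len(p)
  pad <- function(x) {
    xp <- matrix(0, P1, P2)
    xp[seq_len(n), seq_len(p)] <- x
    xp
  }
  list(
    one = function(x) {
      y <- fft(fft(pad(x)) * KF, inverse = TRUE)
      Re(y)[rows, cols] / (P1 * P2)
    },
    pair = function(x1, x2) {
      y <- fft(fft(pad(x1) + 1i * pad(x2)) * KF, inverse = TRUE) / (P1 * P2)
      list(Re(y)[rows, cols], Im(y)[rows, cols])
    }
  )
}

# Truncated, discretely normalized Gaussian window: support |d| <= rho
# (Euclidean), weights exp(-|d|^2 / (2 sigma^2)), renormalized to sum 1.
gaussian_window <- function(sigma, radius = ceiling(2 * sigma)) {
  stopifnot(sigma > 0, radius >= 1)
  d <- seq(-radius, radius)
  g <- outer(d^2, d^2, `+`)
  w <- exp(-g / (2 * sigma^2))
  w[g > radius^2 + 1e-12] <- 0
  w / sum(w)
}

# Rasterized disc mask: pixels whose centre lies within `radius` of `center`
# (row, col).
disc_mask <- function(dims, center, radius) {
  r <- outer(seq_len(dims[1]) - center[1], rep(1, dims[2]))
  c <- outer(rep(1, dims[1]), seq_len(dims[2]) - center[2])
  (r^2 + c^2) <= radius^2
}
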