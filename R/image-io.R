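#' Read a fundus photograph
#'
#' Decodes a JPEG or PNG file into the package's raster convention: a numeric
#' matrix (grayscale) or an H x W x 3 array (RGB) with intensities on
#' \[0, 255\].
#'
#' @param path File path to a `.jpg`/`.jpeg` or `.png` image.
#' @return Numeric matrix or H x W x 3 array on \[0, 255\].
#' @export
read_fundus <- function(path) {
  if (!file.exists(path)) abort(sprintf("image not found: %s", path))
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores images as [x, y(, c)]; transpose to rows = y.
  if (length(dim(a)) == 2L) {
    out <- t(a) * 255
  } else {
    a <- a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE]
    if (dim(a)[3] == 1L) {
      out <- t(a[, , 1]) * 255
    } else {
      out <- aperm(a, c(2, 1, 3)) * 255
    }
  }
  out
}

#' Write a fundus image or mask
#'
#' Encodes a \[0, 255\] raster as PNG or JPEG (chosen from the file
#' extension).  Logical matrices are written as 8-bit \{0, 255\} masks.
#'
#' @param img Numeric matrix, logical matrix (mask) or H x W x 3 array.
#' @param path Output path ending in `.png`, `.jpg` or `.jpeg`.
#' @param quality JPEG quality on (0, 1\]; ignored for PNG.
#' @return `path`, invisibly.
#' @export
write_fundus <- function(img, path, quality = 0.95) {
  if (is.logical(img)) {
    storage <- matrix(as.numeric(img), nrow(img), ncol(img)) * 255
    img <- storage
  }
  assert_image(img)
  x <- img / 255
  x[x < 0] <- 0; x[x > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(x, target = path)
  } else if (ext %in% c("jpg", "jpeg")) {
    jpeg::writeJPEG(x, target = path, quality = quality)
  } else {
    abort(sprintf("unsupported image extension '.%s' (use png/jpg)", ext))
  }
  invisible(path)
}
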