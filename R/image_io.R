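png_bit_depth <- function(path) {
  # IHDR bit depth: byte 25 of the file (8 signature + 4 length +
  # 4 "IHDR" + 4 width + 4 height + 1)
  hdr <- readBin(path, "raw", 25)
  if (length(hdr) < 25) stop("corrupt PNG: ", path)
  as.integer(hdr[25])
}

#' Read a section image as an 8-bit RGB(A) array
#'
#' Reads PNG, TIFF or JPEG into the integer array format used throughout
#' the package (`height x width x channels`, values 0-255). Grayscale
#' images are expanded to RGB; an alpha channel is preserved when
#' present. Bit depths other than 8 are refused — stain thresholds are
#' defined on the 8-bit scale.
#'
#' @param path Image file path.
#' @return Integer array `height x width x 3` (RGB) or `4` (RGBA).
#' @export
read_section_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      if (png_bit_depth(path) != 8L) {
        stop("unsupported bit depth (expected 8-bit) in ", path)
      }
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      img <- tiff::readTIFF(path, info = TRUE)
      bits <- attr(img, "bits.per.sample")
      if (!is.null(bits) && any(bits != 8L)) {
        stop("unsupported bit depth (expected 8-bit) in ", path)
      }
      attributes(img) <- list(dim = dim(img))
      img
    },
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' for ", path)
  )
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1L))
  if (dim(arr)[3] == 1L) {
    arr <- array(rep(arr, 3L), dim = c(dim(arr)[1:2], 3L))
  } else if (dim(arr)[3] == 2L) { # gray + alpha
    arr <- array(c(rep(arr[, , 1], 3L), arr[, , 2]),
                 dim = c(dim(arr)[1:2], 4L))
  }
  out <- round(arr * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write an RGB(A) integer array as PNG
#'
#' @param image Integer array `height x width x 3` or `4`, values 0-255.
#' @param path Destination PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a binary region-of-interest mask
#'
#' Any nonzero pixel (maximum over colour channels for RGB masks) is
#' inside the ROI. The mask must match the section's dimensions.
#'
#' @param path Mask image path (PNG/TIFF/JPEG; single-channel or RGB).
#' @param expected_dims `c(height, width)` of the section the mask
#'   belongs to, checked against the file.
#' @return Logical matrix of `expected_dims`.
#' @export
read_roi_mask <- function(path, expected_dims = NULL) {
  arr <- read_section_image(path)
  v <- pmax(arr[, , 1], pmax(arr[, , 2], arr[, , 3]))
  dim(v) <- dim(arr)[1:2]
  if (!is.null(expected_dims) &&
      !identical(as.integer(dim(v)), as.integer(expected_dims))) {
    stop(sprintf("ROI mask %s is %s but the section is %s",
                 path, paste(dim(v), collapse = "x"),
                 paste(expected_dims, collapse = "x")))
  }
  v > 0
}
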