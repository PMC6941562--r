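# Per-class predicate matrices for an image held as integer channel
# matrices. Returns a named list of logical matrices; `other_tissue` is the
# always-true fallback. Alpha is handled by the caller.
class_predicates <- function(R, G, B, scheme) {
  mn <- pmin(R, pmin(G, B))
  mx <- pmax(R, pmax(G, B))
  list(
    background = mn >= scheme$background_min_channel,
    collagen = (B >= R + scheme$blue_margin & B >= G) |
      (mx - mn <= scheme$gray_spread &
         mn >= scheme$gray_low & mx <= scheme$gray_high),
    muscle = R >= B + scheme$red_margin,
    other_tissue = array(TRUE, dim = dim(R))
  )
}

#' Classify a single pixel by its RGB value
#'
#' Reference (scalar) form of the classifier: applies the scheme's class
#' tests in precedence order and returns the first class whose test the
#' pixel satisfies. [segment_section()] is the vectorised equivalent and
#' agrees with this function pixel for pixel.
#'
#' @param rgb Numeric vector of length 3 (red, green, blue), 0-255.
#' @param alpha Optional alpha value 0-255; an alpha of exactly 0 always
#'   yields `"background"` regardless of colour or precedence.
#' @param scheme A [threshold_scheme()].
#' @return One of the four class names.
#' @export
#' @examples
#' classify_pixel(c(255, 255, 255))  # background
#' classify_pixel(c(30, 30, 200))    # collagen (blue dominance)
#' classify_pixel(c(200, 40, 40))    # muscle (red dominance)
classify_pixel <- function(rgb, alpha = NULL, scheme = threshold_scheme()) {
  if (length(rgb) != 3L || any(!is.finite(rgb)) ||
      any(rgb < 0) || any(rgb > 255)) {
    stop("rgb must be three finite values in [0, 255]")
  }
  if (!is.null(alpha)) {
    if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha > 255) {
      stop("alpha must be a single value in [0, 255]")
    }
    if (alpha == 0) return("background")
  }
  one <- function(v) matrix(v, 1, 1)
  preds <- class_predicates(one(rgb[1]), one(rgb[2]), one(rgb[3]), scheme)
  for (cl in scheme$precedence) {
    if (preds[[cl]][1, 1]) return(cl)
  }
  "other_tissue" # unreachable: fallback always matches
}

#' Segment a section image into stain classes
#'
#' Applies the threshold scheme to every pixel and returns the label grid
#' together with per-class pixel counts. The per-class counts always sum
#' to `width * height`.
#'
#' @param image Either a file path (PNG/TIFF/JPEG) or an integer array
#'   `height x width x channels` (3 = RGB, 4 = RGBA) with 8-bit values.
#' @param scheme A [threshold_scheme()].
#' @param min_object_px Optional minimum connected-component size (4-
#'   connectivity) for the tissue classes; components of collagen, muscle
#'   or other tissue smaller than this are reassigned to `background`.
#'   Default 0 = raw pixel counting, no cleanup. Requires the EBImage
#'   package when positive.
#' @return An object of class `pixel_class_map`: a list with `labels`
#'   (integer matrix, values 1-4 indexing [color_classes()]), `counts`
#'   (named integer vector over the four classes), `width`, `height` and
#'   the `scheme` used.
#' @seealso [classify_pixel()], [count_roi_classes()], [render_overlay()]
#' @export
#' @examples
#' img <- array(255L, dim = c(10, 10, 3))  # uniform white
#' m <- segment_section(img)
#' m$counts  # 100 background pixels
segment_section <- function(image, scheme = threshold_scheme(),
                            min_object_px = 0) {
  if (is.character(image)) image <- read_section_image(image)
  if (!is.array(image) || length(dim(image)) != 3L ||
      !dim(image)[3] %in% c(3L, 4L)) {
    stop("image must be a height x width x 3 (RGB) or 4 (RGBA) array")
  }
  if (any(image < 0) || any(image > 255)) {
    stop("channel values must be 8-bit (0-255)")
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h == 0L || w == 0L) stop("image is empty")
  R <- image[, , 1, drop = TRUE]
  G <- image[, , 2, drop = TRUE]
  B <- image[, , 3, drop = TRUE]
  # matrices even for 1-pixel-wide images
  dim(R) <- dim(G) <- dim(B) <- c(h, w)
  preds <- class_predicates(R, G, B, scheme)
  idx <- match(color_classes(), color_classes()) # 1:4 in canonical order
  names(idx) <- color_classes()
  labels <- matrix(idx[["other_tissue"]], h, w)
  # reverse precedence: earliest class painted last, so it wins ties
  for (cl in rev(scheme$precedence)) {
    labels[preds[[cl]]] <- idx[[cl]]
  }
  if (dim(image)[3] == 4L) {
    A <- image[, , 4, drop = TRUE]
    dim(A) <- c(h, w)
    labels[A == 0] <- idx[["background"]]
  }
  map <- new_class_map(labels, scheme)
  if (min_object_px > 0) map <- drop_small_objects(map, min_object_px)
  map
}

new_class_map <- function(labels, scheme = NULL) {
  counts <- tabulate(labels, nbins = 4L)
  names(counts) <- color_classes()
  structure(
    list(labels = labels, counts = counts,
         width = ncol(labels), height = nrow(labels), scheme = scheme),
    class = "pixel_class_map")
}

# Reassign tissue-class connected components smaller than min_px to the
# background class. Kept out of the default path: raw per-pixel counting
# is the primary measurement.
drop_small_objects <- function(map, min_px) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("small-object removal requires the EBImage package")
  }
  labels <- map$labels
  bg <- match("background", color_classes())
  for (cl in setdiff(seq_len(4L), bg)) {
    mask <- labels == cl
    if (!any(mask)) next
    comp <- EBImage::bwlabel(mask)
    sizes <- tabulate(comp[comp > 0])
    small <- which(sizes < min_px)
    if (length(small)) labels[comp %in% small] <- bg
  }
  new_class_map(labels, map$scheme)
}

#' @export
print.pixel_class_map <- function(x, ...) {
  cat(sprintf("pixel class map: %d x %d px\n", x$width, x$height))
  tot <- sum(x$counts)
  for (cl in color_classes()) {
    cat(sprintf("  %-12s %9d px (%.2f%%)\n", cl, x$counts[[cl]],
                100 * x$counts[[cl]] / tot))
  }
  invisible(x)
}

#' @export
plot.pixel_class_map <- function(x, colors = class_display_colors(), ...) {
  img <- matrix(colors[color_classes()[x$labels]], x$height, x$width)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, x$width), c(0, x$height), asp = 1)
  graphics::rasterImage(img, 0, 0, x$width, x$height, interpolate = FALSE)
  invisible(x)
}

#' Per-class pixel counts inside a region of interest
#'
#' Restricts the class counts of a segmented section to the pixels where
#' `roi` is `TRUE` — typically a manually delineated scar or remote-zone
#' mask. The counts sum to the number of `TRUE` pixels in the ROI.
#'
#' @param map A `pixel_class_map` from [segment_section()].
#' @param roi Logical matrix with the same dimensions as the map.
#' @return Named integer vector of per-class counts within the ROI.
#' @export
count_roi_classes <- function(map, roi) {
  stopifnot(inherits(map, "pixel_class_map"))
  if (is.null(dim(roi))) stop("roi must be a matrix")
  storage.mode(roi) <- "logical"
  if (!identical(dim(roi), dim(map$labels))) {
    stop(sprintf("ROI dimensions (%s) do not match map dimensions (%s)",
                 paste(dim(roi), collapse = "x"),
                 paste(dim(map$labels), collapse = "x")))
  }
  counts <- tabulate(map$labels[roi], nbins = 4L)
  names(counts) <- color_classes()
  counts
}

#' Render a segmentation overlay with transparent background
#'
#' Paints the pixels of the included classes with their display colours at
#' full opacity; all other pixels are fully transparent. Stacking such
#' overlays slice by slice reconstructs the heart in 3D.
#'
#' @param map A `pixel_class_map`.
#' @param include Character vector of classes to paint (nonempty subset of
#'   [color_classes()]). Default: all stained tissue classes.
#' @param colors Display colours, as in [class_display_colors()].
#' @return RGBA integer array `height x width x 4`, values 0-255.
#' @export
render_overlay <- function(map,
                           include = c("collagen", "muscle", "other_tissue"),
                           colors = class_display_colors()) {
  stopifnot(inherits(map, "pixel_class_map"))
  if (length(include) == 0L) stop("include must name at least one class")
  if (!all(include %in% color_classes())) {
    stop("include must be a subset of color_classes()")
  }
  h <- map$height; w <- map$width
  out <- array(0L, dim = c(h, w, 4))
  for (cl in include) {
    sel <- map$labels == match(cl, color_classes())
    if (!any(sel)) next
    rgbv <- grDevices::col2rgb(colors[[cl]])
    out[, , 1][sel] <- rgbv[1]
    out[, , 2][sel] <- rgbv[2]
    out[, , 3][sel] <- rgbv[3]
    out[, , 4][sel] <- 255L
  }
  storage.mode(out) <- "integer"
  out
}
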