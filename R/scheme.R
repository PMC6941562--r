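#' Colour classes recognised by the segmenter
#'
#' Every pixel of a trichrome-stained section is assigned to exactly one of
#' four classes: `background` (unstained slide / transparent), `collagen`
#' (blue to blue-gray: infarct scar and interstitial fibrosis), `muscle`
#' (red: viable myocardium) and `other_tissue` (stained tissue matching
#' neither colour test, e.g. cytoplasmic intermediates, staining artefacts).
#'
#' @return Character vector of the four class names, in canonical order.
#' @export
#' @examples
#' color_classes()
color_classes <- function() {
  c("background", "collagen", "muscle", "other_tissue")
}

#' Display colours used for overlays and stack slices
#'
#' @return Named vector of hex colours, one per class. Overlay rendering
#'   paints included classes with these colours at full opacity.
#' @export
class_display_colors <- function() {
  c(background   = "#F5F5F5",
    collagen     = "#1E1EC8",
    muscle       = "#C82828",
    other_tissue = "#969696")
}

#' Define an RGB threshold scheme for stain classification
#'
#' The scheme encodes the colour tests applied to every pixel, in a
#' configurable precedence order (first matching class wins):
#'
#' * `background`: `min(R, G, B) >= background_min_channel`, i.e. near-white
#'   unstained slide. Fully transparent pixels (alpha 0) are always
#'   background, independent of precedence.
#' * `collagen`: blue dominance `B >= R + blue_margin` and `B >= G`, *or*
#'   the blue-to-gray gradient test: channel spread
#'   `max - min <= gray_spread` with all channels inside
#'   `[gray_low, gray_high]`. The gradient test captures the washed-out
#'   blue-gray collagen at the scar margin that a pure blue-dominance test
#'   misses.
#' * `muscle`: red dominance `R >= B + red_margin`.
#' * `other_tissue`: anything else (always matches; the fallback).
#'
#' All intensity parameters are on the 8-bit scale (0-255).
#'
#' @param background_min_channel Minimum of R,G,B at or above which a pixel
#'   is background. Default 230.
#' @param blue_margin Required excess of blue over red for the collagen
#'   test. Default 20.
#' @param red_margin Required excess of red over blue for the muscle test.
#'   Default 20.
#' @param gray_low,gray_high Intensity bounds of the blue-to-gray gradient
#'   window. Defaults 90 and 200.
#' @param gray_spread Maximum channel spread (`max - min`) for a pixel to
#'   count as gradient gray. Default 15.
#' @param precedence Character vector, a permutation of [color_classes()],
#'   giving the order in which class tests are evaluated.
#' @return An object of class `threshold_scheme`.
#' @seealso [classify_pixel()], [segment_section()], [read_scheme()]
#' @export
#' @examples
#' sch <- threshold_scheme()
#' classify_pixel(c(30, 30, 200), scheme = sch)
threshold_scheme <- function(background_min_channel = 230,
                             blue_margin = 20,
                             red_margin = 20,
                             gray_low = 90,
                             gray_high = 200,
                             gray_spread = 15,
                             precedence = color_classes()) {
  num <- c(background_min_channel = background_min_channel,
           blue_margin = blue_margin, red_margin = red_margin,
           gray_low = gray_low, gray_high = gray_high,
           gray_spread = gray_spread)
  if (any(!is.finite(num)) || any(num < 0) || any(num > 255)) {
    stop("all intensity parameters must be finite and within [0, 255]")
  }
  if (gray_low >= gray_high) {
    stop("gray_low must be strictly less than gray_high")
  }
  if (length(precedence) != 4L || !setequal(precedence, color_classes())) {
    stop("precedence must be a permutation of the four colour classes")
  }
  structure(
    list(background_min_channel = as.numeric(background_min_channel),
         blue_margin = as.numeric(blue_margin),
         red_margin = as.numeric(red_margin),
         gray_low = as.numeric(gray_low),
         gray_high = as.numeric(gray_high),
         gray_spread = as.numeric(gray_spread),
         precedence = as.character(precedence)),
    class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat("RGB threshold scheme\n")
  cat(sprintf("  background : min(R,G,B) >= %g (alpha 0 always background)\n",
              x$background_min_channel))
  cat(sprintf("  collagen   : B >= R + %g & B >= G, or spread <= %g in [%g, %g]\n",
              x$blue_margin, x$gray_spread, x$gray_low, x$gray_high))
  cat(sprintf("  muscle     : R >= B + %g\n", x$red_margin))
  cat("  other      : fallback\n")
  cat("  precedence :", paste(x$precedence, collapse = " > "), "\n")
  invisible(x)
}

#' Read or write a threshold scheme as YAML
#'
#' The on-disk representation is a flat YAML mapping with the same
#' parameter names as [threshold_scheme()]; missing keys take the
#' defaults, unknown keys are an error.
#'
#' @param path File path of the YAML scheme.
#' @return `read_scheme()` returns a `threshold_scheme`;
#'   `write_scheme()` returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(threshold_scheme))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown scheme parameter(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  do.call(threshold_scheme, vals)
}

#' @rdname read_scheme
#' @param scheme A `threshold_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  yaml::write_yaml(unclass(scheme), path)
  invisible(path)
}
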