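# Palette endpoints. Collagen runs from saturated blue to the washed-out
# blue-gray of the scar margin; muscle from deep to lighter trichrome red.
# Both stay strictly inside the default class predicates even after
# integer rounding and per-channel jitter up to PHANTOM_MAX_JITTER.
PHANTOM_MAX_JITTER <- 4
phantom_collagen_rgb <- function(t) {
  cbind(30 + 110 * t, 30 + 110 * t, 200 - 30 * t)
}
phantom_muscle_rgb <- function(t) {
  cbind(200 + 20 * t, 40 + 50 * t, 40 + 50 * t)
}
PHANTOM_BACKGROUND <- c(245, 245, 245)

#' Specify a synthetic trichrome-like section phantom
#'
#' The phantom emulates a mid-ventricular cross-section: an annular left
#' ventricular wall (red muscle) on a near-white background, with a blue
#' collagen wedge standing in for the infarct scar and optional
#' single-pixel blue speckles in the remote wall standing in for
#' interstitial fibrosis. Every pixel's class is recorded while painting,
#' giving exact ground truth for segmentation tests.
#'
#' @param canvas `c(height, width)` in pixels. Default `c(256, 256)`.
#' @param outer_radius,inner_radius Annulus radii in pixels (wall between
#'   them; the lumen inside `inner_radius` is background).
#' @param infarct_angle Angular extent of the scar wedge in degrees,
#'   0-360.
#' @param transmural If `TRUE` (default) the wedge spans the full wall
#'   thickness; if `FALSE` only the outer half, mimicking a
#'   non-transmural infarct.
#' @param fibrosis_density Probability that a muscle pixel carries a blue
#'   interstitial speckle. Default 0.
#' @param hue_jitter Maximum per-channel colour perturbation (intensity
#'   units, 0-4). Bounded so every jittered colour still satisfies its
#'   class predicate under the default scheme; segmentation therefore
#'   recovers ground truth exactly at any allowed jitter.
#' @param seed Optional random seed for reproducible phantoms.
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom_section()], [make_phantom_series()]
#' @export
phantom_spec <- function(canvas = c(256, 256),
                         outer_radius = 100,
                         inner_radius = 55,
                         infarct_angle = 120,
                         transmural = TRUE,
                         fibrosis_density = 0,
                         hue_jitter = 3,
                         seed = NULL) {
  if (length(canvas) != 2L || any(canvas < 8)) {
    stop("canvas must be c(height, width), each >= 8 pixels")
  }
  if (inner_radius >= outer_radius) {
    stop("inner_radius must be smaller than outer_radius")
  }
  if (outer_radius > min(canvas) / 2) {
    stop("outer_radius must fit inside the canvas")
  }
  if (inner_radius < 1) stop("inner_radius must be >= 1")
  if (infarct_angle < 0 || infarct_angle > 360) {
    stop("infarct_angle must be within [0, 360] degrees")
  }
  if (fibrosis_density < 0 || fibrosis_density > 1) {
    stop("fibrosis_density must be a probability")
  }
  if (hue_jitter < 0 || hue_jitter > PHANTOM_MAX_JITTER) {
    stop("hue_jitter must be within [0, ", PHANTOM_MAX_JITTER,
         "] to keep jittered colours inside their class predicates")
  }
  structure(
    list(canvas = as.integer(canvas),
         outer_radius = as.numeric(outer_radius),
         inner_radius = as.numeric(inner_radius),
         infarct_angle = as.numeric(infarct_angle),
         transmural = isTRUE(transmural),
         fibrosis_density = as.numeric(fibrosis_density),
         hue_jitter = as.numeric(hue_jitter),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom section spec: %dx%d px, wall radii %g-%g px\n",
              x$canvas[1], x$canvas[2], x$inner_radius, x$outer_radius))
  cat(sprintf("  scar wedge %g deg (%s), fibrosis density %g, jitter %g\n",
              x$infarct_angle,
              if (x$transmural) "transmural" else "outer half wall",
              x$fibrosis_density, x$hue_jitter))
  invisible(x)
}

# integer jitter in [-j, j], clamped to 8-bit range
jitter_colors <- function(rgb, j) {
  if (j > 0 && nrow(rgb) > 0) {
    rgb <- rgb + matrix(sample(seq(-j, j), length(rgb), replace = TRUE),
                        nrow(rgb), 3)
  }
  pmin(pmax(round(rgb), 0), 255)
}

#' Paint one phantom section with exact ground truth
#'
#' Rasterises the annulus/wedge geometry on an integer pixel grid and
#' paints each region from its palette. Ground truth counts the painted
#' (rasterised) pixels, not analytic areas, so segmentation of the
#' returned image must reproduce them exactly. The scar ROI is the wedge
#' sector of the wall (full thickness), the remote ROI its complement
#' within the wall; together they partition the tissue.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_section`: list with `image` (RGB
#'   integer array), `counts` (ground-truth per-class pixel counts),
#'   `scar_roi` and `remote_roi` (logical matrices), `roi_counts`
#'   (ground-truth counts per ROI: `scar_collagen_px`, `scar_total_px`,
#'   `remote_fibrosis_px`, `remote_total_px`) and the `spec`.
#' @export
#' @examples
#' ph <- make_phantom_section(phantom_spec(seed = 1))
#' ph$counts
make_phantom_section <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  h <- spec$canvas[1]; w <- spec$canvas[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  wall <- r >= spec$inner_radius & r < spec$outer_radius
  sector <- wall & theta < spec$infarct_angle
  mid <- (spec$inner_radius + spec$outer_radius) / 2
  infarct <- if (spec$transmural) sector else sector & r >= mid
  muscle <- wall & !infarct
  # interstitial speckles: single collagen pixels inside the muscle wall
  speckle <- muscle & matrix(
    stats::runif(h * w) < spec$fibrosis_density, h, w)
  muscle_only <- muscle & !speckle
  collagen <- infarct | speckle

  img <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- PHANTOM_BACKGROUND[ch]
  paint <- function(img, mask, palette_fun) {
    n <- sum(mask)
    if (n == 0) return(img)
    cols <- jitter_colors(palette_fun(stats::runif(n)), spec$hue_jitter)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- cols[, ch]
      img[, , ch] <- plane
    }
    img
  }
  img <- paint(img, collagen, phantom_collagen_rgb)
  img <- paint(img, muscle_only, phantom_muscle_rgb)
  if (spec$hue_jitter > 0) {
    bgmask <- !wall
    nbg <- sum(bgmask)
    bgcols <- jitter_colors(matrix(PHANTOM_BACKGROUND, nbg, 3, byrow = TRUE),
                            spec$hue_jitter)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[bgmask] <- bgcols[, ch]
      img[, , ch] <- plane
    }
  }
  storage.mode(img) <- "integer"

  counts <- c(background = sum(!wall),
              collagen = sum(collagen),
              muscle = sum(muscle_only),
              other_tissue = 0L)
  roi_counts <- c(
    scar_collagen_px = sum(collagen & sector),
    scar_total_px = sum(sector),
    remote_fibrosis_px = sum(speckle & !sector),
    remote_total_px = sum(wall & !sector))
  structure(
    list(image = img, counts = counts,
         scar_roi = sector, remote_roi = wall & !sector,
         roi_counts = roi_counts, spec = spec),
    class = "phantom_section")
}

#' @export
print.phantom_section <- function(x, ...) {
  cat("synthetic trichrome-like section\n")
  print(x$counts)
  invisible(x)
}

#' Generate a tapered serial-section phantom series
#'
#' Emulates serial sectioning from apex to base: section radii change by
#' `taper` pixels per step (negative taper grows the heart towards the
#' base, the usual anatomy) and the scar wedge follows a per-section
#' angular profile, by default shrinking linearly from the apex value to
#' zero at the base. The ground-truth counts of every section yield an
#' exact volumetric infarct percentage to compare the pipeline against.
#'
#' @param base A [phantom_spec()] describing the first (apical) section.
#' @param k Number of sections (>= 1).
#' @param taper Outer-radius decrement per section in pixels; the inner
#'   radius is scaled proportionally. Negative values enlarge sections
#'   towards the base. Default -6.
#' @param infarct_profile Numeric vector of `k` wedge angles in degrees;
#'   default `seq(base$infarct_angle, 0, length.out = k)`.
#' @return List of `k` `phantom_section` objects (apex first).
#' @export
make_phantom_series <- function(base, k = 5, taper = -6,
                                infarct_profile = NULL) {
  stopifnot(inherits(base, "phantom_spec"))
  if (k < 1) stop("k must be >= 1")
  infarct_profile <- infarct_profile %||%
    seq(base$infarct_angle, 0, length.out = k)
  if (length(infarct_profile) != k) {
    stop("infarct_profile must have one angle per section")
  }
  seed0 <- base$seed %||% sample.int(.Machine$integer.max, 1)
  lapply(seq_len(k), function(i) {
    outer_i <- base$outer_radius - (i - 1) * taper
    inner_i <- max(1, round(base$inner_radius * outer_i /
                              base$outer_radius))
    if (outer_i <= inner_i || outer_i > min(base$canvas) / 2) {
      stop(sprintf("taper produces invalid radii at section %d", i))
    }
    sp <- phantom_spec(canvas = base$canvas,
                       outer_radius = outer_i,
                       inner_radius = inner_i,
                       infarct_angle = infarct_profile[i],
                       transmural = base$transmural,
                       fibrosis_density = base$fibrosis_density,
                       hue_jitter = base$hue_jitter,
                       seed = (seed0 + i) %% .Machine$integer.max)
    make_phantom_section(sp)
  })
}

#' Measurements and ground truth of a phantom series
#'
#' Convenience bridge from a phantom series to the morphometry layer:
#' builds a [section_series()] from the painter's ground-truth counts
#' (not from segmentation), for use as the expected value in end-to-end
#' comparisons.
#'
#' @param phantoms List of `phantom_section` objects.
#' @param spacing_um,n_px_per_spacing Passed to [section_series()].
#' @return A [section_series()].
#' @export
phantom_truth_series <- function(phantoms, spacing_um = 300,
                                 n_px_per_spacing = 1) {
  stopifnot(all(vapply(phantoms, inherits, logical(1), "phantom_section")))
  rows <- lapply(seq_along(phantoms), function(i) {
    ph <- phantoms[[i]]
    tissue <- sum(ph$counts[c("collagen", "muscle", "other_tissue")])
    section_measurement(
      section_index = i,
      total_area_px = tissue,
      infarct_area_px = ph$counts[["collagen"]],
      scar_collagen_px = ph$roi_counts[["scar_collagen_px"]],
      scar_total_px = ph$roi_counts[["scar_total_px"]],
      remote_fibrosis_px = ph$roi_counts[["remote_fibrosis_px"]],
      remote_total_px = ph$roi_counts[["remote_total_px"]])
  })
  section_series(rows, spacing_um = spacing_um,
                 n_px_per_spacing = n_px_per_spacing)
}
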