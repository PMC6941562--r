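# Tissue centroid (row, col) of a class map; NULL when the section holds
# no tissue pixels.
tissue_centroid <- function(map) {
  bg <- match("background", color_classes())
  sel <- map$labels != bg
  if (!any(sel)) return(NULL)
  idx <- which(sel, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Align serial sections by tissue centroid
#'
#' Computes a whole-pixel translation for every section so that its
#' tissue centroid lands on the centre of a common canvas. Translation is
#' the only transform applied — no rotation or scaling — so per-class
#' pixel counts are preserved exactly (padding is background).
#'
#' @param maps List of `pixel_class_map` objects.
#' @param canvas Canvas size `c(height, width)`; default: the maximal
#'   section size plus `margin` on each side.
#' @param margin Padding in pixels added around the largest section when
#'   the canvas is derived automatically. Default 8.
#' @return A list with `offsets` (matrix, one `(row, col)` shift per
#'   section) and `canvas` (`c(height, width)`). A section with no tissue
#'   gets offset `(0, 0)` with a warning.
#' @seealso [build_stack()]
#' @export
align_sections <- function(maps, canvas = NULL, margin = 8) {
  if (length(maps) == 0L) stop("need at least one section map")
  stopifnot(all(vapply(maps, inherits, logical(1), "pixel_class_map")))
  hs <- vapply(maps, function(m) m$height, numeric(1))
  ws <- vapply(maps, function(m) m$width, numeric(1))
  canvas <- canvas %||% c(max(hs) + 2 * margin, max(ws) + 2 * margin)
  centre <- (canvas + 1) / 2
  offsets <- matrix(0L, nrow = length(maps), ncol = 2,
                    dimnames = list(NULL, c("row", "col")))
  for (i in seq_along(maps)) {
    cen <- tissue_centroid(maps[[i]])
    if (is.null(cen)) {
      warning(sprintf("section %d has no tissue pixels; offset (0, 0)", i))
      next
    }
    offsets[i, ] <- as.integer(round(centre - cen))
  }
  list(offsets = offsets, canvas = as.integer(canvas))
}

# Place a label matrix onto a canvas at a whole-pixel offset; pixels
# falling outside the canvas are dropped, uncovered canvas is background.
translate_labels <- function(labels, offset, canvas) {
  bg <- match("background", color_classes())
  out <- matrix(bg, canvas[1], canvas[2])
  rows <- seq_len(nrow(labels)) + offset[1]
  cols <- seq_len(ncol(labels)) + offset[2]
  rkeep <- rows >= 1 & rows <= canvas[1]
  ckeep <- cols >= 1 & cols <= canvas[2]
  out[rows[rkeep], cols[ckeep]] <- labels[rkeep, ckeep, drop = FALSE]
  out
}

#' Assemble serial class maps into a labeled voxel stack
#'
#' Replicates every section into `z_step_px` consecutive slabs in
#' apex-to-base order, after centroid alignment onto a common canvas, and
#' returns the 3D label array. With the slab thickness chosen as the
#' number of pixels spanning one physical spacing interval, the stack is
#' an isotropic voxel model of the heart.
#'
#' @param maps List of `pixel_class_map` objects, ordered apex to base.
#' @param z_step_px Slabs per section (>= 1).
#' @param align If `TRUE` (default) sections are centroid-aligned via
#'   [align_sections()]; if `FALSE` all maps must share dimensions and
#'   are stacked as-is with zero offsets.
#' @param spacing_um Physical inter-section spacing recorded in the
#'   stack metadata. Default 300.
#' @return An object of class `voxel_stack`: list with `labels`
#'   (`height x width x depth` integer array), `z_step_px`,
#'   `section_of_slab` (source section per slab), `offsets`, `spacing_um`.
#' @export
#' @examples
#' img <- array(255L, dim = c(8, 8, 3))
#' img[3:6, 3:6, ] <- rep(c(200L, 40L, 40L), each = 16)
#' m <- segment_section(img)
#' st <- build_stack(list(m, m), z_step_px = 2)
#' dim(st$labels)  # depth 4
build_stack <- function(maps, z_step_px = 1, align = TRUE, spacing_um = 300) {
  if (length(maps) == 0L) stop("need at least one section map")
  stopifnot(all(vapply(maps, inherits, logical(1), "pixel_class_map")))
  if (z_step_px < 1) stop("z_step_px must be >= 1")
  z_step_px <- as.integer(z_step_px)
  if (align) {
    al <- align_sections(maps)
    offsets <- al$offsets
    canvas <- al$canvas
  } else {
    dims <- vapply(maps, function(m) c(m$height, m$width), numeric(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("with align = FALSE all maps must share canvas dimensions")
    }
    offsets <- matrix(0L, length(maps), 2,
                      dimnames = list(NULL, c("row", "col")))
    canvas <- c(maps[[1]]$height, maps[[1]]$width)
  }
  depth <- length(maps) * z_step_px
  labels <- array(match("background", color_classes()),
                  dim = c(canvas[1], canvas[2], depth))
  section_of_slab <- integer(depth)
  z <- 0L
  for (i in seq_along(maps)) {
    slab <- translate_labels(maps[[i]]$labels, offsets[i, ], canvas)
    for (k in seq_len(z_step_px)) {
      z <- z + 1L
      labels[, , z] <- slab
      section_of_slab[z] <- i
    }
  }
  structure(
    list(labels = labels, z_step_px = z_step_px,
         section_of_slab = section_of_slab, offsets = offsets,
         spacing_um = as.numeric(spacing_um)),
    class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("voxel stack: %d x %d x %d (depth = %d sections x %d slabs)\n",
              d[1], d[2], d[3], length(unique(x$section_of_slab)),
              x$z_step_px))
  cat(sprintf("  spacing %g um per section\n", x$spacing_um))
  invisible(x)
}

#' Per-class voxel counts and volumetric infarct size of a stack
#'
#' Counts voxels per class over the whole stack and derives the
#' volumetric infarct percentage as collagen voxels over all tissue
#' (non-background) voxels. For a stack built with uniform slab
#' thickness from the same maps, this equals
#' [volumetric_infarct_fraction()] of the corresponding series exactly —
#' a cross-check between the 2D and 3D pipelines.
#'
#' @param stack A [build_stack()] result.
#' @return List with `voxel_counts` (named, the four classes) and
#'   `volumetric_infarct_pct`.
#' @export
stack_volume_summary <- function(stack) {
  stopifnot(inherits(stack, "voxel_stack"))
  counts <- tabulate(stack$labels, nbins = 4L)
  names(counts) <- color_classes()
  tissue <- sum(counts[c("collagen", "muscle", "other_tissue")])
  list(voxel_counts = counts,
       volumetric_infarct_pct =
         if (tissue == 0) 0 else 100 * counts[["collagen"]] / tissue)
}

#' Export a voxel stack as transparent PNG slices
#'
#' Writes one RGBA PNG per slab (background transparent, tissue classes
#' in their display colours) plus a JSON sidecar holding the slab
#' thickness, spacing, per-section offsets and the colour-to-class
#' legend. [import_stack_slices()] reproduces the label array from such
#' a directory.
#'
#' @param stack A [build_stack()] result.
#' @param dir Output directory (created if missing).
#' @param colors Display colours per class.
#' @return Invisibly, the vector of slice file paths.
#' @export
export_stack_slices <- function(stack, dir,
                                colors = class_display_colors()) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  depth <- dim(stack$labels)[3]
  paths <- character(depth)
  bg <- match("background", color_classes())
  for (z in seq_len(depth)) {
    slab <- stack$labels[, , z]
    map <- new_class_map(slab)
    ov <- render_overlay(map, include = setdiff(color_classes(),
                                                "background"),
                         colors = colors)
    paths[z] <- file.path(dir, sprintf("slice_%04d.png", z))
    png::writePNG(ov / 255, paths[z])
  }
  legend <- as.list(colors[setdiff(color_classes(), "background")])
  meta <- list(z_step_px = stack$z_step_px,
               spacing_um = stack$spacing_um,
               depth = depth,
               section_of_slab = stack$section_of_slab,
               offsets = unname(stack$offsets),
               class_colors = legend)
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Re-import a slice directory written by [export_stack_slices()]
#'
#' @param dir Directory holding `slice_*.png` files and `stack.json`.
#' @return A `voxel_stack` with labels reconstructed from the slice
#'   colours.
#' @export
import_stack_slices <- function(dir) {
  meta_path <- file.path(dir, "stack.json")
  if (!file.exists(meta_path)) stop("no stack.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^slice_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no slice PNGs in ", dir)
  colmap <- vapply(meta$class_colors, identity, character(1))
  key <- t(grDevices::col2rgb(colmap)) # one row per class colour
  bg <- match("background", color_classes())
  slabs <- lapply(files, function(f) {
    arr <- round(png::readPNG(f) * 255)
    lab <- matrix(bg, dim(arr)[1], dim(arr)[2])
    opaque <- arr[, , 4] > 0
    for (ci in seq_along(colmap)) {
      cl <- match(names(colmap)[ci], color_classes())
      sel <- opaque & arr[, , 1] == key[ci, 1] &
        arr[, , 2] == key[ci, 2] & arr[, , 3] == key[ci, 3]
      lab[sel] <- cl
    }
    lab
  })
  labels <- array(unlist(slabs),
                  dim = c(nrow(slabs[[1]]), ncol(slabs[[1]]),
                          length(slabs)))
  offsets <- matrix(as.integer(meta$offsets), ncol = 2,
                    dimnames = list(NULL, c("row", "col")))
  structure(
    list(labels = labels, z_step_px = as.integer(meta$z_step_px),
         section_of_slab = as.integer(meta$section_of_slab),
         offsets = offsets, spacing_um = as.numeric(meta$spacing_um)),
    class = "voxel_stack")
}
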