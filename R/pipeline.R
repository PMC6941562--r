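#' Configuration of a full morphometry run
#'
#' Collects everything one batch run needs: the section images (a glob
#' pattern or an explicit ordered vector of paths), optional scar and
#' remote ROI masks (parallel to the sections), the threshold scheme,
#' the physical spacing, and output options. Sections given as a glob
#' are ordered lexicographically, so zero-padded filenames sort
#' correctly.
#'
#' @param images Character vector of image paths, or a single glob
#'   pattern (e.g. `"sections/*.png"`).
#' @param scar_masks,remote_masks Optional mask paths, one per section
#'   (`NA` entries allowed for sections without a ROI).
#' @param scheme A [threshold_scheme()].
#' @param spacing_um Inter-section spacing, micrometres. Default 300.
#' @param n_px_per_spacing Voxel slabs per spacing interval. Default 1.
#' @param out_dir Output directory.
#' @param write_overlays Write per-section RGBA overlays. Default `TRUE`.
#' @param write_stack Export the aligned voxel stack as PNG slices.
#'   Default `FALSE`.
#' @param report_format `"csv"` or `"spreadsheet"` (see
#'   [write_report()]).
#' @param min_object_px Optional small-object cleanup size passed to
#'   [segment_section()]. Default 0 (raw counting).
#' @param verbose Log per-section class counts. Default `TRUE`.
#' @return An object of class `run_config`.
#' @seealso [run_pipeline()], [read_run_config()]
#' @export
run_config <- function(images, scar_masks = NULL, remote_masks = NULL,
                       scheme = threshold_scheme(), spacing_um = 300,
                       n_px_per_spacing = 1, out_dir = "cardiomorph_out",
                       write_overlays = TRUE, write_stack = FALSE,
                       report_format = c("csv", "spreadsheet"),
                       min_object_px = 0, verbose = TRUE) {
  if (length(images) == 1L && grepl("[*?\\[]", images)) {
    images <- sort(Sys.glob(images))
  }
  if (length(images) == 0L) stop("no input images: empty glob or vector")
  missing <- images[!file.exists(images)]
  if (length(missing)) {
    stop("input image(s) not found: ", paste(missing, collapse = ", "))
  }
  check_masks <- function(masks, what) {
    if (is.null(masks)) return(NULL)
    if (length(masks) != length(images)) {
      stop(what, " must have one entry per section (NA allowed)")
    }
    bad <- masks[!is.na(masks) & !file.exists(masks)]
    if (length(bad)) stop(what, " not found: ", paste(bad, collapse = ", "))
    masks
  }
  if (spacing_um <= 0) stop("spacing_um must be positive")
  if (n_px_per_spacing < 1) stop("n_px_per_spacing must be >= 1")
  stopifnot(inherits(scheme, "threshold_scheme"))
  structure(
    list(images = images,
         scar_masks = check_masks(scar_masks, "scar_masks"),
         remote_masks = check_masks(remote_masks, "remote_masks"),
         scheme = scheme,
         spacing_um = as.numeric(spacing_um),
         n_px_per_spacing = as.numeric(n_px_per_spacing),
         out_dir = out_dir,
         write_overlays = isTRUE(write_overlays),
         write_stack = isTRUE(write_stack),
         report_format = match.arg(report_format),
         min_object_px = as.numeric(min_object_px),
         verbose = isTRUE(verbose)),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML file may hold any [run_config()] argument; the `scheme` key,
#' when present, is a nested mapping of [threshold_scheme()] parameters.
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML configuration path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | grepl("^/", p), p, file.path(base, p))
  }
  for (key in c("images", "scar_masks", "remote_masks")) {
    if (!is.null(vals[[key]])) {
      vals[[key]] <- resolve(as.character(vals[[key]]))
    }
  }
  if (!is.null(vals$out_dir) && !grepl("^/", vals$out_dir)) {
    vals$out_dir <- file.path(base, vals$out_dir)
  }
  if (!is.null(vals$scheme)) vals$scheme <- do.call(threshold_scheme, vals$scheme)
  do.call(run_config, vals)
}

#' Run the full section-to-report pipeline
#'
#' For every section image: read, segment, count (within ROIs when masks
#' are given) and, if requested, write the transparent overlay. The
#' per-section measurements are assembled into a [section_series()],
#' summarised, and written out as a measurement CSV plus a report with
#' summary footer; optionally the aligned voxel stack is exported as
#' PNG slices. A failing section is recorded and skipped — the run
#' continues and the exit status reflects whether any section failed.
#'
#' @param config A [run_config()] or the path of a YAML configuration.
#' @return Invisibly, a list with `status` (0 if every section
#'   succeeded, 1 otherwise), `series`, `summary`, `failures` (named
#'   character vector of error messages) and `outputs` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (config$verbose) message(sprintf(...))

  maps <- list()
  measurements <- list()
  failures <- character(0)
  for (i in seq_along(config$images)) {
    path <- config$images[i]
    res <- tryCatch({
      img <- read_section_image(path)
      map <- segment_section(img, config$scheme,
                             min_object_px = config$min_object_px)
      dims <- c(map$height, map$width)
      scar <- remote <- NULL
      if (!is.null(config$scar_masks) && !is.na(config$scar_masks[i])) {
        scar <- read_roi_mask(config$scar_masks[i], dims)
      }
      if (!is.null(config$remote_masks) && !is.na(config$remote_masks[i])) {
        remote <- read_roi_mask(config$remote_masks[i], dims)
      }
      m <- measure_section(map, section_index = i,
                           scar_roi = scar, remote_roi = remote)
      log("section %d (%s): %s", i, basename(path),
          paste(sprintf("%s=%d", names(map$counts), map$counts),
                collapse = " "))
      list(map = map, m = m)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[basename(path)] <- conditionMessage(res)
      log("section %d (%s) FAILED: %s", i, basename(path),
          conditionMessage(res))
      next
    }
    maps[[length(maps) + 1L]] <- res$map
    measurements[[length(measurements) + 1L]] <- res$m
    if (config$write_overlays) {
      ov <- render_overlay(res$map)
      write_image_png(
        ov, file.path(config$out_dir,
                      sprintf("overlay_%03d.png", i)))
    }
  }
  if (length(measurements) == 0L) {
    stop("every section failed; no measurements produced")
  }
  series <- section_series(measurements, spacing_um = config$spacing_um,
                           n_px_per_spacing = config$n_px_per_spacing)
  summ <- summarize_series(series)

  outputs <- character(0)
  meas_path <- file.path(config$out_dir, "measurements.csv")
  utils::write.csv(as.data.frame(series), meas_path, row.names = FALSE)
  outputs <- c(outputs, meas_path)
  report_path <- file.path(config$out_dir, "report.csv")
  outputs <- c(outputs,
               write_report(report_rows(series), summ, report_path,
                            format = config$report_format))
  if (config$write_stack) {
    stack <- build_stack(maps, z_step_px = config$n_px_per_spacing,
                         spacing_um = config$spacing_um)
    export_stack_slices(stack, file.path(config$out_dir, "stack"))
    outputs <- c(outputs, file.path(config$out_dir, "stack"))
  }
  status <- if (length(failures)) 1L else 0L
  invisible(list(status = status, series = series, summary = summ,
                 failures = failures, outputs = outputs))
}
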