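#' Per-section pixel measurements
#'
#' One row of a serial-section measurement table: total stained-tissue
#' area and infarcted (collagen) area of a section, plus optional
#' region-of-interest counts for scar collagen content and remote
#' interstitial fibrosis. Counts from sections that were not measured
#' (e.g. the apex tip) are recorded as `NA` and excluded from averages —
#' never silently treated as zero.
#'
#' @param section_index Ordinal position of the section, counted from the
#'   apex (1-based).
#' @param total_area_px Total heart tissue area, pixels (all
#'   non-background pixels of the section).
#' @param infarct_area_px Infarcted area, pixels (collagen-class pixels of
#'   the section, or of the scar ROI when one was delineated).
#' @param scar_collagen_px,scar_total_px Collagen pixels and total tissue
#'   pixels inside the scar ROI, or `NA` when no scar ROI exists.
#' @param remote_fibrosis_px,remote_total_px Collagen (fibrosis) pixels
#'   and total tissue pixels inside the remote-zone ROI, or `NA`.
#' @return An object of class `section_measurement` (named list).
#' @seealso [section_series()], [measure_section()]
#' @export
section_measurement <- function(section_index,
                                total_area_px,
                                infarct_area_px,
                                scar_collagen_px = NA,
                                scar_total_px = NA,
                                remote_fibrosis_px = NA,
                                remote_total_px = NA) {
  m <- list(section_index = as.integer(section_index),
            total_area_px = as.numeric(total_area_px),
            infarct_area_px = as.numeric(infarct_area_px),
            scar_collagen_px = as.numeric(scar_collagen_px),
            scar_total_px = as.numeric(scar_total_px),
            remote_fibrosis_px = as.numeric(remote_fibrosis_px),
            remote_total_px = as.numeric(remote_total_px))
  counts <- unlist(m[-1])
  if (any(counts < 0, na.rm = TRUE)) stop("pixel counts must be nonnegative")
  if (!is.na(m$total_area_px) && !is.na(m$infarct_area_px) &&
      m$infarct_area_px > m$total_area_px) {
    stop("infarct_area_px cannot exceed total_area_px")
  }
  if (!is.na(m$scar_collagen_px) && !is.na(m$scar_total_px) &&
      m$scar_collagen_px > m$scar_total_px) {
    stop("scar_collagen_px cannot exceed scar_total_px")
  }
  if (!is.na(m$remote_fibrosis_px) && !is.na(m$remote_total_px) &&
      m$remote_fibrosis_px > m$remote_total_px) {
    stop("remote_fibrosis_px cannot exceed remote_total_px")
  }
  structure(m, class = "section_measurement")
}

measurement_fields <- function() {
  c("section_index", "total_area_px", "infarct_area_px",
    "scar_collagen_px", "scar_total_px",
    "remote_fibrosis_px", "remote_total_px")
}

#' A serial-section series with physical spacing
#'
#' Orders per-section measurements from apex to base and attaches the
#' physical inter-section spacing. Volumetric quantities weight each
#' section by `n_px_per_spacing`, the slab thickness in pixels that one
#' spacing interval corresponds to; with uniform spacing the weight
#' cancels out of all ratios.
#'
#' @param sections A list of [section_measurement()] objects, or a data
#'   frame with (a subset of) the measurement columns.
#' @param spacing_um Physical distance between consecutive sections in
#'   micrometres. Default 300.
#' @param n_px_per_spacing Number of voxel slabs per spacing interval
#'   (>= 1). Default 1.
#' @return An object of class `section_series`: a data frame with one row
#'   per section, ordered by increasing `section_index`, with the spacing
#'   stored as attributes.
#' @export
#' @examples
#' s <- section_series(data.frame(
#'   section_index = 1:3,
#'   total_area_px = c(1000, 2000, 3000),
#'   infarct_area_px = c(100, 100, 0)))
#' summary(s)
section_series <- function(sections, spacing_um = 300, n_px_per_spacing = 1) {
  if (inherits(sections, "section_measurement")) sections <- list(sections)
  if (is.list(sections) && !is.data.frame(sections)) {
    ok <- vapply(sections, inherits, logical(1), "section_measurement")
    if (!all(ok)) stop("sections must all be section_measurement objects")
    df <- do.call(rbind, lapply(sections, function(m) {
      as.data.frame(unclass(m))
    }))
  } else if (is.data.frame(sections)) {
    df <- sections
    for (f in setdiff(measurement_fields(), names(df))) df[[f]] <- NA_real_
    df <- df[measurement_fields()]
    # route each row through the constructor for validation
    for (i in seq_len(nrow(df))) do.call(section_measurement, as.list(df[i, ]))
  } else {
    stop("sections must be a data frame or a list of section_measurement")
  }
  if (nrow(df) == 0L) stop("series must contain at least one section")
  if (anyDuplicated(df$section_index)) stop("duplicate section_index")
  if (spacing_um <= 0) stop("spacing_um must be positive")
  if (n_px_per_spacing < 1) stop("n_px_per_spacing must be >= 1")
  df <- df[order(df$section_index), ]
  rownames(df) <- NULL
  structure(df,
            spacing_um = as.numeric(spacing_um),
            n_px_per_spacing = as.numeric(n_px_per_spacing),
            class = c("section_series", "data.frame"))
}

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf("serial-section series: %d sections, %g um apart (n = %g px per interval)\n",
              nrow(x), attr(x, "spacing_um"), attr(x, "n_px_per_spacing")))
  print(as.data.frame(x), ...)
  invisible(x)
}

pct <- function(num, den) 100 * num / den

#' Per-section infarct size
#'
#' The infarcted fraction of one section: `100 * infarct / total` in
#' percent of the section's tissue area.
#'
#' @param m A [section_measurement()], or a [section_series()] (then a
#'   vector with one value per section is returned, `NA` for unmeasured
#'   sections).
#' @return Percent value(s) in `[0, 100]`.
#' @export
infarct_fraction_section <- function(m) {
  if (inherits(m, "section_series")) {
    return(ifelse(is.na(m$total_area_px) | is.na(m$infarct_area_px),
                  NA_real_, pct(m$infarct_area_px, m$total_area_px)))
  }
  stopifnot(inherits(m, "section_measurement"))
  if (is.na(m$total_area_px) || is.na(m$infarct_area_px)) return(NA_real_)
  if (m$total_area_px <= 0) {
    stop("infarct fraction undefined: total_area_px is zero")
  }
  pct(m$infarct_area_px, m$total_area_px)
}

valid_rows <- function(s) {
  !is.na(s$total_area_px) & !is.na(s$infarct_area_px) & s$total_area_px > 0
}

#' Volumetric infarct size of a serial-section series
#'
#' Approximates infarct volume over heart volume by summing per-section
#' areas weighted by the slab thickness `n` (pixels per 300 um spacing
#' interval):
#' \deqn{S = 100 \frac{\sum_i \vartheta_i \, n_i}{\sum_i \theta_i \, n_i}}
#' where \eqn{\vartheta_i} is the infarcted and \eqn{\theta_i} the total
#' tissue area of section \eqn{i}. With uniform `n` the weight cancels and
#' the result is `100 * sum(infarct) / sum(total)`. Sections without
#' measurements are skipped. This area-weighted volume fraction generally
#' differs from (and for apical infarcts lies below) the unweighted mean
#' of per-section percentages, because large basal sections with little
#' infarct dominate the volume.
#'
#' @param s A [section_series()].
#' @param n Slab weight(s): a scalar, or a vector with one weight per
#'   section. Defaults to the series' `n_px_per_spacing`.
#' @return Volumetric infarct size in percent.
#' @seealso [average_infarct_fraction()], [stack_volume_summary()]
#' @export
volumetric_infarct_fraction <- function(s, n = NULL) {
  stopifnot(inherits(s, "section_series"))
  n <- n %||% attr(s, "n_px_per_spacing")
  if (length(n) == 1L) n <- rep(n, nrow(s))
  if (length(n) != nrow(s)) stop("n must be scalar or one weight per section")
  if (any(n < 1)) stop("slab weights must be >= 1")
  keep <- valid_rows(s)
  if (!any(keep)) stop("no section with measured areas")
  pct(sum(s$infarct_area_px[keep] * n[keep]),
      sum(s$total_area_px[keep] * n[keep]))
}

#' Average per-section infarct size
#'
#' The unweighted arithmetic mean of the per-section infarct percentages
#' over the measured sections — the conventional reporting of infarct
#' size from a handful of sections.
#'
#' @param s A [section_series()].
#' @return Percent.
#' @export
average_infarct_fraction <- function(s) {
  stopifnot(inherits(s, "section_series"))
  v <- infarct_fraction_section(s)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no section with measured areas")
  mean(v)
}

#' Scar collagen content of a section
#'
#' Net collagen content of the scar: collagen-class (blue) pixels as a
#' percentage of the tissue pixels inside the scar ROI. Returns `NA` when
#' the section has no scar ROI measurement, so it drops out of averages.
#'
#' @param m A [section_measurement()] or [section_series()].
#' @return Percent, or `NA`.
#' @export
collagen_content_pct <- function(m) {
  if (inherits(m, "section_series")) {
    return(ifelse(is.na(m$scar_total_px) | is.na(m$scar_collagen_px) |
                    m$scar_total_px <= 0,
                  NA_real_, pct(m$scar_collagen_px, m$scar_total_px)))
  }
  stopifnot(inherits(m, "section_measurement"))
  if (is.na(m$scar_total_px) || is.na(m$scar_collagen_px)) return(NA_real_)
  if (m$scar_total_px <= 0) stop("collagen content undefined: empty scar ROI")
  pct(m$scar_collagen_px, m$scar_total_px)
}

#' Interstitial fibrosis of the remote myocardium
#'
#' Fine collagen deposits between surviving muscle fibres, away from the
#' scar: collagen-class pixels inside the remote ROI as a percentage of
#' the tissue pixels of that ROI. `NA` when no remote ROI was delineated.
#'
#' @param m A [section_measurement()] or [section_series()].
#' @return Percent, or `NA`.
#' @export
interstitial_fibrosis_pct <- function(m) {
  if (inherits(m, "section_series")) {
    return(ifelse(is.na(m$remote_total_px) | is.na(m$remote_fibrosis_px) |
                    m$remote_total_px <= 0,
                  NA_real_, pct(m$remote_fibrosis_px, m$remote_total_px)))
  }
  stopifnot(inherits(m, "section_measurement"))
  if (is.na(m$remote_total_px) || is.na(m$remote_fibrosis_px)) return(NA_real_)
  if (m$remote_total_px <= 0) {
    stop("interstitial fibrosis undefined: empty remote ROI")
  }
  pct(m$remote_fibrosis_px, m$remote_total_px)
}

#' Summarise a serial-section series
#'
#' Assembles the per-section infarct percentages, their unweighted
#' average, the volumetric infarct fraction, and the averages of scar
#' collagen content and remote interstitial fibrosis over the sections
#' where those ROIs were measured.
#'
#' @param s A [section_series()].
#' @return An object of class `series_summary` with fields
#'   `per_section_pct`, `average_infarct_pct`, `volumetric_infarct_pct`,
#'   `avg_collagen_pct`, `avg_fibrosis_pct`, `n_sections`,
#'   `n_measured` and `spacing_um`.
#' @export
summarize_series <- function(s) {
  stopifnot(inherits(s, "section_series"))
  coll <- collagen_content_pct(s)
  fib <- interstitial_fibrosis_pct(s)
  structure(
    list(per_section_pct = infarct_fraction_section(s),
         average_infarct_pct = average_infarct_fraction(s),
         volumetric_infarct_pct = volumetric_infarct_fraction(s),
         avg_collagen_pct = if (all(is.na(coll))) NA_real_
                            else mean(coll, na.rm = TRUE),
         avg_fibrosis_pct = if (all(is.na(fib))) NA_real_
                            else mean(fib, na.rm = TRUE),
         n_sections = nrow(s),
         n_measured = sum(valid_rows(s)),
         spacing_um = attr(s, "spacing_um")),
    class = "series_summary")
}

#' @export
summary.section_series <- function(object, ...) summarize_series(object)

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf("serial-section morphometry (%d of %d sections measured, %g um spacing)\n",
              x$n_measured, x$n_sections, x$spacing_um))
  cat(sprintf("  average infarct size    : %6.2f %%\n", x$average_infarct_pct))
  cat(sprintf("  volumetric infarct size : %6.2f %%\n",
              x$volumetric_infarct_pct))
  if (!is.na(x$avg_collagen_pct)) {
    cat(sprintf("  scar collagen content   : %6.2f %%\n", x$avg_collagen_pct))
  }
  if (!is.na(x$avg_fibrosis_pct)) {
    cat(sprintf("  interstitial fibrosis   : %6.2f %%\n", x$avg_fibrosis_pct))
  }
  invisible(x)
}

#' Measure a segmented section
#'
#' Turns a [segment_section()] class map (plus optional scar / remote ROI
#' masks) into a [section_measurement()]: total tissue area = all
#' non-background pixels; infarcted area = collagen pixels (of the scar
#' ROI when given, of the whole section otherwise); ROI sub-counts for
#' collagen content and interstitial fibrosis when masks are supplied.
#'
#' @param map A `pixel_class_map`.
#' @param section_index Ordinal of the section from the apex.
#' @param scar_roi,remote_roi Optional logical masks (section dimensions)
#'   delineating the scar and the remote myocardium.
#' @return A [section_measurement()].
#' @export
measure_section <- function(map, section_index,
                            scar_roi = NULL, remote_roi = NULL) {
  stopifnot(inherits(map, "pixel_class_map"))
  tissue <- function(counts) sum(counts[c("collagen", "muscle", "other_tissue")])
  infarct <- map$counts[["collagen"]]
  scar_collagen <- scar_total <- remote_fibrosis <- remote_total <- NA
  if (!is.null(scar_roi)) {
    sc <- count_roi_classes(map, scar_roi)
    scar_collagen <- sc[["collagen"]]
    scar_total <- tissue(sc)
    infarct <- sc[["collagen"]]
  }
  if (!is.null(remote_roi)) {
    rc <- count_roi_classes(map, remote_roi)
    remote_fibrosis <- rc[["collagen"]]
    remote_total <- tissue(rc)
  }
  section_measurement(
    section_index = section_index,
    total_area_px = tissue(map$counts),
    infarct_area_px = infarct,
    scar_collagen_px = scar_collagen,
    scar_total_px = scar_total,
    remote_fibrosis_px = remote_fibrosis,
    remote_total_px = remote_total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
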