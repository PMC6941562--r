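#' Bundled reference dataset: infarcted mouse heart, 10 serial sections
#'
#' Per-section pixel measurements of one chronically infarcted mouse
#' heart (4 weeks after coronary ligation), sectioned apex to mitral
#' valve at 300 um intervals and trichrome-stained. Each section was
#' measured twice: manually with a commercial morphometry workstation
#' (`manual_*` columns) and by automated per-pixel colour counting
#' (`auto_*` columns). Section 1 (the apex tip) was not measurable and
#' is `NA` throughout.
#'
#' `mouse_mi_sections()` returns the area table (total heart area and
#' infarcted area per section, in pixels); `mouse_mi_roi()` returns the
#' companion ROI percentages (scar collagen content and remote
#' interstitial fibrosis per section, in percent), where the manual
#' collagen column is missing for the basal sections that have no scar.
#'
#' @param method `"auto"`, `"manual"` or `"both"` (default). For
#'   `mouse_mi_sections()` with a single method, a [section_series()]
#'   ready for morphometry is returned; with `"both"` the raw table.
#' @return A data frame (or a [section_series()], see above).
#' @export
#' @examples
#' summary(mouse_mi_sections("auto"))
mouse_mi_sections <- function(method = c("both", "auto", "manual")) {
  method <- match.arg(method)
  tab <- utils::read.csv(system.file("extdata",
                                     "mouse_mi_serial_sections.csv",
                                     package = "cardiomorph"))
  if (method == "both") return(tab)
  pre <- paste0(method, "_")
  section_series(data.frame(
    section_index = tab$section_index,
    total_area_px = tab[[paste0(pre, "total_px")]],
    infarct_area_px = tab[[paste0(pre, "infarct_px")]]))
}

#' @rdname mouse_mi_sections
#' @export
mouse_mi_roi <- function() {
  utils::read.csv(system.file("extdata", "mouse_mi_roi_percentages.csv",
                              package = "cardiomorph"))
}
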