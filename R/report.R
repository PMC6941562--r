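#' Build the per-section report table
#'
#' One row per section with the pixel counts and the derived
#' percentages, mirroring the layout of a morphometry report: section
#' index, total and infarcted area in pixels, infarct size, scar
#' collagen content and remote interstitial fibrosis in percent.
#' Unmeasured quantities stay `NA` — they are never silently zero.
#'
#' @param s A [section_series()].
#' @param digits Decimal places for the percentage columns (round
#'   half-even). Default 2.
#' @return Data frame of report rows.
#' @export
report_rows <- function(s, digits = 2) {
  stopifnot(inherits(s, "section_series"))
  data.frame(
    section_index = s$section_index,
    total_area_px = s$total_area_px,
    infarct_area_px = s$infarct_area_px,
    infarct_pct = round(infarct_fraction_section(s), digits),
    collagen_pct = round(collagen_content_pct(s), digits),
    fibrosis_pct = round(interstitial_fibrosis_pct(s), digits))
}

format_num <- function(x, decimal_mark = ".") {
  out <- ifelse(is.na(x), "NA", format(x, trim = TRUE, scientific = FALSE))
  if (decimal_mark != ".") out <- gsub(".", decimal_mark, out, fixed = TRUE)
  out
}

#' Write a morphometry report (CSV, optionally a spreadsheet)
#'
#' Writes the per-section rows followed by labeled summary footer rows
#' (`Average`, `Volume infarction (%)`). A CSV is always produced; with
#' `format = "spreadsheet"` an additional SpreadsheetML XML file (the
#' plain-text spreadsheet format Excel opens natively) is written next
#' to it with the same content.
#'
#' @param rows Report rows from [report_rows()].
#' @param summary A [summarize_series()] result.
#' @param path Output CSV path.
#' @param format `"csv"` (default) or `"spreadsheet"` (CSV plus
#'   `.xml` spreadsheet).
#' @param decimal_mark Decimal separator for the report, `"."` by
#'   default; `","` emits the continental convention (the CSV delimiter
#'   then switches to `";"`).
#' @param digits Decimal places for summary percentages. Default 2.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(rows, summary, path, format = c("csv", "spreadsheet"),
                         decimal_mark = ".", digits = 2) {
  format <- match.arg(format)
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("rows must be a nonempty data frame of report rows")
  }
  stopifnot(inherits(summary, "series_summary"))
  sep <- if (decimal_mark == ",") ";" else ","
  fmt <- function(x) format_num(x, decimal_mark)
  header <- names(rows)
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste(vapply(rows[i, ], function(v) fmt(v), character(1)), collapse = sep)
  }, character(1))
  footer <- c(
    paste(c("Average", "", "", fmt(round(summary$average_infarct_pct, digits)),
            fmt(round(summary$avg_collagen_pct, digits)),
            fmt(round(summary$avg_fibrosis_pct, digits))), collapse = sep),
    paste(c("Volume infarction (%)", "", "",
            fmt(round(summary$volumetric_infarct_pct, digits)), "", ""),
          collapse = sep))
  lines <- c(paste(header, collapse = sep), body, footer)
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report to ", path)
  written <- path
  if (format == "spreadsheet") {
    xml_path <- paste0(tools::file_path_sans_ext(path), ".xml")
    write_spreadsheetml(rows, summary, xml_path, digits = digits)
    written <- c(written, xml_path)
  }
  invisible(written)
}

# SpreadsheetML 2003 workbook: a single worksheet with typed cells.
write_spreadsheetml <- function(rows, summary, path, digits = 2) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  cell <- function(v) {
    if (length(v) == 1 && (is.na(v) || identical(v, ""))) {
      return("   <Cell><Data ss:Type=\"String\"></Data></Cell>")
    }
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) {
      sprintf("   <Cell><Data ss:Type=\"Number\">%s</Data></Cell>",
              format(num, scientific = FALSE, trim = TRUE))
    } else {
      sprintf("   <Cell><Data ss:Type=\"String\">%s</Data></Cell>",
              esc(as.character(v)))
    }
  }
  row_xml <- function(values) {
    c("  <Row>", vapply(values, cell, character(1)), "  </Row>")
  }
  lines <- c(
    "<?xml version=\"1.0\"?>",
    "<?mso-application progid=\"Excel.Sheet\"?>",
    "<Workbook xmlns=\"urn:schemas-microsoft-com:office:spreadsheet\"",
    " xmlns:ss=\"urn:schemas-microsoft-com:office:spreadsheet\">",
    " <Worksheet ss:Name=\"morphometry\">",
    " <Table>",
    row_xml(names(rows)))
  for (i in seq_len(nrow(rows))) {
    lines <- c(lines, row_xml(as.list(rows[i, ])))
  }
  lines <- c(lines,
    row_xml(list("Average", "", "",
                 round(summary$average_infarct_pct, digits),
                 round(summary$avg_collagen_pct, digits),
                 round(summary$avg_fibrosis_pct, digits))),
    row_xml(list("Volume infarction (%)", "", "",
                 round(summary$volumetric_infarct_pct, digits), "", "")),
    " </Table>",
    " </Worksheet>",
    "</Workbook>")
  writeLines(lines, path)
  invisible(path)
}

#' Read back a report CSV
#'
#' Parses a file written by [write_report()] into its per-section rows
#' and summary footer. Counts and `NA` markers round-trip losslessly.
#'
#' @param path Report CSV path.
#' @param decimal_mark Decimal separator used when writing.
#' @return List with `rows` (data frame) and `summary` (list with
#'   `average_infarct_pct`, `avg_collagen_pct`, `avg_fibrosis_pct`,
#'   `volumetric_infarct_pct`).
#' @export
read_report <- function(path, decimal_mark = ".") {
  sep <- if (decimal_mark == ",") ";" else ","
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a report file: ", path)
  is_footer <- grepl("^(Average|Volume infarction)", lines)
  tab <- utils::read.table(text = lines[!is_footer], sep = sep,
                           header = TRUE, dec = decimal_mark,
                           na.strings = "NA")
  foot <- strsplit(lines[is_footer], sep, fixed = TRUE)
  num <- function(x) {
    if (decimal_mark != ".") x <- gsub(decimal_mark, ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(x))
  }
  avg <- foot[[grep("^Average", lines[is_footer])[1]]]
  vol <- foot[[grep("^Volume", lines[is_footer])[1]]]
  list(rows = tab,
       summary = list(average_infarct_pct = num(avg[4]),
                      avg_collagen_pct = num(avg[5]),
                      avg_fibrosis_pct = num(avg[6]),
                      volumetric_infarct_pct = num(vol[4])))
}
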