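#' Export facet tables to CSV files or an Excel workbook
#'
#' Writes the comparison result in one of two forms:
#'
#' * `format = "csv"`: one RFC-4180 CSV file per facet (`all.csv`,
#'   `common.csv`, ...) inside the directory `path`, UTF-8 encoded. The
#'   first column is the aligner column (the name literal), followed by one
#'   column per hierarchy. Re-reading with [read_facet_tables()] reproduces
#'   the tables cell for cell.
#' * `format = "xlsx"`: a single Excel workbook at `path` with one worksheet
#'   per facet, same column layout, source columns labelled by dataset name.
#'   The workbook is written directly as minimal Office Open XML (inline
#'   strings), readable by spreadsheet applications and by `readxl`.
#'
#' Empty facets produce a header-only sheet/file.
#'
#' @param tables a `facet_tables` object from [classify()].
#' @param path output directory (csv) or file path (xlsx).
#' @param format `"csv"` or `"xlsx"`.
#' @param use_labels label source columns with dataset names instead of
#'   source ids (default `TRUE` for xlsx, `FALSE` for csv so that csv
#'   round-trips are exact).
#' @return the paths written, invisibly.
#' @export
export_tables <- function(tables, path, format = c("csv", "xlsx"),
                          use_labels = NULL) {
  stopifnot(inherits(tables, "facet_tables"))
  format <- match.arg(format)
  if (!length(tables) || !nrow(tables$all)) {
    stop("facet tables are empty", call. = FALSE)
  }
  labels <- attr(tables, "labels")
  relabel <- function(tab) {
    idx <- match(names(tab), names(labels))
    names(tab)[!is.na(idx)] <- unname(labels[idx[!is.na(idx)]])
    tab
  }
  if (format == "csv") {
    use_labels <- use_labels %||% FALSE
    if (!dir.exists(path)) dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(path)) stop(sprintf("cannot create directory %s", path), call. = FALSE)
    paths <- vapply(names(tables), function(f) {
      tab <- tables[[f]]
      if (use_labels) tab <- relabel(tab)
      fp <- file.path(path, paste0(f, ".csv"))
      readr::write_csv(tab, fp, na = "")
      fp
    }, character(1))
    return(invisible(paths))
  }
  use_labels <- use_labels %||% TRUE
  sheets <- lapply(unclass(tables), function(tab) if (use_labels) relabel(tab) else tab)
  write_xlsx_inline(sheets, path)
  invisible(path)
}

#' Read back a CSV facet export
#'
#' Inverse of `export_tables(format = "csv")`: returns the facet tables as a
#' named list of tibbles with all-character cells, preserving the absent
#' (`""`) and root (`"(root)"`) markers exactly.
#'
#' @param path directory written by [export_tables()].
#' @param facets facet names to read.
#' @return named list of tibbles.
#' @export
read_facet_tables <- function(path, facets = facet_names()) {
  out <- lapply(facets, function(f) {
    fp <- file.path(path, paste0(f, ".csv"))
    if (!file.exists(fp)) stop(sprintf("missing facet file %s", fp), call. = FALSE)
    readr::read_csv(fp,
      col_types = readr::cols(.default = readr::col_character()),
      na = character(), progress = FALSE, show_col_types = FALSE
    )
  })
  setNames(out, facets)
}

# ---- minimal xlsx writer -------------------------------------------------
# One sheet per table, inline strings only. No installed package writes
# xlsx, so the workbook parts are assembled directly and zipped.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

xlsx_col_ref <- function(j) {
  ref <- ""
  while (j > 0L) {
    ref <- paste0(LETTERS[(j - 1L) %% 26L + 1L], ref)
    j <- (j - 1L) %/% 26L
  }
  ref
}

xlsx_sheet_xml <- function(tab) {
  header <- names(tab)
  cells <- rbind(header, as.matrix(tab))
  rows <- vapply(seq_len(nrow(cells)), function(i) {
    cs <- vapply(seq_len(ncol(cells)), function(j) {
      v <- cells[i, j]
      if (is.na(v) || !nzchar(v)) {
        return("")
      }
      sprintf(
        '<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
        xlsx_col_ref(j), i, xml_escape(v)
      )
    }, character(1))
    sprintf('<row r="%d">%s</row>', i, paste(cs, collapse = ""))
  }, character(1))
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>"
  )
}

write_xlsx_inline <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1L, !is.null(names(sheets)))
  stage <- tempfile("xlsx-stage-")
  dir.create(file.path(stage, "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "worksheets"), recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  n <- length(sheets)
  idx <- seq_len(n)
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf(
      '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
      idx
    ), collapse = ""),
    "</Types>"
  ), file.path(stage, "[Content_Types].xml"), useBytes = TRUE)

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"
  ), file.path(stage, "_rels", ".rels"), useBytes = TRUE)

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>",
    paste(sprintf(
      '<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
      xml_escape(names(sheets)), idx, idx
    ), collapse = ""),
    "</sheets></workbook>"
  ), file.path(stage, "xl", "workbook.xml"), useBytes = TRUE)

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf(
      '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
      idx, idx
    ), collapse = ""),
    "</Relationships>"
  ), file.path(stage, "xl", "_rels", "workbook.xml.rels"), useBytes = TRUE)

  for (i in idx) {
    writeLines(
      xlsx_sheet_xml(sheets[[i]]),
      file.path(stage, "xl", "worksheets", sprintf("sheet%d.xml", i)),
      useBytes = TRUE
    )
  }

  # anchor to the parent directory: zip() changes directory while writing
  path <- file.path(normalizePath(dirname(path), mustWork = FALSE), basename(path))
  ok <- tryCatch(
    {
      zip::zip(
        zipfile = path,
        files = c(
          "[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
          "xl/_rels/workbook.xml.rels",
          sprintf("xl/worksheets/sheet%d.xml", idx)
        ),
        root = stage, mode = "mirror"
      )
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok || !file.exists(path)) {
    stop(sprintf("cannot write workbook %s", path), call. = FALSE)
  }
  invisible(path)
}
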