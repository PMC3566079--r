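#' Read a gridded height map from disk
#'
#' Two plain-text dialects are supported. `"csv-grid"` is a
#' comma-separated matrix of heights in µm, one file row per scan line
#' (first row is the `y = 0` line), preceded by comment header lines of
#' the form `# dx=<um> dy=<um> unit=um stage=<stage>`; the token `NaN`
#' marks a non-measured point. `"x3p-like"` is a minimal XML container
#' carrying the axis increments, matrix dimensions, stage and a
#' whitespace-separated point list in row-major order.
#'
#' @param path Path to an existing file.
#' @param format `"csv-grid"` or `"x3p-like"`.
#' @return A [height_map]; points marked non-measured in the file are
#'   masked. The stage recorded in the file metadata is restored
#'   (defaulting to `"raw"`).
#' @seealso [write_height_map()]
#' @export
read_height_map <- function(path, format = c("csv-grid", "x3p-like")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "csv-grid") read_csv_grid(path) else read_x3p_like(path)
}

#' Write a gridded height map to disk
#'
#' Heights are serialized with 17 significant digits, so a
#' write-then-read round trip reproduces heights, mask and spacing
#' bit-exactly for both dialects.
#'
#' @param hm A [height_map].
#' @inheritParams read_height_map
#' @return `path`, invisibly.
#' @export
write_height_map <- function(hm, path, format = c("csv-grid", "x3p-like")) {
  stopifnot(is_height_map(hm))
  format <- match.arg(format)
  if (format == "csv-grid") write_csv_grid(hm, path) else write_x3p_like(hm, path)
  invisible(path)
}

fmt_heights <- function(z, mask) {
  s <- sprintf("%.17g", z)
  s[!mask] <- "NaN"
  s
}

write_csv_grid <- function(hm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dx=%.17g dy=%.17g unit=um stage=%s precision=17g",
                     hm$dx, hm$dy, hm$stage), con)
  z <- hm$heights
  for (i in seq_len(nrow(z)))
    writeLines(paste(fmt_heights(z[i, ], hm$mask[i, ]), collapse = ","), con)
}

parse_header_fields <- function(lines) {
  txt <- paste(sub("^#\\s*", "", lines), collapse = " ")
  kv <- regmatches(txt, gregexpr("[A-Za-z_]+=[^ ]+", txt))[[1]]
  out <- list()
  for (p in kv) {
    parts <- strsplit(p, "=", fixed = TRUE)[[1]]
    out[[parts[1]]] <- parts[2]
  }
  out
}

read_csv_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  dat <- lines[!startsWith(lines, "#") & nzchar(lines)]
  meta <- parse_header_fields(hdr)
  if (is.null(meta$dx) || is.null(meta$dy))
    stopf("csv-grid header is missing spacing metadata (dx=..., dy=...)")
  if (length(dat) == 0) stopf("csv-grid file contains no data rows")
  rows <- strsplit(dat, ",", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1)
    stopf("ragged rows: row lengths %s", paste(unique(ncols), collapse = ", "))
  z <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              nrow = length(rows), ncol = ncols[1], byrow = TRUE)
  mask <- is.finite(z)
  if (!any(mask)) stopf("all points are non-measured")
  stage <- if (is.null(meta$stage)) "raw" else meta$stage
  height_map(z, as.numeric(meta$dx), as.numeric(meta$dy), mask = mask,
             stage = stage)
}

write_x3p_like <- function(hm, path) {
  doc <- xml2::xml_new_root("SurfaceContainer")
  rec1 <- xml2::xml_add_child(doc, "Record1")
  xml2::xml_add_child(rec1, "FeatureType", "SUR")
  axes <- xml2::xml_add_child(rec1, "Axes")
  cx <- xml2::xml_add_child(axes, "CX")
  xml2::xml_add_child(cx, "Increment", sprintf("%.17g", hm$dx))
  xml2::xml_add_child(cx, "Unit", "um")
  cy <- xml2::xml_add_child(axes, "CY")
  xml2::xml_add_child(cy, "Increment", sprintf("%.17g", hm$dy))
  xml2::xml_add_child(cy, "Unit", "um")
  rec2 <- xml2::xml_add_child(doc, "Record2")
  xml2::xml_add_child(rec2, "Stage", hm$stage)
  rec3 <- xml2::xml_add_child(doc, "Record3")
  md <- xml2::xml_add_child(rec3, "MatrixDimension")
  xml2::xml_add_child(md, "SizeX", as.character(ncol(hm$heights)))
  xml2::xml_add_child(md, "SizeY", as.character(nrow(hm$heights)))
  pts <- paste(fmt_heights(t(hm$heights), t(hm$mask)), collapse = " ")
  dl <- xml2::xml_add_child(rec3, "DataList")
  xml2::xml_set_attr(dl, "format", "text")
  xml2::xml_set_text(dl, pts)
  xml2::write_xml(doc, path)
}

read_x3p_like <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("not a readable x3p-like XML file: %s",
                                            conditionMessage(e)))
  get1 <- function(xp) {
    node <- xml2::xml_find_first(doc, xp)
    if (inherits(node, "xml_missing")) NULL else xml2::xml_text(node)
  }
  dx <- get1("//Axes/CX/Increment")
  dy <- get1("//Axes/CY/Increment")
  if (is.null(dx) || is.null(dy)) stopf("x3p-like file is missing axis increments")
  nx <- as.integer(get1("//MatrixDimension/SizeX"))
  ny <- as.integer(get1("//MatrixDimension/SizeY"))
  if (is.na(nx) || is.na(ny)) stopf("x3p-like file is missing matrix dimensions")
  pts <- suppressWarnings(as.numeric(strsplit(trimws(get1("//DataList")),
                                              "\\s+")[[1]]))
  if (length(pts) != nx * ny)
    stopf("point list length %d does not match %d x %d grid",
          length(pts), ny, nx)
  z <- matrix(pts, nrow = ny, ncol = nx, byrow = TRUE)
  mask <- is.finite(z)
  if (!any(mask)) stopf("all points are non-measured")
  stage <- get1("//Record2/Stage")
  if (is.null(stage)) stage <- "raw"
  height_map(z, as.numeric(dx), as.numeric(dy), mask = mask, stage = stage)
}
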