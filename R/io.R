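# Tab-delimited synteny / annotation interchange format.
#
# Synteny files: header line with six mandatory columns
#   org1 org1_start org1_end org2 org2_start org2_end
# followed by any number of extra named columns ("open-ended" format) that
# become filterable block attributes.  Annotation files: exactly eight
# columns (org start end strand feature track shape color); the feature
# cell may be "name|URL".  "#" comments and blank lines are skipped.
# Files may be plain text, gzip or single-member zip.

# Open a text connection with transparent decompression, by extension
# first and gzip magic bytes as a fallback.
open_source <- function(source) {
  if (inherits(source, "connection")) return(list(con = source, close = FALSE))
  stopifnot(is.character(source), length(source) == 1)
  if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
  ext <- tolower(tools::file_ext(source))
  if (ext == "zip") {
    members <- utils::unzip(source, list = TRUE)
    if (nrow(members) != 1)
      stop("zip archive must contain exactly one file, found ",
           nrow(members), call. = FALSE)
    return(list(con = unz(source, members$Name[1]), close = TRUE))
  }
  if (ext == "gz") return(list(con = gzfile(source), close = TRUE))
  magic <- readBin(source, "raw", n = 2)
  if (length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    return(list(con = gzfile(source), close = TRUE))
  list(con = file(source), close = TRUE)
}

read_source_lines <- function(source) {
  src <- open_source(source)
  if (src$close) on.exit(close(src$con))
  readLines(src$con, warn = FALSE)
}

# A cell is numeric iff it parses as a finite decimal or scientific-notation
# number; "NA" and "" are text.
parse_numeric_cells <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[!is.finite(v) | x == "" | toupper(x) == "NA" | toupper(x) == "NAN"] <- NA
  v
}

# Render numbers for file output: round-trip stable, never in exponent
# notation (so re-reading yields the same value and type).
format_cell <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA"
      else format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, "")
    return(out)
  }
  x <- as.character(x)
  x[is.na(x)] <- "NA"
  x
}

split_data_lines <- function(lines) {
  keep <- !grepl("^\\s*$", lines) & !startsWith(trimws(lines), "#")
  list(lines = lines[keep], numbers = which(keep))
}

#' Read a synteny file
#'
#' Parses the tab-delimited synteny format: a header whose first six
#' columns must be `org1 org1_start org1_end org2 org2_start org2_end`,
#' then one conserved region pair per line.  Extra header columns become
#' attribute columns in file order; a column whose every non-blank value
#' parses as a finite number is stored numeric, otherwise as text.  Plain,
#' gzip-compressed and single-member zip files are accepted.
#'
#' @param source File path (optionally `.gz`/`.zip`) or open connection.
#' @return A block `data.frame` as from [synteny_blocks()], with the
#'   originating file line numbers in `attr(, "source_lines")`.
#' @seealso [write_synteny()], [synteny_dataset()]
#' @export
read_synteny <- function(source) {
  raw <- split_data_lines(read_source_lines(source))
  if (length(raw$lines) == 0)
    stop("no synteny data: file has no header line", call. = FALSE)
  header <- strsplit(raw$lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 6 || !identical(header[1:6], SYNTENY_COLS))
    stop("bad synteny header; expected columns starting with: ",
         paste(SYNTENY_COLS, collapse = " "), call. = FALSE)
  if (anyDuplicated(header))
    stop("duplicated column name in synteny header", call. = FALSE)
  body <- raw$lines[-1]
  body_nums <- raw$numbers[-1]
  if (length(body) == 0)
    stop("no synteny data: file has a header but no data lines",
         call. = FALSE)
  cells <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(cells)
  bad <- which(nfield != length(header))
  if (length(bad))
    stop("line ", body_nums[bad[1]], ": expected ", length(header),
         " tab-separated fields, found ", nfield[bad[1]], call. = FALSE)
  mat <- matrix(unlist(cells), ncol = length(header), byrow = TRUE)
  df <- data.frame(org1 = mat[, 1], stringsAsFactors = FALSE)
  for (k in c(2, 3, 5, 6)) {
    v <- parse_numeric_cells(mat[, k])
    if (anyNA(v))
      stop("line ", body_nums[which(is.na(v))[1]],
           ": non-numeric coordinate in column ", header[k], call. = FALSE)
    df[[header[k]]] <- v
  }
  df$org2 <- mat[, 4]
  df <- df[, SYNTENY_COLS]
  if (length(header) > 6) {
    for (k in 7:length(header)) {
      v <- parse_numeric_cells(mat[, k])
      df[[header[k]]] <- if (anyNA(v)) mat[, k] else v
    }
  }
  attr(df, "source_lines") <- body_nums
  validate_blocks(df, body_nums)
  df
}

#' Read an annotation file
#'
#' Parses the eight-column tab-delimited annotation format.  A feature
#' cell of the form `name|URL` is split into the display name and a
#' hyperlink stored in the `link` column.
#'
#' @inheritParams read_synteny
#' @return A feature `data.frame` as from [annotation_features()].
#' @export
read_annotation <- function(source) {
  raw <- split_data_lines(read_source_lines(source))
  if (length(raw$lines) == 0)
    stop("annotation file has no header line", call. = FALSE)
  header <- strsplit(raw$lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, ANNOTATION_COLS))
    stop("bad annotation header; expected columns: ",
         paste(ANNOTATION_COLS, collapse = " "), call. = FALSE)
  body <- raw$lines[-1]
  body_nums <- raw$numbers[-1]
  if (length(body) == 0) {
    out <- annotation_features(character(), numeric(), numeric(),
                               character(), character(), character(),
                               character(), character())
    return(out)
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(cells)
  bad <- which(nfield != length(header))
  if (length(bad))
    stop("line ", body_nums[bad[1]], ": expected ", length(header),
         " tab-separated fields, found ", nfield[bad[1]], call. = FALSE)
  mat <- matrix(unlist(cells), ncol = length(header), byrow = TRUE)
  for (k in c(2, 3)) {
    if (anyNA(parse_numeric_cells(mat[, k])))
      stop("line ",
           body_nums[which(is.na(parse_numeric_cells(mat[, k])))[1]],
           ": non-numeric coordinate in column ", header[k], call. = FALSE)
  }
  feat_cell <- mat[, 5]
  has_link <- grepl("|", feat_cell, fixed = TRUE)
  name <- ifelse(has_link, sub("\\|.*$", "", feat_cell), feat_cell)
  link <- ifelse(has_link, sub("^[^|]*\\|", "", feat_cell), NA_character_)
  out <- annotation_features(mat[, 1], parse_numeric_cells(mat[, 2]),
                             parse_numeric_cells(mat[, 3]), mat[, 4],
                             name, mat[, 6], mat[, 7], mat[, 8], link)
  attr(out, "source_lines") <- body_nums
  validate_features(out, body_nums)
  out
}

emit_lines <- function(lines, sink) {
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(sink)) return(text)
  if (inherits(sink, "connection")) writeLines(lines, sink)
  else writeLines(lines, sink, useBytes = TRUE)
  invisible(text)
}

#' Write a synteny file
#'
#' Emits the dialect-conformant tab-delimited file: mandatory six columns
#' first, attribute columns in their original order.  Numeric values are
#' written in plain decimal notation so the file re-reads to an equal
#' table.
#'
#' @param blocks A block `data.frame`.
#' @param sink File path, connection, or `NULL` to return the text.
#' @return The file text, invisibly when written to a sink.
#' @export
write_synteny <- function(blocks, sink = NULL) {
  validate_blocks(blocks)
  extras <- setdiff(names(blocks), SYNTENY_COLS)
  cols <- c(SYNTENY_COLS, extras)
  cells <- lapply(blocks[cols], format_cell)
  lines <- c(paste(cols, collapse = "\t"),
             do.call(paste, c(cells, sep = "\t")))
  emit_lines(lines, sink)
}

#' Write an annotation file
#'
#' Features with a hyperlink are written with a `name|URL` feature cell.
#'
#' @param features A feature `data.frame`.
#' @inheritParams write_synteny
#' @return The file text, invisibly when written to a sink.
#' @export
write_annotation <- function(features, sink = NULL) {
  validate_features(features)
  feat_cell <- ifelse(is.na(features$link), features$feature,
                      paste0(features$feature, "|", features$link))
  lines <- c(paste(ANNOTATION_COLS, collapse = "\t"),
             paste(features$org, format_cell(features$start),
                   format_cell(features$end), features$strand, feat_cell,
                   features$track, features$shape, features$color,
                   sep = "\t"))
  if (nrow(features) == 0) lines <- lines[1]
  emit_lines(lines, sink)
}
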