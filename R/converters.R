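# Converters from common third-party outputs (BLAST tabular, axt, GFF3)
# into the synteny / annotation interchange tables.

#' Convert BLAST tabular output to synteny blocks
#'
#' Accepts 12-column BLAST tabular output (`-outfmt 6`): qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore.
#' Each HSP becomes one block with `org1` = query, `org2` = subject.
#' Subject coordinates with sstart > send indicate a minus-strand hit:
#' they are swapped into start <= end form and the orientation recorded in
#' a `strand` attribute.  Attribute columns, in order: pident,
#' align_length, evalue, bitscore, strand.
#'
#' @param source File path or connection with BLAST tabular lines.
#' @return A block `data.frame`.
#' @examples
#' con <- textConnection(
#'   "q1\ts1\t98.0\t50\t1\t0\t1\t50\t200\t151\t1e-20\t95.0")
#' blast_to_synteny(con)
#' @export
blast_to_synteny <- function(source) {
  lines <- read_source_lines(source)
  raw <- split_data_lines(lines)
  if (length(raw$lines) == 0)
    stop("no BLAST tabular rows found", call. = FALSE)
  cells <- strsplit(raw$lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != 12)
  if (length(bad))
    stop("line ", raw$numbers[bad[1]], ": expected 12 tab-separated ",
         "BLAST fields, found ", lengths(cells)[bad[1]], call. = FALSE)
  mat <- matrix(unlist(cells), ncol = 12, byrow = TRUE)
  num <- function(k, what) {
    v <- parse_numeric_cells(mat[, k])
    if (anyNA(v))
      stop("line ", raw$numbers[which(is.na(v))[1]], ": unparseable ",
           what, call. = FALSE)
    v
  }
  qstart <- num(7, "coordinate (qstart)")
  qend <- num(8, "coordinate (qend)")
  sstart <- num(9, "coordinate (sstart)")
  send <- num(10, "coordinate (send)")
  minus <- sstart > send
  synteny_blocks(mat[, 1], pmin(qstart, qend), pmax(qstart, qend),
                 mat[, 2], pmin(sstart, send), pmax(sstart, send),
                 pident = num(3, "pident"),
                 align_length = num(4, "alignment length"),
                 evalue = num(11, "evalue"),
                 bitscore = num(12, "bitscore"),
                 strand = ifelse(minus, "-", "+"))
}

#' Convert axt alignments to synteny blocks
#'
#' Each axt record is a header line (alignment index, target name, target
#' start/end, query name, query start/end, strand, score) followed by two
#' sequence lines, which are ignored.  One block is produced per record,
#' with `score` and `strand` attributes.  For minus-strand records axt
#' gives query coordinates on the reverse strand; when the query genome
#' length is supplied they are converted to plus-strand coordinates,
#' otherwise they are kept as given with the `strand` attribute recording
#' the orientation.
#'
#' @param source File path or connection with axt records.
#' @param query_lengths Optional named numeric vector of query genome
#'   lengths in bp, used to convert minus-strand query coordinates.
#' @return A block `data.frame` (zero rows for an empty stream).
#' @export
axt_to_synteny <- function(source, query_lengths = NULL) {
  lines <- read_source_lines(source)
  raw <- split_data_lines(lines)
  lines <- raw$lines
  empty <- synteny_blocks(character(), numeric(), numeric(), character(),
                          numeric(), numeric(), score = numeric(),
                          strand = character())
  if (length(lines) == 0) return(empty)
  if (length(lines) %% 3 != 0)
    stop("truncated axt stream: records are header + 2 sequence lines",
         call. = FALSE)
  headers <- lines[seq(1, length(lines), by = 3)]
  recs <- strsplit(trimws(headers), "\\s+")
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    f <- recs[[i]]
    if (length(f) != 9)
      stop("malformed axt header at record ", i - 1,
           ": expected 9 fields, found ", length(f), call. = FALSE)
    coords <- parse_numeric_cells(f[c(3, 4, 6, 7, 9)])
    if (anyNA(coords) || !(f[8] %in% c("+", "-")))
      stop("malformed axt header at record ", i - 1, call. = FALSE)
    qs <- coords[3]; qe <- coords[4]
    if (f[8] == "-" && !is.null(query_lengths) && f[5] %in% names(query_lengths)) {
      L <- query_lengths[[f[5]]]
      new_qs <- L - qe + 1
      qe <- L - qs + 1
      qs <- new_qs
    }
    out[[i]] <- synteny_blocks(f[2], coords[1], coords[2],
                               f[5], min(qs, qe), max(qs, qe),
                               score = coords[5], strand = f[8])
  }
  do.call(rbind, out)
}

#' Convert GFF3 features to annotation features
#'
#' Maps GFF3 columns onto the annotation table: seqid becomes the genome,
#' the type column becomes the track, and the display name is taken from
#' the `Name` attribute, falling back to `ID`, then to `type:start-end`.
#' Stranded features default to the arrow shape, unstranded ones to a box;
#' `default_shape` overrides both.  `##` directives are skipped and
#' everything after a `##FASTA` directive is ignored.
#'
#' @param source File path or connection with GFF3 lines.
#' @param type_filter Optional character vector of feature types to keep
#'   (e.g. `"gene"`); `NULL` keeps all.
#' @param default_shape Optional shape (`"box"`, `"arrow"`, `"line"`)
#'   applied to every feature; `NULL` selects arrow/box by strand.
#' @param default_color Fill color assigned to every feature.
#' @return A feature `data.frame`.
#' @export
gff3_to_annotation <- function(source, type_filter = NULL,
                               default_shape = NULL,
                               default_color = "#3366cc") {
  if (!is.null(default_shape) && !(default_shape %in% ANNOTATION_SHAPES))
    stop("unknown shape '", default_shape, "' (allowed shapes: ",
         paste(ANNOTATION_SHAPES, collapse = ", "), ")", call. = FALSE)
  lines <- read_source_lines(source)
  fasta_at <- which(startsWith(lines, "##FASTA"))
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1] - 1)]
  raw <- split_data_lines(lines)
  keep <- !startsWith(raw$lines, "#")
  lines <- raw$lines[keep]
  numbers <- raw$numbers[keep]
  if (length(lines) == 0)
    return(annotation_features(character(), numeric(), numeric(),
                               character(), character(), character(),
                               character(), character()))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) < 9)
  if (length(bad))
    stop("line ", numbers[bad[1]], ": GFF3 requires 9 tab-separated ",
         "columns, found ", lengths(cells)[bad[1]], call. = FALSE)
  mat <- t(vapply(cells, `[`, character(9), 1:9))
  start <- parse_numeric_cells(mat[, 4])
  end <- parse_numeric_cells(mat[, 5])
  if (anyNA(start) || anyNA(end))
    stop("line ", numbers[which(is.na(start) | is.na(end))[1]],
         ": non-numeric GFF3 coordinate", call. = FALSE)
  bad <- which(end < start)
  if (length(bad))
    stop("line ", numbers[bad[1]], ": GFF3 end < start", call. = FALSE)
  if (!is.null(type_filter)) {
    sel <- mat[, 3] %in% type_filter
    mat <- mat[sel, , drop = FALSE]
    start <- start[sel]; end <- end[sel]
  }
  if (nrow(mat) == 0)
    return(annotation_features(character(), numeric(), numeric(),
                               character(), character(), character(),
                               character(), character()))
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)\\s*", key, "="),
                                              attrs))) > 0
    out[hit] <- sub(paste0("^.*", key, "="), "", m)
    out
  }
  nm <- attr_field(mat[, 9], "Name")
  id <- attr_field(mat[, 9], "ID")
  fallback <- paste0(mat[, 3], ":", format_cell(start), "-", format_cell(end))
  name <- ifelse(!is.na(nm), nm, ifelse(!is.na(id), id, fallback))
  strand <- ifelse(mat[, 7] %in% c("+", "-"), mat[, 7], ".")
  shape <- if (is.null(default_shape))
    ifelse(strand %in% c("+", "-"), "arrow", "box")
  else rep(default_shape, nrow(mat))
  annotation_features(mat[, 1], start, end, strand, name, mat[, 3],
                      shape, default_color)
}
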