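# Core domain model: synteny blocks, annotation features, datasets,
# association summaries and genome extents.

SYNTENY_COLS <- c("org1", "org1_start", "org1_end",
                  "org2", "org2_start", "org2_end")
ANNOTATION_COLS <- c("org", "start", "end", "strand",
                     "feature", "track", "shape", "color")
ANNOTATION_SHAPES <- c("box", "arrow", "line")
STRAND_VALUES <- c("+", "-", ".")

#' Construct a table of synteny blocks
#'
#' A synteny block is one conserved region pair: an interval on each of two
#' genomes, plus any number of named attributes (alignment score, percent
#' identity, ...) carried as extra columns.  Coordinates are 1-based
#' inclusive base pairs, normalized so that start <= end on both sides;
#' orientation, when known, rides in an attribute column (e.g. `strand`).
#'
#' @param org1,org2 Character vectors of genome names (case-sensitive
#'   tokens; tabs and empty strings are rejected).
#' @param org1_start,org1_end,org2_start,org2_end Numeric coordinate
#'   vectors, 1-based inclusive.
#' @param ... Named attribute columns, recycled to the number of blocks.
#'   Names must not collide with the six mandatory column names.
#' @return A `data.frame` with the six mandatory columns followed by the
#'   attribute columns in the order given.
#' @examples
#' synteny_blocks("G1", 1, 100, "G2", 51, 150, pident = 87.5)
#' @export
synteny_blocks <- function(org1, org1_start, org1_end,
                           org2, org2_start, org2_end, ...) {
  extras <- list(...)
  if (length(extras) && (is.null(names(extras)) || any(names(extras) == "")))
    stop("attribute columns must be named", call. = FALSE)
  bad <- intersect(names(extras), SYNTENY_COLS)
  if (length(bad))
    stop("attribute name collides with mandatory column: ",
         paste(bad, collapse = ", "), call. = FALSE)
  df <- data.frame(org1 = as.character(org1),
                   org1_start = as.numeric(org1_start),
                   org1_end = as.numeric(org1_end),
                   org2 = as.character(org2),
                   org2_start = as.numeric(org2_start),
                   org2_end = as.numeric(org2_end),
                   stringsAsFactors = FALSE)
  for (nm in names(extras)) df[[nm]] <- extras[[nm]]
  df
}

#' Construct a table of annotation features
#'
#' @param org Genome names.
#' @param start,end 1-based inclusive coordinates, start <= end.
#' @param strand One of `"+"`, `"-"`, `"."` per feature.
#' @param feature Display label.  In files a label of the form
#'   `name|URL` splits into `feature` and `link`.
#' @param track Annotation track name (e.g. `"gene"`); only one track is
#'   displayed per genome at a time in the pairwise view.
#' @param shape One of `"box"`, `"arrow"`, `"line"`.
#' @param color CSS hex or named color.
#' @param link Optional URL vector (`NA` for none).
#' @return A `data.frame` with columns org, start, end, strand, feature,
#'   track, shape, color, link.
#' @export
annotation_features <- function(org, start, end, strand, feature, track,
                                shape, color, link = NA_character_) {
  data.frame(org = as.character(org), start = as.numeric(start),
             end = as.numeric(end), strand = as.character(strand),
             feature = as.character(feature), track = as.character(track),
             shape = as.character(shape), color = as.character(color),
             link = rep_len(as.character(link), length(org)),
             stringsAsFactors = FALSE)
}

validate_blocks <- function(blocks, lines = NULL) {
  if (is.null(blocks) || nrow(blocks) == 0)
    stop("no synteny data", call. = FALSE)
  missing_cols <- setdiff(SYNTENY_COLS, names(blocks))
  if (length(missing_cols))
    stop("synteny table lacks mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(lines)) lines <- seq_len(nrow(blocks))
  where <- function(i) paste0("line ", lines[i])
  coord_cols <- SYNTENY_COLS[c(2, 3, 5, 6)]
  for (cc in coord_cols) {
    v <- blocks[[cc]]
    if (!is.numeric(v) || anyNA(v))
      stop("non-numeric coordinate in column ", cc, call. = FALSE)
  }
  bad <- which(blocks$org1_start < 1 | blocks$org2_start < 1)
  if (length(bad))
    stop("coordinate below 1 at ", where(bad[1]), call. = FALSE)
  bad <- which(blocks$org1_start > blocks$org1_end |
               blocks$org2_start > blocks$org2_end)
  if (length(bad))
    stop("start greater than end at ", where(bad[1]), call. = FALSE)
  for (oc in c("org1", "org2")) {
    v <- blocks[[oc]]
    bad <- which(is.na(v) | v == "" | grepl("\t", v, fixed = TRUE))
    if (length(bad))
      stop("invalid genome name at ", where(bad[1]), call. = FALSE)
  }
  invisible(blocks)
}

validate_features <- function(features, lines = NULL) {
  if (is.null(features) || nrow(features) == 0) return(invisible(features))
  if (is.null(lines)) lines <- seq_len(nrow(features))
  where <- function(i) paste0("line ", lines[i])
  for (cc in c("start", "end")) {
    if (!is.numeric(features[[cc]]) || anyNA(features[[cc]]))
      stop("non-numeric coordinate in annotation column ", cc, call. = FALSE)
  }
  bad <- which(features$start > features$end | features$start < 1)
  if (length(bad))
    stop("invalid feature interval at ", where(bad[1]), call. = FALSE)
  bad <- which(!(features$strand %in% STRAND_VALUES))
  if (length(bad))
    stop("invalid strand at ", where(bad[1]),
         " (allowed: ", paste(STRAND_VALUES, collapse = " "), ")",
         call. = FALSE)
  bad <- which(!(features$shape %in% ANNOTATION_SHAPES))
  if (length(bad))
    stop("unknown annotation shape at ", where(bad[1]),
         " (allowed shapes: ", paste(ANNOTATION_SHAPES, collapse = ", "), ")",
         call. = FALSE)
  bad <- which(is.na(features$track) | features$track == "")
  if (length(bad))
    stop("empty track name at ", where(bad[1]), call. = FALSE)
  invisible(features)
}

#' Assemble and validate a synteny dataset
#'
#' Bundles synteny blocks, optional annotation features and optional
#' declared genome lengths into a validated dataset: the unit passed to
#' filtering, ordering and rendering.  Hard invariant violations (empty
#' block list, start > end, bad strand/shape vocabulary) are errors naming
#' the offending line; soft issues (a feature on a genome absent from the
#' blocks, a declared length smaller than an observed coordinate) are
#' collected as warning-level diagnostics on the returned object.
#'
#' The extent of a genome is `[1, L]` where `L` is the maximum end
#' coordinate observed over all its block sides and features, overridden by
#' the declared length when that is larger.
#'
#' @param blocks A block table from [synteny_blocks()] or [read_synteny()].
#' @param features Optional feature table from [annotation_features()] or
#'   [read_annotation()].
#' @param genome_lengths Optional named numeric vector of declared genome
#'   lengths in bp.
#' @return An object of class `synteny_dataset`: a list with elements
#'   `blocks`, `features`, `genome_lengths`, `genomes` (sorted names),
#'   `extents` (named vector of extent maxima) and `diagnostics`
#'   (character vector of warnings).
#' @examples
#' d <- synteny_dataset(synteny_blocks("G1", 1, 100, "G2", 51, 150))
#' genome_extent(d, "G2")
#' @export
synteny_dataset <- function(blocks, features = NULL, genome_lengths = NULL) {
  validate_blocks(blocks, attr(blocks, "source_lines"))
  if (!is.null(features))
    validate_features(features, attr(features, "source_lines"))
  else
    features <- annotation_features(character(), numeric(), numeric(),
                                    character(), character(), character(),
                                    character(), character())
  if (!is.null(genome_lengths)) {
    if (is.null(names(genome_lengths)) || any(names(genome_lengths) == ""))
      stop("genome_lengths must be a named numeric vector", call. = FALSE)
    genome_lengths <- stats::setNames(as.numeric(genome_lengths),
                                      names(genome_lengths))
  }
  diags <- character()

  block_genomes <- unique(c(blocks$org1, blocks$org2))
  known <- unique(c(block_genomes, names(genome_lengths)))
  if (nrow(features)) {
    orphan <- setdiff(unique(features$org), known)
    if (length(orphan))
      diags <- c(diags, paste0("feature genome not present in synteny data: ",
                               paste(orphan, collapse = ", ")))
  }

  observed <- c(stats::setNames(blocks$org1_end, blocks$org1),
                stats::setNames(blocks$org2_end, blocks$org2))
  if (nrow(features))
    observed <- c(observed, stats::setNames(features$end, features$org))
  obs_max <- tapply(observed, names(observed), max)
  genomes <- sort(unique(c(names(obs_max), names(genome_lengths))))
  extents <- stats::setNames(rep(1, length(genomes)), genomes)
  extents[names(obs_max)] <- obs_max
  for (g in names(genome_lengths)) {
    if (!is.na(extents[g]) && genome_lengths[g] < extents[g])
      diags <- c(diags, paste0("declared length of ", g, " (",
                               genome_lengths[g],
                               ") is smaller than observed maximum (",
                               extents[g], "); using observed maximum"))
    else
      extents[g] <- genome_lengths[g]
  }

  structure(list(blocks = blocks, features = features,
                 genome_lengths = genome_lengths,
                 genomes = genomes, extents = extents,
                 diagnostics = diags),
            class = "synteny_dataset")
}

#' @export
print.synteny_dataset <- function(x, ...) {
  cat("synteny_dataset:", nrow(x$blocks), "blocks,",
      nrow(x$features), "features,",
      length(x$genomes), "genomes\n")
  cat("genomes:", paste(x$genomes, collapse = ", "), "\n")
  if (length(x$diagnostics))
    cat("diagnostics:\n", paste(" -", x$diagnostics, collapse = "\n"), "\n")
  invisible(x)
}

# Mean of the two side spans; the symmetric per-block size used for
# association totals, filter attribute "length" and ordering weights.
block_sizes <- function(blocks) {
  ((blocks$org1_end - blocks$org1_start + 1) +
   (blocks$org2_end - blocks$org2_start + 1)) / 2
}

pair_keys <- function(g1, g2) {
  paste(pmin(g1, g2), pmax(g1, g2), sep = "\t")
}

#' Summarize genome associations
#'
#' One row per unordered genome pair that shares at least one conserved
#' region: the number of regions and their total size in bp, where each
#' block contributes the mean of its two side spans.  This is the table
#' shown beside the circular overview.  Rows are sorted by descending
#' count, ties broken by pair name.
#'
#' @param dataset A `synteny_dataset`.
#' @return A `data.frame` with columns `genome1`, `genome2`, `n_regions`,
#'   `total_size`.
#' @examples
#' d <- synteny_dataset(synteny_blocks(c("A", "A"), c(1, 1), c(10, 20),
#'                                     c("B", "C"), c(1, 1), c(20, 10)))
#' association_summary(d)
#' @export
association_summary <- function(dataset) {
  stopifnot(inherits(dataset, "synteny_dataset"))
  b <- dataset$blocks
  key <- pair_keys(b$org1, b$org2)
  size <- block_sizes(b)
  counts <- tapply(size, key, length)
  totals <- tapply(size, key, sum)
  parts <- strsplit(names(counts), "\t", fixed = TRUE)
  out <- data.frame(genome1 = vapply(parts, `[`, "", 1),
                    genome2 = vapply(parts, `[`, "", 2),
                    n_regions = as.integer(counts),
                    total_size = as.numeric(totals),
                    stringsAsFactors = FALSE)
  pair_name <- paste(out$genome1, out$genome2)
  out <- out[order(-out$n_regions, pair_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extent of a genome
#'
#' @param dataset A `synteny_dataset`.
#' @param genome Genome name.
#' @return Numeric vector `c(1, L)`.
#' @export
genome_extent <- function(dataset, genome) {
  stopifnot(inherits(dataset, "synteny_dataset"))
  if (!(genome %in% names(dataset$extents)))
    stop("unknown genome: ", genome, call. = FALSE)
  c(1, unname(dataset$extents[genome]))
}
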