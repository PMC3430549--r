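# Numeric filtering of conserved regions on file-supplied or derived
# block attributes.

DERIVED_ATTRIBUTES <- c("length")

#' Define a numeric filter criterion
#'
#' A range constraint on one block attribute.  The attribute is either a
#' column of the synteny table (e.g. `pident`, `score`) or the derived
#' attribute `length` (mean of the two side spans).  At least one bound
#' must be set; an unset bound is unbounded.
#'
#' @param attribute Attribute name.
#' @param min,max Optional numeric bounds (inclusive).
#' @return An object of class `filter_criterion`.
#' @examples
#' filter_criterion("pident", min = 85)
#' filter_criterion("length", min = 1000, max = 50000)
#' @export
filter_criterion <- function(attribute, min = NULL, max = NULL) {
  stopifnot(is.character(attribute), length(attribute) == 1,
            nzchar(attribute))
  if (is.null(min) && is.null(max))
    stop("filter criterion needs at least one of min, max", call. = FALSE)
  if (!is.null(min) && !is.null(max) && min > max)
    stop("filter criterion has min > max", call. = FALSE)
  structure(list(attribute = attribute,
                 min = if (is.null(min)) -Inf else as.numeric(min),
                 max = if (is.null(max)) Inf else as.numeric(max)),
            class = "filter_criterion")
}

#' Compute a derived block attribute
#'
#' `length` is the mean of the two side spans, the same per-block size
#' used by [association_summary()] and the ordering weights.
#'
#' @param blocks A block `data.frame`.
#' @param name Derived attribute name; currently only `"length"`.
#' @return Numeric vector, one value per block.
#' @export
derived_attribute <- function(blocks, name) {
  if (!(name %in% DERIVED_ATTRIBUTES))
    stop("unknown derived attribute '", name, "' (available: ",
         paste(DERIVED_ATTRIBUTES, collapse = ", "), ")", call. = FALSE)
  block_sizes(blocks)
}

criterion_values <- function(blocks, attribute) {
  if (attribute %in% DERIVED_ATTRIBUTES)
    return(derived_attribute(blocks, attribute))
  if (!(attribute %in% names(blocks)))
    stop("filter attribute '", attribute,
         "' is not present in the synteny data", call. = FALSE)
  col <- blocks[[attribute]]
  if (is.numeric(col)) col else parse_numeric_cells(as.character(col))
}

#' Filter conserved regions by numeric criteria
#'
#' A block is retained iff for every criterion its attribute value exists,
#' is numeric and lies within `[min, max]`.  Blocks lacking a filtered
#' attribute, or holding non-numeric text there, are dropped: under a
#' stringency cutoff an unknown value must not pass.  Criteria are
#' conjunctive and order-independent; input block order is preserved.
#'
#' @param blocks A block `data.frame`.
#' @param criteria A single [filter_criterion()] or a list of them; an
#'   empty list is the identity.
#' @return The retained subset of `blocks`.
#' @examples
#' b <- synteny_blocks(c("A", "A", "A"), 1, 10, "B", 1, 10,
#'                     pident = c(80, 90, 99))
#' apply_filters(b, filter_criterion("pident", min = 85))
#' @export
apply_filters <- function(blocks, criteria) {
  if (inherits(criteria, "filter_criterion")) criteria <- list(criteria)
  if (is.null(criteria) || length(criteria) == 0) return(blocks)
  stopifnot(all(vapply(criteria, inherits, TRUE, "filter_criterion")))
  keep <- rep(TRUE, nrow(blocks))
  for (cr in criteria) {
    v <- criterion_values(blocks, cr$attribute)
    keep <- keep & !is.na(v) & v >= cr$min & v <= cr$max
  }
  out <- blocks[keep, , drop = FALSE]
  attr(out, "source_lines") <- attr(blocks, "source_lines")[keep]
  rownames(out) <- NULL
  out
}

#' Parse a filter flag of the form ATTR:MIN:MAX
#'
#' Empty MIN or MAX means unbounded on that side; used by the command-line
#' interface (`--filter pident:85:` keeps blocks with pident >= 85).
#'
#' @param spec Character scalar `"ATTR:MIN:MAX"`.
#' @return A [filter_criterion()].
#' @export
parse_filter_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2 || length(parts) > 3 || !nzchar(parts[1]))
    stop("bad filter spec '", spec, "'; expected ATTR:MIN:MAX", call. = FALSE)
  parts <- c(parts, rep("", 3 - length(parts)))
  num_or_null <- function(s) {
    if (!nzchar(s)) return(NULL)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("bad numeric bound '", s, "' in filter spec '",
                       spec, "'", call. = FALSE)
    v
  }
  filter_criterion(parts[1], min = num_or_null(parts[2]),
                   max = num_or_null(parts[3]))
}
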