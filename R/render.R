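# Deterministic SVG rendering: pairwise mode, multiple mode, circular
# overview.  Rendering is a pure function of its inputs — no timestamps,
# no randomness — so identical calls yield byte-identical documents.

# fixed qualitative palette, cycled in drawing order
BLOCK_PALETTE <- c("#a6cee3", "#1f78b4", "#b2df8a", "#33a02c",
                   "#fb9a99", "#e31a1c", "#fdbf6f", "#ff7f00",
                   "#cab2d6", "#6a3d9a", "#ffff99", "#b15928")

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

px <- function(x) {
  s <- sprintf("%.2f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Define a genome viewport
#'
#' The visible interval of one genome mapped onto the drawing width.
#'
#' @param from,to Visible interval in bp, `1 <= from <= to`.
#' @param width Drawing width in px (>= 100).
#' @return An object of class `viewport`.
#' @export
viewport <- function(from, to, width = 1000) {
  stopifnot(is.numeric(from), is.numeric(to), is.numeric(width))
  if (width < 100) stop("viewport width must be >= 100 px", call. = FALSE)
  if (from < 1 || from > to)
    stop("viewport requires 1 <= from <= to", call. = FALSE)
  structure(list(from = from, to = to, width = width), class = "viewport")
}

#' Map a genomic coordinate to an x position
#'
#' Affine map of the visible interval `[from, to]` onto `[0, width]`.
#' Positions outside the visible interval are clamped to the nearest
#' edge and flagged as clipped.
#'
#' @param bp Numeric vector of base-pair positions.
#' @param vp A [viewport()].
#' @return List with `x` (clamped px positions) and `clipped` (logical).
#' @export
map_coordinate <- function(bp, vp) {
  stopifnot(inherits(vp, "viewport"))
  if (vp$from == vp$to)
    stop("degenerate viewport: from equals to", call. = FALSE)
  x <- (bp - vp$from) / (vp$to - vp$from) * vp$width
  clipped <- bp < vp$from | bp > vp$to
  list(x = pmin(pmax(x, 0), vp$width), clipped = clipped)
}

#' Ruler tick positions for a viewport
#'
#' The tick interval is the largest value of the form {1, 2, 5} x 10^k
#' that yields 4 to 10 ticks across the visible interval; spans too short
#' for 4 ticks fall back to the largest interval yielding at least one.
#' Labels carry a bp/kb/Mb unit chosen from the interval magnitude.
#'
#' @param vp A [viewport()].
#' @return A `data.frame` with columns `bp` and `label`.
#' @export
tick_marks <- function(vp) {
  stopifnot(inherits(vp, "viewport"))
  span <- vp$to - vp$from + 1
  kmax <- max(0, ceiling(log10(span)))
  candidates <- sort(as.vector(outer(c(1, 2, 5), 10^(0:kmax))),
                     decreasing = TRUE)
  n_ticks <- function(interval)
    max(0, floor(vp$to / interval) - ceiling(vp$from / interval) + 1)
  counts <- vapply(candidates, n_ticks, 0)
  ok <- counts >= 4 & counts <= 10
  interval <- if (any(ok)) candidates[which(ok)[1]]
  else candidates[which(counts >= 1)[1]]
  at <- seq(ceiling(vp$from / interval), floor(vp$to / interval)) * interval
  unit <- if (interval >= 1e6) c(1e6, "Mb")
  else if (interval >= 1e3) c(1e3, "kb")
  else c(1, "bp")
  label <- paste0(vapply(at / as.numeric(unit[1]), function(v)
    format(v, digits = 15, scientific = FALSE, trim = TRUE), ""), unit[2])
  data.frame(bp = at, label = label, stringsAsFactors = FALSE)
}

#' Display style options
#'
#' @param color_mode `"distinct"` (each drawn region its own palette
#'   color, cycled in drawing order) or `"uniform"`.
#' @param uniform_color Fill used in uniform mode.
#' @param pair_colors Optional named character vector overriding the
#'   per-pair colors of multiple mode; names of the form `"A|B"` with the
#'   two genome names sorted.
#' @param annotation_track Name of the annotation track to display inside
#'   each genome ruler; pairwise mode only.
#' @param hidden_pairs Genome pairs whose regions are hidden in multiple
#'   mode: a list of length-2 character vectors.
#' @param opacity Fill opacity of conserved-region polygons.
#' @return An object of class `style_options`.
#' @export
style_options <- function(color_mode = c("distinct", "uniform"),
                          uniform_color = "#5588cc",
                          pair_colors = NULL,
                          annotation_track = NULL,
                          hidden_pairs = NULL,
                          opacity = 0.45) {
  color_mode <- match.arg(color_mode)
  if (!is.null(hidden_pairs)) {
    if (is.character(hidden_pairs)) hidden_pairs <- list(hidden_pairs)
    stopifnot(all(lengths(hidden_pairs) == 2))
  }
  structure(list(color_mode = color_mode, uniform_color = uniform_color,
                 pair_colors = pair_colors,
                 annotation_track = annotation_track,
                 hidden_pairs = hidden_pairs, opacity = opacity),
            class = "style_options")
}

svg_open <- function(width, height) {
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
           "xmlns:xlink=\"http://www.w3.org/1999/xlink\" ",
           "width=\"", px(width), "\" height=\"", px(height), "\" ",
           "font-family=\"sans-serif\" font-size=\"11\">"))
}

resolve_viewports <- function(dataset, genomes, viewports, width) {
  out <- list()
  for (g in unique(genomes)) {
    if (!is.null(viewports) && g %in% names(viewports)) {
      v <- viewports[[g]]
      if (inherits(v, "viewport")) out[[g]] <- viewport(v$from, v$to, width)
      else out[[g]] <- viewport(v[1], v[2], width)
    } else {
      out[[g]] <- viewport(1, genome_extent(dataset, g)[2], width)
    }
  }
  out
}

ruler_svg <- function(genome, vp, y, track_height, margin_left,
                      features = NULL) {
  th <- track_height
  out <- c(paste0("<g class=\"ruler\" transform=\"translate(",
                  px(margin_left), ",", px(y), ")\">"),
           paste0("<rect class=\"genome-bar\" x=\"0\" y=\"0\" width=\"",
                  px(vp$width), "\" height=\"", px(th),
                  "\" fill=\"#f4f4f4\" stroke=\"#555555\"/>"),
           paste0("<text x=\"-8\" y=\"", px(th / 2 + 4),
                  "\" text-anchor=\"end\">", xml_escape(genome), "</text>"))
  ticks <- tick_marks(vp)
  for (i in seq_len(nrow(ticks))) {
    tx <- map_coordinate(ticks$bp[i], vp)$x
    out <- c(out,
             paste0("<line class=\"tick\" x1=\"", px(tx), "\" y1=\"",
                    px(th), "\" x2=\"", px(tx), "\" y2=\"", px(th + 5),
                    "\" stroke=\"#555555\"/>"),
             paste0("<text class=\"tick-label\" x=\"", px(tx), "\" y=\"",
                    px(th + 16), "\" text-anchor=\"middle\" font-size=\"9\">",
                    xml_escape(ticks$label[i]), "</text>"))
  }
  if (!is.null(features) && nrow(features)) {
    for (i in seq_len(nrow(features))) {
      s <- map_coordinate(features$start[i], vp)
      e <- map_coordinate(features$end[i], vp)
      if (features$end[i] < vp$from || features$start[i] > vp$to) next
      body <- feature_svg(features[i, ], s$x, e$x, th)
      if (!is.na(features$link[i]))
        body <- c(paste0("<a xlink:href=\"", xml_escape(features$link[i]),
                         "\">"), body, "</a>")
      out <- c(out, body)
    }
  }
  c(out, "</g>")
}

feature_svg <- function(f, x1, x2, th) {
  title <- paste0("<title>", xml_escape(paste0(f$feature, " ", f$org, ":",
                                               f$start, "-", f$end)),
                  "</title>")
  col <- xml_escape(f$color)
  if (f$shape == "line") {
    return(paste0("<line class=\"feature\" x1=\"", px(x1), "\" y1=\"",
                  px(th / 2), "\" x2=\"", px(x2), "\" y2=\"", px(th / 2),
                  "\" stroke=\"", col, "\" stroke-width=\"1\">", title,
                  "</line>"))
  }
  y0 <- th * 0.18
  h <- th * 0.64
  if (f$shape == "box" || f$strand == ".") {
    return(paste0("<rect class=\"feature\" x=\"", px(min(x1, x2)),
                  "\" y=\"", px(y0), "\" width=\"", px(abs(x2 - x1)),
                  "\" height=\"", px(h), "\" fill=\"", col, "\">", title,
                  "</rect>"))
  }
  # arrow: body rectangle plus a strand-pointing head
  head_w <- min(6, abs(x2 - x1))
  if (f$strand == "+") {
    bx1 <- x1; bx2 <- max(x1, x2 - head_w)
    pts <- paste(paste0(px(bx2), ",", px(y0)),
                 paste0(px(x2), ",", px(y0 + h / 2)),
                 paste0(px(bx2), ",", px(y0 + h)))
  } else {
    bx1 <- min(x2, x1 + head_w); bx2 <- x2
    pts <- paste(paste0(px(bx1), ",", px(y0)),
                 paste0(px(x1), ",", px(y0 + h / 2)),
                 paste0(px(bx1), ",", px(y0 + h)))
  }
  c(paste0("<rect class=\"feature\" x=\"", px(bx1), "\" y=\"", px(y0),
           "\" width=\"", px(bx2 - bx1), "\" height=\"", px(h),
           "\" fill=\"", col, "\">", title, "</rect>"),
    paste0("<polygon class=\"feature-head\" points=\"", pts,
           "\" fill=\"", col, "\"/>"))
}

block_polygon <- function(b, top_genome, vps, y_top, y_bot, fill, opacity,
                          margin_left) {
  if (b$org1 == top_genome) {
    ts <- b$org1_start; te <- b$org1_end; tg <- b$org1
    bs <- b$org2_start; be <- b$org2_end; bg <- b$org2
  } else {
    ts <- b$org2_start; te <- b$org2_end; tg <- b$org2
    bs <- b$org1_start; be <- b$org1_end; bg <- b$org1
  }
  vt <- vps[[tg]]; vb <- vps[[bg]]
  vis_top <- te >= vt$from && ts <= vt$to
  vis_bot <- be >= vb$from && bs <= vb$to
  if (!vis_top && !vis_bot) return(NULL)
  xt <- map_coordinate(c(ts, te), vt)$x + margin_left
  xb <- map_coordinate(c(bs, be), vb)$x + margin_left
  pts <- paste(paste0(px(xt[1]), ",", px(y_top)),
               paste0(px(xt[2]), ",", px(y_top)),
               paste0(px(xb[2]), ",", px(y_bot)),
               paste0(px(xb[1]), ",", px(y_bot)))
  title <- paste0(b$org1, ":", b$org1_start, "-", b$org1_end, " | ",
                  b$org2, ":", b$org2_start, "-", b$org2_end)
  paste0("<polygon class=\"block\" points=\"", pts, "\" fill=\"", fill,
         "\" fill-opacity=\"", px(opacity),
         "\" stroke=\"#333333\" stroke-width=\"0.3\"><title>",
         xml_escape(title), "</title></polygon>")
}

# shared layout constants
LAYOUT <- list(margin_left = 110, margin_right = 30, margin_top = 30,
               margin_bottom = 30)

#' Render the pairwise viewing mode as SVG
#'
#' One horizontal ruler per order entry (a genome may appear more than
#' once and there is no designated reference); between each pair of
#' adjacent rulers the retained conserved regions are drawn as translucent
#' quadrilaterals joining their two mapped intervals.  Each adjacent-pair
#' track can be filtered independently.  If an annotation track is
#' selected in `style`, its features are drawn inside each ruler with
#' their declared shape and color, wrapped in a hyperlink when one was
#' given.
#'
#' @param dataset A `synteny_dataset`.
#' @param order Character vector of genome names; repeats allowed.
#' @param viewports Optional named list (genome -> `c(from, to)` or
#'   [viewport()]); default is each genome's full extent.
#' @param filters Either a list of [filter_criterion()] applied to every
#'   track, or a named list keyed by adjacent-track position (`"1"` =
#'   between order entries 1 and 2) of criterion lists.
#' @param style A [style_options()]; `hidden_pairs` is not valid here.
#' @param width Drawing width in px.
#' @param track_height,track_gap Ruler height and inter-ruler gap in px.
#' @return SVG document as a single character string.
#' @export
render_pairwise <- function(dataset, order, viewports = NULL,
                            filters = NULL, style = style_options(),
                            width = 1000, track_height = 28,
                            track_gap = 90) {
  stopifnot(inherits(dataset, "synteny_dataset"),
            inherits(style, "style_options"))
  if (length(order) == 0) stop("empty genome order", call. = FALSE)
  if (!is.null(style$hidden_pairs))
    stop("hidden pairs are a multiple-mode option", call. = FALSE)
  missing_g <- setdiff(order, dataset$genomes)
  if (length(missing_g))
    stop("genome in order absent from dataset: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  m <- length(order)
  vps <- resolve_viewports(dataset, order, viewports, width)
  track_filters <- function(k) {
    if (is.null(filters)) return(NULL)
    if (length(filters) && all(vapply(filters, inherits, TRUE,
                                      "filter_criterion")))
      return(filters)
    filters[[as.character(k)]]
  }
  ys <- LAYOUT$margin_top + (seq_len(m) - 1) * (track_height + track_gap)
  height <- ys[m] + track_height + 40
  out <- svg_open(LAYOUT$margin_left + width + LAYOUT$margin_right, height)
  feats <- dataset$features
  sel_feats <- if (!is.null(style$annotation_track) && nrow(feats))
    feats[feats$track == style$annotation_track, , drop = FALSE]
  else NULL
  for (k in seq_len(m)) {
    g <- order[k]
    fk <- if (!is.null(sel_feats))
      sel_feats[sel_feats$org == g, , drop = FALSE]
    else NULL
    out <- c(out, ruler_svg(g, vps[[g]], ys[k], track_height,
                            LAYOUT$margin_left, fk))
  }
  for (k in seq_len(m - 1)) {
    ga <- order[k]; gb <- order[k + 1]
    b <- dataset$blocks
    sel <- (b$org1 == ga & b$org2 == gb) | (b$org1 == gb & b$org2 == ga)
    if (ga == gb) sel <- b$org1 == ga & b$org2 == ga
    b <- b[sel, , drop = FALSE]
    b <- apply_filters(b, track_filters(k))
    if (nrow(b) == 0) next
    polys <- character()
    drawn <- 0
    for (i in seq_len(nrow(b))) {
      fill <- if (style$color_mode == "uniform") style$uniform_color
      else BLOCK_PALETTE[(drawn %% length(BLOCK_PALETTE)) + 1]
      p <- block_polygon(b[i, ], ga, vps, ys[k] + track_height, ys[k + 1],
                         fill, style$opacity, LAYOUT$margin_left)
      if (!is.null(p)) {
        polys <- c(polys, p)
        drawn <- drawn + 1
      }
    }
    if (length(polys))
      out <- c(out, paste0("<g class=\"synteny-track\" data-track=\"", k,
                           "\">"), polys, "</g>")
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Render the multiple viewing mode as SVG
#'
#' Conserved regions are drawn between all pairs of displayed genomes,
#' not only adjacent ones; links between non-adjacent tracks pass over
#' the intermediate rulers as translucent ribbons.  Every region of a
#' given genome pair shares one color so overlapping regions can be told
#' apart; individual pairs can be hidden via `style$hidden_pairs`.  Each
#' genome may appear at most once and annotation tracks are not shown in
#' this mode.  A single global filter applies to all regions.
#'
#' @inheritParams render_pairwise
#' @param order Character vector of distinct genome names.
#' @param filters A list of [filter_criterion()] applied globally.
#' @return SVG document as a single character string.
#' @export
render_multiple <- function(dataset, order, viewports = NULL,
                            filters = NULL, style = style_options(),
                            width = 1000, track_height = 28,
                            track_gap = 90) {
  stopifnot(inherits(dataset, "synteny_dataset"),
            inherits(style, "style_options"))
  if (length(order) == 0) stop("empty genome order", call. = FALSE)
  if (anyDuplicated(order))
    stop("repeated genome in multiple-mode order: each genome is shown ",
         "only once", call. = FALSE)
  if (!is.null(style$annotation_track))
    stop("annotation tracks are not shown in multiple viewing mode",
         call. = FALSE)
  missing_g <- setdiff(order, dataset$genomes)
  if (length(missing_g))
    stop("genome in order absent from dataset: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  m <- length(order)
  vps <- resolve_viewports(dataset, order, viewports, width)
  ys <- LAYOUT$margin_top + (seq_len(m) - 1) * (track_height + track_gap)
  height <- ys[m] + track_height + 40
  out <- svg_open(LAYOUT$margin_left + width + LAYOUT$margin_right, height)
  for (k in seq_len(m))
    out <- c(out, ruler_svg(order[k], vps[[order[k]]], ys[k], track_height,
                            LAYOUT$margin_left))
  blocks <- apply_filters(dataset$blocks, filters)
  hidden <- if (is.null(style$hidden_pairs)) character()
  else vapply(style$hidden_pairs, function(p) pair_keys(p[1], p[2]), "")
  pair_color <- function(key, rank) {
    user_key <- sub("\t", "|", key, fixed = TRUE)
    if (!is.null(style$pair_colors) && user_key %in% names(style$pair_colors))
      style$pair_colors[[user_key]]
    else BLOCK_PALETTE[((rank - 1) %% length(BLOCK_PALETTE)) + 1]
  }
  pos <- stats::setNames(seq_len(m), order)
  keys_in_view <- character()
  for (i in seq_len(m - 1))
    for (j in (i + 1):m)
      keys_in_view <- c(keys_in_view, pair_keys(order[i], order[j]))
  keys_in_view <- sort(keys_in_view)
  for (rank in seq_along(keys_in_view)) {
    key <- keys_in_view[rank]
    if (key %in% hidden) next
    gs <- strsplit(key, "\t", fixed = TRUE)[[1]]
    b <- blocks[pair_keys(blocks$org1, blocks$org2) == key &
                blocks$org1 != blocks$org2, , drop = FALSE]
    if (nrow(b) == 0) next
    top_g <- gs[which.min(pos[gs])]
    bot_g <- gs[which.max(pos[gs])]
    y_top <- ys[pos[top_g]] + track_height
    y_bot <- ys[pos[bot_g]]
    fill <- pair_color(key, rank)
    polys <- character()
    for (i in seq_len(nrow(b))) {
      p <- block_polygon(b[i, ], top_g, vps, y_top, y_bot, fill,
                         style$opacity, LAYOUT$margin_left)
      if (!is.null(p)) polys <- c(polys, p)
    }
    if (length(polys))
      out <- c(out, paste0("<g class=\"pair-group\" data-pair=\"",
                           xml_escape(sub("\t", "|", key, fixed = TRUE)),
                           "\">"), polys, "</g>")
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Circular overview geometry
#'
#' Angular layout of the genome arcs: each genome receives an angular
#' span proportional to its extent out of `360 - n * gap_deg` degrees,
#' genomes in name order starting at angle 0.
#'
#' @param dataset A `synteny_dataset`.
#' @param gap_deg Gap between consecutive arcs in degrees (shrunk when
#'   many genomes would otherwise consume the circle).
#' @return A `data.frame` with columns `genome`, `start_deg`, `span_deg`.
#' @export
overview_geometry <- function(dataset, gap_deg = 4) {
  stopifnot(inherits(dataset, "synteny_dataset"))
  genomes <- dataset$genomes
  n <- length(genomes)
  gap_deg <- min(gap_deg, 180 / n)
  ext <- dataset$extents[genomes]
  span <- (360 - n * gap_deg) * ext / sum(ext)
  start <- cumsum(c(0, utils::head(span, -1) + gap_deg))
  data.frame(genome = genomes, start_deg = as.numeric(start),
             span_deg = as.numeric(span), stringsAsFactors = FALSE)
}

polar_xy <- function(cx, cy, r, deg) {
  rad <- (deg - 90) * pi / 180
  c(cx + r * cos(rad), cy + r * sin(rad))
}

#' Render the circular overview as SVG
#'
#' All genomes arranged on a circle, arc length proportional to genome
#' extent; one chord per associated genome pair with stroke width
#' proportional to the pair's total conserved size; the association table
#' (pair, region count, total size) is rendered beside the circle.
#'
#' @param dataset A `synteny_dataset`.
#' @param size Diameter of the drawing area in px.
#' @param gap_deg Gap between arcs in degrees.
#' @return SVG document as a single character string.
#' @export
render_overview <- function(dataset, size = 620, gap_deg = 4) {
  stopifnot(inherits(dataset, "synteny_dataset"))
  geom <- overview_geometry(dataset, gap_deg)
  assoc <- association_summary(dataset)
  cross <- assoc[assoc$genome1 != assoc$genome2, , drop = FALSE]
  cx <- size / 2; cy <- size / 2
  R <- size / 2 - 40
  table_w <- 300
  out <- svg_open(size + table_w, size)
  mid <- stats::setNames(geom$start_deg + geom$span_deg / 2, geom$genome)
  for (i in seq_len(nrow(geom))) {
    a1 <- geom$start_deg[i]
    a2 <- a1 + geom$span_deg[i]
    p1 <- polar_xy(cx, cy, R, a1)
    p2 <- polar_xy(cx, cy, R, a2)
    large <- if (geom$span_deg[i] > 180) 1 else 0
    out <- c(out,
             paste0("<path class=\"genome-arc\" d=\"M ", px(p1[1]), " ",
                    px(p1[2]), " A ", px(R), " ", px(R), " 0 ", large,
                    " 1 ", px(p2[1]), " ", px(p2[2]),
                    "\" fill=\"none\" stroke=\"",
                    BLOCK_PALETTE[((i - 1) %% length(BLOCK_PALETTE)) + 1],
                    "\" stroke-width=\"14\"/>"))
    lp <- polar_xy(cx, cy, R + 24, (a1 + a2) / 2)
    out <- c(out,
             paste0("<text class=\"arc-label\" x=\"", px(lp[1]), "\" y=\"",
                    px(lp[2]), "\" text-anchor=\"middle\">",
                    xml_escape(geom$genome[i]), "</text>"))
  }
  if (nrow(cross)) {
    wmax <- max(cross$total_size)
    for (i in seq_len(nrow(cross))) {
      p1 <- polar_xy(cx, cy, R - 10, mid[cross$genome1[i]])
      p2 <- polar_xy(cx, cy, R - 10, mid[cross$genome2[i]])
      sw <- 1 + 9 * cross$total_size[i] / wmax
      out <- c(out,
               paste0("<line class=\"chord\" x1=\"", px(p1[1]), "\" y1=\"",
                      px(p1[2]), "\" x2=\"", px(p2[1]), "\" y2=\"",
                      px(p2[2]), "\" stroke=\"#777777\" stroke-opacity=",
                      "\"0.6\" stroke-width=\"", px(sw), "\"/>"))
    }
  }
  out <- c(out, paste0("<g class=\"assoc-table\" transform=\"translate(",
                       px(size + 20), ",40)\">"),
           paste0("<text font-weight=\"bold\" x=\"0\" y=\"0\">",
                  "Associations provided</text>"))
  for (i in seq_len(nrow(assoc))) {
    out <- c(out,
             paste0("<text class=\"assoc-row\" x=\"0\" y=\"", px(i * 16),
                    "\">",
                    xml_escape(paste0(assoc$genome1[i], " - ",
                                      assoc$genome2[i], ": ",
                                      assoc$n_regions[i], " regions, ",
                                      format_cell(assoc$total_size[i]),
                                      " bp")),
                    "</text>"))
  }
  paste(c(out, "</g>", "</svg>"), collapse = "\n")
}
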