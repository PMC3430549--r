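count_matches <- function(svg, pattern) {
  m <- gregexpr(pattern, svg, fixed = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

toy_dataset <- function() {
  synteny_dataset(synteny_blocks("G1", 10, 60, "G2", 100, 160,
                                 pident = 95))
}

test_that("coordinate mapping is the affine map with edge clamping", {
  vp <- viewport(100, 1100, width = 500)
  expect_equal(map_coordinate(100, vp)$x, 0)
  expect_equal(map_coordinate(1100, vp)$x, 500)
  expect_equal(map_coordinate(600, vp)$x, 250)
  set.seed(5)
  bp <- runif(100, 100, 1100)
  got <- map_coordinate(bp, vp)
  expect_equal(got$x, (bp - 100) / 1000 * 500)
  expect_false(any(got$clipped))
  out <- map_coordinate(c(50, 2000), vp)
  expect_true(all(out$clipped))
  expect_equal(out$x, c(0, 500))
  expect_error(map_coordinate(5, viewport(5, 5)), "degenerate")
  expect_error(viewport(10, 5), "from <= to")
  expect_error(viewport(1, 10, width = 50), "100 px")
})

test_that("tick intervals follow the 1-2-5 ladder giving 4-10 ticks", {
  t1000 <- tick_marks(viewport(1, 1000))
  expect_equal(t1000$bp, seq(200, 1000, by = 200))
  expect_equal(t1000$label, paste0(seq(200, 1000, by = 200), "bp"))

  tm <- tick_marks(viewport(1, 10e6))
  expect_equal(tm$bp, seq(2e6, 10e6, by = 2e6))
  expect_equal(tm$label[1], "2Mb")

  expect_equal(nrow(tick_marks(viewport(1, 1))), 1)

  set.seed(11)
  for (i in 1:50) {
    from <- sample.int(1e6, 1)
    span <- sample.int(1e7, 1) + 10
    n <- nrow(tick_marks(viewport(from, from + span - 1)))
    expect_gte(n, 4)
    expect_lte(n, 10)
  }
})

test_that("pairwise rendering draws one ruler per entry and the blocks", {
  d <- toy_dataset()
  svg <- render_pairwise(d, c("G1", "G2"))
  expect_equal(count_matches(svg, "<g class=\"ruler\""), 2L)
  expect_equal(count_matches(svg, "<polygon class=\"block\""), 1L)
  # tooltip carries the numerical start and end positions
  expect_match(svg, "G1:10-60 | G2:100-160", fixed = TRUE)

  # repeated genomes are a pairwise-mode feature: no designated reference
  b4 <- synteny_blocks(c("A", "A", "A"), 1, 100, c("B", "C", "D"), 1, 100)
  d4 <- synteny_dataset(b4)
  svg4 <- render_pairwise(d4, c("B", "A", "C", "A", "D"))
  expect_equal(count_matches(svg4, "<g class=\"ruler\""), 5L)
  expect_equal(count_matches(svg4, "<polygon class=\"block\""), 4L)

  expect_error(render_pairwise(d, character()), "empty")
  expect_error(render_pairwise(d, c("G1", "GX")), "absent")
})

test_that("rendering is deterministic and clips x within the canvas", {
  fx <- generate_dataset(fixture_spec(n_genomes = 4, n_blocks = 30,
                                      seed = 3))
  d <- fx$dataset
  ord <- d$genomes
  views <- list(Gen02 = c(2e5, 6e5))
  svg_a <- render_pairwise(d, ord, viewports = views)
  svg_b <- render_pairwise(d, ord, viewports = views)
  expect_identical(svg_a, svg_b)
  expect_identical(render_multiple(d, ord), render_multiple(d, ord))
  expect_identical(render_overview(d), render_overview(d))

  pts <- regmatches(svg_a, gregexpr("points=\"[^\"]*\"", svg_a))[[1]]
  xs <- as.numeric(unlist(lapply(pts, function(p) {
    coords <- strsplit(gsub("points=|\"", "", p), "[ ,]")[[1]]
    coords[seq(1, length(coords), by = 2)]
  })))
  expect_true(all(xs >= 110 - 1e-9 & xs <= 110 + 1000 + 1e-9))
})

test_that("filtering before rendering equals rendering with filters", {
  fx <- generate_dataset(fixture_spec(n_genomes = 4, n_blocks = 40,
                                      seed = 13))
  d <- fx$dataset
  crit <- list(filter_criterion("pident", min = 70))
  views <- lapply(d$extents, function(e) c(1, e))
  pre <- synteny_dataset(apply_filters(d$blocks, crit), d$features,
                         d$genome_lengths)
  expect_identical(
    render_pairwise(pre, d$genomes, viewports = views),
    render_pairwise(d, d$genomes, viewports = views, filters = crit))
  expect_identical(
    render_multiple(pre, d$genomes, viewports = views),
    render_multiple(d, d$genomes, viewports = views, filters = crit))
})

test_that("multiple mode draws all pairs, honors hiding and pair colors", {
  b <- synteny_blocks(c("A", "A", "B"), 1, 1000, c("B", "C", "C"),
                      1, 1000)
  d <- synteny_dataset(b)
  svg <- render_multiple(d, c("A", "B", "C"))
  expect_equal(count_matches(svg, "<g class=\"pair-group\""), 3L)
  expect_equal(count_matches(svg, "<polygon class=\"block\""), 3L)

  hid <- render_multiple(d, c("A", "B", "C"),
                         style = style_options(hidden_pairs = list(c("A", "C"))))
  expect_equal(count_matches(hid, "<g class=\"pair-group\""), 2L)
  expect_false(grepl("data-pair=\"A|C\"", hid, fixed = TRUE))
  expect_true(grepl("data-pair=\"A|B\"", hid, fixed = TRUE))

  # all regions of one genome pair share one color
  ab <- synteny_dataset(synteny_blocks(c("A", "A"), c(1, 500), c(99, 700),
                                       c("B", "B"), c(1, 500), c(99, 700)))
  svg_ab <- render_multiple(ab, c("A", "B"))
  block_lines <- grep("class=\"block\"", strsplit(svg_ab, "\n")[[1]],
                      value = TRUE)
  fills <- vapply(regmatches(block_lines,
                             regexpr("fill=\"#[0-9a-fA-F]+\"", block_lines)),
                  identity, "")
  expect_equal(length(block_lines), 2L)
  expect_equal(length(unique(fills)), 1L)
})

test_that("mode constraints reject invalid order and style combinations", {
  d <- toy_dataset()
  expect_error(render_multiple(d, c("G1", "G1", "G2")), "only once")
  expect_error(render_multiple(d, c("G1", "G2"),
                               style = style_options(annotation_track = "gene")),
               "not shown in multiple")
  expect_error(render_pairwise(d, c("G1", "G2"),
                               style = style_options(hidden_pairs = list(c("G1", "G2")))),
               "multiple-mode option")
  # pairwise accepts repeats
  expect_silent(invisible(render_pairwise(d, c("G1", "G2", "G1"))))
})

test_that("annotation features render with shape, color and hyperlink", {
  f <- annotation_features(c("G1", "G1", "G2"), c(20, 30, 110),
                           c(28, 45, 140), c("+", ".", "-"),
                           c("abc", "noy", "withlink"), "gene",
                           c("arrow", "box", "line"), "#ff0000",
                           c(NA, NA, "http://x.org/a"))
  d <- synteny_dataset(toy_dataset()$blocks, f)
  svg <- render_pairwise(d, c("G1", "G2"),
                         style = style_options(annotation_track = "gene"))
  expect_equal(count_matches(svg, "<a xlink:href=\"http://x.org/a\""), 1L)
  expect_gte(count_matches(svg, "class=\"feature\""), 3L)
  # no track selected: no features drawn
  svg0 <- render_pairwise(d, c("G1", "G2"))
  expect_equal(count_matches(svg0, "class=\"feature\""), 0L)
  # uniform color mode uses the requested fill for every block
  svg_u <- render_pairwise(d, c("G1", "G2"),
                           style = style_options(color_mode = "uniform",
                                                 uniform_color = "#123456"))
  expect_match(svg_u, "fill=\"#123456\"", fixed = TRUE)
})

test_that("overview lays out arcs proportionally and chords per pair", {
  b <- synteny_blocks(c("A", "A"), 1, 1000, c("B", "C"), 1, 1000)
  d <- synteny_dataset(b, genome_lengths = c(A = 4000, B = 2000, C = 2000))
  svg <- render_overview(d)
  expect_equal(count_matches(svg, "<path class=\"genome-arc\""), 3L)
  expect_equal(count_matches(svg, "<line class=\"chord\""), 2L)
  expect_equal(count_matches(svg, "<text class=\"assoc-row\""), 2L)

  geom <- overview_geometry(d, gap_deg = 4)
  expect_equal(sum(geom$span_deg), 360 - 3 * 4)
  # arc spans proportional to extents: A twice B
  expect_equal(geom$span_deg[geom$genome == "A"],
               2 * geom$span_deg[geom$genome == "B"])

  # one genome, self-blocks only: one arc, no chords
  solo <- synteny_dataset(synteny_blocks("A", 1, 10, "A", 50, 60))
  svg1 <- render_overview(solo)
  expect_equal(count_matches(svg1, "<path class=\"genome-arc\""), 1L)
  expect_equal(count_matches(svg1, "<line class=\"chord\""), 0L)
})
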