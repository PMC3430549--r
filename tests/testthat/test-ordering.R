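path_graph <- function(weights, genomes = LETTERS[seq_len(length(weights) + 1)]) {
  n <- length(genomes)
  w <- matrix(0, n, n, dimnames = list(genomes, genomes))
  for (k in seq_along(weights)) {
    w[k, k + 1] <- w[k + 1, k] <- weights[k]
  }
  w
}

test_that("weight graph sums per-pair conserved sizes", {
  b <- synteny_blocks(c("A", "A", "B"), 1, c(15, 15, 10),
                      c("B", "B", "C"), 1, c(15, 15, 10))
  g <- build_weight_graph(synteny_dataset(b))
  expect_equal(g$w["A", "B"], 30)
  expect_equal(g$w["B", "C"], 10)
  expect_equal(g$w["A", "C"], 0)
  expect_true(isSymmetric(g$w))
  gc <- build_weight_graph(synteny_dataset(b), weight = "count")
  expect_equal(gc$w["A", "B"], 2)

  # self-synteny contributes no off-diagonal weight
  gs <- build_weight_graph(synteny_dataset(
    synteny_blocks("A", 1, 10, "A", 50, 60)))
  expect_equal(sum(gs$w), 0)

  # cross-module consistency with the association summary
  fx <- generate_dataset(fixture_spec(n_genomes = 5, n_blocks = 40,
                                      seed = 7))
  gf <- build_weight_graph(fx$dataset)
  s <- association_summary(fx$dataset)
  s <- s[s$genome1 != s$genome2, ]
  for (i in seq_len(nrow(s)))
    expect_equal(gf$w[s$genome1[i], s$genome2[i]], s$total_size[i])
})

test_that("objectives match direct re-summation and are reversal-symmetric", {
  w <- path_graph(c(100, 90))
  expect_equal(pairwise_score(c("A", "B", "C"), w), 190)
  expect_equal(pairwise_score("A", w), 0)
  w2 <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  w2["A", "C"] <- w2["C", "A"] <- 10
  expect_equal(multiple_cost(c("A", "B", "C"), w2), 10)
  expect_equal(multiple_cost(c("A", "C", "B"), w2), 0)
  expect_equal(multiple_cost(c("A", "B"), path_graph(5)), 0)
  expect_error(multiple_cost(c("A", "A", "B"), w2), "distinct")

  set.seed(3)
  for (i in 1:25) {
    w <- random_weight_graph(6, seed = i)
    ord <- sample(rownames(w))
    expect_equal(pairwise_score(ord, w), oracle_pairwise_score(ord, w))
    expect_equal(multiple_cost(ord, w), oracle_multiple_cost(ord, w))
    expect_equal(pairwise_score(rev(ord), w), pairwise_score(ord, w))
    expect_equal(multiple_cost(rev(ord), w), multiple_cost(ord, w))
  }
})

test_that("greedy pairwise order follows the max-weight path construction", {
  w <- path_graph(c(100, 90))
  w["A", "C"] <- w["C", "A"] <- 1
  res <- optimize_pairwise_order(w)
  expect_equal(res$score, 190)
  expect_true(identical(res$order, c("A", "B", "C")) ||
              identical(res$order, c("C", "B", "A")))

  # all-zero weights: name-sorted order
  z <- matrix(0, 3, 3, dimnames = list(c("Z", "M", "A"), c("Z", "M", "A")))
  rz <- optimize_pairwise_order(z)
  expect_equal(rz$order, c("A", "M", "Z"))
  expect_equal(rz$score, 0)

  expect_equal(optimize_pairwise_order(
    matrix(0, 1, 1, dimnames = list("A", "A")))$order, "A")
  expect_error(optimize_pairwise_order(
    structure(list(genomes = character(),
                   w = matrix(0, 0, 0)), class = "weight_graph")),
    "empty")
})

test_that("greedy multiple order reaches zero cost on path graphs", {
  # only consecutive pairs weighted: a zero-cost order exists
  res <- optimize_multiple_order(path_graph(c(7, 3, 9)))
  expect_equal(res$score, 0)
  # adversarial weights where insertion alone lays a segment backwards
  res2 <- optimize_multiple_order(path_graph(c(10, 9, 2, 8, 20)))
  expect_equal(res2$score, 0)
  # two genomes always cost zero
  expect_equal(optimize_multiple_order(path_graph(5))$score, 0)
})

test_that("heuristics never beat the exhaustive optimum on random graphs", {
  n_hit_pair <- 0
  n_hit_mult <- 0
  for (i in 1:60) {
    w <- random_weight_graph(6, seed = 7000 + i)
    hp <- optimize_pairwise_order(w)
    hm <- optimize_multiple_order(w)
    op <- exhaustive_order(w, "pairwise")
    om <- exhaustive_order(w, "multiple")
    expect_lte(hp$score, op$score)
    expect_gte(hm$score, om$score)
    expect_false(anyDuplicated(hp$order) > 0)
    expect_setequal(hp$order, rownames(w))
    if (hp$score == op$score) n_hit_pair <- n_hit_pair + 1
    if (hm$score == om$score) n_hit_mult <- n_hit_mult + 1
  }
  # greedy should find the optimum in a clear majority of small instances
  expect_gte(n_hit_pair, 30)
  expect_gte(n_hit_mult, 30)
})

test_that("exhaustive search agrees with independent enumeration", {
  for (i in 1:10) {
    w <- random_weight_graph(4, seed = 100 + i)
    for (mode in c("pairwise", "multiple")) {
      mine <- exhaustive_order(w, mode)
      ref <- oracle_best_order(w, mode)
      expect_equal(mine$score, ref$score)
    }
  }
  one <- exhaustive_order(matrix(0, 1, 1, dimnames = list("A", "A")),
                          "pairwise")
  expect_equal(one$order, "A")
  expect_equal(one$score, 0)
  big <- matrix(0, 9, 9, dimnames = list(LETTERS[1:9], LETTERS[1:9]))
  expect_error(exhaustive_order(big, "pairwise"), "refused")
})
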