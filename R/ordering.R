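# Genome display-order optimization.
#
# The weight between two genomes is the total conserved size in bp shared
# between them (sum over their blocks of the mean side span).  Pairwise
# viewing mode rewards placing heavy pairs on adjacent tracks (maximize the
# sum of adjacent-pair weights, a max-weight Hamiltonian path objective);
# multiple viewing mode penalizes links that cross intermediate tracks
# (minimize the size-weighted count of tracks each association spans).

#' Build the genome weight graph
#'
#' Symmetric weights `w(i, j)` equal to the total conserved size between
#' genomes i and j — the `total_size` column of [association_summary()] —
#' or, with `weight = "count"`, the number of shared conserved regions.
#' Self-synteny (both sides on one genome) does not contribute to
#' off-diagonal weights.
#'
#' @param dataset A `synteny_dataset`.
#' @param weight `"size"` (total conserved bp, the default) or `"count"`
#'   (number of associations).
#' @return An object of class `weight_graph`: list with `genomes`
#'   (name-sorted) and `w` (symmetric numeric matrix, zero diagonal).
#' @export
build_weight_graph <- function(dataset, weight = c("size", "count")) {
  stopifnot(inherits(dataset, "synteny_dataset"))
  weight <- match.arg(weight)
  genomes <- sort(unique(c(dataset$blocks$org1, dataset$blocks$org2,
                           names(dataset$genome_lengths))))
  w <- matrix(0, length(genomes), length(genomes),
              dimnames = list(genomes, genomes))
  s <- association_summary(dataset)
  s <- s[s$genome1 != s$genome2, , drop = FALSE]
  val <- if (weight == "size") s$total_size else s$n_regions
  w[cbind(s$genome1, s$genome2)] <- val
  w[cbind(s$genome2, s$genome1)] <- val
  structure(list(genomes = genomes, w = w), class = "weight_graph")
}

as_weight_graph <- function(graph) {
  if (inherits(graph, "weight_graph")) return(graph)
  if (is.matrix(graph) && !is.null(rownames(graph)))
    return(structure(list(genomes = rownames(graph), w = graph),
                     class = "weight_graph"))
  stop("expected a weight_graph or a named symmetric matrix", call. = FALSE)
}

#' Score an order for pairwise viewing mode
#'
#' Sum of weights over consecutive track pairs: the total conserved size
#' made visible between adjacent genomes.
#'
#' @param order Character vector of genome names (repeats allowed).
#' @param graph A [build_weight_graph()] result or named weight matrix.
#' @return Numeric score.
#' @export
pairwise_score <- function(order, graph) {
  graph <- as_weight_graph(graph)
  if (length(order) < 2) return(0)
  a <- order[-length(order)]
  b <- order[-1]
  sum(ifelse(a == b, 0, graph$w[cbind(a, b)]))
}

#' Cost of an order for multiple viewing mode
#'
#' Size-weighted number of intermediate tracks each association must
#' cross: sum over genome pairs of `w(i, j) * max(0, |pos(i) - pos(j)| - 1)`.
#' Zero when every associated pair sits on adjacent tracks.
#'
#' @param order Character vector of distinct genome names.
#' @param graph A [build_weight_graph()] result or named weight matrix.
#' @return Numeric cost (>= 0).
#' @export
multiple_cost <- function(order, graph) {
  graph <- as_weight_graph(graph)
  if (anyDuplicated(order))
    stop("multiple viewing mode requires distinct genomes", call. = FALSE)
  n <- length(order)
  if (n < 3) return(0)
  pos <- stats::setNames(seq_len(n), order)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  gi <- order[idx[, 1]]
  gj <- order[idx[, 2]]
  wij <- graph$w[cbind(gi, gj)]
  gap <- abs(pos[gi] - pos[gj]) - 1
  sum(wij * pmax(0, gap))
}

#' Greedy genome order for pairwise viewing mode
#'
#' Greedy max-weight path construction: seed with the highest-weight
#' genome pair, then repeatedly append to either path end the unused
#' genome with maximum weight to that end.  Ties are broken toward the
#' lexicographically smaller genome name, and equal-weight end ties
#' prefer the right end.  Genomes with zero weight to both ends are
#' appended at the right in name order.  The result is a simple
#' permutation of the genomes; the heuristic does not guarantee the
#' optimal order (see [exhaustive_order()]).
#'
#' @param graph A [build_weight_graph()] result or named weight matrix.
#' @return An object of class `genome_order`: list with `order`
#'   (character), `mode = "pairwise"` and `score` ([pairwise_score()]).
#' @export
optimize_pairwise_order <- function(graph) {
  graph <- as_weight_graph(graph)
  genomes <- sort(graph$genomes)
  if (length(genomes) == 0) stop("empty weight graph", call. = FALSE)
  w <- graph$w[genomes, genomes, drop = FALSE]
  diag(w) <- 0
  n <- length(genomes)
  if (n == 1 || max(w) == 0) {
    path <- genomes
  } else {
    seed <- which(w == max(w), arr.ind = TRUE)
    seed <- seed[seed[, 1] < seed[, 2], , drop = FALSE]
    # lexicographically smallest pair among maxima (names are sorted)
    seed <- seed[order(seed[, 1], seed[, 2]), , drop = FALSE][1, ]
    path <- genomes[c(seed[1], seed[2])]
    unused <- setdiff(genomes, path)
    while (length(unused)) {
      wl <- w[path[1], unused]
      wr <- w[path[length(path)], unused]
      best <- max(wl, wr)
      if (best == 0) {
        path <- c(path, sort(unused))
        break
      }
      # candidates attaining the best weight; genome name first, then
      # prefer the right end on an end tie
      cand_r <- unused[wr == best]
      cand_l <- unused[wl == best]
      pick <- sort(c(cand_r, cand_l))[1]
      if (pick %in% cand_r) path <- c(path, pick)
      else path <- c(pick, path)
      unused <- setdiff(unused, pick)
    }
  }
  structure(list(order = path, mode = "pairwise",
                 score = pairwise_score(path, graph)),
            class = "genome_order")
}

#' Greedy genome order for multiple viewing mode
#'
#' Greedy insertion followed by local search.  Genomes are taken in
#' decreasing total weight, starting with the heaviest pair adjacent;
#' each next genome is inserted at the position minimizing the
#' [multiple_cost()] of the partial order (ties to the leftmost
#' position).  The local search then repeatedly applies the best
#' improving adjacent swap or segment reversal until no move lowers the
#' cost; reversals rescue chain segments laid down in the wrong
#' orientation, which adjacent swaps alone cannot repair.
#'
#' @param graph A [build_weight_graph()] result or named weight matrix.
#' @return An object of class `genome_order` with `mode = "multiple"`
#'   and `score` = [multiple_cost()].
#' @export
optimize_multiple_order <- function(graph) {
  graph <- as_weight_graph(graph)
  genomes <- sort(graph$genomes)
  if (length(genomes) == 0) stop("empty weight graph", call. = FALSE)
  w <- graph$w[genomes, genomes, drop = FALSE]
  diag(w) <- 0
  n <- length(genomes)
  if (n <= 2) {
    ord <- genomes
  } else {
    totals <- rowSums(w)
    by_total <- genomes[order(-totals, genomes)]
    if (max(w) == 0) {
      ord <- by_total
    } else {
      seed <- which(w == max(w), arr.ind = TRUE)
      seed <- seed[seed[, 1] < seed[, 2], , drop = FALSE]
      seed <- seed[order(seed[, 1], seed[, 2]), , drop = FALSE][1, ]
      ord <- genomes[c(seed[1], seed[2])]
      for (g in setdiff(by_total, ord)) {
        costs <- vapply(seq_len(length(ord) + 1), function(p)
          multiple_cost(append(ord, g, after = p - 1), graph), 0)
        ord <- append(ord, g, after = which.min(costs) - 1)
      }
    }
    ord <- refine_multiple_order(ord, graph)
  }
  structure(list(order = ord, mode = "multiple",
                 score = multiple_cost(ord, graph)),
            class = "genome_order")
}

# Steepest-descent local search over adjacent swaps and segment
# reversals; first-listed move wins on a tie so the result is
# deterministic.
refine_multiple_order <- function(ord, graph) {
  n <- length(ord)
  cur <- multiple_cost(ord, graph)
  repeat {
    best_ord <- NULL
    best_cost <- cur
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cand <- ord
        cand[i:j] <- cand[j:i]
        cc <- multiple_cost(cand, graph)
        if (cc < best_cost) {
          best_cost <- cc
          best_ord <- cand
        }
      }
    }
    if (is.null(best_ord)) return(ord)
    ord <- best_ord
    cur <- best_cost
  }
}

#' @export
print.genome_order <- function(x, ...) {
  cat(paste(x$order, collapse = " - "), "\n")
  cat("mode:", x$mode, " score:", x$score, "\n")
  invisible(x)
}

# All permutations of 1..n in lexicographic order, one per row.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1
    }
  }
  out
}

#' Exact optimum genome order by exhaustive search
#'
#' Enumerates all permutations (refused above 8 genomes, i.e. 40320
#' orders) and returns the best under the requested objective: maximum
#' [pairwise_score()] or minimum [multiple_cost()].  Ties break to the
#' lexicographically smallest order sequence.  Intended as the exact
#' reference against which the greedy heuristics are measured.
#'
#' @param graph A [build_weight_graph()] result or named weight matrix.
#' @param mode `"pairwise"` or `"multiple"`.
#' @return An object of class `genome_order`.
#' @export
exhaustive_order <- function(graph, mode = c("pairwise", "multiple")) {
  graph <- as_weight_graph(graph)
  mode <- match.arg(mode)
  genomes <- sort(graph$genomes)
  n <- length(genomes)
  if (n == 0) stop("empty weight graph", call. = FALSE)
  if (n > 8)
    stop("exhaustive search refused for more than 8 genomes", call. = FALSE)
  w <- graph$w[genomes, genomes, drop = FALSE]
  diag(w) <- 0
  perms <- permutations_of(n)
  if (mode == "pairwise") {
    vals <- rep(0, nrow(perms))
    if (n >= 2)
      for (k in seq_len(n - 1))
        vals <- vals + w[cbind(perms[, k], perms[, k + 1])]
    best <- which.max(vals)  # first maximum = lexicographically smallest
  } else {
    vals <- rep(0, nrow(perms))
    if (n >= 3) {
      pos <- matrix(0L, nrow(perms), n)
      pos[cbind(rep(seq_len(nrow(perms)), n), as.vector(perms))] <-
        rep(seq_len(n), each = nrow(perms))
      for (i in seq_len(n - 1))
        for (j in (i + 1):n)
          if (w[i, j] > 0)
            vals <- vals + w[i, j] * pmax(0L, abs(pos[, i] - pos[, j]) - 1L)
    }
    best <- which.min(vals)
  }
  structure(list(order = genomes[perms[best, ]], mode = mode,
                 score = vals[best]),
            class = "genome_order")
}
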