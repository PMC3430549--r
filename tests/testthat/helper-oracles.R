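# Independent oracles and fuzz generators used across the suite.  These
# deliberately re-derive quantities with different code paths than the
# package (plain loops, recursive enumeration) so agreement is evidence,
# not tautology.

# random block table with numeric and text attribute columns
fuzz_blocks <- function(n, seed, genomes = paste0("G", 1:4),
                        with_text = TRUE) {
  set.seed(seed)
  g1 <- sample(genomes, n, replace = TRUE)
  g2 <- sample(genomes, n, replace = TRUE)
  s1 <- sample.int(1e5, n)
  s2 <- sample.int(1e5, n)
  len1 <- sample.int(5000, n)
  len2 <- sample.int(5000, n)
  b <- synteny_blocks(g1, s1, s1 + len1 - 1, g2, s2, s2 + len2 - 1,
                      score = round(stats::rlnorm(n, 5, 2), 3),
                      pident = round(stats::runif(n, 40, 100), 2))
  if (with_text) {
    b$note <- sample(c("dup", "inv", "syn-1", "NA"), n, replace = TRUE)
    # mixed column: numeric-looking and text values so it stays text
    b$mixed <- sample(c("12.5", "high", "low", "3"), n, replace = TRUE)
    b$mixed[1] <- "high"  # a text value pins the column type
  }
  b
}

# all permutations of a vector, by recursive insertion (a different
# construction than the package's lexicographic generator)
perms_by_insertion <- function(items) {
  if (length(items) <= 1) return(list(items))
  rest <- perms_by_insertion(items[-1])
  out <- list()
  for (p in rest) {
    for (k in 0:length(p)) {
      out[[length(out) + 1]] <- append(p, items[1], after = k)
    }
  }
  out
}

# direct loop re-implementations of the two ordering objectives
oracle_pairwise_score <- function(ord, w) {
  s <- 0
  for (k in seq_len(length(ord) - 1)) {
    if (ord[k] != ord[k + 1]) s <- s + w[ord[k], ord[k + 1]]
  }
  s
}

oracle_multiple_cost <- function(ord, w) {
  s <- 0
  n <- length(ord)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        gap <- j - i - 1
        s <- s + w[ord[i], ord[j]] * gap
      }
    }
  }
  s
}

oracle_best_order <- function(w, mode) {
  best <- NULL
  best_val <- if (mode == "pairwise") -Inf else Inf
  for (p in perms_by_insertion(sort(rownames(w)))) {
    v <- if (mode == "pairwise") oracle_pairwise_score(p, w)
    else oracle_multiple_cost(p, w)
    if ((mode == "pairwise" && v > best_val) ||
        (mode == "multiple" && v < best_val)) {
      best <- p
      best_val <- v
    }
  }
  list(order = best, score = best_val)
}

random_weight_graph <- function(n_genomes, seed, zero_frac = 0.3) {
  set.seed(seed)
  gn <- sprintf("W%02d", seq_len(n_genomes))
  w <- matrix(0, n_genomes, n_genomes, dimnames = list(gn, gn))
  for (i in seq_len(n_genomes - 1)) {
    for (j in (i + 1):n_genomes) {
      v <- if (stats::runif(1) < zero_frac) 0
      else round(stats::rlnorm(1, 8, 1.5))
      w[i, j] <- w[j, i] <- v
    }
  }
  w
}

# brute-force per-block filter scan: the drop rule spelled out one block
# at a time
oracle_filter <- function(blocks, criteria) {
  keep <- logical(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    ok <- TRUE
    for (cr in criteria) {
      v <- if (cr$attribute == "length") {
        ((blocks$org1_end[i] - blocks$org1_start[i] + 1) +
         (blocks$org2_end[i] - blocks$org2_start[i] + 1)) / 2
      } else if (cr$attribute %in% names(blocks)) {
        raw <- blocks[[cr$attribute]][i]
        if (is.numeric(raw)) raw
        else suppressWarnings(as.numeric(as.character(raw)))
      } else NA_real_
      if (is.na(v) || !is.finite(v) || v < cr$min || v > cr$max) ok <- FALSE
    }
    keep[i] <- ok
  }
  blocks[keep, , drop = FALSE]
}

# single-member zip built with Python's zipfile module (no zip binary in
# the test image; the package only ever reads zip)
make_zip <- function(zip_path, src_path, member = basename(src_path)) {
  code <- "import zipfile,sys; zipfile.ZipFile(sys.argv[1],'w').write(sys.argv[2], arcname=sys.argv[3])"
  status <- system2("python", c("-c", shQuote(code), shQuote(zip_path),
                                shQuote(src_path), shQuote(member)))
  stopifnot(status == 0)
  zip_path
}

expect_blocks_equal <- function(a, b) {
  attr(a, "source_lines") <- NULL
  attr(b, "source_lines") <- NULL
  rownames(a) <- NULL
  rownames(b) <- NULL
  expect_equal(a, b)
}
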