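# Seeded synthetic-data generator.  A hidden "true chain" (a random
# permutation of the genomes) provides ground truth for order-recovery
# tests: chain_strength controls the fraction of blocks placed between
# consecutive genomes of that chain, the remainder join uniformly random
# genome pairs.

#' Specification for a synthetic synteny dataset
#'
#' @param n_genomes Number of genomes (>= 1), named `Gen01`, `Gen02`, ...
#' @param genome_length Genome length in bp.
#' @param n_blocks Number of conserved region pairs.
#' @param chain_strength Fraction in `[0, 1]` of blocks placed between
#'   consecutive genomes of the hidden true chain.
#' @param extra_columns Named list of attribute column generators, each
#'   `list(dist = "uniform", min =, max =)` or
#'   `list(dist = "lognormal", meanlog =, sdlog =)`.
#' @param annotation_density Annotation features generated per genome.
#' @param seed Integer seed; the same spec always yields the same data.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genomes = 5, genome_length = 1e6, n_blocks = 40,
                         chain_strength = 0.5,
                         extra_columns = list(
                           pident = list(dist = "uniform", min = 50,
                                         max = 100),
                           score = list(dist = "lognormal",
                                        meanlog = log(1000), sdlog = 1)),
                         annotation_density = 3, seed = 1) {
  stopifnot(n_genomes >= 1, genome_length >= 1000, n_blocks >= 1,
            chain_strength >= 0, chain_strength <= 1,
            annotation_density >= 0)
  structure(list(n_genomes = n_genomes, genome_length = genome_length,
                 n_blocks = n_blocks, chain_strength = chain_strength,
                 extra_columns = extra_columns,
                 annotation_density = annotation_density,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_column <- function(spec, n) {
  if (identical(spec$dist, "uniform"))
    return(round(stats::runif(n, spec$min, spec$max), 2))
  if (identical(spec$dist, "lognormal"))
    return(round(stats::rlnorm(n, spec$meanlog, spec$sdlog), 2))
  stop("unknown column distribution '", spec$dist,
       "' (use uniform or lognormal)", call. = FALSE)
}

#' Generate a synthetic synteny dataset
#'
#' Block spans are lognormal (median 5 kb, sdlog 1), exercising both tiny
#' and long regions; starts are uniform within the genome.  With
#' `chain_strength = 1` every association lies on a consecutive pair of
#' the hidden chain, so the chain is recoverable from the weight graph.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `dataset` (a `synteny_dataset`), `true_order`
#'   (hidden chain, character) and `spec`.
#' @examples
#' fx <- generate_dataset(fixture_spec(n_genomes = 4, n_blocks = 20,
#'                                     seed = 7))
#' fx$dataset
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    genomes <- sprintf("Gen%02d", seq_len(spec$n_genomes))
    true_order <- sample(genomes)
    n <- spec$n_blocks
    n_chain <- if (spec$n_genomes >= 2) round(spec$chain_strength * n) else 0
    pair_a <- character(n); pair_b <- character(n)
    if (n_chain > 0) {
      k <- sample.int(spec$n_genomes - 1, n_chain, replace = TRUE)
      pair_a[seq_len(n_chain)] <- true_order[k]
      pair_b[seq_len(n_chain)] <- true_order[k + 1]
    }
    n_rand <- n - n_chain
    if (n_rand > 0) {
      idx <- n_chain + seq_len(n_rand)
      if (spec$n_genomes >= 2) {
        i <- sample.int(spec$n_genomes, n_rand, replace = TRUE)
        j <- sample.int(spec$n_genomes - 1, n_rand, replace = TRUE)
        j <- ifelse(j >= i, j + 1, j)
        pair_a[idx] <- genomes[i]
        pair_b[idx] <- genomes[j]
      } else {
        pair_a[idx] <- genomes[1]
        pair_b[idx] <- genomes[1]
      }
    }
    span_of <- function(n) pmin(pmax(round(stats::rlnorm(n, log(5000), 1)),
                                     1), spec$genome_length)
    sp_a <- span_of(n); sp_b <- span_of(n)
    st_a <- floor(stats::runif(n, 1, spec$genome_length - sp_a + 1))
    st_b <- floor(stats::runif(n, 1, spec$genome_length - sp_b + 1))
    extras <- lapply(spec$extra_columns, sample_column, n = n)
    blocks <- do.call(synteny_blocks,
                      c(list(pair_a, st_a, st_a + sp_a - 1,
                             pair_b, st_b, st_b + sp_b - 1), extras))
    n_feat <- spec$annotation_density * spec$n_genomes
    features <- NULL
    if (n_feat > 0) {
      fg <- rep(genomes, each = spec$annotation_density)
      fs <- floor(stats::runif(n_feat, 1, max(2, spec$genome_length - 2000)))
      fl <- floor(stats::runif(n_feat, 200, 2000))
      fl <- pmin(fl, spec$genome_length - fs + 1)
      link <- ifelse(seq_len(n_feat) %% 4 == 0,
                     paste0("https://example.org/feat",
                            seq_len(n_feat)), NA_character_)
      features <- annotation_features(
        fg, fs, fs + fl - 1,
        sample(c("+", "-"), n_feat, replace = TRUE),
        sprintf("feat%03d", seq_len(n_feat)), "gene",
        sample(c("arrow", "box"), n_feat, replace = TRUE),
        sample(c("#cc4444", "#44aa44", "#4444cc"), n_feat, replace = TRUE),
        link)
    }
    lengths <- stats::setNames(rep(spec$genome_length, spec$n_genomes),
                               genomes)
    list(dataset = synteny_dataset(blocks, features, lengths),
         true_order = true_order, spec = spec)
  })
}

#' Write fixture files to a directory
#'
#' Emits the synteny and annotation files both plain and gzip-compressed
#' (four files), suitable as end-to-end command-line test inputs.
#'
#' @param dataset A `synteny_dataset`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the four paths, invisibly.
#' @export
write_fixture_files <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synteny_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("synteny.tsv", "synteny.tsv.gz",
                            "annotation.tsv", "annotation.tsv.gz"))
  write_synteny(dataset$blocks, paths[1])
  con <- gzfile(paths[2], "wb")
  writeLines(readLines(paths[1]), con)
  close(con)
  write_annotation(dataset$features, paths[3])
  con <- gzfile(paths[4], "wb")
  writeLines(readLines(paths[3]), con)
  close(con)
  invisible(paths)
}
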