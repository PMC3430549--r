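test_that("BLAST tabular rows convert with strand normalization", {
  row <- "q1\ts1\t98.0\t50\t1\t0\t1\t50\t200\t151\t1e-20\t95.0"
  b <- blast_to_synteny(textConnection(row))
  expect_equal(b$org1, "q1")
  expect_equal(c(b$org1_start, b$org1_end), c(1, 50))
  # minus-strand hit: subject coordinates normalized to start <= end
  expect_equal(c(b$org2_start, b$org2_end), c(151, 200))
  expect_equal(b$strand, "-")
  expect_equal(b$pident, 98)
  expect_equal(b$align_length, 50)
  expect_equal(b$evalue, 1e-20)
  expect_equal(b$bitscore, 95)
  expect_equal(names(b)[7:11],
               c("pident", "align_length", "evalue", "bitscore", "strand"))

  plus <- "q1\ts1\t90.0\t40\t4\t0\t11\t50\t101\t140\t1e-5\t60.1"
  expect_equal(blast_to_synteny(textConnection(plus))$strand, "+")

  expect_error(blast_to_synteny(textConnection("q1\ts1\t98.0")),
               "line 1.*12")
})

test_that("fuzzed BLAST rows convert 1:1 and satisfy block invariants", {
  set.seed(42)
  n <- 100
  qs <- sample.int(1e5, n)
  qe <- qs + sample.int(2000, n)
  ss <- sample.int(1e5, n)
  se <- ss + sample(c(-1, 1), n, replace = TRUE) * sample.int(2000, n)
  se <- pmax(se, 1)
  rows <- sprintf("q%d\ts%d\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.0e\t%.1f",
                  sample.int(5, n, replace = TRUE),
                  sample.int(5, n, replace = TRUE),
                  runif(n, 60, 100), qe - qs + 1,
                  sample.int(50, n, replace = TRUE),
                  sample.int(5, n, replace = TRUE),
                  qs, qe, ss, se, 10^-sample.int(50, n, replace = TRUE),
                  runif(n, 40, 900))
  b <- blast_to_synteny(textConnection(rows))
  expect_equal(nrow(b), n)
  expect_true(all(b$org1_start <= b$org1_end))
  expect_true(all(b$org2_start <= b$org2_end))
  expect_true(all(b$org1_start >= 1 & b$org2_start >= 1))
  # converter output always passes dataset validation
  expect_s3_class(synteny_dataset(b), "synteny_dataset")
})

test_that("axt records convert one block per record", {
  axt <- c("0 chrT 1 100 chrQ 11 110 + 5000", "ACGT", "ACGT")
  b <- axt_to_synteny(textConnection(axt))
  expect_equal(nrow(b), 1)
  expect_equal(b$org1, "chrT")
  expect_equal(c(b$org1_start, b$org1_end), c(1, 100))
  expect_equal(c(b$org2_start, b$org2_end), c(11, 110))
  expect_equal(b$score, 5000)
  expect_equal(b$strand, "+")

  expect_equal(nrow(axt_to_synteny(textConnection(character()))), 0)

  # minus strand: coordinates converted only when a query length is known
  axt_m <- c("0 chrT 1 100 chrQ 11 110 - 400", "ACGT", "ACGT")
  kept <- axt_to_synteny(textConnection(axt_m))
  expect_equal(c(kept$org2_start, kept$org2_end), c(11, 110))
  conv <- axt_to_synteny(textConnection(axt_m), query_lengths = c(chrQ = 1000))
  expect_equal(c(conv$org2_start, conv$org2_end), c(891, 990))
  expect_equal(conv$strand, "-")

  # record indices in errors follow axt's zero-based numbering
  expect_error(axt_to_synteny(textConnection(
    c("0 chrT 1 100 chrQ 11 110 +", "A", "A"))), "record 0")
})

test_that("synthetic axt streams preserve record count and invariants", {
  set.seed(9)
  n <- 20
  ts <- sample.int(1e5, n)
  qs <- sample.int(1e5, n)
  lines <- as.vector(rbind(
    sprintf("%d chr%d %d %d q%d %d %d %s %d", seq_len(n) - 1,
            sample.int(3, n, replace = TRUE), ts, ts + sample.int(500, n),
            sample.int(3, n, replace = TRUE), qs, qs + sample.int(500, n),
            sample(c("+", "-"), n, replace = TRUE),
            sample.int(9999, n)),
    "ACGTACGT", "ACGTACGT"))
  b <- axt_to_synteny(textConnection(lines))
  expect_equal(nrow(b), n)
  expect_s3_class(synteny_dataset(b), "synteny_dataset")
})

test_that("GFF3 features map onto annotation columns", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t10\t40\t.\t+\t.\tID=g1;Name=abc",
           "chr1\tsrc\tgene\t50\t60\t.\t.\t.\tscore=5",
           "chr2\tsrc\tmRNA\t5\t25\t.\t-\t.\tID=m1",
           "##FASTA", ">chr1", "ACGT")
  f <- gff3_to_annotation(textConnection(gff))
  expect_equal(nrow(f), 3)
  expect_equal(f$feature, c("abc", "gene:50-60", "m1"))
  expect_equal(f$track, c("gene", "gene", "mRNA"))
  expect_equal(f$shape, c("arrow", "box", "arrow"))
  expect_equal(f$strand, c("+", ".", "-"))
  expect_equal(f$org, c("chr1", "chr1", "chr2"))

  only_genes <- gff3_to_annotation(textConnection(gff),
                                   type_filter = "gene")
  expect_equal(unique(only_genes$track), "gene")
  boxes <- gff3_to_annotation(textConnection(gff), default_shape = "box",
                              default_color = "#112233")
  expect_equal(unique(boxes$shape), "box")
  expect_equal(unique(boxes$color), "#112233")

  expect_error(gff3_to_annotation(textConnection("chr1\tsrc\tgene\t10")),
               "9")
  expect_error(gff3_to_annotation(textConnection(
    "chr1\tsrc\tgene\t40\t10\t.\t+\t.\tID=x")), "end < start")
  expect_silent(invisible(write_annotation(f)))
})
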