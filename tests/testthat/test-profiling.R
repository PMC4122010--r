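aln <- function(query, identity, start, end, subject = "ref") {
  data.frame(query = query, subject = subject, identity = identity,
             length = end - start + 1, start = start, end = end,
             bitscore = 2 * (end - start + 1), stringsAsFactors = FALSE)
}

test_that("alignment filtering applies identity and uniqueness rules", {
  recs <- rbind(aln("r1", 98.0, 1, 100),      # below identity
                aln("r2", 99.5, 1, 100),      # unique, kept
                aln("r3", 99.5, 1, 100),      # multi-mapper (two hits)
                aln("r3", 99.6, 201, 300),
                aln("r4", 99.0, 501, 600))    # boundary identity, kept
  f <- filter_alignments(recs, min_identity = 99, unique_only = TRUE)
  expect_setequal(f$query, c("r2", "r4"))
  # without the uniqueness rule, multi-mappers are retained
  f2 <- filter_alignments(recs, min_identity = 99, unique_only = FALSE)
  expect_setequal(unique(f2$query), c("r2", "r3", "r4"))
  # ties by bitscore are not rescued: both hits pass identity, query dropped
  expect_false("r3" %in% f$query)
})

test_that("depth and breadth arithmetic matches interval-union definitions", {
  # 100 disjoint 100-bp alignments on 1000 bp: depth 10, breadth 1
  starts <- rep(seq(1, 901, by = 100), 10)
  recs <- aln(paste0("r", seq_along(starts)), 99.5, starts, starts + 99)
  gc <- genome_coverage(recs, 1000)
  expect_equal(gc$depth, 10)
  expect_equal(gc$breadth, 1.0)

  gc2 <- genome_coverage(aln("r1", 99.5, 1, 100), 1000)
  expect_equal(gc2$depth, 0.1)
  expect_equal(gc2$breadth, 0.1)

  # two fully overlapping alignments: depth counts both, breadth does not
  gc3 <- genome_coverage(rbind(aln("r1", 99.5, 101, 200),
                               aln("r2", 99.5, 101, 200)), 1000)
  expect_equal(gc3$depth, 0.2)
  expect_equal(gc3$breadth, 0.1)

  expect_error(genome_coverage(aln("r1", 99, 900, 1100), 1000), "outside")
  expect_equal(genome_coverage(recs[0, ], 1000), list(depth = 0, breadth = 0))
})

test_that("breadth never exceeds depth without overlaps, nor 1 overall", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(1:50, 1)
    starts <- sample.int(900, n)
    recs <- aln(paste0("r", 1:n), 99.5, starts, starts + sample(10:99, n, TRUE))
    gc <- genome_coverage(recs, 1000)
    expect_lte(gc$breadth, 1)
    expect_lte(gc$breadth, gc$depth + 1e-12)
  }
})

test_that("strain calls use an inclusive depth threshold", {
  cov <- data.frame(strain = c("a", "b", "c"),
                    depth = c(10.0, 9.99, 25),
                    breadth = c(0.9, 0.9, 1.0))
  calls <- call_strains(cov, depth_threshold = 10)
  expect_equal(calls$present, c(TRUE, FALSE, TRUE))
  expect_error(call_strains(cov, depth_threshold = 0), "> 0")
})

test_that("cohort aggregation recovers planted prevalences", {
  coh <- planted_cohort(
    n_samples = 10,
    strains = data.frame(strain = c("always", "often", "some"),
                         prevalence = c(1.0, 0.8, 0.6),
                         depth = c(20, 15, 12),
                         identity = c(99.5, 99.5, 99.5)),
    seed = 21)
  ma <- make_alignments(coh, genome_length = 20000)
  cov <- coverage_table(ma$alignments, ma$genome_length, min_identity = 99)
  calls <- call_strains(cov, depth_threshold = 10)
  prev <- attr(calls, "prevalence")
  expect_equal(prev$prevalence[match(c("always", "often", "some"), prev$strain)],
               c(1.0, 0.8, 0.6))
  # sorted by descending prevalence
  expect_equal(prev$strain, c("always", "often", "some"))
})

test_that("gene coverage enforces the single-scaffold 80% rule inclusively", {
  genes <- data.frame(gene = c("g1", "g2", "g3"),
                      start = c(100, 1000, 2000),
                      end = c(199, 1099, 2099))
  recs <- rbind(
    aln("s1", 99.9, 100, 179),    # g1: exactly 80 of 100 bp -> covered
    aln("s2", 99.9, 1000, 1049),  # g2: 50% + 50% from two scaffolds
    aln("s3", 99.9, 1050, 1099),
    aln("s4", 99.9, 1900, 2300))  # g3: fully spanned
  cov <- gene_coverage_from_scaffolds(recs, genes)
  expect_equal(cov$fraction, c(0.8, 0.5, 1.0))
  expect_equal(cov$covered, c(TRUE, FALSE, TRUE))

  expect_error(gene_coverage_from_scaffolds(recs,
    data.frame(gene = "bad", start = 10, end = 9)), "length")
})

test_that("enrichment p-values match the frozen worked examples", {
  # [[8,2],[2,8]]: one-sided hypergeometric tail = 0.011517...
  r <- enrichment_test(8, 10, 10, 20)
  expect_equal(r$p_value, oracle_hyper_tail(8, 10, 20, 10), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0115, tolerance = 1e-3)
  # [[10,0],[0,10]]: single term 1 / C(20,10)
  r2 <- enrichment_test(10, 10, 10, 20)
  expect_equal(r2$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r2$p_value, 5.41e-6, tolerance = 1e-3)
  # equal proportions: no enrichment signal
  r3 <- enrichment_test(5, 10, 10, 20)
  expect_gte(r3$p_value, 0.5)
  expect_error(enrichment_test(11, 10, 10, 20), "inconsistent")
})

test_that("log-space reporting survives astronomically small p-values", {
  r <- enrichment_test(500, 500, 500, 5000)
  expect_equal(r$p_value, 0)          # underflows double precision
  expect_lt(r$log10_p, -300)          # but the log survives
  expect_true(is.finite(r$log10_p))
})

test_that("SAM alignments read through Rsamtools when available", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:ref\tLN:10000",
    "r1\t0\tref\t101\t60\t100M\t*\t0\t0\t*\t*\tNM:i:1",
    "r2\t0\tref\t501\t60\t50M10D50M\t*\t0\t0\t*\t*\tNM:i:10",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  recs <- read_alignments(sam, format = "sam")
  expect_equal(nrow(recs), 2)   # unmapped r3 excluded
  expect_equal(recs$start[recs$query == "r1"], 101)
  expect_equal(recs$end[recs$query == "r1"], 200)
  expect_equal(recs$identity[recs$query == "r1"], 99)
  expect_equal(recs$length[recs$query == "r2"], 110)  # reference space
})

test_that("BLAST outfmt-6 parsing normalizes coordinates and checks shape", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c(
    "read1\tref\t99.5\t100\t0\t0\t1\t100\t201\t300\t1e-50\t190",
    "read2\tref\t99.0\t100\t1\t0\t1\t100\t800\t701\t1e-48\t185"), p)
  recs <- read_alignments(p)
  expect_equal(recs$start, c(201, 701))  # minus-strand hit normalized
  expect_equal(recs$end, c(300, 800))
  p2 <- tempfile(fileext = ".tsv")
  writeLines("read1\tref\t99.5", p2)
  expect_error(read_alignments(p2), "12")
})
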