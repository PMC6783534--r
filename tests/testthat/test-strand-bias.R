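test_that("C[N>N]T context selection keeps exactly the C..T envelope", {
  # contig with known trinucleotides at fixed positions
  ref <- toy_reference("ACTGCTTAGCATTCCTAAGTCGAA")
  #                     123456789012345678901234
  v <- data.frame(
    chrom = "1",
    pos = c(2, 6, 11, 15, 18, 21),
    ref = c("C", "T", "A", "C", "A", "C"),
    alt = c("A", "G", "C", "T", "T", "G"),
    sample_id = "s"
  )
  kept <- select_cnt_context(v, ref)
  # pos 2  ACT -> A[C>A]T: no (5' is A)
  # pos 6  CTT -> C[T>G]T: yes
  # pos 11 CAT -> revcomp ATG -> A[T>G]G: no
  # pos 15 CCT -> C[C>T]T: yes
  # pos 18 AAG -> revcomp CTT -> C[T>A]T: yes
  # pos 21 TCG -> T[C>G]G: no
  expect_identical(kept$pos, c(6, 15, 18))
  expect_identical(kept$type96, c("C[T>G]T", "C[C>T]T", "C[T>A]T"))
})

test_that("high-contribution filter applies strict thresholds", {
  expect_true(high_contribution_filter(2001, 0.26))
  expect_false(high_contribution_filter(2000, 0.30))
  expect_false(high_contribution_filter(2500, 0.25))
  expect_true(high_contribution_filter(1e5, 0.9))
})

test_that("replication strand assignment follows the pyrimidine base", {
  regions <- data.frame(
    chrom = "1", start = c(1, 101), end = c(100, 200),
    strand_label = c("lagging", "leading")
  )
  v <- data.frame(
    chrom = "1", pos = c(50, 150, 250, 60),
    ref = c("T", "T", "T", "A"),  # pyrimidine on plus except the A
    alt = c("G", "G", "G", "C"),
    sample_id = "s"
  )
  asg <- assign_replication_strand(v, regions)
  # pyrimidine-plus in plus-lagging region -> lagging
  expect_identical(asg, c("lagging", "leading", "unassigned", "leading"))

  # flipping the annotation labels flips every assignment
  flipped <- regions
  flipped$strand_label <- c("leading", "lagging")
  asg2 <- assign_replication_strand(v, flipped)
  expect_identical(asg2, c("leading", "lagging", "unassigned", "lagging"))

  # contradictory overlapping regions are an annotation error
  bad <- rbind(regions,
               data.frame(chrom = "1", start = 40, end = 70,
                          strand_label = "leading"))
  expect_error(assign_replication_strand(v, bad), "contradictory")
})

test_that("transcription strand assignment uses the template-strand rule", {
  genes <- data.frame(
    chrom = "1", start = c(1, 101, 201, 230), end = c(100, 200, 260, 260),
    strand = c("+", "-", "+", "-")
  )
  # pyrimidine ref (pyr on plus): inside + gene -> coding strand
  # -> untranscribed; inside - gene template is +, so -> transcribed
  v <- data.frame(
    chrom = "1", pos = c(50, 150, 50, 150, 300, 240),
    ref = c("C", "C", "G", "G", "C", "C"),
    alt = c("T", "T", "A", "A", "T", "T"),
    sample_id = "s"
  )
  asg <- assign_transcription_strand(v, genes)
  expect_identical(asg, c(
    "untranscribed",  # pyr+, gene + (coding strand)
    "transcribed",    # pyr+, gene - (template of - gene is +)
    "transcribed",    # pyr-, gene +
    "untranscribed",  # pyr-, gene -
    "unassigned",     # intergenic
    "unassigned"      # overlap of opposite-strand genes
  ))
})

test_that("asymmetry test equals binomial-tail enumeration for all
           totals up to 200", {
  # independent oracle: enumerate the binomial tail mass by summing
  # choose(N, k) / 2^N terms directly
  enum_p <- function(n1, n2) {
    N <- n1 + n2
    mass <- choose(N, 0:N) / 2^N
    lower <- sum(mass[seq_len(n1 + 1)])
    upper <- sum(mass[(n1 + 1):(N + 1)])
    min(1, 2 * min(lower, upper))
  }
  for (N in c(1:30, seq(35, 200, by = 5))) {
    n1 <- unique(c(0L, 1L, N %/% 4L, N %/% 2L, N - 1L, N))
    for (k in n1) {
      expect_equal(poisson_asymmetry_test(k, N - k), enum_p(k, N - k),
                   tolerance = 1e-12)
    }
  }
  expect_equal(poisson_asymmetry_test(5, 5), 1)
  expect_equal(poisson_asymmetry_test(15, 3), 0.00754, tolerance = 1e-3)
  expect_equal(poisson_asymmetry_test(3, 15),
               poisson_asymmetry_test(15, 3))
  expect_error(poisson_asymmetry_test(0, 0), "zero")
})

test_that("strand count matrix conserves assigned variants and tests
           per class", {
  v <- data.frame(
    type96 = c("C[T>G]T", "C[T>G]T", "C[T>G]T", "C[C>T]T", "C[T>A]T"),
    stringsAsFactors = FALSE
  )
  asg <- c("lagging", "lagging", "leading", "unassigned", "lagging")
  res <- strand_count_matrix(v, asg)
  expect_identical(sum(res$counts), 4L)  # one unassigned excluded
  expect_identical(res$counts["T>G", "lagging"], 2L)
  expect_identical(res$counts["T>G", "leading"], 1L)
  expect_identical(res$counts["T>A", "lagging"], 1L)
  expect_true(is.na(res$tests$p.value[res$tests$substitution == "C>A"]))

  # all unassigned: zero matrix, no tests
  res0 <- strand_count_matrix(v, rep("unassigned", 5))
  expect_identical(sum(res0$counts), 0L)
  expect_true(all(is.na(res0$tests$p.value)))
})

test_that("planted lagging enrichment is detected via the full path", {
  det <- vapply(1:20, function(s) {
    v <- data.frame(
      chrom = "1", pos = seq(10, by = 20, length.out = 400),
      ref = "T", alt = "G", sample_id = "s",
      type96 = "C[T>G]T", stringsAsFactors = FALSE
    )
    ann <- simulate_strand_annotations(v, enrichment_ratio = 3,
                                       classes = "C[T>G]T", seed = s)
    asg <- assign_replication_strand(v, ann$regions)
    # region construction reproduces the drawn truth exactly
    expect_identical(asg, ann$truth)
    res <- strand_count_matrix(v, asg)
    row <- res$tests[res$tests$substitution == "T>G", ]
    row$lagging > row$leading && row$p.value < 0.05
  }, logical(1))
  expect_gte(mean(det), 0.9)

  # ratio 1 gives balanced assignment on average
  v <- data.frame(
    chrom = "1", pos = seq(10, by = 20, length.out = 2000),
    ref = "T", alt = "G", sample_id = "s",
    type96 = "C[T>G]T", stringsAsFactors = FALSE
  )
  ann <- simulate_strand_annotations(v, enrichment_ratio = 1, seed = 4)
  expect_lt(abs(mean(ann$truth == "lagging") - 0.5), 0.05)
})

test_that("BED ingest converts to 1-based inclusive coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tlagging", "chr1\t100\t200\tleading"), bed)
  reg <- read_strand_bed(bed, mode = "replication")
  expect_identical(reg$start, c(1L, 101L))
  expect_identical(reg$end, c(100L, 200L))
  expect_identical(reg$strand_label, c("lagging", "leading"))

  genes <- tempfile(fileext = ".bed")
  writeLines(c("1\t0\t100\tgeneA\t0\t+", "1\t150\t300\tgeneB\t0\t-"),
             genes)
  g <- read_strand_bed(genes, mode = "transcription")
  expect_identical(g$strand, c("+", "-"))
  expect_identical(g$start, c(1L, 151L))

  bad <- tempfile(fileext = ".bed")
  writeLines("1\t0\t10\tforward", bad)
  expect_error(read_strand_bed(bad, mode = "replication"),
               "leading|lagging")
})
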