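test_that("variant ploidy is the adjusted-VAF x copy-number product", {
  expect_identical(variant_ploidy(0.5, 2), 1)
  expect_identical(variant_ploidy(0, 7), 0)
  expect_identical(variant_ploidy(0.2, 2), 0.4)
  expect_error(variant_ploidy(1.2, 2), "\\[0, 1\\]")
  expect_error(variant_ploidy(0.5, -1), "non-negative")
})

test_that("peak detection finds the planted subclonal mode", {
  sim <- simulate_clonality(2000, clonal_frac = 0.7,
                            subclonal_ploidy = 0.4, sd = 0.05, seed = 5)
  pk <- detect_subclonal_peaks(sim$ploidy)
  expect_length(pk$subclonal_peaks, 1L)
  expect_lt(abs(pk$subclonal_peaks - 0.4), 0.05)
  expect_lt(abs(pk$main_peak - 1), 0.05)
  expect_identical(pk$peaks, sort(pk$peaks))
})

test_that("unimodal samples yield no subclonal peak; small samples skip
           the search", {
  uni <- simulate_clonality(1000, clonal_frac = 1, seed = 6)
  pk <- detect_subclonal_peaks(uni$ploidy)
  expect_length(pk$subclonal_peaks, 0L)

  few <- c(rep(1, 50), 0.4, 0.41, 0.39, 0.4, 0.42)  # only 5 below 1
  expect_warning(pk2 <- detect_subclonal_peaks(few), "fewer than 10")
  expect_length(pk2$subclonal_peaks, 0L)
  expect_error(detect_subclonal_peaks(numeric(0)), "no ploidy")
})

test_that("classification follows the >1 rule and nearest-peak
           assignment", {
  sim <- simulate_clonality(2000, 0.7, 0.4, 0.05, seed = 5)
  pk <- detect_subclonal_peaks(sim$ploidy)
  lab <- classify_clonality(c(1.2, 0.41, 0.95, NA), pk)
  expect_identical(lab, c("clonal", "subclonal", "clonal", "unassigned"))

  # planted truth recovered for nearly all variants
  full <- classify_clonality(sim$ploidy, pk)
  expect_gt(mean(full == sim$truth), 0.98)
  # partition is exhaustive over non-NA input
  expect_true(all(full %in% c("clonal", "subclonal")))

  # no subclonal peaks: everything at or below 1 is clonal
  pk0 <- suppressWarnings(detect_subclonal_peaks(rep(1, 100)))
  expect_identical(classify_clonality(c(0.2, 1.5), pk0),
                   c("clonal", "clonal"))
})

test_that("classification is monotone and order-invariant", {
  sim <- simulate_clonality(2000, 0.7, 0.4, 0.05, seed = 7)
  pk <- detect_subclonal_peaks(sim$ploidy)
  grid <- seq(0, 2, by = 0.05)
  lab <- classify_clonality(grid, pk)
  # raising ploidy never flips clonal -> subclonal
  first_clonal <- min(which(lab == "clonal"))
  expect_true(all(lab[first_clonal:length(lab)] == "clonal"))
  # input order does not matter
  perm <- sample(seq_along(grid))
  expect_identical(classify_clonality(grid[perm], pk), lab[perm])
})

test_that("eligibility needs 500 subclonal mutations and 5% contribution", {
  expect_false(subclonal_eligibility(499, 0.10))
  expect_true(subclonal_eligibility(500, 0.05))
  expect_false(subclonal_eligibility(600, 0.04))
  expect_true(subclonal_eligibility(10000, 0.9))
})

test_that("clonal/subclonal contrast recovers a planted enrichment", {
  sigs <- planted_signature_trio()
  set.seed(31)
  # one sample: clonal mutations have 10% focal signature, subclonal 30%
  n_clonal <- 2500; n_sub <- 900
  draw_types <- function(n, w) {
    p <- drop(sigs %*% w)
    sample(mut_types_96(), n, replace = TRUE, prob = p)
  }
  types <- c(draw_types(n_clonal, c(0.10, 0.60, 0.30)),
             draw_types(n_sub, c(0.30, 0.47, 0.23)))
  catalog <- matrix(0L, 96, 1, dimnames = list(mut_types_96(), "s1"))
  tab <- table(factor(types, levels = mut_types_96()))
  catalog[, 1] <- as.integer(tab)
  out <- emit_reference_and_vcf(catalog, tempfile(), seed = 32, pad = 1)
  v <- read_vcf(out$vcf)
  # re-align emitted variants with the intended compartment by class:
  # clonal variants sit in the clonal ploidy mode, subclonal in the 0.4
  # mode; assignment by planted proportion per class
  cls <- classify_sbs(v$ref, v$alt,
                      extract_context(out$fasta, v$chrom, v$pos, 1))
  v$adjusted_vaf <- NA_real_
  v$copy_number <- 2
  set.seed(33)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    n_cl_sub <- sum(types[seq_len(n_clonal)] == cl)
    stopifnot(length(idx) == sum(types == cl))
    clonal_idx <- idx[seq_len(n_cl_sub)]
    sub_idx <- setdiff(idx, clonal_idx)
    v$adjusted_vaf[clonal_idx] <- pmin(
      pmax(rnorm(length(clonal_idx), 0.5, 0.025), 0), 1)
    v$adjusted_vaf[sub_idx] <- pmin(
      pmax(rnorm(length(sub_idx), 0.2, 0.025), 0), 1)
  }
  res <- clonal_subclonal_contrast(v, out$fasta, sigs, "sig17like")
  row <- res$per_sample[1, ]
  expect_true(row$eligible)
  expect_gt(row$subclonal_contribution, row$clonal_contribution)
  expect_true(row$ratio > 2 && row$ratio < 4.5)
})

test_that("identical compartment spectra give a ratio near 1", {
  sigs <- planted_signature_trio()
  E <- matrix(c(600, 300, 100), 3, 1,
              dimnames = list(colnames(sigs), "s1"))
  catalog <- sample_catalog(sigs, E, seed = 44)
  out <- emit_reference_and_vcf(catalog, tempfile(), seed = 45, pad = 1)
  v <- read_vcf(out$vcf)
  set.seed(46)
  # random half subclonal, independent of mutation class
  subclonal <- sample(c(TRUE, FALSE), nrow(v), replace = TRUE)
  v$copy_number <- 2
  v$adjusted_vaf <- ifelse(subclonal,
                           pmax(rnorm(nrow(v), 0.2, 0.02), 0.05),
                           pmin(rnorm(nrow(v), 0.5, 0.02), 0.6))
  res <- clonal_subclonal_contrast(v, out$fasta, sigs, "sig17like")
  expect_equal(res$per_sample$ratio[1], 1, tolerance = 0.35)
})
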