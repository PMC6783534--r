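#' Synthetic signature set with a signature-17-like profile
#'
#' Builds a small column-stochastic signature matrix for simulation and
#' testing. The `sig17like` profile places 36% of its mass on C[T>G]T
#' (the hallmark class of the fluoropyrimidine-associated process), 14%
#' on C[T>C]T and 10% on G[T>G]T, with the remaining 40% spread
#' uniformly over the other classes. A flat profile and seeded random
#' (Dirichlet) profiles complete the set.
#'
#' @param n_random number of additional random signatures (default 1).
#' @param seed RNG seed for the random profiles.
#' @return 96 x (2 + n_random) column-stochastic matrix with columns
#'   `sig17like`, `flat`, `random1`, ...
#' @export
make_signature_set <- function(n_random = 1L, seed = 1L) {
  types <- mut_types_96()
  anchor <- c("C[T>G]T" = 0.36, "C[T>C]T" = 0.14, "G[T>G]T" = 0.10)
  sig17 <- stats::setNames(rep(0, 96L), types)
  sig17[names(anchor)] <- anchor
  rest <- setdiff(types, names(anchor))
  sig17[rest] <- (1 - sum(anchor)) / length(rest)
  flat <- rep(1 / 96, 96L)
  out <- cbind(sig17like = sig17, flat = flat)
  if (n_random > 0L) {
    set.seed(seed)
    rnd <- matrix(stats::rgamma(96L * n_random, shape = 1), 96L,
                  n_random)
    rnd <- sweep(rnd, 2L, colSums(rnd), "/")
    colnames(rnd) <- paste0("random", seq_len(n_random))
    out <- cbind(out, rnd)
  }
  rownames(out) <- types
  out
}

#' Sample a mutation catalog from known signature mixtures
#'
#' Each sample's counts are drawn from a multinomial with probabilities
#' equal to its normalized signature mixture and total equal to its
#' (rounded) exposure sum, so the planted exposures are the ground truth
#' for refitting tests.
#'
#' @param signatures 96 x K column-stochastic matrix.
#' @param exposures K x S non-negative matrix of absolute contributions.
#' @param seed RNG seed.
#' @return 96 x S integer catalog (canonical row order).
#' @export
sample_catalog <- function(signatures, exposures, seed = 1L) {
  if (any(exposures < 0)) stop("exposures must be non-negative")
  set.seed(seed)
  S <- ncol(exposures)
  counts <- matrix(0L, 96L, S,
                   dimnames = list(rownames(signatures),
                                   colnames(exposures)))
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(S))
  }
  for (j in seq_len(S)) {
    total <- round(sum(exposures[, j]))
    if (total == 0) next
    mix <- drop(signatures %*% exposures[, j])
    counts[, j] <- as.integer(stats::rmultinom(1L, total,
                                               mix / sum(mix)))
  }
  counts
}

pad_block <- function(k, pad_probs, n) {
  matrix(sample(BASES, k * n, replace = TRUE, prob = pad_probs), n, k)
}

#' Emit a toy reference FASTA and VCF realizing a catalog
#'
#' Constructs a synthetic autosomal contig of concatenated blocks, one
#' per mutation, where each block carries the pyrimidine-centered
#' trinucleotide of the mutation's class flanked by `pad` random bases on
#' each side. The emitted VCF (one genotype column per catalog sample)
#' reproduces the catalog exactly when re-read with [read_vcf()] and
#' [build_catalog()].
#'
#' @param catalog 96 x S count matrix (canonical row order).
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed for the pad bases.
#' @param pad pad width on each side of every trinucleotide (default 5,
#'   so eleven-base contexts are extractable).
#' @param pad_probs sampling weights for pad bases over A/C/G/T (default
#'   uniform); an A/T-heavy choice plants flanking-base enrichment for
#'   extended-context tests.
#' @param chrom contig name (default `"1"`).
#' @return list with `fasta`, `vcf` (paths) and `variants` (the emitted
#'   variant table).
#' @export
emit_reference_and_vcf <- function(catalog, out_dir, seed = 1L,
                                   pad = 5L, pad_probs = rep(0.25, 4L),
                                   chrom = "1") {
  stopifnot(identical(rownames(catalog), mut_types_96()))
  if (any(catalog < 0)) stop("catalog must be non-negative")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  per_type <- rowSums(catalog)
  # one block per needed variant; samples sharing a class use distinct
  # blocks so every VCF record is a single position
  block_len <- 2L * pad + 3L
  total <- sum(catalog)
  parsed <- split_type_96(mut_types_96())
  ref_base <- substr(parsed$substitution, 1L, 1L)
  alt_base <- substr(parsed$substitution, 3L, 3L)
  tri <- paste0(parsed$five_prime, ref_base, parsed$three_prime)

  recs <- list()
  seqs <- character(0)
  offset <- 0L
  for (t in seq_len(96L)) {
    m <- per_type[t]
    if (m == 0L) next
    left <- pad_block(pad, pad_probs, m)
    right <- pad_block(pad, pad_probs, m)
    blocks <- paste0(apply(left, 1L, paste, collapse = ""), tri[t],
                     apply(right, 1L, paste, collapse = ""))
    pos <- offset + (seq_len(m) - 1L) * block_len + pad + 2L
    # distribute this class's variants over the samples owning them
    owners <- rep(colnames(catalog), catalog[t, ])
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref_base[t], alt = alt_base[t],
      sample_id = owners, stringsAsFactors = FALSE
    )
    seqs <- c(seqs, blocks)
    offset <- offset + m * block_len
  }
  contig <- paste(seqs, collapse = "")
  if (nchar(contig) == 0L) contig <- paste(rep("A", block_len), collapse = "")
  fasta <- file.path(out_dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(contig)
  names(dna) <- chrom
  Biostrings::writeXStringSet(dna, fasta)

  variants <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), sample_id = character())
  vcf <- file.path(out_dir, "variants.vcf")
  samples <- colnames(catalog)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(contig)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  body <- character(0)
  if (nrow(variants)) {
    ord <- order(variants$pos)
    variants <- variants[ord, , drop = FALSE]
    gt <- vapply(seq_len(nrow(variants)), function(i) {
      paste(ifelse(samples == variants$sample_id[i], "0/1", "0/0"),
            collapse = "\t")
    }, character(1L))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                    variants$chrom, variants$pos, variants$ref,
                    variants$alt, gt)
  }
  writeLines(c(header, body), vcf)
  list(fasta = fasta, vcf = vcf, variants = variants)
}

#' Simulate a clonal / subclonal variant-ploidy mixture
#'
#' Draws ploidy scores from a two-component normal mixture: a clonal
#' mode at 1.0 and a planted subclonal mode, both truncated at 0, with
#' truth labels for peak-recovery and classification tests.
#'
#' @param n number of variants.
#' @param clonal_frac fraction of clonal variants, in (0, 1\].
#' @param subclonal_ploidy location of the subclonal mode (default 0.4).
#' @param sd mode standard deviation (default 0.05).
#' @param seed RNG seed.
#' @return data.frame with `ploidy` and `truth`
#'   (`"clonal"`/`"subclonal"`).
#' @export
simulate_clonality <- function(n, clonal_frac = 0.7,
                               subclonal_ploidy = 0.4, sd = 0.05,
                               seed = 1L) {
  if (clonal_frac <= 0 || clonal_frac > 1) {
    stop("clonal_frac must be in (0, 1]")
  }
  set.seed(seed)
  is_clonal <- stats::runif(n) < clonal_frac
  mu <- ifelse(is_clonal, 1.0, subclonal_ploidy)
  ploidy <- pmax(stats::rnorm(n, mean = mu, sd = sd), 0)
  data.frame(ploidy = ploidy,
             truth = ifelse(is_clonal, "clonal", "subclonal"),
             stringsAsFactors = FALSE)
}

#' Simulate a paired-biopsy cohort with a planted treatment effect
#'
#' Generates two biopsies per patient: the first draws Poisson counts per
#' mutation type from a signature-mixture baseline, the second rescales
#' the baseline by a patient-level lognormal depth factor and, for
#' patients treated with the focal drug, adds Poisson extra counts on the
#' effect types. The planted mean extra count is `effect_size` baseline
#' standard deviations (`sqrt(lambda)`) of each effect type. A second
#' drug with no effect is co-administered to a subset of patients so the
#' dose and time covariates are not proxies of the focal indicator.
#'
#' @param n_patients total patients (default 20).
#' @param n_treated patients receiving the focal drug (default 8).
#' @param baseline_total expected mutations per biopsy (default 3000).
#' @param mixture mixing weights over the [make_signature_set()] columns
#'   used for the baseline spectrum.
#' @param effect_types 96-class labels receiving the planted effect.
#' @param effect_size planted effect in baseline SD units (default 3).
#' @param depth_sdlog SD of the lognormal depth factor of the second
#'   biopsy (default 0.15).
#' @param focal_drug focal drug name (default `"5-FU"`).
#' @param seed RNG seed.
#' @return list with `counts` (96 x 2 * n_patients), `design`,
#'   `treatments`, `truth` (treated patients and effect types).
#' @export
simulate_paired_cohort <- function(n_patients = 20L, n_treated = 8L,
                                   baseline_total = 3000,
                                   mixture = c(sig17like = 0.15,
                                               flat = 0.85),
                                   effect_types = "C[T>G]T",
                                   effect_size = 3,
                                   depth_sdlog = 0.15,
                                   focal_drug = "5-FU", seed = 1L) {
  stopifnot(n_treated <= n_patients, n_treated >= 3L)
  set.seed(seed)
  sigs <- make_signature_set(n_random = 0L)
  sigs <- sigs[, names(mixture), drop = FALSE]
  p <- drop(sigs %*% (mixture / sum(mixture)))
  lambda <- baseline_total * p
  types <- mut_types_96()
  patients <- paste0("P", seq_len(n_patients))
  treated <- patients[seq_len(n_treated)]
  # a co-administered inert drug, assigned independently of the focal
  # drug, so co-treatment covariates vary on their own
  other_drug_patients <- sample(patients, max(3L, round(n_patients / 2)))

  counts <- matrix(0L, 96L, 2L * n_patients,
                   dimnames = list(types, paste0(
                     rep(patients, each = 2L), "_b", rep(1:2, n_patients)
                   )))
  eff_idx <- match(effect_types, types)
  extra_mean <- effect_size * sqrt(lambda[eff_idx])
  for (i in seq_len(n_patients)) {
    depth <- stats::rlnorm(1L, 0, depth_sdlog)
    b1 <- stats::rpois(96L, lambda)
    b2 <- stats::rpois(96L, lambda * depth)
    if (patients[i] %in% treated && effect_size > 0) {
      b2[eff_idx] <- b2[eff_idx] +
        stats::rpois(length(eff_idx), extra_mean * depth)
    }
    counts[, 2L * i - 1L] <- b1
    counts[, 2L * i] <- b2
  }
  design <- data.frame(
    sample_id = colnames(counts),
    patient = rep(patients, each = 2L),
    biopsy = rep(1:2, n_patients),
    stringsAsFactors = FALSE
  )
  treatments <- rbind(
    data.frame(patient = treated, drug = focal_drug,
               dose = stats::runif(length(treated), 0.5, 2),
               exposure_time = stats::runif(length(treated), 8, 30),
               stringsAsFactors = FALSE),
    data.frame(patient = other_drug_patients, drug = "Oxaliplatin",
               dose = stats::runif(length(other_drug_patients), 0.5, 2),
               exposure_time = stats::runif(length(other_drug_patients),
                                            8, 30),
               stringsAsFactors = FALSE)
  )
  list(counts = counts, design = design, treatments = treatments,
       truth = list(treated = treated, effect_types = effect_types,
                    effect_size = effect_size))
}

#' Simulate strand annotations with planted lagging-strand enrichment
#'
#' For each variant, a replication strand is drawn with odds
#' `enrichment_ratio` of lagging over leading for the chosen classes and
#' even odds otherwise. A consistent non-overlapping region annotation
#' is constructed around each variant position so that
#' [assign_replication_strand()] reproduces the drawn truth exactly.
#'
#' @param variants variant data.frame with a `type96` column (e.g. from
#'   [select_cnt_context()]); positions must be distinct.
#' @param enrichment_ratio lagging:leading odds for enriched classes
#'   (> 0).
#' @param classes 96-class labels subject to the enrichment.
#' @param seed RNG seed.
#' @return list with `regions` (replication region table), `truth`
#'   (drawn strand per variant).
#' @export
simulate_strand_annotations <- function(variants, enrichment_ratio = 3,
                                        classes = "C[T>G]T", seed = 1L) {
  if (enrichment_ratio <= 0) stop("enrichment_ratio must be positive")
  if (any(duplicated(variants[, c("chrom", "pos")]))) {
    stop("variant positions must be distinct")
  }
  set.seed(seed)
  p_lag <- ifelse(variants$type96 %in% classes,
                  enrichment_ratio / (1 + enrichment_ratio), 0.5)
  truth <- ifelse(stats::runif(nrow(variants)) < p_lag,
                  "lagging", "leading")
  pyr_on_plus <- toupper(variants$ref) %in% PYRIMIDINES
  plus_label <- ifelse(pyr_on_plus, truth,
                       ifelse(truth == "lagging", "leading", "lagging"))
  regions <- data.frame(
    chrom = variants$chrom,
    start = variants$pos, end = variants$pos,
    strand_label = plus_label,
    stringsAsFactors = FALSE
  )
  list(regions = regions, truth = truth)
}
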