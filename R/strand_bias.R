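#' Select variants with a C[N>N]T pyrimidine-normalized context
#'
#' The focal signature's dominant classes share a C..T trinucleotide
#' envelope; restricting to C[N>N]T mutations keeps the signal classes and
#' a matched set of control substitution types.
#'
#' @param variants variant data.frame.
#' @param reference `DNAStringSet` or FASTA path.
#' @return variants whose pyrimidine-normalized trinucleotide is
#'   `C[*>*]T`, with the 96-class label added as column `type96`.
#' @export
select_cnt_context <- function(variants, reference) {
  if (nrow(variants) == 0L) {
    variants$type96 <- character(0)
    return(variants)
  }
  ctx <- extract_context(reference, variants$chrom, variants$pos, 1L)
  clean <- !grepl("[^ACGT]", ctx)
  variants <- variants[clean, , drop = FALSE]
  cls <- classify_sbs(variants$ref, variants$alt, ctx[clean])
  keep <- substr(cls, 1L, 1L) == "C" &
    substr(cls, nchar(cls), nchar(cls)) == "T"
  out <- variants[keep, , drop = FALSE]
  out$type96 <- cls[keep]
  out
}

#' Sample inclusion rule for strand-bias cohorts
#'
#' Strand asymmetry is only interpretable in samples where the focal
#' signature is strongly active; both thresholds are strict.
#'
#' @param abs_contribution absolute signature contribution (mutations).
#' @param rel_contribution relative signature contribution in \[0, 1\].
#' @param min_abs,min_rel strict thresholds (defaults 2000 and 0.25).
#' @return logical: include the sample.
#' @export
high_contribution_filter <- function(abs_contribution, rel_contribution,
                                     min_abs = 2000, min_rel = 0.25) {
  stopifnot(abs_contribution >= 0, rel_contribution >= 0)
  abs_contribution > min_abs & rel_contribution > min_rel
}

#' Read strand-annotated regions from a BED file
#'
#' BED intervals (0-based half-open on disk) are converted to 1-based
#' inclusive coordinates. For replication annotations the 4th (name)
#' column must label the role of the plus strand (`leading` or
#' `lagging`); for gene annotations the 6th (strand) column must be `+`
#' or `-`.
#'
#' @param path BED file.
#' @param mode `"replication"` or `"transcription"`.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and `strand_label` (replication) or `strand` (transcription).
#' @export
read_strand_bed <- function(path, mode = c("replication", "transcription")) {
  mode <- match.arg(mode)
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- data.frame(
    chrom = as.character(bed[[1L]]),
    start = bed[[2L]] + 1L,
    end = bed[[3L]],
    stringsAsFactors = FALSE
  )
  if (mode == "replication") {
    if (ncol(bed) < 4L) stop("replication BED needs a label (name) column")
    out$strand_label <- bed[[4L]]
    if (!all(out$strand_label %in% c("leading", "lagging"))) {
      stop("replication labels must be 'leading' or 'lagging'")
    }
  } else {
    if (ncol(bed) < 6L) stop("gene BED needs a strand column (6th)")
    out$strand <- bed[[6L]]
    if (!all(out$strand %in% c("+", "-"))) {
      stop("gene strand must be '+' or '-'")
    }
  }
  out
}

regions_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(regions$chrom),
    ranges = IRanges::IRanges(start = regions$start, end = regions$end)
  )
}

variants_granges <- function(variants) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(variants$chrom),
    ranges = IRanges::IRanges(start = variants$pos, width = 1L)
  )
}

#' Assign replication strand to variants
#'
#' A variant inside an annotated region is labeled by the replication role
#' of the strand carrying its pyrimidine base: when the reference base is
#' a pyrimidine the label is the region's plus-strand role, and when it is
#' a purine (the pyrimidine lies on the minus strand) the opposite role.
#' Variants outside every region are `"unassigned"`. Regions overlapping
#' with contradictory plus-strand labels are an annotation error.
#'
#' @param variants variant data.frame.
#' @param regions data.frame as from
#'   `read_strand_bed(mode = "replication")`.
#' @return character vector (`"leading"`, `"lagging"`, `"unassigned"`)
#'   parallel to `variants`.
#' @export
assign_replication_strand <- function(variants, regions) {
  if (nrow(variants) == 0L) return(character(0))
  hits <- GenomicRanges::findOverlaps(variants_granges(variants),
                                      regions_granges(regions))
  out <- rep("unassigned", nrow(variants))
  q <- S4Vectors::queryHits(hits)
  r <- S4Vectors::subjectHits(hits)
  if (any(duplicated(q))) {
    dup <- unique(q[duplicated(q)])
    for (i in dup) {
      if (length(unique(regions$strand_label[r[q == i]])) > 1L) {
        stop("variant ", variants$chrom[i], ":", variants$pos[i],
             " falls in regions with contradictory replication labels")
      }
    }
  }
  plus_label <- regions$strand_label[r]
  pyr_on_plus <- toupper(variants$ref[q]) %in% PYRIMIDINES
  flipped <- ifelse(plus_label == "lagging", "leading", "lagging")
  out[q] <- ifelse(pyr_on_plus, plus_label, flipped)
  out
}

#' Assign transcription strand to variants
#'
#' Inside a gene body, the strand complementary to the gene (the template
#' strand) is transcribed. A variant whose pyrimidine base lies on the
#' template strand is `"transcribed"`; on the gene (coding) strand,
#' `"untranscribed"`. Intergenic variants and variants inside overlapping
#' genes of opposite orientation are `"unassigned"`.
#'
#' @param variants variant data.frame.
#' @param gene_regions data.frame as from
#'   `read_strand_bed(mode = "transcription")`.
#' @return character vector (`"transcribed"`, `"untranscribed"`,
#'   `"unassigned"`).
#' @export
assign_transcription_strand <- function(variants, gene_regions) {
  if (nrow(variants) == 0L) return(character(0))
  hits <- GenomicRanges::findOverlaps(variants_granges(variants),
                                      regions_granges(gene_regions))
  out <- rep("unassigned", nrow(variants))
  q <- S4Vectors::queryHits(hits)
  r <- S4Vectors::subjectHits(hits)
  strands <- split(gene_regions$strand[r], q)
  for (key in names(strands)) {
    i <- as.integer(key)
    s <- unique(strands[[key]])
    if (length(s) > 1L) next  # opposite-strand overlap -> unassigned
    pyr_strand <- if (toupper(variants$ref[i]) %in% PYRIMIDINES) "+" else "-"
    # template strand is the complement of the gene strand
    out[i] <- if (pyr_strand != s) "transcribed" else "untranscribed"
  }
  out
}

#' Exact two-sided test for strand asymmetry
#'
#' Under equal Poisson mutation rates on the two strands, the count on one
#' strand given the total N is Binomial(N, 1/2) (the exact conditional
#' formulation of the two-rate Poisson comparison). The two-sided p-value
#' doubles the smaller tail and is capped at 1. A rate-ratio variant (the
#' asymptotic Poisson rate test) is available via `method`.
#'
#' @param n_strand1,n_strand2 non-negative counts, not both zero.
#' @param method `"exact"` (default) or `"rate_ratio"`.
#' @return two-sided p-value.
#' @export
poisson_asymmetry_test <- function(n_strand1, n_strand2,
                                   method = c("exact", "rate_ratio")) {
  method <- match.arg(method)
  if (n_strand1 < 0 || n_strand2 < 0) stop("counts must be non-negative")
  total <- n_strand1 + n_strand2
  if (total == 0) stop("both counts are zero")
  if (method == "exact") {
    lower <- stats::pbinom(n_strand1, total, 0.5)
    upper <- stats::pbinom(n_strand1 - 1, total, 0.5, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  } else {
    stats::poisson.test(n_strand1, total / 2)$p.value
  }
}

#' Strand-resolved mutation counts and asymmetry tests
#'
#' Tabulates assigned variants into a 6 substitution classes x 2 strands
#' matrix and applies the asymmetry test per class. Unassigned variants
#' are excluded; the matrix total equals the number of assigned variants.
#'
#' @param variants variant data.frame with a `type96` column (see
#'   [select_cnt_context()]).
#' @param assignments strand labels parallel to `variants` (from
#'   [assign_replication_strand()] or [assign_transcription_strand()]).
#' @return list with `counts` (6 x 2 matrix), `tests` (data.frame:
#'   substitution, counts, `p.value`, `p.adjust` by Benjamini-Hochberg;
#'   classes with zero total have `NA` p).
#' @export
strand_count_matrix <- function(variants, assignments) {
  stopifnot(nrow(variants) == length(assignments))
  strand_levels <- setdiff(unique(assignments), "unassigned")
  if (length(strand_levels) == 0L) {
    strand_levels <- c("leading", "lagging")
  }
  strand_levels <- sort(strand_levels)
  keep <- assignments != "unassigned"
  subs <- factor(substitution_of(variants$type96[keep]),
                 levels = SUBSTITUTIONS_6)
  counts <- table(subs, factor(assignments[keep], levels = strand_levels))
  counts <- matrix(as.integer(counts), nrow = 6L,
                   dimnames = list(SUBSTITUTIONS_6, strand_levels))
  if (ncol(counts) == 1L) {
    counts <- cbind(counts, 0L)
    colnames(counts)[2L] <- "other"
  }
  p <- vapply(seq_len(6L), function(i) {
    if (sum(counts[i, ]) == 0L) return(NA_real_)
    poisson_asymmetry_test(counts[i, 1L], counts[i, 2L])
  }, numeric(1L))
  tests <- data.frame(
    substitution = SUBSTITUTIONS_6,
    n1 = counts[, 1L], n2 = counts[, 2L],
    p.value = p,
    p.adjust = stats::p.adjust(p, method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  names(tests)[2:3] <- colnames(counts)
  list(counts = counts, tests = tests)
}
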