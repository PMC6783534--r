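#' Read somatic variants from a VCF file
#'
#' Parses a VCF (plain or bgzipped) into a variant table with one row per
#' variant allele. Multi-allelic records are split. When genotype columns
#' are present, a variant is replicated for every sample whose genotype
#' carries the alternative allele; otherwise all variants are assigned to a
#' single sample named after the file (or `sample_id`).
#'
#' Recognised annotations: `VAF`/`AF` (variant allele fraction), `AVAF`
#' (purity-adjusted allele fraction) and `CN` (local total copy number)
#' from the INFO column, and a per-sample `AF` FORMAT field.
#'
#' @param path path to a VCF file.
#' @param sbs_only drop records that are not single base substitutions
#'   (default `TRUE`).
#' @param sample_id override for the sample label of sample-less VCFs.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `vaf`, `adjusted_vaf`, `copy_number`, `sample_id`. Records with an
#'   ambiguous reference base are skipped with a warning; the number of
#'   skipped records is available as `attr(x, "n_skipped")`.
#' @export
read_vcf <- function(path, sbs_only = TRUE, sample_id = NULL) {
  if (!file.exists(path)) {
    stop("VCF file not found: ", path)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  empty <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), vaf = numeric(), adjusted_vaf = numeric(),
    copy_number = numeric(), sample_id = character(),
    stringsAsFactors = FALSE
  )
  if (nrow(fix) == 0L) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  info_field <- function(info, key) {
    parts <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"),
                                      info))
    val <- vapply(parts, function(p) {
      if (length(p) >= 2L) p[length(p)] else NA_character_
    }, character(1L))
    suppressWarnings(as.numeric(val))
  }
  info <- fix[, "INFO"]
  info[is.na(info)] <- ""
  df <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = toupper(fix[, "REF"]),
    alt = toupper(fix[, "ALT"]),
    vaf = info_field(info, "(?:VAF|AF)"),
    adjusted_vaf = info_field(info, "AVAF"),
    copy_number = info_field(info, "CN"),
    stringsAsFactors = FALSE
  )
  # split multi-allelic records
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  times <- lengths(alts)
  df <- df[rep(seq_len(nrow(df)), times), , drop = FALSE]
  df$alt <- unlist(alts)
  rec_idx <- rep(seq_along(times), times)

  n_skipped <- 0L
  bad <- !(df$ref %in% BASES & nchar(df$ref) == 1L) & nchar(df$ref) == 1L
  if (any(bad)) {
    warning(sum(bad), " record(s) with ambiguous reference base skipped")
    n_skipped <- n_skipped + sum(bad)
    df <- df[!bad, , drop = FALSE]
    rec_idx <- rec_idx[!bad]
  }
  if (sbs_only) {
    keep <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
      df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt
    df <- df[keep, , drop = FALSE]
    rec_idx <- rec_idx[keep]
  }

  gt <- vcf@gt
  if (!is.null(gt) && ncol(gt) >= 2L) {
    samples <- colnames(gt)[-1L]
    out <- list()
    for (s in samples) {
      geno <- gt[, s]
      fmt <- gt[, 1L]
      gt_val <- vapply(strsplit(geno, ":", fixed = TRUE), `[`, "", 1L)
      carrier <- grepl("1", gt_val, fixed = TRUE)
      af_idx <- vapply(
        strsplit(fmt, ":", fixed = TRUE),
        function(f) match("AF", f, nomatch = NA_integer_), 1L
      )
      af <- rep(NA_real_, length(geno))
      has_af <- !is.na(af_idx)
      if (any(has_af)) {
        af[has_af] <- suppressWarnings(as.numeric(mapply(
          function(g, i) strsplit(g, ":", fixed = TRUE)[[1L]][i],
          geno[has_af], af_idx[has_af]
        )))
      }
      keep <- carrier[rec_idx]
      sub <- df[keep, , drop = FALSE]
      sub$vaf <- ifelse(is.na(af[rec_idx][keep]), sub$vaf, af[rec_idx][keep])
      if (nrow(sub)) {
        sub$sample_id <- s
        out[[s]] <- sub
      }
    }
    df <- if (length(out)) do.call(rbind, out) else empty
  } else {
    df$sample_id <- if (is.null(sample_id)) {
      sub("\\.vcf(\\.gz)?$", "", basename(path))
    } else {
      sample_id
    }
  }
  rownames(df) <- NULL
  attr(df, "n_skipped") <- n_skipped
  df
}

#' Read a per-variant annotation table (TSV)
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt` and optionally
#'   `vaf`, `adjusted_vaf`, `copy_number`, `sample_id`.
#' @return data.frame in the same layout as [read_vcf()].
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("vaf", "adjusted_vaf", "copy_number")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  if (is.null(df$sample_id)) {
    df$sample_id <- sub("\\.tsv$", "", basename(path))
  }
  df$chrom <- as.character(df$chrom)
  df
}

#' Load a reference genome from FASTA
#'
#' @param path FASTA file (one or more contigs).
#' @return `DNAStringSet` keyed by contig name (first whitespace token).
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

norm_chrom <- function(chrom) sub("^chr", "", chrom)

#' Extract the plus-strand sequence context around a position
#'
#' @param reference a `DNAStringSet` (see [read_reference()]) or the path
#'   to a FASTA file.
#' @param chrom contig name ("chr" prefixes are normalised away on both
#'   sides).
#' @param pos 1-based position of the center base.
#' @param flank number of bases on each side; the window
#'   `[pos - flank, pos + flank]` must lie inside the contig.
#' @return Uppercase string of length `2 * flank + 1`. Soft-masked
#'   (lowercase) bases are uppercased.
#' @export
extract_context <- function(reference, chrom, pos, flank = 1L) {
  if (is.character(reference) && length(reference) == 1L) {
    reference <- read_reference(reference)
  }
  stopifnot(flank >= 0L)
  key <- match(norm_chrom(chrom), norm_chrom(names(reference)))
  if (any(is.na(key))) {
    stop("contig not found in reference: ",
         paste(unique(chrom[is.na(key)]), collapse = ", "))
  }
  len <- Biostrings::width(reference)[key]
  if (any(pos - flank < 1L) || any(pos + flank > len)) {
    stop("context window [pos-flank, pos+flank] outside contig bounds")
  }
  unname(toupper(as.character(Biostrings::subseq(
    reference[key],
    start = pos - flank, end = pos + flank
  ))))
}

#' Keep variants with VAF inside a closed interval
#'
#' Somatic calls acquired before a clonal bottleneck are expected at
#' intermediate allele fractions; the default closed interval
#' \[0.3, 0.7\] retains heterozygous clonal variants and discards
#' later-arising low-frequency calls. Variants lacking a VAF are excluded
#' and tallied in `attr(x, "n_excluded_na")`.
#'
#' @param variants variant data.frame with a `vaf` column.
#' @param low,high inclusive bounds (defaults 0.3 and 0.7).
#' @return filtered data.frame, input order preserved.
#' @export
vaf_filter <- function(variants, low = 0.3, high = 0.7) {
  keep <- !is.na(variants$vaf) & variants$vaf >= low & variants$vaf <= high
  out <- variants[keep, , drop = FALSE]
  attr(out, "n_excluded_na") <- sum(is.na(variants$vaf))
  out
}

#' Keep variants on autosomes (chromosomes 1-22)
#'
#' @param variants variant data.frame.
#' @return variants on chromosomes 1-22, with or without "chr" prefix.
#' @export
autosome_filter <- function(variants) {
  chrom <- norm_chrom(variants$chrom)
  variants[chrom %in% as.character(1:22), , drop = FALSE]
}

#' Build a 96-context mutation catalog
#'
#' Classifies every variant into its pyrimidine-centered trinucleotide
#' class and tabulates counts per sample. Variants whose trinucleotide
#' window contains an ambiguous base (N) are skipped and tallied.
#'
#' @param variants variant data.frame (columns `chrom`, `pos`, `ref`,
#'   `alt`, `sample_id`).
#' @param reference `DNAStringSet` or FASTA path.
#' @param sample_ids optional explicit column order; defaults to the sorted
#'   unique sample ids present.
#' @return 96 x S integer matrix with `mut_types_96()` rownames; column
#'   sums equal the number of classified variants per sample. Skipped
#'   variants tallied in `attr(x, "n_skipped")`.
#' @export
build_catalog <- function(variants, reference, sample_ids = NULL) {
  if (is.character(reference) && length(reference) == 1L) {
    reference <- read_reference(reference)
  }
  if (is.null(sample_ids)) {
    sample_ids <- sort(unique(as.character(variants$sample_id)))
  }
  if (length(sample_ids) == 0L) sample_ids <- "sample"
  types <- mut_types_96()
  counts <- matrix(0L, nrow = 96L, ncol = length(sample_ids),
                   dimnames = list(types, sample_ids))
  n_skipped <- 0L
  if (nrow(variants)) {
    ctx <- extract_context(reference, variants$chrom, variants$pos, 1L)
    center_ok <- substr(ctx, 2L, 2L) == toupper(variants$ref)
    if (any(!center_ok)) {
      bad <- which(!center_ok)[1L]
      stop(sprintf(
        "reference mismatch at %s:%d (VCF ref %s, FASTA %s)",
        variants$chrom[bad], variants$pos[bad], variants$ref[bad],
        substr(ctx[bad], 2L, 2L)
      ))
    }
    clean <- !grepl("[^ACGT]", ctx)
    n_skipped <- sum(!clean)
    if (n_skipped > 0L) {
      warning(n_skipped,
              " variant(s) skipped: ambiguous base in trinucleotide window")
    }
    v <- variants[clean, , drop = FALSE]
    ctx <- ctx[clean]
    if (nrow(v)) {
      cls <- classify_sbs(v$ref, v$alt, ctx)
      tab <- table(
        factor(cls, levels = types),
        factor(as.character(v$sample_id), levels = sample_ids)
      )
      counts[] <- as.integer(tab)
    }
  }
  attr(counts, "n_skipped") <- n_skipped
  counts
}

#' Tumor mutational burden (mutations per megabase)
#'
#' TMB is the genome-wide SBS count divided by the number of mappable
#' megabases. The default denominator, 2,858,674,662 bases, is the number
#' of mappable (ACGT) nucleotides of the GRCh37 reference assembly.
#'
#' @param sbs_count non-negative SBS count (vectorised).
#' @param mappable_bases mappable genome size in bases.
#' @return mutations per Mbp.
#' @export
tmb <- function(sbs_count, mappable_bases = 2858674662) {
  if (any(sbs_count < 0)) stop("sbs_count must be non-negative")
  if (mappable_bases <= 0) stop("mappable_bases must be positive")
  sbs_count / (mappable_bases / 1e6)
}

#' Drop hypermutant samples from a catalog
#'
#' Hypermutators dominate both absolute and relative contribution analyses,
#' so samples above a TMB cutoff are excluded before signature analysis.
#'
#' @param catalog 96 x S count matrix.
#' @param threshold TMB cutoff in mutations/Mbp; samples with TMB strictly
#'   greater are dropped (default 10).
#' @param mappable_bases see [tmb()].
#' @return catalog restricted to retained samples; dropped sample ids in
#'   `attr(x, "dropped")`.
#' @export
hypermutant_filter <- function(catalog, threshold = 10,
                               mappable_bases = 2858674662) {
  burden <- tmb(colSums(catalog), mappable_bases)
  keep <- burden <= threshold
  out <- catalog[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(catalog)[!keep]
  out
}

#' Base frequencies of the extended sequence context around a mutation class
#'
#' For every variant of the requested class, the window of
#' `2 * flank + 1` bases centered on the mutation is read from the
#' reference on the pyrimidine-normalized strand: variants whose reference
#' base is a purine contribute the reverse complement of their window, so
#' offsets are mirrored. Rows are per-offset base frequency vectors.
#'
#' @param variants variant data.frame.
#' @param reference `DNAStringSet` or FASTA path.
#' @param flank window half-width (default 5, an eleven-base context).
#' @param mutation_class one or more 96-class labels selecting the variants
#'   to summarize, e.g. `"C[T>G]T"`.
#' @return `(2 * flank + 1) x 4` matrix of base frequencies with offset
#'   rownames (-flank..flank) and A/C/G/T colnames; each row sums to 1.
#'   `attr(x, "n")` is the number of contributing variants; a matrix with
#'   `n == 0` is all-NA.
#' @export
extended_context_matrix <- function(variants, reference, flank = 5L,
                                    mutation_class) {
  if (is.character(reference) && length(reference) == 1L) {
    reference <- read_reference(reference)
  }
  offsets <- seq(-flank, flank)
  freqs <- matrix(NA_real_, nrow = length(offsets), ncol = 4L,
                  dimnames = list(offsets, BASES))
  if (nrow(variants) == 0L) {
    attr(freqs, "n") <- 0L
    return(freqs)
  }
  ctx3 <- extract_context(reference, variants$chrom, variants$pos, 1L)
  clean <- !grepl("[^ACGT]", ctx3)
  v <- variants[clean, , drop = FALSE]
  cls <- classify_sbs(v$ref, v$alt, ctx3[clean])
  v <- v[cls %in% mutation_class, , drop = FALSE]
  if (nrow(v) == 0L) {
    attr(freqs, "n") <- 0L
    return(freqs)
  }
  win <- extract_context(reference, v$chrom, v$pos, flank)
  ok <- !grepl("[^ACGT]", win)
  v <- v[ok, , drop = FALSE]
  win <- win[ok]
  if (length(win) == 0L) {
    attr(freqs, "n") <- 0L
    return(freqs)
  }
  flip <- toupper(v$ref) %in% PURINES
  win[flip] <- revcomp(win[flip])
  mat <- do.call(rbind, strsplit(win, ""))
  for (i in seq_along(offsets)) {
    freqs[i, ] <- tabulate(factor(mat[, i], levels = BASES), 4L) / nrow(mat)
  }
  attr(freqs, "n") <- nrow(mat)
  freqs
}

#' Write / read a mutation catalog as TSV
#'
#' The on-disk layout is 96 labeled rows (first column `MutationType`,
#' values like `A[C>A]A`) and one column per sample.
#'
#' @param catalog 96 x S matrix.
#' @param path output TSV path.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(MutationType = rownames(catalog), catalog,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @return `read_catalog()` returns the 96 x S matrix reordered to the
#'   canonical type order.
#' @export
read_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  types <- mut_types_96()
  if (!setequal(rownames(mat), types)) {
    stop("catalog rows are not the 96 canonical mutation types")
  }
  mat[types, , drop = FALSE]
}
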