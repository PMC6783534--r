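#' Variant ploidy score
#'
#' The local ploidy of a somatic variant is the product of its
#' purity-adjusted allele fraction and the local total copy number. A
#' heterozygous clonal variant in a diploid region scores 1; scores above
#' 1 imply presence on more than one copy (early, clonal), and a second
#' density mode below 1 marks a subclonal population.
#'
#' @param adjusted_vaf purity-adjusted allele fraction(s) in \[0, 1\].
#' @param copy_number local total copy number(s), >= 0.
#' @return numeric vector of ploidy scores.
#' @export
variant_ploidy <- function(adjusted_vaf, copy_number) {
  if (any(!is.na(adjusted_vaf) &
          (adjusted_vaf < 0 | adjusted_vaf > 1))) {
    stop("adjusted_vaf must lie in [0, 1]")
  }
  if (any(!is.na(copy_number) & copy_number < 0)) {
    stop("copy_number must be non-negative")
  }
  adjusted_vaf * copy_number
}

#' Detect density peaks in a variant-ploidy distribution
#'
#' A Gaussian kernel density with fixed bandwidth is evaluated on a
#' regular grid over `[0, max(ploidy) + 3 * bandwidth]`; peaks are strict
#' local maxima of the grid values reaching at least 1% of the density
#' maximum (the floor suppresses floating-point wiggles in empty tail
#' regions). Peaks located below `1 - bandwidth` are reported as
#' subclonal candidates. The search requires at least 10
#' variants with ploidy below 1; otherwise no subclonal search is
#' performed and the candidate list is empty (with a warning).
#'
#' @param ploidies numeric vector of variant ploidy scores (non-empty;
#'   `NA` dropped).
#' @param bandwidth Gaussian kernel standard deviation (default 0.05).
#' @param grid_step density grid spacing (default 0.01).
#' @return list with `peaks` (all strict local maxima, ascending),
#'   `subclonal_peaks` (subset below `1 - bandwidth`), `main_peak` (peak
#'   closest to 1, or 1 if none detected), `bandwidth`, `density`
#'   (data.frame `x`, `y`).
#' @export
detect_subclonal_peaks <- function(ploidies, bandwidth = 0.05,
                                   grid_step = 0.01) {
  ploidies <- ploidies[!is.na(ploidies)]
  if (length(ploidies) == 0L) stop("no ploidy values supplied")
  to <- max(ploidies) + 3 * bandwidth
  n_grid <- max(2L, round(to / grid_step) + 1L)
  dens <- stats::density(ploidies, bw = bandwidth, kernel = "gaussian",
                         from = 0, to = to, n = n_grid)
  y <- dens$y
  k <- length(y)
  is_peak <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] &
                 y[2:(k - 1)] > y[3:k], FALSE)
  is_peak <- is_peak & y >= 0.01 * max(y)
  peaks <- sort(dens$x[is_peak])
  searched <- sum(ploidies < 1) >= 10L
  if (!searched) {
    warning("fewer than 10 variants with ploidy < 1; ",
            "subclonal peak search skipped")
  }
  subclonal <- if (searched) peaks[peaks < (1 - bandwidth)] else numeric(0)
  main_candidates <- peaks[peaks >= (1 - bandwidth)]
  main_peak <- if (length(main_candidates)) {
    main_candidates[which.min(abs(main_candidates - 1))]
  } else {
    1
  }
  list(peaks = peaks, subclonal_peaks = subclonal, main_peak = main_peak,
       bandwidth = bandwidth,
       density = data.frame(x = dens$x, y = dens$y))
}

#' Classify variants as clonal or subclonal
#'
#' Every variant with ploidy above 1 is clonal. Variants at or below 1 are
#' assigned to the nearest density peak: nearest subclonal peak means
#' subclonal, nearest main peak (around 1) means clonal. With no detected
#' subclonal peak all sub-unity variants are clonal. `NA` ploidies are
#' `"unassigned"`.
#'
#' @param ploidies numeric vector of variant ploidy scores.
#' @param peaks result of [detect_subclonal_peaks()].
#' @return character vector with values `"clonal"`, `"subclonal"`,
#'   `"unassigned"`, parallel to `ploidies`.
#' @export
classify_clonality <- function(ploidies, peaks) {
  labels <- rep("unassigned", length(ploidies))
  known <- !is.na(ploidies)
  labels[known & ploidies > 1] <- "clonal"
  low <- known & ploidies <= 1
  if (!any(low)) return(labels)
  sub_peaks <- peaks$subclonal_peaks
  if (length(sub_peaks) == 0L) {
    labels[low] <- "clonal"
    return(labels)
  }
  centers <- c(sub_peaks, peaks$main_peak)
  role <- c(rep("subclonal", length(sub_peaks)), "clonal")
  nearest <- vapply(ploidies[low],
                    function(p) which.min(abs(centers - p)), 1L)
  labels[low] <- role[nearest]
  labels
}

#' Eligibility of a sample for subclonal timing analysis
#'
#' A sample enters the clonal-versus-subclonal contrast only when its
#' subclonal compartment is large enough and the focal signature is
#' active overall.
#'
#' @param n_subclonal number of subclonal mutations.
#' @param focal_signature_relative_contribution overall relative
#'   contribution of the focal signature in the sample.
#' @param min_subclonal,min_contribution inclusive thresholds
#'   (defaults 500 and 0.05).
#' @return logical.
#' @export
subclonal_eligibility <- function(n_subclonal,
                                  focal_signature_relative_contribution,
                                  min_subclonal = 500L,
                                  min_contribution = 0.05) {
  stopifnot(n_subclonal >= 0, focal_signature_relative_contribution >= 0)
  n_subclonal >= min_subclonal &
    focal_signature_relative_contribution >= min_contribution
}

#' Contrast signature activity between clonal and subclonal mutations
#'
#' Splits each sample's variants by clonality label, builds a catalog per
#' compartment, refits both against the signature set, and reports the
#' relative contribution of the focal signature in each compartment and
#' their ratio (subclonal / clonal). Samples failing the eligibility rule
#' or with an empty compartment are skipped with a warning. When two or
#' more samples are evaluable a Wilcoxon rank-sum p-value contrasts the
#' clonal and subclonal contributions across samples.
#'
#' @param variants variant data.frame with `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `adjusted_vaf`, `copy_number`.
#' @param reference `DNAStringSet` or FASTA path.
#' @param signatures 96 x K column-stochastic signature matrix.
#' @param focal_signature column name of the signature of interest.
#' @param bandwidth KDE bandwidth for peak detection.
#' @return list with `per_sample` (data.frame: sample, n_clonal,
#'   n_subclonal, clonal and subclonal relative contribution, ratio,
#'   eligible) and `p.value` (cohort-level contrast over eligible samples,
#'   `NA` when fewer than 2).
#' @export
clonal_subclonal_contrast <- function(variants, reference, signatures,
                                      focal_signature, bandwidth = 0.05) {
  if (!focal_signature %in% colnames(signatures)) {
    stop("focal_signature not found in signature matrix")
  }
  assigned <- !is.na(variants$adjusted_vaf) & !is.na(variants$copy_number)
  variants <- variants[assigned, , drop = FALSE]
  samples <- sort(unique(variants$sample_id))
  rows <- list()
  for (s in samples) {
    v <- variants[variants$sample_id == s, , drop = FALSE]
    pl <- variant_ploidy(v$adjusted_vaf, v$copy_number)
    peaks <- tryCatch(
      detect_subclonal_peaks(pl, bandwidth = bandwidth),
      warning = function(w) {
        suppressWarnings(detect_subclonal_peaks(pl, bandwidth = bandwidth))
      }
    )
    lab <- classify_clonality(pl, peaks)
    overall <- refit_nnls(build_catalog(v, reference, sample_ids = s),
                          signatures)
    overall_rel <- relative_contribution(overall)[focal_signature, 1L]
    n_sub <- sum(lab == "subclonal")
    eligible <- subclonal_eligibility(n_sub, overall_rel)
    res <- data.frame(
      sample_id = s, n_clonal = sum(lab == "clonal"), n_subclonal = n_sub,
      clonal_contribution = NA_real_, subclonal_contribution = NA_real_,
      ratio = NA_real_, eligible = eligible, stringsAsFactors = FALSE
    )
    if (res$n_clonal > 0L && n_sub > 0L) {
      rel_of <- function(idx) {
        cat_c <- build_catalog(v[idx, , drop = FALSE], reference,
                               sample_ids = s)
        relative_contribution(refit_nnls(cat_c, signatures))[
          focal_signature, 1L]
      }
      res$clonal_contribution <- rel_of(lab == "clonal")
      res$subclonal_contribution <- rel_of(lab == "subclonal")
      res$ratio <- res$subclonal_contribution / res$clonal_contribution
    } else {
      warning("sample ", s, " has an empty compartment; skipped")
    }
    rows[[s]] <- res
  }
  per_sample <- do.call(rbind, rows)
  rownames(per_sample) <- NULL
  ok <- per_sample$eligible & !is.na(per_sample$ratio)
  p <- if (sum(ok) >= 2L) {
    cohort_contrast(per_sample$subclonal_contribution[ok],
                    per_sample$clonal_contribution[ok])$p.value
  } else {
    NA_real_
  }
  list(per_sample = per_sample, p.value = p)
}
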