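#' Parameters of the oncogenic-driver risk model
#'
#' The model counts the expected number of driver-activating mutations
#' introduced into a population of normal cells by a mutational process
#' with a known 96-class spectrum:
#' `M_active = coding_fraction * dp * N * mu * sum_c P_c * n_c / L`
#' where `coding_fraction` is the exon-coding fraction of the genome,
#' `dp` the mutational depletion of coding sequence relative to the
#' genome average, `N` the number of cells at risk, `mu` the number of
#' mutations accumulated per cell over the scenario, `P` the 96-class
#' spectrum of the process, `n` the per-class count of positions whose
#' mutation activates a driver gene, and `L` the coding-sequence length.
#'
#' Defaults: 1.5% coding fraction, coding depletion 0.3094464 and a CDS
#' length of 22,563,618 bp (small intestinal cells).
#'
#' @param N number of cells at risk.
#' @param mu mutations per cell over the scenario (rate x duration).
#' @param P 96-class probability vector (sums to 1).
#' @param n 96-vector of driver-activating position counts per class.
#' @param coding_fraction fraction of the genome that is exon coding.
#' @param dp coding-sequence mutational depletion factor.
#' @param L coding sequence length in bp.
#' @return list of class `"risk_params"`.
#' @export
risk_params <- function(N, mu, P, n, coding_fraction = 0.015,
                        dp = 0.3094464, L = 22563618) {
  if (L <= 0) stop("L must be positive")
  if (any(P < 0) || any(n < 0)) stop("P and n must be non-negative")
  if (abs(sum(P) - 1) > 1e-6) stop("P must sum to 1")
  if (length(P) != length(n)) stop("P and n must have equal length")
  structure(
    list(N = N, mu = mu, P = P, n = n,
         coding_fraction = coding_fraction, dp = dp, L = L),
    class = "risk_params"
  )
}

#' Expected number of driver-activating mutations
#'
#' @param params a [risk_params()] object.
#' @return expected count `M_active`, linear in each of `N`, `mu` and
#'   `n`.
#' @export
expected_driver_mutations <- function(params) {
  stopifnot(inherits(params, "risk_params"))
  with(params, coding_fraction * dp * N * mu * sum(P * n) / L)
}

#' Build the per-class oncogenic position table from a driver list
#'
#' Collapses duplicate rows, classifies every distinct driver position's
#' substitution into its 96 class, and counts positions per class.
#'
#' @param driver_variants data.frame with `chrom`, `pos`, `ref`, `alt`
#'   (optionally `gene`).
#' @param reference `DNAStringSet` or FASTA path.
#' @return list with `n` (named 96-vector of distinct position counts)
#'   and `positions` (data.frame of distinct classified variants with a
#'   `type96` column). Variants with an unavailable or ambiguous context
#'   are skipped and tallied in `attr(x, "n_skipped")`.
#' @export
build_oncogenic_table <- function(driver_variants, reference) {
  types <- mut_types_96()
  key_cols <- c("chrom", "pos", "ref", "alt")
  dv <- unique(driver_variants[, intersect(
    c(key_cols, "gene"), colnames(driver_variants)
  ), drop = FALSE])
  dv <- dv[!duplicated(dv[, key_cols]), , drop = FALSE]
  n <- stats::setNames(rep(0L, 96L), types)
  n_skipped <- 0L
  if (nrow(dv)) {
    ctx <- tryCatch(
      extract_context(reference, dv$chrom, dv$pos, 1L),
      error = function(e) stop("driver context unavailable: ",
                               conditionMessage(e))
    )
    clean <- !grepl("[^ACGT]", ctx)
    n_skipped <- sum(!clean)
    dv <- dv[clean, , drop = FALSE]
    if (nrow(dv)) {
      dv$type96 <- classify_sbs(dv$ref, dv$alt, ctx[clean])
      tab <- table(factor(dv$type96, levels = types))
      n[] <- as.integer(tab)
    }
  }
  out <- list(n = n, positions = dv)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Define an exposure scenario
#'
#' @param name scenario label.
#' @param annual_rate mutations per cell per year attributed to the
#'   process.
#' @param duration_years exposure duration in years (`mu = annual_rate *
#'   duration_years`).
#' @param P 96-class spectrum of the process.
#' @param n per-class driver-activating position counts.
#' @param N number of cells at risk (default 1e8 colonic stem cells).
#' @param ... further arguments to [risk_params()].
#' @return list of class `"scenario"` with the name, rates and embedded
#'   `params`.
#' @export
scenario <- function(name, annual_rate, duration_years, P, n, N = 1e8,
                     ...) {
  if (duration_years < 0) stop("duration must be non-negative")
  structure(
    list(name = name, annual_rate = annual_rate,
         duration_years = duration_years,
         params = risk_params(N = N, mu = annual_rate * duration_years,
                              P = P, n = n, ...)),
    class = "scenario"
  )
}

#' Fold change in expected driver mutations between two scenarios
#'
#' When both scenarios share `P`, `n` and the cell count, the fold
#' reduces exactly to the ratio of `rate * duration`.
#'
#' @param a,b [scenario()] objects; `b` must yield a positive expectation.
#' @return `M_active(a) / M_active(b)`.
#' @export
scenario_fold_change <- function(a, b) {
  stopifnot(inherits(a, "scenario"), inherits(b, "scenario"))
  mb <- expected_driver_mutations(b$params)
  if (mb <= 0) stop("reference scenario has zero expected mutations")
  expected_driver_mutations(a$params) / mb
}

#' Treatment exposure expressed in years of baseline mutagenesis
#'
#' Converts a treatment-associated mutation rate maintained for a given
#' number of weeks into the number of years over which the baseline
#' process would accumulate the same number of mutations.
#'
#' @param treatment_rate mutations per cell per year under treatment.
#' @param duration_weeks treatment duration (default 24 weeks, a typical
#'   12-cycle regimen).
#' @param baseline_rate baseline mutations per cell per year (default
#'   40).
#' @return equivalent years of baseline mutation accumulation.
#' @export
treatment_equivalent_years <- function(treatment_rate,
                                       duration_weeks = 24,
                                       baseline_rate = 40) {
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  (treatment_rate * duration_weeks / 52) / baseline_rate
}

#' Risk fold for a germline-predisposition (second-hit) scenario
#'
#' Re-evaluates the risk model with the oncogenic-position table
#' restricted to the inactivating positions of a single predisposition
#' gene, and reports the fold between the treated and untreated scenario
#' under that restricted table.
#'
#' @param treated,untreated [scenario()] objects (their `P` spectra and
#'   rates are used).
#' @param gene_n 96-vector of second-hit position counts restricted to
#'   the predisposition gene (not all zero).
#' @return list with `fold`, `M_treated`, `M_untreated`.
#' @export
germline_predisposition_scenario <- function(treated, untreated, gene_n) {
  if (sum(gene_n) == 0) {
    stop("restricted oncogenic table is empty")
  }
  ta <- treated$params; ua <- untreated$params
  mt <- expected_driver_mutations(
    risk_params(ta$N, ta$mu, ta$P, gene_n, ta$coding_fraction, ta$dp,
                ta$L))
  mu_ <- expected_driver_mutations(
    risk_params(ua$N, ua$mu, ua$P, gene_n, ua$coding_fraction, ua$dp,
                ua$L))
  if (mu_ <= 0) stop("untreated scenario has zero expected mutations")
  list(fold = mt / mu_, M_treated = mt, M_untreated = mu_)
}
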