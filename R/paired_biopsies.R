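#' Median-of-ratios normalization of a mutation-type count table
#'
#' The median-ratio (size factor) algorithm: for each sample, the size
#' factor is the median over mutation types of the ratio between the
#' sample's count and the geometric mean of that type across samples;
#' counts are divided by their sample's factor. Types with a zero count
#' in any sample are excluded from factor estimation only. This corrects
#' paired biopsies for differences in total mutation yield before
#' treatment effects are modeled.
#'
#' @param count_table 96 types x M samples non-negative matrix.
#' @return list with `size_factors` (length M) and `normalized`
#'   (same shape as `count_table`).
#' @export
median_ratio_normalize <- function(count_table) {
  mat <- as.matrix(count_table)
  all_pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(all_pos)) {
    stop("no mutation type has a non-zero count in every sample")
  }
  log_geo <- rowMeans(log(mat[all_pos, , drop = FALSE]))
  sf <- apply(mat[all_pos, , drop = FALSE], 2L, function(cnt) {
    exp(stats::median(log(cnt) - log_geo))
  })
  list(size_factors = sf,
       normalized = sweep(mat, 2L, sf, "/"))
}

#' Normalize paired biopsies patient by patient
#'
#' Applies [median_ratio_normalize()] separately to each patient's set of
#' biopsies, so factors compare a patient's samples against each other
#' rather than across the cohort.
#'
#' @param count_table 96 x M count matrix, columns named by sample id.
#' @param design data.frame with `sample_id`, `patient`, `biopsy`.
#' @return list with `normalized` (96 x M) and `size_factors`.
#' @export
normalize_paired <- function(count_table, design) {
  stopifnot(all(design$sample_id %in% colnames(count_table)))
  normalized <- count_table
  sf <- stats::setNames(rep(NA_real_, ncol(count_table)),
                        colnames(count_table))
  for (p in unique(design$patient)) {
    ids <- design$sample_id[design$patient == p]
    if (length(ids) < 2L) {
      stop("patient ", p, " has fewer than 2 biopsies")
    }
    res <- median_ratio_normalize(count_table[, ids, drop = FALSE])
    normalized[, ids] <- res$normalized
    sf[ids] <- res$size_factors
  }
  list(normalized = normalized, size_factors = sf)
}

eligible_drugs <- function(treatments, min_patients = 3L) {
  tab <- table(unique(treatments[, c("patient", "drug")])$drug)
  names(tab)[tab >= min_patients]
}

build_model_frame <- function(y, design, treatments, drugs, focal_drug) {
  df <- data.frame(
    y = y,
    patient = factor(design$patient),
    biopsy = design$biopsy,
    stringsAsFactors = FALSE
  )
  post <- design$biopsy >= 2L
  for (d in drugs) {
    got <- design$patient %in% treatments$patient[treatments$drug == d]
    df[[make.names(d)]] <- as.numeric(post & got)
  }
  # co-treatment intensity: dose and exposure-time totals over the other
  # drugs (the focal drug's own dose would compete with its indicator)
  other <- treatments[treatments$drug != focal_drug, , drop = FALSE]
  df$dose <- 0
  df$exposure_time <- 0
  if (nrow(other)) {
    totals <- stats::aggregate(
      cbind(dose, exposure_time) ~ patient, data = other, FUN = sum
    )
    idx <- match(design$patient, totals$patient)
    hit <- post & !is.na(idx)
    df$dose[hit] <- totals$dose[idx[hit]]
    df$exposure_time[hit] <- totals$exposure_time[idx[hit]]
  }
  df
}

#' Mixed-model treatment test for one mutation type
#'
#' Fits a linear mixed model of the normalized count on per-drug exposure
#' indicators (1 for biopsies taken after the patient received the drug)
#' with co-treatment dose and exposure-time totals (summed over the
#' non-focal drugs) as fixed covariates and a patient-level random
#' intercept. The focal drug's p-value is the
#' conditional F-test for its term from an ANOVA on the fitted model
#' (`method = "anova"`, the default); a likelihood-ratio comparison
#' against the null model without the focal term, both fitted by maximum
#' likelihood, is available via `method = "lrt"`.
#'
#' Only drugs administered to at least `min_patients` patients enter the
#' model.
#'
#' @param y normalized counts of one mutation type, one value per sample,
#'   ordered as the rows of `design`.
#' @param design data.frame with `sample_id`, `patient`, `biopsy`
#'   (1, 2, ...).
#' @param treatments data.frame with `patient`, `drug`, `dose`,
#'   `exposure_time` (one row per drug a patient received between
#'   biopsies).
#' @param focal_drug drug whose effect is tested (default `"5-FU"`).
#' @param min_patients minimum patients per modeled drug (default 3).
#' @param method `"anova"` (conditional F, default) or `"lrt"`.
#' @return list with `effect` (fixed-effect coefficient of the focal
#'   drug), `p.value`, `n_drugs`; both are `NA` with `ok = FALSE` when
#'   the fit fails or the design is singular.
#' @export
fit_type_model <- function(y, design, treatments, focal_drug = "5-FU",
                           min_patients = 3L,
                           method = c("anova", "lrt")) {
  method <- match.arg(method)
  drugs <- eligible_drugs(treatments, min_patients)
  if (!focal_drug %in% drugs) {
    stop("focal drug was not administered to at least ",
         min_patients, " patients")
  }
  df <- build_model_frame(y, design, treatments, drugs, focal_drug)
  focal_col <- make.names(focal_drug)
  other_cols <- setdiff(make.names(drugs), focal_col)
  rhs_full <- paste(c(focal_col, other_cols, "dose", "exposure_time"),
                    collapse = " + ")
  fit <- tryCatch({
    if (method == "anova") {
      full <- nlme::lme(stats::as.formula(paste("y ~", rhs_full)),
                        random = ~ 1 | patient, data = df,
                        method = "REML")
      an <- stats::anova(full, type = "marginal")
      p <- an[focal_col, "p-value"]
    } else {
      rhs_null <- paste(c(other_cols, "dose", "exposure_time"),
                        collapse = " + ")
      full <- nlme::lme(stats::as.formula(paste("y ~", rhs_full)),
                        random = ~ 1 | patient, data = df, method = "ML")
      null <- nlme::lme(stats::as.formula(paste("y ~", rhs_null)),
                        random = ~ 1 | patient, data = df, method = "ML")
      p <- stats::anova(null, full)[["p-value"]][2L]
    }
    list(effect = nlme::fixef(full)[[focal_col]], p.value = p,
         n_drugs = length(drugs), ok = TRUE)
  }, error = function(e) {
    list(effect = NA_real_, p.value = NA_real_, n_drugs = length(drugs),
         ok = FALSE)
  })
  fit
}

#' Scan all 96 mutation types for treatment enrichment
#'
#' Normalizes the count table per patient pair and applies
#' [fit_type_model()] to every mutation type. Raw p-values are the
#' headline output; Benjamini-Hochberg adjusted values are emitted
#' alongside. Per-type failures are recorded and the scan continues.
#'
#' @param count_table 96 x M count matrix (canonical row order), columns
#'   named by sample id.
#' @param design,treatments,focal_drug,min_patients see
#'   [fit_type_model()].
#' @param normalize `"absolute"` (median-ratio normalized counts,
#'   default) or `"relative"` (counts divided by the sample total).
#' @return data.frame with one row per mutation type: `type`, `effect`,
#'   `p.value`, `p.adjust`, `ok`.
#' @export
scan_all_types <- function(count_table, design, treatments,
                           focal_drug = "5-FU", min_patients = 3L,
                           normalize = c("absolute", "relative"),
                           method = c("anova", "lrt")) {
  normalize <- match.arg(normalize)
  method <- match.arg(method)
  stopifnot(identical(rownames(count_table), mut_types_96()))
  norm <- if (normalize == "absolute") {
    normalize_paired(count_table, design)$normalized
  } else {
    sweep(count_table, 2L, pmax(colSums(count_table), 1), "/")
  }
  norm <- norm[, design$sample_id, drop = FALSE]
  res <- lapply(seq_len(nrow(norm)), function(i) {
    fit_type_model(norm[i, ], design, treatments, focal_drug,
                   min_patients, method = method)
  })
  data.frame(
    type = rownames(count_table),
    effect = vapply(res, `[[`, numeric(1L), "effect"),
    p.value = vapply(res, `[[`, numeric(1L), "p.value"),
    p.adjust = stats::p.adjust(
      vapply(res, `[[`, numeric(1L), "p.value"), method = "BH"
    ),
    ok = vapply(res, `[[`, logical(1L), "ok"),
    stringsAsFactors = FALSE
  )
}
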