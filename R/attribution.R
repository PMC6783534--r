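#' Per-mutation signature attribution likelihood
#'
#' Given a sample's absolute signature exposures and the signatures'
#' class probabilities, the probability that a mutation of trinucleotide
#' class `c` was generated by signature `x` is
#' `e_x * p_x(c) / sum_s e_s * p_s(c)`: the exposure-weighted share of
#' that class explained by each signature. The likelihoods over all
#' signatures sum to 1 whenever the denominator is positive; a class on
#' which no active signature places mass is unattributable (all `NA`).
#'
#' @param exposures_for_sample non-negative K-vector of absolute
#'   contributions with positive sum (names matching `signatures`
#'   columns).
#' @param signatures 96 x K column-stochastic signature matrix.
#' @param tnc_class one or more 96-class labels.
#' @return K-vector of likelihoods (or a `length(tnc_class)` x K matrix
#'   when several classes are given).
#' @export
attribution_likelihood <- function(exposures_for_sample, signatures,
                                   tnc_class) {
  if (any(exposures_for_sample < 0)) stop("exposures must be non-negative")
  if (sum(exposures_for_sample) <= 0) {
    stop("sample has zero total exposure")
  }
  if (length(exposures_for_sample) != ncol(signatures)) {
    stop("exposure vector length must match the number of signatures")
  }
  idx <- match(tnc_class, rownames(signatures))
  if (any(is.na(idx))) {
    stop("unknown mutation class: ",
         paste(tnc_class[is.na(idx)], collapse = ", "))
  }
  probs <- signatures[idx, , drop = FALSE]
  num <- sweep(probs, 2L, exposures_for_sample, "*")
  denom <- rowSums(num)
  out <- num / ifelse(denom > 0, denom, NA_real_)
  colnames(out) <- colnames(signatures)
  if (length(tnc_class) == 1L) out[1L, ] else out
}

#' Attribution table for a set of classified mutations
#'
#' @param types 96-class labels, one per mutation.
#' @param sample_ids sample label per mutation.
#' @param exposures K x S absolute exposure matrix (samples as columns).
#' @param signatures 96 x K column-stochastic signature matrix.
#' @return data.frame with `sample_id`, `type96` and one likelihood
#'   column per signature; rows of unattributable mutations are `NA`.
#' @export
attribution_table <- function(types, sample_ids, exposures, signatures) {
  stopifnot(length(types) == length(sample_ids))
  out <- matrix(NA_real_, length(types), ncol(signatures),
                dimnames = list(NULL, colnames(signatures)))
  for (s in unique(sample_ids)) {
    rows <- which(sample_ids == s)
    lik <- attribution_likelihood(exposures[, s], signatures,
                                  types[rows])
    if (is.null(dim(lik))) lik <- matrix(lik, nrow = 1L)
    out[rows, ] <- lik
  }
  data.frame(sample_id = sample_ids, type96 = types, out,
             check.names = FALSE, stringsAsFactors = FALSE)
}

likelihood_columns <- function(attribution) {
  setdiff(colnames(attribution),
          c("sample_id", "type96", "chrom", "pos", "ref", "alt",
            "assigned"))
}

#' Assign each mutation to its originating signature
#'
#' A mutation is assigned to a signature when that signature's likelihood
#' strictly exceeds the threshold (at most one signature can exceed 0.5);
#' otherwise it is `"unassigned"`.
#'
#' @param attribution data.frame from [attribution_table()].
#' @param threshold strict likelihood cutoff (default 0.5).
#' @return `attribution` with an `assigned` column added.
#' @export
assign_origin <- function(attribution, threshold = 0.5) {
  lik_cols <- likelihood_columns(attribution)
  lik <- as.matrix(attribution[, lik_cols, drop = FALSE])
  assigned <- rep("unassigned", nrow(attribution))
  valid <- stats::complete.cases(lik)
  if (any(valid)) {
    best <- max.col(lik[valid, , drop = FALSE], ties.method = "first")
    top <- lik[valid, , drop = FALSE][cbind(seq_len(sum(valid)), best)]
    hit <- top > threshold
    assigned[valid][hit] <- lik_cols[best[hit]]
  }
  attribution$assigned <- assigned
  attribution
}

#' Cohort-cumulative signature attribution
#'
#' Sums the per-mutation likelihood vectors over all mutations with a
#' valid attribution; the grand total equals the number of attributable
#' mutations, so the totals divided by their sum give the cohort-level
#' share of mutations explained by each signature.
#'
#' @param attribution data.frame from [attribution_table()] (one or more
#'   samples row-bound together).
#' @return named numeric vector of per-signature cumulative likelihoods.
#' @export
cohort_cumulative <- function(attribution) {
  lik_cols <- likelihood_columns(attribution)
  lik <- as.matrix(attribution[, lik_cols, drop = FALSE])
  valid <- stats::complete.cases(lik)
  colSums(lik[valid, , drop = FALSE])
}

#' Export variants assigned to one signature
#'
#' Writes a TSV of (sample_id, chrom, pos, ref, alt) for downstream
#' selection analysis of mutations attributed to the signature.
#'
#' @param variants variant data.frame aligned row-wise with `assigned`.
#' @param assigned character vector of per-mutation signature labels.
#' @param signature_id the signature whose mutations to export.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
export_assigned_variants <- function(variants, assigned, signature_id,
                                     path) {
  stopifnot(nrow(variants) == length(assigned))
  out <- variants[assigned == signature_id,
                  c("sample_id", "chrom", "pos", "ref", "alt"),
                  drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
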