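#' Cosine similarity between two non-negative spectra
#'
#' @param a,b non-negative numeric vectors of equal length, not all zero.
#' @return `sum(a * b) / (||a|| * ||b||)`, in \[0, 1\] for non-negative
#'   input and invariant to positive rescaling of either argument.
#' @export
cosine_sim <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

#' Match de novo signatures to a reference set by cosine similarity
#'
#' @param denovo,reference 96 x K / 96 x R column-stochastic matrices with
#'   identical canonical row order.
#' @return list with `matches` (data.frame: `denovo`, `best_match`,
#'   `cosine`) and `scores` (K x R full cosine matrix).
#' @export
match_to_reference <- function(denovo, reference) {
  if (!identical(rownames(denovo), rownames(reference))) {
    stop("row (mutation type) order differs between the two matrices")
  }
  scores <- matrix(NA_real_, ncol(denovo), ncol(reference),
                   dimnames = list(colnames(denovo), colnames(reference)))
  for (i in seq_len(ncol(denovo))) {
    for (j in seq_len(ncol(reference))) {
      scores[i, j] <- cosine_sim(denovo[, i], reference[, j])
    }
  }
  best <- apply(scores, 1L, which.max)
  matches <- data.frame(
    denovo = colnames(denovo),
    best_match = colnames(reference)[best],
    cosine = scores[cbind(seq_along(best), best)],
    stringsAsFactors = FALSE
  )
  list(matches = matches, scores = scores)
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0`.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @return list with `x` (solution) and `gradient` (`t(A) %*% (b - A x)`,
#'   the KKT residual: ~0 on the active set, <= 0 elsewhere at optimum).
#' @export
nnls_solve <- function(A, b) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  tol <- 1e-10 * max(1, sum(abs(crossprod(A, b))))
  iter <- 0L
  max_iter <- 30L * n
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- drop(qr.coef(qr(A[, P, drop = FALSE]), b))
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) {
        x <- z
        break
      }
      neg <- P[z[P] <= tol]
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio <- ratio[is.finite(ratio)]
      alpha <- if (length(ratio)) min(ratio) else 0
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, gradient = w)
}

#' Refit a catalog against a fixed signature set (NNLS)
#'
#' For each sample, finds non-negative absolute contributions `e`
#' minimizing `||counts - P e||_2` where `P` is the column-stochastic
#' signature matrix. This is the standard signature refitting step used to
#' quantify the activity of known signatures in new samples.
#'
#' @param catalog 96 x S count matrix (canonical row order).
#' @param signatures 96 x K column-stochastic signature matrix.
#' @return K x S exposure matrix of absolute contributions (>= 0).
#' @export
refit_nnls <- function(catalog, signatures) {
  if (!identical(rownames(catalog), rownames(signatures))) {
    if (!is.null(rownames(catalog)) && !is.null(rownames(signatures)) &&
        setequal(rownames(catalog), rownames(signatures))) {
      signatures <- signatures[rownames(catalog), , drop = FALSE]
    } else if (nrow(catalog) != nrow(signatures)) {
      stop("catalog and signatures have incompatible rows")
    }
  }
  csum <- colSums(signatures)
  if (any(abs(csum - 1) > 1e-6)) {
    stop("signature columns must each sum to 1")
  }
  E <- matrix(0, ncol(signatures), ncol(catalog),
              dimnames = list(colnames(signatures), colnames(catalog)))
  for (s in seq_len(ncol(catalog))) {
    E[, s] <- nnls_solve(signatures, catalog[, s])$x
  }
  E
}

#' Relative signature contributions per sample
#'
#' @param exposures K x S matrix of absolute contributions.
#' @return K x S matrix whose columns sum to 1; columns of all-zero
#'   exposure are `NA` (flagged, not 0/0).
#' @export
relative_contribution <- function(exposures) {
  totals <- colSums(exposures)
  out <- sweep(exposures, 2L, ifelse(totals > 0, totals, NA_real_), "/")
  out
}

#' Difference between two mutation spectra
#'
#' @param p,q 96-class probability vectors (each summing to 1 within 1e-6).
#' @return `p - q`: a signed vector summing to 0, positive where the first
#'   spectrum has excess probability mass.
#' @export
difference_spectrum <- function(p, q) {
  if (length(p) != length(q)) stop("spectra differ in length")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("spectra must each be normalized to sum 1")
  }
  p - q
}

#' Two-group cohort contrast (Wilcoxon rank-sum)
#'
#' Exact two-sided test when the combined size is at most 25 and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `p.value`, `median_x`, `median_y`, `exact`.
#' @export
cohort_contrast <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 25L && !ties
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(p.value = wt$p.value, median_x = stats::median(x),
       median_y = stats::median(y), exact = exact)
}

#' Write / read a signature probability matrix as TSV
#'
#' Layout: 96 labeled rows (first column `MutationType`) and one column per
#' signature. COSMIC-style downloads with a leading type column under a
#' different header are accepted on read.
#'
#' @param signatures 96 x K column-stochastic matrix.
#' @param path TSV path.
#' @export
write_signatures <- function(signatures, path) {
  df <- data.frame(MutationType = rownames(signatures), signatures,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  label_col <- which(vapply(df, function(x) {
    is.character(x) && all(grepl("^.\\[.>.\\].$", x))
  }, TRUE))[1L]
  if (is.na(label_col)) {
    stop("no mutation-type label column (values like 'A[C>A]A') found")
  }
  rest <- df[, -label_col, drop = FALSE]
  mat <- as.matrix(rest[, vapply(rest, is.numeric, TRUE), drop = FALSE])
  rownames(mat) <- df[[label_col]]
  types <- mut_types_96()
  if (!setequal(rownames(mat), types)) {
    stop("signature rows are not the 96 canonical mutation types")
  }
  mat[types, , drop = FALSE]
}
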