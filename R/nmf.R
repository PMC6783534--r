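#' Non-negative matrix factorization of a mutation catalog
#'
#' Factorizes a non-negative catalog `V` (96 x S) into signatures `W`
#' (96 x K, column-stochastic) and exposures `H` (K x S, absolute counts)
#' by minimizing the generalized Kullback-Leibler divergence
#' `D(V || WH) = sum(V * log(V / WH) - V + WH)` with multiplicative
#' updates (Brunet-style). A Frobenius (Euclidean) variant is available
#' via `objective = "frobenius"`.
#'
#' After convergence `W` is rescaled so that each column sums to 1, with
#' the compensating scale moved into `H`, so `W %*% H` is unchanged and
#' `H` is interpretable as absolute mutation contributions.
#'
#' @param catalog non-negative 96 x S matrix (at least one positive entry).
#' @param rank number of signatures K, `1 <= K <= min(dim(catalog))`.
#' @param seed integer seed for the uniform(0, 1] initialization.
#' @param max_iter maximum multiplicative updates (default 10000).
#' @param tol relative change in the objective below which iteration stops
#'   (default 1e-6).
#' @param objective `"kl"` (default) or `"frobenius"`.
#' @return list of class `"nmf_result"` with elements `W`, `H`,
#'   `objective_trace` (non-increasing), `converged`, `iterations`,
#'   `rank`, `seed`, `objective`.
#' @export
nmf_factorize <- function(catalog, rank, seed = 1L, max_iter = 10000L,
                          tol = 1e-6, objective = c("kl", "frobenius")) {
  objective <- match.arg(objective)
  V <- as.matrix(catalog)
  if (any(V < 0)) stop("catalog must be non-negative")
  if (all(V == 0)) stop("catalog is all zero")
  if (rank < 1L || rank > min(dim(V))) {
    stop("rank must be between 1 and min(dim(catalog))")
  }
  eps <- .Machine$double.eps
  set.seed(seed)
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * rank, min = eps, max = 1), n, rank)
  H <- matrix(stats::runif(rank * m, min = eps, max = 1), rank, m)

  kl_div <- function(V, WH) {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }
  obj_fun <- if (objective == "kl") {
    function(V, WH) kl_div(V, WH)
  } else {
    function(V, WH) 0.5 * sum((V - WH)^2)
  }

  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (objective == "kl") {
      WH <- pmax(W %*% H, eps)
      H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
      WH <- pmax(W %*% H, eps)
      W <- W * ((V / WH) %*% t(H)) / pmax(
        matrix(rowSums(H), n, rank, byrow = TRUE), eps
      )
    } else {
      H <- H * (t(W) %*% V) / pmax(t(W) %*% W %*% H, eps)
      W <- W * (V %*% t(H)) / pmax(W %*% (H %*% t(H)), eps)
    }
    cur <- obj_fun(V, pmax(W %*% H, eps))
    trace <- c(trace, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(abs(prev), eps)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  scale <- colSums(W)
  scale[scale == 0] <- 1
  W <- sweep(W, 2L, scale, "/")
  H <- H * scale  # scale recycles down columns: row k of H times scale[k]
  sig_ids <- paste0("denovo_", seq_len(rank))
  dimnames(W) <- list(rownames(catalog), sig_ids)
  dimnames(H) <- list(sig_ids, colnames(catalog))
  structure(
    list(W = W, H = H, objective_trace = trace, converged = converged,
         iterations = it, rank = rank, seed = seed, objective = objective),
    class = "nmf_result"
  )
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf(
    "NMF result: rank %d, %d iteration(s), %sconverged, final %s = %.6g\n",
    x$rank, x$iterations, if (x$converged) "" else "NOT ",
    x$objective, utils::tail(x$objective_trace, 1L)
  ))
  if (!is.null(x$cophenetic)) {
    cat(sprintf("consensus over %d run(s), cophenetic = %.4f\n",
                x$n_runs, x$cophenetic))
  }
  invisible(x)
}

sample_assignment <- function(H) {
  # dominant signature per sample; ties broken toward the lowest index
  apply(H, 2L, which.max)
}

#' Consensus NMF with cophenetic correlation
#'
#' Runs `n_runs` seeded NMF factorizations from random initializations.
#' Samples are co-clustered by their dominant (argmax-exposure) signature;
#' `consensus[i, j]` is the fraction of runs in which samples i and j share
#' a dominant signature. The cophenetic correlation is the correlation
#' between the consensus dissimilarities (1 - consensus) and the
#' cophenetic distances of their average-linkage dendrogram, a standard
#' stability score for choosing the factorization rank.
#'
#' @inheritParams nmf_factorize
#' @param n_runs number of random restarts (>= 2; 100 is conventional).
#' @param ... passed on to [nmf_factorize()].
#' @return the best-objective `nmf_result`, augmented with `consensus`
#'   (S x S, symmetric, unit diagonal), `cophenetic` and `n_runs`.
#' @export
consensus_cophenetic <- function(catalog, rank, n_runs = 100L, seed = 1L,
                                 ...) {
  if (n_runs < 2L) stop("n_runs must be at least 2")
  S <- ncol(catalog)
  co <- matrix(0, S, S)
  best <- NULL
  best_obj <- Inf
  for (r in seq_len(n_runs)) {
    fit <- nmf_factorize(catalog, rank, seed = seed + r - 1L, ...)
    a <- sample_assignment(fit$H)
    co <- co + outer(a, a, "==")
    obj <- utils::tail(fit$objective_trace, 1L)
    if (obj < best_obj) {
      best_obj <- obj
      best <- fit
    }
  }
  consensus <- co / n_runs
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(catalog), colnames(catalog))
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) {
    warning("degenerate consensus (all samples always co-cluster); ",
            "cophenetic reported as 1")
    coph <- 1
  } else {
    hc <- stats::hclust(d, method = "average")
    coph <- stats::cor(d, stats::cophenetic(hc))
  }
  best$consensus <- consensus
  best$cophenetic <- coph
  best$n_runs <- n_runs
  best
}

#' Scan factorization ranks by cophenetic correlation
#'
#' Computes the consensus cophenetic correlation for each candidate rank
#' and suggests the largest rank whose cophenetic is at least 0.95 before
#' the first drop greater than 0.05. The suggestion is advisory: headline
#' analyses should fix the rank explicitly after inspecting the table.
#'
#' @inheritParams consensus_cophenetic
#' @param rank_range integer vector of candidate ranks (increasing).
#' @return list with `table` (data.frame of rank and cophenetic) and
#'   `suggested` rank.
#' @export
select_rank <- function(catalog, rank_range, n_runs = 30L, seed = 1L, ...) {
  rank_range <- sort(unique(as.integer(rank_range)))
  coph <- vapply(rank_range, function(k) {
    consensus_cophenetic(catalog, k, n_runs = n_runs,
                         seed = seed + 1000L * k, ...)$cophenetic
  }, numeric(1L))
  tab <- data.frame(rank = rank_range, cophenetic = coph)
  if (length(rank_range) == 1L) {
    return(list(table = tab, suggested = rank_range))
  }
  drops <- which(diff(coph) < -0.05)
  candidates <- if (length(drops)) seq_len(drops[1L]) else seq_along(coph)
  good <- candidates[coph[candidates] >= 0.95]
  if (length(good)) {
    suggested <- rank_range[max(good)]
    if (!length(drops) && all(coph >= 0.95)) {
      warning("cophenetic is high across the whole range; ",
              "suggestion defaults to the largest rank")
    }
  } else {
    suggested <- rank_range[which.max(coph)]
    warning("no rank reaches cophenetic 0.95; ",
            "suggesting the rank with the highest value")
  }
  list(table = tab, suggested = suggested)
}
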