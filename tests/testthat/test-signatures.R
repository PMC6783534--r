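test_that("cosine similarity matches hand values and is scale-invariant", {
  expect_equal(cosine_sim(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_sim(c(1, 0, 0), c(0, 1, 1)), 0)
  a <- c(1, 2, 2, rep(0, 93)); b <- c(2, 1, 2, rep(0, 93))
  expect_equal(cosine_sim(a, b), 8 / 9)
  expect_equal(cosine_sim(5 * a, 0.1 * b), 8 / 9)
  expect_error(cosine_sim(a, rep(0, 96)), "zero")
})

test_that("reference matching returns argmax matches and full scores", {
  ref <- planted_signature_trio()
  m <- match_to_reference(ref, ref)
  expect_identical(m$matches$best_match, colnames(ref))
  expect_equal(m$matches$cosine, rep(1, 3))
  expect_identical(dim(m$scores), c(3L, 3L))
  # order mismatch is an error
  shuffled <- ref[c(2:96, 1), ]
  expect_error(match_to_reference(ref, shuffled), "order")
  # single-column reference: everything maps to it
  single <- ref[, 1, drop = FALSE]
  expect_identical(unique(match_to_reference(ref, single)$matches$best_match),
                   "sig17like")
})

test_that("NNLS is exact on noiseless mixtures and KKT-optimal", {
  sigs <- planted_signature_trio()
  e_true <- c(200, 100, 50)
  b <- drop(sigs %*% e_true)
  fit <- nnls_solve(sigs, b)
  expect_equal(fit$x, e_true, tolerance = 1e-9)
  # zero sample -> zero exposures
  expect_equal(nnls_solve(sigs, rep(0, 96))$x, rep(0, 3))

  # KKT on a clipped problem: active gradient ~ 0, zero components <= 0
  b2 <- drop(sigs %*% c(300, 0, 0)) - 0.5 * sigs[, 2]
  f2 <- nnls_solve(sigs, pmax(b2, 0))
  act <- f2$x > 1e-8
  expect_true(all(abs(f2$gradient[act]) < 1e-6))
  expect_true(all(f2$gradient[!act] < 1e-6))
})

test_that("NNLS agrees with a brute-force grid oracle on 2-signature toys", {
  sigs <- planted_signature_trio()[, 1:2]
  set.seed(41)
  for (rep in 1:3) {
    e <- stats::runif(2, 0, 1)
    counts <- drop(sigs %*% e) + stats::runif(96, 0, 0.02)
    fit <- nnls_solve(sigs, counts)
    obj <- function(x) sum((counts - drop(sigs %*% x))^2)
    # exhaustive grid with step 0.01 over [0, 2]^2
    grid <- seq(0, 2, by = 0.01)
    grid_best <- Inf
    for (g1 in grid) {
      resid <- counts - g1 * sigs[, 1]
      vals <- vapply(grid, function(g2) sum((resid - g2 * sigs[, 2])^2),
                     numeric(1))
      grid_best <- min(grid_best, min(vals))
    }
    expect_lte(obj(fit$x), grid_best + 1e-12)
  }
})

test_that("NNLS solution matches an independent solver", {
  skip_if_not_installed("pracma")
  sigs <- planted_signature_trio()
  set.seed(42)
  for (rep in 1:5) {
    counts <- stats::rpois(96, 30)
    ours <- nnls_solve(sigs, counts)$x
    theirs <- pracma::lsqnonneg(sigs, counts)$x
    expect_equal(ours, theirs, tolerance = 1e-6)
  }
})

test_that("refitting recovers exact exposures and flags zero samples", {
  sigs <- planted_signature_trio()
  E <- matrix(c(500, 200, 100, 0, 0, 0), 3, 2,
              dimnames = list(colnames(sigs), c("s1", "s0")))
  catalog <- sigs %*% E
  rownames(catalog) <- rownames(sigs)
  Eh <- refit_nnls(catalog, sigs)
  expect_equal(Eh[, "s1"], E[, "s1"], tolerance = 1e-6)
  expect_equal(unname(Eh[, "s0"]), rep(0, 3))

  rel <- relative_contribution(Eh)
  expect_equal(sum(rel[, "s1"]), 1)
  expect_true(all(is.na(rel[, "s0"])))
  expect_equal(unname(relative_contribution(
    matrix(c(300, 700), 2, 1))[, 1]), c(0.3, 0.7))
})

test_that("NMF reconstructs an exactly low-rank matrix", {
  sigs <- planted_signature_trio()[, 1, drop = FALSE]
  V <- sigs %*% matrix(c(1000, 2000, 500), 1, 3)
  rownames(V) <- rownames(sigs)
  fit <- nmf_factorize(V, 1, seed = 8)
  rel_err <- norm(V - fit$W %*% fit$H, "F") / norm(V, "F")
  expect_lt(rel_err, 1e-6)
  # W column-stochastic, scale absorbed by H
  expect_equal(colSums(fit$W), c(denovo_1 = 1))
})

test_that("NMF objective is non-increasing and factors stay non-negative", {
  set.seed(9)
  V <- matrix(rpois(96 * 10, 20), 96, 10,
              dimnames = list(mut_types_96(), paste0("s", 1:10)))
  fit <- nmf_factorize(V, 3, seed = 10)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))
  # reconstruction identity after normalization
  fit2 <- nmf_factorize(V, 3, seed = 10)
  expect_equal(fit$W %*% fit$H, fit2$W %*% fit2$H)
})

test_that("NMF input validation", {
  V <- matrix(1, 96, 4)
  expect_error(nmf_factorize(V, 5), "rank")
  expect_error(nmf_factorize(matrix(0, 96, 4), 2), "zero")
  expect_error(nmf_factorize(-V, 2), "non-negative")
})

test_that("planted signatures are recovered from a synthetic catalog", {
  sigs <- planted_signature_trio()
  set.seed(20)
  mix <- matrix(rgamma(3 * 30, 2), 3, 30)
  mix <- sweep(mix, 2, colSums(mix), "/")
  E <- mix * 5000
  dimnames(E) <- list(colnames(sigs), paste0("s", 1:30))
  catalog <- sample_catalog(sigs, E, seed = 21)
  best <- NULL; best_obj <- Inf
  for (r in 1:4) {
    f <- nmf_factorize(catalog, 3, seed = 30 + r)
    o <- utils::tail(f$objective_trace, 1)
    if (o < best_obj) { best_obj <- o; best <- f }
  }
  m <- match_to_reference(best$W, sigs)
  expect_identical(sort(m$matches$best_match), sort(colnames(sigs)))
  expect_true(all(m$matches$cosine >= 0.95))
})

test_that("consensus is symmetric with unit diagonal; separable data give
           cophenetic ~ 1", {
  sigs <- planted_signature_trio()[, 1:2]
  # two clean blocks of samples, one signature each
  E <- cbind(matrix(rep(c(2000, 0), 6), 2), matrix(rep(c(0, 2000), 6), 2))
  dimnames(E) <- list(colnames(sigs), paste0("s", 1:12))
  catalog <- sample_catalog(sigs, E, seed = 50)
  fit <- consensus_cophenetic(catalog, 2, n_runs = 8, seed = 51)
  expect_true(isSymmetric(fit$consensus))
  expect_equal(unname(diag(fit$consensus)), rep(1, 12))
  expect_gte(fit$cophenetic, 0.99)
  expect_error(consensus_cophenetic(catalog, 2, n_runs = 1), "at least 2")
})

test_that("cophenetic scan suggests the planted rank", {
  # noisy balanced mixtures destabilize over-factorization: the
  # cophenetic stays ~1 up to the planted rank 3 and drops beyond it
  sigs <- planted_signature_trio()
  set.seed(300)
  mix <- matrix(rgamma(3 * 30, 3), 3, 30)
  mix <- sweep(mix, 2, colSums(mix), "/")
  E <- mix * 200
  dimnames(E) <- list(colnames(sigs), paste0("s", 1:30))
  catalog <- sample_catalog(sigs, E, seed = 301)
  sel <- select_rank(catalog, 2:6, n_runs = 20, seed = 302)
  expect_identical(sel$suggested, 3L)
  expect_gte(sel$table$cophenetic[sel$table$rank == 3], 0.95)
  expect_lt(sel$table$cophenetic[sel$table$rank == 4],
            sel$table$cophenetic[sel$table$rank == 3])
})

test_that("rank scan handles the single-rank and flat-curve cases", {
  sigs <- planted_signature_trio()[, 1:2]
  E <- cbind(matrix(rep(c(2000, 0), 4), 2), matrix(rep(c(0, 2000), 4), 2))
  dimnames(E) <- list(colnames(sigs), paste0("s", 1:8))
  catalog <- sample_catalog(sigs, E, seed = 60)
  one <- select_rank(catalog, 2, n_runs = 4, seed = 61)
  expect_identical(one$suggested, 2L)
  expect_identical(nrow(one$table), 1L)
})

test_that("difference spectra are antisymmetric and zero-sum", {
  p <- c(0.5, 0.3, 0.2, rep(0, 93))
  q <- c(0.2, 0.3, 0.5, rep(0, 93))
  d <- difference_spectrum(p, q)
  expect_equal(d[1:3], c(0.3, 0, -0.3))
  expect_equal(sum(d), 0, tolerance = 1e-9)
  expect_equal(difference_spectrum(q, p), -d)
  expect_equal(difference_spectrum(p, p), rep(0, 96))
  expect_error(difference_spectrum(p * 2, q), "normalized")
})

test_that("cohort contrast: exact rank-sum for small untied groups", {
  res <- cohort_contrast(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p.value, 0.1)   # 2/20 per tail, doubled
  expect_identical(res$median_x, 2)
  sym <- cohort_contrast(c(1, 3, 5), c(2, 4, 6))
  expect_gt(sym$p.value, 0.5)
  expect_error(cohort_contrast(numeric(0), 1), "non-empty")
})

test_that("shifted groups are detected in most seeded replicates", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(50)
    y <- rnorm(50, mean = 1)   # shift of 1 SD
    cohort_contrast(x, y)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("signature TSV round trip preserves order and values", {
  sigs <- planted_signature_trio()
  path <- tempfile(fileext = ".tsv")
  write_signatures(sigs, path)
  back <- read_signatures(path)
  expect_equal(back, sigs, tolerance = 1e-12)
  expect_identical(rownames(back), mut_types_96())
})
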