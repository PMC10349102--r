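test_that("Hungarian assignment equals exhaustive search", {
  set.seed(19)
  for (i in 1:100) {
    C <- matrix(runif(16), 4)
    got <- solveAssignment(C)
    oracle <- oracleAssignment(C)
    expect_equal(attr(got, "cost"), oracle$cost, tolerance = 1e-12)
  }
  for (i in 1:20) {
    C <- matrix(rnorm(25), 5)
    got <- solveAssignment(C)
    expect_equal(attr(got, "cost"), oracleAssignment(C)$cost,
                 tolerance = 1e-12)
  }
})

mkSolution <- function(means, seed = 1L) {
  n <- nrow(means)
  new("HMMSolution", n_states = as.integer(n), pi = rep(1 / n, n),
      Theta = matrix(1 / n, n, n), means = means,
      covariances = rep(list(diag(ncol(means))), n),
      gamma = matrix(1 / n, 10, n), log_likelihood = 0,
      loglik_trace = 0, seed = seed, iterations = 1L, converged = TRUE)
}

test_that("state alignment recovers exact permutations", {
  set.seed(20)
  mu <- matrix(rnorm(4 * 6), 4)
  tmpl <- mkSolution(mu)
  # self-match: identity, zero cost
  al <- alignStates(tmpl, tmpl)
  expect_equal(al$permutation, 1:4)
  expect_equal(al$cost, 0)
  # permuted copy: inverse permutation, zero cost
  rho <- c(2L, 4L, 1L, 3L)
  other <- mkSolution(mu[rho, ])    # other's state k is template rho[k]
  al2 <- alignStates(tmpl, other)
  expect_equal(al2$permutation, rho)
  expect_equal(al2$cost, 0, tolerance = 1e-12)
  # matches brute-force search on random model pairs
  for (i in 1:25) {
    a <- mkSolution(matrix(rnorm(24), 4))
    b <- mkSolution(matrix(rnorm(24), 4))
    cost <- outer(1:4, 1:4, Vectorize(function(k, l)
      sqrt(sum((stateMeans(b)[k, ] - stateMeans(a)[l, ])^2))))
    expect_equal(alignStates(a, b)$cost, oracleAssignment(cost)$cost,
                 tolerance = 1e-12)
  }
  expect_error(alignStates(tmpl, mkSolution(matrix(0, 3, 6))),
               "equal state counts")
})

test_that("partitioning routes every timepoint to its hard state", {
  set.seed(21)
  g <- matrix(rexp(80 * 4), 80); g <- g / rowSums(g)
  X <- matrix(rnorm(80 * 3), 80)
  parts <- partitionByState(g, X)
  expect_equal(sum(vapply(parts, function(p) nrow(p$block),
                          integer(1))), 80L)
  hs <- hardAssign(g)
  for (k in 1:4) {
    expect_equal(parts[[k]]$rows, which(hs == k))
    expect_equal(parts[[k]]$block, X[hs == k, , drop = FALSE])
  }
  # single-state sequence: one partition holds everything
  parts1 <- partitionByState(rep(1L, 30), X[1:30, ])
  expect_equal(nrow(parts1[[1]]$block), 30L)
})

test_that("group concatenation stacks subjects in order", {
  X1 <- matrix(1, 10, 2); X2 <- matrix(2, 15, 2)
  E1 <- matrix(1, 10, 3); E2 <- matrix(2, 15, 3)
  bp <- list(list(list(rows = 1:10, block = X1)),
             list(list(rows = 1:15, block = X2)))
  dp <- list(list(list(rows = 1:10, block = E1)),
             list(list(rows = 1:15, block = E2)))
  g <- concatGroup(bp, dp)
  expect_equal(nrow(g[[1]]$G), 25L)
  expect_equal(nrow(g[[1]]$E), nrow(g[[1]]$G))
  expect_equal(g[[1]]$subject, rep(1:2, c(10, 15)))
  # column mismatch is a schema error
  bp2 <- list(bp[[1]], list(list(rows = 1:15,
                                 block = matrix(2, 15, 3))))
  expect_error(concatGroup(bp2, dp), "column layouts")
})

test_that("one-component PLS finds the dominant cross-covariance pair", {
  set.seed(22)
  # noiseless rank-1 link through a single informative column; the
  # other columns are orthogonalized so one PLS component captures the
  # link exactly
  x1 <- rnorm(20)
  x2 <- resid(lm(rnorm(20) ~ x1))
  x3 <- resid(lm(rnorm(20) ~ x1 + x2))
  E <- cbind(x1, x2, x3)
  b <- c(1, 0, 0)
  G <- cbind(E %*% b, (E %*% b) * 0.5)
  sig <- fitPls1(E, G, standardize_E = FALSE)
  expect_gt(cor(sig@scores_E, sig@scores_G), 1 - 1e-8)
  # centered scores
  expect_lt(abs(mean(sig@scores_E)), 1e-10)
  expect_lt(abs(mean(sig@scores_G)), 1e-10)

  # weight pair equals the dominant singular vectors of centered E'G
  E2 <- matrix(rnorm(6 * 3), 6)
  G2 <- matrix(rnorm(6 * 2), 6)
  sig2 <- fitPls1(E2, G2, standardize_E = FALSE)
  C <- crossprod(sweep(E2, 2, colMeans(E2)),
                 sweep(G2, 2, colMeans(G2)))
  sv <- svd(C)
  w <- sv$u[, 1]; cc <- sv$v[, 1]
  if (w[which.max(abs(w))] < 0) { w <- -w; cc <- -cc }
  expect_equal(sig2@description_loadings, w, tolerance = 1e-8)
  expect_equal(sig2@brain_loadings, cc, tolerance = 1e-8)

  # optimality: training covariance beats 1000 random unit pairs
  set.seed(23)
  E3 <- matrix(rnorm(40 * 5), 40)
  G3 <- matrix(rnorm(40 * 4), 40)
  sig3 <- fitPls1(E3, G3, standardize_E = FALSE)
  best <- abs(mean(sig3@scores_E * sig3@scores_G))
  Ec <- sweep(E3, 2, colMeans(E3)); Gc <- sweep(G3, 2, colMeans(G3))
  for (i in 1:1000) {
    wr <- rnorm(5); wr <- wr / sqrt(sum(wr^2))
    cr <- rnorm(4); cr <- cr / sqrt(sum(cr^2))
    expect_lte(abs(mean((Ec %*% wr) * (Gc %*% cr))), best + 1e-10)
  }
  expect_error(fitPls1(E3[1:2, ], G3[1:2, ]), "at least 3")
})

test_that("blocked cross-validation generalizes a planted signature", {
  set.seed(24)
  N <- 2100; P <- 8; R <- 5
  subj <- rep(1:3, each = 700)
  E <- matrix(rnorm(N * P), N)
  w0 <- rnorm(P); w0 <- w0 / sqrt(sum(w0^2))
  c0 <- rnorm(R); c0 <- c0 / sqrt(sum(c0^2))
  G <- (E %*% w0) %*% t(c0) + 0.2 * matrix(rnorm(N * R), N)
  sig <- crossvalPls(E, G, subj, n_folds = 20)
  expect_length(sig@cv_correlations, 20L)
  expect_gte(sig@cv_mean, 0.9)
  expect_gte(abs(cor(sig@brain_loadings, c0)), 0.95)
  # row-shuffled descriptions: no held-out association
  sh <- sample(N)
  sig0 <- crossvalPls(E[sh, ], G, subj, n_folds = 20)
  expect_lte(abs(sig0@cv_mean), 0.1)
  # warns when a subject has fewer rows than folds
  expect_warning(
    crossvalPls(E[1:50, ], G[1:50, ], c(rep(1, 45), rep(2, 5)),
                n_folds = 10),
    "fewer rows")
  expect_error(crossvalPls(E[1:10, ], G[1:10, ], rep(1, 10),
                           n_folds = 20), "too few rows")
})

test_that("signature reports name top contributors per category", {
  set.seed(25)
  gt <- gtSmall()
  ctxs <- contextsSmall()
  s <- ncol(contextExpressions(ctxs))
  A <- 6
  meta <- data.frame(name = sprintf("a%d", 1:A),
                     category = rep(c("emotion", "place", "other"), 2),
                     kind = "binary")
  pca <- fitLimbicPca(matrix(rnorm(200), 40), matrix(rnorm(200), 40),
                      n_pc = 3)$model
  sig <- new("GroupSignature", state = 1L,
             description_loadings = rnorm(s + A),
             brain_loadings = rnorm(6 + 6),
             scores_E = numeric(0), scores_G = numeric(0),
             covariance_explained = 1,
             cv_correlations = numeric(0), cv_mean = NA_real_)
  rep1 <- signatureReport(sig, ctxs, meta, pca_model = pca, top_k = 3)
  expect_length(rep1$top_contexts, 3L)
  expect_length(rep1$top_contexts[[1]]$words, 5L)
  # category partition covers all A entries exactly once
  expect_equal(sum(vapply(rep1$top_annotations, nrow, integer(1))), A)
  # limbic block length = 2 x subregions per hemisphere
  expect_length(rep1$limbic_subregion_loadings, 10L)
  expect_length(rep1$parcel_loadings, 6L)
  # top_k saturation
  rep2 <- signatureReport(sig, ctxs, meta, pca_model = pca,
                          top_k = 100)
  expect_length(rep2$top_contexts, s)
  expect_error(signatureReport(sig, ctxs, meta[1:2, ], pca_model = pca),
               "inconsistent")
})
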