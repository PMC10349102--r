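test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(21)
  for (i in 1:20) {
    pi <- runif(2); pi <- pi / sum(pi)
    Theta <- matrix(runif(4, 0.05, 1), 2)
    Theta <- Theta / rowSums(Theta)
    means <- matrix(rnorm(2 * 2), 2)
    sds <- c(1, 1)
    X <- matrix(rnorm(3 * 2), 3)
    fb <- forwardBackward(X, pi, Theta, means,
                          list(diag(2), diag(2)))
    oracle <- oracleForwardBackward(X, pi, Theta, means, sds)
    expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(fb$log_likelihood, oracle$log_likelihood,
                 tolerance = 1e-10)
  }
})

test_that("forward-backward degenerate cases behave analytically", {
  set.seed(2)
  X <- matrix(rnorm(50 * 3), 50)
  # single state: gamma all ones, LL is the plain Gaussian log-density
  fb1 <- forwardBackward(X, 1, matrix(1, 1, 1),
                         matrix(0, 1, 3), list(diag(3)))
  expect_equal(unname(fb1$gamma[, 1]), rep(1, 50))
  expect_equal(fb1$log_likelihood, sum(dnorm(X, log = TRUE)),
               tolerance = 1e-10)
  # identical emissions + uniform pi, Theta: gamma = 1/n everywhere
  fb2 <- forwardBackward(X, rep(1 / 3, 3), matrix(1 / 3, 3, 3),
                         matrix(0, 3, 3, byrow = TRUE),
                         rep(list(diag(3)), 3))
  expect_equal(unname(fb2$gamma), matrix(1 / 3, 50, 3),
               tolerance = 1e-12)
  # gamma rows always sum to one
  expect_true(all(abs(rowSums(fb2$gamma) - 1) <= 1e-8))
  # non-SPD covariance is rejected
  expect_error(forwardBackward(X, 1, matrix(1, 1, 1), matrix(0, 1, 3),
                               list(-diag(3))), "positive definite")
})

test_that("single-state EM reduces to the closed-form Gaussian fit", {
  set.seed(4)
  X <- matrix(rnorm(500 * 2), 500) %*% matrix(c(1, 0.4, 0, 0.8), 2)
  sol <- fitHmmEm(X, 1, seed = 1, max_iter = 10)
  expect_equal(unname(stateMeans(sol)[1, ]), unname(colMeans(X)),
               tolerance = 1e-8)
  S <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  ridge <- 1e-6 * mean(apply(X, 2, var) * (nrow(X) - 1) / nrow(X))
  expect_equal(unname(stateCovariances(sol)[[1]]),
               unname(S + diag(ridge, 2)), tolerance = 1e-8)
})

test_that("EM recovers a well-separated 2-state chain", {
  set.seed(2)
  T <- 2000
  z <- integer(T); z[1] <- 1
  for (t in 2:T) z[t] <- if (runif(1) < 0.9) z[t - 1] else 3 - z[t - 1]
  X <- matrix(rnorm(T * 3), T) + outer(ifelse(z == 1, -5, 5), rep(1, 3))
  sol <- fitHmmEm(X, 2, seed = 5)
  hard <- hardAssign(statePresence(sol))
  expect_gte(matchedAccuracy(hard, z, 2), 0.98)
  expect_true(all(diag(transitionMatrix(sol)) >= 0.87 &
                  diag(transitionMatrix(sol)) <= 0.93))
  # log-likelihood trace is monotone nondecreasing
  expect_true(all(diff(sol@loglik_trace) >= -1e-8))
  # constant input converges with a warning, not a crash
  expect_warning(fitHmmEm(matrix(1, 50, 2), 2, seed = 1, max_iter = 5),
                 "constant")
})

test_that("EM is a near fixed point at the generating parameters", {
  gt <- gtSmall()
  # long series so the finite-sample refit gain (~p/2 log-lik units) is
  # small relative to the data log-likelihood
  sim <- simulateCombinationSeries(gt, "DN&HC", seed = 5, T = 20000)
  p <- gt@hmm_params[["DN&HC"]]
  sol <- fitHmmEm(sim$series, 4, max_iter = 10, tol = 0,
                  init = list(pi = p$pi, Theta = p$Theta,
                              means = p$means,
                              covariances = p$covariances))
  tr <- sol@loglik_trace[1:10]
  expect_lt(abs(tr[10] - tr[1]) / abs(tr[1]), 0.001)
})

test_that("hard assignment is the row argmax with low-index ties", {
  g <- rbind(c(0, 1, 0), c(1, 0, 0), c(1/3, 1/3, 1/3))
  expect_equal(hardAssign(g), c(2L, 1L, 1L))
  set.seed(9)
  G <- matrix(rexp(100 * 4), 100)
  G <- G / rowSums(G)
  expect_equal(hardAssign(G),
               apply(G, 1, function(r) which(r == max(r))[1]))
})

test_that("BIC applies the stated parameter count and penalty", {
  mk <- function(n, R, ll, T) {
    new("HMMSolution", n_states = as.integer(n),
        pi = rep(1 / n, n),
        Theta = matrix(1 / n, n, n),
        means = matrix(0, n, R),
        covariances = rep(list(diag(R)), n),
        gamma = matrix(1 / n, T, n), log_likelihood = ll,
        loglik_trace = ll, seed = 1L, iterations = 1L,
        converged = TRUE)
  }
  # n = 1, R = 1: p = 2
  expect_equal(bicHmm(mk(1, 1, -100, 50)), 200 + 2 * log(50))
  # penalty is monotone in p at fixed log-likelihood
  expect_lt(bicHmm(mk(2, 3, -100, 50)), bicHmm(mk(4, 3, -100, 50)))
  # parsimony wins on single-Gaussian data
  set.seed(6)
  X <- matrix(rnorm(1000 * 2), 1000)
  s1 <- fitHmmEm(X, 1, seed = 1)
  s4 <- fitHmmEm(X, 4, seed = 1)
  expect_lt(bicHmm(s1), bicHmm(s4))
})

test_that("multi-restart selection honors its argmax contract", {
  set.seed(8)
  X <- matrix(rnorm(200 * 2), 200)
  W <- matrix(runif(200 * 30), 200)
  single <- fitHmmEm(X, 2, seed = nbstates:::.subSeed(3, 1))
  mr <- multiRestartFit(X, 2, W, n_restarts = 1, seed = 3)
  expect_equal(statePresence(mr), statePresence(single))
  expect_equal(modelLogLik(mr), modelLogLik(single))

  mr5 <- multiRestartFit(X, 2, W, n_restarts = 5, seed = 3)
  idx <- attr(mr5, "restart_indices")
  expect_length(idx, 5)
  expect_equal(attr(mr5, "link_index"), max(idx))
  expect_gte(attr(mr5, "link_index"), median(idx))
})

test_that("relabeling states leaves likelihood and partition invariant", {
  sim <- combinationSmall()
  sol <- fitHmmEm(sim$series[1:600, ], 4, seed = 2)
  perm <- c(3L, 1L, 4L, 2L)
  rel <- applyAlignment(sol, perm)
  expect_equal(modelLogLik(rel), modelLogLik(sol))
  expect_equal(perm[hardAssign(statePresence(sol))],
               hardAssign(statePresence(rel)))
})

test_that("state-count selection by BIC finds the planted four states", {
  sim <- combinationSmall()
  W <- contextExpressions(contextsSmall())
  sel <- selectNStates(sim$series, W, candidates = 2:8,
                       n_restarts = 5, seed = 6, limbic_cols = 7:12)
  expect_equal(nrow(sel$table), 7L)
  expect_equal(sel$selected, 4L)
  expect_equal(which.min(sel$table$bic_no_limbic), 3L)  # n = 4 row
  # singleton range is forced
  sel1 <- selectNStates(sim$series[1:400, ], W[1:400, ],
                        candidates = 3L, n_restarts = 2, seed = 1)
  expect_equal(sel1$selected, 3L)
  expect_error(selectNStates(sim$series, W, candidates = integer(0)),
               "nonempty")
})
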