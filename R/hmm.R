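## Multivariate-Gaussian-emission hidden Markov modeling: exact
## forward-backward inference, Baum-Welch EM, multi-restart training with
## semantic-link selection, and BIC-based state-count selection.

# log N(x; mu, Sigma) for every row of X, via the Cholesky factor
.mvnLogDensity <- function(X, mu, Sigma) {
  R <- ncol(X)
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop("covariance matrix is not positive definite"))
  centered <- sweep(X, 2, mu)
  z <- centered %*% backsolve(ch, diag(R))
  q <- rowSums(z^2)
  -0.5 * (R * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

.logEmissions <- function(X, means, covariances) {
  n <- nrow(means)
  logB <- matrix(0, nrow(X), n)
  for (k in seq_len(n))
    logB[, k] <- .mvnLogDensity(X, means[k, ], covariances[[k]])
  logB
}

#' Forward-backward inference for a Gaussian-emission HMM
#'
#' Computes the exact posterior state-presence probabilities
#' `gamma[t, k] = P(S_t = k | data)` and the data log-likelihood under
#' fixed parameters, using per-step scaling so that sequences of
#' thousands of timepoints do not underflow.
#'
#' @param series numeric T x R observation matrix.
#' @param pi length-n initial state distribution.
#' @param Theta n x n row-stochastic transition matrix.
#' @param means n x R state mean matrix.
#' @param covariances list of n R x R SPD covariance matrices.
#' @return list with `gamma` (T x n), `xi_sum` (n x n summed pairwise
#'   posteriors) and `log_likelihood`.
#' @export
forwardBackward <- function(series, pi, Theta, means, covariances) {
  series <- as.matrix(series)
  n <- length(pi)
  stopifnot(all(dim(Theta) == c(n, n)),
            max(abs(rowSums(Theta) - 1)) < 1e-6,
            nrow(means) == n, length(covariances) == n)
  logB <- .logEmissions(series, means, covariances)
  .forwardBackwardCpp(logB, pi, Theta)
}

# k-means-style initialization: means seeded from random timepoints,
# shared sample covariance, near-uniform pi/Theta with self-transition
# prior mass.
.initHmm <- function(X, n_states, self_mass = 0.8) {
  T <- nrow(X); R <- ncol(X)
  idx <- sample.int(T, n_states)
  means <- X[idx, , drop = FALSE]
  S <- cov(X) * (T - 1) / T
  S <- S + diag(1e-6 * mean(diag(S)) + 1e-12, R)
  covariances <- rep(list(S), n_states)
  pi0 <- rep(1 / n_states, n_states)
  off <- (1 - self_mass) / max(n_states - 1, 1)
  Theta <- matrix(off, n_states, n_states)
  diag(Theta) <- if (n_states > 1) self_mass else 1
  list(pi = pi0, Theta = Theta, means = means, covariances = covariances)
}

#' Fit a Gaussian-emission HMM by expectation-maximization
#'
#' Baum-Welch EM with full state covariances, a small ridge on each
#' covariance (`1e-6` times the mean diagonal variance of the data) and a
#' relative log-likelihood convergence tolerance. The log-likelihood is
#' nondecreasing across iterations up to numerical slack.
#'
#' @param series numeric T x R observation matrix.
#' @param n_states number of hidden states.
#' @param seed integer seed controlling the random initialization.
#' @param max_iter EM iteration cap (default 500).
#' @param tol relative log-likelihood change below which EM stops.
#' @param init optional list(pi, Theta, means, covariances) to start from
#'   instead of the random initialization.
#' @return an [HMMSolution-class].
#' @export
fitHmmEm <- function(series, n_states, seed = 1L, max_iter = 500L,
                     tol = 1e-6, init = NULL) {
  X <- as.matrix(series)
  T <- nrow(X); R <- ncol(X)
  stopifnot(T > n_states, R >= 1)
  ridge <- 1e-6 * mean(apply(X, 2, var) * (T - 1) / T)
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-10
  par <- if (is.null(init)) {
    .withSeed(as.integer(seed), .initHmm(X, n_states))
  } else init
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  degenerate <- max(apply(X, 2, var)) < 1e-14
  if (degenerate)
    warning("constant input series: EM will converge degenerately")
  it <- 0L
  fb <- NULL
  while (it < max_iter) {
    it <- it + 1L
    logB <- .logEmissions(X, par$means, par$covariances)
    fb <- .forwardBackwardCpp(logB, par$pi, par$Theta)
    ll <- fb$log_likelihood
    trace <- c(trace, ll)
    if (is.finite(prev)) {
      if (abs(ll - prev) / max(abs(prev), 1) < tol) {
        converged <- TRUE
        break
      }
    }
    prev <- ll
    g <- fb$gamma
    Nk <- colSums(g)
    par$pi <- pmax(g[1, ], 1e-300)
    par$pi <- par$pi / sum(par$pi)
    Xi <- fb$xi_sum
    rs <- rowSums(Xi)
    Theta <- Xi / ifelse(rs > 0, rs, 1)
    Theta[rs <= 0, ] <- 1 / n_states
    par$Theta <- Theta
    for (k in seq_len(n_states)) {
      w <- g[, k] / max(Nk[k], 1e-300)
      mu <- colSums(X * w)
      cx <- sweep(X, 2, mu)
      S <- crossprod(cx * sqrt(w), cx * sqrt(w))
      par$means[k, ] <- mu
      par$covariances[[k]] <- S + diag(ridge, R)
    }
  }
  if (!converged) {
    # final E-step so posteriors match the returned parameters
    logB <- .logEmissions(X, par$means, par$covariances)
    fb <- .forwardBackwardCpp(logB, par$pi, par$Theta)
    trace <- c(trace, fb$log_likelihood)
  }
  new("HMMSolution", n_states = as.integer(n_states), pi = par$pi,
      Theta = par$Theta, means = par$means,
      covariances = par$covariances, gamma = fb$gamma,
      log_likelihood = fb$log_likelihood, loglik_trace = trace,
      seed = as.integer(seed), iterations = it, converged = converged)
}

#' Multi-restart HMM training with semantic-link selection
#'
#' Runs `n_restarts` independent EM fits from distinct random starts and
#' keeps the solution whose posterior state presence has the strongest
#' semantic linkage: the mean over states of the state's top-k mean
#' Pearson correlation with the supplied context-expression matrix.
#'
#' @param series numeric T x R observation matrix.
#' @param n_states number of hidden states.
#' @param contexts_W T x s context-expression matrix (`W` from NMF-LSA).
#' @param n_restarts number of random restarts (study protocol: 100).
#' @param seed base seed; each restart derives its own.
#' @param k top-k of the link statistic (default 10).
#' @param absolute use absolute instead of signed correlations in the
#'   selection index.
#' @param ... passed to [fitHmmEm()].
#' @return an [HMMSolution-class] with a `restart_indices` attribute
#'   logging every restart's link index.
#' @export
multiRestartFit <- function(series, n_states, contexts_W,
                            n_restarts = 100L, seed = 1L, k = 10L,
                            absolute = FALSE, ...) {
  stopifnot(nrow(as.matrix(contexts_W)) == nrow(as.matrix(series)))
  best <- NULL
  best_idx <- -Inf
  indices <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    sol <- fitHmmEm(series, n_states, seed = .subSeed(seed, r), ...)
    P <- correlationMatrix(statePresence(sol), contexts_W)
    if (absolute) P <- abs(P)
    indices[r] <- topKLinkStrength(P, k = k)$model_index
    if (indices[r] > best_idx) {
      best_idx <- indices[r]
      best <- sol
    }
  }
  attr(best, "restart_indices") <- indices
  attr(best, "link_index") <- best_idx
  best
}

#' Hard state assignment from posterior marginals
#'
#' @param gamma T x n posterior matrix (rows sum to 1).
#' @return integer vector of per-timepoint argmax states (1-based); ties
#'   resolve to the lowest state index.
#' @export
hardAssign <- function(gamma) {
  gamma <- as.matrix(gamma)
  max.col(gamma, ties.method = "first")
}

#' Bayesian information criterion of an HMM solution
#'
#' `BIC = -2 log L + p ln(T)` with
#' `p = (n - 1) + n(n - 1) + n (R + R(R + 1)/2)` free parameters (initial
#' distribution, transition matrix, means and symmetric covariances).
#'
#' @param solution an [HMMSolution-class].
#' @param T number of timepoints (defaults to the fitted length).
#' @return the BIC value.
#' @export
bicHmm <- function(solution, T = nrow(statePresence(solution))) {
  n <- solution@n_states
  R <- ncol(solution@means)
  p <- (n - 1) + n * (n - 1) + n * (R + R * (R + 1) / 2)
  -2 * solution@log_likelihood + p * log(T)
}

#' Sweep candidate state counts and select by BIC
#'
#' For each candidate number of states, multi-restart-fits the model and
#' tabulates the semantic link index, the BIC on the full feature set and
#' the BIC with the limbic columns removed, plus (when several subjects'
#' series are given) the mean pairwise cross-subject correlation of the
#' state presence. Selection is by minimum full BIC, ties broken by the
#' larger link index.
#'
#' @param series a T x R matrix, or a list of them (one per subject).
#' @param contexts_W T x s context-expression matrix.
#' @param candidates integer vector of state counts (study range 2..8).
#' @param n_restarts restarts per candidate.
#' @param seed base seed.
#' @param limbic_cols optional integer indices of the limbic-embedding
#'   columns, removed for the second BIC column.
#' @param ... passed to [fitHmmEm()].
#' @return list with `selected` and `table` (one row per candidate).
#' @export
selectNStates <- function(series, contexts_W, candidates = 2:8,
                          n_restarts = 5L, seed = 1L, limbic_cols = NULL,
                          ...) {
  if (!length(candidates)) stop("candidate range must be nonempty")
  series_list <- if (is.list(series)) series else list(series)
  rows <- lapply(candidates, function(n) {
    sols <- lapply(seq_along(series_list), function(i)
      multiRestartFit(series_list[[i]], n, contexts_W,
                      n_restarts = n_restarts,
                      seed = .subSeed(seed, n, i), ...))
    link <- mean(vapply(sols, function(s) attr(s, "link_index"),
                        numeric(1)))
    bic_full <- mean(vapply(sols, bicHmm, numeric(1)))
    bic_nolimbic <- NA_real_
    if (!is.null(limbic_cols)) {
      sols2 <- lapply(seq_along(series_list), function(i)
        multiRestartFit(series_list[[i]][, -limbic_cols, drop = FALSE],
                        n, contexts_W, n_restarts = n_restarts,
                        seed = .subSeed(seed, n, i, 9L), ...))
      bic_nolimbic <- mean(vapply(sols2, bicHmm, numeric(1)))
    }
    xsubj <- NA_real_
    if (length(sols) > 1) {
      pairs <- utils::combn(length(sols), 2)
      xsubj <- mean(apply(pairs, 2, function(p) {
        g1 <- statePresence(sols[[p[1]]])
        g2 <- statePresence(sols[[p[2]]])
        mean(diag(cor(g1, g2[, .matchStates(g1, g2), drop = FALSE])))
      }))
    }
    data.frame(n_states = n, link_index = link, cross_subject = xsubj,
               bic = bic_full, bic_no_limbic = bic_nolimbic)
  })
  tab <- do.call(rbind, rows)
  best <- which(tab$bic == min(tab$bic))
  if (length(best) > 1) best <- best[which.max(tab$link_index[best])]
  list(selected = tab$n_states[best], table = tab)
}

# greedy gamma-correlation matching used only for the cross-subject
# similarity diagnostic
.matchStates <- function(g1, g2) {
  n <- ncol(g1)
  C <- cor(g1, g2)
  perm <- integer(n)
  used <- logical(n)
  for (k in order(-apply(C, 1, max))) {
    j <- order(-C[k, ])
    j <- j[!used[j]][1]
    perm[k] <- j
    used[j] <- TRUE
  }
  perm
}
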