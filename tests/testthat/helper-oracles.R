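# Independent oracle implementations used to cross-check the package's
# vectorized/compiled code paths.

# naive per-entry tf-idf per the printed formula
oracleTfidf <- function(V) {
  T <- nrow(V)
  out <- V * 0
  n_w <- apply(V, 2, function(col) sum(col > 0))
  for (t in seq_len(T)) {
    tot <- sum(V[t, ])
    for (w in seq_len(ncol(V))) {
      tf <- if (tot > 0) V[t, w] / tot else 0
      out[t, w] <- tf * log(T / (1 + n_w[w]))
    }
  }
  out
}

# direct truncated-mean smoothing loop
oracleSmooth <- function(V, hw) {
  T <- nrow(V)
  out <- V * 0
  for (t in seq_len(T)) {
    lo <- max(1, t - hw)
    hi <- min(T, t + hw)
    out[t, ] <- colMeans(V[lo:hi, , drop = FALSE])
  }
  out
}

# exhaustive path-sum posterior for a Gaussian HMM (tiny T only)
oracleForwardBackward <- function(X, pi, Theta, means, sds) {
  T <- nrow(X)
  n <- length(pi)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T)))
  pw <- apply(paths, 1, function(z) {
    p <- pi[z[1]] * prod(dnorm(X[1, ], means[z[1], ], sds))
    if (T > 1) for (t in 2:T)
      p <- p * Theta[z[t - 1], z[t]] * prod(dnorm(X[t, ], means[z[t], ], sds))
    p
  })
  gamma <- sapply(seq_len(n), function(k)
    sapply(seq_len(T), function(t) sum(pw[paths[, t] == k]) / sum(pw)))
  list(gamma = gamma, log_likelihood = log(sum(pw)))
}

# run-length dwell spells by explicit scanning
oracleDwell <- function(z, tr) {
  out <- list()
  start <- 1
  for (t in seq_along(z)) {
    if (t == length(z) || z[t + 1] != z[t]) {
      k <- as.character(z[t])
      out[[k]] <- c(out[[k]], (t - start + 1) * tr)
      start <- t + 1
    }
  }
  out
}

# exhaustive assignment search
oracleAssignment <- function(cost) {
  n <- nrow(cost)
  perms <- permutationsAll(n)
  costs <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(perm = perms[which.min(costs), ], cost = min(costs))
}

permutationsAll <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid[apply(grid, 1, function(r) length(unique(r)) == n), ,
       drop = FALSE]
}

# accuracy of a hard assignment against a true sequence under the best
# label permutation
matchedAccuracy <- function(hard, truth, n = max(truth)) {
  perms <- permutationsAll(n)
  max(apply(perms, 1, function(p) mean(p[hard] == truth)))
}

# label permutation maximizing matched accuracy
bestPermutation <- function(hard, truth, n = max(truth)) {
  perms <- permutationsAll(n)
  accs <- apply(perms, 1, function(p) mean(p[hard] == truth))
  perms[which.max(accs), ]
}

boxcar <- function(x, hw) {
  T <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(T) - hw, 1L)
  hi <- pmin(seq_len(T) + hw, T)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1)
}

cosineSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# cosine matrix between planted topic dictionaries and recovered H rows
topicCosineMatrix <- function(gt, contexts) {
  H <- wordWeights(contexts)
  vocab <- vocabulary(contexts)
  Tw <- gt@topics$topic_word_probs
  Tw2 <- matrix(0, nrow(Tw), length(vocab))
  for (j in seq_along(vocab)) {
    k <- match(vocab[j], gt@topics$vocabulary)
    if (!is.na(k)) Tw2[, j] <- Tw[, k]
  }
  outer(seq_len(nrow(Tw)), seq_len(nrow(H)), Vectorize(function(a, b)
    cosineSim(Tw2[a, ], H[b, ])))
}
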