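## Semantics-brain and annotation-brain association statistics:
## correlation matrices, the top-k link statistic, permutation nulls and
## network-level comparisons.

#' Pearson correlation matrix between state presence and features
#'
#' @param gamma T x n state-presence matrix.
#' @param features T x F feature matrix (context expressions or
#'   annotation series).
#' @return F x n matrix of Pearson correlations; any pair involving a
#'   zero-variance column is set to 0 with a warning.
#' @export
correlationMatrix <- function(gamma, features) {
  gamma <- as.matrix(gamma)
  features <- as.matrix(features)
  if (nrow(gamma) != nrow(features))
    stop("gamma and features must have the same number of rows")
  sg <- apply(gamma, 2, sd)
  sf <- apply(features, 2, sd)
  P <- suppressWarnings(cor(features, gamma))
  if (any(sg == 0) || any(sf == 0)) {
    warning("zero-variance column(s): correlations set to 0")
    P[sf == 0, ] <- 0
    P[, sg == 0] <- 0
  }
  P
}

#' Top-k link strength per state
#'
#' For every state (column of `P`), the mean of the k largest signed
#' correlations; the model-level index is the mean across states. When
#' fewer than k features exist, all are used with a warning.
#'
#' @param P F x n correlation matrix.
#' @param k number of top links (default 10, the study's choice).
#' @return list with `state_means` (length n) and `model_index`.
#' @export
topKLinkStrength <- function(P, k = 10L) {
  P <- as.matrix(P)
  if (nrow(P) < 1) stop("P must have at least one feature row")
  if (nrow(P) < k) {
    warning(sprintf("only %d features available for top-%d: using all",
                    nrow(P), k))
    k <- nrow(P)
  }
  state_means <- apply(P, 2, function(col)
    mean(sort(col, decreasing = TRUE)[seq_len(k)]))
  list(state_means = state_means, model_index = mean(state_means))
}

#' Permutation test of the model link index
#'
#' Shuffles the rows of the state-presence matrix (one joint permutation
#' of all columns, preserving each row's simplex constraint), recomputes
#' the top-k model link index B times, and reports the add-one p-value
#' `p = (1 + #\{null >= observed\}) / (1 + B)`.
#'
#' @param gamma T x n state-presence matrix.
#' @param features T x F feature matrix.
#' @param B number of permutations (study protocol: 1000).
#' @param seed integer seed.
#' @param k top-k of the link statistic.
#' @param circular use random circular shifts instead of full
#'   permutations (preserves autocorrelation).
#' @return a [LinkageProfile-class] carrying the observed statistic, the
#'   null sample and the p-value.
#' @export
permutationTest <- function(gamma, features, B = 1000L, seed = 1L,
                            k = 10L, circular = FALSE) {
  gamma <- as.matrix(gamma)
  features <- as.matrix(features)
  stopifnot(B >= 1)
  P <- correlationMatrix(gamma, features)
  top <- topKLinkStrength(P, k = k)
  T <- nrow(gamma)
  null_sample <- .withSeed(as.integer(seed), vapply(seq_len(B), function(b) {
    idx <- if (circular) {
      s <- sample.int(T, 1)
      c(seq(s, T), seq_len(s - 1))
    } else sample.int(T)
    Pb <- suppressWarnings(cor(features, gamma[idx, , drop = FALSE]))
    Pb[is.na(Pb)] <- 0
    suppressWarnings(topKLinkStrength(Pb, k = k)$model_index)
  }, numeric(1)))
  p <- (1 + sum(null_sample >= top$model_index)) / (1 + B)
  new("LinkageProfile", P_semantic = P,
      P_annotation = matrix(0, 0, ncol(gamma)),
      top_links = .topLinkTables(P, k), state_means = top$state_means,
      model_index = top$model_index, k = as.integer(min(k, nrow(P))),
      p_value = p, null_sample = null_sample)
}

.topLinkTables <- function(P, k) {
  k <- min(k, nrow(P))
  lapply(seq_len(ncol(P)), function(j) {
    ord <- order(P[, j], decreasing = TRUE)[seq_len(k)]
    data.frame(feature = ord, r = P[ord, j])
  })
}

#' Build a full linkage profile for one HMM solution
#'
#' Convenience wrapper combining the semantic and annotation correlation
#' matrices, the top-k statistic on the semantic side and (optionally)
#' the permutation test.
#'
#' @param solution an [HMMSolution-class].
#' @param contexts_W T x s context-expression matrix.
#' @param annotations optional T x A annotation matrix (or
#'   [AnnotationMatrix-class]).
#' @param k top-k of the link statistic.
#' @param B permutations for the null (0 skips the test).
#' @param seed integer seed for the permutation test.
#' @return a [LinkageProfile-class].
#' @export
linkageProfile <- function(solution, contexts_W, annotations = NULL,
                           k = 10L, B = 0L, seed = 1L) {
  gamma <- statePresence(solution)
  P <- correlationMatrix(gamma, contexts_W)
  top <- topKLinkStrength(P, k = k)
  PA <- if (is.null(annotations)) matrix(0, 0, ncol(gamma)) else
    correlationMatrix(gamma, if (is(annotations, "AnnotationMatrix"))
      valuesMatrix(annotations) else annotations)
  pv <- NA_real_
  nullv <- numeric(0)
  if (B > 0) {
    pt <- permutationTest(gamma, contexts_W, B = B, seed = seed, k = k)
    pv <- pt@p_value
    nullv <- pt@null_sample
  }
  new("LinkageProfile", P_semantic = P, P_annotation = PA,
      top_links = .topLinkTables(P, k), state_means = top$state_means,
      model_index = top$model_index, k = as.integer(min(k, nrow(P))),
      p_value = pv, null_sample = nullv)
}

#' Compare a reference network's link indices against the others
#'
#' Two-sample t-tests (pooled variance by default) of the per-subject
#' model link indices of a reference network against each other network.
#'
#' @param link_table numeric subjects x networks matrix (named columns)
#'   of model link indices.
#' @param reference column name of the reference network.
#' @param welch use Welch's unequal-variance t-test instead.
#' @return data.frame with one row per non-reference network: network, t,
#'   df, p_value, mean_reference, mean_other.
#' @export
compareNetworks <- function(link_table, reference, welch = FALSE) {
  link_table <- as.matrix(link_table)
  if (nrow(link_table) < 2)
    stop("at least 2 subjects per network are required")
  if (!reference %in% colnames(link_table))
    stop(sprintf("reference network '%s' not found", reference))
  ref <- link_table[, reference]
  others <- setdiff(colnames(link_table), reference)
  rows <- lapply(others, function(nm) {
    other <- link_table[, nm]
    if (sd(ref) == 0 && sd(other) == 0 && mean(ref) == mean(other)) {
      # degenerate identical groups: no evidence of a difference
      return(data.frame(network = nm, t = 0,
                        df = length(ref) + length(other) - 2,
                        p_value = 1, mean_reference = mean(ref),
                        mean_other = mean(other)))
    }
    tt <- t.test(ref, other, var.equal = !welch)
    data.frame(network = nm, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               mean_reference = mean(ref), mean_other = mean(other))
  })
  do.call(rbind, rows)
}
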