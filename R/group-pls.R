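## Group-level signatures: Hungarian state alignment across subjects,
## state-based partitioning/concatenation, one-component PLS regression
## with blocked cross-validation, and signature reporting.

#' Solve the assignment problem (Hungarian algorithm)
#'
#' Minimum-cost perfect matching of rows to columns of a square cost
#' matrix, via the O(n^3) potentials / shortest-augmenting-path form of
#' the Kuhn-Munkres algorithm.
#'
#' @param cost square numeric cost matrix.
#' @return integer permutation `p` with `p[i]` the column assigned to
#'   row i; total cost in attribute `"cost"`.
#' @export
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L                # 1-based index into the padded column array
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    way <- integer(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n) + 1L) perm[p[j]] <- j - 1L
  total <- sum(cost[cbind(seq_len(n), perm)])
  structure(perm, cost = total)
}

#' Align one subject's states to a template solution
#'
#' Optimal relabeling of the `other` solution's states onto the
#' template's, minimizing the summed Euclidean distance between state
#' mean vectors (optionally adding a Frobenius covariance term).
#'
#' @param template,other [HMMSolution-class] objects with equal state
#'   counts and feature spaces.
#' @param use_covariance add the Frobenius distance between state
#'   covariances to the cost.
#' @return list with `permutation` (`permutation[k]` = template state
#'   matched to `other`'s state k) and `cost`.
#' @export
alignStates <- function(template, other, use_covariance = FALSE) {
  n <- nStates(template)
  if (nStates(other) != n)
    stop("solutions must have equal state counts")
  if (ncol(stateMeans(template)) != ncol(stateMeans(other)))
    stop("solutions must share a feature space")
  cost <- matrix(0, n, n)
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      cost[k, l] <- sqrt(sum((stateMeans(other)[k, ] -
                              stateMeans(template)[l, ])^2))
      if (use_covariance)
        cost[k, l] <- cost[k, l] +
          sqrt(sum((stateCovariances(other)[[k]] -
                    stateCovariances(template)[[l]])^2))
    }
  }
  perm <- solveAssignment(cost)
  list(permutation = as.integer(perm), cost = attr(perm, "cost"))
}

#' Relabel a solution's states by an alignment permutation
#'
#' @param solution an [HMMSolution-class].
#' @param permutation integer vector mapping old state k to new label
#'   `permutation[k]` (from [alignStates()]).
#' @return the relabeled [HMMSolution-class].
#' @export
applyAlignment <- function(solution, permutation) {
  inv <- order(permutation)   # inv[new] = old
  new("HMMSolution", n_states = solution@n_states,
      pi = solution@pi[inv],
      Theta = solution@Theta[inv, inv, drop = FALSE],
      means = solution@means[inv, , drop = FALSE],
      covariances = solution@covariances[inv],
      gamma = solution@gamma[, inv, drop = FALSE],
      log_likelihood = solution@log_likelihood,
      loglik_trace = solution@loglik_trace, seed = solution@seed,
      iterations = solution@iterations, converged = solution@converged)
}

#' Partition a timeline's rows by hard-assigned state
#'
#' @param gamma T x n posterior matrix or a length-T hard state sequence.
#' @param series T x R matrix to partition.
#' @return list of n row-index/block pairs: each element holds `rows`
#'   (timepoint indices) and `block` (the corresponding series rows).
#' @export
partitionByState <- function(gamma, series) {
  series <- as.matrix(series)
  is_post <- is.matrix(gamma) && ncol(gamma) > 1
  seq_hard <- if (is_post) hardAssign(gamma) else as.integer(gamma)
  if (length(seq_hard) != nrow(series))
    stop("gamma and series must cover the same timepoints")
  n <- if (is_post) ncol(gamma) else max(seq_hard)
  lapply(seq_len(n), function(k) {
    rows <- which(seq_hard == k)
    list(rows = rows, block = series[rows, , drop = FALSE])
  })
}

#' Concatenate state-specific partitions across subjects
#'
#' Row-stacks each state's brain blocks and description blocks in subject
#' order, keeping per-row subject labels for fold construction.
#'
#' @param brain_parts per-subject lists from [partitionByState()] on the
#'   brain series.
#' @param descr_parts per-subject lists from [partitionByState()] on the
#'   description matrix (same state routing).
#' @return list of n elements, each with `G` (brain rows), `E`
#'   (description rows) and `subject` (per-row labels).
#' @export
concatGroup <- function(brain_parts, descr_parts) {
  stopifnot(length(brain_parts) == length(descr_parts))
  n <- length(brain_parts[[1]])
  lapply(seq_len(n), function(k) {
    G <- NULL; E <- NULL; subj <- integer(0)
    for (i in seq_along(brain_parts)) {
      bk <- brain_parts[[i]][[k]]$block
      ek <- descr_parts[[i]][[k]]$block
      if (nrow(bk) != nrow(ek))
        stop("brain and description partitions disagree on row counts")
      if (!is.null(G) && ncol(bk) != ncol(G))
        stop("subjects must share brain column layouts")
      G <- rbind(G, bk); E <- rbind(E, ek)
      subj <- c(subj, rep(i, nrow(bk)))
    }
    list(G = G, E = E, subject = subj)
  })
}

# one-component NIPALS PLS on centered (optionally standardized) data;
# returns weights and the projection function pieces
.pls1Core <- function(E, G, standardize_E = TRUE, tol = 1e-10,
                      max_iter = 500L) {
  cE <- colMeans(E); cG <- colMeans(G)
  Ec <- sweep(E, 2, cE); Gc <- sweep(G, 2, cG)
  sE <- rep(1, ncol(E))
  if (standardize_E) {
    sE <- apply(Ec, 2, sd)
    sE[sE < 1e-12] <- 1
    Ec <- sweep(Ec, 2, sE, `/`)
  }
  C <- crossprod(Ec, Gc)          # P x R cross-covariance
  w <- C[, which.max(colSums(C^2))]
  if (sqrt(sum(w^2)) < 1e-300) w <- rep(1, nrow(C))
  w <- w / sqrt(sum(w^2))
  for (i in seq_len(max_iter)) {
    cvec <- drop(crossprod(C, w))
    cvec <- cvec / sqrt(sum(cvec^2))
    w_new <- drop(C %*% cvec)
    w_new <- w_new / sqrt(sum(w_new^2))
    if (sum((w_new - w)^2) < tol^2) { w <- w_new; break }
    w <- w_new
  }
  cvec <- drop(crossprod(C, w))
  cvec <- cvec / sqrt(sum(cvec^2))
  j <- which.max(abs(w))
  if (w[j] < 0) { w <- -w; cvec <- -cvec }
  list(w = w, c = cvec, center_E = cE, center_G = cG, scale_E = sE)
}

.plsScores <- function(fit, E, G) {
  Ec <- sweep(sweep(E, 2, fit$center_E), 2, fit$scale_E, `/`)
  Gc <- sweep(G, 2, fit$center_G)
  list(sE = drop(Ec %*% fit$w), sG = drop(Gc %*% fit$c))
}

#' One-component PLS regression of brain on descriptions
#'
#' Finds the single pair of weight vectors maximizing the covariance
#' between the (column-centered, description-side standardized) external
#' description matrix `E_k` and brain matrix `G_k` — the dominant
#' singular pair of the cross-covariance — by NIPALS power iteration.
#' The sign convention makes the largest-magnitude description weight
#' positive.
#'
#' @param E_k N x P description matrix (contexts + annotations).
#' @param G_k N x R brain matrix.
#' @param state state index recorded in the result.
#' @param standardize_E standardize description columns (default TRUE;
#'   contexts and annotations live on different scales).
#' @return a [GroupSignature-class] (without CV fields).
#' @export
fitPls1 <- function(E_k, G_k, state = 1L, standardize_E = TRUE) {
  E_k <- as.matrix(E_k); G_k <- as.matrix(G_k)
  if (nrow(E_k) != nrow(G_k)) stop("E and G must have equal row counts")
  if (nrow(E_k) <= 2) stop("at least 3 rows are required")
  fit <- .pls1Core(E_k, G_k, standardize_E)
  sc <- .plsScores(fit, E_k, G_k)
  new("GroupSignature", state = as.integer(state),
      description_loadings = fit$w, brain_loadings = fit$c,
      scores_E = sc$sE, scores_G = sc$sG,
      covariance_explained = mean(sc$sE * sc$sG),
      cv_correlations = numeric(0), cv_mean = NA_real_)
}

#' Blocked 20-fold cross-validation of the PLS signature
#'
#' Splits each subject's state-specific rows into `n_folds` contiguous
#' blocks (respecting temporal order); fold f's test set concatenates
#' block f across subjects. A PLS model is trained on the remaining rows
#' and the held-out Pearson correlation between the two latent scores is
#' reported per fold.
#'
#' @param E_k,G_k row-aligned description and brain matrices.
#' @param subject_index per-row subject labels.
#' @param n_folds number of folds (study protocol: 20).
#' @param state state index recorded in the result.
#' @param standardize_E as in [fitPls1()].
#' @return a [GroupSignature-class] with `cv_correlations` and `cv_mean`
#'   filled in (training fit on all rows).
#' @export
crossvalPls <- function(E_k, G_k, subject_index, n_folds = 20L,
                        state = 1L, standardize_E = TRUE) {
  E_k <- as.matrix(E_k); G_k <- as.matrix(G_k)
  N <- nrow(E_k)
  if (N < 2 * n_folds)
    stop("too few rows for the requested number of folds")
  fold <- integer(N)
  for (s in unique(subject_index)) {
    rows <- which(subject_index == s)
    if (length(rows) < n_folds)
      warning(sprintf(
        "subject %s contributes fewer rows (%d) than folds (%d)",
        s, length(rows), n_folds))
    fold[rows] <- ceiling(seq_along(rows) / length(rows) * n_folds)
  }
  rs <- vapply(seq_len(n_folds), function(f) {
    test <- fold == f
    if (sum(test) < 2 || sum(!test) < 3) return(NA_real_)
    fit <- .pls1Core(E_k[!test, , drop = FALSE],
                     G_k[!test, , drop = FALSE], standardize_E)
    sc <- .plsScores(fit, E_k[test, , drop = FALSE],
                     G_k[test, , drop = FALSE])
    suppressWarnings(cor(sc$sE, sc$sG))
  }, numeric(1))
  sig <- fitPls1(E_k, G_k, state = state, standardize_E = standardize_E)
  sig@cv_correlations <- rs
  sig@cv_mean <- mean(rs, na.rm = TRUE)
  sig
}

#' Structured report of one group signature
#'
#' Names the top-k semantic contexts (with their top words), the top
#' annotations per category, the neocortical parcel loadings and the
#' limbic subregion loadings obtained by inverse-projecting the PC block.
#'
#' @param signature a [GroupSignature-class].
#' @param contexts the [SemanticContexts-class] whose expressions formed
#'   E's first columns.
#' @param annotation_meta data.frame (name, category, kind) for the
#'   remaining E columns (may be 0-row).
#' @param pca_model the limbic PCA `model` whose PCs occupy the last
#'   `2 n_pc` brain columns (NULL to skip back-projection).
#' @param brain_labels labels of the brain columns.
#' @param top_k contexts/annotations to list (default 3).
#' @return list with `top_contexts` (index, loading, words),
#'   `top_annotations` (per category), `parcel_loadings` and
#'   `limbic_subregion_loadings`.
#' @export
signatureReport <- function(signature, contexts, annotation_meta = NULL,
                            pca_model = NULL, brain_labels = NULL,
                            top_k = 3L) {
  s <- ncol(contextExpressions(contexts))
  w <- signature@description_loadings
  A <- length(w) - s
  if (!is.null(annotation_meta) && nrow(annotation_meta) != A)
    stop("annotation metadata inconsistent with loading length")
  ctx_w <- w[seq_len(s)]
  ord <- order(-abs(ctx_w))[seq_len(min(top_k, s))]
  top_contexts <- lapply(ord, function(j)
    list(context = j, loading = ctx_w[j],
         words = topWords(contexts, j, 5L)))
  top_annotations <- list()
  if (A > 0 && !is.null(annotation_meta)) {
    ann_w <- w[s + seq_len(A)]
    for (cat in unique(annotation_meta$category)) {
      idx <- which(annotation_meta$category == cat)
      o <- idx[order(-abs(ann_w[idx]))][seq_len(min(top_k, length(idx)))]
      top_annotations[[cat]] <- data.frame(
        name = annotation_meta$name[o], loading = ann_w[o])
    }
  }
  b <- signature@brain_loadings
  limbic <- NULL
  parcels <- b
  if (!is.null(pca_model)) {
    n_pc <- nrow(pca_model$components)
    pc_block <- tail(b, 2 * n_pc)
    parcels <- head(b, length(b) - 2 * n_pc)
    limbic <- inverseProjectLoadings(pca_model, pc_block)
  }
  if (!is.null(brain_labels))
    names(parcels) <- head(brain_labels, length(parcels))
  list(top_contexts = top_contexts, top_annotations = top_annotations,
       parcel_loadings = parcels, limbic_subregion_loadings = limbic)
}
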