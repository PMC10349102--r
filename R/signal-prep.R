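## Subregion signal preparation: per-segment detrending and z-scoring,
## hemisphere-shared limbic PCA embeddings, and assembly of the
## region-network feature matrices fed to the HMMs.

#' Segment-wise detrend and z-score
#'
#' Within each movie segment and each column: removes the least-squares
#' linear trend, then scales to mean 0 and (population, 1/N) standard
#' deviation 1. Columns constant within a segment become zeros.
#'
#' @param series numeric T x D matrix.
#' @param segment_bounds integer matrix (segments x 2) of half-open
#'   0-based `[start, end)` intervals partitioning `[0, T)`.
#' @return standardized T x D matrix.
#' @export
segmentwiseStandardize <- function(series, segment_bounds) {
  X <- as.matrix(series)
  T <- nrow(X)
  sb <- as.matrix(segment_bounds)
  if (sb[1, 1] != 0 || sb[nrow(sb), 2] != T ||
      (nrow(sb) > 1 && any(sb[-1, 1] != sb[-nrow(sb), 2])))
    stop("segment bounds must partition [0, T) without gaps or overlaps")
  out <- X
  for (i in seq_len(nrow(sb))) {
    idx <- (sb[i, 1] + 1):sb[i, 2]
    tt <- seq_along(idx)
    basis <- cbind(1, tt - mean(tt))
    seg <- X[idx, , drop = FALSE]
    resid <- seg - basis %*% qr.coef(qr(basis), seg)
    s <- sqrt(colMeans(resid^2))
    resid <- sweep(resid, 2, ifelse(s > 1e-12, s, 1), `/`)
    resid[, s <= 1e-12] <- 0
    out[idx, ] <- resid
  }
  out
}

#' Hemisphere-shared PCA embedding of limbic subregions
#'
#' Fits one PCA on the two hemispheres' subregion series row-stacked
#' along the time axis (2T x m), so both hemispheres share the same
#' singular vectors, then projects each hemisphere with those shared
#' components. Column means are removed per hemisphere before stacking;
#' each component's largest-magnitude element is made positive for
#' deterministic signs.
#'
#' @param left,right numeric T x m matrices (same m).
#' @param n_pc number of components per hemisphere (default 3).
#' @return list with `model` (list: components n_pc x m, center_left,
#'   center_right, explained_variance) and `embeddings`
#'   (T x 2 n_pc matrix, left components then right).
#' @export
fitLimbicPca <- function(left, right, n_pc = 3L) {
  left <- as.matrix(left); right <- as.matrix(right)
  stopifnot(ncol(left) == ncol(right), nrow(left) == nrow(right))
  m <- ncol(left)
  if (n_pc > m) stop(sprintf("n_pc = %d exceeds %d subregions", n_pc, m))
  cl <- colMeans(left); cr <- colMeans(right)
  stacked <- rbind(sweep(left, 2, cl), sweep(right, 2, cr))
  sv <- svd(stacked, nu = 0, nv = n_pc)
  comp <- t(sv$v)
  for (i in seq_len(n_pc)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  ev <- sv$d^2 / sum(sv$d^2)
  emb <- cbind(sweep(left, 2, cl) %*% t(comp),
               sweep(right, 2, cr) %*% t(comp))
  colnames(emb) <- c(sprintf("L-PC%d", seq_len(n_pc)),
                     sprintf("R-PC%d", seq_len(n_pc)))
  list(model = list(components = comp, center_left = cl,
                    center_right = cr,
                    explained_variance = ev[seq_len(n_pc)]),
       embeddings = emb)
}

#' Assemble one region-network combination's feature matrix
#'
#' Column-concatenates a network's parcel series with the limbic PC
#' embeddings, giving the `R = r_network + 2 r_limbic` feature layout the
#' HMMs are trained on.
#'
#' @param network_series T x r_network matrix of parcel time series.
#' @param limbic_embeddings T x 2 n_pc matrix from [fitLimbicPca()].
#' @param labels optional column labels (parcels then PCs).
#' @return T x R numeric matrix with column labels.
#' @export
assembleCombination <- function(network_series, limbic_embeddings,
                                labels = NULL) {
  network_series <- as.matrix(network_series)
  limbic_embeddings <- as.matrix(limbic_embeddings)
  if (nrow(network_series) != nrow(limbic_embeddings))
    stop("network and limbic series must have the same number of rows")
  out <- cbind(network_series, limbic_embeddings)
  if (!is.null(labels)) {
    stopifnot(length(labels) == ncol(out))
    colnames(out) <- labels
  }
  out
}

#' Map PC-space loadings back to limbic subregions
#'
#' Inverse PCA transformation: each hemisphere's `n_pc` loadings are
#' mapped through the transposed shared component matrix, producing one
#' loading per subregion (left hemisphere first).
#'
#' @param model the `model` element returned by [fitLimbicPca()].
#' @param pc_loadings numeric vector of length `2 n_pc` (L then R).
#' @return numeric vector of length `2 m` of subregion loadings.
#' @export
inverseProjectLoadings <- function(model, pc_loadings) {
  comp <- model$components
  n_pc <- nrow(comp)
  if (length(pc_loadings) != 2 * n_pc)
    stop(sprintf("expected %d loadings, got %d", 2 * n_pc,
                 length(pc_loadings)))
  lh <- drop(t(comp) %*% pc_loadings[seq_len(n_pc)])
  rh <- drop(t(comp) %*% pc_loadings[n_pc + seq_len(n_pc)])
  c(lh, rh)
}
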