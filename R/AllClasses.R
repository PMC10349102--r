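#' Class containers for the narrative-brain-state pipeline
#'
#' The pipeline's central objects are small S4 containers around plain
#' matrices with the metadata needed to keep timepoints, vocabulary,
#' states and subregions aligned across stages.
#'
#' @name nbstates-classes
NULL

#' TokenTimeline: per-timepoint token lists on the TR grid
#'
#' Holds the tokenized, time-binned text of a movie corpus: one list of
#' lowercase, punctuation-free words per repetition-time (TR) bin.
#'
#' @slot tokens list of character vectors, one per timepoint.
#' @slot tr_seconds sampling interval of the timepoint grid, seconds.
#' @export
setClass("TokenTimeline",
  representation(tokens = "list", tr_seconds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@tr_seconds) != 1L || object@tr_seconds <= 0)
      msg <- c(msg, "tr_seconds must be a single positive number")
    ok <- vapply(object@tokens, function(x) {
      is.character(x) && !any(grepl("[[:upper:]]", x)) &&
        !any(grepl("[[:punct:]]", x))
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "tokens must be lowercase and punctuation-free")
    if (length(msg)) msg else TRUE
  })

#' WordCountMatrix: timepoints x vocabulary weights
#'
#' A timepoint-by-word matrix at one of three processing stages:
#' `"raw"` occurrence counts, `"smoothed"` sliding-window means, or
#' `"tfidf"` term-frequency inverse-document-frequency weights.
#'
#' @slot values numeric matrix, timepoints in rows, vocabulary in columns.
#' @slot vocabulary character vector of unique, lexicographically sorted
#'   words naming the columns.
#' @slot stage one of `"raw"`, `"smoothed"`, `"tfidf"`.
#' @export
setClass("WordCountMatrix",
  representation(values = "matrix", vocabulary = "character",
                 stage = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@stage %in% c("raw", "smoothed", "tfidf"))
      msg <- c(msg, "stage must be raw, smoothed or tfidf")
    if (ncol(object@values) != length(object@vocabulary))
      msg <- c(msg, "vocabulary length must match column count")
    if (anyDuplicated(object@vocabulary))
      msg <- c(msg, "vocabulary entries must be unique")
    if (is.unsorted(object@vocabulary))
      msg <- c(msg, "vocabulary must be lexicographically sorted")
    if (object@stage %in% c("raw", "smoothed") &&
        length(object@values) && min(object@values) < 0)
      msg <- c(msg, "raw/smoothed values must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' SemanticContexts: nonnegative factorization of a word count matrix
#'
#' The result of nonnegativity-constrained latent semantic analysis:
#' `M ~ W H` with elementwise nonnegative factors. Each of the `s`
#' contexts pairs a per-timepoint expression trajectory (a column of `W`)
#' with a word-weight vector (a row of `H`, unit Euclidean norm).
#'
#' @slot W numeric T x s nonnegative expression matrix.
#' @slot H numeric s x V nonnegative word-weight matrix, unit-norm rows.
#' @slot vocabulary character vector naming H's columns.
#' @slot reconstruction_error Frobenius norm of `M - W H` at convergence.
#' @slot objective_trace objective value per multiplicative-update
#'   iteration (squared-Frobenius/2).
#' @slot clipped_count number of negative tf-idf entries clipped to zero
#'   before factorization.
#' @slot seed,iterations,converged fit metadata.
#' @export
setClass("SemanticContexts",
  representation(W = "matrix", H = "matrix", vocabulary = "character",
                 reconstruction_error = "numeric",
                 objective_trace = "numeric", clipped_count = "numeric",
                 seed = "integer", iterations = "integer",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@W) != nrow(object@H))
      msg <- c(msg, "W column count must equal H row count")
    if (ncol(object@H) != length(object@vocabulary))
      msg <- c(msg, "vocabulary length must match H columns")
    if (length(object@W) && min(object@W) < 0)
      msg <- c(msg, "W must be nonnegative")
    if (length(object@H) && min(object@H) < 0)
      msg <- c(msg, "H must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' AnnotationMatrix: timepoints x attribute description series
#'
#' Inter-observer-agreement derived description time series: unipolar
#' attributes in \[0, 1\], bipolar attributes in \[-1, 1\], binary
#' attributes in \{0, 1\}.
#'
#' @slot values numeric T x A matrix.
#' @slot attributes character vector of attribute names.
#' @slot category factor-like character: "emotion", "place" or "other".
#' @slot kind character: "unipolar", "bipolar" or "binary" per attribute.
#' @export
setClass("AnnotationMatrix",
  representation(values = "matrix", attributes = "character",
                 category = "character", kind = "character"),
  validity = function(object) {
    msg <- character()
    A <- ncol(object@values)
    if (length(object@attributes) != A || length(object@category) != A ||
        length(object@kind) != A)
      msg <- c(msg, "attribute metadata must match column count")
    if (!all(object@category %in% c("emotion", "place", "other")))
      msg <- c(msg, "category must be emotion, place or other")
    if (!all(object@kind %in% c("unipolar", "bipolar", "binary")))
      msg <- c(msg, "kind must be unipolar, bipolar or binary")
    for (j in seq_len(A)) {
      v <- object@values[, j]
      ok <- switch(object@kind[j],
        unipolar = all(v >= 0 & v <= 1),
        bipolar  = all(v >= -1 & v <= 1),
        binary   = all(v %in% c(0, 1)))
      if (!ok) {
        msg <- c(msg, sprintf("attribute '%s' outside its declared range",
                              object@attributes[j]))
        break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' HMMSolution: a fitted Gaussian-emission hidden Markov model
#'
#' Parameters and posteriors of one hidden Markov model with multivariate
#' Gaussian emissions fitted to a region-network time series: initial
#' probabilities `pi`, row-stochastic transition matrix `Theta`
#' (`Theta[l, k] = P(S_t = k | S_{t-1} = l)`), per-state mean vectors and
#' covariance matrices, and the posterior state-presence probabilities
#' `gamma` (T x n) from forward-backward inference.
#'
#' @slot n_states number of hidden states.
#' @slot pi numeric length-n initial state distribution.
#' @slot Theta numeric n x n transition matrix, rows sum to 1.
#' @slot means numeric n x R matrix of state means.
#' @slot covariances list of n R x R symmetric positive-definite matrices.
#' @slot gamma numeric T x n posterior state presence, rows sum to 1.
#' @slot log_likelihood final data log-likelihood.
#' @slot loglik_trace per-iteration log-likelihood during EM.
#' @slot seed,iterations,converged fit metadata.
#' @export
setClass("HMMSolution",
  representation(n_states = "integer", pi = "numeric", Theta = "matrix",
                 means = "matrix", covariances = "list", gamma = "matrix",
                 log_likelihood = "numeric", loglik_trace = "numeric",
                 seed = "integer", iterations = "integer",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    n <- object@n_states
    if (length(object@pi) != n || abs(sum(object@pi) - 1) > 1e-8)
      msg <- c(msg, "pi must have length n and sum to 1")
    if (!all(dim(object@Theta) == c(n, n)) ||
        max(abs(rowSums(object@Theta) - 1)) > 1e-8)
      msg <- c(msg, "Theta must be n x n with unit row sums")
    if (nrow(object@means) != n || length(object@covariances) != n)
      msg <- c(msg, "means/covariances must have one entry per state")
    if (ncol(object@gamma) != n)
      msg <- c(msg, "gamma must have n columns")
    if (nrow(object@gamma) &&
        max(abs(rowSums(object@gamma) - 1)) > 1e-8)
      msg <- c(msg, "gamma rows must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' LinkageProfile: semantics-brain and annotation-brain link statistics
#'
#' Pearson correlation matrices between posterior state presence and
#' external description features, with the top-k link statistic and an
#' optional permutation null.
#'
#' @slot P_semantic numeric s x n correlation matrix (contexts x states).
#' @slot P_annotation numeric A x n correlation matrix (may be 0-row).
#' @slot top_links per-state list of data.frames (feature index, r).
#' @slot state_means per-state mean of the top-k correlations.
#' @slot model_index mean of `state_means` across states.
#' @slot k the top-k used.
#' @slot p_value permutation p-value (NA when no test was run).
#' @slot null_sample permutation null draws of the model index.
#' @export
setClass("LinkageProfile",
  representation(P_semantic = "matrix", P_annotation = "matrix",
                 top_links = "list", state_means = "numeric",
                 model_index = "numeric", k = "integer",
                 p_value = "numeric", null_sample = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@P_semantic) &&
        max(abs(object@P_semantic)) > 1 + 1e-12)
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (!is.na(object@p_value) &&
        (object@p_value <= 0 || object@p_value > 1))
      msg <- c(msg, "p-value must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' GroupSignature: one state's group-level PLS component
#'
#' The single most explanatory partial-least-squares direction linking the
#' combined external-description matrix `E_k` (semantic contexts plus
#' annotations) to the concatenated state-specific brain matrix `G_k`.
#'
#' @slot state template-aligned state index.
#' @slot description_loadings PLS weights over E's columns.
#' @slot brain_loadings PLS weights over brain columns (parcels + limbic
#'   PCs).
#' @slot scores_E,scores_G training latent score pair per row.
#' @slot covariance_explained covariance of the training latent pair.
#' @slot cv_correlations held-out Pearson r per cross-validation fold.
#' @slot cv_mean mean of `cv_correlations`.
#' @export
setClass("GroupSignature",
  representation(state = "integer", description_loadings = "numeric",
                 brain_loadings = "numeric", scores_E = "numeric",
                 scores_G = "numeric", covariance_explained = "numeric",
                 cv_correlations = "numeric", cv_mean = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@description_loadings)) ||
        any(!is.finite(object@brain_loadings)))
      msg <- c(msg, "loadings must be finite")
    if (length(object@cv_correlations) &&
        any(abs(object@cv_correlations) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "CV correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' GroundTruth: the generative configuration of a synthetic study
#'
#' All parameters of the synthetic data generator: cohort layout, the
#' per-network hidden Markov chains and Gaussian emission parameters of
#' every region-network combination, the topic dictionary driving the
#' synthetic subtitle stream, topic-to-state coupling targets, and the
#' planted observer-annotation episodes.
#'
#' @slot config the generator settings list (see [groundTruthConfig()]).
#' @slot networks named integer vector of parcels per network.
#' @slot limbic named integer vector of subregions per hemisphere
#'   (hippocampus, amygdala).
#' @slot segment_bounds integer matrix (segments x 2) of half-open
#'   timepoint intervals partitioning the timeline.
#' @slot hmm_params per-combination list with elements pi, Theta, means,
#'   covariances; combinations named "<network>&<HC|AM>".
#' @slot state_chains per-network integer state sequence shared by all
#'   subjects (stimulus-locked dynamics).
#' @slot topics list: vocabulary, topic_word_probs (s_true x V),
#'   background_probs.
#' @slot coupling data.frame: topic, network, state, rho, beta (calibrated
#'   emission gain).
#' @slot annotation_spec data.frame of attributes with planted agreement.
#' @slot episodes data.frame of planted annotation episodes (seconds).
#' @slot seed master seed.
#' @export
setClass("GroundTruth",
  representation(config = "list", networks = "integer",
                 limbic = "integer", segment_bounds = "matrix",
                 hmm_params = "list", state_chains = "list",
                 topics = "list", coupling = "data.frame",
                 annotation_spec = "data.frame", episodes = "data.frame",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    for (nm in names(object@hmm_params)) {
      p <- object@hmm_params[[nm]]
      if (max(abs(rowSums(p$Theta) - 1)) > 1e-12)
        msg <- c(msg, sprintf("Theta rows of %s must sum to 1", nm))
      for (S in p$covariances) {
        ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) <= 0 || max(abs(S - t(S))) > 1e-10) {
          msg <- c(msg, sprintf("covariances of %s must be symmetric PD", nm))
          break
        }
      }
    }
    tw <- object@topics$topic_word_probs
    if (!is.null(tw) && max(abs(rowSums(tw) - 1)) > 1e-8)
      msg <- c(msg, "topic word probabilities must sum to 1 per topic")
    sb <- object@segment_bounds
    T <- object@config$n_timepoints
    if (nrow(sb)) {
      if (sb[1, 1] != 0L || sb[nrow(sb), 2] != T ||
          (nrow(sb) > 1 && any(sb[-1, 1] != sb[-nrow(sb), 2])))
        msg <- c(msg, "segment_bounds must partition [0, n_timepoints)")
    }
    if (length(msg)) msg else TRUE
  })
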