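#' Accessors for pipeline containers
#'
#' Small accessor generics so downstream code never touches slots.
#'
#' @param object an S4 container from this package.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("valuesMatrix", function(object) standardGeneric("valuesMatrix"))
#' @rdname accessors
#' @export
setGeneric("vocabulary", function(object) standardGeneric("vocabulary"))
#' @rdname accessors
#' @export
setGeneric("contextExpressions", function(object)
  standardGeneric("contextExpressions"))
#' @rdname accessors
#' @export
setGeneric("wordWeights", function(object) standardGeneric("wordWeights"))
#' @rdname accessors
#' @export
setGeneric("statePresence", function(object) standardGeneric("statePresence"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object)
  standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("stateMeans", function(object) standardGeneric("stateMeans"))
#' @rdname accessors
#' @export
setGeneric("stateCovariances", function(object)
  standardGeneric("stateCovariances"))
#' @rdname accessors
#' @export
setGeneric("modelLogLik", function(object) standardGeneric("modelLogLik"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("modelLinkIndex", function(object)
  standardGeneric("modelLinkIndex"))

#' @rdname accessors
#' @export
setMethod("valuesMatrix", "WordCountMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("valuesMatrix", "AnnotationMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("vocabulary", "WordCountMatrix", function(object) object@vocabulary)
#' @rdname accessors
#' @export
setMethod("vocabulary", "SemanticContexts", function(object)
  object@vocabulary)
#' @rdname accessors
#' @export
setMethod("contextExpressions", "SemanticContexts", function(object)
  object@W)
#' @rdname accessors
#' @export
setMethod("wordWeights", "SemanticContexts", function(object) object@H)
#' @rdname accessors
#' @export
setMethod("statePresence", "HMMSolution", function(object) object@gamma)
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "HMMSolution", function(object) object@Theta)
#' @rdname accessors
#' @export
setMethod("stateMeans", "HMMSolution", function(object) object@means)
#' @rdname accessors
#' @export
setMethod("stateCovariances", "HMMSolution", function(object)
  object@covariances)
#' @rdname accessors
#' @export
setMethod("modelLogLik", "HMMSolution", function(object) object@log_likelihood)
#' @rdname accessors
#' @export
setMethod("nStates", "HMMSolution", function(object) object@n_states)
#' @rdname accessors
#' @export
setMethod("modelLinkIndex", "LinkageProfile", function(object)
  object@model_index)

setMethod("show", "TokenTimeline", function(object) {
  n <- sum(lengths(object@tokens))
  cat(sprintf("TokenTimeline: %d timepoints (TR = %g s), %d tokens\n",
              length(object@tokens), object@tr_seconds, n))
})

setMethod("show", "WordCountMatrix", function(object) {
  cat(sprintf("WordCountMatrix [%s]: %d timepoints x %d words\n",
              object@stage, nrow(object@values), ncol(object@values)))
})

setMethod("show", "SemanticContexts", function(object) {
  cat(sprintf(
    "SemanticContexts: %d contexts over %d timepoints, %d words\n",
    ncol(object@W), nrow(object@W), ncol(object@H)))
  cat(sprintf("  reconstruction error (Frobenius): %.4g; %d iterations%s\n",
              object@reconstruction_error, object@iterations,
              if (object@converged) " (converged)" else ""))
})

setMethod("show", "HMMSolution", function(object) {
  cat(sprintf(
    "HMMSolution: %d states, %d timepoints x %d features\n",
    object@n_states, nrow(object@gamma), ncol(object@means)))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations%s\n",
              object@log_likelihood, object@iterations,
              if (object@converged) " (converged)" else ""))
})

setMethod("show", "LinkageProfile", function(object) {
  cat(sprintf(
    "LinkageProfile: %d contexts x %d states; top-%d model index %.4f\n",
    nrow(object@P_semantic), ncol(object@P_semantic), object@k,
    object@model_index))
  if (!is.na(object@p_value))
    cat(sprintf("  permutation p = %.4g (B = %d)\n", object@p_value,
                length(object@null_sample)))
})

setMethod("show", "GroupSignature", function(object) {
  cat(sprintf(
    "GroupSignature (state %d): %d description + %d brain loadings\n",
    object@state, length(object@description_loadings),
    length(object@brain_loadings)))
  if (length(object@cv_correlations))
    cat(sprintf("  CV mean r = %.3f over %d folds\n", object@cv_mean,
                length(object@cv_correlations)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d subjects x %d timepoints (TR = %g s), %d segments\n",
    object@config$n_subjects, object@config$n_timepoints,
    object@config$tr_seconds, nrow(object@segment_bounds)))
  cat(sprintf("  %d networks x %d limbic structures = %d combinations, %d states\n",
              length(object@networks), length(object@limbic),
              length(object@hmm_params), object@config$n_states))
})
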