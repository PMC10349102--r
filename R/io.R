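## Plain-text serialization: TSV matrices with header rows, JSON
## metadata sidecars, SRT files. All writers are deterministic (fixed
## numeric formatting) so identical runs produce byte-identical files.

.fmtNum <- function(x, digits = 10) {
  out <- formatC(x, digits = digits, format = "g")
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

#' Write a numeric matrix as TSV (header = column names)
#'
#' @param x numeric matrix.
#' @param path output file.
#' @param digits significant digits (fixed for reproducible bytes).
#' @export
writeMatrixTsv <- function(x, path, digits = 10) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  cn <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  writeLines(paste(cn, collapse = "\t"), con)
  body <- apply(x, 1, function(r) paste(.fmtNum(r, digits),
                                        collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a TSV matrix written by [writeMatrixTsv()]
#' @param path input file.
#' @return numeric matrix with column names.
#' @export
readMatrixTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  as.matrix(df)
}

#' Serialize an HMM solution to JSON + TSV files
#'
#' Writes `<prefix>.json` (pi, Theta, metadata), `<prefix>_means.tsv`,
#' `<prefix>_cov_state<k>.tsv` and `<prefix>_gamma.tsv`.
#'
#' @param solution an [HMMSolution-class].
#' @param prefix path prefix.
#' @export
writeHmmSolution <- function(solution, prefix) {
  meta <- list(n_states = solution@n_states, pi = solution@pi,
               Theta = solution@Theta,
               log_likelihood = solution@log_likelihood,
               seed = solution@seed, iterations = solution@iterations,
               converged = solution@converged)
  jsonlite::write_json(meta, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  writeMatrixTsv(solution@means, paste0(prefix, "_means.tsv"))
  for (k in seq_len(solution@n_states))
    writeMatrixTsv(solution@covariances[[k]],
                   sprintf("%s_cov_state%d.tsv", prefix, k))
  writeMatrixTsv(solution@gamma, paste0(prefix, "_gamma.tsv"))
  invisible(prefix)
}

#' Write semantic contexts as two TSVs + JSON metadata
#' @param contexts a [SemanticContexts-class].
#' @param prefix path prefix (writes `<prefix>_W.tsv`, `<prefix>_H.tsv`,
#'   `<prefix>.json`).
#' @export
writeSemanticContexts <- function(contexts, prefix) {
  writeMatrixTsv(contexts@W, paste0(prefix, "_W.tsv"))
  writeMatrixTsv(contexts@H, paste0(prefix, "_H.tsv"))
  jsonlite::write_json(
    list(s = ncol(contexts@W),
         reconstruction_error = contexts@reconstruction_error,
         clipped_count = contexts@clipped_count, seed = contexts@seed,
         iterations = contexts@iterations,
         converged = contexts@converged),
    paste0(prefix, ".json"), digits = NA, auto_unbox = TRUE,
    pretty = TRUE)
  invisible(prefix)
}

#' Write an annotation matrix as TSV + JSON sidecar
#' @param ann an [AnnotationMatrix-class].
#' @param prefix path prefix.
#' @export
writeAnnotationMatrix <- function(ann, prefix) {
  writeMatrixTsv(ann@values, paste0(prefix, ".tsv"))
  jsonlite::write_json(
    data.frame(name = ann@attributes, category = ann@category,
               kind = ann@kind),
    paste0(prefix, ".json"), pretty = TRUE)
  invisible(prefix)
}

#' Read observer annotation intervals from TSV
#' @param path TSV with columns observer_id, character, attribute,
#'   start_s, end_s, value.
#' @return data.frame of intervals.
#' @export
readObserverIntervals <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
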