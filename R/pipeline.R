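## End-to-end orchestration: simulate -> semantics -> per-subject HMMs ->
## linkage -> temporal -> group PLS, from one config list, with a
## machine-readable results bundle and provenance manifest.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed for every stage.
#' @param gt_config synthetic-study settings ([groundTruthConfig()]).
#' @param window_minutes text smoothing window (study choice: 4).
#' @param s semantic contexts to extract.
#' @param n_states HMM states per combination.
#' @param n_restarts EM restarts per fit (study protocol: 100).
#' @param B permutations for the link-strength null.
#' @param n_folds PLS cross-validation folds (study protocol: 20).
#' @param limbic_for_pls limbic structure paired with the PLS target
#'   network.
#' @param pls_network network whose combinations feed the group PLS.
#' @return a named settings list for [runPipeline()].
#' @export
pipelineConfig <- function(out_dir = tempfile("nbstates"), seed = 1L,
                           gt_config = groundTruthConfig(),
                           window_minutes = 4, s = 200L, n_states = 4L,
                           n_restarts = 100L, B = 1000L, n_folds = 20L,
                           pls_network = "DN", limbic_for_pls = "HC") {
  cfg <- as.list(environment())
  stopifnot(s > 0, n_states > 1, n_restarts > 0, B >= 0, n_folds > 1)
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of [pipelineConfig()] keys (nested `gt_config` keys
#' become [groundTruthConfig()] arguments) and fills unset values with
#' the defaults.
#'
#' @param path YAML file.
#' @return a settings list for [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  gt_args <- y$gt_config %||% list()
  if (!is.null(gt_args$networks))
    gt_args$networks <- unlist(gt_args$networks)
  if (!is.null(gt_args$limbic)) gt_args$limbic <- unlist(gt_args$limbic)
  y$gt_config <- do.call(groundTruthConfig, gt_args)
  do.call(pipelineConfig, y)
}

#' Run the full synthetic-study analysis pipeline
#'
#' Stages: (1) generate ground truth and simulate subjects, subtitle
#' stream and observer annotations; (2) text pipeline: parse, clean,
#' bin, smooth, tf-idf, NMF-LSA; (3) annotation IOA matrix; (4) per
#' subject and per region-network combination: segment-wise
#' standardization, limbic PCA, feature assembly, multi-restart HMM;
#' (5) linkage statistics with permutation nulls; (6) dwell-time table;
#' (7) group PLS signatures per aligned state. All stage outputs are
#' written under `config$out_dir` together with a provenance manifest
#' (parameters, seeds, file hashes). Reruns with an identical config are
#' byte-identical.
#'
#' @param config a list from [pipelineConfig()] (or a YAML path).
#' @return invisibly, the results bundle (a list; see vignette).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  gt <- stage("simulate", generateGroundTruth(config$gt_config))
  cfg <- gt@config
  T <- cfg$n_timepoints
  stream <- stage("simulate", simulateSubtitleStream(gt, config$seed))
  writeLines(stream$srt, out("subtitles.srt"))
  intervals <- stage("simulate",
    simulateObserverAnnotations(gt, cfg$n_observers, config$seed))
  write.table(intervals, out("observer_intervals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  contexts <- stage("semantics", {
    tl <- preprocessTokens(stream$timeline)
    M <- buildWordCountMatrix(tl)
    sm <- smoothCounts(M, config$window_minutes, cfg$tr_seconds)
    tf <- tfidfTransform(sm)
    fitNmfLsa(tf, s = min(config$s, min(dim(valuesMatrix(tf)))),
              seed = config$seed)
  })
  writeSemanticContexts(contexts, out("contexts"))

  ann <- stage("annotations",
    buildAnnotationMatrix(intervals, gt@annotation_spec,
                          cfg$n_observers, T, cfg$tr_seconds))
  writeAnnotationMatrix(ann, out("annotations"))

  combos <- names(gt@hmm_params)
  solutions <- list()
  pca_models <- list()
  link_rows <- list()
  for (i in seq_len(cfg$n_subjects)) {
    subj <- stage("signal_prep", {
      sim <- simulateSubjectTimeseries(gt, i, config$seed)
      std <- segmentwiseStandardize(sim$series, gt@segment_bounds)
      colnames(std) <- colnames(sim$series)
      list(series = std, metadata = sim$metadata)
    })
    emb <- list()
    for (lb in names(gt@limbic)) {
      lcols <- subj$metadata$structure == lb &
        subj$metadata$hemisphere == "L"
      rcols <- subj$metadata$structure == lb &
        subj$metadata$hemisphere == "R"
      fit <- fitLimbicPca(subj$series[, lcols, drop = FALSE],
                          subj$series[, rcols, drop = FALSE])
      emb[[lb]] <- fit
    }
    pca_models[[i]] <- lapply(emb, `[[`, "model")
    solutions[[i]] <- list()
    for (cmb in combos) {
      p <- gt@hmm_params[[cmb]]
      ncols <- subj$metadata$network %in% p$network
      X <- stage("signal_prep", assembleCombination(
        subj$series[, which(ncols), drop = FALSE],
        emb[[p$limbic]]$embeddings))
      sol <- stage("fit_hmm", multiRestartFit(
        X, config$n_states, contextExpressions(contexts),
        n_restarts = config$n_restarts,
        seed = .subSeed(config$seed, i, match(cmb, combos))))
      solutions[[i]][[cmb]] <- sol
      prof <- stage("link", linkageProfile(
        sol, contextExpressions(contexts), ann, B = config$B,
        seed = .subSeed(config$seed, i, match(cmb, combos), 3L)))
      link_rows[[length(link_rows) + 1L]] <- data.frame(
        subject = i, combination = cmb, network = p$network,
        limbic = p$limbic, link_index = prof@model_index,
        p_value = prof@p_value)
      writeHmmSolution(sol, out(sprintf("hmm_s%02d_%s", i,
                                        gsub("&", "_", cmb))))
    }
  }
  link_table <- do.call(rbind, link_rows)
  write.table(link_table, out("link_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  dwell <- stage("dwell",
    groupDwellTable(solutions, gt@segment_bounds, cfg$tr_seconds))
  write.table(cbind(dwell[1:2],
                    round(dwell[3:ncol(dwell)], 10)),
              out("dwell_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  pls_cmb <- paste0(config$pls_network, "&", config$limbic_for_pls)
  signatures <- stage("group_pls", {
    E <- cbind(contextExpressions(contexts), valuesMatrix(ann))
    aligned <- lapply(seq_len(cfg$n_subjects), function(i) {
      sol <- solutions[[i]][[pls_cmb]]
      if (i == 1) return(sol)
      applyAlignment(sol,
                     alignStates(solutions[[1]][[pls_cmb]],
                                 sol)$permutation)
    })
    brain_parts <- lapply(seq_len(cfg$n_subjects), function(i) {
      sim <- simulateSubjectTimeseries(gt, i, config$seed)
      std <- segmentwiseStandardize(sim$series, gt@segment_bounds)
      colnames(std) <- colnames(sim$series)
      lb <- config$limbic_for_pls
      lcols <- std[, grepl(paste0("^", lb, "_L_"), colnames(std)),
                   drop = FALSE]
      rcols <- std[, grepl(paste0("^", lb, "_R_"), colnames(std)),
                   drop = FALSE]
      emb_i <- fitLimbicPca(lcols, rcols)
      X <- assembleCombination(
        std[, grepl(paste0("^", config$pls_network, "_"),
                    colnames(std)), drop = FALSE],
        emb_i$embeddings)
      partitionByState(statePresence(aligned[[i]]), X)
    })
    descr_parts <- lapply(seq_len(cfg$n_subjects), function(i)
      partitionByState(statePresence(aligned[[i]]), E))
    groups <- concatGroup(brain_parts, descr_parts)
    lapply(seq_along(groups), function(k) {
      g <- groups[[k]]
      if (nrow(g$G) < 2 * config$n_folds) return(NULL)
      crossvalPls(g$E, g$G, g$subject, n_folds = config$n_folds,
                  state = k)
    })
  })
  for (k in seq_along(signatures)) {
    if (is.null(signatures[[k]])) next
    sig <- signatures[[k]]
    jsonlite::write_json(
      list(state = k, cv_mean = sig@cv_mean,
           cv_correlations = sig@cv_correlations,
           description_loadings = sig@description_loadings,
           brain_loadings = sig@brain_loadings),
      out(sprintf("signature_state%d.json", k)), digits = NA,
      auto_unbox = TRUE, pretty = TRUE)
  }

  bundle <- list(config = config, ground_truth = gt,
                 contexts = contexts, annotations = ann,
                 solutions = solutions, link_table = link_table,
                 dwell_table = dwell, signatures = signatures,
                 pca_models = pca_models)
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("nbstates")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("gt_config", "out_dir"))],
    gt_config = config$gt_config[!vapply(config$gt_config, is.null,
                                         logical(1))],
    files = as.list(setNames(
      unname(tools::md5sum(file.path(config$out_dir, files))), files)))
  jsonlite::write_json(manifest, out("manifest.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(bundle)
}

#' Build the description matrix from observer intervals
#'
#' IOA rasterization of every attribute in the spec: unipolar attributes
#' keep the per-character episode-median aggregation, bipolar attributes
#' subtract the two poles, binary attributes become presence series.
#'
#' @param intervals observer interval data.frame.
#' @param spec attribute spec (name, category, kind, character).
#' @param n_observers observer count.
#' @param T timepoints.
#' @param tr_seconds bin width.
#' @return an [AnnotationMatrix-class].
#' @export
buildAnnotationMatrix <- function(intervals, spec, n_observers, T,
                                  tr_seconds = 2) {
  binary_series <- list()
  episodes <- list()
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    if (spec$kind[i] == "binary") {
      ioa <- computeIoa(intervals, nm, n_observers, T, tr_seconds)
      binary_series[[nm]] <- as.numeric(ioa >= 0.5)
    } else if (spec$kind[i] == "bipolar") {
      pv <- switch(nm, arousal = c("high", "low"),
                   valence = c("positive", "negative"),
                   direction = c("self", "other"),
                   c("present", "absent"))
      pos <- computeIoa(intervals, nm, n_observers, T, tr_seconds,
                        value = pv[1])
      neg <- computeIoa(intervals, nm, n_observers, T, tr_seconds,
                        value = pv[2])
      series <- bipolarIoa(pos, neg)
      eps <- detectEpisodes(setNames(list(series), nm))
      episodes[[nm]] <- eps
    } else {
      ioa <- computeIoa(intervals, nm, n_observers, T, tr_seconds,
                        character_id = spec$character[i])
      eps <- detectEpisodes(setNames(list(ioa), nm))
      episodes[[nm]] <- eps
    }
  }
  aggregateAnnotationSeries(episodes, spec, T, binary_series)
}

#' Write a human-readable markdown report from a results bundle
#'
#' @param bundle list returned by [runPipeline()].
#' @param path output markdown file.
#' @return invisibly, the report lines.
#' @export
writeReport <- function(bundle, path) {
  need <- c("link_table", "dwell_table", "signatures")
  miss <- need[!need %in% names(bundle)]
  if (length(miss))
    stop(sprintf("incomplete bundle, missing: %s",
                 paste(miss, collapse = ", ")))
  lt <- bundle$link_table
  med <- vapply(split(lt$link_index, lt$network), median, numeric(1))
  lines <- c("# Pipeline report", "",
             "## Median semantics-brain link index per network", "")
  for (nm in names(sort(med, decreasing = TRUE)))
    lines <- c(lines, sprintf("- %s: %.6g", nm, med[[nm]]))
  lines <- c(lines, "", "## Dwell-time summary per combination", "")
  dt <- bundle$dwell_table
  for (cmb in unique(dt$combination)) {
    sub <- dt[dt$combination == cmb, ]
    lines <- c(lines, sprintf(
      "- %s: mean dwell %.6g s (sd %.6g s) across %d subjects",
      cmb, mean(sub$mean_dwell), mean(sub$sd_dwell), nrow(sub)))
  }
  lines <- c(lines, "", "## Group PLS signatures", "")
  for (k in seq_along(bundle$signatures)) {
    sig <- bundle$signatures[[k]]
    if (is.null(sig)) next
    lines <- c(lines, sprintf("- state %d: CV mean r = %.6g", k,
                              sig@cv_mean))
  }
  writeLines(lines, path)
  invisible(lines)
}
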