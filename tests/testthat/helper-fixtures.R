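# Shared fixtures, memoized so expensive synthetic-study builds run once
# per session.

.fixtures <- new.env(parent = emptyenv())

fixtureMemo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), .fixtures)
  get(name, .fixtures)
}

# one-network study at full timeline: combination "DN&HC" has R = 12
gtSmall <- function() fixtureMemo("gt_small",
  generateGroundTruth(groundTruthConfig(seed = 4, networks = c(DN = 6L))))

streamSmall <- function() fixtureMemo("stream_small",
  simulateSubtitleStream(gtSmall(), seed = 2))

contextsSmall <- function() fixtureMemo("contexts_small", {
  tl <- preprocessTokens(streamSmall()$timeline)
  tf <- tfidfTransform(smoothCounts(buildWordCountMatrix(tl), 4, 2))
  suppressMessages(fitNmfLsa(tf, s = 50, seed = 3))
})

combinationSmall <- function() fixtureMemo("combination_small",
  simulateCombinationSeries(gtSmall(), "DN&HC", seed = 2,
                            use_chain = TRUE))

# five-subject, four-network cohort with the DN analog coupled at
# rho = 0.4 (the headline-pattern conditions)
gtHeadline <- function() fixtureMemo("gt_headline",
  generateGroundTruth(groundTruthConfig(
    seed = 5, n_subjects = 5,
    networks = c(VIS = 8L, SMN = 8L, DAN = 8L, DN = 12L),
    limbic = c(HC = 10L, AM = 6L))))

contextsHeadline <- function() fixtureMemo("contexts_headline", {
  st <- simulateSubtitleStream(gtHeadline(), seed = 2)
  tl <- preprocessTokens(st$timeline)
  tf <- tfidfTransform(smoothCounts(buildWordCountMatrix(tl), 4, 2))
  suppressMessages(fitNmfLsa(tf, s = 50, seed = 3))
})

# per-subject per-network fits and permutation p-values for the headline
# cohort; computed once, used by linkage and acceptance tests
headlineLinkTable <- function() fixtureMemo("headline_link_table", {
  gt <- gtHeadline()
  W <- contextExpressions(contextsHeadline())
  rows <- list()
  for (i in seq_len(gt@config$n_subjects)) {
    sim <- simulateSubjectTimeseries(gt, i, seed = 1)
    std <- segmentwiseStandardize(sim$series, gt@segment_bounds)
    colnames(std) <- colnames(sim$series)
    emb <- fitLimbicPca(std[, grepl("^HC_L_", colnames(std))],
                        std[, grepl("^HC_R_", colnames(std))])$embeddings
    for (g in names(gt@networks)) {
      X <- assembleCombination(
        std[, grepl(paste0("^", g, "_p"), colnames(std))], emb)
      sol <- multiRestartFit(X, 4, W, n_restarts = 5,
                             seed = i * 100 + match(g, names(gt@networks)))
      pt <- permutationTest(statePresence(sol), W, B = 200, seed = 7)
      rows[[paste(i, g)]] <- data.frame(
        subject = i, network = g, link = attr(sol, "link_index"),
        p = pt@p_value)
    }
  }
  do.call(rbind, rows)
})

demoPipelineConfig <- function(out_dir) {
  pipelineConfig(
    out_dir = out_dir, seed = 9,
    gt_config = groundTruthConfig(
      n_subjects = 3, n_timepoints = 400, n_segments = 4L,
      networks = c(VIS = 6L, DN = 8L), limbic = c(HC = 8L, AM = 5L),
      seed = 5),
    s = 20L, n_restarts = 3L, B = 100L, n_folds = 5L)
}

demoBundle <- function() fixtureMemo("demo_bundle", {
  dir <- file.path(tempdir(), "nbstates-demo")
  suppressMessages(runPipeline(demoPipelineConfig(dir)))
})
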