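test_that("ground truth layout follows the configured cohort", {
  gt2 <- generateGroundTruth(groundTruthConfig(
    seed = 1, networks = c(DN = 6L, VIS = 5L),
    limbic = c(HC = 4L, AM = 3L), calibrate_coupling = FALSE))
  # 2 networks x 2 limbic structures -> 4 combinations
  expect_length(gt2@hmm_params, 4L)
  # every transition row sums to 1
  for (p in gt2@hmm_params)
    expect_lt(max(abs(rowSums(p$Theta) - 1)), 1e-12)
  # covariances symmetric positive definite
  for (p in gt2@hmm_params) for (S in p$covariances) {
    expect_lt(max(abs(S - t(S))), 1e-10)
    expect_gt(min(eigen(S, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  # topic word probabilities sum to one
  expect_equal(unname(rowSums(gt2@topics$topic_word_probs)),
               rep(1, 10))
  # segment bounds partition the timeline
  sb <- gt2@segment_bounds
  expect_equal(unname(sb[1, 1]), 0)
  expect_equal(unname(sb[nrow(sb), 2]), gt2@config$n_timepoints)

  # the default study layout: 14 combinations, 4 states each
  gt <- gtHeadline()   # reduced cohort, same construction
  full <- groundTruthConfig()
  expect_equal(length(full$networks) * length(full$limbic), 14L)
  expect_equal(full$n_timepoints, 3543L)
  expect_equal(full$n_subjects, 15L)
  # invalid settings are rejected
  expect_error(groundTruthConfig(networks = c(A = 3L)))
  expect_error(groundTruthConfig(coupling_rho = 1.5))
})

test_that("subject simulation is reproducible and correctly shaped", {
  gt <- gtSmall()
  sim1 <- simulateSubjectTimeseries(gt, 1, seed = 1)
  sim2 <- simulateSubjectTimeseries(gt, 1, seed = 1)
  expect_identical(sim1$series, sim2$series)   # same seed, same bytes
  sim3 <- simulateSubjectTimeseries(gt, 2, seed = 1)
  expect_false(identical(sim1$series, sim3$series))
  # 3543 rows; columns = parcels + 2 x (19 + 9) limbic subregions
  expect_equal(nrow(sim1$series), 3543L)
  expect_equal(ncol(sim1$series), 6L + 2L * (19L + 9L))
  expect_equal(nrow(sim1$metadata), ncol(sim1$series))
  expect_named(sim1$true_states, names(gt@hmm_params))
  expect_error(simulateSubjectTimeseries(gt, 99, seed = 1),
               "out of range")
})

test_that("chain occupancy matches the stationary distribution", {
  gt <- generateGroundTruth(groundTruthConfig(
    seed = 2, networks = c(DN = 5L), self_transition = 0.8,
    calibrate_coupling = FALSE))
  sim <- simulateCombinationSeries(gt, "DN&HC", seed = 3, T = 10000)
  Theta <- gt@hmm_params[["DN&HC"]]$Theta
  # stationary distribution by eigen-decomposition of t(Theta)
  e <- eigen(t(Theta))
  stat <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stat <- stat / sum(stat)
  freq <- tabulate(sim$states, 4) / 10000
  expect_lt(max(abs(freq - stat)), 0.03)
})

test_that("true parameters decode their own simulation without EM", {
  gt <- gtSmall()     # mean separation 4: well-separated regime
  sim <- combinationSmall()
  p <- gt@hmm_params[["DN&HC"]]
  fb <- forwardBackward(sim$series, p$pi, p$Theta, p$means,
                        p$covariances)
  acc <- mean(hardAssign(fb$gamma) == sim$states)
  expect_gte(acc, 0.9)
})

test_that("the token stream stays inside the closed vocabulary", {
  gt <- gtSmall()
  st <- streamSmall()
  toks <- unlist(st$timeline@tokens)
  expect_true(all(toks %in% gt@topics$vocabulary))
  # nonnegative expression proxies
  expect_gte(min(st$topic_counts), 0)
  # bit-reproducible under a fixed seed
  st2 <- simulateSubtitleStream(gt, seed = 2)
  expect_identical(st$timeline@tokens, st2$timeline@tokens)
  expect_identical(st$srt, st2$srt)
})

test_that("SRT serialization round-trips the token timeline exactly", {
  st <- streamSmall()
  back <- parseTimedText(st$srt, 2, gtSmall()@config$n_timepoints)
  expect_identical(back@tokens, st$timeline@tokens)
})

test_that("realized topic coupling lands near the target rho", {
  # planted rho = 0.5: realized smoothed-expression correlation with
  # the smoothed planted presence within [0.4, 0.6]
  gt <- generateGroundTruth(groundTruthConfig(
    seed = 3, networks = c(DN = 6L), coupling_rho = 0.5))
  st <- simulateSubtitleStream(gt, seed = 1)
  hw <- 60
  rr <- vapply(seq_len(nrow(gt@coupling)), function(i) {
    z <- as.numeric(gt@state_chains[[gt@coupling$network[i]]] ==
                    gt@coupling$state[i])
    cor(boxcar(st$topic_counts[, gt@coupling$topic[i]], hw),
        boxcar(z, hw))
  }, numeric(1))
  expect_gte(mean(rr), 0.4)
  expect_lte(mean(rr), 0.6)
})

test_that("observer annotations respect the planted agreement levels", {
  gt <- gtSmall()
  iv <- simulateObserverAnnotations(gt, seed = 3)
  expect_equal(max(iv$observer_id), 9L)   # default observer count
  dur <- gt@config$n_timepoints * gt@config$tr_seconds
  expect_true(all(iv$start_s >= 0 & iv$end_s <= dur &
                  iv$start_s < iv$end_s))

  # full agreement: IOA = 1 on every planted episode bin
  gt1 <- generateGroundTruth(groundTruthConfig(
    seed = 6, networks = c(DN = 5L), agreement = 1,
    calibrate_coupling = FALSE))
  iv1 <- simulateObserverAnnotations(gt1, 9, seed = 1)
  T <- gt1@config$n_timepoints
  ep <- gt1@episodes[gt1@episodes$attribute == "forrest_happiness", ]
  ioa <- computeIoa(iv1, "forrest_happiness", 9, T, 2)
  bins <- unique(unlist(lapply(seq_len(nrow(ep)), function(i)
    (floor(ep$start_s[i] / 2) + 1):min(ceiling(ep$end_s[i] / 2), T))))
  expect_true(all(ioa[bins] == 1))

  # agreement 0.6: mean IOA over planted episode bins near 0.6
  gt6 <- generateGroundTruth(groundTruthConfig(
    seed = 7, networks = c(DN = 5L), agreement = 0.6,
    calibrate_coupling = FALSE))
  iv6 <- simulateObserverAnnotations(gt6, 9, seed = 2)
  T6 <- gt6@config$n_timepoints
  vals <- c()
  for (att in unique(gt6@episodes$attribute)[1:20]) {
    ep <- gt6@episodes[gt6@episodes$attribute == att, ]
    if (att %in% c("arousal", "valence", "direction")) next
    ioa <- computeIoa(iv6, att, 9, T6, 2)
    bins <- unique(unlist(lapply(seq_len(nrow(ep)), function(i)
      (floor(ep$start_s[i] / 2) + 1):min(ceiling(ep$end_s[i] / 2),
                                         T6))))
    vals <- c(vals, ioa[bins])
  }
  expect_gte(length(vals), 100L)
  expect_gte(mean(vals), 0.5)
  expect_lte(mean(vals), 0.7)
})
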