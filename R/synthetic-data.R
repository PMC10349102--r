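## Ground-truth-known synthetic study generator: stimulus-locked hidden
## state chains per network, Gaussian subregion emissions, a topic-coupled
## token stream serialized as SubRip text, and multi-observer annotation
## intervals. Defaults mirror the emulated study layout: 15 subjects x
## 3543 timepoints at TR = 2 s in 8 segments, 7 neocortical networks of
## 5-24 parcels, 19 hippocampal and 9 amygdalar subregions per
## hemisphere, 4 hidden states per region-network combination.

#' Default generator settings
#'
#' @param n_subjects cohort size.
#' @param n_timepoints timepoints per subject.
#' @param tr_seconds repetition time, seconds.
#' @param n_segments movie cuts (near-equal blocks).
#' @param n_states hidden states per combination.
#' @param networks named integer vector of parcels per network (5..24).
#' @param limbic named integer vector of subregions per hemisphere.
#' @param self_transition per-state self-transition probability; a
#'   single value, or a vector recycled over networks (named entries are
#'   matched by network name). The default plants the
#'   unimodal-to-associative dwell-time gradient: fast visual dynamics
#'   (mean dwell TR/(1-a) = 10 s) up to slow default-network dynamics
#'   (25 s).
#' @param mean_separation minimum pairwise Mahalanobis distance between
#'   state means (well-separated regime).
#' @param n_topics planted semantic topics in the token stream.
#' @param words_per_topic signature words per topic (disjoint supports).
#' @param n_background_words words of the state-independent background.
#' @param tokens_per_bin Poisson mean of tokens per TR bin.
#' @param zero_inflation probability of a silent (token-free) bin.
#' @param topic_base_weight state-independent mixture weight per topic.
#' @param idio_weight gain of each topic's idiosyncratic episodic
#'   activation (recurring theme bursts unrelated to the brain states;
#'   makes topics temporally separable).
#' @param idio_episodes expected episodic bursts per topic.
#' @param idio_minutes length-2 range of burst durations, minutes.
#' @param coupling data.frame (topic, network, state, rho) of planted
#'   topic-to-state couplings; NULL plants every topic on the `coupled_network`
#'   with states cycling 1..n_states at `coupling_rho`.
#' @param coupled_network,coupling_rho used when `coupling` is NULL.
#' @param n_observers annotation observers.
#' @param agreement planted probability that an observer marks an episode.
#' @param calibrate_coupling run the bisection that tunes token-emission
#'   gains to the target rho values (skip when the token stream is not
#'   needed; gains then default to 1).
#' @param seed master seed.
#' @return a settings list for [generateGroundTruth()].
#' @export
groundTruthConfig <- function(n_subjects = 15L, n_timepoints = 3543L,
                              tr_seconds = 2, n_segments = 8L,
                              n_states = 4L,
                              networks = c(VIS = 14L, SMN = 15L,
                                           DAN = 13L, VAN = 12L,
                                           LIM = 5L, FPC = 17L,
                                           DN = 24L),
                              limbic = c(HC = 19L, AM = 9L),
                              self_transition = c(VIS = 0.80,
                                                  SMN = 0.82,
                                                  DAN = 0.84,
                                                  VAN = 0.86,
                                                  LIM = 0.88,
                                                  FPC = 0.90,
                                                  DN = 0.92),
                              mean_separation = 4,
                              n_topics = 10L, words_per_topic = 12L,
                              n_background_words = 40L,
                              tokens_per_bin = 4, zero_inflation = 0.3,
                              topic_base_weight = 0.05,
                              idio_weight = 2.0, idio_episodes = 8L,
                              idio_minutes = c(1, 5),
                              coupling = NULL,
                              coupled_network = "DN",
                              coupling_rho = 0.4,
                              n_observers = 9L, agreement = 0.8,
                              calibrate_coupling = TRUE,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_subjects > 0, n_timepoints > 0, tr_seconds > 0,
            n_segments > 0, n_states > 1,
            all(networks >= 5), all(networks <= 24),
            all(self_transition > 0), all(self_transition < 1),
            is.null(coupling) ||
              all(coupling$rho > 0 & coupling$rho < 1),
            coupling_rho > 0, coupling_rho < 1)
  cfg
}

.segmentBounds <- function(T, n_segments) {
  cuts <- round(seq(0, T, length.out = n_segments + 1))
  cbind(start = cuts[-length(cuts)], end = cuts[-1])
}

.simulateChain <- function(pi, Theta, T) {
  n <- length(pi)
  z <- integer(T)
  z[1] <- sample.int(n, 1, prob = pi)
  for (t in 2:T) z[t] <- sample.int(n, 1, prob = Theta[z[t - 1], ])
  z
}

# symmetric diagonal-dominant covariance; off-diagonals drawn then the
# matrix projected to the nearest SPD by eigenvalue clipping
.randomSpd <- function(R, off_scale = 0.2, floor = 0.05) {
  S <- diag(R)
  if (R > 1) {
    off <- matrix(runif(R * R, -off_scale, off_scale), R, R)
    off <- (off + t(off)) / 2
    diag(off) <- 0
    S <- S + off
  }
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  S <- e$vectors %*% (vals * t(e$vectors))
  (S + t(S)) / 2
}

.rmvn <- function(n, mu, Sigma) {
  ch <- chol(Sigma)
  matrix(rnorm(n * length(mu)), n) %*% ch +
    matrix(mu, n, length(mu), byrow = TRUE)
}

# draw state means separated by at least `sep` in (approximate)
# Mahalanobis distance: random directions rescaled so the minimum
# pairwise Euclidean distance hits `sep` (covariances are near-identity)
.separatedMeans <- function(n_states, R, sep) {
  M <- matrix(rnorm(n_states * R), n_states, R)
  d <- as.matrix(dist(M))
  diag(d) <- Inf
  M * (sep / min(d))
}

.boxcarSmooth <- function(x, hw) {
  T <- length(x)
  if (hw < 1) return(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(T) - hw, 1L)
  hi <- pmin(seq_len(T) + hw, T)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1)
}

# draw the token stream for given per-topic gains; returns per-bin token
# lists and the per-bin topic signature-word counts
.drawTokens <- function(T, topics, weights_t, lambda, zero_inflation) {
  vocab <- topics$vocabulary
  n_topics <- nrow(topics$topic_word_probs)
  counts <- matrix(0, T, n_topics)
  toks <- vector("list", T)
  n_t <- rpois(T, lambda) * (runif(T) >= zero_inflation)
  for (t in seq_len(T)) {
    if (n_t[t] == 0) { toks[[t]] <- character(); next }
    w <- weights_t[t, ]
    src <- sample.int(n_topics + 1L, n_t[t], replace = TRUE, prob = w)
    out <- character(n_t[t])
    for (i in seq_len(n_t[t])) {
      p <- if (src[i] <= n_topics) topics$topic_word_probs[src[i], ]
           else topics$background_probs
      out[i] <- vocab[sample.int(length(vocab), 1, prob = p)]
    }
    toks[[t]] <- out
    tc <- table(factor(src[src <= n_topics], levels = seq_len(n_topics)))
    counts[t, ] <- counts[t, ] + as.numeric(tc)
  }
  list(tokens = toks, topic_counts = counts)
}

# mixture weights per bin: background + base topic weight + the topic's
# idiosyncratic episodic activation + coupled gain following the
# default-window-smoothed planted state presence
.topicWeights <- function(cfg, coupling, smoothed_presence, beta_by_rho,
                          idio) {
  T <- nrow(smoothed_presence$per_topic)
  n_topics <- cfg$n_topics
  W <- matrix(cfg$topic_base_weight, T, n_topics) +
    cfg$idio_weight * idio
  for (i in seq_len(nrow(coupling))) {
    j <- coupling$topic[i]
    W[, j] <- W[, j] + beta_by_rho[[as.character(coupling$rho[i])]] *
      smoothed_presence$per_topic[, j]
  }
  cbind(W, background = 1)
}

# per-topic idiosyncratic activation: episodic bursts smoothed at the
# analysis timescale
.idioActivation <- function(cfg) {
  T <- cfg$n_timepoints
  hw <- floor(4 * 60 / 2 / cfg$tr_seconds)
  len_bins <- round(cfg$idio_minutes * 60 / cfg$tr_seconds)
  out <- matrix(0, T, cfg$n_topics)
  for (j in seq_len(cfg$n_topics)) {
    n_ep <- rpois(1, cfg$idio_episodes) + 1L
    b <- numeric(T)
    for (e in seq_len(n_ep)) {
      len <- sample(len_bins[1]:len_bins[2], 1)
      s0 <- sample.int(max(T - len, 1), 1)
      b[s0:(s0 + len - 1)] <- 1
    }
    out[, j] <- .boxcarSmooth(b, hw)
  }
  out
}

.smoothedPresence <- function(cfg, coupling, chains) {
  T <- cfg$n_timepoints
  hw <- floor(4 * 60 / 2 / cfg$tr_seconds)   # default 4-min analysis window
  per_topic <- matrix(0, T, cfg$n_topics)
  raw <- matrix(0, T, cfg$n_topics)
  for (i in seq_len(nrow(coupling))) {
    z <- as.numeric(chains[[coupling$network[i]]] == coupling$state[i])
    raw[, coupling$topic[i]] <- z
    per_topic[, coupling$topic[i]] <- .boxcarSmooth(z, hw)
  }
  list(per_topic = per_topic, raw = raw, any = per_topic, hw = hw)
}

# realized coupling: correlation between the smoothed signature-word
# counts and the smoothed planted presence, averaged over coupled topics
# and over a few token draws (the smoothed series have few effective
# degrees of freedom, so a single draw is a noisy estimate)
.realizedRho <- function(cfg, topics, coupling, sp, beta, idio,
                         n_rep = 3L) {
  W <- matrix(cfg$topic_base_weight, cfg$n_timepoints, cfg$n_topics) +
    cfg$idio_weight * idio
  for (i in seq_len(nrow(coupling)))
    W[, coupling$topic[i]] <- W[, coupling$topic[i]] +
      beta * sp$per_topic[, coupling$topic[i]]
  weights_t <- cbind(W, background = 1)
  mean(vapply(seq_len(n_rep), function(rep) {
    drawn <- .drawTokens(cfg$n_timepoints, topics, weights_t,
                         cfg$tokens_per_bin, cfg$zero_inflation)
    mean(vapply(seq_len(nrow(coupling)), function(i) {
      j <- coupling$topic[i]
      x <- .boxcarSmooth(drawn$topic_counts[, j], sp$hw)
      suppressWarnings(cor(x, sp$per_topic[, j]))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1)))
}

#' Generate the ground truth of a synthetic study
#'
#' Builds every planted ingredient: per-network hidden Markov chains
#' (shared by all subjects — stimulus-locked dynamics), Gaussian emission
#' parameters for each region-network combination, a topic dictionary
#' with calibrated topic-to-state coupling gains (bisection on the
#' emission gain until the realized smoothed-expression/state-presence
#' correlation hits the target rho), and planted annotation episodes.
#'
#' @param config settings from [groundTruthConfig()].
#' @return a [GroundTruth-class].
#' @export
generateGroundTruth <- function(config = groundTruthConfig()) {
  cfg <- config
  n <- cfg$n_states
  T <- cfg$n_timepoints
  .withSeed(.subSeed(cfg$seed, 101L), {
    seg <- .segmentBounds(T, cfg$n_segments)
    # per-network chain + emission parameters
    net_params <- list()
    chains <- list()
    st <- rep_len(cfg$self_transition, length(cfg$networks))
    if (!is.null(names(cfg$self_transition)))
      for (g in names(cfg$networks))
        if (g %in% names(cfg$self_transition))
          st[match(g, names(cfg$networks))] <- cfg$self_transition[[g]]
    for (g in names(cfg$networks)) {
      r <- cfg$networks[[g]]
      a <- st[match(g, names(cfg$networks))]
      Theta <- matrix((1 - a) / (n - 1), n, n)
      diag(Theta) <- a
      pi0 <- rep(1 / n, n)
      means <- .separatedMeans(n, r, cfg$mean_separation)
      covs <- lapply(seq_len(n), function(k) .randomSpd(r))
      net_params[[g]] <- list(pi = pi0, Theta = Theta, means = means,
                              covariances = covs)
      chains[[g]] <- .simulateChain(pi0, Theta, T)
    }
    # combination parameters: network block + inert limbic PC block
    hmm_params <- list()
    for (g in names(cfg$networks)) {
      for (lb in names(cfg$limbic)) {
        np <- net_params[[g]]
        r <- cfg$networks[[g]]
        R <- r + 6L
        means <- cbind(np$means, matrix(0, n, 6))
        covs <- lapply(seq_len(n), function(k) {
          S <- diag(R)
          S[seq_len(r), seq_len(r)] <- np$covariances[[k]]
          S
        })
        hmm_params[[paste0(g, "&", lb)]] <-
          list(pi = np$pi, Theta = np$Theta, means = means,
               covariances = covs, network = g, limbic = lb)
      }
    }
    # topic dictionary with disjoint signature supports
    n_topics <- cfg$n_topics
    n_tw <- cfg$words_per_topic
    V <- n_topics * n_tw + cfg$n_background_words
    vocab <- sprintf("word%03d", seq_len(V))
    topic_word_probs <- matrix(0, n_topics, V)
    for (j in seq_len(n_topics)) {
      idx <- (j - 1) * n_tw + seq_len(n_tw)
      p <- rexp(n_tw) + 0.2
      topic_word_probs[j, idx] <- p / sum(p)
    }
    bg <- numeric(V)
    bg_idx <- n_topics * n_tw + seq_len(cfg$n_background_words)
    p <- rexp(cfg$n_background_words) + 0.2
    bg[bg_idx] <- p / sum(p)
    topics <- list(vocabulary = vocab,
                   topic_word_probs = topic_word_probs,
                   background_probs = bg)
    # coupling table (default: all topics on one network, cycling states)
    coupling <- cfg$coupling
    if (is.null(coupling))
      coupling <- data.frame(
        topic = seq_len(n_topics),
        network = cfg$coupled_network,
        state = ((seq_len(n_topics) - 1) %% n) + 1L,
        rho = cfg$coupling_rho)
    stopifnot(all(coupling$network %in% names(cfg$networks)),
              all(coupling$rho > 0 & coupling$rho < 1))
    idio <- .idioActivation(cfg)
    topics$idio_activation <- idio
    sp <- .smoothedPresence(cfg, coupling, chains)
    beta_by_rho <- list()
    if (!cfg$calibrate_coupling)
      for (rho in unique(coupling$rho))
        beta_by_rho[[as.character(rho)]] <- 1
    else for (rho in unique(coupling$rho)) {
      sub <- coupling[coupling$rho == rho, , drop = FALSE]
      lo <- 0; hi <- 2
      # expand until the bracket covers the target, then bisect
      while (.realizedRho(cfg, topics, sub, sp, hi, idio) < rho &&
             hi < 512)
        hi <- hi * 2
      for (it in seq_len(10)) {
        mid <- (lo + hi) / 2
        if (.realizedRho(cfg, topics, sub, sp, mid, idio) < rho)
          lo <- mid
        else hi <- mid
      }
      beta_by_rho[[as.character(rho)]] <- (lo + hi) / 2
    }
    coupling$beta <- vapply(coupling$rho, function(r)
      beta_by_rho[[as.character(r)]], numeric(1))
    # planted annotation attributes and episodes
    spec <- .defaultAnnotationSpec(cfg)
    episodes <- .plantEpisodes(spec, T * cfg$tr_seconds)
    new("GroundTruth", config = cfg,
        networks = vapply(cfg$networks, as.integer, integer(1)),
        limbic = vapply(cfg$limbic, as.integer, integer(1)),
        segment_bounds = seg, hmm_params = hmm_params,
        state_chains = chains, topics = topics, coupling = coupling,
        annotation_spec = spec, episodes = episodes,
        seed = as.integer(cfg$seed))
  })
}

# 52 default attributes: 4 characters x 11 emotions (unipolar), 3
# bipolar dimensional indicators, 4 binary location/time annotations and
# 1 binary soundtrack flag
.defaultAnnotationSpec <- function(cfg) {
  characters <- c("forrest", "jenny", "dan", "mrsgump")
  emotions <- c("happiness", "fear", "love", "sadness", "anger",
                "surprise", "disgust", "pride", "shame", "gratitude",
                "hope")
  uni <- expand.grid(character = characters, emotion = emotions,
                     stringsAsFactors = FALSE)
  spec <- data.frame(
    name = c(paste(uni$character, uni$emotion, sep = "_"),
             "arousal", "valence", "direction",
             "interior", "exterior", "day", "night", "music"),
    category = c(rep("emotion", nrow(uni) + 3), rep("place", 4),
                 "other"),
    kind = c(rep("unipolar", nrow(uni)), rep("bipolar", 3),
             rep("binary", 5)),
    character = c(uni$character, rep("scene", 8)),
    agreement = cfg$agreement)
  spec
}

.plantEpisodes <- function(spec, duration_s) {
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    n_ep <- rpois(1, 4) + 1L
    starts <- sort(runif(n_ep, 0, duration_s - 60))
    lens <- runif(n_ep, 10, 60)
    value <- if (spec$kind[i] == "bipolar") {
      pole <- sample(c("pos", "neg"), n_ep, replace = TRUE)
      c(pos = switch(spec$name[i], arousal = "high",
                     valence = "positive", direction = "self"),
        neg = switch(spec$name[i], arousal = "low",
                     valence = "negative", direction = "other"))[pole]
    } else rep("present", n_ep)
    rows[[i]] <- data.frame(
      attribute = spec$name[i], character = spec$character[i],
      start_s = starts, end_s = pmin(starts + lens, duration_s),
      value = unname(value))
  }
  do.call(rbind, rows)
}

#' Simulate one region-network combination's feature series
#'
#' Draws directly from a combination's stored generative model: a fresh
#' hidden chain (or the stimulus-locked chain shared by all subjects)
#' and multivariate Gaussian emissions.
#'
#' @param gt a [GroundTruth-class].
#' @param combination name like `"DN&HC"` (see `names(gt@hmm_params)`).
#' @param seed integer seed.
#' @param T timepoints (defaults to the configured timeline).
#' @param use_chain reuse the stimulus-locked chain instead of sampling a
#'   fresh one (then `T` must equal the configured timeline).
#' @return list with `series` (T x R) and `states` (length-T truth).
#' @export
simulateCombinationSeries <- function(gt, combination, seed = 1L,
                                      T = gt@config$n_timepoints,
                                      use_chain = FALSE) {
  p <- gt@hmm_params[[combination]]
  if (is.null(p)) stop(sprintf("unknown combination '%s'", combination))
  .withSeed(.subSeed(gt@seed, seed, 7L), {
    z <- if (use_chain) gt@state_chains[[p$network]] else
      .simulateChain(p$pi, p$Theta, T)
    R <- ncol(p$means)
    X <- matrix(0, T, R)
    for (k in seq_len(gt@config$n_states)) {
      idx <- which(z == k)
      if (length(idx))
        X[idx, ] <- .rmvn(length(idx), p$means[k, ], p$covariances[[k]])
    }
    list(series = X, states = z)
  })
}

#' Simulate one subject's full subregion time-series table
#'
#' Network parcels are emitted from the stimulus-locked per-network
#' hidden chains; hippocampal and amygdalar subregions follow a
#' three-factor latent structure per hemisphere (so the shared-PCA
#' embedding is well-defined) independent of the chains. All subjects
#' share the hidden chains; emissions are subject-specific.
#'
#' @param gt a [GroundTruth-class].
#' @param subject_id 1-based subject index.
#' @param seed integer seed.
#' @return list with `series` (T x D matrix, named columns), `metadata`
#'   (data.frame: subregion_id, structure, hemisphere, network) and
#'   `true_states` (per-combination hidden sequences).
#' @export
simulateSubjectTimeseries <- function(gt, subject_id, seed = 1L) {
  cfg <- gt@config
  if (subject_id < 1 || subject_id > cfg$n_subjects)
    stop("subject_id out of range")
  T <- cfg$n_timepoints
  .withSeed(.subSeed(gt@seed, seed, subject_id, 13L), {
    cols <- list()
    meta <- list()
    for (g in names(gt@networks)) {
      p <- gt@hmm_params[[paste0(g, "&HC")]]
      r <- gt@networks[[g]]
      z <- gt@state_chains[[g]]
      X <- matrix(0, T, r)
      for (k in seq_len(cfg$n_states)) {
        idx <- which(z == k)
        if (length(idx))
          X[idx, ] <- .rmvn(length(idx), p$means[k, seq_len(r)],
                            p$covariances[[k]][seq_len(r), seq_len(r)])
      }
      ids <- sprintf("%s_p%02d", g, seq_len(r))
      colnames(X) <- ids
      cols[[g]] <- X
      meta[[g]] <- data.frame(subregion_id = ids, structure = g,
                              hemisphere = "both", network = g)
    }
    for (lb in names(gt@limbic)) {
      m <- gt@limbic[[lb]]
      for (hemi in c("L", "R")) {
        L <- matrix(rnorm(3 * m), 3, m)
        F <- matrix(rnorm(T * 3), T, 3)
        X <- F %*% L + 0.5 * matrix(rnorm(T * m), T, m)
        ids <- sprintf("%s_%s_s%02d", lb, hemi, seq_len(m))
        colnames(X) <- ids
        cols[[paste(lb, hemi, sep = "_")]] <- X
        meta[[paste(lb, hemi, sep = "_")]] <- data.frame(
          subregion_id = ids, structure = lb, hemisphere = hemi,
          network = NA_character_)
      }
    }
    true_states <- lapply(gt@hmm_params, function(p)
      gt@state_chains[[p$network]])
    list(series = do.call(cbind, cols),
         metadata = do.call(rbind, c(meta, make.row.names = FALSE)),
         true_states = true_states)
  })
}

#' Simulate the topic-coupled subtitle stream
#'
#' Per timepoint, a zero-inflated Poisson number of tokens is drawn from
#' a mixture of a background word distribution and the planted topics,
#' whose mixture weights follow the smoothed planted state presence with
#' the calibrated gains. The stream is returned both as a
#' [TokenTimeline-class] and as serialized SubRip text (one cue per
#' non-silent TR bin).
#'
#' @param gt a [GroundTruth-class].
#' @param seed integer seed.
#' @return list with `timeline`, `srt` (single string),
#'   `topic_counts` (T x n_topics signature-word draws per bin).
#' @export
simulateSubtitleStream <- function(gt, seed = 1L) {
  cfg <- gt@config
  sp <- .smoothedPresence(cfg, gt@coupling, gt@state_chains)
  beta_by_rho <- as.list(setNames(gt@coupling$beta,
                                  as.character(gt@coupling$rho)))
  weights_t <- .topicWeights(cfg, gt@coupling, sp, beta_by_rho,
                             gt@topics$idio_activation)
  drawn <- .withSeed(.subSeed(gt@seed, seed, 23L),
    .drawTokens(cfg$n_timepoints, gt@topics, weights_t,
                cfg$tokens_per_bin, cfg$zero_inflation))
  timeline <- new("TokenTimeline", tokens = drawn$tokens,
                  tr_seconds = cfg$tr_seconds)
  list(timeline = timeline, srt = serializeSrt(timeline),
       topic_counts = drawn$topic_counts)
}

#' Serialize a token timeline as SubRip text
#'
#' One cue per non-empty bin, spanning exactly that bin's `[t*TR,
#' (t+1)*TR)` interval, so parsing the output reproduces the timeline.
#'
#' @param timeline a [TokenTimeline-class].
#' @return a single SubRip-formatted string.
#' @export
serializeSrt <- function(timeline) {
  fmt <- function(s) {
    ms <- round(s * 1000)
    sprintf("%02d:%02d:%02d,%03d", ms %/% 3600000,
            (ms %/% 60000) %% 60, (ms %/% 1000) %% 60, ms %% 1000)
  }
  tr <- timeline@tr_seconds
  out <- character(0)
  cue <- 0L
  for (t in seq_along(timeline@tokens)) {
    toks <- timeline@tokens[[t]]
    if (!length(toks)) next
    cue <- cue + 1L
    out <- c(out, as.character(cue),
             sprintf("%s --> %s", fmt((t - 1) * tr), fmt(t * tr)),
             paste(toks, collapse = " "), "")
  }
  paste(out, collapse = "\n")
}

#' Simulate multi-observer annotation intervals
#'
#' Each observer independently marks each planted episode with the
#' attribute's configured agreement probability; marked intervals copy
#' the planted boundaries.
#'
#' @param gt a [GroundTruth-class].
#' @param n_observers number of observers (study protocol: 9).
#' @param seed integer seed.
#' @return data.frame (observer_id, character, attribute, start_s,
#'   end_s, value).
#' @export
simulateObserverAnnotations <- function(gt, n_observers = 9L, seed = 1L) {
  stopifnot(n_observers >= 1)
  eps <- gt@episodes
  agree <- setNames(gt@annotation_spec$agreement, gt@annotation_spec$name)
  .withSeed(.subSeed(gt@seed, seed, 31L), {
    rows <- list()
    for (o in seq_len(n_observers)) {
      keep <- runif(nrow(eps)) < agree[eps$attribute]
      if (!any(keep)) next
      sub <- eps[keep, , drop = FALSE]
      sub$observer_id <- o
      rows[[o]] <- sub
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, c("observer_id", "character", "attribute", "start_s", "end_s",
            "value")]
  })
}
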