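test_that("SubRip cues land in every TR bin they overlap", {
  srt <- "1\n00:00:01,000 --> 00:00:03,500\nHello world\n"
  tl <- parseTimedText(srt, tr_seconds = 2, n_timepoints = 4)
  expect_equal(tl@tokens[[1]], c("hello", "world"))
  expect_equal(tl@tokens[[2]], c("hello", "world"))
  expect_equal(tl@tokens[[3]], character(0))
  expect_equal(tl@tokens[[4]], character(0))

  # empty input -> empty bins
  tl0 <- parseTimedText("", tr_seconds = 2, n_timepoints = 3)
  expect_equal(lengths(tl0@tokens), rep(0L, 3))

  # cue starting past the last bin is dropped with a warning
  late <- "1\n00:00:10,000 --> 00:00:11,000\ntoo late\n"
  expect_warning(tl2 <- parseTimedText(late, 2, 4), "dropped")
  expect_equal(sum(lengths(tl2@tokens)), 0L)

  # malformed timestamp names the cue
  bad <- "1\n00:00:xx,000 --> 00:00:02,000\noops\n"
  expect_error(parseTimedText(bad, 2, 4), "cue 1")
})

test_that("token preprocessing is idempotent and removes stop words", {
  tl <- preprocessTokens(list(c("The", "DOG", "ran.")),
                         stopwords = "the")
  expect_equal(tl@tokens[[1]], c("dog", "ran"))
  tl2 <- preprocessTokens(list(c("the", "The", "THE")),
                          stopwords = "the")
  expect_equal(tl2@tokens[[1]], character(0))
  once <- preprocessTokens(list(c("A", "b.", "c")), stopwords = "a")
  twice <- preprocessTokens(once, stopwords = "a")
  expect_identical(once@tokens, twice@tokens)
})

test_that("word count matrix matches manual counts and conserves totals", {
  tl <- new("TokenTimeline", tokens = list(c("a", "b", "a"), "b"),
            tr_seconds = 2)
  M <- buildWordCountMatrix(tl)
  expect_equal(vocabulary(M), c("a", "b"))
  expect_equal(unname(valuesMatrix(M)), rbind(c(2, 1), c(0, 1)))

  # empty timeline
  M0 <- buildWordCountMatrix(new("TokenTimeline",
                                 tokens = rep(list(character()), 3),
                                 tr_seconds = 2))
  expect_equal(dim(valuesMatrix(M0)), c(3L, 0L))

  # column sums equal corpus frequencies
  set.seed(1)
  toks <- lapply(1:20, function(i)
    sample(letters[1:5], rpois(1, 3), replace = TRUE))
  M1 <- buildWordCountMatrix(new("TokenTimeline", tokens = toks,
                                 tr_seconds = 2))
  freq <- table(unlist(toks))
  expect_equal(colSums(valuesMatrix(M1)),
               setNames(as.numeric(freq[vocabulary(M1)]),
                        vocabulary(M1)))
})

test_that("sliding-window smoothing follows the truncated-mean rule", {
  mk <- function(v) new("WordCountMatrix", values = cbind(v),
                        vocabulary = "w", stage = "raw")
  M <- mk(c(0, 3, 0, 0, 3))
  # window shorter than one TR: identity
  expect_equal(valuesMatrix(smoothCounts(M, 0.01, 2)), valuesMatrix(M))
  # half-window of 1 bin (0.1 min at TR = 2 s)
  sm <- unname(valuesMatrix(smoothCounts(M, 0.1, 2)))
  expect_equal(sm[2, 1], 1.0)          # (0 + 3 + 0) / 3
  expect_equal(sm[1, 1], 1.5)          # edge: mean of bins 1-2 only
  expect_equal(sm[5, 1], 1.5)

  # matches the direct loop oracle on random matrices
  set.seed(7)
  for (hw in c(1, 3, 10)) {
    V <- matrix(rpois(30 * 4, 2), 30, 4)
    Mv <- new("WordCountMatrix", values = V,
              vocabulary = letters[1:4], stage = "raw")
    w_min <- hw * 2 * 2 / 60            # half-window hw bins at TR = 2
    expect_equal(unname(valuesMatrix(smoothCounts(Mv, w_min, 2))),
                 unname(oracleSmooth(V, hw)), tolerance = 1e-12)
  }

  # interior rows conserve the grand total scale (full windows only)
  V <- matrix(runif(40), 20, 2)
  Mv <- new("WordCountMatrix", values = V, vocabulary = c("a", "b"),
            stage = "raw")
  sm2 <- valuesMatrix(smoothCounts(Mv, 2 * 2 * 2 / 60, 2))  # hw = 2
  t_int <- 3:18
  expect_equal(sm2[t_int, 1],
               sapply(t_int, function(t) mean(V[(t - 2):(t + 2), 1])))
})

test_that("tf-idf matches the printed formula", {
  # T = 4; word 'a' present in 2 bins with tf = 2/4 at bin 1
  V <- rbind(c(2, 2), c(1, 0), c(0, 3), c(0, 1))
  colnames(V) <- c("a", "b")
  M <- new("WordCountMatrix", values = V, vocabulary = c("a", "b"),
           stage = "smoothed")
  tf <- valuesMatrix(tfidfTransform(M))
  expect_equal(unname(tf[1, "a"]), 0.5 * log(4 / 3),
               tolerance = 1e-12)
  # absent word -> weight 0
  expect_equal(unname(tf[3, "a"]), 0)
  # ubiquitous word: idf = ln(T/(T+1)) < 0, kept as printed
  V2 <- cbind(a = c(1, 1, 1), b = c(2, 0, 0))
  M2 <- new("WordCountMatrix", values = V2,
            vocabulary = c("a", "b"), stage = "smoothed")
  tf2 <- valuesMatrix(tfidfTransform(M2))
  expect_lt(tf2[2, "a"], 0)
  expect_equal(unname(tf2[2, "a"]), 1 * log(3 / 4), tolerance = 1e-12)

  # agrees with the naive double loop on random matrices
  set.seed(11)
  for (i in 1:5) {
    V3 <- matrix(rpois(200, 1), 20, 10)
    V3[1, ] <- pmax(V3[1, ], 1)  # keep at least one nonzero row
    M3 <- new("WordCountMatrix", values = V3,
              vocabulary = sprintf("w%02d", 1:10), stage = "smoothed")
    expect_equal(unname(valuesMatrix(tfidfTransform(M3))),
                 unname(oracleTfidf(V3)), tolerance = 1e-12)
  }
})

test_that("NMF-LSA factors exactly factorable matrices and stays feasible", {
  M <- new("WordCountMatrix", values = diag(2),
           vocabulary = c("a", "b"), stage = "smoothed")
  ctx <- fitNmfLsa(M, s = 2, seed = 1, max_iter = 5000, tol = 0)
  expect_lte(ctx@reconstruction_error, 1e-6)
  expect_gte(min(contextExpressions(ctx)), 0)
  expect_gte(min(wordWeights(ctx)), 0)

  # planted nonnegative rank-3 factorization
  set.seed(3)
  W0 <- matrix(runif(20 * 3), 20, 3)
  H0 <- matrix(runif(3 * 10), 3, 10)
  X <- W0 %*% H0
  Mx <- new("WordCountMatrix", values = X,
            vocabulary = sprintf("w%02d", 1:10), stage = "smoothed")
  ctx3 <- fitNmfLsa(Mx, s = 3, seed = 2, max_iter = 5000, tol = 1e-12)
  rel <- ctx3@reconstruction_error / sqrt(sum(X^2))
  expect_lte(rel, 1e-3)
  # the factorization reproduces the product
  expect_equal(contextExpressions(ctx3) %*% wordWeights(ctx3), X,
               tolerance = 1e-2, ignore_attr = TRUE)

  # objective is monotone nonincreasing
  expect_true(all(diff(ctx3@objective_trace) <= 1e-10))
  # H rows are unit norm
  expect_equal(unname(sqrt(rowSums(wordWeights(ctx3)^2))), rep(1, 3))
  # dimension guard
  expect_error(fitNmfLsa(Mx, s = 15, seed = 1), "exceeds")
})

test_that("topWords ranks by H weight with lexicographic ties", {
  H <- rbind(c(0.1, 0.9, 0.3), c(0.5, 0.5, 0.1))
  ctx <- new("SemanticContexts", W = matrix(1, 2, 2), H = H,
             vocabulary = c("apple", "pear", "quince"),
             reconstruction_error = 0, objective_trace = 0,
             clipped_count = 0, seed = 1L, iterations = 1L,
             converged = TRUE)
  expect_equal(topWords(ctx, 1, 1), "pear")
  expect_equal(topWords(ctx, 2, 2), c("apple", "pear"))  # tie -> lexical
  expect_equal(topWords(ctx, 1, 10),
               c("pear", "quince", "apple"))             # saturation
  # equals a brute-force sort of the row
  set.seed(5)
  h <- runif(12)
  vocab <- sort(sprintf("w%02d", sample(1:99, 12)))
  ctx2 <- new("SemanticContexts", W = matrix(1, 2, 1),
              H = matrix(h, 1), vocabulary = vocab,
              reconstruction_error = 0, objective_trace = 0,
              clipped_count = 0, seed = 1L, iterations = 1L,
              converged = TRUE)
  expect_equal(topWords(ctx2, 1, 5), vocab[order(-h)][1:5])
})

test_that("window grid search returns one row per candidate", {
  set.seed(2)
  V <- matrix(rpois(60 * 6, 2), 60, 6)
  M <- new("WordCountMatrix", values = V,
           vocabulary = sprintf("w%02d", 1:6), stage = "raw")
  zp <- matrix(runif(60 * 2), 60, 2)
  gs <- suppressWarnings(suppressMessages(
    gridSearchWindow(M, c(0.5, 1), zp, s = 3, tr_seconds = 2,
                     seed = 1, max_iter = 50)))
  expect_equal(nrow(gs$table), 2L)
  expect_true(gs$selected %in% c(0.5, 1))
  # singleton candidate is returned as selected
  gs1 <- suppressWarnings(suppressMessages(
    gridSearchWindow(M, 1, zp, s = 3, tr_seconds = 2, seed = 1,
                     max_iter = 50)))
  expect_equal(gs1$selected, 1)
  expect_error(gridSearchWindow(M, numeric(0), zp, s = 3), "nonempty")
})

test_that("a sparse low-SNR stream is best read at its planted 4-minute scale", {
  # slow states (mean dwell 100 s), instantaneous topic coupling, very
  # sparse speech: the smoothing window matching the planted semantic
  # timescale maximizes the mean link metric over {1, 4, 16} minutes
  set.seed(1)
  T <- 3543; n <- 4
  Theta <- matrix(0.02 / 3, n, n); diag(Theta) <- 0.98
  z <- integer(T); z[1] <- 1
  for (t in 2:T) z[t] <- sample.int(n, 1, prob = Theta[z[t - 1], ])
  n_topics <- 8; wpt <- 12; V <- n_topics * wpt + 40
  vocab <- sprintf("word%03d", 1:V)
  tw <- matrix(0, n_topics, V)
  for (j in 1:n_topics) tw[j, (j - 1) * wpt + 1:wpt] <- 1 / wpt
  bg <- numeric(V); bg[n_topics * wpt + 1:40] <- 1 / 40
  toks <- vector("list", T)
  for (t in 1:T) {
    nt <- rpois(1, 0.5) * (runif(1) >= 0.3)
    if (nt == 0) { toks[[t]] <- character(); next }
    w <- 0.05 + 0.3 * as.numeric(z[t] == ((1:n_topics - 1) %% 4) + 1)
    src <- sample.int(n_topics + 1, nt, replace = TRUE, prob = c(w, 1.5))
    toks[[t]] <- vapply(src, function(s)
      vocab[sample.int(V, 1, prob = if (s <= n_topics) tw[s, ] else bg)],
      character(1))
  }
  tl <- new("TokenTimeline", tokens = toks, tr_seconds = 2)
  M <- buildWordCountMatrix(preprocessTokens(tl))
  zp <- sapply(1:4, function(k) as.numeric(z == k))
  gs <- suppressMessages(gridSearchWindow(M, c(1, 4, 16), zp, s = 16,
                                          tr_seconds = 2, seed = 3,
                                          max_iter = 300))
  expect_equal(gs$selected, 4)
})
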