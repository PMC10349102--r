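## Timed-text -> semantic-context pipeline: SRT parsing, token cleanup,
## bag-of-words binning, sliding-window smoothing, tf-idf, and
## nonnegativity-constrained latent semantic analysis (NMF-LSA).

.tokenizeLine <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", " ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

.parseSrtTimestamp <- function(x, cue_index) {
  m <- regmatches(x, regexec(
    "^\\s*(\\d+):(\\d{2}):(\\d{2})[,.](\\d{1,3})\\s*$", x))[[1]]
  if (length(m) != 5)
    stop(sprintf("malformed timestamp '%s' in cue %d", x, cue_index))
  as.numeric(m[2]) * 3600 + as.numeric(m[3]) * 60 + as.numeric(m[4]) +
    as.numeric(m[5]) / 1000
}

#' Parse SubRip timed text onto the TR grid
#'
#' Reads SubRip (.srt) cue text and assigns each cue's tokens to every
#' repetition-time bin its time span overlaps, where bin `t` covers the
#' half-open interval `[t*TR, (t+1)*TR)` seconds. Tokens are lowercased
#' and stripped of punctuation. Cues starting at or beyond the end of the
#' timeline are dropped with a warning.
#'
#' @param srt_text a single string or character vector of SubRip lines.
#' @param tr_seconds bin width in seconds (the fMRI TR).
#' @param n_timepoints number of bins on the timeline.
#' @return a [TokenTimeline-class].
#' @export
parseTimedText <- function(srt_text, tr_seconds, n_timepoints) {
  stopifnot(tr_seconds > 0, n_timepoints >= 0)
  lines <- if (length(srt_text) == 1L)
    strsplit(srt_text, "\r?\n")[[1]] else as.character(srt_text)
  tokens <- rep(list(character()), n_timepoints)
  i <- 1L
  cue <- 0L
  dropped <- 0L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    cue <- cue + 1L
    # optional numeric index line
    if (grepl("^\\s*\\d+\\s*$", lines[i])) i <- i + 1L
    if (i > n || !grepl("-->", lines[i]))
      stop(sprintf("missing timing line in cue %d", cue))
    parts <- strsplit(lines[i], "-->")[[1]]
    if (length(parts) != 2)
      stop(sprintf("malformed timing line in cue %d", cue))
    t0 <- .parseSrtTimestamp(parts[1], cue)
    t1 <- .parseSrtTimestamp(parts[2], cue)
    i <- i + 1L
    text <- character()
    while (i <= n && nzchar(trimws(lines[i]))) {
      text <- c(text, lines[i])
      i <- i + 1L
    }
    toks <- .tokenizeLine(paste(text, collapse = " "))
    if (!length(toks)) next
    if (t0 >= n_timepoints * tr_seconds) {
      dropped <- dropped + 1L
      next
    }
    b0 <- floor(t0 / tr_seconds)
    b1 <- min(ceiling(t1 / tr_seconds) - 1, n_timepoints - 1)
    if (t1 <= t0) b1 <- b0
    for (b in seq(b0, max(b0, b1)))
      tokens[[b + 1L]] <- c(tokens[[b + 1L]], toks)
  }
  if (dropped > 0)
    warning(sprintf("%d cue(s) past the last timepoint were dropped",
                    dropped))
  new("TokenTimeline", tokens = tokens, tr_seconds = tr_seconds)
}

#' Clean a token timeline
#'
#' Case-folds, strips punctuation and removes stop words. Idempotent.
#'
#' @param timeline a [TokenTimeline-class] (or plain list of character
#'   vectors).
#' @param stopwords character vector of stop words (compared after case
#'   folding).
#' @param tr_seconds TR used when a plain list is given.
#' @return a [TokenTimeline-class].
#' @export
preprocessTokens <- function(timeline, stopwords = character(),
                             tr_seconds = 2) {
  toks <- if (is(timeline, "TokenTimeline")) timeline@tokens else timeline
  tr <- if (is(timeline, "TokenTimeline")) timeline@tr_seconds else
    tr_seconds
  stopwords <- tolower(stopwords)
  cleaned <- lapply(toks, function(x) {
    x <- unlist(lapply(x, .tokenizeLine), use.names = FALSE)
    if (is.null(x)) x <- character()
    x[!(x %in% stopwords)]
  })
  new("TokenTimeline", tokens = cleaned, tr_seconds = tr)
}

#' Build the raw word count matrix
#'
#' Bag-of-words counts per timepoint: `values[t, w]` is the number of
#' occurrences of word `w` in bin `t`. The vocabulary is the sorted set of
#' all observed words.
#'
#' @param timeline a preprocessed [TokenTimeline-class].
#' @return a [WordCountMatrix-class] with stage `"raw"`.
#' @export
buildWordCountMatrix <- function(timeline) {
  toks <- timeline@tokens
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  T <- length(toks)
  M <- matrix(0, nrow = T, ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (t in seq_len(T)) {
    if (!length(toks[[t]])) next
    tab <- table(toks[[t]])
    M[t, names(tab)] <- as.numeric(tab)
  }
  new("WordCountMatrix", values = M, vocabulary = vocab, stage = "raw")
}

#' Smooth counts with a centered sliding window
#'
#' Replaces each row by the mean of the rows within half a window on each
#' side, truncated at the timeline edges (the mean is taken over the rows
#' actually available). A window shorter than one TR leaves the matrix
#' unchanged.
#'
#' @param M a [WordCountMatrix-class] (stage `"raw"`).
#' @param window_minutes full window length in minutes (e.g. 4 means 2 min
#'   before and 2 min after the center bin).
#' @param tr_seconds bin width in seconds.
#' @return a [WordCountMatrix-class] with stage `"smoothed"`.
#' @export
smoothCounts <- function(M, window_minutes, tr_seconds) {
  stopifnot(is(M, "WordCountMatrix"), window_minutes >= 0, tr_seconds > 0)
  hw <- floor(window_minutes * 60 / 2 / tr_seconds)
  V <- M@values
  T <- nrow(V)
  if (hw >= 1 && T > 1) {
    cs <- rbind(0, apply(V, 2, cumsum))
    lo <- pmax(seq_len(T) - hw, 1L)
    hi <- pmin(seq_len(T) + hw, T)
    V <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
    dimnames(V) <- dimnames(M@values)
  }
  new("WordCountMatrix", values = V, vocabulary = M@vocabulary,
      stage = "smoothed")
}

#' tf-idf weighting of a (smoothed) word count matrix
#'
#' Transforms counts `f[w, t]` into
#' `tf * idf = (f[w, t] / sum_w' f[w', t]) * ln(T / (1 + n_w))`, where
#' `n_w` is the number of timepoints whose count for word `w` is positive
#' and `T` the number of timepoints. Timepoints with no tokens map to zero
#' rows. Words present at (almost) every timepoint get a negative idf and
#' hence negative weights; these are kept as-is at this stage.
#'
#' @param M a [WordCountMatrix-class], typically stage `"smoothed"`.
#' @return a [WordCountMatrix-class] with stage `"tfidf"`.
#' @export
tfidfTransform <- function(M) {
  stopifnot(is(M, "WordCountMatrix"))
  V <- M@values
  T <- nrow(V)
  if (T == 0 || max(V) == 0) stop("matrix must have at least one nonzero row")
  row_tot <- rowSums(V)
  tf <- V / ifelse(row_tot > 0, row_tot, 1)
  tf[row_tot == 0, ] <- 0
  n_w <- colSums(V > 0)
  idf <- log(T / (1 + n_w))
  out <- sweep(tf, 2, idf, `*`)
  new("WordCountMatrix", values = out, vocabulary = M@vocabulary,
      stage = "tfidf")
}

#' Nonnegativity-constrained latent semantic analysis (NMF-LSA)
#'
#' Factors a nonnegative word-weight matrix as `M ~ W H` with
#' `W >= 0, H >= 0` by multiplicative updates minimizing the squared
#' Frobenius reconstruction error. Negative entries of tf-idf input are
#' clipped to zero (count reported in the result). The objective is
#' nonincreasing across iterations. Rows of `H` are scaled to unit
#' Euclidean norm (the scale moves into `W`) and contexts are ordered by
#' total expression for stable reporting.
#'
#' @param M a [WordCountMatrix-class].
#' @param s number of semantic contexts (`s <= min(T, V)`).
#' @param seed integer seed for the random uniform initialization.
#' @param max_iter iteration cap (default 500).
#' @param tol relative objective-change convergence tolerance.
#' @return a [SemanticContexts-class].
#' @export
fitNmfLsa <- function(M, s, seed = 1L, max_iter = 500L, tol = 1e-6) {
  X <- if (is(M, "WordCountMatrix")) M@values else as.matrix(M)
  vocab <- if (is(M, "WordCountMatrix")) M@vocabulary else
    (colnames(X) %||% sprintf("w%04d", seq_len(ncol(X))))
  T <- nrow(X); V <- ncol(X)
  if (s > min(T, V))
    stop(sprintf("s = %d exceeds min(T, V) = %d", s, min(T, V)))
  clipped <- sum(X < 0)
  if (clipped > 0) {
    message(sprintf("clipping %d negative entries to 0 before NMF",
                    clipped))
    X[X < 0] <- 0
  }
  eps <- 1e-12
  scale0 <- sqrt(max(mean(X), eps) / s)
  res <- .withSeed(as.integer(seed), {
    W <- matrix(runif(T * s), T, s) * scale0
    H <- matrix(runif(s * V), s, V) * scale0
    obj <- numeric(0)
    prev <- Inf
    it <- 0L
    converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
      W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
      err2 <- sum((X - W %*% H)^2) / 2
      obj <- c(obj, err2)
      if (is.finite(prev) && prev > 0 &&
          abs(prev - err2) / max(prev, eps) < tol) {
        converged <- TRUE
        break
      }
      prev <- err2
    }
    list(W = W, H = H, obj = obj, it = it, converged = converged)
  })
  W <- res$W; H <- res$H
  hn <- sqrt(rowSums(H^2))
  hn[hn == 0] <- 1
  H <- H / hn
  W <- sweep(W, 2, hn, `*`)
  ord <- order(colSums(W), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  colnames(W) <- rownames(H) <- sprintf("context%03d", seq_len(s))
  colnames(H) <- vocab
  new("SemanticContexts", W = W, H = H, vocabulary = vocab,
      reconstruction_error = sqrt(2 * res$obj[length(res$obj)]),
      objective_trace = res$obj, clipped_count = as.numeric(clipped),
      seed = as.integer(seed), iterations = res$it,
      converged = res$converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top-weighted words of a semantic context
#'
#' @param contexts a [SemanticContexts-class].
#' @param context_index 1-based context index.
#' @param k number of words to return (all words if `k >= V`).
#' @return character vector of words, by descending H weight; ties broken
#'   lexicographically.
#' @export
topWords <- function(contexts, context_index, k = 10L) {
  stopifnot(context_index >= 1, context_index <= nrow(contexts@H))
  h <- contexts@H[context_index, ]
  ord <- order(-h, contexts@vocabulary)
  contexts@vocabulary[ord][seq_len(min(k, length(h)))]
}

#' Grid search over smoothing-window lengths
#'
#' For each candidate window, runs smooth -> tf-idf -> NMF and scores the
#' mean and maximum of the per-state top-k link strengths between the
#' resulting context expressions and a supplied state-presence matrix.
#' Returns the window maximizing the mean metric, plus the full table.
#'
#' @param M_raw a raw-stage [WordCountMatrix-class].
#' @param candidate_windows numeric vector of window lengths in minutes.
#' @param state_presence T x n state-presence matrix to score against.
#' @param s number of contexts for each NMF fit.
#' @param tr_seconds bin width in seconds.
#' @param seed integer seed shared across candidates.
#' @param k top-k used in the link statistic (default 10).
#' @param ... passed to [fitNmfLsa()] (e.g. `max_iter`).
#' @return list with elements `selected` (window, minutes) and `table`
#'   (data.frame: window_minutes, mean_link, max_link).
#' @export
gridSearchWindow <- function(M_raw, candidate_windows, state_presence, s,
                             tr_seconds = 2, seed = 1L, k = 10L, ...) {
  if (!length(candidate_windows)) stop("candidate_windows must be nonempty")
  rows <- lapply(candidate_windows, function(w) {
    sm <- smoothCounts(M_raw, w, tr_seconds)
    tf <- tfidfTransform(sm)
    ctx <- fitNmfLsa(tf, s = s, seed = seed, ...)
    P <- correlationMatrix(state_presence, contextExpressions(ctx))
    top <- topKLinkStrength(P, k = k)
    data.frame(window_minutes = w, mean_link = top$model_index,
               max_link = max(P))
  })
  tab <- do.call(rbind, rows)
  list(selected = tab$window_minutes[which.max(tab$mean_link)],
       table = tab)
}
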