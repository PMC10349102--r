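## Inter-observer-agreement (IOA) annotation series: rasterization of
## observer intervals onto the TR grid, bipolar differencing, episode
## detection and aggregation into the description matrix.

#' Inter-observer agreement time series for one attribute
#'
#' `IOA[t]` is the fraction of observers with at least one interval for
#' the attribute overlapping bin `t` (an interval covers a bin iff it
#' intersects `[t*TR, (t+1)*TR)` with positive measure).
#'
#' @param intervals data.frame with columns observer_id, attribute,
#'   start_s, end_s (optionally character and value).
#' @param attribute attribute name to rasterize.
#' @param n_observers total number of observers (the denominator).
#' @param T number of timepoint bins.
#' @param tr_seconds bin width in seconds.
#' @param character_id optional: restrict to one character's intervals.
#' @param value optional: restrict to one value label (e.g. "high").
#' @return numeric length-T IOA series in \[0, 1\].
#' @export
computeIoa <- function(intervals, attribute, n_observers, T,
                       tr_seconds = 2, character_id = NULL, value = NULL) {
  stopifnot(n_observers >= 1)
  sel <- intervals$attribute == attribute
  if (!is.null(character_id)) sel <- sel & intervals$character == character_id
  if (!is.null(value)) sel <- sel & intervals$value == value
  iv <- intervals[sel, , drop = FALSE]
  total <- T * tr_seconds
  count <- matrix(FALSE, T, n_observers)
  for (i in seq_len(nrow(iv))) {
    s <- iv$start_s[i]; e <- iv$end_s[i]
    if (s < 0 || e > total) {
      warning("interval outside the timeline was clipped")
      s <- max(s, 0); e <- min(e, total)
    }
    if (e <= s) next
    b0 <- floor(s / tr_seconds) + 1
    b1 <- min(ceiling(e / tr_seconds), T)
    count[b0:b1, iv$observer_id[i]] <- TRUE
  }
  rowSums(count) / n_observers
}

#' Bipolar IOA series from two opposing poles
#'
#' The study's bipolar indicators (arousal, valence, direction) subtract
#' the IOA of the negative pole from that of the positive pole, giving a
#' series in \[-1, 1\] whose extremes mark perfect agreement on one pole.
#'
#' @param pos,neg equal-length IOA series.
#' @return numeric series `pos - neg`.
#' @export
bipolarIoa <- function(pos, neg) {
  if (length(pos) != length(neg))
    stop("pos and neg series must have equal length")
  pos - neg
}

#' Detect episodes by thresholding IOA series
#'
#' Maximal runs of timepoints where any attribute's absolute IOA meets
#' the threshold. Per episode, the median IOA of each supplied series
#' across the episode's span is recorded.
#'
#' @param ioa_set named list of equal-length IOA series (typically one
#'   character's attributes).
#' @param threshold absolute IOA threshold in (0, 1\]; the boundary value
#'   counts (>= rule), so an even observer split at 0.5 is included.
#' @return data.frame with columns start, end (1-based inclusive
#'   timepoints) and one `median_<name>` column per series.
#' @export
detectEpisodes <- function(ioa_set, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  mat <- do.call(cbind, ioa_set)
  active <- apply(abs(mat) >= threshold, 1, any)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start = integer(0), end = integer(0)))
  out <- data.frame(start = starts[keep], end = ends[keep])
  for (nm in names(ioa_set)) {
    out[[paste0("median_", nm)]] <- vapply(seq_len(nrow(out)), function(i)
      median(ioa_set[[nm]][out$start[i]:out$end[i]]), numeric(1))
  }
  out
}

#' Aggregate episodes and IOA series into the description matrix
#'
#' Continuous attributes (arousal/valence-style, `kind = "unipolar"` or
#' `"bipolar"`) take, at each timepoint, the maximum episode-median value
#' across all episodes (of any character) covering that timepoint.
#' All other attributes become binary presence series: 1 inside any
#' episode expressing them. Pass-through binary series (locations, time
#' of day) are copied as-is.
#'
#' @param episodes named list (per character) of episode data.frames from
#'   [detectEpisodes()], whose `median_<attr>` columns feed the
#'   continuous attributes.
#' @param attributes data.frame with columns name, category, kind.
#' @param T number of timepoints.
#' @param binary_series optional named list of length-T 0/1 series copied
#'   straight into the matrix (e.g. location annotations).
#' @return an [AnnotationMatrix-class].
#' @export
aggregateAnnotationSeries <- function(episodes, attributes, T,
                                      binary_series = list()) {
  A <- nrow(attributes)
  vals <- matrix(0, T, A, dimnames = list(NULL, attributes$name))
  for (j in seq_len(A)) {
    nm <- attributes$name[j]
    kind <- attributes$kind[j]
    if (nm %in% names(binary_series)) {
      vals[, j] <- binary_series[[nm]]
      next
    }
    col <- paste0("median_", nm)
    for (ep in episodes) {
      if (!nrow(ep)) next
      for (i in seq_len(nrow(ep))) {
        span <- ep$start[i]:ep$end[i]
        if (kind %in% c("unipolar", "bipolar") && col %in% names(ep)) {
          v <- ep[[col]][i]
          upd <- if (kind == "bipolar") abs(vals[span, j]) < abs(v)
                 else vals[span, j] < v
          vals[span, j][upd] <- v
        } else if (col %in% names(ep)) {
          vals[span, j][abs(ep[[col]][i]) > 0] <- 1
        }
      }
    }
    if (!(kind %in% c("unipolar", "bipolar"))) vals[, j] <-
        as.numeric(vals[, j] > 0)
  }
  new("AnnotationMatrix", values = vals, attributes = attributes$name,
      category = attributes$category, kind = attributes$kind)
}
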