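## Dwell-time and volatility statistics of hard-assigned state sequences.

#' Dwell-time spells of a state sequence
#'
#' Maximal runs of consecutive timepoints in the same state, converted to
#' seconds, attributed to their state in temporal order.
#'
#' @param state_seq integer vector of hard state assignments (1-based).
#' @param tr_seconds bin width in seconds.
#' @param n_states number of states (defaults to the largest observed).
#' @return list of numeric vectors of spell durations (seconds), one per
#'   state.
#' @export
dwellTimes <- function(state_seq, tr_seconds = 2, n_states = max(state_seq)) {
  if (!length(state_seq)) stop("state sequence must be nonempty")
  r <- rle(as.integer(state_seq))
  out <- rep(list(numeric(0)), n_states)
  for (k in seq_len(n_states))
    out[[k]] <- r$lengths[r$values == k] * tr_seconds
  names(out) <- sprintf("state%d", seq_len(n_states))
  out
}

#' Pooled dwell-time summary
#'
#' Mean and sample (n-1) standard deviation of all spells pooled across
#' states, matching the study's single mu/sigma per model.
#'
#' @param spells a per-state spell list from [dwellTimes()].
#' @return list with `mean` and `sd` (sd is 0 for a single spell).
#' @export
dwellSummary <- function(spells) {
  pooled <- unlist(spells, use.names = FALSE)
  if (!length(pooled)) stop("at least one spell is required")
  list(mean = mean(pooled), sd = if (length(pooled) > 1) sd(pooled) else 0)
}

#' Local volatility of dwell times across movie segments
#'
#' Computes dwell spells within each segment independently (runs are
#' truncated at segment edges, not bridged) and returns the sample
#' standard deviation of the per-segment mean dwell times.
#'
#' @param state_seq integer state sequence.
#' @param segment_bounds integer matrix (segments x 2) of half-open
#'   `[start, end)` timepoint intervals (0-based, as produced by the
#'   synthetic generator).
#' @param tr_seconds bin width in seconds.
#' @return list with `volatility` (sd of segment means) and
#'   `segment_means`.
#' @export
localVolatility <- function(state_seq, segment_bounds, tr_seconds = 2) {
  segment_bounds <- as.matrix(segment_bounds)
  if (nrow(segment_bounds) < 2)
    stop("at least 2 segments are required")
  seg_means <- apply(segment_bounds, 1, function(b) {
    seg <- state_seq[(b[1] + 1):b[2]]
    dwellSummary(dwellTimes(seg, tr_seconds))$mean
  })
  list(volatility = sd(seg_means), segment_means = seg_means)
}

#' Group-level dwell table across subjects and combinations
#'
#' One row per (subject, combination): pooled mean and sd of dwell times
#' and the local volatility across segments, recomputed from each
#' solution's posterior state presence.
#'
#' @param solutions nested list: `solutions[[subject]][[combination]]` of
#'   [HMMSolution-class] objects (combination names taken from the inner
#'   list names).
#' @param segment_bounds segment intervals for the volatility (optional).
#' @param tr_seconds bin width in seconds.
#' @return long-format data.frame (subject, combination, mean_dwell,
#'   sd_dwell, volatility).
#' @export
groupDwellTable <- function(solutions, segment_bounds = NULL,
                            tr_seconds = 2) {
  rows <- list()
  for (i in seq_along(solutions)) {
    for (nm in names(solutions[[i]])) {
      sol <- solutions[[i]][[nm]]
      seq_i <- hardAssign(statePresence(sol))
      ds <- dwellSummary(dwellTimes(seq_i, tr_seconds, nStates(sol)))
      vol <- if (!is.null(segment_bounds))
        localVolatility(seq_i, segment_bounds, tr_seconds)$volatility
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, combination = nm, mean_dwell = ds$mean,
        sd_dwell = ds$sd, volatility = vol)
    }
  }
  do.call(rbind, rows)
}
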