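# Sliding-window scoring: windows of query size step across the target at
# 25% of the window size; motifs overlapping a window's boundaries are
# attached to it ("virtual extension"); Score_PURE is the sum of scores of
# the query-filtered, above-noise motifs in the window.

#' Enumerate scan windows over a target sequence
#'
#' Windows have size `min(query_len, target_len)` and advance by
#' `max(1, round(size * window_step_fraction))`.  If the last regular window
#' does not reach the end of the target, a final flush-right window is
#' appended so the whole target is covered.
#'
#' @param target_len,query_len Sequence lengths in nt.
#' @param params A [scan_params].
#' @return Data frame with 0-based half-open columns `start`, `end`.
#' @export
iter_windows <- function(target_len, query_len, params = scan_params()) {
  stopifnot(target_len >= 1, query_len >= 1)
  size <- min(query_len, target_len)
  step <- max(1L, as.integer(round(size * params$window_step_fraction)))
  starts <- seq.int(0L, target_len - size, by = step)
  if (starts[length(starts)] + size < target_len) {
    starts <- c(starts, target_len - size)
  }
  data.frame(start = starts, end = starts + size)
}

#' Select the motifs attached to a window
#'
#' All motifs whose target interval intersects the window, including partial
#' boundary overlaps, unmodified.
#'
#' @param profile `motif_profile` (target-filtered) or motif data frame.
#' @param window A [ginterval] or list with `start`, `end`.
#' @return Motif data frame subset.
#' @export
select_window_motifs <- function(profile, window) {
  motifs <- if (inherits(profile, "motif_profile")) profile$motifs else profile
  motifs[motifs$t_start < window$end & motifs$t_end > window$start, ,
         drop = FALSE]
}

#' Basic window similarity score (Score_PURE)
#'
#' The window's motif selection is filtered for overlaps on the query axis,
#' motifs scoring below the noise threshold are discarded, and the surviving
#' scores are summed.
#'
#' @param motifs The window's motif selection ([select_window_motifs()]).
#' @param window The window interval (unused by the score itself; kept for
#'   interface symmetry).
#' @param params A [scan_params].
#' @param query_len Query length (needed for the query-axis overlap filter).
#' @return List with `score` (Score_PURE), `valid` (the surviving motifs,
#'   M_Valid) and `filtered` (the query-filtered selection before the noise
#'   cut, which pattern detection consumes).
#' @export
score_pure <- function(motifs, window, params = scan_params(),
                       query_len = NULL) {
  if (is.null(query_len)) {
    query_len <- if (nrow(motifs) > 0L) max(motifs$q_end) else 1L
  }
  filtered <- filter_overlaps(motifs, axis = "query", params = params,
                              axis_len = query_len)
  valid <- filtered[filtered$score >= noise_threshold(params), ,
                    drop = FALSE]
  list(score = sum(valid$score), valid = valid, filtered = filtered)
}
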