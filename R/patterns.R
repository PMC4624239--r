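# Co-linear pattern detection.  Motifs conserved from a common ancestral
# enhancer tend to keep their relative order and spacing even when the
# spacer sequence between them has turned over completely.  Within a window
# such motifs share a similar diagonal (query-target shift).  Starting at
# the strongest motif, two elliptical motif spaces are laid along its
# diagonal (the motif in the shared focus, foci separated by the window
# length, semi-minor axis = max_shift); all motifs whose centre falls inside
# either ellipse and that chain with inter-motif gaps <= max_distance form a
# pattern.  Patterns need >= 3 members of which >= 2 score at or above the
# noise threshold; sub-threshold motifs may be rescued as members.  Each
# member is weighted by how tight the pattern is (mean gap) and how close
# the member sits to the pattern's weighted midline (shift deviation); the
# weighted score sum is added to Score_PURE to give Score_COMB.

#' Query-target shift of a motif within a window
#'
#' The signed diagonal offset: (target centre - window start) - query
#' centre, using interval midpoints.  Motifs from a conserved co-linear
#' arrangement share similar shifts.
#'
#' @param m One-row motif data frame.
#' @param window Window interval (list with `start`).
#' @return Signed shift in nt.
#' @export
motif_shift <- function(m, window) {
  ((m$t_start + m$t_end) / 2 - window$start) - (m$q_start + m$q_end) / 2
}

#' Elliptical motif-space membership test
#'
#' Two ellipses are anchored on the motif's diagonal, overlapping in the
#' focus where the anchor sits; the second focus of each lies one window
#' length downstream/upstream along the diagonal.  In (query-centre, shift)
#' coordinates the diagonal is the horizontal line through the anchor's
#' shift, the semi-minor axis is `max_shift`, and the semi-major axis is
#' `sqrt((window_len/2)^2 + max_shift^2)` so the focus distance is exactly
#' the window length.
#'
#' @param anchor,candidate One-row motif data frames.
#' @param window_len Window length in nt.
#' @param window Window interval (for shift computation).
#' @param params A [scan_params].
#' @return Logical.
#' @export
in_motif_space <- function(anchor, candidate, window_len, window,
                           params = scan_params()) {
  a_q <- (anchor$q_start + anchor$q_end) / 2
  a_s <- motif_shift(anchor, window)
  c_q <- (candidate$q_start + candidate$q_end) / 2
  c_s <- motif_shift(candidate, window)
  in_ellipses(c_q - a_q, c_s - a_s, window_len, params$max_shift)
}

# membership in either of the two ellipses, relative to the anchor focus at
# the origin; dx along the diagonal, dy perpendicular (shift deviation)
in_ellipses <- function(dx, dy, window_len, max_shift) {
  b <- max_shift
  a <- sqrt((window_len / 2)^2 + b^2)
  inside <- function(cx) ((dx - cx) / a)^2 + (dy / b)^2 <= 1
  inside(window_len / 2) | inside(-window_len / 2)
}

#' Assemble co-linear motif patterns in a window
#'
#' Input is the window's query-filtered selection before the noise cut
#' (sub-threshold motifs may join patterns).  Only forward-orientation
#' motifs participate.  Anchors are above-threshold motifs taken in rank
#' order; each anchor collects the unassigned motifs inside its elliptical
#' motif spaces, orders them by query start and keeps the maximal chain
#' containing the anchor in which consecutive end-to-start gaps on both
#' query and target are `<= max_distance`.  Chains with >= 3 members, >= 2
#' of them at or above the noise threshold, become patterns; motifs in a
#' pattern are removed from the pool, members of dissolved chains return to
#' it.
#'
#' @param motifs Motif data frame (window selection, query-filtered).
#' @param window Window interval (list with `start`, `end`).
#' @param params A [scan_params].
#' @return List of patterns; each is a list with `members` (motif data frame
#'   ordered by query start), `mean_distance`, `pattern_shift`, `weights`,
#'   `pattern_score`.
#' @export
assemble_patterns <- function(motifs, window, params = scan_params()) {
  thr <- noise_threshold(params)
  window_len <- window$end - window$start
  fwd <- motifs[motifs$orientation == "+", , drop = FALSE]
  n <- nrow(fwd)
  if (n < 3L) return(list())
  qc <- (fwd$q_start + fwd$q_end) / 2
  sh <- ((fwd$t_start + fwd$t_end) / 2 - window$start) - qc

  assigned <- rep(FALSE, n)
  patterns <- list()
  anchor_order <- motif_rank_order(fwd, fwd$q_start)
  for (ai in anchor_order) {
    if (assigned[ai] || fwd$score[ai] < thr) next
    member <- !assigned &
      in_ellipses(qc - qc[ai], sh - sh[ai], window_len, params$max_shift)
    idx <- which(member)
    if (length(idx) < 3L) next
    idx <- idx[order(fwd$q_start[idx], fwd$t_start[idx])]
    # split into maximal chains where consecutive gaps hold on both axes
    gq <- fwd$q_start[idx][-1L] - fwd$q_end[idx][-length(idx)]
    gt <- fwd$t_start[idx][-1L] - fwd$t_end[idx][-length(idx)]
    brk <- gq > params$max_distance | gt > params$max_distance
    chain_id <- cumsum(c(0L, as.integer(brk)))
    keep <- idx[chain_id == chain_id[which(idx == ai)]]
    if (length(keep) < 3L || sum(fwd$score[keep] >= thr) < 2L) next
    members <- fwd[keep, , drop = FALSE]
    pat <- pattern_metrics(list(members = members, shifts = sh[keep]),
                           params)
    pat <- pattern_weights(pat, params)
    pat$pattern_score <- sum(pat$members$score * pat$weights)
    patterns[[length(patterns) + 1L]] <- pat
    assigned[keep] <- TRUE
  }
  patterns
}

#' Pattern geometry: mean inter-motif distance and pattern shift
#'
#' Members ordered by query start; the mean distance is the average
#' end-to-start gap between consecutive members on the target axis, the
#' pattern shift is the length-weighted mean of the member shifts (the
#' pattern's weighted midline).
#'
#' @param p Pattern (list with `members` and per-member `shifts`).
#' @param params A [scan_params].
#' @return The pattern with `mean_distance` and `pattern_shift` filled in.
#' @export
pattern_metrics <- function(p, params = scan_params()) {
  m <- p$members
  n <- nrow(m)
  if (n < 2L) stop("pattern_metrics requires >= 2 members")
  p$mean_distance <- sum(m$t_start[-1L] - m$t_end[-n]) / (n - 1L)
  p$pattern_shift <- sum(m$length * p$shifts) / sum(m$length)
  p
}

#' Per-member pattern weights
#'
#' `Factor_Distance = 1 - mean_distance / max_distance` (pattern-wide) and
#' `Factor_Shift_i = 1 - |shift_i - pattern_shift| / (2 * max_shift)`
#' (per member); the weight is their mean, clamped to `[0, 1]` so extreme
#' members can never subtract score.
#'
#' @param p Pattern with metrics computed.
#' @param params A [scan_params].
#' @return The pattern with `weights` filled in.
#' @export
pattern_weights <- function(p, params = scan_params()) {
  fd <- 1 - p$mean_distance / params$max_distance
  fs <- 1 - abs(p$shifts - p$pattern_shift) / (2 * params$max_shift)
  p$weights <- pmin(1, pmax(0, (fd + fs) / 2))
  p
}

#' Combined window score (Score_COMB)
#'
#' Score_PURE plus the weighted score sum of every detected pattern.
#'
#' @param score_pure The window's Score_PURE.
#' @param patterns Output of [assemble_patterns()].
#' @param params A [scan_params].
#' @return Numeric Score_COMB.
#' @export
score_comb <- function(score_pure, patterns, params = scan_params()) {
  score_pure + sum(vapply(patterns, function(p) p$pattern_score, numeric(1)))
}

#' Dump patterns as a TSV
#'
#' @param patterns List of patterns (one window's [assemble_patterns()]
#'   output, or concatenated).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_patterns_tsv <- function(patterns, path) {
  rows <- lapply(seq_along(patterns), function(i) {
    p <- patterns[[i]]
    data.frame(pattern = i,
               member = seq_len(nrow(p$members)),
               q_start = p$members$q_start, q_end = p$members$q_end,
               t_start = p$members$t_start, t_end = p$members$t_end,
               score = p$members$score,
               mean_distance = p$mean_distance,
               pattern_shift = p$pattern_shift,
               weight = p$weights,
               pattern_score = p$pattern_score)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(pattern = integer(0), member = integer(0),
               q_start = integer(0), q_end = integer(0),
               t_start = integer(0), t_end = integer(0), score = numeric(0),
               mean_distance = numeric(0), pattern_shift = numeric(0),
               weight = numeric(0), pattern_score = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
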