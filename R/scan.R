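# High-level scan pipeline: raw profile -> target-axis overlap filter ->
# per window: motif selection, query-axis filter, noise cut, Score_PURE,
# pattern detection, Score_COMB -> MAD thresholds -> region calls -> top-N
# ranking.

#' Score every window of one target sequence against a query
#'
#' @param query,target `dna_seq` objects.
#' @param params A [scan_params].
#' @param keep_patterns Keep per-window pattern lists in the result (memory
#'   heavy on large targets).
#' @return List with `windows` (data frame: `start`, `end`, `score_pure`,
#'   `score_comb`, `n_motifs_valid`), `profile` (the target-filtered
#'   `motif_profile`) and, if requested, `patterns` (list per window).
#' @export
scan_target <- function(query, target, params = scan_params(),
                        keep_patterns = FALSE) {
  profile <- build_raw_profile(query, target, params)
  profile <- filter_overlaps(profile, axis = "target", params = params)
  windows <- iter_windows(seq_length(target), seq_length(query), params)
  qlen <- seq_length(query)

  n <- nrow(windows)
  sp <- numeric(n); sc <- numeric(n); nv <- integer(n)
  pats <- if (keep_patterns) vector("list", n) else NULL
  motifs <- profile$motifs
  for (i in seq_len(n)) {
    w <- list(start = windows$start[i], end = windows$end[i])
    sel <- motifs[motifs$t_start < w$end & motifs$t_end > w$start, ,
                  drop = FALSE]
    if (nrow(sel) == 0L) next
    ps <- score_pure(sel, w, params, query_len = qlen)
    sp[i] <- ps$score
    nv[i] <- nrow(ps$valid)
    pw <- assemble_patterns(ps$filtered, w, params)
    sc[i] <- score_comb(ps$score, pw, params)
    if (keep_patterns) pats[[i]] <- pw
  }
  windows$score_pure <- sp
  windows$score_comb <- pmax(sc, sp)
  windows$n_motifs_valid <- nv
  out <- list(windows = windows, profile = profile)
  if (keep_patterns) out$patterns <- pats
  out
}

#' Scan a query enhancer against a multi-record target
#'
#' Each target record is scanned independently (no cross-record windows);
#' the region-calling threshold for each score type pools the window scores
#' of all records of the scan, and the returned predictions are the top-N
#' per score type across records.
#'
#' @param query A `dna_seq`.
#' @param targets List of `dna_seq` (e.g. from [read_fasta()]).
#' @param params A [scan_params].
#' @param score_types Character subset of `c("PURE", "COMB")`.
#' @return List with `regions` (ranked prediction data frame), `windows`
#'   (per-record window score tables), `thresholds` (named numeric).
#' @export
scan_genome <- function(query, targets, params = scan_params(),
                        score_types = c("PURE", "COMB")) {
  if (inherits(targets, "dna_seq")) targets <- list(targets)
  score_types <- match.arg(score_types, c("PURE", "COMB"),
                           several.ok = TRUE)
  scans <- lapply(targets, function(t) scan_target(query, t, params))
  names(scans) <- vapply(targets, function(t) t$id, character(1))

  thresholds <- c(
    PURE = mad_threshold(unlist(lapply(scans, function(s)
      s$windows$score_pure)), params),
    COMB = mad_threshold(unlist(lapply(scans, function(s)
      s$windows$score_comb)), params)
  )
  regions <- list()
  for (st in score_types) {
    per_rec <- lapply(names(scans), function(id) {
      call_regions(scans[[id]]$windows, st, thresholds[[st]],
                   seq_id = id, query_id = query$id)
    })
    regions[[st]] <- rank_predictions(do.call(rbind, per_rec), params)
  }
  list(regions = do.call(rbind, c(regions, list(make.row.names = FALSE))),
       windows = lapply(scans, `[[`, "windows"),
       thresholds = thresholds[score_types])
}
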