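# Region calling: windows scoring above median + 3*MAD of the scan's score
# distribution are merged into maximal runs; runs become predicted regions
# scored by their best window, called separately for PURE and COMB scores
# and ranked top-N per query.

#' Robust region-calling threshold
#'
#' `median(scores) + mad_multiplier * MAD(scores)` where MAD is the raw
#' median absolute deviation (no consistency constant).
#'
#' @param scores Window score vector.
#' @param params A [scan_params].
#' @return Numeric threshold.
#' @export
mad_threshold <- function(scores, params = scan_params()) {
  if (length(scores) == 0L) stop("mad_threshold: empty score vector")
  med <- stats::median(scores)
  med + params$mad_multiplier * stats::median(abs(scores - med))
}

#' Call predicted regions from a window score track
#'
#' Maximal runs of consecutive windows with score strictly above the
#' threshold are merged into one region spanning the first window's start to
#' the last window's end; the region score is the best window score in the
#' run.
#'
#' @param windows Data frame with columns `start`, `end` and the score
#'   column named by `score_type` (`score_pure` / `score_comb`), in genomic
#'   order.
#' @param score_type `"PURE"` or `"COMB"`.
#' @param threshold Calling threshold (see [mad_threshold()]).
#' @param seq_id Target sequence identifier stamped on the regions.
#' @param query_id Query identifier stamped on the regions.
#' @return Data frame of regions: `seq_id`, `start`, `end`, `score_type`,
#'   `region_score`, `peak_start`, `peak_end`, `query_id`.
#' @export
call_regions <- function(windows, score_type = c("PURE", "COMB"), threshold,
                         seq_id = "target", query_id = "query") {
  score_type <- match.arg(score_type)
  col <- if (score_type == "PURE") "score_pure" else "score_comb"
  sc <- windows[[col]]
  above <- sc > threshold
  if (!any(above)) {
    return(data.frame(seq_id = character(0), start = numeric(0),
                      end = numeric(0), score_type = character(0),
                      region_score = numeric(0), peak_start = numeric(0),
                      peak_end = numeric(0), query_id = character(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  rows <- lapply(runs, function(j) {
    i <- starts[j]:ends[j]
    peak <- i[which.max(sc[i])]
    data.frame(seq_id = seq_id, start = min(windows$start[i]),
               end = max(windows$end[i]), score_type = score_type,
               region_score = max(sc[i]), peak_start = windows$start[peak],
               peak_end = windows$end[peak], query_id = query_id)
  })
  do.call(rbind, rows)
}

#' Rank predicted regions and keep the top N
#'
#' Sorted by region score descending; ties broken by longer interval first,
#' then ascending (seq_id, start).  Ranks run 1..min(top_n, count).
#'
#' @param regions Region data frame for one (query, score type).
#' @param params A [scan_params].
#' @return The top `top_n` regions with a `rank` column.
#' @export
rank_predictions <- function(regions, params = scan_params()) {
  if (nrow(regions) == 0L) {
    regions$rank <- integer(0)
    return(regions)
  }
  len <- regions$end - regions$start
  ord <- order(-regions$region_score, -len, regions$seq_id, regions$start)
  out <- regions[ord, , drop = FALSE][seq_len(min(params$top_n,
                                                  nrow(regions))), ,
                                      drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
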