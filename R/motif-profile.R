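# Motif profile construction: exact k-mer seeding between query and target,
# bidirectional mismatch extension with max-score truncation, motif scoring
# (score = (p*s_p + q*s_q) * length), reverse-complement merging, and greedy
# overlap filtering on either axis.
#
# Internally a motif set is a data.frame with one row per motif:
#   q_start, q_end   query interval (0-based half-open)
#   t_start, t_end   target interval, forward-strand coordinates
#   orientation      "+" (forward) or "-" (reverse)
#   p, q, length     match / mismatch counts, p + q = length
#   score            (p*s_p + q*s_q) * length
#   core_len         longest perfect-match run
# plus a list column `match`: logical match vector in query order.

#' Motif score
#'
#' The score of a motif with `p` matching and `q` mismatching nucleotides is
#' `(p*s_p + q*s_q) * (p + q)`: the plain match/mismatch sum amplified by the
#' motif length, so long mismatch-containing motifs outscore short perfect
#' words of equal identity.
#'
#' @param p Matching nucleotide count.
#' @param q Mismatching nucleotide count.
#' @param params A [scan_params].
#' @return Numeric score (vectorised over `p`, `q`).
#' @export
score_motif <- function(p, q, params = scan_params()) {
  stopifnot(all(p >= 0), all(q >= 0), all(p + q >= 1))
  (p * params$s_p + q * params$s_q) * (p + q)
}

#' Noise threshold
#'
#' The score of a perfect word of length `noise_word_len` (default 12).
#' Shorter words are so abundant in genomic windows that they carry no
#' signal; motifs scoring below this threshold are discarded unless rescued
#' by membership in a co-linear pattern.
#'
#' @param params A [scan_params].
#' @return Numeric threshold.
#' @export
noise_threshold <- function(params = scan_params()) {
  score_motif(params$noise_word_len, 0, params)
}

# positions (1-based) at which a k-mer may start: all k residues non-N and
# unmasked
seedable_starts <- function(chars, mask, k) {
  n <- length(chars)
  if (n < k) return(integer(0))
  ok <- as.integer(!mask & chars != "N")
  run <- stats::filter(ok, rep(1L, k), sides = 1)   # run[i] = sum ok[(i-k+1)..i]
  which(run[k:n] == k)                              # start positions 1..n-k+1
}

#' Find perfectly matching seeds between query and target
#'
#' Enumerates every pair of positions whose `k`-length substrings are
#' identical, N-free, and entirely unmasked in both sequences.
#'
#' @param query,target `dna_seq` objects.
#' @param params A [scan_params].
#' @param orientation Orientation label recorded on the seeds (`"+"` or
#'   `"-"`); the caller passes the reverse-complemented target for `"-"`.
#' @return Data frame with 0-based columns `q_start`, `t_start` and columns
#'   `length`, `orientation`, sorted by (`q_start`, `t_start`).
#' @export
find_seeds <- function(query, target, params = scan_params(),
                       orientation = "+") {
  k <- params$k
  empty <- data.frame(q_start = integer(0), t_start = integer(0),
                      length = integer(0), orientation = character(0))
  if (seq_length(query) < k || seq_length(target) < k) return(empty)
  qchars <- strsplit(query$seq, "", fixed = TRUE)[[1]]
  tchars <- strsplit(target$seq, "", fixed = TRUE)[[1]]
  qs <- seedable_starts(qchars, query$mask, k)
  ts <- seedable_starts(tchars, target$mask, k)
  if (length(qs) == 0L || length(ts) == 0L) return(empty)
  qk <- substring(query$seq, qs, qs + k - 1L)
  tk <- substring(target$seq, ts, ts + k - 1L)
  tmap <- split(ts, tk)
  hit <- qk %in% names(tmap)
  if (!any(hit)) return(empty)
  qhit <- qs[hit]
  tlist <- tmap[qk[hit]]
  nper <- lengths(tlist)
  out <- data.frame(
    q_start = rep(qhit, nper) - 1L,
    t_start = unlist(tlist, use.names = FALSE) - 1L,
    length = k,
    orientation = orientation
  )
  out[order(out$q_start, out$t_start), , drop = FALSE]
}

# one-direction extension: step scores for candidate positions, running
# score seeded with the seed score; halt strictly below 0, then truncate to
# the shortest prefix achieving the maximal running score.
# Returns the chosen extension length and its match vector.
extend_direction <- function(qchars, tchars, qpos, tpos, step_dir, seed_score,
                             params) {
  n <- if (step_dir > 0) {
    min(length(qchars) - qpos + 1L, length(tchars) - tpos + 1L)
  } else {
    min(qpos, tpos)
  }
  if (n <= 0L) return(list(len = 0L, match = logical(0)))
  qi <- qpos + step_dir * (seq_len(n) - 1L)
  ti <- tpos + step_dir * (seq_len(n) - 1L)
  m <- qchars[qi] == tchars[ti] & qchars[qi] != "N" & tchars[ti] != "N"
  run <- seed_score + cumsum(ifelse(m, params$s_p, params$s_q))
  below <- which(run < 0)
  if (length(below) > 0L) {
    n <- below[1L] - 1L
    if (n == 0L) return(list(len = 0L, match = logical(0)))
    m <- m[seq_len(n)]
    run <- run[seq_len(n)]
  }
  best <- max(seed_score, max(run))
  len <- if (best <= seed_score) 0L else which(run == best)[1L]
  list(len = len, match = m[seq_len(len)])
}

#' Extend a seed into a motif
#'
#' The seed is extended independently upstream and downstream under the
#' match/mismatch scheme; each direction's running score starts at the seed
#' score and extension halts once it drops below zero.  Each extension is
#' then truncated back to the shortest prefix achieving the maximal running
#' score, and the merged region is rescored with the length-amplified motif
#' score.
#'
#' @param query,target `dna_seq` objects (same frame as the seed).
#' @param seed One row of [find_seeds()] output (or a list with `q_start`,
#'   `t_start`, `length`, `orientation`).
#' @param params A [scan_params].
#' @return One-row motif data frame (see file header for the layout);
#'   coordinates are in the frame of the supplied `target`.
#' @export
extend_seed <- function(query, target, seed, params = scan_params()) {
  qchars <- strsplit(query$seq, "", fixed = TRUE)[[1]]
  tchars <- strsplit(target$seq, "", fixed = TRUE)[[1]]
  extend_seed_chars(qchars, tchars, seed, params)
}

extend_seed_chars <- function(qchars, tchars, seed, params) {
  k <- seed$length
  seed_score <- k * params$s_p
  qs1 <- seed$q_start + 1L       # 1-based seed start
  ts1 <- seed$t_start + 1L
  up <- extend_direction(qchars, tchars, qs1 - 1L, ts1 - 1L, -1L,
                         seed_score, params)
  down <- extend_direction(qchars, tchars, qs1 + k, ts1 + k, +1L,
                           seed_score, params)
  mv <- c(rev(up$match), rep(TRUE, k), down$match)
  p <- sum(mv); q <- length(mv) - p
  new_motif(
    q_start = seed$q_start - up$len, q_end = seed$q_start + k + down$len,
    t_start = seed$t_start - up$len, t_end = seed$t_start + k + down$len,
    orientation = seed$orientation, match = mv, params = params
  )
}

# assemble a one-row motif data frame from a match vector + coordinates
new_motif <- function(q_start, q_end, t_start, t_end, orientation, match,
                      params) {
  p <- sum(match); q <- length(match) - p
  df <- data.frame(q_start = q_start, q_end = q_end,
                   t_start = t_start, t_end = t_end,
                   orientation = orientation,
                   p = p, q = q, length = p + q,
                   score = score_motif(p, q, params),
                   core_len = longest_run(match))
  df$match <- list(match)
  df
}

longest_run <- function(x) {
  if (length(x) == 0L || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

empty_motifs <- function() {
  df <- data.frame(q_start = integer(0), q_end = integer(0),
                   t_start = integer(0), t_end = integer(0),
                   orientation = character(0), p = integer(0), q = integer(0),
                   length = integer(0), score = numeric(0),
                   core_len = integer(0))
  df$match <- list()
  df
}

#' Build the raw motif profile for a query/target pair
#'
#' Seeds are found and extended on the forward target and on its reverse
#' complement; reverse-orientation motifs are mapped back to forward target
#' coordinates.  Exact duplicates (identical intervals and orientation,
#' produced by multiple seeds inside one motif) are collapsed.
#'
#' @param query,target `dna_seq` objects.
#' @param params A [scan_params].
#' @return A `motif_profile`: list with `motifs` (data frame), `query_len`,
#'   `query_id`, `target_id`, `target_len`.
#' @export
build_raw_profile <- function(query, target, params = scan_params()) {
  tlen <- seq_length(target)
  qchars <- strsplit(query$seq, "", fixed = TRUE)[[1]]

  extend_all <- function(tgt, orientation) {
    seeds <- find_seeds(query, tgt, params, orientation)
    if (nrow(seeds) == 0L) return(empty_motifs())
    tchars <- strsplit(tgt$seq, "", fixed = TRUE)[[1]]
    rows <- lapply(seq_len(nrow(seeds)), function(i) {
      extend_seed_chars(qchars, tchars, seeds[i, ], params)
    })
    do.call(rbind, rows)
  }

  fwd <- extend_all(target, "+")
  rev_ <- extend_all(reverse_complement(target), "-")
  if (nrow(rev_) > 0L) {
    # map reverse-complement coordinates back to the forward strand
    ts <- tlen - rev_$t_end
    te <- tlen - rev_$t_start
    rev_$t_start <- ts
    rev_$t_end <- te
  }
  motifs <- rbind(fwd, rev_)
  if (nrow(motifs) > 0L) {
    key <- paste(motifs$q_start, motifs$q_end, motifs$t_start, motifs$t_end,
                 motifs$orientation)
    motifs <- motifs[!duplicated(key), , drop = FALSE]
    motifs <- motifs[order(motifs$t_start, motifs$q_start,
                           motifs$orientation), , drop = FALSE]
    rownames(motifs) <- NULL
  }
  structure(list(motifs = motifs, query_len = seq_length(query),
                 query_id = query$id, target_id = target$id,
                 target_len = tlen),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("motif_profile: %s vs %s, %d motifs\n",
              x$query_id, x$target_id, nrow(x$motifs)))
  invisible(x)
}

# rank order used everywhere ties must break deterministically:
# score desc, length desc, axis coordinate asc, forward before reverse
motif_rank_order <- function(motifs, axis_start) {
  order(-motifs$score, -motifs$length, axis_start,
        motifs$orientation != "+")
}

# map a query-order relative range [a, b] (0-based) onto both axes and
# rebuild the motif row; returns NULL when nothing survives
rebuild_motif <- function(m, a, b, params) {
  mv <- m$match[[1]]
  # trim to the next matching nucleotide inside the kept range
  while (a <= b && !mv[a + 1L]) a <- a + 1L
  while (b >= a && !mv[b + 1L]) b <- b - 1L
  if (a > b) return(NULL)
  sub <- mv[(a + 1L):(b + 1L)]
  if (longest_run(sub) < params$k) return(NULL)
  len <- m$length
  if (m$orientation == "+") {
    t_start <- m$t_start + a; t_end <- m$t_start + b + 1L
  } else {
    t_start <- m$t_end - b - 1L; t_end <- m$t_end - a
  }
  new_motif(m$q_start + a, m$q_start + b + 1L, t_start, t_end,
            m$orientation, sub, params)
}

#' Filter a motif set for overlaps on one axis
#'
#' Motifs are ranked (score descending; ties: longer first, smaller axis
#' coordinate, forward before reverse) and placed greedily.  A lower-ranked
#' motif overlapping an already-placed motif of unequal score keeps its
#' longest conflict-free stretch, trimmed inward to the next matching
#' nucleotide, and is rescored; motifs whose remaining perfect-match core is
#' shorter than the seed size are discarded.  Motifs whose score equals the
#' overlapped motif's score are kept unmodified (equal-score overlaps are
#' allowed).
#'
#' @param profile A `motif_profile` (or plain motif data frame).
#' @param axis `"target"` or `"query"`: the axis on which overlaps are
#'   resolved.
#' @param params A [scan_params].
#' @param axis_len Length of the axis sequence; inferred from the profile
#'   when omitted.
#' @return Same type as `profile`, with the filtered motif set.
#' @export
filter_overlaps <- function(profile, axis = c("target", "query"),
                            params = scan_params(), axis_len = NULL) {
  axis <- match.arg(axis)
  is_prof <- inherits(profile, "motif_profile")
  motifs <- if (is_prof) profile$motifs else profile
  if (nrow(motifs) <= 1L) return(profile)
  if (is.null(axis_len)) {
    axis_len <- if (is_prof) {
      if (axis == "target") profile$target_len else profile$query_len
    } else {
      max(if (axis == "target") motifs$t_end else motifs$q_end)
    }
  }
  starts <- if (axis == "target") motifs$t_start else motifs$q_start
  ord <- motif_rank_order(motifs, starts)

  occ <- rep(NA_real_, axis_len)   # score of the motif occupying each base
  kept <- list()
  for (i in ord) {
    m <- motifs[i, , drop = FALSE]
    repeat {
      s <- if (axis == "target") m$t_start else m$q_start
      e <- if (axis == "target") m$t_end else m$q_end
      pos <- (s + 1L):e
      conflict <- !is.na(occ[pos]) & occ[pos] != m$score
      if (!any(conflict)) {
        occ[pos][is.na(occ[pos])] <- m$score
        kept[[length(kept) + 1L]] <- m
        break
      }
      # longest contiguous conflict-free run (leftmost on ties), in axis order
      r <- rle(!conflict)
      ends <- cumsum(r$lengths)
      starts_r <- ends - r$lengths + 1L
      free <- which(r$values)
      if (length(free) == 0L) break
      best <- free[which.max(r$lengths[free])]
      a_ax <- starts_r[best] - 1L; b_ax <- ends[best] - 1L   # axis-order rel
      len <- m$length
      if (axis == "query" || m$orientation == "+") {
        a <- a_ax; b <- b_ax
      } else {                     # target axis, reverse motif
        a <- len - 1L - b_ax; b <- len - 1L - a_ax
      }
      m2 <- rebuild_motif(m, a, b, params)
      if (is.null(m2)) break
      m <- m2
      # re-check: trimming inward may have freed all conflicts; loop places it
    }
  }
  out <- if (length(kept) > 0L) do.call(rbind, kept) else empty_motifs()
  if (nrow(out) > 0L) {
    out <- out[order(if (axis == "target") out$t_start else out$q_start,
                     out$score), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (is_prof) {
    profile$motifs <- out
    profile
  } else {
    out
  }
}

#' Dump a motif set as a TSV
#'
#' Debug output: one row per motif with fixed column order
#' (query/target coordinates, orientation, p, q, length, score, core_len).
#'
#' @param motifs Motif data frame or `motif_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(motifs, path) {
  if (inherits(motifs, "motif_profile")) motifs <- motifs$motifs
  cols <- c("q_start", "q_end", "t_start", "t_end", "orientation",
            "p", "q", "length", "score", "core_len")
  utils::write.table(motifs[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
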