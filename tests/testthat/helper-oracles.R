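# Independent brute-force reference implementations ("oracles") used to
# cross-check the package's optimised code paths.  These are deliberately
# written as plain nested loops over the stated rules, with no shared code
# with R/.

# every (q_start, t_start) pair whose k-substrings are identical, N-free,
# and unmasked in both sequences (0-based)
oracle_seeds <- function(query, target, k) {
  qc <- strsplit(query$seq, "", fixed = TRUE)[[1]]
  tc <- strsplit(target$seq, "", fixed = TRUE)[[1]]
  out <- list()
  for (i in seq_len(max(0L, length(qc) - k + 1L))) {
    for (j in seq_len(max(0L, length(tc) - k + 1L))) {
      qi <- i:(i + k - 1L); tj <- j:(j + k - 1L)
      if (all(qc[qi] == tc[tj]) && !any(qc[qi] == "N") &&
            !any(tc[tj] == "N") && !any(query$mask[qi]) &&
            !any(target$mask[tj])) {
        out[[length(out) + 1L]] <- c(i - 1L, j - 1L)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(q_start = integer(0), t_start = integer(0)))
  }
  m <- do.call(rbind, out)
  df <- data.frame(q_start = m[, 1], t_start = m[, 2])
  df[order(df$q_start, df$t_start), , drop = FALSE]
}

# exhaustive-prefix extension: in each direction enumerate every reachable
# prefix (running score, seeded with the seed score, never below zero
# before it), score each, keep the max score then the min length
oracle_extend <- function(query, target, seed, params) {
  qc <- strsplit(query$seq, "", fixed = TRUE)[[1]]
  tc <- strsplit(target$seq, "", fixed = TRUE)[[1]]
  k <- seed$length
  seed_score <- k * params$s_p
  best_dir <- function(dir) {
    qpos <- if (dir > 0) seed$q_start + k + 1L else seed$q_start
    tpos <- if (dir > 0) seed$t_start + k + 1L else seed$t_start
    nmax <- if (dir > 0) {
      min(length(qc) - qpos + 1L, length(tc) - tpos + 1L)
    } else {
      min(qpos, tpos)
    }
    best_len <- 0L; best_score <- seed_score; run <- seed_score
    matches <- logical(0)
    if (nmax > 0) {
      for (n in 1:nmax) {
        qi <- qpos + dir * (n - 1L); ti <- tpos + dir * (n - 1L)
        m <- qc[qi] == tc[ti] && qc[qi] != "N" && tc[ti] != "N"
        matches <- c(matches, m)
        run <- run + if (m) params$s_p else params$s_q
        if (run < 0) break
        if (run > best_score) { best_score <- run; best_len <- n }
      }
    }
    list(len = best_len, match = matches[seq_len(best_len)])
  }
  up <- best_dir(-1L); down <- best_dir(+1L)
  mv <- c(rev(up$match), rep(TRUE, k), down$match)
  p <- sum(mv); q <- length(mv) - p
  list(q_start = seed$q_start - up$len,
       q_end = seed$q_start + k + down$len,
       t_start = seed$t_start - up$len,
       t_end = seed$t_start + k + down$len,
       p = p, q = q, score = (p * params$s_p + q * params$s_q) * (p + q),
       match = mv)
}

# greedy overlap filter, transcribed with explicit interval loops
oracle_filter <- function(motifs, axis, params) {
  n <- nrow(motifs)
  if (n == 0L) return(motifs)
  ax_start <- if (axis == "target") motifs$t_start else motifs$q_start
  ord <- order(-motifs$score, -motifs$length, ax_start,
               motifs$orientation != "+")
  placed <- list()
  kept <- list()
  for (i in ord) {
    m <- motifs[i, , drop = FALSE]
    repeat {
      s <- if (axis == "target") m$t_start else m$q_start
      e <- if (axis == "target") m$t_end else m$q_end
      conflict <- rep(FALSE, e - s)
      for (pl in placed) {
        if (pl$score == m$score) next
        lo <- max(s, pl$s); hi <- min(e, pl$e)
        if (lo < hi) conflict[(lo - s + 1L):(hi - s)] <- TRUE
      }
      if (!any(conflict)) {
        placed[[length(placed) + 1L]] <- list(s = s, e = e,
                                              score = m$score)
        kept[[length(kept) + 1L]] <- m
        break
      }
      # longest free run, leftmost on ties (axis order)
      best_a <- NA; best_b <- NA; best_len <- 0L
      a <- NA
      for (pos in seq_len(e - s + 1L)) {
        free <- pos <= e - s && !conflict[pos]
        if (free && is.na(a)) a <- pos
        if (!free && !is.na(a)) {
          if (pos - a > best_len) {
            best_len <- pos - a; best_a <- a; best_b <- pos - 1L
          }
          a <- NA
        }
      }
      if (best_len == 0L) break
      ax_a <- best_a - 1L; ax_b <- best_b - 1L
      len <- m$length
      if (axis == "query" || m$orientation == "+") {
        qa <- ax_a; qb <- ax_b
      } else {
        qa <- len - 1L - ax_b; qb <- len - 1L - ax_a
      }
      mv <- m$match[[1]]
      while (qa <= qb && !mv[qa + 1L]) qa <- qa + 1L
      while (qb >= qa && !mv[qb + 1L]) qb <- qb - 1L
      if (qa > qb) break
      sub <- mv[(qa + 1L):(qb + 1L)]
      r <- rle(sub)
      core <- if (any(r$values)) max(r$lengths[r$values]) else 0L
      if (core < params$k) break
      p <- sum(sub); q <- length(sub) - p
      if (m$orientation == "+") {
        nt_s <- m$t_start + qa; nt_e <- m$t_start + qb + 1L
      } else {
        nt_s <- m$t_end - qb - 1L; nt_e <- m$t_end - qa
      }
      m2 <- data.frame(q_start = m$q_start + qa, q_end = m$q_start + qb + 1L,
                       t_start = nt_s, t_end = nt_e,
                       orientation = m$orientation, p = p, q = q,
                       length = p + q,
                       score = (p * params$s_p + q * params$s_q) * (p + q),
                       core_len = core)
      m2$match <- list(sub)
      m <- m2
    }
  }
  out <- if (length(kept) > 0L) do.call(rbind, kept) else
    motifs[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical sorted key for motif-set comparison (ignores row order and the
# match list column)
motif_key <- function(m) {
  sort(paste(m$q_start, m$q_end, m$t_start, m$t_end, m$orientation, m$p,
             m$q, signif(m$score, 12)))
}

# direct two-ellipse membership (closed form)
oracle_ellipse <- function(dx, dy, window_len, max_shift) {
  b <- max_shift
  a <- sqrt((window_len / 2)^2 + b^2)
  e1 <- ((dx - window_len / 2)^2) / a^2 + dy^2 / b^2 <= 1
  e2 <- ((dx + window_len / 2)^2) / a^2 + dy^2 / b^2 <= 1
  e1 || e2
}

# ranked-greedy pattern partition, plain loops
oracle_patterns <- function(motifs, window, params) {
  thr <- (params$noise_word_len * params$s_p) * params$noise_word_len
  wl <- window$end - window$start
  fwd <- motifs[motifs$orientation == "+", , drop = FALSE]
  n <- nrow(fwd)
  if (n < 3L) return(list())
  centers_q <- (fwd$q_start + fwd$q_end) / 2
  shifts <- ((fwd$t_start + fwd$t_end) / 2 - window$start) - centers_q
  assigned <- rep(FALSE, n)
  out <- list()
  ord <- order(-fwd$score, -fwd$length, fwd$q_start,
               fwd$orientation != "+")
  for (ai in ord) {
    if (assigned[ai] || fwd$score[ai] < thr) next
    cand <- integer(0)
    for (ci in seq_len(n)) {
      if (assigned[ci]) next
      if (oracle_ellipse(centers_q[ci] - centers_q[ai],
                         shifts[ci] - shifts[ai], wl, params$max_shift)) {
        cand <- c(cand, ci)
      }
    }
    if (length(cand) < 3L) next
    cand <- cand[order(fwd$q_start[cand], fwd$t_start[cand])]
    # chain containing the anchor
    apos <- which(cand == ai)
    lo <- apos
    while (lo > 1L) {
      gq <- fwd$q_start[cand[lo]] - fwd$q_end[cand[lo - 1L]]
      gt <- fwd$t_start[cand[lo]] - fwd$t_end[cand[lo - 1L]]
      if (gq > params$max_distance || gt > params$max_distance) break
      lo <- lo - 1L
    }
    hi <- apos
    while (hi < length(cand)) {
      gq <- fwd$q_start[cand[hi + 1L]] - fwd$q_end[cand[hi]]
      gt <- fwd$t_start[cand[hi + 1L]] - fwd$t_end[cand[hi]]
      if (gq > params$max_distance || gt > params$max_distance) break
      hi <- hi + 1L
    }
    keep <- cand[lo:hi]
    if (length(keep) < 3L || sum(fwd$score[keep] >= thr) < 2L) next
    mem <- fwd[keep, , drop = FALSE]
    nd <- nrow(mem)
    md <- sum(mem$t_start[-1L] - mem$t_end[-nd]) / (nd - 1L)
    psh <- sum(mem$length * shifts[keep]) / sum(mem$length)
    fd <- 1 - md / params$max_distance
    fs <- 1 - abs(shifts[keep] - psh) / (2 * params$max_shift)
    w <- pmin(1, pmax(0, (fd + fs) / 2))
    out[[length(out) + 1L]] <- list(members = mem, mean_distance = md,
                                    pattern_shift = psh, weights = w,
                                    pattern_score = sum(mem$score * w))
    assigned[keep] <- TRUE
  }
  out
}

# run-length region caller
oracle_regions <- function(windows, score_col, threshold) {
  sc <- windows[[score_col]]
  mask <- sc > threshold
  if (!any(mask)) return(data.frame(start = numeric(0), end = numeric(0),
                                    region_score = numeric(0)))
  grp <- cumsum(c(TRUE, diff(which(mask)) > 1))
  runs <- split(which(mask), grp)
  do.call(rbind, lapply(runs, function(i) {
    data.frame(start = windows$start[min(i)], end = windows$end[max(i)],
               region_score = max(sc[i]))
  }))
}

# exhaustive flank classification: recompute environments and evaluate the
# class definitions from scratch
oracle_classify <- function(case) {
  env_of <- function(anchor, genes) {
    g <- genes[genes$seq_id == anchor$seq_id, , drop = FALSE]
    mid <- (anchor$start + anchor$end) / 2
    side <- ifelse(g$tss < anchor$start, "up",
                   ifelse(g$tss >= anchor$end, "down",
                          ifelse(g$tss < mid, "up", "down")))
    dist <- ifelse(side == "up", pmax(0, anchor$start - g$tss),
                   pmax(0, g$tss - anchor$end + 1))
    res <- list()
    for (s in c("up", "down")) {
      gs <- g[side == s, , drop = FALSE]
      ds <- dist[side == s]
      o <- order(ds, gs$gene_id)
      gs <- gs[o, , drop = FALSE]; ds <- ds[o]
      nkeep <- max(sum(ds <= case$margin), min(case$min_per_side, nrow(gs)))
      res[[s]] <- gs$gene_id[seq_len(nkeep)]
    }
    res
  }
  qe <- env_of(case$query_anchor, case$query_genes)
  te <- env_of(case$target_anchor, case$target_genes)
  q_flank <- c(qe$up[1], qe$down[1]); q_flank <- q_flank[!is.na(q_flank)]
  t_flank <- c(te$up[1], te$down[1]); t_flank <- t_flank[!is.na(t_flank)]
  q_all <- c(qe$up, qe$down); t_all <- c(te$up, te$down)
  ortho <- case$orthologs
  maps_to <- function(qg, tset) {
    any(ortho$target_gene[ortho$query_gene == qg] %in% tset)
  }
  n_df <- 0L
  for (qg in q_flank) if (maps_to(qg, t_flank)) n_df <- n_df + 1L
  if (n_df == 2L && length(q_flank) == 2L) return("double_flanked")
  if (n_df >= 1L) return("single_flanked")
  for (qg in q_flank) if (maps_to(qg, t_all)) return("near_flank")
  for (qg in setdiff(q_all, q_flank)) {
    if (maps_to(qg, t_all)) return("not_flanked")
  }
  "not_orthologous"
}
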