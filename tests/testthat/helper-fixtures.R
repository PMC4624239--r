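# Fixture builders shared across test files.  Everything is generated in
# code under explicit seeds; no binary fixtures.

rand_dna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_seq <- function(n, seed = NULL, id = "s") {
  dna_seq(id, rand_dna(n, seed))
}

# build a motif row the way the package lays them out, from an explicit
# match vector (query order)
mk_motif <- function(q_start, t_start, match, orientation = "+",
                     params = scan_params()) {
  len <- length(match)
  p <- sum(match)
  df <- data.frame(q_start = q_start, q_end = q_start + len,
                   t_start = t_start, t_end = t_start + len,
                   orientation = orientation, p = p, q = len - p,
                   length = len, score = score_motif(p, len - p, params),
                   core_len = with(rle(match),
                                   if (any(values)) max(lengths[values])
                                   else 0L))
  df$match <- list(match)
  df
}

# random match vector of length len guaranteed to contain a perfect core
# of at least k
rand_match <- function(len, k, p_match = 0.8) {
  stopifnot(len >= k)
  m <- stats::runif(len) < p_match
  at <- sample.int(len - k + 1L, 1L)
  m[at:(at + k - 1L)] <- TRUE
  m
}

# random synthetic motif set on a qlen x tlen rectangle
rand_motif_set <- function(n, qlen, tlen, params = scan_params(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    len <- sample(params$k:min(40L, qlen, tlen), 1L)
    mk_motif(sample.int(qlen - len + 1L, 1L) - 1L,
             sample.int(tlen - len + 1L, 1L) - 1L,
             rand_match(len, params$k),
             orientation = sample(c("+", "-"), 1L),
             params = params)
  })
  do.call(rbind, rows)
}

# ---- junction-safe permutation fixture -------------------------------------
# Motif blocks over {G,T} (no runs of one base >= 4 so the complement strand
# cannot seed against homopolymer spacers); query spacers are all A, target
# spacers all C.  Every position outside a motif block mismatches on both
# strands, so extension stops exactly at block boundaries and seeds can only
# arise inside motif blocks.  The co-linear and permuted targets then carry
# exactly the same motif set, making their best-window Score_PURE equal by
# construction.
make_junction_safe_fixture <- function(n_motifs = 4L, motif_len = 20L,
                                       spacer_len = 60L, seed = 1L) {
  set.seed(seed)
  block <- function() {
    repeat {
      b <- sample(c("G", "T"), motif_len, replace = TRUE)
      r <- rle(b)
      if (max(r$lengths) < 4L) return(paste(b, collapse = ""))
    }
  }
  blocks <- replicate(n_motifs, block())
  stopifnot(!anyDuplicated(blocks))
  assemble <- function(blks, spacer_char) {
    sp <- strrep(spacer_char, spacer_len)
    paste0(sp, paste0(blks, sp, collapse = ""))
  }
  starts <- spacer_len + (seq_len(n_motifs) - 1L) * (motif_len + spacer_len)
  list(
    query = dna_seq("q", assemble(blocks, "A")),
    target_colinear = dna_seq("t_colin", assemble(blocks, "C")),
    target_permuted = dna_seq("t_perm", assemble(rev(blocks), "C")),
    blocks = blocks,
    motif_starts = starts,
    motif_len = motif_len
  )
}

# random gene layout + ortholog map for classification property tests
rand_classification_case <- function(seed) {
  set.seed(seed)
  n_q <- sample(4:8, 1L); n_t <- sample(4:8, 1L)
  q_anchor <- ginterval("qc", 500000, 501000)
  t_anchor <- ginterval("tc", 500000, 501000)
  mk_genes <- function(n, chr, prefix) {
    data.frame(gene_id = paste0(prefix, seq_len(n)), seq_id = chr,
               tss = sort(sample.int(1000000L, n)), strand = "+")
  }
  qg <- mk_genes(n_q, "qc", "qg")
  tg <- mk_genes(n_t, "tc", "tg")
  n_pairs <- sample(0:6, 1L)
  orth <- data.frame(
    query_gene = sample(qg$gene_id, n_pairs, replace = TRUE),
    target_gene = sample(tg$gene_id, n_pairs, replace = TRUE))
  list(query_anchor = q_anchor, target_anchor = t_anchor,
       query_genes = qg, target_genes = tg, orthologs = orth,
       margin = 200000, min_per_side = 2L)
}

overlaps_interval <- function(region_row, iv) {
  region_row$start < iv$end && region_row$end > iv$start
}
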