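# Candidate assessment.  A predicted region far from any gene orthologous
# to the query enhancer's neighbourhood is unlikely to be the functional
# counterpart; predictions are therefore classified by how well the
# orthology of their flanking genes mirrors the query locus.  A second,
# orthogonal check compares the evolutionary conservation of the motifs
# backing a prediction against random same-length segments from the same
# region.

#' Read gene records (TSS table) from BED6 or GFF3
#'
#' The TSS is the start for `+` genes and `end - 1` for `-` genes (0-based).
#' GFF3 input keeps only `gene` feature lines and uses the `ID` or
#' `gene_id` attribute.
#'
#' @param path BED6 or GFF3 file path (format inferred from extension, or
#'   forced with `format`).
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return Data frame with `gene_id`, `seq_id`, `tss` (0-based), `strand`.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      as.character(gr$gene_id)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  tss <- ifelse(strand == "+",
                GenomicRanges::start(gr) - 1L,   # to 0-based
                GenomicRanges::end(gr) - 1L)
  data.frame(gene_id = ids,
             seq_id = as.character(GenomicRanges::seqnames(gr)),
             tss = as.numeric(tss), strand = strand)
}

#' Read a two-column ortholog-pair table
#'
#' @param path TSV with columns query gene id, target gene id (header
#'   optional; detected when the first line repeats known column names
#'   `query`/`target`).
#' @return Data frame with `query_gene`, `target_gene`.
#' @export
read_orthologs <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog table needs two columns: ", path)
  df <- df[, 1:2]
  names(df) <- c("query_gene", "target_gene")
  if (nrow(df) > 0L && tolower(df$query_gene[1]) %in%
        c("query", "query_gene") ) {
    df <- df[-1L, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Gene environment of an anchor interval
#'
#' All genes with TSS within `margin` of the anchor's boundaries, split into
#' upstream (TSS left of the anchor midpoint side) and downstream sets.
#' A side with fewer than `min_per_side` genes is extended to the nearest
#' TSSs until the minimum is met or the chromosome is exhausted.  Genes with
#' TSS inside the anchor are assigned to the nearer boundary.
#'
#' @param anchor A [ginterval].
#' @param genes Gene data frame ([read_genes()]); only the anchor's
#'   chromosome is used.
#' @param margin Environment half-width in nt.
#' @param min_per_side Minimum genes per side.
#' @return List with data frames `upstream`, `downstream` (each sorted by
#'   distance to the anchor).
#' @export
gene_environment <- function(anchor, genes, margin = 1.5e6,
                             min_per_side = 5L) {
  g <- genes[genes$seq_id == anchor$seq_id, , drop = FALSE]
  mid <- (anchor$start + anchor$end) / 2
  inside <- g$tss >= anchor$start & g$tss < anchor$end
  up_side <- g$tss < anchor$start | (inside & g$tss < mid)
  up <- g[up_side, , drop = FALSE]
  dn <- g[!up_side, , drop = FALSE]
  up$dist <- pmax(0, anchor$start - up$tss)
  dn$dist <- pmax(0, dn$tss - anchor$end + 1)
  pick <- function(side) {
    side <- side[order(side$dist, side$gene_id), , drop = FALSE]
    within <- side$dist <= margin
    n <- max(sum(within), min(min_per_side, nrow(side)))
    side[seq_len(n), , drop = FALSE]
  }
  list(upstream = pick(up), downstream = pick(dn))
}

# nearest gene on each side of the anchor (the "flanking" genes)
flanking_genes <- function(env) {
  c(if (nrow(env$upstream) > 0L) env$upstream$gene_id[1L],
    if (nrow(env$downstream) > 0L) env$downstream$gene_id[1L])
}

#' Classify a prediction by orthology of its flanking genes
#'
#' The query anchor's flanking genes (nearest TSS on each side) are looked
#' up in the ortholog map and compared with the target prediction's gene
#' environment:
#' \describe{
#'   \item{double_flanked}{orthologs of both query flankers are the target
#'     prediction's flanking genes}
#'   \item{single_flanked}{exactly one query flanker has an ortholog in
#'     flanking position at the target}
#'   \item{near_flank}{an ortholog of a query flanking gene lies inside the
#'     target environment but not in flanking position}
#'   \item{not_flanked}{an ortholog of a non-flanking query-environment
#'     gene lies in the target environment}
#'   \item{not_orthologous}{no query-environment gene has an ortholog in
#'     the target environment}
#' }
#' When several ortholog placements exist the most favourable one counts.
#'
#' @param query_anchor,target_prediction [ginterval]s.
#' @param query_genes,target_genes Gene data frames.
#' @param orthologs Ortholog data frame ([read_orthologs()]).
#' @param margin,min_per_side Environment parameters
#'   ([gene_environment()]).
#' @return Character scalar, one of the five classes.
#' @export
classify_flanking <- function(query_anchor, query_genes, target_prediction,
                              target_genes, orthologs, margin = 1.5e6,
                              min_per_side = 5L) {
  if (!target_prediction$seq_id %in% target_genes$seq_id) {
    warning("prediction chromosome '", target_prediction$seq_id,
            "' absent from target annotation")
    return("not_orthologous")
  }
  q_env <- gene_environment(query_anchor, query_genes, margin, min_per_side)
  t_env <- gene_environment(target_prediction, target_genes, margin,
                            min_per_side)
  q_flank <- flanking_genes(q_env)
  t_flank <- flanking_genes(t_env)
  q_all <- c(q_env$upstream$gene_id, q_env$downstream$gene_id)
  t_all <- c(t_env$upstream$gene_id, t_env$downstream$gene_id)
  orth_of <- function(g) orthologs$target_gene[orthologs$query_gene == g]

  # flanker -> is some ortholog a target flanker / in the target environment?
  flank_hits <- vapply(q_flank, function(g) any(orth_of(g) %in% t_flank),
                       logical(1))
  n_flank <- sum(flank_hits)
  if (n_flank == 2L && length(q_flank) == 2L) return("double_flanked")
  if (n_flank >= 1L) return("single_flanked")
  if (any(vapply(q_flank, function(g) any(orth_of(g) %in% t_all),
                 logical(1)))) {
    return("near_flank")
  }
  q_nonflank <- setdiff(q_all, q_flank)
  if (any(vapply(q_nonflank, function(g) any(orth_of(g) %in% t_all),
                 logical(1)))) {
    return("not_flanked")
  }
  "not_orthologous"
}

#' Random motif sets for conservation comparison
#'
#' For a region containing real motifs of the given lengths, draws
#' `n_sets` independent placements of non-overlapping segments of exactly
#' those lengths, uniformly at random inside the region (rejection
#' sampling).
#'
#' @param region A [ginterval].
#' @param motif_lengths Integer vector of segment lengths.
#' @param n_sets Number of independent sets.
#' @param rng_seed Optional seed for reproducibility.
#' @param max_tries Rejection-sampling attempts per set before giving up.
#' @return List of `n_sets` data frames with `seq_id`, `start`, `end`.
#' @export
random_motif_sets <- function(region, motif_lengths, n_sets = 10L,
                              rng_seed = NULL, max_tries = 10000L) {
  if (sum(motif_lengths) > interval_length(region)) {
    stop("motif lengths exceed region length")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rlen <- interval_length(region)
  one_set <- function() {
    for (try in seq_len(max_tries)) {
      starts <- vapply(motif_lengths, function(l) {
        region$start + sample.int(rlen - l + 1L, 1L) - 1L
      }, numeric(1))
      ends <- starts + motif_lengths
      ord <- order(starts)
      if (all(ends[ord][-length(ord)] <= starts[ord][-1L])) {
        return(data.frame(seq_id = region$seq_id, start = starts,
                          end = ends))
      }
    }
    stop("could not place non-overlapping segments after ", max_tries,
         " attempts")
  }
  lapply(seq_len(n_sets), function(i) one_set())
}

#' Read a per-base conservation score track
#'
#' Accepts bedGraph or wiggle (fixed/variable step); scores must lie in
#' `[0, 1]`.  Positions not covered by the track are treated as missing.
#'
#' @param path Track file path (`.bedgraph`/`.bg` or `.wig`).
#' @param format `"auto"`, `"bedGraph"` or `"wig"`.
#' @return A `cons_track`: list mapping seq_id to a data frame with
#'   0-based `pos` and `score`.
#' @export
read_track <- function(path, format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("wig", "wiggle")) "wig" else "bedGraph"
  }
  gr <- rtracklayer::import(path, format = format)
  sc <- gr$score
  if (any(sc < 0 | sc > 1)) stop("conservation scores must be in [0, 1]")
  per_base <- data.frame(
    seq_id = rep(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::width(gr)),
    pos = unlist(lapply(seq_along(gr), function(i) {
      seq.int(GenomicRanges::start(gr)[i] - 1L,
              GenomicRanges::end(gr)[i] - 1L)
    })),
    score = rep(sc, GenomicRanges::width(gr))
  )
  per_base <- per_base[!duplicated(per_base[c("seq_id", "pos")]), ,
                       drop = FALSE]
  structure(split(per_base[c("pos", "score")], per_base$seq_id),
            class = "cons_track")
}

#' Mean conservation per interval
#'
#' The arithmetic mean of the available per-base scores of each interval;
#' intervals with no covered base yield `NA`.
#'
#' @param intervals List of [ginterval]s or a data frame with `seq_id`,
#'   `start`, `end`.
#' @param track A `cons_track` ([read_track()]).
#' @return Numeric vector of per-interval means (NA where uncovered).
#' @export
motif_conservation <- function(intervals, track) {
  if (is.data.frame(intervals)) {
    intervals <- lapply(seq_len(nrow(intervals)), function(i) {
      ginterval(intervals$seq_id[i], intervals$start[i], intervals$end[i])
    })
  }
  vapply(intervals, function(iv) {
    tr <- track[[iv$seq_id]]
    if (is.null(tr)) return(NA_real_)
    sel <- tr$score[tr$pos >= iv$start & tr$pos < iv$end]
    if (length(sel) == 0L) NA_real_ else mean(sel)
  }, numeric(1))
}

#' Compare real vs random motif conservation
#'
#' Two-sided Wilcoxon rank-sum test of the real per-motif conservation
#' means against the pooled random-set means.
#'
#' @param real_means,random_means Numeric vectors (NAs dropped).
#' @return List with `statistic` (W) and `p_value`.
#' @export
compare_conservation <- function(real_means, random_means) {
  real_means <- real_means[!is.na(real_means)]
  random_means <- random_means[!is.na(random_means)]
  if (length(real_means) == 0L || length(random_means) == 0L) {
    stop("empty conservation sample after dropping missing values")
  }
  wt <- suppressWarnings(stats::wilcox.test(real_means, random_means,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
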