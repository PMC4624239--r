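# Synthetic sequence evolution.  The scanner assumes enhancers evolve as a
# chain of conserved motif blocks separated by fast-evolving spacers; this
# module generates exactly that world: an ancestral enhancer of alternating
# spacer/motif blocks, descendants produced by substitution-only evolution
# at separate motif/spacer rates, optional permutation of the motif blocks
# (with freshly resampled spacers so block junctions create no accidental
# seeds), and embedding into an i.i.d. random background genome.  Matching
# gene annotations, ortholog tables and conservation tracks exercise the
# annotation module.

#' Evolution / fixture configuration
#'
#' Defaults follow the canonical fixture: eight motif blocks of 15-25 nt
#' separated by 30-60 nt spacers, motif substitution rate 0.05 vs spacer
#' rate 0.4 (conserved motifs, heavily turned-over spacers), no
#' permutation, a 100 kb background at GC 0.5.
#'
#' @param n_motifs Number of motif blocks.
#' @param motif_len_range Motif length bounds (nt).
#' @param spacer_len_range Spacer length bounds (nt).
#' @param motif_subst_rate Per-base substitution probability inside motifs.
#' @param spacer_subst_rate Per-base substitution probability in spacers.
#' @param permute Permute motif blocks in the second descendant.
#' @param background_len Background genome length (nt).
#' @param gc_content Background/ancestor GC fraction.
#' @param rng_seed Integer seed; all generators are deterministic under it.
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(n_motifs = 8L, motif_len_range = c(15L, 25L),
                             spacer_len_range = c(30L, 60L),
                             motif_subst_rate = 0.05,
                             spacer_subst_rate = 0.4, permute = FALSE,
                             background_len = 100000L, gc_content = 0.5,
                             rng_seed = 1L) {
  cfg <- list(n_motifs = as.integer(n_motifs),
              motif_len_range = as.integer(motif_len_range),
              spacer_len_range = as.integer(spacer_len_range),
              motif_subst_rate = motif_subst_rate,
              spacer_subst_rate = spacer_subst_rate,
              permute = isTRUE(permute),
              background_len = as.integer(background_len),
              gc_content = gc_content,
              rng_seed = as.integer(rng_seed))
  stopifnot(
    cfg$n_motifs >= 0L,
    length(cfg$motif_len_range) == 2L, length(cfg$spacer_len_range) == 2L,
    all(cfg$motif_len_range >= 1L), all(cfg$spacer_len_range >= 1L),
    diff(cfg$motif_len_range) >= 0L, diff(cfg$spacer_len_range) >= 0L,
    cfg$motif_subst_rate >= 0, cfg$motif_subst_rate <= 1,
    cfg$spacer_subst_rate >= 0, cfg$spacer_subst_rate <= 1,
    cfg$background_len >= 1L, cfg$gc_content > 0, cfg$gc_content < 1
  )
  class(cfg) <- "evolution_config"
  cfg
}

random_bases <- function(n, gc = 0.5) {
  if (n == 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate an ancestral enhancer with recorded motif blocks
#'
#' Alternating spacer/motif blocks (spacer first and last), lengths drawn
#' uniformly from the configured ranges, i.i.d. bases at the configured GC.
#'
#' @param cfg An [evolution_config()].
#' @param id Sequence id.
#' @return List with `seq` (a `dna_seq`) and `motifs` (data frame `start`,
#'   `end`, 0-based half-open).
#' @export
make_ancestor <- function(cfg = evolution_config(), id = "ancestor") {
  set.seed(cfg$rng_seed)
  mlen <- if (cfg$n_motifs > 0L) {
    sample(seq.int(cfg$motif_len_range[1], cfg$motif_len_range[2]),
           cfg$n_motifs, replace = TRUE)
  } else integer(0)
  slen <- sample(seq.int(cfg$spacer_len_range[1], cfg$spacer_len_range[2]),
                 cfg$n_motifs + 1L, replace = TRUE)
  parts <- character(0)
  starts <- integer(0)
  pos <- 0L
  for (i in seq_len(cfg$n_motifs)) {
    sp <- paste(random_bases(slen[i], cfg$gc_content), collapse = "")
    mo <- paste(random_bases(mlen[i], cfg$gc_content), collapse = "")
    parts <- c(parts, sp, mo)
    pos <- pos + slen[i]
    starts <- c(starts, pos)
    pos <- pos + mlen[i]
  }
  parts <- c(parts, paste(random_bases(slen[cfg$n_motifs + 1L],
                                       cfg$gc_content), collapse = ""))
  list(seq = dna_seq(id, paste(parts, collapse = "")),
       motifs = data.frame(start = starts, end = starts + mlen))
}

#' Evolve a sequence by per-base substitution
#'
#' Each base mutates independently to a uniformly chosen different base,
#' with probability `motif_subst_rate` inside the recorded motif intervals
#' and `spacer_subst_rate` outside.  Substitution-only: coordinates are
#' unchanged.
#'
#' @param seq A `dna_seq`.
#' @param motifs Motif coordinate data frame (`start`, `end`).
#' @param cfg An [evolution_config()].
#' @param id Id for the descendant.
#' @return List with `seq` and the (unchanged) `motifs`.
#' @export
evolve <- function(seq, motifs, cfg = evolution_config(),
                   id = paste0(seq$id, "_desc")) {
  chars <- strsplit(seq$seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  in_motif <- rep(FALSE, n)
  for (i in seq_len(nrow(motifs))) {
    in_motif[(motifs$start[i] + 1L):motifs$end[i]] <- TRUE
  }
  rate <- ifelse(in_motif, cfg$motif_subst_rate, cfg$spacer_subst_rate)
  hit <- stats::runif(n) < rate
  if (any(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
    idx <- which(hit)
    pick <- ceiling(stats::runif(length(idx)) * 3)
    chars[idx] <- vapply(seq_along(idx), function(j) {
      a <- alt[[chars[idx[j]]]]
      a[min(pick[j], length(a))]
    }, character(1))
  }
  list(seq = dna_seq(id, paste(chars, collapse = "")), motifs = motifs)
}

#' Permute the motif blocks of a sequence
#'
#' Motif blocks are reordered per `order`; the spacers are freshly
#' resampled (same lengths, so the sequence length and the motif slot
#' positions are preserved) to avoid accidental seeds across the new block
#' junctions.
#'
#' @param seq A `dna_seq`.
#' @param motifs Motif coordinate data frame.
#' @param order Permutation of `seq_len(nrow(motifs))`; block `i` of the
#'   output carries the sequence of input block `order[i]`.
#' @param cfg An [evolution_config()] (GC for spacer resampling).
#' @param resample_spacers Set `FALSE` to keep original spacer sequence.
#' @param id Output id.
#' @return List with `seq` and updated `motifs` plus a `permutation`
#'   attribute recording `order`.
#' @export
permute_motifs <- function(seq, motifs, order, cfg = evolution_config(),
                           resample_spacers = TRUE,
                           id = paste0(seq$id, "_perm")) {
  n <- nrow(motifs)
  if (!setequal(order, seq_len(n)) || length(order) != n) {
    stop("`order` must be a permutation of 1..", n)
  }
  blocks <- substring(seq$seq, motifs$start + 1L, motifs$end)
  # output slots: lengths must match the incoming block lengths
  out_len <- nchar(blocks)[order]
  spacer_sub <- function(i) {
    # spacer i sits between motif i-1's end and motif i's start
    from <- if (i == 1L) 0L else motifs$end[i - 1L]
    to <- if (i > n) seq_length(seq) else motifs$start[i]
    if (resample_spacers) {
      paste(random_bases(to - from, cfg$gc_content), collapse = "")
    } else {
      substring(seq$seq, from + 1L, to)
    }
  }
  parts <- character(0)
  starts <- integer(0)
  pos <- 0L
  for (i in seq_len(n)) {
    sp <- spacer_sub(i)
    parts <- c(parts, sp, blocks[order[i]])
    pos <- pos + nchar(sp)
    starts <- c(starts, pos)
    pos <- pos + out_len[i]
  }
  parts <- c(parts, spacer_sub(n + 1L))
  res <- list(seq = dna_seq(id, paste(parts, collapse = "")),
              motifs = data.frame(start = starts, end = starts + out_len),
              permutation = order)
  res
}

#' Embed a region into a random background genome
#'
#' @param region A `dna_seq`.
#' @param cfg An [evolution_config()] (`background_len`, `gc_content`).
#' @param position Insertion offset (0-based) or `"random"`.
#' @param id Genome sequence id.
#' @return List with `genome` (a `dna_seq`) and `truth` (list with
#'   `enhancer_interval` [ginterval] and `offset`).
#' @export
embed_in_background <- function(region, cfg = evolution_config(),
                                position = "random", id = "chrSim") {
  rlen <- seq_length(region)
  if (rlen > cfg$background_len) stop("region longer than background")
  max_off <- cfg$background_len - rlen
  off <- if (identical(position, "random")) {
    if (max_off == 0L) 0L else sample.int(max_off + 1L, 1L) - 1L
  } else {
    as.integer(position)
  }
  if (off < 0L || off > max_off) stop("invalid insertion offset")
  bg <- random_bases(cfg$background_len, cfg$gc_content)
  reg <- strsplit(region$seq, "", fixed = TRUE)[[1]]
  if (rlen > 0L) bg[(off + 1L):(off + rlen)] <- reg
  list(genome = dna_seq(id, paste(bg, collapse = "")),
       truth = list(enhancer_interval = ginterval(id, off, off + rlen),
                    offset = off))
}

#' Generate a full planted-enhancer fixture
#'
#' Convenience wrapper: ancestor -> two descendants (query and target
#' enhancer), optional permutation of the target's motif blocks, embedding
#' of the target enhancer into a random background genome.
#'
#' @param cfg An [evolution_config()].
#' @return List with `query` (`dna_seq`), `genome` (`dna_seq`), `truth`
#'   (enhancer interval, per-descendant motif coordinates, permutation).
#' @export
make_planted_fixture <- function(cfg = evolution_config()) {
  anc <- make_ancestor(cfg)
  d1 <- evolve(anc$seq, anc$motifs, cfg, id = "query_enh")
  d2 <- evolve(anc$seq, anc$motifs, cfg, id = "target_enh")
  perm <- seq_len(cfg$n_motifs)
  if (cfg$permute && cfg$n_motifs > 1L) {
    perm <- rev(seq_len(cfg$n_motifs))
    d2 <- permute_motifs(d2$seq, d2$motifs, perm, cfg, id = "target_enh")
  }
  emb <- embed_in_background(d2$seq, cfg)
  motifs_genome <- d2$motifs
  motifs_genome$start <- motifs_genome$start + emb$truth$offset
  motifs_genome$end <- motifs_genome$end + emb$truth$offset
  list(query = d1$seq, genome = emb$genome,
       truth = list(enhancer_interval = emb$truth$enhancer_interval,
                    query_motifs = d1$motifs,
                    genome_motifs = motifs_genome,
                    permutation = perm))
}

#' Synthetic annotation fixture for flank classification
#'
#' Constructs paired gene layouts realizing each of the five flank classes
#' by placement: for every class one query locus and one target locus with
#' genes, an ortholog table, and the intended label.
#'
#' @param rng_seed Seed (placement jitter).
#' @param margin Environment margin used when classifying (kept small so
#'   the fixture stays compact).
#' @return List of cases; each has `label`, `query_anchor`,
#'   `target_anchor`, `query_genes`, `target_genes`, `orthologs`,
#'   `margin`, `min_per_side`.
#' @export
make_annotation_fixture <- function(rng_seed = 1L, margin = 50000L) {
  set.seed(rng_seed)
  min_per_side <- 2L
  gene_row <- function(id, chr, tss) {
    data.frame(gene_id = id, seq_id = chr, tss = tss, strand = "+")
  }
  # query locus: anchor [100000, 101000), genes qU2 qU1 | anchor | qD1 qD2
  q_anchor <- ginterval("qchr", 100000, 101000)
  q_genes <- rbind(gene_row("qU2", "qchr", 60000),
                   gene_row("qU1", "qchr", 90000),
                   gene_row("qD1", "qchr", 110000),
                   gene_row("qD2", "qchr", 140000))
  t_anchor <- ginterval("tchr", 200000, 201000)
  base_t <- function(u2, u1, d1, d2) {
    rbind(gene_row(u2, "tchr", 160000), gene_row(u1, "tchr", 190000),
          gene_row(d1, "tchr", 210000), gene_row(d2, "tchr", 240000))
  }
  orth <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(query_gene = m[, 1], target_gene = m[, 2])
  }
  cases <- list(
    list(label = "double_flanked",
         target_genes = base_t("tU2", "tU1", "tD1", "tD2"),
         orthologs = orth("qU1", "tU1", "qD1", "tD1")),
    list(label = "single_flanked",
         target_genes = base_t("tU2", "tU1", "tD1", "tD2"),
         orthologs = orth("qU1", "tU1")),
    # ortholog of a query flanker present in the target environment but in
    # non-flanking position (tU2)
    list(label = "near_flank",
         target_genes = base_t("tU2", "tU1", "tD1", "tD2"),
         orthologs = orth("qU1", "tU2")),
    # only a non-flanking query gene (qU2) has an ortholog nearby
    list(label = "not_flanked",
         target_genes = base_t("tU2", "tU1", "tD1", "tD2"),
         orthologs = orth("qU2", "tU1")),
    list(label = "not_orthologous",
         target_genes = base_t("tU2", "tU1", "tD1", "tD2"),
         orthologs = orth("qU1", "elsewhere1", "qD1", "elsewhere2"))
  )
  lapply(cases, function(cs) {
    list(label = cs$label, query_anchor = q_anchor,
         target_anchor = t_anchor, query_genes = q_genes,
         target_genes = cs$target_genes, orthologs = cs$orthologs,
         margin = margin, min_per_side = min_per_side)
  })
}

#' Write a planted fixture to disk in standard formats
#'
#' Emits the query FASTA, genome FASTA, truth BED (enhancer + motif
#' intervals), a synthetic conservation bedGraph (0.9 inside motif truth
#' intervals, 0.1 outside the enhancer, 0.3 in enhancer spacers) and a JSON
#' manifest.
#'
#' @param fixture Output of [make_planted_fixture()].
#' @param dir Output directory (created if needed).
#' @param cfg The [evolution_config()] used (recorded in the manifest).
#' @return Invisibly, named vector of paths.
#' @export
write_fixture <- function(fixture, dir, cfg = evolution_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(query = file.path(dir, "query.fa"),
             genome = file.path(dir, "genome.fa"),
             truth = file.path(dir, "truth.bed"),
             track = file.path(dir, "conservation.bedgraph"),
             manifest = file.path(dir, "manifest.json"))
  write_fasta(fixture$query, paths["query"])
  write_fasta(fixture$genome, paths["genome"])
  tr <- fixture$truth
  bed <- rbind(
    data.frame(chrom = fixture$genome$id, start = tr$enhancer_interval$start,
               end = tr$enhancer_interval$end, name = "enhancer"),
    if (nrow(tr$genome_motifs) > 0L)
      data.frame(chrom = fixture$genome$id, start = tr$genome_motifs$start,
                 end = tr$genome_motifs$end,
                 name = paste0("motif", seq_len(nrow(tr$genome_motifs))))
  )
  utils::write.table(bed, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # piecewise-constant synthetic conservation track over the genome
  gl <- seq_length(fixture$genome)
  brk <- sort(unique(c(0, tr$enhancer_interval$start,
                       tr$enhancer_interval$end, tr$genome_motifs$start,
                       tr$genome_motifs$end, gl)))
  seg <- data.frame(start = brk[-length(brk)], end = brk[-1L])
  seg$score <- vapply(seq_len(nrow(seg)), function(i) {
    s <- seg$start[i]
    if (nrow(tr$genome_motifs) > 0L &&
          any(s >= tr$genome_motifs$start & s < tr$genome_motifs$end)) {
      0.9
    } else if (s >= tr$enhancer_interval$start &&
                 s < tr$enhancer_interval$end) {
      0.3
    } else {
      0.1
    }
  }, numeric(1))
  utils::write.table(
    data.frame(chrom = fixture$genome$id, start = seg$start, end = seg$end,
               score = seg$score),
    paths["track"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  manifest <- list(config = unclass(cfg),
                   permutation = tr$permutation,
                   permuted = !identical(tr$permutation,
                                         seq_along(tr$permutation)),
                   motif_free = nrow(tr$genome_motifs) == 0L,
                   enhancer_interval = c(tr$enhancer_interval$start,
                                         tr$enhancer_interval$end),
                   query_len = seq_length(fixture$query),
                   genome_len = gl)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
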