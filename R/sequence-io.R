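#' DNA sequence with soft-mask information
#'
#' Residues are stored uppercase over the alphabet {A,C,G,T,N}; lowercase
#' letters in the source FASTA set a per-position soft-mask flag (repeat
#' annotation).  Masked positions are excluded from seeding but behave
#' normally (match/mismatch by identity) during extension.
#'
#' @param id Sequence identifier.
#' @param residues Character string of residues; lowercase marks soft-masked
#'   positions.
#' @param mask Optional logical vector overriding the case-derived mask.
#' @return An object of class `dna_seq`: list with `id`, `seq` (uppercase
#'   string) and `mask` (logical vector, one flag per residue).
#' @export
dna_seq <- function(id, residues, mask = NULL) {
  residues <- as.character(residues)
  stopifnot(length(residues) == 1L, nchar(residues) >= 1L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- !chars %in% c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")
  if (any(bad)) {
    stop("illegal residue symbol(s) in sequence '", id, "': ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  if (is.null(mask)) {
    mask <- chars %in% c("a", "c", "g", "t", "n")
  }
  stopifnot(is.logical(mask), length(mask) == length(chars))
  structure(list(id = as.character(id),
                 seq = toupper(residues),
                 mask = mask),
            class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  cat(sprintf("dna_seq '%s': %d nt (%d soft-masked)\n",
              x$id, seq_length(x), sum(x$mask)))
  invisible(x)
}

#' Sequence length in nucleotides
#' @param s A `dna_seq`.
#' @return Integer length.
#' @export
seq_length <- function(s) nchar(s$seq)

#' Read a FASTA file into a list of sequences
#'
#' Lowercase residues (soft-masking) set the per-position mask flag and are
#' uppercased for storage.  Characters outside `{A,C,G,T,N}` (either case)
#' are rejected.
#'
#' @param path FASTA file path.
#' @return Named list of [dna_seq] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- dna_seq(ids[i], as.character(set[[i]]))
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA, restoring soft-mask case
#'
#' @param seqs A `dna_seq` or list of them.
#' @param path Output path.
#' @param width Line width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    chars <- strsplit(s$seq, "", fixed = TRUE)[[1]]
    chars[s$mask] <- tolower(chars[s$mask])
    txt <- paste(chars, collapse = "")
    writeLines(paste0(">", s$id), con)
    starts <- seq(1L, nchar(txt), by = width)
    writeLines(substring(txt, starts, pmin(starts + width - 1L, nchar(txt))),
               con)
  }
  invisible(path)
}

COMPLEMENT_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a sequence
#'
#' Standard complement with N <-> N; the soft-mask flags are reversed in the
#' same order so they stay attached to their residues.
#'
#' @param s A `dna_seq`.
#' @return A `dna_seq` of equal length.
#' @export
reverse_complement <- function(s) {
  chars <- strsplit(s$seq, "", fixed = TRUE)[[1]]
  rc <- paste(rev(unname(COMPLEMENT_MAP[chars])), collapse = "")
  dna_seq(s$id, rc, mask = rev(s$mask))
}

#' Genomic interval (0-based, half-open)
#'
#' The internal coordinate convention throughout the package: `start` is a
#' 0-based inclusive offset, `end` is exclusive, so the interval length is
#' `end - start` (BED semantics).
#'
#' @param seq_id Sequence/chromosome identifier.
#' @param start 0-based inclusive start.
#' @param end Exclusive end.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `ginterval`.
#' @export
ginterval <- function(seq_id, start, end, strand = "+") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start >= 0 && start < end)) {
    stop("invalid interval: start=", start, " end=", end)
  }
  stopifnot(strand %in% c("+", "-"))
  structure(list(seq_id = as.character(seq_id), start = start, end = end,
                 strand = strand),
            class = "ginterval")
}

#' Interval length
#' @param x A `ginterval`.
#' @return `end - start`.
#' @export
interval_length <- function(x) x$end - x$start

#' @export
print.ginterval <- function(x, ...) {
  cat(sprintf("%s:[%g,%g)%s\n", x$seq_id, x$start, x$end, x$strand))
  invisible(x)
}

#' Convert printed 1-based inclusive coordinates to an internal interval
#'
#' Published genome coordinates (browser style) are 1-based and inclusive on
#' both ends; this converts them to the package's 0-based half-open
#' convention so that `interval_length()` equals the printed size
#' (`end - start + 1`).
#'
#' @param chrom Chromosome identifier.
#' @param start_1based 1-based inclusive start.
#' @param end_1based 1-based inclusive end.
#' @return A [ginterval].
#' @export
interval_from_printed <- function(chrom, start_1based, end_1based) {
  if (start_1based < 1 || start_1based > end_1based) {
    stop("invalid printed coordinates: ", start_1based, "-", end_1based)
  }
  ginterval(chrom, start_1based - 1, end_1based)
}

#' Write predicted regions as BED6 plus a full-precision TSV sidecar
#'
#' BED scores are the region scores rounded to integer; the sidecar TSV
#' keeps full precision and the score type (PURE/COMB).  BED name column is
#' `queryID.rank`.
#'
#' @param regions Data frame of predicted regions as returned by
#'   [rank_predictions()] / [scan_target()] (columns `seq_id`, `start`,
#'   `end`, `score_type`, `region_score`, `rank`, `query_id`).
#' @param path Output BED path; the sidecar is written next to it with a
#'   `.tsv` extension.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_predictions <- function(regions, path) {
  tsv_path <- paste0(tools::file_path_sans_ext(path), ".tsv")
  cols <- c("seq_id", "start", "end", "score_type", "region_score", "rank",
            "query_id")
  if (nrow(regions) == 0L) {
    regions <- data.frame(seq_id = character(), start = numeric(),
                          end = numeric(), score_type = character(),
                          region_score = numeric(), rank = integer(),
                          query_id = character())
  }
  stopifnot(all(cols %in% names(regions)))
  bed <- if (nrow(regions) > 0L) {
    data.frame(
      chrom = regions$seq_id,
      start = format(regions$start, scientific = FALSE, trim = TRUE),
      end = format(regions$end, scientific = FALSE, trim = TRUE),
      name = paste0(regions$query_id, ".", regions$rank),
      score = round(regions$region_score),
      strand = "+"
    )
  } else {
    data.frame()
  }
  tryCatch({
    if (nrow(bed) > 0L) {
      utils::write.table(bed, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else {
      cat("", file = path)
    }
    TRUE
  }, error = function(e) stop("cannot write predictions to '", path, "': ",
                              conditionMessage(e)))
  utils::write.table(regions[, cols], tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(path, tsv_path))
}
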