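test_that("gene_environment: margin, side split, extension rule", {
  # 12 genes evenly spaced 200 kb around the anchor: 7 per side in 1.5 Mb
  anchor <- ginterval("c", 5000000, 5001000)
  tss <- c(anchor$start - (1:12) * 200000, anchor$end + (1:12) * 200000)
  genes <- data.frame(gene_id = paste0("g", seq_along(tss)), seq_id = "c",
                      tss = tss, strand = "+")
  env <- gene_environment(anchor, genes)
  expect_equal(nrow(env$upstream), 7L)
  expect_equal(nrow(env$downstream), 7L)

  # 3 genes upstream within margin, 4 beyond: extended to the 5 nearest
  tss_u <- c(anchor$start - c(1, 2, 3) * 400000,
             anchor$start - c(2, 3, 4, 5) * 1e6)
  genes2 <- rbind(
    data.frame(gene_id = paste0("u", 1:7), seq_id = "c", tss = tss_u,
               strand = "+"),
    data.frame(gene_id = paste0("d", 1:6), seq_id = "c",
               tss = anchor$end + (1:6) * 200000, strand = "+"))
  env2 <- gene_environment(anchor, genes2)
  expect_equal(nrow(env2$upstream), 5L)
  expect_equal(env2$upstream$gene_id[1:3], c("u1", "u2", "u3"))

  # gene-poor side: exhausted at 3
  genes3 <- genes2[c(1:3, 8:13), ]
  expect_equal(nrow(gene_environment(anchor, genes3)$upstream), 3L)
})

test_that("classify_flanking reproduces every constructed label", {
  cases <- make_annotation_fixture(rng_seed = 4)
  expect_setequal(vapply(cases, `[[`, character(1), "label"),
                  c("double_flanked", "single_flanked", "near_flank",
                    "not_flanked", "not_orthologous"))
  for (cs in cases) {
    got <- classify_flanking(cs$query_anchor, cs$query_genes,
                             cs$target_anchor, cs$target_genes,
                             cs$orthologs, cs$margin, cs$min_per_side)
    expect_equal(got, cs$label)
  }
  # prediction on an unannotated chromosome: not_orthologous with warning
  cs <- cases[[1]]
  expect_warning(
    got <- classify_flanking(cs$query_anchor, cs$query_genes,
                             ginterval("chrUn", 0, 1000), cs$target_genes,
                             cs$orthologs, cs$margin, cs$min_per_side),
    "absent")
  expect_equal(got, "not_orthologous")
})

test_that("classify_flanking matches the exhaustive oracle on random cases", {
  for (seed in 1:100) {
    cs <- rand_classification_case(seed)
    got <- classify_flanking(cs$query_anchor, cs$query_genes,
                             cs$target_anchor, cs$target_genes,
                             cs$orthologs, cs$margin, cs$min_per_side)
    expect_equal(got, oracle_classify(cs), label = paste("seed", seed))
    # order-insensitive to gene-list input order
    perm <- cs
    perm$query_genes <- perm$query_genes[sample(nrow(perm$query_genes)), ]
    perm$target_genes <- perm$target_genes[sample(nrow(perm$target_genes)), ]
    got2 <- classify_flanking(perm$query_anchor, perm$query_genes,
                              perm$target_anchor, perm$target_genes,
                              perm$orthologs, perm$margin, perm$min_per_side)
    expect_equal(got2, got)
  }
})

test_that("random_motif_sets: contract, non-overlap, uniformity", {
  region <- ginterval("c", 0, 1000)
  sets <- random_motif_sets(region, c(20, 30), n_sets = 10, rng_seed = 42)
  expect_length(sets, 10L)
  for (s in sets) {
    expect_equal(sort(s$end - s$start), c(20, 30))
    expect_true(all(s$start >= 0 & s$end <= 1000))
    o <- order(s$start)
    expect_true(all(s$end[o][-nrow(s)] <= s$start[o][-1]))
  }
  # reproducible under the seed
  sets2 <- random_motif_sets(region, c(20, 30), n_sets = 10, rng_seed = 42)
  expect_identical(sets, sets2)

  expect_error(random_motif_sets(ginterval("c", 0, 1000), c(600, 600)),
               "exceed")

  # single length-10 segment in a 100 nt region: uniform starts over 0..90
  starts <- vapply(random_motif_sets(ginterval("c", 0, 100), 10,
                                     n_sets = 10000, rng_seed = 1),
                   function(s) s$start, numeric(1))
  tab <- tabulate(starts + 1, nbins = 91)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("motif_conservation averages covered bases; track I/O round-trips", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("c\t0\t2\t0.2", "c\t2\t3\t0.4", "c\t3\t4\t0.6",
               "c\t4\t8\t0.8"), bg)
  track <- read_track(bg)
  # interval [0,4): bases 0.2 0.2 0.4 0.6 -> 0.35
  expect_equal(motif_conservation(list(ginterval("c", 0, 4)), track), 0.35)
  # fully outside coverage: missing
  expect_true(is.na(motif_conservation(list(ginterval("c", 100, 110)),
                                       track)))
  expect_true(is.na(motif_conservation(list(ginterval("other", 0, 4)),
                                       track)))

  # fixed-step wiggle input
  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=c start=1 step=1",
               format(seq(0.1, 1, by = 0.1))), wig)
  tw <- read_track(wig)
  expect_equal(motif_conservation(list(ginterval("c", 0, 4)), tw),
               mean(c(0.1, 0.2, 0.3, 0.4)))

  # random tracks: matches a per-base loop
  set.seed(77)
  n <- 500
  writeLines(sprintf("c\t%d\t%d\t%.3f", 0:(n - 1), 1:n,
                     round(stats::runif(n), 3)), bg)
  tr <- read_track(bg)
  vals <- tr$c$score[order(tr$c$pos)]
  for (i in 1:20) {
    a <- sample(0:(n - 20), 1); b <- a + sample(5:20, 1)
    ref <- mean(vals[(a + 1):b])
    expect_equal(motif_conservation(list(ginterval("c", a, b)), tr), ref)
  }
})

test_that("compare_conservation: Wilcoxon rank-sum behaviour and oracle", {
  x <- c(0.1, 0.5, 0.9, 0.3, 0.7)
  same <- compare_conservation(x, x)
  expect_gt(same$p_value, 0.9)

  sep <- compare_conservation(rep(1, 8), rep(0, 80))
  expect_lt(sep$p_value, 0.01)

  expect_error(compare_conservation(numeric(0), x), "empty")
  expect_error(compare_conservation(NA_real_, x), "empty")

  # agreement with a permutation null on shifted normals
  set.seed(31)
  a <- stats::rnorm(15, 0.6, 0.1)
  b <- stats::rnorm(40, 0.45, 0.1)
  got <- compare_conservation(a, b)
  pooled <- c(a, b)
  n_perm <- 4000
  ref_stat <- sum(rank(pooled)[seq_along(a)]) -
    length(a) * (length(a) + 1) / 2
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pooled), length(a))
    s <- sum(rank(pooled)[idx]) - length(a) * (length(a) + 1) / 2
    mu <- length(a) * length(b) / 2
    if (abs(s - mu) >= abs(ref_stat - mu)) exceed <- exceed + 1L
  }
  p_perm <- exceed / n_perm
  expect_lt(abs(got$p_value - p_perm),
            0.05 + 3 * sqrt(p_perm * (1 - p_perm) / n_perm))
})
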