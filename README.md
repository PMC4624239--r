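# crescan

Permutation-tolerant enhancer similarity scanning in R.

## The problem

Enhancers built on the "billboard" model tolerate rearrangement and turnover
of their transcription-factor binding sites: over large evolutionary
distances the functional motifs survive while the spacer sequence between
them turns over completely, and the motifs themselves may be permuted.  Such
elements are invisible to local aligners (which need co-linearity) and
poorly handled by plain k-mer ("alignment-free") profiles (which fragment
every variable position into different words).  `crescan` implements a
composite scoring principle for predicting candidate enhancer regions in a
target genome from a *single* query enhancer sequence — no training set, no
multi-species alignment, no TFBS models.

## The method

For a query of length `L` scanned against a target:

1. **Seeding** — every perfectly matching, unmasked, N-free `k`-mer between
   query and target (default `k = 8`), on both strands.
2. **Mismatch extension** — each seed is extended independently up- and
   downstream under a match/mismatch scheme (`s_p = +1`, `s_q = -1`); a
   direction's running score starts at the seed score and extension halts
   when it drops below 0, then is truncated back to the shortest prefix with
   the maximal running score.  The merged region is a *motif*, scored

   `score = (p*s_p + q*s_q) * (p + q)`

   with `p`/`q` matching/mismatching nucleotides — long, mismatch-tolerant
   motifs outscore short perfect words.
3. **Overlap filtering** — motifs are ranked by score and placed greedily,
   first on the target axis and then (per window) on the query axis; a
   lower-scoring motif overlapping a placed one is truncated to the next
   matching nucleotide outside the overlap and rescored; equal-score motifs
   may overlap.
4. **Window scoring** — windows of size `L` step across the target at 25%
   of `L`; motifs overlapping a window boundary still count.
   `Score_PURE` = sum of motif scores at or above the noise threshold (the
   score of a perfect 12-mer, 144 by default).  Because it is a plain sum
   over a filtered motif set, `Score_PURE` is indifferent to motif order —
   this is what tolerates permutation.
5. **Pattern detection** — co-linear motifs share a diagonal (query-target
   shift).  Starting at the strongest motif, elliptical motif spaces along
   its diagonal (semi-minor axis `Max_Shift = 25` nt, foci one window length
   apart) collect motifs that chain with inter-motif gaps `<= Max_Distance =
   200` nt into patterns (>= 3 members, >= 2 above threshold; sub-threshold
   motifs can be rescued).  Members are weighted by pattern tightness and
   shift deviation, and the weighted sum is added to give `Score_COMB`.
6. **Region calling** — windows scoring strictly above
   `median + 3 * MAD` of the scan's score distribution are merged into
   maximal runs; regions are ranked and the top 25 per query reported,
   separately for PURE and COMB.

## Worked example

Simulate a planted enhancer — ancestor with 8 motif blocks, two descendants
(motif substitution rate 0.05, spacer rate 0.4), one embedded in a 50 kb
random genome — and scan for it:

```r
library(crescan)
cfg <- evolution_config(background_len = 50000L, rng_seed = 42L)
fx  <- make_planted_fixture(cfg)
fx$truth$enhancer_interval
#> chrSim:[15002,15548)+
res <- scan_genome(fx$query, fx$genome)
res$regions[res$regions$rank <= 2,
            c("seq_id","start","end","score_type","region_score","rank")]
#>  seq_id start   end score_type region_score rank
#>  chrSim 14552 15914       PURE        15699    1
#>  chrSim 36856 39034       PURE          560    2
#>  chrSim 14552 15914       COMB        15699    1
#>  chrSim 36856 39034       COMB          560    2
```

The rank-1 region (both score types) overlaps the planted locus
[15002,15548); its score (15699) is the best window's motif-score sum.  The
rank-2 region is background noise an order of magnitude weaker.  In this
replicate the conserved motifs were close enough for mismatch extension to
bridge the mutated spacers, so the locus is carried by one long motif and
the pattern bonus adds nothing (`COMB == PURE`); with heavier spacer
divergence the enhancer fragments and the co-linear pattern bonus is what
lifts the true locus above the noise (see the methods vignette).

Command-line equivalents:

```sh
Rscript inst/cli/crescan simulate --out fx --background-len 50000 --seed 42
Rscript inst/cli/crescan scan --query fx/query.fa --target fx/genome.fa --out out
Rscript inst/cli/crescan annotate --predictions out/query_enh.predictions.bed \
    --query-anchor chrQ:100000-101000 --query-genes qgenes.bed \
    --target-genes tgenes.bed --orthologs orth.tsv --out class.tsv
```

`scan` writes BED6 (`name = queryID.rank`, integer scores) plus a
full-precision TSV sidecar and a run log recording every effective
parameter.

## Candidate assessment

* `classify_flanking()` labels a prediction by whether orthologs of the
  query locus' flanking genes also flank it (`double_flanked`,
  `single_flanked`, `near_flank`, `not_flanked`, `not_orthologous`), using
  1.5 Mb / >= 5-genes-per-side environments around both loci.
* `random_motif_sets()` + `motif_conservation()` + `compare_conservation()`
  test whether the motifs backing a prediction are more conserved (per-base
  score track in [0,1], bedGraph or wiggle) than random same-length segments
  from the same region (two-sided Wilcoxon rank-sum).

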