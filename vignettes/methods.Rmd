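---
title: "crescan: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crescan: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crescan)
```

## The model and its assumptions

`crescan` scores the similarity of a query enhancer to windows of a target
sequence under a specific evolutionary model: enhancers are clusters of
functional motifs (transcription-factor binding sites and their immediate
context) under purifying selection, separated by spacers that mutate much
faster and may rearrange.  Three consequences drive the design:

* **Mismatch-containing motifs, not exact words.**  Ancestrally related
  motifs accumulate scattered substitutions; seeding on short perfect
  `k`-mers and extending through mismatches recovers them as single units,
  where a fixed-`k` word profile would shatter them.
* **Permutation tolerance.**  `Score_PURE` is an order-free sum over the
  window's filtered motif set, so reshuffled motif arrangements score the
  same as co-linear ones.
* **Co-linearity is still evidence.**  When motifs *do* keep their ancestral
  order and spacing, that arrangement is unlikely by chance; the pattern
  detector adds a bonus (`Score_COMB`) for motifs sharing a diagonal, which
  lifts fragmented-but-co-linear enhancers whose individual motifs are weak.

The motif score `(p*s_p + q*s_q)*(p+q)` multiplies the match/mismatch sum
by the motif length, so a long 90%-identity motif dominates a short perfect
word with the same sum — deliberate, since long imperfect matches are far
less likely by chance.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `s_p`, `s_q` | +1, −1 | per nt | match/mismatch scores for extension and motif scoring.  The published method never prints them; the simplest scheme satisfying "extension stops once accumulated mismatches outweigh matches" is ±1.  Both configurable. |
| `k` | 8 | nt | minimum seed size; also the minimum perfect core a motif must keep to survive overlap truncation. |
| `noise_word_len` | 12 | nt | the noise threshold is the score of a perfect word of this length (144 under ±1).  Shorter words occur in most genomic windows and carry no signal. |
| `window_step_fraction` | 0.25 | — | window step as a fraction of window size (window size = query length, capped at target length). |
| `max_distance` | 200 | nt | largest end-to-start gap (on both axes) between consecutive pattern members. |
| `max_shift` | 25 | nt | semi-minor axis of the elliptical motif spaces: admissible diagonal deviation of pattern members. |
| `mad_multiplier` | 3 | — | region calling at `median + 3*MAD` of the scan's window scores. |
| `top_n` | 25 | — | predictions reported per query and score type. |

## Numerical and procedural choices

**Coordinates.** Internally everything is 0-based half-open (BED
semantics).  Published browser-style coordinates are 1-based inclusive;
`interval_from_printed()` converts, and the bundled
`candidate_regions.tsv` verifies the convention: every printed size equals
`end − start + 1`.

**Extension stop and truncation.**  Each direction's running score starts
at the seed score (`k*s_p`) and extension halts strictly below 0 — with it
seeded at 0 a first mismatch would end every extension, contradicting the
mismatch-bridging purpose.  Each direction is then truncated to the
*shortest* prefix achieving the *maximal* running score, so score ties
resolve to the shorter motif.  The finished motif is rescored with the
length-amplified formula; the length factor plays no role during extension
(it cannot change the sign of the running score, only its magnitude).

**Overlap filtering.**  Rank order is score desc, length desc, axis
coordinate asc, forward before reverse — fully deterministic.  A
lower-ranked motif conflicting with placed motifs keeps its longest
conflict-free stretch, shrunk inward to the next matching nucleotide, and
must retain a perfect core of `k` or is discarded.  Motifs whose score
equals the overlapped motif's placed score are kept unmodified.  Comparing
against the *placed* (possibly truncated) score is what makes the filter
idempotent and guarantees that surviving overlapping motifs have equal
scores; target-axis filtering is global per target record, query-axis
filtering is applied per window on the window's selection (the workflow
extracts windows before query filtering, and a motif may legitimately be
reused by distant windows).

**Windows.**  Step rounds to the nearest integer (minimum 1); if the last
regular window stops short of the target end a flush-right window is
appended so the scan covers the whole target.  A target shorter than the
query is a single window.

**Patterns.**  Only forward-orientation motifs participate: a
query–target shift is ill-defined across orientations.  (Consequence:
`Score_COMB` is not symmetric under reverse-complementing the target,
while `Score_PURE` and the motif profile are — the test suite asserts
exactly that.)  Anchors must score at or above the noise threshold;
sub-threshold motifs can only be recruited.  The ellipse parameters are
not printed in the original description beyond "standard values"; we fix
the foci one window length apart along the anchor's diagonal and the
semi-minor axis at `max_shift`, giving semi-major
`sqrt((L/2)^2 + max_shift^2)`.  This makes full-window-spanning patterns
detectable while bounding shift deviation near mid-span by `max_shift`.
Mean inter-motif distance is measured on target coordinates with members
ordered by query start; chaining enforces `max_distance` on both axes.
`Factor_Shift` can go negative for extreme members under the printed
formula, so weights are clamped to `[0, 1]`, preserving
`Score_COMB >= Score_PURE` everywhere.

**Region calling.**  MAD is raw (no 1.4826 consistency constant) —
the threshold is a rank statistic of the empirical score track, not a
normal-σ estimate.  Membership is strictly `>` threshold: on degenerate
tracks (all scores equal, e.g. a single window or a motif-free target,
where MAD = 0) nothing is called, the conservative reading.  For
multi-record targets the threshold pools all records of one query's scan.
Rank ties break by longer region, then coordinates.

**Flank classification.**  Environments take every gene with TSS within
1.5 Mb of the anchor boundaries and extend to the nearest TSSs when a side
has fewer than five genes.  "Flanking" means nearest TSS on each side;
genes with TSS inside the anchor join the nearer side.  With multiple
orthologs the most favourable placement counts, and the most specific
class wins (double > single > near_flank > not_flanked > not_orthologous).

## What the synthetic generator emulates — and what it does not

`make_planted_fixture()` realizes the assumed world: uniform-random
ancestor (GC 0.5) with 8 motif blocks of 15–25 nt separated by 30–60 nt
spacers; two descendants by independent per-base substitution (motif rate
0.05, spacer rate 0.4); optional block permutation with freshly resampled
spacers (lengths kept, so coordinates are preserved and junctions rarely
seed); embedding in a 100 kb i.i.d. background.  Defaults are the
conditions stated for the recovery properties; the GC and length choices
are ordinary vertebrate-like values fixed once.

It deliberately omits: indels (coordinates would shift without adding test
power to a substitution-driven scanner), repeats and compositional
heterogeneity (real genomes produce far more noise seeds; soft-masking
support exists but the generator does not emulate repeat families),
realistic substitution matrices, and phylogenies deeper than one
ancestor–two-descendant split.  A green recovery test therefore
establishes that the pipeline finds conserved-motif structure over random
background at the stated rates — not performance on real repeat-rich
genomes.

One observed regime is worth noting: at spacer substitution rate 0.4 the
two descendants still agree on roughly a third of spacer positions, so
mismatch extension often bridges 30–60 nt spacers and the planted enhancer
is recovered as one long motif (pattern bonus unused).  The junction-safe
fixtures used for the permutation-exactness tests force extension to stop
at block boundaries instead; both regimes are exercised.

## Known limitations

* Seeding is hash-based but extension and filtering are plain R; scans are
  comfortable at the tens-of-kilobases-per-target scale of the test suite,
  not chromosome scale.
* No gapped extension or spaced seeds; a motif bisected by an indel is
  recovered as two motifs (and may then need the pattern bonus to count).
* No significance estimate for predictions — ranks and the MAD threshold
  are the only calibration, and the threshold is relative to each scan's
  own score distribution.
* Pattern detection is greedy (strongest anchor first), not optimal
  chaining; and reverse-orientation motifs never form patterns.
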