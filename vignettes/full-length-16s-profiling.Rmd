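---
title: "Full-length 16S rRNA nanopore profiling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-length 16S rRNA nanopore profiling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagitax)
```

## The problem this package addresses

Low-diversity microbiomes — the vaginal community is the canonical example —
are dominated by a handful of closely related species (often congeneric
*Lactobacillus*), so the clinically interesting question is usually *which*
species dominates, not merely which genera are present. Short 16S amplicons
(V3–4, ~0.4 kb) frequently cannot separate such species, while nanopore
long reads cover the full-length gene (V1–9, ~1.5 kb) at the price of a high
per-base error rate. `vagitax` implements the complete analysis path for this
setting: read filtering, host-read removal, per-read best-hit classification
against a reference panel, composition and diversity summaries, and
phylogenetic ordination — plus a deterministic simulator so every stage is
verifiable without any external download.

## The workflow and its assumptions

A sample moves through fixed stages, in this order:

1. **Quality/length filter.** A read passes when its mean quality is at
   least `min_q = 7` and its length falls in the closed region window
   (V1–9: 1300–1950 bp; V3–4: 350–600 bp). Mean quality is the Phred
   transform of the *average error probability*,
   $Q = -10\log_{10}\bigl(\tfrac1L\sum_i 10^{-q_i/10}\bigr)$, which is the
   convention behind a basecaller's pass/fail split; the arithmetic mean of
   Phred scores would be systematically higher (Jensen's inequality).
2. **Low-complexity masking.** A greedy tandem-repeat masker (periods 1–10,
   runs ≥ 15 bp) replaces repeats with `N` before alignment; `N` never
   matches during scoring. This is a simplified stand-in for probabilistic
   repeat maskers: the pipeline needs repeat *suppression*, not
   bit-compatibility with any particular tool. Reads that end up ≥ 90% `N`
   (`mask_discard_fraction = 0.9`) are dropped — such reads carry no
   taxonomic signal. Rejections are counted with fixed precedence
   (quality → length → mask) so the category counts are deterministic and
   always partition the input.
3. **Host screening.** A read is discarded as host when its best local
   alignment against a host panel reaches 70% of its perfect-match score —
   i.e. a near-full-length, high-identity hit. Host removal precedes
   bacterial classification.
4. **Subsampling.** Classification is performed on a seeded uniform random
   subsample (default 3000 reads). Subsampling runs *after* filtering and
   host screening but *before* alignment, so no alignment work is wasted
   and the analysis depth is exactly the target.
5. **Best-hit classification with even tie allocation.** For each read the
   score of every candidate reference is computed; the score of a *taxon*
   is the maximum over that taxon's references. The read's unit weight is
   split evenly, $1/k$ to each of the $k$ taxa attaining the top score; if
   the top score is below `min_score_frac = 0.4` of the perfect-match score
   the read is unclassified. Taking the per-taxon maximum *before* tie
   detection means a taxon with many redundant (e.g. strain-level)
   references can never absorb tie mass, and it fixes the strain-collapse
   question: strains collapse to their species before selection.
6. **Composition, diversity, ordination.** Weights are rolled up to the
   reporting rank (conserving fractional mass exactly), taxa below 1% are
   pooled into "Others" (strictly below — a taxon at exactly 1% is kept),
   Shannon diversity $H = -\sum p_i \ln p_i$ is computed on the *un-grouped*
   profile (grouping distorts $H$), and samples are compared by weighted
   UniFrac followed by classical PCoA.

## Alignment scoring

The built-in scorer is Smith–Waterman with affine gaps (match +2,
mismatch −4, gap open −4, gap extend −2; a gap of length $L$ costs
$4 + 2(L-1)$), evaluated in compiled code, score-only. Both strands are
considered. Because exhaustive alignment of every read against every
reference is wasteful, a minimizer prescreen (canonical k-mers, k = 15,
window 10 — chosen to mirror a long-read mapper's defaults in spirit)
selects up to 20 candidate references per read, pruned to those sharing at
least a quarter of the top candidate's shared-minimizer count. At 16S-scale
divergences this prune is conservative: references of the wrong genus share
well under a quarter of the top count, while same-genus (potentially tied)
references share nearly all of it, so the prune cannot change a best-hit
outcome; setting `min_shared_frac = 0` restores the plain top-20 behaviour.
The read's strand is resolved once per read — both strands against the top
candidate, the winning orientation for the rest — because a read has a
single true orientation and strand score differences dwarf inter-reference
differences.

Alternatively, precomputed alignments can be supplied as PAF
(external-mapper mode): scores are then taken from the `AS:i` tag when
present, falling back to the residue-match column. The mapper's score field
is not standardised across tools, so both sources are supported and the one
used is recorded. Integer built-in scores tie only when exactly equal;
external floating-point scores tie within 1e−9.

`min_score_frac = 0.4` is permissive enough for 10–15% read error (a read
at 10% error against its true reference still scores ≈ 0.7 of perfect) and
strict enough that random sequence (expected per-base score < 0) never
reaches it; the tests verify both directions against a brute-force dynamic
programming oracle and a random-sequence null.

## Weighted UniFrac and PCoA

Raw weighted UniFrac between samples $A$ and $B$ over a rooted tree with
branch lengths $l_b$ is $\sum_b l_b\,|P_A(b) - P_B(b)|$, where $P_X(b)$ is
the fraction of sample $X$ descending from branch $b$. The normalized
variant divides by $\sum_j d_j (p_{Aj} + p_{Bj})$ ($d_j$ = root-to-leaf
path length), bounding it in $[0,1]$; normalized is the default and the
choice is recorded in the distance-matrix metadata. The tree is an explicit
input (the fixture generator produces one; users may supply any rooted
Newick) — the package never invents a phylogeny silently, and it refuses
profile bins that are not tree leaves rather than dropping them.

PCoA is classical metric scaling: eigendecomposition of
$B = -\tfrac12 J D^{(2)} J$. Negative eigenvalues (non-Euclidean input) are
clamped to zero for coordinate scaling but reported, and they are excluded
from the proportion-explained denominator; no Cailliez correction is
applied — simple, standard, and testable against `stats::cmdscale`.

## In-silico PCR

The two built-in primer sets are the inner primers of a four-primer
amplification strategy (anchored full-length V1–9 and V3–4 pairs). Matching
is IUPAC-aware — a degenerate primer position never counts as a mismatch
when the template base is in the code's set — with up to 3 mismatches per
primer by default (tolerant of reference variation, yet random 17–20-mers
essentially never match; the tests check both). When several sites pair,
only the minimal-length product per forward site is emitted (PCR favours
short products, and this keeps output deterministic). Whether reported
product sizes include the anchor tails is explicit in the output
(`includes_anchors`).

## What the simulator emulates — and what it does not

`make_reference_fixture()` builds a 10-genus (by default) panel of 1550-bp
16S-like sequences with primer cores embedded at canonical positions,
giving a 1534-bp V1–9 product and a 465-bp V3–4 product — inside the filter
windows and close to the ~1.6 kb / ~0.4 kb products of the real assay.
Pairwise inter-genus divergence is ~0.15 and intra-genus divergence 0.02,
roughly the 16S separation of distinct genera versus congeneric species.
`simulate_reads()` draws source taxa from a stated abundance vector,
applies per-base substitutions/insertions/deletions (defaults 3%/2%/3%,
~8% total — realistic for basecalled long amplicon reads), emits qualities
with mean Q14 at match positions and Q8 at error positions, and assigns
each read a random strand. Anchor tails are included so local alignment,
strand handling and the length filter are exercised as on real reads.

Deliberate unrealisms, so that passing tests are interpreted correctly:

* mutations avoid the primer-core spans, so every species remains
  amplifiable by construction;
* read-length jitter comes only from indels — there is no fragmentation or
  chimera model (observed filtered read lengths sit close to amplicon
  length, so fragmentation is second-order for this purpose);
* no homopolymer-specific error structure; error positions are i.i.d.;
* the backbone is random sequence, not a real 16S alignment — conserved
  regions, secondary structure and real database redundancy are absent.

Consequently, recovery results on simulated data demonstrate the
*pipeline's* correctness (filtering, tie allocation, roll-up, thresholds),
not classification performance on any real reference database.

`make_v34_confusable_pair()` constructs the species-resolution contrast
deliberately: two congeneric species identical across the whole V3–4
amplicon but ≥ 5% divergent over the rest of the V1–9 span. Error-free
V3–4 reads from either species therefore tie exactly and are split 0.5/0.5,
while V1–9 reads carry full weight on the true species — the mechanism
behind the short-amplicon ambiguity among closely related species.

Determinism: one global integer seed; each stage derives its own stream
seed by a fixed rule, so adding a downstream stage never perturbs the draws
of earlier stages, and every result is bit-reproducible under the same
seed.

## Numerical and boundary choices

* Length windows are closed intervals ("1300 to 1950" reads as inclusive).
  The V3–4 extraction window is 350–600 bp by default; descriptions of
  similar assays also quote 300–650 bp, so the window is a config field
  rather than a constant.
* The "Others" boundary is strict (< 1%); exactly 1% is retained.
* Unclassified reads stay in the composition denominator by default (a
  flag flips this), so reported fractions are fractions of analysed reads.
* Roll-up walks transparently through "no rank" nodes and conserves
  fractional mass to within one ulp; tie weights are never re-rounded.
* Phred+33 is the only accepted FASTQ encoding; Phred+64 input fails
  loudly rather than being auto-detected (silent auto-detection hides
  corruption).
* All internal coordinates are 0-based half-open; conversion happens only
  at format boundaries (PAF stays 0-based half-open end to end).
* Whether masked reads should be discarded outright or only soft-masked
  is exposed via `mask_discard_fraction` (default keeps reads under 90%
  masked), since either behaviour is defensible.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely on generated data at
desk scale, chosen to exercise every stage meaningfully: a 10-reference
panel, 3000-read mock-community recovery (the per-sample analysis depth of
the workflow), 60–200-read batches for per-module checks, and cohorts of
6–8 samples for the ordination properties. A full 3000-read sample
processes end to end in about two minutes on one CPU.

## Known limitations

* The built-in aligner is score-only: no CIGAR, no coordinates, so PAF
  export of built-in results carries nominal full-length spans.
* The minimizer prescreen is exact-match based; at divergences far beyond
  ~25% the candidate list may miss distant homologs (irrelevant for
  within-database 16S classification, where the concern is the opposite).
* UniFrac requires every profile bin to be a tree leaf; profiles containing
  display bins ("Others", "unclassified") must be renormalised first
  (`run_cohort()` does this automatically).
* No chimera detection, no adapter/barcode trimming (assumed done
  upstream), no strain-level reporting below the species rank.
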