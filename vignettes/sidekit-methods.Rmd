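---
title: "Methods: discovering and dating short internally deleted elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and dating short internally deleted elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Non-LTR retrotransposons (LINEs) of the CR1 clade occasionally give rise to
short internally deleted elements (SIDEs): nonautonomous derivatives that
keep the LINE's 5' end (which carries the internal promoter) and its 3' end
(the recognition site for the LINE-encoded reverse transcriptase) around a
short, non-homologous central region. Because a SIDE can be transcribed and
mobilised by its partner's machinery, SIDE and LINE copy numbers and
replication histories are expected to track each other. `sidekit`
implements the complete desk-scale analysis for such a system: finding the
elements, rebuilding their consensus sequences, annotating the SIDE's
architecture, counting and dating copies, and testing the cross-genome
copy-number association — all validated against a generator that plants a
known truth.

## Homology search

The scanner is a seed-and-extend local aligner standing in for blastn:

* exact 11-mer seeds between query and genome, hashed in 2-bit encoding;
* seeds grouped by diagonal (`subject - query` offset, tolerance 50 bp,
  subject-gap tolerance 1 kb), so each candidate locus is extended once;
* banded affine-gap Smith-Waterman extension (band = the cluster's diagonal
  range +/- 60) under the classic DNA scheme +1/-2, gap open -5, extend -2,
  where a gap of length L costs `gap_open + L * gap_extend`;
* both strands searched by reverse-complementing the query, with hits
  always reported in forward genome coordinates and forward query
  orientation; overlapping claims (e.g. from the two strands) keep the
  higher score, exact ties keep the plus strand.

Tie-breaking inside the DP is deterministic (lowest start on the query,
then on the subject), so results are bit-reproducible. The exhaustive,
unbanded DP is retained as the test oracle; the band never changes a result
in the tested regimes because substitution-only divergence keeps optimal
alignments within a few diagonals of their seeds.

Significance uses the Karlin-Altschul form `E = K m n exp(-lambda S)`. For
+1/-2 the ungapped solution at uniform composition is
`lambda = ln((3 + sqrt(21))/2) ~ 1.3328`, with `K ~ 0.62`; these are the
defaults, and `calibrate_karlin()` re-fits both by the method of moments on
the Gumbel law of shuffled-pair maximum scores
(`sd = pi/(lambda sqrt 6)`, `mean = (ln(K m n) + gamma)/lambda`) for other
schemes. The published threshold is printed as "e-value > 1e-10" in the
source material's methods; that direction would discard significant hits,
so it is implemented as `E <= 1e-10` (and `1e-5` for the protein-level
stage, which is emulated at DNA level against the ORF rather than through a
six-frame translated search).

## Consensus reconstruction

The two-round repeat-library procedure:

1. search with a seed query (a single recovered copy);
2. rank hits by score, keep those spanning >= 90% of the query
   ("full-length" is undefined in the source; 90% is standard repeat-library
   practice and configurable), take the top 50, and build a majority-rule
   consensus;
3. re-search exhaustively with that consensus and rebuild the consensus
   from *all* significant hits.

The multiple alignment behind the profile is anchored pairwise: each copy
is locally aligned to the current consensus and its bases are projected
onto consensus columns. Insertions relative to the consensus are counted
but excluded, so coordinates are stable within a round (growth can only
happen by re-seeding); deletions contribute gap counts. Majority voting
takes the most frequent base per column, removes columns where gap is the
strict majority, and breaks base ties by the fixed order A < C < G < T — a
strict-DNA alternative to IUPAC ambiguity codes that keeps every downstream
consumer simple. Tie counts are logged. "First 50 hits" is read as
top-scoring 50 (the plausible alternatives, encounter order, would make
results depend on genome coordinates).

Consensus validation uses the longest six-frame ATG-to-stop ORF as a proxy
for reverse-transcriptase coding capacity (default threshold 300 aa; the
intact simulated LINE carries a 1,019 aa ORF, and any internal deletion
destroys it). No profile database is consulted.

## Structural annotation

* **Homologous blocks.** The two highest-scoring collinear local alignments
  of SIDE against LINE, anchored within 10 bp of the SIDE's termini (the
  poly-A tail may extend past the 3' block). Identity is
  `100 * matches / gap-free columns` — gap columns are excluded from both
  numerator and denominator, the common ungapped-identity convention,
  stated explicitly because the source never defines its formula.
* **Poly-A tails.** Longest 3'-terminal run of the target base allowing at
  most one non-target base per 10 most recent positions; the tail must
  start and end on the target base and reach 5 bp. The same detector with
  `base = "C"` reports the poly-C stretch that terminates the 5' homology
  block.
* **Target-site duplications.** Exact duplicated word with its right edge
  at the insertion start and left edge at the insertion end, 2-20 bp.
  Exactness is deliberate (the motivating observation is an exact (T)6);
  detection therefore requires exact insertion boundaries, and callers
  working from alignment-trimmed copy boundaries should scan a few bp of
  slack (stage 4 of the analysis does).
* **Breakpoint microhomologies.** All words of length 3-12 present near
  both deletion breakpoints. The windows straddle each breakpoint by one
  word length (`[start - 15, start + k)` and `[end - k, end + 15)`) rather
  than sitting strictly outside the deleted interval: under template-jump
  (copy-choice) deletion one repeat copy is retained in the product, which
  places the other copy flush against a breakpoint, half a phase inside
  the deleted coordinates. Strictly one-sided windows would never see that
  geometry.
* **Logos.** Per-position base frequencies with information content
  `2 + sum(f log2 f)` bits.

## Copy counting and divergence landscapes

Because SIDE and LINE share their ends, each family's consensus cross-masks
the other's copies. The ambiguity filter drops fragments spanning less than
160 bp of genome — shorter than the shared blocks' alignable span — leaving
fragments unambiguously attributable to one family; 160 is inclusive
("exclude < 160"), and 250 is the documented stricter variant. Filtering
precedes merging.

Defragmentation chains consecutive fragments that share family and strand,
resume within 20 bp of where the previous fragment ended in consensus
coordinates (strand-aware), and sit within `merge_max_gap` plus the
consensus-coordinate gap of each other on the genome. The published
defragmentation tool is cited without parameters in the source; the base
gap default here is 500 bp rather than the 50 bp a first reading might
suggest, because the only process that fragments a copy — a nested
insertion by another element — separates the fragments by that element's
full length, and a 50 bp allowance could never rejoin them.

Per copy, the mismatch proportion `p` is pooled over gap-free aligned
columns of its fragments and corrected for multiple hits with the
Jukes-Cantor distance `d = -(3/4) ln(1 - 4p/3)`; `p >= 0.75` is saturation
and such copies are flagged and excluded from landscapes. Landscapes bin
`d` at 0.01 substitutions/site (the resolution of typical
activity-through-age plots), recording copy counts and summed bp; bin
totals conserve total matched bp. Low-divergence bins are the most recent
replication activity — no calendar dating is attempted, as that would
require a substitution-rate calibration out of scope here.

Cross-genome association of SIDE and LINE copy numbers uses Spearman rank
correlation — real copy-number tables span four orders of magnitude, which
rules out plain Pearson — with an exact permutation p-value (all `n!`
permutations) for `n <= 8` and 10,000 seeded Monte-Carlo permutations
otherwise, two-sided.

## The synthetic world

`plant_copies()` generates the stated scenario: a 2 Mb i.i.d. background at
GC 0.375 (lepidopteran-like), 150 LINE and 300 SIDE copies. The LINE master
is ~3.3 kb — 100 bp 5'-UTR, one 1,019 aa ORF, 100 bp 3'-UTR, poly-A tail —
matching the ~3.3 kb full-length elements real surveys report; the SIDE
master is 360 bp (120 bp 5' block + 100 bp variable region + 140 bp 3'
block), inside the 263-386 bp range of real SIDE families. A 9 bp poly-C
stretch and the AGGCC direct repeat are planted at the future deletion
flanks (codon-aligned, with any planting-induced stop codon repaired
outside protected bases), and the SIDE retains exactly one repeat copy, as
template jumping predicts. Copies are aged by per-site substitution at
`p_sub = (3/4)(1 - exp(-4d/3))` with `d ~ N(0.05, 0.01)` floored at zero —
a single replication burst; the truncated-normal mixture is the simplest
generative stand-in for graphically reported bursts, and the defaults are
one component. Half the LINE copies are 5'-truncated with geometric depth
(mean 500 bp, capped at 90%); SIDEs are not truncated (the truncation
hallmark belongs to CR1 LINEs, and a truncated 360 bp element would mostly
fall below the ambiguity filter anyway). Ten percent of copies are split by
a 300 bp unrelated nested insertion; insertions carry 4-8 bp target-site
duplications copied from host-like sequence; per-copy poly-A tails are
redrawn from 8-18 bp. Copies are spaced by at least 600 bp of background so
planted intervals stay unambiguous. Everything is reproducible from one
seed.

What the generator does **not** emulate — and therefore what a green test
does not establish: no indel process inside copies (so `p` and `d` relate
exactly; indel-bearing copies are exercised by dedicated fixtures), no
nested TE graphs beyond the single fragmentation insert, no selection or
insertion-site preference, no GC heterogeneity or low-complexity regions,
and no subfamily structure. Recovery results on this world are a
correctness check of the pipeline, not a claim about sensitivity on real
genomes.

## Numerical choices and edge cases

* Coordinates are 0-based half-open everywhere internally; BED export is
  native, GFF3 converts to 1-based inclusive.
* Minus-strand hits are stored in forward genome coordinates with a strand
  flag; query coordinates always refer to the forward query orientation.
* The scanner's e-value uses the summed genome length as `n`.
* `jukes_cantor` raises a domain error at `p >= 0.75` rather than returning
  infinity; pipeline callers flag and exclude such copies.
* The burst mean 0.05 of the default world sits exactly on a landscape bin
  edge, so the two adjacent bins carry near-equal mass and the *modal* bin
  of each family is decided by sampling noise. Peak-coincidence checks are
  therefore made at one-bin resolution, with the sharper statement — the
  family median divergences agree to half a bin — tested on the exact
  scale.
* Degenerate annotator inputs are defined: a SIDE identical to its LINE
  yields a single spanning block and no variable region, and deletion
  inference then errors (there is no internal deletion); insertions at
  contig edges yield no TSD call with a warning.

## Limitations

The aligner has no low-complexity masking, no gapped e-value theory beyond
the Karlin-Altschul approximation, and the protein-level search stage is a
DNA-level emulation. Consensus building cannot grow beyond its reference
within a round. TSD detection is exact-match by design. None of the
phylogenetic analyses downstream of the exported alignments (tree
inference, subfamily splitting) are in scope; alignments and consensuses
are exported for external tools.
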