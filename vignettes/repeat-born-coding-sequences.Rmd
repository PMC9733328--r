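---
title: "Models and methods: coding sequences born from trinucleotide repeats"
author: "cagevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: coding sequences born from trinucleotide repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagevol)
```

## The scientific problem

New protein-coding genes occasionally arise with no ancestral protein-coding
sequence at all. One documented route runs through two common mutational
mechanisms: an LTR retrotransposon insertion donates an oocyte-active
promoter, a first exon, a splice donor and an AUG; and a downstream
trinucleotide repeat — `(CAG)n` — expands, erodes and duplicates until a long
open reading frame exists. This package implements the quantitative analyses
that make that account testable: the codon-level combinatorics that explain
*why* such an ORF survives point mutation in some reading frames and not
others, sequence-level detectors for the repeat tracts, reading-frame
structure and internal duplications of such a CDS, alignment-level statistics
for the donating LTR family, and a forward simulator of the whole process.

A `(CAG)n` run encodes polyglutamine read as `CAG`, polyserine read as
`AGC`, and polyalanine read as `GCA`. Under the standard genetic code the
stop codons are TAA, TAG and TGA. The exact Hamming distances from each frame
codon to the nearest stop are

```{r}
min_mutations_to_stop_per_frame("CAG")
```

so a single point mutation can create a stop only in the polyQ frame
(C→T in codon position 1, giving TAG), while the polyS and polyA frames are
buffered by at least two mutations. Two simultaneous hits on CAG reach a stop
in `1/27` of the equiprobable outcomes:

```{r}
stop_fraction("CAG", distance = 2)
```

These numbers are computed by exhaustive enumeration
(`enumerate_point_mutants()`), never tabulated by hand, and the test suite
checks all 64 codons at distances 1–3 against an independent brute-force
enumerator. One documentation note: the six amino acids reachable from the
serine codon by single mutation without any stop (Gly, Arg, Cys, Asn, Thr,
Ile) identify the codon `AGC` — the polyS reading of the repeat — and we
anchor to it; `ACG` (a threonine codon with the same letters) also reaches
six amino acids and no stop, but a different set, and both are supported by
the same functions.

### Mutation weighting

`stop_fraction()` is unweighted by default — all outcomes equiprobable, which
is the convention behind the 3.7% figure. Passing `kappa` reweights the
target bases by a transition/transversion ratio: each mutated site chooses a
transition with weight `kappa` and each transversion with weight 1,
normalised per site. The same `kappa` enters the simulator and the
closed-form hazard `stop_gain_hazard()`, which for the polyQ frame equals
`mu * kappa / (kappa + 2)` per codon per generation (`mu/3` when unbiased).
We do not model CpG hypermutability or codon-usage weighting.

## Repeat tract detection

`find_repeat_tracts()` is a greedy seed-and-extend detector for eroded
trinucleotide tracts. Its parameters: `unit` (the 3-mer), `min_units`
(default 3 reported units) and `max_divergence` (default 0, the running
mismatch budget in `[0, 0.5)`). The algorithm:

1. **Seeds** are exact two-unit matches of any rotation of the unit,
   overlapping occurrences included.
2. **Extension** proceeds one 3-nt window at a time in both directions while
   the cumulative mismatched bases over bases covered stay within
   `max_divergence`; a window mismatching at ≥2 of its 3 positions always
   terminates extension.
3. **Merging:** extents from all seeds and registers that overlap are merged
   — register-shifted extensions describe the same tract with boundaries
   offset by 1–2 nt, so they are one candidate, not competitors.
4. **Register vote:** within a merged span, the register (window offset ×
   rotation) is chosen to minimise the number of ≥2-mismatch windows, then
   to maximise exact windows. The rationale: erosion by point mutation hits
   each unit at most once per event, so the true register of an eroded tract
   shows only 0- or 1-mismatch windows, whereas a shifted register turns two
   adjacent eroded units into one 2-mismatch window.
5. **Re-delimiting:** boundaries are recomputed by walking outward from the
   longest exact-window run under the same running budget, then at most one
   single-mismatch terminal window per side is trimmed — a lone mismatching
   terminal window is as likely to be flank as repeat, and trimming one
   bounds the boundary error at one unit either way.

The reported `unit` is the lexicographically minimal rotation, `phase` the
offset of the first canonical unit, and `purity` the fraction of exactly
matching unit windows. Properties verified in the suite: a planted
`(CAG)30` tract with per-unit erosion up to 0.2 inside repeat-free flanks is
recovered with both boundaries within one unit in 200/200 seeded replicates.
That test builds flanks from pyrimidines only: with fully random flanks a
chance `CAG` immediately adjacent to the tract makes the planted boundary
ill-defined as ground truth (the detector legitimately extends into it),
which is an ambiguity of the truth labels, not an error of the detector —
and correspondingly real-genome boundaries of eroded repeats carry an
inherent uncertainty of a unit or so.

## Frame classification and the CDS report

`classify_codon_frames()` labels each codon by minimal Hamming distance to
the three unit rotations, assigning a frame only when the minimum is ≤1 and
unique; ties are a conservative `"other"`, and codons containing N are
`"undetermined"`, never translated silently. The one-mismatch threshold
matches the dominant erosion mode (one point mutation per codon); it is our
decision, as no published threshold exists for this kind of per-codon frame
track. `n_switches` counts transitions between repeat frames across adjacent
runs — the frameshift events that, in real repeat-born proteins, are rare
within a species group and visible as one major polyS→polyA switch.

`repeat_frame_report()` additionally counts stop codons when the same
nucleotides are read in each of the three registers, mapping registers to
frame names through the phase of the longest detected tract, and
`cds_report()` joins this with ORF inference: transcripts are assembled by
`splice_transcript()` (exons extracted from BED-style 0-based half-open
intervals; minus-strand models reverse-complemented at extraction; GT..AG
checked per intron on the transcribed strand, non-canonical introns flagged
but kept), and `find_orf()` scans for the first AUG or translates from a
caller-designated offset. Both policies exist because the LTR-donated start
is a tandem `AUGAUG`, and probing the second AUG requires a fixed offset.
Unterminated ORFs are reported with `terminated = FALSE` rather than
discarded, since truncated assemblies (N blocks) occur in real genomes.
Isoform choice is the caller's input: where a locus has several promoters the
analysis is per-transcript.

## Duplication decomposition

Coding sequences of repeat-born genes grow partly by repeat expansion and
mostly by internal segmental duplication. `self_alignment_blocks()` finds
direct (same-strand) duplicated segments by exact 12-mer seeding off the main
diagonal and ungapped X-drop extension (match +1, mismatch −3, drop 12,
trimmed back to the best-scoring endpoints), keeping blocks of length ≥
`min_len` (default 24 nt) and identity ≥ `min_identity`. The X-drop with
trim-back matters: extension under a plain running-identity threshold
overshoots breakpoints by several bases into random flank before the average
dips, while the best-scoring endpoint sits at the true boundary. Seeding
(not extension) is masked inside pure repeat tracts when `mask_unit` is
given, because a pure `(CAG)n` is trivially self-similar at every multiple-
of-3 lag; a window is unseedable only when it lies entirely inside a pure
tract, so eroded positions still seed. Gapped alignment and inverted
duplications are out of scope — observed blocks in the motivating locus are
contiguous direct copies.

On a planted duplication (≥48 nt, identity 1) in non-repeat background the
suite requires breakpoint recovery within 3 nt in ≥95 of 100 seeded cases.
Inside an eroded repeat the background itself aligns at ~90% identity at any
in-frame lag, so there exact breakpoints are not identifiable by any method;
the corresponding test checks that a block on the true diagonal covers the
planted copies. `tile_decomposition()` converts blocks into non-overlapping
labelled tiles (longest block first, later blocks trimmed), with uncovered
positions reported as `unexplained`; tiles plus unexplained intervals always
partition the sequence.

## LTR-family statistics

For a gapped alignment of element copies against a family consensus
(`family_alignment`, first record the consensus unless named), the
nucleotide exchange rate of `column_exchange_rates()` is the per-consensus-
position fraction of informative copies differing from the consensus base.
"Informative" excludes gaps and Ns from that position's denominator —
deletion-bearing copies drop out of affected windows naturally — and
positions with no informative copy are flagged undefined rather than
reported as zero. This is the simplest definition consistent with a
per-position divergence profile; indels are not counted as mismatches.

`motif_presence()` and `motif_cooccurrence()` implement start-codon censuses:
fractions of copies carrying a motif at consensus-mapped windows, with
copies gapped in a window excluded from numerator and denominator, and the
two-window census reported as exclusive categories (A-only, B-only, both)
plus marginals, on the copies informative at both windows, so
`at_least_one = a_only + b_only + both` holds exactly. Exclusive categories
were chosen because published censuses of this form (14% + 29% + 15% = 58%)
are additive.

## The evolution simulator

`evolve()` advances a sequence one generation at a time under three event
types, reflecting the mutational triad that shapes repeat-born CDSs:

- **substitution:** every site independently with probability `mu`
  per generation, target base drawn with transition/transversion weight
  `kappa`;
- **slippage:** with probability `sigma`, one ±1-unit event (insertion
  probability `ins_prob`, default equiprobable) at a uniformly chosen unit
  boundary inside a tract detected at event time
  (`max_divergence = 0.1`) — slippage is replication-mediated and confined
  to repeats;
- **duplication:** with probability `delta`, a uniformly chosen segment of
  length uniform on `dup_len` is copied to the position immediately after
  its source.

At most one slippage and one duplication occur per generation; this is the
simplest generative model in which the three rates stay interpretable
per generation. All rates are illustrative parameters — the underlying
biology fixes no quantitative values — and defaults are labelled as such.
Every event is logged, and `replay_events()` reproduces any snapshot
byte-exactly from the log (a tested invariant). Replicate `r` is seeded with
`seed + r`, making trajectories reproducible and embarrassingly independent.

Stop-codon gain is tracked in the register of the longest pure tract of the
initial sequence. The first generation at which each frame's reading of the
tracked region contains a stop is recorded (first passage, so
`frame_survival()` is monotone non-increasing); insertions of
non-multiple-of-3 length inside the region mark the replicate frameshifted,
reported separately — unit slippage never frameshifts. In the single-hit
regime (`mu · generations ≪ 1`, no indels) polyQ survival of an initially
pure `(CAG)n` locus follows `exp(-n (mu/3) t)`; the suite checks a
1,000-replicate run of `(CAG)60` at `mu = 0.001` over 100 generations
against this form within 3 Monte-Carlo standard errors at the recorded
(every 10th) generations, and — a sharper check — against the exact
64-state codon Markov chain with absorbing stops, which also quantifies how
the single-hit form drifts optimistic by `t = 100` (about 0.02 in absolute
survival) as eroded codons leave the one-step-from-TAG state.

## Synthetic data and what passing tests mean

All inputs the pipeline consumes can be generated with planted truth:
`gen_ltr_family()` (per-position substitution rates, optional gap deletions,
motif-carrier categories assigned deterministically in `exact_fractions`
mode — the first ⌊f·n⌋ copies per category — so census tests are exact,
or sampled for statistical tests), `gen_repeat_cds()` (framed repeat body,
per-codon erosion rejected if it would stop the chosen frame, codon-aligned
planted duplications with final-coordinate breakpoints), and
`gen_transcript_locus()` (spliced toy locus with a planted `ATGATG` start
and ATG-scrubbed upstream sequence). Every generator is a pure function of
its parameters and seed.

The generators emulate the *structure* of real data — divergence profiles,
motif carriage, erosion, duplications, splice sites — not its full texture:
no CpG effects, no indel-rich alignments beyond simple deletions, no
assembly gaps except explicit Ns, uniform base composition. Tests passing on
these inputs demonstrate the algorithms' contracts and calibration, not
performance on any particular genome assembly.

## Numerical and scale choices

Intervals are 0-based half-open throughout (BED convention), with
`to_onebased()`/`to_zerobased()` as exact inverses for reports. Floats in
TSV/JSON output are fixed at 6 significant digits so identical analyses are
byte-identical. Test problem sizes were chosen to exercise the claimed
regimes at desk scale: all 64 codons exhaustively; 100-copy families
(binomial SE ≈ 0.05 at worst); 20 replicate families for rate recovery
(6,000 position checks); 1,000 simulator replicates (MC SE ≤ 0.016);
100 duplication seeds. The full suite runs in under two minutes.

## Known limitations

- Tract detection assumes 3-nt units; other unit lengths are not supported.
- Duplication detection is ungapped and direct-orientation only; a
  duplication that has since suffered an indel will be reported as two
  blocks.
- The simulator has no selection and no population: it models a single
  lineage's neutral sequence trajectory.
- Exchange-rate profiling requires a trusted alignment and consensus; it
  does not build either.
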