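# cagevol

Analyses of how protein-coding sequences are born from expanding
trinucleotide repeats.

A `(CAG)n` repeat can be read in three frames, encoding polyglutamine (CAG),
polyserine (AGC) or polyalanine (GCA) homopolymers. The three frames are not
equal in the face of point mutation: under the standard genetic code a single
point mutation can create a stop codon **only** in the polyQ frame (the C→T
change giving TAG), while single hits in the polyS and polyA frames are
either silent or missense. Even two simultaneous hits on a CAG codon create a
stop in only 1/27 ≈ 3.7% of outcomes. A repeat-derived open reading frame
therefore erodes towards diversity while, in the serine and alanine frames,
remaining remarkably stop-free — a mechanism by which an
LTR-retrotransposon-supplied promoter, first exon and AUG can stochastically
acquire a real protein-coding sequence. This package implements the
computational side of that story for loci like the murine oocyte gene built
on an MTD LTR insertion and a CAG repeat:

- **codon mutation space** — exhaustive point-mutant enumeration,
  silent/missense/nonsense classification, stop-gain fractions
  (optionally transition/transversion-weighted), per-frame minimum mutations
  to a stop (`enumerate_point_mutants()`, `amino_reachability()`,
  `stop_fraction()`, `min_mutations_to_stop_per_frame()`);
- **repeat frames** — detection of eroded repeat tracts (seed-and-extend
  with a running mismatch budget), per-codon polyQ/polyS/polyA frame
  classification, amino-acid composition, per-register stop counts
  (`find_repeat_tracts()`, `classify_codon_frames()`,
  `repeat_frame_report()`);
- **CDS inference** — spliced-transcript assembly from a genome plus a
  BED-style exon model with GT..AG splice checking, ORF finding under
  first-AUG or fixed-offset policies, and a joint CDS report including
  repeat content downstream of the stop (`splice_transcript()`,
  `find_orf()`, `cds_report()`);
- **duplication decomposition** — ungapped self-alignment (12-mer seeds,
  X-drop extension) resolving a coding sequence into duplicated blocks and a
  tiled decomposition, with repeat masking of the trivial self-similarity
  (`self_alignment_blocks()`, `tile_decomposition()`);
- **LTR family profiling** — per-position nucleotide exchange rates of
  element copies against their consensus and motif presence/co-occurrence
  censuses such as "which copies retain the first AUG, the second, or both"
  (`column_exchange_rates()`, `motif_presence()`, `motif_cooccurrence()`);
- **evolution simulator** — a generational model of a repeat locus under
  point substitution, unit slippage and segmental duplication, with
  replayable event logs and per-frame ORF survival curves (`evolve()`,
  `frame_survival()`, `stop_gain_hazard()`);
- **synthetic data** — seeded generators with planted ground truth for every
  input class: LTR families with known rate profiles and motif-carrier
  fractions, eroded repeat CDSs with planted duplications, and small spliced
  gene loci (`gen_ltr_family()`, `gen_repeat_cds()`,
  `gen_transcript_locus()`).

## Worked example

```r
library(cagevol)

stop_fraction("CAG", distance = 2)
#> [1] 0.03703704

min_mutations_to_stop_per_frame("CAG")
#> polyQ polyS polyA
#>     1     2     2

amino_reachability("AGC", 1)$amino_acids
#> [1] "C" "G" "I" "N" "R" "T"
```

One point mutation suffices to stop the polyQ frame; the serine frame needs
two, and its nine single mutants reach six other amino acids (Gly, Arg, Cys,
Asn, Thr, Ile), one silent change and no stop.

A transcript whose CDS terminates inside the repeat region leaves repeat
units stranded in the 3′ UTR:

```r
tx <- paste0("ATG", strrep("AGC", 12), "TAG", strrep("CAG", 9), "TGA",
             strrep("CAG", 6))
cds_report(tx, unit = "CAG")
#> ORF at [0, 42): 13 codons, terminated
#> CDS: 13 codons; 15 repeat unit(s) downstream of stop
```

Simulating a pure `(CAG)60` locus under neutral point mutation shows the
polyQ reading frame dying quickly while polyS/polyA survive:

```r
p <- sim_params(mu = 0.001, generations = 100, n_replicates = 300, seed = 42)
traj <- evolve(strrep("CAG", 60), p)
subset(frame_survival(traj, "polyQ"), generation %in% c(25, 50, 100))
#>     generation surviving_fraction         se   n
#> 26          25          0.6333333 0.02782219 300
#> 51          50          0.4300000 0.02858321 300
#> 101        100          0.1533333 0.02080242 300
```

At these settings the single-hit expectation is `exp(-60 * (mu/3) * t)`,
i.e. 0.61, 0.37 and 0.14 at generations 25, 50 and 100.

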