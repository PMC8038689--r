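---
title: "Designing editing polypurine reverse-Hoogsteen hairpins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing editing polypurine reverse-Hoogsteen hairpins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprhtools)
```

## The molecule and the problem

A polypurine reverse-Hoogsteen hairpin (PPRH) is a single-stranded,
unmodified DNA oligo built from two *mirror-repeat* polypurine arms joined by
a pentathymidine loop. The arms fold back on each other and pair
intramolecularly through reverse-Hoogsteen bonds; one arm then binds the
genomic polypyrimidine strand opposite a polypurine track by Watson–Crick
bonds, displacing the purine strand. The mirror relation is the structural
signature: the 3' arm is the plain character **reverse** of the 5' arm,
never its reverse complement.

An *editing* PPRH extends this core at its 5' end through a second
pentathymidine stretch (a linker, the "long-distance" arrangement) with a
homology tail that spans an edit junction: typically 20 nt upstream plus
20 nt downstream of a restriction site at which an unwanted cassette — for
example a duplicated exon that shifts the reading frame — was inserted. The
two halves of the tail are contiguous only in the *restored* (post-edit)
sequence, so the tail can template a homologous-recombination event that
deletes the intervening cassette, i.e. permanent exon skipping at the DNA
level.

`pprhtools` implements the full design loop: find candidate polypurine
tracks, assemble and decompose editing PPRHs, check designs with
sequence-level assays (restriction scan, virtual PCR, splice-isoform
enumeration with RT-PCR band prediction, oligo physicochemistry), and
exercise everything end to end on a seeded synthetic minigene that emulates
an exon-2 duplication and its reversion.

## The design grammar

Every editing PPRH is the concatenation

```
full_seq = tail + TTTTT + arm + TTTTT + reverse(arm)
```

with the tail at the 5' end. `decompose_pprh()` inverts this by enumerating
all placements of one or two exact 5-T windows inside maximal T-runs of
length ≥ 5 and accepting a partition only when the 3' arm is the character
reverse of the 5' arm. A tail that itself ends in T fuses with the linker
into a 6-T run; the enumeration tries both splits and the mirror constraint
resolves the ambiguity. When several partitions pass, the longest arm wins,
then the longest tail, then the leftmost linker — a deterministic tie-break
that favours the biologically larger binding domain. Arms shorter than
`min_arm = 10` are rejected because spurious mirror partitions become common
in random sequence below that length.

```{r grammar}
oligos <- published_pprh_oligos()
d <- decompose_pprh(oligos$sequence[oligos$name == "LDSHpE6I1DPstI"])
str(d)
```

Pyrimidine interruptions inside an arm are kept verbatim and mirrored into
the second arm: every published arm pair is an exact reverse, so the grammar
performs no base substitution.

## Coordinates and the junction convention

Internally every interval is 0-based half-open; printed reports are 1-based
inclusive. The edit junction is a *position between bases*. Under the
default policy (`site_starts_at_junction`) the recognition motif (`CTGCAG`
by default) begins exactly at the junction, so the upstream 20-mer excludes
the site and the downstream 20-mer starts with it. This is the only
convention consistent with the published 40-nt tail, whose second half
begins `CTGCAG`.

`build_tail()` always stores the two + strand genomic windows (`up_seq`,
`down_seq`); a minus-strand tail is their reverse complement with the order
swapped, so that the oligo reads 5'→3' on the minus strand. The rule mapping
the core's target strand to the tail strand ("same sequence and orientation
as the strand to be recombined") is under-determined from sequence alone, so
`design_candidates()` emits both tail orientations per track, plus strand
first, and records the choice. Design names follow the
`LDSHp<region>I<k><mode><motif>` labelling style of the published set; they
are opaque labels, never parsed.

## Finding polypurine tracks

`scan_polypurine_tracks()` reports every **maximal** track on both strands:
trimmed to purine boundaries and not contained in any larger window that
still passes the gates. Maximality over fixed-width windows was chosen
because real targets are track-shaped — the published arms are 17, 20 and
22 nt. Overlapping maximal tracks are all reported; ranking is a design-time
decision, not a scan-time one. Windows containing `N` are skipped: designs
must be concrete.

The default gates (`min_track_len = 15`, `min_purity = 0.80`,
`max_pyr_run = 2`) are the loosest values that admit all three published
arms (purine fractions 0.82–0.87, longest pyrimidine run 2). The
constructor enforces `min_track_len ≥ 8` and `min_purity ∈ [0.5, 1]`;
below those bounds "track" stops being a meaningful unit.

`brute_force_tracks()` is a deliberately naive re-implementation (walk every
purine-bounded substring, filter, keep maximal) kept as an independent
oracle; the test suite asserts set-equality against the scanner on hundreds
of seeded random sequences. It refuses sequences over 2 kb.

## In-silico assays

* `find_restriction_sites()` matches IUPAC motifs (degenerate codes are
  allowed in motifs, though not in designs); palindromic motifs are reported
  once, on the + strand.
* `virtual_pcr()` uses the standard product-length convention: forward
  5'-end through reverse 5'-end on the bottom strand, both primer footprints
  included. The default is exact priming (`max_mismatch = 0`) for
  reproducibility; when mismatches are allowed the 3'-terminal 3 nt must
  still match exactly, since polymerase extension is 3'-anchored.
* `enumerate_isoforms()` builds the canonical isoform plus one isoform per
  requested event (`skip:<exon>`, `retain:<intron>`); combinations are
  generated only when requested explicitly, avoiding combinatorial blow-up.
  `rtpcr_band_table()` returns a sorted length table — a gel as data, not as
  an image — with the largest product on top and `NA` where a primer site is
  missing.

## Oligo physicochemistry

`molecular_weight()` uses the anhydrous linear ssDNA free-acid convention:
per-monomer masses (A 313.21, T 304.2, C 289.18, G 329.21 Da) minus a
single 61.96 Da terminal correction. Under this convention the five
published editing PPRHs average 25,652 Da, matching the published figure;
the tail-only control is excluded from that average because it is
introduced as a control, not an editing PPRH. `molarity()` is the exact
conversion `nM = µg / Da / mL × 10⁶`, rounded only at display; the worked
dose examples use a 1.0 mL final transfection volume (a 200 µL
transfection mix added to 800 µL of medium). The melting-temperature
helpers are deliberately simple closed forms (Wallace rule below 14 nt, a
GC-fraction formula above) — QC aids that avoid nearest-neighbour
parameter-set ambiguity, with the method recorded in the report.

```{r physchem}
editing <- oligos[oligos$editing, ]
mean(vapply(editing$sequence, molecular_weight, numeric(1)))
molarity(3, 25652, 1.0)
```

## The synthetic minigene

No sequence for the original duplication construct is deposited, so the
package generates a structural analogue. `make_minigene()` draws a uniform
random background and patches in, deterministically per seed:

* a 250-nt promoter-like region, six exons (60/50/70/50/50/40 nt) and five
  introns (300/250/250/250/250 nt) — about 1.9 kb in total, chosen so the
  full pipeline runs in well under a second per seed;
* `GT`/`AG` at every intron boundary;
* the published 20-nt upstream and downstream homology blocks around the
  single `CTGCAG` in intron 1 (the junction), so the published tails map
  onto the fixture exactly;
* the three published polypurine arms in the promoter, exon 3 and exon 6;
* the published exon-1 and exon-3 primer footprints, placed so that the
  spliced inclusion and skip products are 166 and 116 bp — the published
  band sizes. The 50-nt duplicated exon equals their difference.

Backgrounds violating any uniqueness invariant (one motif copy, single
occurrences of each arm, block and primer footprint, on both the restored
and the mutant sequence) are rejected and resampled, so the invariants hold
for every seed, not just the default. `make_mutant()` inserts the cassette
(100-nt intron flanks around a duplicate exon-2 copy, splice sites intact)
with one motif copy regenerated upstream — the cloned fragment had two
different ends, so symmetric regeneration is not guaranteed and the choice
is configurable. `apply_edit()` emulates the recombination outcome purely at
the sequence level: it finds the unique homology blocks and splices out
everything between them.

The fixture emulates geometry, not biology. It does not model chromatin,
recombination frequency (the published efficacy range is a biological
quantity, not computable from sequence), splice-site strength, the reported
intron-1 retention levels, or the real hamster gene; base composition is
uniform rather than genomic. Passing tests therefore demonstrate that the
design grammar, the scanner, the edit emulator and the assay arithmetic are
mutually consistent and reproduce the published computable numbers — they
say nothing about editing efficiency in cells. The virtual-PCR check against
the real hamster cDNA requires that external sequence; given a FASTA of it,
`virtual_pcr()` with the published exon-1/exon-3 primers predicts the
116-bp skip product directly.

```{r minigene}
mg <- make_minigene(minigene_spec(seed = 42))
mut <- make_mutant(mg)
isos <- enumerate_isoforms(mut$record, mut$gene, list("skip:E2b"))
primers <- published_primer_pairs()
rtpcr_band_table(isos, primers$forward[1], primers$reverse[1])
identical(apply_edit(mut$record, mg$record, mg$junction)$seq, mg$record$seq)
```

## Degenerate inputs and numerical choices

* Sequences are normalized to uppercase `{A,C,G,T,N}`; `U` maps to `T` with
  a recorded flag (RNA-style input is tolerated, not silently accepted).
* A record shorter than `min_track_len` scans to an empty table, not an
  error; an all-pyrimidine record yields minus-strand tracks only.
* Loops shorter than 3 nt are rejected (the hairpin cannot close);
  zero-width homology windows are rejected as degenerate.
* Purity comparisons are exact rational comparisons (`count / length ≥
  threshold` computed identically in scanner and oracle), so no epsilon is
  needed.
* All randomness flows from explicit integer seeds; identical inputs give
  identical bytes everywhere, including the command line.

## Problem sizes used by the test suite

The shipped tests run the scanner-vs-oracle comparison on 100 seeded
200-mers, the assemble/decompose identity on 500 randomized designs, the
duplication/edit round trip on 10 seeds, and the restriction-scan oracle on
100 random 250-mers — sizes chosen so the whole suite completes in well
under a minute on one CPU while still exercising every branch of the
grammar.

## Known limitations

* No triplex thermodynamics: tracks are gated by composition, not predicted
  binding energy; pH and Mg²⁺ dependence of reverse-Hoogsteen pairing is out
  of scope.
* No primer thermodynamics: virtual PCR is exact string matching with an
  optional mismatch budget, not a hybridization model.
* Single-nucleotide repair designs share the grammar but are not
  specialized; chemical modification planning and vendor order files are out
  of scope.
* Band intensities (relative abundance of isoforms) are not modelled; the
  band table is qualitative presence/size only.
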