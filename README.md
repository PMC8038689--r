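# pprhtools

Design and in-silico validation of **editing polypurine reverse-Hoogsteen
hairpins (PPRHs)** — unmodified single-stranded DNA oligos that bind a
genomic polypyrimidine target and carry a homology tail spanning an edit
junction, templating the permanent removal (skipping) of an unwanted exon at
the DNA level.

The package is for molecular biologists designing PPRH-based editing
experiments and for anyone who wants a reproducible, scriptable version of
the design arithmetic: target finding, oligo assembly/QC, predicted
restriction maps, PCR products and RT-PCR band patterns, and dose
calculations.

## The design in one formula

An editing PPRH is

```
5'- tail (20 nt up and/or 20 nt down of the junction) - TTTTT - arm - TTTTT - reverse(arm) -3'
```

* the **arm** is a polypurine track sequence (purine fraction ≥ 0.80, length
  ≥ 15, pyrimidine runs ≤ 2 under the default gates);
* the second arm is the plain character **reverse** of the first
  (mirror-repeat, reverse-Hoogsteen pairing) — *not* the reverse complement;
* both T-stretches are pentathymidines: the inner one is the hairpin loop,
  the outer one the long-distance linker to the homology tail;
* the tail maps contiguously onto the **restored** (post-edit) reference: its
  two halves flank the recognition site (`CTGCAG` by default) and only
  become adjacent when the intervening cassette is deleted.

## Worked example

Everything below runs offline: the synthetic minigene generator emulates a
wildtype-like minigene, its exon-2-duplication derivative and the edited
reversion, with the published homology blocks, polypurine arms and primer
footprints embedded.

```r
library(pprhtools)

mg  <- make_minigene(minigene_spec(seed = 42))  # restored reference, ~1.9 kb
mut <- make_mutant(mg)                          # + 256-nt cassette insertion

# 1. candidate designs for the junction
des <- design_candidates(mut$record, mg$record, mg$junction, mut$gene)
head(des[, c("name", "region", "arm", "purity", "valid")])
#>               name region                     arm    purity valid
#> 1  LDSHpPrI1UDPstI     Pr  GGGGAAGGAAAAGTGGGTGACA 0.8636364  TRUE
#> 2 LDSHpPrI1UDPstIm     Pr  GGGGAAGGAAAAGTGGGTGACA 0.8636364  TRUE
#> 3  LDSHpE3I1UDPstI     E3  ...

# 2. the edit they template, emulated at the sequence level
identical(apply_edit(mut$record, mg$record, mg$junction)$seq, mg$record$seq)
#> [1] TRUE

# 3. predicted RT-PCR bands: inclusion vs skip of the duplicated exon
isos    <- enumerate_isoforms(mut$record, mut$gene, list("skip:E2b"))
primers <- published_primer_pairs()
rtpcr_band_table(isos, primers$forward[1], primers$reverse[1])
#>     isoform                  exons length
#> 1 canonical E1,E2a,E2b,E3,E4,E5,E6    166
#> 2  skip:E2b     E1,E2a,E3,E4,E5,E6    116

# 4. oligo QC and dose arithmetic for the published set
oligos <- published_pprh_oligos()
decompose_pprh(oligos$sequence[3])$arm1
#> [1] "AGGAGGAAAAAGGCATCAAG"
mean(vapply(oligos$sequence[oligos$editing], molecular_weight, numeric(1)))
#> [1] 25652.08
molarity(3, 25652, 1.0)   # 3 ug in 1.0 mL
#> [1] 116.9496            # prints as 117 nM
```

The 166/116 bp pair is the published inclusion/skip signature; their
difference is the 50-nt duplicated exon. The mean molecular weight matches
the published 25,652 Da average for the five editing PPRHs, and 3 µg / 5 µg
doses convert to the published 117 / 195 nM.

## Command line

A thin wrapper is installed at `inst/cli/pprh`
(`system.file("cli", "pprh", package = "pprhtools")`):

```
pprh scan     --fasta ref.fa [--min-len 15 --min-purity 0.80 --max-pyr-run 2] --out tracks.bed
pprh design   --fasta mutant.fa --restored restored.fa --gff genes.gff3 \
              --junction mg1:460 --out designs.tsv
pprh validate --seq <oligo> [--fasta restored.fa --junction mg1:460] [--strict]
pprh pcr      --fasta template.fa --fwd SEQ --rev SEQ
pprh isoforms --fasta mg.fa --gff mg.gff3 --skip E2b --retain 1 --fwd SEQ --rev SEQ
pprh physchem --seq <oligo> | --file oligos.tsv
pprh dose     --mass-ug 3 --mw 25652 --volume-ml 1.0     # -> 117 nM
pprh fixtures --out DIR --seed 42
```

All output is TSV (or BED6 for `scan`); identical invocations produce
identical bytes. `--config file.yaml` supplies flag values; explicit flags
override it.

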