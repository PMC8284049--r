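# braidr

Offline design and simulation of multiplex CRISPR/Cas constructs in the
GoldenBraid (GB) modular-cloning standard, for plant genome engineers who
want their cloning plans checked *before* touching an enzyme.

Multiplex editing constructs minimally carry three transcriptional units —
a guide-RNA TU, a Cas nuclease TU and a selection marker — and the guide TU
is the hard part: up to six tandemly arrayed guides must be cloned from
repetitive elements and then mature in planta into exactly the planned
units. `braidr` implements the whole stack:

* **Grammar** — the GB standard as data: BsaI/BsmBI, a table of 4-nt fusion
  sites keyed by junction role, the pUPD2 / alpha / omega backbone classes
  with their entry/exit enzymes and markers, and the array capacity (6).
* **Assembly engine** — in-silico Type IIS restriction–ligation:
  digestion on both strands (circular-aware), enumeration of circular
  products over the overhang graph, antibiotic selection, re-cut
  (irreversibility) filtering, and uniqueness with diagnosable failures.
* **Cas9 tools** — single-guide domesticator/assembler, and the three-step
  multiplex pipeline (position-independent oligos → Level 0 tRNA–spacer–
  scaffold units → polycistronic Level 1 TU), including MS2-aptamer
  scaffolds for dCas regulation arrays.
* **Cas12a tools** — single crRNA with HDV-ribozyme 3' trimming, and
  synthesis-ready DR–spacer array fragments (2–6 units).
* **Multigene composition** — binary alpha/omega assembly, a minimal
  3-TU editing construct, the one-shot `crispr_for_dummies()` pipeline and
  a multi-array stress composition.
* **Processing oracle** — simulated Pol III transcription, tRNA excision,
  Cas12a self-processing and HDV cleavage; `verify_scarless()` is the
  package's ground truth. Editing-efficiency estimates are binned into
  genotype calls at 20/40/60/80 %.
* **Synthetic inputs** — seeded spacer and toy-locus generators; no
  downloads, everything runs offline.

Outputs are annotated GenBank files, 2×N oligo order sheets (CSV), and
step-by-step laboratory protocols.

## Worked example

```r
library(braidr)

spacers <- random_spacers(3, "Cas9", seed = 7, prefix = "gSPL")
bundle  <- crispr_for_dummies(spacers)
bundle
#> <gb_bundle> final construct crispr_dummies_construct (3556 bp), 6 oligos,
#>             6 intermediates, 7 reactions

## the final T-DNA: nptII, Cas9, DsRed and the polycistronic gRNA TU
subset(bundle$final$features, role == "TU")$label
#> [1] "nptII_TU"        "Cas9_TU"         "DsRed_TU"        "dummies_gRNA_TU"

## what the plant will make of it
process_transcript(bundle$final)
#>   cassette unit spacer                                        sequence
#> 1        1    1  gSPL1 CGGTGCGCCTTGTTCGTGCTGTTTTAGAGCTAGAAATAGCAAG...
#> 2        1    2  gSPL2 GTTCGGCTCGATGCCGCTCTGTTTTAGAGCTAGAAATAGCAAG...
#> 3        1    3  gSPL3 GTTAGCTAGAATAACTAGAGGTTTTAGAGCTAGAAATAGCAAG...

write_bundle(bundle, "my_construct/")   # oligos.csv, protocol.md, *.gb
```

Each mature guide is exactly `spacer + scaffold` — the 4-nt junctions are
part of the biological elements (scaffold head, tRNA tail), so assembly
leaves no scar; `verify_scarless(attr(..., "plan"), process_transcript(...))`
checks this for any construct. The reverse oligo of a guide starts with
`AAAC` (the complement of the scaffold's `GTTT` head), as bench scientists
will expect.

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/gbdesign", package="braidr"))')" \
    fixtures spacers --n 6 --nuclease cas9 --seed 42 --out spacers.csv
```

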