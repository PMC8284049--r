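---
title: "Designing multiplex CRISPR constructs with the GoldenBraid grammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multiplex CRISPR constructs with the GoldenBraid grammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braidr)
```

## The problem

Multiplex CRISPR/Cas editing in plants needs constructs that carry several
tandemly arrayed guide RNAs next to a Cas nuclease and selection markers.
Building these is harder than ordinary multigene cloning because guide
arrays are repetitive (one constant scaffold or direct repeat per unit) and
because the mature guides must be released from one polycistronic
transcript *exactly*: a single extra nucleotide riding along on a spacer
changes its target. `braidr` implements the GoldenBraid (GB) answer to
this problem as an offline, fully simulatable library: a Type IIS cloning
grammar, an in-silico digestion-ligation engine, the complete single and
multiplex guide design tools for Cas9 and Cas12a, and an in-planta
RNA-processing simulator that acts as the package's own correctness
oracle.

## The cloning model

Two Type IIS enzymes (BsaI and BsmBI) cut outside their recognition
sequences and leave user-defined 4-nt 5' overhangs ("fusion sites"). The
grammar assigns one tetramer to every junction role: vector/cargo
boundaries, the promoter-spacer and spacer-scaffold junctions, the
direct-repeat-spacer and spacer-HDV junctions, and one site per array
position. All correctness guarantees in the package are
internal-consistency properties of this table (ligation fidelity,
scarless maturation); the specific letters are package defaults and the
table is swappable through `load_grammar()`. Validation enforces that
sites are pairwise distinct and never self-reverse-complementary (a
self-complementary overhang would ligate ambiguously).

The hierarchy has three working levels plus an auxiliary one:

* **Level 0** parts (promoters, scaffolds, guide units) live in the pUPD2
  entry vector (chloramphenicol), are created with BsmBI, and are released
  with BsaI by flanks the cargo itself carries.
* **Level 1** transcriptional units (TUs) are multipartite BsaI assemblies
  of Level 0 parts in alpha-class vectors (kanamycin).
* **Level >1** modules grow by binary assembly: alpha1 + alpha2 cargos
  join with BsmBI in an omega vector (spectinomycin), omega1 + omega2
  cargos join with BsaI back in an alpha vector, indefinitely.
* **Level -1** tRNA-scaffold plasmids (ampicillin) supply the constant
  pieces of multiplex Cas9 guide units, pre-assigned to array positions.

The engine (`simulate_reaction()`) digests every input, enumerates all
circular ligation products over the overhang-matching graph, applies the
destination's antibiotic selection, discards any candidate still carrying
a site of the reaction enzyme (it would be re-cut -- this is what makes
Golden Gate reactions effectively irreversible), and demands exactly one
surviving product. Failures are diagnosable: no product, ambiguous
products, or re-cuttable products each raise a distinct condition
carrying the overhang graph.

### Composition planning

Strict pairwise binary assembly alone can only reach module counts of the
form 3k+1 (in alpha) or 3k+2 (in omega): a three-TU editing construct or
a six-module stress construct would be unreachable. The package follows
the collection-centric GB practice instead: the bundled marker and Cas
TUs are pre-made fixtures hosted in *all four* destination classes, and
the composition planner (`compose_modules()`, used by
`crispr_for_dummies()` and `compose_stress_test()`) recursively packs the
ordered module list into a binary tree whose node classes alternate
alpha/omega with depth, drawing each fixture from whichever class the
plan requires. User-built guide arrays are always assembled into an alpha
vector first. Along any provenance path the enzymes then alternate
BsaI/BsmBI, which the test-suite asserts.

## Scarlessness by construction

The design insight that makes tandem arrays scarless is that every 4-nt
junction is part of a biological element rather than a foreign scar:

* the spacer-scaffold junction is the scaffold's first four nucleotides
  (the familiar `GTTT` head, which is why the reverse oligo of a single
  guide starts with `AAAC`);
* the tRNA-spacer junction is the tRNA's last four nucleotides;
* the junction between consecutive Cas9 units is the *next* unit's tRNA
  head -- each array position uses a tRNA variant whose first tetramer is
  the position's fusion site. Position-specific assembly and scarless
  processing are otherwise in direct tension: a constant tRNA cannot
  provide six different junction tetramers;
* for Cas12a, the upstream element ends in the direct repeat's last four
  nucleotides and the spacer-HDV junction is the ribozyme's first four.

Because the last unit of an array must ligate to the vector boundary and
carry the Pol III terminator, the level -1 collection holds, per position,
an *internal* cassette (ending in the next position's tRNA head) and a
*terminal* cassette (ending in terminator + vector site). `build_guide_L0()`
selects between them via its `terminal` flag, and `assemble_cas9_array()`
reads each unit's position and terminal status back from the fusion-site
annotations of the molecules themselves, rejecting gaps, duplicates and
non-terminal last units. MS2-aptamer scaffold variants (for dCas-based
regulation) exist for positions 1-3 only; regulation arrays are capped at
three units.

For Cas12a, the synthesis fragment designed by
`design_cas12a_array_fragment()` carries one direct repeat per spacer and
ends with the HDV ribozyme and terminator; the upstream element's own DR
then acts as a spacer-less leader that self-processing consumes. In the
single-crRNA design the same upstream DR *is* the crRNA's repeat --
sharing the upstream part between the two tools is what fixes this
asymmetry. A `--no-hdv` style flag (`include_hdv = FALSE`) switches the
array 3' end to terminator run-off; the default keeps HDV, mirroring the
single-guide design.

## The processing oracle

`process_transcript()` simulates maturation from annotations: Pol III
transcription runs from the promoter's 3' end to the first poly-T
terminator; RNase P/Z excise annotated tRNAs; Cas12a cuts at every DR 5'
boundary; HDV removes everything 3' of its own start. Boundaries are
annotation-driven by design -- they are known exactly at design time, and
modelling the cleavage chemistry itself is out of scope. The oracle is
independent of the assembly path: `verify_scarless()` compares the
processed guides against sequences recomputed directly from the element
table (`spacer + scaffold` per Cas9 unit, `DR + spacer` per Cas12a unit)
and reports count, order and per-unit sequence mismatches.

Editing-efficiency estimates are a separate, purely numeric concern:
`classify_edit_estimate()` bins percentages at 20/40/60/80 into negative,
chimeric-one-allele, heterozygous, chimeric-both-alleles and biallelic
calls. The boundary assignment (a value of exactly 40 is
chimeric-one-allele, i.e. right-closed bins) is a package decision, made
configurable only through the documented bin definition, since published
range notation leaves the boundary open. The conservative rule for two
guides hitting one gene at about 50% each is deliberately *not* applied
silently: it is a flag on the gene-level aggregator
(`classify_gene_edits(conservative = TRUE)`).

## Synthetic inputs and fixtures

Nothing is downloaded. `random_spacers()` draws uniform spacers
(20 nt Cas9, 20-23 nt Cas12a), rejecting candidates containing a
BsaI/BsmBI recognition on either strand -- also in the junction contexts
the cloning flanks will create, so a spacer ending in `GAGAC` cannot form
a recognition against the scaffold's `GTTT` head. The generator is
integer-seeded with no float state and restores the caller's RNG.
`toy_target_locus()` builds demonstration target "genes" with NGG (Cas9)
or 5' TTTV (Cas12a) PAM geometry.

The registry ships as annotated GenBank fixtures. Element bodies
(scaffold, pre-tRNA, direct repeat, HDV, MS2 aptamer) are realistic
domain-style sequences whose junction tetramers are adjusted to satisfy
the grammar; chassis, promoters, stuffers and the Cas9/Cas12a/nptII/DsRed
TU bodies are synthetic stand-ins -- deterministic pseudo-random,
recognition-free segments generated once with a fixed authoring seed.
Every pseudo-random segment starts and ends with `AA`, which provably
prevents any Type IIS recognition from forming across a junction with a
random segment (no recognition contains `AA`, starts with `A`, or ends in
`A`). Consequently, what passing tests show about real data is the
grammar's consistency, not the behaviour of any particular published
plasmid: swapping in real vector sequences is supported but their letters
are the user's responsibility.

## Numerical and engineering choices

* Coordinates are 0-based, half-open, top strand; circular molecules are
  indexed modulo length, and wrap-around features are split at the origin
  in GenBank output and re-merged on input.
* Sticky fragments are represented by their virtual top strand including
  both overhang regions once; joining drops the shared tetramer, so a
  circular product of k fragments has length `sum(len_i) - 4k` -- asserted
  for every simulated product.
* Overhang matching is exact Watson-Crick; mismatch ligation would need
  an empirical fidelity model that is out of scope.
* Products are canonicalized starting at the backbone fragment;
  rotationally identical candidates are deduplicated by canonical
  rotation before ambiguity is declared. Ambiguity is an error, never a
  silent choice.
* Self-religation of a single digested input still carrying recognition
  sites is ignored when deciding between "no product" and "re-cuttable
  product" diagnoses; it is chemically present but uninformative.
* Registry digestion is memoized per enzyme (validated against the full
  sequence), which is what keeps a 500-construct property suite in the
  minutes range.

## Problem sizes used in the checked properties

The shipped test-suite exercises: GenBank round-trip identity on 1,000
randomized records (lengths 100-20,000); equivalence of the ligation
enumerator with a brute-force ordering/orientation oracle on pools of up
to six fragments; scarless maturation, irreversibility and length
conservation over 500 random constructs (300 Cas9 arrays of 1-6 guides,
200 Cas12a arrays of 2-6 crRNAs); the 17-guide three-array stress
composition; and the exhaustive bin-boundary behaviour of the edit-call
classifier. These sizes were chosen to cover every array cardinality and
position combination many times over while keeping a full run in a few
minutes on one core.

## Known limitations

* No kinetic or efficiency modelling: ligation either closes a circle or
  does not; partial digestion and enzyme star activity are not modelled.
* Processing is annotation-driven; it will not detect a cleavage boundary
  the design did not annotate.
* Protospacer discovery and on-target scoring are out of scope; spacers
  are user input (external scoring tools fill that role).
* The GenBank dialect is single-record, simple ranges; `join()` locations
  beyond the origin-split convention are not parsed.
* Positional efficiency effects in long arrays (last-position bias) are a
  biological observation, not something a cloning simulator can
  reproduce; the package only guarantees that every position's guide
  matures correctly.
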