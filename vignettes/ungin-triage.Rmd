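---
title: "Heuristic genome triage for uracil-DNA glycosylase inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heuristic genome triage for uracil-DNA glycosylase inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ungmine)
```

## The problem

Uracil-DNA glycosylase inhibitors (UngIns) are small acidic proteins that
mimic DNA: their surface charge aligns with the DNA-binding cleft of
family-1 uracil-DNA glycosylase (Ung), and a hydrophobic pocket sequesters
the residue Ung uses to intercalate the DNA minor groove. Phages whose
genomes contain uracil depend on them, yet the known folds tolerate such
extreme sequence plasticity (pairwise identities of 12-32% among verified
Ugi/SAUGI-family members) that BLAST-style homology search routinely fails.
What *is* conserved is physicochemical: small size, strong net acidity, a
characteristic glutamate-anchored tripeptide in the Ung-binding
$\beta$-strand, and a low glycine/proline content. `ungmine` turns those
shared properties into a genome triage pipeline.

## Putative-polypeptide extraction

Genomes are translated in all six reading frames with the standard genetic
code (the segmentation only depends on the stop set TAA/TAG/TGA, which the
bacterial table shares). Every stop-to-stop segment -- sequence ends count
as boundaries, so genome-edge genes are not silently dropped -- is trimmed
to its first valid start residue, defined conservatively as M, I, V or L,
and kept if it has at least `min_len = 40` residues. Ambiguous codons that
resolve to a unique residue are translated; others become `X`, which is
never accepted as a start residue and never matches a motif class.

Two conventions are deliberately configurable:

* `length_check`: whether the 40-residue minimum applies to the raw
  stop-to-stop segment (`pre_trim`) or to the trimmed protein
  (`post_trim`, the default -- stricter, and the one a downstream length
  filter would effectively impose anyway).
* `circular`: genomes are treated as linear by default; circular mode
  appends the first `3 * min_len` nucleotides so origin-spanning ORFs are
  captured once, with wrapped duplicates removed.

Coordinates are reported 1-based inclusive on the forward strand and span
exactly the codons of the emitted protein, so every record can be
re-translated and checked -- the test suite does this against a
brute-force enumerator on random genomes.

## Property vectors

Per protein the cascade sees: residue count; GRAVY (mean Kyte-Doolittle
hydropathy -- the community default hydrophobicity scale; the choice is
not load-bearing because thresholds are calibrated, not copied); counts of
acidic (D+E) and basic (K+R) residues -- histidine is excluded because it
is mostly uncharged at cytoplasmic pH, and D+E reproduces the acidic
counts recorded for the reference inhibitors; the D+E and G+P chain
fractions; and the whole-chain molecular mass (average isotopic residue
masses plus one water; `X` contributes the 110 Da mean residue mass).
"Mass bounds" are interpreted as whole-chain mass: UngIns are ~9.5-13 kDa,
and a sliding-window reading would need window parameters nothing defines.
A protein with no basic residue gets an acid:base ratio of `Inf`, a
sentinel that passes any finite lower bound -- strongly acidic DNA mimics
are exactly the target of that filter.

## The ESI motif and the PROSITE engine

The Ung-binding $\beta$-strand of the Ugi/SAUGI family carries a conserved
glutamate-anchored tripeptide (ESI in the prototypes). Curated natural
variation gives `E-[ASVFHTNI]-[LVIFMT]`; viable synthetic mutants extend
position 3 to `[LVIFMTPWC]`. Four leniency modes combine the two axes:

| mode | position 2 | position 3 |
|---|---|---|
| `strict_natural` | `[ASVFHTNI]` | `[LVIFMT]` |
| `strict_synthetic` | `[ASVFHTNI]` | `[LVIFMTPWC]` |
| `lenient_natural` | any | `[LVIFMT]` |
| `lenient_synthetic` | any | `[LVIFMTPWC]` |

Scanning is sequence-wide: the pipeline runs on unannotated translations,
so no positional restriction to a predicted strand is imposed.

The motif engine compiles the PROSITE dialect these patterns need --
fixed residues, classes, `X`, `X(n)`, `X(n,m)` -- and reports *all*
matches, including every (start, length) combination of variable-length
patterns. Exclusion classes, anchors and repeats of non-wildcard elements
are intentionally unsupported: implementing only what is exercised keeps
the matcher small enough to verify against a brute-force expansion oracle
(which the tests do, on random patterns and sequences).

## The cascade and its calibration

Stages run in a fixed order (length, acidity, hydrophobicity, Gly/Pro,
acid:base ratio, mass, ESI motif, optional extra motifs), but each stage
is an independent predicate, so the final candidate set is order-invariant
-- only the per-stage survivor report depends on the order. `run_bulk()`
adds genome-level GC binning (5% half-open bins; verified Ugi-encoding
genomes sit at 25-30% GC, so the 25-35% window is flagged as priority, and
5% bins resolve that window into two). `relax_serially()` re-runs the
cascade disabling one stage at a time, the experiment that surfaces
near-misses failing a single filter (in practice the Gly/Pro stage: low-GC
genomes under-encode G and P, so decoys rarely fail it alone while true
borderline inhibitors may).

Calibration is deliberately *not* a stochastic search. For independent
interval filters, the configuration that retains every known positive
while admitting the least background is exactly the min/max envelope of
the positives' property vectors; `calibrate()` computes that envelope,
optionally widened outward by a relative `margin`, and validates that
every positive carries the ESI motif under the requested mode. The
shipped `default_filter_config()` is the envelope of the bundled
Ugi/SAUGI-type reference set at `margin = 0.1` with `strict_natural` ESI.
Margin 0 is used when the positives are exactly the targets of interest
(the end-to-end recovery tests); a wider margin trades false positives for
robustness to unseen family members.

## Bundled references

One bundled record is the genuine 84-residue Ugi of *Bacillus* phages
PBS1/PBS2/AR9. The SAUGI, Ugi-2, MCUGI1 and p56 entries are **synthetic
stand-ins** (so labelled in their identifiers, headers and filename): the
authentic records could not be redistributed with the package, so each
stand-in was constructed to reproduce its namesake's documented length,
acidic-residue count, Ung-binding $\beta$-strand fragment at its recorded
position, and family motifs (ESI classes; `E-X(6)-[ED]-[ED]` and its
Ugi-family extension; `E-X(2)-Y-X(0,2)-G` for the p56 profile). They make
the default calibration and the end-to-end tests self-contained, but any
analysis of real genomes should substitute authentic sequences via
`calibrate()` -- results on stand-ins validate the machinery, not the
biology of the stand-ins themselves. The p56 profile is kept separate
from Ugi/SAUGI calibration: p56-type inhibitors are recognized by their
own PROSITE pattern, not by the ESI heuristics.

## The synthetic-genome generator

`synthetic_genome()` emulates the one property of uracil-DNA phage
genomes the filters care about -- low GC content -- with i.i.d.
nucleotides at a target GC (default 0.28, inside the 25-30% window where
verified Ugi variants occur). Positives and decoys are reverse-translated
with the synonymous codon nearest the GC target (ties broken
lexicographically; codon-usage realism is irrelevant to the filters,
exact re-translation is not) and spliced in between stop codons, which
makes recovery assertions exact rather than probabilistic. Three decoy
profiles are constructed and verified on emission: `motifless` (no
glutamate at all), `lenient_only` (a lenient-mode motif whose position 2
is outside the strict class), and `property_violating` (a strict ESI
motif inside a basic, Gly/Pro-rich chain). The generator does *not*
emulate operon structure, tRNAs, repeats, codon bias or mutational
processes -- so passing tests demonstrate correct mechanics and
separability under controlled composition, not expected candidate yields
on real phage genomes.

Default study conditions for the end-to-end tests: 50 kb genomes at 28%
GC with 10 decoys per profile; oracle-equivalence tests use random
genomes up to 300 nt; GC control uses twenty 10-kb genomes (binomial
3$\sigma$ at that length is ~0.013, comfortably inside the +/-0.02
acceptance band).

## Worked example

```{r example, eval = FALSE}
refs <- ungin_references("ugi_saugi")
sg <- synthetic_genome(length = 50000, gc_target = 0.28, seed = 1,
                       positives = refs$seq, decoys_per_profile = 10)
cal <- calibrate(refs, margin = 0)
res <- run_pipeline(sg$genome, cal$config)
res$report
all(refs$seq %in% res$candidates$aa_seq)
```

## Known limitations

* The heuristics target the Ugi/SAUGI fold family; genuinely novel
  inhibitor folds are invisible to them by construction.
* Homology confirmation (BLAST and relatives), MSA construction and any
  structural screening are out of scope; candidates are starting points
  for such follow-up, not calls.
* Comparative statistics (`identical_positions()` and friends) consume
  existing alignments; they never compute one, because the reference
  alignments in this field are structure-based and recomputing them would
  silently change every count.
* Published triage counts for real uracil-DNA phage genomes (e.g.
  *Yersinia* phage phiR1-37) can only be reproduced with the genome FASTA
  supplied by the user; it is not bundled.
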