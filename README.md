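# ungmine

Heuristic genome triage for candidate uracil-DNA glycosylase inhibitor
(UngIn) genes.

## Why

UngIns are small, strongly acidic DNA-mimicking proteins that phages (and
mobile elements such as SCC*mec*) use to shut down family-1 uracil-DNA
glycosylase (Ung), protecting uracil-containing DNA from host excision
repair. The known folds — Ugi/SAUGI and p56 — tolerate extreme sequence
plasticity (down to ~12% pairwise identity within a fold), so homology
search often finds nothing even in genomes that must encode an inhibitor.
What the verified repertoire does share is physicochemical: ~9.5–13 kDa,
a high D+E fraction with few K/R, low Gly/Pro content, moderate
hydrophobicity, and a glutamate-anchored tripeptide ("ESI") in the
Ung-binding β-strand, generalized as `E-[ASVFHTNI]-[LVIFMT]` (natural
variation) with position 3 extended to `[LVIFMTPWC]` by viable synthetic
mutants. `ungmine` screens genomes for exactly these signatures.

## What it does

1. **Extraction** — six-frame translation; every stop-to-stop segment is
   trimmed to its first valid start residue (M/I/V/L) and kept at ≥ 40
   residues (`extract_putative_proteins()`).
2. **Properties** — length, GRAVY (Kyte–Doolittle), acidic/basic counts
   and ratio, D+E and G+P fractions, molecular mass
   (`property_vector()`).
3. **Motifs** — a PROSITE-style engine (`compile_prosite()`,
   `find_matches()`) plus the four ESI leniency modes
   (`has_esi_motif()`).
4. **Triage** — the filter cascade with per-stage survivor reporting,
   GC binning for bulk screens, and serial single-stage relaxation
   (`run_pipeline()`, `run_bulk()`, `relax_serially()`).
5. **Calibration** — thresholds are fitted as the min/max envelope over
   known positives (optionally widened by a margin), the exact solution
   of "retain every positive with as few false positives as possible"
   for interval filters (`calibrate()`).
6. **Synthetic validation** — seeded low-GC genomes with embedded
   positives and profile-controlled decoys (`synthetic_genome()`).

A thin CLI over the same functions ships at `inst/cli/ungmine`
(`simulate`, `motif-scan`, `filter`, `calibrate`).

## Worked example

Spike the bundled inhibitor references into a 50 kb synthetic genome at
28% GC alongside 30 decoys, calibrate on the references, and triage:

```r
library(ungmine)
refs <- ungin_references("ugi_saugi")
sg   <- synthetic_genome(length = 50000, gc_target = 0.28, seed = 1,
                         positives = refs$seq, decoys_per_profile = 10)
cal  <- calibrate(refs, margin = 0)
res  <- run_pipeline(sg$genome, cal$config)
res$report
#> # A tibble: 7 × 3
#>   stage            n_in n_out
#>   <chr>           <int> <int>
#> 1 length            337    26
#> 2 acidity            26     4
#> 3 hydrophobicity      4     4
#> 4 gly_pro             4     4
#> 5 acid_base_ratio     4     4
#> 6 mass                4     4
#> 7 esi                 4     4
```

The 50 kb genome yields 337 putative proteins; the length filter leaves
26, the acidity filter 4, and those 4 survivors are precisely the four
embedded references — no decoy (including the ten that carry a genuine
strict ESI motif inside a basic, Gly/Pro-rich chain) survives:

```r
res$candidates[, c("protein_id", "length", "de_fraction", "gravy")]
#> # A tibble: 4 × 4
#>   protein_id            length de_fraction  gravy
#> 1 synth_g1|+2|1040-1291     84       0.214 -0.340
#> 2 synth_g1|+3|3714-3974     87       0.241 -0.714
#> 3 synth_g1|-2|5018-5347    110       0.164 -0.565
#> 4 synth_g1|-3|2335-2670    112       0.152 -0.4
```

Protein ids encode provenance as `genome|frame|nt_start-nt_end` on the
forward strand. Motif scanning works the same way on any FASTA:

```r
find_matches("E-X(2)-Y-X(0,2)-G", ungin_references("p56")$seq)
#> # A tibble: 1 × 3
#>   start   end matched
#> 1    10    15 EKSYTG
```

Note on bundled sequences: the Ugi record is the genuine PBS1/PBS2/AR9
protein; the SAUGI/Ugi-2/MCUGI1/p56 entries are synthetic stand-ins
(labelled as such) constructed to match their namesakes' documented
lengths, acidic compositions and motifs — substitute authentic sequences
for real analyses. See the methods vignette
(`vignettes/ungin-triage.Rmd`) for the reasoning behind every default.

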