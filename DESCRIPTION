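Package: ungmine
Title: Heuristic Genome Triage for Uracil-DNA Glycosylase Inhibitor Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines bacteriophage and other microbial genomes for candidate
    uracil-DNA glycosylase inhibitor (UngIn) genes of the Ugi/SAUGI fold
    family. Genomes are translated in all six reading frames, stop-to-stop
    segments are trimmed to the first valid start residue and screened
    through a cascade of physicochemical filters (length, acidity, GRAVY
    hydropathy, glycine/proline content, acidic-to-basic residue ratio,
    molecular mass) followed by a PROSITE-style motif filter built around
    the conserved ESI tripeptide of the Ung-binding beta-strand. Filter
    thresholds are calibrated from verified inhibitor sequences so that all
    known positives are retained with as few false positives as possible.
    Includes a seeded generator of low-GC phage-like genomes with embedded
    positive and decoy open reading frames for end-to-end validation, and
    GC-content binning for bulk genome screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    tibble,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
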