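# Bundled reference material: the verified Ugi sequence, synthetic
# stand-ins for the other inhibitor references, and the mutagenesis
# library of Ung-binding beta-strand heptapeptides.

#' Bundled uracil-DNA glycosylase inhibitor reference sequences
#'
#' The Ugi/SAUGI profile drives the default calibration of the filter
#' cascade; the p56 profile is recognized by the PROSITE pattern
#' `E-X(2)-Y-X(0,2)-G` only. The PBS1/PBS2/AR9 Ugi entry is the genuine
#' 84-residue phage sequence; the remaining entries are synthetic
#' stand-ins (flagged in the `synthetic` column and in their FASTA
#' headers) that reproduce the documented lengths, acidic-residue
#' compositions, Ung-binding beta-strand fragments and family motifs of
#' their namesakes.
#'
#' @param set Which profile to load: `"ugi_saugi"` (default), `"p56"` or
#'   `"all"`.
#' @return A protein tibble (`id`, `description`, `seq`) with a logical
#'   `synthetic` column.
#' @export
ungin_references <- function(set = c("ugi_saugi", "p56", "all")) {
  set <- match.arg(set)
  real <- read_fasta_aa(system.file("extdata", "ugi_pbs1.fasta",
                                    package = "ungmine", mustWork = TRUE))
  real$synthetic <- FALSE
  standins <- read_fasta_aa(system.file("extdata",
                                        "ungin_synthetic_standins.fasta",
                                        package = "ungmine", mustWork = TRUE))
  standins$synthetic <- TRUE
  all_ref <- rbind(real, standins)
  switch(set,
    all = all_ref,
    p56 = all_ref[grepl("p56", all_ref$id), , drop = FALSE],
    ugi_saugi = all_ref[!grepl("p56", all_ref$id), , drop = FALSE])
}

#' Mutagenesis library of Ung-binding beta-strand heptapeptides
#'
#' The seven-residue first beta-strand of Ugi (`QESILML`, carrying the ESI
#' motif at positions 2-4) was randomized in three libraries: L1 fully
#' randomized the strand (its two soluble clones lost inhibitor
#' function), L2 shuffled the ESI motif within naturally observed classes,
#' and L3 randomized ESI freely; the functional L2/L3 clones define the
#' synthetic position-3 extension of the ESI motif.
#'
#' @return A tibble with columns `library`, `clone`, `sequence`,
#'   `functional` (logical: retained inhibitor activity).
#' @export
ugi_library_table <- function() {
  path <- system.file("extdata", "ugi_library_betastrands.tsv",
                      package = "ungmine", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$functional <- as.logical(tab$functional)
  tibble::as_tibble(tab)
}
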