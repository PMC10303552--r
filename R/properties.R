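# Physicochemical property vectors used by the heuristic filter cascade,
# and genome GC content for bulk binning.

#' Kyte-Doolittle hydropathy values
#'
#' The standard per-residue hydropathy scale; the mean over a protein is its
#' GRAVY score.
#' @format Named numeric vector over the 20 standard residues.
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Average isotopic residue masses (Da); whole-chain mass adds one water.
AA_RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)
MASS_WATER <- 18.01524
MASS_X <- 110  # mean residue mass stand-in for ambiguous residues

ACIDIC_RESIDUES <- c("D", "E")
BASIC_RESIDUES <- c("K", "R")  # histidine excluded: mostly uncharged at ~pH 7

#' GC content of a nucleotide sequence
#'
#' Fraction of G+C among unambiguous A/C/G/T positions; ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param seq A DNA string (IUPAC letters).
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (length(s) == 0L) stop("empty sequence")
  gc <- sum(s == "G" | s == "C")
  at <- sum(s == "A" | s == "T")
  if (gc + at == 0L) stop("sequence has no unambiguous A/C/G/T positions")
  gc / (gc + at)
}

#' Heuristic property vector of protein sequences
#'
#' Computes, per sequence, the attributes screened by the filter cascade:
#' length, GRAVY (mean Kyte-Doolittle hydropathy), counts of acidic (D+E)
#' and basic (K+R) residues, the acidic-to-basic ratio, the D+E and G+P
#' fractions of the chain, and the average-isotopic molecular mass.
#'
#' `X` residues count toward `length` and the fraction denominators, are
#' excluded from the GRAVY mean, and contribute 110 Da (mean residue mass)
#' to `mass_da`. When a sequence has no basic residue the ratio is `Inf`,
#' so strongly acidic DNA mimics pass any finite ratio threshold.
#'
#' @param seq Character vector of protein sequences (standard residues
#'   plus `X`; no `*`).
#' @return A tibble with one row per sequence: `length`, `gravy`,
#'   `acidic_count`, `basic_count`, `acid_base_ratio`, `de_fraction`,
#'   `glypro_fraction`, `mass_da`.
#' @examples
#' property_vector(c("ECESIEEI", "GGGG"))
#' @export
property_vector <- function(seq) {
  stopifnot(is.character(seq), length(seq) >= 1L)
  if (any(nchar(seq) == 0L)) stop("empty protein sequence")
  if (any(grepl("*", seq, fixed = TRUE)))
    stop("sequences must not contain stop markers ('*')")
  one <- function(x) {
    s <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(s), c(names(KYTE_DOOLITTLE), "X"))
    if (length(bad) > 0L)
      stop("invalid residue(s): ", paste(bad, collapse = ", "))
    n <- length(s)
    plain <- s[s != "X"]
    acidic <- sum(s %in% ACIDIC_RESIDUES)
    basic <- sum(s %in% BASIC_RESIDUES)
    c(length = n,
      gravy = if (length(plain) > 0L) mean(KYTE_DOOLITTLE[plain]) else NA_real_,
      acidic_count = acidic,
      basic_count = basic,
      acid_base_ratio = if (basic == 0L) Inf else acidic / basic,
      de_fraction = acidic / n,
      glypro_fraction = sum(s %in% c("G", "P")) / n,
      mass_da = sum(AA_RESIDUE_MASS[plain]) + MASS_X * sum(s == "X") + MASS_WATER)
  }
  tmpl <- c(length = 0, gravy = 0, acidic_count = 0, basic_count = 0,
            acid_base_ratio = 0, de_fraction = 0, glypro_fraction = 0,
            mass_da = 0)
  m <- t(vapply(seq, one, tmpl))
  rownames(m) <- NULL
  out <- tibble::as_tibble(as.data.frame(m))
  out$length <- as.integer(out$length)
  out$acidic_count <- as.integer(out$acidic_count)
  out$basic_count <- as.integer(out$basic_count)
  out
}

#' Count acidic residues (D + E)
#'
#' @param seq Character vector of protein sequences.
#' @return Integer vector of D+E counts.
#' @examples
#' count_acidic("ECESIEEI")
#' @export
count_acidic <- function(seq) {
  stopifnot(is.character(seq))
  vapply(toupper(seq), function(x) {
    s <- strsplit(x, "", fixed = TRUE)[[1L]]
    sum(s %in% ACIDIC_RESIDUES)
  }, integer(1L), USE.NAMES = FALSE)
}
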