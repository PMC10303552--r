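# Small comparative computations over pre-aligned sequence pairs. The
# alignments themselves (structure-based or from external MSA tools) are
# inputs, never computed here: re-deriving them would silently change the
# position-wise counts.

check_pair <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b))
    stop("aligned sequences must have equal length")
  if (nchar(a) == 0L) stop("empty alignment")
  list(a = strsplit(toupper(a), "", fixed = TRUE)[[1L]],
       b = strsplit(toupper(b), "", fixed = TRUE)[[1L]])
}

#' Identical positions in an aligned pair
#'
#' Counts columns where the two residues are identical and neither is a
#' gap (`-`).
#'
#' @param a,b Equal-length aligned protein strings (gaps as `-`).
#' @return Non-negative integer.
#' @examples
#' identical_positions("ECESIEEI", "LTEFVQLG")
#' @export
identical_positions <- function(a, b) {
  p <- check_pair(a, b)
  sum(p$a == p$b & p$a != "-")
}

#' Shared acidic positions in an aligned pair
#'
#' Counts columns where both residues are acidic (D or E), not necessarily
#' the same residue -- conservation of negative charge rather than
#' identity.
#'
#' @inheritParams identical_positions
#' @return Non-negative integer.
#' @examples
#' shared_acidic_positions("ED", "DE")
#' @export
shared_acidic_positions <- function(a, b) {
  p <- check_pair(a, b)
  sum(p$a %in% ACIDIC_RESIDUES & p$b %in% ACIDIC_RESIDUES)
}

#' Percent identity over comparable columns
#'
#' Identical positions divided by the number of columns where neither
#' sequence is gapped.
#'
#' @inheritParams identical_positions
#' @return Fraction in `[0, 1]`.
#' @examples
#' percent_identity("A-AA", "AGAA")
#' @export
percent_identity <- function(a, b) {
  p <- check_pair(a, b)
  comparable <- p$a != "-" & p$b != "-"
  if (!any(comparable)) stop("no comparable (gap-free) columns")
  sum(p$a == p$b & comparable) / sum(comparable)
}
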