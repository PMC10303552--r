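# PROSITE-style pattern engine and the four ESI-motif leniency modes.
#
# Supported dialect (the subset the filters need): fixed residues, residue
# classes [..], the wildcard X, fixed repeats X(n) and bounded repeats
# X(n,m), with '-' or whitespace separators. An ambiguous 'X' in a SEQUENCE
# matches wildcard elements only, never a fixed residue or a class.

ESI_POS2_STRICT <- c("A", "S", "V", "F", "H", "T", "N", "I")
ESI_POS3_NATURAL <- c("L", "V", "I", "F", "M", "T")
ESI_POS3_SYNTHETIC <- c("L", "V", "I", "F", "M", "T", "P", "W", "C")

#' The four ESI-motif leniency modes
#'
#' The conserved tripeptide of the Ung-binding beta-strand is `E` followed
#' by two class positions. Strict modes restrict position 2 to the residues
#' observed across curated natural variants (`[ASVFHTNI]`); lenient modes
#' allow any residue there. Natural modes restrict position 3 to
#' `[LVIFMT]`; synthetic modes extend it with the substitutions recovered
#' from viable library mutants (`[LVIFMTPWC]`).
#'
#' @return Character vector of mode names, ordered from most to least
#'   strict: `strict_natural`, `strict_synthetic`, `lenient_natural`,
#'   `lenient_synthetic`.
#' @export
esi_modes <- function() {
  c("strict_natural", "strict_synthetic", "lenient_natural", "lenient_synthetic")
}

esi_classes <- function(mode) {
  mode <- match.arg(mode, esi_modes())
  list(
    pos2 = if (startsWith(mode, "strict")) ESI_POS2_STRICT else NULL,
    pos3 = if (endsWith(mode, "natural")) ESI_POS3_NATURAL else ESI_POS3_SYNTHETIC)
}

#' Compile a PROSITE-style pattern
#'
#' @param pattern Pattern string, e.g. `"E-X(2)-Y-X(0,2)-G"` or
#'   `"E-X(6)-[ED]-[ED]"`. Elements may be separated by `-` or whitespace.
#' @return An object of class `pros_pattern` with the ordered element list.
#' @examples
#' compile_prosite("E-X(2)-Y-X(0,2)-G")
#' @export
compile_prosite <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  toks <- strsplit(trimws(pattern), "[-[:space:]]+")[[1L]]
  toks <- toks[toks != ""]
  if (length(toks) == 0L) stop("empty pattern")
  aa <- paste(AA_STANDARD, collapse = "")
  elements <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tok <- toupper(toks[i])
    if (grepl(sprintf("^[%s]$", aa), tok)) {
      elements[[i]] <- list(type = "fixed", residue = tok)
    } else if (tok == "X") {
      elements[[i]] <- list(type = "wild", min = 1L, max = 1L)
    } else if (grepl("^X\\(\\d+\\)$", tok)) {
      n <- as.integer(sub("^X\\((\\d+)\\)$", "\\1", tok))
      elements[[i]] <- list(type = "wild", min = n, max = n)
    } else if (grepl("^X\\(\\d+,\\d+\\)$", tok)) {
      n <- as.integer(sub("^X\\((\\d+),(\\d+)\\)$", "\\1", tok))
      m <- as.integer(sub("^X\\((\\d+),(\\d+)\\)$", "\\2", tok))
      if (m < n)
        stop(sprintf("element %d ('%s'): upper repeat bound smaller than lower",
                     i, toks[i]))
      elements[[i]] <- list(type = "wild", min = n, max = m)
    } else if (grepl(sprintf("^\\[[%s]+\\]$", aa), tok)) {
      set <- sort(unique(strsplit(gsub("\\[|\\]", "", tok), "")[[1L]]))
      elements[[i]] <- list(type = "class", set = set)
    } else {
      stop(sprintf("element %d: unknown token '%s'", i, toks[i]))
    }
  }
  structure(list(source = pattern, elements = elements),
            class = "pros_pattern")
}

#' Serialize a compiled pattern to its normalized PROSITE form
#'
#' Classes are alphabetically sorted and elements joined with `-`;
#' `compile_prosite(serialize_prosite(p))` reproduces `p`.
#'
#' @param pattern A `pros_pattern`.
#' @return A character scalar.
#' @export
serialize_prosite <- function(pattern) {
  stopifnot(inherits(pattern, "pros_pattern"))
  paste(vapply(pattern$elements, function(el) {
    switch(el$type,
      fixed = el$residue,
      class = paste0("[", paste(el$set, collapse = ""), "]"),
      wild = if (el$min == el$max) {
        if (el$min == 1L) "X" else sprintf("X(%d)", el$min)
      } else sprintf("X(%d,%d)", el$min, el$max))
  }, ""), collapse = "-")
}

#' @export
print.pros_pattern <- function(x, ...) {
  cat("<pros_pattern> ", serialize_prosite(x), "\n", sep = "")
  invisible(x)
}

# Recursive matcher: returns all end positions (inclusive) of matches of
# elements k.. starting at position pos.
match_ends <- function(chars, pos, elements, k) {
  if (k > length(elements)) return(pos - 1L)
  n <- length(chars)
  el <- elements[[k]]
  if (el$type == "fixed") {
    if (pos <= n && chars[pos] == el$residue)
      match_ends(chars, pos + 1L, elements, k + 1L) else integer()
  } else if (el$type == "class") {
    if (pos <= n && chars[pos] %in% el$set)
      match_ends(chars, pos + 1L, elements, k + 1L) else integer()
  } else {
    ends <- integer()
    for (len in el$min:el$max) {
      if (pos + len - 1L > n) break
      ends <- c(ends, match_ends(chars, pos + len, elements, k + 1L))
    }
    unique(ends)
  }
}

#' Find all matches of a PROSITE pattern in a protein sequence
#'
#' Reports every match at every start position; for variable-length
#' patterns all matching (start, end) combinations are returned. An `X` in
#' the sequence satisfies wildcard elements only.
#'
#' @param pattern A `pros_pattern` (or a pattern string, compiled on the
#'   fly).
#' @param seq A protein sequence (character scalar).
#' @return A tibble with columns `start`, `end` (1-based inclusive) and
#'   `matched`, ordered by start then end.
#' @examples
#' find_matches("E-X(6)-[ED]-[ED]", "EAAAAAADE")
#' @export
find_matches <- function(pattern, seq) {
  if (is.character(pattern)) pattern <- compile_prosite(pattern)
  stopifnot(inherits(pattern, "pros_pattern"),
            is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  starts <- integer(); ends <- integer()
  for (i in seq_along(chars)) {
    e <- match_ends(chars, i, pattern$elements, 1L)
    e <- sort(e[e >= i])  # ignore zero-length degenerate matches
    if (length(e) > 0L) {
      starts <- c(starts, rep.int(i, length(e)))
      ends <- c(ends, e)
    }
  }
  if (length(starts) == 0L)
    return(tibble::tibble(start = integer(), end = integer(),
                          matched = character()))
  tibble::tibble(start = starts, end = ends,
                 matched = substring(seq, starts, ends))
}

#' Test a sequence for the ESI motif
#'
#' Scans the whole sequence for a tripeptide `E` + position-2 class +
#' position-3 class under the given leniency mode (see [esi_modes()]).
#'
#' @param seq Character vector of protein sequences.
#' @param mode One of `esi_modes()`.
#' @return Logical vector.
#' @examples
#' has_esi_motif("QEAMLML", "strict_natural")
#' @export
has_esi_motif <- function(seq, mode = "strict_natural") {
  cl <- esi_classes(mode)
  pos2 <- if (is.null(cl$pos2)) "." else paste0("[", paste(cl$pos2, collapse = ""), "]")
  pos3 <- paste0("[", paste(cl$pos3, collapse = ""), "]")
  grepl(paste0("E", pos2, pos3), toupper(seq))
}

#' PROSITE pattern of an ESI mode
#'
#' @param mode One of [esi_modes()].
#' @return A `pros_pattern` equivalent to [has_esi_motif()] under `mode`.
#' @export
esi_pattern <- function(mode = "strict_natural") {
  cl <- esi_classes(mode)
  pos2 <- if (is.null(cl$pos2)) "X" else paste0("[", paste(cl$pos2, collapse = ""), "]")
  pos3 <- paste0("[", paste(cl$pos3, collapse = ""), "]")
  compile_prosite(paste("E", pos2, pos3, sep = "-"))
}

#' Derive per-position residue classes from equal-length motifs
#'
#' For each column the set of observed residues is rendered as a PROSITE
#' class (a bare residue when only one is observed) -- the procedure used
#' to generalize the ESI motif from curated alignments.
#'
#' @param motifs Character vector of equal-length motif strings.
#' @return The derived PROSITE pattern string.
#' @examples
#' derive_position_classes(c("ESI", "EAM", "ETC"))
#' @export
derive_position_classes <- function(motifs) {
  stopifnot(is.character(motifs))
  if (length(motifs) == 0L) stop("at least one motif is required")
  motifs <- toupper(motifs)
  if (length(unique(nchar(motifs))) != 1L)
    stop("motifs must all have the same length")
  mat <- do.call(rbind, strsplit(motifs, "", fixed = TRUE))
  cols <- apply(mat, 2L, function(col) sort(unique(col)), simplify = FALSE)
  paste(vapply(cols, function(set) {
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, ""), collapse = "-")
}
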