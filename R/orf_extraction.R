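# Six-frame translation and putative-polypeptide extraction: every
# stop-to-stop segment is trimmed to its first valid start residue
# (M, I, V or L) and kept if it meets the minimum length (default 40 aa).

FRAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")
START_RESIDUES <- c("M", "I", "V", "L")

as_genome_record <- function(genome) {
  if (is.data.frame(genome)) {
    stopifnot(all(c("id", "seq") %in% names(genome)), nrow(genome) == 1L)
    list(id = genome$id[[1L]], seq = toupper(genome$seq[[1L]]))
  } else if (is.list(genome) && all(c("id", "seq") %in% names(genome))) {
    list(id = genome$id, seq = toupper(genome$seq))
  } else {
    stop("genome must be a one-row record (columns/fields id, seq)")
  }
}

#' Reverse complement of a DNA sequence
#'
#' Handles the full IUPAC ambiguity alphabet (N<->N, R<->Y, ...).
#'
#' @param seq A DNA string (IUPAC letters).
#' @return The reverse complement as a character scalar.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# Translate a (multiple-of-3-truncated) DNA string with the standard code.
# Ambiguous codons that resolve to a unique residue are translated; others
# become X; stops become '*'.
translate_nt <- function(seq) {
  n <- nchar(seq)
  n3 <- n - n %% 3L
  if (n3 < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, n3)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
}

#' Translate a genome in all six reading frames
#'
#' Frames +1..+3 read the forward strand at offsets 0/1/2; frames -1..-3
#' read the reverse complement at offsets 0/1/2. Stop codons are marked
#' `*`; ambiguous codons that do not resolve to a unique residue become
#' `X`; 1-2 trailing nucleotides are dropped.
#'
#' @param genome A one-row genome record (fields `id`, `seq`).
#' @return A tibble with columns `genome_id`, `frame`, `peptide`.
#' @export
six_frame_translate <- function(genome) {
  g <- as_genome_record(genome)
  if (nchar(g$seq) < 3L) stop("genome shorter than 3 nt cannot be translated")
  rc <- reverse_complement(g$seq)
  pep <- c(
    vapply(1:3, function(k) translate_nt(substr(g$seq, k, nchar(g$seq))), ""),
    vapply(1:3, function(k) translate_nt(substr(rc, k, nchar(rc))), ""))
  tibble::tibble(genome_id = g$id, frame = FRAMES, peptide = pep)
}

# Split a frame peptide into stop-delimited segments; sequence ends act as
# boundaries. Returns start/end positions (1-based, in peptide coordinates)
# of the non-empty segments between stops.
stop_segments <- function(peptide) {
  n <- nchar(peptide)
  stops <- which(strsplit(peptide, "", fixed = TRUE)[[1L]] == "*")
  bounds <- c(0L, stops, n + 1L)
  starts <- head(bounds, -1L) + 1L
  ends <- bounds[-1L] - 1L
  keep <- ends >= starts
  list(start = starts[keep], end = ends[keep])
}

# Map a run of codons [p1..p2] (1-based positions in the frame peptide) to
# forward-strand nucleotide coordinates.
codons_to_nt <- function(frame, p1, p2, genome_len) {
  offset <- abs(as.integer(substr(frame, 2L, 2L))) - 1L
  a <- offset + 3L * (p1 - 1L) + 1L
  b <- offset + 3L * p2
  if (startsWith(frame, "+")) c(a, b) else c(genome_len - b + 1L, genome_len - a + 1L)
}

#' Extract putative proteins from a genome
#'
#' Implements the stop-to-stop rule: each frame peptide is split on stop
#' markers (sequence ends count as boundaries), each segment is trimmed to
#' its first residue in `M/I/V/L`, and segments without a start residue or
#' shorter than `min_len` are discarded. With
#' `length_check = "post_trim"` (default, stricter) the minimum applies to
#' the trimmed protein; with `"pre_trim"` it applies to the raw
#' stop-to-stop segment. `X` is never a valid start residue.
#'
#' @param genome A one-row genome record (fields `id`, `seq`).
#' @param min_len Minimum protein length in residues (default 40).
#' @param length_check Where the length minimum is applied,
#'   `"post_trim"` or `"pre_trim"`.
#' @param circular If `TRUE`, the genome is treated as circular: the first
#'   `3 * min_len` nucleotides are appended to capture origin-spanning
#'   ORFs, coordinates are wrapped back onto `1..L` and duplicates removed.
#'   For origin-spanning proteins `nt_end` exceeds the genome length and
#'   wraps past position `L`.
#' @return A tibble with columns `protein_id`, `genome_id`, `frame`,
#'   `aa_seq`, `nt_start`, `nt_end`, `length`, `trimmed_prefix_len`,
#'   ordered by frame (+1,+2,+3,-1,-2,-3) then `nt_start`. Coordinates are
#'   1-based inclusive on the forward strand and span exactly the codons of
#'   `aa_seq`.
#' @export
extract_putative_proteins <- function(genome, min_len = 40L,
                                      length_check = c("post_trim", "pre_trim"),
                                      circular = FALSE) {
  length_check <- match.arg(length_check)
  g <- as_genome_record(genome)
  min_len <- as.integer(min_len)
  stopifnot(min_len >= 1L)
  L <- nchar(g$seq)
  work <- g
  if (circular) work$seq <- paste0(g$seq, substr(g$seq, 1L, 3L * min_len))
  frames <- six_frame_translate(work)
  n_work <- nchar(work$seq)

  rows <- vector("list", 64L); nr <- 0L
  for (fi in seq_len(nrow(frames))) {
    frame <- frames$frame[fi]
    pep <- frames$peptide[fi]
    seg <- stop_segments(pep)
    for (si in seq_along(seg$start)) {
      s <- seg$start[si]; e <- seg$end[si]
      if (length_check == "pre_trim" && (e - s + 1L) < min_len) next
      segment <- substr(pep, s, e)
      hit <- regexpr("[MIVL]", segment)
      if (hit < 0L) next
      p1 <- s + as.integer(hit) - 1L
      if (length_check == "post_trim" && (e - p1 + 1L) < min_len) next
      nt <- codons_to_nt(frame, p1, e, n_work)
      nr <- nr + 1L
      if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[nr]] <- list(frame = frame, aa_seq = substr(pep, p1, e),
                         nt_start = nt[1L], nt_end = nt[2L],
                         trimmed_prefix_len = as.integer(hit) - 1L)
    }
  }
  if (nr == 0L) {
    out <- tibble::tibble(protein_id = character(), genome_id = character(),
                          frame = character(), aa_seq = character(),
                          nt_start = integer(), nt_end = integer(),
                          length = integer(), trimmed_prefix_len = integer())
    return(out)
  }
  rows <- rows[seq_len(nr)]
  out <- tibble::tibble(
    genome_id = g$id,
    frame = vapply(rows, `[[`, "", "frame"),
    aa_seq = vapply(rows, `[[`, "", "aa_seq"),
    nt_start = vapply(rows, `[[`, 1L, "nt_start"),
    nt_end = vapply(rows, `[[`, 1L, "nt_end"),
    trimmed_prefix_len = vapply(rows, `[[`, 1L, "trimmed_prefix_len"))

  if (circular) {
    # drop copies living entirely in the appended origin duplicate, wrap the rest
    out <- out[out$nt_start <= L, , drop = FALSE]
    # drop re-discoveries whose wrapped start coincides with a linear hit
    key <- paste(out$frame, ((out$nt_start - 1L) %% L) + 1L, out$aa_seq)
    out <- out[!duplicated(key), , drop = FALSE]
  }

  out$length <- nchar(out$aa_seq)
  out$protein_id <- sprintf("%s|%s|%d-%d", out$genome_id, out$frame,
                            out$nt_start, out$nt_end)
  out <- out[order(match(out$frame, FRAMES), out$nt_start), , drop = FALSE]
  out[, c("protein_id", "genome_id", "frame", "aa_seq", "nt_start", "nt_end",
          "length", "trimmed_prefix_len")]
}

#' Count putative proteins in a genome
#'
#' Convenience wrapper equal to
#' `nrow(extract_putative_proteins(genome, ...))`, reproducing the
#' "possible protein-coding sequences" denominator of a genome screen.
#'
#' @inheritParams extract_putative_proteins
#' @return A non-negative integer.
#' @export
count_putative_proteins <- function(genome, min_len = 40L,
                                    length_check = c("post_trim", "pre_trim"),
                                    circular = FALSE) {
  nrow(extract_putative_proteins(genome, min_len = min_len,
                                 length_check = length_check,
                                 circular = circular))
}
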