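# FASTA input/output. Records travel as tibbles with columns id, description,
# seq; parsing itself is delegated to Biostrings, validation is ours.

IUPAC_DNA <- "ACGTRYSWKMBDHVN"
AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L","M",
                 "N","P","Q","R","S","T","V","W","Y")

split_header <- function(nm) {
  id <- sub("\\s.*$", "", nm)
  desc <- sub("^\\S+\\s*", "", nm)
  list(id = id, description = desc)
}

read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- split_header(names(set))
  ids <- hdr$id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  tibble::tibble(id = ids, description = unname(hdr$description),
                 seq = unname(as.character(set)))
}

#' Read a nucleotide FASTA file
#'
#' Sequences are uppercased and RNA-style `U` is converted to `T`. Each
#' sequence must consist of IUPAC DNA letters (`ACGT`, ambiguity codes,
#' `N`); gap characters are rejected because aligned FASTA is a different
#' artifact. Record ids (first whitespace-delimited header token) must be
#' unique within the file.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `seq`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 toy genome", "acgtacgu"), tf)
#' read_fasta_nt(tf)
#' @export
read_fasta_nt <- function(path) {
  rec <- read_fasta_raw(path)
  rec$seq <- chartr("U", "T", toupper(rec$seq))
  bad <- regexpr(sprintf("[^%s]", IUPAC_DNA), rec$seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("record '%s': invalid nucleotide '%s' at position %d",
                 rec$id[i], substr(rec$seq[i], bad[i], bad[i]), bad[i]),
         call. = FALSE)
  }
  if (any(nchar(rec$seq) == 0L))
    stop("record '", rec$id[which(nchar(rec$seq) == 0L)[1L]],
         "' has an empty sequence", call. = FALSE)
  rec
}

#' Read a protein FASTA file
#'
#' Sequences are uppercased and must consist of the 20 standard residues
#' plus `X`. Stop markers (`*`) are not accepted: putative proteins are
#' stored stop-free.
#'
#' @inheritParams read_fasta_nt
#' @return A tibble with columns `id`, `description`, `seq`.
#' @export
read_fasta_aa <- function(path) {
  rec <- read_fasta_raw(path)
  rec$seq <- toupper(rec$seq)
  bad <- regexpr(sprintf("[^%sX]", paste(AA_STANDARD, collapse = "")), rec$seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("record '%s': invalid residue '%s' at position %d",
                 rec$id[i], substr(rec$seq[i], bad[i], bad[i]), bad[i]),
         call. = FALSE)
  }
  if (any(nchar(rec$seq) == 0L))
    stop("record '", rec$id[which(nchar(rec$seq) == 0L)[1L]],
         "' has an empty sequence", call. = FALSE)
  rec
}

#' Write records to FASTA
#'
#' Output is deterministic byte-for-byte for given records and width (LF
#' line endings). Records containing `*` are refused; stop markers must be
#' stripped upstream.
#'
#' @param records A tibble/data.frame with columns `id`, `seq` and
#'   optionally `description`.
#' @param path Output path.
#' @param width Sequence line width (positive integer, default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            all(c("id", "seq") %in% names(records)))
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("width must be a positive integer")
  if (any(grepl("*", records$seq, fixed = TRUE)))
    stop("sequences contain '*'; stop markers must be removed before writing",
         call. = FALSE)
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(is.na(desc) | desc == "", records$id,
                paste(records$id, desc))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
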