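# Seeded generator of phage-like test genomes: i.i.d. nucleotides at a
# target GC, reverse-translated ORFs spliced in between stop codons, and
# decoy proteins with controlled filter-violation profiles. Everything is
# deterministic per seed so end-to-end recovery tests are exact.

#' Random genome at a target GC content
#'
#' Nucleotides are drawn i.i.d. with `P(G) = P(C) = gc_target/2` and
#' `P(A) = P(T) = (1 - gc_target)/2`; reproducible per seed.
#'
#' @param length Genome length in nucleotides.
#' @param gc_target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param id Record id (default derived from the seed).
#' @return A one-row genome tibble (`id`, `description`, `seq`).
#' @export
random_genome <- function(length, gc_target, seed,
                          id = sprintf("synth_g%d", seed)) {
  stopifnot(length >= 1L)
  if (!(gc_target > 0 && gc_target < 1))
    stop("gc_target must be strictly between 0 and 1")
  set.seed(as.integer(seed))
  nt <- sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
               prob = c((1 - gc_target) / 2, gc_target / 2,
                        gc_target / 2, (1 - gc_target) / 2))
  tibble::tibble(id = id, description = "synthetic random genome",
                 seq = paste(nt, collapse = ""))
}

# Per-amino-acid codon choice nearest a GC target (ties: lexicographically
# first codon). Stop codons are handled separately.
codon_for <- function(aa, gc_target) {
  code <- Biostrings::GENETIC_CODE
  codons <- sort(names(code)[code == aa])
  if (length(codons) == 0L) stop("no codon for residue '", aa, "'")
  gcf <- vapply(strsplit(codons, ""), function(s) mean(s %in% c("G", "C")), 0)
  codons[which.min(abs(gcf - gc_target))]
}

stop_codon_for <- function(gc_target) {
  codons <- c("TAA", "TAG", "TGA")
  gcf <- c(0, 1 / 3, 1 / 3)
  codons[which.min(abs(gcf - gc_target))]
}

#' Reverse-translate a protein with GC-nearest codons
#'
#' Each residue is encoded by the synonymous codon whose GC fraction is
#' closest to `gc_target` (ties broken lexicographically), so translating
#' the result reproduces the protein exactly and the insert blends into a
#' genome of that GC content. `X` and `*` are rejected.
#'
#' @param protein Protein string over the 20 standard residues.
#' @param gc_target GC fraction in `[0, 1]`.
#' @return A nucleotide string of length `3 * nchar(protein)`.
#' @examples
#' reverse_translate("MKL", gc_target = 0)
#' @export
reverse_translate <- function(protein, gc_target) {
  stopifnot(is.character(protein), length(protein) == 1L, nchar(protein) > 0L)
  s <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  if (any(!(s %in% AA_STANDARD)))
    stop("protein contains non-standard residues (X or '*' are not allowed)")
  paste(vapply(s, codon_for, "", gc_target = gc_target), collapse = "")
}

#' Embed a protein-coding ORF into a genome
#'
#' Splices `[stop codon] + reverse_translate(protein) + [stop codon]` into
#' the genome at `position` (overwriting), reverse-complemented for the
#' minus strand. The flanking stops guarantee clean stop-to-stop segment
#' boundaries, so [extract_putative_proteins()] recovers the protein
#' exactly (after trimming to its first start residue). Overlap with a
#' previously embedded ORF is an error; embedded intervals travel in the
#' `embeds` attribute of the returned record.
#'
#' @param genome A one-row genome tibble.
#' @param protein Protein string (standard residues).
#' @param position 1-based position where the insert starts.
#' @param strand `"+"` or `"-"`.
#' @param gc_target GC target for codon choice.
#' @return The modified genome tibble, with an updated `embeds` attribute
#'   (tibble of `start`, `end`, `cds_start`, `cds_end`, `strand`, `frame`,
#'   `protein`).
#' @export
embed_orf <- function(genome, protein, position, strand = c("+", "-"),
                      gc_target = 0.3) {
  strand <- match.arg(strand)
  g <- as_genome_record(genome)
  stp <- stop_codon_for(gc_target)
  insert <- paste0(stp, reverse_translate(protein, gc_target), stp)
  L <- nchar(g$seq)
  end <- position + nchar(insert) - 1L
  if (position < 1L || end > L)
    stop("insert does not fit the genome at position ", position)
  embeds <- attr(genome, "embeds")
  if (!is.null(embeds) &&
      any(position <= embeds$end & end >= embeds$start))
    stop("insert overlaps a previously embedded ORF")
  seq2 <- paste0(substr(g$seq, 1L, position - 1L),
                 insert,
                 substr(g$seq, end + 1L, L))
  cds_start <- position + 3L
  cds_end <- end - 3L
  frame_fwd <- ((cds_start - 1L) %% 3L) + 1L
  frame <- if (strand == "+") sprintf("+%d", frame_fwd) else
    sprintf("-%d", ((L - cds_end) %% 3L) + 1L)
  if (strand == "-") {
    ins_rc <- reverse_complement(insert)
    seq2 <- paste0(substr(g$seq, 1L, position - 1L),
                   ins_rc,
                   substr(g$seq, end + 1L, L))
  }
  out <- genome
  out$seq <- seq2
  new_row <- tibble::tibble(start = position, end = end,
                            cds_start = cds_start, cds_end = cds_end,
                            strand = strand, frame = frame,
                            protein = protein)
  attr(out, "embeds") <- if (is.null(embeds)) new_row else
    rbind(embeds, new_row)
  out
}

DECOY_PROFILES <- c("motifless", "lenient_only", "property_violating")

#' Generate decoy proteins with controlled violation profiles
#'
#' Decoys are 40-200 residues, start with `M`, and are constructed to a
#' named profile, checked on emission:
#' * `motifless` -- no glutamate anywhere, so no ESI mode can match;
#' * `lenient_only` -- exactly one `E`, followed by a residue outside the
#'   strict position-2 class and then a natural position-3 residue: the
#'   lenient modes match, the strict modes never do;
#' * `property_violating` -- carries a strict-natural ESI motif but is
#'   basic/Gly-Pro-rich and almost free of acidic residues, so it fails
#'   the property envelope of any acidic-inhibitor calibration.
#'
#' @param n Number of decoys.
#' @param seed Integer seed.
#' @param profile One of `"motifless"`, `"lenient_only"`,
#'   `"property_violating"`.
#' @return Character vector of `n` protein sequences.
#' @export
make_decoys <- function(n, seed, profile = DECOY_PROFILES) {
  profile <- match.arg(profile)
  stopifnot(n >= 0L)
  if (n == 0L) return(character())
  set.seed(as.integer(seed))
  no_e <- setdiff(AA_STANDARD, "E")
  out <- vapply(seq_len(n), function(i) {
    len <- sample(40:200, 1L)
    if (profile == "motifless") {
      body <- sample(no_e, len - 1L, replace = TRUE)
      paste0("M", paste(body, collapse = ""))
    } else if (profile == "lenient_only") {
      body <- sample(no_e, len - 1L, replace = TRUE)
      pos2 <- sample(c("D", "G", "K", "Q", "R", "Y"), 1L)  # outside strict class
      pos3 <- sample(ESI_POS3_NATURAL, 1L)
      at <- sample(2:(len - 3L), 1L)
      body[at:(at + 2L)] <- c("E", pos2, pos3)
      paste0("M", paste(body, collapse = ""))
    } else {
      pool <- c("G", "P", "K", "R", "S", "N", "T", "Q")
      body <- sample(pool, len - 1L, replace = TRUE)
      at <- sample(2:(len - 3L), 1L)
      body[at:(at + 2L)] <- c("E", "S", "I")
      paste0("M", paste(body, collapse = ""))
    }
  }, "")
  ok <- switch(profile,
    motifless = !Reduce(`|`, lapply(esi_modes(), function(m) has_esi_motif(out, m))),
    lenient_only = has_esi_motif(out, "lenient_natural") &
      !has_esi_motif(out, "strict_synthetic"),
    property_violating = has_esi_motif(out, "strict_natural"))
  if (!all(ok)) stop("decoy profile check failed on emission")  # construction bug
  out
}

#' Build a synthetic phage-like genome with embedded positives and decoys
#'
#' Generates a random genome at `gc_target`, then splices in the positive
#' proteins and the decoys of each requested profile as stop-flanked ORFs
#' at evenly spaced positions on alternating strands.
#'
#' @param length Genome length (nt), default 50 kb.
#' @param gc_target GC fraction, default 0.28 (the low-GC window where
#'   verified Ugi-encoding genomes concentrate).
#' @param seed Integer seed.
#' @param positives Character vector of positive protein sequences (or a
#'   protein tibble with a `seq` column).
#' @param decoys_per_profile Number of decoys of each profile in
#'   [DECOY_PROFILES] (default 10).
#' @return A list with `genome` (one-row genome tibble, `embeds`
#'   attribute set) and `truth` (tibble: `role`, `profile`, `protein`,
#'   `strand`, `frame`, `cds_start`, `cds_end`).
#' @export
synthetic_genome <- function(length = 50000L, gc_target = 0.28, seed = 1L,
                             positives = character(),
                             decoys_per_profile = 10L) {
  if (is.data.frame(positives)) positives <- positives$seq
  decs <- lapply(seq_along(DECOY_PROFILES), function(k) {
    make_decoys(decoys_per_profile, seed = seed + 1000L * k,
                profile = DECOY_PROFILES[k])
  })
  proteins <- c(positives, unlist(decs))
  roles <- c(rep("positive", length(positives)),
             rep("decoy", decoys_per_profile * length(DECOY_PROFILES)))
  profiles <- c(rep(NA_character_, length(positives)),
                rep(DECOY_PROFILES, each = decoys_per_profile))
  genome <- random_genome(length, gc_target, seed)
  ins_len <- 3L * nchar(proteins) + 6L
  gap <- (length - sum(ins_len)) %/% (length(proteins) + 1L)
  if (gap < 10L)
    stop("genome too short for the requested embeds")
  pos <- cumsum(c(gap, head(ins_len, -1L) + gap))
  strands <- rep(c("+", "-"), length.out = length(proteins))
  for (i in seq_along(proteins)) {
    genome <- embed_orf(genome, proteins[i], position = pos[i],
                        strand = strands[i], gc_target = gc_target)
  }
  emb <- attr(genome, "embeds")
  truth <- tibble::tibble(role = roles, profile = profiles,
                          protein = proteins, strand = emb$strand,
                          frame = emb$frame, cds_start = emb$cds_start,
                          cds_end = emb$cds_end)
  list(genome = genome, truth = truth)
}
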