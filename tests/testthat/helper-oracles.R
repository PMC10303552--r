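# Independent oracles for property-style tests. These deliberately avoid
# the implementation's machinery: translation uses a literal codon table,
# ORF enumeration scans windows directly, and the PROSITE oracle expands
# bounded repeats into fixed-length element lists before character-wise
# matching.

oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64); k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1; codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
})

oracle_translate <- function(nt) {
  nt <- toupper(nt)
  n3 <- nchar(nt) - nchar(nt) %% 3
  if (n3 < 3) return("")
  out <- character(n3 / 3)
  for (j in seq_len(n3 / 3)) {
    codon <- substr(nt, 3 * j - 2, 3 * j)
    out[j] <- if (codon %in% names(oracle_codon_table))
      oracle_codon_table[[codon]] else "X"
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(nt) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                            toupper(nt)), "")[[1]]), collapse = "")
}

# Brute-force putative-protein enumeration: all six frames, all
# stop-delimited windows, trim to first M/I/V/L, apply the length rule.
# Returns sorted aa sequences only (coordinates are checked separately via
# the re-translation invariant).
oracle_putative <- function(seq, min_len, length_check = "post_trim") {
  seq <- toupper(seq)
  out <- character()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (off in 0:2) {
      pep <- oracle_translate(substr(s, off + 1, nchar(s)))
      if (nchar(pep) == 0) next
      segs <- strsplit(pep, "*", fixed = TRUE)[[1]]
      for (seg in segs) {
        if (length_check == "pre_trim" && nchar(seg) < min_len) next
        m <- regexpr("[MIVL]", seg)
        if (m < 0) next
        trimmed <- substr(seg, m, nchar(seg))
        if (length_check == "post_trim" && nchar(trimmed) < min_len) next
        out <- c(out, trimmed)
      }
    }
  }
  sort(out)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# PROSITE oracle: expand every bounded repeat into each concrete length, so
# each expansion is a fixed list of single-position element sets; then test
# each (start, expansion) pair by direct character comparison. An 'X' in
# the sequence satisfies only wildcard positions (represented as NULL).
oracle_prosite_expansions <- function(elements) {
  expansions <- list(list())
  for (el in elements) {
    if (el$type == "fixed") {
      expansions <- lapply(expansions, function(e) c(e, list(el$residue)))
    } else if (el$type == "class") {
      expansions <- lapply(expansions, function(e) c(e, list(el$set)))
    } else {
      new <- list()
      for (len in el$min:el$max) {
        pads <- rep(list(NULL), len)
        new <- c(new, lapply(expansions, function(e) c(e, pads)))
      }
      expansions <- new
    }
  }
  expansions
}

oracle_prosite_match <- function(pattern_string, seq) {
  elements <- ungmine::compile_prosite(pattern_string)$elements
  expansions <- oracle_prosite_expansions(elements)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  hits <- list()
  for (start in seq_len(max(n, 0))) {
    for (exp in expansions) {
      len <- length(exp)
      if (len == 0 || start + len - 1 > n) next
      ok <- TRUE
      for (k in seq_len(len)) {
        want <- exp[[k]]
        have <- chars[start + k - 1]
        if (!is.null(want) && !(have %in% want)) { ok <- FALSE; break }
      }
      if (ok) hits[[length(hits) + 1]] <- c(start, start + len - 1)
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), end = integer()))
  m <- unique(do.call(rbind, hits))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

# Random PROSITE pattern of <= max_el elements (fixed residues, small
# classes, wildcards with modest repeat bounds).
random_pattern <- function(seed, max_el = 6) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- sample(2:max_el, 1)
  toks <- vapply(seq_len(n), function(i) {
    kind <- sample(c("fixed", "class", "x", "xn", "xnm"), 1)
    switch(kind,
      fixed = sample(aa, 1),
      class = paste0("[", paste(sample(aa, sample(2:4, 1)), collapse = ""), "]"),
      x = "X",
      xn = sprintf("X(%d)", sample(0:3, 1)),
      xnm = { lo <- sample(0:2, 1); sprintf("X(%d,%d)", lo, lo + sample(0:2, 1)) })
  }, "")
  paste(toks, collapse = "-")
}

toy_genome <- function(seq, id = "g1") {
  tibble::tibble(id = id, description = "", seq = toupper(seq))
}

# Encode a peptide (with '*' for stops) as frame +1 DNA, using fixed
# codons independent of the package's reverse_translate.
dna_encode <- function(pep) {
  paste(vapply(strsplit(pep, "")[[1]], function(a) {
    if (a == "*") "TAA" else names(oracle_codon_table)[
      match(a, oracle_codon_table)]
  }, ""), collapse = "")
}
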