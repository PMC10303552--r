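test_that("reverse complement handles IUPAC codes and is an involution", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement("AN"), "NT")
  expect_equal(reverse_complement("ARYC"), "GRYT")
  for (s in vapply(1:10, function(i) random_dna(50, seed = i), "")) {
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s), oracle_revcomp(s))
  }
  expect_error(reverse_complement("AQC"))
})

test_that("six-frame translation follows the standard code with stops and X", {
  fr <- six_frame_translate(toy_genome("ATGAAA"))
  expect_equal(fr$peptide[fr$frame == "+1"], "MK")
  expect_equal(fr$peptide[fr$frame == "-1"], "FH")
  fr2 <- six_frame_translate(toy_genome("ATGTAAATG"))
  expect_equal(fr2$peptide[fr2$frame == "+1"], "M*M")
  # unresolvable ambiguity becomes X; resolvable is translated
  fr3 <- six_frame_translate(toy_genome("GGNNNNTAA"))
  expect_equal(fr3$peptide[fr3$frame == "+1"], "GX*")
  expect_error(six_frame_translate(toy_genome("AT")), "shorter")
})

test_that("frame peptide lengths and strand relationship hold on random genomes", {
  for (i in 1:10) {
    g <- toy_genome(random_dna(60 + i * 7, seed = 40 + i))
    fr <- six_frame_translate(g)
    L <- nchar(g$seq)
    for (k in 1:3) {
      expect_equal(nchar(fr$peptide[fr$frame == sprintf("+%d", k)]),
                   (L - (k - 1)) %/% 3)
      expect_equal(fr$peptide[fr$frame == sprintf("-%d", k)],
                   oracle_translate(substr(oracle_revcomp(g$seq), k, L)))
    }
  }
})

test_that("putative-protein extraction trims to the first start residue", {
  # frame +1 peptide GGMKLV* -> trimmed to MKLV
  g <- toy_genome(dna_encode("GGMKLV*"))
  got <- extract_putative_proteins(g, min_len = 3)
  p1 <- got[got$frame == "+1", ]
  expect_equal(p1$aa_seq, "MKLV")
  expect_equal(p1$trimmed_prefix_len, 2L)
  # re-check coordinates: the codons of MKLV start at nt 7
  expect_equal(p1$nt_start, 7L)
  expect_equal(p1$nt_end, 18L)

  # no start residue in the frame -> nothing from it
  g2 <- toy_genome(dna_encode("GGGG*"))
  got2 <- extract_putative_proteins(g2, min_len = 1)
  expect_equal(nrow(got2[got2$frame == "+1", ]), 0L)

  # X is not a start residue
  g3 <- toy_genome(paste0("NNN", dna_encode("MKL"), "TAA"))
  got3 <- extract_putative_proteins(g3, min_len = 2)
  expect_true("MKL" %in% got3$aa_seq)
  expect_false(any(grepl("^X", got3$aa_seq)))
})

test_that("the length minimum applies post-trim by default, pre-trim on request", {
  # stop-to-stop segment of 6 residues trimmed to 4
  g <- toy_genome(dna_encode(paste0("*GGMKLV*")))
  post <- extract_putative_proteins(g, min_len = 5)
  expect_false("MKLV" %in% post$aa_seq)
  pre <- extract_putative_proteins(g, min_len = 5, length_check = "pre_trim")
  expect_true("MKLV" %in% pre$aa_seq[pre$frame == "+1"])
  # raising min_len never increases the count (monotonicity)
  g4 <- toy_genome(random_dna(300, seed = 7))
  counts <- vapply(c(1, 5, 10, 20, 40), function(m)
    count_putative_proteins(g4, min_len = m), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("extraction agrees with the brute-force oracle on random genomes", {
  for (i in 1:25) {
    g <- toy_genome(random_dna(sample(30:300, 1), seed = 500 + i))
    for (mode in c("post_trim", "pre_trim")) {
      got <- extract_putative_proteins(g, min_len = 5, length_check = mode)
      expect_equal(sort(got$aa_seq),
                   oracle_putative(g$seq, min_len = 5, length_check = mode),
                   info = sprintf("seed %d mode %s", 500 + i, mode))
    }
  }
})

test_that("every emitted protein re-translates from its coordinates", {
  for (i in 1:8) {
    g <- toy_genome(random_dna(400, seed = 700 + i))
    got <- extract_putative_proteins(g, min_len = 10)
    expect_equal((got$nt_end - got$nt_start + 1), 3L * got$length)
    for (r in seq_len(nrow(got))) {
      nt <- substr(g$seq, got$nt_start[r], got$nt_end[r])
      if (startsWith(got$frame[r], "-")) nt <- oracle_revcomp(nt)
      expect_equal(oracle_translate(nt), got$aa_seq[r])
      expect_true(substr(got$aa_seq[r], 1, 1) %in% c("M", "I", "V", "L"))
    }
  }
})

test_that("minus-strand proteins equal plus-strand proteins of the reverse complement", {
  for (i in 1:10) {
    g <- toy_genome(random_dna(250, seed = 900 + i))
    rc <- toy_genome(oracle_revcomp(g$seq))
    fwd <- extract_putative_proteins(g, min_len = 5)
    rev <- extract_putative_proteins(rc, min_len = 5)
    expect_equal(sort(fwd$aa_seq[startsWith(fwd$frame, "-")]),
                 sort(rev$aa_seq[startsWith(rev$frame, "+")]))
  }
})

test_that("circular mode recovers an ORF spanning the origin exactly once", {
  # place MKLVNE... across the join: tail codons at the end, head at the start
  prot <- "MKLVNEQWHTYF"
  cds <- dna_encode(prot)
  tail_part <- paste0("TAA", substr(cds, 1, 18))       # stop + first 6 codons
  head_part <- paste0(substr(cds, 19, nchar(cds)), "TAA")
  mid <- random_dna(120, seed = 5)
  g <- toy_genome(paste0(head_part, mid, tail_part))
  lin <- extract_putative_proteins(g, min_len = nchar(prot))
  expect_false(prot %in% lin$aa_seq)
  circ <- extract_putative_proteins(g, min_len = nchar(prot), circular = TRUE)
  expect_equal(sum(circ$aa_seq == prot), 1L)
})
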