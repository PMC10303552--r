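refs <- ungin_references("ugi_saugi")

test_that("the permissive configuration passes every putative protein through", {
  g <- random_genome(6000, gc_target = 0.30, seed = 21)
  res <- run_pipeline(g, filter_config(orf_min_len = 20))
  expect_equal(nrow(res$candidates), res$n_proteins)
  expect_true(all(res$report$n_in == res$report$n_out))
})

test_that("stage report chains: each stage's input is the previous survivors", {
  sg <- synthetic_genome(length = 20000, gc_target = 0.28, seed = 31,
                         positives = refs$seq[1], decoys_per_profile = 3)
  cfg <- calibrate(refs, margin = 0.1)$config
  res <- run_pipeline(sg$genome, cfg)
  rep <- res$report
  expect_true(all(rep$n_out <= rep$n_in))
  expect_equal(rep$n_in[-1], rep$n_out[-nrow(rep)])
  expect_equal(rep$n_in[1], res$n_proteins)
  expect_equal(rep$n_out[nrow(rep)], nrow(res$candidates))
})

test_that("a calibrated cascade recovers a spiked positive among decoys", {
  sg <- synthetic_genome(length = 30000, gc_target = 0.28, seed = 41,
                         positives = refs$seq, decoys_per_profile = 5)
  cfg <- calibrate(refs, margin = 0)$config
  res <- run_pipeline(sg$genome, cfg)
  expect_true(all(refs$seq %in% res$candidates$aa_seq))
  bad <- sg$truth$protein[sg$truth$role == "decoy" &
                            sg$truth$profile == "property_violating"]
  expect_equal(sum(bad %in% res$candidates$aa_seq), 0L)
})

test_that("final candidate membership does not depend on the stage order", {
  # the cascade is a conjunction of independent predicates: dropping the
  # ESI stage from the config and intersecting manually, in any order,
  # gives the same set
  sg <- synthetic_genome(length = 20000, gc_target = 0.28, seed = 51,
                         positives = refs$seq[1:2], decoys_per_profile = 4)
  cfg <- calibrate(refs, margin = 0.05)$config
  res <- run_pipeline(sg$genome, cfg)
  # recompute membership predicate-by-predicate in reversed order
  prot <- extract_putative_proteins(sg$genome, min_len = cfg$orf_min_len)
  pv <- property_vector(prot$aa_seq)
  keep <- has_esi_motif(prot$aa_seq, cfg$esi_mode)
  keep <- keep & pv$mass_da >= cfg$mass_lo & pv$mass_da <= cfg$mass_hi
  keep <- keep & pv$acid_base_ratio >= cfg$ratio_min
  keep <- keep & pv$glypro_fraction >= cfg$glypro_lo &
    pv$glypro_fraction <= cfg$glypro_hi
  keep <- keep & pv$gravy >= cfg$gravy_lo & pv$gravy <= cfg$gravy_hi
  keep <- keep & pv$de_fraction >= cfg$de_lo & pv$de_fraction <= cfg$de_hi
  keep <- keep & pv$length >= cfg$min_len & pv$length <= cfg$max_len
  expect_setequal(res$candidates$protein_id, prot$protein_id[keep])
})

test_that("tightening any single bound never adds a candidate", {
  sg <- synthetic_genome(length = 20000, gc_target = 0.28, seed = 61,
                         positives = refs$seq, decoys_per_profile = 3)
  base <- calibrate(refs, margin = 0.2)$config
  n_base <- nrow(run_pipeline(sg$genome, base)$candidates)
  tighten <- list(
    function(c) { c$min_len <- c$min_len + 5; c },
    function(c) { c$de_lo <- c$de_lo * 1.2; c },
    function(c) { c$gravy_hi <- c$gravy_hi - 0.1; c },
    function(c) { c$ratio_min <- c$ratio_min + 0.5; c },
    function(c) { c$mass_hi <- c$mass_hi - 1500; c },
    function(c) { c$esi_mode <- "strict_natural"; c })
  for (f in tighten) {
    cfg <- f(base)
    expect_lte(nrow(run_pipeline(sg$genome, cfg)$candidates), n_base)
  }
})

test_that("bulk runs bin genomes by GC and flag the low-GC priority window", {
  g1 <- random_genome(4000, gc_target = 0.27, seed = 71, id = "low_gc")
  g2 <- random_genome(4000, gc_target = 0.52, seed = 72, id = "high_gc")
  genomes <- rbind(g1, g2)
  out <- run_bulk(genomes, filter_config(orf_min_len = 30))
  expect_equal(nrow(out$failures), 0L)
  bin_of <- function(id) out$genomes$gc_bin[out$genomes$id == id]
  expect_equal(bin_of("low_gc"), "[25,30)")
  expect_equal(bin_of("high_gc"), "[50,55)")
  expect_equal(out$bins$priority, c(TRUE, FALSE))
  expect_equal(sum(out$bins$n_genomes), 2L)
})

test_that("bulk candidates concentrate in priority bins when positives are low-GC", {
  cfg <- calibrate(refs, margin = 0)$config
  genomes <- do.call(rbind, lapply(seq_along(c(0.26, 0.30, 0.34)), function(i) {
    gc <- c(0.26, 0.30, 0.34)[i]
    sg <- synthetic_genome(length = 15000, gc_target = gc, seed = 80 + i,
                           positives = refs$seq[1], decoys_per_profile = 0)
    sg$genome
  }))
  genomes$id <- sprintf("g%d", 1:3)
  out <- run_bulk(genomes, cfg)
  expect_true(refs$seq[1] %in% out$candidates$aa_seq)
  expect_true(all(out$bins$priority[out$bins$n_candidates > 0]))
})

test_that("ESI-mode escalation is monotone for bulk candidate sets", {
  sg <- synthetic_genome(length = 25000, gc_target = 0.28, seed = 91,
                         positives = refs$seq[1:2], decoys_per_profile = 5)
  strict <- filter_config(esi_mode = "strict_natural", orf_min_len = 40)
  lenient <- filter_config(esi_mode = "lenient_synthetic", orf_min_len = 40)
  cs <- run_pipeline(sg$genome, strict)$candidates$protein_id
  cl <- run_pipeline(sg$genome, lenient)$candidates$protein_id
  expect_true(all(cs %in% cl))
})

test_that("serial relaxation recovers a positive failing exactly one stage", {
  # a near-positive whose Gly/Pro fraction alone leaves the envelope:
  # asparagine-to-glycine swaps keep length/acidity/ratio identical and
  # shift GRAVY and mass only slightly
  base_seq <- refs$seq[refs$id == "Ugi2_like_synthetic"]
  gp_violator <- chartr("N", "G", base_seq)
  sg <- synthetic_genome(length = 20000, gc_target = 0.28, seed = 101,
                         positives = gp_violator, decoys_per_profile = 0)
  cfg <- calibrate(refs, margin = 0.1)$config
  full <- run_pipeline(sg$genome, cfg)
  expect_false(gp_violator %in% full$candidates$aa_seq)
  relaxed <- relax_serially(sg$genome, cfg)
  hit_stages <- names(relaxed)[vapply(relaxed, function(r)
    gp_violator %in% r$candidates$aa_seq, TRUE)]
  expect_equal(hit_stages, "gly_pro")
  # disabling a stage never shrinks the candidate set
  for (r in relaxed)
    expect_gte(nrow(r$candidates), nrow(full$candidates))
})

test_that("configurations survive a YAML round-trip including infinities", {
  cfg <- filter_config(min_len = 40, max_len = Inf, gravy_lo = -Inf,
                       gravy_hi = 0.5, esi_mode = "strict_synthetic",
                       extra_patterns = "E-X(2)-Y-X(0,2)-G")
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_filter_config(cfg, tf)
  back <- read_filter_config(tf)
  expect_equal(unclass(back), unclass(cfg))
  dflt <- default_filter_config()
  expect_s3_class(dflt, "filter_config")
  expect_equal(dflt$esi_mode, "strict_natural")
})
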