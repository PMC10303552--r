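# The triage cascade: length -> acidity -> hydrophobicity -> Gly/Pro ->
# acid:base ratio -> mass -> ESI motif, with GC binning for bulk inputs.
# Each stage is an independent predicate over the per-protein property
# vector, so final candidate membership is order-invariant; the cascade
# order only shapes the per-stage survivor report.

PIPELINE_STAGES <- c("length", "acidity", "hydrophobicity", "gly_pro",
                     "acid_base_ratio", "mass", "esi")

#' Filter cascade configuration
#'
#' All bounds are inclusive. The default configuration is fully permissive
#' (every bound infinite, ESI filter disabled): `run_pipeline()` under it
#' returns every putative protein. Use [default_filter_config()] for the
#' thresholds calibrated on the bundled inhibitor references, or
#' [calibrate()] to fit your own.
#'
#' @param min_len,max_len Protein length bounds (residues).
#' @param de_lo,de_hi Bounds on the D+E fraction of the chain (acidity).
#' @param gravy_lo,gravy_hi Bounds on GRAVY (mean Kyte-Doolittle hydropathy).
#' @param glypro_lo,glypro_hi Bounds on the G+P fraction.
#' @param ratio_min Lower bound on the acidic-to-basic residue ratio
#'   (sequences with no basic residue have ratio `Inf` and always pass).
#' @param mass_lo,mass_hi Molecular mass bounds (Da).
#' @param esi_mode One of [esi_modes()], or `NA` to disable the ESI filter.
#' @param glypro_enabled Set `FALSE` to inactivate the Gly/Pro stage (the
#'   serial-relaxation experiment).
#' @param extra_patterns Optional character vector of PROSITE patterns that
#'   must all be present in a candidate (bulk screens for additional
#'   motifs); `NULL` disables the stage.
#' @param gc_bin_width GC bin width for bulk runs, in percent (default 5).
#' @param gc_priority_range Two-element percent range flagged as the
#'   priority GC window (default `c(25, 35)`, where verified Ugi-encoding
#'   genomes concentrate).
#' @param orf_min_len Minimum putative-protein length passed to extraction
#'   (default 40).
#' @param length_check Passed to [extract_putative_proteins()].
#' @param circular Passed to [extract_putative_proteins()].
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_len = 1, max_len = Inf,
                          de_lo = -Inf, de_hi = Inf,
                          gravy_lo = -Inf, gravy_hi = Inf,
                          glypro_lo = -Inf, glypro_hi = Inf,
                          ratio_min = -Inf,
                          mass_lo = -Inf, mass_hi = Inf,
                          esi_mode = NA_character_,
                          glypro_enabled = TRUE,
                          extra_patterns = NULL,
                          gc_bin_width = 5,
                          gc_priority_range = c(25, 35),
                          orf_min_len = 40,
                          length_check = "post_trim",
                          circular = FALSE) {
  cfg <- list(min_len = min_len, max_len = max_len,
              de_lo = de_lo, de_hi = de_hi,
              gravy_lo = gravy_lo, gravy_hi = gravy_hi,
              glypro_lo = glypro_lo, glypro_hi = glypro_hi,
              ratio_min = ratio_min,
              mass_lo = mass_lo, mass_hi = mass_hi,
              esi_mode = esi_mode,
              glypro_enabled = isTRUE(glypro_enabled),
              extra_patterns = extra_patterns,
              gc_bin_width = gc_bin_width,
              gc_priority_range = gc_priority_range,
              orf_min_len = as.integer(orf_min_len),
              length_check = match.arg(length_check, c("post_trim", "pre_trim")),
              circular = isTRUE(circular))
  for (pair in list(c("min_len", "max_len"), c("de_lo", "de_hi"),
                    c("gravy_lo", "gravy_hi"), c("glypro_lo", "glypro_hi"),
                    c("mass_lo", "mass_hi"))) {
    if (cfg[[pair[1L]]] > cfg[[pair[2L]]])
      stop(sprintf("%s > %s", pair[1L], pair[2L]))
  }
  if (!is.na(cfg$esi_mode)) cfg$esi_mode <- match.arg(cfg$esi_mode, esi_modes())
  if (cfg$orf_min_len < 1L) stop("orf_min_len must be >= 1")
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat(sprintf("  length          [%s, %s]\n", x$min_len, x$max_len))
  cat(sprintf("  de_fraction     [%.4g, %.4g]\n", x$de_lo, x$de_hi))
  cat(sprintf("  gravy           [%.4g, %.4g]\n", x$gravy_lo, x$gravy_hi))
  cat(sprintf("  glypro_fraction [%.4g, %.4g]%s\n", x$glypro_lo, x$glypro_hi,
              if (x$glypro_enabled) "" else "  (disabled)"))
  cat(sprintf("  acid:base ratio >= %.4g\n", x$ratio_min))
  cat(sprintf("  mass_da         [%.4g, %.4g]\n", x$mass_lo, x$mass_hi))
  cat(sprintf("  esi_mode        %s\n", x$esi_mode))
  invisible(x)
}

# Logical pass/fail per protein per stage; proteins as a property tibble
# (with aa_seq column). Disabled stages pass everything.
stage_pass_matrix <- function(props, config) {
  n <- nrow(props)
  esi <- if (is.na(config$esi_mode)) rep(TRUE, n) else
    has_esi_motif(props$aa_seq, config$esi_mode)
  extra <- rep(TRUE, n)
  if (!is.null(config$extra_patterns) && length(config$extra_patterns) > 0L) {
    pats <- lapply(config$extra_patterns, compile_prosite)
    extra <- vapply(props$aa_seq, function(s) {
      all(vapply(pats, function(p) nrow(find_matches(p, s)) > 0L, TRUE))
    }, TRUE, USE.NAMES = FALSE)
  }
  m <- cbind(
    length = props$length >= config$min_len & props$length <= config$max_len,
    acidity = props$de_fraction >= config$de_lo & props$de_fraction <= config$de_hi,
    hydrophobicity = props$gravy >= config$gravy_lo & props$gravy <= config$gravy_hi,
    gly_pro = if (config$glypro_enabled)
      props$glypro_fraction >= config$glypro_lo &
      props$glypro_fraction <= config$glypro_hi else rep(TRUE, n),
    acid_base_ratio = props$acid_base_ratio >= config$ratio_min,
    mass = props$mass_da >= config$mass_lo & props$mass_da <= config$mass_hi,
    esi = esi)
  if (!is.null(config$extra_patterns)) m <- cbind(m, extra_motifs = extra)
  m[is.na(m)] <- FALSE
  m
}

protein_properties <- function(proteins) {
  tmpl <- property_vector("A")
  tmpl$length <- NULL  # length is already a column of the extraction table
  if (nrow(proteins) == 0L) {
    return(tibble::as_tibble(cbind(proteins, tmpl[0, ])))
  }
  pv <- property_vector(proteins$aa_seq)
  pv$length <- NULL
  tibble::as_tibble(cbind(proteins, pv))
}

cascade_report <- function(pass) {
  stages <- colnames(pass)
  surviving <- rep(TRUE, nrow(pass))
  n_in <- integer(length(stages)); n_out <- integer(length(stages))
  for (k in seq_along(stages)) {
    n_in[k] <- sum(surviving)
    surviving <- surviving & pass[, k]
    n_out[k] <- sum(surviving)
  }
  tibble::tibble(stage = stages, n_in = n_in, n_out = n_out)
}

#' Run the heuristic triage pipeline on one genome
#'
#' Extracts putative proteins, computes their property vectors and applies
#' the filter cascade in the fixed order length, acidity, hydrophobicity,
#' Gly/Pro, acid:base ratio, mass, ESI motif (plus an extra-motif stage if
#' configured). The final candidate set is the conjunction of all enabled
#' stage predicates, so it does not depend on the stage order.
#'
#' @param genome A one-row genome record (fields `id`, `seq`).
#' @param config A [filter_config()].
#' @return A list with `candidates` (surviving proteins with their
#'   property columns, ordered by frame then `nt_start`), `report`
#'   (per-stage `n_in`/`n_out` counts) and `n_proteins` (the
#'   putative-protein denominator).
#' @export
run_pipeline <- function(genome, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  proteins <- extract_putative_proteins(
    genome, min_len = config$orf_min_len,
    length_check = config$length_check, circular = config$circular)
  props <- protein_properties(proteins)
  pass <- stage_pass_matrix(props, config)
  keep <- if (nrow(props) == 0L) logical(0) else rowSums(!pass) == 0L
  list(candidates = props[keep, , drop = FALSE],
       report = cascade_report(pass),
       n_proteins = nrow(proteins))
}

gc_bin_label <- function(gc_pct, width) {
  lo <- floor(gc_pct / width) * width
  sprintf("[%g,%g)", lo, lo + width)
}

#' Run the pipeline over many genomes with GC binning
#'
#' Each genome is assigned to the half-open GC bin containing its
#' whole-genome GC content, then triaged independently. Genomes whose GC
#' falls in `gc_priority_range` are flagged: verified Ugi-type inhibitors
#' concentrate in low-GC (25-35%) genomes. Failures in individual genomes
#' are collected, not fatal.
#'
#' @param genomes A tibble of genome records (columns `id`, `seq`).
#' @param config A [filter_config()].
#' @return A list with `candidates` (row-bound candidate sets with a
#'   `gc` column), `report` (aggregate stage counts), `bins` (per-bin
#'   genome/candidate counts with a `priority` flag), `genomes`
#'   (per-genome gc, bin, counts) and `failures` (id + error message).
#' @export
run_bulk <- function(genomes, config = filter_config()) {
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 1L)
  per <- vector("list", nrow(genomes))
  fail_id <- character(); fail_msg <- character()
  gcs <- rep(NA_real_, nrow(genomes))
  ncand <- rep(NA_integer_, nrow(genomes))
  nprot <- rep(NA_integer_, nrow(genomes))
  agg_report <- NULL
  for (i in seq_len(nrow(genomes))) {
    res <- tryCatch({
      g <- genomes[i, , drop = FALSE]
      gc <- gc_content(g$seq)
      out <- run_pipeline(g, config)
      list(gc = gc, out = out)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail_id <- c(fail_id, genomes$id[i])
      fail_msg <- c(fail_msg, conditionMessage(res))
      next
    }
    gcs[i] <- res$gc
    ncand[i] <- nrow(res$out$candidates)
    nprot[i] <- res$out$n_proteins
    cand <- res$out$candidates
    if (nrow(cand) > 0L) cand$gc <- res$gc
    per[[i]] <- cand
    agg_report <- if (is.null(agg_report)) res$out$report else {
      r <- agg_report
      r$n_in <- r$n_in + res$out$report$n_in
      r$n_out <- r$n_out + res$out$report$n_out
      r
    }
  }
  ok <- !is.na(gcs)
  gc_pct <- gcs * 100
  width <- config$gc_bin_width
  bin <- ifelse(ok, gc_bin_label(gc_pct, width), NA_character_)
  per_genome <- tibble::tibble(id = genomes$id, gc = gcs, gc_bin = bin,
                               n_proteins = nprot, n_candidates = ncand)
  bins <- NULL
  if (any(ok)) {
    lo <- floor(gc_pct[ok] / width) * width
    split_idx <- split(which(ok), lo)
    bins <- tibble::tibble(
      bin_lo = as.numeric(names(split_idx)),
      bin_hi = as.numeric(names(split_idx)) + width,
      n_genomes = vapply(split_idx, length, 1L),
      n_candidates = vapply(split_idx, function(ix) sum(ncand[ix]), 1L))
    bins$bin <- sprintf("[%g,%g)", bins$bin_lo, bins$bin_hi)
    pr <- config$gc_priority_range
    bins$priority <- bins$bin_lo < pr[2L] & bins$bin_hi > pr[1L]
    bins <- bins[order(bins$bin_lo),
                 c("bin", "bin_lo", "bin_hi", "n_genomes", "n_candidates",
                   "priority")]
  }
  cand_all <- do.call(rbind, per[!vapply(per, is.null, TRUE)])
  if (is.null(cand_all)) {
    cand_all <- protein_properties(
      extract_putative_proteins(list(id = "x", seq = "AAA"), min_len = 1L))[0, ]
  }
  list(candidates = tibble::as_tibble(cand_all), report = agg_report,
       bins = bins, genomes = per_genome,
       failures = tibble::tibble(id = fail_id, message = fail_msg))
}

#' Serial single-stage relaxation of the cascade
#'
#' Re-runs the pipeline disabling one stage at a time, in cascade order --
#' the leniency experiment that recovers candidates failing exactly one
#' filter (e.g. the Gly/Pro content stage in low-GC genomes).
#'
#' @param genome A one-row genome record.
#' @param config A [filter_config()].
#' @return A named list, one entry per disabled stage, each with
#'   `disabled` (stage name) and `candidates`.
#' @export
relax_serially <- function(genome, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  proteins <- extract_putative_proteins(
    genome, min_len = config$orf_min_len,
    length_check = config$length_check, circular = config$circular)
  props <- protein_properties(proteins)
  pass <- stage_pass_matrix(props, config)
  stages <- colnames(pass)
  out <- lapply(seq_along(stages), function(k) {
    keep <- if (nrow(props) == 0L) logical(0) else
      rowSums(!pass[, -k, drop = FALSE]) == 0L
    list(disabled = stages[k], candidates = props[keep, , drop = FALSE])
  })
  names(out) <- stages
  out
}

#' Read / write a filter configuration as YAML
#'
#' Infinite bounds are stored as the strings `".inf"`/`"-.inf"` per YAML
#' convention and restored on read.
#'
#' @param path YAML file path.
#' @param config A [filter_config()].
#' @return `read_filter_config()` returns a `filter_config`;
#'   `write_filter_config()` invisibly returns `path`.
#' @export
read_filter_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$extra_patterns <- if (length(raw$extra_patterns) == 0L) NULL else
    unlist(raw$extra_patterns)
  raw$gc_priority_range <- unlist(raw$gc_priority_range)
  do.call(filter_config, raw)
}

#' @rdname read_filter_config
#' @export
write_filter_config <- function(config, path) {
  stopifnot(inherits(config, "filter_config"))
  x <- unclass(config)
  if (is.null(x$extra_patterns)) x$extra_patterns <- list()
  yaml::write_yaml(x, path)
  invisible(path)
}

#' The calibrated default configuration
#'
#' Reads the configuration shipped with the package, fitted by
#' [calibrate()] on the bundled Ugi/SAUGI-type reference set with a 10%
#' relative margin and the strict natural ESI mode.
#'
#' @return A `filter_config`.
#' @export
default_filter_config <- function() {
  read_filter_config(system.file("extdata", "default_config.yaml",
                                 package = "ungmine", mustWork = TRUE))
}
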