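# Threshold calibration: the tuning rule is the deterministic min/max
# envelope over known positives, optionally widened by a relative margin.
# For independent interval filters this exactly solves "retain every
# positive with as few false positives as possible": any tighter bound
# rejects a positive, any wider one can only admit more background.

widen_lo <- function(x, margin) x - margin * abs(x)
widen_hi <- function(x, margin) x + margin * abs(x)

#' Calibrate the filter cascade on known positive sequences
#'
#' Fits every scalar bound of the cascade to the min/max envelope of the
#' positives' property vectors, widened outward by `margin` (a relative
#' fraction). The acid:base ratio lower bound is the minimum over
#' positives, shrunk by `margin`. Every positive must contain the ESI
#' motif under `esi_mode`, otherwise calibration errors naming the first
#' offending sequence. If `background` genomes are given, the fitted
#' configuration is run over them with [run_bulk()] and surviving
#' sequences not identical to a positive are counted as false positives.
#'
#' @param positives A protein tibble (columns `id`, `seq`) of verified
#'   inhibitor sequences, e.g. [ungin_references()].
#' @param background Optional genome tibble (columns `id`, `seq`).
#' @param margin Relative widening applied outward to every bound
#'   (default 0, the tight envelope).
#' @param esi_mode ESI leniency mode to validate and fix (see
#'   [esi_modes()]).
#' @param base_config A `filter_config` providing the non-fitted settings
#'   (GC binning, ORF extraction options).
#' @return An object of class `calibration_result`: `config` (the fitted
#'   `filter_config`), `envelope` (per-attribute min/max over positives),
#'   `retained` (named logical: does each positive pass the fitted
#'   config), `fp_count` (background false positives, `NA` without
#'   background).
#' @export
calibrate <- function(positives, background = NULL, margin = 0,
                      esi_mode = "strict_natural",
                      base_config = filter_config()) {
  stopifnot(is.data.frame(positives), all(c("id", "seq") %in% names(positives)))
  if (nrow(positives) == 0L) stop("at least one positive sequence is required")
  stopifnot(margin >= 0)
  esi_mode <- match.arg(esi_mode, esi_modes())
  ok <- has_esi_motif(positives$seq, esi_mode)
  if (!all(ok))
    stop(sprintf("positive '%s' lacks the ESI motif under mode '%s'",
                 positives$id[which(!ok)[1L]], esi_mode))
  pv <- property_vector(positives$seq)
  env <- tibble::tibble(
    attribute = c("length", "de_fraction", "gravy", "glypro_fraction",
                  "mass_da", "acid_base_ratio"),
    min = c(min(pv$length), min(pv$de_fraction), min(pv$gravy),
            min(pv$glypro_fraction), min(pv$mass_da), min(pv$acid_base_ratio)),
    max = c(max(pv$length), max(pv$de_fraction), max(pv$gravy),
            max(pv$glypro_fraction), max(pv$mass_da), max(pv$acid_base_ratio)))
  cfg <- filter_config(
    min_len = widen_lo(min(pv$length), margin),
    max_len = widen_hi(max(pv$length), margin),
    de_lo = widen_lo(min(pv$de_fraction), margin),
    de_hi = widen_hi(max(pv$de_fraction), margin),
    gravy_lo = widen_lo(min(pv$gravy), margin),
    gravy_hi = widen_hi(max(pv$gravy), margin),
    glypro_lo = widen_lo(min(pv$glypro_fraction), margin),
    glypro_hi = widen_hi(max(pv$glypro_fraction), margin),
    ratio_min = widen_lo(min(pv$acid_base_ratio), margin),
    mass_lo = widen_lo(min(pv$mass_da), margin),
    mass_hi = widen_hi(max(pv$mass_da), margin),
    esi_mode = esi_mode,
    glypro_enabled = base_config$glypro_enabled,
    extra_patterns = base_config$extra_patterns,
    gc_bin_width = base_config$gc_bin_width,
    gc_priority_range = base_config$gc_priority_range,
    orf_min_len = base_config$orf_min_len,
    length_check = base_config$length_check,
    circular = base_config$circular)

  props <- cbind(tibble::tibble(aa_seq = positives$seq), pv)
  pass <- stage_pass_matrix(props, cfg)
  retained <- setNames(rowSums(!pass) == 0L, positives$id)

  fp_count <- NA_integer_
  if (!is.null(background) && nrow(background) > 0L) {
    bulk <- run_bulk(background, cfg)
    fp_count <- sum(!(bulk$candidates$aa_seq %in% positives$seq))
  }
  structure(list(config = cfg, envelope = env, retained = retained,
                 fp_count = fp_count, margin = margin, esi_mode = esi_mode),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d positives, margin %.3g, esi_mode %s\n",
              length(x$retained), x$margin, x$esi_mode))
  print(x$envelope)
  cat(sprintf("retained: %d/%d; background false positives: %s\n",
              sum(x$retained), length(x$retained),
              ifelse(is.na(x$fp_count), "not assessed", x$fp_count)))
  invisible(x)
}

#' False-positive profile across ESI leniency modes
#'
#' Calibrates once per mode (same positives, same margin) and counts
#' background false positives; counts are non-decreasing along each chain
#' of the leniency lattice (strict implies lenient at position 2, natural
#' implies synthetic at position 3).
#'
#' @inheritParams calibrate
#' @param modes Character vector of ESI modes to profile.
#' @return A tibble with columns `mode`, `fp_count`.
#' @export
leniency_profile <- function(positives, background, modes = esi_modes(),
                             margin = 0, base_config = filter_config()) {
  fp <- vapply(modes, function(m) {
    res <- calibrate(positives, background = background, margin = margin,
                     esi_mode = m, base_config = base_config)
    if (is.na(res$fp_count)) 0L else as.integer(res$fp_count)
  }, integer(1L))
  tibble::tibble(mode = modes, fp_count = unname(fp))
}
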