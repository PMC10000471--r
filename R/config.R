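#' Pipeline configuration
#'
#' Bundles the assay geometry, the three channel models and the caller
#' tuning parameters. All defaults are the package's standard assay values;
#' any field can be overridden here or via a YAML file
#' ([read_fmca_config()]).
#'
#' @param channels named list of three [channel_model()]s.
#' @param assay a [probe_assay()].
#' @param smoothing_window Savitzky-Golay window for
#'   [negative_derivative()] (grid points, odd).
#' @param min_prominence_fraction peak screening threshold for
#'   [detect_peaks()].
#' @param tm_tolerance Tm bin half-width (degrees C) for species
#'   assignment.
#' @param ratio_threshold SEC1P peak-height ratio threshold for fusion
#'   zygosity (see [call_fut2()]).
#' @param classifier `"peaks"` (peak-pattern caller, default) or
#'   `"score_resolution"` (reference-curve grouping for FUT2).
#' @param score_threshold,resolution_threshold thresholds for the
#'   score/resolution classifier.
#' @param references optional named list of reference `derivative_curve`s
#'   for the score/resolution classifier; built from zero-noise standards
#'   when `NULL`.
#' @param vcf_sites data.frame of variant-site metadata for
#'   [write_calls_vcf()] (defaults to [default_vcf_sites()]).
#' @return An `fmca_config` list.
#' @export
fmca_config <- function(channels = default_channels(),
                        assay = probe_assay(),
                        smoothing_window = 11L,
                        min_prominence_fraction = 0.15,
                        tm_tolerance = 1.5,
                        ratio_threshold = 0.75,
                        classifier = c("peaks", "score_resolution"),
                        score_threshold = 0.70,
                        resolution_threshold = 0.10,
                        references = NULL,
                        vcf_sites = default_vcf_sites()) {
  classifier <- match.arg(classifier)
  structure(
    list(channels = channels, assay = assay,
         smoothing_window = as.integer(smoothing_window),
         min_prominence_fraction = min_prominence_fraction,
         tm_tolerance = tm_tolerance,
         ratio_threshold = ratio_threshold,
         classifier = classifier,
         score_threshold = score_threshold,
         resolution_threshold = resolution_threshold,
         references = references,
         vcf_sites = vcf_sites),
    class = "fmca_config"
  )
}

#' Variant-site metadata for VCF output
#'
#' dbSNP identifiers for the three assayed SNPs plus a symbolic record for
#' the SEC1P-FUT2 fusion allele. Genomic positions are approximate GRCh38
#' placeholders (the assay itself works in gene-local coordinates); adjust
#' them via [fmca_config()] if exact coordinates matter downstream.
#'
#' @return Data.frame with columns `site`, `chrom`, `pos`, `id`, `ref`,
#'   `alt`.
#' @export
default_vcf_sites <- function() {
  data.frame(
    site = c("c.385A>T", "fusion", "c.59T>G", "c.314C>T"),
    chrom = c("chr19", "chr19", "chr19", "chr19"),
    pos = c(48703160L, 48695000L, 5844649L, 5844394L),
    id = c("rs1047781", "FUT2_SEC1P_FUS", "rs28362459", "rs778986"),
    ref = c("A", "N", "T", "C"),
    alt = c("T", "<FUS>", "G", "T"),
    stringsAsFactors = FALSE
  )
}

#' Read a YAML configuration file
#'
#' The file may override any subset of the defaults. Recognised top-level
#' keys: `assay` (primer/probe strings and spans, passed to
#' [probe_assay()]), `channels` (per-channel `species_tm`,
#' `transition_width`, `amplitude_per_copy`, `baseline_intercept`,
#' `baseline_slope`, `noise_sd`), and `caller` (`smoothing_window`,
#' `min_prominence_fraction`, `tm_tolerance`, `ratio_threshold`,
#' `classifier`, `score_threshold`, `resolution_threshold`).
#'
#' @param path YAML file path.
#' @return An [fmca_config()].
#' @export
read_fmca_config <- function(path) {
  y <- yaml::read_yaml(path)
  assay <- if (is.null(y$assay)) probe_assay() else {
    a <- y$assay
    do.call(probe_assay, a[intersect(names(a), names(formals(probe_assay)))])
  }
  channels <- default_channels()
  for (ch in intersect(names(y$channels), names(channels))) {
    o <- y$channels[[ch]]
    args <- list(channel = ch)
    for (f in c("transition_width", "amplitude_per_copy",
                "baseline_intercept", "baseline_slope", "noise_sd")) {
      if (!is.null(o[[f]])) args[[f]] <- o[[f]]
    }
    if (!is.null(o$species_tm)) args$species_tm <- unlist(o$species_tm)
    channels[[ch]] <- do.call(channel_model, args)
  }
  caller_args <- y$caller %||% list()
  do.call(fmca_config, c(list(channels = channels, assay = assay),
                         caller_args[intersect(names(caller_args),
                                               names(formals(fmca_config)))]))
}
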