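.check_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("file not found: ", path)
  }
  invisible(path)
}

#' Read a melting-curve table
#'
#' Long-format TSV with header `subject_id  channel  temperature
#' fluorescence`, one row per acquisition point. Temperatures must be
#' strictly increasing on a uniform grid within each (subject, channel).
#'
#' @param path TSV file path.
#' @return A `curve_set` data.frame.
#' @export
read_curves <- function(path) {
  .check_file(path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  required <- c("subject_id", "channel", "temperature", "fluorescence")
  if (!identical(header, required)) {
    stop("malformed curve table ", path, ": expected header '",
         paste(required, collapse = "\t"), "'")
  }
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "numeric", "numeric"))
  bad_ch <- setdiff(unique(df$channel), c("HEX", "FAM", "CY5"))
  if (length(bad_ch)) {
    stop("unknown channel(s) in ", path, ": ",
         paste(bad_ch, collapse = ", "))
  }
  bad <- which(is.na(df$temperature) | is.na(df$fluorescence))
  if (length(bad)) {
    stop("malformed row at line ", bad[1L] + 1L, " of ", path)
  }
  for (key in split(seq_len(nrow(df)),
                    paste(df$subject_id, df$channel, sep = "\r"))) {
    .check_uniform_grid(df$temperature[key])
  }
  class(df) <- c("curve_set", "data.frame")
  df
}

#' Write a melting-curve table
#'
#' Temperatures are written at 0.1-degree precision, fluorescence at full
#' float precision, so [read_curves()] round-trips losslessly.
#'
#' @param curves a `curve_set` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  df <- as.data.frame(curves)
  df$temperature <- sprintf("%.1f", df$temperature)
  df$fluorescence <- sprintf("%.10g", df$fluorescence)
  utils::write.table(df[, c("subject_id", "channel", "temperature",
                            "fluorescence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort genotype-configuration table
#'
#' @param path TSV path; defaults to the shipped 96-subject Japanese
#'   reference cohort.
#' @return Data.frame with one row per genotype configuration (columns
#'   `c385`, `fusion_copies`, `fut2_genotype`, `secretor_phenotype`, `c59`,
#'   `c314`, `fut3_genotype`, `lewis_phenotype`, `count`).
#' @export
read_genotype_fixture <- function(path = system.file(
    "extdata", "cohort_genotypes_japanese96.tsv", package = "fmcaller")) {
  .check_file(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("c385", "fusion_copies", "fut2_genotype",
                "secretor_phenotype", "c59", "c314", "fut3_genotype",
                "lewis_phenotype", "count")
  if (!all(required %in% names(df))) {
    stop("genotype fixture ", path, " is missing columns: ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  df
}

#' Write per-subject genotype calls as TSV
#' @param calls data.frame from [call_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype-calls TSV written by [write_calls()]
#' @param path input path.
#' @return Data.frame of calls.
#' @export
read_calls <- function(path) {
  .check_file(path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write per-subject Lewis reports as TSV
#' @param reports data.frame from [lewis_reports()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  utils::write.table(reports, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Lewis-report TSV written by [write_reports()]
#' @param path input path.
#' @return Data.frame of reports.
#' @export
read_reports <- function(path) {
  .check_file(path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write genotype calls as a VCF file
#'
#' Emits three SNP records carrying the dbSNP identifiers of c.385A>T,
#' c.59T>G and c.314C>T, plus one symbolic-allele record (`<FUS>`, INFO
#' flag `FUSION`) for the SEC1P-FUT2 fusion, with one GT column per
#' subject. A fusion chromosome carries the reference A at the c.385 SNP
#' record (sequence-true) and an alternate allele at the symbolic record.
#' Undetermined calls are written as `./.`.
#'
#' @param calls data.frame from [call_cohort()].
#' @param path output VCF path.
#' @param sites site metadata (see [default_vcf_sites()]).
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, sites = default_vcf_sites()) {
  n_alt <- function(group) switch(group, hom_ref = 0L, het = 1L,
                                  hom_alt = 2L, NA_integer_)
  gt <- function(k) if (is.na(k)) "./." else c("0/0", "0/1", "1/1")[k + 1L]
  # per-subject alt-allele dosages at the four records
  fus_copies <- vapply(calls$fut2_group, function(g) {
    switch(g, "fusion/fusion" = 2L, "385A/fusion" = 1L,
           "385T/fusion" = 1L,
           "385A/A" = 0L, "385A/T" = 0L, "385T/T" = 0L, NA_integer_)
  }, integer(1))
  t385 <- vapply(calls$fut2_group, function(g) {
    switch(g, "385A/A" = 0L, "385A/fusion" = 0L, "fusion/fusion" = 0L,
           "385A/T" = 1L, "385T/fusion" = 1L, "385T/T" = 2L, NA_integer_)
  }, integer(1))
  dosage <- list(
    "c.385A>T" = t385,
    "fusion" = fus_copies,
    "c.59T>G" = vapply(calls$c59_group, n_alt, integer(1)),
    "c.314C>T" = vapply(calls$c314_group, n_alt, integer(1))
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fmcaller",
    "##ALT=<ID=FUS,Description=\"SEC1P-FUT2 fusion allele (se^fus)\">",
    paste0("##INFO=<ID=FUSION,Number=0,Type=Flag,Description=",
           "\"Symbolic SEC1P-FUT2 fusion-allele record\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$subject_id), collapse = "\t")
  )
  records <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    info <- if (s$site == "fusion") "FUSION" else "."
    gts <- vapply(dosage[[s$site]], gt, character(1))
    paste(c(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", info, "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}
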