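# shared fixtures built in code

zero_noise_channels <- function() default_channels(noise_sd = 0)

fixture_table <- function() read_genotype_fixture()

fixture_genotypes <- function() cohort_from_fixture(fixture_table())

# truth vectors for a genotype list, in caller vocabulary
truth_of <- function(genotypes) {
  list(
    fut2 = vapply(genotypes, fut2_group_of, character(1)),
    c59 = paste0("59", vapply(genotypes, `[[`, character(1), "fut3_59")),
    c314 = paste0("314", vapply(genotypes, `[[`, character(1), "fut3_314"))
  )
}

# fixture genotype labels -> caller group vocabulary
fut2_label_to_group <- function(label) {
  unname(c("Se/Se" = "385A/A", "Se/Se^w" = "385A/T",
           "Se^w/Se^w" = "385T/T", "Se/se^fus" = "385A/fusion",
           "Se^w/se^fus" = "385T/fusion",
           "se^fus/se^fus" = "fusion/fusion")[label])
}

biallelic_genotype_to_group <- function(g, ref) {
  alleles <- strsplit(g, "/", fixed = TRUE)[[1L]]
  n_alt <- sum(alleles != ref)
  c("hom_ref", "het", "hom_alt")[n_alt + 1L]
}

# expand the fixture into a per-subject calls data.frame straight from the
# genotype columns (no curves involved): input for the inference engine
fixture_calls <- function(fix = fixture_table()) {
  rows <- rep(seq_len(nrow(fix)), fix$count)
  data.frame(
    subject_id = sprintf("S%03d", seq_along(rows)),
    fut2_group = fut2_label_to_group(fix$fut2_genotype[rows]),
    c59_group = vapply(fix$c59[rows], biallelic_genotype_to_group,
                       ref = "T", character(1), USE.NAMES = FALSE),
    c314_group = vapply(fix$c314[rows], biallelic_genotype_to_group,
                        ref = "C", character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

# analytic two-state melt curve: one logistic transition per row of specs
analytic_curve <- function(tg = default_temperature_grid(),
                           tms = 68, amps = 1, width = 0.85,
                           intercept = 0, slope = 0) {
  f <- intercept + slope * (tg - tg[1L])
  for (i in seq_along(tms)) {
    f <- f + amps[i] / (1 + exp((tg - tms[i]) / width))
  }
  melting_curve(tg, f)
}
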