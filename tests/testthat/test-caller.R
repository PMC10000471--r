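peakset <- function(tm, height) {
  structure(data.frame(tm = tm, height = height, prominence = height),
            class = c("peak_set", "data.frame"))
}

test_that("FUT2 peak patterns map to the six genotype groups", {
  # copy-count oracle: expected 73:68:62 heights per diplotype follow the
  # hybridization-site multiset (2:2, 1:2, 2:1:1, 1:1:1, 2:-:2, -:2:-)
  cases <- list(
    list(tm = 68, h = 2, group = "fusion/fusion"),
    list(tm = c(73, 62), h = c(2, 2), group = "385T/T"),
    list(tm = c(73, 68), h = c(2, 2), group = "385A/A"),
    list(tm = c(73, 68), h = c(1, 2), group = "385A/fusion"),
    list(tm = c(73, 68, 62), h = c(2, 1, 1), group = "385A/T"),
    list(tm = c(73, 68, 62), h = c(1, 1, 1), group = "385T/fusion")
  )
  for (cs in cases) {
    call <- call_fut2(peakset(cs$tm, cs$h))
    expect_equal(call$group, cs$group, info = cs$group)
  }
  # no peaks vs peaks matching no species
  expect_equal(call_fut2(peakset(numeric(0), numeric(0)))$group,
               "no_amplification")
  stray <- call_fut2(peakset(c(73, 55), c(2, 1)))
  expect_equal(stray$group, "unknown")
  expect_match(stray$note, "outside every Tm bin")
})

test_that("the SEC1P height-ratio threshold splits fusion heterozygotes", {
  # two-peak pattern: fusion-free expectation 1.0, threshold at 0.75
  expect_equal(call_fut2(peakset(c(73, 68), c(1.6, 2)))$group, "385A/A")
  expect_equal(call_fut2(peakset(c(73, 68), c(1.4, 2)))$group,
               "385A/fusion")
  # three-peak pattern: fusion-free expectation 2.0, threshold at 1.5
  expect_equal(call_fut2(peakset(c(73, 68, 62), c(3.1, 2, 2)))$group,
               "385A/T")
  expect_equal(call_fut2(peakset(c(73, 68, 62), c(2.9, 2, 2)))$group,
               "385T/fusion")
  r <- call_fut2(peakset(c(73, 68), c(1, 2)))
  expect_equal(r$sec1p_ratio, 0.5)
})

test_that("biallelic patterns map to three genotype groups plus no-call", {
  fam <- channel_model("FAM")$species_tm
  expect_equal(call_biallelic(peakset(66, 1), fam)$group, "hom_ref")
  expect_equal(call_biallelic(peakset(66, 1), fam)$genotype, "59T/T")
  expect_equal(call_biallelic(peakset(c(66, 59), c(1, 1)), fam)$group,
               "het")
  expect_equal(call_biallelic(peakset(59, 1), fam)$group, "hom_alt")
  expect_equal(call_biallelic(peakset(numeric(0), numeric(0)), fam)$group,
               "no_call")
  expect_equal(call_biallelic(peakset(c(66, 72), c(1, 1)), fam)$group,
               "no_call")
  cy5 <- channel_model("CY5")$species_tm
  expect_equal(call_biallelic(peakset(c(64, 57), c(1, 1)), cy5,
                              snp = "c.314C>T")$genotype, "314C/T")
})

test_that("zero-noise round trip recovers every genotype combination exactly", {
  fut2_groups <- c("385A/A", "385A/T", "385T/T", "385A/fusion",
                   "385T/fusion", "fusion/fusion")
  combos <- expand.grid(f2 = fut2_groups,
                        g59 = c("T/T", "T/G", "G/G"),
                        g314 = c("C/C", "C/T", "T/T"),
                        stringsAsFactors = FALSE)
  gts <- lapply(seq_len(nrow(combos)), function(i) {
    subject_genotype(fmcaller:::.group_to_haps(combos$f2[i]),
                     combos$g59[i], combos$g314[i],
                     subject_id = sprintf("G%02d", i))
  })
  curves <- simulate_cohort(genotypes = gts,
                            channels = zero_noise_channels())
  calls <- call_cohort(curves)
  expect_equal(nrow(calls), 54L)
  truth <- truth_of(gts)
  expect_identical(calls$fut2_group, truth$fut2)
  expect_identical(calls$c59_genotype, truth$c59)
  expect_identical(calls$c314_genotype, truth$c314)
})

test_that("call_subject matches call_cohort and handles degenerate input", {
  gts <- fixture_genotypes()[c(3, 60, 96)]
  curves <- simulate_cohort(genotypes = gts,
                            channels = zero_noise_channels())
  calls <- call_cohort(curves)
  for (gt in gts) {
    sc <- call_subject(curves, subject_id = gt$subject_id)
    i <- which(calls$subject_id == gt$subject_id)
    expect_equal(sc$fut2$group, calls$fut2_group[i])
    expect_equal(sc$fut3_59$group, calls$c59_group[i])
    expect_equal(sc$fut3_314$group, calls$c314_group[i])
  }
  # all-flat curves: every channel degrades to its no-call
  tg <- default_temperature_grid()
  flat <- list(HEX = melting_curve(tg, rep(1, 301), "HEX", "f"),
               FAM = melting_curve(tg, rep(1, 301), "FAM", "f"),
               CY5 = melting_curve(tg, rep(1, 301), "CY5", "f"))
  sc <- call_subject(flat)
  expect_equal(sc$fut2$group, "no_amplification")
  expect_equal(sc$fut3_59$group, "no_call")
  expect_equal(sc$fut3_314$group, "no_call")
  # a missing channel is a per-channel no-call, not an error
  sc <- call_subject(flat[c("HEX", "FAM")])
  expect_equal(sc$fut3_314$group, "no_call")
})

test_that("score/resolution classification follows the instrument semantics", {
  refs <- fut2_reference_curves(c("385A/A", "385A/fusion"))
  ch0 <- channel_model("HEX", noise_sd = 0)
  dAA <- negative_derivative(simulate_channel(
    subject_genotype(c("A_allele", "A_allele")), ch0))
  # self-similar sample: score exactly 1
  sr <- score_resolution_classify(dAA, refs, 0.70, 0.10)
  expect_equal(sr$score, 1.0)
  # raised score threshold with zero resolution threshold separates the
  # fusion heterozygote from the homozygote...
  sr <- score_resolution_classify(dAA, refs, 0.85, 0.00)
  expect_equal(sr$decision, "grouped")
  expect_equal(sr$best, "385A/A")
  # ...but the default resolution threshold merges them into unknown
  sr <- score_resolution_classify(dAA, refs, 0.70, 0.10)
  expect_equal(sr$decision, "unknown")
  # unattainable resolution threshold always yields unknown
  sr <- score_resolution_classify(dAA, refs, 0.0, 1.0)
  expect_equal(sr$decision, "unknown")
  expect_error(score_resolution_classify(dAA, refs[1]), "at least two")
  short <- refs
  short[[1]] <- short[[1]][1:100, ]
  expect_error(score_resolution_classify(dAA, short, 0.7, 0.1),
               "grid does not match")
})

test_that("the score/resolution pathway can drive cohort FUT2 calls", {
  gts <- fixture_genotypes()[c(1, 40, 96)]
  curves <- simulate_cohort(genotypes = gts,
                            channels = zero_noise_channels())
  cfg <- fmca_config(classifier = "score_resolution",
                     score_threshold = 0.85, resolution_threshold = 0.00)
  calls <- call_cohort(curves, cfg)
  expect_identical(calls$fut2_group, truth_of(gts)$fut2)
  expect_identical(unique(calls$classifier), "score_resolution")
})

test_that("documented assay blind spots are reproduced, not repaired", {
  ch0 <- channel_model("HEX", noise_sd = 0)
  # a weak secretor carrying the rare se^628 null is read as Se/Se^w
  gt <- subject_genotype(c("T_allele", "se628_like"), subject_id = "blind1")
  call <- call_fut2(detect_peaks(negative_derivative(
    simulate_channel(gt, ch0))))
  expect_equal(call$group, "385A/T")
  # a c.375A>G chromosome contributes pure SEC1P-like signal: paired with
  # an A allele the SEC1P peak triples and swallows the single-copy 68
  # peak, leaving an anomalous SEC1P-only profile no genotype can explain
  gt <- subject_genotype(c("A_allele", "sec1p_like_variant"),
                         subject_id = "blind2")
  p <- detect_peaks(negative_derivative(simulate_channel(gt, ch0)))
  expect_equal(nrow(p), 1L)
  expect_lt(abs(p$tm - 73), 0.1)
  expect_equal(call_fut2(p)$group, "unknown")
  # paired with a fusion allele the profile looks like a normal 385A/A:
  # a clean miscall, exactly the extra-SEC1P failure mode
  gt <- subject_genotype(c("sec1p_like_variant", "fusion"),
                         subject_id = "blind3")
  call <- call_fut2(detect_peaks(negative_derivative(
    simulate_channel(gt, ch0))))
  expect_equal(call$group, "385A/A")
})

test_that("FUT2 calls are unchanged by the presence of the FUT3 channels", {
  gts <- fixture_genotypes()
  hex_only <- simulate_cohort(genotypes = gts,
                              channels = default_channels()["HEX"],
                              seed = 33)
  triplex <- simulate_cohort(genotypes = gts, channels = default_channels(),
                             seed = 33)
  expect_identical(call_cohort(hex_only)$fut2_group,
                   call_cohort(triplex)$fut2_group)
})
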