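test_that("curve tables round-trip losslessly through TSV", {
  gts <- fixture_genotypes()[c(1, 96)]
  curves <- simulate_cohort(genotypes = gts, channels = default_channels(),
                            seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curves(curves, path)
  back <- read_curves(path)
  expect_equal(back$temperature, curves$temperature)
  expect_equal(back$fluorescence, curves$fluorescence, tolerance = 1e-9)
  expect_identical(back$subject_id, curves$subject_id)
  expect_identical(back$channel, curves$channel)
})

test_that("malformed curve tables are rejected with a location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("temp\tfluor", "60\t1"), path)
  expect_error(read_curves(path), "header")
  writeLines(c("subject_id\tchannel\ttemperature\tfluorescence",
               "s1\tROX\t50.0\t1.0"), path)
  expect_error(read_curves(path), "unknown channel")
  writeLines(c("subject_id\tchannel\ttemperature\tfluorescence",
               "s1\tHEX\t50.0\t1.0", "s1\tHEX\t50.2\t1.0",
               "s1\tHEX\t50.3\t1.0"), path)
  expect_error(read_curves(path), "uniform")
})

test_that("the shipped genotype fixture satisfies its own invariants", {
  fix <- fixture_table()
  expect_equal(nrow(fix), 16L)
  expect_equal(sum(fix$count), 96L)
  expect_true(all(fix$fut2_genotype %in%
    c("Se/Se", "Se/Se^w", "Se^w/Se^w", "Se/se^fus", "Se^w/se^fus",
      "se^fus/se^fus")))
  expect_true(all(fix$lewis_phenotype %in%
    c("Le(a-b+)", "Le(a+b+)", "Le(a+b-)", "Le(a-b-)")))
  expect_true(all(fix$fusion_copies %in% 0:2))
  # fusion copy number is consistent with the genotype label
  n_fus <- vapply(strsplit(fix$fut2_genotype, "/", fixed = TRUE),
                  function(a) sum(a == "se^fus"), integer(1))
  expect_equal(n_fus, fix$fusion_copies)
})

test_that("VCF output encodes SNP and symbolic fusion records correctly", {
  curves <- simulate_cohort(genotypes = fixture_genotypes(),
                            channels = zero_noise_channels())
  calls <- call_cohort(curves)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(calls, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 4L)
  ids <- vapply(strsplit(body, "\t"), `[[`, character(1), 3L)
  expect_setequal(ids, c("rs1047781", "FUT2_SEC1P_FUS", "rs28362459",
                         "rs778986"))
  # independent reader cross-check
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  expect_equal(ncol(gt), 96L)
  # spot checks against the calls table
  het385 <- calls$subject_id[calls$fut2_group == "385A/T"][1]
  expect_equal(unname(gt["rs1047781", het385]), "0/1")
  fus_hom <- calls$subject_id[calls$fut2_group == "fusion/fusion"]
  expect_equal(unname(gt["FUT2_SEC1P_FUS", fus_hom]), "1/1")
  expect_equal(unname(gt["rs1047781", fus_hom]), "0/0")
  het314 <- calls$subject_id[calls$c314_group == "het"][1]
  expect_equal(unname(gt["rs778986", het314]), "0/1")
  # undetermined calls become missing genotypes
  calls$fut2_group[1] <- "unknown"
  write_calls_vcf(calls, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  expect_true(is.na(gt["rs1047781", calls$subject_id[1]]))
})

test_that("YAML configuration overrides defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "channels:",
    "  HEX:",
    "    noise_sd: 0",
    "    species_tm: {0mm: 74.0, 1mm: 68.0, 2mm: 61.0}",
    "caller:",
    "  ratio_threshold: 0.6",
    "  smoothing_window: 9"
  ), path)
  cfg <- read_fmca_config(path)
  expect_equal(unname(cfg$channels$HEX$species_tm["0mm"]), 74)
  expect_equal(cfg$channels$HEX$noise_sd, 0)
  expect_equal(cfg$ratio_threshold, 0.6)
  expect_equal(cfg$smoothing_window, 9L)
  # untouched channels keep their defaults
  expect_equal(unname(cfg$channels$FAM$species_tm["matched"]), 66)
})

test_that("the CLI pipeline runs end to end and is bit-stable", {
  dir <- withr::local_tempdir()
  p <- function(f) file.path(dir, f)
  run_all <- function(suffix) {
    expect_equal(fmca_cli(c("simulate", "--seed", "9", "--out",
                            p(paste0("curves", suffix, ".tsv")))), 0L)
    expect_equal(fmca_cli(c("call", "--curves",
                            p(paste0("curves", suffix, ".tsv")),
                            "--out", p(paste0("calls", suffix, ".tsv")))),
                 0L)
    expect_equal(fmca_cli(c("phenotype", "--calls",
                            p(paste0("calls", suffix, ".tsv")),
                            "--out", p(paste0("reports", suffix, ".tsv")),
                            "--vcf", p(paste0("calls", suffix, ".vcf")))),
                 0L)
    expect_equal(fmca_cli(c("summarize", "--reports",
                            p(paste0("reports", suffix, ".tsv")),
                            "--out", p(paste0("summary", suffix, ".tsv")))),
                 0L)
  }
  run_all("1")
  run_all("2")
  for (f in c("curves", "calls", "reports", "summary")) {
    expect_identical(readLines(p(paste0(f, "1.tsv"))),
                     readLines(p(paste0(f, "2.tsv"))),
                     info = f)
  }
  # the summary of the default cohort reproduces the reference counts
  s <- read.delim(p("summary1.tsv"))
  expect_equal(s$count[s$secretor_status == "secretor" &
                       s$lewis_phenotype == "Le(a-b+)"], 60L)
  # errors surface as nonzero status, not exceptions
  expect_equal(fmca_cli(c("call", "--curves", p("nope.tsv"),
                          "--out", p("x.tsv"))), 1L)
  expect_equal(fmca_cli("frobnicate"), 1L)
  expect_equal(fmca_cli(character(0)), 1L)
})

test_that("frequency-mode CLI simulation respects seed and size", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "freq.tsv")
  expect_equal(fmca_cli(c("simulate", "--freq", "385T/T|T/G|C/C:0.5,385A/A|T/T|C/C:0.5",
                          "--n", "6", "--seed", "4", "--out", out)), 0L)
  curves <- read_curves(out)
  expect_equal(length(unique(curves$subject_id)), 6L)
  calls <- call_cohort(curves)
  expect_true(all(calls$fut2_group %in% c("385T/T", "385A/A")))
})
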