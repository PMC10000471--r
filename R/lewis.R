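#' FUT2 allele names from a called genotype group
#'
#' Maps chromosome calls to allele nomenclature: 385A is the functional
#' secretor allele `Se`, 385T the weak-secretor allele `Se^w`, and the
#' fusion allele the null `se^fus`.
#'
#' @param call a `fut2_call` from [call_fut2()], or a group string.
#' @return Character vector of two allele names, or `c(NA, NA)` for
#'   `unknown`/`no_amplification`.
#' @export
fut2_alleles <- function(call) {
  group <- if (inherits(call, "fut2_call")) call$group else call
  map <- list(
    "385A/A" = c("Se", "Se"),
    "385A/T" = c("Se", "Se^w"),
    "385T/T" = c("Se^w", "Se^w"),
    "385A/fusion" = c("Se", "se^fus"),
    "385T/fusion" = c("Se^w", "se^fus"),
    "fusion/fusion" = c("se^fus", "se^fus")
  )
  map[[group]] %||% c(NA_character_, NA_character_)
}

#' FUT3 allele names from the two tag-SNP calls
#'
#' Each 59G allele tags a member of the le^59 family (le^59, le^59,508,
#' le^59,1067 -- indistinguishable by this tag), each 314T allele tags
#' le^202,314, and remaining chromosomes are functional `Le`. The double
#' heterozygote (59T/G with 314C/T) is assigned the trans configuration
#' le^59/le^202,314 -- two null alleles -- with `phase_assumed` set, since
#' the two tags are not physically phased by the assay.
#'
#' @param call59,call314 `biallelic_call` objects from [call_biallelic()],
#'   or group strings (`hom_ref`/`het`/`hom_alt`/`no_call`).
#' @return List with `alleles` (character length 2, NA if undetermined) and
#'   `phase_assumed` (logical).
#' @export
fut3_alleles <- function(call59, call314) {
  g59 <- if (inherits(call59, "biallelic_call")) call59$group else call59
  g314 <- if (inherits(call314, "biallelic_call")) call314$group else call314
  n_alt <- function(g) switch(g, hom_ref = 0L, het = 1L, hom_alt = 2L,
                              NA_integer_)
  a <- n_alt(g59)
  b <- n_alt(g314)
  if (is.na(a) || is.na(b)) {
    return(list(alleles = c(NA_character_, NA_character_),
                phase_assumed = FALSE))
  }
  if (a + b > 2L) {
    stop("inconsistent FUT3 tag genotypes: ", a, " x 59G and ", b,
         " x 314T alleles exceed two chromosomes")
  }
  alleles <- c(rep("le^59", a), rep("le^202,314", b),
               rep("Le", 2L - a - b))
  list(alleles = alleles, phase_assumed = (a == 1L && b == 1L))
}

#' Secretor status from a FUT2 allele pair
#'
#' Any functional `Se` allele makes a secretor; otherwise any weak `Se^w`
#' allele makes a weak secretor; two null alleles make a non-secretor.
#'
#' @param alleles character vector of two FUT2 allele names
#'   (from [fut2_alleles()]).
#' @return `"secretor"`, `"weak secretor"`, `"non-secretor"` or
#'   `"undetermined"`.
#' @export
secretor_status <- function(alleles) {
  if (any(is.na(alleles))) return("undetermined")
  if ("Se" %in% alleles) "secretor"
  else if ("Se^w" %in% alleles) "weak secretor"
  else "non-secretor"
}

#' Lewis red-cell phenotype from secretor status and FUT3 alleles
#'
#' Lewis-negative genotypes (no functional `Le` allele) give Le(a-b-)
#' whatever the secretor status. With at least one `Le`, the phenotype
#' follows the secretor status: secretors are Le(a-b+), weak secretors
#' Le(a+b+) and non-secretors Le(a+b-).
#'
#' @param status secretor status string (see [secretor_status()]).
#' @param fut3_alleles character vector of two FUT3 allele names.
#' @return Phenotype string, or `"undetermined"`.
#' @export
lewis_phenotype <- function(status, fut3_alleles) {
  if (status == "undetermined" || any(is.na(fut3_alleles))) {
    return("undetermined")
  }
  if (!"Le" %in% fut3_alleles) return("Le(a-b-)")
  switch(status,
         "secretor" = "Le(a-b+)",
         "weak secretor" = "Le(a+b+)",
         "non-secretor" = "Le(a+b-)")
}

#' Full per-subject report from called genotypes
#'
#' @param subject_id identifier.
#' @param fut2_group FUT2 group string (or `fut2_call`).
#' @param c59_group,c314_group biallelic group strings (or
#'   `biallelic_call`s).
#' @return A one-row data.frame with allele pairs, `phase_assumed`,
#'   `secretor_status` and `lewis_phenotype`.
#' @export
lewis_report <- function(subject_id, fut2_group, c59_group, c314_group) {
  f2 <- fut2_alleles(fut2_group)
  f3 <- fut3_alleles(c59_group, c314_group)
  status <- secretor_status(f2)
  pheno <- lewis_phenotype(status, f3$alleles)
  data.frame(
    subject_id = subject_id,
    fut2_allele1 = f2[1L], fut2_allele2 = f2[2L],
    fut3_allele1 = f3$alleles[1L], fut3_allele2 = f3$alleles[2L],
    phase_assumed = f3$phase_assumed,
    secretor_status = status,
    lewis_phenotype = pheno,
    stringsAsFactors = FALSE
  )
}

#' Reports for a whole cohort of calls
#'
#' @param calls data.frame from [call_cohort()] (columns `subject_id`,
#'   `fut2_group`, `c59_group`, `c314_group`).
#' @return Data.frame of [lewis_report()] rows, one per subject.
#' @export
lewis_reports <- function(calls) {
  if (!nrow(calls)) {
    return(lewis_report("x", "385A/A", "hom_ref", "hom_ref")[0, ])
  }
  out <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    lewis_report(calls$subject_id[i], calls$fut2_group[i],
                 calls$c59_group[i], calls$c314_group[i])
  }))
  rownames(out) <- NULL
  out
}

#' Cohort summary of secretor and Lewis phenotypes
#'
#' @param reports data.frame from [lewis_reports()].
#' @return A `cohort_summary`: list with `n`, `lewis_counts`,
#'   `secretor_counts`, `cross` (secretor x Lewis table) and
#'   `n_undetermined`. Undetermined subjects are counted separately, never
#'   dropped.
#' @export
summarize_cohort <- function(reports) {
  phen_lv <- c("Le(a-b+)", "Le(a+b+)", "Le(a+b-)", "Le(a-b-)",
               "undetermined")
  sec_lv <- c("secretor", "weak secretor", "non-secretor", "undetermined")
  lp <- factor(reports$lewis_phenotype, levels = phen_lv)
  ss <- factor(reports$secretor_status, levels = sec_lv)
  structure(
    list(n = nrow(reports),
         lewis_counts = table(lewis_phenotype = lp),
         secretor_counts = table(secretor_status = ss),
         cross = table(secretor_status = ss, lewis_phenotype = lp),
         n_undetermined = sum(lp == "undetermined" | ss == "undetermined")),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n, "subjects",
      if (x$n_undetermined) paste0("(", x$n_undetermined, " undetermined)"),
      "\n\nLewis phenotype counts:\n")
  print(x$lewis_counts)
  cat("\nSecretor status counts:\n")
  print(x$secretor_counts)
  cat("\nSecretor status x Lewis phenotype:\n")
  print(x$cross)
  invisible(x)
}
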