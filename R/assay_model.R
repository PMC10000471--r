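#' Assay geometry: primers, probe and polymorphic positions
#'
#' A single fluorescent probe spans the FUT2 c.385A>T site. Because FUT2 and
#' its pseudogene SEC1P are nearly identical over the amplified window, one
#' primer pair amplifies FUT2, SEC1P and the SEC1P-FUT2 fusion allele
#' together, and the probe hybridises to all of them. The probe matches SEC1P
#' exactly; within the probe window only two positions vary between the
#' amplified species: the position homologous to FUT2 c.375 (probe carries G,
#' the SEC1P base) and the position homologous to FUT2 c.385 (probe carries
#' A). Mismatch count at these two offsets therefore determines the duplex
#' melting temperature class: 0 mismatches (SEC1P), 1 (385A allele and the
#' fusion allele), or 2 (385T allele).
#'
#' @param forward_primer,reverse_primer,probe DNA strings (upper-case ACGT).
#' @param probe_span_fut2,probe_span_sec1p 1-based inclusive probe coordinates
#'   on the FUT2 and SEC1P templates.
#' @param amplicon_span_fut2,amplicon_span_sec1p 1-based inclusive amplicon
#'   coordinates (forward-primer start to reverse-primer end).
#' @param polymorphic_offsets positions of the two variable sites in FUT2
#'   coordinates (c.375- and c.385-homologous positions).
#' @return An object of class `probe_assay`.
#' @examples
#' assay <- probe_assay()
#' probe_mismatches(c("A", "A"), assay)  # the 385A allele: one mismatch
#' @export
probe_assay <- function(forward_primer = "TGGCAGAACTACCACCTGAA",
                        reverse_primer = "AGGTCCAGGAGCAGGGGTAG",
                        probe = "GGAGGAGTACCGCCACATCCCGGGG",
                        probe_span_fut2 = c(369L, 393L),
                        probe_span_sec1p = c(411L, 435L),
                        amplicon_span_fut2 = c(337L, 433L),
                        amplicon_span_sec1p = c(379L, 475L),
                        polymorphic_offsets = c(375L, 385L)) {
  .check_dna(forward_primer, "forward_primer")
  .check_dna(reverse_primer, "reverse_primer")
  .check_dna(probe, "probe")
  if (nchar(probe) != 25L) {
    stop("probe must be 25 nt, got ", nchar(probe))
  }
  span_len <- function(s) s[2L] - s[1L] + 1L
  if (span_len(amplicon_span_fut2) != span_len(amplicon_span_sec1p)) {
    stop("FUT2 and SEC1P amplicon spans must have identical length")
  }
  if (any(polymorphic_offsets < probe_span_fut2[1L]) ||
      any(polymorphic_offsets > probe_span_fut2[2L])) {
    stop("polymorphic offsets must fall inside the FUT2 probe span")
  }
  structure(
    list(
      forward_primer = forward_primer,
      reverse_primer = reverse_primer,
      probe = probe,
      probe_span_fut2 = as.integer(probe_span_fut2),
      probe_span_sec1p = as.integer(probe_span_sec1p),
      amplicon_span_fut2 = as.integer(amplicon_span_fut2),
      amplicon_span_sec1p = as.integer(amplicon_span_sec1p),
      polymorphic_offsets = as.integer(polymorphic_offsets),
      # probe bases at the two polymorphic offsets, read off the probe string
      probe_bases = vapply(polymorphic_offsets - probe_span_fut2[1L] + 1L,
                           function(i) substr(probe, i, i), character(1))
    ),
    class = "probe_assay"
  )
}

.check_dna <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) ||
      grepl("[^ACGT]", x)) {
    stop(what, " must be a single ACGT string")
  }
  invisible(x)
}

#' @export
print.probe_assay <- function(x, ...) {
  cat("FUT2/SEC1P melting-probe assay\n")
  cat("  forward primer:", x$forward_primer, "\n")
  cat("  reverse primer:", x$reverse_primer, "\n")
  cat("  probe:         ", x$probe, "\n")
  cat(sprintf("  probe span: FUT2 %d-%d, SEC1P %d-%d\n",
              x$probe_span_fut2[1], x$probe_span_fut2[2],
              x$probe_span_sec1p[1], x$probe_span_sec1p[2]))
  cat(sprintf("  amplicon:   FUT2 %d-%d, SEC1P %d-%d (both %d bp)\n",
              x$amplicon_span_fut2[1], x$amplicon_span_fut2[2],
              x$amplicon_span_sec1p[1], x$amplicon_span_sec1p[2],
              in_silico_amplicon(x$amplicon_span_fut2)))
  cat("  polymorphic offsets (FUT2 numbering):",
      paste(x$polymorphic_offsets, collapse = ", "),
      " probe bases:", paste(x$probe_bases, collapse = ", "), "\n")
  invisible(x)
}

#' FUT2 chromosome-level haplotypes
#'
#' Five haplotype kinds are modelled. `A_allele` (functional Se, base A at
#' both c.375 and c.385) and `T_allele` (weak-secretor Se^w, T at c.385) are
#' ordinary FUT2 chromosomes carrying both a SEC1P copy and a FUT2 copy of
#' the probe site. `fusion` is the SEC1P-FUT2 fusion null allele (se^fus): an
#' unequal crossover leaves a single probe-binding region carrying A at both
#' polymorphic positions. `sec1p_like_variant` is an A-background chromosome
#' with the synonymous c.375A>G change, which makes its FUT2 probe site
#' base-identical to SEC1P. `se628_like` is an A-background chromosome whose
#' inactivating variant lies outside the probe window, so it is
#' indistinguishable from `A_allele` by this assay (deliberately so: the
#' assay's documented blind spot).
#'
#' @param kind one of `"A_allele"`, `"T_allele"`, `"fusion"`,
#'   `"sec1p_like_variant"`, `"se628_like"`.
#' @return A `fut2_haplotype` object with `kind`, `base_at_375`, `base_at_385`.
#' @export
fut2_haplotype <- function(kind = c("A_allele", "T_allele", "fusion",
                                    "sec1p_like_variant", "se628_like")) {
  kind <- match.arg(kind)
  bases <- switch(kind,
    A_allele           = c("A", "A"),
    T_allele           = c("A", "T"),
    fusion             = c("A", "A"),
    sec1p_like_variant = c("G", "A"),
    se628_like         = c("A", "A")
  )
  structure(list(kind = kind, base_at_375 = bases[1L], base_at_385 = bases[2L]),
            class = "fut2_haplotype")
}

#' FUT3 chromosome-level haplotype (tag-SNP bases)
#'
#' @param base_at_59 `"T"` (functional) or `"G"` (le^59 family tag).
#' @param base_at_314 `"C"` (functional) or `"T"` (le^202,314 tag).
#' @return A `fut3_haplotype` object.
#' @export
fut3_haplotype <- function(base_at_59, base_at_314) {
  if (!base_at_59 %in% c("T", "G")) stop("base_at_59 must be T or G")
  if (!base_at_314 %in% c("C", "T")) stop("base_at_314 must be C or T")
  structure(list(base_at_59 = base_at_59, base_at_314 = base_at_314),
            class = "fut3_haplotype")
}

#' Probe-template mismatch count at the polymorphic offsets
#'
#' The 23 non-polymorphic probe positions match every amplified species by
#' construction, so the full-sequence Hamming distance between probe and
#' template reduces to the distance at the two polymorphic offsets.
#'
#' @param site_bases character vector of length 2: template bases at the
#'   c.375- and c.385-homologous positions.
#' @param assay a [probe_assay()].
#' @return Integer mismatch count (0, 1 or 2).
#' @examples
#' assay <- probe_assay()
#' probe_mismatches(c("G", "A"), assay)  # SEC1P: perfect match
#' probe_mismatches(c("A", "T"), assay)  # 385T allele: two mismatches
#' @export
probe_mismatches <- function(site_bases, assay = probe_assay()) {
  if (length(site_bases) != 2L || !all(site_bases %in% c("A", "C", "G", "T"))) {
    stop("site_bases must be two bases in {A,C,G,T}")
  }
  sum(site_bases != assay$probe_bases)
}

#' Probe hybridization sites contributed by one FUT2 haplotype
#'
#' A chromosome carrying the 385A or 385T allele has two probe-binding
#' regions, one on its SEC1P copy (perfect match) and one on FUT2. A fusion
#' chromosome has lost the SEC1P copy and contributes a single site. The
#' c.375A>G variant chromosome keeps two sites but both match the probe
#' perfectly, so it masquerades as extra SEC1P signal.
#'
#' @param haplotype a [fut2_haplotype()].
#' @param assay a [probe_assay()].
#' @return A data.frame with columns `species`, `mismatches`,
#'   `source_haplotype`; one row per hybridization site.
#' @export
hybridization_sites <- function(haplotype, assay = probe_assay()) {
  stopifnot(inherits(haplotype, "fut2_haplotype"))
  hap_bases <- c(haplotype$base_at_375, haplotype$base_at_385)
  if (haplotype$kind == "fusion") {
    sites <- data.frame(
      species = "FUSION",
      mismatches = probe_mismatches(hap_bases, assay),
      stringsAsFactors = FALSE
    )
  } else {
    fut2_species <- switch(haplotype$kind,
      A_allele           = "FUT2_A",
      T_allele           = "FUT2_T",
      sec1p_like_variant = "SEC1P_LIKE",
      se628_like         = "FUT2_A"  # identical bases; same species class
    )
    sites <- data.frame(
      species = c("SEC1P", fut2_species),
      mismatches = c(probe_mismatches(c("G", "A"), assay),
                     probe_mismatches(hap_bases, assay)),
      stringsAsFactors = FALSE
    )
  }
  sites$source_haplotype <- haplotype$kind
  sites
}

#' In-silico amplicon length
#'
#' Inclusive span length from the forward-primer start to the reverse-primer
#' end on one template. Both the FUT2 and the SEC1P template yield the same
#' length because the primer pair was chosen to amplify FUT2, SEC1P and the
#' fusion allele collectively.
#'
#' @param template_span integer length-2, 1-based inclusive
#'   (forward-primer start, reverse-primer end).
#' @param forward_primer,reverse_primer primer sequences (lengths must fit
#'   inside the span).
#' @return Integer amplicon length in bp.
#' @examples
#' in_silico_amplicon(c(337, 433))  # FUT2: 97 bp
#' in_silico_amplicon(c(379, 475))  # SEC1P: 97 bp
#' @export
in_silico_amplicon <- function(template_span,
                               forward_primer = probe_assay()$forward_primer,
                               reverse_primer = probe_assay()$reverse_primer) {
  s <- as.integer(template_span)
  if (length(s) != 2L || s[2L] < s[1L]) {
    stop("template_span must be (start, end) with end >= start")
  }
  len <- s[2L] - s[1L] + 1L
  # forward primer anneals at the span start, reverse primer at the span end;
  # either running past the other's anchor is a geometry error
  fwd_end <- s[1L] + nchar(forward_primer) - 1L
  rev_start <- s[2L] - nchar(reverse_primer) + 1L
  if (fwd_end > rev_start) {
    stop("primer spans overlap or are inverted on a ", len, " bp template")
  }
  len
}
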