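#' Channel model for melting-curve simulation
#'
#' One dye channel of the triplex assay: HEX carries the FUT2/SEC1P probe,
#' FAM the FUT3 c.59T>G probe and CY5 the FUT3 c.314C>T probe. Each channel
#' resolves a small set of duplex species; a species is parameterised by its
#' melting temperature and a logistic transition width. Probe dissociation is
#' modelled as a two-state transition: the bound fraction at temperature T is
#' theta(T) = 1 / (1 + exp((T - Tm) / width)), so each duplex copy contributes
#' `amplitude_per_copy * theta(T)` to the channel fluorescence and a -dF/dT
#' peak of height `amplitude_per_copy / (4 * width)` at its Tm.
#'
#' Default melting temperatures on HEX are 73, 68 and 62 degrees C for the
#' 0-, 1- and 2-mismatch duplexes (SEC1P; 385A allele and fusion allele;
#' 385T allele). FAM and CY5 defaults (66/59 and 64/57 for matched/mismatched)
#' are package conventions, configurable like everything else.
#'
#' @param channel `"HEX"`, `"FAM"` or `"CY5"`.
#' @param species_tm named numeric vector of melting temperatures (degrees C).
#'   Names are mismatch classes `"0mm"`, `"1mm"`, `"2mm"` for HEX and
#'   `"matched"`, `"mismatched"` for FAM/CY5.
#' @param transition_width logistic steepness in degrees C (default 0.85,
#'   giving a -dF/dT full width at half maximum of about 3 degrees C).
#' @param amplitude_per_copy fluorescence units contributed by one duplex
#'   copy at low temperature.
#' @param baseline_intercept,baseline_slope linear background fluorescence
#'   `intercept + slope * (T - 50)`; the gentle negative slope imitates
#'   unbound-probe background.
#' @param noise_sd additive Gaussian noise standard deviation, in
#'   fluorescence units (default 1% of the single-copy amplitude).
#' @param temperature_grid acquisition grid in degrees C; default 50 to 80
#'   in 0.1-degree steps.
#' @return A `channel_model` object.
#' @export
channel_model <- function(channel = c("HEX", "FAM", "CY5"),
                          species_tm = NULL,
                          transition_width = 0.85,
                          amplitude_per_copy = 1,
                          baseline_intercept = 2,
                          baseline_slope = -0.002,
                          noise_sd = 0.01 * amplitude_per_copy,
                          temperature_grid = default_temperature_grid()) {
  channel <- match.arg(channel)
  if (is.null(species_tm)) {
    species_tm <- switch(channel,
      HEX = c("0mm" = 73, "1mm" = 68, "2mm" = 62),
      FAM = c(matched = 66, mismatched = 59),
      CY5 = c(matched = 64, mismatched = 57)
    )
  }
  stopifnot(transition_width > 0, amplitude_per_copy >= 0, noise_sd >= 0)
  steps <- diff(temperature_grid)
  if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-8) {
    stop("temperature_grid must be strictly increasing with uniform step")
  }
  rng <- range(temperature_grid)
  if (any(species_tm < rng[1]) || any(species_tm > rng[2])) {
    stop("species Tm outside the acquisition window [",
         rng[1], ", ", rng[2], "] degrees C")
  }
  if (length(species_tm) > 1) {
    seps <- abs(diff(sort(species_tm)))
    if (any(seps < 2 * 1.5)) {
      stop("species Tm values must be separated by at least twice the ",
           "caller's Tm bin tolerance (1.5 degrees C)")
    }
  }
  structure(
    list(channel = channel, species_tm = species_tm,
         transition_width = transition_width,
         amplitude_per_copy = amplitude_per_copy,
         baseline_intercept = baseline_intercept,
         baseline_slope = baseline_slope,
         noise_sd = noise_sd,
         temperature_grid = temperature_grid),
    class = "channel_model"
  )
}

#' Default acquisition grid: 50 to 80 degrees C in 0.1-degree steps
#' @return Numeric vector of 301 temperatures.
#' @export
default_temperature_grid <- function() {
  round(seq(50, 80, by = 0.1), 1)
}

#' Default three-channel triplex configuration
#' @param ... arguments forwarded to every [channel_model()] call
#'   (e.g. `noise_sd = 0`).
#' @return Named list of three `channel_model` objects (HEX, FAM, CY5).
#' @export
default_channels <- function(...) {
  list(HEX = channel_model("HEX", ...),
       FAM = channel_model("FAM", ...),
       CY5 = channel_model("CY5", ...))
}

#' Subject genotype configuration
#'
#' @param fut2 character vector of length 2 naming the two FUT2 haplotypes
#'   (see [fut2_haplotype()] for the vocabulary), in any order.
#' @param fut3_59 genotype string at c.59T>G: `"T/T"`, `"T/G"` or `"G/G"`
#'   (unordered; `"G/T"` is normalised).
#' @param fut3_314 genotype string at c.314C>T: `"C/C"`, `"C/T"` or `"T/T"`.
#' @param subject_id sample identifier.
#' @return A `subject_genotype` object.
#' @export
subject_genotype <- function(fut2 = c("A_allele", "A_allele"),
                             fut3_59 = "T/T", fut3_314 = "C/C",
                             subject_id = "S1") {
  stopifnot(length(fut2) == 2L)
  haps <- lapply(fut2, fut2_haplotype)
  structure(
    list(fut2 = haps,
         fut3_59 = .normalize_genotype(fut3_59, ref = "T", alt = "G"),
         fut3_314 = .normalize_genotype(fut3_314, ref = "C", alt = "T"),
         subject_id = as.character(subject_id)),
    class = "subject_genotype"
  )
}

.normalize_genotype <- function(g, ref, alt) {
  a <- strsplit(g, "/", fixed = TRUE)[[1L]]
  if (length(a) != 2L || !all(a %in% c(ref, alt))) {
    stop("genotype must be two '/'-separated alleles in {", ref, ",", alt, "}")
  }
  paste(sort(factor(a, levels = c(ref, alt))), collapse = "/")
}

#' True FUT2 genotype group of a subject (generator-side label)
#'
#' The six-group vocabulary used by the caller. `se628_like` chromosomes are
#' labelled as the A allele and `sec1p_like_variant` chromosomes have no
#' group of their own: this function returns what the melting-curve assay
#' can in principle express, which for those haplotypes differs from the
#' underlying functional genotype (the assay's documented blind spots).
#'
#' @param genotype a [subject_genotype()].
#' @return One of `"385A/A"`, `"385A/T"`, `"385T/T"`, `"385A/fusion"`,
#'   `"385T/fusion"`, `"fusion/fusion"`.
#' @export
fut2_group_of <- function(genotype) {
  kinds <- vapply(genotype$fut2, function(h) h$kind, character(1))
  simple <- ifelse(kinds == "T_allele", "T",
            ifelse(kinds == "fusion", "fusion", "A"))
  n_fus <- sum(simple == "fusion")
  n_t <- sum(simple == "T")
  if (n_fus == 2L) "fusion/fusion"
  else if (n_fus == 1L) if (n_t == 1L) "385T/fusion" else "385A/fusion"
  else if (n_t == 2L) "385T/T"
  else if (n_t == 1L) "385A/T"
  else "385A/A"
}

# per-channel duplex copy counts for one subject: named integer vector over
# the channel's species classes
.copy_counts <- function(genotype, channel, assay = probe_assay()) {
  if (channel == "HEX") {
    sites <- do.call(rbind, lapply(genotype$fut2, hybridization_sites,
                                   assay = assay))
    cls <- paste0(sites$mismatches, "mm")
    counts <- c("0mm" = 0L, "1mm" = 0L, "2mm" = 0L)
    tab <- table(cls)
    counts[names(tab)] <- as.integer(tab)
  } else {
    g <- if (channel == "FAM") genotype$fut3_59 else genotype$fut3_314
    ref <- if (channel == "FAM") "T" else "C"
    alleles <- strsplit(g, "/", fixed = TRUE)[[1L]]
    counts <- c(matched = sum(alleles == ref),
                mismatched = sum(alleles != ref))
  }
  counts
}

# two-state bound fraction on a temperature grid, one column per species
.theta_matrix <- function(model) {
  tg <- model$temperature_grid
  w <- model$transition_width
  vapply(model$species_tm,
         function(tm) 1 / (1 + exp((tg - tm) / w)),
         numeric(length(tg)))
}

#' Simulate one channel's melting curve for a subject
#'
#' Fluorescence is the copy-number-weighted sum of two-state dissociation
#' transitions plus a linear baseline and optional Gaussian noise:
#' `F(T) = sum_s copies_s * A * theta(T; Tm_s, w) + b0 + b1 * (T - 50) + eps`.
#' On the HEX channel the species copy numbers come from
#' [hybridization_sites()] applied to both chromosomes, so the 1-mismatch
#' contributions of a 385A allele and a fusion allele share one Tm and sum --
#' which is exactly why the SEC1P (0-mismatch) to 1-mismatch peak-height
#' ratio carries the fusion zygosity information. On FAM/CY5 each chromosome
#' contributes one matched or mismatched duplex according to its allele.
#'
#' @param genotype a [subject_genotype()].
#' @param channel a [channel_model()].
#' @param seed integer seed; required whenever `channel$noise_sd > 0`
#'   (reproducibility contract), ignored at zero noise.
#' @param assay a [probe_assay()].
#' @return A [melting_curve()] object.
#' @export
simulate_channel <- function(genotype, channel, seed = NULL,
                             assay = probe_assay()) {
  stopifnot(inherits(genotype, "subject_genotype"),
            inherits(channel, "channel_model"))
  counts <- .copy_counts(genotype, channel$channel, assay)
  theta <- .theta_matrix(channel)
  tg <- channel$temperature_grid
  f <- as.vector(theta %*% counts) * channel$amplitude_per_copy +
    channel$baseline_intercept + channel$baseline_slope * (tg - tg[1L])
  if (channel$noise_sd > 0) {
    if (is.null(seed)) {
      stop("a seed is required when noise_sd > 0 (reproducible simulation)")
    }
    set.seed(as.integer(seed))
    f <- f + stats::rnorm(length(f), sd = channel$noise_sd)
  }
  melting_curve(tg, f, channel = channel$channel,
                subject_id = genotype$subject_id)
}

#' Expand a genotype-configuration table into per-subject genotypes
#'
#' The input is a cohort genotype table in the fixture format shipped at
#' `system.file("extdata", "cohort_genotypes_japanese96.tsv", package =
#' "fmcaller")`: one row per genotype configuration with a `count` column
#' (see [read_genotype_fixture()]).
#'
#' @param fixture data.frame as returned by [read_genotype_fixture()].
#' @param id_prefix subject identifier prefix; ids are `S001`, `S002`, ...
#' @return List of [subject_genotype()] objects, one per subject.
#' @export
cohort_from_fixture <- function(fixture, id_prefix = "S") {
  allele_to_hap <- c("Se" = "A_allele", "Se^w" = "T_allele",
                     "se^fus" = "fusion")
  rows <- rep(seq_len(nrow(fixture)), fixture$count)
  lapply(seq_along(rows), function(i) {
    r <- fixture[rows[i], ]
    alleles <- strsplit(r$fut2_genotype, "/", fixed = TRUE)[[1L]]
    if (!all(alleles %in% names(allele_to_hap))) {
      stop("unknown FUT2 allele label in fixture row ", rows[i])
    }
    subject_genotype(
      fut2 = unname(allele_to_hap[alleles]),
      fut3_59 = r$c59, fut3_314 = r$c314,
      subject_id = sprintf("%s%03d", id_prefix, i)
    )
  })
}

#' Simulate a cohort of three-channel melting curves
#'
#' Either an explicit genotype list (deterministic expansion: one curve set
#' per subject, per channel) or a genotype-frequency specification from
#' which `n` subjects are drawn multinomially.
#'
#' @param genotypes list of [subject_genotype()] objects; mutually exclusive
#'   with `frequencies`.
#' @param frequencies named numeric vector of genotype frequencies summing
#'   to 1. Names are `"<fut2 group>|<c59>|<c314>"`, e.g.
#'   `"385A/T|T/G|C/C"`; FUT2 groups use the [fut2_group_of()] vocabulary.
#' @param n number of subjects to draw in frequency mode.
#' @param channels list of [channel_model()]s, as from [default_channels()].
#' @param seed integer seed; required if any channel has `noise_sd > 0`, if
#'   `crosstalk_sd > 0`, or in frequency mode.
#' @param crosstalk_sd optional extra Gaussian noise (fluorescence units)
#'   added to every channel when more than one channel is simulated,
#'   imitating the mild resolution loss of multiplexed acquisition relative
#'   to a single-probe run; default 0 (off).
#' @param assay a [probe_assay()].
#' @return A long-format data.frame (class `curve_set`) with columns
#'   `subject_id`, `channel`, `temperature`, `fluorescence`.
#' @export
simulate_cohort <- function(genotypes = NULL, frequencies = NULL, n = NULL,
                            channels = default_channels(), seed = NULL,
                            crosstalk_sd = 0, assay = probe_assay()) {
  if (is.null(genotypes) == is.null(frequencies)) {
    stop("supply exactly one of 'genotypes' or 'frequencies'")
  }
  if (!is.null(frequencies)) {
    if (abs(sum(frequencies) - 1) > 1e-9) {
      stop("frequencies must sum to 1 (tolerance 1e-9)")
    }
    if (is.null(n)) stop("'n' is required in frequency mode")
    if (is.null(seed)) stop("a seed is required in frequency mode")
    set.seed(as.integer(seed))
    drawn <- sample(names(frequencies), n, replace = TRUE,
                    prob = frequencies)
    genotypes <- lapply(seq_len(n), function(i) {
      parts <- strsplit(drawn[i], "|", fixed = TRUE)[[1L]]
      if (length(parts) != 3L) {
        stop("frequency names must be '<fut2 group>|<c59>|<c314>'")
      }
      subject_genotype(fut2 = .group_to_haps(parts[1L]),
                       fut3_59 = parts[2L], fut3_314 = parts[3L],
                       subject_id = sprintf("S%03d", i))
    })
  }
  crosstalk_sd <- if (length(channels) > 1L) crosstalk_sd else 0
  noisy <- crosstalk_sd > 0 ||
    any(vapply(channels, function(ch) ch$noise_sd > 0, logical(1)))
  if (noisy && is.null(seed)) {
    stop("a seed is required when any channel has noise_sd > 0")
  }
  if (noisy) set.seed(as.integer(seed))

  ids <- vapply(genotypes, function(g) g$subject_id, character(1))
  n_subj <- length(genotypes)
  # per-haplotype-kind HEX site counts computed once via
  # hybridization_sites, then summed per subject
  kinds <- vapply(genotypes, function(g)
    c(g$fut2[[1L]]$kind, g$fut2[[2L]]$kind), character(2))
  kind_counts <- vapply(unique(as.vector(kinds)), function(k) {
    s <- hybridization_sites(fut2_haplotype(k), assay)
    cls <- factor(paste0(s$mismatches, "mm"),
                  levels = c("0mm", "1mm", "2mm"))
    as.numeric(table(cls))
  }, numeric(3))
  rownames(kind_counts) <- c("0mm", "1mm", "2mm")
  allele1 <- function(g) substr(g, 1L, 1L)
  allele2 <- function(g) substr(g, 3L, 3L)
  g59 <- vapply(genotypes, `[[`, character(1), "fut3_59")
  g314 <- vapply(genotypes, `[[`, character(1), "fut3_314")

  fmat <- vector("list", length(channels))
  for (k in seq_along(channels)) {
    ch <- channels[[k]]
    counts <- switch(ch$channel,
      HEX = kind_counts[, kinds[1L, ], drop = FALSE] +
            kind_counts[, kinds[2L, ], drop = FALSE],
      FAM = rbind(matched = (allele1(g59) == "T") + (allele2(g59) == "T"),
                  mismatched = (allele1(g59) == "G") +
                               (allele2(g59) == "G")),
      CY5 = rbind(matched = (allele1(g314) == "C") + (allele2(g314) == "C"),
                  mismatched = (allele1(g314) == "T") +
                               (allele2(g314) == "T"))
    )
    tg <- ch$temperature_grid
    f <- .theta_matrix(ch) %*% counts * ch$amplitude_per_copy +
      ch$baseline_intercept + ch$baseline_slope * (tg - tg[1L])
    sd_k <- sqrt(ch$noise_sd^2 + crosstalk_sd^2)
    if (sd_k > 0) {
      f <- f + matrix(stats::rnorm(length(f), sd = sd_k), nrow(f))
    }
    fmat[[k]] <- f
  }
  # assemble subject-major: all three channels of subject 1, then 2, ...
  grid_lens <- vapply(channels, function(ch)
    length(ch$temperature_grid), integer(1))
  stacked <- do.call(rbind, fmat)
  res <- data.frame(
    subject_id = rep(ids, each = sum(grid_lens)),
    channel = rep(rep(vapply(channels, `[[`, character(1), "channel"),
                      grid_lens), n_subj),
    temperature = rep(unlist(lapply(channels, `[[`, "temperature_grid"),
                             use.names = FALSE), n_subj),
    fluorescence = as.vector(stacked),
    stringsAsFactors = FALSE
  )
  class(res) <- c("curve_set", "data.frame")
  res
}

# inverse of fut2_group_of for the six callable groups
.group_to_haps <- function(group) {
  switch(group,
    "385A/A" = c("A_allele", "A_allele"),
    "385A/T" = c("A_allele", "T_allele"),
    "385T/T" = c("T_allele", "T_allele"),
    "385A/fusion" = c("A_allele", "fusion"),
    "385T/fusion" = c("T_allele", "fusion"),
    "fusion/fusion" = c("fusion", "fusion"),
    stop("unknown FUT2 group: ", group)
  )
}

#' Extract one subject/channel curve from a curve set
#' @param curves a `curve_set` data.frame.
#' @param subject_id,channel selectors.
#' @return A [melting_curve()].
#' @export
curve_of <- function(curves, subject_id, channel) {
  sel <- curves$subject_id == subject_id & curves$channel == channel
  if (!any(sel)) stop("no curve for subject ", subject_id, " channel ", channel)
  melting_curve(curves$temperature[sel], curves$fluorescence[sel],
                channel = channel, subject_id = subject_id)
}
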