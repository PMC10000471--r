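#' Assign detected peaks to duplex species by melting temperature
#'
#' Each expected species Tm claims at most the nearest detected peak within
#' `tm_tolerance`; peaks claimed by no species are returned as unassigned.
#'
#' @param peaks a `peak_set` from [detect_peaks()].
#' @param species_tm named numeric vector of expected species Tm values.
#' @param tm_tolerance half-width of the Tm bin in degrees C (default 1.5).
#' @return List with `assigned` (named integer vector indexing `peaks`
#'   rows, `NA` where a species has no peak) and `unassigned` (indices of
#'   peaks matching no species).
#' @export
bin_peaks <- function(peaks, species_tm, tm_tolerance = 1.5) {
  idx <- .assign_species(peaks$tm, species_tm, tm_tolerance)
  list(assigned = idx,
       unassigned = setdiff(seq_along(peaks$tm), idx[!is.na(idx)]))
}

# greedy nearest-peak-per-species assignment on plain vectors
.assign_species <- function(tm, species_tm, tol) {
  idx <- rep(NA_integer_, length(species_tm))
  names(idx) <- names(species_tm)
  if (!length(tm)) return(idx)
  taken <- rep(FALSE, length(tm))
  for (k in seq_along(species_tm)) {
    d <- abs(tm - species_tm[[k]])
    d[taken] <- Inf
    i <- which.min(d)
    if (d[i] <= tol) {
      idx[k] <- i
      taken[i] <- TRUE
    }
  }
  idx
}

# six-group FUT2 decision from peak positions/heights; shared by the
# single-sample caller and the cohort fast path
.fut2_decide <- function(tm, height, species_tm, ratio_threshold, tol) {
  idx <- .assign_species(tm, species_tm, tol)
  n_unassigned <- length(tm) - sum(!is.na(idx))
  h0 <- if (!is.na(idx[["0mm"]])) height[idx[["0mm"]]] else NA_real_
  h1 <- if (!is.na(idx[["1mm"]])) height[idx[["1mm"]]] else NA_real_
  h2 <- if (!is.na(idx[["2mm"]])) height[idx[["2mm"]]] else NA_real_
  ratio <- if (!is.na(h0) && !is.na(h1)) h0 / h1 else NA_real_
  group <-
    if (!length(tm)) "no_amplification"
    else if (n_unassigned > 0L) "unknown"
    else if (!is.na(h1) && is.na(h0) && is.na(h2)) "fusion/fusion"
    else if (!is.na(h0) && is.na(h1) && !is.na(h2)) "385T/T"
    else if (!is.na(h0) && !is.na(h1) && is.na(h2)) {
      # expected 73:68 copy ratio 2:2 without fusion vs 1:2 with fusion
      if (ratio < ratio_threshold * 1) "385A/fusion" else "385A/A"
    } else if (!is.na(h0) && !is.na(h1) && !is.na(h2)) {
      # expected 73:68 copy ratio 2:1 without fusion vs 1:1 with fusion
      if (ratio < ratio_threshold * 2) "385T/fusion" else "385A/T"
    } else "unknown"
  list(group = group, ratio = ratio, idx = idx,
       n_unassigned = n_unassigned)
}

# three-way biallelic decision from peak positions
.biallelic_decide <- function(tm, species_tm, tol) {
  idx <- .assign_species(tm, species_tm, tol)
  if (length(tm) > sum(!is.na(idx))) return(list(group = "no_call",
                                                 idx = idx))
  have_m <- !is.na(idx[["matched"]])
  have_x <- !is.na(idx[["mismatched"]])
  group <- if (have_m && have_x) "het"
           else if (have_m) "hom_ref"
           else if (have_x) "hom_alt"
           else "no_call"
  list(group = group, idx = idx)
}

.evidence_df <- function(peaks, idx) {
  found <- !is.na(idx)
  if (!any(found)) return(NULL)
  out <- data.frame(species = names(idx)[found],
                    tm = peaks$tm[idx[found]],
                    height = peaks$height[idx[found]],
                    prominence = peaks$prominence[idx[found]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Six-group FUT2 genotype call from HEX-channel melting peaks
#'
#' The peak-presence pattern over the three mismatch classes (0 mm = SEC1P
#' at ~73 degrees C, 1 mm = 385A allele / fusion allele at ~68, 2 mm = 385T
#' allele at ~62) determines a coarse group; the two patterns shared by a
#' fusion-free and a fusion-bearing genotype are resolved by the SEC1P
#' peak-height ratio. A fusion chromosome lacks the SEC1P copy, so with two
#' peaks the expected 73:68 height ratio is 2:2 without fusion versus 1:2
#' with one fusion allele, and with three peaks 2:1 versus 1:1. The observed
#' ratio is compared against `ratio_threshold` times the fusion-free
#' expectation: below it, the fusion-bearing member is called. Peaks that
#' match no species yield `unknown` (with a diagnostic note), an empty peak
#' set `no_amplification`.
#'
#' @param peaks a `peak_set` from [detect_peaks()] on the HEX channel.
#' @param species_tm named Tm vector (`"0mm"`, `"1mm"`, `"2mm"`), default
#'   from [channel_model()].
#' @param ratio_threshold fraction of the fusion-free expected 0mm:1mm
#'   height ratio below which the fusion-bearing genotype is called
#'   (default 0.75, midway between the ideal fusion-free and fusion-het
#'   ratios).
#' @param tm_tolerance Tm bin half-width in degrees C.
#' @return A `fut2_call` object: list with `group`, `peaks` (per-species
#'   evidence), `sec1p_ratio`, `note`.
#' @export
call_fut2 <- function(peaks, species_tm = channel_model("HEX")$species_tm,
                      ratio_threshold = 0.75, tm_tolerance = 1.5) {
  d <- .fut2_decide(peaks$tm, peaks$height, species_tm, ratio_threshold,
                    tm_tolerance)
  note <- if (d$n_unassigned > 0L) {
    paste0(d$n_unassigned, " peak(s) outside every Tm bin")
  } else NA_character_
  structure(
    list(group = d$group, peaks = .evidence_df(peaks, d$idx),
         sec1p_ratio = d$ratio, note = note),
    class = "fut2_call"
  )
}

#' @export
print.fut2_call <- function(x, ...) {
  cat("FUT2 call:", x$group,
      if (!is.na(x$sec1p_ratio)) sprintf("(SEC1P ratio %.2f)", x$sec1p_ratio),
      "\n")
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Biallelic SNP call from a two-species melting-peak pattern
#'
#' The probe matches the reference allele, so a matched-Tm peak reads the
#' reference allele and a mismatched-Tm (lower) peak the alternate allele.
#' Degenerate inputs (no peaks, or peaks outside both Tm bins) give
#' `no_call`, never an error.
#'
#' @param peaks a `peak_set` from [detect_peaks()] on the FAM or CY5 channel.
#' @param species_tm named Tm vector with entries `matched`, `mismatched`.
#' @param snp SNP identifier, `"c.59T>G"` or `"c.314C>T"`.
#' @param tm_tolerance Tm bin half-width in degrees C.
#' @return A `biallelic_call`: list with `snp`, `group` (`hom_ref`, `het`,
#'   `hom_alt`, `no_call`), `genotype` (e.g. `"59T/G"`), `peaks`.
#' @export
call_biallelic <- function(peaks,
                           species_tm = channel_model("FAM")$species_tm,
                           snp = "c.59T>G", tm_tolerance = 1.5) {
  d <- .biallelic_decide(peaks$tm, species_tm, tm_tolerance)
  structure(
    list(snp = snp, group = d$group,
         genotype = .biallelic_genotype_label(snp, d$group),
         peaks = .evidence_df(peaks, d$idx)),
    class = "biallelic_call"
  )
}

.biallelic_genotype_label <- function(snp, group) {
  al <- switch(snp,
    "c.59T>G" = c(pos = "59", ref = "T", alt = "G"),
    "c.314C>T" = c(pos = "314", ref = "C", alt = "T"),
    return(NA_character_)
  )
  switch(group,
    hom_ref = paste0(al["pos"], al["ref"], "/", al["ref"]),
    het     = paste0(al["pos"], al["ref"], "/", al["alt"]),
    hom_alt = paste0(al["pos"], al["alt"], "/", al["alt"]),
    NA_character_
  )
}

#' Reference-curve similarity classification (instrument-style grouping)
#'
#' Mirrors the grouping logic of melting-curve gene-scanning software:
#' `score` is the similarity between the sample and its most similar
#' standard, and `resolution` the margin over the second most similar
#' standard. Similarity here is the Pearson correlation of max-normalised
#' -dF/dT vectors mapped affinely from [-1, 1] to [0, 1]. The sample is
#' grouped iff `score >= score_threshold` and
#' `resolution >= resolution_threshold`, otherwise it is `unknown`.
#' Equal similarities are broken lexicographically by group label.
#'
#' @param sample_deriv a `derivative_curve` for the sample.
#' @param references named list of `derivative_curve`s, one per standard
#'   group, all on the sample's temperature grid (at least two).
#' @param score_threshold,resolution_threshold decision thresholds.
#' @return A `score_resolution` object: `best`, `score`, `resolution`,
#'   `decision` (`"grouped"` or `"unknown"`), `similarities`, thresholds.
#' @export
score_resolution_classify <- function(sample_deriv, references,
                                      score_threshold = 0.70,
                                      resolution_threshold = 0.10) {
  if (length(references) < 2L) stop("at least two reference groups required")
  norm <- function(d) {
    m <- max(abs(d$neg_dfdt))
    if (m == 0) d$neg_dfdt else d$neg_dfdt / m
  }
  for (r in references) {
    if (length(r$temperature) != length(sample_deriv$temperature) ||
        max(abs(r$temperature - sample_deriv$temperature)) > 1e-8) {
      stop("reference curve grid does not match the sample grid")
    }
  }
  s <- norm(sample_deriv)
  sims <- vapply(references,
                 function(r) (stats::cor(s, norm(r)) + 1) / 2,
                 numeric(1))
  ord <- order(-sims, names(sims))  # ties: lexicographic by label
  best <- names(sims)[ord[1L]]
  score <- sims[[ord[1L]]]
  resolution <- min(max(score - sims[[ord[2L]]], 0), 1)
  decision <- if (score >= score_threshold &&
                  resolution >= resolution_threshold) "grouped" else "unknown"
  structure(
    list(best = best, score = score, resolution = resolution,
         score_threshold = score_threshold,
         resolution_threshold = resolution_threshold,
         decision = decision, similarities = sims[ord]),
    class = "score_resolution"
  )
}

#' @export
print.score_resolution <- function(x, ...) {
  cat(sprintf("score %.3f (best: %s), resolution %.3f -> %s\n",
              x$score, x$best, x$resolution,
              if (x$decision == "grouped") x$best else "unknown"))
  invisible(x)
}

#' Zero-noise reference derivative curves for FUT2 standard groups
#'
#' Simulates one noise-free HEX curve per requested group and returns its
#' -dF/dT, for use as standards in [score_resolution_classify()].
#'
#' @param groups character vector of FUT2 groups (default: all six).
#' @param channel a HEX [channel_model()]; its `noise_sd` is forced to 0.
#' @param config an [fmca_config()] (smoothing window, assay).
#' @return Named list of `derivative_curve`s.
#' @export
fut2_reference_curves <- function(groups = c("385A/A", "385A/T", "385T/T",
                                             "385A/fusion", "385T/fusion",
                                             "fusion/fusion"),
                                  channel = channel_model("HEX"),
                                  config = fmca_config()) {
  channel$noise_sd <- 0
  refs <- lapply(groups, function(g) {
    gt <- subject_genotype(fut2 = .group_to_haps(g), subject_id = g)
    negative_derivative(simulate_channel(gt, channel, assay = config$assay),
                        config$smoothing_window)
  })
  names(refs) <- groups
  refs
}

#' Call all three channels for one subject
#'
#' Runs [negative_derivative()] and [detect_peaks()] on each channel and
#' dispatches to [call_fut2()] (HEX) and [call_biallelic()] (FAM, CY5). With
#' `config$classifier = "score_resolution"`, the FUT2 group is instead taken
#' from [score_resolution_classify()] against zero-noise standards of the
#' six groups; the biallelic channels always use the peak-pattern caller.
#' A failed or missing channel yields that channel's no-call, never an error.
#'
#' @param curves either a `curve_set` data.frame containing the subject's
#'   rows, or a named list of [melting_curve()]s (`HEX`, `FAM`, `CY5`).
#' @param subject_id required when `curves` is a `curve_set` with several
#'   subjects.
#' @param config an [fmca_config()].
#' @return A `subject_call`: list with `subject_id`, `fut2`, `fut3_59`,
#'   `fut3_314`, `classifier`.
#' @export
call_subject <- function(curves, subject_id = NULL, config = fmca_config()) {
  if (is.data.frame(curves)) {
    if (is.null(subject_id)) {
      ids <- unique(curves$subject_id)
      if (length(ids) != 1L) stop("subject_id required: curve set has ",
                                  length(ids), " subjects")
      subject_id <- ids
    }
    get_curve <- function(ch) {
      sel <- curves$subject_id == subject_id & curves$channel == ch
      if (!any(sel)) return(NULL)
      melting_curve(curves$temperature[sel], curves$fluorescence[sel],
                    channel = ch, subject_id = subject_id)
    }
    curves <- list(HEX = get_curve("HEX"), FAM = get_curve("FAM"),
                   CY5 = get_curve("CY5"))
  } else if (is.null(subject_id)) {
    subject_id <- attr(curves[[1L]], "subject_id")
  }
  pk <- function(ch) {
    if (is.null(curves[[ch]])) return(NULL)
    detect_peaks(negative_derivative(curves[[ch]], config$smoothing_window),
                 config$min_prominence_fraction)
  }
  hex_peaks <- pk("HEX")
  fut2 <-
    if (is.null(hex_peaks)) {
      structure(list(group = "no_amplification", peaks = NULL,
                     sec1p_ratio = NA_real_, note = "channel missing"),
                class = "fut2_call")
    } else if (config$classifier == "score_resolution") {
      sr <- score_resolution_classify(
        negative_derivative(curves$HEX, config$smoothing_window),
        config$references %||% fut2_reference_curves(
          channel = config$channels$HEX, config = config),
        config$score_threshold, config$resolution_threshold)
      pc <- call_fut2(hex_peaks, config$channels$HEX$species_tm,
                      config$ratio_threshold, config$tm_tolerance)
      structure(list(group = if (sr$decision == "grouped") sr$best
                             else "unknown",
                     peaks = pc$peaks, sec1p_ratio = pc$sec1p_ratio,
                     note = sprintf("score %.3f resolution %.3f", sr$score,
                                    sr$resolution)),
                class = "fut2_call")
    } else {
      call_fut2(hex_peaks, config$channels$HEX$species_tm,
                config$ratio_threshold, config$tm_tolerance)
    }
  bi <- function(ch, snp) {
    p <- pk(ch)
    if (is.null(p)) {
      structure(list(snp = snp, group = "no_call", genotype = NA_character_,
                     peaks = NULL), class = "biallelic_call")
    } else {
      call_biallelic(p, config$channels[[ch]]$species_tm, snp,
                     config$tm_tolerance)
    }
  }
  structure(
    list(subject_id = subject_id, fut2 = fut2,
         fut3_59 = bi("FAM", "c.59T>G"), fut3_314 = bi("CY5", "c.314C>T"),
         classifier = config$classifier),
    class = "subject_call"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call every subject in a curve set
#'
#' @param curves a `curve_set` (long data.frame) as produced by
#'   [simulate_cohort()] or [read_curves()].
#' @param config an [fmca_config()].
#' @return Data.frame with one row per subject: `subject_id`, `fut2_group`,
#'   `sec1p_ratio`, `c59_group`, `c59_genotype`, `c314_group`,
#'   `c314_genotype`, `classifier`.
#' @export
call_cohort <- function(curves, config = fmca_config()) {
  ids <- unique(curves$subject_id)
  if (config$classifier == "score_resolution") {
    if (is.null(config$references)) {
      config$references <- fut2_reference_curves(
        channel = config$channels$HEX, config = config)
    }
    rows <- lapply(ids, function(id) {
      sc <- call_subject(curves[curves$subject_id == id, , drop = FALSE],
                         subject_id = id, config = config)
      data.frame(subject_id = id, fut2_group = sc$fut2$group,
                 sec1p_ratio = sc$fut2$sec1p_ratio,
                 c59_group = sc$fut3_59$group,
                 c59_genotype = sc$fut3_59$genotype,
                 c314_group = sc$fut3_314$group,
                 c314_genotype = sc$fut3_314$genotype,
                 classifier = sc$classifier, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  # peak-pattern fast path: the same plain-vector pipeline as
  # call_subject(), with the derivative filter applied to all of a
  # channel's curves at once when they share one grid
  fut2_group <- character(length(ids))
  sec1p_ratio <- numeric(length(ids))
  c59 <- character(length(ids))
  c314 <- character(length(ids))
  id_f <- factor(curves$subject_id, levels = ids)
  # per channel: list of -dF/dT vectors indexed like ids (NULL = missing)
  channel_derivs <- function(ch) {
    sel <- which(curves$channel == ch)
    if (!length(sel)) return(list(rep(list(NULL), length(ids)), NULL))
    by_subj <- split(sel, id_f[sel])
    lens <- lengths(by_subj)
    present <- lens > 0L
    tg1 <- curves$temperature[by_subj[[which(present)[1L]]]]
    shared <- all(lens[present] == length(tg1)) &&
      all(vapply(by_subj[present], function(r)
        max(abs(curves$temperature[r] - tg1)) < 1e-8, logical(1)))
    out <- rep(list(NULL), length(ids))
    if (shared) {
      .check_uniform_grid(tg1)
      fm <- matrix(curves$fluorescence[unlist(by_subj[present],
                                              use.names = FALSE)],
                   nrow = length(tg1))
      dm <- .neg_deriv_mat(tg1, fm, config$smoothing_window)
      out[present] <- lapply(seq_len(ncol(dm)), function(j) dm[, j])
      list(out, rep(list(tg1), length(ids)))
    } else {
      tgs <- rep(list(NULL), length(ids))
      for (i in which(present)) {
        r <- by_subj[[i]]
        tg <- curves$temperature[r]
        .check_uniform_grid(tg)
        out[[i]] <- .neg_deriv(tg, curves$fluorescence[r],
                               config$smoothing_window)
        tgs[[i]] <- tg
      }
      list(out, tgs)
    }
  }
  peaks_of <- function(dlist, i) {
    if (is.null(dlist[[1L]][[i]])) return(NULL)
    .find_peaks(dlist[[2L]][[i]], dlist[[1L]][[i]],
                config$min_prominence_fraction, c(50, 80))
  }
  d_hex <- channel_derivs("HEX")
  d_fam <- channel_derivs("FAM")
  d_cy5 <- channel_derivs("CY5")
  for (i in seq_along(ids)) {
    m <- peaks_of(d_hex, i)
    if (is.null(m)) {
      fut2_group[i] <- "no_amplification"
      sec1p_ratio[i] <- NA_real_
    } else {
      d <- .fut2_decide(m[, "tm"], m[, "height"],
                        config$channels$HEX$species_tm,
                        config$ratio_threshold, config$tm_tolerance)
      fut2_group[i] <- d$group
      sec1p_ratio[i] <- d$ratio
    }
    m <- peaks_of(d_fam, i)
    c59[i] <- if (is.null(m)) "no_call" else
      .biallelic_decide(m[, "tm"], config$channels$FAM$species_tm,
                        config$tm_tolerance)$group
    m <- peaks_of(d_cy5, i)
    c314[i] <- if (is.null(m)) "no_call" else
      .biallelic_decide(m[, "tm"], config$channels$CY5$species_tm,
                        config$tm_tolerance)$group
  }
  data.frame(
    subject_id = ids, fut2_group = fut2_group, sec1p_ratio = sec1p_ratio,
    c59_group = c59,
    c59_genotype = vapply(c59, .biallelic_genotype_label, snp = "c.59T>G",
                          character(1), USE.NAMES = FALSE),
    c314_group = c314,
    c314_genotype = vapply(c314, .biallelic_genotype_label,
                           snp = "c.314C>T", character(1),
                           USE.NAMES = FALSE),
    classifier = config$classifier, stringsAsFactors = FALSE
  )
}
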