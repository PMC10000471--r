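---
title: "Melting-curve genotyping of FUT2/FUT3 and Lewis phenotype inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-curve genotyping of FUT2/FUT3 and Lewis phenotype inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmcaller)
```

## Scope

fmcaller is an in-silico counterpart of a triplex probe-based fluorescence
melting curve analysis (FMCA) assay for Lewis blood-group genetics in
Japanese populations. It covers four layers:

1. **Assay geometry** — the primer/probe configuration on *FUT2*, its
   pseudogene *SEC1P*, and the *SEC1P–FUT2* fusion allele, and the
   mismatch count of every probe–template duplex a haplotype can form.
2. **Curve simulation** — synthetic three-channel (HEX/FAM/CY5) melting
   curves for arbitrary genotype configurations.
3. **Calling** — peak detection on −dF/dT and genotype assignment,
   including fusion zygosity from relative peak heights, plus an
   instrument-style reference-curve (score/resolution) classifier.
4. **Inference** — allele naming, secretor status, Lewis red-cell
   phenotype, and cohort summaries.

Wet-lab concerns (PCR kinetics, asymmetric primer ratios, artificial
recombinants) are not modelled mechanistically: the probe signal amplitude
absorbs them.

## Assay geometry

The probe matches *SEC1P* exactly over its 25-nt window; the only variable
positions relative to the co-amplified species are the two homologous to
*FUT2* c.375 and c.385, where the probe carries G and A. Hence a Hamming
distance restricted to those two offsets equals the full-window distance,
and the duplex classes are 0 mismatches (SEC1P), 1 (385A allele; also the
fusion allele, which carries A at both positions), and 2 (385T allele). A
normal chromosome presents two probe sites (SEC1P copy + FUT2 copy); a
fusion chromosome, created by unequal crossover that removed the SEC1P
copy, presents one. These counts — not just the Tm classes — carry the
genotype information: diploid site totals are 4, 3 and 2 for zero, one and
two fusion alleles.

Coordinates are 1-based inclusive in the gene-local numbering convention
of the assay (`probe_assay()` defaults); both amplicons are 97 bp. Template
sequence outside the primer/probe windows is tracked symbolically, not
reconstructed.

## The melt model

Probe dissociation is a two-state transition: the bound fraction is
$\theta(T) = \left(1 + e^{(T - T_m)/w}\right)^{-1}$, so channel
fluorescence is

$$F(T) = \sum_s c_s\, A\, \theta(T; T_{m,s}, w) \;+\; b_0 + b_1 (T - 50) \;+\; \varepsilon(T),$$

with $c_s$ the diploid copy number of duplex species $s$, $A$ the
amplitude per copy, and $\varepsilon \sim N(0, \sigma^2)$ i.i.d. Gaussian
noise requiring an explicit seed. Defaults, with rationale:

* **Tm (HEX)**: 73 / 68 / 62 °C for 0/1/2 mismatches — the assay's
  characteristic values. **Tm (FAM/CY5)**: 66/59 and 64/57 °C for
  matched/mismatched duplexes — package conventions (the upstream assay
  publication for the FUT3 probes is not reproduced here); configurable.
* **Width** `w = 0.85` °C, giving a −dF/dT full width at half maximum of
  ≈3 °C (the FWHM of the logistic derivative is $2w\ln(3+2\sqrt2)$).
  Probe-FMCA peaks are visually of this scale, and it keeps the 62/68/73
  peaks resolvable while letting adjacent transitions overlap realistically.
* **Baseline** `b0 = 2`, `b1 = −0.002` per °C: a gentle negative drift
  imitating background probe dissociation. Kept small so that baseline
  drift contributes well under 1% of a single-copy peak height to −dF/dT;
  peak heights are additionally background-corrected at detection (below).
* **Noise** `σ = 1%` of the single-copy amplitude — a clean but not
  noiseless instrument; configurable, and `simulate_cohort()` has an
  optional `crosstalk_sd` knob to emulate the mild resolution loss of
  multiplexed acquisition.
* **Grid**: 50–80 °C at 0.1 °C, matching a continuous-acquisition ramp.

The acquisition window, Tm separation (at least twice the caller's binning
tolerance) and Tm-in-window constraints are enforced at construction.

What the simulator deliberately does **not** emulate: temperature-dependent
quenching and probe re-annealing artefacts, inter-channel optical
bleed-through (beyond the optional white-noise knob), plate-position
effects, and amplification failure modes. Passing tests therefore show the
*decision logic* is sound under the stated signal model; they do not by
themselves validate performance on instrument exports.

## Curve processing

−dF/dT is computed with a Savitzky–Golay first-derivative filter (local
quadratic fit, default window 11 points ≈ 1.1 °C, asymmetric end filters at
the boundaries; window 1 falls back to bare central differences). The
least-squares slope has roughly half the noise variance of
smoothing-then-differencing and preserves the position of symmetric peaks
exactly.

Peak detection keeps interior local maxima that clear **both** a height
floor and a topographic-prominence threshold, each 15% of the tallest
candidate's height. The two screens fail differently: baseline noise bumps
have small height but prominence inflated by negative dips on either side,
while wiggles riding a real peak's shoulder have height but negligible
prominence. Heights are reported above the curve background, estimated as
the 10th percentile of −dF/dT (flat inter-peak stretches dominate the
grid), so that they track dissociation amplitude rather than baseline
drift — this is what makes the copy-number ratios below clean. Peak
positions are refined below grid resolution by a parabola through the three
samples around each maximum. A flat curve yields an empty peak set, never
an error; an absolute floor (1e-9) prevents floating-point ripple on
constant curves from being read as structure.

## Calling rules

Peaks are assigned to expected species greedily by nearest Tm within a
±1.5 °C bin (half the minimum inter-species spacing). The FUT2 pattern
logic over present classes {0 mm, 1 mm, 2 mm}:

| pattern | call |
|---|---|
| {68} | fusion/fusion |
| {73, 62} | 385T/T |
| {73, 68} | 385A/A **or** 385A/fusion — by ratio |
| {73, 68, 62} | 385A/T **or** 385T/fusion — by ratio |
| other / stray peaks | unknown |
| none | no_amplification |

The ratio rule: ideal 73:68 height ratios are 2:2 vs 1:2 (two-peak) and
2:1 vs 1:1 (three-peak); the observed ratio is compared with
`ratio_threshold` (default 0.75, the midpoint between the ideal fusion-free
and fusion-het ratios on the normalised scale) times the fusion-free
expectation, and the fusion-bearing genotype is called below it. FAM/CY5
calls are pattern-only: matched peak → hom ref, both → het, mismatched →
hom alt, none or stray → no call.

The parallel **score/resolution** classifier mirrors melting-curve
gene-scanning software: similarity of a sample to each reference standard
is the Pearson correlation of max-normalised −dF/dT vectors mapped to
[0, 1] (the vendor's formula is proprietary; correlation preserves the
most-similar / second-most-similar ordering the decision needs), `score` is
the best similarity, `resolution` the margin over the runner-up, and a
sample is grouped only if both clear their thresholds. Ties break
lexicographically by group label, which is documented and deterministic.
With zero-noise standards this reproduces the characteristic threshold
behaviour: 385A/A and 385A/fusion standards are so similar (resolution
≈ 0.03) that default thresholds (0.70, 0.10) merge them into `unknown`,
while raised-score/zero-resolution settings (0.85, 0.00) separate them.
The peak-pattern caller is primary; the classifier is an optional pathway
(`classifier = "score_resolution"`), and call tables record which produced
each call.

## Known blind spots, reproduced on purpose

Two haplotypes are simulated to document assay limitations rather than fix
them. A chromosome carrying a loss-of-function variant outside the probe
window (modelled after *se^628*) is base-identical to the functional A
allele at both probed positions, so a weak secretor *Se^w*/*se^628* is
called 385A/T — i.e. reported as a full secretor. A chromosome with the
synonymous c.375A>G change presents two perfect-match duplexes and
masquerades as extra SEC1P signal: paired with an A allele the SEC1P peak
triples and swallows the single-copy 68 °C peak (yielding an anomalous
SEC1P-only profile, called `unknown`), and paired with a fusion allele the
profile is indistinguishable from a normal 385A/A — a clean miscall. Tests
assert these misbehaviours.

## Phenotype inference

Allele naming is closed-vocabulary: 385A → *Se*, 385T → *Se^w*, fusion →
*se^fus*; each 59G allele → *le^59* (a family label — *le^59*, *le^59,508*
and *le^59,1067* are indistinguishable by this tag), each 314T →
*le^202,314*, remainder → *Le*. The FUT3 double heterozygote (59T/G +
314C/T) is assigned the trans phase *le^59*/*le^202,314* — two null
alleles — with `phase_assumed = TRUE` flagged in the report, since the
assay does not phase the tags and a cis configuration would change the
phenotype. 314T/T homozygotes, though absent from the reference cohort,
follow the same rule rather than being rejected; genotypes implying more
than two tagged null alleles on two chromosomes (e.g. 59G/G with 314C/T)
are inconsistent and raise an error. Secretor status is the
maximum-function allele (*Se* > *Se^w* > null) and the Lewis phenotype
follows the two-enzyme rule, with Lewis-negative (no *Le*) overriding
secretor status. Undetermined calls propagate to `undetermined` phenotypes
and are counted separately in summaries, never dropped.

## Validation fixture and problem sizes

The shipped fixture (`inst/extdata/cohort_genotypes_japanese96.tsv`)
transcribes the genotype configuration of a 96-subject Japanese reference
cohort: 16 configurations spanning all six FUT2 groups, three c.59
genotypes and two c.314 genotypes, with known phenotype columns used as
expected output in tests. The test suite runs an exhaustive zero-noise
round trip over all 6 × 3 × 3 = 54 genotype combinations (exact recovery
required) and 1,000 seeded noisy cohort re-simulations (96 subjects × 3
channels each) requiring ≥99% call accuracy; observed accuracy at default
noise is ≈99.8%, with residual errors dominated by borderline
fusion-ratio decisions. Those sizes keep the whole suite comfortably
within a few minutes on a single core while the binomial uncertainty on
the accuracy estimate (~0.03% at n = 288,000) stays far below the 1%
margin being asserted.

## Numerical and degenerate-input conventions

* Temperatures are °C throughout; grids must be strictly increasing and
  uniform (tolerance 1e-6 on step equality).
* `simulate_channel`/`simulate_cohort` refuse noisy runs without a seed —
  reproducibility is a contract, not a convention.
* Curve tables round-trip through TSV at 0.1 °C / 10-significant-digit
  precision; readers validate headers, channels and grid uniformity and
  report the offending line.
* VCF output uses the three dbSNP identifiers plus a symbolic `<FUS>`
  record for the fusion allele (a structural event, not a SNP); genomic
  positions are configurable GRCh38 placeholders since the assay works in
  gene-local coordinates. Undetermined calls become `./.`.
* Equal-similarity and equal-distance ties break deterministically
  (lexicographic label order; nearest-peak assignment is greedy in species
  order).
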