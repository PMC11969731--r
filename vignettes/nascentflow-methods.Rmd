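---
title: "nascentflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nascentflow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentflow)
```

# What the package computes

`nascentflow` is a desk-scale pipeline for two complementary measurements of
RNA polymerase II biology:

1. **Nascent transcription** via metabolic RNA labeling (SLAM-seq): cells are
   pulsed with 4-thiouridine (4sU); incorporated 4sU is alkylated and read
   out as T>C conversions during reverse transcription. Reads carrying
   conversions mark nascent transcripts.
2. **The RNA Pol II protein interactome** via affinity-purification mass
   spectrometry (AP-MS) with RNA Pol II as the bait.

Downstream, effects are stratified by gene length and exon count, and
premature transcription termination is detected as intronic polyadenylation
(IPA) from per-intron read coverage.

Every stage is exercisable on synthetic data generated in-package, so the
whole analysis is testable with no downloads.

# SLAM-seq quantification

## Conversion counting

For each aligned read the quantifier recovers, from the CIGAR string, the MD
tag and the read sequence, the reference base at every aligned position. It
counts:

- `n_ref_T`: reference-T positions covered by the read and not in an
  optional SNP mask;
- `n_TC`: those positions where the read base is C.

Minus-strand alignments are evaluated as A>G in genome space, which is T>C
in transcript space. A read is classified *labeled* when
`n_TC >= threshold`; the threshold defaults to 1 (the smallest value
consistent with "any conversion marks a nascent read") and is configurable
because upstream tools do not document their default publicly.

## RPMu normalization

Per sample,

$$\mathrm{rpmu}(t) \;=\; \frac{\mathrm{tcReadCount}(t)}
{\sum_{\text{all transcripts}} \bigl(\mathrm{readCount} - \mathrm{tcReadCount}\bigr)}
\times 10^7 .$$

The denominator is the library-wide non-TC read sum — a sequencing-depth
proxy — so rpmu is invariant under uniform scaling of all counts in a
sample and strictly increasing in the TC count at a fixed denominator. A
sample whose reads are *all* TC reads has an undefined normalization and is
rejected as degenerate.

## Differential labeling

Differentially labelled transcripts (DLTs) are called at fixed thresholds:
p-value < 0.05 and |log2 fold change| >= 1, with the fold change taken on
condition means of rpmu plus a pseudocount (default 1; negligible at
realistic rpmu magnitudes of $10^4$–$10^6$, and it only exists to keep the
log defined at zero).

**Choice of test.** The default is Student's equal-variance t-test on
per-replicate `log2(rpmu + pseudocount)`. We deliberately did not default to
Welch's test: at n = 3 replicates per condition Welch's random
Satterthwaite degrees of freedom make the test measurably conservative
(empirical size ~0.035 at nominal 0.05, measured by simulation on normal
data), which breaks type-I-error calibration, while Student's test is exact
under the log-normal null and is the test named throughout the upstream
analysis description. Welch remains available (`test_method = "welch"`), as
does an overdispersed-count mode (`test_method = "nb"`: quasi-Poisson Wald
on raw TC counts with size-factor offsets derived from the non-TC sums).
Neither mode claims to reproduce DESeq2 numerically; the thresholds, not
the testing machinery, define the DLT calls. No multiple-testing correction
is applied by default (the thresholds act on raw p-values); BH correction
is available via `bh = TRUE`.

# Gene-length and exon-count stratification

Genes are trichotomized by genomic span (exons + introns):
short = [0, 250), medium = [250, 10001), long = [10001, ∞) nucleotides. The
source description of these boundaries is internally inconsistent by one
nucleotide at each cut (Methods vs Results); the Methods boundaries are the
default and the cutoffs are a visible parameter rather than a hidden
constant. Per-stratum shift tests default to a one-sample t-test of the
stratum's log2FC values against zero (a boxplot-per-stratum comparison most
directly supports this); pairwise between-strata tests are one flag away.
Exon-count stratification splits at > 30 exons by default. The
labeling-time linearity check reports both the raw TC-count ratio and the
rpmu ratio between two labeling durations.

# AP-MS interactome

The workflow, in enforced order:

1. **Pseudo-floor**: intensities of exactly 0 (missing detections) are
   recoded to 1. Idempotent; floored proteins are flagged `imputed_floor`.
2. **Bait normalization**: every protein's intensity is divided by the
   bait's intensity in the same sample, cancelling per-sample
   immunoprecipitation-efficiency differences; the bait row becomes exactly
   1. Swapping steps 1 and 2 gives different (wrong) numbers, so the
   differential step refuses matrices whose bait row is not 1.
3. **Differential interactome**: replicate means per condition, fold change
   = mean treated / mean control, two-sample Student's t-test on
   per-replicate normalized values (a `log_scale` flag tests log2 values
   instead — the statistically safer option, exposed but not default, since
   the source describes testing the intensity values themselves). A protein
   is *gained* when p < 0.05 and log2FC > 0, *lost* when p < 0.05 and
   log2FC < 0. A described "fold change more/less than zero" rule can only
   refer to the sign of the log2 fold change (linear fold changes are
   always positive), and that is how it is implemented.

Set-level utilities implement the stringent dual-response cut (significant
in two perturbations with |log2FC| >= 2 in both, concordance reported),
upset-style exclusive/intersection sets across conditions, and
complex-level relative-binding summaries (per-member treated/control ratio
of normalized means).

# IPA detection

The scorer is an explicitly simplified change-point detector, not a
re-implementation of the external caller used upstream (whose score formula
is not public): over all splits of a per-intron coverage profile with at
least `min_flank` bases on each side, it maximizes

$$\mathrm{score}(k) = \frac{\bar d_{\le k} - \bar d_{> k}}{\bar d_{\le k}},$$

ties to the leftmost position. An event passes when the upstream mean is at
least `min_depth` and the score at least `min_score`. Defaults
(`min_flank = 100`, `min_depth = 10`, `min_score = 0.25`) satisfy the
power/false-positive targets on the synthetic model: detection >= 90% at
usage 0.4 and depth 50, pass rate <= 1% on flat Poisson profiles at depth
100. Because the score definition is package-local, only within-run
contrasts of event counts are meaningful, never absolute counts. Only
composite (coverage-drop) events are modeled.

# The synthetic-data generators

The generators state the world the tests live in:

- **Transcriptome**: log-normal genomic spans (default median 20 kb,
  sdlog 1.6 — human-like), exon counts 1 + Poisson(8), introns carved from
  the span with Dirichlet proportions. `n_uridines` is proportional to the
  read length (default 30 T positions per 100-nt read), not the gene
  length, because reads are fixed-width windows.
- **Labeling**: a labeled read converts each uridine with probability
  `time × rate + background`; an unlabeled read with probability
  `background`. Defaults mirror the linear labeling regime
  (rate $10^{-4}$ per uridine per minute, background $10^{-4}$, 10-minute
  pulse). Sampling uses exact binomial tails, so cost is per transcript.
- **AP-MS**: per-protein log-normal baselines, a per-sample IP-efficiency
  scale (this is how the bait varies across samples; it cancels exactly
  under bait normalization), measurement noise of sdlog `lognormal_sigma`
  on interactors, spikes applied as `2^log2_effect` in the treated
  condition only, missing detections as exact zeros. The bait row carries
  no independent measurement noise: `lognormal_sigma` is therefore the
  noise of *bait-normalized* intensities, the calibration under which the
  stated spike-recovery and false-positive-rate targets are achievable
  (folding noise into the bait doubles the variance of normalized values
  and measurably misses those targets).
- **IPA coverage**: Poisson depth around `depth` upstream and
  `depth × (1 − usage)` downstream of a site placed mid-intron.

**What a green test does not establish.** The generators omit PCR
duplication, UMI structure, non-uniform error models, alignment artifacts,
peptide-level MS effects and real 4sU uptake chemistry. Green acceptance
tests establish that the *analysis* is correct and calibrated on data with
the assumed statistical structure — not that real libraries satisfy those
assumptions.

## Seeding

Every generator derives its stream from `substream_seed(seed, component)` —
a polynomial rolling hash of the component name folded into the global seed
modulo $2^{31}-1$ — so adding a generator never perturbs existing streams.
Within the test suite the same splitter decorrelates repetition seeds
(consecutive raw seeds produce visibly correlated Mersenne–Twister streams;
we measured a pure exact t-test drifting to an empirical size of 0.0484
over one such block of 100 consecutive seeds).

# The labeling-time linearity target

The one quantitative acceptance target is the intensity ratio between 30-
and 10-minute labeling, expected ~threefold in the linear regime. Two
subtleties, both decided analytically before any test was run:

- With a conversion-call threshold of 1, the *raw* TC-read-count ratio is
  concave in the per-read conversion probability and further diluted by the
  background rate; at the stated parameters its analytic value is ~2.74.
- The *normalized* (rpmu) ratio additionally benefits from the smaller
  non-TC denominator at 30 min; its analytic value is ~2.91.

The pipeline's definition of label intensity is the RPMu-normalized signal,
so the acceptance target asserts the normalized ratio (measured: ~2.90,
within 5% of 3). `label_time_ratio()` always reports both so the raw
concavity is visible rather than hidden.

# Numerical choices and degenerate inputs

- p-values are floored at `1e-300`; a zero-variance comparison with equal
  means reports p = 1, with unequal means p ≈ 0.
- All-zero transcripts report log2FC = 0, p = 1 (not an error).
- Strata with fewer than two genes are flagged untestable rather than
  erroring.
- Introns shorter than `2 × min_flank` are skipped with a warning.
- Tabular outputs are sorted by id; reruns under one seed are
  byte-identical except the manifest timestamp.
- Coordinates are 0-based half-open internally; GTF's 1-based closed
  intervals are converted at the boundary.

# Known limitations

- The conversion-rate kinetics are linear by construction; saturation at
  long labeling times is out of scope.
- Multi-mapping reads are assumed resolved upstream; one transcript per
  read.
- SNP masking consumes a position list; no variant calling is performed.
- The IPA scorer recognizes single step-downs only; skipped terminal exons
  and multiple sites per intron are out of scope.
- Config files are JSON (no YAML/TOML parser among the package's
  dependencies).
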