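---
title: "Models and methods: contamination-aware translatome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: contamination-aware translatome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboclean)
```

## The measurement and its failure mode

RiboTag/TRAP designs pair, for every tissue sample, an immunoprecipitated
(IP) library of mRNAs bound to the tagged cell type's ribosomes with an
input library of total tissue RNA. The log-ratio of a gene's abundance in
IP versus input measures its enrichment on the tagged ribosomes; changes of
the IP fraction across conditions are read as the cell type's translational
response.

The known failure mode of the assay is ambient contamination: a fraction of
each IP library is not ribosome-selected material from the tagged cells but
a sample of the bulk mRNA pool, co-purified non-specifically with the
beads. When tissue composition changes drastically — an inflammatory
expansion after injury is the canonical case — transcripts of the invading
cell types become so abundant in the ambient pool that they appear sharply
"upregulated" in the IP fraction, despite never being translated in the
tagged cells. Every statistic in this package exists to make that artifact
visible and removable.

## Count model

All tests run per gene on a negative binomial generalized linear model with
log link and RLE size-factor offsets:

$$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), \qquad
  \log \mu_{gj} = \log s_j + x_j^\top \beta_g .$$

* **Size factors** are plain median-of-ratios: for sample $j$,
  $s_j = \mathrm{median}_g\, K_{gj} / (\prod_{j'} K_{gj'})^{1/n}$ over the
  genes with nonzero counts in every sample. Factors are not rescaled
  further; the estimator is invariant to a global rescaling of the counts
  and responds to the scaling of a single library through the ratio of its
  factor to the others'.
* **Low-count filter**: genes with fewer than 10 counts summed across all
  samples are removed before any fit (configurable, `min_total`).
* **Fitting** is iteratively reweighted least squares on the natural-log
  scale (weights $\mu/(1+\alpha\mu)$, at most 100 iterations, relative
  log-likelihood tolerance $10^{-10}$); coefficients and standard errors
  are reported in log2 units. Non-convergent genes are flagged, not
  dropped. Estimates whose magnitude exceeds 10 log2 units — in practice,
  genes with an all-zero group — are capped at ±10 and flagged
  (`lfc_capped`) so rankings survive without infinite values.
* **Dispersion** is estimated by method of moments on normalized counts
  within the replicate groups defined by the design, floored at $10^{-8}$.
  At the replicate numbers these designs actually have (three pairs per
  condition), the raw per-gene estimate is extremely noisy: close to half
  the genes draw a negative moment estimate, land on the floor, and would
  be tested as if Poisson. We therefore fit a mean–dispersion trend
  $\alpha(\mu) = a_0 + a_1/\mu$ across genes and use the *maximum* of the
  per-gene estimate and the trend. In a 2,000-gene null simulation (3 vs 3,
  true $\alpha = 0.05$) this brings the Wald test's empirical type-I error
  at nominal 0.05 from ≈ 0.13 down to ≈ 0.04; the trade is a little power
  on genuinely low-dispersion genes, which we accept as the conservative
  default. `dispersion = "moments-raw"` restores the unshared estimator,
  and a numeric vector fixes dispersions exactly.
* **Testing**: Wald statistics are estimate/SE with two-sided normal
  p-values; the likelihood-ratio test refits the nested design at the full
  model's dispersions and refers $2(\ell_{full}-\ell_{red})$ to
  $\chi^2_{\Delta\mathrm{rank}}$. Multiple testing is Benjamini–Hochberg
  within each contrast over the post-filter gene universe.

## Enrichment, interaction, and the two-arm filter

Within one condition, the `fraction` coefficient of an IP-vs-input fit is
the gene's enrichment, classified with inclusive thresholds at q < 0.05:
depleted ($\le -0.5$), enriched ($\ge 0.5$), highly selective ($\ge 2$).

Across conditions, the `condition:fraction` interaction of the full
two-factor model is the **differential enrichment**

$$\Delta_g = \log_2\!FC(\mathrm{IP/input})_{injured}
           - \log_2\!FC(\mathrm{IP/input})_{naive},$$

which is the discriminating statistic: a gene whose IP change merely
mirrors its input (ambient) change has $\Delta \approx 0$ regardless of how
large the IP fold-change is.

A DE call in the IP fraction (|log2FC| ≥ 1, q < 0.05) becomes
high-confidence only if it passes one of two arms:

1. **differential enrichment**: $|\Delta| \ge 1$, q < 0.05, with
   $\mathrm{sign}(\Delta) = \mathrm{sign}(\log_2 FC)$ — the enrichment
   moved with the expression change; magnitude equality beyond the
   threshold is deliberately not required;
2. **constant enrichment**: log2FC(IP/input) ≥ 1 at q < 0.05 both in the
   reference condition and in the tested condition — the tagged cell type
   is the gene's major expressor, so even input-parallel changes are its
   own signal. "Before and after" is operationalized as these two
   endpoints; `arm2_mode = "all"` additionally requires enrichment at every
   profiled condition for users who prefer the stricter reading.

Down-regulated genes pass through the same rules with mirrored signs. Ties
at any threshold pass (inclusive comparisons, one documented convention).
The acute-specific selector keeps up-filtered acute responders that later
either lose significance or fall at least two-fold (1 log2 unit) below
their acute response.

Arm 2 does most of the work in practice: for a genuine responder of the
tagged cell type, the input pool partially tracks the IP change (the tagged
cells contribute to the input too), which drags $\Delta$ toward the arm-1
boundary, while strong constant enrichment is robust. Arm 1 in turn is what
rejects the contamination profile — depleted genes with unchanged
de-enrichment never reach either arm.

## Set statistics

Overlaps between gene lists use the exact upper-tail hypergeometric
probability $P[K \ge k]$ and report the representation factor
$k/(n_1 n_2/N)$ (1 = exactly chance). The upper tail at $k=0$ is 1; an
empty set yields an undefined (NA) representation factor rather than a
division by zero.

Operon-style specificity uses a resampling z-score: the observed overlap of
a query list with a target set, standardized against the overlap
distribution of `K` random query-sized draws from the expressed background
(genes surviving the low-count filter), with the sample (K−1) standard
deviation. The default is K = 1,000 — large enough that the z > 5 rule is
meaningful — while `small_resample` (K = 10) reproduces the small-resample
variant of the procedure whose null standard deviation is too unstable to
support a stringent cutoff. One draw list is shared across target sets per
query (`share_null = FALSE` redraws); whether the null standard deviation
should be sample or population is not settled by convention, and we
document the K−1 choice rather than hide it.

## The simulator

`sim_config()`/`simulate_experiment()` generate the study design the
statistics are meant for: four conditions (naive, dpi2, dpi10, dpi42) × two
fractions × three replicate pairs, negative binomial counts from a
cell-type mixture. Each gene has a primary cell type (OL-biased assignment,
2:1:1:1) with a log-normal baseline rate (meanlog 4, sdlog 1.2) and 5%
leak expression elsewhere. Tissue proportions encode an inflammatory
expansion — microglia/macrophages 10% → 45% → 30% → 15% across the four
conditions, the other types shrinking correspondingly — values chosen once
as a plausible contused-CNS time course. Injury acts through per-gene,
per-cell-type log2 fold-changes: by default 5% of genes carry a genuine
±2-unit response in the tagged type, and a further 5% carry a +3-unit surge
in microglia (the contaminants). The input library samples the ambient pool
$\sum_t \pi_{t,c}\lambda_{gt}2^{\beta_{gtc}}$; the IP library samples
$(1-c)\,(\text{tagged pool}) + c\,(\text{ambient pool})$ with contamination
fraction $c = 0.1$ by default — a chosen scenario, not an estimate, since
the real contamination share of any given experiment is unknown. Library
sizes are drawn log-uniformly from $[5\times10^5, 2\times10^6]$ to exercise
the normalization. A seed is mandatory; identical seeds give identical
experiments.

The truth table flags, per gene and injured condition, genuine responders
(|tagged-cell log2FC| ≥ 1), contaminant-driven genes (ambient pool moved ≥
1 log2 unit while the tagged cell did not move at all), and the analytic
enrichment $\log_2(\text{tagged share}/\text{ambient share})$.

What the simulator does **not** emulate: batch effects beyond library size,
gene–gene count correlation, UMI/read-level structure, isoform complexity,
and dispersion heterogeneity beyond the configured values. Passing the
recovery benchmarks therefore demonstrates that the statistics do what they
claim on data generated by this mixture mechanism — not that any particular
real experiment has a 10% contamination share.

## Numerical and design choices

* No fold-change shrinkage: thresholds like |log2FC| > 1 are applied to raw
  MLEs, matching how such cutoffs are conventionally read.
* No pseudo-counts in the GLM; the ±10 cap plus flag handles zero groups.
  The count-based marker QC, by contrast, uses normalized counts + 1 — a
  deliberately biased but zero-safe ratio for a descriptive report.
* Pairing of IP/input libraries is carried in the metadata and available as
  a blocking fixed effect (`pair_effect = TRUE`), but the default
  interaction model is group-level, matching the stated formula of the
  analysis it re-implements; both modes are exposed because the two
  readings of "paired" differ.
* The interaction q-values default to the Wald test on the interaction
  coefficient; `test = "lrt"` gives the likelihood-ratio alternative.
* RLE medians are taken on ratios (not log-ratios); with an even number of
  reference genes this differs from log-space medians in the 4th decimal —
  both conventions are defensible, ours is stated.
* PCA runs on log2(normalized + 1), feature-centered and unscaled by
  default, with a scaling flag.
* qPCR ΔΔCt folds combine multiple reference transcripts by arithmetic mean
  of their Ct values before differencing.
* All randomness in the pipeline driver flows from one root seed expanded
  deterministically per stage; `run_all` is bit-reproducible given config +
  seed, and every run writes a provenance record (config hash, seed,
  package version).

## Problem sizes used in the test suite

The shipped benchmarks run at desk scale, chosen to exercise the statistics
with stable margins: the default scenario is 2,000 genes × 24 libraries;
recovery and contamination-suppression claims average 20 simulated
experiments; null calibrations use 2,000-gene 3-vs-3 simulations and 1,000
resampled queries; the enumeration oracle for the hypergeometric test
covers all universes up to N = 25. On this scenario the two-arm filter
recovers ≈ 99% of true ±2-unit responders while the contaminant-driven
fraction among final calls stays ≈ 0.1% (55% among unfiltered DE calls);
exact values for any seed are reproduced by `scripts/acceptance.R`.

## Known limitations

* The dispersion trend is a two-parameter curve without empirical-Bayes
  weighting; genes with genuinely extreme dispersions are handled
  conservatively rather than optimally.
* Wald p-values use the normal reference; at n = 3 per group they are
  approximate, which is why the conservative dispersion default matters.
* The two-arm filter inherits the sensitivity/specificity trade of its
  thresholds: genes whose true response is mirrored in the ambient pool and
  that are not constantly enriched are unrecoverable by design — the filter
  prefers missing them to reporting contamination.
* Gene identifiers are opaque strings; no symbol mapping is attempted.
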