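---
title: "Methods: cross-state vs intra-replicate scoring for paired omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-state vs intra-replicate scoring for paired omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsnr)
```

## The problem and the model

A two-state × two-replicate paired transcriptome–proteome experiment — the
minimal design that still measures its own noise — cannot support per-feature
variance estimation, so `omicsnr` takes a population view. On log2 abundances
(alignment counts for RNA, total ion counts for protein):

* the **cross-state score** $Z_f = \bar{x}_{f,B} - \bar{x}_{f,A}$ (replicate
  means per state) carries signal plus noise;
* the **intra-replicate score** $R_{f,s} = x_{f,s,1} - x_{f,s,2}$ carries
  noise only, under the assumption that biological replicates differ by
  measurement and culture noise, not by condition.

If per-sample noise is roughly i.i.d. with sd $\sigma$ within a layer,
$\mathrm{sd}(R) = \sqrt{2}\sigma$ and, for null features,
$\mathrm{sd}(Z) = \sigma$: the R population is a direct, assumption-light
yardstick for Z. Everything downstream — the Znet transform, the system and
per-feature S/N, and the Monte-Carlo FDR — is a comparison of these two
populations.

Key modelling assumptions, stated explicitly:

1. noise is exchangeable across replicates and approximately homoscedastic on
   the log2 scale within a layer (abundance-dependent variance is *not*
   modelled);
2. most features are null, so population quantiles of Z are dominated by
   noise plus a minority of signal;
3. the two layers are normalized as separate populations (separate Rnet and
   Pnet scores), because their noise scales differ several-fold.

## Znet and the ±1.65 rule

The default normalization is a rank-based inverse-normal transform within the
layer: $Znet_f = \Phi^{-1}\!\big((\mathrm{rank}(Z_f) - 0.5)/n\big)$ with
average ranks for ties. The offset $-0.5$ keeps percentiles strictly inside
$(0,1)$ so the extreme features get finite scores. By construction
$|Znet| > 1.645$ selects the outermost ~10% of the population — the call rule
"|Znet| > 1.65 is up/down-regulated" is then a *population asymmetry*
statement: it flags the features whose cross-state change is most extreme
relative to everything else measured in that layer, which is the right notion
when the null fraction is high but unknown. The cost is that the flagged
fraction is fixed (~10%) regardless of how much true signal exists; that is
what the S/N machinery below corrects for.

The alternative `noise_scaled` normalization,
$Znet_f = (Z_f - \mathrm{median}(Z))/\hat\sigma_Z$ with
$\hat\sigma_Z = \mathrm{sd}(R)/\sqrt{2}\cdot\sqrt{2/n_{rep}}$, anchors the
cutoff to the noise distribution instead of the population rank; on pure-noise
data it flags ~10% two-sided at 1.65 and *fewer* as signal grows. Both are
rank-preserving, so they disagree only near the boundary. Calls use strict
inequalities; a score of exactly ±1.65 is not significant.

Degenerate inputs: fewer than 50 defined Z in a layer is an error (percentile
calibration on a smaller population is meaningless); an all-identical Z
population yields Znet = 0 everywhere with a warning. Features quantified in
only one state carry no Znet and are reported qualitatively
(`present_only_in_B` / `absent_in_B` / `undetected`), mirroring the `+`/`−`
symbols of printed pathway tables.

## Signal-to-noise ratios and the FDR calibration

The **system S/N**, $\mathrm{sd}(Z) / \mathrm{mean}_s\,\mathrm{sd}(R_s)$,
summarizes a whole layer: ~$1/\sqrt 2$ on pure noise, 3+ when cross-state
responses are profound. "Mean of the per-state sds" (two states here) is used
as the denominator.

The **per-feature S/N** is $|Z_f| / \max(\mathrm{rms}(R_{f,A}, R_{f,B}),
\varepsilon)$ with $\mathrm{rms} = \sqrt{(R_A^2 + R_B^2)/2}$. The noise floor
$\varepsilon$ matters more than it looks. With two replicates per state the
per-feature rms is a 2-df estimate, and the unfloored ratio is distributed as
$|t_2|/\sqrt{2}$ under the null — a *scale-free* heavy-tailed law whose tail
above 2.8 is ≈ 6% no matter how small the noise is. A floor at a low quantile
(e.g. the 5th percentile of rms, kept available as
`snr_floor = "quantile05"`) leaves that tail essentially intact, so no S/N
cutoff in a usable range can have a 10% FDR. The default
(`snr_floor = "population"`) floors the denominator at the **population mean
rms** — the system's noise scale: a feature can be *penalized* for unusually
noisy replicates (its own rms exceeds the floor) but never *rewarded* for a
luckily quiet pair. Under this floor the null S/N tail is governed by the
Gaussian body, and the Monte-Carlo calibration below lands the 10%-FDR point
near S/N ≈ 2.8 in the shipped regime. The statistic is dimensionless and
invariant to rescaling all log2 differences by a common factor.

The **Monte-Carlo FDR** simulates null datasets with zero cross-state effect:
$Z^\ast = (R'-R'')/2$ and denominators $\mathrm{rms}(R''', R'''')$ from
independent draws of the pooled empirical R values (`empirical_R`; a
`gaussian_fit` variant draws from $N(0, \mathrm{sd}(R))$), using the
*observed* population's noise floor so null and observed S/N share a scale.
Then $\mathrm{FDR}(c) = \overline{\#\{null > c\}} / \max(1, \#\{obs > c\})$,
clipped to [0, 1] — an empirical-Bayes style estimate with the observed
exceedances in the denominator. Because both counts shrink with $c$, the raw
ratio need not be monotone; the curve is made non-increasing by taking the
running maximum from the right (the conservative direction, in the spirit of
q-values). Reported proteins with S/N below the calibrated 10%-FDR cutoff
carry a `*` marker in pathway tables.

## Quantitation choices

**RNA.** The counting engine indexes every k-length window (default k = 100)
of the gene models and their reverse complements in a hash, and a read
increments a gene iff its first k bases match a window exactly — no
mismatches, gaps or scores, relying on high base quality for counting
statistics. Reads longer than k are truncated to their first k bases; shorter
or non-ACGT reads are skipped and tallied. Open choices resolved here:
multimapping reads count once toward *every* matching gene by default
(`multimap = "all"`, with `"unique"` and `"fractional"` available), and
`strand_mode = "both"` since library orientation is not assumed. The
acceptance filter (≥ 2 alignment counts, applied per sample) marks
sub-threshold entries as *not quantified* rather than zero, and log2 is only
applied to accepted counts, so no pseudo-count is ever needed.

**Protein.** Per protein and sample, abundance is the log2 of the summed TICs
of peptides passing log(e) < −1.5 (strict); a protein is quantified in a
state only if ≥ 2 passing peptides appear in *both* replicates of that state.
Absent values propagate downstream as `−`, never imputed.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` defaults encode the study conditions the package is
calibrated against: 5200 genes with log2 RNA abundance ~N(10, 1) (range
roughly 7–13), 16% truly differential with a fixed |effect| of 3 log2 units
(sign ±, split symmetrically across the two states), per-sample noise sd 0.25
(RNA) and 0.6 (protein), giving system S/N ≈ 3.4–3.5 and ≈ 1.5–1.6
respectively; protein true levels are RNA plus a per-gene offset
~N(10, 0.7) plus decoupling noise sd 0.9, attenuating per-state R² into the
0.24–0.42 window; protein detection is top-26% by true abundance with a
logistic dropout edge (width 0.2 log2 units), yielding ≈ 1360–1400 detected
proteins and log2 TICs roughly 17–23. A fixed effect magnitude (rather than
an unknown effect distribution) is deliberate: it makes power and FDR
properties analytically checkable against the generator truth. Peptide
evidence conserves protein TIC exactly by construction, and violator proteins
are planted to break each acceptance filter in a known way. qPCR triplicates
are moment-matched (sample mean and sd equal the requested values exactly),
so t-tests on the raw groups reproduce summary-statistics t-tests to machine
precision. Reads are error-free exact substrings — an optional
mismatch-injection flag exists solely to verify that mismatched reads are
*not* counted.

Not emulated: sequencing error, GC/positional bias, fragment-length effects,
abundance-dependent (heteroscedastic) noise, spectrum-level peptide
identification, or correlated replicate structure. Passing tests therefore
demonstrate the pipeline's internal calibration and correctness on idealized
data; they do not certify real-data error rates, where heteroscedasticity and
identification artefacts can widen the tails.

## qPCR utilities

Standard curves are least-squares fits of Cq on log10 template quantity over
a 10-fold dilution series (200 → 0.02 ng); amplification efficiency is
$10^{-1/slope} - 1$ (slope −3.3219 ⇔ 100%), curves with non-negative slope
are flagged invalid, and unknowns are quantified as
$10^{(Cq - intercept)/slope}$. Group comparisons use a two-tailed two-sample
t-test computed from mean ± sd (n) summaries; the pooled (Student) variant is
the default, with Welch available — the two agree exactly for equal sds and
group sizes, and both round to p = 0.04 for the worked triplicate example
(0.89 ± 0.15 vs 0.49 ± 0.18, n = 3). In a three-condition comparison of such
summaries (one fatty-acid condition against two glycerol growth phases) the
pairing matters: the example pairs the fatty-acid culture with the
stationary-phase glycerol culture; pairing it with the exponential phase
instead gives p ≈ 0.006.

## Problem sizes and runtime

The shipped test suite and acceptance script run the calibration checks at
the sizes at which their guarantees are stated and comfortably within a
single CPU: 10,000 null features for the ±1.65 call-rate check (the
rank-based rule is deterministic at fixed n: 9.9% at n = 10,000), 5,000
features × 200 Monte-Carlo simulations for the FDR(2.8) check, 5,000 features
for parameter-recovery checks (10% relative error), and ≤ 10 kb references
with ≤ 1,000 reads for exact-counter/oracle equivalence. The full suite runs
in a few seconds.

## Known limitations

* Two replicates per state are assumed by `intra_replicate_R()`; larger
  designs would need a generalized noise score.
* The fixed ~10% flag rate of the rank-based rule is a feature of the
  population definition, not an error rate; use the S/N + FDR machinery to
  attach error control to calls.
* The FDR denominator uses observed exceedances and is undefined (guarded to
  a warning) when nothing exceeds the smallest cutoff.
* No shrinkage, moderated variances, count models, or multi-state designs —
  the procedure is intentionally score-based.
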