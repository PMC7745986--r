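---
title: "Counting-based basal/luminal subtyping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting-based basal/luminal subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosubtype)
```

## The problem

Muscle-invasive urothelial cancer splits into basal-like and
luminal-like intrinsic subtypes with clinically different behaviour.
The reference way to call the subtype — RNA-seq plus a transcriptome
centroid classifier — is impractical for routine FFPE specimens, so a
small signature (47 endogenous genes, 4 housekeeping genes, negative
controls) is measured instead by molecular barcode counting on the
NanoString nCounter platform. Two facts drive the whole design:

1. **Counts from one lane are self-contained.** Background, quality
   control and scaling can all be computed from a single sample's
   controls, so the classifier can stay a *single-sample* diagnostic:
   nothing about a patient's call depends on which other samples were
   run. `nanosubtype` enforces this structurally (no operation in the
   normalization chain sees more than one column at a time) and tests
   it (cohort runs equal single-sample runs bit-for-bit).
2. **A classifier trained on one platform miscalls on another.**
   Centroids learned from log RNA-seq expression are on the wrong scale
   for count-derived expression; the cure is to *re-train* the same
   classifier form on counts, using the established platform's calls as
   the supervising labels. The package ships that whole loop —
   normalization, training, prediction, cross-validation, concordance —
   plus a simulator so every stage is testable without instrument data.

## Normalization chain

For each sample $s$, with negative-control counts $g_1,\dots,g_m$
(floored at 1 read):

* background $B_s = (\prod_i \max(g_i,1))^{1/m}$;
* every housekeeping and endogenous count **strictly** below $B_s$ is
  set to 0 ("below" is read literally; a count equal to the background
  survives);
* the sample is **excluded** if any housekeeping gene was zeroed — its
  lane signal is indistinguishable from noise. Excluded samples remain
  in the QC report with the offending genes named;
* the normalization factor is $F_s = 100 / H_s$, with $H_s$ the
  geometric mean of the (thresholded, floored) housekeeping counts, and
  all endogenous values are multiplied by $F_s$; afterwards the
  housekeeping geometric mean is exactly 100 in every retained sample
  (a tested invariant, tolerance $10^{-9}$ relative);
* expression is then $\log_2(x + 1)$.

Three choices here were genuinely open:

* *Thresholding vs dividing by the background.* "Scaled to the
  geometric mean of the negative controls" could mean dividing each
  count by $B_s$. For every above-background probe the division cancels
  exactly through the subsequent $100/H_s$ scaling, so the simpler
  thresholding-only reading is implemented; the cancellation is the
  per-sample scale-invariance property test (rescaling a lane by $c$,
  controls included, leaves final values unchanged whenever the
  threshold crossings are unchanged).
* *Log base and pseudocount.* Base 2 matches the comparison platform's
  log2 convention; a pseudocount of 1 is required because thresholding
  creates zeros, and maps them to 0 on the log scale.
* *The floor.* The 1-read floor precedes every geometric mean (negative
  controls and housekeeping alike), so an all-zero negative row yields
  $B_s = 1$ rather than 0.

The comparison-platform preprocessing (`median_center()`) subtracts the
per-gene across-sample median from log2 expression — the one deliberate
exception to per-sample purity, because the *training* platform in the
two-platform workflow is a cohort-level matrix by nature.

## The classifier

Nearest shrunken centroids on the $G = 47$ signature genes: class
centroids $\bar x_{kj}$, overall centroid $\bar x_j$, pooled
within-class deviation $s_j$ (divisor $n - K$), fudge
$s_0 = \mathrm{median}_j\, s_j$, $m_k = \sqrt{1/n_k - 1/n}$,
standardized difference
$d_{kj} = (\bar x_{kj} - \bar x_j) / (m_k (s_j + s_0))$, soft threshold
$d'_{kj} = \mathrm{sign}(d_{kj}) \max(|d_{kj}| - \Delta, 0)$, shrunken
centroid $\bar x'_{kj} = \bar x_j + m_k (s_j + s_0) d'_{kj}$, and call

$$\hat k(x) = \arg\min_k \; \sum_j \frac{(x_j - \bar x'_{kj})^2}{(s_j + s_0)^2} \; - \; 2 \log \pi_k .$$

Parameters that matter:

* **$\Delta$ (shrinkage), default 0.** The 47-gene panel is a fixed,
  externally validated signature; there is nothing to eliminate, so by
  default every gene stays. `choose_delta()` provides the standard
  cross-validated selection (largest $\Delta$ attaining the minimum CV
  error) for users who do want parsimony.
* **Priors, default empirical.** Class frequencies of the training set,
  matching the ecosystem default; `"uniform"` is one switch away and is
  the right choice when the training prevalence is not representative.
* **$s_0$.** The median of $s_j$, with the even-length median taken as
  the midpoint of the central pair. If the training data are perfectly
  separated (every $s_j = 0$ for half the genes or more — reachable in
  simulation with zero biological noise), $s_0$ would be 0 and the
  discriminant undefined; the package substitutes
  $10^{-6} \times$ (overall SD) with a warning rather than failing.

Reported per sample: the discriminants $\delta_k$, softmax posteriors
$e^{-\delta_k/2} / \sum_l e^{-\delta_l/2}$ (invariant to the shared
prior constant), Pearson correlations $r_k$ to each shrunken centroid
over the full gene list, and the **basal score**
$(1 + r_{basal} - r_{luminal})/2$, clipped to $[0,1]$. The published
description of the score — a scaled distance from 0 (luminal) to
1 (basal) — comes without a formula; this stand-in is symmetric,
monotone in relative basal affinity, 0.5 at indifference, and hits the
endpoints exactly when a sample correlates perfectly with one centroid
and anti-perfectly with the other. Correlations are taken against the
*shrunken* (trained) centroids; the unshrunken alternative differs only
at $\Delta > 0$.

Degenerate cases are deterministic and flagged: an exact discriminant
tie sets `tie = TRUE` and resolves to the larger prior, then to the
lexicographically last class (so basal/luminal at uniform priors →
luminal); a zero-variance expression vector gets $r = 0$ and
`flag = TRUE`; genes missing at prediction are refused by name unless
`impute_missing = TRUE` fills them from the overall centroid (a
deliberate barrier — silently imputing signature genes in a
single-sample diagnostic is how ports go wrong).

## Validation machinery

* `monte_carlo_cv()`: simple-random (not stratified) 2/3 train splits,
  re-drawn (and counted) when a class drops below 2 training samples;
  mean test error over iterations plus a row-normalized confusion
  matrix. Matching the stated protocol, splits are *simple* random —
  stratification would understate the variance a small cohort really
  has.
* `mcnemar_test()`: discordant counts $b, c$; exact two-sided binomial
  $p = \min(1,\, 2 P(\mathrm{Bin}(b{+}c, 1/2) \le \min(b,c)))$ below
  $b + c = 25$, else the continuity-corrected $\chi^2$
  $(|b-c|-1)^2/(b+c)$. The switch point is conventional; the reference
  analysis names only the test.
* `enrichment_test()`: two-sided Fisher by the probability-mass
  criterion (the most common convention; the doubling alternative
  differs and is deliberately not offered) or Pearson $\chi^2$ without
  continuity correction.
* `coefficient_of_variance()`, `pearson_correlation()`,
  `subtype_proportion()` (with round-half-away-from-zero printed
  rounding, so 61.9 prints as the quoted 62), and `cluster_order()` —
  UPGMA under $1 - $ centered Pearson correlation, the heatmap ordering
  convention.

Every one of these is certified in the test suite against an
independent brute-force oracle: a loop-level re-derivation of the NSC
formulas, binomial/hypergeometric enumeration for McNemar and Fisher,
and an $O(n^3)$ naive UPGMA.

## What the simulator states, and what a green test means

`simulation_config()` fixes the stated world: 60 samples, balanced
subtypes, 20 basal-high / 20 luminal-high / 7 neutral genes, 4
housekeeping and 8 negative probes, per-gene baselines drawn once from
$\mathrm{Uniform}(6, 10)$ log2 counts (64–1024 raw counts, the working
range of the platform), housekeeping at $2^9$, subtype shift
$\delta = 2$ log2 units against biological noise $\sigma_b = 1$, lane
factors log-uniform in $[0.8, 1.25]$, Poisson(10) background, technical
wobble $\sigma_t = 0.1$ log2 units, and cross-platform correlation
$\rho = 0.9$. Counts are Poisson on a log-normal rate — barcode
counting is near-Poisson at probe level, and a hierarchical rate keeps
every knob interpretable — rather than negative binomial with a fitted
dispersion.

The paired layer mixes each gene's standardized true expression with
independent noise at weight $\rho$, standing in for RNA-seq. The
label-transfer fixture trains the platform-A model on an
*independently simulated* cohort before labelling the cohort under
study: like the real transcriptome classifier, the transfer labels
must predate the samples they label, and resubstitution labelling
would smuggle truth signal into the $\rho = 0$ null (nearest-centroid
resubstitution retains roughly 80% agreement with its training labels
even on pure noise).

A green suite therefore establishes: the normalization algebra and its
invariants; exact agreement of classifier and statistics with their
formulas; recovery of a planted two-block subtype structure at
realistic noise (Monte Carlo CV error ≤ 5% at $\delta = 2$, chance at
$\delta = 0$); and the qualitative two-platform story (perfect transfer
at $\rho = 1$, monotone degradation, chance at $\rho = 0$). It does
*not* establish performance on patient FFPE data: the simulator has no
FFPE degradation, no probe-specific efficiency, no correlated gene-gene
biology beyond the subtype blocks, and no cohort composition effects.
The published cohort percentages are reproduced only as worked
examples from their printed numerator/denominator pairs
(`scripts/acceptance.R`).

## Numerical choices and limitations

* Monte Carlo estimates in tests use 2,000 iterations (acceptance) and
  less (unit tests) in place of the reference 10,000; the standard
  error scales as $1/\sqrt{\text{iterations}}$ and is asserted, not
  assumed.
* Model JSON uses 17 significant digits so a serialize/load round trip
  reproduces predictions bit-exactly.
* Counts are integers; fractional input is refused, never rounded —
  a fractional "count" means the file is not raw instrument output.
* Panels ship as TSV and run configurations as JSON.
* The shipped default panel mirrors the published signature's geometry
  but uses synthetic endogenous gene names; it is a stand-in for
  pipeline testing, not the published gene list.
* Out of scope: positive-control linearity normalization and lane-image
  QC (passed through, not interpreted), batch correction, survival
  analysis, multi-class ($>2$) subtype schemes, and any attempt to
  match the empirical distribution of real cohorts.
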