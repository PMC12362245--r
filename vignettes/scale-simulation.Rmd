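---
title: "Scale-simulation differential abundance: model, defaults and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-simulation differential abundance: model, defaults and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssda)
```

## The problem and the model

Sequencing a sample is a chain of fixed-size subsampling steps, so a count
table `Y` (features × samples) carries information about each sample's
*composition* but essentially none about its *scale* — the total amount of
material in the system the sample came from. Decompose the true abundance
multiplicatively, `W = Wcomp * Wtot`, or additively in logs:

`log2 W_dn = log2 Wcomp_dn + log2 Wtot_n`

Any differential abundance analysis must supply `Wtot` from outside the
data. Normalizations do this with a point mass: the centred log-ratio (CLR)
assumes `log2 Wtot_n = -log2 G_n`, where `G_n` is the geometric mean of the
sample's composition. `ssda` replaces the point mass with a probability
model and propagates both sources of uncertainty by Monte-Carlo simulation:

1. **Composition draws.** For each sample `n` and instance `k = 1..K`,
   `Wcomp_n^(k) ~ Dirichlet(Y[, n] + prior)`. The Dirichlet posterior under
   a per-cell pseudo-count prior captures multinomial counting noise and
   handles zeros without a separate zero model.
2. **Scale draws.** The default model keeps the CLR location but adds
   log-normal noise: `log2 Wtot_n^(k) = -log2 G_n^(k) + eps_nk`,
   `eps_nk ~ N(0, gamma^2)` independently per sample and instance. At
   `gamma = 0` this *is* the CLR; the multiplier `2^eps` is log-normal,
   while `gamma` itself is a fixed scalar (the SD of log2 scale noise).
   The informed configuration adds per-group location offsets `log2 mu`;
   a user scale matrix replaces the CLR term entirely.
3. **Tests and effects.** Per instance, a Welch t and/or Wilcoxon rank-sum
   test per feature, Benjamini–Hochberg corrected *within* the instance;
   expected p and q are means over instances. Nonparametric summaries —
   between-group difference, within-group dispersion, standardized
   effect — are medians over random sample pairings across instances.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `gamma` | 0.5 | SD of scale noise on the log2 scale. 0 = plain CLR. 0.2–0.5 is realistic for most designs: 0.5 for strong FDR control, 0.2 when differences below ~1 log2 matter. Values above 1 trigger an advisory. |
| `mu` | 1 per group | dimensionless per-group scale multipliers; only the between-group ratio is identifiable, and draws are anchored to the reference group internally, so `c * mu` gives bit-identical output. |
| `n_instances` (K) | 128 | Monte-Carlo instances. Expected values stabilize quickly; the Monte-Carlo error of group scale means shrinks as `gamma / sqrt(K * n)`. |
| `prior` | 0.5 | per-cell Dirichlet pseudo-count (half-count uniform prior). Strictly positive so zero counts stay on the simplex. |
| `q_max` | 0.05 | significance threshold on the expected BH q-value; the Welch column `eq_t` is the primary call column (the Wilcoxon column tracks it closely). |

Both additive and replacing uses of `mu` are supported because they answer
different questions. `scale_model("informed", mu = ...)` *adds* offsets to
the CLR location: `mu` then means "how the group scales differ beyond what
the CLR already absorbs". A matrix from `make_scale_matrix()` *replaces*
the CLR term: `mu` then means the absolute group scale ratio, which is
what `estimate_mu_from_reference()` returns — its readout is minus the
mean log2 composition of the reference features (the reference set acting
as the CLR denominator), so an exactly-invariant reference set recovers
the true total ratio. The run's provenance records which form was used.

`estimate_mu_from_reference()` defaults to `gamma = 1e-3`: the estimate is
a location readout, and scale uncertainty belongs in the downstream model
built *from* the estimate, not in the estimate itself. The LVHA selector
takes features below the 25th percentile of CLR variance and above the
75th percentile of mean relative abundance (quartile reading of
"low variance, high abundance"), ties at either boundary included; both
quantiles are exposed.

## What the synthetic data emulate — and what they do not

`nb_backbone()` generates a null two-group table: per-feature abundances
log-uniform over `log2_abundance_range` (default 0–8, spanning the orders
of magnitude of a transcriptome), library sizes log-uniform over
`lib_size_range` (default 0.5–2 M reads), and negative-binomial counts
with `dispersion` (default 0.5, typical of biological replication;
variance = mu + dispersion * mu^2).

Two structured subsets make scale experiments possible:

* **Invariant (housekeeping-like) features** (default 50) are drawn from
  the upper half of the abundance range — constitutively expressed genes
  are solidly expressed — and never receive the group scale offset.
* **Scale carriers** (default 25 high-abundance features) absorb a
  requested `group_scale_log2_offset`: their multiplier is solved so the
  true total ratio is exactly `2^offset`. The offset must be concentrated
  in a minority of features to be recoverable at all — a proportional
  change to *every* feature alters no composition and is invisible to any
  composition-based estimate. Biologically this mirrors load differences
  driven by dominant transcripts or taxa.

`spike_thinning()` implants truth into any backbone (or real table):
`round(tp_fraction * D)` features get `b ~ N(0, effect_sd^2)` (defaults
0.05 and 2) and each cell keeps reads with probability
`2^(b * x_n - max(0, b))`, which is always in (0, 1] and leaves an
expected between-group log2 fold change of exactly `b`. Thinning
subsamples the original counts, so the semi-synthetic data keep the
backbone's noise structure; non-TP features are bit-identical.

`technical_replicate_data()` freezes the regime used for the
scale-sensitivity property: 20 samples per group, dispersion 0.001
(near-Poisson — repeated sequencing of near-identical material), 5–6 M
reads, and widespread small effects (`tp_fraction = 0.5`,
`effect_sd = 0.1`). Here the per-sample technical SD is ~0.05 log2, so at
`gamma = 0` many features with negligible differences are significant,
and `gamma = 0.1` — noise twice the technical floor — removes well over
half of them. The regime's point is the *ordering*, not the absolute
counts.

What passing tests on these generators do **not** show: real data have
correlated features (co-regulation, taxonomic blocks), batch structure,
library-preparation biases that are not multinomial, and zero patterns
beyond sampling zeros. The generators also make the scale offset exactly
recoverable by construction; in real data the carrier structure is unknown
and reference-based estimates inherit whatever invariance assumption the
analyst makes. Benchmarks here measure calibration of the machinery, not
performance on any particular tissue or ecosystem.

## Numerical choices

* All logarithms are base 2; differences, dispersions and `gamma` are on
  the log2 scale.
* Every stage draws from its own sub-stream keyed on
  `(seed, stage, index)` — Dirichlet draws per sample, scale noise per
  sample, effect-size pairings per instance, benchmark replicates per
  replicate — so composition draws are reusable across a gamma grid
  (`sen_analysis()` isolates the scale model this way) and results are
  independent of chunking.
* Expected q is the mean over instances of per-instance BH q, not BH
  applied to expected p: the expected value of the corrected quantity is
  what the Monte-Carlo framework reports. Per feature, `eq >= ep` always.
* Welch t is vectorized in closed form (Satterthwaite df); degenerate
  zero-variance cases use p = 1 for equal means, p = 0 otherwise.
  Wilcoxon uses the exact distribution when the smaller group has at most
  10 samples and there are no ties, otherwise the Normal approximation
  with continuity and tie corrections; all-tied rows give p = 1.
* The effect denominator (dispersion) is floored at 1e-8 to keep the
  standardized effect finite on degenerate draws.
* Group labels: the reference level is the lexicographically first
  condition unless overridden; `diff_btw` is non-reference minus
  reference. Scale noise is symmetric across groups by default; the
  one-group (indicator-coupled) form of the model is available via
  `asymmetric = TRUE`.
* `gamma_threshold` in the sensitivity analysis is the first grid value at
  which significance is lost (`Inf` if never lost); re-gains at larger
  gamma are flagged rather than smoothed into a monotone summary, and
  never-significant features are flagged separately.
* Stratified benchmark scoring at threshold tau counts called TP features
  with `|b| < tau` as false positives (they are positives the analyst did
  not ask for); FDR of an empty call set is 0, reported next to
  `n_calls`. Both `|b|`- and signed-b stratifications are emitted.

## Problem sizes

The bundled tests and the acceptance script run entirely on generated
data: oracle comparisons on 500 × 20 tables at K = 8, calibration and
benchmark properties on 2000-feature backbones with 10 + 10 samples at
K = 128 (20 null permutations; 3 thinning replicates), and the
technical-replicate regime at 1000 features. These sizes put the
Monte-Carlo error of each reported quantity well inside the margins being
checked while keeping a full run in the minutes range on a single core.

## Known limitations

Two-group designs only: no covariates, batch terms, paired samples, or
more than two conditions. No moderated variance estimators — uncertainty
enters through the Dirichlet and scale draws instead. No automatic choice
of `gamma`: it is an analyst-set assumption, and the sensitivity analysis
is the tool for examining its consequences. The benchmark harness scores
call sets; it does not embed other callers.
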