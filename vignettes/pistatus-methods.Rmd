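---
title: "Diagnosing plant phosphate status from leaf transcriptomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing plant phosphate status from leaf transcriptomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pistatus` turns a two-colour time-course microarray experiment — inorganic
phosphate (Pi) withdrawn from hydroponically grown plants and re-supplied
four weeks later — into a set of diagnostic expression markers and a
margin-emitting support-vector-machine (SVM) classifier of crop Pi status.
This vignette explains the statistical models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the method left genuine
freedom.

```{r setup}
library(pistatus)
```

## The experimental design being emulated

The design has seven sampling days (0, 1, 3, 7, 17, 29, 31 relative to Pi
withdrawal; Pi is re-supplied after 28 d), two treatments (`minus_P`
starved, `plus_P` control), and three biological replicates per cell — 42
biological samples. Each array co-hybridises the starved and control sample
of the same (day, replicate); a full dye swap repeats every pairing with
the Cy3/Cy5 labels reversed. Each biological sample is therefore measured
twice, once per dye, giving 84 labelled sample-channels on 42 arrays. The
pairing of samples on arrays is not dictated by the design description;
co-hybridising treated against control of the same replicate is the
simplest scheme that yields the 84 labelled one-colour samples the class
predictor needs, and is the one the generator uses.

```{r design}
design <- sim_design(n_genes = 1000, seed = 1)
design
```

## The synthetic-data generator

Signals are log-normal: each gene draws a baseline log2 intensity from
N(10, 1.5²); measurements add Gaussian noise of `noise_sd` (default 0.25,
a typical per-spot residual for two-colour arrays) on the log2 scale, so
signals stay positive. A fraction `frac_responsive` (default 0.1) of genes
is planted with a response pattern: a 7-symbol string over `↑ ↓ -`, one
symbol per day, where `↑` multiplies the treated-channel mean by
`effect_fold` (default 2) on that day only, `↓` divides by it, and `-`
leaves it unchanged.

Two families of patterns matter:

* **Sustained markers** (the default): up- or down-regulated on every day
  the starved plants are actually deficient — days 1 through 29 — and at
  baseline on day 0 (two hours after withdrawal, before the leaf responds)
  and day 31 (after re-supply). These are the shapes a *diagnostic* marker
  must have: they track physiological status, not the calendar.
* **Transient cluster signatures** (`pi_group_patterns`): the eight
  canonical response-group shapes (late induction, early repression, a
  single-day pulse, ...). They are available through the `patterns`
  argument for testing the clustering and symbolization stages. Note that
  shapes with a single arrow can never satisfy the "1.5-fold at two or
  more time points" call rule, which is why they are not default planting
  material.

The generator also injects, at stated fractions, genes with raw signal
below the conventional low-signal floor (mean linear intensity 20 versus
the floor of 50) and absent flags per gene x array cell, so the pre-filter
has something to remove. `inject_dye_bias()` adds a smooth polynomial
function of centred mean log-intensity to each array's log-ratio by scaling
the experimental channel; the sign is kept consistent across dye
orientations so the trend remains visible when arrays are pooled — it
exercises the per-array Lowess removal, not the dye-swap cancellation path.

A companion generator produces the **field test set**: `n_per_class`
one-colour samples per class (default 15 + 15, the field-trial size), where
deficient samples shift every diagnostic gene by
`attenuation x log2(effect_fold)` in its planted direction. `attenuation`
(default 0.8 in the bundled pipeline configuration) models the field effect
being weaker than the hydroponic extreme.

What the generator does **not** emulate: probe-sequence effects, spatial
array artefacts, scanner saturation, correlated noise between genes,
replicate-level biological covariance, or compositional constraints.
Passing tests on synthetic data therefore demonstrate that the pipeline's
inference machinery is correct and calibrated under its own assumptions —
not that real arrays meet those assumptions.

## Normalization and pre-filtering

For each array the ratio is `experimental / max(control, control_floor)`
with `control_floor = 10`; a Lowess curve (35% span, local linear fits,
tricube weights, two robustness iterations — the classical definition; only
the span is prescribed) of log-ratio on mean log2 intensity is subtracted.
`normalized_channels()` re-expresses the correction at channel level
(control floored, experimental = floored control x corrected ratio) so the
dye-swap experiment can be treated as one-colour data downstream.

Lowess is exactly idempotent only on noise-free data; on noisy bias-free
fixtures a second application still moves log-ratios slightly (the fit of
detrended noise is small but not zero), which is why the idempotence
property is asserted at 1e-6 RMS on a noiseless fixture and at 1e-2 under
noise.

Median scaling divides each gene by the median of its measurements across
all samples of the experiment; genes with no positive finite value cannot
be scaled and are dropped with a warning.

The three pre-filter rules need aggregation choices the prose rules leave
open:

* **Rule 1** ("raw signal below 50 in five of seven time points") is
  evaluated on the mean raw signal across replicates, treatments and dyes
  within each time point.
* **Rule 2** (absent flags): a gene is removed when flagged absent in more
  than 50% of its measurements; no count threshold is prescribed, and a
  majority rule is the least aggressive choice that still removes
  systematically absent probes.
* **Rule 3** (normalized signal within [0.8, 1.2] at all time points) is
  evaluated on per-(day, treatment) means. Pooling the two treatments
  would dilute a treated-only response of 1.5-fold to roughly 1.2 and
  misclassify genuinely responsive genes as flat.

## Differential expression

Fold change at day *t* is the ratio of treated to control means over that
day's channels. Significance comes from a two-factor fixed-effects ANOVA
of log2 signal on day x treatment, testing the treatment main effect and
the treatment-by-day interaction *jointly* against the day-only model via
the extra-sum-of-squares F test. The joint test is deliberate: a gene
responding only late in starvation has a negligible main effect but a
strong interaction, and must still be detectable. Genes with no variance
anywhere are reported at p = 1 rather than propagating 0/0.

The Benjamini–Hochberg step-up adjustment (`q(i) = min over j >= i of
m p(j)/j`, capped at 1) is implemented directly — it is a core primitive
here, with an exact worked example in the tests — and is cross-checked
against `stats::p.adjust(method = "BH")` on random inputs. A gene is called
up- (down-) regulated when adjusted p < `alpha` (default 0.01) and its fold
passes `fc_threshold` (default 1.5) at `min_timepoints` (default 2) or
more days; a gene can legitimately carry both calls at different days and
is counted once in the DE set.

Response groups come from average-linkage agglomerative clustering under
centred-correlation (Pearson) distance — the classical expression-profile
metric — on log2 fold-change profiles, cut to exactly `n_groups` (default
8) groups, labelled by Roman numerals in order of decreasing size.
Constant profiles, whose correlation is undefined, are placed at distance 0
from each other and 1 from varying profiles. Group mean profiles are
symbolized per day at the 1.5-fold threshold.

Term overrepresentation is the one-sided upper-tail hypergeometric test
against the post-filter gene universe (the analysed set, not the full
array), BH-adjusted across terms. The field summary statistics (shoot P,
biomass, yield) are compared by Welch's two-sided t-test reconstructed from
group means, standard errors and sample sizes, with Welch–Satterthwaite
degrees of freedom.

## Class prediction

Training samples are the 84 labelled channels; the class rule is: all
channels from day 0 and day 31, and every `plus_P` channel, are Pi
**replete**; `minus_P` channels at days 1–29 are Pi **deficient** (54 / 30
split). Deficient is coded +1 throughout, so positive margins mean "this
leaf is Pi deficient".

Feature representation required two decisions the method description does
not settle:

* **Scale.** Kernels operate on the positive median-scaled signals
  (centred at 1), not their logarithm. A homogeneous even-order dot-product
  kernel satisfies K(u, v) = K(-u, v): on zero-centred log features it is
  blind to the sign of the class shift and the order-2/3 kernels cannot
  separate the classes at all. On positive features all four kernels are
  informative. The Golub score, in contrast, is computed on log2 features,
  where its mean/sd form is conventional.
* **Cross-dataset comparability.** Each dataset is median-scaled within
  itself (the experiment-wise normalization the method prescribes), and —
  for the prediction paths (`evaluate_grid()`, the pipeline, transfer) —
  each sample's restricted feature vector is scaled to unit Euclidean norm
  inside the SVM (`normalize = "l2"`). Within-dataset medians sit at
  different points of the class mixture when the class balance differs
  (30/84 deficient in training versus 15/30 in the field), a systematic
  scale offset that the unit-norm step absorbs; it also makes margins
  exactly invariant to any global rescaling of the features (a tested
  property). `svm_train()` defaults to `normalize = "none"` so the raw
  geometry of textbook problems is preserved.

The Golub score `s(g) = (mu_def - mu_rep) / (sd_def + sd_rep)` is floored
at 1e-9 times the mean class-sd sum to avoid zero denominators. Selection
is balanced — the `ceiling(k/2)` most positive and `floor(k/2)` most
negative scores, the original practice for this score — with pure |s|
ranking available; ties break on lexicographic gene id so selection is
deterministic.

The SVM dual is solved in-package by sequential minimal optimization with
maximal-violating-pair working-set selection, to a KKT violation tolerance
of 1e-6 (iteration cap raises a convergence error). Kernels are the
homogeneous polynomial dot products `(u . v)^d`, d = 1, 2, 3 — homogeneous
because the tool the study used labels them "Dot Product (Order d)" with no
offset; an offset variant is available via `kernel_spec(offset =)` — and
the radial basis kernel with `gamma` defaulting to
`1 / (n_features x mean feature variance)`. The soft-margin cost defaults
to C = 1. The solver is validated three ways: closed-form maximal-margin
toys, a brute-force primal grid-search QP on instances of up to eight
points, and an independent reference implementation (`e1071`/libsvm) — the
reference is only ever a cross-check, never the implementation.

`evaluate_grid()` re-selects genes on the training set for every size k,
fits every kernel, and tabulates the four confusion counts and the percent
correct (one decimal) per (kernel, k) cell, mirroring the published
evaluation grid's layout.

## Ortholog transfer

`map_features()` projects a diagnostic set through a source-to-target
mapping table: one-to-many records resolve best-first in map order,
many-to-one collapses average log2 signals (`project_expression()`), and
unmapped sources are reported, not imputed. `cross_platform_classify()`
requires an explicitly labelled reference experiment on the target platform
— the method description is silent on what labelled data trained the
transferred classifier, and guessing would hide an essential input. Test
genes are scaled by the *reference* gene medians by default: scaling a
test set within itself maps any one-class collection (say, plants under an
unrelated stress, all Pi replete) onto the class midpoint, where the margin
sign is a coin flip; anchoring to the reference keeps such sets
classifiable. Within-own-dataset scaling remains available
(`scale_by = "own"`).

## Pipeline, determinism and problem sizes

`run_pipeline()` wires the stages through a YAML configuration; every
output TSV carries a provenance header (package version, seed, parameter
hash) and all randomness derives from the single config seed, so identical
configuration gives byte-identical artifacts. The bundled default
configuration runs 2,000 genes with nine diagnostic-set sizes and all four
kernels — a complete 36-cell grid in seconds on a laptop.

The validation suite uses scales chosen to exercise each stage's claims
with comfortable statistical resolution: 5,000 genes with 500 planted
responders for DE recovery, 1,000 x 1,000-gene null repetitions for FDR
calibration, 10,000 genes for dye-bias removal, and 20,000 genes with 200
planted markers for Golub recovery and the field classification grid.

## Known limitations

* Cross-dataset comparability rests on within-dataset median scaling plus
  unit-norm sample vectors; no batch-effect model is fitted, and a test
  dataset whose class balance is extreme will still shift relative to the
  training scale.
* The ANOVA assumes homoscedastic log-normal noise; the generator meets
  this by construction, real arrays only approximately.
* Margins are not calibrated probabilities, and no cross-validation-based
  model selection beyond the published size x kernel sweep is provided.
* GO-style term ancestry is not propagated; enrichment treats terms as
  flat labels.
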