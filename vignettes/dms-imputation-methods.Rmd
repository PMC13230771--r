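---
title: "Imputing missing deep mutational scanning scores: model, evaluation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing missing deep mutational scanning scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsimpute)
```

## The problem

Deep mutational scanning (DMS) experiments score thousands of
single-amino-acid substitutions for their effect on a protein's function or
stability, but few published variant-effect maps are complete. `dmsimpute`
treats the missing entries as a supervised regression problem: learn the
map from biologically informed per-variant features to the measured scores,
then predict the unmeasured substitutions. This vignette explains the
model, its assumptions, the tunable parameters, the evaluation machinery,
and the design decisions taken where several defensible options existed.

## Score normalization

Raw assay scores are placed on a common scale anchored at the two
biologically interpretable extremes:

$$s_{norm} = \frac{s_{dms} - s_{wt}}{s_{wt} - s_{nons}} + 1,$$

so a wild-type-like measurement maps to 1 and the loss-of-function
(nonsense) baseline to 0. The transform is affine: values outside
$[0, 1]$ — hyperstable variants, scoring artifacts — are deliberately
preserved, and per-variant uncertainties are rescaled by the same factor
$1/|s_{wt} - s_{nons}|$ so they stay meaningful on the normalized scale.

Anchors may be supplied by the study, stored on the score set, or derived
from the data (wild type from synonymous records, nonsense from nonsense
records). Published descriptions of this scale are ambiguous about whether
the nonsense baseline is the *mean* or the *median* of nonsense scores; the
package defaults to the mean (matching the formula's symbol definition) and
exposes `nonsense_stat = "median"` as a switch. With anchors derived from
the data, the derived anchor reproduces 1/0 exactly, and the
normalize/denormalize round trip is exact to machine precision — both are
asserted in the test suite.

## Features

Six feature families, assembled in a fixed family-then-name order so that
tables built from the same inputs are bit-identical and trained models are
schema-portable:

| family | columns | missing-capable |
|---|---|---|
| positional mean prior | 1 | yes |
| substitution matrices | 1 per matrix (10 bundled) | no |
| physicochemical properties | wt/var/\|diff\| + one-hots (~40) | no |
| SNV indicator | 1 | no |
| conservation score | 1 | yes |
| embeddings | wt, var, diff rows (D each) | no |

The *positional mean prior* is the mean normalized score of the variants
observed at the same (protein, position) — a direct empirical estimate of
site-specific mutational tolerance. It is the single most informative
feature when the position has been observed, and it is also the most
dangerous one: it must be computed **from the training side of a split
only**. Every protocol in the package recomputes it per partition, and a
sentinel-injection test asserts that altering test-side scores changes no
map entry, no training row and no prediction under any of the eight split
strategies. A position absent from training yields `NA`, which the tree
learner routes natively; there is no fallback constant, because an explicit
"unknown" is more honest than an invented prior.

Embeddings come through a provider contract — `embed(sequence)` returning
an `L x D` matrix, deterministic per sequence — so any protein language
model can be plugged in. The test suite never requires a real language
model: the synthetic provider (below) stands in. The difference vector
`e_var − e_wt` captures the local contextual shift of the substitution;
presets control whether it is included (dropping it was the strongest
cross-protein configuration in the source experiments, hence the
`full_minus_diff` default).

The SNV indicator marks substitutions reachable by a single nucleotide
change. It is defined context-free over the standard genetic code (any
codon of the wild-type residue vs any codon of the variant), because the
actual codon context of a domain insert is generally unknown; the
implementation is verified against a brute-force enumeration over all 380
ordered residue pairs.

Conservation scores are an optional input joined on (protein, UniProt
position, variant residue) through each domain's coordinate offset; absent
values become `NA` with a warning rather than an error, since such scores
exist only for a minority of proteins.

## Model and tuning

The regressor is a gradient-boosted tree ensemble (squared-error
objective, histogram splits, leaf-wise growth) with up to 1000 boosting
rounds and early stopping after 50 consecutive non-improving rounds on an
internal validation split — group-aware (whole proteins) when the table
spans several proteins, random otherwise. Tree learners are a good match
for this problem: the features are tabular, heterogeneous in scale, partly
missing, and interact (tolerance x severity), and the data volume is
thousands to hundreds of thousands of rows.

Tunable parameters (defaults in parentheses): learning rate (0.05), max
depth (8), leaves per tree (31), row subsample (0.8), feature subsample
(0.8), L1/L2 penalties (1e-3). `tune_dms_hyperparams()` searches
learning rate log-uniformly on [1e-3, 0.3], depth on {3..12}, leaves on
{16..256}, subsampling on [0.5, 1] and penalties log-uniformly on
[1e-8, 10] — standard ranges for boosted trees on tabular data; the
search dimensions are fixed by the method, the ranges are package
defaults. The sampler is a tree-structured Parzen estimator: after a
random start-up phase the trials are split at the 25% RMSE quantile,
good and bad sets are modelled by per-dimension Gaussian kernel
densities, and the next candidate maximizes the good/bad density ratio.
The objective is mean RMSE over group-aware 5-fold cross-validation
(folds are whole proteins). The documented default configuration is always
evaluated as the first trial, so tuning can only improve on it; the trial
budget (default 50) is a package default, not a reproduction of the source
setup, which did not state one.

Determinism: every stochastic step (fold assignment, validation split, row
subsampling, the sampler) is seeded, single-threaded training is forced,
and the persistence round trip (`save_imputer()`/`load_imputer()`) is
asserted bit-identical.

## Evaluation protocols

`make_partition()` implements eight split strategies: random by ratio
(within protein), whole proteins by ratio, leave-one-protein-out,
positions by ratio, leave-one-position-out, leave-one-variant-out,
SNV-only training, and a representative-substitution whitelist (H, E, N,
I, G — one residue per physicochemical class). Position- and variant-level
hold-outs are scoped within each protein, matching the per-protein setting
they probe. `run_protocol()` drives any of them end to end, recomputing
positional means per partition, and summarizes per-partition metrics by
median and interquartile range. Metrics are the standard RMSE, MAE,
$R^2 = 1 - SS_{res}/SS_{tot}$ and Pearson correlation; a correlation over
zero-variance observations is reported as `NA` with a warning, never as 0,
so degenerate toys cannot silently corrupt summaries. `binned_rmse()`
reports error in quantile bins of observed or predicted scores (default 10
bins; tied edges are merged and reported as such).

Three reference imputers share the model's predictor contract: the
residue mean (mean of the position's other observed variants); a 5-nearest
-neighbour rule ranking the position's observed substitutions by BLOSUM100
similarity to the target and taking the **median** of the top five; and a
functional 5NN ranking them by closeness of per-substitution mean-score
profiles and taking the **mean**. Similarity/distance ties are broken
alphabetically by variant residue — the published description of these
rules does not specify a tie-break, and alphabetical is deterministic and
order-invariant. A baseline that cannot impute a variant returns `NA`; the
pipeline-level fallback is the protein-wide training mean, reported via a
message.

## Noise ceiling

Assay noise bounds any model's achievable correlation. The estimator
simulates $B = 300$ replicate experiments, adding
$\varepsilon_i \sim \mathcal{N}(0, \sigma_i^2)$ per variant, and averages
the Pearson correlations between the original and each replicate. For
homoscedastic noise this converges to the attenuation factor
$\sqrt{V/(V+\sigma^2)}$ with $V$ the score variance, which the tests use
as a closed-form oracle (±0.02 at n = 500). Variants without a reported
uncertainty are excluded and counted. Ceilings are computed on the
normalized scale, because model correlations are too.

## Benchmarking

Dataset completeness is the number of reported substitutions over
20 x (scanned residues): 19 missense plus the Ter substitution per
residue, wild type excluded; synonymous records never count. Assignment
uses eleven bins — ten half-open intervals $[0.0,0.1), \dots, [0.9,1.0)$
plus a closed bin for exactly complete maps. (The source material counts
eleven bins over increments of 0.1, which only defines ten intervals;
treating exact completeness as its own bin resolves the discrepancy and
matches how "fully complete" datasets are counted separately.) Values
above 1, possible with duplicate-heavy inputs, are reported raw and
clamped only for binning.

`subsampling_curve()` fixes a seeded 10% test set per dataset once —
identical across every fraction and every imputer — then trains each
imputer on increasing fractions of the remainder, recomputing positional
means from the subsample only. `position_budget_curve()` instead caps the
number of kept substitutions per position (N = 1–20). Both emit tidy
per-dataset tables and median summaries.

## The synthetic generator

Every stage of the package is testable without downloads because the
generator produces variant-effect maps with known ground truth:

$$y = 1 - t(pos)\cdot sev(wt, var),$$

where $t(pos) \in [0,1]$ is per-position mutational tolerance — a logistic
function (steepness 10) of a deterministic hash of the local 3-mer
sequence context, so tolerance is recoverable from sequence alone — and
$sev \in [0,1]$ is the normalized Euclidean distance between the two
residues in a (Kyte-Doolittle hydropathy, residue volume) plane, raised to
the 0.5 power. Observations add heteroscedastic Gaussian noise with
per-variant $\sigma \sim U(0.05, 0.15)$, recorded as the reported
uncertainty; one Ter record per position sits at truth 0; raw scores are
produced by inverting the normalization with anchors (0, −4), mimicking a
log-scale abundance assay. A seeded fraction of missense variants is
dropped to hit the target completeness.

The constants were fixed once, before any evaluation, so that generated
maps have the statistical signature of real stability-assay maps: scores
concentrated near neutral with a deleterious tail, standard deviation
about 0.30, noise ceilings about 0.94. The multiplicative
tolerance-x-severity structure is the simplest one that makes the
positional mean informative while leaving substitution-specific residual
signal for the matrix/embedding features — the two feature classes are
complementary by construction, as they are in real maps.

The synthetic embedding provider encodes, per position: the central
residue's two property coordinates, the 3-mer context hash that drives
$t$, and seeded pseudo-random per-residue basis vectors mixed over the
3-mer (weights 0.3/1/0.3). Consequently (e_wt, e_var) determine $y$ up to
noise, embeddings are local (a substitution changes rows only inside its
3-mer window), and identical sequences give identical matrices. What the
generator does **not** emulate: epistasis, assay-specific score
compression, activity-type phenotypes, position-position correlations
beyond 3-mers, and realistic language-model geometry. Passing tests
therefore demonstrate the machinery is correct and leakage-free — not that
any particular accuracy will transfer to a given real assay.

## Problem sizes used in the checks

The shipped verification runs use: a 20-domain x 60-position panel at 80%
completeness with embedding dimension 32 for parameter recovery
(per-protein 80/20 models, median held-out Pearson compared with the
median per-domain noise ceiling); four of those domains for the
subsampling-curve and feature-preset comparisons; and a dedicated
12-residue saturation domain for the position-versus-variant hold-out
comparison, where leave-one-variant-out costs one model fit per variant.
These sizes are the package's choices, balancing statistical stability of
the medians against the cost of several hundred model fits.

## Known limitations

- Predictions are point estimates; no uncertainty head is provided.
- The imputer inherits the assay type of its training data; a model
  trained on stability-like maps will not transfer to activity-based
  phenotypes.
- True zero-shot prediction (unseen protein, `zero_shot_no_mean` preset)
  relies entirely on sequence-derived features and is markedly harder than
  within-protein imputation; the package exposes it but makes no accuracy
  promises.
- The bundled substitution-matrix set (10 matrices) and property table are
  a practical default, not an exhaustive inventory; both are extensible
  through `read_substitution_matrix()` and the `property_table` argument.
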