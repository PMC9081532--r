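---
title: "Tracing tumor tissue of origin from mutational signatures"
author: "sigtrace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing tumor tissue of origin from mutational signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigtrace)
```

## The model

Somatic single-nucleotide variants are classified into 96 channels: six
pyrimidine-referenced substitution types (C>A, C>G, C>T, T>A, T>C, T>G)
crossed with the sixteen combinations of 5' and 3' flanking bases.
Purine-referenced calls are reverse-complemented first, so `G>T` in `TGT`
and `C>A` in `ACA` are the same event. A sample's spectrum is the count
vector over these channels, and the package models the normalized spectrum
as a non-negative linear combination of reference signatures:

$$p \approx \sum_s w_s \, \sigma_s, \qquad w_s \ge 0, \; \sum_s w_s \le 1,$$

where each $\sigma_s$ is a probability distribution over the 96 channels
(one row of the catalog) and $w_s$ is the sample's *exposure* (or
contribution) to signature $s$. Everything downstream — type-specific
pattern selection, per-type classifiers, origin tracing, cfDNA calls,
cohort similarity — operates on these exposures rather than on raw
mutations, because exposures are far more stable within a cancer type than
the identity of the mutated genes.

## Refitting

`refit_exposures()` estimates the weights by greedy forward selection.
Starting from the single best-fitting signature, each step adds the
candidate whose inclusion most reduces the residual sum of squares, with
the weights of the active set re-solved jointly by non-negative least
squares (Lawson–Hanson on the Gram system) and rescaled to sum to at most
one. Selection stops when the relative SSE improvement drops below `tol`
(default `1e-3`). Finally, contributions below `cutoff` (default 0.06, the
same threshold used to call a signature "observed" in a sample) are zeroed
and the survivors re-solved, iterating until every reported weight is
either 0 or at least the cutoff. Joint re-solving, rather than a
one-dimensional search per added signature, makes the procedure
deterministic and order-robust; exact ties are broken toward the lower
catalog index.

Two design points deserve emphasis. First, the weight total is constrained
to at most one and any shortfall shows up in `residual_error` rather than
as an artificial "unassigned" pseudo-signature — the same information with
a simpler contract. Second, the package carries an independent
brute-force reference, `nnls_subset_oracle()`, which enumerates every
signature subset of a small catalog and returns the global constrained
least-squares minimizer. The test suite requires the greedy fit to match
the oracle's reconstruction at cosine $\ge 0.999$ on at least 95 of 100
simulated spectra; the oracle deliberately uses a different NNLS
implementation (`pracma::lsqnonneg`) than the refit path.

## De novo extraction

`extract_denovo()` factorizes the row-normalized cohort matrix by
multiplicative-update NMF under Frobenius loss (iteration cap 2,000,
convergence when the relative error change falls below `1e-6`, best of 10
seeded restarts by default). Extracted rows are renormalized to sum to one
with compensatory rescaling of the loadings, then `map_to_catalog()`
assigns each to the reference signature of maximal cosine similarity when
that similarity strictly exceeds 0.75, and marks it unmapped otherwise.
The rank `k` is a user parameter — reconstruction error is reported per
fit, but no automatic rank selection is attempted.

## Type-specific patterns and classifiers

`select_cts_ms()` implements the three-filter rule for calling a
signature specific to one cancer type against all others pooled:
prevalence (observed, i.e. exposure > 0.06, in at least 20% of the type's
samples), fold change of mean exposures strictly above 1.5, and absolute
difference of means strictly above 0.1. The fold change uses a symmetric
pseudo-count (`1e-3`) so a zero rest-mean cannot blow up the ratio; means
are the default location (a median switch is provided). The one-vs-rest
pooling matches the downstream classifier design; a pairwise variant would
change only the contrast, not the machinery.

Per-type classifiers (`fit_one_vs_rest()`) are logistic regressions with
bidirectional stepwise selection by AIC from the intercept-only model,
restricted to the type's specific signatures. On synthetic cohorts these
features often separate the classes perfectly, where maximum likelihood
diverges; the fit then falls back to a small L2 ridge (`1e-4`) on the
selected set and flags the model. Separation is detected both from
`glm.fit` warnings and from fitted probabilities within `1e-10` of 0 or 1,
because `step()` can swallow the warning.

The metastasis cascade mirrors the clinical question for liver lesions:
stage 1 calls a lesion primary-liver when the liver model's score reaches
0.5 (configurable); stage 2 predicts the origin of the remaining lesions
with a single-hidden-layer neural network (8 logistic hidden units,
softmax output, weight decay `1e-3`, seeded initialization) over the
type-specific exposures concatenated with the per-type model scores. The
network is fit with `nnet`, the standard R implementation of exactly this
architecture; seeding makes it bit-reproducible. For cfDNA, two one-vs-rest
models are compared per sample and the higher score wins; the combined
variant adds tumor-specific mutation-marker indicator columns (genes
mutated in more than 5% of a type with a frequency difference above 0.1
against the rest).

## Similarity and connectivity

`pairwise_rho()` gives the cosine matrix between two exposure cohorts and
`aggregate_similarity()` reduces it to a scalar. Two normalizations of the
aggregate are defensible — the plain mean $\sum_{ij}\rho_{ij}/(mn)$ and the
mean square $\sum_{ij}\rho_{ij}^2/(mn)$ — and both are implemented; the
plain mean is the default because it keeps same-type cohort similarities
on the familiar near-1 scale. `normalize_similarity()` applies, strictly
in sequence: row-mean centering, column-mean centering, average ranks
within rows divided by the column count, then average ranks within columns
divided by the row count. The strict-sequence reading (each step operating
on the previous step's output) is the implemented one.

The mutation connection score of a sample is the fraction of its mutated
genes with at least one interaction *among the mutated set* — the induced
subgraph reading. The alternative (any interaction anywhere in the
network) reduces the score to a coverage statistic of the interaction
database and is available as `mode = "full"` for comparison. Group
comparisons use a two-sided rank-sum test; with small groups the p-value
comes from full enumeration of rank assignments, which remains exact under
ties, and otherwise from the tie-corrected normal approximation.

## What the generator emulates — and what it does not

`simulate_cohort()` draws, per sample: exposures from a Dirichlet centered
on the type's mean profile (concentration 50 by default; `Inf` degenerates
to the mean), a mutation burden from a log-normal with median 200 and
log-sd 0.8, floored at 10 (exome-scale), channel counts from a multinomial
over the implied mixture, and gene mutations as Bernoulli indicators with
planted driver frequencies (0.4) over a 500-gene background at rate 0.01.
The default study profiles plant one specific signature per type at mean
exposure 0.35 over two shared background signatures (0.45 and 0.20) — a
planted difference comfortably above the 0.1 selection threshold, which is
what makes exact recovery the correct expectation rather than an
optimistic one. Metastases re-draw exposures from a Dirichlet centered on
the primary with concentration `1/drift`; cfDNA samples are binomial
thinnings of tissue spectra with independent driver dropout; the PPI
generator plants a dense module (edge rate 0.3) in a sparse background
(0.01).

This emulates the statistical structure the analysis assumes — linear
signature mixing, type-specific enrichment, paired-lesion concordance,
dilution — and nothing else. Real cohorts add contamination, subclonal
structure, copy-number and indel events, flat and correlated signatures,
and between-signature collinearity far worse than the sparse synthetic
catalog's. Passing the synthetic suite therefore demonstrates correctness
of the machinery and recoverability under the stated model, not clinical
performance; the published headline numbers on patient cohorts are not
desk-reproducible and are not claimed by these tests.

## Numerical choices and degenerate inputs

* Empty spectra, empty catalogs, zero exposure rows, one-class labels and
  single-type cohorts raise errors naming the problem; ambiguous (N)
  contexts are skipped with counts rather than failing a whole cohort.
* All threshold comparisons follow the stated strictness: presence and
  marker candidacy are strict (`> 0.06`, `> 0.05`), prevalence is
  inclusive (`>= 0.20`), fold change and difference are strict, and the
  de novo mapping threshold is strict at 0.75.
* Ties: forward selection prefers the lower catalog index; rank steps use
  average ranks; cfDNA score ties go to the first model with a flag.
* The study orchestrator fans a single seed out to fixed per-stage
  offsets, so stages are individually reproducible and two runs of
  `run_full_synthetic_study()` with one configuration are byte-identical.

## Problem sizes

The default `run_config()` study uses 10 types with 100 training and 100
test samples each (12-signature catalog), 50 metastases per origin for the
three-origin cascade, and cfDNA copies of two types' test samples at
dilution 0.3 — about 2,500 refits in total, a scale chosen so the complete
study runs in well under a minute on a laptop while keeping every
statistical check comfortably powered. The test suite runs reduced
variants of the same pipeline where full scale adds nothing.

## Worked example

```{r example, eval = FALSE}
library(sigtrace)
report <- run_full_synthetic_study(run_config(seed = 1))
report
#> Synthetic study report (seed 1)
#>   per-type test AUC: min 1, mean 1
#>   exposure recovery MAE: 0.00892
#>   cascade: stage-1 accuracy 0.997, stage-2 accuracy 0.967
#>   primary-met concordance: within median 0.962, p = 9.16e-95
#>   connection score: clustered 0.678 vs random 0.117, p = 1.27e-18
#>   cfDNA (TYPE09 vs TYPE10): MS-only 1, combined 1
```

## Known limitations

Only single-base substitutions enter spectra (no doublet or indel
classes, no strand-split 192-channel variant). The refit is greedy and can
in principle lodge in a local optimum that the exhaustive oracle would
avoid — the oracle-equivalence test bounds how often this matters at the
catalog sizes used. NMF rank selection is manual. The generator plants
clean, near-orthogonal signatures; heavily collinear catalogs (e.g. the
flat clock-like signatures of real references) will degrade exposure
recovery below what the synthetic figures suggest.
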