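---
title: "Mondrian conformal prediction for imbalanced bioactivity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mondrian conformal prediction for imbalanced bioactivity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformalscreen)
```

## The problem

High-throughput bioassay datasets for endocrine-disruption-relevant
molecular initiating events (nuclear-receptor agonism and antagonism) are
severely imbalanced: active fractions of the endpoints in the reference
battery range from 0.77% to 24.25%. A plain classifier trained on such
data drifts toward the majority class — high specificity, very low
sensitivity — and, worse, gives no per-prediction statement of confidence.
`conformalscreen` addresses both problems with Mondrian
(class-conditional) inductive conformal prediction wrapped around a
random-forest classifier, and provides the surrounding workflow: data
curation, imbalance-protocol comparison, multi-endpoint screening, and
similarity-based prioritization.

## The model

### Mondrian inductive conformal prediction

For a binary endpoint, a random forest (200 trees, Gini impurity) is
trained on 60% of the data; 20% forms a calibration set and 20% is held
out for testing. The conformity score of a compound for a class is the
forest's predicted probability for that class. Calibration is *Mondrian*:
the active calibration table collects scores of the true actives only,
the inactive table of the true inactives only, so each class is
calibrated against its own distribution — this is what neutralizes class
imbalance, since a minority class is never swamped by majority scores.

For a new compound with conformity score $c$ against a class table of $n$
sorted scores, the conformal p-value is the rank statistic

$$p = \frac{\#\{s_i \le c\} + 1}{n + 1},$$

unsmoothed, with ties counted in the numerator, so p-values are
deterministic and lie in $(0, 1]$. A smoothed variant (seeded uniform
tie-break) is available behind a flag but is not the default, because
deterministic screening artifacts are easier to audit.

At a user-chosen significance level $\varepsilon$ (the acceptable error
rate), a class enters the prediction set when its p-value is at least
$\varepsilon$. The four outcomes are `active`, `inactive`, `both` (the
model cannot distinguish the classes at that error rate) and `empty` (the
compound conforms to neither class). Under exchangeability, per-class
coverage is guaranteed: the fraction of true-$c$ compounds whose set
excludes $c$ is at most $\varepsilon$ in expectation — the property the
acceptance simulation measures.

Two conformal quality measures guide the choice of $\varepsilon$:
**validity** (fraction of compounds of a class whose prediction set
contains the class; `both` counts as correct, `empty` as wrong) and
**efficiency** (fraction of single-label predictions). For screening use
both should exceed 0.8, which on reasonably separable data happens around
$\varepsilon = 0.2$.

### Calibration resampling and aggregation

Within each cross-validation fold the 80% non-test pool is re-partitioned
into train/calibration ten times with fresh seeds. Each iteration yields
a p-value pair for every test compound; pairs are combined by the
componentwise **median**. The median was chosen over the mean because it
is permutation-invariant, robust to a single badly calibrated iteration,
and maps $(0,1]$ values into $(0,1]$; the aggregation level (per fold,
across folds, or both) is exposed through the model object, whose
prediction method simply takes the median over *all* stored sub-models
(fold × iteration) — the interpretation used for screening.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `folds` | 5 | stratified cross-validation folds (test 20% each) |
| `iterations` | 10 | calibration resamplings per fold |
| `ntree` | 200 | trees per random forest |
| `epsilons` | 0.1–0.3 | significance grid for validity/efficiency reports |
| `epsilon` (screening) | 0.2 | class-assignment error level |
| `epsStrict` | 0.8 | strict threshold for high-confidence selection (`p1 > 0.8`, strict inequality) |
| `oodThreshold` | 0.2 | both p-values strictly below this flags out-of-domain |
| `minActiveRatio` | 0.003 | curation cutoff on the active fraction, boundary inclusive |

The curation boundary is read as keep-if $\ge$ 0.003 because the
reference battery retains endpoints at 0.77–0.78% while the cutoff is
stated as 0.3%. Replicate aggregation resolves a compound by a
two-thirds majority; `Inconclusive` replicates remain in the denominator
by default (the conservative reading — they make the majority harder to
reach), with `dropInconclusive = TRUE` to vote on the conclusive
replicates only, since either order of operations is defensible.

## Chemistry input

Structures are standardized with a deliberately minimal pipeline: largest
organic fragment (salt stripping), proton-level charge neutralization,
canonical SMILES — all through Open Babel. This is a small stand-in
pipeline; it does not attempt tautomer canonicalization or stereo repair.
Descriptors are Open Babel's 2-D physicochemical set (hydrogen-bond
acceptors and donors, logP, molar refractivity, molecular weight,
fluorine count, topological polar surface area); the descriptor list and
order are stored in every model artifact, and screening featurization
must match it exactly — a mismatch is a hard error, never a silent
reorder. Non-finite descriptor values are replaced by a sentinel `0` and
the affected compounds flagged for exclusion.

## Imbalance protocols

Six training protocols are compared on the same splits: `naive` (control),
equal-size under-sampling (majority reduced to the exact minority size),
duplication over-sampling, SMOTE (interpolation toward one of 5 nearest
same-class neighbors; neighbor search on standardized descriptors,
interpolation in raw space), ROSE-style smoothed bootstrap
(per-class Gaussian jitter at the Silverman bandwidth, output twice the
original size with balanced classes — a from-description implementation,
not a port of any existing ROSE code), and conformal prediction. Because
conformal assignment can return `both`/`empty`, its metrics are reported
twice: over single-label predictions only (coverage < 1) and with
unclassified compounds counted as errors (coverage 1).

Balanced PPV/NPV are not standard confusion-matrix entries; here they are
the predictive values after rescaling each true-class row to equal mass,
i.e. $\mathrm{bPPV} = \mathrm{sens} / (\mathrm{sens} + 1 - \mathrm{spec})$,
describing a hypothetical 50/50 prevalence.

## Screening, fingerprints and prioritization

`screenLibrary()` applies a battery of trained models to a library and
returns the compounds × endpoints grid of $(p_1, p_0)$ pairs. From the
grid the package derives: class assignment at any $\varepsilon$;
high-confidence selections (strict $p_1 > 0.8$ — the strict inequality is
a deliberate reading, since thresholded p-values, not class assignments,
drive this strategy); out-of-domain flags ($p_1, p_0 < 0.2$, strict); and
fold-differences of predicted versus expected actives. The
expected-actives anchor is the training prevalence, and a balanced-PPV
adjusted variant is emitted alongside because the correction can be read
either way.

The **bioactivity fingerprint** sets bit $j$ to 1 when $p_{1j} > p_{0j}$
(ties to 0 — only strict comparisons are defined), giving a
battery-length binary profile that expresses which class carries the
larger p-value, not the class assignment. Profiles are compared with the
Tanimoto coefficient (hit cutoff 0.8; both-zero pairs return 0 with a
warning, the usual cheminformatics convention even though two all-zero
profiles are arguably alike). For the embedding view, the p-value
profiles (default: $p_1 \oplus p_0$ concatenation; $p_1$-only behind a
flag) are mapped to two dimensions with exact t-SNE — per-point
bandwidths calibrated to the target perplexity by binary search, early
exaggeration, momentum gradient descent — implemented inside the package
and deterministic given the seed. Clusters around a reference compound
are delimited by DBSCAN on the map (`minPts = 4`, `eps` from the 0.9
quantile of 4-NN distances), because a reference-centred neighborhood
needs *some* documented delimitation rule and density connectivity is the
least parametric choice; the consensus of the t-SNE cluster and the
Tanimoto hit list is their intersection, reference excluded.

## The synthetic-data generator

`makeEndpointDataset()` draws two multivariate Gaussian classes in
descriptor space; the class-mean distance in pooled-sigma units
(`separation`) controls problem difficulty. The defaults — 20 features,
separation 2.5 — give a 200-tree forest a test AUC near 0.9 on 4%-active
data, the regime of a good but imperfect QSAR model. Prevalences for the
battery fixture default to the 23 reference-battery values (0.77–24.25%).
`makeBatteryFixture()` plants a screening library with known per-endpoint
truth, two dense-profile reference compounds and near-duplicates within
Hamming distance 2, so fingerprint ranking and cluster recovery are
testable against ground truth. `makeReplicateTable()` corrupts known
labels at set flip/inconclusive rates to exercise the curation rules.

What the generator emulates is the *statistical* shape of descriptor data
(imbalance, class overlap, exchangeability); what it does not emulate is
real chemistry — discrete and heavy-tailed descriptor distributions,
activity cliffs, assay noise correlated with cytotoxicity, or covariate
shift between training data and a screening inventory. Passing tests
therefore demonstrate that the machinery delivers its distribution-free
guarantees under exchangeability, not that any particular real endpoint
will reach a given validity.

## Numerical choices and degenerate inputs

* p-values use the +1 correction, so they are never 0 and every
  calibration table yields a floor of $1/(n+1)$.
* The boundary convention is inclusion at $p \ge \varepsilon$; the strict
  selection and out-of-domain rules use strict inequalities.
* A calibration split with zero members of either class is an error (the
  sub-model is unusable), as is a single-class training set, a
  stratification request a class cannot support, and a SMOTE minority
  below 6 compounds.
* Degenerate confusion-matrix denominators report `NA`, never NaN.
* All randomness (splits, forests, resampling, t-SNE initialization)
  is derived from explicit integer seeds; full runs are bit-reproducible.

## Problem sizes

The test suite and the acceptance script run entirely on generated data.
The coverage simulation uses one endpoint of n = 2000 at 4% active with
the full 5-fold × 10-iteration protocol; property suites use 500–2500
compounds; the battery fixture uses 23 endpoints × 400 training compounds
with a 212-compound library. These sizes were chosen as the smallest at
which the binomial error bands around the conformal guarantees are tight
enough to be informative (3 standard errors on 80 active test compounds
is ~13 percentage points).

## Known limitations

* Descriptor coverage is the 8-descriptor Open Babel physicochemical set;
  richer descriptor engines would sharpen real-data models but change
  nothing structural.
* The standardizer is not a full QSAR-ready curation workflow.
* Exact t-SNE is $O(n^2)$ per iteration; fine up to a few thousand
  compounds, not for hundred-thousand-compound inventories.
* Conformal guarantees are marginal per class and assume exchangeability;
  covariate shift between training data and screening library degrades
  them — which is exactly what the out-of-domain flag is for.
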