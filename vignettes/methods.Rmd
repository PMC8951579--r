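---
title: "lungReporter: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lungReporter: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind lungReporter, the
design decisions that were genuinely open, the synthetic data the tests
rely on, and the numerical conventions — the material a maintainer or
reviewer needs beyond the function reference.

## 1. The problem and the pipeline

Screening-detected lung nodules are described in radiology reports by a
small set of semantic labels — the lobe the nodule sits in, its
attenuation (solid, part-solid, pure ground-glass), its margin appearance
— together with its size and a Lung-RADS management category. lungReporter
automates that chain from a quantitative nodule description: a
113-dimensional feature vector per nodule (107 radiomics features in the
conventional seven groups, plus 6 SISN slice-information features computed
from the segmentation stack), flowing through semantic classification,
rule-based Lung-RADS assignment, and template-based report rendering.

The stages are deliberately decoupled: the classifier never decides the
Lung-RADS category (that is a transparent, replaceable rule table), and
the report text is never free-form generation (clinical text must be
controllable, so it is slot filling into vetted templates).

## 2. The multi-objective classifier

Three per-task towers share one standardized input. Each tower is

    dense(64) -> activation -> dropout -> dense(32) -> activation
      -> dropout -> dense(K) -> softmax

with K = 6 (Location), 3 (Texture), 4 (Margin). Location and Texture use
tanh activations, Margin uses ReLU. The Location tower consumes all 113
dimensions; Texture and Margin consume only the 107 radiomics dimensions
— the SISN features describe where the nodule sits along the axial stack,
which informs lobe location but not attenuation or margin.

Joint training minimises the sum over tasks of the categorical
cross-entropy, with predicted probabilities clipped to
`[1e-7, 1 - 1e-7]` so a confident wrong prediction cannot produce an
infinite loss. Because the towers share no parameters, one optimisation
loop over the summed loss updates each tower with exactly its own task
gradient; "joint" here means one loop, one shuffling, one loss accounting
— the reading that is simultaneously compatible with per-task dense
stacks and a joint learning scheme.

Open choices and how they were resolved:

- **Hidden widths (64, 32).** Not prescribed anywhere; chosen small so a
  full leave-one-out experiment over a ~458-record cohort runs on a desk
  machine in minutes. Configurable via `modelConfig(hidden = ...)`.
- **Margin-tower dropout.** Only the Location (0.35/0.25) and Texture
  (0.25/0.15) rates are prescribed; the Margin tower defaults to the
  Texture rates. Flagged here because it is a convention, not a datum.
- **Shared layers.** The towers could in principle share an early trunk;
  the per-task-towers reading was kept because nothing in the
  architecture description requires shared weights, and disjoint towers
  make the "summed loss = per-task gradients" equivalence exact.
- **Standardization.** Z-scoring (fit on the training split only) was
  added: tanh saturates on raw radiomics magnitudes, which span orders of
  magnitude across features. Constant features get unit scale rather than
  a division by zero.
- **Optimizer.** RMSprop with learning rate 1e-3, decay 0.9, epsilon
  1e-8; batch 32, 50 epochs by default. The learning-rate and decay
  values are package defaults (none are prescribed), matching the common
  defaults for this optimizer.
- **Initialization.** Symmetric fan-based (Glorot-uniform) from the
  seeded generator; biases start at zero. Everything downstream —
  shuffling, dropout masks — draws from seeded streams, so training is
  bit-reproducible given the config seed.

Dropout is *inverted* (activations divided by the keep-probability at
training time), so inference applies no mask and no rescaling; the test
suite checks the unbiasedness contract by averaging many stochastic
training-mode passes against the deterministic inference pass.

## 3. SISN slice-information features

The six SISN values summarise which axial slices contain the segmented
nodule, all normalised by the total slice count so they live in [0, 1]:

| name | definition (0-based slice indices) |
|---|---|
| `SISN_ratio` | labeled slices / total slices |
| `SISN_first` | first labeled index / total |
| `SISN_last` | last labeled index / total |
| `SISN_centroid` | area-weighted mean labeled index / total |
| `SISN_span` | (last − first + 1) / total |
| `SISN_peak` | index of the largest-area slice / total (ties → lowest) |

Only the ratio has a canonical published definition; the other five are
this package's reconstruction — the minimal slice-position statistics
that indicate where along the craniocaudal axis the nodule lies. They are
documented prominently as a surrogate set: any user with the original
feature definitions can substitute their own values, since the schema
only fixes the six column names.

Conventions worth noting: indices are 0-based and the divisor is the
total slice count (not total − 1), which keeps all six values on the same
[0, 1] scale as the ratio; for non-contiguous masks the ratio counts
labeled slices while the span measures the envelope, so ratio ≤ span with
equality exactly when the run is contiguous.

## 4. The synthetic cohort generator

No screening cohort ships with the package, so the generator is the
substrate for every statistical test. Its defaults encode the study
conditions the pipeline targets: **458 nodules**, every diameter below
the **30 mm** inclusion bound, **5 mm** slice thickness, **0.618 mm**
pixel pitch, 60-slice stacks.

- **Labels.** Location and texture are drawn from uniform priors by
  default; margin is drawn conditionally on texture, tilted so that
  suspicious margins (spiculated, indistinct) are likelier for solid
  nodules and benign-leaning margins for pure ground-glass — mirroring
  the clinical association between margin and malignancy. Real cohorts
  are heavily imbalanced; that is reachable through the config, but the
  default stays uniform so per-class statistics are well powered.
- **Radiomics features.** `x = mu(labels) + noise`, noise i.i.d. Gaussian
  (SD 1). The prototype `mu` lives on disjoint feature blocks per task,
  fixed by registry order: texture owns the intensity + GLCM dimensions,
  margin owns shape + GLDM, location owns GLRLM + GLSZM + NGTDM. Within
  a task's block, the contiguous sub-block indexed by the class is
  shifted by the effect size delta (default 3). This block-prototype
  scheme was chosen over a full covariance model because it is auditable
  (block disjointness is testable), collapses cleanly at delta = 0, and
  makes parameter recovery a sharp test: at delta = 3 the Bayes-optimal
  error per task is far below 1% (the class prototypes sit
  `sqrt(2 * m) * delta` apart for sub-block size m ≥ 6), which the test
  suite verifies by Monte-Carlo against a nearest-prototype oracle.
- **Sizes.** Log-normal (log-mean log 8, log-SD 0.6, i.e. median 8 mm,
  right-skewed) truncated to (0, 30) mm by rejection — the shape a
  screening population's nodule diameters actually have under an
  inclusion cap.
- **SISN.** Each record gets a simulated axial extent:
  `ceiling(size / thickness)` contiguous slices placed inside a
  location-dependent band (upper lobes in the top third of the stack,
  middle/lingular in the middle, lower lobes in the bottom), with a
  unimodal elliptical area profile; the six SISN values are computed from
  that extent. `simulatePhantom()` materialises the same construction as
  an actual 3D binary mask for testing `computeSISN()` on arrays.

What the generator does **not** emulate: CT intensities and HU windowing,
realistic inter-feature covariance (real radiomics features are strongly
correlated within groups), label noise, class imbalance (by default), or
any association between size and the semantic labels. Passing tests
therefore demonstrate that the machinery — optimisation, evaluation,
plumbing — is correct and well calibrated, not that the classifier would
reach any particular accuracy on clinical data.

One consequence of the design is worth spelling out because the test
suite encodes it: at delta = 0 the radiomics dimensions are pure noise,
so Texture and Margin predictions must sit at chance — but Location
remains above chance, because the SISN features encode the lobe band *by
construction*. That is not leakage; it is precisely why the Location
tower is given the SISN channel. The chance level itself is estimated by
a permutation null (gold labels shuffled against the fixed predictions,
200 draws, 4-SD acceptance band) rather than a binomial band around 1/K,
because the sampling distribution of macro-F1 is not binomial.

## 5. Lung-RADS rule engine

The rule table is data, not code: an ordered list of
(texture set, margin set or wildcard, size interval, category) rules in
YAML. Load-time validation guarantees **totality** (every texture ×
margin × positive size combination is covered) and **determinism**
(overlapping rules must agree in category), so first-match lookup is
safe by construction and a malformed table fails at load, never at
assignment time.

The shipped default transcribes the ACR Lung-RADS v1.1 baseline size
cut-offs into the texture-first branch structure: solid nodules by size
alone (<6 → 2, [6,8) → 3, [8,15) → 4A, ≥15 → 4B); pure ground-glass by
size (<30 → 2, ≥30 → 3); part-solid nodules branch on margin, with
benign-leaning margins (sharp circumscribed, lobulated) mapping to 2/3 at
6 mm and suspicious margins (spiculated, indistinct) to 4A/4B at 8 mm.
The margin branch is an interpretation — the category per size bin at
that branch is not published — which is exactly why the table is
replaceable data with a version tag. Intervals are half-open `[lo, hi)`
in mm, so a size exactly at a cut-off belongs to the upper category,
matching the "≥" phrasing of the ACR thresholds. Categories 1, 0, 4X and
S are out of scope: they require prior exams or solid-component
measurements this pipeline does not produce.

## 6. Evaluation conventions

- Precision, recall and F1 are computed one-vs-rest per class with the
  conventions P = 0 when TP + FP = 0, R = 0 when TP + FN = 0, F1 = 0 when
  both are zero; macro averages are unweighted means over classes
  *present in the gold labels*, so a fold without some class does not
  contribute undefined rows.
- ROC curves sweep the distinct score values (ties grouped); AUC is the
  trapezoid-rule area, equal to the Mann-Whitney statistic with half
  credit for ties. Per-task macro AUC averages the one-vs-rest class
  AUCs of the softmax probabilities.
- LOOCV trains one model per held-out record, with a per-fold seed drawn
  deterministically from the config seed, so the n-fold experiment is
  reproducible and order-independent. Metrics are computed from the
  pooled held-out predictions (one confusion matrix across all folds):
  per-fold metrics on test sets of size 1 are degenerate.

Both metric routes are verified in the test suite against independent
brute-force oracles (direct pair enumeration for the confusion counts,
the Mann-Whitney pair count for AUC, and pROC as an external
cross-check).

## 7. Problem sizes and numerical notes

The test suite exercises LOOCV at full study scale (458 folds) with a
2-epoch training budget, and the statistical fixtures at n = 100–400
records with 10–50 epochs; the parameter-recovery check uses delta = 3,
n = 400, an 80/20 split and the default 50 epochs. These sizes are the
package's own choices for a desk-scale, minutes-not-hours default
experience; all of them scale up through the config objects. The
reduced-epoch budgets are per-implementation choices: the recovery
fixture at n = 100 uses 15 epochs, where all three tasks clear the 0.85
pooled macro-F1 mark with margin.

Degenerate inputs are handled explicitly: empty cohorts round-trip
through CSV as header-only files; an all-background mask is a value
error; constant features standardize to unit scale; argmax ties break
toward the first class in canonical vocabulary order; `which.max`'s
lowest-index convention breaks peak-area ties in SISN. Feature CSV
round-trips write `%.17g`, which is lossless for doubles.

## 8. Known limitations

- The network is a fixed two-hidden-layer architecture; no architecture
  search, GPU path, or early stopping.
- The synthetic generator's independence assumptions (see §4) make its
  accuracy figures optimistic relative to clinical data; it validates
  machinery, not clinical performance.
- One nodule per report: multi-nodule studies are upstream concatenations
  of single-nodule reports.
- The shipped templates and lexicon are English-only.
- The rule engine covers baseline categories 2–4B only.
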