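---
title: "Sequence-based prediction of protein folding kinetics and rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based prediction of protein folding kinetics and rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldrate)
```

## The problem

The folding rate constant $k_f$ of a protein spans more than ten orders of
magnitude across proteins, and proteins fold by qualitatively different
kinetics: *two-state* folders reach the native state without detectable
intermediates, while *multi-state* folders populate one or more intermediates.
The two regimes have different rate determinants — multi-state rates are
dominated by chain length, two-state rates by native-state topology — so a
single regression over both classes is mis-specified.

`foldrate` implements a fully sequence-based, two-stage predictor:

1. **Kinetic-type classification.** An RBF-kernel support vector classifier
   assigns two-state vs multi-state from 25 sequence-derived features.
2. **Kinetic-type-specific rate regression.** Two $\varepsilon$-support-vector
   regressors, one per class, predict $\log_{10}(k_f/\mathrm{s}^{-1})$.

No experimental structure is needed: topology enters through a residue–residue
*contact probability map* predicted from sequence by any upstream contact
predictor (consumed as a CASP-RR-style text file), and secondary structure
through a predicted 3-state (H/E/C) string.

## Features

For a protein of length $L$ with contact probability map $P$ (symmetric,
$P_{ij} \in [0,1]$, zero diagonal):

* **Long-range contact number**, the expected number of long-range contacts,
  $$\mathrm{LRCN} = \frac{1}{L^{c}} \sum_{|i-j| \ge 12} P_{ij}, \qquad c = 1,$$
* **Long-range contact order**, its separation-weighted counterpart,
  $$\mathrm{LRCO} = \frac{1}{L^{c}} \sum_{|i-j| \ge 12} P_{ij}\,|i-j|, \qquad c = 2,$$

both summed over *unordered* pairs (each pair once) at sequence separation of
at least 12 residues. The probability weighting uses the predictor's full
confidence information instead of first thresholding the map to binary
contacts; on a binary map both definitions degenerate exactly to the classic
binary-contact forms (this is asserted by a test). A contact is defined at
C$\alpha$–C$\alpha$ distance $\le 8$ Å (closed comparison; the boundary case
is also pinned by a test). When a structure is available,
`real_contact_map()` rebuilds the binary map from coordinates, giving the
structure-derived descriptors rLRCN/rLRCO for comparison. The all-separation
relative contact order `contact_order()` is provided for feature screening.

* **Secondary-structure composition**: helix and sheet fractions of the H/E/C
  string. Coil content is excluded from every model — it carries almost no
  rate signal in either class.
* **Amino-acid composition**: the 20 residue frequencies, used by the
  *classifier only*; for the small per-class regression datasets 20 extra
  dimensions invite over-fitting.
* **Length** $L$: used by the classifier and the multi-state regressor.

Model-specific vectors (defaults):

| model | features | dim |
|---|---|---|
| classifier | $L$, LRCO, LRCN, helix, sheet, 20 AA frequencies | 25 |
| two-state regressor | LRCO, LRCN, helix, sheet | 4 |
| multi-state regressor | $L$, LRCO, LRCN, helix, sheet | 5 |

Whether the multi-state regressor should keep the helix/sheet contents is a
genuinely open design point (their rate correlation is weak in that class, but
keeping them measurably changes nothing); both readings are implemented
(`feature_config(multistate_features = "length_contacts_only")` gives the
3-feature alternative) and the 5-feature set — length added to the two-state
predictors — is the default. A precomputed structure-derived geometric-contact
scalar can be appended as an optional extra column
(`feature_config(use_gc = TRUE)`); computing geometric contacts is out of
scope.

## Normalization and pair-counting conventions

Whether the descriptor sums run over ordered or unordered pairs is a pure
factor of two; it is fixed here as *unordered* and documented so values are
reproducible. It is irrelevant to correlations and, after feature scaling, to
the SVMs. The exponents ($c=1$ for LRCN, $c=2$ for LRCO), the 12-residue
separation and the 8 Å threshold are all configurable through
`contact_params()` so alternates can be tested.

Features are min–max scaled to $[0,1]$ per column by default
(`fit_scaling()`); sensible for RBF kernels when raw features mix lengths
$\sim 10^2$ with compositions $\sim 10^{-1}$. Scaling parameters are learned
from training rows only and re-fitted inside every cross-validation fold; a
sentinel test corrupts held-out rows after the fold fit and asserts the model
is unchanged. Constant columns scale to 0 with a guarded denominator.

## The SVM layer

No SVM implementation is available among this package's allowed dependencies,
so the optimizer is built in: a sequential-minimal-optimization solver
(maximal-violating-pair working-set selection, C++ via Rcpp) for the generic
dual $\min_\alpha \tfrac12 \alpha^\top Q \alpha + p^\top \alpha$ subject to
$y^\top \alpha = 0$, $0 \le \alpha_i \le C$, to which both C-SVC and
$\varepsilon$-SVR reduce. Kernels: RBF $e^{-\gamma\|u-v\|^2}$ (default),
linear, polynomial, sigmoid. The solver is deterministic (no internal
randomness), stops at KKT violation $10^{-3}$, and its decision values agree
with an independent implementation (scikit-learn's libsvm wrapper) to within
the two solvers' tolerances on shared fixtures — that cross-check is a test,
not a dependency.

Class labels are encoded two-state $= +1$, multi-state $= -1$, fixed for
reproducibility of decision values. No class weighting is applied by default
(typical benchmark imbalance is mild, roughly 3:2).

## Hyperparameter selection

* **Classifier**: exhaustive grid over $(C, \gamma)$, each point scored by
  full leave-one-out cross-validated accuracy
  (`grid_search_classifier()`); the whole accuracy surface is retained and
  plotted by `plot()`.
* **Regressors**: grid search in three dimensions is expensive, so tuning is
  the two-phase heuristic (`tune_regressor()`): phase 1 grids $(C, \gamma)$
  with the tube width held at the common default $\varepsilon = 0.1$, scored
  by LOOCV Pearson correlation; phase 2 sweeps $\varepsilon$ at the phase-1
  optimum. Because the sweep includes the incumbent 0.1, the final score can
  never drop below phase 1 (asserted on seeded runs).

Ties on score break toward smaller $C$, then $\gamma$, then $\varepsilon$ —
prefer the simpler model, deterministically. Default grids are powers of two,
$C \in 2^{-5..5}$, $\gamma \in 2^{-7..3}$,
$\varepsilon \in \{0.01, 0.05, 0.1, 0.2, 0.5\}$. The packaged default
operating points (classifier $C=1, \gamma=0.25$; regressors
$C=8, \gamma=0.125, \varepsilon=0.1$) are reasonable starting values for
min–max-scaled features, but tuning is recommended for any new dataset — the
optimum depends on the scaling in use.

## Evaluation protocols

Everything is validated under **strict leave-one-out cross-validation**: for
each held-out protein, scaling and models are re-fitted on the remaining
$n-1$. `loocv_pipeline()` evaluates the full two-stage system (the held-out
protein is routed by its *predicted* class, so classification errors propagate
into the rate metrics, as they would in use). `repeated_split_eval()`
implements the complementary protocol of five random 90/10 splits; the test
fraction rounds as $\max(2, \lfloor 0.1 n \rfloor)$ (the size rule is a
package decision; the sources are silent) and splitting is unstratified by
default with a `stratify` switch. Metrics are the Pearson correlation and the
mean absolute difference (MAD) between predicted and experimental
$\log_{10} k_f$, plus classification accuracy.

`single_feature_screen()` evaluates each feature alone (one-feature SVR,
LOOCV, per class). It reports two numbers per feature–class pair:
`pearson_r`, the predicted-vs-true correlation (how much rate signal the
feature carries), and `direction_r`, the raw feature-vs-rate correlation
(the sign of the relationship — negative for length, since longer proteins
fold slower). These are separated deliberately: a one-feature model that
learns a *decreasing* relationship still produces *positive*
predicted-vs-true correlation, so a single signed column conflates two
different quantities.

`linear_baseline()` fits ordinary least squares on any predictor subset and
reports fitted-vs-observed correlation, residual RMSE and the overall ANOVA
$F$ and $p$ — the standard of comparison for the claim that the feature–rate
relationship is nonlinear.

## The synthetic benchmark

Real folding-rate compilations are small lab-curated tables tied to external
structure and contact-predictor runs, so the package carries a generator
(`synth_records()` / `generate_benchmark()`) that emulates their *structure*
rather than their proteins:

* Per protein, a compact **C$\alpha$ chain** is built as a confined
  self-avoiding random walk (3.8 Å virtual bonds, 3.5 Å excluded volume,
  confinement radius $\propto L^{1/3}$ — constant density, like globular
  proteins). The "real" contact map follows from the geometry.
* The **contact probability map** is a predictor-like corruption of the real
  map: true contacts get high but imperfect probabilities (0.60–0.98),
  non-contacts occasionally get false-positive mass. Estimated and
  structure-derived descriptors therefore correlate strongly but imperfectly
  across the benchmark, as they do for real contact predictors (asserted as
  $r > 0.5$). This "structure first, then noisy map" construction was chosen
  over patching a random map onto a walk because it guarantees that
  consistency by construction.
* **Classes** differ the way real kinetic classes do: two-state proteins are
  shorter (40–110 vs 90–300, overlapping), more compact, helix-richer, and
  have a mild amino-acid usage bias; no single feature separates the classes.
* **Planted rates** are class-specific functions of each protein's own
  *emitted* descriptors — two-state rates fall with LRCO/LRCN and rise with
  helix content; multi-state rates fall steeply with length — plus one mild
  quadratic term (so the nonlinear regressor measurably beats the linear
  baseline) and Gaussian noise (default sd 0.3 log units, about the
  reproducibility of experimental rate measurements). The standardization
  constants inside the planted model are frozen design constants calibrated
  once to this generator's typical descriptor scales, not fitted to any
  realization; with `noise_sd = 0` recomputing descriptors from the emitted
  files reproduces the emitted rates exactly (a test closes this loop
  through the file round trip).
* Probabilities are rounded to 6 decimals and coordinates to 3 *in memory*,
  i.e. to the on-disk text precision, so file round trips are bit-exact.

What a green synthetic test does **not** establish: performance on real
proteins. The generator's maps are statistically simpler than real contact
predictions (no systematic secondary-structure-dependent error correlations),
its chains are not real folds, and the planted rate law is far smoother than
folding thermodynamics. The synthetic results validate the machinery —
descriptors, leakage-free protocols, routing, tuning — not the biology.

## Numerical choices and degenerate inputs

* Contact maps: symmetry enforced by mirroring; diagonal zero; duplicate pairs
  allowed only when consistent; probabilities outside $[0,1]$ rejected.
* Missing residues in structures (no C$\alpha$) contribute no contact.
* `contact_order()` of an empty map is 0 by definition; Pearson correlation of
  a constant vector is an *error*, never a silent 0 — except in the feature
  screen, where a constant feature is reported as `NA` with a note.
* Strict sequence alphabet by default (the 20 canonical codes); lenient mode
  drops non-canonical residues from composition numerator and denominator.
  Strict-mode errors name the record and the first offending position.
* Rates are $\log_{10}(k_f/\mathrm{s}^{-1})$ everywhere; `ln_to_log10()`
  converts natural-log literature values.
* LOOCV row-order invariance, split determinism given a seed, and SMO
  determinism are all tested properties.

## A worked run

```{r example, eval = FALSE}
recs <- synth_records(synth_config(n_proteins = 80, seed = 42))
fit <- foldrate(recs)
print(fit)

rep <- loocv_pipeline(recs)
rep$accuracy
head(rep$predictions)

# what-if: force the other kinetic model for one protein
predict(fit, recs[[1]], force_label = "multi_state")
```

## Known limitations

* The package consumes contact probability maps and SS strings; it does not
  run any contact or secondary-structure predictor.
* Only model 1 of a PDB file and C$\alpha$ atoms are read; mmCIF is not
  supported.
* Pair-counting and normalization constants may differ from other
  implementations of contact-order-style descriptors by fixed factors;
  comparisons across tools should go through correlations, not raw values.
* The two-phase $\varepsilon$ heuristic is not a full 3-D grid search; it can
  miss joint optima, which is the accepted trade-off for its cost.
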