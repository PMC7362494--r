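---
title: "Immune-inspired QSAR modelling with grey-wolf descriptor selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-inspired QSAR modelling with grey-wolf descriptor selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarwolf)
```

`qsarwolf` models the "structure–property" dependence of drug compounds —
concretely, predicting the duration class of sulfonamide antimicrobials
(*short* <10 h, *medium* 10–24 h, *long* 24–48 h) from wide molecular
descriptor tables — with a pipeline of wrapper feature selection by grey
wolf optimization (GWO) followed by artificial-immune-system (AIS)
classifiers.  This vignette is the package's account of the science: what
each model assumes, which tunables matter, what the synthetic benchmark
generator does and does not emulate, and where the method's limits are.

## Data model

All functions operate on a *labeled descriptor table*: a tibble with a
`compound_id` column, a `label` factor over the closed class set
`short < medium < long`, and numeric descriptor columns.  Classifier tie
breaks always resolve to the lowest class index in that ordering, which
makes every prediction deterministic.  Missing values are rejected at load
time — descriptor databases are computed, not measured, so missingness
signals a broken export rather than something to impute.  Binary analyses
use the short-vs-long pairing by default (with `long` positive), because
duration's extremes are the pharmacologically interesting contrast; macro
one-vs-rest averaging is available via `pairing = "macro"`.

Every classifier assumes inputs in the unit cube; `minmax_normalize()`
maps each column through `(x − min)/(max − min)` and sends constant columns
to 0 (they carry no information; any constant works and 0 keeps
idempotence).

## Constitutional descriptors

`parse_smiles()` implements the bracketless organic subset of SMILES —
atoms B/C/N/O/P/S and halogens, aromatic lowercase atoms, branches, single
digit ring closures, `-`/`=`/`#` bonds.  Implicit hydrogens follow the
standard valences (C 4; N 3 or 5; O 2; S 2, 4 or 6 — so the sulfonyl
`S(=O)(=O)` is hexavalent with no hydrogen); an aromatic carbon, or an
aromatic nitrogen with two ring connections, accounts for one ring double
bond, which yields the familiar result that a substituted aromatic carbon
carries no hydrogen.  Charged species, isotopes and stereochemistry are out
of scope: the sulfonamides are neutral and achiral at this level of
description, and a parse error is more useful than a silent guess.

`constitutional_descriptors()` reduces a parsed molecule to formula-level
descriptors: atom count, non-hydrogen atom count, relative element
fractions (which sum to one by construction), molecular weight under the
IUPAC standard atomic weights (overridable through `atomic_weights()` —
published tables do not always state their weight convention, and ±0.01 u
absorbs the difference), and relative (per-atom) molecular weight.  These
are the only descriptors a reader can verify against a printed table with
pencil and paper, which is exactly why the package computes them itself;
the thousands of topological/electronic descriptors of a commercial
database are not reimplemented.

## Grey wolf descriptor selection

The wrapper treats descriptor selection as continuous optimization over
weight vectors `X ∈ [0,1]^d`.  A wolf's fitness is evaluated on the top-`k`
subset of its weights:

* stratified `fitness_folds`-fold cross-validated accuracy of a
  nearest-centroid classifier on the subset columns (cheap enough to be
  called thousands of times),
* **plus** `margin_weight` (default 0.1) times the mean relative centroid
  margin `(d_other − d_own)/(d_other + d_own)`,
* **minus** `size_penalty · k/d` (default 0.01).

The margin term deserves a note.  On well-separated data many subsets reach
identical CV accuracy (accuracy is integer-grained in 1/n), so an
accuracy-only objective plateaus and the search cannot tell a saturated
partial marker set from the full one.  The margin is a continuous,
bounded tie-breaker that prefers subsets separating the classes more
widely; with `margin_weight = 0` the objective reduces to plain penalized
CV accuracy.

The pack update is the canonical encircling model: per leader
`ℓ ∈ {α, β, δ}` (the current pack's three fittest wolves),
`D_ℓ = |C_ℓ·X_ℓ − X|` componentwise, `X_ℓ' = X_ℓ − A_ℓ·D_ℓ`, and the wolf
moves to the clipped mean `(X'_1 + X'_2 + X'_3)/3`, with `A = 2a·r₁ − a`,
`C = 2·r₂` and the control scalar `a` decaying linearly from 2 to 0 over
the run.  Two bookkeeping choices matter and were made deliberately:

* **Leaders are the current iteration's top three**, not a persistent
  elite.  A persistent elite collapsed the pack prematurely (wolves average
  towards three nearly identical leaders and exploration dies); the
  current-iteration form kept exploring and roughly doubled marker
  recovery in our benchmarks.  A separate best-so-far record supplies the
  returned weights and the monotone fitness trace.
* **Half the pack is warm-started** at `0.7·s + 0.3·U(0,1)` where `s` is
  the per-column Fisher score (one-way ANOVA F ratio, min-max normalized).
  Filter-informed initialization is standard practice in metaheuristic
  feature selection; it seeds the search in promising regions while the
  wrapper objective still makes every decision.  `init = "uniform"`
  disables it.

Defaults: `k = 200` (the reduced-table width the pipeline targets),
`n_wolves = 12`, `iterations = 30` for pipeline use; the benchmark study in
the acceptance script uses 30 wolves × 50 iterations.  One RNG stream per
run, in documented draw order (fold shuffle, initial positions, then
per-wolf `r₁`/`r₂` per leader per iteration), makes runs bitwise
reproducible.

## The immune classifiers

**AIRS** follows the two-stage resource-limited formulation.  The affinity
between patterns is `1 − ‖x − y‖/√k` (1 at identity, 0 across the unit-cube
diagonal).  For each training antigen, the best same-class memory cell
spawns a population of mutated clones (per-coordinate uniform redraw with
probability `1/hypermutation_rate`); clones receive resources proportional
to stimulation and the weakest are removed until the budget
`total_resources` (default 100) is met; rounds repeat until mean
stimulation reaches `stimulation_threshold` (default 0.9, capped at
`max_refinements` rounds).  The fittest survivor becomes a candidate
memory cell, enters the pool if it out-stimulates the matched cell, and
replaces it when they lie closer than `affinity_threshold_scalar` (default
0.2) times the mean inter-antigen distance.  Classification is a majority
vote of the `k_neighbors` (default 3) highest-affinity cells, ties broken
by the single nearest cell.

**CLONALG** keeps one repertoire of `N` antibodies (default 30) per class.
Each presentation selects the `n_select` highest-affinity antibodies,
clones the rank-`i` antibody `round(β·N/i)` times (halves round up),
matures clones with Gaussian noise of SD `mutation_sd·(1 − affinity)` —
high-affinity clones mutate little — and keeps the best clone versus its
parent.  Elitism is enforced across antigens: a replacement (including the
`d_replace` fresh random antibodies injected per presentation) is rejected
if it would lower the pool's best affinity to *any* antigen of the class.
Without that guard, presenting antigen B can silently degrade the pool's
best recognizer of antigen A, and the learner loses its monotone
convergence guarantee.

**Immune network model.**  Each class's training vectors (the "formal
peptides") are unit-normalized and stacked into a standard matrix `M`; the
SVD of `M` provides singular values `σᵢ` and right singular vectors `vᵢ`
spanning the class's recognition subspace.  The binding energy of a query
`x` is `E = −Σᵢ σᵢ·|⟨vᵢ, x/‖x‖⟩|`, and the minimal energy assigns the
class.  This closed form is the simplest SVD-projection energy consistent
with minimal-energy recognition; it is isolated behind `binding_energy()`
so alternatives can be swapped.  Notable properties: `E ≤ 0`; invariance
under positive rescaling of the query (direction is what binds); and with
full rank the training rows themselves bind most strongly to their own
class.  One row per compound is the folding convention for the standard
matrix — it keeps standards well defined for any class size.  The margin
between the two lowest class energies (`energy_margin()`) serves as a
confidence for candidate ranking.  Because the model sees only
*directions*, it needs classes that differ in direction after
normalization; data whose classes differ only in overall magnitude are a
degenerate input (see the generator notes below).

## Baselines and evaluation

Naive Bayes, ridge-regularized multinomial logistic regression, decision
tree, random forest, and SVM are delegated to their established R
implementations behind a uniform train/predict/score adapter; the Bayes
posterior formula itself (`bayes_posterior()`) is implemented in-package.
Logistic regression uses glmnet's ridge path at a fixed penalty because the
tables have far more descriptors than compounds.

`roc_auc()` integrates the ROC by trapezoid with tied scores grouped, which
equals the Mann–Whitney pair statistic (ties count ½) to machine precision
— the test suite asserts agreement with the exhaustive pair count at
1e-12.  `lift_table()` sorts by descending score into near-equal bins
(earlier bins take the remainder) and reports per-bin lift and cumulative
coverage of positives.  `compare_algorithms()` refits the selector inside
every CV training fold: selection leakage would otherwise inflate exactly
the improvement the comparison is meant to measure.

## The synthetic generator

`generate_synthetic()` emulates the *shape* of the motivating database: a
few dozen compounds, ~2005 descriptors, a stated number of informative
columns.  The informative columns are assigned round-robin to the classes
as class-specific markers: rows of class `j` are shifted upward on block
`j` by `class_separation·noise_sd/√(2b)` (block size `b`), which places
every pair of class mean vectors at distance `class_separation·noise_sd`
over the informative subspace.  The marker-block geometry was chosen over
collinear class means deliberately: collinear means give all classes the
same direction, a degenerate input for the direction-based immune-network
model, whereas marker descriptors — substructures characteristic of one
class — are also the chemically natural picture.  Indices of the
informative columns are recorded so selection recovery can be scored.

What the generator does **not** emulate: correlated descriptors (real
descriptor families are strongly redundant), heterogeneous informativeness
(real markers vary widely in strength), non-Gaussian marginals, and label
noise.  Passing tests on this generator therefore show that the machinery
works where signal exists and is identifiable; they do not show that 15
real compounds suffice to fit 2005-descriptor QSAR models.

With 200 equal-strength informative columns at total separation 3 and only
tens of compounds, the per-column effect (~0.26 noise-SD) is below any
detector's power — even an oracle univariate filter barely enriches its
top 200 — so descriptor selection cannot beat no-selection for the dense
baselines under those conditions, and the package's acceptance suite
reports that outcome honestly rather than engineering around it.  This is
a statement about that specific synthetic regime, not about the method.

## Numerical and design notes

* Problem sizes in the tests and acceptance script (e.g. 45×2005 with
  3-fold CV for the comparison study, 40×50 for recovery, 36×15 over 20
  seeds for classifier hold-out) were chosen as the smallest designs that
  still exercise the claimed behaviour stably.
* All stochastic components take explicit integer seeds and are bitwise
  reproducible; the pipeline manifest (config echo, seeds, timings, MD5
  hashes) is sufficient to re-run a study byte-identically.
* Ties: top-`k` thresholding keeps the lower index; classifier ties break
  short < medium < long; equal ROC scores are grouped into one threshold.
* Degenerate inputs: constant columns normalize to 0; a zero query vector
  is rejected by the immune-network model; metric ratios with zero
  denominators are reported as 0 with a `degenerate` flag and a warning.
* The component registry mirrors the surrounding multi-agent system design
  as plain R functions — selector stubs (PSO, ACO, ABC, PCA) and the
  negative-selection classifier raise a uniform not-implemented error
  naming their ontology class; a random-forest-importance selector is the
  one implemented comparison baseline.

## Known limitations

* The SMILES dialect is the neutral organic subset; bracket atoms, charges
  and stereo descriptors are rejected by design.
* AIRS pool growth is data-dependent; pathological configurations (clonal
  rate larger than the resource budget) can void the resource bound.
* The immune-network model ignores magnitude information by construction;
  pair it with the distance-based learners when magnitudes matter.
* Wrapper selection at `p ≫ n` can overfit its own cross-validation; the
  comparison harness guards the *evaluation* against leakage, but the
  selected subset itself is still an optimistic object, as in any wrapper
  method.
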