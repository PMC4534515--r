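---
title: "Comparing SVM hyperparameter search strategies on fingerprint data"
author: "svmtune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing SVM hyperparameter search strategies on fingerprint data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Support vector machines with the radial-basis-function kernel
$K(x, x') = \exp(-\gamma \lVert x - x'\rVert^2)$ are a standard classifier
for virtual screening: given compounds encoded as binary substructure
fingerprints, predict whether they are active against a protein target.
Predictive performance depends strongly on two hyperparameters, the
regularization strength $C$ and the kernel width $\gamma$, which must be set
*before* training.  Hyperparameter selection is itself an optimization
problem over the box
$\mathcal{L} = [C_\min, C_\max] \times [\gamma_\min, \gamma_\max]$
of a black-box objective
$f(\lambda)$ — the expected generalization accuracy at
$\lambda = (C, \gamma)$ — that is expensive to evaluate (each evaluation
trains classifiers) and whose gradient is unavailable.  `svmtune` implements
and compares, under one trace-producing contract, the selection strategies in
common use:

* **libSVM heuristic** — the fixed default $C = 1$, $\gamma = 1/d$ for $d$
  fingerprint bits (one evaluation, no search);
* **SVMlight heuristic** — the fixed default
  $C = 1 / \mathrm{mean}_i \lVert x_i \rVert^2$, $\gamma = 1/d$;
* **grid search** — $M_C \times M_\gamma$ points placed uniformly in log10
  scale, visited in column-raveled order ($C$ sweeps fastest at fixed
  $\gamma$, starting from $\gamma_\min$), the most common library behaviour;
* **small grid** — a budget-constrained grid (see below);
* **random search** — independent log-uniform draws of $\log_{10} C$ and
  $\log_{10} \gamma$;
* **Bayesian optimization** — a Gaussian-process surrogate over the box with
  the expected-improvement acquisition, written from scratch in this
  package.

The objective actually optimized is the internal cross-validated accuracy
$\bar f(\lambda) = f(\lambda) + \varepsilon$, with
$\mathrm{Accuracy} = (TP + TN)/(TP + TN + FP + FN)$ averaged over stratified
folds.  Strategies are compared by final accuracy, by the *best-so-far
curve* (running maximum of $\bar f$ against iteration), by the normalized
area under that curve (how quickly a strategy converges to a strong model),
by win counts across a suite (draws credited to all tied strategies), and —
on benchmarks with a known optimum $\hat\lambda$ — by the simple regret
$\delta_n = f(\hat\lambda) - f(\lambda_{\text{best}})$.

# The synthetic data generator

Real ChEMBL-derived screening sets cannot be redistributed with a package,
so every experiment here runs on synthetic fingerprint data from
`generate_dataset()`.  The generative model is a class-conditional Bernoulli
mixture: each of $d$ bits is drawn independently; non-informative bits have
density $p$ in both classes, while the first $m$ *informative* bits have
density $p$ in inactives and $\min(1, p + e)$ in actives.  The `effect` $e$
tunes class overlap continuously from exchangeable classes ($e = 0$, CV
accuracy at chance) to linearly separable ones ($e = 1$, $p = 0$).
Informative bits occupy fixed leading columns so that tests can inspect
them directly.

`make_benchmark_suite()` emulates a multi-target benchmark: per-target
difficulty (effect and class sizes) is drawn once and shared by all of that
target's fingerprint representations, mirroring study designs in which one
protein target is described by several fingerprints.  Defaults:

* class sizes uniform on `[72, 6852]`, the span of per-class counts in
  published ChEMBL extracts ("paper-shapes");
* effect uniform on `[0.15, 0.6]`, chosen once so that tuned CV accuracies
  spread over roughly 0.65–0.97, the spread seen in published multi-target
  accuracy tables.  The true overlap structure of real data is unknown, so
  this range is a package-level config choice, not an assertion about any
  particular dataset.

What the generator does **not** emulate: inter-bit correlation (real
fingerprint bits are strongly correlated through shared substructures),
heavy-tailed bit frequencies, and activity-cliff structure.  Passing tests
therefore demonstrate correctness of the strategies and of the comparison
machinery, and directional conclusions about optimizer behaviour on
fingerprint-shaped inputs — not accuracy levels transferable to real
screening data.

# The objective

`svm_objective()` wraps a dataset in the evaluation contract
`evaluate_point(obj, lambda)`.  Inner SVM training is delegated to libsvm
(via `e1071`); the package never re-implements the quadratic-program solver.
Design choices that matter:

* **Folds are frozen per objective instance** (default 5-fold, stratified,
  a deterministic function of `fold_seed` and the labels).  All strategies
  run against one instance therefore see the *same* noise realization
  $\varepsilon$, making comparisons paired and traces exactly reproducible.
  The alternative — re-randomized folds per evaluation — is supported by the
  formalism but makes every comparison noisier at desk scale.
* **Caching at 12 decimals** in log10 coordinates: EI maximization can
  re-propose near-duplicate points; the cache guarantees one solver run per
  distinct point, and `eval_count()` counts solver evaluations rather than
  calls.
* **No class weighting**: plain $C$ for both classes, matching the default
  behaviour of the tools whose heuristics are compared.
* **Final accuracy** is reported as the inner-CV value at the selected
  $\lambda$ (the quantity the strategies maximize); `final_evaluate()`
  provides the outer hold-out alternative for users who keep a naive test
  set.

# The strategies

**Random search** samples $\log_{10} C \sim U(\log_{10} C_\min, \log_{10}
C_\max)$ and $\log_{10}\gamma$ analogously, independently — the log-uniform
product distribution.  It ignores all previous results; its incumbent is the
running maximum.  Because meaningful SVM response structure lives on the log
scale, this is the standard "uninformed but sensible" baseline.

**Grid search** uses the closed-form level placement
$C_i = 10^{\log_{10} C_\min + (i-1)\,\Delta_C}$ with
$\Delta_C = (\log_{10} C_\max - \log_{10} C_\min)/(M_C - 1)$, default
$14 \times 14$.  Column raveling means a truncated run spends its whole
budget at the smallest $\gamma$ values — the behaviour responsible for grid
search's poor anytime performance, and worth modeling exactly because it is
what standard libraries do.  Randomly permuting the visit order is exposed
as an option in principle but deliberately not used in the comparisons,
since in practice grids are almost never permuted.

**Small grid** is a budget-constrained strict grid: among all
$M_C \times M_\gamma \le \text{budget}$ (both $\ge 2$), the axis counts whose
ratio best matches the ratio of the axis log-ranges are chosen (ties: more
points, then more $\gamma$ levels), e.g. budget 20 on the default box (7 and
13 decades) gives a $3 \times 6$ grid.  Published descriptions of truncated
grid modes do not pin down a construction; this one was chosen because it
keeps the method a genuine grid (distinguishable from full grid search) with
resolution proportional to each axis's extent, and it is flagged here as a
package design decision.

# Gaussian-process Bayesian optimization

The surrogate is a Gaussian process with an anisotropic squared-exponential
kernel on min–max-normalized log10 coordinates,
$k(u, v) = \sigma_f^2 \exp\!\big(-\tfrac{1}{2}\sum_a (u_a - v_a)^2/\ell_a^2\big)$,
constant prior mean equal to the mean of the observations, and observation
noise $\sigma_n^2$ on the diagonal.  The posterior at a query point is
computed exactly via a Cholesky factorization of the training covariance.
The acquisition is expected improvement in closed form,
$\alpha_{EI} = \sigma\,(z\,\Phi(z) + \varphi(z))$ with
$z = (\mu - f_{\text{best}})/\sigma$, degenerating to
$\max(0, \mu - f_{\text{best}})$ at $\sigma = 0$.

Numerical and loop choices:

* **Kernel hyperparameters** are refit each iteration by maximizing the log
  marginal likelihood (L-BFGS-B, 3 starts: one conventional default plus two
  random; length scales bounded to $[0.01, 10]$ in normalized units; noise
  variance floored at $10^{-6}$).  A fixed-kernel mode exists for
  deterministic unit tests.
* **Jitter** (the pure numerical diagonal floor) defaults to $10^{-12}$ and
  escalates by factors of 100 up to $10^{-4}$ only if the Cholesky fails;
  beyond that the fit raises a numerical error and the optimization loop
  falls back to a random point for that iteration, recording the event in
  the trace.  The tiny default keeps the noise-free posterior at a training
  point essentially exact (std $\sim 10^{-6}$), so EI at an already-observed
  incumbent is $\le 10^{-6}$ and the loop cannot stall by re-proposing it.
* **Acquisition maximization** scores 2048 log-uniform candidates plus the
  box corners and center and takes the argmax; EI values within $10^{-12}$
  count as tied and the earliest candidate wins.  The tie tolerance matters
  on flat response plateaus (common on fingerprint data, where most of the
  box yields majority-class accuracy): without it, microscopic
  posterior-variance differences deterministically steer every proposal to
  a box corner.  For the same reason, an iteration whose entire observation
  history is constant draws a log-uniform exploration point instead of
  consulting the (uninformative) surrogate.  In a 2-D
  box this is simple, seed-reproducible, and accurate enough that gradient
  refinement is not worth its complexity.  A proposal within $10^{-9}$
  (normalized) of an observed point is replaced by the next-best candidate
  to keep the covariance non-singular.
* **Initialization**: 5 log-uniform points drawn from the same seeded stream
  as random search, so the two strategies share their opening evaluations
  under a common seed — useful both as a test contract and for paired
  comparisons.

# Evaluation methodology

`best_so_far()` converts a trace to its non-decreasing incumbent curve;
`curve_auc()` computes the trapezoidal area over an iteration axis
normalized to $[0, 1]$.  Curves shorter than the axis — notably the
length-1 curves of the fixed heuristics — are extended at their final value,
which makes a constant strategy's AUC equal its accuracy (the identity
visible in published AUC tables where the heuristics' AUC and final accuracy
columns coincide).  Win counting compares final values rounded to 4 decimals
(one digit finer than typically printed accuracies, avoiding spurious draws
from float noise) and credits all tied strategies.  `run_suite()` executes
the full cross product; each stochastic strategy runs once per seed at the
largest budget and smaller budgets are exact prefix truncations, valid
because every implemented strategy is an anytime algorithm.

`analytic_benchmark()` provides two closed-form surfaces on the default box
with documented optima for regret measurement: `two_bump` (a dominant and a
secondary anisotropic Gaussian bump — multimodal, the interesting case for
EI) and `plateau_cliff` (a logistic ramp in $\log C$ times a Gaussian band
in $\log\gamma$ on a 0.5 floor, mimicking the wide high-accuracy plateaus of
real SVM response surfaces).

# Study sizes used in the shipped tests and acceptance script

The package's own test suite and `scripts/acceptance.R` exercise the
pipeline at desk scale, chosen as the smallest sizes at which the
directional conclusions are stable across seeds: suites of 10 targets
$\times$ 2 fingerprint specs (79 and 166 bits — the two shortest published
fingerprint lengths), class sizes uniform on $[30, 80]$, 5-fold CV, budget
50 with 5 replicate seeds for the suite comparison, and 20 seeds at budget
30 on `two_bump` for regret.  With these sizes the full acceptance run
completes in minutes on one core while reproducing the expected ordering
(Bayesian optimization winning most experiments; mean curve-AUC ordering
Bayes $\ge$ random $>$ grid $>$ SVMlight heuristic).

# Known limitations

* Bit independence in the generator (see above): absolute accuracies are not
  transferable to real fingerprints.
* The GP assumes a stationary smooth response; genuinely discontinuous
  response surfaces would favor heavier-tailed surrogates.
* Only the two-hyperparameter RBF case is supported; no kernel-type
  selection, no additional hyperparameters, accuracy is the only metric
  (no MCC/AUROC), and no significance testing of strategy differences is
  performed.
* The "small grid" construction and the BayesOpt loop settings are package
  design decisions where common practice is under-specified; both are
  documented above rather than asserted as equivalent to any particular
  published configuration.
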