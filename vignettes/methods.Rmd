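---
title: "Quality-by-design optimisation of ointment rheology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-by-design optimisation of ointment rheology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheodsd)
```

## The problem

An ointment is a two-phase semisolid: a drug powder dispersed in a fatty
base. How it is made — how much drug is loaded, how long and how fast it is
mixed, how the base is composed, and whether the drug is added to the molten
base (method A) or worked into the cooled base (method B) — determines its
rheology, and the rheology determines whether it stays in the jar, spreads
on skin, and stays physically stable. `rheodsd` implements a
quality-by-design (QbD) chain that connects six process factors to four
rheological quality attributes and then carves out an operating region where
the predicted probability of an out-of-specification batch is low.

The four responses and their specification windows are:

| response | window | meaning |
|---|---|---|
| yield stress | 40–55 Pa | stress at which the soft solid starts to flow |
| high-shear viscosity (100 s⁻¹) | 0–7 Pa·s | spreadability under rubbing |
| low-shear viscosity (0.01 s⁻¹) | 11000–18000 Pa·s | resistance to sagging/settling |
| storage modulus G′ (37 °C) | 200–1000 Pa | stiffness at body temperature |

## Stage 1: the definitive screening design

Six factors at three levels each would be prohibitive as a full factorial.
A definitive screening design (DSD) screens `m` continuous factors in about
`2m + 4` runs while keeping main effects orthogonal to every second-order
effect. The construction starts from a conference matrix `C` of even order:
one zero per row and column, ±1 elsewhere, with

$$C'C = (m-1)\,I.$$

For five continuous factors the order-6 conference matrix is used with its
last column dropped; the design is the half-fraction, its fold-over (every
run mirrored with all coded values negated), and two centre runs. The
dropped column slot carries the two-level method factor: its ±1 entries
select the level, the fold-over flips it, and the two centre runs split
across levels. This reproduces the 14-run structure of the case study: six
mirror pairs plus two centre runs, one per method.

Two structural notes discovered while validating against the printed
14-run table. First, the mirror pair whose conference-matrix zero fell in
the dropped column has *no* centre-valued continuous factor (the other ten
non-centre runs have exactly one). Second, the ±1-coded method column is
not exactly orthogonal to the continuous main effects (the zero-row
convention breaks it by one inner-product unit); the package therefore
asserts second-order orthogonality for the continuous factors, where it is
exact.

Conference matrices are served from a verified lookup (orders 4, 6, 8 and
12 by the Paley construction; order 10 precomputed over GF(9); order 2
trivial) and re-verified on every call. No general existence search is
attempted — screening practice does not need orders beyond 12.

Factors are coded as $(x - \text{mid})/\text{half-range}$, so low/mid/high
map to −1/0/+1. `mid` defaults to the arithmetic centre; asymmetric ranges
are accepted but the coded quadratics then lose their usual interpretation,
so the default is recommended.

## Stage 2: responses from rheometer curves

Each batch yields three curves, and each curve one or two responses:

* **Yield stress** from an oscillatory amplitude sweep: the
  linear-viscoelastic (LVR) plateau of G′ is grown from the low-strain end
  while each next point stays within a fraction `f` (default 0.05) of the
  running plateau mean; the yield stress is the oscillatory stress at the
  first point where G′ drops below $(1-f)$ of the plateau mean. This is
  deterministic, unlike the visual onset-reading often used on instrument
  software. A sweep with fewer than three plateau points or no drop raises
  an explicit error rather than guessing.
* **Power-law flow parameters** from the flow curve, fitted in the
  viscosity form of the Ostwald–de Waele model,
  $\eta = K\dot\gamma^{\,n-1}$, by least squares on the log–log scale over
  a configurable window (default 1–100 s⁻¹, the medium-to-high shear
  range). The fitted `n` is the flow index: `n < 1` shear thinning. The
  form matters: quoting the model as $\eta = K\dot\gamma^{\,n}$ while
  calling `n < 1` pseudoplastic is a common notational slip, and this
  package standardises on the viscosity form so the reported flow indices
  are comparable with tabulated ones.
* **Low/high-shear viscosity** by log–log interpolation at 0.01 and
  100 s⁻¹ (curve endpoints by convention, configurable).
* **Storage modulus at 37 °C** by linear interpolation of the temperature
  sweep. The readout temperature is a parameter; 37 °C (body temperature)
  is the default.

## Stage 3: stepwise response-surface models

Each response is modelled on the coded scale as intercept + main effects +
pairwise interactions + quadratics of continuous factors, with the
categorical factor entering as −1/+1 — its coefficient is the "match"
value added for method B and subtracted for method A, so the two level
values always sum to zero.

Selection is bidirectional stepwise with partial-*t* entry/removal
thresholds, with weak effect heredity on by default (a second-order term
may enter only while a parent main effect is present; one of the printed
case-study models itself violates *strong* heredity, which is why heredity
is a switch and not an assumption). Three operating points are worth
knowing, because at `n = 14` the threshold *is* the model:

* `p_enter = p_remove = 0.10` (default): exploratory; with ~25 candidate
  terms it over-selects by construction — the minimum of ~25 null
  p-values falls below 0.10 about 90% of the time.
* `p_enter = p_remove = 0.002` (≈ 0.05/25, Bonferroni-style): use when the
  goal is exact recovery of a sparse active set; this controls the
  best-of-many entry bias.
* `p_enter = p_remove = 0.25` (the classic screening entry default): use
  when the goal is fit quality / prediction; the case-study refits use
  this. A small-sample AICc criterion is also available, but note that it
  too chases vanishing residuals when the signal is strong.

Inference on the selected terms (`t_ratios()`, `summary()`) is ordinary
linear-model inference, sorted by |t| — with the usual caveat that
post-selection p-values are optimistic.

## Stage 4: desirability optimisation

Each response gets a two-sided desirability: 0 outside its window, rising
linearly from the window edges to 1 across the central 50% of the window.
The overall desirability is the weighted geometric mean, and it is
maximised over the coded box at fixed method level by 32 seeded
maximin-Latin-hypercube starts polished with Nelder–Mead. Ties at
desirability 1 (common — the feasible region has positive volume here) are
broken toward the largest scaled margin to the nearest window edge. The
tie-break deliberately does *not* consult the later defect simulation:
the desirability stage models preference, not noise, and keeping the
stages independent keeps the before/after defect comparison meaningful.

## Stage 5: Monte Carlo defect rates

A batch is *defective* when any response leaves its window. The simulator
perturbs the continuous settings (Gaussian, per-factor SD) and adds
Gaussian residual noise to each model prediction; both SD sets are
configurable, and both factor-only and response-only perturbation are
supported. The shipped default — factor SD = 5% of each half-range,
response SD = the fit RMSE when available, else 5% of the model's
intercept scale — is a deliberate, frozen choice: the case study's source
never states its simulation SDs, so printed defect rates can only be
reproduced directionally, not numerically.

Common random numbers (one seed reused across operating points) make
before/after comparisons fair. The overall defect is floored at `1/n`
before taking log10 so the GP target stays finite.

For space-filling defect surfaces the radial stratification sampler cycles
run `i` through layer `(i-1) mod L`; layer 0 spans radii `[0, d]` and layer
`i` spans `[d+(i-1)2d, d+i\,2d]`, with `d` chosen by default so the
outermost radius reaches the coded-box corner $\sqrt{\text{dims}}$. Points
carry stratification weights (layers have unequal radial widths), so a
weighted mean over a stratified sample estimates the same expectation as
i.i.d. sampling of the radial measure — that equivalence is tested.

## Stage 6: design space by prior-weighted CART

Labelled points (settings sampled over the factor box, pass/fail from the
noisy models) train a greedy binary classification tree maximising the
size-weighted Gini decrease, grown best-first to a total split budget
(default 15, the case-study depth) with a minimum leaf size of 5% of the
data. Node class probabilities are prior-weighted: a node's prior blends
its parent's prior and posterior, $\text{Prior} = \lambda p + (1-\lambda)P$
(λ default 0.5; with λ = 1 and uniform priors the leaf posteriors reduce to
Laplace-smoothed frequencies), and the posterior is
$(n_i + \text{Prior}_i)/\sum_j (n_j + \text{Prior}_j)$. The tree is stored
as its leaf partition — each leaf keeps its full constraint path, counts,
prior and posterior — which is exactly the information the design-space
extraction needs. The design space is the axis-aligned box of the
highest-pass-posterior leaf, clipped to the factor ranges and reported as
centre ± half-width; a rank-based AUC quantifies the tree's diagnostic
ability. The tree is implemented from scratch (not via `rpart`) because the
λ-blended node priors are the method's point; `pROC` serves as an
independent oracle for the AUC in the test suite.

## Stage 7: Gaussian-process refinement

The log10 defect rate over the design-space box is modelled with
constant-mean kriging under the Gaussian correlation
$r_{ij} = \exp(-\sum_k \theta_k (x_{ik}-x_{jk})^2)$, inputs on the coded
scale. θ and the process variance are estimated by maximum likelihood
(profiled over the GLS constant mean) with seeded multi-start L-BFGS-B over
log θ ∈ [log 10⁻⁶, log 10⁴]. A fixed quadratic prior mean
$m(x) = \tfrac14\sum_k x_k^2$ is available as an option but is not the
default: a hard-coded quadratic mean is an odd prior for a 5-D defect
surface and is included only for completeness.

The nugget (default 10⁻⁸, raised automatically with a warning if the
correlation matrix will not factorise) is treated as numerical jitter, not
observation noise: at an exact training-point match the nugget joins the
correlation vector, so the predictor interpolates its training data
exactly. The training design for the case study is a seeded maximin Latin
hypercube in the box's coded image (128 points by default); the surrogate
minimum is located by seeded multi-start bounded minimisation and the
operating point is reported in natural units alongside the four model
predictions there.

## The synthetic-data generator

Every pipeline stage is testable offline because the generator produces
all inputs with known ground truth:

* **DoE response tables**: ground-truth model evaluations plus Gaussian
  residual noise (default SD 5% of each intercept scale). With the shipped
  case-study models the yield-stress column lands inside the reported
  35.0–75.1 Pa batch band.
* **Rheometer curves**: log-spaced grids matching the instrument protocol
  (strain 10⁻³–10², shear rate 0.01–100 s⁻¹, 20–50 °C; 30 points per
  decade), from a piecewise plateau/decay G′ model, a pure power law, and
  a linear modulus–temperature decay, with multiplicative log-normal noise
  (σ_log default 0.02). With σ_log = 0 every extraction round-trips to the
  generating parameters exactly — that round trip is the basis of the
  rheology acceptance checks.
* **Labelled pass/fail points** for the tree, sampled uniformly or
  radially.

What the generator does *not* emulate: instrument inertia and slip,
evaporation during long sweeps, thixotropic history effects, batch-to-batch
base variability, and any correlation between the four responses beyond
what the shared factors induce. Passing tests on synthetic data therefore
demonstrate the correctness of the algorithms, not the adequacy of the
response models for any particular formulation.

## Problem sizes and determinism

The end-to-end `run_case_study()` defaults are 100 000 Monte Carlo batches
per defect estimate, 6 000 labelled tree points, and a 128-point GP surface
with 20 000 inner runs per point — a few minutes on one CPU; the test suite
exercises the same chain at reduced sizes. Every stochastic step takes a
seed; stage seeds are derived from the master seed, and identical
configuration + seed reproduces a byte-identical JSON report.

## Known limitations

* The defect-rate *levels* depend on the unstated noise magnitudes of the
  original study; only ordering and orders of magnitude are meaningful.
  Under the shipped defaults the desirability optimum is already robust,
  so the study's "high defect before, lower after" narrative inverts: a
  uniform average over the design-space box is worse than either optimised
  point. The box is a tolerance region, not an operating point.
* Stepwise selection at `n = 14` cannot recover 9-term models reliably
  under any criterion; the fitted equations should be read as predictive
  summaries, not causal structure.
* The tree handles one two-level categorical factor (as a 0/1 feature) and
  produces a single box; unions of leaves are out of scope.
* GP fitting is dense Cholesky — fine to a few hundred points, not beyond.
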