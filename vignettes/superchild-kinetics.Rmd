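---
title: "Whole-body retinol kinetics from super-child tracer data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body retinol kinetics from super-child tracer data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retkin)
```

## The problem

Total body vitamin A stores (TBS) are the reference indicator of vitamin A
status, but they cannot be measured directly in vivo. Stable-isotope tracer
kinetics offer a route: a child ingests a small dose of ¹³C-labelled retinyl
acetate, and the fraction of the dose appearing in plasma over the following
weeks (FDp) carries information about absorption, exchange with storage
pools, recycling, and irreversible utilisation. In young children frequent
blood sampling is infeasible, so *super-child* designs pool a population:
each child contributes one or two samples, and a composite group curve —
the geometric mean of FDp across children at each scheduled time — is
modelled as if it came from one "average" child.

`retkin` implements the full analysis chain for such studies: the
compartmental model, its tracer solution, the steady-state tracee solution
that yields TBS, derived residence and recycling statistics,
retinol-isotope-dilution (RID) coefficients, multi-group weighted nonlinear
fitting with parameter sharing, and a synthetic cohort generator for design
evaluation.

## The model

Six components describe whole-body retinol kinetics:

* **Delay 3** — digestion, absorption, chylomicron processing. A pure
  transport delay of `DT(3)` days: an ingested bolus emerges intact after
  `DT(3)`, split `L(4,3)` (default 0.8, the assumed absorption efficiency)
  into hepatocytes and `L(0,3) = 1 − L(4,3)` to unabsorbed loss. The two are
  split *fractions* applied at the delay exit, not competing rates — this
  matters for how absorption efficiency enters every downstream formula.
* **Compartment 4** — hepatocyte retinol, secreted into plasma at `L(5,4)`.
* **Compartment 5** — plasma retinol bound to retinol-binding protein, the
  sampling site. It exchanges with two extravascular pools and feeds an
  irreversible tissue route.
* **Compartment 6** — the larger exchangeable store (presumably mostly
  hepatic retinyl esters); return at `L(5,6)`, irreversible loss at
  `L(10,6)`.
* **Compartment 7** — a smaller, faster exchangeable pool.
* **Delay 8** — nonexchangeable tissues: retinol that leaves plasma at
  `L(8,5)` is catabolised after a short fixed delay `DT(8)` (75 min) and
  never returns.

All coefficients `L(I,J)` are fractions of compartment J's content moved to
I per day. The delays are implemented as exact time shifts, not
chains of compartments: the model distinguishes delay elements from
compartments, and a chain approximation would distort the early upslope of
the curve where the 4-d anchor sits.

### Tracer solution

For a unit bolus, after the shift by `DT(3)` the subsystem {4, 5, 6, 7}
is a linear constant-coefficient ODE system

$$\dot F_4 = -L(5,4)F_4,\qquad
\dot F_5 = L(5,4)F_4 + L(5,6)F_6 + L(5,7)F_7 - [L(6,5)+L(7,5)+L(8,5)]F_5,$$
$$\dot F_6 = L(6,5)F_5 - [L(5,6)+L(10,6)]F_6,\qquad
\dot F_7 = L(7,5)F_5 - L(5,7)F_7,$$

solved in closed form with the matrix exponential applied to the post-delay
state \((L(4,3), 0, 0, 0)\). Delay-8 content is the trailing-window integral
\(L(8,5)\int_{\tau-DT(8)}^{\tau} F_5\,ds\); all cumulative integrals are
computed exactly via an augmented matrix exponential (a 5×5 block matrix
whose exponential carries \(\int_0^\tau e^{As}x_0\,ds\)), which remains
valid when the system matrix is singular (a closed system). As a result the
mass balance — fractions plus cumulative losses sum to 1 — closes to
better than 1e−8 at every time, and the tests verify the solution against an
independent adaptive stiff ODE integration (`deSolve::lsoda`) to 1e−6
relative.

### Steady-state tracee solution

With the measured geometric-mean plasma pool `M(5)` fixed and intake `U(3)`
entering the absorption delay, each compartment's mass follows from its own
balance: `M(4) = L(4,3)U(3)/L(5,4)`, `M(6) = L(6,5)M(5)/[L(5,6)+L(10,6)]`,
`M(7) = L(7,5)M(5)/L(5,7)`; each transfer rate is `R(I,J) = L(I,J)M(J)`.
Then `TBS = M(6)+M(7)`, the disposal rate is `DR = R(10,6)+R(8,5)`, days of
stores `TBS/DR`, and the predicted intake `DR/L(4,3)` is the quantity the
fit compares against the intake datum. Masses are deliberately taken from
per-compartment balances rather than a global least-squares mass solve:
printed 3-significant-figure parameter sets leave the plasma balance
inconsistent at the 0.1–2% level, and the per-compartment convention
reproduces the published arithmetic exactly. `check_plasma_balance()`
reports the residual inconsistency as a diagnostic; whether the original
software enforced that balance during estimation is not documented, so the
package records rather than resolves it.

`L(8,5)` is not estimated: assuming steady state, disposal equals absorbed
intake `0.8·U(3)`, half of which is routed through the tissue pathway, so
`L(8,5) = 0.5·0.8·U(3)/M(5)` (`compute_l85()`), fixed per group.

### Residence times and recycling

`residence_kinetics()` computes every quantity twice and verifies agreement
(to 1e−8 in the tests):

* **Markov closed forms.** Per plasma exit, the probability of eventual
  return is
  \(p = [L(7,5) + L(6,5)\,L(5,6)/(L(5,6)+L(10,6))]/[L(6,5)+L(7,5)+L(8,5)]\);
  the recycling number is the geometric-series mean \(\nu(5) = p/(1-p)\)
  (returns after the first arrival); plasma residence
  \(\bar T(5,5) = \bar t(5)(1+\nu(5))\); pool residences
  \(\bar T(I,5) = L(I,5)\,\bar T(5,5)\,\bar t(I)\); recycling time
  \([\bar T(6,5)+\bar T(7,5)]/\nu(5)\).
* **Matrix route.** \(-A^{-1}\) is the mean-residence-time matrix of the
  subsystem; its plasma column gives every \(\bar T(I,5)\) directly.

The system residence time \(\bar T(SYS)\) sums the residences of 5, 6 and 7
only; time spent in the delay elements is excluded, matching the convention
under which the published rows add up. The recycling-time formula above
reproduces all three published groups within rounding; the original
reference for these definitions is not reproduced here, so the formula is
fixed by that agreement.

### RID coefficients

`Fa(t) = F(6)+F(7)` is the fraction of the dose retained in stores, and
`S(t)` the plasma-to-stores specific-activity ratio; their product satisfies
the identity `FaS(t) = F(5)(t)·TBS/M(5)`, which makes the RID equation
`TBS = FaS/SAp` exactly self-consistent: applied to model-generated plasma
specific activity it returns the model's own TBS at any time where `Fa > 0`
(tested to 1e−6). The package computes FaS on integer days 4–28 by default
rather than hard-coding published values.

## Fitting

`fit_superchild()` minimises weighted least squares with
Levenberg–Marquardt (`minpack.lm::nls.lm`) on **log-transformed**
parameters: rates span four orders of magnitude (≈0.001–14 /d) and
positivity must hold by construction. Residuals follow the fractional
standard deviation convention: `(y − F5(t))/(FSD·y)` with FSD 0.05, tightened
to 0.025 at the 4-d anchor (so that observation carries 4× weight), and the
intake datum enters as `(U3 − DR/L(4,3))/(0.05·U3)`. Observed-value-based
sigma is used rather than model-based so the objective is comparable across
iterations.

Multi-group (*partially parallel*) fits share parameters through a
`sharing_map()`: each adjustable parameter is shared, fully independent, or
independent for a named subset of groups. The published final configuration
is `L(10,6)` independent everywhere and `L(5,4)`, `L(7,5)`, `L(5,7)`,
`L(5,6)` independent for the Bangladeshi group only.

Parameter FSDs come from the scaled inverse Gauss–Newton Hessian at the
optimum, with the Jacobian computed by central differences on the log scale
(the SE of log θ *is* the FSD of θ); a singular covariance is flagged, never
fatal, and `fsd_report()` marks FSD > 0.5 as poorly identified. Convergence
tolerances are 1e−10 on relative objective change and step norm, with at
most 500 iterations; an optional multistart (log-uniform perturbations
within a factor of 2, best objective wins) guards against local optima.
Degrees of freedom are reported as (data points − parameters); the original
software's fractional degrees-of-freedom convention is not reproduced.

## The synthetic super-child generator

`generate_children()` emulates the study structure, not any literal cohort:

* **Design.** Presets: the two-sample design (all children at 4 d plus one
  randomly assigned time among 6, 9, 12 h and 1, 2, 7, 11, 16, 22, 28 d;
  n = 120 and 135), the one-sample variant (n = 87, 40 children at 4 d, the
  rest spread evenly over the other ten times), and a recommended future
  design (60 children, 13 times from 5 h to 42 d anchored at 7 d; the exact
  schedule 0.208, 0.5, 1, 2, 4, 7, 10, 14, 18, 24, 30, 36, 42 d is this
  package's choice, since only the span and count are prescribed).
* **Between-child variability.** Which parameters vary between children, and
  by how much, is not documented for any real cohort; the defaults are a
  conservative geometric SD of 1.2 on `L(10,6)`, `L(5,6)` and `L(5,4)`
  (storage turnover, mobilisation, and hepatic secretion — the parameters
  that plausibly track vitamin A status), fully configurable. Body weight is
  normal with CV 0.12, plasma retinol log-normal with GSD 1.15, both typical
  anthropometric spreads for these ages.
* **Measurement.** Per-sample FDp is the child's own model curve times
  log-normal noise (SD 0.10 on the log scale by default); tracer
  concentration, plasma volume and pool size are kept mutually consistent
  (`FDp = c13·PV/dose`, `pool = retinol·PV`).
* **Plasma volume.** A linear-in-weight model whose coefficients are
  *required* configuration — the regression the field studies used is
  published only in supplementary material, so nothing is silently assumed.
  The group presets carry a back-solved proportional slope
  (`M(5)/(retinol·weight)`), an explicitly synthetic calibration that makes
  the mean child reproduce the group plasma pool.
* **Compositing.** `composite_children()` takes geometric means of actual
  times and FDp per slot, counts samples, assigns the FSD weights, and
  computes the group pool as the geometric mean over all samples —
  geometric-mean compositing is exactly unbiased on the log scale for
  log-normal noise, which the tests verify by Monte Carlo.

What the generator does **not** emulate: covariate effects (breastfeeding,
supplementation), assay physics, dropout or missingness beyond slot
assignment, and any real child's record. Passing recovery tests therefore
show that the estimator recovers the truth *under the model's own
assumptions with realistic sparsity and noise* — not that the model is
correct for real children.

## Numerical and design choices

* Time is days everywhere; `DT(8)` = 75 min is stored as 75/1440 d and
  displays as 0.052.
* The default curve grid is log-spaced over 0.01–40 d, matching how these
  curves are displayed.
* Closed systems (no irreversible loss) are detected and reported: the
  steady state flags infinite days of stores, and residence kinetics refuse
  the singular matrix with a clear error.
* `S(t)` is masked (`NA`) before tracer reaches the stores, where the
  specific-activity ratio is 0/0.
* Writers emit comma-separated UTF-8 text with `#` provenance headers
  (package version, seed) and 12 significant digits; under a fixed seed the
  whole pipeline is byte-reproducible, which the tests assert literally.

## Benchmark problem sizes

The test suite's simulation benchmarks use 20 replicates of the two-sample
design (n = 120 children) at 5% log-normal noise for parameter recovery —
median TBS error is required below 10% and every adjustable parameter's
median error below 15% — and 20 paired fits for the intake-datum
experiment. With the closed-form simulator each fit takes well under a
second, so the full suite runs in about half a minute on one core.

The intake-datum experiment deserves a note. On data generated by the model
itself, dropping the intake datum does not push TBS in one fixed direction:
the no-intake objective becomes bimodal, with a strongly deflated mode (the
fitted terminal slope steepens) and a mildly inflated one (the slope
flattens toward zero), and the noise realisation decides which wins. Both
behaviours are exactly the two directions reported for real cohorts. What
is systematic — and what the acceptance test asserts — is the coupling
(the TBS shift always opposes the terminal-slope shift) and the loss of
stability: the median TBS error grows several-fold once the datum is
dropped. This is the package's own reading of how that qualitative
real-data observation translates to a well-specified synthetic benchmark.

## Known limitations

* Group composites are treated as a single average child; no nonlinear
  mixed-effects model is offered, matching the analysis approach being
  implemented.
* The tracee solution assumes strict steady state; depletion or repletion
  trajectories are out of scope.
* Published parameter values are rounded to 3 significant figures, so
  table reproductions carry ≈1–2% slack by construction, and RID
  coefficients at 4 d about 3%.
* The fractional degrees-of-freedom and the original software's intake
  residual scaling conventions are not reproducible from the published
  description; the package documents its own conventions instead.
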