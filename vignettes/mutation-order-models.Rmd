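---
title: "Modeling order-of-mutation effects in MPN: bistable expression and a five-type Moran process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling order-of-mutation effects in MPN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutorder)
```

## The scientific problem

In myeloproliferative neoplasms (MPN), the JAK2 V617F and TET2 mutations
frequently co-occur, and patients can often be classified as *JAK2-first* or
*TET2-first* from the single-mutant cell types still present alongside the
double-mutants. Strikingly, the order matters: JAK2-first and TET2-first
patients differ in gene expression patterns, in the fraction of cells
carrying only the first mutation, and in age at diagnosis. A linear model of
gene regulation cannot produce such effects — if mutation effects on a
production rate add, they also commute. This package implements two minimal
mechanistic model families that do produce them:

1. **A bistable gene-expression ODE.** Expression of a gene X follows
   $\dot x = \lambda + f(x) - x$ with cubic autoregulation
   $f(x) = -(x-2)^3 + 2(x-2)$ and a production rate
   $\lambda = \lambda_0 + \lambda_J \mathbb 1_J + \lambda_T \mathbb 1_T$
   switched by the cell's mutations. For intermediate $\lambda$ the system
   is bistable; mutations that push $\lambda$ across a saddle-node threshold
   switch the branch, and the branch reached depends on the *path* of
   $\lambda$, i.e. on the mutation order (hysteresis).
2. **A generalized five-type Moran process.** A fixed population of $n$
   cells in states O, J, T, JT, TJ evolves by paired death/birth steps with
   per-type weights and per-birth mutation probabilities. The process is
   stopped at the first double-mutant; the single-mutant count and stopping
   time, conditioned on a pure JAK2-first or TET2-first outcome, model the
   clonal-composition and age-at-diagnosis contrasts.

## The bistable module

### Model and assumptions

Time is rescaled so degradation has unit rate; $x$ and $\lambda$ are
dimensionless. The cubic $f$ must have a negative leading coefficient (the
constructor enforces this), which caps the number of fixed points at three.
With the default cubic the drift $\lambda + f(x) - x$ has roots
$\{1, 2, 3\}$ at $\lambda = 2$ and saddle-node thresholds at
$\lambda = 2 \mp 2/(3\sqrt 3) \approx 1.615, 2.385$ (computed in closed form
from the critical points of $g(x) = x - f(x)$ by
`saddle_node_thresholds()`).

Mutations act only on $\lambda$, as discrete jumps at mutation events; the
epigenetic state supporting a given $\lambda$ is assumed to be inherited
across divisions, so a lineage accumulates rate changes. Relaxation between
mutation events is assumed complete (quasi-static continuation), which is
appropriate when mutations are separated by many cell generations.

### Numerical choices

* **Root finding.** `find_fixed_points()` uses the analytic cubic solver
  (`polyroot`) followed by three Newton polish steps; reported roots have
  drift residuals below $10^{-9}$ (property-tested). Roots closer than
  $10^{-7}$ are merged and flagged degenerate.
* **At-threshold convention.** Exactly at a saddle-node threshold the
  marginal (double) root counts as an existing branch and is labelled
  stable; a branch jump happens only strictly beyond the threshold. This
  keeps continuation continuous in $\lambda$.
* **Branch following.** `follow_branch()` implements basin-of-attraction
  logic exactly (in one dimension basins are intervals bounded by the
  unstable fixed point): no time stepping is involved, and the tests verify
  agreement with an independent RK4 integration of the ODE to $10^{-6}$.
  When the current level sits exactly on the unstable separatrix the low
  branch is chosen; this is a measure-zero tie-break that no preset
  exercises.
* **Initial branch.** The pre-mutation cell is placed on the stable fixed
  point reached by relaxing from $x = 0$ at the wild-type $\lambda$. This
  generalizes "the system starts on the low branch" to presets whose
  wild-type rate is monostable-high (e.g. the $\lambda_0 = 3.5$ preset,
  where relaxation from 0 correctly lands on the only, high, branch).
* **Potential.** $U(x) = -\int_0^x (\lambda + f(s) - s)\,ds$ with
  $U(0) = 0$; the constant is a pure convention.

### Scenario presets and classification

`scenario_preset()` ships the published regulation specs
($\lambda_0, \lambda_J, \lambda_T$): four gating scenarios
(fig2a–fig2d), two order-dependence scenarios (fig4a/fig4b) and the coupled
two-gene model (fig3) in which a bistable gene Y drives a linear gene X
($\dot x = 1 - \mathbb 1_J + y - x$, so $x^* = 1 - \mathbb 1_J + y^*$).
The coupled model encodes the regulatory hypothesis
JAK2 → PRMT5 → E2F1 → AURKB/MCM/TK1 with TET2 ⊣ PRMT5/E2F1: the role of Y is
played by E2F1 (and/or PRMT5), whose TET2-driven down-regulation cancels the
JAK2-driven up-regulation, inverting the sign of the JAK2 effect on X.

`classify_observation()` reports quantitative flags and a qualitative
pattern label. Two tolerances are deliberately distinct:

* `tol = 0.05` (one decimal, half a printed unit) decides *non-additivity*
  ($x^*_J - x^*_O \ne x^*_{TJ} - x^*_T$ or the symmetric condition) and
  *non-commutativity* ($x^*_{JT} \ne x^*_{TJ}$).
* `label_tol = 0.5` (about half the gap between the expression branches)
  decides the qualitative pattern, because the published patterns treat
  small same-branch shifts (0.6 vs 0.8) as "unchanged" while branch
  switches (0.8 vs 3.2) are "changed". A single 0.05 tolerance would
  misclassify the canonical gating scenarios.

## The Moran module

### Step semantics

One replacement step: a cell dies (type drawn with probability
$n_i d_i / \sum_j n_j d_j$) and another divides (type drawn with
probability proportional to $n_i b_i$); one daughter may mutate one step
along O→J→JT or O→T→TJ. Two readings of "another" are possible, and they
differ at order $1/n$:

* **exclusive** (package default, `birth_exclusive = TRUE`): the dying cell
  is removed before the birth draw, so birth weights use post-death counts;
* **independent**: the draws are independent and the same cell may die and
  divide.

Both are implemented throughout. The exclusive reading reproduces the
reference conditional statistics at $n = 100$ to two decimals in all twelve
entries, while the independent reading is off in the second decimal; the
acceptance tests therefore pin the exclusive reading.

Absorption is the first birth of a JT or TJ daughter. The death is applied
and the daughter added, then the outcome is classified on the post-step
counts: pure JAK2-first means $n_{JT} = 1, n_T = 0$ (record $n_J$), pure
TET2-first means $n_{TJ} = 1, n_J = 0$ (record $n_T$); outcomes with both
single-mutant types present are *ambiguous* — clinically the order could not
be inferred — and are excluded from conditional statistics (their mass is
reported). Time is counted in replacement steps, the initial state being
step 0 and the absorbing step included.

### Exact propagation

Before absorption only O, J, T cells exist, so the reachable space is
$\{(n_J, n_T): n_J + n_T \le n\}$ — $\binom{n+2}{2}$ configurations, 5151
for $n = 100$ (the count $101 \cdot 100/2 = 5050$ sometimes quoted for this
triangle omits the diagonal; the package enumerates all 5151, unreachable
states simply carrying zero mass). The one-step kernel restricted to this
space is assembled once as a sparse matrix and the probability vector is
pushed forward step by step; the mass entering each absorbing channel is
accumulated jointly with its class, post-step count and step index, so
conditional means and standard deviations of both the count and the time are
exact. Propagation stops when the survival probability satisfies
$S(t) < 10^{-8}$ *and* $t > 400$ (defaults), bounding the truncation error
of count expectations by about $n \times 10^{-8}$; a hard cap (default
$10^6$ steps) guards pathological parameter sets. Mass conservation
(absorbed + surviving = 1 to $10^{-10}$) and monotone $S(t)$ are
property-tested at every step.

The tests validate the propagation against two independent routes: an
exhaustive trajectory-tree expansion written from first principles (death
draw, then mother draw, then mutation outcome) for $n \le 4$, agreeing to
$10^{-8}$; and Monte-Carlo simulation (`simulate()` on the parameter
object), agreeing within three standard errors at $10^4$ pure replicates.

### Mechanism presets and what they state

`make_scenario()` ships the three mechanism presets (death coefficients all
1):

| mechanism | birth b | mutation m | interpretation |
|---|---|---|---|
| A | (1,2,4,4,4) | (.1,.1,.1,.1) | TET2-mutated cells proliferate faster |
| B | (1,2,2,2,2) | (.1,.2,.2,.1) | TET2 arises more readily than JAK2 |
| C | (1,2,2,2,2) | (.1,.1,.2,.1) | JAK2 raises the TET2 mutation rate |

These parameter values and the all-wild-type initial state at $n = 100$ are
the stated world of the acceptance suite; they are presets, not fitted
quantities. All three mechanisms produce the two observed order effects:
more TET2-only cells at absorption in TET2-first outcomes than JAK2-only
cells in JAK2-first outcomes, and earlier first double-mutants for
JAK2-first. `system_size_sweep()` shows the contrasts are insensitive to
$n$ beyond roughly 40–50 cells, and `required_sample_size()` (normal
approximation to the two-sample t-test, default $\alpha = 0.01$ two-sided,
power 0.80 — the power is this package's choice, exposed as an argument)
quantifies that mechanism B is resolvable with tens of patients while A and
C need a few hundred.

## What the tests do and do not establish

The deterministic module is exact arithmetic on polynomial roots; green
tests establish the printed steady-state tables follow from the stated
cubic and rate specs. The Moran acceptance tests establish that exact
propagation under the stated presets reproduces the reference conditional
statistics. Monte-Carlo agreement is a consistency check of the sampler
against the same kernel, not independent evidence about real hematopoiesis:
the model fixes total population size, ignores post-double-mutant expansion
and diagnosis delay, treats mutation probabilities as constant per birth,
and its time unit (replacement steps) maps to chronological age only up to
an unknown turnover rate.

## Known limitations

* No stochastic gene-expression (SDE / chemical master equation) variant;
  expression dynamics are deterministic between mutation events.
* No continuous-time Moran variant; statistics are per replacement step.
* `classify_observation()`'s qualitative label assumes a clear two-branch
  separation; tables from other cubics may need a different `label_tol`.
* Exact propagation scales as $O(n^2)$ states per step with a few thousand
  steps; it is comfortable at $n = 100$ but not intended for $n \gg 10^3$
  (use `simulate()` there).
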