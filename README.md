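# mutorder

Models for order-of-mutation effects in myeloproliferative neoplasms (MPN).

In patients carrying both the JAK2 V617F and a TET2 mutation, *which
mutation came first* affects gene expression, clonal composition and age at
diagnosis. `mutorder` implements the two minimal model families that explain
these effects, for modelers and quantitative biologists studying
order-dependent tumor evolution:

* **Bistable gene expression.** A single-gene ODE
  `dx/dt = λ + f(x) − x` with cubic autoregulation
  `f(x) = −(x−2)³ + 2(x−2)` and a mutation-controlled production rate
  `λ = λ₀ + λ_J·1_J + λ_T·1_T`. For `1.615 < λ < 2.385` the gene is
  bistable; mutation histories that cross a saddle-node threshold in
  different orders end on different branches (hysteresis), producing
  non-additive and non-commutative expression patterns. Includes fixed
  points with stability, closed-form thresholds, quasi-static branch
  following, scenario presets, a coupled two-gene (Y → X) variant and a
  classifier for the observed expression patterns.
* **Generalized five-type Moran process.** A fixed population of n cells in
  states {O, J, T, JT, TJ} with per-type birth/death weights and per-birth
  mutation probabilities, stopped at the first double-mutant. Provides the
  exact one-step kernel, Monte-Carlo simulation, exact transient probability
  propagation over all (n_J, n_T) configurations, conditional first-passage
  statistics (E and SD of the single-mutant count and the stopping time per
  JAK2-first / TET2-first outcome), system-size sweeps and t-test
  sample-size estimates.

## Worked example

```r
library(mutorder)

saddle_node_thresholds()
#> <bifurcation_thresholds> lambda_low = 1.615100, lambda_high = 2.384900

find_fixed_points(2)$x          # 1 2 3 (stable / unstable / stable)
follow_branch(c(2, 3, 2), 1)    # 3  : raise then restore lambda -> high branch
follow_branch(c(2, 1, 2), 1)    # 1  : lower then restore        -> low branch

# order-dependent expression, lambda = 2 + 1_J - 1_T
mutation_trajectory_steady_states(scenario_preset("fig4a"))
#> <expression_table>
#>      O      J      T     JT     TJ
#> 1.0000 3.3247 0.6753 3.0000 1.0000
```

JAK2-then-TET2 lineages end high (x* = 3), TET2-then-JAK2 lineages end low
(x* = 1): same final rate, different history.

```r
st <- absorption_statistics(propagate_exact(make_scenario("B", n = 100)))
st[, c("class", "mean_count", "sd_count", "mean_T", "sd_T")]
#>             class mean_count sd_count   mean_T      sd_T
#> 1 JAK2_first_pure   2.338669 1.650871 11.45707  7.816162
#> 2 TET2_first_pure   6.491687 5.088093 24.68371 17.797979
```

Under mechanism B (TET2 mutates more readily), a pure TET2-first patient
shows ~6.5 TET2-only cells when the first double-mutant appears versus ~2.3
JAK2-only cells for JAK2-first, and the first double-mutant arrives much
earlier for JAK2-first (11.5 vs 24.7 replacement steps) — matching the two
clinical order effects. `required_sample_size(2.34, 1.65, 6.49, 5.09)`
says ~20 patients per group resolve this contrast at p = 0.01.

## Command line

```sh
inst/cli/mutorder bifurcation --lambda-min 0 --lambda-max 4 --step 0.01 --out diagram.csv
inst/cli/mutorder scenario --preset fig2a --out table.csv
inst/cli/mutorder moran-exact --scenario B --n 100 --out stats.csv
inst/cli/mutorder moran-simulate --scenario B --n 100 --replicates 10000 --seed 42 --out records.csv
inst/cli/mutorder moran-sweep --scenario B --sizes 50,75,100
inst/cli/mutorder reproduce-paper --out-dir reports
```

All subcommands accept `--config <file.json>` (see `?load_config` for the
schema), `--seed`, and `--format csv|json`.

## Documentation

The methods vignette (`vignettes/mutation-order-models.Rmd`) describes the
models, assumptions, numerical conventions (at-threshold behavior, stopping
rule, step semantics) and limitations.
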