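# vstriage

Evaluation machinery for benchmarks of binding-free-energy (BFE)
predictors used in virtual screening (VS) triage.

When a predictor — alchemical free-energy calculation, end-state
method, or a machine-learning scorer — is asked to rescore a docking
hit list, the practically relevant question is not a ROC curve but:
*of the n compounds the predictor designates as positives, how many
are truly active, and could random selection have done as well?*
`vstriage` answers this with the exact hypergeometric law and projects
benchmark results onto realistic campaign scales; around that core it
provides the standard companion analyses: accuracy statistics on
experimental/calculated ΔG pairs, a lead-likeness curation funnel,
Butina diversity clustering, per-complex structural descriptors, and
kernel-density summaries of active/decoy score separation — plus
seeded synthetic-data generators so everything is testable offline.

## The core model

Drawing `n` designated positives from a pool of `N_tot` compounds
containing `N_pos` actives, the number `k` of actives recovered under
random selection follows

    P(k) = C(N_pos, k) * C(N_tot - N_pos, n - k) / C(N_tot, n)

The package reports, for an observed hit count `k_obs`:

* the upper tail `P(X >= k_obs)` — the significance of the observed
  enrichment (the probability random selection does at least as
  well);
* the mass `P(k_obs)` and the maximum mass over the support — the
  yardstick for TPRs near the random expectation `N_pos / N_tot`;
* the projection onto a scaled scenario `(N2, K2, n2)`: the smallest
  `k2` whose scaled upper tail does not exceed the benchmark upper
  tail, capped at `K2`.  This translates, say, 59 true positives
  among 63 designated on a 307-compound benchmark pool into the
  number of actives a 100-compound hit list would capture out of
  1,000 rescored docking hits containing 10 actives.

All binomial coefficients are evaluated in log space, so pools of
10^4+ compounds are unproblematic.

## Worked example

```r
library(vstriage)

# a synthetic 9-target screen: 15 actives + 20 decoys per target,
# strong active/decoy separation
tab <- simulate_screen_scores(screen_sim_spec(seed = 7))
enrichment_report(tab, per_target_n = 7,
                  scaled = scaled_scenario(1000, 10, 100))
#> Enrichment over 9 target(s)
#>   pooled: k = 58 of n = 63 (TPR 92%), pool 315/135
#>   P(X >= k) = 7.59e-20   pmf(k) = 7.31e-20   max pmf = 0.113
#>   random expectation = 43%
#>   projected recovery at scale (1000, 10, 100): 10 actives
```

Reading: the top-7 selections over nine targets recovered 58 of 63
possible actives (TPR 92%) from a pool of 315 scored ligands of which
135 are active.  The chance of random selection doing at least as
well is ~8×10⁻²⁰; the largest probability any hit count has under
chance is 11%, and a random draw would average a 43% TPR.  Projected
to a realistic campaign (100 picks from 1,000 rescored hits holding
10 actives), this level of enrichment captures all 10 actives.

Direct use of the statistics:

```r
hypergeom_upper_tail(51, 307, 135, 63)   # 2.1e-11
round(100 * max_pmf(307, 135, 63))       # 11
bench <- hypergeom_setup(307, 135, 63, k_observed = 59)
extrapolate_recovered_actives(bench, scaled_scenario(1000, 10, 100))
#> 10
```

Accuracy metrics on simulated exp/calc pairs with a planted Pearson
correlation of 0.69 (632 pairs):

```r
pairs <- simulate_accuracy_pairs(accuracy_sim_spec(seed = 7))
dg_accuracy(pairs)
#> r = 0.696, rho = 0.705, RMSE = 1.85 kcal/mol, n = 632
```

Curation funnel and clustering:

```r
fx <- fixture_molecules()
props <- compute_properties(fx$smiles, ids = fx$ligand_id)
apply_filter_pipeline(props)      # per-stage counts + per-rule tallies
fp <- morgan_fingerprints(fx$smiles, ids = fx$ligand_id)
butina_cluster(fp, similarity_threshold = 0.5)
```

A thin command-line wrapper over the same functions ships under
`inst/cli/vstriage` (subcommands `enrich`, `extrapolate`, `accuracy`,
`filter`, `cluster`, `descriptors`, `separation`, `simulate`).

## Package layout

* `R/hypergeom.R`, `R/screen.R` — exact enrichment statistics, top-n
  selection, pooling, scale extrapolation
* `R/accuracy.R` — ΔG accuracy metrics, stratified splits, pose
  sensitivity
* `R/filters.R`, `R/molgraph.R` — property computation and the
  curation funnel (SMARTS rule tables under `inst/extdata/`)
* `R/fingerprints.R`, `R/butina.R` — circular fingerprints and
  sphere-exclusion clustering
* `R/descriptors.R` — PDB parsing, burial, pocket lipophilicity,
  metal flagging
* `R/kde.R` — score-density estimation and overlap
* `R/simulate.R` — seeded generators with built-in oracles
* `R/io.R` — score-table readers and self-describing JSON reports
* `vignettes/vstriage-methods.Rmd` — the model, conventions and
  design choices in detail
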