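---
title: "Evaluating binding-free-energy predictors for virtual screening triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating binding-free-energy predictors for virtual screening triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vstriage)
```

## The problem

A virtual screening (VS) triage step rescoring a docking hit list must
answer two questions about a binding-free-energy (BFE) predictor.
First, how accurately does it reproduce experimental affinities on
complexes where the answer is known?  Second — and closer to practice —
if the predictor designates a short hit list, how many of the truly
active compounds does that list capture, and how does that compare to
chance?  `vstriage` implements the evaluation machinery for both
questions: accuracy statistics on experimental/calculated
$\Delta G$ pairs, exact hypergeometric enrichment statistics on
active/decoy score tables, a lead-likeness curation funnel for
assembling benchmark sets, structural descriptors for stratified error
analysis, and seeded generators that make the whole pipeline testable
without any external download.

ROC-AUC-style classification summaries are deliberately not part of
the package.  Benchmark panels are small (tens of compounds per
target) and have an artificially high active fraction, so
threshold-free classification metrics misrepresent the practical
setting, where a laboratory tests a fixed-size hit list drawn from a
pool in which actives are rare.  The package instead works directly
with the distribution of the hit count.

## The exact enrichment model

Consider a pool of $N_{tot}$ scored compounds containing $N_{pos}$
true actives, from which the predictor's top-ranked $n$ compounds are
designated positives.  Under uniform random selection the number $k$
of actives among the $n$ designated positives follows the
hypergeometric law

$$P(k) = \frac{\binom{N_{pos}}{k}\binom{N_{tot}-N_{pos}}{n-k}}
              {\binom{N_{tot}}{n}}.$$

Three quantities are reported for an observed hit count $k_{obs}$:

* **Upper tail** $P(X \ge k_{obs})$ — the probability that random
  selection would do at least as well.  This is the significance
  measure attached to an observed result (`hypergeom_upper_tail()`).
* **Mass at the observed count** $P(k_{obs})$ and the **maximum mass**
  $\max_k P(k)$ (`hypergeom_pmf()`, `max_pmf()`).  The maximum is the
  largest probability any single outcome can have under chance, a
  useful yardstick when an observed true-positive rate (TPR) sits
  near the random expectation $N_{pos}/N_{tot}$.
* **Random expectation** $N_{pos}/N_{tot}$, the expected TPR of a
  uniform draw (`random_expectation()`).

Reporting the upper tail as the significance of an observed count —
rather than the point mass — is a deliberate design choice: the point
mass of a composite "at least this good" result understates the
evidence, and the tail is the quantity that extrapolates cleanly (see
below).  Both are returned, so nothing is hidden.

The pooled population counts are always **explicit caller inputs**
(`pool_targets()`).  Evaluated pools are routinely smaller than
nominal datasets because some ligands fail upstream of scoring;
inferring $N_{tot}$ from a nominal design invites silent mistakes, so
the default simply counts the rows actually present in the score
table.

### Top-$n$ selection

`select_top_n()` designates the $n$ lowest (most negative) predicted
free energies as positives.  Ties on the score are broken by ascending
ligand id: deterministic and independent of input order.  A
`higher_is_better` flag inverts the direction for scores that are not
free energies.

### Projection to screening-campaign scale

A benchmark of a few hundred compounds says little directly about a
campaign rescoring 1,000 docking hits that contain perhaps 10 actives
(a realistic active rate for a primary docking screen) to pick 100
compounds for testing.  `extrapolate_recovered_actives()` projects a
benchmark result onto such a scaled scenario $(N_2, K_2, n_2)$ by
matching cumulative probabilities: the projected recovery is the
smallest $k_2 \in [0, K_2]$ with

$$P(X \ge k_2 \mid N_2, K_2, n_2) \le P(X \ge k_{obs} \mid
  N_{tot}, N_{pos}, n).$$

When even $k_2 = K_2$ retains a larger tail than the benchmark — the
benchmark evidence is stronger than anything the scaled scenario can
express — the projection is capped at full recovery.  "Smallest
$k_2$ with tail at or below the benchmark tail" is one of several ways
to operationalise "matching"; it was fixed because it is monotone in
$k_{obs}$, exact, and free of interpolation choices.

The inverse question — the smallest hit-list size $n_2$ whose
probability of capturing *all* $K_2$ actives reaches the benchmark
tail — is answered by `min_hitlist_full_recovery()`.  The answer is
sensitive to the matching convention in a way the forward projection
is not, so reports should treat it as rule-dependent; the
documentation of the function says so explicitly.

### Numerical choices

Binomial coefficients are evaluated in log space as sums of $O(1)$
log-ratios rather than via the log-gamma function: this keeps the
absolute error of $\log\binom{n}{k}$ near $10^{-14}$ even for
populations in the thousands (log-gamma differencing loses about
$10^{-12}$ there), at a cost that is irrelevant at these sizes.  Tails
are accumulated from the small end of the summand range to limit
cancellation, and the mass is exactly zero outside the support.  The
extrapolation comparison switches to the complementary lower tail
when the benchmark tail exceeds $1/2$ — mathematically the identical
rule, but it preserves resolution where the upper tail saturates at 1
in double precision.  The test suite pins the mass function to
exhaustive enumeration of all $\binom{N}{n}$ draws for small $N$, to
the reference distribution functions in base R, and to normalization
and symmetry identities across random setups.

## Accuracy metrics

`dg_accuracy()` reports Pearson $r$, Spearman $\rho$ (average ranks on
ties) and RMSE on $(\Delta G_{exp}, \Delta G_{calc})$ pairs in
kcal/mol.  Correlations on degenerate (zero-variance) input are an
error, never a silent zero.  Experimental dissociation or inhibition
constants convert through the standard-state relation
$\Delta G = RT \ln(K_d / 1\,\mathrm{M})$ with $T = 298$ K by default
($R = 1.98720 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$); $K_i$ is
treated identically to $K_d$, and both the temperature and the choice
to correlate on $\Delta G$ rather than p$K$ are configurable package
conventions.

Stratified views:

* `intratarget_correlations()` computes per-target metrics only for
  targets with at least 10 ligands (configurable) — below that,
  correlation estimates are mostly noise.
* `median_split_analysis()` splits at the median of any numeric
  descriptor; ties at the median go to the low subset so the split is
  deterministic and exhaustive.
* `affinity_half_split_rmse()` compares RMSE between the tighter- and
  weaker-binding halves, ranking by experimental $\Delta G$ (most
  negative = tightest); an odd count puts the middle pair in the top
  half.
* `pose_divergence_analysis()` flags docking poses diverging from the
  crystal pose by RMSD strictly greater than 3 Å and prediction
  shifts strictly greater than 2 kcal/mol, and counts how many
  significant shifts weaken the predicted affinity.  Strict
  inequalities are used because the thresholds are phrased as
  "greater than"; a value exactly at a threshold is unflagged.

## The curation funnel

Benchmark sets for hit finding should contain lead-like ligands.
`apply_filter_pipeline()` applies three stages in order, with per-rule
rejection accounting:

1. **Affinity records** (`affinity_record_filter()`): keep only
   measurements typed $K_d$ or $K_i$ with an exact (`=`) relation.
   IC50 values depend on assay conditions and censored relations
   carry no usable magnitude.
2. **Amended Lipinski ranges** (`lipinski_amended_filter()`):
   molecular weight 250–600 Da (inclusive; the classical 500 Da cap
   is raised and a lower bound added to exclude fragments), cLogP
   1–5 (inclusive), H-bond donors ≤ 5, acceptors ≤ 10, rotatable
   bonds strictly < 14.
3. **Structural rules** (`structural_filter()`): no phosphorus atoms,
   at most 2 ionizable groups, at least one ring, no run of 7 or more
   consecutive acyclic sp3 carbons, no fused system of 4 or more
   rings, no reactive/toxic alerts.

The survivor set is a pure conjunction of the rules, so it is
independent of stage order; the staging only attributes rejections.
Several thresholds here are genuinely open conventions, fixed as
follows and all configurable:

* **Ionizable cap**: 2 by default.  A cap of 1 is an equally
  defensible reading of "multiply ionizable compounds are poor
  leads"; the default follows the more permissive convention and the
  documentation points out the alternative.
* **Ionizable definition**: a shipped SMARTS table
  (`inst/extdata/ionizable_groups.smarts`) covering carboxylic,
  sulfonic and phosphonic acids, acidic tetrazoles, basic aliphatic
  amines (excluding amides and anilines), amidines and guanidines.
* **"Long aliphatic chain"**: ≥ 7 consecutive acyclic sp3 carbons,
  computed on the heavy-atom graph (the induced subgraph of such
  carbons is a forest, so the longest run is a tree diameter).
* **"Large fused-ring system"**: ≥ 4 rings sharing bonds, measured as
  the cyclomatic number of the largest connected component of the
  ring-bond subgraph (ring bonds are the non-bridge edges).
* **Reactive alerts**: a versioned SMARTS file
  (`inst/extdata/reactive_alerts.smarts`) listing acyl and sulfonyl
  halides, aldehydes, Michael acceptors, vinyl sulfones, epoxides,
  aziridines, isocyanates, anhydrides, sp3 alkyl halides, nitroso and
  peroxide groups.  Users can ship their own file of the same shape.

MW, cLogP, HBD and HBA follow the conventions of the OpenBabel
backend (through ChemmineR/ChemmineOB); because these definitions
differ between toolkits, the property table records the backend in an
attribute.  Survivor counts on any real corpus will depend on these
conventions, on the alert list, and on upstream attrition outside the
filters' control — the package therefore treats funnel counts on
external corpora as data-dependent observations, not test anchors.

## Diversity clustering

`butina_cluster()` implements sphere-exclusion (Butina) clustering on
a Tanimoto similarity matrix at an inclusion threshold of 0.5 by
default: molecules are ranked by neighbour count at the threshold
(ties by input order), the best-connected unassigned molecule becomes
a centroid and claims its unassigned neighbours, and the sweep repeats
until the input is partitioned.  Every non-centroid member is within
the threshold of its centroid by construction.  The algorithm is
implemented in the package rather than delegated, because the
centroid-selection and tie rules are exactly what determines the
partition; tests verify the partition property, the sphere criterion
and permutation invariance.

Fingerprints are circular (Morgan-style, radius 2, folded to 2048
bits — the ECFP4-class setup), computed in-package on the heavy-atom
graph with an element/degree/bond-order/ring-flag initial invariant.
The bit assignments are not interchangeable with any other toolkit's
ECFP4 bits — folded-bit identities never are across implementations —
but Tanimoto similarities behave equivalently for clustering, and any
external 0/1 fingerprint matrix or precomputed similarity matrix can
be passed in directly.

## Structural descriptors

For stratified error analysis, `descriptor_table()` computes per
complex: protein and ligand mass from the atoms present (no modelling
of unresolved residues), ligand burial, pocket lipophilicity and a
metal-site flag.  Hydrogens are ignored throughout because deposited
structures are inconsistent about them.

* **Burial** (`burial_descriptor()`): the median over ligand heavy
  atoms of the number of protein heavy atoms within 4.5 Å — a common
  heavy-atom contact convention; the cutoff is configurable and
  recorded in the output.
* **Pocket lipophilicity** (`pocket_mean_clogp()`): the unweighted
  mean of a per-residue lipophilicity value over residues with any
  heavy atom within 5.0 Å of the ligand.  Residue-level "cLogP" has
  no canonical definition, so the shipped table is the
  Fauchère–Pliška side-chain analog logP scale
  (`inst/extdata/residue_logp.csv`); any named residue table can be
  substituted.  Metal species carry no residue lipophilicity and are
  excluded from the average.
* **Metal flag** (`detect_metal_site()`): true if any atom of a
  configurable metal list (Zn, Fe, Mg, Mn, Ca, Cu, Ni, Co, Na, K)
  lies within 5.0 Å of the ligand.  Metalloprotein sites are poorly
  served by standard force fields, so flagged complexes are usually
  excluded from physics-based benchmarks.

## Score-distribution summaries

`separation_report()` estimates Gaussian kernel densities of active
and decoy scores (Silverman's rule bandwidth by default — the
estimator is a package convention, chosen as the minimal defensible
default, and both kernel bandwidth and grid are configurable) and
reports the overlap coefficient $\int \min(f_a, f_d)$ together with
the pooled top-$n$ TPR from the same table, so the qualitative
density picture and the quantitative enrichment number always refer
to the same data.  The overlap is reported as a descriptive scalar
only; no decision rule is built on it.

## Synthetic data: what it does and does not emulate

The generators exist so that every stage has an exact or statistical
oracle without any download.

* `simulate_screen_scores()` emulates the shape of a small
  discrimination benchmark: 9 targets × (15 actives + 20 decoys),
  Gaussian scores with a method-tunable mean separation.  Defaults
  put actives 3 kcal/mol below decoys at a common SD of 1.8 kcal/mol
  (a strong, alchemical-grade separation); `screen_sim_presets()`
  names weaker regimes (`endstate_like`, `ml_like`).  These presets
  target qualitative TPR regimes only and make no claim to reproduce
  any particular predictor's numbers.
* `simulate_accuracy_pairs()` draws experimental $\Delta G$ uniformly
  on $[-14, -5]$ kcal/mol (the realistic lead-like affinity window)
  and adds an affine response with Gaussian noise, with the slope
  solved from the noise SD so the population Pearson correlation
  equals the requested value exactly:
  $a = (\sigma_{noise}/\sigma_{exp})\, r/\sqrt{1-r^2}$.
* `simulate_complex_geometry()` plants per-ligand-atom contact
  counts, pocket residues, metals and waters at known distances, so
  the structural descriptors have a constructed oracle.
* `fixture_molecules()` ships a curated SMILES set in which each
  violator breaks exactly one curation rule.

Real screening data are not Gaussian-per-role with a common SD: score
distributions have heavy tails, per-target offsets, and errors
correlated within chemical series.  Passing the statistical tests
therefore demonstrates that the *evaluation machinery* is correct and
calibrated (e.g. that zero separation reproduces the random
expectation $15/35$), not that any predictor behaves like the
generator.  All generators are pure functions of their spec and seed,
restore the caller's RNG state, and produce tables that pass the
consuming modules' validation.

## Problem sizes in the test suite

The statistical tests use 632 pairs × 100 seeds for correlation
recovery and 2,000 replicates of the 315-record screen for the
null-enrichment check — sizes chosen so that three standard errors of
the checked means are well inside the asserted tolerances while the
whole suite stays fast on a single CPU.  The exact-arithmetic checks
(enumeration oracles, planted geometries, hand-built similarity
matrices) are independent of these sizes.

## Known limitations

* Funnel survivor counts and cluster counts on external corpora
  (PDBbind-scale inputs) depend on toolkit property conventions and
  on the configurable SMARTS sets; the package reports its
  conventions but cannot reproduce counts produced under unstated
  ones.
* The inverse hit-list size is matching-rule-dependent (see above)
  and is labelled as such in reports.
* Significance statements assume the designated-positive count $n$ is
  known; when only a TPR is reported for a method, reconstructing
  $k = \mathrm{round}(\mathrm{TPR} \times n)$ inherits the rounding
  of the report.
* The PDB reader targets single-complex files with the ligand as a
  named HETATM residue; mmCIF and multi-model files are out of scope.
* Docking-pose RMSD computation (with symmetry correction) is out of
  scope; `pose_divergence_analysis()` consumes RMSD values computed
  elsewhere.
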