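---
title: "Designing, clustering, and greedily accumulating stabilizing mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, clustering, and greedily accumulating stabilizing mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabmut)
```

## The problem and the strategy

Single-point stability predictors are individually weak: energy-function
methods (FoldX, Rosetta) suffer from force-field error and shallow
conformational sampling, statistical methods (ABACUS) from uneven structure
databases. But their errors are only partly correlated, so a *union* of
thresholded predictions collects more genuinely stabilizing mutations than
any single method — at the cost of precision, which is acceptable when the
library will be validated experimentally. The second difficulty is epistasis:
measured single-mutant ΔTm values do not add, so naive "combine everything
that helped" designs frequently fail. The workflow implemented here addresses
both: a threshold-consensus library feeds experimental validation; validated
mutations are clustered into independent tracks; and combinations are built
*measurement by measurement* with a greedy rule, so that a deleterious
interaction is discovered and avoided at the cost of one experiment rather
than baked into a large multi-mutant.

The package implements this as composable stages — `read_pdb()` /
`select_chain()` / `enumerate_candidate_mutations()`, scorers plus
`apply_thresholds()` / `merge_libraries()` / `consensus_design()`,
`feature_table()`, `cluster_mutations()`, `greedy_accumulate()` /
`plan_experiment()` / `combine_cluster_winners()` — with
`run_design_stage()` and `run_full_demo()` tying them together.

## Structures and mutant models

Structures are reduced at parse time to heavy atoms of standard amino acids:
waters, ligands, hydrogens, and non-primary alternate locations are dropped,
because every geometric feature below is defined on heavy atoms (a
deliberate choice that also makes features independent of whether the
input was protonated). Residue identity is (chain, author number, insertion
code) end to end, so mutation names match the user's PDB numbering. The
first model of a multi-model file is used (or refused, under
`model_policy = "error"`).

Mutant models are deliberately naive: the replaced side chain is a template
of the most common rotamer, constructed by internal coordinates directly off
the residue's actual N–CA–C frame, with no repacking or minimization.
Production campaigns delegate model building to the scoring programs
themselves; what the package needs internally is a *deterministic, testable*
geometry for feature deltas, and a template rotamer supplies exactly that.
The proline ring closes only approximately under this scheme, which is
inconsequential here because no feature infers bonds from side-chain ring
geometry.

## Library design

`threshold_config()` defaults to the operating points −1.5 kcal/mol (FoldX),
−1.0 REU (Rosetta), −2.5 AEU (ABACUS). Selection is **score ≤ threshold,
boundary inclusive**: thresholds are phrased as cutoff levels, ties in
floating-point scores are rare, and inclusivity is the conservative,
library-enriching reading. A mutation enters the merged library when *any
one* algorithm selects it; requiring agreement would discard exactly the
complementary, method-exclusive hits the union exists to capture
(`exclusivity_report()` quantifies that complementarity). Tightening any
threshold can only shrink the selection — a monotonicity property the test
suite exercises on a thousand random score sets.

`consensus_design()` adds sequence-derived candidates: a back-to-consensus
substitution is proposed where an alignment column's modal residue differs
from the target, with frequency ≥ 0.6 over non-gap symbols and ≥ 10 informative
sequences. These defaults are conventional consensus-design practice (the
frequency gate keeps weakly conserved columns out; the depth gate keeps
thin alignments from voting); both are arguments, not constants. Columns
where the target row is gapped are never proposed — this is substitution
design, not insertion design.

External predictors integrate as score tables (`read_predictions()`) in a
shared convention — more negative = more stabilizing — rather than as
subprocess wrappers, keeping the package fully offline. Two built-ins
(`scorer_planted()`, `scorer_contact()`) let the entire pipeline run without
any external program.

## The feature vector

Each validated mutation gets nine columns: name, residue index, measured
ΔTm, ΔHbond, ΔHydrophobic, an entropy flag, and the wild-type Cα
coordinates. The geometric criteria are package decisions, chosen to be
standard, hydrogen-placement-free, and configurable:

* **Hydrogen bond**: N/O donor and N/O acceptor heavy atoms (by residue
  chemistry; the proline backbone N, having no amide hydrogen, never
  donates) within 3.5 Å, with antecedent–donor–acceptor angle ≥ 90°.
  Intra-residue pairs and the amide-N/carbonyl-O pair of one peptide unit
  are excluded.
* **Hydrophobic contact**: side-chain carbon pairs ≤ 5.0 Å between residues
  of {A, V, L, I, M, F, W, P, Y} separated by ≥ 2 in author numbering.
* **Entropy flag**: 1 when either side of the substitution is Gly or Pro —
  the canonical backbone-conformational-entropy effects (flexibility
  removed/introduced) — else 0. This is the one deliberately coarse feature:
  it is a deterministic 0/1, not an energy.

Δ-counts are mutant minus wild type, restricted to residues within 8.0 Å of
the mutated residue so that distant structural noise cannot contaminate a
local feature. All geometric features are isometry-invariant and are checked
exactly against an independent O(n²) brute-force pair scan in the tests,
which licenses replacing the implementation with a neighbor-grid version
later without touching the contract.

## Clustering

Features are z-scored per column (zero-spread columns map to 0), the binary
entropy flag passes through unscaled, and the three coordinate columns share
a single `coordinate_weight` multiplier (default 1; 0 removes spatial
structure entirely). Clustering is k-means with 20 restarts; when `k = "auto"`
the mean silhouette width over k ∈ 2..min(8, n−1) decides, ties toward
smaller k because every extra cluster is an extra parallel experimental
track. The number of clusters is thus an *outcome*, not a constant: on the
demo data below it varies with the seed. Labels are reported 0-based.

## Greedy accumulation and its cost

`greedy_accumulate()` is steepest ascent over measured values: each round
measures every one-mutation extension of the current variant and accepts the
best only if it beats the current measurement by `min_improvement`, default
1.5 °C — the same bar that defines a stabilizing single mutant, reused as the
combination acceptance criterion since no separate tolerance is established
for combination steps. A candidate that measures worse in combination is
simply never accepted; there is no backtracking or removal of accepted
mutations. For k candidates the search needs at most k(k+1)/2 measurements.
`plan_experiment()` is the same logic inverted for the wet lab: given the
measurements so far it emits the next round's variants, so the loop can run
with a spreadsheet instead of a callback.

`combine_cluster_winners()` is the optional final stage: measure the union
of cluster endpoints, then greedily re-check cross-cluster additions on top
of the best endpoint under the same bar. Two clusters proposing different
substitutions at one residue is a hard conflict (reported, not resolved);
the demo resolves such collisions beforehand by keeping the better single.

## The synthetic landscape: what it emulates and what it does not

`simulate_landscape()` stands in for wet-lab ΔTm measurements:
ΔTm(S) = Σ aₘ + Σ e₍ₘₙ₎ + ε, with additive effects aₘ, pairwise epistasis
e₍ₘₙ₎ ~ N(0, epistasis_sd) on a random fraction of pairs (default 0.3, a
mild-epistasis regime), and i.i.d. Gaussian noise ε per evaluation (each
requested measurement is a fresh single replicate). `brute_force_best()`
enumerates all subsets noise-free and is the oracle for regret statistics
(`greedy_benchmark()`).

The demo (`run_full_demo()`) draws a 36-residue helix, plants 14 truly
stabilizing mutations (aₘ ~ N(2.5, 1.0) °C, distinct positions) among
neutral-to-destabilizing background effects (N(−2.0, 1.5) °C), emulates the
three predictors as noisy negatively-scaled readouts of aₘ on their native
scales, and measures with 0.5 °C noise — sizes chosen to mirror a realistic
small campaign (tens of validated singles, a final variant in the tens of
°C) while keeping the full run in seconds. What the landscape does *not*
model: higher-than-pairwise epistasis, measurement drift between rounds,
expression/solubility failures, and any coupling between a mutation's
predictor score and its epistatic behavior. Passing tests on this generator
therefore demonstrate the machinery's correctness and the greedy strategy's
behavior under additive-plus-pairwise assumptions — not predictor accuracy
on real proteins.

## Benchmarking metrics

`benchmark_report()` computes sensitivity, specificity, precision, accuracy,
and F1 per algorithm at its threshold, plus a `union` row under the
any-algorithm ensemble rule. Conventions: experimental stabilization is
ΔΔG ≤ 0 (the benchmark convention; configurable) or ΔTm ≥ 1.5 °C, boundary
inclusive on both the experimental and score sides; undefined ratios (0/0)
are `NA`, never 0, so they cannot silently deflate averages; F1 is computed
as 2tp/(2tp+fp+fn), which equals the harmonic mean of precision and
sensitivity wherever that is defined and extends it to 0 when tp = 0 with
errors present. A published reference benchmark of six predictors on a
350-mutant ProTherm-derived set ships in `extdata` for verifying the F1
identity.

## Numerical and degenerate-input choices

* Toy helices use a 1.5 Å rise and 100°/residue at radius 2.28 Å, making
  consecutive Cα distances 3.80 Å; strands 3.3 Å rise, 180°/residue.
* PDB round-trips are exact at the format's 3-decimal coordinate precision.
* Zero-spread feature columns standardize to 0 rather than dividing by zero;
  silhouette is reported `NA` outside 2 ≤ k ≤ n−1.
* Auto-k silhouette ties break toward smaller k; `which.max` order makes
  this deterministic.
* A scorer failure on one mutation records a missing score (never selected)
  and a run-log entry instead of aborting the scan.
* All stochastic operations take explicit seeds and restore the caller's RNG
  state; the demo is byte-identical across reruns of one seed.

## Known limitations

* Template side chains ignore real rotamer preferences and local packing, so
  absolute contact/H-bond counts are crude; only *differences* near the
  mutation site are used, and only as clustering features, never as energies.
* The H-bond criterion has no energy term and treats all N/O pairs equally;
  salt bridges, π-stacking, and solvation terms are out of scope.
* k-means with Euclidean distance is the minimal faithful reading of
  "cluster the feature vectors"; density-based alternatives would slot in
  behind the same `cluster_assignment` contract.
* Greedy accumulation cannot escape a local optimum that requires accepting
  a temporarily worse intermediate; `greedy_benchmark()` exists precisely to
  quantify that forfeit under chosen epistasis regimes.

```{r demo, eval = FALSE}
summ <- run_full_demo(seed = 0, out_dir = tempfile())
summ$k_clusters      # cluster count is data-driven, not fixed
summ$final_delta_tm  # never below best_single_delta_tm
```
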