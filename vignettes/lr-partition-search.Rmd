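---
title: "Fine population structure by likelihood-ratio partition search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine population structure by likelihood-ratio partition search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrstructure)
```

## The model

`lrstructure` assigns `N` individuals to `K` subgroups so that the allele
counts of the subgroups are as different as possible. At one polymorphic
locus with `n` allele states, cross-tabulating allele calls by group gives a
`K x n` contingency table `O`. Writing `E[k, i] = rowsum_k * colsum_i /
grand` for the expected counts under independence of allele and group, the
per-locus statistic is

    LR = sum_{k,i} O[k, i] * log(O[k, i] / E[k, i])

in natural-log units (nats); `2 * LR` is the classical G-statistic of the
table, and `LR = 0` exactly when every group has the same allele
frequencies. For `S` mutually independent loci the objective is the sum of
the per-locus values, and the inferred structure is

    Z_best = argmax_Z LR(X | Z)

over all assignments `Z` of individuals to `1..K`. The statistic measures
how strongly the classification of allele calls by allele state depends on
the classification by subgroup, which is exactly what allele-frequency
differentiation between subpopulations produces. Unlike a delta-allele-
frequency objective (`objective_daf()`, defined only for `K = 2`) it extends
to any `K` and any number of alleles per locus, and on simulated data it
discriminates groups more reliably than a Hudson-type Fst objective
(`objective_fst()`), both of which are included for comparison.

Because the objective sums over loci as if they were independent, linked
loci overweight their shared signal. `ld_prune()` therefore applies greedy
windowed pruning on the squared dosage correlation (defaults `r2_max = 0.2`,
`window = 50`, `step = 5`, the usual array-data settings) before analysis.

### Missing data and counting conventions

The counting unit is the individual allele call, two per diploid individual
and locus; a half-called genotype such as `1/.` contributes its one observed
call. Cells with `O = 0` contribute `0 * log 0 := 0`, so the statistic is
finite for any table, and a table with an empty group row equals the same
table with that row removed — empty groups are legal intermediate (and
final) states of the search.

## The search

Exhaustive enumeration of `K^N` assignments is feasible only for tiny `N`
(it is used as the test oracle below `N = 10`). The search instead runs
simulated annealing with single-individual Gibbs updates: pick an individual
`r` uniformly at random, evaluate the objective for each candidate label
`C`, and redraw the label from

    p(z_r = C) ∝ exp( LR(X | z_r = C) / T )

with the softmax evaluated after subtracting the largest candidate value for
numerical stability. This is the stationary update of a Boltzmann chain with
energy `-LR` at temperature `T`; as `T -> 0` it degenerates to hill
climbing, and as `T -> infinity` to uniform relabeling. A move changes only
the two affected rows of each locus table, and column/grand totals never
change, so one update costs `O(S * ploidy * K)` via incremental deltas
(`delta_lr_move()`), not a full rebuild. All `x log x` terms come from an
integer-indexed lookup table in the compiled core.

Choices not fixed by the update rule itself, and this package's defaults:

* **Temperature ladder** — geometric, `T_i = T0 * alpha^i` with one
  temperature per epoch of `N` updates, `alpha = 0.95`, 200 epochs.
  `T0 = "auto"` sets `max(1, LR(initial)/N)` so the first epochs accept
  nearly everything on any data scale.
* **Refinement** — up to 50 greedy passes after the ladder; each individual
  moves to its best label only for a strictly positive gain (> 1e-10 nats),
  ties keep the current label and otherwise the smallest label wins, so the
  phase terminates deterministically and never decreases the objective.
* **Restarts** — 10 by default, each from a fresh uniform random
  assignment; restart seeds are derived from the master seed, so results are
  identical whatever order restarts run in. The best state *ever visited*
  (not the final state) across restarts is returned, relabeled canonically
  by order of first appearance.

One point where a design decision was genuinely open: redrawing a label with
the same random variate after permuting the group labels of the initial
state can pick a differently-relabeled category, so individual trajectories
are not label-equivariant; the objective itself is label-invariant, and on
well-separated data all relabelings converge to the same canonical optimum,
which is what the tests assert.

## Deciding whether structure exists

Under homogeneity, any two-group split captures only sampling noise. The
test destroys structure while conserving everything else: for each locus
independently, the non-missing allele calls are shuffled across the
non-missing call slots (`permute_alleles()`), preserving per-locus allele
totals and the missingness mask exactly. The observed data and (by default)
20 permuted copies are each optimized at `K = 2` with the *same* schedule
and restart count — identical optimization effort under null and
alternative — and structure is declared when the observed maximized LR
exceeds every null value. With 20 permutations that decision has a built-in
false-positive rate of about 1/21 per dataset under exchangeability, which
the calibration test observes; `empirical_p` is also reported for users who
want a different cutoff.

## Choosing K

`lr_profile()` records the best LR for `K = 1..K_max` (`LR(1) = 0` by
definition). The profile is non-decreasing in `K` — a `K+1`-group search can
always park a group empty — so its value alone cannot select `K`. The
second-order difference

    SOD(K) = LR(K) - (LR(K-1) + LR(K+1)) / 2

is large and positive at an elbow. `k_max_info()` screens candidates
`K in 2..(K_max - 3)` with two guards, `SOD(K) > 0` and `SOD(K) > SOD(K+1)`,
and maximizes the scale-free discriminant

    SOD(K)^2 / sum_{i=K..K_max-1} SOD(i)^2 * (1 - SOD(K+1)/SOD(K))^2

taking the smallest K on ties (parsimony) and returning `NA` when no
candidate passes the guards (e.g. a linear profile) or when the
normalization sum vanishes. One practical subtlety: the normalization sum
shrinks as `K` grows, so sampling noise in a heavily optimized high-K tail
can occasionally score competitively with the true elbow; the shortened
profile schedule below keeps the tail smooth, and inspecting the
`discriminant` attribute (and the profile itself) is always advisable
rather than consuming the selected K blindly. The discriminant is invariant to multiplying
the whole profile by a positive constant. K selection is deliberately
advisory: when subgroup count is known from study design, pass it directly —
the tool never overrides a user-supplied `K`.

## What the simulator emulates

`simulate_genotypes()` is the package's study-condition generator, not a
convenience fixture. Each locus draws an ancestral frequency from a uniform
law truncated to `[0.05, 0.95]` — array-style common variants; without the
truncation, near-monomorphic loci would dominate the variance of every
estimator. Under the Balding–Nichols `"bn"` model each of `K` subpopulations
then draws its frequency from `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so `F` is the
expected Fst of each subpopulation against the ancestral pool (the tests
confirm a Hudson estimate near `F` at `F = 0.05`, and near 0 at `F = 0`).
The `"split_tree"` variant drifts frequencies along a balanced binary split
tree with one `F`-sized step per branch, giving the nested divergence
characteristic of fine structure: sister subpopulations are measurably
closer than distant ones. Genotypes are drawn binomially per chromosome,
and missingness is masked uniformly at random.

What it does **not** emulate: linkage disequilibrium (all loci are
independent given frequencies), admixed individuals (each individual has
exactly one source subpopulation), ascertainment bias, genotyping error,
and informative missingness. Passing tests therefore demonstrate correctness
of the statistic and search under an idealized F-model; on real data the
LD-pruning step is doing real work, and admixture is explicitly outside the
model — an admixed sample will simply be forced into its closest discrete
group.

Default study conditions used by the test suite and the acceptance script,
chosen once as realistic desk-scale analogues of array-data scenarios
(hundreds of individuals, thousands of pruned SNVs): recovery at `K = 5`,
40 individuals per subpopulation, 2,000 loci, `F = 0.05`; the
locus-count sweep at `S = 250 / 1,000 / 4,000` with `F = 0.02`; structure
testing at `N = 200`, `S = 1,000` with `F = 0` (null) and `F = 0.05`
(two subpopulations). Profile and permutation runs use shortened schedules
(60/40 epochs, 3/2 restarts) — on data this strongly separated, the greedy
phase does most of the work and the full default ladder adds nothing but
time; the full defaults remain in force for the headline recovery runs.

## Evaluation helpers

`adjusted_rand_index()` is the Hubert–Arabie chance-corrected pair-counting
agreement (1 = identical up to relabeling, ~0 = independent).
`confusion_table()` cross-tabulates a clustering against reference labels
and names each cluster by its majority label (lexicographic on ties);
`concordance()` is the fraction of individuals whose cluster name matches
their reference label after dropping excluded columns. The package ships
one reference dataset, `wgs11257_confusion()`: the published K = 6
cross-tabulation from an 11,257-genome validation against supervised
super-population labels, whose ADMIX column (2,385 admixed individuals) is
excluded by convention; the remaining cells give 8,795 matches of 8,872
individuals:

```{r concordance}
tab <- wgs11257_confusion()
concordance(tab, exclude_labels = "ADMIX")
```

## Numerical and degenerate-input notes

* All LR values are in nats; the argmax is base-invariant, but reported
  magnitudes would scale by `log2(e)` or `log10(e)` in other bases.
* Incremental deltas and a cumulative LR drift at roughly machine epsilon
  per move; the returned `best_lr` is therefore recomputed exactly from the
  best state, and the build-vs-rebuild invariant is tested at `1e-6`.
* A locus with zero non-missing calls scores 0 and is harmless; `K = 1`
  bypasses the search entirely (LR identically 0).
* `k_max_info()` requires `K_max >= 6`; with noisy profiles near-equal
  consecutive SOD values drive the discriminant to 0 and the argmax simply
  decides.
* Brute-force enumeration, used as a test oracle, is limited to about 30
  individuals in principle and 10 in the tests.

## Limitations

The method reports discrete group memberships, not ancestry proportions;
it trades resolution for speed by pruning LD rather than modeling it; and
an imbalanced design (one very small subgroup) weakens the contingency
signal. Runtime grows linearly in both `N` and `S` per restart-epoch,
which is the regime where the approach pays off relative to pairwise
coancestry methods whose cost is quadratic in `N`.
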