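---
title: "Energy landscapes of logical gene regulatory networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy landscapes of logical gene regulatory networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enscape)
```

This vignette is the package's account of its model, its tunable
parameters, the numerical and design choices that were genuinely open, and
what the packaged synthetic inputs do and do not demonstrate.

## Why an energy picture

Logical models of gene regulation are usually analyzed by updating the
network until it settles. That yields *some* stable states but no global
view: which other stable states exist, how deep each one is, and what lies
between them. `enscape` instead scores **every** binary state of the
network at once. A state where each gene's expression agrees with the
signal computed from its regulators is energetically rewarded; conflicts
are penalized. Cell types appear as minima of the resulting landscape,
their robustness as basin depth and width, and transitions (development,
reprogramming) as paths over barriers — the quantitative version of the
marble-on-a-hillside metaphor for cell fate.

## Three-valued logic

Expression is binary, but regulatory *influence* is three-valued:
`{-1, 0, +1}` for repressive, neutral, and activating. The key rule is that
an OFF regulator exerts **no** influence (neutral), rather than the
opposite influence; plain Boolean logic with NOT cannot express this and
produces spurious symmetric landscapes for activation versus repression.
With the neutral value, the single-activator motif B → A gives the energy
vector `T = (0, 0, 1, -1)` (states ordered 00, 01, 10, 11 with A as bit 0)
and B ⊣ A gives exactly its negative — both properly directed.

Combining several inputs needs binary operators on the effect space. We
require idempotence (`q(i,i) = i`), commutativity, and associativity —
associativity is what makes "a tree of binary operators" meaningful
independent of bracketing. `enumerate_operators()` brute-forces all 3^9 =
19683 tables: exactly 9 pass all three constraints, of which six are
non-trivial and shipped as `builtin_operators()`; dropping idempotence
gives 63. The mixed-sign input pair `(+1, -1)` is where the six differ:
`AND_HI`/`OR_HI` resolve it to +1, `AND_LO`/`OR_LO` to -1, `MAX`/`MIN` to
the extreme value. The two-valued sanity check — the same constraints
reduce the 16 Boolean operators to AND and OR — is part of the test suite.

## The discrete energy

For each gene `g` in each state `s`, its regulators' effects are combined
by the gene's expression tree into `F_g(s)`; the gene contributes the
agreement energy `L` when its expression equals the forced value, the
disagreement energy `H` when it differs, and the neutral energy `(L+H)/2`
when `F_g = 0` (including genes with no inputs, such as media components).
Defaults are `L = -1`, `H = +1`, neutral 0, matching every worked example
in the test suite; they are parameters of `compute_landscape()` because
only their ordering, not their scale, is structural.

**Attractor semantics.** An attractor is a maximal Hamming-connected
equal-energy plateau none of whose members has a strictly lower neighbor.
Plateau (rather than strict-minimum) semantics is deliberate: degenerate
attractors — cell types indifferent to one gene — are biologically
meaningful (a free gene under an absent medium, for example) and appear in
all three packaged systems. `find_attractors()` implements this by flagging
every state with a lower neighbor, propagating the flag across flat edges
to fixpoint, and splitting the survivors into connected components.

**Basins.** A state belongs to an attractor's basin if a path of
non-increasing-energy steps reaches it; flat steps are traversable in both
directions, matching the dashed (equal-energy) connections in the landscape
plots. A `strict = TRUE` variant disallows flat moves outside the attractor
and always yields subsets — useful to separate "can drift there" from
"must fall there".

## Configurations of operators

A gene with `k` regulators and `p` available operators admits
`N(p,k) = p (3p-2)^(k-2)` expression trees distinct under commutativity and
associativity (`N(p,1) = 1`, `N(p,2) = p`); a network's configuration space
is the product over target genes, which reaches 2.6 × 10^25 for the
packaged 14-node reprogramming network — hence exact big-integer
arithmetic in `total_configs()` and both exhaustive and stochastic search
modes.

The enumerator realizes the count constructively. A tree over regulators
g1..gk is encoded by one operator choice for the initial pair and, for each
further regulator, one of `3p - 2` extensions of the current tree (root
operator `o`): join at the root with any operator (p ways; choosing `o`
itself is the associative flatten and keeps the tree maximally left-heavy),
or pair the new leaf with the root's left or right subtree using any
operator other than `o` (2(p-1) ways). Each extension of each distinct
tree yields a canonically distinct tree — verified in the tests by
canonicalizing every yielded tree (flatten same-operator runs, sort
children) and checking both the count and the absence of duplicates for
p ∈ {2..6}, k ∈ {1..5}.

One property of this scheme deserves emphasis, because we verified it by
brute force during development: for k ≥ 4 the closed form `N(p,k)` counts a
*proper, duplicate-free subset* of all trees distinct under commutativity
and associativity. At p = 2, k = 4 there are 52 distinct canonical forms
but `N = 32`; the extensions deliberately act only at the root level
(depth ≤ 2), so forms such as pairing the new leaf with a deeply nested
subtree are never produced. We keep the closed-form family as the
package's definition of the enumeration space — it is the recursion the
combinatorics are built on, it is duplicate-free, and its per-step
structure is what makes streaming enumeration cheap — but "exhaustive"
search should be read as exhaustive over this family, not over every
conceivable bracketing.

`exhaustive_search_space()` takes the per-target iterators in ascending
in-degree order with the smallest trees outermost, is restartable, and
guards spaces above 10^7 configurations (overridable) — beyond that scale
stochastic search is the realistic option anyway.

**Stochastic sampling.** The distribution of random trees is a genuine
design choice; we use recursive uniform splitting (the left-subtree size
of every internal node uniform over its possible values), a uniform random
assignment of regulators to leaves, and independent uniform operator
labels. Search statistics that depend on this distribution — e.g. how
often a given state is an attractor across random configurations — are
therefore reproducible under a seed but not comparable across packages
with different samplers; the tests assert distributional invariants
(uniform operator marginals at k = 2, reproducibility, prevalence bounds)
rather than specific percentages.

## The continuous landscape

The discrete energy extends uniquely to the multilinear polynomial
`E(s) = Σ_b ω_b Π_{i∈b} s_i` on the solid hypercube. The coefficient
vector solves `M ω = T` where `M[a,b] = 1` iff the bit set of b is
contained in that of a; `M` is a Kronecker power of `[[1,0],[1,1]]` and its
inverse carries alternating signs. `omega_from_T()` computes `ω = M⁻¹T` by
the in-place subset Möbius transform in O(n·2^n) — never materializing the
2^n × 2^n matrix, which at n = 15 would be infeasible — and the dense
`build_M()` (guarded at n ≤ 14) exists to cross-check the transform in
tests, where the two routes are compared exactly for n ≤ 6 and corner
evaluation is checked to reproduce `T` exactly (integer equality) up to
n = 10.

With the mixing entropy `S(s) = -Σ_i [s_i log s_i + (1-s_i) log(1-s_i)]`
(natural log — a base change only rescales temperature; corners by the
continuous extension 0·log 0 = 0), the free energy `F = E - T·S` has
stationary points at `s_i = logistic(-∂E/∂s_i / T)`: the model generates
sigmoid gain functions without any additional parameters. The package
computes these quantities; pathfinding on the continuous landscape is out
of scope.

## Marble simulations

From state `s`, a marble flips one gene or stays with probabilities
`softmax(-β ΔE)` over the N+1 options (stay has ΔE = 0); moves are chosen
by inverse-CDF sampling with the smallest-index rule, and a marble has
arrived when its state is unchanged for `stop_repeats = 3` consecutive
updates. β multiplies the energy difference directly: larger β means
colder, more deterministic descent; smaller β more uphill noise. On a
two-state landscape the stationary occupancy ratio of unstopped walks is
exactly `e^{-β ΔE}`, which the tests verify empirically.

Numerical/design choices:

* **Softmax stabilization.** Logits are shifted by their row maximum before
  exponentiation, so the β → ∞ greedy-descent limit stays finite.
* **Frozen genes** (media constraints) are removed *before* normalization —
  a constrained marble has fewer admissible moves, its stay probability is
  not inflated. Freezing the media genes partitions the landscape into
  disconnected sub-landscapes, which is how `media_transfer()` emulates
  moving a colony between culture media; initial attractor states are
  projected into the target medium by overwriting the media bits.
* **Censoring.** The stopping rule alone cannot bound runtime on large flat
  regions, so walks are capped at `max_steps` (default `10 · N ·
  stop_repeats`) and censored walks are counted as "Other", the same bucket
  as genuine non-attractor terminals. On landscapes with large plateaus the
  default cap leaves a percent-level censored fraction; raise `max_steps`
  when that matters.
* **Reproducibility.** Every (initial state, replicate) pair derives its own
  RNG substream from the master seed by a counter scheme, so tables are
  byte-identical across runs and insensitive to evaluation order. Replicate
  means and standard deviations (default 3 replicates) are reported.
* **Degenerate attractors** pool their member states: arrivals anywhere in
  the plateau credit the attractor, and marbles released "in" a degenerate
  attractor are split evenly over its member states.

`basin_strength_summary()` orders initial states by dominating attractor
and increasing dominating probability — the stacked-composition view of
basin strength — with "Other" as the topmost band.

## Visualization

`hypercube_layout()` flattens the n-cube recursively: the layout for n is
two copies of the layout for n-1 (inner and scaled outer) with
corresponding corners joined; base cases are a vertical pair and a rounded
square. The scheme is practical up to n = 7, and the function refuses
larger n with a pointer to the two workarounds: `slice_landscape()` (fix
some genes) and `merge_genes()` (collapse co-behaving genes into one
dimension, keeping only internally uniform states). Merged landscapes are
*not* faithful — reduced neighbors are not Hamming-1 neighbors of the full
landscape, so merged minima can differ from true attractors — and the
merged object carries a mandatory caveat attribute that plotting keeps
visible. Node glyphs are pies (one sector per gene, filled iff ON), node
color is energy through a diverging palette symmetric about zero (so
agreement and disagreement are visually signed), arrows point downhill
with width linear in |ΔE|, flat edges are dashed, and an optional ring
shows basin membership. Exact coordinates beyond the recursive scheme are
a free choice; we fix concentric placement with a constant scale factor
per shell.

## Packaged inputs and the synthetic-data generator

* `fixture("mef_ipsc")` — the 14-node, 38-edge MEF → iPSC reprogramming
  network, transcribed verbatim from the published interaction table;
  media = {LIF}. Its in-degrees give the exact configuration count
  26142282979403407520956416 with six operators. Its *constraint* file is
  a synthetic stand-in (marked so in the filename): the published
  binarized patterns appear only in a figure.
* `fixture("pluripotency")` — a 15-node naive-pluripotency maintenance
  network (media LIF, CH, PD). The published wiring is figure-only, so the
  edge list is a reconstruction from the textual circuit description,
  built to reproduce the published in-degree profile and hence the exact
  configuration count 28179280429056.
* `fixture("toy")` — a 5-gene toy system. The two constraint states
  (10110 → 22, 11101 → 29) are the published ones; the edge list is a
  reconstruction (gene C regulated by B and E, as described) chosen so
  that the constraints are satisfiable under the `{AND_HI, OR_HI}` pair —
  12 of its 16 two-operator configurations are valid, and valid landscapes
  also expose a surplus attractor, the qualitative behavior the toy is
  meant to illustrate.
* `random_grn()` draws seeded random signed networks (no self-loops by
  default, configurable repression fraction) as test inputs for property
  checks such as oracle equivalence of the landscape computation.

What passing tests on these inputs shows: the algebra, combinatorics,
landscape semantics, interpolation, and walk machinery are correct on
networks with realistic size, sign structure, and in-degree profiles. What
it does not show: that the reconstructed wirings equal the published
figures edge-for-edge, or that biological conclusions about those systems
transfer. Figure-derived quantities (basin-strength bar heights, search
prevalence percentages) are deliberately not asserted anywhere.

## Problem sizes and budgets in the test suite

The suite runs the full enumerator check up to p = 6 operators and k = 5
regulators (24576 trees), exercises exhaustive search on the toy network
(16 configurations), and runs the stochastic-search smoke test at 10^4
sampled configurations on the toy system — enough to exercise the
streaming search path, the prevalence statistics, and the validity filter
with comfortable margins. A full exhaustive two-operator sweep of the
pluripotency network (~10^6 landscapes of 32768 states per operator pair)
is possible with `search_configurations(..., guard = 2e6)` but takes hours
on one core; it is documented here rather than run in the suite.

## Known limitations

* Only commutative, associative operators may label trees; the
  non-commutative/non-associative extensions (mirrored updates, forced
  re-bracketing) are documented but not implemented.
* The enumeration family is the closed-form `N(p,k)` subset discussed
  above, not every bracketing distinct under the axioms.
* Cyclic attractors and asynchronous update dynamics are out of scope; the
  landscape is static and walks are memoryless.
* Continuous-landscape pathfinding (optimal reprogramming routes) is not
  implemented; the interpolation exists to bridge toward such methods.
* Binarization of expression data happens upstream; the package consumes
  already-binarized constraint patterns.
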