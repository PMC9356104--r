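# enscape — energy landscapes of logical gene regulatory networks

`enscape` maps a signed gene regulatory network (GRN), together with a
configuration of three-valued logical operators, onto a discrete **energy
landscape** over all 2^N binary cell states, and provides the tools to
analyze that landscape: attractor and basin detection, operator-configuration
search, exact multilinear interpolation, stochastic "marble" simulations of
cell-state transitions, and flattened-hypercube visualization.

It is aimed at systems biologists who study cell fate decisions —
pluripotency maintenance, differentiation, reprogramming — with logical
network models, and who want the *global* picture (every stable state and
the barriers between them) that neither rate-equation integration nor
synchronous Boolean updating provides.

## The model

Each gene g is binarized, `a_g ∈ {0,1}`. A regulator's influence on a target
lives in the *effect* space `E = {-1, 0, +1}`: an OFF input is always
neutral (0), an ON activator maps to +1 and an ON repressor to -1.
Multiple inputs are combined with binary operators `q : E × E → E` that are
idempotent, commutative and associative; brute-force enumeration of all
3^9 = 19683 tables shows exactly nine such operators, six of which are
non-trivial: the AND-like pair (`AND_HI`, `AND_LO`, differing in whether
mixed-sign inputs yield +1 or -1), the OR-like pair (`OR_HI`, `OR_LO`),
and `MAX`/`MIN`. (The same constraints reduce the 16 Boolean operators to
AND and OR.)

For a state `s` with gene expressions `a_g` and combined input effects
`F_g(s)`, the energy is

    T(s) = Σ_g τ(a_g, F_g),   τ = L if a_g = f(F_g);  H if a_g ≠ f(F_g);
                                  (L+H)/2 if F_g = 0,

with `f(+1) = 1, f(-1) = 0` the forcing function and defaults `L = -1`,
`H = +1`, so `T(s) ∈ [-N, +N]` and `-N` means every gene agrees with its
input signal. Attractors are maximal connected equal-energy plateaus with
no strictly lower neighbor (multi-state plateaus are *degenerate*
attractors). Because the assignment of operators to multi-input genes is
usually unknown, the package enumerates or samples *configurations* of
operator expression trees — `N(p,k) = p(3p-2)^(k-2)` distinct trees for one
gene with `k` regulators and `p` operators — and searches them against
binarized expression constraints.

The discrete landscape extends uniquely to a multilinear polynomial
`E(s) = Σ_b ω_b Π_{i∈b} s_i` on `[0,1]^N` (coefficients `ω = M⁻¹T` by a fast
subset Möbius transform), and pairs with the mixing entropy to a free energy
`F = E - T·S` whose stationary points are logistic in the energy gradient.
Basin strengths are probed by Boltzmann-weighted random walks: from state
`s` a marble flips one gene or stays, with probabilities
`softmax(-β ΔE)`, until its state is unchanged over three consecutive
updates.

## Worked example

The packaged 5-gene toy network has two constraint states, blue = `10110`
(state 22) and red = `11101` (state 29). Searching all 16 configurations of
the `{AND_HI, OR_HI}` pair and analyzing one valid landscape:

```r
library(enscape)
fx  <- fixture("toy")
res <- search_configurations(fx$grn, operator_preset("bar"), fx$constraints,
                             mode = "exhaustive")
res$n_valid
#> [1] 12                      # 12 of 16 configurations satisfy both states

cfg  <- parse_configuration(res$valid[[12]])
land <- compute_landscape(fx$grn, cfg, operator_preset("bar"))
at   <- find_attractors(land)
for (a in at)
  cat(state_label(a$states, 5), "energy", a$energy, "\n")
#> 11101 energy -5             # red: all five genes agree with their inputs
#> 10110 energy -4             # blue
#> 01001 energy -3             # surplus attractor predicted by the landscape

tab <- simulate_ensemble(land, at,
                         marble_config(beta = 1, n_marbles = 10000,
                                       n_replicates = 3, seed = 1))
round(tab$mean[c(23, 30), ], 3)   # rows: start at 10110, 11101
#>          A1    A2    A3 Other
#> 10110 0.117 0.880 0.001 0.002
#> 11101 0.974 0.015 0.010 0.001
```

At noise level β = 1, marbles released in the blue state stay with
probability 0.88 and reprogram to the deeper red attractor with probability
0.12; red (energy -5, the global minimum) retains 97% of its marbles. The
surplus attractor `01001` is the kind of unanticipated stable state — a
potential roadblock — that landscape analysis is designed to expose.

The larger packaged fixtures behave the same way at scale:
`fixture("mef_ipsc")` is the 14-node MEF→iPSC reprogramming network
(16384 states; 26142282979403407520956416 six-operator configurations —
`count_configs`/`total_configs` use exact big-integer arithmetic), and
`fixture("pluripotency")` the 15-node naive-pluripotency network
(32768 states, 28179280429056 configurations).

A command-line interface wraps the same workflow
(`inst/cli/enscape count-configs|landscape|search|marbles|plot`); see the
vignette for details.

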