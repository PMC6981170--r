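# endonet

Attractor landscape analysis of core endogenous gene regulatory networks.

Developmental cell types can be understood as the attractors of a small,
closed "core" network of master transcription factors: stable states of the
network dynamics are stable phenotypes, saddle points are the intermediate
phenotypes that mediate transitions between them. `endonet` implements this
program end to end for any small signed regulation table, with the
eight-factor network of early pancreatic lineage decisions (PDX1, PTF1A,
NKX6.1, SOX9, HES1, NGN3, ARX, PAX4; 12 activations, 10 inhibitions) as the
canonical, fully worked example. It is aimed at systems biologists who want
to go from a curated TF regulation table to a testable catalog of predicted
cell states and transition paths.

## What it computes

**Hill ODE model.** Each gene follows

```
dx_i/dt = [2^n Σ_{u∈act(i)} x_u^n / (1 + 2^n Σ_{u∈act(i)} x_u^n)]
        · [1 / (1 + 2^n Σ_{r∈inh(i)} x_r^n)] − x_i
```

with concentrations normalized to [0, 1], dissociation constant K = 0.5 and
Hill coefficient n ≥ 4 (switch-like regulation). The package provides the
velocity field and its analytic Jacobian (`hill_rhs()`, `hill_jacobian()`).

**Equilibrium atlas.** `find_equilibria()` runs a damped Newton search from
the deterministic grid {0, 0.5, 1}^G and classifies every root by the real
parts of its Jacobian eigenvalues: all negative → stable state; exactly one
positive → transition state (saddle); two or more → hyper-transition state.

**Adaptive landscape.** `build_landscape_graph()` perturbs each saddle
within its unstable eigenspace (squared amplitude < δ₁ = 0.25e−8),
integrates the flow, and records which equilibrium each trajectory reaches
(squared distance < δ₂ = 1e−6), yielding the directed saddle→attractor
graph of the landscape. `limit_cycle_scan()` confirms that random
trajectories always settle onto equilibria.

**Boolean cross-check.** `boolean_weights()` / `enumerate_fixed_points()`
build the synchronous dominant-inhibition Boolean model (activator weight
+1, inhibitor weight −100, strict threshold at 0) and enumerate all 2^G
states; `compare_ode_boolean()` verifies that every binarized ODE attractor
is a Boolean fixed point.

**Most probable paths.** `minimize_action()` minimizes the discretized
Freidlin–Wentzell action

```
S = ¼ Δt Σ_k Σ_i [ (x_i^{k+1} − x_i^k)/Δt − (f_i^{k+1} + f_i^k)/2 ]²
```

(D = identity, endpoints clamped, line-segment initialization, T = 10,
N = 100 by default) to predict the dominant TF dynamics of noise-driven
transitions; `lineage_mpp_suite()` chains these along the endocrine,
ductal and two acinar maturation routes.

**Single-cell state matching.** `catalog_from_atlas()` turns the atlas into
a binary cell-state catalog; `assign_cells()` matches binarized cell
profiles against it exactly; `correlation_cluster()` groups cells by
1 − Pearson correlation; `generate_cells()` simulates negative-binomial
scRNA-seq counts with dropout at the catalog patterns so the whole pipeline
is testable without any external data.

## Worked example

```r
library(endonet)
net <- pancreas_network()
net
#> gene_network: 8 genes, 12 activations, 10 inhibitions
#> genes: PDX1, PTF1A, NKX6.1, SOX9, HES1, NGN3, ARX, PAX4

atlas <- find_equilibria(net, hill_params(n = 4))
atlas
#> equilibrium_atlas: 35 states at n = 4 (11 stable, 16 transition,
#>                    8 hyper-transition, 0 degenerate)
```

The 11 stable states and 3 of the transition states are recognizable
pancreatic cell identities; `annotate_pancreas_atlas()` names them from
their marker patterns:

```r
annotate_pancreas_atlas(atlas)
#>      Ibeta        TiP      AciP2        TrP     Ialpha     acinar       AciP
#>       "S1"       "S2"       "S3"       "S4"       "S5"       "S6"       "S7"
#>      trunk NKX61_only     ductal       none         MP        EEP        LEP
#>       "S8"       "S9"      "S10"      "S11"       "T2"       "T4"       "T8"
```

so e.g. the multipotent progenitor (MP) is a saddle, and the immature beta
cell (Ibeta, S1) is the attractor with PDX1, NKX6.1, NGN3 and PAX4 on. The
Boolean model reproduces every attractor, and the landscape graph wires the
saddles to the attractors they mediate:

```r
cmp <- compare_ode_boolean(atlas, enumerate_fixed_points(boolean_weights(net)))
sum(cmp$per_state$is_fixed_point)
#> 11

build_landscape_graph(net, atlas, include_hyper = FALSE)
#> landscape_graph: 35 nodes, 32 edges (32 from transition,
#>                  0 from hyper-transition states)
```

Each of the 16 transition saddles connects exactly two states — for
instance the MP saddle links the tip and trunk progenitors (TiP, TrP), and
the LEP saddle links the immature alpha and beta attractors, tracing the
endocrine maturation route MP → TrP → EEP → LEP → Iα/Iβ.

## Vignette

`vignettes/core-network-landscape.Rmd` documents the model assumptions,
every tunable parameter with its default and rationale, the numerical
choices (multistart density, Newton damping, deduplication and eigenvalue
tolerances, integrator, optimizer), what the synthetic-cell generator does
and does not emulate, and known limitations.
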