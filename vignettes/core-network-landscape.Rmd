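---
title: "Quantifying cell states and transitions from a core endogenous network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell states and transitions from a core endogenous network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`endonet` analyzes small, closed networks of master transcription factors
under the hypothesis that stable cell phenotypes are attractors of the
network dynamics and that intermediate phenotypes are the saddles between
them. The dynamics are deliberately coarse-grained: real regulatory
kinetics are unknown at the parameter level, so every gene is given the
same normalized Hill-function equation,

$$\dot x_i \;=\; \eta\,
  \frac{\sum_{u \in act(i)} x_u^n}{K^n + \sum_{u \in act(i)} x_u^n}\cdot
  \frac{K^n}{K^n + \sum_{r \in inh(i)} x_r^n} \;-\; \tau x_i,$$

with concentrations scaled to $[0,1]$, $\eta = \tau = 1$ so that maximal
steady-state expression is 1, and $K = 0.5$ so that the response is
half-maximal at half-maximal regulator expression. Activators and
inhibitors each aggregate as a *summed* $x^n$ inside one shared Hill term
(one fraction per regulation sign, not a product of per-regulator
factors); a gene with no activators has zero production and can only
decay, and a gene with no inhibitors has repression factor 1. In the
canonical pancreas network only the inhibitor convention is exercised
(HES1 has no inhibitors; every gene has at least one activator).

The conclusions drawn from such a model are *qualitative*: which
attractors exist, how they are wired through saddles, and which dominant
transition dynamics connect them — not quantitative expression levels or
time scales.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| Hill coefficient `n` | 4 | — | regulation must be switch-like for multistability; the attractor repertoire should be (and is, see the robustness tests) insensitive for `n` in 4–7 |
| `K` | 0.5 | normalized conc. | half-maximal response at half-maximal regulator level |
| `eta`, `tau` | 1 | 1/time | fixes the concentration and time normalization |
| `delta1` | 0.25e-8 | squared norm | squared amplitude bound of saddle perturbations: small enough that the local linearization is faithful |
| `delta2` | 1e-6 | squared norm | squared distance at which a trajectory has "reached" an equilibrium (norm distance 1e-3, far above the root tolerance, far below inter-state distances) |
| action mesh `T`, `N` | 10, 100 | time, — | resolves the switch-like transitions; refining to (20, 200) moves converged actions by well under 0.01 |
| generator `on_mean`/`off_mean` | 50 / 0.5 | counts | typical detected-TF vs leaky-background scRNA count levels |
| generator `dispersion` | 2 | — | strong negative-binomial overdispersion, as in real droplet data |
| generator `dropout_prob` | 0.1 | — | zero-inflation of expressed genes |

## Numerical choices

**Multistart root finding.** The grid $\{0, 0.5, 1\}^G$ (6561 starts for
$G = 8$) covers every on/half/off orthant deterministically; seeded
uniform random starts can be added. Newton steps are damped by step
halving (up to 50 halvings, at most 200 iterations), converged when
$\lVert f \rVert_\infty < 10^{-10}$. Roots are merged when closer than
$10^{-6}$ (Euclidean; the same scale as `delta2`), and roots outside
$[-0.05, 1.05]^G$ are discarded because the unit box is forward-invariant,
so anything outside it cannot be a biologically meaningful state.

**Classification.** Eigenvalue real parts within $10^{-8}$ of zero make a
state `degenerate` — reported, never silently classified. The atlas is
sorted by class and then decreasing lexicographic state vector, which
makes the `S1...`, `T1...`, `H1...` labels deterministic. (With this sort
the all-off attractor of the pancreas network is S11.)

**Landscape construction.** Perturbation directions are $\pm$ each
orthonormalized unstable eigenvector (real and imaginary parts for
complex pairs); saddles with two or more unstable directions additionally
get seeded random unit combinations within the unstable subspace
(8 by default). No sampling rule is canonical here; the axis directions
guarantee determinism and the random combinations add coverage.
Trajectories use fixed-step classical RK4 with `dt = 0.01` up to
`t_max = 500`, stopping when $\lVert f\rVert_\infty < 10^{-8}$; a forward
Euler mode is available for fidelity comparisons with simpler
integrators. The acceptance property that matters — the saddle-to-attractor
edge set — is integrator-agnostic and is checked to be invariant under
doubling `t_max` and shrinking `delta1` tenfold. A perturbed saddle starts
inside its own `delta2`-ball, so the graph builder excludes the source
state when deciding which equilibrium a trajectory reaches first.

**Boolean model.** The inhibitor weight $-100$ makes any active inhibitor
override all activators for networks with fewer than 100 activators per
gene; the threshold is strict, so a weighted sum of zero maps to "off"
(hence the all-zero state is always fixed). Overriding the weight warns,
because dominance can be lost. Enumeration is exact up to 24 genes,
chunked to bound memory.

**Action minimization.** Only the $(N-1) \cdot G$ interior mesh points are
optimized (endpoints are hard-clamped: the action is a boundary-value
functional); the optimizer is L-BFGS-B with the analytic gradient of the
discretized action, initialized on the straight line between the
endpoints. Multi-well lineage transitions are solved stagewise (one
segment per consecutive pair of named states) rather than as one global
path, matching how maturation proceeds through intermediate phenotypes.
One numerical subtlety: discretized actions on different meshes are not
nested path spaces, so the minimized value is not exactly monotone in
`N`; successive refinements instead converge in the Cauchy sense, which
is what the refinement check reports (both the action change and the
maximum pointwise path deviation after time-rescaling; the headline
stability bound is applied to the action). The underlying A-type
stochastic-integration theory (potential $U = \min S$, steady state
$\propto e^{-U/\epsilon}$, symmetric/antisymmetric drift decomposition)
motivates the functional but is not itself computed — the most probable
paths only require minimizing the $D = I$ action.

**Degenerate inputs.** Empty edge tables, unknown sign tokens and
duplicate edges are rejected by name; negative concentrations are outside
the model domain unless explicitly permitted; identical path endpoints
are refused; stable states have no unstable subspace to perturb; an atlas
without saddles cannot yield a landscape.

## Cell-state catalog and annotation choices

Attractors binarize at the half-maximum (0.5) into distinct on/off
patterns; these patterns are exactly the marker signatures of the known
pancreatic cell types (acinar/tip, trunk, ductal, immature alpha/beta)
plus the predicted progenitors (TiP, TrP, AciP, AciP2) and two
unclassified states. The progenitor *saddles* (MP, EEP, LEP) express some
markers at intermediate levels, so two choices are exposed:

* `annotate_pancreas_atlas()` identifies them by value-range marker rules
  (MP: all five early TFs appreciably expressed, endocrine TFs off; EEP:
  trunk-progenitor-like with NGN3 risen but below half-maximum; LEP: NGN3
  high, other lineage TFs below half-maximum).
* `catalog_from_atlas(transition_threshold = )` lets saddles binarize at a
  lower detection level (0.2 is a good choice) so that their patterns stay
  distinct from the neighbouring attractors — at 0.5 the EEP and MP
  patterns collapse onto TrP and TiP, and the collision is warned.

For matching cells, the default detection rule calls a gene "on" at
`on_threshold = 1` (any observed count). Under realistic background noise
(the generator's `off_mean = 0.5` with dispersion 2 makes an off gene
fire at least one count with probability 0.36) a midpoint threshold is
the appropriate two-level detector; the geometric mean of the on/off
levels, $\sqrt{50 \times 0.5} \approx 5$ counts, is used in the
package's own end-to-end checks and is derived from the generator
parameters alone.

## What the synthetic generator does and does not emulate

`generate_cells()` reproduces the *on/off block structure* of the
predicted states with negative-binomial noise, dropout on expressed
genes, and uninformative background genes — enough to exercise every file
format, gene-resolution and assignment code path and to measure recovery
rates against known truth. It does not emulate library-size variation,
batch effects, gene-gene correlation beyond the state patterns, realistic
gene counts, or doublets. Passing the recovery tests therefore shows the
pipeline is correct and calibrated for NB + dropout noise; it does not
show that any particular real data set will match the catalog.

## Problem sizes used in the shipped checks

The package's tests and the reproduction script use: the full 6561-start
grid at $n = 4$ (and $n = 5, 6, 7$ for the robustness sweep); all 16
transition saddles for the landscape (hyper-transition saddles are
computed but flagged, and excluded from the stability checks, since paths
through them connect several attractors at once); the four endocrine-chain
segments at mesh (10, 100) vs (20, 200); 200 random trajectories for the
limit-cycle scan; and 200 synthetic cells per catalog state. These sizes
fully reproduce the analysis on a laptop-class single core in a few
minutes.

## Known limitations

* Root finding is multistart-based; there is no global certification
  (interval arithmetic or homotopy continuation) that the atlas is
  complete. The grid density argument plus the Boolean cross-check is the
  evidence.
* Fixed-step integration with early stopping is tuned for this model
  family (bounded, strongly contracting off the saddle set); stiff or
  oscillatory systems would need an adaptive integrator.
* Boolean analysis reports fixed points only; cyclic attractors of the
  synchronous dynamics are not chased.
* t-SNE-style embeddings are visualization conveniences and are
  deliberately excluded from all quantitative checks; none is bundled.
* GEO ingestion is out of scope: expression input is a plain TSV or
  MatrixMarket triplet, and column conventions are the user's
  responsibility.
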