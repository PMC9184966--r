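---
title: "Steady states, thermodynamics and sharpness on labelled directed graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady states, thermodynamics and sharpness on labelled directed graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linfra)
```

## The model

`linfra` works with finite, simple, directed graphs whose edges carry
positive labels with the dimension of rates (time^-1). Vertices stand for
biochemical species or molecular states, edges for reactions or
transitions. Treating each edge as a first-order reaction gives the linear
dynamics

    du/dt = L(G) u,

where `L(G)` is the column-sum-zero graph Laplacian: `L[j, i]` holds the
label of edge `i -> j` and the diagonal balances each column, so total mass
`u_1 + ... + u_N` is conserved. When the labels are interpreted as
infinitesimal transition rates and `u` as a probability vector, the same
equation is the master equation of a continuous-time Markov chain. Only the
column-sum convention is implemented; offering the row-sum transpose as an
option is an invitation to silent transposition bugs.

Labels are restricted syntactically to sums and products of named positive
parameters, positive literals and at most one input symbol (a ligand
concentration). That restriction is what lets the package guarantee
positivity without evaluating anything, and it makes every derived
steady-state quantity a polynomial with non-negative coefficients in the
parameters — which is exactly what the package's small exact polynomial
engine (`poly_sym()`, `poly_mul()`, ...) represents. Rates that genuinely
need ratios (aggregated parameters, equilibrium constants) arise as
*outputs* of the machinery, never inside labels.

## Steady states from spanning trees

For a strongly connected graph the Laplacian kernel is one-dimensional, and
the Matrix-Tree theorem gives a canonical basis vector with entirely
positive entries: entry `i` of `rho_symbolic(g)` is the sum over all
spanning trees rooted at `i` of the product of the tree's edge labels. The
normalized steady state is `u_i* = rho_i / sum_j rho_j * u_tot`.

```{r}
g <- lf_graph(c("1", "2"),
              data.frame(from = c("1", "2"), to = c("2", "1"),
                         label = c("a", "b")),
              parameters = c(a = 2, b = 1))
sapply(rho_symbolic(g), poly_format)
steady_state(g)
```

Two code paths exist and are tested against each other: exact symbolic
enumeration (reverse-pointer backtracking that generates each forest once,
cross-checked against a brute-force filter over all edge subsets on small
graphs), and a numeric fast path that never enumerates — it solves the
linear system with a reference vertex pinned, falling back to an SVD null
vector when the reduced system is ill conditioned (reciprocal condition
below 1e-12). Tree *counts* use fraction-free integer elimination on the
unit-label Laplacian minor, so combinatorial anchors like the
3-dimensional hypercube's 384 spanning trees per root, or the 42 467 328
of the 4-dimensional hypercube, are exact integers, not floating-point
approximations.

Enumeration cost grows with the tree count; the package enumerates
explicitly only where that is feasible (hundreds of trees) and otherwise
relies on determinants, which is the same division of labour the theory
itself suggests.

## The thermodynamic layer

When every edge has a reverse partner, the ratio of a label pair has a
thermodynamic reading: its logarithm is the total entropy change of the
transition in units of kB (`edge_entropy()`). A reversible graph can reach
thermodynamic equilibrium exactly when the product of label ratios around
every cycle is 1 (the Wegscheider/cycle condition). `satisfies_cycle_condition()`
checks `|log mu(C)| < tol` on a fundamental cycle basis built from one
spanning tree of the undirected support; the log form makes the test
symmetric under reversing the traversal. The default tolerance 1e-9 is a
numerical choice — with floating labels some tolerance is unavoidable, and
1e-9 sits far above accumulated rounding on the graph sizes used here yet
far below any genuine violation produced by generic parameters. Labels
whose ratios span more than 1e12 trigger a conditioning warning rather
than an error.

At equilibrium the steady state needs only label ratios: path products
from a reference vertex (the first declared vertex, by convention) give
Boltzmann-type weights `mu_i` with `mu_1 = 1`, and
`equilibrium_steady_state()` normalizes them by their sum — the partition
function. The suite verifies on hundreds of seeded fixtures that this
local, path-based prescription agrees with the global Matrix-Tree one to
1e-10, that detailed balance (`u_i* l(i->j) = u_j* l(j->i)`) holds pair by
pair, and that the cycle-condition verdict and the detailed-balance
verdict always coincide — the two classical characterizations of
equilibrium.

`solve_ligand_conservation()` closes the loop when the input symbol is a
ligand with finite total: free plus bound ligand is monotone increasing in
the free concentration, so the conservation equation has a unique root,
found by bracketed 1-D root finding.

## Coarse graining

Given any partition of the vertices of a strongly connected reversible
graph, `coarse_grain()` builds the quotient graph whose edge `w -> z`
carries `Q` times the sum of the fine tree polynomials over the target
block `z`. Two properties make this labelling the right one: the quotient
always satisfies the cycle condition (its label ratios derive from a
potential-like block quantity), even when the fine graph is away from
equilibrium; and its steady state equals the block sums of the fine steady
state. The constant `Q` only fixes the label dimension and cancels from
every steady-state quantity; the suite checks invariance across six orders
of magnitude. `Q` defaults to 1.

Coarse graining is a steady-state statement only. A regression test keeps
a fixture where the transient trajectory of the quotient visibly differs
from the block-aggregated fine trajectory, so nobody mistakes the
construction for model reduction of the dynamics.

Coarse labels are stored numerically (evaluated at bound parameters and,
when an input symbol is present, at a given input value); the symbolic
block sums can explode combinatorially and nothing downstream needs them.

## Responses, sharpness and the Hill reference

An output is a non-negative combination `f(x) = sum_i lambda_i u_i*(x)` of
steady-state probabilities, a bounded rational function of the input.
`response_function()` assembles it exactly from the tree polynomials,
either fully symbolically or with parameters bound, and cancels common
powers of `x`. Sharpness is measured after normalizing the input by the
half-max point `x0.5` (the smallest positive crossing of the midpoint of
the global range over `[0, Inf)`): the steepness `s` is the global maximum
of `|g'(y)|` for `g(y) = f(y x0.5)` and the position `p` is where it is
attained. Critical points come from the exact roots of the derivative's
numerator polynomial (endpoint `y = 0` included; ties broken towards the
smallest `y`, matching the minimality convention in `x0.5`); a dense
log-grid maximizer is kept purely as a test oracle. Because outputs here
are probabilities in `[0, 1]`, steepness is comparable across models;
rescaling the raw output would rescale `s` linearly, which is why the test
fixtures pin outputs to probability scale.

The Hill function `H_h(x) = x^h / (1 + x^h)` is the reference family: its
half-max point is 1 and for `h > 1` its position-steepness point has the
closed form `p = ((h-1)/(h+1))^(1/h)`, with `h = 1` degenerating to the
`p = 0` boundary. `hill_line()` traces this locus.

`sample_ps_region()` draws equilibrium parametrizations of the
regulated-recruitment model: a transcription factor (the input) binding at
`m` sites and a polymerase at one further site, on the hypercube of all
occupancy patterns. At equilibrium a state's weight is `c_i x^(b_i)` with
`b_i` its number of input-bound sites, and the free energies are
unconstrained, so sampling the weights `c_i` log-uniformly over
`[10^-r, 10^r]` (default `r = 3`; the range is a modelling choice, kept
configurable) sweeps the equilibrium family directly. The sampler is plain
seeded Monte Carlo with a summary of the cloud — no incremental
boundary-growing is attempted, and the package says so rather than
pretending to reproduce region-boundary algorithms it does not contain.

Two facts about the sampled clouds are worth stating precisely, because
they are easy to mis-read. First, the `p = 0` boundary is anomalous:
degenerate responses with very low position can be arbitrarily steep even
at equilibrium, which is why points with `p < 0.05` are flagged rather
than celebrated or discarded. Second, the Hopfield-barrier property that
the suite checks is a *dominance* statement: no equilibrium sample may lie
above and to the right of the position-steepness point of `H_m` — with
`m` input-binding sites, beating the Hill function with coefficient `m` in
both coordinates at once requires energy expenditure. It is not the
claim that `s <= s(H_m)` uniformly in `p`; both the low-position anomaly
and the equilibrium region's own extent at positions beyond `p(H_m)`
violate that stronger reading. The suite checks the dominance property on
10^4 seeded samples for `m = 4`; this is an empirical check of a
conjectured universal bound, not a proof.

## Enzyme mechanisms and the modification cycle

Enzyme mechanisms are written in a three-production grammar — binding
`X + S* -> Yi`, conversion `Yi -> Yj`, release `Yk -> X + S*` — with `S*`
either the unmodified (`S0`) or modified (`S1`) substrate form. Substrate
never binds to an intermediate (the uncoupling condition), which is what
makes the tree polynomial of each intermediate *linear* in the substrate
concentrations and that of the free enzyme constant; `aggregated_params()`
verifies both facts symbolically and would fail loudly on a mechanism
outside the grammar. From the linear coefficients come the four aggregated
descriptions of any mechanism: reciprocal generalized Michaelis-Menten
constants `kappa` (how much substrate each complex sequesters per unit
free enzyme; for the textbook scheme `kappa0 = kon/(koff+kcat)`, the
reciprocal Michaelis constant), and total generalized catalytic
efficiencies `c01`, `c10` (release-rate-weighted sums of the matching
`kappa`). The classification `kappa1 = 0` (strongly irreversible: product
cannot rebind) versus `kappa1 > 0, c10 = 0` (weakly irreversible: product
rebinds but is never converted back) falls out of the same numbers.
Cofactors such as ATP/ADP are absorbed into the rates; dead-end complexes
are supported and contribute to sequestration but not to catalysis.

A modification-demodification cycle couples a forward and a reverse
mechanism on one substrate. Eliminating the substrate and intermediate
concentrations through the 2-vertex substrate graph and the conservation
law leaves two relations `E_tot = R_E([E]*, [F]*)`,
`F_tot = R_F([E]*, [F]*)` in the free enzyme concentrations alone —
polynomial after clearing the common positive denominator; the package
keeps the rational closure, which is what root finding wants.
`solve_cycle()` finds all roots in `(0, E_tot] x (0, F_tot]` by damped
Newton iteration started from a 12 x 12 log-spaced grid, deduplicating at
1e-6 relative; the rational-parametrization theory guarantees the steady
states are isolated points of this 2-D system, and multistability appears
as multiple roots. The independent check is `ode_oracle()`, which integrates the full
mass-action network (every enzyme state, both substrate forms) to
stationarity; on fifty random cycles drawn across the four mechanism
families the oracle's steady state always coincides with a reduced-system
root to 1e-6. Where a direction is catalytically dead in both mechanisms
the solver reports the degenerate configuration instead of guessing.

## What the generators emulate — and what they do not

The seeded fixture generators define the test conditions. Hypercubes model
ligand-binding state spaces (shared per-site rates are automatically at
equilibrium; per-edge random rates are generically not).
`make_detailed_balanced()` draws vertex potentials (Boltzmann weights
spanning `[10^-r, 10^r]`, `r = 3`) and symmetric edge scales, so its
output is detailed balanced by construction up to rounding.
`make_random_strong()` guarantees strong connectivity through a random
cycle covering all vertices plus extra edges. Random mechanisms draw rates log-uniformly
over one decade either side of 1, and totals of order one with substrate
up to tenfold larger — dimensionless ranges typical of modelling practice.
These synthetic families exercise the algebra and the solvers; they do not
capture measurement noise, unmodelled species, timescale overlap or
parameter correlations of real systems, so green tests certify the
mathematics, not any particular biological fit.

Problem sizes used by the suite — graphs up to 8 vertices for symbolic
work, hypercubes up to 16 vertices for exact counting and 32 states for
equilibrium sampling, 400 fixture draws for the equivalence checks, 10^4
sharpness samples, 50 random cycles for the reduction check — were chosen
as the smallest sizes at which every property is exercised with real
margin.

## Known limitations

Non-strongly-connected graphs, synthesis/degradation extensions, stochastic
trajectory simulation, first-passage machinery beyond single-root minors,
multisite/multi-enzyme reductions beyond the single cycle, entropy
decomposition into environment and internal parts, and reproduction of
published region boundaries are all out of scope. Symbolic computation is
exact but exponential in graph size by nature; the numeric paths are the
ones meant for larger graphs.
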