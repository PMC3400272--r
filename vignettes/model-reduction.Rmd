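---
title: "Multiscale reduction of reaction networks with crnreduce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale reduction of reaction networks with crnreduce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnreduce)
```

# The problem

Mechanistic models of cell signalling, metabolism and gene regulation are
systems of mass-action ODEs, `dc/dt = P(c)` with `P` a polynomial vector
field assembled from the stoichiometry and the rate constants. Realistic
models are too large and too poorly parametrized to analyse directly, but
they are *multiscale*: rate constants and concentrations spread over many
orders of magnitude. crnreduce implements a reduction calculus that exploits
exactly this property. Its simplifications depend on the *order relations*
among parameters, not on their precise values, which makes the reduced
models robust to parametric uncertainty.

The package covers four connected techniques:

1. **Monomolecular networks with totally separated constants** reduce to
   acyclic deterministic digraphs by three graph-rewriting rules
   (`rank_label()`, `reduce_monomolecular()`), and the reduced digraph's
   relaxation is described by 0–1 eigenvectors: one effective reaction per
   timescale (`spectral_approximation()`, `single_step_approximations()`).
2. **Tropicalization** replaces each balance polynomial by its dominant
   monomial, turning the smooth system into a piecewise-smooth (max-plus)
   one (`tropicalize()`); the discontinuity locus is the tropical manifold
   (`tropical_manifold_2d()`), and its attracting parts — detected by the
   Filippov sliding condition (`sliding_test()`,
   `detect_fast_constraints()`) — are tropical proxies of the slow invariant
   manifold. `simulate_hybrid()` integrates the resulting hybrid dynamics.
3. **Slaved species detection**: a species is slaved when its trajectory
   stays within a small log-distance of an *imposed trajectory*, a positive
   root of its own balance polynomial with the other species frozen at
   their simulated values (`imposed_trajectory()`, `slaved_report()`).
   Pruning dominated monomials of the balance separates quasi-equilibrium
   (QE) from quasi-steady-state (QSS) species (`classify_qe_vs_qss()`).
4. **QSS/QE rewriting** turns the algebraic approximations back into a
   smaller reaction network: exact integer kernels of the fast
   stoichiometric matrix give species pools (QE, left kernel) and reaction
   routes / elementary flux modes (QSS, right kernel); the fast conditions
   are solved in closed form and new rates are fixed by matching terminal
   species' production (`reduce_qss()`, `reduce_qe()`). Every coefficient
   of the new rates is tracked as a monomial — or a named rational
   composite — of the original parameters (`effective_parameters()`), the
   identifiable quantities for backward-pruning parameter estimation.

# The worked example: the enzymatic mechanism

The two-reaction mechanism `S + E <=> ES -> P + E` is the package's
reference example, built by `build_michaelis_menten()` together with its
two-variable form in `(S, ES)` (free enzyme and product eliminated through
the conservation totals).

```{r}
mm <- build_michaelis_menten(k1 = 2, km1 = 3, k2 = 5, Etot = 0.1, Stot = 10)
mm$mechanism
conservation_laws(mm$mechanism)
```

Under fast catalysis the complex is a low-concentration fast species; QSS
rewriting pools the two reactions into one route `S -> P` and recovers the
hyperbolic rate law in closed form:

```{r}
red <- reduce_qss(mm$mechanism, "ES",
                  substitutions = list(E = sp_sub(sp_var("Etot"), sp_var("ES"))))
red
effective_parameters(red)
```

The effective parameters are the maximal-velocity monomial `k2*Etot` and
the composite Michaelis constant `(km1 + k2)/k1`; with a dominance margin
the composite collapses to a monomial when one term wins by more than the
margin. Under fast reversible binding the same mechanism is a QE problem:
species pool over the fast conservation laws, with the substrate total as
the surviving slow variable and the complex given by the admissible root of
a quadratic (`quad_root`), whose low-enzyme limit
(`limit_small_parameter()`) is again the hyperbolic law.

# Design choices and their rationale

## Exact arithmetic where exactness is the point

Stoichiometric kernels (conservation laws, pools, routes) are computed by
rational Gaussian elimination on integers (`nullspace_int()`), so
`b %*% S == 0` holds exactly, not to a tolerance. The symbolic layer
(`sp_*`, `srat`, sparse exponent-vector polynomials with cross-multiplied
rational equality) exists because the package's headline claims are
*symbolic identities* — the reduced rate equals `k2*Etot*S/(km + S)` as an
expression, not as a fitted curve. Floating point is used only for rate
evaluation, simulation, and dominance comparisons (taken on log-values with
absolute tolerance 1e-9).

## Total separation, ties, and the tie-breaking option

The linear-reduction theory assumes *totally separated* constants: every
dominance comparison is strict. The random generator
(`generate_separated_monomolecular()`) enforces this for the original
constants by construction (`eps^rank`), but *derived* monomials produced by
cycle gluing can still tie exactly when rank sums coincide (for instance a
glued cycle whose two exit monomials both evaluate to `eps^24`). Such a
network is genuinely outside the theory's premise — the true relaxation
rate of the tied cycle is the *sum* of the two constants, and any
single-monomial label is off by a factor of about two. `reduce_monomolecular()`
therefore raises an error naming the tied pair; the `tie_break = "perturb"`
option multiplies constant *i* by `exp(1e-9 * log(prime_i))` — log-primes
are linearly independent over the rationals, so no two distinct
integer-exponent monomials can remain tied — and is meant for exploratory
work, not for accuracy claims. The convergence experiments sample networks
that reduce without ties, i.e. networks satisfying the hypothesis.

## Rule c and the restoration of glued cycles

A cycle whose nodes' dominant edges all stay inside it is glued to one
node; its quasi-stationary distribution in the separated limit is the
monomial `k_lim / k_i` (`k_lim` the slowest intra-cycle exit), so an
outgoing reaction with constant `k` leaving node *i* is renormalized to the
monomial `k * k_lim / k_i`. On restoration the cycle is cut at the limiting
step and the surviving outgoing edge is re-attached *from the limiting
node* — the node that carries the quasi-stationary mass. This is the only
choice that keeps the digraph deterministic and the slow timescale equal to
the renormalized monomial; it reproduces the `k5*k4/k3` behaviour of the
canonical glued-cycle example (see `tests/testthat/helper-networks.R`).

## Numerics for extreme multiscaleness

With constants spanning 40+ decades, dense eigensolvers lose every
eigenvalue below about `1e-16 * ||K||`, and standard matrix exponentials
return zero at horizons of `1e40`. Two dedicated tools keep the full
cascade computable:

* `eigenvalues_separated()` assembles the characteristic polynomial by
  enumerating directed out-forests — all coefficients are sums of positive
  products, hence cancellation-free — stores them as logs, locates the root
  magnitudes on the Newton polygon and polishes each root by Newton
  iteration carried out entirely in log space.
* `linear_solution_multiscale()` computes `expm(K t) c0` by scaling and
  squaring with the scaling exponent computed in logs; for mass-conserving
  kinetics the column sums are renormalized to exactly one after each
  squaring, because an eigenvalue `1 - 1e-16` raised to the `2^600` hardly
  survives otherwise.

Both are validated against `eigen()` and a plain matrix exponential in the
regime where those work.

## Sliding modes: the residual-consistent drift

The Filippov condition (both one-sided fields pointing at the surface)
decides *whether* a tie surface carries a sliding mode. One-sided fields
are always evaluated geometrically, at points displaced off the surface
along its normal, because in mass-action systems several species are
typically discontinuous on the *same* hyperplane (the same two reactions
appear in their balances with opposite stoichiometry) and must switch
together.

For the sliding *motion* the textbook convex combination
`lambda f+ + (1-lambda) f-` is insufficient precisely in that shared-plane
case: the two tied monomials cancel at leading order in every balance that
contains them, `lambda` comes out exactly 1/2, and the drift evaluates to
zero — the trajectory freezes on the saturated arm of the enzymatic
example while the true dynamics consumes substrate at the zero-order rate.
The default `sliding_drift = "residual"` treats the tied group's exact
value as one shared unknown `T` (shared through the proportionality of the
copies), writes every discontinuous species' drift as
`(residual monomials + kappa * T)/c`, and closes the system with the
surface-invariance condition, which is linear in `T`. The result is the
QSS/QE-reduced dynamics that the sliding mode represents — sliding modes
*are* the tropical picture of those approximations — and it restores the
bounded log-distance between tropicalized and smooth trajectories. The
plain combination remains available as `sliding_drift = "filippov"`.

When `lambda` leaves `[0, 1]`, or a tie involves three or more monomials
(the tripod vertex), the event is logged (`exit_sliding`, `degenerate`)
and integration continues with the appropriate cell field; events are
located by bisection on the tie function with time tolerance
`1e-10 * horizon`, and a positivity floor (default `1e-30`) guards the
logarithmic coordinates.

## Slaved-species thresholds

The slaving threshold defaults to `delta = log(2)` — the trajectory within
two-fold of the imposed value — and the comparison interval excludes an
initial layer of three times the fastest timescale (estimated from the
Jacobian diagonal at the initial state). Both are configurable; no
canonical values exist, and the defaults are chosen so that the enzymatic
example classifies cleanly in both of its regimes at `Etot/Stot = 1e-2`.
When several positive roots exist the one closest in log-distance to the
actual trajectory is selected and all roots are retained in the result.
The monomial-pruning margin for the QE/QSS call is one decade on
time-median magnitudes; if nothing is dominated and the surviving balance
is not a clean reversible pairing the species is reported `unresolved`
rather than guessed.

## QSS/QE rewriting conventions

Kernel bases are reduced to primitive integer vectors with a preference
for non-negative combinations (chemically meaningful pools). In the QE
case the left-kernel pools are listed before the species untouched by the
fast reactions, and the full network's conservation laws are projected
out by greedy exact-rank filtering, so a genuine fast-conservation pool
(the substrate total) survives rather than an equivalent untouched
species. Elementary modes are enumerated exhaustively (exact
minimal-support search) up to 12 reactions and by the tableau /
double-description iteration above that; the two implementations are
tested against each other on hundreds of random matrices. Route rates are
matched to the terminal species' production with exact elimination; an
underdetermined matching is flagged and unmatched routes get zero rate
(the uniqueness theory for these rates is outside this package's scope).
Fast conditions are solved in closed form up to one final quadratic; the
`"minus"` branch is selected as the root continuous in the
vanishing-displacement limit, which for binding equilibria lies between 0
and the smaller conserved total.

# What the generators emulate — and what they do not

`generate_separated_monomolecular()` draws a uniform random simple digraph
and assigns constants `eps^rank` under a seeded permutation: totally
separated by construction, closed (mass-conserving), with log-uniform
constants whose power-law density exponent is −1 (`zipf_diagnostic()`
estimates this exponent by regressing log bin counts on log bin midpoints
over logarithmic bins; a log-rank plot is returned for display). The
convergence experiments use 20 such networks with up to 8 species at
separations `1e-1`, `1e-2`, `1e-3`, a log-spaced time grid covering
`0.01/k_max` to `10/k_min`, and report the median sup-norm trajectory
error; sizes were chosen so the whole experiment runs in seconds on one
core while still exercising nested cycle gluing.

These fixtures do *not* emulate real networks' degree distributions,
bimolecular couplings, or compartmental structure; conclusions from the
passing tests are about the calculus (the rewriting rules, the spectral
approximation, the kernels and rate recalculation), not about any
particular biological model. The five-variable cell-cycle oscillator is
wired exactly from its published balance equations but its rate constants
are not printed with the equations; the parameter set used in tests is a
plausible, clearly arbitrary choice, and nothing is asserted about that
model beyond structure (conservation, tripod geometry of the
autocatalytic balance, and the generic dimension of its constrained slow
set, which is 5 − 3 = 2).

The enzymatic fixtures pin the regimes by explicit constants: separation
`k2/km1 = 1e3` (or its inverse), enzyme-to-substrate ratio `1e-2` for
slaving, and a substrate load of a few Michaelis constants for the hybrid
comparison, where the tropicalized trajectory's asymptotic log-offset
grows like `log(Stot/km)` (the lag accumulated during the saturated
phase) — the documented bound of one decade therefore holds for moderate
loads.

# Known limitations

* SBML support is restricted to mass-action kinetic laws with unit
  compartments; anything else fails loudly naming the reaction.
* Tropical manifolds are computed as curves in two effective variables
  only; higher dimensions are handled pairwise (tie hyperplanes), without
  a full polyhedral complex.
* Coupled quadratic (or higher) fast conditions are not solved
  symbolically; the sequential eliminator stops with an error rather than
  returning an unverified branch.
* The hybrid integrator is an explicit method with step rejection; it is
  intended for low-dimensional reduced models, not for stiff production
  simulation (use `integrate_full()` for that).
* Sliding with two or more simultaneous independent surfaces falls back
  to the multilinear Filippov combination, which can lose slow drifts in
  doubly-degenerate configurations.
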