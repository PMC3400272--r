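# crnreduce

Multiscale model reduction of deterministic biochemical reaction networks.

Mechanistic models in systems biology — signalling cascades, metabolic
pathways, gene-regulation circuits — are mass-action ODE systems
`dc/dt = P(c) = Σ_j ν_j (R⁺_j(c) − R⁻_j(c))` whose rate constants and
concentrations spread over many orders of magnitude. That multiscaleness is
what makes them reducible: when constants are well separated, sums of
monomials are dominated by their largest term, and the network's dynamics
collapses, scale by scale, onto a much smaller *dominant subsystem* that
depends only on the order relations among parameters. `crnreduce`
implements this reduction calculus for R:

* **Monomolecular networks with totally separated constants** — graph
  rewriting (prune dominated reactions; glue cycles with quasi-stationary
  monomial renormalization `k·k_lim/k_i`; cut restored cycles at the
  limiting step) reduces the network to an acyclic deterministic digraph
  whose eigenvalues are minus its edge constants and whose eigenvectors are
  0–1 valued: one effective reaction per timescale.
* **Tropicalization** — each balance polynomial is replaced by its dominant
  monomial, `dc_i/dt = s_i exp[max_α(log|a_α| + ⟨log c, α⟩)]`; the tie
  locus (tropical manifold) partitions log-concentration space into cells
  of monomial dynamics, and its attracting parts, detected by the Filippov
  sliding condition, are tropical proxies of slow invariant manifolds. A
  hybrid simulator follows the piecewise-smooth flow, sliding included.
* **Slaved-species detection** — a species is *slaved* when its trajectory
  stays within a log-distance δ of an *imposed trajectory*: a positive root
  `c*_i(t)` of `P_i(c_1(t), …, c*_i, …, c_n(t)) = 0`. Pruning dominated
  monomials of the balance classifies slaved species as quasi-equilibrium
  (QE, reversible rates balancing) or quasi-steady state (QSS).
* **QSS/QE network rewriting** — exact integer kernels of the fast
  stoichiometric matrix `S^f` give species pools (left kernel, QE) and
  reaction routes / elementary flux modes (right kernel, QSS); fast
  conditions are solved in closed form (up to a symbolic quadratic root),
  new rates are fixed by matching terminal-species production, and every
  coefficient is tracked as a monomial — or named rational composite — of
  the original parameters (the identifiable *effective parameters*).

Networks are read and written in a native tab-separated format and a
mass-action subset of SBML Level 2/3. A command-line front end
(`inst/cli/crnreduce`) exposes generation, linear reduction,
tropicalization, simulation, slaved detection, and QSS/QE reduction.

## Worked example

The enzymatic mechanism `S + E ⇌ ES → P + E` with symbolic constants:

```r
library(crnreduce)
mm <- build_michaelis_menten(k1 = 2, km1 = 3, k2 = 5, Etot = 0.1, Stot = 10)
mm$mechanism
#> Mass-action reaction network: 4 species, 2 reactions, 5 parameters
#>   r1: S + E <=> ES   (kf=2, kr=3)
#>   r2: ES --> P + E   (kf=5)
```

Treating the complex as a QSS species and eliminating the free enzyme
through `E + ES = Etot` pools the two reactions into a single route and
recovers the hyperbolic rate law *symbolically*:

```r
red <- reduce_qss(mm$mechanism, "ES",
                  substitutions = list(E = sp_sub(sp_var("Etot"), sp_var("ES"))))
red
#> Reduced network (QSS): 1 reactions over {S, P}
#>   route1: S --> P
#>       rate = (-Etot*k1*k2*S) / (-k1*S - k2 - km1)
effective_parameters(red)
#>        name      kind           expression value
#> P route1_a1  monomial              Etot*k2   0.5
#> 1 route1_K1 composite k2*k1^-1 + km1*k1^-1   4.0
```

The rate is `k2·Etot·S / (km + S)` with the Michaelis constant
`km = (km1 + k2)/k1 = 4` reported as a composite effective parameter and
the maximal velocity `k2·Etot = 0.5` as a monomial. Which approximation is
appropriate is itself detected from trajectories — under fast catalysis
(`k2/km1 = 10³`, `Etot/Stot = 10⁻²`) the complex (and with it the free
enzyme) is slaved with QSS character, while substrate and product are the
slow variables a reduced model must keep:

```r
mm2 <- build_michaelis_menten(k1 = 1, km1 = 1e-3, k2 = 1, Etot = 0.1, Stot = 10)
traj <- integrate_full(mm2$mechanism, horizon = 50)
slaved_report(mm2$mechanism, traj)
#> Slaved-species report (delta = 0.693 log units)
#>  species status substatus sup_logdist t_from t_to
#>        S   slow       n/a       7.250    0.3   50
#>        E slaved       QSS       0.338    0.3   50
#>       ES slaved       QSS       0.338    0.3   50
#>        P   slow       n/a          NA    0.3   50
```

(`sup_logdist` is the largest log-distance to the imposed trajectory after
the initial layer; below `delta = log 2` means slaved.)

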