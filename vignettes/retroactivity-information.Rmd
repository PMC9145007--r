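---
title: "Retroactivity and information transmission: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retroactivity and information transmission: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromi)
```

# The question

When a signaling circuit's output protein binds downstream targets, those
targets pull output molecules out of circulation and thereby act back on
the circuit — retroactivity. This package treats the circuit as a
communication channel (input symbol at time 0, output read at steady
state) and asks how much mutual information that back-action costs. The
analysis deliberately excludes diffusion, intersymbol interference and
transient dynamics: the symbol is considered received once the system is
at steady state, which isolates the retroactivity contribution from
everything else. Reaction rates are assumed time-invariant and a steady
state is assumed to exist (true for all five supported topologies under
positive rates; the degenerate non-cyclic case is handled as an absorbing
state).

# Circuit models

The upstream module is the two-step enzymatic cycle
$I_1 + E \rightleftharpoons M_1 \to E + Z_1$, closed by the one-step
recycling $Z_1 \to I_1$ (one step rather than two to keep the state space
tractable; the cycle is what distinguishes this channel from a
unidirectional telecommunication link). Downstream target $j$ is a
reversible binding site $Z_1 + D_j \rightleftharpoons C_j$. The five
supported topologies (`TOPOLOGIES`) wire these pieces as: isolated SISO;
SISO + $N$ sites (broadcast); two substrate branches sharing one enzyme
(MIMO); MIMO + $N$ sites on the first output; and two independent SISO
circuits sharing $N$ sites of which the first claims $Q$ (multiple
access). The second branch is by default a replica of the first (same
rate constants), which is the symmetric design the analysis assumes;
`buildModel(rates2 =)` overrides it. In the multiple-access model the
number of claimed sites $Q$ is an explicit parameter: sites $1..Q$ react
with $Z_1$ and the rest with $Z_2$, and every site keeps the shared law
$Dtot_j = D_j + C_{j1} + C_{j2}$, so exclusive binding is structural
rather than rule-based. When both outputs are emitted at the same rate the
natural ensemble is a symmetric binomial allocation with mean $N/2$
(`macAllocateQ()`); the deterministic default is $\lfloor N/2 \rfloor$.

Counts vs concentrations: the exact (master-equation) engine works in
molecule counts with bimolecular propensities scaled by $1/\Omega$; the
high-count engine works in concentrations (counts per volume). That single
scaling is the only conversion between the two regimes, and it is why the
dissociation constants appear as $k_0 = k_0^- \Omega / k_0^+$.

# Low counts: exact stationary analysis

The input alphabet is concentration on–off keying with one molecule:
$I_{tot}(t_0) \in \{0, 1\}$, and likewise $E_{tot} = Dtot_j = 1$. This
makes the microstate space small enough to enumerate exactly (3 states for
the isolated circuit with the input on, 8 for the MIMO circuit with both
inputs on, and a few dozen for loaded models). `enumerateStates()` walks
the conservation polytope depth-first with pruning, so it returns exactly
the lattice points of the conservation laws; `buildGenerator()` fills the
transition-rate matrix from mass-action propensities and errors if any
transition would leave the enumerated set (that would be an enumeration
bug, not a recoverable condition).

`stationaryDistribution()` solves $\pi^T Q = 0$, $\sum \pi = 1$ as a dense
linear system with one equation replaced by the normalization — state
spaces here are at most a few hundred states, so sparse or iterative
methods would be over-engineering. The solve is restricted to the closed
communicating class reachable from the all-free initial state (found via
strongly connected components): the input-off condition gives a trivial
one-state class, and the non-cyclic ($c_2 = 0$) circuit gives an absorbing
output state, both of which are legitimate. If more than one recurrent
class were reachable the stationary law would be ambiguous and the solver
reports an error rather than averaging. Residual tolerance is $10^{-10}$
in the infinity norm, checked after every solve.

Because symbol 0 puts no input molecule in the system, conservation forces
$Z_1 = 0$ exactly under that symbol — no solve needed, and the channel is
exactly a Z-channel for every topology. The retroactivity constant is read
off operationally as $A = P(Z_1(t_s) = 0 \mid I_1(t_0) = 1)$; for
two-input topologies the per-symbol conditionals of the second input are
computed separately and mixed with the priors $(P_{02}, P_{12})$, which is
also how the mixture components $B$ and $G$ are extracted numerically.

Information quantities are in nats by default (a `units = "bits"` toggle
exists everywhere); $0 \log 0 := 0$ by continuity. Mutual information is
always computed canonically as $H(X) - H(X|Y)$ from the joint pmf rather
than from a transcribed closed-form expression — the joint is unambiguous,
and the tests verify the entropy path against an independent brute-force
sum on a $101 \times 101$ grid.

# Closed-form constants and their regime

The closed forms
$A_0 = (1+k_0)c_2 / (c_1 + (1+k_0)c_2)$ and
$A_N = 1 - c_1 / [(1+k_0)c_2 + (1 + \sum_j 1/k_{3j}) c_1]$
are pinned by four limit facts they must reproduce: $A_0 = 0$ at
$c_2 = 0$; $A_0, A_N \to 1$ as $c_2 \to \infty$; $A_N = A_0$ with no load;
$A_N \to 1$ as $N \to \infty$ with equal $k_3$. The package treats them as
fast-binding asymptotics rather than exact finite-rate results: the test
suite shows $|\hat A - A_0|$ falling like $\sim 0.1\,c/k_0^\pm$ along the
ladder $k_0^\pm \in \{10, 100, 1000\}\,c$ (about $10^{-2}$ at $100c$,
$10^{-4}$ at $1000c$), and the same for $A_N$ and $B$. This is verified
numerically, not assumed. The $B$ constant additionally assumes equal
catalytic rates $c_1 = c_2 = c$; outside $\min(k_0^+/\Omega, k_0^-) \ge
100\,c$ it emits a warning (configurable via `regimeFactor`), not an
error, because the expression remains a well-defined number. $G$, the
loaded-MIMO mixture component, has no tractable closed form and is defined
operationally from the exact solver (`gConstNumeric()`, cached per
parameter set). Symbolic-limit claims are exercised numerically at large
finite surrogates ($c_2 = 10^9$, $N = 10^6$), with tolerances $10^{-6}$
and $10^{-5}$ respectively — at those magnitudes the truncation error is
an order below the tolerance.

# Capacity and capacity bounds

The Z-channel capacity uses the standard closed form
$C = \log_2(1 + (1-A) A^{A/(1-A)})$, cross-checked against a
Blahut–Arimoto iteration (stopping on the duality gap, tolerance
$10^{-12}$) and against direct maximization of the mutual information over
the prior; the three agree to $10^{-8}$ across the $A$ grid. The upper
bound surface uses the generic dual bound $C \le \max_x KL(W_x \| q)$,
valid for every output distribution $q$ and tight at the
capacity-achieving one. This choice reproduces the qualitative structure
of interest — at every $A$, the maximum of the lower bound (the MI), the
capacity, and the minimum over $q$ of the upper bound coincide — without
committing to any particular published parameterization of the bound. On a
finite $q$ grid the minimum sits above capacity by an amount linear in the
grid step (the maximized KL has a kink at the crossing), about $10^{-2}$
at step $0.01$; the tests assert exactly that scaling.

# High counts: linear noise approximation

With a single upstream system the two-step cycle is reduced to one step
($I_1 + E \to E + Z_1$, $Z_1 \to I_1$) with the enzyme concentration
fixed, giving the steady-state mean $\mu_0 = c_1 E I_{tot1}/(c_2 + c_1 E)$
and, from the one-dimensional Lyapunov equation, the variance
$\sigma_0^2 = c_1 E I_{tot1} c_2 / (\Omega (c_1 E + c_2)^2)$ — the
$1/\Omega$ scaling is exact and tested across $\Omega \in \{1, 10, 100\}$.

For the loaded circuit, each site's occupancy at steady state is the
hyperbolic $C_j = Z_1 Dtot/(k_3 + Z_1)$. Substituting it into the output
rate equation makes the binding and unbinding fluxes cancel identically
(each complex's net flux is zero at the fixed point), and the output mean
is then *unchanged by the load*: $\mu_N = \mu_0$. This is the classic
retroactivity picture — load reshapes dynamics and fluctuations, not the
stationary mean — and it holds under the convention adopted here that the
production term draws on the unsequestered pool $I_{tot1} - Z_1$. The
alternative reading, in which complexes also deplete the substrate pool of
the *reduced* one-step model, would make the mean decrease with load and
break the identity; the package follows the identity, states the
convention here, and notes that the full (unreduced) MIMO engine *does*
keep the sequestration term $I_1 = I_{tot1} - M_1 - Z_1 - \sum_j C_j$ in
its substrate balance, which is why its output mean does decline with $N$
(`mimoDownstreamSteadyState()`).

The generic `lyapunovCovariance()` solves $A\Sigma + \Sigma A^T + BB^T = 0$
by dense Kronecker vectorization (systems here are at most a handful of
species), refuses non-Hurwitz Jacobians, and is verified against an
independent eigen-decomposition solver and against the closed-form
one-dimensional instance. Diffusion matrices are assembled from
steady-state propensity fluxes scaled by $1/\Omega$. The Gaussian channel
takes the stationary variance of $Z_1$ as signal power with unit noise
variance, $C = \frac12 \ln(1 + \sigma^2)$ — a documented convention
(`awgnCapacity()` accepts any noise power). Whether load lowers the output
variance is left as a recorded observation, not an assertion:
`runLnaSuite()` writes the sign of $\sigma_0^2 - \sigma_N^2$ per row, and
at unit rates the two-species Lyapunov solve in fact gives
$\sigma_N^2 > \sigma_0^2$, so the speculation that load subtracts a
positive constant from the variance is not supported by this reduction.

Steady states of the MIMO systems are found by a damped Newton iteration
with numerical Jacobian, started from the interior of the conservation
polytope (a quarter of each total), residual tolerance $10^{-10}$; the
scalar loaded-SISO equation is bracketed on $[0, I_{tot1}]$.

# Stochastic-simulation oracle

`gillespie()` implements the direct method with a fixed
random-number order (waiting time first, then reaction selection), making
paths bit-reproducible by seed. Validation uses the time-averaged
occupancy of one long trajectory rather than many endpoint samples: on the
closed class the chain is ergodic, so both estimate the stationary law,
and time averaging is far cheaper. Defaults: burn-in 10% of the horizon,
20 equal-time batches. The agreement yardstick is total variation distance
against the exact stationary law, compared to three batch-means standard
errors; since the distance is half a sum of absolute deviations, its
standard error is bounded through the triangle inequality by half the sum
of per-state batch-means errors — a deliberately conservative bound, so
"within 3 SE" is a strict test that does not loosen as the state space
grows. Fixture horizons of 2000 time units at unit rates (roughly 3–4
thousand events) put the distance near 0.02 with 3 SE near 0.05.

# Synthetic parameter generation

`sampleRates()` draws rate sets log-uniformly — the claims under test span
ratios over orders of magnitude ($c_2 \to 0$ and $c_2 \to \infty$ limits),
so a linear prior would concentrate all draws in one decade. Defaults:
catalytic rates in $[10^{-2}, 10^2]$, downstream dissociation constants in
$[10^{-1}, 10]$, fast-binding multipliers in $[10^2, 10^4]$ above the
catalytic scale (so the regime constraint
$\min(k_0^+, k_0^-) \ge 100 \max(c_1, c_2)$ holds on every draw, and is
re-validated per draw rather than trusted). $\Omega$ defaults to 1 in the
count-regime fixtures and is swept over $\{1, 10, 100\}$ in the
volume-scaling tests. The generator emulates parameter and symbol-prior
diversity only; there is no wet-lab noise or measurement model to emulate,
so passing tests speak to the mathematics of the models, not to fit
against experimental data.

Ensemble sizes in the shipped suites: 100 seeded draws for the closed-form
ordering battery and the mean-identity battery, 5 CME-backed draws for the
$B \le G$ comparison (each requires a loaded-MIMO stationary solve), and a
three-rung fast-binding ladder — sizes chosen so the whole suite stays in
the tens of seconds while every claim is exercised across its regime.

# Known limitations

- Only the five wired topologies are validated surfaces; the reaction
  engine underneath is generic mass action, but arbitrary user networks
  are out of scope.
- The exact engine is for the one-molecule alphabet; larger totals
  enumerate combinatorially (a configurable `maxStates` guard errors
  early).
- Closed forms are asymptotic in the fast-binding regime; at generic rates
  the exact solver is the authority and the experiment drivers enforce a
  regime-dependent cross-engine tolerance.
- Time-dependent (transient) solutions, moment closures, tau-leaping and
  spatial effects are deliberately absent.
- The high-count variance analysis for MIMO and multiple-access layouts is
  numeric only; no closed forms are claimed.
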