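# retromi

Retroactivity — the load that downstream binding sites exert back on the
signaling circuit that drives them — is the biomolecular analogue of
impedance in electrical circuits. `retromi` quantifies what that load costs
in *information*: how many nats per symbol an enzymatic signaling circuit
can push from its input to its steady-state output, and how that number
degrades as downstream targets are connected. It is written for systems and
synthetic biologists who want communication-theoretic numbers (mutual
information, channel capacity) for small signaling motifs, and for
molecular-communication researchers who want an exact, reproducible
reference implementation.

## The model

The upstream system is a two-step enzymatic cycle

    I1 + E  ⇌(k0+, k0−)  M1  →(c1)  E + Z1,     Z1 →(c2) I1

with conservation laws `Etot = E + M1` and `Itot1 = I1 + M1 + Z1 (+ ΣCj)`.
Each downstream target is a reversible binding site
`Z1 + Dj ⇌(k3j+, k3j−) Cj` with `Dtotj = Dj + Cj`. Five topologies are
supported: the isolated SISO cycle, the SISO cycle loaded by N sites
(a broadcast layout), an isolated two-input MIMO circuit sharing one
enzyme, the MIMO circuit with N sites on its first output, and two
independent SISO circuits sharing a pool of N sites of which the first
claims Q (a multiple-access layout).

In the low molecular count regime (one input molecule: concentration
on–off keying), the stationary chemical master equation is solved exactly
on the enumerated microstate space. Because input symbol 0 cannot produce
any output, every topology induces a **Z-channel** with joint pmf

    P(I1(t0), Z1(ts)) = [ P01        0          ]
                        [ A·P11      (1−A)·P11  ]

where `A = P(Z1 = 0 | I1(t0) = 1)` is the retroactivity constant. Closed
forms are provided in the fast-binding regime, e.g.

    A0 = (1 + k0)·c2 / (c1 + (1 + k0)·c2),
    AN = 1 − c1 / [ (1 + k0)·c2 + (1 + Σj 1/k3j)·c1 ],

with `k0 = k0−·Ω/k0+`, `k3j = k3j−·Ω/k3j+`. Mutual information,
Z-channel capacity `C = log2(1 + (1−A)·A^(A/(1−A)))` bits, a
Blahut–Arimoto oracle and dual Kullback–Leibler capacity bounds follow. In
the high molecular count regime, the linear noise approximation gives
steady-state means from the rate equations and stationary covariances from
a Lyapunov equation, feeding a Gaussian-channel capacity `½·ln(1 + σ²/σn²)`.
A Gillespie simulator validates the exact solver throughout.

## Worked example

```r
library(retromi)

rates <- rateParameters(1, 1, 1, 1, k3Plus = rep(1, 2), k3Minus = rep(1, 2))
m <- buildModel("SISO_N_DOWNSTREAM", rates, nDownstream = 2)
channelFromCME(m, P01 = 0.5)
#> ZChannel: A = 0.833333  P01 = 0.5
#>      output
#> input        0        1
#>     0 0.500000 0.000000
#>     1 0.416667 0.083333

runMiVsLoad(experimentConfig(nMax = 3L))
#>               model N Q A_analytic  A_cme      MI capacity
#> 1 SISO_N_DOWNSTREAM 0 0     0.6667 0.7500 0.09560  0.10027
#> 2 SISO_N_DOWNSTREAM 1 1     0.7500 0.8000 0.07488  0.07874
#> 3 SISO_N_DOWNSTREAM 2 2     0.8000 0.8333 0.06156  0.06483
#> 4 SISO_N_DOWNSTREAM 3 3     0.8333 0.8571 0.05226  0.05511
#> 5      TWO_SISO_MAC 3 0     0.6667 0.7500 0.09560  0.10027
#> ...
```

Reading the numbers: at unit rates the unloaded circuit already loses most
of the input's 0.693 nats (A = 3/4, MI ≈ 0.096 nats) because the recycling
reaction keeps consuming free output. Each added downstream site pushes A
toward 1 and the mutual information down — retroactivity costs information
monotonically. The multiple-access rows show the mitigation: with a second
upstream system claiming some of the pool, the first circuit at Q sites
behaves exactly like a broadcast circuit with only Q targets, so sharing
the pool (Q < N) always beats carrying the full load. The `A_analytic`
column is the fast-binding closed form; at unit rates (binding no faster
than catalysis) it sits below the exact `A_cme`, and the gap closes as
`k0± / c` grows (see the fast-binding ladder in the tests).

The high-count counterpart:

```r
runLnaSuite(experimentConfig(nMax = 5L, omegaGrid = 1))
# muN == mu0 (load leaves the mean untouched), variances scale as 1/omega
```

## Layout

- `R/` — reaction networks, CME engine, information metrics, closed-form
  constants, LNA engine, Gillespie oracle, synthetic parameter generator,
  experiment drivers.
- `tests/testthat/` — unit, property and end-to-end suites (hand-solved
  chains, eigen-decomposition and Blahut–Arimoto oracles, fast-binding
  ladders, ordering batteries).
- `vignettes/retroactivity-information.Rmd` — the methods vignette: model
  assumptions, parameter regimes, numerical choices, limitations.
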