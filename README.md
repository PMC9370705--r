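# sfkin — stopped-flow fluorescence kinetics of sequential enzyme mechanisms

`sfkin` is an R package for pre-steady-state kinetic analysis of
enzyme–DNA interactions observed by stopped-flow fluorescence, built
around the repair of alkylated DNA bases (N1-methyladenine,
N3-methylcytosine, 1,N6-ethenoadenine) by the human dioxygenase ALKBH2.
It is aimed at enzymologists who record multi-phase fluorescence traces
under single-turnover conditions and want rate constants for each
elementary step of the mechanism.

## The model

A mechanism is a sequential chain

```
E + S <=> C1 <=> C2 <=> ... <=> Cn  [-> EP  [<=> E + P]]
```

with a bimolecular association step (k1, M⁻¹s⁻¹), unimolecular
isomerizations (k±i, s⁻¹), an optional irreversible chemistry step (k_r)
and an optional product-release equilibrium parameterized by its
dissociation constant K_d. Trajectories come from stiff mass-action ODE
integration (compiled right-hand side; free species reconstructed from
conservation totals, so mass balance is exact). The recorded signal is a
linear observation model

F(t) = F_b + Σᵢ fᵢ·[Xᵢ](t)

over the species carrying the fluorophore, with the free labeled species
anchored at 1 a.u./µM. Global fits share rate constants and coefficients
across a concentration series (backgrounds per trace), profile the linear
parameters out by weighted least squares, and search the log rate
constants by multi-start Levenberg–Marquardt with an iterated-local-search
polish. Model complexity is chosen by sequential complication: schemes of
increasing depth are fitted until an extra step is no longer justified by
a nested F-test (α = 0.05) with decisive AIC improvement (ΔAIC > 10).

Alongside the trace machinery: the quadratic (tight-binding) titration
isotherm for K_d estimation, the composite association constant
K_a^SF = K1(1 + K2(1 + K3)), the observed dealkylation rate
k_obs = V0/[ES], half-conversion times ln2/k_obs, and a seeded
synthetic-data generator with lesion-like reference parameter sets
("m1A-like", "m3C-like", "epsilonA-like") for validation by parameter
recovery.

## Worked example

Simulate a two-step ("m3C-like") concentration series at 1% noise and
recover its mechanism and rate constants:

```r
library(sfkin)

p <- kinetic_preset("m3C-like")          # scheme + truth rates + observation
g <- generate_sf_series(p$scheme, p$rates, p$obs, seed = 42)
sel <- select_scheme(g$series, 3, fit_options(n_starts = 4, seed = 11))
sel$table
#>   n_reversible n_par         sse       aic p_vs_simpler selected
#> 1            1     8 0.034790887 -46402.04           NA    FALSE
#> 2            2    11 0.008073938 -52216.99    0.0000000     TRUE
#> 3            3    14 0.008068540 -52213.65    0.4477914    FALSE
sel$fit
#> Global stopped-flow fit: 2 reversible steps
#>   SSE 0.00807394 over 3985 points, 11 parameters, AIC -52217.0
#>      estimate       se multistart_sd
#> k1  2.314e+06 1.87e+04      1.44e+01
#> k2  2.001e+00 7.07e-02      3.27e-05
#> km1 1.004e+01 5.58e-02      1.10e-05
#> km2 2.015e+00 4.43e-02      3.71e-05
```

The one-step scheme is rejected (huge SSE drop on complication), the
three-step scheme is not justified (p = 0.45), and the four rate
constants land within 1% of the generating truth
(k1 = 2.3e6 M⁻¹s⁻¹, k−1 = 10 s⁻¹, k2 = 2 s⁻¹, k−2 = 2 s⁻¹). The
composite association constant of the recovered mechanism,

```r
association_constant_sf(sel$fit$rates, 2)
#> [1] 462715.8
```

is the affinity accumulated over binding and isomerization
(truth: 4.6e5 M⁻¹), and `half_time(0.0037)` returns the 187 s
half-conversion time corresponding to a slow demethylation rate of
0.0037 s⁻¹.

The numbered scripts under `analysis/` run the full workflow — simulate
series (`01`), globally fit and select the scheme (`02`), fit equilibrium
titrations (`03`), tabulate derived constants (`04`) — writing tables
under `results/`.

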