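---
title: "Pre-steady-state kinetics of sequential enzyme mechanisms from stopped-flow fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-steady-state kinetics of sequential enzyme mechanisms from stopped-flow fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfkin)
```

## The problem

A DNA-repair dioxygenase such as ALKBH2 meets its alkylated substrate,
bends the duplex, flips the damaged base into the active-site pocket,
hydroxylates it, and lets the repaired product go. Each of those events is
a step in a sequential kinetic mechanism, and each changes the local
environment of some fluorophore — tryptophan in the protein,
2-aminopurine or a FAM/BHQ1 FRET pair in the DNA, or an intrinsically
fluorescent lesion such as 1,N6-ethenoadenine. A stopped-flow instrument
mixes enzyme and substrate within a millisecond and records fluorescence
over five to six decades of time, so the consecutive conformational
transitions appear as distinguishable phases of the signal.

`sfkin` turns those recordings into rate constants. It provides

* a parametric family of sequential mass-action mechanisms,
* a stiff ODE simulator mapping mechanisms to fluorescence traces,
* global multi-start least-squares fitting of concentration series,
* model selection by sequential complication,
* quadratic-isotherm fitting of equilibrium titrations,
* closed-form derived constants, and
* a seeded synthetic-data generator used to validate all of the above by
  parameter recovery.

## The mechanism family

Every mechanism is a chain

$$E + S \rightleftharpoons C_1 \rightleftharpoons C_2 \rightleftharpoons
\cdots \rightleftharpoons C_n \;[\rightarrow EP\;
[\rightleftharpoons E + P]]$$

with one bimolecular association step ($k_1$, 1/M/s), $n-1$ unimolecular
isomerizations ($k_i$, $k_{-i}$, 1/s), an optional irreversible chemistry
step ($k_r$), and an optional product-release equilibrium. Three members
of the family describe the lesions studied by stopped-flow fluorescence:
a five-step scheme (three reversible steps, chemistry, release) for
N1-methyladenine, a two-step binding/isomerization scheme for
N3-methylcytosine, whose slow chemistry is invisible on the stopped-flow
timescale, and a four-step scheme for 1,N6-ethenoadenine.

Only the ratio of the product-release rates is identifiable from such
data, so release is parameterized by its equilibrium dissociation constant
$K_d$ with the dissociation rate fixed at 100 1/s (configurable); the
association rate is derived as their ratio. Product rebinding is allowed
by default — the release step is a true equilibrium — because traces
extending to 550 s otherwise misrepresent the post-catalytic plateau; a
one-way release is obtained by setting $K_d$ large.

Internally all concentrations are molar and time is in seconds; files and
user-facing arguments use micromolar, converted only at the I/O boundary.

## Integration and conservation

`integrate_scheme()` propagates only the complex species with a stiff
solver (`deSolve::lsoda`, compiled right-hand side) and reconstructs free
enzyme and substrate from the conservation totals. Both mass balances
therefore hold to rounding error at every reported time — not merely to
integrator tolerance — which the test suite checks at the 1e-9 relative
level. The full-state mass-action derivative is kept as `mass_action_rhs()`
and cross-checked against the reduced system.

Tolerances default to 1e-12 M absolute and 1e-9 relative. The relative
tolerance is deliberately one decade tighter than the coarsest setting
that visually reproduces the traces: on the 550-second split-window grid
the accumulated error at 1e-8 reaches the order of 1e-6 relative, which
would be within a decade of the noise floor of a 0.1%-noise experiment
and fails a halving-refinement check at the 1e-6 level. At 1e-9 the
solution is refinement-stable with margin, at negligible cost.

## The observation model

Fluorescence is modeled as background plus a linear combination of the
species that contain the labeled molecule,

$$F(t) = F_b + \sum_i f_i\,[X_i](t),$$

with specific-fluorescence coefficients $f_i$ in a.u./µM. With an
arbitrary instrument scale the absolute coefficients are not identifiable
— doubling all $f_i$ and halving the implied concentrations scale is
invisible — so the free labeled species is anchored at 1 a.u./µM and the
per-trace background $F_b$ absorbs static offsets. The coefficients then
describe only the part of the fluorescence that changes upon binding,
which is also how such fits are reported in practice. The fluorophore
type (Trp, aPu, FRET, ethenoadenine) does not change the mathematics,
only which molecule carries the label and the expected signs of the
transitions; it travels through as metadata.

## Global fitting

`fit_traces()` estimates the rate constants of a candidate scheme from a
whole concentration series at once: rate constants and fluorescence
coefficients are shared across traces, backgrounds are per-trace. Two
structural choices matter:

**Variable projection.** For fixed rate constants the model is linear in
$F_b$ and the $f_i$, so those are profiled out by weighted linear least
squares at every candidate point. The nonlinear search runs only over the
log rate constants — four dimensions for the two-step scheme, eight for
the five-step one — which is dramatically better conditioned than the
joint problem.

**Physically typed bounds.** Optimization uses box bounds in log space,
per parameter class: 1e4–1e9 1/M/s for the association rate (the upper
end at the diffusion limit), 1e-4–1e4 1/s for isomerizations, 1e-5–1e2
1/s for the chemistry step, and 1e-9–1e-3 M for the product-complex
$K_d$. A single generic box spanning all classes admits spurious boundary
minima (for instance an association rate of 1e9 1/M/s paired with a
molar-scale $K_d$) that can defeat any practical number of random starts
on the five-step problem; the typed bounds remove those regions while
comfortably containing every plausible estimate.

The optimizer is Levenberg–Marquardt (`minpack.lm`) with a
finite-difference step (`epsfcn = 1e-6`) chosen to sit well above the
integrator's noise floor, multi-start (default 5 starts: one heuristic or
warm start, the rest log-uniform within the start ranges), followed by an
iterated local search: the incumbent optimum is jittered in log space
(SD 0.6) and re-optimized, keeping improvements, five times by default.
The jitter phase is what reliably escapes the shallow local minima of
multi-phase kinetic landscapes; with it, the noise-free five-step
benchmark recovers all eight generating parameters exactly. All
randomness derives from the seed in `fit_options()`, so identical options
give bit-identical fits.

Residuals are weighted so that each acquisition window contributes
equally (per-point weight inversely proportional to the number of points
in the window); otherwise the dense millisecond window dominates the
fit. With the default grid of equal points per window this reduces to
uniform weighting.

Parameter uncertainty is reported two ways, mirroring the practice of
quoting the dispersion over fitting iterations: asymptotic standard
errors from the Gauss–Newton curvature at the optimum, and the standard
deviation of estimates across converged multi-start runs that reached the
optimal SSE within 0.1%.

## Scheme selection by sequential complication

`select_scheme()` fits a nested ladder of schemes — 1, 2, …,
`max_reversible` reversible steps, each warm-started by embedding the
previous optimum with the new step switched off — and stops at the first
rung whose successor is not justified. A complication is accepted only
when the nested F-test rejects the simpler model at $\alpha = 0.05$
**and** the AIC improves by more than 10. The decisive-AIC requirement is
deliberate: a series holds thousands of points, where an F-test at 0.05
together with the conventional ΔAIC > 2 accepts SSE improvements of
~0.2% — the size of improvement three extra parameters extract from pure
noise — and replicate experiments show such gates over-complicate roughly
one series in ten. Genuine complications in these data improve AIC by
hundreds to thousands, so the stricter gate costs no power. The ladder
also stops once the simpler model already fits at numerical precision
(weighted RMS residual below 1e-6 of the signal RMS), where further SSE
ratios reflect integrator noise rather than evidence.

## Equilibrium titrations

At micromolar protein concentrations the free-ligand approximation fails,
so titrations are fitted with the quadratic single-site isotherm: the
complex concentration is the smaller root of
$[EP]^2 - (e_0 + p_0 + K_d)[EP] + e_0 p_0 = 0$ and the fluorescence is
$F = F_0 + f_1(e_0 - [EP]) + f_2[EP]$. A published typeset arrangement of
this formula that does not reduce to the free-protein fluorescence at
zero ligand is retained behind `variant = "as_printed"` for traceability
against literature fits; the canonical form is the default. $F_0$ and
$f_1$ are jointly unidentifiable from a single series, so $F_0$ is fixed
at zero and $f_1$ carries the free-protein signal. $K_d$ is profiled on
the log scale with the linear parameters solved exactly, then polished by
Levenberg–Marquardt for standard errors. No titrant-dilution correction
is applied.

## Derived constants

The composite association constant over the reversible steps is the
nested product $K_a^{SF} = K_1(1 + K_2(1 + K_3))$ with
$K_i = k_i/k_{-i}$, truncated to the available steps; it equals the
sum-of-products expansion $K_1 + K_1K_2 + K_1K_2K_3$ identically, which
the tests verify against an independent evaluation on random draws. The
observed single-turnover dealkylation rate is the initial gel-assay
velocity over the equilibrium pre-catalytic complex concentration,
$k_{obs} = V_0/[ES]$ with $[ES]$ from the quadratic root using
$K_a^{SF}$; a printed plus-root variant that algebraically equals
$V_0[ES]/(e_0 s_0)$ is kept behind a flag, with the verbal definition of
the quantity taken as authoritative. Half-conversion times are
$\ln 2/k_{obs}$.

## The synthetic-data generator

Since no raw traces are publicly deposited, validation rests on synthetic
data with the statistical structure the analysis assumes:

* the single-turnover design — fluorescent component fixed at 1.5 µM,
  counterpart at 0.5, 1, 2, 3, 5 µM;
* the split-window log grid, 1–100 ms, 0.1–1 s, 1–50 s, 50–550 s, 200
  points per window (instrument outputs do not state the count; 200 is a
  typical oscilloscope depth per window);
* additive Gaussian noise, defaulting to 1% of each trace's dynamic range
  (the studies do not report noise magnitudes; 1% of range is routine for
  averaged stopped-flow fluorescence);
* product time courses over a 120-minute incubation, and titration series
  optionally averaged over three replicates.

Reference truth sets `"m1A-like"`, `"m3C-like"` and `"epsilonA-like"`
bundle a scheme, rate constants and observation model per lesion. Their
rate constants are anchored to text-reported values — the step-2 pairs,
the chemistry rates, the product-complex dissociation constants, and the
first-step and composite equilibrium ratios (e.g. $2.3\times 10^5$ and
$4.6\times 10^5$ 1/M for the m3C mechanism, $8.6\times 10^5$ and
$1.9\times 10^6$ 1/M for the ethenoadenine one) — with the remaining
degrees of freedom (individual first-step magnitudes, observation
coefficients) chosen once for plausible stopped-flow timescales and
documented as synthetic. Every generator returns a machine-readable truth
record, and recovery tests compare fits to that record, never to
published figures.

What the generator deliberately omits: photobleaching and drift,
autocorrelated instrument noise, inner-filter effects, and spectral
overlap between fluorophores. Passing recovery tests therefore
demonstrate identifiability and correctness of the estimation machinery
under the stated noise model, not robustness to instrument artifacts
real data may carry.

## Interfaces

The package functions are the interface: `analysis/01…04` under the
repository root are thin narrative drivers that simulate series, fit
them, and tabulate derived constants into `results/`. Traces travel as
CSV files (`time_s`, `fluorescence_au`) listed in a manifest
(`file, e0_uM, s0_uM, fluorophore`); fit reports are JSON with a flat CSV
parameter table, with deterministic field order so identical fits
serialize identically.

## Problem sizes and numerical choices

The validation experiments use 20 replicate series of 5 traces × ~800
points for recovery and selection-accuracy rates, 100 random draws for
the equilibrium-consistency property, 1000 draws for the algebraic
identity of the composite constant, and 20 seeds per dissociation
constant for titration recovery; unit tests use reduced 40-point windows,
which preserve every qualitative feature at a fraction of the cost. Ties
and degenerate inputs fail loudly: schemes reject impossible flag
combinations, traces with non-monotone time or non-finite signal are
named row-by-row, constant-signal titrations are refused, and an
all-starts-failed fit raises an error carrying per-start diagnostics.

## Known limitations

Branched or parallel pathways, substrate inhibition, explicit cofactor
binding, multi-site or competitive titrations, and Bayesian uncertainty
quantification are out of scope. The F-test used for nesting is exact
only for linear models; for these nonlinear fits it is the usual
approximation, and the decisive-AIC gate is the practical safeguard.
Standard errors from the Gauss–Newton curvature understate uncertainty
when parameters are near bounds or weakly identified — the multi-start
dispersion column is the more honest indicator there.
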