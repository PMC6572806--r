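---
title: "Modelling nitrogen cycling in oligotrophic deep-sea sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nitrogen cycling in oligotrophic deep-sea sediments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sednitro)
```

## The system

More than half of the ocean floor is covered by organic-poor (oligotrophic)
sediments in which oxygen penetrates metres to tens of metres and nitrate is
present throughout. Where the underlying basaltic crust hosts a
hydrologically active, oxygenated aquifer, the sediment column receives
oxygen from *both* boundaries: the bottom seawater above and the crustal
fluids below. The oxygen profile is then C-shaped, with an anoxic core
bounded by an oxic–anoxic transition zone (OATZ) on its way down and an
anoxic–oxic transition zone (AOTZ) below it, and the nitrate profile is
roughly its mirror image, accumulating above the concentrations of either
boundary because nitrification outpaces carbon-starved denitrification.

`sednitro` models this system end to end: a steady-state
reaction–transport model of the porewater and solid-phase chemistry,
Fick's-law flux budgets and transition-zone detection, conversion of
volumetric reaction rates and gene abundances into cell-specific metabolic
rates and biomass turnover times, community statistics for the
transition-zone "resurrection" of surface taxa, and a synthetic-data
generator with known ground truth against which every step is tested.

## The reaction–transport model

Six species are tracked: two solids — organic matter (OM) and MnO~2~ —
advected downward with burial, and four solutes — O~2~, NO~3~^−^,
NH~4~^+^, Mn^2+^ — transported by molecular diffusion. Five reactions
connect them: three primary organic-matter oxidation pathways and two
secondary reoxidation reactions,

$$
\begin{aligned}
R_1 &= k_{OM}\,[OM]\,\frac{[O_2]}{K_{O_2}+[O_2]} &&\text{aerobic respiration}\\
R_2 &= k_{OM}\,[OM]\,\frac{[NO_3]}{K_{NO_3}+[NO_3]}\,\frac{h_1}{h_1+[O_2]} &&\text{denitrification}\\
R_3 &= k_{OM}\,[OM]\,\frac{[MnO_2]}{K_{MnO_2}+[MnO_2]}\,\frac{h_2}{h_2+[O_2]}\,\frac{h_3}{h_3+[NO_3]} &&\text{Mn reduction}\\
R_4 &= k_{nit}\,[NH_4][O_2] &&\text{nitrification}\\
R_5 &= k_{mnox}\,[Mn^{2+}][O_2] &&\text{Mn$^{2+}$ oxidation}
\end{aligned}
$$

with Monod limitation on each electron acceptor and hyperbolic inhibition
by the energetically preferred oxidants; $h_1$ is the O~2~ level at which
the denitrification inhibition factor equals one half. Stoichiometry per
mol C oxidised: $R_1$ consumes 1 O~2~; $R_2$ consumes 4/5 NO~3~^−^; $R_3$
consumes 2 MnO~2~ and releases 2 Mn^2+^; all three release $r_N = 16/106$
NH~4~^+^ (Redfield). $R_4$ consumes 1 NH~4~^+^ and 2 O~2~ and produces
1 NO~3~^−^; $R_5$ consumes 1 Mn^2+^ and ½ O~2~.

Each solute obeys, at steady state,
$$
0 = \frac{d}{dz}\!\left(\varphi D_s \frac{dC}{dz}\right)
  - \frac{d(\varphi v C)}{dz} + \sum_j \nu_j R_j ,
$$
with the reaction rates expressed per unit volume of *total* sediment (the
units the rates are reported in), so no additional porosity factor
multiplies the source term; the advection term is off by default because
burial ($10^{-5}$ m yr^−1^) is negligible against diffusion on these length
scales, and can be enabled in the configuration. Solids obey the
advection–reaction analogue. The tortuosity correction is
$D_s = D_0/(1-\ln\varphi^2)$, and the free-solution $D_0$ come from the
standard linear seawater fits evaluated at the configured temperature
(1.5&nbsp;°C by default). The bimolecular constants $k_{nit}$ and
$k_{mnox}$ are defined such that $k\,[A\,\mu M][B\,\mu M]$ is a rate in
$10^{-3}$ mol m^−3^ (total sediment) yr^−1^, i.e. they absorb porosity;
this keeps `reaction_rates()` a pure function of concentrations and rate
constants.

Boundary conditions: Dirichlet concentrations for all solutes at both
boundaries (bottom-seawater values above, crustal-fluid values below, with
nitrate 21.1&nbsp;µM in the basement fluid); organic matter enters as a
prescribed depositional flux at the seafloor and leaves by burial at the
base (zero-gradient), MnO~2~ analogously; NH~4~^+^ and Mn^2+^ default to
zero at both boundaries. The default burial velocity spreads the column
over 8&nbsp;Myr of deposition.

### Discretization and solver

Node-centred finite volumes on a uniform grid; central differences for
diffusion, first-order upwind for the (slow) burial advection. The
discrete nonlinear system is solved by damped Newton iteration — with a
finite-difference Jacobian assembled in banded column groups, since the
coupling is within-node plus nearest-neighbour — to a normalized residual
of $10^{-10}$, where each equation is scaled by the magnitude of its
dominant transport or source term. When the steady problem is too far
from the initial guess (linear solute profiles, advective solid
profiles), the solver falls back to pseudo-transient continuation:
implicit Euler steps whose time step grows geometrically until plain
Newton converges from the current iterate. Rate evaluations clamp
negative trial concentrations to zero; a converged solution with
concentrations below $-10^{-6}$ of the species scale is rejected rather
than silently clamped. Non-convergence is always flagged, never returned
as a solution.

The suite verifies the solver against two closed forms (zeroth-order and
first-order consumption of a single solute), against an independent
transient integration (`deSolve::lsoda` run to $3\times10^7$ yr on the same
discretization), by grid-refinement order, and by per-species mass-balance
closure, in which boundary fluxes from one-sided three-point derivatives
are compared with trapezoidal quadrature of the net reaction sink — two
estimates that agree only up to discretization error, so the closure
residual is a genuine accuracy diagnostic (≤1% for every species at 200
nodes on the shipped scenario).

### Parameters of the shipped scenario

The `northpond_like` configuration describes an 80&nbsp;m oligotrophic
ridge-flank column, porosity 0.7, oxygenated from above (250&nbsp;µM) and
below (160&nbsp;µM):

| parameter | value | units | rationale |
|---|---|---|---|
| `k_OM` | 3.3e-8 | 1/yr | single-pool decay of highly refractory OM; sets O~2~ penetration ~30 m from each boundary |
| OM flux | 1.5e-3 | mol C m^−2^ yr^−1^ | gives ~0.23 wt% TOC, inside the <0.3% observed range |
| `K_O2` | 1 | µM | high O~2~ affinity of deep-sediment aerobes |
| `K_NO3` | 700 | µM | *effective* value, see below |
| `h1` | 10 | µM | denitrification proceeds even at sub-oxic O~2~ |
| `h2`, `h3` | 1, 5 | µM | Mn reduction suppressed by O~2~ and NO~3~^−^ |
| `k_nit` | 6e-6 | 1/(µM yr) | nitrification fast relative to transport but with a reaction length (~2–3 m) resolved by the grid |
| `k_mnox` | 2e-6 | 1/(µM yr) | likewise for Mn^2+^ oxidation |
| `rN` | 16/106 | mol N/mol C | Redfield |

The large effective `K_NO3` deserves an honest paragraph. With a single
OM pool, the organic matter that survives aerobic burning arrives in the
anoxic core with its full (already tiny) reactivity `k_OM`, and a
µM-scale `K_NO3` would let denitrification consume the accumulated
nitrate there, flattening the interior maximum to ~35&nbsp;µM. In real
sediments the OM reaching that depth is millions of years old and far
less reactive than the pool average — the effect a multi-G or
reactive-continuum model would capture, but multi-G kinetics are outside
this package's scope. The nitrate half-saturation is therefore used as
the effective throttle on deep denitrification, chosen once so that the
simulated column reproduces the observed 40–50&nbsp;µM interior nitrate
maximum while denitrification remains active throughout (its
depth-integrated rate is still highest in the anoxic zone). Every
parameter is exposed in the YAML configuration, so users preferring a
literal `K_NO3` with their own OM model can set one.

### The h1 sensitivity fit

`fit_h1()` refits the O~2~-inhibition constant by grid search (typically 25
log-spaced candidates on 0.01–50&nbsp;µM), solving the column per candidate
(warm-started from the previous solution) and scoring a range-normalized
RMSE: per observed species, the model is interpolated to the observed
depths, the RMSE is divided by the observed concentration range, and
species are weighted equally. The objective is deliberately simple — the
fit mirrors a sensitivity analysis, not a formal inversion — and the full
misfit curve is returned so the flatness of the optimum is visible.
Candidates that fail to converge are recorded as missing rather than
aborting the scan. On profiles simulated from the scenario's own truth
with 2% multiplicative noise, the grid minimizer recovers the generating
h1 within one grid step (median over 10 seeds).

## Flux budgets and transition zones

`fick_flux()` computes $J = -\varphi D_s\, dC/dz$ with the gradient from a
least-squares line through the `n_points` samples nearest the interface on
one side. The default window of 3 points reflects the coarse sampling
typical of the uppermost sediments; with sparse data the steepest
near-interface curvature is underestimated, so these fluxes are minimum
estimates — the window is an argument and is recorded in the output.
Below-detection values enter the fit as half the detection limit and flag
the estimate. Positive flux is downward everywhere in the package.

`detect_transition_zones()` follows the oceanographic convention: the OATZ
spans the downward crossing of 10&nbsp;µM O~2~ to the subsequent crossing
of the 3&nbsp;µM detection limit; the AOTZ spans the upward crossings in
the opposite order. Boundaries are linearly interpolated between
bracketing samples. Noise chatter around a threshold is collapsed by
keeping the innermost bracketing pair, and zones narrower than the median
sample spacing (configurable) are discarded with a note.

## Cell-specific rates and metabolic state

Bulk volumetric rates are converted to per-cell rates by dividing by the
gene-derived cell density: nitrification (R~4~) by archaeal + bacterial
*amoA*, denitrification (4/5&nbsp;R~2~, the nitrate actually consumed) by
*nirK* + *nirS*, and O~2~ consumption (R~1~ + 2R~4~ + ½R~5~) by total 16S
— the pairing is an argument (`process_markers`), and dividing by AOA
*amoA* alone is a one-line change. Copies are converted to cells with a
wet bulk density of 1.7&nbsp;g cm^−3^ (typical deep-sea pelagic clay,
configurable) and one gene copy per genome by default; since genomes may
carry several copies, the densities are upper bounds and all cell-specific
rates are minimum estimates. Electron normalization uses 4 e^−^/O~2~,
8 e^−^/NH~4~^+^ for nitrification to nitrate (6 available for the
ammonia-oxidation step alone), 5 e^−^/NO~3~^−^ for denitrification to
N~2~, and 2 for nitrate reduction to nitrite. Carbon metabolic rates
assume 10 mol NH~4~^+^ oxidised per mol C fixed and 14&nbsp;fg C per
cell; turnover time is the exact reciprocal of the rate. A year is
365.25 d and carbon is 12.011 g/mol throughout.

Metabolic-state classification compares log10 rate against user-supplied
survival and growth threshold lines in temperature; the package ships no
coefficients because the published threshold curves are read off figures,
not printed — with no curves the state is omitted, never guessed. A rate
exactly on a line is assigned upward (survival line → maintenance).

## Community statistics

Rarefaction subsamples reads without replacement to a fixed depth
(1000 by default) with an explicit seed; samples below the depth are
dropped with a message. Its mean behaviour is tested against the exact
hypergeometric expectation $\sum_i 1 - \binom{N-n_i}{d}/\binom{N}{d}$
(independently cross-checked against `vegan::rarefy`). Functional groups
are assigned by exact taxon-name match at any rank of the rank-delimited
taxonomy string, because the canonical group definitions mix order-level
(Nitrosopumilales) and genus-level names; the map must be disjoint and
unmatched OTUs are pooled as "other". The reappearance statistic counts,
among OTUs detected in the surface zone and undetected in every sample of
the intervening gap zones, the fraction detected again in the target zone;
"detected" means ≥1 read, after rarefaction if requested — both rarefied
and raw modes are supported since published counts of this kind do not
always state which was used. Zone labels may come from detected O~2~
transition zones or from explicit sample metadata; explicit metadata wins.

## The synthetic-data generator

The generator emulates the study conditions with known ground truth:

* **Profiles** — the forward model solved on the shipped configuration,
  sampled at 1&nbsp;m spacing with 2% multiplicative lognormal noise
  (lognormal keeps concentrations positive); O~2~ below 3&nbsp;µM is
  flagged below-detection.
* **Abundances** — log10 copies decline linearly with depth from
  10^8^ copies g^−1^ (one decade per 30&nbsp;m for the 16S pool; faster,
  one decade per 16–22&nbsp;m, for functional genes, which fall 4–5
  decades over the column), with Gaussian peaks of up to 100-fold centred
  in the transition zones, lognormal noise, and a 10^2^ copies g^−1^
  detection limit.
* **Communities** — a log-series rank-abundance distribution (one shape
  parameter yields the realistic many-rare/few-dominant structure);
  each OTU's relative weight decays exponentially with depth at its own
  lognormally distributed rate, so richness collapses downcore while a
  persistent minority dominates at depth; in OATZ samples each OTU is
  restored to its surface weight with probability 0.75 (the planted
  resurrection signal, emitted as truth alongside the table); counts are
  multinomial at 8000 reads per sample. Every 10th abundance rank is
  labelled Nitrosopumilales so the ammonia-oxidizer subset spans the
  abundance spectrum; with ~600 OTUs this yields ~30 surface-detected
  AOA OTUs at the shipped read depth, matching the scale of the observed
  statistic.

What the generator does *not* emulate: qPCR standard-curve and extraction
biases, contamination and its removal, chimeras, primer effects,
inter-site variability, coring disturbance, or non-steady deposition
history. Tests passing on synthetic data therefore demonstrate the
correctness of the computations under the stated statistical model, not
the fidelity of that model to any particular core.

## Problem sizes and reproducibility

The shipped analyses and tests use 200 grid nodes (400 in the
grid-refinement check), 10 noise seeds for the h1 recovery, 1000
Monte-Carlo draws for the rarefaction oracle, and 5 seeds for the
resurrection recovery — sizes at which every stochastic check is stable
under seed changes. All randomness flows through explicit seeds; identical
seeds give bit-identical generator output, and `run_pipeline()` writes a
manifest of config and output digests so a run can be verified
end-to-end.

## Known limitations

Single-pool (1-G) organic matter is the model's strongest simplification
(see the `K_NO3` discussion above). Sulfur and iron chemistry,
bioturbation, bioirrigation and porosity compaction are out of scope. The
steady-state assumption means the 8-Myr deposition history is not
hindcast. The h1 fit is a grid-search sensitivity analysis, not a
posterior; parameters trading off against each other (e.g. `k_OM` against
the OM flux) are not jointly identified. Transition-zone widths on the
shipped scenario are sensitive to the calibration of total O~2~
consumption, as they are in nature.
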