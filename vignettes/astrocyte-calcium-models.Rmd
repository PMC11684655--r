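---
title: "Modeling glutamate- and dopamine-evoked calcium signaling in astrocyte compartment trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling glutamate- and dopamine-evoked calcium signaling in astrocyte compartment trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroca)
```

## The scientific question

Astrocytes do not fire action potentials; their unit of activity is the
Ca²⁺ signal, a discrete elevation of intracellular Ca²⁺. Synaptic
glutamate reaches an astrocyte only at the fine distal processes that
ensheathe synaptic terminals, whereas neuromodulators such as dopamine
arrive everywhere at once by volume transmission. `astroca` implements a
family of multi-compartment, conductance-based astrocyte models built to
ask how these two input classes interact: whether a global dopaminergic
tone changes the glutamatergic stimulation frequency needed to evoke
Ca²⁺ signals in the thinnest, most distal compartments, and whether that
interaction lets two processes of one cell communicate.

## Morphologies

A model cell is a tree of compartments: a spherical soma (radius 20 µm)
and unit-length cylinders whose radii taper from 2 µm next to the soma
to 0.0625 µm at the tip, eight cylinders per soma-to-tip path. Three
templates are built in (`build_morphology()`): *unipolar* (soma + one
process, compartments 1–9), *bipolar* (two processes from the soma,
1–17) and *bifurcated-terminal* (one primary process splitting into two
secondary processes, 1–14). Each process arm carries two proximal, three
intermediate and three distal compartments. Morphologies can also be
read from and written to 7-column SWC files.

Only the extreme radii (2 and 0.0625 µm) are fixed by the experimental
range the templates emulate; the interior schedule is a modelling
choice. The default is a monotone, two-segment taper: a geometric
descent 2 → 0.5 µm across the proximal and intermediate compartments,
then leaflet-scale radii (0.1, 0.08, 0.0625 µm) for the distal set. The
reason is the phase-plane structure of the reduced model (below): the
qualitative switch from ER-dominated to exchanger-dominated Ca²⁺
dynamics happens near a radius of 0.5 µm, and the biology this family of
models describes places that switch exactly at the transition into the
distal leaflets that contact synapses. A single geometric taper instead
smears the regime boundary over compartments 6–8 and cannot reproduce
the sharp proximal/distal division of labour. The schedule is a plain
argument (`radius_schedule`) and any monotone 8-vector can be supplied.

Two geometric quantities drive everything else. The surface-to-volume
ratio `A/V` is `3/r` for the soma and `2/r` for cylinders (lateral
surface only — the thin-process limit in which the ER relation below was
fitted; a switch includes end caps). The ER-to-cytosol volume ratio is

r_ER = a · exp(−(b · A/V)^c),  a = 0.15, b = 0.073 µm, c = 2.34,

a strictly decreasing function of `A/V`: thick compartments hold
proportionally much more ER than leaflets (r_ER ≈ 0.15 at the soma
versus ≈ 1 × 10⁻⁴ at the tip).

## The detailed compartment model

Each compartment carries twelve state variables: intracellular,
extracellular and ER Ca²⁺; IP₃; the IP₃-receptor gate `h`; intra- and
extracellular Na⁺ and K⁺; membrane potential; and the extracellular
transmitter concentrations [Glu] and [DA]. The mechanisms are the
classical ones of the astrocyte Ca²⁺-modelling literature:

* **ER fluxes** — Li–Rinzel IP₃R gating (`m∞³ n∞³ h³`, constants d₁ =
  0.13, d₂ = 1.049, d₃ = 0.9434, d₅ = 0.08234 µM, a₂ = 0.2 µM⁻¹s⁻¹), a
  Hill-type SERCA pump, and a linear ER leak.
* **Membrane transport** — an Na⁺/Ca²⁺ exchanger with Luo–Rudy kinetics
  (3:1 stoichiometry, voltage-dependent partition η = 0.35), a
  saturable glutamate transporter (3 Na⁺ in, 1 K⁺ out per cycle), an
  Na⁺/K⁺-ATPase (3:2), and ohmic Na⁺/K⁺ leaks.
* **IP₃ metabolism** — PLCβ synthesis driven by mGluR (glutamate) and
  D₁/α₁ receptors (dopamine), both with Hill-0.7 agonist dependence and
  Ca²⁺-dependent inhibition; Ca²⁺-stimulated PLCδ synthesis; degradation
  by Ca²⁺-activated IP₃-3K and by IP-5P.
* **Transmitter kinetics** — release events are instantaneous jumps
  (ρ_Glu = 0.5 µM, ρ_DA = 3 µM) with first-order decay (G_Glu = 100 s⁻¹,
  G_DA = 4.201 s⁻¹): a glutamate bolus lives ~10 ms, a dopamine bolus
  ~¼ s.

Geometry enters through the `A/V` and `A·r_ER/V` prefactors that convert
current densities (pA/µm²) into concentration rates, so a leaflet with
`A/V = 32 µm⁻¹` feels its membrane fluxes two orders of magnitude more
strongly than a proximal branch, while its ER term is suppressed by
r_ER ≈ 10⁻⁴. This single geometric fact produces the division of labour
the models exist to study: ER-driven, high-amplitude signals in thick
and intermediate compartments; weak, slow, exchanger-buffered responses
in the leaflets.

Adjacent compartments exchange every diffusible species with coupling
strength `F(j←k) = D·A_c/(V_j·δ)` (s⁻¹), where `A_c` is the contact
cross-section (π times the squared radius of the thinner compartment;
a mean-radius convention is available), and δ the centre-to-centre
distance. The form satisfies `V_j F(j←k) = V_k F(k←j)`, so diffusion
conserves mass exactly; because the somatic volume is ~3 × 10⁴ µm³, the
soma is a near-perfect sink. ER Ca²⁺ diffuses between the ER
compartments of neighbours with its own coefficient — leaflets hold
almost no store, so any sustained distal release is fed by luminal
Ca²⁺ tunnelling from the ER network, which is what gives distal signals
their characteristic low amplitude and long duration.

## Resting state by construction

Rather than hand-tuning leaks, the package solves the derived constants
so that a nominal physiological state — Ca_i 0.1 µM, Ca_e 1.8 mM, Ca_ER
120 µM, Na_i/Na_e 15/145 mM, K_i/K_e 100/3 mM — is an exact equilibrium
of every compartment regardless of geometry
(`finalize_parameters()`): resting IP₃ balances PLCδ against
degradation; the resting potential sits at the NCX reversal
`3E_Na − 2E_Ca ≈ −80 mV` so the exchanger carries no resting current;
the Na⁺ and K⁺ leak conductances absorb the resting pump flux; and the
ER leak closes the store balance. `find_rest_state()` then verifies the
equilibrium by relaxation (residual < 10⁻⁹). This construction makes
trials start from a genuine fixed point and makes conservation tests
exact.

## Stimulation protocols

`make_protocol()` implements the stimulation design: independent Poisson
trains (exact exponential inter-arrival sampling) of rate ν_g delivered
to the distal compartments of each process (one shared release site per
arm — the tripartite-synapse picture; per-compartment independent trains
are a switch), and a dopamine train of rate ν_d delivered to every
compartment (volume transmission). Trials last 100 s and start from
rest. Sub-seeds are derived per train with a counter scheme so adding a
train never changes another train's events.

## Event detection and summary measures

A Ca²⁺ signal is a local maximum of the Ca_i trace whose topographic
prominence exceeds `max(0.05 µM, 50% of baseline)`, with a 2 s minimum
separation (`detect_calcium_events()`). The two thresholds are
deliberately calibrated, not derived: they are set so that the slow
sub-threshold elevations that diffusion feeds into non-stimulated
leaflets do not count as events, while clear transients anywhere along
the process do. Summary measures follow: events per trial and mean
amplitude per compartment, activation thresholds on a frequency grid
(smallest rate with ≥ 1 event/trial in a strict majority of ≥ 5 seeds),
the complementary largest-failing rate, propagation range (contiguous
active compartments counted from the tip), and raster tables.

## The reduced two-variable model

On the seconds timescale only Ca_i and IP₃ matter; ions, voltage,
extracellular and ER Ca²⁺ relax in milliseconds. The reduced model
(`rhs_simplified()`, `nullclines()`, `find_equilibria()`,
`simulate_simplified()`) pins the fast variables at rest, holds the ER
store at its resting content, and replaces `h` by a constant average.
Drives are dimensionless: `g` and `d` are the stationary mean
transmitter concentrations ρν/G divided by calibration scales (500 µM
for glutamate, 3571.43 µM for dopamine) chosen to reproduce the
frequency–drive pairs used in the phase-plane analyses (2/5/10 Hz ↔
g = 2·10⁻⁵/5·10⁻⁵/10⁻⁴; 5/10 Hz ↔ d = 10⁻³/2·10⁻³). The printed 2 Hz
dopamine pair (5·10⁻⁴) is not consistent with linear scaling of the 5
and 10 Hz pairs; the linear map through the latter two is used.

Two reduction choices deserve emphasis, both fixed before the test
suite was frozen and documented here as the package's own decisions:

* **h_avg = 0.68.** The detailed model's gate averages 0.63–0.74 during
  distal activity; within that band 0.68 makes the reduced model's
  stability boundary coincide with the detailed model's behavioural
  boundary (oscillating compartment 7, damped 8, accumulating 9 under
  5 Hz distal drive).
* **Shot-noise averaging of receptor drive.** The Hill-0.7 occupancy is
  concave, so evaluating it at the mean concentration overestimates the
  true average over the spiky release process by about a factor of two
  at these rates. In constant-drive (phase-plane) work the PLCβ terms
  therefore use the exact dilute-pulse average, which has the closed
  form `o·(ν/G)·(10/7)·ln(1 + (ρ/K_eff)^0.7)`. Event-driven reduced
  simulations apply the instantaneous occupancy to the simulated
  transmitter states, as the detailed model does.

With these choices the (c, i) phase plane behaves as the detailed model
does: the `i` nullcline is radius-independent and far more sensitive to
glutamate than to dopamine; the `c` nullcline flips from a plateau shape
to a steep exchanger-dominated branch below ~0.5 µm radius; at a 5 Hz
glutamatergic drive the three distal compartments are an unstable focus,
a stable focus and a stable node respectively. Equilibria are located by
parametrising the `i` nullcline (monotone in `i`), bracketing the
remaining one-dimensional root in `c`, polishing with 2-D Newton steps,
and classifying eigenvalues of a central finite-difference Jacobian
(relative step 10⁻⁶; |Re λ| < 10⁻⁸ is reported as marginal). A
finite-difference Jacobian was preferred to symbolic derivatives because
the flux table is configuration-driven.

## Numerical choices

The coupled system mixes millisecond (voltage, ions) and second (Ca²⁺)
timescales, so integration uses `deSolve::lsoda` (adaptive, stiff) with
relative tolerance 10⁻⁶ and per-variable-class absolute tolerances; the
right-hand side is compiled (Rcpp) and asserted in the test suite to
agree with the plain-R reference implementation to 10⁻¹⁰. Transmitter
release is exact: the solver restarts at each Poisson event time and
applies the concentration jump as a state event, so no release is
smeared by interpolation. Output is sampled at 10–50 ms, fast enough for
transients lasting seconds. Degenerate inputs (zero rates, zero
diffusion, empty traces) are exercised in the tests.

## Parameter provenance and calibration

Physical constants, Li–Rinzel constants, transmitter kinetics and the
r_ER relation are fixed literature values. The maximal rates of the
mechanism set (IP₃R permeability, SERCA, NCX, GluT, NKA, PLCβ gains) and
the effective diffusion coefficients are not constrained by direct measurements for this exact
compartmental formulation, so they were calibrated once, as part of
model construction, against the qualitative and threshold structure the
model family is known to produce: no responses anywhere at 1 Hz distal
glutamate; distal-onset signals from about 2 Hz with compartment 9
activating at ≈ 2 Hz; dopamine effective at arbitrarily low rates with a
proximal/intermediate emphasis and a silent leaflet pair (8–9) at
0.2 Hz; and a dopamine-induced reduction of the glutamatergic threshold
(to ≈ 1 Hz at 0.1 Hz dopamine, and to ≤ 0.1 Hz at 0.5 Hz dopamine). The
calibrated defaults are the package defaults and are not per-experiment
tuning knobs; `scripts/acceptance.R` recomputes the thresholds from
scratch with exactly these defaults. Effective diffusion coefficients
(Ca²⁺ 0.8, IP₃ 2, Na⁺/K⁺ 20, transmitters 5, ER lumen 30 µm²/s) are
well below dilute-solution values, reflecting buffering, tortuosity and
organelle crowding in sub-micron processes.

The synthetic-stimulation generator's defaults are the experimental conditions
(100 s trials, distal glutamate, global dopamine, the frequency grids of
the threshold analyses, five seeds per grid cell). What passing tests
show is therefore internal: that this parameterization produces the
expected threshold arithmetic under its own stimulation statistics. They
do not show that the constants transfer to real astrocytes, whose
processes are not cylinders, whose IP₃ receptors gate stochastically,
and whose transmitters do not arrive as ideal Poisson deltas.

## Problem sizes

The test suite runs trials at full duration (100 s) but on reduced
grids and 2–3 seeds per cell (a few minutes in total); the acceptance
script uses the full grids with five seeds per cell and ascends each
grid only until the majority rule fires, since grid cells are
independent. Phase-plane computations are effectively instantaneous.

## Known limitations

* The mechanism-level maximal rates are calibrated rather than measured
  (see above), so the quantitative thresholds inherit that uncertainty. Two consequences are documented in the
  acceptance analysis: occasional single events in position-5
  compartments under 1 Hz glutamate (Poisson bursts can trigger one
  distal transient), which blurs the "quiet at 1 Hz" baseline of the
  branched-morphology experiments; and essentially zero passive
  cross-process transport, because volume dilution at the
  leaflet-to-branch junctions and the somatic sink swallow distal IP₃,
  so the bifurcated-terminal cross-process thresholds are not
  reproduced by this parameterization.
* The somatic compartment produces clear dopamine-evoked events, but its
  amplitude does not exceed the intermediate compartments' as reported
  for strong dopamine; with a frozen store and quasi-static gate the
  soma's slow orbit is amplitude-limited.
* The reduced model's dopamine column of the phase portraits is more
  fragile than its glutamate column: near the stability boundary the
  classification at d = 10⁻³ depends on the h average within its
  plausible band.
* No electrodiffusion, no spatial PDEs, no stochastic channel gating, no
  temperature dependence; neuron–astrocyte feedback and gliotransmitter
  release are out of scope.
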