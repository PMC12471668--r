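---
title: "Transition-state-theory estimation of single-channel water permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition-state-theory estimation of single-channel water permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqpflux)
```

## The model

Water permeation through an aquaporin-family channel is treated as a
thermally activated barrier crossing. A dividing plane is placed at the most
constricted point of the pore, at channel-frame coordinate $z = z_0 = 0$,
with $+z$ pointing from the intracellular (IC) to the extracellular (EC)
side. Every crossing of that plane is an elementary transition attempt. The
no-recrossing rate of transition state theory is the equilibrium one-way
Maxwell–Boltzmann flux through the plane,

$$k_0^{\mathrm{TST}} = \sqrt{\frac{RT}{2\pi m_W}}\; n(z_0),$$

where $m_W$ is the molar mass of water and $n(z_0)$ the *linear* density of
water at the plane (molecules per unit length of channel axis). Real
trajectories recross: a molecule that hops across the plane usually returns
instead of continuing to the far bulk. The transmission coefficient
$\kappa \in [0,1]$ corrects for this,

$$k_0 = \kappa \sqrt{\frac{RT}{2\pi m_W}}\; n(z_0),$$

and is measured directly by *event following*: each dividing-plane crossing
is tracked forward until the molecule either reaches the destination bulk
(success) or returns across the plane (recrossing failure); $\kappa$ is the
fraction of resolved crossings that succeed.

At equilibrium the two directional rate constants are equal, and each
transported molecule carries one molecular volume of water, so the
single-channel osmotic permeability is

$$p_f = \frac{2 k_0\, \nu_W}{N_A} \quad [\mathrm{cm^3/s}],$$

with $\nu_W$ the molar volume of water. Under an osmotic gradient the
directional rates are tilted by the solute activity factor,
$k_{I\to E} = k_{E\to I} e^{(c_e - c_i)\nu_W}$, and each is reduced by the
solute's displacement of water; the net molecular transition rate is

$$r = k_0\left[e^{\Delta c\,\nu_W}(1 - c_i \nu_W) - (1 - c_e \nu_W)\right]
  \;\approx\; 2 k_0 \Delta c\, \nu_W,$$

the linearisation being quantitatively accurate for sub-molar osmolyte
concentrations ($\Delta c\,\nu_W \ll 1$). The implied permeability
$r/(N_A \Delta c)$ then equals $2 k_0 \nu_W / N_A$ exactly, which is the
identity `osmotic_rate()` and `single_channel_pf()` preserve to floating
point. The volume flux reported alongside is $J = r\,\nu_W/N_A$.

Comparing permeabilities at two temperatures gives the apparent Arrhenius
activation energy

$$E_a = \frac{R\,T_1 \ln(p_1/p_2)}{T_1/T_2 - 1},$$

reported in kcal/mol to three decimals, the convention of the permeability
literature. Values near 3–4 kcal/mol indicate transport through aqueous
pores rather than across the bare bilayer.

### Unit conventions

`k0` is a rate in $s^{-1}$ throughout; the conversions between the
rate-constant picture and concentrations are carried explicitly by the
$\nu_W/N_A$ factors above, never folded into $k_0$. The linear density is
reported in molecules per **nm** of channel axis. A volume-density unit is
sometimes quoted for such profiles, but only a linear density gives $k_0$
units of inverse time in the flux formula, so the per-nm convention is used
and stated on every output. Internally the generator works in Å, ps, g/mol
and K (gas constant $0.8314\ \mathrm{g\,mol^{-1}\,\text{Å}^2\,ps^{-2}\,K^{-1}}$,
1 kcal/mol = 418.4 internal energy units); the public constants are in
`physical_constants()`. $\nu_W$ is held at 18.0153 cm³/mol across the
5–25 °C range — the true variation is below 0.2 %, smaller than any
statistical uncertainty here.

## The crossing-event state machine

`detect_events()` operates on stored frames, with these rules:

* An event **opens** at a sign change of $z - z_0$ between consecutive
  frames while the particle is inside the lateral gate on both frames; the
  crossing time is the later frame. Sub-frame interpolation would not change
  either count entering $\kappa$.
* An open IC→EC event **resolves** as success when $z \ge z_{\mathrm{bulk,EC}}$
  (default +15 Å), as recross when $z$ falls back below $z_0$; mirrored for
  EC→IC. A particle that exits the lateral gate while still inside the slab
  resolves as a recross-equivalent failure — it did not reach the bulk.
* While an event is open, further plane oscillations of the same particle
  open nothing; the resolving transition itself never opens a new event, but
  the very next crossing may.
* Events still open at the final frame are emitted as `unresolved` and enter
  neither the numerator nor the denominator of $\kappa$; counting them as
  failures would bias $\kappa$ downward at the end of every trajectory.

A molecule that recrosses and then tries again therefore contributes two
attempts, which is consistent with defining $\kappa$ as successes over total
dividing-plane crossings. The independent cross-check in the test suite is a
brute-force scan for complete bulk-to-bulk passages; machine successes and
brute-force traversals agree identically up to first-passage/tail edge
effects (at most one event per particle).

For the tetramers this package targets, waters are assigned per frame to the
monomer whose axis they are nearest (within `radius_gate`, default 6 Å,
ties to the lowest monomer id), events are pooled over monomers for the
per-channel estimate, and per-monomer estimates feed the uncertainty.

## Density, $n(z_0)$ and the single-file region

`linear_density()` bins molecules passing the lateral gate into half-open
bins of width 0.5 Å by default — fine enough to resolve single-file
structure (water–water spacing ≈ 2.8 Å) with more than five bins per
molecule. $n(z_0)$ is read from the bin containing the dividing plane, with
no interpolation or smoothing; a smoothed estimate can be had by rebinning,
but the raw containing-bin value is the literal realisation of the flux
formula. Monomer-averaged profiles are the bin-by-bin mean of per-monomer
profiles (the alternative — pooling counts before normalising — differs only
when monomer occupancies differ; the per-monomer-first order keeps each
channel's profile an unbiased estimate of its own occupancy).

The single-file extent is the length of the maximal contiguous run of bins
with density at or below 2.5 (in the profile's per-nm unit) that contains
the dividing-plane bin. Low linear density means waters spaced too far apart
to pass one another — the rate-limiting single-file configuration.

## Hydrogen bonds

No universally agreed geometric criterion exists; the package defaults to
the de facto MD convention — donor-heavy-atom to acceptor distance
≤ 3.5 Å and D–H⋯A deviation from linearity ≤ 30° — and both cutoffs are
recorded in every output. Single-file waters are selected per frame within a
fixed z-interval (by default the sub-threshold extent of the density
profile). Pore-lining residues, when not given explicitly, are those with
any heavy atom within 4.5 Å of a selected water in at least 1 % of frames.
Histograms are normalised per monomer and merged with frame-count weights.

## The synthetic generator

The pipeline's statistical assumptions are exercised by an inertial Langevin
model: non-interacting tagged particles in a box with reflecting walls, a
configurable axial potential of mean force over the channel slab (a Gaussian
barrier at $z=0$ and/or a tabulated curve), flat in the reservoirs. The
integrator is the BAOAB splitting, chosen because its stationary velocity
marginal is Maxwell–Boltzmann — exactly the average behind the flux
prefactor — and its configurational bias is small at the step sizes used.
An *overdamped* integrator would have no velocity distribution to test.

Defaults mirror a membrane-channel setup: box 90 Å (≈30 Å reservoirs beyond
the ±15 Å slab), water mass, dt = 0.002 ps (the MD convention),
friction 10 ps⁻¹ for liquid-like diffusivity. Positions are initialised
from the stationary Boltzmann law by rejection sampling and velocities from
the Maxwell distribution, so runs are stationary from the first frame.
Force evaluation uses a table on a 0.01 Å grid with linear interpolation
(error far below thermal noise); `simulate_langevin()` refuses to run when
$\omega\,dt$ at the stiffest point of the potential exceeds 1.5 and warns
beyond 0.5, likewise for marginal `friction * dt`.

Randomness comes from one master stream (R's Mersenne–Twister, seeded from
the spec): a chunked run continued through the returned `state` is
bit-identical to a single long run, which the chunked estimator
`simulate_and_estimate()` relies on. The trade-off, made deliberately for
simplicity and exact chunk-concatenation semantics, is that changing
`n_particles` reshuffles all streams.

Single-file mode exploits that for identical non-interacting particles,
hard-core no-passing dynamics is the order-statistics process of the free
ensemble: stored frames are sorted along z, so particle order is preserved
in every frame. Cylinder mode adds a lateral Langevin walk confined by
specular reflection at the cylinder wall, giving 3-D coordinates for the
export and lateral-gate paths.

## Problem sizes and what the tests show

The test suite validates the estimator on this synthetic world at sizes
chosen to run comfortably on one CPU:

* **Flux identity** — a flat-potential run of 200 particles × 5×10⁶ steps
  with every step stored; the one-way plane-crossing rate matches
  $\sqrt{RT/2\pi m}\,n(z_0)$ within 3 block-method standard errors
  (≈0.5 % here). This is the equilibrium average behind the rate formula,
  verified end-to-end through the same binning and counting code used on
  real trajectories.
* **Boltzmann sampling** — stationary densities for barriers of 0–4 kcal/mol
  agree with $e^{-U/RT}$ (Kolmogorov–Smirnov, α = 0.01, independent
  replicate ensembles so the test statistic is honest).
* **Activation-energy recovery** — 240 particles in a ±12 Å box with a
  σ = 2 Å Gaussian barrier of 0/1.5/3 kcal/mol, 20 ns per temperature
  (278.15/298.15 K) against a 10×-longer reference: recovered $E_a$ rises
  monotonically with the barrier and tracks the reference within
  1 kcal/mol. The recovered value is approximately the barrier height plus a
  ≈0.3 kcal/mol free-diffusion baseline from the $\sqrt{T}$ prefactor and
  the mild temperature dependence of $\kappa$.

Passing these shows the *estimator* is correct on data satisfying its
assumptions. It does not show that any real channel's absolute $p_f$ is
reproduced: that requires hundreds of ns of all-atom MD of the
protein/membrane system, which this package consumes (PDB/PSF + DCD) but
does not produce. The synthetic world has no explicit water structure, no
protein flexibility, and no glycerol or other co-permeants.

## Known limitations

* XTC trajectories are not read; convert to DCD upstream. PSF parsing
  covers the atom section only (sufficient for selections).
* $\kappa$ and $n(z_0)$ are estimated from stored frames: storage intervals
  much above ~1 ps degrade crossing detection, so store densely.
* For drifting systems a per-frame reference offset (`reference_z` in
  `project_md_tracks()`) recentres the frame on e.g. the constriction
  residues; it is off by default, so a rigid channel frame is assumed
  otherwise.
* The ± margins on $p_f$ are SEMs over monomers or over time blocks; both
  are labelled in the output, and neither captures force-field or sampling
  bias of the underlying MD.
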