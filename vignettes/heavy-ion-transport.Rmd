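---
title: "Heavy-ion transport, fragmentation, and mixed-field dosimetry with hzesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-ion transport, fragmentation, and mixed-field dosimetry with hzesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hzesim)
```

# Scope and model

`hzesim` is a desk-scale toolkit for the transport physics of heavy charged
particles (HZE ions) through matter, the physics shared by galactic-cosmic-ray
(GCR) shielding studies and heavy-ion radiotherapy. Two interactions compete:

* **Ionization energy loss**, which continuously slows the ion and raises its
  LET, producing the Bragg peak at the end of range.
* **Nuclear charge-changing interactions**, which replace a heavy primary by
  lighter projectile fragments of roughly the same velocity, lower summed LET
  and longer range.

The package implements each piece explicitly and then couples them in a 1-D
Monte Carlo slab transport.

## Stopping power and ranges

The electronic mass stopping power is the uncorrected Bethe form

$$ S = k\,(Z/A)_{\mathrm{mat}}\,\frac{Z_{\mathrm{proj}}^2}{\beta^2}
   \left[\ln\!\frac{2 m_e c^2 \beta^2}{I(1-\beta^2)} - \beta^2\right], $$

with $k = 0.307075$ MeV cm$^2$/mol. The density effect and shell corrections
are deliberately omitted and projectiles are treated as bare nuclei; this is
accurate to a few percent above tens of MeV/nuc, and the dominant residual
uncertainty is the mean excitation energy $I$. $I$ values are fixed at the
ICRU standards (water 75 eV, polyethylene 57.4 eV, aluminum 166 eV); no
source for the original figures' $I$ choices exists, so the ICRU values are
adopted and flagged here. The $(Z/A)$ of a compound is the mass-weighted mean
of the elemental values, so Bragg additivity holds by construction.

Bethe breaks down as the ion approaches its stopping point, so the model has
a hard **validity floor of 1 MeV/nuc**: evaluation below the floor is an
error, never an extrapolation, and the range below the floor is a fixed
residual of $0.01\,(A/Z^2)$ g cm$^{-2}$ (a sub-0.05% effect for the beams
studied). Because $S$ scales exactly as $Z^2$ at fixed velocity, the CSDA
range of any ion is $(A/Z^2)$ times the proton range at the same energy per
nucleon; ranges are therefore interpolated from one cached proton
range–energy table per material (trapezoidal quadrature on a log-spaced grid,
120 points per decade; halving the step moves ranges by well under 0.1%).
With these choices the 200 MeV/nuc carbon beam penetrates 8.40 cm of
polyethylene ($\rho = 0.97$), against the measured ~8.4 cm, and 600 MeV/nuc
oxygen reaches 37.7 cm.

LET for dosimetry is always LET$_\infty$ in water:
1 MeV cm$^2$ g$^{-1}$ at unit density $=$ 0.1 keV/µm, which puts iron near
1 GeV/nuc at ~150 keV/µm.

## Charge-changing cross sections

Nuclear charge-changing cross sections use the geometric overlapping-spheres
model in its transport-code parameterisation,

$$ \sigma_{cc} = \pi r_0^2\,\bigl(A_p^{1/3} + A_t^{1/3} - b
   - 1/A_p - 1/A_t\bigr)^2 , $$

energy-independent, with nucleon radius $r_0 = 1.26$ fm and transparency
$b = 0.2$ by default. The subtracted $1/A$ terms are implemented literally as
printed in the source parameterisation; with integer mass numbers for the
target elements this reproduces the published aluminum attenuation table to
three decimals. Mean free paths follow from
$\lambda^{-1} = (N_A/M)\sum_i n_i \sigma_i$.

Two deliberate refinements:

* **Measured cross sections always take precedence** over the model when a
  record table (or an explicit per-species mean-free-path table) is supplied.
  The published worked survival numbers (λ = 23 cm for carbon and 17 cm for
  oxygen in polyethylene, 66 g cm$^{-2}$ for helium) come from measured data;
  the geometric model gives ~19 cm for carbon in CH$_2$ because it
  overestimates σ on hydrogen targets, and the package does not pretend
  otherwise.
* **Helium is special.** Emulsion-data fits give $b = 1.10$ for $^4$He
  against 0.2–0.4 for heavier ions — tightly bound helium is anomalously
  transparent. The transport's default provider therefore applies $b = 1.10$
  to mass-4-and-lighter projectiles, which brings the helium mean free path
  in polyethylene to 77 g cm$^{-2}$ (measured: 66; plain $b=0.2$ would give
  34 and over-fragment every helium fragment twice over).

## The chi-squared grid fit

`chi2_fit()` fits $(r_0, b)$ to a table of measured cross sections by
exhaustive grid search, $\chi^2 = \sum_i ((\sigma_i -
\sigma_{\mathrm{model},i})/\max(\sigma_{\mathrm{err},i},
f\,\sigma_i))^2$ with a 10% error floor, mirroring the practice of inflating
quoted errors so the best fit lands near $\chi^2 \approx 1$ per record. The
two parameters are strongly degenerate (they enter as $r_0(S-b)$ for a
slowly varying size term $S$); on synthetic 30-record data sets with 10%
noise the marginal sampling spreads are $\mathrm{sd}(r_0) \approx 0.026$ fm
and $\mathrm{sd}(b) \approx 0.095$ with correlation 0.89. The default grids
(0.08 fm and 0.2 steps) are sized at two to three times these spreads so that
point recovery is well-posed — on finer grids the ridge runs into the $b \ge
0$ boundary and the minimum slides along it. Finer grids remain appropriate
for mapping the $\chi^2$ surface itself (`analysis/05_xsec_fit.R` draws one).

## Fragmentation kinematics and branching

Fragment momenta follow the Goldhaber statistical model: each Cartesian
momentum component of a fragment of mass $A_f$ from a projectile of mass
$A_p$ is Gaussian with
$\sigma^2 = \sigma_0^2\,A_f(A_p - A_f)/(A_p - 1)$, $\sigma_0 = 90$ MeV/c by
default. Two width conventions circulate: the fragment-total width (153.5
MeV/c for $^{12}$C$\to{}^4$He) and the per-nucleon width (38.4 MeV/c 1-D,
54.3 MeV/c 2-D). The widely quoted ~1° polar-angle width pairs the
*per-nucleon* transverse width with the *fragment-total* longitudinal
momentum; the self-consistent fragment-total pairing gives ~3°. Both are
computed (`transverse_width(..., per_nucleon=)`, `angular_width()`); the
package exposes the discrepancy rather than resolving it.

Species production uses a **heaviest-fragment branching table**: per
charge-changing event one heaviest fragment is drawn (for carbon:
B 0.20, Be 0.10, Li 0.10, He 0.40, H 0.20 — the boron fraction is the
well-measured anchor), and the remaining charge is booked as
$\lfloor \Delta Z/2 \rfloor$ $^4$He plus an odd proton, so charge is
conserved exactly in every event and the carbon → helium draw reduces to the
canonical 3-alpha channel. The mass remainder becomes free neutrons (counted,
not transported — the package reports the yield per primary but contains no
neutron physics). Species without an explicit table entry get a
peripheral/central mixture (65% geometric in $\Delta Z$, 35% "central" with
the heaviest fragment uniform on $2..\lceil Z/2\rceil$); all tables are
config-editable YAML and documented as phenomenological.

Each conservation particle is tagged a forward-going *spectator* with
probability `forward_fraction` (default 0.4) and otherwise a *participant*:
slow, wide-angle ejecta that a forward scoring plane never sees, which is
booked in the event record but not transported. This is the
participant–spectator picture reduced to a single number, and the default is
calibrated against the measured peak-region composition of the 293 MeV/nuc
carbon beam (about 45% surviving carbon, one-third helium, 10% hydrogen, 7%
boron); transporting *every* conservation particle forward would triple the
light-fragment fluence at the peak and put carbon near 14%, incompatible
with any measured composition. Target fragments (the isotropic, short-ranged
"stars") carry no physics model here at all — only this bookkeeping hook.

## Monte Carlo slab transport

`transport_slab()` is a 1-D cohort engine: between interactions a particle
slows deterministically along its range–energy relation; interaction depths
are sampled from the exponential free-path law (a per-step Bernoulli sampler
with $p = \mathrm{step}/\lambda$ is available for comparison and warns when
the step exceeds $\lambda/10$); fragments inherit the projectile's energy
per nucleon perturbed by Goldhaber longitudinal draws and are transported
recursively. Protons do not interact (proton–nucleus physics is out of
scope), and particles reaching the floor energy stop. Transverse structure
is a scalar offset per particle integrated from the fragment's polar angle;
scoring excludes particles beyond `scoring_radius` (default 100 mm,
mirroring the wide cylindrical scoring region of the reference beamline
simulations).

`bragg_curve()` scores, at planes every 0.05 g cm$^{-2}$, the sum of
weighted stopping powers of all charged particles crossing each plane,
normalised to the entrance plane — an idealised LET-proportional
ionization-chamber pair with no recombination or quenching. The incident
beam carries a relative Gaussian energy spread of 0.2% by default: real
synchrotron beams have $\delta p/p \sim 0.1$%, perfectly monoenergetic
simulated beams are known to overshoot measured peak amplitudes, and with
0.2% the simulated 200 MeV/nuc carbon peak lands at amplitude ~6.8 between
the measured 6.5 and the monoenergetic-simulation level, at 8.10 g cm$^{-2}$
against the measured 8.13. Set `energy_spread = 0` for the ideal beam.

Composition summaries (`composition_at_depth()`) are read one scoring plane
upstream of the argmax when characterising the "peak region": at the argmax
plane itself the primary beam is mid-range-out and the fluence composition
moves ~10% per plane, while one plane upstream it is stable.

## Dosimetry

Quality factors are the piecewise LET-only form: $Q = 1$ below 10 keV/µm,
$0.32L - 2.2$ to 100 keV/µm, $300/\sqrt{L}$ above. The form is continuous at
10 keV/µm and has the well-known small step at 100 keV/µm (29.8 vs 30.0);
the $\le 100$ branch owns the boundary exactly as published. Dose from a
fluence-weighted particle list is $D = \sum w_i L_i \times 1.602 \times
10^{-9}$ Gy per (keV/µm · cm$^{-2}$) at unit density, $H$ weights each term
by $Q(L_i)$, and $\langle Q \rangle = H/D$. LET is evaluated in water
regardless of the slab material; charged particles below 10 keV/nuc are not
scored. The $Z^{*2}/\beta^2$-based quality-factor revision is deliberately
out of scope. A user-supplied neutron conversion-coefficient hook exists but
is disabled by default (no coefficients ship with the package).

## The synthetic GCR spectrum

No external flux model is bundled. `make_gcr_spectrum()` generates a
parametric stand-in: differential flux $\propto (E/(E+\Phi))^a \,((E +
m)/1000)^{-\gamma}$ per species with spectral index $\gamma = 2.7$ (the
conventional GCR value, not taken from any specific epoch), roll-off
exponent $a = 2$ and a modulation-like parameter $\Phi = 600$ (MV-ish but
deliberately uncalibrated — the reference epoch's modulation potential is
not printed anywhere this package relies on). The roll-off is anchored at
10 GeV/nuc, so increasing $\Phi$ suppresses only the sub-GeV flux, as solar
modulation does. Default abundances: H 0.87, He 0.12, and 1% heavies split
C 0.004 / O 0.0035 / Mg 0.001 / Si 0.0008 / Fe 0.0007 — a documented
stand-in chosen (by closed-form calculation, before any simulation) so that
the dose-weighted mean heavy charge is ~10 and the unshielded
$\langle Q \rangle$ falls in the free-space 6–7 band. What the generator
does *not* emulate: isotopic composition, solar-cycle time dependence,
anomalous cosmic rays, trapped particles and solar-particle events — so
passing pipeline tests says the machinery is consistent, not that any real
epoch's field has been reproduced.

`sample_spectrum()` allocates species counts by largest-remainder rounding
and draws energies by stratified inverse-CDF sampling. Both are variance
reductions: the dosimetric summaries are dominated by the ~0.07% iron
abundance, and Poisson noise on ~70 iron primaries per 10$^5$ would
otherwise swamp the quantities of interest at desk scale.

## Study sizes

The shipped analyses and tests use: 10$^4$ primaries per Bragg curve, 10$^5$
sampled primaries per shielding depth (0/5/10/20 g cm$^{-2}$ of aluminum),
30-record synthetic cross-section sets with 100 seeded repetitions for the
recovery study, and 2–3 × 10$^4$ events for sampler distribution checks.
These sizes put Monte Carlo errors comfortably below every tolerance tested
while keeping any single script in the seconds-to-a-minute range.

## Known limitations

* 1-D transport: no true lateral beam model, no Coulomb multiple scattering
  (its angular effect is far smaller than the fragmentation angles for these
  ions and energies), no back-wall or complex geometry.
* No proton–nucleus interactions, no neutron transport, no target-fragment
  physics beyond bookkeeping; consequently the charged-particle
  multiplication behind shielding (~1.01) and the neutron yield (~0.05 per
  ion) are well below full transport-code values (~1.16 and ~0.5), which
  include exactly the processes excluded here.
* Energy-independent cross sections, validated only for ~200–1200 MeV/nuc
  (requests outside the band warn); hydrogen-target energy dependence is not
  modelled.
* The branching tables are phenomenological, anchored to a handful of
  measured composition facts; isotope-resolved spectra are out of scope.
* Bragg-curve amplitudes depend on the beam energy spread, which is a free
  parameter; only the 5–9 amplitude band, not a point value, is meaningful.
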