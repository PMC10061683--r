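---
title: "Rare nonadiabatic events with state-aware forward flux sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare nonadiabatic events with state-aware forward flux sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxhop)
```

## The problem

Photochemical processes that cross between electronic surfaces can be slow:
a barrier on an excited surface, or a small diabatic coupling, separates
time scales by many orders of magnitude while the integration step stays
fixed by the fastest nuclear motion.  Trajectory surface hopping (TSH) is
the workhorse for nonadiabatic dynamics, but it cannot be integrated
backwards in time, which rules out the transition-path-sampling machinery
usually used for rare events.  Forward flux sampling (FFS) only ever
propagates forward, so it survives both the irreversibility and the unknown
stationary distribution of TSH.  `fluxhop` couples the two: a
fewest-switches hopping engine driven by Langevin dynamics, and an FFS
driver whose stable regions and interfaces carry an electronic-state label
in addition to a collective-variable threshold.

The rate constant is assembled in the usual FFS form,

$$k_{AB} \;=\; \phi_A \prod_{i=0}^{n} P_A(\lambda_{i+1}\mid\lambda_i),$$

where $\phi_A$ is the effective positive flux of trajectories out of the
stable region $A$ through its boundary $\lambda_0$, and each
$P_A(\lambda_{i+1}\mid\lambda_i) = N_{i+1}/M_i$ is the fraction of trial
shots started on interface $i$ that reach interface $i+1$ before falling
back into $A$.  The relative error follows from Gaussian propagation of the
Poisson flux count and the binomial shot counts,

$$\Big(\frac{\Delta k_{AB}}{k_{AB}}\Big)^2 = \frac{1}{N_0}
  + \sum_i \frac{1-P_i}{P_i\,M_i}.$$

What makes the scheme *nonadiabatic* is that membership of $A$, $B$, and
every interface is decided jointly by a collective variable and by the
active adiabatic state.  A trajectory that slides past a boundary on the
wrong surface has not entered the region.

## The two model landscapes

Both models are two-state diabatic Hamiltonians over three Cartesian
coordinates, in reduced units: energy in units of the barrier scale,
length in units of the well offset, particle mass 1, and
$k_B = \hbar = 1$.  Temperatures are entered directly as multiples of the
energy unit.

**Avoided crossing.**  Two harmonic diabats with minima at $\pm x_0$ cross
at $x = 0$ with height $\varepsilon$ and are coupled by a constant
$V_c$:

$$V_{11} = \varepsilon\Big(\frac{x + x_0}{x_0}\Big)^2,\qquad
  V_{22} = \varepsilon\Big(\frac{x - x_0}{x_0}\Big)^2,\qquad
  V_{12} = V_c,$$

plus tight transverse harmonic wells $\tfrac12\kappa_\perp(y^2+z^2)$ on
both diagonal entries.  The transverse terms are invariant under
diagonalization, so the landscape is effectively one-dimensional; the
transverse modes couple to the reaction coordinate only through velocity
rescaling at hops and through the kinetic energy entering the decoherence
time.  Diagonalization gives a bistable lower surface: with $V_c = 0.4$
the gap is $g = 2V_c = 0.8$, the minima sit at $x = \pm 0.98$ (energy
$-0.04$), the saddle at $x=0$ has energy $0.6$, hence a barrier
$E_a = 0.64$, an unstable-mode frequency $\omega_b = \sqrt{8}$, and a well
frequency $\sqrt{1.92} \approx 1.39$.  The turnover-friction estimate
$\gamma_{max} = \omega_b k_B T/E_a \approx 0.94$ at $T = E_a/3$.  The
standard thermostat settings for this model are $\Delta t = 0.0539$
(about 84 steps per well oscillation), $T = 0.64/3$, $\gamma = 1.4133$
(slightly above turnover), $s = 25$ substeps, $C = 0.1$.

The transverse stiffness is deliberately an exposed, required parameter
(`transverse_stiffness`, default curvature 12.8, mirroring the narrow
z-confinement of the second model): it does not alter the static surfaces
along $x$, but it sets the kinetic-energy pool available to hops.

**Conical intersection.**  In the sum and difference coordinates
$u = x - y$ (reaction coordinate) and $v = x + y$:

$$V_{11/22} = a\Big(\frac{u \mp d}{d}\Big)^2 + b\Big(\frac{v \mp d}{d}\Big)^2
            + c\,e\,z^2, \qquad
  V_{12} = k\,(x+y)\,e^{\,f\,(1 - (x-y)^2)},$$

with defaults $a = 0.512$, $b = 0.128$, $c = 0.5$, $d = 3$, $e = 12.8$,
$k = 0.0128$, $f = 2.3$.  The diabatic wells sit at $(x,y) = (\pm 3, 0)$,
inside the stable regions $|x-y| \ge 2.5$; the crossing seam passes
through the origin, where the coupling vanishes, so the two adiabatic
surfaces touch in a conical intersection at energy $a + b = 0.64$ above
the wells — about one $k_BT$ at the standard temperature $T = 0.6370$.
Away from the intersection the coupling grows quickly (the $e^{f}$ factor
at the seam), so passages near the origin are strongly diabatic while
passages slightly off-center can proceed adiabatically.  The rare event is
a passage between the two *diabatic* states.  Standard settings:
$\Delta t = 0.1348$, $T = 0.6370$, $\gamma = 0.7995$, $s = 25$, $C = 0.1$.

Because the regions are defined in the adiabatic ground state, a
ground-to-ground transition path can only contain an even number of hops;
this parity is asserted in the test suite on every run of this model.

## Propagation

**Nuclear step.**  Langevin dynamics
$m\ddot{x} = -\nabla E - \gamma m\dot{x} + \eta(t)$ is integrated with the
Grønbech-Jensen–Farago velocity-Verlet discretization: one Gaussian noise
vector per step with variance $2\gamma k_B T \Delta t$ per component, and
coefficients $b = (1+\gamma\Delta t/2)^{-1}$,
$a = (1-\gamma\Delta t/2)\,b$.  This integrator reduces exactly to
velocity Verlet at $\gamma = 0$ and samples the configurational Boltzmann
distribution of a harmonic mode without step-size bias, which is why the
equipartition and Kolmogorov–Smirnov checks in the test suite can be
tight.

**Electronic step.**  At the new geometry the diabatic Hamiltonian is
diagonalized ($H = U^\dagger H^{diab} U$, energies ascending, each column's
largest-magnitude component made positive so the decomposition is
deterministic).  The overlap $S = U^\dagger(t)\,U(t+\Delta t)$ is phase
corrected — per-state signs are chosen so its diagonal is non-negative, and
those signs persist on the stored transformation, so phases compose across
steps.  If the aligned overlap still has negative determinant (the trivial
crossing of two states within one step, e.g. at $V_c = 0$), one column is
flipped so $S$ is a proper rotation; the resulting coupling then performs
the full diabatic swap, which is the correct physical limit.  The
amplitudes are propagated with $s$ substeps,

$$c(t+\Delta t) = R\,c(t), \qquad
  R = \prod_{j} \exp\{(-i\,\mathrm{diag}(H_j) - K)\,\Delta\tau\},$$

with the adiabatic energies interpolated linearly across the substeps and
the overlap-derived coupling $K = \log(S)/\Delta t$ held constant over the
step.  Each substep factor is exactly unitary (closed form for two
states), so the norm is conserved to machine precision; the engine tracks
the worst norm deviation and the tests require it below $10^{-9}$.

**Hops.**  The fewest-switches probability of leaving the active state
$\beta$ for $\alpha$ uses the step propagator,

$$P_{\beta\to\alpha} =
  \Big(1-\tfrac{|c_\beta(t+\Delta t)|^2}{|c_\beta(t)|^2}\Big)\,
  \frac{\mathrm{Re}[\,c_\alpha(t+\Delta t)R^*_{\alpha\beta}c^*_\beta(t)\,]}
       {|c_\beta(t)|^2 - \mathrm{Re}[\,c_\beta(t+\Delta t)R^*_{\beta\beta}c^*_\beta(t)\,]},$$

clipped to $[0,1]$ and zeroed when the active population grew.  A uniform
draw from a dedicated hop stream selects the target by the cumulative
interval rule (intervals in state-index order; for two states the ordering
question does not arise).  If the total energy cannot pay the potential
difference the hop is frustrated and nothing changes — no velocity
reversal is applied.  Otherwise the full velocity vector is rescaled
parallel to itself so total energy is conserved exactly; using the full
vector is known to slightly overestimate upward hops compared with
rescaling along the nonadiabatic-coupling direction, and both model
studies inherit that property.

**Decoherence.**  After the hop decision, every non-active amplitude is
damped on the energy-based decoherence time
$\tau_\alpha = |E_\alpha - E_\beta|^{-1}\,(1 + C/E_{kin})$ and the active
amplitude is rescaled so the total population is exactly one.  $C$ is a
plain energy in reduced units with default $0.1$; the kinetic energy is
the full three-component kinetic energy.

**Reproducibility.**  Thermostat noise and hop draws come from two
independent counter-based streams (splitmix64 with Box-Muller), so a run
is bitwise reproducible from `(seed_noise, seed_hop)`, segments can be
resumed exactly from stored counters, and every FFS shot derives its own
seeds from its id — shot outcomes are independent of execution order, and
an interrupted cycle rerun over the remaining shot ids reproduces the full
cycle exactly.

## The FFS driver

`flux_with_reset()` runs dynamics around $A$, counts outward crossings of
$\lambda_0$ whose post-crossing state is allowed, stores each crossing
snapshot as a shooting point, and on reaching $B$ resets to a random
stored in-$A$ snapshot followed by a burn-in of $10/\gamma$ time units
that is excluded from the counted time.  `flux_without_reset()` instead
accumulates the time $\tilde T$ spent in or around $A$ — counting pauses
on entering $B$ and resumes when $A$ is re-entered — and divides the
crossing count by it.  Crossing detection is discrete (sign change of the
collective variable between consecutive steps, no interpolation),
consistent with step-based counting; a refinement test bounds the
associated bias.

Shots start from stored crossing snapshots chosen uniformly with
replacement — position, velocity, amplitudes, and active state are reused
bitwise, and stochasticity comes entirely from fresh noise and hop draws.
A shot is accepted when it crosses the next interface outward (allowed
state at the post-crossing step), rejected when it enters $A$, and
rejected separately (with a warning, so it can be audited) when it exceeds
the step cap, which defaults to 100 times the mean accepted-shot length of
the previous cycle.  Two state-aware details deserve emphasis:

* intermediate interfaces allow both electronic states by default — a
  trajectory temporarily on the upper surface is still making progress —
  while $\lambda_0$ inherits its allowed set from the definition used for
  the flux count;
* the *final* cycle accepts on full membership of $B$ (collective variable
  and state), not on a bare level crossing.  A shot that slides past the
  boundary on the upper surface has not arrived; scoring it as reactive
  inflates the rate wherever hops are frequent.  This asymmetry is exactly
  the difference between ground-state FFS and the state-aware variant.

Interfaces default to equidistant placements between the region
boundaries; the configuration accepts explicit lists, and a pilot run
targeting per-interface probabilities of roughly 0.2–0.5 is the
recommended way to refine them.  Accepted shots record their parent, so
every final shot stitches into a complete transition path by walking the
provenance chain; the stitcher verifies bitwise that each segment starts
at its parent's stored endpoint.  Path duration runs from the
$\lambda_0$-crossing snapshot to the first snapshot in $B$, matching the
convention used for paths cut out of long trajectories (first snapshot
after the last exit of $A$, to the first snapshot in $B$); hop counts
include accepted hops only.

## Analysis conventions

`brute_force_rate()` advances a single long trajectory in
region-to-region segments (memory stays bounded at any step count) and
divides the number of $A\to B$ transition events by the time whose most
recently visited stable region is $A$.  `extract_transitions()` applies
the segment convention above; standard deviations of path ensembles are
population standard deviations, so a single path has spread zero.

Rate fits are weighted least squares in log-rate space with
$\sigma_{\ln k} = \Delta k/k$: `fit_arrhenius()` fits
$k = \nu e^{-E_a/k_BT}$ with the slope free or pinned, and
`fit_landau_zener()` fits the gap law $k(g) = k^0_{AB}(1 - e^{-z g^2})$,
which vanishes at $g = 0$ (diabatic trapping) and saturates at the
adiabatic lower-surface rate.  Both are scale-equivariant, and fitted
objects support `tidy()` and `glance()`.

For the friction dependence of the barrier-crossing rate, the package's
test uses first-passage rates (equilibrated start in the $A$ well to the
first entry of $B$) rather than transitions-per-time: at a tenth of the
turnover friction an activated excursion recrosses ballistically several
times before thermalizing, and counting each recrossing as a transition
genuinely inverts the expected ordering.  The first-passage rate is the
observable for which the turnover (maximal rate near
$\gamma_{max} \approx 0.94$) is clean.

## Numerical choices and degenerate inputs

* Eigen-decomposition below a gap of $10^{-10}$ falls back to the diabatic
  diagonal gradients: the Hellmann–Feynman expression is ill-conditioned
  at a conical intersection.
* Saddle and minimum searches are dense one-dimensional scans along the
  line joining the two located minima with golden-section refinement —
  the models are effectively low-dimensional by construction — with
  frequencies from second differences (mass 1).
* A hop attempted with exactly zero kinetic energy is frustrated uphill
  and leaves the velocity untouched downhill (measure-zero case).
* An active amplitude of exactly zero makes the decoherence
  renormalization impossible; that step is left undamped and flagged.
* At most $2^{31}$ distinguishes the two RNG streams; all derived seeds
  stay below $2^{31}$.

## What the models emulate, and what passing tests do not show

The two landscapes are analytic stand-ins for the two canonical
nonadiabatic motifs — a strongly avoided crossing with predominantly
adiabatic dynamics and rare upward excursions, and a conical intersection
with diabatic trapping.  They have three nuclear degrees of freedom, a
single particle, separable transverse modes, and linear collective
variables.  Passing tests therefore demonstrate the correctness of the
propagation and of the rare-event machinery on such landscapes; they say
nothing about on-the-fly electronic structure, many-atom systems,
spin-orbit manifolds with more than two states, or collective variables
that mix into the coupling coordinates.  The engine is written for N
states but exercised with two.

The test suite and the acceptance script use deliberately scaled problem
sizes — brute-force runs of $10^6$ steps (the acceptance script uses
$5\times10^6$), flux simulations of $10^5$–$10^6$ steps, and 250–2000
shots per interface — chosen so the whole suite completes comfortably on
one core while keeping relative rate errors in the few-percent range.

## Known limitations

* Velocity rescaling along the full velocity vector overestimates upward
  hops relative to rescaling along the coupling direction; hop-count
  statistics are sensitive to this and to the decoherence parameter,
  which is interpreted as 0.1 in reduced energy units.
* Crossing detection is discrete in time; the flux acquires an
  $O(\Delta t)$ bias that the refinement test bounds at the percent
  level but does not remove.
* The conical-intersection coupling envelope concentrates nonadiabaticity
  near the seam; transition-path durations on that landscape are
  sensitive to the coupling's spatial profile, and the shipped form
  produces direct, short transits rather than long wandering ones.
* Gaussian error propagation for $k_{AB}$ ignores correlations between
  interfaces introduced by shared shooting-point ancestry; the bootstrap
  comparison in the tests shows it is accurate to better than a factor of
  two, and path-ensemble means in the tests use a cluster-corrected
  effective sample size for the same reason.
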