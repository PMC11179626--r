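---
title: "Methods: sets-of-sites ITC fitting and desk-scale free-energy profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sets-of-sites ITC fitting and desk-scale free-energy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alloitc)
```

## Scope and scientific background

Serum albumin binds Zn²⁺ at two inter-domain sites of different affinity
(A and B) and fatty acids at seven sites (FA1–FA7). Binding of a fatty
acid at FA2, which straddles the domain I/II interface, forces an open
conformation in which the residues of zinc site A are pulled apart, so
fatty-acid load converts into a loss of zinc-binding capacity. `alloitc`
provides the two quantitative workflows this mechanism calls for: fitting
ITC titration panels with a shared-thermodynamics, per-isotherm-occupancy
model, and reconstructing conformational free-energy profiles along
collective variables with umbrella sampling and WHAM — the latter at desk
scale, on analytic landscapes, so that every stage of the protocol is
verifiable against closed forms.

## The equilibrium model

The cell contents are modelled as independent classes of identical sites:
class $i$ has stoichiometry $N_i \ge 0$, association constant $K_i > 0$
(M⁻¹, concentration-based; activity corrections are deliberately omitted,
matching standard ITC practice) and molar enthalpy $\Delta H_i$ (J/mol,
either sign). The binding polynomial is the product of per-class
polynomials — no inter-class cooperativity. This is the "sets of sites"
family used by the common ITC fitting packages; a stoichiometric-series
(cooperative) model is out of scope. Classes are exchangeable, so models
are canonically ordered by decreasing $K$ and "class 1" always denotes the
highest-affinity set.

At free ligand $x$, mass balance requires
$x + [M]_t \sum_i N_i \frac{K_i x}{1 + K_i x} = [X]_t$.
The left side is strictly increasing in $x$, with opposite signs at
$x = 0$ and $x = [X]_t$, so the root is bracketed and unique. The solver
takes safeguarded Newton steps inside a shrinking bisection bracket
(globally convergent; Newton near the root), stops when the mass balance
is satisfied to `rel_tol` (default $10^{-12}$) relative to $[X]_t$, and
then applies two Newton polish steps: the residual-based stopping rule
alone would leave the *root* under-resolved in strong-excess regimes where
$x \ll [X]_t$. Degenerate inputs short-circuit exactly: no ligand gives
$x = 0$, no macromolecule (or zero total capacity) gives $x = [X]_t$.

All internal quantities are SI (mol/L, L, J). Conversions to the
presentation units of the field — µcal per injection, kcal/mol of
injectant — happen only at the I/O boundary, which avoids silent
factor-of-4.184 errors.

## Forward simulation of titrations

A perfusion (constant-volume) cell displaces liquid as it is injected
into. After cumulative injected volume $\Delta V$,

$$[M]_t = [M]_0\,\frac{1 - \Delta V/2V}{1 + \Delta V/2V}, \qquad
  [X]_t = [X]_{syr}\,\frac{\Delta V/V}{1 + \Delta V/2V},$$

the bookkeeping used by the Origin-style software family; the exact
exponential-dilution alternative was rejected for fidelity to that
convention. The heat of injection $k$ is

$$q_k = Q_k - Q_{k-1} + \frac{dV_k}{V}\,\frac{Q_k + Q_{k-1}}{2} + q_{dil},$$

where $Q = V [M]_t \sum_i N_i \theta_i \Delta H_i$ is the cell heat
content and the middle term accounts for bound material carried out with
the displaced volume. Heats of dilution enter as a single constant offset
per isotherm, mirroring the experimental practice of subtracting an
averaged blank titration; the offset can be fixed or fitted. The first
injection is simulated like any other; fitting offers an `exclude_first`
flag, since discarding the small first injection is common practice.

### The synthetic-data generator

The generator replaces instrument data and fixes the study conditions:

* **Zinc titrations** (`zn_titration_config()`): 1.5 mM ligand into 50 µM
  albumin, 35 injections (2 µL then 34 × 8 µL), 25 °C. The cell volume is
  not part of the titration description in most reports; the default is
  1.4 mL, the nominal cell of the instrument class these schedules come
  from, and it is configurable.
* **Fatty-acid titrations** (`myristate_titration_config()`): 500 µM
  ligand into 12.5 µM albumin, same schedule.
* **Zinc model** (`hsa_zn_model()`): one site of $K_1 = 2.9\times10^5$
  M⁻¹ plus a set of two weaker sites of $K_2 = 2.5\times10^4$ M⁻¹ — the
  constants of the global-fit model. Enthalpies are not part of the
  published constants; representative exothermic values
  ($\Delta H_1 = -18$, $\Delta H_2 = -8$ kJ/mol) were chosen once, giving
  heats of realistic magnitude (tens of µcal early in a titration), and
  are not tuned thereafter.
* **Myristate model** (`hsa_myristate_model()`): three classes with
  stoichiometries 2/1/4 and $K$ = 1.76×10⁶, 3.91×10⁵, 3.11×10⁴ M⁻¹.
* **Occupancy panel** (`palmitate_panel()`): two arms of six isotherms at
  0–5 mol. eq. fatty acid. The wild-type-like arm follows Θ = 1, 0.85,
  0.65, 0.45, 0.25, 0.10 — a smooth decline from full occupancy to 0.1,
  the shape an allosterically coupled site shows with increasing load —
  and the knockout-like arm stays at Θ = 1.
* **Noise**: additive i.i.d. Gaussian on each $q_k$, default SD 1% of the
  largest absolute noiseless heat in the panel. This is the simplest
  model that supports recovery testing; it does not emulate baseline
  drift, integration error that scales with peak size, or
  injection-volume jitter.

What passing tests on these panels demonstrates is therefore internal
consistency — the fitting machinery recovers what the forward model
generated, at realistic noise — not robustness to the structured
artefacts of real thermograms.

## Fitting

Single-isotherm and global fits minimise the unweighted sum of squared
residuals with bounded Levenberg-Marquardt (`minpack.lm::nls.lm`,
numerical Jacobian). Per-point uncertainties are rarely published for ITC
data, so residuals are unweighted and goodness of fit is reported as
plain and reduced SSR. Association constants are fitted internally as
$\log_{10} K$ for conditioning; the reparameterisation-invariance test
confirms the optimum is the same either way. Standard errors come from
the Gauss-Newton covariance $\hat\sigma^2 (J^\top J)^{-1}$ at the
optimum; seeded residual-bootstrap errors were considered and left out as
the Jacobian errors proved adequate for the panel sizes used.

Design choices that matter in practice:

* **Parameter fixing.** Any subset of $N$, $K$, $\Delta H$, $q_{dil}$ can
  be fixed, reproducing the strategies used for mutant panels: fixing
  $K_1/\Delta H_1$ at wild-type values and freeing stoichiometries makes
  a knocked-out high-affinity site report $N_1 \to 0$; fixing all $K$ and
  $\Delta H$ makes attenuated sites report proportionally reduced $N$.
* **Multi-start.** The SSR surface has local minima (and an exact
  relabelling degeneracy when all class parameters are free); a seeded
  multi-start (default off, 8 starts recommended for knockout-style fits)
  returns the best of several perturbed starts and the SSR spread.
  Reported per-class parameters of a fully free fit are compared in
  canonical decreasing-$K$ order for this reason.
* **Identifiability guard.** When any pair of free parameters has
  $|r| > 0.95$ in the fit correlation matrix (as happens when two classes
  have $K$ within a factor of ~2), the result carries a
  `high_correlation` flag rather than silently reporting precise-looking
  numbers. A singular information matrix sets the same flag.
* **Global fit.** All $K$ and $\Delta H$ are shared across the panel;
  stoichiometries are fixed (one high-affinity site, one set of two
  weaker sites, i.e. $N_2 = 2$ as a single class — one $\Delta H$ per
  class); the only per-isotherm parameter is the occupancy Θ of class 1.
  Θ is bounded on $[0, 1.5]$: values above the physical ceiling of 1 are
  allowed so that model misfit surfaces in the estimate instead of being
  clamped, which would bias the errors of near-saturated isotherms.
  Whether the original global analyses weighted residuals per isotherm is
  not documented; unweighted is assumed.
* **Bias check.** The package's accuracy claim for the displacement
  correction is a median-unbiasedness check of $K_1$ over 200 seeded 1%
  noise replicates with the nuisance parameters of the weak class held at
  their generating values. Freeing $K_2/\Delta H_2$ as well inflates the
  spread and skew of $K_1$ (an identifiability effect, flagged by the
  correlation guard) without saying anything about the forward model, so
  the bias check deliberately isolates the high-affinity constant.

## Collective variables and structures

Collective variables are distances, planar angles and dihedrals over
centres of mass of atom groups. Distances are Euclidean norms (nm);
planar angles use $\arccos$ of the normalised dot product, on
$[0°, 180°]$, non-periodic; dihedrals use the signed `atan2` convention
on $(-180°, 180°]$, periodic, with colinear centre triples rejected as
undefined geometry. Group definitions are configuration-driven (YAML
residue-range selections over PDB ATOM records, first-listed alternate
conformer kept); the shipped example file uses albumin subdomain ranges
(domain I ≈ residues 1–195, II ≈ 196–383, III ≈ 384–585) purely as
placeholders and is flagged as such. RMSD uses Kabsch superposition via
SVD, with the 0.25 nm backbone threshold as the conventional
transition-completeness criterion.

## The desk-scale free-energy protocol

Cluster-scale all-atom sampling is out of scope; the module implements
the *protocol* — steered path generation, window selection with overlap
control, biased sampling, WHAM, read-out at target CV values — on
analytic landscapes where every answer has a closed form, while the CV
geometry runs on real coordinates. The engine is overdamped
Euler-Maruyama Langevin dynamics in reduced units ($kT = 1$), seeded and
bit-reproducible; steps that leave the landscape's domain abort with a
suggestion to reduce `dt`. The first-order integrator inflates the
sampled variance of a stiffness-$k$ mode by a factor
$\approx 1/(1 - k\,dt/2)$, so production runs keep $k\,dt \lesssim 0.1$.

Window selection starts from the minimum window count spaced uniformly
over the steered trajectory's range, samples each window briefly, and
inserts windows at the worst-overlapping gap until every adjacent
histogram intersection reaches the target — so spacing densifies where
the landscape is stiff. If the maximum count cannot reach the target, an
infeasibility error suggests a softer window stiffness (window width
scales as $\sqrt{kT/k}$). The default count range of 28–39 windows
matches the scale used in the umbrella-sampling studies this protocol is
modelled on.

WHAM iterates the standard self-consistent equations on (by default) 200
bins to a tolerance of $10^{-8}$ kT on the window free energies, anchored
at $f_1 = 0$, capped at $10^5$ iterations with the $f$ history returned
on non-convergence. Empty bins inside the profile are reported as `NA`
gaps, never interpolated; `delta_g_at_target()` interpolates linearly
between finite bins and refuses to extrapolate outside the sampled range.
Relative read-outs between systems subtract profiles at a common target
CV value against a named reference system; summing the per-CV relative
values treats the CVs as independent contributions.

### Problem sizes

The validation runs use sizes chosen to make their statistical error
comfortably smaller than the tolerance they certify: 10⁴ random
equilibria against the bisection oracle; 200 noisy fit replicates; 12
umbrella windows × 25 000 retained samples for the harmonic WHAM check
(held to 0.1 kT over ±2σ); 10⁶ exact Boltzmann draws for the two-state
gap (held to 0.02 kT); and a 28-window protocol run with 4 000 production
samples per window on a 5 kT double well (barrier held to 0.3 kT). The
unit-test copies of these checks run at reduced size with
correspondingly looser tolerances.

## Known limitations

* The binding model is apparent/concentration-based: no proton-linkage or
  ion-competition corrections, no conversion of $K_{ITC}$ to absolute
  affinities, no $\Delta C_p$/temperature-series support.
* The noise model is unstructured; real thermogram artefacts (baseline
  drift, first-injection anomalies beyond a constant offset) are not
  emulated, so recovery results bound only the statistical part of the
  error budget.
* The Langevin engine is one-dimensional and overdamped; it validates the
  umbrella/WHAM machinery, not force-field physics. WHAM is 1-D only, as
  per-CV profiles are the intended read-out.
* Kabsch superposition assumes a one-to-one atom correspondence; no
  sequence alignment is performed.
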