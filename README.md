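# alloitc

Serum albumin carries both Zn²⁺ (at two inter-domain sites, A and B) and
fatty acids (at seven sites, FA1–FA7). Occupation of the high-affinity
fatty-acid site FA2, which spans the domain I/II interface, allosterically
disables the high-affinity zinc site A: the protein cannot close around a
Zn²⁺ ion while a fatty-acid tail pins the interface open. `alloitc`
implements the two computational workflows needed to study this kind of
allosteric ligand competition:

1. **ITC occupancy analysis** — an independent sets-of-sites binding model
   for isothermal titration calorimetry, with forward simulation of
   titration isotherms, single-isotherm least-squares fitting under the
   usual parameter-fixing strategies, and a *global* fit of a whole panel
   of isotherms in which the thermodynamic parameters are shared and only
   the per-isotherm occupancy Θ of the high-affinity site varies.
2. **A desk-scale free-energy protocol** — collective-variable geometry
   (dihedral, planar angle, distance over atom-group centres of mass) on
   protein structures, steered pulling and umbrella sampling with an
   overdamped Langevin engine on analytic landscapes, and WHAM
   reconstruction of ΔG profiles with read-out at target CV values.

## The model

Each site class *i* has stoichiometry *Nᵢ*, association constant *Kᵢ*
(M⁻¹) and molar enthalpy *ΔHᵢ*. Classes bind independently, so at free
ligand concentration *x* each class saturates as

θᵢ = Kᵢ x / (1 + Kᵢ x),

and the free ligand in the cell solves the mass balance

x + [M]ₜ Σᵢ Nᵢ θᵢ(x) = [X]ₜ,

which is strictly monotone in *x* and solved by bracketed Newton
iteration. The heat after injection *k* is the finite difference of the
cell heat content Q = V [M]ₜ Σᵢ Nᵢ θᵢ ΔHᵢ, corrected for the liquid
displaced from the perfusion cell:

qₖ = Qₖ − Qₖ₋₁ + (dVₖ/V)·(Qₖ + Qₖ₋₁)/2 + q_dil.

In the global fit, all *K* and *ΔH* are shared across isotherms and a
per-isotherm occupancy Θ (bounded on [0, 1.5]) scales the stoichiometry of
the highest-affinity class; Θ plotted against fatty-acid load is the
allosteric read-out.

The umbrella-sampling module iterates the standard WHAM equations,

P(b) = Σ_w n_w(b) / Σ_w N_w exp[(f_w − U_w(b))/kT],
f_w = −kT ln Σ_b P(b) exp[−U_w(b)/kT],

to self-consistency, with ΔG(b) = −kT ln P(b) shifted to zero at its
minimum.

## Worked example

Simulate the reference study design — two arms of six Zn²⁺ titrations
(1.5 mM ZnCl₂ into 50 µM albumin, 35 injections) at 0–5 mol. eq. fatty
acid, occupancy declining with load in the wild-type-like arm only — and
fit all 12 isotherms globally:

```r
library(alloitc)
panel <- palmitate_panel(seed = 7)
fit <- fit_global(panel, hsa_zn_model(), seed = 1)
fit$shared[!fit$shared$fixed, c("name", "value", "se")]
#>   name  value       se
#> 2   K1 308724 17007.10
#> 3   H1 -17915   176.73
#> 5   K2  25491   621.07
#> 6   H2  -7925    83.49
occupancy_vs_condition(fit)
#>    condition    arm theta      se
#> 1          0 FA2-KO 1.011 0.01082
#> 2          1 FA2-KO 1.019 0.01085
#> 3          2 FA2-KO 1.009 0.01081
#> 4          3 FA2-KO 1.009 0.01081
#> 5          4 FA2-KO 1.010 0.01081
#> 6          5 FA2-KO 1.009 0.01081
#> 7          0     WT 0.992 0.01074
#> 8          1     WT 0.852 0.01016
#> 9          2     WT 0.666 0.00945
#> 10         3     WT 0.441 0.00867
#> 11         4     WT 0.254 0.00799
#> 12         5     WT 0.092 0.00715
```

The shared constants recover the generating values (K₁ = 2.9×10⁵ M⁻¹,
K₂ = 2.5×10⁴ M⁻¹) within their standard errors, and the two arms separate
cleanly: Θ collapses from ≈1 to ≈0.1 with fatty-acid load in the wild-type
arm while staying at ≈1 in the knockout arm — the signature of an
allosteric switch carried by a single fatty-acid site.

The same analysis runs from files via a manifest
(`run_pipeline("panel.yaml", seed = 1)`), which writes `occupancy.csv`, a
machine-readable `report.json` and fit plots. A thin command-line wrapper
over these functions is installed at `inst/cli/alloitc.R` (subcommands
`simulate`, `fit`, `globalfit`, `run-pipeline`, `cv-eval`, `pull`,
`umbrella`, `wham`, `profile-diff`).

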