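---
title: "Methods: a coupled water-column / sediment diagenesis eutrophication model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coupled water-column / sediment diagenesis eutrophication model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and state

`eutrosim` simulates lake eutrophication with explicit benthic–pelagic
coupling. One or two fully mixed water compartments each carry a sediment
column of up to ten layers whose thickness grows with depth (the default
stack is 4 × 1 mm, 2 mm, 4 mm, 1 cm, 2 cm, 6 cm and 10 cm); the
millimetre-scale top layers resolve the steep redox gradients across the
sediment–water interface that control nutrient return fluxes.

The state is a bulk concentration (g m⁻³ of cell volume) for every
substance in every cell: 14 phytoplankton phenotypes (three adaptive
variants — energy, nitrogen and phosphorus type — for each of five species
groups), four particulate and one dissolved detrital organic fraction for
each of C, N, P and S, nitrate, ammonium, the four phosphate species
(dissolved, iron-adsorbed, vivianite-like, apatite-like), dissolved and
opal silica, oxygen, sulphate, dissolved and particulate sulphide, methane,
three inorganic sediment fractions and chloride. Solute process laws act on
the pore-water concentration (bulk divided by porosity); the conversions
are centralized in the engine.

## Process formulations

**Decomposition** follows a multi-G scheme: each fraction mineralizes with
first-order kinetics. The fast fraction's rate is interpolated between a
minimum (0.15 d⁻¹) and maximum (0.2 d⁻¹) by the lesser of the N- and
P-content band weights (a Liebig-style choice: bacteria are limited by the
scarcer nutrient). Organic N and P mineralize faster than C by
`max(1, content/target)` — preferential stripping towards the low residual
contents of humic matter (targets 0.07 g N and 0.007 g P per g C). The
factor is capped (default 10) so that a vanishing carbon pool cannot
produce an unbounded nutrient flux. Conversion to the next, more
refractory fraction accompanies mineralization in fixed ratios (0.3, 0.2,
0.2; 0.17 to the dissolved fraction).

**Electron acceptors.** Mineralized carbon is allocated over aerobic
oxidation, denitrification, sulphate reduction and methanogenesis with
Michaelis–Menten limitation and inhibition factors, rescaled to sum to
exactly one; methanogenesis is the unconditional remainder, so the
allocation is defined even with all acceptors depleted. Stoichiometry is
half-reaction arithmetic (2.67 g O₂, 0.933 g NO₃-N, 1.333 g SO₄-S per g C;
methanogenic carbon splits equally into CH₄ and CO₂); the printed source
for these couplings is graphical, so the constants are exposed in the
coefficient set rather than hard-wired.

**Phosphate.** The adsorption capacity is the reactive-iron content of the
sediment (7.5% of the silt in the top 4 mm, 2.5% below; 5% of suspended
sediment in the water column), corrected for the oxidized iron(III)
fraction: 1 above 0.25 g O₂ m⁻³, ramping linearly to 0.2 (top 4 mm) or 0.1
(deeper) at anoxia. Adsorption follows a Langmuir isotherm whose affinity
`K_ads (OH⁻)^(-a)` (a = 0.2) falls as pH rises, reproducing alkaline
desorption. A design point worth stating: the engine computes the
equilibrium by partitioning the **total** (dissolved + adsorbed) pool over
the isotherm and relaxes towards that split with the 10 d⁻¹ sorption rate.
Evaluating the isotherm at the instantaneous dissolved concentration
instead would request an equilibrium far beyond the available pool
whenever capacity is plentiful, and a rate law built on that difference
overshoots catastrophically at any usable time step. The partition form
has the same fixed point and is unconditionally mass-limited. Vivianite
precipitates first-order on supersaturation above 0.15 g P m⁻³ pore water,
only under anoxia, and redissolves proportional to mineral and oxygen;
apatite shares the driving force through the 2:1 precipitation ratio, has
no redox gate, and dissolves proportional to both mineral and
undersaturation. Opal dissolves towards the 10 g Si m⁻³ saturation.

**Sulphur and methane.** Dissolved sulphide is speciated diprotically
(pK₁ = 7, pK₂ = 14); iron-monosulphide precipitation/dissolution uses the
free-ion saturation 0.2·10⁻¹⁰ mol L⁻¹ as its fixed point. Because the
nominal rates (10⁶ d⁻¹) are far stiffer than the 5-minute step, the
exchange is integrated analytically within the step — dissolved sulphide
tracks its equilibrium, which is the intended quasi-equilibrium behaviour.
Methane oxidation is double-Michaelis–Menten in CH₄ and the oxidant; the
oxygen pathway excludes the sulphate pathway via a smooth O₂ inhibition
factor (an exact switch would be non-differentiable and numerically
brittle for no physical gain). Methane above the hydrostatic,
temperature-corrected saturation is removed instantly as ebullition and
booked to the atmosphere boundary.

**Gas exchange** uses the double-film model with the wind polynomial
`0.728√W − 0.317W + 0.0372W²` m d⁻¹ (constants exposed in the
configuration) and the classical temperature/chlorinity oxygen solubility
fit.

**Phytoplankton.** A daily linear program reallocates biomass over
phenotypes, maximizing total community biomass — equivalent to maximizing
net production — subject to (i) nutrient constraints (new biomass content
≤ dissolved pool + surviving biomass content, so phenotype switching frees
its nutrients), (ii) a growth bound per group,
`Σ b_i exp((fL·kp_i(T) − kr_i(T))Δt)` plus a small invasion seed, and
(iii) a mortality bound, the surviving biomass `Σ b_i exp(−km_i(T)Δt)`.
The solver is the simplex method (`boot::simplex`); an infeasible program
falls back to mortality-only with a diagnostic, though feasibility is
guaranteed by construction (the survivors always satisfy every
constraint). Nitrogen uptake takes ammonium before nitrate.

Two open choices deserve emphasis. First, the published growth-temperature
coefficients mix plain exponential bases (≈1.05–1.1) with the values 0, 3
and 5, which cannot be exponential bases for rates quoted at 0 °C; the
package reads the latter as offsets of a linear response
`kp·max(0, T − kt_p)` and keeps the selector (`temp_fun`) editable in the
phenotype table. Second, the full light-efficiency tabulation of the
original community model is not reproducible from available material; the
energy constraint instead folds a saturating response to depth-averaged
Lambert–Beer light (half-saturation 20 W m⁻² PAR, configurable) into the
growth bound. This is the model's largest simplification: absolute
production levels should not be over-interpreted, while the competition
structure (who wins under which nutrient/light regime) is preserved.

Mortality releases 35% of each element directly (autolysis; C to dissolved
organic matter, N/P/S to their dissolved pools) and splits the remainder
55/45 (eukaryotes) or 62/38 (cyanobacteria) over the two labile detritus
fractions; all diatom silica goes to opal. Grazing removes algae and
labile detritus in proportion to the imposed zooplankton biomass
(0.1 (g C m⁻³)⁻¹ d⁻¹ by default, with a 30% respired/excreted share — both
calibration-grade constants exposed in the coefficients, since the source
defers them to companion literature).

## Transport and numerics

The integrator is first-order operator splitting at a 5-minute step:
water-balance flows, settling, burial, seepage (explicit upwind; Courant
numbers are ≤ 0.05 for all shipped velocities), then vertical sediment
dispersion with a **backward-Euler tridiagonal solve** per column — the
top sediment layers are 1 mm thick and the interface conductance makes
explicit diffusion unconditionally unstable there — then kinetics
(explicit), the analytic sorption and sulphide substeps, ebullition, and
the daily community step. The dispersion solve exchanges with the
overlying water through a 0.5 mm diffusive boundary layer; solute
dispersion is the seasonal bio-irrigation/flow coefficient (1.78·10⁻⁴ to
7.73·10⁻⁴ m² d⁻¹ at the interface, decaying to 10% at 5 cm) plus molecular
diffusion corrected for tortuosity by porosity²; particulate bioturbation
(2.8·10⁻⁷ to 2.8·10⁻⁶ m² d⁻¹, 10% at 4 cm) mixes on a solids basis.
Burial advects the whole bulk — pore water included, which constant
porosity and layer thickness imply — at the velocity that exactly balances
the settled solid volume.

Negativity is handled by source-limited clipping: any concentration driven
below zero within a step is set to zero and the created mass is credited
to a dedicated ledger category, preserving auditability rather than
silently losing closure. Rates are temperature-adjusted as `k·kt^(T−20)`
with an additional factor 1/1.25 per degree below 2 °C for microbial
rates.

Every boundary flux — loads, outflow, seepage, burial, atmosphere, carbon
exchanged with the implicit CO₂ pool, nitrogen lost as N₂, clipping — is
accumulated in the flux ledger, so for each element (C, N, P, S, Si, Cl)
the storage change must equal the ledgered boundary sum. On the one-year
synthetic run the relative residuals are below 10⁻¹², i.e. pure floating-
point accumulation; the tests enforce 10⁻⁹.

## The synthetic lake

`synthetic_lake()` defines the study conditions: a 32.3 km² two-compartment
shallow lake (60% sandy at 0.75 m, porosity 0.4, upward seepage
0.0057 m d⁻¹, net settling 0.115 m d⁻¹; 40% silty at 2.5 m, porosity 0.7,
infiltration −0.015 m d⁻¹, settling 0.23 m d⁻¹), weekly sinusoidal
temperature (2–22 °C) and PAR (20–180 W m⁻²), seeded Gaussian wind around
4 m s⁻¹, seasonal pH and zooplankton, constant suspended sediment
(10 g m⁻³), inflows giving a quarter-year residence time, and constant
loads (1.5 g P, 30 g N, 20 g C m⁻² yr⁻¹). Initial sediment composition
(organic carbon 1.6 and 10 g per kg dry matter in the sandy and silty
beds, inorganic P pools of matching magnitude) is synthetic but scaled to
measured shallow-lake sediments. The only randomness anywhere is the wind
series; the simulator itself is deterministic.

What the fixture does *not* emulate: measured water balances and loads,
resuspension (net settling only), macrophytes and microphytobenthos,
near-bottom stratification. Passing tests on the fixture therefore
demonstrate internal consistency (conservation, analytic limits,
qualitative seasonal diagenesis — a thinner summer oxic layer, adsorption
collapse under anoxia releasing phosphate, the spring diatom silica
drawdown), not a hindcast of any real lake.

## Problem sizes used by the checks

The test suite runs the full year (365 d × 288 steps d⁻¹ ≈ 10⁵ steps, 22
cells × 51 substances) once and shares it between the closure and seasonal
checks; a 30-day run is repeated at a halved step for the convergence
check (trajectory change < 1%); the analytic-limit oracles use 10–15 day
single-box runs; the LP oracle sweeps 100 seeded two-type instances
against brute-force vertex enumeration.

## Known limitations

- The adsorption isotherm's algebraic form and the A-equation
  stoichiometries are reconstructions (their printed sources are
  graphical); both are isolated behind configurable coefficients.
- The light-energy constraint is a saturating scalar, not the original
  efficiency tabulation; absolute primary production is approximate.
- Water compartments are fully mixed: transient near-bottom anoxia in deep
  water, and the associated extra phosphate release, cannot develop.
- First-order splitting is globally first-order accurate; the convergence
  check bounds the step-size sensitivity rather than eliminating it.
- Explicit Fe(II)/Fe(III) and Mn pools are absent; their redox roles are
  implicit in the sulphur cycle and the oxidized-iron correction factor.
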