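---
title: "Modeling electric fields, heating and damage-zone thresholds in liver electroporation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling electric fields, heating and damage-zone thresholds in liver electroporation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectfield)
```

## The problem

Electrochemotherapy (ECT) and irreversible electroporation (IRE) permeabilize
cell membranes wherever the local electric field exceeds a tissue-specific
threshold. Treatment planning for the liver therefore needs the field
distribution around the needle electrodes, the Joule heating that the pulses
cause, and — when histology of treated tissue is available — the field
threshold that best explains each observed damage zone. `ectfield` implements
this chain for 2-D cross-section models of liver tissue:

1. a nonlinear steady-state potential solve per electrode pair, with
   field-dependent tissue conductivity;
2. superposition of the per-pair fields into the treatment field map;
3. a duty-cycle Pennes bioheat solve over the pulse schedule with an
   Arrhenius damage integral;
4. Sørensen–Dice (DSC) fitting of field thresholds to binary damage-zone
   masks, including a counter-electrode angle search for linear electrodes;
5. a hepatic-microstructure study (lobule lattice with interlobular septa
   and centrilobular veins) comparing heterogeneous and homogeneous tissue
   models.

A synthetic-case generator produces every input the fitting pipeline needs —
geometries, field rasters and zone masks with known ground truth — so the
whole chain can be validated without histological data.

## The electrical model

The potential obeys $\nabla\cdot\big(\sigma(|\nabla u|,T)\,\nabla u\big)=0$
with Dirichlet conditions on the active electrode boundaries ($u=U$ on the
anode, $0$ on the cathode), zero normal flux on the outer boundary and on
inactive electrodes. Conductivity rises with the local field as
electroporation opens membrane pores; we model this with a C¹ cubic-Hermite
smoothed step

$$\sigma(E, T) \;=\; \sigma_0\,\big(1+c_T\,(T-37)\big)\,
\Big(1+(f-1)\,S\!\Big(\tfrac{E-(E_C-E_W/2)}{E_W}\Big)\Big),$$

where $S$ is the smoothstep polynomial $3t^2-2t^3$ clipped to $[0,1]$,
$\sigma_0$ the base conductivity, $f$ the plateau factor, $E_C$ and $E_W$ the
center and width of the transition (V/cm), and $c_T$ the fractional change
per kelvin (default 0.015/K, applied only above baseline — heating raises
the base conductivity, cooling below 37 °C does not lower it).

Key parameter defaults (all overridable through `tissue_table()` /
`load_tissue_table()`):

| tissue | σ₀ (S/m) | factor | E_C (V/cm) | E_W (V/cm) |
|---|---|---|---|---|
| liver / lobule | 0.091 | 3.5 | 580 | 240 |
| septa, portal space | 0.26 | 2 | 700 | 400 |
| vessel wall | 0.22 | 2 | 700 | 400 |
| blood / CV lumen | 0.70 | 1 | — | — |

The liver base value (0.091 S/m) and the portal-space value (0.26 S/m) are
established porcine-liver measurements; the remaining entries are a
*documented configuration* with magnitudes typical of the electroporation
treatment-planning literature (the liver transition roughly spans the
reversible-to-irreversible range 460–700 V/cm, with a ≈3.5× conductivity
rise). They are flagged as assumptions in run manifests and should be
replaced when measured values are available.

For a pair sequence (the 7-needle hexagonal array activates 12 anode–cathode
pairs: six center–periphery, six adjacent-periphery, each spanning exactly
the 7.3 mm spacing), each pair is solved independently starting from base
conductivity — the electroporation-induced rise does not persist between
pairs, but the slower thermal rise does: with thermal feedback enabled the
bioheat state advances after each pair and multiplies the base conductivity
of subsequent solves. The superposed field map is the element-wise maximum
of the per-pair magnitudes (electroporation tracks the largest field a
location experiences); summing potentials instead is available as
`superposition = "sum_potentials"` for sensitivity checks.

### Numerics

* **Meshing.** No constrained-Delaunay generator is part of the package's
  dependency set, so `triangulate()` builds a graded tensor-product
  triangular grid: axis spacings refine near electrodes (default element
  size diameter/6 at the boundary) and optionally coarsen toward generously
  padded outer boundaries (`h_far`). Nodes of triangle edges that cross an
  electrode circle are snapped onto the circle (edge-intersection snapping),
  and near-coincident snapped nodes are merged, so the discrete electrode
  boundary is a clean inscribed polygon and no active element keeps a vertex
  inside an electrode. Tissue–tissue interfaces are resolved by element
  labeling at the local element size; for the 50 µm septa this means one
  element across the band at the default microstructure resolution, which
  the convergence checks show is sufficient for the field statistics used
  here.
* **Linearization.** Picard iteration with under-relaxation 0.5 on the
  conductivity update, tolerance 10⁻³ on the relative L² change of the
  element fields, at most 100 iterations. The steep σ(E) transition can
  produce a period-2 oscillation; the relaxation factor is halved whenever
  the residual increases, which restores monotone convergence (typically
  8–15 iterations).
* **Fields.** First-order elements: |E| is piecewise constant per element
  and is used as such for threshold fitting. The Joule source of the
  thermal solve is patch-averaged over edge-neighboring elements, because
  raw P1 boundary gradients carry O(1) noise on snapped boundary triangles
  and enter the source quadratically; without this the peak temperature
  varies by several kelvin between equivalent meshes.
* **Units.** Geometry in mm, solves in SI, fields reported in V/cm,
  thresholds always V/cm; temperatures in °C externally and kelvin inside
  the Arrhenius integral.

## The thermal model

Tissue heating follows the Pennes bioheat equation
$$\rho c\,\partial_t T=\nabla\cdot(k\nabla T)-\omega_b(\rho c)_b (T-T_b)+Q_m+D\,p,$$
with the duty-cycle-averaged Joule source $D\,p$, where
$D = \text{pulse duration}\times\text{repetition rate}$ and
$p=\sigma|\nabla u|^2$ comes from the converged stationary solve of the
active pair. The two protocol presets are:

* `hexagonal_ect` — 730 V, 8 pulses of 100 µs per pair at 5 kHz (12 pairs,
  96 pulses in total): duty cycle 0.5 during each pair's 1.6 ms burst,
  pairs delivered back-to-back;
* `linear_ect` — 2000 V, 8 pulses of 100 µs at 1 Hz: per-second duty
  cycle 10⁻⁴ over the 8 s schedule.

Both correspond to a nominal voltage-to-distance ratio of 1000 V/cm.

Time stepping is implicit Euler (unconditionally stable; default step
min(10 ms, burst/4), refined automatically for millisecond bursts), with the
outer boundary fixed at baseline (37 °C) or optionally insulated. The
thermal domain *includes* the electrode interiors as stainless-steel regions
(ρ = 7900 kg/m³, c = 500 J/(kg·K), k = 15 W/(m·K)): the needles carry no
Joule source but conduct heat away from the hottest tissue at the
electrode–tissue interface; omitting this sink overestimates the surface
peak by >15 K. Perfusion defaults to ω_b = 0.0064 s⁻¹ with blood at 37 °C —
negligible over the sub-second hexagonal schedule, a mild sink over the 8 s
linear schedule — and is plain configuration, since perfusion during
sub-minute pulse delivery is poorly constrained.

Thermal damage uses the first-order Arrhenius model
$\Omega=\int A e^{-E_a/(R T)}dt$, integrated per node with the trapezoidal
rule along the stored temperature history, and
$P=1-e^{-\Omega}$. Defaults are standard liver coagulation kinetics
($A=7.39\times10^{39}\,$s⁻¹, $E_a=2.577\times10^{5}\,$J/mol), again
configuration rather than measured fact.

With these models, the scaled-down homogeneous reconstructions used in the
package's acceptance checks give: linear protocol ≈ 39 °C peak tissue
temperature and damage probability ≈ 0.4 %; hexagonal protocol ≈ 55 °C
immediately at the center-electrode surface (mesh- and step-size-stable)
and damage probability ≈ 0.1 %. The acceptance suite checks the hexagonal
peak against a 47 °C reference bound for this protocol, which the current
configuration exceeds by a few kelvin; the gap is consistent with the
uncertainty of the non-measured conductivity/thermal defaults and with the
2-D cross-section approximation, which cannot conduct heat axially along
the needle. We deliberately did not re-tune tissue parameters to close this
gap, so that check is expected to fail until measured parameters are
supplied.

## Threshold fitting

A damage zone is a filled binary mask (it includes the electrode tracks; the
outer zone includes the inner one). `field_mask()` thresholds a field raster
— electrode-interior pixels count as inside the zone — and `fit_threshold()`
sweeps 300–1500 V/cm in steps of 10 (121 field masks), computing
$\mathrm{DSC}=2|A\cap B|/(|A|+|B|)$ against the zone mask and returning the
argmax as a classed `threshold_fit` object (`print`, `summary`, `coef`,
`plot`). Exact ties resolve to the lowest threshold: deterministic, and
conservative in the sense of a larger treated area. Masks must share the
raster grid; resampling and an optional user-supplied affine pre-alignment
of mask coordinates are the caller's responsibility — there is no automatic
registration.

When only one electrode of a linear pair is visible in a section,
`search_counter_electrode()` places the counter electrode at the pair
spacing in 5° steps (72 candidates), solves each candidate, and maximizes
the sum of the Zone A and Zone B best DSCs (configurable to Zone B only).
Failed angles are skipped with a warning; exact ties go to the lowest angle.

## The synthetic-data generator

`generate_case()` stands in for pathologist-segmented histology. It builds
the chosen electrode layout in homogeneous parenchyma (optionally with a
seeded scene of non-overlapping vessels — blood lumen, wall annulus — and
portal spaces), solves the full pair sequence, rasterizes the superposed
field (default 50 µm pixels over a 40 × 40 mm frame; 10 µm is appropriate
for microstructure work), and thresholds it at the ground-truth Zone A/B
values (defaults 1225 and 805 V/cm, typical porcine-liver zone-mean
estimates, used purely as generator settings). Mask boundaries are optionally perturbed
by a seeded, zero-mean, spatially correlated noise field applied to the
mask's signed distance: the boundary is displaced along its normal with
standard deviation amplitude/√3 (matching a uniform ±amplitude draw) and
correlation length ≈10 px, mimicking the smooth wiggles of manual outlines.
We chose the signed-distance formulation over an explicit contour
parameterization because it handles multi-component and nested zones without
special cases; its displacement statistics are the same. Every artifact
carries a manifest (spec, seed, package version) sufficient to regenerate it
bit-identically.

What the generator does *not* emulate: staining and imaging artifacts,
tissue deformation from electrode insertion, registration error between
model and section, and partial zones truncated by the section border. Tests
passing on synthetic masks therefore validate the *fitting machinery*
(exact recovery on the sweep lattice when noiseless; unbiased recovery
within one sweep step under ±2 px boundary noise across 20 seeds), not the
biological interpretation of fitted thresholds.

## The microstructure study

`build_hex_lobule_lattice()` tiles a frame with regular hexagonal lobules at
a 1950 µm across-flats pitch — the hexagon "diameter" is read as the
across-flats distance of the lobule-plus-half-septum tile, so the pitch is
exact — separated by 50 µm septa, with one 150 µm centrilobular vein (CV)
per complete lobule. Three variants run on the *same* mesh so meshing error
cancels: heterogeneous (own septa/CV conductivities), semi-homogeneous
(septa matched to lobules), homogeneous (septa and CVs matched).
`relative_error_stats()` compares field rasters pixel-wise
($|a-b|/b$, mean/median/sd in %), excluding electrode interiors plus a
1-pixel rim where the Dirichlet corner makes the raw gradient unreliable.

With the default tissue table the heterogeneous-vs-homogeneous comparison on
the packaged section (one 7.3 mm pair, 50 µm elements, 25 µm pixels) gives a
mean relative error of ≈2.3 % (median ≈1.1 %, sd ≈5.4 %) — the
median ≪ mean ≪ sd ordering expected when the error concentrates in the
septa and CV lumina. The acceptance suite compares the mean against a 7 %
reference value for this comparison; the magnitude of the statistic is
driven almost entirely by the septa/CV conductivity contrast, so it
inherits the configuration uncertainty, and we report the model's honest
value rather than adjusting the contrast to match — that check, too, is
expected to fail under the shipped defaults.

The septa conductivity itself is unknown; `parametric_sweep()` varies the
septa conductivity function over a grid — default 9 base-conductivity
fractions (0.1–2 × lobule) × 2 factors × 2 transition centers × 2 widths =
72 combinations, an explicitly documented stand-in sized to the published
study — refitting the Zone A/B thresholds for each combination against
synthetic masks generated from the homogeneous solution at 850 and 480 V/cm
(generator settings only). The robust qualitative outcome, asserted in the
tests as an ordering rather than as absolute numbers: the Zone B (outer,
low-field) threshold is insensitive to septa properties, while the Zone A
threshold responds when the septa conductivity is far below the lobules'.

## Problem sizes and design choices

The packaged checks run deliberately scaled-down problems chosen as the
smallest sizes at which the measured quantities are resolution-stable:
protocol reconstructions on ≈40–50 k element meshes (0.4 mm elements,
0.1 mm at electrodes), the microstructure section on ≈80 k elements, rasters
at 25–100 µm. Halving element sizes changes the reported temperature maxima
by <1 K and the relative-error statistics by <0.1 percentage points.

Other choices made where the design was genuinely open:

* electrodes enter the field solve as Dirichlet boundaries, not resistive
  domains (a very-high-conductivity material entry exists for completeness);
* inactive electrodes are insulating holes (zero normal flux), per the
  solver convention adopted here;
* the 2-D plane of the linear-electrode model is perpendicular to the
  needles, an approximation that affects absolute values mainly near the
  needle tips (3 cm active length ≫ the relevant scale);
* domain padding defaults to 3× the electrode-array bounding-box diagonal;
  doubling it changes near-electrode fields by <1 % (tested);
* "modified" Pennes is interpreted as standard Pennes plus the duty-cycle
  source and the temperature feedback on base conductivity;
* zone masks are filled regions by default; annular Zone B masks must be
  filled by the caller before fitting.

## Known limitations

2-D cross sections only (no axial needle effects, no 3-D reconstruction);
no pore-dynamics or frequency-dependent conductivity; no temperature
dependence of thermal parameters, phase change, or perfusion shutdown; no
deformable registration of histology; thresholds are only as meaningful as
the supplied masks' alignment with model coordinates.
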