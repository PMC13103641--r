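---
title: "Curved-element membrane Monte Carlo: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curved-element membrane Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiform)
```

# The model

`vesiform` simulates a closed fluid-membrane vesicle as a dynamically
triangulated surface (DTS) whose faces carry their own lipid composition and
peptide occupancy. The total free energy, in units of kT, is

$$
F = E_{HF} + E_{pV} + E_{stretch} + \sum_{\mathrm{face}} \left( F_b + F_{mix} \right)
$$

with

* **Curvature elasticity** $E_{HF} = \int dA\, \left[ \tfrac{\kappa}{2}\,(2H - J_s)^2 + \bar\kappa_b K_G \right]$.
  $H$ is the mean of the principal curvatures, so $2H$ is their sum, which is
  what the local spontaneous curvature $J_s$ (1/nm) is compared against.
  $\kappa$ (kT), $J_s$ and the bilayer Gaussian modulus $\bar\kappa_b$ (kT)
  vary over the mesh but are constant on each face, because they are computed
  from the face's composition.
* **Osmotic work** $E_{pV} = c_0 k_B T\,[(V - V_0) - V_0 \ln(V/V_0)]$:
  non-negative, zero exactly at the target volume $V_0$. The osmolarity
  $c_0$ defaults to 300 mM (a physiological buffer), converted internally to
  molecules/nm³.
* **Area compression** $E_{stretch} = \tfrac{K_A}{2}\,(1 - A/A_0)^2 A_0$ with
  $K_A = 200$ pN/nm by default. The trailing $A_0$ makes the expression an
  energy for a per-area modulus; the factor is isolated in `stretchEnergy()`
  and can be reviewed independently of the sampler.
* **Peptide binding** $F_b = n_p \sum_i \phi_i\, \mu_{ads,i}$ per face, with
  $\phi_i$ the face's outer-leaflet lipid fractions and $\mu_{ads,i}$ the
  whole-peptide binding free energies to the pure bilayers (kJ/mol in the
  tables, kT internally). A peptide occupies whole faces: occupancies are
  integers, and the coverage fraction $\phi_p = n_p A_p / A_l$ is capped at 1.
* **Ideal mixing** $F_{mix} = k_B T\, M \sum_{i,b} \phi_i \ln \phi_i$ per face
  and leaflet, where $M$ is the face's lipid population (reference area over
  the composition-weighted area per lipid). This is the entropy that opposes
  demixing; peptides contribute no explicit per-face entropy term — their
  translational entropy emerges from the Monte Carlo moves that spread them
  over the mesh.

Shapes are compared through the reduced volume
$\nu_0 = 6\sqrt{\pi}\, V_0 / A_0^{3/2}$ (1 for a sphere, $1/\sqrt2$ for two
fused equal spheres).

## Curved elements

Instead of discretizing curvature operators on vertices, each triangle is a
curved patch assembled from cubic edge interpolants
$\varphi(t) = x_A + (d - c_1 - c_2)t + c_1 t^2 + c_2 t^3$ constrained by the
*vertex normals*, which are independent degrees of freedom of the sampler.
The endpoint tangents are required to be orthogonal to the vertex normal and
to the binormal estimate $d \times n$; the resulting 4×6 linear system is
underdetermined and solved minimum-norm with a pseudo-inverse (relative
singular-value cutoff $10^{-8}$), which keeps the construction finite even
for normal orientations where a quadratic-only interpolant degenerates. On
the patch, first and second fundamental forms — hence the full shape
operator, including off-diagonal elements — are evaluated at symmetric
triangle quadrature points. The default is the 6-point order-4 rule: it is
the cheapest symmetric rule whose weights are all positive, which keeps the
integrated squared curvature non-negative — under the negative-centroid
order-3 rule the pointwise curvature energy is indefinite on "hourglass"
patch shapes, and a Metropolis sampler will find and exploit exactly such
modes. Orders 1–5 remain selectable. Per-face $H$ and $K_G$ are
area-weighted quadrature means; the area, the signed volume contribution
and the integrated $H^2$ entering the energy come from the same
quadrature.

A tangent-continuity penalty across edges is exposed as configuration with a
default weight of zero: the geometric invariants (Gauss–Bonnet, convergence
under refinement) must not depend on it, and no principled default weight is
available.

## Material parameters and mixing rules

Per-lipid monolayer parameters (bundled defaults for DOPE, DOPS, DOPC, from
all-atom estimates: bending moduli from real-space tilt-divergence
fluctuations, spontaneous curvatures from stress-profile first moments) are
blended with the face's area fractions:
$J_s = \sum_i \phi_i c_i^0$ and harmonically $1/\kappa = \sum_i
\phi_i/\kappa_i$. Under peptide coverage $\phi_p$, the covered-material
values (per-lipid parameters measured with bound peptide at full coverage)
are mixed in linearly for $J_s$ and harmonically for $\kappa$, mirroring the
free-lipid rules. The fraction weighting inside the covered-lipid sum is the
only dimensionally consistent reading of the coverage rule and is used
throughout.

Leaflets combine with the outward-normal sign convention:
$\kappa_b = \kappa_{out} + \kappa_{in}$,
$J_s = J_{s,out} - J_{s,in}$, so identical bare leaflets have zero bilayer
spontaneous curvature and flat membranes are stress-free. Peptides bind the
outer leaflet only (they are applied from the outside, and an invagination
keeps the outer leaflet topologically exterior). The bilayer Gaussian
modulus uses the linear-in-thickness expansion per leaflet,
$\bar\kappa_b = -f(\kappa_{out}+\kappa_{in}) - 2d\,(J_{s,out}\kappa_{out} +
J_{s,in}\kappa_{in})$, which reduces to $2\bar\kappa - 4 J_s \kappa d$ for
symmetric leaflets. Defaults: monolayer Gaussian factor $f = 0.8$ (low end
of the accepted 0.8–0.85 band; results should be, and are documented to be,
insensitive to it) and $d = 2$ nm (a monolayer-scale thickness; no measured
value is available for this system). Energies are stored in kT at T = 300 K
(1 kT = 2.494 kJ/mol); lengths in nm.

## Monte Carlo protocol

Moves: vertex displacements (uniform cube), vertex-normal perturbations
(random perturbation followed by renormalization — the parameterization of
this move is a free choice; only its symmetry matters for detailed balance),
lipid swaps (two random species exchanged across a random edge by a uniform
random amount of *reference area*, so per-face reference area and global
species totals are conserved exactly), integer peptide hops across edges
(rejected when the destination would exceed full coverage), and bond flips
at a configured cadence (production default: every 1200 steps, 10 iterations
per cycle; neck constriction uses every 500 steps). The move mix defaults to
40/30/20/10% vertex/normal/lipid/peptide — the cadence of flips is
prescribed by the protocol, the mix itself is a package choice. Leaflets are
sealed: no flip-flop moves (a configuration switch can enable inner-leaflet
swaps among themselves, on by default; exchange *between* leaflets never
happens).

Step sizes start at 1.0 and are autotuned over the first 10 tuning cycles
(each cycle aggregates a batch of 500 attempts per move class — single-move
"acceptance" is 0/1 and cannot be tuned) toward targets of 0.3 / 0.7 / 0.8
for vertex / normal / lipid moves, then frozen so production sampling obeys
detailed balance.

Bond flips pool the two faces' lipid amounts and peptides and redistribute
them proportionally to the new face areas (peptides integer, biased to the
larger face); conservation is exact by construction. Mesh-quality guards
reject moves that create flat-triangle aspect ratios above 20, areas below
1% of the mean, or — important in practice — near-conical faces with
$|H| > 1$ nm⁻¹ or per-face $|K_G| \cdot A$ above 2. The last guard exists
because Gauss–Bonnet only constrains the *integral* of $K_G$: once
$\bar\kappa_b$ varies with composition, an unconstrained mesh can segregate
lipids so that cone-like spikes drain energy without bound. The caps are set
an order of magnitude above the curvatures a resolved neck reaches, and well
below the conical regime.

Target volumes follow piecewise-linear schedules. The stomatocyte protocol
first deflates a sphere to a deep transient target (default $\nu_0 = 0.60$),
then oscillates $V_0$ near the working reduced volume (default 0.75; a
triangle wave of ±0.03 — the oscillation shape is a package choice) under
high-frequency remeshing to constrict the neck while re-inflating. The
deflation default sits below the two-fused-spheres value $1/\sqrt2$ on
purpose: at the 500-face resolution used throughout, the shallower target
produces only dimples that thermal shape fluctuations flatten again, whereas
a transient deep deflation followed by re-inflation retains the bud. A configuration is
classified as a stomatocyte when faces with $H < 0$ and $K_G > 0$ (the bud
interior) cover at least 5% of the area.

One master seed feeds a single deterministic generator stream; a seeded run
is reproducible bit-for-bit on the same build. Derived seeds (simple small
offsets) separate protocol phases.

## Flat-patch calibration

The only free parameter of the mesoscale model is the peptide footprint area
$A_p$. It is calibrated on a flat patch by the two-region demixing model:
covered composition $x$, uncovered $y$, lipid conservation
$M_{cov} x_i + M_{unc} y_i = M \phi_i$, and

$$
F(x) = n_p \sum_i x_i \mu_{ads,i}
 + k_B T \left[ M_{cov} \sum_i x_i \ln x_i + M_{unc} \sum_i y_i \ln y_i \right].
$$

The objective is convex; its interior stationarity condition collapses to a
one-dimensional monotone root find solved to machine precision
(`equilibriumDemix()`), cross-checked in the tests against brute-force grid
minimization. The covered lipid count is $n_p A_p$ over the
composition-weighted area per lipid of the *global* composition (held fixed
during the minimization, which keeps the calibration deterministic and the
excess counts exactly count-conserving, $\sum_i \Gamma_i = 0$).
`optimizeFootprint()` then fits $A_p$ by equally weighted least squares of
the model's per-peptide excess lipids $\Gamma_i = M_{cov}(x_i -
\phi_i)/n_p$ against measured Kirkwood–Buff excesses. For the validation
patch of 64 lipids with one peptide the covered ratio is imposed directly
(32.8%), because the implied per-lipid area is the authoritative statement
there. The predicted binding free energy is the free-energy difference
between the bound, demixed state and the unbound uniform patch, per peptide.

This two-region ideal model captures binding-driven enrichment of the
strongly bound species and its competition with mixing entropy. It does not
contain area-packing or curvature-frustration contributions to the covered
region; consequences for what the calibration can and cannot reproduce are
discussed under Limitations.

## Parameter extraction from simulation observables

`kappaFromTilt()` inverts the Gaussian equilibrium distribution of the tilt
divergence, $\kappa = 1/(A_l\,\mathrm{Var}[\nabla\!\cdot t])$;
`tiltModulus()` uses the analogous per-area magnitude estimator
$\kappa_\theta = 2/(A_l \langle |t|^2\rangle)$. The exact normalization
convention of the tilt modulus differs between formulations in the
literature; the implemented form is documented here and validated on
self-consistent synthetic data only. Stress-profile operations are plain
trapezoid quadrature on the supplied grid (matching typical
molecular-dynamics post-processing output): the normal-pressure offset from
the tension-free condition $\int[\pi(z) - p_N]dz = 0$, the first bending
moment $\kappa J_s = \int_0^l \pi z\,dz$ with the *midplane* as origin (the
integration limits define it so; a pivotal-plane origin would shift $J_s$),
and the bilayer Gaussian modulus $\bar\kappa_b = \int_{-l}^{l} \pi z^2 dz$.
Units are declared in the file header (`kT/nm^3` or `bar`; 1 kT/nm³ = 41.4
bar at 300 K). Standard errors use a moving-block bootstrap (200 resamples,
block length from the series' statistical inefficiency) — the exact recipe
behind published error bars is rarely stated, so the package picks one and
names it.

## Post-processing

`statisticalInefficiency()` integrates the normalized autocorrelation
function up to its first zero crossing (automatic windowing),
$s = 1 + 2\sum C(k)$, and corrects the standard error by $\sqrt{s/N}$; 95%
intervals use 1.96. `binAverage2D()` builds curvature-resolved sorting maps:
per-face fractional excess coverage $\bar\Gamma = n/n_0 - 1$ binned over
$(H, K_G)$, averaged snapshot-wise first to preserve spatial correlations.
Sparse bins below a count quantile (default 2% — the published exclusion
region has no stated threshold, so it is configuration here) are masked, and
bins with $H^2 < K_G$ are flagged as geometrically impossible.

# What the synthetic generators emulate

The fixtures produce exactly the observable *formats* the estimators
consume, with known ground truth: Gaussian tilt-divergence samples at
variance $1/(\kappa A_l)$, stress profiles built from mirrored Gaussian
bumps whose moments match requested targets analytically, radial
distribution functions with closed-form excess integrals, AR(1) energy
series with known integrated autocorrelation, and geodesic meshes with exact
analytic normals. They do **not** emulate finite sampling artifacts of real
trajectories (drift, aging, non-Gaussian tails, correlated noise across z),
so passing recovery tests demonstrates correctness of the estimators, not
robustness to real-data pathologies.

# Problem sizes

The test suite and the reproduction script run at deliberately reduced
scale, chosen so each simulation still resolves the physics it checks: a
geodesic sphere of 500 faces (frequency 5) for shape-stability runs with
several hundred thousand Monte Carlo steps per branch, 2000+ faces for
geometry invariants, and $10^5$-sample synthetic sets for estimator
recovery. Full production work would use meshes sized so the mean face area
matches the peptide footprint (about 2000 faces for a 50 nm vesicle) and
order $10^7$ steps.

# Known limitations

* The two-region demixing model is ideal: no packing (area-per-lipid)
  selectivity, no curvature frustration under the peptide. With whole-peptide
  binding energies diluted over ~23 covered lipids, the model's species
  discrimination between similar binders (DOPE vs DOPC) is weak, and the
  sorting it feeds into the mesoscale model is correspondingly conservative.
* At the reduced problem sizes the test suite uses (500 faces), the
  peptide-specific branch ordering is reproduced but the R9 inversion is
  marginal: the stomatocyte-vs-spheroid mean-energy gap is comparable to the
  slow collective fluctuations of the membrane area, so individual seeded
  runs scatter around the inversion point. The robust, seed-independent
  signal at this scale is the monotone trend no-peptide > K9 > R9 of the
  stomatocyte's relative cost.
* Gaussian-modulus physics rests on the $\bar\kappa = -f\kappa$ approximation
  and a nominal thickness; the curvature caps regularize the short-wavelength
  pathology this term would otherwise open.
* Monte Carlo time is not physical time; only equilibrium comparisons are
  meaningful.
* Bond-flip redistribution is deterministic given the flip, so remeshing
  cycles are a relaxation device rather than a strictly detailed-balanced
  move class; energy comparisons between branches use identical remeshing
  cadence.
* Electrostatics enters only implicitly through the measured binding free
  energies and covered-lipid elastic parameters.
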