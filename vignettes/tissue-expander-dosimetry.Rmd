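---
title: "Dosimetry of metal-port breast tissue expanders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosimetry of metal-port breast tissue expanders: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Post-mastectomy radiotherapy is frequently delivered through a temporary
tissue expander (TTE): a silicone balloon, gradually filled with saline,
whose injection and drain ports are located with a small high-density
NdFeB magnet inside a titanium or PEEK casing. The magnet does two
unpleasant things to a photon treatment plan. First, it attenuates the
beam, producing an underdose shadow distal to the port. Second, it
saturates the CT scanner's Hounsfield-to-density conversion (most
clinical tables cap near 2.5 g/cm^3, far below the magnet's ~7.4 g/cm^3)
and blooms into a metal artifact much larger than the true part, so the
planning system computes dose on wrong densities unless the artifact is
handled explicitly.

Two clinical artifact-handling strategies are modeled here:

* **RS1** — window-level the CT to show only the brightest region, keep
  that artifact at its (saturated) CT density, and override the
  surrounding voxels to unity density;
* **RS2** — rigidly register a vendor-supplied geometric template of the
  port (true dimensions, materials and densities) to the artifact, and
  override everything else in the region to unity.

The package builds synthetic phantoms of the two benchmark irradiation
setups used to characterize three expander models (single-port DermaSpan,
dual-port AlloX2, dual-port AlloX2-Pro), computes dose with a voxel Monte
Carlo engine and an analytic raytracer, and quantifies the port effect and
the RS1/RS2 differences with depth-dose profiles, gamma indices and DVH
parameters (D1, D10, mean).

## Geometry and the synthetic-data generator

All inputs are generated internally; there are no external data sets.

**Port templates** (`port_template()`). The magnet dimensions are the
vendor-quoted values: 2.41 mm thickness (DermaSpan), 2.50 mm (each AlloX2
magnet), and 7.14 mm x 10.4 mm diameter (AlloX2-Pro). Casing outer
dimensions are not published; the package uses canonical defaults — a
31.2 mm DermaSpan magnet in a 0.8 mm titanium shell, 26 mm AlloX2 magnets
in 0.4 mm titanium shells 32 mm apart, and the AlloX2-Pro magnet in a
1 mm PEEK sleeve between two PEEK drain/injection ports. These defaults
respect the published relations (the commercial magnets are about three
times wider than the AlloX2-Pro one; the single-port DermaSpan carries a
somewhat heavier casing) and every dimension is a visible constant.

**Wax-slab scene** (`wax_slab_scene()`): a 30 x 30 x 1.7 cm^3 paraffin
slab (0.92 g/cm^3) with the port embedded at its center, between 1.5 cm
of water-equivalent plastic upstream and 10 cm downstream; a 6 MV AP
15 x 10 cm^2 field at 100 cm SSD delivers 500 MU.

**Breast scene** (`breast_scene()`): a water-filled silicone balloon
(about 1 mm shell, 1.1 g/cm^3) shaped as a truncated ellipsoid resting in
a wax holder, the port assembly inside the balloon near the anterior
apex, and a 5 mm wax bolus on top. The balloon half-axes (24, 52, 42 mm,
posterior truncation at +28 mm) were chosen once so that the four 3-mm
shell-expansion contours (`make_shell_contours()`) have volumes in line
with the published contour volumes (anterior ~17.6 cc, posterior
~15.4 cc); they were fixed before any dose calculation and not revisited.
A 6 MV 3 x 3 cm^2 conformal arc, gantry 90 to 270 degrees
counterclockwise through the anterior hemisphere, delivers 355 MU. The
isocenter sits on the magnet the analysis profiles traverse — the
drain-port magnet for AlloX2, the central magnet for AlloX2-Pro — the
worst case in which the port stays in-beam for the whole arc.

**Voxelization** (`voxelize()`). Solids are composited in priority order
(magnet over casing over balloon/slab), emulating layered-geometry
overlap handling. Rasterization is *mass-conserving*: per-voxel density
is the coverage-weighted mixture of the solid and what lies beneath,
with exact per-axis overlaps for boxes and cylinder heights and
subsampled coverage for disc cross-sections and ellipsoids. This matters:
a 2.41 mm magnet on the default 2 mm grid would otherwise occupy one or
two whole voxels depending on sub-voxel alignment, changing its areal
mass — and hence the attenuation it casts — by tens of percent. Labels
follow majority (>= 50%) coverage.

**Synthetic CT** (`synthesize_ct()`). Density maps to HU through a
piecewise-linear curve (air -1000, water 0, then 1000 HU per g/cm^3)
capped at the saturation density (default 2.5 g/cm^3), so metal voxels
read back 2.5 g/cm^3 regardless of their true density. With `bloom = TRUE`
the bright footprint of titanium-encased ports is dilated along the beam
axis so the apparent artifact is about three times the magnet thickness;
the PEEK-encased AlloX2-Pro shows only its saturated magnet, so its
artifact stays about the magnet's own size. Bloom is restricted to the
beam axis (the dimension the published observations quantify), which also
keeps the two AlloX2 ports separable in the CT. An optional seeded streak
model adds low-amplitude HU noise; it is off by default.

What the generator does **not** emulate: reconstruction physics (beam
hardening, sinogram-domain streaks, residuals of iterative metal-artifact
reduction), partial-volume blur of the scanner, couch structures, or
anatomic heterogeneity. Passing tests therefore demonstrate that the
pipeline reproduces the published dosimetric mechanisms under an idealized
artifact model, not that it would segment a clinical CT.

## Artifact strategies

`rs1_override()` thresholds the CT at the HU of 2.0 g/cm^3 by default
(the published procedure says only "the brightest region"), keeps the
largest connected components up to the model's port count, leaves the
artifact at its CT density and sets the rest of the override region to
unity. The override region defaults to the artifact bounding box plus
1 cm (slab) or the bag plus 1 cm (breast); its extent is not published
and is exposed as a parameter. All RS1 voxels transport as
density-scaled water, as a TPS does after a density override.

`rs2_register()` estimates the template pose from the artifact centroid,
then refines it by exhaustive search over +/-3 voxels of translation and
+/-10 degrees of in-plane rotation (1 degree steps), maximizing the Dice
overlap between the template's high-density footprint and the artifact
mask. The search is deterministic; ties break toward the smallest
translation, then the smallest rotation; an overlap floor (default Dice
0.2) raises a registration failure. The registered template is voxelized
with its true materials — the magnet at 7.4 g/cm^3 even though the CT
says 2.5.

Two no-port baselines exist deliberately. `no_port_grid()` rebuilds the
true phantom with the port replaced by the enclosing medium (wax or
water): this is the physical baseline for the wax-slab port-effect
profiles. `no_port_override()` removes the port from the *planning*
context (whole override region at unity density): this is the baseline
for the DVH difference tables, so that a tabulated "no port minus RS2"
isolates the port representation rather than the override bookkeeping.

## Dose engines

**Monte Carlo** (`mc_dose()`). Photons are sampled from the source
spectrum across the rectangular aperture of a point source at 100 cm.
Free flights use Woodcock delta tracking against an exact energy-dependent
grid majorant; below 0.3 MeV — where photoelectric absorption in the
magnet drives the majorant and delta tracking would reject almost every
tentative collision — flights switch to exact voxel ray-marching with
optical-depth sampling (the two samplers draw from the same distribution;
this is purely an efficiency device). Interactions: photoelectric
absorption, Compton scattering sampled from the exact free-electron
Klein–Nishina distribution by rejection, and pair production with two
tracked 511 keV annihilation photons. Photons below 10 keV are absorbed
on the spot.

Dose is scored with a **track-length collision-kerma estimator**: every
voxel segment of every photon flight contributes
`E * (mu_tr/rho)(E, material) * dl / V`. The energy-transfer coefficient
uses the Klein–Nishina mean electron fraction for the Compton channel.
This estimator is the reason desk-scale history counts work at all: at
the study's 2-4 million histories, analog local deposition on a 2 mm
grid would leave tens of percent of per-voxel noise, swamping every
percent-level quantity of interest. Energy bookkeeping stays analog and
exact (launched = transferred + escaped to machine precision), and is
asserted to 0.1%.

Kerma scoring means **no electron transport**: dose equals collision
kerma. Consequences, stated plainly: there is no buildup ramp (the water
"dmax" sits essentially at the surface), interface doses within about
2 mm of material boundaries are approximate, the mm-scale
electron-backscatter enhancement upstream of metal faces is absent, and
shadows whose lateral size is comparable to the 6 MV secondary-electron
range (~mm) are *not* healed by lateral electron spread. The narrow
10.4 mm AlloX2-Pro magnet sits squarely in that regime; see Limitations.

Statistical uncertainties come from >= 10 independent batches; per-voxel
relative uncertainty is the standard error of the batch mean. Runs are
bit-reproducible for a fixed seed, with per-history random substreams.
Paired runs (port vs no-port, RS1 vs RS2) share one seed and one majorant
via `majorant_from`, so photon histories are identical wherever the two
geometries agree: difference profiles then carry only the variance of the
genuinely diverging paths (correlated sampling), which is what makes
sub-percent difference uncertainties reachable at these budgets.

**Raytracer** (`raytrace_dose()`). The deterministic stand-in for a TPS
algorithm: per-voxel dose proportional to
`exp(-optical depth) x inverse square x B(d_eff) x (1 + k_s d_eff)`,
with the optical depth accumulated by Siddon-style traversal at the
spectrum's effective energy, a buildup factor `B(d) = 1 - exp(-beta d)`
(`beta` = 2.7 cm^-1, placing the peak near the clinical 6 MV dmax), and a
linear scatter-buildup term with `k_s` = 0.024 cm^-1 commissioned once
against the package's Monte Carlo water depth-dose curve (agreement
within 3% between 2 and 20 cm depth, the region the package uses; the
buildup region is excluded by construction). It models no penumbra and
no in-scatter around heterogeneities.

**Source spectrum** (`spectrum_6mv()`). No vendor phase-space files are
used; the 6 MV spectrum is the documented parameterization
`phi(E) ~ E exp(-E/T)` on 0.25-6 MeV with `T` = 0.9 MeV, giving a
fluence-weighted mean ("effective") energy of about 1.8 MeV, in line with
published flattened 6 MV spectra. A monoenergetic override exists for
benchmarks.

**Calibration** (`calibrate_engine()`). A 10 x 10 cm^2, SSD 100 water
reference run fixes 1 cGy/MU at the depth of maximum dose, with a
fluence-area correction for other field sizes; the central-axis curve is
summarized by a least-squares exponential fit over 5-15 cm depth
(`fit_pdd_exponential()`), the standard way a calibration protocol reads
the dose at 10 cm from a noisy curve. All published comparisons are
dose *ratios*, so calibration affects units, not conclusions.

## Physics data

No cross-section database is bundled from an external source; the element
tables in `inst/extdata/xs_photon.csv` (0.01-10 MeV, ~53 log-spaced
points, regenerable with `tools/make_xs_tables.R`) are computed from
standard analytic physics:

* incoherent scattering: exact free-electron Klein–Nishina total cross
  section times the electron density `N_A Z / A`;
* photoelectric: a two-term `Z^4.6/E^3.25 + Z^5/E` parameterization
  anchored on classic water and high-Z values;
* pair production: a universal energy curve obtained as the residual of
  the classic water attenuation totals minus the Klein–Nishina part,
  scaled between elements by `Z(Z+1)/A`.

Coherent (Rayleigh) scattering is excluded throughout — a few-percent
effect below 0.1 MeV and negligible for 6 MV dose ratios. Absorption
edges are not modeled (the Nd K-edge at 43.6 keV affects only photons
that are locally absorbed either way at these geometries). Interpolation
is log-log, identically in R and in the transport kernel. The tables
reproduce classic anchor values (water at 2 MeV: 0.0494 cm^2/g against
the textbook 0.0493) within the tested 2%.

The magnet density deserves a note: vendor literature quotes
7.6 g/cm^3 for the NdFeB magnet while the published attenuation analysis
uses 7.4 g/cm^3. Both are accepted; 7.4 is the default everywhere dose is
computed, and the density is a parameter of `tte_material("ndfeb")` and
`port_template()`.

## Analysis conventions

* Profiles (`extract_profile()`) are laterally averaged over a 1 x 1 cm^2
  window by default — the size of the measurement films in the benchmark
  setups — with uncertainties combined in quadrature.
* The gamma index (`gamma_index()`) uses global normalization to the
  reference maximum (local behind a flag); for curves the minimum over
  each linear segment is solved in closed form, making the implementation
  exact rather than search-grid-limited. Gamma is intentionally
  *asymmetric* under swapping the curves; a regression test guards this.
* D_x (`dvh_parameters()`) is the (100 - x)th percentile of the voxel
  dose distribution by linear interpolation of the empirical CDF
  (`quantile` type 7); the published convention is unstated. The
  run-level uncertainty attached to a DVH parameter is the standard error
  of the contour mean dose; combined uncertainties of differences add in
  quadrature.
* Percentage differences are normalized to the first-named run
  (`100 (A - B) / A`); positive entries mean the first-named run is
  hotter. The published normalization is unstated; this one is recorded
  in every report header.
* The maximum distal underdose is read from the smoothed (3-point moving
  average) film-window profile over the whole region beyond the slab;
  the proximal overdose search stops 1 mm above the port assembly.

## Problem sizes and reproducibility

The shipped studies use the published conditions at desk scale: 2 mm dose
grids, 2-4 million histories per wax-slab run and 8-16 million per arc
(split over 91 control points of the 180-degree arc at the default
2-degree spacing). At these sizes the paired-difference profiles carry
roughly half-percent uncertainties while a full characterization
(`reproduce_study()`, or `scripts/acceptance.R`) runs in minutes on one
CPU. Every stochastic stage takes an explicit integer seed; outputs carry
seeds and a configuration hash in their sidecars.

The published simulations kept per-voxel statistical uncertainty at or
below 0.5%; that figure was achieved with on the order of 5 x 10^10
effective histories (10^9 per phase space with 50-fold particle
splitting). The package reports its own per-voxel batch uncertainty
honestly — a few percent at the desk-scale budgets; reaching 0.5% per
voxel would need on the order of 10^9 histories. The *difference*
quantities the characterization actually rests on are far better
conditioned than per-voxel dose because of the correlated paired runs.

## Known limitations

* **Kerma approximation.** The dominant limitation. Quantities governed
  by electron transport are out of reach: the proximal
  electron-backscatter overdose at metal faces (published at ~3%
  decaying within 5 mm for the AlloX2-Pro) appears only at its small
  photon-backscatter level here, and the distal shadow of the narrow
  AlloX2-Pro magnet, which in reality is largely filled in by lateral
  electron spread and measured at ~2%, remains at the photon-only level
  of roughly 10-14% in this engine. The wide-magnet models
  (DermaSpan, AlloX2), whose shadows are much wider than the electron
  range, are reproduced well. This asymmetry is itself a faithful
  illustration of *why* the published analysis attributes the AlloX2-Pro
  behavior to in-scatter over its small cross-section.
* The analytic "about five percent" magnet attenuation estimate is
  reproduced only under a hard-spectrum reading: at the fluence-weighted
  mean energy (~1.8 MeV) the closed form gives ~7%, at 4-6 MeV it gives
  5-6%. The package computes the check at the effective energy and
  documents the spread rather than choosing the flattering number.
* **Dual-port arc geometry.** A 3 x 3 cm^2 field cannot keep two ~26 mm
  ports simultaneously in-beam; the package centers the arc on the
  drain-port magnet (32 mm from its twin, the smallest separation that
  keeps the two CT artifacts distinct). Even so, the posterior-shell D10
  deficit computes one to two percentage points smaller than the
  published table value — the combination of photon-only scatter fill
  and a port/field arrangement that the text alone does not pin down.
* The CCC treatment-planning algorithm is represented by the primary-beam
  raytracer; no penumbra, head scatter, or heterogeneity kernels.
* Casing geometries are canonical, not vendor-exact; all dimensions are
  parameters.
* The synthetic CT's artifact model is geometric (saturation + axial
  bloom), not a reconstruction simulation.
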