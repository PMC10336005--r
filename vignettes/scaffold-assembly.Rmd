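---
title: "Models and methods: lattice self-assembly, equilibrium sedimentation, and MINFLUX cylinder statistics"
author: "pcmscaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmscaffold)
```

# The biological problem

Centriole duplication is seeded on a pericentriolar scaffold in which a 2:2
coiled-coil heterotetramer (the Cep63•Cep152 building block) self-associates
into octamers, hexadecamers and ultimately a hollow cylindrical
super-assembly around the centriole. This package implements the three
quantitative strands of that story: (i) a square-lattice mass-action model
that converts two measured dissociation constants into a contact energy and
predicts species abundances, saturation and nucleation behaviour; (ii) a
sedimentation-equilibrium simulator and global fitter that recovers those
dissociation constants from multi-speed, multi-loading absorbance data; and
(iii) a MINFLUX single-molecule localization pipeline that measures the
cylindrical geometry and local concentration of the assembled scaffold.
Seed-deterministic synthetic-data generators stand in for raw instrument
data throughout.

# The lattice model of tetramer self-association

The tetramer is treated as a square tile; each of its four faces can bind a
neighbouring tile with contact free energy $\epsilon$ (in units of
$k_\mathrm{B}T$, negative = attractive). With a reference concentration
$c_0$ fixing units, mass action gives for the octamer (one contact) and the
hexadecamer (a 2x2 square, four contacts)

$$k_8 = \frac{c_4^2}{c_8} = c_0 e^{\epsilon}, \qquad
  k_{16} = \frac{c_4^4}{c_{16}} = c_0^3 e^{4\epsilon}.$$

Given measured $k_8$ and $k_{16}$ this is a log-linear system with the
closed-form solution $c_0 = k_8^4 / k_{16}$, $\epsilon = \ln(k_8/c_0)$
(`derive_interaction_params()`). Everything else follows:

* `species_distribution()` solves the conservation equation
  $c_4 + 2c_4^2/k_8 + 4c_4^4/k_{16} = c_\mathrm{tot}$ for the free tetramer
  by bisection. The left side is strictly increasing, so the root on
  $[0, c_\mathrm{tot}]$ is unique and bisection cannot diverge even for
  degenerate constants; we iterate to a relative width of $10^{-14}$.
* `predict_dodecamer()` uses the two contacts of a linear trimer of
  tetramers: $c_{12} = c_4^3/k_8^2$. Its low predicted abundance relative to
  the hexadecamer (about 5-fold at 12.6 uM loading, 15-fold at 55 uM) is
  the model's explanation for why no dodecamer is seen experimentally.
* `saturation_concentration()` balances the dilute chemical potential
  $\ln(c_4/c_0)$ against the bulk lattice energy of two contacts per added
  tile: $c_\mathrm{sat} = c_0 e^{2\epsilon}$, identical to the stepwise
  octamer–octamer dissociation constant $k_{16}/k_8^2$.
* `free_energy_profile()` evaluates
  $G(L) = 2L(L-1)\epsilon - L^2\ln(c_4/c_0)$ for square $L \times L$
  assemblies, and `critical_nucleus()` takes the integer argmax. $L$ is
  restricted to integers because the contact count $2L(L-1)$ is a lattice
  counting argument; interpolating to continuous $L$ would have no physical
  meaning here.

```{r thermo}
k <- dissociation_constants(k8 = 370e-6, k16 = 3.0e-13)
(p <- derive_interaction_params(k))
st <- species_distribution(55e-6, k)
critical_nucleus(p, st$c4, L_max = 20)
```

The free tetramer concentration (not the total loading) enters $G(L)$: the
equilibrium solve at 55 uM total gives $c_4 \approx 33$ uM, which yields the
~10 $k_\mathrm{B}T$ barrier at $L=2$; using the total loading instead would
give ~8 $k_\mathrm{B}T$. The choice is exposed through the `c4` argument, so
a caller who wants a different convention passes a different concentration.

# Sedimentation-equilibrium simulation and global fitting

At equilibrium each species $i$ with molar mass $M_i$ follows
$c_i(r) = c_i(r_0)\exp[\sigma_i(r^2-r_0^2)/2]$ with
$\sigma_i = M_i(1-\bar v\rho)\omega^2/RT$. `simulate_profile()` pins the
species reference concentrations to mass action and scales the free-unit
reference so the sector-shaped cell average
$\int c\, r\,\mathrm{d}r / \int r\,\mathrm{d}r$ equals the loading — the
mass-conservation constraint used in global fitting practice. The average
of each exponential has the elementary closed form $(\mathrm e^{S}-1)/S$
with $S=\sigma(b^2-a^2)/2$, so conservation is enforced exactly by a 1D
root solve rather than by quadrature (the tests verify it against a
trapezoidal oracle).

`global_fit()` estimates the $\log_{10}$ dissociation constants. Per-cell
baselines and the extinction ratio of each non-reference wavelength (the
250 nm extinction is unknown and fitted, as in standard practice) enter the
model linearly, so they are profiled out in closed form at every objective
evaluation (variable projection). Only the $\log_{10} K$'s are left to the
optimiser (`nlminb`), started three times at the default start and at
$\pm 2$ log units to guard against local minima. Defaults for the solvent
($\bar v = 0.73$ mL/g, $\rho = 1.015$ g/mL, 277.15 K) describe a chilled
citrate buffer; the free-unit mass defaults to 51,800 Da, the calculated
heterotetramer mass. The reference 280 nm extinction default (30,000
M$^{-1}$cm$^{-1}$) sets only the overall signal scale of simulations.

Confidence limits follow the F-statistic scan convention:
`fstat_confidence()` fixes one constant at a series of values, refits all
other parameters, and reports where the residual sum of squares crosses
$RSS_\mathrm{best}\,(1 + F(level; 1, \nu)/\nu)$. The crossing is located by
bisection inside the bracketing scan step because the RSS surface is
locally quadratic and a linear interpolation across a wide step would
misplace it. Intervals are allowed to be asymmetric. `compare_models()`
fits a list of candidate ladders (e.g. 1–2–3, 1–2–4, 1–2–6, 1–2–8, and an
isodesmic ladder with a single stepwise K up to n = 8) and ranks them by
reduced $\chi^2$, defined as $RSS/\nu$ since the noise variance is not
assumed known.

# The MINFLUX localization pipeline

A MINFLUX trace is a run of sequential localizations of one fluorophore.
The pipeline reproduces the processing chain literally, in order:

1. `filter_traces()` removes traces with fewer than 5 localizations
   (inclusive boundary: 5 is kept) — short traces are dominated by
   background.
2. `collapse_traces()` reduces each trace to a photon-weighted mean
   position per axis; one trace is assumed to be one molecule, the ~9%
   blink-splitting rate being handled separately as an overcount statistic.
3. `estimate_precision()` reports the median over traces of the per-trace
   coordinate standard deviation; per-axis standard deviations are averaged
   to one scalar per trace before the median. Pooling in 3D instead would
   change the value by a deterministic factor; the averaged-axis convention
   was chosen because the upstream definition refers to "the" coordinate
   standard deviation without pooling.
4. `fit_circle()` locates the cylinder axis by an algebraic (Kasa)
   least-squares circle, refined by geometric Gauss–Newton. The cylinder
   axis is taken parallel to optical z through the fitted center — the
   fitting is only ever done in x–y, so a tilted centriole appears slightly
   widened; no PCA pre-alignment is applied by default.
5. `cylinder_stats()` computes Tukey whiskers (quartiles $\pm$ 1.5 IQR,
   linear-interpolation quantiles) on the radial distance and on z, flags
   molecules outside either whisker range as outliers, excludes them once
   (a single pass, no iteration), and then reports the mean diameter, the
   5th–95th percentile radial width and height, the percentile shell volume
   $\pi(R_{out}^2 - R_{in}^2)h$, and the molar concentration of in-shell
   molecules (`concentration_in_shell()`).
6. `render_density()` bins localizations into cubic voxels (0.5 nm default)
   and smooths with a normalized 3D Gaussian kernel ($\sigma$ = 4 nm
   default), padding the volume so total intensity is conserved.
7. `labeling_statistics()` implements the nuclear-pore calibration
   arithmetic: label fraction $p$ from the cluster/dimer ratio, single-trace
   cluster fraction $1-p^2$, expected trace count $n(1+p^2)$, and the
   observed-over-expected overcount.

```{r nup}
labeling_statistics(n_clusters = 81, n_pores = 24, dimers_per_pore = 16,
                    observed_traces = 93)
```

# What the synthetic data emulates — and what it does not

`gen_cylinder_molecules()` places molecules uniformly in a hollow
cylindrical shell: radius uniform in $r^2$ (uniform areal density — note
this makes the expected radial distance slightly larger than the mid-wall
radius, by ~2.7% at the default geometry), z uniform, angle uniform. The
defaults (192 nm mid radius, 109 nm wall, 262 nm height, 300–600 molecules)
are the wild-type scaffold dimensions. The "clumped" mode concentrates
angles into 1–2 wrapped-Gaussian lobes and halves the density, a free
parameterisation validated only directionally (it produces the lower
in-shell concentration and larger angular concentration expected of
assembly-defective mutants); no quantitative mutant geometry is claimed.

`gen_localization_traces()` models labeling as Bernoulli, blinking as a 9%
chance of a second trace, localizations per trace as shifted Poisson,
photons as log-normal and localization error as isotropic Gaussian with
13 nm standard deviation — the measured precision. Background traces are
short by construction so the length-5 filter is the discriminator. Real
data differ in ways the generator does not model: drift (corrected at
acquisition with fiducials), anisotropic z precision, molecule-density-
dependent trace merging, and unlabeled-epitope heterogeneity. Passing the
recovery tests therefore demonstrates the correctness of the statistical
pipeline, not the instrument model.

`gen_sedeq_dataset()` adds i.i.d. Gaussian absorbance noise (0.005 AU
default) to exact forward profiles over the 3 loadings x 3 speeds x 2
wavelengths design; real equilibrium data additionally carry radial
baseline structure and aggregation losses at high loading, which are out of
the model (the fitter never models aggregates).

# Numerical choices and problem sizes

* Bisection everywhere a 1D monotone root is needed (species equilibrium,
  mass conservation, F-stat crossing); tolerances $10^{-14}$ relative for
  equilibria, 12 bisection steps inside a 0.05 log-unit scan step for
  confidence crossings.
* All concentrations are molar internally; conversions to uM/mM happen only
  at display boundaries. Energies are in $k_\mathrm{B}T$ throughout.
* Quantiles use linear interpolation between order statistics (R type 7),
  the common spreadsheet convention.
* Degenerate inputs: a non-supersaturated solution returns a flagged
  no-barrier result rather than an error; an all-equal radial distribution
  collapses the whisker shell to zero width and reports `NA` concentration;
  a zero-photon trace falls back to the unweighted mean with a warning.
* Simulation studies in the test suite use 60–100 radial points per
  profile, 20 seeds for parameter-recovery/coverage checks, and 100 seeded
  cylinders of 300–600 molecules for geometry recovery. These sizes give
  Monte-Carlo error comfortably below the tolerances being asserted while
  keeping the suite quick to run.

# Known limitations

* The lattice model is 2D and equilibrium-only: no off-lattice geometry,
  no kinetics, and no long-range electrostatic correction (relevant at low
  pH, where excess positive charge may suppress growth beyond the
  hexadecamer).
* The fitter supports both the ($k_8$, $k_{16}$) tetramer-level
  parameterisation and stepwise constants via the identity
  $K_\mathrm{oct-oct} = k_{16}/k_8^2$, but does not attempt to reproduce
  any particular vendor software's internal parameterisation.
* Trace-to-molecule matching is identity (one trace = one molecule); the
  blink overcount is surfaced as a correction factor, not used to merge
  traces spatially.
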