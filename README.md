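# pcmscaffold

Quantitative tools for the concentration-dependent self-assembly of
coiled-coil heterotetramer building blocks into the cylindrical
pericentriolar scaffold that templates centriole duplication. The package
is aimed at structural biophysicists and quantitative cell biologists who
need to (a) interpret self-association constants mechanistically, (b)
simulate and globally fit sedimentation-equilibrium data for reversible
self-association, and (c) process MINFLUX single-molecule localization
data into cylindrical geometry and concentration statistics.

## The models

**Lattice self-association.** The heterotetramer is a square tile whose
faces bind neighbours with contact free energy ε (kBT). Mass action links
the octamer and hexadecamer dissociation constants to two lattice
parameters,

    k8 = c0·e^ε        (octamer ⇌ 2 tetramer, M)
    k16 = c0³·e^{4ε}   (hexadecamer ⇌ 4 tetramer, M³)

solved in closed form as c0 = k8⁴/k16, ε = ln(k8/c0). From these follow the
species distribution at any loading (bisection on the conservation
equation c4 + 2c4²/k8 + 4c4⁴/k16 = c_tot), the predicted dodecamer
c12 = c4³/k8², the saturation concentration c_sat = c0·e^{2ε} = k16/k8²,
and the classical-nucleation profile over square L×L assemblies,
G(L) = 2L(L−1)ε − L²·ln(c4/c0), whose integer argmax is the critical
nucleus.

**Sedimentation equilibrium.** Each species settles into
c_i(r) = c_i(r0)·exp[σ_i(r²−r0²)/2] with σ_i = M_i(1−v̄ρ)ω²/RT; the
simulator enforces sector-cell mass conservation exactly and the global
fitter estimates log10 K's across speeds/loadings/wavelengths with
per-cell baselines and the unknown 250 nm extinction profiled out,
F-statistic confidence scans, and reduced-χ² model comparison (including
an isodesmic alternative).

**MINFLUX pipeline.** Traces shorter than 5 localizations are discarded;
each remaining trace is collapsed to a photon-weighted molecule position;
precision is the median per-trace coordinate standard deviation; the
cylinder axis comes from a least-squares circle fit (Kåsa + Gauss–Newton);
Tukey-whisker outlier exclusion and 5th–95th percentile statistics give
diameter, radial width, height, shell volume and in-shell molar
concentration; a Gaussian-smoothed voxel density volume renders the data;
and nuclear-pore control arithmetic calibrates labeling efficiency and
trace overcounting.

Seed-deterministic generators (`gen_cylinder_molecules()`,
`gen_localization_traces()`, `gen_sedeq_dataset()`, `gen_mass_histogram()`)
produce synthetic inputs with the statistical structure each stage assumes.

## Worked example

```r
library(pcmscaffold)

k <- dissociation_constants(k8 = 370e-6, k16 = 3.0e-13)
(p <- derive_interaction_params(k))
#> Lattice interaction: epsilon = -5.129 kBT, c0 = 0.06247 M

species_distribution(55e-6, k)
#> Species state at total 5.5e-05 M (tetramer units):
#>   free tetramer  3.309e-05 M (60.2%)
#>   octamer        2.96e-06 M (10.8%)
#>   hexadecamer    3.997e-06 M (29.1%)

critical_nucleus(p, species_distribution(55e-6, k)$c4, L_max = 20)
#> Critical nucleus L* = 2 (barrier 9.66 kBT)
```

The contact energy of −5.1 kBT and reference concentration ~62 mM turn the
two measured constants into a full assembly picture: at 55 µM loading the
hexadecamer already carries 29% of the mass while the octamer stays low —
the signature of cooperative assembly — and growth beyond the hexadecamer
must pass a ~10 kBT nucleation barrier at the 2×2 critical nucleus.

A synthetic wild-type centriole imaged and processed end to end:

```r
mol  <- gen_cylinder_molecules(cylinder_truth(n_molecules = 450), seed = 1)
recs <- gen_localization_traces(mol, imaging_model(), seed = 2)
res  <- minflux_pipeline(recs)
res$stats
#> Cylinder statistics (490 molecules, 0.0% outliers excluded)
#>   mean diameter  394.9 nm
#>   radial width   93.5 nm (p5-p95)
#>   height         235.2 nm (p5-p95)
#>   shell volume   2.71e+07 nm^3; 396 molecules in shell -> 2.43e-05 M

labeling_statistics(81, 24, 16, 93)
#> Labeling statistics:
#>   label fraction        21.1%
#>   single-trace fraction 95.6%
#>   expected traces       85
#>   overcount             9.4%
```

The recovered diameter, width and height sit within a few percent of the
generating truth (384/109/262 nm, shrunk by the 5th–95th percentile rule),
and the in-shell concentration lands in the tens-of-µM range expected for
the pericentriolar compartment.

`run_pipeline()` orchestrates the stages from a YAML or list configuration
and writes a JSON summary plus the resolved configuration for provenance.

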