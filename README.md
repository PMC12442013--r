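# bilayr

Comparative analysis of planar lipid-bilayer trajectories in R.

Membrane simulations are routinely judged by a standard battery of
observables: area per lipid, phosphorus–phosphorus thickness, lateral
density profiles and inner-region hydration, phosphate–phosphate radial
distribution functions, hydrogen bonding, C–H order parameters compared
against solid-state NMR, lateral diffusion, and the area compressibility
modulus. `bilayr` computes all of them from a topology (GRO/PDB) plus a
trajectory (DCD, or multi-frame GRO/PDB), driven by declarative
per-species lipid specifications (bundled for POPC, POPE and POPG), and
orchestrates multi-system comparisons — e.g. the same membrane under
different force fields — into a single report with CSV outputs and
figures. It is written for membrane simulators who want a reproducible,
parameter-explicit alternative to ad hoc analysis scripts.

Two pieces are worth singling out:

* **Capacity-normalized H-bond statistic.** Raw bond counts confound
  interaction propensity with abundance and bonding capacity. With
  `n_i` molecules of type `i`, each able to form `χ_i` bonds (per-atom
  rules: neutral O = 2, charged O = 3, polar H = 1),

  ```
  N_max = Σ_i χ_i·n_i,   P(Y) = χ_Y·n_Y / N_max,
  N_norm(X,Y) = N_obs(X,Y) / (N_max · [P(X) + P(Y)])
  ```

  giving a dimensionless, abundance-corrected interaction measure per
  ordered type pair (headgroup/glycerol per species, pooled solvent).

* **A synthetic bilayer with a ground-truth manifest.** There is no
  analytic bilayer, so the package generates an idealized one — lattice
  lipids at a prescribed area per lipid, P planes a prescribed distance
  apart, an exact inner water count, C–H vectors from prescribed tilt
  angles (so `S_CH = (3cos²θ−1)/2` exactly), a 2D random walk with
  prescribed D, and box-area fluctuations carrying a prescribed K_A —
  and every analysis is validated by recovering the manifest through
  real file I/O. See the methods vignette
  (`vignettes/membrane-analysis.Rmd`) for the construction and its
  limits.

## Worked example

```r
library(bilayr)

spec <- synthetic_bilayer_spec(
  species = data.frame(name = "SYN", n_upper = 64L, n_lower = 64L),
  n_frames = 200L, seed = 7L)
sim <- generate_bilayer(spec)

leaflets <- assign_leaflets(sim$trajectory)
area_per_lipid(sim$trajectory, leaflets)
#> <ts_stat> n = 200 frames: mean = 62.5, sd = 1.18035 A^2
bilayer_thickness(sim$trajectory, leaflets)
#> <ts_stat> n = 200 frames: mean = 3.99874, sd = 0.00889218 nm

profile <- lateral_density(sim$trajectory, leaflets, block_length = 5000)
inner_water_count(profile)$waters_per_lipid
#> 0.769 (prescribed: 0.8; the ~3% deficit is the documented binning edge effect)

head(compute_sch(sim$trajectory, "SYN", block_length = 5000), 3)
#>   species label   segment       S_CH  block_error n_samples
#> 1     SYN   C12 headgroup -0.4547695 0.000000e+00     51200
#> 2     SYN   C22      sn-2  0.4567280 2.355139e-16     51200
#> 3     SYN   C32      sn-1  0.5550525 1.110223e-16     51200

dd <- lateral_displacements(sim$trajectory, leaflets, window = 5)
diffusion_from_displacements(dd)
#>   estimator   D_nm2_ns      D_cm2_s
#> 1       msd 0.01017476 1.017476e-07
#> 2       mle 0.01017476 1.017476e-07

area_compressibility(sim$trajectory)
#> <compressibility_estimate> K_A = 300.0 mN/m (<A> = 40.00 nm^2,
#>   Var = 0.5707 nm^4, T = 310 K, n = 200)
```

The area per lipid lands on the prescribed 62.5 Å², the P–P thickness on
4 nm, each fixed-angle S_CH on its closed form (e.g. θ = 37° →
0.4567…), the diffusion estimate within sampling error of the
prescribed 0.01 nm²/ns, and K_A on the prescribed 300 mN/m.

For real data, replace the generator with
`load_system("system.gro", "traj.dcd", list(bundled_lipid_spec("POPC")))`
and drive everything at once through a YAML config:

```r
report <- run_pipeline("run.yaml")   # CSVs + summary.json per system
render_report("bilayr_out")          # figures from the CSVs
```

A thin command-line wrapper with `generate` / `analyze` / `render` verbs
ships in `inst/scripts/bilayr-cli.R`.

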