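# splintfea

Finite-element biomechanics of the mandibular dentition under occlusal load,
with and without a PMMA occlusal splint.

Occlusal splints are the standard appliance for treating masticatory-muscle
parafunction (bruxism): they change both the magnitude of the bite force and
its distribution across the teeth. `splintfea` implements the full analysis
chain for evaluating that redistribution:

1. **T-Scan calibration** — relative intraoral pressure-sensor readings
   (a dimensionless "raw sum" plus per-tooth percentage shares) are converted
   to absolute forces with the linear calibration
   `F = 0.021 × raw_sum + 8.022` (N) and distributed per tooth
   (FDI two-digit notation, quadrants 3 and 4).
2. **Synthetic dentition** — a parametric stand-in for patient CT: a voxel
   Hounsfield phantom with threshold segmentation and 26-connectivity
   component labelling, parametric tooth solids on a semicircular arch,
   0.25 mm periodontal-ligament (PDL) shells around the roots, an optional
   splint solid bonded gap-free to the crowns, and a conforming
   background-grid tetrahedral mesh (6-tet Kuhn pattern per cell).
3. **FE core** — constant-strain tetrahedra (3 translational DOF per node),
   isotropic linear elasticity in a consistent mm–N–MPa system
   (tooth E = 20300 MPa, ν = 0.26; PDL 68.90 MPa, 0.45; PMMA 2200 MPa,
   0.35), sparse Cholesky solution with residual verification, reactions,
   element-constant stress and von Mises recovery.
4. **Scenario pipeline** — three design options (1: no splint, per-tooth
   loads; 2: splint as manufactured; 3: splint after corrective grinding,
   both loaded on the splint top), per-region maxima, between-option
   ratios, and safety checks against physiological mobility (0.03 mm),
   dentin strength (44.40 MPa conservative tensile bound), per-class PDL
   limits (1.20–1.60 MPa) and the PMMA fracture stress (32.00 MPa).

All solids, meshes and loads are generated in code; no patient data is
required or included. The methods vignette
(`vignettes/splint-biomechanics.Rmd`) documents the model, its assumptions,
and — importantly — why the default synthetic dentition is reduced-scale and
what that means for interpreting magnitudes.

## Worked example: calibrating a measurement

```r
library(splintfea)

m1 <- tscan_measurement(1)          # bundled: no-splint acquisition
#> Occlusal measurement 'measurement1_no_splint': raw sum 11873, 14 teeth, shares sum 100.0%

total <- raw_to_newton(m1$raw_sum)  # 257.355 N, printed as 257.4
d1 <- distribute_force(total, m1)
round_half_up(d1$per_tooth_N[c("36", "37", "46", "47")], 1)
#>   36   37   46   47
#> 54.0 43.8 20.6 46.3
group_share(d1, c(36, 37, 46, 47))  # molars carry 64.0% of the load
#> [1] 64
measurement_ratio(total, raw_to_newton(tscan_measurement(3)$raw_sum))
#> [1] 1.497602     # the no-splint load is ~1.5x the post-grinding load
```

## Worked example: a toy scenario

```r
spec <- dentition_spec(n_teeth = 3)
run <- run_option(scenario_config(
  1, occlusal_measurement("demo", 7801, c("32" = 40, "31" = 35, "41" = 25)),
  spec))
run$summary
#>   region max_disp_mm max_vm_MPa stress_location
#> 1     31    0.006954    79.8599        interior
#> 2     32    0.005901    92.4463        interior
#> 3     41    0.004680    61.8844        interior
#> 4 pdl_31    0.000390     0.0816        interior
#> 5 pdl_32    0.000200     0.0381        interior
#> 6 pdl_41    0.000292     0.0496        interior

head(safety_check(run$summary), 4)
#>  region          check  observed threshold margin  safe
#>      31       mobility  0.006954      0.03 4.3139  TRUE
#>      31 dentin_tensile 79.859932     44.40 0.5560 FALSE
#>      32       mobility  0.005901      0.03 5.0841  TRUE
#>      32 dentin_tensile 92.446312     44.40 0.4803 FALSE
```

Per-tooth maxima are element-constant von Mises values with no nodal
averaging. The unsafe dentin verdicts are expected here: a full clinical
load on deliberately miniaturised synthetic teeth concentrates stress far
beyond what life-size anatomy would see (see the vignette).

## Command line

A thin CLI over the same functions ships in `inst/cli/splintfea.R`:

```sh
Rscript inst/cli/splintfea.R run --option 1 --out out1 --seed 1
Rscript inst/cli/splintfea.R run --option 3 --out out3 --seed 1
Rscript inst/cli/splintfea.R compare --a out1 --b out3 --out cmp.csv
Rscript inst/cli/splintfea.R report --solution out3
```

`run` writes `summary.csv`, `safety.json`, `solution.vtk` (ParaView), one
binary STL per region, and a `manifest.json` with the config hash, seed,
versions, timings and output inventory.

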