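# cochleafield

Volume-conduction modelling of cochlear-implant current spread, for hearing
researchers and neural-engineering modellers who want to study how the
fine structure of the modiolus shapes auditory-nerve stimulation — without
a μCT segmentation pipeline.

A cochlear implant injects current from contacts inside the scala; whether
a given auditory nerve fiber fires depends not on the potential itself but
on its second spatial derivative along the fiber, through the activating
function

    f = d / (4 ρᵢ c) · ∂²V/∂x²

(d fiber diameter, ρᵢ axoplasmic resistivity, c membrane capacity per unit
length). Potentials change little when the porous modiolar bone is replaced
by a solid nerve, but ∂²V/∂x² — and therefore predicted spike-initiation
sites and polarities — can change a lot. This package builds both model
variants and quantifies exactly that contrast.

## What it does

* **Synthetic cochlea** (`cochlea_params()`, `build_cochlea()`): an
  analytic tapered spiral with a 25.003 mm lamina edge curve, a single
  merged scala duct, an inserted insulating carrier with 12 contact pairs
  (0.18 mm radius, 2.4 mm pitch, 720° insertion, duct translocation at
  270°), a modiolar nerve that is either porous (discrete Rosenthal's-canal
  channels; "detailed") or solid ("simplified"), and concentric
  brain/skull/scalp shells carrying the return current to an extracochlear
  ground.
* **FEM solver** (`mesh_geometry()`, `solve_field()`): labeled tetrahedral
  lattice meshes; quasi-static Laplace solve ∇·(−σ∇V) = 0 with
  current-controlled monopolar stimulation, floating inactive contact
  pairs (equipotential, zero net current), grounded reference; exact
  discrete net-current accounting and an all-against-all voltage-spread
  matrix from a single factorization.
* **Fiber tracer** (`make_seed_pairs()`, `shortest_path()`,
  `refine_fiber()`, `trace_fibers()`): 400 fibers as Dijkstra shortest
  paths over the nerve-compartment mesh edges — every vertex guaranteed
  inside the nerve — with tubular-subvolume refinement and soma annotation
  at 1.5 mm / 20 µm.
* **Activation analysis** (`lowpass_filter()`, `second_derivative()`,
  `activating_function()`, `decay_rate()`, `compare_models()`):
  cable-length-constant filtering (λ ≈ 2.83 mm from 80 myelin layers at
  1 kΩ·cm², ρᵢ = 0.05 kΩ·cm, a = 1 µm), uneven-spacing finite differences,
  dB/mm decay fits along the spiral lamina, and detailed-vs-simplified
  comparison metrics (potential RD, derivative extrema ratios, sign-flip
  segments).
* **Telemetry emulation** (`voltage_spread()`, `simulate_measurements()`,
  `compare_to_measurements()`): 50 µA voltage-spread matrices, synthetic
  16-ear cohorts with lognormal variability and basally-biased missing
  electrodes, CSV/JSON round-tripping.

## Worked example

```r
library(cochleafield)

st <- current_spread_study(active_pair = 3, n_fibers = 400)  # ~4 min

st$mesh$ori
#> <volume_mesh> 70244 nodes, 381446 tets
#>   compartments: bony_labyrinth (107839), cochlear_canal (10497),
#>     auditory_nerve (3060), brain (169228), skull (43474), scalp (47348)
#>   patches: contact_1, ..., contact_12, ground

contact_net_current(st$field$ori, "contact_3")   # 0.001  (the injected 1 mA)
contact_net_current(st$field$ori, "ground")      # -0.001 (returned to ground)

range(sapply(st$fibers, fiber_length))
#> 3.926 6.159        # mm, basal to apical fibers

st$decay_basal
#> <decay_fit> basal: 0.6562 dB/mm (R^2 = 0.955, n = 88, window 0.00-5.45 mm)
st$decay_apical
#> <decay_fit> apical: 0.0476 dB/mm (R^2 = 0.069, n = 281, window 7.46-25.00 mm)

st$comparison
#> <model_comparison> 400 fibers: max |RD(V)| 9.29%, dV' ratio up to 1.18,
#>   dV'' ratio up to 1.44, 226 sign-flip segments
```

Reading the output: the 1 mA stimulus is conserved to solver precision;
fiber potentials decay an order of magnitude faster toward the base than
toward the apex (0.66 vs 0.05 dB/mm on this synthetic, scaled-down
geometry); and while the detailed and simplified variants disagree by at
most ~9 % in potential along any fiber, their second derivatives differ in
peak size by up to ~1.4× and take *opposite signs* on 226 fiber segments —
i.e. where one variant predicts depolarization the other predicts
hyperpolarization. That is the study's central contrast.

A thin command-line front end over the same functions lives in
`inst/cli/cochleafield.R` (`geom`, `solve`, `fibers`, `analyze`,
`telemetry` subcommands; plain-text VTU/VTK/CSV/JSON outputs).

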