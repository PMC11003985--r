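# tactovis

Whisker touch suppresses visually evoked activity in mouse primary
visual cortex (VISp): long-range input from barrel cortex recruits local
fast-spiking (FS) interneurons, whose feedforward inhibition pulls down
pyramidal-neuron (PN) firing, and the whiskers themselves sweep through
the same lower-nasal region of visual space that VISp represents.
`tactovis` re-implements the three computational pillars of that story
as a tested R package with seeded synthetic inputs, for modelers and
analysts who want to probe the circuit model or reuse the spatial
statistics:

1. **Network model** — a two-population (PN/FS) threshold-linear rate
   model with capped cross-modal drive,

   τ_i dA_i/dt = −A_i + G_i [h_i − θ_i]_+ ,  h_P = J_PP A_P − J_PF A_F + I^cm + I^v_P
   (and symmetrically for FS), I^cm ← max(min(I^cm, δ·θ_P), 0),

   with closed-form steady states, suppression amplitudes
   ΔA* = A*(v+w) − A*(v), inhibition-stabilized-network (ISN) regime
   classification, and parameter sweeps.
2. **Whisker geometry** — parametric 3D whisker arrays (24 whiskers,
   rows A–E plus greek column), whisking-plane fitting, retraction /
   protraction / plane-inclination / roll scenarios, left-eye-centered
   spherical coordinates, overlap with the VISp visual-field polygon,
   and tip-position uncertainty spheres.
3. **Spatial statistics** — PCA axes and 200-unit parcellation of
   projected cell clouds, Gaussian KDE density maps (Scott bandwidth),
   the area-normalized barrel enrichment index
   fr_b = (#Cells_b/#Cells_tot)·(#Area_tot/#Area_b) with a one-tailed
   permutation test (2500 shuffles, α = 0.001), and visual-space
   assignment of parcels through a retinotopy.

Every input is produced by seeded generators with recorded ground truth
(`generator_config()`, `gen_*()`), so all statistical routines are
testable against known answers.

## Worked example

```r
library(tactovis)

p <- network_params()          # published basal parameter set
classify_regime(p)
#> regime: ISN with suppression (phi = 3, k = 0.2)
#>   ISN criteria I/II/III: TRUE/TRUE/TRUE; suppression P/F: TRUE/TRUE

steady_state_analytic(p, "v")
#> steady state (v): A_P* = 3.5 Hz, A_F* = 1.65 Hz
steady_state_analytic(p, "v+w")
#> steady state (v+w): A_P* = 1 Hz, A_F* = 1.15 Hz
suppression_analytic(p)
#> dA_P dA_F
#> -2.5 -0.5
```

Visual stimulation alone drives the network to (3.5, 1.65) Hz; adding
the whisker-evoked drive (capped at ρ = δ·θ_P = 0.5) suppresses both
populations to (1.0, 1.15) Hz — a 2.5 Hz drop in PN activity even
though the tactile input is excitatory on both populations. A forward-
Euler simulation (`simulate_network(p)`) reproduces these fixed points
to ~1e-13 Hz.

Geometry and statistics in one breath:

```r
cfg <- generator_config(seed = 1)
arr <- gen_whisker_array(cfg)
map <- gen_visual_space(cfg, dilation = 20)   # 20 deg eye-movement allowance
tips_in_space(pose_array(arr, +40), map)$fraction   # protracted: 1.00
tips_in_space(pose_array(arr, -40), map)$fraction   # retracted:  0.417

bg <- gen_barrel_map(generator_config(seed = 1,
        barrel = list(enrichment = c(`13` = 5), layer_split = c(1, 0))))
pt <- barrel_permutation_test(bg$cells, bg$map, seed = 2)
which(pt$significant[, 1])
#> 13
```

The whisker tips overlap the VISp field far more when protracted than
retracted, and the permutation test flags exactly the barrel that was
constructed with a fivefold cell density.

## Analysis scripts

The `analysis/` directory holds the numbered drivers that reproduce the
full set of analyses on synthetic data, writing tables under `results/`:

```sh
Rscript analysis/01_network_model.R     # basal model, sweeps, regime map
Rscript analysis/02_whisker_overlap.R   # overlap under all whisking scenarios
Rscript analysis/03_spatial_stats.R     # PCA parcellation, KDE, barrel test
```

Each script prints a short narrative of what it found; an optional
integer argument sets the seed (default 1). `run_pipeline()` performs
the same stages programmatically from a YAML/JSON config and writes a
run manifest.

## The methods vignette

`vignettes/tactovis-methods.Rmd` documents the model equations and
assumptions, coordinate conventions, numerical choices (integrator,
boundary rules, bandwidths, tie-breaks), the design decisions taken
where the published description leaves latitude, and what the synthetic
generators do and do not emulate.
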