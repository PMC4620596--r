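# cfba — conditional flux balance analysis for diurnal phototrophic growth

Cyanobacteria live by the sun: carbon is fixed and biomass built while
light lasts, glycogen is stockpiled toward dusk and burned through the
night to keep the cell alive. Classical flux-balance analysis (FBA)
cannot describe this — it assumes a time-invariant metabolism. `cfba`
implements *conditional FBA*: a time-discretized, resource-constrained
linear-programming framework in which every flux is limited by the
amount of the compound that catalyzes it (enzyme, ribosome pool, or
photosynthetic pigments), and those catalysts are themselves products of
the network.

The period `T` (default 24 h, 12 h light / 12 h dark) is split into
`n_t` intervals. Balanced metabolites satisfy `S_B v^k = 0` per
interval; dynamic compounds follow the Euler update
`M^k = M^{k-1} + dt * S_A v^k`; capacity rows couple fluxes to catalyst
amounts at the interval start, `sum_i v_i^k / kcat_ij <= M_j^{k-1}`;
quota and maintenance rows pin minimum composition and basal ATP
demand. Growth is cyclic: `M^{n_t} >= alpha * M^0` with `w' M^0 = B0`,
and the maximal fold change `alpha` is found by bisection over LP
feasibility. Because no LP backend is available as an R package here,
`cfba` ships its own deterministic sparse interior-point solver
(homogeneous self-dual embedding on CHOLMOD factorizations).

The package includes two ready-made models: a three-reaction
illustrative network (`build_toy_model()`) and a minimal diurnal model
of *Synechocystis* sp. PCC 6803 with 52 reactions and 50 compounds
(`build_synechocystis_model()`), plus flux variability analysis,
light-profile scenarios (binary and bell-shaped), kcat robustness scans,
and self-consistency calibration of catalytic efficiencies from
reference flux distributions.

## A worked example

```r
library(cfba)

model <- build_toy_model()
grid  <- make_grid(T_hours = 24, n_t = 48, light_hours = 24)
traj  <- maximize_alpha(model, grid, tol = 1e-8)
traj
#> <cfba_trajectory>: alpha = 2.20744 over 24 h (48 intervals), 2 compounds, 3 reactions

# when does synthesis of the target compound Z start?
(min(which(traj$v[, "v3"] > 1e-8)) - 1) * grid$dt_sec / 3600
#> [1] 14

env <- variability(model, grid, NULL, traj$alpha, intervals = c(1, 12, 40, 48))
max(env$max - env$min, na.rm = TRUE)
#> [1] 1.822646e-06
```

The toy cell more than doubles over the cycle (`alpha = 2.207`): it
first builds only its enzyme Y (exponential growth), then switches the
shared catalytic capacity to the target compound Z at hour 14. The
variability envelope has zero width — this optimum is unique.

The diurnal model runs the same way:

```r
syn   <- build_synechocystis_model()
grid  <- make_grid(24, 48, 12)
light <- binary_light(grid)
traj  <- maximize_alpha(syn, grid, light, tol = 1e-4)   # a few minutes
traj$alpha                      # cyclic growth factor per day
night_activity(traj, syn)       # synthesis reactions active in the dark
composition_timecourse(traj, syn)$biomass   # b^k over the cycle
```

A command-line front end covers the same operations
(`solve`, `fva`, `scan`, `calibrate`, `validate`):

```sh
Rscript inst/scripts/cfba.R solve --model builtin:synechocystis \
        --nt 48 --light binary --out results/
```

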