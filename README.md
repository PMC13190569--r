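# edfm: closed-loop morphology–physiology simulation of maize organ growth

`edfm` is an R package for simulating maize organ growth as a daily closed
loop between physiological function and 3-D morphology. It is aimed at crop
modellers and plant-phenomics researchers who want the two halves that are
usually modelled separately — carbon/stress physiology (WOFOST-style) and
3-D canopy geometry (phenotyping-style) — coupled in one mechanistic loop,
exercisable end-to-end on synthetic data without any field dataset.

## The model in brief

Each simulated day:

1. **Fusion** — modality features (weather window via a from-scratch
   ConvLSTM, point-cloud descriptor, canopy-image descriptor) are combined
   by a gated attention network: `s_i = tanh(w_i·h_i + b_i)`,
   `α = softmax(s)`, `h_fusion = Σ α_i h_i` (logged, with per-stage weight
   trajectories).
2. **Water stress** — `WSF = ((θ − θ_wp)/(θ_fc − θ_wp))^γ · (1 + ψ_root)`,
   a WOFOST-type response extended with a root osmotic adjustment
   coefficient `ψ_root`.
3. **Supply** — `E = ε · I · min(1, Vcmax/Vcmax_ref) · WSF` from the
   previous day's ray-traced light capture `I`.
4. **Allocation** — `Q_organ = R_organ/ΣR · E` by sink strength (potential
   carbon demand).
5. **Phenology** — physiological development time (PDT) accumulates
   `max(0, T − T_base)/pdt_norm`.
6. **Expansion** — each organ follows
   `L(PDT) = Lmax/(1 + e^{−k(PDT − PDTm)})`; realized growth is
   `min(potential, Q·conversion) · WSF`.
7. **Morphology & light** — leaf NURBS surfaces are rescaled, the canopy is
   rebuilt, and vertical-beam ray tracing computes per-leaf capture
   (cross-checked against Beer–Lambert `1 − e^{−k·LAI}`).
8. **Feedback** — per-leaf `Vcmax ← Vcmax_ref · clamp(capture/ref)^β`
   closes the loop for the next day.

The package also implements the surrounding toolchain: synthetic weather /
soil-moisture / point-cloud / trait generators, the preprocessing pipeline
(z-score, SOR filter, voxel downsampling, 224×224 image standardization,
plant-level 6:2:2 splits), one-at-a-time sensitivity analysis with the
normalized sensitivity coefficient, and evaluation utilities (RMSE, R²,
NRMSE, benchmark percent reductions, logistic growth-curve fitting).

## Worked example

```r
library(edfm)

cfg     <- default_config(seed = 7)
weather <- generate_weather(weather_scenario(n_days = 120, seed = 7))
season  <- run_season(cfg, weather)

tail(season$diagnostics[, c("day", "pdt", "wsf", "E", "height_cm", "lai")], 3)
#>     day      pdt       wsf         E height_cm       lai
#> 118 118 131.3619 0.3253328 0.3993780  19.37213 0.4032856
#> 119 119 132.4515 0.3137298 0.3705380  19.37215 0.4032859
#> 120 120 133.5485 0.3026104 0.3142752  19.37216 0.4032861
```

`pdt` is the developmental clock (physiological days), `wsf` the daily
water-stress multiplier (the default scenario is strongly water-limited:
drawdown between 14-day irrigations keeps WSF near 0.3), `E` the daily
assimilate supply (g CH₂O per plant), and `height_cm`/`lai` the simulated
stand traits. Growth has ceased by day ~118 because all organs have passed
their logistic window. Under ample water and carbon the same engine reaches
a ~206 cm, LAI ~4.2 canopy.

Sensitivity of LAI at silking to the three key parameters (±20%,
7 engine runs):

```r
w   <- generate_weather(weather_scenario(n_days = 100, seed = 11))
cfg <- default_config(seed = 11); cfg$season$n_days <- 100L
run_oat(c("psi_root", "k", "t_base"), cfg, w, metric = "lai")
#>   parameter baseline  out_base ...      S_mean
#> 1  psi_root    -0.30 0.4197268 ... -1.75499783
#> 2         k     0.15 0.4197268 ... -0.13937942
#> 3    t_base     8.00 0.4197268 ... -0.03450837
```

The root osmotic adjustment coefficient dominates, the thermal-time base
temperature barely matters — the ordering expected for a water-limited
stand, since PDT-driven development largely cancels out of a metric read
*at* a PDT threshold.

A command-line wrapper over the same functions is in
`inst/cli/edfm.R` (`synth-weather`, `synth-cloud`, `synth-traits`,
`simulate`, `sensitivity`, `evaluate`, `report`).

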