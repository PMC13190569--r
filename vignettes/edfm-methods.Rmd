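---
title: "Methods: the closed-loop morphology-physiology maize simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the closed-loop morphology-physiology maize simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`edfm` simulates the growth of a single maize plant in a uniform stand as a
daily closed loop between *physiological function* and *3-D morphology*.
Functional-structural plant models traditionally keep these two halves
separate — crop models (WOFOST and kin) track carbon and stress with no
geometry, while 3-D phenotyping reconstructs geometry with no physiology.
Here both halves drive each other every 24 hours:

1. **Multimodal fusion (diagnostic).** Feature vectors from three
   modalities — a ConvLSTM encoding of the recent weather window
   (`h_env`), a geometric point-cloud descriptor (`h_point`) and a canopy
   image descriptor (`h_rgb`) — are combined by a gated attention network:
   per-modality scores `s_i = tanh(w_i·h_i + b_i)`, softmax weights
   `alpha_i`, and the convex combination `h_fusion = sum alpha_i h_i`. The
   weights form an interpretable trajectory across growth stages.
2. **Water stress.** The water stress factor is a WOFOST-style soil
   moisture response extended with a root osmotic adjustment coefficient:
   `WSF = ((theta - theta_wp)/(theta_fc - theta_wp))^gamma * (1 + psi_root)`.
3. **Assimilate supply.** `E = lue * I * min(1, Vcmax/Vcmax_ref) * WSF`,
   with `I` the *previous* day's ray-traced light capture. The one-day lag
   is what makes the loop well-defined without same-day fixed-point
   iteration.
4. **Allocation.** Each organ receives `Q = R/sum(R) * E`, where the sink
   strength `R` is the organ's *potential carbon demand*: the derivative of
   its logistic growth curve divided by its carbon-to-size conversion. This
   keeps leaf area (cm^2) and internode length (cm) competing in common
   units of g CH2O per physiological day.
5. **Phenology.** Physiological development time (PDT) accumulates
   `max(0, T_mean - T_base)/pdt_norm` per day; with the defaults
   (`T_base = 8`, `pdt_norm = 17` degC day) one physiological day equals one
   calendar day at 25 degC.
6. **Organ expansion.** Each organ's potential increment is the difference
   of its logistic curve `L(PDT) = Lmax/(1 + exp(-k(PDT - PDTm)))` between
   yesterday's and today's PDT; the realized increment is
   `min(potential, Q * conversion) * WSF`.
7. **Morphology and light.** Leaf NURBS surfaces are rescaled to their new
   areas, stacked on the internode column, and a vertical-beam ray tracer
   computes per-leaf light capture over the plant's footprint (treated as
   periodic, emulating neighbours in a uniform stand).
8. **Capacity feedback.** Each leaf's Vcmax is reset to
   `Vcmax_ref * clamp(capture/reference, 0.2, 1.5)^beta`, where the
   reference exposure is the leaf's unshaded projected capture
   (`PAR * area * k_ext`). Shaded leaves down-regulate; the canopy's
   effective capacity next day is the capture-weighted mean of the per-leaf
   saturation factors.

Steps are executed in this exact order each day; the ordering and the
one-day lag are design choices, documented here because the loop itself
does not dictate a serialization.

## What drives growth, and what is only logged

The mechanistic loop runs entirely on steps 2–8. The fused feature
`h_fusion` and the attention weights of step 1 are computed and logged
(and exported per growth stage) but do not modulate the physiology: no
coupling equation from fused features to growth is defined here, so the
package deliberately keeps fusion as an observation/diagnostic layer with
a plug-in contract (`register_encoder()`) for learned encoders and an
optional readout. Treating the attention layer as load-bearing would have
required inventing a coupling with no basis.

# Parameters

| Group | Parameter | Default | Units | Why |
|---|---|---|---|---|
| phenology | `t_base` | 8 | degC | maize thermal-time base |
| phenology | `pdt_norm` | 17 | degC day | 1 physiological day = 1 day at 25 degC |
| water | `theta_wp`, `theta_fc` | 0.10, 0.32 | m3 m-3 | loam-like soil |
| water | `gamma` | 1 | — | linear moisture response; no crop/stage value is established, exposed in config |
| water | `psi_root` | -0.3 | nominally MPa | root osmotic adjustment; enters as the dimensionless factor `1 + psi_root = 0.7` |
| growth | `k` | 0.15 | per physiological day | leaf expansion rate |
| growth | `pdt_to_inflection` | 12 | physiological days | organ initiation-to-inflection delay |
| physiology | `lue` | 1.5 | g CH2O / mol photons | quantum-yield-scale *potential* efficiency; saturation and stress act through the Vcmax and WSF factors, so a canopy-average value here would double-count them |
| physiology | `vcmax_ref`, `beta` | 60, 0.5 | umol m-2 s-1, — | reference Rubisco capacity and feedback strength |
| physiology | `sla` | 180 | cm2 g-1 | specific leaf area |
| physiology | `internode_cm_per_g` | 2.5 | cm g-1 | ~96 g structural carbon for a 240 cm stalk |
| plant | `density` | 7.5 | plants m-2 | typical stand |
| plant | `n_organs`, `phyllochron` | 14, 3 | —, physiological days | leaf/internode pairs and initiation interval |
| morphology | `n_rays` | 900 | — | Monte-Carlo rays per day |
| morphology | `extinction_k` | 0.7 | — | mean leaf-angle projection factor |

A note on `psi_root`: its printed unit is MPa, but it enters the stress
factor as the dimensionless modifier `(1 + psi_root)`. The package
implements the published dimensionless form (so `psi_root = -0.3` caps WSF at 0.7
even in wet soil) and flags the unit tension rather than resolving it.

# The synthetic-data generators

No field data ship with the package; the `synthdata` generators define the
study conditions:

* **Weather** — a seasonal cosine temperature curve with AR(1) daily noise
  and a half-sine diurnal PAR course; soil moisture from a per-layer bucket
  (temperature-driven ET demand throttled by availability, rain refill with
  cascade, drainage above field capacity, all clipped to
  `[theta_wp, theta_sat]`). The default schedule applies 30 mm every
  14 days, which draws the root zone well below the midpoint of
  plant-available water between applications: the season is genuinely
  water-limited, the regime the root-osmotic water response exists for.
* **Point clouds** — a parametric maize plant: cylindrical internode stack
  and leaves as curved laminae (quadratic midrib arc set by the
  inclination, sine-bump width profile), sampled uniformly in parameter
  space, with Gaussian noise and uniform-box outliers. Ground-truth
  dimensions are returned alongside.
* **Trait trajectories** — the logistic law evaluated on PDT accumulated
  from generated weather, plus seeded Gaussian observation noise; the
  fixture for parameter-recovery experiments.

Every generator derives a child seed from the single global seed plus a
fixed stream label (`child_seed()`), so adding a generator never shifts
existing streams and all outputs are bit-reproducible.

What the generators do *not* emulate: sensor artefacts beyond isotropic
noise and box outliers (no occlusion, no registration error), weather
extremes, pests, nutrient limitation, and any genotype-by-environment
interaction. Passing tests therefore demonstrate the internal coherence of
the pipeline and loop under controlled conditions, not predictive skill on
field data.

# Numerical choices

* **Population standard deviation** in z-score fitting (divide by *n*), so
  the transformed training partition has variance exactly 1; constant
  channels are a named error.
* **Smoothing** is a trailing (not centered) 7-day window, so no future
  information leaks into a day's features; mean or median kernels.
* **Voxel origin** is anchored at the cloud's per-axis minimum: results are
  translation-dependent in a defined, documented way.
* **`downsample_to_count`** bisects the voxel size geometrically (counts
  vary over decades of voxel size) for at most 40 iterations, returning the
  best iterate within 5% of the target.
* **NURBS surfaces** default to degree 3 x 2 with a 6 x 4 control grid;
  knots are clamped uniform. Surface area uses composite Gauss-Legendre
  quadrature *per knot span* (the integrand is only piecewise-smooth across
  knots). Leaf fitting parameterizes points by principal axes with the
  cross-axis normalized by a smoothed (low-order polynomial) outline
  envelope, so tapered laminae fill the whole parameter square and every
  control point is constrained by data.
* **Organ rescaling** exploits that uniform scaling multiplies area by the
  squared factor (`s = sqrt(target/area)`), verified against the computed
  area and refined by 1-D root finding only if the 0.5% tolerance is
  missed. Internodes scale axially and exactly.
* **Ray tracing** uses one vertical ray per jittered-grid cell; the
  periodic canopy replicates triangles into the eight neighbouring tiles.
  Horizontal-leaf canopies agree with `1 - exp(-LAI)` (extinction 1 for
  horizontal leaves under a vertical beam) within Monte-Carlo error; the
  binomial standard error is reported and is conservative for jittered
  sampling. Stems are thin and excluded from interception.
* **Allocation** assigns the floating-point residual to the last organ, so
  daily allocations sum to the supply exactly.
* **Initial state**: 3 leaves and 1 internode at 5% of their asymptotes,
  PDT = 0; the seedling's light capture is computed once at initialization
  so day 1 has a well-defined previous-day input.
* **Sensitivity analysis** perturbs one parameter at a time by +/-20% with
  identical seeds everywhere, reports both one-sided normalized
  sensitivities and their mean, and defines "silking" as the first day PDT
  crosses a configurable threshold (default 70 physiological days) — a
  definition chosen here, since silking has no canonical PDT value.

# Problem sizes

The default test and analysis sizes are chosen as the smallest that
exercise the full loop meaningfully: 120-day seasons at 900 rays/day for
simulation properties, 100-day seasons at 400 rays/day for the
one-at-a-time sensitivity (7 engine runs), 20,000 rays for the
Beer-Lambert cross-check, and 100-seed Monte-Carlo for establishing the
logistic-recovery tolerance (max observed 7.7% relative error on `k`;
the tolerance is frozen at 15%).

# Design decisions taken where the design was open

* Two scoring forms exist for the attention gate; the two-stage
  tanh-then-softmax form is canonical here, and the single-stage
  concatenated linear scoring is kept as an alternate mode with a
  documented block-sparse equivalence between the two.
* Modality descriptors have different lengths; fixed Xavier-initialized
  linear projections map them to a common dimension (default 32) before
  scoring and fusion. Projections are fitted only if the optional readout
  trainer is used.
* Learned backbones (temporal, point-cloud and image networks) are out of
  scope; deterministic hand-crafted descriptors implement the same
  interface and a registry allows substituting trained encoders. The
  claims exercised here concern the fusion mechanism and the feedback
  loop, not backbone weights.
* The point-cloud descriptor's compactness feature is a voxel-occupancy to
  bounding-box volume ratio.
* WSF multiplies both assimilation and organ expansion. This reading of
  "water stress inhibits growth" is the harsher of the plausible couplings
  and is flagged here: it squares the stress penalty on realized growth.
* Smooth-then-normalize is the default preprocessing order.
* A 7-day-ahead forecast is just the engine run on supplied forecast
  weather; no separate algorithm.

# Known limitations

* Absolute canopy sizes under the default water-limited scenario are those
  of a strongly stressed stand (final LAI well below 1 at the default
  settings; about 4 under ample water and carbon). The `(1 + psi_root)`
  ceiling of 0.7 and the squared stress coupling dominate this.
* The attention weights logged in pure simulation mode come from
  Xavier-initialized (untrained) gates over deterministic descriptors;
  their values are structural diagnostics, not the learned weights a
  trained system would produce.
* No nutrient dynamics, no organ temperature budget, no spectral radiative
  transfer, no data assimilation, and no swarm-based calibration.
* The linear thermal-time clock ignores photoperiod and heat-stress
  nonlinearity.
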