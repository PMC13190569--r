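#' Default simulation configuration
#'
#' Nested list of every tunable parameter group of the daily loop. Values
#' are agronomically plausible defaults for a temperate maize stand; see the
#' package vignette for units and rationale.
#'
#' @param seed global seed fanned out to all internal streams.
#' @return Named nested list of class `edfm_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    season = list(n_days = 120L, silking_pdt = 70),
    plant = list(
      density = 7.5,            # plants m-2
      n_organs = 14L,           # leaf/internode pairs
      phyllochron = 3,          # physiological days between initiations
      leaf_area_max = 600,      # cm2, largest leaf
      total_height_max = 240,   # cm, sum of internode asymptotes
      leaf_inclination = 45,    # degrees
      leaf_len_wid_ratio = 9,   # midrib length / max width
      init_frac = 0.05,         # starting size of the seedling organs
      n_init_leaves = 3L
    ),
    phenology = list(t_base = 8, t_ref = 25),
    water = list(theta_wp = 0.10, theta_fc = 0.32, gamma = 1,
                 psi_root = -0.3),
    physiology = list(
      lue = 1.5,                # g CH2O per mol photons (quantum-yield-scale
                                # potential; saturation and stress enter via
                                # the Vcmax and WSF factors)
      vcmax_ref = 60,           # umol m-2 s-1
      beta = 0.5,               # Vcmax feedback exponent
      sla = 180,                # specific leaf area, cm2 per g CH2O
      internode_cm_per_g = 2.5  # internode elongation per g CH2O
    ),
    growth = list(k = 0.15, pdt_to_inflection = 12),
    morphology = list(grid_u = 6L, grid_v = 4L, tri_u = 5L, tri_v = 4L,
                      n_rays = 900L, extinction_k = 0.7,
                      min_leaf_area_cm2 = 1),
    fusion = list(dim = 32L, scoring_mode = "per_modality"),
    encoders = list(hidden = 64L, kernel_size = 3L, window = 7L)
  ), class = c("edfm_config", "list"))
}

#' Validate a simulation configuration
#'
#' Checks the presence, type and range of every parameter group before a
#' run; errors name the offending key.
#'
#' @param config nested list as produced by [default_config()].
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  need <- c("seed", "season", "plant", "phenology", "water", "physiology",
            "growth", "morphology", "fusion", "encoders")
  miss <- setdiff(need, names(config))
  if (length(miss))
    edfm_stop("edfm_invalid_argument",
              "config missing group(s): %s", paste(miss, collapse = ", "))
  chk <- function(ok, key) if (!isTRUE(ok))
    edfm_stop("edfm_invalid_argument", "invalid config value: %s", key)
  chk(config$season$n_days >= 0, "season.n_days")
  chk(config$plant$density > 0, "plant.density")
  chk(config$plant$n_organs >= 1, "plant.n_organs")
  chk(config$plant$phyllochron > 0, "plant.phyllochron")
  chk(config$phenology$t_ref > config$phenology$t_base, "phenology.t_ref")
  chk(config$water$theta_wp > 0 && config$water$theta_wp < config$water$theta_fc,
      "water.theta_wp/theta_fc")
  chk(config$water$gamma > 0, "water.gamma")
  chk(1 + config$water$psi_root > 0, "water.psi_root")
  chk(config$physiology$lue >= 0, "physiology.lue")
  chk(config$physiology$vcmax_ref > 0, "physiology.vcmax_ref")
  chk(config$growth$k > 0, "growth.k")
  chk(config$growth$pdt_to_inflection > 0, "growth.pdt_to_inflection")
  chk(config$morphology$n_rays >= 100, "morphology.n_rays")
  chk(config$fusion$scoring_mode %in% c("per_modality", "concatenated"),
      "fusion.scoring_mode")
  chk(config$encoders$window >= 1, "encoders.window")
  invisible(config)
}

#' Read a configuration from YAML, merged over the defaults
#'
#' Keys present in the file override the defaults; everything else keeps its
#' default value. The merged config is validated.
#'
#' @param path YAML file path.
#' @return Validated `edfm_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modify_list_deep(default_config(), user)
  class(cfg) <- c("edfm_config", "list")
  validate_config(cfg)
  cfg
}

# recursive list merge (user values win)
modify_list_deep <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}
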