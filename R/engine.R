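# organ size profiles along the stem: leaves bell-shaped (largest
# mid-canopy), internodes longer toward the top
organ_profiles <- function(config) {
  n <- config$plant$n_organs
  i <- seq_len(n)
  leaf_rel <- exp(-((i - 0.63 * n) / (0.45 * n))^2)
  leaf_lmax <- config$plant$leaf_area_max * (0.25 + 0.75 * leaf_rel)
  int_w <- 0.3 + 0.7 * i / n
  int_lmax <- config$plant$total_height_max * int_w / sum(int_w)
  list(leaf_area_cm2 = leaf_lmax, internode_cm = int_lmax)
}

# nominal leaf length (m) for a target lamina area (cm2): the sine-bump
# lamina has area ~ (2/pi) * length * width
leaf_template_dims <- function(area_cm2, ratio) {
  len_cm <- sqrt(area_cm2 * ratio / (2 / pi))
  c(len_m = len_cm / 100, wid_m = len_cm / ratio / 100)
}

# rotate control points of a surface about the z axis
rotate_surface_z <- function(surface, azimuth) {
  R <- cbind(c(cos(azimuth), sin(azimuth), 0),
             c(-sin(azimuth), cos(azimuth), 0), c(0, 0, 1))
  ctrl <- surface$control
  d <- dim(ctrl)
  flat <- matrix(ctrl, ncol = 3) %*% t(R)
  nurbs_surface(array(flat, d), surface$weights,
                surface$degree_u, surface$degree_v)
}

#' Initial plant state (seedling)
#'
#' All leaf/internode pairs are instantiated with their growth curves
#' (initiation staggered by the phyllochron); the first `n_init_leaves`
#' leaves and the first internode start at `init_frac` of their asymptote,
#' everything else at zero. The seedling's light capture is computed once so
#' the first day's assimilation has a well-defined previous-day input.
#'
#' @param config an `edfm_config` (see [default_config()]).
#' @param par_above PAR used for the bootstrap interception, mol m-2 d-1.
#' @return Object of class `plant_state`.
#' @export
initial_state <- function(config = default_config(), par_above = 40) {
  validate_config(config)
  prof <- organ_profiles(config)
  n <- config$plant$n_organs
  organs <- list()
  for (i in seq_len(n)) {
    init_pdt <- (i - 1) * config$plant$phyllochron
    pdtm <- init_pdt + config$growth$pdt_to_inflection
    azim <- (i %% 2) * pi + 0.3 * sin(i * 2.4)
    dims <- leaf_template_dims(prof$leaf_area_cm2[i],
                               config$plant$leaf_len_wid_ratio)
    template <- rotate_surface_z(
      make_leaf_surface(dims["len_m"], dims["wid_m"],
                        config$plant$leaf_inclination,
                        c(config$morphology$grid_u, config$morphology$grid_v)),
      azim)
    leaf0 <- if (i <= config$plant$n_init_leaves)
      config$plant$init_frac * prof$leaf_area_cm2[i] else 0
    int0 <- if (i == 1) config$plant$init_frac * prof$internode_cm[i] else 0
    organs[[length(organs) + 1]] <- list(
      id = sprintf("leaf_%02d", i), type = "leaf", idx = i,
      gp = growth_params(prof$leaf_area_cm2[i], config$growth$k, pdtm),
      init_pdt = init_pdt, L = leaf0, template = template,
      vcmax = config$physiology$vcmax_ref)
    organs[[length(organs) + 1]] <- list(
      id = sprintf("internode_%02d", i), type = "internode", idx = i,
      gp = growth_params(prof$internode_cm[i], config$growth$k, pdtm),
      init_pdt = init_pdt, L = int0, template = NULL,
      vcmax = config$physiology$vcmax_ref)
  }
  state <- structure(list(
    pdt = 0, day = 0L, organs = organs,
    height_cm = sum(vapply(organs, function(o)
      if (o$type == "internode") o$L else 0, numeric(1))),
    lai = 0, intercepted_mol = 0, capture_fraction = 0,
    ledger = data.frame(day = integer(), E = numeric(), sumQ = numeric())
  ), class = "plant_state")
  state$lai <- plant_lai(state, config)
  sc <- build_scene(state, config)
  li <- light_interception(sc, par_above, config$morphology$n_rays,
                           seed = child_seed(config$seed, "day0"))
  state$intercepted_mol <- li$total
  state$per_organ_mol <- li$per_organ
  state$capture_fraction <- li$fraction
  state
}

plant_lai <- function(state, config) {
  leaf_area <- sum(vapply(state$organs, function(o)
    if (o$type == "leaf") o$L else 0, numeric(1)))
  leaf_area * config$plant$density / 1e4
}

#' Build the canopy scene from the current plant state
#'
#' Each visible leaf's template surface is rescaled to its current area and
#' translated to its attachment height (top of its internode); internodes
#' are thin and excluded from light capture. The footprint is one plant's
#' share of ground at the configured density, treated as periodic.
#'
#' @param state a `plant_state`.
#' @param config an `edfm_config`.
#' @return A [canopy_scene()].
#' @export
build_scene <- function(state, config) {
  ints <- Filter(function(o) o$type == "internode", state$organs)
  tops <- cumsum(vapply(ints, function(o) o$L, numeric(1))) / 100  # m
  meshes <- list()
  for (o in state$organs) {
    if (o$type != "leaf" || o$L < config$morphology$min_leaf_area_cm2) next
    surf <- scale_organ_to_size(o$template, "leaf", o$L / 1e4)
    surf$control[, , 3] <- surf$control[, , 3] + tops[min(o$idx, length(tops))]
    meshes[[o$id]] <- triangulate_surface(surf, config$morphology$tri_u,
                                          config$morphology$tri_v)
  }
  canopy_scene(meshes, footprint_area = 1 / config$plant$density, wrap = TRUE)
}

# orthographic top-down raster of the scene (plant pixels green), for the
# self-contained image-feature path of pure simulation mode
render_topdown <- function(scene, size = 224) {
  img <- array(0, c(size, size, 3))
  img[, , 1] <- 0.35; img[, , 2] <- 0.25; img[, , 3] <- 0.15  # soil
  side <- sqrt(scene$footprint_area)
  st <- scene_triangles(scene)
  if (nrow(st$tri) > 0) {
    # splat triangle vertices and edge midpoints
    pts <- rbind(st$tri[, 1:2, drop = FALSE], st$tri[, 4:5, drop = FALSE],
                 st$tri[, 7:8, drop = FALSE],
                 (st$tri[, 1:2, drop = FALSE] + st$tri[, 4:5, drop = FALSE]) / 2,
                 (st$tri[, 4:5, drop = FALSE] + st$tri[, 7:8, drop = FALSE]) / 2,
                 (st$tri[, 1:2, drop = FALSE] + st$tri[, 7:8, drop = FALSE]) / 2)
    ij <- floor((pts / side + 0.5) * size) + 1
    ij <- ij[ij[, 1] >= 2 & ij[, 1] <= size - 1 &
               ij[, 2] >= 2 & ij[, 2] <= size - 1, , drop = FALSE]
    for (r in seq_len(nrow(ij))) {
      ii <- (ij[r, 1] - 1):(ij[r, 1] + 1)
      jj <- (ij[r, 2] - 1):(ij[r, 2] + 1)
      img[ii, jj, 1] <- 0.15; img[ii, jj, 2] <- 0.55; img[ii, jj, 3] <- 0.1
    }
  }
  img
}

# feature bundle computed from the simulator's own synthetic scene
self_bundle <- function(state, scene, env_window, conv_params) {
  st <- scene_triangles(scene)
  verts <- unique(rbind(st$tri[, 1:3, drop = FALSE],
                        st$tri[, 4:6, drop = FALSE],
                        st$tri[, 7:9, drop = FALSE]))
  h_point <- if (nrow(verts) >= 8) encode_point_cloud(verts) else
    stats::setNames(numeric(22),
                    c(paste0("z_q", c(5, 25, 50, 75, 95)),
                      paste0("ext_", c("x", "y", "z")),
                      c("linearity", "planarity", "sphericity"),
                      paste0("zhist_", 1:10), "occupancy"))
  h_rgb <- encode_image(render_topdown(scene))
  h_env <- encode_environment(env_window, conv_params,
                              width = nrow(env_window))
  list(env = h_env, point = h_point, rgb = h_rgb)
}

#' Advance the plant one day through the closed loop
#'
#' The fixed daily ordering is: (1) gated-attention fusion of the modality
#' bundle (logged); (2) water stress factor from root-zone soil moisture;
#' (3) assimilate supply from the \emph{previous} day's light capture and
#' Vcmax (the one-day lag is what makes the loop well-defined);
#' (4) sink-strength allocation; (5) thermal-time advance of PDT;
#' (6) per-organ potential logistic increment, realized as
#' `min(potential, allocation * conversion) * WSF`; (7) rescale organ
#' surfaces, rebuild the canopy and ray-trace light capture; (8) update each
#' leaf's Vcmax from its capture ratio for the next day.
#'
#' @param state a `plant_state`.
#' @param env one-row `edfm_weather` slice (day's driving data).
#' @param bundle named list of modality descriptors for the fusion stage,
#'   or `NULL` to skip fusion logging.
#' @param config an `edfm_config`.
#' @param gate a [gate_params()] (required when `bundle` is given).
#' @return List with the new `state` and a one-row `diagnostics`
#'   data.frame.
#' @export
step_day <- function(state, env, bundle = NULL, config = default_config(),
                     gate = NULL) {
  day <- state$day + 1L
  res <- tryCatch({
    # (1) fusion
    alpha <- c(env = NA_real_, point = NA_real_, rgb = NA_real_)
    if (!is.null(bundle)) {
      fused <- fuse(bundle, gate)
      alpha[names(fused$weights)] <- fused$weights
    }
    # (2) water stress
    wp <- water_params(config$water$theta_wp, config$water$theta_fc,
                       config$water$gamma, config$water$psi_root)
    theta <- root_zone_theta(env)
    wsf <- water_stress_factor(theta, wp)
    # (3) supply from yesterday's capture and Vcmax. The canopy's effective
    # capacity is the capture-weighted mean of the per-leaf saturation
    # factors min(1, Vcmax_i / Vcmax_ref): sunlit leaves dominate supply.
    vref <- config$physiology$vcmax_ref
    caps <- state$per_organ_mol
    mean_vcmax <- if (length(caps) && sum(caps) > 0) {
      vc <- vapply(state$organs, function(o) o$vcmax, numeric(1))
      names(vc) <- vapply(state$organs, function(o) o$id, character(1))
      fac <- pmin(1, vc[names(caps)] / vref)
      vref * sum(caps * fac) / sum(caps)
    } else vref
    E <- daily_assimilation(state$intercepted_mol, mean_vcmax, wsf,
                            config$physiology$lue,
                            config$physiology$vcmax_ref)
    # (4) allocation by sink strength: potential carbon demand (potential
    # growth rate divided by the carbon->size conversion), so leaf area and
    # internode length compete in common units of g CH2O per physiological day
    R <- vapply(state$organs, function(o) {
      if (state$pdt < o$init_pdt) return(0)
      conv <- if (o$type == "leaf") config$physiology$sla
              else config$physiology$internode_cm_per_g
      logistic_rate(state$pdt, o$gp) / conv
    }, numeric(1))
    Q <- if (sum(R) > 0) allocate(E, R) else rep(0, length(R))
    # (5) phenology
    ph <- phenology_params(config$phenology$t_base, config$phenology$t_ref)
    pdt_new <- state$pdt + pdt_increment(env$t_mean, ph)
    # (6) organ expansion: carbon- and water-limited logistic increments
    for (j in seq_along(state$organs)) {
      o <- state$organs[[j]]
      if (pdt_new < o$init_pdt) next
      d_pot <- logistic_size(pdt_new, o$gp) -
        logistic_size(max(state$pdt, o$init_pdt), o$gp)
      conv <- if (o$type == "leaf") config$physiology$sla
              else config$physiology$internode_cm_per_g
      state$organs[[j]]$L <- o$L + min(d_pot, Q[j] * conv) * wsf
    }
    # (7) morphology update and light capture
    scene <- build_scene(state, config)
    li <- light_interception(scene, env$par_mol, config$morphology$n_rays,
                             seed = child_seed(config$seed,
                                               paste0("day", day)))
    # (8) Vcmax feedback from per-leaf capture ratio
    for (j in seq_along(state$organs)) {
      o <- state$organs[[j]]
      if (o$type != "leaf" || !(o$id %in% names(li$per_organ))) next
      area_m2 <- o$L / 1e4
      if (area_m2 <= 0 || env$par_mol <= 0) next
      # reference exposure: the leaf's unshaded projected capture, using the
      # extinction coefficient as the mean projection factor of leaf angle
      ref <- env$par_mol * area_m2 * config$morphology$extinction_k
      ratio <- li$per_organ[[o$id]] / ref
      state$organs[[j]]$vcmax <- update_vcmax(ratio,
                                              config$physiology$vcmax_ref,
                                              config$physiology$beta)
    }
    state$pdt <- pdt_new
    state$day <- day
    state$height_cm <- sum(vapply(state$organs, function(o)
      if (o$type == "internode") o$L else 0, numeric(1)))
    state$lai <- plant_lai(state, config)
    state$intercepted_mol <- li$total
    state$per_organ_mol <- li$per_organ
    state$capture_fraction <- li$fraction
    state$ledger <- rbind(state$ledger,
                          data.frame(day = day, E = E, sumQ = sum(Q)))
    diag <- data.frame(
      day = day, pdt = pdt_new, t_mean = env$t_mean, theta = theta,
      wsf = wsf, E = E, sumQ = sum(Q), height_cm = state$height_cm,
      lai = state$lai, intercepted_mol = li$total,
      capture_fraction = li$fraction,
      alpha_env = alpha[["env"]], alpha_point = alpha[["point"]],
      alpha_rgb = alpha[["rgb"]])
    list(state = state, diagnostics = diag)
  }, edfm_error = function(e) {
    edfm_stop("edfm_step_error", "day %d: %s", day, conditionMessage(e))
  })
  res
}

#' Run a full season of the daily loop
#'
#' Folds [step_day()] over the weather record from a seedling state. In
#' pure simulation mode (no `observations`) the fusion stage runs on
#' encoder outputs computed from the simulator's own synthetic scene, so
#' the loop is closed and self-contained. Fused features and attention
#' weights are logged; the mechanistic growth loop itself is driven by the
#' physiology/morphology equations.
#'
#' @param config an `edfm_config`.
#' @param weather an `edfm_weather` record (must be gap-free: consecutive
#'   `day` values).
#' @param observations optional list (one per day) of externally supplied
#'   modality bundles; `NULL` selects pure simulation mode.
#' @param fuse_every compute the (diagnostic) fusion features every this
#'   many days (default 7; fusion is logged, not load-bearing for growth).
#' @param out_dir optional directory for `traits.csv`, `weights.csv` and
#'   `diagnostics.csv`.
#' @return List of class `season_result`: `final_state`, `traits`
#'   (day/height/LAI/per-leaf areas), `diagnostics`, `weights`, `config`.
#' @export
run_season <- function(config = default_config(), weather,
                       observations = NULL, fuse_every = 7L,
                       out_dir = NULL) {
  validate_config(config)
  if (nrow(weather) == 0) {
    state <- initial_state(config)
    return(structure(list(final_state = state, traits = NULL,
                          diagnostics = NULL, weights = NULL,
                          config = config), class = "season_result"))
  }
  if (any(diff(weather$day) != 1))
    edfm_stop("edfm_invalid_argument",
              "weather record has gaps (non-consecutive days)")
  n_days <- min(config$season$n_days, nrow(weather))

  conv_params <- convlstm_params(1, config$encoders$hidden,
                                 config$encoders$kernel_size,
                                 seed = config$seed)
  # normalization stats for the environmental channels over this run's record
  env_mat <- as.matrix(weather[, c("t_mean", "t_min", "t_max", "par_mol")])
  env_mat <- cbind(env_mat, theta = root_zone_theta(weather))
  # tolerant scaling: constant channels (possible in controlled synthetic
  # scenarios) are centred but not scaled
  mu <- colMeans(env_mat)
  sg <- sqrt(colMeans(sweep(env_mat, 2, mu)^2))
  sg[sg <= 0] <- 1
  env_z <- sweep(sweep(env_mat, 2, mu), 2, sg, "/")
  gate <- NULL
  state <- initial_state(config, par_above = weather$par_mol[1])
  diags <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    bundle <- NULL
    if (!is.null(observations)) {
      bundle <- observations[[d]]
    } else if (d %% fuse_every == 0 || d == 1) {
      win <- env_z[max(1, d - config$encoders$window + 1):d, , drop = FALSE]
      scene <- build_scene(state, config)
      bundle <- self_bundle(state, scene, win, conv_params)
    }
    if (!is.null(bundle) && is.null(gate)) {
      gate <- gate_params(vapply(bundle, length, integer(1)),
                          D = config$fusion$dim,
                          scoring_mode = config$fusion$scoring_mode,
                          seed = config$seed)
    }
    out <- step_day(state, weather[d, , drop = FALSE], bundle, config, gate)
    state <- out$state
    diags[[d]] <- out$diagnostics
  }
  diagnostics <- do.call(rbind, diags)
  leaf_areas <- t(vapply(
    Filter(function(o) o$type == "leaf", state$organs),
    function(o) c(o$idx, o$L), numeric(2)))
  traits <- diagnostics[, c("day", "pdt", "height_cm", "lai")]
  weights <- diagnostics[!is.na(diagnostics$alpha_env),
                         c("day", "alpha_env", "alpha_point", "alpha_rgb")]
  res <- structure(list(final_state = state, traits = traits,
                        diagnostics = diagnostics, weights = weights,
                        final_leaf_areas = stats::setNames(
                          leaf_areas[, 2], paste0("leaf_", leaf_areas[, 1])),
                        config = config), class = "season_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                     row.names = FALSE)
    utils::write.csv(weights, file.path(out_dir, "weights.csv"),
                     row.names = FALSE)
    utils::write.csv(diagnostics, file.path(out_dir, "diagnostics.csv"),
                     row.names = FALSE)
  }
  res
}

#' Metric value at the silking stage
#'
#' Silking is operationalized as the first day PDT crosses the configured
#' threshold; if the season ends earlier the last day is used with a
#' warning.
#'
#' @param result a `season_result`.
#' @param metric `"lai"` or `"height_cm"`.
#' @param silking_pdt threshold in physiological days (default from the
#'   run's config).
#' @return Scalar metric value.
#' @export
metric_at_silking <- function(result, metric = c("lai", "height_cm"),
                              silking_pdt = result$config$season$silking_pdt) {
  metric <- match.arg(metric)
  d <- result$diagnostics
  idx <- which(d$pdt >= silking_pdt)[1]
  if (is.na(idx)) {
    warning("season ended before silking threshold; using final day")
    idx <- nrow(d)
  }
  d[[metric]][idx]
}
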