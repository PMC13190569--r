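#' Weather scenario description
#'
#' Defines a synthetic growing-season weather record: a seasonal mean
#' temperature curve, diurnal range, day-to-day autocorrelated temperature
#' noise, photosynthetically active radiation (PAR), rain/irrigation events
#' and a layered soil-moisture bucket.
#'
#' @param n_days number of days (>= 1).
#' @param t_base_seasonal seasonal mean temperature at the curve base, degC.
#' @param t_amp_seasonal amplitude of the seasonal cosine, degC (0 = flat).
#' @param t_peak_day day of the seasonal maximum.
#' @param diurnal_amplitude daily max-min temperature range, degC.
#' @param t_noise_sd standard deviation of AR(1) day-to-day temperature
#'   noise, degC (0 disables it).
#' @param par_max midday PAR at the seasonal peak, umol m-2 s-1.
#' @param rain_events data.frame with columns `day`, `depth_mm`; rain or
#'   irrigation water applied on those days.
#' @param soil list of bucket-model constants: `theta_wp`, `theta_fc`,
#'   `theta_sat` (m3 m-3), `layer_depth_mm`, `root_frac` (per layer, sums
#'   to 1), `theta_init`, `et_coef` (mm per degC above `et_t_base`),
#'   `et_t_base` (degC).
#' @param seed integer seed; the series is bit-reproducible for a fixed seed.
#' @return An object of class `weather_scenario`.
#' @export
weather_scenario <- function(n_days = 120,
                             t_base_seasonal = 22,
                             t_amp_seasonal = 6,
                             t_peak_day = 70,
                             diurnal_amplitude = 10,
                             t_noise_sd = 1.2,
                             par_max = 1800,
                             rain_events = default_rain_events(n_days),
                             soil = default_soil(),
                             seed = 1L) {
  if (!is.numeric(n_days) || n_days < 1)
    edfm_stop("edfm_invalid_argument", "n_days must be >= 1, got %s", n_days)
  if (par_max <= 0)
    edfm_stop("edfm_invalid_argument", "par_max must be positive")
  stopifnot(soil$theta_wp > 0, soil$theta_wp < soil$theta_fc,
            soil$theta_fc <= soil$theta_sat,
            abs(sum(soil$root_frac) - 1) < 1e-9)
  structure(list(
    n_days = as.integer(n_days), t_base_seasonal = t_base_seasonal,
    t_amp_seasonal = t_amp_seasonal, t_peak_day = t_peak_day,
    diurnal_amplitude = diurnal_amplitude, t_noise_sd = t_noise_sd,
    par_max = par_max, rain_events = rain_events, soil = soil,
    seed = as.integer(seed)
  ), class = "weather_scenario")
}

#' @rdname weather_scenario
#' @export
default_soil <- function() {
  list(theta_wp = 0.10, theta_fc = 0.32, theta_sat = 0.45,
       layer_depth_mm = c(200, 300, 500),
       root_frac = c(0.5, 0.3, 0.2),
       theta_init = 0.32,
       et_coef = 0.22, et_t_base = 5)
}

#' Default rain/irrigation schedule: one 30 mm application every 14 days
#'
#' The drawdown between applications takes the root zone well below the
#' midpoint of plant-available water, so the default season is genuinely
#' water-limited — the regime the water-stress factor is designed for.
#'
#' @param n_days season length.
#' @return data.frame with columns `day`, `depth_mm`.
#' @export
default_rain_events <- function(n_days) {
  d <- seq(1L, as.integer(n_days), by = 14L)
  data.frame(day = d, depth_mm = rep(30, length(d)))
}

#' Generate a synthetic daily weather and soil-moisture record
#'
#' Temperature is a seasonal cosine plus AR(1) noise; daily PAR is the
#' integral of a half-sine diurnal course scaled by a stochastic cloudiness
#' factor; soil moisture follows a per-layer bucket: evapotranspiration
#' drawdown (temperature-driven demand, reduced linearly with relative
#' available water), refill by rain events with excess cascading to deeper
#' layers, all values clipped to `[theta_wp, theta_sat]`.
#'
#' @param scenario a [weather_scenario()].
#' @return A data.frame of class `edfm_weather`, one row per day, with
#'   columns `day`, `t_mean`, `t_min`, `t_max` (degC), `par_mol` (mol m-2
#'   d-1) and `theta_1 ... theta_L` (m3 m-3 per soil layer).
#' @export
generate_weather <- function(scenario) {
  stopifnot(inherits(scenario, "weather_scenario"))
  n <- scenario$n_days
  with_seed(child_seed(scenario$seed, "weather"), {
    day <- seq_len(n)
    t_seas <- scenario$t_base_seasonal +
      scenario$t_amp_seasonal * cos(2 * pi * (day - scenario$t_peak_day) / 365)
    noise <- numeric(n)
    if (scenario$t_noise_sd > 0) {
      rho <- 0.6
      eps <- stats::rnorm(n, 0, scenario$t_noise_sd * sqrt(1 - rho^2))
      noise[1] <- stats::rnorm(1, 0, scenario$t_noise_sd)
      for (i in seq_len(n)[-1]) noise[i] <- rho * noise[i - 1] + eps[i]
    }
    t_mean <- t_seas + noise
    t_min <- t_mean - scenario$diurnal_amplitude / 2
    t_max <- t_mean + scenario$diurnal_amplitude / 2

    # half-sine diurnal PAR over a 12 h photoperiod: integral = peak * 2/pi * T
    daylength_s <- 12 * 3600
    cloud <- if (scenario$t_noise_sd > 0) 1 - 0.6 * stats::runif(n)^2 else rep(1, n)
    par_peak <- scenario$par_max *
      (0.85 + 0.15 * cos(2 * pi * (day - scenario$t_peak_day) / 365))
    par_mol <- par_peak * (2 / pi) * daylength_s / 1e6 * cloud

    soil <- scenario$soil
    nl <- length(soil$layer_depth_mm)
    theta <- matrix(NA_real_, n, nl)
    th <- rep(soil$theta_init, nl)
    rain <- numeric(n)
    if (!is.null(scenario$rain_events) && nrow(scenario$rain_events) > 0) {
      ev <- scenario$rain_events
      ok <- ev$day >= 1 & ev$day <= n
      rain[ev$day[ok]] <- rain[ev$day[ok]] + ev$depth_mm[ok]
    }
    for (i in seq_len(n)) {
      # infiltrate rain top-down; excess above saturation cascades
      if (rain[i] > 0) {
        w <- rain[i]
        for (l in seq_len(nl)) {
          cap <- (soil$theta_sat - th[l]) * soil$layer_depth_mm[l]
          add <- min(w, cap)
          th[l] <- th[l] + add / soil$layer_depth_mm[l]
          w <- w - add
          if (w <= 0) break
        }
      }
      # drainage of water held above field capacity moves to the next layer
      for (l in seq_len(nl)) {
        excess <- max(0, th[l] - soil$theta_fc) * 0.5  # half drains per day
        th[l] <- th[l] - excess
        if (l < nl) {
          th[l + 1] <- min(soil$theta_sat,
                           th[l + 1] + excess * soil$layer_depth_mm[l] /
                             soil$layer_depth_mm[l + 1])
        }
      }
      # ET demand split by root fraction, throttled by available water
      demand <- soil$et_coef * max(0, t_mean[i] - soil$et_t_base)
      for (l in seq_len(nl)) {
        avail <- (th[l] - soil$theta_wp) / (soil$theta_fc - soil$theta_wp)
        take <- demand * soil$root_frac[l] * min(1, max(0, avail))
        th[l] <- th[l] - take / soil$layer_depth_mm[l]
      }
      th <- pmin(soil$theta_sat, pmax(soil$theta_wp, th))
      theta[i, ] <- th
    }

    out <- data.frame(day = day, t_mean = t_mean, t_min = t_min,
                      t_max = t_max, par_mol = par_mol)
    colnames(theta) <- paste0("theta_", seq_len(nl))
    out <- cbind(out, as.data.frame(theta))
    class(out) <- c("edfm_weather", "data.frame")
    out
  })
}

#' Root-zone soil moisture of a weather record
#'
#' Root-fraction-weighted mean of the per-layer volumetric water contents.
#'
#' @param weather an `edfm_weather` data.frame.
#' @param root_frac per-layer weights (defaults to equal weights).
#' @return Numeric vector, one value per day (m3 m-3).
#' @export
root_zone_theta <- function(weather, root_frac = NULL) {
  cols <- grep("^theta_", names(weather), value = TRUE)
  th <- as.matrix(weather[cols])
  if (is.null(root_frac)) root_frac <- rep(1 / length(cols), length(cols))
  stopifnot(length(root_frac) == length(cols))
  as.numeric(th %*% (root_frac / sum(root_frac)))
}

#' Synthetic maize plant specification
#'
#' Parametric plant used by the point-cloud generator: leaves are curved
#' laminae (quadratic midrib arc in a vertical plane set by the inclination,
#' sine-bump width profile) attached to a stack of cylindrical internodes.
#'
#' @param n_leaves leaf count (>= 0).
#' @param leaf_length_max longest leaf midrib length, cm.
#' @param leaf_width_max widest leaf width, cm.
#' @param internode_lengths internode lengths bottom-up, cm.
#' @param leaf_inclination midrib elevation angle at the base, degrees above
#'   horizontal.
#' @param points_per_leaf points sampled per leaf (>= 10).
#' @param noise_sd isotropic Gaussian point noise, cm.
#' @param outlier_fraction fraction of additional uniform-box outliers,
#'   in [0, 0.5).
#' @param seed integer seed.
#' @return Object of class `synthetic_plant_spec`.
#' @export
synthetic_plant_spec <- function(n_leaves = 10,
                                 leaf_length_max = 80,
                                 leaf_width_max = 9,
                                 internode_lengths = rep(15, 10),
                                 leaf_inclination = 45,
                                 points_per_leaf = 400,
                                 noise_sd = 0.2,
                                 outlier_fraction = 0.02,
                                 seed = 1L) {
  if (points_per_leaf < 10)
    edfm_stop("edfm_invalid_argument", "points_per_leaf must be >= 10")
  if (outlier_fraction < 0 || outlier_fraction >= 0.5)
    edfm_stop("edfm_invalid_argument",
              "outlier_fraction must be in [0, 0.5), got %s", outlier_fraction)
  stopifnot(n_leaves >= 0, leaf_length_max > 0, leaf_width_max > 0)
  structure(list(
    n_leaves = as.integer(n_leaves), leaf_length_max = leaf_length_max,
    leaf_width_max = leaf_width_max,
    internode_lengths = as.numeric(internode_lengths),
    leaf_inclination = leaf_inclination,
    points_per_leaf = as.integer(points_per_leaf),
    noise_sd = noise_sd, outlier_fraction = outlier_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_plant_spec")
}

# Parametric leaf lamina in local coordinates (metres).
# s in [0,1] along the midrib, w01 in [0,1] across it. The midrib is a
# quadratic arc in the x-z plane: elevation `incl` at the base, drooping so
# the tip returns toward horizontal; width profile is a sine bump.
lamina_local <- function(s, w01, length_m, width_m, incl_deg, droop = 0.8) {
  a <- incl_deg * pi / 180
  x <- length_m * s * cos(a)
  z <- length_m * (s * sin(a) - droop * sin(a) * s^2 / 2)
  halfw <- width_m * sin(pi * s) / 2
  y <- (w01 * 2 - 1) * halfw
  cbind(x, y, z)
}

# numeric arc length of the lamina midrib (metres)
lamina_arc_length <- function(length_m, incl_deg, droop = 0.8, n = 400) {
  s <- seq(0, 1, length.out = n + 1)
  p <- lamina_local(s, rep(0.5, n + 1), length_m, 0, incl_deg, droop)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Generate a synthetic plant point cloud with ground truth
#'
#' Samples points uniformly in parameter space on each lamina and internode
#' cylinder, adds Gaussian coordinate noise and a fraction of uniform-box
#' outliers. Coordinates are metres, z up, stem base at the origin.
#'
#' @param spec a [synthetic_plant_spec()].
#' @return List with `points` (N x 3 matrix, metres), `labels` (integer: 0 =
#'   outlier, 1..n stem internodes, 100+i leaf i) and `truth`, a list of the
#'   analytic dimensions (per-leaf midrib arc length and maximum width in cm,
#'   attachment heights, stem height in cm, and the noiseless bounding box).
#' @export
generate_point_cloud <- function(spec) {
  stopifnot(inherits(spec, "synthetic_plant_spec"))
  with_seed(child_seed(spec$seed, "cloud"), {
    stem_r <- 0.012  # 1.2 cm stem radius
    il_m <- spec$internode_lengths / 100
    tops <- cumsum(il_m)
    stem_h <- sum(il_m)
    pts <- list(); lab <- list()

    n_int <- length(il_m)
    if (n_int > 0) {
      npts_i <- max(10L, spec$points_per_leaf %/% 2L)
      for (i in seq_len(n_int)) {
        ang <- stats::runif(npts_i, 0, 2 * pi)
        z0 <- if (i == 1) 0 else tops[i - 1]
        z <- stats::runif(npts_i, z0, tops[i])
        pts[[length(pts) + 1]] <- cbind(stem_r * cos(ang), stem_r * sin(ang), z)
        lab[[length(lab) + 1]] <- rep.int(i, npts_i)
      }
    }

    leaf_len <- leaf_wid <- attach_h <- numeric(spec$n_leaves)
    if (spec$n_leaves > 0) {
      for (i in seq_len(spec$n_leaves)) {
        # leaf size profile: bell along the stem, largest mid-canopy
        rel <- if (spec$n_leaves == 1) 1 else
          exp(-((i - 0.63 * spec$n_leaves) / (0.45 * spec$n_leaves))^2)
        len_m <- spec$leaf_length_max / 100 * (0.4 + 0.6 * rel)
        wid_m <- spec$leaf_width_max / 100 * (0.4 + 0.6 * rel)
        att <- if (n_int == 0) 0 else tops[min(i, n_int)]
        azim <- (i %% 2) * pi + 0.3 * sin(i * 2.4)  # distichous + jitter
        s <- stats::runif(spec$points_per_leaf)
        w <- stats::runif(spec$points_per_leaf)
        loc <- lamina_local(s, w, len_m, wid_m, spec$leaf_inclination)
        rot <- cbind(c(cos(azim), sin(azim), 0),
                     c(-sin(azim), cos(azim), 0), c(0, 0, 1))
        p <- loc %*% t(rot)
        p[, 3] <- p[, 3] + att
        pts[[length(pts) + 1]] <- p
        lab[[length(lab) + 1]] <- rep.int(100L + i, spec$points_per_leaf)
        leaf_len[i] <- lamina_arc_length(len_m, spec$leaf_inclination) * 100
        leaf_wid[i] <- wid_m * 100
        attach_h[i] <- att * 100
      }
    }

    points <- do.call(rbind, pts)
    labels <- unlist(lab)
    bbox <- rbind(min = apply(points, 2, min), max = apply(points, 2, max))
    if (spec$noise_sd > 0)
      points <- points + matrix(stats::rnorm(length(points), 0,
                                             spec$noise_sd / 100),
                                ncol = 3)
    if (spec$outlier_fraction > 0) {
      n_out <- round(nrow(points) * spec$outlier_fraction /
                       (1 - spec$outlier_fraction))
      if (n_out > 0) {
        span <- bbox[2, ] - bbox[1, ]
        lo <- bbox[1, ] - 0.2 * span
        hi <- bbox[2, ] + 0.2 * span
        out <- sapply(1:3, function(j) stats::runif(n_out, lo[j], hi[j]))
        out <- matrix(out, ncol = 3)
        points <- rbind(points, out)
        labels <- c(labels, rep.int(0L, n_out))
      }
    }
    colnames(points) <- c("x", "y", "z")
    list(points = points, labels = labels,
         truth = list(leaf_length_cm = leaf_len, leaf_width_cm = leaf_wid,
                      attach_height_cm = attach_h, stem_height_cm = stem_h * 100,
                      bbox_m = bbox))
  })
}

#' Ground-truth and noisy trait trajectories from weather
#'
#' Accumulates physiological development time (PDT) from daily mean
#' temperature, evaluates the logistic organ-growth law on it, and adds
#' Gaussian observation noise — the fixture for parameter-recovery studies.
#'
#' @param params a [growth_params()] (asymptote `Lmax`, rate `k` per
#'   physiological day, inflection `PDTm`).
#' @param weather an `edfm_weather` record (or any data.frame with `t_mean`).
#' @param noise_sd observation noise standard deviation, trait units.
#' @param phenology a [phenology_params()].
#' @param n_days optional span; defaults to the whole record.
#' @param seed integer seed for the noise stream.
#' @return data.frame: `day`, `pdt`, `trait_true`, `trait_obs`.
#' @export
generate_trait_trajectories <- function(params, weather, noise_sd = 0,
                                        phenology = phenology_params(),
                                        n_days = nrow(weather), seed = 1L) {
  stopifnot(inherits(params, "growth_params"))
  if (n_days > nrow(weather))
    edfm_stop("edfm_invalid_argument",
              "weather record (%d days) does not cover the requested span (%d)",
              nrow(weather), n_days)
  t_mean <- weather$t_mean[seq_len(n_days)]
  pdt <- cumsum(vapply(t_mean, pdt_increment, numeric(1), params = phenology))
  true <- logistic_size(pdt, params)
  obs <- if (noise_sd > 0)
    with_seed(child_seed(seed, "traits"),
              true + stats::rnorm(n_days, 0, noise_sd))
  else true
  data.frame(day = seq_len(n_days), pdt = pdt,
             trait_true = true, trait_obs = obs)
}
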