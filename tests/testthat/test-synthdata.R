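test_that("a flat noise-free scenario yields constant temperatures", {
  w <- generate_weather(weather_scenario(
    n_days = 5, t_base_seasonal = 25, t_amp_seasonal = 0,
    diurnal_amplitude = 0, t_noise_sd = 0))
  expect_equal(w$t_mean, rep(25, 5))
  expect_equal(w$t_min, rep(25, 5))
  expect_equal(w$t_max, rep(25, 5))
})

test_that("weather generation is bit-reproducible for a fixed seed", {
  sc <- weather_scenario(n_days = 40, seed = 9L)
  expect_identical(generate_weather(sc), generate_weather(sc))
  sc2 <- weather_scenario(n_days = 40, seed = 10L)
  expect_false(identical(generate_weather(sc), generate_weather(sc2)))
})

test_that("soil bucket without rain is non-increasing and matches hand arithmetic", {
  soil <- default_soil()
  w <- generate_weather(weather_scenario(
    n_days = 30, t_base_seasonal = 25, t_amp_seasonal = 0, t_noise_sd = 0,
    rain_events = data.frame(day = integer(), depth_mm = numeric())))
  th <- as.matrix(w[grep("^theta_", names(w))])
  for (l in seq_len(ncol(th))) expect_true(all(diff(th[, l]) <= 1e-12))
  # day 1, layer 1 by hand: demand = et_coef*(25 - et_t_base); layer share
  # root_frac[1], availability 1 at field capacity
  demand <- soil$et_coef * (25 - soil$et_t_base)
  expect_equal(unname(th[1, 1]),
               soil$theta_init - demand * soil$root_frac[1] /
                 soil$layer_depth_mm[1],
               tolerance = 1e-12)
  # day 2 layer 1: availability has dropped below 1
  avail <- (th[1, 1] - soil$theta_wp) / (soil$theta_fc - soil$theta_wp)
  expect_equal(unname(th[2, 1]),
               unname(th[1, 1] - demand * soil$root_frac[1] * avail /
                        soil$layer_depth_mm[1]),
               tolerance = 1e-12)
})

test_that("soil moisture stays within physical bounds across scenarios", {
  soil <- default_soil()
  for (s in 1:5) {
    w <- generate_weather(weather_scenario(n_days = 80, seed = s,
                                           par_max = 1500 + 100 * s))
    th <- as.matrix(w[grep("^theta_", names(w))])
    expect_true(all(th >= soil$theta_wp - 1e-12))
    expect_true(all(th <= soil$theta_sat + 1e-12))
  }
})

test_that("weather scenario validation rejects bad arguments", {
  expect_error(weather_scenario(n_days = 0), class = "edfm_invalid_argument")
  expect_error(weather_scenario(par_max = -1), class = "edfm_invalid_argument")
})

test_that("noiseless one-leaf cloud lies in the analytic lamina bounding box", {
  spec <- synthetic_plant_spec(
    n_leaves = 1, leaf_length_max = 50, leaf_width_max = 8,
    internode_lengths = numeric(0), leaf_inclination = 0,
    points_per_leaf = 200, noise_sd = 0, outlier_fraction = 0)
  pc <- generate_point_cloud(spec)
  lp <- pc$points[pc$labels > 100, , drop = FALSE]
  # inclination 0: the lamina is flat at z = 0; extent bounded by the
  # nominal length and half-width in its own (azimuth-rotated) plane
  expect_true(all(abs(lp[, 3]) < 1e-9))
  expect_true(all(sqrt(lp[, 1]^2 + lp[, 2]^2) <= 0.50 + 1e-9))
  ev <- eigen(stats::cov(lp[, 1:2]), symmetric = TRUE)$vectors
  across <- as.matrix(lp[, 1:2]) %*% ev[, 2]
  expect_true(diff(range(across)) <= 0.08 + 1e-9)
})

test_that("a leafless single internode gives max z at the internode length", {
  spec <- synthetic_plant_spec(n_leaves = 0, internode_lengths = 10,
                               noise_sd = 0, outlier_fraction = 0)
  pc <- generate_point_cloud(spec)
  expect_lt(abs(max(pc$points[, 3]) - 0.10), 0.005)
  expect_true(all(pc$points[, 3] <= 0.10 + 1e-12))
  expect_equal(pc$truth$stem_height_cm, 10)
})

test_that("point clouds are deterministic under a fixed seed and ground truth round-trips", {
  spec <- synthetic_plant_spec(n_leaves = 4, internode_lengths = rep(12, 4),
                               noise_sd = 0.3, outlier_fraction = 0.05,
                               seed = 21L)
  a <- generate_point_cloud(spec)
  b <- generate_point_cloud(spec)
  expect_identical(a, b)
  # ground truth is internally consistent with the spec dimensions
  expect_equal(a$truth$stem_height_cm, sum(spec$internode_lengths),
               tolerance = 1e-9)
  expect_equal(a$truth$attach_height_cm,
               cumsum(spec$internode_lengths)[pmin(1:4, 4)],
               tolerance = 1e-9)
})

test_that("plant spec validation enforces its invariants", {
  expect_error(synthetic_plant_spec(points_per_leaf = 5),
               class = "edfm_invalid_argument")
  expect_error(synthetic_plant_spec(outlier_fraction = 0.6),
               class = "edfm_invalid_argument")
})

test_that("trait trajectories follow the logistic law on accumulated PDT", {
  w <- fixture("flat60", function() flat_weather(60))
  gp <- growth_params(Lmax = 800, k = 0.15, PDTm = 40)
  tr <- generate_trait_trajectories(gp, w, noise_sd = 0)
  expect_equal(tr$trait_obs, tr$trait_true)
  # constant 25 degC with defaults: PDT advances exactly 1 per day, so the
  # midpoint is crossed on day 40
  expect_equal(tr$pdt, as.numeric(1:60))
  expect_equal(tr$trait_true[40], 800 / 2, tolerance = 1e-9)
  # frozen at T = T_base
  wb <- generate_weather(weather_scenario(n_days = 10, t_base_seasonal = 8,
                                          t_amp_seasonal = 0, t_noise_sd = 0))
  trb <- generate_trait_trajectories(gp, wb, noise_sd = 0)
  expect_equal(trb$trait_true, rep(logistic_size(0, gp), 10))
  # span mismatch errors
  expect_error(generate_trait_trajectories(gp, wb, n_days = 20),
               class = "edfm_invalid_argument")
})

test_that("noisy trait observations are seeded and unbiased around the truth", {
  w <- fixture("flat60", function() flat_weather(60))
  gp <- growth_params(800, 0.15, 40)
  a <- generate_trait_trajectories(gp, w, noise_sd = 10, seed = 4L)
  b <- generate_trait_trajectories(gp, w, noise_sd = 10, seed = 4L)
  expect_identical(a, b)
  expect_gt(stats::sd(a$trait_obs - a$trait_true), 0)
  expect_lt(abs(mean(a$trait_obs - a$trait_true)), 10)
})

test_that("PLY round-trips in both ascii and binary formats", {
  pts <- matrix(stats::rnorm(60), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  for (fmt in c("ascii", "binary_little_endian")) {
    f <- tempfile(fileext = ".ply")
    write_ply(pts, f, fmt)
    back <- read_ply(f)
    expect_equal(back, pts, tolerance = 1e-6)  # float32 precision
    unlink(f)
  }
})

test_that("weather CSV round-trips with schema validation", {
  w <- fixture("flat60", function() flat_weather(60))
  f <- tempfile(fileext = ".csv")
  write_weather_csv(w, f)
  back <- read_weather_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(w), tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(day = 1, t_mean = 20), bad, row.names = FALSE)
  expect_error(read_weather_csv(bad), class = "edfm_invalid_argument")
  unlink(c(f, bad))
})
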