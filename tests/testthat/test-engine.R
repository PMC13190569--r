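test_that("configuration validation and YAML merge work", {
  cfg <- default_config()
  expect_silent(validate_config(cfg))
  bad <- cfg; bad$water$gamma <- -1
  expect_error(validate_config(bad), class = "edfm_invalid_argument")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("water:", "  psi_root: -0.1", "growth:", "  k: 0.2"), f)
  merged <- read_config(f)
  expect_equal(merged$water$psi_root, -0.1)
  expect_equal(merged$growth$k, 0.2)
  expect_equal(merged$water$theta_fc, cfg$water$theta_fc)
  unlink(f)
})

test_that("the seedling state matches the documented initialization", {
  cfg <- fast_config()
  st <- initial_state(cfg)
  leaves <- Filter(function(o) o$type == "leaf", st$organs)
  ints <- Filter(function(o) o$type == "internode", st$organs)
  expect_length(leaves, cfg$plant$n_organs)
  expect_equal(sum(vapply(leaves, function(o) o$L > 0, logical(1))), 3)
  expect_equal(sum(vapply(ints, function(o) o$L > 0, logical(1))), 1)
  expect_equal(leaves[[1]]$L, 0.05 * leaves[[1]]$gp$Lmax)
  expect_equal(st$pdt, 0)
  expect_gt(st$intercepted_mol, 0)   # bootstrap capture for day 1
})

test_that("a dark day allocates nothing but phenology still advances", {
  cfg <- fast_config()
  st <- initial_state(cfg)
  out <- step_day(st, env_row(t_mean = 25, par_mol = 30), NULL, cfg)
  st1 <- out$state
  # intercepted energy was zeroed by a dark previous day
  st1$intercepted_mol <- 0
  out2 <- step_day(st1, env_row(t_mean = 25, par_mol = 0), NULL, cfg)
  expect_equal(out2$diagnostics$E, 0)
  expect_equal(out2$diagnostics$sumQ, 0)
  L1 <- vapply(st1$organs, function(o) o$L, numeric(1))
  L2 <- vapply(out2$state$organs, function(o) o$L, numeric(1))
  expect_equal(L2, L1)
  expect_equal(out2$state$pdt, st1$pdt + 1)
})

test_that("with ample carbon and no water stress growth equals the logistic potential", {
  cfg <- fast_config()
  cfg$physiology$lue <- 1e9
  cfg$water$psi_root <- 0
  st <- initial_state(cfg)
  env <- env_row(t_mean = 25, par_mol = 30, theta = cfg$water$theta_fc)
  out <- step_day(st, env, NULL, cfg)
  for (j in seq_along(st$organs)) {
    o0 <- st$organs[[j]]; o1 <- out$state$organs[[j]]
    d_pot <- logistic_size(1, o1$gp) - logistic_size(max(0, o0$init_pdt), o1$gp)
    if (o0$init_pdt > 1) d_pot <- 0
    expect_equal(o1$L - o0$L, d_pot, tolerance = 1e-9)
  }
})

test_that("zero water stress shuts down expansion entirely", {
  cfg <- fast_config()
  st <- initial_state(cfg)
  env <- env_row(theta = cfg$water$theta_wp)   # at wilting point: WSF = 0
  out <- step_day(st, env, NULL, cfg)
  expect_equal(out$diagnostics$wsf, 0)
  L0 <- vapply(st$organs, function(o) o$L, numeric(1))
  L1 <- vapply(out$state$organs, function(o) o$L, numeric(1))
  expect_equal(L1, L0)
  expect_gt(out$state$pdt, 0)
})

test_that("a zero-day season returns the initial state unchanged", {
  cfg <- fast_config(n_days = 0L)
  w <- flat_weather(5)
  r <- run_season(cfg, w[0, ])
  expect_s3_class(r$final_state, "plant_state")
  expect_equal(r$final_state$pdt, 0)
  expect_null(r$diagnostics)
})

test_that("season runs are deterministic and satisfy the core invariants", {
  cfg <- fast_config(seed = 5L, n_days = 40L)
  w <- fixture("flat40", function() flat_weather(40))
  r1 <- fixture("season40", function() run_season(cfg, w))
  r2 <- run_season(cfg, w)
  expect_identical(r1$diagnostics, r2$diagnostics)
  d <- r1$diagnostics
  expect_true(all(diff(d$pdt) >= 0))
  expect_true(all(diff(d$height_cm) >= -1e-12))
  expect_equal(d$sumQ, d$E, tolerance = 1e-12)
  for (o in r1$final_state$organs)
    expect_lte(o$L, o$gp$Lmax + 1e-9)
  # weight rows live on the simplex
  ws <- as.matrix(r1$weights[, c("alpha_env", "alpha_point", "alpha_rgb")])
  expect_equal(unname(rowSums(ws)), rep(1, nrow(ws)), tolerance = 1e-9)
  # trait CSV export round-trips
  td <- tempfile(); dir.create(td)
  run_season(cfg, w, out_dir = td)
  expect_true(all(file.exists(file.path(td, c("traits.csv", "weights.csv",
                                              "diagnostics.csv")))))
  tr <- utils::read.csv(file.path(td, "traits.csv"))
  expect_equal(tr$height_cm, d$height_cm, tolerance = 1e-9)
  unlink(td, recursive = TRUE)
})

test_that("gap-filled weather is required", {
  cfg <- fast_config()
  w <- flat_weather(10)
  expect_error(run_season(cfg, w[c(1:4, 6:10), ]),
               class = "edfm_invalid_argument")
})

test_that("a drier season never ends with a larger canopy (paired seeds)", {
  cfg <- fast_config(seed = 9L, n_days = 40L)
  dry <- generate_weather(weather_scenario(
    n_days = 40, seed = 9, rain_events = data.frame(day = 1, depth_mm = 5)))
  wet <- generate_weather(weather_scenario(
    n_days = 40, seed = 9,
    rain_events = data.frame(day = seq(1, 40, 4), depth_mm = 25)))
  r_dry <- run_season(cfg, dry)
  r_wet <- run_season(cfg, wet)
  expect_lte(tail(r_dry$diagnostics$lai, 1), tail(r_wet$diagnostics$lai, 1))
  expect_lte(tail(r_dry$diagnostics$height_cm, 1),
             tail(r_wet$diagnostics$height_cm, 1))
})

test_that("silking metrics are read at the PDT crossing", {
  cfg <- fast_config(seed = 5L, n_days = 40L)
  w <- fixture("flat40", function() flat_weather(40))
  r <- fixture("season40", function() run_season(cfg, w))
  # constant 25 degC: PDT = day, so crossing a threshold of 20 is day 20
  v <- metric_at_silking(r, "lai", silking_pdt = 20)
  expect_equal(v, r$diagnostics$lai[20])
  expect_warning(metric_at_silking(r, "lai", silking_pdt = 999),
                 "before silking")
})
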