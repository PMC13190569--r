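# shared fixtures, built lazily once per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# constant 25 degC, noise-free scenario (PDT advances exactly 1/day)
flat_weather <- function(n_days = 60, rain = data.frame(day = seq(1, n_days, 7),
                                                        depth_mm = 25)) {
  generate_weather(weather_scenario(
    n_days = n_days, t_base_seasonal = 25, t_amp_seasonal = 0,
    diurnal_amplitude = 8, t_noise_sd = 0, rain_events = rain, seed = 1))
}

# small fast config for engine tests
fast_config <- function(seed = 5L, n_days = 40L) {
  cfg <- default_config(seed = seed)
  cfg$season$n_days <- as.integer(n_days)
  cfg$morphology$n_rays <- 400L
  cfg
}

# one-row weather data.frame with given temperature/par/theta
env_row <- function(t_mean = 25, par_mol = 30, theta = 0.32) {
  structure(data.frame(day = 1, t_mean = t_mean, t_min = t_mean - 4,
                       t_max = t_mean + 4, par_mol = par_mol,
                       theta_1 = theta, theta_2 = theta, theta_3 = theta),
            class = c("edfm_weather", "data.frame"))
}

# independent scalar peephole LSTM (direct formulas), the oracle for the
# ConvLSTM cell at kernel size 1 and spatial size 1
scalar_lstm_oracle <- function(x, h_prev, c_prev, p) {
  sig <- function(z) 1 / (1 + exp(-z))
  hidden <- p$hidden
  i <- f <- o <- cc <- numeric(hidden)
  for (j in seq_len(hidden)) {
    wx <- function(W) sum(W[1, , j] * x)
    wh <- function(W) sum(W[1, , j] * h_prev)
    i[j] <- sig(wx(p$W_xi) + wh(p$W_hi) + p$W_ci[j] * c_prev[j] + p$b_i[j])
    f[j] <- sig(wx(p$W_xf) + wh(p$W_hf) + p$W_cf[j] * c_prev[j] + p$b_f[j])
    cc[j] <- f[j] * c_prev[j] + i[j] * tanh(wx(p$W_xc) + wh(p$W_hc) + p$b_c[j])
    o[j] <- sig(wx(p$W_xo) + wh(p$W_ho) + p$W_co[j] * cc[j] + p$b_o[j])
  }
  list(H = o * tanh(cc), C = cc)
}

# brute-force SOR oracle: full pairwise distance matrix
sor_oracle <- function(points, k, std_ratio) {
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  diag(D) <- Inf
  d <- apply(D, 1, function(r) mean(sort(r)[1:k]))
  unname(which(d > mean(d) + std_ratio * stats::sd(d)))
}

# brute-force voxel oracle: hash map of voxel indices
voxel_oracle <- function(points, voxel_size) {
  origin <- apply(points, 2, min)
  idx <- floor(sweep(points, 2, origin) / voxel_size)
  key <- apply(idx, 1, paste, collapse = "/")
  out <- t(sapply(split(seq_len(nrow(points)), key),
                  function(i) colMeans(points[i, , drop = FALSE])))
  out[order(rownames(out)), , drop = FALSE]
}

# randomized horizontal-leaf canopy over a unit footprint (for the
# Beer-Lambert cross-check; k = 1 for horizontal leaves, vertical beam)
horizontal_leaf_canopy <- function(lai, n_leaf = 150, seed = 1) {
  set.seed(seed)
  foot <- 1; side <- sqrt(foot)
  a_leaf <- lai * foot / n_leaf
  s_leaf <- sqrt(a_leaf)
  meshes <- lapply(seq_len(n_leaf), function(i) {
    cx <- stats::runif(1, -side / 2, side / 2)
    cy <- stats::runif(1, -side / 2, side / 2)
    z <- stats::runif(1, 0.2, 2)
    v <- rbind(c(cx - s_leaf / 2, cy - s_leaf / 2, z),
               c(cx + s_leaf / 2, cy - s_leaf / 2, z),
               c(cx + s_leaf / 2, cy + s_leaf / 2, z),
               c(cx - s_leaf / 2, cy + s_leaf / 2, z))
    list(vertices = v, faces = rbind(c(1, 2, 3), c(1, 3, 4)))
  })
  canopy_scene(meshes, foot, wrap = TRUE)
}

# flat rectangular control grid surface (analytic area w * h)
flat_rect_surface <- function(w = 10, h = 5, nu = 6, nv = 4) {
  ctrl <- array(0, c(nu, nv, 3))
  gx <- seq(0, w, length.out = nu)
  gy <- seq(0, h, length.out = nv)
  for (i in seq_len(nu)) for (j in seq_len(nv)) ctrl[i, j, ] <- c(gx[i], gy[j], 0)
  nurbs_surface(ctrl)
}
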