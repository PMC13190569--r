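#' Parameters for the 1-D convolutional peephole LSTM cell
#'
#' Kernels act along the channel axis of the daily weather vector (treated
#' as a 1-D spatial signal with one input channel). Input-to-state kernels
#' have shape `kernel_size x in_channels x hidden`, state-to-state kernels
#' `kernel_size x hidden x hidden`; peephole weights and biases are
#' per-hidden-channel vectors (broadcast over space). Initialization is
#' Xavier-uniform from a seed.
#'
#' @param in_channels input channels (default 1).
#' @param hidden hidden channels (default 64).
#' @param kernel_size odd convolution kernel width (default 3).
#' @param seed integer seed for the Xavier draw.
#' @return Object of class `convlstm_params`.
#' @export
convlstm_params <- function(in_channels = 1, hidden = 64, kernel_size = 3,
                            seed = 1L) {
  if (kernel_size %% 2 == 0)
    edfm_stop("edfm_invalid_argument", "kernel_size must be odd")
  stopifnot(hidden >= 1, in_channels >= 1)
  with_seed(child_seed(seed, "convlstm"), {
    kx <- function() xavier_uniform(c(kernel_size, in_channels, hidden),
                                    kernel_size * in_channels,
                                    kernel_size * hidden)
    kh <- function() xavier_uniform(c(kernel_size, hidden, hidden),
                                    kernel_size * hidden, kernel_size * hidden)
    structure(list(
      W_xi = kx(), W_xf = kx(), W_xc = kx(), W_xo = kx(),
      W_hi = kh(), W_hf = kh(), W_hc = kh(), W_ho = kh(),
      W_ci = stats::runif(hidden, -0.1, 0.1),
      W_cf = stats::runif(hidden, -0.1, 0.1),
      W_co = stats::runif(hidden, -0.1, 0.1),
      b_i = numeric(hidden), b_f = numeric(hidden),
      b_c = numeric(hidden), b_o = numeric(hidden),
      in_channels = in_channels, hidden = hidden, kernel_size = kernel_size
    ), class = "convlstm_params")
  })
}

#' Zero parameters (all kernels, peepholes and biases 0) — mainly for tests
#' @rdname convlstm_params
#' @export
convlstm_params_zero <- function(in_channels = 1, hidden = 4, kernel_size = 1) {
  p <- convlstm_params(in_channels, hidden, kernel_size, seed = 0L)
  for (nm in grep("^(W|b)_", names(p), value = TRUE)) p[[nm]][] <- 0
  p
}

# 1-D convolution with same padding.
# x: S x Cin matrix, w: K x Cin x Cout array -> S x Cout matrix
conv1d_same <- function(x, w) {
  S <- nrow(x); K <- dim(w)[1]; Cout <- dim(w)[3]
  pad <- (K - 1) %/% 2
  xp <- rbind(matrix(0, pad, ncol(x)), x, matrix(0, pad, ncol(x)))
  out <- matrix(0, S, Cout)
  for (dk in seq_len(K)) {
    out <- out + xp[dk:(dk + S - 1), , drop = FALSE] %*%
      matrix(w[dk, , ], nrow = dim(w)[2])
  }
  out
}

#' One step of the convolutional peephole LSTM
#'
#' Gates use sigmoid activations with peephole (Hadamard) terms on the cell
#' state; the candidate uses tanh:
#' \deqn{i_t = \sigma(W_{xi}*X_t + W_{hi}*H_{t-1} + W_{ci}\circ C_{t-1} + b_i)}
#' \deqn{f_t = \sigma(W_{xf}*X_t + W_{hf}*H_{t-1} + W_{cf}\circ C_{t-1} + b_f)}
#' \deqn{C_t = f_t\circ C_{t-1} + i_t\circ\tanh(W_{xc}*X_t + W_{hc}*H_{t-1} + b_c)}
#' \deqn{o_t = \sigma(W_{xo}*X_t + W_{ho}*H_{t-1} + W_{co}\circ C_t + b_o)}
#' \deqn{H_t = o_t\circ\tanh(C_t)}
#' `*` is a same-padded 1-D convolution and `\circ` elementwise product.
#'
#' @param x input, S x in_channels matrix (S = spatial length).
#' @param state list with `H` and `C` (S x hidden matrices), or `NULL` for
#'   the zero initial state.
#' @param params a [convlstm_params()].
#' @return List with new `H` and `C`.
#' @export
convlstm_cell <- function(x, state, params) {
  stopifnot(inherits(params, "convlstm_params"))
  x <- as.matrix(x)
  if (ncol(x) != params$in_channels)
    edfm_stop("edfm_invalid_argument",
              "input has %d channels, params expect %d",
              ncol(x), params$in_channels)
  S <- nrow(x)
  if (is.null(state))
    state <- list(H = matrix(0, S, params$hidden),
                  C = matrix(0, S, params$hidden))
  if (nrow(state$H) != S)
    edfm_stop("edfm_invalid_argument", "state spatial size mismatch")
  H <- state$H; C <- state$C
  peep <- function(wc) sweep(C, 2, wc, "*")
  bias <- function(b, m) sweep(m, 2, b, "+")
  i <- sigmoid(bias(params$b_i,
                    conv1d_same(x, params$W_xi) + conv1d_same(H, params$W_hi) +
                      peep(params$W_ci)))
  f <- sigmoid(bias(params$b_f,
                    conv1d_same(x, params$W_xf) + conv1d_same(H, params$W_hf) +
                      peep(params$W_cf)))
  Cn <- f * C + i * tanh(bias(params$b_c,
                              conv1d_same(x, params$W_xc) +
                                conv1d_same(H, params$W_hc)))
  o <- sigmoid(bias(params$b_o,
                    conv1d_same(x, params$W_xo) + conv1d_same(H, params$W_ho) +
                      sweep(Cn, 2, params$W_co, "*")))
  list(H = o * tanh(Cn), C = Cn)
}

#' Encode a normalized weather window into h_env
#'
#' Unrolls the ConvLSTM cell over the window's days (each day's channel
#' vector is the 1-D spatial signal) from a zero initial state; `h_env` is
#' the spatial average of the final hidden state, one value per hidden
#' channel.
#'
#' @param window width x channels numeric matrix (z-scored weather).
#' @param params a [convlstm_params()].
#' @param width expected window width (default 7 days).
#' @return Numeric vector of length `params$hidden`.
#' @export
encode_environment <- function(window, params, width = 7) {
  window <- as.matrix(window)
  if (nrow(window) != width)
    edfm_stop("edfm_invalid_argument",
              "window has %d rows, expected %d", nrow(window), width)
  state <- NULL
  for (t in seq_len(nrow(window))) {
    x_t <- matrix(window[t, ], ncol = 1)  # channels as space, 1 input channel
    state <- convlstm_cell(x_t, state, params)
  }
  colMeans(state$H)
}

# deterministic farthest-point sampling, seeded by the lowest-z point
farthest_point_sample <- function(points, n) {
  N <- nrow(points)
  if (N <= n) return(seq_len(N))
  sel <- integer(n)
  sel[1] <- which.min(points[, 3])
  d <- rowSums(sweep(points, 2, points[sel[1], ])^2)
  for (i in 2:n) {
    sel[i] <- which.max(d)
    d <- pmin(d, rowSums(sweep(points, 2, points[sel[i], ])^2))
  }
  sel
}

#' Hand-crafted geometric point-cloud descriptor (h_point)
#'
#' Resamples the cloud to 1024 points by deterministic farthest-point
#' sampling (started from the lowest point, so no seed is needed), then
#' emits a fixed 22-length descriptor: height percentiles (5/25/50/75/95),
#' bounding-box extents, covariance eigenvalue shape ratios (linearity,
#' planarity, sphericity), a 10-bin vertical point-density histogram and a
#' voxel-occupancy-to-bounding-box volume ratio (compactness).
#'
#' @param points N x 3 matrix, N >= 8.
#' @param n_sample resample size (default 1024).
#' @return Named numeric vector of length 22.
#' @export
encode_point_cloud <- function(points, n_sample = 1024) {
  points <- as.matrix(points)
  if (nrow(points) < 8)
    edfm_stop("edfm_invalid_argument", "need >= 8 points, got %d", nrow(points))
  p <- points[farthest_point_sample(points, n_sample), , drop = FALSE]
  z <- p[, 3]
  qs <- stats::quantile(z, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE,
                        type = 7)
  ext <- apply(p, 2, function(x) diff(range(x)))
  ev <- sort(eigen(stats::cov(p), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  ev[ev < 0] <- 0
  l1 <- max(ev[1], .Machine$double.eps)
  shape <- c(linearity = (ev[1] - ev[2]) / l1,
             planarity = (ev[2] - ev[3]) / l1,
             sphericity = ev[3] / l1)
  zr <- range(z)
  hist10 <- if (diff(zr) > 0) {
    br <- seq(zr[1], zr[2], length.out = 11)
    as.numeric(table(cut(z, br, include.lowest = TRUE))) / length(z)
  } else c(1, numeric(9))
  # occupancy ratio: occupied voxels / total voxels of a 10^3 bbox grid
  occ <- if (all(ext > 0)) {
    g <- floor(sweep(sweep(p, 2, apply(p, 2, min)), 2, ext, "/") * 10)
    g[g > 9] <- 9
    length(unique(paste(g[, 1], g[, 2], g[, 3]))) / 1000
  } else 0
  out <- c(qs, ext, shape, hist10, occ)
  names(out) <- c(paste0("z_q", c(5, 25, 50, 75, 95)),
                  paste0("ext_", c("x", "y", "z")),
                  names(shape), paste0("zhist_", 1:10), "occupancy")
  out
}

#' Hand-crafted canopy image descriptor (h_rgb)
#'
#' Operates on standardized 224 x 224 x 3 rasters in [0, 1]. Emits a fixed
#' 33-length descriptor: per-channel 8-bin intensity histograms, excess
#' green index (2G - R - B) mean and sd, green-cover fraction (ExG > 0.1),
#' gradient-energy texture of the grey image, and a 5-ring radial cover
#' profile.
#'
#' @param image standardized array from [standardize_image()].
#' @param size expected edge length (default 224).
#' @return Named numeric vector of length 33.
#' @export
encode_image <- function(image, size = 224) {
  d <- dim(image)
  if (length(d) != 3 || d[1] != size || d[2] != size || d[3] != 3 ||
      min(image) < 0 || max(image) > 1)
    edfm_stop("edfm_invalid_argument",
              "image must be a standardized %d x %d x 3 raster in [0,1]", size, size)
  br <- seq(0, 1, length.out = 9)
  hists <- unlist(lapply(1:3, function(c) {
    h <- as.numeric(table(cut(image[, , c], br, include.lowest = TRUE)))
    h / (size * size)
  }))
  exg <- 2 * image[, , 2] - image[, , 1] - image[, , 3]
  cover_mask <- exg > 0.1
  grey <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  gx <- grey[, -1] - grey[, -size]
  gy <- grey[-1, ] - grey[-size, ]
  grad_energy <- mean(gx^2) + mean(gy^2)
  # radial cover: fraction of plant pixels per concentric ring
  ctr <- (size + 1) / 2
  r <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  ring <- pmin(4L, floor(r / (size / 2) * 5))
  radial <- vapply(0:4, function(k) {
    m <- ring == k
    if (any(m)) mean(cover_mask[m]) else 0
  }, numeric(1))
  out <- c(hists, mean(exg), stats::sd(exg), mean(cover_mask),
           grad_energy, radial)
  names(out) <- c(paste0(rep(c("r", "g", "b"), each = 8), "_hist", 1:8),
                  "exg_mean", "exg_sd", "cover", "grad_energy",
                  paste0("radial_", 1:5))
  out
}

# --- encoder plug-in registry -------------------------------------------

.encoder_registry <- new.env(parent = emptyenv())

#' Encoder plug-in registry
#'
#' Learned encoders (e.g. a trained temporal or point-cloud network) can be
#' substituted for the built-in deterministic ones by registering a callable
#' under the modality name used in the configuration
#' (`encoders.{env,point,rgb}.impl`).
#'
#' @param name registry key.
#' @param fn callable mapping the modality input to a numeric vector.
#' @return `register_encoder` returns `fn` invisibly; `get_encoder` the
#'   registered callable.
#' @export
register_encoder <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .encoder_registry)
  invisible(fn)
}

#' @rdname register_encoder
#' @export
get_encoder <- function(name) {
  if (!exists(name, envir = .encoder_registry))
    edfm_stop("edfm_invalid_argument", "no encoder registered as '%s'", name)
  get(name, envir = .encoder_registry)
}
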