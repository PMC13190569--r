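#' Fit per-channel z-score normalization statistics
#'
#' Statistics must be computed on the training partition only; the same
#' `zscore_stats` object is then applied to validation/test data. The
#' standard deviation is the population form (divide by n), so the
#' transformed training data has variance exactly 1.
#'
#' @param train numeric matrix or data.frame, one column per channel.
#' @return Object of class `zscore_stats` with fields `mu` and `sigma`.
#' @export
fit_zscore <- function(train) {
  x <- as.matrix(train)
  if (nrow(x) < 2)
    edfm_stop("edfm_invalid_argument", "need >= 2 rows to fit z-score stats")
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2, mu)^2))
  bad <- sigma <= 0 | !is.finite(sigma)
  if (any(bad)) {
    nm <- colnames(x) %||% as.character(seq_len(ncol(x)))
    edfm_stop("edfm_degenerate_channel",
              "constant channel(s): %s", paste(nm[bad], collapse = ", "))
  }
  structure(list(mu = mu, sigma = sigma), class = "zscore_stats")
}

#' Apply (or invert) a fitted z-score transform
#'
#' `apply_zscore` computes `(x - mu) / sigma` per channel; `invert_zscore`
#' is its exact inverse `z * sigma + mu`.
#'
#' @param x numeric matrix/data.frame with the same channels as the fit.
#' @param stats a `zscore_stats` object.
#' @return Matrix of the same shape.
#' @export
apply_zscore <- function(x, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mu))
    edfm_stop("edfm_invalid_argument",
              "channel mismatch: data has %d, stats has %d",
              ncol(x), length(stats$mu))
  sweep(sweep(x, 2, stats$mu), 2, stats$sigma, "/")
}

#' @rdname apply_zscore
#' @export
invert_zscore <- function(x, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mu))
    edfm_stop("edfm_invalid_argument", "channel mismatch")
  sweep(sweep(x, 2, stats$sigma, "*"), 2, stats$mu, "+")
}

#' Trailing moving-window smoothing
#'
#' Each smoothed value summarises the window ending at that index (shorter
#' at the start of the series), so no future information leaks backwards.
#'
#' @param x numeric vector.
#' @param width window width in samples (days).
#' @param kernel `"mean"` or `"median"`.
#' @return Numeric vector, same length as `x`.
#' @export
smooth_series <- function(x, width = 7, kernel = c("mean", "median")) {
  kernel <- match.arg(kernel)
  stopifnot(width >= 1)
  f <- if (kernel == "mean") mean else stats::median
  vapply(seq_along(x),
         function(i) f(x[max(1, i - width + 1):i]),
         numeric(1))
}

#' Extract sliding windows from a time-ordered series
#'
#' @param series numeric vector, matrix or data.frame (rows = time).
#' @param width window width (>= 1).
#' @param stride step between window starts (>= 1).
#' @return List of windows (same type as `series`); empty list with a warning
#'   if the series is shorter than `width`. For `n >= width` the number of
#'   windows is `floor((n - width) / stride) + 1`.
#' @export
sliding_windows <- function(series, width, stride = 1) {
  if (width < 1 || stride < 1)
    edfm_stop("edfm_invalid_argument", "width and stride must be >= 1")
  n <- if (is.null(dim(series))) length(series) else nrow(series)
  if (n < width) {
    warning(sprintf("series length %d < window width %d: no windows", n, width))
    return(list())
  }
  starts <- seq(1L, n - width + 1L, by = stride)
  lapply(starts, function(s) {
    if (is.null(dim(series))) series[s:(s + width - 1L)]
    else series[s:(s + width - 1L), , drop = FALSE]
  })
}

# blocked k-nearest-neighbour mean distances (avoids an N x N matrix)
knn_mean_dist <- function(points, k, block = 512L) {
  n <- nrow(points)
  out <- numeric(n)
  sq <- rowSums(points^2)
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(sq[s:e], sq, "+") - 2 * points[s:e, , drop = FALSE] %*% t(points)
    d2[d2 < 0] <- 0
    for (i in seq_len(e - s + 1L)) {
      di <- sqrt(d2[i, ])
      di[s + i - 1L] <- Inf              # exclude the point itself
      out[s + i - 1L] <- mean(sort.int(di, partial = k)[1:k])
    }
  }
  out
}

#' Statistical Outlier Removal (SOR) filter
#'
#' For each point the mean distance to its `k` nearest neighbours is
#' computed; points whose mean distance exceeds
#' `mean(d) + std_ratio * sd(d)` (global statistics over all points) are
#' removed.
#'
#' @param points N x 3 numeric matrix.
#' @param k number of neighbours (default 16).
#' @param std_ratio threshold multiplier on the standard deviation
#'   (default 2).
#' @return List with `points` (kept rows), `removed` (indices of removed
#'   rows in the input) and `mean_dist` (the per-point statistic).
#' @export
sor_filter <- function(points, k = 16, std_ratio = 2.0) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= k)
    edfm_stop("edfm_invalid_argument",
              "need more points (%d) than neighbours k=%d", n, k)
  d <- knn_mean_dist(points, k)
  thr <- mean(d) + std_ratio * stats::sd(d)
  removed <- which(d > thr)
  keep <- setdiff(seq_len(n), removed)
  list(points = points[keep, , drop = FALSE], removed = removed, mean_dist = d)
}

#' Voxel-grid downsampling
#'
#' Points are binned into cubic voxels of side `voxel_size`; the voxel index
#' of a point is `floor((p - origin) / voxel_size)` with the origin anchored
#' at the per-axis minimum of the cloud. Each occupied voxel is replaced by
#' the centroid of its points.
#'
#' @param points N x 3 numeric matrix.
#' @param voxel_size voxel edge length (same units as the cloud).
#' @return M x 3 matrix of voxel centroids (M = occupied voxels), ordered by
#'   voxel index.
#' @export
voxel_downsample <- function(points, voxel_size) {
  if (voxel_size <= 0)
    edfm_stop("edfm_invalid_argument", "voxel_size must be positive")
  points <- as.matrix(points)
  if (nrow(points) == 0) return(points)
  origin <- apply(points, 2, min)
  idx <- floor(sweep(points, 2, origin) / voxel_size)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  g <- factor(key, levels = unique(key))
  out <- rowsum(points, g, reorder = FALSE) / as.vector(table(g)[levels(g)])
  colnames(out) <- colnames(points)
  rownames(out) <- NULL
  out
}

#' Downsample a cloud to approximately a target point count
#'
#' Binary-searches the voxel size until the voxel-downsampled cloud is
#' within +/-5% of `target`, or 40 iterations elapse (best iterate
#' returned).
#'
#' @param points N x 3 matrix.
#' @param target desired point count (default 10000).
#' @param tol relative tolerance on the achieved count.
#' @param max_iter search iteration cap.
#' @return List with `points`, `voxel_size`, and achieved `n`.
#' @export
downsample_to_count <- function(points, target = 10000, tol = 0.05,
                                max_iter = 40) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= target) {
    warning(sprintf("cloud has %d <= target %d points: returned unchanged",
                    n, target))
    return(list(points = points, voxel_size = 0, n = n))
  }
  span <- apply(points, 2, function(x) diff(range(x)))
  lo <- 1e-6 * max(span)          # ~no merging
  hi <- max(span)                 # everything in one voxel
  best <- NULL
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)          # geometric bisection: scale spans decades
    ds <- voxel_downsample(points, mid)
    m <- nrow(ds)
    if (is.null(best) || abs(m - target) < abs(best$n - target))
      best <- list(points = ds, voxel_size = mid, n = m)
    if (abs(m - target) <= tol * target) break
    if (m > target) lo <- mid else hi <- mid
  }
  best
}

#' Standardize an RGB raster to 224 x 224 in [0, 1]
#'
#' Center-crops to the largest square, bilinearly resizes to 224 x 224 and
#' scales 8-bit intensities to the unit interval.
#'
#' @param image H x W x 3 numeric array; values in 0..255 (or already in
#'   [0, 1], see `max_value`).
#' @param size output edge length (default 224).
#' @param max_value intensity denominator (default 255; use 1 for inputs
#'   already in the unit interval).
#' @return `size` x `size` x 3 array with values in [0, 1].
#' @export
standardize_image <- function(image, size = 224, max_value = 255) {
  if (length(dim(image)) == 2) image <- array(rep(image, 3), c(dim(image), 3))
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3 || d[1] < 1 || d[2] < 1)
    edfm_stop("edfm_invalid_argument", "image must be a non-empty H x W x 3 array")
  h <- d[1]; w <- d[2]
  side <- min(h, w)
  r0 <- (h - side) %/% 2
  c0 <- (w - side) %/% 2
  sq <- image[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), , drop = FALSE]
  out <- EBImage::resize(sq, w = size, h = size, filter = "bilinear")
  out <- out / max_value
  out[out < 0] <- 0
  out[out > 1] <- 1
  array(out, c(size, size, 3))
}

#' Plant-level dataset split
#'
#' Shuffles plant ids with the seed and assigns them to partitions by
#' cumulative fraction with largest-remainder rounding, so every record of a
#' plant lands in exactly one partition (no leakage across partitions).
#'
#' @param plant_ids character or integer vector of unique plant ids.
#' @param ratio three fractions (train, validation, test) summing to 1;
#'   default 6:2:2.
#' @param seed integer seed.
#' @return Object of class `split_assignment`: named character vector
#'   (id -> `"train"`/`"validation"`/`"test"`) with the seed and sizes as
#'   attributes.
#' @export
split_plants <- function(plant_ids, ratio = c(0.6, 0.2, 0.2), seed = 1L) {
  if (anyDuplicated(plant_ids))
    edfm_stop("edfm_invalid_argument", "duplicate plant ids")
  n <- length(plant_ids)
  if (n < 5)
    edfm_stop("edfm_invalid_argument", "need >= 5 plants to split, got %d", n)
  if (abs(sum(ratio) - 1) > 1e-9 || length(ratio) != 3)
    edfm_stop("edfm_invalid_argument", "ratio must be 3 fractions summing to 1")
  # largest-remainder apportionment of n among the three partitions
  quota <- n * ratio
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    ord <- order(quota - sizes, decreasing = TRUE)
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
  }
  shuffled <- with_seed(child_seed(seed, "split"), sample(plant_ids))
  part <- rep(c("train", "validation", "test"), times = sizes)
  out <- stats::setNames(part, shuffled)[as.character(plant_ids)]
  structure(out, sizes = stats::setNames(sizes, c("train", "validation", "test")),
            seed = seed, class = c("split_assignment", class(out)))
}
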