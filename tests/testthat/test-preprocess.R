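test_that("z-score statistics use the population standard deviation", {
  st <- fit_zscore(cbind(a = c(1, 2, 3)))
  expect_equal(unname(st$mu), 2)
  expect_equal(unname(st$sigma), sqrt(2 / 3), tolerance = 1e-4)  # 0.8165
  expect_equal(unname(apply_zscore(cbind(a = 3), st)[1, 1]), 1.2247,
               tolerance = 1e-4)
})

test_that("constant channels are rejected by name", {
  expect_error(fit_zscore(cbind(ok = 1:3, flat = c(2, 2, 2))),
               regexp = "flat", class = "edfm_degenerate_channel")
})

test_that("the z-score transform standardizes train data and is invertible", {
  x <- matrix(stats::rnorm(300, 5, 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  st <- fit_zscore(x)
  z <- apply_zscore(x, st)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(z^2))), rep(1, 3), tolerance = 1e-12)
  expect_equal(invert_zscore(z, st), x, tolerance = 1e-12)
  expect_equal(unname(apply_zscore(rbind(st$mu), st)[1, ]), rep(0, 3))
  expect_equal(unname(apply_zscore(rbind(st$mu + st$sigma), st)[1, ]),
               rep(1, 3))
  expect_error(apply_zscore(x[, 1:2], st), class = "edfm_invalid_argument")
})

test_that("sliding window counts follow floor((n - width)/stride) + 1", {
  expect_length(sliding_windows(1:7, 7), 1)
  expect_length(sliding_windows(1:10, 7, 1), 4)
  expect_warning(w0 <- sliding_windows(1:6, 7), "no windows")
  expect_length(w0, 0)
  w <- sliding_windows(matrix(1:20, ncol = 2), width = 3, stride = 2)
  expect_length(w, 4)
  expect_equal(w[[2]], matrix(1:20, ncol = 2)[3:5, ])
})

test_that("trailing smoothing uses only past samples", {
  x <- c(1, 2, 3, 4, 100)
  expect_equal(smooth_series(x, 3)[3], 2)
  expect_equal(smooth_series(x, 3)[1], 1)            # shorter head window
  expect_equal(smooth_series(x, 3, "median")[5], 4)
  # no future leakage: smoothing at i is unchanged by later values
  expect_equal(smooth_series(x, 3)[1:4], smooth_series(x[1:4], 3))
})

test_that("SOR removes exactly the far outlier from a regular grid", {
  grid <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  cloud <- rbind(grid, c(100, 100, 100))
  res <- sor_filter(cloud, k = 8, std_ratio = 2)
  expect_equal(res$removed, 28L)
  expect_equal(nrow(res$points), 27)
  # no outliers: nothing removed (all neighbour distances equal, sd = 0)
  res2 <- sor_filter(grid, k = 8, std_ratio = 2)
  expect_length(res2$removed, 0)
  expect_error(sor_filter(grid[1:5, ], k = 8), class = "edfm_invalid_argument")
})

test_that("SOR agrees with the brute-force pairwise oracle", {
  for (s in 1:4) {
    set.seed(100 + s)
    n <- sample(50:200, 1)
    cloud <- matrix(stats::rnorm(3 * n), ncol = 3)
    cloud[1:3, ] <- cloud[1:3, ] * 10      # a few gross outliers
    res <- sor_filter(cloud, k = 10, std_ratio = 1.5)
    expect_equal(res$removed, sor_oracle(cloud, 10, 1.5))
  }
})

test_that("voxel downsampling takes centroids of occupied voxels", {
  cloud <- matrix(stats::runif(30, 0, 0.05), ncol = 3)
  one <- voxel_downsample(cloud, 1)
  expect_equal(nrow(one), 1)
  expect_equal(one[1, ], colMeans(cloud), ignore_attr = TRUE)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  out <- voxel_downsample(corners, 0.6)
  expect_equal(nrow(out), 8)
  expect_equal(out[order(out[, 1], out[, 2], out[, 3]), ],
               corners[order(corners[, 1], corners[, 2], corners[, 3]), ],
               ignore_attr = TRUE)
  expect_error(voxel_downsample(corners, 0), class = "edfm_invalid_argument")
})

test_that("voxel downsampling agrees with a hash-map oracle and is monotone", {
  set.seed(7)
  cloud <- matrix(stats::rnorm(3 * 150), ncol = 3)
  for (vs in c(0.3, 0.7, 1.5)) {
    got <- voxel_downsample(cloud, vs)
    got <- got[order(got[, 1], got[, 2], got[, 3]), ]
    exp <- voxel_oracle(cloud, vs)
    exp <- exp[order(exp[, 1], exp[, 2], exp[, 3]), ]
    expect_equal(got, exp, ignore_attr = TRUE)
  }
  counts <- vapply(c(0.1, 0.2, 0.5, 1, 2, 5),
                   function(vs) nrow(voxel_downsample(cloud, vs)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("downsample_to_count reaches the target within tolerance", {
  set.seed(11)
  cloud <- matrix(stats::rnorm(3 * 40000, sd = 0.5), ncol = 3)
  res <- downsample_to_count(cloud, target = 8000)
  expect_gte(res$n, 7600)
  expect_lte(res$n, 8400)
  small <- cloud[1:100, ]
  expect_warning(unch <- downsample_to_count(small, 1000), "unchanged")
  expect_equal(unch$points, small)
})

test_that("image standardization crops, resizes and rescales to [0,1]", {
  img <- array(sample(0:255, 640 * 480 * 3, replace = TRUE), c(480, 640, 3))
  out <- standardize_image(img)
  expect_equal(dim(out), c(224, 224, 3))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(standardize_image(array(255, c(100, 100, 3))),
               array(1, c(224, 224, 3)))
  expect_equal(standardize_image(array(0L, c(224, 224, 3))),
               array(0, c(224, 224, 3)))
  # idempotence on already-standardized rasters
  std <- standardize_image(img)
  again <- standardize_image(std * 255)
  expect_equal(again, std, tolerance = 1e-6)
  expect_error(standardize_image(array(0, c(0, 5, 3))),
               class = "edfm_invalid_argument")
})

test_that("plant-level splits follow largest-remainder 6:2:2 apportionment", {
  sp <- split_plants(paste0("p", 1:10), seed = 3L)
  expect_equal(unname(attr(sp, "sizes")), c(6, 2, 2))
  expect_identical(sp, split_plants(paste0("p", 1:10), seed = 3L))
  expect_setequal(names(sp), paste0("p", 1:10))
  expect_error(split_plants(c("a", "a", "b", "c", "d")),
               class = "edfm_invalid_argument")
  expect_error(split_plants(paste0("p", 1:4)), class = "edfm_invalid_argument")
  # 11 plants: remainder goes to the largest fractional quota (train)
  s11 <- split_plants(paste0("p", 1:11), seed = 1L)
  expect_equal(unname(attr(s11, "sizes")), c(7, 2, 2))
})

test_that("no plant ever appears in two partitions across many seeds", {
  ids <- paste0("plant", 1:23)
  for (s in 1:1000) {
    sp <- split_plants(ids, seed = s)
    expect_equal(sort(names(sp)), sort(ids))
    expect_false(anyNA(sp))
  }
})

test_that("stream alignment enforces the synchronisation tolerance", {
  a <- data.frame(time = c(0, 1, 2), va = 1:3)
  b <- data.frame(time = c(0.04, 0.96, 2.05), vb = 4:6)
  j <- align_streams(a, b, tol = 0.1)
  expect_equal(j$vb, 4:6)
  expect_true(all(j$residual <= 0.1))
  b$time[2] <- 1.5
  expect_error(align_streams(a, b, tol = 0.1), class = "edfm_alignment_error")
})
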