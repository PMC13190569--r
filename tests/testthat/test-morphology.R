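test_that("logistic growth matches its closed forms", {
  gp <- growth_params(Lmax = 1, k = 0.15, PDTm = 40)
  expect_equal(logistic_size(40, gp), 0.5)
  expect_equal(logistic_size(50, gp), 0.8176, tolerance = 1e-4)
  expect_lt(abs(logistic_size(400, gp) - 1), 1e-10)
  pdt <- seq(0, 100, by = 0.5)
  L <- logistic_size(pdt, gp)
  expect_true(all(diff(L) > 0))
  expect_true(all(L > 0 & L < 1))
  # rate is the analytic derivative
  expect_equal(logistic_rate(40, gp), 0.15 / 4, tolerance = 1e-12)
  expect_error(growth_params(-1, 0.15, 40), class = "edfm_invalid_argument")
})

test_that("NURBS evaluation interpolates corners and sums basis to one", {
  surf <- flat_rect_surface()
  expect_equal(eval_surface(surf, 0, 0), surf$control[1, 1, ])
  expect_equal(eval_surface(surf, 1, 1), surf$control[6, 4, ])
  expect_equal(eval_surface(surf, 1, 0), surf$control[6, 1, ])
  # all control points equal c: partition of unity returns c everywhere
  ctrl <- array(rep(c(3, -2, 7), each = 20), c(5, 4, 3))
  cs <- nurbs_surface(ctrl)
  for (uv in list(c(0.3, 0.7), c(0.05, 0.5), c(0.99, 0.01)))
    expect_equal(eval_surface(cs, uv[1], uv[2]), c(3, -2, 7),
                 tolerance = 1e-12)
  expect_error(eval_surface(surf, 1.2, 0), class = "edfm_invalid_argument")
})

test_that("equal-weight NURBS matches an independent B-spline summation oracle", {
  set.seed(44)
  ctrl <- array(stats::rnorm(6 * 4 * 3), c(6, 4, 3))
  surf <- nurbs_surface(ctrl, degree_u = 3, degree_v = 2)
  # direct Cox-de Boor summation, written independently of eval_surface
  cox <- function(u, p, knots, i) {
    if (p == 0)
      return(as.numeric(knots[i] <= u && (u < knots[i + 1] ||
             (u == 1 && knots[i + 1] == 1 && knots[i] < 1))))
    a <- knots[i + p] - knots[i]
    b <- knots[i + p + 1] - knots[i + 1]
    t1 <- if (a > 0) (u - knots[i]) / a * cox(u, p - 1, knots, i) else 0
    t2 <- if (b > 0) (knots[i + p + 1] - u) / b * cox(u, p - 1, knots, i + 1)
          else 0
    t1 + t2
  }
  for (rep in 1:10) {
    u <- stats::runif(1); v <- stats::runif(1)
    want <- c(0, 0, 0)
    for (i in 1:6) for (j in 1:4)
      want <- want + cox(u, 3, surf$knots_u, i) * cox(v, 2, surf$knots_v, j) *
        ctrl[i, j, ]
    expect_equal(eval_surface(surf, u, v), want, tolerance = 1e-10)
  }
})

test_that("surface area quadrature is exact on a flat rectangle and scales", {
  surf <- flat_rect_surface(10, 5)
  expect_equal(surface_area(surf, 16), 50, tolerance = 1e-8)
  ctrl2 <- surf$control * 2
  expect_equal(surface_area(nurbs_surface(ctrl2), 16), 200, tolerance = 1e-7)
})

test_that("quarter-cylinder area converges to pi with quadrature order", {
  patch <- make_cylinder_patch(1, 2, 90)
  expect_equal(surface_area(patch, 16), pi, tolerance = 1e-4)
  errs <- vapply(c(2, 4, 8, 16),
                 function(o) abs(surface_area(patch, o) - pi), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))   # monotone decrease
})

test_that("least-squares fitting is self-consistent and recovers planar area", {
  set.seed(5)
  ctrl <- array(stats::rnorm(24 * 3, sd = 0.3), c(6, 4, 3))
  ctrl[, , 1] <- ctrl[, , 1] + seq(0, 2, length.out = 6)
  surf <- nurbs_surface(ctrl)
  gr <- expand.grid(u = seq(0, 1, length.out = 12),
                    v = seq(0, 1, length.out = 8))
  S <- eval_surface(surf, seq(0, 1, length.out = 12),
                    seq(0, 1, length.out = 8))
  pts <- cbind(as.vector(S[, , 1]), as.vector(S[, , 2]), as.vector(S[, , 3]))
  fit <- fit_leaf_surface(pts, c(6, 4), uv = as.matrix(gr))
  expect_lt(fit$rms_residual, 1e-8)
  expect_equal(fit$surface$control, ctrl, tolerance = 1e-6)
  # planar noiseless leaf: fitted area equals the lamina's polygon area
  s <- seq(0, 1, length.out = 25); w <- seq(0, 1, length.out = 11)
  gr2 <- expand.grid(s = s, w = w)
  lam <- cbind(gr2$s * 0.5,
               (gr2$w * 2 - 1) * 0.05 * sin(pi * gr2$s) / 2, 0)
  fit2 <- fit_leaf_surface(lam, c(6, 4))
  # analytic area of the flat sine-bump lamina: width integral 2/pi * L * W
  analytic <- (2 / pi) * 0.5 * 0.05
  expect_lt(abs(surface_area(fit2$surface) - analytic) / analytic, 0.005)
  expect_error(fit_leaf_surface(lam[1:10, ], c(6, 4)),
               class = "edfm_fit_error")
  # collinear points cannot be parameterized
  line <- cbind(seq(0, 1, length.out = 30), 0, 0)
  expect_error(fit_leaf_surface(line, c(4, 3)), class = "edfm_fit_error")
})

test_that("refitting points sampled from a fitted planar surface is idempotent", {
  s <- seq(0, 1, length.out = 25); w <- seq(0, 1, length.out = 11)
  gr <- expand.grid(s = s, w = w)
  lam <- cbind(gr$s * 0.5, (gr$w - 0.5) * 0.08, 0)
  fit1 <- fit_leaf_surface(lam, c(6, 4), uv = as.matrix(gr))
  S <- eval_surface(fit1$surface, s, w)
  pts <- cbind(as.vector(S[, , 1]), as.vector(S[, , 2]), as.vector(S[, , 3]))
  fit2 <- fit_leaf_surface(pts, c(6, 4), uv = as.matrix(gr))
  expect_equal(fit2$surface$control, fit1$surface$control, tolerance = 1e-6)
})

test_that("organ rescaling hits leaf area and internode length targets", {
  leaf <- make_leaf_surface(0.6, 0.07, 45)
  a0 <- surface_area(leaf)
  same <- scale_organ_to_size(leaf, "leaf", a0)
  expect_equal(surface_area(same), a0, tolerance = 0.005)
  dbl <- scale_organ_to_size(leaf, "leaf", 2 * a0)
  expect_equal(surface_area(dbl), 2 * a0, tolerance = 0.005)
  # linear dimensions scale by sqrt(2)
  ext0 <- apply(matrix(leaf$control, ncol = 3), 2, function(x) diff(range(x)))
  ext2 <- apply(matrix(dbl$control, ncol = 3), 2, function(x) diff(range(x)))
  expect_equal(ext2, sqrt(2) * ext0, tolerance = 0.01)
  cyl <- make_cylinder_patch(0.01, 0.05, 90)
  st <- scale_organ_to_size(cyl, "internode", 0.12)
  expect_equal(diff(range(st$control[, , 3])), 0.12, tolerance = 1e-12)
  expect_error(scale_organ_to_size(leaf, "leaf", -1),
               class = "edfm_invalid_argument")
})

test_that("ray-traced interception reproduces simple geometry and energy bounds", {
  empty <- canopy_scene(list(), 4)
  expect_equal(light_interception(empty, 40, 400)$total, 0)
  # one opaque 1 m2 horizontal leaf over a 4 m2 footprint
  leaf <- list(vertices = rbind(c(-.5, -.5, 1), c(.5, -.5, 1),
                                c(.5, .5, 1), c(-.5, .5, 1)),
               faces = rbind(c(1, 2, 3), c(1, 3, 4)))
  sc <- canopy_scene(list(leaf = leaf), 4, wrap = FALSE)
  li <- light_interception(sc, 40, 10000, seed = 1)
  expect_equal(li$fraction, 0.25, tolerance = 3 * max(li$fraction_se, 1e-3))
  expect_lte(li$total, 40 * 4)
  expect_equal(li$total, li$fraction * 40 * 4, tolerance = 1e-9)
  # determinism under a fixed seed
  expect_identical(li, light_interception(sc, 40, 10000, seed = 1))
  expect_error(light_interception(sc, 40, 50), class = "edfm_invalid_argument")
})

test_that("two stacked leaves shade correctly (first hit wins)", {
  top <- list(vertices = rbind(c(-.5, -.5, 2), c(.5, -.5, 2),
                               c(.5, .5, 2), c(-.5, .5, 2)),
              faces = rbind(c(1, 2, 3), c(1, 3, 4)))
  bottom <- list(vertices = rbind(c(-.5, -.5, 1), c(.5, -.5, 1),
                                  c(.5, .5, 1), c(-.5, .5, 1)),
                 faces = rbind(c(1, 2, 3), c(1, 3, 4)))
  sc <- canopy_scene(list(top = top, bottom = bottom), 4, wrap = FALSE)
  li <- light_interception(sc, 10, 5000, seed = 3)
  expect_gt(li$per_organ[["top"]], 0)
  expect_equal(unname(li$per_organ[["bottom"]]), 0)
})

test_that("Beer-Lambert fraction follows its closed form", {
  expect_equal(beer_lambert_fraction(0, 0.7), 0)
  expect_equal(beer_lambert_fraction(2, 0.5), 0.6321, tolerance = 1e-4)
  lai <- seq(0, 6, by = 0.5)
  expect_true(all(diff(beer_lambert_fraction(lai, 0.7)) > 0))
})

test_that("OBJ export writes valid vertex and face records", {
  m <- triangulate_surface(flat_rect_surface(1, 1), 3, 3)
  f <- tempfile(fileext = ".obj")
  write_obj(list(m, m), f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "v ")), 18)
  expect_equal(sum(startsWith(lines, "f ")), 16)
  # face indices of the second mesh are offset past the first mesh
  last <- as.integer(strsplit(lines[length(lines)], " ")[[1]][-1])
  expect_true(all(last > 9))
  unlink(f)
})
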