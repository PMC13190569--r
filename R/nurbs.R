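#' Clamped uniform knot vector
#'
#' `degree + 1` repeated knots at each end, uniform interior knots, domain
#' [0, 1].
#'
#' @param n_ctrl number of control points (>= degree + 1).
#' @param degree spline degree.
#' @return Numeric knot vector of length `n_ctrl + degree + 1`.
#' @export
clamped_knots <- function(n_ctrl, degree) {
  if (n_ctrl < degree + 1)
    edfm_stop("edfm_invalid_argument",
              "need >= %d control points for degree %d", degree + 1, degree)
  n_int <- n_ctrl - degree - 1
  c(rep(0, degree + 1),
    if (n_int > 0) seq_len(n_int) / (n_int + 1),
    rep(1, degree + 1))
}

# B-spline basis functions N_{i,p}(u) for one u (Cox-de Boor).
# Returns the full vector of n_ctrl = length(knots) - p - 1 values.
bspline_basis_point <- function(u, p, knots) {
  m <- length(knots)
  nb <- m - p - 1
  # degree-0: indicator of the knot span; u at the right end belongs to the
  # last non-empty span
  N <- as.numeric(knots[-m] <= u & u < knots[-1])
  if (u >= knots[m - p]) {
    N[] <- 0
    N[max(which(knots[-m] < knots[-1]))] <- 1
  }
  if (p == 0) return(N[seq_len(nb)])
  for (d in seq_len(p)) {
    len <- m - 1 - d
    Nn <- numeric(len)
    for (i in seq_len(len)) {
      a <- knots[i + d] - knots[i]
      b <- knots[i + d + 1] - knots[i + 1]
      t1 <- if (a > 0) (u - knots[i]) / a * N[i] else 0
      t2 <- if (b > 0) (knots[i + d + 1] - u) / b * N[i + 1] else 0
      Nn[i] <- t1 + t2
    }
    N <- Nn
  }
  N[seq_len(nb)]
}

# basis matrix (length(u) x n_ctrl); deriv = TRUE gives dN/du
bspline_basis <- function(u, p, knots, deriv = FALSE) {
  nb <- length(knots) - p - 1
  if (!deriv) {
    t(vapply(u, bspline_basis_point, numeric(nb), p = p, knots = knots))
  } else {
    t(vapply(u, function(ui) {
      Nl <- bspline_basis_point(ui, p - 1, knots)       # length nb + 1
      d <- numeric(nb)
      for (i in seq_len(nb)) {
        a <- knots[i + p] - knots[i]
        b <- knots[i + p + 1] - knots[i + 1]
        d[i] <- p * ((if (a > 0) Nl[i] / a else 0) -
                       (if (b > 0) Nl[i + 1] / b else 0))
      }
      d
    }, numeric(nb)))
  }
}

#' Construct a NURBS surface
#'
#' Clamped knot vectors are generated automatically; the surface
#' interpolates its corner control points.
#'
#' @param control array `nu x nv x 3` of control-point coordinates.
#' @param weights `nu x nv` positive weights (default all 1, i.e. a
#'   non-rational B-spline surface).
#' @param degree_u,degree_v spline degrees (defaults 3 and 2).
#' @return Object of class `nurbs_surface`.
#' @export
nurbs_surface <- function(control, weights = NULL, degree_u = 3, degree_v = 2) {
  d <- dim(control)
  if (length(d) != 3 || d[3] != 3)
    edfm_stop("edfm_invalid_argument", "control must be nu x nv x 3")
  nu <- d[1]; nv <- d[2]
  if (is.null(weights)) weights <- matrix(1, nu, nv)
  stopifnot(all(dim(weights) == c(nu, nv)), all(weights > 0),
            all(is.finite(control)))
  structure(list(control = control, weights = weights,
                 degree_u = degree_u, degree_v = degree_v,
                 knots_u = clamped_knots(nu, degree_u),
                 knots_v = clamped_knots(nv, degree_v)),
            class = "nurbs_surface")
}

#' Evaluate a NURBS surface
#'
#' Rational de Boor evaluation on the tensor grid `u x v`. With clamped
#' knots the domain corners reproduce the corner control points exactly.
#'
#' @param surface a [nurbs_surface()].
#' @param u,v parameter values in [0, 1] (vectors allowed).
#' @return If both `u` and `v` are scalars, a length-3 point; otherwise an
#'   array `length(u) x length(v) x 3`.
#' @export
eval_surface <- function(surface, u, v) {
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1))
    edfm_stop("edfm_invalid_argument", "u and v must lie in [0, 1]")
  Bu <- bspline_basis(u, surface$degree_u, surface$knots_u)
  Bv <- bspline_basis(v, surface$degree_v, surface$knots_v)
  W <- surface$weights
  den <- Bu %*% W %*% t(Bv)
  out <- array(NA_real_, c(length(u), length(v), 3))
  for (k in 1:3)
    out[, , k] <- (Bu %*% (surface$control[, , k] * W) %*% t(Bv)) / den
  if (length(u) == 1 && length(v) == 1) as.numeric(out[1, 1, ]) else out
}

# surface point and first partials at (u, v) grids; returns list of arrays
eval_surface_derivs <- function(surface, u, v) {
  Bu <- bspline_basis(u, surface$degree_u, surface$knots_u)
  Bv <- bspline_basis(v, surface$degree_v, surface$knots_v)
  Du <- bspline_basis(u, surface$degree_u, surface$knots_u, deriv = TRUE)
  Dv <- bspline_basis(v, surface$degree_v, surface$knots_v, deriv = TRUE)
  W <- surface$weights
  den <- Bu %*% W %*% t(Bv)
  den_u <- Du %*% W %*% t(Bv)
  den_v <- Bu %*% W %*% t(Dv)
  S <- Su <- Sv <- array(NA_real_, c(length(u), length(v), 3))
  for (k in 1:3) {
    PW <- surface$control[, , k] * W
    num <- Bu %*% PW %*% t(Bv)
    num_u <- Du %*% PW %*% t(Bv)
    num_v <- Bu %*% PW %*% t(Dv)
    S[, , k] <- num / den
    Su[, , k] <- (num_u * den - num * den_u) / den^2   # quotient rule
    Sv[, , k] <- (num_v * den - num * den_v) / den^2
  }
  list(S = S, Su = Su, Sv = Sv)
}

#' Surface area by Gauss-Legendre quadrature
#'
#' Integrates `|dS/du x dS/dv|` over the unit parameter square with a
#' composite tensor Gauss-Legendre rule, `order` nodes per knot span and
#' direction (the integrand is only piecewise-smooth across knots, so the
#' rule is applied span by span); the error decreases with the order.
#'
#' @param surface a [nurbs_surface()].
#' @param quadrature_order nodes per knot span and direction (default 16).
#' @return Area in the squared length unit of the control points.
#' @export
surface_area <- function(surface, quadrature_order = 16) {
  span_rule <- function(knots) {
    br <- unique(knots)
    xs <- ws <- numeric(0)
    for (i in seq_len(length(br) - 1)) {
      g <- pracma::gaussLegendre(quadrature_order, br[i], br[i + 1])
      xs <- c(xs, g$x); ws <- c(ws, g$w)
    }
    list(x = xs, w = ws)
  }
  gu <- span_rule(surface$knots_u)
  gv <- span_rule(surface$knots_v)
  d <- eval_surface_derivs(surface, gu$x, gv$x)
  cx <- d$Su[, , 2] * d$Sv[, , 3] - d$Su[, , 3] * d$Sv[, , 2]
  cy <- d$Su[, , 3] * d$Sv[, , 1] - d$Su[, , 1] * d$Sv[, , 3]
  cz <- d$Su[, , 1] * d$Sv[, , 2] - d$Su[, , 2] * d$Sv[, , 1]
  jac <- sqrt(cx^2 + cy^2 + cz^2)
  as.numeric(gu$w %*% jac %*% gv$w)
}

#' Fit a NURBS surface to leaf points by linear least squares
#'
#' Points are parameterized by projection onto the leaf's first two
#' principal axes (normalized to [0, 1]); control points then solve an
#' ordinary least-squares problem with unit weights.
#'
#' @param points N x 3 matrix (N >= `prod(control_grid)`).
#' @param control_grid `(nu, nv)` control-point counts (default `c(6, 4)`).
#' @param degree_u,degree_v spline degrees.
#' @param uv optional N x 2 matrix of known parameters; skips the PCA
#'   parameterization when supplied.
#' @return List with `surface` (a [nurbs_surface()]), `rms_residual` and
#'   the parameterization `uv`.
#' @export
fit_leaf_surface <- function(points, control_grid = c(6, 4),
                             degree_u = 3, degree_v = 2, uv = NULL) {
  points <- as.matrix(points)
  nu <- control_grid[1]; nv <- control_grid[2]
  if (nrow(points) < nu * nv)
    edfm_stop("edfm_fit_error",
              "need >= %d points for a %d x %d control grid, got %d",
              nu * nv, nu, nv, nrow(points))
  if (is.null(uv)) {
    ctr <- colMeans(points)
    pc <- eigen(stats::cov(points), symmetric = TRUE)$vectors
    s1 <- as.numeric(sweep(points, 2, ctr) %*% pc[, 1])
    s2 <- as.numeric(sweep(points, 2, ctr) %*% pc[, 2])
    rng1 <- range(s1); rng2 <- range(s2)
    if (diff(rng1) <= 0 || diff(rng2) <= 0)
      edfm_stop("edfm_fit_error", "degenerate parameterization (collinear points)")
    u <- (s1 - rng1[1]) / diff(rng1)
    # normalize the cross-axis by the local outline width, so a tapered
    # outline (e.g. a leaf narrowing to its tip) still fills the whole
    # parameter square and every control point is constrained by data. The
    # outline envelope is estimated from per-strip extremes and smoothed by
    # a low-order polynomial (kink-free, so the spline can follow it).
    nb <- 16L
    strip <- pmin(nb - 1L, floor(u * nb))
    u_lo <- y_lo <- u_hi <- y_hi <- numeric(0)
    for (b in sort(unique(strip))) {
      m <- which(strip == b)
      i_lo <- m[which.min(s2[m])]
      i_hi <- m[which.max(s2[m])]
      u_lo <- c(u_lo, u[i_lo]); y_lo <- c(y_lo, s2[i_lo])
      u_hi <- c(u_hi, u[i_hi]); y_hi <- c(y_hi, s2[i_hi])
    }
    env_fit <- function(ue, ye) {
      deg <- min(4L, length(ue) - 1L)
      if (deg < 1) return(function(x) rep(ye[1], length(x)))
      cf <- stats::lm(ye ~ stats::poly(ue, deg, raw = TRUE))
      function(x) stats::predict(cf, data.frame(ue = x))
    }
    lo_u <- env_fit(u_lo, y_lo)(u)
    hi_u <- env_fit(u_hi, y_hi)(u)
    wid <- pmax(hi_u - lo_u, 1e-6 * diff(rng2))
    v <- pmin(1, pmax(0, (s2 - lo_u) / wid))
    uv <- cbind(u = u, v = as.numeric(v))
  }
  ku <- clamped_knots(nu, degree_u)
  kv <- clamped_knots(nv, degree_v)
  Bu <- bspline_basis(uv[, 1], degree_u, ku)
  Bv <- bspline_basis(uv[, 2], degree_v, kv)
  A <- Bu[, rep(seq_len(nu), times = nv), drop = FALSE] *
    Bv[, rep(seq_len(nv), each = nu), drop = FALSE]
  qa <- qr(A)
  if (qa$rank < nu * nv)
    edfm_stop("edfm_fit_error",
              "rank-deficient design (%d < %d): points do not cover the domain",
              qa$rank, nu * nv)
  ctrl_flat <- qr.coef(qa, points)
  control <- array(ctrl_flat, c(nu, nv, 3))
  resid <- A %*% ctrl_flat - points
  list(surface = nurbs_surface(control, degree_u = degree_u,
                               degree_v = degree_v),
       rms_residual = sqrt(mean(rowSums(resid^2))),
       uv = uv)
}

#' Parametric maize leaf as a fitted NURBS surface
#'
#' Samples the package's parametric lamina (quadratic midrib arc, sine-bump
#' width profile) on a regular grid and fits the default control net to it.
#'
#' @param length_m nominal midrib length, metres.
#' @param width_m maximum lamina width, metres.
#' @param incl_deg base inclination above horizontal, degrees.
#' @param control_grid `(nu, nv)` control counts.
#' @return A [nurbs_surface()] with the leaf base (attachment) at the origin.
#' @export
make_leaf_surface <- function(length_m, width_m, incl_deg = 45,
                              control_grid = c(6, 4)) {
  s <- seq(0, 1, length.out = 21)
  w <- seq(0, 1, length.out = 9)
  gr <- expand.grid(s = s, w = w)
  pts <- lamina_local(gr$s, gr$w, length_m, width_m, incl_deg)
  fit_leaf_surface(pts, control_grid, uv = cbind(gr$s, gr$w))$surface
}

#' Cylinder patch as a rational NURBS surface
#'
#' Axis along z from 0 to `length`; the cross-section arc is an exact
#' rational quadratic circle segment. A 90-degree patch of radius 1 and
#' length 2 has area pi exactly.
#'
#' @param radius cylinder radius.
#' @param length axial length.
#' @param sweep_deg arc angle in degrees (default 90).
#' @return A [nurbs_surface()] (degree 1 along the axis, 2 around).
#' @export
make_cylinder_patch <- function(radius, length, sweep_deg = 90) {
  stopifnot(sweep_deg > 0, sweep_deg <= 90)
  a <- sweep_deg * pi / 180
  # rational quadratic arc from angle 0 to a
  p0 <- c(radius, 0)
  p2 <- radius * c(cos(a), sin(a))
  p1 <- radius / cos(a / 2) * c(cos(a / 2), sin(a / 2))  # tangent intersection
  w1 <- cos(a / 2)
  control <- array(NA_real_, c(2, 3, 3))
  for (i in 1:2) {
    z <- if (i == 1) 0 else length
    control[i, 1, ] <- c(p0, z)
    control[i, 2, ] <- c(p1, z)
    control[i, 3, ] <- c(p2, z)
  }
  weights <- rbind(c(1, w1, 1), c(1, w1, 1))
  nurbs_surface(control, weights, degree_u = 1, degree_v = 2)
}

#' Rescale an organ surface to a target size
#'
#' Leaves are scaled uniformly about the organ base until the surface area
#' matches the target (the scale factor is solved on the 1-D area equation;
#' since uniform scaling is affine the solution `s = sqrt(target / area)` is
#' verified and refined by root finding only if needed). Internodes are
#' scaled axially so the z-extent equals the target exactly.
#'
#' @param surface a [nurbs_surface()].
#' @param organ_type `"leaf"` or `"internode"`.
#' @param target target area (cm2 -> use consistent units with the control
#'   points) for leaves, axial length for internodes.
#' @param base 3-point about which to scale; defaults to the first control
#'   point (the attachment).
#' @param tol relative tolerance on the achieved size (default 0.005).
#' @return The rescaled [nurbs_surface()].
#' @export
scale_organ_to_size <- function(surface, organ_type = c("leaf", "internode"),
                                target, base = NULL, tol = 0.005) {
  organ_type <- match.arg(organ_type)
  if (target <= 0)
    edfm_stop("edfm_invalid_argument", "target size must be positive")
  if (is.null(base)) base <- surface$control[1, 1, ]
  ctrl <- surface$control
  if (organ_type == "internode") {
    zext <- diff(range(ctrl[, , 3]))
    if (zext <= 0) edfm_stop("edfm_invalid_argument", "degenerate axial extent")
    f <- target / zext
    ctrl[, , 3] <- base[3] + (ctrl[, , 3] - base[3]) * f
  } else {
    a0 <- surface_area(surface)
    s <- sqrt(target / a0)         # exact under uniform affine scaling
    scale_by <- function(s) {
      c2 <- ctrl
      for (k in 1:3) c2[, , k] <- base[k] + (c2[, , k] - base[k]) * s
      c2
    }
    achieved <- a0 * s^2
    if (abs(achieved - target) > tol * target) {
      g <- function(sc) surface_area(nurbs_surface(scale_by(sc),
                                                   surface$weights,
                                                   surface$degree_u,
                                                   surface$degree_v)) - target
      s <- stats::uniroot(g, c(s / 2, s * 2), tol = 1e-10)$root
    }
    ctrl <- scale_by(s)
  }
  nurbs_surface(ctrl, surface$weights, surface$degree_u, surface$degree_v)
}

#' Triangulate a NURBS surface
#'
#' @param surface a [nurbs_surface()].
#' @param n_u,n_v sample counts per direction (default 8 x 6).
#' @return List with `vertices` (V x 3) and `faces` (F x 3 vertex indices).
#' @export
triangulate_surface <- function(surface, n_u = 8, n_v = 6) {
  u <- seq(0, 1, length.out = n_u)
  v <- seq(0, 1, length.out = n_v)
  S <- eval_surface(surface, u, v)
  verts <- matrix(NA_real_, n_u * n_v, 3)
  for (k in 1:3) verts[, k] <- as.vector(S[, , k])   # u fastest
  id <- function(i, j) (j - 1) * n_u + i
  faces <- list()
  for (j in seq_len(n_v - 1)) for (i in seq_len(n_u - 1)) {
    faces[[length(faces) + 1]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    faces[[length(faces) + 1]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Export triangle meshes as Wavefront OBJ
#'
#' @param meshes list of `triangulate_surface()` meshes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(meshes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  offset <- 0L
  for (m in meshes) {
    apply(m$vertices, 1, function(v)
      writeLines(sprintf("v %.6f %.6f %.6f", v[1], v[2], v[3]), con))
    apply(m$faces, 1, function(f)
      writeLines(paste("f", paste(f + offset, collapse = " ")), con))
    offset <- offset + nrow(m$vertices)
  }
  invisible(path)
}
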