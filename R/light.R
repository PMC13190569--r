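#' Assemble a canopy scene for light-capture computation
#'
#' The scene is a set of triangle meshes (one per organ) over a square
#' ground footprint centred on the origin. With `wrap = TRUE` the canopy is
#' treated as periodic in x and y (triangles are replicated into the eight
#' neighbouring footprint tiles), which emulates shading by neighbouring
#' plants in a uniform stand.
#'
#' @param meshes named list of `triangulate_surface()` meshes (names become
#'   organ ids).
#' @param footprint_area ground area per plant, m2.
#' @param wrap logical, periodic canopy (default TRUE).
#' @return Object of class `canopy_scene`.
#' @export
canopy_scene <- function(meshes, footprint_area, wrap = TRUE) {
  stopifnot(footprint_area > 0)
  if (length(meshes) > 0 && is.null(names(meshes)))
    names(meshes) <- paste0("organ_", seq_along(meshes))
  structure(list(meshes = meshes, footprint_area = footprint_area,
                 wrap = wrap), class = "canopy_scene")
}

# triangles of a scene as one matrix: columns x1,y1,z1,x2,y2,z2,x3,y3,z3 + organ
scene_triangles <- function(scene) {
  tri <- list(); org <- list()
  for (nm in names(scene$meshes)) {
    m <- scene$meshes[[nm]]
    v <- m$vertices; f <- m$faces
    tri[[length(tri) + 1]] <- cbind(v[f[, 1], , drop = FALSE],
                                    v[f[, 2], , drop = FALSE],
                                    v[f[, 3], , drop = FALSE])
    org[[length(org) + 1]] <- rep(nm, nrow(f))
  }
  if (length(tri) == 0) return(list(tri = matrix(0, 0, 9), organ = character()))
  list(tri = do.call(rbind, tri), organ = unlist(org))
}

#' Ray-traced canopy light interception
#'
#' Casts vertical rays downward on a jittered grid over the footprint; the
#' highest intersected triangle's organ absorbs the ray's PAR share (organs
#' are opaque, single-scattering absorbers). Reports per-organ intercepted
#' PAR, the canopy interception fraction and its Monte-Carlo standard error
#' (binomial bound, conservative for jittered-grid sampling).
#'
#' @param scene a [canopy_scene()].
#' @param par_above incident PAR above the canopy, mol m-2 d-1.
#' @param n_rays number of rays (>= 100).
#' @param seed integer seed for the jitter.
#' @return List: `per_organ` (named, mol d-1), `total` (mol d-1),
#'   `fraction`, `fraction_se`, `n_rays`.
#' @export
light_interception <- function(scene, par_above, n_rays = 2000, seed = 1L) {
  stopifnot(inherits(scene, "canopy_scene"), par_above >= 0)
  if (n_rays < 100)
    edfm_stop("edfm_invalid_argument", "need n_rays >= 100, got %d", n_rays)
  st <- scene_triangles(scene)
  organs <- unique(st$organ)
  zero <- list(per_organ = stats::setNames(numeric(length(organs)), organs),
               total = 0, fraction = 0, fraction_se = 0, n_rays = n_rays)
  if (nrow(st$tri) == 0) return(zero)

  side <- sqrt(scene$footprint_area)
  m <- ceiling(sqrt(n_rays))
  n_rays <- m * m                      # jittered grid: one ray per cell
  cell <- side / m
  jit <- with_seed(child_seed(seed, "rays"),
                   matrix(stats::runif(2 * n_rays), ncol = 2))
  gx <- rep(seq_len(m) - 1, times = m)
  gy <- rep(seq_len(m) - 1, each = m)
  rx <- -side / 2 + (gx + jit[, 1]) * cell
  ry <- -side / 2 + (gy + jit[, 2]) * cell

  hit_z <- rep(-Inf, n_rays)
  hit_org <- rep(NA_character_, n_rays)
  offsets <- if (scene$wrap) as.matrix(expand.grid(ox = -1:1, oy = -1:1)) * side
             else matrix(0, 1, 2)

  for (tr in seq_len(nrow(st$tri))) {
    t9 <- st$tri[tr, ]
    ax0 <- t9[1]; ay0 <- t9[2]; az <- t9[3]
    bx0 <- t9[4]; by0 <- t9[5]; bz <- t9[6]
    cx0 <- t9[7]; cy0 <- t9[8]; cz <- t9[9]
    for (o in seq_len(nrow(offsets))) {
      ax <- ax0 + offsets[o, 1]; bx <- bx0 + offsets[o, 1]; cx <- cx0 + offsets[o, 1]
      ay <- ay0 + offsets[o, 2]; by <- by0 + offsets[o, 2]; cy <- cy0 + offsets[o, 2]
      xmin <- min(ax, bx, cx); xmax <- max(ax, bx, cx)
      ymin <- min(ay, by, cy); ymax <- max(ay, by, cy)
      if (xmax < -side / 2 || xmin > side / 2 ||
          ymax < -side / 2 || ymin > side / 2) next
      # candidate rays from the grid cells under the triangle's xy bbox
      i0 <- max(0L, floor((xmin + side / 2) / cell) - 1L)
      i1 <- min(m - 1L, ceiling((xmax + side / 2) / cell))
      j0 <- max(0L, floor((ymin + side / 2) / cell) - 1L)
      j1 <- min(m - 1L, ceiling((ymax + side / 2) / cell))
      if (i1 < i0 || j1 < j0) next
      cand <- as.vector(outer(i0:i1 + 1L, (j0:j1) * m, "+"))
      px <- rx[cand]; py <- ry[cand]
      # 2-D barycentric point-in-triangle test
      d <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
      if (abs(d) < 1e-14) next
      l1 <- ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / d
      l2 <- ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / d
      l3 <- 1 - l1 - l2
      inside <- l1 >= 0 & l2 >= 0 & l3 >= 0
      if (!any(inside)) next
      zhit <- l1[inside] * az + l2[inside] * bz + l3[inside] * cz
      ci <- cand[inside]
      upd <- zhit > hit_z[ci]
      hit_z[ci[upd]] <- zhit[upd]
      hit_org[ci[upd]] <- st$organ[tr]
    }
  }

  ray_par <- par_above * scene$footprint_area / n_rays   # mol/day per ray
  hits <- !is.na(hit_org)
  per_organ <- stats::setNames(numeric(length(organs)), organs)
  if (any(hits)) {
    tab <- table(hit_org[hits])
    per_organ[names(tab)] <- as.numeric(tab) * ray_par
  }
  p <- mean(hits)
  list(per_organ = per_organ, total = sum(per_organ), fraction = p,
       fraction_se = sqrt(p * (1 - p) / n_rays), n_rays = n_rays)
}

#' Beer-Lambert canopy interception fraction
#'
#' `1 - exp(-k * LAI)`: the closed-form interception of a homogeneous
#' canopy, used as the analytic cross-check for the ray tracer (extinction
#' coefficient k = 1 for horizontal leaves under a vertical beam).
#'
#' @param lai leaf area index (>= 0).
#' @param extinction_k extinction coefficient (default 0.7).
#' @return Fraction of incident light intercepted.
#' @export
beer_lambert_fraction <- function(lai, extinction_k = 0.7) {
  stopifnot(all(lai >= 0))
  1 - exp(-extinction_k * lai)
}
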