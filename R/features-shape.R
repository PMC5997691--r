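# Shape (morphology) features.
#
# Surface area comes from a triangulated isosurface of the binary mask at
# level 0.5, built by marching tetrahedra: each grid cell between 8 voxel
# centers is split into 6 tetrahedra sharing the main diagonal; since corner
# values are binary, every edge crossing sits at the edge midpoint, so the
# triangle geometry per (tetrahedron, sign pattern) is constant across cells
# and the total area reduces to a case count times a precomputed area table.
# Convexity compares the foreground voxel count against the voxel count of
# the digitized convex hull (incremental quickhull of foreground voxel
# centers), which guarantees convexity <= 1 with equality, up to
# digitization, for convex digital shapes.

# Corner offsets of the unit cell, x fastest.
.cube_corners <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

# Six tetrahedra around the v0-v6 diagonal (1-based corner indices).
.cube_tets <- rbind(
  c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

tri_area <- function(a, b, c) {
  u <- b - a
  v <- c - a
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  0.5 * sqrt(sum(w^2))
}

# Area contributed by one tetrahedron (physical corner coords `P`, 4x3) for
# one inside/outside sign pattern; crossings at edge midpoints.
tet_case_area <- function(P, inside) {
  n_in <- sum(inside)
  if (n_in == 0 || n_in == 4) return(0)
  if (n_in == 1 || n_in == 3) {
    apex <- if (n_in == 1) which(inside) else which(!inside)
    others <- setdiff(1:4, apex)
    m <- lapply(others, function(o) (P[apex, ] + P[o, ]) / 2)
    return(tri_area(m[[1]], m[[2]], m[[3]]))
  }
  ins <- which(inside)
  outs <- which(!inside)
  # quad vertices: midpoints of the 4 in-out edges, ordered around the quad
  q <- list((P[ins[1], ] + P[outs[1], ]) / 2,
            (P[ins[1], ] + P[outs[2], ]) / 2,
            (P[ins[2], ] + P[outs[2], ]) / 2,
            (P[ins[2], ] + P[outs[1], ]) / 2)
  tri_area(q[[1]], q[[2]], q[[3]]) + tri_area(q[[1]], q[[3]], q[[4]])
}

# Precompute the 6 x 16 table of per-case areas for a given spacing.
tet_area_table <- function(spacing) {
  tab <- matrix(0, nrow = 6, ncol = 16)
  corners <- sweep(.cube_corners, 2, spacing, `*`)
  for (t in 1:6) {
    P <- corners[.cube_tets[t, ], , drop = FALSE]
    for (case in 0:15) {
      inside <- as.logical(bitwAnd(case, c(1L, 2L, 4L, 8L)) > 0)
      tab[t, case + 1L] <- tet_case_area(P, inside)
    }
  }
  tab
}

#' Triangulated isosurface area of a binary mask
#'
#' Marching-tetrahedra surface area (mm^2) of the 0.5-isosurface of the
#' mask, with the grid padded by one background layer so the surface is
#' closed.
#'
#' @param mask an [roi_mask()].
#' @return Surface area in mm^2.
#' @export
surface_area_mesh <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sp <- mask$spacing
  d <- dim(mask$voxels)
  m <- array(0L, d + 2L)
  m[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask$voxels
  dd <- dim(m)
  nx <- dd[1] - 1L; ny <- dd[2] - 1L; nz <- dd[3] - 1L
  base <- as.vector(outer(outer(seq_len(nx), (seq_len(ny) - 1L) * dd[1], `+`),
                          (seq_len(nz) - 1L) * dd[1] * dd[2], `+`))
  off <- .cube_corners %*% c(1L, dd[1], dd[1] * dd[2])
  vals <- matrix(0L, nrow = length(base), ncol = 8)
  for (cc in 1:8) vals[, cc] <- m[base + off[cc]]
  tab <- tet_area_table(sp)
  area <- 0
  for (t in 1:6) {
    v <- vals[, .cube_tets[t, ], drop = FALSE]
    case <- v %*% c(1L, 2L, 4L, 8L)
    cnt <- tabulate(case + 1L, nbins = 16L)
    area <- area + sum(cnt * tab[t, ])
  }
  area
}

# ---- 3D convex hull (incremental quickhull, matrix face storage) ---------

#' Incremental 3D convex hull
#'
#' Quickhull-style incremental construction. Faces are stored as outward
#' normals and offsets, so point-in-hull tests are a matrix product.
#'
#' @param pts numeric matrix, one point per row (3 columns).
#' @return A list with `normals` (F x 3), `offsets` (length F), `tris`
#'   (F x 3 vertex indices), `volume`, and `degenerate` (TRUE when the
#'   points do not span 3D, in which case the other fields are NULL/NA).
#' @export
quickhull3d <- function(pts) {
  pts <- unname(unique(as.matrix(pts)))
  n <- nrow(pts)
  degenerate <- list(normals = NULL, offsets = NULL, tris = NULL,
                     volume = NA_real_, degenerate = TRUE)
  if (is.null(n) || n < 4) return(degenerate)
  scale <- max(apply(pts, 2, function(z) diff(range(z))), 1e-12)
  eps <- 1e-9 * scale
  # initial simplex: farthest pair among axis extremes, then line, then plane
  ext <- unique(as.vector(vapply(1:3, function(j)
    c(which.min(pts[, j]), which.max(pts[, j])), integer(2))))
  best <- ext[1:2]; bd <- -1
  for (i in ext) for (j in ext) if (i < j) {
    dd <- sum((pts[i, ] - pts[j, ])^2)
    if (dd > bd) { bd <- dd; best <- c(i, j) }
  }
  i1 <- best[1]; i2 <- best[2]
  ab <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * ab[3] - rel[, 3] * ab[2],
              rel[, 3] * ab[1] - rel[, 1] * ab[3],
              rel[, 1] * ab[2] - rel[, 2] * ab[1])
  dline <- sqrt(rowSums(cr^2))
  i3 <- which.max(dline)
  if (dline[i3] < eps) return(degenerate)
  u <- pts[i2, ] - pts[i1, ]
  v <- pts[i3, ] - pts[i1, ]
  nrm <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  dplane <- abs(drop(pts %*% nrm) - sum(nrm * pts[i1, ]))
  i4 <- which.max(dplane)
  if (dplane[i4] < eps) return(degenerate)
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])

  face_geom <- function(tri) {
    a <- pts[tri[1], ]; b <- pts[tri[2], ]; c_ <- pts[tri[3], ]
    u <- b - a; v <- c_ - a
    nn <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    len <- sqrt(sum(nn^2))
    if (len < 1e-14 * scale^2) return(NULL)
    nn <- nn / len
    if (sum(nn * (interior - a)) > 0) nn <- -nn
    list(normal = nn, offset = sum(nn * a))
  }

  tris <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  geo <- lapply(seq_len(4), function(f) face_geom(tris[f, ]))
  normals <- do.call(rbind, lapply(geo, `[[`, "normal"))
  offsets <- vapply(geo, `[[`, numeric(1), "offset")

  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    dists <- drop(normals %*% pts[p, ]) - offsets
    vis <- which(dists > eps)
    if (length(vis) == 0) next
    vt <- tris[vis, , drop = FALSE]
    ea <- c(vt[, 1], vt[, 2], vt[, 3])
    eb <- c(vt[, 2], vt[, 3], vt[, 1])
    e1 <- pmin(ea, eb)
    e2 <- pmax(ea, eb)
    key <- e1 * (n + 1) + e2
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    horizon <- cbind(e1, e2)[!dup, , drop = FALSE]
    tris <- tris[-vis, , drop = FALSE]
    normals <- normals[-vis, , drop = FALSE]
    offsets <- offsets[-vis]
    for (e in seq_len(nrow(horizon))) {
      tri <- c(horizon[e, 1], horizon[e, 2], p)
      g <- face_geom(tri)
      if (is.null(g)) next
      tris <- rbind(tris, tri)
      normals <- rbind(normals, g$normal)
      offsets <- c(offsets, g$offset)
    }
  }
  a <- pts[tris[, 1], , drop = FALSE] - matrix(interior, nrow(tris), 3, byrow = TRUE)
  b <- pts[tris[, 2], , drop = FALSE] - matrix(interior, nrow(tris), 3, byrow = TRUE)
  c_ <- pts[tris[, 3], , drop = FALSE] - matrix(interior, nrow(tris), 3, byrow = TRUE)
  det <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
         a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
         a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  list(normals = normals, offsets = offsets, tris = tris,
       volume = sum(abs(det)) / 6, degenerate = FALSE)
}

#' Volume of the 3D convex hull of a point set
#'
#' @param pts numeric matrix, one point per row (3 columns).
#' @return Hull volume, or `NA_real_` if the points do not span 3D.
#' @export
convex_hull_volume <- function(pts) {
  quickhull3d(pts)$volume
}

# Count grid voxel centers inside the hull, column by column: within each
# (y, z) grid column the hull intersection is an x-interval obtained from
# the face half-space constraints, so the digitized hull volume reduces to
# an interval length per column.
digitized_hull_count <- function(hull, lo, hi, sp, tol = 1e-7) {
  nrm <- hull$normals
  scale <- max(abs(hull$offsets), 1)
  thr <- hull$offsets + tol * scale
  ys <- (lo[2]:hi[2] - 1) * sp[2]
  zs <- (lo[3]:hi[3] - 1) * sp[3]
  cols <- expand.grid(y = ys, z = zs)
  rhs <- matrix(thr, nrow = nrow(nrm), ncol = nrow(cols)) -
    nrm[, 2] %o% cols$y - nrm[, 3] %o% cols$z
  nx <- nrm[, 1]
  eps <- 1e-12
  pos <- nx > eps
  neg <- nx < -eps
  zer <- !pos & !neg
  upper <- if (any(pos)) apply(rhs[pos, , drop = FALSE] / nx[pos], 2, min) else Inf
  lower <- if (any(neg)) apply(rhs[neg, , drop = FALSE] / nx[neg], 2, max) else -Inf
  feas <- if (any(zer)) colSums(rhs[zer, , drop = FALSE] < 0) == 0 else TRUE
  i_hi <- pmin(floor(upper / sp[1] + 1 + 1e-9), hi[1])
  i_lo <- pmax(ceiling(lower / sp[1] + 1 - 1e-9), lo[1])
  cnt <- pmax(i_hi - i_lo + 1, 0)
  sum(cnt[feas & is.finite(cnt)])
}

# Which of `query` lie inside (or on) the hull.
points_in_hull <- function(hull, query, tol = 1e-7) {
  stopifnot(!hull$degenerate)
  scale <- max(abs(hull$offsets), 1)
  inside <- rep(TRUE, nrow(query))
  thr <- hull$offsets + tol * scale
  chunk <- 4096L
  for (s in seq(1L, nrow(query), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(query))
    d <- hull$normals %*% t(query[s:e, , drop = FALSE])
    inside[s:e] <- colSums(d > thr) == 0
  }
  inside
}

# Boundary foreground voxels: those with a 6-neighbor background (or edge).
boundary_voxels <- function(vox) {
  d <- dim(vox)
  m <- array(0L, d + 2L)
  m[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- vox
  core <- m[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  nb <- m[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] +
        m[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] +
        m[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] +
        m[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] +
        m[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] +
        m[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  which(core > 0 & nb < 6, arr.ind = TRUE)
}

# Keep only points that can be hull vertices: per-axis column extremes.
hull_candidate_points <- function(pts) {
  keep <- rep(FALSE, nrow(pts))
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    key <- paste(pts[, others[1]], pts[, others[2]])
    ord <- order(key, pts[, ax])
    r <- rle(key[ord])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep[ord[starts]] <- TRUE
    keep[ord[ends]] <- TRUE
  }
  pts[keep, , drop = FALSE]
}

max_pair_distance <- function(pts) {
  n <- nrow(pts)
  best <- 0
  chunk <- 256L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(pts^2), `+`) - 2 * block %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Shape features (10)
#'
#' Morphological features of the ROI: volume, triangulated surface area,
#' surface-to-volume ratio, compactness `V / (sqrt(pi) * A^1.5)`, sphericity
#' `pi^(1/3) * (6V)^(2/3) / A`, convexity `V / V_hull` with the hull volume
#' digitized on the voxel grid, maximum 3D diameter
#' (farthest foreground-voxel pair, mm), elongation `sqrt(lambda2 / lambda1)`
#' of the voxel-coordinate covariance, density (mean HU + 1000) and mass
#' (volume times density). Degenerate (planar or linear) masks yield
#' missing-with-reason convexity and elongation.
#'
#' @param mask an [roi_mask()] with at least 27 foreground voxels.
#' @param image the aligned [image_volume()].
#' @return A list with `values` (named numeric, 10 entries) and `reasons`.
#' @export
shape_features <- function(mask, image) {
  stopifnot(inherits(mask, "roi_mask"), inherits(image, "image_volume"))
  check_alignment(image, mask)
  vox <- mask$voxels
  sp <- mask$spacing
  N <- sum(vox)
  if (N < 27) stopf("too-small ROI: %d foreground voxels (< 27)", N)
  volume <- N * prod(sp)
  area <- surface_area_mesh(mask)
  idx <- which(vox > 0, arr.ind = TRUE)
  centers <- sweep(idx - 1, 2, sp, `*`)
  reasons <- character(0)

  bidx <- boundary_voxels(vox)
  bcent <- unname(sweep(bidx - 1, 2, sp, `*`))
  # convexity on the grid: hull of foreground voxel centers, digitized back
  # to the grid by counting the voxel centers it contains; N_hull >= N so
  # convexity <= 1, with equality (up to digitization) for convex shapes
  hull <- quickhull3d(hull_candidate_points(bcent))
  if (hull$degenerate) {
    convexity <- NA_real_
    reasons["convexity"] <- "degenerate mask: convex hull does not span 3D"
  } else {
    lo <- apply(bidx, 2, min)
    hi <- apply(bidx, 2, max)
    n_hull <- digitized_hull_count(hull, lo, hi, sp)
    convexity <- N / max(n_hull, N)
  }

  maxdiam <- max_pair_distance(bcent)
  cv <- stats::cov(centers)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  elong <- if (ev[1] <= 1e-12) NA_real_ else sqrt(max(ev[2], 0) / ev[1])
  if (is.na(elong)) reasons["elongation"] <- "degenerate mask: zero principal variance"

  dens <- mean(image$voxels[vox > 0]) + 1000
  values <- c(
    volume = volume,
    surface_area = area,
    surface_to_volume = area / volume,
    compactness = volume / (sqrt(pi) * area^1.5),
    sphericity = pi^(1 / 3) * (6 * volume)^(2 / 3) / area,
    convexity = convexity,
    max_3d_diameter = maxdiam,
    elongation = elong,
    density = dens,
    mass = volume * dens
  )
  list(values = values, reasons = reasons)
}
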