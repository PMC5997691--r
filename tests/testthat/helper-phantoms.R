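# Phantom builders and independent brute-force oracles used across tests.
# Oracles deliberately use naive nested-loop / flood-fill implementations,
# independent of the package's vectorized code paths.

make_sphere_mask <- function(r, side = 2 * r + 5, spacing = c(1, 1, 1)) {
  ctr <- (side + 1) / 2
  x <- seq_len(side) - ctr
  a <- outer(outer(x^2, x^2, `+`), x^2, `+`) <= r^2
  roi_mask(array(as.integer(a), dim = rep(side, 3)), spacing = spacing)
}

# Digital ball with an exact foreground count: the n grid points closest to
# the center (ties broken by linear index).
make_ball_exact_n <- function(n, side = 21, spacing = c(1, 1, 1)) {
  ctr <- (side + 1) / 2
  x <- seq_len(side) - ctr
  d2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  ord <- order(as.vector(d2), seq_along(d2))
  a <- array(0L, dim = rep(side, 3))
  a[ord[seq_len(n)]] <- 1L
  roi_mask(a, spacing = spacing)
}

flat_image <- function(mask, value = 0) {
  image_volume(array(value, dim = dim(mask$voxels)), spacing = mask$spacing)
}

random_phantom <- function(side = 8, seed = 1, n_levels = NULL) {
  set.seed(seed)
  vox <- array(stats::rnorm(side^3, 0, 50), dim = rep(side, 3))
  if (!is.null(n_levels)) vox <- array(sample(seq_len(n_levels), side^3, TRUE) * 10,
                                       dim = rep(side, 3))
  msk <- array(as.integer(stats::runif(side^3) > 0.3), dim = rep(side, 3))
  if (sum(msk) < 2) msk[1:2] <- 1L
  list(image = image_volume(vox), mask = roi_mask(msk))
}

# All 26 neighbor offsets; canonical 13 with first nonzero component > 0.
oracle_offsets <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    v <- c(dx, dy, dz)
    nz <- v[v != 0]
    if (nz[1] > 0) out[[length(out) + 1L]] <- v
  }
  out
}

oracle_discretize <- function(vals, levels) {
  mn <- min(vals); mx <- max(vals)
  if (mx == mn) return(rep(1L, length(vals)))
  b <- floor((vals - mn) / (mx - mn) * levels) + 1
  as.integer(pmin(b, levels))
}

# Brute-force GLCM: nested loops over every foreground voxel and neighbor.
oracle_glcm <- function(image, mask, levels = 256L) {
  vox <- image$voxels
  fg <- mask$voxels > 0
  lev <- array(NA_integer_, dim = dim(vox))
  lev[fg] <- oracle_discretize(vox[fg], levels)
  d <- dim(vox)
  acc <- matrix(0, levels, levels)
  used <- 0L
  for (off in oracle_offsets()) {
    M <- matrix(0, levels, levels)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!fg[x, y, z]) next
      xx <- x + off[1]; yy <- y + off[2]; zz <- z + off[3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
      if (!fg[xx, yy, zz]) next
      a <- lev[x, y, z]; b <- lev[xx, yy, zz]
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
    if (sum(M) > 0) {
      acc <- acc + M / sum(M)
      used <- used + 1L
    }
  }
  acc / used
}

# Brute-force size-zone matrix via explicit flood fill (26-connectivity).
oracle_iszm <- function(image, mask, levels = 32L) {
  vox <- image$voxels
  fg <- mask$voxels > 0
  lev <- array(NA_integer_, dim = dim(vox))
  lev[fg] <- oracle_discretize(vox[fg], levels)
  d <- dim(vox)
  seen <- array(FALSE, dim = d)
  zones <- data.frame(level = integer(0), size = integer(0))
  idx <- which(fg, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    g <- lev[p0[1], p0[2], p0[3]]
    stack <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (any(q < 1) || any(q > d)) next
        if (!fg[q[1], q[2], q[3]] || seen[q[1], q[2], q[3]]) next
        if (lev[q[1], q[2], q[3]] != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1L]] <- q
      }
    }
    zones <- rbind(zones, data.frame(level = g, size = size))
  }
  P <- matrix(0L, nrow = levels, ncol = max(zones$size))
  for (r in seq_len(nrow(zones)))
    P[zones$level[r], zones$size[r]] <- P[zones$level[r], zones$size[r]] + 1L
  list(matrix = P, n_zones = nrow(zones))
}

# Brute-force spacing-aware distance to nearest background voxel.
oracle_distance <- function(mask) {
  vox <- mask$voxels
  sp <- mask$spacing
  fgi <- which(vox > 0, arr.ind = TRUE)
  bgi <- which(vox == 0, arr.ind = TRUE)
  fgp <- sweep(fgi, 2, sp, `*`)
  bgp <- sweep(bgi, 2, sp, `*`)
  apply(fgp, 1, function(p) sqrt(min(colSums((t(bgp) - p)^2))))
}

# Class-wise (two-sample) delete-one jackknife variance of an AUC.
oracle_jackknife_auc_var <- function(p, y) {
  th <- pooled_roc_auc(p, y)
  ip <- which(y == 1)
  ineg <- which(y == 0)
  m <- length(ip); nn <- length(ineg)
  pvp <- vapply(ip, function(i) m * th - (m - 1) * pooled_roc_auc(p[-i], y[-i]), numeric(1))
  pvn <- vapply(ineg, function(i) nn * th - (nn - 1) * pooled_roc_auc(p[-i], y[-i]), numeric(1))
  stats::var(pvp) / m + stats::var(pvn) / nn
}

# Hand-built risk-table log-rank statistic for two groups.
oracle_logrank <- function(times, events, group) {
  group <- as.integer(factor(group))
  ut <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

make_lesion <- function(patient = "P1", id = "L1", type = "primary", size = 30,
                        image = NULL, mask = NULL) {
  lesion_record(patient, id, type, size, image = image, mask = mask)
}
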