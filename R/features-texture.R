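# Texture features: gray-level co-occurrence matrix (GLCM) and intensity
# size-zone (ISZ / GLSZM) features.

# The 13 unique 3D offsets at Chebyshev distance 1 (26-neighborhood modulo
# sign): canonical representative has its first nonzero component positive.
glcm_offsets <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- apply(offs, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  as.matrix(offs[keep, , drop = FALSE])
}

# Co-occurrence counts for one offset; `g` is the discretized level array
# with NA outside the ROI.
offset_ranges <- function(d, off) {
  lo <- pmax(1, 1 - off)
  hi <- pmin(d, d - off)
  if (any(lo > hi)) return(NULL)
  list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
}

glcm_count_one <- function(g, off, levels) {
  d <- dim(g)
  rg <- offset_ranges(d, off)
  if (is.null(rg)) return(NULL)
  x1 <- rg$x; y1 <- rg$y; z1 <- rg$z
  a <- g[x1, y1, z1, drop = FALSE]
  b <- g[x1 + off[1], y1 + off[2], z1 + off[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  counts <- tabulate((a[ok] - 1L) * levels + b[ok], nbins = levels * levels)
  matrix(counts, nrow = levels, ncol = levels, byrow = TRUE)
}

#' Gray-level co-occurrence matrix averaged over 13 directions
#'
#' ROI intensities are discretized to 256 fixed-width bins over the ROI's own
#' intensity range. For each of the 13 unique distance-1 offsets of the
#' 26-neighborhood, co-occurrences between foreground voxel pairs are
#' accumulated, symmetrized and normalized to sum 1; the returned matrix is
#' the element-wise average of the per-direction normalized matrices
#' (directions without any valid pair cannot be normalized and are skipped;
#' it is an error if no direction has a pair).
#'
#' @param image an [image_volume()].
#' @param mask the aligned [roi_mask()].
#' @param levels number of gray levels (default 256).
#' @return A `levels x levels` matrix of class `glcm`, symmetric with unit
#'   sum, with attributes `n_directions` (13) and `n_directions_used`.
#' @export
glcm_matrix <- function(image, mask, levels = 256L) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  check_alignment(image, mask)
  fg <- mask$voxels > 0
  vals <- image$voxels[fg]
  if (length(vals) < 2) stopf("need at least 2 foreground voxels")
  g <- array(NA_integer_, dim = dim(image$voxels))
  g[fg] <- discretize_intensities(vals, levels)
  offs <- glcm_offsets()
  acc <- matrix(0, levels, levels)
  used <- 0L
  for (k in seq_len(nrow(offs))) {
    cnt <- glcm_count_one(g, offs[k, ], levels)
    if (is.null(cnt)) next
    sym <- cnt + t(cnt)
    acc <- acc + sym / sum(sym)
    used <- used + 1L
  }
  if (used == 0L) stopf("empty GLCM: no valid voxel pair in any direction")
  out <- acc / used
  structure(out, class = c("glcm", "matrix"),
            n_directions = nrow(offs), n_directions_used = used,
            levels = levels)
}

#' GLCM features (11)
#'
#' Features of a normalized symmetric co-occurrence matrix; `i`, `j` are
#' 1-based bin labels. `0 * log(0)` is taken as 0; for a degenerate matrix
#' with zero marginal variance the correlation is reported as 1 (its limit).
#'
#' @param G a matrix from [glcm_matrix()] (normalized, symmetric).
#' @return Named numeric vector of 11 features, names prefixed `glcm_`.
#' @export
glcm_features <- function(G) {
  p <- unclass(G)
  attributes(p) <- list(dim = dim(G))
  L <- nrow(p)
  i <- seq_len(L)
  px <- rowSums(p)
  mu <- sum(i * px)
  sigma2 <- sum((i - mu)^2 * px)
  I <- matrix(i, L, L)
  J <- t(I)
  A <- abs(I - J)
  S <- I + J
  autoc <- sum(I * J * p)
  correlation <- if (sigma2 <= .Machine$double.eps) 1 else (autoc - mu^2) / sigma2
  pos <- p > 0
  c(glcm_autocorrelation = autoc,
    glcm_contrast = sum((I - J)^2 * p),
    glcm_correlation = correlation,
    glcm_dissimilarity = sum(A * p),
    glcm_energy = sum(p^2),
    glcm_entropy = -sum(p[pos] * log2(p[pos])),
    glcm_homogeneity = sum(p / (1 + A)),
    glcm_cluster_shade = sum((S - 2 * mu)^3 * p),
    glcm_cluster_prominence = sum((S - 2 * mu)^4 * p),
    glcm_sum_average = sum(S * p),
    glcm_variance = sigma2)
}

#' Intensity size-zone matrix
#'
#' ROI intensities are discretized to 32 fixed-width bins over the ROI's own
#' range; zones are 26-connected components of equal discretized level within
#' the ROI. Entry `P[g, s]` counts zones of gray level `g` and size `s`
#' voxels.
#'
#' @inheritParams glcm_matrix
#' @param levels number of gray levels (default 32).
#' @return An object of class `iszm`: list with `matrix` (`levels x S_max`
#'   integer counts), `n_zones`, `zone_levels`, `zone_sizes`.
#' @export
iszm_matrix <- function(image, mask, levels = 32L) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  check_alignment(image, mask)
  fg_lin <- which(mask$voxels > 0)
  if (length(fg_lin) < 1) stopf("empty ROI")
  vals <- image$voxels[fg_lin]
  lev <- discretize_intensities(vals, levels)
  d <- dim(mask$voxels)
  g <- array(NA_integer_, dim = d)
  g[fg_lin] <- lev
  vid <- array(NA_integer_, dim = d)
  vid[fg_lin] <- seq_along(fg_lin)
  offs <- glcm_offsets()
  edge_from <- integer(0)
  edge_to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    off <- offs[k, ]
    rg <- offset_ranges(d, off)
    if (is.null(rg)) next
    x1 <- rg$x; y1 <- rg$y; z1 <- rg$z
    a <- g[x1, y1, z1, drop = FALSE]
    b <- g[x1 + off[1], y1 + off[2], z1 + off[3], drop = FALSE]
    ia <- vid[x1, y1, z1, drop = FALSE]
    ib <- vid[x1 + off[1], y1 + off[2], z1 + off[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (any(ok)) {
      edge_from <- c(edge_from, ia[ok])
      edge_to <- c(edge_to, ib[ok])
    }
  }
  gr <- igraph::make_empty_graph(n = length(fg_lin), directed = FALSE)
  if (length(edge_from))
    gr <- igraph::add_edges(gr, rbind(edge_from, edge_to))
  comp <- igraph::components(gr)
  zone_sizes <- as.integer(comp$csize)
  zone_levels <- lev[match(seq_len(comp$no), comp$membership)]
  smax <- max(zone_sizes)
  P <- matrix(0L, nrow = levels, ncol = smax)
  for (z in seq_len(comp$no))
    P[zone_levels[z], zone_sizes[z]] <- P[zone_levels[z], zone_sizes[z]] + 1L
  structure(list(matrix = P, n_zones = comp$no,
                 zone_levels = zone_levels, zone_sizes = zone_sizes,
                 levels = levels),
            class = "iszm")
}

#' Intensity size-zone features (2)
#'
#' Intensity variability (gray-level non-uniformity of zones) and size-zone
#' variability (zone-size non-uniformity):
#' `IV = sum_g (sum_s P[g,s])^2 / Nz`, `SZV = sum_s (sum_g P[g,s])^2 / Nz`.
#'
#' @param Z an [iszm_matrix()] result, or an `image`/`mask` pair via `...`.
#' @return Named numeric vector with `intensity_variability` and
#'   `size_zone_variability`.
#' @export
iszm_features <- function(Z) {
  stopifnot(inherits(Z, "iszm"))
  P <- Z$matrix
  nz <- Z$n_zones
  c(intensity_variability = sum(rowSums(P)^2) / nz,
    size_zone_variability = sum(colSums(P)^2) / nz)
}
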