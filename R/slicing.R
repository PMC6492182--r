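#' Long axis of an LV surface pair
#'
#' Principal-component analysis of the endocardial vertex cloud: the dominant
#' principal direction is taken as the long axis `e_z`. The sign is fixed
#' deterministically by pointing `+z` towards the wider (basal) end, i.e. the
#' half of the cloud with the larger mean distance from the axis. For a
#' perfect sphere the direction is arbitrary but the operation succeeds.
#'
#' @param pair a [surface_pair()].
#' @return list with `axis` (unit vector) and `centroid` (mm).
#' @export
long_axis <- function(pair) {
  v <- pair$endo$vertices
  if (nrow(v) < 4) stop("degenerate vertex cloud")
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] < 1e-9) stop("degenerate vertex cloud")
  ax <- pc$rotation[, 1]
  ctr <- colMeans(v)
  rel <- sweep(v, 2, ctr)
  z <- drop(rel %*% ax)
  perp <- sqrt(pmax(rowSums(rel^2) - z^2, 0))
  if (mean(perp[z > 0]) < mean(perp[z <= 0])) ax <- -ax
  list(axis = as.numeric(ax), centroid = as.numeric(ctr))
}

# Moeller-Trumbore: first positive intersection of one ray with a triangle
# soup. tri is a list(v0, e1, e2) of m x 3 matrices. Returns the distance and
# the (unnormalized) facet normal of the hit triangle.
.ray_first_hit <- function(origin, dir, tri, eps = 1e-9) {
  pvec <- cbind(dir[2] * tri$e2[, 3] - dir[3] * tri$e2[, 2],
                dir[3] * tri$e2[, 1] - dir[1] * tri$e2[, 3],
                dir[1] * tri$e2[, 2] - dir[2] * tri$e2[, 1])
  det <- rowSums(tri$e1 * pvec)
  ok <- abs(det) > eps
  tvec <- sweep(tri$v0, 2, origin, `-`) * -1
  u <- rowSums(tvec * pvec) / det
  ok <- ok & u >= -1e-9 & u <= 1 + 1e-9
  qvec <- cbind(tvec[, 2] * tri$e1[, 3] - tvec[, 3] * tri$e1[, 2],
                tvec[, 3] * tri$e1[, 1] - tvec[, 1] * tri$e1[, 3],
                tvec[, 1] * tri$e1[, 2] - tvec[, 2] * tri$e1[, 1])
  v <- (qvec[, 1] * dir[1] + qvec[, 2] * dir[2] + qvec[, 3] * dir[3]) / det
  ok <- ok & v >= -1e-9 & (u + v) <= 1 + 1e-9
  tt <- rowSums(tri$e2 * qvec) / det
  ok <- ok & tt > eps
  if (!any(ok)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
  k <- which(ok)[which.min(tt[ok])]
  n <- cross3(tri$e1[k, ], tri$e2[k, ])
  c(tt[k], n)
}

.tri_soup <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  v0 <- v[f[, 1], , drop = FALSE]
  list(v0 = v0,
       e1 = v[f[, 2], , drop = FALSE] - v0,
       e2 = v[f[, 3], , drop = FALSE] - v0)
}

#' Short-axis slicing and radial sampling of an LV surface pair
#'
#' Reproduces the automated short-axis analysis workflow: the pair is
#' decomposed into slices of about `slice_width` mm perpendicular to the long
#' axis; slice centers are anchored symmetrically around the mean axial
#' coordinate of the endocardium. In each slice plane, `N = 360 / dphi` rays
#' are cast from the axis point outward; the first intersections with the
#' endocardial and epicardial surfaces give the inner radius `r_ij`, outer
#' radius `R_ij` and wall width `h_ij = R_ij - r_ij`. Slices in which any ray
#' misses either surface (grazing near apex or base) are dropped and listed
#' in the result.
#'
#' The in-plane azimuthal reference direction is anchored to the endocardial
#' vertex farthest from the axis (first index on ties), which makes the whole
#' construction equivariant under rigid motions of the pair: rotating and
#' translating both meshes rotates the sampled rays with them, so the slice
#' radii are bitwise invariant up to floating round-off.
#'
#' @param pair a [surface_pair()].
#' @param slice_width slice thickness (mm), default 8 (short-axis
#'   imaging-like out-of-plane resolution).
#' @param dphi angular sampling (degrees), default 9 (N = 40 rays).
#' @param axis optional precomputed [long_axis()] result.
#' @param max_incidence maximal ray-to-surface-normal incidence angle
#'   (degrees); a slice is dropped when any of its rays strikes either
#'   surface more obliquely (grazing hits near the apex/base caps).
#' @return object of class `slice_set`: per-slice matrices `r`, `R`, `h`
#'   (kept slices x N), slice centers `z` (mm, kept, relative to the
#'   centroid), `dropped` (centers of dropped slices), the axis, and
#'   per-slice means `r_bar_i`, `h_bar_i`.
#' @export
slice_and_sample <- function(pair, slice_width = 8, dphi = 9, axis = NULL,
                             max_incidence = 75) {
  if (is.null(axis)) axis <- long_axis(pair)
  ez <- axis$axis; ctr <- axis$centroid
  # covariant in-plane basis: anchor to the farthest-from-axis endo vertex
  rel <- sweep(pair$endo$vertices, 2, ctr)
  zc <- drop(rel %*% ez)
  perp <- rel - outer(zc, ez)
  # tie-stable anchor: among vertices within round-off of the maximal
  # perpendicular distance, take the largest index (vertex order is
  # preserved by rigid motion, so the choice is motion-invariant even for
  # symmetric meshes with exactly tied candidates)
  p2 <- rowSums(perp^2)
  anchor <- perp[max(which(p2 >= max(p2) * (1 - 1e-9))), ]
  ex <- anchor - sum(anchor * ez) * ez
  ex <- ex / sqrt(sum(ex^2))
  ey <- cross3(ez, ex)
  zlo <- min(zc); zhi <- max(zc)
  # guard the slice count against round-off when the extent is an exact
  # multiple of the slice width
  M <- max(1L, floor((zhi - zlo) / slice_width + 1e-9))
  z_ctr <- mean(range(zc))
  centers <- z_ctr + (seq_len(M) - (M + 1) / 2) * slice_width
  N <- round(360 / dphi)
  phis <- (seq_len(N) - 1) * 2 * pi / N
  dirs <- cbind(cos(phis), sin(phis)) %*% rbind(ex, ey)
  endo_tri <- .tri_soup(pair$endo)
  epi_tri <- .tri_soup(pair$epi)
  cos_min <- cos(max_incidence * pi / 180)
  r_m <- R_m <- matrix(NA_real_, M, N)
  grazing <- logical(M)
  for (i in seq_len(M)) {
    origin <- ctr + centers[i] * ez
    for (j in seq_len(N)) {
      hit_in <- .ray_first_hit(origin, dirs[j, ], endo_tri)
      hit_out <- .ray_first_hit(origin, dirs[j, ], epi_tri)
      r_m[i, j] <- hit_in[1]
      R_m[i, j] <- hit_out[1]
      for (hit in list(hit_in, hit_out)) {
        if (is.finite(hit[1])) {
          n <- hit[2:4] / sqrt(sum(hit[2:4]^2))
          if (abs(sum(n * dirs[j, ])) < cos_min) grazing[i] <- TRUE
        }
      }
    }
  }
  valid <- apply(r_m, 1, function(x) all(is.finite(x))) &
    apply(R_m, 1, function(x) all(is.finite(x))) &
    apply(R_m - r_m, 1, function(x) all(x > 0 | is.na(x))) &
    !grazing
  if (!any(valid)) stop("geometry error: no valid slices")
  ss <- structure(list(
    axis = ez, centroid = ctr, z = centers[valid],
    dropped = centers[!valid], dphi = dphi, slice_width = slice_width,
    r = r_m[valid, , drop = FALSE], R = R_m[valid, , drop = FALSE],
    h = (R_m - r_m)[valid, , drop = FALSE]),
    class = "slice_set")
  ss$r_bar_i <- rowMeans(ss$r)
  ss$h_bar_i <- rowMeans(ss$h)
  ss
}

#' Multislice mean radius and wall width
#'
#' Arithmetic means: per slice over the `N` polar samples, then over the `M`
#' kept slices.
#'
#' @param ss a `slice_set` from [slice_and_sample()].
#' @return named vector `c(r_bar, h_bar)` in mm.
#' @export
slice_means <- function(ss) {
  stopifnot(inherits(ss, "slice_set"), nrow(ss$r) >= 1)
  c(r_bar = mean(rowMeans(ss$r)), h_bar = mean(rowMeans(ss$h)))
}
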