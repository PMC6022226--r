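# Geometry-dependent descriptor machinery: principal-axis alignment,
# dipole components, Shrake-Rupley solvent-accessible surface area, and
# the shadow projection family.  All of these depend on the molecular
# orientation convention, which is fixed here once: principal axes of the
# mass-weighted inertia tensor, smallest moment (longest extent) on x,
# largest on z, axis signs chosen by the third-moment rule below.

#' Align a molecule to its principal inertia axes
#'
#' Translates the mass-weighted centroid to the origin and rotates the
#' principal axes of the mass-weighted inertia tensor onto x, y, z, with
#' the axis of smallest moment (the longest molecular extent) on x and the
#' largest on z.  Axis signs are fixed deterministically: x and y are
#' oriented so that the third moment of the atom coordinates along each is
#' >= 0 (ties broken toward the first atom's positive side), and z
#' completes a right-handed frame (det = +1).  Exactly degenerate
#' eigenvalues keep the symmetric-eigendecomposition order (a stable
#' index-based tie-break).
#'
#' @param mol a `qsar_molecule` with coordinates.
#' @return the molecule with rotated coordinates; the transform is stored
#'   in fields `align_rotation` (3x3, rows = axes) and `align_center`.
#' @export
inertial_align <- function(mol) {
  X <- coords_matrix(mol)
  m <- mol$atoms$mass
  ctr <- colSums(X * m) / sum(m)
  Xc <- sweep(X, 2, ctr)
  if (nrow(X) == 1) {
    R <- diag(3)
  } else {
    I3 <- matrix(0, 3, 3)
    for (k in seq_len(nrow(Xc))) {
      r <- Xc[k, ]
      I3 <- I3 + m[k] * (sum(r^2) * diag(3) - tcrossprod(r))
    }
    e <- eigen(I3, symmetric = TRUE)   # eigenvalues in decreasing order
    # smallest inertia moment -> x, largest -> z
    R <- t(e$vectors[, c(3, 2, 1)])
    for (ax in 1:2) {
      proj <- drop(Xc %*% R[ax, ])
      s3 <- sum((proj - mean(proj))^3)
      flip <- if (abs(s3) > 1e-8) s3 < 0 else proj[1] < 0
      if (flip) R[ax, ] <- -R[ax, ]
    }
    R[3, ] <- pracma_cross(R[1, ], R[2, ])
  }
  Y <- Xc %*% t(R)
  mol$atoms$x <- Y[, 1]; mol$atoms$y <- Y[, 2]; mol$atoms$z <- Y[, 3]
  mol$align_rotation <- R
  mol$align_center <- ctr
  mol
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# 1 e*Angstrom in Debye
E_ANGSTROM_TO_DEBYE <- 4.80320

#' Dipole moment components and magnitude
#'
#' Point-charge dipole mu = sum(q_i r_i) from the partial charges and the
#' inertially aligned coordinates, converted at 1 e*Angstrom = 4.80320 D.
#' Components are reported in the aligned frame, so their signs follow the
#' alignment sign convention; the magnitude is frame-invariant.
#'
#' @param mol an aligned `qsar_molecule` with partial charges.
#' @return named vector `Dipole_X`, `Dipole_Y`, `Dipole_Z`, `Dipole_mag`
#'   (Debye).
#' @export
dipole_descriptors <- function(mol) {
  if (!has_charges(mol)) stop("molecule has no partial charges")
  X <- coords_matrix(mol)
  mu <- colSums(X * mol$atoms$partial_charge) * E_ANGSTROM_TO_DEBYE
  c(Dipole_X = mu[[1]], Dipole_Y = mu[[2]], Dipole_Z = mu[[3]],
    Dipole_mag = sqrt(sum(mu^2)))
}

# deterministic Fibonacci sphere of n unit vectors
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area by deterministic spherical point sampling on
#' each atom's solvent-expanded sphere (van der Waals radius plus probe):
#' a sample point is accessible if it lies outside every other atom's
#' expanded sphere.
#'
#' @param mol a `qsar_molecule` with coordinates.
#' @param probe_radius probe sphere radius in Angstrom (water: 1.4).
#' @param n_points sample points per atom (>= 32).
#' @return numeric vector of per-atom areas (Angstrom^2) with attributes
#'   `probe_radius` and `n_points`; `sum()` of it is the total SASA.
#' @export
sasa <- function(mol, probe_radius = 1.4, n_points = 960) {
  if (n_points < 32) stop("n_points below the accuracy floor (32)")
  X <- coords_matrix(mol)
  R <- mol$atoms$vdw_radius + probe_radius
  n <- nrow(X)
  sph <- fibonacci_sphere(n_points)
  areas <- numeric(n)
  d2 <- as.matrix(stats::dist(X))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    pts <- sweep(sph * R[i], 2, X[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (pts[acc, 1] - X[j, 1])^2 + (pts[acc, 2] - X[j, 2])^2 +
             (pts[acc, 3] - X[j, 3])^2
      acc[acc] <- dj2 >= R[j]^2
    }
    areas[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  attr(areas, "probe_radius") <- probe_radius
  attr(areas, "n_points") <- n_points
  areas
}

#' Shadow (projection) descriptors
#'
#' Projects each atom's van der Waals disc onto the xy, yz and xz planes
#' of the aligned frame and measures the rasterized union area, the
#' molecular extents (coordinate +/- vdW radius) along each axis, and the
#' area fractions of the enclosing rectangles.
#'
#' @param mol an inertially aligned `qsar_molecule`.
#' @param grid_step rasterization step in Angstrom.
#' @return named vector `Shadow_XY`, `Shadow_YZ`, `Shadow_XZ` (Angstrom^2),
#'   `Shadow_Xlength`, `Shadow_Ylength`, `Shadow_Zlength` (Angstrom),
#'   `Shadow_XYfrac`, `Shadow_YZfrac`, `Shadow_XZfrac`.
#' @export
shadow_descriptors <- function(mol, grid_step = 0.1) {
  if (grid_step <= 0) stop("grid_step must be positive")
  X <- coords_matrix(mol)
  r <- mol$atoms$vdw_radius
  ext <- vapply(1:3, function(a)
    diff(range(X[, a] - r, X[, a] + r)), 0)
  proj_area <- function(a, b) {
    lo_a <- min(X[, a] - r); lo_b <- min(X[, b] - r)
    na <- ceiling((max(X[, a] + r) - lo_a) / grid_step)
    nb <- ceiling((max(X[, b] + r) - lo_b) / grid_step)
    covered <- matrix(FALSE, na, nb)
    ga <- lo_a + (seq_len(na) - 0.5) * grid_step
    gb <- lo_b + (seq_len(nb) - 0.5) * grid_step
    for (i in seq_len(nrow(X))) {
      ia <- which(abs(ga - X[i, a]) <= r[i])
      ib <- which(abs(gb - X[i, b]) <= r[i])
      if (!length(ia) || !length(ib)) next
      da2 <- (ga[ia] - X[i, a])^2
      db2 <- (gb[ib] - X[i, b])^2
      covered[ia, ib] <- covered[ia, ib] |
        (outer(da2, db2, `+`) <= r[i]^2)
    }
    sum(covered) * grid_step^2
  }
  a_xy <- proj_area(1, 2); a_yz <- proj_area(2, 3); a_xz <- proj_area(1, 3)
  c(Shadow_XY = a_xy, Shadow_YZ = a_yz, Shadow_XZ = a_xz,
    Shadow_Xlength = ext[1], Shadow_Ylength = ext[2],
    Shadow_Zlength = ext[3],
    Shadow_XYfrac = a_xy / (ext[1] * ext[2]),
    Shadow_YZfrac = a_yz / (ext[2] * ext[3]),
    Shadow_XZfrac = a_xz / (ext[1] * ext[3]))
}
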