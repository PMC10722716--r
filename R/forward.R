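#' Cubic-grid source space inside the model brain
#'
#' Regular grid of source voxels inside the brain sphere of a concentric-spheres
#' head model. The grid is centred on the origin (so it is mirror-symmetric),
#' with points kept strictly inside `max_radius_mm`. The atlas used by the
#' reference tomography has 6239 cortical voxels at 5-mm spacing; here the
#' voxel count is configurable through the spacing and radius so that test
#' problems stay small.
#'
#' @param spacing_mm Grid step in mm.
#' @param max_radius_mm Maximum source eccentricity in mm (must be strictly
#'   inside the brain sphere of the head model; default 78 against a brain
#'   radius of 87).
#' @return A `source_space` list with `voxel_coords` (Nv x 3 matrix, mm),
#'   `n_voxels`, `spacing_mm`.
#' @export
source_space_grid <- function(spacing_mm = 20, max_radius_mm = 78) {
  g <- seq(-max_radius_mm, max_radius_mm, by = spacing_mm)
  g <- g - mean(range(g))   # centre the grid so it is symmetric about 0
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  keep <- sqrt(rowSums(pts^2)) <= max_radius_mm
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2) stop("source space must contain at least 2 voxels")
  rownames(pts) <- NULL
  structure(list(voxel_coords = pts, n_voxels = nrow(pts),
                 spacing_mm = spacing_mm, max_radius_mm = max_radius_mm),
            class = "source_space")
}

#' Three-concentric-spheres head model
#'
#' Brain, skull and scalp modelled as concentric spheres with conductivity
#' ratio 1 : 1/80 : 1; sources are radial current dipoles. Radii follow the
#' common 0.87 / 0.92 / 1.00 relative convention scaled to a 100-mm scalp.
#'
#' @param radii_mm Radii of brain, skull and scalp spheres (ascending, mm).
#' @param conductivities Conductivities of the three shells (relative units).
#' @return A `head_model` list.
#' @export
head_model_spheres <- function(radii_mm = c(87, 92, 100),
                               conductivities = c(1, 1 / 80, 1)) {
  stopifnot(length(radii_mm) == 3, all(diff(radii_mm) > 0),
            length(conductivities) == 3, all(conductivities > 0))
  structure(list(radii_mm = radii_mm, conductivities = conductivities),
            class = "head_model")
}

# Per-harmonic scalp coefficients for a unit radial dipole at eccentricity b.
# Solves the 5-unknown boundary-value system (secondary field in the brain,
# full field in skull and scalp, insulating outer boundary) for each Legendre
# order n. Returns g_n such that V(gamma) = sum_n g_n P_n(cos gamma).
sphere_harmonic_coefs <- function(b, hm, n_max) {
  # work in scalp-radius units: keeps r^n and r^-(n+1) terms of comparable
  # magnitude so the per-order linear systems stay well conditioned
  R <- hm$radii_mm[3]
  b <- b / R
  r1 <- hm$radii_mm[1] / R; r2 <- hm$radii_mm[2] / R; r3 <- 1
  s1 <- hm$conductivities[1]; s2 <- hm$conductivities[2]
  s3 <- hm$conductivities[3]
  g <- numeric(n_max)
  for (n in seq_len(n_max)) {
    cn <- n * b^(n - 1) / (4 * pi * s1)
    # unknowns: A1, A2, B2, A3, B3
    A <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # V continuity at r1
    A[1, ] <- c(r1^n, -r1^n, -r1^-(n + 1), 0, 0)
    rhs[1] <- -cn * r1^-(n + 1)
    # sigma dV/dr continuity at r1
    A[2, ] <- c(s1 * n * r1^(n - 1), -s2 * n * r1^(n - 1),
                s2 * (n + 1) * r1^-(n + 2), 0, 0)
    rhs[2] <- s1 * (n + 1) * cn * r1^-(n + 2)
    # V continuity at r2
    A[3, ] <- c(0, r2^n, r2^-(n + 1), -r2^n, -r2^-(n + 1))
    # sigma dV/dr continuity at r2
    A[4, ] <- c(0, s2 * n * r2^(n - 1), -s2 * (n + 1) * r2^-(n + 2),
                -s3 * n * r2^(n - 1), s3 * (n + 1) * r2^-(n + 2))
    # insulating scalp boundary at r3
    A[5, ] <- c(0, 0, 0, n * r3^(n - 1), -(n + 1) * r3^-(n + 2))
    sol <- solve(A, rhs)
    g[n] <- sol[4] * r3^n + sol[5] * r3^-(n + 1)
  }
  g
}

# Legendre polynomials P_1..P_n at x, by recurrence; returns n x length(x)
legendre_upto <- function(n_max, x) {
  P <- matrix(0, n_max, length(x))
  p0 <- rep(1, length(x)); p1 <- x
  P[1, ] <- p1
  if (n_max >= 2) for (n in 2:n_max) {
    p2 <- ((2 * n - 1) * x * p1 - (n - 1) * p0) / n
    P[n, ] <- p2
    p0 <- p1; p1 <- p2
  }
  P
}

#' Lead field for radial sources in the spherical head model
#'
#' Analytic series solution for the scalp potential of unit radial current
#' dipoles at each source voxel, evaluated at the montage's electrodes
#' (projected onto the scalp sphere) and average-referenced column-wise.
#' The radial direction of a source at the exact centre of the head is
#' undefined; by convention its lead-field column is zero.
#'
#' @param montage An [montage_1020()] montage.
#' @param source_space A [source_space_grid()].
#' @param head_model A [head_model_spheres()].
#' @param n_terms Number of Legendre terms in the series (default 80).
#' @return A `lead_field` list with `K` (channels x Nv matrix), plus the
#'   montage, source space and head model used.
#' @export
build_forward <- function(montage, source_space,
                          head_model = head_model_spheres(), n_terms = 80) {
  stopifnot(inherits(montage, "eeg_montage"),
            inherits(source_space, "source_space"))
  hm <- head_model
  pts <- source_space$voxel_coords
  ecc <- sqrt(rowSums(pts^2))
  if (any(ecc >= hm$radii_mm[1]))
    stop("source voxels must lie strictly inside the brain sphere (radius ",
         hm$radii_mm[1], " mm)")
  elec <- montage$positions            # unit vectors -> scalp sphere
  ne <- nrow(elec); nv <- nrow(pts)
  K <- matrix(0, ne, nv)
  for (v in seq_len(nv)) {
    b <- ecc[v]
    if (b < 1e-9) next                 # centre source: radial direction undefined
    g <- sphere_harmonic_coefs(b, hm, n_terms)
    u <- pts[v, ] / b
    cosg <- pmin(1, pmax(-1, as.numeric(elec %*% u)))
    P <- legendre_upto(n_terms, cosg)
    K[, v] <- as.numeric(g %*% P)
  }
  K <- sweep(K, 2, colMeans(K), "-")   # average-reference the columns
  rownames(K) <- montage$channel_names
  structure(list(K = K, montage = montage, source_space = source_space,
                 head_model = hm),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat("<lead_field> ", nrow(x$K), " ch x ", ncol(x$K), " voxels\n", sep = "")
  invisible(x)
}
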