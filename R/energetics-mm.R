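#' Molecular-mechanics cross interaction energy
#'
#' Electrostatic and Lennard-Jones energy between two disjoint atom groups:
#' \code{elec = 332.0637 * sum q_i q_j / (eps * r_ij)} and
#' \code{vdW = sum eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)} with
#' Lorentz-Berthelot combination (\code{rmin_ij = rmin2_i + rmin2_j},
#' \code{eps_ij = sqrt(eps_i eps_j)}). No distance cutoff: this is the
#' post-processing (rescoring) convention.
#'
#' @param xyz atoms x 3 coordinates for one frame.
#' @param structure a \code{param_structure} supplying charges and LJ
#'   parameters.
#' @param groupA,groupB disjoint atom index sets.
#' @param dielectric interior dielectric constant (default 1).
#' @param exclude optional data.frame of atom index pairs (i, j) to skip
#'   (e.g. bonded and 1-3 pairs).
#' @return list with \code{elec} and \code{vdw} (kcal/mol).
#' @export
mm_interaction_energy <- function(xyz, structure, groupA, groupB,
                                  dielectric = 1, exclude = NULL) {
  if (length(intersect(groupA, groupB)) > 0)
    .fail("groups must be disjoint")
  a <- structure$atoms
  r <- .cross_dist(xyz[groupA, , drop = FALSE], xyz[groupB, , drop = FALSE])
  keep <- matrix(TRUE, length(groupA), length(groupB))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (k in seq_len(nrow(exclude))) {
      ia <- match(exclude$i[k], groupA); jb <- match(exclude$j[k], groupB)
      if (!is.na(ia) && !is.na(jb)) keep[ia, jb] <- FALSE
      ia <- match(exclude$j[k], groupA); jb <- match(exclude$i[k], groupB)
      if (!is.na(ia) && !is.na(jb)) keep[ia, jb] <- FALSE
    }
  }
  if (any(r[keep] < 1e-6)) {
    w <- which(r < 1e-6 & keep, arr.ind = TRUE)[1, ]
    .fail("atoms %d and %d overlap (r < 1e-6 A)",
          groupA[w[1]], groupB[w[2]])
  }
  qq <- outer(a$charge[groupA], a$charge[groupB])
  elec <- .const$coulomb * sum((qq / (dielectric * r))[keep])
  rmin <- outer(a$rmin2[groupA], a$rmin2[groupB], "+")
  epsij <- sqrt(outer(a$eps[groupA], a$eps[groupB]))
  sr6 <- (rmin / r)^6
  vdw <- sum((epsij * (sr6^2 - 2 * sr6))[keep])
  list(elec = elec, vdw = vdw)
}

# deterministic golden-spiral points on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA: each atom's accessible sphere (radius + probe) is
#' sampled with a deterministic golden-spiral point set; a point is exposed
#' when it lies outside every other atom's accessible sphere.
#'
#' @param xyz atoms x 3 coordinates.
#' @param radii atomic (vdW) radii, Angstrom.
#' @param probe water probe radius (default 1.4 Angstrom).
#' @param n_points sphere sample points per atom.
#' @return numeric vector of per-atom SASA (Angstrom^2); sum for the total.
#' @export
shrake_rupley_sasa <- function(xyz, radii, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  rr <- radii + probe
  out <- numeric(n)
  d <- if (n > 1) as.matrix(dist(xyz)) else matrix(0, 1, 1)
  for (i in seq_len(n)) {
    nb <- if (n > 1) which(d[i, ] < rr[i] + rr & seq_len(n) != i) else integer(0)
    sp <- pts * rr[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(sp, 2, xyz[j, ])^2)
      exposed <- exposed & dj2 >= rr[j]^2
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * rr[i]^2 * mean(exposed)
  }
  out
}

#' Generalized-Born + surface-area solvation energy
#'
#' Polar term by Still's pairwise GB formula including self terms
#' (\code{f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))}, double sum
#' over all ordered atom pairs), which reduces to the Born ion formula for
#' an isolated charge. Nonpolar term = gamma * SASA (Shrake-Rupley).
#'
#' @param xyz atoms x 3 coordinates.
#' @param structure a \code{param_structure} (charges, Born radii, radii).
#' @param group atom indices scored.
#' @param eps_solvent solvent dielectric (default 78.5).
#' @param probe water probe radius (default 1.4 Angstrom).
#' @param gamma surface tension constant, kcal/(mol A^2) (default 0.0072).
#' @param n_points SASA sphere samples per atom.
#' @return list with \code{polar}, \code{nonpolar} (kcal/mol) and
#'   \code{sasa} (A^2); \code{polar_pairs} carries the symmetric per-pair
#'   polar matrix for decomposition.
#' @export
solvation_energy <- function(xyz, structure, group,
                             eps_solvent = 78.5, probe = 1.4,
                             gamma = 0.0072, n_points = 960) {
  a <- structure$atoms
  R <- a$born[group]
  if (any(R <= 0)) .fail("nonpositive Born radius for atom %d",
                         group[which(R <= 0)[1]])
  q <- a$charge[group]
  x <- xyz[group, , drop = FALSE]
  r2 <- as.matrix(dist(x))^2
  RR <- outer(R, R)
  f <- sqrt(r2 + RR * exp(-r2 / (4 * RR)))
  fac <- .const$gb * (1 - 1 / eps_solvent)
  pairs <- -fac * outer(q, q) / f
  polar <- sum(pairs)
  sasa <- shrake_rupley_sasa(x, a$radius[group], probe, n_points)
  list(polar = polar, nonpolar = gamma * sum(sasa), sasa = sum(sasa),
       sasa_atoms = sasa, polar_pairs = pairs)
}
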