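#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the atoms: each atom is covered with a
#' deterministic quasi-uniform mesh of test points on its solvent-accessible
#' sphere (radius = van der Waals radius + probe) and the accessible area is
#' the fraction of points not buried inside any neighbouring atom's
#' accessible sphere.
#'
#' @param s a `protein_structure`, or a data frame of atoms with columns
#'   `x`, `y`, `z` and `vdw_r`.
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_sphere_points number of test points per atom (default 960).
#' @return Numeric vector of per-atom areas in Angstrom squared.
#' @export
sasa <- function(s, probe = 1.4, n_sphere_points = 960L) {
  a <- if (inherits(s, "protein_structure")) s$atoms else s
  if (is.null(a$vdw_r) || anyNA(a$vdw_r))
    stop_validation("missing van der Waals radius for atom(s) ",
                    paste(which(is.na(a$vdw_r)), collapse = ", "))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  shrake_rupley(xyz, a$vdw_r + probe, n_sphere_points)
}

## golden-spiral points on the unit sphere: deterministic quasi-uniform mesh
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

shrake_rupley <- function(xyz, radii, n_points) {
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  rmax <- max(radii)
  for (i in seq_len(n)) {
    ri <- radii[i]
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (ri + rmax)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (ri + radii[nb])^2]
    if (!length(nb)) {
      area[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p <- sweep(p, 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[acc, 1L] - xyz[j, 1L])^2 + (p[acc, 2L] - xyz[j, 2L])^2 +
        (p[acc, 3L] - xyz[j, 3L])^2
      acc[acc] <- dj2 > radii[j]^2
    }
    area[i] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  area
}

#' Nonpolar surface of residue i buried by residue j
#'
#' Sums, over the nonpolar atoms of residue `i`, the loss of solvent
#' accessibility caused by the presence of residue `j`: the accessible area of
#' the atom with residue `i` alone minus its area in the two-residue system.
#' This is the buried-area term of the nonpolar solvation energy; note it is
#' directional (A_ij != A_ji in general).
#'
#' @param s a `protein_structure`.
#' @param i,j residue indices (1-based, `i != j`).
#' @param probe probe radius in Angstrom.
#' @param context `"pairwise"` (default) evaluates burial in the isolated
#'   two-residue subsystem; `"full"` evaluates it in the whole structure
#'   (with and without residue `j`).
#' @param n_sphere_points mesh size per atom.
#' @return Buried nonpolar area A_ij in Angstrom squared (non-negative).
#' @export
pairwise_buried_nonpolar_area <- function(s, i, j, probe = 1.4,
                                          context = c("pairwise", "full"),
                                          n_sphere_points = 960L) {
  context <- match.arg(context)
  if (i == j) stop_validation("i and j must differ")
  a <- s$atoms
  sel_i <- a$residue == i
  if (!any(sel_i) || !any(a$residue == j))
    stop_validation("residue index out of range")
  np_i <- sel_i & a$nonpolar
  if (!any(np_i)) return(0)

  if (context == "pairwise") {
    base_atoms <- a[sel_i, , drop = FALSE]
    both <- a[sel_i | a$residue == j, , drop = FALSE]
    area_alone <- sasa(base_atoms, probe, n_sphere_points)
    area_both <- sasa(both, probe, n_sphere_points)
    keep <- base_atoms$nonpolar
    al <- area_alone[keep]
    ab <- area_both[both$residue == i & both$nonpolar]
  } else {
    without <- a[a$residue != j, , drop = FALSE]
    area_without <- sasa(without, probe, n_sphere_points)
    area_with <- sasa(a, probe, n_sphere_points)
    al <- area_without[without$residue == i & without$nonpolar]
    ab <- area_with[np_i]
  }
  max(sum(al - ab), 0)
}
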