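#' Specification for a toy multi-segment structure
#'
#' @param segments list of `(ss_class, length)` pairs, e.g.
#'   `list(c("helix", 10), c("loop", 4))`; classes are `"helix"`, `"sheet"`,
#'   `"loop"`.
#' @param seed integer seed (the geometry is deterministic; the seed is part
#'   of the reproducibility contract and is recorded on the output).
#' @param atom_detail `"backbone_cb"` (N, CA, C, O and CB where chemically
#'   sensible) or `"calpha_only"`.
#' @return Object of class `toy_spec`.
#' @export
toy_spec <- function(segments, seed = 1L,
                     atom_detail = c("backbone_cb", "calpha_only")) {
  atom_detail <- match.arg(atom_detail)
  if (!is.list(segments) || !length(segments))
    stop_validation("'segments' must be a non-empty list")
  seg <- lapply(segments, function(s) {
    if (length(s) != 2L)
      stop_validation("'segments': each entry needs (ss_class, length)")
    cls <- as.character(s[[1L]])
    len <- suppressWarnings(as.integer(s[[2L]]))
    if (!cls %in% c("helix", "sheet", "loop"))
      stop_validation("'segments': unknown ss_class '", cls, "'")
    if (is.na(len) || len < 1L)
      stop_validation("'segments': length must be >= 1, got ", s[[2L]])
    list(class = cls, length = len)
  })
  total <- sum(vapply(seg, `[[`, integer(1), "length"))
  if (total < 4L)
    stop_validation("'segments': total length must be >= 4, got ", total)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_validation("'seed' must be a single finite integer")
  structure(list(segments = seg, seed = as.integer(seed),
                 atom_detail = atom_detail),
            class = "toy_spec")
}

## ideal alpha-helix Calpha trace: rise 1.5 A, 100 deg per residue, radius 2.3
helix_calpha <- function(n, origin = c(0, 0, 0)) {
  k <- seq_len(n) - 1L
  th <- k * 100 * pi / 180
  cbind(origin[1L] + 1.5 * k, origin[2L] + 2.3 * cos(th),
        origin[3L] + 2.3 * sin(th))
}

## fully extended Calpha trace: consecutive spacing exactly 3.8 A via a zigzag
.ext_h <- 1.12
.ext_a <- sqrt(3.8^2 - .ext_h^2)
extended_calpha <- function(n, origin = c(0, 0, 0)) {
  k <- seq_len(n) - 1L
  cbind(origin[1L] + .ext_a * k, origin[2L] + .ext_h * (k %% 2L),
        origin[3L] + 0 * k)
}

#' Generate a toy structure with prescribed secondary-structure segments
#'
#' Helix segments use ideal alpha-helical geometry (rise 1.5 A, 100 degrees
#' per residue), so i,i+3 and i,i+4 Calpha pairs fall inside the 6.5 A
#' contact cutoff; sheet and loop segments are fully extended (no contacts
#' within the segment).  Segments are chained head-to-tail along the x axis
#' with 3.8 A junctions.  The same spec always yields byte-identical PDB
#' output through [write_pdb()].
#'
#' @param spec a [toy_spec()].
#' @return A `protein_structure` with the secondary-structure string recorded.
#' @examples
#' s <- make_toy_structure(toy_spec(list(c("helix", 8))))
#' nrow(contact_map(s)$pairs) >= 1
#' @export
make_toy_structure <- function(spec) {
  if (!inherits(spec, "toy_spec")) stop_validation("'spec' must be a toy_spec")
  ca <- NULL
  ss <- character(0)
  for (sg in spec$segments) {
    start <- if (is.null(ca)) c(0, 0, 0) else ca[nrow(ca), ] + c(3.8, 0, 0)
    seg_ca <- if (sg$class == "helix") {
      h <- helix_calpha(sg$length)
      sweep(h, 2L, h[1L, ] - start, "-")
    } else {
      extended_calpha(sg$length, origin = start)
    }
    ca <- rbind(ca, seg_ca)
    ss <- c(ss, rep(switch(sg$class, helix = "helix", sheet = "sheet",
                           loop = "turn_loop"), sg$length))
  }
  resname <- c(helix = "ALA", sheet = "VAL", turn_loop = "GLY")[ss]
  structure_from_calpha(ca, ss, resname,
                        backbone = spec$atom_detail == "backbone_cb")
}

## decorate a Calpha trace with approximate backbone (and CB) positions
structure_from_calpha <- function(ca, ss, resname, backbone = TRUE) {
  n <- nrow(ca)
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    atoms <- data.frame(residue = r, resname = resname[r], name = "CA",
                        element = "C", x = ca[r, 1L], y = ca[r, 2L],
                        z = ca[r, 3L], stringsAsFactors = FALSE)
    if (backbone) {
      ## local chain direction for placing N (behind) and C/O (ahead)
      d <- if (r < n) ca[r + 1L, ] - ca[r, ] else ca[r, ] - ca[r - 1L, ]
      d <- d / sqrt(sum(d^2))
      up <- c(0, 0.8, 0.45)
      add <- function(name, element, pos)
        data.frame(residue = r, resname = resname[r], name = name,
                   element = element, x = pos[1L], y = pos[2L], z = pos[3L],
                   stringsAsFactors = FALSE)
      atoms <- rbind(atoms,
                     add("N", "N", ca[r, ] - 1.2 * d + up),
                     add("C", "C", ca[r, ] + 1.2 * d + up),
                     add("O", "O", ca[r, ] + 1.2 * d + up + c(0, 0.7, 0.95)))
      if (resname[r] != "GLY")
        atoms <- rbind(atoms, add("CB", "C", ca[r, ] + c(0, -0.9, -1.2)))
    }
    rows[[r]] <- atoms
  }
  new_structure(do.call(rbind, rows), ss = ss)
}

#' Specification for a noisy two-state melting curve
#'
#' @param midpoint transition midpoint (degC or mol/L).
#' @param width transition width, same units, > 0.
#' @param grid strictly increasing x values.
#' @param baseline_native,baseline_denatured signal plateaus.
#' @param noise_sd Gaussian noise level, signal units, >= 0.
#' @param seed integer seed.
#' @return Object of class `curve_spec`.
#' @export
curve_spec <- function(midpoint, width, grid, baseline_native = 0,
                       baseline_denatured = 1, noise_sd = 0, seed = 1L) {
  if (!is.numeric(width) || width <= 0)
    stop_validation("'width' must be > 0, got ", width)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop_validation("'grid' must be strictly increasing")
  if (noise_sd < 0) stop_validation("'noise_sd' must be >= 0")
  structure(list(midpoint = midpoint, width = width, grid = grid,
                 baseline_native = baseline_native,
                 baseline_denatured = baseline_denatured,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "curve_spec")
}

#' Generate a noisy two-state sigmoidal melting curve
#'
#' \deqn{y(x) = b_N + (b_D - b_N)/(1 + e^{(midpoint - x)/width}) +
#'   N(0, noise\_sd).}
#' The generating parameters are kept on the curve (`$truth`) so parameter-
#' recovery tests can compare against them.
#'
#' @param spec a [curve_spec()].
#' @param x_kind,y_kind axis labels, see [melting_curve()].
#' @return A `melting_curve`.
#' @export
make_melting_curve <- function(spec, x_kind = "temperature",
                               y_kind = "fraction") {
  if (!inherits(spec, "curve_spec"))
    stop_validation("'spec' must be a curve_spec")
  f <- sigmoid2(spec$grid, spec$midpoint, spec$width)
  y <- spec$baseline_native +
    (spec$baseline_denatured - spec$baseline_native) * f
  if (spec$noise_sd > 0)
    y <- y + with_seed(spec$seed, stats::rnorm(length(y), 0, spec$noise_sd))
  melting_curve(spec$grid, y, x_kind = x_kind, y_kind = y_kind,
                truth = spec[c("midpoint", "width", "baseline_native",
                               "baseline_denatured", "noise_sd")])
}

.element_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)

#' Generate a Gaussian coordinate ensemble around a mean structure
#'
#' Frames are drawn independently; within a frame, the displacement of atom a
#' along each Cartesian axis is `stdev_per_atom[a]` times a standard normal,
#' with the prescribed atom-atom correlation applied identically and
#' independently per axis (isotropic displacement convention).  The expected
#' RMSF of atom a is therefore `stdev_per_atom[a] * sqrt(3)`, and the
#' expected [correlation_matrix()] equals `correlation`.
#'
#' @param mean a `protein_structure` or an `n_atoms x 3` coordinate matrix.
#' @param stdev_per_atom per-atom per-axis displacement scale, Angstrom
#'   (recycled if scalar).
#' @param correlation atom-atom correlation matrix (symmetric, unit diagonal,
#'   positive semidefinite); identity if `NULL`.
#' @param n_frames number of frames, >= 2.
#' @param seed integer seed.
#' @return An `wsme_ensemble`.
#' @export
make_gaussian_ensemble <- function(mean, stdev_per_atom, correlation = NULL,
                                   n_frames, seed = 1L) {
  mu <- if (inherits(mean, "protein_structure"))
    as.matrix(mean$atoms[, c("x", "y", "z")]) else as.matrix(mean)
  n_atoms <- nrow(mu)
  masses <- if (inherits(mean, "protein_structure"))
    unname(.element_mass[mean$atoms$element]) else rep(12, n_atoms)
  atom_res <- if (inherits(mean, "protein_structure"))
    mean$atoms$residue else seq_len(n_atoms)
  if (n_frames < 2L) stop_validation("'n_frames' must be >= 2")
  s <- rep_len(stdev_per_atom, n_atoms)
  if (any(s < 0)) stop_validation("'stdev_per_atom' must be >= 0")
  if (is.null(correlation)) correlation <- diag(n_atoms)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8)))
    stop_validation("'correlation' must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-8)
    stop_validation("'correlation' must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop_validation("'correlation' must be positive semidefinite ",
                    "(smallest eigenvalue ", format(min(ev$values)), ")")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n_atoms)
  coords <- array(0, c(n_frames, n_atoms, 3L))
  with_seed(seed, {
    for (ax in 1:3) {
      z <- matrix(stats::rnorm(n_frames * n_atoms), n_frames, n_atoms)
      disp <- z %*% t(L)
      coords[, , ax] <- sweep(sweep(disp, 2L, s, "*"), 2L, mu[, ax], "+")
    }
  })
  as_ensemble(coords, masses = masses, atom_residue = atom_res)
}

#' Generate paired chemical-shift tables with known perturbations
#'
#' A reference table of amide shifts plus a perturbed copy in which selected
#' residues are shifted by a prescribed amount and all residues receive
#' Gaussian noise; used to exercise [csp_profile()].
#'
#' @param n_residues chain length.
#' @param perturbed integer indices of strongly perturbed residues.
#' @param d1h,d15n perturbation magnitudes (ppm) for those residues.
#' @param noise_sd background shift noise, ppm.
#' @param seed integer seed.
#' @return List with `native` and `perturbed` data frames (columns `residue`,
#'   `d1H_ppm`, `d15N_ppm`).
#' @export
make_shift_tables <- function(n_residues, perturbed = integer(0), d1h = 0.2,
                              d15n = 1.0, noise_sd = 0, seed = 1L) {
  with_seed(seed, {
    native <- data.frame(residue = seq_len(n_residues),
                         d1H_ppm = stats::runif(n_residues, 7.5, 9.5),
                         d15N_ppm = stats::runif(n_residues, 105, 130))
    pert <- native
    pert$d1H_ppm[perturbed] <- pert$d1H_ppm[perturbed] + d1h
    pert$d15N_ppm[perturbed] <- pert$d15N_ppm[perturbed] + d15n
    if (noise_sd > 0) {
      pert$d1H_ppm <- pert$d1H_ppm + stats::rnorm(n_residues, 0, noise_sd)
      pert$d15N_ppm <- pert$d15N_ppm + stats::rnorm(n_residues, 0, 5 * noise_sd)
    }
    list(native = native, perturbed = pert)
  })
}

## n loop residues between anchors P and Q along the circular arc, bulging
## toward `away`, whose chords are exactly one 3.8 A virtual bond; equal
## angular spacing keeps non-adjacent loop residues well separated (no
## self-clash, no spurious loop contacts)
arc_bridge <- function(P, Q, n, away) {
  v <- Q - P
  chord <- sqrt(sum(v^2))
  if (chord >= 3.8 * (n + 1))
    stop("bridge gap ", round(chord, 1), " A too long for ", n, " residues")
  u <- v / chord
  w <- away - sum(away * u) * u
  if (sum(w^2) < 1e-6) w <- c(-u[2L], u[1L], 0)
  w <- w / sqrt(sum(w^2))
  ## arc angle theta: n+1 equal chords of 3.8 A subtend it on a circle that
  ## also subtends the anchor chord
  f <- function(th) 2 * (n + 1) * sin(th / (2 * (n + 1))) * chord /
    (2 * sin(th / 2)) - 3.8 * (n + 1)
  if (abs(f(1e-8)) < 1e-6) {   # essentially straight
    tt <- seq_len(n) / (n + 1)
    return(sweep(outer(tt, v), 2L, P, "+"))
  }
  th <- stats::uniroot(f, c(1e-8, 2 * pi - 1e-8))$root
  R <- chord / (2 * sin(th / 2))
  dcen <- sqrt(max(R^2 - (chord / 2)^2, 0))
  ctr <- (P + Q) / 2 + (if (th > pi) +1 else -1) * dcen * w
  ## angles of P and Q about the centre in the (u, w) plane
  ang <- function(X) atan2(sum((X - ctr) * w), sum((X - ctr) * u))
  aP <- ang(P); aQ <- ang(Q)
  ccw <- (aQ - aP) %% (2 * pi)
  dir <- if (abs(ccw - th) < abs((2 * pi - ccw) - th)) +1 else -1
  step <- th / (n + 1)
  t(vapply(seq_len(n), function(k) {
    a <- aP + dir * step * k
    ctr + R * cos(a) * u + R * sin(a) * w
  }, numeric(3)))
}

#' Synthetic 88-residue stand-in with a small alpha/beta fold
#'
#' Builds a deterministic 88-residue Calpha-trace structure with three
#' alpha-helices and a three-stranded antiparallel beta-sheet, the fold class
#' of the small thermophilic proteins this model family targets.  This is a
#' topological stand-in generated from ideal geometry, not an experimental
#' structure: strand pairs run antiparallel 4.8 A apart, helices pack against
#' the sheet, and connecting loops are smooth extended bridges.  Useful
#' whenever an MTH1880-sized test case is needed without any input file.
#'
#' @return A `protein_structure` with 88 residues (35 helix, 20 sheet,
#'   33 turn/loop).
#' @export
synthetic_mth1880 <- function() {
  seg_strand <- function(x, y0, dir, n) {
    k <- seq_len(n) - 1L
    cbind(x, y0 + dir * .ext_a * k, .ext_h * (k %% 2L))
  }
  seg_helix <- function(x, z, y0, dir, n) {
    k <- seq_len(n) - 1L
    th <- k * 100 * pi / 180
    cbind(x + 2.3 * cos(th), y0 + dir * 1.5 * k, z + 2.3 * sin(th))
  }
  ## sheet with the sequence-middle strand (beta-3) at its spatial centre,
  ## helices packing both faces: the high-contact-order arrangement in which
  ## most interactions span distant parts of the chain
  b1 <- seg_strand(-4.8, 0, +1, 6L)        # beta-1, edge strand
  a1 <- seg_helix(0.5, -6.5, 17, -1, 11L)  # alpha-1, under the sheet
  b2 <- seg_strand(4.8, 0, +1, 7L)         # beta-2, edge strand
  b3 <- seg_strand(0, 21.8, -1, 7L)        # beta-3, central strand
  a2 <- seg_helix(0, 7.5, 1, +1, 13L)      # alpha-2, over the sheet
  a3 <- seg_helix(-7.5, 11, 18, -1, 11L)   # alpha-3, over alpha-2/beta-1

  centroid <- colMeans(rbind(b1, a1, b2, b3, a2, a3))
  br <- function(P, Q, n) arc_bridge(P, Q, n, (P + Q) / 2 - centroid)
  nterm <- seg_strand(-4.8, -7 * .ext_a, +1, 7L)
  ca <- rbind(
    nterm,                                   # 1-7   loop (N-terminal tail)
    b1,                                      # 8-13  sheet
    br(b1[6L, ], a1[1L, ], 3L),              # 14-16 loop
    a1,                                      # 17-27 helix
    br(a1[11L, ], b2[1L, ], 8L),             # 28-35 loop
    b2,                                      # 36-42 sheet
    br(b2[7L, ], b3[1L, ], 7L),              # 43-49 loop
    b3,                                      # 50-56 sheet
    br(b3[7L, ], a2[1L, ], 3L),              # 57-59 loop
    a2,                                      # 60-72 helix
    br(a2[13L, ], a3[1L, ], 3L),             # 73-75 loop
    a3,                                      # 76-86 helix
    rbind(a3[11L, ] + c(-3.8, 0, 0),         # 87-88 tail (C-terminal)
          a3[11L, ] + c(-3.8 - .ext_a, .ext_h, 0)))

  ss <- c(rep("turn_loop", 7L), rep("sheet", 6L), rep("turn_loop", 3L),
          rep("helix", 11L), rep("turn_loop", 8L), rep("sheet", 7L),
          rep("turn_loop", 7L), rep("sheet", 7L), rep("turn_loop", 3L),
          rep("helix", 13L), rep("turn_loop", 3L), rep("helix", 11L),
          rep("turn_loop", 2L))
  resname <- c(helix = "ALA", sheet = "VAL", turn_loop = "GLY")[ss]
  structure_from_calpha(ca, ss, resname, backbone = FALSE)
}
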