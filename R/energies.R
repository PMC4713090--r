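#' Pairwise residue-residue interaction energies
#'
#' The folding Hamiltonian needs one interaction energy per native contact,
#' decomposed into Coulomb, van der Waals, polar-solvation and
#' nonpolar-solvation components (kcal/mol).  All atomistic terms sum over
#' every atom pair (a in residue i, b in residue j).
#'
#' `coulomb_energy()` uses a distance-dependent dielectric eps(r) = 4r by
#' default (a common implicit-solvent surrogate for ensemble-averaged
#' screening); pass a finite `dielectric` for a constant-eps model.
#'
#' @param s a `protein_structure`.
#' @param i,j residue indices.
#' @param dielectric `"4r"` (default) or a positive constant.
#' @return Energy in kcal/mol.
#' @name pair_energies
NULL

residue_atoms <- function(s, i) {
  a <- s$atoms[s$atoms$residue == i, , drop = FALSE]
  if (!nrow(a)) stop_validation("residue index out of range: ", i)
  a
}

pair_distances <- function(ai, aj) {
  xi <- as.matrix(ai[, c("x", "y", "z")])
  xj <- as.matrix(aj[, c("x", "y", "z")])
  d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 0.1))
    stop("overlapping atoms (r < 0.1 A) between residues; malformed structure",
         call. = FALSE)
  r
}

#' @rdname pair_energies
#' @export
coulomb_energy <- function(s, i, j, dielectric = "4r") {
  ai <- residue_atoms(s, i); aj <- residue_atoms(s, j)
  r <- pair_distances(ai, aj)
  qq <- outer(ai$charge, aj$charge)
  eps <- if (identical(dielectric, "4r")) 4 * r else {
    stopifnot(is.numeric(dielectric), dielectric > 0)
    dielectric
  }
  sum(COULOMB_K * qq / (eps * r))
}

#' @rdname pair_energies
#' @export
vdw_energy <- function(s, i, j) {
  ai <- residue_atoms(s, i); aj <- residue_atoms(s, j)
  r <- pair_distances(ai, aj)
  ## Lorentz-Berthelot combination
  sig <- outer(ai$lj_sigma, aj$lj_sigma, function(a, b) (a + b) / 2)
  eps <- sqrt(outer(ai$lj_eps, aj$lj_eps))
  sr6 <- (sig / r)^6
  sum(4 * eps * (sr6^2 - sr6))
}

#' @rdname pair_energies
#' @param eps_water solvent dielectric constant (default 78.5).
#' @details `polar_solvation_energy()` is the pairwise generalized-Born
#'   cross-term (Still form): for atoms a, b,
#'   \deqn{-332.0636 (1 - 1/\epsilon_w) q_a q_b / f_{GB}(r),}
#'   with \eqn{f_{GB} = \sqrt{r^2 + R_a R_b \exp(-r^2 / 4 R_a R_b)}} and
#'   \eqn{R} the intrinsic Born radii.  It screens (opposes) the direct
#'   Coulomb interaction.
#' @export
polar_solvation_energy <- function(s, i, j, eps_water = 78.5) {
  ai <- residue_atoms(s, i); aj <- residue_atoms(s, j)
  r <- pair_distances(ai, aj)
  qq <- outer(ai$charge, aj$charge)
  rr <- outer(ai$born_r, aj$born_r)
  fgb <- sqrt(r^2 + rr * exp(-r^2 / (4 * rr)))
  sum(-COULOMB_K * (1 - 1 / eps_water) * qq / fgb)
}

#' Nonpolar (cavity/hydrophobic) solvation energy from buried area
#'
#' The burial of nonpolar surface on contact formation is rewarded at
#' -7.2 cal per mol per Angstrom squared.  The Hamiltonian counts each pair
#' once, so the two directional buried areas A_ij and A_ji are summed into a
#' single symmetric term.
#'
#' @param a_ij,a_ji directional buried nonpolar areas, Angstrom squared.
#' @return Energy in kcal/mol (non-positive).
#' @export
nonpolar_solvation_energy <- function(a_ij, a_ji = 0) {
  if (any(c(a_ij, a_ji) < 0)) stop_validation("buried areas must be >= 0")
  -0.0072 * (a_ij + a_ji)
}

#' Build the per-contact energy table
#'
#' One row per native contact with the four energy components and their sum.
#' Three modes: `"go_uniform"` assigns a homogeneous energy `go_epsilon` to
#' every contact (the original, sequence-independent model);
#' `"atomistic_single_structure"` evaluates the four components on the given
#' structure; `"from_file"` reads a precomputed table (see
#' [read_energy_table()]).
#'
#' @param s a `protein_structure`.
#' @param cm a [contact_map()]; computed from `s` if `NULL`.
#' @param mode energy mode.
#' @param go_epsilon uniform contact energy, kcal/mol (default -1).
#' @param file CSV path for `mode = "from_file"`.
#' @param strict for `"from_file"`: error (TRUE) or warn-and-drop (FALSE,
#'   default) on pairs absent from the contact map.
#' @param probe probe radius for the buried-area term.
#' @param dielectric Coulomb dielectric model, see [coulomb_energy()].
#' @return An object of class `energy_table`: data frame `pairs` with columns
#'   `i`, `j`, `e_coulomb`, `e_vdw`, `e_polar_solv`, `e_nonpolar_solv`,
#'   `e_total`, plus `n_residues`, `mode` and `denaturant_state`.
#' @export
build_energy_table <- function(s, cm = NULL,
                               mode = c("go_uniform",
                                        "atomistic_single_structure",
                                        "from_file"),
                               go_epsilon = -1.0, file = NULL, strict = FALSE,
                               probe = 1.4, dielectric = "4r") {
  mode <- match.arg(mode)
  if (is.null(cm)) cm <- contact_map(s)
  p <- cm$pairs[, c("i", "j"), drop = FALSE]
  np <- nrow(p)
  zeros <- numeric(np)
  if (mode == "go_uniform") {
    tab <- data.frame(p, e_coulomb = zeros, e_vdw = zeros, e_polar_solv = zeros,
                      e_nonpolar_solv = zeros, e_total = rep(go_epsilon, np))
    ## bookkeeping: the uniform energy lives in a single component so that
    ## e_total stays the exact sum of the four
    tab$e_vdw <- tab$e_total
  } else if (mode == "atomistic_single_structure") {
    ec <- ev <- ep <- en <- numeric(np)
    for (k in seq_len(np)) {
      i <- p$i[k]; j <- p$j[k]
      ec[k] <- coulomb_energy(s, i, j, dielectric)
      ev[k] <- vdw_energy(s, i, j)
      ep[k] <- polar_solvation_energy(s, i, j)
      en[k] <- nonpolar_solvation_energy(
        pairwise_buried_nonpolar_area(s, i, j, probe),
        pairwise_buried_nonpolar_area(s, j, i, probe))
    }
    tab <- data.frame(p, e_coulomb = ec, e_vdw = ev, e_polar_solv = ep,
                      e_nonpolar_solv = en, e_total = ec + ev + ep + en)
  } else {
    if (is.null(file)) stop_validation("mode 'from_file' needs 'file'")
    ft <- utils::read.csv(file)
    need <- c("i", "j", "e_coulomb", "e_vdw", "e_polar_solv", "e_nonpolar_solv")
    if (!all(need %in% names(ft)))
      stop_validation("energy file lacks column(s): ",
                      paste(setdiff(need, names(ft)), collapse = ", "))
    key_cm <- paste(p$i, p$j)
    key_f <- paste(ft$i, ft$j)
    extra <- !(key_f %in% key_cm)
    if (any(extra)) {
      msg <- paste0(sum(extra), " file pair(s) not in the contact map")
      if (strict) stop_validation(msg)
      warning(msg, ", dropped", call. = FALSE)
      ft <- ft[!extra, , drop = FALSE]
    }
    m <- match(key_cm, paste(ft$i, ft$j))
    comp <- ft[m, need[-(1:2)], drop = FALSE]
    comp[is.na(m), ] <- 0
    tab <- data.frame(p, comp, e_total = rowSums(comp))
  }
  rownames(tab) <- NULL
  structure(list(pairs = tab, n_residues = cm$n_residues, mode = mode,
                 denaturant_state = list(species = "none", concentration = 0)),
            class = "energy_table")
}

#' Construct an energy table from explicit pairs
#'
#' Low-level constructor for models defined directly by a contact topology
#' and per-contact energies, without a structure (e.g. theoretical chains or
#' externally derived energies).
#'
#' @param n_residues chain length.
#' @param pairs data frame with columns `i`, `j` (`j >= i + 3`) and either
#'   `e_total` alone or the four components.
#' @return An `energy_table` (mode `"from_file"`).
#' @export
energy_table <- function(n_residues, pairs) {
  if (!all(c("i", "j") %in% names(pairs)))
    stop_validation("'pairs' needs columns i and j")
  if (nrow(pairs) && any(pairs$j - pairs$i < 3))
    stop_validation("contact pairs must satisfy j >= i + 3")
  if (nrow(pairs) && (any(pairs$i < 1) || any(pairs$j > n_residues)))
    stop_validation("pair indices out of 1..n_residues")
  comp <- c("e_coulomb", "e_vdw", "e_polar_solv", "e_nonpolar_solv")
  if (!all(comp %in% names(pairs))) {
    if (!"e_total" %in% names(pairs))
      stop_validation("'pairs' needs e_total or the four components")
    z <- rep(0, nrow(pairs))
    pairs$e_coulomb <- z; pairs$e_polar_solv <- z; pairs$e_nonpolar_solv <- z
    pairs$e_vdw <- pairs$e_total
  }
  pairs$e_total <- rowSums(pairs[, comp])
  pairs <- pairs[order(pairs$i, pairs$j),
                 c("i", "j", comp, "e_total"), drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_residues = as.integer(n_residues),
                 mode = "from_file",
                 denaturant_state = list(species = "none", concentration = 0)),
            class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat("Energy table (", x$mode, "): ", nrow(x$pairs), " contacts, total ",
      sprintf("%.3f", sum(x$pairs$e_total)), " kcal/mol\n", sep = "")
  ds <- x$denaturant_state
  if (ds$species != "none")
    cat("  denaturant:", ds$species, "at", ds$concentration, "M\n")
  invisible(x)
}

#' Attenuate contact energies by a denaturant
#'
#' A minimal linear denaturation model: every native-contact energy is scaled
#' by (1 - alpha * c), weakening stabilising interactions in proportion to
#' denaturant concentration.  Components scale together so that additivity is
#' preserved.  If alpha * c exceeds 1 the energies are clamped at zero with a
#' warning (contacts cannot become destabilising through this mechanism).
#'
#' @param t an `energy_table`.
#' @param species `"urea"` or `"gdnhcl"`.
#' @param concentration mol/L, >= 0.
#' @param alpha attenuation coefficient per molar, >= 0.
#' @return A new `energy_table` with scaled energies and the denaturant state
#'   recorded.
#' @export
apply_denaturant <- function(t, species = c("urea", "gdnhcl"), concentration,
                             alpha) {
  species <- match.arg(species)
  stopifnot(inherits(t, "energy_table"))
  if (concentration < 0) stop_validation("concentration must be >= 0")
  if (alpha < 0) stop_validation("alpha must be >= 0")
  f <- 1 - alpha * concentration
  if (f < 0) {
    warning("alpha * concentration > 1: contact energies clamped at 0",
            call. = FALSE)
    f <- 0
  }
  cols <- c("e_coulomb", "e_vdw", "e_polar_solv", "e_nonpolar_solv", "e_total")
  t$pairs[cols] <- t$pairs[cols] * f
  t$denaturant_state <- list(species = species, concentration = concentration)
  t
}

#' Read / write energy tables as CSV
#'
#' Columns: i, j, e_coulomb, e_vdw, e_polar_solv, e_nonpolar_solv, e_total
#' (kcal/mol, header required).
#'
#' @param t an `energy_table`.
#' @param path CSV file path.
#' @return `write_energy_table()` returns `path` invisibly;
#'   `read_energy_table()` returns a data frame suitable for
#'   `build_energy_table(mode = "from_file")`.
#' @export
write_energy_table <- function(t, path) {
  utils::write.csv(t$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_energy_table
#' @export
read_energy_table <- function(path) utils::read.csv(path)
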