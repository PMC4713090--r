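## Minimal built-in atom parameter template.
##
## Per-element Lennard-Jones parameters (sigma in A, epsilon in kcal/mol),
## Bondi-type van der Waals radii used for solvent accessibility, and intrinsic
## Born radii for the generalized-Born polar-solvation cross-term.  Partial
## charges come from a compact per-atom-name table covering the backbone plus
## the ionisable side-chain groups; every atom the table does not know receives
## zero charge and is flagged on the structure.  This is deliberately a minimal
## template, not a force field: the model machinery is agnostic to where its
## energies come from, and precomputed tables can be supplied instead
## (see read_energy_table()).

.element_params <- data.frame(
  element   = c("C",    "N",    "O",    "S",    "H"),
  lj_sigma  = c(3.40,   3.25,   2.96,   3.56,   1.07),
  lj_eps    = c(0.086,  0.170,  0.210,  0.250,  0.0157),
  vdw_r     = c(1.70,   1.55,   1.52,   1.80,   1.20),
  born_r    = c(1.70,   1.55,   1.50,   1.80,   1.20),
  stringsAsFactors = FALSE
)

## Backbone partial charges (e), roughly amide-group dipoles; applied to every
## residue.  Side-chain entries only for groups carrying net or strong partial
## charge; apolar side-chain atoms default to zero.
.backbone_charges <- c(
  N = -0.416, H = 0.272, HN = 0.272, CA = 0.035, HA = 0.048,
  C = 0.597, O = -0.568, OXT = -0.568
)

.sidechain_charges <- list(
  ASP = c(CB = -0.04, CG = 0.80, OD1 = -0.80, OD2 = -0.80),
  GLU = c(CG = -0.04, CD = 0.80, OE1 = -0.80, OE2 = -0.80),
  LYS = c(CE = 0.20, NZ = -0.30, HZ1 = 0.34, HZ2 = 0.34, HZ3 = 0.34),
  ARG = c(CD = 0.20, NE = -0.55, HE = 0.35, CZ = 0.64,
          NH1 = -0.80, NH2 = -0.80, HH11 = 0.46, HH12 = 0.46,
          HH21 = 0.46, HH22 = 0.46),
  HIS = c(ND1 = -0.38, HD1 = 0.36, NE2 = -0.57, HE2 = 0.36,
          CE1 = 0.21, CD2 = 0.13),
  SER = c(OG = -0.65, HG = 0.43, CB = 0.22),
  THR = c(OG1 = -0.65, HG1 = 0.43, CB = 0.22),
  TYR = c(OH = -0.56, HH = 0.40, CZ = 0.16),
  CYS = c(SG = -0.31, HG = 0.19, CB = 0.12),
  ASN = c(CG = 0.60, OD1 = -0.57, ND2 = -0.80, HD21 = 0.39, HD22 = 0.39),
  GLN = c(CD = 0.60, OE1 = -0.57, NE2 = -0.80, HE21 = 0.39, HE22 = 0.39),
  TRP = c(NE1 = -0.34, HE1 = 0.34)
)

## Element symbol from a PDB atom name when the element column is absent.
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  el <- substring(gsub("^[0-9]+", "", nm), 1L, 1L)
  el[!el %in% .element_params$element] <- NA_character_
  el
}

lookup_element_params <- function(element) {
  idx <- match(element, .element_params$element)
  .element_params[idx, , drop = FALSE]
}

lookup_charge <- function(resname, atomname) {
  q <- unname(.backbone_charges[atomname])
  miss <- which(is.na(q))
  for (k in miss) {
    side <- .sidechain_charges[[resname[k]]]
    if (!is.null(side)) q[k] <- unname(side[atomname[k]])
  }
  known <- !is.na(q)
  q[!known] <- 0
  list(charge = q, known = known)
}
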