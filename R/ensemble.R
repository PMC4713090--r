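#' Coordinate ensembles
#'
#' An `wsme_ensemble` is a stack of coordinate frames (frames x atoms x 3, in
#' Angstrom) with per-atom masses (amu) and an atom-to-residue mapping, as
#' produced by molecular simulation or by [make_gaussian_ensemble()].
#'
#' @param coords numeric array `n_frames x n_atoms x 3`.
#' @param masses per-atom masses, amu (default 12 for all atoms).
#' @param atom_residue integer atom-to-residue mapping (default one residue
#'   per atom).
#' @return Object of class `wsme_ensemble`.
#' @export
as_ensemble <- function(coords, masses = NULL, atom_residue = NULL) {
  d <- dim(coords)
  if (length(d) != 3L || d[3L] != 3L)
    stop_validation("'coords' must be an n_frames x n_atoms x 3 array")
  if (!all(is.finite(coords))) stop_validation("non-finite coordinates")
  if (d[1L] < 1L) stop_validation("need at least one frame")
  if (is.null(masses)) masses <- rep(12, d[2L])
  if (length(masses) != d[2L] || any(masses <= 0))
    stop_validation("'masses' must be positive, one per atom")
  if (is.null(atom_residue)) atom_residue <- seq_len(d[2L])
  structure(list(coords = coords, masses = masses,
                 atom_residue = as.integer(atom_residue),
                 n_frames = d[1L], n_atoms = d[2L]),
            class = "wsme_ensemble")
}

#' @export
print.wsme_ensemble <- function(x, ...) {
  cat("Coordinate ensemble:", x$n_frames, "frames x", x$n_atoms, "atoms\n")
  invisible(x)
}

#' Read an ensemble from a multi-MODEL PDB file
#'
#' @param path PDB file with MODEL/ENDMDL blocks.
#' @param masses optional per-atom masses (default: 12 amu).
#' @return An `wsme_ensemble`.
#' @export
read_ensemble_pdb <- function(path, masses = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_atoms <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(nrow(xyz), n_atoms, 3L))
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    coords[f, , ] <- m
  }
  key <- paste(pdb$atom$chain, pdb$atom$resno)
  as_ensemble(coords, masses, atom_residue = match(key, unique(key)))
}

#' Radius of gyration of one frame
#'
#' Root of the mass-weighted mean squared distance of the atoms from their
#' centre of mass.
#'
#' @param frame numeric matrix `n_atoms x 3`.
#' @param masses per-atom masses (amu).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame, masses = rep(1, nrow(frame))) {
  frame <- as.matrix(frame)
  if (!nrow(frame)) stop_validation("empty frame")
  if (sum(masses) <= 0) stop_validation("total mass must be positive")
  com <- colSums(frame * masses) / sum(masses)
  d2 <- rowSums(sweep(frame, 2L, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Radius-of-gyration series and distribution over an ensemble
#'
#' @param e an `wsme_ensemble` with at least 2 frames.
#' @param n_bins histogram bin count.
#' @return List with `rg` (per-frame series), `mean`, `sd` (sample sd),
#'   and `histogram` (density-normalised, area 1).
#' @export
rg_distribution <- function(e, n_bins = 50L) {
  stopifnot(inherits(e, "wsme_ensemble"))
  if (e$n_frames < 2L) stop_validation("need at least 2 frames")
  rg <- vapply(seq_len(e$n_frames),
               function(f) radius_of_gyration(e$coords[f, , , drop = TRUE],
                                              e$masses),
               numeric(1))
  rng <- range(rg)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  h <- graphics::hist(rg, breaks = seq(rng[1L], rng[2L], length.out = n_bins + 1L),
                      plot = FALSE)
  list(rg = rg, mean = mean(rg), sd = stats::sd(rg), histogram = h)
}

## per-atom mean positions: n_atoms x 3
ensemble_means <- function(e) {
  apply(e$coords, c(2L, 3L), mean)
}

#' Root-mean-square fluctuation per atom
#'
#' \eqn{RMSF_a = \sqrt{\langle |r_a(t) - \langle r_a \rangle|^2 \rangle}}
#' about the ensemble-average position (no superposition is applied; align
#' beforehand if frames contain rigid-body motion).
#'
#' @param e an `wsme_ensemble` with at least 2 frames.
#' @param group_by_residue average member-atom RMSF per residue.
#' @return Numeric vector of RMSF values in Angstrom.
#' @export
rmsf <- function(e, group_by_residue = FALSE) {
  stopifnot(inherits(e, "wsme_ensemble"))
  if (e$n_frames < 2L) stop_validation("need at least 2 frames")
  mu <- ensemble_means(e)
  dev2 <- 0
  for (ax in 1:3)
    dev2 <- dev2 + sweep(e$coords[, , ax, drop = TRUE], 2L, mu[, ax])^2
  out <- sqrt(colMeans(dev2))
  if (group_by_residue)
    out <- as.vector(tapply(out, e$atom_residue, mean))
  out
}

#' Variance-covariance matrix of atomic displacements
#'
#' \eqn{\sigma_{ij} = \langle (r_i - \langle r_i\rangle) \cdot
#' (r_j - \langle r_j\rangle) \rangle}: the 3-D displacement vectors are
#' contracted by dot product, so the diagonal equals the squared RMSF.
#' Population (1/n) averaging.
#'
#' @param e an `wsme_ensemble` with at least 2 frames.
#' @return Symmetric `n_atoms x n_atoms` matrix, Angstrom squared.
#' @export
covariance_matrix <- function(e) {
  stopifnot(inherits(e, "wsme_ensemble"))
  if (e$n_frames < 2L) stop_validation("need at least 2 frames")
  mu <- ensemble_means(e)
  sig <- 0
  for (ax in 1:3) {
    d <- sweep(e$coords[, , ax, drop = TRUE], 2L, mu[, ax])
    sig <- sig + crossprod(d) / e$n_frames
  }
  sig
}

#' Normalised correlation matrix of atomic motions
#'
#' \eqn{c_{ij} = \sigma_{ij} / \sqrt{\sigma_{ii}\,\sigma_{jj}}}, the
#' normalisation that gives a unit diagonal.  Atoms with zero variance
#' (static) produce `NA` rows/columns rather than silent division.
#'
#' @param e an `wsme_ensemble`, or a covariance matrix from
#'   [covariance_matrix()].
#' @return Symmetric matrix with unit diagonal and entries in \[-1, 1\].
#' @export
correlation_matrix <- function(e) {
  sig <- if (inherits(e, "wsme_ensemble")) covariance_matrix(e) else e
  v <- diag(sig)
  static <- v <= 0
  s <- sqrt(v)
  cmat <- sig / outer(s, s)
  if (any(static)) {
    cmat[static, ] <- NA_real_
    cmat[, static] <- NA_real_
  }
  diag(cmat)[!static] <- 1
  cmat
}

#' Write a square matrix with residue labels as CSV
#' @param m matrix.
#' @param path output CSV.
#' @param labels row/column labels (default 1..n).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, labels = seq_len(nrow(m))) {
  dimnames(m) <- list(labels, labels)
  utils::write.csv(m, path, quote = FALSE)
  invisible(path)
}

#' Kabsch superposition of every frame onto a reference
#'
#' Optional pre-processing for [rmsf()]/[covariance_matrix()] when frames
#' contain rigid-body motion; least-squares rotation + translation onto the
#' reference frame (default: the first frame), unweighted.
#'
#' @param e an `wsme_ensemble`.
#' @param reference reference coordinates (`n_atoms x 3`; default frame 1).
#' @return A superposed `wsme_ensemble`.
#' @export
superpose_ensemble <- function(e, reference = NULL) {
  stopifnot(inherits(e, "wsme_ensemble"))
  ref <- if (is.null(reference)) e$coords[1L, , , drop = TRUE] else reference
  ref_c <- sweep(ref, 2L, colMeans(ref))
  out <- e$coords
  for (f in seq_len(e$n_frames)) {
    x <- e$coords[f, , , drop = TRUE]
    xc <- sweep(x, 2L, colMeans(x))
    sv <- svd(crossprod(xc, ref_c))
    d <- sign(det(sv$v %*% t(sv$u)))
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    out[f, , ] <- sweep(xc %*% t(rot), 2L, colMeans(ref), "+")
  }
  as_ensemble(out, e$masses, e$atom_residue)
}
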