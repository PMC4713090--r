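#' Protein structures with typed, parameterised atoms
#'
#' A `protein_structure` holds an ordered chain of residues (1-based,
#' contiguous indices) with a secondary-structure class per residue
#' (`"helix"`, `"sheet"` or `"turn_loop"`) and, per atom: name, element,
#' Cartesian coordinates (Angstrom), partial charge (e), Lennard-Jones
#' parameters, van der Waals and Born radii, and a nonpolar flag.  Nonpolar
#' atoms are carbons and sulfurs plus hydrogens bonded to them (the standard
#' hydrophobic-surface convention); nitrogens, oxygens and their hydrogens are
#' polar.  Hydrogen attachment is resolved geometrically (nearest heavy atom
#' within 1.3 Angstrom).
#'
#' @param atoms data frame with columns `residue`, `resname`, `name`,
#'   `element`, `x`, `y`, `z` (and optionally `charge`).
#' @param ss character vector of secondary-structure classes, one per residue.
#' @return An object of class `protein_structure`.
#' @seealso [read_structure()], [make_toy_structure()], [contact_map()]
#' @export
new_structure <- function(atoms, ss = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("residue", "resname", "name", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop_validation("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_validation("non-finite atom coordinates")

  ridx <- unique(atoms$residue)
  if (!identical(as.integer(ridx), seq_along(ridx)))
    stop_validation("residue indices must be contiguous and start at 1")
  n_res <- length(ridx)
  if (n_res < 4L)
    stop_validation("a structure needs at least 4 residues, got ", n_res)

  has_ca <- tapply(atoms$name == "CA", atoms$residue, any)
  if (!all(has_ca))
    stop_validation("residue(s) without a CA atom: ",
                    paste(ridx[!has_ca], collapse = ", "))

  ep <- lookup_element_params(atoms$element)
  if (anyNA(ep$lj_sigma))
    stop_validation("unknown element(s): ",
                    paste(unique(atoms$element[is.na(ep$lj_sigma)]), collapse = ", "))
  atoms$lj_sigma <- ep$lj_sigma
  atoms$lj_eps <- ep$lj_eps
  atoms$vdw_r <- ep$vdw_r
  atoms$born_r <- ep$born_r

  if (is.null(atoms$charge)) {
    cq <- lookup_charge(atoms$resname, atoms$name)
    atoms$charge <- cq$charge
    atoms$charge_known <- cq$known
  } else if (is.null(atoms$charge_known)) {
    atoms$charge_known <- TRUE
  }

  atoms$nonpolar <- assign_polarity(atoms)

  resname <- atoms$resname[!duplicated(atoms$residue)]
  if (is.null(ss)) ss <- rep("turn_loop", n_res)
  ss <- normalize_ss(ss, n_res)

  structure(
    list(atoms = atoms,
         residues = data.frame(index = seq_len(n_res), name = resname,
                               ss = ss, stringsAsFactors = FALSE),
         n_residues = n_res),
    class = "protein_structure")
}

normalize_ss <- function(ss, n_res) {
  if (length(ss) == 1L && nchar(ss[1L]) == n_res)
    ss <- strsplit(ss, "")[[1L]]
  if (length(ss) != n_res)
    stop_validation("secondary-structure annotation length ", length(ss),
                    " != number of residues ", n_res)
  map <- c(H = "helix", G = "helix", I = "helix", E = "sheet", B = "sheet",
           C = "turn_loop", T = "turn_loop", L = "turn_loop", "-" = "turn_loop",
           helix = "helix", sheet = "sheet", turn_loop = "turn_loop",
           loop = "turn_loop", turn = "turn_loop")
  out <- unname(map[ss])
  if (anyNA(out))
    stop_validation("unknown secondary-structure code(s): ",
                    paste(unique(ss[is.na(out)]), collapse = ", "))
  out
}

## carbon/sulfur plus their hydrogens are nonpolar
assign_polarity <- function(atoms) {
  nonpolar <- atoms$element %in% c("C", "S")
  hyd <- which(atoms$element == "H")
  if (length(hyd)) {
    heavy <- which(atoms$element != "H")
    hx <- as.matrix(atoms[hyd, c("x", "y", "z")])
    mx <- as.matrix(atoms[heavy, c("x", "y", "z")])
    for (k in seq_along(hyd)) {
      d2 <- colSums((t(mx) - hx[k, ])^2)
      j <- heavy[which.min(d2)]
      nonpolar[hyd[k]] <- min(d2) <= 1.3^2 && atoms$element[j] %in% c("C", "S")
    }
  }
  nonpolar
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records (waters and hetero groups are dropped), keeps the first
#' MODEL of a multi-model file by default, renumbers residues contiguously
#' from 1, and fills partial charges and Lennard-Jones/Born parameters from
#' the built-in residue template table.  Atoms the template does not know get
#' zero charge and are flagged (`charge_known = FALSE`).  Secondary structure
#' is taken from the PDB HELIX/SHEET records when present, otherwise from the
#' `ss` argument, defaulting to all turn/loop.
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB lines.
#' @param model which MODEL to use (default 1).
#' @param ss optional secondary-structure annotation (string of H/E/C codes or
#'   vector of class names), overriding any HELIX/SHEET records.
#' @return A [new_structure()] object.
#' @export
read_structure <- function(pdb_source, model = 1L, ss = NULL) {
  if (length(pdb_source) == 1L && !grepl("\n", pdb_source) &&
      file.exists(pdb_source)) {
    pdb <- bio3d::read.pdb(pdb_source, multi = TRUE, verbose = FALSE)
    lines <- readLines(pdb_source, warn = FALSE)
  } else {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(pdb_source, tf)
    pdb <- bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE)
    lines <- pdb_source
  }
  at <- pdb$atom
  keep <- at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT"))
  if (!any(keep)) stop_validation("no ATOM records in PDB input")
  at <- at[keep, , drop = FALSE]

  nmodel <- nrow(pdb$xyz)
  if (model > nmodel)
    stop_validation("requested MODEL ", model, " but file has ", nmodel)
  if (nmodel > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }

  key <- paste(at$chain, at$resno, at$insert)
  residue <- match(key, unique(key))
  element <- toupper(trimws(at$elesy))
  bad <- is.na(element) | element == "" | !(element %in% .element_params$element)
  if (any(bad)) element[bad] <- guess_element(at$elety[bad])
  known_el <- !is.na(element)
  atoms <- data.frame(residue = residue[known_el],
                      resname = at$resid[known_el],
                      name = toupper(trimws(at$elety[known_el])),
                      element = element[known_el],
                      x = at$x[known_el], y = at$y[known_el], z = at$z[known_el],
                      stringsAsFactors = FALSE)
  atoms$residue <- match(atoms$residue, unique(atoms$residue))

  if (is.null(ss)) ss <- ss_from_records(lines, at, residue)
  new_structure(atoms, ss = ss)
}

## HELIX/SHEET record parsing; anything unannotated is turn/loop
ss_from_records <- function(lines, at, residue) {
  n_res <- length(unique(residue))
  if (is.null(lines)) return(rep("turn_loop", n_res))
  resno1 <- at$resno[!duplicated(residue)]
  chain1 <- at$chain[!duplicated(residue)]
  ss <- rep("turn_loop", n_res)
  hx <- lines[startsWith(lines, "HELIX")]
  for (l in hx) {
    ch <- trimws(substr(l, 20, 20))
    from <- suppressWarnings(as.integer(substr(l, 22, 25)))
    to <- suppressWarnings(as.integer(substr(l, 34, 37)))
    if (is.na(from) || is.na(to)) next
    ss[chain1 == ch & resno1 >= from & resno1 <= to] <- "helix"
  }
  sh <- lines[startsWith(lines, "SHEET")]
  for (l in sh) {
    ch <- trimws(substr(l, 22, 22))
    from <- suppressWarnings(as.integer(substr(l, 23, 26)))
    to <- suppressWarnings(as.integer(substr(l, 34, 37)))
    if (is.na(from) || is.na(to)) next
    ss[chain1 == ch & resno1 >= from & resno1 <= to] <- "sheet"
  }
  if (!length(hx) && !length(sh)) return(rep("turn_loop", n_res))
  ss
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("Protein structure:", x$n_residues, "residues,", nrow(x$atoms), "atoms\n")
  tab <- table(factor(x$residues$ss, c("helix", "sheet", "turn_loop")))
  cat("  secondary structure:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  nk <- sum(!x$atoms$charge_known)
  if (nk) cat("  ", nk, "atom(s) with template-unknown charge (set to 0)\n")
  invisible(x)
}

## Calpha coordinate matrix, one row per residue
calpha_coords <- function(s) {
  ca <- s$atoms[s$atoms$name == "CA", ]
  ca <- ca[!duplicated(ca$residue), ]
  as.matrix(ca[order(ca$residue), c("x", "y", "z")])
}

#' Native contact map from Calpha distances
#'
#' Residues i < j form a native contact when their Calpha atoms lie within
#' `cutoff` (inclusive) and the sequence separation j - i is at least
#' `min_separation`.  These pairs are the interaction terms of the folding
#' Hamiltonian.
#'
#' @param s a `protein_structure`.
#' @param cutoff distance cutoff in Angstrom (default 6.5).
#' @param min_separation minimum sequence separation j - i (default 3).
#' @return An object of class `contact_map`: list with `n_residues`, `pairs`
#'   (data frame `i`, `j`, `distance`, i < j), `cutoff`, `min_separation`.
#' @export
contact_map <- function(s, cutoff = 6.5, min_separation = 3L) {
  stopifnot(inherits(s, "protein_structure"))
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop_validation("'cutoff' must be positive, got ", cutoff)
  ca <- calpha_coords(s)
  n <- nrow(ca)
  d <- as.matrix(stats::dist(ca))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  sep_ok <- idx[, 2L] - idx[, 1L] >= min_separation
  close <- d[idx] <= cutoff
  keep <- sep_ok & close
  pairs <- data.frame(i = idx[keep, 1L], j = idx[keep, 2L],
                      distance = d[idx][keep])
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(n_residues = n, pairs = pairs, cutoff = cutoff,
                 min_separation = as.integer(min_separation)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Contact map:", nrow(x$pairs), "native pairs over", x$n_residues,
      "residues (Calpha cutoff", x$cutoff, "A, |j-i| >=", x$min_separation, ")\n")
  invisible(x)
}

#' Export a contact map to CSV
#'
#' @param cm a `contact_map`.
#' @param path output file.
#' @param format `"pairs"` writes 3 columns (i, j, distance); `"matrix"`
#'   writes a square 0/1 incidence matrix.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path, format = c("pairs", "matrix")) {
  format <- match.arg(format)
  if (format == "pairs") {
    utils::write.csv(cm$pairs, path, row.names = FALSE, quote = FALSE)
  } else {
    m <- matrix(0L, cm$n_residues, cm$n_residues)
    m[cbind(cm$pairs$i, cm$pairs$j)] <- 1L
    m[cbind(cm$pairs$j, cm$pairs$i)] <- 1L
    utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a structure as PDB text
#'
#' Single-chain, single-model ATOM records with a TER line; formatting is
#' deterministic so that identical structures give byte-identical files.
#' With `include_ss = TRUE`, helix and sheet runs of the structure's
#' annotation are emitted as HELIX/SHEET records, so the secondary structure
#' survives a round trip through [read_structure()].
#'
#' @param s a `protein_structure`.
#' @param path output file; if `NULL` the lines are returned.
#' @param include_ss also write HELIX/SHEET records.
#' @return The PDB lines, invisibly when written to a file.
#' @export
write_pdb <- function(s, path = NULL, include_ss = FALSE) {
  a <- s$atoms
  header <- if (include_ss) ss_records(s) else character(0)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)), format_atom_name(a$name), a$resname, a$residue,
    a$x, a$y, a$z, a$element)
  lines <- c(header, lines,
             sprintf("TER   %5d      %3s A%4d", nrow(a) + 1L,
                     a$resname[nrow(a)], a$residue[nrow(a)]),
             "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

## HELIX/SHEET records for contiguous annotated runs (fixed-column format)
ss_records <- function(s) {
  put <- function(line, at, text) {
    substring(line, at, at + nchar(text) - 1L) <- text
    line
  }
  blank <- strrep(" ", 46L)
  r <- s$residues
  runs <- rle(r$ss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- character(0)
  nh <- 0L; ns <- 0L
  for (k in seq_along(runs$values)) {
    cls <- runs$values[k]
    if (cls == "turn_loop") next
    i <- starts[k]; j <- ends[k]
    if (cls == "helix") {
      nh <- nh + 1L
      l <- put(blank, 1L, "HELIX")
      l <- put(l, 8L, formatC(nh, width = 3L))
      l <- put(l, 12L, formatC(nh, width = 3L))
      l <- put(l, 16L, r$name[i]); l <- put(l, 20L, "A")
      l <- put(l, 22L, formatC(i, width = 4L))
      l <- put(l, 28L, r$name[j]); l <- put(l, 32L, "A")
      l <- put(l, 34L, formatC(j, width = 4L))
      l <- put(l, 39L, "1")
    } else {
      ns <- ns + 1L
      l <- put(blank, 1L, "SHEET")
      l <- put(l, 8L, formatC(ns, width = 3L))
      l <- put(l, 12L, "  S"); l <- put(l, 15L, formatC(1L, width = 2L))
      l <- put(l, 18L, r$name[i]); l <- put(l, 22L, "A")
      l <- put(l, 23L, formatC(i, width = 4L))
      l <- put(l, 29L, r$name[j]); l <- put(l, 33L, "A")
      l <- put(l, 34L, formatC(j, width = 4L))
      l <- put(l, 39L, "0")
    }
    out <- c(out, l)
  }
  out
}

## PDB columns 13-16: names shorter than 4 characters start in column 14
format_atom_name <- function(name) {
  ifelse(nchar(name) >= 4L, substr(name, 1L, 4L), paste0(" ", name))
}

#' Write a coordinate ensemble as a multi-MODEL PDB
#'
#' @param e an `ensemble` (see [as_ensemble()]).
#' @param s the `protein_structure` giving atom metadata.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(e, s, path) {
  stopifnot(inherits(e, "wsme_ensemble"), nrow(s$atoms) == e$n_atoms)
  con <- file(path, "w")
  on.exit(close(con))
  a <- s$atoms
  for (f in seq_len(e$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)), format_atom_name(a$name), a$resname, a$residue,
      e$coords[f, , 1L], e$coords[f, , 2L], e$coords[f, , 3L], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
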