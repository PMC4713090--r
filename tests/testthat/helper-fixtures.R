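## Shared fixture builders for the test suite.  Everything is generated in
## code with explicit seeds; no test reads files that are not written by the
## test itself.

## a minimal structure of single-"CA" pseudo-residues at given coordinates,
## with caller-controlled charges; bypasses the charge template
point_structure <- function(xyz, charge = rep(0, nrow(xyz)),
                            element = rep("C", nrow(xyz)),
                            resname = rep("GLY", nrow(xyz))) {
  n <- nrow(xyz)
  stopifnot(n >= 4)
  new_structure(data.frame(
    residue = seq_len(n), resname = resname, name = "CA", element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = charge,
    stringsAsFactors = FALSE))
}

## a random sequence-dependent model on a random contact topology,
## used for DP-vs-enumeration property tests
random_model <- function(n, seed) {
  set.seed(seed)
  cand <- which(outer(seq_len(n), seq_len(n), function(i, j) j - i >= 3),
                arr.ind = TRUE)
  keep <- cand[runif(nrow(cand)) < 0.3, , drop = FALSE]
  pairs <- data.frame(i = keep[, 1], j = keep[, 2],
                      e_total = runif(nrow(keep), -2.5, -0.2))
  ss <- sample(c("helix", "sheet", "turn_loop"), n, replace = TRUE)
  wsme(energy = energy_table(n, pairs), entropy = entropy_profile(ss))
}

## a 20-residue beta-hairpin: two antiparallel strands (1-8, 13-20) joined by
## a 4-residue loop.  The cross-strand ladder gives a genuinely cooperative
## two-state folding transition (every contact spans the loop).
hairpin_structure <- function() {
  a <- sqrt(3.8^2 - 1.12^2)
  k <- 0:7
  s1 <- cbind(0, a * k, 1.12 * (k %% 2))
  s2 <- cbind(4.8, a * (7 - k), 1.12 * ((7 - k) %% 2))
  loop <- wsme:::arc_bridge(s1[8, ], s2[1, ], 4, c(0, 1, 0))
  ca <- rbind(s1, loop, s2)
  ss <- c(rep("sheet", 8), rep("turn_loop", 4), rep("sheet", 8))
  atoms <- data.frame(residue = 1:20, resname = ifelse(ss == "sheet", "VAL",
                                                       "GLY"),
                      name = "CA", element = "C",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3],
                      stringsAsFactors = FALSE)
  new_structure(atoms, ss = ss)
}

toy_two_state <- function() wsme(hairpin_structure())

## rigid rotation matrix from an axis-angle triple (deterministic)
rotation_matrix <- function(axis = c(1, 2, 3), angle = 0.7) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sa * K + (1 - ca) * (K %*% K)
}

rotate_structure <- function(s, Rm = rotation_matrix(), shift = c(5, -3, 11)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(Rm)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}
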