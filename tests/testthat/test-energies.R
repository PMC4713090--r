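two_charge_structure <- function(d = 3.0, q = c(1, -1)) {
  point_structure(rbind(c(0, 0, 0), c(d, 0, 0), c(100, 0, 0), c(200, 0, 0)),
                  charge = c(q, 0, 0))
}

test_that("coulomb energy reproduces the hand-evaluated 4r-dielectric value", {
  s <- two_charge_structure(3.0)
  ## 332.0636 * (+1)(-1) / (eps(r) * r) with eps = 4r = 12
  expect_equal(coulomb_energy(s, 1, 2), 332.0636 * (-1) / (12 * 3),
               tolerance = 1e-12)
  expect_equal(coulomb_energy(s, 1, 2), -9.224, tolerance = 1e-3)
  ## constant-dielectric alternative
  expect_equal(coulomb_energy(s, 1, 2, dielectric = 1),
               332.0636 * (-1) / 3, tolerance = 1e-12)
})

test_that("coulomb energy is zero without charges and even under q -> -q", {
  s0 <- point_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(50, 0, 0),
                              c(100, 0, 0)))
  expect_equal(coulomb_energy(s0, 1, 2), 0)
  s <- two_charge_structure(3.0)
  sneg <- two_charge_structure(3.0, q = c(-1, 1))
  expect_equal(coulomb_energy(s, 1, 2), coulomb_energy(sneg, 1, 2))
})

test_that("overlapping atoms are rejected as malformed", {
  s <- two_charge_structure(0.05)
  expect_error(coulomb_energy(s, 1, 2), "malformed")
})

test_that("Lennard-Jones energy has its minimum and zero where it must", {
  sig <- 3.40; eps <- 0.086    # carbon-carbon, Lorentz-Berthelot trivially
  smin <- point_structure(rbind(c(0, 0, 0), c(sig * 2^(1 / 6), 0, 0),
                                c(100, 0, 0), c(200, 0, 0)))
  expect_equal(vdw_energy(smin, 1, 2), -eps, tolerance = 1e-12)
  szero <- point_structure(rbind(c(0, 0, 0), c(sig, 0, 0), c(100, 0, 0),
                                 c(200, 0, 0)))
  expect_equal(vdw_energy(szero, 1, 2), 0, tolerance = 1e-12)
})

test_that("multi-atom vdW sums equal an independent atom-pair enumeration", {
  ## residues with 2 and 3 atoms; oracle sums the 6 pair terms directly
  at <- data.frame(
    residue = c(1, 1, 2, 2, 2, 3, 4),
    resname = "GLY", name = c("CA", "CB", "CA", "CB", "CG", "CA", "CA"),
    element = c("C", "S", "C", "O", "N", "C", "C"),
    x = c(0, 1.4, 4.0, 5.1, 4.6, 50, 100),
    y = c(0, 0.6, 0.2, -0.8, 1.4, 0, 0),
    z = c(0, 0, 0.3, 0, -0.5, 0, 0), charge = 0)
  at$name[c(2, 4, 5)] <- c("SG", "OX", "NX")
  s <- new_structure(at)
  p <- wsme:::.element_params
  prm <- function(el) p[p$element == el, ]
  oracle <- 0
  for (a in 1:2) for (b in 3:5) {
    pa <- prm(at$element[a]); pb <- prm(at$element[b])
    r <- sqrt(sum((at[a, c("x", "y", "z")] - at[b, c("x", "y", "z")])^2))
    sg <- (pa$lj_sigma + pb$lj_sigma) / 2
    ep <- sqrt(pa$lj_eps * pb$lj_eps)
    oracle <- oracle + 4 * ep * ((sg / r)^12 - (sg / r)^6)
  }
  expect_equal(vdw_energy(s, 1, 2), oracle, tolerance = 1e-12)
})

test_that("generalized-Born cross-term matches its closed form and screens", {
  ## carbon has Born radius 1.7; build the closed form independently
  s <- two_charge_structure(5.0)
  rb <- 1.7
  fgb <- sqrt(25 + rb * rb * exp(-25 / (4 * rb * rb)))
  expect_equal(polar_solvation_energy(s, 1, 2),
               -332.0636 * (1 - 1 / 78.5) * (-1) / fgb, tolerance = 1e-10)
  ## screening opposes the vacuum interaction
  expect_true(sign(polar_solvation_energy(s, 1, 2)) !=
                sign(coulomb_energy(s, 1, 2)))
  s0 <- point_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(50, 0, 0),
                              c(100, 0, 0)))
  expect_equal(polar_solvation_energy(s0, 1, 2), 0)
})

test_that("nonpolar solvation is the linear buried-area reward", {
  expect_equal(nonpolar_solvation_energy(60, 40), -0.72, tolerance = 1e-12)
  expect_equal(nonpolar_solvation_energy(0, 0), 0)
  expect_equal(nonpolar_solvation_energy(120, 80),
               2 * nonpolar_solvation_energy(60, 40))
  expect_error(nonpolar_solvation_energy(-1, 0), ">= 0")
})

test_that("energy tables keep components additive in every mode", {
  s <- make_toy_structure(toy_spec(list(c("helix", 8), c("loop", 3),
                                        c("helix", 5))))
  cm <- contact_map(s)
  go <- build_energy_table(s, cm, mode = "go_uniform", go_epsilon = -1)
  expect_equal(sum(go$pairs$e_total), -nrow(cm$pairs))
  at <- build_energy_table(s, cm, mode = "atomistic_single_structure")
  comp_sum <- with(at$pairs, e_coulomb + e_vdw + e_polar_solv + e_nonpolar_solv)
  expect_equal(at$pairs$e_total, comp_sum, tolerance = 1e-14)
  ## file round trip
  tf <- withr::local_tempfile(fileext = ".csv")
  write_energy_table(at, tf)
  rt <- build_energy_table(s, cm, mode = "from_file", file = tf)
  expect_equal(rt$pairs, at$pairs, tolerance = 1e-12)
})

test_that("atomistic tables are rigid-motion invariant", {
  s <- make_toy_structure(toy_spec(list(c("helix", 7), c("loop", 2),
                                        c("sheet", 4))))
  cm <- contact_map(s)
  t1 <- build_energy_table(s, cm, mode = "atomistic_single_structure")
  s2 <- rotate_structure(s)
  t2 <- build_energy_table(s2, contact_map(s2),
                           mode = "atomistic_single_structure")
  ## analytic terms are invariant to machine precision; the buried-area term
  ## only to the quadrature tolerance of the rotated point mesh
  expect_equal(t1$pairs$e_coulomb, t2$pairs$e_coulomb, tolerance = 1e-9)
  expect_equal(t1$pairs$e_vdw, t2$pairs$e_vdw, tolerance = 1e-9)
  expect_equal(t1$pairs$e_polar_solv, t2$pairs$e_polar_solv,
               tolerance = 1e-9)
  expect_lt(max(abs(t1$pairs$e_nonpolar_solv - t2$pairs$e_nonpolar_solv)),
            0.02)
  expect_lt(max(abs(t1$pairs$e_total - t2$pairs$e_total)), 0.02)
})

test_that("file pairs outside the contact map warn-and-drop or error", {
  s <- make_toy_structure(toy_spec(list(c("helix", 8))))
  cm <- contact_map(s)
  tf <- withr::local_tempfile(fileext = ".csv")
  bad <- rbind(cm$pairs[, c("i", "j")], data.frame(i = 1, j = 8))
  bad$e_coulomb <- 0; bad$e_vdw <- -1; bad$e_polar_solv <- 0
  bad$e_nonpolar_solv <- 0
  utils::write.csv(bad, tf, row.names = FALSE)
  expect_warning(build_energy_table(s, cm, mode = "from_file", file = tf),
                 "not in the contact map")
  expect_error(suppressWarnings(
    build_energy_table(s, cm, mode = "from_file", file = tf, strict = TRUE)))
})

test_that("denaturant attenuation scales, clamps and records state", {
  s <- make_toy_structure(toy_spec(list(c("helix", 8))))
  et <- build_energy_table(s, mode = "go_uniform")
  expect_equal(apply_denaturant(et, "urea", 0, 0.1)$pairs$e_total,
               et$pairs$e_total)
  half <- apply_denaturant(et, "urea", 5, 0.1)
  expect_equal(half$pairs$e_total, et$pairs$e_total / 2)
  expect_equal(half$denaturant_state,
               list(species = "urea", concentration = 5))
  expect_warning(cl <- apply_denaturant(et, "gdnhcl", 20, 0.1), "clamped")
  expect_true(all(cl$pairs$e_total == 0))
  expect_error(apply_denaturant(et, "urea", -1, 0.1), ">= 0")
})
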