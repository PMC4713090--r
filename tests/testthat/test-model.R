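R_GAS <- 1.987204e-3

loop_chain <- function(n) {
  wsme(energy = energy_table(n, data.frame(i = integer(0), j = integer(0),
                                           e_total = numeric(0))),
       entropy = entropy_profile(rep("turn_loop", n)))
}

test_that("configuration free energies evaluate the Hamiltonian exactly", {
  m <- toy_two_state()
  N <- m$n_residues
  expect_equal(config_free_energy(m, rep(0, N), 300), 0)
  expect_equal(config_free_energy(m, rep(1, N), 300),
               sum(m$energy$pairs$e_total) - 300 * sum(m$entropy$delta_s),
               tolerance = 1e-12)
  ## single native loop residue, no contacts: -T dS = 300 * 1.3e-3 kcal/mol
  ml <- loop_chain(6)
  expect_equal(config_free_energy(ml, c(0, 0, 1, 0, 0, 0), 300), 0.39,
               tolerance = 1e-12)
  ## a contact pays off only when the whole stretch is native
  pairs <- data.frame(i = 1, j = 4, e_total = -2)
  mc <- wsme(energy = energy_table(5, pairs),
             entropy = entropy_profile(rep("turn_loop", 5), ds_loop = 0))
  expect_equal(config_free_energy(mc, c(1, 1, 0, 1, 0), 300), 0)
  expect_equal(config_free_energy(mc, c(1, 1, 1, 1, 0), 300), -2)
  expect_error(config_free_energy(mc, c(1, 1), 300), "length")
})

test_that("stretch weights factorise entropy and close over hand values", {
  ml <- loop_chain(6)
  w1 <- stretch_weight(ml, 2, 2, 300)
  expect_equal(w1, exp(-1.3e-3 / R_GAS), tolerance = 1e-12)
  expect_equal(w1, 0.5199, tolerance = 1e-4)
  expect_equal(stretch_weight(ml, 2, 3, 300), w1^2, tolerance = 1e-12)
  m0 <- wsme(energy = energy_table(4, data.frame(i = integer(0),
                                                 j = integer(0),
                                                 e_total = numeric(0))),
             entropy = entropy_profile(rep("turn_loop", 4), ds_loop = 0))
  expect_equal(stretch_weight(m0, 1, 4, 300), 1)
})

test_that("brute-force partition function matches independent-site closure", {
  ml <- loop_chain(3)
  ## no contacts: sites independent, Z = (1 + w)^N
  w <- exp(-1.3e-3 / R_GAS)
  bf <- partition_function_bruteforce(ml, 300)
  expect_equal(exp(bf$log_z), (1 + w)^3, tolerance = 1e-12)
  expect_equal(exp(bf$log_z), 3.5115, tolerance = 1e-3)
  ## dS = 0: every configuration weighs 1
  m0 <- wsme(energy = energy_table(5, data.frame(i = integer(0),
                                                 j = integer(0),
                                                 e_total = numeric(0))),
             entropy = entropy_profile(rep("turn_loop", 5), ds_loop = 0))
  expect_equal(exp(partition_function_bruteforce(m0, 300)$log_z), 2^5)
  expect_error(partition_function_bruteforce(loop_chain(21), 300), "N > 20")
})

test_that("dynamic programming equals exhaustive enumeration on random models", {
  for (k in 1:25) {
    n <- 6 + (k %% 9)
    m <- random_model(n, seed = 1000 + k)
    Tk <- 250 + 20 * (k %% 5)
    bf <- partition_function_bruteforce(m, Tk)
    dp <- partition_function_dp(m, Tk)
    expect_equal(dp$log_z, bf$log_z, tolerance = 1e-12)
    reach <- is.finite(bf$log_zq)
    expect_identical(reach, is.finite(dp$log_zq))
    expect_lt(max(abs(exp(dp$log_zq[reach] - bf$log_zq[reach]) - 1)), 1e-10)
  }
})

test_that("restricted sums obey the partition identity at protein size", {
  m <- wsme(synthetic_mth1880())
  t0 <- Sys.time()
  pf <- partition_function_dp(m, 350)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(wsme:::logsumexp(pf$log_zq), pf$log_z, tolerance = 1e-12)
})

test_that("the high-temperature limit is the entropy-weighted binomial", {
  n <- 9
  m <- random_model(n, seed = 77)
  ds <- m$entropy$delta_s
  pf <- partition_function_dp(m, 1e9)
  ## energies vanish from the weights; per-residue factors exp(dS_k / R)
  ## summed over subsets of size q (oracle: explicit subset enumeration)
  w <- exp(ds / R_GAS)
  oracle <- vapply(0:n, function(q) {
    sets <- utils::combn(n, q)
    if (q == 0) return(1)
    sum(apply(matrix(w[sets], nrow = q), 2, prod))
  }, numeric(1))
  expect_equal(exp(pf$log_zq), oracle, tolerance = 1e-6)
})

test_that("zero-entropy zero-energy landscapes are exactly binomial", {
  n <- 30
  m0 <- wsme(energy = energy_table(n, data.frame(i = integer(0),
                                                 j = integer(0),
                                                 e_total = numeric(0))),
             entropy = entropy_profile(rep("turn_loop", n), ds_loop = 0))
  p <- free_energy_profile(m0, 300)
  RT <- R_GAS * 300
  expected <- -RT * lchoose(n, 0:n)
  expected <- expected - min(expected)
  expect_equal(p$dG, expected, tolerance = 1e-9)
  expect_equal(p$q[which.min(p$dG)], n / 2)
})

test_that("energy- and entropy-dominated limits pin the global minimum", {
  ## all-helix chain: every residue holds contacts, so at low temperature the
  ## fully native state is the global minimum
  m <- wsme(make_toy_structure(toy_spec(list(c("helix", 12)))))
  cold <- free_energy_profile(m, 10)
  expect_equal(cold$q[which.min(cold$dG)], m$n_residues)
  hot <- free_energy_profile(m, 2000)
  expect_lt(hot$M[which.min(hot$dG)], 0.35)
})

test_that("basin location reports barrier arithmetic on a hand profile", {
  RT <- R_GAS * 300
  mk_profile <- function(dG) {
    structure(list(q = seq_along(dG) - 1L, M = (seq_along(dG) - 1) /
                     (length(dG) - 1), dG = dG, dG_RT = dG / RT,
                   temperature = 300, log_zq = -dG / RT,
                   log_z = wsme:::logsumexp(-dG / RT), gas_constant = R_GAS,
                   denaturant_state = list(species = "none",
                                           concentration = 0)),
              class = "free_energy_profile")
  }
  b <- locate_basins(mk_profile(c(0, 3, 1)))
  expect_false(b$no_barrier)
  expect_equal(b$q_denatured, 0); expect_equal(b$q_native, 2)
  expect_equal(b$q_barrier, 1)
  expect_equal(b$barrier_height, 3 - 1)      # measured from the native basin
  ## monotone profile: flagged, split falls back to the midpoint
  mono <- locate_basins(mk_profile(c(0, 1, 2, 3, 4)))
  expect_true(mono$no_barrier)
  expect_equal(mono$q_barrier, 2)
  ## symmetric double well: equal basins
  ## the barrier bin itself joins the native-side sum, so symmetry holds to
  ## the barrier population RT*exp(-5/RT) ~ 1e-4, not to machine precision
  sym <- locate_basins(mk_profile(c(0, 5, 0)))
  expect_equal(sym$ddG_DN, 0, tolerance = 1e-3)
  expect_equal(sym$f_unfolded, 0.5, tolerance = 1e-2)
})

test_that("the melting temperature halves the unfolded population", {
  m <- toy_two_state()
  tm <- melting_temperature(m, 150, 900)
  expect_lt(abs(fraction_unfolded(m, tm) - 0.5), 1e-6)
  expect_lt(abs(ddG_DN(m, tm)), 1e-6)
  expect_error(melting_temperature(m, 2000, 3000), "no transition")
})

test_that("melting temperature matches an independent enumeration oracle", {
  ## 8-residue chain, one long contact: oracle enumerates all 2^8 weights
  ## directly from the Hamiltonian, splits basins at the landscape maximum,
  ## and solves ddG(T) = 0 with uniroot
  n <- 8
  pairs <- data.frame(i = 1, j = n, e_total = -6)
  ss <- rep("turn_loop", n)
  m <- wsme(energy = energy_table(n, pairs), entropy = entropy_profile(ss))
  ds <- -1.3e-3
  oracle_ddG <- function(T) {
    cfg <- as.matrix(expand.grid(rep(list(0:1), n)))
    e <- ifelse(rowSums(cfg) == n, -6, 0)
    g <- e - T * ds * rowSums(cfg)
    wgt <- exp(-g / (R_GAS * T))
    zq <- tapply(wgt, rowSums(cfg), sum)
    dG <- -R_GAS * T * log(zq)
    qs <- as.integer(names(zq))
    mins <- which(diff(sign(diff(c(Inf, dG, Inf)))) > 0)
    qb <- if (length(mins) < 2) floor(n / 2) else {
      deep <- mins[order(dG[mins])][1:2]
      qs[which.max(dG[min(deep):max(deep)]) + min(deep) - 1]
    }
    -R_GAS * T * (log(sum(wgt[rowSums(cfg) < qb])) -
                    log(sum(wgt[rowSums(cfg) >= qb])))
  }
  t_oracle <- stats::uniroot(oracle_ddG, c(200, 1500), tol = 1e-9)$root
  t_pkg <- melting_temperature(m, 200, 1500)
  expect_equal(t_pkg, t_oracle, tolerance = 1e-4)
})

test_that("T_m tracks the energy-to-entropy ratio under rescaling", {
  ## scaling contact energies and entropy costs together preserves every
  ## configuration energy ratio; T_m moves only through the unscaled
  ## configurational mixing entropy, an order of magnitude less than when
  ## the energies are scaled alone
  m <- toy_two_state()
  tm1 <- melting_temperature(m, 150, 900)
  m2 <- scale_energies(m, 1.7)
  m2$entropy$delta_s <- m2$entropy$delta_s * 1.7
  tm_joint <- melting_temperature(m2, 150, 900)
  tm_energy <- melting_temperature(scale_energies(m, 1.7), 150, 1500)
  expect_lt(abs(tm_joint - tm1), 0.15 * abs(tm_energy - tm1))
  expect_gt(tm_energy, tm1 * 1.3)
})

test_that("unfolded fraction rises monotonically through the transition", {
  m <- toy_two_state()
  f <- vapply(seq(180, 700, length.out = 40),
              function(T) fraction_unfolded(m, T), numeric(1))
  ## strictly monotone through the transition; tiny basin-reassignment
  ## artefacts are tolerated only in the saturated tails
  core <- f > 1e-3 & f < 0.999
  expect_true(all(diff(f[core]) > -1e-10))
  expect_true(all(diff(f) > -0.005))
  expect_lt(f[1], 0.01)
  expect_gt(f[40], 0.9)
})

test_that("denaturation midpoints honour a constructed root and shift with T", {
  m <- toy_two_state()
  t_eval <- melting_temperature(m, 150, 900) - 30   # folded at zero denaturant
  lam <- attr(calibrate_tm(m, t_eval), "lambda")
  alpha <- 0.08
  c_star <- (1 - lam) / alpha
  cm <- mid_concentration(m, t_eval, "urea", alpha, 0, 12)
  expect_equal(cm, c_star, tolerance = 1e-3)
  expect_lt(abs(fraction_unfolded(
    wsme(energy = suppressWarnings(
      apply_denaturant(m$energy, "urea", cm, alpha)),
      entropy = m$entropy), t_eval) - 0.5), 1e-6)
  expect_error(mid_concentration(m, t_eval, "urea", 0, 0, 12),
               "no transition")
  ## higher temperature leaves less stability for the denaturant to erase
  cms <- vapply(t_eval + c(-20, 0, 10),
                function(T) mid_concentration(m, T, "urea", alpha, 0, 12),
                numeric(1))
  expect_true(all(diff(cms) < 0))
})

test_that("uniform go models depend only on contact topology", {
  s1 <- make_toy_structure(toy_spec(list(c("helix", 8), c("loop", 4))))
  cm1 <- contact_map(s1)
  ss <- rep("turn_loop", 12)
  m1 <- wsme(energy = build_energy_table(s1, cm1, mode = "go_uniform"),
             entropy = entropy_profile(ss))
  m2 <- wsme(energy = energy_table(12, transform(cm1$pairs[, c("i", "j")],
                                                 e_total = -1)),
             entropy = entropy_profile(ss))
  expect_equal(partition_function_dp(m1, 320)$log_zq,
               partition_function_dp(m2, 320)$log_zq, tolerance = 1e-12)
})

test_that("model object methods expose the fit surface", {
  m <- toy_two_state()
  expect_output(print(m), "Wako-Saito")
  expect_s3_class(predict(m, 300), "free_energy_profile")
  f2 <- predict(m, c(250, 400), what = "fraction_unfolded")
  expect_length(f2, 2)
  expect_true(all(f2 >= 0 & f2 <= 1))
  expect_named(coef(m)[1], "E_1:19")   # first cross-strand contact
  sims <- simulate(m, nsim = 500, seed = 9, temperature = 250)
  expect_true(all(sims$q >= 0 & sims$q <= m$n_residues))
  pf <- partition_function_dp(m, 250)
  expect_equal(mean(sims$q), sum((0:20) * exp(pf$log_zq - pf$log_z)),
               tolerance = 0.15)
  sm <- summary(m)
  expect_s3_class(sm, "summary.wsme_model")
  expect_false(is.na(sm$t_m))
})
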