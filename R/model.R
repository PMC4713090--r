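#' Per-residue conformational entropy reductions
#'
#' Ordering a residue into its native dihedral state costs conformational
#' entropy: -3.8 cal/(mol K) for helix or sheet residues, -1.3 cal/(mol K)
#' for turn/loop residues under the default assignment.  Values are stored
#' internally in kcal/(mol K); the `unit` knob states the unit of the supplied
#' numbers.
#'
#' @param ss character vector of classes (`"helix"`, `"sheet"`, `"turn_loop"`).
#' @param ds_helix_sheet,ds_loop entropy reduction for structured and for
#'   turn/loop residues (negative, in `unit`).
#' @param unit `"cal"` (default) or `"kcal"` per mol per K.
#' @return Object of class `entropy_profile`: list with `delta_s`
#'   (kcal/(mol K), one per residue) and `ss`.
#' @export
entropy_profile <- function(ss, ds_helix_sheet = -3.8, ds_loop = -1.3,
                            unit = c("cal", "kcal")) {
  unit <- match.arg(unit)
  ss <- normalize_ss(ss, length(ss))
  ds <- ifelse(ss %in% c("helix", "sheet"), ds_helix_sheet, ds_loop)
  if (unit == "cal") ds <- ds / 1000
  if (any(ds > 0))
    stop_validation("entropy reductions must be <= 0")
  structure(list(delta_s = ds, ss = ss), class = "entropy_profile")
}

#' Fit/assemble a Wako-Saito-Munoz-Eaton folding model
#'
#' Builds the residue-level spin model of folding for a structure: binary
#' native/disordered state per residue, native-contact interaction energies
#' active only across fully native stretches, and per-residue entropy costs.
#' The conformational free energy of a configuration \eqn{\{m_k\}} is
#' \deqn{\Delta G = \sum_{\langle i,j\rangle, j \ge i+3} E_{ij}
#'   \prod_{k=i}^{j} m_k - T \sum_k \Delta S_k m_k,}
#' with \eqn{E_{ij}} the (sequence-dependent) contact energy and
#' \eqn{\Delta S_k \le 0} the entropy reduction on ordering residue k.
#' Because a contact contributes only when the whole interval i..j is native,
#' the Boltzmann weight of any configuration factorises over its maximal
#' native stretches, which makes the partition function exactly computable in
#' polynomial time (see [partition_function_dp()]).
#'
#' @param s a `protein_structure` (or `NULL` when `energy` and `entropy` are
#'   supplied ready-made).
#' @param energy an `energy_table`, or a mode string passed to
#'   [build_energy_table()] (`"go_uniform"`, `"atomistic_single_structure"`,
#'   `"from_file"`).
#' @param entropy an [entropy_profile()]; built from the structure's
#'   secondary-structure annotation by default.
#' @param cutoff,min_separation contact-map parameters.
#' @param go_epsilon,file,dielectric passed to [build_energy_table()].
#' @param ds_helix_sheet,ds_loop,ds_unit passed to [entropy_profile()].
#' @return Object of class `wsme_model` with elements `energy`
#'   (`energy_table`), `entropy` (`entropy_profile`), `n_residues` and
#'   `gas_constant` (kcal/(mol K)).
#' @examples
#' toy <- make_toy_structure(toy_spec(list(c("helix", 10), c("loop", 4),
#'                                         c("helix", 8)), seed = 1))
#' m <- wsme(toy)
#' m
#' tm <- melting_temperature(m, 200, 600)
#' fraction_unfolded(m, tm)  # 0.5 at the midpoint
#' @export
wsme <- function(s = NULL, energy = "go_uniform", entropy = NULL,
                 cutoff = 6.5, min_separation = 3L, go_epsilon = -1.0,
                 file = NULL, dielectric = "4r",
                 ds_helix_sheet = -3.8, ds_loop = -1.3, ds_unit = "cal") {
  if (is.character(energy)) {
    if (is.null(s))
      stop_validation("a structure is needed to build the energy table")
    cm <- contact_map(s, cutoff = cutoff, min_separation = min_separation)
    energy <- build_energy_table(s, cm, mode = energy,
                                 go_epsilon = go_epsilon, file = file,
                                 dielectric = dielectric)
  }
  stopifnot(inherits(energy, "energy_table"))
  if (is.null(entropy)) {
    if (is.null(s))
      stop_validation("an entropy profile is needed when no structure is given")
    entropy <- entropy_profile(s$residues$ss, ds_helix_sheet, ds_loop, ds_unit)
  }
  stopifnot(inherits(entropy, "entropy_profile"))
  if (length(entropy$delta_s) != energy$n_residues)
    stop_validation("entropy profile length ", length(entropy$delta_s),
                    " != number of residues ", energy$n_residues)
  structure(list(energy = energy, entropy = entropy,
                 n_residues = energy$n_residues,
                 gas_constant = GAS_CONSTANT),
            class = "wsme_model")
}

#' @export
print.wsme_model <- function(x, ...) {
  cat("Wako-Saito-Munoz-Eaton model: N =", x$n_residues, "residues,",
      nrow(x$energy$pairs), "native contacts (", x$energy$mode, ")\n")
  cat("  total contact energy:", sprintf("%.3f", sum(x$energy$pairs$e_total)),
      "kcal/mol; total entropy cost at 300 K:",
      sprintf("%.3f", -300 * sum(x$entropy$delta_s)), "kcal/mol\n")
  ds <- x$energy$denaturant_state
  if (ds$species != "none")
    cat("  denaturant:", ds$species, "at", ds$concentration, "M\n")
  invisible(x)
}

#' Free energy of one spin configuration
#'
#' Direct evaluation of the Hamiltonian: contact energies gated by the
#' all-native product over the enclosed stretch, minus T times the summed
#' entropy reductions of the native residues.
#'
#' @param model a `wsme_model`.
#' @param m binary vector of length N (1 = native).
#' @param temperature kelvin.
#' @return Free energy in kcal/mol; exactly 0 for the all-zero configuration.
#' @export
config_free_energy <- function(model, m, temperature) {
  N <- model$n_residues
  if (length(m) != N || !all(m %in% c(0, 1)))
    stop_validation("'m' must be a binary vector of length ", N)
  p <- model$energy$pairs
  e <- 0
  if (nrow(p)) {
    cs <- cumsum(m)
    full <- (cs[p$j] - cs[p$i] + m[p$i]) == (p$j - p$i + 1)
    e <- sum(p$e_total[full])
  }
  e - temperature * sum(model$entropy$delta_s * m)
}

## internal contact-energy matrix: E_int[i, j] = sum of contact energies fully
## inside the interval [i, j]
internal_energy_matrix <- function(model) {
  N <- model$n_residues
  p <- model$energy$pairs
  E <- matrix(0, N, N)
  if (nrow(p)) {
    for (j in sort(unique(p$j))) {
      contrib <- numeric(N)
      sel <- p$j == j
      contrib[p$i[sel]] <- p$e_total[sel]
      ## sum over contacts (k, j) with k >= i
      E[, j] <- rev(cumsum(rev(contrib)))
    }
    for (j in 2:N) E[, j] <- E[, j] + E[, j - 1L]
  }
  E
}

#' Boltzmann weight of a single native stretch
#'
#' For a maximal native stretch from residue i to j the weight is
#' \deqn{\omega_{j,i} = \exp[-(1/RT)(\sum E_{kl} - T \sum_{k=i}^{j}
#'   \Delta S_k)],}
#' where the energy sum runs over contacts contained in the stretch (empty
#' for stretches shorter than the minimum contact separation, leaving an
#' entropy-only weight).  The weight of any configuration is the product of
#' its stretch weights.
#'
#' @param model a `wsme_model`.
#' @param i,j stretch boundaries, `i <= j`.
#' @param temperature kelvin.
#' @return Dimensionless weight.
#' @export
stretch_weight <- function(model, i, j, temperature) {
  if (i > j) stop_validation("need i <= j")
  RT <- model$gas_constant * temperature
  E <- internal_energy_matrix(model)[i, j]
  S <- sum(model$entropy$delta_s[i:j])
  exp(-(E - temperature * S) / RT)
}

#' Exact partition function by exhaustive enumeration
#'
#' Sums the Boltzmann weights of all 2^N configurations, binned by the number
#' of native residues q.  Feasible only for small chains (N <= 20); serves as
#' the independent oracle for [partition_function_dp()].
#'
#' @param model a `wsme_model` with `n_residues <= 20`.
#' @param temperature kelvin.
#' @return List with `log_z` and `log_zq` (length N + 1, q = 0..N).
#' @export
partition_function_bruteforce <- function(model, temperature) {
  N <- model$n_residues
  if (N > 20L)
    stop("brute-force enumeration refused for N > 20 (got ", N, ")",
         call. = FALSE)
  RT <- model$gas_constant * temperature
  p <- model$energy$pairs
  ds <- model$entropy$delta_s
  log_zq <- rep(-Inf, N + 1L)
  total <- 2^N
  chunk <- 65536L
  for (start in seq(0, total - 1, by = chunk)) {
    cfgs <- start:min(start + chunk - 1, total - 1)
    bits <- matrix(0L, length(cfgs), N)
    for (k in seq_len(N))
      bits[, k] <- bitwAnd(cfgs %/% (2^(k - 1)), 1L)
    q <- rowSums(bits)
    en <- numeric(length(cfgs))
    if (nrow(p)) {
      cs <- t(apply(bits, 1L, cumsum))
      for (r in seq_len(nrow(p))) {
        i <- p$i[r]; j <- p$j[r]
        full <- (cs[, j] - cs[, i] + bits[, i]) == (j - i + 1)
        en[full] <- en[full] + p$e_total[r]
      }
    }
    g <- en - temperature * as.vector(bits %*% ds)
    lw <- -g / RT
    for (qq in unique(q)) {
      sel <- q == qq
      log_zq[qq + 1L] <- logsumexp(c(log_zq[qq + 1L], lw[sel]))
    }
  }
  list(log_z = logsumexp(log_zq), log_zq = log_zq)
}

#' Exact partition function by stretch dynamic programming
#'
#' Uses the exact factorisation of configuration weights over maximal native
#' stretches: scanning the chain once, each position either stays disordered
#' or terminates a native stretch \[i..p\] (preceded by a disordered residue),
#' whose weight is [stretch_weight()].  The number of native residues q is
#' tracked alongside, giving all restricted partition functions Z_q in a
#' single O(N^2) sweep over stretches.  All accumulation is done in the log
#' domain (log-sum-exp), so kcal-scale energies at N ~ 90 cannot overflow.
#'
#' @param model a `wsme_model`.
#' @param temperature kelvin.
#' @return List with `log_z` and `log_zq` (length N + 1, q = 0..N).
#' @export
partition_function_dp <- function(model, temperature) {
  N <- model$n_residues
  RT <- model$gas_constant * temperature
  ds <- model$entropy$delta_s
  E <- internal_energy_matrix(model)
  cs <- cumsum(ds)
  ## logw[i, p]: weight of native stretch [i..p]
  ## L[p + 1, ]: log partition over residues 1..p, by q (columns q = 0..N)
  L <- matrix(-Inf, N + 1L, N + 1L)
  L[1L, 1L] <- 0
  for (p in seq_len(N)) {
    cand <- matrix(-Inf, p + 1L, N + 1L)
    cand[1L, ] <- L[p, ]                       # residue p disordered
    for (i in seq_len(p)) {                    # last stretch is [i..p]
      len <- p - i + 1L
      s_sum <- cs[p] - if (i > 1L) cs[i - 1L] else 0
      logw <- -(E[i, p] - temperature * s_sum) / RT
      prefix <- L[max(i - 1L, 1L), ]           # residues 1..(i-2); row i-1
      cand[i + 1L, (len + 1L):(N + 1L)] <- prefix[1L:(N + 1L - len)] + logw
    }
    mx <- apply(cand, 2L, max)
    fin <- is.finite(mx)
    out <- mx
    if (any(fin))
      out[fin] <- mx[fin] +
        log(colSums(exp(sweep(cand[, fin, drop = FALSE], 2L, mx[fin], "-"))))
    L[p + 1L, ] <- out
  }
  log_zq <- L[N + 1L, ]
  list(log_z = logsumexp(log_zq), log_zq = log_zq)
}

#' Free-energy landscape over the number of native residues
#'
#' \eqn{\Delta G(q) = -RT \log Z_q}, shifted so the global minimum is zero.
#' q runs from 0 (fully denatured) to N (fully native); the conventional
#' reaction coordinate is M = q/N.
#'
#' @param model a `wsme_model`.
#' @param temperature kelvin.
#' @return Object of class `free_energy_profile`: data-frame-like list with
#'   `q`, `M`, `dG` (kcal/mol, min 0), `dG_RT`, plus `temperature`,
#'   `log_zq`, `log_z` and the model's denaturant state.
#' @export
free_energy_profile <- function(model, temperature) {
  pf <- partition_function_dp(model, temperature)
  RT <- model$gas_constant * temperature
  dG <- -RT * pf$log_zq
  dG <- dG - min(dG[is.finite(dG)])
  N <- model$n_residues
  structure(list(q = 0:N, M = (0:N) / N, dG = dG, dG_RT = dG / RT,
                 temperature = temperature, log_zq = pf$log_zq,
                 log_z = pf$log_z, gas_constant = model$gas_constant,
                 denaturant_state = model$energy$denaturant_state),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("Free-energy profile at", x$temperature, "K over q = 0..",
      max(x$q), "\n", sep = " ")
  b <- locate_basins(x)
  if (b$no_barrier) {
    cat("  single basin at M =", sprintf("%.3f", b$q_native / max(x$q)), "\n")
  } else {
    cat(sprintf("  basins at M = %.3f (denatured) and %.3f (native); barrier %.2f kcal/mol (%.2f RT) at M = %.3f\n",
                b$q_denatured / max(x$q), b$q_native / max(x$q),
                b$barrier_height, b$barrier_height_RT, b$q_barrier / max(x$q)))
    cat(sprintf("  ddG_D-N = %.3f kcal/mol, fraction unfolded = %.4f\n",
                b$ddG_DN, b$f_unfolded))
  }
  invisible(x)
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  graphics::plot(x$M, x$dG, type = "l", xlab = "M = q/N",
                 ylab = expression(Delta * G ~ "(kcal/mol)"),
                 main = sprintf("T = %.1f K", x$temperature), ...)
  graphics::points(x$M, x$dG, pch = 16, cex = 0.4)
  invisible(x)
}

#' Write a landscape to CSV (q, M, dG in kcal/mol and RT units)
#' @param profile a `free_energy_profile`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(data.frame(q = profile$q, M = profile$M,
                              dG_kcal_mol = profile$dG, dG_RT = profile$dG_RT),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## plateau-collapsed local minima of a numeric vector (indices)
local_minima <- function(y) {
  n <- length(y)
  pad <- c(Inf, y, Inf)
  out <- integer(0)
  k <- 1L
  while (k <= n) {
    ## plateau [k..k2]
    k2 <- k
    while (k2 < n && y[k2 + 1L] == y[k]) k2 <- k2 + 1L
    if (pad[k] > y[k] && pad[k2 + 2L] > y[k])
      out <- c(out, k + (k2 - k) %/% 2L)
    k <- k2 + 1L
  }
  out
}

#' Locate folding basins, barrier and two-state observables on a landscape
#'
#' Finds the denatured and native basins (the two deepest local minima of
#' \eqn{\Delta G(q)}) and the highest maximum between them.  Basin free
#' energies are the restricted sums \eqn{-RT \log \sum_{basin} Z_q} with the
#' split at the barrier position, giving
#' \eqn{\Delta\Delta G_{D-N} = \Delta G_D - \Delta G_N} (positive when the
#' native basin is more stable) and the unfolded fraction
#' \eqn{f_U = \sum_{q < q^*} Z_q / Z}.  Single-minimum landscapes are flagged
#' `no_barrier` and fall back to a split at q = N/2.
#'
#' @param profile a `free_energy_profile`.
#' @return Object of class `basin_summary`: list with `q_native`,
#'   `q_denatured`, `q_barrier`, `barrier_height` (kcal/mol),
#'   `barrier_height_RT`, `ddG_DN` (kcal/mol), `f_unfolded`, `M_native`,
#'   `M_denatured`, `M_barrier`, `no_barrier`.
#' @export
locate_basins <- function(profile) {
  stopifnot(inherits(profile, "free_energy_profile"))
  dG <- profile$dG
  q <- profile$q
  N <- max(q)
  RT <- profile$gas_constant * profile$temperature
  mins <- local_minima(dG)
  no_barrier <- length(mins) < 2L
  if (no_barrier) {
    q_star <- floor(N / 2)
    qn <- q[which.min(dG)]
    res <- list(q_native = qn, q_denatured = qn, q_barrier = q_star,
                barrier_height = 0, barrier_height_RT = 0)
  } else {
    deep <- mins[order(dG[mins])][1:2]
    lo <- min(deep); hi <- max(deep)
    between <- (lo + 1L):(hi - 1L)
    qb_idx <- between[which.max(dG[between])]
    qd <- q[lo]; qn <- q[hi]
    barrier <- dG[qb_idx] - dG[hi]
    res <- list(q_native = qn, q_denatured = qd, q_barrier = q[qb_idx],
                barrier_height = barrier, barrier_height_RT = barrier / RT)
    q_star <- q[qb_idx]
  }
  split <- q < q_star
  log_zd <- logsumexp(profile$log_zq[split])
  log_zn <- logsumexp(profile$log_zq[!split])
  res$ddG_DN <- -RT * (log_zd - log_zn)
  res$f_unfolded <- exp(log_zd - profile$log_z)
  res$M_native <- res$q_native / N
  res$M_denatured <- res$q_denatured / N
  res$M_barrier <- q_star / N
  res$no_barrier <- no_barrier
  class(res) <- "basin_summary"
  res
}

#' @export
print.basin_summary <- function(x, ...) {
  if (x$no_barrier) {
    cat("Single-basin landscape (no barrier); minimum at M =",
        sprintf("%.3f", x$M_native), "\n")
  } else {
    cat(sprintf("Two-state landscape: native M = %.3f, denatured M = %.3f\n",
                x$M_native, x$M_denatured))
    cat(sprintf("  barrier %.3f kcal/mol (%.2f RT) at M = %.3f\n",
                x$barrier_height, x$barrier_height_RT, x$M_barrier))
  }
  cat(sprintf("  ddG_D-N = %.3f kcal/mol, fraction unfolded = %.4f\n",
              x$ddG_DN, x$f_unfolded))
  invisible(x)
}

#' Two-state observables as functions of temperature
#'
#' @param model a `wsme_model`.
#' @param temperature kelvin.
#' @return `fraction_unfolded()`: unfolded fraction in \[0, 1\];
#'   `ddG_DN()`: denatured-minus-native basin free energy, kcal/mol.
#' @export
fraction_unfolded <- function(model, temperature) {
  locate_basins(free_energy_profile(model, temperature))$f_unfolded
}

#' @rdname fraction_unfolded
#' @export
ddG_DN <- function(model, temperature) {
  locate_basins(free_energy_profile(model, temperature))$ddG_DN
}

#' Melting temperature by bisection
#'
#' The melting temperature is the root of
#' \eqn{\Delta\Delta G_{D-N}(T) = 0}, equivalently where the unfolded
#' fraction crosses 0.5.  Bisection is used (rather than a derivative-based
#' method) because basin reassignment makes the objective only piecewise
#' smooth; iterations continue until the unfolded fraction at the midpoint is
#' 0.5 to within `tol_f`.
#'
#' @param model a `wsme_model`.
#' @param t_low,t_high bracketing temperatures in kelvin;
#'   \eqn{\Delta\Delta G} must change sign on the interval.
#' @param tol temperature tolerance in kelvin.
#' @param tol_f tolerance on |f_U - 0.5| (default 1e-9).
#' @return The melting temperature T_m in kelvin.
#' @export
melting_temperature <- function(model, t_low, t_high, tol = 0.01,
                                tol_f = 1e-9) {
  f <- function(T) ddG_DN(model, T)
  g_lo <- f(t_low); g_hi <- f(t_high)
  if (sign(g_lo) == sign(g_hi))
    stop("no transition in range [", t_low, ", ", t_high, "] K", call. = FALSE)
  for (it in seq_len(200L)) {
    mid <- (t_low + t_high) / 2
    g <- f(mid)
    fu <- fraction_unfolded(model, mid)
    if (abs(fu - 0.5) < tol_f || (t_high - t_low) < min(tol, 1e-10) ||
        g == 0) break
    if (sign(g) == sign(g_lo)) t_low <- mid else t_high <- mid
  }
  mid
}

#' Denaturation mid-concentration by bisection
#'
#' Finds, at fixed temperature, the denaturant concentration at which the
#' native and denatured basins are iso-stable (\eqn{\Delta\Delta G_{D-N}=0},
#' unfolded fraction 0.5), with the contact energies attenuated by
#' [apply_denaturant()].
#'
#' @param model a `wsme_model` (denaturant-free reference energies).
#' @param temperature kelvin.
#' @param species `"urea"` or `"gdnhcl"`.
#' @param alpha attenuation per molar.
#' @param c_low,c_high bracketing concentrations, mol/L.
#' @param tol concentration tolerance, mol/L.
#' @param tol_f tolerance on |f_U - 0.5|.
#' @return The mid-concentration C_m in mol/L.
#' @export
mid_concentration <- function(model, temperature, species = "urea", alpha,
                              c_low = 0, c_high = 10, tol = 0.001,
                              tol_f = 1e-9) {
  at_c <- function(conc) {
    m <- model
    m$energy <- suppressWarnings(
      apply_denaturant(model$energy, species, conc, alpha))
    m
  }
  f <- function(conc) ddG_DN(at_c(conc), temperature)
  g_lo <- f(c_low); g_hi <- f(c_high)
  if (sign(g_lo) == sign(g_hi))
    stop("no transition in range [", c_low, ", ", c_high, "] M", call. = FALSE)
  for (it in seq_len(200L)) {
    mid <- (c_low + c_high) / 2
    g <- f(mid)
    fu <- fraction_unfolded(at_c(mid), temperature)
    if (abs(fu - 0.5) < tol_f || (c_high - c_low) < min(tol, 1e-12) ||
        g == 0) break
    if (sign(g) == sign(g_lo)) c_low <- mid else c_high <- mid
  }
  mid
}

#' Rescale all contact energies by a factor
#'
#' @param model a `wsme_model`.
#' @param lambda multiplicative factor applied to every energy component.
#' @return The rescaled model.
#' @export
scale_energies <- function(model, lambda) {
  cols <- c("e_coulomb", "e_vdw", "e_polar_solv", "e_nonpolar_solv", "e_total")
  model$energy$pairs[cols] <- model$energy$pairs[cols] * lambda
  model
}

#' Calibrate contact energies to a target melting temperature
#'
#' Rescales all contact energies by a single factor lambda so that the
#' denatured and native basins are iso-stable
#' (\eqn{\Delta\Delta G_{D-N} = 0}) at the given temperature.  Stability is
#' monotone in lambda, so bisection converges; used to pin surrogate
#' (single-structure or uniform) energies to an experimentally measured T_m.
#'
#' @param model a `wsme_model`.
#' @param t_target target melting temperature, kelvin.
#' @param lambda_low,lambda_high bracketing scale factors.
#' @param tol tolerance on lambda.
#' @return The calibrated `wsme_model` (with attribute `"lambda"`).
#' @export
calibrate_tm <- function(model, t_target, lambda_low = 0.01,
                         lambda_high = 100, tol = 1e-10) {
  f <- function(l) ddG_DN(scale_energies(model, l), t_target)
  g_lo <- f(lambda_low); g_hi <- f(lambda_high)
  if (sign(g_lo) == sign(g_hi))
    stop("cannot bracket the target melting temperature with lambda in [",
         lambda_low, ", ", lambda_high, "]", call. = FALSE)
  for (it in seq_len(200L)) {
    mid <- (lambda_low + lambda_high) / 2
    g <- f(mid)
    if (abs(g) < 1e-10 || (lambda_high - lambda_low) < tol) break
    if (sign(g) == sign(g_lo)) lambda_low <- mid else lambda_high <- mid
  }
  out <- scale_energies(model, mid)
  attr(out, "lambda") <- mid
  out
}

#' Scan two-state observables over temperature or concentration
#'
#' @param model a `wsme_model`.
#' @param temperatures kelvin grid.
#' @return Data frame with columns `temperature`, `f_unfolded`, `ddG_DN`
#'   (kcal/mol) and `barrier_RT`.
#' @export
melt_scan <- function(model, temperatures) {
  rows <- lapply(temperatures, function(T) {
    b <- locate_basins(free_energy_profile(model, T))
    data.frame(temperature = T, f_unfolded = b$f_unfolded, ddG_DN = b$ddG_DN,
               barrier_RT = b$barrier_height_RT)
  })
  do.call(rbind, rows)
}

#' @rdname melt_scan
#' @param concentrations mol/L grid.
#' @param species,alpha denaturant model, see [apply_denaturant()].
#' @export
denaturation_scan <- function(model, temperature, concentrations,
                              species = "urea", alpha) {
  rows <- lapply(concentrations, function(conc) {
    m <- model
    m$energy <- suppressWarnings(
      apply_denaturant(model$energy, species, conc, alpha))
    b <- locate_basins(free_energy_profile(m, temperature))
    data.frame(concentration = conc, f_unfolded = b$f_unfolded,
               ddG_DN = b$ddG_DN, barrier_RT = b$barrier_height_RT)
  })
  do.call(rbind, rows)
}

#' @export
summary.wsme_model <- function(object, t_low = 150, t_high = 800, ...) {
  tm <- tryCatch(melting_temperature(object, t_low, t_high),
                 error = function(e) NA_real_)
  out <- list(model = object, t_m = tm)
  if (!is.na(tm)) out$basins_at_tm <- locate_basins(
    free_energy_profile(object, tm))
  class(out) <- "summary.wsme_model"
  out
}

#' @export
print.summary.wsme_model <- function(x, ...) {
  print(x$model)
  if (is.na(x$t_m)) {
    cat("  no folding transition found in the scanned temperature range\n")
  } else {
    cat(sprintf("  T_m = %.2f K (%.2f degC)\n", x$t_m, x$t_m - 273.15))
    print(x$basins_at_tm)
  }
  invisible(x)
}

#' @export
predict.wsme_model <- function(object, temperature,
                               what = c("profile", "fraction_unfolded",
                                        "ddG_DN"), ...) {
  what <- match.arg(what)
  switch(what,
         profile = if (length(temperature) == 1L)
           free_energy_profile(object, temperature)
         else lapply(temperature, free_energy_profile, model = object),
         fraction_unfolded = vapply(temperature, function(T)
           fraction_unfolded(object, T), numeric(1)),
         ddG_DN = vapply(temperature, function(T)
           ddG_DN(object, T), numeric(1)))
}

#' @export
coef.wsme_model <- function(object, ...) {
  p <- object$energy$pairs
  stats::setNames(p$e_total, paste0("E_", p$i, ":", p$j))
}

#' @export
plot.wsme_model <- function(x, temperature = 300, ...) {
  if (length(temperature) == 1L) {
    plot(free_energy_profile(x, temperature), ...)
  } else {
    profs <- lapply(temperature, free_energy_profile, model = x)
    ylim <- range(unlist(lapply(profs, `[[`, "dG")))
    graphics::plot(NULL, xlim = c(0, 1), ylim = ylim, xlab = "M = q/N",
                   ylab = expression(Delta * G ~ "(kcal/mol)"), ...)
    cols <- grDevices::hcl.colors(length(profs), "Zissou 1")
    for (k in seq_along(profs))
      graphics::lines(profs[[k]]$M, profs[[k]]$dG, col = cols[k])
    graphics::legend("top", legend = sprintf("%.0f K", temperature),
                     col = cols, lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' @export
simulate.wsme_model <- function(object, nsim = 1, seed = NULL,
                                temperature = 300, ...) {
  pf <- partition_function_dp(object, temperature)
  prob <- exp(pf$log_zq - pf$log_z)
  draw <- function() sample(0:object$n_residues, nsim, replace = TRUE,
                            prob = prob)
  q <- if (is.null(seed)) draw() else with_seed(seed, draw())
  data.frame(sim = seq_len(nsim), q = q, M = q / object$n_residues)
}
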