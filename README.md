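# wsme — sequence-dependent Wako-Saitô-Muñoz-Eaton folding models

`wsme` is an R package for the equilibrium statistical mechanics of
two-state protein folding.  It is aimed at structural biologists and
biophysicists who have a folded structure (PDB), melting or denaturation
curves, and/or NMR shift tables, and want a quantitative, residue-level
thermodynamic picture: free-energy landscapes, folding barriers, melting
temperatures and denaturation midpoints.

## The model

Each residue carries a binary state $m_k \in \{0,1\}$ (native /
disordered).  The conformational free energy of a configuration is

$$\Delta G(\{m_k\}) = \sum_{\langle i,j\rangle,\,j\ge i+3} E_{ij}
  \prod_{k=i}^{j} m_k \;-\; T \sum_k \Delta S_k m_k,$$

with the pair sum over the native contact map (Cα distance ≤ 6.5 Å),
$E_{ij}$ sequence-dependent contact energies (Coulomb + Lennard-Jones +
generalized-Born polar solvation + buried-nonpolar-area terms, or a uniform
Gō energy, or a user-supplied table), and $\Delta S_k$ the conformational
entropy cost of ordering residue $k$ (−3.8 cal mol⁻¹ K⁻¹ for helix/sheet,
−1.3 for turn/loop).  Because a contact only counts when the whole stretch
between its partners is native, configuration weights factorise over native
stretches and *all* restricted partition functions $Z_q$ (q = number of
native residues) are computed **exactly** by a polynomial-time dynamic
program, validated against $2^N$ enumeration.  From $\Delta G(q) = -RT\log
Z_q$ the package locates basins, the folding barrier,
$\Delta\Delta G_{D\text{-}N}$, the unfolded fraction, $T_m$ and $C_m$.

Alongside the core model: Shrake-Rupley solvent-accessible surface areas,
ensemble observables (radius of gyration, RMSF, covariance/correlation
matrices), two-state sigmoid fits of melting curves, chemical-shift
perturbation profiles, and deterministic synthetic-data generators for all
inputs (toy structures, an 88-residue synthetic α/β fold, Gaussian
coordinate ensembles, noisy melting curves, shift tables).

## Worked example

```r
library(wsme)

## a 20-residue helix-loop-helix chain from the toy generator
s <- make_toy_structure(toy_spec(list(c("helix", 8), c("loop", 4),
                                      c("helix", 8))))
m <- wsme(s)                 # uniform Go energies on the 6.5 A contact map
summary(m)
#> Wako-Saito-Munoz-Eaton model: N = 20 residues, 18 native contacts ( go_uniform )
#>   total contact energy: -18.000 kcal/mol; total entropy cost at 300 K: 19.800 kcal/mol
#>   T_m = 268.61 K (-4.54 degC)
#> Two-state landscape: native M = 0.850, denatured M = 0.500
#>   barrier 1.000 kcal/mol (1.87 RT) at M = 0.650
#>   ddG_D-N = -0.000 kcal/mol, fraction unfolded = 0.5000
```

The summary reports the melting temperature (where the denatured and native
basins are iso-stable and half the population is unfolded), the positions of
the two basins on the native-fraction coordinate M = q/N, and the barrier
between them in kcal/mol and units of RT.

At protein scale, with the energy scale calibrated to an experimental
mid-temperature of 76 °C:

```r
model <- calibrate_tm(wsme(synthetic_mth1880()), 349.15)
locate_basins(free_energy_profile(model, 349.15))
#> Two-state landscape: native M = 0.943, denatured M = 0.205
#>   barrier 5.713 kcal/mol (8.23 RT) at M = 0.625
#>   ddG_D-N = 0.000 kcal/mol, fraction unfolded = 0.5000
```

a single-barrier, two-state landscape: the hallmark of cooperative folding
without populated intermediates.  Fitting a noisy synthetic melting curve
recovers its midpoint:

```r
cv <- make_melting_curve(curve_spec(76, 4, grid = seq(25, 105, 10),
                                    noise_sd = 0.02, seed = 42))
fit_sigmoid(cv)
#> Two-state sigmoid fit: midpoint 75.849 +/- 0.310 degC, width 3.710 +/- 0.342 degC
#>   residual sum of squares 0.003286 over 9 points
```

A thin command-line wrapper is installed at `inst/cli/wsme.R`
(`contacts`, `landscape`, `fit-curve` subcommands, YAML config, JSON
reports).

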