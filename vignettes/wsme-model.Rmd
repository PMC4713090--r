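---
title: "Statistical mechanics of two-state folding with the wsme package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical mechanics of two-state folding with the wsme package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(wsme)
```

## The model

The Wako-Saitô-Muñoz-Eaton (WSME) description reduces a folding protein to a
chain of binary variables: residue $k$ is *native* ($m_k = 1$) when its
backbone dihedrals are locked in their folded values, otherwise *disordered*
($m_k = 0$).  The conformational free energy of a configuration
$\{m_k\}$ is

$$\Delta G(\{m_k\}) \;=\; \sum_{\langle i,j\rangle,\; j \ge i+3} E_{ij}
\prod_{k=i}^{j} m_k \;-\; T \sum_{k=1}^{N} \Delta S_k\, m_k ,$$

where the first sum runs over the native contact map (residue pairs whose
C$\alpha$ atoms lie within 6.5 Å in the folded structure, at sequence
separation $\ge 3$).  The product $\prod_{k=i}^j m_k$ encodes the model's
single defining approximation: a native contact pays off only when *every*
residue between the partners is native, because only then is the intervening
backbone geometry in place.  $\Delta S_k \le 0$ is the conformational entropy
lost on ordering residue $k$: $-3.8$ cal mol$^{-1}$ K$^{-1}$ for helix and
sheet residues, $-1.3$ cal mol$^{-1}$ K$^{-1}$ for turns and loops.  (These
per-residue values are on the calorie scale: at physiological temperatures
they cost roughly 0.4–1.3 kcal/mol per ordered residue, which contact
energies of a few kcal/mol can pay for.  On a kcal scale the entropic cost
would be three orders of magnitude larger than any conceivable contact
energy and the chain could never fold; the unit knob `ds_unit` exists for
experimentation but the calorie reading is the physically meaningful
default.)

In the *original* WSME model every contact carries the same energy
($E_{ij} = -1$, mode `"go_uniform"`); the *extended*, sequence-dependent
variant assigns each contact its own energy, decomposed as

$$E_{ij} = E^{\mathrm{coulomb}}_{ij} + E^{\mathrm{vdW}}_{ij} +
  E^{\mathrm{pol.sol.}}_{ij} + E^{\mathrm{non\text{-}pol.sol.}}_{ij},$$

each term summed over all atom pairs between residues $i$ and $j$.

## Exact thermodynamics by stretch factorisation

Because a contact requires an unbroken native stretch, the Boltzmann weight
$\omega(\{m_k\}) = e^{-\Delta G/RT}$ of any configuration factorises over its
maximal native stretches, a stretch $[i..j]$ contributing

$$\omega_{j,i} = \exp\!\Big[-\tfrac{1}{RT}\Big(\textstyle\sum_{\text{contacts
} \subseteq [i,j]} E_{kl} - T\sum_{k=i}^{j}\Delta S_k\Big)\Big].$$

`partition_function_dp()` exploits this: scanning the chain once, each
position either stays disordered or terminates a stretch, and the number of
native residues $q$ is carried along.  One $O(N^2)$ sweep over stretches
yields *all* restricted partition functions
$Z_q = \sum_{\{m\}: \sum m = q} \omega(\{m\})$ exactly — no sampling, no
truncation.  `partition_function_bruteforce()` is the $2^N$ enumeration kept
as an independent oracle (it refuses $N > 20$); the test suite checks the
two agree to $10^{-10}$ relative on random sequence-dependent models.  All
accumulation is done in the log domain with log-sum-exp, since kcal-scale
energies at $N \approx 90$ overflow naive sums.

The free-energy landscape over the reaction coordinate $q$ (or
$M = q/N$) is $\Delta G(q) = -RT\log Z_q$, shifted so its minimum is zero.
`locate_basins()` finds the two deepest local minima — the native and
denatured basins — and the highest maximum between them.  Basin free
energies are restricted sums $-RT\log\sum_{\mathrm{basin}}Z_q$ with the
split at the barrier, giving

* $\Delta\Delta G_{D\text{-}N}$, positive while the native basin wins;
* the unfolded fraction $f_U = \sum_{q<q^*} Z_q / Z$;
* the barrier height, reported in kcal/mol and in units of $RT$.

The melting temperature is the root of $\Delta\Delta G_{D\text{-}N}(T)=0$,
found by bisection (`melting_temperature()`); bisection rather than a
derivative method because the basin split point moves discontinuously with
temperature, making the objective only piecewise smooth.  Iterations
continue until $|f_U - 1/2| < 10^{-9}$.  The same machinery runs over
denaturant concentration (`mid_concentration()`), with
`apply_denaturant()` attenuating every contact energy linearly,
$E_{ij}(c) = E_{ij}(0)\,(1-\alpha c)$ — the minimal model reproducing the
observed linear trade-off between melting temperature and denaturation
midpoint.

A worked example:

```{r hairpin}
## a 20-residue beta-hairpin built from ideal geometry
hp <- make_toy_structure(toy_spec(list(c("helix", 8), c("loop", 4),
                                       c("helix", 8))))
model <- wsme(hp)                      # uniform contact energies
tm <- melting_temperature(model, 150, 900)
c(T_m = tm, f_U = fraction_unfolded(model, tm))
plot(model, temperature = tm * c(0.8, 1.0, 1.2))
```

## Where the contact energies come from

The extended model is agnostic about the origin of its $E_{ij}$; the package
offers three parameterisations behind one interface
(`build_energy_table()`):

* **`go_uniform`** — the original sequence-independent model; one number
  per contact.
* **`atomistic_single_structure`** — evaluates the four components on the
  input coordinates: Coulomb with a distance-dependent dielectric
  $\varepsilon(r)=4r$ (a standard implicit-screening surrogate; a constant
  dielectric is a flag away), 12-6 Lennard-Jones with Lorentz-Berthelot
  combination, a Still-type pairwise generalized-Born cross-term
  $-332.0636\,(1-1/\varepsilon_w)\,q_aq_b/f_{GB}$ with
  $f_{GB}=\sqrt{r^2+R_aR_b\,e^{-r^2/4R_aR_b}}$ and $\varepsilon_w = 78.5$,
  and a buried-nonpolar-area term at $-7.2$ cal mol$^{-1}$ Å$^{-2}$.
  Atom parameters come from a small built-in template (per-element
  Lennard-Jones, van der Waals and Born radii; a compact per-atom-name
  charge table covering the backbone and ionisable side chains); unknown
  atoms get zero charge and are flagged.  This is a deliberate minimal
  surrogate for ensemble-averaged energies, not a force field.
* **`from_file`** — a CSV of precomputed components, for energies derived
  elsewhere (e.g. from simulation).

Buried nonpolar area $A_{ij}$ is computed by Shrake-Rupley quadrature
(deterministic golden-spiral mesh, 960 points per atom, 1.4 Å probe):
the accessibility loss of residue $i$'s nonpolar atoms — carbons, sulfurs
and their hydrogens — when residue $j$ is present.  Burial is evaluated in
the isolated two-residue subsystem by default (full-structure context is a
flag): the Hamiltonian wants the *pairwise* occlusion, and full-context
burial would double-count shared neighbours.  Since the Hamiltonian counts
each pair once, the two directional areas are symmetrised,
$E^{\mathrm{non\text{-}pol.sol.}}_{ij} = -0.0072\,(A_{ij}+A_{ji})$
kcal/mol, which preserves the total buried area.

## Ensemble observables

For coordinate ensembles (multi-MODEL PDB or generated) the package computes
the mass-weighted radius of gyration, its distribution over frames, the
per-atom RMSF about the ensemble mean, and the displacement
variance-covariance matrix
$\sigma_{ij} = \langle \Delta\mathbf r_i \cdot \Delta\mathbf r_j\rangle$
(3-D vectors contracted; population averaging).  The correlation matrix is
normalised as $c_{ij} = \sigma_{ij}/\sqrt{\sigma_{ii}\sigma_{jj}}$ — the
only normalisation with a unit diagonal.  No superposition is applied
implicitly; `superpose_ensemble()` offers an explicit Kabsch fit when frames
carry rigid-body motion.

## Melting curves and chemical-shift perturbations

Spectroscopic melts are normalised to fraction unfolded between native and
denatured baselines (estimated from the flat ends when not supplied; values
pushed outside $[0,1]$ by noise are flagged, never clipped) and fitted with
the Boltzmann sigmoid $f(x) = 1/(1+e^{(x_m - x)/w})$ by Levenberg-Marquardt
least squares.  The logistic form, rather than a full Gibbs-Helmholtz fit,
matches what melting midpoints are: the $x$ at half-unfolding.  Falling
(refolding-direction) curves are detected and mirrored; the midpoint is
orientation-invariant.  Raw-signal curves get free baseline parameters.

Per-residue NMR perturbations use the weighted-euclidean combination
$\Delta\delta_{AV} = \sqrt{(\Delta\delta_{1H})^2 +
(\Delta\delta_{15N}/5)^2}$; `csp_profile()` flags residues above
mean $+\,k\cdot$sd (default $k=1$, configurable — reported "large"
perturbations rarely come with a printed threshold).

## Synthetic data: what it emulates and what it does not

All fixtures are generated in code, deterministically from explicit seeds:

* **Toy chains** (`make_toy_structure()`): ideal helix geometry (1.5 Å
  rise, 100°/residue — guaranteeing $i,i{+}3$/$i,i{+}4$ contacts inside the
  6.5 Å cutoff) and fully extended strands/loops (no short-range contacts).
  These pin down contact-map and Hamiltonian semantics exactly.
* **The 88-residue stand-in** (`synthetic_mth1880()`): a deterministic
  C$\alpha$ model of a small thermophilic $\alpha/\beta$ fold — a
  three-stranded antiparallel sheet whose sequence-middle strand sits at
  the sheet's spatial centre, three helices packing both faces, clash-free
  (no non-bonded C$\alpha$ pair under 3.5 Å) with near-ideal virtual bonds.
  The arrangement deliberately maximises contact order the way the real
  fold's salt bridges and hydrophobic clusters do (termini pairing with the
  sequence middle), which is what makes folding cooperative.  It is a
  topological stand-in built from ideal geometry, *not* an experimental
  structure: side chains, true loop conformations and the native sequence
  are absent, so sequence-specific energetics on it are illustrative only.
* **Gaussian ensembles** (`make_gaussian_ensemble()`): isotropic per-axis
  displacements with a prescribed atom-atom correlation, applied
  independently per Cartesian axis, so the expected RMSF is
  $s\sqrt{3}$ and the expected correlation matrix is the prescription.
  Real trajectories are neither Gaussian nor isotropic; these fixtures test
  estimator correctness and convergence, not simulation realism.
* **Melting curves** (`make_melting_curve()`): exact two-state sigmoids
  plus i.i.d. Gaussian noise, with the generating parameters kept as
  metadata for recovery tests.

Passing tests on these fixtures demonstrate that the estimators and the
thermodynamic machinery are correct; they do not demonstrate that any
particular surrogate energy set reproduces a specific protein's measured
stability.

## Calibrated landscapes at protein scale

With surrogate energies the *absolute* energy scale is the one genuinely
unknown quantity, so the package pins it to experiment:
`calibrate_tm()` rescales all contact energies by a single factor
$\lambda$ (stability is monotone in $\lambda$; bisection) until
$\Delta\Delta G_{D\text{-}N} = 0$ at a measured mid-temperature.  On the
88-residue stand-in calibrated to a 349.15 K (76 °C) midpoint, uniform
contact energies give a genuinely two-state landscape — native basin near
$M \approx 0.94$, denatured basin near $M \approx 0.21$, a single barrier
of about 8 $RT_m$, and a high-temperature global minimum near
$M \approx 0.2$ (the entropic position
$\bar s/(1+\bar s)$ set by the loop/structured entropy ratio, since a
residue with $\Delta S_k$ contributes native weight
$e^{\Delta S_k/R}$ once energies no longer bind):

```{r standin, eval = FALSE}
model <- calibrate_tm(wsme(synthetic_mth1880()), 349.15)
locate_basins(free_energy_profile(model, 349.15))
```

(Not evaluated here to keep the vignette light; `scripts/acceptance.R`
recomputes these numbers from scratch, at roughly a second of CPU for the
calibration bisection.)

## Numerical choices and degenerate inputs

* Distances compare inclusively at the contact cutoff ($\le 6.5$ Å);
  residue indexing is 1-based and contiguous after parsing.
* Multi-model (NMR-style) PDB input uses the first MODEL by default; any
  model can be selected.
* Log-sum-exp everywhere in partition sums; $Z_q = 0$ bins are reported as
  unreachable (infinite $\Delta G$), and a landscape with a single minimum
  is flagged `no_barrier` with the basin split falling back to $q = N/2$ —
  the unfolded fraction stays defined.
* The Shrake-Rupley mesh is deterministic, so buried areas are exactly
  reproducible; they are rotation-invariant only to quadrature tolerance
  (~0.5%), while the analytic energy terms are invariant to machine
  precision.
* Sigmoid fits report non-convergence through a flag with diagnostics
  rather than an exception; standard errors come from the NLS covariance.
* Static atoms in an ensemble produce flagged `NA` rows in the correlation
  matrix, never a silent division by zero.
* Problem sizes in the test suite — 25–100 random models at $N \le 14$
  against the $2^N$ oracle, 50,000-frame recovery ensembles, 100-curve fit
  replicates — were chosen so the whole suite runs in well under a minute
  while keeping Monte-Carlo assertions at three standard errors.

## Known limitations

* The single-sequence approximation is exact for the stated Hamiltonian but
  is itself an approximation to folding: interactions between separate
  native stretches are absent by construction.
* Surrogate single-structure energies (dielectric choice, Born radii,
  minimal charge template) are stand-ins for ensemble-averaged energetics;
  conclusions about specific sequences require externally derived energy
  tables (`from_file`).
* The linear denaturant attenuation uses one coefficient per species; no
  attempt is made to model species-specific binding mechanisms.
* No kinetics: the model yields equilibrium populations and barriers, not
  rates or transition paths.
* Secondary structure comes from annotations (HELIX/SHEET records or user
  input); the package does not re-derive it from geometry.
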