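---
title: "Alchemical transfer free energies on toy host-guest systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alchemical transfer free energies on toy host-guest systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atmkit)
```

## What the package computes

atmkit implements the full machinery of a relative binding free energy
(RBFE) pipeline built around the Alchemical Transfer Method (ATM), scaled
down from protein-ligand molecular dynamics to toy host-guest systems small
enough that every claim is testable on one CPU against closed forms or
independent oracles.

The pipeline is the one used by production RBFE studies:

1. a molecular system with two "ligands", a binding site and a bulk region;
2. an alchemical potential `U_lambda(x) = E(x) + W_lambda(u_sc(u(x)))`
   biasing the *perturbation energy* `u(x) = E(swap(x)) - E(x)`, where
   `swap` rigidly exchanges the two ligands between site and bulk;
3. Langevin dynamics with Hamiltonian replica exchange over a ladder of
   lambda windows, run separately for the two transfer legs that meet at the
   symmetric intermediate lambda = 1/2;
4. UWHAM (the unbinned weighted histogram analysis method, statistically
   equivalent to MBAR) to estimate each leg's free energy and its
   uncertainty, combined as `ddG = dG_leg1 - dG_leg2`;
5. a maximum-likelihood reconstruction of absolute per-ligand dG values
   from the ddG edge network; and
6. the benchmark statistics layer: MAE, RMSE, Kendall tau with pair
   bootstrap uncertainties, and accuracy-threshold fractions.

An NNP/MM-style hybrid mode replaces each ligand's intramolecular
molecular-mechanics terms with a smooth surrogate potential, mirroring how a
neural network potential supplies ligand internal energetics in production
hybrid simulations while the environment stays classical.

## The toy model and its closed form

Real RBFE systems get their two distinct thermodynamic states from the
physical environment: a ligand interacts strongly with the binding site and
weakly with water. A desk-scale model must reproduce that asymmetry with a
potential simple enough to integrate exactly. atmkit uses a **double-well
tether**: each ligand particle feels

$$E(r) = -k_B T \,\ln\!\left[e^{-E_{site}(r)/k_B T} + e^{-E_{bulk}(r)/k_B T}\right],
\qquad E_{c}(r) = \tfrac{1}{2} k_c \lVert r - x_c \rVert^2 ,$$

the softmin of a site well (spring `k_site`, center `x_site`) and a bulk
well (`k_bulk`, `x_bulk`). Two properties make this the right construction:

* it is smooth (infinitely differentiable), so the same term works in
  dynamics and in gradient tests; and
* its configurational integral is *exactly* `Z_site + Z_bulk`, the sum of
  two Gaussian integrals, so basin-restricted partition functions equal the
  single-well closed forms up to a relative error of order
  `exp(-k d^2 / 8 k_B T)` -- below 1e-12 at the default 16 A separation.

The transfer free energy for swapping ligand A (wells `k_site_A`,
`k_bulk_A`) with ligand B is therefore exactly

$$\Delta\Delta G = \tfrac{3}{2} k_B T \left[ \ln\frac{k_{bulk,A}}{k_{site,A}}
  - \ln\frac{k_{bulk,B}}{k_{site,B}} \right],$$

implemented as `analytic_transfer_ddg()` and verified against 3D numerical
quadrature in the tests. The flagship fixture
`make_harmonic_host_guest(4, 1, 1, 1, temperature = 1/0.0019872041)` (so
that `kT = 1` kcal/mol) has `ddG = -(3/2) ln 4 = -2.0794` kcal/mol.

```{r analytic}
sys <- make_harmonic_host_guest(4, 1, 1, 1, temperature = 1 / 0.0019872041)
sys$analytic_ddg
```

A second generator, `make_lj_ligand_system()`, builds 1-4 bead ligand
chains (harmonic bonds, a cosine torsion for 4-bead chains, a Coulomb pair
across chain ends) inside a Lennard-Jones host cage. It has no closed form
and serves as the stress fixture for the hybrid decomposition and the
integrator.

### The swap transform

`swap_transform()` translates the ligand group nearer the site center by
`+d` and the other group by `-d`, with `d = x_bulk - x_site`. Assigning the
directions by proximity (rather than by ligand label) makes the transform an
involution -- applying it twice restores the input -- which in turn makes
the perturbation energy antisymmetric, `u(swap(x)) = -u(x)`. One caveat of
binary floating point: a rigid translation shifts coordinate exponents, so
the round trip is exact only to the ulp of the displaced position (relative
1e-15 in practice; the tests assert 1e-14).

### Units and indexing

Amber-style units throughout: kcal/mol, Angstrom, ps, Kelvin, amu, with
`k_B = 0.0019872041` kcal/mol/K. All particle indices -- in the API and in
every file format -- are **1-based**, the native convention of R and of the
R structural-biology ecosystem; a 0-based convention would have every user
off by one against `coords[i, ]`.

## The alchemical potential

The perturbation energy is soft-core capped before biasing:
`u_sc = u` for `u <= uc`, and above `uc`

$$u_{sc} = u_c + (u_{max} - u_c)\,\frac{z^{1/a} - 1}{z^{1/a} + 1},
\qquad z = 1 + 2y + 2y^2,\quad y = \frac{a (u - u_c)}{u_{max} - u_c},$$

a strictly increasing C1 transform bounded by `umax` whose joint at `uc`
has slope exactly 1 on both sides. Defaults `umax = 200`, `uc = 100`,
`a = 1/16` kcal/mol-scale; on the toy fixtures `u` rarely exceeds a few
kcal/mol, so the cap exists to guarantee robustness, not to shape results.
Note the cap saturates to `umax` in double precision beyond
`u - u_c \approx 30 (u_{max}-u_c)`; strict monotonicity holds where the
floating point grid resolves it.

The bias is the softplus coupling

$$W_\lambda(u_{sc}) = \lambda_2 u_{sc} + \frac{\lambda_1 - \lambda_2}{\alpha}
  \ln\!\left[1 + e^{-\alpha (u_{sc} - u_0)}\right] + w_0,$$

computed overflow-safely; with `lambda1 = lambda2 = lambda` it reduces
exactly to linear coupling `W = lambda u + w0`, which is the default ladder
(`lambda_schedule(family = "linear")`, 11 windows evenly spaced on
`[0, 1/2]` per leg). With this sign convention the large-`u` slope is
`lambda2` and the `u -> -Inf` slope is `2 lambda2 - lambda1`. The
`"softplus-defaults"` family (`lambda1 = min(2 lambda, 1/2)`,
`lambda2 = max(0, 2 lambda - 1/2)`, `alpha = 0.1`, `u0 = 110`, `w0 = 0`)
is provided as a configurable alternative; all checks and defaults use the
linear family, whose reduction is itself a tested contract.

Both legs share one lambda grid and differ only in direction: leg 1 is
annealed from the physical basin (A bound, B solvated), leg 2 from the
swapped basin. At the symmetric intermediate the two legs sample the same
state, so `ddG = dG_leg1 - dG_leg2` telescopes to the transfer free energy.

## Sampling

Dynamics use the BAOAB splitting of Langevin dynamics -- the de facto
standard for configurational sampling accuracy -- with Maxwell-Boltzmann
velocity initialisation. Defaults: 4 fs timestep in mm mode, 1 fs in hybrid
mode (mirroring the factor-four cost difference such hybrid simulations
accept), friction 1 /ps, particle mass 12 amu; the stiffest default well
(`k = 4` kcal/mol/A^2) has a period of about 530 fs, comfortably resolved.

Replica exchange is synchronous with even/odd neighbour alternation:
a swap between states i and j with current perturbation energies
`u_i, u_j` is accepted with probability
`min(1, exp(-[W_i(u_j) + W_j(u_i) - W_i(u_i) - W_j(u_j)]/kT))`.
Production ATM deployments use an asynchronous exchange service; the
synchronous kernel has the identical stationary distribution and is far
easier to test (the suite checks the Metropolis rate and the exact
two-state Boltzmann occupancy on frozen configurations).

The default desk-scale budget -- 11 windows x 20,000 steps per leg,
exchange every 250 steps, samples every 50, 2,200 annealing steps -- runs a
two-leg estimate in about half a minute on one CPU and gives a ddG
uncertainty near 0.05 kcal/mol on the harmonic fixture. Every stochastic
element draws from a stream derived from the run seed
(`derive_seed(seed, stream)`), so reruns are bit-identical including
exchange decisions, and no global RNG state leaks.

## Free energy estimation

`uwham_solve()` maximises the UWHAM likelihood through the self-consistent
iteration

$$f_k = -\ln \sum_n \frac{e^{-B_{kn}}}{\sum_l N_l e^{f_l - B_{ln}}}$$

(log-sum-exp stabilised, gauge `f_1 = 0`), switching to quasi-Newton
maximisation of the same likelihood if the iteration stalls; convergence is
declared at a residual of 1e-10 reduced units. States with zero samples of
their own are allowed and reduce correctly to the Zwanzig exponential
average. Since the configurational energy is common to all states for a
given sample, only the bias `W_k(u_sc(u_n))/kT` enters the matrix; the
estimator is invariant to per-sample column shifts.

Uncertainties come from the standard multistate-reweighting asymptotic
covariance, computed via the thin SVD of the weight matrix so only K x K
systems are inverted. The gauge direction of that covariance is analytically
singular but lands at ~1e-16 numerically; it is cut at a relative tolerance
of 1e-10, well above rounding and well below any physical mode.

**Correlated dynamics output.** The asymptotic error bar assumes
independent samples. Two things break that for replica-exchange series:
autocorrelation within a window and the fact that neighbouring windows share
replica trajectories. The pipeline therefore (a) thins each window's series
by its statistical inefficiency before solving, and (b) computes a block
uncertainty (`uwham_block_sigma()`: contiguous time blocks, one UWHAM solve
per block, SEM over blocks) that sees all correlation, and reports the
larger of the two (`sigma_method = "conservative"` in `atm_ddg()`). On the
identity fixture the asymptotic sigma alone understates the leg-to-leg
fluctuation by roughly a factor of two; the block estimate restores
coverage. For genuinely independent samples -- the calibration tests --
the asymptotic estimator is used directly and its 2-sigma coverage is
93-97% over 200 repetitions.

Replicates (the triplicate protocol of production benchmarks) are combined
as an unweighted mean with the standard error of the mean; a single
replicate passes through its estimator sigma.

## Network reconstruction and benchmark statistics

`mle_absolute_dg()` minimises
`sum_edges (ddG_ij - (g_j - g_i))^2 / sigma_ij^2` per connected component
under the gauge `sum g = 0`, via the pseudo-inverse of the weighted graph
Laplacian; node sigmas are the square roots of the pseudo-inverse diagonal.
Estimates are never compared across components -- a disconnected
perturbation network simply does not determine relative values between its
parts, which is why poorly connected networks preclude absolute dG for all
ligands. `center_to_experiment()` shifts each component so the mean
estimated dG over experimentally annotated ligands matches the mean
experimental value (mean anchoring; a single-reference-ligand anchor is a
one-line variant on top of the returned tibble). The edge convention is
`ddG_ij = dG_j - dG_i`, also used in the CSV formats.

The statistics layer reports MAE, RMSE and Kendall tau (tau-b, i.e.
tie-corrected, via `stats::cor`, cross-checked against exhaustive pair
counting) with pair-bootstrap uncertainties (default 1,000 resamples;
degenerate tau resamples are skipped and counted), plus the fraction of
pairs within 1 and 1.5 kcal/mol. Pearson correlation is deliberately absent
from default reports: for ddG edge sets it depends on the arbitrary choice
of ligand pairs.

## What the generators emulate -- and what they do not

`make_edge_network()` emulates a deposited benchmark free-energy table:
true per-ligand dG values (mean -9, spread 1.5 kcal/mol, typical of
binding-affinity series), a random subset of ligand pairs, Gaussian noise
on calculated edges, exact values as the experimental reference. Zero noise
gives exactly consistent cycles; the warning flag fires when fewer than
`n - 1` edges make connectivity impossible.

The toy systems preserve the *structure* of the production problem -- two
basins, a transfer coordinate, a lambda ladder, correlated replica-exchange
output -- but not its hard parts: there is no explicit solvent, no slow
conformational degrees of freedom, no force-field error, and the surrogate
ligand potential is a fixed seeded radial-basis function, not a trained
model. Passing tests therefore validate the estimators, kernels and
plumbing exactly; they say nothing about force-field accuracy or sampling
hardness on real protein-ligand systems, which is precisely the part that
needs GPUs and nanoseconds.

## Numerical choices and degenerate inputs

* Double precision throughout the alchemical path; free energy estimators
  amplify rounding.
* Pseudo-inverses cut singular values at `max(dim) * max(s) * eps`
  (Laplacians) or at 1e-10 relative (UWHAM covariance, see above).
* Coincident particles in LJ/Coulomb pairs raise a singular-geometry error
  rather than returning infinities; collinear torsions likewise.
* Zero-count states are legal in UWHAM; zero-sigma edges, self-edges and
  duplicate unordered pairs are rejected at network construction with the
  offending row named.
* The energy path used by the samplers is a compiled-closure variant of the
  reference `mm_energy()`/`hybrid_energy()`/`total_alchemical_energy()`
  implementations; a property test pins both paths together at machine
  precision.
* `kendall_tau` on all-constant input raises an undefined-correlation error
  instead of returning NA.

## Known limitations

* Single-CPU, pure R: roughly 25,000 force evaluations per second on the
  two-particle fixture; the default two-leg estimate takes ~30 s. Real MD
  workloads are out of scope by design.
* Mechanical embedding only: ligand-environment electrostatics stay MM in
  hybrid mode; electrostatic embedding is not modelled.
* No periodic boundary conditions; systems are tethered clusters.
* The block uncertainty needs at least 3 blocks of samples per window; very
  short runs fall back to the asymptotic estimate.
* `fraction_within` uses a strict inequality; errors exactly equal to a
  threshold do not count as within it.
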