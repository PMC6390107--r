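---
title: "Models and methods behind ttrstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ttrstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttrstab)
```

Transthyretin (TTR) is a homotetramer — a dimer of dimers — whose
dissociation is the rate-limiting step toward amyloid fibril formation.
`ttrstab` implements the three quantitative pillars used to dissect how
point mutations (the pathogenic S52P, the protective T119M) and the
stabiliser tafamidis shift TTR between its folded, dissociated and
unfolded states: subunit-exchange kinetics, native-contact trajectory
analysis with functional mode analysis, and alchemical free-energy cycles.
This vignette records the models, the defaults, and the design choices —
including what the synthetic data generators do and do not emulate.

## 1. Subunit-exchange simulation

Mixing hydrogenated (4H) and deuterated (4D) tetramers in equal parts
starts a relaxation toward a scrambled population of hybrids (3H1D, 2H2D,
1H3D) that native mass spectrometry can resolve. The simulator propagates
mass-action kinetics over the network

```
tetramer  <=>  dimer + dimer  <=>  4 monomers
```

with four rate constants (`rate_set()`): unimolecular dissociation rates
in day⁻¹ and bimolecular association rates in per-molecule-per-day (the
state is held in copy numbers). Because the tetramer is a dimer of dimers,
each tetramer is tracked internally by its unordered pair of constituent
dimers (six states), and dissociation returns exactly those two dimers;
subunits scramble only at the dimer–monomer level. The two structurally
distinct 2H2D assemblies (HH+DD and HD+HD) are therefore distinct inside
the simulator but pooled in every reported abundance, since MS cannot
separate them. This bookkeeping is what makes the two analytic
equilibria hold exactly:

* all rates positive → tetramer composition is Binomial(4, ½):
  6.25 / 25 / 37.5 / 25 / 6.25 %;
* dimers frozen (`k_dim_diss = 0`) → random pairing of intact HH/DD
  dimers: 25 / 0 / 50 / 0 / 25 %.

A per-deuteron multiplicative `isotope_factor` scales every reaction rate
once per D subunit among the reactants; at 1 the dynamics are exactly
H/D-exchangeable. Integration is deterministic (`deSolve::lsoda`) or an
exact direct-method Gillespie simulation (compiled; reproducible under a
seed). The default copy number of 1e5 tetramers keeps relative
fluctuations below ~1 %, matching the smooth experimental curves; the SSA
mean over replicates agrees with the ODE solution within Monte-Carlo
error. `render_peak_areas()` turns abundances into per-charge-state peak
areas with truncated Gaussian noise, emulating the Q-TOF output that the
abundance computation consumes; it models neither m/z envelopes nor
instrument calibration.

## 2. Bayesian one-phase exponential fitting

Relative abundances are computed from summed peak areas over an inclusive
charge range (13+ to 15+ by default) and each species group is fitted
with the one-phase exponential model

$$y(t) = c + (y_0 - c)\,e^{-kt},$$

with $t$ in minutes, by MCMC under the priors: $y_0 \sim \mathcal
N(50, 15)$ for dissociating series or $\mathcal N(0, 5)$ for associating
ones; $c \sim \mathcal U(0, y_0)$ or $\mathcal U(y_0, 100)$ respectively;
$k \sim$ HalfNormal(scale 10 min⁻¹); and white noise $\sigma \sim$
HalfNormal(scale 10 %). Defaults are 10 000 posterior draws after 5 000
discarded warm-up iterations, initialised at the maximum a posteriori
point found by numerical optimisation (Nelder–Mead on a transformed,
box-free parameterisation). Sampling is delegated to JAGS; its
slice/conjugate samplers target the identical posterior as any other
MCMC engine, so only sampling efficiency, not the estimand, differs.
Numerical choices worth knowing:

* the noise scale is truncated below at 0.01 % — with exactly noise-free
  input the likelihood otherwise degenerates into a point mass and wedges
  any sampler; the truncation is invisible at real noise levels;
* convergence is monitored by split-chain potential scale reduction over
  4 chains with a 1.01 threshold; exceeding it attaches a warning to the
  fit rather than failing, since a non-mixing nuisance parameter (the
  $c$–$y_0$ ridge of a flat series) need not invalidate the rate;
* rates are fitted in min⁻¹ and reported in both min⁻¹ and day⁻¹
  (×1440), rounded to two decimals in reports, e.g. `0.20 ± 0.03 day⁻¹`;
* `fit_experiment()` pools 4H with 4D and 3H1D with 1H3D by averaging
  before fitting, because a single rate is reported per group; noise is
  estimated per series, not shared.

## 3. Fraction of native contacts

The degree of (un)folding is measured by the smoothed fraction of native
contacts

$$Q(x) = \frac{1}{N}\sum_{(i,j)}
  \frac{1}{1 + \exp\!\big[\beta\,(r_{ij}(x) - \lambda\,r^0_{ij})\big]},$$

with $\beta = 5\ \text{Å}^{-1}$ and $\lambda = 1.8$ (the atomistic
value). Native pairs are all heavy-atom pairs within 4.5 Å in the
reference structure; *fold* contacts additionally require both atoms on
one chain and at least three residues between their residues
($|i - j| \ge 4$), *interface* contacts require two different chains.
Hydrogens and deuteriums are excluded; side chains are included. The
reference state is the starting structure as supplied. Per-region Q
(`q_by_region()`) assigns a pair to a region when either residue belongs
to it, so regions overlap by default; a strict partition is available by
flag. Q is a function of distances only, hence rigid-motion invariant,
and each term decreases monotonically as its pair distance grows.

## 4. PLS functional mode analysis

`fit_fma()` regresses a scalar property (here Q) on main-chain (N, CA, C,
O) coordinates by partial least squares, after least-squares superposition
of every frame onto the reference to remove rigid-body motion. Defaults
follow the analysis the package reproduces: 20 PLS components and a
75 % / 25 % train/validation split. The split is the contiguous leading
fraction of frames — time-ordered, so validation probes genuine
extrapolation; a seeded shuffled split is available by flag. Coordinates
are centred per feature and the property standardised. Model quality is
the Pearson correlation between predicted and observed property on each
set; on the default synthetic unfolding trajectory the validation
correlation exceeds 0.97, the model-quality bar the analysis is held to.

The reported mode is the *ensemble-weighted* maximally correlated mode:
the covariance between the centred coordinates and the model prediction,
normalised. The raw regression-coefficient direction (kept as
`$coefficients`) maximises correlation but spreads weight onto
low-variance noise dimensions, which misranks uninvolved residues; the
covariance weighting restores the displacement pattern the ensemble
actually performs. Sample covariances below the universal threshold of
their own sampling noise ($\mathrm{mad}\times\sqrt{2\log p}$) are shrunk
to zero so that atoms uninvolved in the motion do not accumulate spurious
amplitude from finite sampling. `mode_rmsf()` aggregates the unit mode to
residues as the Euclidean norm of each residue's components, so squared
amplitudes sum to one.

## 5. Free-energy estimation and the mutant cycle

`bar_free_energy()` solves the Bennett acceptance ratio self-consistency
equation

$$\sum_F \big[1 + \tfrac{n_F}{n_R} e^{\beta (W_F - \Delta G)}\big]^{-1}
 = \sum_R \big[1 + \tfrac{n_R}{n_F} e^{\beta (W_R + \Delta G)}\big]^{-1}$$

by bracketed root finding to 1e-10 kcal/mol, with reverse works in the
forward sign convention. The point estimate pools all samples; the
standard error is that of per-replicate-group estimates (the canonical
design is 10 independent equilibrium simulations spawning 50
nonequilibrium trajectories each). On Gaussian work distributions the
estimate converges to the Crooks closed form $\Delta G = \mu_F - \beta
\sigma^2/2$, which the tests exploit as an oracle. Poor forward/reverse
overlap is flagged (solver residual, vanishing Fermi sums, or non-finite
group error), not silently ignored.

The mutant thermodynamic cycle compares each mutation in an oligomeric
state against the same mutation in a capped-tripeptide unfolded
reference: `ddg_state()` subtracts the two with errors in quadrature.
Positive values shift the equilibrium toward the dissociated/unfolded
side. The overall dissociation-and-unfolding stability per tetramer
combines the per-state legs stoichiometrically,

$$\Delta\Delta G_\mathrm{unf} = \Delta\Delta G_\mathrm{tetr}
 + 2\,\Delta\Delta G_\mathrm{dime} + 4\,\Delta\Delta G_\mathrm{mono},$$

one tetramer dissociating into two dimers and four monomers. The
combination is not printed alongside the per-state values it is derived
from in the original analysis; this stoichiometry reproduces both
reported combined values within their stated uncertainties (8.4 vs 8.1
and −12.9 vs −12.4 kcal/mol), which is why the package adopts it and why
the thermodynamic-cycle checks carry a 0.6 kcal/mol tolerance.
Conversions use $R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ at 298 K:
`fold_change()` maps a ΔΔG to $e^{|\Delta\Delta G|/RT}$ with the
direction carried as a label, and `kd_to_dg()` maps a dissociation
constant to $|{-RT \ln(K_d/c^0)}|$ at 1 M standard state. Mutations at
well-separated sites are treated as energetically additive
(`ddg_additivity()`), quadrature errors included.

## 6. Structure geometry

`atom_distance()` resolves `chain/resno/atom` selectors (alternate
locations: highest occupancy first, ties broken alphabetically — the
conventional crystallographic policy) and reports Euclidean distances,
conventionally rounded to 0.1 Å. The headline diagnostic is the CD-loop
distance between Ser50 Cα and the residue-52 amide nitrogen: 4.2 Å when
serine 52 pins the loop with two hydrogen bonds to Ser50, 0.4 Å wider
when proline abolishes both donors. `find_hbonds()` detects
donor–H–acceptor triplets with a 3.5 Å donor–acceptor cutoff and a 120°
angle threshold (a common crystallographic criterion; none is mandated by
the underlying analysis); deuteriums are treated exactly as hydrogens, as
in neutron structures, and structures without any H/D fall back to a
distance-only criterion.

## 7. The synthetic generators — what they emulate, and what not

No structure download or MD engine is available to a desk-scale test
suite, so `make_toy_oligomer()` builds a compact serpentine-lattice
protein — 24 five-atom residues per chain, chains stacked so that every
adjacent pair shares an interface at the 4.5 Å criterion — as a stand-in
for the monomer/dimer/tetramer systems. Q and PLS-FMA depend only on
contact topology, not fold class, so a lattice serves as well as a
β-sandwich. Residues are labelled as eight sequential strand analogues
A–H; the default perturbation region (`cd_region()`, residues 7–14) is
the C/D-strand analogue plus the adjoining turn, mirroring where TTR
unfolding is proposed to initiate.

`make_unfolding_trajectory()` emulates the phenomenology of
high-temperature unfolding runs: a steady, region-localised loss of
native contacts against a 0.2 Å thermal jitter. The region residues
*peel* sequentially — each residue follows its own displacement window
(50 % overlap with its neighbour) along a randomised escape direction out
of the chain slab, up to the schedule's maximum amplitude (default 8 Å
over 1000 frames). Two facts shaped this design. First, the Q sigmoid's
effective threshold is $\lambda r^0 \le 8.1$ Å, so an 8 Å displacement in
an isotropic random direction leaves a large fraction of contacts intact;
only a directionally coherent escape breaks a region's contacts at that
amplitude. Second, a model that is linear in coordinates can only
represent property changes along directions the ensemble actually
explores; if all region atoms moved proportionally to one scalar, PLS
predictions would be affine in that scalar while Q is not, capping the
achievable correlation. Sequential peeling curves the coordinate path
through several independent directions and restores the
regression-friendly structure real unfolding trajectories have. The
generator does *not* emulate: secondary-structure formation, chain
connectivity during unfolding, refolding events, force-field energetics,
or solvent. Passing tests therefore certify the analysis machinery —
contact bookkeeping, Q evaluation, alignment, regression, mode
extraction — on data with a known ground truth; they do not certify
force-field realism.

`make_hierarchy_series()` reuses the same machinery at three amplitudes
(8 / 5.5 / 3.5 Å for the monomer / dimer / tetramer context) to reproduce
the qualitative ordering in which a free monomer unfolds fastest and a
tetramer-embedded one slowest. The ordering is imposed by construction —
it is a fixture for testing the analysis of that ordering, not a
prediction of it.

## 8. Problem sizes and determinism

The test suite and the acceptance script run the study conditions at desk
scale: 1000-frame trajectories for the mode analysis, 1e4–1e5 copies and
200 stochastic replicates for the exchange simulator, 10 × 50 work
samples for BAR, and 2-chain / 4000-draw samplers inside parameterised
test loops (the user-facing defaults remain 4 chains, 10 000 draws,
5 000 warm-up). Every stochastic path takes an explicit integer seed —
the Gillespie simulator uses R's RNG, JAGS chains are seeded per chain,
and the generators consume one seed each — so identical calls are
bit-reproducible.

## 9. Known limitations

* The exchange model resolves only the dimer-mediated dissociation
  route; direct tetramer→monomer channels, if any, are not modelled.
* `fit_experiment()` averages pooled species rather than fitting them
  jointly with a shared rate; with strongly asymmetric isotope effects
  the two differ.
* The ensemble-weighted mode is an approximation to the full
  ensemble-weighting construction of the FMA literature; it is not
  asserted to be equivalent, only to satisfy the recovery properties the
  tests encode.
* mmCIF support covers the standard `atom_site` loop (sufficient for
  coordinate work), not the full dictionary.
* Whether per-monomer Q should be averaged over the four chains before
  averaging over repeats is left to the user: both reductions are simple
  aggregations of `q_timeseries()` output.
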