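# ttrstab

Transthyretin (TTR) is a homotetrameric transport protein whose
dissociation into dimers and monomers is the rate-limiting step toward
amyloid fibril formation. Point mutations push this equilibrium in both
directions — S52P accelerates dissociation and causes aggressive
amyloidosis, T119M locks the tetramer and protects carriers — and the
drug tafamidis mimics the protective mutation by binding the thyroxine
sites. `ttrstab` is an R toolkit for the three quantitative analyses
that dissect these effects:

1. **Subunit-exchange kinetics.** Mass-action simulation (deterministic
   ODE or exact Gillespie) of H/D tetramer subunit exchange through the
   dimer-of-dimers network `tetramer ⇌ 2 dimers ⇌ 4 monomers`, rendering
   of native-MS style charge-state peak areas, and Bayesian MCMC fitting
   of the one-phase exponential model
   *y(t) = c + (y₀ − c)·e^(−kt)* with literature priors
   (y₀ ~ N(50, 15) or N(0, 5); c uniform on the admissible side of y₀;
   k and noise half-normal). Rates are reported as posterior
   `mean ± sd day⁻¹`.

2. **Native contacts and functional mode analysis.** The smoothed
   fraction of native contacts
   *Q = ⟨1 / (1 + exp[β(r −λr⁰)])⟩* (β = 5 Å⁻¹, λ = 1.8, 4.5 Å
   heavy-atom cutoff) for monomer folds, inter-chain interfaces and
   per-strand subsets over coordinate trajectories, plus
   partial-least-squares functional mode analysis (20 components,
   75/25 time-ordered split) extracting the collective mode maximally
   correlated with unfolding.

3. **Free-energy cycles.** Bennett-acceptance-ratio estimation from
   forward/reverse nonequilibrium work samples, the mutant
   thermodynamic cycle ΔΔG_unf = ΔΔG_tetr + 2·ΔΔG_dime + 4·ΔΔG_mono,
   and conversions to equilibrium fold changes (`exp(|ΔΔG|/RT)`) and
   binding free energies from dissociation constants. Plus
   structure-geometry diagnostics (CD-loop distances, hydrogen-bond
   detection with deuterium-aware donors) on PDB/mmCIF models.

A synthetic toy-protein and unfolding-trajectory generator provides
ground-truth inputs for all trajectory analyses with no downloads, so
the entire pipeline is testable at desk scale.

## Worked example

Simulate an equimolar 4H/4D exchange experiment at wild-type-like rates,
render noisy peak areas, recover abundances, and fit the three rate
groups:

```r
library(ttrstab)

rates <- rate_set(k_tet_diss = 0.2, k_tet_assoc = 1e-2,
                  k_dim_diss = 0.5, k_dim_assoc = 1e-2)   # per day
sys   <- equimolar_mix(n_tetramers = 1e5, rates = rates)
ts    <- simulate_exchange(sys, t_grid = seq(0.25, 11, length.out = 12))
peaks <- render_peak_areas(ts, charge_states = 13:15, noise_sd = 2, seed = 8)
abund <- relative_abundance(peaks, charge_range = c(13, 15))
fits  <- fit_experiment(abund, seed = 4)
fits
#> Subunit-exchange kinetics (one-phase exponential fits)
#>   4H + 4D (dissociation)     k = 0.20 ± 0.03 day⁻¹
#>   2H2D (association)         k = 0.23 ± 0.03 day⁻¹
#>   3H1D + 1H3D (association)  k = 0.21 ± 0.28 day⁻¹
```

The homo-tetramer dissociation rate recovers the generating 0.2 day⁻¹.
The slowest hetero group carries a wide posterior — the synthetic series
has not plateaued within 11 days, and the fit reports that honestly (a
convergence warning flags the weakly identified group).

Thermodynamic cycle for a destabilising mutation whose only significant
leg is the monomer fold (+2.1 kcal/mol):

```r
s52p <- ddg_unfold(ddg_tetr = 0, ddg_dime = 0, ddg_mono = 2.1,
                   se_tetr = 0.4, se_dime = 0.3, se_mono = 0.3)
s52p
#> ddG = +8.40 ± 1.40 kcal/mol (destabilising)
fold_change(2.1)
#> fold change: 34.7 (destabilising)
kd_to_dg(2e-9)          # a 2 nM binder
#> [1] 11.86022
```

A +2.1 kcal/mol fold destabilisation is a ~35-fold shift toward the
unfolded monomer; summed over the whole tetramer-to-unfolded process it
amounts to +8.4 kcal/mol. A 2 nM dissociation constant corresponds to
~12 kcal/mol of binding free energy.

Unfolding trajectory analysis on synthetic ground truth — Q of the
perturbed monomer as the functional property, PLS-FMA mode localisation:

```r
toy  <- make_toy_oligomer(4)
traj <- make_unfolding_trajectory(toy, n_frames = 1000, seed = 1)
cs   <- build_contacts(toy, "fold", chain = "A")
q    <- q_timeseries(traj, cs)$Q
fma  <- fit_fma(traj, q, n_components = 20,
                selection = mainchain_indices(toy, "A"))
fma
#> PLS functional mode analysis
#>   20 components, 75%/25% block split
#>   Pearson r: training 0.9981, validation 0.9831
head(mode_rmsf(fma), 4)
#>    chain resno amplitude
#> 3      A    11 0.4788463
#> 2      A    10 0.4718028
#> 24     A     9 0.4031078
#> 4      A    12 0.3860069
```

The model predicts held-out Q with r = 0.98, and the top-amplitude
residues are exactly the C/D-strand-analogue region (residues 7–14) that
the generator unfolds — the mode points at where the contacts are lost.

See `vignettes/ttr-stability-methods.Rmd` for the models, priors,
defaults and design decisions, including what the synthetic generators
do and do not emulate.

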