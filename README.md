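# ionscape

Analysis of the mobile-ion atmosphere around DNA and RNA double helices.

Nucleic acid duplexes are strongly charged polyanions — a 12-bp duplex
carries 22 phosphate groups and a net formal charge of −22 e — and their
solvated structure includes a diffuse cloud of counterions (Na⁺, K⁺,
Mg²⁺) and co-ions (Cl⁻) that screens that charge, occupies groove and
backbone binding sites, and sometimes locks into multi-atom "ion traps"
for nanoseconds at a time.  `ionscape` turns molecular-dynamics-style
trajectories of such systems (multi-model PDB, or XYZ frames with a JSON
sidecar) into the standard quantitative descriptions of that atmosphere,
for right-handed B-DNA/A-RNA and left-handed Z-DNA/Z-RNA duplexes alike:

* **Cylindrical distribution functions** — ion molarity
  c(r) = ⟨n(shell)⟩ / (N_A · π(r₂²−r₁²)·h) versus perpendicular distance
  from the fitted helical axis, with time-window convergence series;
* **Radial distribution functions** g(r) around chosen duplex atoms
  (G-O6, C-O2, OP1/OP2, the O′ backbone oxygens, …), first-peak/
  first-minimum location and coordination numbers N(r) = ρ∫g·4πr²dr;
* **Charge accumulation** Q(r): cumulative ionic charge normalized by the
  duplex net charge (−22 e for the dodecamer);
* **Occupancy** — percent of frames with ≥ 1 ion within a cutoff of a
  site (direct: 3 Å Na⁺, 3.5 Å K⁺, 5 Å hexahydrated Mg²⁺;
  water-mediated: 6 Å), per atom, per nucleotide and per groove region;
* **Residence times** τ_R from the occupancy autocorrelation
  C(t) = ⟨p(t₀)p(t₀+t)⟩ ~ exp(−t/τ_R), fitted on a 10 ps–1 ns lag grid;
* **Binding-pocket detection** — one ion simultaneously coordinated by
  several electronegative atoms (e.g. the 2×O2 + 2×O2′ trap of Z-RNA);
* **Diffusion coefficients** via Einstein MSD on unwrapped coordinates;
* **Conformational descriptors** — glycosidic χ with anti/syn
  classification (Z-form guanines are syn) and sugar pucker
  pseudorotation (C2′-endo/C3′-endo, …).

Because the trajectories such analyses are usually run on are rarely
deposited, the package ships a first-class synthetic-data module: an
idealized (CG)₆ duplex builder for all four forms, a telegraph (two-state
Markov) binding simulator, a Brownian ion simulator with optional
attractive wells, and a hydration-shell sampler — each seed-deterministic
with known ground truth, so every estimator is validated by parameter
recovery.  See the methods vignette
(`vignettes/ion-atmosphere-methods.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(ionscape)

## an idealized left-handed RNA dodecamer
dup <- build_duplex(duplex_spec("Z-RNA"))
dup
#> <Duplex> Z-RNA CGCGCGCGCGCG (510 atoms, net charge -22e)

## helix axis fitted through the base-pair reference centers
hf <- fit_axis(pair_reference_centers(dup$coords, dup$topology))
round(hf$direction, 3)
#> [1] -0.038 -0.018  0.999

## first hydration shell of a hexahydrated cation: 6 water oxygens at
## Gaussian(2.43 A, 0.05 A) radii in bulk water, 1000 configurations
ht <- hydration_trajectory(n_frames = 1000, n_shell = 6, d0 = 2.43,
                           sigma = 0.05, rho_bulk = 0.0334, box = 20,
                           seed = 1)
rdf <- compute_rdf(ht, "WAT-O", sites = 1L, r_max = 6, dr = 0.02)
unlist(first_peak(rdf))
#>   r_peak   height     none
#>  2.43000 19.35078  0.00000
coordination_number(rdf, first_minimum(rdf)$r_min)
#> [1] 5.998

## residence-time recovery from a telegraph binding trace with known
## mean bound duration 2.26 ns (a strong phosphate-site regime)
tg <- simulate_telegraph(telegraph_spec(k_on = 1 / 2.26, k_off = 1 / 2.26,
                                        dt = 10, T = 452, seed = 2))
trace <- occupancy_trace(tg$traj, site = 1L, species = "Na+",
                         window = FALSE)
occupancy_fraction(trace)
#> [1] 46.7733
residence_time(trace)
#> <ResidenceResult> tau_R = 2.04 ns (fit R^2 = 1.000, mean occupancy 46.8%)
```

The RDF first peak sits at the construction distance (2.43 Å, the
measured cation–water first-shell scale), the coordination number
integrates to the six shell waters, and the fitted residence time
recovers the 2.26 ns ground truth to within the estimator's single-trace
spread (the 20-seed median is accurate to a few percent; see the test
suite).

## Command line

A single entry point drives simulation and reporting:

```sh
ionscape simulate  --config cfg.json --seed 7 --out out/      # write PDB + truth TSV
ionscape report    --config cfg.json --seed 7 --out out/      # full TSV bundle
ionscape cdf|rdf|charge|occupancy|residence|pockets|bindstats|structure|diffusion ...
```

Outputs are TSV files with `#`-prefixed metadata headers (units: Å, ns,
percent) plus a `manifest.json` recording version, seed and a config
hash; identical config + seed reproduces the bundle byte-for-byte.

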